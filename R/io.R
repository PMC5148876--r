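#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(set))) stop("duplicate FASTA ids in ", path)
  stats::setNames(toupper(as.character(set)), names(set))
}

#' Write sequences to FASTA (wrapped at 80 columns)
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must be uniquely named")
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a BED-like interval table (0-based half-open)
#'
#' @param path TSV with columns `scaffold`, `start`, `end`, `type`
#'   (`#`-prefixed header/comment lines allowed).
#' @param seq_lengths optional named vector of scaffold lengths for bounds
#'   checking.
#' @return data.frame sorted by scaffold then start.
#' @export
read_intervals <- function(path, seq_lengths = NULL) {
  iv <- utils::read.delim(path, comment.char = "#", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("scaffold", "start", "end") %in% names(iv)))
  if (!"type" %in% names(iv)) iv$type <- NA_character_
  validate_intervals(iv, seq_lengths)
  iv <- iv[order(iv$scaffold, iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

#' Validate a 0-based half-open interval table
#' @param iv interval data.frame.
#' @param seq_lengths optional named scaffold lengths.
#' @return `iv` invisibly; errors describe the offending rows.
#' @export
validate_intervals <- function(iv, seq_lengths = NULL) {
  bad <- which(iv$end <= iv$start | iv$start < 0)
  if (length(bad)) {
    stop("malformed interval(s) (need 0 <= start < end) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(seq_lengths)) {
    over <- which(iv$end > seq_lengths[iv$scaffold])
    if (length(over)) {
      stop("interval(s) beyond scaffold end at row(s): ",
           paste(utils::head(over, 5), collapse = ", "))
    }
  }
  invisible(iv)
}

#' Write a BED-like interval table
#' @param iv interval data.frame (`scaffold`, `start`, `end`, `type`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(iv, path) {
  validate_intervals(iv)
  utils::write.table(iv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a labeled numeric matrix from TSV
#'
#' @param path TSV with a header of column labels and row labels in the
#'   first column.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate row labels in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate column labels in ", path)
  if (!is.numeric(m)) stop("non-numeric cells in matrix ", path)
  rownames(m) <- ids
  m
}

#' Write a labeled numeric matrix to TSV
#' @param m matrix with row and column names.
#' @param path output path.
#' @param id_label header label for the row-name column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_label = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_label
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Percentage with half-up rounding
#'
#' Computes `100 * numerator / denominator` rounded half-up (away from
#' zero) to `decimals` places, matching how published genome summary
#' ratios are conventionally printed (bankers' rounding would disagree on
#' exact halves).
#'
#' @param numerator non-negative number.
#' @param denominator positive number.
#' @param decimals digits after the decimal point.
#' @return numeric percentage.
#' @examples
#' proportion(12932, 20555, 1)  # 62.9
#' proportion(28045, 28092, 2)  # 99.83
#' @export
proportion <- function(numerator, denominator, decimals = 1L) {
  if (denominator <= 0) stop("denominator must be > 0")
  if (numerator < 0) stop("numerator must be >= 0")
  x <- 100 * numerator / denominator
  f <- 10^decimals
  floor(x * f + 0.5) / f
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates every synthetic input under one master seed and runs the
#' corresponding analysis stages: RIP dinucleotide fold change, HGT
#' candidate screen, ortholog lifestyle enrichment with PCA placement,
#' annotation Z-test/fold enrichment, and the shipped secondary-metabolite
#' classifier golden table. The report is deterministic for a given
#' configuration (no timestamps).
#'
#' @param cfg a [sim_config()].
#' @param panel a [species_panel()].
#' @param outdir optional directory; when given, the report is written as
#'   `report.json` plus TSV tables.
#' @param stages character subset of
#'   `c("rip", "hgt", "clusters", "domains", "smclass")`.
#' @return named list report.
#' @export
run_pipeline <- function(cfg = sim_config(), panel = species_panel(),
                         outdir = NULL,
                         stages = c("rip", "hgt", "clusters", "domains",
                                    "smclass")) {
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list(version = as.character(utils::packageVersion("endosig")),
                 seed = cfg$seed)

  if ("rip" %in% stages) {
    genome <- simulate_ripped_genome(cfg)
    reps <- count_dinucleotides(repeat_sequences(genome))
    ctrl <- count_dinucleotides(
      sample_controls(genome, seed = .stage_seed(cfg, "controls")))
    fc <- fold_change(reps, ctrl)
    report$rip <- list(
      fold_change = fc,
      tpa_fold = fc$fold[fc$dinucleotide == "TA"],
      cpa_fold = fc$fold[fc$dinucleotide == "CA"])
  }
  if ("hgt" %in% stages) {
    sim <- simulate_hit_tables(cfg)
    calls <- lapply(sim$tables, function(tab) {
      call_candidate(filter_hits(tab))
    })
    flagged <- names(calls)[vapply(calls, `[[`, TRUE, "is_candidate")]
    planted <- sim$truth$hgt_genes
    report$hgt <- list(
      n_candidates = length(flagged),
      candidates = flagged,
      recall = if (length(planted)) mean(planted %in% flagged) else NA_real_,
      false_positives = setdiff(flagged, planted))
  }
  if ("clusters" %in% stages) {
    sim <- simulate_cluster_matrix(panel, cfg)
    sel <- select_enriched_clusters(sim$matrix, panel,
                                    enrichment_rule("pathogen"))
    pca <- pca_placement(t(sim$matrix[sel, , drop = FALSE]), panel)
    report$clusters <- list(
      n_selected = length(sel),
      recall = if (length(sim$truth$pathogen))
                 mean(sim$truth$pathogen %in% sel) else NA_real_,
      sharing = sharing_table(sim$matrix),
      focal_nearest = unname(pca$nearest_centroid[focal_species(panel)]))
  }
  if ("domains" %in% stages) {
    sim <- simulate_annotation_counts(panel, cfg)
    res <- ztest_enrichment(sim$counts, focal_species(panel))
    over <- res$accession[res$status %in% c("over", "degenerate_over")]
    report$domains <- list(
      n_over = length(over),
      recall = if (length(sim$truth$accessions))
                 mean(sim$truth$accessions %in% over) else NA_real_,
      saturation = saturation_curve(sim$counts))
  }
  if ("smclass" %in% stages) {
    tab <- classify_sm_genes(sm_key_gene_table())
    report$smclass <- list(
      n_genes = nrow(tab),
      agreement = mean(tab$predicted_class == tab$class),
      n_nonreducing_pks = sum(tab$predicted_class ==
                              "nonreducing type I PKS"))
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    slim <- report
    slim$clusters$sharing <- NULL
    jsonlite::write_json(slim, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(report$rip)) {
      utils::write.table(report$rip$fold_change,
                         file.path(outdir, "rip_fold_change.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(report$clusters)) {
      write_matrix(report$clusters$sharing,
                   file.path(outdir, "cluster_sharing.tsv"),
                   id_label = "species")
    }
  }
  report
}
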