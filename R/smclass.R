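.sm_vocabulary <- c("SAT", "KS", "AT", "DH", "MT", "ER", "KR", "PT", "T",
                    "TE", "TH", "C", "A", "R", "DUF", "Kinase",
                    "Acyltransferase")

#' Classify a secondary-metabolite key gene from its domain architecture
#'
#' Decision rules over the ordered domain symbols of PKS/NRPS key enzymes,
#' applied as a strict priority:
#' \enumerate{
#'   \item KS together with both C and A: PKS-NRPS hybrid.
#'   \item KS (otherwise): type I PKS, nonreducing when neither KR nor ER
#'     is present, reducing otherwise (a trailing C on a reducing PKS, as
#'     in lovastatin-nonaketide-like synthases, does not make it a hybrid
#'     without an adenylation domain).
#'   \item AT with a reducing domain (KR or ER) but no KS: reducing type I
#'     PKS (KS-less PKS remnant).
#'   \item C with A and T: NRPS.
#'   \item A with T (no C, no KS): NRPS-like (A-T-R, A-T-TE, A-T-DUF and
#'     variants).
#'   \item otherwise unclassified.
#' }
#'
#' @param arch hyphen-joined domain string (e.g. `"A-T-R"`) or character
#'   vector of domain symbols. Allowed symbols: SAT, KS, AT, DH, MT, ER,
#'   KR, PT, T, TE, TH, C, A, R, DUF, Kinase, Acyltransferase.
#' @return single class label: `"NRPS"`, `"NRPS-like"`,
#'   `"PKS-NRPS hybrid"`, `"nonreducing type I PKS"`,
#'   `"reducing type I PKS"`, or `"unclassified"`.
#' @examples
#' classify_architecture("A-T-R")                  # NRPS-like
#' classify_architecture("SAT-KS-AT-PT-T-MT-TE")   # nonreducing type I PKS
#' classify_architecture("KS-AT-DH-MT-ER-KR-T")    # reducing type I PKS
#' @export
classify_architecture <- function(arch) {
  if (length(arch) == 1L && grepl("-", arch, fixed = TRUE)) {
    arch <- strsplit(arch, "-", fixed = TRUE)[[1]]
  }
  arch <- trimws(arch)
  if (length(arch) == 0L || !any(nzchar(arch))) {
    stop("empty domain architecture")
  }
  bad <- setdiff(arch, .sm_vocabulary)
  if (length(bad)) {
    stop("unknown domain symbol(s): ", paste(bad, collapse = ", "))
  }
  has <- function(s) s %in% arch
  if (has("KS") && has("C") && has("A")) return("PKS-NRPS hybrid")
  if (has("KS")) {
    if (!has("KR") && !has("ER")) return("nonreducing type I PKS")
    return("reducing type I PKS")
  }
  if (has("AT") && (has("KR") || has("ER"))) return("reducing type I PKS")
  if (has("C") && has("A") && has("T")) return("NRPS")
  if (has("A") && has("T")) return("NRPS-like")
  "unclassified"
}

#' Classify a table of secondary-metabolite key genes
#'
#' Vectorized wrapper around [classify_architecture()]. Genes without a
#' domain string but with an InterPro-style tag class (type III PKS, DMATS,
#' terpene synthases) are passed through unchanged via the `ipr_class`
#' column.
#'
#' @param genes data.frame with columns `gene`, `architecture`
#'   (hyphen-joined; may be empty), and optionally `ipr_class` for
#'   pass-through classes.
#' @return the input with an added `predicted_class` column.
#' @export
classify_sm_genes <- function(genes) {
  stopifnot(all(c("gene", "architecture") %in% names(genes)))
  pred <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (nzchar(genes$architecture[i])) {
      pred[i] <- classify_architecture(genes$architecture[i])
    } else if (!is.null(genes$ipr_class) && nzchar(genes$ipr_class[i])) {
      pred[i] <- genes$ipr_class[i]
    } else {
      pred[i] <- "unclassified"
    }
  }
  genes$predicted_class <- pred
  genes
}

#' Curated secondary-metabolite key genes of the focal endophyte genome
#'
#' Loads the shipped table of 58 curated PKS/NRPS/terpene key genes of the
#' Phialocephala subalpina genome with their published class labels and
#' domain architectures, used as a golden file for the classifier.
#'
#' @return data.frame with columns `gene`, `class`, `length_aa`,
#'   `architecture`, `ipr_class`.
#' @export
sm_key_gene_table <- function() {
  path <- system.file("extdata", "psubalpina_sm_key_genes.tsv",
                      package = "endosig")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = NULL)
}

#' Detect putative secondary-metabolite clusters around key genes
#'
#' Scans up to `window_genes` genes up- and downstream of every key gene
#' for genes encoding tailoring enzymes (acyl-/methyltransferases,
#' oxidoreductases, cytochrome P450s, transcription factors). A cluster is
#' reported when at least two tailoring genes fall in the window; it spans
#' the maximal run from the first to the last qualifying gene (key gene
#' included).
#'
#' @param nbhd data.frame ordered by coordinate within scaffold, with
#'   columns `scaffold`, `gene`, `tailoring` (logical).
#' @param key_genes character vector of key-gene ids (must be in `nbhd`).
#' @param window_genes window half-width in genes.
#' @param min_tailoring minimum tailoring genes required in the window.
#' @return data.frame with one row per detected cluster: `key_gene`,
#'   `scaffold`, `n_tailoring`, `members` (comma-joined gene ids from first
#'   to last qualifying gene).
#' @export
detect_sm_clusters <- function(nbhd, key_genes, window_genes = 10L,
                               min_tailoring = 2L) {
  stopifnot(all(c("scaffold", "gene", "tailoring") %in% names(nbhd)))
  missing <- setdiff(key_genes, nbhd$gene)
  if (length(missing)) {
    stop("key gene(s) absent from neighborhood: ",
         paste(missing, collapse = ", "))
  }
  out <- list()
  for (kg in key_genes) {
    scf <- nbhd$scaffold[nbhd$gene == kg]
    sub <- nbhd[nbhd$scaffold == scf, , drop = FALSE]
    i <- match(kg, sub$gene)
    lo <- max(1L, i - window_genes)
    hi <- min(nrow(sub), i + window_genes)
    win <- lo:hi
    tailoring_idx <- win[sub$tailoring[win] & win != i]
    if (length(tailoring_idx) >= min_tailoring) {
      qual <- sort(c(i, tailoring_idx))
      span <- qual[1]:qual[length(qual)]
      out[[length(out) + 1L]] <- data.frame(
        key_gene = kg, scaffold = scf,
        n_tailoring = length(tailoring_idx),
        members = paste(sub$gene[span], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(key_gene = character(), scaffold = character(),
                      n_tailoring = integer(), members = character()))
  }
  do.call(rbind, out)
}

#' Median copy numbers of gene families across species
#'
#' Summarizes a gene family x species copy-number table by the median over
#' all species columns (focal species included; even-sized sets use the
#' mean of the central pair) plus the range. Ambiguous cells such as
#' `"2(3)"` are resolved to their first integer with a warning.
#'
#' @param counts data.frame whose non-numeric id columns are given in
#'   `id_cols`; all remaining columns are species copy numbers (integer or
#'   character).
#' @param id_cols names of identifier columns (default: all non-count-like
#'   columns `mechanism`/`gene`/`family` that are present).
#' @return data.frame with the id columns plus `median`, `min`, `max`.
#' @export
copy_number_summary <- function(counts,
                                id_cols = intersect(c("mechanism", "gene",
                                                      "family"),
                                                    names(counts))) {
  species_cols <- setdiff(names(counts), c(id_cols, "printed_median"))
  vals <- counts[species_cols]
  resolve <- function(x) {
    if (is.numeric(x)) return(x)
    ambiguous <- grepl("\\(", x)
    if (any(ambiguous)) {
      warning("ambiguous copy-number cell(s) resolved to first integer: ",
              paste(unique(x[ambiguous]), collapse = ", "))
    }
    as.integer(sub("^([0-9]+).*$", "\\1", x))
  }
  mat <- vapply(vals, resolve, numeric(nrow(counts)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(counts))
  out <- counts[id_cols]
  out$median <- apply(mat, 1, stats::median)
  out$min <- apply(mat, 1, min)
  out$max <- apply(mat, 1, max)
  out
}

#' RNAi and RIP core-protein copy numbers across fungal genomes
#'
#' Loads the shipped copy-number table of RNAi (Argonaute, Dicer, RdRP) and
#' RIP (Dnmt1-family cytosine methyltransferase) core genes across nine
#' fungal genomes, including the published median column for comparison.
#'
#' @return data.frame with columns `mechanism`, `gene`, nine species codes,
#'   and `printed_median`.
#' @export
rnai_rip_copy_table <- function() {
  path <- system.file("extdata", "psubalpina_rnai_rip_copy_numbers.tsv",
                      package = "endosig")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
}
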