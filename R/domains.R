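#' Z-test enrichment of focal-species annotation counts
#'
#' For each accession, the focal species' count is compared against the
#' mean and sample standard deviation (n - 1) of the comparison species via
#' a Z statistic with a two-sided normal p-value. No multiple-testing
#' correction is applied by default (raw flagged counts are the headline
#' statistic); Benjamini-Hochberg is available. A zero comparison standard
#' deviation yields status `ns` when the focal count equals the common
#' value and `degenerate_over`/`degenerate_under` otherwise (counted as
#' significant).
#'
#' @param counts non-negative integer accession x species matrix.
#' @param focal focal species column name (excluded from the mean/sd).
#' @param alpha significance level.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per accession: `focal`, `mean`, `sd`,
#'   `z`, `p`, `fold`, `status` in `over`, `under`, `ns`,
#'   `degenerate_over`, `degenerate_under`.
#' @export
ztest_enrichment <- function(counts, focal, alpha = 0.05,
                             p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(focal %in% colnames(counts))
  comp <- counts[, setdiff(colnames(counts), focal), drop = FALSE]
  if (ncol(comp) < 3L) stop("need at least 3 comparison species")
  f <- counts[, focal]
  mu <- rowMeans(comp)
  sdv <- apply(comp, 1, stats::sd)
  z <- ifelse(sdv > 0, (f - mu) / sdv, NA_real_)
  p <- 2 * stats::pnorm(-abs(z))
  if (p_adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  status <- rep("ns", length(f))
  status[!is.na(p) & p < alpha & f > mu] <- "over"
  status[!is.na(p) & p < alpha & f < mu] <- "under"
  status[sdv == 0 & f > mu] <- "degenerate_over"
  status[sdv == 0 & f < mu] <- "degenerate_under"
  data.frame(accession = rownames(counts),
             focal = f, mean = mu, sd = sdv, z = z, p = p,
             fold = ifelse(mu > 0, f / mu, NA_real_),
             status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Accessions encoded more than `fold_threshold`-fold in the focal species
#'
#' Selects accessions whose focal count strictly exceeds
#' `fold_threshold` times the comparison mean. Accessions absent from all
#' comparison species (zero mean) qualify when the focal count reaches
#' `min_absolute`.
#'
#' @inheritParams ztest_enrichment
#' @param fold_threshold strict fold threshold (> 1).
#' @param min_absolute minimum focal count for zero-mean accessions.
#' @return character vector of qualifying accession ids.
#' @export
fold_screen <- function(counts, focal, fold_threshold, min_absolute = 3L) {
  stopifnot(fold_threshold > 1, focal %in% colnames(counts))
  comp <- counts[, setdiff(colnames(counts), focal), drop = FALSE]
  f <- counts[, focal]
  mu <- rowMeans(comp)
  pass <- ifelse(mu > 0, f > fold_threshold * mu, f >= min_absolute)
  rownames(counts)[pass]
}

#' Accessions overrepresented in one lifestyle's comparison species
#'
#' An accession passes when its mean count over the target-lifestyle
#' species strictly exceeds `fold_threshold` times its mean over all other
#' comparison species; the focal species is excluded from both sides. The
#' selected species x accession submatrix is the input for the downstream
#' PCA placement.
#'
#' @inheritParams ztest_enrichment
#' @param panel a [species_panel()].
#' @param target_lifestyle `"pathogen"` or `"saprotroph"` (any non-focal
#'   lifestyle present in the panel).
#' @param fold_threshold strict fold threshold.
#' @return character vector of qualifying accession ids.
#' @export
lifestyle_fold_screen <- function(counts, panel, target_lifestyle,
                                  fold_threshold = 2) {
  panel <- assert_panel(panel)
  tgt <- lifestyle_species(panel, target_lifestyle)
  if (length(tgt) == 0L) stop("empty lifestyle group: ", target_lifestyle)
  comp <- setdiff(panel$code[panel$lifestyle != "focal"], tgt)
  stopifnot(all(c(tgt, comp) %in% colnames(counts)))
  mu_t <- rowMeans(counts[, tgt, drop = FALSE])
  mu_o <- rowMeans(counts[, comp, drop = FALSE])
  rownames(counts)[mu_t > fold_threshold * mu_o]
}

#' Annotation saturation summary per species
#'
#' For each species, the total number of annotated accession instances
#' (column sum) and the number of distinct accessions (count >= 1); used to
#' check whether distinct-accession counts plateau across genomes.
#'
#' @param counts accession x species count matrix.
#' @return data.frame with columns `species`, `total`, `distinct`.
#' @export
saturation_curve <- function(counts) {
  data.frame(species = colnames(counts),
             total = as.integer(colSums(counts)),
             distinct = as.integer(colSums(counts >= 1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Roll enriched accessions up to GO terms
#'
#' Counts, per GO term, the number of distinct enriched accessions mapping
#' to it; an accession mapped to several terms contributes once to each,
#' and accessions without any mapping are collected in an `"NA"` bin.
#' Optionally sums per-accession gene-model counts into the terms.
#'
#' @param accessions character vector of enriched accession ids.
#' @param accession_to_go data.frame with columns `accession`, `go_id`.
#' @param accession_gene_counts optional named numeric vector of focal
#'   gene-model counts per accession, summed per term.
#' @return data.frame with columns `go_id`, `n_accessions` (and
#'   `n_gene_models` when counts are supplied), ranked by accession count
#'   descending.
#' @export
go_rollup <- function(accessions, accession_to_go,
                      accession_gene_counts = NULL) {
  stopifnot(all(c("accession", "go_id") %in% names(accession_to_go)))
  map <- unique(accession_to_go[accession_to_go$accession %in% accessions,
                                c("accession", "go_id")])
  unmapped <- setdiff(accessions, map$accession)
  if (length(unmapped)) {
    map <- rbind(map, data.frame(accession = unmapped, go_id = "NA",
                                 stringsAsFactors = FALSE))
  }
  if (nrow(map) == 0L) {
    return(data.frame(go_id = character(), n_accessions = integer()))
  }
  out <- stats::aggregate(accession ~ go_id, data = map,
                          FUN = function(a) length(unique(a)))
  names(out) <- c("go_id", "n_accessions")
  if (!is.null(accession_gene_counts)) {
    out$n_gene_models <- vapply(out$go_id, function(g) {
      sum(accession_gene_counts[map$accession[map$go_id == g]], na.rm = TRUE)
    }, numeric(1))
  }
  out <- out[order(-out$n_accessions, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
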