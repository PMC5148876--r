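#' Lifestyle-enrichment rule for ortholog clusters
#'
#' The pathogen preset requires at least 4 of the 5 pathogens present, at
#' most one saprotroph, at most one mycorrhizal species, and the focal
#' species present. The saprotroph preset is the proportional analogue
#' (at least 5 of the 6 saprotrophs, pathogens and mycorrhizal species each
#' capped at 1, focal required); all thresholds can be overridden.
#'
#' @param target target lifestyle (`"pathogen"` or `"saprotroph"`).
#' @param min_present_in_target minimum number of target-lifestyle species
#'   present (defaults: group size minus one).
#' @param max_present_per_other named integer vector of per-lifestyle caps
#'   for the other non-focal lifestyles (default 1 each).
#' @param require_focal must the focal species be present?
#' @return list of class `enrichment_rule`.
#' @export
enrichment_rule <- function(target = c("pathogen", "saprotroph"),
                            min_present_in_target = NULL,
                            max_present_per_other = NULL,
                            require_focal = TRUE) {
  target <- match.arg(target)
  if (is.null(min_present_in_target)) {
    min_present_in_target <- switch(target, pathogen = 4L, saprotroph = 5L)
  }
  if (is.null(max_present_per_other)) {
    max_present_per_other <- switch(target,
      pathogen = c(saprotroph = 1L, mycorrhizal = 1L),
      saprotroph = c(pathogen = 1L, mycorrhizal = 1L))
  }
  structure(list(target = target,
                 min_present_in_target = as.integer(min_present_in_target),
                 max_present_per_other = max_present_per_other,
                 require_focal = isTRUE(require_focal)),
            class = "enrichment_rule")
}

#' Select lifestyle-enriched ortholog clusters
#'
#' Applies an [enrichment_rule()] row-wise to a binary cluster x species
#' presence/absence matrix.
#'
#' @param m binary matrix (clusters x species) with species codes as column
#'   names matching the panel.
#' @param panel a [species_panel()].
#' @param rule an [enrichment_rule()].
#' @return character vector of qualifying cluster ids (row names).
#' @export
select_enriched_clusters <- function(m, panel, rule) {
  panel <- assert_panel(panel)
  stopifnot(inherits(rule, "enrichment_rule"))
  if (!all(panel$code %in% colnames(m))) {
    stop("matrix columns must cover all panel species codes")
  }
  if (!all(m %in% c(0, 1))) stop("matrix cells must be 0/1")
  known <- unique(panel$lifestyle)
  bad <- setdiff(c(rule$target, names(rule$max_present_per_other)), known)
  if (length(bad)) stop("unknown lifestyle in rule: ",
                        paste(bad, collapse = ", "))
  tgt <- lifestyle_species(panel, rule$target)
  ok <- rowSums(m[, tgt, drop = FALSE]) >= rule$min_present_in_target
  for (ls in names(rule$max_present_per_other)) {
    sp <- lifestyle_species(panel, ls)
    ok <- ok & rowSums(m[, sp, drop = FALSE]) <= rule$max_present_per_other[[ls]]
  }
  if (rule$require_focal) ok <- ok & m[, focal_species(panel)] == 1
  rownames(m)[ok]
}

#' Pairwise cluster-sharing table
#'
#' Number of ortholog clusters containing both species of every pair; the
#' diagonal holds each species' total cluster count.
#'
#' @param m binary cluster x species matrix.
#' @return symmetric integer matrix (species x species).
#' @export
sharing_table <- function(m) {
  if (!all(m %in% c(0, 1))) stop("matrix cells must be 0/1")
  crossprod(m)
}

#' PCA placement of species with lifestyle centroids
#'
#' Centered (by default unscaled) principal component analysis of a species
#' x feature matrix, with a deterministic sign convention (within each PC
#' the loading of largest magnitude is positive). Lifestyle centroids are
#' computed in PC1/PC2 space excluding the focal species, and each species
#' is assigned its nearest centroid.
#'
#' @param x numeric species x feature matrix with species row names.
#' @param panel a [species_panel()].
#' @param scale. scale features to unit variance (correlation-mode PCA)?
#' @return list of class `pca_placement` with `scores`, `loadings`,
#'   `var_explained`, `centroids`, `nearest_centroid`, `centered` (the
#'   centered input), and `degenerate` (TRUE when the matrix has no
#'   variance).
#' @export
pca_placement <- function(x, panel, scale. = FALSE) {
  panel <- assert_panel(panel)
  stopifnot(is.matrix(x), nrow(x) >= 2, ncol(x) >= 2, !anyNA(x))
  if (!all(rownames(x) %in% panel$code)) {
    stop("row names of x must be panel species codes")
  }
  centered <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) {
    return(structure(list(scores = NULL, loadings = NULL,
                          var_explained = NULL, centroids = NULL,
                          nearest_centroid = NULL, centered = centered,
                          degenerate = TRUE),
                     class = "pca_placement"))
  }
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) stop("zero-variance feature with scale. = TRUE")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  # sign convention: largest-magnitude loading positive within each PC
  for (k in seq_len(ncol(p$rotation))) {
    lead <- which.max(abs(p$rotation[, k]))
    if (p$rotation[lead, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  k2 <- min(2L, ncol(p$x))
  sc2 <- p$x[, seq_len(k2), drop = FALSE]
  non_focal <- panel[panel$lifestyle != "focal", ]
  lifestyles <- unique(non_focal$lifestyle)
  centroids <- do.call(rbind, lapply(lifestyles, function(ls) {
    sp <- intersect(lifestyle_species(panel, ls), rownames(sc2))
    if (length(sp) == 0L) return(NULL)
    colMeans(sc2[sp, , drop = FALSE])
  }))
  rownames(centroids) <- lifestyles[vapply(lifestyles, function(ls) {
    length(intersect(lifestyle_species(panel, ls), rownames(sc2))) > 0
  }, logical(1))]
  nearest <- apply(sc2, 1, function(pt) {
    d <- sqrt(rowSums(sweep(centroids, 2, pt)^2))
    rownames(centroids)[which.min(d)]
  })
  structure(list(scores = p$x, loadings = p$rotation,
                 var_explained = ve, centroids = centroids,
                 nearest_centroid = nearest, centered = centered,
                 degenerate = FALSE),
            class = "pca_placement")
}

#' Most frequent functional categories among a gene set
#'
#' Counts, for each functional category, the number of distinct selected
#' genes annotated with it; every (gene, category) pair is considered only
#' once. Categories are ranked by gene count (descending, ties broken by
#' category id ascending) and the top `k` are returned.
#'
#' @param gene_to_categories data.frame with columns `gene` and `category`
#'   (repeated pairs allowed).
#' @param selected_genes character vector of genes to tally.
#' @param k number of categories to return.
#' @return data.frame with columns `category` and `n_genes`.
#' @export
funcat_top_categories <- function(gene_to_categories, selected_genes,
                                  k = 10L) {
  stopifnot(all(c("gene", "category") %in% names(gene_to_categories)))
  map <- unique(gene_to_categories[gene_to_categories$gene %in%
                                   selected_genes, c("gene", "category")])
  if (nrow(map) == 0L) {
    return(data.frame(category = character(), n_genes = integer()))
  }
  counts <- as.data.frame(table(map$category), stringsAsFactors = FALSE)
  names(counts) <- c("category", "n_genes")
  counts$n_genes <- as.integer(counts$n_genes)
  counts <- counts[order(-counts$n_genes, counts$category), , drop = FALSE]
  rownames(counts) <- NULL
  utils::head(counts, k)
}
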