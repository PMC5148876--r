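#' Default CAZyme substrate-class map for plant cell wall degradation
#'
#' The canonical assignment of CAZyme families to plant cell wall
#' substrates: cellulose, hemicellulose, pectin, cutin, and a class of
#' families likely acting on several of these substrates.
#'
#' @return named list of character vectors (class -> family codes).
#' @export
default_substrate_map <- function() {
  list(cellulose = c("GH6", "GH7", "GH45"),
       hemicellulose = c("GH10", "GH11", "GH26", "GH31", "GH67", "GH115",
                         "GH134"),
       pectin = c("GH28", "GH53", "GH78", "GH79", "GH88", "GH105", "GH106",
                  "GH127", "PL1", "PL3", "PL4", "PL9", "PL11", "CE8",
                  "CE12"),
       cutin = c("CE5"),
       multiple = c("GH12", "GH30", "GH43", "GH5", "GH51", "GH54", "GH62",
                    "GH74", "GH93"))
}

.check_family_codes <- function(fams, context = "") {
  bad <- fams[!grepl("^(GH|GT|PL|CE|AA|CBM)[0-9]+$", fams)]
  if (length(bad)) {
    stop("malformed CAZyme family code(s) ", context, ": ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(TRUE)
}

#' Per-species CAZyme module counts
#'
#' Counts every module occurrence individually (a gene carrying the same
#' family twice contributes two modules), the convention under which a
#' genome's module total exceeds its CAZyme gene count.
#'
#' @param ann data.frame with columns `species`, `gene`, `modules`
#'   (semicolon-joined family codes, e.g. `"GH5;GH5;CBM1"`).
#' @return list with `counts` (species x family integer matrix) and
#'   `class_totals` (species x enzyme-class matrix over GH, GT, PL, CE, AA,
#'   CBM).
#' @export
module_counts <- function(ann) {
  stopifnot(all(c("species", "gene", "modules") %in% names(ann)))
  species <- sort(unique(ann$species))
  mods <- strsplit(ann$modules, ";", fixed = TRUE)
  for (i in seq_along(mods)) {
    mods[[i]] <- trimws(mods[[i]])
    mods[[i]] <- mods[[i]][nzchar(mods[[i]])]
    .check_family_codes(mods[[i]],
                        context = paste0("(gene ", ann$gene[i], ")"))
  }
  long <- data.frame(species = rep(ann$species, lengths(mods)),
                     family = unlist(mods), stringsAsFactors = FALSE)
  fams <- sort(unique(long$family))
  counts <- matrix(0L, length(species), length(fams),
                   dimnames = list(species, fams))
  if (nrow(long)) {
    tab <- table(long$species, long$family)
    counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  cls <- sub("[0-9]+$", "", fams)
  class_levels <- c("GH", "GT", "PL", "CE", "AA", "CBM")
  class_totals <- sapply(class_levels, function(cl) {
    rowSums(counts[, cls == cl, drop = FALSE])
  })
  if (is.null(dim(class_totals))) {
    class_totals <- matrix(class_totals, nrow = length(species),
                           dimnames = list(species, class_levels))
  }
  list(counts = counts, class_totals = class_totals)
}

#' Substrate-class totals per species
#'
#' Sums module counts over the families of each substrate class. Families
#' outside the map are excluded from the classes but reported as an
#' `unassigned` total per species.
#'
#' @param counts species x family matrix (see [module_counts()]).
#' @param map substrate-class map (default [default_substrate_map()]);
#'   classes must be disjoint.
#' @return species x (classes + `unassigned`) numeric matrix.
#' @export
substrate_profile <- function(counts, map = default_substrate_map()) {
  all_fams <- unlist(map, use.names = FALSE)
  .check_family_codes(all_fams, context = "in substrate map")
  if (anyDuplicated(all_fams)) {
    stop("substrate classes must be disjoint; duplicated: ",
         paste(unique(all_fams[duplicated(all_fams)]), collapse = ", "))
  }
  prof <- sapply(map, function(fams) {
    rowSums(counts[, intersect(fams, colnames(counts)), drop = FALSE])
  })
  if (is.null(dim(prof))) {
    prof <- matrix(prof, nrow = nrow(counts),
                   dimnames = list(rownames(counts), names(map)))
  }
  unassigned <- rowSums(counts[, setdiff(colnames(counts), all_fams),
                               drop = FALSE])
  cbind(prof, unassigned = unassigned)
}
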