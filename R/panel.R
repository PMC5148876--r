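#' Species panel with lifestyle labels
#'
#' Constructs the ordered species panel used throughout the comparative
#' analyses. The default panel holds the 14 ascomycete species of the study
#' design: five plant pathogens, six soil/litter saprotrophs, two
#' ectomycorrhizal species, and one focal root endophyte.
#'
#' @param codes character vector of unique short species codes.
#' @param lifestyles character vector (same length) with values from
#'   `"pathogen"`, `"saprotroph"`, `"mycorrhizal"`, `"focal"`.
#'
#' @return A data.frame of class `species_panel` with columns `code` and
#'   `lifestyle`. Exactly one species must be `focal`.
#' @examples
#' panel <- species_panel()
#' table(panel$lifestyle)
#' @export
species_panel <- function(codes = NULL, lifestyles = NULL) {
  if (is.null(codes)) {
    codes <- c("Bc", "Ssc", "Bg", "Mb", "Fo",
               "Af", "Tr", "Chg", "Pc", "Gl", "Om",
               "Tm", "Ceg", "Ps")
    lifestyles <- c(rep("pathogen", 5), rep("saprotroph", 6),
                    rep("mycorrhizal", 2), "focal")
  }
  stopifnot(length(codes) == length(lifestyles))
  lifestyles <- match.arg(lifestyles, c("pathogen", "saprotroph",
                                        "mycorrhizal", "focal"),
                          several.ok = TRUE)
  if (anyDuplicated(codes)) {
    stop("species codes must be unique")
  }
  if (sum(lifestyles == "focal") != 1L) {
    stop("the panel must contain exactly one focal species")
  }
  panel <- data.frame(code = as.character(codes),
                      lifestyle = lifestyles,
                      stringsAsFactors = FALSE)
  class(panel) <- c("species_panel", "data.frame")
  panel
}

#' @export
print.species_panel <- function(x, ...) {
  cat("Species panel:", nrow(x), "species (",
      paste(names(table(x$lifestyle)), table(x$lifestyle),
            sep = "=", collapse = ", "), ")\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Code of the focal species in a panel
#' @param panel a [species_panel()].
#' @return single character code.
#' @export
focal_species <- function(panel) {
  panel$code[panel$lifestyle == "focal"]
}

#' Species codes belonging to a lifestyle
#' @param panel a [species_panel()].
#' @param lifestyle one of `"pathogen"`, `"saprotroph"`, `"mycorrhizal"`,
#'   `"focal"`.
#' @return character vector of codes.
#' @export
lifestyle_species <- function(panel, lifestyle) {
  lifestyle <- match.arg(lifestyle,
                         c("pathogen", "saprotroph", "mycorrhizal", "focal"))
  panel$code[panel$lifestyle == lifestyle]
}

assert_panel <- function(panel) {
  if (!inherits(panel, "species_panel")) {
    panel <- species_panel(panel$code, panel$lifestyle)
  }
  panel
}
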