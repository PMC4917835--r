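# Frozen element data (version 1): IUPAC conventional standard atomic
# weights (abridged, 2021) and the integer mass number of the most
# abundant isotope. Kept in-package so descriptor values are reproducible
# without any external resource.
.ELEMENT_DATA_VERSION <- "1"

.ELEMENTS <- data.frame(
  symbol  = c("C", "H", "N", "O", "S", "F", "Cl", "Br", "I", "Se", "P"),
  average = c(12.011, 1.008, 14.007, 15.999, 32.06, 18.998,
              35.45, 79.904, 126.904, 78.971, 30.974),
  nominal = c(12L, 1L, 14L, 16L, 32L, 19L, 35L, 79L, 127L, 80L, 31L),
  stringsAsFactors = FALSE
)

# Lowest-first feasible valence states of the standard organic valence
# model; implicit hydrogens use the smallest state that accommodates the
# explicit bonding.
.VALENCES <- list(
  C = 4L, H = 1L, N = 3L, O = 2L, S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L, Se = 2L, P = c(3L, 5L)
)

.HALOGENS <- c("F", "Cl", "Br", "I")

#' Allowed element symbols
#'
#' The element vocabulary of the package: the ten organic-subset elements
#' commonly found in commercial building-block catalogues plus phosphorus.
#' Formulas containing any other symbol are rejected by the parsers.
#'
#' @return Character vector of IUPAC element symbols.
#' @export
#' @examples
#' allowed_elements()
allowed_elements <- function() .ELEMENTS$symbol

#' Element mass table
#'
#' Average (standard atomic weight) and nominal (most-abundant-isotope)
#' masses for the allowed element set, frozen in the package for
#' reproducibility.
#'
#' @return A `mass_table` object: list with numeric named vectors
#'   `average` and `nominal` (Da) and a `version` string.
#' @export
#' @examples
#' mass_table()$nominal[["C"]]
mass_table <- function() {
  structure(
    list(
      average = stats::setNames(.ELEMENTS$average, .ELEMENTS$symbol),
      nominal = stats::setNames(as.numeric(.ELEMENTS$nominal), .ELEMENTS$symbol),
      version = .ELEMENT_DATA_VERSION
    ),
    class = "mass_table"
  )
}

#' @export
print.mass_table <- function(x, ...) {
  cat("<mass_table> version", x$version, "-", length(x$average), "elements\n")
  print(data.frame(average = x$average, nominal = x$nominal))
  invisible(x)
}
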