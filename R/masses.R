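# Monoisotopic atomic masses (Da). Fixed constants: theoretical metabolite
# m/z values must reproduce to 4 decimals, so these are never user-settable.
MONOISOTOPIC_MASS <- c(
  C = 12.000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

#' Mass of a proton in daltons
#'
#' Used to convert a neutral monoisotopic mass into the singly protonated
#' ion m/z observed in positive-mode ESI/MALDI, \eqn{[M+H]^+}.
#' @export
PROTON_MASS <- 1.00727646

#' Parse a molecular formula string
#'
#' Accepts compact element-count notation such as `"C18H18N2O8"` or `"H2O"`;
#' an omitted count means 1. Only the elements C, H, N, O and S occurring in
#' the metabolites of the betalain pathway are accepted.
#'
#' @param text A single formula string.
#' @return A `chem_formula`: a named integer vector of element counts in Hill
#'   order (C first, then H, then remaining elements alphabetically).
#' @examples
#' parse_formula("C9H9NO5")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    stop("empty formula string")
  }
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text)) {
    stop("malformed formula string: ", sQuote(text))
  }
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1L]]
  elements <- sub("[0-9]*$", "", tokens)
  counts <- sub("^[A-Za-z]+", "", tokens)
  counts <- ifelse(nzchar(counts), as.integer(counts), 1L)
  unknown <- setdiff(elements, names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  counts <- vapply(split(counts, elements), sum, integer(1))
  counts <- counts[counts > 0L]
  if (!length(counts)) stop("formula contains no atoms")
  structure(counts[hill_order(names(counts))], class = "chem_formula")
}

hill_order <- function(elements) {
  rest <- sort(setdiff(elements, c("C", "H")))
  intersect(c("C", "H", rest), elements)
}

#' @export
format.chem_formula <- function(x, ...) {
  paste0(names(x), ifelse(x == 1L, "", x), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "  (",
      format(round(monoisotopic_mass(x), 4), nsmall = 4), " Da)\n", sep = "")
  invisible(x)
}

as_chem_formula <- function(f) {
  if (inherits(f, "chem_formula")) f else parse_formula(f)
}

#' Monoisotopic mass of a neutral molecule
#'
#' @param f A `chem_formula` or formula string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O") # 18.0106
#' @export
monoisotopic_mass <- function(f) {
  f <- as_chem_formula(f)
  sum(MONOISOTOPIC_MASS[names(f)] * as.numeric(f))
}

#' Protonated-ion m/z of a neutral molecule
#'
#' The singly charged \eqn{[M+H]^+} ion monitored in positive-mode TOF
#' analyses: neutral monoisotopic mass plus one proton.
#'
#' @inheritParams monoisotopic_mass
#' @param digits Decimals used by the rounded convenience value; metabolite
#'   tables print 4.
#' @return m/z in Da, rounded to `digits`.
#' @examples
#' protonated_mz("C18H18N2O8") # dopaxanthin, 391.1136
#' @export
protonated_mz <- function(f, digits = 4) {
  round(monoisotopic_mass(f) + PROTON_MASS, digits)
}

#' Signed relative mass error in parts per million
#'
#' @param experimental,theoretical Masses in Da; `theoretical` must be > 0.
#' @return `(experimental - theoretical) / theoretical * 1e6`.
#' @examples
#' ppm_error(391.1141, 391.1136)
#' @export
ppm_error <- function(experimental, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  (experimental - theoretical) / theoretical * 1e6
}
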