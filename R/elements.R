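# Element tables and formula string handling.
#
# The unit library is built from the elements C, H, S, O, N, P, F, Cl, Br, Si
# plus the placeholder X, which marks a connection point between a repeating
# unit and its molecular scaffold.  X behaves as a massless valence-1 atom:
# it participates in valence bookkeeping but contributes 0 Da, so the
# searched mass of a unit depends only on its real atoms (the PEG unit
# C2H4OX2 weighs 44.0262 Da, the mass of C2H4O).

# Monoisotopic masses of the most abundant isotope (AME2020), >= 7 decimals.
.MONOISOTOPIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503190,
  S  = 31.97207117354,
  O  = 15.99491461926,
  N  = 14.00307400425,
  P  = 30.97376199768,
  F  = 18.99840316207,
  Cl = 34.968852694,
  Br = 78.9183376,
  Si = 27.97692653442,
  X  = 0.0
)

#' Monoisotopic masses of the supported elements
#'
#' @return Named numeric vector of monoisotopic masses in Da (most abundant
#'   isotope). The connection placeholder `X` has mass 0.
#' @export
element_masses <- function() .MONOISOTOPIC_MASS

#' Default element table for unit library generation
#'
#' Returns the element specifications used to enumerate candidate repeat-unit
#' formulas: each element's allowed valence states and its default count
#' range. Sulfur (2, 4, 6) and phosphorus (3, 5) carry several valence
#' states, each of which is iterated independently during enumeration so that
#' mixed valence-state combinations are considered. `X` is a massless
#' valence-1 placeholder for the bond(s) connecting a repeat unit to the rest
#' of the molecule; a bridging unit carries one or two of them.
#'
#' @return A data frame with one row per element and columns `symbol`,
#'   `mass` (Da), `valences` (list column of integer vectors), `count_min`
#'   and `count_max`.
#' @examples
#' tab <- default_element_table()
#' tab$valences[[which(tab$symbol == "S")]]  # 2 4 6
#' @export
default_element_table <- function() {
  element_table(
    symbols   = c("C", "H", "S", "O", "N", "P", "F", "Cl", "Br", "Si", "X"),
    valences  = list(4L, 1L, c(2L, 4L, 6L), 2L, 3L, c(3L, 5L),
                     1L, 1L, 1L, 4L, 1L),
    count_min = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L),
    count_max = c(10L, 20L, 4L, 4L, 2L, 2L, 4L, 2L, 2L, 1L, 2L)
  )
}

#' Construct an element table
#'
#' @param symbols Character vector of element symbols (must be known to
#'   [element_masses()]).
#' @param valences List of integer vectors, one per symbol: the allowed
#'   valence states (each >= 1).
#' @param count_min,count_max Integer vectors of per-element count bounds.
#' @return A validated element table (data frame, class `element_table`).
#' @export
element_table <- function(symbols, valences, count_min, count_max) {
  stopifnot(length(symbols) == length(valences),
            length(symbols) == length(count_min),
            length(symbols) == length(count_max))
  unknown <- setdiff(symbols, names(.MONOISOTOPIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(symbols))
    stop("duplicate element symbols in table")
  valences <- lapply(valences, function(v) sort(as.integer(v)))
  if (any(vapply(valences, length, 1L) == 0L))
    stop("every element needs at least one valence state")
  if (any(unlist(valences) < 1L))
    stop("valence states must be >= 1")
  count_min <- as.integer(count_min); count_max <- as.integer(count_max)
  if (any(count_min < 0L) || any(count_min > count_max))
    stop("count bounds must satisfy 0 <= count_min <= count_max")
  out <- data.frame(symbol = symbols, mass = .MONOISOTOPIC_MASS[symbols],
                    count_min = count_min, count_max = count_max,
                    row.names = NULL)
  out$valences <- valences
  class(out) <- c("element_table", "data.frame")
  out
}

# Element ordering used for formula display: Hill-like with X last.
.FORMULA_ORDER <- c("C", "H", "Br", "Cl", "F", "N", "O", "P", "S", "Si", "X")

#' Parse a molecular formula string into element counts
#'
#' Accepts element+count tokens, e.g. `"C2H4OX2"`; a count of 1 may be
#' omitted. Only the elements supported by [element_masses()] are accepted.
#'
#' @param formula A single formula string.
#' @return Named integer vector of element counts (only elements present).
#' @examples
#' parse_formula("C2H4OX2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse formula string: ", formula)
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Z][a-z]?", "", tokens)
  cnts <- ifelse(cnts == "", 1L, suppressWarnings(as.integer(cnts)))
  unknown <- setdiff(syms, names(.MONOISOTOPIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s) in formula: ",
         paste(unique(unknown), collapse = ", "))
  counts <- tapply(cnts, syms, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[out > 0L]
}

#' Format element counts as a formula string
#'
#' Elements are printed in Hill-like order (C, H, then alphabetically) with
#' the placeholder X always last; counts of 1 are omitted.
#'
#' @param counts Named integer vector of element counts.
#' @return A single formula string.
#' @examples
#' format_formula(c(C = 2L, H = 4L, O = 1L, X = 2L))
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0L]
  ord <- .FORMULA_ORDER[.FORMULA_ORDER %in% names(counts)]
  extra <- setdiff(names(counts), ord)  # unknown symbols keep input order
  ord <- c(setdiff(ord, "X"), extra, intersect("X", ord))
  paste0(ord, ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

#' Monoisotopic mass of a composition
#'
#' @param x A formula string, a named count vector, or a valenced
#'   composition (see [valenced_composition()]). The placeholder X
#'   contributes 0 Da.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C2H4OX2")  # 44.02621
#' @export
monoisotopic_mass <- function(x) {
  counts <- as_element_counts(x)
  unknown <- setdiff(names(counts), names(.MONOISOTOPIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(counts * .MONOISOTOPIC_MASS[names(counts)])
}

# Coerce the accepted composition representations to a named count vector.
as_element_counts <- function(x) {
  if (is.character(x)) return(parse_formula(x))
  if (inherits(x, "valenced_composition")) return(collapse_composition(x))
  if (is.numeric(x) && !is.null(names(x))) {
    storage.mode(x) <- "integer"
    return(x[x > 0L])
  }
  stop("cannot interpret composition of class ", paste(class(x), collapse = "/"))
}
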