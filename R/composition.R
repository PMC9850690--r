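# Valenced compositions and chemical validation.
#
# Enumeration iterates every valence state of every element independently, so
# the unit of work is a composition keyed by (element, valence state) rather
# than by element alone.  Validation uses the ring-and-double-bond count
# (DBE) together with a restricted saturation identity that rejects
# impossible bridging units such as NX, which a bare DBE test would accept.

#' Construct a valenced composition
#'
#' A valenced composition assigns a positive atom count to each
#' (element, valence state) pair. Collapsing over valence states yields a
#' plain elemental composition.
#'
#' @param symbol Character vector of element symbols.
#' @param valence Integer vector of valence states (>= 1), parallel to
#'   `symbol`.
#' @param count Integer vector of positive atom counts, parallel to `symbol`.
#' @return An object of class `valenced_composition` (a data frame with
#'   columns `symbol`, `valence`, `count`).
#' @examples
#' vc <- valenced_composition(c("C", "H", "X"), c(4, 1, 1), c(1, 2, 2))
#' compute_dbe(vc)
#' @export
valenced_composition <- function(symbol, valence, count) {
  stopifnot(length(symbol) == length(valence), length(symbol) == length(count))
  valence <- as.integer(valence); count <- as.integer(count)
  if (any(valence < 1L)) stop("valence states must be >= 1")
  if (any(count < 1L)) stop("counts must be >= 1 (omit absent entries)")
  key <- paste(symbol, valence, sep = ":")
  if (anyDuplicated(key)) stop("duplicate (symbol, valence) entries")
  out <- data.frame(symbol = as.character(symbol), valence = valence,
                    count = count, row.names = NULL)
  class(out) <- c("valenced_composition", "data.frame")
  out
}

#' Parse a compact valenced-composition string
#'
#' Convenience constructor used mainly in examples and tests: entries are
#' `symbol:valence=count` separated by whitespace or commas, e.g.
#' `"C:4=1 H:1=2 X:1=2"` for methylene with two connection points.
#'
#' @param spec A single specification string.
#' @return A [valenced_composition()].
#' @export
parse_vcomp <- function(spec) {
  parts <- strsplit(trimws(spec), "[,[:space:]]+")[[1]]
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec("^([A-Z][a-z]?):([0-9]+)=([0-9]+)$", parts))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("cannot parse entries: ", paste(parts[bad], collapse = " "))
  valenced_composition(
    symbol  = vapply(m, `[`, "", 2L),
    valence = as.integer(vapply(m, `[`, "", 3L)),
    count   = as.integer(vapply(m, `[`, "", 4L))
  )
}

#' Collapse a valenced composition to element counts
#'
#' @param vc A [valenced_composition()].
#' @return Named integer vector of per-element atom counts.
#' @export
collapse_composition <- function(vc) {
  stopifnot(inherits(vc, "valenced_composition"))
  counts <- tapply(vc$count, vc$symbol, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Double-bond equivalents of a valenced composition
#'
#' Computes `DBE = 1/2 * sum(E_i * (nu_i - 2)) + 1` over all
#' (element, valence) entries, where `E_i` is the atom count and `nu_i` the
#' valence state. The result may be negative or half-integral; such values
#' flag chemically impossible formulas.
#'
#' @param vc A [valenced_composition()].
#' @return The DBE value (numeric, possibly half-integral or negative).
#' @examples
#' compute_dbe(parse_vcomp("C:4=1 H:1=2 X:1=2"))  # 0
#' @export
compute_dbe <- function(vc) {
  stopifnot(inherits(vc, "valenced_composition"), nrow(vc) > 0L)
  sum(vc$count * (vc$valence - 2)) / 2 + 1
}

#' Validate a candidate unit formula
#'
#' A composition passes when it can exist as a saturation-consistent bridging
#' fragment. Writing `P` for the number of polyvalent atoms (valence >= 2),
#' `M` for the number of monovalent atoms and `V` for the summed valences of
#' the polyvalent atoms:
#'
#' * `P == 0`: rejected — a unit made only of valence-1 atoms cannot be
#'   bonded into a scaffold.
#' * `P == 1`: valid iff the single polyvalent atom's valence equals the
#'   monovalent atom count (`V == M`); this saturation identity rejects
#'   fragments such as NX that a bare DBE test would accept.
#' * `P > 1`: valid iff the DBE of [compute_dbe()] is a non-negative
#'   integer; with that DBE the saturation identity holds automatically.
#'
#' @param vc A [valenced_composition()].
#' @return A list with fields `valid` (logical), `dbe` (the [compute_dbe()]
#'   value, always reported) and `reason` (one of `"ok"`, `"no-polyvalent"`,
#'   `"saturation"`, `"negative-dbe"`, `"non-integer-dbe"`).
#' @examples
#' validate_formula(parse_vcomp("N:3=1 X:1=1"))     # invalid (NX)
#' validate_formula(parse_vcomp("C:4=1 H:1=2 X:1=2"))  # valid, DBE 0
#' @export
validate_formula <- function(vc) {
  stopifnot(inherits(vc, "valenced_composition"), nrow(vc) > 0L)
  dbe <- compute_dbe(vc)
  poly <- vc$valence >= 2L
  P <- sum(vc$count[poly])
  M <- sum(vc$count[!poly])
  V <- sum(vc$count[poly] * vc$valence[poly])
  res <- function(valid, reason) list(valid = valid, dbe = dbe, reason = reason)
  if (P == 0L) return(res(FALSE, "no-polyvalent"))
  if (P == 1L) {
    if (V == M) return(res(TRUE, "ok"))
    return(res(FALSE, "saturation"))
  }
  if (dbe < 0) return(res(FALSE, "negative-dbe"))
  if (dbe != round(dbe)) return(res(FALSE, "non-integer-dbe"))
  res(TRUE, "ok")
}
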