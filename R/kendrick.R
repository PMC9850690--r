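# Kendrick mass defect transformation.
#
# Rescaling m/z by nominal/exact mass of a repeating unit sends every member
# of an exact homologous series to the same mass defect, so series appear as
# horizontal rows in a (Kendrick mass, Kendrick mass defect) plot.

#' Kendrick mass defect transform of a peak list
#'
#' For each peak, `KM = mz * nominal(unit) / exact(unit)` with
#' `nominal(unit)` the unit's exact mass rounded to the nearest integer,
#' and `KMD = round(KM) - KM` (fractional mass, accurate subtracted from
#' nominal). Round-to-nearest keeps KMD in (-0.5, 0.5].
#'
#' @param peaks A [peaklist()].
#' @param unit The rescaling unit: a formula string (e.g. `"C2H4OX2"`), a
#'   unit-library row, or a bare positive mass in Da.
#' @return A `kendrick_table`: data frame with columns `mz`, `intensity`,
#'   `km`, `kmd`, and attributes `unit_formula`, `unit_mass`,
#'   `unit_nominal`.
#' @examples
#' pk <- peaklist(c(100, 144.0262147, 188.0524294), c(3, 2, 1))
#' kendrick_transform(pk, "C2H4OX2")
#' @export
kendrick_transform <- function(peaks, unit) {
  peaks <- as_peaklist(peaks)
  info <- unit_info(unit)
  if (!is.finite(info$mass) || info$mass <= 0)
    stop("unit mass must be positive")
  nominal <- round(info$mass)
  if (nominal < 1) stop("unit nominal mass rounds to zero; unit too light")
  km <- peaks$mz * nominal / info$mass
  kmd <- round(km) - km
  out <- data.frame(mz = peaks$mz, intensity = peaks$intensity,
                    km = km, kmd = kmd)
  attr(out, "unit_formula") <- info$formula
  attr(out, "unit_mass") <- info$mass
  attr(out, "unit_nominal") <- nominal
  class(out) <- c("kendrick_table", "data.frame")
  out
}

# Resolve the accepted unit representations to (formula, mass).
unit_info <- function(unit) {
  if (is.numeric(unit) && length(unit) == 1L && is.null(names(unit)))
    return(list(formula = sprintf("m%.5f", unit), mass = as.numeric(unit)))
  if (is.character(unit) && length(unit) == 1L)
    return(list(formula = unit, mass = monoisotopic_mass(unit)))
  if (is.data.frame(unit) && nrow(unit) == 1L &&
      all(c("formula", "mass") %in% names(unit)))
    return(list(formula = unit$formula, mass = unit$mass))
  stop("cannot interpret unit specification")
}

#' Write a Kendrick table as delimited text
#'
#' @param kt A `kendrick_table` from [kendrick_transform()].
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_kendrick <- function(kt, path, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit ", attr(kt, "unit_formula"),
                    sprintf(" exact %.7f nominal %d", attr(kt, "unit_mass"),
                            as.integer(attr(kt, "unit_nominal")))), con)
  writeLines(paste("mz", "km", "kmd", sep = sep), con)
  writeLines(paste(sprintf("%.6f", kt$mz), sprintf("%.9f", kt$km),
                   sprintf("%.9f", kt$kmd), sep = sep), con)
  invisible(path)
}
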