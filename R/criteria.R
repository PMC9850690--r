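# Candidate-unit selection criteria and screening.
#
# A generated library still holds far more formulas than are plausible
# repeat units.  Selection screens it with four independently disable-able
# filters: per-element count bounds, elemental ratios relative to carbon
# (after the Seven Golden Rules style of heuristics), a unit mass window,
# and a DBE ceiling.

.RATIO_ELEMENTS <- c("H", "N", "O", "P", "S", "F", "Cl", "Br", "Si")

#' Construct selection criteria
#'
#' @param count_min,count_max Named integer vectors of per-element count
#'   bounds (elements absent from the vectors are unbounded).
#' @param ratios Named list of `c(lo, hi)` bounds for element/C ratios
#'   (names among H, N, O, P, S, F, Cl, Br, Si). The placeholder X never
#'   enters ratio computation.
#' @param mass_min,mass_max Unit mass window in Da (inclusive).
#' @param dbe_max DBE ceiling (inclusive).
#' @param use_counts,use_ratios,use_mass,use_dbe Logical switches enabling
#'   each filter.
#' @return An object of class `unit_criteria`.
#' @export
unit_criteria <- function(count_min = integer(0), count_max = integer(0),
                          ratios = list(), mass_min = 0, mass_max = Inf,
                          dbe_max = Inf, use_counts = TRUE, use_ratios = TRUE,
                          use_mass = TRUE, use_dbe = TRUE) {
  stopifnot(mass_min >= 0, mass_min <= mass_max)
  bad <- names(ratios)[!vapply(ratios, function(b)
    length(b) == 2L && b[1] <= b[2], logical(1))]
  if (length(bad))
    stop("ratio bounds must be c(lo, hi) with lo <= hi: ",
         paste(bad, collapse = ", "))
  structure(list(count_min = count_min, count_max = count_max,
                 ratios = ratios, mass_min = mass_min, mass_max = mass_max,
                 dbe_max = dbe_max, use_counts = use_counts,
                 use_ratios = use_ratios, use_mass = use_mass,
                 use_dbe = use_dbe),
            class = "unit_criteria")
}

#' Default selection criteria
#'
#' The stock screen for plausible repeat units: the default element-table
#' count limits, elemental ratios
#' 0.3 <= H/C <= 4.0, 0 <= N/C <= 1.3, 0 <= O/C <= 1.2, 0 <= P/C <= 0.3,
#' 0 <= S/C <= 0.8, 0 <= F/C <= 1.5, 0 <= Cl/C <= 0.8, 0 <= Br/C <= 0.8,
#' 0 <= Si/C <= 0.5 (all inclusive; skipped for carbon-free compositions),
#' a unit mass window of 14–200 Da, and a generous DBE ceiling of 40.
#'
#' @return A [unit_criteria()] object.
#' @export
default_criteria <- function() {
  tab <- default_element_table()
  unit_criteria(
    count_min = stats::setNames(tab$count_min, tab$symbol),
    count_max = stats::setNames(tab$count_max, tab$symbol),
    ratios = list(H = c(0.3, 4.0), N = c(0, 1.3), O = c(0, 1.2),
                  P = c(0, 0.3), S = c(0, 0.8), F = c(0, 1.5),
                  Cl = c(0, 0.8), Br = c(0, 0.8), Si = c(0, 0.5)),
    mass_min = 14, mass_max = 200, dbe_max = 40
  )
}

#' Derive criteria automatically from a peak list (untargeted mode)
#'
#' Starts from [default_criteria()] and caps the unit mass at the largest
#' m/z in the dataset divided by the minimum number of desired repetitions
#' (a unit larger than that cannot repeat often enough to be seen). The
#' elemental-ratio screen is disabled in this mode: the ratio heuristics
#' presuppose hydrogen-bearing CHNOPS-type organics and would discard
#' legitimate units such as CF2 (H/C = 0, F/C = 2) that untargeted runs are
#' expected to recover.
#'
#' @param peaks A [peaklist()].
#' @param min_repetitions Minimum number of desired unit repetitions
#'   (>= 1).
#' @return A [unit_criteria()] object.
#' @export
auto_criteria <- function(peaks, min_repetitions = 3L) {
  peaks <- as_peaklist(peaks)
  if (!length(peaks$mz)) stop("empty peak list")
  stopifnot(min_repetitions >= 1)
  crit <- default_criteria()
  crit$mass_max <- min(crit$mass_max, max(peaks$mz) / min_repetitions)
  crit$use_ratios <- FALSE
  crit
}

# Logical mask of library rows passing the criteria. `counts` is a matrix
# with one column per element symbol; symbols missing from the matrix count
# as zero.
criteria_mask <- function(counts, mass, dbe, criteria) {
  stopifnot(inherits(criteria, "unit_criteria"))
  keep <- rep(TRUE, length(mass))
  col <- function(s) if (s %in% colnames(counts)) counts[, s] else
    rep(0L, nrow(counts))
  if (criteria$use_counts) {
    for (s in names(criteria$count_min))
      keep <- keep & col(s) >= criteria$count_min[[s]]
    for (s in names(criteria$count_max))
      keep <- keep & col(s) <= criteria$count_max[[s]]
  }
  if (criteria$use_mass)
    keep <- keep & mass >= criteria$mass_min & mass <= criteria$mass_max
  if (criteria$use_dbe)
    keep <- keep & dbe <= criteria$dbe_max
  if (criteria$use_ratios && length(criteria$ratios)) {
    carbon <- col("C")
    has_c <- carbon > 0L
    for (s in names(criteria$ratios)) {
      b <- criteria$ratios[[s]]
      r <- ifelse(has_c, col(s) / pmax(carbon, 1L), NA_real_)
      # carbon-free compositions pass ratio filters vacuously
      keep <- keep & (!has_c | (r >= b[1] & r <= b[2]))
    }
  }
  keep
}

#' Screen a unit library against selection criteria
#'
#' Applies all enabled filters of `criteria` to the candidates. Ratio
#' filters are skipped for carbon-free compositions (the bounds are all
#' "per C"), and the placeholder X never enters ratio computation. Output
#' is sorted by exact mass ascending.
#'
#' @param library A `unit_library` (see [build_unit_library()]).
#' @param criteria A [unit_criteria()].
#' @return The filtered `unit_library`.
#' @examples
#' tab <- element_table(c("C", "H", "O", "X"), list(4L, 1L, 2L, 1L),
#'                      c(0L, 0L, 0L, 1L), c(3L, 8L, 2L, 2L))
#' lib <- build_unit_library(tab)
#' nrow(select_units(lib, default_criteria()))
#' @export
select_units <- function(library, criteria) {
  stopifnot(inherits(library, "unit_library") || is.data.frame(library))
  count_cols <- setdiff(names(library), c("formula", "mass", "dbe"))
  counts <- as.matrix(library[, count_cols, drop = FALSE])
  if (!is.integer(counts)) storage.mode(counts) <- "integer"
  keep <- criteria_mask(counts, library$mass, library$dbe, criteria)
  out <- library[keep, , drop = FALSE]
  out <- out[order(out$mass, out$formula), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("unit_library", "data.frame")
  out
}

#' Write criteria to a flat key-value config file
#'
#' @param criteria A [unit_criteria()].
#' @param path Output path.
#' @export
write_criteria <- function(criteria, path) {
  lines <- c(
    sprintf("mass_min = %.6g", criteria$mass_min),
    sprintf("mass_max = %.6g", criteria$mass_max),
    sprintf("dbe_max = %.6g", criteria$dbe_max),
    sprintf("use_counts = %s", criteria$use_counts),
    sprintf("use_ratios = %s", criteria$use_ratios),
    sprintf("use_mass = %s", criteria$use_mass),
    sprintf("use_dbe = %s", criteria$use_dbe),
    vapply(names(criteria$count_min), function(s)
      sprintf("count_min.%s = %d", s, criteria$count_min[[s]]), ""),
    vapply(names(criteria$count_max), function(s)
      sprintf("count_max.%s = %d", s, criteria$count_max[[s]]), ""),
    vapply(names(criteria$ratios), function(s)
      sprintf("ratio.%s = %.6g %.6g", s, criteria$ratios[[s]][1],
              criteria$ratios[[s]][2]), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read criteria from a flat key-value config file
#'
#' Unknown keys are ignored; keys absent from the file keep the
#' [default_criteria()] value.
#'
#' @param path File path written by [write_criteria()] (or hand-edited).
#' @return A [unit_criteria()].
#' @export
read_criteria <- function(path) {
  crit <- default_criteria()
  lines <- readLines(path)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    if (key %in% c("mass_min", "mass_max", "dbe_max"))
      crit[[key]] <- as.numeric(val)
    else if (grepl("^use_", key))
      crit[[key]] <- as.logical(val)
    else if (grepl("^count_min\\.", key))
      crit$count_min[[sub("^count_min\\.", "", key)]] <- as.integer(val)
    else if (grepl("^count_max\\.", key))
      crit$count_max[[sub("^count_max\\.", "", key)]] <- as.integer(val)
    else if (grepl("^ratio\\.", key))
      crit$ratios[[sub("^ratio\\.", "", key)]] <-
        as.numeric(strsplit(val, "[[:space:]]+")[[1]])
  }
  crit
}
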