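# Repeat-unit detection: local chain search and global difference search.
#
# Both algorithms test whether a candidate unit mass u repeats m times in a
# peak list, within a first-match tolerance (selection error) and a chained
# tolerance (loop error).  The local search demands a sequential ladder
# p, p+u, ..., p+m*u anchored at a single peak p, extending with theoretical
# sums p + n*u so mass errors do not accumulate.  The global search only
# demands that each multiple k*u (k = 1..m) occurs somewhere in the multiset
# of pairwise m/z differences, with no constraint on where.

#' Search configuration
#'
#' @param selection_error Tolerance in Da for the first match of a unit
#'   (default 0.0025 Da).
#' @param loop_error Tolerance in Da for chained / multiplied matches
#'   (default 0.0025 Da).
#' @param steps Required repetition count m (>= 1, default 3).
#' @param algorithm `"global"` (difference search, the default) or
#'   `"local"` (chain search).
#' @param mode `"untargeted"` (criteria auto-derived, global algorithm) or
#'   `"targeted"` (user settings honoured).
#' @param min_repetitions Minimum desired repetitions used by
#'   [auto_criteria()] in untargeted mode (default 3).
#' @param ppm If `TRUE`, interpret both errors as parts-per-million of the
#'   target mass instead of absolute Da.
#' @param strict_multiples Global search only: require a match at every
#'   multiple k = 1..m (default). If `FALSE`, a lenient variant reports a
#'   unit when the first multiple and at least one higher multiple match.
#' @param keep_evidence Record per-hit evidence (matched chains /
#'   differences)? Disable for large benchmark runs.
#' @return A `search_config` list.
#' @export
search_config <- function(selection_error = 0.0025, loop_error = 0.0025,
                          steps = 3L, algorithm = c("global", "local"),
                          mode = c("targeted", "untargeted"),
                          min_repetitions = 3L, ppm = FALSE,
                          strict_multiples = TRUE, keep_evidence = TRUE) {
  stopifnot(selection_error > 0, loop_error > 0, steps >= 1)
  structure(list(selection_error = selection_error, loop_error = loop_error,
                 steps = as.integer(steps),
                 algorithm = match.arg(algorithm), mode = match.arg(mode),
                 min_repetitions = as.integer(min_repetitions), ppm = ppm,
                 strict_multiples = strict_multiples,
                 keep_evidence = keep_evidence),
            class = "search_config")
}

# Absolute tolerance for a target mass at step n (selection vs loop error).
step_tol <- function(cfg, n, target) {
  err <- if (n == 1L) cfg$selection_error else cfg$loop_error
  if (cfg$ppm) err * 1e-6 * abs(target) else err
}

# Count matches of each target in a sorted vector within +/- tol
# (tol scalar or vector). Returns list(count, lo) where lo is the number of
# elements strictly below target - tol.
count_in_sorted <- function(sorted, targets, tol) {
  hi <- findInterval(targets + tol, sorted)
  lo <- findInterval(targets - tol, sorted, left.open = TRUE)
  list(count = hi - lo, lo = lo, hi = hi)
}

# Index of the element of `sorted` nearest to `target` among those within
# tolerance, or NA.
nearest_in_sorted <- function(sorted, target, tol) {
  r <- count_in_sorted(sorted, target, tol)
  if (r$count < 1L) return(NA_integer_)
  idx <- (r$lo + 1L):r$hi
  idx[which.min(abs(sorted[idx] - target))]
}

empty_hits <- function(cfg) {
  out <- data.frame(formula = character(0), mass = numeric(0),
                    dbe = numeric(0), count = integer(0),
                    algorithm = character(0), m = integer(0),
                    selection_error = numeric(0), loop_error = numeric(0))
  out$evidence <- list()
  class(out) <- c("unit_hits", "data.frame")
  out
}

make_hits <- function(rows, cfg, algorithm, counts, evidence) {
  if (!length(counts)) return(empty_hits(cfg))
  out <- data.frame(formula = rows$formula, mass = rows$mass,
                    dbe = rows$dbe, count = as.integer(counts),
                    algorithm = algorithm, m = cfg$steps,
                    selection_error = cfg$selection_error,
                    loop_error = cfg$loop_error)
  out$evidence <- evidence
  out <- out[order(-out$count, out$mass), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("unit_hits", "data.frame")
  out
}

#' Local (chain) search for repeating units
#'
#' For each candidate unit u and each peak p, a chain is opened when some
#' peak matches p + u within the selection error; it is extended by testing
#' the theoretical sums p + n*u against the data within the loop error for
#' n = 2, 3, ... and is complete when n reaches m. A candidate is reported
#' iff at least one complete chain exists; its count is the number of
#' distinct starting peaks with a complete chain.
#'
#' @param peaks A [peaklist()].
#' @param candidates A `unit_library` (or data frame with `formula`, `mass`,
#'   `dbe`).
#' @param cfg A [search_config()].
#' @return A `unit_hits` data frame (formula, mass, dbe, count, algorithm,
#'   m, errors, evidence), sorted by count descending then mass ascending.
#'   Evidence per hit: one data frame per complete chain with columns
#'   `start_mz`, `step`, `target_mz`, `matched_mz`.
#' @export
local_search <- function(peaks, candidates, cfg = search_config()) {
  peaks <- as_peaklist(peaks)
  if (!length(peaks$mz)) stop("empty peak list")
  stopifnot(nrow(candidates) >= 1)
  mz <- peaks$mz
  m <- cfg$steps
  counts <- integer(0); rows <- list(); evidence <- list()
  for (ci in seq_len(nrow(candidates))) {
    u <- candidates$mass[ci]
    alive <- rep(TRUE, length(mz))
    for (n in seq_len(m)) {
      targets <- mz[alive] + n * u
      tol <- step_tol(cfg, n, targets)
      r <- count_in_sorted(mz, targets, tol)
      alive[alive] <- r$count > 0L
      if (!any(alive)) break
    }
    cnt <- sum(alive)
    if (cnt >= 1L) {
      ev <- NULL
      if (cfg$keep_evidence) {
        starts <- which(alive)
        ev <- lapply(starts, function(si) {
          tgt <- mz[si] + seq_len(m) * u
          matched <- vapply(seq_len(m), function(n)
            mz[nearest_in_sorted(mz, tgt[n], step_tol(cfg, n, tgt[n]))],
            numeric(1))
          data.frame(start_mz = mz[si], step = seq_len(m), target_mz = tgt,
                     matched_mz = matched)
        })
      }
      rows[[length(rows) + 1L]] <- candidates[ci, c("formula", "mass", "dbe")]
      counts <- c(counts, cnt)
      evidence[length(evidence) + 1L] <- list(ev)
    }
  }
  make_hits(do.call(rbind, rows), cfg, "local", counts, evidence)
}

#' All pairwise m/z differences of a peak list
#'
#' Every unordered peak pair contributes exactly one positive difference
#' (larger minus smaller).
#'
#' @param peaks A [peaklist()] with at least 2 peaks.
#' @param provenance Keep the contributing peak indices? (Needed for
#'   evidence; costs memory on large lists.)
#' @return A `difference_multiset`: list with sorted numeric `delta` and,
#'   with provenance, parallel integer vectors `i`, `j` (indices into the
#'   peak list, `mz[j] - mz[i] = delta`, `i < j` by m/z order).
#' @export
pairwise_differences <- function(peaks, provenance = TRUE) {
  peaks <- as_peaklist(peaks)
  n <- length(peaks$mz)
  if (n < 2L) stop("need at least 2 peaks for pairwise differences")
  j <- rep.int(2:n, 1:(n - 1L))
  i <- sequence(1:(n - 1L))
  delta <- peaks$mz[j] - peaks$mz[i]
  o <- order(delta)
  out <- list(delta = delta[o])
  if (provenance) { out$i <- i[o]; out$j <- j[o] }
  out$n_peaks <- n
  structure(out, class = "difference_multiset")
}

#' @export
length.difference_multiset <- function(x) length(x$delta)

#' Global (difference) search for repeating units
#'
#' Computes the multiset of pairwise m/z differences, then for each
#' candidate unit u tests whether some difference matches u within the
#' selection error and, for n = 2..m, whether n*u matches some difference
#' within the loop error. With `strict_multiples` (default) the candidate
#' is reported iff every multiple up to m matched; no constraint is placed
#' on where in the spectrum the matches occur. The count is the total
#' number of differences matching k*u over k = 1..m.
#'
#' @param peaks A [peaklist()] with >= 2 peaks.
#' @param candidates A `unit_library` (or data frame with `formula`, `mass`,
#'   `dbe`).
#' @param cfg A [search_config()].
#' @param diffs Optional precomputed [pairwise_differences()] of `peaks`.
#' @return A `unit_hits` data frame; evidence per hit is a data frame of
#'   matched differences with columns `k`, `target`, `delta`, `mz_lo`,
#'   `mz_hi` (the contributing peak pair, when provenance is available).
#' @export
global_search <- function(peaks, candidates, cfg = search_config(),
                          diffs = NULL) {
  peaks <- as_peaklist(peaks)
  if (length(peaks$mz) < 2L) stop("need at least 2 peaks for global search")
  stopifnot(nrow(candidates) >= 1)
  if (is.null(diffs))
    diffs <- pairwise_differences(peaks, provenance = cfg$keep_evidence)
  delta <- diffs$delta
  m <- cfg$steps
  counts <- integer(0); rows <- list(); evidence <- list()
  for (ci in seq_len(nrow(candidates))) {
    u <- candidates$mass[ci]
    k <- seq_len(m)
    tol <- vapply(k, function(n) step_tol(cfg, n, n * u), numeric(1))
    r <- count_in_sorted(delta, k * u, tol)
    hit <- if (cfg$strict_multiples) all(r$count > 0L) else
      r$count[1L] > 0L && (m == 1L || any(r$count[-1L] > 0L))
    if (!hit) next
    cnt <- sum(r$count)
    ev <- NULL
    if (cfg$keep_evidence) {
      pieces <- lapply(which(r$count > 0L), function(n) {
        idx <- (r$lo[n] + 1L):r$hi[n]
        data.frame(k = n, target = n * u, delta = delta[idx],
                   mz_lo = if (!is.null(diffs$i)) peaks$mz[diffs$i[idx]]
                           else NA_real_,
                   mz_hi = if (!is.null(diffs$j)) peaks$mz[diffs$j[idx]]
                           else NA_real_)
      })
      ev <- do.call(rbind, pieces)
    }
    rows[[length(rows) + 1L]] <- candidates[ci, c("formula", "mass", "dbe")]
    counts <- c(counts, cnt)
    evidence[length(evidence) + 1L] <- list(ev)
  }
  make_hits(do.call(rbind, rows), cfg, "global", counts, evidence)
}

# Cache for the default (full element table) unit library.
.unitfindr_cache <- new.env(parent = emptyenv())

#' The default candidate-unit library
#'
#' Builds (once per session, then caches) the library over the full default
#' element table. Roughly 9.4 million collapsed compositions are screened;
#' expect tens of seconds on first use.
#'
#' @param criteria Optional [unit_criteria()] applied during the build (the
#'   cache is only used for the unfiltered call).
#' @return A `unit_library`.
#' @export
default_unit_library <- function(criteria = NULL) {
  if (!is.null(criteria))
    return(build_unit_library(default_element_table(), criteria))
  if (is.null(.unitfindr_cache$default_library))
    .unitfindr_cache$default_library <-
      build_unit_library(default_element_table())
  .unitfindr_cache$default_library
}

#' Find repeating units in a peak list
#'
#' Orchestrates the full workflow. In untargeted mode the selection
#' criteria are derived from the data with [auto_criteria()] and the global
#' (difference) algorithm is used; in targeted mode the supplied criteria
#' and the configured algorithm are honoured. Candidates are screened with
#' [select_units()] before searching.
#'
#' @param peaks A [peaklist()].
#' @param cfg A [search_config()].
#' @param criteria A [unit_criteria()], or `NULL` to use
#'   [default_criteria()] (targeted) / [auto_criteria()] (untargeted).
#' @param library A `unit_library` of candidates; `NULL` uses
#'   [default_unit_library()].
#' @return A `unit_hits` data frame sorted by count descending then mass
#'   ascending.
#' @export
find_units <- function(peaks, cfg = search_config(), criteria = NULL,
                       library = NULL) {
  peaks <- as_peaklist(peaks)
  if (cfg$mode == "untargeted") {
    criteria <- auto_criteria(peaks, cfg$min_repetitions)
    cfg$algorithm <- "global"
  } else if (is.null(criteria)) {
    criteria <- default_criteria()
  }
  if (is.null(library)) library <- default_unit_library()
  candidates <- select_units(library, criteria)
  if (!nrow(candidates)) {
    warning("no candidate units survive selection; empty hit list")
    return(empty_hits(cfg))
  }
  if (cfg$algorithm == "local")
    local_search(peaks, candidates, cfg)
  else
    global_search(peaks, candidates, cfg)
}

#' Write a hit list as delimited text
#'
#' @param hits A `unit_hits` data frame.
#' @param path Output path.
#' @param evidence_path Optional second file receiving the per-hit evidence
#'   records (long format).
#' @export
write_unit_hits <- function(hits, path, evidence_path = NULL) {
  con <- file(path, "w")
  writeLines("formula\tmass\tdbe\tcount\talgorithm\tm\tselection_error\tloop_error",
             con)
  if (nrow(hits))
    writeLines(paste(hits$formula, sprintf("%.7f", hits$mass),
                     as.integer(round(hits$dbe)), hits$count, hits$algorithm,
                     hits$m, format(hits$selection_error, trim = TRUE),
                     format(hits$loop_error, trim = TRUE), sep = "\t"), con)
  close(con)
  if (!is.null(evidence_path)) {
    con2 <- file(evidence_path, "w")
    writeLines("formula\trecord", con2)
    for (r in seq_len(nrow(hits))) {
      ev <- hits$evidence[[r]]
      if (is.null(ev)) next
      if (is.data.frame(ev)) ev <- list(ev)
      for (chain in ev) {
        txt <- apply(chain, 1L, function(row)
          paste(trimws(format(row)), collapse = ","))
        writeLines(paste(hits$formula[r], txt, sep = "\t"), con2)
      }
    }
    close(con2)
  }
  invisible(path)
}
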