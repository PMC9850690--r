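# Deterministic synthetic HRMS spectra with planted homologous series.
#
# The generator emulates the kind of data the search algorithms target:
# polymeric ladders scaffold + k * unit (PEG-like C2H4O, PPG-like C3H6O,
# perfluorinated CF2, ...), with a monotone-decay intensity envelope,
# optional sparse presence (only some rungs retained), bounded mass-error
# jitter, and uniform random noise peaks.  Jitter is a truncated normal
# (+/- 3 sd) so tolerance guarantees stay testable, and noise peaks are
# rejected if they land within a guard band of any planted position, so
# recall tests are deterministic at a fixed seed.

#' Specify one planted homologous series
#'
#' @param unit The repeating unit: formula string (e.g. `"C2H4OX2"`) or
#'   bare mass in Da.
#' @param scaffold_mass Base (k = 0) mass in Da.
#' @param n_min,n_max Repetition range: peaks are planted at
#'   `scaffold_mass + k * unit` for `k = n_min..n_max`.
#' @param base_intensity Intensity of the first rung.
#' @param decay Multiplicative intensity decay per rung (monotone
#'   envelope), in (0, 1].
#' @param jitter_sd Mass-error scale in Da; each planted m/z is perturbed
#'   by a normal deviate truncated at +/- 3 sd. The default 0.0004 Da keeps
#'   the worst-case pairwise error (2 * 3 sd = 0.0024 Da) inside the
#'   default loop tolerance of 0.0025 Da.
#' @param presence `"sequential"` (all rungs) or `"sparse"` (a subset).
#' @param keep_k With sparse presence, an explicit integer vector of rungs
#'   to keep; `NULL` samples a random subset.
#' @param sparse_fraction Fraction of rungs kept when sampling a sparse
#'   subset (default 0.5).
#' @return A `series_spec` list.
#' @export
series_spec <- function(unit, scaffold_mass, n_min = 0L, n_max = 8L,
                        base_intensity = 1000, decay = 0.85,
                        jitter_sd = 0.0004,
                        presence = c("sequential", "sparse"),
                        keep_k = NULL, sparse_fraction = 0.5) {
  info <- unit_info(unit)
  stopifnot(info$mass > 0, n_min >= 0, n_min <= n_max, jitter_sd >= 0,
            base_intensity > 0, decay > 0, decay <= 1)
  structure(list(unit_formula = info$formula, unit_mass = info$mass,
                 scaffold_mass = scaffold_mass, n_min = as.integer(n_min),
                 n_max = as.integer(n_max), base_intensity = base_intensity,
                 decay = decay, jitter_sd = jitter_sd,
                 presence = match.arg(presence), keep_k = keep_k,
                 sparse_fraction = sparse_fraction),
            class = "series_spec")
}

# Normal deviates truncated at +/- 3 sd (rejection sampling).
rnorm_trunc3 <- function(n, sd) {
  if (sd == 0 || n == 0L) return(rep(0, n))
  out <- stats::rnorm(n, 0, sd)
  bad <- which(abs(out) > 3 * sd)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[abs(out[bad]) > 3 * sd]
  }
  out
}

#' Generate a synthetic peak list with planted series
#'
#' Fully reproducible for a given seed; the caller's RNG state is
#' preserved. Exact duplicate m/z values are merged by the [peaklist()]
#' constructor.
#'
#' @param series A list of [series_spec()] objects (or a single one).
#' @param n_noise Number of uniform random noise peaks.
#' @param mz_range Numeric length-2 interval for noise peaks.
#' @param seed Integer seed.
#' @param noise_guard Minimum distance (Da) between a noise peak and any
#'   planted position (default 0.005, twice the default loop error).
#' @param noise_intensity Length-2 range of noise-peak intensities.
#' @return A [peaklist()] with attribute `manifest`: a data frame of the
#'   planted ground truth (series index, unit formula and mass, scaffold,
#'   rung k, exact and jittered m/z).
#' @examples
#' s <- series_spec("C2H4OX2", 181.07, 0, 7, jitter_sd = 0)
#' pk <- generate_spectrum(list(s), n_noise = 20, mz_range = c(50, 600),
#'                         seed = 1)
#' @export
generate_spectrum <- function(series, n_noise = 0L, mz_range = c(50, 1000),
                              seed = 1L, noise_guard = 0.005,
                              noise_intensity = c(10, 100)) {
  if (inherits(series, "series_spec")) series <- list(series)
  stopifnot(all(vapply(series, inherits, logical(1), "series_spec")),
            length(mz_range) == 2L, mz_range[1] > 0,
            mz_range[1] < mz_range[2])
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(as.integer(seed))

  rows <- lapply(seq_along(series), function(si) {
    sp <- series[[si]]
    k <- sp$n_min:sp$n_max
    if (sp$presence == "sparse") {
      k <- if (!is.null(sp$keep_k)) {
        stopifnot(all(sp$keep_k >= sp$n_min), all(sp$keep_k <= sp$n_max))
        sort(as.integer(sp$keep_k))
      } else {
        n_keep <- max(1L, round(length(k) * sp$sparse_fraction))
        sort(sample(k, n_keep))
      }
    }
    exact <- sp$scaffold_mass + k * sp$unit_mass
    mz <- exact + rnorm_trunc3(length(k), sp$jitter_sd)
    data.frame(series = si, unit_formula = sp$unit_formula,
               unit_mass = sp$unit_mass, scaffold_mass = sp$scaffold_mass,
               k = k, mz_exact = exact, mz = mz,
               intensity = sp$base_intensity * sp$decay^(k - sp$n_min))
  })
  manifest <- do.call(rbind, rows)

  noise_mz <- numeric(0)
  if (n_noise > 0L) {
    planted <- manifest$mz_exact
    noise_mz <- numeric(n_noise)
    filled <- 0L
    while (filled < n_noise) {
      draw <- stats::runif(n_noise - filled, mz_range[1], mz_range[2])
      if (length(planted)) {
        near <- vapply(draw, function(x) min(abs(x - planted)), numeric(1))
        draw <- draw[near > noise_guard]
      }
      if (length(draw)) {
        noise_mz[(filled + 1L):(filled + length(draw))] <- draw
        filled <- filled + length(draw)
      }
    }
    noise_int <- stats::runif(n_noise, noise_intensity[1], noise_intensity[2])
  } else noise_int <- numeric(0)

  pk <- peaklist(c(manifest$mz, noise_mz),
                 c(manifest$intensity, noise_int),
                 metadata = sprintf("synthetic seed=%d", as.integer(seed)))
  attr(pk, "manifest") <- manifest
  pk
}

#' Write the planted-truth manifest of a synthetic spectrum
#'
#' @param peaks A [generate_spectrum()] result.
#' @param path Output path (tab-delimited).
#' @export
write_manifest <- function(peaks, path) {
  manifest <- attr(peaks, "manifest")
  if (is.null(manifest)) stop("peak list carries no manifest")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
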