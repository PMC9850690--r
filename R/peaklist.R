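# Peak list container, IO and data-reduction filters.

#' Construct a peak list
#'
#' @param mz Numeric vector of m/z values in Da.
#' @param intensity Parallel numeric vector of non-negative intensities.
#' @param metadata Free-form source description.
#' @return A `peaklist`: list with sorted, unique `mz`, parallel
#'   `intensity`, and `metadata`. Exact duplicate m/z values are merged by
#'   summing their intensities.
#' @export
peaklist <- function(mz, intensity, metadata = "") {
  stopifnot(length(mz) == length(intensity))
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("non-finite m/z or intensity")
  if (any(intensity < 0)) stop("negative intensity")
  if (any(mz <= 0)) stop("non-positive m/z")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.vector(tapply(intensity, factor(mz, levels = unique(mz)),
                                  sum))
    mz <- unique(mz)
  }
  structure(list(mz = mz, intensity = intensity, metadata = metadata),
            class = "peaklist")
}

#' Coerce to a peak list
#'
#' Accepts a `peaklist`, a two-column data frame/matrix (m/z, intensity), or
#' a bare numeric m/z vector (unit intensities).
#'
#' @param x Object to coerce.
#' @return A `peaklist`.
#' @export
as_peaklist <- function(x) {
  if (inherits(x, "peaklist")) return(x)
  if (is.data.frame(x) || is.matrix(x))
    return(peaklist(as.numeric(x[, 1]), as.numeric(x[, 2])))
  if (is.numeric(x)) return(peaklist(x, rep(1, length(x))))
  stop("cannot coerce class ", paste(class(x), collapse = "/"),
       " to a peaklist")
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("<peaklist: %d peaks, m/z %.4f-%.4f%s>\n", length(x$mz),
              if (length(x$mz)) min(x$mz) else NA,
              if (length(x$mz)) max(x$mz) else NA,
              if (nzchar(x$metadata)) paste0(", ", x$metadata) else ""))
  invisible(x)
}

#' @export
length.peaklist <- function(x) length(x$mz)

#' Read a peak list from delimited text
#'
#' Expects two numeric columns (m/z in Da, intensity); comma, tab and
#' whitespace dialects are auto-detected, as is an optional single header
#' row. Rows are sorted by m/z and exact duplicate m/z values merged by
#' summing intensity.
#'
#' @param path File path (or connection) to read.
#' @param sep Field separator; `NULL` (default) auto-detects among comma,
#'   tab and whitespace.
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path, sep = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no parsable rows in peak list")
  if (is.null(sep)) {
    first <- lines[[1]]
    sep <- if (grepl(",", first, fixed = TRUE)) "," else
      if (grepl("\t", first, fixed = TRUE)) "\t" else ""
  }
  split1 <- function(x) {
    if (sep == "") strsplit(x, "[[:space:]]+") else strsplit(x, sep,
                                                             fixed = TRUE)
  }
  cells <- split1(lines)
  bad <- vapply(cells, length, 1L) < 2L
  if (any(bad)) stop("rows with fewer than 2 fields in peak list")
  num <- function(row) suppressWarnings(as.numeric(trimws(row[1:2])))
  vals <- t(vapply(cells, num, numeric(2)))
  start <- 1L
  if (anyNA(vals[1L, ])) {  # single header row tolerated
    start <- 2L
    if (nrow(vals) < 2L) stop("no parsable rows in peak list")
  }
  vals <- vals[start:nrow(vals), , drop = FALSE]
  if (anyNA(vals)) stop("non-numeric cell in peak list body")
  peaklist(vals[, 1], vals[, 2], metadata = if (is.character(path))
    basename(path) else "")
}

#' Write a peak list as delimited text
#'
#' @param peaks A [peaklist()].
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @param digits Decimal places for m/z (default 6).
#' @param header Write a `mz<sep>intensity` header row?
#' @export
write_peaklist <- function(peaks, path, sep = "\t", digits = 6,
                           header = TRUE) {
  peaks <- as_peaklist(peaks)
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines(paste("mz", "intensity", sep = sep), con)
  writeLines(paste(sprintf(paste0("%.", digits, "f"), peaks$mz),
                   format(peaks$intensity, trim = TRUE, scientific = FALSE),
                   sep = sep), con)
  invisible(path)
}

#' Keep the x most intense peaks
#'
#' Selects the `min(x, N)` highest-intensity peaks and discards the rest;
#' intensity ties at the cutoff are broken in favour of the lower m/z.
#' Output is re-sorted by m/z.
#'
#' @param peaks A [peaklist()].
#' @param x Target data length (positive integer).
#' @return The filtered `peaklist`.
#' @export
filter_top_n <- function(peaks, x) {
  peaks <- as_peaklist(peaks)
  stopifnot(x >= 1)
  n <- length(peaks$mz)
  if (x >= n) return(peaks)
  o <- order(-peaks$intensity, peaks$mz)[seq_len(x)]
  keep <- sort(o)
  peaklist(peaks$mz[keep], peaks$intensity[keep], peaks$metadata)
}

#' Remove peaks below a relative intensity threshold
#'
#' Intensities are normalised to the base (highest-intensity) peak; peaks
#' whose normalised intensity is smaller than `i_percent` are removed.
#' Equality survives, so the base peak itself always does.
#'
#' @param peaks A non-empty [peaklist()].
#' @param i_percent Threshold in percent, in (0, 100].
#' @return The filtered `peaklist`.
#' @export
filter_intensity <- function(peaks, i_percent) {
  peaks <- as_peaklist(peaks)
  stopifnot(length(peaks$mz) > 0, i_percent > 0, i_percent <= 100)
  top <- max(peaks$intensity)
  if (top <= 0) stop("all-zero intensities")
  keep <- 100 * peaks$intensity / top >= i_percent
  peaklist(peaks$mz[keep], peaks$intensity[keep], peaks$metadata)
}
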