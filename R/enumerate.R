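# Systematic enumeration of candidate unit formulas.
#
# Two routes are provided.  enumerate_formulas() is the literal iteration:
# every valence state of every element is a separate loop axis, each grid
# point is validated, and the surviving valenced compositions are returned.
# It is exact but materialises the full valence-state grid, so it is meant
# for small element tables and as the reference oracle in tests.
#
# build_unit_library() produces the deduplicated, collapsed library used by
# the search algorithms.  It iterates the collapsed per-element count grid
# and decides validity analytically: for a fixed collapsed composition the
# set of achievable summed polyvalent valences V is a contiguous
# even-stepped range [Vmin, Vmax] (valence states of one element differ by
# 2), so "valid under at least one valence assignment" reduces to a parity
# and range check.  This is what makes the full default table (~7e8 raw
# valenced grid points, ~9.4e6 collapsed compositions) tractable.

#' Enumerate valid valenced compositions over an element table
#'
#' Iterates every valence state of every element independently within the
#' table's per-element count bounds, validates each grid point with
#' [validate_formula()], and returns the survivors. Order is deterministic:
#' lexicographic in table order, valence states ascending.
#'
#' @param elements An [element_table()].
#' @param cap Maximum number of raw valence-state grid points (guards
#'   against pathological limit settings).
#' @return A list of [valenced_composition()] objects.
#' @examples
#' tab <- element_table(c("C", "H", "X"), list(4L, 1L, 1L),
#'                      c(0L, 0L, 1L), c(1L, 4L, 2L))
#' enumerate_formulas(tab)  # CH3X and CH2X2
#' @export
enumerate_formulas <- function(elements, cap = 5e6) {
  stopifnot(inherits(elements, "element_table"))
  states <- element_states(elements)
  npts <- prod(states$count_max + 1)
  if (npts > cap)
    stop("valence-state grid has ", format(npts, big.mark = ","),
         " points, exceeding the cap of ", format(cap, big.mark = ","),
         "; tighten the elemental limits or raise `cap`")

  axes <- lapply(rev(seq_len(nrow(states))),
                 function(i) 0:states$count_max[i])
  grid <- as.matrix(rev(expand.grid(axes)))  # cols in table/state order
  colnames(grid) <- states$key

  # per-element totals within [count_min, count_max]
  keep <- rep(TRUE, nrow(grid))
  for (i in seq_len(nrow(elements))) {
    tot <- rowSums(grid[, states$element == i, drop = FALSE])
    keep <- keep & tot >= elements$count_min[i] & tot <= elements$count_max[i]
  }
  grid <- grid[keep, , drop = FALSE]

  poly <- states$valence >= 2L
  P <- rowSums(grid[, poly, drop = FALSE])
  M <- rowSums(grid[, !poly, drop = FALSE])
  V <- as.vector(grid[, poly, drop = FALSE] %*% states$valence[poly])
  dbe <- (V - 2 * P - M) / 2 + 1
  valid <- (P == 1L & V == M) | (P > 1L & dbe >= 0 & dbe == round(dbe))
  grid <- grid[valid, , drop = FALSE]

  lapply(seq_len(nrow(grid)), function(r) {
    nz <- grid[r, ] > 0L
    valenced_composition(states$symbol[nz], states$valence[nz], grid[r, nz])
  })
}

# Flatten an element table into one row per (element, valence state).
element_states <- function(elements) {
  n <- lengths(elements$valences)
  data.frame(
    element   = rep(seq_len(nrow(elements)), n),
    symbol    = rep(elements$symbol, n),
    valence   = unlist(elements$valences),
    count_max = rep(elements$count_max, n),
    key       = paste(rep(elements$symbol, n), unlist(elements$valences),
                      sep = ":"),
    row.names = NULL
  )
}

#' Build the collapsed candidate-unit library
#'
#' Enumerates every collapsed elemental composition within the table's count
#' bounds, keeps those that are valid under at least one valence-state
#' assignment, and records for each the smallest non-negative integer DBE
#' achievable (the most saturated consistent assignment). Compositions
#' differing only in valence-state assignment are therefore reported once;
#' the searched unit mass depends only on the collapsed composition.
#'
#' @param elements An [element_table()].
#' @param criteria Optional [unit_criteria()] applied on the fly (mass
#'   window, DBE ceiling, elemental ratios, count bounds).
#' @param cap Maximum number of raw valence-state grid points represented by
#'   the table (the same measure [enumerate_formulas()] caps). The default
#'   admits the default element table (~1.05e9 raw points).
#' @param chunk_size Number of collapsed compositions processed per chunk
#'   (memory control).
#' @return A `unit_library`: a data frame with columns `formula`, `mass`
#'   (Da), `dbe`, plus one count column per element, sorted by mass.
#' @examples
#' tab <- element_table(c("C", "H", "O", "X"), list(4L, 1L, 2L, 1L),
#'                      c(0L, 0L, 0L, 1L), c(3L, 8L, 2L, 2L))
#' lib <- build_unit_library(tab)
#' lib[lib$formula == "C2H4OX2", ]
#' @export
build_unit_library <- function(elements, criteria = NULL, cap = 2e9,
                               chunk_size = 5e5) {
  stopifnot(inherits(elements, "element_table"))
  states <- element_states(elements)
  npts <- prod(states$count_max + 1)
  if (npts > cap)
    stop("valence-state grid has ", format(npts, big.mark = ","),
         " points, exceeding the cap of ", format(cap, big.mark = ","),
         "; tighten the elemental limits or raise `cap`")

  ok_fast <- vapply(elements$valences, function(v) {
    all(v == 1L) || (all(v >= 2L) && (length(v) == 1L || all(diff(v) == 2L)))
  }, logical(1))
  if (!all(ok_fast))
    stop("fast library build requires each element's valence states to be ",
         "all 1, or all >= 2 in steps of 2; use enumerate_formulas() for ",
         "exotic tables")

  syms <- elements$symbol
  nel <- length(syms)
  mono <- vapply(elements$valences, function(v) all(v == 1L), logical(1))
  vmin <- vapply(elements$valences, min, 1L)
  vmax <- vapply(elements$valences, max, 1L)
  masses <- elements$mass

  axes <- lapply(seq_len(nel), function(i)
    seq.int(elements$count_min[i], elements$count_max[i]))
  axis_len <- lengths(axes)

  # chunk over leading axes so each inner expand.grid stays small
  n_outer <- 0L
  while (n_outer < nel && prod(axis_len[(n_outer + 1L):nel]) > chunk_size)
    n_outer <- n_outer + 1L
  inner_idx <- if (n_outer < nel) (n_outer + 1L):nel else integer(0)
  inner <- if (length(inner_idx))
    as.matrix(rev(expand.grid(rev(axes[inner_idx])))) else
    matrix(integer(0), nrow = 1L, ncol = 0L)
  outer_grid <- if (n_outer > 0L)
    as.matrix(rev(expand.grid(rev(axes[seq_len(n_outer)])))) else
    matrix(integer(0), nrow = 1L, ncol = 0L)
  n_chunks <- max(1L, nrow(outer_grid))

  pieces <- vector("list", n_chunks)
  for (ch in seq_len(n_chunks)) {
    counts <- matrix(0L, nrow(inner), nel)
    colnames(counts) <- syms
    if (n_outer > 0L)
      counts[, seq_len(n_outer)] <-
        matrix(rep(outer_grid[ch, ], each = nrow(inner)), nrow(inner))
    if (length(inner_idx)) counts[, inner_idx] <- inner
    pieces[[ch]] <- library_chunk(counts, elements, mono, vmin, vmax,
                                  masses, criteria)
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$mass, out$formula), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("unit_library", "data.frame")
  out
}

# Validate one chunk of collapsed compositions and return surviving rows.
library_chunk <- function(counts, elements, mono, vmin, vmax, masses,
                          criteria) {
  M <- as.vector(counts[, mono, drop = FALSE] %*% rep(1, sum(mono)))
  P <- as.vector(counts[, !mono, drop = FALSE] %*% rep(1, sum(!mono)))
  Vmin <- as.vector(counts[, !mono, drop = FALSE] %*% vmin[!mono])
  Vmax <- as.vector(counts[, !mono, drop = FALSE] %*% vmax[!mono])

  dbe <- rep(NA_real_, nrow(counts))
  valid <- rep(FALSE, nrow(counts))

  # P == 1: the lone polyvalent atom must have an allowed valence equal to M
  one <- which(P == 1L)
  if (length(one)) {
    poly_idx <- which(!mono)
    for (i in poly_idx) {
      rows <- one[counts[one, i] == 1L]
      if (!length(rows)) next
      hit <- M[rows] %in% elements$valences[[i]]
      valid[rows[hit]] <- TRUE
      dbe[rows[hit]] <- 0
    }
  }

  # P > 1: need V == M (mod 2) and an achievable V >= 2P + M - 2
  many <- which(P > 1L)
  if (length(many)) {
    parity_ok <- (Vmin[many] - M[many]) %% 2 == 0
    delta <- pmax(0, 2 * P[many] + M[many] - 2 - Vmin[many])
    reachable <- Vmin[many] + delta <= Vmax[many]
    ok <- parity_ok & reachable
    valid[many[ok]] <- TRUE
    dbe[many[ok]] <-
      (Vmin[many[ok]] + delta[ok] - 2 * P[many[ok]] - M[many[ok]]) / 2 + 1
  }

  counts <- counts[valid, , drop = FALSE]
  dbe <- dbe[valid]
  mass <- as.vector(counts %*% masses)

  if (!is.null(criteria)) {
    keep <- criteria_mask(counts, mass, dbe, criteria)
    counts <- counts[keep, , drop = FALSE]
    dbe <- dbe[keep]; mass <- mass[keep]
  }
  if (!nrow(counts)) {
    out <- data.frame(formula = character(0), mass = numeric(0),
                      dbe = numeric(0))
    for (s in elements$symbol) out[[s]] <- integer(0)
    return(out)
  }
  out <- data.frame(formula = formula_strings(counts), mass = mass, dbe = dbe)
  cbind(out, as.data.frame(counts))
}

# Vectorised formula formatting for a count matrix (Hill-like, X last).
formula_strings <- function(counts) {
  ord <- .FORMULA_ORDER[.FORMULA_ORDER %in% colnames(counts)]
  ord <- c(ord, setdiff(colnames(counts), ord))
  res <- rep("", nrow(counts))
  for (s in ord) {
    n <- counts[, s]
    piece <- ifelse(n == 0L, "", ifelse(n == 1L, s, paste0(s, n)))
    res <- paste0(res, piece)
  }
  res
}

#' Write a unit library to delimited text
#'
#' Columns: formula string, exact mass (Da, 7 decimals), DBE (integer).
#' Lines starting with `#` carry generation metadata and are skipped on
#' read.
#'
#' @param library A `unit_library` (or any data frame with `formula`, `mass`,
#'   `dbe`).
#' @param path Output file path.
#' @param header Optional character vector of metadata lines (written as
#'   `# `-prefixed comments).
#' @export
write_unit_library <- function(library, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("formula\tmass\tdbe", con)
  if (nrow(library))
    writeLines(paste(library$formula, sprintf("%.7f", library$mass),
                     as.integer(round(library$dbe)), sep = "\t"), con)
  invisible(path)
}

#' Read a unit library written by [write_unit_library()]
#'
#' Element count columns are reconstructed from the formula strings.
#'
#' @param path File path.
#' @return A `unit_library` data frame.
#' @export
read_unit_library <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c("character", "numeric", "numeric"))
  names(df) <- c("formula", "mass", "dbe")
  counts <- lapply(df$formula, parse_formula)
  syms <- unique(unlist(lapply(counts, names)))
  syms <- c(.FORMULA_ORDER[.FORMULA_ORDER %in% syms],
            setdiff(syms, .FORMULA_ORDER))
  for (s in syms)
    df[[s]] <- vapply(counts, function(x) {
      v <- x[s]; if (is.na(v)) 0L else as.integer(v)
    }, integer(1))
  class(df) <- c("unit_library", "data.frame")
  df
}

#' Collapse enumerated valenced compositions into a library
#'
#' Reference (slow) construction of a `unit_library` from
#' [enumerate_formulas()] output: collapse, deduplicate, and keep the
#' smallest valid DBE per collapsed composition. Used to cross-check
#' [build_unit_library()].
#'
#' @param vcs List of valenced compositions (all valid).
#' @return A `unit_library` data frame.
#' @export
collapse_to_library <- function(vcs) {
  if (!length(vcs)) {
    out <- data.frame(formula = character(0), mass = numeric(0),
                      dbe = numeric(0))
    class(out) <- c("unit_library", "data.frame")
    return(out)
  }
  rows <- lapply(vcs, function(vc) {
    counts <- collapse_composition(vc)
    data.frame(formula = format_formula(counts),
               mass = monoisotopic_mass(counts),
               dbe = compute_dbe(vc))
  })
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(dbe ~ formula + mass, data = df, FUN = min)
  counts <- lapply(agg$formula, parse_formula)
  syms <- unique(unlist(lapply(counts, names)))
  syms <- c(.FORMULA_ORDER[.FORMULA_ORDER %in% syms],
            setdiff(syms, .FORMULA_ORDER))
  for (s in syms)
    agg[[s]] <- vapply(counts, function(x) {
      v <- x[s]; if (is.na(v)) 0L else as.integer(v)
    }, integer(1))
  agg <- agg[order(agg$mass, agg$formula), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("unit_library", "data.frame")
  agg
}
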