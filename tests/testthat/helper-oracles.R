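# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately brute-force and kept separate from the
# implementation paths it checks.

# Canonical key for a valenced composition: "sym:val=count;..." in
# (symbol, valence) order.
vc_key <- function(vc) {
  o <- order(vc$symbol, vc$valence)
  paste(sprintf("%s:%d=%d", vc$symbol[o], vc$valence[o], vc$count[o]),
        collapse = ";")
}

# Brute-force enumeration oracle: nested recursion over every
# (element, valence-state) axis, per-element totals filtered against the
# table bounds, every surviving grid point validated with
# validate_formula(). Returns a sorted character vector of vc keys.
brute_enumerate_keys <- function(elements) {
  states <- do.call(rbind, lapply(seq_len(nrow(elements)), function(i)
    data.frame(element = i, symbol = elements$symbol[i],
               valence = elements$valences[[i]],
               count_max = elements$count_max[i])))
  n_states <- nrow(states)
  keys <- character(0)
  counts <- integer(n_states)
  recurse <- function(axis) {
    if (axis > n_states) {
      for (i in seq_len(nrow(elements))) {
        tot <- sum(counts[states$element == i])
        if (tot < elements$count_min[i] || tot > elements$count_max[i])
          return(invisible())
      }
      nz <- counts > 0L
      if (!any(nz)) return(invisible())
      vc <- valenced_composition(states$symbol[nz], states$valence[nz],
                                 counts[nz])
      if (validate_formula(vc)$valid)
        keys[[length(keys) + 1L]] <<- vc_key(vc)
      return(invisible())
    }
    for (k in 0:states$count_max[axis]) {
      counts[axis] <<- k
      recurse(axis + 1L)
    }
    counts[axis] <<- 0L
  }
  recurse(1L)
  sort(keys)
}

# Random small element table (<= 6 elements, counts <= 4) for the
# enumeration-equivalence property.
random_small_table <- function(seed) {
  set.seed(seed)
  pool <- list(
    C = 4L, H = 1L, O = 2L, N = 3L, F = 1L, Cl = 1L,
    S = c(2L, 4L, 6L), P = c(3L, 5L), X = 1L
  )
  syms <- sample(names(pool), sample(2:5, 1))
  if (!"X" %in% syms) syms <- c(syms[-1], "X")
  hi <- sample(0:4, length(syms), replace = TRUE)
  hi[hi == 0L] <- 1L
  lo <- ifelse(syms == "X", 1L, 0L)
  hi <- pmax(hi, lo)
  element_table(syms, pool[syms], lo, hi)
}

# Random valenced composition drawn over the default table's states.
random_vcomp <- function(seed, max_count = 3L) {
  set.seed(seed)
  tab <- default_element_table()
  states <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    data.frame(symbol = tab$symbol[i], valence = tab$valences[[i]])))
  take <- sample(nrow(states), sample(2:5, 1))
  counts <- sample(1:max_count, length(take), replace = TRUE)
  valenced_composition(states$symbol[take], states$valence[take], counts)
}

# Small CHONF element table whose library contains the classic polymer
# units C2H4O (PEG), C3H6O (PPG) and CF2.
polymer_test_table <- function() {
  element_table(c("C", "H", "O", "N", "F", "X"),
                list(4L, 1L, 2L, 3L, 1L, 1L),
                c(0L, 0L, 0L, 0L, 0L, 1L),
                c(6L, 12L, 3L, 2L, 4L, 2L))
}

polymer_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_unit_library(polymer_test_table())
    cache
  }
})

# The three-series evaluation mixture: sequential PEG-like and PPG-like
# ladders plus a sparse perfluorinated CF2 pattern whose kept rungs
# {0, 1, 3, 6} provide the difference multiples 1u, 2u, 3u without any
# sequential chain of length 3.
evaluation_mixture <- function(seed = 42, jitter_sd = 0.0004,
                               n_noise = 150) {
  generate_spectrum(
    list(
      series_spec("C2H4OX2", 181.07, 0, 7, jitter_sd = jitter_sd),
      series_spec("C3H6OX2", 217.10, 0, 6, jitter_sd = jitter_sd),
      series_spec("CF2X2", 262.98, 0, 6, jitter_sd = jitter_sd,
                  presence = "sparse", keep_k = c(0, 1, 3, 6))
    ),
    n_noise = n_noise, mz_range = c(50, 900), seed = seed
  )
}

# Random planted-series dataset for the containment / monotonicity
# properties: one or two sequential ladders over units drawn from the
# polymer library, plus noise.
random_planted_dataset <- function(seed, lib) {
  set.seed(seed)
  n_series <- sample(1:2, 1)
  rows <- sample(nrow(lib), n_series)
  series <- lapply(rows, function(r)
    series_spec(lib$mass[r], scaffold_mass = runif(1, 120, 320),
                n_min = 0, n_max = sample(4:7, 1), jitter_sd = 0.0004))
  generate_spectrum(series, n_noise = 40, mz_range = c(50, 800),
                    seed = seed + 1000L)
}

hit_set <- function(hits) sort(unique(hits$formula))
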