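# Local chain search, global difference search, orchestration.

peg <- function() data.frame(formula = "C2H4OX2",
                             mass = monoisotopic_mass("C2H4OX2"), dbe = 0)

test_that("local_search chains theoretical sums up to m steps", {
  u <- monoisotopic_mass("C2H4OX2")
  ladder <- peaklist(c(100, 100 + u, 100 + 2 * u, 100 + 3 * u), rep(1, 4))
  cfg <- search_config(0.001, 0.001, steps = 3, algorithm = "local")
  h <- local_search(ladder, peg(), cfg)
  expect_equal(nrow(h), 1L)
  expect_equal(h$count, 1L)  # one complete chain, anchored at 100
  chain <- h$evidence[[1]][[1]]
  expect_equal(chain$step, 1:3)
  expect_equal(chain$matched_mz, 100 + (1:3) * u, tolerance = 1e-9)

  # only 3 additions exist, so m = 4 fails
  expect_equal(nrow(local_search(ladder, peg(),
                                 search_config(0.001, 0.001, 4))), 0L)

  # m = 1: every peak with a partner one unit up opens a complete chain
  two <- peaklist(c(100, 100 + u, 200, 200 + u), rep(1, 4))
  h1 <- local_search(two, peg(), search_config(0.001, 0.001, 1))
  expect_equal(h1$count, 2L)
})

test_that("pairwise differences enumerate every unordered pair", {
  d <- pairwise_differences(peaklist(c(100, 150, 175), rep(1, 3)))
  expect_equal(d$delta, c(25, 50, 75))
  expect_equal(length(d), 3L)

  set.seed(5)
  pk <- peaklist(sort(runif(15, 100, 900)), rep(1, 15))
  d <- pairwise_differences(pk)
  expect_equal(length(d), 15 * 14 / 2)
  expect_true(all(d$delta > 0))
  expect_true(!is.unsorted(d$delta))
  # provenance reconstructs every difference
  expect_equal(pk$mz[d$j] - pk$mz[d$i], d$delta)

  # equally spaced 5-peak ladder: multiples 1..4 with multiplicity 4..1
  lad <- pairwise_differences(peaklist(100 + (0:4) * 10, rep(1, 5)))
  expect_equal(as.vector(table(round(lad$delta / 10))), c(4, 3, 2, 1))
  expect_error(pairwise_differences(peaklist(100, 1)), "at least 2")
})

test_that("global_search requires every multiple up to m", {
  u <- monoisotopic_mass("C2H4OX2")
  ladder <- peaklist(c(100, 100 + u, 100 + 2 * u, 100 + 3 * u), rep(1, 4))
  cfg <- search_config(0.001, 0.001, steps = 3)
  h <- global_search(ladder, peg(), cfg)
  expect_equal(h$count, 6L)  # differences u*{1,2,3} x multiplicities {3,2,1}
  expect_equal(sort(unique(h$evidence[[1]]$k)), 1:3)

  # {b, b+u, b+4u}: differences {1,3,4}*u lack the multiple 2u -> no hit
  gap <- peaklist(c(100, 100 + u, 100 + 4 * u), rep(1, 3))
  expect_equal(nrow(global_search(gap, peg(), cfg)), 0L)
  # {b, b+u, b+3u} does hit: b+3u - (b+u) supplies the 2u difference
  gap2 <- peaklist(c(100, 100 + u, 100 + 3 * u), rep(1, 3))
  expect_equal(nrow(global_search(gap2, peg(), cfg)), 1L)

  # a unit heavier than the largest difference can never match
  heavy <- data.frame(formula = "Z", mass = 1000, dbe = 0)
  expect_equal(nrow(global_search(ladder, heavy, cfg)), 0L)
})

test_that("sparse patterns are global-only at default m", {
  # rungs {0, 1, 3, 6} give differences {1,2,3,5,6}*u but no 3-chain
  u <- monoisotopic_mass("CF2X2")
  pk <- peaklist(262.98 + c(0, 1, 3, 6) * u, rep(1, 4))
  cand <- data.frame(formula = "CF2X2", mass = u, dbe = 0)
  cfg <- search_config(steps = 3)
  expect_equal(nrow(global_search(pk, cand, cfg)), 1L)
  expect_equal(nrow(local_search(pk, cand, cfg)), 0L)
  expect_equal(nrow(local_search(pk, cand, search_config(steps = 1))), 1L)
})

test_that("local hits are contained in global hits at identical settings", {
  lib <- polymer_library()
  cand <- select_units(lib, unit_criteria(mass_min = 14, mass_max = 120,
                                          use_ratios = FALSE))
  for (seed in 1:20) {
    pk <- random_planted_dataset(seed, cand)
    cfg <- search_config(0.0025, 0.0025, steps = 3)
    loc <- hit_set(local_search(pk, cand, cfg))
    glo <- hit_set(global_search(pk, cand, cfg))
    expect_true(all(loc %in% glo), label = paste("seed", seed))
  }
})

test_that("hit sets shrink as m grows and as tolerances shrink", {
  lib <- polymer_library()
  cand <- select_units(lib, unit_criteria(mass_min = 14, mass_max = 120,
                                          use_ratios = FALSE))
  for (seed in 21:30) {
    pk <- random_planted_dataset(seed, cand)
    for (alg in c("local", "global")) {
      run <- function(m, tol = 0.0025)
        hit_set(if (alg == "local")
          local_search(pk, cand, search_config(tol, tol, m))
        else global_search(pk, cand, search_config(tol, tol, m)))
      h1 <- run(1); h2 <- run(2); h3 <- run(3)
      expect_true(all(h3 %in% h2) && all(h2 %in% h1),
                  label = paste(alg, "m-monotone, seed", seed))
      expect_true(all(run(3, 0.001) %in% h3),
                  label = paste(alg, "tol-monotone, seed", seed))
    }
  }
})

test_that("planted sequential units are recovered by both algorithms", {
  lib <- polymer_library()
  cand <- select_units(lib, unit_criteria(mass_min = 14, mass_max = 120,
                                          use_ratios = FALSE))
  for (seed in 31:38) {
    pk <- random_planted_dataset(seed, cand)
    manifest <- attr(pk, "manifest")
    planted <- unique(manifest$unit_mass)
    cfg <- search_config(steps = 3)
    for (hits in list(local_search(pk, cand, cfg),
                      global_search(pk, cand, cfg))) {
      found <- vapply(planted, function(u)
        any(abs(hits$mass - u) < 1e-6), logical(1))
      expect_true(all(found), label = paste("seed", seed))
    }
  }
})

test_that("find_units orchestrates untargeted and targeted modes", {
  pk <- evaluation_mixture(seed = 42)
  lib <- polymer_library()

  un <- find_units(pk, search_config(mode = "untargeted"), library = lib)
  expect_true(all(un$algorithm == "global"))
  expect_true(all(c("C2H4OX2", "C3H6OX2", "CF2X2") %in% un$formula))
  expect_true(all(diff(un$count) <= 0))  # sorted by count desc

  tg <- find_units(pk, search_config(algorithm = "local", mode = "targeted"),
                   criteria = unit_criteria(mass_min = 14, mass_max = 200,
                                            use_ratios = FALSE),
                   library = lib)
  direct <- local_search(pk, select_units(lib, unit_criteria(
    mass_min = 14, mass_max = 200, use_ratios = FALSE)), search_config())
  expect_setequal(tg$formula, direct$formula)

  # empty candidate list: empty hits plus a warning
  expect_warning(
    empty <- find_units(pk, search_config(mode = "targeted"),
                        criteria = unit_criteria(mass_min = 500,
                                                 mass_max = 600),
                        library = lib),
    "no candidate")
  expect_equal(nrow(empty), 0L)
})

test_that("ppm tolerances scale with the target mass", {
  u <- 100.0
  pk <- peaklist(c(300, 400.002, 500.0035), rep(1, 3))
  cand <- data.frame(formula = "U", mass = u, dbe = 0)
  # 10 ppm of 400 = 0.004: first step matches; 10 ppm of 500 = 0.005 covers
  # the 0.0035 offset at step 2
  cfg <- search_config(10, 10, steps = 2, algorithm = "local", ppm = TRUE)
  expect_equal(nrow(local_search(pk, cand, cfg)), 1L)
  cfg2 <- search_config(1, 1, steps = 2, algorithm = "local", ppm = TRUE)
  expect_equal(nrow(local_search(pk, cand, cfg2)), 0L)
})

test_that("hit lists export with evidence records", {
  u <- monoisotopic_mass("C2H4OX2")
  ladder <- peaklist(c(100, 100 + u, 100 + 2 * u, 100 + 3 * u), rep(1, 4))
  hits <- global_search(ladder, peg(), search_config(steps = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  evpath <- withr::local_tempfile(fileext = ".tsv")
  write_unit_hits(hits, path, evidence_path = evpath)
  lines <- readLines(path)
  expect_match(lines[1], "^formula\tmass\tdbe\tcount")
  expect_match(lines[2], "^C2H4OX2\t44")
  expect_gt(length(readLines(evpath)), 1L)
})
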