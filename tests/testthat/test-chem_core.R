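# Element tables, DBE, formula validation and enumeration.

test_that("default element table carries the stock valences and limits", {
  tab <- default_element_table()
  expect_setequal(tab$symbol,
                  c("C", "H", "S", "O", "N", "P", "F", "Cl", "Br", "Si", "X"))
  expect_equal(tab$valences[[which(tab$symbol == "S")]], c(2L, 4L, 6L))
  expect_equal(tab$valences[[which(tab$symbol == "P")]], c(3L, 5L))
  expect_equal(tab$valences[[which(tab$symbol == "X")]], 1L)
  x <- tab[tab$symbol == "X", ]
  expect_equal(c(x$count_min, x$count_max), c(1L, 2L))
  expect_identical(unname(tab$mass[tab$symbol == "C"]), 12)
  expect_identical(unname(tab$mass[tab$symbol == "X"]), 0)
  lim <- setNames(paste(tab$count_min, tab$count_max), tab$symbol)
  expect_equal(unname(lim[c("C", "H", "S", "O", "N")]),
               c("0 10", "0 20", "0 4", "0 4", "0 2"))
  expect_equal(unname(lim[c("P", "F", "Cl", "Br", "Si")]),
               c("0 2", "0 4", "0 2", "0 2", "0 1"))
})

test_that("compute_dbe matches hand evaluation", {
  cases <- list(
    list("C:4=1 H:1=2 X:1=2", 0),    # methylene bridge
    list("N:3=1 X:1=1", 1),          # NX: DBE alone does not reject it
    list("C:4=2 H:1=4 O:2=1 X:1=2", 0),
    list("S:6=1 O:2=3", 3),          # SO3, hypervalent sulfur
    list("C:4=1 H:1=1", 1.5),        # half-integral flags impossibility
    list("C:4=1 O:2=1 H:1=8", -2)    # oversaturated: negative DBE
  )
  for (cs in cases)
    expect_equal(compute_dbe(parse_vcomp(cs[[1]])), cs[[2]])
})

test_that("validate_formula applies the saturation identity", {
  nx <- validate_formula(parse_vcomp("N:3=1 X:1=1"))
  expect_false(nx$valid)
  expect_identical(nx$reason, "saturation")
  expect_equal(nx$dbe, 1)  # Eq.-1 value still reported

  ch2 <- validate_formula(parse_vcomp("C:4=1 H:1=2 X:1=2"))
  expect_true(ch2$valid)
  expect_equal(ch2$dbe, 0)

  peg <- validate_formula(parse_vcomp("C:4=2 H:1=4 O:2=1 X:1=2"))
  expect_true(peg$valid)
  expect_equal(peg$dbe, 0)

  hx <- validate_formula(parse_vcomp("H:1=1 X:1=1"))
  expect_false(hx$valid)
  expect_identical(hx$reason, "no-polyvalent")

  frac <- validate_formula(parse_vcomp("C:4=1 H:1=1 O:2=1"))
  expect_false(frac$valid)
  expect_identical(frac$reason, "non-integer-dbe")

  neg <- validate_formula(parse_vcomp("C:4=1 O:2=1 H:1=8"))
  expect_false(neg$valid)
  expect_identical(neg$reason, "negative-dbe")
})

test_that("monoisotopic masses add up and X is massless", {
  expect_equal(monoisotopic_mass("C2H4OX2"), 44.02621, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("CF2X2"), 49.99681, tolerance = 1e-4)
  expect_identical(monoisotopic_mass("X2"), 0)
  expect_error(monoisotopic_mass("Zz2"), "unknown element")
  # additivity over a disjoint union of compositions
  a <- c(C = 2L, H = 4L, O = 1L)
  b <- c(C = 1L, F = 2L, S = 1L)
  ab <- c(C = 3L, H = 4L, O = 1L, F = 2L, S = 1L)
  expect_equal(monoisotopic_mass(ab),
               monoisotopic_mass(a) + monoisotopic_mass(b))
})

test_that("formula strings round-trip and follow Hill-like order", {
  expect_identical(format_formula(c(X = 2L, O = 1L, C = 2L, H = 4L)),
                   "C2H4OX2")
  expect_identical(format_formula(c(F = 2L, C = 1L, X = 2L)), "CF2X2")
  counts <- parse_formula("C2H4OX2")
  expect_equal(counts[c("C", "H", "O", "X")], c(C = 2L, H = 4L, O = 1L,
                                                X = 2L))
  expect_identical(format_formula(parse_formula("C10H2Cl2Si")),
                   "C10H2Cl2Si")
})

test_that("enumeration over C/H/X yields exactly methyl and methylene", {
  tab <- element_table(c("C", "H", "X"), list(4L, 1L, 1L),
                       c(0L, 0L, 1L), c(1L, 4L, 2L))
  vcs <- enumerate_formulas(tab)
  forms <- sort(vapply(vcs, function(v)
    format_formula(collapse_composition(v)), ""))
  expect_identical(forms, c("CH2X2", "CH3X"))
  # every output item re-validates
  expect_true(all(vapply(vcs, function(v) validate_formula(v)$valid,
                         logical(1))))
})

test_that("an N-only table enumerates to nothing (NX is impossible)", {
  tab <- element_table(c("N", "X"), list(3L, 1L), c(1L, 1L), c(1L, 1L))
  expect_length(enumerate_formulas(tab), 0L)
})

test_that("enumeration equals the brute-force oracle on random tables", {
  for (seed in 1:8) {
    tab <- random_small_table(seed)
    got <- sort(vapply(enumerate_formulas(tab), vc_key, ""))
    expect_identical(got, brute_enumerate_keys(tab),
                     label = paste("table seed", seed))
  }
})

test_that("saturation identity is consistent with the DBE for P > 1", {
  # substituting the computed DBE into the identity with chi = 1 gives 0
  for (seed in 1:60) {
    vc <- random_vcomp(seed)
    poly <- vc$valence >= 2L
    P <- sum(vc$count[poly]); M <- sum(vc$count[!poly])
    if (P <= 1L) next
    r <- validate_formula(vc)
    lhs <- sum(vc$count[poly] * vc$valence[poly]) / 2 - M / 2 -
      (P + r$dbe - 1)
    expect_equal(lhs, 0, label = vc_key(vc))
    expect_identical(r$valid, r$dbe >= 0 && r$dbe == round(r$dbe))
  }
})

test_that("substituted hydrocarbons with two connection points have DBE d", {
  for (n in 1:6) for (d in 0:min(3, n - 1)) {
    h <- 2 * n - 2 * d
    if (h < 1) next
    vc <- valenced_composition(c("C", "H", "X"), c(4L, 1L, 1L),
                               c(n, h, 2L))
    expect_equal(compute_dbe(vc), d, label = sprintf("C%dH%dX2", n, h))
  }
})

test_that("fast collapsed library equals the collapse of full enumeration", {
  for (seed in c(3, 7, 11)) {
    tab <- random_small_table(seed)
    fast <- build_unit_library(tab)
    slow <- collapse_to_library(enumerate_formulas(tab))
    expect_identical(fast$formula, slow$formula,
                     label = paste("table seed", seed))
    expect_equal(fast$mass, slow$mass, label = paste("table seed", seed))
    expect_equal(fast$dbe, slow$dbe, label = paste("table seed", seed))
  }
})

test_that("library text round-trips through write/read", {
  lib <- build_unit_library(polymer_test_table())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_unit_library(lib, path, header = c("test library"))
  back <- read_unit_library(path)
  expect_identical(back$formula, lib$formula)
  expect_equal(back$mass, lib$mass, tolerance = 1e-7)
  expect_equal(back$C, lib$C)
  expect_equal(back$X, lib$X)
})

test_that("the enumeration cap rejects pathological limits", {
  tab <- default_element_table()
  expect_error(enumerate_formulas(tab, cap = 5e6), "exceeding the cap")
  expect_error(build_unit_library(tab, cap = 1e3), "exceeding the cap")
})
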