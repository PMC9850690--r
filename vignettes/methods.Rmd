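---
title: "Detecting repeating chemical units in HRMS peak lists: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting repeating chemical units in HRMS peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unitfindr)
```

## Scope

`unitfindr` answers one question about a centroided high-resolution mass
spectrum: *which chemically plausible masses repeat in it, and how often?*
A "repeating unit" here is the mass increment linking members of a
homologous (typically polymeric) series — C₂H₄O for PEG, C₃H₆O for PPG,
CF₂ for perfluorinated chains, CH₂ for alkylation series. The package
covers the whole pipeline: formula library generation, chemical screening,
two detection algorithms, Kendrick mass defect support, data-reduction
filters, a synthetic-data generator, and a CLI. It deliberately does
*not* model adducts, charge states, isotopologue patterns, or downstream
series-linking in mass-defect space: hits (unit, count, evidence) are the
terminal output.

## The formula model

### The placeholder X

A repeat unit is a molecular *fragment*, not a molecule: it is bonded into
a scaffold at one or two points. We represent each open bond by a
placeholder atom X with valence 1 and **mass exactly 0 Da**. X
participates in valence bookkeeping (CH₂X₂ is methylene bridging two
neighbours) but never shifts the searched mass: the PEG unit C₂H₄OX₂
weighs `r sprintf("%.5f", monoisotopic_mass("C2H4OX2"))` Da, the mass of
C₂H₄O. Default generation allows 1–2 X per unit (end group vs. bridging
unit). Massless X is an inference — the convention is fixed by requiring
the PEG unit to weigh 44.0262 Da — and we treat it as definitional.

### Valence states

Sulfur (2, 4, 6) and phosphorus (3, 5) take several valence states in
organic compounds, so enumeration iterates each valence state of each
element as an independent axis; mixed combinations (e.g. one S(II) and one
S(VI) in the same unit) are reachable. Monoisotopic masses are AME2020
most-abundant-isotope values embedded as constants at ≥ 9 decimals.

### Validation

For a valenced composition with counts $E_i$ at valences $\nu_i$, the
ring-and-double-bond count is

$$\mathrm{DBE} = \tfrac12 \sum_i E_i(\nu_i - 2) + 1 .$$

A negative or non-integer DBE flags an impossible formula, but the DBE
test alone accepts fragments that cannot exist, NX being the canonical
example (DBE = 1). We therefore layer a saturation identity on top. Let
$P$ be the number of polyvalent atoms ($\nu \ge 2$), $M$ the number of
monovalent atoms, and $V$ the summed valence of the polyvalent atoms:

* $P = 0$: rejected. A unit made only of valence-1 atoms has no backbone
  to carry its bonds (this case is undefined in the source rule, which
  distinguishes only $P = 1$ and $P > 1$; rejection is our choice).
* $P = 1$: valid iff $V = M$ — the lone polyvalent atom must be exactly
  saturated by its monovalent partners. NX fails (3 ≠ 1); CH₂X₂ passes
  (4 = 4).
* $P > 1$: valid iff the DBE is a non-negative integer; with that DBE the
  saturation identity holds algebraically (the tests verify this over
  random compositions).

### Two enumeration routes

`enumerate_formulas()` is the literal iteration: every valence-state axis
is materialised, every grid point validated. It is exact and simple, and
the test suite pins it to an independent brute-force nested-loop oracle —
but it cannot scale to the default table, whose valence-state grid has
~10⁹ points.

`build_unit_library()` therefore works on the *collapsed* per-element
count grid (~9.4 × 10⁶ points for the default table) and decides "valid
under at least one valence assignment" analytically: within one collapsed
composition, the achievable $V$ values form a contiguous range of step 2
(the valence states of S and P differ by 2), so validity reduces to a
parity check plus a range check, fully vectorised. The recorded DBE is the
smallest valid one (the most saturated assignment); compositions differing
only in valence assignment appear once, because the searched quantity —
mass — depends only on the collapsed composition. The fast route requires
every element's states to be "all 1" or "all ≥ 2 with step 2"; exotic
tables fall back to the literal route. Both routes are cross-checked
against each other in the tests. The full default build yields 3,853,273
formulas in ~100 s and is cached per session; passing a custom library to
`find_units()` avoids it entirely.

A configurable cap (default 2 × 10⁹ raw valence-state grid points for the
library builder, 5 × 10⁶ for the materialising enumerator) aborts
pathological limit settings with a clear error.

## Selection criteria

`default_criteria()` reflects common organic-chemistry screening
heuristics: per-element count limits (C ≤ 10, H ≤ 20, S ≤ 4, O ≤ 4,
N ≤ 2, P ≤ 2, F ≤ 4, Cl ≤ 2, Br ≤ 2, Si ≤ 1, X 1–2), elemental ratios per
carbon (0.3 ≤ H/C ≤ 4.0, N/C ≤ 1.3, O/C ≤ 1.2, P/C ≤ 0.3, S/C ≤ 0.8,
F/C ≤ 1.5, Cl/C ≤ 0.8, Br/C ≤ 0.8, Si/C ≤ 0.5; all bounds inclusive), a
unit mass window of 14–200 Da, and a DBE ceiling of 40. Each filter can be
disabled. Design choices worth knowing:

* **Carbon-free compositions pass the ratio filters vacuously** — the
  bounds are all "per C", and pure S/O units (e.g. SO₃) are legitimate.
* **X never enters ratio computation**; it is bookkeeping, not an atom.
* **The DBE ceiling of 40** is a user-tunable guard, not a sharp chemical
  claim: for ≤ 200 Da units it is effectively inactive, which is the
  point — the referenced "maximum DBE rule" comes without a published
  number.
* **Untargeted mode (`auto_criteria()`) disables the ratio screen.** This
  is the one deliberate deviation from a naive reading of the source
  filters, and it matters: the ratio heuristics presuppose
  hydrogen-bearing CHNOPS organics, and would silently discard CF₂
  (H/C = 0, F/C = 2) — the flagship perfluoro unit that untargeted
  analyses are expected to recover. An untargeted first pass must not
  presuppose composition class; analysts who want the ratio screen can
  enable it in targeted mode, where all filters are fully adjustable.
* Untargeted mode also caps the unit mass at max(m/z) divided by the
  minimum desired repetition count (default 3): a heavier unit could not
  repeat often enough to be detected.

## The search algorithms

Both algorithms share the tolerance model: a **selection error** for the
first match of a candidate and a **loop error** for chained/multiplied
matches, both absolute Da by default (0.0025 Da each), with an optional
ppm mode. Absolute Da matches the "± error" matching semantics and keeps
chain tests independent of absolute mass; the defaults correspond to
~5 ppm at m/z 500 and are deliberately conservative for Orbitrap/FT-ICR
data. The repetition requirement *m* defaults to 3. None of these
defaults are published values; they are this package's own, chosen once
and documented here.

**Local (chain) search.** For candidate u and peak p, a chain opens if
some peak matches p + u within the selection error, and extends by testing
the *theoretical* sums p + n·u (not the matched peak's observed m/z — this
prevents error accumulation) within the loop error, until n = m. A
candidate is reported iff at least one complete chain exists; its count is
the number of distinct chain-starting peaks. One complete chain suffices
(the alternative — requiring several — is left to users via the reported
counts).

**Global (difference) search.** All N(N−1)/2 pairwise differences are
computed once. A candidate is reported iff each multiple k·u (k = 1…m)
matches some difference (selection error at k = 1, loop error above); no
locality constraint is applied. The count is the total number of matching
differences over k = 1…m. A lenient mode (`strict_multiples = FALSE`,
non-default) relaxes "every multiple" to "the first multiple plus at
least one higher multiple".

Matching uses binary search (`findInterval`) over the sorted peak and
difference arrays; any peak within tolerance counts once per step, with
the nearest recorded as evidence. When several near-isobaric candidates
match the same pattern, all are reported — disambiguation is the
analyst's call, and the evidence records make recounting possible.

Two structural properties follow from these definitions and are enforced
as tests: local hits are always a subset of global hits at identical
settings (a complete chain implies all multiples exist as differences),
and hit sets shrink monotonically as m grows or tolerances shrink.

`find_units()` orchestrates: untargeted mode = auto-derived criteria +
global search (chosen as default because it also catches weak local
repetition); targeted mode honours the caller's criteria and algorithm.
Hits are sorted by count descending, then mass ascending.

### Scaling

Global search pays an O(N²) difference construction once, then O(m log N²)
per candidate; local search pays O(m · N log N) per candidate. Growing the
candidate library therefore hurts the local search roughly linearly while
the global search amortises its fixed cost — the benchmark in the
acceptance tests asserts exactly this shape (and only the shape; absolute
timings are hardware noise).

## Kendrick mass defect

`kendrick_transform()` computes KM = m/z × nominal(u)/exact(u) with
nominal(u) = round(exact(u)), and KMD = round(KM) − KM. Round-to-nearest
(rather than floor) keeps KMD in (−0.5, 0.5] and matches common practice
for CH₂-based plots; the sign convention is "accurate subtracted from
nominal". For an exact series b + k·u the KMD is constant to floating
point (≤ 10⁻⁹ asserted), and its spread grows smoothly with injected mass
jitter — which is what makes the transform a useful verification tool for
reported hits.

## The synthetic generator

`generate_spectrum()` emulates what the detection algorithms are designed
for, and nothing more: arithmetic ladders scaffold + k·u with a monotone
exponential intensity envelope (decay 0.85/rung), optional sparse presence
(an explicit rung subset or a sampled fraction), truncated-normal mass
jitter, and uniform noise peaks. Two guard rails keep tests deterministic:

* jitter is truncated at ±3σ, and the default σ = 0.0004 Da makes the
  worst-case error of a *difference* (2 × 3σ = 0.0024 Da) fit inside the
  default loop error of 0.0025 Da — so planted ladders are recoverable by
  construction, not by luck;
* noise peaks are re-drawn until they are more than 0.005 Da (twice the
  loop error) from every planted position.

What the generator does **not** emulate: isotope patterns, charge
envelopes, mass-dependent resolution, detector saturation, correlated
(calibration-drift) mass errors, or a chromatographic dimension. A green
recovery test therefore establishes the algorithms' correctness on the
stated model of homologous series, not instrument-grade performance on
real spectra; the data filters (`filter_top_n()`, `filter_intensity()`)
exist precisely because real data are denser and dirtier than this model.

The three-series evaluation mixture used throughout the tests (sequential
C₂H₄O and C₃H₆O ladders plus CF₂ kept only at rungs {0, 1, 3, 6}) is
constructed so that the CF₂ pattern supplies the difference multiples
1u, 2u, 3u without containing any 3-step sequential chain: the global
search finds it at defaults, the local search provably cannot, and
loosened targeted parameters (m = 1) recover it — the designed contrast
between the algorithms.

## Numerical and degenerate-input choices

* Peak lists are sorted on ingest; exact duplicate m/z rows are merged by
  summing intensity.
* Intensity threshold: "smaller than i is removed", so equality survives
  and the base peak always does. Top-N ties at the cutoff keep the lower
  m/z. The two filters are independent operations, never silently chained.
* Tolerance windows are closed (boundary-inclusive) on both sides.
* All counts and bounds are validated at construction; empty peak lists,
  all-zero intensities and non-positive unit masses raise errors rather
  than propagating NaN.
* Library export rounds masses to 7 decimals (0.05 ppm at m/z 200 —
  negligible against the 0.0025 Da search tolerance); peak-list export
  defaults to 6 decimals.

## Known limitations

* Neutral mass differences only: no adduct/charge awareness, so
  multiply-charged series (spacing u/z) are not modelled.
* The global count conflates co-linear candidates (k·u ≡ j·v); expect
  combination formulas among the hits and use the evidence to
  disambiguate.
* The full default library build is ~100 s and memory-heavy; supply a
  domain-restricted element table when you know the chemistry.
* Validation is saturation arithmetic, not structure generation: a
  "valid" formula is bondable in principle, not guaranteed synthesizable.
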