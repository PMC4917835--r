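---
title: "Structure-economy analysis of chemical catalogues: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-economy analysis of chemical catalogues: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qser)
```

## The problem

Commercial building-block catalogues quote prices the way any commodity
market does: per weight unit, in $/g. Chemistry, however, counts
molecules. A gram of benzene (C6H6, 78 Da) contains three times as many
molecules as a gram of [18]annulene (C18H18, 234 Da), so a $/g price
and a $/mol price rank the same compounds differently. `qser`
implements the analysis machinery for asking, across a catalogue of
millions of compounds, what the market is actually pricing: the mass of
material, the number of molecules, the atom count a chemist sees in the
structure drawing, or the difficulty of synthesis.

The package computes everything from the molecular *formula* alone —
molecular weight (average and nominal), atom counts, heteroatom
composition, nominal-mass parity. This is deliberate: at the
catalogue scale the interesting signal turns out to live in
composition-level descriptors, and formulas are the one representation
every vendor file provides reliably.

## Price metrics

Two metrics are interconverted by `wbm_to_mbm()` / `mbm_to_wbm()`:

* **WBM** (weight-based): the vendor's $/g price, `P1`.
* **MBM** (molar-based): `P2 = P1 × MW` in $/mol, with MW the
  *average* molecular weight in g/mol. Nominal (integer,
  most-abundant-isotope) masses are used only where parity matters —
  they are the masses the nitrogen rule is a statement about.

The element mass tables are frozen inside the package (IUPAC
conventional atomic weights; integer mass numbers of the most abundant
isotopes) so descriptor values cannot drift with external data updates.

## Data binning

`build_bin_table()` groups records into fixed-width, half-open bins
`[origin + k·w, origin + (k+1)·w)` — by default 1 Da over MW — and
computes per-bin occupancy and per-variable means. Records in the same
1 Da MW bin ("iso-MW" compounds) are structurally diverse but
mass-equivalent, so bin means of price and atom counts expose trends
that record-level correlations (typically |R| < 0.5 at this scale)
drown in noise. Numerical choices:

* bins are floor-based and anchored at origin 0, so tables at 1 Da and
  2 Da resolutions compose exactly (a 2 Da bin is the union of two
  1 Da bins — the package tests assert the re-aggregation identity to
  1e-9);
* empty bins inside the data range are emitted with count 0 and `NA`
  means, never zero-filled, and are excluded from bin-level
  correlations;
* the bin's representative x-value in `binned_r()` is its center by
  default, with the within-bin mean of the binning variable as a
  configurable alternative — the choice is not dictated by anything in
  the method, so it is exposed rather than hidden;
* bin means conserve totals: for every tracked variable,
  `sum(n_b * mean_b)` equals the raw column sum.

`binned_r()` correlates bin means against bin representatives with one
*unweighted* point per occupied bin. Weighting by occupancy would hide
exactly the sparse-bin instability (high-MW bins with a handful of
records) that the occupancy column is meant to expose; users filter
with `range`/`min_occupancy` instead.

## Credibility nulls

Bin means are averages, and averaging manufactures smoothness; a
correlation across bins can look impressive for structureless data.
`qser` therefore ships two seeded Monte-Carlo nulls:

* `random_variate_null()`: replace the response with i.i.d.
  Uniform(0,1) draws, keep the descriptor fixed;
* `shuffled_price_null()`: randomly permute the real price column
  (Fisher–Yates via `sample.int()`), preserving its marginal
  distribution — every order statistic — exactly.

At the record level both nulls concentrate near the folded-normal
limit `E|R| = sqrt(2/(π n))` (`expected_null_abs_r()`), about 5.3e-4
at n = 2.25 million — three orders of magnitude below the observed
record-level correlations, which is what licenses reading those
correlations as signal. At the bin level the same nulls are run on bin
*means*, where only as many points as occupied bins enter; the null
|R| inflates accordingly (order 0.05 for a few hundred bins), and that
inflated value — not the record-level one — is the right yardstick for
a binned correlation. Every null result records its seed, run count
and n, and is bit-reproducible.

Run counts of 10,000 (record-level) and 2,000 (binned) are the
reference settings; the package's own tests and the bundled acceptance
script use 150–400 runs, which puts the Monte-Carlo standard error of
the mean |R| one to two orders below the quantities being compared
while keeping the default suite inside a coffee break.

## Nitrogen rule and sub-libraries

For molecules containing only C, H, N and O, the parity of the nominal
molecular mass equals the parity of the nitrogen count (C and O
contribute even mass and even valence; H contributes odd mass but is
constrained by valence; each N, with even mass 14 and odd valence 3,
flips the hydrogen count's parity instead of its own). `qser` uses the
rule twice:

* as a *data-curation check* — `nitrogen_parity()` flags records whose
  stored formula violates it;
* as an *analysis lens* — `parity_split_bins()` splits a C/H/N/O
  nitrogen sub-library (`extract_sublibrary()`) into even- and odd-MW
  classes and compares their mean prices within MW bins, alongside
  their mean N counts. Note the parity classes occupy alternating
  nominal masses, so a within-bin contrast requires bins at least 2 Da
  wide; the default here is 2 Da.

`heteroatom_price_profile()` reports mean price as a function of an
element's per-molecule count. No grouping of elements into
"cheap"/"expensive" classes is hard-coded; the profiles let the data
show it. Per-count means below 30 records (configurable) are flagged
unreported — sparse-cell means are noise.

## The synthetic catalogue generator

No vendor catalogue can be redistributed, so every pipeline stage is
exercised against `generate_catalog()`, whose defaults define the
package's reference conditions:

* **MW distribution**: a three-component Gaussian mixture truncated to
  [218.26, 738.74] Da — weights (0.600, 0.388, 0.012), means
  (250, 300, 480) Da, SDs (24, 34, 110) Da — calibrated once,
  numerically, so that the mode sits near 250 Da, ~96% of records fall
  below 350 Da and ~99% below 400 Da. The fine comb of sharp maxima a
  real catalogue shows (preferred scaffolds at particular masses) is
  *not* emulated; a smooth mixture cannot and does not claim to
  reproduce peak placement.
* **Formulas**: heteroatom counts are drawn per element (inclusion
  probabilities chosen so every heteroatom sub-library holds ≥1,000
  members at n = 1e5), then integer C/H counts are solved so the
  average mass lands within 0.5 Da of the sampled target and the
  degree of unsaturation `DBE = (2C + 2 + N − H − halogens)/2` is a
  non-negative integer. Because DBE integrality ties H's parity to
  N + halogens, some fractional masses are reachable in only one
  parity class; the solver therefore tries each heteroatom draw both
  as-is and with one extra N (a parity flip), scanning a wide carbon
  window (the mass residual drifts only ~0.085 Da per carbon once
  parity is fixed). Every emitted formula is valence-feasible, and
  C/H/N/O records obey the nitrogen rule by construction.
* **Prices**: `P1 = max(floor, intercept + 2.0·min(MW, 250) +
  Σ_e count(e)·premium(e) + N(0, 150))` in $/g. The slope saturates at
  250 Da — the reference claim is that mean price rises with MW only
  through the low-MW range — and the premiums plant the recoverable
  effects: N +15, O/S/F +5, Cl −20, Br −25, Se −25, I −30 $/g per
  atom. The intercept is solved per catalogue so the expected mean
  price is 537.83 $/g.
* **SAS column**: a stand-in score, affine in the total atom count on
  a 1–10 scale with Gaussian noise whose SD is set by inverting the
  attenuation identity `corr = 1/sqrt(1 + σ²_noise/σ²_signal)` for a
  target corr(SAS, AC) = 0.380. It reproduces that one marginal
  correlation and nothing else about any real synthetic-accessibility
  method.

What passing tests on this generator shows: the pipeline's statistics
(binning, correlations, nulls, parity splits, profiles) recover known
planted structure at realistic scale and noise. What it does not show:
anything about real market prices — the generator's price model is
linear by construction, so e.g. a high bin-level correlation of molar
price with MW on synthetic data validates the estimator, not the
economics.

## Degenerate inputs and numerical conventions

* Correlations require ≥3 complete observations and non-constant
  vectors; constant inputs are an error, never a silent 0 or NA.
* The correlation matrix uses listwise deletion (records missing any
  requested variable leave the matrix, not the catalogue).
* Curation never crashes on a bad record: unparseable structures
  without a formula field, non-positive or unparseable prices, and
  duplicates (same id, or same formula at the same price) are dropped
  and *counted*; the report's categories always reconcile with the
  input size.
* Prices accept a leading/trailing currency symbol; thousands
  separators are rejected rather than guessed.
* V2000 connection tables get implicit hydrogens as
  `max(0, valence − bond-order sum − |charge|)` with lowest-feasible
  valence states for S and P; aromatic (order 4) bonds count 1.5 and
  the sum is rounded up. V3000 input is an explicit unsupported-dialect
  error. When both a formula field and a connection table exist, the
  formula field wins (vendor MF fields reflect salts/hydrates the
  drawing may omit).
* The SD writer emits zero-atom connection tables plus `MF`/`PRICE`/
  `SAS` data items rather than realizing formulas as bonded graphs:
  the reader's formula-field path is exactly what formula-only vendor
  records use, and inventing ring/multiple-bond layouts for arbitrary
  DBE would add chemistry the analysis never consumes. Connection-table
  parsing is tested against hand-built V2000 fixtures and
  cross-checked against ChemmineR where available.

## Problem sizes

The shipped tests run the full analysis at n = 1e4–1e5 records, the
generator calibration at n = 1e6, and the null simulations at the full
reference size n = 2,248,243 with 150–400 Monte-Carlo runs; the
complete suite finishes in under two minutes on one core. All sizes
are plain function arguments — nothing in the package is specialised
to them.

## Known limitations

* Formulas are flat Hill strings: no parentheses, hydrates, isotopes
  or charges in the grammar (catalogue MF fields are flat in
  practice).
* No structure normalization (salt stripping, tautomers,
  canonicalization); deduplication is by id or (formula, price) only.
* The generator's price model is piecewise-linear with additive
  Gaussian noise — adequate for estimator validation, silent on price
  heteroscedasticity and vendor-specific pricing rules.
* Binned correlations treat bins as exchangeable points;
  no autocorrelation-aware inference across adjacent bins is
  attempted.
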