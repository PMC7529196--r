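---
title: "Processing CE probing data with ceprobe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing CE probing data with ceprobe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceprobe)
```

## The problem

Chemical probing reagents such as SHAPE electrophiles and dimethyl
sulfate (DMS) modify RNA nucleotides in a structure-dependent way:
flexible, unpaired positions react more. Reverse transcription stops at
the adduct, and capillary electrophoresis (CE) of the fluorescently
labeled cDNA fragments yields, after upstream signal processing in
ShapeFinder or QuShape, a per-nucleotide table of peak areas for the
modification reaction and for an untreated background control. Two
quality-control steps stand between those tables and a reactivity
profile usable as pseudo-energy restraints for RNA folding software:

1. **Exclusion of RT strong-stops** — positions where reverse
   transcription terminated for reasons other than an adduct
   (pre-existing cleavage or modification). Their signal is an artifact.
2. **Normalization** — absolute, background-subtracted reactivities are
   on an arbitrary fluorescence scale and must be mapped to the uniform
   scale (roughly 0–2, with 1 near the mean of the most reactive
   positions) that downstream tools expect.

`ceprobe` implements both steps, plus replicate averaging, a statistical
comparison cascade, plotting, `.shape` output and an adapter to an
external folding engine.

## Strong-stop exclusion

The automated classifier computes the average background peak area
`mean_bg` once, over all non-missing positions, and excludes a position
when the first of these criteria fires:

* **C1** — the absolute reactivity is negative;
* **C2** — the background peak area is at least `5 * mean_bg`
  (inclusive: a position exactly on the 5x line is excluded);
* **C3** — the reaction-minus-background difference is below
  `0.35 * mean_bg` *and* the background is at least `mean_bg`.

Criteria are ratio tests against `mean_bg` or sign tests, so the mask is
invariant under rescaling all areas by a positive constant — a property
the tests verify. Two points were genuinely open and are fixed here:

* `mean_bg` is a **single pass**. No re-computation after excluding
  high-background positions; nothing in the procedure's description
  suggests iteration, and a fixed point would complicate the otherwise
  order-free criteria.
* C1 in automated mode uses threshold exactly 0 (not a configurable
  negative threshold, which belongs to the manual mode).

The manual mode replaces C1–C3 with user choices: an explicit set of
positions to exclude, a negative-reactivity threshold, and one of three
treatments for sub-threshold values — keep them, zero them, or mark them
as no-data. Values kept negative stay in the analysis and participate in
the normalization quartiles; silently dropping them would contradict the
user's explicit choice.

## Box-plot normalization

Given the reactivities `V` at the `n` reliable positions (at least 10
are required; below that the data cannot support a stable scale and the
function errors):

1. `Q1`, `Q3` are computed by **linear interpolation between order
   statistics** (the quantile "type 7" convention). No convention is
   canonical in the field's descriptions; this one is the R default,
   and it is pinned by a frozen example: for `V = 1..100`,
   `Q1 = 25.75`, `Q3 = 75.25`, upper extreme `149.5`, effective maximum
   `96.5` (the mean of 93..100).
2. The upper extreme is `UP = Q3 + 1.5 * IQR`. Values above `UP` are
   outlier candidates, capped at `floor(0.10 n)` when `n > 100` and
   `floor(0.05 n)` otherwise. When candidates exceed the cap, the
   largest values win (ties: higher value, then lower position) — the
   most extreme values are the ones that most distort the scale.
   The "longer than 100 nucleotides" rule is read as `n > 100` **data
   points**, since the computation operates on the included data
   vector, not the declared RNA length; `n = 100` therefore takes the
   5% branch.
3. The **effective maximum** is the mean of the top
   `ceiling(0.08 * n_nonoutlier)` non-outlier values, with a minimum of
   one so the set is never empty.
4. Every reliable value — **outliers included** — is divided by the
   effective maximum. Outliers are flagged in the diagnostics but kept
   in the output: they are excluded only from computing the scale, not
   from the data. Excluded positions become missing and are written as
   `-999` downstream.

Color bins for display are half-open: `[0, 0.4)` black, `[0.4, 0.85)`
orange, `[0.85, Inf)` red; negative values (manual keep policy) land in
the black bin.

For DMS experiments an optional A/C restriction flags G/U positions as
missing before exclusion and normalization, since DMS probes the
Watson–Crick edge of A and C only. It is **off by default**: the core
pipeline normalizes whatever survives exclusion, and the restriction is
an explicit user decision.

## Replicates and comparison statistics

Replicate profiles (1–15) are averaged per position with the sample
(`n-1`) standard deviation, skipping missing values rather than imputing
zeros; the per-position support `n_obs` is reported. Sample sd is the
right convention because replicates are a sample of experimental
repetitions, and it is pinned by the example `mean(1, 2) = 1.5`,
`sd ≈ 0.7071`.

The comparison cascade over 2–5 experiments pools each profile's
non-missing values into one sample and runs Shapiro-Wilk per sample and
Bartlett across samples, then — only if **any** sample departs from
normality at `alpha` — a two-sided Mann-Whitney test (2 samples) or a
Kruskal-Wallis rank-sum test (3–5 samples). Design points:

* *Any vs all non-normal*: nonparametric location tests are justified as
  soon as one sample violates normality, so "any" gates the branch.
* When all samples pass normality, **no** location test runs and the
  report says so; no parametric fallback is defined for this pipeline.
* Bartlett's verdict is informational; it does not gate the branch.
* The Mann-Whitney test is two-sided (no direction is privileged when
  comparing probing conditions), exact for samples of at most 20,
  normal approximation with continuity correction above that.

All standard tests are base R's `shapiro.test`, `bartlett.test`,
`wilcox.test` and `kruskal.test`; the package owns only the cascade.

## Plots and output

Bar plots color each position by its bin; missing positions are gaps,
never zero-height bars — a zero would fabricate "unreactive" signal.
Step plots break at missing runs. Comparison box plots put whiskers at
the sample minimum and maximum (position measures, not 1.5 IQR fences),
and violins show the density per experiment. Figure geometry and fonts
are fixed defaults (overridable), so repeated renders of the same plot
are byte-identical — which the tests exploit.

`.shape` files are two-column TSV, three decimal places, `-999` for
missing, contiguous positions 1..L (use `pad_profile()` to fill gaps).
The spreadsheet export is a plain-text workbook — a directory of CSV
sheets (raw input per experiment, normalized values per replicate with
bin tags, mean ± SD) plus a JSON manifest.

The structure adapter does **no folding of its own**: it writes the
FASTA and `.shape` restraint files, invokes an external RNAstructure
`Fold`-compatible executable, and parses the connectivity-table result
into pseudoknot-free dot-bracket. SHAPE slope/intercept are passed
through untouched. The adapter is fully testable against a mocked
executable.

## The synthetic-data generator

`synthetic_spec()` / `generate_experiment()` emulate the peak-area
tables the pipeline consumes, with planted strong-stops and a known
intended reactivity profile. Defaults describe a typical CE experiment:
300 nt (CE resolves roughly 300–600 nt per read), gamma-distributed
background areas (mean 100 arbitrary fluorescence units, shape 8,
truncated to 0.5–2x the mean), log-normal signal noise with sd 0.1 per
replicate, and an intended profile drawn from a right-skewed gamma
capped at 1.5 — mostly unreactive positions with a reactive tail, as in
real profiles.

The generator guarantees margins by construction rather than by
rejection sampling:

* every reliable position carries a background-subtracted signal of
  `(0.45 + intended) * mean_bg`, so its difference is at least 10%
  above the C3 threshold even at the lowest noise factor (noise factors
  are clamped to `[0.87, 1.15]`);
* background truncation at `2 * bg_mean` keeps clean positions at least
  10% below the C2 line;
* planted stops are realized as `diff = -0.3 * mean_bg` (NEGATIVE),
  `bg = 5.5 * mean_bg` (HIGH_BG), or `bg = 1.5 * mean_bg` with
  `diff = 0.2 * mean_bg` (LOW_DIFF), and the planted background levels
  are solved **jointly** with the mean in closed form
  (`m = s / (L - 5.5 k_high - 1.5 k_low)`), so the realized mean equals
  the design mean exactly and every margin is checked post hoc.

Consequences: classifier recovery of the planted mask is exact, not
probabilistic, for every seed — an intentionally rigid test. An
adversarial `HIGH_BG_BOUNDARY` mode places a stop exactly on the 5x
line to pin the inclusive comparison. What the generator does **not**
emulate: electropherogram-level effects (peak overlap, mobility shifts,
signal decay), correlated noise along the read, and partial reverse
transcription drop-off. Passing tests therefore show the pipeline's
logic is correct on well-formed tables, not that upstream signal
processing is solved — that is ShapeFinder/QuShape's job.

The baseline signal offset deserves a note: real profiles contain truly
unreactive positions whose difference is near zero, and on real data
such positions with above-average background are (correctly) excluded
by C3. The generator's offset exists so that the *planted* mask is the
*provable* mask; it trades that one realism point for exactness.

## Problem sizes and numerical choices

The test suite and the acceptance script use 1000 random experiments of
up to 50 records for the criteria-transcription equivalence, 20 seeds
at lengths 100–600 with 5–30 planted stops for recovery, 50 random
vectors (n 10–250) for the normalization invariants, and 500
same-distribution pairs (n = 50 each) for the Mann-Whitney type-I rate
— sizes at which each property is decisive while the whole suite runs
in seconds. Normalization agreement is asserted to 1e-12 against a
brute-force transcription and 1e-9 for the rescaling invariant (two
divisions on different scales); the type-I band `[0.03, 0.07]` is ±2
binomial standard deviations around 0.05 at n = 500.

## Known limitations

* Overlapping-read merging for long RNAs is not implemented.
* The exact output column order of ShapeFinder builds varies; the
  positional five-column map is a documented assumption, and the
  QuShape header map is overridable via `dialect`.
* The sign convention for absolute reactivity is fixed as
  reaction − background (adduct signal positive); files that encode the
  opposite convention must be negated upstream.
* Per-nucleotide paired testing and multiple-testing correction across
  positions are out of scope; the cascade compares whole-profile
  distributions only.
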