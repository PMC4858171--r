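---
title: "Methods: the co-expression and misregulation screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the co-expression and misregulation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexscreen)
```

## The experimental design and its vocabulary

The screen assumes a factorial qRT-PCR experiment: a set of strains (one
wild type plus insertional mutants), grown in several nitrogen contexts and
harvested at several times after induction. The default design
(`default_design()`) is 9 strains × 4 conditions (4 mM nitrate; 8 mM
ammonium; nitrate + 8 mM ammonium; nitrate + 1 mM ammonium) × 4 time points
(0.5, 1, 3, 24 h), i.e. 144 samples, each measured for a 12-gene candidate
panel with *CYG56* as the reference gene and a ubiquitin-ligase transcript
("UBQ") as the qPCR internal standard. Condition labels are fixed spellings
(`NO3_4mM`, `NH4_8mM`, `NO3_4mM+NH4_8mM`, `NO3_4mM+NH4_1mM`) so that tables
join reliably; time points are stored as decimal hours so that sorting is
numeric. Two panel slots (`CG-A`, `CG-B`) are configurable placeholders for
candidates a user may wish to substitute.

Measurements travel as tidy long-format tables (`measurement_table`), one
row per (sample, gene), with a single declared value kind (`ct`,
`relative_expression`, `fold_change`, `log2_fold_change`). Missing
measurements are absent rows, never sentinel numbers, and all statistics
downstream use pairwise-complete data with the sample count `n` reported
per result so differing coverage is visible. Validation is total: malformed
input (duplicate rows, out-of-range values, unknown labels, `NA`
sentinels) is rejected with a named error, never repaired.

## From threshold cycles to relative expression

Quantification uses the comparative-Ct form against the internal standard
measured in the same sample: `E^(Ct_ref − Ct_target)` with amplification
efficiency `E = 2` (perfect doubling) by default. No efficiency corrections
or multi-reference normalizations are applied — `E` is exposed as a
parameter in `(1, 2]` for users with calibrated assays. Replicates are
aggregated (arithmetic mean; sample SD with the n−1 denominator, 0 for a
single replicate) *before* the screens, which consume one value per
(sample, gene). Normalization happens per well, then replicates are
averaged.

## The co-expression screen

`coexpression_screen()` implements the pipeline:

1. **Own-mutant removal.** A gene's values in the strain carrying its own
   insertional knockout reflect the insertion, not regulation, so they are
   not considered for that gene at all. They are removed *before* the
   centring means are computed, which makes each gene's results exactly
   invariant to whatever value the disrupted gene takes in its own mutant
   (the suite asserts this by planting extreme artifacts). Genes whose
   mutant was never profiled lose nothing.
2. **Mean-centring** (`mean_center()`). Within each (gene, condition,
   timepoint) cell, values are divided by the cell's arithmetic mean across
   strains (wild type included). Centring is per condition × time cell, not
   per condition pooled over time: the point is to remove *both*
   environmental axes, and pooled centring would leave the time signal in.
   The mean is taken on the linear scale and the log2 comes strictly after,
   in that order. Cells with fewer than two strains, and all-zero cells,
   yield missing outputs.
3. **log2 transform** (`log2_transform()`), with zeros floored at a
   configurable `2^-10` rather than dropped, so strong knockdowns in
   non-excluded strains stay informative.
4. **Pearson correlation** (`pearson_cor()`) of each candidate against the
   reference over admissible samples: by default the union of both genes'
   own-mutant strains is excluded (a sample must be admissible for both
   members of the pair), plus any user `leave_out` strains; then
   pairwise-complete filtering. The two-sided p comes from the exact t
   transform `t = r√((n−2)/(1−r²))` on `n−2` df; `|r| = 1` reports the
   smallest representable positive double. Results are ranked by `r²` with
   lexicographic tie-break on the gene label; degenerate genes (constant
   vector, `n < 3`) surface as flagged rows rather than aborting the
   screen.

Under the default design with complete data this yields `n = 128` for a
candidate whose mutant was not profiled (144 − 16 reference-mutant samples)
and `n = 112` when the candidate's own mutant was also profiled, or when one
strain is left out.

A `pair_exclusion = "per_gene"` switch retains the reference's own-mutant
samples for candidates; because own-mutant rows are removed before centring,
this switch only changes results when the screen is fed a precomputed
fold-change table that still carries those rows — with raw expression input
the reference is simply absent in its own mutant either way.

`invert_pearson_p(p, n)` inverts the t transform: given a reported p-value
and a sample count it returns the implied `R²`. This is useful as a
consistency check between a published (R², p) pair and the sample count
behind it; for p = 2.24 × 10⁻¹¹ the implied R² crosses 0.343 near n ≈ 109–112,
exactly the union-exclusion leave-one-strain-out count of the default
design (and slightly lower counts correspond to a handful of missing
wells).

## The misregulation screen

`misregulation_screen()` summarizes each (mutant, gene) pair by the mean
fold change over *all* of the strain's samples — 16 points under the default
design — so the profile reflects the gene's general behaviour in that mutant
and a single aberrant condition cannot flip it (a one-in-16 corruption by a
factor ≤ 3 around an otherwise flat profile never crosses the cutoff; the
suite enumerates this). Profiles are flagged `down` below 1/3 and `up` above
3, with strict inequalities: the threefold band is a highlight zone, and a
gene sitting exactly on the boundary is not flagged. The arithmetic mean of
linear fold changes is the default (matching means computed on data already
expressed as fold change); a geometric-mean option exists because the
back-transformed-log alternative is equally defensible. The wild type is
excluded from profiles but included in the centring means — it is one of the
strains the mean is taken over.

## The synthetic-data generator

`simulate_dataset()` draws, for sample s and gene g,
`2^(b_g + c_g(cond) + t_g(time) + e_g(strain) + ε)` with
`ε ~ N(0, σ²)` on the log2 scale — multiplicative lognormal noise, matching
the log-scale analysis space; heavier-tailed noise is out of scope for the
default. One RNG stream is seeded once per dataset and consumed
sample-major, gene-minor, so an identical seed is bit-reproducible and
appending genes to the panel does not perturb earlier columns within a
sample. A gene in its own profiled mutant takes `2^knockout_floor_log2`
(default −10) exactly, and everything is clipped below at a detection floor
(default `2^-10`).

The default configuration (`default_config()`, shipped as
`inst/extdata/non1_screen.yaml`) encodes the qualitative structure the
screen is meant to detect, with magnitudes chosen once as plausible
qRT-PCR-scale values:

* ammonium induction of *CYG56* and *CDP1* (+2 log2 under 8 mM ammonium,
  +1 under 1 mM, −0.5 by 24 h) — removed by centring, kept for realism;
* a latent shared-regulator activity per strain (0 in the wild type, ±0.5–2.5
  log2 across mutants) onto which the planted co-regulated trio loads
  (*42.49CG1* at 1, *85.37CG* and *209.82CG* at 0.9) along with the
  reference (1); *CDP1* loads weakly (0.1), the stable genes not at all;
* a distinct strain-54.10 signature: −3 log2 on *CYG56*, *CDP1* and
  *42.49CG1*, −1 on *85.37CG*, 0 on *209.82CG* — so one co-expressed gene is
  also strongly down in 54.10, one only mildly, one not at all, and the
  weakly loading *CDP1* shares the 54.10 drop without co-varying elsewhere;
* noise σ = 0.5 log2. No measured noise magnitude was available for this
  assay family; 0.5 (a ±40% one-sigma band) is a deliberate stand-in and
  recovery tests treat it as a free parameter.

With these choices the trio occupies the top three R² ranks and the 54.10
knockdown flag is recovered in ≥95 of 100 seeds (the suite measures both),
while the leave-54.10-out correlation of *42.49CG1* remains high — the
correlation is driven by co-variation across the other strains too, not by
one genotype.

What the generator deliberately does **not** emulate: PCR efficiency
variation between genes, plate/batch effects, heteroskedastic or
heavy-tailed noise, correlated noise between genes within a well, partial
(hypomorphic) insertions, or any mechanistic NO/cGMP kinetics — genotype and
condition effects are phenomenological log2 shifts. Passing recovery tests
therefore shows the pipeline detects the assumed covariance structure at
realistic noise, not that real experiments are free of these complications.
`null_config()` strips all genotype structure (effects and knockouts) for
type-I-error calibration.

## Numerical choices and degenerate inputs

* CSV serialization writes doubles at `%.17g`, so write→read is exactly the
  identity, including the absent-row encoding of missingness.
* `quantify_table(ct_layer(x))` is the exact inverse on noise-free positive
  tables (asserted to 10⁻¹²); Cts above the cap (default 40) become missing
  rows, mirroring instrument detection limits.
* Correlation of a constant vector is an error at the operation level and a
  flagged row at the screen level; `n < 3` likewise.
* The log2 floor, detection floor and knockout floor are all configurable
  and logged when `options(coexscreen.verbose = TRUE)`; every stage then
  reports row counts in and out, making sample-count provenance auditable.
* Ties in the ranked output break lexicographically for reproducible
  reports.

## Known limitations

The screen reports raw Pearson p-values on n−2 degrees of freedom, as the
method prescribes — no multiple-testing correction across candidates, and no
adjustment for the degrees of freedom absorbed by centring. The latter is a
real, quantifiable effect: centring constrains each gene's values within
every condition × time cell, so both members of a pair effectively live in a
(144 − 16)-dimensional space while the test assumes 142 free df. Worked
through the t threshold, the true type-I rate at nominal α = 0.05 is ≈ 0.065,
and the suite's null calibration (12 independent 1000-gene null datasets)
measures ≈ 0.062. Users screening large panels should treat p-values near
the nominal threshold accordingly; the ranking by R², which is how the
screen is used, is unaffected.

Problem sizes in the shipped tests were chosen for desk-scale runs: 100
seeds for recovery rates, 12 × 1000 genes for null calibration, 50–100
random small tables for the oracle and centring properties.
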