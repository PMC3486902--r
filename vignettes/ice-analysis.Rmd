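---
title: "Quantifying the inter-chromosomal effect in oocyte and embryo cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the inter-chromosomal effect in oocyte and embryo cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icecohort)
library(dplyr)
```

## The question

Carriers of balanced chromosome rearrangements — Robertsonian
translocations, reciprocal translocations, inversions — are at elevated
risk of producing gametes and embryos with imbalances of the rearranged
chromosomes. The *inter-chromosomal effect* (ICE) hypothesis goes further:
the presence of a rearrangement may also disturb the segregation of
*structurally normal* chromosomes, for instance through disrupted pairing
or altered positioning on the spindle, inflating aneuploidy rates genome
wide. Testing this requires comprehensive per-chromosome copy-number calls
(microarray-CGH of polar bodies, single blastomeres, or trophectoderm
biopsies), careful exclusion of the chromosomes involved in each carrier's
rearrangement, and a fair comparison against age- and stage-matched
controls.

`icecohort` implements that analysis end to end: an ISCN-subset karyotype
parser, whole-chromosome aneuploidy accounting, a patient-matched control
weighting transform, Yates-corrected chi-squared inference with relative
risks stratified by rearrangement class, biopsy stage and carrier sex, and
a seedable synthetic-cohort generator so that every stage can be exercised
and validated without clinical data. The package ships a study-scale
reference cohort (44 carrier couples, 54 testing cycles, 283 samples;
5,078 matched control samples) as plain-text tables, and its headline
quantities are recomputed from those tables by the test suite and by
`scripts/acceptance.R`.

## Aneuploidy accounting

The unit of analysis is the whole chromosome within one biopsied sample.
Copy states are `EXPECTED`, `GAIN`, `LOSS` (plus `NOCALL` for unscorable
chromosomes). Two conventions, both forced by the arithmetic of the
reference tables, deserve explanation:

**Exclusion of rearranged chromosomes.** Aneuploidy affecting a chromosome
involved in the carrier's rearrangement is an expected consequence of
malsegregation of the rearrangement itself and says nothing about an ICE.
`excluded_chromosomes()` therefore removes the union of involved
chromosomes — for both the carrier's samples and the matched control
group — before any error is counted. A carrier of der(13;14) loses two
chromosomes from the assessable complement; the one compound couple in the
reference cohort (a reciprocal translocation in one partner and an
inversion in the other) loses three.

**Denominators and the net-pair convention.** Polar-body analysis infers
the oocyte's haploid complement, so each sample contributes `23 − k`
assessable chromosomes when `k` distinct chromosomes are excluded.
Cleavage-stage and trophectoderm samples are diploid and denominators count
both homologues: `46 − 2k`. Array-CGH, however, reports one *net* copy
state per chromosome label (a trisomy and a monosomy of the same chromosome
in one sample cannot both be seen), so errors are scored at most once per
label per sample while the denominator still counts 46 chromosomes. The
per-sample state map therefore covers 23 labels at every stage
(`complement_labels()`; the sex-chromosome pair is tracked as a single
unit), and `per_sample_complement()` supplies the stage-correct
denominator. Every one of the 54 case rows in the packaged table satisfies
`chromosomes assessed = samples × complement`, which is how the two rules
above were pinned down.

```{r accounting}
cases <- read_case_table(ice_example("table2_carrier_cases.tsv"))
controls <- read_control_table(ice_example("table3_control_groups.tsv"))
pool_tally(tally_cases(cases))
stage_table(tally_cases(cases), controls)
```

## The matched-control weighting transform

Each carrier case has its own control group — samples from karyotypically
normal patients of identical female age, stage, clinic and time window —
but control groups differ greatly in size. Pooling raw control counts
would let large groups at particular maternal ages dominate, and age is
the strongest known determinant of aneuploidy risk. The weighting
transform gives every control group exactly its patient's weight: the
control per-chromosome error frequency is multiplied by the matched
patient's assessed chromosome count,

$$ E_i = \left[ \frac{e_i^{ctrl}}{N_i^{ctrl}} \times N_i^{pat} \right], $$

rounded half-up to the nearest integer, with
`expected normal = patient chromosomes − expected errors`. Rounding
half-up (never half-to-even) is the only convention that reproduces the
reference expected-error column row for row — one row's scaled expectation
lands exactly on 1.5 and prints as 2. `weight_control(round = FALSE)`
keeps unrounded expectations for sensitivity analysis, since rounding then
summing is not the same as summing then rounding. Pooled over all 54
groups, the transform conserves the carrier chromosome total:
462 expected errors + 10,375 expected normal = 10,837.

```{r weighting}
weighted <- weight_control(controls, cases)
pool_weighted(weighted)
```

One caveat the package preserves deliberately: cycles of the same patient
may share a control group, and pooled statistics use the per-case weighted
values exactly as tabulated, without deduplication.

## Inference

`ice_test()` assembles the 2×2 table (carrier errors/normal vs weighted
control expected errors/normal), per-chromosome rates, their difference,
the chromosome-level relative risk (ratio of unrounded rates), and a
chi-squared test with Yates' continuity correction,

$$ X^2 = \sum_{\text{cells}} \frac{\max(|O - E| - \tfrac12,\, 0)^2}{E}, $$

with a two-sided p-value from the upper tail of the 1-df chi-squared
distribution. The correction term is clamped at zero so that a perfectly
null table yields statistic 0 and p = 1. The implementation is checked
against `stats::chisq.test(correct = TRUE)` on a thousand random tables to
six significant figures.

`stratified_ice()` runs the weight–pool–test chain within strata defined
by rearrangement class, biopsy stage, and/or carrier sex. The compound
couple is excluded from stratified inference by default (it belongs to no
single class; `include_compound = TRUE` restores it, and it is always part
of stage-level accounting). Strata whose carrier arm contains fewer than
`min_chromosomes` assessed chromosomes (default 1,000) are flagged
`underpowered` rather than suppressed — in the reference cohort the
inversion stratum is far below any useful sensitivity.

```{r strata}
stratified_ice(cases, controls, by = c("class", "stage")) |>
  select(stratum, n_cases, carrier_rate, control_rate, relative_risk, p_value, underpowered)
```

`embryo_level_comparison()` addresses a complementary question: because
embryos often carry several aneuploidies, extra errors caused by an ICE
frequently land in embryos that were already abnormal, so the relative
risk of producing an *abnormal embryo* is much smaller than the
per-chromosome relative risk. A sample counts as abnormal only if at least
one chromosome outside the rearrangement is aberrant. The per-embryo
abnormal counts for the cleavage-stage Robertsonian analysis are not
derivable from the per-chromosome tables, so they ship as their own small
input fixture.

**p-values.** The reported statistics and p-values are computed from the
tabulated counts. Stratum p-values printed elsewhere for this cohort could
not be reconstructed unambiguously from the aggregate tables, so the
package's validation pins counts and rates — never p-values — and the
computed p-values are reported as such.

## The synthetic cohort generator

`sim_config()` + `simulate_cohort()` generate carrier cohorts with matched
controls that have the statistical structure the analysis assumes. The
defaults are the reference study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_cases` | 54 | carrier cases (karyotypes drawn from the packaged pool) |
| `stage_mix` | 9/54, 29/54, 16/54 | PB / blastomere / TE case mix |
| `ages` | empirical | maternal ages 26–43, case-table frequencies |
| `samples_per_case` | 5 | ≈ 283/54 samples with a result per cycle |
| `n_control_samples` | 94 | ≈ 5,078/54 control samples per matched group |
| `baseline_rates` | 0.080 / 0.053 / 0.020 | control per-chromosome aneuploidy by stage |
| `ice_multiplier` | 1.25 | multiplicative ICE on non-involved chromosomes |
| `ice_stages` | blastomere | the effect acts at cleavage stage only |
| `involved_malseg_rate` | 0.4 | aberration probability of involved chromosomes |
| `call_accuracy` | 0.94 / 0.98 / 0.95 | per-stage probability of a correct call |
| `probes_per_chromosome` | 100 | array density per chromosome |
| `ratio_noise_sd` | 0.1 | log-normal multiplicative probe noise |

Choices that the data do not fix directly, made once and documented here:
the default effect size 1.25 is the ratio of the cleavage-stage carrier
and control rates (6.6%/5.3%); the involved-chromosome malsegregation rate
of 0.4 reflects the high (tens of percent) malsegregation typical of
translocation carriers' embryos while leaving most samples scorable; 100
probes per chromosome corresponds to a few-thousand-clone BAC array spread
over 24 chromosome targets; and maternal-age dependence is a logistic ramp
(default slope 0.1 log-odds per year) whose per-stage intercepts are
calibrated by `uniroot()` so the age-*averaged* rate equals the configured
pooled rate — only pooled per-stage rates are tabulated, so any per-age
shape is a modelling choice, switched off with `age_slope = 0`.

Internally a per-chromosome rate $r$ becomes a per-label event probability
of $r$ at the haploid (polar-body) stage and $2r$ at diploid stages, so
that `errors / chromosomes assessed` recovers $r$ under the net-pair
convention above; configurations whose implied label probability exceeds 1
are rejected. Aberrations are gains or losses with equal probability. The
call-accuracy channel then flips each label, with stage-specific
probability `1 − accuracy`, to one of the two other states uniformly —
symmetric noise that inflates both arms equally. Everything is
deterministic given `(config, seed)`, and the generator restores the
caller's RNG state.

What the generator does *not* emulate: chromosomal mosaicism within an
embryo (a TE biopsy yields one consensus call), segmental aneuploidy and
chromosome breakage, meiotic segregation modes of multivalents,
trisomy/monosomy rescue, and any dependence between chromosomes within a
sample beyond the involved/non-involved distinction. Passing simulation
tests therefore validates the accounting, weighting and testing machinery
under independent per-chromosome errors — not the biology of real embryos.

## Array profiles and calling

`simulate_acgh_profile()` draws linear test/reference ratios per probe
around the copy-state centres 1.0 (expected), 0.5 (net single-copy loss)
and 1.5 (net single-copy gain) with multiplicative log-normal noise;
`call_copy_number()` calls whole chromosomes by comparing the per-chromosome
*median* ratio (median, not mean, for robustness to outlying probes)
against thresholds. Defaults are 0.75/1.25 — the midpoints between class
centres on the linear scale. Rendered array plots of clear monosomies can
show much more extreme ratios (below 0.3), but an extreme observed ratio
in one figure is not a calling rule; the midpoint thresholds are the
symmetric Bayes-style decision boundaries and are fully config-exposed.
Chromosomes with fewer than `min_probes` probes are flagged `NOCALL`
rather than guessed. There is no within-chromosome segmentation: the
analysis unit is the whole chromosome. Whether gains beyond one copy
(e.g. tetrasomy) should be distinguished is unresolvable from net ratios
at these noise levels; the caller emits only `GAIN`/`LOSS`/`EXPECTED`.

## Numerical and design notes

- **Karyotype grammar.** `parse_karyotype()` accepts
  `<45|46>,<XX|XY>,<event>` with events `t(a;b)(…)`, `der(a;b)(q10;q10)`
  and `inv(a)(…)`, and two `/`-separated constitutions for a couple in
  which both partners carry a rearrangement (merged into one case, since
  embryo analysis excludes all involved chromosomes). Breakpoint bands are
  preserved verbatim and never interpreted. Rings, markers, mosaics and
  three-way translocations are out of scope and rejected loudly. By strict
  notation the packaged pool parses as 19 Robertsonian, 23 reciprocal and
  3 inversion events; one reciprocal-notation translocation joins two
  acrocentric chromosomes (13 and 15) and is flagged
  `acrocentric_candidate`, because by convention such events are sometimes
  counted as Robertsonian — the parser flags, and never silently
  reclassifies. Carrier sex is the sex designation of the constitution
  carrying the rearrangement; the compound couple is recorded as `"both"`
  and drops out of sex-stratified inference.
- **Conservatism of the weighted test.** Rescaling a large control group
  down to the patient's chromosome count produces an "expected" count with
  far less sampling variance than the binomial the 2×2 chi-squared
  assumes, so with realistically large control groups the test is
  conservative (its true type-I error is well below nominal); the diploid
  net-pair convention adds a further mild conservatism (true error
  variance is about half binomial at 46−2k denominators). These are
  properties of the weighting procedure itself. The package's null
  calibration experiment is therefore designed where the variance model
  holds exactly — polar-body stage, control groups matched in size to the
  patient (the transform is then the identity) — and there the rejection
  rate sits at the nominal level within Monte-Carlo error.
- **Relative-risk recovery.** Parameter recovery of the configured
  multiplier is assessed on simulated *truth* states: the symmetric
  call-accuracy channel adds equal false-positive rates to both arms,
  which attenuates rate ratios toward 1 (by roughly the ratio of added to
  true errors), exactly as platform noise would in practice.
- **Problem sizes.** The packaged analyses are desk scale (54 rows).
  Simulation tests use cohorts of roughly 40–60 cases with 5–20 samples
  each (10⁴–10⁵ chromosome draws), 1,000 replicates for the null
  calibration, 1,000 profiles for caller accuracy, and 1,000 random tables
  for the chi-squared cross-check — sizes at which the binomial
  Monte-Carlo error bounds used in the assertions are tight enough to be
  meaningful.
- **Known data quirks.** The reference tables carry a handful of internal
  inconsistencies that the package surfaces rather than hides: the control
  error column sums to 9,598 while its printed total is 9,597; the
  polar-body control stage row is off by the same single error; one
  summary table's totals row does not equal the sum of its own stage rows
  (the stage rows, which recompute from the per-case tables, are
  authoritative here); and two adjacent control rows swap error counts
  between tables without affecting any pooled quantity. Tests assert the
  recomputed column sums.

## Limitations

The pipeline analyses whole-chromosome net copy states; it cannot see
segmental imbalances, uniparental disomy, or mosaicism below the biopsy's
resolution. The weighting transform guarantees fair age weighting but, as
noted, sacrifices calibration of the chi-squared's nominal level when
control groups are large — its p-values are honest but conservative.
Matching of control groups is taken as given input; the package does not
re-derive who the controls were. And the embryo-level comparison consumes
tabulated per-embryo counts, because per-embryo call data are not part of
the packaged per-chromosome tables.
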