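---
title: "Methods: from Cq values to candidate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from Cq values to candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddCtScreen)
```

## Scope and data model

`ddCtScreen` analyses RT-qPCR screens with a full factorial layout: genes
× cultivars × tissues × treatments (control/stress) × timepoints ×
biological replicates, one quantification cycle (Cq) per combination. The
central container, `CqExperiment`, extends `SummarizedExperiment` with a
genes-by-samples `cq` assay and the factorial sample annotation; the
analysis contract (reference gene, treatment-label mapping, cultivar roles,
thresholds) lives in a `QpcrDesign` object carried in the metadata.

Deliberate restrictions of the data model: the only input dialect is tidy
long CSV (wide vendor exports and instrument formats like RDML are out of
scope); a missing replicate is an error, not an `NA`, because the screens
this package targets report complete replication and silent imputation
would bias the small-n tests; technical (within-plate) replicates are not
modelled — replicates are biological; timepoints are analysed
independently and never interpolated.

## Relative quantification

Within each sample, ΔCt = Cq(target) − Cq(reference) is reference-
normalized log2 expression. Relative quantities are calibrated against the
control sample of the *same* gene, cultivar, tissue and timepoint:
RQ_i = 2^−(ΔCt_i − mean ΔCt_cal). Two aggregation conventions exist in
practice and differ once replicates are noisy:

* `per_replicate` (default): mean and SE of the per-replicate RQ values,
  on the linear scale. This is the convention implied by figures that show
  SE bars of n = 3 biological replicates on a linear RQ axis.
* `of_means`: 2^−(mean ΔCt − mean ΔCt_cal), the geometric-mean style
  estimate. Available via the `aggregate` design slot.

The reported control mean RQ is pinned to exactly 1 (matching
"normalized to a value of 1" figure conventions) while the unpinned value
(`mean_rq_raw`, the mean of 2^± replicate deviations, which exceeds 1 under
noise by Jensen's inequality) is retained for variance work and for the
algebraic-invariant tests. No amplification-efficiency correction is
applied: the model is the pure 2^-ΔΔCt method, which assumes near-100 %
efficiency for target and reference alike.

Whether published SE bars were linear-RQ or log-RQ is rarely stated; we
assume linear RQ per the figure-axis convention. This choice affects only
reported SEs, never calls: all decisions are made on ΔCt or fold changes.

## Statistical calls

**One-tailed t test.** All significance calls use an unpaired,
equal-variance Student *t* with the tail taken in the direction of the
observed mean difference — numerically, half the two-tailed p. The
published description ("one tail") does not fix a direction; taking the
observed direction is the only reading consistent with two-sided reporting
of both up- and down-calls. Degenerate inputs get fixed conventions so
zero-noise synthetic data remain analysable: both groups constant and
equal → p = 0.5 (t = 0); zero pooled variance with unequal means → p = 0,
flagged `zero_variance`. Groups need ≥ 2 values (the variance must be
estimable).

**Test scale.** The test runs on ΔCt replicates by default: on that scale
qPCR noise is approximately Gaussian and variance-homogeneous, which is
what the pooled-variance t assumes. Because the source screens rarely say
whether testing was done on ΔCt or on linear RQ, a `test_scale = "rq"`
switch preserves the alternative; both modes reproduce the qualitative
calls on low-noise data (this is tested).

**Responsiveness.** Fold change is 2^−(ΔΔCt of means). A gene is called
`up` at a timepoint iff fold ≥ threshold and p < alpha; `down` iff
fold ≤ 1/threshold and p < alpha. Thresholds are *inclusive* — "at least
two-fold" means exactly 2.0 counts — and the boundary semantics are
exercised by tests with exactly-two-fold programmed effects. Defaults:
threshold 2.0 (dimensionless fold), alpha 0.05. The per-gene pattern is
`mixed` iff both an up and a down call occur across timepoints,
`unchanged` iff neither occurs, else the single direction; one responsive
timepoint suffices for responsiveness. No multiple-testing correction is
applied by default, matching the raw per-gene p-value practice of the
screens this reproduces; users can apply `p.adjust` to the returned
p-values if they prefer.

**Genotype contrasts.** Tolerant/sensitive ratios are computed from ΔCt,
never from calibrated RQ. This is forced, not stylistic: calibration pins
both cultivars' controls at RQ = 1, so any between-genotype baseline
difference — including the 20-fold control-condition differences that
drive candidate selection — is unrecoverable from RQ. A test constructs a
scenario with an 8-fold baseline difference and zero stress response and
asserts that RQ carries no signal while the ΔCt contrast recovers the
ratio exactly. Each treatment × timepoint is contrasted independently
(four cells per gene × tissue); `similar` is the explicit third call.

## Tissue-overlap partition

`vennPartition()` partitions responsive genes across two tissues per
direction. A gene `mixed` in *either* tissue is wholly excluded — even if
cleanly directional in the other — mirroring how screens drop such genes
from overlap figures while still counting them as responsive. A gene with
clean opposite directions in the two tissues legitimately appears in one
up-set and one down-set; disjointness is therefore enforced within each
direction family, not across all six sets. Genes unchanged in both tissues
appear nowhere. The partition is checked against an exhaustive per-gene
case analysis on random inputs, plus conservation (each tissue's
responsive count is recoverable from the partition margins) and symmetry
(swapping tissues swaps the `*_only` sets).

## Candidate rule engine

The Group-1/Group-2 classification is table-driven over a qualitative
state matrix: per gene × tissue, the response pattern of each cultivar
plus the four contrast calls. Two profiles:

* **`paper` (default)** — the operational rule set. Group 1: `higher` in
  ≥ 1 cell, AND no control-condition cell `lower`, AND NOT (tolerant
  `down` while sensitive `up`/`unchanged`). Group 2: `lower` in ≥ 1 cell
  AND neither cultivar's pattern contains an up call (`mixed` counts as
  containing up). This operationalization is dictated by
  reverse-engineering published selections that a literal reading of the
  stated criteria misfits in two ways: a gene induced in both cultivars
  and `higher` under late dehydration was nevertheless *not* selected —
  explained only by its constitutively `lower` control cells, hence the
  control-lower veto; and a gene down-regulated in *both* cultivars *was*
  selected — hence down-in-both does not disqualify when the gene is
  higher-in-tolerant and never control-lower. Selected genes carry a
  trace naming the predicates and the stated criterion ((i)/(ii)/(iii),
  Group-2 rule, or `operational_rule`) their pattern instantiates.
* **`literal`** — verbatim transcription of criteria (i)–(iii) and the
  Group-2 sentence, for sensitivity analysis. Criterion (ii)'s "higher
  up-regulated expression change" is ambiguous between higher contrast
  level and higher induction fold; the state-matrix representation
  supports the contrast-level reading, which is the one both profiles use
  (the induction-fold reading would need quantitative folds that a
  qualitative matrix does not carry — a known limitation).

Two tie-breaks are explicit: a gene satisfying both rule sets is reported
Group 1 (precedence; without it a contrived pattern — both cultivars down,
one stress cell higher and another stress cell lower — would satisfy
both), and `unknown` contrast cells (present in the packaged matrix where
the source prose gives counts but not identities) carry no evidence,
behaving as `similar`. The engine is verified against an independent
literal transcription of its post-condition over all
4 × 4 × 3⁴ = 1,296 single-gene state matrices, together with
mutual-exclusivity and monotonicity (upgrading any `similar` cell to
`higher` never demotes a Group-1 gene).

## The synthetic generator

`simulateCq()` draws, per sample, one reference Cq
(`reference_ct + N(0, noise_sd)`) shared by every target gene of that
sample, then per gene `Cq = refCq + baseline ΔCt − true_log2FC·[stress] +
N(0, noise_sd)`. Noise is additive Gaussian on the Cq scale — the standard
qPCR error model (multiplicative on expression); the shared reference draw
mirrors same-sample normalization, so reference noise cancels within a
replicate's ΔCt. Defaults: reference Cq 20 cycles, 3 biological
replicates, noise SD 0 (truth scenarios); 0.25 cycles is used as the
realistic biological-noise level in the statistical checks, a typical
replicate SD for plant RT-qPCR. The generator does *not* simulate
amplification-efficiency deviations, plate effects, non-detects or
technical replicates — so passing tests demonstrate correctness of the
analysis chain under the stated error model, not robustness to those
artefacts.

The control-condition truth (`baseline_dct`) is indexed per timepoint as
well as per gene × cultivar × tissue: control plants sampled at 2 h and
5 h are distinct samples, and the encoded screen indeed reports different
cross-cultivar control contrasts at the two times, which a time-constant
baseline could not represent.

`paperScenario()` encodes the 19-gene screen's qualitative call matrix as
programmed truth: printed fold magnitudes are used exactly where reported
(the 17.5-/9.2-fold repressions, the 3.8-/2.1-fold mixed pattern, the
3.9-/3.3-fold tissue-opposite gene, 350- and 450-fold standing in for the
">300"/">400" inductions, and all eight control/dehydration contrast folds
of the two flagship genes); every other responsive cell uses the
|log2FC| = 2 placeholder convention (flagged in the `placeholder` slot),
and contrast baselines use ±2 with a few near-threshold values (0.9-cycle
offsets, 1-cycle effects) where jointly satisfying all printed calls
requires them. Stress-condition contrasts are not free parameters — they
follow arithmetically as control contrast + (tolerant − sensitive)
log2FC — so the encoding was solved so that every derived cell matches its
transcribed call; cells the source prose leaves unidentified or labels
inconsistently (one dehydration enumeration mislabeled as a control
comparison) are marked `unknown`/ambiguous in the fixture and excluded
from truth-recovery comparisons. Dyadic placeholder values keep replicate
means floating-point-exact, so inclusive-threshold boundary cells (true
fold exactly 2) are decided identically by the analytic truth table and
the simulated pipeline.

## Numerical and interface choices

* Exactness: zero-noise RQ recovery is asserted at tolerance 1e-12;
  boundary calls rely on exact dyadic arithmetic as above, never on
  epsilon fudging of the ≥ comparisons themselves.
* Zero-variance detection uses exact `== 0` on the pooled variance: it
  arises only from programmatically identical replicates, which subtract
  to exactly zero.
* Reports serialize numbers at 6 significant digits, tab-separated, fixed
  column order; `runPipeline()` uses fixed output filenames and refuses to
  overwrite without `force`, and echoes all thresholds to the log so every
  call is auditable.
* The command-line entry point is a thin optparse wrapper
  (`inst/scripts/qpcr-pipeline.R`) over the exported functions; the
  functions themselves are the primary interface. `simulateCq()` takes the
  seed as an argument (restoring the caller's RNG state) rather than
  storing it in the scenario object, keeping scenarios purely declarative.

## Problem sizes of the statistical checks

The simulation-based properties run at desk scale, chosen so each check is
statistically decisive yet completes in seconds: null false-call rate with
2,000 genes (n = 3, SD 0.25 cycles; the two-fold gate makes the expected
rate effectively zero, asserted < 0.05); directional recovery > 0.95 at
|log2FC| = 3 with 500 genes; mean log2FC bias within ±0.05 with 500 genes;
monotonicity of recovery over |log2FC| ∈ {0.5, 1, 1.5, 2, 3} with 400
genes per level; and a duplicate-implementation cross-check of the
generator-plus-caller at the threshold boundary with 2,000 genes.

## Known limitations

* Pure 2^-ΔΔCt: no Pfaffl efficiency correction, no reference-gene
  stability assessment (a single reference gene is assumed valid).
* Qualitative rule engine: no scoring or ranking beyond the binary
  grouping; narrative rankings ("best candidate by contrast magnitude")
  are outside its scope.
* Two-tissue Venn only; no ≥ 3-set partitions.
* No interaction (cultivar × treatment) model — pairwise comparisons only,
  as in the screens this package reproduces; users wanting joint modelling
  should export ΔCt values to `limma`/`lme4`.
* The packaged call matrix transcribes qualitative published results;
  where the source is silent (unidentified lower cells) or internally
  inconsistent (one mislabeled enumeration; aggregate per-timepoint counts
  that cannot all be reconciled with the enumerated lists), the fixture
  records `unknown`/ambiguous rather than a guess.
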