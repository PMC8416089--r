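---
title: "Models and methods behind vitreomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vitreomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vitreomics implements a two-group label-free proteomics workflow:
per-sample iFOT normalization, detection-aware differential analysis,
mean-Z signature scoring with rank-based validation, and upstream
transcription-factor (TF) inference by over-representation and gene set
enrichment analysis (GSEA). This vignette explains the models, the
defaults, and the design decisions, in that order of importance.

## Quantification model

Label-free protein quantification arrives as iBAQ-style abundances with
missing measurements stored as zero. We keep that convention end to end:
**zero means not detected**, and "detected in a group" means a positive
value in at least `min_detect` samples of the group (default 1, matching
the usual "detected only in one group" phrasing of discovery studies
with no per-sample threshold).

iFOT (intensity fraction of total) divides each sample column by its
total, making samples comparable while remaining *compositional*: values
are fractions summing to 1, so a genuine increase in some proteins
necessarily deflates the remaining fractions. We keep iFOT as a fraction
(not scaled by 10^5): the scale cancels in fold changes, Z-scores, and
ranks.

Statistical testing operates on `log2(iFOT + ε)` with ε = 1e-8 by
default. The pseudocount is applied only at the log stage — stored iFOT
keeps exact zeros so detection semantics survive — and sits below any
plausible single-protein fraction in cohorts of hundreds of proteins, so
it affects only the undetected entries, which map to log2(1e-8) ≈ −26.6.
Consequences of that choice are discussed under "Known limitations".

## Differential analysis

Proteins are partitioned into case-only, control-only, shared, and
undetected classes; the partition is a disjoint cover of the matrix and
is asserted as such in the tests. Only shared proteins are tested:
group-exclusive proteins have no within-group observations on one side,
so a two-sample test is undefined for them; they keep their (pseudocount
guarded) fold change and their exclusive status instead.

The two-group test is Welch's unequal-variance t on the log scale by
default, with a Mann–Whitney option. Neither choice is canonical in
discovery proteomics; Welch is the robust default for small unequal
groups with approximately log-normal abundances, and the option is
exposed (and logged by the pipeline) rather than hidden. Degenerate
inputs follow fixed conventions: both groups constant and equal gives
p = 1, constant but different gives p = 0.

Multiple testing uses Benjamini–Hochberg step-up over the tested
(shared) subset only. The up-signature is `q < α` (α = 0.05 default) and
positive log2 fold change; `include_exclusive = TRUE` additionally folds
case-only proteins into the up-signature. The default is `FALSE`: a
signature defined from shared proteins is the configuration consistent
with an 88 + 68 ≤ 189 arithmetic in which significant calls are a subset
of the jointly detected proteome, and exclusive detection at tiny n is
dominated by dropout noise, which inflates the false discovery rate when
folded in (we measured ~0.16 observed FDR with exclusives versus ~0.01
without on simulated 20v20 cohorts).

## Signature scoring and validation

An independent cohort is scored in three steps:

1. **Z-standardization per protein** across *all* cohort samples
   jointly (sample SD, n − 1). Whether standardization should use
   controls only is genuinely open; joint scaling is the common
   signature-scoring convention and does not require two samples per
   group, so it is the default, with the log-scale input (not raw
   fractions, whose heavy tails would let single outliers dominate).
   Zero-variance proteins cannot be standardized and are excluded and
   reported.
2. **Mean signature Z per sample**, with coverage (fraction of
   signature proteins present) enforced at `min_coverage` (default 0.5)
   because a sparse overlap no longer measures the signature.
3. **One-tailed Mann–Whitney U** (case > control, the direction an
   up-signature predicts) and **ROC/AUC**. The U statistic counts
   case–control pairs with the case score higher, ties at half credit;
   the p-value is the exact null enumeration when n1 + n2 ≤ 12 without
   ties and the tie/continuity-corrected normal approximation otherwise.
   The ROC sweeps all score thresholds with trapezoidal integration, so
   AUC = U/(n1·n2) holds as an identity; it, the complement rule
   AUC(−s) = 1 − AUC(s), and invariance to monotone score transforms are
   all asserted in the tests.

## TF over-representation

Enrichment of the signature in a GMT collection is the one-sided
hypergeometric tail `P(X ≥ k)` for `X ~ Hypergeom(N, K, n)` with the 2×2
sample odds ratio. The background universe defaults to **all proteins
detected in the experiment**, not a whole-genome list: detectability in
a body-fluid proteome is strongly biased, and testing against the genome
would manufacture enrichment of anything detectable. Each gene set is
intersected with the background before testing; BH adjustment runs over
the whole collection per query (the adjusted-p convention of the popular
enrichment web tools). TFs are ranked by ascending p with ties broken by
larger overlap, then name, so the ranking is deterministic.

One property worth stating because it is easy to get backwards:
enlarging the background with set-free proteins makes a fixed overlap
*more* extreme, so each set's p-value is non-increasing in the
background size.

## GSEA

The GSEA statistic is authored here, not delegated. Genes are ranked
descending by signal-to-noise, `(μ_case − μ_ctrl)/(σ_case + σ_ctrl)`,
with each group SD floored at `max(0.2·|μ|, 0.2)` — the classic
convention preventing near-constant genes from exploding the metric — or
by log-scale mean difference; ties break by symbol so the ranking is
strict. The running sum gains `|score|^p / Σ_hits |score|^p` at set
members (weight p = 1 by default; p = 0 recovers the unweighted
Kolmogorov–Smirnov form, asserted against a separate implementation) and
loses `1/(N − K)` at non-members. The enrichment score (ES) is the
extremum of largest magnitude; the leading edge collects members at or
before it (after it, for negative ES).

Significance is by permutation. The default scheme is **gene-set
permutation** (random member sets of the same size): the intended
cohorts are far too small (5 vs 3) for stable phenotype permutation,
which is nevertheless implemented, re-ranking shuffled labels, and
refuses to run below 6 samples with a pointer to the gene-set mode.
Because the running sum between hits is linear, the null ES for a
permuted member set is computed from the hit positions alone in O(K)
rather than O(N), which keeps thousands of permutations per set cheap;
equality with the full running sum is covered by the brute-force oracle
tests.

The p-value is the add-one estimator restricted to the sign side of the
observed ES — `p = (1 + #{same-side |ES_null| ≥ |ES|}) / (#same-side +
1)` — the side-normalized convention of the standard GSEA
implementations. Normalizing by all permutations while counting only
same-side exceedances would roughly double the null rejection rate,
which the calibration tests would catch. NES divides ES by the mean
|ES_null| of the matching sign side (Subramanian-style, sign-consistent).
Across a collection, sets share one seeded permutation stream (a
singleton collection reproduces a direct call with the same seed) and
receive BH q-values over their permutation p-values — simpler and valid,
in place of the original NES-histogram FDR; this is a deliberate,
documented deviation.

## The synthetic cohort generator

`generate_cohort()` draws, per protein p and sample s,

> log2 abundance(p, s) = baseline_p + effect_p · [s is case] + noise,

with baseline_p ~ N(10, 3) on the log2 scale, noise SD 1 (about a
two-fold coefficient of variation, typical of label-free replicates),
and planted effects ±2 log2 units on 80 up and 40 down proteins among
1,000 by default, in 20 vs 20 cohorts (the tests also exercise the 5 vs
3 regime typical of vitrectomy studies). Each measurement survives
detection with probability `plogis(2·log2abundance − 12)`: a fairly
sharp limit of detection centred ~16-fold below the median protein,
yielding ~12% missing values concentrated in low-abundance proteins —
the missing-not-at-random structure of real label-free data, and the
mechanism that produces group-exclusive detection when an effect shifts
a borderline protein. A further 2% of proteins are zeroed wholesale in
one random group to emulate strictly on/off proteins.

Two deliberate choices about where effects are planted:

* **Not in the top abundance decile.** Under a log-normal proteome the
  top decile carries most of the total intensity mass; planting
  four-fold effects there makes iFOT renormalization itself a group
  signal that systematically depresses every null protein in cases —
  an artifact (random signatures scoring AUC ≈ 0.3) that real
  signature studies do not exhibit, because disease signatures live in
  the mid/low-abundance proteome, not among the albumin-scale bulk
  proteins.
* **Not below the detection floor.** A "signature" protein is by
  construction quantifiable in both groups; proteins whose baseline
  sits at the detection limit belong to the group-exclusive class, not
  to the shared-proteome signature the differential test sees.

The ground truth records planted identities, effects, and per-protein
baselines; regenerating with a previous truth yields an independent
validation cohort with the same biology (a protein's characteristic
abundance is a property of the protein) but fresh samples and noise.

What the generator does **not** emulate: peptide-level noise,
shared/razor peptide ambiguity, batch effects, and correlated protein
modules. Passing recovery tests on these cohorts therefore demonstrates
that the statistics do what they claim under the stated model — not that
any particular real cohort meets the model's assumptions.

## Numerical conventions and problem sizes

Identifiers are upper-cased, trimmed, and truncated at the first ";"
(multi-id MaxQuant cells), matching how TF target collections key their
members. Duplicate identifiers in a quantification file resolve to the
row with the larger total intensity. iFOT columns are validated to sum
to 1 within 1e-9; Z rows to mean 0 and SD 1 within 1e-9. All seeded
operations restore the RNG state they found (`withr::with_seed`), and a
`NULL` seed means "use the current stream", which is what lets a
collection-level run share one stream across sets.

The test-suite simulations use 1,000-protein cohorts at 20v20 (recovery
and calibration, 20 seeds), 5v3 for the small-cohort smoke tests, and
enumeration oracles at n ≤ 8–16; these sizes give stable statistics at
desk scale and run in well under two minutes.

## Known limitations

* The ε pseudocount maps undetected entries to an extreme log value
  (−26.6); a single undetected measurement inside a "shared" protein
  inflates its Welch variance considerably. The rank-based test option
  is immune to this; imputation models are deliberately out of scope.
* iFOT is compositional; strong one-sided regulation deflates all other
  fractions. Fold changes and signature scores inherit this, as the
  generator documentation above illustrates.
* ORA treats gene sets as flat lists — no ontology topology or
  redundancy reduction — and tests enrichment only, not depletion.
* AUC is reported without a confidence interval; with a handful of
  samples per arm, the ROC is a coarse step function and should be read
  accordingly.
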