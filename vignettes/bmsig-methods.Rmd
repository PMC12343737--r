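---
title: "Methods: mutational-signature subtyping and prognostic screening in bmsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutational-signature subtyping and prognostic screening in bmsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmsig)
```

# Scope and model

`bmsig` analyzes somatic-mutation cohorts of brain-metastasis (BM) patients
in three tiers:

1. **Mutational process signatures.** Single-base substitutions are
   classified into the 96 pyrimidine-collapsed trinucleotide channels; the
   samples × 96 count matrix \(V\) is factorized as \(V \approx H W\) with
   \(W\) (k × 96) the signature patterns and \(H\) (samples × k) the
   exposures, by multiplicative updates minimizing the generalized
   Kullback–Leibler divergence \(D(V \,\|\, HW)\).
2. **Molecular subtypes.** Relative signature activities are clustered by
   resampled consensus clustering (Pearson-correlation distance, Ward
   trees), with CDF/delta-area diagnostics and a cluster-consensus quality
   gate.
3. **Association screens.** Kaplan–Meier/log-rank survival contrasts, Cox
   proportional-hazards models (Efron ties) with Schoenfeld diagnostics,
   pairwise co-occurrence/mutual-exclusivity Fisher tests under
   Benjamini–Hochberg control, CNV-deletion survival screens, burden
   comparisons and ICI response-rate contrasts.

All statistics are implemented in the package (the `survival` package
appears only as an independent oracle in the test suite), because the
screens compose these primitives in bulk and the implementation needs to be
auditable end-to-end.

# Key parameters

| parameter | default | units / scale | rationale |
|---|---|---|---|
| `min_sample_frac` (catalog) | 0.01 | fraction of samples | channels hit in under 1% of samples are zeroed as noise; the filter acts at channel level (the matrix stays 96-wide) because it belongs to matrix construction |
| `panel_mb` | 1.14 | megabases | a published targeted-capture footprint; TMB = count / panel_mb |
| NMF loss | generalized KL | — | canonical for count catalogs (Poisson likelihood up to a constant); Frobenius available |
| `nmf.n_runs` | 10 | restarts per rank | rank stability is judged over 10 random restarts |
| `binarize.threshold` | 0.25 | relative activity | a signature is *present* when its per-sample relative exposure strictly exceeds 25%; strict `>` makes the boundary case absent |
| `cluster.sd_min` | 0.1 | activity SD | signatures with SD < 0.1 across samples carry mostly technical noise; strict `<`, so SD = 0.1 is kept |
| `cluster.*` | k_max 8, 1000 reps, p_item 0.8 | — | resampled hierarchical consensus at the conventional settings |
| `cluster.min_consensus` | 0.9 | mean within-cluster consensus | clusters below the gate are flagged unstable; labels are still emitted (the gate reports quality, it does not gate k) |
| `screens.min_frac` | 0.05 | fraction of samples | recurrence filter: genes mutated in ≥ ceil(0.05 n) samples |
| `screens.fdr` | 0.1 | BH q | pairwise co-occurrence discovery threshold |
| `screens.alpha` | 0.05 | raw p | per-gene prognostic flags mirror the raw-p screening convention; BH q is always co-emitted so the multiplicity cost stays visible |
| `screens.min_carriers` | 5 | samples | Cox fits on fewer carriers are degenerate and skipped |

# Numerical choices

* **NMF.** Uniform random initialization under a caller seed; run seeds in
  rank estimation derive as `seed + run − 1`. The KL objective is
  non-increasing at every multiplicative update (asserted by a property
  test); convergence is declared when the relative objective change over 10
  iterations falls below `tol`. On return, rows of \(W\) are normalized to
  sum to 1 with the compensating scale folded into \(H\), so \(HW\) is
  unchanged and relative activities are scale-free (multiplying \(V\) by a
  constant leaves `H_rel` unchanged).
* **Rank selection.** Each run assigns every sample to its dominant
  signature; the run-averaged co-assignment matrix gives a consensus whose
  cophenetic correlation (average-linkage dendrogram) measures stability.
  The chosen rank is the largest k still on the high cophenetic plateau
  (within `plateau_tol = 0.01` of the maximum) before the steepest drop.
  A literal "largest k before the steepest drop anywhere" mis-selects when
  the profile declines gently right after the true rank and faster later —
  which is exactly what 4-signature synthetic cohorts produce — so the drop
  is measured from the plateau. The choice is advisory; the pipeline
  accepts an explicit `nmf.k`.
* **Consensus clustering.** Distance is 1 − Pearson correlation between
  activity profiles; trees use the Lance–Williams `ward.D2` update (Ward on
  a non-Euclidean dissimilarity is convention-dependent, so the convention
  is pinned). A zero-variance profile within a subsample gets distance 1 to
  everything (documented fallback). Pairs never co-subsampled get consensus
  0 with a flag; at 1000 reps and p_item 0.8 this is vanishingly rare for
  n ≥ 30. The area under the consensus CDF is computed exactly as
  1 − mean(consensus entries); `delta_area[k]` is the relative gain, and
  `select_k` returns the smallest k after which the gain falls below 0.1
  (the elbow the reference method reads off a plot).
* **Survival.** Cox models maximize the Efron partial likelihood by
  Newton–Raphson with step-halving; ties default to Efron. Wald 95% CIs on
  the log-hazard scale; categorical covariates are dummy-coded against
  their first level. Rows with missing covariates are dropped complete-case
  at fit time and counted — missingness is never imputed upstream. Monotone
  likelihoods (separation) are flagged and CIs reported unbounded. The
  Schoenfeld check is the Grambsch–Therneau score test of scaled residuals
  against the event-time rank; under proportional hazards its p-values are
  uniform (verified by simulation), with ~0.9 power against a sign-flipping
  effect at n = 150.
* **Small-sample exactness.** The rank-sum test enumerates all group
  assignments when the combined n ≤ 20 and there are no ties; Fisher's test
  enumerates the hypergeometric support and sums probabilities ≤ that of
  the observed table (two-sided); BH is the step-up procedure with monotone
  q-values.

# The synthetic world

`sim_config()` states the world the generator emulates, once:

* four planted signatures built in code — C>A-dominated (tobacco-like),
  C>T at NpCpG (mismatch-repair-like), C>T at 5'-pyrimidine (UV-like), and
  C>G/C>T at tCw (APOBEC-like) — with Dirichlet(0.5) exposures, which
  yield the sparse, few-signatures-per-sample activity profiles seen in
  real catalogs;
* negative-binomial mutation loads with mean 1500 per sample (size 10):
  large enough that a 300-sample cohort identifies four signatures, which
  is what the recovery criteria require of the stated world;
* exponential survival with baseline rate log(2)/21.4 per month (a
  21.4-month median, the cohort-level figure for BM), uniform censoring
  over 120 months, and planted hazard ratios 1.31 (signature presence),
  0.54/1.6 (protective/deleterious gene mutations), 1.71/0.31
  (deleterious/protective deletions);
* Bernoulli gene mutations at literature-style prevalences (TP53 0.58,
  PTPRT 0.14, …) with one planted co-occurring pair at odds ratio 6, drawn
  from the exact 2×2 joint distribution solving the margin/odds-ratio
  system. Driver mutations are overlaid onto each sample's MAF records so
  the MAF-derived gene matrix reproduces the planted one; every remaining
  record hits its own singleton passenger gene, mirroring the reality that
  almost all genes are mutated in well under 5% of samples;
* an ICI cohort of 109 with response rates 32.2% (wild-type) vs 58.3%
  (mutant).

What the generator does **not** emulate: panel footprints and real genomic
coordinates, indel/doublet catalogs, covariate-dependent censoring,
correlated gene backgrounds beyond the planted pairs, and
transcription-strand asymmetries. A green recovery test therefore
establishes correctness of the estimators on well-specified data, not
robustness to annotation artifacts or model misspecification.

Half of all emitted records are strand-flipped so the pyrimidine collapse
is exercised on every simulated cohort; `context3` always stays consistent
with the recorded reference allele. Identical configs and seeds produce
byte-identical files.

# Design decisions on genuinely open points

* **Activity scale for binarization.** "Activity exceeds 25%" is only
  interpretable on the per-sample relative scale, so presence is defined on
  `H_rel` rows (each sample's exposures summing to 1).
* **The <1% low-frequency filter** acts on channels (zeroing), not on
  records or genes: it is part of matrix construction, and removing records
  would silently change TMB. The threshold and the interpretation are
  configurable.
* **Splice_Region, Translation_Start_Site, Nonstop_Mutation** are *not*
  nonsynonymous by default (the retained set is exactly missense,
  frameshift indel, in-frame indel, nonsense, splice-site); an
  `extra_classes` switch admits them per cohort.
* **TMB scale.** The per-unit hazard ratio of TMB depends on whether TMB
  enters raw or log-scaled; both are supported and the scale must be given
  explicitly when reproducing a cohort-level model.
* **Reference signatures.** Public signature databases cannot be shipped;
  the packaged reference (`reference_signatures_synthetic.tsv`) is a
  constructed stand-in generated by `synthetic_reference_signatures()`,
  and is labelled synthetic. Annotation against a real reference is a
  drop-in TSV (channels × signatures, probability layout).
* **Pairwise screens** accept an explicit gene list, because restricting to
  prognostic genes versus all recurrent genes is a cohort-level choice.
* **Config format** is JSON (`jsonlite`), the environment's supported
  structured-config reader.

# Limitations

* Exposure uncertainty is not propagated (no bootstrapped exposure CIs);
  signature presence is a point-estimate call.
* The per-gene screen reports raw-p flags by design; treat them as
  hypothesis-generating and read the co-emitted q-values.
* Consensus clustering of few (2–4) activity dimensions is sensitive to the
  correlation-distance floor; the cluster-consensus gate flags, but cannot
  repair, unstable partitions.
* No time-varying covariates, stratified Cox, frailty terms, or restricted
  mean survival.
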