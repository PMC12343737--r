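# bmsig

Somatic-mutation analysis for brain-metastasis (BM) cohorts: de novo
mutational-signature extraction, signature-activity molecular subtyping, and
survival / immunogenicity association screens — with a synthetic-cohort
generator so the whole pipeline is testable without any external data.

BM patients have poor and heterogeneous prognoses, and panel/exome somatic
mutation data are often the only molecular readout available. `bmsig`
implements the standard analytic chain for extracting prognostic structure
from such data:

1. **96-channel catalog.** Single-base substitutions are classified by
   pyrimidine-collapsed substitution class and flanking bases into the 96
   trinucleotide channels, giving the samples × 96 count matrix *V* (plus
   TMB and the APOBEC-targeted tCw motif burden).
2. **Signatures (NMF).** *V* ≈ *H W*, with *W* (k × 96) the mutational
   process signatures and *H* (samples × k) per-sample exposures, fitted by
   multiplicative updates under generalized Kullback–Leibler divergence.
   The signature number is chosen by cophenetic stability over random
   restarts; signatures are annotated by cosine similarity against a
   reference set; a signature is *present* in a sample when its relative
   activity exceeds 25%.
3. **Molecular subtypes.** Consensus clustering of signature activities
   (1000 subsamples of 80% of samples, Pearson-correlation distance, Ward
   linkage), with CDF/delta-area k selection and a within-cluster consensus
   quality gate (> 0.9).
4. **Screens.** Kaplan–Meier / log-rank contrasts; Cox proportional-hazards
   models (Efron ties, Newton–Raphson) with Schoenfeld PH diagnostics;
   recurrent genes (≥ 5% of samples); per-gene prognostic Cox screens;
   pairwise co-occurrence / mutual exclusivity (two-tailed Fisher,
   Benjamini–Hochberg FDR < 0.1); CNV-deletion survival screens; and ICI
   response-rate (CR+PR) contrasts by mutation status.

All statistics are implemented in the package and validated in the test
suite against independent oracles (brute-force partial-likelihood
maximization, exact enumeration, and the `survival` package).

## Worked example

Simulate a default synthetic cohort (300 samples, 4 planted signatures,
planted prognostic genes and deletions, an ICI cohort) and run the full
pipeline:

```r
library(bmsig)

dir <- tempfile()
simulate_cohort(sim_config(seed = 42), dir = dir)

config <- list(
  inputs = list(
    maf = file.path(dir, "maf.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    cnv = file.path(dir, "cnv.tsv"),
    ici = file.path(dir, "ici.tsv"),
    ici_mutation_status = file.path(dir, "ici_mutation_status.tsv")),
  seed = 42,
  nmf = list(n_runs = 10, max_iter = 1000),
  cluster = list(k_max = 6, reps = 250),
  out_dir = file.path(dir, "out"))

run_pipeline(config)
#> [ingest] 447281 mutation records, 300 samples
#> [signatures] k = 4 (S1~Ref_6_mmr(1.00), S2~Ref_7_uv(1.00),
#>                     S3~Ref_4_tobacco(1.00), S4~Ref_13_apobec(1.00))
#> [cluster] k = 4, cluster consensus 0.913/0.983/0.873/0.774
```

`out/report.json` then holds (numbers printed by the run above):

* `chosen_k = 4` with every extracted signature matching its planted
  pattern at cosine ≥ 0.9998 — the rank selection and factorization
  recover the planted mutational processes;
* 11 recurrent genes; the planted prognostic genes flagged by the Cox
  screen: RB1 HR 2.77 (deleterious, p = 6.6e-05) and PTPRT HR 0.57
  (protective, p = 0.022; planted HR 0.54);
* the planted co-occurring pair PTPRT–FAT1 at odds ratio 7.8
  (q = 0.013, planted OR 6);
* CNV screen: PTEN deletion HR 1.84 (p = 0.007; planted 1.71), DUSP4
  deletion HR 0.50 (p = 0.045; planted 0.31);
* ICI response rates 87.5% (mutant) vs 39.6% (wild-type), Fisher
  p = 0.020 (planted rates 58.3% vs 32.2% — the mutant arm is small, so
  its realized rate is noisy).

Each stage also writes TSV artifacts (`catalog96.tsv`, `signatures.tsv`,
`exposures_rel.tsv`, `cluster_labels.tsv`, `prognostic_genes.tsv`,
`cooccurrence_pairs.tsv`, `cnv_screen.tsv`, …) and `manifest.json` with
input/output content hashes, seeds and stage timings; identical configs
reproduce identical hashes.

A command-line wrapper lives at `inst/cli/bmsig.R`
(`simulate` / `run` / `report` subcommands).

## Documentation

`vignettes/bmsig-methods.Rmd` describes the models, the tunable parameters
and their defaults, the synthetic world (what it emulates and what it does
not), numerical conventions, and known limitations.
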