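Package: bmsig
Title: Mutational Process Signatures and Prognostic Genomic Screens for
    Brain-Metastasis Cohorts
Version: 0.1.0
Authors@R:
    person("BM Genomics", "Maintainers", email = "maintainers@bmsig.dev",
           role = c("aut", "cre"))
Description: A tested pipeline for somatic-mutation analysis of
    brain-metastasis cohorts: construction of the samples x 96
    trinucleotide-context substitution catalog from MAF-like input, de novo
    mutational-signature extraction by non-negative matrix factorization
    (generalized Kullback-Leibler loss) with cophenetic rank selection and
    cosine annotation against a reference signature set, molecular subtyping
    by resampled consensus clustering of signature activities, and
    survival/immunogenicity association screens (Kaplan-Meier, log-rank, Cox
    proportional hazards with Schoenfeld diagnostics, Fisher/BH co-occurrence
    networks, CNV deletion screens, ICI response contrasts). Includes a
    synthetic-cohort generator with planted ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
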