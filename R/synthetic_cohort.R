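# Synthetic brain-metastasis-like cohorts with planted ground truth.
#
# The generator states a world: Dirichlet-mixed exposures over planted
# 96-channel signatures, negative-binomially dispersed mutation loads,
# exponential survival whose hazard responds to signature presence, gene
# mutations and CNV deletions, uniform censoring, Bernoulli gene mutations
# with planted pair odds ratios, and an ICI cohort whose response
# probability depends on planted mutation status. Every draw happens under
# the config seed, so identical configs give byte-identical outputs.

BM_GENES <- c("TP53", "KRAS", "EGFR", "PTPRT", "PTPRD", "APC", "ARID1A",
              "FAT1", "PAK7", "EPHA7", "SPEN", "NOTCH3", "ATM", "TET2",
              "PREX2", "CARD11", "PIK3CG", "RB1", "PTEN", "DUSP4")

#' Planted mutational signatures
#'
#' Four well-separated, biologically styled 96-channel profiles built in
#' code (no external data): a C>A-dominated tobacco-like pattern, a C>T at
#' NpCpG mismatch-repair-like pattern, a C>T at 5'-pyrimidine UV-like
#' pattern, and a C>G/C>T at tCw APOBEC-like pattern. Rows sum to 1.
#'
#' @param k Number of signatures (1-4, subsets taken in the order above).
#' @return k x 96 row-stochastic matrix with channel column names.
#' @export
planted_signatures <- function(k = 4L) {
  stopifnot(k >= 1L, k <= 4L)
  channels <- sbs96_channels()
  five <- substr(channels, 1L, 1L)
  ref <- substr(channels, 3L, 3L)
  alt <- substr(channels, 5L, 5L)
  three <- substr(channels, 7L, 7L)
  cls <- paste0(ref, ">", alt)
  base <- rep(0.2 / 96, 96)
  w_tobacco <- base + 0.8 * (cls == "C>A") / sum(cls == "C>A")
  w_mmr <- base + 0.8 * (cls == "C>T" & three == "G") /
    sum(cls == "C>T" & three == "G")
  uv_mask <- cls == "C>T" & five %in% c("C", "T") & three != "G"
  w_uv <- base + 0.8 * uv_mask / sum(uv_mask)
  ap_mask <- cls %in% c("C>G", "C>T") & five == "T" & three %in% c("A", "T")
  w_apobec <- base + 0.8 * ap_mask / sum(ap_mask)
  W <- rbind(tobacco_like = w_tobacco, mmr_like = w_mmr, uv_like = w_uv,
             apobec_like = w_apobec)[seq_len(k), , drop = FALSE]
  colnames(W) <- channels
  W / rowSums(W)
}

#' Synthetic reference signature set
#'
#' A constructed stand-in for a public reference signature database (which
#' cannot be shipped): the four planted patterns under reference-style names
#' plus four decoy processes (flat, T>C-dominated, T>A-dominated, and C>A at
#' GpCpG). Used for cosine-annotation tests; it is synthetic and carries no
#' external signature values.
#'
#' @return 8 x 96 row-stochastic matrix.
#' @export
synthetic_reference_signatures <- function() {
  channels <- sbs96_channels()
  five <- substr(channels, 1L, 1L)
  ref <- substr(channels, 3L, 3L)
  alt <- substr(channels, 5L, 5L)
  three <- substr(channels, 7L, 7L)
  cls <- paste0(ref, ">", alt)
  base <- rep(0.2 / 96, 96)
  planted <- planted_signatures(4L)
  rownames(planted) <- c("Ref_4_tobacco", "Ref_6_mmr", "Ref_7_uv",
                         "Ref_13_apobec")
  flat <- rep(1 / 96, 96)
  t_c <- base + 0.8 * (cls == "T>C") / sum(cls == "T>C")
  t_a <- base + 0.8 * (cls == "T>A") / sum(cls == "T>A")
  gcg <- base + 0.8 * (cls == "C>A" & five == "G" & three == "G") /
    sum(cls == "C>A" & five == "G" & three == "G")
  decoys <- rbind(Ref_flat = flat, Ref_TC = t_c, Ref_TA = t_a,
                  Ref_GCG = gcg)
  colnames(decoys) <- channels
  R <- rbind(planted, decoys)
  R / rowSums(R)
}

#' Simulation configuration
#'
#' Defaults state the emulated world: 300 samples, four planted signatures
#' with Dirichlet(0.5) exposures, negative-binomial loads around 1500
#' mutations/sample, exponential baseline hazard calibrated to a 21.4-month
#' median survival, 120-month uniform censoring, planted hazard ratios of
#' 1.31 (signature presence), 0.54 (protective gene mutation), 1.71
#' (deleterious deletion) and 0.31 (protective deletion), a planted
#' co-occurring gene pair (odds ratio 6), and an ICI cohort with 32.2%
#' wild-type vs 58.3% mutant response rates.
#'
#' @param n_samples Cohort size (>= 10).
#' @param signatures Planted k x 96 row-stochastic matrix.
#' @param exposure_alpha Dirichlet concentration per signature.
#' @param load_mean,load_size Negative-binomial mutation load (mean, size).
#' @param baseline_rate Exponential baseline hazard (per month).
#' @param censor_window Uniform censoring upper bound (months).
#' @param hr_signature HR of presence (activity > 0.25) of signature 1.
#' @param gene_probs Named background mutation probabilities.
#' @param planted_pairs List of `list(a=, b=, or=)` pair plantings.
#' @param gene_hrs Named HRs of planted prognostic gene mutations.
#' @param deletion_probs Named CNV deletion probabilities.
#' @param deletion_hrs Named HRs of planted deletions.
#' @param hr_tmb HR per mutation/Mb of TMB.
#' @param panel_mb Panel size used to convert loads to TMB.
#' @param n_ici ICI cohort size.
#' @param ici_mut_prob Mutation prevalence in the ICI cohort.
#' @param ici_rate_wt,ici_rate_mut Response probabilities by arm.
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300L,
                       signatures = planted_signatures(4L),
                       exposure_alpha = rep(0.5, nrow(signatures)),
                       load_mean = 1500, load_size = 10,
                       baseline_rate = log(2) / 21.4,
                       censor_window = 120,
                       hr_signature = 1.31,
                       gene_probs = c(TP53 = 0.58, KRAS = 0.20, EGFR = 0.15,
                                      PTPRT = 0.14, PTPRD = 0.10, APC = 0.09,
                                      ARID1A = 0.08, FAT1 = 0.08, RB1 = 0.06,
                                      SPEN = 0.06, ATM = 0.05, TET2 = 0.05),
                       planted_pairs = list(list(a = "PTPRT", b = "FAT1",
                                                 or = 6)),
                       gene_hrs = c(PTPRT = 0.54, RB1 = 1.6),
                       deletion_probs = c(PTEN = 0.10, DUSP4 = 0.08,
                                          RB1 = 0.04, CDKN2A = 0.06),
                       deletion_hrs = c(PTEN = 1.71, DUSP4 = 0.31),
                       hr_tmb = 1.0, panel_mb = 1.14,
                       n_ici = 109L, ici_mut_prob = 0.12,
                       ici_rate_wt = 0.322, ici_rate_mut = 0.583,
                       seed = 1L) {
  stopifnot(n_samples >= 10L, load_mean >= 0, load_size > 0,
            baseline_rate > 0, censor_window > 0,
            all(abs(rowSums(signatures) - 1) < 1e-9),
            all(gene_probs >= 0 & gene_probs <= 1),
            all(deletion_probs >= 0 & deletion_probs <= 1),
            length(exposure_alpha) == nrow(signatures))
  structure(as.list(environment()), class = "sim_config")
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), n, k, byrow = TRUE)
  x / rowSums(x)
}

channel_to_record <- function(channel) {
  data.frame(ref = substr(channel, 3L, 3L), alt = substr(channel, 5L, 5L),
             context3 = paste0(substr(channel, 1L, 1L),
                               substr(channel, 3L, 3L),
                               substr(channel, 7L, 7L)),
             stringsAsFactors = FALSE)
}

#' Simulate the mutation catalog layer
#'
#' Per sample: exposures ~ Dirichlet(alpha); load ~ NegBin(mean, size);
#' each mutation drawn from the exposure-weighted signature mixture over the
#' 96 channels. Half of the emitted records are strand-flipped
#' (reverse-complemented ref/alt/context) so the pyrimidine collapse is
#' exercised; `context3` is always consistent with `ref`.
#'
#' @param cfg A `sim_config`.
#' @param records When `FALSE`, skip the per-mutation record expansion and
#'   return only the per-sample channel `counts` matrix drawn from the same
#'   distribution — much faster for simulation-heavy studies (`records`
#'   is `NULL` then).
#' @return List: `records` (mutation record data.frame), `counts`
#'   (samples x 96 matrix), `exposures` (true samples x k relative
#'   exposures), `loads` (per-sample counts), `samples`.
#' @export
simulate_catalog <- function(cfg, records = TRUE) {
  with_seed(cfg$seed, function() {
    n <- cfg$n_samples
    k <- nrow(cfg$signatures)
    samples <- sprintf("BM%03d", seq_len(n))
    expo <- rdirichlet(n, cfg$exposure_alpha)
    dimnames(expo) <- list(samples, rownames(cfg$signatures))
    loads <- if (cfg$load_mean == 0) {
      rep(0L, n)
    } else {
      stats::rnbinom(n, size = cfg$load_size, mu = cfg$load_mean)
    }
    channels <- sbs96_channels()
    counts_mat <- matrix(0L, n, 96L, dimnames = list(samples, channels))
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      m <- loads[i]
      if (m == 0L) next
      p <- drop(expo[i, ] %*% cfg$signatures)
      counts <- drop(stats::rmultinom(1L, m, p))
      counts_mat[i, ] <- counts
      if (!records) next
      ch <- rep(channels, counts)
      parts <- channel_to_record(ch)
      flip <- stats::runif(m) < 0.5
      if (any(flip)) {
        tmp_ref <- parts$ref[flip]
        parts$ref[flip] <- unname(.COMPLEMENT[tmp_ref])
        parts$alt[flip] <- unname(.COMPLEMENT[parts$alt[flip]])
        parts$context3[flip] <- revcomp(parts$context3[flip])
      }
      recs[[i]] <- data.frame(
        sample_id = samples[i],
        gene = NA_character_,  # assigned after rbind (unique passengers)
        chrom = "1",
        pos = sample.int(2e8L, m),
        ref = parts$ref, alt = parts$alt,
        variant_classification = "Missense_Mutation",
        variant_type = "SNP",
        context3 = parts$context3,
        germline_flag = FALSE,
        stringsAsFactors = FALSE
      )
    }
    if (!records) {
      return(list(records = NULL, counts = counts_mat, exposures = expo,
                  loads = loads, samples = samples))
    }
    records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
    if (is.null(records)) {
      records <- data.frame(sample_id = character(), gene = character(),
                            chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            variant_classification = character(),
                            variant_type = character(),
                            context3 = character(), germline_flag = logical(),
                            stringsAsFactors = FALSE)
    }
    rownames(records) <- NULL
    # each passenger record hits its own singleton gene: in panel/WES
    # cohorts the vast majority of genes are mutated in well under 5% of
    # samples, so passengers must not recur. Driver genes are overlaid by
    # simulate_cohort() from the planted gene matrix.
    records$gene <- sprintf("PSG%07d", seq_len(nrow(records)))
    list(records = records, counts = counts_mat, exposures = expo,
         loads = loads, samples = samples)
  })
}

#' Simulate survival from planted hazards
#'
#' `T ~ Exponential(rate * exp(sum(beta * x)))`, `C ~ Uniform(0, window)`,
#' `time = min(T, C)`, `event = (T <= C)`.
#'
#' @param cfg A `sim_config` (supplies `baseline_rate`, `censor_window`,
#'   `seed`).
#' @param linear_predictor Per-sample log-hazard offset `sum(beta * x)`.
#' @param seed Seed override (default `cfg$seed + 1`, so the survival layer
#'   has its own stream).
#' @return data.frame (os_months, os_event).
#' @export
simulate_survival <- function(cfg, linear_predictor,
                              seed = cfg$seed + 1L) {
  with_seed(seed, function() {
    n <- length(linear_predictor)
    t_event <- stats::rexp(n, rate = cfg$baseline_rate *
                             exp(linear_predictor))
    t_cens <- stats::runif(n, 0, cfg$censor_window)
    data.frame(os_months = pmin(t_event, t_cens),
               os_event = as.integer(t_event <= t_cens))
  })
}

#' Simulate the gene-mutation, CNV and ICI layers
#'
#' Independent genes are Bernoulli with their background probabilities;
#' planted pairs are drawn jointly from the 2x2 distribution with the
#' requested margins and odds ratio. Deletions are Bernoulli per gene. The
#' ICI cohort draws responses from arm-specific rates and maps responders to
#' CR/PR and non-responders to SD/PD.
#'
#' @param cfg A `sim_config`.
#' @param samples Sample ids for the mutation/CNV layers.
#' @param seed Seed override (default `cfg$seed + 2`).
#' @return List: `gene_matrix` (logical samples x genes), `cnv` (records),
#'   `ici` (records), `ici_mutant` (named logical).
#' @export
simulate_gene_matrix <- function(cfg, samples, seed = cfg$seed + 2L) {
  with_seed(seed, function() {
    n <- length(samples)
    genes <- names(cfg$gene_probs)
    M <- matrix(FALSE, n, length(genes), dimnames = list(samples, genes))
    paired <- unlist(lapply(cfg$planted_pairs, function(pp) c(pp$a, pp$b)))
    for (g in setdiff(genes, paired)) {
      M[, g] <- stats::runif(n) < cfg$gene_probs[[g]]
    }
    for (pp in cfg$planted_pairs) {
      pa <- cfg$gene_probs[[pp$a]]; pb <- cfg$gene_probs[[pp$b]]
      p11 <- joint_prob_from_or(pa, pb, pp$or)
      cell <- sample.int(4L, n, replace = TRUE,
                         prob = c(p11, pa - p11, pb - p11,
                                  1 - pa - pb + p11))
      M[, pp$a] <- cell %in% c(1L, 2L)
      M[, pp$b] <- cell %in% c(1L, 3L)
    }
    cnv_genes <- names(cfg$deletion_probs)
    cnv <- expand.grid(sample_id = samples, gene = cnv_genes,
                       stringsAsFactors = FALSE)
    del <- stats::runif(nrow(cnv)) <
      cfg$deletion_probs[match(cnv$gene, cnv_genes)]
    cnv$call <- ifelse(del, "deletion", "neutral")
    ici_samples <- sprintf("ICI%03d", seq_len(cfg$n_ici))
    mut <- stats::runif(cfg$n_ici) < cfg$ici_mut_prob
    rate <- ifelse(mut, cfg$ici_rate_mut, cfg$ici_rate_wt)
    resp <- stats::runif(cfg$n_ici) < rate
    response <- ifelse(resp,
                       sample(c("CR", "PR"), cfg$n_ici, replace = TRUE),
                       sample(c("SD", "PD"), cfg$n_ici, replace = TRUE))
    t_event <- stats::rexp(cfg$n_ici,
                           rate = cfg$baseline_rate * exp(log(0.6) * mut))
    t_cens <- stats::runif(cfg$n_ici, 0, cfg$censor_window)
    ici <- data.frame(sample_id = ici_samples, response = response,
                      os_months = pmin(t_event, t_cens),
                      os_event = as.integer(t_event <= t_cens),
                      cohort = "ICI_1", stringsAsFactors = FALSE)
    list(gene_matrix = M, cnv = cnv[order(cnv$sample_id, cnv$gene), ],
         ici = ici, ici_mutant = setNames(mut, ici_samples))
  })
}

# p11 solving OR = p11 p00 / (p10 p01) for given margins
joint_prob_from_or <- function(pa, pb, or) {
  if (abs(or - 1) < 1e-12) return(pa * pb)
  aa <- or - 1
  bb <- -((or - 1) * (pa + pb) + 1)
  cc <- or * pa * pb
  disc <- bb^2 - 4 * aa * cc
  p11 <- (-bb - sqrt(disc)) / (2 * aa)
  lo <- max(0, pa + pb - 1); hi <- min(pa, pb)
  min(max(p11, lo), hi)
}

#' Generate a full synthetic cohort
#'
#' Runs the catalog, gene/CNV/ICI and survival layers and assembles the
#' clinical table; the per-sample log-hazard combines the planted signature
#' presence (true exposure of signature 1 > 0.25), the planted gene and
#' deletion effects and the TMB effect. When `dir` is given, writes
#' `maf.tsv`, `clinical.tsv`, `cnv.tsv`, `ici.tsv`,
#' `ici_mutation_status.tsv` (planted mutation status of the ICI cohort)
#' and `truth.json`.
#'
#' @param cfg A `sim_config`.
#' @param dir Optional output directory (created if needed).
#' @return List: `records`, `clinical`, `cnv`, `ici`, `gene_matrix`,
#'   `truth` (planted parameters and per-sample ground truth).
#' @export
simulate_cohort <- function(cfg = sim_config(), dir = NULL) {
  cat_layer <- simulate_catalog(cfg)
  gen_layer <- simulate_gene_matrix(cfg, cat_layer$samples)
  samples <- cat_layer$samples
  n <- length(samples)
  M <- gen_layer$gene_matrix
  # overlay the planted driver genes onto each sample's records so the
  # MAF-derived gene matrix reproduces the planted one
  idx_by_sample <- split(seq_len(nrow(cat_layer$records)),
                         factor(cat_layer$records$sample_id,
                                levels = samples))
  for (i in seq_len(n)) {
    drivers <- colnames(M)[M[i, ]]
    idx <- idx_by_sample[[i]]
    take <- min(length(drivers), length(idx))
    if (take > 0L) {
      cat_layer$records$gene[idx[seq_len(take)]] <- drivers[seq_len(take)]
      if (take < length(drivers)) M[i, drivers[-seq_len(take)]] <- FALSE
    } else if (length(drivers)) {
      M[i, drivers] <- FALSE  # sample has no records to carry them
    }
  }
  gen_layer$gene_matrix <- M
  tmb <- cat_layer$loads / cfg$panel_mb  # mutations per Mb of panel
  sig_present <- cat_layer$exposures[, 1] > 0.25
  lp <- log(cfg$hr_signature) * sig_present + log(cfg$hr_tmb) * tmb
  for (g in names(cfg$gene_hrs)) {
    if (g %in% colnames(M)) lp <- lp + log(cfg$gene_hrs[[g]]) * M[, g]
  }
  del_mat <- with(gen_layer$cnv[gen_layer$cnv$call == "deletion", ],
                  table(factor(sample_id, levels = samples), gene) > 0)
  for (g in names(cfg$deletion_hrs)) {
    if (g %in% colnames(del_mat)) {
      lp <- lp + log(cfg$deletion_hrs[[g]]) * del_mat[, g]
    }
  }
  surv <- simulate_survival(cfg, lp)
  clinical <- with_seed(cfg$seed + 3L, function() {
    data.frame(
      sample_id = samples,
      os_months = surv$os_months,
      os_event = surv$os_event,
      age = round(stats::rnorm(n, 61, 11), 1),
      sex = sample(c("F", "M"), n, replace = TRUE),
      tumor_type = sample(c("NSCLC", "SKCM", "BRCA", "Other"), n,
                          replace = TRUE,
                          prob = c(0.466, 0.150, 0.097, 0.287)),
      tmb = tmb,
      fga = round(stats::rbeta(n, 2, 8), 4),
      msi = round(stats::rgamma(n, shape = 1.5, rate = 0.5), 3),
      stringsAsFactors = FALSE
    )
  })
  truth <- list(
    seed = cfg$seed,
    k = nrow(cfg$signatures),
    signature_names = rownames(cfg$signatures),
    exposures = unname(cat_layer$exposures),
    signature_present = unname(sig_present),
    gene_hrs = as.list(cfg$gene_hrs),
    deletion_hrs = as.list(cfg$deletion_hrs),
    hr_signature = cfg$hr_signature,
    planted_pairs = cfg$planted_pairs,
    ici_rates = c(wt = cfg$ici_rate_wt, mut = cfg$ici_rate_mut),
    ici_mutant = as.list(gen_layer$ici_mutant)
  )
  out <- list(records = cat_layer$records, clinical = clinical,
              cnv = gen_layer$cnv, ici = gen_layer$ici,
              gene_matrix = M, exposures = cat_layer$exposures,
              signatures = cfg$signatures, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_maf(out$records, file.path(dir, "maf.tsv"))
    utils::write.table(out$clinical, file.path(dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$cnv, file.path(dir, "cnv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(out$ici, file.path(dir, "ici.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = names(gen_layer$ici_mutant),
                 mutant = unname(gen_layer$ici_mutant)),
      file.path(dir, "ici_mutation_status.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
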