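# Cohort-level screens: recurrent genes, per-gene prognostic Cox,
# co-occurrence / mutual-exclusivity network, CNV survival screens, burden
# comparisons and ICI response association.

#' Sample x gene mutation indicator matrix
#'
#' TRUE when the sample carries at least one (already nonsynonymous-filtered)
#' mutation in the gene. Deterministic and order-invariant in the records.
#'
#' @param records Mutation record data.frame.
#' @param samples Ordered sample ids (must cover record sample ids).
#' @param genes Optional gene universe; defaults to genes seen in `records`.
#' @return Logical samples x genes matrix.
#' @export
gene_mutation_matrix <- function(records, samples, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(records$gene))
  extra <- setdiff(records$sample_id, samples)
  if (length(extra)) {
    stop("samples does not cover record sample ids", call. = FALSE)
  }
  M <- matrix(FALSE, length(samples), length(genes),
              dimnames = list(samples, genes))
  keep <- records$gene %in% genes
  if (any(keep)) {
    M[cbind(match(records$sample_id[keep], samples),
            match(records$gene[keep], genes))] <- TRUE
  }
  M
}

#' Recurrently mutated genes
#'
#' Genes mutated in at least `ceiling(min_frac * n_samples)` samples
#' (default 5%), sorted by decreasing frequency then gene name.
#'
#' @param M Logical samples x genes matrix from [gene_mutation_matrix()].
#' @param min_frac Recurrence threshold as a fraction of samples.
#' @return Character vector of gene names.
#' @export
recurrent_genes <- function(M, min_frac = 0.05) {
  n <- nrow(M)
  counts <- colSums(M)
  keep <- counts >= ceiling(min_frac * n)
  genes <- colnames(M)[keep]
  genes[order(-counts[keep], genes)]
}

cox_screen_row <- function(indicator, clinical, adjust) {
  cov <- data.frame(x = as.numeric(indicator))
  if (length(adjust)) cov <- cbind(cov, clinical[, adjust, drop = FALSE])
  fit <- coxph_fit(clinical$os_months, clinical$os_event, cov)
  row <- fit$coefficients[fit$coefficients$covariate == "x", ]
  data.frame(n_carrier = sum(indicator, na.rm = TRUE), hr = row$hr,
             ci_low = row$ci_low, ci_high = row$ci_high, beta = row$beta,
             se = row$se, p = row$p, n_used = fit$n_used,
             separation = fit$separation, stringsAsFactors = FALSE)
}

#' Per-gene prognostic Cox screen
#'
#' For each gene, a Cox model on the mutant indicator (optionally adjusted
#' for clinical covariates). The screen flags genes at raw `p < alpha` —
#' mirroring common practice for hypothesis generation — and always co-emits
#' BH q-values so the multiplicity cost is visible.
#'
#' @param M Logical samples x genes matrix (rows aligned with `clinical`).
#' @param clinical Clinical record data.frame (same sample order as `M`).
#' @param adjust Character vector of clinical columns to adjust for
#'   (e.g. `c("age", "sex", "tumor_type")`).
#' @param alpha Raw significance flag level.
#' @param min_carriers Genes with fewer mutant samples are skipped.
#' @return data.frame: gene, n_carrier, hr, ci_low, ci_high, p, q,
#'   significant.
#' @export
prognostic_gene_screen <- function(M, clinical, adjust = character(),
                                   alpha = 0.05, min_carriers = 5L) {
  stopifnot(nrow(M) == nrow(clinical))
  res <- list()
  for (gene in colnames(M)) {
    ind <- M[, gene]
    if (sum(ind) < min_carriers || sum(ind) == nrow(M)) {
      warning("gene ", gene, " skipped: ", sum(ind), " carrier(s)",
              call. = FALSE)
      next
    }
    row <- tryCatch(cox_screen_row(ind, clinical, adjust),
                    error = function(e) NULL)
    if (is.null(row)) next
    res[[gene]] <- cbind(data.frame(gene = gene, stringsAsFactors = FALSE),
                         row)
  }
  if (!length(res)) {
    return(data.frame(gene = character(), n_carrier = integer(),
                      hr = numeric(), ci_low = numeric(), ci_high = numeric(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      n_used = integer(), separation = logical(),
                      q = numeric(), significant = logical()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out$significant <- out$p < alpha
  out[order(out$p), ]
}

#' Pairwise co-occurrence / mutual-exclusivity network
#'
#' Every unordered gene pair is tested with the two-tailed Fisher exact test
#' on the 2x2 mutant/wild-type table; BH correction across all pairs;
#' direction is co-occurrence when the odds ratio exceeds 1, mutual
#' exclusivity otherwise. Per-gene degree counts significant partners.
#'
#' @param M Logical samples x genes matrix.
#' @param genes Genes to test (default: all columns); supply a prognostic
#'   subset to restrict the network.
#' @param fdr BH q-value cut for significance.
#' @return List: `pairs` data.frame (gene_a, gene_b, n_both, n_a_only,
#'   n_b_only, n_neither, odds_ratio, p, q, direction, significant) and
#'   `degree` (named integer vector over `genes`).
#' @export
cooccurrence_network <- function(M, genes = colnames(M), fdr = 0.1) {
  genes <- intersect(genes, colnames(M))
  if (length(genes) < 2L) {
    return(list(pairs = data.frame(), degree = setNames(integer(length(genes)),
                                                        genes)))
  }
  combs <- utils::combn(genes, 2L)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    ga <- combs[1, i]; gb <- combs[2, i]
    a <- M[, ga]; b <- M[, gb]
    tab <- c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
    ft <- fisher_exact(matrix(tab, 2L, byrow = TRUE))
    data.frame(gene_a = ga, gene_b = gb, n_both = tab[1], n_a_only = tab[2],
               n_b_only = tab[3], n_neither = tab[4], odds_ratio = ft$effect,
               p = ft$p, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pairs$q <- bh_adjust(pairs$p)
  pairs$direction <- ifelse(pairs$odds_ratio > 1, "co-occurrence",
                            "mutual-exclusivity")
  pairs$significant <- pairs$q < fdr
  sig <- pairs[pairs$significant, , drop = FALSE]
  degree <- setNames(integer(length(genes)), genes)
  if (nrow(sig)) {
    tab <- table(factor(c(sig$gene_a, sig$gene_b), levels = genes))
    degree[] <- as.integer(tab)
  }
  list(pairs = pairs[order(pairs$p), ], degree = degree)
}

#' CNV survival screen
#'
#' Per gene, a Cox model on the indicator of the requested call (deletion by
#' default), optionally adjusted; genes with fewer than `min_carriers`
#' carriers are skipped.
#'
#' @param cnv CNV record data.frame (`sample_id, gene, call`).
#' @param clinical Clinical record data.frame (defines the sample order).
#' @param call `"deletion"` or `"amplification"`.
#' @param adjust Clinical adjustment columns.
#' @param alpha Raw significance flag level.
#' @param min_carriers Carrier floor.
#' @return data.frame as in [prognostic_gene_screen()].
#' @export
cnv_survival_screen <- function(cnv, clinical, call = "deletion",
                                adjust = character(), alpha = 0.05,
                                min_carriers = 5L) {
  call <- match.arg(call, c("deletion", "amplification"))
  hits <- cnv[cnv$call == call, , drop = FALSE]
  genes <- sort(unique(cnv$gene))
  M <- matrix(FALSE, nrow(clinical), length(genes),
              dimnames = list(clinical$sample_id, genes))
  keep <- hits$sample_id %in% clinical$sample_id
  if (any(keep)) {
    M[cbind(match(hits$sample_id[keep], clinical$sample_id),
            match(hits$gene[keep], genes))] <- TRUE
  }
  prognostic_gene_screen(M, clinical, adjust = adjust, alpha = alpha,
                         min_carriers = min_carriers)
}

#' Compare a burden variable across groups
#'
#' Dispatches the Wilcoxon rank-sum test for two groups and Kruskal-Wallis
#' for three or more, the convention for non-normally distributed burden
#' variables such as TMB.
#'
#' @param values Numeric burden values.
#' @param grouping Grouping vector.
#' @return `test_result`.
#' @export
group_burden_compare <- function(values, grouping) {
  g <- factor(grouping)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (nlevels(g) == 2L) {
    wilcoxon_rank_sum(values[g == levels(g)[1]], values[g == levels(g)[2]])
  } else {
    kruskal_wallis(values, g)
  }
}

#' ICI response-rate association with a mutation
#'
#' Responders are CR or PR; NE records are excluded. Tests the 2x2
#' responder x mutant table with the Fisher exact test and reports
#' per-arm response rates (percent).
#'
#' @param ici ICI record data.frame (`sample_id, response, ...`).
#' @param mutant Named logical vector (or data.frame `sample_id`,
#'   `mutant`) giving mutation status per sample.
#' @return List: `test` (`test_result`), `rate_mutant`, `rate_wildtype`
#'   (percent), `n_mutant`, `n_wildtype`, `table`.
#' @export
ici_response_assoc <- function(ici, mutant) {
  if (is.data.frame(mutant)) {
    mutant <- setNames(as.logical(mutant$mutant), mutant$sample_id)
  }
  ici <- ici[ici$response != "NE", , drop = FALSE]
  status <- mutant[ici$sample_id]
  keep <- !is.na(status)
  ici <- ici[keep, , drop = FALSE]; status <- status[keep]
  if (sum(status) == 0L || sum(!status) == 0L) {
    stop("undefined contrast: both mutant and wild-type arms are required",
         call. = FALSE)
  }
  responder <- ici$response %in% c("CR", "PR")
  tab <- matrix(c(sum(status & responder), sum(status & !responder),
                  sum(!status & responder), sum(!status & !responder)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("mutant", "wildtype"),
                                c("responder", "non_responder")))
  list(test = fisher_exact(tab),
       rate_mutant = 100 * tab[1, 1] / sum(tab[1, ]),
       rate_wildtype = 100 * tab[2, 1] / sum(tab[2, ]),
       n_mutant = sum(tab[1, ]), n_wildtype = sum(tab[2, ]),
       table = tab)
}

#' Per-protein-change hotspot tally
#'
#' Reduces per-gene amino-acid change annotations to a count table (the
#' numeric content of a lollipop panel).
#'
#' @param records Mutation records carrying a `protein_change` column.
#' @param gene Gene symbol to tally.
#' @return data.frame (protein_change, n), decreasing.
#' @export
hotspot_tally <- function(records, gene) {
  if (!"protein_change" %in% names(records)) {
    stop("records carry no protein_change column", call. = FALSE)
  }
  sub <- records[records$gene == gene & !is.na(records$protein_change), ]
  if (!nrow(sub)) return(data.frame(protein_change = character(),
                                    n = integer()))
  tab <- sort(table(sub$protein_change), decreasing = TRUE)
  data.frame(protein_change = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
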