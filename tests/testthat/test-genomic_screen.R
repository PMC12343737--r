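test_that("recurrent_genes applies the >= 5% boundary with ceiling", {
  mk <- function(n, hits) {
    M <- matrix(FALSE, n, 1, dimnames = list(NULL, "G1"))
    M[seq_len(hits), 1] <- TRUE
    M
  }
  expect_equal(recurrent_genes(mk(100, 5)), "G1")   # 5 >= ceil(5) = 5
  expect_equal(recurrent_genes(mk(100, 4)), character(0))
  expect_equal(recurrent_genes(mk(421, 21)), character(0))  # ceil(21.05)=22
  expect_equal(recurrent_genes(mk(421, 22)), "G1")

  # sorted by frequency then name
  M <- cbind(A = c(TRUE, TRUE, FALSE, TRUE), B = c(TRUE, TRUE, TRUE, TRUE),
             C = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(recurrent_genes(M, 0.25), c("B", "A", "C"))
})

test_that("gene_mutation_matrix is idempotent and order-invariant", {
  rec <- make_records(c("S1", "S2", "S1", "S3"), "C", "T", "ACA",
                      gene = c("TP53", "TP53", "KRAS", "PTEN"))
  samples <- c("S1", "S2", "S3", "S4")
  M1 <- gene_mutation_matrix(rec, samples)
  M2 <- gene_mutation_matrix(rec[sample(4), ], samples)
  expect_identical(M1, M2)
  expect_true(M1["S1", "TP53"] && M1["S1", "KRAS"])
  expect_false(any(M1["S4", ]))
  expect_error(gene_mutation_matrix(rec, c("S1", "S2")), "cover")
})

test_that("cooccurrence_network matches the Fisher oracle and edge cases", {
  # perfectly co-occurring pair in n = 6: table [[3,0],[0,3]]
  M <- cbind(A = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
             B = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  net <- cooccurrence_network(M)
  expect_equal(net$pairs$p, 0.1)
  expect_equal(net$pairs$direction, "co-occurrence")
  expect_equal(net$pairs$n_both + net$pairs$n_a_only + net$pairs$n_b_only +
                 net$pairs$n_neither, 6L)

  # single gene: empty network
  single <- cooccurrence_network(M[, 1, drop = FALSE])
  expect_equal(nrow(single$pairs), 0L)

  # permutation invariance of the p-values
  set.seed(77)
  Mr <- matrix(runif(200) < 0.3, 50, 4,
               dimnames = list(NULL, c("A", "B", "C", "D")))
  p1 <- cooccurrence_network(Mr)$pairs
  perm <- sample(50)
  p2 <- cooccurrence_network(Mr[perm, ])$pairs
  key <- paste(p1$gene_a, p1$gene_b)
  expect_equal(p1$p, p2$p[match(key, paste(p2$gene_a, p2$gene_b))])
})

test_that("prognostic_gene_screen recovers a planted protective gene", {
  set.seed(101)
  n <- 400
  M <- cbind(PROT = rbinom(n, 1, 0.3) == 1,
             NULL1 = rbinom(n, 1, 0.25) == 1,
             NULL2 = rbinom(n, 1, 0.25) == 1)
  rownames(M) <- sprintf("S%03d", 1:n)
  lp <- log(0.5) * M[, "PROT"]
  tm <- rexp(n, 0.05 * exp(lp)); cs <- runif(n, 0, 60)
  clin <- data.frame(sample_id = rownames(M),
                     os_months = pmin(tm, cs),
                     os_event = as.integer(tm <= cs),
                     age = rnorm(n, 60, 10),
                     sex = sample(c("F", "M"), n, TRUE),
                     tumor_type = "NSCLC", tmb = 1, fga = 0.1, msi = 0.2)
  scr <- prognostic_gene_screen(M, clin)
  prot <- scr[scr$gene == "PROT", ]
  expect_true(prot$significant)
  expect_lt(abs(prot$beta - log(0.5)), 2 * prot$se)
  expect_true(all(c("q", "hr", "ci_low", "ci_high") %in% names(scr)))

  # zero-carrier gene is skipped with a warning
  M2 <- cbind(M, EMPTY = rep(FALSE, n))
  expect_warning(scr2 <- prognostic_gene_screen(M2, clin), "EMPTY")
  expect_false("EMPTY" %in% scr2$gene)
})

test_that("cnv_survival_screen recovers planted deletion effects", {
  set.seed(33)
  n <- 400
  del_bad <- rbinom(n, 1, 0.15) == 1
  del_good <- rbinom(n, 1, 0.15) == 1
  samples <- sprintf("S%03d", 1:n)
  lp <- log(1.7) * del_bad + log(0.3) * del_good
  tm <- rexp(n, 0.05 * exp(lp)); cs <- runif(n, 0, 60)
  clin <- data.frame(sample_id = samples, os_months = pmin(tm, cs),
                     os_event = as.integer(tm <= cs),
                     age = rnorm(n, 60, 10),
                     sex = sample(c("F", "M"), n, TRUE),
                     tumor_type = "NSCLC", tmb = 1, fga = 0.1, msi = 0.2)
  cnv <- rbind(
    data.frame(sample_id = samples, gene = "PTEN",
               call = ifelse(del_bad, "deletion", "neutral")),
    data.frame(sample_id = samples, gene = "DUSP4",
               call = ifelse(del_good, "deletion", "neutral")),
    data.frame(sample_id = samples, gene = "NEVER", call = "neutral")
  )
  scr <- suppressWarnings(cnv_survival_screen(cnv, clin))
  expect_false("NEVER" %in% scr$gene)       # never deleted: skipped
  expect_gt(scr$hr[scr$gene == "PTEN"], 1)
  expect_lt(scr$hr[scr$gene == "DUSP4"], 1)
})

test_that("group_burden_compare dispatches on the number of groups", {
  v <- c(1, 2, 3, 4, 10, 11, 12, 13)
  two <- group_burden_compare(v, rep(c("a", "b"), each = 4))
  expect_match(two$method, "wilcoxon")
  three <- group_burden_compare(c(v, 20, 21), rep(c("a", "b", "c"),
                                                  c(4, 4, 2)))
  expect_equal(three$method, "kruskal_wallis")
  expect_error(group_burden_compare(v, rep("a", 8)), "2 groups")
})

test_that("ici_response_assoc reproduces the response-rate contrast", {
  ici <- data.frame(
    sample_id = sprintf("P%02d", 1:12),
    response = c("CR", "PR", "CR", "PR", "SD", "PD",   # 6 mutants: 4 resp
                 "PR", "SD", "PD", "PD", "SD", "PD"),  # 6 wt: 1 resp
    os_months = 10, os_event = 1, cohort = "c1")
  mutant <- setNames(rep(c(TRUE, FALSE), each = 6), ici$sample_id)
  res <- ici_response_assoc(ici, mutant)
  expect_equal(res$rate_mutant, 100 * 4 / 6, tolerance = 1e-12)
  expect_equal(res$rate_wildtype, 100 * 1 / 6, tolerance = 1e-12)
  # hypergeometric enumeration oracle for table [[4,2],[1,5]]
  probs <- dhyper(0:5, 6, 6, 5)
  p_oracle <- sum(probs[probs <= dhyper(4, 6, 6, 5) * (1 + 1e-7)])
  expect_equal(res$test$p, p_oracle, tolerance = 1e-12)

  # all responders in both arms -> p = 1
  ici2 <- ici; ici2$response <- "CR"
  expect_equal(ici_response_assoc(ici2, mutant)$test$p, 1)

  # NE records are excluded before testing
  ici3 <- ici; ici3$response[1] <- "NE"
  expect_equal(ici_response_assoc(ici3, mutant)$n_mutant, 5L)

  # zero mutants: undefined contrast
  expect_error(ici_response_assoc(ici, setNames(rep(FALSE, 12),
                                                ici$sample_id)),
               "undefined contrast")
})

test_that("hotspot_tally reduces protein changes to a count table", {
  rec <- make_records(paste0("S", 1:5), "C", "T", "ACA", gene = "PTPRT")
  rec$protein_change <- c("R364Q", "R364Q", "E548K", "R364Q", NA)
  tal <- hotspot_tally(rec, "PTPRT")
  expect_equal(tal$protein_change, c("R364Q", "E548K"))
  expect_equal(tal$n, c(3L, 1L))
  expect_error(hotspot_tally(rec[, -ncol(rec)], "PTPRT"), "protein_change")
})
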