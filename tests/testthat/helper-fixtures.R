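# Shared fixtures and independent oracles (kept deliberately naive and
# separate from the package's implementation paths).

make_records <- function(sample_id, ref, alt, context3,
                         gene = "TP53",
                         classification = "Missense_Mutation",
                         type = "SNP", germline = FALSE) {
  n <- max(length(sample_id), length(ref), length(alt), length(context3),
           length(gene), length(classification), length(germline))
  data.frame(
    sample_id = rep_len(sample_id, n),
    gene = rep_len(gene, n),
    chrom = "1",
    pos = seq_len(n) * 10L,
    ref = rep_len(ref, n),
    alt = rep_len(alt, n),
    variant_classification = rep_len(classification, n),
    variant_type = rep_len(type, n),
    context3 = rep_len(context3, n),
    germline_flag = rep_len(germline, n),
    stringsAsFactors = FALSE
  )
}

write_toy_maf <- function(rows, path = tempfile(fileext = ".maf")) {
  header <- paste("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
                  "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
                  "Variant_Classification", "Variant_Type", sep = "\t")
  writeLines(c(header, rows), path)
  path
}

# brute-force Efron partial log-likelihood for a single covariate, written
# as the textbook double sum -- the oracle for coxph_fit
brute_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    s0r <- sum(exp(beta * x[R]))
    s0d <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(s0r - (l / d) * s0d)
    }
  }
  ll
}

# independent log-rank oracle: direct O-E/V tabulation over event tables
brute_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  O1 <- E1 <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    n1 <- sum(time >= t & g == 1); n2 <- sum(time >= t & g == 2)
    d1 <- sum(time == t & event == 1 & g == 1)
    d2 <- sum(time == t & event == 1 & g == 2)
    n <- n1 + n2; d <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n - d) * n1 * n2 / (n^2 * (n - 1))
  }
  (O1 - E1)^2 / V
}

# adjusted Rand index between two labelings (contingency-table formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small deterministic survival fixture (n = 12, one binary covariate)
cox_fixture_n12 <- function() {
  list(time = c(4, 3, 1, 1, 2, 2, 3, 5, 6, 7, 8, 9),
       event = c(1, 1, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1),
       x = c(0, 1, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0))
}
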