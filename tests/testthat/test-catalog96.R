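test_that("channel order is the fixed 96-channel constant", {
  ch <- sbs96_channels()
  expect_length(ch, 96L)
  expect_false(anyDuplicated(ch) > 0)
  expect_equal(ch[1], "A[C>A]A")
  expect_equal(ch[96], "T[T>G]T")
  # pyrimidine references only
  expect_true(all(substr(ch, 3, 3) %in% c("C", "T")))
})

test_that("classify_channel collapses to pyrimidine reference", {
  expect_equal(classify_channel("C", "T", "ACA"), "A[C>T]A")
  expect_equal(classify_channel("G", "A", "TGT"), "A[C>T]A")
  # oracle: revcomp("CAG") = "CTG", A>C becomes T>G, flanks C/G
  expect_equal(classify_channel("A", "C", "CAG"), "C[T>G]G")
  expect_error(classify_channel("AT", "A", "ATA"), "single")
  expect_error(classify_channel("C", "T", "AAA"), "context")
})

test_that("classify_channel is reverse-complement symmetric (property)", {
  set.seed(7)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(unname(comp[strsplit(s, "")[[1]]])),
                          collapse = "")
  for (i in 1:50) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ctx <- paste0(sample(c("A", "C", "G", "T"), 1), ref,
                  sample(c("A", "C", "G", "T"), 1))
    expect_equal(classify_channel(ref, alt, ctx),
                 classify_channel(unname(comp[ref]), unname(comp[alt]),
                                  rc(ctx)))
  }
})

test_that("resolve_context prefers the context column, else the reference", {
  rec <- make_records("S1", "C", "T", "ACA")
  expect_equal(resolve_context(rec[1, ]), "ACA")

  rec$context3 <- NA_character_
  rec$chrom <- "chr1"; rec$pos <- 3L
  ref <- list(chr1 = "GACAT")
  expect_equal(resolve_context(rec[1, ], ref), "ACA")

  bad <- rec; bad$ref <- "T"; bad$alt <- "C"
  expect_error(resolve_context(bad[1, ], ref), "reference mismatch")
  expect_error(resolve_context(rec[1, ]), "context unavailable")

  indel <- rec; indel$variant_type <- "DEL"
  expect_error(resolve_context(indel[1, ], ref), "unsupported")
})

test_that("resolve_context works against a FASTA file via Biostrings", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 test contig", "GACAT"), fa)
  ref <- read_reference_fasta(fa)
  rec <- make_records("S1", "C", "T", NA_character_)
  rec$chrom <- "chr1"; rec$pos <- 3L
  expect_equal(resolve_context(rec[1, ], ref), "ACA")
})

test_that("build_catalog counts, zero rows, and the <1% channel filter", {
  rec <- make_records(c("S1", "S2"), "C", "T", "ACA")
  cat1 <- build_catalog(rec, samples = c("S1", "S2", "S3"),
                        min_sample_frac = 0)
  expect_equal(unname(cat1$counts[, "A[C>T]A"]), c(1L, 1L, 0L))
  expect_equal(sum(cat1$counts), 2L)
  expect_equal(unname(rowSums(cat1$counts)), c(1L, 1L, 0L))  # zero row kept

  # 201 samples: channel hit in exactly 1 sample (0.5% < 1%) is zeroed,
  # channel hit in all samples is retained
  samples <- sprintf("P%03d", 1:201)
  common <- make_records(samples, "C", "T", "ACA")
  rare <- make_records("P001", "C", "G", "TCT")
  cat2 <- build_catalog(rbind(common, rare), samples = samples)
  expect_equal(sum(cat2$counts[, "T[C>G]T"]), 0L)
  expect_equal(cat2$zeroed_channels, "T[C>G]T")
  expect_equal(sum(cat2$counts[, "A[C>T]A"]), 201L)

  # filter disabled: row sums equal per-sample SNP counts
  cat3 <- build_catalog(rbind(common, rare), samples = samples,
                        min_sample_frac = 0)
  expect_equal(unname(rowSums(cat3$counts)),
               unname(as.integer(table(factor(c(common$sample_id,
                                                rare$sample_id),
                                              levels = samples)))))
})

test_that("catalog strand symmetry and additivity (properties)", {
  set.seed(11)
  cfg <- sim_config(n_samples = 20, load_mean = 50, seed = 3)
  sim <- simulate_catalog(cfg)
  rec <- sim$records
  cat_a <- build_catalog(rec, samples = sim$samples, min_sample_frac = 0)

  # reverse-complement every record: catalog must be identical
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- vapply(strsplit(rec$context3, ""), function(ch)
    paste(rev(unname(comp[ch])), collapse = ""), character(1))
  flipped <- rec
  flipped$ref <- unname(comp[rec$ref])
  flipped$alt <- unname(comp[rec$alt])
  flipped$context3 <- rc
  cat_b <- build_catalog(flipped, samples = sim$samples, min_sample_frac = 0)
  expect_identical(cat_a$counts, cat_b$counts)

  # additivity with filtering disabled
  half <- nrow(rec) %/% 2
  c1 <- build_catalog(rec[1:half, ], samples = sim$samples,
                      min_sample_frac = 0)
  c2 <- build_catalog(rec[(half + 1):nrow(rec), ], samples = sim$samples,
                      min_sample_frac = 0)
  expect_identical(cat_a$counts, c1$counts + c2$counts)
})

test_that("catalog TSV serialization is bit-stable", {
  cfg <- sim_config(n_samples = 12, load_mean = 30, seed = 5)
  sim <- simulate_catalog(cfg)
  catal <- build_catalog(sim$records, samples = sim$samples,
                         min_sample_frac = 0)
  p1 <- tempfile(); p2 <- tempfile()
  write_catalog(catal, p1)
  back <- read_catalog(p1)
  expect_identical(back$counts, catal$counts)
  write_catalog(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("compute_tmb divides by panel size", {
  rec10 <- make_records(rep("S1", 10), "C", "T", "ACA")
  expect_equal(compute_tmb(rec10, panel_mb = 1.0), 10)
  expect_equal(compute_tmb(rec10[0, ], panel_mb = 1.0), 0)
  rec21 <- make_records(rep("S1", 21), "C", "T", "ACA")
  expect_equal(compute_tmb(rec21, panel_mb = 1.14), 21 / 1.14)
  expect_error(compute_tmb(rec10, panel_mb = 0), "panel_mb")
})

test_that("compute_tcw counts the APOBEC-context motif", {
  expect_equal(compute_tcw(make_records("S1", "C", "T", "TCA"))$tcw_count, 1L)
  r2 <- compute_tcw(make_records("S1", "C", "T", "ACA"))
  expect_equal(r2$tcw_count, 0L)
  expect_equal(r2$total_c_mut, 1L)
  # G>A at TGA is the reverse strand of C>T at TCA
  expect_equal(compute_tcw(make_records("S1", "G", "A", "TGA"))$tcw_count, 1L)
  # C>G at tCw counts too; T>C does not
  expect_equal(compute_tcw(make_records("S1", "C", "G", "TCT"))$tcw_count, 1L)
  expect_equal(compute_tcw(make_records("S1", "T", "C", "TTA"))$tcw_count, 0L)
})
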