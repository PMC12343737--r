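# samples x 96 catalog construction, TMB and tCw (APOBEC-context) burden.

#' Resolve the trinucleotide context of a SNP record
#'
#' A `context3` value supplied on the record takes precedence; otherwise the
#' context is looked up in a reference FASTA (via Biostrings) at
#' `chrom:pos +/- 1` and checked against the recorded reference allele.
#'
#' @param record One-row mutation record data.frame.
#' @param reference Optional named `Biostrings::DNAStringSet` (or any named
#'   list of character sequences) keyed by chromosome.
#' @return Uppercase 3-mer.
#' @export
resolve_context <- function(record, reference = NULL) {
  if (record$variant_type != "SNP") {
    stop("unsupported variant: context resolution is defined for SNPs only",
         call. = FALSE)
  }
  if (!is.na(record$context3)) {
    return(toupper(record$context3))
  }
  if (is.null(reference)) {
    stop("context unavailable: record has no context3 and no reference ",
         "FASTA was provided", call. = FALSE)
  }
  chrom <- as.character(record$chrom)
  if (!chrom %in% names(reference)) {
    stop("context unavailable: chromosome '", chrom,
         "' absent from reference", call. = FALSE)
  }
  seq <- toupper(as.character(reference[[chrom]]))
  pos <- record$pos
  if (pos < 2L || pos + 1L > nchar(seq)) {
    stop("context unavailable: position ", pos,
         " +/- 1 outside reference sequence", call. = FALSE)
  }
  ctx <- substr(seq, pos - 1L, pos + 1L)
  if (substr(ctx, 2L, 2L) != record$ref) {
    stop("reference mismatch: FASTA base '", substr(ctx, 2L, 2L),
         "' at ", chrom, ":", pos, " differs from recorded ref '",
         record$ref, "'", call. = FALSE)
  }
  ctx
}

#' Load a reference FASTA for context resolution
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()`; Biostrings is only
#' required when FASTA-backed context resolution is actually used.
#'
#' @param path FASTA path.
#' @return Named DNAStringSet.
#' @export
read_reference_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA-backed context resolution",
         call. = FALSE)
  }
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

resolve_contexts <- function(records, reference = NULL) {
  ctx <- toupper(records$context3)
  need <- is.na(ctx)
  if (any(need)) {
    for (i in which(need)) {
      ctx[i] <- resolve_context(records[i, , drop = FALSE], reference)
    }
  }
  ctx
}

#' Build the samples x 96 trinucleotide-context catalog
#'
#' Aggregates SNP records into the count matrix V (rows = samples, columns =
#' the 96 channels of [sbs96_channels()]). Channels that are nonzero in fewer
#' than `min_sample_frac` of samples (strict `<`, default 1%) are zeroed to
#' suppress noise; channel positions are retained so the matrix stays
#' 96-wide. Samples without SNPs appear as zero rows.
#'
#' @param records Mutation record data.frame (SNPs; non-SNP rows are
#'   rejected — filter first).
#' @param samples Ordered sample ids covering all record sample ids.
#' @param min_sample_frac Low-frequency channel threshold; 0 disables.
#' @param reference Optional reference passed to [resolve_context()].
#' @return List of class `mutation_catalog`: `samples`, `channels`,
#'   `counts` (samples x 96 integer matrix), `zeroed_channels`.
#' @export
build_catalog <- function(records, samples = NULL, min_sample_frac = 0.01,
                          reference = NULL) {
  if (any(records$variant_type != "SNP")) {
    stop("unsupported variant: build_catalog() expects SNP records only",
         call. = FALSE)
  }
  if (is.null(samples)) samples <- sort(unique(records$sample_id))
  extra <- setdiff(records$sample_id, samples)
  if (length(extra)) {
    stop("samples does not cover record sample ids: ",
         paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
  }
  channels <- sbs96_channels()
  counts <- matrix(0L, nrow = length(samples), ncol = 96L,
                   dimnames = list(samples, channels))
  if (nrow(records)) {
    ctx <- resolve_contexts(records, reference)
    ch <- classify_channel(records$ref, records$alt, ctx)
    tab <- table(factor(records$sample_id, levels = samples),
                 factor(ch, levels = channels))
    counts[] <- as.integer(tab)
  }
  zeroed <- character()
  if (min_sample_frac > 0 && length(samples) > 0) {
    frac <- colMeans(counts > 0L)
    drop <- frac > 0 & frac < min_sample_frac
    if (any(drop)) {
      zeroed <- channels[drop]
      counts[, drop] <- 0L
    }
  }
  structure(list(samples = samples, channels = channels, counts = counts,
                 zeroed_channels = zeroed),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("mutation_catalog:", length(x$samples), "samples x 96 channels;",
      sum(x$counts), "mutations;", length(x$zeroed_channels),
      "channel(s) zeroed by the low-frequency filter\n")
  invisible(x)
}

#' Serialize / read a catalog as TSV
#'
#' First column `sample_id`, then the 96 channel columns in the fixed order.
#'
#' @param catalog A `mutation_catalog`.
#' @param path Output path.
#' @return `path` invisibly / a `mutation_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  out <- data.frame(sample_id = catalog$samples, catalog$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  channels <- sbs96_channels()
  missing <- setdiff(channels, names(tab))
  if (length(missing)) {
    stop("catalog file lacks channel column(s), e.g. ", missing[1],
         call. = FALSE)
  }
  counts <- as.matrix(tab[, channels])
  storage.mode(counts) <- "integer"
  rownames(counts) <- tab$sample_id
  structure(list(samples = tab$sample_id, channels = channels,
                 counts = counts, zeroed_channels = character()),
            class = "mutation_catalog")
}

#' Tumor mutational burden of one sample
#'
#' `count / panel_mb`, mutations per megabase. `records` should already be
#' nonsynonymous-filtered. The default panel size (1.14 Mb) matches a
#' published targeted-capture footprint; set `panel_mb = 1` for raw counts.
#'
#' @param records Mutation records of one sample.
#' @param panel_mb Sequenced territory in megabases (> 0).
#' @return Non-negative mutations/Mb.
#' @export
compute_tmb <- function(records, panel_mb = 1.14) {
  if (!is.numeric(panel_mb) || length(panel_mb) != 1L || panel_mb <= 0) {
    stop("parameter error: panel_mb must be a positive scalar", call. = FALSE)
  }
  nrow(records) / panel_mb
}

#' tCw-motif (APOBEC-context) burden of one sample
#'
#' Counts pyrimidine-collapsed C>T and C>G substitutions whose context is
#' tCw — 5' base T and 3' base A or T, the motif preferentially deaminated by
#' APOBEC enzymes — alongside the total number of C>N substitutions.
#'
#' @param records SNP mutation records of one sample.
#' @param reference Optional reference for context resolution.
#' @return List with `tcw_count` and `total_c_mut`.
#' @export
compute_tcw <- function(records, reference = NULL) {
  if (nrow(records) == 0L) return(list(tcw_count = 0L, total_c_mut = 0L))
  snp <- records[records$variant_type == "SNP", , drop = FALSE]
  if (nrow(snp) == 0L) return(list(tcw_count = 0L, total_c_mut = 0L))
  ch <- classify_channel(snp$ref, snp$alt, resolve_contexts(snp, reference))
  ref_py <- substr(ch, 3L, 3L)
  alt_py <- substr(ch, 5L, 5L)
  five <- substr(ch, 1L, 1L)
  three <- substr(ch, 7L, 7L)
  is_c <- ref_py == "C"
  tcw <- is_c & alt_py %in% c("T", "G") & five == "T" & three %in% c("A", "T")
  list(tcw_count = sum(tcw), total_c_mut = sum(is_c))
}
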