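# Cohort IO: MAF-like mutation tables, clinical, CNV and ICI tables.
#
# Records are plain data.frames with a class tag; readers validate invariants
# up front and keep missing clinical covariates as NA so that model-fit code
# can do complete-case handling (dropped rows are counted there, not here).

NONSYNONYMOUS_CLASSES <- c(
  "Missense_Mutation", "Frame_Shift_Ins", "Frame_Shift_Del",
  "In_Frame_Ins", "In_Frame_Del", "Nonsense_Mutation", "Splice_Site"
)

KNOWN_CLASSES <- c(NONSYNONYMOUS_CLASSES, "Silent")

#' Default MAF column dialect
#'
#' Maps the logical columns the package needs onto standard MAF v2.4 header
#' names. Override entries to ingest tables from heterogeneous studies.
#'
#' @return Named character vector (logical name -> header name).
#' @export
maf_dialect <- function() {
  c(sample = "Tumor_Sample_Barcode",
    gene = "Hugo_Symbol",
    chrom = "Chromosome",
    pos = "Start_Position",
    ref = "Reference_Allele",
    alt = "Tumor_Seq_Allele2",
    classification = "Variant_Classification",
    type = "Variant_Type",
    context3 = "ref_context",       # optional
    germline_flag = "dbSNP_Flag")   # optional
}

#' Read a MAF-like tab-separated mutation table
#'
#' Lines starting with `#` are skipped; unknown columns are ignored; unknown
#' variant classifications are mapped to `"other"`. Records flagged as known
#' germline polymorphisms are retained but marked (`germline_flag`), so the
#' dbSNP exclusion happens in [filter_nonsynonymous()], not at parse time.
#'
#' @param path Path to the tab-separated file (header row required).
#' @param dialect Named map of logical column names to header names; see
#'   [maf_dialect()]. `context3` and `germline_flag` entries are optional.
#' @return A `data.frame` of mutation records with columns `sample_id`,
#'   `gene`, `chrom`, `pos`, `ref`, `alt`, `variant_classification`,
#'   `variant_type`, `context3` (NA when absent), `germline_flag`.
#' @export
read_maf <- function(path, dialect = maf_dialect()) {
  if (!file.exists(path)) stop("MAF file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  required <- c("sample", "gene", "chrom", "pos", "ref", "alt",
                "classification", "type")
  for (key in required) {
    col <- dialect[[key]]
    if (is.null(col) || is.na(col) || !col %in% names(tab)) {
      stop("format error: required MAF column '", key, "' (header '",
           if (is.null(col)) "?" else col, "') is missing", call. = FALSE)
    }
  }
  pos_raw <- tab[[dialect[["pos"]]]]
  pos <- suppressWarnings(as.integer(pos_raw))
  bad <- which(is.na(pos) & !is.na(pos_raw))
  if (length(bad)) {
    stop("parse error: non-integer position '", pos_raw[bad[1]],
         "' at data line ", bad[1] + 1L, call. = FALSE)
  }
  cls <- tab[[dialect[["classification"]]]]
  cls[!cls %in% KNOWN_CLASSES] <- "other"
  ctx_col <- dialect[["context3"]]
  ctx <- if (!is.null(ctx_col) && !is.na(ctx_col) && ctx_col %in% names(tab)) {
    x <- toupper(tab[[ctx_col]])
    x[x == ""] <- NA_character_
    x
  } else {
    rep(NA_character_, nrow(tab))
  }
  gl_col <- dialect[["germline_flag"]]
  gl <- if (!is.null(gl_col) && !is.na(gl_col) && gl_col %in% names(tab)) {
    tolower(tab[[gl_col]]) %in% c("1", "true", "yes")
  } else {
    rep(FALSE, nrow(tab))
  }
  rec <- data.frame(
    sample_id = tab[[dialect[["sample"]]]],
    gene = tab[[dialect[["gene"]]]],
    chrom = tab[[dialect[["chrom"]]]],
    pos = pos,
    ref = toupper(tab[[dialect[["ref"]]]]),
    alt = toupper(tab[[dialect[["alt"]]]]),
    variant_classification = cls,
    variant_type = tab[[dialect[["type"]]]],
    context3 = ctx,
    germline_flag = gl,
    stringsAsFactors = FALSE
  )
  validate_mutation_records(rec)
  rec
}

validate_mutation_records <- function(rec) {
  if (nrow(rec) == 0L) return(invisible(rec))
  if (any(rec$pos < 1L, na.rm = TRUE)) {
    stop("validation error: positions must be >= 1", call. = FALSE)
  }
  snp <- rec$variant_type == "SNP"
  if (any(snp)) {
    ok <- rec$ref[snp] %in% .BASES & rec$alt[snp] %in% .BASES &
      rec$ref[snp] != rec$alt[snp]
    if (!all(ok)) {
      stop("validation error: SNP records must have single distinct A/C/G/T ",
           "ref and alt alleles", call. = FALSE)
    }
    has_ctx <- snp & !is.na(rec$context3)
    if (any(has_ctx)) {
      mid <- substr(rec$context3[has_ctx], 2L, 2L)
      if (any(mid != rec$ref[has_ctx])) {
        stop("validation error: context3 middle base must equal ref for SNPs",
             call. = FALSE)
      }
    }
  }
  invisible(rec)
}

#' Write mutation records back to a MAF-like table
#'
#' Inverse of [read_maf()]: emits the required columns under the dialect's
#' header names (plus context/germline columns when mapped), so that
#' `read_maf(write_maf(x))` round-trips.
#'
#' @param records Mutation record data.frame.
#' @param path Output path.
#' @param dialect Column dialect, as in [read_maf()].
#' @return `path`, invisibly.
#' @export
write_maf <- function(records, path, dialect = maf_dialect()) {
  out <- data.frame(
    records$sample_id, records$gene, records$chrom, records$pos,
    records$ref, records$alt, records$variant_classification,
    records$variant_type,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out) <- unname(dialect[c("sample", "gene", "chrom", "pos", "ref",
                                 "alt", "classification", "type")])
  if (!is.na(dialect["context3"])) {
    out[[unname(dialect[["context3"]])]] <- ifelse(is.na(records$context3),
                                                   "", records$context3)
  }
  if (!is.na(dialect["germline_flag"])) {
    out[[unname(dialect[["germline_flag"]])]] <-
      ifelse(records$germline_flag, "1", "0")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict mutation records to nonsynonymous classes
#'
#' Keeps exactly missense, frameshift indel, in-frame indel, nonsense and
#' splice-site mutations; drops silent and unclassified records as well as
#' records marked as known germline polymorphisms. Order is preserved and
#' the operation is idempotent. `Splice_Region`, `Translation_Start_Site`
#' and `Nonstop_Mutation` are not retained by default; pass them through
#' `extra_classes` if a cohort requires them.
#'
#' @param records Mutation record data.frame.
#' @param extra_classes Additional classification strings to retain.
#' @return Filtered records.
#' @export
filter_nonsynonymous <- function(records, extra_classes = character()) {
  keep <- records$variant_classification %in%
    c(NONSYNONYMOUS_CLASSES, extra_classes) & !records$germline_flag
  records[keep, , drop = FALSE]
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, header = TRUE, sep = sep, quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("format error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Read a clinical table
#'
#' Expects columns `sample_id, os_months, os_event, age, sex, tumor_type,
#' tmb, fga, msi`. Missing covariate values are retained as `NA`; they are
#' dropped (and counted) only when a model is fitted.
#'
#' @param path TSV/CSV path.
#' @return Clinical record data.frame.
#' @export
read_clinical <- function(path) {
  tab <- read_table_checked(path, c("sample_id", "os_months", "os_event",
                                    "age", "sex", "tumor_type", "tmb",
                                    "fga", "msi"))
  num <- function(x) suppressWarnings(as.numeric(x))
  rec <- data.frame(
    sample_id = as.character(tab$sample_id),
    os_months = num(tab$os_months),
    os_event = as.integer(num(tab$os_event)),
    age = num(tab$age),
    sex = as.character(tab$sex),
    tumor_type = as.character(tab$tumor_type),
    tmb = num(tab$tmb),
    fga = num(tab$fga),
    msi = num(tab$msi),
    stringsAsFactors = FALSE
  )
  rec$sex[rec$sex == ""] <- NA_character_
  rec$tumor_type[rec$tumor_type == ""] <- NA_character_
  if (any(rec$os_months < 0, na.rm = TRUE)) {
    stop("validation error: os_months must be non-negative", call. = FALSE)
  }
  if (any(rec$fga < 0 | rec$fga > 1, na.rm = TRUE)) {
    stop("validation error: fga must lie in [0, 1]", call. = FALSE)
  }
  if (any(!rec$os_event %in% c(0L, 1L), na.rm = TRUE)) {
    stop("validation error: os_event must be 0/1", call. = FALSE)
  }
  rec
}

#' Read a gene-level copy-number call table
#'
#' Expects columns `sample_id, gene, call` with calls in
#' `{amplification, deletion, neutral}`; one call per (sample, gene).
#'
#' @param path TSV/CSV path.
#' @return CNV record data.frame.
#' @export
read_cnv <- function(path) {
  tab <- read_table_checked(path, c("sample_id", "gene", "call"))
  call <- tolower(as.character(tab$call))
  bad <- setdiff(unique(call), c("amplification", "deletion", "neutral"))
  if (length(bad)) {
    stop("validation error: unknown CNV call(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rec <- data.frame(sample_id = as.character(tab$sample_id),
                    gene = as.character(tab$gene), call = call,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(rec[c("sample_id", "gene")])) {
    stop("validation error: multiple CNV calls for one (sample, gene)",
         call. = FALSE)
  }
  rec
}

#' Read an immune-checkpoint-inhibitor outcome table
#'
#' Expects columns `sample_id, response, os_months, os_event, cohort` with
#' response in `{CR, PR, SD, PD, NE}`.
#'
#' @param path TSV/CSV path.
#' @return ICI record data.frame.
#' @export
read_ici <- function(path) {
  tab <- read_table_checked(path, c("sample_id", "response", "os_months",
                                    "os_event", "cohort"))
  resp <- toupper(as.character(tab$response))
  bad <- setdiff(unique(resp), c("CR", "PR", "SD", "PD", "NE"))
  if (length(bad)) {
    stop("validation error: unknown response value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  os <- suppressWarnings(as.numeric(tab$os_months))
  if (any(os < 0, na.rm = TRUE)) {
    stop("validation error: os_months must be non-negative", call. = FALSE)
  }
  data.frame(sample_id = as.character(tab$sample_id), response = resp,
             os_months = os,
             os_event = as.integer(suppressWarnings(as.numeric(tab$os_event))),
             cohort = as.character(tab$cohort), stringsAsFactors = FALSE)
}
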