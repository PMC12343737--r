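# End-to-end orchestration: ingest -> catalog -> signatures -> clustering ->
# survival & genomic screens -> report, with a provenance manifest.

default_config <- function() {
  list(
    seed = 1L,
    catalog = list(min_sample_frac = 0.01, panel_mb = 1.14),
    nmf = list(k_range = c(2L, 6L), n_runs = 10L, max_iter = 2000L,
               tol = 1e-6, auto_k = TRUE),
    binarize = list(threshold = 0.25),
    cluster = list(k_max = 8L, reps = 1000L, p_item = 0.8, sd_min = 0.1,
                   min_consensus = 0.9),
    screens = list(min_frac = 0.05, fdr = 0.1, alpha = 0.05,
                   adjust = c("age", "sex", "tumor_type"),
                   min_carriers = 5L, ici_gene = "PTPRT")
  )
}

merge_config <- function(base, override) {
  for (key in names(override)) {
    base[[key]] <- if (is.list(base[[key]]) && is.list(override[[key]])) {
      merge_config(base[[key]], override[[key]])
    } else {
      override[[key]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' JSON file with an `inputs` block (`maf`, `clinical` required; `cnv`,
#' `ici`, `reference_signatures` optional) and optional overrides of the
#' documented defaults (`seed`, `catalog.*`, `nmf.*`, `binarize.threshold`,
#' `cluster.*`, `screens.*`). Violations are reported with the offending
#' keys.
#'
#' @param path JSON config path, or an equivalent named list.
#' @return Validated config list.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    path
  }
  merged <- merge_config(default_config(), cfg)
  problems <- character()
  if (is.null(merged$inputs)) {
    problems <- c(problems, "inputs")
  } else {
    for (key in c("maf", "clinical")) {
      if (is.null(merged$inputs[[key]])) {
        problems <- c(problems, paste0("inputs.", key))
      }
    }
  }
  if (!is.null(merged$binarize$threshold) &&
      (merged$binarize$threshold < 0 || merged$binarize$threshold >= 1)) {
    problems <- c(problems, "binarize.threshold")
  }
  if (length(problems)) {
    stop("config error: missing/invalid key(s): ",
         paste(problems, collapse = ", "), call. = FALSE)
  }
  merged
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stage graph on the configured inputs and writes intermediate
#' TSV/JSON artifacts plus a run manifest (config snapshot, seeds, input
#' hashes, stage timings, output index with content hashes) to `out_dir`.
#' Any stage failure aborts with a stage-tagged error; identical config and
#' inputs reproduce identical numeric outputs.
#'
#' @param config Path to a JSON config (or a config list), see
#'   [load_config()].
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return The manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% stop(
    "config error: missing/invalid key(s): out_dir", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- character()
  timings <- list()
  stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  ing <- stage("ingest", function() {
    maf <- read_maf(cfg$inputs$maf)
    clinical <- read_clinical(cfg$inputs$clinical)
    cnv <- if (!is.null(cfg$inputs[["cnv"]])) read_cnv(cfg$inputs[["cnv"]])
    ici <- if (!is.null(cfg$inputs[["ici"]])) read_ici(cfg$inputs[["ici"]])
    list(maf = maf, clinical = clinical, cnv = cnv, ici = ici)
  })
  message(sprintf("[ingest] %d mutation records, %d samples",
                  nrow(ing$maf), nrow(ing$clinical)))

  nonsyn <- stage("filter", function() filter_nonsynonymous(ing$maf))
  message(sprintf("[filter] %d -> %d nonsynonymous records",
                  nrow(ing$maf), nrow(nonsyn)))

  catalog <- stage("catalog", function() {
    snp <- nonsyn[nonsyn$variant_type == "SNP", , drop = FALSE]
    build_catalog(snp, samples = ing$clinical$sample_id,
                  min_sample_frac = cfg$catalog$min_sample_frac)
  })
  outputs <- c(outputs, write_tsv(
    data.frame(sample_id = catalog$samples, catalog$counts,
               check.names = FALSE),
    file.path(out_dir, "catalog96.tsv")))

  sig <- stage("signatures", function() {
    ks <- seq.int(cfg$nmf$k_range[1], cfg$nmf$k_range[2])
    rank_sel <- NULL
    k <- cfg$nmf[["k"]]
    if (is.null(k)) {
      if (!isTRUE(cfg$nmf$auto_k)) {
        stop("no nmf.k given and nmf.auto_k is not enabled; set one")
      }
      rank_sel <- estimate_rank(catalog, k_range = ks,
                                n_runs = cfg$nmf$n_runs, seed = cfg$seed)
      k <- rank_sel$chosen_k
    }
    fit <- nmf_factorize(catalog, k = k, seed = cfg$seed,
                         max_iter = cfg$nmf$max_iter, tol = cfg$nmf$tol)
    ref_path <- cfg$inputs[["reference_signatures"]] %||%
      system.file("extdata", "reference_signatures_synthetic.tsv",
                  package = "bmsig")
    ref <- read_reference_signatures(ref_path)
    matched <- match_reference(fit, ref)
    present <- binarize_activity(fit, cfg$binarize$threshold)
    list(rank_sel = rank_sel, fit = fit, matched = matched,
         present = present, k = k)
  })
  message(sprintf("[signatures] k = %d (%s)", sig$k,
                  paste(sprintf("%s~%s(%.2f)",
                                sig$matched$assignment$signature,
                                sig$matched$assignment$reference,
                                sig$matched$assignment$cosine),
                        collapse = ", ")))
  outputs <- c(outputs,
    write_tsv(data.frame(signature = rownames(sig$fit$W), sig$fit$W,
                         check.names = FALSE),
              file.path(out_dir, "signatures.tsv")),
    write_tsv(data.frame(sample_id = rownames(sig$fit$H_rel),
                         sig$fit$H_rel, check.names = FALSE),
              file.path(out_dir, "exposures_rel.tsv")),
    write_tsv(sig$matched$assignment,
              file.path(out_dir, "signature_annotation.tsv")))
  if (!is.null(sig$rank_sel)) {
    p <- file.path(out_dir, "rank_selection.json")
    jsonlite::write_json(sig$rank_sel[c("k_range", "cophenetic",
                                        "reconstruction_error", "chosen_k")],
                         p, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, p)
  }

  clus <- stage("cluster", function() {
    X <- tryCatch(filter_low_variance(sig$fit$H_rel, cfg$cluster$sd_min),
                  error = function(e) NULL)
    if (is.null(X)) return(NULL)  # too few variable signatures to subtype
    res <- consensus_cluster(X, k_max = cfg$cluster$k_max,
                             reps = cfg$cluster$reps,
                             p_item = cfg$cluster$p_item, seed = cfg$seed)
    sub <- finalize_subtypes(res,
                             min_cluster_consensus = cfg$cluster$min_consensus)
    list(res = res, sub = sub)
  })
  if (!is.null(clus)) {
    message(sprintf("[cluster] k = %d, cluster consensus %s", clus$sub$k,
                    paste(round(clus$sub$cluster_consensus, 3),
                          collapse = "/")))
    outputs <- c(outputs,
      write_tsv(data.frame(sample_id = names(clus$sub$labels),
                           cluster = clus$sub$labels),
                file.path(out_dir, "cluster_labels.tsv")))
    p <- file.path(out_dir, "cluster_quality.json")
    jsonlite::write_json(list(k = clus$sub$k,
                              area = clus$res$area,
                              delta_area = clus$res$delta_area,
                              cluster_consensus = clus$sub$cluster_consensus,
                              unstable = clus$sub$unstable),
                         p, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, p)
  } else {
    message("[cluster] skipped: fewer than 2 variable signature activities")
  }

  scr <- stage("screens", function() {
    clinical <- ing$clinical
    # pre-count carriers from the records so the indicator matrix is only
    # built over candidate genes (cohorts carry vast numbers of singleton
    # passenger genes)
    ug <- unique(nonsyn[c("sample_id", "gene")])
    carriers <- table(ug$gene)
    thresh <- ceiling(cfg$screens$min_frac * nrow(clinical))
    candidates <- names(carriers)[carriers >= thresh]
    M <- gene_mutation_matrix(nonsyn[nonsyn$gene %in% candidates, ,
                                     drop = FALSE],
                              clinical$sample_id, genes = candidates)
    rec <- recurrent_genes(M, cfg$screens$min_frac)
    prog <- if (length(rec)) {
      suppressWarnings(prognostic_gene_screen(
        M[, rec, drop = FALSE], clinical, adjust = cfg$screens$adjust,
        alpha = cfg$screens$alpha, min_carriers = cfg$screens$min_carriers))
    }
    net <- if (length(rec) >= 2L) {
      cooccurrence_network(M, genes = rec, fdr = cfg$screens$fdr)
    }
    cnv_scr <- if (!is.null(ing$cnv)) {
      suppressWarnings(cnv_survival_screen(
        ing$cnv, clinical, call = "deletion", adjust = cfg$screens$adjust,
        alpha = cfg$screens$alpha, min_carriers = cfg$screens$min_carriers))
    }
    # signature-presence survival (per extracted signature)
    sig_surv <- lapply(colnames(sig$present), function(s) {
      grp <- sig$present[clinical$sample_id, s]
      if (length(unique(grp)) < 2L) return(NULL)
      lr <- logrank_test(clinical$os_months, clinical$os_event, grp)
      data.frame(signature = s, n_present = sum(grp),
                 logrank_chisq = lr$statistic, logrank_p = lr$p)
    })
    sig_surv <- do.call(rbind, sig_surv[!vapply(sig_surv, is.null,
                                                logical(1))])
    cluster_lr <- if (!is.null(clus)) {
      labs <- clus$sub$labels[clinical$sample_id]
      km <- lapply(sort(unique(labs)), function(cl) {
        f <- km_fit(clinical$os_months[labs == cl],
                    clinical$os_event[labs == cl])
        data.frame(cluster = cl, n = sum(labs == cl), median_os = f$median)
      })
      do.call(rbind, km)
    }
    ici_res <- NULL
    if (!is.null(ing$ici)) {
      gene <- cfg$screens$ici_gene
      status_path <- cfg$inputs[["ici_mutation_status"]]
      status <- if (!is.null(status_path)) {
        tab <- utils::read.delim(status_path, stringsAsFactors = FALSE)
        setNames(as.logical(tab$mutant), tab$sample_id)
      } else if (gene %in% colnames(M)) {
        M[, gene]
      }
      if (!is.null(status)) {
        ici_res <- tryCatch(ici_response_assoc(ing$ici, status),
                            error = function(e) NULL)
      }
    }
    list(recurrent = rec, prognostic = prog, network = net, cnv = cnv_scr,
         sig_surv = sig_surv, cluster_km = cluster_lr, ici = ici_res)
  })
  if (!is.null(scr$prognostic)) {
    outputs <- c(outputs, write_tsv(scr$prognostic,
                                    file.path(out_dir,
                                              "prognostic_genes.tsv")))
  }
  if (!is.null(scr$network) && nrow(scr$network$pairs)) {
    outputs <- c(outputs, write_tsv(scr$network$pairs,
                                    file.path(out_dir,
                                              "cooccurrence_pairs.tsv")))
  }
  if (!is.null(scr$cnv)) {
    outputs <- c(outputs, write_tsv(scr$cnv,
                                    file.path(out_dir, "cnv_screen.tsv")))
  }
  if (!is.null(scr$sig_surv)) {
    outputs <- c(outputs, write_tsv(scr$sig_surv,
                                    file.path(out_dir,
                                              "signature_survival.tsv")))
  }
  if (!is.null(scr$cluster_km)) {
    outputs <- c(outputs, write_tsv(scr$cluster_km,
                                    file.path(out_dir, "cluster_km.tsv")))
  }

  report <- stage("report", function() {
    list(
      n_samples = nrow(ing$clinical),
      n_mutations = nrow(ing$maf),
      n_nonsynonymous = nrow(nonsyn),
      chosen_k = sig$k,
      signature_annotation = sig$matched$assignment,
      cluster_k = if (!is.null(clus)) clus$sub$k,
      cluster_consensus = if (!is.null(clus)) clus$sub$cluster_consensus,
      n_recurrent_genes = length(scr$recurrent),
      n_prognostic_genes = if (!is.null(scr$prognostic)) {
        sum(scr$prognostic$significant)
      } else 0L,
      n_significant_pairs = if (!is.null(scr$network) &&
                                nrow(scr$network$pairs)) {
        sum(scr$network$pairs$significant)
      } else 0L,
      ici = if (!is.null(scr$ici)) {
        list(rate_mutant = scr$ici$rate_mutant,
             rate_wildtype = scr$ici$rate_wildtype,
             p = scr$ici$test$p)
      }
    )
  })
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  outputs <- c(outputs, p)

  manifest <- list(
    config = cfg,
    seed = cfg$seed,
    input_hashes = as.list(tools::md5sum(
      unlist(cfg$inputs[vapply(cfg$inputs, is.character, logical(1))]))),
    stage_timings = timings,
    outputs = as.list(tools::md5sum(sort(unique(outputs))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
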