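# Molecular subtyping by resampled consensus clustering of signature
# activities.
#
# Per repetition, floor(p_item * n) samples are drawn without replacement,
# the pairwise distance is 1 - Pearson correlation between sample activity
# profiles, and an agglomerative Ward tree (Lance-Williams ward.D2 on the
# correlation-derived dissimilarity) is cut at every k in 2..k_max. The
# consensus index of a sample pair at a given k is the fraction of
# co-subsampled repetitions in which the pair co-clustered.

#' Drop low-variance signature activity columns
#'
#' Signatures whose activity standard deviation across samples is strictly
#' below `sd_min` carry little subtype information (mostly technical noise)
#' and are removed before clustering. At least two columns must survive.
#'
#' @param H_rel Samples x k relative-activity matrix.
#' @param sd_min Threshold on the column standard deviation (strict `<`).
#' @return The reduced matrix; dropped columns in `attr(, "dropped")`.
#' @export
filter_low_variance <- function(H_rel, sd_min = 0.1) {
  H_rel <- as.matrix(H_rel)
  sds <- apply(H_rel, 2L, stats::sd)
  keep <- sds >= sd_min
  if (sum(keep) < 2L) {
    stop("degenerate input: fewer than 2 signature activities have sd >= ",
         sd_min, call. = FALSE)
  }
  out <- H_rel[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(H_rel)[!keep]
  out
}

# 1 - Pearson correlation between rows; zero-variance rows get distance 1
# to every other sample (documented fallback).
pearson_dist <- function(X) {
  ok <- apply(X, 1L, stats::sd) > 0
  d <- matrix(1, nrow(X), nrow(X))
  if (sum(ok) >= 2L) {
    d[ok, ok] <- 1 - stats::cor(t(X[ok, , drop = FALSE]))
  }
  diag(d) <- 0
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Consensus clustering with subsampled Ward trees
#'
#' @param X Samples x features activity matrix (rows named by sample).
#' @param k_max Largest cluster count evaluated (consensus computed for
#'   k = 2..k_max).
#' @param reps Number of subsampling repetitions.
#' @param p_item Fraction of samples drawn (without replacement) per rep.
#' @param seed RNG seed; runs are deterministic given the seed.
#' @return List of class `consensus_result`: `consensus` (list over k of
#'   samples x samples matrices, unit diagonal), `never_cosampled` (logical
#'   matrix flag), `cdf` (list of ECDFs), `area`, `delta_area`, `labels`
#'   (matrix, one column per k, from re-clustering each consensus matrix),
#'   `k_max`, `samples`.
#' @export
consensus_cluster <- function(X, k_max = 8L, reps = 1000L, p_item = 0.8,
                              seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k_max + 1L) {
    stop("need at least k_max + 1 samples", call. = FALSE)
  }
  if (ncol(X) < 2L) stop("need at least 2 features", call. = FALSE)
  if (is.null(rownames(X))) rownames(X) <- paste0("sample", seq_len(n))
  n_sub <- floor(p_item * n)
  ks <- 2L:k_max
  co_sampled <- matrix(0, n, n)
  co_clustered <- lapply(ks, function(k) matrix(0, n, n))
  names(co_clustered) <- ks
  n_skipped <- 0L

  with_seed(seed, function() {
    for (rep_i in seq_len(reps)) {
      idx <- sort(sample.int(n, n_sub))
      if (n_sub < k_max) {  # cannot cut this subsample at every k
        n_skipped <<- n_skipped + 1L
        next
      }
      d <- pearson_dist(X[idx, , drop = FALSE])
      hc <- stats::hclust(d, method = "ward.D2")
      co_sampled[idx, idx] <<- co_sampled[idx, idx] + 1
      for (k in ks) {
        lab <- stats::cutree(hc, k = k)
        same <- outer(lab, lab, `==`)
        co_clustered[[as.character(k)]][idx, idx] <<-
          co_clustered[[as.character(k)]][idx, idx] + same
      }
    }
  })

  if (n_skipped > 0L) {
    warning(n_skipped, " repetition(s) skipped: subsample smaller than k_max",
            call. = FALSE)
  }
  never <- co_sampled == 0
  diag(never) <- FALSE
  consensus <- lapply(co_clustered, function(M) {
    C <- M / pmax(co_sampled, 1)
    C[never] <- 0  # never co-sampled: consensus undefined, reported as 0
    diag(C) <- 1
    dimnames(C) <- list(rownames(X), rownames(X))
    C
  })

  up <- upper.tri(consensus[[1]])
  entries <- lapply(consensus, function(C) C[up])
  cdf <- lapply(entries, stats::ecdf)
  # area under the ECDF on [0,1] equals 1 - mean(entries)
  area <- vapply(entries, function(e) 1 - mean(e), numeric(1))
  delta_area <- area
  if (length(area) > 1L) {
    delta_area[-1] <- diff(area) / area[-length(area)]
  }
  labels <- vapply(ks, function(k) {
    C <- consensus[[as.character(k)]]
    stats::cutree(stats::hclust(stats::as.dist(1 - C), method = "ward.D2"),
                  k = k)
  }, integer(n))
  dimnames(labels) <- list(rownames(X), ks)

  structure(list(consensus = consensus, never_cosampled = never, cdf = cdf,
                 area = area, delta_area = delta_area, labels = labels,
                 k_max = k_max, samples = rownames(X)),
            class = "consensus_result")
}

#' Pick the cluster number from the delta-area profile
#'
#' `delta_area[k] = (area[k] - area[k-1]) / area[k-1]` (with
#' `delta_area[2] = area[2]`). Returns the smallest k after which the
#' relative area gain falls below `elbow` — i.e. adding more clusters no
#' longer increases consensus mass appreciably. Advisory: pipelines may
#' override.
#'
#' @param result A `consensus_result`.
#' @param elbow Relative-gain threshold (default 0.1).
#' @return Integer k in `2..k_max`.
#' @export
select_k <- function(result, elbow = 0.1) {
  ks <- 2L:result$k_max
  for (i in seq_along(ks)) {
    if (i == length(ks)) return(ks[i])
    if (result$delta_area[i + 1L] < elbow) return(ks[i])
  }
  ks[length(ks)]
}

#' Final subtype labels with a cluster-consensus quality gate
#'
#' Reports the mean within-cluster consensus for each cluster at the chosen
#' k; clusters below `min_cluster_consensus` are flagged unstable. Labels
#' are always emitted — the gate is a quality report, not a filter.
#'
#' @param result A `consensus_result`.
#' @param k Cluster number (default [select_k()]).
#' @param min_cluster_consensus Stability gate (default 0.9).
#' @return List of class `subtype_result`: `k`, `labels` (named integer
#'   vector), `cluster_consensus`, `unstable` (logical per cluster).
#' @export
finalize_subtypes <- function(result, k = select_k(result),
                              min_cluster_consensus = 0.9) {
  C <- result$consensus[[as.character(k)]]
  labels <- result$labels[, as.character(k)]
  cc <- vapply(seq_len(k), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) return(NA_real_)  # singleton: no within pairs
    sub <- C[idx, idx]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  names(cc) <- paste0("cluster", seq_len(k))
  unstable <- !is.na(cc) & cc < min_cluster_consensus
  structure(list(k = k, labels = labels, cluster_consensus = cc,
                 unstable = unstable,
                 min_cluster_consensus = min_cluster_consensus),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat("subtype_result: k =", x$k, "| sizes:",
      paste(table(x$labels), collapse = "/"), "\n")
  cat("cluster consensus:",
      paste(sprintf("%s=%.3f%s", names(x$cluster_consensus),
                    x$cluster_consensus,
                    ifelse(x$unstable, "*", "")), collapse = " "),
      "(* = below", x$min_cluster_consensus, "gate)\n")
  invisible(x)
}
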