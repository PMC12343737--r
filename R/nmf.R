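# De novo mutational-signature extraction.
#
# V (samples x 96) is factorized as V ~ H %*% W with H (samples x k) the
# exposure matrix and W (k x 96) the signature matrix, by multiplicative
# updates minimizing the generalized Kullback-Leibler divergence
#   D(V || HW) = sum( V * log(V / HW) - V + HW ).
# KL on raw counts is the canonical loss for mutation catalogs (Poisson
# likelihood up to a constant). A Frobenius option is provided.

.NMF_EPS <- .Machine$double.eps

kl_divergence <- function(V, R) {
  # R = reconstruction HW; terms with V == 0 contribute R
  pos <- V > 0
  sum(V[pos] * log(V[pos] / pmax(R[pos], .NMF_EPS))) - sum(V) + sum(R)
}

#' Factorize a mutation catalog into signatures and exposures
#'
#' Multiplicative-update NMF (Lee-Seung) under generalized KL divergence:
#' the objective is non-increasing at every iteration and the run is
#' deterministic for a fixed seed (uniform random initialization). On
#' return, signature rows of `W` are rescaled to sum to 1 with the
#' compensating rescale folded into `H`, so the product `H %*% W` is
#' unchanged and `H` carries absolute mutation contributions.
#'
#' @param V Samples x 96 non-negative matrix (or a `mutation_catalog`).
#' @param k Number of signatures, `1 <= k <= min(n_samples, 96)`.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Iteration cap.
#' @param tol Relative-change convergence threshold on the objective,
#'   checked every 10 iterations.
#' @param loss `"kl"` (default) or `"frobenius"`.
#' @param track When TRUE, record the objective at every iteration in
#'   `objective_trace` (costs one divergence evaluation per iteration).
#' @return List of class `nmf_fit`: `W` (k x 96, rows sum to 1), `names`,
#'   `H_counts` (samples x k), `H_rel` (rows sum to 1; all-zero samples
#'   flagged in `zero_samples`, left as zero rows), `present` placeholder,
#'   `k`, `loss_value`, `n_iter`, `converged`.
#' @export
nmf_factorize <- function(V, k, seed = 1L, max_iter = 2000L, tol = 1e-6,
                          loss = c("kl", "frobenius"), track = FALSE) {
  loss <- match.arg(loss)
  if (inherits(V, "mutation_catalog")) V <- V$counts
  V <- as.matrix(V)
  storage.mode(V) <- "double"
  if (any(V < 0)) stop("V must be non-negative", call. = FALSE)
  if (all(V == 0)) stop("degenerate input: all-zero catalog", call. = FALSE)
  n <- nrow(V); m <- ncol(V)
  if (k < 1L || k > min(n, m)) {
    stop("parameter error: k must lie in [1, min(n_samples, n_channels)]",
         call. = FALSE)
  }
  rng <- local_rng(seed)
  H <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  W <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  rng$restore()

  obj_prev <- Inf
  converged <- FALSE
  n_iter <- max_iter
  trace <- if (track) numeric(max_iter) else NULL
  for (it in seq_len(max_iter)) {
    R <- H %*% W
    if (loss == "kl") {
      Q <- V / pmax(R, .NMF_EPS)
      H <- H * ((Q %*% t(W)) / rep(rowSums(W), each = n))
      R <- pmax(H %*% W, .NMF_EPS)
      Q <- V / R
      W <- W * ((t(H) %*% Q) / matrix(colSums(H), k, m))
    } else {
      H <- H * (V %*% t(W)) / pmax(H %*% (W %*% t(W)), .NMF_EPS)
      W <- W * (t(H) %*% V) / pmax((t(H) %*% H) %*% W, .NMF_EPS)
    }
    if (track) {
      R <- H %*% W
      trace[it] <- if (loss == "kl") kl_divergence(V, R) else
        sum((V - R)^2) / 2
    }
    if (it %% 10L == 0L || it == max_iter) {
      R <- H %*% W
      obj <- if (loss == "kl") kl_divergence(V, R) else sum((V - R)^2) / 2
      denom <- max(abs(obj_prev), 1)
      if (is.finite(obj_prev) && abs(obj_prev - obj) / denom < tol) {
        converged <- TRUE
        n_iter <- it
        obj_prev <- obj
        break
      }
      obj_prev <- obj
    }
  }

  # row-normalize W; fold scales into H so H %*% W is unchanged
  s <- rowSums(W)
  s[s == 0] <- 1
  W <- W / s
  H <- sweep(H, 2L, s, `*`)
  rs <- rowSums(H)
  zero_samples <- rs <= 0
  H_rel <- H
  H_rel[!zero_samples, ] <- H[!zero_samples, , drop = FALSE] /
    rs[!zero_samples]
  dimnames(W) <- list(paste0("S", seq_len(k)), colnames(V))
  dimnames(H) <- list(rownames(V), rownames(W))
  dimnames(H_rel) <- dimnames(H)
  structure(list(W = W, names = rownames(W), H_counts = H, H_rel = H_rel,
                 k = k, loss = loss, loss_value = obj_prev, n_iter = n_iter,
                 converged = converged, zero_samples = zero_samples,
                 objective_trace = if (track) trace[seq_len(n_iter)]),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat("nmf_fit: k =", x$k, "| loss =", x$loss, "=",
      format(x$loss_value, digits = 6), "|", x$n_iter, "iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' Select the number of signatures by consensus stability
#'
#' For each candidate rank, `n_runs` random-restart factorizations are run
#' (run seeds derived as `seed + run - 1`); each run assigns every sample to
#' its dominant signature, and the run-averaged co-assignment matrix forms a
#' connectivity consensus. `cophenetic[k]` is the cophenetic correlation
#' between the consensus dissimilarity (1 - consensus) and its
#' average-linkage dendrogram; `reconstruction_error[k]` is the best run's
#' divergence. `chosen_k` is the largest k before the steepest cophenetic
#' drop off the high plateau: among candidate ranks whose cophenetic lies
#' within `plateau_tol` of the profile maximum, the one with the largest
#' subsequent decrease `cophenetic[k] - cophenetic[k+1]` is chosen — the
#' last rank still on the stability plateau before consensus degrades. If
#' the profile never drops, the k with maximal cophenetic is chosen. The
#' choice is advisory and overridable downstream.
#'
#' @param V Catalog counts (or `mutation_catalog`).
#' @param k_range Inclusive integer range of candidate ranks.
#' @param n_runs Random restarts per rank (>= 2; consensus is undefined for
#'   a single run).
#' @param seed Base seed.
#' @param max_iter,tol Passed to [nmf_factorize()]; rank selection does not
#'   need tight convergence, so defaults are looser than the final fit's.
#' @param plateau_tol Cophenetic tolerance defining the high plateau from
#'   which the steepest drop is measured.
#' @return List of class `rank_selection`: `k_range`, `cophenetic`,
#'   `reconstruction_error`, `chosen_k`.
#' @export
estimate_rank <- function(V, k_range = 2:6, n_runs = 10L, seed = 1L,
                          max_iter = 300L, tol = 1e-5, plateau_tol = 0.01) {
  if (inherits(V, "mutation_catalog")) V <- V$counts
  if (n_runs < 2L) {
    stop("parameter error: n_runs must be >= 2 (consensus is undefined ",
         "for a single run)", call. = FALSE)
  }
  k_range <- sort(unique(as.integer(k_range)))
  n <- nrow(V)
  coph <- rec_err <- setNames(numeric(length(k_range)), k_range)
  for (idx in seq_along(k_range)) {
    k <- k_range[idx]
    consensus <- matrix(0, n, n)
    best <- Inf
    for (run in seq_len(n_runs)) {
      fit <- nmf_factorize(V, k, seed = seed + run - 1L,
                           max_iter = max_iter, tol = tol)
      assign <- max.col(fit$H_rel, ties.method = "first")
      consensus <- consensus + outer(assign, assign, `==`)
      best <- min(best, fit$loss_value)
    }
    consensus <- consensus / n_runs
    d <- stats::as.dist(1 - consensus)
    coph[idx] <- if (max(d) < 1e-12) {
      1.0  # all samples always co-cluster (e.g. k = 1)
    } else {
      hc <- stats::hclust(d, method = "average")
      stats::cor(d, stats::cophenetic(hc))
    }
    rec_err[idx] <- best
  }
  chosen <- if (length(k_range) == 1L) {
    k_range
  } else {
    drops <- coph[-length(coph)] - coph[-1]
    on_plateau <- coph[-length(coph)] >= max(coph) - plateau_tol
    if (all(drops <= 0) || !any(on_plateau & drops > 0)) {
      k_range[which.max(coph)]
    } else {
      drops[!on_plateau] <- -Inf
      k_range[which.max(drops)]
    }
  }
  structure(list(k_range = k_range, cophenetic = coph,
                 reconstruction_error = rec_err, chosen_k = chosen),
            class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("rank_selection over k =", paste(range(x$k_range), collapse = ".."),
      "| chosen_k =", x$chosen_k, "\n")
  print(round(rbind(cophenetic = x$cophenetic,
                    reconstruction_error = x$reconstruction_error), 4))
  invisible(x)
}

#' Cosine similarity between two non-negative vectors or matrix rows
#'
#' @param u,v Numeric vectors of equal length.
#' @return `u . v / (|u| |v|)` in `[0, 1]` for non-negative input.
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Annotate extracted signatures against a reference set
#'
#' Computes the full k x m cosine-similarity matrix between extracted
#' signature rows and reference rows (both row-normalized over the same
#' channel order) and assigns each extracted signature its arg-max
#' reference.
#'
#' @param S An `nmf_fit` (or a k x 96 matrix with channel column names).
#' @param R Reference set: an m x 96 matrix with channel column names and
#'   reference names as row names (see [read_reference_signatures()]).
#' @return List: `assignment` data.frame (signature, reference, cosine) and
#'   `similarity` (k x m matrix).
#' @export
match_reference <- function(S, R) {
  W <- if (inherits(S, "nmf_fit")) S$W else as.matrix(S)
  R <- as.matrix(R)
  if (is.null(colnames(W)) || is.null(colnames(R)) ||
      !identical(colnames(W), colnames(R))) {
    stop("alignment error: extracted and reference signatures must share ",
         "an identical channel order", call. = FALSE)
  }
  sim <- matrix(0, nrow(W), nrow(R), dimnames = list(rownames(W), rownames(R)))
  for (i in seq_len(nrow(W))) {
    for (j in seq_len(nrow(R))) {
      sim[i, j] <- cosine_similarity(W[i, ], R[j, ])
    }
  }
  best <- max.col(sim, ties.method = "first")
  assignment <- data.frame(
    signature = rownames(W),
    reference = rownames(R)[best],
    cosine = sim[cbind(seq_len(nrow(W)), best)],
    stringsAsFactors = FALSE
  )
  list(assignment = assignment, similarity = sim)
}

#' Binarize per-sample signature presence
#'
#' A signature is called present in a sample when its relative activity
#' strictly exceeds `threshold` (default 25%: at most 3 signatures can be
#' present per sample). Activities are per-sample relative exposures, so the
#' call is scale-free.
#'
#' @param E An `nmf_fit` or a samples x k relative-activity matrix.
#' @param threshold Presence cut in `[0, 1)`; strict `>`.
#' @return Logical samples x k matrix.
#' @export
binarize_activity <- function(E, threshold = 0.25) {
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1) {
    stop("parameter error: threshold must lie in [0, 1)", call. = FALSE)
  }
  H_rel <- if (inherits(E, "nmf_fit")) E$H_rel else as.matrix(E)
  H_rel > threshold
}

#' Read / write a reference signature table
#'
#' TSV layout follows the public v2 probability files: one row per
#' trinucleotide channel (`channel` column, `"X[R>A]Y"` labels) and one
#' column per signature. Rows are reordered to the fixed channel order and
#' columns renormalized to sum to 1.
#'
#' @param path TSV path.
#' @return m x 96 matrix, signatures in rows, channels in columns.
#' @export
read_reference_signatures <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"channel" %in% names(tab)) {
    stop("reference file must have a 'channel' column", call. = FALSE)
  }
  channels <- sbs96_channels()
  if (!setequal(tab$channel, channels)) {
    stop("reference file must cover exactly the 96 channels", call. = FALSE)
  }
  rownames(tab) <- tab$channel
  mat <- t(as.matrix(tab[channels, setdiff(names(tab), "channel"),
                         drop = FALSE]))
  colnames(mat) <- channels
  mat / rowSums(mat)
}

#' @rdname read_reference_signatures
#' @param R Signatures x channels matrix.
#' @export
write_reference_signatures <- function(R, path) {
  out <- data.frame(channel = colnames(R), t(R), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
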