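# Self-contained survival and association statistics: Kaplan-Meier,
# log-rank, Cox proportional hazards (Efron ties, Newton-Raphson),
# Schoenfeld PH diagnostics, logistic regression, rank tests, Fisher exact,
# Benjamini-Hochberg. The survival package is used only as an independent
# cross-check oracle in the test suite, never here.

#' Kaplan-Meier product-limit estimator
#'
#' Greenwood variance with log(-log) 95% confidence bands; the median is the
#' smallest time with `S(t) <= 0.5` and its CI follows the
#' Brookmeyer-Crowley construction (smallest times at which the upper/lower
#' band crosses 0.5). With no censoring, `S(t)` equals the empirical
#' survival fraction exactly.
#'
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicators (1 = death observed).
#' @param conf_level Confidence level for the bands.
#' @return List of class `km_fit`: `table` (time, n_risk, n_event, surv,
#'   ci_low, ci_high), `median`, `median_ci` (NA = not reached).
#' @export
km_fit <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(time < 0)) stop("times must be non-negative", call. = FALSE)
  ord <- order(time)
  time <- time[ord]; event <- as.integer(event[ord])
  ut <- sort(unique(time[event == 1L]))
  n <- length(time)
  if (length(ut) == 0L) {
    return(structure(list(
      table = data.frame(time = numeric(0), n_risk = integer(0),
                         n_event = integer(0), surv = numeric(0),
                         ci_low = numeric(0), ci_high = numeric(0)),
      median = NA_real_, median_ci = c(NA_real_, NA_real_)),
      class = "km_fit"))
  }
  n_risk <- vapply(ut, function(t) sum(time >= t), integer(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1L), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood on the log(-log S) scale
  gw <- cumsum(n_event / (n_risk * (n_risk - n_event)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_low <- ci_high <- rep(NA_real_, length(ut))
  pos <- surv > 0 & surv < 1
  se_ll <- sqrt(gw[pos]) / abs(log(surv[pos]))
  ci_low[pos] <- surv[pos]^exp(z * se_ll)
  ci_high[pos] <- surv[pos]^exp(-z * se_ll)
  # log(-log) bands are undefined once S(t) hits 0 (reference convention: NA)
  median_at <- function(s) {
    i <- which(s <= 0.5)
    if (length(i)) ut[i[1]] else NA_real_
  }
  med <- median_at(surv)
  # lower band crosses 0.5 first (lower CI bound), upper band last
  med_ci <- c(median_at(ifelse(is.na(ci_low), 1, ci_low)),
              median_at(ifelse(is.na(ci_high), 1, ci_high)))
  structure(list(table = data.frame(time = ut, n_risk = n_risk,
                                    n_event = n_event, surv = surv,
                                    ci_low = ci_low, ci_high = ci_high),
                 median = med, median_ci = med_ci),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  med <- if (is.na(x$median)) "not reached" else format(x$median)
  cat("km_fit:", sum(x$table$n_event), "events; median =", med,
      sprintf("(95%% CI %s-%s)",
              ifelse(is.na(x$median_ci[1]), "NR", format(x$median_ci[1])),
              ifelse(is.na(x$median_ci[2]), "NR", format(x$median_ci[2]))),
      "\n")
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard O-E/V chi-square with 1 degree of freedom over the pooled event
#' times, hypergeometric variance.
#'
#' @param time,event Follow-up and status vectors over both groups.
#' @param group Two-level grouping vector.
#' @return List of class `test_result`: `statistic`, `p`, `method`,
#'   `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2L || any(table(g) == 0L)) {
    stop("logrank_test requires exactly two non-empty groups", call. = FALSE)
  }
  event <- as.integer(event)
  if (sum(event) == 0L) {
    stop("undefined test: no events observed", call. = FALSE)
  }
  ut <- sort(unique(time[event == 1L]))
  in1 <- g == levels(g)[1]
  O1 <- E1 <- V <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & in1)
    d <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & in1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1L) V <- V + d * (n - d) * n1 * (n - n1) / (n^2 * (n - 1))
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  structure(list(statistic = stat,
                 p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
                 effect = NA_real_, method = "logrank",
                 observed = O1, expected = E1, variance = V),
            class = "test_result")
}

# ---- Cox proportional hazards -------------------------------------------

# Efron partial log-likelihood, score and information at beta, plus the
# pieces needed for Schoenfeld residuals. X already complete-case and
# numeric. Vectorized over a descending time sort with cumulative sums.
cox_quantities <- function(beta, time, event, X) {
  n <- nrow(X); p <- ncol(X)
  ord <- order(time, decreasing = TRUE)
  t_s <- time[ord]; e_s <- event[ord]; X_s <- X[ord, , drop = FALSE]
  eta <- drop(X_s %*% beta)
  eta <- eta - max(eta)  # numeric guard; partial likelihood is shift-invariant
  w <- exp(eta)
  wX <- X_s * w
  cw <- cumsum(w)
  cwX <- apply(wX, 2L, cumsum)
  if (p == 1L) cwX <- matrix(cwX, ncol = 1L)
  # cumulative second moments, packed lower-triangular
  pair_idx <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  cwXX <- matrix(0, n, nrow(pair_idx))
  for (q in seq_len(nrow(pair_idx))) {
    cwXX[, q] <- cumsum(wX[, pair_idx[q, 1]] * X_s[, pair_idx[q, 2]])
  }
  unpack <- function(v) {
    M <- matrix(0, p, p)
    M[cbind(pair_idx[, 1], pair_idx[, 2])] <- v
    M[cbind(pair_idx[, 2], pair_idx[, 1])] <- v
    M
  }
  loglik <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  sch_resid <- NULL; sch_times <- NULL
  ev_times <- unique(t_s[e_s == 1L])
  for (t in ev_times) {
    pos <- max(which(t_s == t))        # all of 1..pos have time >= t
    D <- which(t_s == t & e_s == 1L)
    d <- length(D)
    s0r <- cw[pos]
    s1r <- cwX[pos, ]
    s2r <- unpack(cwXX[pos, ])
    s0d <- sum(w[D])
    s1d <- colSums(wX[D, , drop = FALSE])
    s2d <- crossprod(X_s[D, , drop = FALSE], wX[D, , drop = FALSE])
    s2d <- (s2d + t(s2d)) / 2
    xbar_breslow <- s1r / s0r
    for (l in seq_len(d) - 1L) {
      f <- l / d
      denom <- s0r - f * s0d
      m1 <- (s1r - f * s1d) / denom
      m2 <- (s2r - f * s2d) / denom
      loglik <- loglik - log(denom)
      U <- U - m1
      I <- I + m2 - tcrossprod(m1)
    }
    loglik <- loglik + sum(eta[D])
    U <- U + colSums(X_s[D, , drop = FALSE])
    # Schoenfeld residuals (risk-set mean at the event time)
    r <- sweep(X_s[D, , drop = FALSE], 2L, xbar_breslow)
    sch_resid <- rbind(sch_resid, r)
    sch_times <- c(sch_times, rep(t, d))
  }
  o <- order(sch_times)
  list(loglik = unname(loglik), U = unname(U), I = unname(I),
       sch_resid = sch_resid[o, , drop = FALSE], sch_times = sch_times[o])
}

# dummy-code a covariate data.frame against first-level references
build_design <- function(covariates) {
  covariates <- as.data.frame(covariates)
  for (j in seq_along(covariates)) {
    if (is.character(covariates[[j]]) || is.logical(covariates[[j]])) {
      covariates[[j]] <- factor(covariates[[j]])
    }
  }
  mm <- stats::model.matrix(~ ., data = covariates)
  mm[, -1, drop = FALSE]
}

#' Cox proportional-hazards regression (Efron ties)
#'
#' Newton-Raphson maximization of the Efron partial likelihood with
#' step-halving. Categorical covariates are dummy-coded against their first
#' level; rows with missing covariates, time or status are dropped
#' complete-case and counted. Monotone likelihoods (complete separation) are
#' flagged and the affected confidence bounds reported as unbounded.
#'
#' @param time,event Follow-up times and 0/1 status.
#' @param covariates data.frame (or named matrix) of covariates.
#' @param max_iter Newton-Raphson cap.
#' @param tol Convergence threshold on the coefficient step.
#' @return List of class `cox_fit`: `coefficients` data.frame (covariate,
#'   beta, se, hr, ci_low, ci_high, z, p), `loglik`, `loglik_null`,
#'   `score_test` (chi-square at beta = 0), `n_used`, `n_dropped_missing`,
#'   `n_events`, `converged`, `separation`, plus internals for diagnostics.
#' @export
coxph_fit <- function(time, event, covariates, max_iter = 25L, tol = 1e-9) {
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  ok <- stats::complete.cases(covariates) & !is.na(time) & !is.na(event)
  n_dropped <- sum(!ok)
  time <- time[ok]; event <- as.integer(event[ok])
  covariates <- covariates[ok, , drop = FALSE]
  X <- build_design(covariates)
  p <- ncol(X)
  if (nrow(X) < p + 1L) {
    stop("too few complete-case rows for the requested covariates",
         call. = FALSE)
  }
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance covariate: ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  if (sum(event) < 1L) stop("no events observed", call. = FALSE)

  beta <- numeric(p)
  q0 <- cox_quantities(beta, time, event, X)
  loglik_null <- q0$loglik
  score_test <- tryCatch(
    drop(t(q0$U) %*% solve(q0$I, q0$U)),
    error = function(e) NA_real_)
  q <- q0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(q$I, q$U), error = function(e) NULL)
    if (is.null(step)) break
    step_scale <- 1
    repeat {
      beta_new <- beta + step_scale * step
      q_new <- cox_quantities(beta_new, time, event, X)
      if (is.finite(q_new$loglik) && q_new$loglik >= q$loglik - 1e-12) break
      step_scale <- step_scale / 2
      if (step_scale < 1e-8) break
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new; q <- q_new
    if (moved < tol) { converged <- TRUE; break }
  }
  separation <- !converged && max(abs(beta)) > 10 ||
    any(abs(beta) > 15)
  var_beta <- tryCatch(solve(q$I), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(diag(var_beta), 0))
  z <- beta / se
  ci_low <- exp(beta - 1.959963984540054 * se)
  ci_high <- exp(beta + 1.959963984540054 * se)
  if (separation) { ci_low[] <- 0; ci_high[] <- Inf }
  coef_tab <- data.frame(
    covariate = colnames(X), beta = beta, se = se, hr = exp(beta),
    ci_low = ci_low, ci_high = ci_high, z = z,
    p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE
  )
  structure(list(coefficients = coef_tab, loglik = q$loglik,
                 loglik_null = loglik_null, score_test = score_test,
                 n_used = nrow(X), n_dropped_missing = n_dropped,
                 n_events = sum(event), converged = converged,
                 separation = separation, var = var_beta,
                 sch_resid = q$sch_resid, sch_times = q$sch_times,
                 design_names = colnames(X)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("cox_fit: n =", x$n_used, "(", x$n_dropped_missing,
      "dropped missing ),", x$n_events, "events\n")
  tab <- x$coefficients
  tab[, -1] <- lapply(tab[, -1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Schoenfeld proportional-hazards diagnostic
#'
#' Grambsch-Therneau score test: scaled Schoenfeld residuals are regressed
#' on the rank of the event times; a chi-square per covariate plus a global
#' test. Small p-values indicate a time-varying effect, i.e. a PH
#' violation.
#'
#' @param fit A `cox_fit`.
#' @return data.frame (covariate, chisq, df, p) with a final `GLOBAL` row.
#' @export
schoenfeld_check <- function(fit) {
  r <- fit$sch_resid
  d <- nrow(r)
  if (is.null(r) || d < 3L) {
    stop("undefined: Schoenfeld check needs at least 3 events",
         call. = FALSE)
  }
  p <- ncol(r)
  g <- rank(fit$sch_times, ties.method = "average")
  g <- g - mean(g)
  V <- fit$var                        # var(beta_hat) = I^{-1}
  r_scaled <- r %*% V * d
  u <- drop(g %*% r_scaled)           # per-covariate numerators
  chisq <- u^2 / (diag(V) * d * sum(g^2))
  u0 <- drop(g %*% r)
  global <- drop(t(u0) %*% V %*% u0) * d / sum(g^2)
  data.frame(
    covariate = c(fit$design_names, "GLOBAL"),
    chisq = c(chisq, global),
    df = c(rep(1L, p), p),
    p = c(stats::pchisq(chisq, 1L, lower.tail = FALSE),
          stats::pchisq(global, p, lower.tail = FALSE)),
    stringsAsFactors = FALSE
  )
}

#' Logistic regression by iteratively reweighted least squares
#'
#' @param outcome 0/1 outcome vector.
#' @param covariates data.frame of covariates (dummy-coded as in
#'   [coxph_fit()]); complete-case.
#' @return List of class `logistic_fit`: `coefficients` data.frame
#'   (covariate, beta, se, or, ci_low, ci_high, p; includes the intercept),
#'   `n_used`, `n_dropped_missing`, `converged`, `separation`.
#' @export
logistic_fit <- function(outcome, covariates, max_iter = 50L, tol = 1e-10) {
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  ok <- stats::complete.cases(covariates) & !is.na(outcome)
  y <- as.numeric(outcome[ok])
  covariates <- covariates[ok, , drop = FALSE]
  if (length(unique(y)) < 2L) {
    stop("degenerate outcome: both classes must be present", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, build_design(covariates))
  p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-12)
    XtW <- t(X * wt)
    step <- tryCatch(solve(XtW %*% X, t(X) %*% (y - mu)),
                     error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  separation <- !converged || max(abs(beta[-1])) > 15
  eta <- drop(X %*% beta)
  wt <- pmax(stats::plogis(eta) * (1 - stats::plogis(eta)), 1e-12)
  var_beta <- tryCatch(solve(t(X * wt) %*% X),
                       error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(var_beta), 0))
  z <- beta / se
  coef_tab <- data.frame(
    covariate = colnames(X), beta = beta, se = se, or = exp(beta),
    ci_low = exp(beta - 1.959963984540054 * se),
    ci_high = exp(beta + 1.959963984540054 * se),
    p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE
  )
  structure(list(coefficients = coef_tab, n_used = length(y),
                 n_dropped_missing = sum(!ok), converged = converged,
                 separation = separation),
            class = "logistic_fit")
}

# ---- rank tests ----------------------------------------------------------

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p by full enumeration of group assignments when the combined sample
#' size is at most `exact_max` and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction. Two-sided.
#'
#' @param x,y Numeric samples.
#' @param exact_max Combined-size threshold for the exact path.
#' @return `test_result` with `statistic` (Mann-Whitney U of `x`), `p`,
#'   `effect` (rank-biserial correlation), `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 20L) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1L, ny >= 1L)
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  effect <- 2 * U / (nx * ny) - 1  # rank-biserial
  has_ties <- anyDuplicated(all_v) > 0L
  if (!has_ties && nx + ny <= exact_max) {
    combos <- utils::combn(nx + ny, nx)
    r_all <- rank(all_v)
    u_all <- colSums(matrix(r_all[combos], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    method <- "wilcoxon_exact"
  } else {
    N <- nx + ny
    tie_tab <- table(all_v)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_corr)
    zval <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    if (sigma2 <= 0) zval <- 0
    p <- 2 * stats::pnorm(-abs(zval))
    method <- "wilcoxon_normal"
  }
  structure(list(statistic = U, p = min(p, 1), effect = effect,
                 method = method),
            class = "test_result")
}

#' Kruskal-Wallis H test
#'
#' Tie-corrected H with a chi-square approximation on k - 1 degrees of
#' freedom.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (>= 2 non-empty groups).
#' @return `test_result`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  N <- length(values)
  r <- rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  tie_tab <- table(values)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (corr > 0) H <- H / corr
  df <- nlevels(g) - 1L
  structure(list(statistic = H,
                 p = stats::pchisq(H, df, lower.tail = FALSE),
                 effect = NA_real_, method = "kruskal_wallis"),
            class = "test_result")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Hypergeometric enumeration with fixed margins; the two-sided p-value sums
#' the probabilities of all tables at most as probable as the observed one.
#' The effect is the sample odds ratio `(a d) / (b c)`.
#'
#' @param tab 2x2 integer matrix or a length-4 vector (a, b, c, d row-wise).
#' @return `test_result` with `effect` = odds ratio.
#' @export
fisher_exact <- function(tab) {
  tab <- matrix(as.numeric(tab), 2L, 2L, byrow = is.null(dim(tab)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("fisher_exact expects non-negative integer counts", call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row-1 margin
  k <- a + cc         # col-1 margin
  n_tot <- a + b + cc + d
  if (n_tot == 0) stop("empty table", call. = FALSE)
  lo <- max(0, k - (n_tot - m)); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n_tot - m, k)
  p_obs <- stats::dhyper(a, m, n_tot - m, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * cc == 0) {
    if (a * d == 0) 1 else Inf
  } else {
    (a * d) / (b * cc)
  }
  structure(list(statistic = a, p = min(p, 1), effect = or,
                 method = "fisher_exact", table = tab),
            class = "test_result")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Monotone q-values, never below the input p and capped at 1. NA p-values
#' propagate as NA and do not count toward the number of tests.
#'
#' @param p Vector of p-values.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(q)
  o <- order(p[ok])
  ranked <- p[ok][o] * m / seq_len(m)
  ranked <- rev(cummin(rev(ranked)))
  q[ok[o]] <- pmin(ranked, 1)
  q
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic =", format(x$statistic, digits = 5),
      "p =", format(x$p, digits = 4),
      if (!is.na(x$effect)) paste("effect =", format(x$effect, digits = 4)),
      "\n")
  invisible(x)
}
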