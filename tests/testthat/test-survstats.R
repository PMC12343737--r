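test_that("km_fit matches the hand product-limit computation", {
  f <- km_fit(1:5, rep(1, 5))
  expect_equal(f$table$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(f$median, 3)

  f1 <- km_fit(2, 1)
  expect_equal(f1$table$surv, 0)
  expect_equal(f1$median, 2)

  f2 <- km_fit(c(3, 5, 8), c(0, 0, 0))
  expect_true(is.na(f2$median))  # all censored: median not reached

  # no censoring: S(t) equals the empirical survival fraction exactly
  set.seed(4)
  tm <- sort(rexp(40, 0.2))
  f3 <- km_fit(tm, rep(1, 40))
  expect_equal(f3$table$surv,
               vapply(f3$table$time, function(t) mean(tm > t), numeric(1)))
})

test_that("km_fit agrees with the survival package (log-log CIs, median CI)", {
  set.seed(12)
  tm <- round(rexp(60, 0.1), 1) + 0.1
  ev <- rbinom(60, 1, 0.7)
  f <- km_fit(tm, ev)
  sf <- survival::survfit(survival::Surv(tm, ev) ~ 1, conf.type = "log-log")
  s <- summary(sf, times = f$table$time)
  expect_equal(f$table$surv, s$surv, tolerance = 1e-12)
  expect_equal(f$table$ci_low, s$lower, tolerance = 1e-10)
  expect_equal(f$table$ci_high, s$upper, tolerance = 1e-10)
  med <- unname(summary(sf)$table[c("median", "0.95LCL", "0.95UCL")])
  expect_equal(f$median, med[1])
  expect_equal(unname(f$median_ci), med[2:3])
})

test_that("logrank_test: symmetry, oracle tabulation, degenerate input", {
  tm <- c(1, 3, 5, 7, 9, 11); ev <- c(1, 1, 0, 1, 1, 0)
  same <- logrank_test(c(tm, tm), c(ev, ev), rep(c("a", "b"), each = 6))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # textbook-style fixture against the independent O-E/V oracle
  time <- c(6, 6, 6, 7, 10, 13, 16, 22, 23, 6, 9, 10, 11, 17, 19, 20, 25, 32)
  event <- c(1, 1, 1, 1, 0, 1, 1, 1, 1, 1, 1, 0, 1, 0, 1, 1, 1, 0)
  group <- rep(c("t", "c"), c(9, 9))
  r <- logrank_test(time, event, group)
  expect_equal(r$statistic, brute_logrank(time, event, group),
               tolerance = 1e-12)
  sd_or <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(r$statistic, sd_or$chisq, tolerance = 1e-10)

  expect_error(logrank_test(tm, ev, rep("a", 6)), "two non-empty")
  expect_error(logrank_test(tm, rep(0, 6), rep(c("a", "b"), 3)),
               "no events")
})

test_that("coxph_fit matches the brute-force partial-likelihood oracle", {
  fx <- cox_fixture_n12()
  fit <- coxph_fit(fx$time, fx$event, data.frame(x = fx$x))
  # golden-section maximization of the independently coded Efron likelihood
  beta_star <- optimize(function(b) brute_cox_loglik(b, fx$time, fx$event,
                                                     fx$x),
                        c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(fit$coefficients$beta, beta_star, tolerance = 1e-4)
  # and the reference implementation agrees to high precision
  of <- survival::coxph(survival::Surv(fx$time, fx$event) ~ fx$x,
                        ties = "efron")
  expect_equal(fit$coefficients$beta, unname(coef(of)), tolerance = 1e-8)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(of)))), tolerance = 1e-8)
  expect_equal(fit$loglik, of$loglik[2], tolerance = 1e-8)
})

test_that("coxph_fit handles covariates, missing rows and ties like the
           reference implementation", {
  set.seed(71)
  n <- 90
  x <- rbinom(n, 1, 0.4); z <- rnorm(n)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  tm <- round(rexp(n, 0.1 * exp(0.6 * x - 0.2 * z)), 0) + 1  # many ties
  ev <- rbinom(n, 1, 0.8)
  z[c(3, 7)] <- NA  # complete-case handling
  fit <- coxph_fit(tm, ev, data.frame(x = x, z = z, sex = sex))
  expect_equal(fit$n_dropped_missing, 2L)
  of <- survival::coxph(survival::Surv(tm, ev) ~ x + z + sex,
                        ties = "efron")
  expect_equal(fit$coefficients$beta, unname(coef(of)), tolerance = 1e-7)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(of)))),
               tolerance = 1e-7)
  expect_true(all(fit$coefficients$ci_low < fit$coefficients$hr &
                    fit$coefficients$hr < fit$coefficients$ci_high))
  expect_error(coxph_fit(tm, ev, data.frame(c = rep(1, n))),
               "zero-variance")
})

test_that("score test at beta = 0 equals the log-rank statistic", {
  set.seed(23)
  n <- 50
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 0.1 * exp(0.4 * x))  # continuous: no ties
  ev <- rbinom(n, 1, 0.9)
  fit <- coxph_fit(tm, ev, data.frame(x = x))
  lr <- logrank_test(tm, ev, x)
  expect_equal(fit$score_test, lr$statistic, tolerance = 1e-8)
})

test_that("coxph_fit is unbiased at beta = 0 (coverage simulation)", {
  set.seed(55)
  inside <- replicate(100, {
    n <- 500
    x <- rbinom(n, 1, 0.5)
    tm <- rexp(n, 0.08); cs <- runif(n, 0, 30)
    fit <- coxph_fit(pmin(tm, cs), as.integer(tm <= cs), data.frame(x = x))
    abs(fit$coefficients$beta) < 2 * fit$coefficients$se
  })
  expect_gte(sum(inside), 93)
})

test_that("separation is flagged with unbounded CIs", {
  tm <- c(1, 2, 3, 4, 10, 11, 12, 13)
  ev <- rep(1, 8)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)  # all early deaths are mutants
  fit <- suppressWarnings(coxph_fit(tm, ev, data.frame(x = x)))
  expect_true(fit$separation)
  expect_equal(fit$coefficients$ci_low, 0)
  expect_equal(fit$coefficients$ci_high, Inf)
})

test_that("schoenfeld_check needs >= 3 events and flags PH violations", {
  fx <- cox_fixture_n12()
  one_event <- coxph_fit(fx$time, c(1, rep(0, 11)), data.frame(x = fx$x))
  expect_error(schoenfeld_check(one_event), "3 events")

  # strong sign-flipping effect is detected most of the time
  set.seed(10)
  hits <- replicate(40, {
    n <- 150
    x <- rbinom(n, 1, 0.5)
    t1 <- rexp(n, 0.08 * exp(1.0 * x))
    tm <- ifelse(t1 <= 8, t1, 8 + rexp(n, 0.08 * exp(-1.0 * x)))
    cs <- runif(n, 10, 60)
    fit <- coxph_fit(pmin(tm, cs), as.integer(tm <= cs), data.frame(x = x))
    schoenfeld_check(fit)$p[1] < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("logistic_fit matches glm and respects symmetry", {
  set.seed(31)
  n <- 120
  x <- rbinom(n, 1, 0.5); z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 0.9 * x + 0.3 * z))
  lf <- logistic_fit(y, data.frame(x = x, z = z))
  og <- glm(y ~ x + z, family = binomial)
  expect_equal(lf$coefficients$beta, unname(coef(og)), tolerance = 1e-8)
  expect_equal(lf$coefficients$se,
               unname(sqrt(diag(vcov(og)))), tolerance = 1e-6)

  # perfectly balanced 2x2: beta exactly 0
  y2 <- c(0, 1, 0, 1); x2 <- c(0, 0, 1, 1)
  lf2 <- logistic_fit(y2, data.frame(x = x2))
  expect_equal(lf2$coefficients$beta[2], 0, tolerance = 1e-12)

  # OR direction agrees with the Fisher conditional odds ratio
  y3 <- rep(c(1, 0, 1, 0), c(8, 2, 3, 7))
  x3 <- rep(c(1, 1, 0, 0), c(8, 2, 3, 7))
  lf3 <- logistic_fit(y3, data.frame(x = x3))
  fe <- fisher_exact(matrix(c(8, 2, 3, 7), 2, byrow = TRUE))
  expect_equal(lf3$coefficients$or[2] > 1, fe$effect > 1)

  expect_error(logistic_fit(rep(1, 10), data.frame(x = rnorm(10))),
               "degenerate")
})

test_that("wilcoxon_rank_sum: exact enumeration and normal approximation", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)          # 2/20 by full enumeration
  expect_equal(r$method, "wilcoxon_exact")
  expect_equal(r$effect, -1)      # complete separation, x below y

  same <- wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p, 1)         # statistic at the null center

  set.seed(44)
  x <- rnorm(40); y <- rnorm(40, 0.4)
  mine <- wilcoxon_rank_sum(x, y)
  base_r <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$p, base_r$p.value, tolerance = 1e-10)
  expect_equal(mine$method, "wilcoxon_normal")
})

test_that("kruskal_wallis matches base R and is ~0 for identical groups", {
  same <- kruskal_wallis(rep(c(1, 2, 3), 3), rep(1:3, each = 3))
  expect_lt(same$statistic, 1e-10)

  set.seed(5)
  v <- rnorm(60) + rep(1:3, each = 20) / 3
  g <- rep(1:3, each = 20)
  expect_equal(kruskal_wallis(v, g)$p, kruskal.test(v, g)$p.value,
               tolerance = 1e-12)
})

test_that("fisher_exact enumerates the hypergeometric tail", {
  r <- fisher_exact(matrix(c(3, 0, 0, 3), 2, byrow = TRUE))
  expect_equal(r$p, 0.1)         # P(3) + P(0) = 1/20 + 1/20
  expect_equal(r$effect, Inf)

  flat <- fisher_exact(matrix(c(2, 2, 2, 2), 2))
  expect_equal(flat$p, 1)
  expect_equal(flat$effect, 1)

  set.seed(61)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact(tab)$p, fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(fisher_exact(matrix(c(-1, 0, 0, 1), 2)), "non-negative")
})

test_that("bh_adjust is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  for (i in 1:10) {
    p <- runif(25)^2
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12 & q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))  # monotone in sorted order
  }
  expect_equal(bh_adjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
})
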