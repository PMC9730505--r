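test_that("AFT fitting recovers the exponential special case", {
  # uncensored exponential data is Weibull with sigma = 1
  withr::with_seed(71, {
    time <- rexp(3000, rate = 0.2)
  })
  fit <- fit_aft(time, rep(1L, 3000), distribution = "weibull")
  expect_lt(abs(fit$sigma - 1), 0.05)
  expect_true(fit$converged)
  # AIC identity
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)

  expect_error(fit_aft(time, rep(0L, 3000)), "at least one event")
})

test_that("hazard-ratio conversion follows the Weibull closed form", {
  withr::with_seed(72, {
    n <- 1500
    x <- rbinom(n, 1, 0.4)
    X <- cbind(core = x)
    d <- simulate_survival(X, c(core = -0.4), mu = 2, sigma = 0.7,
                           admin_censor_time = 20,
                           random_censor_rate = 0.02, seed = 8)
  })
  fit <- fit_aft(d$time, d$event, X, "weibull")
  hr <- aft_to_hr(fit, "core")
  beta <- fit$coefficients["core", "estimate"]
  expect_equal(hr$hr, exp(-beta / fit$sigma))
  expect_true(hr$ci95[1] <= hr$hr && hr$hr <= hr$ci95[2])
  expect_gt(hr$hr, 1)  # harmful exposure

  lfit <- fit_aft(d$time, d$event, X, "lognormal")
  expect_error(aft_to_hr(lfit, "core"), "Weibull")
  expect_error(aft_to_hr(fit, "nope"), "no coefficient")
})

test_that("confidence intervals achieve nominal coverage under the null", {
  n <- 400
  hits <- 0L
  reps <- 100
  for (r in seq_len(reps)) {
    withr::with_seed(9000 + r, {
      x <- rnorm(n)
    })
    X <- cbind(x = x)
    d <- simulate_survival(X, c(x = 0), mu = 1.5, sigma = 0.8,
                           admin_censor_time = 20, seed = 9000 + r)
    fit <- fit_aft(d$time, d$event, X, "weibull")
    est <- fit$coefficients["x", ]
    lo <- est["estimate"] - qnorm(0.975) * est["se"]
    hi <- est["estimate"] + qnorm(0.975) * est["se"]
    if (lo <= 0 && 0 <= hi) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.89)
})

test_that("the PH diagnostic behaves under proportional and crossing hazards", {
  # under PH (Weibull AFT is PH in the binary covariate)
  ps <- vapply(1:40, function(r) {
    withr::with_seed(500 + r, {
      n <- 300
      x <- rbinom(n, 1, 0.5)
    })
    X <- cbind(x = x)
    d <- simulate_survival(X, c(x = -0.4), mu = 1, sigma = 0.8,
                           admin_censor_time = 30, seed = 500 + r)
    ph_test(d$time, d$event, X, "x")
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.175)

  # crossing hazards: effect reverses over time
  withr::with_seed(99, {
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    t1 <- rexp(n, rate = ifelse(x == 1, 3.0, 1.0))
    flip <- t1 > 0.6
    time <- ifelse(flip, 0.6 + rexp(n, rate = ifelse(x == 1, 0.3, 1.0)), t1)
  })
  p_cross <- ph_test(time, rep(1L, n), cbind(x = x), "x")
  expect_lt(p_cross, 0.01)

  expect_warning(p_const <- ph_test(time, rep(1L, n),
                                    cbind(x = rep(1, n)), "x"), "constant")
  expect_true(is.na(p_const))
})

test_that("AIC comparison identifies the generating family", {
  wins <- 0L
  for (r in 1:10) {
    withr::with_seed(600 + r, {
      n <- 1500
      x <- rbinom(n, 1, 0.4)
    })
    X <- cbind(x = x)
    d <- simulate_survival(X, c(x = -0.4), mu = 1.2, sigma = 0.7,
                           admin_censor_time = 25, seed = 600 + r)
    tab <- aic_compare(d$time, d$event, X)
    aft <- tab[tab$model %in% c("weibull", "lognormal", "loglogistic",
                                "exponential"), ]
    if (aft$model[which.min(aft$aic)] == "weibull") wins <- wins + 1L
  }
  expect_gte(wins, 7L)

  # exponential data: exponential within 2 AIC of Weibull (nested)
  withr::with_seed(611, {
    time <- rexp(2000, 0.3)
  })
  tab <- aic_compare(time, rep(1L, 2000), cbind(x = rnorm(2000)))
  a <- setNames(tab$aic, tab$model)
  expect_lt(abs(a["exponential"] - a["weibull"]), 2.1)
})

test_that("BH adjustment equals the independent step-up oracle", {
  # independent step-up implementation
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in m:1) {
      prev <- min(prev, p[o[i]] * m / i)
      q[o[i]] <- prev
    }
    q
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  for (r in 1:25) {
    p <- withr::with_seed(700 + r, runif(sample(2:12, 1)))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("screening recovers planted signal and respects the support filter", {
  mat <- synthetic_tcemm_matrix(800, 60, seed = 81)
  planted <- setNames(c(-0.6), mat$tcemm_ids[which.max(mat$support)])
  cohort <- synthetic_cohort_for(mat, seed = 82, planted = planted)
  scr <- screen_tcemm(cohort, mat, min_support = 100, compute_ph = FALSE)
  expect_s3_class(scr, "screen_result")
  expect_equal(scr$included, scr$support >= 100)
  expect_true(all(is.na(scr$hr[!scr$included])))
  row <- scr[scr$tcemm == names(planted), ]
  expect_gt(row$hr, 1)
  expect_lt(row$q, 0.05)
  expect_true(all(scr$q >= scr$p, na.rm = TRUE))
  expect_true(all(scr$ci_lo <= scr$hr & scr$hr <= scr$ci_hi, na.rm = TRUE))

  # raising min_support never adds an included TcEMM
  scr2 <- screen_tcemm(cohort, mat, min_support = 200, compute_ph = FALSE)
  expect_true(all(which(scr2$included) %in% which(scr$included)))

  bad <- cohort
  bad$pair_id <- rev(bad$pair_id)
  expect_error(screen_tcemm(bad, mat), "align")
})

test_that("mismatch-load association uses log(score + 1) exposure", {
  mat <- synthetic_tcemm_matrix(600, 40, seed = 91)
  cohort <- synthetic_cohort_for(mat, seed = 92)
  scores <- as.integer(Matrix::rowSums(mat$incidence))
  expect_error(score_association(cohort, scores - 100), "nonnegative")
  res <- score_association(cohort, scores)
  for (m in res) {
    expect_true(m$ci95[1] <= m$hr && m$hr <= m$ci95[2])
    expect_gt(m$hr, 0)
  }
  # zero scores map to exposure zero: a pair with score 0 contributes
  # baseline risk; shifting all scores by a common factor through the log
  # leaves inference on the transformed scale intact
  expect_equal(log(0 + 1), 0)
})

test_that("frequency comparison reports group medians and ranges", {
  mat <- synthetic_tcemm_matrix(500, 50, seed = 95)
  planted <- setNames(rep(-0.8, 2),
                      mat$tcemm_ids[order(-mat$support)][1:2])
  cohort <- synthetic_cohort_for(mat, seed = 96, planted = planted)
  scr <- screen_tcemm(cohort, mat, min_support = 50, compute_ph = FALSE)
  fc <- frequency_compare(scr, alpha = 0.05)
  scr_ok <- scr[scr$included & !is.na(scr$q), ]
  # sort-oracle check of the medians
  med_oracle <- function(v) {
    s <- sort(v); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  if (!is.null(fc$not_significant)) {
    grp <- scr_ok$frequency[scr_ok$q >= 0.05]
    expect_equal(fc$not_significant$median, med_oracle(grp))
    expect_equal(fc$not_significant$range, c(min(grp), max(grp)))
  }
  all_sig <- scr_ok
  all_sig$q <- 0
  fc2 <- frequency_compare(all_sig, alpha = 0.05)
  expect_null(fc2$not_significant)
  expect_equal(fc2$significant$n, nrow(scr_ok))
})
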