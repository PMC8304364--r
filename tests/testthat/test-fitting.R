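# construct a minimal fit object by hand for closed-form interval checks
fake_fit <- function(beta_hat, se, q = ppd_reference_intensity()) {
  lb <- log(rates_of(q))
  beta <- beta_single("z", "1->3", beta_hat)
  model <- covariate_model(lb, beta, centers = c(z = 0))
  mask <- matrix(FALSE, 6, 1); mask[2, 1] <- TRUE
  map <- ppdmarkov:::par_map_for(model, mask)
  par <- ppdmarkov:::pack_model(model, map)
  vcov <- diag(c(rep(1e-4, 6), se^2))
  dimnames(vcov) <- list(map$names, map$names)
  structure(list(model = model, loglik = 0, vcov = vcov, par = par,
                 par_map = map, converged = TRUE, grad_norm = 0,
                 n_subjects = 0L, n_pairs = 0L, covariates = "z"),
            class = "ppd_fit")
}

test_that("single-free-rate profile matches a 1-D grid-search oracle", {
  cohort <- simulate_reference_cohort(n = 300, seed = 5)
  truth <- rates_of(ppd_reference_intensity())
  fit <- fit_mle(cohort$panel, fixed_rates = truth[-1], n_starts = 1)
  expect_true(fit$converged)
  q12_hat <- exp(fit$model$log_baseline[["1->2"]])

  # oracle: golden-section search over the single free rate
  model0 <- covariate_model(log(truth))
  prof <- function(q12) {
    lb <- log(truth); lb[1] <- log(q12)
    panel_loglik(covariate_model(lb), cohort$panel)$value
  }
  opt <- optimize(prof, c(1e-5, 0.2), maximum = TRUE, tol = 1e-10)
  expect_equal(q12_hat, opt$maximum, tolerance = 1e-4)
})

test_that("homogeneous rates are recovered from a large simulated cohort", {
  cohort <- simulate_reference_cohort(n = 5000, seed = 31)
  fit <- fit_mle(cohort$panel)
  expect_true(fit$converged)
  expect_true(!is.null(fit$vcov))
  truth <- rates_of(ppd_reference_intensity())
  rel <- abs(exp(fit$model$log_baseline) - truth) / truth
  # the direct severe->normal rate is barely identified by three visits at
  # 6/13/26 weeks (direct 3->1 jumps are indistinguishable from 3->2->1
  # paths at this spacing); assert tight recovery for the other five rates
  # and Wald-band consistency for all six
  expect_true(all(rel[names(truth) != "3->1"] < 0.15))
  se <- sqrt(diag(fit$vcov)[1:6])
  z <- abs(fit$model$log_baseline - log(truth)) / se
  expect_true(all(z < 3))
})

test_that("transitions without direct support can be disallowed", {
  df <- data.frame(
    subject = rep(c("a", "b", "c", "d"), each = 2),
    time = rep(c(6, 13), 4),
    state = c(1, 2, 2, 1, 1, 1, 2, 2)
  )
  pd <- panel_data(df)
  fit <- suppressWarnings(
    fit_mle(pd, allowed_transitions = c("1->2", "2->1"), n_starts = 1)
  )
  expect_true(fit$converged)
  q <- unclass(baseline_intensity(fit))
  expect_equal(q[1, 3], 0)
  expect_equal(q[3, ], rep(0, 3), ignore_attr = TRUE)
  expect_equal(sum(fit$par_map$allowed), 2L)
})

test_that("hazard_ratio_report applies the Wald closed form", {
  hr0 <- hazard_ratio_report(fake_fit(0, 0.1))
  expect_equal(hr0$hr, 1)
  expect_equal(hr0$lower, exp(-qnorm(0.975) * 0.1), tolerance = 1e-12)
  expect_equal(round(c(hr0$lower, hr0$upper), 2), c(0.82, 1.22))

  # SE -> 0 collapses the interval onto the point estimate
  hr1 <- hazard_ratio_report(fake_fit(log(2), 0))
  expect_equal(c(hr1$hr, hr1$lower, hr1$upper), rep(2, 3), tolerance = 1e-12)

  # rows filterable to CI excluding 1
  hr2 <- hazard_ratio_report(fake_fit(log(0.5), 0.05), significant_only = TRUE)
  expect_equal(nrow(hr2), 1L)
  hr3 <- hazard_ratio_report(fake_fit(0, 10), significant_only = TRUE)
  expect_equal(nrow(hr3), 0L)

  bad <- fake_fit(0, 0.1); bad$vcov <- NULL
  expect_error(hazard_ratio_report(bad), "covariance")
})

test_that("fitted_summary_table delegates to the generator algebra", {
  q_eq <- intensity_matrix(matrix(0.1, 3, 3) - diag(3) * 0.3)
  fit <- fake_fit(0, 0.1, q = q_eq)
  summ <- fitted_summary_table(fit)
  off <- unclass(summ$jump)[!is.na(unclass(summ$jump))]
  expect_equal(off, rep(0.5, 6), ignore_attr = TRUE)
  expect_equal(as.numeric(summ$sojourn), rep(5, 3))

  # purity: identical tables on repeated calls
  expect_identical(fitted_summary_table(fit), summ)
})

test_that("interval_probability_table points and degenerate CIs behave", {
  q <- ppd_reference_intensity()
  # horizon -> 0: off-diagonal mass vanishes
  tab0 <- interval_probability_table(q, horizons = 1e-9, ci = "none")
  expect_true(all(tab0$estimate < 1e-9))

  # printed 9-month severe -> normal cell
  tab <- interval_probability_table(q, horizons = "9m", ci = "none")
  cell <- tab$estimate[tab$transition == "3->1"]
  expect_equal(cell, 0.769, tolerance = 0.01)

  # zero covariance: bootstrap interval width collapses to zero
  fit <- fake_fit(0, 0)
  fit$vcov[] <- 0
  tabz <- interval_probability_table(fit, horizons = c("3m", "1y"), B = 50)
  expect_equal(tabz$lower, tabz$estimate, tolerance = 1e-12)
  expect_equal(tabz$upper, tabz$estimate, tolerance = 1e-12)

  # delta and bootstrap agree to first order for a real fit
  cohort <- simulate_reference_cohort(n = 500, seed = 13)
  rfit <- fit_mle(cohort$panel, n_starts = 1)
  tb <- interval_probability_table(rfit, horizons = "3m", B = 400, seed = 2)
  td <- interval_probability_table(rfit, horizons = "3m", ci = "delta")
  expect_equal(tb$estimate, td$estimate, tolerance = 1e-12)
  expect_lt(max(abs(tb$lower - td$lower)), 0.08)
  expect_lt(max(abs(tb$upper - td$upper)), 0.08)

  # bootstrap is reproducible under a fixed seed
  tb2 <- interval_probability_table(rfit, horizons = "3m", B = 400, seed = 2)
  expect_identical(tb, tb2)
})

test_that("horizon tokens convert at 52/12 weeks per month", {
  wk <- parse_horizons(c("1m", "3m", "1y", "2y", "10w"))
  expect_equal(unname(wk), c(52 / 12, 13, 52, 104, 10))
  expect_equal(unname(parse_horizons(c(7, 13))), c(7, 13))
  expect_error(parse_horizons("3 months"), "parse")
})

test_that("fits are invariant to affine covariate rescaling", {
  beta <- beta_single("emotional", "1->3", log(0.6))
  truth <- covariate_model(log(rates_of(ppd_reference_intensity())), beta,
                           centers = c(emotional = 10.2))
  cohort <- simulate_reference_cohort(n = 400, seed = 17, model = truth)
  df <- as.data.frame(cohort$panel)
  df$rescaled <- 2 * df$emotional + 5

  f1 <- fit_mle(panel_data(df), covariates = "emotional",
                on_transitions = "1->3", n_starts = 1)
  f2 <- fit_mle(panel_data(df), covariates = "rescaled",
                on_transitions = "1->3", n_starts = 1)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
  b1 <- f1$model$beta["1->3", "emotional"]
  b2 <- f2$model$beta["1->3", "rescaled"]
  expect_equal(b1, 2 * b2, tolerance = 1e-3)
})
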