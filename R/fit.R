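WEEKS_PER_MONTH <- 52 / 12

#' Maximum-likelihood fit of the panel-observed three-state model
#'
#' Maximizes the panel log-likelihood over the six log baseline intensities
#' and (optionally) per-transition log hazard ratios, by quasi-Newton (BFGS)
#' search with a numerically differenced gradient and multiple jittered
#' starts. Initial rates are crude occurrence/exposure estimates from the
#' observed counts, floored at `1e-4` per week. The parameter covariance is
#' the inverse of the numerically differenced observed information at the
#' optimum.
#'
#' @param data A [panel_data()] object.
#' @param covariates Character vector of covariate column names to model
#'   (default none: homogeneous model).
#' @param on_transitions Transitions carrying covariate effects, as labels
#'   among `"1->2","1->3","2->1","2->3","3->1","3->2"`; default all six.
#' @param allowed_transitions Transitions with free rates; transitions left
#'   out are pinned at rate zero (e.g. to disallow direct moves).
#' @param fixed_rates Optional named vector of rates (per week) to hold
#'   fixed during optimization, named by transition label; useful for
#'   profile checks and submodels.
#' @param n_starts Number of optimizer starts (first from the crude
#'   estimate, the rest jittered).
#' @param jitter_sd Standard deviation of the Gaussian jitter on the start.
#' @param seed Seed for the jitter (local to the fit; the global RNG state
#'   is restored).
#' @param control Passed to [stats::optim()] (method BFGS).
#' @return A `ppd_fit` object: the estimated [covariate_model()], maximized
#'   log-likelihood, parameter covariance, convergence flag, gradient norm,
#'   counts and optimizer trace.
#' @export
fit_mle <- function(data, covariates = character(),
                    on_transitions = TRANSITION_LABELS,
                    allowed_transitions = TRANSITION_LABELS,
                    fixed_rates = NULL,
                    n_starts = 3L, jitter_sd = 0.2, seed = 1L,
                    control = list(maxit = 500, reltol = 1e-10)) {
  stopifnot(inherits(data, "panel_data"))
  pairs <- transition_pairs(data)
  if (nrow(pairs) == 0L) ppd_stop("no observed transitions to fit")
  bad_tr <- setdiff(c(on_transitions, allowed_transitions), TRANSITION_LABELS)
  if (length(bad_tr)) {
    ppd_stop(sprintf("unknown transition label(s): %s",
                     paste(bad_tr, collapse = ", ")))
  }
  allowed <- TRANSITION_LABELS %in% allowed_transitions

  # crude occurrence/exposure start: n_ij / (n_i. * mean dt), floored
  n_ij <- unclass(observed_transition_table(data))
  n_i <- rowSums(n_ij)
  mean_dt <- mean(pairs$dt)
  q0 <- pmax(n_ij / pmax(n_i, 1) / mean_dt, 1e-4)
  rates0 <- q0[cbind(TRANSITION_FROM, TRANSITION_TO)]
  support <- n_ij[cbind(TRANSITION_FROM, TRANSITION_TO)] > 0
  if (any(allowed & !support)) {
    warning(sprintf("transition(s) %s have no observed direct support",
                    paste(TRANSITION_LABELS[allowed & !support],
                          collapse = ", ")), call. = FALSE)
  }
  lb0 <- log(rates0)
  lb0[!allowed] <- -Inf
  if (!is.null(fixed_rates)) {
    bad <- setdiff(names(fixed_rates), TRANSITION_LABELS)
    if (length(bad)) {
      ppd_stop(sprintf("unknown transition label(s) in fixed_rates: %s",
                       paste(bad, collapse = ", ")))
    }
    pin <- match(names(fixed_rates), TRANSITION_LABELS)
    lb0[pin] <- log(fixed_rates)
    allowed[pin] <- FALSE
  }

  p <- length(covariates)
  beta0 <- NULL
  centers <- NULL
  if (p > 0) {
    miss <- setdiff(covariates, names(data))
    if (length(miss)) {
      ppd_stop(sprintf("covariate column(s) not found in data: %s",
                       paste(miss, collapse = ", ")))
    }
    first_row <- match(unique(data$subject), data$subject)
    centers <- colMeans(as.data.frame(data)[first_row, covariates,
                                            drop = FALSE])
    beta0 <- matrix(0, 6, p, dimnames = list(TRANSITION_LABELS, covariates))
  }
  template <- covariate_model(lb0, beta0, centers)
  beta_mask <- if (p > 0) {
    matrix(TRANSITION_LABELS %in% on_transitions, 6, p)
  } else {
    matrix(logical(0), 6, 0)
  }
  map <- par_map_for(template, beta_mask, allowed)
  inp <- loglik_inputs(template, data, aggregate = (p == 0))

  negll <- function(par) {
    m <- unpack_model(par, template, map)
    ll <- sum(.panel_loglik_terms_cpp(m$log_baseline, m$beta, inp$X, inp$grp,
                                      inp$from, inp$to, inp$dt, inp$wt))
    if (!is.finite(ll)) 1e10 else -ll
  }
  grad_negll <- function(par) -central_diff(function(x) -negll(x), par)

  par0 <- pack_model(template, map)
  starts <- list(par0)
  if (n_starts > 1) {
    old_seed <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()), add = TRUE)
    set.seed(seed)
    for (s in seq_len(n_starts - 1L)) {
      starts[[s + 1L]] <- par0 + rnorm(length(par0), sd = jitter_sd)
    }
  }
  trace <- lapply(starts, function(st) {
    tryCatch(
      optim(st, negll, gr = grad_negll, method = "BFGS", control = control),
      error = function(e) list(value = Inf, convergence = 99L,
                               message = conditionMessage(e))
    )
  })
  best <- trace[[which.min(vapply(trace, `[[`, numeric(1), "value"))]]
  if (!is.finite(best$value)) {
    ppd_stop("all optimizer starts failed", class = "ppd_fit_error")
  }
  par_hat <- setNames(best$par, map$names)
  model_hat <- unpack_model(par_hat, template, map)
  grad <- -grad_negll(par_hat)
  grad_norm <- max(abs(grad))
  value <- -best$value

  hess <- tryCatch(optimHess(par_hat, negll, gr = grad_negll),
                   error = function(e) NULL)
  vcov <- NULL
  if (!is.null(hess)) {
    vcov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vcov)) {
      ev <- eigen(vcov, symmetric = TRUE, only.values = TRUE)$values
      if (any(ev < -1e-8 * max(abs(ev)))) vcov <- NULL
      else dimnames(vcov) <- list(map$names, map$names)
    }
  }
  converged <- best$convergence == 0 &&
    grad_norm < 1e-4 * max(1, abs(value)) * 10

  structure(list(
    model = model_hat, loglik = value, vcov = vcov, par = par_hat,
    par_map = map, converged = converged, grad_norm = grad_norm,
    n_subjects = length(unique(data$subject)), n_pairs = nrow(pairs),
    counts = observed_transition_table(data), covariates = covariates,
    n_iter = if (!is.null(best$counts)) unname(best$counts[1]) else NA_integer_,
    optim_trace = lapply(trace, function(tr)
      list(value = -tr$value, convergence = tr$convergence)),
    seed = seed
  ), class = "ppd_fit")
}

#' @export
print.ppd_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Three-state panel Markov fit: %d subjects, %d transitions\n",
    x$n_subjects, x$n_pairs))
  cat(sprintf("log-likelihood %.3f; converged: %s (max |grad| %.2e)\n",
              x$loglik, x$converged, x$grad_norm))
  print(x$model, digits = digits)
  if (is.null(x$vcov)) cat("(parameter covariance unavailable)\n")
  invisible(x)
}

#' Fitted baseline intensity matrix
#'
#' @param fit A `ppd_fit`.
#' @return The baseline [intensity_matrix()] (at covariate reference values).
#' @export
baseline_intensity <- function(fit) {
  stopifnot(inherits(fit, "ppd_fit"))
  intensity_from_rates(exp(fit$model$log_baseline))
}

#' Jump probabilities and sojourn times of a fitted model
#'
#' Summarizes the fitted baseline generator as the embedded jump-chain
#' probabilities ("probability of the next transition, if and when one
#' occurs") and the per-state mean sojourn times in weeks.
#'
#' @param fit A `ppd_fit`.
#' @return A `ppd_summary` list with elements `jump` and `sojourn`.
#' @export
fitted_summary_table <- function(fit) {
  stopifnot(inherits(fit, "ppd_fit"))
  if (!fit$converged) {
    warning("summarizing a fit that did not converge", call. = FALSE)
  }
  q <- baseline_intensity(fit)
  structure(list(jump = jump_chain_probabilities(q),
                 sojourn = mean_sojourn_times(q)),
            class = "ppd_summary")
}

#' @export
print.ppd_summary <- function(x, digits = 3, ...) {
  print(x$jump, digits = digits)
  print(x$sojourn, digits = 2)
  invisible(x)
}

#' Hazard-ratio report for fitted covariate effects
#'
#' For each estimated (transition, covariate) coefficient reports the hazard
#' ratio `exp(beta)` per one-unit covariate increase with a Wald confidence
#' interval `exp(beta +/- z * SE)` from the fit's parameter covariance.
#'
#' @param fit A converged `ppd_fit` with covariates and covariance.
#' @param level Confidence level (default 0.95).
#' @param significant_only If `TRUE`, keep only rows whose CI excludes 1.
#' @return A `hazard_ratio_report` data frame: transition, covariate, hr,
#'   lower, upper, se_log.
#' @export
hazard_ratio_report <- function(fit, level = 0.95, significant_only = FALSE) {
  stopifnot(inherits(fit, "ppd_fit"))
  if (ncol(fit$model$beta) == 0) ppd_stop("fit has no covariates")
  if (is.null(fit$vcov)) {
    ppd_stop("parameter covariance unavailable; cannot form intervals",
             class = "ppd_fit_error")
  }
  z <- qnorm(1 - (1 - level) / 2)
  idx <- which(fit$par_map$beta_mask, arr.ind = TRUE)
  pos <- sum(fit$par_map$allowed) + seq_len(nrow(idx))
  est <- fit$par[pos]
  se <- sqrt(pmax(diag(fit$vcov)[pos], 0))
  out <- data.frame(
    transition = TRANSITION_LABELS[idx[, 1]],
    covariate = colnames(fit$model$beta)[idx[, 2]],
    hr = exp(est), lower = exp(est - z * se), upper = exp(est + z * se),
    se_log = se, row.names = NULL, stringsAsFactors = FALSE
  )
  if (significant_only) out <- out[out$lower > 1 | out$upper < 1, ]
  structure(out, class = c("hazard_ratio_report", "data.frame"),
            level = level)
}

#' @export
print.hazard_ratio_report <- function(x, digits = 2, ...) {
  cat(sprintf("Hazard ratios per one-unit covariate increase (%d%% CI)\n",
              round(100 * attr(x, "level"))))
  df <- as.data.frame(x)
  df$hr <- sprintf("%.2f (%.2f, %.2f)", df$hr, df$lower, df$upper)
  print(df[c("transition", "covariate", "hr")], row.names = FALSE)
  cat("note: per raw covariate unit; no multiplicity adjustment\n")
  invisible(x)
}

#' Parse follow-up horizon tokens into weeks
#'
#' Accepts numeric weeks or tokens like `"1m"`, `"9m"`, `"2y"`; months are
#' converted at 52/12 weeks per month, years at 52 weeks.
#'
#' @param horizons Character or numeric vector.
#' @return Named numeric vector of weeks.
#' @export
parse_horizons <- function(horizons) {
  if (is.numeric(horizons)) {
    return(setNames(horizons, paste0(horizons, "w")))
  }
  wk <- vapply(horizons, function(h) {
    m <- regmatches(h, regexec("^([0-9]+(?:\\.[0-9]+)?)([mwy])$", h))[[1]]
    if (length(m) != 3) ppd_stop(sprintf("cannot parse horizon token '%s'", h))
    val <- as.numeric(m[2])
    switch(m[3], m = val * WEEKS_PER_MONTH, y = val * 52, w = val)
  }, numeric(1))
  setNames(wk, horizons)
}

#' Interval transition probabilities over follow-up horizons
#'
#' Computes, for each follow-up horizon, selected entries of
#' `P(t) = exp(Q t)` — the probability of being in the target state after an
#' interval of t given the source state now — with optional 95% confidence
#' intervals. CIs come from a parametric bootstrap: `B` parameter vectors are
#' drawn from the asymptotic normal at the MLE, each cell recomputed, and
#' percentile bounds taken. A delta-method alternative is available.
#'
#' @param x A `ppd_fit` (CIs possible) or an [intensity_matrix()] (points
#'   only).
#' @param horizons Horizon tokens or numeric weeks; see [parse_horizons()].
#'   Default: 1, 3, 6, 9 months; 1, 2, 3 years.
#' @param transitions Cells to report, as `"from->to"` labels.
#' @param ci `"bootstrap"`, `"delta"`, or `"none"`.
#' @param B Bootstrap draws (default 1000).
#' @param level Confidence level.
#' @param seed Seed for the bootstrap (local; global RNG restored).
#' @return An `interval_table` data frame: horizon, weeks, transition,
#'   estimate, lower, upper.
#' @export
interval_probability_table <- function(x,
                                       horizons = c("1m", "3m", "6m", "9m",
                                                    "1y", "2y", "3y"),
                                       transitions = c("1->3", "2->3",
                                                       "3->1", "2->1"),
                                       ci = c("bootstrap", "delta", "none"),
                                       B = 1000L, level = 0.95, seed = 1L) {
  ci <- match.arg(ci)
  weeks <- parse_horizons(horizons)
  if (any(weeks < 0)) ppd_stop("horizons must be non-negative")
  tr <- parse_transitions(transitions)

  is_fit <- inherits(x, "ppd_fit")
  q_hat <- if (is_fit) baseline_intensity(x) else as_intensity(x)
  cells <- function(q) {
    out <- vapply(weeks, function(t) {
      p <- unclass(transition_probability_matrix(q, t))
      p[cbind(tr$from, tr$to)]
    }, numeric(nrow(tr)))
    matrix(out, nrow = nrow(tr))  # transitions x horizons
  }
  est <- cells(q_hat)

  lower <- upper <- matrix(NA_real_, nrow(tr), length(weeks))
  if (ci != "none") {
    if (!is_fit || is.null(x$vcov)) {
      warning("covariance unavailable; reporting point estimates only",
              call. = FALSE)
      ci <- "none"
    }
  }
  if (ci == "bootstrap") {
    old_seed <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()), add = TRUE)
    set.seed(seed)
    nq <- sum(x$par_map$allowed)
    ev <- eigen(x$vcov, symmetric = TRUE)
    rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(ev$values))
    draws <- array(NA_real_, c(nrow(tr), length(weeks), B))
    for (b in seq_len(B)) {
      par_b <- x$par + as.numeric(rt %*% rnorm(length(x$par)))
      lb <- x$model$log_baseline
      lb[x$par_map$allowed] <- par_b[seq_len(nq)]
      draws[, , b] <- cells(intensity_from_rates(exp(lb)))
    }
    a <- (1 - level) / 2
    lower <- apply(draws, c(1, 2), quantile, probs = a)
    upper <- apply(draws, c(1, 2), quantile, probs = 1 - a)
  } else if (ci == "delta") {
    z <- qnorm(1 - (1 - level) / 2)
    nq <- sum(x$par_map$allowed)
    for (j in seq_along(weeks)) {
      for (i in seq_len(nrow(tr))) {
        f <- function(par) {
          lb <- x$model$log_baseline
          lb[x$par_map$allowed] <- par[seq_len(nq)]
          p <- unclass(transition_probability_matrix(
            intensity_from_rates(exp(lb)), weeks[j]))
          p[tr$from[i], tr$to[i]]
        }
        g <- central_diff(f, x$par, 1e-5)
        se <- sqrt(max(0, as.numeric(t(g) %*% x$vcov %*% g)))
        lower[i, j] <- max(0, est[i, j] - z * se)
        upper[i, j] <- min(1, est[i, j] + z * se)
      }
    }
  }

  out <- data.frame(
    horizon = rep(names(weeks), each = nrow(tr)),
    weeks = rep(unname(weeks), each = nrow(tr)),
    transition = rep(transitions, length(weeks)),
    estimate = as.numeric(est),
    lower = as.numeric(lower),
    upper = as.numeric(upper),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("interval_table", "data.frame"),
            ci = ci, level = level, B = if (ci == "bootstrap") B else NA)
}

#' @export
print.interval_table <- function(x, digits = 3, ...) {
  cat("Interval transition probabilities P(t)[from, to]\n")
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, digits)
  if (!all(is.na(df$lower))) {
    df$ci <- sprintf("(%.3f, %.3f)", df$lower, df$upper)
    df <- df[c("horizon", "weeks", "transition", "estimate", "ci")]
  } else {
    df <- df[c("horizon", "weeks", "transition", "estimate")]
  }
  df$weeks <- round(df$weeks, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

parse_transitions <- function(labels) {
  m <- regmatches(labels, regexec("^([123])->([123])$", labels))
  bad <- labels[vapply(m, length, integer(1)) != 3]
  if (length(bad)) {
    ppd_stop(sprintf("bad transition label(s): %s",
                     paste(bad, collapse = ", ")))
  }
  data.frame(from = vapply(m, function(x) as.integer(x[2]), integer(1)),
             to = vapply(m, function(x) as.integer(x[3]), integer(1)))
}
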