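#' Panel-data log-likelihood of the three-state model
#'
#' For panel-observed Markov data the likelihood conditions on each subject's
#' first observed state and multiplies, over consecutive visit pairs, the
#' interval transition probability of the observed move:
#' `sum_subjects sum_pairs log P(s_k -> s_{k+1}; dt_k, Q(z_subject))`,
#' with `P(.) = exp(Q dt)` and `Q(z)` the subject-specific generator under
#' the proportional-intensity model. Covariates are time-fixed per subject
#' (taken from the first visit row).
#'
#' @param model A [covariate_model()].
#' @param data A [panel_data()] object whose covariate columns cover the
#'   model's covariates.
#' @return A `log_likelihood` object: `value`, per-subject contributions
#'   `by_subject`, and `n_pairs`.
#' @export
panel_loglik <- function(model, data) {
  stopifnot(inherits(model, "covariate_model"))
  inp <- loglik_inputs(model, data, aggregate = FALSE)
  terms <- .panel_loglik_terms_cpp(model$log_baseline, model$beta, inp$X,
                                   inp$grp, inp$from, inp$to, inp$dt, inp$wt)
  if (any(is.nan(terms))) {
    bad <- inp$subject[which(is.nan(terms))[1]]
    ppd_stop(sprintf(
      "non-finite likelihood term for subject %s at log-rates (%s)", bad,
      paste(signif(model$log_baseline, 4), collapse = ", ")),
      class = "ppd_numeric_error")
  }
  by_subject <- vapply(split(terms, inp$subject), sum, numeric(1))
  structure(list(value = sum(terms), by_subject = by_subject,
                 n_pairs = length(terms)),
            class = "log_likelihood")
}

#' @export
print.log_likelihood <- function(x, ...) {
  cat(sprintf("Panel log-likelihood: %.4f over %d transitions (%d subjects)\n",
              x$value, x$n_pairs, length(x$by_subject)))
  invisible(x)
}

#' Numerical gradient of the panel log-likelihood
#'
#' Central finite differences of [panel_loglik()] with respect to the free
#' parameters (finite log baseline intensities first, then the log hazard
#' ratios column by column). Used by the optimizer and exposed for
#' diagnostics; at a maximum-likelihood estimate the gradient is numerically
#' zero.
#'
#' @param model A [covariate_model()].
#' @param data A [panel_data()] object.
#' @param step Base finite-difference step (scaled by `1 + |parameter|`).
#' @return Named numeric gradient vector.
#' @export
loglik_gradient <- function(model, data, step = 1e-5) {
  map <- par_map_for(model)
  inp <- loglik_inputs(model, data, aggregate = ncol(model$beta) == 0)
  f <- function(par) {
    m <- unpack_model(par, model, map)
    sum(.panel_loglik_terms_cpp(m$log_baseline, m$beta, inp$X, inp$grp,
                                inp$from, inp$to, inp$dt, inp$wt))
  }
  central_diff(f, pack_model(model, map), step)
}

# ---- internal machinery shared with the fitter -----------------------------

# Parameter packing: which of the 6 log rates are free, and which beta
# entries are estimated.
par_map_for <- function(model, beta_mask = NULL,
                        allowed = is.finite(model$log_baseline)) {
  if (is.null(beta_mask)) {
    beta_mask <- matrix(TRUE, 6, ncol(model$beta))
  }
  nm_q <- paste0("logq(", TRANSITION_LABELS[allowed], ")")
  nm_b <- character(0)
  if (ncol(model$beta) > 0) {
    grid <- which(beta_mask, arr.ind = TRUE)
    nm_b <- sprintf("beta(%s:%s)", TRANSITION_LABELS[grid[, 1]],
                    colnames(model$beta)[grid[, 2]])
  }
  list(allowed = allowed, beta_mask = beta_mask, names = c(nm_q, nm_b))
}

pack_model <- function(model, map) {
  setNames(c(model$log_baseline[map$allowed], model$beta[map$beta_mask]),
           map$names)
}

unpack_model <- function(par, template, map) {
  lb <- template$log_baseline
  nq <- sum(map$allowed)
  lb[map$allowed] <- par[seq_len(nq)]
  beta <- template$beta
  beta[map$beta_mask] <- par[-seq_len(nq)]
  covariate_model(lb, if (ncol(beta) > 0) beta else NULL, template$centers)
}

central_diff <- function(f, par, step = 1e-5) {
  g <- numeric(length(par))
  for (k in seq_along(par)) {
    h <- step * (1 + abs(par[k]))
    up <- dn <- par
    up[k] <- par[k] + h
    dn[k] <- par[k] - h
    g[k] <- (f(up) - f(dn)) / (2 * h)
  }
  setNames(g, names(par))
}

# Assemble the C++ kernel inputs. With covariates each subject is its own
# covariate pattern; without covariates all subjects share one generator and
# records collapse to weighted unique (from, to, dt) triples, which makes the
# homogeneous likelihood O(#unique dt) regardless of cohort size.
loglik_inputs <- function(model, data, aggregate = FALSE) {
  pairs <- transition_pairs(data)
  covs <- colnames(model$beta)
  if (length(covs) == 0 && aggregate) {
    key <- paste(pairs$from, pairs$to, pairs$dt, sep = "\r")
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
    ord <- order(as.numeric(parts[, 3]))
    list(X = matrix(0, 1, 0),
         grp = rep(1L, nrow(agg))[ord],
         from = as.integer(parts[ord, 1]),
         to = as.integer(parts[ord, 2]),
         dt = as.numeric(parts[ord, 3]),
         wt = as.numeric(agg$Freq[ord]),
         subject = rep("all", nrow(agg)))
  } else {
    subj <- unique(data$subject)
    if (length(covs)) {
      miss <- setdiff(covs, names(data))
      if (length(miss)) {
        ppd_stop(sprintf("data lack covariate column(s): %s",
                         paste(miss, collapse = ", ")))
      }
      first_row <- match(subj, data$subject)
      X <- as.matrix(as.data.frame(data)[first_row, covs, drop = FALSE])
      if (anyNA(X)) ppd_stop("missing covariate values at first visits")
      X <- sweep(X, 2, model$centers[covs])
    } else {
      X <- matrix(0, max(1L, length(subj)), 0)
    }
    grp <- match(pairs$subject, subj)
    ord <- order(grp, pairs$dt)
    list(X = X, grp = as.integer(grp[ord]), from = pairs$from[ord],
         to = pairs$to[ord], dt = pairs$dt[ord], wt = rep(1, nrow(pairs)),
         subject = pairs$subject[ord])
  }
}
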