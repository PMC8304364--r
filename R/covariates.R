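#' Proportional-intensity covariate model
#'
#' Each off-diagonal transition intensity is modelled as
#' `q_ij(z) = q0_ij * exp(beta_ij . (z - ref))`, where `q0_ij` is the
#' baseline rate at the covariate reference values `ref` (typically sample
#' means) and `exp(beta)` is the hazard ratio for a one-unit covariate
#' increase on that specific transition. An empty covariate set reduces
#' exactly to the homogeneous six-rate model.
#'
#' @param log_baseline Numeric vector of 6 log baseline intensities in the
#'   transition order (1,2),(1,3),(2,1),(2,3),(3,1),(3,2); `-Inf` marks a
#'   disallowed transition (rate pinned at zero).
#' @param beta 6 x p matrix of log hazard ratios (rows in transition order,
#'   columns named by covariate), or `NULL` for no covariates.
#' @param centers Named numeric vector of covariate reference values
#'   (defaults to zeros).
#' @return A `covariate_model` object.
#' @export
#' @examples
#' m <- covariate_model(log(rates_of(ppd_reference_intensity())))
#' intensity_at(m)
covariate_model <- function(log_baseline, beta = NULL, centers = NULL) {
  if (length(log_baseline) != 6L || !is.numeric(log_baseline)) {
    ppd_stop("`log_baseline` must be 6 log intensities")
  }
  if (any(is.na(log_baseline)) || any(log_baseline == Inf)) {
    ppd_stop("log baseline intensities must be finite or -Inf")
  }
  log_baseline <- setNames(as.numeric(log_baseline), TRANSITION_LABELS)
  if (is.null(beta)) beta <- matrix(0, 6, 0)
  if (!is.matrix(beta) || nrow(beta) != 6L) {
    ppd_stop("`beta` must be a 6 x p matrix of log hazard ratios")
  }
  p <- ncol(beta)
  if (p > 0 && is.null(colnames(beta))) {
    ppd_stop("`beta` columns must be named by covariate")
  }
  rownames(beta) <- TRANSITION_LABELS
  if (is.null(centers)) centers <- setNames(numeric(p), colnames(beta))
  if (p > 0 && !setequal(names(centers), colnames(beta))) {
    ppd_stop("`centers` must name exactly the covariates in `beta`")
  }
  centers <- centers[colnames(beta)]
  structure(list(log_baseline = log_baseline, beta = beta,
                 centers = centers),
            class = "covariate_model")
}

#' @export
print.covariate_model <- function(x, digits = 4, ...) {
  cat("Proportional-intensity covariate model\n")
  cat("Baseline intensities (per week):\n")
  print(round(exp(x$log_baseline), digits))
  if (ncol(x$beta) > 0) {
    cat("Hazard ratios per unit covariate increase:\n")
    print(round(exp(x$beta), digits))
    cat("Covariate reference values:\n")
    print(round(x$centers, digits))
  } else {
    cat("(no covariates: homogeneous model)\n")
  }
  invisible(x)
}

#' Extract the six off-diagonal rates of an intensity matrix
#'
#' @param q An [intensity_matrix()].
#' @return Named vector of 6 rates in the package transition order.
#' @export
rates_of <- function(q) rates_from_intensity(as_intensity(q))

#' Subject-specific intensity matrix under a covariate model
#'
#' Evaluates `q_ij(z) = q0_ij * exp(beta_ij . (z - ref))` for one subject's
#' covariate values. With all coefficients zero, or `z` at the reference
#' values, the baseline generator is returned.
#'
#' @param model A [covariate_model()].
#' @param z Named numeric vector of covariate values covering the model's
#'   covariates (ignored entries allowed). May be empty for a homogeneous
#'   model.
#' @return An [intensity_matrix()].
#' @export
intensity_at <- function(model, z = numeric()) {
  stopifnot(inherits(model, "covariate_model"))
  covs <- colnames(model$beta)
  eta <- model$log_baseline
  if (length(covs)) {
    miss <- setdiff(covs, names(z))
    if (length(miss)) {
      ppd_stop(sprintf("missing covariate value(s): %s",
                       paste(miss, collapse = ", ")))
    }
    eta <- eta + as.numeric(model$beta %*% (z[covs] - model$centers))
  }
  intensity_from_rates(exp(eta))
}
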