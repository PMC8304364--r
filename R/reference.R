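#' Reference values from the motivating screening cohort
#'
#' The package ships the published summary statistics of a three-visit
#' postpartum screening cohort (304 primiparous women assessed with the EPDS
#' at about 6, 13 and 26 weeks postpartum; 912 assessments, 608
#' consecutive-visit transitions). Raw subject-level data are not public, but
#' these printed summaries are sufficient to rebuild the fitted
#' three-state generator, reproduce the interval-probability tables, and
#' parameterize realistic synthetic cohorts.
#'
#' `ppd_reference_counts()` returns the observed consecutive-visit transition
#' counts; `ppd_reference_jump()` and `ppd_reference_sojourn()` the fitted
#' embedded jump-chain probabilities and mean sojourn times;
#' `ppd_reference_intensity()` the generator reconstructed from the latter
#' two; `ppd_reference_covariates()` the means/SDs of the social-support and
#' age covariates used for simulation defaults.
#'
#' @return See individual descriptions.
#' @name ppd_reference
NULL

#' @rdname ppd_reference
#' @export
ppd_reference_counts <- function() {
  transition_table(rbind(
    c(155L, 9L, 10L),
    c(88L, 33L, 19L),
    c(63L, 92L, 139L)
  ), kind = "counts")
}

#' @rdname ppd_reference
#' @export
ppd_reference_jump <- function() {
  transition_table(rbind(
    c(NA, 0.498, 0.502),
    c(0.800, NA, 0.200),
    c(0.064, 0.936, NA)
  ), kind = "probabilities", jump = TRUE)
}

#' @rdname ppd_reference
#' @export
ppd_reference_sojourn <- function() {
  structure(setNames(c(64.12, 6.29, 9.37), ppd_states()),
            class = "sojourn_times", units = "weeks")
}

#' @rdname ppd_reference
#' @export
ppd_reference_intensity <- function() {
  reconstruct_intensity(ppd_reference_jump(), ppd_reference_sojourn())
}

#' @rdname ppd_reference
#' @export
ppd_reference_covariates <- function() {
  data.frame(
    name = c("age", "emotional", "material", "informational", "evaluation"),
    mean = c(24.8, 10.2, 9.9, 6.8, 8.4),
    sd = c(2.89, 2.72, 3.43, 3.14, 2.92),
    min = c(18, 0, 0, 0, 0),
    max = c(Inf, 15, 15, 15, 15),
    stringsAsFactors = FALSE
  )
}
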