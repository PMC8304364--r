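#' PPD severity state space
#'
#' The model's state space is fixed at three transient, mutually communicating
#' severity states derived from EPDS total scores: state 1 "normal"
#' (EPDS 0-9), state 2 "mild" (EPDS 10-12), state 3 "severe" (EPDS >= 13).
#'
#' @return Character vector of the three state labels, in state-index order.
#' @export
#' @examples
#' ppd_states()
ppd_states <- function() c("normal", "mild", "severe")

#' Classify EPDS scores into severity states
#'
#' Maps Edinburgh Postnatal Depression Scale total scores (0-30) onto the
#' three-state severity scale using two cutpoints: scores below the first
#' cutpoint are "normal" (state 1), scores from the first up to (excluding)
#' the second are "mild" (state 2), and scores at or above the second are
#' "severe" (state 3). Defaults reproduce the conventional 10/13 cutpoints.
#'
#' @param score Integer vector of EPDS total scores, each in 0-30.
#' @param thresholds Two increasing integer cutpoints, default `c(10, 13)`.
#' @return Integer vector of states in `1:3`.
#' @export
#' @examples
#' classify_epds(c(9, 12, 13))
classify_epds <- function(score, thresholds = c(10, 13)) {
  if (length(thresholds) != 2 || !is.numeric(thresholds) ||
      thresholds[1] >= thresholds[2]) {
    ppd_stop("`thresholds` must be two increasing cutpoints")
  }
  if (!is.numeric(score) || anyNA(score)) {
    ppd_stop("EPDS scores must be numeric and non-missing")
  }
  if (any(score < 0 | score > 30)) {
    bad <- score[score < 0 | score > 30]
    ppd_stop(sprintf("EPDS scores out of range 0-30: %s",
                     paste(utils::head(bad, 5), collapse = ", ")))
  }
  as.integer(1L + (score >= thresholds[1]) + (score >= thresholds[2]))
}
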