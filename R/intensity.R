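#' Construct and validate a transition intensity (generator) matrix
#'
#' The intensity matrix Q of the three-state model holds instantaneous
#' transition rates in events per week: off-diagonal `q[i, j]` is the rate of
#' moving from state i to state j, and each diagonal is the negative row sum,
#' so rows sum to zero. All six off-diagonal transitions are permitted.
#'
#' @param q Numeric 3x3 matrix with non-negative off-diagonals and rows
#'   summing to zero (diagonals may be supplied or left to be filled in;
#'   pass `fill_diagonal = TRUE` to set them from the off-diagonals).
#' @param labels State labels, default [ppd_states()].
#' @param fill_diagonal If `TRUE`, overwrite the diagonal with negative row
#'   sums of the off-diagonals.
#' @return An object of class `intensity_matrix` (a labelled 3x3 matrix).
#' @export
#' @examples
#' q <- intensity_matrix(rbind(
#'   c(-0.2, 0.1, 0.1),
#'   c(0.3, -0.5, 0.2),
#'   c(0.1, 0.4, -0.5)
#' ))
intensity_matrix <- function(q, labels = ppd_states(), fill_diagonal = FALSE) {
  if (!is.matrix(q) || !is.numeric(q) || any(dim(q) != 3L)) {
    ppd_stop("an intensity matrix must be a numeric 3x3 matrix")
  }
  if (length(labels) != 3L) ppd_stop("exactly three state labels required")
  q <- matrix(as.numeric(q), 3, 3)
  off <- q
  diag(off) <- 0
  if (any(off < 0)) {
    ppd_stop("off-diagonal intensities must be non-negative")
  }
  if (fill_diagonal) diag(q) <- -rowSums(off)
  if (any(diag(q) > 0)) ppd_stop("diagonal intensities must be non-positive")
  if (any(abs(rowSums(q)) > 1e-8)) {
    ppd_stop("intensity matrix rows must sum to zero")
  }
  # enforce the generator identity exactly
  diag(q) <- -rowSums(off)
  dimnames(q) <- list(from = labels, to = labels)
  structure(q, class = c("intensity_matrix", "matrix", "array"))
}

#' @export
print.intensity_matrix <- function(x, digits = 4, ...) {
  cat("Transition intensity matrix (events per week)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

# Build an intensity matrix from the six off-diagonal rates in the
# package-wide transition order (1,2),(1,3),(2,1),(2,3),(3,1),(3,2).
intensity_from_rates <- function(rates, labels = ppd_states()) {
  stopifnot(length(rates) == 6L)
  q <- matrix(0, 3, 3)
  q[cbind(TRANSITION_FROM, TRANSITION_TO)] <- rates
  intensity_matrix(q, labels = labels, fill_diagonal = TRUE)
}

# Inverse of intensity_from_rates.
rates_from_intensity <- function(q) {
  setNames(unclass(q)[cbind(TRANSITION_FROM, TRANSITION_TO)],
           TRANSITION_LABELS)
}

#' Tables of transition counts or probabilities
#'
#' A `transition_table` is a labelled 3x3 matrix of either observed
#' transition counts or transition probabilities (full row-stochastic
#' matrices, or embedded jump-chain matrices whose diagonal is undefined and
#' whose off-diagonals sum to one per row).
#'
#' @param values Numeric 3x3 matrix.
#' @param kind `"counts"` or `"probabilities"`.
#' @param jump If `TRUE`, the table is an embedded jump-chain table: the
#'   diagonal is set to `NA` and each row's off-diagonals must sum to 1.
#' @param labels State labels.
#' @return An object of class `transition_table`.
#' @export
transition_table <- function(values, kind = c("counts", "probabilities"),
                             jump = FALSE, labels = ppd_states()) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || any(dim(values) != 3L)) {
    ppd_stop("a transition table must be a 3x3 matrix")
  }
  values <- matrix(as.numeric(values), 3, 3)
  if (kind == "counts") {
    if (any(values < 0) || any(values != round(values))) {
      ppd_stop("count tables must hold non-negative integers")
    }
  } else if (jump) {
    diag(values) <- NA_real_
    offsums <- rowSums(values, na.rm = TRUE)
    if (any(abs(offsums - 1) > 1e-6)) {
      ppd_stop("jump-chain rows must have off-diagonals summing to 1")
    }
  } else {
    if (any(values < -1e-12) || any(abs(rowSums(values) - 1) > 1e-9)) {
      ppd_stop("probability tables must be row-stochastic")
    }
    values[values < 0] <- 0
  }
  dimnames(values) <- list(from = labels, to = labels)
  structure(values, class = c("transition_table", "matrix", "array"),
            kind = kind, jump = jump)
}

#' @export
print.transition_table <- function(x, digits = 4, ...) {
  kind <- attr(x, "kind")
  hdr <- if (kind == "counts") {
    "Observed transitions (from state in rows, to state in columns)"
  } else if (isTRUE(attr(x, "jump"))) {
    "Embedded jump-chain probabilities (next state if and when a transition occurs)"
  } else {
    "Transition probabilities"
  }
  cat(hdr, "\n")
  v <- unclass(x)
  attr(v, "kind") <- NULL
  attr(v, "jump") <- NULL
  if (kind == "counts") print(v) else print(round(v, digits))
  invisible(x)
}

#' Interval transition probability matrix P(t) = exp(Qt)
#'
#' For a time-homogeneous chain with generator Q, the probability of being in
#' state j after an interval of t weeks given state i now is the (i, j) entry
#' of the matrix exponential exp(Qt). Computed by a scaling-and-squaring Pade
#' routine.
#'
#' @param q An [intensity_matrix()].
#' @param t Interval length in weeks, a single non-negative number.
#' @return A row-stochastic [transition_table()] of probabilities.
#' @export
#' @examples
#' q <- ppd_reference_intensity()
#' transition_probability_matrix(q, 13)
transition_probability_matrix <- function(q, t) {
  q <- as_intensity(q)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    ppd_stop("interval length `t` must be a single non-negative number of weeks")
  }
  p <- .expm_cpp(unclass(q) * t)
  p[p < 0] <- 0
  p <- p / rowSums(p)
  transition_table(p, kind = "probabilities", labels = rownames(q))
}

#' Embedded jump-chain probabilities
#'
#' Given that a subject in state i does transition, the probability that the
#' next state is j equals `q[i, j] / -q[i, i]`. The diagonal is undefined.
#'
#' @param q An [intensity_matrix()] with strictly negative diagonal.
#' @return A jump-chain [transition_table()].
#' @export
jump_chain_probabilities <- function(q) {
  q <- as_intensity(q)
  d <- diag(unclass(q))
  if (any(d == 0)) {
    ppd_stop(sprintf(
      "state(s) %s have zero total exit rate; jump probabilities undefined",
      paste(rownames(q)[d == 0], collapse = ", ")))
  }
  j <- unclass(q) / -d
  transition_table(j, kind = "probabilities", jump = TRUE,
                   labels = rownames(q))
}

#' Mean sojourn times
#'
#' The expected continuous dwell time in state i before any transition is
#' `-1 / q[i, i]`, in weeks.
#'
#' @param q An [intensity_matrix()] with strictly negative diagonal.
#' @return Named numeric vector of per-state mean sojourn times (weeks),
#'   class `sojourn_times`.
#' @export
mean_sojourn_times <- function(q) {
  q <- as_intensity(q)
  d <- diag(unclass(q))
  if (any(d == 0)) {
    ppd_stop(sprintf(
      "state(s) %s have zero total exit rate (infinite sojourn)",
      paste(rownames(q)[d == 0], collapse = ", ")))
  }
  structure(setNames(-1 / d, rownames(q)),
            class = "sojourn_times", units = "weeks")
}

#' @export
print.sojourn_times <- function(x, digits = 2, ...) {
  cat("Mean sojourn times (weeks)\n")
  print(setNames(round(as.numeric(x), digits), names(x)))
  invisible(x)
}

#' Stationary distribution of the chain
#'
#' Solves pi Q = 0 with sum(pi) = 1. For an irreducible three-state chain
#' this is the long-run occupancy distribution and the limit of every row of
#' P(t) as t grows.
#'
#' @param q An irreducible [intensity_matrix()].
#' @return Named probability vector of length 3.
#' @export
stationary_distribution <- function(q) {
  q <- as_intensity(q)
  m <- unclass(q)
  # irreducibility check: P(t) of an irreducible chain is strictly positive
  tscale <- 1 / max(abs(diag(m)), 1e-12)
  p <- .expm_cpp(m * tscale)
  if (any(p <= 1e-12)) {
    ppd_stop("intensity matrix is reducible; no unique stationary distribution")
  }
  a <- rbind(t(m), rep(1, 3))
  pi_hat <- qr.solve(a, c(0, 0, 0, 1))
  pi_hat <- pi_hat / sum(pi_hat)
  if (any(pi_hat <= 0)) {
    ppd_stop("intensity matrix is reducible; no unique stationary distribution")
  }
  setNames(pi_hat, rownames(q))
}

#' Reconstruct an intensity matrix from jump probabilities and sojourn times
#'
#' Inverts the summary representation of a generator: with mean sojourn times
#' S and jump-chain matrix J, `q[i, i] = -1 / S[i]` and
#' `q[i, j] = J[i, j] / S[i]`. Round-trips exactly with
#' [jump_chain_probabilities()] and [mean_sojourn_times()].
#'
#' @param jump_probs Jump-chain [transition_table()] (or plain 3x3 matrix
#'   with zero/NA diagonal and off-diagonal rows summing to 1).
#' @param sojourn Numeric vector of 3 positive mean sojourn times in weeks.
#' @return An [intensity_matrix()].
#' @export
#' @examples
#' q <- reconstruct_intensity(ppd_reference_jump(), ppd_reference_sojourn())
reconstruct_intensity <- function(jump_probs, sojourn) {
  j <- unclass(jump_probs)
  if (!is.matrix(j) || any(dim(j) != 3L)) {
    ppd_stop("`jump_probs` must be a 3x3 matrix")
  }
  sojourn <- unclass(sojourn)
  if (length(sojourn) != 3L || any(!is.finite(sojourn)) || any(sojourn <= 0)) {
    ppd_stop("`sojourn` must be 3 positive times in weeks")
  }
  diag(j) <- 0
  if (any(abs(rowSums(j) - 1) > 1e-6)) {
    ppd_stop("jump probability rows must sum to 1")
  }
  q <- j / sojourn          # row i scaled by 1/S_i
  diag(q) <- -1 / sojourn
  intensity_matrix(q)
}

# Coerce plain matrices, validating on the way.
as_intensity <- function(q) {
  if (inherits(q, "intensity_matrix")) return(q)
  intensity_matrix(as.matrix(q))
}
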