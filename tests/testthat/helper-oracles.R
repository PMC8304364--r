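# Independent numerical oracles and small fixture builders. These stay
# deliberately separate from the package implementation: the matrix
# exponential oracle is a uniformization series (non-negative terms, no
# cancellation), not the scaling-and-squaring route the package uses.

expm_oracle <- function(m, t) {
  lambda <- max(-diag(m))
  if (lambda <= 0 || t == 0) return(diag(3))
  u <- diag(3) + m / lambda
  lt <- lambda * t
  kmax <- max(30, ceiling(lt + 12 * sqrt(lt) + 40))
  p <- exp(-lt) * diag(3)
  term <- diag(3)
  w <- exp(-lt)
  for (k in seq_len(kmax)) {
    term <- term %*% u
    w <- w * lt / k
    p <- p + w * term
  }
  unname(p)
}

trans_labels <- c("1->2", "1->3", "2->1", "2->3", "3->1", "3->2")

# 6 x 1 coefficient matrix with a single non-zero log hazard ratio
beta_single <- function(covariate, transition, log_hr) {
  b <- matrix(0, 6, 1, dimnames = list(trans_labels, covariate))
  b[transition, 1] <- log_hr
  b
}

# random irreducible generator with moderate rates
random_generator <- function() {
  intensity_matrix(
    {
      q <- matrix(stats::runif(9, 0.02, 0.4), 3, 3)
      diag(q) <- 0
      q
    },
    fill_diagonal = TRUE
  )
}

random_jump_sojourn <- function() {
  j <- matrix(stats::runif(9, 0.05, 1), 3, 3)
  diag(j) <- 0
  j <- j / rowSums(j)
  list(jump = j, sojourn = stats::runif(3, 0.5, 60))
}

# the printed interval-probability table of the reference cohort:
# horizons x transitions (1->3, 2->3, 3->1, 2->1)
reference_interval_values <- function() {
  m <- rbind(
    "1m" = c(0.028, 0.085, 0.104, 0.390),
    "3m" = c(0.060, 0.114, 0.407, 0.680),
    "6m" = c(0.079, 0.101, 0.673, 0.782),
    "9m" = c(0.085, 0.093, 0.769, 0.806),
    "1y" = c(0.087, 0.090, 0.801, 0.813),
    "2y" = c(0.088, 0.088, 0.816, 0.816),
    "3y" = c(0.088, 0.088, 0.816, 0.816)
  )
  colnames(m) <- c("1->3", "2->3", "3->1", "2->1")
  m
}

write_temp_panel <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# homogeneous cohort under the reference design, used by recovery tests
simulate_reference_cohort <- function(n, seed, model = NULL) {
  simulate_cohort(cohort_config(n_subjects = n, seed = seed, model = model))
}
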