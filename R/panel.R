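#' Construct a panel dataset of repeated severity observations
#'
#' A panel dataset holds one row per subject-visit with the subject
#' identifier, the visit time in weeks postpartum, the observed severity
#' state (1/2/3), and optional time-fixed covariates. If a `state` column is
#' absent but an `epds` column is present, states are derived with
#' [classify_epds()]. Rows are sorted by subject and time; duplicate
#' (subject, time) pairs and non-increasing times are rejected. Subjects with
#' a single visit are retained but flagged (they contribute no transitions).
#'
#' @param df Data frame with columns `subject`, `time`, and `state` and/or
#'   `epds`, plus optional covariate columns.
#' @param covariates Character vector naming covariate columns; default: all
#'   remaining numeric columns.
#' @param thresholds EPDS cutpoints used when deriving states from scores.
#' @return A `panel_data` object (a data frame with attributes `covariates`
#'   and `singletons`).
#' @export
#' @examples
#' df <- data.frame(subject = 1, time = c(6, 13, 26), state = c(1, 2, 1))
#' panel_data(df)
panel_data <- function(df, covariates = NULL, thresholds = c(10, 13)) {
  if (!is.data.frame(df)) ppd_stop("`df` must be a data frame")
  need <- c("subject", "time")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    ppd_stop(sprintf("missing required column(s): %s",
                     paste(miss, collapse = ", ")))
  }
  if (!"state" %in% names(df) && !"epds" %in% names(df)) {
    ppd_stop("need a `state` or `epds` column")
  }
  if (!is.numeric(df$time) || anyNA(df$time) || any(df$time < 0)) {
    ppd_stop("`time` must be non-negative weeks postpartum")
  }
  if (!"state" %in% names(df)) {
    df$state <- classify_epds(df$epds, thresholds)
  }
  if (anyNA(df$state) || !all(df$state %in% 1:3)) {
    bad <- unique(df$state[!df$state %in% 1:3])
    ppd_stop(sprintf("unknown state code(s): %s",
                     paste(bad, collapse = ", ")))
  }
  df$state <- as.integer(df$state)
  df <- df[order(df$subject, df$time), , drop = FALSE]
  rownames(df) <- NULL

  key <- paste(df$subject, df$time, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(df$subject[duplicated(key)])
    ppd_stop(sprintf("duplicate (subject, time) rows for subject(s): %s",
                     paste(utils::head(dup, 5), collapse = ", ")))
  }
  nvis <- table(df$subject)
  if (is.null(covariates)) {
    cand <- setdiff(names(df), c("subject", "time", "state", "epds"))
    covariates <- cand[vapply(df[cand], is.numeric, logical(1))]
  } else {
    miss <- setdiff(covariates, names(df))
    if (length(miss)) {
      ppd_stop(sprintf("covariate column(s) not found: %s",
                       paste(miss, collapse = ", ")))
    }
  }
  structure(df,
            covariates = covariates,
            singletons = names(nvis)[nvis == 1L],
            class = c("panel_data", "data.frame"))
}

#' @export
print.panel_data <- function(x, ...) {
  n_sub <- length(unique(x$subject))
  cat(sprintf("Panel dataset: %d observations of %d subjects", nrow(x), n_sub))
  covs <- attr(x, "covariates")
  if (length(covs)) cat("; covariates:", paste(covs, collapse = ", "))
  cat("\n")
  sing <- attr(x, "singletons")
  if (length(sing)) {
    cat(sprintf("  %d subject(s) with a single visit (no transitions)\n",
                length(sing)))
  }
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a panel dataset from delimited text
#'
#' Reads a long-format CSV (one row per subject-visit, header required) and
#' validates it into a [panel_data()] object. Column names can be remapped
#' via `col_map` for files using different headers.
#'
#' @param path Path to a CSV file.
#' @param col_map Named list mapping the canonical names `subject`, `time`,
#'   `state`, `epds` to the file's column names.
#' @param covariates,thresholds Passed to [panel_data()].
#' @return A `panel_data` object.
#' @export
read_panel <- function(path, col_map = list(), covariates = NULL,
                       thresholds = c(10, 13)) {
  if (!file.exists(path)) ppd_stop(sprintf("no such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (canon in intersect(names(col_map), c("subject", "time", "state", "epds"))) {
    src <- col_map[[canon]]
    if (!src %in% names(df)) {
      ppd_stop(sprintf("mapped column `%s` (for %s) not in file", src, canon))
    }
    names(df)[names(df) == src] <- canon
  }
  panel_data(df, covariates = covariates, thresholds = thresholds)
}

#' Write a panel dataset to CSV
#'
#' @param data A [panel_data()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Consecutive-visit transition records: one row per (subject, from, to, dt).
# The panel likelihood conditions on each subject's first observed state, so
# these triples (plus per-subject covariates) are the likelihood's
# sufficient data.
transition_pairs <- function(data) {
  stopifnot(inherits(data, "panel_data"))
  by_sub <- split(seq_len(nrow(data)), data$subject)
  out <- lapply(by_sub, function(idx) {
    if (length(idx) < 2L) return(NULL)
    i <- idx[-length(idx)]
    j <- idx[-1L]
    dt <- data$time[j] - data$time[i]
    if (any(dt <= 0)) {
      ppd_stop(sprintf("non-increasing visit times for subject %s",
                       data$subject[idx[1]]))
    }
    data.frame(subject = data$subject[i], from = data$state[i],
               to = data$state[j], dt = dt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(subject = character(), from = integer(),
                      to = integer(), dt = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Observed consecutive-visit transition counts
#'
#' Tabulates, over all subjects, the number of consecutive-visit pairs that
#' moved from state i (row) to state j (column). The grand total equals the
#' number of consecutive pairs, i.e. total observations minus the number of
#' subjects with at least one visit.
#'
#' @param data A [panel_data()] object.
#' @return A counts [transition_table()].
#' @export
observed_transition_table <- function(data) {
  pairs <- transition_pairs(data)
  tab <- table(factor(pairs$from, levels = 1:3),
               factor(pairs$to, levels = 1:3))
  transition_table(matrix(as.integer(tab), 3, 3), kind = "counts")
}

#' Summarize deterioration, improvement and stability
#'
#' Classifies each observed transition by severity order (1 < 2 < 3): moves
#' to a higher state are deterioration, to a lower state improvement, and
#' same-state pairs no change.
#'
#' @param counts A counts [transition_table()].
#' @return A `change_summary` list with counts and percentages.
#' @export
summarize_changes <- function(counts) {
  stopifnot(inherits(counts, "transition_table"),
            attr(counts, "kind") == "counts")
  v <- unclass(counts)
  n_worse <- sum(v[upper.tri(v)])
  n_better <- sum(v[lower.tri(v)])
  n_same <- sum(diag(v))
  n <- n_worse + n_better + n_same
  pct <- if (n > 0) 100 * c(n_worse, n_better, n_same) / n else c(0, 0, 0)
  structure(list(
    n_transitions = n, n_worse = n_worse, n_better = n_better,
    n_same = n_same,
    pct_worse = pct[1], pct_better = pct[2], pct_same = pct[3]
  ), class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("Of %d observed transitions:\n", x$n_transitions))
  cat(sprintf("  deterioration: %4d (%.1f%%)\n", x$n_worse, x$pct_worse))
  cat(sprintf("  improvement:   %4d (%.1f%%)\n", x$n_better, x$pct_better))
  cat(sprintf("  no change:     %4d (%.1f%%)\n", x$n_same, x$pct_same))
  invisible(x)
}
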