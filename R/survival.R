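# Two-sample log-rank machinery, implemented from the standard
# hypergeometric observed-minus-expected construction so the pipeline is
# self-contained and testable against permutation and survival-package
# oracles.

logrank_two_sample <- function(time, event, in_high) {
  stopifnot(length(time) == length(event), length(time) == length(in_high))
  o <- order(time)
  time <- time[o]; event <- event[o]; in_high <- in_high[o]
  ev_times <- unique(time[event == 1])
  O <- 0; E <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_high)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & in_high)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chisq <- if (V > 0) (O - E)^2 / V else 0
  list(
    statistic = chisq,
    p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
    observed_high = O, expected_high = E, variance = V
  )
}

#' Median-split log-rank test of a continuous marker against survival
#'
#' Splits patients at the median of `values` (ties go to the low arm:
#' high = strictly above the median), then compares overall survival between
#' the two arms with the two-sample log-rank test (1 df chi-square).
#' `direction` reports which arm fares worse, from the sign of the
#' observed-minus-expected event count in the high arm.
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicator (1 = death, 0 = censored).
#' @param values Per-patient marker values (e.g. one gene's expression or a
#'   signature score).
#' @param min_arm Minimum patients per arm (default 2); a smaller arm —
#'   e.g. from heavy ties at the median — raises a degenerate-split error.
#' @return A list with `statistic`, `p_value`, `direction`
#'   (`"high_worse"`/`"low_worse"`/`"none"`), `n_high`, `n_low`.
#' @export
logrank_median_split <- function(time, event, values, min_arm = 2L) {
  check_numeric(time, "time")
  if (any(time <= 0)) abort("Follow-up times must be positive.")
  if (!all(event %in% c(0, 1))) abort("`event` must be 0/1.")
  check_numeric(values, "values")
  in_high <- values > median(values)
  if (sum(in_high) < min_arm || sum(!in_high) < min_arm) {
    abort(sprintf(
      "Degenerate median split: arms of size %d and %d (need >= %d each).",
      sum(in_high), sum(!in_high), min_arm
    ))
  }
  res <- logrank_two_sample(time, event, in_high)
  diff <- res$observed_high - res$expected_high
  res$direction <- if (abs(diff) < 1e-12) {
    "none"
  } else if (diff > 0) "high_worse" else "low_worse"
  res$n_high <- sum(in_high)
  res$n_low <- sum(!in_high)
  res
}

#' Filter a gene signature by median-cut survival association
#'
#' The integrated-signature procedure: each signature gene is tested for
#' overall-survival association in the cohort by a median-cut log-rank test;
#' p-values are Benjamini-Hochberg adjusted across the signature's genes; a
#' gene is retained when its q-value clears `fdr_threshold` and — if
#' `direction_filter` is on and the signature declares an expected
#' prognosis — its hazard direction is consistent (a "favorable" signature
#' keeps genes whose high-expression arm fares better; an "adverse" one the
#' reverse).
#'
#' @param signature A `gene_signature` (or character vector of genes).
#' @param cohort Data frame with columns `time_days`, `event` and one column
#'   per gene (expression on the same scale as the training matrix).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param direction_filter Apply the hazard-direction consistency filter
#'   (default TRUE; ignored when the signature has no declared prognosis).
#' @return A list with `signature` (the filtered `gene_signature`) and
#'   `results`, an object of class `survival_filter` — a tibble with per-gene
#'   `statistic`, `p_value`, `q_value`, `direction`, `retained`.
#' @export
integrate_signature <- function(signature, cohort, fdr_threshold = 0.05,
                                direction_filter = TRUE) {
  genes <- if (inherits(signature, "gene_signature")) {
    signature$gene
  } else {
    as.character(signature)
  }
  if (length(genes) == 0) abort("Empty signature.")
  check_columns(cohort, c("time_days", "event"), "cohort")
  present <- intersect(genes, names(cohort))
  if (length(present) == 0) {
    abort("No signature gene has an expression column in the cohort.")
  }
  prognosis <- if (inherits(signature, "gene_signature")) {
    attr(signature, "prognosis")
  } else {
    NA_character_
  }

  res <- purrr::map_dfr(present, function(g) {
    lr <- logrank_median_split(cohort$time_days, cohort$event, cohort[[g]])
    tibble(
      gene = g, statistic = lr$statistic, p_value = lr$p_value,
      direction = lr$direction
    )
  })
  res$q_value <- bh_fdr(res$p_value)
  # a threshold of 1 disables the FDR filter entirely (q-values can equal 1)
  keep <- if (fdr_threshold >= 1) {
    rep(TRUE, nrow(res))
  } else {
    res$q_value < fdr_threshold
  }
  if (direction_filter && !is.na(prognosis)) {
    wanted <- if (prognosis == "favorable") "low_worse" else "high_worse"
    keep <- keep & res$direction == wanted
  }
  res$retained <- keep
  class(res) <- c("survival_filter", class(res))
  attr(res, "fdr_threshold") <- fdr_threshold

  kept_genes <- res$gene[res$retained]
  filtered <- if (length(kept_genes) > 0) {
    nm <- if (inherits(signature, "gene_signature")) {
      paste0(attr(signature, "name"), "_integrated")
    } else {
      "integrated"
    }
    gene_signature(kept_genes, name = nm, prognosis = prognosis)
  } else {
    NULL
  }
  list(signature = filtered, results = res)
}

#' Kaplan-Meier survival curve estimate
#'
#' Product-limit estimator for one group: step-function survival
#' probabilities at the distinct event times.
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicator (1 = death, 0 = censored).
#' @return A tibble with columns `time`, `n_risk`, `n_event`, `survival`.
#' @export
kaplan_meier <- function(time, event) {
  check_numeric(time, "time")
  if (any(time <= 0)) abort("Follow-up times must be positive.")
  if (!all(event %in% c(0, 1))) abort("`event` must be 0/1.")
  ev_times <- sort(unique(time[event == 1]))
  surv <- 1
  rows <- purrr::map_dfr(ev_times, function(t) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    surv <<- surv * (1 - d / n)
    tibble(time = t, n_risk = n, n_event = d, survival = surv)
  })
  rows
}
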