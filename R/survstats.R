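check_survival_records <- function(records) {
  records <- as_tibble(records)
  needed <- c("group", "time_h", "event")
  if (!all(needed %in% names(records))) {
    abort("survival records need columns group, time_h, event.")
  }
  if (any(!is.finite(records$time_h)) || any(records$time_h <= 0)) {
    abort("survival times must be positive.")
  }
  if (!all(records$event %in% c(0, 1))) {
    abort("`event` must be 0 (censored) or 1 (death).")
  }
  records
}

#' Kaplan-Meier survival proportions
#'
#' Product-limit estimate of the survival function for one group of
#' animals: right-continuous steps at event times, unchanged at censoring
#' times. Survivors at the end of the observation window (default 24 h in a
#' lethality challenge) enter as censored records.
#'
#' @param records Data frame with columns `group`, `time_h` (positive
#'   hours), `event` (1 = death, 0 = censored).
#' @param group Group label to estimate; `NULL` if `records` holds a single
#'   group.
#'
#' @return Tibble `time_h`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   one row per distinct observed time.
#' @export
km_proportions <- function(records, group = NULL) {
  records <- check_survival_records(records)
  if (!is.null(group)) records <- records[records$group == group, ]
  if (nrow(records) == 0) abort("no records for the requested group.")
  fit <- survival::survfit(
    survival::Surv(time_h, event) ~ 1,
    data = records
  )
  tibble(
    time_h = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
}

#' Mantel-Cox log-rank test between two groups
#'
#' Compares the survival distributions of two groups by the Mantel-Cox
#' (log-rank) statistic: observed versus expected event counts accumulated
#' over the risk sets at each distinct event time, with the hypergeometric
#' variance and simultaneous accounting for tied event times. The p-value
#' is from the chi-square distribution with 1 degree of freedom.
#'
#' @param records Data frame `group`, `time_h`, `event`.
#' @param group_a,group_b The two group labels to compare.
#'
#' @return An object of class `"logrank_result"` with elements `chisq`,
#'   `df`, `p_value`, and `counts` (tibble `group`, `n`, `observed`,
#'   `expected`).
#' @export
logrank_test <- function(records, group_a, group_b) {
  records <- check_survival_records(records)
  records <- records[records$group %in% c(group_a, group_b), ]
  for (g in c(group_a, group_b)) {
    if (!any(records$group == g)) abort(sprintf("group '%s' has no records.", g))
  }
  if (sum(records$event) == 0) {
    abort("log-rank statistic undefined: no events in either group.")
  }
  records$group <- factor(records$group, levels = c(group_a, group_b))
  sd <- survival::survdiff(survival::Surv(time_h, event) ~ group,
                           data = records)
  counts <- tibble(
    group = c(group_a, group_b),
    n = as.integer(sd$n),
    observed = as.numeric(sd$obs),
    expected = as.numeric(sd$exp)
  )
  structure(
    list(chisq = as.numeric(sd$chisq), df = 1L,
         p_value = as.numeric(pchisq(sd$chisq, df = 1, lower.tail = FALSE)),
         counts = counts),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Mantel-Cox log-rank: chisq = %.4g (df = %d), p = %.4g\n",
              x$chisq, x$df, x$p_value))
  print(x$counts)
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `logrank_result`.
#' @param ... Unused.
#' @method tidy logrank_result
#' @export
tidy.logrank_result <- function(x, ...) x$counts

#' @rdname logrank_test
#' @method glance logrank_result
#' @export
glance.logrank_result <- function(x, ...) {
  tibble(statistic = x$chisq, df = x$df, p.value = x$p_value)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m` for `m` concurrent comparisons against a shared control.
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of comparisons (`>= 1`).
#'
#' @return The corrected per-comparison threshold.
#' @examples
#' bonferroni_threshold(0.05, 2) # 0.025
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (m < 1 || m != floor(m)) abort("`m` must be a positive integer.")
  alpha / m
}

#' Significance annotation for a p-value
#'
#' Maps a p-value to a printable star annotation given a corrected
#' threshold, mirroring figure-style labels such as `"**"` for
#' `P < 0.005` and `"NS"` for non-significant comparisons.
#'
#' @param p P-value(s).
#' @param threshold Significance threshold (e.g. a
#'   [bonferroni_threshold()]).
#' @param star_map Named numeric vector mapping labels to upper p bounds,
#'   checked in order.
#'
#' @return Character vector of labels.
#' @export
significance_label <- function(p, threshold,
                               star_map = c("***" = 0.0005, "**" = 0.005,
                                            "*" = 0.05)) {
  vapply(p, function(pp) {
    if (pp >= threshold) return("NS")
    hit <- names(star_map)[pp < star_map]
    if (length(hit) == 0) "NS" else hit[1]
  }, character(1))
}
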