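#' Bin immunohistochemistry scores
#'
#' Maps ordinal staining scores on the 0-4 half-point grid into the three
#' expression groups used for tissue-microarray analysis: score 0 is
#' negative, 0.5-2.5 weak positive, 3-4 strong positive.
#'
#' @param score Numeric vector of scores on `{0, 0.5, 1, ..., 4}`.
#' @return Factor with levels `negative`, `weak_positive`, `strong_positive`.
#' @examples
#' bin_ihc(c(0, 2.5, 3))
#' @export
bin_ihc <- function(score) {
  if (any(!is.finite(score))) rlang::abort("scores must be finite")
  off <- which(score < 0 | score > 4 | abs(score * 2 - round(score * 2)) > 1e-8)
  if (length(off)) {
    rlang::abort(sprintf("score %g is not on the 0-4 half-point grid", score[off[1]]))
  }
  bin <- ifelse(score == 0, "negative",
                ifelse(score <= 2.5, "weak_positive", "strong_positive"))
  factor(bin, levels = c("negative", "weak_positive", "strong_positive"))
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' Two-sided comparison of expression (or score) distributions between two
#' groups. Exact mode enumerates the permutation distribution of the U
#' statistic and reports `2 * min(tail probabilities)` capped at 1; it is
#' available for `nA + nB <= 12` with no ties, otherwise the normal
#' approximation with tie and continuity correction is used (with a warning
#' if exact mode was requested).
#'
#' @param a,b Numeric vectors of observations in the two groups.
#' @param mode `"auto"` (exact when feasible), `"exact"` or `"asymptotic"`.
#' @return A tibble with `statistic` (U for group `a`), `p_value` and
#'   `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4), mode = "exact")
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) rlang::abort("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  feasible <- (length(a) + length(b) <= 12) && !ties
  use_exact <- switch(mode,
                      auto = feasible,
                      exact = {
                        if (!feasible) {
                          rlang::warn("exact mode needs nA + nB <= 12 and no ties; falling back to the normal approximation")
                        }
                        feasible
                      },
                      asymptotic = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 method = if (use_exact) "exact" else "asymptotic")
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Nonparametric survival curve with right censoring: at each event time the
#' curve is multiplied by `1 - d/n` (events over at-risk); censored records
#' leave the curve flat and only shrink the risk set.
#'
#' @param data Tibble with columns `time` (non-negative) and `event`
#'   (logical or 0/1; `TRUE` = event observed), and optionally `group`.
#' @return A tibble of step coordinates: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, plus `group` when grouped.
#' @export
km_estimate <- function(data) {
  if (!nrow(data)) rlang::abort("at least one survival record is required")
  if (any(data$time < 0)) rlang::abort("survival times must be non-negative")
  grouped <- "group" %in% names(data) && length(unique(data$group)) > 1
  fml <- if (grouped) survival::Surv(time, event) ~ group else survival::Surv(time, event) ~ 1
  fit <- survival::survfit(fml, data = data)
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        survival = fit$surv)
  if (grouped) {
    out$group <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
    out <- out[, c("group", "time", "n_risk", "n_event", "n_censor", "survival")]
  }
  out
}

#' Survival probability at given times
#'
#' Evaluates a Kaplan-Meier step function from [km_estimate()] at arbitrary
#' times (right-continuous; 1 before the first event).
#'
#' @param km Ungrouped tibble from [km_estimate()].
#' @param times Numeric vector of evaluation times.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, times) {
  ev <- km[km$n_event > 0, ]
  vapply(times, function(t0) {
    s <- ev$survival[ev$time <= t0]
    if (length(s)) s[length(s)] else 1
  }, 0)
}

#' Two-group (or k-group) log-rank test
#'
#' Standard log-rank comparison of survival distributions: at every event
#' time the observed events per group are compared with their hypergeometric
#' expectation given the risk sets, and the summed discrepancy is referred
#' to a chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param data Tibble with columns `time`, `event`, `group`.
#' @return A tibble with `statistic`, `df` and `p_value`.
#' @export
logrank_test <- function(data) {
  groups <- unique(data$group)
  if (length(groups) < 2) rlang::abort("log-rank needs at least two groups")
  if (any(vapply(groups, function(g) sum(data$group == g) == 0, TRUE))) {
    rlang::abort("all groups must be non-empty")
  }
  if (sum(data$event) < 1) rlang::abort("log-rank needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = data)
  df <- length(sd$n) - 1
  tibble::tibble(statistic = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Stratify patients by metastatic lymph-node ratio
#'
#' Groups patients by the ratio of positive metastatic lymph nodes to lymph
#' nodes examined: no positive node, ratio at or below the cutoff (default
#' 30%), or ratio above it. A ratio of exactly the cutoff falls in the low
#' group ("more than 30%" defines the high group).
#'
#' @param data Tibble with columns `positive_ln` and `examined_ln`.
#' @param cutoff Ratio cutoff (default 0.30).
#' @return `data` with added columns `ln_ratio` and `ln_group` (factor
#'   `no_ln_met` / `low_ratio` / `high_ratio`).
#' @export
ln_ratio_group <- function(data, cutoff = 0.30) {
  if (any(data$examined_ln < 1)) rlang::abort("examined_ln must be at least 1")
  if (any(data$positive_ln < 0 | data$positive_ln > data$examined_ln)) {
    rlang::abort("positive_ln must lie between 0 and examined_ln")
  }
  data |>
    dplyr::mutate(
      ln_ratio = .data$positive_ln / .data$examined_ln,
      ln_group = factor(
        dplyr::case_when(
          .data$positive_ln == 0 ~ "no_ln_met",
          .data$ln_ratio > cutoff ~ "high_ratio",
          TRUE ~ "low_ratio"
        ),
        levels = c("no_ln_met", "low_ratio", "high_ratio")
      )
    )
}

#' Correlation between two markers
#'
#' Spearman (rank) or Pearson correlation with the usual t-distribution
#' p-value; Spearman uses average ranks for ties.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @param method `"spearman"` or `"pearson"`.
#' @return A tibble with `estimate`, `p_value` and `method`.
#' @export
marker_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) rlang::abort("x and y must have equal length")
  if (length(x) < 3) rlang::abort("at least 3 paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("correlation is undefined for a constant vector")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
                 method = method)
}

#' Split values at their median into low/high groups
#'
#' Default dichotomization of marker expression for survival comparisons:
#' values strictly above the median are `high`, the rest `low`.
#'
#' @param x Numeric vector.
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(x) {
  factor(ifelse(x > stats::median(x), "high", "low"), levels = c("low", "high"))
}
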