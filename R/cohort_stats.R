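#' Median and range with missing values dropped
#'
#' Continuous clinical descriptors are summarized non-parametrically:
#' missing values are dropped, the even-n median is the mean of the central
#' pair, and the count of values actually used is reported.
#'
#' @param values numeric vector, `NA` allowed.
#' @return list with `median`, `min`, `max`, `n_used`, `n_missing`.
#' @examples
#' median_and_range(c(1, 2, 3, 4, NA))
#' @export
median_and_range <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("median_and_range: all values missing")
  list(median = stats::median(v), min = min(v), max = max(v),
       n_used = length(v), n_missing = sum(is.na(values)))
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric computation with fixed margins.  The two-sided
#' p-value is the sum of the probabilities of all tables whose probability
#' is at most that of the observed table (the conventional exact
#' definition).  One-sided `"greater"` is the upper tail in the direction
#' of enrichment of cell `[1,1]`; `"less"` the lower tail.  A zero margin
#' makes every table identical to the observed one: p = 1 with a
#' `degenerate` flag.
#'
#' The odds ratio reported is the sample odds ratio `ad/bc` with its
#' Haldane-Anscombe-corrected 95% CI (see [odds_ratio_ci()]).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param sidedness `"two.sided"` (default), `"greater"` or `"less"`.
#' @param conf_level confidence level for the odds-ratio CI.
#' @return object of class `contingency_result`: list with `table`,
#'   `sidedness`, `p_value`, `odds_ratio`, `conf_int`, `degenerate`.
#' @examples
#' # 1p loss in expression Group A (5/6) vs Group B (0/7)
#' fisher_exact(matrix(c(5, 1, 0, 7), 2, byrow = TRUE))$p_value
#' @export
fisher_exact <- function(table, sidedness = c("two.sided", "greater", "less"),
                         conf_level = 0.95) {
  sidedness <- match.arg(sidedness)
  table <- check_2x2(table)
  a <- table[1, 1]
  m <- sum(table[1, ]); n2 <- sum(table[2, ]); k <- sum(table[, 1])
  degenerate <- m == 0 || n2 == 0 || k == 0 || sum(table[, 2]) == 0
  if (degenerate) {
    p <- 1
  } else {
    support <- max(0, k - n2):min(k, m)
    probs <- stats::dhyper(support, m, n2, k)
    p_obs <- stats::dhyper(a, m, n2, k)
    p <- switch(sidedness,
      two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
      greater = sum(probs[support >= a]),
      less = sum(probs[support <= a]))
    p <- min(1, p)
  }
  or <- odds_ratio_ci(table, conf_level)
  structure(list(table = table, sidedness = sidedness, p_value = p,
                 odds_ratio = or$odds_ratio, conf_int = or$conf_int,
                 degenerate = degenerate),
            class = "contingency_result")
}

#' Chi-square test for a 2x2 table
#'
#' The explicit (never auto-selected) large-sample alternative to
#' [fisher_exact()], without continuity correction.
#'
#' @inheritParams fisher_exact
#' @param correct logical, Yates continuity correction (default `FALSE`).
#' @return `contingency_result` (two-sided by construction).
#' @export
chisq_contingency <- function(table, correct = FALSE, conf_level = 0.95) {
  table <- check_2x2(table)
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  or <- odds_ratio_ci(table, conf_level)
  structure(list(table = table, sidedness = "two.sided",
                 p_value = unname(ct$p.value), statistic = unname(ct$statistic),
                 odds_ratio = or$odds_ratio, conf_int = or$conf_int,
                 degenerate = any(rowSums(table) == 0) || any(colSums(table) == 0)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("2x2 contingency test (", x$sidedness, ")\n", sep = "")
  print(x$table)
  cat(sprintf("p = %.4g, OR = %.3g (95%% CI %.3g-%.3g)\n",
              x$p_value, x$odds_ratio, x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

check_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)) || anyNA(table)) {
    stop("table entries must be non-negative integers")
  }
  storage.mode(table) <- "double"
  table
}

#' Sample odds ratio with normal-approximation confidence interval
#'
#' OR = ad/bc.  The CI uses the log-OR normal approximation; when any cell
#' is zero, the Haldane-Anscombe correction (0.5 added to every cell) is
#' applied to both the standard error and the CI midpoint (the point
#' estimate itself stays `ad/bc`, so it can be `0` or `Inf`).  Two zero
#' cells on one diagonal make the OR undefined.
#'
#' @inheritParams fisher_exact
#' @param conf_level confidence level (default 0.95).
#' @return list with `odds_ratio`, `conf_int` (length 2), `undefined` flag.
#' @examples
#' odds_ratio_ci(matrix(c(2, 1, 1, 2), 2))$odds_ratio  # 4
#' @export
odds_ratio_ci <- function(table, conf_level = 0.95) {
  table <- check_2x2(table)
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  undefined <- (a == 0 && d == 0) || (b == 0 && c_ == 0)
  or <- if (undefined) NA_real_ else (a * d) / (b * c_)
  if (undefined) {
    ci <- c(NA_real_, NA_real_)
  } else {
    if (any(table == 0)) {
      a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
    }
    log_or <- log((a * d) / (b * c_))
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(log_or + c(-1, 1) * z * se)
  }
  list(odds_ratio = or, conf_int = ci, undefined = undefined)
}

#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric survival estimate from possibly right-censored data, with
#' the Greenwood variance on the log scale and the median survival time as
#' the smallest time with S(t) <= 0.5.  The 95% CI of the median is the
#' Brookmeyer-Crowley inversion of the log-transformed Greenwood pointwise
#' interval: the bound is where the corresponding confidence curve first
#' drops to 0.5 (undefined when a curve never reaches 0.5).
#'
#' @param times non-negative event/censoring times.
#' @param events logical (or 0/1): `TRUE` = event observed, `FALSE` =
#'   censored.
#' @param conf_level confidence level for the pointwise bands and median CI.
#' @return object of class `km_estimate`: list with `time` (event times),
#'   `n_risk`, `n_event`, `surv`, `lower`, `upper`, `median`, `median_ci`,
#'   `n`, `n_events`.
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
#' km$surv    # 2/3, 1/3, 0
#' km$median  # 2
#' @export
km_estimate <- function(times, events, conf_level = 0.95) {
  stopifnot(length(times) == length(events))
  if (any(is.na(times)) || any(times < 0)) stop("times must be non-negative and non-missing")
  events <- as.logical(events)
  o <- order(times)
  times <- times[o]; events <- events[o]
  ut <- sort(unique(times[events]))
  n <- length(times)
  if (!length(ut)) {
    return(structure(list(time = numeric(), n_risk = numeric(),
                          n_event = numeric(), surv = numeric(),
                          lower = numeric(), upper = numeric(),
                          median = NA_real_, median_ci = c(NA_real_, NA_real_),
                          n = n, n_events = 0), class = "km_estimate"))
  }
  n_risk <- vapply(ut, function(t) sum(times >= t), 0)
  n_event <- vapply(ut, function(t) sum(times == t & events), 0)
  surv <- cumprod(1 - n_event / n_risk)
  # log-scale Greenwood standard error and pointwise bands
  gw <- cumsum(n_event / (n_risk * (n_risk - n_event)))
  se_log <- sqrt(gw)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lower <- exp(log(surv) - z * se_log)
  upper <- pmin(1, exp(log(surv) + z * se_log))
  lower[surv == 0] <- 0
  upper[surv == 0] <- 0
  first_below <- function(curve) {
    i <- which(curve <= 0.5 + 1e-12)
    if (length(i)) ut[i[1]] else NA_real_
  }
  structure(list(time = ut, n_risk = n_risk, n_event = n_event, surv = surv,
                 lower = lower, upper = upper,
                 median = first_below(surv),
                 median_ci = c(first_below(lower), first_below(upper)),
                 n = n, n_events = sum(events)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d\n", x$n, x$n_events))
  if (is.na(x$median)) {
    cat("median survival not reached\n")
  } else {
    cat(sprintf("median survival %.3g (95%% CI %.3g-%.3g)\n",
                x$median, x$median_ci[1], x$median_ci[2]))
  }
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square with one degree of freedom,
#' computed from the pooled event times.
#'
#' @param times1,events1 times and event flags for group 1.
#' @param times2,events2 times and event flags for group 2.
#' @return list with `statistic`, `p_value`, `observed` and `expected`
#'   event counts per group.
#' @export
logrank <- function(times1, events1, times2, events2) {
  if (!length(times1) || !length(times2)) stop("both groups must be non-empty")
  events1 <- as.logical(events1); events2 <- as.logical(events2)
  if (!any(c(events1, events2))) stop("log-rank requires at least one event")
  times <- c(times1, times2)
  events <- c(events1, events2)
  grp1 <- rep(c(TRUE, FALSE), c(length(times1), length(times2)))
  ut <- sort(unique(times[events]))
  o1 <- 0; e1 <- 0; v <- 0
  for (t in ut) {
    at_risk <- times >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & grp1)
    d_t <- sum(times == t & events)
    d1_t <- sum(times == t & events & grp1)
    o1 <- o1 + d1_t
    e1 <- e1 + d_t * n1_t / n_t
    if (n_t > 1) {
      v <- v + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- if (v > 0) stats::pchisq(stat, df = 1, lower.tail = FALSE) else 1
  list(statistic = stat, p_value = p,
       observed = c(o1, sum(events) - o1),
       expected = c(e1, sum(events) - e1))
}

#' Wilcoxon-Mann-Whitney rank-sum test (thin wrapper)
#'
#' Convenience wrapper used for continuous clinical comparisons across
#' strata; delegates to [stats::wilcox.test()].
#'
#' @param x,y numeric vectors (missing values dropped).
#' @param ... passed to [stats::wilcox.test()].
#' @return list with `statistic` and `p_value`.
#' @export
rank_sum_test <- function(x, y, ...) {
  wt <- suppressWarnings(stats::wilcox.test(x[!is.na(x)], y[!is.na(y)], ...))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
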