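#' Exact Clopper-Pearson binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion in the
#' beta-quantile form: with `a = 1 - conf_level`, the lower bound is the
#' `a/2` quantile of Beta(k, n - k + 1) (0 when `k = 0`) and the upper
#' bound the `1 - a/2` quantile of Beta(k + 1, n - k) (1 when `k = n`).
#' Equivalent to inverting the exact binomial tail probabilities; the
#' interval is conservative, with coverage at least the nominal level.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @param conf_level two-sided confidence level in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson(26, 26)  # one-sided-looking bound from all successes
#' clopper_pearson(88, 107)
#' @export
clopper_pearson <- function(k, n, conf_level = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n)) {
    stop("k and n must be single non-missing numbers", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1 (proportion undefined)", call. = FALSE)
  if (k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("need integer 0 <= k <= n", call. = FALSE)
  }
  if (conf_level <= 0 || conf_level >= 1) {
    stop("conf_level must lie strictly in (0, 1)", call. = FALSE)
  }
  alpha <- 1 - conf_level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Binomial proportion with exact confidence bounds
#'
#' Bundles `k/n` with its Clopper-Pearson interval. A zero denominator
#' yields an explicitly undefined estimate (all `NA`) rather than an
#' error, so that partial accuracy panels on degenerate tables remain
#' usable.
#'
#' @param numerator,denominator integer counts.
#' @param conf_level two-sided confidence level.
#' @return Object of class `proportion_estimate` with fields
#'   `numerator`, `denominator`, `point`, `conf_level`, `lower`,
#'   `upper`.
#' @examples
#' proportion_estimate(26, 45)
#' @export
proportion_estimate <- function(numerator, denominator,
                                conf_level = 0.95) {
  if (denominator == 0) {
    return(structure(list(numerator = 0L, denominator = 0L,
                          point = NA_real_, conf_level = conf_level,
                          lower = NA_real_, upper = NA_real_),
                     class = "proportion_estimate"))
  }
  ci <- clopper_pearson(numerator, denominator, conf_level)
  structure(
    list(numerator = as.integer(numerator),
         denominator = as.integer(denominator),
         point = numerator / denominator,
         conf_level = conf_level,
         lower = unname(ci["lower"]), upper = unname(ci["upper"])),
    class = "proportion_estimate"
  )
}

is_undefined <- function(p) is.na(p$point)

#' @export
print.proportion_estimate <- function(x, digits = 1, ...) {
  if (is_undefined(x)) {
    cat("undefined (zero denominator)\n")
    return(invisible(x))
  }
  cat(sprintf("%.*f%% (%g%% CI %.*f-%.*f) [%d/%d]\n",
              digits, 100 * x$point, 100 * x$conf_level,
              digits, 100 * x$lower, digits, 100 * x$upper,
              x$numerator, x$denominator))
  invisible(x)
}

#' @export
format.proportion_estimate <- function(x, digits = 1, ...) {
  if (is_undefined(x)) return("undefined")
  sprintf("%.*f (%.*f-%.*f)", digits, 100 * x$point,
          digits, 100 * x$lower, digits, 100 * x$upper)
}

#' Full diagnostic accuracy panel for one test
#'
#' Sensitivity, specificity, PPV, NPV (each with exact Clopper-Pearson
#' intervals), disease prevalence, and the likelihood ratios
#' `PLR = se / (1 - sp)` and `NLR = (1 - se) / sp`. A perfect
#' specificity with non-zero sensitivity gives an infinite PLR. Metrics
#' whose denominator is zero are reported as undefined, not as errors.
#'
#' Likelihood-ratio confidence intervals (standard log method) are
#' optional extras beyond the core panel; an NLR of exactly 0 carries no
#' interval (the log method is undefined there), flagged as
#' unavailable.
#'
#' @param table a [two_by_two] table.
#' @param test_name label used in printing.
#' @param conf_level two-sided confidence level for all intervals.
#' @param lr_ci if `TRUE`, attach log-method intervals to the likelihood
#'   ratios.
#' @return Object of class `test_performance`.
#' @examples
#' performance_panel(two_by_two(26, 19, 0, 88), "POC test")
#' @export
performance_panel <- function(table, test_name = "index test",
                              conf_level = 0.95, lr_ci = FALSE) {
  stopifnot(inherits(table, "two_by_two"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  total <- tp + fp + fn + tn
  se <- proportion_estimate(tp, tp + fn, conf_level)
  sp <- proportion_estimate(tn, tn + fp, conf_level)
  ppv <- proportion_estimate(tp, tp + fp, conf_level)
  npv <- proportion_estimate(tn, tn + fn, conf_level)
  prev <- proportion_estimate(tp + fn, total, conf_level)

  plr <- if (is_undefined(se) || is_undefined(sp)) {
    NA_real_
  } else if (sp$point < 1) {
    se$point / (1 - sp$point)
  } else if (se$point > 0) Inf else NA_real_
  nlr <- if (is_undefined(se) || is_undefined(sp) || sp$point == 0) {
    NA_real_
  } else {
    (1 - se$point) / sp$point
  }

  lr_cis <- NULL
  if (lr_ci) lr_cis <- lr_log_ci(tp, fp, fn, tn, conf_level)

  structure(
    list(test_name = test_name, table = table,
         sensitivity = se, specificity = sp, ppv = ppv, npv = npv,
         prevalence = prev, plr = plr, nlr = nlr,
         plr_ci = lr_cis$plr, nlr_ci = lr_cis$nlr,
         conf_level = conf_level),
    class = "test_performance"
  )
}

# log-method intervals for likelihood ratios (Simel et al. form);
# undefined (NA) at boundary counts where the log variance blows up
lr_log_ci <- function(tp, fp, fn, tn, conf_level) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- tp / (tp + fn); sp <- tn / (tn + fp)
  plr_ci <- nlr_ci <- c(lower = NA_real_, upper = NA_real_)
  if (tp > 0 && fp > 0) {
    plr <- se / (1 - sp)
    s <- sqrt((1 - se) / tp + sp / fp)
    plr_ci <- c(lower = plr * exp(-z * s), upper = plr * exp(z * s))
  }
  if (fn > 0 && tn > 0) {
    nlr <- (1 - se) / sp
    s <- sqrt(se / fn + (1 - sp) / tn)
    nlr_ci <- c(lower = nlr * exp(-z * s), upper = nlr * exp(z * s))
  }
  list(plr = plr_ci, nlr = nlr_ci)
}

#' @export
print.test_performance <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy: %s (n = %d, %g%% CI)\n",
              x$test_name,
              x$table$tp + x$table$fp + x$table$fn + x$table$tn,
              100 * x$conf_level))
  cat(sprintf("  sensitivity %s\n", format(x$sensitivity)))
  cat(sprintf("  specificity %s\n", format(x$specificity)))
  cat(sprintf("  PPV         %s\n", format(x$ppv)))
  cat(sprintf("  NPV         %s\n", format(x$npv)))
  cat(sprintf("  prevalence  %s\n", format(x$prevalence)))
  fmt_lr <- function(v, ci) {
    if (is.na(v)) return("undefined")
    s <- if (is.infinite(v)) "Inf" else sprintf("%.2f", v)
    if (!is.null(ci) && !all(is.na(ci))) {
      s <- sprintf("%s (%.2f-%.2f)", s, ci["lower"], ci["upper"])
    } else if (!is.na(v) && v == 0) {
      s <- paste(s, "(CI unavailable)")
    }
    s
  }
  cat(sprintf("  PLR         %s\n", fmt_lr(x$plr, x$plr_ci)))
  cat(sprintf("  NLR         %s\n", fmt_lr(x$nlr, x$nlr_ci)))
  invisible(x)
}

#' Predictive values at an assumed prevalence
#'
#' Bayes-theorem transport of sensitivity and specificity to a
#' population with pre-test probability `prevalence`:
#' `ppv = p se / (p se + (1 - p)(1 - sp))` and
#' `npv = (1 - p) sp / ((1 - p) sp + p (1 - se))`. At the 2x2 table's
#' own prevalence these reproduce the table-based PPV/NPV exactly. A
#' degenerate denominator (e.g. `p = 0` with perfect specificity for
#' the PPV) yields an explicit `NA`.
#'
#' @param sensitivity,specificity,prevalence proportions in `[0, 1]`.
#' @return Named numeric vector `c(ppv, npv)`; `NA` where undefined.
#' @examples
#' predictive_values_at_prevalence(1, 88/107, 0.05)
#' @export
predictive_values_at_prevalence <- function(sensitivity, specificity,
                                            prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            prevalence >= 0, prevalence <= 1)
  p <- prevalence; se <- sensitivity; sp <- specificity
  ppv_den <- p * se + (1 - p) * (1 - sp)
  npv_den <- (1 - p) * sp + p * (1 - se)
  c(ppv = if (ppv_den > 0) p * se / ppv_den else NA_real_,
    npv = if (npv_den > 0) (1 - p) * sp / npv_den else NA_real_)
}
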