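#' Crossover treatment-effect estimate (LS means difference)
#'
#' Estimates the active-minus-placebo treatment effect from post-treatment
#' values of a two-period crossover table with the ANOVA model
#' `value ~ treatment + period + patient`. The patient factor absorbs
#' between-subject variation, so for balanced complete data the point
#' estimate coincides with the least-squares treatment-means difference of
#' the random-intercept formulation, and equals the closed form
#' \deqn{\hat\tau = \tfrac12\left[\overline{d}_{AB} - \overline{d}_{BA}\right]}
#' where \eqn{d_i = y_{i,period 1} - y_{i,period 2}} and AB / BA are the
#' active-first / placebo-first sequence groups. The 95% CI and two-sided p
#' value use the t distribution on the within-patient error degrees of
#' freedom.
#'
#' Patients missing a period are excluded with a warning. Baseline visits
#' are not used in this comparison.
#'
#' @param table a `crossover_table` (see [generate_crossover_table()]) or
#'   data frame with columns `patient_id`, `sequence`, `period`, `visit`,
#'   `treatment` and the outcome column.
#' @param outcome name of the outcome column.
#' @param conf_level confidence level for the interval.
#' @return A `crossover_estimate`: list with `effect`, `ci_low`, `ci_high`,
#'   `p_value`, `se`, `df`, `n_patients`.
#' @export
estimate_crossover_effect <- function(table, outcome = "value",
                                      conf_level = 0.95) {
  need <- c("patient_id", "sequence", "period", "visit", "treatment", outcome)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- as.data.frame(table)[table$visit == "post", need]
  names(d)[names(d) == outcome] <- "value"
  d <- d[is.finite(d$value), ]

  per_patient <- table(d$patient_id)
  incomplete <- names(per_patient)[per_patient < 2L]
  if (length(incomplete)) {
    warning(sprintf("excluding %d patient(s) with a missing period: %s",
                    length(incomplete), paste(incomplete, collapse = ", ")))
    d <- d[!(d$patient_id %in% incomplete), ]
  }
  if (length(unique(d$sequence)) < 2L) {
    stop("both sequence groups must be represented")
  }
  n_pat <- length(unique(d$patient_id))
  if (n_pat < 2L) stop("at least 2 complete patients are required")

  d$treatment <- factor(d$treatment, levels = c("placebo", "active"))
  d$period <- factor(d$period)
  d$patient_id <- factor(d$patient_id)
  fit <- stats::lm(value ~ treatment + period + patient_id, data = d)
  # suppress summary.lm's perfect-fit warning; the zero-residual case is
  # handled explicitly below
  sm <- suppressWarnings(summary(fit))$coefficients
  est <- unname(stats::coef(fit)["treatmentactive"])
  df <- fit$df.residual
  se <- if ("treatmentactive" %in% rownames(sm)) {
    unname(sm["treatmentactive", "Std. Error"])
  } else NA_real_

  eps <- sqrt(.Machine$double.eps) * max(1, abs(est))
  if (!is.finite(se) || se < eps) {
    # saturated/degenerate residual: a zero effect is exactly consistent
    # with the null, a non-zero one maximally inconsistent
    p <- if (abs(est) < eps) 1 else .Machine$double.xmin
    ci <- c(est, est)
    se <- 0
  } else {
    tval <- est / se
    p <- 2 * stats::pt(-abs(tval), df)
    p <- max(p, .Machine$double.xmin)
    crit <- stats::qt(1 - (1 - conf_level) / 2, df)
    ci <- est + c(-1, 1) * crit * se
  }

  structure(list(effect = est, ci_low = ci[1], ci_high = ci[2],
                 p_value = p, se = se, df = df, n_patients = n_pat),
            class = "crossover_estimate")
}

#' @export
print.crossover_estimate <- function(x, ...) {
  cat(sprintf("<crossover_estimate> effect %.4g (95%% CI %.4g, %.4g), p = %.3g, n = %d\n",
              x$effect, x$ci_low, x$ci_high, x$p_value, x$n_patients))
  invisible(x)
}

#' Closed-form balanced 2x2 crossover estimator
#'
#' Independent closed form for the treatment effect on balanced complete
#' data: half the difference between the sequence groups' mean
#' (period 1 - period 2) within-patient differences. Used as an oracle
#' against the regression-based estimator.
#'
#' @inheritParams estimate_crossover_effect
#' @return The point estimate (active minus placebo).
#' @export
crossover_effect_closed_form <- function(table, outcome = "value") {
  d <- as.data.frame(table)[table$visit == "post", ]
  v <- d[[outcome]]
  p1 <- d$period == 1
  ids <- unique(d$patient_id)
  diffs <- vapply(ids, function(id) {
    rows <- d$patient_id == id
    v[rows & p1] - v[rows & !p1]
  }, numeric(1))
  seq1 <- vapply(ids, function(id) d$sequence[d$patient_id == id][1], character(1))
  active_first <- vapply(ids, function(id) {
    d$treatment[d$patient_id == id & p1][1] == "active"
  }, logical(1))
  (mean(diffs[active_first]) - mean(diffs[!active_first])) / 2
}

#' Pearson correlation with two-sided p value
#'
#' Standard product-moment correlation with p from the t transform; no
#' multiplicity adjustment (intended for post hoc exploration).
#'
#' @param x,y paired numeric vectors, n >= 3, finite, non-constant.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 paired finite observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Difference-in-differences of group means
#'
#' `(active_post - active_base) - (placebo_post - placebo_base)`: the
#' raw-means counterpart of the LS-means treatment difference in a balanced
#' crossover.
#'
#' @param active_base,active_post,placebo_base,placebo_post group means.
#' @return the difference-in-differences, in outcome units.
#' @export
diff_in_differences <- function(active_base, active_post,
                                placebo_base, placebo_post) {
  (active_post - active_base) - (placebo_post - placebo_base)
}

#' Relative change in percent
#'
#' @param change absolute change (e.g. an LS-means treatment difference).
#' @param reference reference level the change is expressed against.
#' @return `100 * change / reference`.
#' @export
relative_change_pct <- function(change, reference) {
  if (reference == 0) stop("reference must be non-zero")
  100 * change / reference
}
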