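#' Simulate a two-period crossover trial table
#'
#' Generates per-patient, per-period biomarker values for a randomized
#' two-sequence (active-first / placebo-first) crossover design with a
#' baseline and a post-treatment visit in each period:
#' \deqn{y_{post} = \mu + b_i + \pi\,1\{period\,2\} + \tau\,1\{active\} + e}
#' \deqn{y_{base} = \mu + b_i + e}
#' with patient intercepts \eqn{b_i \sim N(0, patient\_sd^2)} and residuals
#' \eqn{e \sim N(0, noise\_sd^2)}.
#'
#' @param n_patients number of patients (even, >= 2); split equally across
#'   the two sequences.
#' @param true_effect treatment effect \eqn{\tau} (active minus placebo) in
#'   biomarker units.
#' @param period_effect additive period-2 effect \eqn{\pi}.
#' @param patient_sd SD of the patient random intercepts.
#' @param noise_sd residual SD.
#' @param baseline_mean grand mean \eqn{\mu}.
#' @param seed integer seed.
#' @return A `data.frame` of class `crossover_table` with columns
#'   `patient_id`, `sequence`, `period`, `visit`, `treatment`, `value`.
#' @export
generate_crossover_table <- function(n_patients,
                                     true_effect = 0.05,
                                     period_effect = 0.01,
                                     patient_sd = 0.10,
                                     noise_sd = 0.05,
                                     baseline_mean = 0.77,
                                     seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 2L) stop("n_patients must be at least 2")
  if (n_patients %% 2L != 0L) {
    stop("n_patients must be even for an equal split across sequences")
  }
  sequence <- rep(c("active-first", "placebo-first"), each = n_patients / 2L)

  tab <- withr::with_seed(seed, {
    b <- stats::rnorm(n_patients, sd = patient_sd)
    rows <- lapply(seq_len(n_patients), function(i) {
      trt1 <- if (sequence[i] == "active-first") "active" else "placebo"
      trt2 <- if (trt1 == "active") "placebo" else "active"
      data.frame(
        patient_id = sprintf("P%03d", i),
        sequence = sequence[i],
        period = rep(1:2, each = 2L),
        visit = rep(c("baseline", "post"), 2L),
        treatment = rep(c(trt1, trt2), each = 2L),
        stringsAsFactors = FALSE
      )
    })
    tab <- do.call(rbind, rows)
    idx <- match(tab$patient_id, sprintf("P%03d", seq_len(n_patients)))
    mu <- baseline_mean + b[idx]
    post <- tab$visit == "post"
    tab$value <- mu +
      ifelse(post & tab$period == 2L, period_effect, 0) +
      ifelse(post & tab$treatment == "active", true_effect, 0) +
      stats::rnorm(nrow(tab), sd = noise_sd)
    tab
  })
  class(tab) <- c("crossover_table", "data.frame")
  tab
}
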