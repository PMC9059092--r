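#' Published summary values from a dual-bronchodilator crossover trial
#'
#' Group-level summary statistics reported for a randomized, double-blind,
#' placebo-controlled two-period crossover trial of 14-day
#' indacaterol-glycopyrronium versus placebo in 50 patients with COPD, in
#' which the imaging biomarkers implemented by this package were the
#' endpoints. Baseline and post-treatment group means are given per
#' treatment period together with the reported LS-means treatment
#' difference (active minus placebo). These values serve as worked-example
#' inputs for the difference-in-differences and relative-change
#' computations; they are inputs, not outputs, of this package.
#'
#' @return A data frame with columns `parameter`, `unit`, `active_baseline`,
#'   `active_post`, `placebo_baseline`, `placebo_post`, `ls_diff`
#'   (reported LS-means treatment difference), `ci_low`, `ci_high`.
#' @export
copd_crossover_summary <- function() {
  data.frame(
    parameter = c("FVL-CM", "Q", "VDP_CM", "VQM_RVent", "VQM_CM"),
    unit = c("correlation", "mL/min/100 mL", "%", "fraction", "fraction"),
    active_baseline  = c(0.77,  97, 40.9, 0.64, 0.60),
    active_post      = c(0.83, 122, 31.1, 0.70, 0.66),
    placebo_baseline = c(0.77, 108, 41.1, 0.64, 0.59),
    placebo_post     = c(0.78, 113, 40.0, 0.65, 0.60),
    ls_diff          = c(0.05, 9.27, -8.9, 0.05, 0.06),
    ci_low           = c(0.03, 0.05, -11.5, 0.02, 0.03),
    ci_high          = c(0.07, 18.49, -6.3, 0.08, 0.08),
    stringsAsFactors = FALSE
  )
}
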