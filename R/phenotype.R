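#' Comparative-Ct relative expression
#'
#' The 2^-ddCt statistic: relative expression of the target gene in a
#' sample, normalized to the reference gene (beta-actin role) and to a
#' calibrator sample. `fold = 2^-((Ct_target - Ct_ref)_sample -
#' (Ct_target - Ct_ref)_calibrator)`.
#'
#' @param ct_target,ct_ref Target/reference Ct of the sample (cycles).
#' @param calib_target,calib_ref Target/reference Ct of the calibrator.
#' @return Fold change relative to the calibrator (vectorized over samples).
#' @examples
#' ddct_fold_change(20, 22, 25, 25)  # ddCt = -2 -> fold 4
#' @export
ddct_fold_change <- function(ct_target, ct_ref, calib_target, calib_ref) {
  if (anyNA(c(ct_target, ct_ref, calib_target, calib_ref))) {
    abort("missing Ct value (reference or target)")
  }
  stopifnot(all(c(ct_target, ct_ref, calib_target, calib_ref) > 0))
  ddct <- (ct_target - ct_ref) - (calib_target - calib_ref)
  2^-ddct
}

#' Relative expression for a Ct table
#'
#' Data-frame front end to [ddct_fold_change()]: expects one row per sample
#' with target and reference Ct values and a logical `calibrator` column
#' flagging at least one calibrator sample (their mean delta-Ct is used when
#' several are flagged).
#'
#' @param ct Tibble with `sample_id`, `target_ct`, `reference_ct`,
#'   `calibrator`.
#' @return `ct` with an added `fold_change` column.
#' @export
relative_expression <- function(ct) {
  stopifnot(all(c("sample_id", "target_ct", "reference_ct", "calibrator")
                %in% names(ct)))
  if (!any(ct$calibrator)) abort("no calibrator sample flagged")
  if (anyNA(ct$reference_ct) || anyNA(ct$target_ct)) {
    abort("missing Ct value (reference or target)")
  }
  dct <- ct$target_ct - ct$reference_ct
  calib_dct <- mean(dct[ct$calibrator])
  dplyr::mutate(ct, fold_change = 2^-(dct - calib_dct))
}

#' Classify phenotypic sex from marker expression
#'
#' Male if and only if dmrt1 expression strictly exceeds cyp19a1a;
#' otherwise (including an exact tie) female. A message reports ties when
#' they occur.
#'
#' @param dmrt1,cyp19a1a Non-negative expression levels in the same unit
#'   (vectorized).
#' @return Character vector `"male"` / `"female"`.
#' @export
call_phenotypic_sex <- function(dmrt1, cyp19a1a) {
  stopifnot(all(dmrt1 >= 0), all(cyp19a1a >= 0))
  ties <- sum(dmrt1 == cyp19a1a)
  if (ties > 0) {
    inform(sprintf("%d marker tie(s) resolved to female", ties))
  }
  ifelse(dmrt1 > cyp19a1a, "male", "female")
}

#' Classify every fish in a cohort
#'
#' @param cohort Cohort tibble with `dmrt1` and `cyp19a1a` columns.
#' @return `cohort` with an added `phenotype` column.
#' @export
classify_cohort <- function(cohort) {
  dplyr::mutate(cohort,
                phenotype = call_phenotypic_sex(.data$dmrt1, .data$cyp19a1a))
}

#' Sex-reversal ratio with exact binomial confidence interval
#'
#' The proportion of fish whose called phenotype contradicts their genotype
#' (genetic XX called male = pseudomale; genetic XY called female), per
#' family and pooled, with a Clopper-Pearson confidence interval on the
#' pooled proportion. Filter the cohort to the stratum of interest before
#' calling (e.g. `dplyr::filter(cohort, genotype == "XX", treatment_c ==
#' 36)`).
#'
#' @param cohort Cohort tibble with `genotype`, `family` and either a
#'   `phenotype` column or the marker columns for [classify_cohort()].
#' @param conf_level Confidence level of the interval.
#' @return An object of class `reversal_ratio`; [tidy()] gives per-family
#'   proportions, [glance()] the pooled estimate and interval.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(conversion_prob = 0.75), seed = 1)
#' glance(reversal_ratio(cohort))
#' @export
reversal_ratio <- function(cohort, conf_level = 0.95) {
  if (nrow(cohort) == 0) abort("empty stratum")
  if (!"phenotype" %in% names(cohort)) cohort <- classify_cohort(cohort)
  cohort <- dplyr::mutate(
    cohort,
    reversed = (.data$genotype == "XX" & .data$phenotype == "male") |
      (.data$genotype == "XY" & .data$phenotype == "female"))
  per_family <- cohort |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(n = dplyr::n(), n_reversed = sum(.data$reversed),
                     proportion = mean(.data$reversed), .groups = "drop")
  n <- nrow(cohort)
  x <- sum(cohort$reversed)
  ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
  structure(list(per_family = per_family,
                 n = n, n_reversed = x, proportion = x / n,
                 conf_low = ci[1], conf_high = ci[2],
                 conf_level = conf_level),
            class = "reversal_ratio")
}

#' @export
print.reversal_ratio <- function(x, ...) {
  cat(sprintf("Sex reversal: %d / %d = %.1f%% (%.0f%% CI %.1f-%.1f%%)\n",
              x$n_reversed, x$n, 100 * x$proportion, 100 * x$conf_level,
              100 * x$conf_low, 100 * x$conf_high))
  invisible(x)
}

#' @rdname reversal_ratio
#' @param x A `reversal_ratio` object.
#' @param ... Unused.
#' @export
tidy.reversal_ratio <- function(x, ...) x$per_family

#' @rdname reversal_ratio
#' @export
glance.reversal_ratio <- function(x, ...) {
  tibble(n = x$n, n_reversed = x$n_reversed, estimate = x$proportion,
         conf.low = x$conf_low, conf.high = x$conf_high,
         conf.level = x$conf_level)
}

#' Percent reduction relative to a baseline
#'
#' `(baseline - observed) / baseline * 100`, both arguments on the percent
#' scale. Used, e.g., for the reduction in phenotypic males of a
#' heterozygous-knockout cohort against its wild-type baseline.
#'
#' @param observed_pct Observed percentage, in `[0, 100]`.
#' @param baseline_pct Baseline percentage, in `(0, 100]`.
#' @return The percent reduction.
#' @examples
#' percent_reduction(32.7, 100)
#' @export
percent_reduction <- function(observed_pct, baseline_pct) {
  stopifnot(baseline_pct > 0, baseline_pct <= 100,
            observed_pct >= 0, observed_pct <= 100)
  (baseline_pct - observed_pct) / baseline_pct * 100
}
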