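#' Trimmed-mean-of-M-values scaling factors
#'
#' Computes TMM scaling factors for a gene-level count matrix, or CMM factors
#' when applied to histone-mark peak fragment counts (the algorithm is the
#' same; only the feature universe differs). The reference sample is the one
#' whose upper quartile of depth-scaled counts is closest to the mean upper
#' quartile; features with a zero count in either the sample or the reference
#' are excluded; 30% of log-ratios (M) and 5% of average abundances (A) are
#' trimmed from each tail and the remaining M-values averaged with
#' precision weights. Factors are rescaled to geometric mean 1.
#'
#' @param counts Wide counts tibble (`gene_id`/`peak_id` column + one numeric
#'   column per sample) with at least two samples.
#' @param logratio_trim Two-sided trim fraction on M-values.
#' @param abs_trim Two-sided trim fraction on A-values.
#' @return A tibble with `sample_id`, `lib_size`, `norm_factor`.
#' @examples
#' sim <- simulate_counts(sim_design(n_genes = 100), seed = 1)
#' tmm_factors(sim$counts)
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  m <- counts_to_matrix(counts)
  if (ncol(m) < 2) abort("TMM needs at least two samples")
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(sprintf("sample(s) with all-zero counts: %s",
                  paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  f <- edgeR::calcNormFactors(m, method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim)
  tibble(sample_id = colnames(m), lib_size = unname(lib),
         norm_factor = unname(f))
}

#' Apply scaling factors to a count matrix
#'
#' Converts counts to normalized counts per million:
#' `count / (lib_size * factor) * 1e6`.
#'
#' @param counts Wide counts tibble.
#' @param factors Output of [tmm_factors()]; computed on the fly if omitted.
#' @return The normalized wide tibble, with the factor table attached as the
#'   `"norm_factors"` attribute.
#' @export
normalize_counts <- function(counts, factors = tmm_factors(counts)) {
  m <- counts_to_matrix(counts)
  idx <- match(colnames(m), factors$sample_id)
  if (anyNA(idx)) abort("`factors` does not cover every sample in `counts`")
  f <- factors$norm_factor[idx]
  lib <- factors$lib_size[idx]
  if (any(f <= 0)) abort("normalization factors must be positive")
  norm <- sweep(m, 2, lib * f, `/`) * 1e6
  out <- matrix_to_counts(norm, counts_key(counts))
  attr(out, "norm_factors") <- factors
  out
}

#' Z-scale a numeric profile
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (denominator
#' n - 1). A constant input cannot be scaled; it is returned as all zeros
#' with the attribute `degenerate = TRUE`.
#'
#' @param x Numeric vector of length >= 2.
#' @return The scaled vector; check `attr(, "degenerate")`.
#' @export
zscale <- function(x) {
  if (length(x) < 2) abort("zscale needs at least two values")
  s <- stats::sd(x)
  if (s == 0) {
    return(structure(rep(0, length(x)), degenerate = TRUE))
  }
  structure((x - mean(x)) / s, degenerate = FALSE)
}
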