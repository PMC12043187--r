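resolve_sample_set <- function(spec, samples, arg) {
  if (all(spec %in% samples$sample_id)) return(spec)
  if (all(spec %in% samples$group)) {
    return(samples$sample_id[samples$group %in% spec])
  }
  abort(sprintf("`%s` must name sample ids or group labels present in `samples`",
                arg))
}

#' Negative-binomial Wald differential-expression test
#'
#' A fully specified two-group test on library-normalized counts: the fold
#' change is `log2((mean2 + c) / (mean1 + c))` over TMM-normalized
#' counts-per-million with pseudocount `c`; the dispersion is a pooled
#' method-of-moments estimate per feature, floored at `dispersion_floor`;
#' the Wald statistic on the log2 scale is referred to a t distribution with
#' `n1 + n2 - 2` degrees of freedom (the small-sample reference keeps the
#' type-I rate near nominal at three replicates per group).
#'
#' Positive `log2fc` means higher expression in `group2`. Features that are
#' all-zero in both groups get `log2fc = 0`, `p_value = 1`.
#'
#' @param counts Wide counts tibble.
#' @param samples Sample sheet with `sample_id` and `group` columns.
#' @param group1,group2 Group labels or sample-id vectors; must not overlap
#'   and must each contain at least two samples.
#' @param factors [tmm_factors()] table; computed from `counts` if omitted.
#' @param stage Optional stage filter applied to `samples` before resolving
#'   groups.
#' @param pseudocount Added to group means before the ratio.
#' @param dispersion_floor Lower bound on the moment dispersion estimate.
#' @return A tibble with `feature_id`, `mean1`, `mean2`, `log2fc`,
#'   `p_value`, `padj` (Benjamini-Hochberg, informational only — the DEG
#'   gate uses raw P), `dispersion` and `comparison`.
#' @examples
#' sim <- simulate_counts(sim_design(n_genes = 100), seed = 1)
#' res <- de_test(sim$counts, sim$samples, "XX28F", "XY28M")
#' head(res)
#' @export
de_test <- function(counts, samples, group1, group2, factors = NULL,
                    stage = NULL, pseudocount = 0.5, dispersion_floor = 1e-4) {
  if (!is.null(stage)) samples <- samples[samples$stage %in% stage, ]
  s1 <- resolve_sample_set(group1, samples, "group1")
  s2 <- resolve_sample_set(group2, samples, "group2")
  if (length(intersect(s1, s2))) abort("group1 and group2 overlap")
  if (length(s1) < 2 || length(s2) < 2) {
    abort("each group needs at least two samples")
  }
  if (is.null(factors)) {
    keep <- c(counts_key(counts), s1, s2)
    factors <- tmm_factors(counts[keep])
  }
  m <- counts_to_matrix(counts)[, c(s1, s2), drop = FALSE]
  idx <- match(colnames(m), factors$sample_id)
  sf <- (factors$lib_size * factors$norm_factor)[idx] / 1e6  # CPM scale units
  q <- sweep(m, 2, sf, `/`)

  i1 <- seq_along(s1)
  i2 <- length(s1) + seq_along(s2)
  n1 <- length(s1); n2 <- length(s2)
  m1 <- unname(rowMeans(q[, i1, drop = FALSE]))
  m2 <- unname(rowMeans(q[, i2, drop = FALSE]))
  v1 <- unname(apply(q[, i1, drop = FALSE], 1, stats::var))
  v2 <- unname(apply(q[, i2, drop = FALSE], 1, stats::var))

  # method-of-moments NB dispersion on the normalized scale:
  # Var(q) = mu * mean(1/s) + alpha * mu^2, pooled across groups by df
  inv1 <- mean(1 / sf[i1]); inv2 <- mean(1 / sf[i2])
  a1 <- (v1 - m1 * inv1) / pmax(m1, pseudocount)^2
  a2 <- (v2 - m2 * inv2) / pmax(m2, pseudocount)^2
  alpha <- pmax(((n1 - 1) * a1 + (n2 - 1) * a2) / (n1 + n2 - 2),
                dispersion_floor)

  log2fc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  mu1 <- m1 + pseudocount; mu2 <- m2 + pseudocount
  var_m1 <- mu1 * inv1 / n1 + alpha * mu1^2 / n1
  var_m2 <- mu2 * inv2 / n2 + alpha * mu2^2 / n2
  se <- sqrt(var_m1 / mu1^2 + var_m2 / mu2^2) / log(2)
  z <- log2fc / se
  p <- 2 * stats::pt(-abs(z), df = n1 + n2 - 2)

  zero <- m1 == 0 & m2 == 0
  log2fc[zero] <- 0
  p[zero] <- 1

  tibble(feature_id = rownames(m),
         mean1 = m1, mean2 = m2,
         log2fc = log2fc, p_value = p,
         padj = stats::p.adjust(p, "BH"),
         dispersion = alpha,
         comparison = paste0(paste(group2, collapse = "+"), "_vs_",
                             paste(group1, collapse = "+")))
}

#' Apply the differential-expression gate
#'
#' Retains features with `p_value < p_max` and `|log2fc| >= min_abs_log2fc`
#' and labels them `up` or `down` by the sign of the fold change. The
#' printed DEG rule "P < 0.05 and fold change > 1" is interpreted as a
#' two-fold change on the linear scale (`|log2FC| >= 1`); reading it as "any
#' change" would make the filter vacuous.
#'
#' @param results Output of [de_test()].
#' @param p_max Raw P-value cutoff.
#' @param min_abs_log2fc Minimum absolute log2 fold change.
#' @return The filtered tibble with an added `direction` column.
#' @export
call_degs <- function(results, p_max = 0.05, min_abs_log2fc = 1.0) {
  stopifnot(p_max > 0, min_abs_log2fc > 0)
  results |>
    dplyr::filter(.data$p_value < p_max,
                  abs(.data$log2fc) >= min_abs_log2fc) |>
    dplyr::mutate(direction = ifelse(.data$log2fc > 0, "up", "down"))
}

#' Temperature-response DEGs per stage, unioned across stages
#'
#' Runs the 36 vs 28 degree comparison separately at each developmental
#' stage (all genotypes of a temperature pooled into one group) and returns
#' the union of the per-stage DEG sets.
#'
#' @inheritParams de_test
#' @inheritParams call_degs
#' @param pooled Pool all stages into one comparison instead.
#' @return Character vector of DEG feature ids.
#' @export
temperature_degs <- function(counts, samples, p_max = 0.05,
                             min_abs_log2fc = 1.0, pooled = FALSE, ...) {
  cold <- samples$sample_id[samples$temperature == 28]
  hot <- samples$sample_id[samples$temperature == 36]
  stages <- if (pooled) list(unique(samples$stage)) else
    as.list(sort(unique(samples$stage)))
  degs <- purrr::map(stages, function(st) {
    keep <- samples$sample_id[samples$stage %in% st]
    res <- de_test(counts, samples, intersect(cold, keep),
                   intersect(hot, keep), ...)
    call_degs(res, p_max, min_abs_log2fc)$feature_id
  })
  sort(unique(unlist(degs)))
}
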