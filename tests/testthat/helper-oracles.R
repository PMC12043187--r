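# Independent oracles, written directly from first principles / canonical
# formula descriptions, against which the package implementations are
# checked. They deliberately use naive algorithms (rank-based trimming,
# boolean masks, quadratic scans, grid search) rather than the package's
# code paths.

# Trimmed-mean-of-M-values factor for one sample against a reference:
# weighted mean of depth-adjusted log ratios after two-sided rank trimming
# of 30% on M and 5% on A, with inverse asymptotic-variance weights.
oracle_tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                            logratio_trim = 0.3, abs_trim = 0.05) {
  M <- log2((obs / lib_obs) / (ref / lib_ref))
  A <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  keep <- is.finite(M) & is.finite(A)
  M <- M[keep]; A <- A[keep]; w <- w[keep]
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1;      hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  inwin <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  2^(sum(M[inwin] / w[inwin]) / sum(1 / w[inwin]))
}

oracle_tmm <- function(m) {
  lib <- colSums(m)
  uq <- apply(sweep(m, 2, lib, `/`), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    oracle_tmm_pair(m[, j], m[, ref], lib[j], lib[ref])
  }, numeric(1))
  f / exp(mean(log(f)))
}

# interval union by boolean mask over a small integer chromosome
oracle_union <- function(intervals, chrom_len) {
  mask <- logical(chrom_len)
  for (i in seq_len(nrow(intervals))) {
    mask[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# quadratic-scan overlap counting, half-open convention
oracle_count_overlaps <- function(fragments, peaks) {
  vapply(seq_len(nrow(peaks)), function(i) {
    sum(fragments$start < peaks$end[i] & fragments$end > peaks$start[i])
  }, integer(1))
}

# exhaustive taxonomy by pairwise case checking
oracle_taxonomy <- function(temp, sex) {
  if (sex == "male-biased" && temp == "Temp-up") return("M-T_up")
  if (sex == "male-biased" && temp == "Temp-down") return("M-T_down")
  if (sex == "female-biased" && temp == "Temp-up") return("F-T_up")
  if (sex == "female-biased" && temp == "Temp-down") return("F-T_down")
  "none"
}

# residual-minimizing isoform fractions by 0.01-step simplex grid search;
# the depth is profiled out analytically for each candidate fraction vector
oracle_grid_fractions <- function(b, M, step = 0.01) {
  best <- NULL; best_res <- Inf
  for (f1 in seq(0, 1, by = step)) {
    for (f2 in seq(0, 1 - f1, by = step)) {
      f <- c(f1, f2, 1 - f1 - f2)
      v <- as.numeric(M %*% f)
      d <- sum(v * b) / sum(v * v)  # least-squares depth for this mixture
      res <- sqrt(sum((d * v - b)^2))
      if (res < best_res) {
        best_res <- res
        best <- f
      }
    }
  }
  list(fractions = best, residual = best_res)
}

# minimal deterministic sample sheet for hand-built count fixtures
toy_samples <- function(groups, reps = 1, stage = 20) {
  grid <- expand.grid(replicate = seq_len(reps), group = groups,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = sprintf("%s_%d_r%d", grid$group, stage, grid$replicate),
    group = grid$group,
    stage = stage,
    replicate = grid$replicate,
    temperature = as.integer(sub("^X[XY](\\d+).*$", "\\1", grid$group)))
}
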