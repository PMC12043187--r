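#' Length-weighted mean coverage of a genomic segment
#'
#' Averages per-base depth over a 0-based half-open segment; bases not
#' covered by any track block count as depth 0.
#'
#' @param track Coverage track tibble (`chrom`, `start`, `end`, `depth`).
#' @param start,end Segment coordinates (half-open; `end > start`).
#' @return The mean depth over the segment.
#' @export
segment_mean_coverage <- function(track, start, end) {
  if (end <= start) abort("zero- or negative-length segment")
  ov_start <- pmax(track$start, start)
  ov_end <- pmin(track$end, end)
  w <- pmax(ov_end - ov_start, 0)
  sum(w * track$depth) / (end - start)
}

#' Mean coverage of every segment in a gene model
#'
#' @param track Coverage track tibble.
#' @param model Gene model tibble (see [kdm6bb_model()]).
#' @return `model` with an added `mean_coverage` column.
#' @export
coverage_by_segment <- function(track, model) {
  model$mean_coverage <- purrr::map2_dbl(
    model$start, model$end, ~segment_mean_coverage(track, .x, .y))
  model
}

tagged_segment <- function(model, tag) {
  row <- model[model$tag == tag, ]
  if (nrow(row) != 1) abort(sprintf("gene model lacks tagged segment %s", tag))
  row
}

#' Intron inclusion ratio from per-base coverage
#'
#' The retention statistic of the alternatively spliced intron: mean per-base
#' coverage of the intron divided by the average of the mean per-base
#' coverages of the two flanking exons. With `pooled = TRUE` the denominator
#' is instead the base-pair-pooled mean over both exons (length-weighted);
#' the two readings coincide when the exons have equal length.
#'
#' @param track Coverage track tibble.
#' @param model Gene model with the tagged segments present.
#' @param intron Tag of the intron (default `"I8"`).
#' @param flanks Tags of the two flanking exons.
#' @param pooled Pool exon bases instead of averaging exon means.
#' @return The ratio; `NA` with attribute `undefined = TRUE` when the exon
#'   coverage is zero (never infinity).
#' @examples
#' model <- kdm6bb_model()
#' track <- simulate_coverage(model, isoform_truth(c(I5_dI8 = 0.7,
#'   dI5_I8 = 0.3, dI5_dI8 = 0)), seed = 1)
#' intron_inclusion_ratio(track, model)
#' @export
intron_inclusion_ratio <- function(track, model, intron = "I8",
                                   flanks = c("E8", "E9"), pooled = FALSE) {
  stopifnot(length(flanks) == 2)
  iseg <- tagged_segment(model, intron)
  e1 <- tagged_segment(model, flanks[1])
  e2 <- tagged_segment(model, flanks[2])
  num <- segment_mean_coverage(track, iseg$start, iseg$end)
  den <- if (pooled) {
    w1 <- e1$end - e1$start; w2 <- e2$end - e2$start
    (segment_mean_coverage(track, e1$start, e1$end) * w1 +
       segment_mean_coverage(track, e2$start, e2$end) * w2) / (w1 + w2)
  } else {
    (segment_mean_coverage(track, e1$start, e1$end) +
       segment_mean_coverage(track, e2$start, e2$end)) / 2
  }
  if (den == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  num / den
}

#' Estimate isoform fractions from segment coverage
#'
#' Models the observed mean coverages of the measured segments (constitutive
#' exons pooled, plus each alternatively retained intron) as the inclusion
#' matrix of the isoform set times a depth-scaled fraction vector, solved by
#' non-negative least squares; fractions are the non-negative solution
#' renormalized to sum 1 and the overall depth falls out as the solution's
#' sum. Multiplying all coverages by a constant leaves the fractions
#' unchanged.
#'
#' The default three-isoform universe (`I5_dI8`, `dI5_I8`, `dI5_dI8`) is
#' identifiable from coverage alone; isoform sets whose inclusion matrix is
#' rank-deficient over the measured segments (for instance adding the doubly
#' retained `I5_I8` form) are rejected with advice to use junction evidence.
#'
#' @param track Coverage track tibble.
#' @param model Gene model with tags `I5`, `I8` and exon segments.
#' @param isoforms Isoform labels; `d` before an intron tag marks it
#'   spliced out.
#' @return An object of class `isoform_fit`; [tidy()] gives the fraction
#'   table and [glance()] the residual, depth and method.
#' @export
estimate_isoform_fractions <- function(track, model,
                                       isoforms = c("I5_dI8", "dI5_I8",
                                                    "dI5_dI8")) {
  exons <- model[grepl("^exon_", model$role), ]
  alt <- c("I5", "I8")
  for (tag in alt) tagged_segment(model, tag)
  # constitutive exons are included by every isoform: pooled length-weighted
  # mean over all exon bases
  w <- exons$end - exons$start
  exon_cov <- sum(purrr::map2_dbl(exons$start, exons$end,
                                  ~segment_mean_coverage(track, .x, .y)) * w) /
    sum(w)
  b <- c(exons = exon_cov,
         stats::setNames(purrr::map_dbl(alt, function(tag) {
           seg <- tagged_segment(model, tag)
           segment_mean_coverage(track, seg$start, seg$end)
         }), alt))
  includes <- function(iso, tag) {
    tokens <- strsplit(iso, "_")[[1]]
    tag %in% tokens[!startsWith(tokens, "d")]
  }
  M <- rbind(exons = rep(1, length(isoforms)),
             I5 = vapply(isoforms, includes, logical(1), tag = "I5"),
             I8 = vapply(isoforms, includes, logical(1), tag = "I8"))
  storage.mode(M) <- "double"
  colnames(M) <- isoforms
  if (qr(M)$rank < ncol(M)) {
    abort(paste("isoform set is not identifiable from segment coverage;",
                "junction-read evidence is required for this set"))
  }
  fit <- pracma::lsqnonneg(M, unname(b))
  g <- fit$x
  if (sum(g) == 0) abort("no coverage signal: all fitted abundances are zero")
  structure(
    list(fractions = stats::setNames(g / sum(g), isoforms),
         depth = sum(g),
         residual = sqrt(sum((M %*% g - b)^2)),
         method = "nnls_coverage",
         isoforms = isoforms),
    class = "isoform_fit")
}

#' @export
print.isoform_fit <- function(x, ...) {
  cat("Isoform fractions (", x$method, ")\n", sep = "")
  print(round(x$fractions, 4))
  cat("depth:", signif(x$depth, 4), " residual:", signif(x$residual, 4), "\n")
  invisible(x)
}

#' @rdname estimate_isoform_fractions
#' @param x An `isoform_fit` object.
#' @param ... Unused.
#' @export
tidy.isoform_fit <- function(x, ...) {
  tibble(isoform = names(x$fractions), fraction = unname(x$fractions))
}

#' @rdname estimate_isoform_fractions
#' @export
glance.isoform_fit <- function(x, ...) {
  tibble(depth = x$depth, residual = x$residual, method = x$method,
         n_isoforms = length(x$fractions))
}
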