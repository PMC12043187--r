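# All genomic coordinates in this package are BED-convention: 0-based,
# half-open [start, end). GRanges (1-based, closed) is used internally for
# the interval arithmetic; the +1/-0 shifts live only in these two helpers.

tbl_to_granges <- function(x) {
  validate_intervals(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

granges_to_tbl <- function(gr) {
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

validate_intervals <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    abort(sprintf("malformed interval at line %d: [%s, %s)",
                  bad[1], x$start[bad[1]], x$end[bad[1]]))
  }
  invisible(x)
}

#' Merge peak calls into a reference peak set
#'
#' Unions overlapping-or-touching intervals (per chromosome) from all
#' samples of one histone mark into a disjoint, sorted reference peak set.
#' Intervals that touch end-to-start are joined. Each merged peak records
#' how many samples contributed at least one peak to it.
#'
#' @param peaks Tibble with `chrom`, `start`, `end` and optionally `sample`.
#' @return Tibble `chrom`, `start`, `end`, `peak_id`, `n_samples`, sorted
#'   and pairwise disjoint.
#' @export
merge_peaks <- function(peaks) {
  gr <- tbl_to_granges(peaks)
  merged <- GenomicRanges::reduce(sort(gr), min.gapwidth = 1L)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  sample_of <- if ("sample" %in% names(peaks)) peaks$sample else
    rep("s1", nrow(peaks))
  n_samples <- vapply(
    split(sample_of[S4Vectors::subjectHits(hits)],
          factor(S4Vectors::queryHits(hits), levels = seq_along(merged))),
    function(s) length(unique(s)), integer(1))
  out <- granges_to_tbl(merged)
  out$peak_id <- sprintf("peak%05d", seq_len(nrow(out)))
  out$n_samples <- unname(n_samples)
  out
}

gene_spans <- function(gene_models) {
  if (all(c("role", "start", "end") %in% names(gene_models)) &&
      any(grepl("^exon_", gene_models$role))) {
    gene_models <- gene_models |>
      dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       .groups = "drop")
  }
  gene_models |>
    dplyr::mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end),
                  tes = ifelse(.data$strand == "+", .data$end, .data$start))
}

#' Annotate peaks to genes and genomic regions
#'
#' Assigns each peak to its nearest transcription start site (by peak
#' midpoint) and classifies it as `promoter` (overlapping the strand-aware
#' window `[TSS - promoter_up, TSS + promoter_down)`), `genic` (overlapping
#' the gene span beyond the promoter window) or `intergenic`, with
#' precedence promoter > genic > intergenic. The signed distance to the TSS
#' is negative upstream of the gene. A peak equidistant from two TSSs is
#' assigned to the lexicographically smaller `gene_id` and flagged; peaks on
#' chromosomes absent from the models become unassigned intergenic, flagged.
#'
#' @param peaks Tibble of peak intervals (needs `chrom`, `start`, `end`;
#'   `peak_id` kept if present).
#' @param gene_models Gene-span tibble (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`) or a segment-level model as from [kdm6bb_model()].
#' @param promoter_up,promoter_down Promoter window, bp up/downstream of the
#'   TSS.
#' @return `peaks` with added `gene_id`, `region`, `distance_to_tss`,
#'   `tie`, `no_model` columns.
#' @export
annotate_peaks <- function(peaks, gene_models,
                           promoter_up = 3000, promoter_down = 3000) {
  validate_intervals(peaks)
  genes <- gene_spans(gene_models)
  mid <- (peaks$start + peaks$end) %/% 2L

  out <- peaks
  out$gene_id <- NA_character_
  out$region <- "intergenic"
  out$distance_to_tss <- NA_integer_
  out$tie <- FALSE
  out$no_model <- !(peaks$chrom %in% genes$chrom)

  for (i in which(!out$no_model)) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    d_abs <- abs(mid[i] - g$tss)
    near <- which(d_abs == min(d_abs))
    if (length(near) > 1) {
      out$tie[i] <- TRUE
      near <- near[order(g$gene_id[near])][1]
    }
    gn <- g[near, ]
    out$gene_id[i] <- gn$gene_id
    out$distance_to_tss[i] <- if (gn$strand == "+") mid[i] - gn$tss else
      gn$tss - mid[i]
    prom <- if (gn$strand == "+") {
      c(gn$tss - promoter_up, gn$tss + promoter_down)
    } else {
      c(gn$tss - promoter_down, gn$tss + promoter_up)
    }
    overlaps <- function(a, b) peaks$start[i] < b && peaks$end[i] > a
    out$region[i] <-
      if (overlaps(prom[1], prom[2])) "promoter"
      else if (overlaps(min(gn$start, gn$end), max(gn$start, gn$end))) "genic"
      else "intergenic"
  }
  if (any(out$tie)) inform(sprintf("%d peak(s) tied between TSSs", sum(out$tie)))
  out
}

#' Count fragments overlapping reference peaks
#'
#' A fragment counts toward a peak when the two intervals share at least one
#' base (half-open coordinates: a fragment abutting a peak end does not
#' overlap).
#'
#' @param fragments Tibble of fragment intervals; an optional `sample`
#'   column yields one count column per sample.
#' @param peaks Reference peak tibble (e.g. from [merge_peaks()]).
#' @return `peaks` with one `count` column, or one column per sample.
#' @export
count_fragments <- function(fragments, peaks) {
  pk <- tbl_to_granges(peaks)
  out <- peaks
  if ("sample" %in% names(fragments)) {
    for (s in unique(fragments$sample)) {
      fr <- tbl_to_granges(fragments[fragments$sample == s, ])
      out[[s]] <- GenomicRanges::countOverlaps(pk, fr, minoverlap = 1L)
    }
  } else {
    out$count <- GenomicRanges::countOverlaps(pk, tbl_to_granges(fragments),
                                              minoverlap = 1L)
  }
  out
}

#' Correlate expression with histone-mark signal across temperature-sex groups
#'
#' For each unit (gene, or cluster of genes) and one histone mark: the x
#' profile is the z-scaled TMM expression of the unit over the five
#' temperature-sex group means (averaged over member genes after scaling,
#' for clusters); the y profile is the mean of z-scaled CMM peak signals
#' over the unit's promoter and/or genic peaks; the record is their Pearson
#' correlation over the groups.
#'
#' @param expr_norm Normalized expression tibble.
#' @param expr_samples Sample sheet for `expr_norm`.
#' @param peak_norm Normalized (CMM) peak-count tibble.
#' @param peak_samples Sample sheet for `peak_norm`.
#' @param annotation [annotate_peaks()] output carrying `peak_id`,
#'   `gene_id`, `region`.
#' @param genes Tibble with `gene_id` and, for `unit = "cluster"`, a
#'   `cluster` column.
#' @param mark Mark label stored in the records.
#' @param unit `"gene"` for per-gene records, `"cluster"` for per-cluster.
#' @param region Which annotated peaks feed the mark profile.
#' @param stage Developmental stage of the group means.
#' @param groups The group profile; Pearson needs at least 3 points.
#' @return A tibble of correlation records: `unit_id`, `mark`, `pcc`,
#'   `n_points`, `n_genes`, `n_peaks`. Units without usable peaks are
#'   skipped with a message.
#' @export
integrate_correlation <- function(expr_norm, expr_samples, peak_norm,
                                  peak_samples, annotation, genes,
                                  mark = "mark", unit = c("gene", "cluster"),
                                  region = c("both", "promoter", "genic"),
                                  stage = 20,
                                  groups = c("XX28F", "XY28M", "XX36F",
                                             "XX36P", "XY36M")) {
  unit <- match.arg(unit)
  region <- match.arg(region)
  if (length(groups) < 3) abort("need at least 3 group profile points")
  keep_regions <- if (region == "both") c("promoter", "genic") else region

  group_profile <- function(mat, samples) {
    cols <- lapply(groups, function(g) {
      keep <- samples$group == g & samples$stage == stage
      if (!any(keep)) abort(sprintf("no samples for group %s at stage %s",
                                    g, stage))
      rowMeans(mat[, samples$sample_id[keep], drop = FALSE])
    })
    matrix(unlist(cols), nrow = nrow(mat),
           dimnames = list(rownames(mat), groups))
  }
  ex <- group_profile(counts_to_matrix(expr_norm), expr_samples)
  pk <- group_profile(counts_to_matrix(peak_norm), peak_samples)

  ann <- annotation[annotation$region %in% keep_regions &
                      !is.na(annotation$gene_id) &
                      annotation$peak_id %in% rownames(pk), ]
  zrow <- function(m) t(apply(m, 1, zscale))

  genes <- as_tibble(genes)
  units <- if (unit == "gene") {
    split(genes$gene_id, genes$gene_id)
  } else {
    if (!"cluster" %in% names(genes)) abort("`genes` needs a cluster column")
    split(genes$gene_id, genes$cluster)
  }
  recs <- purrr::imap(units, function(gs, uid) {
    gs <- intersect(gs, rownames(ex))
    pks <- ann$peak_id[ann$gene_id %in% gs]
    if (length(gs) == 0 || length(pks) == 0) {
      inform(sprintf("unit %s skipped: no expression or no annotated peaks",
                     uid))
      return(NULL)
    }
    x <- colMeans(zrow(ex[gs, , drop = FALSE]))
    y <- colMeans(zrow(pk[pks, , drop = FALSE]))
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      inform(sprintf("unit %s skipped: degenerate profile", uid))
      return(NULL)
    }
    tibble(unit_id = uid, mark = mark, pcc = stats::cor(x, y),
           n_points = length(groups), n_genes = length(gs),
           n_peaks = length(pks))
  })
  dplyr::bind_rows(recs)
}

#' Screen correlation records by a signed threshold
#'
#' A unit is retained for a mark when its correlation lies strictly beyond
#' the signed threshold: below `-threshold` for repressive-configured marks
#' (expected sign -1, e.g. H3K27me3), above `+threshold` for
#' activating-configured marks (expected sign +1, e.g. H3K4me3).
#'
#' @param records [integrate_correlation()] output.
#' @param threshold Absolute correlation cutoff in (0, 1).
#' @param sign_config Named vector, mark -> expected sign (-1 or +1).
#' @return `records` with `expected_sign` and `retained` columns; the
#'   configuration is attached as attribute `"sign_config"`.
#' @export
screen_by_pcc <- function(records, threshold = 0.5,
                          sign_config = c(H3K27me3 = -1, H3K4me3 = 1)) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  unknown <- setdiff(unique(records$mark), names(sign_config))
  if (length(unknown)) {
    abort(sprintf("no expected sign configured for mark(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  out <- records |>
    dplyr::mutate(expected_sign = unname(sign_config[.data$mark]),
                  retained = ifelse(.data$expected_sign < 0,
                                    .data$pcc < -threshold,
                                    .data$pcc > threshold))
  attr(out, "sign_config") <- sign_config
  out
}
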