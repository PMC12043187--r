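# File round-trips for the pipeline's tabular and genomic formats. TSV/CSV
# go through readr; BED/bedGraph/BED12 go through rtracklayer's importers so
# the on-disk convention (0-based half-open) is handled by the standard
# toolchain, and are converted at the boundary to the package's tibbles.

#' Read and write pipeline tables
#'
#' `read_counts_tsv()`/`write_counts_tsv()` handle the wide genes-by-samples
#' counts table (first column `gene_id`, header = sample ids);
#' `read_sample_sheet()`/`write_sample_sheet()` and
#' `read_cohort_csv()`/`write_cohort_csv()` their CSV companions.
#'
#' @param path File path.
#' @param x Table to write.
#' @return The tibble (readers) or `path`, invisibly (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname table_io
#' @export
write_counts_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_sample_sheet <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname table_io
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_cohort_csv <- read_sample_sheet

#' @rdname table_io
#' @export
write_cohort_csv <- write_sample_sheet

#' Read and write genomic intervals and coverage
#'
#' BED intervals and bedGraph coverage tracks, 0-based half-open on disk and
#' in the returned tibbles. `read_bed12_model()` reads a BED12 gene model
#' and expands its blocks into the package's segment representation
#' (`exon_k` segments with `E<k>` tags and the `intron_k`/`I<k>` gaps
#' between them, numbered 5' to 3' on the annotated strand).
#'
#' @param path File path.
#' @param x Tibble to write (`chrom`, `start`, `end` plus `depth` for
#'   bedGraph; optional `name` column for BED).
#' @return A tibble (readers) or `path`, invisibly (writers).
#' @name genomic_io
NULL

#' @rdname genomic_io
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_tbl(gr)
  if (!is.null(gr$name)) out$name <- gr$name
  out
}

#' @rdname genomic_io
#' @export
write_bed <- function(x, path) {
  gr <- tbl_to_granges(x)
  if ("name" %in% names(x)) gr$name <- x$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname genomic_io
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- granges_to_tbl(gr)
  out$depth <- gr$score
  out
}

#' @rdname genomic_io
#' @export
write_bedgraph <- function(x, path) {
  gr <- tbl_to_granges(x)
  gr$score <- x$depth
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname genomic_io
#' @export
read_bed12_model <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  blocks <- rtracklayer::blocks(gr)
  purrr::map_dfr(seq_along(gr), function(i) {
    strand <- as.character(GenomicRanges::strand(gr[i]))
    if (strand == "*") strand <- "+"
    ex <- granges_to_tbl(blocks[[i]])
    ex <- ex[order(ex$start), ]
    n <- nrow(ex)
    segs <- dplyr::bind_rows(
      dplyr::mutate(ex, kind = "exon"),
      if (n > 1) tibble(chrom = ex$chrom[-n], start = ex$end[-n],
                        end = ex$start[-1], kind = "intron"))
    segs <- segs[order(segs$start), ]
    # number 5'->3' on the strand, separately for exons and introns
    idx <- integer(nrow(segs))
    for (kind in unique(segs$kind)) {
      which_k <- which(segs$kind == kind)
      ranks <- seq_along(which_k)
      idx[which_k] <- if (strand == "+") ranks else rev(ranks)
    }
    tibble(gene_id = gr$name[i] %||% sprintf("gene%d", i),
           chrom = segs$chrom, strand = strand,
           role = paste0(segs$kind, "_", idx),
           tag = paste0(ifelse(segs$kind == "exon", "E", "I"), idx),
           start = segs$start, end = segs$end)
  })
}

#' @rdname genomic_io
#' @param model Segment-level gene model tibble (see [kdm6bb_model()]).
#' @export
write_bed12_model <- function(model, path) {
  per_gene <- split(model, model$gene_id)
  grl <- purrr::map(per_gene, function(m) {
    ex <- m[grepl("^exon_", m$role), ]
    ex <- ex[order(ex$start), ]
    GenomicRanges::GRanges(
      ex$chrom[1],
      IRanges::IRanges(min(ex$start) + 1L, max(ex$end)),
      strand = m$strand[1],
      name = m$gene_id[1],
      blocks = IRanges::IRangesList(
        IRanges::IRanges(ex$start - min(ex$start) + 1L,
                         width = ex$end - ex$start)))
  })
  gr <- do.call(c, unname(grl))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
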