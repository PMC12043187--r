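test_that("peak merging unions touching intervals and matches the mask oracle", {
  got <- merge_peaks(tibble::tibble(chrom = "c1", start = c(100, 150),
                                    end = c(200, 250)))
  expect_equal(got[c("start", "end")], tibble::tibble(start = 100, end = 250))

  disjoint <- merge_peaks(tibble::tibble(chrom = "c1", start = c(0, 60),
                                         end = c(50, 80)))
  expect_equal(disjoint$start, c(0, 60))
  expect_equal(disjoint$end, c(50, 80))

  # end-to-start touching intervals are joined
  touching <- merge_peaks(tibble::tibble(chrom = "c1", start = c(0, 50),
                                         end = c(50, 80)))
  expect_equal(nrow(touching), 1)

  set.seed(61)
  for (i in 1:10) {
    iv <- tibble::tibble(chrom = "c1",
                         start = sample(0:9900, 100, TRUE))
    iv$end <- iv$start + sample(1:100, 100, TRUE)
    got <- merge_peaks(iv)
    exp <- oracle_union(iv, chrom_len = 10100)
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
    # disjoint and sorted
    expect_true(all(diff(got$start) > 0))
    expect_true(all(got$start[-1] > got$end[-nrow(got)]))
  }
  expect_error(merge_peaks(tibble::tibble(chrom = "c1", start = 10, end = 10)),
               "malformed interval")
})

test_that("merged peaks record contributing sample counts", {
  iv <- tibble::tibble(chrom = "c1",
                       start = c(100, 150, 500), end = c(200, 250, 600),
                       sample = c("s1", "s2", "s1"))
  got <- merge_peaks(iv)
  expect_equal(got$n_samples, c(2, 1))
})

test_that("peak annotation applies the promoter window, precedence and tie rule", {
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "c1",
                          strand = c("+", "-"),
                          start = c(10000, 40000), end = c(20000, 48000))
  # centred 500 bp upstream of gA's plus-strand TSS
  up <- annotate_peaks(tibble::tibble(chrom = "c1", start = 9400, end = 9600),
                       genes)
  expect_equal(up$gene_id, "gA")
  expect_equal(up$region, "promoter")
  expect_equal(up$distance_to_tss, -500)

  # mid-gene-body beyond the 3 kb promoter window
  body <- annotate_peaks(tibble::tibble(chrom = "c1", start = 14950,
                                        end = 15050), genes)
  expect_equal(body$region, "genic")
  expect_equal(body$gene_id, "gA")

  # far from everything
  far <- annotate_peaks(tibble::tibble(chrom = "c1", start = 30000,
                                       end = 30100), genes)
  expect_equal(far$region, "intergenic")

  # minus-strand promoter: TSS at end coordinate, upstream is to the right
  mup <- annotate_peaks(tibble::tibble(chrom = "c1", start = 48400,
                                       end = 48600), genes)
  expect_equal(mup$gene_id, "gB")
  expect_equal(mup$region, "promoter")
  expect_equal(mup$distance_to_tss, -500)

  # constructed equidistant ties resolve to the lexicographically smaller id
  tie_genes <- tibble::tibble(gene_id = c("gZ", "gA"), chrom = "c1",
                              strand = "+", start = c(1000, 3000),
                              end = c(1500, 3500))
  tie <- suppressMessages(
    annotate_peaks(tibble::tibble(chrom = "c1", start = 1995, end = 2005),
                   tie_genes))
  expect_equal(tie$gene_id, "gA")
  expect_true(tie$tie)

  # chromosome absent from the models
  off <- annotate_peaks(tibble::tibble(chrom = "c9", start = 0, end = 100),
                        genes)
  expect_true(off$no_model)
  expect_equal(off$region, "intergenic")
  expect_true(is.na(off$gene_id))
})

test_that("fragment counting matches the quadratic oracle and the half-open rule", {
  peaks <- tibble::tibble(chrom = "c1", start = 100, end = 200,
                          peak_id = "p1")
  frags <- tibble::tibble(chrom = "c1",
                          start = c(110, 150, 190, 300),
                          end = c(130, 170, 210, 320))
  expect_equal(count_fragments(frags, peaks)$count, 3L)
  # a fragment abutting the peak end does not overlap
  abut <- tibble::tibble(chrom = "c1", start = 200, end = 250)
  expect_equal(count_fragments(abut, peaks)$count, 0L)
  before <- tibble::tibble(chrom = "c1", start = 50, end = 100)
  expect_equal(count_fragments(before, peaks)$count, 0L)

  set.seed(71)
  pk <- tibble::tibble(chrom = "c1", start = sort(sample(seq(0, 9500, 300), 20)))
  pk$end <- pk$start + 150
  fr <- tibble::tibble(chrom = "c1", start = sample(0:9900, 1000, TRUE))
  fr$end <- fr$start + sample(20:80, 1000, TRUE)
  expect_equal(count_fragments(fr, pk)$count,
               oracle_count_overlaps(fr, pk))
})

test_that("correlation records reproduce hand-computed Pearson coefficients", {
  groups <- c("XX28F", "XY28M", "XX36F", "XX36P", "XY36M")
  samples <- tibble::tibble(sample_id = paste0(groups, "_20_r1"),
                            group = groups, stage = 20, replicate = 1)
  expr <- cbind(tibble::tibble(gene_id = "g1"),
                tibble::as_tibble(matrix(c(1, 2, 3, 4, 5), nrow = 1,
                                         dimnames = list(NULL, samples$sample_id))))
  ann <- tibble::tibble(peak_id = "p1", gene_id = "g1", region = "promoter")
  mkpeak <- function(y) {
    cbind(tibble::tibble(peak_id = "p1"),
          tibble::as_tibble(matrix(y, nrow = 1,
                                   dimnames = list(NULL, samples$sample_id))))
  }
  rec_same <- integrate_correlation(expr, samples, mkpeak(c(1, 2, 3, 4, 5)),
                                    samples, ann,
                                    tibble::tibble(gene_id = "g1"))
  expect_equal(rec_same$pcc, 1)
  rec_neg <- integrate_correlation(expr, samples, mkpeak(c(5, 4, 3, 2, 1)),
                                   samples, ann,
                                   tibble::tibble(gene_id = "g1"))
  expect_equal(rec_neg$pcc, -1)
  # x = 1..5 vs y = (2,1,4,3,5): cov 8 / sqrt(10 * 10) = 0.8
  rec08 <- integrate_correlation(expr, samples, mkpeak(c(2, 1, 4, 3, 5)),
                                 samples, ann,
                                 tibble::tibble(gene_id = "g1"))
  expect_equal(rec08$pcc, 0.8)
  expect_equal(rec08$n_points, 5)

  # a unit with no annotated peaks is skipped with a message
  expect_message(
    out <- integrate_correlation(expr, samples, mkpeak(c(1, 2, 3, 4, 5)),
                                 samples, ann,
                                 tibble::tibble(gene_id = c("g1", "g9"))),
    "skipped")
  expect_equal(nrow(out), 1)
})

test_that("the correlation screen retains only signed exceedances", {
  rec <- tibble::tibble(unit_id = c("a", "b", "c", "d"),
                        mark = c("H3K27me3", "H3K27me3", "H3K4me3", "H3K4me3"),
                        pcc = c(-0.6, -0.4, 0.6, 0.5), n_points = 5)
  scr <- screen_by_pcc(rec)
  expect_equal(scr$retained, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(screen_by_pcc(dplyr::mutate(rec, mark = "H3K9me3")),
               "no expected sign")
  expect_error(screen_by_pcc(rec, threshold = 1.2), "threshold")
})
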