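test_that("count simulation is seeded, correctly sized and validates designs", {
  d <- sim_design(n_genes = 100)
  a <- simulate_counts(d, seed = 11)
  b <- simulate_counts(d, seed = 11)
  expect_identical(a, b)
  # 5 groups x 4 stages x 3 replicates
  expect_equal(dim(a$counts), c(100, 1 + 60))
  expect_equal(nrow(a$samples), 60)
  expect_false(identical(a$counts, simulate_counts(d, seed = 12)$counts))

  expect_error(
    sim_design(n_genes = 10, cluster_spec = tibble::tibble(
      cluster = "Temp-up", n_genes = 50L, log2_effect = 2)),
    "exceed")
  expect_error(sim_design(cluster_spec = tibble::tibble(
    cluster = "bogus", n_genes = 1L, log2_effect = 1)), "unknown cluster")
})

test_that("planted effects land in the right groups", {
  d <- sim_design(
    n_genes = 400, nb_dispersion = 0.01, lib_size_cv = 0,
    cluster_spec = tibble::tibble(
      cluster = c("Temp-up", "Temp-down", "male-biased", "female-biased"),
      n_genes = c(50L, 50L, 30L, 30L), log2_effect = 2))
  sim <- simulate_counts(d, seed = 3)
  m <- as.matrix(sim$counts[-1])
  hot <- sim$samples$temperature == 36
  lfc_temp <- log2(rowMeans(m[, hot]) / rowMeans(m[, !hot]))
  up <- sim$truth$cluster == "Temp-up"
  dn <- sim$truth$cluster == "Temp-down"
  expect_gt(min(lfc_temp[up]), 1.5)
  expect_lt(max(lfc_temp[dn]), -1.5)
  male <- sim$samples$group == "XY28M"
  fem <- sim$samples$group == "XX28F"
  lfc_sex <- log2(rowMeans(m[, male]) / rowMeans(m[, fem]))
  expect_gt(min(lfc_sex[sim$truth$cluster == "male-biased"]), 1.5)
  expect_lt(max(lfc_sex[sim$truth$cluster == "female-biased"]), -1.5)
})

test_that("peak simulation plants couplings of the requested sign", {
  d <- sim_design(n_genes = 40, cluster_spec = tibble::tibble(
    cluster = "Temp-up", n_genes = 20L, log2_effect = 2))
  pk1 <- simulate_peak_counts(d, coupling = c(H3K27me3 = -1), seed = 5,
                              nb_dispersion = 0.01)
  pk2 <- simulate_peak_counts(d, coupling = c(H3K27me3 = -1), seed = 5,
                              nb_dispersion = 0.01)
  expect_identical(pk1, pk2)
  expect_error(simulate_peak_counts(d, coupling = c(1), seed = 1), "named")
  expect_error(simulate_peak_counts(d, coupling = c(H3K4me3 = 0.5), seed = 1),
               "signs")

  # negative coupling: planted genes' peak means move against expression
  sim <- simulate_counts(d, seed = 5)
  truth_up <- sim$truth$gene_id[sim$truth$cluster == "Temp-up"]
  pkm <- as.matrix(pk1$counts[-1])
  rownames(pkm) <- pk1$counts$peak_id
  hot <- pk1$samples$temperature == 36
  prom <- pk1$peaks[pk1$peaks$gene_id %in% truth_up, ]
  lfc <- log2((rowMeans(pkm[prom$peak_id, hot]) + 0.5) /
                (rowMeans(pkm[prom$peak_id, !hot]) + 0.5))
  expect_lt(median(lfc), 0)

  # sign 0 decouples: peak fold changes centred at zero
  pk0 <- simulate_peak_counts(d, coupling = c(H3K9me2 = 0), seed = 6,
                              nb_dispersion = 0.01)
  pkm0 <- as.matrix(pk0$counts[-1])
  lfc0 <- log2((rowMeans(pkm0[, hot]) + 0.5) / (rowMeans(pkm0[, !hot]) + 0.5))
  expect_lt(abs(median(lfc0)), 0.1)
})

test_that("coverage simulation obeys the mixture expectation at zero noise", {
  model <- kdm6bb_model()
  # pure I8-retaining isoform: I8 at exon depth, I5 empty
  pure <- simulate_coverage(model, isoform_truth(
    c(I5_dI8 = 0, dI5_I8 = 1, dI5_dI8 = 0), depth = 50), seed = 1)
  i8 <- model[model$tag == "I8", ]
  i5 <- model[model$tag == "I5", ]
  e8 <- model[model$tag == "E8", ]
  expect_equal(segment_mean_coverage(pure, i8$start, i8$end), 50)
  expect_equal(segment_mean_coverage(pure, i5$start, i5$end), 0)
  expect_equal(segment_mean_coverage(pure, e8$start, e8$end), 50)

  # 0.7/0.3 mixture: intron coverage is the included fraction times depth
  mix <- simulate_coverage(model, isoform_truth(
    c(I5_dI8 = 0.7, dI5_I8 = 0.3, dI5_dI8 = 0), depth = 50), seed = 1)
  expect_equal(segment_mean_coverage(mix, i8$start, i8$end) /
                 segment_mean_coverage(mix, e8$start, e8$end), 0.3)
  expect_equal(segment_mean_coverage(mix, i5$start, i5$end) / 50, 0.7)

  expect_error(isoform_truth(c(I5_dI8 = 0.5, dI5_I8 = 0.4, dI5_dI8 = 0)),
               "sum to 1")
  expect_error(
    simulate_coverage(model[model$tag != "I8", ],
                      isoform_truth(), seed = 1),
    "I8")

  noisy1 <- simulate_coverage(model, isoform_truth(noise_cv = 0.1), seed = 9)
  noisy2 <- simulate_coverage(model, isoform_truth(noise_cv = 0.1), seed = 9)
  expect_identical(noisy1, noisy2)
})

test_that("cohort simulation plants conversion outcomes and consistent markers", {
  none <- simulate_cohort(cohort_spec(conversion_prob = 0), seed = 2)
  expect_equal(glance(reversal_ratio(none))$estimate, 0)
  all_conv <- simulate_cohort(cohort_spec(conversion_prob = 1), seed = 2)
  expect_equal(glance(reversal_ratio(all_conv))$estimate, 1)

  cohort <- simulate_cohort(cohort_spec(conversion_prob = 0.75), seed = 4)
  expect_equal(nrow(cohort), 180)
  # marker noise is bounded, so the classifier always recovers the truth
  called <- classify_cohort(cohort)
  expect_identical(called$phenotype, cohort$phenotype_truth)
  expect_identical(simulate_cohort(cohort_spec(), seed = 4),
                   simulate_cohort(cohort_spec(), seed = 4))
})
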