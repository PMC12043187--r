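test_that("temperature clustering recovers planted labels and is seeded", {
  d <- sim_design(
    n_genes = 200, nb_dispersion = 0.05,
    cluster_spec = tibble::tibble(cluster = c("Temp-up", "Temp-down"),
                                  n_genes = c(120L, 80L), log2_effect = 2))
  sim <- simulate_counts(d, seed = 41)
  norm <- normalize_counts(sim$counts)
  genes <- sim$truth$gene_id[sim$truth$cluster != "null"]
  tc <- temperature_clusters(norm, sim$samples, genes, seed = 1)
  expect_identical(tidy(tc),
                   tidy(temperature_clusters(norm, sim$samples, genes,
                                             seed = 1)))
  joined <- dplyr::inner_join(tidy(tc), sim$truth, by = "gene_id")
  expect_gte(mean(joined$temp_cluster == joined$cluster), 0.95)
  expect_error(temperature_clusters(norm, sim$samples, genes[1], k = 2),
               "fewer genes")
})

test_that("two opposite genes each get the semantically correct label", {
  d <- sim_design(
    n_genes = 2, nb_dispersion = 1e-3,
    cluster_spec = tibble::tibble(cluster = c("Temp-up", "Temp-down"),
                                  n_genes = c(1L, 1L), log2_effect = 3))
  sim <- simulate_counts(d, seed = 8)
  norm <- normalize_counts(sim$counts)
  tc <- tidy(temperature_clusters(norm, sim$samples, sim$truth$gene_id,
                                  seed = 2))
  expect_equal(tc$temp_cluster[tc$gene_id == sim$truth$gene_id[1]], "Temp-up")
  expect_equal(tc$temp_cluster[tc$gene_id == sim$truth$gene_id[2]],
               "Temp-down")
})

test_that("sex bias follows the sign of the male/female fold change", {
  res <- tibble::tibble(feature_id = c("m", "f", "ns"),
                        log2fc = c(2, -2, 3),
                        p_value = c(0.01, 0.01, 0.5))
  sb <- sex_bias(res)
  expect_equal(sb$sex_cluster[sb$feature_id == "m"], "male-biased")
  expect_equal(sb$sex_cluster[sb$feature_id == "f"], "female-biased")
  expect_equal(sb$sex_cluster[sb$feature_id == "ns"], "none")
})

test_that("taxonomy matches the exhaustive pairwise oracle and partitions", {
  g1 <- tibble::tibble(gene_id = "g1", temp_cluster = "Temp-up")
  s1 <- tibble::tibble(feature_id = c("g1", "g2", "g3"),
                       sex_cluster = c("male-biased", "female-biased", "none"))
  tax <- gene_taxonomy(g1, s1)
  expect_equal(tax$taxonomy[tax$gene_id == "g1"], "M-T_up")
  expect_true(all(tax$taxonomy[tax$gene_id != "g1"] == "none"))

  set.seed(23)
  genes <- sprintf("g%03d", 1:300)
  temp <- tibble::tibble(
    gene_id = genes,
    temp_cluster = sample(c("Temp-up", "Temp-down", "none"), 300, TRUE))
  sex <- tibble::tibble(
    feature_id = genes,
    sex_cluster = sample(c("male-biased", "female-biased", "none"), 300, TRUE))
  tax <- gene_taxonomy(temp, sex)
  expected <- mapply(oracle_taxonomy, temp$temp_cluster, sex$sex_cluster)
  expect_equal(tax$taxonomy[match(genes, tax$gene_id)], unname(expected))
  # the four classes are pairwise disjoint by construction: each gene has
  # exactly one taxonomy value
  expect_equal(nrow(tax), length(genes))
  # non-none taxonomy iff both parents non-none
  expect_equal(tax$taxonomy != "none",
               tax$temp_cluster != "none" & tax$sex_cluster != "none")
})

test_that("trajectory ratios recover planted stage-specific shifts", {
  groups <- c("XX28F", "XX36P")
  stages <- c(10, 12, 15, 20)
  samples <- tidyr::expand_grid(group = groups, stage = stages) |>
    dplyr::mutate(sample_id = paste0(group, "_", stage),
                  replicate = 1)
  m <- matrix(100, nrow = 3, ncol = nrow(samples),
              dimnames = list(c("gA", "gB", "gC"), samples$sample_id))
  norm <- cbind(tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(m))
  tax <- tibble::tibble(gene_id = rownames(m), temp_cluster = "Temp-up",
                        sex_cluster = "male-biased", taxonomy = "M-T_up")
  flat <- suppressWarnings(trajectory_ratio(norm, samples, tax))
  expect_equal(flat$mean_ratio, rep(1, 4))

  m2 <- m
  m2[, "XX36P_20"] <- 2 * (m2[, "XX36P_20"] + 0.5) - 0.5  # exact 2x with pseudocount
  norm2 <- cbind(tibble::tibble(gene_id = rownames(m2)), tibble::as_tibble(m2))
  shifted <- suppressWarnings(trajectory_ratio(norm2, samples, tax))
  expect_equal(shifted$mean_ratio[shifted$stage == 20], 2)
  expect_equal(shifted$mean_ratio[shifted$stage != 20], rep(1, 3))

  # zero denominator stays finite through the pseudocount
  m3 <- m
  m3[, "XX28F_10"] <- 0
  norm3 <- cbind(tibble::tibble(gene_id = rownames(m3)), tibble::as_tibble(m3))
  r3 <- suppressWarnings(trajectory_ratio(norm3, samples, tax))
  expect_true(all(is.finite(r3$mean_ratio)))

  expect_warning(trajectory_ratio(norm, samples, tax), "omitted")
})
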