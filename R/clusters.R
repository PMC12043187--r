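#' Per-gene group-by-stage mean profiles
#'
#' Averages normalized expression over replicates within every group x stage
#' cell, giving each gene one profile point per cell (20 points in the full
#' five-group, four-stage design).
#'
#' @param norm Normalized wide tibble (see [normalize_counts()]).
#' @param samples Sample sheet.
#' @return A list with `means` (genes x cells matrix-backed tibble) and
#'   `cells` (tibble mapping profile columns to `group`, `stage`,
#'   `temperature`).
#' @export
group_stage_means <- function(norm, samples) {
  m <- counts_to_matrix(norm)
  samples <- samples[match(colnames(m), samples$sample_id), ]
  cells <- samples |>
    dplyr::distinct(.data$group, .data$stage) |>
    dplyr::arrange(.data$group, .data$stage) |>
    dplyr::mutate(column = stage_col(.data$group, .data$stage),
                  temperature = parse_group(.data$group)$temperature)
  prof <- vapply(seq_len(nrow(cells)), function(i) {
    keep <- samples$group == cells$group[i] & samples$stage == cells$stage[i]
    rowMeans(m[, keep, drop = FALSE])
  }, numeric(nrow(m)))
  colnames(prof) <- cells$column
  rownames(prof) <- rownames(m)
  list(means = prof, cells = cells)
}

#' Temperature-response clustering of differentially expressed genes
#'
#' K-means clustering of z-scaled group-by-stage mean profiles, followed by
#' semantic relabeling: a cluster is `Temp-up` when its centroid averages
#' higher over the 36 degree profile points than over the 28 degree points,
#' `Temp-down` otherwise. Relabeling makes the result invariant to the
#' arbitrary permutation of k-means cluster numbers.
#'
#' @param norm Normalized wide tibble.
#' @param samples Sample sheet.
#' @param genes DEG feature ids to cluster (must contain at least `k` genes).
#' @param k Number of clusters.
#' @param seed Seed for the k-means restarts.
#' @param nstart Number of random restarts.
#' @return An object of class `temp_clusters`; use [tidy()] for the per-gene
#'   assignments and [glance()] for cluster sizes.
#' @export
temperature_clusters <- function(norm, samples, genes, k = 2, seed = 1,
                                 nstart = 25) {
  if (length(genes) < k) abort("fewer genes than clusters requested")
  gsm <- group_stage_means(norm, samples)
  prof <- gsm$means[genes, , drop = FALSE]
  z <- t(apply(prof, 1, zscale))
  keep <- apply(prof, 1, function(x) stats::sd(x) > 0)
  if (!all(keep)) {
    warn(sprintf("%d constant-profile gene(s) left unclustered", sum(!keep)))
  }
  z <- z[keep, , drop = FALSE]
  if (nrow(z) < k) abort("fewer non-degenerate genes than clusters requested")
  km <- if (nrow(z) == k) {
    # every gene is its own cluster; nothing to optimise
    list(cluster = seq_len(k), centers = z, tot.withinss = 0)
  } else {
    withr::with_seed(seed, stats::kmeans(z, centers = k, nstart = nstart,
                                         iter.max = 50))
  }
  hot <- gsm$cells$temperature == 36
  centroid_label <- apply(km$centers, 1, function(ctr) {
    if (mean(ctr[hot]) > mean(ctr[!hot])) "Temp-up" else "Temp-down"
  })
  assignments <- tibble(gene_id = genes,
                        temp_cluster = "none")
  assignments$temp_cluster[match(rownames(z), genes)] <-
    unname(centroid_label[km$cluster])
  structure(list(assignments = assignments, centers = km$centers,
                 cells = gsm$cells, k = k, seed = seed,
                 tot_withinss = km$tot.withinss),
            class = "temp_clusters")
}

#' @export
print.temp_clusters <- function(x, ...) {
  cat("Temperature-response clustering (k =", x$k, ")\n")
  print(table(x$assignments$temp_cluster))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname temperature_clusters
#' @param x A `temp_clusters` object.
#' @param ... Unused.
#' @export
tidy.temp_clusters <- function(x, ...) x$assignments

#' @rdname temperature_clusters
#' @export
glance.temp_clusters <- function(x, ...) {
  tibble(k = x$k,
         n_genes = nrow(x$assignments),
         n_temp_up = sum(x$assignments$temp_cluster == "Temp-up"),
         n_temp_down = sum(x$assignments$temp_cluster == "Temp-down"),
         tot_withinss = x$tot_withinss)
}

#' Sex-biased gene classification at normal temperature
#'
#' Labels DEGs from the 28 degree male vs female comparison: `male-biased`
#' when expression is higher in XY28M, `female-biased` when higher in XX28F.
#'
#' @param results [de_test()] output where `group1 = XX28F` (females) and
#'   `group2 = XY28M` (males), so positive `log2fc` means male-higher.
#' @param p_max,min_abs_log2fc DEG gate, as in [call_degs()].
#' @return A tibble `feature_id`, `sex_cluster` covering every tested
#'   feature (`none` for non-DEGs).
#' @export
sex_bias <- function(results, p_max = 0.05, min_abs_log2fc = 1.0) {
  degs <- call_degs(results, p_max, min_abs_log2fc)
  results |>
    dplyr::transmute(
      .data$feature_id,
      sex_cluster = dplyr::case_when(
        .data$feature_id %in% degs$feature_id[degs$direction == "up"] ~
          "male-biased",
        .data$feature_id %in% degs$feature_id[degs$direction == "down"] ~
          "female-biased",
        TRUE ~ "none"))
}

#' Four-way sex-by-temperature gene taxonomy
#'
#' Intersects the sex-bias labels with the temperature-response clusters:
#' `M-T_up` = male-biased and heat-upregulated, `M-T_down` = male-biased and
#' heat-downregulated, `F-T_up` and `F-T_down` the female-biased analogues.
#' A gene gets a non-`none` taxonomy exactly when both parent labels are
#' non-`none`.
#'
#' @param temp_labels Tibble `gene_id`/`feature_id` + `temp_cluster` (or a
#'   `temp_clusters` object).
#' @param sex_labels Tibble `feature_id` + `sex_cluster`.
#' @return A tibble `gene_id`, `temp_cluster`, `sex_cluster`, `taxonomy`
#'   over the union of the two feature universes.
#' @export
gene_taxonomy <- function(temp_labels, sex_labels) {
  if (inherits(temp_labels, "temp_clusters")) temp_labels <- tidy(temp_labels)
  use_gene_id <- function(x) {
    x <- as_tibble(x)
    if (!"gene_id" %in% names(x)) names(x)[names(x) == "feature_id"] <- "gene_id"
    x
  }
  tl <- use_gene_id(temp_labels)
  sl <- use_gene_id(sex_labels)
  dplyr::full_join(tl[c("gene_id", "temp_cluster")],
                   sl[c("gene_id", "sex_cluster")], by = "gene_id") |>
    tidyr::replace_na(list(temp_cluster = "none", sex_cluster = "none")) |>
    dplyr::mutate(taxonomy = dplyr::case_when(
      .data$sex_cluster == "male-biased" & .data$temp_cluster == "Temp-up" ~
        "M-T_up",
      .data$sex_cluster == "male-biased" & .data$temp_cluster == "Temp-down" ~
        "M-T_down",
      .data$sex_cluster == "female-biased" & .data$temp_cluster == "Temp-up" ~
        "F-T_up",
      .data$sex_cluster == "female-biased" & .data$temp_cluster == "Temp-down" ~
        "F-T_down",
      TRUE ~ "none"))
}

#' Pseudomale-to-female expression trajectory ratios
#'
#' For each taxonomy cluster and developmental stage, the mean over member
#' genes of the ratio of XX36P (pseudomale) to XX28F (control female) group
#' mean expression, with a pseudocount guarding zero denominators.
#'
#' @param norm Normalized wide tibble.
#' @param samples Sample sheet.
#' @param taxonomy [gene_taxonomy()] output (rows with taxonomy `none` are
#'   ignored).
#' @param numerator,denominator Group labels forming the ratio.
#' @param pseudocount Added to both group means.
#' @return A tibble `cluster`, `stage`, `mean_ratio`, `sd_ratio`, `n_genes`.
#'   Empty clusters are omitted with a warning.
#' @export
trajectory_ratio <- function(norm, samples, taxonomy,
                             numerator = "XX36P", denominator = "XX28F",
                             pseudocount = 0.5) {
  gsm <- group_stage_means(norm, samples)
  stages <- sort(unique(gsm$cells$stage))
  for (grp in c(numerator, denominator)) {
    if (!all(stages %in% gsm$cells$stage[gsm$cells$group == grp])) {
      abort(sprintf("group %s is missing at some stages", grp))
    }
  }
  members <- taxonomy[taxonomy$taxonomy != "none", c("gene_id", "taxonomy")]
  empty <- setdiff(c("M-T_up", "M-T_down", "F-T_up", "F-T_down"),
                   unique(members$taxonomy))
  if (length(empty)) {
    warn(sprintf("empty taxonomy cluster(s) omitted: %s",
                 paste(empty, collapse = ", ")))
  }
  purrr::map_dfr(split(members$gene_id, members$taxonomy), function(genes) {
    purrr::map_dfr(stages, function(st) {
      num <- gsm$means[genes, stage_col(numerator, st)]
      den <- gsm$means[genes, stage_col(denominator, st)]
      r <- (num + pseudocount) / (den + pseudocount)
      tibble(stage = st, mean_ratio = mean(r),
             sd_ratio = stats::sd(r), n_genes = length(genes))
    })
  }, .id = "cluster")
}
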