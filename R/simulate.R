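#' Simulation design for the temperature-treatment RNA-seq experiment
#'
#' Describes the experimental frame the simulator emulates: five
#' temperature-sex groups of Nile tilapia gonads (XX28F, XY28M, XX36F, XX36P,
#' XY36M) sampled at four developmental stages (10, 12, 15, 20 days
#' post-fertilization) with three biological replicates, and a set of planted
#' gene clusters with known log2 effect sizes.
#'
#' The default `cluster_spec` plants temperature-responsive and sex-biased
#' clusters in proportions mirroring a whole-transcriptome screen (roughly
#' 15% heat-up, 12% heat-down, ~1% sex-biased each way); all remaining genes
#' are null. Effects are applied multiplicatively on the negative-binomial
#' mean: Temp-up genes gain `2^log2_effect` in every 36 degree group, Temp-down
#' genes lose it; male-biased genes gain it in XY28M, female-biased genes in
#' XX28F.
#'
#' @param n_genes Number of simulated genes.
#' @param groups Temperature-sex group labels (see [parse_group()]).
#' @param stages Developmental stages in days post-fertilization.
#' @param replicates Biological replicates per group-stage combination.
#' @param cluster_spec Tibble with columns `cluster` (one of `"Temp-up"`,
#'   `"Temp-down"`, `"male-biased"`, `"female-biased"`), `n_genes` and
#'   `log2_effect` (positive magnitude; direction is implied by the label).
#' @param base_mean Expected count of a null gene at library-average depth.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param lib_size_cv Coefficient of variation of per-sample depth factors;
#'   set to 0 for equal library sizes.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_genes = 2000,
                       groups = c("XX28F", "XY28M", "XX36F", "XX36P", "XY36M"),
                       stages = c(10, 12, 15, 20),
                       replicates = 3,
                       cluster_spec = default_cluster_spec(n_genes),
                       base_mean = 100,
                       nb_dispersion = 0.1,
                       lib_size_cv = 0.2) {
  stopifnot(replicates >= 1, n_genes >= 1, base_mean > 0, nb_dispersion > 0,
            lib_size_cv >= 0)
  parse_group(groups)  # validates labels
  cluster_spec <- as_tibble(cluster_spec)
  stopifnot(all(c("cluster", "n_genes", "log2_effect") %in% names(cluster_spec)))
  known <- c("Temp-up", "Temp-down", "male-biased", "female-biased", "null")
  bad <- setdiff(cluster_spec$cluster, known)
  if (length(bad)) abort(sprintf("unknown cluster label(s): %s",
                                 paste(bad, collapse = ", ")))
  if (!all(is.finite(cluster_spec$log2_effect))) abort("effect sizes must be finite")
  if (sum(cluster_spec$n_genes) > n_genes) {
    abort("cluster gene counts exceed n_genes")
  }
  structure(
    list(n_genes = n_genes, groups = groups, stages = stages,
         replicates = replicates, cluster_spec = cluster_spec,
         base_mean = base_mean, nb_dispersion = nb_dispersion,
         lib_size_cv = lib_size_cv),
    class = "sim_design")
}

#' @rdname sim_design
#' @export
default_cluster_spec <- function(n_genes) {
  tibble(
    cluster = c("Temp-up", "Temp-down", "male-biased", "female-biased"),
    n_genes = pmax(0L, round(n_genes * c(0.15, 0.12, 0.011, 0.009))),
    log2_effect = 2)
}

sample_sheet_from_design <- function(design) {
  grid <- tidyr::expand_grid(group = design$groups, stage = design$stages,
                             replicate = seq_len(design$replicates))
  meta <- parse_group(grid$group)
  tibble(
    sample_id = sprintf("%s_%d_r%d", grid$group, grid$stage, grid$replicate),
    group = grid$group,
    genotype = meta$genotype,
    temperature = meta$temperature,
    phenotype = meta$phenotype,
    stage = grid$stage,
    replicate = grid$replicate)
}

# deterministic NB mean matrix (genes x samples) implied by a design and its
# planted truth; shared by the count and peak-count simulators
design_mean_matrix <- function(design, truth, samples) {
  mu <- matrix(design$base_mean, nrow = design$n_genes, ncol = nrow(samples),
               dimnames = list(truth$gene_id, samples$sample_id))
  eff <- stats::setNames(truth$log2_effect, truth$gene_id)
  hot <- samples$temperature == 36
  up <- truth$gene_id[truth$cluster == "Temp-up"]
  dn <- truth$gene_id[truth$cluster == "Temp-down"]
  mb <- truth$gene_id[truth$cluster == "male-biased"]
  fb <- truth$gene_id[truth$cluster == "female-biased"]
  mu[up, hot] <- mu[up, hot] * 2^eff[up]
  mu[dn, hot] <- mu[dn, hot] * 2^-eff[dn]
  mu[mb, samples$group == "XY28M"] <- mu[mb, samples$group == "XY28M"] * 2^eff[mb]
  mu[fb, samples$group == "XX28F"] <- mu[fb, samples$group == "XX28F"] * 2^eff[fb]
  mu
}

planted_truth <- function(design) {
  spec <- design$cluster_spec
  labels <- rep("null", design$n_genes)
  if (nrow(spec)) {
    labels[seq_len(sum(spec$n_genes))] <- rep(spec$cluster, spec$n_genes)
  }
  eff <- rep(0, design$n_genes)
  if (nrow(spec)) {
    eff[seq_len(sum(spec$n_genes))] <- rep(spec$log2_effect, spec$n_genes)
  }
  tibble(gene_id = sprintf("g%04d", seq_len(design$n_genes)),
         cluster = labels, log2_effect = eff)
}

#' Simulate a gene-level count matrix with planted clusters
#'
#' Draws negative-binomial counts for every gene and sample of the design.
#' Genes belonging to planted clusters have their means shifted as described
#' in [sim_design()]; the planted labels are returned alongside so downstream
#' stages can be scored against ground truth.
#'
#' @param design A [sim_design()] object.
#' @param seed Integer seed; the same (design, seed) pair always yields a
#'   bit-identical result.
#' @return A list with `counts` (tibble, `gene_id` + one column per sample),
#'   `samples` (the sample sheet) and `truth` (planted cluster labels).
#' @examples
#' sim <- simulate_counts(sim_design(n_genes = 50), seed = 1)
#' dim(sim$counts)
#' @export
simulate_counts <- function(design, seed) {
  stopifnot(inherits(design, "sim_design"))
  samples <- sample_sheet_from_design(design)
  truth <- planted_truth(design)
  mu <- design_mean_matrix(design, truth, samples)
  counts <- withr::with_seed(seed, {
    depth <- if (design$lib_size_cv > 0) {
      sdlog <- sqrt(log(1 + design$lib_size_cv^2))
      stats::rlnorm(nrow(samples), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, nrow(samples))
    mu <- sweep(mu, 2, depth, `*`)
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / design$nb_dispersion),
           nrow = nrow(mu), dimnames = dimnames(mu))
  })
  list(counts = matrix_to_counts(counts, "gene_id"),
       samples = samples, truth = truth)
}

#' Simulate histone-mark peak counts coupled to expression
#'
#' Places one promoter peak (and optionally one gene-body peak) per gene on a
#' synthetic chromosome and draws negative-binomial fragment counts whose
#' across-group mean profile follows the gene's expression profile with a
#' requested sign: `+1` couples the mark positively (activating, e.g.
#' H3K4me3), `-1` negatively (repressive, e.g. H3K27me3), `0` decouples it.
#'
#' @param design A [sim_design()] object (defines groups/stages/replicates and
#'   the expression profiles of the planted genes).
#' @param coupling Named numeric vector, mark label -> sign in `{-1, 0, 1}`.
#' @param seed Integer seed.
#' @param truth Planted gene table; defaults to the design's own.
#' @param base_mean Expected fragment count per peak at profile-average level.
#' @param nb_dispersion Dispersion of the fragment-count noise; drive it
#'   towards zero to recover the planted coupling exactly.
#' @param gene_body Also place a gene-body peak per gene?
#' @return A list with `peaks` (intervals, BED-style 0-based half-open),
#'   `counts` (peak_id x samples per mark, stacked with a `mark` column kept
#'   in `peaks`), `samples` and `genes` (synthetic gene spans usable as
#'   annotation input).
#' @export
simulate_peak_counts <- function(design, coupling, seed,
                                 truth = planted_truth(design),
                                 base_mean = 50, nb_dispersion = 0.1,
                                 gene_body = FALSE) {
  stopifnot(inherits(design, "sim_design"))
  if (is.null(names(coupling)) || any(!nzchar(names(coupling)))) {
    abort("`coupling` must be a named vector (mark -> sign)")
  }
  if (!all(coupling %in% c(-1, 0, 1))) abort("coupling signs must be -1, 0 or 1")
  samples <- sample_sheet_from_design(design)
  mu_expr <- design_mean_matrix(design, truth, samples)
  # log2 deviation of each gene's profile from its own average drives the peak
  dev <- log2(mu_expr) - rowMeans(log2(mu_expr))

  n <- design$n_genes
  tss <- 10000L + (seq_len(n) - 1L) * 20000L
  genes <- tibble(gene_id = truth$gene_id, chrom = "chrS", strand = "+",
                  start = tss, end = tss + 5000L)
  one_mark_peaks <- function(mark) {
    prom <- tibble(chrom = "chrS", start = tss - 1000L, end = tss - 400L,
                   gene_id = truth$gene_id, region = "promoter", mark = mark)
    if (!gene_body) return(prom)
    body <- tibble(chrom = "chrS", start = tss + 2000L, end = tss + 2600L,
                   gene_id = truth$gene_id, region = "genic", mark = mark)
    dplyr::bind_rows(prom, body)
  }
  peaks <- purrr::map_dfr(names(coupling), one_mark_peaks)
  peaks$peak_id <- sprintf("%s_pk%05d", peaks$mark, seq_len(nrow(peaks)))

  counts <- withr::with_seed(seed, {
    purrr::map(names(coupling), function(mark) {
      s <- coupling[[mark]]
      pk <- peaks[peaks$mark == mark, ]
      mu <- base_mean * 2^(s * dev[pk$gene_id, , drop = FALSE])
      rownames(mu) <- pk$peak_id
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
             nrow = nrow(mu), dimnames = dimnames(mu))
    })
  })
  counts <- do.call(rbind, counts)
  list(peaks = peaks, counts = matrix_to_counts(counts, "peak_id"),
       samples = samples, genes = genes)
}

#' Isoform mixture ground truth for coverage simulation
#'
#' The default isoform universe holds the three transcript forms of the
#' alternatively spliced kdm6bb-like two-intron gene: `I5_dI8` (intron 5
#' retained, intron 8 spliced), `dI5_I8` (intron 8 retained; the
#' nuclear-localizing form) and `dI5_dI8` (both spliced).
#'
#' @param fractions Named non-negative fractions summing to 1.
#' @param depth Expected per-base coverage on constitutive exons.
#' @param noise_cv Coefficient of variation of multiplicative per-base noise.
#' @return A list of class `isoform_truth`.
#' @export
isoform_truth <- function(fractions = c(I5_dI8 = 0.63, dI5_I8 = 0.30,
                                        dI5_dI8 = 0.07),
                          depth = 50, noise_cv = 0) {
  stopifnot(depth > 0, noise_cv >= 0)
  if (any(fractions < 0)) abort("isoform fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) abort("isoform fractions must sum to 1")
  structure(list(fractions = fractions, depth = depth, noise_cv = noise_cv),
            class = "isoform_truth")
}

#' A ten-exon gene model with alternatively retained introns I5 and I8
#'
#' Synthetic stand-in for the kdm6bb locus: ten exons of 150 bp separated by
#' nine introns (I5 = 400 bp, I8 = 500 bp, others 300 bp) on a plus-strand
#' synthetic chromosome, BED-style 0-based half-open coordinates.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param offset Start coordinate of exon 1.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `role`,
#'   `start`, `end`; roles are `exon_1` ... `exon_10`, `intron_1` ...
#'   `intron_9` plus the short tags `E1..E10` / `I1..I9` in `tag`.
#' @export
kdm6bb_model <- function(gene_id = "kdm6bb", chrom = "chrS", offset = 1000L) {
  exon_len <- 150L
  intron_len <- c(300L, 300L, 300L, 300L, 400L, 300L, 300L, 500L, 300L)
  widths <- integer(19)
  widths[seq(1, 19, by = 2)] <- exon_len
  widths[seq(2, 18, by = 2)] <- intron_len
  starts <- offset + cumsum(c(0L, widths[-19]))
  role <- character(19)
  role[seq(1, 19, by = 2)] <- paste0("exon_", 1:10)
  role[seq(2, 18, by = 2)] <- paste0("intron_", 1:9)
  tag <- character(19)
  tag[seq(1, 19, by = 2)] <- paste0("E", 1:10)
  tag[seq(2, 18, by = 2)] <- paste0("I", 1:9)
  tibble(gene_id = gene_id, chrom = chrom, strand = "+",
         role = role, tag = tag, start = starts, end = starts + widths)
}

# which segments of the model does an isoform label include? tokens separated
# by "_": "I5" retains intron 5, "dI5" splices it out; exons are always in
isoform_inclusion <- function(model, isoforms) {
  seg_included <- function(iso) {
    tokens <- strsplit(iso, "_")[[1]]
    retained <- tokens[!startsWith(tokens, "d")]
    grepl("^exon_", model$role) |
      model$tag %in% retained
  }
  m <- vapply(isoforms, seg_included, logical(nrow(model)))
  storage.mode(m) <- "double"
  rownames(m) <- model$tag
  m
}

#' Simulate a per-base coverage track over an alternatively spliced gene
#'
#' The expected coverage of every base in a segment is `depth` times the
#' summed fraction of isoforms that include the segment; multiplicative
#' log-normal noise with the requested coefficient of variation (mean 1) is
#' then applied per base. Contiguous equal-depth runs are compressed into
#' bedGraph-style blocks.
#'
#' @param model Gene model tibble (see [kdm6bb_model()]).
#' @param truth An [isoform_truth()] object.
#' @param seed Integer seed (ignored when `noise_cv = 0`, which is noiseless
#'   and deterministic anyway).
#' @return A coverage track tibble with columns `chrom`, `start`, `end`,
#'   `depth` (0-based half-open blocks, sorted, non-overlapping).
#' @export
simulate_coverage <- function(model, truth, seed = 1) {
  stopifnot(inherits(truth, "isoform_truth"))
  need <- c("I5", "I8", "E8", "E9")
  missing <- setdiff(need, model$tag)
  if (length(missing)) {
    abort(sprintf("gene model lacks tagged segment(s): %s",
                  paste(missing, collapse = ", ")))
  }
  incl <- isoform_inclusion(model, names(truth$fractions))
  expected <- truth$depth * as.numeric(incl %*% truth$fractions)

  per_base <- rep(expected, times = model$end - model$start)
  pos <- unlist(purrr::map2(model$start, model$end, ~seq(.x, .y - 1L)))
  if (truth$noise_cv > 0) {
    sdlog <- sqrt(log(1 + truth$noise_cv^2))
    per_base <- withr::with_seed(seed, {
      per_base * stats::rlnorm(length(per_base), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
    })
  }
  # compress runs of equal depth over contiguous positions
  brk <- c(TRUE, diff(pos) != 1L | per_base[-1] != per_base[-length(per_base)])
  grp <- cumsum(brk)
  tibble(chrom = model$chrom[[1]],
         start = pos[brk],
         end = c(pos[which(brk)[-1] - 1L], pos[length(pos)]) + 1L,
         depth = per_base[brk])
}

#' Cohort specification for sex-reversal simulations
#'
#' Frames a temperature-treatment (or transgene) experiment: `n_families`
#' independent families of `n_per_family` fish of one genotype, each fish
#' converting away from its genotypic sex with probability `conversion_prob`
#' (XX converting means pseudomale; XY converting means phenotypic female).
#' Marker expression (`dmrt1`, `cyp19a1a`) is generated on the log2 scale
#' with a separation of `marker_sep` between the dominant and recessive
#' marker of the realized phenotype; the noise is Gaussian truncated at
#' `marker_sep / 4` so the marker-based classifier is always consistent with
#' the planted phenotype whenever `marker_sep > 0`.
#'
#' @param n_families Number of independent families.
#' @param n_per_family Fish per family.
#' @param genotype `"XX"` or `"XY"`.
#' @param treatment_c Rearing temperature, 28 or 36.
#' @param conversion_prob Per-fish probability of sex conversion.
#' @param marker_sep Log2-scale separation of dmrt1 vs cyp19a1a between
#'   phenotypes.
#' @param marker_noise_sd Standard deviation of the (truncated) marker noise.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_families = 3, n_per_family = 60, genotype = "XX",
                        treatment_c = 36, conversion_prob = 0.75,
                        marker_sep = 2, marker_noise_sd = 0.3) {
  stopifnot(n_per_family >= 1, n_families >= 1,
            conversion_prob >= 0, conversion_prob <= 1,
            genotype %in% c("XX", "XY"), treatment_c %in% c(28, 36),
            marker_sep > 0, marker_noise_sd >= 0)
  structure(list(n_families = n_families, n_per_family = n_per_family,
                 genotype = genotype, treatment_c = treatment_c,
                 conversion_prob = conversion_prob, marker_sep = marker_sep,
                 marker_noise_sd = marker_noise_sd),
            class = "cohort_spec")
}

rnorm_trunc <- function(n, sd, bound) {
  if (sd == 0) return(rep(0, n))
  p <- stats::pnorm(c(-bound, bound), sd = sd)
  stats::qnorm(stats::runif(n, p[1], p[2]), sd = sd)
}

#' Simulate a fish cohort with planted sex-conversion outcomes
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per fish: `fish_id`, `family`, `genotype`,
#'   `treatment_c`, `converted` (planted truth), `phenotype_truth`, and
#'   linear-scale marker levels `dmrt1` and `cyp19a1a`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(conversion_prob = 0.75), seed = 1)
#' mean(cohort$converted)
#' @export
simulate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_families * spec$n_per_family
  withr::with_seed(seed, {
    converted <- stats::runif(n) < spec$conversion_prob
    phen_male <- if (spec$genotype == "XX") converted else !converted
    d <- spec$marker_sep / 2
    base <- 4  # arbitrary log2 abundance origin; ratios are what matter
    bound <- spec$marker_sep / 4
    noise_sd <- min(spec$marker_noise_sd, spec$marker_sep / 4)
    e1 <- rnorm_trunc(n, noise_sd, bound) / 2
    e2 <- rnorm_trunc(n, noise_sd, bound) / 2
    dmrt1_log2 <- base + ifelse(phen_male, d, -d) + e1
    cyp_log2 <- base + ifelse(phen_male, -d, d) + e2
    tibble(
      fish_id = sprintf("fish%04d", seq_len(n)),
      family = rep(sprintf("fam%d", seq_len(spec$n_families)),
                   each = spec$n_per_family),
      genotype = spec$genotype,
      treatment_c = spec$treatment_c,
      converted = converted,
      phenotype_truth = ifelse(phen_male, "male", "female"),
      dmrt1 = 2^dmrt1_log2,
      cyp19a1a = 2^cyp_log2)
  })
}

#' Simulate a per-cell fluorescence intensity table
#'
#' Emulates the per-cell measurements behind a nuclear/cytoplasmic
#' localization experiment: each cell gets a nuclear and a cytoplasmic
#' compartment with log-normally perturbed intensity densities whose planted
#' nuclear:cytoplasmic density ratio is `nc_ratio`.
#'
#' @param n_cells Number of cells.
#' @param nc_ratio Planted nuclear/cytoplasmic intensity-density ratio.
#' @param cyt_density Cytoplasmic intensity per pixel.
#' @param noise_cv Coefficient of variation of per-compartment noise.
#' @param seed Integer seed.
#' @return A tibble with `cell_id`, `nuclear_intensity`,
#'   `cytoplasmic_intensity`, `nuclear_area`, `cytoplasmic_area`.
#' @export
simulate_cell_intensities <- function(n_cells = 20, nc_ratio = 3,
                                      cyt_density = 50, noise_cv = 0.1,
                                      seed = 1) {
  stopifnot(n_cells >= 1, nc_ratio > 0, cyt_density > 0, noise_cv >= 0)
  withr::with_seed(seed, {
    a_nuc <- round(stats::runif(n_cells, 80, 120))
    a_cyt <- round(stats::runif(n_cells, 250, 350))
    sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    jitter <- function(n) {
      if (sdlog == 0) rep(1, n) else
        stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    tibble(
      cell_id = sprintf("cell%03d", seq_len(n_cells)),
      nuclear_intensity = cyt_density * nc_ratio * a_nuc * jitter(n_cells),
      cytoplasmic_intensity = cyt_density * a_cyt * jitter(n_cells),
      nuclear_area = a_nuc,
      cytoplasmic_area = a_cyt)
  })
}
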