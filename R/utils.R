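#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# counts tables are wide: a `gene_id` (or `peak_id`) key column plus one
# numeric column per sample.  These helpers move between that layout and the
# plain matrix the numerical code wants.

counts_key <- function(counts) {
  key <- intersect(c("gene_id", "peak_id", "feature_id"), names(counts))
  if (length(key) == 0L) {
    abort("`counts` must have a 'gene_id', 'peak_id' or 'feature_id' column.")
  }
  key[[1L]]
}

counts_to_matrix <- function(counts) {
  key <- counts_key(counts)
  ids <- counts[[key]]
  if (anyDuplicated(ids)) abort(sprintf("duplicate %s values in `counts`", key))
  m <- as.matrix(counts[setdiff(names(counts), key)])
  if (!is.numeric(m)) abort("sample columns of `counts` must be numeric")
  if (any(m < 0)) abort("`counts` contains negative values")
  rownames(m) <- ids
  m
}

matrix_to_counts <- function(m, key = "gene_id") {
  out <- as_tibble(m)
  out[[key]] <- rownames(m)
  dplyr::relocate(out, dplyr::all_of(key))
}

#' Parse temperature-sex group labels
#'
#' Group labels follow the `XX28F` / `XX36P` convention: genotype (`XX`/`XY`),
#' rearing temperature in degrees Celsius (28 or 36) and phenotypic sex
#' (`F` female, `M` male, `P` pseudomale).
#'
#' @param group Character vector of group labels.
#' @return A tibble with columns `group`, `genotype`, `temperature`,
#'   `phenotype`.
#' @examples
#' parse_group(c("XX28F", "XX36P"))
#' @export
parse_group <- function(group) {
  m <- regmatches(group, regexec("^(XX|XY)(28|36)([FMP])$", group))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    abort(sprintf("malformed group label(s): %s",
                  paste(unique(group[bad]), collapse = ", ")))
  }
  tibble(
    group = group,
    genotype = vapply(m, `[[`, "", 2L),
    temperature = as.integer(vapply(m, `[[`, "", 3L)),
    phenotype = c(F = "female", M = "male", P = "pseudomale")[
      vapply(m, `[[`, "", 4L)]
  )
}

stage_col <- function(group, stage) paste0(group, "_", stage)
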