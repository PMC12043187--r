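#' Per-cell nuclear/cytoplasmic signal ratio
#'
#' Two readings of area normalization are offered. `density` (default)
#' divides each compartment's summed intensity by its own area:
#' `(I_nuc / A_nuc) / (I_cyt / A_cyt)`. `dapi_area` normalizes both
#' compartments to the nuclear (DAPI) area, in which the areas cancel and
#' the ratio reduces to `I_nuc / I_cyt`. The two agree exactly when the two
#' areas are equal. Cells with zero cytoplasmic intensity get an `NA` ratio
#' flagged in `undefined`.
#'
#' @param cells Tibble with `nuclear_intensity`, `cytoplasmic_intensity`,
#'   `nuclear_area`, `cytoplasmic_area`.
#' @param mode `"density"` or `"dapi_area"`.
#' @return `cells` with added `ratio` and `undefined` columns.
#' @examples
#' cells <- simulate_cell_intensities(n_cells = 5, nc_ratio = 3, seed = 1)
#' cell_ratio(cells)$ratio
#' @export
cell_ratio <- function(cells, mode = c("density", "dapi_area")) {
  mode <- match.arg(mode)
  stopifnot(all(cells$nuclear_area > 0), all(cells$cytoplasmic_area > 0),
            all(cells$nuclear_intensity >= 0),
            all(cells$cytoplasmic_intensity >= 0))
  undefined <- cells$cytoplasmic_intensity == 0
  ratio <- switch(mode,
    density = (cells$nuclear_intensity / cells$nuclear_area) /
      (cells$cytoplasmic_intensity / cells$cytoplasmic_area),
    dapi_area = cells$nuclear_intensity / cells$cytoplasmic_intensity)
  ratio[undefined] <- NA_real_
  dplyr::mutate(cells, ratio = ratio, undefined = undefined)
}

#' Mean nuclear/cytoplasmic ratio over a group of cells
#'
#' Arithmetic mean and standard error of the per-cell ratio after dropping
#' undefined cells; refuses to summarise fewer than `min_cells` usable
#' cells (twenty by default, the usual per-image quota).
#'
#' @param cells Per-cell intensity tibble.
#' @param min_cells Minimum usable cells required.
#' @param mode Passed to [cell_ratio()].
#' @return A tibble with `mean_ratio`, `sem`, `n_cells`, `mode`.
#' @export
group_mean_ratio <- function(cells, min_cells = 20,
                             mode = c("density", "dapi_area")) {
  mode <- match.arg(mode)
  r <- cell_ratio(cells, mode)$ratio
  r <- r[!is.na(r)]
  if (length(r) < min_cells) {
    abort(sprintf("only %d usable cell(s); %d more needed to reach %d",
                  length(r), min_cells - length(r), min_cells))
  }
  tibble(mean_ratio = mean(r),
         sem = stats::sd(r) / sqrt(length(r)),
         n_cells = length(r),
         mode = mode)
}

#' Synthetic cell image and intensity extraction (fixture generator)
#'
#' Builds a toy single-cell image — a rectangular cytoplasm of uniform
#' intensity with a disk-shaped nucleus — and extracts the per-compartment
#' intensity sums and areas, giving a ground-truthed
#' [cell_ratio()]-compatible record. This exists to exercise the
#' localization statistics, not to segment real micrographs.
#'
#' @param width,height Cell rectangle in pixels.
#' @param radius Nucleus radius in pixels (centered).
#' @param nuc_density,cyt_density Intensity per pixel in each compartment.
#' @return A list with the intensity `image` matrix, the logical
#'   `nucleus_mask`, and `cells`: a one-row tibble of extracted sums/areas.
#' @export
synthetic_cell_image <- function(width = 30, height = 20, radius = 6,
                                 nuc_density = 150, cyt_density = 50) {
  stopifnot(radius < min(width, height) / 2)
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), times = width), nrow = height)
  mask <- (xs - (width + 1) / 2)^2 + (ys - (height + 1) / 2)^2 <= radius^2
  img <- matrix(cyt_density, nrow = height, ncol = width)
  img[mask] <- nuc_density
  cells <- tibble(cell_id = "synth1",
                  nuclear_intensity = sum(img[mask]),
                  cytoplasmic_intensity = sum(img[!mask]),
                  nuclear_area = sum(mask),
                  cytoplasmic_area = sum(!mask))
  list(image = img, nucleus_mask = mask, cells = cells)
}
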