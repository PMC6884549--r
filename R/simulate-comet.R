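#' Simulate per-cell comet-FLARE measurements
#'
#' Generates head/tail fluorescence intensities for single-cell comet assays
#' with a lesion-specific enzyme digestion arm. The per-cell tail fraction is
#' Beta-distributed around the planted group mean; total comet intensity is
#' log-normal and split between head and tail, so the expected percent-tail
#' of every group equals its planted mean exactly. The default group layout
#' follows a transcription-inhibition experiment: {DMSO, DRB} treatment
#' crossed with {buffer, AAG} digestion, with extra AAG-revealed damage under
#' DRB.
#'
#' @param group_means Tibble with columns `condition`, `enzyme`,
#'   `mean_tail_fraction` (each in (0, 1)). The default plants equal
#'   background break levels in the buffer arms, a moderate AAG-specific
#'   signal under DMSO and an elevated one under DRB.
#' @param n_cells_per_replicate Cells scored per replicate and group.
#' @param n_replicates Replicates per group.
#' @param dispersion Beta concentration parameter (larger = tighter spread
#'   of per-cell tail fractions around the group mean).
#' @param seed Integer RNG seed.
#' @return A `bertx_sim` list with `cells` (columns `cell_id`, `condition`,
#'   `enzyme`, `replicate`, `head_intensity`, `tail_intensity`) and `truth`
#'   (planted means and the implied AAG-specific contrast per condition).
#' @examples
#' sim <- simulate_comet_cells(n_cells_per_replicate = 10, seed = 4)
#' head(sim$cells)
#' @export
simulate_comet_cells <- function(group_means = default_comet_means(),
                                 n_cells_per_replicate = 50L,
                                 n_replicates = 4L,
                                 dispersion = 30,
                                 seed = 1L) {
  check_columns(group_means, c("condition", "enzyme", "mean_tail_fraction"),
                "`group_means`")
  m <- group_means$mean_tail_fraction
  if (any(!is.finite(m)) || any(m <= 0) || any(m >= 1)) {
    abort("All `mean_tail_fraction` values must lie strictly in (0, 1).",
          class = "bertx_invalid_parameter")
  }
  n_cells_per_replicate <- check_count(n_cells_per_replicate,
                                       "n_cells_per_replicate")
  n_replicates <- check_count(n_replicates, "n_replicates")
  check_number(dispersion, "dispersion", min = 0, strict_min = TRUE)
  local_seed(seed)

  cells <- group_means |>
    tidyr::expand_grid(replicate = seq_len(n_replicates),
                       cell = seq_len(n_cells_per_replicate)) |>
    dplyr::mutate(
      tail_fraction = rbeta(dplyr::n(),
                            .data$mean_tail_fraction * dispersion,
                            (1 - .data$mean_tail_fraction) * dispersion),
      total = rlnorm(dplyr::n(), log(10000), 0.3),
      head_intensity = .data$total * (1 - .data$tail_fraction),
      tail_intensity = .data$total * .data$tail_fraction,
      cell_id = sprintf("%s_%s_r%d_c%03d", .data$condition, .data$enzyme,
                        .data$replicate, .data$cell)
    ) |>
    dplyr::select("cell_id", "condition", "enzyme", "replicate",
                  "head_intensity", "tail_intensity")

  contrast <- group_means |>
    tidyr::pivot_wider(names_from = "enzyme",
                       values_from = "mean_tail_fraction") |>
    dplyr::mutate(expected_aag_specific =
                    100 * (.data$AAG - .data$buffer)) |>
    dplyr::select("condition", "expected_aag_specific")

  truth <- list(
    assay = "comet",
    group_means = group_means |>
      dplyr::mutate(expected_percent_tail = 100 * .data$mean_tail_fraction),
    expected_contrast = contrast,
    dispersion = dispersion,
    n_cells_per_replicate = n_cells_per_replicate,
    n_replicates = n_replicates,
    seed = seed
  )
  new_bertx_sim(cells = cells, truth = truth)
}

#' Default planted comet group means
#'
#' @return Tibble of `condition`, `enzyme`, `mean_tail_fraction` for the
#'   {DMSO, DRB} x {buffer, AAG} layout.
#' @export
default_comet_means <- function() {
  tibble(
    condition = rep(c("DMSO", "DRB"), each = 2),
    enzyme = rep(c("buffer", "AAG"), 2),
    mean_tail_fraction = c(0.06, 0.12, 0.06, 0.22)
  )
}
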