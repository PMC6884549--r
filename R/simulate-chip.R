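#' Simulate a ChIP-qPCR experiment with a planted occupancy profile
#'
#' Generates paired immunoprecipitate (`IP`) and chromatin-input (`input`)
#' Ct values whose noiseless percent-of-input exactly recovers the planted
#' occupancy profile. The input well measures an aliquot containing
#' `input_fraction` of the chromatin; the IP well pulls down
#' `promoter_percent_input/100 * occupancy` of the full chromatin at each
#' region, so factor-specific binding gradients (e.g. rising towards the
#' 3' end of a transcribed gene) are encoded directly in `occupancy`.
#'
#' @param occupancy Tibble with columns `gene`, `region`, `occupancy`
#'   (relative occupancy, > 0; promoter rows are the usual reference). A
#'   convenient constructor is [lesion_landscape()] renamed, or build it with
#'   [tibble::tibble()].
#' @param input_fraction Fraction of chromatin kept as input aliquot
#'   (0 < f < 1; 0.01 = the common "1% input").
#' @param promoter_percent_input Percent of input recovered by the IP at
#'   occupancy 1 (sets the overall pulldown efficiency scale).
#' @param input_ct Ct of the input aliquot well.
#' @param ct_noise_sd Additive Gaussian Ct noise in cycles.
#' @param n_replicates Technical replicates per well group.
#' @param efficiency Per-cycle amplification factor (> 1).
#' @param sample_id Sample label stamped on every well.
#' @param seed Integer RNG seed.
#'
#' @return A `bertx_sim` list with `wells` (columns `sample_id`, `gene`,
#'   `region`, `treatment` in `IP`/`input`, `replicate`, `ct`) and `truth`
#'   (planted occupancy and expected percent-input per region).
#' @examples
#' occ <- tibble::tibble(gene = "CDH23",
#'                       region = c("promoter", "middle", "end"),
#'                       occupancy = c(1, 2, 4))
#' simulate_chip_qpcr(occ, seed = 3)$wells
#' @export
simulate_chip_qpcr <- function(occupancy, input_fraction = 0.01,
                               promoter_percent_input = 1,
                               input_ct = 24, ct_noise_sd = 0.15,
                               n_replicates = 3L, efficiency = 2,
                               sample_id = "sim", seed = 1L) {
  check_columns(occupancy, c("gene", "region", "occupancy"), "`occupancy`")
  if (any(!is.finite(occupancy$occupancy)) || any(occupancy$occupancy <= 0)) {
    abort("All `occupancy` values must be finite and > 0.",
          class = "bertx_invalid_parameter")
  }
  check_number(input_fraction, "input_fraction", min = 0, max = 1,
               strict_min = TRUE)
  if (input_fraction >= 1) {
    abort("`input_fraction` must be < 1.", class = "bertx_invalid_parameter")
  }
  check_number(promoter_percent_input, "promoter_percent_input",
               min = 0, strict_min = TRUE)
  check_number(ct_noise_sd, "ct_noise_sd", min = 0)
  n_replicates <- check_count(n_replicates, "n_replicates")
  check_number(efficiency, "efficiency", min = 1, strict_min = TRUE)
  local_seed(seed)

  log_e <- function(x) log(x) / log(efficiency)
  # Ct of the notional 100% input template: the measured aliquot holds only
  # input_fraction of it, i.e. sits log_E(1/f) cycles later.
  full_input_ct <- input_ct - log_e(1 / input_fraction)

  plan <- occupancy |>
    dplyr::mutate(
      percent_input_true = promoter_percent_input * .data$occupancy,
      ct_ip_true = full_input_ct - log_e(.data$percent_input_true / 100),
      ct_input_true = input_ct
    )

  wells <- plan |>
    tidyr::expand_grid(treatment = c("IP", "input"),
                       replicate = seq_len(n_replicates)) |>
    dplyr::mutate(
      ct = dplyr::if_else(.data$treatment == "IP",
                          .data$ct_ip_true, .data$ct_input_true) +
        rnorm(dplyr::n(), 0, ct_noise_sd),
      sample_id = sample_id
    ) |>
    dplyr::select("sample_id", "gene", "region", "treatment", "replicate",
                  "ct")

  truth <- list(
    assay = "chip_qpcr",
    occupancy = plan |>
      dplyr::select("gene", "region", "occupancy", "percent_input_true"),
    input_fraction = input_fraction,
    promoter_percent_input = promoter_percent_input,
    input_ct = input_ct,
    ct_noise_sd = ct_noise_sd,
    n_replicates = n_replicates,
    efficiency = efficiency,
    seed = seed
  )
  new_bertx_sim(wells = wells, truth = truth)
}
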