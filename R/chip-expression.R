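#' Percent of chromatin input recovered by a ChIP
#'
#' Standard percent-input arithmetic: the measured input well contains only
#' `input_fraction` of the chromatin, so its Ct is first shifted by
#' `log_E(1/input_fraction)` cycles to represent 100% of input, then the IP
#' signal is expressed as a percentage of that:
#' `100 * E^((ct_input - log_E(1/input_fraction)) - ct_ip)`.
#'
#' @param ct_ip Ct of the immunoprecipitate well (vectorised).
#' @param ct_input Ct of the input-aliquot well.
#' @param input_fraction Fraction of chromatin kept as input (0 < f < 1).
#' @param efficiency Amplification factor E (> 1).
#' @return Percent input (>= 0; can exceed 100 for super-efficient pulldown).
#' @examples
#' percent_input(24, 24, input_fraction = 0.01)  # IP equals its 1% aliquot
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction, efficiency = 2) {
  check_number(ct_ip, "ct_ip", allow_vector = TRUE)
  check_number(ct_input, "ct_input", allow_vector = TRUE)
  check_number(input_fraction, "input_fraction", min = 0, max = 1,
               strict_min = TRUE)
  if (input_fraction >= 1) {
    abort("`input_fraction` must be < 1.", class = "bertx_invalid_parameter")
  }
  check_number(efficiency, "efficiency", min = 1, strict_min = TRUE)
  adj_input <- ct_input - log(1 / input_fraction) / log(efficiency)
  100 * efficiency^(adj_input - ct_ip)
}

#' Promoter-relative ChIP occupancy
#'
#' Expresses each region's percent input relative to the promoter of the
#' same gene: `relative occupancy = (% input of region) / (% input of
#' promoter)`. Promoter rows are exactly 1 by construction.
#'
#' @param occupancies Tibble with columns `gene`, `region`, `percent_input`
#'   (optionally `sample_id`).
#' @param promoter_region Label of the reference region.
#' @return Input with a `relative_occupancy` column added.
#' @export
relative_occupancy <- function(occupancies, promoter_region = "promoter") {
  check_columns(occupancies, c("gene", "region", "percent_input"),
                "`occupancies`")
  keys <- intersect(c("sample_id", "gene"), names(occupancies))
  ref <- occupancies |>
    dplyr::filter(.data$region == promoter_region) |>
    dplyr::select(dplyr::all_of(keys), ref_pi = "percent_input")
  out <- dplyr::left_join(occupancies, ref, by = keys)
  if (any(is.na(out$ref_pi))) {
    abort(sprintf("Missing `%s` percent_input for gene(s): %s.",
                  promoter_region,
                  paste(unique(out$gene[is.na(out$ref_pi)]), collapse = ", ")),
          class = "bertx_missing_data")
  }
  if (any(out$ref_pi == 0)) {
    abort("Promoter percent_input is 0; relative occupancy undefined.",
          class = "bertx_division_guard")
  }
  out |>
    dplyr::mutate(relative_occupancy = .data$percent_input / .data$ref_pi) |>
    dplyr::select(-"ref_pi")
}

#' ChIP occupancy profile from a well table
#'
#' Averages technical replicates on the Ct scale, computes percent input per
#' sample x gene x region, and normalizes each region to the promoter.
#'
#' @param wells Tidy Ct table with columns `sample_id`, `gene`, `region`,
#'   `treatment` (values `IP` / `input`), `replicate`, `ct`.
#' @inheritParams percent_input
#' @inheritParams relative_occupancy
#' @return Tibble of class `occupancy_profile`: one row per sample x gene x
#'   region with `percent_input` and `relative_occupancy`.
#' @examples
#' occ <- tibble::tibble(gene = "CDH23",
#'                       region = c("promoter", "middle", "end"),
#'                       occupancy = c(1, 2, 4))
#' sim <- simulate_chip_qpcr(occ, ct_noise_sd = 0, seed = 1)
#' chip_occupancy(sim$wells, input_fraction = 0.01)
#' @export
chip_occupancy <- function(wells, input_fraction, efficiency = 2,
                           promoter_region = "promoter") {
  check_columns(wells, c("sample_id", "gene", "region", "treatment", "ct"),
                "`wells`")
  arms <- c("IP", "input")
  missing_arms <- setdiff(arms, unique(wells$treatment))
  if (length(missing_arms) > 0L) {
    abort(sprintf("`wells` lacks treatment arm(s): %s.",
                  paste(missing_arms, collapse = ", ")),
          class = "bertx_missing_data")
  }
  wide <- wells |>
    dplyr::filter(.data$treatment %in% arms) |>
    aggregate_ct(.data$sample_id, .data$gene, .data$region,
                 .data$treatment) |>
    tidyr::pivot_wider(id_cols = c("sample_id", "gene", "region"),
                       names_from = "treatment", values_from = "ct_mean")
  if (any(is.na(wide$IP)) || any(is.na(wide$input))) {
    abort("Some sample/gene/region groups lack an IP or input arm.",
          class = "bertx_missing_data")
  }
  out <- wide |>
    dplyr::mutate(percent_input = percent_input(.data$IP, .data$input,
                                                input_fraction, efficiency)) |>
    dplyr::select("sample_id", "gene", "region", "percent_input") |>
    relative_occupancy(promoter_region = promoter_region)
  class(out) <- c("occupancy_profile", class(out))
  out
}

#' Fold change by the delta-delta-Ct method
#'
#' Relative expression of a target gene normalized to a reference transcript
#' (GAPDH in the assays this package models) and expressed against a
#' calibrator sample: `E^-((Ct_t,s - Ct_ref,s) - (Ct_t,cal - Ct_ref,cal))`.
#'
#' @param ct_target,ct_reference Ct of target and reference gene in the
#'   sample of interest (vectorised).
#' @param ct_target_calibrator,ct_reference_calibrator Same in the
#'   calibrator sample.
#' @param efficiency Amplification factor E (> 1).
#' @return Fold change (> 0; 1 for the calibrator itself).
#' @examples
#' relative_expression(24, 20, 25, 20)  # one cycle earlier -> 2-fold
#' @export
relative_expression <- function(ct_target, ct_reference,
                                ct_target_calibrator,
                                ct_reference_calibrator, efficiency = 2) {
  for (nm in c("ct_target", "ct_reference", "ct_target_calibrator",
               "ct_reference_calibrator")) {
    check_number(get(nm), nm, allow_vector = TRUE)
  }
  check_number(efficiency, "efficiency", min = 1, strict_min = TRUE)
  ddct <- (ct_target - ct_reference) -
    (ct_target_calibrator - ct_reference_calibrator)
  efficiency^(-ddct)
}

#' Expression fold changes across samples from a well table
#'
#' Averages replicates, forms delta-Ct against the reference gene within
#' each sample, and reports fold change of every sample against the
#' calibrator sample (which gets fold change 1 by construction).
#'
#' @param wells Tidy Ct table with columns `sample_id`, `gene`, `replicate`,
#'   `ct` (treatment column optional and ignored).
#' @param reference_gene Normalizer transcript (default `"GAPDH"`).
#' @param calibrator Sample id used as the fold-change baseline.
#' @param efficiency Amplification factor E (> 1).
#' @return Tibble with one row per sample x target gene: `delta_ct` (target
#'   minus reference) and `fold_change` vs the calibrator.
#' @export
expression_fold_change <- function(wells, reference_gene = "GAPDH",
                                   calibrator, efficiency = 2) {
  check_columns(wells, c("sample_id", "gene", "ct"), "`wells`")
  if (!reference_gene %in% wells$gene) {
    abort(sprintf("Reference gene `%s` absent from `wells`.", reference_gene),
          class = "bertx_missing_data")
  }
  if (!calibrator %in% wells$sample_id) {
    abort(sprintf("Calibrator sample `%s` absent from `wells`.", calibrator),
          class = "bertx_missing_data")
  }
  means <- aggregate_ct(wells, .data$sample_id, .data$gene)
  ref <- means |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select("sample_id", ref_ct = "ct_mean")
  dct <- means |>
    dplyr::filter(.data$gene != reference_gene) |>
    dplyr::inner_join(ref, by = "sample_id") |>
    dplyr::mutate(delta_ct = .data$ct_mean - .data$ref_ct)
  cal <- dct |>
    dplyr::filter(.data$sample_id == calibrator) |>
    dplyr::select("gene", cal_delta_ct = "delta_ct")
  dct |>
    dplyr::inner_join(cal, by = "gene") |>
    dplyr::mutate(fold_change =
                    efficiency^(-(.data$delta_ct - .data$cal_delta_ct))) |>
    dplyr::select("sample_id", "gene", "delta_ct", "fold_change")
}
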