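#' Average technical qPCR replicates on the Ct scale
#'
#' Replicate Ct values are averaged arithmetically on the cycle scale before
#' any delta-Ct arithmetic, the standard qPCR convention.
#'
#' @param wells Tidy well table with a `ct` column and the grouping columns.
#' @param ... Grouping columns (tidy-select); defaults to the well key
#'   `sample_id`, `gene`, `region`, `treatment` (whichever are present).
#' @return Tibble with one row per group: grouping columns, `ct_mean`,
#'   `n_replicates`.
#' @examples
#' tibble::tibble(sample_id = "s", gene = "g", region = "promoter",
#'                treatment = "IP", replicate = 1:3,
#'                ct = c(25.0, 25.2, 24.8)) |>
#'   aggregate_ct()
#' @export
aggregate_ct <- function(wells, ...) {
  check_columns(wells, "ct", "`wells`")
  if (nrow(wells) == 0L) {
    abort("`wells` is empty: no replicate groups to aggregate.",
          class = "bertx_missing_data")
  }
  if (any(!is.finite(wells$ct))) {
    abort("Non-finite Ct values in `wells`.",
          class = "bertx_validation_error")
  }
  keys <- rlang::enquos(...)
  if (length(keys) == 0L) {
    present <- intersect(c("sample_id", "gene", "region", "treatment"),
                         names(wells))
    keys <- rlang::syms(present)
  }
  wells |>
    dplyr::group_by(!!!keys) |>
    dplyr::summarise(ct_mean = mean(.data$ct),
                     n_replicates = dplyr::n(),
                     .groups = "drop")
}

#' Lesion delta-Ct between digestion arms
#'
#' The cycle shift between the glycosylase + AP-endonuclease arm and the
#' endonuclease-only baseline arm: `Ct(+AAG+APE1) - Ct(APE1-only)`. Positive
#' values mean template loss in the digested arm, i.e. lesions. Negative
#' values are returned unclamped (they are flagged only at the
#' lesion-frequency step).
#'
#' @param ct_plus Ct of the `AAG+APE1` arm (cycles, vectorised).
#' @param ct_minus Ct of the `APE1-only` arm.
#' @return Numeric delta-Ct in cycles.
#' @examples
#' lesion_delta_ct(26, 25)
#' @export
lesion_delta_ct <- function(ct_plus, ct_minus) {
  check_number(ct_plus, "ct_plus", allow_vector = TRUE)
  check_number(ct_minus, "ct_minus", allow_vector = TRUE)
  ct_plus - ct_minus
}

#' Lesions per amplicon from a delta-Ct
#'
#' Inverts the Poisson digestion model: an intact-template fraction
#' `E^(-delta_ct)` corresponds to `lambda = delta_ct * log(E)` mean lesions
#' per amplicon. Negative delta-Ct (baseline noise) is clamped to zero, since
#' negative lesion frequencies are unphysical; use the `clamped` attribute to
#' see which entries were floored.
#'
#' @param delta_ct Delta-Ct in cycles (vectorised).
#' @param efficiency Amplification factor E per cycle (> 1).
#' @return Numeric vector of lambda-hat values (>= 0) with a logical
#'   `clamped` attribute marking floored entries.
#' @examples
#' lesion_frequency(1, efficiency = 2)  # log(2)
#' @export
lesion_frequency <- function(delta_ct, efficiency = 2) {
  check_number(delta_ct, "delta_ct", allow_vector = TRUE)
  check_number(efficiency, "efficiency", min = 1, strict_min = TRUE)
  clamped <- delta_ct < 0
  lambda <- pmax(delta_ct, 0) * log(efficiency)
  attr(lambda, "clamped") <- clamped
  lambda
}

#' Promoter-relative lesion levels
#'
#' Expresses each region's lesion estimate relative to the promoter of the
#' same gene. The default `"ratio"` mode reports `lambda_hat /
#' lambda_hat[promoter]`, the physically interpretable quantity under the
#' Poisson model; `"ddct"` mode reports the cycle difference
#' `delta_ct - delta_ct[promoter]` instead. Promoter rows are exactly 1
#' (ratio mode) or 0 (ddct mode) by construction.
#'
#' @param estimates Tibble with columns `gene`, `region`, `delta_ct`,
#'   `lambda_hat` (one row per gene x region), e.g. from [lesion_profile()].
#' @param mode `"ratio"` or `"ddct"`.
#' @param promoter_region Label of the reference region.
#' @param pseudocount Added to a zero promoter `lambda_hat` in ratio mode to
#'   avoid division by zero; affected genes are flagged in
#'   `promoter_pseudocount` and a warning is emitted.
#' @return `estimates` with a `rel_to_promoter` column (and
#'   `promoter_pseudocount` flag in ratio mode).
#' @export
relative_lesions <- function(estimates, mode = c("ratio", "ddct"),
                             promoter_region = "promoter",
                             pseudocount = 0.01) {
  mode <- match.arg(mode)
  check_columns(estimates, c("gene", "region", "delta_ct", "lambda_hat"),
                "`estimates`")
  keys <- intersect(c("sample_id", "gene"), names(estimates))
  ref <- estimates |>
    dplyr::filter(.data$region == promoter_region) |>
    dplyr::select(dplyr::all_of(keys), ref_delta_ct = "delta_ct",
                  ref_lambda = "lambda_hat")
  out <- dplyr::left_join(estimates, ref, by = keys)
  if (any(is.na(out$ref_lambda))) {
    missing <- unique(out$gene[is.na(out$ref_lambda)])
    abort(sprintf("No `%s` row for gene%s %s.", promoter_region,
                  if (length(missing) > 1L) "s" else "",
                  paste(missing, collapse = ", ")),
          class = "bertx_missing_data")
  }
  if (mode == "ratio") {
    needs_eps <- out$ref_lambda == 0
    if (any(needs_eps)) {
      warn(sprintf(
        "Promoter lambda-hat is 0 for %d gene(s); pseudocount %g applied.",
        length(unique(out$gene[needs_eps])), pseudocount))
    }
    out <- out |>
      dplyr::mutate(
        promoter_pseudocount = .data$ref_lambda == 0,
        rel_to_promoter = (.data$lambda_hat +
                             ifelse(.data$promoter_pseudocount, pseudocount, 0)) /
          (.data$ref_lambda +
             ifelse(.data$promoter_pseudocount, pseudocount, 0))
      )
  } else {
    out <- dplyr::mutate(out,
                         rel_to_promoter = .data$delta_ct - .data$ref_delta_ct)
  }
  dplyr::select(out, -"ref_delta_ct", -"ref_lambda")
}

#' Region-specific lesion profile from a well table
#'
#' End-to-end lesion quantification: averages technical replicates on the Ct
#' scale, takes the arm difference per region, converts to lesions per
#' amplicon under the Poisson digestion model, and expresses each region
#' relative to the promoter.
#'
#' @param wells Tidy Ct table with columns `sample_id`, `gene`, `region`,
#'   `treatment` (values `AAG+APE1` / `APE1-only`), `replicate`, `ct`.
#' @inheritParams lesion_frequency
#' @inheritParams relative_lesions
#' @return Tibble of class `lesion_profile`: one row per sample x gene x
#'   region with `delta_ct`, `lambda_hat`, `clamped`, `rel_to_promoter`.
#' @examples
#' sim <- lesion_landscape("CRMP1") |>
#'   simulate_damage_qpcr(ct_noise_sd = 0, seed = 1)
#' lesion_profile(sim$wells)
#' @export
lesion_profile <- function(wells, efficiency = 2, mode = c("ratio", "ddct"),
                           pseudocount = 0.01) {
  mode <- match.arg(mode)
  check_columns(wells, c("sample_id", "gene", "region", "treatment", "ct"),
                "`wells`")
  arms <- c("AAG+APE1", "APE1-only")
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
  if (any(is.na(wide$`AAG+APE1`)) || any(is.na(wide$`APE1-only`))) {
    abort("Some sample/gene/region groups lack one of the two arms.",
          class = "bertx_missing_data")
  }
  out <- wide |>
    dplyr::mutate(
      delta_ct = lesion_delta_ct(.data$`AAG+APE1`, .data$`APE1-only`),
      lambda_hat = as.numeric(lesion_frequency(.data$delta_ct, efficiency)),
      clamped = .data$delta_ct < 0
    ) |>
    dplyr::select("sample_id", "gene", "region", "delta_ct", "lambda_hat",
                  "clamped") |>
    relative_lesions(mode = mode, pseudocount = pseudocount)
  class(out) <- c("lesion_profile", class(out))
  out
}
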