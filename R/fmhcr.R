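#' Gating configuration for FM-HCR flow analysis
#'
#' Thresholds for the standard pre-gating chain: scatter bounds to drop
#' debris and aggregates, an FSC-H/FSC-A ratio band to keep singlets, a
#' viability-dye ceiling to drop dead cells, and per-channel positivity
#' thresholds that split expressing cells from autofluorescent background.
#' Defaults match the intensity scales of [simulate_flow_experiment()].
#'
#' @param fsc_bounds,ssc_bounds Length-2 numeric intervals for FSC-A and
#'   SSC-A.
#' @param singlet_ratio_band Allowed FSC-H/FSC-A interval.
#' @param viability_max Events with viability dye above this are dead.
#' @param positivity Named numeric thresholds per fluorescence channel.
#' @return A validated list of class `gate_config`.
#' @export
gate_config <- function(fsc_bounds = c(10000, 120000),
                        ssc_bounds = c(5000, 80000),
                        singlet_ratio_band = c(0.8, 1.2),
                        viability_max = 1000,
                        positivity = c(ch_reporter = 1000,
                                       ch_egfp = 1000)) {
  for (iv in list(fsc_bounds = fsc_bounds, ssc_bounds = ssc_bounds,
                  singlet_ratio_band = singlet_ratio_band)) {
    if (length(iv) != 2L || any(!is.finite(iv[1])) || iv[1] >= iv[2]) {
      abort("Gate intervals must be increasing length-2 numerics.",
            class = "bertx_invalid_parameter")
    }
  }
  check_number(viability_max, "viability_max", min = 0)
  if (is.null(names(positivity)) || any(positivity < 0)) {
    abort("`positivity` must be a named vector of non-negative thresholds.",
          class = "bertx_invalid_parameter")
  }
  structure(list(fsc_bounds = fsc_bounds, ssc_bounds = ssc_bounds,
                 singlet_ratio_band = singlet_ratio_band,
                 viability_max = viability_max, positivity = positivity),
            class = "gate_config")
}

#' Gate live singlet events
#'
#' Retains events inside the scatter bounds, inside the FSC-H/FSC-A singlet
#' band, and below the viability-dye ceiling. Gating is idempotent: applying
#' it to its own output changes nothing.
#'
#' @param events Event tibble with columns `fsc_a`, `fsc_h`, `ssc_a`,
#'   `viability` (other columns pass through).
#' @param config A [gate_config()].
#' @return The gated subset of `events`. An empty result triggers a warning
#'   (downstream signal extraction then errors on an empty sample).
#' @export
gate_live_singlets <- function(events, config = gate_config()) {
  stopifnot(inherits(config, "gate_config"))
  check_columns(events, c("fsc_a", "fsc_h", "ssc_a", "viability"),
                "`events`")
  if (nrow(events) == 0L) {
    abort("`events` is empty.", class = "bertx_missing_data")
  }
  out <- events |>
    dplyr::filter(
      .data$fsc_a >= config$fsc_bounds[1],
      .data$fsc_a <= config$fsc_bounds[2],
      .data$ssc_a >= config$ssc_bounds[1],
      .data$ssc_a <= config$ssc_bounds[2],
      .data$fsc_h / .data$fsc_a >= config$singlet_ratio_band[1],
      .data$fsc_h / .data$fsc_a <= config$singlet_ratio_band[2],
      .data$viability <= config$viability_max
    )
  if (nrow(out) == 0L) {
    warn("Gating removed every event.")
  }
  out
}

#' Per-cell-normalized fluorescence signal of a gated sample
#'
#' Computes the reporter signal `F = (N x MFI) / S`, where `S` is the number
#' of live singlet events, `N` the number of those above the channel's
#' positivity threshold, and MFI the arithmetic mean intensity (linear
#' scale) of the `N` positive events. With no positive events `F = 0` and
#' MFI is reported as 0.
#'
#' @param gated Gated event tibble (see [gate_live_singlets()]).
#' @param channel Channel column to score (e.g. `"ch_reporter"`).
#' @param config A [gate_config()] providing the positivity threshold.
#' @return One-row tibble: `channel`, `n_positive`, `mfi`, `n_live`,
#'   `signal`.
#' @export
reporter_signal <- function(gated, channel = "ch_reporter",
                            config = gate_config()) {
  stopifnot(inherits(config, "gate_config"))
  check_columns(gated, channel, "`gated`")
  s <- nrow(gated)
  if (s == 0L) {
    abort("Empty gated sample: no live singlet events (S = 0).",
          class = "bertx_empty_sample")
  }
  thr <- config$positivity[[channel]]
  if (is.null(thr) || is.na(thr)) {
    abort(sprintf("No positivity threshold configured for channel `%s`.",
                  channel),
          class = "bertx_invalid_parameter")
  }
  x <- gated[[channel]]
  pos <- x > thr
  n <- sum(pos)
  mfi <- if (n > 0L) mean(x[pos]) else 0
  tibble(channel = channel, n_positive = n, mfi = mfi, n_live = s,
         signal = n * mfi / s)
}

#' Normalize a reporter signal to the transfection control
#'
#' `F_O = F / F_E`, with `F_E` the EGFP transfection-control signal of the
#' same sample.
#'
#' @param f Reporter signal F.
#' @param f_e EGFP control signal (> 0).
#' @param sample Label used in the error message when the control is zero.
#' @return Normalized signal F_O.
#' @export
normalize_to_transfection <- function(f, f_e, sample = "sample") {
  check_number(f, "f", min = 0, allow_vector = TRUE)
  check_number(f_e, "f_e", min = 0, allow_vector = TRUE)
  if (any(f_e == 0)) {
    abort(sprintf("Transfection control signal is 0 for %s.", sample),
          class = "bertx_transfection_control_error")
  }
  f / f_e
}

#' Percent reporter expression
#'
#' The repair-capacity readout: `%R.E. = 100 * F_O_dam / F_O_un`, the
#' normalized signal of the lesion-bearing reporter as a percentage of the
#' same reporter without damage. 100 means damage did not reduce expression
#' (complete repair); 0 means no functional reporter was produced.
#'
#' @param f_o_dam Normalized signal of the damaged-reporter sample.
#' @param f_o_un Normalized signal of the undamaged-reporter sample (> 0).
#' @return Percent reporter expression (>= 0).
#' @examples
#' percent_reporter_expression(0.5, 1)  # 50
#' @export
percent_reporter_expression <- function(f_o_dam, f_o_un) {
  check_number(f_o_dam, "f_o_dam", min = 0, allow_vector = TRUE)
  check_number(f_o_un, "f_o_un", min = 0, allow_vector = TRUE)
  if (any(f_o_un == 0)) {
    abort("Undamaged-control normalized signal is 0; %R.E. undefined.",
          class = "bertx_undamaged_control_error")
  }
  100 * f_o_dam / f_o_un
}

#' Repair capacity from a full FM-HCR experiment
#'
#' Runs the whole scoring chain for every sample: gate live singlets,
#' compute the reporter signal F and the EGFP control signal F_E, normalize
#' (F_O = F/F_E), pair each damaged sample with the undamaged sample of the
#' same condition and replicate, and take `%R.E. = 100 * F_O_dam / F_O_un`
#' per replicate. Replicate %R.E. values are then averaged per condition
#' (mean +/- SEM).
#'
#' @param events Event tibble for all samples, with a `sample_id` column and
#'   the channel/scatter columns of [gate_live_singlets()].
#' @param samples Sample sheet: `sample_id`, `condition`, `damaged`
#'   (logical), `replicate`.
#' @param config A [gate_config()].
#' @param reporter_channel,control_channel Channel column names.
#' @return Object of class `fmhcr_result` with elements `per_sample`
#'   (signals per sample), `per_replicate` (%R.E. per condition x
#'   replicate) and `by_condition` (mean, SEM, n). Use [tidy()], [glance()]
#'   or [autoplot()] on it.
#' @examples
#' sim <- simulate_flow_experiment(flow_sim_config(n_events = 2000, seed = 1))
#' fit <- analyze_fmhcr(sim$events, sim$samples)
#' tidy(fit)
#' @export
analyze_fmhcr <- function(events, samples, config = gate_config(),
                          reporter_channel = "ch_reporter",
                          control_channel = "ch_egfp") {
  check_columns(samples, c("sample_id", "condition", "damaged", "replicate"),
                "`samples`")
  check_columns(events, "sample_id", "`events`")
  missing <- setdiff(samples$sample_id, unique(events$sample_id))
  if (length(missing) > 0L) {
    abort(sprintf("No events for sample(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "bertx_missing_data")
  }

  per_sample <- samples |>
    dplyr::mutate(purrr::map_dfr(.data$sample_id, function(sid) {
      gated <- gate_live_singlets(
        dplyr::filter(events, .data$sample_id == sid), config)
      sig <- reporter_signal(gated, reporter_channel, config)
      ctrl <- reporter_signal(gated, control_channel, config)
      tibble(n_live = sig$n_live, n_positive = sig$n_positive,
             mfi = sig$mfi, f = sig$signal, f_e = ctrl$signal,
             f_o = normalize_to_transfection(sig$signal, ctrl$signal,
                                             sample = sid))
    }))

  paired <- per_sample |>
    dplyr::select("condition", "replicate", "damaged", "f_o") |>
    dplyr::mutate(arm = dplyr::if_else(.data$damaged, "dam", "un")) |>
    dplyr::select(-"damaged") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "f_o")
  if (!all(c("dam", "un") %in% names(paired)) ||
      any(is.na(paired$dam)) || any(is.na(paired$un))) {
    abort("Each condition x replicate needs both a damaged and an undamaged sample.",
          class = "bertx_pairing_error")
  }
  per_replicate <- paired |>
    dplyr::mutate(percent_re = percent_reporter_expression(.data$dam,
                                                           .data$un)) |>
    dplyr::select("condition", "replicate", f_o_dam = "dam", f_o_un = "un",
                  "percent_re")

  by_condition <- per_replicate |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mean_percent_re = mean(.data$percent_re),
      sem = if (dplyr::n() > 1L) sd(.data$percent_re) / sqrt(dplyr::n())
            else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )

  structure(list(per_sample = per_sample, per_replicate = per_replicate,
                 by_condition = by_condition),
            class = "fmhcr_result")
}

#' @export
print.fmhcr_result <- function(x, ...) {
  cat("<fmhcr_result>", nrow(x$per_sample), "samples,",
      nrow(x$by_condition), "condition(s)\n")
  print(x$by_condition)
  invisible(x)
}
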