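#' Configuration for the flow-cytometry reporter simulator
#'
#' Bundles and validates the parameters of [simulate_flow_experiment()].
#' Events are a mixture of live singlets, dead cells (high viability-dye
#' signal) and doublets (depressed FSC-H/FSC-A ratio); fluorescence channels
#' are two-component log-normal mixtures (autofluorescent background vs
#' expressing population), the minimal model that supports threshold gating.
#'
#' @param n_events Events per simulated sample (> 0).
#' @param transfection_rate Probability an event carries the reporter
#'   plasmids (the EGFP control channel is positive for these events).
#' @param repair_prob Probability `r` that a transfected cell repairs the
#'   lesion on the damaged reporter and expresses fluorescent protein; the
#'   expected percent reporter expression is `100 * r`.
#' @param dead_fraction,doublet_fraction Planted contamination fractions.
#' @param background,positive Lists with `meanlog`, `sdlog` for the
#'   log-normal intensity of non-expressing and expressing events; shared by
#'   the reporter and EGFP channels so damaged and undamaged samples are
#'   intensity-matched.
#' @param seed Integer RNG seed.
#' @return A validated list of class `flow_sim_config`.
#' @export
flow_sim_config <- function(n_events = 10000L,
                            transfection_rate = 0.4,
                            repair_prob = 0.25,
                            dead_fraction = 0.10,
                            doublet_fraction = 0.05,
                            background = list(meanlog = log(100), sdlog = 0.4),
                            positive = list(meanlog = log(10000), sdlog = 0.5),
                            seed = 1L) {
  n_events <- check_count(n_events, "n_events")
  check_probability(transfection_rate, "transfection_rate")
  check_probability(repair_prob, "repair_prob")
  check_probability(dead_fraction, "dead_fraction")
  check_probability(doublet_fraction, "doublet_fraction")
  for (pop in list(background = background, positive = positive)) {
    stopifnot(is.list(pop), all(c("meanlog", "sdlog") %in% names(pop)))
  }
  structure(
    list(n_events = n_events, transfection_rate = transfection_rate,
         repair_prob = repair_prob, dead_fraction = dead_fraction,
         doublet_fraction = doublet_fraction, background = background,
         positive = positive, seed = seed),
    class = "flow_sim_config"
  )
}

#' Simulate a paired damaged/undamaged FM-HCR flow experiment
#'
#' Emits event tables for the two samples of a host-cell reactivation
#' measurement: cells transfected with the lesion-bearing reporter plasmid
#' (`damaged`) and with the intact reporter (`undamaged`), each carrying an
#' EGFP transfection-control channel. On the damaged sample only the
#' transfected cells that repaired the lesion (probability `repair_prob`)
#' express fluorescent reporter; on the undamaged sample every transfected
#' cell does. Dead cells and doublets are planted at the configured
#' fractions so the gating chain can be validated.
#'
#' @param config A [flow_sim_config()].
#' @param condition,replicate Metadata stamped into the sample sheet.
#' @return A `bertx_sim` list with `events` (columns `sample_id`, `fsc_a`,
#'   `fsc_h`, `ssc_a`, `viability`, `ch_egfp`, `ch_reporter`), `samples`
#'   (sample sheet: `sample_id`, `condition`, `damaged`, `replicate`) and
#'   `truth` (planted probabilities; `expected_percent_re = 100 * repair_prob`).
#' @examples
#' sim <- simulate_flow_experiment(flow_sim_config(n_events = 500, seed = 2))
#' dplyr::count(sim$events, sample_id)
#' @export
simulate_flow_experiment <- function(config = flow_sim_config(),
                                     condition = "sim", replicate = 1L) {
  stopifnot(inherits(config, "flow_sim_config"))
  local_seed(config$seed)

  draw_sample <- function(sample_id, damaged) {
    n <- config$n_events
    doublet <- runif(n) < config$doublet_fraction
    dead <- runif(n) < config$dead_fraction
    transfected <- runif(n) < config$transfection_rate
    expressing <- transfected &
      (if (damaged) runif(n) < config$repair_prob else TRUE)

    fsc_a <- pmax(rnorm(n, 50000, 8000), 1)
    ratio <- ifelse(doublet, rnorm(n, 0.55, 0.05), rnorm(n, 1, 0.03))
    draw_chan <- function(on) {
      ifelse(on,
             rlnorm(n, config$positive$meanlog, config$positive$sdlog),
             rlnorm(n, config$background$meanlog, config$background$sdlog))
    }
    tibble(
      sample_id = sample_id,
      fsc_a = fsc_a,
      fsc_h = fsc_a * ratio,
      ssc_a = pmax(rnorm(n, 30000, 6000), 1),
      viability = ifelse(dead,
                         rlnorm(n, log(5000), 0.4),
                         rlnorm(n, log(100), 0.4)),
      ch_egfp = draw_chan(transfected),
      ch_reporter = draw_chan(expressing)
    )
  }

  prefix <- paste0(condition, "_rep", replicate)
  events <- dplyr::bind_rows(
    draw_sample(paste0(prefix, "_dam"), damaged = TRUE),
    draw_sample(paste0(prefix, "_un"), damaged = FALSE)
  )
  samples <- tibble(
    sample_id = paste0(prefix, c("_dam", "_un")),
    condition = condition,
    damaged = c(TRUE, FALSE),
    replicate = as.integer(replicate)
  )
  truth <- list(
    assay = "flow",
    repair_prob = config$repair_prob,
    expected_percent_re = 100 * config$repair_prob,
    transfection_rate = config$transfection_rate,
    dead_fraction = config$dead_fraction,
    doublet_fraction = config$doublet_fraction,
    n_events = config$n_events,
    seed = config$seed
  )
  new_bertx_sim(events = events, samples = samples, truth = truth)
}
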