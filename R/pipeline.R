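#' Run a simulate-then-analyze pipeline from a config
#'
#' Drives every selected assay end to end: generate synthetic data with the
#' configured parameters, run the matching estimator, and (optionally) write
#' tidy CSV outputs plus a provenance record (config hash, seed, package
#' version) so a rerun with the same config reproduces identical numbers.
#'
#' @param config A named list, or the path to a YAML file, with elements:
#'   `seed` (integer, required), `assays` (subset of `damage_qpcr`, `chip`,
#'   `flow`, `de`, `comet`; defaults to all), and one optional parameter
#'   block per assay, passed through to the corresponding simulator
#'   (`lesion_landscape()`/[simulate_damage_qpcr()], [simulate_chip_qpcr()],
#'   [flow_sim_config()], [de_sim_config()], [simulate_comet_cells()]).
#' @param out_dir Output directory; `NULL` (default) skips writing.
#' @return Named list per assay with `sim` (the `bertx_sim`) and `result`
#'   (the estimator output), plus a `provenance` element.
#' @examples
#' res <- run_pipeline(list(seed = 1, assays = "comet",
#'                          comet = list(n_cells_per_replicate = 10)))
#' res$comet$result
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  check_count(seed, "seed", min = 0L)
  all_assays <- c("damage_qpcr", "chip", "flow", "de", "comet")
  assays <- config$assays %||% all_assays
  bad <- setdiff(assays, all_assays)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown assay(s): %s.", paste(bad, collapse = ", ")),
          class = "bertx_invalid_parameter")
  }
  pars <- function(assay) config[[assay]] %||% list()
  results <- list()

  if ("damage_qpcr" %in% assays) {
    p <- pars("damage_qpcr")
    land <- lesion_landscape(
      genes = p$genes %||% "gene1",
      base_lambda = p$base_lambda %||% 0.1,
      end_enrichment = p$end_enrichment %||% 5
    )
    sim_args <- p[intersect(names(p), names(formals(simulate_damage_qpcr)))]
    sim <- do.call(simulate_damage_qpcr,
                   modifyList(list(landscape = land, seed = seed), sim_args))
    results$damage_qpcr <- list(
      sim = sim,
      result = lesion_profile(sim$wells,
                              efficiency = sim$truth$efficiency)
    )
  }
  if ("chip" %in% assays) {
    p <- pars("chip")
    occ <- if (!is.null(p$occupancy)) {
      as_tibble(p$occupancy)
    } else {
      tibble(gene = "gene1", region = region_levels(),
             occupancy = c(1, 2, 4))
    }
    sim_args <- p[intersect(names(p), names(formals(simulate_chip_qpcr)))]
    sim <- do.call(simulate_chip_qpcr,
                   modifyList(list(occupancy = occ, seed = seed), sim_args))
    results$chip <- list(
      sim = sim,
      result = chip_occupancy(sim$wells,
                              input_fraction = sim$truth$input_fraction,
                              efficiency = sim$truth$efficiency)
    )
  }
  if ("flow" %in% assays) {
    p <- pars("flow")
    cfg_args <- p[intersect(names(p), names(formals(flow_sim_config)))]
    cfg <- do.call(flow_sim_config, modifyList(list(seed = seed), cfg_args))
    sim <- simulate_flow_experiment(cfg)
    results$flow <- list(sim = sim,
                         result = analyze_fmhcr(sim$events, sim$samples))
  }
  if ("de" %in% assays) {
    p <- pars("de")
    cfg_args <- p[intersect(names(p), names(formals(de_sim_config)))]
    cfg <- do.call(de_sim_config, modifyList(list(seed = seed), cfg_args))
    sim <- simulate_de_tables(cfg)
    results$de <- list(sim = sim,
                       result = coregulation(sim$table_a, sim$table_b))
  }
  if ("comet" %in% assays) {
    p <- pars("comet")
    sim_args <- p[intersect(names(p), names(formals(simulate_comet_cells)))]
    sim <- do.call(simulate_comet_cells,
                   modifyList(list(seed = seed), sim_args))
    results$comet <- list(sim = sim, result = summarize_comet(sim$cells))
  }

  results$provenance <- list(
    config_hash = rlang::hash(config),
    seed = seed,
    assays = assays,
    package_version = as.character(packageVersion("bertx")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (assay in assays) {
      write_simulation(results[[assay]]$sim, out_dir, prefix = assay)
      res <- results[[assay]]$result
      res_tbl <- if (inherits(res, "data.frame")) res else tidy(res)
      readr::write_csv(res_tbl,
                       file.path(out_dir, paste0(assay, "_result.csv")))
    }
    jsonlite::write_json(results$provenance,
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  results
}
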