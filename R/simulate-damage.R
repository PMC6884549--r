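#' Construct a lesion landscape with a 3'-end damage gradient
#'
#' Builds the per-gene, per-region ground-truth lesion rates used by
#' [simulate_damage_qpcr()]. Each gene gets three amplicons (promoter, middle,
#' end of the gene body), following the design of region-specific
#' glycosylase/endonuclease digestion qPCR assays. The 3' end carries
#' `end_enrichment` times the promoter rate and the middle region sits at the
#' geometric mean of the two, giving the monotone promoter < middle < end
#' gradient observed for aberrantly methylated AAG substrates on co-regulated
#' genes.
#'
#' @param genes Character vector of gene identifiers.
#' @param base_lambda Mean lesions per amplicon at the promoter
#'   (dimensionless Poisson rate, >= 0).
#' @param end_enrichment Ratio of the 3'-end rate to the promoter rate (> 0).
#'   `1` gives a flat landscape.
#' @param amplicon_len_bp Amplicon length in base pairs; the default matches
#'   chromatin sheared to ~200 bp fragments.
#' @param seed Reserved for interface symmetry with the stochastic generators;
#'   the landscape itself is a deterministic function of the other arguments.
#'
#' @return A tibble with columns `gene`, `region` (`promoter`, `middle`,
#'   `end`), `lambda_true`, `amplicon_len_bp`.
#' @examples
#' lesion_landscape(c("ALDH1A2", "CRMP1"), base_lambda = 0.1, end_enrichment = 5)
#' @export
lesion_landscape <- function(genes, base_lambda = 0.1, end_enrichment = 5,
                             amplicon_len_bp = 200L, seed = NULL) {
  if (length(genes) < 1L || anyDuplicated(genes)) {
    abort("`genes` must be a non-empty vector of unique identifiers.",
          class = "bertx_invalid_parameter")
  }
  check_number(base_lambda, "base_lambda", min = 0)
  check_number(end_enrichment, "end_enrichment", min = 0, strict_min = TRUE)
  check_count(amplicon_len_bp, "amplicon_len_bp")

  lambdas <- base_lambda * c(
    promoter = 1,
    middle   = sqrt(end_enrichment),
    end      = end_enrichment
  )
  tidyr::expand_grid(gene = as.character(genes),
                     region = region_levels()) |>
    dplyr::mutate(
      lambda_true = unname(lambdas[.data$region]),
      amplicon_len_bp = as.integer(amplicon_len_bp)
    )
}

region_levels <- function() c("promoter", "middle", "end")

#' Intact fraction of amplicons under Poisson lesion placement
#'
#' Under the digestion model, lesions per amplicon are Poisson(`lambda`) and a
#' single lesion is enough for the glycosylase + AP-endonuclease combination
#' to cleave the fragment and block amplification. The amplifiable (intact)
#' fraction is therefore the Poisson zero class, `exp(-lambda)`.
#'
#' @param lambda Mean lesions per amplicon (>= 0, vectorised).
#' @return Numeric vector of intact fractions in (0, 1].
#' @seealso [mc_intact_fraction()] for the brute-force Monte-Carlo counterpart.
#' @export
intact_fraction <- function(lambda) {
  check_number(lambda, "lambda", min = 0, allow_vector = TRUE)
  exp(-lambda)
}

#' Monte-Carlo intact fraction by explicit fragment digestion
#'
#' Brute-force counterpart to the closed form [intact_fraction()]: draws a
#' Poisson lesion count for each of `n_fragments` simulated amplicons, cleaves
#' any fragment carrying at least one lesion, and reports the surviving
#' proportion. Used to validate the analytic zero-class formula.
#'
#' @param lambda Mean lesions per amplicon (>= 0, scalar).
#' @param n_fragments Number of fragments to simulate.
#' @param seed Integer RNG seed.
#' @return Proportion of fragments with zero lesions.
#' @export
mc_intact_fraction <- function(lambda, n_fragments = 1e5, seed = 1L) {
  check_number(lambda, "lambda", min = 0)
  n_fragments <- check_count(n_fragments, "n_fragments")
  local_seed(seed)
  lesions <- rpois(n_fragments, lambda)
  mean(lesions == 0L)
}

#' Simulate a region-specific damage-qPCR experiment
#'
#' Generates technical-replicate Ct values for the two digestion arms of the
#' aberrant-base mapping assay: genomic fragments treated with glycosylase
#' plus AP endonuclease (`AAG+APE1`, lesions cleave the template) and the
#' endonuclease-only baseline arm (`APE1-only`). For a region with true rate
#' `lambda`, the amplifiable template fraction is `exp(-lambda)`, so the
#' expected cycle shift between arms is `lambda / log(efficiency)`.
#'
#' @param landscape Tibble from [lesion_landscape()] (columns `gene`,
#'   `region`, `lambda_true`).
#' @param n_replicates Technical replicates per well group.
#' @param efficiency Per-cycle amplification factor E (> 1; 2 = perfect
#'   doubling).
#' @param ct_noise_sd Additive Gaussian Ct noise, in cycles.
#' @param baseline_ct Ct of undamaged template, in cycles.
#' @param control_lambda Lesion rate seen by the `APE1-only` arm
#'   (pre-existing AP sites / strand breaks); 0 by default so the arm is a
#'   pure baseline.
#' @param sample_id Sample label stamped on every well.
#' @param seed Integer RNG seed.
#'
#' @return A list of class `bertx_sim` with elements `wells` (tidy Ct table:
#'   `sample_id`, `gene`, `region`, `treatment`, `replicate`, `ct`) and
#'   `truth` (planted parameters, including per-region `lambda_true` and
#'   expected `delta_ct`).
#' @examples
#' sim <- lesion_landscape("CRMP1") |> simulate_damage_qpcr(seed = 7)
#' sim$wells
#' @export
simulate_damage_qpcr <- function(landscape, n_replicates = 3L, efficiency = 2,
                                 ct_noise_sd = 0.15, baseline_ct = 25,
                                 control_lambda = 0, sample_id = "sim",
                                 seed = 1L) {
  check_columns(landscape, c("gene", "region", "lambda_true"), "`landscape`")
  check_number(efficiency, "efficiency", min = 1, strict_min = TRUE)
  n_replicates <- check_count(n_replicates, "n_replicates")
  check_number(ct_noise_sd, "ct_noise_sd", min = 0)
  check_number(baseline_ct, "baseline_ct", min = 0, strict_min = TRUE)
  check_number(control_lambda, "control_lambda", min = 0)
  local_seed(seed)

  wells <- landscape |>
    dplyr::select("gene", "region", "lambda_true") |>
    tidyr::expand_grid(treatment = c("AAG+APE1", "APE1-only"),
                       replicate = seq_len(n_replicates)) |>
    dplyr::mutate(
      lambda_arm = dplyr::if_else(.data$treatment == "AAG+APE1",
                                  .data$lambda_true + control_lambda,
                                  control_lambda),
      ct_true = baseline_ct - log(intact_fraction(.data$lambda_arm)) /
        log(efficiency),
      ct = .data$ct_true + rnorm(dplyr::n(), 0, ct_noise_sd),
      sample_id = sample_id
    ) |>
    dplyr::select("sample_id", "gene", "region", "treatment", "replicate",
                  "ct")

  truth <- list(
    assay = "damage_qpcr",
    lambda_true = landscape |>
      dplyr::select("gene", "region", "lambda_true") |>
      dplyr::mutate(expected_delta_ct = .data$lambda_true / log(efficiency)),
    efficiency = efficiency,
    ct_noise_sd = ct_noise_sd,
    baseline_ct = baseline_ct,
    control_lambda = control_lambda,
    n_replicates = n_replicates,
    seed = seed
  )
  new_bertx_sim(wells = wells, truth = truth)
}

new_bertx_sim <- function(...) {
  structure(list(...), class = "bertx_sim")
}

#' @export
print.bertx_sim <- function(x, ...) {
  tables <- setdiff(names(x), "truth")
  cat("<bertx_sim> assay:", x$truth$assay %||% "?", "\n")
  for (nm in tables) {
    cat(" $", nm, ": ", nrow(x[[nm]]), " rows\n", sep = "")
  }
  cat(" $truth: ", length(x$truth), " planted parameters (seed ",
      x$truth$seed %||% NA, ")\n", sep = "")
  invisible(x)
}
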