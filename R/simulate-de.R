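#' Configuration for the two-knockout differential-expression simulator
#'
#' Describes a pair of DE tables (knockout A vs WT, knockout B vs WT) with a
#' planted co-regulation structure: genes regulated only in A, only in B, and
#' a shared overlap partitioned into four direction quadrants. The defaults
#' emulate the published HEK293T comparison of an AAG knockout (table A,
#' 1,045 DEGs, mostly up) and an ELP1 knockout (table B, 489 DEGs, 343 of
#' them down) sharing 113 co-regulated genes whose plurality is
#' up-in-A / down-in-B.
#'
#' @param n_genes Total genes per table.
#' @param n_a_only,n_b_only Genes regulated in one knockout only.
#' @param overlap_quadrants Named counts for the co-regulated genes:
#'   `up_down` (up in A, down in B), `up_up`, `down_down`, `down_up`.
#' @param a_only_up_fraction,b_only_down_fraction Direction splits of the
#'   single-table sets.
#' @param effect_size Planted |log2 fold change| for regulated genes (> 0).
#' @param null_sd Standard deviation of log2FC noise; applied to null genes
#'   and added on top of planted effects. `0` gives noiseless tables.
#' @param planted_p_max Upper bound of the uniform p-value draw for planted
#'   genes (null genes get Uniform(0, 1) p-values).
#' @param seed Integer RNG seed.
#' @return A validated list of class `de_sim_config`.
#' @export
de_sim_config <- function(n_genes = 10000L,
                          n_a_only = 932L,
                          n_b_only = 376L,
                          overlap_quadrants = c(up_down = 77L, up_up = 15L,
                                                down_down = 13L, down_up = 8L),
                          a_only_up_fraction = 0.65,
                          b_only_down_fraction = 0.673,
                          effect_size = 2,
                          null_sd = 0.1,
                          planted_p_max = 1e-6,
                          seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_a_only <- check_count(n_a_only, "n_a_only", min = 0L)
  n_b_only <- check_count(n_b_only, "n_b_only", min = 0L)
  quads <- c("up_down", "up_up", "down_down", "down_up")
  if (!all(quads %in% names(overlap_quadrants))) {
    abort("`overlap_quadrants` must be named counts for up_down, up_up, down_down, down_up.",
          class = "bertx_invalid_parameter")
  }
  overlap_quadrants <- vapply(overlap_quadrants[quads], check_count,
                              integer(1), name = "overlap_quadrants", min = 0L)
  n_planted <- n_a_only + n_b_only + sum(overlap_quadrants)
  if (n_planted > n_genes) {
    abort("Planted set sizes exceed `n_genes`.",
          class = "bertx_invalid_parameter")
  }
  check_probability(a_only_up_fraction, "a_only_up_fraction")
  check_probability(b_only_down_fraction, "b_only_down_fraction")
  check_number(effect_size, "effect_size", min = 0, strict_min = TRUE)
  check_number(null_sd, "null_sd", min = 0)
  check_number(planted_p_max, "planted_p_max", min = 0, max = 1)
  structure(
    list(n_genes = n_genes, n_a_only = n_a_only, n_b_only = n_b_only,
         overlap_quadrants = overlap_quadrants,
         a_only_up_fraction = a_only_up_fraction,
         b_only_down_fraction = b_only_down_fraction,
         effect_size = effect_size, null_sd = null_sd,
         planted_p_max = planted_p_max, seed = seed),
    class = "de_sim_config"
  )
}

#' Simulate paired knockout differential-expression tables
#'
#' Builds the two per-gene DE tables consumed by [call_degs()] and
#' [coregulation()], with membership, direction and quadrant of every
#' planted gene recorded in the truth object. Planted genes carry
#' `|log2fc| = effect_size` (plus `null_sd` noise) with the assigned sign
#' and small p-values; null genes get log2FC noise around zero and
#' Uniform(0, 1) p-values. FDR columns are Benjamini-Hochberg adjusted
#' within each table.
#'
#' @param config A [de_sim_config()].
#' @return A `bertx_sim` list with `table_a`, `table_b` (columns `gene`,
#'   `log2fc`, `pvalue`, `fdr`) and `truth` (per-gene `set`, `dir_a`,
#'   `dir_b`, `quadrant` plus the config).
#' @examples
#' sim <- simulate_de_tables(de_sim_config(n_genes = 500, n_a_only = 30,
#'   n_b_only = 20, overlap_quadrants = c(up_down = 8, up_up = 2,
#'   down_down = 2, down_up = 1), seed = 5))
#' head(sim$table_a)
#' @export
simulate_de_tables <- function(config = de_sim_config()) {
  stopifnot(inherits(config, "de_sim_config"))
  local_seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))

  oq <- config$overlap_quadrants
  n_overlap <- sum(oq)
  n_a <- config$n_a_only
  n_b <- config$n_b_only

  set <- rep("null", n)
  idx <- seq_len(n_a + n_b + n_overlap)
  set[idx] <- rep(c("a_only", "b_only", "overlap"),
                  times = c(n_a, n_b, n_overlap))

  dir_a <- rep(NA_character_, n)
  dir_b <- rep(NA_character_, n)
  a_idx <- which(set == "a_only")
  b_idx <- which(set == "b_only")
  dir_a[a_idx] <- ifelse(seq_along(a_idx) <=
                           round(config$a_only_up_fraction * n_a),
                         "up", "down")
  dir_b[b_idx] <- ifelse(seq_along(b_idx) <=
                           round(config$b_only_down_fraction * n_b),
                         "down", "up")
  o_idx <- which(set == "overlap")
  quadrant <- rep(NA_character_, n)
  quadrant[o_idx] <- rep(names(oq), times = oq)
  dir_a[o_idx] <- sub("_.*", "", quadrant[o_idx])
  dir_b[o_idx] <- sub(".*_", "", quadrant[o_idx])

  make_table <- function(dir) {
    planted <- !is.na(dir)
    sign <- ifelse(dir == "up", 1, -1)
    log2fc <- rnorm(n, 0, config$null_sd)
    log2fc[planted] <- log2fc[planted] + sign[planted] * config$effect_size
    pvalue <- runif(n)
    pvalue[planted] <- runif(sum(planted), 0, config$planted_p_max)
    tibble(gene = genes, log2fc = log2fc, pvalue = pvalue,
           fdr = bh_adjust(pvalue))
  }

  truth <- list(
    assay = "de_tables",
    genes = tibble(gene = genes, set = set, dir_a = dir_a, dir_b = dir_b,
                   quadrant = quadrant),
    n_overlap = n_overlap,
    overlap_quadrants = oq,
    effect_size = config$effect_size,
    null_sd = config$null_sd,
    seed = config$seed
  )
  new_bertx_sim(table_a = make_table(dir_a), table_b = make_table(dir_b),
                truth = truth)
}
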