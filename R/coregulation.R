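#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment of a p-value vector; output order
#' matches input order. Thin, validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values (FDR) in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues < 0 | pvalues > 1)) {
    abort("`pvalues` must be finite numbers in [0, 1].",
          class = "bertx_validation_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when `|log2fc| >= log2(min_fold)` and `fdr <= max_fdr`
#' (both inclusive); its direction is the sign of `log2fc`, and a fold
#' change of exactly 0 is never called. If the table lacks an `fdr` column
#' it is derived from `pvalue` via [bh_adjust()].
#'
#' @param records DE table with columns `gene`, `log2fc` and `fdr` (or
#'   `pvalue`).
#' @param min_fold Fold-change threshold on the linear scale (>= 1;
#'   1.5 and 2.0 are the thresholds used for the AAG and ELP1 knockouts this
#'   package models).
#' @param max_fdr FDR ceiling in (0, 1\].
#' @return Tibble of called genes: `gene`, `log2fc`, `fdr`, `direction`
#'   (`"up"` / `"down"`).
#' @examples
#' tibble::tibble(gene = c("a", "b"), log2fc = c(1, 0.2),
#'                fdr = c(0.01, 0.01)) |>
#'   call_degs(min_fold = 1.5, max_fdr = 0.1)
#' @export
call_degs <- function(records, min_fold = 1.5, max_fdr = 0.1) {
  check_columns(records, c("gene", "log2fc"), "`records`")
  if (anyDuplicated(records$gene)) {
    abort("Duplicate gene identifiers in DE table.",
          class = "bertx_validation_error")
  }
  check_number(min_fold, "min_fold", min = 1)
  check_number(max_fdr, "max_fdr", min = 0, max = 1, strict_min = TRUE)
  if (!"fdr" %in% names(records)) {
    if (!"pvalue" %in% names(records)) {
      abort("DE table needs an `fdr` or a `pvalue` column.",
            class = "bertx_validation_error")
    }
    records <- dplyr::mutate(records, fdr = bh_adjust(.data$pvalue))
  }
  records |>
    dplyr::filter(abs(.data$log2fc) >= log2(min_fold),
                  .data$log2fc != 0,
                  .data$fdr <= max_fdr) |>
    dplyr::mutate(direction = dplyr::if_else(.data$log2fc > 0, "up", "down")) |>
    dplyr::select("gene", "log2fc", "fdr", "direction")
}

#' Venn overlap of two DEG sets
#'
#' @param degs_a,degs_b DEG tables from [call_degs()] (columns `gene`,
#'   `direction`).
#' @return List with counts `n_a_only`, `n_b_only`, `n_overlap` and the
#'   corresponding gene character vectors.
#' @export
overlap_sets <- function(degs_a, degs_b) {
  check_columns(degs_a, c("gene", "direction"), "`degs_a`")
  check_columns(degs_b, c("gene", "direction"), "`degs_b`")
  shared <- intersect(degs_a$gene, degs_b$gene)
  a_only <- setdiff(degs_a$gene, shared)
  b_only <- setdiff(degs_b$gene, shared)
  list(n_a_only = length(a_only), n_b_only = length(b_only),
       n_overlap = length(shared),
       genes_a_only = a_only, genes_b_only = b_only,
       genes_overlap = shared)
}

#' Direction quadrants of co-regulated genes
#'
#' Assigns every gene called in both knockouts to one of four quadrants by
#' its direction in each set (`up_up`, `up_down`, `down_up`, `down_down`;
#' first position = set A). Counts always sum to the overlap size.
#'
#' @param degs_a,degs_b DEG tables from [call_degs()].
#' @param genes_overlap Optional overlap gene vector (computed if missing).
#' @return Tibble: `gene`, `dir_a`, `dir_b`, `quadrant`.
#' @export
direction_quadrants <- function(degs_a, degs_b, genes_overlap = NULL) {
  genes_overlap <- genes_overlap %||% intersect(degs_a$gene, degs_b$gene)
  dir_a <- setNames(degs_a$direction, degs_a$gene)[genes_overlap]
  dir_b <- setNames(degs_b$direction, degs_b$gene)[genes_overlap]
  if (any(is.na(dir_a)) || any(is.na(dir_b))) {
    abort("Gene in overlap lacks a direction in one of the sets.",
          class = "bertx_internal_consistency_error")
  }
  tibble(gene = genes_overlap, dir_a = unname(dir_a), dir_b = unname(dir_b),
         quadrant = paste(dir_a, dir_b, sep = "_"))
}

#' Two-knockout co-regulation analysis
#'
#' Calls DEGs in each knockout-vs-WT table at its own thresholds, computes
#' the Venn overlap and classifies every co-regulated gene into a direction
#' quadrant. This is the analysis behind statements such as "the majority of
#' co-regulated genes were upregulated in the AAG knockout and downregulated
#' in the ELP1 knockout".
#'
#' @param de_a,de_b DE tables (columns `gene`, `log2fc`, `fdr` or `pvalue`).
#' @param min_fold_a,max_fdr_a,min_fold_b,max_fdr_b Per-table thresholds;
#'   the defaults are the AAG-knockout (1.5-fold) and ELP1-knockout (2-fold)
#'   cuts at FDR 0.1.
#' @return Object of class `coregulation`: DEG tables, overlap counts and
#'   gene lists, quadrant table and quadrant counts. Use [tidy()],
#'   [glance()] or [autoplot()] on it.
#' @examples
#' sim <- simulate_de_tables(de_sim_config(n_genes = 1000, n_a_only = 50,
#'   n_b_only = 30, overlap_quadrants = c(up_down = 10, up_up = 3,
#'   down_down = 2, down_up = 1), seed = 2))
#' glance(coregulation(sim$table_a, sim$table_b))
#' @export
coregulation <- function(de_a, de_b, min_fold_a = 1.5, max_fdr_a = 0.1,
                         min_fold_b = 2.0, max_fdr_b = 0.1) {
  degs_a <- call_degs(de_a, min_fold_a, max_fdr_a)
  degs_b <- call_degs(de_b, min_fold_b, max_fdr_b)
  venn <- overlap_sets(degs_a, degs_b)
  quads <- direction_quadrants(degs_a, degs_b, venn$genes_overlap)
  quadrant_counts <- quads |>
    dplyr::count(.data$quadrant, name = "n") |>
    tidyr::complete(quadrant = c("up_up", "up_down", "down_up", "down_down"),
                    fill = list(n = 0L))
  structure(
    list(degs_a = degs_a, degs_b = degs_b, venn = venn, quadrants = quads,
         quadrant_counts = quadrant_counts,
         thresholds = list(a = c(min_fold = min_fold_a, max_fdr = max_fdr_a),
                           b = c(min_fold = min_fold_b, max_fdr = max_fdr_b))),
    class = "coregulation"
  )
}

#' @export
print.coregulation <- function(x, ...) {
  cat("<coregulation>\n")
  cat("  DEGs A:", nrow(x$degs_a), " DEGs B:", nrow(x$degs_b),
      " overlap:", x$venn$n_overlap, "\n")
  cat("  quadrants (A_B):",
      paste(x$quadrant_counts$quadrant, x$quadrant_counts$n, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
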