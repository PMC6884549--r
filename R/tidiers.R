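# broom-style accessors for the fitted/summarized result objects.

#' Tidy an FM-HCR result
#'
#' @param x An `fmhcr_result` from [analyze_fmhcr()].
#' @param ... Unused.
#' @return One row per condition x replicate with the normalized signals and
#'   percent reporter expression.
#' @method tidy fmhcr_result
#' @export
tidy.fmhcr_result <- function(x, ...) {
  x$per_replicate
}

#' Glance at an FM-HCR result
#'
#' @inheritParams tidy.fmhcr_result
#' @return One row per condition: `mean_percent_re`, `sem`, `n`.
#' @method glance fmhcr_result
#' @export
glance.fmhcr_result <- function(x, ...) {
  x$by_condition
}

#' Tidy a co-regulation analysis
#'
#' @param x A `coregulation` object.
#' @param ... Unused.
#' @return One row per co-regulated gene with its direction in each
#'   knockout and its quadrant.
#' @method tidy coregulation
#' @export
tidy.coregulation <- function(x, ...) {
  x$quadrants
}

#' Glance at a co-regulation analysis
#'
#' @inheritParams tidy.coregulation
#' @return One-row tibble with DEG counts, overlap and quadrant counts.
#' @method glance coregulation
#' @export
glance.coregulation <- function(x, ...) {
  qc <- setNames(as.list(x$quadrant_counts$n),
                 paste0("n_", x$quadrant_counts$quadrant))
  dplyr::bind_cols(
    tibble(n_degs_a = nrow(x$degs_a), n_degs_b = nrow(x$degs_b),
           n_a_only = x$venn$n_a_only, n_b_only = x$venn$n_b_only,
           n_overlap = x$venn$n_overlap),
    as_tibble(qc)
  )
}

#' Tidy a comet summary
#'
#' @param x A `comet_summary` object.
#' @param ... Unused.
#' @return One row per condition x enzyme group with mean percent tail and
#'   SEMs.
#' @method tidy comet_summary
#' @export
tidy.comet_summary <- function(x, ...) {
  x$groups
}

#' Glance at a comet summary
#'
#' @inheritParams tidy.comet_summary
#' @return One row per condition with the enzyme-specific damage signal.
#' @method glance comet_summary
#' @export
glance.comet_summary <- function(x, ...) {
  if (is.null(x$contrast)) return(tibble(condition = character(),
                                         aag_specific = numeric()))
  x$contrast
}
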