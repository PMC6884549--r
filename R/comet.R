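#' Percent DNA in the comet tail
#'
#' `100 * tail / (head + tail)`; scale-free in the common intensity factor,
#' always in \[0, 100\].
#'
#' @param head,tail Non-negative head and tail intensities (vectorised;
#'   their sum must be > 0 per cell).
#' @return Percent tail DNA.
#' @examples
#' percent_tail_dna(80, 20)
#' @export
percent_tail_dna <- function(head, tail) {
  check_number(head, "head", min = 0, allow_vector = TRUE)
  check_number(tail, "tail", min = 0, allow_vector = TRUE)
  if (any(head + tail == 0)) {
    abort("Comet with zero total intensity (head + tail = 0).",
          class = "bertx_empty_comet")
  }
  100 * tail / (head + tail)
}

#' Summarize comet-FLARE cells into group-level damage estimates
#'
#' Computes percent tail DNA per cell, then per (condition, enzyme) group:
#' the mean with SEM across cells and, when replicate labels are present,
#' SEM across replicate means. Within each condition the AAG-specific signal
#' is the difference in mean percent tail between the enzyme-digested arm
#' and the buffer arm - the extra breaks the glycosylase reveals at its
#' substrates.
#'
#' @param cells Tibble with columns `condition`, `enzyme` (values including
#'   `buffer` and the enzyme arm), `head_intensity`, `tail_intensity`, and
#'   optionally `replicate`.
#' @param enzyme_arm,buffer_arm Labels of the digestion and buffer arms.
#' @return Object of class `comet_summary` with elements `groups` (per-group
#'   means) and `contrast` (per-condition enzyme-specific signal). Use
#'   [tidy()], [glance()] or [autoplot()] on it.
#' @examples
#' sim <- simulate_comet_cells(n_cells_per_replicate = 20, seed = 1)
#' summarize_comet(sim$cells)
#' @export
summarize_comet <- function(cells, enzyme_arm = "AAG",
                            buffer_arm = "buffer") {
  check_columns(cells, c("condition", "enzyme", "head_intensity",
                         "tail_intensity"), "`cells`")
  if (nrow(cells) == 0L) {
    abort("`cells` is empty.", class = "bertx_missing_data")
  }
  scored <- cells |>
    dplyr::mutate(percent_tail = percent_tail_dna(.data$head_intensity,
                                                  .data$tail_intensity))
  groups <- scored |>
    dplyr::group_by(.data$condition, .data$enzyme) |>
    dplyr::summarise(
      mean_percent_tail = mean(.data$percent_tail),
      sem_cells = if (dplyr::n() > 1L) sd(.data$percent_tail) / sqrt(dplyr::n())
                  else NA_real_,
      n_cells = dplyr::n(),
      .groups = "drop"
    )
  if ("replicate" %in% names(scored)) {
    rep_sem <- scored |>
      dplyr::group_by(.data$condition, .data$enzyme, .data$replicate) |>
      dplyr::summarise(m = mean(.data$percent_tail), .groups = "drop_last") |>
      dplyr::summarise(
        sem_replicates = if (dplyr::n() > 1L) sd(.data$m) / sqrt(dplyr::n())
                         else NA_real_,
        n_replicates = dplyr::n(),
        .groups = "drop"
      )
    groups <- dplyr::left_join(groups, rep_sem,
                               by = c("condition", "enzyme"))
  }

  wide <- groups |>
    dplyr::select("condition", "enzyme", "mean_percent_tail") |>
    tidyr::pivot_wider(names_from = "enzyme",
                       values_from = "mean_percent_tail")
  contrast <- NULL
  if (all(c(enzyme_arm, buffer_arm) %in% names(wide))) {
    contrast <- wide |>
      dplyr::filter(!is.na(.data[[enzyme_arm]]),
                    !is.na(.data[[buffer_arm]])) |>
      dplyr::mutate(aag_specific =
                      .data[[enzyme_arm]] - .data[[buffer_arm]]) |>
      dplyr::select("condition", "aag_specific")
    dropped <- setdiff(wide$condition, contrast$condition)
    if (length(dropped) > 0L) {
      warn(sprintf("No %s/%s pair for condition(s) %s; contrast omitted.",
                   enzyme_arm, buffer_arm, paste(dropped, collapse = ", ")))
    }
  } else {
    warn(sprintf("Missing `%s` or `%s` arm; enzyme-specific contrast omitted.",
                 enzyme_arm, buffer_arm))
  }
  structure(list(groups = groups, contrast = contrast, cells = scored),
            class = "comet_summary")
}

#' @export
print.comet_summary <- function(x, ...) {
  cat("<comet_summary>\n")
  print(x$groups)
  if (!is.null(x$contrast)) {
    cat("enzyme-specific signal (percentage points):\n")
    print(x$contrast)
  }
  invisible(x)
}

#' One-way group comparison with multiple-testing correction
#'
#' The package's significance convention for grouped assay readouts: a
#' one-way ANOVA followed by Dunnett contrasts against a stated control
#' group (via the multcomp package when installed) or, as a fallback,
#' Holm-corrected pairwise t-tests, which is noted in the output.
#'
#' @param data Data frame with the response and grouping columns.
#' @param response,group Column names (strings).
#' @param control Control level for Dunnett contrasts (defaults to the first
#'   factor level).
#' @return List with the `aov` fit, a tidy `comparisons` tibble
#'   (`contrast`, `estimate`, `p_adjusted`) and the `method` used.
#' @export
group_anova <- function(data, response, group, control = NULL) {
  check_columns(data, c(response, group), "`data`")
  df <- data.frame(y = data[[response]],
                   g = factor(data[[group]]))
  if (!is.null(control)) df$g <- stats::relevel(df$g, ref = control)
  fit <- aov(y ~ g, data = df)
  if (requireNamespace("multcomp", quietly = TRUE)) {
    dn <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
    comparisons <- tibble(
      contrast = names(dn$test$coefficients),
      estimate = unname(dn$test$coefficients),
      p_adjusted = unname(dn$test$pvalues)
    )
    method <- "dunnett"
  } else {
    pw <- pairwise.t.test(df$y, df$g, p.adjust.method = "holm")
    comparisons <- as_tibble(as.data.frame(as.table(pw$p.value)),
                             .name_repair = "minimal") |>
      setNames(c("group1", "group2", "p_adjusted")) |>
      dplyr::filter(!is.na(.data$p_adjusted)) |>
      dplyr::mutate(contrast = paste(.data$group1, "-", .data$group2),
                    estimate = NA_real_) |>
      dplyr::select("contrast", "estimate", "p_adjusted")
    method <- "holm_pairwise"
    inform("multcomp not installed; using Holm-corrected pairwise t-tests.")
  }
  list(fit = fit, comparisons = comparisons, method = method)
}
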