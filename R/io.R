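# Canonical table schemas: required columns, numeric columns that must be
# finite, and key columns that must be jointly unique.

table_schemas <- function() {
  list(
    qpcr_wells = list(
      required = c("sample_id", "gene", "region", "treatment", "replicate",
                   "ct"),
      numeric = "ct",
      key = c("sample_id", "gene", "region", "treatment", "replicate")
    ),
    flow_events = list(
      required = c("sample_id", "fsc_a", "fsc_h", "ssc_a", "viability",
                   "ch_egfp", "ch_reporter"),
      numeric = c("fsc_a", "fsc_h", "ssc_a", "viability", "ch_egfp",
                  "ch_reporter"),
      key = character()
    ),
    de_records = list(
      required = c("gene", "log2fc", "pvalue", "fdr"),
      numeric = c("log2fc", "pvalue", "fdr"),
      key = "gene"
    ),
    comet_cells = list(
      required = c("cell_id", "condition", "enzyme", "replicate",
                   "head_intensity", "tail_intensity"),
      numeric = c("head_intensity", "tail_intensity"),
      key = "cell_id"
    ),
    gene_regions = list(
      required = c("gene", "region", "chrom", "start", "end"),
      numeric = c("start", "end"),
      key = c("gene", "region")
    )
  )
}

#' Load and validate a tidy assay table
#'
#' Reads a CSV and validates it against one of the package's table schemas:
#' required columns present, numeric columns finite, key columns jointly
#' unique. The schema-specific readers ([read_qpcr_wells()] and friends) are
#' thin wrappers over this.
#'
#' @param path CSV file path.
#' @param schema Schema name: one of `"qpcr_wells"`, `"flow_events"`,
#'   `"de_records"`, `"comet_cells"`, `"gene_regions"`.
#' @return Validated tibble.
#' @export
load_table <- function(path, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas)) {
    abort(sprintf("Unknown schema `%s`.", schema),
          class = "bertx_invalid_parameter")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_table(tbl, schema)
}

validate_table <- function(tbl, schema) {
  sc <- table_schemas()[[schema]]
  check_columns(tbl, sc$required, sprintf("`%s` table", schema))
  for (col in sc$numeric) {
    if (!is.numeric(tbl[[col]]) || any(!is.finite(tbl[[col]]))) {
      abort(sprintf("Column `%s` must be finite numeric.", col),
            class = "bertx_validation_error")
    }
  }
  if (length(sc$key) > 0L) {
    dup <- tbl |>
      dplyr::count(dplyr::across(dplyr::all_of(sc$key))) |>
      dplyr::filter(.data$n > 1L)
    if (nrow(dup) > 0L) {
      abort(sprintf("Duplicated key (%s) in `%s` table: %d duplicate group(s).",
                    paste(sc$key, collapse = ", "), schema, nrow(dup)),
            class = "bertx_validation_error")
    }
  }
  as_tibble(tbl)
}

#' @rdname load_table
#' @export
read_qpcr_wells <- function(path) load_table(path, "qpcr_wells")

#' @rdname load_table
#' @export
read_flow_events <- function(path) load_table(path, "flow_events")

#' @rdname load_table
#' @export
read_de_table <- function(path) load_table(path, "de_records")

#' @rdname load_table
#' @export
read_comet_cells <- function(path) load_table(path, "comet_cells")

#' Read gene-region definitions from a BED file
#'
#' Expects BED intervals (0-based half-open) whose name field encodes
#' `gene|region` (e.g. `ALDH1A2|promoter`). Parsed with rtracklayer when it
#' is installed.
#'
#' @param path BED file path.
#' @return Tibble with columns `gene`, `region`, `chrom`, `start`, `end`,
#'   `amplicon_len_bp` (`start`/`end` kept 0-based half-open).
#' @export
read_gene_regions <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_gene_regions() requires the rtracklayer package.",
          class = "bertx_missing_dependency")
  }
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  parts <- strsplit(as.character(gr$name), "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    abort("BED name field must encode `gene|region`.",
          class = "bertx_validation_error")
  }
  tbl <- tibble(
    gene = vapply(parts, `[[`, character(1), 1L),
    region = vapply(parts, `[[`, character(1), 2L),
    chrom = as.character(gr$seqnames),
    start = gr$start - 1L, # back to BED 0-based half-open
    end = gr$end
  ) |>
    dplyr::mutate(amplicon_len_bp = .data$end - .data$start)
  validate_table(tbl, "gene_regions")
}

#' Write a simulation to disk as tidy CSV plus a truth sidecar
#'
#' Each table element of the simulation becomes `<prefix>_<name>.csv`; the
#' planted ground truth is written as `<prefix>_truth.json` with data-frame
#' entries stored row-wise.
#'
#' @param sim A `bertx_sim` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to the assay label.
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir, prefix = NULL) {
  stopifnot(inherits(sim, "bertx_sim"))
  prefix <- prefix %||% sim$truth$assay %||% "sim"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- setdiff(names(sim), "truth")
  files <- character()
  for (nm in tables) {
    f <- file.path(dir, paste0(prefix, "_", nm, ".csv"))
    readr::write_csv(sim[[nm]], f)
    files <- c(files, f)
  }
  truth_file <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(sim$truth, truth_file, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(c(files, truth_file))
}
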