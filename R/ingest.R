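# Perturbation ingestion and direction labeling -------------------------------

#' Read a long-format perturbation table
#'
#' Expects a TSV or CSV (delimiter inferred from the extension) with columns
#' `drug_id`, `gene_symbol`, `cell_line`, `z_score`, `dose_value`,
#' `dose_unit`, `time_h`. Rows whose numeric fields fail to parse (including
#' non-finite Z-scores or non-positive times) are rejected with their row
#' indices.
#'
#' @param path Path to the file.
#' @return A tibble of perturbation records.
#' @export
read_perturbations <- function(path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  assert_columns(raw, c("drug_id", "gene_symbol", "cell_line", "z_score",
                        "dose_value", "dose_unit", "time_h"),
                 "perturbation table")
  if (nrow(raw) == 0) {
    return(tibble(drug_id = character(0), gene_symbol = character(0),
                  cell_line = character(0), z_score = numeric(0),
                  dose_value = numeric(0), dose_unit = character(0),
                  time_h = numeric(0)))
  }
  z <- suppressWarnings(as.numeric(raw$z_score))
  dv <- suppressWarnings(as.numeric(raw$dose_value))
  th <- suppressWarnings(as.numeric(raw$time_h))
  bad <- which(!is.finite(z) | !is.finite(dv) | !is.finite(th) | th <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed numeric fields in perturbation table at row%s %s",
      if (length(bad) > 1) "s" else "",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  raw |>
    mutate(z_score = z, dose_value = dv, time_h = th)
}

#' Read a longevity gene label table
#'
#' Expects a CSV/TSV with columns `gene_symbol` and `label`
#' (`"pro"`/`"anti"`). Each gene must carry exactly one label.
#'
#' @param path Path to the file.
#' @return A tibble with columns `gene_symbol`, `label`.
#' @export
read_longevity <- function(path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    gene_symbol = readr::col_character(), label = readr::col_character()
  ), progress = FALSE)
  assert_columns(tbl, c("gene_symbol", "label"), "longevity table")
  if (anyDuplicated(tbl$gene_symbol)) {
    abort("longevity table assigns more than one label to some gene")
  }
  if (!all(tbl$label %in% c("pro", "anti"))) {
    abort('longevity labels must be "pro" or "anti"')
  }
  tbl
}

#' Filter perturbation records by treatment conditions
#'
#' Keeps only records measured at the given treatment time and molecular
#' dose unit (both exact matches; the micro sign and the Greek small mu are
#' treated as the same character). Input row order is preserved.
#'
#' @param records Perturbation tibble.
#' @param time_h Required treatment time in hours (default 24).
#' @param dose_unit Required dose unit literal (default `"µM"`).
#' @return The filtered tibble.
#' @export
filter_records <- function(records, time_h = 24, dose_unit = "µM") {
  assert_columns(records, c("dose_unit", "time_h"), "perturbation table")
  records |>
    filter(.data$time_h == !!time_h,
           normalize_unit(.data$dose_unit) == normalize_unit(!!dose_unit))
}

#' Restrict perturbation records to a gene set
#'
#' @param records Perturbation tibble.
#' @param genes A longevity tibble (with `gene_symbol`) or a character vector
#'   of gene symbols.
#' @return Records whose `gene_symbol` is in the set, input order preserved.
#' @export
restrict_genes <- function(records, genes) {
  if (is.data.frame(genes)) genes <- genes$gene_symbol
  records |>
    filter(.data$gene_symbol %in% genes)
}

#' Label regulation direction by per-cell-line left-right percentile
#'
#' Within each cell line independently, marks exactly `floor(fraction * n)`
#' records positive: the largest Z-scores for `direction = "up"` (right
#' tail), the smallest for `direction = "down"` (left tail). All remaining
#' records -- whose regulating effect is unknown -- are treated as negative.
#' Ties are broken by `(drug_id, gene_symbol)` lexical order, so the result
#' is invariant to input row order.
#'
#' @param records Perturbation tibble.
#' @param direction `"up"` or `"down"`.
#' @param fraction Labeling fraction in (0, 0.5); default 0.05.
#' @return A labeled tibble: the input columns plus `direction` and
#'   `is_positive`, sorted by (cell_line, drug_id, gene_symbol).
#' @export
label_direction <- function(records, direction = c("up", "down"),
                            fraction = 0.05) {
  direction <- match.arg(direction)
  if (!(fraction > 0 && fraction < 0.5)) {
    abort("`fraction` must lie in (0, 0.5)")
  }
  assert_columns(records, c("drug_id", "gene_symbol", "cell_line", "z_score"),
                 "perturbation table")
  sgn <- if (direction == "up") -1 else 1    # -z sorts descending for "up"
  records |>
    group_by(.data$cell_line) |>
    arrange(sgn * .data$z_score, .data$drug_id, .data$gene_symbol,
            .by_group = TRUE) |>
    mutate(is_positive = row_number() <= floor(fraction * n())) |>
    ungroup() |>
    mutate(direction = direction) |>
    arrange(.data$cell_line, .data$drug_id, .data$gene_symbol)
}
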