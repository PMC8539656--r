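#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join inner_join semi_join anti_join bind_rows distinct n
#'   row_number desc pull count slice rename relocate if_else
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_chr map_dbl map_int map2 pmap imap walk
#' @importFrom stats rnorm rgamma runif predict setNames
#' @importFrom utils head
NULL

# floor(frac * n) with a guard against representation error such as
# (397/889) * 889 evaluating to 396.999...
floor_frac <- function(frac, n) {
  as.integer(floor(frac * n + 1e-9))
}

# Exact-match unit comparison after mapping the Greek small mu (U+03BC)
# onto the micro sign (U+00B5), so "μM" and "µM" are the same unit.
normalize_unit <- function(x) {
  stringr::str_replace_all(x, "μ", "µ")
}

assert_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# zero-padded identifier series, e.g. drug_ids(3) -> DRUG001 DRUG002 DRUG003
id_series <- function(prefix, n) {
  if (n == 0) return(character(0))
  sprintf(paste0(prefix, "%0", max(3L, nchar(n)), "d"), seq_len(n))
}
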