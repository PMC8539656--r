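# Drug repurposing: interaction ranking and prediction pools ------------------

#' Collect desired positive drug-gene-cell interactions
#'
#' Keeps the positive labeled interactions whose gene label matches the
#' desired mode -- upregulation of pro-longevity genes or downregulation of
#' anti-longevity genes -- and deduplicates them so each (gene, cell) pair
#' counts once per drug regardless of how many doses hit it.
#'
#' @param labeled Labeled interaction tibble from [label_direction()].
#' @param longevity Tibble with `gene_symbol`, `label` (`"pro"`/`"anti"`).
#' @param mode `"up-on-pro"` or `"down-on-anti"`; the labeled direction must
#'   agree with it.
#' @return Tibble of unique positive (`drug_id`, `gene_symbol`,
#'   `cell_line`) triples.
#' @export
collect_interactions <- function(labeled, longevity,
                                 mode = c("up-on-pro", "down-on-anti")) {
  mode <- match.arg(mode)
  want_dir <- if (mode == "up-on-pro") "up" else "down"
  want_label <- if (mode == "up-on-pro") "pro" else "anti"
  if (nrow(labeled) > 0 && !all(labeled$direction == want_dir)) {
    abort(sprintf("mode '%s' requires interactions labeled for direction '%s'",
                  mode, want_dir))
  }
  wanted_genes <- longevity$gene_symbol[longevity$label == want_label]
  labeled |>
    filter(.data$is_positive, .data$gene_symbol %in% wanted_genes) |>
    distinct(.data$drug_id, .data$gene_symbol, .data$cell_line)
}

#' Rank drugs by desired interaction counts
#'
#' Counts, per drug, its unique positive (gene, cell) interactions along
#' with the unique genes and cell lines they span; keeps only drugs whose
#' coverage is diverse enough (strictly more than `min_genes` unique genes
#' AND strictly more than `min_cells` unique cell lines); and returns the
#' top drugs by interaction count. Count ties are broken by drug id,
#' lexically.
#'
#' @param interactions Output of [collect_interactions()].
#' @param min_genes Gene-diversity filter; a drug must cover more than this
#'   many unique genes (default 100).
#' @param min_cells Cell-diversity filter, strict as well (default 5).
#' @param top_k Maximum ranking length (default 10).
#' @return A `drug_ranking` tibble: `rank`, `drug_id`, `n_interactions`,
#'   `n_unique_genes`, `n_unique_cells`.
#' @export
rank_drugs <- function(interactions, min_genes = 100, min_cells = 5,
                       top_k = 10) {
  counts <- interactions |>
    group_by(.data$drug_id) |>
    summarise(
      n_interactions = dplyr::n_distinct(paste(.data$gene_symbol, .data$cell_line)),
      n_unique_genes = dplyr::n_distinct(.data$gene_symbol),
      n_unique_cells = dplyr::n_distinct(.data$cell_line),
      .groups = "drop"
    ) |>
    filter(.data$n_unique_genes > min_genes, .data$n_unique_cells > min_cells) |>
    arrange(desc(.data$n_interactions), .data$drug_id) |>
    head(top_k) |>
    mutate(rank = row_number(), .before = 1)
  structure(counts, class = c("drug_ranking", class(counts)))
}

#' Drugs present in both an up- and a down-ranking
#'
#' @param up_rank,down_rank `drug_ranking` tibbles (e.g. the up-on-pro and
#'   down-on-anti top lists).
#' @return Tibble of shared drugs with their interaction counts in each
#'   list, ordered by combined interaction count, descending.
#' @export
intersect_rankings <- function(up_rank, down_rank) {
  inner_join(
    up_rank |> select("drug_id", up_interactions = "n_interactions"),
    down_rank |> select("drug_id", down_interactions = "n_interactions"),
    by = "drug_id"
  ) |>
    mutate(total_interactions = .data$up_interactions + .data$down_interactions) |>
    arrange(desc(.data$total_interactions), .data$drug_id)
}

#' Build a drug x gene x cell prediction pool
#'
#' Enumerates the full Cartesian product of candidate drugs, longevity genes
#' and (normal) cell lines -- every triple a trained model will score.
#'
#' @param drugs,genes,cells Nonempty character vectors.
#' @return A `prediction_pool` tibble of triples (`drug_id`, `gene_symbol`,
#'   `cell_line`), lexically ordered, with
#'   `|drugs| * |genes| * |cells|` rows.
#' @export
#' @examples
#' nrow(build_pool(paste0("D", 1:10), paste0("G", 1:397), c("N1", "N2")))
build_pool <- function(drugs, genes, cells) {
  for (axis in c("drugs", "genes", "cells")) {
    if (length(get(axis)) == 0) {
      abort(sprintf("`%s` must be nonempty to build a pool", axis))
    }
  }
  pool <- tidyr::expand_grid(
    drug_id = sort(unique(drugs)),
    gene_symbol = sort(unique(genes)),
    cell_line = sort(unique(cells))
  )
  structure(pool, class = c("prediction_pool", class(pool)))
}

# descriptor rows for pool triples; normal cells get an all-zero mutation
# block and their beta values at the model's selected sites
assemble_pool_features <- function(pool, features, feature_type,
                                   normal_beta = NULL) {
  beta <- normal_beta %||% features$beta
  missing_drug <- setdiff(unique(pool$drug_id), rownames(features$fp))
  missing_gene <- setdiff(unique(pool$gene_symbol), rownames(features$go))
  missing_cell <- setdiff(unique(pool$cell_line), rownames(beta))
  if (length(missing_drug) + length(missing_gene) + length(missing_cell) > 0) {
    abort(sprintf(
      "pool members lack descriptors: %s",
      paste(c(missing_drug, missing_gene, missing_cell), collapse = ", ")))
  }
  sel <- features$selected_sites
  missing_sites <- setdiff(sel, colnames(beta))
  if (length(missing_sites) > 0) {
    abort(sprintf("beta table lacks selected site(s): %s",
                  paste(missing_sites, collapse = ", ")))
  }
  blocks <- feature_blocks(feature_type)
  mut0 <- matrix(0, nrow = nrow(pool), ncol = ncol(features$mutations),
                 dimnames = list(NULL, colnames(features$mutations)))
  parts <- list(
    features$go[pool$gene_symbol, , drop = FALSE],
    features$fp[pool$drug_id, , drop = FALSE]
  )
  if ("mutation" %in% blocks) parts <- c(parts, list(mut0))
  if ("methylation" %in% blocks) {
    parts <- c(parts, list(beta[pool$cell_line, sel, drop = FALSE]))
  }
  x <- do.call(cbind, parts)
  rownames(x) <- NULL
  x
}

#' Score a prediction pool with a trained classifier
#'
#' Builds descriptor rows for every pool triple (normal cell lines carry an
#' all-zero mutation block), scores them, and summarizes per drug: pool
#' size, positive predictions at the threshold, positive rate, and the
#' number of unique genes among the positives.
#'
#' @param model A `gero_classifier` (its layout determines the feature
#'   blocks used).
#' @param pool A `prediction_pool` from [build_pool()].
#' @param features The `gero_features` bundle the model was trained from.
#' @param normal_beta Optional beta matrix for the pool's cell lines (rows =
#'   cell lines, columns covering the model's selected sites); defaults to
#'   the bundle's beta matrix. Missing sites are an error, not imputed.
#' @param threshold Positive-call threshold on the probability (default
#'   0.5).
#' @return A `pool_report` tibble: `drug_id`, `pool_size`, `n_positive`,
#'   `positive_rate`, `n_unique_genes`. The per-triple scores are attached
#'   as attribute `"scores"`.
#' @export
score_pool <- function(model, pool, features, normal_beta = NULL,
                       threshold = 0.5) {
  stopifnot(inherits(model, "gero_classifier"))
  x <- assemble_pool_features(pool, features, model$spec$feature_type,
                              normal_beta)
  proba <- predict_proba(model, x)
  scored <- pool |> mutate(probability = proba,
                           positive = proba >= threshold)
  report <- scored |>
    group_by(.data$drug_id) |>
    summarise(
      pool_size = n(),
      n_positive = sum(.data$positive),
      positive_rate = mean(.data$positive),
      n_unique_genes = dplyr::n_distinct(.data$gene_symbol[.data$positive]),
      .groups = "drop"
    )
  structure(report, class = c("pool_report", class(report)), scores = scored)
}

#' Plot a drug ranking or pool report
#'
#' For a `drug_ranking`: interaction counts per ranked drug. For a
#' `pool_report`: positive predictions and unique positive genes per drug,
#' side by side.
#'
#' @param object A `drug_ranking` or `pool_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot drug_ranking
#' @export
autoplot.drug_ranking <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$drug_id, .data$n_interactions),
    y = .data$n_interactions)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Unique positive (gene, cell) interactions") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.drug_ranking
#' @method autoplot pool_report
#' @export
autoplot.pool_report <- function(object, ...) {
  long <- object |>
    select("drug_id", `positive predictions` = "n_positive",
           `unique positive genes` = "n_unique_genes") |>
    tidyr::pivot_longer(-"drug_id", names_to = "measure", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$drug_id, y = .data$count,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("orange", "steelblue")) +
    ggplot2::labs(x = NULL, y = "Count", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
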