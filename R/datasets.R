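# Model layouts and dataset assembly ------------------------------------------

#' The eight model layouts
#'
#' Returns the standard grid of model configurations: models 1-2 predict up-
#' and downregulation over all cell lines with balanced class sampling and
#' the full feature set; models 3-8 use the imbalanced data of a named
#' two-cell-line subset with feature sets that drop the methylation block
#' (type 2) or the mutation block (type 3). Feature types: 1 = GO + drug
#' fingerprints + mutations + methylation; 2 = GO + fingerprints +
#' mutations; 3 = GO + fingerprints + methylation.
#'
#' @param subset_cells The two cell lines used by models 3-8; defaults to
#'   `c("U266", "NOMO1")` and should be overridden for synthetic worlds.
#' @return A tibble with columns `model_id`, `direction`, `cell_scope`,
#'   `cells` (list column; `NULL` means all), `balanced`, `feature_type`.
#' @export
model_specs <- function(subset_cells = c("U266", "NOMO1")) {
  tibble(
    model_id = 1:8,
    direction = rep(c("up", "down"), 4),
    cell_scope = c("all", "all", rep("subset", 6)),
    cells = c(list(NULL), list(NULL), rep(list(subset_cells), 6)),
    balanced = c(TRUE, TRUE, rep(FALSE, 6)),
    feature_type = c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L)
  )
}

#' Build all descriptor blocks for a world
#'
#' Convenience wrapper that computes every descriptor the models consume:
#' the GO one-hot gene matrix, the Morgan fingerprint drug matrix, the
#' mutation matrix, the beta-value matrix (including normal lines), and the
#' FCBF methylation-site selection against histology.
#'
#' @param world A `gero_world` (or an equivalent list of tables).
#' @param min_genes GO vocabulary threshold (default 3).
#' @param radius,n_bits Fingerprint parameters (defaults 2, 2048).
#' @param alpha Beta-value stabilizer (default 100).
#' @param delta FCBF relevance cutoff (default 0.6).
#' @param bins Equal-width bins for beta discretization (default 3).
#' @return A `gero_features` list: `go`, `fp`, `fp_failures`, `mutations`,
#'   `beta`, `fcbf`, `selected_sites`, `histology`, `normal_cells`, and the
#'   parameters used.
#' @export
featurize_world <- function(world, min_genes = 3, radius = 2, n_bits = 2048,
                            alpha = 100, delta = 0.6, bins = 3) {
  genes <- sort(unique(c(world$perturbations$gene_symbol,
                         world$longevity$gene_symbol)))
  go <- build_go_matrix(world$go_annotations, genes, min_genes = min_genes)
  fp <- fingerprint_drugs(world$smiles, radius = radius, n_bits = n_bits)
  mut <- as.matrix(world$mutations[, -1, drop = FALSE])
  rownames(mut) <- world$mutations$cell_line
  beta <- beta_matrix(world$intensities_meth, world$intensities_unmeth,
                      alpha = alpha)
  hist_cells <- world$histology$cell_line
  fcbf <- fcbf_select(
    discretize_beta(beta[hist_cells, , drop = FALSE], bins = bins),
    world$histology$histology, delta = delta
  )
  structure(
    list(go = go, fp = fp$matrix, fp_failures = fp$failures,
         mutations = mut, beta = beta, fcbf = fcbf,
         selected_sites = fcbf_features(fcbf),
         histology = world$histology,
         normal_cells = world$normal_cells %||% character(0),
         params = list(min_genes = min_genes, radius = radius,
                       n_bits = n_bits, alpha = alpha, delta = delta,
                       bins = bins)),
    class = "gero_features"
  )
}

#' @export
print.gero_features <- function(x, ...) {
  cat("<gero_features> ", nrow(x$go), " genes x ", ncol(x$go), " GO terms; ",
      nrow(x$fp), " drugs x ", ncol(x$fp), " fingerprint bits; ",
      nrow(x$mutations), " cell lines x ", ncol(x$mutations), " markers; ",
      length(x$selected_sites), " selected CpG sites\n", sep = "")
  invisible(x)
}

feature_blocks <- function(feature_type) {
  switch(feature_type,
         `1` = c("mutation", "methylation"),
         `2` = "mutation",
         `3` = "methylation",
         abort("`feature_type` must be 1, 2 or 3"))
}

#' Assemble a feature matrix for one model layout
#'
#' Restricts labeled interactions to the layout's cell scope, deduplicates
#' dose replicates of the same (drug, gene, cell) triple keeping the record
#' with the most extreme Z-score in the model's direction, drops samples
#' whose drug failed fingerprinting, and builds the design matrix by
#' concatenating descriptor blocks in fixed order gene | drug | cell.
#'
#' @param labeled Labeled interaction tibble from [label_direction()].
#' @param features A `gero_features` bundle from [featurize_world()].
#' @param spec One row of [model_specs()] (or a list with elements
#'   `direction`, `cells` (`NULL` = all), `feature_type`, `model_id`).
#' @param dedup Collapse dose replicates per (drug, gene, cell)? Default
#'   `TRUE`.
#' @return A `gero_dataset`: list with `x` (numeric matrix), `y` (integer
#'   0/1 target), `keys` (tibble of drug/gene/cell per row, sorted), `spec`.
#' @export
assemble <- function(labeled, features, spec, dedup = TRUE) {
  if (is.data.frame(spec)) spec <- as.list(spec[1, ])
  if (is.list(spec$cells)) spec$cells <- spec$cells[[1]]
  if (!all(labeled$direction == spec$direction)) {
    abort(sprintf("labeled interactions are for direction '%s' but the model predicts '%s'",
                  unique(labeled$direction)[1], spec$direction))
  }
  dat <- labeled
  if (!is.null(spec$cells)) {
    dat <- dat |> filter(.data$cell_line %in% spec$cells)
  }
  if (nrow(dat) > 0 && dedup) {
    sgn <- if (spec$direction == "up") -1 else 1
    dat <- dat |>
      group_by(.data$drug_id, .data$gene_symbol, .data$cell_line) |>
      arrange(sgn * .data$z_score, .by_group = TRUE) |>
      slice(1) |>
      ungroup()
  }
  known_drug <- dat$drug_id %in% rownames(features$fp)
  known_gene <- dat$gene_symbol %in% rownames(features$go)
  known_cell <- dat$cell_line %in% rownames(features$mutations) &
    dat$cell_line %in% rownames(features$beta)
  dropped <- sum(!(known_drug & known_gene & known_cell))
  if (dropped > 0) {
    inform(sprintf("assemble: dropped %d sample(s) lacking descriptors", dropped))
  }
  dat <- dat[known_drug & known_gene & known_cell, ] |>
    arrange(.data$drug_id, .data$gene_symbol, .data$cell_line)

  blocks <- feature_blocks(spec$feature_type)
  cell_part <- NULL
  sel <- features$selected_sites
  if (nrow(dat) > 0) {
    parts <- list(
      features$go[dat$gene_symbol, , drop = FALSE],
      features$fp[dat$drug_id, , drop = FALSE]
    )
    if ("mutation" %in% blocks) {
      parts <- c(parts, list(features$mutations[dat$cell_line, , drop = FALSE]))
    }
    if ("methylation" %in% blocks) {
      parts <- c(parts, list(features$beta[dat$cell_line, sel, drop = FALSE]))
    }
    x <- do.call(cbind, parts)
    rownames(x) <- NULL
  } else {
    width <- ncol(features$go) + ncol(features$fp) +
      if ("mutation" %in% blocks) ncol(features$mutations) else 0L
    width <- width + if ("methylation" %in% blocks) length(sel) else 0L
    x <- matrix(numeric(0), nrow = 0, ncol = width)
  }
  structure(
    list(
      x = x,
      y = as.integer(dat$is_positive),
      keys = dat |> select("drug_id", "gene_symbol", "cell_line",
                           "z_score", "is_positive"),
      spec = spec
    ),
    class = "gero_dataset"
  )
}

#' @export
print.gero_dataset <- function(x, ...) {
  cat("<gero_dataset> ", nrow(x$x), " samples x ", ncol(x$x), " features (",
      sum(x$y), " positive); direction ", x$spec$direction, ", feature type ",
      x$spec$feature_type, "\n", sep = "")
  invisible(x)
}

#' Balance a dataset by downsampling negatives
#'
#' Keeps every positive sample and draws, uniformly without replacement, an
#' equal number of negatives.
#'
#' @param dataset A `gero_dataset`.
#' @param seed Integer seed for the negative draw.
#' @return A `gero_dataset` with a 1:1 class ratio.
#' @export
balance <- function(dataset, seed = 1L) {
  pos <- which(dataset$y == 1)
  neg <- which(dataset$y == 0)
  if (length(pos) == 0) abort("cannot balance a dataset with no positives")
  if (length(neg) < length(pos)) {
    abort("fewer negatives than positives; balancing by downsampling undefined")
  }
  keep <- sort(c(pos, withr::with_seed(seed, sample(neg, length(pos)))))
  structure(
    list(x = dataset$x[keep, , drop = FALSE], y = dataset$y[keep],
         keys = dataset$keys[keep, ], spec = dataset$spec),
    class = "gero_dataset"
  )
}

#' Stratified k-fold partitions
#'
#' Splits rows into `k` disjoint, exhaustive validation folds, stratified by
#' the binary target so every fold's class mix tracks the global one.
#'
#' @param dataset A `gero_dataset`.
#' @param k Number of folds (default 3).
#' @param seed Integer seed for the shuffles.
#' @return A list of `k` elements, each `list(train = , val = )` of row
#'   indices.
#' @export
kfold <- function(dataset, k = 3, seed = 1L) {
  n <- length(dataset$y)
  if (n < k) abort("fewer rows than folds")
  if (sum(dataset$y == 1) < k) {
    abort(sprintf("only %d positive sample(s) for %d folds; use a smaller k",
                  sum(dataset$y == 1), k))
  }
  fold_of <- integer(n)
  withr::with_seed(seed, {
    for (cls in unique(dataset$y)) {
      idx <- sample(which(dataset$y == cls))
      fold_of[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  purrr::map(seq_len(k), function(f) {
    list(train = which(fold_of != f), val = which(fold_of == f))
  })
}
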