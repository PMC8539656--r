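# Shared fixtures, built lazily once per test run.
.fixtures <- new.env(parent = emptyenv())

test_world <- function() {
  if (is.null(.fixtures$world)) {
    .fixtures$cfg <- synth_config(seed = 42)
    .fixtures$world <- gen_world(.fixtures$cfg)
  }
  .fixtures$world
}
test_world_config <- function() {
  test_world()
  .fixtures$cfg
}

# small features bundle on the default world (256-bit fingerprints keep the
# design matrix small)
test_features <- function() {
  if (is.null(.fixtures$features)) {
    .fixtures$features <- suppressMessages(
      featurize_world(test_world(), n_bits = 256)
    )
  }
  .fixtures$features
}

test_labeled <- function(direction = "up") {
  key <- paste0("labeled_", direction)
  if (is.null(.fixtures[[key]])) {
    w <- test_world()
    .fixtures[[key]] <- w$perturbations |>
      filter_records() |>
      restrict_genes(unique(w$perturbations$gene_symbol)) |>
      label_direction(direction)
  }
  .fixtures[[key]]
}

# an independent, literal FCBF reference: rank by SU with the class,
# threshold, then remove features dominated by an earlier kept feature
reference_fcbf <- function(x, class, delta) {
  su <- vapply(colnames(x), function(f) symmetrical_uncertainty(x[, f], class),
               numeric(1))
  ord <- names(su)[order(-su, names(su))]
  ord <- ord[su[ord] >= delta]
  kept <- character(0)
  for (f in ord) {
    dominated <- any(vapply(kept, function(k) {
      symmetrical_uncertainty(x[, k], x[, f]) >= su[f]
    }, logical(1)))
    if (!dominated) kept <- c(kept, f)
  }
  kept
}
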