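# Gene, cell and methylation descriptors --------------------------------------

#' Build a one-hot GO-term gene descriptor matrix
#'
#' The term vocabulary consists of the GO terms that annotate at least
#' `min_genes` of the given genes, sorted lexically; each gene's row is its
#' binary membership vector over that vocabulary. Genes absent from the
#' annotation map get an all-zero row (reported via a message).
#'
#' @param annotations Tibble with columns `gene_symbol`, `go_term`.
#' @param genes Character vector of gene symbols (nonempty).
#' @param min_genes Minimum number of the given genes a term must annotate
#'   to enter the vocabulary (default 3).
#' @return Integer 0/1 matrix, rownames = `genes`, colnames = vocabulary.
#' @export
build_go_matrix <- function(annotations, genes, min_genes = 3) {
  assert_columns(annotations, c("gene_symbol", "go_term"), "GO annotation map")
  if (length(genes) == 0) abort("`genes` must be nonempty")
  ann <- annotations |>
    distinct(.data$gene_symbol, .data$go_term) |>
    filter(.data$gene_symbol %in% genes)
  vocab <- ann |>
    count(.data$go_term) |>
    filter(.data$n >= min_genes) |>
    pull(.data$go_term) |>
    sort()
  m <- matrix(0L, nrow = length(genes), ncol = length(vocab),
              dimnames = list(genes, vocab))
  ann <- ann |> filter(.data$go_term %in% vocab)
  if (nrow(ann) > 0) {
    m[cbind(match(ann$gene_symbol, genes), match(ann$go_term, vocab))] <- 1L
  }
  unannotated <- genes[rowSums(m) == 0]
  if (length(unannotated) > 0) {
    inform(sprintf("%d gene(s) have no vocabulary GO annotation (all-zero rows)",
                   length(unannotated)))
  }
  m
}

#' Methylation beta value from channel intensities
#'
#' Computes `max(meth, 0) / (max(meth, 0) + max(unmeth, 0) + alpha)`: the
#' methylated-channel intensity over the total intensity, stabilized by a
#' positive constant `alpha` in the denominator. Negative intensities are
#' clamped to zero, so the result always lies in `[0, 1)`.
#'
#' @param meth,unmeth Methylated / unmethylated probe intensities
#'   (vectorized).
#' @param alpha Positive stabilizing constant; 100 by default, the constant
#'   conventionally used for Illumina array beta values.
#' @return Beta values in `[0, 1)`.
#' @export
#' @examples
#' compute_beta(300, 700, 100)  # 300 / 1100
compute_beta <- function(meth, unmeth, alpha = 100) {
  if (any(alpha <= 0)) abort("`alpha` must be > 0")
  m <- pmax(meth, 0)
  u <- pmax(unmeth, 0)
  m / (m + u + alpha)
}

#' Beta-value matrix from wide intensity tables
#'
#' @param intensities_meth,intensities_unmeth Wide tibbles: `cell_line`
#'   column plus one column per CpG site (as written by [write_world()]).
#' @param alpha Passed to [compute_beta()].
#' @return Numeric matrix (cell lines x CpG sites).
#' @export
beta_matrix <- function(intensities_meth, intensities_unmeth, alpha = 100) {
  assert_columns(intensities_meth, "cell_line", "methylated intensity table")
  assert_columns(intensities_unmeth, "cell_line", "unmethylated intensity table")
  if (!identical(intensities_meth$cell_line, intensities_unmeth$cell_line) ||
      !identical(names(intensities_meth), names(intensities_unmeth))) {
    abort("intensity tables must have identical cell lines and CpG sites")
  }
  m <- as.matrix(intensities_meth[, -1, drop = FALSE])
  u <- as.matrix(intensities_unmeth[, -1, drop = FALSE])
  b <- compute_beta(m, u, alpha)
  rownames(b) <- intensities_meth$cell_line
  b
}

# plug-in entropy in bits of a discrete vector
entropy_bits <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

#' Symmetrical uncertainty between two discrete vectors
#'
#' `SU(x, y) = 2 I(x; y) / (H(x) + H(y))` with plug-in entropies in bits: a
#' normalized mutual-information dependence measure in `[0, 1]`. When either
#' variable is constant (zero entropy) the value is defined as 0.
#'
#' @param x,y Discrete vectors of equal length (>= 1).
#' @return A number in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1) {
    abort("`x` and `y` must be equal-length, nonempty vectors")
  }
  hx <- entropy_bits(x)
  hy <- entropy_bits(y)
  if (hx == 0 || hy == 0) return(0)
  hxy <- entropy_bits(paste(x, y, sep = "\r"))
  mi <- hx + hy - hxy
  max(0, min(1, 2 * mi / (hx + hy)))
}

#' Discretize beta values into equal-width bins
#'
#' @param beta Numeric matrix or vector of beta values in `[0, 1]`.
#' @param bins Number of equal-width bins on `[0, 1]` (default 3).
#' @return Integer bin indices (1..bins), same shape as `beta`.
#' @export
discretize_beta <- function(beta, bins = 3) {
  d <- pmin(pmax(floor(beta * bins) + 1L, 1L), as.integer(bins))
  if (is.matrix(beta)) d <- matrix(d, nrow = nrow(beta), dimnames = dimnames(beta))
  d
}

#' Fast correlation-based filter (FCBF) feature selection
#'
#' Ranks features by symmetrical uncertainty with the class, keeps those at
#' or above `delta`, then scans the kept features in rank order and removes
#' every later feature that is dominated by an earlier kept one (i.e. whose
#' SU with that feature is at least its SU with the class). SU rank ties are
#' broken by feature name, lexically, so the selection is invariant to input
#' column order.
#'
#' @param x Discrete feature matrix (rows = samples, named columns =
#'   features), e.g. a discretized beta matrix over cell lines.
#' @param class Discrete class vector (e.g. histology per cell line), length
#'   `nrow(x)`.
#' @param delta Relevance cutoff on SU with the class (default 0.6).
#' @return An `fcbf_result` tibble with columns `feature`, `su` (SU with the
#'   class), `selected`, ordered by decreasing relevance; selected rows form
#'   the predominant feature set. Attribute `delta` records the cutoff.
#' @export
fcbf_select <- function(x, class, delta = 0.6) {
  if (nrow(x) < 2) abort("FCBF needs at least 2 samples")
  if (length(class) != nrow(x)) abort("`class` must have one label per row of `x`")
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))

  su_class <- vapply(seq_len(ncol(x)), function(j) {
    symmetrical_uncertainty(x[, j], class)
  }, numeric(1))
  ranked <- tibble(feature = colnames(x), su = su_class) |>
    filter(.data$su >= delta) |>
    arrange(desc(.data$su), .data$feature)

  selected <- logical(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    dominated <- FALSE
    for (k in which(selected)) {
      su_ij <- symmetrical_uncertainty(x[, ranked$feature[k]],
                                       x[, ranked$feature[i]])
      if (su_ij >= ranked$su[i]) { dominated <- TRUE; break }
    }
    selected[i] <- !dominated
  }
  out <- ranked |> mutate(selected = selected)
  if (nrow(out) == 0) {
    inform(sprintf("FCBF: no feature reached the relevance cutoff %.2f", delta))
  }
  structure(out, class = c("fcbf_result", class(out)), delta = delta)
}

#' Selected features of an FCBF result
#'
#' @param fcbf An `fcbf_result` from [fcbf_select()].
#' @return Character vector of selected feature names, in selection order.
#' @export
fcbf_features <- function(fcbf) {
  stopifnot(inherits(fcbf, "fcbf_result"))
  fcbf$feature[fcbf$selected]
}

#' Assemble one cell line's descriptor vector
#'
#' Concatenates the binary mutation-marker block and the FCBF-selected
#' methylation beta block, in fixed order. A cell line declared `normal` is
#' treated as mutation-free (an all-zero mutation block), matching how
#' non-cancer lines carry no mutation annotation; its methylation block must
#' still be present in `beta`.
#'
#' @param cell Cell-line identifier.
#' @param mutations Binary matrix (cell lines x markers).
#' @param beta Numeric matrix (cell lines x CpG sites).
#' @param selected Character vector of selected CpG sites (e.g.
#'   [fcbf_features()]), or an `fcbf_result`.
#' @param normal If `TRUE`, the cell is a normal line absent from
#'   `mutations`; its mutation block is all zeros.
#' @return Named numeric vector: markers then selected sites.
#' @export
build_cell_descriptor <- function(cell, mutations, beta, selected,
                                  normal = FALSE) {
  if (inherits(selected, "fcbf_result")) selected <- fcbf_features(selected)
  if (normal) {
    mut <- setNames(numeric(ncol(mutations)), colnames(mutations))
  } else {
    if (!cell %in% rownames(mutations)) {
      abort(sprintf("cell line %s not found in mutation matrix", cell))
    }
    mut <- mutations[cell, ]
  }
  if (!cell %in% rownames(beta)) {
    abort(sprintf("cell line %s not found in beta matrix", cell))
  }
  missing_sites <- setdiff(selected, colnames(beta))
  if (length(missing_sites) > 0) {
    abort(sprintf("cell line %s is missing beta values for selected site(s): %s",
                  cell, paste(missing_sites, collapse = ", ")))
  }
  c(mut, beta[cell, selected])
}
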