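test_that("GO vocabulary keeps only terms annotating enough genes", {
  ann <- tibble::tibble(
    gene_symbol = c("g1", "g2", "g1", "g2", "g3", "g4"),
    go_term = c("T:rare", "T:rare", "T:common", "T:common", "T:common",
                "T:common")
  )
  m <- build_go_matrix(ann, c("g1", "g2", "g3", "g4", "g5"), min_genes = 3)
  expect_equal(colnames(m), "T:common")
  expect_equal(unname(m[, "T:common"]), c(1L, 1L, 1L, 1L, 0L))
  expect_true(all(colSums(m) >= 3))
})

test_that("GO matrix equals the brute-force membership table on a toy map", {
  genes <- paste0("g", 1:5)
  terms <- paste0("T", 1:6)
  set.seed(11)
  ann <- tidyr::expand_grid(gene_symbol = genes, go_term = terms) |>
    dplyr::slice_sample(prop = 0.6)
  m <- suppressMessages(build_go_matrix(ann, genes, min_genes = 1))
  for (g in genes) for (t in colnames(m)) {
    expect_equal(m[g, t],
                 as.integer(any(ann$gene_symbol == g & ann$go_term == t)))
  }
})

test_that("beta values follow the stabilized intensity ratio", {
  expect_equal(compute_beta(0, 500, 100), 0)
  expect_equal(compute_beta(-5, -5, 100), 0)      # clamped channels
  expect_equal(compute_beta(300, 700, 100), 300 / 1100)
  expect_error(compute_beta(1, 1, alpha = 0), "alpha")
})

test_that("beta is bounded and monotone in its arguments", {
  set.seed(12)
  meth <- runif(200, -100, 2000)
  unmeth <- runif(200, -100, 2000)
  b <- compute_beta(meth, unmeth, 100)
  expect_true(all(b >= 0 & b < 1))
  expect_true(all(compute_beta(meth + 50, unmeth, 100) >= b))
  expect_true(all(compute_beta(meth, unmeth + 50, 100) <= b))
  expect_true(all(compute_beta(meth, unmeth, 150) <= b))
})

test_that("symmetrical uncertainty matches a contingency-table oracle", {
  # exhaustive joint-count computation, written independently
  su_oracle <- function(x, y) {
    n <- length(x)
    hx <- -sum((table(x) / n) * log2(table(x) / n))
    hy <- -sum((table(y) / n) * log2(table(y) / n))
    if (hx == 0 || hy == 0) return(0)
    joint <- table(x, y) / n
    hxy <- -sum(joint[joint > 0] * log2(joint[joint > 0]))
    2 * (hx + hy - hxy) / (hx + hy)
  }
  x8 <- c(1, 1, 2, 2, 1, 2, 1, 2)
  y8 <- c(1, 1, 1, 2, 2, 2, 1, 2)
  expect_equal(symmetrical_uncertainty(x8, y8), su_oracle(x8, y8))

  set.seed(13)
  for (i in 1:25) {
    x <- sample(1:3, 12, replace = TRUE)
    y <- sample(1:2, 12, replace = TRUE)
    expect_equal(symmetrical_uncertainty(x, y), su_oracle(x, y))
    expect_equal(symmetrical_uncertainty(x, y), symmetrical_uncertainty(y, x))
  }
})

test_that("symmetrical uncertainty hits its boundary cases", {
  x <- c(1, 2, 1, 2, 2)
  expect_equal(symmetrical_uncertainty(x, x), 1)
  expect_equal(symmetrical_uncertainty(rep(1, 5), x), 0)
  expect_error(symmetrical_uncertainty(1:3, 1:4), "equal-length")
})

test_that("FCBF keeps a class-identical site and drops duplicated sites", {
  cls <- rep(c("a", "b"), each = 6)
  set.seed(14)
  x <- cbind(
    perfect = as.integer(factor(cls)),
    copy = as.integer(factor(cls)),       # redundant duplicate
    noise = sample(1:3, 12, replace = TRUE)
  )
  res <- suppressMessages(fcbf_select(x, cls, delta = 0.6))
  expect_equal(fcbf_features(res)[1], "copy")   # lexical tie-break on SU = 1
  expect_length(fcbf_features(res), 1)          # duplicate dominated
  expect_equal(res$su[1], 1)
})

test_that("FCBF equals brute-force enumeration on random small toys", {
  set.seed(15)
  for (i in 1:20) {
    cls <- sample(c("a", "b", "c"), 12, replace = TRUE)
    x <- matrix(sample(1:3, 12 * 6, replace = TRUE), nrow = 12,
                dimnames = list(NULL, paste0("s", 1:6)))
    # make a couple of sites informative
    x[, 1] <- as.integer(factor(cls))
    x[, 2] <- x[, 1]
    x[sample(12, 2), 2] <- 1L
    res <- suppressMessages(fcbf_select(x, cls, delta = 0.3))
    expect_equal(fcbf_features(res), reference_fcbf(x, cls, delta = 0.3))
  }
})

test_that("FCBF selection is invariant to site order", {
  set.seed(16)
  cls <- sample(c("a", "b"), 10, replace = TRUE)
  x <- matrix(sample(1:3, 10 * 5, replace = TRUE), nrow = 10,
              dimnames = list(NULL, paste0("s", 1:5)))
  x[, 3] <- as.integer(factor(cls))
  res1 <- suppressMessages(fcbf_select(x, cls, delta = 0.2))
  res2 <- suppressMessages(fcbf_select(x[, 5:1], cls, delta = 0.2))
  expect_equal(fcbf_features(res1), fcbf_features(res2))
})

test_that("selected relevance respects the cutoff and ordering", {
  feats <- test_features()
  res <- feats$fcbf
  expect_true(all(res$su >= attr(res, "delta")))
  expect_true(all(diff(res$su) <= 1e-12))
  expect_true(all(fcbf_features(res) %in% colnames(feats$beta)))
})

test_that("beta discretization uses equal-width bins", {
  expect_equal(discretize_beta(c(0, 0.2, 0.34, 0.5, 0.67, 0.99, 1)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 3L))
  m <- matrix(c(0.1, 0.9, 0.5, 0.4), 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(dimnames(discretize_beta(m)), dimnames(m))
})

test_that("cell descriptors concatenate mutation and methylation blocks", {
  mut <- matrix(c(1, 0, 1, 0, 1, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("CL1", "CL2"), c("m1", "m2", "m3")))
  beta <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), nrow = 2,
                 dimnames = list(c("CL1", "NORM1"), c("cg1", "cg2", "cg3")))
  d <- build_cell_descriptor("CL1", mut, beta, c("cg3", "cg1"))
  expect_equal(unname(d), c(1, 0, 1, 0.5, 0.1))    # manual assembly
  expect_length(d, 5)
  expect_identical(d, build_cell_descriptor("CL1", mut, beta, c("cg3", "cg1")))

  nd <- build_cell_descriptor("NORM1", mut, beta, c("cg3", "cg1"),
                              normal = TRUE)
  expect_equal(unname(nd[1:3]), c(0, 0, 0))
  expect_equal(unname(nd[4:5]), c(0.6, 0.2))

  expect_error(build_cell_descriptor("NOPE", mut, beta, "cg1"), "NOPE")
  expect_error(build_cell_descriptor("CL1", mut, beta, "cg9"), "cg9")
})
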