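toy_labeled <- function(rows) {
  tibble::tibble(
    drug_id = rows$d, gene_symbol = rows$g, cell_line = rows$c,
    z_score = if (is.null(rows$z)) 1 else rows$z,
    direction = if (is.null(rows$dir)) "up" else rows$dir,
    is_positive = if (is.null(rows$pos)) TRUE else rows$pos
  )
}

test_that("interaction collection honors gene labels and deduplicates doses", {
  longevity <- tibble::tibble(gene_symbol = c("PRO1", "PRO2", "ANTI1"),
                              label = c("pro", "pro", "anti"))
  lab <- toy_labeled(list(
    d = c("D1", "D1", "D1", "D2", "D2"),
    g = c("PRO1", "PRO1", "ANTI1", "PRO2", "PRO2"),
    c = c("C1", "C1", "C1", "C1", "C2"),
    z = c(3, 4, 5, 3, 3)
  ))
  ints <- collect_interactions(lab, longevity, "up-on-pro")
  # anti gene excluded; duplicate dose of (D1, PRO1, C1) collapsed
  expect_equal(nrow(ints), 3)
  expect_false("ANTI1" %in% ints$gene_symbol)
  expect_equal(sum(ints$drug_id == "D1"), 1)

  expect_equal(nrow(collect_interactions(lab[0, ], longevity, "up-on-pro")), 0)
  expect_error(collect_interactions(lab, longevity, "down-on-anti"),
               "direction 'down'")

  neg <- lab |> dplyr::mutate(is_positive = FALSE)
  expect_equal(nrow(collect_interactions(neg, longevity, "up-on-pro")), 0)
})

test_that("drug ranking applies strict diversity filters and sorts by count", {
  make_ints <- function(drug, n_genes, n_cells) {
    tidyr::expand_grid(gene_symbol = sprintf("G%03d", seq_len(n_genes)),
                       cell_line = sprintf("C%02d", seq_len(n_cells))) |>
      dplyr::mutate(drug_id = drug, .before = 1)
  }
  ints <- dplyr::bind_rows(
    make_ints("passes", 101, 6),
    make_ints("few_cells", 150, 5),   # 5 cells is not "more than five"
    make_ints("few_genes", 100, 9)    # 100 genes is not "above 100"
  )
  rk <- rank_drugs(ints)
  expect_equal(rk$drug_id, "passes")
  expect_equal(rk$n_interactions, 101 * 6)
  expect_equal(rk$n_unique_genes, 101)
  expect_equal(rk$n_unique_cells, 6)

  expect_equal(nrow(rank_drugs(ints, min_genes = 1000)), 0)

  toy <- dplyr::bind_rows(
    make_ints("a", 4, 3)[1:12, ], make_ints("b", 4, 3)[1:9, ],
    make_ints("c", 5, 4)
  )
  rk <- rank_drugs(toy, min_genes = 2, min_cells = 2, top_k = 10)
  expect_equal(rk$n_interactions, c(20, 12, 9))   # sort oracle
  expect_equal(rk$drug_id, c("c", "a", "b"))
  expect_equal(rk$rank, 1:3)

  shuffled <- toy[withr::with_seed(31, sample(nrow(toy))), ]
  expect_equal(rank_drugs(shuffled, min_genes = 2, min_cells = 2), rk)
})

test_that("relaxing the diversity filters never shrinks the passing set", {
  w <- test_world()
  lab <- test_labeled("up")
  ints <- collect_interactions(lab, w$longevity, "up-on-pro")
  strict <- rank_drugs(ints, min_genes = 3, min_cells = 3, top_k = Inf)
  loose <- rank_drugs(ints, min_genes = 1, min_cells = 1, top_k = Inf)
  expect_true(all(strict$drug_id %in% loose$drug_id))
})

test_that("ranking intersection is an ordered set intersection", {
  mk <- function(ids, counts) {
    tibble::tibble(rank = seq_along(ids), drug_id = ids,
                   n_interactions = counts,
                   n_unique_genes = counts, n_unique_cells = counts)
  }
  a <- mk(c("d1", "d2", "d3", "d4", "d5"), c(50, 40, 30, 20, 10))
  b <- mk(c("d9", "d3", "d2", "d8", "d5", "d6"), c(60, 50, 40, 30, 20, 10))
  both <- intersect_rankings(a, b)
  expect_setequal(both$drug_id, c("d2", "d3", "d5"))
  expect_equal(both$total_interactions, sort(both$total_interactions,
                                             decreasing = TRUE))
  # set identity: intersection plus symmetric differences recover the union
  expect_setequal(c(both$drug_id, setdiff(a$drug_id, b$drug_id),
                    setdiff(b$drug_id, a$drug_id)),
                  union(a$drug_id, b$drug_id))

  disjoint <- intersect_rankings(mk("x", 1), mk("y", 1))
  expect_equal(nrow(disjoint), 0)
})

test_that("prediction pools are exact Cartesian products", {
  pool <- build_pool(sprintf("D%02d", 1:10), sprintf("G%03d", 1:397),
                     c("N1", "N2"))
  expect_equal(nrow(pool), 7940)
  expect_equal(nrow(build_pool(sprintf("D%02d", 1:10),
                               sprintf("G%03d", 1:492), c("N1", "N2"))),
               9840)
  expect_equal(nrow(build_pool("d", "g", "c")), 1)
  expect_false(anyDuplicated(build_pool(c("a", "b"), c("x", "y"), "c")) > 0)
  expect_error(build_pool(character(0), "g", "c"), "drugs")
  expect_error(build_pool("d", "g", character(0)), "cells")
})

test_that("pool scoring summarizes per-drug positives and boundary cases", {
  w <- test_world()
  feats <- test_features()
  lab <- test_labeled("up")
  bal <- balance(assemble(lab, feats, model_specs()[1, ]), seed = 2)
  clf <- train_classifier(bal, "ridge_logistic", seed = 2)

  pro <- w$longevity$gene_symbol[w$longevity$label == "pro"][1:8]
  pool <- build_pool(rownames(feats$fp)[1:4], pro, w$normal_cells)
  rep <- score_pool(clf, pool, feats)
  expect_equal(rep$pool_size, rep(8 * length(w$normal_cells), 4))
  expect_true(all(rep$n_positive <= rep$pool_size))
  expect_true(all(rep$n_unique_genes <= rep$n_positive |
                    (rep$n_positive == 0 & rep$n_unique_genes == 0)))
  expect_true(all(rep$positive_rate >= 0 & rep$positive_rate <= 1))

  # hand count from the attached per-triple scores
  scores <- attr(rep, "scores")
  for (d in rep$drug_id) {
    sub <- scores[scores$drug_id == d, ]
    expect_equal(rep$n_positive[rep$drug_id == d], sum(sub$probability >= 0.5))
    expect_equal(rep$n_unique_genes[rep$drug_id == d],
                 length(unique(sub$gene_symbol[sub$positive])))
  }

  # boundary thresholds: everything positive / nothing positive
  all_pos <- score_pool(clf, pool, feats, threshold = 0)
  expect_true(all(all_pos$positive_rate == 1))
  none <- score_pool(clf, pool, feats, threshold = 1.000001)
  expect_true(all(none$positive_rate == 0))
  expect_true(all(none$n_unique_genes == 0))

  # unknown pool member is an error naming the entity
  bad <- build_pool("NOT_A_DRUG", pro, w$normal_cells)
  expect_error(score_pool(clf, bad, feats), "NOT_A_DRUG")
})
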