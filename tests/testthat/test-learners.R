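separable_dataset <- function(n = 240, width = 10, seed = 21) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * width), nrow = n)
    x[, 1] <- x[, 1] + 3 * y
    colnames(x) <- paste0("f", seq_len(width))
  })
  structure(
    list(x = x, y = y,
         keys = tibble::tibble(drug_id = sprintf("D%03d", seq_len(n)),
                               gene_symbol = "G", cell_line = "C",
                               z_score = 0, is_positive = y == 1),
         spec = list(model_id = 1L, direction = "up", cells = NULL,
                     balanced = TRUE, feature_type = 1L)),
    class = "gero_dataset"
  )
}

test_that("DNN layer widths follow the equal-to-input policy", {
  net <- build_dnn(100, dnn_config(seed = 1))
  expect_equal(dim(net$W1), c(100, 100))
  expect_equal(dim(net$W2), c(100, 100))
  expect_equal(dim(net$W3), c(100, 2))
  # closed-form parameter count: w*w + w twice, then w*2 + 2
  w <- 100
  expect_equal(dnn_n_params(net), (w * w + w) + (w * w + w) + (2 * w + 2))
  expect_error(build_dnn(0), "input_width")
})

test_that("untrained forward passes are proper softmax distributions", {
  net <- build_dnn(7, dnn_config(seed = 2))
  x <- matrix(rnorm(35), nrow = 5)
  p <- gerochem:::dnn_forward(net, x)$p
  expect_equal(rowSums(p), rep(1, 5))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("inference is deterministic: identical rows score identically", {
  ds <- separable_dataset(60)
  net <- fit_dnn(build_dnn(ncol(ds$x), dnn_config(max_epochs = 5, seed = 3)),
                 ds$x, ds$y)
  x2 <- ds$x[c(1, 1), , drop = FALSE]
  p <- gerochem:::dnn_forward(net, x2)$p
  expect_equal(p[1, ], p[2, ])
})

test_that("early stopping retains the best monitored checkpoint", {
  ds <- separable_dataset(120)
  net <- fit_dnn(build_dnn(ncol(ds$x), dnn_config(max_epochs = 40, seed = 4)),
                 ds$x[1:80, ], ds$y[1:80], ds$x[81:120, ], ds$y[81:120])
  h <- net$history
  expect_equal(min(h$monitored_loss), h$monitored_loss[net$best_epoch])
  expect_lte(h$monitored_loss[net$best_epoch], h$monitored_loss[1])
})

test_that("evaluation metrics match hand-counted confusion entries", {
  perfect <- evaluate(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc_roc, 1)
  expect_equal(perfect$apr, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  # TP = 3, FP = 1, FN = 2, TN = 4 at threshold 0.5
  y <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  s <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.2, 0.1, 0.1)
  ev <- evaluate(y, s)
  expect_equal(c(ev$tp, ev$fp, ev$fn, ev$tn), c(3, 1, 2, 4))
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.6)
  expect_equal(ev$accuracy, 0.7)

  set.seed(22)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(30), 2)
    ev <- evaluate(y, s, threshold = 0.5)
    expect_equal(ev$tp, sum(s >= 0.5 & y == 1))
    expect_equal(ev$fp, sum(s >= 0.5 & y == 0))
    expect_equal(ev$precision, ev$tp / (ev$tp + ev$fp))
    expect_equal(ev$recall, ev$tp / (ev$tp + ev$fn))
  }
})

test_that("AUC equals brute-force pairwise concordance (and pROC agrees)", {
  concordance <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(23)
  for (i in 1:15) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), 1)   # coarse scores force ties
    expect_equal(evaluate(y, s)$auc_roc, concordance(y, s))
  }
  y <- rbinom(150, 1, 0.5); s <- rnorm(150)
  expect_equal(evaluate(y, s)$auc_roc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("random scores give chance-level AUC on a large sample", {
  set.seed(24)
  y <- rep(c(0, 1), 5000)
  s <- runif(10000)
  expect_lt(abs(evaluate(y, s)$auc_roc - 0.5), 0.02)
})

test_that("single-class truth yields undefined ranking metrics", {
  ev <- evaluate(c(1, 1, 1), c(0.9, 0.2, 0.7))
  expect_true(is.na(ev$auc_roc))
  expect_true(is.na(ev$apr))
  expect_equal(ev$recall, 2 / 3)
})

test_that("training rejects single-class datasets and mismatched widths", {
  ds <- separable_dataset(40)
  ds$y <- rep(1L, 40)
  expect_error(train_classifier(ds, "ridge_logistic"), "negative")

  ds2 <- separable_dataset(90)
  clf <- train_classifier(ds2, "ridge_logistic", seed = 5)
  expect_error(predict_proba(clf, ds2$x[, 1:4]), "width mismatch")
  p <- predict_proba(clf, ds2$x)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("ridge logistic shrugs off collinear duplicate columns", {
  ds <- separable_dataset(80, width = 5)
  ds$x <- cbind(ds$x, ds$x)   # exact collinearity
  colnames(ds$x) <- paste0("f", 1:10)
  clf <- train_classifier(ds, "ridge_logistic", seed = 6)
  expect_true(all(is.finite(clf$cv$auc_roc)))
  expect_gt(mean(clf$cv$auc_roc), 0.8)
})

test_that("all four learner kinds train and separate an easy toy", {
  ds <- separable_dataset(150)
  for (kind in c("dnn", "random_forest", "naive_bayes", "ridge_logistic")) {
    # minibatches sized to give the optimizer enough updates on a 100-row fold
    cfg <- if (kind == "dnn") {
      dnn_config(batch_size = 16, max_epochs = 60, patience = 15, seed = 7)
    } else {
      NULL
    }
    clf <- train_classifier(ds, kind, seed = 7, config = cfg)
    expect_gt(mean(clf$cv$auc_roc), 0.85)
    expect_equal(nrow(tidy(clf)), 3)
    expect_equal(glance(clf)$kind, kind)
  }
})

test_that("label shuffling destroys the signal (chance-level AUC)", {
  ds <- separable_dataset(600, width = 8, seed = 25)
  ds$y <- withr::with_seed(26, sample(ds$y))
  ds$keys$is_positive <- ds$y == 1
  clf <- train_classifier(ds, "ridge_logistic", seed = 8)
  expect_lt(abs(mean(clf$cv$auc_roc) - 0.5), 0.1)
})

test_that("cross-validation results are reproducible under a fixed seed", {
  ds <- separable_dataset(90)
  a <- train_classifier(ds, "ridge_logistic", seed = 9)
  b <- train_classifier(ds, "ridge_logistic", seed = 9)
  expect_equal(a$cv, b$cv)
})
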