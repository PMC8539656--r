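# Classifier training and prediction ------------------------------------------
#
# One surface over four binary classifiers: the deep neural network of
# R/dnn.R, plus three standard benchmarks -- random forest (randomForest),
# Gaussian naive Bayes (e1071, with a small variance floor so constant
# binary columns cannot yield degenerate densities) and ridge-penalized
# logistic regression (glmnet, alpha = 0).

learner_defaults <- function(kind, seed) {
  switch(kind,
    dnn = dnn_config(seed = seed),
    random_forest = list(ntree = 500),
    naive_bayes = list(sd_floor = 1e-3),
    ridge_logistic = list(lambda = 0.01)
  )
}

fit_one <- function(kind, x, y, config, seed, x_val = NULL, y_val = NULL) {
  switch(kind,
    dnn = {
      net <- build_dnn(ncol(x), config)
      fit_dnn(net, x, y, x_val, y_val)
    },
    random_forest = withr::with_seed(seed, {
      randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                 ntree = config$ntree)
    }),
    naive_bayes = {
      fit <- e1071::naiveBayes(x = as.data.frame(x),
                               y = factor(y, levels = c(0, 1)))
      fit$tables <- lapply(fit$tables, function(tab) {
        tab[, 2] <- pmax(tab[, 2], config$sd_floor)
        tab
      })
      fit
    },
    ridge_logistic = withr::with_seed(seed, {
      glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                     alpha = 0, lambda = config$lambda)
    }),
    abort(sprintf("unknown classifier kind '%s'", kind))
  )
}

predict_one <- function(kind, fit, x) {
  switch(kind,
    dnn = dnn_forward(fit, x)$p[, 2],
    random_forest = unname(predict(fit, x, type = "prob")[, "1"]),
    naive_bayes = unname(predict(fit, as.data.frame(x), type = "raw")[, "1"]),
    ridge_logistic = as.numeric(predict(fit, x, type = "response"))
  )
}

#' Train a classifier with stratified cross-validation
#'
#' Runs k-fold cross-validation (each fold's held-out part is used both for
#' early stopping, where the learner supports it, and for the fold's
#' evaluation report) and then refits on all data for downstream
#' prediction. For the DNN the final refit holds out a random 15% of rows
#' for early stopping.
#'
#' @param dataset A `gero_dataset` from [assemble()] (optionally
#'   [balance()]d). Both classes must be present.
#' @param kind `"dnn"`, `"random_forest"`, `"naive_bayes"` or
#'   `"ridge_logistic"`.
#' @param k Number of CV folds (default 3).
#' @param seed Integer seed controlling folds, initialization and sampling.
#' @param config Learner configuration; defaults to [dnn_config()] for the
#'   DNN, `list(ntree = 500)`, `list(sd_floor = 1e-3)` or
#'   `list(lambda = 0.01)` for the benchmarks.
#' @param threshold Score threshold for fold confusion counts (default 0.5).
#' @return A `gero_classifier`: the refit model plus `cv` (per-fold metric
#'   tibble), `cv_reports` (list of [evaluate()] reports), the model layout
#'   `spec`, `input_width`, `kind`, `seed`.
#' @export
train_classifier <- function(dataset, kind = c("dnn", "random_forest",
                                               "naive_bayes", "ridge_logistic"),
                             k = 3, seed = 1L, config = NULL,
                             threshold = 0.5) {
  kind <- match.arg(kind)
  stopifnot(inherits(dataset, "gero_dataset"))
  classes <- unique(dataset$y)
  if (length(classes) < 2) {
    abort(sprintf("dataset lacks %s samples; both classes are required",
                  if (1 %in% classes) "negative" else "positive"))
  }
  config <- config %||% learner_defaults(kind, seed)
  if (kind == "dnn" && !inherits(config, "dnn_config")) {
    abort("`config` for the DNN must come from dnn_config()")
  }

  folds <- kfold(dataset, k = k, seed = seed)
  cv_reports <- purrr::imap(folds, function(f, i) {
    cfg <- if (kind == "dnn") {
      dnn_config(dropout_rate = config$dropout_rate,
                 activations = config$activations,
                 learning_rate = config$learning_rate,
                 batch_size = config$batch_size,
                 max_epochs = config$max_epochs, patience = config$patience,
                 seed = config$seed + i)
    } else {
      config
    }
    fit <- fit_one(kind, dataset$x[f$train, , drop = FALSE], dataset$y[f$train],
                   cfg, seed + i,
                   dataset$x[f$val, , drop = FALSE], dataset$y[f$val])
    scores <- predict_one(kind, fit, dataset$x[f$val, , drop = FALSE])
    evaluate(dataset$y[f$val], scores, threshold = threshold)
  })
  cv <- purrr::imap(cv_reports, function(r, i) {
    tidy(r) |> mutate(fold = i, .before = 1)
  }) |> bind_rows()

  final <- if (kind == "dnn") {
    n <- nrow(dataset$x)
    hold <- withr::with_seed(seed, sample(n, max(2, round(0.15 * n))))
    fit_one(kind, dataset$x[-hold, , drop = FALSE], dataset$y[-hold], config,
            seed, dataset$x[hold, , drop = FALSE], dataset$y[hold])
  } else {
    fit_one(kind, dataset$x, dataset$y, config, seed)
  }

  structure(
    list(kind = kind, model = final, cv = cv, cv_reports = cv_reports,
         spec = dataset$spec, input_width = ncol(dataset$x),
         feature_names = colnames(dataset$x),
         seed = as.integer(seed), config = config, threshold = threshold),
    class = "gero_classifier"
  )
}

#' Positive-class probabilities from a trained classifier
#'
#' @param object A `gero_classifier`.
#' @param x Feature matrix whose width matches the training data.
#' @return Numeric vector of positive-class probabilities in `[0, 1]`.
#' @export
predict_proba <- function(object, x) {
  stopifnot(inherits(object, "gero_classifier"))
  if (!is.matrix(x)) x <- as.matrix(x)
  if (ncol(x) != object$input_width) {
    abort(sprintf("feature width mismatch: model expects %d, got %d",
                  object$input_width, ncol(x)))
  }
  if (!is.null(object$feature_names)) colnames(x) <- object$feature_names
  predict_one(object$kind, object$model, x)
}

#' @export
print.gero_classifier <- function(x, ...) {
  cat("<gero_classifier> ", x$kind, ", input width ", x$input_width,
      "; mean CV: APR=", sprintf("%.3f", mean(x$cv$apr)),
      " AUC=", sprintf("%.3f", mean(x$cv$auc_roc)),
      " accuracy=", sprintf("%.3f", mean(x$cv$accuracy)), "\n", sep = "")
  invisible(x)
}

#' Tidy and glance methods for fitted objects
#'
#' `tidy()` on a `gero_classifier` returns the per-fold cross-validation
#' metrics; `glance()` returns a one-row summary with fold-averaged
#' metrics. `tidy()` on an `eval_report` returns its metrics as one row.
#'
#' @param x A `gero_classifier` or `eval_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gero_classifier
#' @export
tidy.gero_classifier <- function(x, ...) {
  x$cv
}

#' @rdname tidy.gero_classifier
#' @method glance gero_classifier
#' @export
glance.gero_classifier <- function(x, ...) {
  tibble(
    kind = x$kind, input_width = x$input_width, folds = nrow(x$cv),
    accuracy = mean(x$cv$accuracy), auc_roc = mean(x$cv$auc_roc),
    precision = mean(x$cv$precision), recall = mean(x$cv$recall),
    apr = mean(x$cv$apr)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
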