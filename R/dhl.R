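# DHL head: deep features -> MinMax -> PCA(0.99) -> RBF-SVM, fit strictly on
# the training partition, evaluated on the held-out test partition.

#' Fit the MinMax -> PCA -> SVM head on training features
#'
#' @param features numeric matrix of training deep features (rows = samples).
#' @param labels integer class labels in `0..k-1`.
#' @param variance_target PCA explained-variance target, default 0.99.
#' @param C,gamma RBF-SVM hyperparameters (defaults 1000 and 0.001).
#' @return a `dhl_head` bundling scaler, PCA model and SVM.
#' @export
fit_dhl_head <- function(features, labels, variance_target = 0.99,
                         C = 1000, gamma = 0.001) {
  scaler <- fit_minmax(features)
  scaled <- minmax_transform(features, scaler)
  pca <- fit_pca(scaled, variance_target)
  reduced <- pca_reduce(scaled, pca)
  svm <- fit_svm(reduced, labels, C = C, gamma = gamma)
  structure(list(scaler = scaler, pca = pca, svm = svm,
                 dims = c(features = ncol(features), reduced = pca$n_components)),
            class = "dhl_head")
}

#' @rdname fit_dhl_head
#' @param head a fitted `dhl_head`.
#' @param type "class" or "score" (passed to the SVM).
#' @export
predict_dhl_head <- function(head, features, type = c("class", "score")) {
  type <- match.arg(type)
  reduced <- pca_reduce(minmax_transform(features, head$scaler), head$pca)
  predict(head$svm, reduced, type = type)
}

# images+labels for one split of a dataset, preprocessed to network input
split_inputs <- function(dataset, split, config = preproc_config()) {
  raw <- load_images(dataset, split = split)
  list(images = lapply(raw$images, preprocess_image, config = config),
       grades = raw$grades)
}

#' Run the DHL-I pipeline: extract, scale, reduce, classify, evaluate
#'
#' Extracts penultimate-layer deep features from the trained CNN for the
#' train and test partitions, fits the MinMax -> PCA -> RBF-SVM head on the
#' training features only, and evaluates on the test partition.
#'
#' @param model a trained `kneedhl_model`.
#' @param train,test lists with `images` (preprocessed matrices) and `labels`
#'   (integer classes).
#' @param variance_target,C,gamma head hyperparameters.
#' @param verbose log each stage's dimensions.
#' @return a `dhl_result`: `metrics` ([metrics_report()]), `head`,
#'   `accuracy`, predictions and scores.
#' @export
run_dhl <- function(model, train, test, variance_target = 0.99,
                    C = 1000, gamma = 0.001, verbose = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_kneedhl(sprintf("DHL stage '%s' failed: %s", name, conditionMessage(e)),
                   "kneedhl_stage_error")
    })
  }
  ftr <- stage("extract-train", extract_features(model, train$images))
  fte <- stage("extract-test", extract_features(model, test$images))
  if (verbose) {
    message(sprintf("features: train %dx%d, test %dx%d",
                    nrow(ftr), ncol(ftr), nrow(fte), ncol(fte)))
  }
  head <- stage("fit-head", fit_dhl_head(ftr, train$labels, variance_target, C, gamma))
  if (verbose) message(sprintf("PCA kept %d components", head$pca$n_components))
  pred <- stage("predict", predict_dhl_head(head, fte))
  scores <- stage("score", predict_dhl_head(head, fte, type = "score"))
  k <- length(head$svm$classes)
  metrics <- metrics_report(test$labels, pred, k, scores = scores)
  structure(list(metrics = metrics, head = head, accuracy = metrics$accuracy,
                 predictions = pred, scores = scores),
            class = "dhl_result")
}

#' @export
print.dhl_result <- function(x, ...) {
  cat("DHL result\n")
  print(x$metrics)
  invisible(x)
}
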