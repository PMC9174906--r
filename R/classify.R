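# Supervised classifiers over window feature matrices. Four algorithms are
# supported; XGB carries the fixed global hyperparameter set used throughout
# the comparison (100 trees, depth 6, learning rate 0.4, gamma 0.1,
# subsample 0.8, min_child_weight 1). KNN and SVM operate on standardized
# features (distance- and kernel-based methods need comparable scales);
# scaling is fit on the training data only. Tree methods are left unscaled.

xgb_default_params <- function() {
  list(n_estimators = 100, max_depth = 6, learning_rate = 0.4,
       gamma = 0.1, subsample = 0.8, min_child_weight = 1)
}

#' Classifier configuration
#'
#' Algorithm choice plus hyperparameters. XGB defaults are the fixed global
#' setting used for all pipeline comparisons; KNN uses k = 5 neighbors, SVM
#' an RBF kernel on standardized features, DT an unpruned CART tree.
#'
#' @param algorithm one of \code{"xgb"}, \code{"knn"}, \code{"svm"},
#'   \code{"dt"}.
#' @param ... named hyperparameter overrides (e.g. \code{k}, \code{cost},
#'   \code{max_depth}).
#' @return A list of class \code{classifier_config}.
#' @export
classifier_config <- function(algorithm = c("xgb", "knn", "svm", "dt"), ...) {
  algorithm <- match.arg(tolower(algorithm), c("xgb", "knn", "svm", "dt"))
  defaults <- switch(algorithm,
    xgb = xgb_default_params(),
    knn = list(k = 5),
    svm = list(cost = 1, kernel = "radial"),
    dt = list())
  override <- list(...)
  defaults[names(override)] <- override
  structure(list(algorithm = algorithm, hyperparameters = defaults),
            class = "classifier_config")
}

#' Fit a behavior classifier
#'
#' Trains one of the four supported algorithms on a window feature matrix.
#' The returned object predicts hard labels and per-class probabilities
#' (rows summing to 1) via \code{\link{predict.behavior_classifier}}. A
#' fixed seed makes training reproducible.
#'
#' @param x numeric feature matrix (rows = windows).
#' @param labels factor (or coercible) of behavior labels, one per row;
#'   at least two classes must be present.
#' @param config a \code{\link{classifier_config}} (or an algorithm name).
#' @param seed integer seed for the stochastic learners.
#' @return Object of class \code{behavior_classifier}.
#' @export
behavior_classifier <- function(x, labels, config = classifier_config("xgb"),
                                seed = 1L) {
  if (is.character(config)) config <- classifier_config(config)
  stopifnot(inherits(config, "classifier_config"))
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop("feature matrix contains missing or non-finite values", call. = FALSE)
  # syntactic internal names keep formula-based backends happy
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- droplevels(as.factor(labels))
  if (length(labels) != nrow(x))
    stop("labels must match feature matrix rows", call. = FALSE)
  if (nlevels(labels) < 2L)
    stop("training data must contain at least 2 classes", call. = FALSE)
  alg <- config$algorithm
  hp <- config$hyperparameters

  center <- scale_sd <- NULL
  if (alg %in% c("knn", "svm")) {
    center <- colMeans(x)
    scale_sd <- apply(x, 2, stats::sd)
    scale_sd[scale_sd == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale_sd, "/")
  }

  fit <- with_seed(seed, switch(alg,
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(labels) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = nlevels(labels),
                      max_depth = hp$max_depth, eta = hp$learning_rate,
                      gamma = hp$gamma, subsample = hp$subsample,
                      min_child_weight = hp$min_child_weight,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = hp$n_estimators, verbose = 0)
    },
    knn = caret::knn3(x, labels, k = hp$k),
    svm = e1071::svm(x, labels, kernel = hp$kernel, cost = hp$cost,
                     probability = TRUE, scale = FALSE),
    dt = {
      df <- data.frame(.label = labels, x, check.names = FALSE)
      rpart::rpart(.label ~ ., data = df, method = "class")
    }))

  structure(list(algorithm = alg, config = config, fit = fit,
                 levels = levels(labels), center = center,
                 scale_sd = scale_sd, seed = seed,
                 n_features = ncol(x)),
            class = "behavior_classifier")
}

#' Predict behaviors from a fitted classifier
#'
#' @param object a \code{\link{behavior_classifier}}.
#' @param newdata numeric feature matrix with the training feature count.
#' @param type \code{"class"} for hard labels, \code{"prob"} for a per-class
#'   probability matrix (rows sum to 1).
#' @param ... unused.
#' @return Factor of labels, or a numeric probability matrix with one column
#'   per class.
#' @export
predict.behavior_classifier <- function(object, newdata,
                                        type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != object$n_features)
    stop(sprintf("expected %d features, got %d", object$n_features, ncol(x)),
         call. = FALSE)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!is.null(object$center))
    x <- sweep(sweep(x, 2, object$center), 2, object$scale_sd, "/")

  prob <- switch(object$algorithm,
    xgb = {
      p <- predict(object$fit, xgboost::xgb.DMatrix(x))
      if (!is.matrix(p))
        p <- matrix(p, nrow = nrow(x), byrow = TRUE)
      colnames(p) <- object$levels
      p
    },
    knn = unclass(predict(object$fit, x, type = "prob")),
    svm = attr(predict(object$fit, x, probability = TRUE), "probabilities"),
    dt = {
      df <- as.data.frame(x)
      colnames(df) <- colnames(x)
      predict(object$fit, df, type = "prob")
    })
  prob <- as.matrix(prob)
  # column order follows the training levels regardless of backend; rows are
  # renormalized (Platt-scaled SVM probabilities sum to 1 only approximately)
  prob <- prob[, object$levels, drop = FALSE]
  prob <- prob / rowSums(prob)
  if (type == "prob") return(prob)
  factor(object$levels[max.col(prob, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.behavior_classifier <- function(x, ...) {
  hp <- x$config$hyperparameters
  cat(sprintf("<behavior_classifier> %s on %d features, classes: %s\n",
              toupper(x$algorithm), x$n_features,
              paste(x$levels, collapse = ", ")))
  if (length(hp))
    cat("  hyperparameters:",
        paste(sprintf("%s=%s", names(hp), unlist(hp)), collapse = ", "), "\n")
  invisible(x)
}
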