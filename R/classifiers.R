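#' Classifier specification
#'
#' Names one of the nine supported model families and its hyperparameters.
#' [default_classifier_specs()] returns all nine with the shipped defaults
#' (grid-search-selected values frozen into the package): AdaBoost
#' `n_estimators = 50, learning_rate = 0.01`; DT gini/best split; ETC and RF
#' `n_estimators = 100`; KNN `n_neighbours = 5`; LR L2, `C = 1`; MLP one
#' hidden layer of 100 units, `alpha = 1e-4`; SVM RBF, `C = 1`; XGB
#' `learning_rate = 0.1, n_estimators = 100`. Every stochastic model uses
#' `random_state = 42` unless reseeded by the experiment runner.
#'
#' @param name One of `"AdaBoost"`, `"DT"`, `"ETC"`, `"KNN"`, `"LR"`,
#'   `"MLP"`, `"RF"`, `"SVM"`, `"XGB"`.
#' @param params Named list of hyperparameter overrides.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, params = list()) {
  name <- match.arg(name, c("AdaBoost", "DT", "ETC", "KNN", "LR", "MLP",
                            "RF", "SVM", "XGB"))
  defaults <- switch(name,
    AdaBoost = list(n_estimators = 50L, learning_rate = 0.01,
                    random_state = 42L),
    DT = list(criterion = "gini", splitter = "best", random_state = 42L),
    ETC = list(n_estimators = 100L, random_state = 42L),
    KNN = list(n_neighbours = 5L, leaf_size = 30L, p = 2, metric = "minkowski"),
    LR = list(penalty = "l2", C = 1.0, max_iter = 100L, random_state = 42L),
    MLP = list(hidden_layer_sizes = 100L, activation = "relu",
               alpha = 1e-4, random_state = 42L),
    RF = list(n_estimators = 100L, random_state = 42L),
    SVM = list(C = 1.0, gamma = "scale", kernel = "rbf", probability = TRUE,
               random_state = 42L),
    XGB = list(eval_metric = "logloss", learning_rate = 0.1,
               n_estimators = 100L, random_state = 42L)
  )
  defaults[names(params)] <- params
  structure(list(name = name, params = defaults), class = "classifier_spec")
}

#' @rdname classifier_spec
#' @export
default_classifier_specs <- function() {
  nms <- c("AdaBoost", "DT", "ETC", "KNN", "LR", "MLP", "RF", "SVM", "XGB")
  stats::setNames(lapply(nms, classifier_spec), nms)
}

#' Fit a classifier adapter
#'
#' Binds a [classifier_spec()] to the corresponding implementation from the
#' standard R modelling stack (rpart, randomForest, ranger with the
#' extra-trees split rule, class::knn, glm, nnet, e1071::svm, xgboost).
#' AdaBoost is provided natively as SAMME over depth-1 rpart stumps. Every
#' fitted adapter answers [predict()] (hard 0/1 labels) and
#' [classifier_score()] (class-1 probability or margin-derived score).
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric feature matrix.
#' @param y 0/1 labels.
#' @param seed Integer seed overriding the spec's `random_state`.
#' @return An object of class `fitted_classifier`.
#' @export
fit_classifier <- function(spec, X, y, seed = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop_kmsmote("training labels contain a single class")
  }
  seed <- seed %||% spec$params$random_state %||% 42L
  p <- spec$params
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X), unique = TRUE)
  model <- with_seed(seed, switch(spec$name,
    DT = rpart::rpart(y ~ ., data = cbind(df, y = factor(y, c(0, 1))),
                      method = "class",
                      parms = list(split = p$criterion %||% "gini")),
    RF = randomForest::randomForest(x = df, y = factor(y, c(0, 1)),
                                    ntree = p$n_estimators),
    ETC = ranger::ranger(x = df, y = factor(y, c(0, 1)),
                         num.trees = p$n_estimators,
                         splitrule = "extratrees", probability = TRUE,
                         seed = seed, num.threads = 1L),
    KNN = list(X = X, y = y, k = p$n_neighbours),
    LR = suppressWarnings(
      stats::glm(y ~ ., data = cbind(df, y = y), family = stats::binomial())),
    MLP = nnet::nnet(x = X, y = y, size = p$hidden_layer_sizes,
                     decay = p$alpha, maxit = 200L, MaxNWts = 100000L,
                     trace = FALSE, entropy = TRUE),
    SVM = e1071::svm(x = X, y = factor(y, c(0, 1)), kernel = "radial",
                     cost = p$C, probability = TRUE),
    XGB = xgboost::xgboost(data = X, label = y, nrounds = p$n_estimators,
                           params = list(eta = p$learning_rate,
                                         objective = "binary:logistic",
                                         nthread = 1L, seed = seed),
                           verbose = 0),
    AdaBoost = fit_adaboost(df, y, p$n_estimators, p$learning_rate)
  ))
  structure(list(spec = spec, model = model, feature_names = names(df),
                 raw_names = colnames(X)),
            class = "fitted_classifier")
}

# SAMME AdaBoost over depth-1 rpart stumps with learning-rate shrinkage.
fit_adaboost <- function(df, y, n_estimators, learning_rate) {
  n <- length(y)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  dat <- cbind(df, y = factor(y, c(0, 1)))
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = 0, minsplit = 2, xval = 0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(y ~ ., data = dat, weights = w, method = "class",
                        control = ctrl)
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w[pred != y])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- learning_rate * log((1 - err) / err)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}

score_adaboost <- function(model, df) {
  if (length(model$stumps) == 0L) return(rep(0.5, nrow(df)))
  votes <- vapply(model$stumps, function(fit) {
    as.numeric(as.character(predict(fit, df, type = "class")))
  }, numeric(nrow(df)))
  votes <- matrix(votes, nrow = nrow(df))
  as.numeric(votes %*% model$alphas) / sum(model$alphas)
}

#' Class-1 score of a fitted classifier
#'
#' @param object A `fitted_classifier`.
#' @param X Feature matrix to score.
#' @return Numeric vector of class-1 scores in `[0, 1]`.
#' @export
classifier_score <- function(object, X) {
  X <- as.matrix(X)
  df <- as.data.frame(X)
  names(df) <- object$feature_names
  p <- object$spec$params
  switch(object$spec$name,
    DT = unname(predict(object$model, df, type = "prob")[, "1"]),
    RF = unname(predict(object$model, df, type = "prob")[, "1"]),
    ETC = unname(predict(object$model, data = df)$predictions[, "1"]),
    KNN = {
      k <- min(p$n_neighbours, nrow(object$model$X))
      nn <- knn_query(object$model$X, X, k = k)
      rowMeans(matrix(object$model$y[nn$idx], nrow(X), k))
    },
    LR = unname(predict(object$model, df, type = "response")),
    MLP = as.numeric(predict(object$model, X)),
    SVM = {
      pr <- predict(object$model, X, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    },
    XGB = as.numeric(predict(object$model, X)),
    AdaBoost = score_adaboost(object$model, df)
  )
}

#' @export
predict.fitted_classifier <- function(object, newdata, ...) {
  as.integer(classifier_score(object, newdata) >= 0.5)
}

#' @export
print.fitted_classifier <- function(x, ...) {
  cat("<fitted_classifier> ", x$spec$name, "\n", sep = "")
  invisible(x)
}
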