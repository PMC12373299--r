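# Adapters around the four classifier families. Each returns a fitted
# object wrapped with its family tag; prediction always yields a
# probability of the positive class.

slecast_families <- function() {
  c("logistic_regression", "decision_tree", "random_forest",
    "gradient_boosted_trees")
}

#' Default hyperparameter grids for the four model families
#'
#' Small, documented defaults: ridge penalty for logistic regression, tree
#' depth for the decision tree, forest size / leaf size for the random
#' forest, and depth x learning rate for the gradient-boosted trees. Each
#' entry is a data frame whose rows are hyperparameter combinations.
#'
#' @return Named list of data frames.
#' @export
default_grids <- function() {
  list(
    logistic_regression = data.frame(lambda = c(0.001, 0.01, 0.1)),
    decision_tree = data.frame(maxdepth = c(3, 5, 10), cp = 0.001),
    random_forest = expand.grid(num_trees = 200, min_node_size = c(10, 25)),
    gradient_boosted_trees = expand.grid(max_depth = c(3, 5), eta = 0.1,
                                         nrounds = 150)
  )
}

fit_family <- function(family, params, x, y, seed = 1) {
  feature_names <- colnames(x)
  x <- as.data.frame(x)
  fit <- switch(
    family,
    logistic_regression = {
      xm <- as.matrix(x)
      list(model = glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                                  lambda = params$lambda),
           lambda = params$lambda,
           feature_means = colMeans(xm))
    },
    decision_tree = {
      d <- cbind(data.frame(.outcome = factor(y, levels = c(0, 1))), x)
      rpart::rpart(.outcome ~ ., data = d, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = params$maxdepth, cp = params$cp,
                     xval = 0, maxcompete = 0, maxsurrogate = 0))
    },
    random_forest = ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = params$num_trees, min.node.size = params$min_node_size,
      seed = seed, num.threads = 1, respect.unordered.factors = "ignore"),
    gradient_boosted_trees = {
      dm <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1),
        data = dm, nrounds = params$nrounds, verbose = 0)
    },
    stop("unknown model family: ", family, call. = FALSE)
  )
  structure(list(family = family, params = params, fit = fit,
                 feature_names = feature_names),
            class = "slecast_fit")
}

predict_family <- function(object, x) {
  missing_cols <- setdiff(object$feature_names, colnames(x))
  if (length(missing_cols) > 0) {
    stop("prediction rows lack model columns: ",
         paste(head(missing_cols, 5), collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)[, object$feature_names, drop = FALSE]
  pp <- switch(
    object$family,
    logistic_regression = as.numeric(
      predict(object$fit$model, as.matrix(x), type = "response")),
    decision_tree = as.numeric(predict(object$fit, x, type = "prob")[, "1"]),
    random_forest = as.numeric(
      predict(object$fit, data = x, num.threads = 1)$predictions[, "1"]),
    gradient_boosted_trees = as.numeric(
      predict(object$fit, xgboost::xgb.DMatrix(as.matrix(x))))
  )
  pmin(pmax(pp, 0), 1)
}
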