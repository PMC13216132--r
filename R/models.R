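#' Random-forest configuration for cover classification
#'
#' Pins the three ensemble hyperparameters used throughout: 100 trees, a
#' minimum of 10 samples per leaf, and a maximum depth of 10, plus the
#' seed. Remaining engine settings (features per split, bootstrap) follow
#' the engine defaults and are recorded on the fitted model for
#' reproducibility.
#'
#' @param n_trees Number of trees.
#' @param min_samples_leaf Minimum samples per leaf.
#' @param max_depth Maximum tree depth.
#' @param seed Integer seed; a fixed seed gives a reproducible fit.
#' @return Object of class `model_config`.
#' @export
model_config <- function(n_trees = 100L, min_samples_leaf = 10L,
                         max_depth = 10L, seed = 1L) {
  vals <- c(n_trees, min_samples_leaf, max_depth)
  if (any(vals < 1) || any(vals != round(vals)))
    stop("config values must be positive integers", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 max_depth = as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "model_config")
}

sample_feature_cols <- function(samples) {
  setdiff(names(samples), c("label", "tile_id", "row", "col"))
}

#' Fit the binary open/closed cover classifier
#'
#' A probability random forest (impurity importance, single-threaded for
#' determinism) predicting the pixel cover state from the topographic
#' feature columns of a sample set.
#'
#' @param train Sample-set data frame with both classes present.
#' @param config A [model_config()].
#' @return Object of class `cover_model`: the fitted ensemble plus the
#'   feature-name order, class order, config and a training fingerprint.
#' @export
fit_cover_model <- function(train, config = model_config()) {
  if (!inherits(config, "model_config"))
    stop("`config` must be a model_config", call. = FALSE)
  if (!is.factor(train$label))
    stop("`train` must have a factor `label` column", call. = FALSE)
  tab <- table(train$label)
  if (sum(tab > 0) < 2L)
    stop("training data contain a single class; cannot fit", call. = FALSE)
  feats <- sample_feature_cols(train)
  d <- train[, c(feats, "label"), drop = FALSE]
  rf <- ranger::ranger(
    label ~ ., data = d,
    num.trees = config$n_trees,
    min.node.size = config$min_samples_leaf,
    max.depth = config$max_depth,
    probability = TRUE,
    importance = "impurity",
    seed = config$seed,
    num.threads = 1L,
    verbose = FALSE
  )
  structure(list(
    engine = rf,
    features = feats,
    classes = c("open", "closed"),
    config = config,
    fingerprint = list(n = nrow(train), class_counts = as.list(tab),
                       engine_defaults = list(mtry = rf$mtry,
                                              replace = TRUE))
  ), class = "cover_model")
}

#' Predicted probability of closed cover
#'
#' Soft-vote probability of the `closed` class: the fraction of trees
#' voting closed. Generic so that closed-form response functions (plain
#' functions of a data frame) can stand in for a fitted model when
#' validating effect curves.
#'
#' @param model A `cover_model`, or a function `data.frame -> probability
#'   vector`.
#' @param newdata Data frame containing the model's feature columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_closed_prob <- function(model, newdata) {
  UseMethod("predict_closed_prob")
}

#' @export
predict_closed_prob.cover_model <- function(model, newdata) {
  p <- stats::predict(model$engine,
                      data = newdata[, model$features, drop = FALSE],
                      num.threads = 1L, verbose = FALSE)$predictions
  if ("closed" %in% colnames(p)) p[, "closed"] else 1 - p[, "open"]
}

#' @export
predict_closed_prob.function <- function(model, newdata) {
  model(newdata)
}

#' Classification accuracy on a test set
#'
#' Fraction of correct predictions; a pixel is predicted closed when its
#' closed-class probability exceeds 0.5 (exact 0.5 predicts open).
#'
#' @param model A `cover_model`.
#' @param test Non-empty sample-set data frame with a `label` column.
#' @return Fraction in `[0, 1]`.
#' @export
model_accuracy <- function(model, test) {
  if (nrow(test) == 0L) stop("empty test set", call. = FALSE)
  p <- predict_closed_prob(model, test)
  pred <- ifelse(p > 0.5, "closed", "open")
  mean(pred == as.character(test$label))
}

#' Impurity-based feature importance
#'
#' Per-feature nonnegative weights normalized to sum to 1. When the
#' ensemble made no splits (all features constant) every feature is
#' equally uninformative and uniform weights are returned.
#'
#' @param model A fitted `cover_model`.
#' @return Named numeric vector over the model's features, summing to 1.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "cover_model"))
    stop("`model` must be a fitted cover_model", call. = FALSE)
  v <- model$engine$variable.importance[model$features]
  v[is.na(v) | v < 0] <- 0
  if (sum(v) == 0) {
    v <- stats::setNames(rep(1 / length(model$features),
                             length(model$features)), model$features)
  } else {
    v <- v / sum(v)
  }
  v
}

#' Most important feature of a fitted model
#'
#' Argmax of [feature_importance()]; ties are broken lexicographically by
#' feature name.
#'
#' @param model A fitted `cover_model`.
#' @return Feature name (character scalar).
#' @export
top_feature <- function(model) {
  v <- feature_importance(model)
  nm <- sort(names(v)[v == max(v)])
  nm[1]
}
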