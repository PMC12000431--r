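#' Fit a boosted regression tree (BRT) transfer function
#'
#' A stochastic gradient-boosted ensemble of shallow regression trees mapping
#' taxon proportions to a climate target. Defaults follow the standard
#' pollen-calibration settings: at most 3000 trees, learning rate 0.025,
#' tree complexity (interaction depth) 4, bagging fraction 0.5. The tree
#' count actually used is selected by internal cross-validated squared-error
#' deviance with early stopping, capped at `max_trees`.
#'
#' @inheritParams mat_fit
#' @param max_trees Maximum ensemble size.
#' @param learning_rate Shrinkage applied to each tree.
#' @param tree_complexity Maximum tree depth (interaction order).
#' @param bag_fraction Row subsample fraction per tree.
#' @param cv_folds Folds for internal tree-count selection.
#' @param n_trees Optional fixed ensemble size, skipping the internal
#'   cross-validation (used e.g. inside [hblock_crossvalidate()]).
#' @param seed Integer seed; fixing it makes the fit bit-reproducible.
#' @return A `brt_model` object.
#' @export
brt_fit <- function(train, target,
                    max_trees = 3000, learning_rate = 0.025,
                    tree_complexity = 4, bag_fraction = 0.5,
                    cv_folds = 5, n_trees = NULL, seed = NULL) {
  train <- as_calibration(train, attr(train, "taxa"))
  if (!target %in% names(train)) abort(sprintf("Target column `%s` missing from training data.", target))
  if (nrow(train) < 2) abort("`train` must contain at least 2 sites.")
  taxa <- calibration_taxa(train)
  y <- train[[target]]
  if (any(!is.finite(y))) abort("Target column contains non-finite values.")
  if (sd(y) == 0) abort(sprintf("Target `%s` is constant; nothing to calibrate.", target))
  X <- composition_matrix(train, taxa)
  colnames(X) <- taxa
  params <- list(
    objective = "reg:squarederror",
    learning_rate = learning_rate,
    max_depth = as.integer(tree_complexity),
    subsample = bag_fraction,
    nthread = 1L,
    seed = if (is.null(seed)) 0L else as.integer(seed)
  )
  fit <- with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
    best <- n_trees
    if (is.null(best)) {
      cv <- xgboost::xgb.cv(
        params = params, data = dtrain, nrounds = max_trees,
        nfold = cv_folds, early_stopping_rounds = 50, verbose = 0
      )
      best <- cv$early_stop$best_iteration
    }
    booster <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = best, verbose = 0)
    list(booster = booster, n_trees = best)
  })
  structure(
    list(
      method = "BRT",
      target = target,
      taxa = taxa,
      booster = fit$booster,
      n_trees = fit$n_trees,
      hyperparameters = list(
        max_trees = max_trees, learning_rate = learning_rate,
        tree_complexity = tree_complexity, bag_fraction = bag_fraction
      ),
      training_range = range(y),
      seed = seed
    ),
    class = c("brt_model", "transfer_model")
  )
}

#' Predict climate from assemblages with a fitted BRT model
#'
#' @param model A `brt_model` from [brt_fit()].
#' @param assemblages Tibble or matrix of compositions over the model taxonomy.
#' @return Numeric vector, one prediction per assemblage.
#' @export
brt_predict <- function(model, assemblages) {
  stopifnot(inherits(model, "brt_model"))
  if (is.null(model$booster)) abort("Model is not fitted.")
  comp <- align_assemblages(assemblages, model$taxa)
  colnames(comp) <- model$taxa
  as.numeric(predict(model$booster, comp))
}

#' @export
predict.brt_model <- function(object, newdata, ...) brt_predict(object, newdata)

#' @export
print.brt_model <- function(x, ...) {
  h <- x$hyperparameters
  cat(sprintf(paste0(
    "BRT transfer function for `%s`: %d trees (cap %d), ",
    "learning rate %.3f, complexity %d, bag fraction %.2f\n"),
    x$target, x$n_trees, h$max_trees, h$learning_rate,
    h$tree_complexity, h$bag_fraction))
  invisible(x)
}

#' @export
glance.brt_model <- function(x, ...) {
  h <- x$hyperparameters
  tibble(method = "BRT", target = x$target, n_trees = x$n_trees,
         max_trees = h$max_trees, learning_rate = h$learning_rate,
         tree_complexity = h$tree_complexity, bag_fraction = h$bag_fraction)
}

#' Relative predictor importance of a BRT transfer function
#'
#' Relative contributions (%) of each taxon to the fitted ensemble, from the
#' per-split gain totals; contributions sum to 100.
#'
#' @param model A fitted `brt_model`.
#' @return Tibble `(taxon, contribution)` in descending order of contribution.
#' @export
predictor_importance <- function(model) {
  if (!inherits(model, "brt_model")) {
    abort("Predictor importance is only defined for BRT models.")
  }
  imp <- xgboost::xgb.importance(model = model$booster)
  out <- tibble(taxon = imp$Feature, contribution = 100 * imp$Gain)
  # taxa never used by any split contribute exactly zero
  unused <- setdiff(model$taxa, out$taxon)
  if (length(unused)) {
    out <- bind_rows(out, tibble(taxon = unused, contribution = 0))
  }
  arrange(out, dplyr::desc(.data$contribution))
}

#' @export
tidy.brt_model <- function(x, ...) predictor_importance(x)
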