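MODEL_FAMILIES <- c("linear", "random_forest", "gradient_boosting",
                    "extreme_gradient_boosting", "stacked_ensemble",
                    "neural_network")

#' Specify a regression model family
#'
#' @param family one of \code{"linear"}, \code{"random_forest"},
#'   \code{"gradient_boosting"}, \code{"extreme_gradient_boosting"},
#'   \code{"stacked_ensemble"}, \code{"neural_network"}.
#' @param grid named list of hyperparameter value vectors to grid-search
#'   over; \code{NULL} uses [default_grid()] for the family.
#' @param seed integer seed, fixed and recorded with the fit.
#' @export
model_spec <- function(family, grid = NULL, seed = 1L) {
  family <- match.arg(family, MODEL_FAMILIES)
  structure(list(family = family, grid = grid %||% default_grid(family),
                 seed = as.integer(seed)),
            class = "panther_model_spec")
}

#' Default hyperparameter grids
#'
#' Small, documented grids per family, overridable through [model_spec()].
#' Kept deliberately compact so a cross-validated grid search stays cheap
#' and reproducible on a single CPU.
#'
#' @param family model family name.
#' @export
default_grid <- function(family) {
  switch(family,
    linear = list(),
    random_forest = list(ntree = 200L, mtry = c(5L, 10L)),
    gradient_boosting = list(nrounds = 200L, max_depth = 3L, eta = 0.1),
    extreme_gradient_boosting = list(nrounds = 200L, max_depth = 6L,
                                     eta = 0.3),
    neural_network = list(size = 16L, decay = 1e-3, maxit = 300L),
    stacked_ensemble = list(),
    stop_domain("unknown model family '%s'; valid: %s", family,
                paste(MODEL_FAMILIES, collapse = ", "))
  )
}

#' Split records into training and validation subsets
#'
#' Disjoint, exhaustive and reproducible for a given seed.
#'
#' @param records records data.frame.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{validation}.
#' @export
split_train_validation <- function(records, fraction = 0.8, seed = 1L) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2) stop_domain("need at least 2 records to split")
  if (!(fraction > 0 && fraction < 1))
    stop_domain("fraction must lie strictly between 0 and 1")
  n <- nrow(records)
  set.seed(seed)
  idx <- sample.int(n, size = round(fraction * n))
  list(train = records[sort(idx), , drop = FALSE],
       validation = records[setdiff(seq_len(n), idx), , drop = FALSE])
}

# ---- family back ends -------------------------------------------------------

#' @noRd
fit_one <- function(family, X, y, hp, seed) {
  set.seed(seed)
  switch(family,
    linear = {
      fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0  # aliased columns (full one-hot blocks are collinear)
      list(kind = "linear", coef = cf)
    },
    random_forest = {
      mtry <- hp$mtry %||% max(floor(ncol(X) / 3), 1L)
      mtry <- min(mtry, ncol(X))
      list(kind = "random_forest",
           fit = randomForest::randomForest(x = X, y = y,
                                            ntree = hp$ntree %||% 200L,
                                            mtry = mtry))
    },
    gradient_boosting = ,
    extreme_gradient_boosting = {
      d <- xgboost::xgb.DMatrix(data = X, label = y)
      params <- list(objective = "reg:squarederror",
                     max_depth = hp$max_depth %||% 3L,
                     eta = hp$eta %||% 0.1,
                     subsample = hp$subsample %||% 1,
                     colsample_bytree = hp$colsample_bytree %||% 1,
                     nthread = 1L, seed = seed)
      list(kind = "xgb",
           fit = xgboost::xgb.train(params = params, data = d,
                                    nrounds = hp$nrounds %||% 200L,
                                    verbose = 0))
    },
    neural_network = {
      list(kind = "nnet",
           fit = nnet::nnet(x = X, y = y, size = hp$size %||% 16L,
                            decay = hp$decay %||% 1e-3,
                            maxit = hp$maxit %||% 300L,
                            linout = TRUE, trace = FALSE,
                            MaxNWts = 10000L))
    },
    stop_domain("unknown model family '%s'", family)
  )
}

#' @noRd
predict_one <- function(fit, X) {
  switch(fit$kind,
    linear = as.numeric(cbind(1, X) %*% fit$coef),
    random_forest = as.numeric(stats::predict(fit$fit, X)),
    xgb = as.numeric(stats::predict(fit$fit, xgboost::xgb.DMatrix(X))),
    nnet = as.numeric(stats::predict(fit$fit, X)),
    stop_domain("unknown fitted-model kind '%s'", fit$kind)
  )
}

#' @noRd
expand_grid_list <- function(grid) {
  if (!length(grid)) return(list(list()))
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Train a model with cross-validated grid search
#'
#' The hyperparameter grid is scored by k-fold cross-validated mean absolute
#' error on the training records (fold assignment fixed by the spec's seed);
#' the configuration with the smallest CV MAE (first on ties, in grid order)
#' is refit on the full training split. The stacked ensemble trains its
#' three tree-based base models (random forest and the two boosting
#' configurations) and averages their predictions.
#'
#' @param records training records carrying \code{local_energy} targets.
#' @param spec a [model_spec()].
#' @param encoding a fitted [fit_encoding()]; \code{NULL} fits one on
#'   \code{records}.
#' @param cv_folds folds for cross-validation, default 10.
#' @param validation optional held-out records; when supplied the report
#'   includes validation metrics.
#' @param numeric numeric feature columns when \code{encoding} is fitted
#'   here.
#' @return a \code{panther_model}: family, fitted state, encoding, chosen
#'   hyperparameters, seed, and a \code{report} with cv_scores (per-fold MAE
#'   of the chosen configuration), training metrics, and validation metrics
#'   if requested. A constant (zero-variance) target is flagged via
#'   \code{report$degenerate_target} with undefined correlations.
#' @export
train_model <- function(records, spec, encoding = NULL, cv_folds = 10,
                        validation = NULL,
                        numeric = c("com_distance", "hbonds")) {
  stopifnot(inherits(spec, "panther_model_spec"))
  y <- records$local_energy
  if (is.null(y) || anyNA(y))
    stop_domain("training records must carry local_energy targets")
  n <- nrow(records)
  if (cv_folds > n) stop_domain("cv_folds (%d) exceeds record count (%d)",
                                cv_folds, n)
  if (cv_folds < 2) stop_domain("cv_folds must be >= 2")
  encoding <- encoding %||% fit_encoding(records, numeric = numeric)
  X <- encode_records(records, encoding)
  degenerate <- stats::sd(y) == 0

  families <- if (spec$family == "stacked_ensemble")
    c("random_forest", "gradient_boosting", "extreme_gradient_boosting")
  else spec$family

  set.seed(spec$seed)
  fold <- sample(rep_len(seq_len(cv_folds), n))

  pick <- list(); cv_best <- NULL
  for (fam in families) {
    grid <- if (spec$family == "stacked_ensemble") default_grid(fam)
            else spec$grid
    configs <- expand_grid_list(grid)
    cv_mae <- matrix(NA_real_, length(configs), cv_folds)
    for (ci in seq_along(configs)) {
      for (k in seq_len(cv_folds)) {
        tr <- fold != k
        fit <- fit_one(fam, X[tr, , drop = FALSE], y[tr], configs[[ci]],
                       spec$seed + k)
        pred <- predict_one(fit, X[!tr, , drop = FALSE])
        cv_mae[ci, k] <- mean(abs(pred - y[!tr]))
      }
    }
    mean_mae <- rowMeans(cv_mae)
    best <- which.min(mean_mae)
    pick[[fam]] <- list(hp = configs[[best]],
                        cv_mae = cv_mae[best, ],
                        grid_cv_mae = mean_mae,
                        configs = configs)
    if (fam == families[1]) cv_best <- cv_mae[best, ]
  }

  fits <- lapply(families, function(fam)
    fit_one(fam, X, y, pick[[fam]]$hp, spec$seed))
  names(fits) <- families

  model <- structure(list(
    family = spec$family,
    fits = fits,
    encoding = encoding,
    hyperparameters = lapply(pick, `[[`, "hp"),
    grid_cv_mae = lapply(pick, `[[`, "grid_cv_mae"),
    grid_configs = lapply(pick, `[[`, "configs"),
    seed = spec$seed,
    format_version = 1L
  ), class = "panther_model")

  train_pred <- predict_local_energies(model, records)
  report <- list(
    family = spec$family,
    cv_scores = if (spec$family == "stacked_ensemble")
      rowMeans(do.call(cbind, lapply(pick, `[[`, "cv_mae"))) else cv_best,
    chosen_hyperparameters = model$hyperparameters,
    degenerate_target = degenerate,
    train = evaluate_predictions(train_pred, y)
  )
  if (!is.null(validation) && nrow(validation)) {
    vp <- predict_local_energies(model, validation)
    report$validation <- evaluate_predictions(vp, validation$local_energy)
  }
  model$report <- report
  model
}

#' @export
print.panther_model <- function(x, ...) {
  cat(sprintf("panther_model [%s], seed %d\n", x$family, x$seed))
  if (!is.null(x$report$validation))
    cat(sprintf("  validation: r = %.3f, MAE = %.3f kcal/mol\n",
                x$report$validation$r, x$report$validation$mae))
  invisible(x)
}

#' Predict local interaction energies for records
#'
#' Encodes the records with the model's frozen encoding and returns one
#' finite energy (kcal/mol) per record; deterministic for a fixed model. For
#' the stacked ensemble this is the unweighted mean of the base-model
#' predictions.
#'
#' @param model a \code{panther_model} (or an oracle model from the fixtures
#'   module).
#' @param records records data.frame; zero rows give a zero-length result.
#' @export
predict_local_energies <- function(model, records) {
  UseMethod("predict_local_energies")
}

#' @export
predict_local_energies.panther_model <- function(model, records) {
  if (!nrow(records)) return(numeric(0))
  X <- encode_records(records, model$encoding)
  preds <- vapply(model$fits, function(f) predict_one(f, X),
                  numeric(nrow(records)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(records))
  rowMeans(preds)
}

#' Aggregate base-model predictions by direct (unweighted) averaging
#'
#' @param base_models list of at least two trained \code{panther_model}s.
#' @param records records data.frame.
#' @export
stacked_predict <- function(base_models, records) {
  stopifnot(length(base_models) >= 2)
  preds <- vapply(base_models, predict_local_energies, records = records,
                  numeric(nrow(records)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(records))
  rowMeans(preds)
}

#' Regression metrics between predicted and observed values
#'
#' Pearson r with its two-sided t-distribution p-value, mean absolute error,
#' and Spearman rank correlation. Zero variance in either vector flags the
#' correlations as undefined (\code{degenerate = TRUE}, NA correlations)
#' rather than returning a number.
#'
#' @param predicted,observed equal-length numeric vectors (length >= 3 for
#'   correlations).
#' @return list with r, mae, r_s, p_value, n, degenerate.
#' @export
evaluate_predictions <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop_domain("predicted and observed lengths differ (%d vs %d)",
                length(predicted), length(observed))
  n <- length(predicted)
  mae <- mean(abs(predicted - observed))
  if (n < 3 || stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    return(list(r = NA_real_, mae = mae, r_s = NA_real_,
                p_value = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- stats::cor.test(predicted, observed, method = "pearson")
  list(r = unname(ct$estimate), mae = mae,
       r_s = stats::cor(predicted, observed, method = "spearman"),
       p_value = ct$p.value, n = n, degenerate = FALSE)
}

#' Permutation feature importance
#'
#' Shuffles one feature column across all records, re-predicts, and measures
#' the degradation in RMSE and Pearson r against the unpermuted baseline,
#' repeated \code{n_perm} times. Deltas are summarized as mean and SD with a
#' one-sided paired t-test (alternative: degradation greater than zero). A
#' zero-variance feature column yields deltas of exactly 0.
#'
#' @param model trained model accepted by [predict_local_energies()].
#' @param records records with \code{local_energy} targets.
#' @param feature feature column name to permute.
#' @param n_perm number of permutations, default 30.
#' @param seed RNG seed.
#' @return object of class \code{panther_permutation_report}: feature,
#'   delta_rmse / delta_r (means), their SDs, per-permutation vectors,
#'   n_permutations and one-sided p-values.
#' @export
permutation_importance <- function(model, records, feature, n_perm = 30,
                                   seed = 1L) {
  if (!feature %in% names(records))
    stop_domain("unknown feature '%s'; records have: %s", feature,
                paste(names(records), collapse = ", "))
  if (n_perm < 2) stop_domain("n_perm must be >= 2")
  y <- records$local_energy
  if (is.null(y) || anyNA(y))
    stop_domain("records must carry local_energy targets")
  base_pred <- predict_local_energies(model, records)
  rmse0 <- sqrt(mean((base_pred - y)^2))
  r0 <- stats::cor(base_pred, y)

  set.seed(seed)
  d_rmse <- d_r <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    shuf <- records
    shuf[[feature]] <- shuf[[feature]][sample.int(nrow(records))]
    pred <- predict_local_energies(model, shuf)
    d_rmse[p] <- sqrt(mean((pred - y)^2)) - rmse0
    d_r[p] <- r0 - stats::cor(pred, y)
  }
  one_sided <- function(d) {
    if (all(d == d[1])) return(if (d[1] > 0) 0 else 1)
    stats::t.test(d, mu = 0, alternative = "greater")$p.value
  }
  structure(list(feature = feature,
                 baseline_rmse = rmse0, baseline_r = r0,
                 delta_rmse = mean(d_rmse), delta_rmse_sd = stats::sd(d_rmse),
                 delta_r = mean(d_r), delta_r_sd = stats::sd(d_r),
                 delta_rmse_all = d_rmse, delta_r_all = d_r,
                 n_permutations = n_perm,
                 p_value_rmse = one_sided(d_rmse),
                 p_value_r = one_sided(d_r)),
            class = "panther_permutation_report")
}

#' @export
print.panther_permutation_report <- function(x, ...) {
  cat(sprintf("permutation importance of '%s' (%d permutations)\n",
              x$feature, x$n_permutations))
  cat(sprintf("  delta RMSE: %.4f +/- %.4f kcal/mol (one-sided p = %.2g)\n",
              x$delta_rmse, x$delta_rmse_sd, x$p_value_rmse))
  cat(sprintf("  delta r:    %.4f +/- %.4f (one-sided p = %.2g)\n",
              x$delta_r, x$delta_r_sd, x$p_value_r))
  invisible(x)
}

#' Persist / restore a trained model
#'
#' Versioned archive carrying the encoding, family, hyperparameters, seed
#' and fitted state; loading refuses archives written under an incompatible
#' format version.
#'
#' @param model a \code{panther_model}.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "panther_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "panther_model"))
    stop_domain("'%s' is not a panther model archive", path)
  if (!identical(model$format_version, 1L))
    stop_domain("model archive format version %s is not supported",
                model$format_version %||% "<missing>")
  model
}
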