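#' Cohort feature dataset
#'
#' Container pairing the model-by-feature matrix with the aBMD labels and
#' the feature-block column ranges.
#'
#' @param X numeric matrix (rows = tissue models, columns = features,
#'   unstandardized).
#' @param y aBMD labels, g/cm^2.
#' @param blocks named list of column index vectors (Bf, Ff, Lf); defaults
#'   to one block spanning all columns.
#' @param provenance free-form provenance (seeds, config) carried along.
#' @return A list of class \code{cohort_dataset}.
#' @export
cohort_dataset <- function(X, y, blocks = NULL, provenance = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (is.null(blocks)) blocks <- list(all = seq_len(ncol(X)))
  structure(list(X = X, y = as.numeric(y), blocks = blocks,
                 provenance = provenance),
            class = "cohort_dataset")
}

#' Split a dataset into training and held-out test parts
#'
#' @param ds a [cohort_dataset()].
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed for the random row selection.
#' @return list with \code{train} and \code{test} datasets (disjoint, union
#'   = input rows) and the \code{train_idx}.
#' @export
split_dataset <- function(ds, fraction = 0.8, seed = 1L) {
  stopifnot(inherits(ds, "cohort_dataset"), fraction > 0, fraction < 1)
  n <- nrow(ds$X)
  if (n < 10) stop("too few rows to split")
  n_train <- round(fraction * n)
  set.seed(seed)
  idx <- sample.int(n, n_train)
  sub <- function(i) cohort_dataset(ds$X[i, , drop = FALSE], ds$y[i],
                                    ds$blocks, ds$provenance)
  list(train = sub(idx), test = sub(-idx), train_idx = sort(idx))
}

#' Default hyperparameter grids
#'
#' Grid-search candidates for the four algorithms. The ridge penalty spans
#' 1e-5 to 1e-1 and the SVM RBF kernel coefficient 1e-4 to 1; the remaining
#' grids cover the usual working ranges of each learner and can be
#' overridden (or thinned for quick runs) by passing a modified copy.
#'
#' @return Named list of data.frames, one row per candidate.
#' @export
default_grids <- function() {
  list(
    RR = expand.grid(alpha = 10^seq(-5, -1)),
    SVM = expand.grid(gamma = 10^seq(-4, 0),
                      cost = c(0.1, 1, 10, 100, 1000),
                      epsilon = c(0.001, 0.01, 0.1)),
    RF = expand.grid(num_trees = c(100, 300, 500),
                     min_node = c(1, 3, 5),
                     mtry_frac = c(NA, 1 / 3, 1)),  # NA = sqrt(p)
    GTB = expand.grid(nrounds = c(100, 300),
                      eta = c(0.05, 0.1, 0.3),
                      max_depth = c(3, 5, 7),
                      min_child_weight = c(1, 5),
                      subsample = c(0.7, 1.0),
                      colsample_bytree = c(0.7, 1.0))
  )
}

#' Reduced grids for quick runs
#'
#' Thinned versions of [default_grids()] keeping the endpoints and center
#' of each range; used by the scaled-down pipeline profile.
#' @return Named list of data.frames.
#' @export
quick_grids <- function() {
  list(
    RR = expand.grid(alpha = 10^c(-5, -3, -1)),
    SVM = expand.grid(gamma = 10^c(-3, -2, -1),
                      cost = c(1, 10, 100, 1000),
                      epsilon = c(0.001, 0.01, 0.1)),
    RF = expand.grid(num_trees = 300, min_node = c(1, 5),
                     mtry_frac = c(NA, 1 / 3)),
    GTB = expand.grid(nrounds = 150, eta = c(0.1, 0.3),
                      max_depth = c(3, 6), min_child_weight = 1,
                      subsample = 1.0, colsample_bytree = c(0.7, 1.0))
  )
}

fit_learner <- function(algorithm, params, X, y, seed = 1L) {
  p <- as.list(params)
  switch(algorithm,
    RR = {
      fit <- MASS::lm.ridge(y ~ X, lambda = p$alpha)
      structure(list(coef = coef(fit)), class = "osteosim_rr")
    },
    SVM = e1071::svm(x = X, y = y, type = "eps-regression",
                     kernel = "radial", gamma = p$gamma, cost = p$cost,
                     epsilon = p$epsilon, scale = FALSE),
    RF = {
      mtry <- if (is.na(p$mtry_frac)) max(1L, floor(sqrt(ncol(X))))
              else max(1L, floor(p$mtry_frac * ncol(X)))
      ranger::ranger(y = y, x = as.data.frame(X),
                     num.trees = p$num_trees, min.node.size = p$min_node,
                     mtry = mtry, seed = seed, num.threads = 1)
    },
    GTB = {
      dtr <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = p$eta,
                      max_depth = p$max_depth,
                      min_child_weight = p$min_child_weight,
                      subsample = p$subsample,
                      colsample_bytree = p$colsample_bytree,
                      nthread = 1, seed = seed),
        data = dtr, nrounds = p$nrounds, verbose = 0)
    },
    stop("unknown algorithm: ", algorithm))
}

predict_learner <- function(fit, X) {
  if (inherits(fit, "osteosim_rr"))
    return(drop(cbind(1, X) %*% fit$coef))
  if (inherits(fit, "ranger"))
    return(predict(fit, data = as.data.frame(X), num.threads = 1)$predictions)
  if (inherits(fit, "xgb.Booster"))
    return(predict(fit, xgboost::xgb.DMatrix(X)))
  as.numeric(predict(fit, X))
}

#' Coefficient of determination
#'
#' \eqn{r^2 = 1 - SS_{res}/SS_{tot}}; can be negative for predictions worse
#' than the mean.
#'
#' @param y_true reference values (variance must be positive).
#' @param y_pred predictions.
#' @return r^2.
#' @export
evaluate_r2 <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("evaluate_r2: zero label variance")
  1 - sum((y_true - y_pred)^2) / sst
}

make_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Grid-searched k-fold cross-validated model selection
#'
#' Scores every hyperparameter candidate by its mean r^2 over k folds of
#' the training dataset, selects the best, and refits it on the full
#' training data. Features are standardized to mean 0 / SD 1; with
#' \code{standardize = "train-folds"} (default) the scaler is fit on the
#' training folds only and applied to each held-out fold, with
#' \code{"full-dataset"} a single scaler is fit on all rows first.
#'
#' @param ds training [cohort_dataset()].
#' @param algorithm one of \code{"RR"}, \code{"SVM"}, \code{"RF"},
#'   \code{"GTB"}.
#' @param grids named list of candidate data.frames (see
#'   [default_grids()]).
#' @param k number of folds (default 10).
#' @param seed seed controlling fold assignment and stochastic learners.
#' @param standardize leakage policy for the feature scaler.
#' @return A list of class \code{cv_result}: \code{algorithm},
#'   \code{best_params}, \code{fold_r2}, \code{mean_r2}, \code{sd_r2},
#'   \code{fit} (refit on all rows), \code{standardizer}, \code{grid_r2}
#'   (mean CV score per candidate).
#' @export
tune_and_fit <- function(ds, algorithm = c("SVM", "RR", "RF", "GTB"),
                         grids = default_grids(), k = 10, seed = 1L,
                         standardize = c("train-folds", "full-dataset")) {
  algorithm <- match.arg(algorithm)
  standardize <- match.arg(standardize)
  stopifnot(inherits(ds, "cohort_dataset"))
  if (var(ds$y) == 0) stop("degenerate labels: zero variance")
  grid <- grids[[algorithm]]
  if (is.null(grid) || nrow(grid) == 0) stop("empty grid for ", algorithm)
  folds <- make_folds(nrow(ds$X), k, seed)
  full_std <- if (standardize == "full-dataset")
    fit_standardizer(ds$X, "full-dataset") else NULL
  score_one <- function(params) {
    r2 <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      if (is.null(full_std)) {
        s <- fit_standardizer(ds$X[tr, , drop = FALSE], "train-folds")
      } else s <- full_std
      Xtr <- apply_standardizer(s, ds$X[tr, , drop = FALSE])
      Xte <- apply_standardizer(s, ds$X[!tr, , drop = FALSE])
      fit <- fit_learner(algorithm, params, Xtr, ds$y[tr], seed)
      r2[f] <- evaluate_r2(ds$y[!tr], predict_learner(fit, Xte))
    }
    r2
  }
  grid_scores <- matrix(NA_real_, nrow(grid), k)
  for (i in seq_len(nrow(grid)))
    grid_scores[i, ] <- score_one(grid[i, , drop = FALSE])
  mean_scores <- rowMeans(grid_scores)
  best <- which.max(mean_scores)
  s_final <- if (is.null(full_std))
    fit_standardizer(ds$X, "train-folds") else full_std
  fit <- fit_learner(algorithm, grid[best, , drop = FALSE],
                     apply_standardizer(s_final, ds$X), ds$y, seed)
  structure(list(algorithm = algorithm,
                 best_params = as.list(grid[best, , drop = FALSE]),
                 fold_r2 = grid_scores[best, ],
                 mean_r2 = mean_scores[best],
                 sd_r2 = sd(grid_scores[best, ]),
                 fit = fit, standardizer = s_final,
                 grid_r2 = mean_scores),
            class = "cv_result")
}

#' Predict with a tuned model
#'
#' @param object a \code{cv_result} from [tune_and_fit()].
#' @param newdata feature matrix (unstandardized) or [cohort_dataset()].
#' @param ... unused.
#' @return Predicted aBMD values.
#' @export
predict.cv_result <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "cohort_dataset")) newdata$X else newdata
  predict_learner(object$fit, apply_standardizer(object$standardizer, X))
}

#' Feature-block ablation
#'
#' Evaluates every non-empty combination of the feature blocks: for each
#' subset the model is re-tuned on the training data restricted to those
#' columns and scored on the held-out test data.
#'
#' @param train,test [cohort_dataset()] pair from [split_dataset()].
#' @param algorithm learner to use (default SVM).
#' @param grids hyperparameter grids.
#' @param k folds for the inner tuning.
#' @param seed seed.
#' @return Named numeric vector of test r^2, names like "Bf", "Bf+Lf",
#'   "Bf+Ff+Lf".
#' @export
ablation <- function(train, test, algorithm = "SVM",
                     grids = default_grids(), k = 10, seed = 1L) {
  stopifnot(identical(names(train$blocks), names(test$blocks)))
  bn <- names(train$blocks)
  combos <- unlist(lapply(seq_along(bn),
                          function(m) combn(bn, m, simplify = FALSE)),
                   recursive = FALSE)
  out <- numeric(length(combos))
  names(out) <- vapply(combos, paste, "", collapse = "+")
  for (i in seq_along(combos)) {
    cols <- sort(unlist(train$blocks[combos[[i]]]))
    tr <- cohort_dataset(train$X[, cols, drop = FALSE], train$y)
    te <- cohort_dataset(test$X[, cols, drop = FALSE], test$y)
    cv <- tune_and_fit(tr, algorithm, grids, k, seed)
    out[i] <- evaluate_r2(te$y, predict(cv, te))
  }
  out
}

#' Final k-fold cross-validation with agreement statistics
#'
#' Re-fits the selected hyperparameters on k-1 folds and predicts the
#' held-out fold, rotating so every row receives exactly one out-of-fold
#' prediction, then summarizes agreement between predicted and reference
#' aBMD: coefficient of determination, Bland-Altman mean difference,
#' 95% limits of agreement (1.96 SD of the differences, reported as the
#' half-width) and the correlation of difference vs mean (proportional
#' bias).
#'
#' @param ds full [cohort_dataset()].
#' @param algorithm learner name.
#' @param params hyperparameter list (e.g. \code{best_params} of a
#'   [tune_and_fit()] result).
#' @param k folds.
#' @param seed seed for fold assignment.
#' @param standardize leakage policy, as in [tune_and_fit()].
#' @return A list of class \code{agreement_report}: \code{regression_r2},
#'   \code{mean_diff}, \code{loa}, \code{prop_bias_r}, \code{predictions}
#'   (per-row out-of-fold predictions), \code{fold} assignment.
#' @export
final_cv <- function(ds, algorithm, params, k = 10, seed = 1L,
                     standardize = c("train-folds", "full-dataset")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(ds, "cohort_dataset"))
  folds <- make_folds(nrow(ds$X), k, seed)
  pred <- rep(NA_real_, nrow(ds$X))
  full_std <- if (standardize == "full-dataset")
    fit_standardizer(ds$X, "full-dataset") else NULL
  for (f in seq_len(k)) {
    tr <- folds != f
    s <- if (is.null(full_std))
      fit_standardizer(ds$X[tr, , drop = FALSE], "train-folds") else full_std
    fit <- fit_learner(algorithm, params,
                       apply_standardizer(s, ds$X[tr, , drop = FALSE]),
                       ds$y[tr], seed)
    pred[!tr] <- predict_learner(fit, apply_standardizer(s, ds$X[!tr, , drop = FALSE]))
  }
  stopifnot(!anyNA(pred))
  ba <- bland_altman(ds$y, pred)
  structure(c(list(regression_r2 = evaluate_r2(ds$y, pred)), ba,
              list(predictions = pred, fold = folds)),
            class = "agreement_report")
}

#' Bland-Altman agreement statistics
#'
#' @param reference,predicted paired measurements.
#' @return list with \code{mean_diff} (predicted - reference), \code{loa}
#'   (1.96 SD of differences, half-width of the 95% limits of agreement)
#'   and \code{prop_bias_r} (correlation of difference vs pairwise mean; 0
#'   when the differences are constant).
#' @export
bland_altman <- function(reference, predicted) {
  d <- predicted - reference
  m <- (predicted + reference) / 2
  degenerate <- sd(d) <= 1e-12 * max(abs(d), 1) || sd(m) == 0
  pb <- if (degenerate) 0 else cor(d, m)
  list(mean_diff = mean(d), loa = 1.96 * sd(d), prop_bias_r = pb)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Out-of-fold agreement: r^2 = %.3f, mean diff = %.4f, LoA = +/-%.4f g/cm^2, prop. bias r = %.2f\n",
              x$regression_r2, x$mean_diff, x$loa, x$prop_bias_r))
  invisible(x)
}
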