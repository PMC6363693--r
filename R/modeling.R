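# Experimental grid, cross-validated training with hyperparameter search,
# random-forest feature selection, and Y-randomization.

#' Task configuration for the modeling grid
#'
#' Defaults reproduce the full protocol: four fingerprints (ECFP4/ECFP6 at
#' 1024/2048 bits), four feature options (full, top512, top256, top128), five
#' method families (KNN, SVM, GBM, RF and the two networks DNN2/DNN3),
#' nineteen data-splitting schemes for the standard methods and three for the
#' networks, five-fold cross-validation, and an applicability-domain
#' threshold of 0.1 average Tanimoto similarity.
#'
#' @param task `"classification"` or `"regression"`.
#' @param fingerprints Named list of [fp_config()] objects.
#' @param feature_options Subset of `c("full", "top512", "top256", "top128")`.
#' @param methods Subset of `c("KNN", "SVM", "GBM", "RF", "DNN2", "DNN3")`.
#' @param n_schemes,n_schemes_dnn Splitting-scheme counts (19 / 3).
#' @param cv_folds Folds for cross-validation (5).
#' @param grids Hyperparameter grids, see [default_grids()].
#' @param split_fraction CV fraction for classification splits (0.8).
#' @param ad_threshold Applicability-domain threshold (0.1).
#' @return A list of class `task_config`.
#' @export
task_config <- function(task = c("classification", "regression"),
                        fingerprints = standard_fingerprints(),
                        feature_options = c("full", "top512", "top256",
                                            "top128"),
                        methods = METHOD_FAMILIES,
                        n_schemes = 19L, n_schemes_dnn = 3L, cv_folds = 5L,
                        grids = default_grids(), split_fraction = 0.8,
                        ad_threshold = 0.1) {
  task <- match.arg(task)
  if (!length(fingerprints) || !length(feature_options) || !length(methods))
    stop("empty configuration axis")
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  ks <- .feature_k(feature_options)
  min_bits <- min(vapply(fingerprints, function(f) f$n_bits, numeric(1)))
  if (any(ks > min_bits, na.rm = TRUE))
    stop("feature option exceeds fingerprint length")
  if (is.null(names(fingerprints)))
    names(fingerprints) <- vapply(fingerprints, fp_label, character(1))
  structure(list(task = task, fingerprints = fingerprints,
                 feature_options = feature_options, methods = methods,
                 n_schemes = as.integer(n_schemes),
                 n_schemes_dnn = as.integer(n_schemes_dnn),
                 cv_folds = as.integer(cv_folds), grids = grids,
                 split_fraction = split_fraction,
                 ad_threshold = ad_threshold),
            class = "task_config")
}

.feature_k <- function(option) {
  k <- suppressWarnings(as.integer(sub("^top", "", option)))
  k[option == "full"] <- NA_integer_
  k
}

#' Enumerate the model grid
#'
#' Full cross-product of fingerprint, feature option, method and splitting
#' scheme, with the network restriction (DNN2/DNN3 run only on the first
#' `n_schemes_dnn` schemes). Ordering is deterministic: fingerprint, feature
#' option, method, scheme. The full default grid has 1312 cells: 328 without
#' feature selection and 984 with.
#'
#' @param config A [task_config()].
#' @return Data frame with columns `fingerprint`, `feature_option`, `method`,
#'   `scheme_id`.
#' @export
enumerate_grid <- function(config) {
  stopifnot(inherits(config, "task_config"))
  rows <- list()
  for (fpn in names(config$fingerprints)) {
    for (fo in config$feature_options) {
      for (m in config$methods) {
        ns <- if (is_dnn(m)) config$n_schemes_dnn else config$n_schemes
        rows[[length(rows) + 1L]] <-
          data.frame(fingerprint = fpn, feature_option = fo, method = m,
                     scheme_id = seq_len(ns), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Planned random-forest feature-importance runs
#'
#' Feature selection trains one RF per (fingerprint, scheme) pair on the full
#' feature set; with four fingerprints and nineteen schemes this plans 76
#' runs.
#'
#' @param config A [task_config()].
#' @return Data frame with columns `fingerprint`, `scheme_id`.
#' @export
plan_importance_runs <- function(config) {
  stopifnot(inherits(config, "task_config"))
  out <- expand.grid(scheme_id = seq_len(config$n_schemes),
                     fingerprint = names(config$fingerprints),
                     stringsAsFactors = FALSE)[, 2:1]
  rownames(out) <- NULL
  out
}

#' Construct a feature ranking from an importance vector
#'
#' Ranked indices are in descending importance; ties break toward the lower
#' bit index, so an all-equal importance vector yields the identity order.
#'
#' @param importance Non-negative numeric vector (length = fingerprint bits).
#' @param fingerprint Label of the fingerprint the ranking belongs to.
#' @return Object of class `feature_ranking` with `importance` and `ranked`.
#' @export
feature_ranking <- function(importance, fingerprint = NA_character_) {
  structure(list(importance = as.numeric(importance),
                 ranked = order(-importance, seq_along(importance)),
                 fingerprint = fingerprint),
            class = "feature_ranking")
}

#' Rank fingerprint bits by averaged random-forest importance
#'
#' Trains one random forest per splitting scheme on the Dataset-CV rows of
#' the full fingerprint matrix, averages the impurity-based importance
#' vectors (mean decrease in Gini impurity / node purity) over schemes, and
#' ranks bits in descending order of the mean.
#'
#' @param X Full 0/1 fingerprint matrix.
#' @param y Numeric response (0/1 for classification).
#' @param splits List of `split_scheme` objects.
#' @param task `"classification"` or `"regression"`.
#' @param ntree Trees per forest (500).
#' @param seed Base seed; the per-scheme seed is `seed + scheme_id`.
#' @return A [feature_ranking()].
#' @export
rank_features <- function(X, y, splits, task, ntree = 500L, seed = 1000L) {
  if (all(X == 0)) stop("degenerate all-zero feature matrix")
  imp <- matrix(0, nrow = length(splits), ncol = ncol(X))
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    yy <- if (task == "classification")
      factor(y[sp$cv], levels = c(0, 1)) else y[sp$cv]
    fit <- with_seed(seed + sp$scheme_id,
      randomForest::randomForest(x = X[sp$cv, , drop = FALSE], y = yy,
                                 ntree = ntree, importance = FALSE))
    iv <- fit$importance[, ncol(fit$importance)]  # Gini / node purity
    imp[s, ] <- as.numeric(iv)
  }
  feature_ranking(colMeans(imp),
                  fingerprint = fp_label(attr(X, "config")))
}

#' Select the top-k ranked features
#'
#' @param ranking A [feature_ranking()].
#' @param k Number of features (128, 256 or 512 in the standard protocol).
#' @return Integer vector of the first `k` ranked bit indices, ranking order
#'   preserved; `top128` is a prefix of `top256` is a prefix of `top512`.
#' @export
select_top_k <- function(ranking, k) {
  k <- as.integer(k)
  if (k > length(ranking$importance))
    stop("k exceeds the number of fingerprint bits")
  ranking$ranked[seq_len(k)]
}

# Stratified CV fold assignment. Classification keeps class proportions per
# fold and retries with the next seed if a fold misses a class.
.make_folds <- function(y, task, cv_folds, seed) {
  n <- length(y)
  for (attempt in 0:4) {
    folds <- with_seed(seed + attempt, {
      f <- integer(n)
      if (task == "classification") {
        for (cl in unique(y)) {
          idx <- which(y == cl)
          f[idx[sample.int(length(idx))]] <-
            rep_len(seq_len(cv_folds), length(idx))
        }
      } else {
        f[sample.int(n)] <- rep_len(seq_len(cv_folds), n)
      }
      f
    })
    if (task != "classification") return(folds)
    ok <- all(vapply(seq_len(cv_folds), function(k)
      length(unique(y[folds == k])) == 2L, logical(1)))
    if (ok) return(folds)
  }
  stop("could not stratify folds: a fold is missing a class after 5 attempts")
}

.fold_metric <- function(y, scores, task) {
  if (task == "classification") {
    cm <- classification_metrics(
      confusion_counts(y, as.integer(scores >= 0.5), positive = 1L))
    cm$f1
  } else {
    regression_metrics(y, scores)$r2
  }
}

.full_metrics <- function(y, scores, task) {
  if (task == "classification") {
    m <- classification_metrics(
      confusion_counts(y, as.integer(scores >= 0.5), positive = 1L))
    unclass(m)
  } else {
    unclass(regression_metrics(y, scores))
  }
}

# Average per-fold metric lists, ignoring undefined entries.
.average_metrics <- function(metric_list) {
  keys <- names(metric_list[[1L]])
  out <- lapply(keys, function(k) {
    v <- vapply(metric_list, function(m) m[[k]], numeric(1))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  names(out) <- keys
  out
}

#' Train one grid cell with five-fold cross-validation
#'
#' Runs stratified k-fold cross-validation over Dataset-CV for every
#' hyperparameter assignment in the method's grid, picks the assignment with
#' the best mean fold metric (F1-score for classification, R² for
#' regression; ties go to the first assignment in grid order), refits on all
#' of Dataset-CV with the winning assignment, and records the cross-validated
#' metrics.
#'
#' @param method Method family name.
#' @param X Full 0/1 fingerprint matrix for the whole dataset.
#' @param y Numeric response (0/1 for classification).
#' @param split A `split_scheme`.
#' @param task `"classification"` or `"regression"`.
#' @param grid List of hyperparameter assignments (default from
#'   [default_grids()]).
#' @param cv_folds Number of folds (5).
#' @param feature_idx Optional selected feature indices (`NULL` = full).
#' @param feature_option Label recorded on the model (`"full"`, `"top128"`,
#'   ...).
#' @param seed Base seed; defaults to the scheme id.
#' @return Object of class `sweet_model` carrying the fitted learner, the
#'   winning hyperparameters and the CV metrics.
#' @export
train_cv <- function(method, X, y, split, task, grid = NULL, cv_folds = 5L,
                     feature_idx = NULL, feature_option = "full",
                     seed = NULL) {
  if (is.null(grid)) grid <- default_grids()[[method]]
  if (is.null(seed)) seed <- split$scheme_id
  cols <- if (is.null(feature_idx)) seq_len(ncol(X)) else feature_idx
  Xcv <- X[split$cv, cols, drop = FALSE]
  ycv <- y[split$cv]
  folds <- .make_folds(ycv, task, cv_folds, seed * 131L)

  best <- NULL
  for (gi in seq_along(grid)) {
    fold_scores <- numeric(cv_folds)
    fold_metrics <- vector("list", cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      fit <- fit_learner(method, Xcv[tr, , drop = FALSE], ycv[tr], task,
                         grid[[gi]], seed = seed * 1000L + gi * 10L + f)
      sc <- predict_learner(fit, Xcv[!tr, , drop = FALSE])
      fold_metrics[[f]] <- .full_metrics(ycv[!tr], sc, task)
      m <- .fold_metric(ycv[!tr], sc, task)
      fold_scores[f] <- if (is.na(m)) -Inf else m
    }
    mean_score <- mean(fold_scores)
    if (is.null(best) || mean_score > best$score) {
      best <- list(score = mean_score, gi = gi,
                   cv_metrics = .average_metrics(fold_metrics))
    }
  }
  final <- fit_learner(method, Xcv, ycv, task, grid[[best$gi]],
                       seed = seed * 1000L)
  structure(list(method = method,
                 fingerprint = if (!is.null(attr(X, "config")))
                   fp_label(attr(X, "config")) else NA_character_,
                 feature_option = feature_option,
                 feature_idx = cols,
                 scheme_id = split$scheme_id,
                 task = task,
                 best_params = grid[[best$gi]],
                 cv_metrics = best$cv_metrics,
                 test_metrics = NULL,
                 learner = final,
                 seed = seed),
            class = "sweet_model")
}

#' @export
print.sweet_model <- function(x, ...) {
  cv <- if (x$task == "classification") x$cv_metrics$f1 else x$cv_metrics$r2
  te <- if (is.null(x$test_metrics)) NA_real_ else {
    if (x$task == "classification") x$test_metrics$f1 else x$test_metrics$r2
  }
  cat(sprintf("<sweet_model %s %s %s scheme %d: CV %s = %.3f, test = %.3f>\n",
              x$method, x$fingerprint, x$feature_option, x$scheme_id,
              if (x$task == "classification") "F1" else "R2", cv, te))
  invisible(x)
}

#' Evaluate a trained model on its hold-out test set
#'
#' @param model A `sweet_model` from [train_cv()].
#' @param X Full fingerprint matrix (same one used in training).
#' @param y Numeric response.
#' @param split The model's `split_scheme`.
#' @return The model with `test_metrics` (and `test_scores`) attached.
#' @export
evaluate_test <- function(model, X, y, split) {
  if (!length(split$test)) stop("empty test set")
  Xt <- X[split$test, model$feature_idx, drop = FALSE]
  sc <- predict_learner(model$learner, Xt)
  model$test_scores <- sc
  model$test_metrics <- .full_metrics(y[split$test], sc, model$task)
  model
}

#' Y-randomization control run
#'
#' Shuffles the Dataset-CV responses (seed = scheme id), retrains with the
#' identical protocol, and evaluates against the true, unshuffled test
#' responses. A genuine structure-activity model collapses to chance under
#' this scrambling.
#'
#' @inheritParams train_cv
#' @param permutation Optional explicit permutation of the CV responses
#'   (identity gives back the unshuffled run; used as a control).
#' @return A `sweet_model` with test metrics computed against the true test
#'   labels.
#' @export
y_randomize <- function(method, X, y, split, task, grid = NULL,
                        cv_folds = 5L, feature_idx = NULL,
                        feature_option = "full", seed = NULL,
                        permutation = NULL) {
  if (is.null(permutation)) {
    permutation <- with_seed(split$scheme_id,
                             sample.int(length(split$cv)))
  }
  y2 <- y
  y2[split$cv] <- y[split$cv][permutation]
  m <- train_cv(method, X, y2, split, task, grid = grid, cv_folds = cv_folds,
                feature_idx = feature_idx, feature_option = feature_option,
                seed = seed)
  evaluate_test(m, X, y, split)
}
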