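# Average models over splitting schemes and the named consensus models.

#' Parse a fingerprint label back into its configuration
#'
#' @param label A label such as `"ECFP6-2048"` (diameter-bits).
#' @return The corresponding [fp_config()].
#' @export
parse_fp_label <- function(label) {
  m <- regmatches(label, regexec("^ECFP(\\d+)-(\\d+)$", label))[[1L]]
  if (length(m) != 3L) stop("not a fingerprint label: ", label)
  fp_config(as.integer(m[2L]) / 2L, as.integer(m[3L]))
}

group_key <- function(model) {
  paste(model$fingerprint, model$feature_option, model$method, sep = "|")
}

#' Build average models by pooling over splitting schemes
#'
#' Groups trained models by (fingerprint, feature option, method) and
#' averages every CV and test metric over the group's schemes (undefined
#' values excluded). The full default grid yields 96 average models.
#'
#' @param models List of `sweet_model` objects with test metrics attached.
#' @param n_schemes,n_schemes_dnn Expected scheme counts per group (inferred
#'   from the models when `NULL`); incomplete groups are an error.
#' @return List of `average_model` objects.
#' @export
build_average_models <- function(models, n_schemes = NULL,
                                 n_schemes_dnn = NULL) {
  if (!length(models)) stop("no models supplied")
  keys <- vapply(models, group_key, character(1))
  schemes <- vapply(models, function(m) as.integer(m$scheme_id), integer(1))
  dnn <- vapply(models, function(m) is_dnn(m$method), logical(1))
  if (is.null(n_schemes))
    n_schemes <- if (any(!dnn)) max(schemes[!dnn]) else 0L
  if (is.null(n_schemes_dnn))
    n_schemes_dnn <- if (any(dnn)) max(schemes[dnn]) else 0L
  out <- list()
  for (k in unique(keys)) {
    idx <- which(keys == k)
    grp <- models[idx]
    expected <- seq_len(if (is_dnn(grp[[1L]]$method)) n_schemes_dnn
                        else n_schemes)
    missing <- setdiff(expected, schemes[idx])
    if (length(missing))
      stop("group ", k, " is missing scheme(s): ",
           paste(missing, collapse = ", "))
    cv_tab <- do.call(rbind, lapply(grp, function(m)
      unlist(m$cv_metrics)))
    te_tab <- do.call(rbind, lapply(grp, function(m)
      unlist(m$test_metrics)))
    avg <- function(tab) {
      m <- apply(tab, 2L, function(v) {
        if (all(is.na(v))) NA_real_ else {
          if (anyNA(v)) warning("undefined metric excluded from averaging")
          mean(v, na.rm = TRUE)
        }
      })
      s <- apply(tab, 2L, function(v)
        if (sum(!is.na(v)) < 2L) NA_real_ else stats::sd(v, na.rm = TRUE))
      list(mean = as.list(m), sd = as.list(s))
    }
    cv <- avg(cv_tab); te <- avg(te_tab)
    out[[length(out) + 1L]] <- structure(
      list(fingerprint = grp[[1L]]$fingerprint,
           feature_option = grp[[1L]]$feature_option,
           method = grp[[1L]]$method,
           task = grp[[1L]]$task,
           models = grp,
           cv_mean = cv$mean, cv_sd = cv$sd,
           test_mean = te$mean, test_sd = te$sd,
           n = length(grp)),
      class = "average_model")
  }
  out
}

#' @export
print.average_model <- function(x, ...) {
  key <- if (x$task == "classification") "f1" else "r2"
  cat(sprintf("<average_model %s %s %s: %d schemes, mean test %s = %.3f (sd %.3f)>\n",
              x$method, x$fingerprint, x$feature_option, x$n, toupper(key),
              x$test_mean[[key]],
              if (is.na(x$test_sd[[key]])) NA else x$test_sd[[key]]))
  invisible(x)
}

.selection_value <- function(obj, task, select_on) {
  key <- if (task == "classification") "f1" else "r2"
  if (inherits(obj, "average_model")) {
    src <- if (select_on == "cv") obj$cv_mean else obj$test_mean
  } else {
    src <- if (select_on == "cv") obj$cv_metrics else obj$test_metrics
  }
  v <- src[[key]]
  if (is.null(v) || is.na(v)) -Inf else v
}

#' Select a named consensus model
#'
#' The four classification consensus rules (regression uses CM01-CM03 with R²
#' as the selection metric):
#' * `CM01` - per splitting scheme, the best individual model excluding the
#'   networks (19 constituents under the full protocol);
#' * `CM02` - per scheme, the best individual model including the networks;
#' * `CM03` - the top `n_top` (default 5) average models;
#' * `CM04` - the best average model per method family, DNN2/DNN3 pooled as
#'   one DNN family (5 constituents).
#'
#' @param name One of `"CM01".."CM04"`.
#' @param models List of `sweet_model` objects (evaluated on test sets).
#' @param average_models List from [build_average_models()].
#' @param task `"classification"` or `"regression"`.
#' @param select_on Rank constituents by cross-validated (`"cv"`, default) or
#'   test (`"test"`) selection metric.
#' @param n_top Constituent count for CM03.
#' @return Object of class `consensus_model`.
#' @export
select_consensus <- function(name, models, average_models = NULL,
                             task = c("classification", "regression"),
                             select_on = c("cv", "test"), n_top = 5L) {
  task <- match.arg(task)
  select_on <- match.arg(select_on)
  name <- toupper(name)
  if (!name %in% c("CM01", "CM02", "CM03", "CM04"))
    stop("unknown consensus model name: ", name)
  if (name == "CM04" && task == "regression")
    stop("the regression protocol defines CM01-CM03 only")

  pick_best <- function(cands) {
    vals <- vapply(cands, .selection_value, numeric(1), task = task,
                   select_on = select_on)
    cands[[which.max(vals)]]
  }

  if (name %in% c("CM01", "CM02")) {
    pool <- if (name == "CM01")
      Filter(function(m) !is_dnn(m$method), models) else models
    if (!length(pool))
      stop(name, ": no eligible constituent models")
    schemes <- sort(unique(vapply(pool, function(m) m$scheme_id,
                                  integer(1))))
    constituents <- lapply(schemes, function(s)
      pick_best(Filter(function(m) m$scheme_id == s, pool)))
  } else if (name == "CM03") {
    if (!length(average_models)) stop("CM03 requires average models")
    vals <- vapply(average_models, .selection_value, numeric(1),
                   task = task, select_on = select_on)
    ord <- order(-vals)
    constituents <- average_models[ord[seq_len(min(n_top,
                                                   length(average_models)))]]
  } else {
    if (!length(average_models)) stop("CM04 requires average models")
    fam <- vapply(average_models, function(a)
      if (is_dnn(a$method)) "DNN" else a$method, character(1))
    constituents <- lapply(unique(fam), function(f)
      pick_best(average_models[fam == f]))
  }

  metric_tab <- do.call(rbind, lapply(constituents, function(cst) {
    if (inherits(cst, "average_model")) unlist(cst$test_mean)
    else unlist(cst$test_metrics)
  }))
  structure(list(name = name, task = task, constituents = constituents,
                 rule = if (task == "classification") "mean-probability"
                        else "mean-value",
                 select_on = select_on,
                 metrics = metric_tab),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("<consensus_model %s (%s): %d constituents, rule %s>\n",
              x$name, x$task, length(x$constituents), x$rule))
  invisible(x)
}

#' 95% confidence-interval summary of a consensus model's metrics
#'
#' Applies [confidence_interval()] to each metric across the constituent
#' models.
#'
#' @param cm A [select_consensus()] result.
#' @return Data frame with one row per metric: mean, sd, margin, lower,
#'   upper.
#' @export
consensus_summary <- function(cm) {
  tabs <- lapply(colnames(cm$metrics), function(met) {
    v <- cm$metrics[, met]
    ci <- tryCatch(suppressWarnings(confidence_interval(v)),
                   error = function(e) NULL)
    if (is.null(ci))
      data.frame(metric = met, mean = mean(v, na.rm = TRUE), sd = NA,
                 margin = NA, lower = NA, upper = NA)
    else
      data.frame(metric = met, mean = ci$mean, sd = ci$sd,
                 margin = ci$margin, lower = ci$lower, upper = ci$upper)
  })
  do.call(rbind, tabs)
}

# Score one constituent (individual or average model) on fingerprint
# matrices keyed by fingerprint label.
.constituent_scores <- function(cst, fps_by_label) {
  if (inherits(cst, "average_model")) {
    scores <- lapply(cst$models, .constituent_scores,
                     fps_by_label = fps_by_label)
    return(rowMeans(matrix(unlist(scores), ncol = length(scores))))
  }
  X <- fps_by_label[[cst$fingerprint]]
  if (is.null(X)) stop("missing fingerprint matrix for ", cst$fingerprint)
  predict_learner(cst$learner, X[, cst$feature_idx, drop = FALSE])
}

consensus_fp_labels <- function(cm) {
  unique(unlist(lapply(cm$constituents, function(cst) cst$fingerprint)))
}

#' Predict with a consensus model
#'
#' Classification: the mean of the constituent positive-class scores, with
#' label `"sweet"` iff the mean is >= 0.5. Regression: the mean predicted
#' log10 relative sweetness, also reported back-transformed as
#' `RS = 10^mean`. An average-model constituent contributes the mean over its
#' per-scheme members.
#'
#' @param cm A `consensus_model`.
#' @param mols List of [molgraph()] objects (fingerprints are computed as
#'   needed), or `NULL` if `fps` is given.
#' @param fps Optional named list of precomputed fingerprint matrices keyed
#'   by fingerprint label (e.g. `"ECFP6-2048"`).
#' @return Data frame: `id`, `score`, `label` (classification) or `id`,
#'   `log10rs`, `rs` (regression).
#' @export
predict_consensus <- function(cm, mols = NULL, fps = NULL) {
  labels <- consensus_fp_labels(cm)
  if (is.null(fps)) fps <- list()
  for (lb in setdiff(labels, names(fps))) {
    if (is.null(mols)) stop("need molecules to compute fingerprints ", lb)
    fps[[lb]] <- ecfp_matrix(mols, parse_fp_label(lb))
  }
  n <- nrow(fps[[labels[1L]]])
  score_list <- lapply(cm$constituents, .constituent_scores,
                       fps_by_label = fps)
  mean_score <- rowMeans(matrix(unlist(score_list),
                                ncol = length(score_list)))
  ids <- rownames(fps[[labels[1L]]])
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (cm$task == "classification") {
    data.frame(id = ids, score = mean_score,
               label = ifelse(mean_score >= 0.5, "sweet", "non-sweet"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = ids, log10rs = mean_score, rs = 10^mean_score,
               stringsAsFactors = FALSE)
  }
}
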