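# The top-level modeling interface: one fitting function running the whole
# consensus protocol, returning a classed object with predict/summary/plot
# methods.

.AD_FP <- "ECFP6-2048"

#' Fit the consensus QSAR protocol
#'
#' Runs the full pipeline on a set of molecules: curation (largest fragment,
#' element filter, conflict removal, cross-source dedup, sucrose-reference
#' filter), fingerprint generation, multi-scheme data splitting,
#' random-forest feature ranking, grid training of every (fingerprint,
#' feature option, method, scheme) cell with five-fold cross-validation and
#' hyperparameter search, hold-out evaluation, average models over schemes,
#' and the named consensus models (CM01-CM04 for classification, CM01-CM03
#' for regression). Everything is seeded through the scheme ids, so reruns
#' are identical.
#'
#' @param mols List of [molgraph()] objects.
#' @param label Character labels (`"sweet"`/`"non-sweet"`) for
#'   classification.
#' @param rs Positive relative-sweetness values for regression (modeled as
#'   log10 RS).
#' @param source,sucrose_ref Passed to [curate_compounds()].
#' @param config A [task_config()]; defaults to the full protocol for the
#'   inferred task.
#' @param curate Apply the curation rules (default `TRUE`; set `FALSE` for
#'   pre-curated input).
#' @param select_on Consensus constituent selection metric source, `"cv"`
#'   (default) or `"test"`.
#' @param verbose Print stage progress.
#' @return An object of class `sweet_qsar`.
#' @seealso [predict.sweet_qsar()], [y_randomization()], [run_pipeline()]
#' @export
sweet_qsar <- function(mols, label = NULL, rs = NULL, source = NULL,
                       sucrose_ref = NULL, config = NULL, curate = TRUE,
                       select_on = c("cv", "test"), verbose = FALSE) {
  select_on <- match.arg(select_on)
  task <- if (is.null(rs)) "classification" else "regression"
  if (is.null(config)) config <- task_config(task)
  if (config$task != task)
    stop("config task does not match the supplied response")
  say <- function(...) if (verbose) message(sprintf(...))

  if (curate) {
    ds <- curate_compounds(mols, label = label, rs = rs, source = source,
                           sucrose_ref = sucrose_ref)
  } else {
    ds <- structure(list(mols = mols, task = task, source = source,
                         ids = vapply(mols, function(m) m$id, character(1))),
                    class = "sweet_dataset")
    if (task == "classification") ds$label <- as.character(label)
    else { ds$rs <- rs; ds$y <- log10(rs) }
  }
  y <- if (task == "classification") as.integer(ds$label == "sweet") else ds$y
  say("curated %d compounds", length(ds$mols))

  n_schemes_all <- max(config$n_schemes,
                       if (any(is_dnn(config$methods))) config$n_schemes_dnn
                       else 0L)
  splits <- lapply(seq_len(n_schemes_all), function(s) {
    if (task == "classification")
      split_classification(ds$label, fraction = config$split_fraction,
                           scheme_id = s)
    else split_regression(ds$y, ids = ds$ids, scheme_id = s)
  })

  fp_needed <- config$fingerprints
  if (!.AD_FP %in% names(fp_needed)) {
    fp_needed[[.AD_FP]] <- parse_fp_label(.AD_FP)
  }
  fps <- lapply(fp_needed, function(cfg) ecfp_matrix(ds$mols, cfg))
  say("computed %d fingerprint matrices", length(fps))

  needs_ranking <- any(config$feature_options != "full")
  rankings <- list()
  if (needs_ranking) {
    for (fpn in names(config$fingerprints)) {
      rankings[[fpn]] <- rank_features(
        fps[[fpn]], y, splits[seq_len(config$n_schemes)], task)
      say("ranked features for %s", fpn)
    }
  }

  grid <- enumerate_grid(config)
  models <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    X <- fps[[g$fingerprint]]
    k <- .feature_k(g$feature_option)
    fidx <- if (is.na(k)) NULL else select_top_k(rankings[[g$fingerprint]], k)
    m <- train_cv(g$method, X, y, splits[[g$scheme_id]], task,
                  grid = config$grids[[g$method]],
                  cv_folds = config$cv_folds,
                  feature_idx = fidx, feature_option = g$feature_option)
    models[[r]] <- evaluate_test(m, X, y, splits[[g$scheme_id]])
    say("[%d/%d] %s %s %s scheme %d", r, nrow(grid), g$method,
        g$fingerprint, g$feature_option, g$scheme_id)
  }

  avg <- build_average_models(models, n_schemes = config$n_schemes,
                              n_schemes_dnn = config$n_schemes_dnn)
  cm_names <- if (task == "classification") paste0("CM0", 1:4)
              else paste0("CM0", 1:3)
  consensus <- list()
  for (nm in cm_names) {
    consensus[[nm]] <- tryCatch(
      select_consensus(nm, models, avg, task, select_on = select_on),
      error = function(e) {
        warning(nm, " not built: ", conditionMessage(e))
        NULL
      })
  }
  consensus <- Filter(Negate(is.null), consensus)

  structure(list(task = task, config = config, dataset = ds, y = y,
                 splits = splits, fps = fps, rankings = rankings,
                 models = models, average_models = avg,
                 consensus = consensus, select_on = select_on,
                 ad_fp = .AD_FP),
            class = "sweet_qsar")
}

#' @export
print.sweet_qsar <- function(x, ...) {
  cat(sprintf("Consensus QSAR fit (%s)\n", x$task))
  cat(sprintf("  compounds: %d; schemes: %d; models: %d; average models: %d\n",
              length(x$dataset$mols), length(x$splits), length(x$models),
              length(x$average_models)))
  cat(sprintf("  consensus models: %s\n",
              paste(names(x$consensus), collapse = ", ")))
  invisible(x)
}

#' @export
summary.sweet_qsar <- function(object, ...) {
  key <- if (object$task == "classification") "f1" else "r2"
  cat(sprintf("Consensus QSAR fit (%s), %d compounds, %d trained models\n\n",
              object$task, length(object$dataset$mols),
              length(object$models)))
  for (nm in names(object$consensus)) {
    cm <- object$consensus[[nm]]
    s <- consensus_summary(cm)
    row <- s[s$metric == key, ]
    cat(sprintf("%s (%d constituents): test %s = %.3f +/- %.3f (95%% CI)\n",
                nm, length(cm$constituents), toupper(key), row$mean,
                row$margin))
  }
  invisible(lapply(object$consensus, consensus_summary))
}

#' Predict new compounds with a fitted consensus model
#'
#' Computes the fingerprints a consensus model needs, averages the
#' constituent predictions (positive-class probability or log10 RS), and
#' checks the applicability domain: average Tanimoto similarity (2048-bit
#' ECFP6) to the five nearest training compounds must strictly exceed the
#' threshold. Compounds failing the element filter are still predicted but
#' flagged with a warning.
#'
#' @param object A [sweet_qsar()] fit.
#' @param mols List of [molgraph()] objects to predict.
#' @param consensus Consensus model name (default the first available).
#' @param check_domain Attach applicability-domain columns (default `TRUE`).
#' @param threshold Domain threshold; defaults to the fitted configuration's.
#' @param ... Unused.
#' @return Data frame with per-compound predictions, `avg_similarity`,
#'   `in_domain` and `element_ok` columns.
#' @export
predict.sweet_qsar <- function(object, mols, consensus = NULL,
                               check_domain = TRUE, threshold = NULL, ...) {
  if (inherits(mols, "molgraph")) mols <- list(mols)
  if (is.null(consensus)) consensus <- names(object$consensus)[1L]
  cm <- object$consensus[[consensus]]
  if (is.null(cm)) stop("no such consensus model: ", consensus)
  if (is.null(threshold)) threshold <- object$config$ad_threshold

  elem_ok <- vapply(mols, element_filter, logical(1))
  if (any(!elem_ok))
    warning(sum(!elem_ok), " compound(s) fail the element filter; ",
            "predictions are flagged")

  labels <- unique(c(consensus_fp_labels(cm),
                     if (check_domain) object$ad_fp))
  fps <- lapply(labels, function(lb) ecfp_matrix(mols, parse_fp_label(lb)))
  names(fps) <- labels
  out <- predict_consensus(cm, fps = fps)
  out$element_ok <- elem_ok
  if (check_domain) {
    ad <- avg_knn_similarity(fps[[object$ad_fp]], object$fps[[object$ad_fp]],
                             k = 5L)
    out$avg_similarity <- ad
    out$in_domain <- ad > threshold
  }
  out
}

#' @export
plot.sweet_qsar <- function(x, which = c("overfit", "domain"),
                            scheme_id = 1L, ...) {
  which <- match.arg(which)
  key <- if (x$task == "classification") "f1" else "r2"
  if (which == "overfit") {
    te <- vapply(x$models, function(m) m$test_metrics[[key]], numeric(1))
    cv <- vapply(x$models, function(m) m$cv_metrics[[key]], numeric(1))
    d <- abs(te - cv)
    graphics::plot(te, d, pch = 16, col = "steelblue",
                   xlab = sprintf("%s (test set)", toupper(key)),
                   ylab = sprintf("|%s(test) - %s(CV)|", toupper(key),
                                  toupper(key)), ...)
    am_te <- vapply(x$average_models, function(a) a$test_mean[[key]],
                    numeric(1))
    am_cv <- vapply(x$average_models, function(a) a$cv_mean[[key]],
                    numeric(1))
    graphics::points(am_te, abs(am_te - am_cv), pch = 17, col = "darkorange")
    graphics::legend("topleft", legend = c("individual", "average"),
                     pch = c(16, 17), col = c("steelblue", "darkorange"),
                     bty = "n")
  } else {
    h <- ad_histogram(x$fps[[x$ad_fp]], x$splits[[scheme_id]])
    plot(h, ...)
  }
  invisible(x)
}

#' Y-randomization validation of a fitted protocol
#'
#' For each requested grid cell, shuffles the Dataset-CV responses, retrains
#' with the identical protocol, and evaluates on the true hold-out test set;
#' alongside, the unshuffled model's test metrics are reported. Genuine
#' models collapse toward chance under shuffling.
#'
#' @param fit A [sweet_qsar()] object.
#' @param specs Data frame of grid cells to randomize (columns as
#'   [enumerate_grid()]); defaults to the fit's full grid.
#' @return Data frame with per-cell real and shuffled test metrics (F1 and
#'   MCC for classification; R² and MAE for regression).
#' @export
y_randomization <- function(fit, specs = NULL) {
  if (is.null(specs)) specs <- enumerate_grid(fit$config)
  key <- if (fit$task == "classification") "f1" else "r2"
  aux <- if (fit$task == "classification") "mcc" else "mae"
  rows <- lapply(seq_len(nrow(specs)), function(r) {
    g <- specs[r, ]
    X <- fit$fps[[g$fingerprint]]
    k <- .feature_k(g$feature_option)
    fidx <- if (is.na(k)) NULL
            else select_top_k(fit$rankings[[g$fingerprint]], k)
    real <- Filter(function(m)
      m$method == g$method && m$fingerprint == g$fingerprint &&
        m$feature_option == g$feature_option &&
        m$scheme_id == g$scheme_id, fit$models)
    shuf <- y_randomize(g$method, X, fit$y, fit$splits[[g$scheme_id]],
                        fit$task, grid = fit$config$grids[[g$method]],
                        cv_folds = fit$config$cv_folds, feature_idx = fidx,
                        feature_option = g$feature_option)
    data.frame(
      method = g$method, fingerprint = g$fingerprint,
      feature_option = g$feature_option, scheme_id = g$scheme_id,
      real = if (length(real)) real[[1L]]$test_metrics[[key]] else NA_real_,
      shuffled = shuf$test_metrics[[key]],
      real_aux = if (length(real)) real[[1L]]$test_metrics[[aux]]
                 else NA_real_,
      shuffled_aux = shuf$test_metrics[[aux]],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "real"] <- paste0(key, "_real")
  names(out)[names(out) == "shuffled"] <- paste0(key, "_shuffled")
  names(out)[names(out) == "real_aux"] <- paste0(aux, "_real")
  names(out)[names(out) == "shuffled_aux"] <- paste0(aux, "_shuffled")
  out
}

#' Per-model run manifest of a fit
#'
#' @param fit A [sweet_qsar()] object.
#' @return Data frame with one row per trained model and all CV/test
#'   metrics.
#' @export
model_manifest <- function(fit) {
  rows <- lapply(fit$models, function(m) {
    cv <- unlist(m$cv_metrics); names(cv) <- paste0("cv_", names(cv))
    te <- unlist(m$test_metrics); names(te) <- paste0("test_", names(te))
    cbind(data.frame(method = m$method, fingerprint = m$fingerprint,
                     feature_option = m$feature_option,
                     scheme_id = m$scheme_id, stringsAsFactors = FALSE),
          as.data.frame(t(cv)), as.data.frame(t(te)))
  })
  do.call(rbind, rows)
}

#' Run the pipeline end-to-end from a structure manifest
#'
#' Reads a CSV manifest (`id,path,label` or `id,path,RS`), loads MOL2/SDF
#' structures, fits the consensus protocol, and writes the run artifacts
#' (model manifest CSV, average-model CSV, consensus description JSON, split
#' descriptors JSON, applicability-domain histogram CSV, log) to a run
#' directory.
#'
#' @param manifest Path to the manifest CSV.
#' @param out_dir Output directory (created if missing).
#' @param config A [task_config()]; default inferred from the manifest
#'   columns.
#' @param verbose Log progress.
#' @return The fitted `sweet_qsar` object, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(manifest, out_dir, config = NULL, verbose = TRUE) {
  man <- read_manifest(manifest)
  if (!nrow(man)) stop("empty manifest")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(line)
  }
  logf("loading %d structures", nrow(man))
  mols <- lapply(seq_len(nrow(man)), function(r) {
    p <- man$path[r]
    ml <- if (grepl("\\.mol2$", p, ignore.case = TRUE)) read_mol2(p)
          else read_sdf(p)
    if (!length(ml)) stop("no structure in ", p)
    m <- ml[[1L]]
    m$id <- man$id[r]
    m
  })
  task <- if ("RS" %in% names(man)) "regression" else "classification"
  if (is.null(config)) config <- task_config(task)
  logf("fitting %s protocol (%d grid cells)", task,
       nrow(enumerate_grid(config)))
  fit <- if (task == "classification")
    sweet_qsar(mols, label = man$label, config = config, verbose = verbose)
  else
    sweet_qsar(mols, rs = man$RS,
               sucrose_ref = if ("sucrose_ref" %in% names(man))
                 as.logical(man$sucrose_ref) else NULL,
               config = config, verbose = verbose)

  utils::write.csv(model_manifest(fit),
                   file.path(out_dir, "models.csv"), row.names = FALSE)
  am <- do.call(rbind, lapply(fit$average_models, function(a) {
    data.frame(method = a$method, fingerprint = a$fingerprint,
               feature_option = a$feature_option, n = a$n,
               t(unlist(a$test_mean)), stringsAsFactors = FALSE)
  }))
  utils::write.csv(am, file.path(out_dir, "average_models.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(fit$consensus, function(cm) list(
      name = cm$name, rule = cm$rule,
      constituents = lapply(cm$constituents, function(cst)
        list(method = cst$method, fingerprint = cst$fingerprint,
             feature_option = cst$feature_option,
             scheme_id = if (inherits(cst, "average_model")) NULL
                         else cst$scheme_id)))),
    file.path(out_dir, "consensus.json"), auto_unbox = TRUE)
  jsonlite::write_json(
    lapply(fit$splits, function(sp) list(scheme_id = sp$scheme_id,
                                         seed = sp$seed, cv_ids = sp$cv,
                                         test_ids = sp$test)),
    file.path(out_dir, "splits.json"), auto_unbox = TRUE)
  h <- ad_histogram(fit$fps[[fit$ad_fp]], fit$splits[[1L]])
  utils::write.csv(
    data.frame(bin_upper = h$breaks[-1L], cv = h$cv_counts,
               test = h$test_counts),
    file.path(out_dir, "ad_histogram.csv"), row.names = FALSE)
  logf("run complete: %d models, %d average models, %d consensus models",
       length(fit$models), length(fit$average_models),
       length(fit$consensus))
  invisible(fit)
}
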