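# Method backends behind the model grid.
#
# Every classifier exposes a positive-class score in [0, 1] (needed by the
# consensus averaging rule): KNN reports the neighbor vote fraction, SVM a
# Platt-style sigmoid calibrated on its decision values, RF the forest vote
# fraction, GBM the boosted logistic output, and the MLP its sigmoid output.
# Regressors return the predicted response directly. All fits are seeded.

#' The five method families (networks split into DNN2/DNN3)
#' @format Character vector.
#' @export
METHOD_FAMILIES <- c("KNN", "SVM", "GBM", "RF", "DNN2", "DNN3")

#' Is a method one of the network variants?
#' @param method Method name.
#' @return Logical.
#' @export
is_dnn <- function(method) method %in% c("DNN2", "DNN3")

#' Default hyperparameter search grids
#'
#' One list per method family; each element is a list of named parameter
#' assignments tried during five-fold cross-validation. `gamma = NA` for the
#' SVM resolves to `1/n_features` at fit time. The network architectures are
#' two hidden layers (1024, 512) and three hidden layers (1024, 512, 256)
#' with dropout 0.25 and early stopping on an internal 10\% validation slice.
#'
#' @return Named list of grids.
#' @export
default_grids <- function() {
  list(
    KNN = lapply(c(1, 3, 5, 7, 9), function(k) list(k = k)),
    SVM = {
      g <- expand.grid(cost = c(0.1, 1, 10, 100), gamma = c(NA, 0.01, 0.001))
      lapply(seq_len(nrow(g)), function(r) as.list(g[r, ]))
    },
    RF = lapply(c(100, 500), function(nt) list(ntree = nt)),
    GBM = {
      g <- expand.grid(nrounds = c(100, 300), eta = c(0.05, 0.1),
                       max_depth = c(3, 5))
      lapply(seq_len(nrow(g)), function(r) as.list(g[r, ]))
    },
    DNN2 = list(list(hidden = c(1024, 512), dropout = 0.25, epochs = 200,
                     lr = 1e-3, batch = 32)),
    DNN3 = list(list(hidden = c(1024, 512, 256), dropout = 0.25,
                     epochs = 200, lr = 1e-3, batch = 32))
  )
}

#' Reduced hyperparameter grids for quick runs
#'
#' A pruned search (fewer assignments, small networks) used in examples and
#' tests where the full search would be wasteful.
#'
#' @return Named list of grids, same shape as [default_grids()].
#' @export
reduced_grids <- function() {
  list(
    KNN = lapply(c(3, 5), function(k) list(k = k)),
    SVM = list(list(cost = 1, gamma = NA), list(cost = 10, gamma = NA)),
    RF = lapply(c(100, 500), function(nt) list(ntree = nt)),
    GBM = list(list(nrounds = 100, eta = 0.1, max_depth = 3)),
    DNN2 = list(list(hidden = c(32, 16), dropout = 0.25, epochs = 80,
                     lr = 5e-3, batch = 32)),
    DNN3 = list(list(hidden = c(32, 16, 8), dropout = 0.25, epochs = 80,
                     lr = 5e-3, batch = 32))
  )
}

# Fit one learner. X: numeric 0/1 matrix with colnames; y: numeric 0/1
# (classification) or response (regression).
fit_learner <- function(method, X, y, task, params, seed = 1L,
                        importance = FALSE) {
  obj <- with_seed(seed, switch(
    method,
    KNN = list(X = X > 0, y = y, k = params$k),
    SVM = .fit_svm(X, y, task, params),
    RF = {
      yy <- if (task == "classification") factor(y, levels = c(0, 1)) else y
      randomForest::randomForest(x = X, y = yy,
                                 ntree = params$ntree,
                                 mtry = max(1L, floor(sqrt(ncol(X)))),
                                 importance = importance)
    },
    GBM = {
      obj_fun <- if (task == "classification") "binary:logistic"
                 else "reg:squarederror"
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(
        params = list(objective = obj_fun, eta = params$eta,
                      max_depth = params$max_depth, nthread = 1,
                      seed = seed),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
    },
    DNN2 = ,
    DNN3 = do.call(mlp_fit, c(list(X = X, y = y, task = task, seed = seed),
                              params)),
    stop("unknown method: ", method)
  ))
  structure(list(method = method, fit = obj, task = task,
                 features = colnames(X)),
            class = "sweet_learner")
}

.fit_svm <- function(X, y, task, params) {
  gamma <- params$gamma
  if (is.null(gamma) || is.na(gamma)) gamma <- 1 / ncol(X)
  if (task == "classification") {
    fit <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                      kernel = "radial", cost = params$cost, gamma = gamma,
                      scale = FALSE)
    dv <- .svm_decision(fit, X)
    # Platt-style sigmoid on the decision values; orientation is absorbed by
    # the slope sign. Falls back to a step rule under perfect separation.
    platt <- suppressWarnings(
      stats::glm(y ~ dv, family = stats::binomial()))
    list(svm = fit, platt = platt)
  } else {
    list(svm = e1071::svm(x = X, y = y, kernel = "radial",
                          cost = params$cost, gamma = gamma, scale = FALSE))
  }
}

.svm_decision <- function(fit, X) {
  as.numeric(attr(stats::predict(fit, X, decision.values = TRUE),
                  "decision.values"))
}

predict_learner <- function(obj, X) {
  method <- obj$method
  task <- obj$task
  if (method == "KNN") return(.predict_knn(obj$fit, X, task))
  if (method == "SVM") {
    if (task == "classification") {
      dv <- .svm_decision(obj$fit$svm, X)
      p <- stats::predict(obj$fit$platt, newdata = data.frame(dv = dv),
                          type = "response")
      return(as.numeric(p))
    }
    return(as.numeric(stats::predict(obj$fit$svm, X)))
  }
  if (method == "RF") {
    if (task == "classification")
      return(as.numeric(stats::predict(obj$fit, X, type = "prob")[, "1"]))
    return(as.numeric(stats::predict(obj$fit, X)))
  }
  if (method == "GBM")
    return(as.numeric(stats::predict(obj$fit, xgboost::xgb.DMatrix(X))))
  if (is_dnn(method)) return(mlp_predict(obj$fit, X))
  stop("unknown method: ", method)
}

# k nearest neighbors under Jaccard (1 - Tanimoto) distance on bit vectors;
# ties broken by lower training index. Score = mean response of neighbors.
.predict_knn <- function(fit, X, task) {
  sim <- tanimoto_matrix(X > 0, fit$X)
  k <- min(fit$k, ncol(sim))
  apply(sim, 1L, function(s) {
    nn <- order(-s, seq_along(s))[seq_len(k)]
    mean(fit$y[nn])
  })
}

# ---------------------------------------------------------------------------
# Compact multi-layer perceptron (ReLU hidden layers, single output unit,
# inverted dropout, Adam, early stopping on an internal validation slice).
# Binary cross-entropy for classification, mean squared error for regression.

mlp_fit <- function(X, y, task, hidden = c(32, 16), dropout = 0.25,
                    epochs = 100, lr = 1e-3, batch = 32, val_frac = 0.1,
                    patience = 20, l2 = 1e-4, seed = 1L) {
  X <- as.matrix(X) * 1.0
  n <- nrow(X); d <- ncol(X)
  sizes <- c(d, hidden, 1L)
  L <- length(sizes) - 1L

  set.seed(seed)
  W <- lapply(seq_len(L), function(l)
    matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1L]))
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1L]))

  n_val <- floor(val_frac * n)
  val_idx <- if (n_val >= 2L) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]

  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0

  forward <- function(W, b, A, masks = NULL) {
    acts <- list(A)
    for (l in seq_len(L - 1L)) {
      Z <- sweep(acts[[l]] %*% W[[l]], 2L, b[[l]], "+")
      A1 <- pmax(Z, 0)
      if (!is.null(masks)) A1 <- A1 * masks[[l]]
      acts[[l + 1L]] <- A1
    }
    z <- sweep(acts[[L]] %*% W[[L]], 2L, b[[L]], "+")
    list(acts = acts, z = as.numeric(z))
  }
  loss_of <- function(z, yy) {
    if (task == "classification") {
      p <- 1 / (1 + exp(-z))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -mean(yy * log(p) + (1 - yy) * log(1 - p))
    } else mean((z - yy)^2)
  }

  best <- list(W = W, b = b, loss = Inf)
  stale <- 0L
  ntr <- nrow(Xtr)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(ntr)
    starts <- seq(1L, ntr, by = batch)
    for (s in starts) {
      rows <- ord[s:min(s + batch - 1L, ntr)]
      A <- Xtr[rows, , drop = FALSE]
      yy <- ytr[rows]
      B <- length(rows)
      masks <- if (dropout > 0) lapply(seq_len(L - 1L), function(l)
        matrix(stats::rbinom(B * sizes[l + 1L], 1L, 1 - dropout),
               B, sizes[l + 1L]) / (1 - dropout)) else NULL
      fw <- forward(W, b, A, masks)
      z <- fw$z
      dz <- if (task == "classification") {
        (1 / (1 + exp(-z)) - yy) / B
      } else 2 * (z - yy) / B
      dz <- matrix(dz, ncol = 1L)
      gW <- vector("list", L); gb <- vector("list", L)
      delta <- dz
      for (l in L:1) {
        gW[[l]] <- t(fw$acts[[l]]) %*% delta + l2 * W[[l]]
        gb[[l]] <- colSums(delta)
        if (l > 1L) {
          dA <- delta %*% t(W[[l]])
          act <- fw$acts[[l]]
          dA <- dA * (act > 0)
          if (!is.null(masks)) dA <- dA * masks[[l - 1L]]
          delta <- dA
        }
      }
      t_step <- t_step + 1
      corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) /
          (sqrt(vW[[l]] / corr2) + eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) /
          (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    if (length(val_idx)) {
      vloss <- loss_of(forward(W, b, Xval)$z, yval)
      if (vloss < best$loss - 1e-6) {
        best <- list(W = W, b = b, loss = vloss)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    } else {
      best <- list(W = W, b = b, loss = NA_real_)
    }
  }
  list(W = best$W, b = best$b, task = task, sizes = sizes)
}

mlp_predict <- function(fit, X) {
  A <- as.matrix(X) * 1.0
  L <- length(fit$W)
  for (l in seq_len(L - 1L)) {
    A <- pmax(sweep(A %*% fit$W[[l]], 2L, fit$b[[l]], "+"), 0)
  }
  z <- as.numeric(sweep(A %*% fit$W[[L]], 2L, fit$b[[L]], "+"))
  if (fit$task == "classification") 1 / (1 + exp(-z)) else z
}
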