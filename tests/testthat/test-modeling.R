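# Grid enumeration, feature ranking/selection, CV training, Y-randomization.

# small planted feature matrix: a motif block (bits 5-9, mimicking the
# several environments a substructure sets in a real fingerprint)
# determines the class, plus noise bits
planted_X <- function(n = 120L, p = 32L, seed = 1L, flip = 0) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1L, 0.3), n, p)
  colnames(X) <- sprintf("b%04d", seq_len(p))
  y <- X[, 5L]
  for (b in 6:9) X[, b] <- y
  if (flip > 0) {
    fl <- runif(n) < flip
    y <- ifelse(fl, 1L - y, y)
  }
  attr(X, "config") <- fp_config(2, p)
  list(X = X, y = as.integer(y))
}

test_that("grid enumeration honors the method-scheme restriction", {
  cfg <- task_config("classification")
  g <- enumerate_grid(cfg)
  expect_equal(nrow(g), 1312L)
  expect_equal(sum(g$feature_option == "full"), 328L)
  expect_equal(sum(g$feature_option != "full"), 984L)
  expect_true(all(g$scheme_id[g$method %in% c("DNN2", "DNN3")] <= 3L))
  # deterministic ordering: first block is the first fingerprint
  expect_equal(g$fingerprint[1L], names(cfg$fingerprints)[1L])

  g2 <- enumerate_grid(task_config("classification", methods = "RF",
                                   feature_options = "full"))
  expect_equal(nrow(g2), 76L)

  g3 <- enumerate_grid(task_config(
    "classification", methods = "KNN", feature_options = "full",
    fingerprints = standard_fingerprints()["ECFP4-1024"], n_schemes = 1L))
  expect_equal(nrow(g3), 1L)

  expect_error(task_config("classification", methods = character(0)),
               "empty")
})

test_that("feature ranking recovers planted informative bits", {
  set.seed(4)
  n <- 150L
  X <- matrix(rbinom(n * 64, 1, 0.3), n, 64)
  colnames(X) <- sprintf("b%04d", 1:64)
  attr(X, "config") <- fp_config(2, 64)
  y <- as.integer(X[, 7] | X[, 13])
  labels <- ifelse(y == 1, "sweet", "non-sweet")
  splits <- lapply(1:3, function(s) split_classification(labels,
                                                         scheme_id = s))
  rk <- rank_features(X, y, splits, "classification", ntree = 200)
  expect_true(all(c(7L, 13L) %in% rk$ranked[1:10]))
  expect_setequal(rk$ranked, 1:64)

  expect_error(rank_features(X * 0L, y, splits, "classification"),
               "all-zero")
})

test_that("top-k selection is a nested prefix with index tie-breaks", {
  rk <- feature_ranking(rep(1, 1024))
  expect_equal(select_top_k(rk, 10L), 1:10)       # ties -> identity order
  expect_equal(select_top_k(rk, 1024L), 1:1024)
  expect_error(select_top_k(rk, 2048L), "exceeds")

  rk2 <- feature_ranking(runif(512))
  t128 <- select_top_k(rk2, 128L)
  t256 <- select_top_k(rk2, 256L)
  t512 <- select_top_k(rk2, 512L)
  expect_length(unique(t128), 128L)
  expect_true(all(t128 %in% t256) && all(t256 %in% t512))
  expect_equal(t128, t256[1:128])
})

test_that("cross-validated training learns a separable rule and is
           deterministic", {
  pl <- planted_X(seed = 2)
  labels <- ifelse(pl$y == 1, "sweet", "non-sweet")
  sp <- split_classification(labels, scheme_id = 1L)
  for (meth in c("KNN", "RF", "SVM", "GBM")) {
    m <- train_cv(meth, pl$X, pl$y, sp, "classification",
                  grid = reduced_grids()[[meth]])
    expect_gte(m$cv_metrics$f1, 0.95)
    m <- evaluate_test(m, pl$X, pl$y, sp)
    expect_gte(m$test_metrics$f1, 0.9)
    expect_lte(abs(m$test_metrics$f1 - m$cv_metrics$f1), 0.1)
    # rerun: identical winner and metrics
    m2 <- evaluate_test(train_cv(meth, pl$X, pl$y, sp, "classification",
                                 grid = reduced_grids()[[meth]]),
                        pl$X, pl$y, sp)
    expect_identical(m$best_params, m2$best_params)
    expect_identical(m$cv_metrics, m2$cv_metrics)
    expect_identical(m$test_metrics, m2$test_metrics)
  }
})

test_that("the small network learns the planted rule", {
  pl <- planted_X(n = 160L, seed = 6)
  labels <- ifelse(pl$y == 1, "sweet", "non-sweet")
  sp <- split_classification(labels, scheme_id = 1L)
  m <- train_cv("DNN2", pl$X, pl$y, sp, "classification",
                grid = reduced_grids()$DNN2)
  m <- evaluate_test(m, pl$X, pl$y, sp)
  expect_gte(m$test_metrics$f1, 0.9)
})

test_that("pure-noise labels stay at the permutation chance level", {
  set.seed(9)
  n <- 100L
  X <- matrix(rbinom(n * 32, 1, 0.3), n, 32)
  colnames(X) <- sprintf("b%04d", 1:32)
  attr(X, "config") <- fp_config(2, 32)
  y <- rep(c(0L, 1L), n / 2)[sample.int(n)]
  labels <- ifelse(y == 1, "sweet", "non-sweet")
  sp <- split_classification(labels, scheme_id = 3L)
  m <- train_cv("KNN", X, y, sp, "classification",
                grid = list(list(k = 5)))
  # permutation oracle for the chance-level F1 of a coin-flip classifier
  null_f1 <- replicate(300, {
    pred <- sample(y[sp$cv])
    cc <- confusion_counts(y[sp$cv], pred, positive = 1L)
    f <- classification_metrics(cc)$f1
    if (is.na(f)) 0 else f
  })
  expect_lte(abs(m$cv_metrics$f1 - mean(null_f1)), 3 * sd(null_f1) + 1e-8)
})

test_that("regression training recovers a linear-in-bits response", {
  set.seed(12)
  n <- 140L
  X <- matrix(rbinom(n * 32, 1, 0.4), n, 32)
  colnames(X) <- sprintf("b%04d", 1:32)
  attr(X, "config") <- fp_config(2, 32)
  y <- 0.5 + X[, 3] + 0.7 * X[, 11] + 0.5 * X[, 20] + rnorm(n, sd = 0.1)
  sp <- split_regression(y, scheme_id = 1L)
  m <- evaluate_test(train_cv("GBM", X, y, sp, "regression",
                              grid = reduced_grids()$GBM),
                     X, y, sp)
  expect_gte(m$test_metrics$r2, 0.8)
})

test_that("Y-randomization collapses planted performance; identity control
           matches the real run", {
  pl <- planted_X(seed = 21, flip = 0.05)
  labels <- ifelse(pl$y == 1, "sweet", "non-sweet")
  sp <- split_classification(labels, scheme_id = 2L)
  grid <- list(list(ntree = 100))
  real <- evaluate_test(train_cv("RF", pl$X, pl$y, sp, "classification",
                                 grid = grid), pl$X, pl$y, sp)
  shuf <- y_randomize("RF", pl$X, pl$y, sp, "classification", grid = grid)
  expect_lt(shuf$test_metrics$f1, real$test_metrics$f1)

  ident <- y_randomize("RF", pl$X, pl$y, sp, "classification", grid = grid,
                       permutation = seq_along(sp$cv))
  expect_identical(ident$test_metrics, real$test_metrics)
})

test_that("fold stratification errors when a class cannot be represented", {
  y <- c(rep(0L, 40), 1L)  # a single positive cannot reach every fold
  expect_error(sweetqsar:::.make_folds(y, "classification", 5L, 1L),
               "missing a class")
})
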