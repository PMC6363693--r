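# The top-level fitting interface and the end-to-end pipeline runner.

small_cls_config <- function() {
  task_config("classification",
              fingerprints = standard_fingerprints()["ECFP4-1024"],
              feature_options = "full",
              methods = c("KNN", "RF"),
              n_schemes = 2L, n_schemes_dnn = 2L,
              grids = reduced_grids())
}

test_that("sweet_qsar fits, summarizes and predicts on a small dataset", {
  d <- planted_classification_dataset(n = 80, seed = 19, n_atoms = c(6, 10))
  fit <- sweet_qsar(d$mols, label = d$label, config = small_cls_config())
  expect_s3_class(fit, "sweet_qsar")
  expect_length(fit$models, 4L)          # 1 fp x 1 fo x 2 methods x 2 schemes
  expect_length(fit$average_models, 2L)
  expect_true(all(c("CM01", "CM02") %in% names(fit$consensus)))

  mm <- model_manifest(fit)
  expect_equal(nrow(mm), 4L)
  expect_true(all(c("cv_f1", "test_f1", "test_mcc") %in% names(mm)))

  expect_output(print(fit), "Consensus QSAR fit")

  pred <- predict(fit, d$mols[1:6], consensus = "CM01")
  expect_equal(nrow(pred), 6L)
  expect_true(all(pred$label %in% c("sweet", "non-sweet")))
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_true(all(c("avg_similarity", "in_domain", "element_ok") %in%
                    names(pred)))

  # compounds failing the element filter are flagged but still predicted
  alien <- mk_mol("alien", c("C", "Na"), 1, 2, nh = c(3L, 0L))
  expect_warning(pa <- predict(fit, list(alien), consensus = "CM01"),
                 "element filter")
  expect_equal(nrow(pa), 1L)
  expect_false(pa$element_ok)
})

test_that("run_pipeline produces the full artifact set from a MOL2 manifest", {
  d <- planted_classification_dataset(n = 60, seed = 29, n_atoms = c(6, 10))
  dir <- tempfile("run")
  dir.create(dir)
  struct_dir <- file.path(dir, "structures")
  dir.create(struct_dir)
  paths <- vapply(seq_along(d$mols), function(k) {
    p <- file.path(struct_dir, sprintf("m%03d.mol2", k))
    write_mol2(d$mols[[k]], p)
    p
  }, character(1))
  man <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(id = vapply(d$mols, function(m) m$id,
                                          character(1)),
                              path = paths, label = d$label),
                   man, row.names = FALSE)
  out <- file.path(dir, "out")
  fit <- run_pipeline(man, out, config = small_cls_config(),
                      verbose = FALSE)
  expect_s3_class(fit, "sweet_qsar")
  for (f in c("models.csv", "average_models.csv", "consensus.json",
              "splits.json", "ad_histogram.csv", "run.log"))
    expect_true(file.exists(file.path(out, f)))
  models_csv <- utils::read.csv(file.path(out, "models.csv"))
  expect_equal(nrow(models_csv), 4L)
  splits <- jsonlite::read_json(file.path(out, "splits.json"))
  expect_length(splits, 2L)

  # empty manifest errors immediately
  empty <- file.path(dir, "empty.csv")
  utils::write.csv(data.frame(id = character(), path = character(),
                              label = character()), empty,
                   row.names = FALSE)
  expect_error(run_pipeline(empty, out), "empty manifest")
})

test_that("training compounds are in domain; an alien scaffold is not", {
  d <- planted_classification_dataset(n = 80, seed = 19, n_atoms = c(6, 10))
  fit <- sweet_qsar(d$mols, label = d$label, config = small_cls_config())
  pred <- predict(fit, d$mols[1:10])
  expect_true(all(pred$in_domain))

  # structurally alien probe: long silicon chain, disjoint from the C/N/O
  # training chemistry
  si <- mk_mol("si_chain", rep("Si", 8), 1:7, 2:8, nh = c(3L, rep(2L, 6), 3L))
  psi <- predict(fit, list(si))
  expect_false(psi$in_domain)
  expect_lt(psi$avg_similarity, 0.1)
})

test_that("rerunning the fit reproduces metrics bit-identically", {
  d <- planted_classification_dataset(n = 60, seed = 31, n_atoms = c(6, 10))
  cfg <- task_config("classification",
                     fingerprints = standard_fingerprints()["ECFP4-1024"],
                     feature_options = c("full", "top128"),
                     methods = "RF", n_schemes = 2L,
                     grids = reduced_grids())
  f1 <- sweet_qsar(d$mols, label = d$label, config = cfg)
  f2 <- sweet_qsar(d$mols, label = d$label, config = cfg)
  expect_identical(model_manifest(f1), model_manifest(f2))
})
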