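# Lightweight trained-model stubs (for combinatorics tests that do not need
# real learners) and cached full-scale pipeline fits shared by the
# acceptance tests.

stub_model <- function(method, fingerprint, feature_option, scheme_id,
                       cv_f1 = 0.8, test_f1 = 0.8, task = "classification") {
  key <- if (task == "classification") "f1" else "r2"
  cv <- list(); te <- list()
  cv[[key]] <- cv_f1; te[[key]] <- test_f1
  structure(list(method = method, fingerprint = fingerprint,
                 feature_option = feature_option, scheme_id = scheme_id,
                 task = task, cv_metrics = cv, test_metrics = te,
                 feature_idx = 1L, learner = NULL),
            class = "sweet_model")
}

stub_grid_models <- function(cfg, cv_f1 = NULL) {
  g <- enumerate_grid(cfg)
  lapply(seq_len(nrow(g)), function(r) {
    f1 <- if (is.null(cv_f1)) 0.8 else cv_f1(g[r, ])
    stub_model(g$method[r], g$fingerprint[r], g$feature_option[r],
               g$scheme_id[r], cv_f1 = f1, test_f1 = f1,
               task = cfg$task)
  })
}

# --- cached pipeline fits under the planted study conditions --------------

.acceptance_cache <- new.env(parent = emptyenv())

# classification: n = 400, flip noise 0.05, 3 schemes, reduced grid
acceptance_cls <- function() {
  if (is.null(.acceptance_cache$cls)) {
    d <- planted_classification_dataset()
    cfg <- task_config("classification",
                       fingerprints = standard_fingerprints()["ECFP4-1024"],
                       feature_options = c("full", "top128"),
                       methods = c("KNN", "RF"),
                       n_schemes = 3L,
                       grids = reduced_grids())
    fit <- sweet_qsar(d$mols, label = d$label, config = cfg)
    .acceptance_cache$cls <- list(data = d, fit = fit)
  }
  .acceptance_cache$cls
}

# regression: n = 352, noise sigma 0.1, 3 schemes, reduced grid
acceptance_reg <- function() {
  if (is.null(.acceptance_cache$reg)) {
    d <- planted_regression_dataset()
    cfg <- task_config("regression",
                       fingerprints = standard_fingerprints()["ECFP4-1024"],
                       feature_options = "full",
                       methods = c("RF", "GBM"),
                       n_schemes = 3L,
                       grids = reduced_grids())
    fit <- sweet_qsar(d$mols, rs = d$rs, config = cfg)
    .acceptance_cache$reg <- list(data = d, fit = fit)
  }
  .acceptance_cache$reg
}

# Pairwise Tanimoto similarities from an independent reference fingerprint
# implementation (RDKit Morgan, via the python interpreter), in the order
# (2,1), (3,1), ..., i.e. all pairs i > j by column.
rdkit_tanimoto_pairs <- function(mols, radius = 2L, n_bits = 2048L) {
  sdf <- tempfile(fileext = ".sdf")
  write_sdf(mols, sdf)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from rdkit import Chem, RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "from rdkit.Chem import AllChem, DataStructs",
    "radius, nbits = int(sys.argv[2]), int(sys.argv[3])",
    "mols = [m for m in Chem.SDMolSupplier(sys.argv[1])]",
    "assert all(m is not None for m in mols)",
    "fps = [AllChem.GetMorganFingerprintAsBitVect(m, radius, nBits=nbits)",
    "       for m in mols]",
    "out = []",
    "for i in range(len(fps)):",
    "    for j in range(i + 1, len(fps)):",
    "        out.append(str(DataStructs.TanimotoSimilarity(fps[i], fps[j])))",
    "print(chr(10).join(out))"), script)
  res <- system2("python", c(script, sdf, radius, n_bits),
                 stdout = TRUE, stderr = FALSE)
  as.numeric(res)
}
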