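# Dataset curation and multi-scheme data splitting.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

round_half_up <- function(x) floor(x + 0.5)

# Structure identity key for dedup/conflict detection: molecular formula plus
# the 2048-bit ECFP6 bit string. Cheap, and collisions are negligible at
# dataset scale.
structure_key <- function(mol) {
  fp <- ecfp(mol, fp_config(3L, 2048L))
  paste0(molecular_formula(mol), "|",
         paste(which(fp$bits), collapse = ","))
}

#' Curate a taste-labeled compound collection
#'
#' Applies the four curation rules in order: (1) keep only the largest
#' fragment of disconnected structures; (2) keep only compounds made of
#' C, H, O, N, S, P, Si, F, Cl, Br, I; (3) classification: drop every copy of
#' a structure annotated with different taste modalities in different
#' sources; (4) deduplicate identical structures across sources, keeping the
#' first. For regression datasets, records whose relative sweetness was not
#' measured against the 5\% w/v sucrose reference are dropped and the
#' response is `y = log10(RS)`.
#'
#' @param mols List of [molgraph()] objects.
#' @param label Character vector (`"sweet"` / `"non-sweet"`) for
#'   classification; `NULL` for regression.
#' @param rs Positive numeric relative-sweetness values for regression;
#'   `NULL` for classification.
#' @param source Optional character vector of source names.
#' @param sucrose_ref Logical vector: was RS measured against 5\% sucrose?
#'   Defaults to all `TRUE`.
#' @return A list of class `sweet_dataset` with elements `mols`, `task`,
#'   `label` or `rs`/`y`, `source`, and `key` (structure identity keys).
#' @export
curate_compounds <- function(mols, label = NULL, rs = NULL, source = NULL,
                             sucrose_ref = NULL) {
  if (is.null(label) == is.null(rs))
    stop("provide exactly one of 'label' (classification) or 'rs' (regression)")
  task <- if (is.null(rs)) "classification" else "regression"
  n <- length(mols)
  if (is.null(source)) source <- rep("source1", n)
  if (task == "classification") {
    label <- as.character(label)
    if (!all(label %in% c("sweet", "non-sweet")))
      stop("labels must be 'sweet' or 'non-sweet'")
    stopifnot(length(label) == n)
  } else {
    rs <- as.numeric(rs)
    stopifnot(length(rs) == n)
    bad <- which(!is.finite(rs) | rs <= 0)
    if (length(bad))
      stop("RS must be positive; offending record(s): ",
           paste(vapply(mols[bad], function(m) m$id, character(1)),
                 collapse = ", "))
    if (is.null(sucrose_ref)) sucrose_ref <- rep(TRUE, n)
  }

  # rules (1) and (2)
  mols <- lapply(mols, keep_largest_fragment)
  keep <- vapply(mols, element_filter, logical(1))
  # regression rule (4): sucrose reference
  if (task == "regression") keep <- keep & sucrose_ref
  idx <- which(keep)

  keys <- vapply(mols[idx], structure_key, character(1))

  if (task == "classification") {
    # rule (3): same structure, different taste modality -> drop all copies
    lab <- label[idx]
    conflict <- vapply(keys, function(k) {
      length(unique(lab[keys == k])) > 1L
    }, logical(1))
    idx <- idx[!conflict]
    keys <- keys[!conflict]
  }
  # rule (4)/(3): cross-source dedup, keep first occurrence
  first <- !duplicated(keys)
  idx <- idx[first]
  keys <- keys[first]

  out <- list(mols = mols[idx], task = task, source = source[idx], key = keys,
              ids = vapply(mols[idx], function(m) m$id, character(1)))
  if (task == "classification") {
    out$label <- label[idx]
  } else {
    out$rs <- rs[idx]
    out$y <- log10(rs[idx])
  }
  structure(out, class = "sweet_dataset")
}

#' @export
print.sweet_dataset <- function(x, ...) {
  if (x$task == "classification") {
    cat(sprintf("<sweet_dataset classification: %d compounds (%d sweet, %d non-sweet)>\n",
                length(x$mols), sum(x$label == "sweet"),
                sum(x$label == "non-sweet")))
  } else {
    cat(sprintf("<sweet_dataset regression: %d compounds, log10RS in [%.2f, %.2f]>\n",
                length(x$mols), min(x$y), max(x$y)))
  }
  invisible(x)
}

new_split_scheme <- function(scheme_id, cv, test, n) {
  stopifnot(length(intersect(cv, test)) == 0L,
            setequal(c(cv, test), seq_len(n)))
  structure(list(scheme_id = as.integer(scheme_id),
                 seed = as.integer(scheme_id),
                 cv = sort(as.integer(cv)), test = sort(as.integer(test))),
            class = "split_scheme")
}

#' @export
print.split_scheme <- function(x, ...) {
  cat(sprintf("<split_scheme %d: %d CV / %d test>\n", x$scheme_id,
              length(x$cv), length(x$test)))
  invisible(x)
}

#' Class-stratified random split for classification
#'
#' Samples `round(fraction * n_c)` compounds per class (round half up)
#' without replacement into the cross-validation partition (Dataset-CV); the
#' remainder forms the hold-out test set (Dataset-Test). The scheme id doubles
#' as RNG seed so every splitting scheme is reproducible.
#'
#' @param labels Character vector of class labels.
#' @param fraction CV fraction per class, default 0.8.
#' @param scheme_id Integer scheme id / seed.
#' @return A `split_scheme` with index sets `cv` and `test`.
#' @export
split_classification <- function(labels, fraction = 0.8, scheme_id = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  cv <- with_seed(scheme_id, {
    unlist(lapply(unique(labels), function(cl) {
      pool <- which(labels == cl)
      pool[sample.int(length(pool), round_half_up(fraction * length(pool)))]
    }), use.names = FALSE)
  })
  new_split_scheme(scheme_id, cv, setdiff(seq_along(labels), cv),
                   length(labels))
}

#' Response-stratified split for regression
#'
#' Sorts the dataset ascending by `y` (ties broken by id), partitions it into
#' consecutive blocks of five (a final partial block included) and draws
#' exactly one compound uniformly at random per block into the hold-out test
#' set, yielding an evenly stratified test response distribution (a 352
#' compound set gives 71 test / 281 CV compounds).
#'
#' @param y Numeric response vector (log10 relative sweetness).
#' @param ids Optional ids used to break ties in the sort.
#' @param scheme_id Integer scheme id / seed.
#' @return A `split_scheme`.
#' @export
split_regression <- function(y, ids = NULL, scheme_id = 1L) {
  if (!length(y)) stop("empty dataset")
  if (!all(is.finite(y))) stop("all y values must be finite")
  if (is.null(ids)) ids <- as.character(seq_along(y))
  ord <- order(y, ids)
  blocks <- split(ord, ceiling(seq_along(ord) / 5))
  test <- with_seed(scheme_id, {
    vapply(blocks, function(b) if (length(b) == 1L) b else
      b[sample.int(length(b), 1L)], integer(1))
  })
  new_split_scheme(scheme_id, setdiff(seq_along(y), test), test, length(y))
}
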