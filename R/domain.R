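# Applicability domain by average Tanimoto similarity to the five nearest
# training compounds (2048-bit ECFP6 in the standard protocol).

#' Average similarity to the k nearest reference compounds
#'
#' Retrieves the `k` most similar reference (Dataset-CV) compounds by
#' Tanimoto similarity (ties broken by lower reference index) and averages
#' their similarities. A query that is itself a member of the reference set
#' (matched by id) is excluded from its own neighbor list.
#'
#' @param query An [ecfp()] fingerprint or 0/1 vector.
#' @param reference List of fingerprints or a 0/1 matrix (rownames = ids).
#' @param k Number of neighbors (5).
#' @param query_id Id used for self-exclusion (taken from `query` if it is an
#'   `ecfp` object).
#' @param threshold Domain threshold used for the `in_domain` flag (0.1).
#' @return Object of class `ad_result` with `neighbors`, `neighbor_ids`,
#'   `similarities` (descending), `average`, `in_domain`.
#' @export
average_similarity <- function(query, reference, k = 5L, query_id = NULL,
                               threshold = 0.1) {
  if (inherits(query, "ecfp")) {
    if (is.null(query_id)) query_id <- query$id
    qv <- query$bits
  } else qv <- as.logical(query)
  if (is.list(reference)) {
    R <- do.call(rbind, lapply(reference, function(f)
      if (inherits(f, "ecfp")) as.integer(f$bits) else as.integer(f)))
    rownames(R) <- vapply(seq_along(reference), function(i) {
      f <- reference[[i]]
      if (inherits(f, "ecfp") && !is.null(f$id)) f$id else as.character(i)
    }, character(1))
  } else R <- reference
  ref_ids <- rownames(R)
  if (is.null(ref_ids)) ref_ids <- as.character(seq_len(nrow(R)))
  keep <- if (!is.null(query_id)) which(ref_ids != query_id)
          else seq_len(nrow(R))
  if (length(keep) < k)
    stop("reference set has fewer than k = ", k,
         " compounds after self-exclusion")
  sims <- as.numeric(tanimoto_matrix(matrix(as.numeric(qv), nrow = 1L),
                                     R[keep, , drop = FALSE]))
  ord <- order(-sims, seq_along(sims))[seq_len(k)]
  res <- structure(list(query_id = query_id,
                        neighbors = keep[ord],
                        neighbor_ids = ref_ids[keep[ord]],
                        similarities = sims[ord],
                        average = mean(sims[ord]),
                        threshold = threshold),
                   class = "ad_result")
  res$in_domain <- in_domain(res, threshold)
  res
}

#' @export
print.ad_result <- function(x, ...) {
  cat(sprintf("<ad_result %s: average similarity %.3f (%s domain)>\n",
              if (is.null(x$query_id)) "?" else x$query_id, x$average,
              if (x$in_domain) "inside" else "outside"))
  invisible(x)
}

#' Applicability-domain decision
#'
#' A compound is inside the domain iff its average similarity is strictly
#' larger than the threshold; an average of exactly 0.1 is outside.
#'
#' @param r An [average_similarity()] result (or a bare average value).
#' @param threshold Similarity threshold (0.1).
#' @return Logical.
#' @export
in_domain <- function(r, threshold = 0.1) {
  avg <- if (inherits(r, "ad_result")) r$average else as.numeric(r)
  avg > threshold
}

# Average similarity of each row of Q to its k nearest rows of R.
# exclude_self drops exact row correspondence (Q == R case).
avg_knn_similarity <- function(Q, R, k = 5L, exclude_self = FALSE) {
  sim <- tanimoto_matrix(Q, R)
  if (exclude_self) diag(sim) <- -Inf
  apply(sim, 1L, function(s) {
    mean(sort(s, decreasing = TRUE)[seq_len(k)])
  })
}

#' Average-similarity histograms for Dataset-CV and Dataset-Test
#'
#' Computes each test compound's average similarity to its five nearest
#' Dataset-CV neighbors, and each CV compound's average similarity to its
#' five nearest other CV compounds (self-excluded), then bins both on [0, 1].
#' These histograms motivate the domain threshold.
#'
#' @param X Full 0/1 fingerprint matrix (2048-bit ECFP6 in the standard
#'   protocol).
#' @param split A `split_scheme`.
#' @param k Neighbors (5).
#' @param bin_width Histogram bin width (0.05).
#' @return Object of class `ad_histogram`: `breaks`, `cv_counts`,
#'   `test_counts`, `cv_values`, `test_values`.
#' @export
ad_histogram <- function(X, split, k = 5L, bin_width = 0.05) {
  if (!length(split$cv) || !length(split$test))
    stop("empty partition")
  Xcv <- X[split$cv, , drop = FALSE]
  Xte <- X[split$test, , drop = FALSE]
  cv_vals <- avg_knn_similarity(Xcv, Xcv, k = k, exclude_self = TRUE)
  te_vals <- avg_knn_similarity(Xte, Xcv, k = k)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- function(v) graphics::hist(v, breaks = breaks, plot = FALSE,
                                  include.lowest = TRUE, right = TRUE)$counts
  structure(list(breaks = breaks, cv_counts = h(cv_vals),
                 test_counts = h(te_vals), cv_values = cv_vals,
                 test_values = te_vals, k = k),
            class = "ad_histogram")
}

#' @export
print.ad_histogram <- function(x, ...) {
  cat(sprintf("<ad_histogram: %d CV / %d test compounds, %d bins>\n",
              length(x$cv_values), length(x$test_values),
              length(x$breaks) - 1L))
  invisible(x)
}

#' @export
plot.ad_histogram <- function(x, ...) {
  mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  graphics::barplot(rbind(x$cv_counts, x$test_counts), beside = TRUE,
                    names.arg = sprintf("%.2f", mids),
                    col = c("grey30", "grey70"), las = 2,
                    xlab = "average similarity to 5 nearest CV compounds",
                    ylab = "count", ...)
  graphics::legend("topright", legend = c("Dataset-CV", "Dataset-Test"),
                   fill = c("grey30", "grey70"), bty = "n")
  invisible(x)
}
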