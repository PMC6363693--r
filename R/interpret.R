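# Model interpretation: feature-importance reports and bit-to-substructure
# attribution via fingerprint provenance.

#' Report the most important fingerprint bits
#'
#' For the `top_n` bits of a full-feature ranking, reports the averaged
#' importance, how many positive-class and negative-class compounds (or, for
#' regression, the mean response of bit-set versus bit-unset compounds) set
#' the bit, and up to three example compound ids whose fingerprints can be
#' inspected with [bit_substructure()].
#'
#' @param ranking A [feature_ranking()] built on the full feature set.
#' @param X Full 0/1 fingerprint matrix (rownames = compound ids).
#' @param y Numeric response (0/1 for classification).
#' @param task `"classification"` or `"regression"`.
#' @param top_n Number of bits to report (> 0).
#' @return Data frame of class `bit_report`: `bit`, `importance`, and either
#'   `n_pos`/`n_neg` or `mean_y_set`/`mean_y_unset`, plus `examples`.
#' @export
importance_report <- function(ranking, X, y,
                              task = c("classification", "regression"),
                              top_n = 10L) {
  task <- match.arg(task)
  if (top_n <= 0L) stop("top_n must be positive")
  top_n <- min(top_n, length(ranking$ranked))
  bits <- ranking$ranked[seq_len(top_n)]
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  rows <- lapply(bits, function(bit) {
    set <- X[, bit] > 0
    ex <- utils::head(ids[set], 3L)
    base <- data.frame(bit = bit, importance = ranking$importance[bit],
                       stringsAsFactors = FALSE)
    if (task == "classification") {
      base$n_pos <- sum(set & y == 1)
      base$n_neg <- sum(set & y == 0)
    } else {
      base$mean_y_set <- if (any(set)) mean(y[set]) else NA_real_
      base$mean_y_unset <- if (any(!set)) mean(y[!set]) else NA_real_
    }
    base$examples <- paste(ex, collapse = ";")
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bit_report", "data.frame")
  out
}

#' Per-atom attribution of fingerprint-bit importances
#'
#' Each atom receives the summed importance of the set bits whose
#' substructure environments cover it (one contribution per environment), so
#' the total over atoms equals the sum over set-bit environments of
#' importance times environment size.
#'
#' @param ranking A [feature_ranking()] for the fingerprint configuration of
#'   `fp`.
#' @param fp An [ecfp()] fingerprint with provenance.
#' @return Numeric vector of per-atom scores (length = heavy-atom count).
#' @export
attribute_compound <- function(ranking, fp) {
  n_atoms <- max(c(1L, unlist(lapply(fp$provenance, function(envs)
    lapply(envs, function(e) e$atoms)))))
  score <- numeric(n_atoms)
  for (key in names(fp$provenance)) {
    bit <- as.integer(key)
    imp <- ranking$importance[bit]
    if (is.na(imp) || imp == 0) next
    for (e in fp$provenance[[key]]) {
      score[e$atoms] <- score[e$atoms] + imp
    }
  }
  score
}
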