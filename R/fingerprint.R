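# Native extended-connectivity fingerprint (ECFP) engine with per-bit
# substructure provenance.
#
# The algorithm is the classic circular-fingerprint scheme: each heavy atom
# starts from an invariant hash of its local properties; for r = 1..radius
# every atom's identifier is re-hashed together with its bond-ordered
# neighbor identifiers; environments covering an already-seen atom set are
# discarded; surviving 32-bit identifiers fold onto the bit vector modulo
# its length. Hashing uses 32-bit FNV-1a over the little-endian byte
# serialization of the integer tuple, so fingerprints are reproducible
# across platforms without any framework dependence.

.FNV_OFFSET <- 2166136261
.FNV_PRIME <- 16777619
.TWO32 <- 4294967296

# 32-bit FNV-1a over a vector of byte values (0..255), arithmetic on doubles.
fnv1a32 <- function(bytes) {
  h <- .FNV_OFFSET
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * .FNV_PRIME) %% 65536) * 65536 + lo * .FNV_PRIME) %% .TWO32
  }
  h
}

# Serialize non-negative 32-bit integers (as doubles) to little-endian bytes.
.le_bytes <- function(vals) {
  out <- numeric(4L * length(vals))
  for (k in seq_along(vals)) {
    v <- vals[k]
    out[4L * k - 3L] <- v %% 256; v <- v %/% 256
    out[4L * k - 2L] <- v %% 256; v <- v %/% 256
    out[4L * k - 1L] <- v %% 256; v <- v %/% 256
    out[4L * k] <- v %% 256
  }
  out
}

hash_tuple <- function(vals) fnv1a32(.le_bytes(vals))

.BOND_CODE <- c(single = 1, double = 2, triple = 3, aromatic = 4)

#' Fingerprint configuration
#'
#' @param radius Neighborhood radius: 2 for ECFP4, 3 for ECFP6 (the suffix is
#'   the diameter).
#' @param n_bits Folded length, a power of two (1024 or 2048 in the standard
#'   descriptor set).
#' @return An object of class `fp_config`.
#' @export
fp_config <- function(radius = 2L, n_bits = 1024L) {
  radius <- as.integer(radius); n_bits <- as.integer(n_bits)
  if (radius < 0L) stop("radius must be >= 0")
  if (n_bits < 2L || bitwAnd(n_bits, n_bits - 1L) != 0L)
    stop("n_bits must be a power of two")
  structure(list(radius = radius, n_bits = n_bits), class = "fp_config")
}

#' @export
print.fp_config <- function(x, ...) {
  cat(sprintf("<fp_config ECFP%d, %d bits>\n", 2L * x$radius, x$n_bits))
  invisible(x)
}

fp_label <- function(config) {
  sprintf("ECFP%d-%d", 2L * config$radius, config$n_bits)
}

# The four descriptor configurations of the standard protocol.
#' Standard fingerprint axis: ECFP4/ECFP6 at 1024/2048 bits
#' @return A named list of four [fp_config()] objects.
#' @export
standard_fingerprints <- function() {
  cfgs <- list(fp_config(2L, 1024L), fp_config(2L, 2048L),
               fp_config(3L, 1024L), fp_config(3L, 2048L))
  names(cfgs) <- vapply(cfgs, fp_label, character(1))
  cfgs
}

#' Initial atom invariants for the ECFP iteration
#'
#' One 32-bit identifier per heavy atom, a deterministic FNV-1a hash of the
#' tuple (atomic number, heavy-neighbor count, attached-H count, formal
#' charge, in-ring flag, aromatic flag). Symmetry-equivalent atoms (e.g. the
#' six carbons of benzene) share one invariant.
#'
#' @param mol A [molgraph()].
#' @return Numeric vector of identifiers in `[0, 2^32)`.
#' @export
initial_invariants <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(numeric(0))
  adj <- adjacency(mol)$nbr
  deg <- lengths(adj)
  z <- .PERIODIC$number[match(mol$atoms$element, .PERIODIC$symbol)]
  vapply(seq_len(n), function(k) {
    hash_tuple(c(z[k], deg[k], mol$atoms$nh[k],
                 mol$atoms$charge[k] %% 256,
                 as.integer(mol$atoms$in_ring[k]),
                 as.integer(mol$atoms$aromatic[k])))
  }, numeric(1))
}

#' Generate an extended-connectivity fingerprint
#'
#' Performs the iterative neighborhood hashing for `r = 1..radius` (new
#' identifier = hash of `(r, own identifier, sorted (bond code, neighbor
#' identifier) pairs)`), discards environments whose covered atom set
#' duplicates an earlier-kept environment (earlier = smaller
#' `(iteration, identifier)`), and folds each retained identifier to bit
#' `(identifier mod n_bits) + 1`. Provenance (center atom, radius, covered
#' atoms, raw identifier) is recorded for every retained environment.
#'
#' @param mol A [molgraph()] with at least one heavy atom.
#' @param config A [fp_config()] (or radius/n_bits via `...`).
#' @param radius,n_bits Used if `config` is missing.
#' @return An object of class `ecfp` with elements `bits` (logical vector of
#'   length `n_bits`), `provenance` (list keyed by bit index as character),
#'   `config`, and `id`.
#' @export
ecfp <- function(mol, config = NULL, radius = 2L, n_bits = 1024L) {
  if (is.null(config)) config <- fp_config(radius, n_bits)
  n <- n_atoms(mol)
  if (n == 0L) stop("cannot fingerprint an empty molecule")
  adjb <- adjacency(mol)
  adj <- adjb$nbr
  bcode <- lapply(adjb$order, function(o) unname(.BOND_CODE[o]))

  ids <- initial_invariants(mol)
  # covered atom sets per (atom, iteration); radius 0 covers the atom itself
  cover <- lapply(seq_len(n), function(k) k)

  # environment bookkeeping in (iteration, identifier) order
  envs <- list()
  seen_sets <- character(0)
  add_envs <- function(r, ids_now, cover_now, envs, seen_sets) {
    ord <- order(ids_now, seq_along(ids_now))
    for (k in ord) {
      key <- paste(sort(cover_now[[k]]), collapse = ",")
      if (key %in% seen_sets) next
      seen_sets <- c(seen_sets, key)
      envs[[length(envs) + 1L]] <- list(center = k, radius = r,
                                        atoms = sort(cover_now[[k]]),
                                        id = ids_now[k])
    }
    list(envs = envs, seen = seen_sets)
  }
  st <- add_envs(0L, ids, cover, envs, seen_sets)
  envs <- st$envs; seen_sets <- st$seen

  r <- 0L
  while (r < config$radius) {
    r <- r + 1L
    new_ids <- numeric(n)
    new_cover <- vector("list", n)
    for (k in seq_len(n)) {
      nbrs <- adj[[k]]
      if (length(nbrs)) {
        pairs <- cbind(bcode[[k]], ids[nbrs])
        ord <- order(pairs[, 1L], pairs[, 2L])
        flat <- as.numeric(t(pairs[ord, , drop = FALSE]))
      } else flat <- numeric(0)
      new_ids[k] <- hash_tuple(c(r, ids[k], flat))
      new_cover[[k]] <- sort(unique(c(cover[[k]],
                                      unlist(cover[nbrs], use.names = FALSE))))
    }
    st <- add_envs(r, new_ids, new_cover, envs, seen_sets)
    envs <- st$envs; seen_sets <- st$seen
    ids <- new_ids
    cover <- new_cover
  }

  bits <- logical(config$n_bits)
  provenance <- list()
  for (e in envs) {
    bit <- (e$id %% config$n_bits) + 1L
    bits[bit] <- TRUE
    key <- as.character(bit)
    provenance[[key]] <- c(provenance[[key]], list(e))
  }
  structure(list(id = mol$id, bits = bits, provenance = provenance,
                 config = config),
            class = "ecfp")
}

#' @export
print.ecfp <- function(x, ...) {
  cat(sprintf("<ecfp %s %s: %d/%d bits set, %d environments>\n",
              x$id, fp_label(x$config), sum(x$bits), length(x$bits),
              sum(lengths(x$provenance))))
  invisible(x)
}

#' Substructure provenance of one fingerprint bit
#'
#' @param fp An [ecfp()] fingerprint.
#' @param bit Bit index in `1..n_bits`.
#' @return List of environments (`center`, `radius`, `atoms`, `id`) that fold
#'   onto this bit; empty when the bit is 0. Two or more environments signal
#'   a fold collision.
#' @export
bit_substructure <- function(fp, bit) {
  bit <- as.integer(bit)
  if (bit < 1L || bit > length(fp$bits))
    stop("bit index out of range: ", bit)
  env <- fp$provenance[[as.character(bit)]]
  if (is.null(env)) list() else env
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`, defined as 0 when both vectors are all-zero.
#'
#' @param a,b [ecfp()] objects or logical/0-1 vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  va <- if (inherits(a, "ecfp")) a$bits else as.logical(a)
  vb <- if (inherits(b, "ecfp")) b$bits else as.logical(b)
  if (length(va) != length(vb))
    stop("fingerprint length mismatch: ", length(va), " vs ", length(vb))
  un <- sum(va | vb)
  if (un == 0L) return(0)
  sum(va & vb) / un
}

#' Fingerprint matrix for a set of molecules
#'
#' @param mols List of [molgraph()] objects.
#' @param config A [fp_config()].
#' @return A 0/1 integer matrix, one row per molecule (rownames = compound
#'   ids, colnames `b0001..`), with the `fp_config` attached as attribute
#'   `"config"`.
#' @export
ecfp_matrix <- function(mols, config = fp_config()) {
  X <- matrix(0L, nrow = length(mols), ncol = config$n_bits)
  ids <- character(length(mols))
  for (k in seq_along(mols)) {
    fp <- ecfp(mols[[k]], config)
    X[k, ] <- as.integer(fp$bits)
    ids[k] <- mols[[k]]$id
  }
  rownames(X) <- ids
  colnames(X) <- sprintf("b%04d", seq_len(config$n_bits))
  attr(X, "config") <- config
  X
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param X A 0/1 fingerprint matrix (rows = compounds), or `Y` against a
#'   second matrix with the same number of columns.
#' @param Y Optional second matrix; defaults to `X`.
#' @return Matrix of similarities, `nrow(X) x nrow(Y)`; 0/0 is defined as 0.
#' @export
tanimoto_matrix <- function(X, Y = NULL) {
  if (is.null(Y)) Y <- X
  if (ncol(X) != ncol(Y)) stop("fingerprint length mismatch")
  X <- matrix(as.numeric(X > 0), nrow = nrow(X))
  Y <- matrix(as.numeric(Y > 0), nrow = nrow(Y))
  inter <- X %*% t(Y)
  un <- outer(rowSums(X), rowSums(Y), "+") - inter
  sim <- ifelse(un == 0, 0, inter / un)
  sim
}
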