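# Synthetic molecule generator with planted structure-label relationships.
#
# Random connected heavy-atom graphs under common organic valences stand in
# for curated taste datasets: a distinctive substructure motif is embedded
# into a subset of molecules and the response (class label or log10 relative
# sweetness) is a known function of motif presence plus noise, so recovery of
# the planted signal is a quantitative end-to-end check of the whole
# pipeline.

.VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, Si = 4L,
              F = 1L, Cl = 1L, Br = 1L, I = 1L)

#' Generate random connected molecules
#'
#' Grows a random tree of heavy atoms under common organic valences
#' (C 4, N 3, O 2, S 2, P 3, Si 4, halogens 1), optionally closing one ring
#' per molecule with the stated probability, and fills remaining valence
#' with attached hydrogens. All bonds are single; structures are
#' deterministic under the seed and always pass [element_filter()] for the
#' default alphabet.
#'
#' @param n Number of molecules.
#' @param n_atoms Heavy-atom count range, default `c(8, 16)`.
#' @param elements Named probability weights over the element alphabet.
#' @param ring_p Probability of attempting one ring closure (0.3).
#' @param seed RNG seed.
#' @param id_prefix Compound id prefix.
#' @return List of [molgraph()] objects.
#' @export
generate_molecules <- function(n, n_atoms = c(8, 16),
                               elements = c(C = 0.7, N = 0.15, O = 0.15),
                               ring_p = 0.3, seed = 1L, id_prefix = "M") {
  if (!all(names(elements) %in% names(.VALENCE)))
    stop("unsupported element(s): ",
         paste(setdiff(names(elements), names(.VALENCE)), collapse = ", "))
  with_seed(seed, {
    lapply(seq_len(n), function(m) {
      rng <- seq(n_atoms[1L], n_atoms[length(n_atoms)])
      size <- rng[sample.int(length(rng), 1L)]
      els <- sample(names(elements), size, replace = TRUE,
                    prob = as.numeric(elements))
      cap <- .VALENCE[els]
      deg <- integer(size)
      bi <- integer(0); bj <- integer(0)
      for (k in seq_len(size)[-1L]) {
        free <- which(deg[seq_len(k - 1L)] < cap[seq_len(k - 1L)])
        if (!length(free))
          stop("infeasible valence request: no attachment point left")
        parent <- free[sample.int(length(free), 1L)]
        bi <- c(bi, parent); bj <- c(bj, k)
        deg[parent] <- deg[parent] + 1L
        deg[k] <- deg[k] + 1L
      }
      if (stats::runif(1) < ring_p && size >= 3L) {
        free <- which(deg < cap)
        if (length(free) >= 2L) {
          adj_key <- paste(pmin(bi, bj), pmax(bi, bj))
          cand <- utils::combn(free, 2L)
          keys <- paste(pmin(cand[1L, ], cand[2L, ]),
                        pmax(cand[1L, ], cand[2L, ]))
          ok <- which(!(keys %in% adj_key))
          if (length(ok)) {
            pick <- cand[, ok[sample.int(length(ok), 1L)]]
            bi <- c(bi, pick[1L]); bj <- c(bj, pick[2L])
            deg[pick] <- deg[pick] + 1L
          }
        }
      }
      atoms <- data.frame(element = els, charge = 0L, aromatic = FALSE,
                          nh = cap - deg, stringsAsFactors = FALSE)
      bonds <- data.frame(i = bi, j = bj,
                          order = rep("single", length(bi)),
                          stringsAsFactors = FALSE)
      molgraph(sprintf("%s%04d", id_prefix, m), atoms, bonds)
    })
  })
}

#' Planted substructure motifs
#'
#' Small explicit fragments with elements outside the default generator
#' alphabet, so their fingerprint bits are distinctive: a dichloromethyl
#' carbon, a methyl thioether, and a phosphorus diol. Each motif carries an
#' `attach` attribute naming the atom that bonds to the host (consuming one
#' hydrogen on each side).
#'
#' @return Named list of `molgraph` fragments.
#' @export
motif_library <- function() {
  dichloro <- molgraph("motif_dichloro",
    data.frame(element = c("C", "Cl", "Cl"), charge = 0L, aromatic = FALSE,
               nh = c(2L, 0L, 0L)),
    data.frame(i = c(1L, 1L), j = c(2L, 3L), order = "single"))
  attr(dichloro, "attach") <- 1L
  thioether <- molgraph("motif_thioether",
    data.frame(element = c("C", "S", "C"), charge = 0L, aromatic = FALSE,
               nh = c(2L, 0L, 3L)),
    data.frame(i = c(1L, 2L), j = c(2L, 3L), order = "single"))
  attr(thioether, "attach") <- 1L
  phosphodiol <- molgraph("motif_phosphodiol",
    data.frame(element = c("P", "O", "O"), charge = 0L, aromatic = FALSE,
               nh = c(1L, 1L, 1L)),
    data.frame(i = c(1L, 1L), j = c(2L, 3L), order = "single"))
  attr(phosphodiol, "attach") <- 1L
  list(dichloro = dichloro, thioether = thioether,
       phosphodiol = phosphodiol)
}

#' Embed a motif fragment into a host molecule
#'
#' Joins the motif to a random host atom carrying at least one attached
#' hydrogen via a new single bond; one hydrogen on each side is consumed.
#'
#' @param mol Host [molgraph()].
#' @param motif A fragment from [motif_library()].
#' @return The combined `molgraph`; attribute `"motif_atoms"` holds the
#'   indices of the embedded motif atoms.
#' @export
embed_motif <- function(mol, motif) {
  hosts <- which(mol$atoms$nh > 0L)
  if (!length(hosts)) stop("motif embedding failure: no free valence on host")
  host <- hosts[sample.int(length(hosts), 1L)]
  attach <- attr(motif, "attach")
  if (motif$atoms$nh[attach] < 1L)
    stop("motif attachment atom has no free valence")
  n0 <- n_atoms(mol)
  atoms <- rbind(mol$atoms[, c("element", "charge", "aromatic", "nh")],
                 motif$atoms[, c("element", "charge", "aromatic", "nh")])
  atoms$nh[host] <- atoms$nh[host] - 1L
  atoms$nh[n0 + attach] <- atoms$nh[n0 + attach] - 1L
  mb <- motif$bonds
  if (nrow(mb)) { mb$i <- mb$i + n0; mb$j <- mb$j + n0 }
  bonds <- rbind(mol$bonds,
                 data.frame(i = host, j = n0 + attach, order = "single",
                            stringsAsFactors = FALSE),
                 mb)
  out <- molgraph(mol$id, atoms, bonds)
  attr(out, "motif_atoms") <- n0 + seq_len(n_atoms(motif))
  out
}

#' Plant labels or responses on a set of molecules
#'
#' Classification: each molecule receives the first motif independently with
#' probability `p_embed`; the observed label is `sweet` iff the motif is
#' present, flipped with probability `eps` (label noise). Regression: each of
#' the supplied motifs is embedded independently with probability `p_embed`
#' and `log10(RS) = beta0 + sum(beta_i * motif_i) + N(0, sigma)`.
#'
#' @param mols List of [molgraph()] objects (modified copies are returned).
#' @param task `"classification"` or `"regression"`.
#' @param motifs List of motif fragments (default [motif_library()]; the
#'   classification rule uses the first).
#' @param eps Label flip-noise rate in `[0, 0.5)`.
#' @param sigma Regression noise standard deviation (log10 units).
#' @param beta0,betas Regression intercept and motif effects.
#' @param p_embed Per-motif embedding probability.
#' @param seed RNG seed.
#' @return List with `mols`, `label` (or `rs`), and `truth` (motif indicator
#'   matrix and flip vector).
#' @export
plant_labels <- function(mols, task = c("classification", "regression"),
                         motifs = motif_library(), eps = 0.05, sigma = 0.1,
                         beta0 = 0.3, betas = c(1, 0.7, 0.5), p_embed = 0.5,
                         seed = 1L) {
  task <- match.arg(task)
  if (eps < 0 || eps >= 0.5) stop("eps must be in [0, 0.5)")
  if (sigma < 0) stop("sigma must be >= 0")
  n <- length(mols)
  if (task == "classification") motifs <- motifs[1L]
  k <- length(motifs)
  betas <- rep_len(betas, k)
  with_seed(seed, {
    ind <- matrix(stats::runif(n * k) < p_embed, n, k)
    colnames(ind) <- names(motifs)
    out_mols <- mols
    for (i in seq_len(n)) {
      for (j in seq_len(k)) {
        if (ind[i, j]) out_mols[[i]] <- embed_motif(out_mols[[i]],
                                                    motifs[[j]])
      }
    }
    if (task == "classification") {
      flip <- stats::runif(n) < eps
      lab <- ifelse(xor(ind[, 1L], flip), "sweet", "non-sweet")
      list(mols = out_mols, label = lab,
           truth = list(motif = ind, flipped = flip))
    } else {
      y <- beta0 + as.numeric(ind %*% betas) + stats::rnorm(n, sd = sigma)
      list(mols = out_mols, rs = 10^y,
           truth = list(motif = ind, y_clean = beta0 +
                          as.numeric(ind %*% betas)))
    }
  })
}

#' Planted classification dataset under the standard study conditions
#'
#' 400 molecules, one distinctive motif, label flip noise 0.05 - the
#' conditions under which pipeline recovery is asserted.
#'
#' @param n Number of molecules (400).
#' @param eps Flip-noise rate (0.05).
#' @param seed RNG seed.
#' @param n_atoms Heavy-atom size range.
#' @return As [plant_labels()].
#' @export
planted_classification_dataset <- function(n = 400L, eps = 0.05, seed = 1L,
                                           n_atoms = c(8, 16)) {
  mols <- generate_molecules(n, n_atoms = n_atoms, seed = seed)
  plant_labels(mols, "classification", eps = eps, seed = seed + 1L)
}

#' Planted regression dataset under the standard study conditions
#'
#' 352 molecules (the curated relative-sweetness dataset size), three motifs
#' with effects (1, 0.7, 0.5) on log10(RS), Gaussian noise 0.1.
#'
#' @param n Number of molecules (352).
#' @param sigma Noise standard deviation (0.1).
#' @param seed RNG seed.
#' @param n_atoms Heavy-atom size range.
#' @return As [plant_labels()].
#' @export
planted_regression_dataset <- function(n = 352L, sigma = 0.1, seed = 1L,
                                       n_atoms = c(8, 16)) {
  mols <- generate_molecules(n, n_atoms = n_atoms, seed = seed)
  plant_labels(mols, "regression", sigma = sigma, seed = seed + 1L)
}
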