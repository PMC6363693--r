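# Heavy-atom molecular graph representation.
#
# Structures are stored hydrogen-suppressed: explicit hydrogens from input
# files are collapsed into a per-atom attached-H count, since the circular
# fingerprint layer operates on the heavy-atom graph.

# Atomic numbers and average masses for elements we expect to meet in
# taste-compound collections (the modeling element set plus common salt
# counter-ions so that filtering can recognise them).
.PERIODIC <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "F", "Na", "Mg", "Al", "Si", "P", "S",
             "Cl", "K", "Ca", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "As", "Se",
             "Br", "Ag", "Sn", "I", "Ba", "Pt", "Au", "Hg", "Pb", "Li"),
  number = c(1, 5, 6, 7, 8, 9, 11, 12, 13, 14, 15, 16,
             17, 19, 20, 25, 26, 27, 28, 29, 30, 33, 34,
             35, 47, 50, 53, 56, 78, 79, 80, 82, 3),
  mass = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305,
           26.982, 28.085, 30.974, 32.06, 35.45, 39.098, 40.078, 54.938,
           55.845, 58.933, 58.693, 63.546, 65.38, 74.922, 78.971, 79.904,
           107.87, 118.71, 126.90, 137.33, 195.08, 196.97, 200.59, 207.2,
           6.94),
  stringsAsFactors = FALSE
)

#' Elements admitted by the curation element filter
#'
#' The organic element set used when curating taste datasets: C, H, O, N, S,
#' P, Si, F, Cl, Br and I. Compounds containing any other element are dropped.
#'
#' @format Character vector of element symbols.
#' @export
ALLOWED_ELEMENTS <- c("C", "H", "O", "N", "S", "P", "Si", "F", "Cl", "Br", "I")

.BOND_ORDERS <- c("single", "double", "triple", "aromatic")

#' Construct a heavy-atom molecular graph
#'
#' @param id Compound identifier string.
#' @param atoms Data frame with columns `element` (symbol), `charge` (integer
#'   formal charge), `aromatic` (logical), `nh` (attached hydrogen count),
#'   and optionally `in_ring` (logical; recomputed unless supplied).
#' @param bonds Data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (one of `"single"`, `"double"`, `"triple"`, `"aromatic"`).
#' @param recompute_rings Recompute ring membership by cycle detection
#'   (default `TRUE`).
#'
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(id, atoms, bonds = NULL, recompute_rings = TRUE) {
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = character(),
                        stringsAsFactors = FALSE)
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  if (!"aromatic" %in% names(atoms)) atoms$aromatic <- FALSE
  if (!"nh" %in% names(atoms)) atoms$nh <- 0L
  atoms$element <- as.character(atoms$element)
  atoms$charge <- as.integer(atoms$charge)
  atoms$aromatic <- as.logical(atoms$aromatic)
  atoms$nh <- as.integer(atoms$nh)

  n <- nrow(atoms)
  bad <- setdiff(atoms$element, .PERIODIC$symbol)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(unique(bad), collapse = ", "))
  if (any(atoms$nh < 0L)) stop("attached-H counts must be non-negative")
  if (nrow(bonds)) {
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    bonds$order <- as.character(bonds$order)
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond atom index out of range")
    if (any(bonds$i == bonds$j)) stop("self-bond not allowed")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
    if (!all(bonds$order %in% .BOND_ORDERS))
      stop("invalid bond order: ",
           paste(setdiff(bonds$order, .BOND_ORDERS), collapse = ", "))
  }
  m <- structure(list(id = as.character(id), atoms = atoms, bonds = bonds),
                 class = "molgraph")
  if (recompute_rings || is.null(atoms$in_ring)) {
    m$atoms$in_ring <- ring_atoms(m)
  }
  m
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph %s: %d heavy atoms, %d bonds, formula %s>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), molecular_formula(x)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

# Neighbor list: for each atom, data on bonded partners and bond orders.
adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- rep(list(integer()), n)
  ord <- rep(list(character()), n)
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b$i[k]; j <- b$j[k]
      adj[[i]] <- c(adj[[i]], j); ord[[i]] <- c(ord[[i]], b$order[k])
      adj[[j]] <- c(adj[[j]], i); ord[[j]] <- c(ord[[j]], b$order[k])
    }
  }
  list(nbr = adj, order = ord)
}

# Connected components by BFS; returns integer component label per atom.
components <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(integer())
  adj <- adjacency(mol)$nbr
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(comp[w])) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# An atom lies on a cycle iff it is an endpoint of some non-bridge edge.
# Bridges found naively by edge removal + reachability; molecules are small.
ring_atoms <- function(mol) {
  n <- n_atoms(mol)
  in_ring <- rep(FALSE, n)
  b <- mol$bonds
  if (!nrow(b)) return(in_ring)
  for (k in seq_len(nrow(b))) {
    sub <- b[-k, , drop = FALSE]
    if (.reachable(n, sub, b$i[k], b$j[k])) {
      in_ring[b$i[k]] <- TRUE
      in_ring[b$j[k]] <- TRUE
    }
  }
  in_ring
}

.reachable <- function(n, bonds, from, to) {
  adj <- rep(list(integer()), n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
      adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
    }
  }
  seen <- rep(FALSE, n)
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (v == to) return(TRUE)
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  seen[to]
}

# Induced subgraph on the given atom indices (renumbered in their order).
subgraph <- function(mol, idx) {
  idx <- as.integer(idx)
  map <- integer(n_atoms(mol))
  map[idx] <- seq_along(idx)
  b <- mol$bonds
  keep <- b$i %in% idx & b$j %in% idx
  b <- b[keep, , drop = FALSE]
  if (nrow(b)) { b$i <- map[b$i]; b$j <- map[b$j] }
  molgraph(mol$id, mol$atoms[idx, , drop = FALSE], b)
}

#' Keep the largest connected fragment of a molecule
#'
#' Salt-stripping rule for dataset curation: for disconnected structures only
#' the largest fragment (most heavy atoms) is retained. Ties are broken by
#' larger summed atomic mass, then by lowest original atom index.
#'
#' @param mol A [molgraph()].
#' @return A `molgraph` containing a single connected component.
#' @export
keep_largest_fragment <- function(mol) {
  if (n_atoms(mol) == 0L) stop("empty molecule")
  comp <- components(mol)
  if (max(comp) == 1L) return(mol)
  mass <- .PERIODIC$mass[match(mol$atoms$element, .PERIODIC$symbol)] +
    1.008 * mol$atoms$nh
  sizes <- tapply(rep(1L, length(comp)), comp, sum)
  masses <- tapply(mass, comp, sum)
  first <- tapply(seq_along(comp), comp, min)
  ord <- order(-sizes, -masses, first)
  best <- as.integer(names(sizes)[ord[1L]])
  subgraph(mol, which(comp == best))
}

#' Test a molecule against the curation element filter
#'
#' @param mol A [molgraph()].
#' @return `TRUE` iff every atom's element is one of C, H, O, N, S, P, Si, F,
#'   Cl, Br, I.
#' @export
element_filter <- function(mol) {
  all(mol$atoms$element %in% ALLOWED_ELEMENTS)
}

#' Molecular formula (Hill order) of a heavy-atom graph
#'
#' Attached hydrogens are included in the H count.
#'
#' @param mol A [molgraph()].
#' @return A formula string such as `"C2H6O"`.
#' @export
molecular_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  nh <- sum(mol$atoms$nh)
  els <- names(counts)
  hill <- c(intersect(c("C"), els), if (nh > 0) "H",
            sort(setdiff(els, c("C", "H"))))
  if (!"C" %in% els) hill <- c(if (nh > 0) "H", sort(setdiff(els, "H")))
  paste0(vapply(hill, function(e) {
    k <- if (e == "H") nh + sum(counts[names(counts) == "H"]) else counts[[e]]
    paste0(e, if (k > 1) k else "")
  }, character(1)), collapse = "")
}

#' Relabel atoms of a molecule by a permutation
#'
#' Utility mainly used to assert permutation invariance of fingerprints:
#' atom `k` of the result is atom `perm[k]` of the input.
#'
#' @param mol A [molgraph()].
#' @param perm A permutation of `1:n_atoms`.
#' @return The relabeled `molgraph`.
#' @export
permute_atoms <- function(mol, perm) {
  perm <- as.integer(perm)
  stopifnot(length(perm) == n_atoms(mol), !anyDuplicated(perm))
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  b <- mol$bonds
  if (nrow(b)) { b$i <- inv[b$i]; b$j <- inv[b$j] }
  molgraph(mol$id, mol$atoms[perm, , drop = FALSE], b)
}
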