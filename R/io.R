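# Structure file readers/writers: Tripos MOL2 and SDF (V2000).
#
# Both readers build full atom graphs first and then collapse explicit
# hydrogens into per-heavy-atom attached-H counts.

.MOL2_BOND_IN <- c("1" = "single", "2" = "double", "3" = "triple",
                   "am" = "single", "ar" = "aromatic")
.MOL2_BOND_OUT <- c(single = "1", double = "2", triple = "3", aromatic = "ar")
.SDF_BOND_IN <- c("1" = "single", "2" = "double", "3" = "triple",
                  "4" = "aromatic")
.SDF_BOND_OUT <- c(single = "1", double = "2", triple = "3", aromatic = "4")

# Remove explicit hydrogen atoms, counting them on their heavy neighbor.
# Hydrogens without a heavy neighbor (isolated H, H2) are dropped.
collapse_hydrogens <- function(mol) {
  is_h <- mol$atoms$element == "H"
  if (!any(is_h)) return(mol)
  heavy <- which(!is_h)
  nh <- mol$atoms$nh
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b$i[k]; j <- b$j[k]
      if (is_h[i] && !is_h[j]) nh[j] <- nh[j] + 1L
      if (is_h[j] && !is_h[i]) nh[i] <- nh[i] + 1L
    }
  }
  mol$atoms$nh <- nh
  subgraph_keep <- mol
  subgraph_keep$atoms <- mol$atoms
  out <- subgraph(subgraph_keep, heavy)
  out
}

#' Read a Tripos MOL2 file
#'
#' Parses all `@<TRIPOS>MOLECULE` records of a MOL2 file into heavy-atom
#' graphs. Explicit hydrogens are collapsed into attached-H counts; SYBYL
#' atom types are mapped to elements by their leading alphabetic token
#' (`"C.3"` to C, `"N.ar"` to N); bond type `"ar"` maps to aromatic order and
#' flags both atoms aromatic. Formal charges are not encoded in MOL2 (the
#' charge column carries partial charges) and are read as 0.
#'
#' @param path Path to a MOL2 file.
#' @return A list of [molgraph()] objects (empty for an empty file).
#' @export
read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(recs)) {
    if (length(trimws(lines)) && any(nzchar(trimws(lines))))
      stop("no @<TRIPOS>MOLECULE record found in ", path)
    return(list())
  }
  ends <- c(recs[-1L] - 1L, length(lines))
  mols <- vector("list", length(recs))
  for (r in seq_along(recs)) {
    block <- lines[recs[r]:ends[r]]
    offset <- recs[r] - 1L
    mols[[r]] <- .parse_mol2_record(block, offset)
  }
  mols
}

.parse_mol2_record <- function(block, offset) {
  sect <- grep("^@<TRIPOS>", block)
  if (length(block) < 3L)
    stop("malformed MOL2 record at line ", offset + 1L,
         ": missing molecule header")
  name <- trimws(block[2L])
  counts <- strsplit(trimws(block[3L]), "\\s+")[[1L]]
  na <- suppressWarnings(as.integer(counts[1L]))
  nb <- if (length(counts) >= 2L)
    suppressWarnings(as.integer(counts[2L])) else 0L
  if (is.na(na))
    stop("malformed MOL2 counts line at line ", offset + 3L)
  if (is.na(nb)) nb <- 0L

  atom_at <- grep("^@<TRIPOS>ATOM\\s*$", block)
  if (na > 0L && !length(atom_at))
    stop("malformed MOL2 record at line ", offset + 1L,
         ": missing @<TRIPOS>ATOM section")
  elements <- character(na); arom <- logical(na)
  if (na > 0L) {
    atom_lines <- block[(atom_at[1L] + 1L):(atom_at[1L] + na)]
    for (k in seq_len(na)) {
      f <- strsplit(trimws(atom_lines[k]), "\\s+")[[1L]]
      if (length(f) < 6L)
        stop("malformed MOL2 atom line at line ", offset + atom_at[1L] + k)
      type <- f[6L]
      el <- sub("^([A-Za-z]+).*$", "\\1", type)
      el <- paste0(toupper(substr(el, 1, 1)),
                   tolower(substr(el, 2, nchar(el))))
      if (!el %in% .PERIODIC$symbol)
        stop("unknown MOL2 atom type: ", type)
      elements[k] <- el
      arom[k] <- grepl("\\.ar$", type)
    }
  }
  bonds <- data.frame(i = integer(), j = integer(), order = character(),
                      stringsAsFactors = FALSE)
  if (nb > 0L) {
    bond_at <- grep("^@<TRIPOS>BOND\\s*$", block)
    if (!length(bond_at))
      stop("malformed MOL2 record at line ", offset + 1L,
           ": missing @<TRIPOS>BOND section")
    bond_lines <- block[(bond_at[1L] + 1L):(bond_at[1L] + nb)]
    bi <- integer(nb); bj <- integer(nb); bo <- character(nb)
    for (k in seq_len(nb)) {
      f <- strsplit(trimws(bond_lines[k]), "\\s+")[[1L]]
      if (length(f) < 4L)
        stop("malformed MOL2 bond line at line ", offset + bond_at[1L] + k)
      bi[k] <- as.integer(f[2L]); bj[k] <- as.integer(f[3L])
      typ <- tolower(f[4L])
      if (!typ %in% names(.MOL2_BOND_IN))
        stop("unknown MOL2 bond type: ", f[4L])
      bo[k] <- .MOL2_BOND_IN[[typ]]
    }
    bonds <- data.frame(i = bi, j = bj, order = bo, stringsAsFactors = FALSE)
    arom[bonds$i[bonds$order == "aromatic"]] <- TRUE
    arom[bonds$j[bonds$order == "aromatic"]] <- TRUE
  }
  atoms <- data.frame(element = elements, charge = 0L, aromatic = arom,
                      nh = 0L, stringsAsFactors = FALSE)
  collapse_hydrogens(molgraph(name, atoms, bonds))
}

#' Write molecules to a Tripos MOL2 file
#'
#' Attached hydrogens are expanded back to explicit H atoms so that reading
#' the file reproduces the same heavy-atom graph with identical attached-H
#' counts. Coordinates are written as zeros (the descriptor layer is 2D).
#'
#' @param mols A `molgraph` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mol2 <- function(mols, path) {
  if (inherits(mols, "molgraph")) mols <- list(mols)
  out <- character(0)
  for (mol in mols) {
    n <- n_atoms(mol)
    nh <- mol$atoms$nh
    nH_total <- sum(nh)
    bonds <- mol$bonds
    atom_lines <- character(n + nH_total)
    for (k in seq_len(n)) {
      type <- if (isTRUE(mol$atoms$aromatic[k]))
        paste0(mol$atoms$element[k], ".ar") else mol$atoms$element[k]
      atom_lines[k] <- sprintf(
        "%7d %-4s %9.4f %9.4f %9.4f %-6s 1 MOL 0.0000",
        k, paste0(mol$atoms$element[k], k), 0, 0, 0, type)
    }
    hidx <- n
    hb_i <- integer(nH_total); hb_j <- integer(nH_total)
    hn <- 0L
    for (k in seq_len(n)) {
      if (nh[k] > 0L) for (u in seq_len(nh[k])) {
        hidx <- hidx + 1L; hn <- hn + 1L
        atom_lines[hidx] <- sprintf(
          "%7d %-4s %9.4f %9.4f %9.4f %-6s 1 MOL 0.0000",
          hidx, paste0("H", hidx), 0, 0, 0, "H")
        hb_i[hn] <- k; hb_j[hn] <- hidx
      }
    }
    nb <- nrow(bonds) + nH_total
    bond_lines <- character(nb)
    if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
      bond_lines[k] <- sprintf("%6d %5d %5d %-4s", k, bonds$i[k], bonds$j[k],
                               .MOL2_BOND_OUT[[bonds$order[k]]])
    }
    if (nH_total) for (u in seq_len(nH_total)) {
      k <- nrow(bonds) + u
      bond_lines[k] <- sprintf("%6d %5d %5d %-4s", k, hb_i[u], hb_j[u], "1")
    }
    out <- c(out, "@<TRIPOS>MOLECULE", mol$id,
             sprintf("%5d %5d %5d", n + nH_total, nb, 1L),
             "SMALL", "NO_CHARGES", "", "@<TRIPOS>ATOM", atom_lines,
             "@<TRIPOS>BOND", bond_lines, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an SDF (V2000 connection table) file
#'
#' Parses all records of an SD file. Explicit hydrogens are collapsed into
#' attached-H counts; bond type 4 maps to aromatic order; `M  CHG` property
#' lines set formal charges. Data fields after `M  END` are ignored.
#'
#' @param path Path to an SDF/MOL file.
#' @return A list of [molgraph()] objects (empty for an empty file).
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) return(list())
  # split on $$$$ record separators; a bare molfile is one record
  seps <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, seps + 1L)
  ends <- c(seps - 1L, length(lines))
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  mols <- list()
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    if (all(!nzchar(trimws(block)))) next
    mols[[length(mols) + 1L]] <- .parse_sdf_record(block, starts[r] - 1L)
  }
  mols
}

.parse_sdf_record <- function(block, offset) {
  if (length(block) < 4L)
    stop("malformed SDF record at line ", offset + 1L)
  name <- trimws(block[1L])
  counts <- block[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(na) || is.na(nb))
    stop("malformed SDF counts line at line ", offset + 4L)
  need <- 4L + na + nb
  if (length(block) < need)
    stop("SDF counts line inconsistent with atom/bond blocks at line ",
         offset + 4L)
  elements <- character(na)
  if (na > 0L) for (k in seq_len(na)) {
    f <- strsplit(trimws(block[4L + k]), "\\s+")[[1L]]
    if (length(f) < 4L)
      stop("malformed SDF atom line at line ", offset + 4L + k)
    el <- f[4L]
    if (!el %in% .PERIODIC$symbol)
      stop("unknown SDF element symbol: ", el)
    elements[k] <- el
  }
  bonds <- data.frame(i = integer(), j = integer(), order = character(),
                      stringsAsFactors = FALSE)
  arom <- logical(na)
  if (nb > 0L) {
    bi <- integer(nb); bj <- integer(nb); bo <- character(nb)
    for (k in seq_len(nb)) {
      ln <- block[4L + na + k]
      f <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(f) < 3L)
        stop("malformed SDF bond line at line ", offset + 4L + na + k)
      bi[k] <- as.integer(f[1L]); bj[k] <- as.integer(f[2L])
      typ <- f[3L]
      if (!typ %in% names(.SDF_BOND_IN))
        stop("unknown SDF bond type: ", typ)
      bo[k] <- .SDF_BOND_IN[[typ]]
    }
    if (any(bi > na | bj > na))
      stop("SDF counts line inconsistent with atom/bond blocks at line ",
           offset + 4L)
    bonds <- data.frame(i = bi, j = bj, order = bo, stringsAsFactors = FALSE)
    arom[bonds$i[bonds$order == "aromatic"]] <- TRUE
    arom[bonds$j[bonds$order == "aromatic"]] <- TRUE
  }
  charge <- integer(na)
  for (ln in grep("^M  CHG", block, value = TRUE)) {
    f <- strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1L]]
    f <- as.integer(f)
    cnt <- f[1L]
    for (u in seq_len(cnt)) {
      idx <- f[2L * u]; val <- f[2L * u + 1L]
      charge[idx] <- val
    }
  }
  atoms <- data.frame(element = elements, charge = charge, aromatic = arom,
                      nh = 0L, stringsAsFactors = FALSE)
  collapse_hydrogens(molgraph(name, atoms, bonds))
}

#' Write molecules to an SDF (V2000) file
#'
#' Heavy atoms only; attached hydrogens are left implicit (standard SDF
#' convention), formal charges are written as `M  CHG` lines, coordinates as
#' zeros.
#'
#' @param mols A `molgraph` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molgraph")) mols <- list(mols)
  out <- character(0)
  for (mol in mols) {
    n <- n_atoms(mol)
    b <- mol$bonds
    rec <- c(mol$id, "  sweetqsar", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     n, nrow(b)))
    for (k in seq_len(n)) {
      rec <- c(rec, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                            0, 0, 0, mol$atoms$element[k]))
    }
    if (nrow(b)) for (k in seq_len(nrow(b))) {
      rec <- c(rec, sprintf("%3d%3d%3d  0", b$i[k], b$j[k],
                            as.integer(.SDF_BOND_OUT[[b$order[k]]])))
    }
    chg <- which(mol$atoms$charge != 0L)
    if (length(chg)) {
      for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
        rec <- c(rec, paste0("M  CHG", sprintf("%3d", length(grp)),
                             paste0(sprintf("%4d%4d", grp,
                                            mol$atoms$charge[grp]),
                                    collapse = "")))
      }
    }
    rec <- c(rec, "M  END", "$$$$")
    out <- c(out, rec)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a structure manifest CSV
#'
#' A manifest links compound identifiers to structure files and responses:
#' columns `id`, `path` and either `label` (classification, values `sweet` /
#' `non-sweet`) or `RS` (regression, relative sweetness versus 5\% w/v
#' sucrose), optionally `source` and `sucrose_ref`.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "path") %in% names(df)))
    stop("manifest must contain columns 'id' and 'path'")
  if (!("label" %in% names(df) || "RS" %in% names(df)))
    stop("manifest must contain a 'label' or 'RS' column")
  df
}
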