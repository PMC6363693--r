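# Hand-built molecules and structure-file fixtures used across tests.

mk_mol <- function(id, elements, bonds_i = integer(), bonds_j = integer(),
                   order = "single", nh = 0L, charge = 0L, aromatic = FALSE) {
  n <- length(elements)
  molgraph(id,
           data.frame(element = elements,
                      charge = rep_len(charge, n),
                      aromatic = rep_len(aromatic, n),
                      nh = rep_len(nh, n),
                      stringsAsFactors = FALSE),
           if (length(bonds_i))
             data.frame(i = bonds_i, j = bonds_j,
                        order = rep_len(order, length(bonds_i)),
                        stringsAsFactors = FALSE))
}

ethanol <- function() {
  mk_mol("ethanol", c("C", "C", "O"), c(1, 2), c(2, 3), nh = c(3L, 2L, 1L))
}

benzene <- function() {
  mk_mol("benzene", rep("C", 6), 1:6, c(2:6, 1), order = "aromatic",
         nh = 1L, aromatic = TRUE)
}

dimethyl_ether <- function() {
  mk_mol("dme", c("C", "O", "C"), c(1, 2), c(2, 3), nh = c(3L, 0L, 3L))
}

methane <- function() mk_mol("methane", "C", nh = 4L)

# MOL2 text for ethanol with explicit hydrogens: 9 atoms, 8 bonds.
ethanol_mol2_text <- function() c(
  "@<TRIPOS>MOLECULE",
  "ethanol",
  " 9 8 1",
  "SMALL",
  "NO_CHARGES",
  "",
  "@<TRIPOS>ATOM",
  "  1 C1   0.0 0.0 0.0 C.3  1 MOL 0.0",
  "  2 C2   0.0 0.0 0.0 C.3  1 MOL 0.0",
  "  3 O1   0.0 0.0 0.0 O.3  1 MOL 0.0",
  "  4 H1   0.0 0.0 0.0 H    1 MOL 0.0",
  "  5 H2   0.0 0.0 0.0 H    1 MOL 0.0",
  "  6 H3   0.0 0.0 0.0 H    1 MOL 0.0",
  "  7 H4   0.0 0.0 0.0 H    1 MOL 0.0",
  "  8 H5   0.0 0.0 0.0 H    1 MOL 0.0",
  "  9 H6   0.0 0.0 0.0 H    1 MOL 0.0",
  "@<TRIPOS>BOND",
  "  1 1 2 1",
  "  2 2 3 1",
  "  3 1 4 1",
  "  4 1 5 1",
  "  5 1 6 1",
  "  6 2 7 1",
  "  7 2 8 1",
  "  8 3 9 1")

benzene_mol2_text <- function() c(
  "@<TRIPOS>MOLECULE",
  "benzene",
  " 6 6 1",
  "SMALL",
  "NO_CHARGES",
  "",
  "@<TRIPOS>ATOM",
  "  1 C1 0.0 0.0 0.0 C.ar 1 MOL 0.0",
  "  2 C2 0.0 0.0 0.0 C.ar 1 MOL 0.0",
  "  3 C3 0.0 0.0 0.0 C.ar 1 MOL 0.0",
  "  4 C4 0.0 0.0 0.0 C.ar 1 MOL 0.0",
  "  5 C5 0.0 0.0 0.0 C.ar 1 MOL 0.0",
  "  6 C6 0.0 0.0 0.0 C.ar 1 MOL 0.0",
  "@<TRIPOS>BOND",
  "  1 1 2 ar",
  "  2 2 3 ar",
  "  3 3 4 ar",
  "  4 4 5 ar",
  "  5 5 6 ar",
  "  6 6 1 ar")

# SDF V2000 for methane with explicit hydrogens.
methane_sdf_text <- function() c(
  "methane",
  "  test",
  "",
  "  5  4  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0",
  "  1  3  1  0",
  "  1  4  1  0",
  "  1  5  1  0",
  "M  END",
  "$$$$")

# SDF with an M CHG line: deprotonated methanol-like fragment C-O(-).
methoxide_sdf_text <- function() c(
  "methoxide",
  "  test",
  "",
  "  2  1  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0",
  "M  CHG  1   2  -1",
  "M  END",
  "$$$$")

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
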