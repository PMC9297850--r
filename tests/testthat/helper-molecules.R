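# Small-molecule connectivity fixtures for substituent-priority tests.
# Heavy atoms are numbered as in the SMILES used by the reference CIP
# implementation (RDKit _CIPRank, frozen into `expected`); hydrogens are
# appended after the heavy atoms by build_molecule().

# elements: heavy-atom element vector; bonds: list of c(i, j, order);
# h_counts: hydrogens to attach per heavy atom (same length as elements).
build_molecule <- function(elements, bonds, h_counts) {
  stopifnot(length(h_counts) == length(elements))
  n_heavy <- length(elements)
  h_idx <- list()
  all_el <- elements
  bond_rows <- lapply(bonds, function(b) c(b[1], b[2], if (length(b) > 2) b[3] else 1L))
  nxt <- n_heavy
  for (i in seq_len(n_heavy)) {
    hs <- integer(0)
    for (k in seq_len(h_counts[i])) {
      nxt <- nxt + 1L
      all_el <- c(all_el, "H")
      bond_rows[[length(bond_rows) + 1L]] <- c(i, nxt, 1L)
      hs <- c(hs, nxt)
    }
    h_idx[[i]] <- hs
  }
  list(
    graph = molecular_graph(all_el, do.call(rbind, bond_rows)),
    h_of = h_idx
  )
}

# Panel: the four study substrates (2-methylpyrroline, 2-methylpiperideine,
# 2-phenylpiperideine, 1-methyl-3,4-dihydroisoquinoline) plus eight further
# carbonyl/imine molecules. `expected` lists the substituent indices of the
# prochiral center in decreasing CIP priority ("H" = the center's hydrogen);
# `tie` marks centers with two constitutionally identical substituents.
cip_panel <- function() {
  list(
    `2-methyl-1-pyrroline` = list(
      mol = build_molecule(
        c("C", "C", "N", "C", "C", "C"),
        list(c(1, 2), c(2, 3, 2), c(3, 4), c(4, 5), c(5, 6), c(6, 2)),
        c(3, 0, 0, 2, 2, 2)),
      center = 2, expected = c(3, 6, 1), tie = FALSE),
    `2-methylpiperideine` = list(
      mol = build_molecule(
        c("C", "C", "N", "C", "C", "C", "C"),
        list(c(1, 2), c(2, 3, 2), c(3, 4), c(4, 5), c(5, 6), c(6, 7), c(7, 2)),
        c(3, 0, 0, 2, 2, 2, 2)),
      center = 2, expected = c(3, 7, 1), tie = FALSE),
    `2-phenylpiperideine` = list(
      mol = build_molecule(
        c("C", "C", "C", "C", "N", "C", "C", "C", "C", "C", "C", "C"),
        list(c(1, 2), c(2, 3), c(3, 4), c(4, 5, 2), c(5, 6), c(6, 1),
             c(4, 7), c(7, 8, 2), c(8, 9), c(9, 10, 2), c(10, 11),
             c(11, 12, 2), c(12, 7)),
        c(2, 2, 2, 0, 0, 2, 0, 1, 1, 1, 1, 1)),
      center = 4, expected = c(5, 7, 3), tie = FALSE),
    `1-methyl-3,4-dihydroisoquinoline` = list(
      mol = build_molecule(
        c("C", "C", "N", "C", "C", "C", "C", "C", "C", "C", "C"),
        list(c(1, 2), c(2, 3, 2), c(3, 4), c(4, 5), c(5, 6),
             c(6, 7, 2), c(7, 8), c(8, 9, 2), c(9, 10), c(10, 11, 2),
             c(11, 6), c(11, 2)),
        c(3, 0, 0, 2, 2, 0, 1, 1, 1, 1, 0)),
      center = 2, expected = c(3, 11, 1), tie = FALSE),
    ethanimine = list(
      mol = build_molecule(
        c("C", "C", "N"), list(c(1, 2), c(2, 3, 2)), c(3, 1, 1)),
      center = 2, expected = c(3, 1, "H"), tie = FALSE),
    `propan-2-imine` = list(
      mol = build_molecule(
        c("C", "C", "C", "N"), list(c(1, 2), c(2, 3), c(2, 4, 2)),
        c(3, 0, 3, 1)),
      center = 2, expected = c(4, NA, NA), tie = TRUE),
    `butan-2-imine` = list(
      mol = build_molecule(
        c("C", "C", "C", "C", "N"),
        list(c(1, 2), c(2, 3), c(3, 4), c(3, 5, 2)), c(3, 2, 0, 3, 1)),
      center = 3, expected = c(5, 2, 4), tie = FALSE),
    acetaldehyde = list(
      mol = build_molecule(
        c("C", "C", "O"), list(c(1, 2), c(2, 3, 2)), c(3, 1, 0)),
      center = 2, expected = c(3, 1, "H"), tie = FALSE),
    `butan-2-one` = list(
      mol = build_molecule(
        c("C", "C", "C", "C", "O"),
        list(c(1, 2), c(2, 3), c(3, 4), c(3, 5, 2)), c(3, 2, 0, 3, 0)),
      center = 3, expected = c(5, 2, 4), tie = FALSE),
    benzaldehyde = list(
      mol = build_molecule(
        c("O", "C", "C", "C", "C", "C", "C", "C"),
        list(c(1, 2, 2), c(2, 3), c(3, 4, 2), c(4, 5), c(5, 6, 2),
             c(6, 7), c(7, 8, 2), c(8, 3)),
        c(0, 1, 0, 1, 1, 1, 1, 1)),
      center = 2, expected = c(1, 3, "H"), tie = FALSE),
    `pyruvic-acid` = list(
      mol = build_molecule(
        c("C", "C", "O", "C", "O", "O"),
        list(c(1, 2), c(2, 3, 2), c(2, 4), c(4, 5, 2), c(4, 6)),
        c(3, 0, 0, 0, 0, 1)),
      center = 2, expected = c(3, 4, 1), tie = FALSE),
    cyclohexanone = list(
      mol = build_molecule(
        c("O", "C", "C", "C", "C", "C", "C"),
        list(c(1, 2, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 7), c(7, 2)),
        c(0, 0, 2, 2, 2, 2, 2)),
      center = 2, expected = c(1, NA, NA), tie = TRUE)
  )
}

# Resolve an expected entry: "H" means the (single) hydrogen on the center.
expected_order <- function(entry) {
  sapply(entry$expected, function(e) {
    if (identical(e, "H")) entry$mol$h_of[[entry$center]][1] else as.integer(e)
  })
}
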