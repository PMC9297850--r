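# Shared fixtures: tiny PDB text built in code, random-pose helpers, and
# an independent orientation oracle.

pdb_line <- function(record = "ATOM", serial, name, resname, chain, resid,
                     x, y, z, element = "") {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          if (nchar(name) >= 4) name else paste0(" ", name),
          resname, chain, resid, x, y, z, 1, 0, element)
}

toy_pdb_text <- function() {
  paste(c(
    pdb_line("ATOM", 1, "N", "ALA", "A", 1, 0, 0, 0, "N"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 1.458, 0, 0, "C"),
    pdb_line("ATOM", 3, "C", "ALA", "A", 1, 2.0, 1.4, 0, "C"),
    pdb_line("ATOM", 4, "O", "ALA", "A", 1, 1.4, 2.4, 0, "O"),
    pdb_line("ATOM", 5, "CB", "ALA", "A", 1, 2.0, -1.2, 0.9, "C"),
    pdb_line("ATOM", 6, "N", "SER", "A", 2, 3.3, 1.5, 0, "N"),
    pdb_line("ATOM", 7, "CA", "SER", "A", 2, 4.0, 2.8, 0, "C"),
    pdb_line("ATOM", 8, "OG", "SER", "A", 2, 5.4, 2.6, 0.2, "O"),
    pdb_line("HETATM", 9, "C4", "NAD", "N", 1, 8.0, 8.0, 8.0, "C"),
    pdb_line("HETATM", 10, "H41", "NAD", "N", 1, 8.5, 8.9, 8.2, "H"),
    "END"), collapse = "\n")
}

# A planar prochiral toy: center at the origin, three substituents at
# 120-degree spacing in the xy-plane (decreasing priority a, b, c).
toy_pose <- function() {
  list(
    coords = rbind(
      c(0, 0, 0),             # center
      c(1, 0, 0),             # a (priority 1)
      c(-0.5, 0.8660254, 0),  # b (priority 2)
      c(-0.5, -0.8660254, 0)  # c (priority 3)
    ),
    spec = prochiral_spec(1L, c(2L, 3L, 4L))
  )
}

# Independent orientation oracle: the signed volume of the tetrahedron
# (a, b, c, probe) via a determinant. Negative volume = the a->b->c
# circuit appears clockwise from the probe = re face.
signed_volume_face <- function(a, b, c, probe) {
  v <- det(rbind(a - probe, b - probe, c - probe))
  if (v < 0) "si" else "re"
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# A random non-degenerate pose of the toy prochiral fragment plus a probe
# point off-plane; returns coords, spec and probe.
random_pose <- function(min_offset = 0.3) {
  base <- toy_pose()
  repeat {
    R <- random_rotation_matrix()
    t <- stats::runif(3, -20, 20)
    xyz <- sweep(base$coords %*% t(R), 2, t, "+")
    # probe at a random position at least min_offset from the face plane
    n <- xyz[2, ] - xyz[1, ]
    probe <- xyz[1, ] + stats::runif(3, -4, 4)
    nrm <- pracma_cross(xyz[2, ] - xyz[1, ], xyz[3, ] - xyz[1, ])
    nrm <- nrm / sqrt(sum(nrm^2))
    if (abs(sum(nrm * (probe - xyz[1, ]))) > min_offset) {
      return(list(coords = xyz, spec = base$spec, probe = probe))
    }
  }
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# A synthetic phosphate-binding site modelled on a dinucleotide 2'-phosphate
# pocket: four side chains (N32/R33/T34/K37-like) around phosphate oxygens.
synthetic_phosphate_site <- function() {
  rows <- list(
    list("ND2", "N", "ASN", 32L, FALSE, c(2.9, 0.0, 0.0)),
    list("CB",  "C", "ASN", 32L, FALSE, c(4.2, 0.0, 0.0)),
    list("NH1", "N", "ARG", 33L, FALSE, c(-1.6, 2.5, 0.0)),
    list("NH2", "N", "ARG", 33L, FALSE, c(-2.6, 0.5, 1.5)),
    list("OG1", "O", "THR", 34L, FALSE, c(0.0, -3.0, 0.5)),
    list("NZ",  "N", "LYS", 37L, FALSE, c(0.5, 0.5, 3.1)),
    list("CA",  "C", "GLY", 50L, FALSE, c(2.0, 2.0, 2.0)),  # backbone, ignored
    list("O2P", "O", "NAP", 500L, TRUE, c(0.0, 0.0, 0.0)),
    list("O3P", "O", "NAP", 500L, TRUE, c(-0.8, 1.2, 0.4)),
    list("P",   "P", "NAP", 500L, TRUE, c(-0.5, 0.3, 1.2)),
    list("C1",  "C", "NAP", 500L, TRUE, c(1.5, 1.5, 1.0))
  )
  md_structure(
    serial = seq_along(rows),
    name = vapply(rows, `[[`, character(1), 1),
    element = vapply(rows, `[[`, character(1), 2),
    resname = vapply(rows, `[[`, character(1), 3),
    resid = vapply(rows, function(r) r[[4]], integer(1)),
    chain = "A",
    coords = t(vapply(rows, function(r) r[[6]], numeric(3))),
    is_hetero = vapply(rows, function(r) r[[5]], logical(1)),
    source = "synthetic")
}
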