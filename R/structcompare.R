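#' Kabsch superposition of two point sets
#'
#' Least-squares optimal *proper* rotation (plus translation) mapping
#' `mobile` onto `reference`, via singular value decomposition with the
#' usual determinant correction so that a reflection is never returned.
#'
#' @param mobile,reference n x 3 coordinate matrices with matched rows,
#'   n >= 3, not rank-deficient.
#' @return Object of class `rigid_transform`: list with `rotation` (3 x 3,
#'   det +1), `translation` (3-vector) and `rmsd` (Angstrom, after
#'   transformation). Apply with [apply_transform()].
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    abort_geometry("Point sets must have equal sizes.")
  }
  if (nrow(mobile) < 3) abort_geometry("Need at least 3 points to superpose.")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  A <- sweep(mobile, 2, mc)
  B <- sweep(reference, 2, rc)
  H <- t(A) %*% B
  if (qr(H)$rank < 2) abort_geometry("Point sets are rank-deficient (collinear or coincident).")
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  translation <- rc - as.numeric(R %*% mc)
  moved <- sweep(A %*% t(R), 2, rc, "+")
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param transform A `rigid_transform` from [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Fit a helix axis from C-alpha positions
#'
#' Default method `"template"`: an ideal alpha-helix C-alpha trace of the
#' same length (rise 1.5 Angstrom, twist 100 degrees per residue, radius
#' 2.3 Angstrom) is superposed onto the observed points by Kabsch, and the
#' template's axis is carried through the fitted rotation. For segments as
#' short as 5 residues this is far better conditioned under coordinate
#' noise than a principal-component axis, whose leading eigenvalue gap is
#' small for one-to-two-turn segments. Method `"pca"` (the
#' largest-eigenvalue eigenvector of the centered covariance) remains
#' available and is used automatically for (near-)collinear input, where a
#' helix template cannot be fitted. Either way the axis sign points toward
#' increasing residue number.
#'
#' @param ca_coords n x 3 matrix of C-alpha positions, ordered by residue
#'   number, n >= 3.
#' @param method `"auto"` (template, falling back to PCA for collinear
#'   points), `"template"`, or `"pca"`.
#' @return List with `axis` (unit 3-vector) and `centroid`.
#' @export
helix_axis <- function(ca_coords, method = c("auto", "template", "pca")) {
  method <- match.arg(method)
  ca_coords <- as.matrix(ca_coords)
  n <- nrow(ca_coords)
  if (n < 3) abort_geometry("Helix axis needs at least 3 C-alpha positions.")
  centroid <- colMeans(ca_coords)
  X <- sweep(ca_coords, 2, centroid)
  if (max(abs(X)) < 1e-9) abort_geometry("Coincident points: helix axis undefined.")
  ev <- eigen(crossprod(X), symmetric = TRUE)
  if (method == "auto") {
    method <- if (ev$values[2] < 1e-6 * ev$values[1]) "pca" else "template"
  }
  if (method == "template") {
    template <- t(vapply(seq_len(n) - 1, function(i)
      c(2.3 * cos(100 * i * pi / 180), 2.3 * sin(100 * i * pi / 180), 1.5 * i),
      numeric(3)))
    tf <- kabsch_superpose(template, ca_coords)
    axis <- as.numeric(tf$rotation %*% c(0, 0, 1))
  } else {
    axis <- ev$vectors[, 1]
  }
  # orient toward increasing residue number
  if (sum(axis * (ca_coords[n, ] - ca_coords[1, ])) < 0) axis <- -axis
  list(axis = axis / vec_norm(axis), centroid = centroid)
}

#' Helix rotation angle between two structures
#'
#' Superposes structure B onto structure A on the anchor C-alpha set
#' (Kabsch), fits both helix axes, and returns
#' `acos(|axis_A . axis_B'|)` in degrees (range 0-90; the absolute value
#' removes the axis-sign ambiguity).
#'
#' @param struct_a,struct_b `md_structure` objects.
#' @param helix Selection expression for the helix C-alpha atoms, e.g.
#'   `"chain A and resid 241:245 and name CA"`.
#' @param anchor Selection expression for the anchor C-alpha atoms used in
#'   the superposition (e.g. the Rossmann-domain range).
#' @return Angle in degrees.
#' @export
helix_rotation_angle <- function(struct_a, struct_b, helix, anchor) {
  ha <- select_atoms(struct_a, helix); hb <- select_atoms(struct_b, helix)
  aa <- select_atoms(struct_a, anchor); ab <- select_atoms(struct_b, anchor)
  if (length(ha) < 3 || length(hb) < 3) abort_config("Helix selection needs >= 3 atoms in both structures.")
  if (length(aa) < 3 || length(aa) != length(ab)) {
    abort_config("Anchor selection needs >= 3 shared atoms in both structures.")
  }
  tf <- kabsch_superpose(coords(struct_b)[ab, , drop = FALSE],
                         coords(struct_a)[aa, , drop = FALSE])
  axis_a <- helix_axis(coords(struct_a)[ha, , drop = FALSE])$axis
  hb_xyz <- apply_transform(coords(struct_b)[hb, , drop = FALSE], tf)
  axis_b <- helix_axis(hb_xyz)$axis
  acos(min(1, abs(sum(axis_a * axis_b)))) * 180 / pi
}

#' Polar protein-ligand contact fingerprint
#'
#' Enumerates all (protein side-chain N/O atom, ligand N/O/P atom) pairs
#' within `cutoff`. Heavy-atom criterion only: crystal structures
#' typically lack hydrogens, so donor/acceptor proximity stands in for
#' explicit hydrogen bonds.
#'
#' @param structure An `md_structure`.
#' @param ligand Selection expression or indices for the ligand atoms.
#' @param cutoff Distance cutoff, Angstrom (default 3.5).
#' @return Tibble of class `polar_fingerprint`: `resid`, `resname`,
#'   `chain`, `protein_atom`, `ligand_atom`, `distance`, sorted by residue
#'   then distance.
#' @export
polar_fingerprint <- function(structure, ligand, cutoff = 3.5) {
  lig <- resolve_indices(structure, ligand)
  if (length(lig) == 0) abort_config("Ligand selection matched no atoms.")
  lig_polar <- lig[structure$element[lig] %in% c("N", "O", "P")]
  prot <- setdiff(seq_len(nrow(structure)), lig)
  prot <- prot[!structure$is_hetero[prot] &
                 structure$element[prot] %in% c("N", "O") &
                 !structure$name[prot] %in% BACKBONE_NAMES]
  rows <- list()
  xyz <- coords(structure)
  for (p in prot) {
    for (l in lig_polar) {
      d <- vec_norm(xyz[p, ] - xyz[l, ])
      if (d <= cutoff) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          resid = structure$resid[p],
          resname = structure$resname[p],
          chain = structure$chain[p],
          protein_atom = structure$name[p],
          ligand_atom = structure$name[l],
          distance = d
        )
      }
    }
  }
  out <- if (length(rows)) dplyr::arrange(dplyr::bind_rows(rows),
                                          .data$resid, .data$distance)
  else tibble::tibble(resid = integer(), resname = character(),
                      chain = character(), protein_atom = character(),
                      ligand_atom = character(), distance = numeric())
  class(out) <- c("polar_fingerprint", class(out))
  out
}

#' Compare two polar fingerprints
#'
#' Set difference keyed on (resid, protein atom name, ligand atom name).
#'
#' @param fp_a,fp_b [polar_fingerprint()] tibbles.
#' @return List of tibbles `only_a`, `only_b`, `shared`.
#' @export
fingerprint_diff <- function(fp_a, fp_b) {
  key <- function(fp) paste(fp$resid, fp$protein_atom, fp$ligand_atom, sep = "|")
  ka <- key(fp_a); kb <- key(fp_b)
  list(
    only_a = fp_a[!ka %in% kb, , drop = FALSE],
    only_b = fp_b[!kb %in% ka, , drop = FALSE],
    shared = fp_a[ka %in% kb, , drop = FALSE]
  )
}
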