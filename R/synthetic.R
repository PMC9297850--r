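# Seeded generator of synthetic ternary-complex ensembles with per-frame
# ground truth. The geometry is a connectivity-faithful statistical mimic
# of an IRED ternary complex, not a chemically minimized conformer: all
# downstream operations are purely geometric or graph-based, so only the
# planted criteria (face side, contact distances, H-bond geometry) matter.

# Deterministic RNG scope: Mersenne-Twister + inversion + rejection
# sampling, restored afterwards, so identical recipe+seed gives identical
# output on any platform.
with_fixed_seed <- function(seed, code) {
  withr::with_preserve_seed({
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    force(code)
  })
}

# Contact placement distances (Angstrom): planted-true hydrogens sit at
# CONTACT_NEAR from the imine N, planted-false at CONTACT_FAR. Both leave
# at least MARGIN = 0.2 A to the 2.5 A cutoff, and the generator refuses
# noise sigma above MARGIN / 4 so that drawn flags survive the noise.
CONTACT_NEAR <- 2.0
CONTACT_FAR <- 3.2
CONTACT_MARGIN <- 0.2
PYRAMIDAL_SHIFT <- 0.75

#' Recipe for a synthetic ternary-complex ensemble
#'
#' Defaults are the study conditions the generator emulates: a
#' 2-methylpyrroline-like substrate with re-face fraction 0.548 (the
#' re:si balance of a representative contact-conditioned trajectory),
#' per-residue contact occupancies for the S95/D171/W179 panel, and a
#' serine-aspartate dyad H-bonded in 80% of frames at donor-acceptor
#' distances of 2.6-3.0 Angstrom.
#'
#' @param n_frames Number of frames (default 2000).
#' @param re_fraction Fraction of frames with the re face toward the
#'   nearest hydride (default 0.548).
#' @param contact_occupancy Named numeric vector: residue id to contact
#'   occupancy in `[0, 1]`.
#' @param hbond_occupancy Dyad H-bond occupancy in `[0, 1]` (default 0.8).
#' @param da_range Donor-acceptor distance range (Angstrom) the dyad
#'   samples uniformly (default `c(2.6, 3.0)`).
#' @param noise_sigma Isotropic Gaussian coordinate noise sigma
#'   (Angstrom, default 0.04). Refused above 0.05 (= margin / 4) so that
#'   no planted flag can flip.
#' @param pyramidal_fraction Fraction of frames in which the prochiral
#'   center is pyramidalized beyond the planarity tolerance (those frames
#'   are indeterminate by construction; default 0).
#' @param seed Mandatory integer seed.
#' @return An object of class `ensemble_recipe`.
#' @export
ensemble_recipe <- function(n_frames = 2000,
                            re_fraction = 0.548,
                            contact_occupancy = c(
                              "95" = 0.000036, "171" = 0.000052, "179" = 0.084),
                            hbond_occupancy = 0.8,
                            da_range = c(2.6, 3.0),
                            noise_sigma = 0.04,
                            pyramidal_fraction = 0,
                            seed) {
  if (missing(seed)) abort_config("A recipe needs an explicit integer seed.")
  fracs <- c(re_fraction, contact_occupancy, hbond_occupancy, pyramidal_fraction)
  if (any(fracs < 0 | fracs > 1)) abort_config("All fractions must lie in [0, 1].")
  if (n_frames < 1) abort_config("n_frames must be >= 1.")
  if (da_range[1] >= da_range[2]) abort_config("da_range must satisfy lo < hi.")
  if (noise_sigma < 0) abort_config("noise_sigma must be >= 0.")
  if (noise_sigma > CONTACT_MARGIN / 4) {
    abort_config(sprintf(
      "noise_sigma %.3f would endanger the %.1f A contact margin (max %.3f); refusing.",
      noise_sigma, CONTACT_MARGIN, CONTACT_MARGIN / 4))
  }
  if (is.null(names(contact_occupancy)) && length(contact_occupancy) > 0) {
    abort_config("contact_occupancy must be named by residue id.")
  }
  structure(list(
    n_frames = as.integer(n_frames), re_fraction = re_fraction,
    contact_occupancy = contact_occupancy, hbond_occupancy = hbond_occupancy,
    da_range = da_range, noise_sigma = noise_sigma,
    pyramidal_fraction = pyramidal_fraction, seed = as.integer(seed)),
    class = "ensemble_recipe")
}

# Base (pre-noise) substrate geometry: planar 2-methylpyrroline-like
# fragment. C2 is the prochiral center; N1, C3, C6(methyl) its
# substituents at ~120 degrees in the z = 0 plane.
substrate_base <- function() {
  rbind(
    N1 = c(1.33, 0.000, 0),
    C2 = c(0.00, 0.000, 0),
    C3 = c(-0.75, 1.299, 0),
    C4 = c(0.60, 2.200, 0),
    C5 = c(1.90, 1.400, 0),
    C6 = c(-0.75, -1.299, 0)
  )
}

DYAD_SITE <- c(0, 12, 0)  # dyad region kept >10 A from the substrate

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

resname_for <- function(resid) {
  switch(as.character(resid), "95" = "SER", "171" = "ASP", "179" = "TRP", "ALA")
}

#' Generate a synthetic ternary-complex ensemble with ground truth
#'
#' Builds a minimal topology (planar imine substrate, nicotinamide-like
#' fragment with two C4 hydride hydrogens, donor residues with side-chain
#' hydrogens, and an S95/D171-style dyad) and, per frame: places the
#' substrate with its drawn re/si face toward the nearest hydride, each
#' donor residue's contact hydrogen inside (2.0 A) or outside (3.2 A) the
#' 2.5 A cutoff per its drawn flag, and the dyad hydrogen so that the
#' drawn H-bond flag holds at a donor-acceptor distance drawn from
#' `da_range`; then applies a random rigid motion to the whole frame and
#' adds isotropic Gaussian noise. The margins guarantee that no planted
#' flag flips at the admitted noise levels.
#'
#' @param recipe An [ensemble_recipe()].
#' @param replicate_id Replicate label (default `"sim"`).
#' @return List with `ensemble` (an `md_ensemble`), `truth` (tibble:
#'   `frame`, `face`, one `contact_<resid>` column per panel residue,
#'   `hbond`, `da`, `pyramidal`), `spec` (the [prochiral_spec()] on this
#'   topology), `graph` (substrate [molecular_graph()]), and `roles`
#'   (named selection expressions for downstream analyses).
#' @export
generate_ternary_ensemble <- function(recipe, replicate_id = "sim") {
  stopifnot(inherits(recipe, "ensemble_recipe"))
  sub <- substrate_base()
  contact_res <- as.integer(names(recipe$contact_occupancy))
  dyad_res <- c(95L, 171L)
  all_res <- sort(unique(c(contact_res, dyad_res)))

  atoms <- list()
  add <- function(name, element, resname, resid, chain, xyz, hetero) {
    atoms[[length(atoms) + 1L]] <<- tibble::tibble(
      name = name, element = element, resname = resname,
      resid = as.integer(resid), chain = chain,
      x = xyz[1], y = xyz[2], z = xyz[3], is_hetero = hetero)
  }
  for (nm in rownames(sub)) {
    add(nm, substr(nm, 1, 1), "MPL", 1L, "S", sub[nm, ], TRUE)
  }
  add("C4", "C", "NAI", 1L, "N", c(0, 0, 3.9), TRUE)
  add("H41", "H", "NAI", 1L, "N", c(0, 0, 2.8), TRUE)
  add("H42", "H", "NAI", 1L, "N", c(0, 0, 5.0), TRUE)
  n1 <- sub["N1", ]
  # one contact direction per panel residue, spread around the imine N
  dirs <- lapply(seq_along(contact_res), function(k) {
    phi <- (30 + 95 * (k - 1)) * pi / 180
    vec_unit(c(cos(phi), 0.25 * sin(phi), sin(phi)))
  })
  names(dirs) <- as.character(contact_res)
  for (res in all_res) {
    rn <- resname_for(res)
    ch <- "A"
    if (res %in% contact_res) {
      u <- dirs[[as.character(res)]]
      add("CB", "C", rn, res, ch, n1 + (CONTACT_FAR + 1.1) * u, FALSE)
      add("HB1", "H", rn, res, ch, n1 + CONTACT_FAR * u, FALSE)
    } else {
      add("CB", "C", rn, res, ch, DYAD_SITE + c(-2, -2, 0), FALSE)
    }
    if (res == 95L) {
      add("OG", "O", rn, res, ch, DYAD_SITE, FALSE)
      add("HG", "H", rn, res, ch, DYAD_SITE + c(1, 0, 0), FALSE)
    }
    if (res == 171L) {
      add("OD1", "O", rn, res, ch, DYAD_SITE + c(2.8, 0, 0), FALSE)
      add("CG", "C", rn, res, ch, DYAD_SITE + c(4.1, 0, 0), FALSE)
      add("OD2", "O", rn, res, ch, DYAD_SITE + c(4.7, 1.1, 0), FALSE)
    }
  }
  topo_tbl <- dplyr::bind_rows(atoms)
  topology <- md_structure(
    serial = seq_len(nrow(topo_tbl)), name = topo_tbl$name,
    element = topo_tbl$element, resname = topo_tbl$resname,
    resid = topo_tbl$resid, chain = topo_tbl$chain,
    coords = as.matrix(topo_tbl[, c("x", "y", "z")]),
    is_hetero = topo_tbl$is_hetero, source = "synthetic")

  idx_of <- function(expr) select_atoms(topology, expr)
  i_n1 <- idx_of("chain S and name N1")
  i_c2 <- idx_of("chain S and name C2")
  i_c3 <- idx_of("chain S and name C3")
  i_c6 <- idx_of("chain S and name C6")
  i_c4n <- idx_of("chain N and name C4")
  i_h41 <- idx_of("chain N and name H41")
  i_h42 <- idx_of("chain N and name H42")
  i_og <- idx_of("chain A and resid 95 and name OG")
  i_hg <- idx_of("chain A and resid 95 and name HG")
  i_od1 <- idx_of("chain A and resid 171 and name OD1")

  graph <- molecular_graph(
    topology$element,
    tibble::tibble(i = c(i_n1, i_c2, i_c2, i_c3,
                         idx_of("chain S and name C4"), idx_of("chain S and name C5")),
                   j = c(i_c2, i_c3, i_c6,
                         idx_of("chain S and name C4"),
                         idx_of("chain S and name C5"), i_n1),
                   order = c(2L, 1L, 1L, 1L, 1L, 1L)))
  ranking <- rank_substituents(graph, i_c2)
  spec <- prochiral_spec(i_c2, ranking$order)

  base <- coords(topology)
  # face normal of the base pose (priority-1 x priority-2 from the center):
  # its +z sign means the si face points to +z in the base frame.
  n_face <- vec_cross(base[spec$substituents[1], ] - base[i_c2, ],
                      base[spec$substituents[2], ] - base[i_c2, ])
  si_dir <- vec_unit(n_face)

  contact_idx <- lapply(as.character(contact_res), function(res) list(
    h = idx_of(sprintf("chain A and resid %s and name HB1", res)),
    cb = idx_of(sprintf("chain A and resid %s and name CB", res))))
  names(contact_idx) <- as.character(contact_res)

  sim <- with_fixed_seed(recipe$seed, {
    n <- recipe$n_frames
    face_draw <- ifelse(stats::runif(n) < recipe$re_fraction, "re", "si")
    pyramidal <- stats::runif(n) < recipe$pyramidal_fraction
    contact_draw <- lapply(recipe$contact_occupancy,
                           function(p) stats::runif(n) < p)
    hbond_draw <- stats::runif(n) < recipe$hbond_occupancy
    da_draw <- stats::runif(n, recipe$da_range[1], recipe$da_range[2])

    frames <- vector("list", n)
    for (f in seq_len(n)) {
      xyz <- base
      dir <- if (face_draw[f] == "re") -si_dir else si_dir
      xyz[i_h41, ] <- base[i_c2, ] + 2.8 * dir
      xyz[i_c4n, ] <- base[i_c2, ] + 3.9 * dir
      xyz[i_h42, ] <- base[i_c2, ] + 5.0 * dir
      if (pyramidal[f]) xyz[i_c2, ] <- xyz[i_c2, ] + PYRAMIDAL_SHIFT * si_dir
      for (res in names(contact_draw)) {
        u <- dirs[[res]]
        d <- if (contact_draw[[res]][f]) CONTACT_NEAR else CONTACT_FAR
        xyz[contact_idx[[res]]$h, ] <- base[i_n1, ] + d * u
        xyz[contact_idx[[res]]$cb, ] <- base[i_n1, ] + (d + 1.1) * u
      }
      # dyad: OD1 at the drawn DA distance from OG; H on the D->A line for
      # bonded frames (angle 180), behind the donor for unbonded (angle ~0)
      xyz[i_od1, ] <- base[i_og, ] + c(da_draw[f], 0, 0)
      xyz[i_hg, ] <- base[i_og, ] + c(if (hbond_draw[f]) 1 else -1, 0, 0)
      rot <- random_rotation()
      shift <- stats::runif(3, -10, 10)
      xyz <- sweep(xyz %*% t(rot), 2, shift, "+")
      if (recipe$noise_sigma > 0) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, recipe$noise_sigma),
                            ncol = 3)
      }
      frames[[f]] <- xyz
    }
    list(frames = frames, face_draw = face_draw, pyramidal = pyramidal,
         contact_draw = contact_draw, hbond_draw = hbond_draw,
         da_draw = da_draw)
  })
  truth <- tibble::tibble(
    frame = seq_len(recipe$n_frames),
    face = ifelse(sim$pyramidal, "indeterminate", sim$face_draw))
  for (res in names(sim$contact_draw)) {
    truth[[paste0("contact_", res)]] <- sim$contact_draw[[res]]
  }
  truth$hbond <- sim$hbond_draw
  truth$da <- sim$da_draw
  truth$pyramidal <- sim$pyramidal

  roles <- list(
    substrate_imine_N = "chain S and name N1",
    prochiral_center = "chain S and name C2",
    hydride_candidates = "chain N and name H41 H42",
    donor_residues = contact_res,
    donor_chain = "A",
    dyad = list(donor_residue = 95L, acceptor_residue = 171L,
                donor_atom = "OG", hydrogen_atom = "HG",
                acceptor_atoms = c("OD1", "OD2"))
  )
  list(
    ensemble = md_ensemble(topology, sim$frames, replicate_id = replicate_id),
    truth = truth, spec = spec, graph = graph, roles = roles
  )
}

#' Generate a structure pair with a planted helix rotation
#'
#' Structure A holds an ideal 5-residue C-alpha helix (rise 1.5 Angstrom,
#' twist 100 degrees per residue, residues 241-245) plus a rigid 12-residue
#' anchor scaffold. Structure B is A with the helix segment rotated by
#' `theta` degrees about an axis through the helix centroid perpendicular
#' to the helix principal axis; Gaussian noise is then added to all atoms
#' of both structures.
#'
#' @param theta Planted rotation angle in degrees, in (0, 90).
#' @param noise_sigma Per-coordinate Gaussian noise sigma (Angstrom).
#' @param seed Integer seed.
#' @return List with `structure_a`, `structure_b` and `truth`
#'   (list: `theta`, `helix`, `anchor` selection expressions).
#' @export
generate_rotated_helix_pair <- function(theta, noise_sigma = 0, seed) {
  if (theta <= 0 || theta >= 90) abort_config("theta must lie in (0, 90) degrees.")
  ideal_helix <- function(n, origin, perm = 1:3) {
    t(vapply(seq_len(n) - 1, function(i) {
      p <- c(2.3 * cos(100 * i * pi / 180), 2.3 * sin(100 * i * pi / 180), 1.5 * i)
      origin + p[perm]
    }, numeric(3)))
  }
  helix <- ideal_helix(5, c(0, 0, 0))
  anchor <- ideal_helix(12, c(12, 0, 0), perm = c(1, 3, 2))
  build <- function(helix_xyz, anchor_xyz) {
    md_structure(
      serial = 1:17, name = "CA", element = "C", resname = "ALA",
      resid = c(241:245, 1:12), chain = "A",
      coords = rbind(helix_xyz, anchor_xyz), is_hetero = FALSE,
      source = "synthetic")
  }
  ax <- helix_axis(helix)
  # rotation axis: x-hat made exactly perpendicular to the fitted axis
  p <- vec_unit(c(1, 0, 0) - sum(c(1, 0, 0) * ax$axis) * ax$axis)
  th <- theta * pi / 180
  K <- matrix(c(0, -p[3], p[2], p[3], 0, -p[1], -p[2], p[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  helix_b <- sweep(sweep(helix, 2, ax$centroid) %*% t(R), 2, ax$centroid, "+")
  with_fixed_seed(seed, {
    noise <- function(m) m + matrix(stats::rnorm(length(m), 0, noise_sigma), ncol = 3)
    a <- build(if (noise_sigma > 0) noise(helix) else helix,
               if (noise_sigma > 0) noise(anchor) else anchor)
    b <- build(if (noise_sigma > 0) noise(helix_b) else helix_b,
               if (noise_sigma > 0) noise(anchor) else anchor)
    list(structure_a = a, structure_b = b,
         truth = list(theta = theta,
                      helix = "chain A and resid 241:245 and name CA",
                      anchor = "chain A and resid 1:12 and name CA"))
  })
}

#' Write generator ground truth as JSON
#' @param truth The `truth` tibble from [generate_ternary_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
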