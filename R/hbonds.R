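#' Geometric hydrogen-bond test for one frame
#'
#' A donor-hydrogen-acceptor triple is hydrogen bonded when the
#' donor-acceptor (DA) distance is at most `max_da` and the D-H...A angle
#' (at the hydrogen) is at least `min_angle`. Defaults (3.5 Angstrom,
#' 120 degrees) follow common geometric practice in MD analysis; both are
#' configurable.
#'
#' @param frame n x 3 coordinate matrix.
#' @param donor,hydrogen,acceptor Atom indices.
#' @param max_da Maximum donor-acceptor distance, Angstrom.
#' @param min_angle Minimum D-H...A angle, degrees.
#' @return List with `bonded` (logical), `da` (Angstrom) and
#'   `angle` (degrees).
#' @export
is_hbond <- function(frame, donor, hydrogen, acceptor,
                     max_da = 3.5, min_angle = 120) {
  if (max_da <= 0) abort_config("max_da must be positive.")
  if (min_angle <= 0 || min_angle > 180) abort_config("min_angle must be in (0, 180].")
  d <- frame[donor, ]; h <- frame[hydrogen, ]; a <- frame[acceptor, ]
  da <- vec_norm(a - d)
  ang <- point_angle(d, h, a)
  list(bonded = da <= max_da && ang >= min_angle, da = da, angle = ang)
}

# Per-frame dyad evaluation over >=1 acceptor atoms (e.g. both carboxylate
# oxygens): bonded if ANY acceptor satisfies the criterion (counted once);
# the DA distance recorded is that of the nearest acceptor.
frame_hbond <- function(frame, donor, hydrogen, acceptors, max_da, min_angle) {
  res <- lapply(acceptors, function(a)
    is_hbond(frame, donor, hydrogen, a, max_da, min_angle))
  das <- vapply(res, `[[`, numeric(1), "da")
  list(bonded = any(vapply(res, `[[`, logical(1), "bonded")),
       da = min(das))
}

#' Hydrogen-bond frequency over donor-acceptor distance
#'
#' Every frame is assigned to the distance bin of its DA distance
#' (half-open bins `[lo, hi)`); the per-bin frequency is the fraction of
#' that bin's frames satisfying the H-bond criterion. Frames beyond
#' `max_da` still populate their distance bin (with frequency 0 unless the
#' angle alone rescued them, which it cannot); bins with no frames have
#' frequency `NA` ("no data", distinct from "never bonded"). The bin grid
#' is anchored at `range[1]` and extended automatically to cover all
#' observed distances.
#'
#' @param ensemble An `md_ensemble`.
#' @param donor,hydrogen Selection expressions or indices (single atoms).
#' @param acceptors Selection expression or indices; one or more atoms,
#'   any of which may accept (either-oxygen rule for carboxylates).
#' @param max_da,min_angle H-bond criterion (see [is_hbond()]).
#' @param bin_width Bin width in Angstrom (default 0.1).
#' @param range Nominal profile range in Angstrom (default `c(2.2, 5.0)`).
#' @return A tibble of class `hbond_profile` with columns `bin_lo`,
#'   `bin_hi`, `n_frames`, `n_bonded`, `frequency`, and attribute
#'   `occupancy` (overall bonded fraction).
#' @export
hbond_profile <- function(ensemble, donor, hydrogen, acceptors,
                          max_da = 3.5, min_angle = 120,
                          bin_width = 0.1, range = c(2.2, 5.0)) {
  if (bin_width <= 0) abort_config("bin_width must be positive.")
  if (n_frames(ensemble) == 0) abort_config("Ensemble has no frames.")
  topo <- ensemble$topology
  don <- resolve_single(topo, donor, "donor")
  hyd <- resolve_single(topo, hydrogen, "hydrogen")
  acc <- resolve_indices(topo, acceptors)
  if (length(acc) == 0) abort_config("Acceptor selection matched no atoms.")
  per_frame <- purrr::map(ensemble$frames, frame_hbond, donor = don,
                          hydrogen = hyd, acceptors = acc,
                          max_da = max_da, min_angle = min_angle)
  da <- vapply(per_frame, `[[`, numeric(1), "da")
  bonded <- vapply(per_frame, `[[`, logical(1), "bonded")

  lo0 <- range[1]
  lo0 <- lo0 - bin_width * max(0, ceiling((lo0 - min(da)) / bin_width))
  hi0 <- max(range[2], lo0 + bin_width * ceiling((max(da) + 1e-9 - lo0) / bin_width))
  edges <- seq(lo0, hi0 + bin_width / 2, by = bin_width)
  bin <- findInterval(da, edges, rightmost.closed = FALSE)
  n_bins <- length(edges) - 1L
  counts <- tabulate(bin, nbins = n_bins)
  n_bonded <- vapply(seq_len(n_bins), function(b) sum(bonded[bin == b]), integer(1))
  out <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    n_frames = counts,
    n_bonded = n_bonded,
    frequency = ifelse(counts > 0, n_bonded / counts, NA_real_)
  )
  attr(out, "occupancy") <- mean(bonded)
  attr(out, "n_total") <- length(bonded)
  attr(out, "criterion") <- list(max_da = max_da, min_angle = min_angle)
  class(out) <- c("hbond_profile", class(out))
  out
}

#' Catalytic-dyad hydrogen-bond occupancy and distance profile
#'
#' Serine-to-aspartate dyad by default: donor hydroxyl OG with its
#' hydrogen HG, accepting on *either* carboxylate oxygen (OD1/OD2) of the
#' acceptor residue. Direction is reversible via the explicit selections.
#'
#' @param ensemble An `md_ensemble`.
#' @param donor_residue,acceptor_residue Residue ids (default 95 and 171).
#' @param chain Chain id of both residues (default "A").
#' @param donor_atom,hydrogen_atom Donor heavy-atom and hydrogen names
#'   (defaults `"OG"`, `"HG"`).
#' @param acceptor_atoms Acceptor atom names (default `c("OD1", "OD2")`).
#' @inheritParams hbond_profile
#' @return List with `occupancy` (fraction of bonded frames), `n_frames`,
#'   and `profile` (an [hbond_profile()] tibble).
#' @export
dyad_occupancy <- function(ensemble, donor_residue = 95, acceptor_residue = 171,
                           chain = "A", donor_atom = "OG", hydrogen_atom = "HG",
                           acceptor_atoms = c("OD1", "OD2"),
                           max_da = 3.5, min_angle = 120,
                           bin_width = 0.1, range = c(2.2, 5.0)) {
  topo <- ensemble$topology
  sel <- function(res, names) sprintf("chain %s and resid %d and name %s",
                                      chain, res, paste(names, collapse = " "))
  acc_idx <- resolve_indices(topo, sel(acceptor_residue, acceptor_atoms))
  if (length(acc_idx) < 1) {
    abort_config("Acceptor residue has none of the requested acceptor atoms.")
  }
  prof <- hbond_profile(
    ensemble,
    donor = sel(donor_residue, donor_atom),
    hydrogen = sel(donor_residue, hydrogen_atom),
    acceptors = acc_idx,
    max_da = max_da, min_angle = min_angle,
    bin_width = bin_width, range = range
  )
  list(occupancy = attr(prof, "occupancy"),
       n_frames = attr(prof, "n_total"),
       profile = prof)
}

#' Write an H-bond distance profile as TSV and JSON
#'
#' @param profile An [hbond_profile()] tibble.
#' @param tsv,json Output paths (`NULL` to skip either).
#' @return The profile, invisibly.
#' @export
write_hbond_profile <- function(profile, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) readr::write_tsv(tibble::as_tibble(profile), tsv)
  if (!is.null(json)) {
    jsonlite::write_json(list(
      occupancy = attr(profile, "occupancy"),
      n_frames = attr(profile, "n_total"),
      criterion = attr(profile, "criterion"),
      bins = tibble::as_tibble(profile)
    ), json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(profile)
}
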