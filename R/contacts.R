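#' Minimum hydrogen-acceptor distance in one frame
#'
#' @param frame n x 3 coordinate matrix.
#' @param hydrogens Integer indices of the hydrogen atoms considered.
#' @param acceptor Atom index of the acceptor (the substrate imine N).
#' @return Minimum Euclidean distance in Angstrom.
#' @export
min_hydrogen_distance <- function(frame, hydrogens, acceptor) {
  if (length(hydrogens) == 0) {
    abort_config("No hydrogen atoms in the set (residue has no hydrogens under this policy).")
  }
  hx <- frame[hydrogens, , drop = FALSE]
  ax <- matrix(frame[acceptor, ], nrow(hx), 3, byrow = TRUE)
  min(sqrt(rowSums((hx - ax)^2)))
}

#' Close-contact frequency of a residue's hydrogens over one replicate
#'
#' A frame is a contact when the minimum distance between the selected
#' hydrogens and the acceptor is strictly below `cutoff` (the criterion is
#' `< 2.5` Angstrom by default, so a distance of exactly 2.5 is *not* a
#' contact).
#'
#' @param ensemble An `md_ensemble` (one replicate).
#' @param hydrogens Selection expression or indices of the residue's
#'   hydrogens (default policy: all side-chain hydrogens of the residue).
#' @param acceptor Selection expression or index; must resolve to exactly
#'   one atom.
#' @param cutoff Contact cutoff in Angstrom (default 2.5, strict `<`).
#' @return One-row tibble: `replicate_id`, `n_frames`, `n_contact`,
#'   `frequency`, and `mask` (list-column with the per-frame logical
#'   contact mask).
#' @export
contact_frequency <- function(ensemble, hydrogens, acceptor, cutoff = 2.5) {
  if (cutoff <= 0) abort_config("Contact cutoff must be positive.")
  hyd <- resolve_indices(ensemble$topology, hydrogens)
  acc <- resolve_single(ensemble$topology, acceptor, "acceptor")
  d <- vapply(ensemble$frames, min_hydrogen_distance,
              numeric(1), hydrogens = hyd, acceptor = acc)
  mask <- d < cutoff
  tibble::tibble(
    replicate_id = ensemble$replicate_id,
    n_frames = length(mask),
    n_contact = sum(mask),
    frequency = mean(mask),
    mask = list(mask)
  )
}

#' Mean contact frequency over replicates
#'
#' Unweighted arithmetic mean of per-replicate frequencies (replicates of
#' equal length, as in equal-duration MD runs).
#'
#' @param frequencies Numeric vector of per-replicate frequencies.
#' @return The mean frequency.
#' @export
aggregate_replicates <- function(frequencies) {
  if (length(frequencies) == 0) abort_config("Need at least one replicate frequency.")
  mean(frequencies)
}

#' Count face labels, optionally over masked frames
#'
#' @param series A [face_series()] tibble.
#' @param mask Optional logical vector (same length) restricting the count
#'   to contact frames.
#' @param exclude_indeterminate When `TRUE`, indeterminate frames are
#'   dropped before counting (they then contribute to none of the counts).
#' @return One-row tibble with `n_re`, `n_si`, `n_indeterminate`.
#' @export
face_counts <- function(series, mask = NULL, exclude_indeterminate = FALSE) {
  labels <- series$face
  if (!is.null(mask)) {
    if (length(mask) != length(labels)) {
      abort_config("Mask length does not match the face series.")
    }
    labels <- labels[mask]
  }
  if (exclude_indeterminate) labels <- labels[labels != "indeterminate"]
  tibble::tibble(
    n_re = sum(labels == "re"),
    n_si = sum(labels == "si"),
    n_indeterminate = sum(labels == "indeterminate")
  )
}

#' Per-residue contact/stereopreference report over systems
#'
#' For each (system, residue) pair: the mean close-contact frequency across
#' that system's replicates, and the re/si face counts over the frames in
#' which that residue's contact criterion holds (per-residue conditioning —
#' the ratio printed under each residue column). An unconditional
#' whole-trajectory ratio per system is also computed, since conditioning
#' conventions vary between reports.
#'
#' @param systems A list of systems; each system is a list with elements
#'   `label` (string) and `ensembles` (list of `md_ensemble` replicates
#'   sharing one topology).
#' @param spec A [prochiral_spec()] (indices on the shared topology).
#' @param hydride_candidates Selection or indices of hydride candidates.
#' @param acceptor Selection or index of the imine nitrogen.
#' @param residues Integer vector of donor-residue ids (the residue panel).
#' @param chain Chain of the donor residues (default `"A"`).
#' @param cutoff Contact cutoff, Angstrom (default 2.5, strict `<`).
#' @param hydrogen_policy `"all-sidechain"` (default) or `"polar-only"`
#'   (hydrogens bonded to N/O/S heavy atoms are approximated as those whose
#'   nearest non-H atom in the residue is N/O/S in the topology frame).
#' @param exclude_indeterminate Drop indeterminate frames before counting.
#' @param standard_positions Optional named vector mapping residue id to a
#'   family-numbering alias printed alongside (metadata only).
#' @return A tibble of class `contact_report`: one row per
#'   (system, residue) with `system`, `residue`, `standard_position`,
#'   `mean_frequency`, `n_re`, `n_si`, `n_indeterminate`,
#'   `ratio_conditioned`, `ratio_unconditional`.
#' @export
contact_report <- function(systems, spec, hydride_candidates, acceptor,
                           residues, chain = "A", cutoff = 2.5,
                           hydrogen_policy = c("all-sidechain", "polar-only"),
                           exclude_indeterminate = FALSE,
                           standard_positions = NULL) {
  hydrogen_policy <- match.arg(hydrogen_policy)
  if (length(residues) == 0) abort_config("Residue panel is empty.")
  rows <- list()
  for (sys in systems) {
    label <- sys$label
    ensembles <- sys$ensembles
    topo <- ensembles[[1]]$topology
    series_list <- purrr::map(ensembles, face_series,
                              spec = spec, hydride_candidates = hydride_candidates)
    all_labels <- dplyr::bind_rows(series_list)
    uncond <- face_counts(all_labels, exclude_indeterminate = exclude_indeterminate)
    for (res in residues) {
      hyd_sel <- residue_hydrogens(topo, res, chain, hydrogen_policy)
      stats <- purrr::map(ensembles, contact_frequency,
                          hydrogens = hyd_sel, acceptor = acceptor, cutoff = cutoff)
      freqs <- vapply(stats, function(s) s$frequency, numeric(1))
      counts <- purrr::map2(series_list, stats, function(se, st) {
        face_counts(se, mask = st$mask[[1]],
                    exclude_indeterminate = exclude_indeterminate)
      })
      counts <- dplyr::summarise(dplyr::bind_rows(counts),
                                 dplyr::across(dplyr::everything(), sum))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        system = label,
        residue = as.integer(res),
        standard_position = if (!is.null(standard_positions))
          as.character(standard_positions[as.character(res)]) else NA_character_,
        mean_frequency = aggregate_replicates(freqs),
        n_re = counts$n_re,
        n_si = counts$n_si,
        n_indeterminate = counts$n_indeterminate,
        ratio_conditioned = ratio_label(counts$n_re, counts$n_si),
        ratio_unconditional = ratio_label(uncond$n_re, uncond$n_si)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "criterion") <- list(cutoff = cutoff, hydrogen_policy = hydrogen_policy,
                                 exclude_indeterminate = exclude_indeterminate)
  attr(out, "n_replicates") <- vapply(systems, function(s) length(s$ensembles), integer(1))
  class(out) <- c("contact_report", class(out))
  out
}

# Selection of a residue's hydrogen atoms under a policy.
residue_hydrogens <- function(topology, resid, chain, policy) {
  idx <- select_atoms(topology, sprintf("chain %s and resid %d and element H and sidechain",
                                        chain, resid))
  if (policy == "polar-only" && length(idx) > 0) {
    heavy <- select_atoms(topology, sprintf("chain %s and resid %d and not element H",
                                            chain, resid))
    xyz <- coords(topology)
    keep <- vapply(idx, function(h) {
      d <- sqrt(rowSums((xyz[heavy, , drop = FALSE] -
                           matrix(xyz[h, ], length(heavy), 3, byrow = TRUE))^2))
      topology$element[heavy[which.min(d)]] %in% c("N", "O", "S")
    }, logical(1))
    idx <- idx[keep]
  }
  idx
}

ratio_label <- function(n_re, n_si) sprintf("%d : %d", n_re, n_si)

#' Render a frequency with report-style significant digits
#'
#' Frequencies are kept at full precision internally; reports print them
#' with a fixed number of significant digits (so e.g. 3.6e-5 renders as
#' `0.000036`).
#'
#' @param x Numeric frequency.
#' @param digits Significant digits (default 2).
#' @return Character vector.
#' @export
format_frequency <- function(x, digits = 2) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v == 0) return("0.0")
    format(signif(v, digits), scientific = FALSE, trim = TRUE)
  }, character(1))
}

#' Write a contact report as TSV and JSON
#'
#' @param report A [contact_report()] tibble.
#' @param tsv Path of the TSV output (or `NULL` to skip).
#' @param json Path of the JSON output (or `NULL` to skip).
#' @param digits Significant digits for the rendered frequency column.
#' @return The report, invisibly.
#' @export
write_contact_report <- function(report, tsv = NULL, json = NULL, digits = 2) {
  out <- tibble::as_tibble(report)
  out$mean_frequency_printed <- format_frequency(out$mean_frequency, digits)
  if (!is.null(tsv)) readr::write_tsv(out, tsv)
  if (!is.null(json)) {
    jsonlite::write_json(list(
      criterion = attr(report, "criterion"),
      n_replicates = attr(report, "n_replicates"),
      rows = out
    ), json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
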