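#' Build a molecular graph from elements and a bond list
#'
#' Connectivity for substituent priority ranking. Bond orders are integers;
#' a double bond is expanded as phantom duplicate atoms during ranking, per
#' the Cahn-Ingold-Prelog (CIP) convention.
#'
#' @param elements Character vector of element symbols, one per atom; atom
#'   indices in `bonds` refer to positions in this vector.
#' @param bonds Data frame (or tibble) with integer columns `i`, `j` and
#'   `order` (bond order, default 1 when the column is missing).
#' @return An object of class `molecular_graph`.
#' @export
molecular_graph <- function(elements, bonds) {
  if (is.matrix(bonds)) {
    colnames(bonds) <- c("i", "j", "order")[seq_len(ncol(bonds))]
    bonds <- tibble::as_tibble(bonds)
  } else {
    bonds <- tibble::as_tibble(bonds)
  }
  if (!"order" %in% names(bonds)) bonds$order <- 1L
  names(bonds)[1:2] <- c("i", "j")
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  bonds$order <- as.integer(bonds$order)
  if (any(bonds$order < 1)) abort_config("Bond orders must be >= 1.")
  n <- length(elements)
  if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)) {
    abort_config("Bond indices out of range.")
  }
  bad <- !elements %in% names(ATOMIC_NUMBERS)
  if (any(bad)) {
    abort_config(sprintf("Element(s) without atomic number: %s",
                         paste(unique(elements[bad]), collapse = ", ")))
  }
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]; o <- bonds$order[k]
    adj[[i]] <- rbind(adj[[i]], c(j, o))
    adj[[j]] <- rbind(adj[[j]], c(i, o))
  }
  structure(list(elements = elements, bonds = bonds, adjacency = adj, n = n),
            class = "molecular_graph")
}

graph_neighbors <- function(graph, atom) {
  a <- graph$adjacency[[atom]]
  if (is.null(a)) matrix(integer(0), ncol = 2) else a
}

# Sphere-wise ligand expansion for CIP ranking. Each ligand (substituent
# branch seen from the center) is grown breadth-first as a hierarchical
# digraph: traversal never returns along the edge it came in by, a ring
# closure contributes a childless duplicate of the closing atom, and a bond
# of order k contributes (k - 1) childless phantom duplicates on both ends.
# Returns, per sphere, the decreasingly sorted atomic-number multiset.
ligand_spheres <- function(graph, center, substituent, max_depth = 6) {
  z <- function(el) ATOMIC_NUMBERS[[el]]
  # frontier entries: atom, parent, path (atom indices from center)
  frontier <- list(list(atom = substituent, parent = center,
                        path = c(center, substituent), dup = FALSE))
  spheres <- list(sort(z(graph$elements[substituent]), decreasing = TRUE))
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    zs <- numeric(0)
    for (node in frontier) {
      if (node$dup) next  # duplicates have no children
      nb <- graph_neighbors(graph, node$atom)
      if (nrow(nb) == 0) next
      for (r in seq_len(nrow(nb))) {
        other <- nb[r, 1]; ord <- nb[r, 2]
        extra <- ord - 1L  # phantom duplicates from the multiple bond
        if (other == node$parent) {
          if (extra > 0) {
            zs <- c(zs, rep(z(graph$elements[other]), extra))
            for (e in seq_len(extra)) nxt[[length(nxt) + 1L]] <-
              list(atom = other, parent = node$atom, path = node$path, dup = TRUE)
          }
          next
        }
        zs <- c(zs, rep(z(graph$elements[other]), 1L + extra))
        is_ring_closure <- other %in% node$path
        nxt[[length(nxt) + 1L]] <- list(
          atom = other, parent = node$atom,
          path = c(node$path, other), dup = is_ring_closure)
        if (extra > 0) for (e in seq_len(extra)) nxt[[length(nxt) + 1L]] <-
          list(atom = other, parent = node$atom, path = node$path, dup = TRUE)
      }
    }
    spheres[[depth + 1L]] <- sort(zs, decreasing = TRUE)
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  spheres
}

# Lexicographic comparison of two sphere lists: -1, 0, +1.
# Within a sphere, multisets are compared element-wise after descending
# sort; a missing position counts as atomic number 0 (CIP phantom).
compare_spheres <- function(sa, sb) {
  for (d in seq_len(max(length(sa), length(sb)))) {
    a <- if (d <= length(sa)) sa[[d]] else numeric(0)
    b <- if (d <= length(sb)) sb[[d]] else numeric(0)
    len <- max(length(a), length(b))
    if (len == 0) next
    a <- c(a, rep(0, len - length(a)))
    b <- c(b, rep(0, len - length(b)))
    cmp <- sign(a - b)
    nz <- which(cmp != 0)
    if (length(nz) > 0) return(cmp[nz[1]])
  }
  0
}

#' Rank the three substituents of a prochiral sp2 center
#'
#' Bounded CIP subset: substituent branches are compared sphere by sphere
#' (atomic-number multisets, descending), with multiple bonds expanded as
#' phantom duplicate atoms and ring closures as childless duplicates.
#' Search depth is 6 spheres; branches still tied at that depth are
#' reported as a tie and the caller must supply the priority order
#' manually. Isotopes and stereo-descriptors are not considered.
#'
#' @param graph A [molecular_graph()].
#' @param center Atom index of the sp2 carbon; must have exactly 3 bonded
#'   substituents (counting hydrogens present in the graph).
#' @param max_depth Sphere search depth (default 6).
#' @return A list with `order` (substituent atom indices, highest priority
#'   first) and `tie` (`TRUE` when two branches are indistinguishable; the
#'   relative order of tied branches is then by atom index and must not be
#'   used for face assignment).
#' @export
rank_substituents <- function(graph, center, max_depth = 6) {
  nb <- graph_neighbors(graph, center)
  subs <- nb[, 1]
  if (length(subs) != 3) {
    abort_config(sprintf(
      "Prochiral center must have exactly 3 substituents, found %d.", length(subs)))
  }
  spheres <- lapply(subs, function(s) ligand_spheres(graph, center, s, max_depth))
  cmp <- function(i, j) compare_spheres(spheres[[i]], spheres[[j]])
  idx <- order(vapply(1:3, function(i) {
    # score: number of branches this one beats (0..2), stable by atom index
    sum(vapply(1:3, function(j) if (i == j) 0L else as.integer(cmp(i, j) > 0), integer(1)))
  }, integer(1)), -subs, decreasing = TRUE)
  tie <- cmp(idx[1], idx[2]) == 0 || cmp(idx[2], idx[3]) == 0
  list(order = subs[idx], tie = tie)
}

#' Specify a prochiral center
#'
#' @param center Atom index of the sp2 carbon (the carbon reduced in the
#'   C=N bond).
#' @param substituents Integer vector of the 3 atom indices bonded to the
#'   center, in decreasing CIP priority (use [rank_substituents()]).
#' @param planarity_tol Maximum out-of-plane displacement (Angstrom) of the
#'   center from its substituent plane before a frame is called
#'   indeterminate. Default 0.25.
#' @param degeneracy_eps Minimum |unit-normal . (probe - center)| (Angstrom)
#'   below which the probe is considered in-plane and the frame
#'   indeterminate. Default 0.05.
#' @return An object of class `prochiral_spec`.
#' @export
prochiral_spec <- function(center, substituents, planarity_tol = 0.25,
                           degeneracy_eps = 0.05) {
  substituents <- as.integer(substituents)
  if (length(substituents) != 3 || anyDuplicated(substituents)) {
    abort_config("A prochiral center needs 3 distinct substituent indices.")
  }
  if (center %in% substituents) abort_config("Center cannot be its own substituent.")
  structure(list(center = as.integer(center), substituents = substituents,
                 planarity_tol = planarity_tol, degeneracy_eps = degeneracy_eps),
            class = "prochiral_spec")
}

#' Classify the prochiral face presented to a probe point
#'
#' With substituent positions a, b, c in decreasing priority and center x,
#' the face normal is n = (a - x) x (b - x). The face toward the probe is
#' *re* when, viewed from the probe, a -> b -> c runs clockwise, i.e.
#' sign(n . (probe - x)) < 0; *si* when > 0. The frame is indeterminate
#' when the center lies more than `planarity_tol` out of the substituent
#' plane (pyramidalized) or the probe is within `degeneracy_eps` of the
#' plane.
#'
#' @param frame n x 3 coordinate matrix (topology order).
#' @param spec A [prochiral_spec()].
#' @param probe 3-vector: position of the chosen hydride (or fallback
#'   probe point, e.g. the nicotinamide C4 for hydrogen-free input).
#' @return `"re"`, `"si"` or `"indeterminate"`.
#' @export
classify_face <- function(frame, spec, probe) {
  x <- frame[spec$center, ]
  a <- frame[spec$substituents[1], ]
  b <- frame[spec$substituents[2], ]
  c_ <- frame[spec$substituents[3], ]
  plane_n <- vec_cross(b - a, c_ - a)
  if (vec_norm(plane_n) < 1e-9) {
    abort_geometry("Substituent triangle has zero area; face is undefined.")
  }
  out_of_plane <- abs(sum(vec_unit(plane_n) * (x - a)))
  if (out_of_plane > spec$planarity_tol) return("indeterminate")
  n <- vec_cross(a - x, b - x)
  if (vec_norm(n) < 1e-9) {
    abort_geometry("Priority-1/2 substituents are collinear with the center.")
  }
  s <- sum(vec_unit(n) * (probe - x))
  if (abs(s) < spec$degeneracy_eps) return("indeterminate")
  if (s < 0) "re" else "si"
}

#' Find the nearest hydride candidate to the prochiral center
#'
#' @param frame n x 3 coordinate matrix.
#' @param candidates Integer atom indices of the hydride candidates
#'   (typically the two C4 hydrogens of the nicotinamide ring).
#' @param center Atom index of the prochiral carbon.
#' @return List with `atom` (index of the nearest candidate; exact ties go
#'   to the lowest index) and `distance` (Angstrom).
#' @export
nearest_hydride <- function(frame, candidates, center) {
  if (length(candidates) == 0) abort_config("Hydride candidate list is empty.")
  d <- sqrt(rowSums((frame[candidates, , drop = FALSE] -
                       matrix(frame[center, ], length(candidates), 3, byrow = TRUE))^2))
  best <- which(d == min(d))
  pick <- best[which.min(candidates[best])]
  list(atom = candidates[pick], distance = d[pick])
}

#' Per-frame prochiral face series over an ensemble
#'
#' Applies [nearest_hydride()] then [classify_face()] to every frame: the
#' probe is the nearest hydride hydrogen of that frame (chosen per frame).
#'
#' @param ensemble An `md_ensemble`.
#' @param spec A [prochiral_spec()].
#' @param hydride_candidates Selection expression or integer atom indices
#'   of the hydride candidates.
#' @return A tibble of class `face_series` with columns `frame`, `face`
#'   (factor re/si/indeterminate), `hydride_serial`, `hydride_distance`.
#' @export
face_series <- function(ensemble, spec, hydride_candidates) {
  cand <- resolve_indices(ensemble$topology, hydride_candidates)
  if (length(cand) == 0) abort_config("Hydride candidate selection matched no atoms.")
  rows <- purrr::map(seq_along(ensemble$frames), function(i) {
    fr <- ensemble$frames[[i]]
    hh <- nearest_hydride(fr, cand, spec$center)
    tibble::tibble(
      frame = i,
      face = classify_face(fr, spec, fr[hh$atom, ]),
      hydride_serial = ensemble$topology$serial[hh$atom],
      hydride_distance = hh$distance
    )
  })
  out <- dplyr::bind_rows(rows)
  out$face <- factor(out$face, levels = c("re", "si", "indeterminate"))
  attr(out, "replicate_id") <- ensemble$replicate_id
  class(out) <- c("face_series", class(out))
  out
}

# Accept either a selection expression or raw indices.
resolve_indices <- function(topology, sel) {
  if (is.character(sel)) select_atoms(topology, sel) else as.integer(sel)
}

# Same, but insist on exactly one atom (used for e.g. the imine nitrogen).
resolve_single <- function(topology, sel, role = "selection") {
  idx <- resolve_indices(topology, sel)
  if (length(idx) != 1) {
    abort_config(sprintf("Role '%s' must resolve to exactly 1 atom, got %d.",
                         role, length(idx)))
  }
  idx
}
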