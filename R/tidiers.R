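#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a face series into per-label counts
#'
#' @param x A [face_series()] tibble.
#' @param ... Unused.
#' @return Tibble with `face`, `n`, `fraction`.
#' @method tidy face_series
#' @export
tidy.face_series <- function(x, ...) {
  out <- dplyr::count(tibble::as_tibble(x), .data$face, .drop = FALSE)
  out$fraction <- out$n / sum(out$n)
  out
}

#' One-row summary of a face series
#'
#' @param x A [face_series()] tibble.
#' @param ... Unused.
#' @return Tibble with `n_frames`, `n_re`, `n_si`, `n_indeterminate`,
#'   `re_fraction` (of determinate frames) and `mean_hydride_distance`.
#' @method glance face_series
#' @export
glance.face_series <- function(x, ...) {
  det <- x$face[x$face != "indeterminate"]
  tibble::tibble(
    n_frames = nrow(x),
    n_re = sum(x$face == "re"),
    n_si = sum(x$face == "si"),
    n_indeterminate = sum(x$face == "indeterminate"),
    re_fraction = if (length(det)) mean(det == "re") else NA_real_,
    mean_hydride_distance = mean(x$hydride_distance)
  )
}

#' Tidy an H-bond distance profile (bins as rows)
#' @param x An [hbond_profile()] tibble.
#' @param ... Unused.
#' @method tidy hbond_profile
#' @export
tidy.hbond_profile <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of an H-bond profile
#' @param x An [hbond_profile()] tibble.
#' @param ... Unused.
#' @return Tibble with `occupancy`, `n_frames`, `n_bins_populated`.
#' @method glance hbond_profile
#' @export
glance.hbond_profile <- function(x, ...) {
  tibble::tibble(
    occupancy = attr(x, "occupancy"),
    n_frames = attr(x, "n_total"),
    n_bins_populated = sum(x$n_frames > 0)
  )
}

#' Tidy a rigid transform (rotation matrix entries as rows)
#' @param x A `rigid_transform` from [kabsch_superpose()].
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `rotation`, plus the translation.
#' @method tidy rigid_transform
#' @export
tidy.rigid_transform <- function(x, ...) {
  tibble::tibble(
    row = rep(1:3, each = 3), col = rep(1:3, 3),
    rotation = as.numeric(t(x$rotation)),
    translation = rep(x$translation, each = 3)
  )
}

#' One-row summary of a rigid transform
#' @param x A `rigid_transform`.
#' @param ... Unused.
#' @return Tibble with `rmsd`, `det`, `angle_deg` (rotation magnitude).
#' @method glance rigid_transform
#' @export
glance.rigid_transform <- function(x, ...) {
  tr <- sum(diag(x$rotation))
  tibble::tibble(
    rmsd = x$rmsd,
    det = det(x$rotation),
    angle_deg = acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
  )
}
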