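#' Construct an ensemble (frame series over one topology)
#'
#' An ensemble bundles a topology (`md_structure`; its atom order defines
#' every frame's coordinate order) with a list of coordinate matrices and a
#' replicate label. One ensemble corresponds to one MD replicate.
#'
#' @param topology An `md_structure`.
#' @param frames List of n_atoms x 3 coordinate matrices (Angstrom).
#' @param replicate_id Replicate label.
#' @param dt_ps Optional frame spacing in picoseconds (metadata only; it
#'   never enters any statistic).
#' @return An object of class `md_ensemble`.
#' @export
md_ensemble <- function(topology, frames, replicate_id = "rep1", dt_ps = NA_real_) {
  if (length(frames) < 1) abort_format("An ensemble needs at least one frame.")
  n <- nrow(topology)
  for (i in seq_along(frames)) {
    frames[[i]] <- matrix(as.numeric(frames[[i]]), ncol = 3)
    if (nrow(frames[[i]]) != n) {
      abort_format(sprintf(
        "Frame %d has %d atoms but the topology has %d.", i, nrow(frames[[i]]), n))
    }
  }
  structure(
    list(topology = topology, frames = frames,
         replicate_id = replicate_id, dt_ps = dt_ps),
    class = "md_ensemble"
  )
}

#' @export
print.md_ensemble <- function(x, ...) {
  cat(sprintf("<md_ensemble> %s: %d frames x %d atoms\n",
              x$replicate_id, length(x$frames), nrow(x$topology)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble An `md_ensemble`.
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

#' Load an ensemble from PDB or XYZ frame files
#'
#' Frames from several files are concatenated in path order. All files must
#' share the atom count and order of the topology. XYZ files carry no
#' residue metadata, so an explicit `topology` is required for them.
#'
#' @param paths Character vector of file paths (multi-model PDB or XYZ).
#' @param topology Optional `md_structure`; defaults to the first PDB model.
#' @param format `"pdb"` or `"xyz"`; guessed from the first file's extension
#'   when `NULL`.
#' @param replicate_id Replicate label; defaults to the first file's stem.
#' @param dt_ps Optional frame spacing (ps), stored as metadata.
#' @return An `md_ensemble`.
#' @export
load_ensemble <- function(paths, topology = NULL, format = NULL,
                          replicate_id = NULL, dt_ps = NA_real_) {
  if (length(paths) < 1) abort_config("No ensemble files given.")
  if (is.null(format)) {
    format <- if (grepl("\\.xyz$", paths[1], ignore.case = TRUE)) "xyz" else "pdb"
  }
  format <- match.arg(format, c("pdb", "xyz"))
  if (format == "xyz" && is.null(topology)) {
    abort_config("XYZ frame series require an explicit topology structure.")
  }
  frames <- list()
  for (p in paths) {
    if (format == "pdb") {
      models <- read_pdb(p)
      if (is.null(topology)) topology <- models[[1]]
      new_frames <- lapply(models, coords)
    } else {
      new_frames <- read_xyz(p)
    }
    for (k in seq_along(new_frames)) {
      if (nrow(new_frames[[k]]) != nrow(topology)) {
        abort_format(sprintf(
          "Atom-count mismatch in '%s' (frame %d: %d atoms, topology: %d).",
          p, k, nrow(new_frames[[k]]), nrow(topology)))
      }
    }
    frames <- c(frames, new_frames)
  }
  if (is.null(replicate_id)) {
    replicate_id <- sub("\\.[^.]*$", "", basename(paths[1]))
  }
  md_ensemble(topology, frames, replicate_id = replicate_id, dt_ps = dt_ps)
}
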