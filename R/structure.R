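#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Element symbols accepted in the atom table (common biomolecular subset plus
# the metals routinely seen in PDB entries).
PERIODIC_SYMBOLS <- c(
  "H", "D", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg",
  "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
  "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb",
  "Sr", "Y", "Zr", "Mo", "Ru", "Rh", "Pd", "Ag", "Cd", "Sn", "Sb", "Te",
  "I", "Xe", "Cs", "Ba", "W", "Pt", "Au", "Hg", "Pb", "Bi", "U"
)

ATOMIC_NUMBERS <- c(
  H = 1, D = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9,
  Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17,
  Ar = 18, K = 19, Ca = 20, Fe = 26, Cu = 29, Zn = 30, Se = 34, Br = 35,
  I = 53
)

#' Build a structure atom table
#'
#' A structure is a tibble with one row per atom and columns
#' `serial`, `name`, `element`, `resname`, `resid`, `chain`, `x`, `y`, `z`,
#' `is_hetero`. Residue numbering is 1-based and kept exactly as in the
#' source file; atom order is the topology order used by every ensemble
#' frame.
#'
#' @param serial Integer atom serial numbers (unique within a model).
#' @param name Atom names (PDB convention, e.g. `"CA"`, `"OD1"`).
#' @param element Element symbols; inferred from `name` when `NA`.
#' @param resname 3-letter residue names.
#' @param resid Integer residue numbers.
#' @param chain Single-character chain identifiers.
#' @param coords Numeric n x 3 matrix of coordinates in Angstrom.
#' @param is_hetero Logical HETATM flag.
#' @param source Optional source identifier (e.g. a PDB code or file name).
#' @param model Optional model number.
#' @return A tibble of class `md_structure`.
#' @export
md_structure <- function(serial, name, element = NA_character_, resname,
                         resid, chain, coords, is_hetero = FALSE,
                         source = NA_character_, model = 1L) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  element <- rep_len(as.character(element), n)
  missing_el <- is.na(element) | element == ""
  element[missing_el] <- infer_element(name[missing_el],
                                       rep_len(is_hetero, n)[missing_el])
  atoms <- tibble::tibble(
    serial = as.integer(serial),
    name = as.character(name),
    element = element,
    resname = as.character(resname),
    resid = as.integer(resid),
    chain = as.character(chain),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    is_hetero = rep_len(as.logical(is_hetero), n)
  )
  validate_structure(atoms)
  attr(atoms, "source") <- source
  attr(atoms, "model") <- model
  class(atoms) <- c("md_structure", class(tibble::tibble()))
  atoms
}

validate_structure <- function(atoms) {
  if (nrow(atoms) == 0) abort_format("Structure has no atoms.")
  if (anyDuplicated(atoms$serial)) {
    abort_format("Atom serial numbers must be unique within a model.")
  }
  bad <- !atoms$element %in% PERIODIC_SYMBOLS
  if (any(bad)) {
    abort_format(sprintf("Invalid element symbol(s): %s",
                         paste(unique(atoms$element[bad]), collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort_format("Atom coordinates must be finite.")
  }
  # residue identity (chain, resid) must map to a single resname
  key <- paste(atoms$chain, atoms$resid)
  split_names <- split(atoms$resname, key)
  inconsistent <- vapply(split_names, function(v) length(unique(v)) > 1,
                         logical(1))
  if (any(inconsistent)) {
    abort_format(sprintf(
      "Residue identity is inconsistent: (chain, resid) %s maps to several resnames.",
      names(split_names)[inconsistent][1]))
  }
  invisible(atoms)
}

#' Extract the coordinate matrix of a structure
#' @param structure An `md_structure` tibble (or any data frame with x/y/z).
#' @return An n x 3 numeric matrix.
#' @export
coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @inheritParams coords
#' @param xyz n x 3 matrix of new coordinates.
#' @return The structure with updated x/y/z columns.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure))
  structure$x <- xyz[, 1]
  structure$y <- xyz[, 2]
  structure$z <- xyz[, 3]
  structure
}

# Element inference for PDB files whose element column (77-78) is blank.
# Rule: strip digits and primes; a leading H (after stripping a leading
# digit, as in 1HG1) means hydrogen; two-letter metal/halogen names are
# honoured for HETATM records; otherwise the first character is the symbol.
infer_element <- function(name, is_hetero = FALSE) {
  is_hetero <- rep_len(is_hetero, length(name))
  vapply(seq_along(name), function(i) {
    nm <- gsub("[^A-Za-z]", "", name[i])
    if (nm == "") abort_format(sprintf("Cannot infer element from atom name '%s'.", name[i]))
    nm <- toupper(nm)
    two <- paste0(substr(nm, 1, 1), tolower(substr(nm, 2, 2)))
    if (is_hetero[i] && nchar(nm) == 2 &&
        two %in% c("Fe", "Zn", "Mg", "Mn", "Cu", "Na", "Cl", "Br", "Ca", "Ni", "Se")) {
      return(two)
    }
    if (substr(nm, 1, 1) == "H") return("H")
    substr(nm, 1, 1)
  }, character(1))
}

#' Parse PDB-format text into structures
#'
#' Parses fixed-column PDB v3.3 ATOM/HETATM records. `MODEL`/`ENDMDL`
#' records delimit frames; a file without MODEL records yields a single
#' structure. Alternate locations other than `' '` and `'A'` are dropped so
#' the topology is a deterministic single conformer. The element is taken
#' from columns 77-78 and inferred from the atom name when blank.
#'
#' @param text A single string (or character vector of lines) of PDB text.
#' @param source Optional source label stored on each structure.
#' @return A list of `md_structure`, one per MODEL.
#' @export
parse_pdb <- function(text, source = NA_character_) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  is_atom <- grepl("^ATOM  ", lines) | grepl("^HETATM", lines)
  if (!any(is_atom)) abort_format("No ATOM/HETATM records found.")

  model_breaks <- cumsum(substr(lines, 1, 5) == "MODEL")
  model_of_line <- pmax(model_breaks, 1L)

  parse_block <- function(idx, model_no) {
    ln <- lines[idx]
    altloc <- substr(ln, 17, 17)
    keep <- altloc %in% c(" ", "A", "")
    ln <- ln[keep]
    idx <- idx[keep]
    if (length(ln) == 0) abort_format("All atoms dropped by altloc filter.")
    num_field <- function(from, to, what) {
      raw <- substr(ln, from, to)
      val <- suppressWarnings(as.numeric(raw))
      bad <- is.na(val) & trimws(raw) != ""
      bad <- bad | trimws(raw) == ""
      if (any(bad)) {
        abort_format(sprintf("Unparsable %s field at line %d: '%s'",
                             what, idx[which(bad)[1]], raw[which(bad)[1]]))
      }
      val
    }
    element <- trimws(substr(ln, 77, 78))
    element <- ifelse(element == "", NA_character_,
                      paste0(toupper(substr(element, 1, 1)),
                             tolower(substr(element, 2, 2))))
    element <- trimws(element)
    md_structure(
      serial = as.integer(num_field(7, 11, "serial")),
      name = trimws(substr(ln, 13, 16)),
      element = element,
      resname = trimws(substr(ln, 18, 20)),
      resid = as.integer(num_field(23, 26, "resid")),
      chain = substr(ln, 22, 22),
      coords = cbind(num_field(31, 38, "x"),
                     num_field(39, 46, "y"),
                     num_field(47, 54, "z")),
      is_hetero = substr(ln, 1, 6) == "HETATM",
      source = source,
      model = model_no
    )
  }

  atom_idx <- which(is_atom)
  models <- split(atom_idx, model_of_line[atom_idx])
  purrr::imap(unname(models), function(idx, i) parse_block(idx, as.integer(i)))
}

#' Read one or more structures from a PDB file
#' @param path Path to a PDB file (possibly multi-model).
#' @return A list of `md_structure` (see [parse_pdb()]).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("File not found: %s", path))
  parse_pdb(readLines(path, warn = FALSE), source = basename(path))
}

format_pdb_name <- function(name, element) {
  # names of 1-letter elements start in column 14 unless 4 characters long
  ifelse(nchar(name) >= 4 | nchar(element) == 2,
         sprintf("%-4s", name), sprintf(" %-3s", name))
}

pdb_atom_lines <- function(structure) {
  rec <- ifelse(structure$is_hetero, "HETATM", "ATOM  ")
  sprintf("%s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, structure$serial,
          format_pdb_name(structure$name, structure$element),
          structure$resname, structure$chain, structure$resid,
          structure$x, structure$y, structure$z, 1, 0,
          sprintf("%2s", structure$element))
}

#' Write a structure (or ensemble) as PDB
#'
#' Ensembles are written as multi-model PDB with `MODEL`/`ENDMDL` records,
#' readable back by [read_pdb()] / [load_ensemble()].
#'
#' @param x An `md_structure` or `md_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "md_ensemble")) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(x$frames)) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(pdb_atom_lines(set_coords(x$topology, x$frames[[i]])), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    writeLines(c(pdb_atom_lines(x), "END"), path)
  }
  invisible(path)
}

#' Read an XYZ frame series
#'
#' Plain XYZ: atom count line, comment line, then `element x y z` rows,
#' repeated per frame. XYZ carries no residue metadata, so a topology
#' structure must be supplied downstream (see [load_ensemble()]).
#'
#' @param path Path to an XYZ file.
#' @return A list of n x 3 coordinate matrices, one per frame, with the
#'   element symbols of the first frame as attribute `"elements"`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) abort_format(sprintf("Bad XYZ atom-count at line %d.", i))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4)) {
      abort_format(sprintf("Bad XYZ atom line near line %d.", i + 2L))
    }
    mat <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(mat)) abort_format(sprintf("Unparsable XYZ coordinates near line %d.", i + 2L))
    if (is.null(elements)) elements <- vapply(parts, `[`, character(1), 1)
    frames[[length(frames) + 1L]] <- mat
    i <- i + 2L + n
  }
  if (length(frames) == 0) abort_format("No frames found in XYZ file.")
  attr(frames, "elements") <- elements
  frames
}
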