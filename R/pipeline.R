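# End-to-end orchestration: a single YAML config drives every command.
# Primary outputs (TSV/JSON) carry no timestamps, so a rerun on identical
# inputs and config is byte-identical.

#' Read a run configuration file (YAML)
#'
#' Top-level keys: `output_dir`, `seed`, `simulate` (recipe parameters and
#' `n_replicates`), `systems` (list of `label` + `replicates` file paths),
#' `selections` (role name to selection expression), `bonds` (substrate
#' bond list by atom name), `criteria` (cutoffs, thresholds, bins),
#' `structures` (`a`/`b` paths for helix-angle and fingerprint commands),
#' and `standard_positions` (residue-numbering aliases).
#'
#' @param path Path to a YAML config file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("Config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$output_dir)) cfg$output_dir <- dirname(path)
  structure(cfg, class = "run_config")
}

as_run_config <- function(config) {
  if (is.character(config)) read_run_config(config) else config
}

default_selections <- function() {
  list(
    substrate_imine_N = "chain S and name N1",
    prochiral_center = "chain S and name C2",
    hydride_candidates = "chain N and name H41 H42",
    donor_residues = c(95L, 171L, 179L),
    donor_chain = "A",
    dyad = list(donor_residue = 95L, acceptor_residue = 171L,
                donor_atom = "OG", hydrogen_atom = "HG",
                acceptor_atoms = c("OD1", "OD2"))
  )
}

default_bonds <- function() {
  list(list("N1", "C2", 2L), list("C2", "C3", 1L), list("C2", "C6", 1L),
       list("C3", "C4", 1L), list("C4", "C5", 1L), list("C5", "N1", 1L))
}

config_selections <- function(cfg) {
  utils::modifyList(default_selections(), cfg$selections %||% list())
}

config_criteria <- function(cfg) {
  utils::modifyList(
    list(contact_cutoff = 2.5, hydrogen_policy = "all-sidechain",
         hbond_max_da = 3.5, hbond_min_angle = 120,
         bin_width = 0.1, profile_range = c(2.2, 5.0),
         planarity_tol = 0.25, fingerprint_cutoff = 3.5,
         exclude_indeterminate = FALSE),
    cfg$criteria %||% list())
}

# Build the prochiral spec from config roles on a topology; fails fast
# with the role name when a selection cannot be resolved.
config_prochiral_spec <- function(cfg, topology) {
  sel <- config_selections(cfg)
  center <- resolve_single(topology, sel$prochiral_center, "prochiral_center")
  chain <- topology$chain[center]
  bonds <- cfg$bonds %||% default_bonds()
  name_idx <- function(nm) {
    idx <- select_atoms(topology, sprintf("chain %s and name %s", chain, nm))
    if (length(idx) != 1) {
      abort_config(sprintf("Bond atom '%s' must resolve to one atom on chain %s.", nm, chain))
    }
    idx
  }
  bond_tbl <- tibble::tibble(
    i = vapply(bonds, function(b) name_idx(b[[1]]), integer(1)),
    j = vapply(bonds, function(b) name_idx(b[[2]]), integer(1)),
    order = vapply(bonds, function(b) as.integer(b[[3]] %||% 1L), integer(1)))
  graph <- molecular_graph(topology$element, bond_tbl)
  crit <- config_criteria(cfg)
  if (!is.null(sel$substituents)) {
    subs <- vapply(sel$substituents, function(s)
      resolve_single(topology, s, "substituent"), integer(1))
    return(prochiral_spec(center, subs, planarity_tol = crit$planarity_tol))
  }
  ranking <- rank_substituents(graph, center)
  if (ranking$tie) {
    abort_config(paste(
      "Substituent priorities are tied; supply selections$substituents",
      "with the priority order explicitly."))
  }
  prochiral_spec(center, ranking$order, planarity_tol = crit$planarity_tol)
}

config_systems <- function(cfg) {
  if (is.null(cfg$systems) || length(cfg$systems) == 0) {
    abort_config("Config has no 'systems' entry.")
  }
  lapply(cfg$systems, function(sys) {
    if (is.null(sys$label) || is.null(sys$replicates)) {
      abort_config("Each system needs 'label' and 'replicates'.")
    }
    missing <- !file.exists(unlist(sys$replicates))
    if (any(missing)) {
      abort_config(sprintf("Replicate file not found: %s",
                           unlist(sys$replicates)[missing][1]))
    }
    list(label = sys$label,
         ensembles = purrr::imap(sys$replicates, function(p, k)
           load_ensemble(p, replicate_id = sprintf("%s_rep%d", sys$label, k))))
  })
}

provenance <- function(cfg) {
  list(config_hash = rlang::hash(unclass(cfg)),
       seed = cfg$seed %||% NA,
       package = "stereomd",
       version = as.character(utils::packageVersion("stereomd")))
}

#' Simulate synthetic replicate ensembles from a config
#'
#' Generates `simulate$n_replicates` replicates (seeds `seed`,
#' `seed + 1`, ...) with [generate_ternary_ensemble()], writes each as a
#' multi-model PDB plus a ground-truth JSON sidecar under `output_dir`,
#' and returns the written paths.
#'
#' @param config A `run_config` (or path to one).
#' @return Invisibly, a list with `pdb` and `truth` path vectors.
#' @export
run_simulate <- function(config) {
  cfg <- as_run_config(config)
  sim <- cfg$simulate %||% list()
  if (is.null(cfg$seed)) abort_config("Config needs a 'seed' for simulate.")
  n_rep <- sim$n_replicates %||% 3L
  label <- sim$system_label %||% "synthetic"
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  occ <- sim$contact_occupancy %||% c("95" = 0.000036, "171" = 0.000052, "179" = 0.084)
  occ <- stats::setNames(as.numeric(unlist(occ)), names(unlist(occ)))
  pdbs <- character(n_rep); truths <- character(n_rep)
  for (k in seq_len(n_rep)) {
    recipe <- ensemble_recipe(
      n_frames = sim$n_frames %||% 2000L,
      re_fraction = sim$re_fraction %||% 0.548,
      contact_occupancy = occ,
      hbond_occupancy = sim$hbond_occupancy %||% 0.8,
      da_range = as.numeric(sim$da_range %||% c(2.6, 3.0)),
      noise_sigma = sim$noise_sigma %||% 0.04,
      pyramidal_fraction = sim$pyramidal_fraction %||% 0,
      seed = cfg$seed + k - 1L)
    out <- generate_ternary_ensemble(recipe, replicate_id = sprintf("%s_rep%d", label, k))
    pdbs[k] <- file.path(cfg$output_dir, sprintf("%s_rep%d.pdb", label, k))
    truths[k] <- file.path(cfg$output_dir, sprintf("%s_rep%d_truth.json", label, k))
    write_pdb(out$ensemble, pdbs[k])
    write_ground_truth(out$truth, truths[k])
  }
  invisible(list(pdb = pdbs, truth = truths))
}

#' Run the per-residue contact/stereopreference report from a config
#'
#' Orchestrates load -> face series -> contact frequencies -> replicate
#' aggregation -> report, and writes `contact_report.tsv` / `.json` under
#' `output_dir`.
#'
#' @param config A `run_config` (or path to one).
#' @return The [contact_report()] tibble, invisibly.
#' @export
run_table2 <- function(config) {
  cfg <- as_run_config(config)
  sel <- config_selections(cfg)
  crit <- config_criteria(cfg)
  if (length(sel$donor_residues) == 0) abort_config("Residue panel is empty.")
  systems <- config_systems(cfg)
  topo <- systems[[1]]$ensembles[[1]]$topology
  spec <- config_prochiral_spec(cfg, topo)
  # fail fast on every role before touching any frame
  resolve_single(topo, sel$substrate_imine_N, "substrate_imine_N")
  if (length(resolve_indices(topo, sel$hydride_candidates)) == 0) {
    abort_config("Role 'hydride_candidates' matched no atoms.")
  }
  std <- cfg$standard_positions
  if (!is.null(std)) std <- stats::setNames(as.character(unlist(std)), names(unlist(std)))
  report <- contact_report(
    systems, spec,
    hydride_candidates = sel$hydride_candidates,
    acceptor = sel$substrate_imine_N,
    residues = as.integer(unlist(sel$donor_residues)),
    chain = sel$donor_chain %||% "A",
    cutoff = crit$contact_cutoff,
    hydrogen_policy = crit$hydrogen_policy,
    exclude_indeterminate = isTRUE(crit$exclude_indeterminate),
    standard_positions = std)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_contact_report(report,
                       tsv = file.path(cfg$output_dir, "contact_report.tsv"),
                       json = file.path(cfg$output_dir, "contact_report.json"))
  jsonlite::write_json(provenance(cfg),
                       file.path(cfg$output_dir, "contact_report_provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run the dyad H-bond distance profile from a config
#'
#' Pools each system's replicates into one frame series and writes
#' `hbond_profile_<label>.tsv` / `.json` under `output_dir`.
#'
#' @param config A `run_config` (or path to one).
#' @return Named list of per-system [dyad_occupancy()] results, invisibly.
#' @export
run_hbond_profile <- function(config) {
  cfg <- as_run_config(config)
  sel <- config_selections(cfg)
  crit <- config_criteria(cfg)
  dy <- sel$dyad
  systems <- config_systems(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  res <- lapply(systems, function(sys) {
    pooled <- md_ensemble(
      sys$ensembles[[1]]$topology,
      do.call(c, lapply(sys$ensembles, function(e) e$frames)),
      replicate_id = sys$label)
    out <- dyad_occupancy(
      pooled,
      donor_residue = dy$donor_residue, acceptor_residue = dy$acceptor_residue,
      chain = sel$donor_chain %||% "A",
      donor_atom = dy$donor_atom, hydrogen_atom = dy$hydrogen_atom,
      acceptor_atoms = unlist(dy$acceptor_atoms),
      max_da = crit$hbond_max_da, min_angle = crit$hbond_min_angle,
      bin_width = crit$bin_width, range = as.numeric(crit$profile_range))
    write_hbond_profile(
      out$profile,
      tsv = file.path(cfg$output_dir, sprintf("hbond_profile_%s.tsv", sys$label)),
      json = file.path(cfg$output_dir, sprintf("hbond_profile_%s.json", sys$label)))
    out
  })
  names(res) <- vapply(systems, `[[`, character(1), "label")
  invisible(res)
}

#' Measure the helix rotation angle between two structures from a config
#'
#' @param config A `run_config` (or path to one) with `structures$a`,
#'   `structures$b` and `selections$helix` / `selections$anchor`.
#' @return The angle in degrees, invisibly.
#' @export
run_helix_angle <- function(config) {
  cfg <- as_run_config(config)
  sel <- config_selections(cfg)
  if (is.null(cfg$structures$a) || is.null(cfg$structures$b)) {
    abort_config("Config needs structures$a and structures$b paths.")
  }
  if (is.null(sel$helix) || is.null(sel$anchor)) {
    abort_config("Config needs selections$helix and selections$anchor.")
  }
  a <- read_pdb(cfg$structures$a)[[1]]
  b <- read_pdb(cfg$structures$b)[[1]]
  angle <- helix_rotation_angle(a, b, helix = sel$helix, anchor = sel$anchor)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    c(list(angle_deg = angle, helix = sel$helix, anchor = sel$anchor),
      provenance(cfg)),
    file.path(cfg$output_dir, "helix_angle.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(angle)
}

#' Polar-contact fingerprints of two structures and their difference
#'
#' @param config A `run_config` (or path to one) with `structures$a`,
#'   `structures$b` and `selections$ligand`.
#' @return List with `fp_a`, `fp_b`, `diff`, invisibly.
#' @export
run_fingerprint <- function(config) {
  cfg <- as_run_config(config)
  sel <- config_selections(cfg)
  crit <- config_criteria(cfg)
  if (is.null(sel$ligand)) abort_config("Config needs selections$ligand.")
  if (is.null(cfg$structures$a)) abort_config("Config needs structures$a.")
  a <- read_pdb(cfg$structures$a)[[1]]
  fp_a <- polar_fingerprint(a, sel$ligand, cutoff = crit$fingerprint_cutoff)
  out <- list(fp_a = fp_a, fp_b = NULL, diff = NULL)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble::as_tibble(fp_a),
                   file.path(cfg$output_dir, "fingerprint_a.tsv"))
  if (!is.null(cfg$structures$b)) {
    b <- read_pdb(cfg$structures$b)[[1]]
    fp_b <- polar_fingerprint(b, sel$ligand, cutoff = crit$fingerprint_cutoff)
    readr::write_tsv(tibble::as_tibble(fp_b),
                     file.path(cfg$output_dir, "fingerprint_b.tsv"))
    dd <- fingerprint_diff(fp_a, fp_b)
    jsonlite::write_json(
      c(lapply(dd, tibble::as_tibble), provenance(cfg)),
      file.path(cfg$output_dir, "fingerprint_diff.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$fp_b <- fp_b; out$diff <- dd
  }
  invisible(out)
}

#' Write a ready-to-run demo configuration
#'
#' Produces a YAML config whose `simulate` section and `systems` paths are
#' consistent, so `run_simulate()` followed by `run_table2()` /
#' `run_hbond_profile()` works out of the box. Used by the examples and
#' the test-suite round trips.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_frames Frames per replicate.
#' @param n_replicates Number of replicates.
#' @param label System label.
#' @return The config file path, invisibly.
#' @export
demo_config <- function(dir, seed = 1L, n_frames = 500L, n_replicates = 3L,
                        label = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(
    output_dir = dir,
    seed = as.integer(seed),
    simulate = list(
      n_replicates = as.integer(n_replicates),
      n_frames = as.integer(n_frames),
      system_label = label),
    systems = list(list(
      label = label,
      replicates = as.list(file.path(dir, sprintf("%s_rep%d.pdb", label,
                                                  seq_len(n_replicates)))))),
    standard_positions = list("95" = "111", "171" = "187", "179" = "195")
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}
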