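# Close-contact frequencies, replicate aggregation and the contact report.

test_that("min_hydrogen_distance and the strict cutoff boundary behave", {
  xyz <- rbind(c(0, 0, 0), c(1.9, 0, 0), c(0, 3.4, 0), c(2.5, 0, 0))
  expect_equal(min_hydrogen_distance(xyz, c(2L, 3L), 1L), 1.9)
  expect_equal(min_hydrogen_distance(xyz, 4L, 1L), 2.5)
  expect_equal(min_hydrogen_distance(xyz, 2L, 2L), 0)
  expect_error(min_hydrogen_distance(xyz, integer(0), 1L),
               class = "stereomd_config_error")
  # exactly 2.5 A is NOT a contact under strict '<'
  topo <- md_structure(serial = 1:2, name = c("N1", "HB1"),
                       element = c("N", "H"), resname = c("MPL", "SER"),
                       resid = c(1, 95), chain = c("S", "A"),
                       coords = rbind(c(0, 0, 0), c(2.5, 0, 0)),
                       is_hetero = c(TRUE, FALSE))
  ens <- md_ensemble(topo, list(coords(topo)))
  cf <- contact_frequency(ens, 2L, 1L, cutoff = 2.5)
  expect_equal(cf$frequency, 0)
})

test_that("contact_frequency counts frames below the cutoff", {
  # 10 frames: 4 at 2.0 A, 6 at 3.0 A -> frequency 0.4
  topo <- md_structure(serial = 1:2, name = c("N1", "HB1"),
                       element = c("N", "H"), resname = c("MPL", "SER"),
                       resid = c(1, 95), chain = c("S", "A"),
                       coords = rbind(c(0, 0, 0), c(2, 0, 0)),
                       is_hetero = c(TRUE, FALSE))
  frames <- lapply(c(rep(2, 4), rep(3, 6)), function(d)
    rbind(c(0, 0, 0), c(d, 0, 0)))
  ens <- md_ensemble(topo, frames)
  cf <- contact_frequency(ens, 2L, 1L)
  expect_equal(cf$frequency, 0.4)
  expect_equal(sum(cf$mask[[1]]), 4)
  # all frames at/above cutoff -> 0
  far <- md_ensemble(topo, lapply(1:5, function(i) rbind(c(0, 0, 0), c(4, 0, 0))))
  expect_equal(contact_frequency(far, 2L, 1L)$frequency, 0)
  # acceptor must be a single atom
  expect_error(contact_frequency(ens, 2L, c(1L, 2L)),
               class = "stereomd_config_error")
})

test_that("contact_frequency is monotone in the cutoff", {
  g <- generate_ternary_ensemble(
    ensemble_recipe(n_frames = 200, contact_occupancy = c("179" = 0.4), seed = 3))
  sel <- "chain A and resid 179 and element H and sidechain"
  acc <- g$roles$substrate_imine_N
  freqs <- vapply(c(1.5, 2.1, 2.5, 3.0, 3.5, 5),
                  function(ct) contact_frequency(g$ensemble, sel, acc,
                                                 cutoff = ct)$frequency,
                  numeric(1))
  expect_true(all(diff(freqs) >= 0))
})

test_that("aggregate_replicates is an unweighted mean with permutation invariance", {
  expect_equal(aggregate_replicates(c(0.1, 0.3)), 0.2)
  expect_equal(aggregate_replicates(0.084), 0.084)
  expect_equal(aggregate_replicates(rep(0.42, 10)), 0.42)
  f <- c(0.1, 0.5, 0.2, 0.9)
  expect_equal(aggregate_replicates(f), aggregate_replicates(rev(f)))
  expect_error(aggregate_replicates(numeric(0)), class = "stereomd_config_error")
})

test_that("face_counts conserves frames under masks and exclusion", {
  labels <- factor(c("re", "re", "re", "si", "si"),
                   levels = c("re", "si", "indeterminate"))
  series <- tibble::tibble(face = labels)
  fc <- face_counts(series)
  expect_equal(unlist(fc), c(n_re = 3L, n_si = 2L, n_indeterminate = 0L))
  fc2 <- face_counts(series, mask = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(fc2$n_re, 2L)
  expect_equal(fc2$n_re + fc2$n_si + fc2$n_indeterminate, 2L)
  expect_error(face_counts(series, mask = TRUE), class = "stereomd_config_error")
  # exclusion drops indeterminate frames from all counts
  labels3 <- factor(c("re", "indeterminate", "si"),
                    levels = c("re", "si", "indeterminate"))
  fc3 <- face_counts(tibble::tibble(face = labels3), exclude_indeterminate = TRUE)
  expect_equal(unlist(fc3), c(n_re = 1L, n_si = 1L, n_indeterminate = 0L))
})

test_that("contact-conditioned face ratios recover planted values", {
  # plant contact occupancy 0.5 and re fraction 0.75 (re:si = 3:1), n = 4000
  g <- generate_ternary_ensemble(
    ensemble_recipe(n_frames = 4000, re_fraction = 0.75,
                    contact_occupancy = c("179" = 0.5), seed = 21))
  fs <- face_series(g$ensemble, g$spec, g$roles$hydride_candidates)
  cf <- contact_frequency(g$ensemble,
                          "chain A and resid 179 and element H and sidechain",
                          g$roles$substrate_imine_N)
  fc <- face_counts(fs, mask = cf$mask[[1]])
  n <- fc$n_re + fc$n_si
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(fc$n_re / n - 0.75), 3 * se)
  # conservation: masked frame count
  expect_equal(n + fc$n_indeterminate, sum(cf$mask[[1]]))
})

test_that("contact_report emits one row per system x residue with recovery", {
  mk_system <- function(label, seeds, occ) {
    list(label = label, ensembles = lapply(seeds, function(s)
      generate_ternary_ensemble(
        ensemble_recipe(n_frames = 400, re_fraction = 0.6,
                        contact_occupancy = occ, seed = s),
        replicate_id = paste0(label, "_", s))$ensemble))
  }
  g0 <- generate_ternary_ensemble(
    ensemble_recipe(n_frames = 2, contact_occupancy = c("95" = 0.3, "179" = 0.1),
                    seed = 1))
  sysA <- mk_system("A", 1:3, c("95" = 0.3, "179" = 0.1))
  sysB <- mk_system("B", 4:6, c("95" = 0.05, "179" = 0.5))
  rep <- contact_report(list(sysA, sysB), g0$spec,
                        hydride_candidates = g0$roles$hydride_candidates,
                        acceptor = g0$roles$substrate_imine_N,
                        residues = c(95, 179),
                        standard_positions = c("95" = "111", "179" = "195"))
  expect_equal(nrow(rep), 4)
  expect_equal(rep$system, c("A", "A", "B", "B"))
  expect_equal(rep$standard_position[rep$residue == 95][1], "111")
  # recovery within 3 binomial SE of the replicate-pooled n
  for (k in seq_len(nrow(rep))) {
    planted <- c(A.95 = 0.3, A.179 = 0.1, B.95 = 0.05, B.179 = 0.5)[[
      paste(rep$system[k], rep$residue[k], sep = ".")]]
    se <- sqrt(planted * (1 - planted) / 1200)
    expect_lt(abs(rep$mean_frequency[k] - planted), 3 * se)
  }
  # a residue with zero contacts still yields a row
  sysC <- mk_system("C", 7, c("95" = 0, "179" = 0.2))
  repC <- contact_report(list(sysC), g0$spec,
                         hydride_candidates = g0$roles$hydride_candidates,
                         acceptor = g0$roles$substrate_imine_N,
                         residues = c(95, 179))
  row95 <- repC[repC$residue == 95, ]
  expect_equal(row95$mean_frequency, 0)
  expect_equal(row95$n_re + row95$n_si + row95$n_indeterminate, 0L)
  expect_equal(row95$ratio_conditioned, "0 : 0")
})

test_that("report rendering formats frequencies and ratios like the field's tables", {
  expect_equal(format_frequency(0.084), "0.084")
  expect_equal(format_frequency(0.000036), "0.000036")
  expect_equal(format_frequency(0), "0.0")
  expect_equal(format_frequency(0.45), "0.45")
  # rendered row fragments: frequency then re:si counts
  expect_equal(sprintf("%s ... %s", format_frequency(0.084),
                       sprintf("%d : %d", 1763L, 1452L)),
               "0.084 ... 1763 : 1452")
})

test_that("write_contact_report produces deterministic TSV/JSON", {
  g <- generate_ternary_ensemble(
    ensemble_recipe(n_frames = 50, contact_occupancy = c("179" = 0.3), seed = 5))
  sys <- list(label = "S", ensembles = list(g$ensemble))
  rep <- contact_report(list(sys), g$spec, g$roles$hydride_candidates,
                        g$roles$substrate_imine_N, residues = 179)
  d <- withr::local_tempdir()
  t1 <- file.path(d, "a.tsv"); t2 <- file.path(d, "b.tsv")
  j1 <- file.path(d, "a.json"); j2 <- file.path(d, "b.json")
  write_contact_report(rep, t1, j1)
  write_contact_report(rep, t2, j2)
  expect_identical(readLines(t1), readLines(t2))
  expect_identical(readLines(j1), readLines(j2))
  parsed <- jsonlite::read_json(j1)
  expect_equal(parsed$rows[[1]]$mean_frequency, rep$mean_frequency[1])
})
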