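# Substituent priority ranking and prochiral face classification.

test_that("rank_substituents reproduces full-CIP priorities on the molecule panel", {
  # expected orders frozen from an independent full CIP implementation
  # (RDKit canonical CIP ranks) on the same connectivity
  panel <- cip_panel()
  for (name in names(panel)) {
    entry <- panel[[name]]
    res <- rank_substituents(entry$mol$graph, entry$center)
    if (entry$tie) {
      expect_true(res$tie, label = paste(name, "tie flag"))
      expect_equal(res$order[1], expected_order(entry)[1],
                   label = paste(name, "top priority"))
    } else {
      expect_false(res$tie, label = paste(name, "tie flag"))
      expect_equal(unname(res$order), unname(expected_order(entry)),
                   label = paste(name, "priority order"))
    }
  }
})

test_that("ranking handles the documented simple cases", {
  # center bonded to N, C, H -> atomic-number order
  m <- build_molecule(c("C", "N", "C"), list(c(1, 2, 2), c(1, 3)), c(1, 1, 3))
  res <- rank_substituents(m$graph, 1)
  expect_false(res$tie)
  expect_equal(res$order[1:2], c(2L, 3L))
  expect_equal(m$graph$elements[res$order[3]], "H")
  # degree != 3 is an error
  m2 <- build_molecule(c("C", "C"), list(c(1, 2)), c(3, 3))
  expect_error(rank_substituents(m2$graph, 1), "3 substituents")
})

test_that("classify_face matches the hand-derived example and flips with the probe", {
  pose <- toy_pose()
  # probe on +z: a -> b -> c appears counterclockwise -> si
  expect_equal(classify_face(pose$coords, pose$spec, c(0, 0, 2)), "si")
  expect_equal(classify_face(pose$coords, pose$spec, c(0, 0, -2)), "re")
  # in-plane probe is degenerate
  expect_equal(classify_face(pose$coords, pose$spec, c(2, 2, 0)), "indeterminate")
})

test_that("classify_face agrees with the signed-volume oracle on random poses", {
  set.seed(42)
  for (i in 1:1000) {
    pose <- random_pose()
    got <- classify_face(pose$coords, pose$spec, pose$probe)
    want <- signed_volume_face(pose$coords[2, ], pose$coords[3, ],
                               pose$coords[4, ], pose$probe)
    expect_equal(got, want, label = sprintf("pose %d", i))
  }
})

test_that("face labels are SE(3)-invariant and flip under reflection", {
  set.seed(1234)
  pose0 <- toy_pose()
  probe0 <- c(0.3, -0.2, 1.7)
  ref <- classify_face(pose0$coords, pose0$spec, probe0)
  flip <- c(re = "si", si = "re")
  for (i in 1:1000) {
    R <- random_rotation_matrix()
    t <- stats::runif(3, -50, 50)
    xyz <- sweep(pose0$coords %*% t(R), 2, t, "+")
    probe <- as.numeric(R %*% probe0 + t)
    expect_equal(classify_face(xyz, pose0$spec, probe), ref,
                 label = sprintf("rigid motion %d", i))
    # mirror (z -> -z) of the same moved pose flips the label
    m <- diag(c(1, 1, -1))
    expect_equal(classify_face(xyz %*% m, pose0$spec, as.numeric(probe %*% m)),
                 flip[[ref]], label = sprintf("reflection %d", i))
  }
})

test_that("pyramidalized centers are indeterminate, planar ones are not", {
  pose <- toy_pose()
  probe <- c(0, 0, 2)
  xyz <- pose$coords
  xyz[1, 3] <- 0.3  # beyond the 0.25 A default tolerance
  expect_equal(classify_face(xyz, pose$spec, probe), "indeterminate")
  xyz[1, 3] <- 0.2  # within tolerance
  expect_true(classify_face(xyz, pose$spec, probe) %in% c("re", "si"))
  # zero-area substituent triangle is a geometry error
  degenerate <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(classify_face(degenerate, pose$spec, probe),
               class = "stereomd_geometry_error")
})

test_that("nearest_hydride picks the closest candidate with index tie-break", {
  xyz <- rbind(c(0, 0, 0), c(3.1, 0, 0), c(0, 4.2, 0), c(-3.1, 0, 0))
  expect_equal(nearest_hydride(xyz, c(2L, 3L), 1L)$atom, 2L)
  expect_equal(nearest_hydride(xyz, c(2L, 3L), 1L)$distance, 3.1)
  # exact tie: lower atom index wins
  expect_equal(nearest_hydride(xyz, c(4L, 2L), 1L)$atom, 2L)
  # single candidate wins regardless of distance
  expect_equal(nearest_hydride(xyz, 3L, 1L)$atom, 3L)
  expect_error(nearest_hydride(xyz, integer(0), 1L),
               class = "stereomd_config_error")
})

test_that("face_series recovers planted fractions and counts conserve frames", {
  # degenerate planting: every frame re
  g1 <- generate_ternary_ensemble(
    ensemble_recipe(n_frames = 100, re_fraction = 1,
                    contact_occupancy = c("179" = 0.5), seed = 7))
  fs1 <- face_series(g1$ensemble, g1$spec, g1$roles$hydride_candidates)
  expect_equal(sum(fs1$face == "re"), 100)
  # planted 0.7 at n = 2000: recovered within 3 binomial SE
  g2 <- generate_ternary_ensemble(
    ensemble_recipe(n_frames = 2000, re_fraction = 0.7,
                    contact_occupancy = c("179" = 0.5), seed = 11))
  fs2 <- face_series(g2$ensemble, g2$spec, g2$roles$hydride_candidates)
  se <- sqrt(0.7 * 0.3 / 2000)
  expect_lt(abs(mean(fs2$face == "re") - 0.7), 3 * se)
  # planted pyramidalized frames are exactly the indeterminate ones
  g3 <- generate_ternary_ensemble(
    ensemble_recipe(n_frames = 400, re_fraction = 0.5,
                    contact_occupancy = c("179" = 0.5),
                    pyramidal_fraction = 0.02, seed = 13))
  fs3 <- face_series(g3$ensemble, g3$spec, g3$roles$hydride_candidates)
  expect_identical(which(fs3$face == "indeterminate"), which(g3$truth$pyramidal))
  expect_equal(sum(fs3$face == "re") + sum(fs3$face == "si") +
                 sum(fs3$face == "indeterminate"), 400)
  # glance/tidy methods summarize consistently
  gl <- glance(fs3)
  expect_equal(gl$n_re + gl$n_si + gl$n_indeterminate, 400)
  td <- tidy(fs3)
  expect_equal(sum(td$n), 400)
})
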