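# PDB/XYZ parsing, writing, ensembles and the selection language.

test_that("parse_pdb reads fixed-column fields and hetero flags", {
  models <- parse_pdb(toy_pdb_text())
  expect_length(models, 1)
  s <- models[[1]]
  expect_equal(nrow(s), 10)
  expect_equal(s$name[1], "N")
  expect_equal(s$element[1], "N")
  expect_equal(s$resid[1], 1L)
  expect_equal(s$chain[6], "A")
  expect_equal(s$x[2], 1.458)
  expect_true(all(s$is_hetero[9:10]))
  expect_equal(s$resname[9], "NAD")
})

test_that("parse_pdb delimits MODEL blocks and reports bad coordinates", {
  one <- c(pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
           pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 3.8, 0, 0, "C"))
  multi <- paste(c("MODEL     1", one, "ENDMDL",
                   "MODEL     2", one, "ENDMDL",
                   "MODEL     3", one, "ENDMDL", "END"), collapse = "\n")
  models <- parse_pdb(multi)
  expect_length(models, 3)
  expect_identical(models[[1]]$name, models[[3]]$name)
  # unparsable coordinate -> error naming the line
  bad <- sub("   0.000", "  xx.000", one[1])
  expect_error(parse_pdb(bad), "line 1", class = "stereomd_format_error")
  expect_error(parse_pdb("REMARK nothing"), class = "stereomd_format_error")
})

test_that("element inference and altloc policy follow the documented rules", {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, ""),     # carbon
    pdb_line("ATOM", 2, "1HG1", "VAL", "A", 3, 1, 1, 1, ""),   # hydrogen
    pdb_line("ATOM", 3, "OD1", "ASP", "A", 2, 2, 2, 2, ""),    # oxygen
    pdb_line("HETATM", 4, "FE", "HEM", "B", 1, 3, 3, 3, ""))   # iron
  s <- parse_pdb(paste(lines, collapse = "\n"))[[1]]
  expect_equal(s$element, c("C", "H", "O", "Fe"))
  # altloc B dropped, ' ' and A kept
  alt <- c(pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
           pdb_line("ATOM", 2, "CB", "ALA", "A", 1, 1, 0, 0, "C"),
           pdb_line("ATOM", 3, "CB", "ALA", "A", 1, 2, 0, 0, "C"))
  substr(alt[2], 17, 17) <- "A"
  substr(alt[3], 17, 17) <- "B"
  s2 <- parse_pdb(paste(alt, collapse = "\n"))[[1]]
  expect_equal(nrow(s2), 2)
  expect_equal(s2$x, c(0, 1))
})

test_that("write_pdb / parse_pdb round-trips atoms and coordinates", {
  s <- parse_pdb(toy_pdb_text())[[1]]
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, tmp)
  s2 <- read_pdb(tmp)[[1]]
  for (col in c("serial", "name", "element", "resname", "resid", "chain", "is_hetero")) {
    expect_identical(s2[[col]], s[[col]], label = col)
  }
  expect_equal(coords(s2), coords(s), tolerance = 1e-9)
})

test_that("parse_pdb agrees with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_text(), tmp)
  ours <- parse_pdb(toy_pdb_text())[[1]]
  ref <- bio3d::read.pdb(tmp)
  expect_equal(ours$serial, ref$atom$eleno)
  expect_equal(ours$name, ref$atom$elety)
  expect_equal(ours$resname, ref$atom$resid)
  expect_equal(ours$resid, ref$atom$resno)
  expect_equal(coords(ours), matrix(ref$xyz, ncol = 3, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("load_ensemble concatenates frames and enforces topology", {
  one <- c(pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
           pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 3.8, 0, 0, "C"),
           pdb_line("ATOM", 3, "CA", "GLY", "A", 3, 7.6, 0, 0, "C"))
  multi5 <- paste(unlist(lapply(1:5, function(m)
    c(sprintf("MODEL     %d", m), one, "ENDMDL"))), collapse = "\n")
  d <- withr::local_tempdir()
  f1 <- file.path(d, "rep_a.pdb"); f2 <- file.path(d, "rep_b.pdb")
  writeLines(multi5, f1); writeLines(multi5, f2)
  ens <- load_ensemble(c(f1, f2))
  expect_equal(n_frames(ens), 10)
  expect_equal(ens$replicate_id, "rep_a")
  # single-frame ensemble is legal
  f3 <- file.path(d, "single.pdb")
  writeLines(paste(one, collapse = "\n"), f3)
  expect_equal(n_frames(load_ensemble(f3)), 1)
  # mismatched atom count names the offending file
  f4 <- file.path(d, "short.pdb")
  writeLines(paste(one[1:2], collapse = "\n"), f4)
  expect_error(load_ensemble(c(f1, f4)), "short.pdb",
               class = "stereomd_format_error")
  # XYZ needs a topology
  f5 <- file.path(d, "frames.xyz")
  writeLines(c("3", "frame 1", "C 0 0 0", "C 3.8 0 0", "C 7.6 0 0"), f5)
  expect_error(load_ensemble(f5), "topology", class = "stereomd_config_error")
  topo <- parse_pdb(paste(one, collapse = "\n"))[[1]]
  ens_xyz <- load_ensemble(f5, topology = topo)
  expect_equal(n_frames(ens_xyz), 1)
  expect_equal(ens_xyz$frames[[1]][2, 1], 3.8)
})

test_that("selections resolve documented cases, unions and empty matches", {
  s <- parse_pdb(toy_pdb_text())[[1]]
  expect_equal(select_atoms(s, "resid 2 and chain A"), 6:8)
  expect_equal(select_atoms(s, "name CA"), c(2L, 7L))
  expect_equal(select_atoms(s, "element H and resid 1"), 10L)
  expect_equal(select_atoms(s, "resid 9999"), integer(0))
  expect_equal(select_atoms(s, "hetero"), 9:10)
  expect_equal(select_atoms(s, "resname ALA or resname SER"), 1:8)
  expect_equal(select_atoms(s, "not hetero and not backbone"), c(5L, 8L))
  expect_equal(select_atoms(s, "resid 1:2 and element O"), c(4L, 8L))
  expect_equal(select_atoms(s, "(resid 1 or resid 2) and name OG"), 8L)
  # idempotent and order-stable
  expect_identical(select_atoms(s, "element C"), select_atoms(s, "element C"))
  # syntax errors are selection errors
  expect_error(select_atoms(s, "resid"), class = "stereomd_config_error")
  expect_error(select_atoms(s, "frobnicate 1"), class = "stereomd_config_error")
  expect_error(select_atoms(s, "(resid 1"), class = "stereomd_config_error")
})

test_that("structure invariants are enforced", {
  expect_error(
    md_structure(serial = c(1, 1), name = c("CA", "CB"), element = "C",
                 resname = "ALA", resid = 1, chain = "A",
                 coords = rbind(c(0, 0, 0), c(1, 0, 0))),
    "unique", class = "stereomd_format_error")
  expect_error(
    md_structure(serial = 1:2, name = c("CA", "CB"), element = "C",
                 resname = c("ALA", "GLY"), resid = 1, chain = "A",
                 coords = rbind(c(0, 0, 0), c(1, 0, 0))),
    "inconsistent", class = "stereomd_format_error")
  expect_error(
    md_structure(serial = 1, name = "XX", element = "Xx", resname = "LIG",
                 resid = 1, chain = "A", coords = c(0, 0, 0)),
    "element", class = "stereomd_format_error")
})
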