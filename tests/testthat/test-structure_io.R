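# Multi-model PDB reading, annotated writing, selection, and domain
# segmentation contracts.

write_tmp_pdb <- function(lines) {
  p <- withr::local_tempfile(fileext = ".pdb",
                             .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("single-model and multi-model PDBs parse to the right frame count", {
  single <- vapply(1:5, function(i)
    pdb_atom_line(i, "CA", "ALA", "A", i, i * 1.0, 0, 0), character(1))
  p <- write_tmp_pdb(c(single, "END"))
  traj <- read_pdb(p)
  expect_equal(nrow(traj$template$atoms), 5)
  expect_equal(n_frames(traj), 1)

  model <- function(k, dx) c(sprintf("MODEL %8d", k),
                             vapply(1:5, function(i)
                               pdb_atom_line(i, "CA", "ALA", "A", i,
                                             i + dx, 0, 0), character(1)),
                             "ENDMDL")
  p3 <- write_tmp_pdb(c(model(1, 0), model(2, 0.5), model(3, 1.0), "END"))
  traj3 <- read_pdb(p3)
  expect_equal(n_frames(traj3), 3)
  expect_equal(nrow(traj3$template$atoms), 5)
  # template comes from model 1; later models contribute coordinates only
  expect_equal(frame_coords(traj3, 2)[, 1], (1:5) + 0.5)
})

test_that("malformed and inconsistent PDB input is rejected with context", {
  good <- pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 2, 3)
  bad <- sub("   1.000", "   x.000", good, fixed = TRUE)
  p <- write_tmp_pdb(c(good, bad))
  expect_error(read_pdb(p), "line 2")

  m1 <- c("MODEL        1",
          pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 2, 3),
          pdb_atom_line(2, "CA", "ALA", "A", 2, 4, 5, 6),
          "ENDMDL")
  m2 <- c("MODEL        2",
          pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 2, 3),
          "ENDMDL")
  expect_error(read_pdb(write_tmp_pdb(c(m1, m2))), "mismatch")

  ins <- good
  substr(ins, 27, 27) <- "A"    # insertion code
  expect_error(read_pdb(write_tmp_pdb(ins)), "insertion")

  expect_error(read_pdb(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("annotated write round-trips coordinates and scores", {
  set.seed(42)
  coords <- matrix(round(rnorm(30, sd = 10), 3), ncol = 3)
  s <- make_structure(coords, resid = rep(1:5, each = 2),
                      name = rep(c("CA", "CB"), 5))
  s$atoms$score <- round(runif(10, 0, 50), 2)
  s$atoms$score[1:2] <- 0.40
  p <- withr::local_tempfile(fileext = ".pdb")
  write_annotated_pdb(s, p)
  back <- as_structure(read_pdb(p), 1)
  expect_equal(back$coords, s$coords, tolerance = 1e-8)
  expect_equal(back$atoms$score, s$atoms$score, tolerance = 1e-8)
  expect_equal(back$atoms$resid, s$atoms$resid)
  expect_equal(back$atoms$name, s$atoms$name)

  s_bad <- s
  s_bad$atoms$score[1] <- 1e6
  expect_error(write_annotated_pdb(s_bad, p), "range")
  s_bad$atoms$score[1] <- NaN
  expect_error(write_annotated_pdb(s_bad, p), "finite")
})

test_that("trajectory write/read round-trip preserves frames to PDB precision", {
  set.seed(7)
  frames <- lapply(1:4, function(f) matrix(round(rnorm(15, sd = 5), 3),
                                           ncol = 3))
  traj <- make_traj(frames)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, p)
  back <- read_pdb(p)
  expect_equal(n_frames(back), 4)
  expect_equal(back$frames, traj$frames, tolerance = 1e-8)
})

test_that("selection terms combine, reject unknown fields, flag empties", {
  s <- make_structure(matrix(0:26, ncol = 3),
                      resid = rep(1:3, each = 3),
                      name = rep(c("N", "CA", "C"), 3))
  expect_equal(select_atoms(s, name = "CA"), c(2, 5, 8))
  expect_equal(select_atoms(s, resid = 2:3, name = "CA"), c(5, 8))
  # selections come back in template order and are reproducible
  expect_identical(select_atoms(s, name = c("CA", "N")),
                   select_atoms(s, name = c("N", "CA")))
  expect_error(select_atoms(s, foo = "CA"), "unknown selection field")
  expect_warning(idx <- select_atoms(s, resname = "XXX"), "no atoms")
  expect_length(idx, 0)
})

test_that("domain segmentation follows the GfcD map with the plug overlap", {
  expect_equal(segment_domains(100), "GfcD-N")
  expect_equal(segment_domains(680), c("GfcD-C", "plug"))
  expect_equal(segment_domains(10), "signal")
  expect_equal(segment_domains(279), "GfcD-M")
  expect_length(segment_domains(999), 0)
  # defaults cover 1..698 with the single plug overlap
  hits <- vapply(1:698, function(r) length(segment_domains(r)), integer(1))
  expect_true(all(hits >= 1))
  expect_identical(which(hits == 2), 674:698)
  expect_error(validate_domain_map(list(bad = c(5, 1))), "range")
})
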