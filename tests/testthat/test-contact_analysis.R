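# Contact detection vs a brute-force oracle, frequency bookkeeping, the
# geometric-mean score, and score annotation.

test_that("frame contacts respect the cutoff at the boundary", {
  coords <- rbind(c(0, 0, 0),      # residue 1 heavy atom
                  c(10, 0, 0),     # residue 2 heavy atom
                  c(3.9, 0, 0),    # lipid atom within cutoff of residue 1
                  c(10, 4.1, 0))   # 4.1 A from residue 2
  map <- list(`1` = 1L, `2` = 2L)
  expect_equal(frame_contacts(coords, 3L, map, cutoff = 4.0), 1L)
  expect_equal(frame_contacts(coords, 4L, map, cutoff = 4.0), integer(0))
  expect_equal(frame_contacts(coords, c(3L, 4L), map, cutoff = 4.0), 1L)
  expect_error(frame_contacts(coords, integer(0), map), "non-empty")
})

test_that("frame contacts equal the brute-force all-pairs oracle", {
  set.seed(17)
  for (rep in 1:20) {
    coords <- matrix(rnorm(150, sd = 6), ncol = 3)
    prot <- 1:30
    lipid <- 31:50
    map <- split(prot, sample(1:8, 30, replace = TRUE))
    names(map) <- as.character(seq_along(map))
    cutoff <- runif(1, 2, 8)
    expect_identical(frame_contacts(coords, lipid, map, cutoff),
                     brute_contacts(coords, lipid, map, cutoff))
  }
})

test_that("contact frequencies are frame fractions, recovered exactly", {
  pattern <- c(`437` = 0.5, `668` = 1.0, `433` = 0.26)
  spec <- synthetic_spec(n_frames = 50, fluct_sigma = 0,
                         contact_pattern = pattern, seed = 9)
  gen <- generate_trajectory(spec)
  tmpl <- gen$trajectory$template
  lipid <- heavy_atoms(tmpl, gen$truth$lipid_atom_idx)
  freq <- contact_frequencies(gen$trajectory, lipid,
                              residue_atom_map(tmpl,
                                               gen$truth$protein_atoms))
  expect_equal(freq[names(pattern)], gen$truth$contact_frequencies)
  # residue in contact in every frame / half the frames
  expect_equal(unname(freq["668"]), 1.0)
  expect_equal(unname(freq["437"]), 0.5)
  # frequency is permutation-invariant over frames
  perm <- gen$trajectory
  ord <- sample(n_frames(perm))
  perm$frames <- perm$frames[, , ord]
  perm$times <- NULL
  freq2 <- contact_frequencies(perm, lipid,
                               residue_atom_map(tmpl,
                                                gen$truth$protein_atoms))
  expect_equal(freq2, freq)
})

test_that("hydrogens are excluded by element, or by name with a warning", {
  pattern <- c(`437` = 0.2)
  spec <- synthetic_spec(n_frames = 10, fluct_sigma = 0,
                         contact_pattern = pattern, seed = 10)
  gen <- generate_trajectory(spec)
  tmpl <- gen$trajectory$template
  all_lipid <- gen$truth$lipid_atom_idx
  heavy <- heavy_atoms(tmpl, all_lipid)
  expect_true(all(tmpl$atoms$element[heavy] != "H"))
  # the decoy hydrogen sits in contact range every frame: counting it
  # would inflate the frequency to 1
  freq_h <- contact_frequencies(gen$trajectory, all_lipid,
                                residue_atom_map(tmpl,
                                                 gen$truth$protein_atoms))
  expect_equal(unname(freq_h["437"]), 1.0)
  freq <- contact_frequencies(gen$trajectory, heavy,
                              residue_atom_map(tmpl,
                                               gen$truth$protein_atoms))
  expect_equal(unname(freq["437"]), 0.2)
  # name-based fallback
  blank <- tmpl
  blank$atoms$element <- ""
  expect_warning(h2 <- heavy_atoms(blank, all_lipid), "names")
  expect_identical(h2, heavy)
})

test_that("geometric score: products, zero-propagation, K=1, AM-GM", {
  expect_equal(geometric_score(c(0.5, 0.5, 0.5)), 0.5)
  expect_identical(geometric_score(c(0.9, 0, 0.9)), 0)
  expect_equal(geometric_score(c(0.2, 0.4, 0.8)), 0.4)
  expect_equal(geometric_score(0.37), 0.37)
  expect_error(geometric_score(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(geometric_score(numeric(0)), "replica")
  set.seed(23)
  for (i in 1:50) {
    f <- runif(sample(1:5, 1))
    g <- geometric_score(f)
    expect_lte(g, mean(f) + 1e-12)
    expect_gte(g, 0)
    expect_lte(g, max(f) + 1e-12)
  }
  f_eq <- rep(0.63, 4)
  expect_equal(geometric_score(f_eq), mean(f_eq))
})

test_that("score table aligns replicas and annotation maps onto atoms", {
  freqs <- list(c(`10` = 0.2, `11` = 0.9),
                c(`10` = 0.4, `12` = 0.5),
                c(`10` = 0.8, `11` = 0.3))
  tab <- contact_score_table(freqs)
  expect_equal(tab$score[tab$resid == 10], 0.4)
  expect_equal(tab$score[tab$resid == 11], 0)   # absent in replica 2
  expect_equal(tab$score[tab$resid == 12], 0)

  s <- make_structure(matrix(rnorm(30), ncol = 3),
                      resid = rep(c(10, 11, 437, 500, 501), each = 2),
                      name = rep(c("CA", "CB"), 5))
  ann <- annotate_scores(s, data.frame(resid = 437, score = 0.4))
  expect_equal(ann$atoms$score[ann$atoms$resid == 437], c(0.4, 0.4))
  expect_true(all(ann$atoms$score[ann$atoms$resid != 437] == 0))
  empty <- annotate_scores(s, data.frame(resid = integer(0),
                                         score = numeric(0)))
  expect_true(all(empty$atoms$score == 0))
  expect_error(annotate_scores(s, data.frame(resid = 999, score = 1)),
               "not present")
  # round-trip through the annotated writer keeps scores to 2 decimals
  p <- withr::local_tempfile(fileext = ".pdb")
  write_annotated_pdb(ann, p)
  back <- as_structure(read_pdb(p), 1)
  expect_equal(back$atoms$score, ann$atoms$score, tolerance = 1e-8)
})

test_that("top geometric scores single out the declared contact residues", {
  pattern <- c(`427` = 0.7, `433` = 0.8, `437` = 0.9,
               `663` = 0.85, `666` = 0.75, `668` = 0.95)
  freqs <- lapply(1:3, function(r) {
    spec <- synthetic_spec(n_frames = 60, fluct_sigma = 0.3,
                           contact_pattern = pattern, seed = 40 + r)
    gen <- generate_trajectory(spec, replica = r)
    tmpl <- gen$trajectory$template
    contact_frequencies(gen$trajectory,
                        heavy_atoms(tmpl, gen$truth$lipid_atom_idx),
                        residue_atom_map(tmpl, gen$truth$protein_atoms))
  })
  tab <- contact_score_table(freqs)
  top <- tab$resid[tab$score >= 0.35]
  expect_setequal(top, as.integer(names(pattern)))
})
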