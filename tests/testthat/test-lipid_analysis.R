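# Gate-plane fitting, head-vector tilt, membrane-insertion fractions and
# tail egress ordering.

test_that("fit_gate_plane recovers exact and noisy planes, oriented outward", {
  pts <- matrix(c(1, 0, 0, 1, 0, 1, 1, 1, 0, 1, 1, 1), ncol = 3,
                byrow = TRUE)
  s <- make_structure(pts, resid = 1:4)
  pl <- fit_gate_plane(s, 1:4, axis_point = c(0, 0, 0.5))
  expect_equal(pl$normal, c(1, 0, 0), tolerance = 1e-10)
  expect_equal(pl$point[1], 1, tolerance = 1e-10)
  # axis on the other side flips the normal
  pl2 <- fit_gate_plane(s, 1:4, axis_point = c(5, 0.5, 0.5))
  expect_equal(pl2$normal, c(-1, 0, 0), tolerance = 1e-10)

  line <- make_structure(cbind(1:4, 1:4, 1:4), resid = 1:4)
  expect_error(fit_gate_plane(line, 1:4, c(0, 0, 0)), "collinear")

  # noisy plane: normal within 2 degrees of the oracle's direct fit
  set.seed(31)
  true_n <- c(2, 1, 0.5); true_n <- true_n / sqrt(sum(true_n^2))
  basis <- svd(matrix(true_n, 3), nu = 3)$u[, 2:3]
  uv <- matrix(rnorm(60, sd = 4), ncol = 2)
  noisy <- uv %*% t(basis) + matrix(rnorm(90, sd = 0.1), ncol = 3)
  ns <- make_structure(noisy, resid = 1:30)
  fit <- fit_gate_plane(ns, 1:30, axis_point = -10 * true_n)
  ang_true <- acos(abs(sum(fit$normal * true_n))) * 180 / pi
  expect_lt(ang_true, 2)
  ang_oracle <- acos(abs(sum(fit$normal * oracle_plane_normal(noisy)))) *
    180 / pi
  expect_lt(ang_oracle, 1e-4)
})

test_that("tilt angles follow the PA->PB vector against the axis", {
  mk <- function(pb) {
    coords <- rbind(c(0, 0, 0), pb, c(10, 0, 0), c(0, 10, 0), c(12, 3, 1))
    s <- make_structure(coords, resid = c(900, 900, 1, 2, 3),
                        name = c("PA", "PB", "CA", "CA", "CA"),
                        element = c("P", "P", "C", "C", "C"))
    make_traj(list(coords), s)
  }
  lip <- lipid_definition(1L, 2L)
  expect_equal(tilt_series(mk(c(0, 0, 1)), lip)$angles, 0)
  expect_equal(tilt_series(mk(c(0, 0, -1)), lip)$angles, 180)
  expect_equal(tilt_series(mk(c(1, 0, -1)), lip)$angles, 135)
  # PA/PB swap maps theta -> 180 - theta
  expect_equal(tilt_series(mk(c(1, 0, -1)), lip, flip = TRUE)$angles, 45)
  expect_warning(ts_na <- tilt_series(mk(c(0, 0, 0)), lip), "coincident")
  expect_true(is.na(ts_na$angles))
})

test_that("tilt is invariant to translations and rotations about the axis", {
  spec <- synthetic_spec(n_frames = 30, fluct_sigma = 0,
                         tilt_schedule = seq(10, 170, length.out = 30),
                         seed = 2)
  gen <- generate_trajectory(spec)
  base <- tilt_series(gen$trajectory, gen$truth$lipid)$angles
  th <- 1.1
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  moved <- gen$trajectory
  for (f in seq_len(n_frames(moved)))
    moved$frames[, , f] <- sweep(moved$frames[, , f] %*% t(Rz), 2,
                                 c(4, -7, 11), "+")
  expect_equal(tilt_series(moved, gen$truth$lipid)$angles, base,
               tolerance = 1e-9)
})

test_that("a prescribed tilt schedule is recovered frame-exact, histogram aligned", {
  nf <- 80
  sched <- pmin(180, pmax(0, 135 + 30 * sin(2 * pi * seq_len(nf) / 25)))
  spec <- synthetic_spec(n_frames = nf, fluct_sigma = 0.3,
                         tilt_schedule = sched, seed = 3)
  gen <- generate_trajectory(spec)
  ts <- tilt_series(gen$trajectory, gen$truth$lipid)
  expect_equal(ts$angles, sched, tolerance = 1e-6)
  expect_equal(sum(ts$histogram$count), nf)
  # 112.5 falls on a bin edge with the default 2.5-degree bins
  expect_true(112.5 %in% ts$histogram$bin_lo)

  const <- synthetic_spec(n_frames = 10, tilt_schedule = rep(112.5, 10),
                          seed = 4)
  cg <- generate_trajectory(const)
  hist <- tilt_series(cg$trajectory, cg$truth$lipid)$histogram
  expect_equal(hist$count[hist$bin_lo == 112.5], 10)
})

test_that("insertion fractions count tail atoms past the oriented plane", {
  plane <- gate_plane(c(0, 0, 0), c(1, 0, 0))
  mk <- function(xs) {
    coords <- rbind(c(0, 0, 50), c(0, 0, 59),
                    cbind(xs, seq_along(xs), 0))
    nt <- length(xs)
    s <- make_structure(coords, resid = rep(900, nt + 2),
                        name = c("PA", "PB", paste0("C1", seq_len(nt))),
                        element = c("P", "P", rep("C", nt)))
    make_traj(list(coords), s)
  }
  lip2 <- function(nt) lipid_definition(1L, 2L, list(2L + seq_len(nt %/% 2),
                                                     2L + nt %/% 2 +
                                                       seq_len(nt %/% 2)))
  all_in <- insertion_series(mk(rep(-1, 24)), lip2(24), plane)
  expect_equal(all_in$overall, 0)
  all_out <- insertion_series(mk(rep(1, 24)), lip2(24), plane)
  expect_equal(all_out$overall, 1)
  half <- insertion_series(mk(rep(c(1, -1), 12)), lip2(24), plane)
  expect_equal(half$overall, 0.5)
  # overall equals the atom-weighted mean of per-tail fractions
  expect_equal(half$overall,
               sum(half$per_tail * half$tail_sizes) / sum(half$tail_sizes))
  expect_error(insertion_series(mk(rep(1, 4)), lipid_definition(1L, 2L),
                                plane), "tails")
})

test_that("moving a tail atom outward never decreases the fraction", {
  plane <- gate_plane(c(0, 0, 0), c(1, 0, 0))
  set.seed(13)
  for (rep in 1:10) {
    xs <- rnorm(8)
    coords <- rbind(c(0, 0, 50), c(0, 0, 59), cbind(xs, 1:8, 0))
    s <- make_structure(coords, resid = rep(900, 10),
                        name = c("PA", "PB", paste0("C1", 1:8)),
                        element = c("P", "P", rep("C", 8)))
    lip <- lipid_definition(1L, 2L, list(3:6, 7:10))
    f0 <- insertion_series(make_traj(list(coords), s), lip, plane)$overall
    i <- sample(3:10, 1)
    coords2 <- coords
    coords2[i, 1] <- coords2[i, 1] + abs(rnorm(1, sd = 2))
    f1 <- insertion_series(make_traj(list(coords2), s), lip, plane)$overall
    expect_gte(f1, f0)
  }
})

test_that("egress order reproduces a prescribed sequential staircase", {
  nf <- 100
  eg <- matrix(0, nf, 6)
  eg[10:nf, 1] <- 5                       # tail 1 exits at frame 10
  eg[50:nf, 2] <- 5                       # tail 2 at frame 50
  eg[70:nf, 3] <- 2                       # tail 3 only partial
  spec <- synthetic_spec(n_frames = nf, egress_schedule = eg,
                         tail_length = 5, seed = 6)
  gen <- generate_trajectory(spec)
  ins <- insertion_series(gen$trajectory, gen$truth$lipid, gen$truth$plane)
  expect_equal(unname(ins$per_tail), unname(gen$truth$egress_fractions))
  eo <- egress_order(ins)
  expect_equal(eo$order, c(1, 2))
  expect_equal(eo$table$first_exit_frame[1:2], c(10L, 50L))
  expect_false(eo$table$exited[3])
  expect_true(all(!eo$table$exited[4:6]))

  none <- egress_order(ins, exit_threshold = 1.01)
  expect_length(none$order, 0)
  zero <- egress_order(ins, exit_threshold = 0)
  expect_equal(zero$table$first_exit_frame, rep(1L, 6))
})
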