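# Deterministic synthetic structures and trajectories with exact, recorded
# ground truth for every metric in the package. The generator emulates the
# study system at toy scale: a membrane-embedded beta-barrel with a vacant
# strand slot forming a lateral gate, an anchored surrogate lipid whose
# head-vector tilt follows a prescribed schedule, tail pseudo-atoms crossing
# the gate plane on a prescribed insertion schedule, contact probes realising
# prescribed per-replica frame fractions, and a membrane pseudo-atom
# flickering inward on a prescribed depth schedule.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic gate-barrel system
#'
#' All schedules are optional; a schedule that is `NULL` omits the
#' corresponding surrogate atoms from the system (e.g. no lipid in the
#' uncomplexed form). Every random component is fixed by `seed`.
#'
#' @param n_strands number of strands placed on the cylinder (>= 3); one
#'   extra slot is left vacant between the first and last strand to form the
#'   lateral gate.
#' @param strand_length residues per strand.
#' @param barrel_radius cylinder radius, Angstrom.
#' @param spacing Calpha rise per residue along the strand, Angstrom.
#' @param first_resid residue number of the first strand's first residue
#'   (default 424, so the default gate pairs 437-668 / 433-666 / 427-663
#'   fall on the flanking strands).
#' @param n_frames frames to generate.
#' @param dt_ns time step between frames, ns.
#' @param fluct_sigma per-residue Gaussian positional fluctuation
#'   (per-coordinate sigma, Angstrom); scalar or one value per residue.
#' @param tilt_schedule per-frame head tilt angle, degrees in `[0, 180]`
#'   (NA places PA and PB coincident in that frame), or NULL for no lipid
#'   head.
#' @param egress_schedule `n_frames x n_tails` matrix of inserted-atom
#'   counts per tail (0..`tail_length`), or NULL for no tails.
#' @param tail_length pseudo-atoms per tail.
#' @param contact_pattern named numeric vector: per-residue fraction of
#'   frames in contact (names are residue numbers), or NULL.
#' @param gate_pair_schedule `n_frames x n_pairs` matrix of imposed
#'   Calpha-Calpha distances for the gate pairs, or NULL.
#' @param flicker_schedule per-frame inward flicker depth of the membrane
#'   probe (Angstrom, >= 0), or NULL for no membrane atoms.
#' @param gate a `GateDefinition` naming the pairs and flanks (default:
#'   [gate_definition()] with flanks set to the two gate strands).
#' @param seed integer seed fixing all randomness.
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_strands = 13, strand_length = 19,
                           barrel_radius = 12, spacing = 3.3,
                           first_resid = 424,
                           n_frames = 100, dt_ns = 2,
                           fluct_sigma = 0,
                           tilt_schedule = NULL,
                           egress_schedule = NULL, tail_length = 5,
                           contact_pattern = NULL,
                           gate_pair_schedule = NULL,
                           flicker_schedule = NULL,
                           gate = NULL, seed = 1) {
  if (n_strands < 3) stop("n_strands must be >= 3")
  if (barrel_radius <= 0) stop("barrel_radius must be positive")
  stopifnot(strand_length >= 1, n_frames >= 1, tail_length >= 1)
  n_res <- n_strands * strand_length
  if (!length(fluct_sigma) %in% c(1, n_res))
    stop("fluct_sigma must be scalar or one value per residue (", n_res, ")")
  if (any(fluct_sigma < 0)) stop("fluct_sigma must be >= 0")
  last_resid <- first_resid + n_res - 1L
  strand1 <- first_resid:(first_resid + strand_length - 1L)
  strandN <- (last_resid - strand_length + 1L):last_resid
  if (is.null(gate)) {
    pairs <- list(c(437L, 668L), c(433L, 666L), c(427L, 663L))
    in_range <- vapply(pairs, function(p)
      p[1] %in% strand1 && p[2] %in% strandN, logical(1))
    if (!all(in_range))
      stop("default gate pairs do not fall on the flanking strands; ",
           "pass an explicit `gate` for this geometry")
    gate <- gate_definition(pairs,
                            flank_resids = c(strand1, strandN))
  }
  chk_len <- function(x, what, ncol_ok = NULL) {
    if (is.null(x)) return(invisible())
    if (is.matrix(x)) {
      if (nrow(x) != n_frames)
        stop(what, " must have n_frames (", n_frames, ") rows")
      if (!is.null(ncol_ok) && ncol(x) != ncol_ok)
        stop(what, " must have ", ncol_ok, " columns")
    } else if (length(x) != n_frames) {
      stop(what, " length must equal n_frames (", n_frames, ")")
    }
  }
  chk_len(tilt_schedule, "tilt_schedule")
  if (!is.null(tilt_schedule) &&
      any(tilt_schedule < 0 | tilt_schedule > 180, na.rm = TRUE))
    stop("tilt_schedule angles must lie in [0, 180]")
  if (!is.null(egress_schedule)) {
    egress_schedule <- as.matrix(egress_schedule)
    chk_len(egress_schedule, "egress_schedule")
    if (any(egress_schedule < 0 | egress_schedule > tail_length))
      stop("egress_schedule counts must lie in [0, tail_length]")
  }
  if (!is.null(gate_pair_schedule)) {
    gate_pair_schedule <- as.matrix(gate_pair_schedule)
    chk_len(gate_pair_schedule, "gate_pair_schedule", length(gate$pairs))
    if (any(gate_pair_schedule <= 0))
      stop("gate_pair_schedule distances must be positive")
  }
  chk_len(flicker_schedule, "flicker_schedule")
  if (!is.null(flicker_schedule) && any(flicker_schedule < 0))
    stop("flicker_schedule depths must be >= 0")
  if (!is.null(contact_pattern)) {
    if (is.null(names(contact_pattern)))
      stop("contact_pattern must be named by residue number")
    if (any(contact_pattern < 0 | contact_pattern > 1))
      stop("contact_pattern fractions must lie in [0, 1]")
    bad <- as.integer(names(contact_pattern))
    if (any(bad < first_resid | bad > last_resid))
      stop("contact_pattern residue outside the barrel numbering")
  }
  structure(list(n_strands = as.integer(n_strands),
                 strand_length = as.integer(strand_length),
                 barrel_radius = barrel_radius, spacing = spacing,
                 first_resid = as.integer(first_resid),
                 n_frames = as.integer(n_frames), dt_ns = dt_ns,
                 fluct_sigma = fluct_sigma,
                 tilt_schedule = tilt_schedule,
                 egress_schedule = egress_schedule,
                 tail_length = as.integer(tail_length),
                 contact_pattern = contact_pattern,
                 gate_pair_schedule = gate_pair_schedule,
                 flicker_schedule = flicker_schedule,
                 gate = gate, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# strand angles: n_strands + 1 equal slots, the vacant one straddling
# theta = 0, so strands 1 and n flank the gate symmetrically.
strand_angles <- function(spec) {
  2 * pi * seq_len(spec$n_strands) / (spec$n_strands + 1)
}

toy_z_mid <- function(spec) (spec$strand_length - 1) * spec$spacing / 2

# analytic gate plane of the construction: all flank Calphas share
# x = R cos(alpha); outward normal +x (barrel axis is the z axis at x=y=0).
toy_gate_plane <- function(spec) {
  alpha <- 2 * pi / (spec$n_strands + 1)
  gate_plane(c(spec$barrel_radius * cos(alpha), 0, toy_z_mid(spec)),
             c(1, 0, 0))
}

#' Build the toy barrel structure
#'
#' Calpha-only strands placed vertically on a cylinder, with one strand slot
#' left vacant between the first and last strand so their flanking strands
#' straddle a planar lateral opening. Residues are numbered consecutively
#' from `first_resid` strand by strand, which places the default gate pairs
#' on the flanking strands. Deterministic given the spec.
#'
#' @param spec a `SyntheticSpec`.
#' @return a `Structure` (protein only).
#' @export
build_toy_barrel <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  ang <- strand_angles(spec)
  n_res <- spec$n_strands * spec$strand_length
  resid <- spec$first_resid + seq_len(n_res) - 1L
  strand <- rep(seq_len(spec$n_strands), each = spec$strand_length)
  j <- rep(seq_len(spec$strand_length), times = spec$n_strands)
  coords <- cbind(spec$barrel_radius * cos(ang[strand]),
                  spec$barrel_radius * sin(ang[strand]),
                  (j - 1) * spec$spacing)
  atoms <- data.frame(serial = seq_len(n_res),
                      name = "CA", resname = "ALA",
                      resid = resid, chain = "A", element = "C",
                      score = 0, stringsAsFactors = FALSE)
  new_structure(atoms, coords, title = "synthetic toy barrel")
}

# assemble the full synthetic system (barrel + surrogate lipid, probes,
# membrane atoms) as a Structure plus index bookkeeping
toy_system <- function(spec) {
  prot <- build_toy_barrel(spec)
  atoms <- prot$atoms
  coords <- prot$coords
  plane <- toy_gate_plane(spec)
  z_mid <- toy_z_mid(spec)
  add <- function(name, resname, resid, chain, element, xyz) {
    atoms <<- rbind(atoms,
                    data.frame(serial = nrow(atoms) + 1L, name = name,
                               resname = resname, resid = resid,
                               chain = chain, element = element, score = 0,
                               stringsAsFactors = FALSE))
    coords <<- rbind(coords, matrix(xyz, ncol = 3))
    nrow(atoms)
  }
  idx <- list(protein = seq_len(nrow(prot$atoms)))

  if (!is.null(spec$tilt_schedule) || !is.null(spec$egress_schedule)) {
    idx$pa <- add("PA", "LPA", 900L, "L", "P", c(0, 0, z_mid))
    idx$pb <- add("PB", "LPA", 900L, "L", "P", c(0, 0, z_mid + 9))
  }
  if (!is.null(spec$egress_schedule)) {
    nt <- ncol(spec$egress_schedule)
    idx$tails <- vector("list", nt)
    for (t in seq_len(nt)) {
      y_t <- (t - (nt + 1) / 2) * 1.2
      idx$tails[[t]] <- vapply(seq_len(spec$tail_length), function(k) {
        add(sprintf("C%d%d", t, k), "LPA", 900L, "L", "C",
            plane$point + c(-(0.5 + k), y_t, 0))
      }, integer(1))
    }
  }
  if (!is.null(spec$contact_pattern)) {
    resids <- as.integer(names(spec$contact_pattern))
    idx$probes <- vapply(resids, function(r) {
      add(paste0("Q", r), "LPA", 900L, "L", "C", c(0, 0, 0))
    }, integer(1))
    idx$decoys <- vapply(resids, function(r) {
      add(paste0("H", r), "LPA", 900L, "L", "H", c(0, 0, 0))
    }, integer(1))
    names(idx$probes) <- names(idx$decoys) <- resids
  }
  if (!is.null(spec$flicker_schedule)) {
    idx$flicker <- add("CM", "MEM", 2001L, "M", "C",
                       plane$point + c(5, 0, 0))
    # background membrane atoms on the far side of the barrel, outside the
    # gate region, so the membrane selection is never a single atom
    idx$membrane_bg <- vapply(1:4, function(k) {
      th <- pi + (k - 2.5) * 0.4
      add("CM", "MEM", 2001L + k, "M", "C",
          c((spec$barrel_radius + 6) * cos(th),
            (spec$barrel_radius + 6) * sin(th), z_mid))
    }, integer(1))
  }
  sys <- new_structure(atoms, coords, title = "synthetic gate system")
  list(structure = sys, idx = idx, plane = plane)
}

#' Generate a synthetic trajectory with recorded ground truth
#'
#' Frames realise, simultaneously and independently: per-residue Gaussian
#' positional fluctuations of the protein Calphas; a lipid head vector
#' reproducing `tilt_schedule` exactly; tail pseudo-atoms whose per-frame
#' inserted-atom counts match `egress_schedule` exactly relative to the
#' construction's gate plane; contact probes giving each patterned residue
#' its prescribed contact frame-fraction exactly (probes ride the fluctuating
#' target Calpha at a fixed 3 A offset, plus always-near hydrogen decoys that
#' exercise heavy-atom filtering); optional imposed gate-pair distances; and
#' a membrane probe reproducing `flicker_schedule`. Identical spec and seed
#' give bit-identical output; distinct replicas decorrelate the noise stream
#' only.
#'
#' @param spec a `SyntheticSpec`.
#' @param replica replica index (1-based); offsets the noise seed.
#' @return list with `trajectory` (a `Trajectory`), `structure` (the frame-1
#'   template), and `truth`: the schedules plus derived quantities (gate
#'   plane, lipid/membrane/flank index bookkeeping, exact per-residue
#'   contact frequencies, per-tail insertion fractions).
#' @export
generate_trajectory <- function(spec, replica = 1) {
  stopifnot(inherits(spec, "SyntheticSpec"), replica >= 1)
  sys <- toy_system(spec)
  base <- sys$structure$coords
  idx <- sys$idx
  plane <- sys$plane
  nf <- spec$n_frames
  n_prot <- length(idx$protein)
  n_res <- n_prot                       # Calpha-only: one atom per residue
  sigma <- rep(spec$fluct_sigma, length.out = n_res)

  noise <- with_seed(spec$seed + 7919L * (replica - 1L), {
    array(stats::rnorm(n_prot * 3 * nf, sd = rep(sigma, 3 * nf)),
          dim = c(n_prot, 3, nf))
  })

  ang <- strand_angles(spec)
  resid_of <- sys$structure$atoms$resid
  radial_unit <- function(atom_i) {
    th <- atan2(base[atom_i, 2], base[atom_i, 1])
    c(cos(th), sin(th), 0)
  }

  pair_idx <- lapply(spec$gate$pairs,
                     function(p) ca_index(sys$structure, p))
  pair_units <- lapply(pair_idx, function(ii) {
    u <- base[ii[2], ] - base[ii[1], ]
    u / sqrt(sum(u^2))
  })

  contact_resids <- if (is.null(spec$contact_pattern)) integer(0) else
    as.integer(names(spec$contact_pattern))
  n_contact_frames <- if (length(contact_resids) > 0)
    round(spec$contact_pattern * nf) else numeric(0)
  probe_target <- if (length(contact_resids) > 0)
    ca_index(sys$structure, contact_resids) else integer(0)

  frames <- array(NA_real_, dim = c(nrow(base), 3, nf))
  for (f in seq_len(nf)) {
    fr <- base
    fr[idx$protein, ] <- fr[idx$protein, ] + noise[, , f]
    if (!is.null(spec$gate_pair_schedule)) {
      for (j in seq_along(pair_idx)) {
        ii <- pair_idx[[j]]
        fr[ii[2], ] <- fr[ii[1], ] +
          spec$gate_pair_schedule[f, j] * pair_units[[j]]
      }
    }
    if (!is.null(spec$tilt_schedule)) {
      th <- spec$tilt_schedule[f]
      if (is.na(th)) {
        fr[idx$pb, ] <- fr[idx$pa, ]
      } else {
        fr[idx$pb, ] <- fr[idx$pa, ] +
          9 * c(sin(th * pi / 180), 0, cos(th * pi / 180))
      }
    }
    if (!is.null(spec$egress_schedule)) {
      for (t in seq_along(idx$tails)) {
        m <- spec$egress_schedule[f, t]
        ti <- idx$tails[[t]]
        y_t <- base[ti[1], 2]
        for (k in seq_along(ti)) {
          side <- if (k <= m) +1 else -1
          fr[ti[k], ] <- plane$point + c(side * (0.5 + k), y_t, 0)
        }
      }
    }
    for (q in seq_along(contact_resids)) {
      tgt <- fr[probe_target[q], ]
      u <- radial_unit(probe_target[q])
      near <- tgt + 3 * u
      far <- tgt + 33 * u
      fr[idx$probes[q], ] <- if (f <= n_contact_frames[q]) near else far
      fr[idx$decoys[q], ] <- near     # decoy hydrogen always in range
    }
    if (!is.null(spec$flicker_schedule)) {
      d <- spec$flicker_schedule[f]
      fr[idx$flicker, ] <- plane$point +
        if (d > 0) c(-d, 0, 0) else c(5, 0, 0)
    }
    frames[, , f] <- fr
  }
  template <- sys$structure
  template$coords <- frames[, , 1, drop = TRUE]
  traj <- new_trajectory(template, frames,
                         times = (seq_len(nf) - 1) * spec$dt_ns)

  lipid <- if (!is.null(idx$pa))
    lipid_definition(idx$pa, idx$pb,
                     if (is.null(idx$tails)) list() else idx$tails)
  else NULL
  truth <- list(
    spec = spec, replica = replica,
    plane = plane,
    gate = spec$gate,
    flank_atoms = ca_index(sys$structure, spec$gate$flank_resids),
    protein_atoms = idx$protein,
    lipid = lipid,
    lipid_atom_idx = unname(unlist(idx[c("pa", "pb", "tails",
                                         "probes", "decoys")])),
    membrane_atoms = unname(unlist(idx[c("flicker", "membrane_bg")])),
    tilt = spec$tilt_schedule,
    egress_counts = spec$egress_schedule,
    egress_fractions = if (!is.null(spec$egress_schedule))
      spec$egress_schedule / spec$tail_length else NULL,
    contact_frequencies = if (length(contact_resids) > 0)
      stats::setNames(n_contact_frames / nf, contact_resids) else NULL,
    flicker = spec$flicker_schedule,
    fluct_sigma = sigma)
  list(trajectory = traj, structure = template, truth = truth)
}

#' Default study-condition replica specs
#'
#' The synthetic stand-in for the study's three complexed 1-microsecond
#' replicas, at toy scale (200 frames at 2 ns spacing). Each replica carries:
#' Calpha fluctuations of sigma 0.3 A; a tilt schedule that relaxes from 90
#' degrees to a replica-specific plateau (120 / 150 / 172 degrees) within
#' the band the complexed simulations stabilise in; a sequential six-tail
#' egress staircase in which replica 2 completes all six tails while
#' replicas 1 and 3 stall after the leading tails (with a transient retreat
#' of tail 2 in replica 1); reproducible contacts on the gate-flank pair
#' residues plus one single-replica (non-reproducible) contact; and an
#' occasional membrane flicker never deeper than 4 A.
#'
#' @param replica replica index, 1..3.
#' @param seed base seed.
#' @param n_frames frames per replica.
#' @return a `SyntheticSpec`.
#' @export
default_study_spec <- function(replica = 1, seed = 1, n_frames = 200) {
  stopifnot(replica %in% 1:3)
  f <- seq_len(n_frames)
  plateau <- c(120, 150, 172)[replica]
  tilt <- 90 + (plateau - 90) * (1 - exp(-f / (n_frames / 6))) +
    3 * sin(2 * pi * f / 37)
  tilt <- pmin(180, pmax(0, tilt))

  tail_length <- 5
  ramp <- function(start, dur, top = tail_length) {
    cnt <- pmin(top, pmax(0, floor((f - start) / dur * top) + 1))
    cnt[f < start] <- 0
    cnt
  }
  eg <- matrix(0, n_frames, 6)
  if (replica == 1) {
    eg[, 1] <- ramp(5, 30)
    t2 <- ramp(40, 40)                       # exits, retreats, re-emerges
    t2[f >= 90 & f < 110] <- pmax(0, t2[f >= 90 & f < 110] - 3)
    t2[f >= 110] <- tail_length - 1          # almost complete, then stalls
    eg[, 2] <- t2
    eg[, 3] <- pmin(ramp(120, 60), 2)        # partial third tail
  } else if (replica == 2) {
    for (t in 1:6) eg[, t] <- ramp(5 + (t - 1) * 25, 20)
  } else {
    eg[, 1] <- ramp(3, 10)
    eg[, 2] <- ramp(25, 15)
    eg[, 3] <- pmin(ramp(160, 30), 3)        # third tail starting late
  }

  pattern_resids <- c(427, 433, 437, 663, 666, 668)
  base_fracs <- c(0.70, 0.80, 0.90, 0.85, 0.75, 0.95)
  fracs <- pmin(1, base_fracs + 0.02 * (replica - 2))
  pattern <- stats::setNames(fracs, pattern_resids)
  if (replica == 1) pattern <- c(pattern, `445` = 0.5)  # non-reproducible

  flick <- numeric(n_frames)
  flick[f %% 23 == 0] <- 3.2
  flick[f %% 57 == 0] <- 3.8

  synthetic_spec(n_frames = n_frames, fluct_sigma = 0.3,
                 tilt_schedule = tilt, egress_schedule = eg,
                 tail_length = tail_length,
                 contact_pattern = pattern,
                 flicker_schedule = flick,
                 seed = seed)
}
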