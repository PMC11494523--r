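# Anchored-lipid observables: the gate plane, the head-vector tilt angle and
# its histogram, the membrane-insertion fraction of the aliphatic tails, and
# the order in which tails exit through the gate.

#' Fit the gate plane
#'
#' Least-squares plane through the gate-flank Calphas: the plane normal is
#' the direction of smallest positional variance of the flank atoms. The
#' normal is oriented outward, away from the barrel axis: flipped so that
#' `(centroid - axis_point) . normal > 0`.
#'
#' @param structure a `Structure` (typically the reference frame).
#' @param flank_resids residues lining the gate (their Calphas define the
#'   plane).
#' @param axis_point a point on the barrel axis (3-vector, Angstrom), used
#'   only to orient the normal.
#' @return object of class `GatePlane`: list with `point` (plane centroid)
#'   and unit `normal` (outward).
#' @export
fit_gate_plane <- function(structure, flank_resids, axis_point) {
  stopifnot(inherits(structure, "Structure"), length(axis_point) == 3)
  idx <- ca_index(structure, flank_resids)
  pts <- structure$coords[idx, , drop = FALSE]
  if (nrow(pts) < 3)
    stop("degenerate flank set: at least 3 Calphas required")
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(centered) / nrow(pts), symmetric = TRUE)
  # eigenvalues descending; collinear points have two near-zero eigenvalues
  if (ev$values[2] < 1e-10 * max(ev$values[1], 1))
    stop("degenerate flank set: Calphas are collinear")
  normal <- ev$vectors[, 3]
  if (sum((ctr - axis_point) * normal) < 0) normal <- -normal
  gate_plane(ctr, normal)
}

#' Construct an oriented gate plane
#' @param point 3-vector on the plane.
#' @param normal outward normal (normalised internally).
#' @return object of class `GatePlane`.
#' @export
gate_plane <- function(point, normal) {
  stopifnot(length(point) == 3, length(normal) == 3)
  nrm <- sqrt(sum(normal^2))
  if (!is.finite(nrm) || nrm < 1e-12)
    stop("plane normal must be a non-zero vector")
  structure(list(point = as.numeric(point),
                 normal = as.numeric(normal) / nrm),
            class = "GatePlane")
}

check_gate_plane <- function(plane) {
  if (!inherits(plane, "GatePlane") ||
      abs(sqrt(sum(plane$normal^2)) - 1) > 1e-8)
    stop("an oriented GatePlane (unit outward normal) is required")
  invisible(plane)
}

#' Signed distance of points to an oriented plane
#'
#' Positive on the outward (membrane) side of the gate plane, negative on the
#' channel side.
#'
#' @param coords n x 3 matrix.
#' @param plane a `GatePlane`.
#' @return numeric vector of signed distances (Angstrom).
#' @export
signed_plane_distance <- function(coords, plane) {
  check_gate_plane(plane)
  as.numeric(sweep(as.matrix(coords), 2, plane$point) %*% plane$normal)
}

#' Define the anchored lipid
#'
#' Atom bookkeeping for the lipid whose egress is monitored: the two head
#' phosphorus atoms (PA, PB) spanning the tilt vector, and the grouped
#' aliphatic-tail atoms (six tails for lipid A).
#'
#' @param pa_atom,pb_atom atom indices of the head phosphorus atoms.
#' @param tails list of atom-index vectors, one per tail; disjoint, each
#'   non-empty. May be empty (`list()`) for a head-only definition, in which
#'   case tail-based operations refuse to run.
#' @param head_atoms optional atom indices of the full head group.
#' @return object of class `LipidDefinition`.
#' @export
lipid_definition <- function(pa_atom, pb_atom, tails = list(),
                             head_atoms = c(pa_atom, pb_atom)) {
  stopifnot(length(pa_atom) == 1, length(pb_atom) == 1)
  if (pa_atom == pb_atom) stop("PA and PB must be distinct atoms")
  if (any(lengths(tails) == 0))
    stop("each tail must be a non-empty atom-index vector")
  flat <- unlist(tails)
  if (anyDuplicated(flat)) stop("tail atom sets must be disjoint")
  structure(list(pa_atom = as.integer(pa_atom),
                 pb_atom = as.integer(pb_atom),
                 tails = lapply(tails, as.integer),
                 head_atoms = as.integer(head_atoms)),
            class = "LipidDefinition")
}

#' Lipid head tilt-angle series
#'
#' Per frame, the angle (degrees, in `[0, 180]`) between the PA-to-PB head
#' vector and the reference axis (default the simulation-box +Z, the membrane
#' normal). Frames where PA and PB coincide (vector shorter than 1e-6 A) are
#' flagged as missing values, not errors. Reversing the vector direction with
#' `flip = TRUE` maps every angle to 180 minus itself.
#'
#' @param traj a `Trajectory`.
#' @param lipid a `LipidDefinition`.
#' @param axis reference direction, default `c(0, 0, 1)`.
#' @param bin_width histogram bin width in degrees, default 2.5 (so the
#'   112.5 degree boundary falls on a bin edge).
#' @param flip use the PB-to-PA vector instead.
#' @return object of class `TiltSeries`: list with `angles` (degrees, NA
#'   where degenerate), `times`, and `histogram` (data.frame bin_lo, bin_hi,
#'   count; NA angles excluded).
#' @export
tilt_series <- function(traj, lipid, axis = c(0, 0, 1), bin_width = 2.5,
                        flip = FALSE) {
  stopifnot(inherits(traj, "Trajectory"), inherits(lipid, "LipidDefinition"))
  axis <- axis / sqrt(sum(axis^2))
  pa <- atom_track(traj, lipid$pa_atom)
  pb <- atom_track(traj, lipid$pb_atom)
  v <- pb - pa                      # 3 x n_frames
  if (flip) v <- -v
  len <- sqrt(colSums(v^2))
  cosang <- colSums(v * axis) / len
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  degen <- len < 1e-6
  if (any(degen)) {
    warning(sum(degen), " frame(s) with coincident PA/PB flagged as NA")
    ang[degen] <- NA_real_
  }
  breaks <- seq(0, 180, by = bin_width)
  if (breaks[length(breaks)] < 180) breaks <- c(breaks, 180)
  h <- graphics::hist(ang[!is.na(ang)], breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  structure(list(angles = ang,
                 times = traj$times,
                 histogram = data.frame(bin_lo = breaks[-length(breaks)],
                                        bin_hi = breaks[-1],
                                        count = h$counts)),
            class = "TiltSeries")
}

#' @export
print.TiltSeries <- function(x, ...) {
  ok <- x$angles[!is.na(x$angles)]
  cat(sprintf("TiltSeries: %d frames, range %.1f-%.1f deg\n",
              length(x$angles), min(ok), max(ok)))
  invisible(x)
}

#' Membrane-insertion fraction of the lipid tails
#'
#' Per frame, the fraction of aliphatic-tail atoms on the membrane (outward)
#' side of the oriented gate plane: an atom counts as inserted iff its signed
#' plane distance is > 0. Reported per tail and overall; the overall value is
#' the atom-weighted mean of the per-tail fractions. This is an atom-count
#' fraction across the gate plane, the operative proxy for the extent to
#' which the tails have entered the membrane.
#'
#' @param traj a `Trajectory`.
#' @param lipid a `LipidDefinition` (tails must be defined).
#' @param plane an oriented `GatePlane`.
#' @return object of class `InsertionSeries`: list with `overall` (numeric,
#'   per frame), `per_tail` (frames x tails matrix), `tail_sizes`, `times`.
#' @export
insertion_series <- function(traj, lipid, plane) {
  stopifnot(inherits(traj, "Trajectory"), inherits(lipid, "LipidDefinition"))
  check_gate_plane(plane)
  if (length(lipid$tails) == 0) stop("lipid has no tails defined")
  nf <- n_frames(traj)
  nt <- length(lipid$tails)
  per_tail <- matrix(NA_real_, nrow = nf, ncol = nt,
                     dimnames = list(NULL, paste0("tail", seq_len(nt))))
  sizes <- lengths(lipid$tails)
  for (f in seq_len(nf)) {
    fr <- traj$frames[, , f]
    for (t in seq_len(nt)) {
      sd_ <- signed_plane_distance(fr[lipid$tails[[t]], , drop = FALSE],
                                   plane)
      per_tail[f, t] <- sum(sd_ > 0) / sizes[t]
    }
  }
  overall <- as.numeric(per_tail %*% sizes) / sum(sizes)
  structure(list(overall = overall, per_tail = per_tail,
                 tail_sizes = sizes, times = traj$times),
            class = "InsertionSeries")
}

#' @export
print.InsertionSeries <- function(x, ...) {
  cat(sprintf(
    "InsertionSeries: %d frames, %d tails, final overall fraction %.2f\n",
    length(x$overall), ncol(x$per_tail), x$overall[length(x$overall)]))
  invisible(x)
}

#' Tail egress order
#'
#' For each tail, the first frame in which its insertion fraction reaches
#' `exit_threshold`; tails that never reach it are reported as not exited.
#' The exit order sorts exited tails by first-exit frame (ties broken by
#' tail index).
#'
#' @param series an `InsertionSeries`.
#' @param exit_threshold per-tail fraction counting as a complete exit,
#'   default 0.9.
#' @return list with `table` (data.frame tail, first_exit_frame (NA if
#'   never), exited) and `order` (integer tail indices, exited tails only,
#'   in exit order).
#' @export
egress_order <- function(series, exit_threshold = 0.9) {
  stopifnot(inherits(series, "InsertionSeries"))
  if (length(series$overall) == 0) stop("empty insertion series")
  nt <- ncol(series$per_tail)
  first <- vapply(seq_len(nt), function(t) {
    i <- which(series$per_tail[, t] >= exit_threshold)
    if (length(i) == 0) NA_integer_ else i[1]
  }, integer(1))
  exited <- !is.na(first)
  ord <- order(first, seq_len(nt), na.last = NA)
  list(table = data.frame(tail = seq_len(nt),
                          first_exit_frame = first,
                          exited = exited),
       order = ord)
}
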