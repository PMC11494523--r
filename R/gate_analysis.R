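# Lateral-gate aperture monitoring: Calpha-Calpha distances across the gap
# between the first and last barrel strands, a closure report, and the inward
# "flicker" depth of membrane lipids past the gate plane.

#' Define the lateral gate
#'
#' The gate is user-declared: residue pairs whose Calpha-Calpha distances
#' proxy the aperture width, plus the set of residues lining the gate (the
#' flanking strands). Defaults are the three GfcD pairs spread evenly along
#' the gate between strands beta-1 and beta-13 of the C-terminal barrel:
#' 437-668, 433-666, 427-663. Pairs are matched by residue number only; the
#' residue names found are logged, never checked.
#'
#' @param pairs list of `c(resid_a, resid_b)` pairs.
#' @param flank_resids residues lining the gate; defaults to all residues
#'   appearing in `pairs`.
#' @param closure_threshold aperture distance (Angstrom) below which a pair
#'   counts as closed in [closure_report()]. Default 6 A, roughly the
#'   Calpha-Calpha distance of paired beta strands in contact.
#' @return object of class `GateDefinition`.
#' @export
gate_definition <- function(pairs = list(c(437L, 668L),
                                         c(433L, 666L),
                                         c(427L, 663L)),
                            flank_resids = NULL,
                            closure_threshold = 6) {
  if (length(pairs) == 0) stop("gate needs at least one residue pair")
  for (p in pairs)
    if (length(p) != 2 || any(!is.finite(p)))
      stop("each gate pair must be c(resid_a, resid_b)")
  if (is.null(flank_resids))
    flank_resids <- sort(unique(unlist(pairs)))
  stopifnot(is.numeric(closure_threshold), closure_threshold >= 0)
  structure(list(pairs = lapply(pairs, as.integer),
                 flank_resids = as.integer(flank_resids),
                 closure_threshold = closure_threshold),
            class = "GateDefinition")
}

pair_label <- function(p) paste0(p[1], "-", p[2])

# Calpha atom index for each requested residue; errors name the residue.
ca_index <- function(structure, resids) {
  at <- structure$atoms
  vapply(resids, function(r) {
    i <- which(at$resid == r & at$name == "CA")
    if (length(i) == 0)
      stop("no CA atom found for residue ", r)
    i[1]
  }, integer(1))
}

#' Gate aperture distance series
#'
#' Euclidean Calpha-Calpha distance for every gate pair in every frame, with
#' per-pair mean / sd / min summary statistics.
#'
#' @param traj a `Trajectory`.
#' @param gate a `GateDefinition`.
#' @return object of class `ApertureSeries`: list with `distances` (frames x
#'   pairs matrix, columns labelled "a-b"), `times`, `summary` (data.frame
#'   pair, mean_A, sd_A, min_A), and the `gate` used.
#' @export
aperture_series <- function(traj, gate) {
  stopifnot(inherits(traj, "Trajectory"), inherits(gate, "GateDefinition"))
  tmpl <- traj$template
  labels <- vapply(gate$pairs, pair_label, character(1))
  idx <- lapply(gate$pairs, function(p) ca_index(tmpl, p))
  found <- vapply(idx, function(i)
    paste(tmpl$atoms$resname[i], collapse = "/"), character(1))
  message("gate pairs resolved: ",
          paste(sprintf("%s (%s)", labels, found), collapse = ", "))
  nf <- n_frames(traj)
  d <- matrix(NA_real_, nrow = nf, ncol = length(idx),
              dimnames = list(NULL, labels))
  for (j in seq_along(idx)) {
    a <- atom_track(traj, idx[[j]][1])
    b <- atom_track(traj, idx[[j]][2])
    d[, j] <- sqrt(colSums((a - b)^2))
  }
  summary <- data.frame(pair = labels,
                        mean_A = apply(d, 2, mean),
                        sd_A = apply(d, 2, stats::sd),
                        min_A = apply(d, 2, min),
                        row.names = NULL)
  structure(list(distances = d,
                 times = traj$times,
                 summary = summary,
                 gate = gate),
            class = "ApertureSeries")
}

#' @export
print.ApertureSeries <- function(x, ...) {
  cat(sprintf("ApertureSeries: %d frames, %d pairs\n",
              nrow(x$distances), ncol(x$distances)))
  print(x$summary)
  invisible(x)
}

#' Gate closure report
#'
#' Fraction of frames each pair spends below the closure threshold, and
#' whether the gate stayed open throughout (true iff every pair's
#' below-threshold fraction is exactly zero).
#'
#' @param series an `ApertureSeries`.
#' @param gate optional `GateDefinition` overriding the one stored in
#'   `series` (e.g. to probe a different threshold).
#' @return list with `fractions` (data.frame pair, frac_below),
#'   `threshold_A`, and logical `stayed_open`.
#' @export
closure_report <- function(series, gate = series$gate) {
  stopifnot(inherits(series, "ApertureSeries"))
  if (nrow(series$distances) == 0) stop("empty aperture series")
  thr <- gate$closure_threshold
  frac <- apply(series$distances < thr, 2, mean)
  list(fractions = data.frame(pair = colnames(series$distances),
                              frac_below = as.numeric(frac),
                              row.names = NULL),
       threshold_A = thr,
       stayed_open = all(frac == 0))
}

#' Inward flicker depth of membrane lipids
#'
#' Per frame, the deepest inward penetration (Angstrom) of any membrane-lipid
#' atom past the gate plane, restricted to the gate region: only atoms within
#' `gate_region_radius` of the nearest gate-flank Calpha count. Penetration
#' is measured as minus the signed distance to the oriented plane (outward
#' normal positive) and clamped at zero, so a frame with all membrane atoms
#' on the outward side scores 0.
#'
#' @param traj a `Trajectory`.
#' @param plane an oriented `GatePlane` (see [fit_gate_plane()]).
#' @param membrane_atoms atom indices of the membrane lipid selection.
#' @param flank_atoms atom indices of the gate-flank Calphas (defines the
#'   gate region per frame).
#' @param gate_region_radius region radius in Angstrom, default 8.
#' @return data.frame with columns `frame`, `time_ns`, `depth_A`.
#' @export
flicker_depth_series <- function(traj, plane, membrane_atoms, flank_atoms,
                                 gate_region_radius = 8) {
  stopifnot(inherits(traj, "Trajectory"))
  check_gate_plane(plane)
  if (length(membrane_atoms) == 0) stop("membrane_atoms must be non-empty")
  if (length(flank_atoms) == 0) stop("flank_atoms must be non-empty")
  nf <- n_frames(traj)
  depth <- numeric(nf)
  for (f in seq_len(nf)) {
    m <- traj$frames[membrane_atoms, , f, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    fl <- traj$frames[flank_atoms, , f, drop = FALSE]
    dim(fl) <- dim(fl)[1:2]
    d2 <- cross_dist2(m, fl)
    in_region <- sqrt(apply(d2, 1, min)) <= gate_region_radius
    if (!any(in_region)) { depth[f] <- 0; next }
    sd_ <- signed_plane_distance(m[in_region, , drop = FALSE], plane)
    depth[f] <- max(0, -min(sd_))
  }
  data.frame(frame = seq_len(nf),
             time_ns = if (is.null(traj$times)) NA_real_ else traj$times,
             depth_A = depth)
}

# one atom's coordinates across frames, as a 3 x n_frames matrix
atom_track <- function(traj, i) matrix(traj$frames[i, , ], nrow = 3)

# squared distances between two point sets (rows)
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
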