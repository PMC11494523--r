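# Least-squares rigid-body superposition (Kabsch) and the RMSD / RMSF
# observables built on it.

#' Optimal rigid-body superposition of two coordinate sets
#'
#' Kabsch algorithm: the proper rotation and translation minimising the RMSD
#' between `mobile` and `reference` over all rigid transforms. When the
#' optimal orthogonal transform would be a reflection, the rotation is
#' corrected to the best proper rotation (determinant +1).
#'
#' The fitted transform maps a mobile point `p` (row vector) to
#' `p %*% t(rotation) + translation`.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, not collinear.
#' @return object of class `Superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length 3), and `rmsd` (Angstrom).
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3)
    stop("coordinate sets must be n x 3 matrices")
  n <- nrow(mobile)
  if (nrow(reference) != n)
    stop("coordinate sets must have equal point counts")
  if (n < 3)
    stop("degenerate input: at least 3 points are required")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)      # centered mobile
  X <- sweep(reference, 2, cr)   # centered reference
  # collinearity check: a well-defined rotation needs rank >= 2
  if (svd(P, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, svd(P, nu = 0, nv = 0)$d[1]))
    stop("degenerate input: mobile points are collinear")
  if (svd(X, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, svd(X, nu = 0, nv = 0)$d[1]))
    stop("degenerate input: reference points are collinear")
  C <- crossprod(X, P)           # 3x3 cross-covariance  sum x_i p_i^T
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum((fitted - X)^2) / n)
  translation <- as.numeric(cr - R %*% cm)
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "Superposition")
}

#' Apply a fitted superposition to coordinates
#' @param fit a `Superposition` from [kabsch()].
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(fit, coords) {
  stopifnot(inherits(fit, "Superposition"))
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Backbone atom names
#'
#' The default backbone definition used by the RMSD/RMSF observables:
#' N, CA, C (carbonyl O excluded), matching the backbone group conventional
#' in MD analysis of proteins. Pass `with_o = TRUE` to include O.
#'
#' @param with_o include the carbonyl oxygen.
#' @return character vector of atom names.
#' @export
backbone_names <- function(with_o = FALSE) {
  if (with_o) c("N", "CA", "C", "O") else c("N", "CA", "C")
}

#' Per-frame RMSD relative to a reference frame
#'
#' Each frame is independently least-squares superposed onto the reference
#' frame over `selection`, and the minimised RMSD recorded.
#'
#' @param traj a `Trajectory`.
#' @param selection integer atom indices (e.g. the backbone).
#' @param ref_frame reference frame index, default 1 (the starting
#'   structure).
#' @return data.frame with columns `frame`, `time_ns` (NA if the trajectory
#'   is untimed), `rmsd_A`.
#' @export
rmsd_series <- function(traj, selection, ref_frame = 1) {
  stopifnot(inherits(traj, "Trajectory"))
  if (length(selection) == 0) stop("empty selection")
  nf <- n_frames(traj)
  ref <- traj$frames[selection, , ref_frame, drop = FALSE]
  dim(ref) <- dim(ref)[1:2]
  vals <- vapply(seq_len(nf), function(f) {
    fr <- traj$frames[selection, , f, drop = FALSE]
    dim(fr) <- dim(fr)[1:2]
    kabsch(fr, ref)$rmsd
  }, numeric(1))
  data.frame(frame = seq_len(nf),
             time_ns = if (is.null(traj$times)) NA_real_ else traj$times,
             rmsd_A = vals)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed on `align_selection` in two passes: first onto the
#' starting frame, then onto the mean structure computed from that pass (one
#' alignment iteration, the standard fluctuation definition). The per-atom
#' RMSF is the root-mean-square displacement from the mean position; the
#' per-residue value averages the residue's selected atoms.
#'
#' @param traj a `Trajectory` with at least 2 frames.
#' @param selection atom indices whose fluctuations are reported.
#' @param align_selection atom indices used for the rigid fit (default: the
#'   same as `selection`).
#' @param per_atom return per-atom values instead of residue averages.
#' @return data.frame with columns `resid`, `rmsf_A` (or `atom`, `resid`,
#'   `rmsf_A` when `per_atom = TRUE`).
#' @export
rmsf_profile <- function(traj, selection, align_selection = selection,
                         per_atom = FALSE) {
  stopifnot(inherits(traj, "Trajectory"))
  if (length(selection) == 0) stop("empty selection")
  nf <- n_frames(traj)
  if (nf < 2) stop("RMSF requires at least 2 frames")
  all_idx <- sort(union(selection, align_selection))
  a_pos <- match(align_selection, all_idx)
  s_pos <- match(selection, all_idx)

  get <- function(f, idx) {
    m <- traj$frames[idx, , f, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    m
  }
  align_to <- function(ref_align) {
    acc <- array(0, dim = c(length(all_idx), 3, nf))
    for (f in seq_len(nf)) {
      fit <- kabsch(get(f, align_selection), ref_align)
      acc[, , f] <- apply_superposition(fit, get(f, all_idx))
    }
    acc
  }
  pass1 <- align_to(get(1, align_selection))
  mean1 <- apply(pass1, c(1, 2), mean)
  pass2 <- align_to(mean1[a_pos, , drop = FALSE])
  mean2 <- apply(pass2, c(1, 2), mean)
  disp2 <- sweep(pass2, c(1, 2), mean2)^2
  msd <- apply(disp2, 1, sum) / nf      # mean over frames of |dr|^2
  atom_rmsf <- sqrt(msd)[s_pos]

  resid <- traj$template$atoms$resid[selection]
  if (per_atom)
    return(data.frame(atom = selection, resid = resid, rmsf_A = atom_rmsf))
  agg <- tapply(atom_rmsf, resid, mean)
  data.frame(resid = as.integer(names(agg)), rmsf_A = as.numeric(agg),
             row.names = NULL)
}
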