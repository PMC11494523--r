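# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately avoid the code paths they check: rotations are
# explored by direct numerical minimisation, contacts by a naive O(N^2)
# scan, planes by direct optimisation over the normal's spherical angles.

# Rodrigues rotation matrix from a rotation vector (axis * angle)
rot_from_vec <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  k <- r / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# direct numerical minimisation of RMSD over rotations (translation solved
# by centering), multi-start to dodge local minima on SO(3)
oracle_min_rmsd <- function(mobile, reference, n_starts = 10) {
  P <- sweep(mobile, 2, colMeans(mobile))
  X <- sweep(reference, 2, colMeans(reference))
  fn <- function(r) {
    R <- rot_from_vec(r)
    sqrt(sum((P %*% t(R) - X)^2) / nrow(P))
  }
  starts <- c(list(c(0, 0, 0)),
              lapply(seq_len(n_starts - 1), function(i)
                stats::runif(3, -pi, pi)))
  best <- Inf
  for (s in starts) {
    o <- stats::optim(s, fn, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    o <- stats::optim(o$par, fn, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
    best <- min(best, o$value)
  }
  best
}

# naive all-pairs contact scan (no vectorised distance tricks)
brute_contacts <- function(coords, lipid_atoms, protein_atoms_by_resid,
                           cutoff) {
  hits <- integer(0)
  for (rn in names(protein_atoms_by_resid)) {
    found <- FALSE
    for (i in protein_atoms_by_resid[[rn]]) {
      for (j in lipid_atoms) {
        if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= cutoff) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (found) hits <- c(hits, as.integer(rn))
  }
  sort(hits)
}

# least-squares plane normal by direct minimisation over spherical angles
oracle_plane_normal <- function(points) {
  ctr <- colMeans(points)
  cen <- sweep(points, 2, ctr)
  fn <- function(par) {
    n <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]),
           cos(par[1]))
    sum((cen %*% n)^2)
  }
  best <- NULL
  for (s in list(c(0.1, 0.1), c(pi / 2, 0), c(pi / 2, pi / 2),
                 c(2, 2), c(1, 4))) {
    o <- stats::optim(s, fn, control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  n <- c(sin(best$par[1]) * cos(best$par[2]),
         sin(best$par[1]) * sin(best$par[2]), cos(best$par[1]))
  n / sqrt(sum(n^2))
}

random_rotation <- function() rot_from_vec(stats::runif(3, -pi, pi))

# minimal Structure around a bare coordinate matrix (one CA per residue
# unless names are supplied)
make_structure <- function(coords, resid = seq_len(nrow(coords)),
                           name = "CA", resname = "ALA", chain = "A",
                           element = "C") {
  n <- nrow(coords)
  new_structure(data.frame(serial = seq_len(n),
                           name = rep(name, length.out = n),
                           resname = rep(resname, length.out = n),
                           resid = resid,
                           chain = rep(chain, length.out = n),
                           element = rep(element, length.out = n),
                           score = 0, stringsAsFactors = FALSE),
                coords)
}

# Trajectory from a list of per-frame coordinate matrices
make_traj <- function(frames, structure = make_structure(frames[[1]]),
                      times = NULL) {
  arr <- array(NA_real_, dim = c(nrow(frames[[1]]), 3, length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
  new_trajectory(structure, arr, times = times)
}

# hand-built PDB text (fixed-width) for parser contract tests
pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          b = 0, element = "C") {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), resname, chain, resid, x, y, z, 1,
          b, element)
}
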