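# ---- Structure / Trajectory containers --------------------------------------

#' Construct a Structure
#'
#' A `Structure` holds an ordered atom table plus an n x 3 coordinate matrix
#' (Angstrom). The `score` column is a writable annotation slot that maps onto
#' the PDB B-factor column when the structure is written out, so per-residue
#' metrics (e.g. contact scores) can be coloured onto the model in any viewer.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `resid`,
#'   `chain`, `element`, `score`.
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param title optional title string.
#' @return object of class `Structure`.
#' @export
new_structure <- function(atoms, coords, title = "") {
  stopifnot(is.data.frame(atoms), is.matrix(coords), ncol(coords) == 3)
  required <- c("serial", "name", "resname", "resid", "chain", "element")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"score" %in% names(atoms)) atoms$score <- 0
  if (nrow(atoms) != nrow(coords))
    stop("atom table and coordinate matrix disagree on atom count")
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  if (any(atoms$resid < 1))
    stop("resid must be >= 1 (author numbering)")
  if (any(!nzchar(atoms$name)))
    stop("atom names must be non-empty")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key))
    stop("(chain, resid, name) must be unique per atom; duplicated: ",
         key[which(duplicated(key))[1]])
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  dimnames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords, title = title),
            class = "Structure")
}

#' Construct a Trajectory
#'
#' Ordered frames of coordinates over a fixed atom set. The topology (atom
#' template) is immutable: every frame must supply exactly one coordinate per
#' template atom. Frame coordinates are stored as an `n_atoms x 3 x n_frames`
#' array.
#'
#' @param template `Structure` giving the fixed atom set (its own coordinates
#'   are frame 1 unless `frames` overrides them).
#' @param frames `n_atoms x 3 x n_frames` array of coordinates (Angstrom).
#' @param times optional per-frame times (ns), strictly increasing.
#' @param box optional `n_frames x 3` matrix of box dimensions (Angstrom).
#' @return object of class `Trajectory`.
#' @export
new_trajectory <- function(template, frames, times = NULL, box = NULL) {
  stopifnot(inherits(template, "Structure"))
  if (length(dim(frames)) != 3 || dim(frames)[2] != 3)
    stop("frames must be an n_atoms x 3 x n_frames array")
  if (dim(frames)[1] != nrow(template$atoms))
    stop("every frame must have exactly one coordinate per template atom")
  if (!all(is.finite(frames)))
    stop("frame coordinates must be finite")
  nf <- dim(frames)[3]
  if (!is.null(times)) {
    if (length(times) != nf) stop("times length must equal frame count")
    if (nf > 1 && any(diff(times) <= 0))
      stop("times must be strictly increasing")
  }
  if (!is.null(box)) {
    box <- as.matrix(box)
    if (nrow(box) != nf || ncol(box) != 3)
      stop("box must be an n_frames x 3 matrix")
  }
  structure(list(template = template, frames = frames,
                 times = times, box = box),
            class = "Trajectory")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues%s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              if (nzchar(x$title)) paste0(" (", x$title, ")") else ""))
  invisible(x)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms x %d frames%s\n",
              dim(x$frames)[1], dim(x$frames)[3],
              if (!is.null(x$times))
                sprintf(", t = %g..%g ns", min(x$times), max(x$times))
              else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "Trajectory"))
  dim(traj$frames)[3]
}

#' Coordinates of one frame
#' @param traj a `Trajectory`.
#' @param i frame index (1-based).
#' @return n_atoms x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "Trajectory"))
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  traj$frames[, , i, drop = TRUE]
}

#' Structure of a single trajectory frame
#' @param traj a `Trajectory`.
#' @param i frame index.
#' @return `Structure` with the template atom table and frame-i coordinates.
#' @export
as_structure <- function(traj, i = 1) {
  s <- traj$template
  s$coords <- frame_coords(traj, i)
  s
}

# ---- PDB input --------------------------------------------------------------

is_atom_record <- function(lines) {
  substr(lines, 1, 6) %in% c("ATOM  ", "HETATM") |
    substr(lines, 1, 5) == "ATOM "
}

# Light pre-scan of the raw lines: the contract promises line-numbered parse
# errors, insertion-code rejection, and an inter-model atom-count consistency
# check, none of which bio3d reports usefully on its own.
prescan_pdb_lines <- function(lines, path) {
  atom <- is_atom_record(lines)
  if (!any(atom))
    stop("no ATOM/HETATM records found in '", path, "'")
  bad_len <- which(atom & nchar(lines) < 54)
  if (length(bad_len) > 0)
    stop("parse error in '", path, "' at line ", bad_len[1],
         ": ATOM/HETATM record truncated before coordinate fields")
  coords_txt <- substr(lines[atom], 31, 54)
  xs <- suppressWarnings(as.numeric(substr(coords_txt, 1, 8)))
  ys <- suppressWarnings(as.numeric(substr(coords_txt, 9, 16)))
  zs <- suppressWarnings(as.numeric(substr(coords_txt, 17, 24)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad) > 0)
    stop("parse error in '", path, "' at line ", which(atom)[bad[1]],
         ": non-numeric coordinate field")
  icode <- substr(lines[atom], 27, 27)
  bad_icode <- which(!icode %in% c(" ", ""))
  if (length(bad_icode) > 0)
    stop("insertion codes are not supported (line ",
         which(atom)[bad_icode[1]], " in '", path,
         "'); renumber the residues first")
  # per-model atom counts
  model_starts <- which(substr(lines, 1, 5) == "MODEL")
  if (length(model_starts) > 1) {
    model_id <- findInterval(which(atom), model_starts)
    counts <- tabulate(model_id, nbins = length(model_starts))
    if (length(unique(counts[counts > 0])) > 1)
      stop("inter-model atom-count mismatch in '", path, "': models have ",
           paste(unique(counts[counts > 0]), collapse = ", "),
           " atoms; all models must share one atom set")
  }
  invisible(TRUE)
}

#' Read a (multi-model) PDB file as a Trajectory
#'
#' MODEL/ENDMDL records delimit frames; a file without MODEL records yields a
#' single-frame trajectory. The atom template is taken from the first model;
#' subsequent models contribute coordinates only and must contain the same
#' atom set. B-factor values of the first model populate the `score` slot.
#' Alternate locations keep the first altloc; insertion codes are rejected.
#'
#' @param path path to a PDB file.
#' @param times optional per-frame times (ns) to attach.
#' @return a `Trajectory`.
#' @export
read_pdb <- function(path, times = NULL) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  prescan_pdb_lines(lines, path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE, rm.alt = TRUE)
  at <- pdb$atom
  element <- at$elesy
  element[is.na(element)] <- ""
  atoms <- data.frame(serial = at$eleno,
                      name = at$elety,
                      resname = at$resid,
                      resid = at$resno,
                      chain = ifelse(is.na(at$chain), "", at$chain),
                      element = trimws(element),
                      score = ifelse(is.na(at$b), 0, at$b),
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(atoms)
  frames <- array(NA_real_, dim = c(na, 3, nf))
  for (f in seq_len(nf))
    frames[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  template <- new_structure(atoms, frames[, , 1, drop = TRUE],
                            title = basename(path))
  new_trajectory(template, frames, times = times)
}

#' Read a DCD trajectory against a PDB topology
#'
#' Adapter satisfying the same `Trajectory` contract as [read_pdb()]: the PDB
#' supplies the fixed atom set, the DCD the frame coordinates.
#'
#' @param pdb_path reference PDB (single model) giving the atom template.
#' @param dcd_path binary DCD trajectory.
#' @param times optional per-frame times (ns).
#' @return a `Trajectory`.
#' @export
read_dcd <- function(pdb_path, dcd_path, times = NULL) {
  ref <- read_pdb(pdb_path)
  xyz <- bio3d::read.dcd(dcd_path, verbose = FALSE)
  na <- nrow(ref$template$atoms)
  if (ncol(xyz) != 3 * na)
    stop("DCD atom count (", ncol(xyz) / 3,
         ") does not match PDB template (", na, ")")
  nf <- nrow(xyz)
  frames <- array(NA_real_, dim = c(na, 3, nf))
  for (f in seq_len(nf))
    frames[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  new_trajectory(ref$template, frames, times = times)
}

# ---- PDB output -------------------------------------------------------------

#' Write a Structure with scores in the B-factor column
#'
#' Fixed-width PDB output; each atom's `score` is written to the B-factor
#' column (2 decimals), so per-residue metrics can be visualised as colour in
#' a molecular viewer.
#'
#' @param structure a `Structure` with finite scores in `[-9.99, 999.99]`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_annotated_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "Structure"))
  sc <- structure$atoms$score
  if (!all(is.finite(sc)))
    stop("all scores must be finite before writing")
  if (any(sc < -9.99 | sc > 999.99))
    stop("score out of B-factor column range [-9.99, 999.99]: ",
         format(sc[which(sc < -9.99 | sc > 999.99)[1]]))
  at <- structure$atoms
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.vector(t(structure$coords)),
                   resno = at$resid, resid = at$resname,
                   eleno = at$serial, elety = at$name,
                   chain = at$chain, b = round(sc, 2),
                   elesy = at$element)
  invisible(path)
}

#' Write a Trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame over the fixed atom template; the
#' template's scores go to the B-factor column of every model.
#'
#' @param traj a `Trajectory`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  at <- traj$template$atoms
  nf <- n_frames(traj)
  xyz <- t(vapply(seq_len(nf),
                  function(f) as.vector(t(traj$frames[, , f])),
                  numeric(3 * nrow(at))))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   resno = at$resid, resid = at$resname,
                   eleno = at$serial, elety = at$name,
                   chain = at$chain, b = round(at$score, 2),
                   elesy = at$element)
  invisible(path)
}

# ---- Selection --------------------------------------------------------------

#' Select atoms by chain / residue / name criteria
#'
#' Each named term restricts the selection; terms combine with AND. `resid`
#' accepts a vector of residue numbers (use `a:b` for an inclusive range).
#' Unknown term names raise a selection error. An empty result is legal but
#' flagged with a warning.
#'
#' @param structure a `Structure`.
#' @param ... named terms among `chain`, `resid`, `resname`, `name`,
#'   `element`.
#' @return integer atom indices in template order.
#' @export
select_atoms <- function(structure, ...) {
  stopifnot(inherits(structure, "Structure"))
  criteria <- list(...)
  allowed <- c("chain", "resid", "resname", "name", "element")
  if (length(criteria) > 0 &&
      (is.null(names(criteria)) || any(!nzchar(names(criteria)))))
    stop("selection terms must be named")
  unknown <- setdiff(names(criteria), allowed)
  if (length(unknown) > 0)
    stop("unknown selection field(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  for (field in names(criteria))
    keep <- keep & (at[[field]] %in% criteria[[field]])
  idx <- which(keep)
  if (length(idx) == 0)
    warning("selection matched no atoms")
  idx
}

# ---- Domain segmentation ----------------------------------------------------

#' Default GfcD domain map
#'
#' Named inclusive residue ranges for the GfcD multibarrel: the cleaved signal
#' sequence, the N-terminal 12-stranded barrel (GfcD-N), the periplasmic
#' middle domain (GfcD-M), the C-terminal 13-stranded barrel (GfcD-C), and
#' the C-terminal plug folded back into the GfcD-C channel. The plug range is
#' contained in GfcD-C by design; numbering is the author numbering (mature
#' protein keeps residues 19-698).
#'
#' @return named list of `c(first, last)` residue ranges, class `DomainMap`.
#' @export
gfcd_domains <- function() {
  map <- list(signal   = c(1L, 18L),
              `GfcD-N` = c(19L, 278L),
              `GfcD-M` = c(279L, 423L),
              `GfcD-C` = c(424L, 698L),
              plug     = c(674L, 698L))
  validate_domain_map(map)
}

#' Validate a domain map
#' @param map named list of inclusive `c(first, last)` residue ranges.
#' @return the map, classed `DomainMap`.
#' @export
validate_domain_map <- function(map) {
  if (length(map) == 0 || is.null(names(map)) || any(!nzchar(names(map))))
    stop("domain map must be a named list of residue ranges")
  for (nm in names(map)) {
    r <- map[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      stop("domain '", nm, "' must be a non-empty c(first, last) range")
  }
  class(map) <- "DomainMap"
  map
}

#' Domain membership of a residue
#'
#' Returns the names of all domain ranges containing `resid`, in map order.
#' Overlapping ranges (e.g. the C-terminal plug inside GfcD-C) both report.
#' A residue outside every range returns an empty vector, not an error.
#'
#' @param resid residue number (author numbering).
#' @param map a `DomainMap`, default [gfcd_domains()].
#' @return character vector of domain names (possibly empty).
#' @export
segment_domains <- function(resid, map = gfcd_domains()) {
  if (!inherits(map, "DomainMap")) map <- validate_domain_map(map)
  stopifnot(length(resid) == 1, is.finite(resid))
  hits <- vapply(map, function(r) resid >= r[1] && resid <= r[2], logical(1))
  names(map)[hits]
}
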