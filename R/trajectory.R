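#' Structural trajectory container
#'
#' A light container for multi-conformer structures: an atom table (chain,
#' residue number/name, atom name, element) shared by all frames, plus a
#' frames x (3 * n_atoms) coordinate matrix in Angstrom (bio3d `xyz`
#' layout). Built from a multi-model PDB ([read_trajectory()]) or directly
#' from data.
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid`, `elety`
#'   and optionally `elesy` (element symbol, inferred from the atom name
#'   when absent).
#' @param xyz numeric matrix, one row per frame, columns x1,y1,z1,x2,...
#' @return an object of class `kv_trajectory`.
#' @export
trajectory <- function(atoms, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  stopifnot(ncol(xyz) == 3 * nrow(atoms))
  if (is.null(atoms$elesy) || all(is.na(atoms$elesy)))
    atoms$elesy <- .infer_element(atoms$elety)
  structure(list(atoms = atoms, xyz = xyz,
                 n_frames = nrow(xyz), n_atoms = nrow(atoms)),
            class = "kv_trajectory")
}

# PDB atom names: the element is the first alphabetic character(s); for
# standard protein atoms the first letter suffices (CA -> C, NZ -> N,
# SD -> S, OE1 -> O).
#' @noRd
.infer_element <- function(elety) {
  toupper(substr(gsub("^[0-9]+", "", elety), 1, 1))
}

#' @export
print.kv_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frame(s), %d atoms, chains %s\n",
              x$n_frames, x$n_atoms,
              paste(sort(unique(x$atoms$chain)), collapse = "")))
  invisible(x)
}

#' Coordinates of selected atoms in one frame
#'
#' @param traj a `kv_trajectory`.
#' @param frame frame index (1-based).
#' @param idx atom indices (default all).
#' @return n x 3 coordinate matrix (Angstrom).
#' @export
frame_coords <- function(traj, frame = 1, idx = seq_len(traj$n_atoms)) {
  stopifnot(frame >= 1, frame <= traj$n_frames)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  matrix(traj$xyz[frame, cols], ncol = 3, byrow = TRUE)
}

#' Read a multi-model PDB as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame. Parsing is delegated to
#' bio3d; missing element columns are inferred from atom names.
#'
#' @param path PDB file path.
#' @return a `kv_trajectory`.
#' @export
read_trajectory <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom[, c("chain", "resno", "resid", "elety", "elesy")]
  trajectory(atoms, pdb$xyz)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a `kv_trajectory`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  atomic_write(function(tmp) {
    bio3d::write.pdb(pdb = NULL, file = tmp, xyz = traj$xyz,
                     resno = traj$atoms$resno, resid = traj$atoms$resid,
                     eleno = seq_len(traj$n_atoms), elety = traj$atoms$elety,
                     chain = traj$atoms$chain, elesy = traj$atoms$elesy)
  }, path)
}

#' Apply a rigid transformation to every frame
#'
#' Rotates (3 x 3 matrix `rot`) then translates (length-3 `shift`) all
#' coordinates of all frames; used for invariance checks.
#'
#' @param traj a `kv_trajectory`.
#' @param rot 3 x 3 rotation matrix.
#' @param shift length-3 translation (Angstrom).
#' @return transformed `kv_trajectory`.
#' @export
transform_trajectory <- function(traj, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- traj$xyz
  for (f in seq_len(traj$n_frames)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    m <- m %*% t(rot)
    m <- sweep(m, 2, shift, "+")
    xyz[f, ] <- as.vector(t(m))
  }
  trajectory(traj$atoms, xyz)
}

#' Optimal-superposition backbone RMSD
#'
#' Root-mean-square deviation between two coordinate sets after
#' least-squares (Kabsch) superposition, via bio3d.
#'
#' @param coords,reference n x 3 coordinate matrices with matched atoms.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(coords, reference) {
  stopifnot(is.matrix(coords), is.matrix(reference),
            all(dim(coords) == dim(reference)), ncol(coords) == 3)
  a <- as.vector(t(coords))
  b <- as.vector(t(reference))
  as.numeric(bio3d::rmsd(a, b, fit = TRUE))
}

#' Backbone RMSD of every frame against a reference frame
#'
#' @param traj a `kv_trajectory`.
#' @param reference_frame frame index used as reference.
#' @param selection atom-name selection (default backbone heavy atoms).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
trajectory_rmsd <- function(traj, reference_frame = 1,
                            selection = c("N", "CA", "C", "O")) {
  idx <- which(traj$atoms$elety %in% selection)
  if (!length(idx)) stop("selection matches no atoms")
  ref <- frame_coords(traj, reference_frame, idx)
  vapply(seq_len(traj$n_frames), function(f) {
    backbone_rmsd(frame_coords(traj, f, idx), ref)
  }, numeric(1))
}
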