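#' Extract one frame of a trajectory
#' @param traj A `cg_trajectory`.
#' @param f Frame index (1-based).
#' @return List with `xyz` (matrix `[n_beads, 3]`) and `box` (length-3).
#' @export
get_frame <- function(traj, f) {
  list(xyz = traj$coords[, , f, drop = TRUE], box = traj$box[f, ])
}

# Kabsch: rotation + translation superposing `mob` onto `ref` (both n x 3)
.kabsch <- function(mob, ref) {
  cm <- colMeans(mob); cr <- colMeans(ref)
  H <- crossprod(sweep(mob, 2, cm), sweep(ref, 2, cr))
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, center_mob = cm, center_ref = cr)
}

#' Remove overall protein translation and rotation from a trajectory
#'
#' Each frame is rigid-body superposed (least-squares rotation plus
#' translation computed on the protein beads) onto the first frame, and the
#' transform is applied to every bead of that frame. Contact geometry must
#' be evaluated on the raw frames; alignment is for density analysis.
#'
#' @param traj A `cg_trajectory`.
#' @param topology The matching [bead_topology()].
#' @return The aligned trajectory.
#' @export
align_frames <- function(traj, topology) {
  prot <- which(topology$role == "protein")
  if (length(prot) < 3)
    stop_config("alignment needs >= 3 protein beads (got %d)", length(prot))
  ref <- traj$coords[prot, , 1, drop = TRUE]
  cen <- sweep(ref, 2, colMeans(ref))
  if (qr(cen)$rank < 2)
    stop_config("alignment needs >= 3 non-collinear protein beads")
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    k <- .kabsch(traj$coords[prot, , f, drop = TRUE], ref)
    xyz <- sweep(traj$coords[, , f, drop = TRUE], 2, k$center_mob)
    out[, , f] <- sweep(xyz %*% k$R, 2, k$center_ref, `+`)
  }
  new_trajectory(out, traj$box)
}

#' Protein RMSD of every frame to the first frame
#' @param traj A `cg_trajectory`.
#' @param topology The matching [bead_topology()].
#' @return Numeric vector (nm), one value per frame.
#' @export
protein_rmsd <- function(traj, topology) {
  prot <- which(topology$role == "protein")
  ref <- traj$coords[prot, , 1, drop = TRUE]
  vapply(seq_len(n_frames(traj)), function(f) {
    d <- traj$coords[prot, , f, drop = TRUE] - ref
    sqrt(mean(rowSums(d^2)))
  }, 0)
}

#' Mean in-plane position of every protein residue
#'
#' Average x/y over all beads of the residue and all frames; used to link
#' contact residues to density-map sites.
#'
#' @param traj An (aligned) `cg_trajectory`.
#' @param topology The matching [bead_topology()].
#' @return Data frame with `residue_id`, `x`, `y`, `z`.
#' @export
residue_positions <- function(traj, topology) {
  prot <- which(topology$role == "protein")
  rid <- topology$residue_id[prot]
  mx <- rowMeans(traj$coords[prot, 1, , drop = FALSE], dims = 1)
  my <- rowMeans(traj$coords[prot, 2, , drop = FALSE], dims = 1)
  mz <- rowMeans(traj$coords[prot, 3, , drop = FALSE], dims = 1)
  agg <- function(v) tapply(v, rid, mean)
  data.frame(residue_id = as.integer(names(agg(mx))),
             x = unname(agg(mx)), y = unname(agg(my)), z = unname(agg(mz)))
}
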