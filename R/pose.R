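# Pose: one atomic model (protein + glycans).
#
# Atoms live in a metadata data.frame plus a separate n x 3 coordinate
# matrix, so that Monte Carlo moves can rotate coordinate subsets without
# touching the bookkeeping.  Glycan atoms carry the index of their tree in
# pose$trees and their node id within that tree.

#' Construct a pose
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resname}, \code{atom}, \code{element}, \code{role}
#'   ("protein", "glycan" or "water"), \code{tree} (integer index into
#'   \code{trees} or NA), \code{node} (node id or NA).
#' @param xyz numeric matrix, one row per atom, Angstrom.
#' @param trees list of \code{glycan_tree} objects registered on the pose.
#' @param bonds optional two-column integer matrix of covalently bonded atom
#'   row pairs; when absent, bonds are inferred by distance on demand.
#' @return object of class \code{pose}.
#' @export
new_pose <- function(atoms, xyz, trees = list(), bonds = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) == nrow(xyz), ncol(xyz) == 3)
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate atom identifier: ", key[duplicated(key)][1])
  structure(list(atoms = atoms, xyz = unname(as.matrix(xyz)), trees = trees,
                 bonds = bonds),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("pose: %d atoms, %d protein residue(s), %d glycan tree(s)\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno)[x$atoms$role == "protein"])),
              length(x$trees)))
  invisible(x)
}

pose_n_atoms <- function(pose) nrow(pose$atoms)

# row index of one named atom; errors if absent unless must = FALSE
atom_row <- function(pose, chain, resno, atom, must = TRUE) {
  i <- which(pose$atoms$chain == chain & pose$atoms$resno == resno &
             pose$atoms$atom == atom)
  if (length(i) != 1) {
    if (must) stop(sprintf("atom %s/%s/%s not found in pose", chain, resno, atom))
    return(NA_integer_)
  }
  i
}

# all atom rows of a glycan node
node_rows <- function(pose, tree_index, node_id) {
  which(!is.na(pose$atoms$tree) & pose$atoms$tree == tree_index &
        pose$atoms$node == node_id)
}

node_atom_row <- function(pose, tree_index, node_id, name, must = TRUE) {
  i <- which(!is.na(pose$atoms$tree) & pose$atoms$tree == tree_index &
             pose$atoms$node == node_id & pose$atoms$atom == name)
  if (length(i) != 1) {
    if (must) stop(sprintf("glycan atom %s of node %d (tree %d) not found",
                           name, node_id, tree_index))
    return(NA_integer_)
  }
  i
}

heavy_rows <- function(pose, rows = seq_len(nrow(pose$atoms))) {
  rows[pose$atoms$element[rows] != "H"]
}

#' Covalent bonds of a pose
#'
#' Poses built by this package carry their chemical bond list explicitly
#' (template bonds plus glycosidic/attachment bonds), which keeps the steric
#' exclusions correct even when non-bonded atoms approach bonding distance.
#' For poses without a stored list (e.g. read from an external PDB), an
#' element-aware distance criterion is used (heavy-heavy < 1.75 A,
#' X-H < 1.2 A).
#'
#' @param pose a pose.
#' @return two-column integer matrix of bonded atom row pairs.
#' @export
pose_bonds <- function(pose) {
  if (!is.null(pose$bonds)) return(pose$bonds)
  xyz <- pose$xyz
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(), ncol = 2))
  is_h <- pose$atoms$element == "H"
  cpp_detect_bonds(xyz, is_h, 1.75, 1.20)
}

# append bonds (two-column row-index matrix) to a pose's stored bond list
add_pose_bonds <- function(pose, pairs) {
  if (!length(pairs)) return(pose)
  pose$bonds <- rbind(pose$bonds, matrix(as.integer(pairs), ncol = 2))
  pose
}

# map of excluded (bonded within 3 bonds) pairs, encoded i * n + j for use by
# the C++ steric kernel; includes both orders.
bonded_exclusions <- function(pose, max_sep = 3L) {
  bonds <- pose_bonds(pose)
  n <- pose_n_atoms(pose)
  cpp_bond_exclusions(bonds, n, max_sep)
}
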