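# Decoy analytics: rigid superposition, heavy-atom RMSDs, the pNear funnel
# metric and enrichment fractions.

#' Kabsch superposition
#'
#' Optimal proper rotation and translation minimizing the RMSD of P onto Q,
#' via SVD of the covariance with a determinant sign correction.
#'
#' @param P,Q point sets (n x 3 matrices, n >= 3), matched row-wise.
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length 3; maps P as \code{P \%*\% t(R) + t}) and \code{rmsd}.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("point sets differ in size")
  if (nrow(P) < 3) stop("need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(rotation = R, translation = cq - as.numeric(R %*% cp), rmsd = rmsd)
}

# matched heavy-atom coordinate pair for a node selection, by
# (node id, atom name) correspondence
.matched_coords <- function(model, native, tree = 1L, nodes) {
  pick <- function(pose) {
    rows <- nodes_atom_rows(pose, tree, nodes, heavy = TRUE)
    key <- paste(pose$atoms$node[rows], pose$atoms$atom[rows])
    list(rows = rows, key = key)
  }
  m <- pick(model); nv <- pick(native)
  miss <- setdiff(m$key, nv$key)
  if (length(miss))
    stop("no counterpart in native for atom(s): ", paste(miss, collapse = ", "))
  miss2 <- setdiff(nv$key, m$key)
  if (length(miss2))
    stop("no counterpart in model for atom(s): ", paste(miss2, collapse = ", "))
  ord <- match(m$key, nv$key)
  list(P = model$xyz[m$rows, , drop = FALSE],
       Q = native$xyz[nv$rows[ord], , drop = FALSE])
}

#' Fixed-frame heavy-atom RMSD
#'
#' RMSD over glycan heavy atoms without any fitting; both poses must share
#' the protein frame (the benchmark leaves the scaffold untouched).
#'
#' @param model,native poses with the same tree registered.
#' @param tree tree index.
#' @param nodes node ids included (default: all).
#' @return RMSD in Angstrom.
#' @export
rmsd_fixed_frame <- function(model, native, tree = 1L, nodes = NULL) {
  if (is.null(nodes)) nodes <- model$trees[[tree]]$nodes$node_id
  mc <- .matched_coords(model, native, tree, nodes)
  sqrt(mean(rowSums((mc$P - mc$Q)^2)))
}

#' Superimposed heavy-atom RMSD
#'
#' Kabsch-fits the selected glycan heavy atoms onto the native before the
#' RMSD, so the value reflects internal glycan structure and is invariant to
#' rigid motion of either input.
#'
#' @inheritParams rmsd_fixed_frame
#' @return RMSD in Angstrom.
#' @export
rmsd_superimposed <- function(model, native, tree = 1L, nodes = NULL) {
  if (is.null(nodes)) nodes <- model$trees[[tree]]$nodes$node_id
  mc <- .matched_coords(model, native, tree, nodes)
  kabsch(mc$P, mc$Q)$rmsd
}

# RMSD over the first two residues along the chain from the root
root_rmsd <- function(model, native, tree = 1L) {
  tr <- model$trees[[tree]]
  root <- tree_root_id(tr)
  kids <- tree_children(tr, root)$node_id
  nodes <- c(root, if (length(kids)) kids[1])
  rmsd_fixed_frame(model, native, tree, nodes)
}

#' pNear funnel-quality metric
#'
#' Boltzmann-weighted probability of finding the system within about
#' \code{lambda} of the native state:
#' \deqn{P_{near} = \frac{\sum_i e^{-r_i^2/\lambda^2} e^{-(E_i - E_{min})/kT}}
#'                       {\sum_i e^{-(E_i - E_{min})/kT}}}
#' Energies are shifted by their minimum before exponentiation, which leaves
#' the value unchanged and keeps it numerically stable.  A value near 1
#' indicates an ideal funnel.
#'
#' @param rmsd per-decoy RMSD to native (Angstrom).
#' @param energy per-decoy total energy.
#' @param lambda near-native cutoff (Angstrom).
#' @param kT Boltzmann temperature (energy units).
#' @return value in \code{[0, 1]}.
#' @export
pnear <- function(rmsd, energy, lambda = 1.0, kT = 0.62) {
  stopifnot(length(rmsd) == length(energy), lambda > 0, kT > 0)
  if (!length(rmsd)) stop("pnear needs at least one decoy")
  w <- exp(-(energy - min(energy)) / kT)
  sum(exp(-rmsd^2 / lambda^2) * w) / sum(w)
}

#' Decoy enrichment fractions
#'
#' Fraction of decoys with RMSD below each cutoff.
#'
#' @param rmsd per-decoy RMSD (Angstrom).
#' @param cutoffs RMSD cutoffs (Angstrom).
#' @return named numeric vector, one fraction per cutoff.
#' @export
enrichment <- function(rmsd, cutoffs = c(1.0, 2.5, 5.0)) {
  if (!length(cutoffs)) return(setNames(numeric(), character()))
  out <- vapply(cutoffs, function(ct) mean(rmsd < ct), numeric(1))
  names(out) <- paste0("<", format(cutoffs, trim = TRUE), "A")
  out
}
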