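# Weighted-sum score model.
#
# This potential is a deliberately simple torsion-space score: the KDE
# torsional statistical term (sugar_bb analog) plus soft sterics, geometric
# hydrogen bonds and an optional real-space density correlation.  It is not
# an all-atom force field; its job is to discriminate conformer basins and
# clashes during Monte Carlo tree building.
#
# make_energy_context() precomputes everything that depends only on the
# pose topology (atom rows per glycan node, linkage frame indices, bonded
# exclusions, donor/acceptor typing) so that the per-cycle energy
# evaluations touch no data.frame.

.ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 0.0)
.STERIC_CAP <- 10
.STERIC_EPS <- 1.0
.STERIC_SWITCH <- 5.0
.STERIC_CUTOFF <- 6.0

#' Energy weights
#'
#' @param w_sugar_bb weight of the KDE torsional term (default 1.0).
#' @param w_rep,w_atr repulsive/attractive steric weights.
#' @param w_hbond hydrogen-bond weight.
#' @param w_density density-correlation weight (applied when a map is given).
#' @param kT_mc Metropolis temperature of the sampler (energy units).
#' @param kT_pnear temperature used by the pNear funnel metric.
#' @return object of class \code{energy_weights}.
#' @export
energy_weights <- function(w_sugar_bb = 1.0, w_rep = 0.55, w_atr = 0.2,
                           w_hbond = 1.0, w_density = 20, kT_mc = 1.0,
                           kT_pnear = 0.62) {
  w <- list(w_sugar_bb = w_sugar_bb, w_rep = w_rep, w_atr = w_atr,
            w_hbond = w_hbond, w_density = w_density,
            kT_mc = kT_mc, kT_pnear = kT_pnear)
  if (any(unlist(w[1:5]) < 0)) stop("energy weights must be >= 0")
  if (kT_mc <= 0 || kT_pnear <= 0) stop("kT values must be > 0")
  structure(w, class = "energy_weights")
}

# per-node kinematic cache for one tree: atom rows, linkage frame rows,
# subtree (distal) rows for torsion moves
.kin_cache <- function(pose, ti) {
  tr <- pose$trees[[ti]]
  out <- list()
  for (id in tr$nodes$node_id) {
    fr <- linkage_frame_rows(pose, tr, ti, id)
    rows <- node_rows(pose, ti, id)
    sub <- .torsion_moving_rows(pose, tr, ti, id)
    k <- list(
      id = id,
      rows = rows,
      rows_heavy = heavy_rows(pose, rows),
      sub_rows = sub,
      o5 = node_atom_row(pose, ti, id, "O5"),
      c1 = node_atom_row(pose, ti, id, "C1"),
      ox = fr$ox, cx = fr$cx, cprev = fr$cprev,
      x = fr$x, root = fr$root,
      key = linkage_key(tr, id),
      chis = rotatable_chis(pose, ti, id))
    if (!fr$root && fr$x == 6) {
      pid <- tr$nodes$parent_id[tr$nodes$node_id == id]
      k$om <- c(node_atom_row(pose, ti, pid, "O6"),
                node_atom_row(pose, ti, pid, "C6"),
                node_atom_row(pose, ti, pid, "C5"),
                node_atom_row(pose, ti, pid, "O5"))
    }
    out[[as.character(id)]] <- k
  }
  out
}

#' Precomputed energy context for a pose
#'
#' Caches everything that depends only on topology: bonded exclusions,
#' element radii, donor/acceptor typing and per-node kinematic indices.
#' Build it once per pose topology and pass it to the energy functions
#' during sampling; it becomes stale if atoms are added or removed.
#'
#' @param pose a pose.
#' @return list used by the energy functions.
#' @export
make_energy_context <- function(pose) {
  el <- pose$atoms$element
  n <- nrow(pose$atoms)
  radii <- unname(.ELEMENT_RADII[el])
  radii[is.na(radii)] <- 1.7
  excl <- bonded_exclusions(pose, 3L)
  i0 <- excl[, 1] - 1; j0 <- excl[, 2] - 1
  excl_keys <- sort(c(i0 * n + j0, j0 * n + i0))
  hn <- grepl("^H[ON]", pose$atoms$atom) & el == "H"
  don_h <- which(hn)
  don_d <- vapply(don_h, function(h) {
    cand <- which(el %in% c("O", "N"))
    d2 <- rowSums((pose$xyz[cand, , drop = FALSE] -
                   matrix(pose$xyz[h, ], length(cand), 3, byrow = TRUE))^2)
    cand[which.min(d2)]
  }, integer(1))
  acc <- which(el == "O" & pose$atoms$role != "water")
  kin <- lapply(seq_along(pose$trees), function(ti) .kin_cache(pose, ti))
  list(radii = radii, excl_keys = excl_keys, don_h = don_h, don_d = don_d,
       acc = acc, is_h = el == "H", n = n,
       protein_heavy = which(pose$atoms$role == "protein" & el != "H"),
       kin = kin)
}

# atom rows of a node set; uses the kin cache when given
nodes_atom_rows <- function(pose, tree, nodes, heavy = FALSE, ctx = NULL) {
  if (!is.null(ctx) && length(ctx$kin) >= tree) {
    kc <- ctx$kin[[tree]]
    return(unlist(lapply(as.character(nodes), function(id)
      if (heavy) kc[[id]]$rows_heavy else kc[[id]]$rows), use.names = FALSE))
  }
  rows <- which(!is.na(pose$atoms$tree) & pose$atoms$tree == tree &
                pose$atoms$node %in% nodes)
  if (heavy) rows <- heavy_rows(pose, rows)
  rows
}

# fast cached torsion measurement
.tors_cached <- function(xyz, k) {
  out <- list(phi = dihedral_deg(xyz[k$o5, ], xyz[k$c1, ], xyz[k$ox, ], xyz[k$cx, ]),
              psi = dihedral_deg(xyz[k$c1, ], xyz[k$ox, ], xyz[k$cx, ], xyz[k$cprev, ]))
  if (!is.null(k$om))
    out$omega <- dihedral_deg(xyz[k$om[1], ], xyz[k$om[2], ],
                              xyz[k$om[3], ], xyz[k$om[4], ])
  out
}

#' KDE torsional statistical energy (sugar_bb analog)
#'
#' Sum over the included nodes and their defined torsions of the per-torsion
#' KDE energy; zero when every torsion sits at its global mode.
#'
#' @param pose a pose.
#' @param tree tree index in \code{pose$trees}.
#' @param library a \code{conformer_library} covering the tree's linkages.
#' @param nodes node ids to score (masked nodes are simply not listed).
#' @param use_grid score from the cached 1-degree energy grid with linear
#'   interpolation (the sampler's path) instead of the exact kernel sum.
#' @param ctx optional context from [make_energy_context()].
#' @return non-negative energy.
#' @export
sugar_bb_energy <- function(pose, tree = 1L, library, nodes, use_grid = TRUE,
                            ctx = NULL) {
  e <- 0
  if (!is.null(ctx) && length(ctx$kin) >= tree) {
    kc <- ctx$kin[[tree]]
    xyz <- pose$xyz
    for (id in as.character(nodes)) {
      k <- kc[[id]]
      lk <- library$linkages[[k$key]]
      if (is.null(lk)) stop("conformer library has no linkage type '", k$key, "'")
      tors <- .tors_cached(xyz, k)
      for (t in names(lk$kdes)) {
        if (!is.null(tors[[t]]))
          e <- e + kde_energy(lk$kdes[[t]], tors[[t]], use_grid = use_grid)
      }
    }
    return(e)
  }
  tr <- pose$trees[[tree]]
  for (id in nodes) {
    key <- linkage_key(tr, id)
    lk <- library_linkage(library, key)
    tors <- measure_torsions(pose, tree, id)
    for (t in names(lk$kdes)) {
      if (!is.null(tors[[t]]))
        e <- e + kde_energy(lk$kdes[[t]], tors[[t]], use_grid = use_grid)
    }
  }
  e
}

#' Soft steric energy
#'
#' Capped Lennard-Jones-like pair potential over heavy atoms: one atom in the
#' scored node set, the partner any unmasked glycan or protein atom within
#' 6 Angstrom, excluding pairs bonded within three bonds.  Repulsion is
#' \eqn{(r_0/r)^{12} - 1} below the contact distance \eqn{r_0} (sum of
#' element radii), capped at 10 per pair; the attractive well is
#' \eqn{-\epsilon (r_0/r)^6} with a cosine taper from 5 to 6 Angstrom.
#'
#' @inheritParams sugar_bb_energy
#' @param ctx context from [make_energy_context()].
#' @param active_nodes node ids whose atoms may act as partners (defaults to
#'   \code{nodes}); masked residues appear in neither role.
#' @return list with unweighted components \code{rep} and \code{atr}.
#' @export
steric_energy <- function(pose, tree = 1L, nodes, ctx = NULL,
                          active_nodes = nodes) {
  if (is.null(ctx)) ctx <- make_energy_context(pose)
  sel <- nodes_atom_rows(pose, tree, nodes, heavy = TRUE, ctx = ctx)
  if (!length(sel)) return(list(rep = 0, atr = 0))
  partner <- c(ctx$protein_heavy,
               nodes_atom_rows(pose, tree, active_nodes, heavy = TRUE, ctx = ctx))
  res <- cpp_steric_energy(pose$xyz, sel, partner, ctx$radii, ctx$is_h,
                           ctx$excl_keys, .STERIC_EPS, .STERIC_CAP,
                           .STERIC_SWITCH, .STERIC_CUTOFF)
  list(rep = res$rep, atr = res$atr)
}

#' Geometric hydrogen-bond energy
#'
#' Donor-acceptor pairs score \eqn{-1 \cdot w_d(r) \cdot w_a(\theta)} with a
#' cosine-smoothed distance window on 2.6-3.4 Angstrom (peak 2.9) and an
#' angle window opening at 120 degrees (peak at 180), so the total is
#' non-positive and an ideal geometry contributes exactly -1.
#'
#' @inheritParams steric_energy
#' @return energy (<= 0).
#' @export
hbond_energy <- function(pose, tree = 1L, nodes, ctx = NULL,
                         active_nodes = nodes) {
  if (is.null(ctx)) ctx <- make_energy_context(pose)
  if (!length(ctx$don_h)) return(0)
  n <- nrow(pose$atoms)
  in_sel <- rep(FALSE, n)
  in_sel[nodes_atom_rows(pose, tree, nodes, ctx = ctx)] <- TRUE
  allowed <- rep(FALSE, n)
  allowed[pose$atoms$role == "protein"] <- TRUE
  allowed[nodes_atom_rows(pose, tree, active_nodes, ctx = ctx)] <- TRUE
  cpp_hbond_energy(pose$xyz, ctx$don_h, ctx$don_d, ctx$acc, in_sel, allowed)
}

#' Density-correlation energy
#'
#' Negative real-space correlation of the node heavy atoms against the map,
#' so lower is better; bounded in \code{[-1, 1]}.
#'
#' @inheritParams sugar_bb_energy
#' @param map a \code{density_map}.
#' @return energy in \code{[-1, 1]}.
#' @export
density_energy <- function(pose, map, tree = 1L, nodes, ctx = NULL) {
  rows <- nodes_atom_rows(pose, tree, nodes, heavy = TRUE, ctx = ctx)
  if (!length(rows)) return(0)
  -real_space_correlation(pose, map, rows)
}

#' Total weighted energy with per-term breakdown
#'
#' @inheritParams steric_energy
#' @param weights an \code{energy_weights} object.
#' @param library a \code{conformer_library}.
#' @param map optional \code{density_map}; when given, the density term is
#'   included with weight \code{w_density}.
#' @return object of class \code{energy_breakdown}: per-term unweighted
#'   values plus the weighted \code{total}.
#' @export
total_energy <- function(pose, tree = 1L, weights, library, nodes,
                         map = NULL, ctx = NULL, active_nodes = nodes) {
  if (is.null(ctx)) ctx <- make_energy_context(pose)
  sbb <- if (weights$w_sugar_bb > 0)
    sugar_bb_energy(pose, tree, library, nodes, ctx = ctx) else 0
  st <- if (weights$w_rep > 0 || weights$w_atr > 0)
    steric_energy(pose, tree, nodes, ctx, active_nodes) else list(rep = 0, atr = 0)
  hb <- if (weights$w_hbond > 0)
    hbond_energy(pose, tree, nodes, ctx, active_nodes) else 0
  den <- if (!is.null(map) && weights$w_density > 0)
    density_energy(pose, map, tree, nodes, ctx) else 0
  total <- weights$w_sugar_bb * sbb + weights$w_rep * st$rep +
    weights$w_atr * st$atr + weights$w_hbond * hb + weights$w_density * den
  structure(list(sugar_bb = sbb, rep = st$rep, atr = st$atr, hbond = hb,
                 density = den, total = total, weights = weights),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy: total %.3f (sugar_bb %.3f, rep %.3f, atr %.3f, hbond %.3f, density %.3f)\n",
              x$total, x$sugar_bb, x$rep, x$atr, x$hbond, x$density))
  invisible(x)
}
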