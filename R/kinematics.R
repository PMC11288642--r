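# Forward kinematics for glycan trees: placing rigid sugar residues from
# glycosidic torsions, measuring and setting torsions, and randomization.
#
# Torsion conventions (heavy-atom, degrees, wrapped to [-180, 180)):
#   phi   = O5(child)-C1(child)-Ox(parent)-Cx(parent)
#   psi   = C1(child)-Ox(parent)-Cx(parent)-C(x-1)(parent)
#   omega = O6-C6-C5-O5 of the parent, present only for 1->6 linkages
# and for the protein root (Asn ND2):
#   phi   = O5-C1-ND2-CG,  psi = C1-ND2-CG-CB.
#
# The glycosidic bridge uses idealized geometry: C1-Ox 1.40 A, C-O-C 117 deg
# (C1-ND2 1.45 A, C1-ND2-CG 124 deg at the root); the O5-C1-Ox angle follows
# the template's anomeric direction.

.GLYCO_BOND <- 1.40
.GLYCO_ANGLE <- 117
.ROOT_BOND <- 1.45
.ROOT_ANGLE <- 124

# frame atom rows for the linkage of `node`: list(ox, cx, cprev, x)
linkage_frame_rows <- function(pose, tree, ti, node_id) {
  row <- tree$nodes[tree$nodes$node_id == node_id, ]
  if (nrow(row) != 1) stop("node ", node_id, " not in tree")
  if (is.na(row$parent_id)) {
    att <- tree$attachment
    if (is.null(att)) stop("tree has no protein attachment")
    if (att$atom != "ND2")
      stop("only Asn ND2 attachments are supported, got ", att$atom)
    list(ox = atom_row(pose, att$chain, att$resno, "ND2"),
         cx = atom_row(pose, att$chain, att$resno, "CG"),
         cprev = atom_row(pose, att$chain, att$resno, "CB"),
         x = NA_integer_, root = TRUE,
         bond = .ROOT_BOND, angle = .ROOT_ANGLE)
  } else {
    x <- row$parent_pos
    pid <- row$parent_id
    cprev_name <- if (x == 2) "C1" else paste0("C", x - 1)
    list(ox = node_atom_row(pose, ti, pid, paste0("O", x)),
         cx = node_atom_row(pose, ti, pid, paste0("C", x)),
         cprev = node_atom_row(pose, ti, pid, cprev_name),
         x = x, root = FALSE,
         bond = .GLYCO_BOND, angle = .GLYCO_ANGLE)
  }
}

# rotation matrix taking unit vector a onto unit vector b
.align_rotation <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    # pick any perpendicular axis
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unitv(c(a[2] * ref[3] - a[3] * ref[2],
                    a[3] * ref[1] - a[1] * ref[3],
                    a[1] * ref[2] - a[2] * ref[1]))
    return(rotation_about_axis(axis, 180))
  }
  axis <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
  rotation_about_axis(axis, acos(max(-1, min(1, d))) * .rad2deg)
}

# rotate `rows` of the pose about the bond from axis_from to axis_to so that
# the dihedral measured by `measure_fn` reaches `target`; exact by re-measure
.rotate_to_torsion <- function(pose, rows, axis_from, axis_to, measure_fn, target) {
  cur <- measure_fn(pose)
  delta <- wrap_angle(target - cur)
  if (abs(delta) < 1e-12) return(pose)
  origin <- pose$xyz[axis_from, ]
  axis <- pose$xyz[axis_to, ] - origin
  trial <- pose
  trial$xyz[rows, ] <- rotate_points(pose$xyz[rows, , drop = FALSE], origin, axis, delta)
  got <- measure_fn(trial)
  if (abs(wrap_angle(got - target)) > 1e-8) {
    trial$xyz[rows, ] <- rotate_points(pose$xyz[rows, , drop = FALSE], origin, axis, -delta)
    got2 <- measure_fn(trial)
    if (abs(wrap_angle(got2 - target)) > 1e-8)
      stop("internal error: torsion rotation failed to reach target")
  }
  trial
}

.drop_pose_rows <- function(pose, rows) {
  if (!length(rows)) return(pose)
  n <- nrow(pose$atoms)
  keep <- setdiff(seq_len(n), rows)
  pose$atoms <- pose$atoms[keep, , drop = FALSE]
  rownames(pose$atoms) <- NULL
  pose$xyz <- pose$xyz[keep, , drop = FALSE]
  if (!is.null(pose$bonds)) {
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    b <- pose$bonds
    ok <- !(b[, 1] %in% rows) & !(b[, 2] %in% rows)
    pose$bonds <- cbind(remap[b[ok, 1]], remap[b[ok, 2]])
  }
  pose
}

#' Build a glycan tree onto a scaffold in one shot
#'
#' Places every residue of \code{tree} with the supplied glycosidic torsions,
#' starting at the protein attachment (Asn ND2) and proceeding parents before
#' children.  Ring-internal geometry comes from the rigid templates; the
#' glycosidic bridge uses idealized bond geometry.
#'
#' @param scaffold a pose containing the attachment residue.
#' @param tree a \code{glycan_tree} with a non-NULL attachment.
#' @param torsions named list: for each node id (as character) a list with
#'   \code{phi}, \code{psi} and, for 1->6 linkages, \code{omega} (degrees).
#' @return a new pose with the glycan appended and the tree registered.
#' @export
build_glycan <- function(scaffold, tree, torsions) {
  viol <- validate_tree(tree)
  if (length(viol)) stop("invalid tree: ", paste(viol, collapse = "; "))
  missing_t <- setdiff(as.character(tree$nodes$node_id), names(torsions))
  if (length(missing_t))
    stop("torsion map incomplete: missing node(s) ",
         paste(missing_t, collapse = ", "))

  pose <- scaffold
  ti <- length(pose$trees) + 1L
  pose$trees[[ti]] <- tree

  att <- tree$attachment
  chain <- att$chain
  start_resno <- max(pose$atoms$resno[pose$atoms$chain == chain], 0L)

  for (i in seq_len(nrow(tree$nodes))) {
    nd <- tree$nodes[i, ]
    tors <- torsions[[as.character(nd$node_id)]]
    if (is.null(tors$phi) || is.null(tors$psi))
      stop("torsion map incomplete: node ", nd$node_id, " lacks phi/psi")
    fr <- linkage_frame_rows(pose, tree, ti, nd$node_id)
    if (!fr$root && fr$x == 6) {
      if (is.null(tors$omega))
        stop("torsion map incomplete: node ", nd$node_id,
             " (1->6 linkage) lacks omega")
      # position the parent O6 by omega before hanging the child on it
      pid <- nd$parent_id
      o5p <- pose$xyz[node_atom_row(pose, ti, pid, "O5"), ]
      c5p <- pose$xyz[node_atom_row(pose, ti, pid, "C5"), ]
      c6p <- pose$xyz[node_atom_row(pose, ti, pid, "C6"), ]
      pose$xyz[fr$ox, ] <- place_atom(o5p, c5p, c6p, .BOND_CO, 109.5, tors$omega)
      h6 <- node_atom_row(pose, ti, nd$parent_id, "HO6", must = FALSE)
      if (!is.na(h6)) pose <- .drop_pose_rows(pose, h6)
      fr <- linkage_frame_rows(pose, tree, ti, nd$node_id)
    } else if (!fr$root && fr$x %in% 2:4) {
      hx <- node_atom_row(pose, ti, nd$parent_id, paste0("HO", fr$x), must = FALSE)
      if (!is.na(hx)) {
        pose <- .drop_pose_rows(pose, hx)
        fr <- linkage_frame_rows(pose, tree, ti, nd$node_id)
      }
    }

    tpl <- template_for(nd$kind)
    ox <- pose$xyz[fr$ox, ]; cx <- pose$xyz[fr$cx, ]; cprev <- pose$xyz[fr$cprev, ]
    c1w <- place_atom(cprev, cx, ox, fr$bond, fr$angle, tors$psi)
    u <- unitv(ox - c1w)
    c1t <- template_atom_xyz(tpl, "C1")
    R0 <- .align_rotation(tpl$link_dir, u)
    coords <- sweep(tpl$xyz, 2, c1t) %*% t(R0)
    coords <- sweep(coords, 2, c1w, FUN = "+")

    resno <- start_resno + i
    new_atoms <- data.frame(
      chain = chain, resno = resno,
      resname = pdb_code_for_kind(nd$kind),
      atom = tpl$atoms$name, element = tpl$atoms$element,
      role = "glycan", tree = ti, node = nd$node_id,
      stringsAsFactors = FALSE)
    offset <- nrow(pose$atoms)
    pose$atoms <- rbind(pose$atoms, new_atoms)
    pose$xyz <- rbind(pose$xyz, coords)
    if (!is.null(pose$bonds)) {
      local_rows <- offset + cbind(match(tpl$bonds[, 1], tpl$atoms$name),
                                   match(tpl$bonds[, 2], tpl$atoms$name))
      c1_row_new <- offset + match("C1", tpl$atoms$name)
      pose <- add_pose_bonds(pose, rbind(local_rows, c(c1_row_new, fr$ox)))
    }

    rows <- node_rows(pose, ti, nd$node_id)
    mfn <- function(p) {
      o5 <- p$xyz[node_atom_row(p, ti, nd$node_id, "O5"), ]
      dihedral_deg(o5, p$xyz[node_atom_row(p, ti, nd$node_id, "C1"), ],
                   p$xyz[fr$ox, ], p$xyz[fr$cx, ])
    }
    pose <- .rotate_to_torsion(pose, rows, node_atom_row(pose, ti, nd$node_id, "C1"),
                               fr$ox, mfn, tors$phi)
  }
  pose
}

#' Measure the glycosidic torsions of one node
#'
#' @param pose a pose with the glycan placed.
#' @param tree index of the tree in \code{pose$trees}.
#' @param node node id.
#' @return list with \code{phi}, \code{psi} and, for 1->6 linkages,
#'   \code{omega} (degrees in \code{[-180, 180)}).
#' @export
measure_torsions <- function(pose, tree = 1L, node) {
  tr <- pose$trees[[tree]]
  fr <- linkage_frame_rows(pose, tr, tree, node)
  o5 <- pose$xyz[node_atom_row(pose, tree, node, "O5"), ]
  c1 <- pose$xyz[node_atom_row(pose, tree, node, "C1"), ]
  ox <- pose$xyz[fr$ox, ]; cx <- pose$xyz[fr$cx, ]; cprev <- pose$xyz[fr$cprev, ]
  out <- list(phi = dihedral_deg(o5, c1, ox, cx),
              psi = dihedral_deg(c1, ox, cx, cprev))
  if (!fr$root && fr$x == 6) {
    pid <- tr$nodes$parent_id[tr$nodes$node_id == node]
    out$omega <- dihedral_deg(
      pose$xyz[node_atom_row(pose, tree, pid, "O6"), ],
      pose$xyz[node_atom_row(pose, tree, pid, "C6"), ],
      pose$xyz[node_atom_row(pose, tree, pid, "C5"), ],
      pose$xyz[node_atom_row(pose, tree, pid, "O5"), ])
  }
  out
}

# rows moved by each torsion of `node`: phi/psi move the child subtree,
# omega additionally moves the parent O6 (the linkage oxygen itself)
.torsion_moving_rows <- function(pose, tr, ti, node) {
  sub <- subtree_ids(tr, node)
  rows <- unlist(lapply(sub, function(id) node_rows(pose, ti, id)))
  rows
}

#' Set the glycosidic torsions of one node
#'
#' Rotates the distal subtree about the relevant bonds so that the measured
#' torsions equal the request; atoms on the root side of each bond are left
#' bitwise unchanged and no bond length or angle changes.
#'
#' @inheritParams measure_torsions
#' @param torsions list with any of \code{phi}, \code{psi}, \code{omega}
#'   (degrees); omitted angles are left alone.
#' @return the modified pose.
#' @export
set_torsions <- function(pose, tree = 1L, node, torsions) {
  tr <- pose$trees[[tree]]
  if (!(node %in% tr$nodes$node_id)) stop("node ", node, " not in tree")
  fr <- linkage_frame_rows(pose, tr, tree, node)
  sub_rows <- .torsion_moving_rows(pose, tr, tree, node)
  c1_row <- node_atom_row(pose, tree, node, "C1")
  o5_row <- node_atom_row(pose, tree, node, "O5")

  if (!is.null(torsions$omega)) {
    if (fr$root || fr$x != 6)
      stop("omega is only defined for 1->6 linkages")
    pid <- tr$nodes$parent_id[tr$nodes$node_id == node]
    o6 <- node_atom_row(pose, tree, pid, "O6")
    c6 <- node_atom_row(pose, tree, pid, "C6")
    c5 <- node_atom_row(pose, tree, pid, "C5")
    o5p <- node_atom_row(pose, tree, pid, "O5")
    mfn <- function(p) dihedral_deg(p$xyz[o6, ], p$xyz[c6, ], p$xyz[c5, ], p$xyz[o5p, ])
    pose <- .rotate_to_torsion(pose, c(sub_rows, o6), c6, c5, mfn, torsions$omega)
  }
  if (!is.null(torsions$psi)) {
    mfn <- function(p) dihedral_deg(p$xyz[c1_row, ], p$xyz[fr$ox, ],
                                    p$xyz[fr$cx, ], p$xyz[fr$cprev, ])
    pose <- .rotate_to_torsion(pose, sub_rows, fr$ox, fr$cx, mfn, torsions$psi)
  }
  if (!is.null(torsions$phi)) {
    mfn <- function(p) dihedral_deg(p$xyz[o5_row, ], p$xyz[c1_row, ],
                                    p$xyz[fr$ox, ], p$xyz[fr$cx, ])
    pose <- .rotate_to_torsion(pose, sub_rows, c1_row, fr$ox, mfn, torsions$phi)
  }
  pose
}

# rotatable exocyclic positions of a node; presence of the hydroxyl H is the
# marker (it is removed when the position becomes a linkage)
rotatable_chis <- function(pose, tree = 1L, node) {
  out <- integer()
  for (x in c(2L, 3L, 4L, 6L)) {
    h <- node_atom_row(pose, tree, node, paste0("HO", x), must = FALSE)
    if (!is.na(h)) out <- c(out, x)
  }
  out
}

#' Measure an exocyclic chi angle
#'
#' For positions 2/3/4 the chi is the hydroxyl torsion HOx-Ox-Cx-C(x-1).
#' Position 6 is the free hydroxymethyl rotation, measured as O6-C6-C5-O5
#' (when position 6 carries a glycosidic linkage this torsion is the omega
#' backbone angle instead, and position 6 is not a chi).
#'
#' @inheritParams measure_torsions
#' @param position ring position (2, 3, 4 or 6).
#' @return chi in degrees.
#' @export
measure_exocyclic_chi <- function(pose, tree = 1L, node, position) {
  fr <- .chi_rows(pose, tree, node, position)
  dihedral_deg(pose$xyz[fr$a, ], pose$xyz[fr$b, ], pose$xyz[fr$c, ], pose$xyz[fr$d, ])
}

# frame and moving rows for an exocyclic chi; errors when not rotatable
.chi_rows <- function(pose, tree, node, position) {
  if (position %in% 2:4) {
    h <- node_atom_row(pose, tree, node, paste0("HO", position), must = FALSE)
    if (is.na(h))
      stop(sprintf("position %d of node %d is not a rotatable hydroxyl (absent or linkage-occupied)",
                   position, node))
    ox <- node_atom_row(pose, tree, node, paste0("O", position))
    cx <- node_atom_row(pose, tree, node, paste0("C", position))
    cprev_name <- if (position == 2) "C1" else paste0("C", position - 1)
    cp <- node_atom_row(pose, tree, node, cprev_name)
    # chi = H-O-C-Cprev; rotation about the O-C bond moves only the H
    list(a = h, b = ox, c = cx, d = cp, moving = h,
         axis_from = ox, axis_to = cx)
  } else if (position == 6) {
    o6 <- node_atom_row(pose, tree, node, "O6", must = FALSE)
    h6 <- node_atom_row(pose, tree, node, "HO6", must = FALSE)
    if (is.na(o6) || is.na(h6))
      stop(sprintf("position 6 of node %d is not a free hydroxymethyl (deoxy or linkage-occupied)",
                   node))
    c6 <- node_atom_row(pose, tree, node, "C6")
    c5 <- node_atom_row(pose, tree, node, "C5")
    o5 <- node_atom_row(pose, tree, node, "O5")
    list(a = o6, b = c6, c = c5, d = o5, moving = c(o6, h6),
         axis_from = c6, axis_to = c5)
  } else {
    stop("position must be 2, 3, 4 or 6")
  }
}

#' Set an exocyclic chi angle
#'
#' Rotates only the hydroxyl hydrogen (positions 2/3/4) or the O6/H6 pair
#' (position 6, free hydroxymethyl) about the relevant bond.  Errors if the
#' position carries no rotatable group, e.g. when it is occupied by a
#' glycosidic linkage or the sugar is deoxy there.
#'
#' @inheritParams measure_exocyclic_chi
#' @param angle target chi in degrees.
#' @return the modified pose.
#' @export
set_exocyclic_chi <- function(pose, tree = 1L, node, position, angle) {
  fr <- .chi_rows(pose, tree, node, position)
  mfn <- function(p) dihedral_deg(p$xyz[fr$a, ], p$xyz[fr$b, ],
                                  p$xyz[fr$c, ], p$xyz[fr$d, ])
  .rotate_to_torsion(pose, fr$moving, fr$axis_from, fr$axis_to, mfn, angle)
}

# fast cached torsion setter used by the sampler (k = kin-cache entry);
# same rotations as set_torsions but with precomputed row indices
.set_torsions_fast <- function(pose, k, torsions) {
  if (!is.null(torsions$omega) && !is.null(k$om)) {
    om <- k$om
    mfn <- function(p) dihedral_deg(p$xyz[om[1], ], p$xyz[om[2], ],
                                    p$xyz[om[3], ], p$xyz[om[4], ])
    pose <- .rotate_to_torsion(pose, c(k$sub_rows, om[1]), om[2], om[3],
                               mfn, torsions$omega)
  }
  if (!is.null(torsions$psi)) {
    mfn <- function(p) dihedral_deg(p$xyz[k$c1, ], p$xyz[k$ox, ],
                                    p$xyz[k$cx, ], p$xyz[k$cprev, ])
    pose <- .rotate_to_torsion(pose, k$sub_rows, k$ox, k$cx, mfn, torsions$psi)
  }
  if (!is.null(torsions$phi)) {
    mfn <- function(p) dihedral_deg(p$xyz[k$o5, ], p$xyz[k$c1, ],
                                    p$xyz[k$ox, ], p$xyz[k$cx, ])
    pose <- .rotate_to_torsion(pose, k$sub_rows, k$c1, k$ox, mfn, torsions$phi)
  }
  pose
}

#' Randomize glycosidic backbone torsions
#'
#' Draws each phi/psi (and omega for 1->6 linkages) independently from the
#' uniform distribution on \code{[-180, 180)} using R's global RNG; seed with
#' \code{set.seed()} for reproducibility.
#'
#' @inheritParams measure_torsions
#' @param nodes node ids to randomize (default: all nodes of the tree).
#' @return the modified pose.
#' @export
randomize_backbone <- function(pose, tree = 1L, nodes = NULL) {
  tr <- pose$trees[[tree]]
  if (is.null(nodes)) nodes <- tr$nodes$node_id
  for (id in nodes) {
    fr <- linkage_frame_rows(pose, tr, tree, id)
    t <- list(phi = stats::runif(1, -180, 180), psi = stats::runif(1, -180, 180))
    if (!fr$root && fr$x == 6) t$omega <- stats::runif(1, -180, 180)
    pose <- set_torsions(pose, tree, id, t)
  }
  pose
}
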