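# Shared fixtures and independent oracles.  Everything is generated in code;
# the conformer library is built once per test run from the synthetic
# observation generator and cached.

MAN3_CORE <- paste0("a-D-Manp-(1->3)-[a-D-Manp-(1->6)]-b-D-Manp-(1->4)-",
                    "b-D-GlcpNAc-(1->4)-b-D-GlcpNAc")

test_library <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- default_library(n = 1000)
    lib
  }
})

test_scaffold <- function() make_toy_scaffold("helix", 12, 6)

test_core_tree <- function() {
  parse_iupac(MAN3_CORE, attachment = list(chain = "A", resno = 6, atom = "ND2"))
}

test_reference <- local({
  ref <- NULL
  function() {
    if (is.null(ref))
      ref <<- make_reference_complex(test_core_tree(), test_scaffold(),
                                     test_library())
    ref
  }
})

# random valid glycan tree (fuzz generator): depth <= max_depth,
# branching <= 3 children per node
random_tree <- function(max_depth = 5, p_child = 0.5) {
  alphabet <- sugar_alphabet()
  rows <- list()
  next_id <- 1L
  grow <- function(parent_id, parent_pos, depth) {
    id <- next_id; next_id <<- next_id + 1L
    kind <- sample(alphabet, 1)
    # positions that can accept children on this sugar
    free <- c(2L, 3L, 4L, 6L)
    if (grepl("NAc", kind)) free <- setdiff(free, 2L)
    if (grepl("Fucp", kind) || grepl("Xylp", kind)) free <- setdiff(free, 6L)
    rows[[id]] <<- data.frame(
      node_id = id, kind = kind, anomer = substr(kind, 1, 1),
      parent_id = parent_id, parent_pos = parent_pos, child_pos = 1L,
      stringsAsFactors = FALSE)
    if (depth < max_depth) {
      n_kids <- sum(stats::runif(min(3, length(free))) < p_child)
      if (n_kids > 0) {
        for (pos in sample(free, n_kids)) grow(id, pos, depth + 1)
      }
    }
  }
  grow(NA_integer_, NA_integer_, 1)
  glycan_tree(do.call(rbind, rows),
              attachment = list(chain = "A", resno = 6, atom = "ND2"))
}

# independent BFS layer oracle (adjacency-list BFS, no package internals)
bfs_layers_oracle <- function(tree) {
  nd <- tree$nodes
  root <- nd$node_id[is.na(nd$parent_id)]
  depth <- setNames(rep(NA_integer_, nrow(nd)), nd$node_id)
  depth[as.character(root)] <- 0L
  frontier <- root
  while (length(frontier)) {
    nxt <- nd$node_id[!is.na(nd$parent_id) & nd$parent_id %in% frontier]
    depth[as.character(nxt)] <- depth[as.character(nd$parent_id[
      match(nxt, nd$node_id)])] + 1L
    frontier <- nxt
  }
  depth
}

# independent dihedral oracle: projection onto the plane normal to the
# central bond, signed angle by atan2 of cross/dot with the bond direction
dihedral_oracle <- function(p1, p2, p3, p4) {
  b <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  v <- (p4 - p3) - sum((p4 - p3) * b) * b
  cx <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  ang <- atan2(sum(cx * b), sum(u * v)) * 180 / pi
  # measure_torsions reports the IUPAC sign; this construction yields the
  # opposite-handed angle, so flip to compare
  wrap_angle(-ang)
}

# random torsion assignment for a tree
random_torsions <- function(tree) {
  out <- list()
  for (i in seq_len(nrow(tree$nodes))) {
    nd <- tree$nodes[i, ]
    tl <- list(phi = stats::runif(1, -180, 180), psi = stats::runif(1, -180, 180))
    if (!is.na(nd$parent_pos) && nd$parent_pos == 6)
      tl$omega <- stats::runif(1, -180, 180)
    out[[as.character(nd$node_id)]] <- tl
  }
  out
}

# brute-force rigid-superposition RMSD oracle: coarse rotation grid followed
# by Nelder-Mead refinement of the Euler angles
kabsch_oracle <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(e) {
    cx <- cos(e[1]); sx <- sin(e[1]); cy <- cos(e[2]); sy <- sin(e[2])
    cz <- cos(e[3]); sz <- sin(e[3])
    matrix(c(cy * cz, -cy * sz, sy,
             cx * sz + sx * sy * cz, cx * cz - sx * sy * sz, -sx * cy,
             sx * sz - cx * sy * cz, sx * cz + cx * sy * sz, cx * cy),
           3, 3, byrow = TRUE)
  }
  obj <- function(e) sqrt(mean(rowSums((Pc %*% t(rot(e)) - Qc)^2)))
  best <- Inf; best_e <- NULL
  g <- seq(-pi, pi, length.out = 7)
  for (a in g) for (b in g[g > -pi / 2 & g < pi / 2]) for (cc in g) {
    v <- obj(c(a, b, cc))
    if (v < best) { best <- v; best_e <- c(a, b, cc) }
  }
  opt <- stats::optim(best_e, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
  opt$value
}
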