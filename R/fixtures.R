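# Synthetic inputs: torsion observation sets, toy protein scaffolds,
# reference glycan complexes and simulated density maps.  Everything here is
# seed-deterministic so that the whole test suite runs without downloads.
#
# The torsion generator emulates the statistics a PDB-wide linkage harvest
# would give: tight unimodal basins for most phi/psi torsions (circular sd
# around 10 degrees, matching crystallographic scatter for well-ordered
# glycosidic linkages), a bimodal gg/gt omega for 1->6 arms, and an optional
# minor anti basin.  It does not emulate the coverage or outliers of real
# PDB data.

#' Sample angles from a von Mises mixture
#'
#' @param components data.frame (or list coercible to one) with columns
#'   \code{mean} (degrees), \code{kappa}, \code{weight}; weights must sum
#'   to 1.
#' @param n number of draws.
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   first so the draw is reproducible.
#' @return angles in degrees, \code{[-180, 180)}.
#' @export
gen_torsion_mixture <- function(components, n, seed = NULL) {
  components <- as.data.frame(components)
  stopifnot(all(c("mean", "kappa", "weight") %in% names(components)))
  if (any(components$weight < 0) || abs(sum(components$weight) - 1) > 1e-9)
    stop("mixture weights must be >= 0 and sum to 1")
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(nrow(components), n, replace = TRUE,
                     prob = components$weight)
  out <- numeric(n)
  for (i in seq_len(nrow(components))) {
    w <- comp == i
    if (any(w)) out[w] <- rvonmises(sum(w), components$mean[i], components$kappa[i])
  }
  out
}

# curated mixture parameters per linkage key and torsion; a deterministic
# fallback (hash of the key) covers any other linkage in the alphabet
.synthetic_torsion_params <- function(key, torsion) {
  # basin centers are expressed in this package's torsion frame (rigid
  # idealized templates); concentrations mimic crystallographic scatter of
  # well-ordered linkages (circular sd roughly 10-14 degrees)
  curated <- list(
    "b-D-GlcpNAc-(1->ASN)" = list(
      phi = data.frame(mean = 40, kappa = 30, weight = 1),
      psi = data.frame(mean = -110, kappa = 20, weight = 1)),
    "b-D-GlcpNAc-(1->4)-b-D-GlcpNAc" = list(
      phi = data.frame(mean = 10, kappa = 35, weight = 1),
      psi = data.frame(mean = -120, kappa = 25, weight = 1)),
    "b-D-Manp-(1->4)-b-D-GlcpNAc" = list(
      phi = data.frame(mean = 120, kappa = 35, weight = 1),
      psi = data.frame(mean = -110, kappa = 25, weight = 1)),
    "a-D-Manp-(1->3)-b-D-Manp" = list(
      phi = data.frame(mean = -170, kappa = 30, weight = 1),
      psi = data.frame(mean = 70, kappa = 20, weight = 1)),
    "a-D-Manp-(1->6)-b-D-Manp" = list(
      phi = data.frame(mean = -170, kappa = 30, weight = 1),
      psi = data.frame(mean = -180, kappa = 20, weight = 1),
      omega = data.frame(mean = c(-60, 60), kappa = c(25, 25),
                         weight = c(0.65, 0.35))),
    "a-L-Fucp-(1->6)-b-D-GlcpNAc" = list(
      phi = data.frame(mean = -170, kappa = 30, weight = 1),
      psi = data.frame(mean = 170, kappa = 20, weight = 1),
      omega = data.frame(mean = c(60, 180), kappa = c(25, 25),
                         weight = c(0.7, 0.3)))
  )
  if (!is.null(curated[[key]][[torsion]])) return(curated[[key]][[torsion]])
  # deterministic fallback: typical basin perturbed by a stable hash of the key
  h <- sum(utf8ToInt(paste(key, torsion))) %% 61 - 30
  base <- switch(torsion, phi = -120, psi = 120, omega = -60)
  data.frame(mean = wrap_angle(base + h), kappa = 25, weight = 1)
}

#' Generate synthetic torsion observations for a set of linkage types
#'
#' @param keys linkage keys (see [linkage_key()]); default covers the common
#'   N-glycan core linkages.
#' @param n observations per torsion.
#' @param seed integer seed.
#' @return data.frame with columns \code{linkage_key}, \code{torsion},
#'   \code{angle_deg}, suitable for [build_conformer_library()].
#' @export
synthetic_observations <- function(keys = NULL, n = 2000, seed = 17) {
  if (is.null(keys)) {
    keys <- c("b-D-GlcpNAc-(1->ASN)",
              "b-D-GlcpNAc-(1->4)-b-D-GlcpNAc",
              "b-D-Manp-(1->4)-b-D-GlcpNAc",
              "a-D-Manp-(1->3)-b-D-Manp",
              "a-D-Manp-(1->6)-b-D-Manp",
              "a-L-Fucp-(1->6)-b-D-GlcpNAc")
  }
  set.seed(seed)
  rows <- list()
  for (key in keys) {
    tnames <- c("phi", "psi", if (linkage_has_omega(key)) "omega")
    for (t in tnames) {
      ang <- gen_torsion_mixture(.synthetic_torsion_params(key, t), n)
      rows[[length(rows) + 1]] <- data.frame(linkage_key = key, torsion = t,
                                             angle_deg = ang,
                                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Default conformer library for the packaged fixtures
#'
#' Built from [synthetic_observations()] with fixed seed; cached for the
#' session.
#'
#' @param n observations per torsion.
#' @return a \code{conformer_library}.
#' @export
default_library <- function(n = 2000) {
  key <- paste0("lib", n)
  if (is.null(.template_cache[[key]])) {
    .template_cache[[key]] <- build_conformer_library(
      synthetic_observations(n = n, seed = 17))
  }
  .template_cache[[key]]
}

# ideal peptide geometry
.PEP <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
             ang_n_ca_c = 111.0, ang_ca_c_n = 116.6, ang_c_n_ca = 121.7,
             ang_ca_c_o = 120.5, omega = 180)

#' Ideal-geometry toy scaffold
#'
#' Polyalanine helix (phi -57, psi -47) or strand (phi -120, psi 120) with a
#' single Asn carrying the ND2 attachment atom.  Backbone N/CA/C/O plus CB
#' everywhere; the Asn also gets CG/OD1/ND2.  Deterministic.
#'
#' @param style "helix" or "strand".
#' @param length number of residues (>= 5).
#' @param asn_position 1-based residue index of the Asn.
#' @return a pose (chain "A").
#' @export
make_toy_scaffold <- function(style = c("helix", "strand"), length = 12,
                              asn_position = 6) {
  style <- match.arg(style)
  if (length < 5) stop("scaffold length must be >= 5")
  if (asn_position < 1 || asn_position > length)
    stop("asn_position out of range")
  phi <- if (style == "helix") -57 else -120
  psi <- if (style == "helix") -47 else 120

  atoms <- list(); xyz <- list(); bonds <- list()
  add <- function(resno, resname, name, element, pos) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      chain = "A", resno = resno, resname = resname, atom = name,
      element = element, role = "protein", tree = NA_integer_,
      node = NA_integer_, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <<- pos
  }
  bond <- function(r1, a1, r2, a2)
    bonds[[length(bonds) + 1]] <<- c(paste(r1, a1), paste(r2, a2))

  # first residue in a canonical frame
  n1 <- c(0, 0, 0)
  ca1 <- c(.PEP$n_ca, 0, 0)
  c1 <- place_atom(c(0, 1, 0), n1, ca1, .PEP$ca_c, .PEP$ang_n_ca_c, 0)
  prev <- list(n = n1, ca = ca1, c = c1)
  for (i in seq_len(length)) {
    resname <- if (i == asn_position) "ASN" else "ALA"
    if (i == 1) {
      n <- prev$n; ca <- prev$ca; cc <- prev$c
    } else {
      n <- place_atom(prev$n, prev$ca, prev$c, .PEP$c_n, .PEP$ang_ca_c_n, psi)
      ca <- place_atom(prev$ca, prev$c, n, .PEP$n_ca, .PEP$ang_c_n_ca, .PEP$omega)
      cc <- place_atom(prev$c, n, ca, .PEP$ca_c, .PEP$ang_n_ca_c, phi)
    }
    o <- place_atom(n, ca, cc, .PEP$c_o, .PEP$ang_ca_c_o, wrap_angle(psi + 180))
    cb <- place_atom(n, cc, ca, 1.53, 110.1, 122.5)
    add(i, resname, "N", "N", n)
    add(i, resname, "CA", "C", ca)
    add(i, resname, "C", "C", cc)
    add(i, resname, "O", "O", o)
    add(i, resname, "CB", "C", cb)
    bond(i, "N", i, "CA"); bond(i, "CA", i, "C"); bond(i, "C", i, "O")
    bond(i, "CA", i, "CB")
    if (i > 1) bond(i - 1, "C", i, "N")
    if (resname == "ASN") {
      cg <- place_atom(n, ca, cb, 1.52, 114.0, 150)
      od1 <- place_atom(ca, cb, cg, 1.23, 120.8, -30)
      nd2 <- place_atom(ca, cb, cg, 1.33, 116.5, 150)
      add(i, resname, "CG", "C", cg)
      add(i, resname, "OD1", "O", od1)
      add(i, resname, "ND2", "N", nd2)
      bond(i, "CB", i, "CG"); bond(i, "CG", i, "OD1"); bond(i, "CG", i, "ND2")
    }
    prev <- list(n = n, ca = ca, c = cc)
  }
  at <- do.call(rbind, atoms)
  key <- paste(at$resno, at$atom)
  bm <- do.call(rbind, lapply(bonds, function(b) match(b, key)))
  new_pose(at, do.call(rbind, xyz), bonds = bm)
}

#' Native-like reference complex for recovery benchmarks
#'
#' Builds the tree at conformer modes (combination \code{conformer_choice}
#' in mass-descending cross-product order) and asserts the result is
#' clash-free; clashing combinations are skipped and the next one tried.
#'
#' @param tree a \code{glycan_tree} with attachment set.
#' @param scaffold pose with the attachment residue.
#' @param library a \code{conformer_library} covering the tree.
#' @param conformer_choice index of the first conformer combination to try.
#' @param rep_threshold maximum tolerated unweighted steric repulsion.
#' @param max_tries combinations tried before giving up.
#' @return list: \code{pose} (the native), \code{tree}, \code{torsions}.
#' @export
make_reference_complex <- function(tree, scaffold, library,
                                   conformer_choice = 1L, rep_threshold = 5,
                                   max_tries = 64L) {
  ids <- tree$nodes$node_id
  cfs <- lapply(ids, function(id)
    library_linkage(library, linkage_key(tree, id))$conformers)
  names(cfs) <- as.character(ids)
  counts <- vapply(cfs, nrow, integer(1))

  # enumerate combinations in decreasing product-mass order
  combos <- expand.grid(lapply(counts, seq_len))
  mass <- apply(combos, 1, function(ix)
    prod(vapply(seq_along(ids), function(k) cfs[[k]]$mass[ix[k]], numeric(1))))
  combos <- combos[order(-mass), , drop = FALSE]

  tried <- 0L
  for (ci in seq.int(conformer_choice, nrow(combos))) {
    tried <- tried + 1L
    if (tried > max_tries) break
    torsions <- list()
    for (k in seq_along(ids)) {
      cf <- cfs[[k]][combos[ci, k], ]
      tl <- list(phi = cf$phi, psi = cf$psi)
      if ("omega" %in% names(cf)) tl$omega <- cf$omega
      torsions[[as.character(ids[k])]] <- tl
    }
    pose <- build_glycan(scaffold, tree, torsions)
    st <- steric_energy(pose, length(pose$trees), ids)
    if (st$rep < rep_threshold)
      return(list(pose = pose, tree = tree, torsions = torsions))
  }
  stop("no clash-free conformer combination found within ", max_tries, " tries")
}

# --- simulated density -------------------------------------------------------

#' Simulate an electron-density map from a pose
#'
#' Sum of per-heavy-atom isotropic Gaussians with sigma = resolution / 3 on a
#' regular grid covering the pose plus padding.  A crude but deterministic
#' stand-in for an experimental map.
#'
#' @param pose a pose.
#' @param resolution nominal resolution (Angstrom).
#' @param voxel grid spacing (Angstrom).
#' @param padding margin around the pose (Angstrom).
#' @param rows atom rows contributing (default: all heavy atoms).
#' @return object of class \code{density_map}: \code{origin}, \code{voxel},
#'   \code{dim}, \code{sigma}, \code{data} (numeric 3-D array).
#' @export
simulate_density <- function(pose, resolution = 2.0, voxel = 1.0,
                             padding = 4.0, rows = NULL) {
  stopifnot(resolution > 0, voxel > 0)
  if (is.null(rows)) rows <- heavy_rows(pose)
  coords <- pose$xyz[rows, , drop = FALSE]
  lo <- apply(coords, 2, min) - padding
  hi <- apply(coords, 2, max) + padding
  dims <- as.integer(ceiling((hi - lo) / voxel)) + 1L
  sigma <- resolution / 3
  vals <- cpp_sum_gaussians(coords, lo, dims, voxel, sigma, 3.5)
  structure(list(origin = lo, voxel = voxel, dim = dims, sigma = sigma,
                 data = array(vals, dim = dims)),
            class = "density_map")
}

#' Real-space correlation of a pose selection against a map
#'
#' Pearson correlation between the map and a same-grid simulated map of the
#' selection, over voxels within \code{mask_radius} of the selection atoms.
#' Atoms falling outside the map contribute no masked voxels (warning when
#' none remain, returning 0).
#'
#' @param pose a pose.
#' @param map a \code{density_map}.
#' @param rows atom rows of the selection (heavy atoms).
#' @param mask_radius mask radius around atoms (Angstrom).
#' @return correlation in \code{[-1, 1]}.
#' @export
real_space_correlation <- function(pose, map, rows, mask_radius = 2.5) {
  coords <- pose$xyz[rows, , drop = FALSE]
  idx <- cpp_mask_indices(coords, map$origin, map$dim, map$voxel, mask_radius)
  if (!length(idx)) {
    warning("selection lies entirely outside the density map; correlation 0")
    return(0)
  }
  model <- cpp_sum_gaussians(coords, map$origin, map$dim, map$voxel,
                             map$sigma, 3.5)[idx]
  obs <- map$data[idx]
  if (stats::sd(obs) < 1e-12 || stats::sd(model) < 1e-12)
    stop("degenerate (constant) masked density region")
  stats::cor(obs, model)
}

#' Write / read a density map in a simple text grid format
#'
#' Header line (origin, voxel, dims, sigma) followed by the values in
#' column-major order, one per line.
#'
#' @param map a \code{density_map}.
#' @param path file path.
#' @return \code{write_density_map}: invisibly the path;
#'   \code{read_density_map}: a \code{density_map}.
#' @export
write_density_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("DENSITY %.6f %.6f %.6f %.6f %d %d %d %.6f",
                     map$origin[1], map$origin[2], map$origin[3], map$voxel,
                     map$dim[1], map$dim[2], map$dim[3], map$sigma), con)
  writeLines(sprintf("%.6e", as.numeric(map$data)), con)
  invisible(path)
}

#' @rdname write_density_map
#' @export
read_density_map <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(lines[1], "\\s+")[[1]]
  if (hd[1] != "DENSITY") stop("not a density map file")
  origin <- as.numeric(hd[2:4]); voxel <- as.numeric(hd[5])
  dims <- as.integer(hd[6:8]); sigma <- as.numeric(hd[9])
  vals <- as.numeric(lines[-1])
  structure(list(origin = origin, voxel = voxel, dim = dims, sigma = sigma,
                 data = array(vals, dim = dims)),
            class = "density_map")
}
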