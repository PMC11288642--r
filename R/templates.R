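# Idealized rigid-ring pyranose templates.
#
# Every supported sugar is built once, deterministically, from an ideal chair:
# ring atoms C1-C2-C3-C4-C5-O5 on a hexagonal chair (uniform ring bond 1.50 A,
# puckering amplitude 0.25 A), substituents at tetrahedral axial/equatorial
# directions.  D-pyranoses are 4C1; L-fucose is the mirror image of D-galactose
# (1C4) with the 6-hydroxyl removed (6-deoxy).  Ring pucker is never sampled.
#
# Hydrogens are placed only where they matter energetically: hydroxyl H and
# the N-acetyl amide H.  Apolar hydrogens are omitted; all RMSD metrics in the
# package use heavy atoms only.

.BOND_CC <- 1.52
.BOND_CO <- 1.43
.BOND_CN <- 1.45
.BOND_OH <- 0.96
.BOND_NH <- 1.01
.RING_BOND <- 1.50
.RING_PUCKER <- 0.25
.TET <- 109.47

# per-sugar substituent layout in the 4C1 D frame: orientation of the
# anomeric substituent comes from the anomer (a = axial, b = equatorial for
# D-pyranoses in 4C1); the rest is sugar chemistry.
.SUGAR_LAYOUT <- list(
  Glcp    = list(C2 = "O_eq", C3 = "O_eq", C4 = "O_eq", C5 = "C6"),
  GlcpNAc = list(C2 = "NAc_eq", C3 = "O_eq", C4 = "O_eq", C5 = "C6"),
  Manp    = list(C2 = "O_ax", C3 = "O_eq", C4 = "O_eq", C5 = "C6"),
  Galp    = list(C2 = "O_eq", C3 = "O_eq", C4 = "O_ax", C5 = "C6"),
  GalpNAc = list(C2 = "NAc_eq", C3 = "O_eq", C4 = "O_ax", C5 = "C6"),
  Fucp    = list(C2 = "O_eq", C3 = "O_eq", C4 = "O_ax", C5 = "C6deoxy"),
  Xylp    = list(C2 = "O_eq", C3 = "O_eq", C4 = "O_eq", C5 = "none")
)

# PDB 3-letter residue codes <-> internal kinds
.PDB_SUGAR_CODES <- c(
  "b-D-GlcpNAc" = "NAG", "a-D-GlcpNAc" = "NDG",
  "b-D-Manp" = "BMA",    "a-D-Manp" = "MAN",
  "b-D-Galp" = "GAL",    "a-D-Galp" = "GLA",
  "a-L-Fucp" = "FUC",    "b-L-Fucp" = "FUL",
  "b-D-Xylp" = "XYS",    "a-D-Xylp" = "LXC",
  "a-D-Glcp" = "GLC",    "b-D-Glcp" = "BGC",
  "a-D-GalpNAc" = "A2G", "b-D-GalpNAc" = "NGA"
)

pdb_code_for_kind <- function(kind) {
  code <- .PDB_SUGAR_CODES[kind]
  if (any(is.na(code))) stop("no PDB code for kind ", kind[is.na(code)][1])
  unname(code)
}

kind_for_pdb_code <- function(code) {
  inv <- setNames(names(.PDB_SUGAR_CODES), .PDB_SUGAR_CODES)
  k <- inv[code]
  unname(k)  # NA for unknown codes
}

.template_cache <- new.env(parent = emptyenv())

# the two tetrahedral substituent directions at ring atom i given its two
# ring neighbours; returns list(ax = unit vec, eq = unit vec)
.subst_dirs <- function(xyz_ring, i, prev, nxt) {
  p <- xyz_ring[i, ]
  d1 <- unitv(xyz_ring[prev, ] - p)
  d2 <- unitv(xyz_ring[nxt, ] - p)
  u <- unitv(-(d1 + d2))
  w <- unitv(c(d1[2] * d2[3] - d1[3] * d2[2],
               d1[3] * d2[1] - d1[1] * d2[3],
               d1[1] * d2[2] - d1[2] * d2[1]))
  half <- (.TET / 2) * .deg2rad
  s1 <- cos(half) * u + sin(half) * w
  s2 <- cos(half) * u - sin(half) * w
  if (abs(s1[3]) >= abs(s2[3])) list(ax = s1, eq = s2) else list(ax = s2, eq = s1)
}

#' Ideal-geometry template for a sugar residue
#'
#' Returns (and caches) the rigid template: heavy atoms plus polar hydrogens,
#' the direction of the anomeric (linkage) bond at C1, and hydrogen-bond
#' donor/acceptor typing.  D-pyranoses are built in the 4C1 chair, L-fucose
#' in 1C4.
#'
#' @param kind residue token, e.g. \code{"b-D-GlcpNAc"}.
#' @return list with \code{kind}, \code{atoms} (data.frame: name, element,
#'   donor, acceptor), \code{xyz} (matrix, Angstrom), \code{link_dir} (unit
#'   vector of the anomeric bond at C1), \code{ring} (ring atom names).
#' @export
template_for <- function(kind) {
  if (!is.character(kind) || length(kind) != 1 || !(kind %in% sugar_alphabet()))
    stop(sprintf("unsupported residue kind '%s'", as.character(kind)[1]))
  if (!is.null(.template_cache[[kind]])) return(.template_cache[[kind]])

  res <- parse_residue_token(kind)
  mirror <- res$series == "L"
  layout <- .SUGAR_LAYOUT[[res$name]]

  # ideal chair ring: C1 C2 C3 C4 C5 O5 at hexagon vertices, alternating z
  r <- sqrt(.RING_BOND^2 - (2 * .RING_PUCKER)^2)
  ring_names <- c("C1", "C2", "C3", "C4", "C5", "O5")
  kk <- 0:5
  ring <- cbind(r * cos(kk * pi / 3), r * sin(kk * pi / 3),
                .RING_PUCKER * (-1)^kk)
  rownames(ring) <- ring_names

  names_ <- ring_names
  elems <- c("C", "C", "C", "C", "C", "O")
  xyz <- ring
  bonds <- list(c("C1", "C2"), c("C2", "C3"), c("C3", "C4"), c("C4", "C5"),
                c("C5", "O5"), c("O5", "C1"))

  add_atom <- function(name, element, pos, bonded_to = NULL) {
    names_ <<- c(names_, name)
    elems <<- c(elems, element)
    xyz <<- rbind(xyz, pos)
    if (!is.null(bonded_to))
      bonds[[length(bonds) + 1]] <<- c(bonded_to, name)
  }

  prv <- c(6, 1, 2, 3, 4, 5)  # ring neighbour indices (cyclic)
  nxt <- c(2, 3, 4, 5, 6, 1)

  # anomeric substituent direction at C1 (a = axial, b = equatorial in the
  # 4C1 D frame; mirroring maps this correctly for the L series)
  dirs1 <- .subst_dirs(ring, 1, prv[1], nxt[1])
  link_dir <- if (res$anomer == "a") dirs1$ax else dirs1$eq

  place_OH <- function(ci, dir, oname, hname) {
    opos <- ring[ci, ] + .BOND_CO * dir
    add_atom(oname, "O", opos, bonded_to = ring_names[ci])
    # hydroxyl H anti to the lower-numbered ring neighbour
    ref <- ring[prv[ci], ]
    hpos <- place_atom(ref, ring[ci, ], opos, .BOND_OH, 109.5, 180)
    add_atom(hname, "H", hpos, bonded_to = oname)
  }

  for (ci in 2:4) {
    what <- layout[[ring_names[ci]]]
    dirs <- .subst_dirs(ring, ci, prv[ci], nxt[ci])
    if (what == "O_eq" || what == "O_ax") {
      d <- if (what == "O_ax") dirs$ax else dirs$eq
      place_OH(ci, d, paste0("O", ci), paste0("HO", ci))
    } else if (what == "NAc_eq") {
      npos <- ring[ci, ] + .BOND_CN * dirs$eq
      add_atom("N2", "N", npos, bonded_to = "C2")
      c1 <- ring[1, ]; c2 <- ring[2, ]
      c7 <- place_atom(c1, c2, npos, 1.33, 123, -120)
      add_atom("C7", "C", c7, bonded_to = "N2")
      o7 <- place_atom(c2, npos, c7, 1.23, 123, 0)
      add_atom("O7", "O", o7, bonded_to = "C7")
      c8 <- place_atom(c2, npos, c7, 1.50, 115, 180)
      add_atom("C8", "C", c8, bonded_to = "C7")
      hn <- place_atom(c1, c2, npos, .BOND_NH, 118, 120)
      add_atom("HN2", "H", hn, bonded_to = "N2")
    }
  }

  c5sub <- layout[["C5"]]
  if (c5sub %in% c("C6", "C6deoxy")) {
    dirs5 <- .subst_dirs(ring, 5, prv[5], nxt[5])
    c6 <- ring[5, ] + .BOND_CC * dirs5$eq
    add_atom("C6", "C", c6, bonded_to = "C5")
    if (c5sub == "C6") {
      # default hydroxymethyl rotamer: omega (O6-C6-C5-O5) = -60 (gg)
      o6 <- place_atom(ring[6, ], ring[5, ], c6, .BOND_CO, 109.5, -60)
      add_atom("O6", "O", o6, bonded_to = "C6")
      h6 <- place_atom(ring[5, ], c6, o6, .BOND_OH, 109.5, 180)
      add_atom("HO6", "H", h6, bonded_to = "O6")
    }
  }

  if (mirror) {
    xyz[, 1] <- -xyz[, 1]
    link_dir[1] <- -link_dir[1]
  }

  donor <- names_ %in% c("HO2", "HO3", "HO4", "HO6", "HN2")  # flag on the H
  acceptor <- elems == "O"
  tpl <- list(
    kind = kind,
    atoms = data.frame(name = names_, element = elems,
                       donor = donor, acceptor = acceptor,
                       stringsAsFactors = FALSE),
    xyz = unname(xyz),
    link_dir = link_dir,
    ring = ring_names,
    bonds = do.call(rbind, bonds)
  )
  rownames(tpl$xyz) <- NULL
  .template_cache[[kind]] <- tpl
  tpl
}

template_atom_xyz <- function(tpl, name) {
  i <- match(name, tpl$atoms$name)
  if (is.na(i)) stop(sprintf("template %s has no atom %s", tpl$kind, name))
  tpl$xyz[i, ]
}

#' Export sugar templates as a text table
#'
#' Writes every template in the alphabet as a plain-text block (one line per
#' atom: kind, atom name, element, x, y, z) for inspection or external use.
#'
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_template_table <- function(path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (kind in sugar_alphabet()) {
    tpl <- template_for(kind)
    writeLines(sprintf("TEMPLATE %s link_dir %.6f %.6f %.6f", kind,
                       tpl$link_dir[1], tpl$link_dir[2], tpl$link_dir[3]), con)
    for (i in seq_len(nrow(tpl$atoms))) {
      writeLines(sprintf("ATOM %s %s %.6f %.6f %.6f",
                         tpl$atoms$name[i], tpl$atoms$element[i],
                         tpl$xyz[i, 1], tpl$xyz[i, 2], tpl$xyz[i, 3]), con)
    }
  }
  invisible(path)
}
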