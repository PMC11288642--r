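# Carbohydrate-aware PDB input/output and JSON-lines scorefiles.
#
# Sugars are written as HETATM records with standard three-letter codes
# (NAG, BMA, MAN, ...) and one LINK record per glycosidic or N-glycosidic
# bond.  On input, trees are reconstructed from LINK records when present,
# otherwise by C1-to-oxygen distance inference (<= 1.6 A).

#' Write a pose to a PDB file
#'
#' Deterministic byte output for a fixed pose: fixed-width v3 records, LINK
#' lines for every glycan edge and attachment, TER after the protein.
#'
#' @param pose a pose.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_pdb <- function(pose, path) {
  lines <- character()
  at <- pose$atoms
  # LINK records: attachment + tree edges
  for (ti in seq_along(pose$trees)) {
    tr <- pose$trees[[ti]]
    for (i in seq_len(nrow(tr$nodes))) {
      nd <- tr$nodes[i, ]
      crow <- node_atom_row(pose, ti, nd$node_id, "C1")
      if (is.na(nd$parent_id)) {
        att <- tr$attachment
        arow <- atom_row(pose, att$chain, att$resno, att$atom)
        lines <- c(lines, .pdb_link_line(at[crow, ], at[arow, ]))
      } else {
        orow <- node_atom_row(pose, ti, nd$parent_id, paste0("O", nd$parent_pos))
        lines <- c(lines, .pdb_link_line(at[crow, ], at[orow, ]))
      }
    }
  }
  serial <- 0L
  protein <- which(at$role == "protein")
  other <- which(at$role != "protein")
  fmt_atom <- function(i, rec) {
    serial <<- serial + 1L
    name <- at$atom[i]
    namef <- if (nchar(name) >= 4) substr(name, 1, 4) else
      sprintf(" %-3s", name)
    sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, namef, at$resname[i], at$chain[i], at$resno[i],
            pose$xyz[i, 1], pose$xyz[i, 2], pose$xyz[i, 3], 1, 0, at$element[i])
  }
  for (i in protein) lines <- c(lines, fmt_atom(i, "ATOM"))
  if (length(protein)) lines <- c(lines, "TER")
  for (i in other) lines <- c(lines, fmt_atom(i, "HETATM"))
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

.pdb_link_line <- function(a1, a2) {
  sprintf("LINK        %-4s %-3s %1s%4d                %-4s %-3s %1s%4d",
          a1$atom, a1$resname, a1$chain, a1$resno,
          a2$atom, a2$resname, a2$chain, a2$resno)
}

#' Read a PDB file with carbohydrate support
#'
#' Parses ATOM/HETATM records; residues whose three-letter code is a known
#' sugar become glycan residues and are assembled into trees using LINK
#' records when present, else by C1-to-oxygen distance inference (bond
#' taken when within 1.6 A).  Waters (HOH) are stripped by default, matching
#' the benchmarking protocol.
#'
#' @param path PDB file.
#' @param strip_waters drop HOH residues (default TRUE).
#' @return a pose with any glycan trees registered.
#' @export
read_pdb <- function(path, strip_waters = TRUE) {
  lines <- readLines(path)
  recs <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(recs)) stop("no ATOM/HETATM records in ", path)
  f <- function(l, a, b) trimws(substr(l, a, b))
  atom <- vapply(recs, f, character(1), 13, 16)
  resname <- vapply(recs, f, character(1), 18, 20)
  chain <- vapply(recs, f, character(1), 22, 22)
  resno <- as.integer(vapply(recs, f, character(1), 23, 26))
  x <- as.numeric(vapply(recs, f, character(1), 31, 38))
  y <- as.numeric(vapply(recs, f, character(1), 39, 46))
  z <- as.numeric(vapply(recs, f, character(1), 47, 54))
  element <- vapply(recs, f, character(1), 77, 78)
  element[element == ""] <- substr(gsub("[0-9]", "", atom[element == ""]), 1, 1)
  kind <- kind_for_pdb_code(resname)
  role <- ifelse(!is.na(kind), "glycan",
                 ifelse(resname == "HOH", "water", "protein"))
  keep <- rep(TRUE, length(recs))
  if (strip_waters) keep <- role != "water"
  atoms <- data.frame(chain = chain, resno = resno, resname = resname,
                      atom = atom, element = element, role = role,
                      tree = NA_integer_, node = NA_integer_,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  xyz <- cbind(x, y, z)[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  pose <- new_pose(atoms, xyz)

  # glycan connectivity: each sugar's C1 bonds either a sugar oxygen O2..O6
  # of its parent or a protein ND2
  sugar_res <- unique(atoms[atoms$role == "glycan", c("chain", "resno", "resname")])
  if (!nrow(sugar_res)) return(pose)
  links <- .pdb_links(lines)
  edges <- .glycan_edges(pose, sugar_res, links)
  pose <- .register_trees(pose, sugar_res, edges)
  pose
}

.pdb_links <- function(lines) {
  ll <- lines[startsWith(lines, "LINK")]
  if (!length(ll)) return(NULL)
  f <- function(l, a, b) trimws(substr(l, a, b))
  data.frame(
    atom1 = vapply(ll, f, character(1), 13, 16),
    chain1 = vapply(ll, f, character(1), 22, 22),
    resno1 = as.integer(vapply(ll, f, character(1), 23, 26)),
    atom2 = vapply(ll, f, character(1), 43, 46),
    chain2 = vapply(ll, f, character(1), 52, 52),
    resno2 = as.integer(vapply(ll, f, character(1), 53, 56)),
    stringsAsFactors = FALSE)
}

# one row per sugar residue: parent residue (or protein Asn) and position
.glycan_edges <- function(pose, sugar_res, links) {
  at <- pose$atoms
  edges <- list()
  for (i in seq_len(nrow(sugar_res))) {
    sr <- sugar_res[i, ]
    c1 <- atom_row(pose, sr$chain, sr$resno, "C1", must = FALSE)
    if (is.na(c1)) stop("sugar residue ", sr$chain, "/", sr$resno, " lacks C1")
    partner <- NULL
    if (!is.null(links)) {
      for (k in seq_len(nrow(links))) {
        lk <- links[k, ]
        if (lk$atom1 == "C1" && lk$chain1 == sr$chain && lk$resno1 == sr$resno)
          partner <- list(chain = lk$chain2, resno = lk$resno2, atom = lk$atom2)
        if (lk$atom2 == "C1" && lk$chain2 == sr$chain && lk$resno2 == sr$resno)
          partner <- list(chain = lk$chain1, resno = lk$resno1, atom = lk$atom1)
        if (!is.null(partner)) break
      }
    }
    if (is.null(partner)) {
      # distance inference: nearest O2..O6/ND2 of another residue within 1.6 A
      cand <- which((at$atom %in% c("O2", "O3", "O4", "O6", "ND2")) &
                    !(at$chain == sr$chain & at$resno == sr$resno))
      if (length(cand)) {
        d <- sqrt(rowSums((pose$xyz[cand, , drop = FALSE] -
                           matrix(pose$xyz[c1, ], length(cand), 3, byrow = TRUE))^2))
        hit <- cand[d <= 1.6]
        if (length(hit) > 1)
          stop("ambiguous connectivity for sugar ", sr$chain, "/", sr$resno,
               ": candidates ", paste(at$atom[hit], at$resno[hit], collapse = ", "))
        if (length(hit) == 1)
          partner <- list(chain = at$chain[hit], resno = at$resno[hit],
                          atom = at$atom[hit])
      }
    }
    edges[[i]] <- partner
  }
  edges
}

.register_trees <- function(pose, sugar_res, edges) {
  at <- pose$atoms
  key <- function(ch, rn) paste(ch, rn)
  sugar_key <- key(sugar_res$chain, sugar_res$resno)
  # roots: sugars whose partner is a protein atom (or none)
  parent_is_sugar <- vapply(edges, function(e)
    !is.null(e) && key(e$chain, e$resno) %in% sugar_key, logical(1))
  roots <- which(!parent_is_sugar)
  for (r in roots) {
    e <- edges[[r]]
    if (is.null(e)) next  # unattached sugar: leave unregistered
    ti <- length(pose$trees) + 1L
    # BFS over sugars to collect the tree
    rows <- list(); queue <- list(list(i = r, parent = NA_integer_, pos = NA_integer_))
    idmap <- integer(0)
    nid <- 0L
    while (length(queue)) {
      it <- queue[[1]]; queue <- queue[-1]
      nid <- nid + 1L
      sr <- sugar_res[it$i, ]
      idmap[key(sr$chain, sr$resno)] <- nid
      rows[[nid]] <- data.frame(
        node_id = nid, kind = kind_for_pdb_code(sr$resname),
        anomer = substr(kind_for_pdb_code(sr$resname), 1, 1),
        parent_id = it$parent, parent_pos = it$pos, child_pos = 1L,
        stringsAsFactors = FALSE)
      mark <- pose$atoms$chain == sr$chain & pose$atoms$resno == sr$resno
      pose$atoms$tree[mark] <- ti
      pose$atoms$node[mark] <- nid
      kids <- which(vapply(edges, function(e2)
        !is.null(e2) && key(e2$chain, e2$resno) == key(sr$chain, sr$resno),
        logical(1)))
      kids <- kids[kids != it$i]
      if (length(kids)) {
        pos <- vapply(kids, function(k2)
          as.integer(sub("O", "", edges[[k2]]$atom)), integer(1))
        for (k2 in kids[order(pos)]) {
          queue[[length(queue) + 1]] <- list(
            i = k2, parent = nid,
            pos = as.integer(sub("O", "", edges[[k2]]$atom)))
        }
      }
    }
    att <- list(chain = e$chain, resno = e$resno, atom = e$atom)
    pose$trees[[ti]] <- glycan_tree(do.call(rbind, rows), attachment = att)
  }
  pose
}

# --- scorefiles --------------------------------------------------------------

#' Write decoy records as a JSON-lines scorefile
#'
#' One JSON object per line: decoy id, seed, per-term energies, total, and
#' any metrics present on the record.
#'
#' @param records list of decoy records from [generate_ensemble()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_scorefile <- function(records, path) {
  lines <- vapply(records, function(r) {
    obj <- list(decoy = r$id, seed = r$seed,
                sugar_bb = r$energy$sugar_bb, rep = r$energy$rep,
                atr = r$energy$atr, hbond = r$energy$hbond,
                density = r$energy$density, total = r$energy$total)
    if (!is.null(r$metrics)) obj <- c(obj, r$metrics)
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines scorefile
#'
#' @param path file written by [write_scorefile()].
#' @return data.frame, one row per decoy.
#' @export
read_scorefile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(data.frame())
  do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
}
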