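# N-glycosylation sequon utilities: scanning the N-X(S/T) motif (X != P),
# designing typical/enhanced sequons into a sequence, attaching whole glycans
# to a pose, and ranking candidate positions by modeled energy.

.AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Scan a protein sequence for N-glycosylation sequons
#'
#' A sequon is N-X-(S/T) with X any residue except proline.  Overlapping
#' hits are all reported.
#'
#' @param sequence one-letter amino-acid string.
#' @return data.frame: \code{position} (1-based index of the N),
#'   \code{triplet}, \code{hydroxyl} ("S" or "T").
#' @export
scan_sequons <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), .AA1)
  if (length(bad))
    stop("non-amino-acid character(s): ", paste(bad, collapse = ", "))
  n <- length(chars)
  hits <- list()
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      if (chars[i] == "N" && chars[i + 1] != "P" && chars[i + 2] %in% c("S", "T")) {
        hits[[length(hits) + 1]] <- data.frame(
          position = i, triplet = paste(chars[i:(i + 2)], collapse = ""),
          hydroxyl = chars[i + 2], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(position = integer(), triplet = character(),
                      hydroxyl = character(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Design a glycan sequon into a sequence
#'
#' Typical style sets position n to N and n+2 to T (an existing S or T at
#' n+2 is preserved); enhanced style additionally places an aromatic F at
#' n-2.  Idempotent.
#'
#' @param sequence one-letter amino-acid string.
#' @param n_position 1-based position that becomes the N.
#' @param style "typical" or "enhanced".
#' @param immutable optional integer positions that must not be mutated;
#'   touching one raises an error.
#' @return the mutated sequence.
#' @export
create_sequon <- function(sequence, n_position, style = c("typical", "enhanced"),
                          immutable = integer()) {
  style <- match.arg(style)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n_position < 1 || n_position + 2 > n)
    stop("sequon does not fit: positions ", n_position, "..", n_position + 2,
         " outside sequence of length ", n)
  if (style == "enhanced" && n_position - 2 < 1)
    stop("enhanced sequon needs position n-2, absent for n = ", n_position)
  edits <- list(c(n_position, "N"))
  if (!(chars[n_position + 2] %in% c("S", "T")))
    edits[[length(edits) + 1]] <- c(n_position + 2, "T")
  if (style == "enhanced")
    edits[[length(edits) + 1]] <- c(n_position - 2, "F")
  for (e in edits) {
    i <- as.integer(e[1])
    if (chars[i] != e[2] && i %in% immutable)
      stop("position ", i, " is immutable")
    chars[i] <- e[2]
  }
  out <- paste(chars, collapse = "")
  if (!any(scan_sequons(out)$position == n_position))
    stop("internal error: designed sequence fails its own sequon scan")
  out
}

# graft an Asn side chain (CB fixed, ideal CG/OD1/ND2) onto residue resno
pose_mutate_to_asn <- function(pose, chain, resno) {
  keep_atoms <- c("N", "CA", "C", "O", "CB")
  res_rows <- which(pose$atoms$chain == chain & pose$atoms$resno == resno)
  if (!length(res_rows)) stop("residue ", chain, "/", resno, " not in pose")
  drop <- res_rows[!(pose$atoms$atom[res_rows] %in% keep_atoms)]
  pose <- .drop_pose_rows(pose, drop)
  n <- pose$xyz[atom_row(pose, chain, resno, "N"), ]
  ca <- pose$xyz[atom_row(pose, chain, resno, "CA"), ]
  cb <- pose$xyz[atom_row(pose, chain, resno, "CB"), ]
  cg <- place_atom(n, ca, cb, 1.52, 114.0, 150)
  od1 <- place_atom(ca, cb, cg, 1.23, 120.8, -30)
  nd2 <- place_atom(ca, cb, cg, 1.33, 116.5, 150)
  add <- data.frame(chain = chain, resno = resno, resname = "ASN",
                    atom = c("CG", "OD1", "ND2"), element = c("C", "O", "N"),
                    role = "protein", tree = NA_integer_, node = NA_integer_,
                    stringsAsFactors = FALSE)
  pose$atoms$resname[pose$atoms$chain == chain & pose$atoms$resno == resno] <- "ASN"
  offset <- nrow(pose$atoms)
  pose$atoms <- rbind(pose$atoms, add)
  pose$xyz <- rbind(pose$xyz, rbind(cg, od1, nd2))
  if (!is.null(pose$bonds)) {
    cb_row <- atom_row(pose, chain, resno, "CB")
    pose <- add_pose_bonds(pose, rbind(c(cb_row, offset + 1L),
                                       c(offset + 1L, offset + 2L),
                                       c(offset + 1L, offset + 3L)))
  }
  pose
}

#' Attach a whole glycan to a protein residue
#'
#' Parses the condensed-IUPAC string, attaches the tree at the residue's
#' ND2, and builds it with torsions drawn from the conformer library
#' (conformer per linkage drawn weighted by mass, set at its modes).
#' Seeded calls are reproducible via \code{set.seed()}.
#'
#' @param pose a pose.
#' @param chain,resnum the attachment residue (must be Asn unless
#'   \code{force}).
#' @param iupac condensed-IUPAC glycan string.
#' @param library a \code{conformer_library}.
#' @param force attach to a non-Asn residue carrying an ND2 atom.
#' @return the glycosylated pose.
#' @export
glycosylate <- function(pose, chain, resnum, iupac, library, force = FALSE) {
  rows <- which(pose$atoms$chain == chain & pose$atoms$resno == resnum)
  if (!length(rows)) stop("residue ", chain, "/", resnum, " not in pose")
  resname <- pose$atoms$resname[rows[1]]
  if (resname != "ASN" && !force)
    stop("residue ", chain, "/", resnum, " is ", resname,
         ", not ASN (use force = TRUE to override)")
  tree <- parse_iupac(iupac, attachment = list(chain = chain, resno = resnum,
                                               atom = "ND2"))
  torsions <- list()
  for (id in tree$nodes$node_id) {
    cf <- library_linkage(library, linkage_key(tree, id))$conformers
    i <- if (nrow(cf) == 1) 1L else sample.int(nrow(cf), 1, prob = cf$mass)
    tl <- list(phi = cf$phi[i], psi = cf$psi[i])
    if ("omega" %in% names(cf)) tl$omega <- cf$omega[i]
    torsions[[as.character(id)]] <- tl
  }
  build_glycan(pose, tree, torsions)
}

#' Rank candidate glycosylation positions by modeled energy
#'
#' For each candidate position: graft an Asn, attach the glycan, run a small
#' decoy ensemble, and report the best decoy's total energy and steric
#' repulsion.  Rows are ranked ascending by energy, so well-accommodated
#' (low-energy, non-clashing) positions come first.
#'
#' @param scaffold protein pose.
#' @param positions data.frame with columns \code{chain}, \code{resno} (or
#'   an integer vector of residue numbers on chain "A").
#' @param iupac glycan to attach.
#' @param config a \code{modeler_config} (use a small \code{n_decoys}).
#' @param library a \code{conformer_library}.
#' @return data.frame: chain, resno, energy, steric_rep, n_decoys.
#' @export
position_report <- function(scaffold, positions, iupac, config, library) {
  if (is.numeric(positions))
    positions <- data.frame(chain = rep("A", length(positions)),
                            resno = as.integer(positions))
  if (!nrow(positions))
    return(data.frame(chain = character(), resno = integer(),
                      energy = numeric(), steric_rep = numeric(),
                      n_decoys = integer(), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(positions)), function(i) {
    ch <- positions$chain[i]; rn <- positions$resno[i]
    pose <- pose_mutate_to_asn(scaffold, ch, rn)
    set.seed(config$seed)
    pose <- glycosylate(pose, ch, rn, iupac, library)
    recs <- generate_ensemble(pose, config = config, library = library)
    best <- select_best(recs)
    data.frame(chain = ch, resno = rn, energy = best$energy$total,
               steric_rep = best$energy$rep, n_decoys = length(recs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$energy), , drop = FALSE]
}
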