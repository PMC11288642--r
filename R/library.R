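# Conformer libraries: per-linkage-type torsion KDEs plus extracted
# conformers, with a plain-text table format for exchange.
#
# A linkage key is "<child kind>-(1->x)-<parent kind>" (kinds carry their
# anomer, e.g. "a-D-Manp-(1->3)-b-D-Manp"); the protein root is
# "<child kind>-(1->ASN)".  Conformer sets are keyed by the chemically
# distinct saccharide pair; single-torsion sampling additionally uses pooled
# anomeric keys "<anomer>-(1->x)" that aggregate observations across all
# linkages sharing the anomeric chemistry.

#' Linkage-type key of a tree node
#'
#' @param tree a \code{glycan_tree}.
#' @param node node id.
#' @return character key, e.g. \code{"b-D-Manp-(1->4)-b-D-GlcpNAc"} or
#'   \code{"b-D-GlcpNAc-(1->ASN)"} for the protein root.
#' @export
linkage_key <- function(tree, node) {
  row <- tree$nodes[tree$nodes$node_id == node, ]
  if (nrow(row) != 1) stop("node ", node, " not in tree")
  if (is.na(row$parent_id)) return(paste0(row$kind, "-(1->ASN)"))
  parent <- tree$nodes[tree$nodes$node_id == row$parent_id, ]
  paste0(row$kind, "-(1->", row$parent_pos, ")-", parent$kind)
}

# "a-(1->3)"-style anomeric key from a full linkage key
anomeric_key <- function(key) {
  m <- regmatches(key, regexec("^([ab])-.*?-\\(1->(ASN|\\d)\\)", key))[[1]]
  if (length(m) == 0) return(NA_character_)
  paste0(m[2], "-(1->", m[3], ")")
}

linkage_has_omega <- function(key) grepl("-\\(1->6\\)-", key)

#' Build a conformer library from torsion observations
#'
#' Fits an adaptive von Mises KDE per (linkage key, torsion) and extracts
#' conformers for each linkage.  Pooled anomeric-chemistry KDEs are fitted as
#' well and back the sampler's single-torsion moves.
#'
#' @param observations data.frame with columns \code{linkage_key},
#'   \code{torsion} ("phi", "psi" or "omega") and \code{angle_deg}.
#' @param pilot_kappa,alpha KDE parameters, see [fit_adaptive_kde()].
#' @param min_mass conformer mass cutoff, see [extract_conformers()].
#' @return object of class \code{conformer_library}.
#' @export
build_conformer_library <- function(observations, pilot_kappa = NULL,
                                    alpha = 0.5, min_mass = 0.01) {
  stopifnot(all(c("linkage_key", "torsion", "angle_deg") %in% names(observations)))
  bad <- setdiff(unique(observations$torsion), c("phi", "psi", "omega"))
  if (length(bad)) stop("unknown torsion name(s): ", paste(bad, collapse = ", "))
  lib <- list(linkages = list(), anomeric = list(),
              params = list(pilot_kappa = pilot_kappa, alpha = alpha,
                            min_mass = min_mass))
  for (key in unique(observations$linkage_key)) {
    obs_k <- observations[observations$linkage_key == key, ]
    kdes <- list()
    for (t in intersect(c("phi", "psi", "omega"), unique(obs_k$torsion))) {
      kdes[[t]] <- fit_adaptive_kde(obs_k$angle_deg[obs_k$torsion == t],
                                    pilot_kappa, alpha)
    }
    if (is.null(kdes$phi) || is.null(kdes$psi))
      stop("linkage ", key, " needs both phi and psi observations")
    if (linkage_has_omega(key) && is.null(kdes$omega))
      stop("1->6 linkage ", key, " needs omega observations")
    if (!linkage_has_omega(key)) kdes$omega <- NULL
    lib$linkages[[key]] <- list(kdes = kdes,
                                conformers = extract_conformers(kdes, min_mass))
  }
  # pooled anomeric keys for single-torsion sampling
  observations$akey <- vapply(observations$linkage_key, anomeric_key, character(1))
  for (ak in unique(observations$akey)) {
    obs_a <- observations[observations$akey == ak, ]
    kdes <- list()
    for (t in unique(obs_a$torsion)) {
      kdes[[t]] <- fit_adaptive_kde(obs_a$angle_deg[obs_a$torsion == t],
                                    pilot_kappa, alpha)
    }
    lib$anomeric[[ak]] <- kdes
  }
  structure(lib, class = "conformer_library")
}

#' @export
print.conformer_library <- function(x, ...) {
  cat(sprintf("conformer_library: %d linkage type(s)\n", length(x$linkages)))
  for (key in names(x$linkages)) {
    cat(sprintf("  %-45s %d conformer(s)\n", key, nrow(x$linkages[[key]]$conformers)))
  }
  invisible(x)
}

library_linkage <- function(library, key) {
  lk <- library$linkages[[key]]
  if (is.null(lk)) stop("conformer library has no linkage type '", key, "'")
  lk
}

# KDE used for single-torsion proposals: pooled anomeric key when available
single_torsion_kde <- function(library, key, torsion) {
  ak <- anomeric_key(key)
  if (!is.na(ak) && !is.null(library$anomeric[[ak]][[torsion]]))
    return(library$anomeric[[ak]][[torsion]])
  library_linkage(library, key)$kdes[[torsion]]
}

.fmt <- function(x) sprintf("%.17g", x)

#' Write a conformer library as a text table
#'
#' One block per linkage: a header line, one TORSION row per torsion (name,
#' n, kappa0, alpha, then the 360 grid densities) and one CONFORMER row per
#' conformer (mass, then mode and basin sd per torsion).  write/read/write
#' is byte-identical.
#'
#' @param library a \code{conformer_library}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_conformer_table <- function(library, path) {
  lines <- character()
  for (key in names(library$linkages)) {
    lk <- library$linkages[[key]]
    tnames <- names(lk$kdes)
    lines <- c(lines, paste("LINKAGE", key, paste(tnames, collapse = " ")))
    for (t in tnames) {
      kde <- lk$kdes[[t]]
      lines <- c(lines, paste("TORSION", t, kde$n, .fmt(kde$kappa0),
                              .fmt(kde$alpha), paste(.fmt(kde$fgrid), collapse = " ")))
    }
    cf <- lk$conformers
    for (i in seq_len(nrow(cf))) {
      vals <- unlist(lapply(tnames, function(t) c(cf[i, t], cf[i, paste0(t, "_sd")])))
      lines <- c(lines, paste("CONFORMER", .fmt(cf$mass[i]),
                              paste(.fmt(vals), collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a conformer library from a text table
#'
#' The returned KDEs carry the grid densities only (no raw observations);
#' sampling from them uses grid inverse-CDF draws.
#'
#' @param path file written by [write_conformer_table()].
#' @return a \code{conformer_library}.
#' @export
read_conformer_table <- function(path) {
  lines <- readLines(path)
  lib <- list(linkages = list(), anomeric = list(), params = list())
  key <- NULL; tnames <- NULL; kdes <- NULL; conf_rows <- NULL
  flush_block <- function() {
    if (is.null(key)) return()
    for (t in tnames) {
      if (is.null(kdes[[t]]))
        stop("conformer table: linkage ", key, " is missing its ", t, " TORSION row")
    }
    cf <- if (length(conf_rows)) do.call(rbind, conf_rows) else NULL
    lib$linkages[[key]] <<- list(kdes = kdes, conformers = cf)
  }
  for (ln in seq_along(lines)) {
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (!length(parts) || !nzchar(parts[1])) next
    if (parts[1] == "LINKAGE") {
      flush_block()
      if (length(parts) < 3)
        stop("conformer table parse error at line ", ln, ": LINKAGE needs a key and torsion names")
      key <- parts[2]; tnames <- parts[-(1:2)]
      kdes <- list(); conf_rows <- list()
    } else if (parts[1] == "TORSION") {
      if (is.null(key)) stop("conformer table parse error at line ", ln,
                             ": TORSION before any LINKAGE")
      if (length(parts) != 5 + .KDE_GRID_P)
        stop("conformer table parse error at line ", ln,
             ": expected ", 5 + .KDE_GRID_P, " fields, got ", length(parts))
      t <- parts[2]
      fgrid <- as.numeric(parts[-(1:5)])
      if (anyNA(fgrid)) stop("conformer table parse error at line ", ln,
                             ": non-numeric density")
      kde <- structure(list(mu = NULL, kappa0 = as.numeric(parts[4]),
                            alpha = as.numeric(parts[5]),
                            kappa = NULL, n = as.integer(parts[3]),
                            grid = seq(-180, 179, length.out = .KDE_GRID_P),
                            fgrid = fgrid, fmax = max(fgrid),
                            egrid = -log(pmax(fgrid, .KDE_FLOOR) / max(fgrid))),
                       class = "torsion_kde")
      kdes[[t]] <- kde
    } else if (parts[1] == "CONFORMER") {
      if (is.null(key)) stop("conformer table parse error at line ", ln,
                             ": CONFORMER before any LINKAGE")
      if (length(parts) != 2 + 2 * length(tnames))
        stop("conformer table parse error at line ", ln, ": wrong field count")
      vals <- as.numeric(parts[-1])
      if (anyNA(vals)) stop("conformer table parse error at line ", ln,
                            ": non-numeric conformer value")
      row <- as.list(c(vals[seq(2, length(vals), by = 2)],
                       vals[seq(3, length(vals), by = 2)], vals[1]))
      names(row) <- c(tnames, paste0(tnames, "_sd"), "mass")
      conf_rows[[length(conf_rows) + 1]] <- as.data.frame(row)
    } else {
      stop("conformer table parse error at line ", ln,
           ": unknown record '", parts[1], "'")
    }
  }
  flush_block()
  # reorder conformer columns to the canonical layout and sort by mass
  for (key in names(lib$linkages)) {
    cf <- lib$linkages[[key]]$conformers
    if (!is.null(cf)) {
      tn <- names(lib$linkages[[key]]$kdes)
      lib$linkages[[key]]$conformers <-
        cf[, c(tn, paste0(tn, "_sd"), "mass"), drop = FALSE]
    }
  }
  structure(lib, class = "conformer_library")
}
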