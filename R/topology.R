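# Branched glycan tree topology: condensed-IUPAC parsing/serialization and
# layer decomposition.
#
# A tree is stored as a data.frame of nodes in topological order (parents
# before children) plus the protein attachment point.  Node ids are integers
# assigned root = 1 outward, but operations accept trees whose ids have been
# edited, so everything goes through explicit id lookup.

.SUGAR_NAMES <- c("Glcp", "GlcpNAc", "Manp", "Galp", "GalpNAc", "Fucp", "Xylp")
# v1 registry: common N-glycan residues; D-series except L-fucose.
.SUGAR_SERIES <- c(Glcp = "D", GlcpNAc = "D", Manp = "D", Galp = "D",
                   GalpNAc = "D", Fucp = "L", Xylp = "D")

#' Supported sugar residue tokens
#'
#' @return character vector of all residue tokens the package recognizes,
#'   e.g. \code{"b-D-GlcpNAc"}.
#' @export
sugar_alphabet <- function() {
  unlist(lapply(.SUGAR_NAMES, function(nm) {
    paste0(c("a", "b"), "-", .SUGAR_SERIES[[nm]], "-", nm)
  }), use.names = FALSE)
}

parse_residue_token <- function(tok) {
  m <- regmatches(tok, regexec("^([ab])-([DL])-([A-Za-z]+)$", tok))[[1]]
  if (length(m) == 0)
    stop(sprintf("unsupported residue token '%s'", tok))
  anomer <- m[2]; series <- m[3]; name <- m[4]
  if (!(name %in% .SUGAR_NAMES))
    stop(sprintf("unsupported residue token '%s' (unknown sugar '%s')", tok, name))
  if (.SUGAR_SERIES[[name]] != series)
    stop(sprintf("unsupported residue token '%s' (%s is %s-series in this registry)",
                 tok, name, .SUGAR_SERIES[[name]]))
  list(kind = tok, anomer = anomer, series = series, name = name)
}

#' Construct a glycan tree from a node table
#'
#' Low-level constructor; most users will call [parse_iupac()].
#'
#' @param nodes data.frame with columns \code{node_id}, \code{kind},
#'   \code{anomer}, \code{parent_id} (NA for the root), \code{parent_pos}
#'   (ring position on the parent accepting the bond; NA for the root),
#'   \code{child_pos} (anomeric position on the child; 1 in this version).
#' @param attachment list with \code{chain}, \code{resno}, \code{atom}
#'   naming the protein attachment (e.g. ND2 of an Asn), or NULL.
#' @return object of class \code{glycan_tree}.
#' @export
glycan_tree <- function(nodes, attachment = NULL) {
  stopifnot(is.data.frame(nodes))
  need <- c("node_id", "kind", "anomer", "parent_id", "parent_pos", "child_pos")
  missing_cols <- setdiff(need, names(nodes))
  if (length(missing_cols))
    stop("nodes is missing columns: ", paste(missing_cols, collapse = ", "))
  tr <- structure(list(nodes = nodes, attachment = attachment),
                  class = "glycan_tree")
  tr
}

#' @export
print.glycan_tree <- function(x, ...) {
  cat(sprintf("glycan_tree with %d residue(s)\n", nrow(x$nodes)))
  cat("  ", to_iupac(x), "\n", sep = "")
  if (!is.null(x$attachment))
    cat(sprintf("  attached at %s/%d/%s\n", x$attachment$chain,
                x$attachment$resno, x$attachment$atom))
  invisible(x)
}

n_nodes <- function(tree) nrow(tree$nodes)

tree_root_id <- function(tree) tree$nodes$node_id[is.na(tree$nodes$parent_id)]

tree_children <- function(tree, id) {
  kids <- tree$nodes[!is.na(tree$nodes$parent_id) & tree$nodes$parent_id == id, ]
  kids[order(kids$parent_pos), , drop = FALSE]
}

# --- condensed-IUPAC parsing -------------------------------------------------

tokenize_iupac <- function(text) {
  tokens <- list()
  s <- text
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    if (startsWith(rest, "[")) {
      tokens[[length(tokens) + 1L]] <- list(type = "LB")
      pos <- pos + 1L
    } else if (startsWith(rest, "]")) {
      tokens[[length(tokens) + 1L]] <- list(type = "RB")
      pos <- pos + 1L
      # a joining dash follows when the bracket precedes its parent residue
      if (substr(text, pos, pos) == "-" && substr(text, pos + 1, pos + 1) != "(")
        pos <- pos + 1L
    } else {
      # the trailing dash is absent when the linkage closes a branch bracket
      m <- regexpr("^-\\((\\d)->(\\d)\\)(-|(?=\\]))", rest, perl = TRUE)
      if (m == 1) {
        len <- attr(m, "match.length")
        lk <- substr(rest, 1, len)
        nums <- regmatches(lk, regexec("-\\((\\d)->(\\d)\\)", lk))[[1]]
        tokens[[length(tokens) + 1L]] <-
          list(type = "LINK", from = as.integer(nums[2]), to = as.integer(nums[3]))
        pos <- pos + len
      } else {
        m2 <- regexpr("^[A-Za-z-]+?(?=(-\\(|\\[|\\]|$))", rest, perl = TRUE)
        if (m2 != 1)
          stop(sprintf("malformed glycan string near position %d: '%s'", pos, rest))
        len <- attr(m2, "match.length")
        tok <- substr(rest, 1, len)
        tokens[[length(tokens) + 1L]] <- list(type = "RES", token = tok)
        pos <- pos + len
      }
    }
  }
  tokens
}

#' Parse a condensed-IUPAC glycan string
#'
#' Dialect: residue tokens with explicit anomer and ring form
#' (\code{"b-D-GlcpNAc"}), linkages written \code{"-(1->4)-"}, branches in
#' square brackets with their linkage inside the bracket, and the reducing
#' end (root, the residue attached to the protein) rightmost.  Example of the
#' Man3 N-glycan core:
#' \code{"a-D-Manp-(1->3)-[a-D-Manp-(1->6)]-b-D-Manp-(1->4)-b-D-GlcpNAc-(1->4)-b-D-GlcpNAc"}.
#'
#' @param text glycan string.
#' @param attachment optional attachment descriptor passed to [glycan_tree()].
#' @return a \code{glycan_tree}; node ids are assigned in breadth-first order
#'   from the root (root id 1) with siblings ordered by ascending
#'   \code{parent_pos}.
#' @export
parse_iupac <- function(text, attachment = NULL) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text))
    stop("parse error: empty or non-string glycan input")
  tokens <- tokenize_iupac(text)

  # Recursive right-to-left parse.  A sequence is item* RES where
  # item := chain LINK  (main-chain continuation, leftmost, at most one)
  #       | "[" chain LINK "]"   (branch).
  # Returns a nested list: list(res = <parsed residue>, children = list of
  # list(link_to = parent position, sub = subtree)).
  parse_seq <- function(toks) {
    nt <- length(toks)
    if (nt == 0) stop("parse error: empty residue group")
    last <- toks[[nt]]
    if (last$type != "RES")
      stop("parse error: expected a residue token at a chain's reducing end")
    node <- list(res = parse_residue_token(last$token), children = list())
    k <- nt - 1L
    seen_main <- FALSE
    while (k >= 1L) {
      tk <- toks[[k]]
      if (tk$type == "RB") {
        depth <- 1L
        m <- k - 1L
        while (m >= 1L && depth > 0L) {
          if (toks[[m]]$type == "RB") depth <- depth + 1L
          if (toks[[m]]$type == "LB") depth <- depth - 1L
          if (depth > 0L) m <- m - 1L
        }
        if (depth != 0L) stop("parse error: unbalanced ']'")
        inner <- toks[seq.int(m + 1L, k - 1L)]
        ni <- length(inner)
        if (ni < 2L || inner[[ni]]$type != "LINK")
          stop("parse error: branch bracket must end with a linkage")
        lk <- inner[[ni]]
        sub <- parse_seq(inner[seq_len(ni - 1L)])
        node$children[[length(node$children) + 1L]] <-
          list(link_from = lk$from, link_to = lk$to, sub = sub)
        k <- m - 1L
      } else if (tk$type == "LINK") {
        if (seen_main) stop("parse error: two unbracketed chains join one residue")
        seen_main <- TRUE
        if (k == 1L) stop("parse error: linkage with no residue on its left")
        sub <- parse_seq(toks[seq_len(k - 1L)])
        node$children[[length(node$children) + 1L]] <-
          list(link_from = tk$from, link_to = tk$to, sub = sub)
        k <- 0L
      } else if (tk$type == "LB") {
        stop("parse error: unbalanced '['")
      } else {
        stop(sprintf("parse error: unexpected residue token '%s' (missing linkage?)",
                     tk$token))
      }
    }
    node
  }

  ast <- parse_seq(tokens)

  # Flatten breadth-first, siblings by ascending parent position.
  rows <- list()
  next_id <- 1L
  queue <- list(list(ast = ast, parent_id = NA_integer_,
                     parent_pos = NA_integer_, child_pos = NA_integer_))
  while (length(queue)) {
    item <- queue[[1]]; queue <- queue[-1]
    id <- next_id; next_id <- next_id + 1L
    rows[[id]] <- data.frame(
      node_id = id, kind = item$ast$res$kind, anomer = item$ast$res$anomer,
      parent_id = item$parent_id, parent_pos = item$parent_pos,
      child_pos = item$child_pos, stringsAsFactors = FALSE)
    kids <- item$ast$children
    if (length(kids)) {
      pos <- vapply(kids, function(k) k$link_to, numeric(1))
      if (anyDuplicated(pos)) {
        dup <- pos[duplicated(pos)][1]
        stop(sprintf("parse error: duplicate linkage position %d on residue '%s'",
                     dup, item$ast$res$kind))
      }
      for (k in kids[order(pos)]) {
        if (k$link_from != 1L)
          stop(sprintf("parse error: only anomeric position 1 linkages supported, got %d",
                       k$link_from))
        queue[[length(queue) + 1L]] <-
          list(ast = k$sub, parent_id = id,
               parent_pos = as.integer(k$link_to), child_pos = 1L)
      }
    }
  }
  nodes <- do.call(rbind, rows)
  tr <- glycan_tree(nodes, attachment = attachment)
  viol <- validate_tree(tr)
  if (length(viol))
    stop("parse error: ", paste(viol, collapse = "; "))
  tr
}

#' Serialize a glycan tree to its condensed-IUPAC string
#'
#' Branch order is canonicalized by ascending parent position, so the output
#' is deterministic and \code{parse_iupac(to_iupac(t))} is isomorphic to
#' \code{t}.
#'
#' @param tree a \code{glycan_tree}.
#' @return character scalar.
#' @export
to_iupac <- function(tree) {
  emit <- function(id) {
    row <- tree$nodes[tree$nodes$node_id == id, ]
    kids <- tree_children(tree, id)
    out <- ""
    if (nrow(kids)) {
      main <- kids[1, ]
      out <- paste0(emit(main$node_id),
                    sprintf("-(%d->%d)-", main$child_pos, main$parent_pos))
      if (nrow(kids) > 1) {
        for (i in seq.int(2, nrow(kids))) {
          b <- kids[i, ]
          out <- paste0(out, "[", emit(b$node_id),
                        sprintf("-(%d->%d)", b$child_pos, b$parent_pos), "]")
        }
        out <- paste0(out, "-")
      }
    }
    paste0(out, row$kind)
  }
  emit(tree_root_id(tree))
}

#' Layer index of every node
#'
#' The layer of a residue is its graph distance to the root (the reducing-end
#' residue attached to the protein); the root has layer 0.  Layers are the
#' unit of the layer-by-layer build schedule.
#'
#' @param tree a \code{glycan_tree}.
#' @return named integer vector, names are node ids.
#' @export
glycan_layers <- function(tree) {
  ids <- tree$nodes$node_id
  layer <- setNames(rep(NA_integer_, length(ids)), ids)
  root <- tree_root_id(tree)
  layer[as.character(root)] <- 0L
  queue <- root
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    kids <- tree_children(tree, id)$node_id
    if (length(kids)) {
      layer[as.character(kids)] <- layer[as.character(id)] + 1L
      queue <- c(queue, kids)
    }
  }
  layer
}

#' Node ids with layer at most k
#'
#' @param tree a \code{glycan_tree}.
#' @param k layer cutoff (root is layer 0).
#' @return integer vector of node ids, sorted.
#' @export
nodes_through_layer <- function(tree, k) {
  stopifnot(k >= 0)
  ly <- glycan_layers(tree)
  sort(as.integer(names(ly)[ly <= k]))
}

max_layer <- function(tree) max(glycan_layers(tree))

#' Validate a glycan tree
#'
#' Checks the structural invariants (single root, acyclic and connected,
#' unique linkage positions per parent, supported residue kinds) and returns
#' the violations instead of raising.
#'
#' @param tree a \code{glycan_tree}.
#' @return character vector of violation descriptions; empty when valid.
#' @export
validate_tree <- function(tree) {
  v <- character()
  nd <- tree$nodes
  if (anyDuplicated(nd$node_id))
    v <- c(v, "duplicate node ids")
  roots <- nd$node_id[is.na(nd$parent_id)]
  if (length(roots) != 1)
    v <- c(v, sprintf("expected exactly one root, found %d", length(roots)))
  bad_kind <- setdiff(nd$kind, sugar_alphabet())
  if (length(bad_kind))
    v <- c(v, paste0("unsupported residue kind(s): ",
                     paste(bad_kind, collapse = ", ")))
  nonroot <- nd[!is.na(nd$parent_id), , drop = FALSE]
  if (nrow(nonroot)) {
    orphan <- setdiff(nonroot$parent_id, nd$node_id)
    if (length(orphan))
      v <- c(v, paste0("parent id(s) not in tree: ", paste(orphan, collapse = ", ")))
    key <- paste(nonroot$parent_id, nonroot$parent_pos)
    if (anyDuplicated(key)) {
      d <- nonroot[duplicated(key), , drop = FALSE][1, ]
      v <- c(v, sprintf("two children of node %d share linkage position %d",
                        d$parent_id, d$parent_pos))
    }
    bad_pos <- nonroot$parent_pos[!(nonroot$parent_pos %in% 2:6)]
    if (length(bad_pos))
      v <- c(v, paste0("linkage position(s) outside 2..6: ",
                       paste(unique(bad_pos), collapse = ", ")))
  }
  # reachability: every node must reach the root by following parents without
  # revisiting (catches cycles introduced by editing parent_id)
  if (length(roots) == 1) {
    for (id in nd$node_id) {
      seen <- integer()
      cur <- id
      ok <- FALSE
      while (TRUE) {
        if (cur %in% seen) break
        seen <- c(seen, cur)
        row <- nd[nd$node_id == cur, , drop = FALSE]
        if (nrow(row) != 1) break
        if (is.na(row$parent_id)) { ok <- TRUE; break }
        cur <- row$parent_id
      }
      if (!ok) {
        v <- c(v, sprintf("node %d does not reach the root (cycle or orphan)", id))
        break
      }
    }
  }
  v
}

# All node ids of the subtree rooted at `id` (inclusive).
subtree_ids <- function(tree, id) {
  out <- integer()
  queue <- id
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    out <- c(out, cur)
    queue <- c(queue, tree_children(tree, cur)$node_id)
  }
  out
}

#' Dump a glycan tree as JSON
#'
#' Debugging aid: nodes plus attachment in a machine-readable form.
#'
#' @param tree a \code{glycan_tree}.
#' @return JSON string.
#' @export
tree_to_json <- function(tree) {
  jsonlite::toJSON(list(nodes = tree$nodes, attachment = tree$attachment),
                   auto_unbox = TRUE, digits = NA)
}
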