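# The tree modeler protocol: randomize, then build and optimize the glycan
# layer by layer from the root outward, optimize cumulatively after every
# new layer, and finish with a final optimization of the whole tree.  The
# lowest-energy pose found during the final full-tree optimization is the
# decoy; the lowest-energy decoy of an ensemble is the model.
#
# Unbuilt (distal) residues are present in the pose but masked from every
# energy term until their build event; masking rather than deletion keeps
# the kinematics bookkeeping trivial.

#' Modeler configuration
#'
#' @param layer_window how many layers each build block spans (1 = classic
#'   layer-by-layer; larger windows reproduce the hybrid kinematic variants;
#'   \code{Inf} collapses to a single sampler-only pass).
#' @param rounds_per_residue Monte Carlo cycles per residue per optimize
#'   event (the linear budget).
#' @param n_decoys ensemble size.
#' @param mode "de_novo" (randomize then build), "refine" (optimize the
#'   input conformation as-is) or "density" (de novo plus the density term).
#' @param seed base RNG seed; decoy i uses \code{seed + i}.
#' @param spec a \code{move_spec}.
#' @param weights an \code{energy_weights}.
#' @return object of class \code{modeler_config}.
#' @export
modeler_config <- function(layer_window = 1, rounds_per_residue = 15,
                           n_decoys = 20, mode = c("de_novo", "refine", "density"),
                           seed = 1, spec = move_spec(),
                           weights = energy_weights()) {
  mode <- match.arg(mode)
  stopifnot(layer_window >= 1, n_decoys >= 1, rounds_per_residue >= 0)
  structure(list(layer_window = layer_window,
                 rounds_per_residue = rounds_per_residue,
                 n_decoys = n_decoys, mode = mode, seed = seed,
                 spec = spec, weights = weights),
            class = "modeler_config")
}

#' Build/optimize event schedule for a tree
#'
#' For each window of layers (root outward): build the block, optimize the
#' block, then optimize everything built so far.  A final optimization of
#' the whole tree closes the schedule.
#'
#' @param tree a \code{glycan_tree}.
#' @param layer_window layers per build block.
#' @return list of events, each \code{list(type = "build"|"optimize",
#'   nodes = <ids>)}.
#' @export
schedule <- function(tree, layer_window = 1) {
  stopifnot(layer_window >= 1)
  ly <- glycan_layers(tree)
  lmax <- max(ly)
  events <- list()
  built <- integer()
  start <- 0
  while (start <= lmax) {
    top <- min(start + layer_window - 1, lmax)
    block <- sort(as.integer(names(ly)[ly >= start & ly <= top]))
    built <- sort(c(built, block))
    events[[length(events) + 1]] <- list(type = "build", nodes = block)
    events[[length(events) + 1]] <- list(type = "optimize", nodes = block)
    events[[length(events) + 1]] <- list(type = "optimize", nodes = built)
    start <- top + 1
  }
  events[[length(events) + 1]] <- list(type = "optimize",
                                       nodes = sort(as.integer(names(ly))))
  events
}

#' Model one decoy
#'
#' In de novo (and density) mode: the glycan is placed, all backbone
#' torsions are randomized, distal layers are masked from scoring, and the
#' schedule is followed, unmasking each block at its build event; every
#' optimize event runs the sampler on its node set with the linear budget
#' (scoring over all built residues).  The returned pose is the
#' lowest-energy pose found during the closing full-tree optimization.
#' Refine mode skips randomization and masking and runs the final
#' optimization only.
#'
#' @param scaffold pose with the attachment residue; if the tree is already
#'   registered on it (e.g. read from PDB or built by [glycosylate()]) the
#'   existing conformation is the starting point, otherwise the tree is
#'   built at its top conformer modes first.
#' @param tree a \code{glycan_tree} (ignored when already registered).
#' @param config a \code{modeler_config}.
#' @param library a \code{conformer_library}.
#' @param map optional \code{density_map} (required for mode "density").
#' @param native optional native pose for on-the-fly RMSD metrics.
#' @param decoy_id id stored on the record.
#' @param seed RNG seed for this decoy (default: \code{config$seed}).
#' @return list: \code{pose} and \code{record} (the decoy record).
#' @export
model_one_decoy <- function(scaffold, tree = NULL, config, library,
                            map = NULL, native = NULL, decoy_id = 1L,
                            seed = NULL) {
  if (config$mode == "density" && is.null(map))
    stop("density mode requires a density map")
  use_map <- if (config$mode == "density") map else NULL
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)

  if (length(scaffold$trees)) {
    pose <- scaffold
    ti <- length(pose$trees)
    tr <- pose$trees[[ti]]
  } else {
    if (is.null(tree)) stop("no tree registered on the scaffold and none given")
    torsions <- .top_conformer_torsions(tree, library)
    pose <- build_glycan(scaffold, tree, torsions)
    ti <- length(pose$trees)
    tr <- pose$trees[[ti]]
  }
  all_nodes <- sort(tr$nodes$node_id)
  ctx <- make_energy_context(pose)

  if (config$mode == "refine") {
    st <- run_sampler(pose, ti, all_nodes, config$weights, library,
                      config$rounds_per_residue, config$spec, use_map, ctx)
    best_pose <- st$best_pose
  } else {
    pose <- randomize_backbone(pose, ti, all_nodes)
    ev <- schedule(tr, min(config$layer_window, max_layer(tr) + 1))
    built <- integer()
    final_state <- NULL
    for (k in seq_along(ev)) {
      e <- ev[[k]]
      if (e$type == "build") {
        built <- sort(union(built, e$nodes))
      } else {
        st <- run_sampler(pose, ti, e$nodes, config$weights, library,
                          config$rounds_per_residue, config$spec, use_map,
                          ctx, score_nodes = built)
        pose <- st$pose
        if (k == length(ev)) final_state <- st
      }
    }
    best_pose <- final_state$best_pose
  }

  energy <- total_energy(best_pose, ti, config$weights, library, all_nodes,
                         use_map, ctx)
  torsions <- lapply(all_nodes, function(id) measure_torsions(best_pose, ti, id))
  names(torsions) <- as.character(all_nodes)
  metrics <- NULL
  if (!is.null(native)) {
    metrics <- list(rmsd_fixed = rmsd_fixed_frame(best_pose, native, ti),
                    rmsd_super = rmsd_superimposed(best_pose, native, ti),
                    root_rmsd = root_rmsd(best_pose, native, ti))
  }
  record <- list(id = decoy_id, seed = seed, energy = energy,
                 torsions = torsions, metrics = metrics, pose = best_pose)
  list(pose = best_pose, record = record)
}

# torsions at each linkage's highest-mass conformer modes
.top_conformer_torsions <- function(tree, library) {
  out <- list()
  for (id in tree$nodes$node_id) {
    cf <- library_linkage(library, linkage_key(tree, id))$conformers[1, ]
    tl <- list(phi = cf$phi, psi = cf$psi)
    if ("omega" %in% names(cf) && !is.na(cf$omega)) tl$omega <- cf$omega
    out[[as.character(id)]] <- tl
  }
  out
}

#' Generate a decoy ensemble
#'
#' Decoy i runs with seed \code{config$seed + i}; records are returned
#' sorted by total energy ascending, ties broken by decoy id.
#'
#' @inheritParams model_one_decoy
#' @return list of decoy records (each with its pose attached).
#' @export
generate_ensemble <- function(scaffold, tree = NULL, config, library,
                              map = NULL, native = NULL) {
  records <- vector("list", config$n_decoys)
  for (i in seq_len(config$n_decoys)) {
    records[[i]] <- model_one_decoy(scaffold, tree, config, library, map,
                                    native, decoy_id = i,
                                    seed = config$seed + i)$record
  }
  tot <- vapply(records, function(r) r$energy$total, numeric(1))
  ids <- vapply(records, function(r) r$id, numeric(1))
  records[order(tot, ids)]
}

#' Select the best decoy
#'
#' Lowest total energy; on ties, the record that comes first in the list.
#'
#' @param records list of decoy records.
#' @return one decoy record.
#' @export
select_best <- function(records) {
  if (!length(records)) stop("no decoy records")
  tot <- vapply(records, function(r) r$energy$total, numeric(1))
  records[[which.min(tot)]]
}
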