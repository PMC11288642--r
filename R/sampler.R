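# The weighted random sampler: each Monte Carlo cycle draws one move kind
# with a configured probability, proposes a change to the glycan degrees of
# freedom, and accepts or rejects by the Metropolis criterion.  The total
# sampling budget is rounds_per_residue x (number of residues being
# optimized), so effort scales linearly with glycan size.

#' Move specification
#'
#' @param conformer probability of the whole-linkage conformer move.
#' @param kde_torsion probability of the single-torsion KDE draw.
#' @param local_refine probability of the deterministic torsion grid refine.
#' @param exocyclic_chi probability of the hydroxyl/hydroxymethyl rotamer move.
#' @return object of class \code{move_spec}.
#' @export
move_spec <- function(conformer = 0.30, kde_torsion = 0.30,
                      local_refine = 0.20, exocyclic_chi = 0.20) {
  p <- c(conformer = conformer, kde_torsion = kde_torsion,
         local_refine = local_refine, exocyclic_chi = exocyclic_chi)
  if (any(p < 0)) stop("move probabilities must be >= 0")
  if (abs(sum(p) - 1) > 1e-9) stop("move probabilities must sum to 1")
  structure(as.list(p), class = "move_spec")
}

#' Draw a move kind from a move spec
#'
#' @param spec a \code{move_spec}.
#' @return one of "conformer", "kde_torsion", "local_refine", "exocyclic_chi".
#' @export
choose_move <- function(spec) {
  p <- unlist(spec)
  sample(names(p), 1, prob = p)
}

#' Metropolis acceptance
#'
#' Accepts every downhill proposal; uphill proposals are accepted with
#' probability \eqn{\exp(-\Delta E / kT)}.
#'
#' @param dE energy change of the proposal.
#' @param kT Metropolis temperature (> 0).
#' @return logical.
#' @export
metropolis <- function(dE, kT) {
  stopifnot(kT > 0)
  if (!is.finite(dE)) return(dE < 0)
  if (dE <= 0) return(TRUE)
  stats::runif(1) < exp(-dE / kT)
}

# clipped Gaussian jitter used by the conformer move
.jitter <- function(sd) {
  if (sd <= 0) return(0)
  max(-2 * sd, min(2 * sd, stats::rnorm(1, 0, sd)))
}

#' Propose one move
#'
#' \itemize{
#' \item \code{conformer}: uniform node, conformer drawn weighted by mass,
#'   all its torsions set to the modes plus Gaussian jitter with sd equal to
#'   the basin sd (clipped at two sd).
#' \item \code{kde_torsion}: uniform (node, torsion), one angle drawn from
#'   the single-torsion KDE (pooled by anomeric chemistry when available);
#'   the proposed pose carries a \code{log_q_ratio} attribute so the sampler
#'   applies the Metropolis-Hastings correction for this independence
#'   proposal.
#' \item \code{local_refine}: uniform node; each torsion in turn is grid
#'   searched over +/-15 degrees in 3-degree steps and set to the argmin of
#'   the total energy (deterministic given the node).
#' \item \code{exocyclic_chi}: uniform rotatable position, chi set to one of
#'   -60/60/180 plus Gaussian jitter with sd 10 degrees.
#' }
#'
#' @param pose current pose.
#' @param kind move kind from [choose_move()].
#' @param tree tree index.
#' @param nodes node ids available to the sampler.
#' @param library a \code{conformer_library}.
#' @param weights an \code{energy_weights} (used by \code{local_refine}).
#' @param map optional density map (scored by \code{local_refine}).
#' @param ctx energy context.
#' @param score_nodes node ids included in energy evaluations (defaults to
#'   \code{nodes}); during layered building this is the full built set while
#'   \code{nodes} may be just the newest layer.
#' @return the proposed pose.
#' @export
apply_move <- function(pose, kind, tree = 1L, nodes, library, weights = NULL,
                       map = NULL, ctx = NULL, score_nodes = nodes) {
  stopifnot(length(nodes) >= 1)
  kc <- if (!is.null(ctx) && length(ctx$kin) >= tree) ctx$kin[[tree]] else NULL
  node_key <- function(id) {
    if (!is.null(kc)) kc[[as.character(id)]]$key
    else linkage_key(pose$trees[[tree]], id)
  }
  set_fast <- function(pose, id, tors) {
    if (!is.null(kc)) .set_torsions_fast(pose, kc[[as.character(id)]], tors)
    else set_torsions(pose, tree, id, tors)
  }
  if (kind == "conformer") {
    id <- if (length(nodes) == 1) nodes else sample(nodes, 1)
    cf <- library_linkage(library, node_key(id))$conformers
    i <- if (nrow(cf) == 1) 1L else sample.int(nrow(cf), 1, prob = cf$mass)
    tors <- list()
    for (t in intersect(c("phi", "psi", "omega"), names(cf))) {
      tors[[t]] <- wrap_angle(cf[i, t] + .jitter(cf[i, paste0(t, "_sd")]))
    }
    set_fast(pose, id, tors)
  } else if (kind == "kde_torsion") {
    id <- if (length(nodes) == 1) nodes else sample(nodes, 1)
    key <- node_key(id)
    tnames <- names(library_linkage(library, key)$kdes)
    t <- if (length(tnames) == 1) tnames else sample(tnames, 1)
    kde <- single_torsion_kde(library, key, t)
    old <- measure_torsions(pose, tree, id)[[t]]
    tors <- list()
    tors[[t]] <- kde_sample(kde, 1)
    prop <- set_fast(pose, id, tors)
    # independence proposal: carry the Hastings log-ratio so acceptance is
    # corrected for the draw bias (stationary law = the Boltzmann target)
    q <- pmax(kde_density(kde, c(tors[[t]], old), use_grid = TRUE), .KDE_FLOOR)
    attr(prop, "log_q_ratio") <- log(q[1]) - log(q[2])
    prop
  } else if (kind == "local_refine") {
    id <- if (length(nodes) == 1) nodes else sample(nodes, 1)
    if (is.null(weights)) weights <- energy_weights()
    if (is.null(ctx)) ctx <- make_energy_context(pose)
    tnames <- names(library_linkage(library, node_key(id))$kdes)
    offsets <- seq(-15, 15, by = 3)
    for (t in tnames) {
      cur <- measure_torsions(pose, tree, id)[[t]]
      best_pose <- pose
      best_e <- Inf
      for (off in offsets) {
        cand <- pose
        if (off != 0) {
          tl <- list(); tl[[t]] <- wrap_angle(cur + off)
          cand <- set_fast(pose, id, tl)
        }
        e <- total_energy(cand, tree, weights, library, score_nodes, map, ctx)$total
        if (e < best_e - 1e-12) { best_e <- e; best_pose <- cand }
      }
      pose <- best_pose
    }
    pose
  } else if (kind == "exocyclic_chi") {
    chis <- list()
    for (id in nodes) {
      xs <- if (!is.null(kc)) kc[[as.character(id)]]$chis
            else rotatable_chis(pose, tree, id)
      for (x in xs) chis[[length(chis) + 1]] <- c(id, x)
    }
    if (!length(chis)) return(pose)
    pick <- chis[[if (length(chis) == 1) 1L else sample.int(length(chis), 1)]]
    base <- sample(c(-60, 60, 180), 1)
    set_exocyclic_chi(pose, tree, pick[1], pick[2],
                      wrap_angle(base + stats::rnorm(1, 0, 10)))
  } else {
    stop("unknown move kind '", kind, "'")
  }
}

#' Run the Monte Carlo sampler
#'
#' Executes exactly \code{rounds_per_residue * length(nodes)} cycles of
#' choose-move / apply / Metropolis, tracking the best (lowest-energy) pose
#' seen.  Randomness comes from R's global RNG; seed with \code{set.seed()}.
#'
#' @param pose starting pose.
#' @param tree tree index.
#' @param nodes node ids to sample (the unmasked, built residues).
#' @param weights an \code{energy_weights}.
#' @param library a \code{conformer_library}.
#' @param rounds_per_residue sampling budget per residue.
#' @param spec a \code{move_spec}.
#' @param map optional \code{density_map}.
#' @param ctx optional precomputed energy context.
#' @param trace if TRUE, keep a per-cycle data.frame (cycle, move, dE,
#'   accepted).
#' @param score_nodes node ids included in energy evaluations (defaults to
#'   \code{nodes}).
#' @return list (class \code{sampler_state}): \code{pose}, \code{energy},
#'   \code{best_pose}, \code{best_energy}, \code{cycles}, \code{trace}.
#' @export
run_sampler <- function(pose, tree = 1L, nodes, weights, library,
                        rounds_per_residue, spec = move_spec(), map = NULL,
                        ctx = NULL, trace = FALSE, score_nodes = nodes) {
  if (is.null(ctx)) ctx <- make_energy_context(pose)
  n_cycles <- as.integer(round(rounds_per_residue * length(nodes)))
  cur_e <- total_energy(pose, tree, weights, library, score_nodes, map, ctx)$total
  best_pose <- pose
  best_e <- cur_e
  tr_rows <- if (trace) vector("list", n_cycles) else NULL
  if (n_cycles > 0) {
    for (cyc in seq_len(n_cycles)) {
      kind <- choose_move(spec)
      prop <- apply_move(pose, kind, tree, nodes, library, weights, map, ctx,
                         score_nodes)
      e_new <- total_energy(prop, tree, weights, library, score_nodes, map, ctx)$total
      dE <- e_new - cur_e
      lqr <- attr(prop, "log_q_ratio")
      dE_eff <- if (is.null(lqr)) dE else dE + weights$kT_mc * lqr
      attr(prop, "log_q_ratio") <- NULL
      acc <- metropolis(dE_eff, weights$kT_mc)
      if (acc) {
        pose <- prop
        cur_e <- e_new
        if (cur_e < best_e) { best_e <- cur_e; best_pose <- pose }
      }
      if (trace)
        tr_rows[[cyc]] <- data.frame(cycle = cyc, move = kind, dE = dE,
                                     accepted = acc)
    }
  }
  structure(list(pose = pose, energy = cur_e, best_pose = best_pose,
                 best_energy = best_e, cycles = n_cycles,
                 trace = if (trace) do.call(rbind, tr_rows) else NULL),
            class = "sampler_state")
}
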