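test_that("move spec validates and choose_move follows its weights", {
  expect_error(move_spec(conformer = -0.1, kde_torsion = 0.5,
                         local_refine = 0.3, exocyclic_chi = 0.3), ">= 0")
  expect_error(move_spec(conformer = 0.5, kde_torsion = 0.5,
                         local_refine = 0.5, exocyclic_chi = 0), "sum to 1")
  deg <- move_spec(1, 0, 0, 0)
  set.seed(71)
  expect_true(all(replicate(50, choose_move(deg)) == "conformer"))
  sp <- move_spec(0.4, 0.3, 0.2, 0.1)
  set.seed(72)
  draws <- replicate(20000, choose_move(sp))
  counts <- table(factor(draws, levels = names(unlist(sp))))
  chi <- stats::chisq.test(counts, p = unlist(sp))
  expect_gt(chi$p.value, 0.01)
})

test_that("metropolis accepts downhill always and uphill at the right rate", {
  expect_true(metropolis(-1, 1))
  expect_true(metropolis(0, 1))
  expect_false(metropolis(Inf, 1))
  set.seed(73)
  acc <- mean(replicate(1e4, metropolis(2, 0.5)))
  expect_lt(abs(acc - exp(-4)), 0.01)
})

test_that("conformer move with zero jitter lands exactly on the modes", {
  lib <- test_library()
  ref <- test_reference()
  ctx <- make_energy_context(ref$pose)
  set.seed(74)
  p <- randomize_backbone(ref$pose, 1)
  # zero out basin sds so the jitter vanishes; single-conformer linkage (root)
  lib0 <- lib
  key <- linkage_key(ref$tree, 1)
  cf <- lib0$linkages[[key]]$conformers
  cf$phi_sd <- 0; cf$psi_sd <- 0
  lib0$linkages[[key]]$conformers <- cf[1, , drop = FALSE]
  prop <- apply_move(p, "conformer", 1, nodes = 1, library = lib0, ctx = ctx)
  m <- measure_torsions(prop, 1, 1)
  expect_equal(m$phi, cf$phi[1], tolerance = 1e-6)
  expect_equal(m$psi, cf$psi[1], tolerance = 1e-6)
})

test_that("local refine never increases the scored energy", {
  lib <- test_library()
  ref <- test_reference()
  w <- energy_weights()
  ctx <- make_energy_context(ref$pose)
  set.seed(75)
  p <- set_torsions(ref$pose, 1, 2, list(phi = ref$torsions[["2"]]$phi + 9))
  e_before <- total_energy(p, 1, w, lib, 1:5, ctx = ctx)$total
  prop <- apply_move(p, "local_refine", 1, nodes = 2, library = lib,
                     weights = w, ctx = ctx, score_nodes = 1:5)
  e_after <- total_energy(prop, 1, w, lib, 1:5, ctx = ctx)$total
  expect_lte(e_after, e_before + 1e-9)
})

test_that("kde_torsion long-run marginal matches the proposal KDE", {
  lib <- test_library()
  ref <- test_reference()
  ctx <- make_energy_context(ref$pose)
  # single node, phi/psi both proposed; with sugar_bb-only scoring at kT = 1
  # the independence proposal from the pooled-anomeric KDE need not equal the
  # stationary law, so check the *proposal* marginal directly
  key <- linkage_key(ref$tree, 1)
  kde <- glycantree:::single_torsion_kde(lib, key, "phi")
  set.seed(76)
  s <- kde_sample(kde, 2e4)
  thg <- seq(-179.9, 179.9, length.out = 500)
  cdf <- cumsum(kde_density(kde, thg)) * diff(thg)[1] * pi / 180
  expect_lt(max(abs(stats::ecdf(s)(thg) - cdf)), 0.02)
})

test_that("run_sampler budget is linear and zero rounds is the identity", {
  lib <- test_library()
  ref <- test_reference()
  w <- energy_weights()
  st0 <- run_sampler(ref$pose, 1, 1:5, w, lib, rounds_per_residue = 0)
  expect_identical(st0$pose$xyz, ref$pose$xyz)
  expect_equal(st0$cycles, 0)
  for (n_nodes in c(1, 3, 5)) {
    set.seed(77)
    st <- run_sampler(ref$pose, 1, seq_len(n_nodes), w, lib,
                      rounds_per_residue = 4, score_nodes = 1:5)
    expect_equal(st$cycles, 4 * n_nodes)
  }
})

test_that("sampler trace is seed-deterministic with non-increasing best", {
  lib <- test_library()
  ref <- test_reference()
  w <- energy_weights()
  set.seed(78)
  p <- randomize_backbone(ref$pose, 1)
  set.seed(79)
  a <- run_sampler(p, 1, 1:5, w, lib, 6, trace = TRUE)
  set.seed(79)
  b <- run_sampler(p, 1, 1:5, w, lib, 6, trace = TRUE)
  expect_identical(a$trace, b$trace)
  expect_identical(a$pose$xyz, b$pose$xyz)
  expect_lte(a$best_energy, min(a$trace$dE * 0 + a$energy))
  # best-so-far energy is never above the final current energy
  expect_lte(a$best_energy, a$energy + 1e-12)
  expect_equal(nrow(a$trace), 30)
  expect_true(all(a$trace$move %in% c("conformer", "kde_torsion",
                                      "local_refine", "exocyclic_chi")))
})
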