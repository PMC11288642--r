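test_that("sugar_bb energy is zero at conformer modes and additive", {
  lib <- test_library()
  ref <- test_reference()
  expect_equal(sugar_bb_energy(ref$pose, 1, lib, 1:5), 0, tolerance = 1e-9)
  expect_equal(sugar_bb_energy(ref$pose, 1, lib, integer()), 0)
  # shifting one torsion adds exactly that torsion's KDE energy
  p2 <- set_torsions(ref$pose, 1, 2, list(phi = ref$torsions[["2"]]$phi + 20))
  key <- linkage_key(ref$tree, 2)
  kde <- lib$linkages[[key]]$kdes$phi
  expect_equal(sugar_bb_energy(p2, 1, lib, 1:5),
               kde_energy(kde, measure_torsions(p2, 1, 2)$phi, use_grid = TRUE),
               tolerance = 1e-9)
  # missing linkage type errors with the key name
  empty_lib <- structure(list(linkages = list(), anomeric = list()),
                         class = "conformer_library")
  expect_error(sugar_bb_energy(ref$pose, 1, empty_lib, 1),
               "b-D-GlcpNAc-\\(1->ASN\\)")
})

test_that("steric pair term follows the stated closed form", {
  # two isolated atoms: build a minimal fake pose
  mk <- function(d) {
    atoms <- data.frame(chain = "A", resno = 1:2, resname = "XXX",
                        atom = c("C1", "C2"), element = "C",
                        role = "glycan", tree = 1L, node = 1:2,
                        stringsAsFactors = FALSE)
    tr <- glycan_tree(data.frame(node_id = 1:2, kind = "b-D-Glcp",
                                 anomer = "b", parent_id = c(NA, 1L),
                                 parent_pos = c(NA, 4L), child_pos = c(NA, 1L)))
    new_pose(atoms, rbind(c(0, 0, 0), c(d, 0, 0)), trees = list(tr),
             bonds = matrix(integer(), ncol = 2))
  }
  r0 <- 2 * 1.70  # C + C
  st <- function(d) {
    p <- mk(d)
    ctx <- list(radii = rep(1.70, 2), excl_keys = numeric(),
                is_h = c(FALSE, FALSE), n = 2, protein_heavy = integer(),
                don_h = integer(), don_d = integer(), acc = integer(),
                kin = list())
    steric_energy(p, 1, 1:2, ctx)
  }
  at_r0 <- st(r0)
  expect_equal(at_r0$rep, 0, tolerance = 1e-12)
  expect_equal(at_r0$atr, -1, tolerance = 1e-12)  # -eps at contact
  expect_equal(st(0.001)$rep, 10)                 # cap
  mid <- st(3.0)
  expect_equal(mid$rep, (r0 / 3.0)^12 - 1, tolerance = 1e-9)
  expect_equal(st(7)$atr, 0)                      # beyond cutoff
  # taper region: analytic value
  tp <- st(5.5)
  expect_equal(tp$atr, -1 * (r0 / 5.5)^6 * 0.5 * (1 + cos(pi * 0.5)),
               tolerance = 1e-9)
})

test_that("three-atom steric configuration matches a hand sum", {
  atoms <- data.frame(chain = "A", resno = 1:3, resname = "XXX",
                      atom = c("C1", "O2", "C3"), element = c("C", "O", "C"),
                      role = "glycan", tree = 1L, node = c(1L, 1L, 2L),
                      stringsAsFactors = FALSE)
  tr <- glycan_tree(data.frame(node_id = 1:2, kind = "b-D-Glcp", anomer = "b",
                               parent_id = c(NA, 1L), parent_pos = c(NA, 4L),
                               child_pos = c(NA, 1L)))
  xyz <- rbind(c(0, 0, 0), c(3.0, 0, 0), c(0, 3.2, 0))
  p <- new_pose(atoms, xyz, trees = list(tr), bonds = matrix(integer(), ncol = 2))
  ctx <- list(radii = c(1.70, 1.52, 1.70), excl_keys = numeric(),
              is_h = rep(FALSE, 3), n = 3, protein_heavy = integer(),
              don_h = integer(), don_d = integer(), acc = integer(),
              kin = list())
  st <- steric_energy(p, 1, 1:2, ctx)
  pair <- function(r, r0) {
    if (r < r0) min(10, (r0 / r)^12 - 1) else 0
  }
  atrp <- function(r, r0) {
    if (r < r0 || r > 6) return(0)
    sw <- if (r > 5) 0.5 * (1 + cos(pi * (r - 5))) else 1
    -(r0 / r)^6 * sw
  }
  d12 <- 3.0; d13 <- 3.2; d23 <- sqrt(3^2 + 3.2^2)
  expect_equal(st$rep, pair(d12, 3.22) + pair(d13, 3.40) + pair(d23, 3.22),
               tolerance = 1e-9)
  expect_equal(st$atr, atrp(d12, 3.22) + atrp(d13, 3.40) + atrp(d23, 3.22),
               tolerance = 1e-9)
})

test_that("hydrogen-bond windows peak at ideal geometry", {
  # donor O-H ... acceptor O, collinear at 2.9 A
  mk <- function(d_da, angle_dev = 0) {
    atoms <- data.frame(chain = "A", resno = c(1, 1, 2), resname = "XXX",
                        atom = c("O2", "HO2", "O3"), element = c("O", "H", "O"),
                        role = "glycan", tree = 1L, node = c(1L, 1L, 2L),
                        stringsAsFactors = FALSE)
    th <- angle_dev * pi / 180
    acc <- c(d_da * cos(th), d_da * sin(th), 0)
    xyz <- rbind(c(0, 0, 0), c(0.96, 0, 0), acc)
    p <- new_pose(atoms, xyz, bonds = matrix(integer(), ncol = 2))
    ctx <- make_energy_context(p)
    hbond_energy(p, 1, 1:2, ctx)
  }
  expect_equal(mk(2.9), -1, tolerance = 1e-9)   # ideal
  expect_equal(mk(5.0), 0)                      # out of range
  expect_equal(mk(2.6), 0, tolerance = 1e-9)    # window edge
  # intermediate distance: hand-evaluated window product (angle still 180)
  got <- mk(3.15)
  expect_equal(got, -1 * 0.5 * (1 + cos(pi * (3.15 - 2.9) / 0.5)),
               tolerance = 1e-9)
  expect_lt(mk(2.9, 30), 0)       # bent but > 120 deg still bonds weakly
  expect_gt(mk(2.9, 30), -1)
})

test_that("density term is discriminative and bounded", {
  ref <- test_reference()
  rows <- glycantree:::nodes_atom_rows(ref$pose, 1, 1:5, heavy = TRUE)
  map <- simulate_density(ref$pose, 2.0, 1.0, 4.0, rows = rows)
  e0 <- density_energy(ref$pose, map, 1, 1:5)
  expect_equal(e0, -1, tolerance = 0.02)  # self-map correlation ~ 1
  shift <- function(p, d) { p$xyz[rows, 1] <- p$xyz[rows, 1] + d; p }
  e05 <- density_energy(shift(ref$pose, 0.5), map, 1, 1:5)
  e3 <- density_energy(shift(ref$pose, 3), map, 1, 1:5)
  expect_lt(e05, e3)
  far <- shift(ref$pose, 50)
  expect_warning(e_far <- density_energy(far, map, 1, 1:5), "outside")
  expect_equal(e_far, 0)
  expect_true(all(c(e0, e05, e3) >= -1 & c(e0, e05, e3) <= 1))
})

test_that("total energy is a weighted sum and deterministic", {
  lib <- test_library()
  ref <- test_reference()
  w0 <- energy_weights(w_sugar_bb = 0, w_rep = 0, w_atr = 0, w_hbond = 0,
                       w_density = 0)
  expect_equal(total_energy(ref$pose, 1, w0, lib, 1:5)$total, 0)
  w1 <- energy_weights(w_sugar_bb = 1, w_rep = 0, w_atr = 0, w_hbond = 0)
  expect_equal(total_energy(ref$pose, 1, w1, lib, 1:5)$total,
               sugar_bb_energy(ref$pose, 1, lib, 1:5))
  w <- energy_weights()
  e1 <- total_energy(ref$pose, 1, w, lib, 1:5)
  e2 <- total_energy(ref$pose, 1, w, lib, 1:5)
  expect_identical(e1$total, e2$total)
  expect_equal(e1$total,
               w$w_sugar_bb * e1$sugar_bb + w$w_rep * e1$rep +
               w$w_atr * e1$atr + w$w_hbond * e1$hbond +
               w$w_density * e1$density, tolerance = 1e-9)
  # native-like scores below a randomized pose
  set.seed(61)
  pr <- randomize_backbone(ref$pose, 1)
  expect_lt(e1$total, total_energy(pr, 1, w, lib, 1:5)$total)
})

test_that("energy is invariant under rigid-body transformation", {
  lib <- test_library()
  ref <- test_reference()
  w <- energy_weights()
  e0 <- total_energy(ref$pose, 1, w, lib, 1:5)$total
  set.seed(62)
  for (i in 1:5) {
    ax <- stats::rnorm(3); ang <- stats::runif(1, 0, 360)
    shiftv <- stats::rnorm(3, sd = 5)
    p <- ref$pose
    p$xyz <- glycantree:::rotate_points(p$xyz, c(0, 0, 0), ax, ang)
    p$xyz <- sweep(p$xyz, 2, shiftv, FUN = "+")
    expect_equal(total_energy(p, 1, w, lib, 1:5)$total, e0, tolerance = 1e-6)
  }
})

test_that("weight validation rejects bad values", {
  expect_error(energy_weights(w_rep = -1), ">= 0")
  expect_error(energy_weights(kT_mc = 0), "> 0")
})
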