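test_that("von Mises mixture generator is seeded with correct weights", {
  comp <- data.frame(mean = c(-90, 90), kappa = c(50, 50), weight = c(0.25, 0.75))
  a <- gen_torsion_mixture(comp, 500, seed = 131)
  b <- gen_torsion_mixture(comp, 500, seed = 131)
  expect_identical(a, b)
  big <- gen_torsion_mixture(comp, 2e4, seed = 132)
  frac_hi <- mean(abs(wrap_angle(big - 90)) < 90)
  ci <- 3 * sqrt(0.75 * 0.25 / 2e4)
  expect_lt(abs(frac_hi - 0.75), ci + 0.01)
  # near-degenerate concentration collapses on the mean
  tight <- gen_torsion_mixture(data.frame(mean = 33, kappa = 1e6, weight = 1),
                               100, seed = 133)
  expect_true(all(abs(tight - 33) < 1))
  expect_error(gen_torsion_mixture(data.frame(mean = 0, kappa = 1, weight = 0.5),
                                   10), "sum to 1")
})

test_that("toy scaffold has ideal backbone dihedrals and the Asn handle", {
  sc <- make_toy_scaffold("helix", 12, 6)
  expect_equal(sum(sc$atoms$resname == "ASN"), 8)  # 5 backbone + 3 side chain
  expect_false(is.na(atom_row(sc, "A", 6, "ND2", must = FALSE)))
  phi <- dihedral_deg(sc$xyz[atom_row(sc, "A", 5, "C"), ],
                      sc$xyz[atom_row(sc, "A", 6, "N"), ],
                      sc$xyz[atom_row(sc, "A", 6, "CA"), ],
                      sc$xyz[atom_row(sc, "A", 6, "C"), ])
  psi <- dihedral_deg(sc$xyz[atom_row(sc, "A", 6, "N"), ],
                      sc$xyz[atom_row(sc, "A", 6, "CA"), ],
                      sc$xyz[atom_row(sc, "A", 6, "C"), ],
                      sc$xyz[atom_row(sc, "A", 7, "N"), ])
  expect_equal(phi, -57, tolerance = 1e-6)
  expect_equal(psi, -47, tolerance = 1e-6)
  expect_identical(sc$xyz, make_toy_scaffold("helix", 12, 6)$xyz)
  st <- make_toy_scaffold("strand", 8, 4)
  expect_equal(length(unique(st$atoms$resno)), 8)
  expect_error(make_toy_scaffold("helix", 4, 2), ">= 5")
  expect_error(make_toy_scaffold("helix", 12, 20), "out of range")
})

test_that("reference complex is clash-free at conformer modes", {
  ref <- test_reference()
  st <- steric_energy(ref$pose, 1, ref$tree$nodes$node_id)
  expect_lt(st$rep, 5)
  # torsions equal the chosen conformer modes
  for (id in 1:5) {
    m <- measure_torsions(ref$pose, 1, id)
    want <- ref$torsions[[as.character(id)]]
    for (t in names(want)) expect_equal(m[[t]], want[[t]], tolerance = 1e-6)
  }
  ref2 <- make_reference_complex(test_core_tree(), test_scaffold(),
                                 test_library())
  expect_identical(ref2$pose$xyz, ref$pose$xyz)
})

test_that("simulated density behaves like a sum of atom Gaussians", {
  # single atom: maximum at the atom position
  atoms <- data.frame(chain = "A", resno = 1, resname = "XXX", atom = "C1",
                      element = "C", role = "protein", tree = NA_integer_,
                      node = NA_integer_, stringsAsFactors = FALSE)
  p1 <- new_pose(atoms, matrix(c(0.0, 0.0, 0.0), 1, 3),
                 bonds = matrix(integer(), ncol = 2))
  map <- simulate_density(p1, resolution = 2, voxel = 0.5, padding = 4)
  peak <- which(map$data == max(map$data), arr.ind = TRUE)[1, ]
  peak_xyz <- map$origin + (peak - 1) * map$voxel
  expect_true(all(abs(peak_xyz - 0) < map$voxel))
  # numeric integral ~ atom count x Gaussian mass
  total <- sum(map$data) * map$voxel^3
  sigma <- 2 / 3
  expect_equal(total, (2 * pi * sigma^2)^(3 / 2), tolerance = 0.02)
  # two atoms separated by > 4 sigma give two local maxima
  p2 <- new_pose(rbind(atoms, transform(atoms, resno = 2, atom = "C2")),
                 rbind(c(0, 0, 0), c(4 * sigma + 1, 0, 0)),
                 bonds = matrix(integer(), ncol = 2))
  m2 <- simulate_density(p2, resolution = 2, voxel = 0.5, padding = 4)
  ix <- round((c(0, 4 * sigma + 1) - m2$origin[1]) / m2$voxel) + 1
  iy <- round((0 - m2$origin[2]) / m2$voxel) + 1
  iz <- round((0 - m2$origin[3]) / m2$voxel) + 1
  line <- m2$data[, iy, iz]
  expect_gt(line[ix[1]], line[mean(ix)])
  expect_gt(line[ix[2]], line[mean(ix)])
})

test_that("real-space correlation is high on self and decays with shift", {
  ref <- test_reference()
  rows <- glycantree:::nodes_atom_rows(ref$pose, 1, 1:5, heavy = TRUE)
  map <- simulate_density(ref$pose, 2, 1, 4, rows = rows)
  expect_gt(real_space_correlation(ref$pose, map, rows), 0.99)
  shift <- function(d) {
    p <- ref$pose; p$xyz[rows, 1] <- p$xyz[rows, 1] + d; p
  }
  cors <- vapply(c(0.5, 1.5, 3), function(d)
    real_space_correlation(shift(d), map, rows), numeric(1))
  expect_true(all(diff(cors) < 0))
  expect_warning(far <- real_space_correlation(shift(500), map, rows),
                 "outside")
  expect_equal(far, 0)
})

test_that("density maps round trip through the text grid format", {
  ref <- test_reference()
  map <- simulate_density(ref$pose, 2, 1.5, 3)
  f <- withr::local_tempfile()
  write_density_map(map, f)
  m2 <- read_density_map(f)
  expect_equal(m2$origin, unname(map$origin), tolerance = 1e-6)
  expect_equal(m2$dim, unname(map$dim))
  expect_equal(as.numeric(m2$data), as.numeric(map$data), tolerance = 1e-4)
})
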