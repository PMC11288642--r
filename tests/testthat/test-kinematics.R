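test_that("sugar templates have closed chair rings and sane bonds", {
  for (kind in sugar_alphabet()) {
    tpl <- template_for(kind)
    ring <- tpl$xyz[match(tpl$ring, tpl$atoms$name), ]
    d <- sqrt(rowSums((ring - ring[c(2:6, 1), ])^2))
    expect_true(all(abs(d - d[1]) < 0.1), info = kind)  # ring closes
    rt <- vapply(1:6, function(i) {
      ii <- ((i - 1):(i + 2)) %% 6 + 1
      dihedral_deg(ring[ii[1], ], ring[ii[2], ], ring[ii[3], ], ring[ii[4], ])
    }, numeric(1))
    expect_true(all(abs(abs(rt) - abs(rt[1])) < 1),
                info = paste(kind, "chair alternation"))
    expect_true(all(sign(rt) == rep(sign(rt[1]) * c(1, -1), 3)), info = kind)
    # all template bonds in [1.2, 1.7] A except O-H/N-H
    b <- tpl$bonds
    for (k in seq_len(nrow(b))) {
      i <- match(b[k, 1], tpl$atoms$name); j <- match(b[k, 2], tpl$atoms$name)
      len <- sqrt(sum((tpl$xyz[i, ] - tpl$xyz[j, ])^2))
      if (tpl$atoms$element[i] == "H" || tpl$atoms$element[j] == "H") {
        expect_true(len > 0.9 && len < 1.1, info = kind)
      } else {
        expect_true(len >= 1.2 && len <= 1.7, info = kind)
      }
    }
  }
  expect_true(all(c("N2", "C7", "O7", "C8") %in%
                  template_for("b-D-GlcpNAc")$atoms$name))
  expect_false("O6" %in% template_for("a-L-Fucp")$atoms$name)  # 6-deoxy
  expect_false("C6" %in% template_for("b-D-Xylp")$atoms$name)  # pentose
  expect_error(template_for("Hex"), "unsupported")
})

test_that("build then measure returns the requested torsions", {
  sc <- test_scaffold()
  tr1 <- parse_iupac("b-D-GlcpNAc",
                     attachment = list(chain = "A", resno = 6, atom = "ND2"))
  p <- build_glycan(sc, tr1, list("1" = list(phi = -97, psi = 178)))
  m <- measure_torsions(p, 1, 1)
  expect_equal(m$phi, -97, tolerance = 1e-8)
  expect_equal(m$psi, 178, tolerance = 1e-8)
  c1 <- p$xyz[which(p$atoms$atom == "C1" & p$atoms$role == "glycan"), ]
  nd2 <- p$xyz[which(p$atoms$atom == "ND2"), ]
  expect_equal(sqrt(sum((c1 - nd2)^2)), 1.45, tolerance = 1e-9)

  set.seed(7)
  tr5 <- test_core_tree()
  tors <- random_torsions(tr5)
  p5 <- build_glycan(sc, tr5, tors)
  for (id in 1:5) {
    m <- measure_torsions(p5, 1, id)
    want <- tors[[as.character(id)]]
    for (t in names(want)) expect_equal(m[[t]], want[[t]], tolerance = 1e-6)
  }
  # glycosidic bridge geometry is ideal for every linkage
  for (id in 2:5) {
    fr <- glycantree:::linkage_frame_rows(p5, tr5, 1, id)
    c1 <- p5$xyz[glycantree:::node_atom_row(p5, 1, id, "C1"), ]
    expect_equal(sqrt(sum((c1 - p5$xyz[fr$ox, ])^2)), 1.40, tolerance = 1e-9)
    expect_equal(glycantree:::angle_deg(c1, p5$xyz[fr$ox, ], p5$xyz[fr$cx, ]),
                 117, tolerance = 1e-6)
  }
  expect_error(build_glycan(sc, tr5, tors[-3]), "incomplete")
})

test_that("forward build is deterministic", {
  sc <- test_scaffold()
  tr <- test_core_tree()
  set.seed(8); tors <- random_torsions(tr)
  p1 <- build_glycan(sc, tr, tors)
  p2 <- build_glycan(sc, tr, tors)
  expect_identical(p1$xyz, p2$xyz)
})

test_that("dihedral measurement matches an independent oracle", {
  set.seed(11)
  for (i in 1:200) {
    p <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    expect_equal(dihedral_deg(p[1, ], p[2, ], p[3, ], p[4, ]),
                 dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
  # planar cis = 0, trans normalizes to -180
  expect_equal(dihedral_deg(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(dihedral_deg(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)),
               -180)
})

test_that("set_torsions moves exactly the distal subtree", {
  sc <- test_scaffold()
  tr <- test_core_tree()
  set.seed(12); tors <- random_torsions(tr)
  p <- build_glycan(sc, tr, tors)
  p2 <- set_torsions(p, 1, 3, list(phi = 10, psi = -120))
  m <- measure_torsions(p2, 1, 3)
  expect_equal(m$phi, 10, tolerance = 1e-8)
  expect_equal(m$psi, -120, tolerance = 1e-8)
  moved <- which(rowSums(abs(p2$xyz - p$xyz)) > 1e-12)
  expect_setequal(unique(p2$atoms$node[moved]), c(3, 4, 5))
  prot <- which(p$atoms$role == "protein")
  expect_identical(p2$xyz[prot, ], p$xyz[prot, ])

  # composing two +30 phi rotations equals one +60
  a <- set_torsions(set_torsions(p, 1, 2, list(phi = tors[["2"]]$phi + 30)),
                    1, 2, list(phi = tors[["2"]]$phi + 60))
  b <- set_torsions(p, 1, 2, list(phi = tors[["2"]]$phi + 60))
  expect_equal(a$xyz, b$xyz, tolerance = 1e-9)
})

test_that("torsion edits preserve rigid ring geometry and bond lengths", {
  sc <- test_scaffold()
  tr <- test_core_tree()
  set.seed(13); tors <- random_torsions(tr)
  p <- build_glycan(sc, tr, tors)
  p2 <- p
  for (rep in 1:5) {
    set.seed(rep)
    id <- sample(1:5, 1)
    p2 <- set_torsions(p2, 1, id, list(phi = stats::runif(1, -180, 180)))
  }
  bonds <- pose_bonds(p)
  d1 <- sqrt(rowSums((p$xyz[bonds[, 1], ] - p$xyz[bonds[, 2], ])^2))
  d2 <- sqrt(rowSums((p2$xyz[bonds[, 1], ] - p2$xyz[bonds[, 2], ])^2))
  expect_equal(d1, d2, tolerance = 1e-9)
  # ring superimposes exactly on the template ring
  for (id in 1:5) {
    tpl <- template_for(tr$nodes$kind[id])
    ring_rows <- vapply(tpl$ring, function(nm)
      glycantree:::node_atom_row(p2, 1, id, nm), integer(1))
    tring <- tpl$xyz[match(tpl$ring, tpl$atoms$name), ]
    expect_lt(kabsch(p2$xyz[ring_rows, ], tring)$rmsd, 1e-6)
  }
})

test_that("exocyclic chi moves only the hydroxyl group", {
  sc <- test_scaffold()
  tr <- test_core_tree()
  set.seed(14); p <- build_glycan(sc, tr, random_torsions(tr))
  p2 <- set_exocyclic_chi(p, 1, 5, 2, 75)
  expect_equal(measure_exocyclic_chi(p2, 1, 5, 2), 75, tolerance = 1e-8)
  moved <- which(rowSums(abs(p2$xyz - p$xyz)) > 1e-12)
  expect_equal(p2$atoms$atom[moved], "HO2")
  # linkage-occupied position is not rotatable (node 3 accepts 3 and 6)
  expect_error(set_exocyclic_chi(p, 1, 3, 3, 10), "not a rotatable")
  # free hydroxymethyl at position 6 moves O6 + HO6
  p3 <- set_exocyclic_chi(p, 1, 5, 6, -55)
  expect_equal(measure_exocyclic_chi(p3, 1, 5, 6), -55, tolerance = 1e-8)
  moved3 <- which(rowSums(abs(p3$xyz - p$xyz)) > 1e-12)
  expect_setequal(p3$atoms$atom[moved3], c("O6", "HO6"))
})

test_that("randomize_backbone is seeded and uniform", {
  sc <- test_scaffold()
  tr <- test_core_tree()
  set.seed(15); p <- build_glycan(sc, tr, random_torsions(tr))
  set.seed(99); a <- randomize_backbone(p, 1)
  set.seed(99); b <- randomize_backbone(p, 1)
  expect_identical(a$xyz, b$xyz)
  set.seed(100); c2 <- randomize_backbone(p, 1, nodes = integer())
  expect_identical(c2$xyz, p$xyz)
  # marginal uniformity of a torsion over repeated randomization
  set.seed(101)
  phis <- replicate(2000, measure_torsions(
    randomize_backbone(p, 1, nodes = 2), 1, 2)$phi)
  ks <- stats::ks.test(phis, "punif", -180, 180)
  expect_gt(ks$p.value, 0.01)
})

test_that("torsion locality matches the BFS-distal oracle on fuzzed trees", {
  sc <- test_scaffold()
  set.seed(16)
  for (i in 1:25) {
    tr <- random_tree(max_depth = 4)
    tors <- random_torsions(tr)
    p <- build_glycan(sc, tr, tors)
    id <- sample(tr$nodes$node_id, 1)
    p2 <- set_torsions(p, 1, id, list(psi = stats::runif(1, -180, 180)))
    moved <- unique(p2$atoms$node[rowSums(abs(p2$xyz - p$xyz)) > 1e-12])
    # oracle: distal side of the psi bond = the node's whole subtree
    sub <- glycantree:::subtree_ids(tr, id)
    expect_true(all(moved %in% sub))
    expect_true(id %in% moved || length(moved) == 0)
  }
})
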