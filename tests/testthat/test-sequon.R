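test_that("sequon scanning follows N-X(S/T) with X != P", {
  expect_equal(scan_sequons("ANAT")$position, 2)
  expect_equal(nrow(scan_sequons("ANPS")), 0)
  expect_equal(nrow(scan_sequons("NPS")), 0)
  expect_equal(scan_sequons("NCS")$hydroxyl, "S")
  # overlapping hits are all reported
  expect_equal(scan_sequons("NNSS")$position, c(1, 2))
  expect_error(scan_sequons("ANB1"), "non-amino-acid")
})

test_that("sequon scan agrees with the regex oracle on all 8000 3-mers", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  combos <- expand.grid(a = aa, b = aa, c = aa, stringsAsFactors = FALSE)
  seqs <- paste0(combos$a, combos$b, combos$c)
  got <- vapply(seqs, function(s) nrow(scan_sequons(s)) == 1, logical(1))
  want <- grepl("^N[^P][ST]$", seqs)
  expect_identical(unname(got), want)
})

test_that("sequon scan equals the regex oracle on random sequences", {
  set.seed(121)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:200) {
    s <- paste(sample(aa, sample(3:40, 1), replace = TRUE), collapse = "")
    got <- scan_sequons(s)$position
    want <- gregexpr("N(?=[^P][ST])", s, perl = TRUE)[[1]]
    want <- as.integer(want[want > 0])
    expect_identical(got, if (length(want)) want else integer())
  }
})

test_that("create_sequon designs typical/enhanced motifs idempotently", {
  expect_equal(create_sequon("AAAAA", 2, "typical"), "ANATA")
  # existing hydroxyl at n+2 is preserved (S stays S)
  expect_equal(create_sequon("ANASA", 2, "typical"), "ANASA")
  expect_equal(create_sequon("AAAAA", 3, "enhanced"), "FANAT")
  expect_error(create_sequon("AAAAA", 1, "enhanced"), "n-2")
  expect_error(create_sequon("AAAAA", 4, "typical"), "does not fit")
  expect_error(create_sequon("AAAAA", 2, "typical", immutable = 2), "immutable")
  # idempotent
  once <- create_sequon("GGGGGG", 3, "enhanced")
  expect_equal(create_sequon(once, 3, "enhanced"), once)
})

test_that("glycosylate attaches a registered tree at ND2", {
  lib <- test_library()
  sc <- test_scaffold()
  set.seed(122)
  p <- glycosylate(sc, "A", 6, "b-D-GlcpNAc-(1->4)-b-D-GlcpNAc", lib)
  expect_length(p$trees, 1)
  expect_equal(nrow(p$trees[[1]]$nodes), 2)
  expect_equal(sum(p$atoms$role == "glycan" & p$atoms$element != "H" &
                   p$atoms$atom == "C1"), 2)
  c1 <- p$xyz[glycantree:::node_atom_row(p, 1, 1, "C1"), ]
  nd2 <- p$xyz[atom_row(p, "A", 6, "ND2"), ]
  expect_lt(sqrt(sum((c1 - nd2)^2)), 1.6)
  # non-Asn residues refuse without force
  expect_error(glycosylate(sc, "A", 3, "b-D-GlcpNAc", lib), "not ASN")
  # seeded reproducibility
  set.seed(123); a <- glycosylate(sc, "A", 6, MAN3_CORE, lib)
  set.seed(123); b <- glycosylate(sc, "A", 6, MAN3_CORE, lib)
  expect_identical(a$xyz, b$xyz)
})

test_that("position report ranks exposed sites above buried clashes", {
  lib <- test_library()
  sc <- make_toy_scaffold("helix", 14, 6)
  # an artificial cage of protein atoms around residue 10's side chain
  # direction forces any glycan there into contact
  target <- sc$xyz[atom_row(sc, "A", 10, "CB"), ]
  n <- sc$xyz[atom_row(sc, "A", 10, "N"), ]
  ca <- sc$xyz[atom_row(sc, "A", 10, "CA"), ]
  cb <- sc$xyz[atom_row(sc, "A", 10, "CB"), ]
  dir <- (cb - ca) / sqrt(sum((cb - ca)^2))
  extra <- lapply(1:60, function(k) target + dir * (3 + (k %% 5)) +
                    c(sin(k), cos(k), sin(2 * k)) * 2.5)
  add <- data.frame(chain = "B", resno = seq_along(extra), resname = "UNK",
                    atom = paste0("X", seq_along(extra)), element = "C",
                    role = "protein", tree = NA_integer_, node = NA_integer_,
                    stringsAsFactors = FALSE)
  cage <- sc
  cage$atoms <- rbind(cage$atoms, add)
  cage$xyz <- rbind(cage$xyz, do.call(rbind, extra))
  cfg <- modeler_config(rounds_per_residue = 4, n_decoys = 2, seed = 7)
  rep <- position_report(cage, data.frame(chain = "A", resno = c(6, 10)),
                         "b-D-GlcpNAc", cfg, lib)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$resno[1], 6)  # exposed site ranks first
  expect_lt(rep$energy[1], rep$energy[2])
  # empty candidate list gives an empty report
  expect_equal(nrow(position_report(cage, integer(), "b-D-GlcpNAc", cfg, lib)), 0)
})
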