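test_that("PDB parsing drops waters and hydrogens and flags bad elements", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  H   ALA A   1       1.000   0.000   0.000  1.00  0.00           H",
    "HETATM    3  O   HOH A 101       5.000   0.000   0.000  1.00  0.00           O",
    "END"), tmp)
  at <- read_structure(tmp)
  expect_equal(nrow(at), 1L)
  expect_equal(at$elety, "CA")
  expect_equal(at$element, "C")
  expect_equal(unname(unlist(at[1, c("x", "y", "z")])), c(0, 0, 0))

  # unknown element: skip with warning by default, error on request
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2 FE   HEM A   2       3.000   0.000   0.000  1.00  0.00          FE",
    "END"), tmp)
  expect_warning(at <- read_structure(tmp, include_hetatm = TRUE), "FE")
  expect_equal(nrow(at), 1L)
  expect_error(read_structure(tmp, unknown_element = "error"), "FE")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("toy structures round-trip through the package's own reader", {
  for (geom in c("lone-helix", "two-helix-dimer", "three-sphere")) {
    toy <- make_toy_structure(geom)
    tmp <- tempfile(fileext = ".pdb")
    writeLines(toy$pdb, tmp)
    at <- expect_no_warning(read_structure(tmp))
    expect_equal(nrow(at), nrow(toy$atoms))  # generator bookkeeping
    expect_equal(at$resno, toy$atoms$resno)
    expect_equal(at$chain, toy$atoms$chain)
    expect_equal(at$x, toy$atoms$x, tolerance = 1e-3)
  }
})

test_that("isolated and well-separated atoms get the analytic sphere area", {
  p <- sasa_params()
  lone <- data.frame(element = "S", x = 0, y = 0, z = 0)
  analytic <- 4 * pi * (1.8 + 1.4)^2
  expect_lt(abs(shrake_rupley(lone, p) - analytic) / analytic, 0.01)

  apart <- data.frame(element = c("S", "S"), x = c(0, 10), y = 0, z = 0)
  expect_equal(shrake_rupley(apart, p), rep(analytic, 2), tolerance = 1e-9)
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  p <- sasa_params()  # 960 points
  R <- 1.7 + 1.4
  for (d in c(2.0, 3.0, 4.5, 5.5)) {
    atoms <- data.frame(element = c("C", "C"), x = c(0, d), y = 0, z = 0)
    got <- shrake_rupley(atoms, p)
    want <- two_sphere_cap_sasa(R, d)
    expect_lt(max(abs(got - want)) / want, 0.02)
  }
})

test_that("occlusion is monotone and SASA converges with point count", {
  set.seed(21)
  cloud <- data.frame(element = sample(c("C", "N", "O", "S"), 15, TRUE),
                      x = runif(15, 0, 8), y = runif(15, 0, 8),
                      z = runif(15, 0, 8))
  base <- shrake_rupley(cloud)
  for (rep in 1:5) {
    extra <- data.frame(element = "C", x = runif(3, 0, 8),
                        y = runif(3, 0, 8), z = runif(3, 0, 8))
    grown <- shrake_rupley(rbind(cloud, extra))
    expect_true(all(grown[seq_len(nrow(cloud))] <= base + 1e-9))
  }
  # doubling the point count moves total SASA by < 1% on the toy helix
  helix <- make_toy_structure("lone-helix")$atoms
  s1 <- sum(shrake_rupley(helix, sasa_params(n_points = 960)))
  s2 <- sum(shrake_rupley(helix, sasa_params(n_points = 1920)))
  expect_lt(abs(s1 - s2) / s2, 0.01)
})

test_that("relative SASA normalizes by residue type and respects the table", {
  toy <- make_toy_structure("lone-helix")
  sasa <- shrake_rupley(toy$atoms)
  rs <- residue_relative_sasa(toy$atoms, sasa)
  expect_equal(nrow(rs), 24L)
  expect_true(all(rs$abs_sasa > 0))
  expect_equal(rs$rel_sasa, rs$abs_sasa / max_asa_table()["ALA"],
               ignore_attr = TRUE)
  expect_true(all(rs$rel_sasa_capped <= 1))

  # all-zero atom SASA -> relative 0
  rs0 <- residue_relative_sasa(toy$atoms, rep(0, nrow(toy$atoms)))
  expect_true(all(rs0$rel_sasa == 0))

  # equal absolute SASA: smaller denominator -> larger relative value
  two <- data.frame(chain = "A", resno = 1:2, resid = c("GLY", "TRP"),
                    elety = "CA", element = "C",
                    x = c(0, 50), y = 0, z = 0, stringsAsFactors = FALSE)
  rs2 <- residue_relative_sasa(two, c(60, 60))
  expect_gt(rs2$rel_sasa[rs2$resid == "GLY"], rs2$rel_sasa[rs2$resid == "TRP"])

  bad <- two; bad$resid[1] <- "UNK"
  expect_error(residue_relative_sasa(bad, c(60, 60)), "UNK")
})

test_that("assembly context only ever lowers per-residue accessibility", {
  toy <- make_toy_structure("two-helix-dimer")
  a_only <- toy$atoms[toy$atoms$chain == "A", ]
  rs_mono <- residue_relative_sasa(a_only, shrake_rupley(a_only))
  rs_dimer <- residue_relative_sasa(toy$atoms, shrake_rupley(toy$atoms))
  delta <- rs_mono$rel_sasa -
    rs_dimer$rel_sasa[rs_dimer$chain == "A"]
  expect_true(all(delta >= -1e-9))
  # the generator's interface residues lose accessibility; far-side
  # residues are essentially untouched
  iface <- toy$truth$interface[toy$truth$chain == "A"]
  expect_gt(mean(delta[iface]), 0.01)
  expect_gt(mean(delta[iface]), mean(delta[!iface]) + 0.01)
})

test_that("motif accessibility calls monomer exposure, occlusion, and TM override", {
  dimer <- make_toy_structure("two-helix-dimer", motif_placement = "interface")
  call_i <- motif_accessibility(dimer$atoms, dimer$motif$start,
                                dimer$motif$end, "A",
                                assembly_chains = c("A", "B"),
                                motif_id = "iface")
  expect_equal(call_i$call_monomer, "exposed")
  expect_true(call_i$occluded_by_oligomer)
  expect_gt(call_i$rel_sasa_monomer, call_i$rel_sasa_assembly)

  # a surface motif on the lone helix is exposed in every computed context
  surf <- make_toy_structure("lone-helix", motif_placement = "surface")
  call_s <- motif_accessibility(surf$atoms, surf$motif$start,
                                surf$motif$end, "A",
                                assembly_chains = "A", motif_id = "surf")
  expect_equal(call_s$call_monomer, "exposed")
  expect_equal(call_s$call_assembly, "exposed")
  expect_false(call_s$occluded_by_oligomer)

  lone <- make_toy_structure("lone-helix")
  call_l <- motif_accessibility(lone$atoms, lone$motif$start,
                                lone$motif$end, "A", motif_id = "lone")
  expect_equal(call_l$call_monomer, "exposed")
  expect_true(is.na(call_l$rel_sasa_assembly))

  # TM interval forces buried regardless of SASA
  call_tm <- motif_accessibility(lone$atoms, lone$motif$start,
                                 lone$motif$end, "A",
                                 tm_intervals = c(1, 24), motif_id = "tm")
  expect_equal(call_tm$call_monomer, "buried")
  expect_equal(call_tm$reason, "transmembrane")
  expect_false(call_tm$occluded_by_oligomer)

  expect_error(
    motif_accessibility(lone$atoms, 100, 103, "A"), "missing")
})
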