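test_that("reference positions map to alignment columns past gaps", {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">ref", "DE-ELQ", ">t1", "DEAELQ"), tmp)
  aln <- read_alignment(tmp)
  cm <- map_ref_positions(aln, "ref")
  expect_equal(cm$map, c(1L, 2L, 4L, 5L, 6L))

  writeLines(c(">ref", "DEELQ", ">t1", "DEALQ"), tmp)
  cm2 <- map_ref_positions(read_alignment(tmp), "ref")
  expect_equal(cm2$map, 1:5)  # ungapped ref -> identity

  writeLines(c(">ref", "-----", ">t1", "DEALQ"), tmp)
  expect_error(map_ref_positions(read_alignment(tmp), "ref"), "entirely gaps")
  expect_error(map_ref_positions(read_alignment(tmp), "nope"), "not in")
})

test_that("presence calls distinguish GIM, canonical, and absent (gap rule)", {
  aln <- toy_alignment()  # HUMAN WVFV / MOUSE WIFV / CHICK HAGV / FISH -VFV
  cm <- map_ref_positions(aln, "HUMAN")
  hits <- scan_motifs(seq_record("HUMAN", aln$HUMAN$residues))
  expect_equal(hits$core, "WVFV")
  pres <- motif_presence(aln, cm, hits)
  expect_equal(pres["HUMAN", 1], "present_gim")
  expect_equal(pres["MOUSE", 1], "present_gim")       # V->I at X1 allowed
  expect_equal(pres["CHICK", 1], "absent")            # Theta = H fails
  expect_equal(pres["FISH", 1], "absent")             # gap anywhere -> absent
  expect_equal(retention_fraction(setNames(pres[[1]], rownames(pres))), 0.5)
  expect_equal(retention_fraction(setNames(pres[[1]], rownames(pres)),
                                  c("HUMAN", "MOUSE")), 1.0)
  expect_error(retention_fraction(setNames(pres[[1]], rownames(pres)),
                                  character(0)), "empty")
})

test_that("presence is invariant to column shuffles preserving homologous content", {
  aln <- toy_alignment()
  cm <- map_ref_positions(aln, "HUMAN")
  hits <- scan_motifs(seq_record("HUMAN", aln$HUMAN$residues))
  pres <- motif_presence(aln, cm, hits)
  # prepend a column that is a gap in the reference: every homologous
  # column shifts but reference coordinates and column content survive
  tmp <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(aln), function(id) {
    lead <- if (id == "HUMAN") "-" else "G"
    c(paste0(">", id), paste0(lead, aln[[id]]$residues))
  })), tmp)
  shifted <- read_alignment(tmp)
  pres2 <- motif_presence(shifted, map_ref_positions(shifted, "HUMAN"), hits)
  expect_equal(pres2, pres, ignore_attr = TRUE)
})

test_that("information content hits exact endpoints and stays in bounds", {
  tmp <- tempfile(fileext = ".fasta")
  # col1 all W (IC = log2 20), col2 50/50 W/F (IC = log2 20 - 1),
  # col3 gap-only in half the rows (gaps excluded from denominator)
  writeLines(c(">a", "WWW", ">b", "WF-", ">c", "WWW", ">d", "WF-"), tmp)
  aln <- read_alignment(tmp)
  prof <- frequency_profile(aln, 1:3)
  expect_equal(prof$ic[1], log2(20))
  expect_equal(prof$ic[2], log2(20) - 1)
  expect_equal(prof$freq["W", 2], 0.5)
  expect_equal(sum(prof$freq[, 3]), 1)  # gaps excluded from denominator
  expect_error(frequency_profile(aln, 9), "out of range")

  # uniform 20-residue column -> IC exactly 0
  writeLines(unlist(lapply(seq_len(20), function(i) {
    c(paste0(">u", i), setdiff(aa_alphabet(), "X")[i])
  })), tmp)
  expect_equal(frequency_profile(read_alignment(tmp), 1)$ic, 0)

  # all-gap column reported as missing
  writeLines(c(">a", "W-", ">b", "W-"), tmp)
  expect_true(is.na(frequency_profile(read_alignment(tmp), 2)$ic))

  # random alignments respect the bounds
  set.seed(5)
  for (rep in 1:10) {
    rows <- replicate(6, paste(sample(c(setdiff(aa_alphabet(), "X"), "-"),
                                      8, replace = TRUE), collapse = ""))
    writeLines(unlist(lapply(seq_along(rows), function(i) {
      c(paste0(">r", i), rows[i])
    })), tmp)
    ic <- frequency_profile(read_alignment(tmp), 1:8)$ic
    ok <- !is.na(ic)
    expect_true(all(ic[ok] >= -1e-12 & ic[ok] <= log2(20) + 1e-12))
  }
})

test_that("profile JSON lists frequencies and IC per column", {
  aln <- toy_alignment()
  prof <- frequency_profile(aln, 6:9)
  tmp <- tempfile(fileext = ".json")
  write_profile_json(prof, tmp)
  back <- jsonlite::fromJSON(tmp, simplifyVector = FALSE)
  expect_length(back, 4L)
  expect_equal(back[[1]]$column, 6L)
  expect_equal(back[[1]]$ic_bits, prof$ic[1])
  expect_equal(length(back[[1]]$frequencies), 20L)
})

test_that("gain/loss reconstruction matches hand-worked cases", {
  tr <- ape::read.tree(text = "((A,B),C);")
  gl <- fitch_gain_loss(tr, c(A = "present_gim", B = "present_canonical",
                              C = "absent"))
  expect_equal(gl$min_changes, 1L)
  expect_equal(nrow(gl$events), 1L)
  expect_equal(gl$root_state, "absent")  # tie resolves to absent
  expect_equal(gl$events$type, "gain")

  all_present <- fitch_gain_loss(tr, c(A = "present", B = "present",
                                       C = "present"))
  expect_equal(all_present$min_changes, 0L)
  expect_equal(nrow(all_present$events), 0L)

  gl2 <- fitch_gain_loss(ape::read.tree(text = "((A,B),(C,D));"),
                         c(A = "present", B = "absent",
                           C = "present", D = "absent"))
  expect_equal(gl2$min_changes, 2L)

  # root preference is configurable
  glp <- fitch_gain_loss(tr, c(A = "present", B = "present", C = "absent"),
                         root_prefer = "present")
  expect_equal(glp$root_state, "present")
  expect_equal(glp$min_changes, 1L)
  expect_equal(glp$events$type, "loss")

  expect_error(fitch_gain_loss(tr, c(A = "present", B = "absent")),
               "no presence state.*C")
})

test_that("change counts equal brute-force minima on random trees", {
  set.seed(101)
  for (trial in 1:200) {
    case <- random_presence_case(sample(4:12, 1))
    gl <- fitch_gain_loss(case$tree, case$states)
    oracle <- brute_force_parsimony(
      case$tree, setNames(as.integer(case$states == "present"),
                          names(case$states)))
    expect_equal(gl$min_changes, oracle)
    # the branch-resolved event list realizes the minimum
    expect_equal(nrow(gl$events), gl$min_changes)
  }
})

test_that("change counts stay minimal on multifurcating trees", {
  # a polytomy where naive intersect/union undercounts: four children
  # present,present,absent,absent needs two changes
  tr <- ape::read.tree(text = "(A,B,C,D);")
  gl <- fitch_gain_loss(tr, c(A = "present", B = "present",
                              C = "absent", D = "absent"))
  expect_equal(gl$min_changes, 2L)
  set.seed(7)
  for (trial in 1:50) {
    n <- sample(4:10, 1)
    tree <- ape::di2multi(ape::rtree(n), tol = 0.6)
    states <- setNames(sample(c("present", "absent"), n, replace = TRUE),
                       tree$tip.label)
    gl <- fitch_gain_loss(tree, states)
    oracle <- brute_force_parsimony(
      tree, setNames(as.integer(states == "present"), names(states)))
    expect_equal(gl$min_changes, oracle)
    expect_equal(nrow(gl$events), gl$min_changes)
  }
})

test_that("change counts agree with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(33)
  for (trial in 1:25) {
    case <- random_presence_case(sample(5:20, 1))
    gl <- fitch_gain_loss(case$tree, case$states)
    dat <- phangorn::phyDat(
      matrix(case$states[case$tree$tip.label], ncol = 1,
             dimnames = list(case$tree$tip.label, NULL)),
      type = "USER", levels = c("present", "absent"))
    expect_equal(gl$min_changes,
                 as.integer(phangorn::parsimony(case$tree, dat)))
  }
})
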