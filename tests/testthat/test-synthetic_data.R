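test_that("fixture generation is fully deterministic", {
  s1 <- randomFixtureSpec(7)
  s2 <- randomFixtureSpec(7)
  expect_identical(s1, s2)
  f1 <- buildFixture(s1)
  f2 <- buildFixture(s2)
  expect_identical(f1$atoms, f2$atoms)
  expect_identical(f1$truth, f2$truth)
  ## byte-identical on disk
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  writeFixture(f1, p1)
  writeFixture(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
  ## different seeds differ
  expect_false(identical(randomFixtureSpec(7), randomFixtureSpec(8)))
})

test_that("fixtureSpec validates its probe table", {
  expect_error(fixtureSpec("GATC", data.frame(
    strand = 3, index = 1, groove = "major", type = "ASN",
    outcome = "bond")))
  expect_error(fixtureSpec("GATC", data.frame(
    strand = 1, index = 9, groove = "major", type = "ASN",
    outcome = "bond")))
  expect_error(fixtureSpec("GATC", data.frame(
    strand = 1, index = 1, groove = "sideways", type = "ASN",
    outcome = "bond")))
  expect_error(generateBDNA("GATX"), "invalid character")
  expect_error(generateBDNA(""), "non-empty")
})

test_that("the written ground truth round-trips through JSON", {
  fx <- buildFixture(randomFixtureSpec(3))
  pdb <- tempfile(fileext = ".pdb")
  js <- tempfile(fileext = ".json")
  writeFixture(fx, pdb, js)
  tr <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(as.integer(tr$n_pairs), nchar(fx$spec$sequence))
  expect_equal(tr$n_scb_strand1, fx$truth$n_scb_strand1)
  expect_equal(tr$n_scb_strand2, fx$truth$n_scb_strand2)
  expect_equal(tr$pct_dominant, fx$truth$pct_dominant)
  expect_identical(tr$dominant_strand, fx$truth$dominant_strand)
})

test_that("planted truths are recovered exactly on sample fixtures", {
  for (seed in 1:5) {
    fx <- buildFixture(randomFixtureSpec(seed))
    unit <- unitFromFixture(fx)
    tr <- fx$truth
    for (m in c("geometric", "energy")) {
      b <- hbonds(suppressWarnings(
        detectHBonds(unit, detectorParams(m))))
      ## every detected bond is a planted side-chain-base bond
      expect_true(all(b$class == "sidechain-base"))
      got <- sort(paste(b$dna_chain, b$dna_resno, b$dna_atom, b$groove,
                        b$prot_resno, sep = "|"))
      want <- sort(paste(tr$bonds$dna_chain, tr$bonds$dna_resno,
                         tr$bonds$dna_atom, tr$bonds$groove,
                         tr$bonds$prot_resno, sep = "|"))
      expect_identical(got, want)
    }
  }
})

test_that("the restriction-enzyme-like stand-in reproduces its pattern", {
  fx <- syntheticNgoMIVLike()
  unit <- unitFromFixture(fx)
  dup <- detectBasePairs(fx$atoms, fx$dnaChains)
  for (m in c("geometric", "energy")) {
    hb <- suppressWarnings(detectHBonds(unit, detectorParams(m)))
    s <- summarizeComplex(hb, dup)
    ## three bonds per strand, three engaged bases per strand
    expect_equal(unname(s@counts["n_scb_strand1"]), 3)
    expect_equal(unname(s@counts["n_scb_strand2"]), 3)
    expect_equal(unname(s@counts["n_bases_s1"]), 3)
    expect_equal(unname(s@counts["n_bases_s2"]), 3)
    ## three continuous engaged base pairs
    bp <- findBasePairHbonds(hb, dup, "both")
    expect_identical(nrow(bp), 3L)
    expect_identical(sort(bp$resno1), c(7L, 8L, 9L))
    key <- paste0(bp$resid1, "-", bp$resno1, "(", bp$chain1, ").",
                  bp$resid2, "-", bp$resno2, "(", bp$chain2, ")")
    expect_true("DG-7(E).DC-6(H)" %in% key)
    expect_true("DC-9(E).DG-4(H)" %in% key)
  }
})

test_that("the sigma-factor-like stand-in has equal bases, no pairs", {
  fx <- syntheticSigmaE4Like()
  unit <- unitFromFixture(fx)
  dup <- detectBasePairs(fx$atoms, fx$dnaChains)
  for (m in c("geometric", "energy")) {
    hb <- suppressWarnings(detectHBonds(unit, detectorParams(m)))
    s <- summarizeComplex(hb, dup)
    expect_equal(unname(s@counts["n_bases_s1"]),
                 unname(s@counts["n_bases_s2"]))
    expect_gt(s@counts[["n_bases_s1"]], 0)
    expect_true(s@flags[["is_5050_bases_major"]])
    expect_equal(unname(s@counts["n_bp_hb"]), 0)
  }
})

test_that("the bundled stand-in files equal freshly generated ones", {
  fx <- syntheticNgoMIVLike()
  tmp <- tempfile(fileext = ".pdb")
  writeFixture(fx, tmp)
  expect_identical(readLines(tmp),
                   readLines(extdataFile("synthetic_ngomiv_like.pdb")))
  tr <- jsonlite::read_json(
    extdataFile("synthetic_ngomiv_like_truth.json"),
    simplifyVector = TRUE)
  expect_equal(tr$n_scb_strand1, 3)
  expect_identical(sort(unique(tr$bonds$dna_chain)), c("E", "H"))
  fx2 <- syntheticSigmaE4Like()
  tmp2 <- tempfile(fileext = ".pdb")
  writeFixture(fx2, tmp2)
  expect_identical(readLines(tmp2),
                   readLines(extdataFile("synthetic_sigmae4_like.pdb")))
})

test_that("ideal peptides carry their planted labels", {
  pep <- buildPeptide(c("helix", "coil"), c(6, 4))
  expect_identical(attr(pep, "planted"),
                   c(rep("helix", 6), rep("coil", 4)))
  expect_identical(length(unique(pep$resno)), 10L)
  sheet <- buildBetaSheet(6)
  expect_identical(sort(unique(sheet$chain)), c("A", "B"))
  expect_true(all(attr(sheet, "planted") == "strand"))
})
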