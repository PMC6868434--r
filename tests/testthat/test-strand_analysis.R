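## duplex shared by the arithmetic tests: GAATTC fiber duplex, strand 1
## chain B (resno 1..6), strand 2 chain C (resno 1..6, step 7 - resno)
dupGA <- detectBasePairs(generateBDNA("GAATTC"), c("B", "C"))

test_that("summarizeComplex counts a 4-4 split as an equal contribution", {
  b <- rbind(mkBonds("B", 1:4), mkBonds("C", 1:4))
  s <- summarizeComplex(b, dupGA, pdbID = "X", group = "HS",
                        detector = "geometric")
  expect_equal(unname(s@counts["n_scb_strand1"]), 4)
  expect_equal(unname(s@counts["n_scb_strand2"]), 4)
  expect_identical(s@pctDominant, 50)
  expect_identical(s@dominantStrand, "strand1")  # tie resolves to 1
  expect_true(s@flags[["is_5050_bonds"]])
  expect_false(s@flags[["one_strand_only"]])
  expect_true(s@flags[["has_scb"]])
})

test_that("summarizeComplex computes dominant percentages exactly", {
  ## 6 vs 2 -> 75 percent on strand 1
  b62 <- rbind(mkBonds("B", c(1, 1, 2, 3, 4, 5)), mkBonds("C", c(1, 3)))
  s62 <- summarizeComplex(b62, dupGA, detector = "geometric")
  expect_identical(s62@pctDominant, 75)
  expect_identical(s62@dominantStrand, "strand1")
  expect_false(s62@flags[["is_5050_bonds"]])
  ## engaged bases deduplicate repeated bonds to the same base
  expect_equal(unname(s62@counts["n_bases_s1"]), 5)
  expect_equal(unname(s62@counts["n_bases_s2"]), 2)
  ## 5 vs 0 -> one strand only, 100 percent
  b50 <- mkBonds("B", 1:5)
  s50 <- summarizeComplex(b50, dupGA, detector = "geometric")
  expect_identical(s50@pctDominant, 100)
  expect_true(s50@flags[["one_strand_only"]])
  ## no side-chain-base bonds at all
  s0 <- summarizeComplex(mkBonds("B", 1, class = "mainchain-backbone",
                                 groove = "none"),
                         dupGA, detector = "geometric")
  expect_false(s0@flags[["has_scb"]])
  expect_true(is.na(s0@pctDominant))
  expect_equal(unname(s0@counts["n_nonscb_s1"]), 1)
})

test_that("per-strand counts partition the side-chain-base bonds", {
  for (seed in c(1, 5, 10)) {
    fx <- buildFixture(randomFixtureSpec(seed))
    unit <- unitFromFixture(fx)
    dup <- detectBasePairs(fx$atoms, c("B", "C"))
    for (m in c("geometric", "energy")) {
      hb <- suppressWarnings(detectHBonds(unit, detectorParams(m)))
      s <- summarizeComplex(hb, dup)
      co <- s@counts
      nscb <- sum(hbonds(hb)$class == "sidechain-base")
      expect_equal(unname(co["n_scb_strand1"] + co["n_scb_strand2"]),
                   nscb)
      ## groove split partitions each strand's count
      expect_equal(
        unname(co["n_scb_major_s1"] + co["n_scb_minor_s1"] +
                 co["n_scb_none_s1"]),
        unname(co["n_scb_strand1"]))
      expect_equal(
        unname(co["n_scb_major_s2"] + co["n_scb_minor_s2"] +
                 co["n_scb_none_s2"]),
        unname(co["n_scb_strand2"]))
      ## engaged bases never exceed bonds
      expect_lte(co[["n_bases_s1"]], co[["n_scb_strand1"]])
      expect_lte(co[["n_bases_s2"]], co[["n_scb_strand2"]])
    }
  }
})

test_that("energy split is conserved across strands", {
  fx <- buildFixture(randomFixtureSpec(10))
  unit <- unitFromFixture(fx)
  hb <- suppressWarnings(detectHBonds(unit, detectorParams("energy")))
  dup <- detectBasePairs(fx$atoms, c("B", "C"))
  s <- summarizeComplex(hb, dup)
  b <- hbonds(hb)
  expect_equal(unname(s@energies["e_scb_s1"] + s@energies["e_scb_s2"]),
               sum(b$energy[b$class == "sidechain-base"]),
               tolerance = 1e-9)
  ## geometric detector carries no energies
  sg <- summarizeComplex(
    suppressWarnings(detectHBonds(unit, detectorParams("geometric"))),
    dup)
  expect_true(all(is.na(sg@energies)))
})

test_that("relabeling the strands swaps the per-strand counts", {
  fx <- buildFixture(randomFixtureSpec(1))
  unit <- unitFromFixture(fx)
  hb <- suppressWarnings(detectHBonds(unit, detectorParams("geometric")))
  d12 <- detectBasePairs(fx$atoms, c("B", "C"))
  d21 <- detectBasePairs(fx$atoms, c("C", "B"))
  s12 <- summarizeComplex(hb, d12)
  s21 <- summarizeComplex(hb, d21)
  swap <- function(cnt, a, b) {
    expect_equal(unname(s12@counts[a]), unname(s21@counts[b]))
    expect_equal(unname(s12@counts[b]), unname(s21@counts[a]))
  }
  swap(s12@counts, "n_scb_strand1", "n_scb_strand2")
  swap(s12@counts, "n_scb_major_s1", "n_scb_major_s2")
  swap(s12@counts, "n_scb_minor_s1", "n_scb_minor_s2")
  swap(s12@counts, "n_bases_s1", "n_bases_s2")
  swap(s12@counts, "n_nonscb_s1", "n_nonscb_s2")
  ## invariants under relabeling
  expect_identical(s12@pctDominant, s21@pctDominant)
  expect_identical(s12@flags, s21@flags)
  expect_equal(unname(s12@counts["n_bp_hb"]),
               unname(s21@counts["n_bp_hb"]))
})

test_that("findBasePairHbonds requires both bases of a pair", {
  ## GAATTC: bond on B-2 (step 2) and C-5 (step 7-5 = 2) engages pair 2
  b <- rbind(mkBonds("B", 2), mkBonds("C", 5))
  bp <- findBasePairHbonds(b, dupGA, "both")
  expect_identical(nrow(bp), 1L)
  expect_identical(bp$resno1, 2L)
  expect_identical(bp$resno2, 5L)
  expect_identical(bp$pair_type, "AT")
  ## a single engaged base is not enough
  expect_identical(nrow(findBasePairHbonds(mkBonds("B", 2), dupGA,
                                           "both")), 0L)
  ## groove filter: minor-groove bonds do not count under "major"
  bmin <- rbind(mkBonds("B", 2, groove = "minor"),
                mkBonds("C", 5, groove = "major"))
  expect_identical(nrow(findBasePairHbonds(bmin, dupGA, "both")), 1L)
  expect_identical(nrow(findBasePairHbonds(bmin, dupGA, "major")), 0L)
  ## non side-chain-base bonds never engage a base
  bnon <- rbind(mkBonds("B", 2, class = "mainchain-base"),
                mkBonds("C", 5))
  expect_identical(nrow(findBasePairHbonds(bnon, dupGA, "both")), 0L)
})

test_that("bonds to residues outside the duplex are an error", {
  b <- mkBonds("B", 99)
  expect_error(summarizeComplex(b, dupGA), "absent from the")
})

test_that("summarizeGroup aggregates and guards its inputs", {
  mk <- function(b1, b2, pdbID) {
    b <- rbind(if (b1 > 0) mkBonds("B", seq_len(b1)),
               if (b2 > 0) mkBonds("C", seq_len(b2)))
    summarizeComplex(b, dupGA, pdbID = pdbID, group = "HS",
                     detector = "geometric")
  }
  ## 3-3 (50%), 4-2 (66.7%), 5-1 (83.3%), 6-0 (100%, one strand)
  ss <- list(mk(3, 3, "a"), mk(4, 2, "b"), mk(5, 1, "c"), mk(6, 0, "d"))
  g <- summarizeGroup(ss)
  expect_equal(unname(g@counts["n_complexes"]), 4)
  expect_equal(unname(g@counts["n_complexes_with_scb"]), 4)
  expect_equal(unname(g@counts["n_equal_contribution"]), 1)
  ## dominant <= 75 percent is inclusive: 50 and 66.7 qualify
  expect_equal(unname(g@counts["n_dominant_le75"]), 2)
  expect_equal(unname(g@counts["n_one_strand_only"]), 1)
  ## percentages sorted descending
  expect_equal(g@pctDominant,
               sort(c(50, 400 / 6, 500 / 6, 100), decreasing = TRUE),
               tolerance = 1e-9)
  ## mixed groups / detectors are rejected
  sMS <- summarizeComplex(mkBonds("B", 1), dupGA, group = "MS",
                          detector = "geometric")
  expect_error(summarizeGroup(c(ss, list(sMS))), "mix groups")
  sEn <- summarizeComplex(mkBonds("B", 1, energy = -1), dupGA,
                          group = "HS", detector = "energy")
  expect_error(summarizeGroup(c(ss, list(sEn))), "mix detectors")
})

test_that("complexSummaryTable flattens summaries losslessly", {
  b <- rbind(mkBonds("B", 1:2), mkBonds("C", 4))
  s <- summarizeComplex(b, dupGA, pdbID = "P1", group = "MS",
                        detector = "geometric")
  tab <- complexSummaryTable(list(s))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$pdb_id, "P1")
  expect_identical(tab$group, "MS")
  expect_equal(tab$n_scb_strand1, 2)
  expect_equal(tab$n_scb_strand2, 1)
  expect_equal(tab$pct_dominant, 200 / 3, tolerance = 1e-9)
  expect_identical(tab$dominant_strand, "strand1")
})
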