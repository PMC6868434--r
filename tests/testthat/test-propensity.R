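test_that("propensity of a set against itself is 1 for every type", {
  v <- c(rep("helix", 5), rep("strand", 3), rep("coil", 7))
  p <- computePropensity(v, v)
  expect_identical(p$state3, c("helix", "strand", "coil"))
  expect_equal(p$propensity, c(1, 1, 1))
  expect_false(any(p$undefined))
})

test_that("propensity arithmetic matches a hand computation", {
  fg <- c("helix", "helix", "coil", "coil")
  bg <- c("helix", "helix", "strand", "coil")
  p <- computePropensity(fg, bg, fgLabel = "f", bgLabel = "b")
  ## fg freq (0.5, 0, 0.5) over bg freq (0.5, 0.25, 0.25)
  expect_equal(p$freq_fg, c(0.5, 0, 0.5))
  expect_equal(p$freq_bg, c(0.5, 0.25, 0.25))
  expect_equal(p$propensity, c(1, 0, 2))
  expect_identical(p$fg_label, rep("f", 3))
  expect_identical(p$bg_label, rep("b", 3))
})

test_that("propensity is invariant to sample-size scaling", {
  set.seed(42)
  fg <- sample(c("helix", "strand", "coil"), 30, replace = TRUE)
  bg <- sample(c("helix", "strand", "coil"), 50, replace = TRUE)
  p1 <- computePropensity(fg, bg)
  p3 <- computePropensity(rep(fg, 3), rep(bg, 5))
  expect_equal(p1$propensity, p3$propensity, tolerance = 1e-12)
})

test_that("propensity flags states missing from the background", {
  p <- computePropensity(c("strand", "coil"), c("coil", "coil"))
  expect_identical(p$propensity[p$state3 == "strand"], Inf)
  expect_true(p$undefined[p$state3 == "strand"])
  ## absent from both: 0/0
  expect_true(is.nan(p$propensity[p$state3 == "helix"]))
  expect_error(computePropensity(character(0), c("coil")), "foreground")
  expect_error(computePropensity(c("coil"), character(0)), "background")
  expect_error(computePropensity("loop", "coil"))
})

test_that("propensity matches an independent tabulation oracle", {
  set.seed(7)
  states <- c("helix", "strand", "coil")
  for (rep_i in 1:5) {
    fg <- sample(states, sample(10:40, 1), replace = TRUE)
    bg <- sample(states, sample(20:80, 1), replace = TRUE)
    p <- computePropensity(fg, bg)
    for (s in states) {
      ffg <- length(which(fg == s)) / length(fg)
      fbg <- length(which(bg == s)) / length(bg)
      want <- if (fbg > 0) ffg / fbg else if (ffg > 0) Inf else NaN
      got <- p$propensity[p$state3 == s]
      if (is.nan(want)) expect_true(is.nan(got))
      else expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("baseContactingResidues applies the 4.5 Angstrom side-chain rule", {
  fx <- buildFixture(fixtureSpec("GAATTC", data.frame(
    strand = 1, index = 1, groove = "major", type = "ASN",
    outcome = "bond")))
  bc <- baseContactingResidues(unitFromFixture(fx))
  ## the probe touches its target base through ND2 at 2.9 Angstrom
  expect_identical(nrow(bc), 1L)
  expect_identical(bc$resid, "ASN")
  expect_lte(bc$min_dist, 4.5)
  expect_lt(abs(bc$min_dist - 2.9), 0.5)
  ## a residue offering only main-chain atoms can never qualify
  atoms <- fx$atoms
  base <- atoms[atoms$chain == "B" & atoms$resno == 1 &
                  atoms$elety == "N7", ]
  gly <- base[rep(1, 4), ]
  gly$chain <- "A"; gly$resno <- 99L; gly$resid <- "GLY"
  gly$kind <- "amino_acid"
  gly$elety <- c("N", "CA", "C", "O")
  gly$elesy <- c("N", "C", "C", "O")
  gly$x <- gly$x + c(1, 1.5, 2, 2.5)   # right next to the base
  bc2 <- baseContactingResidues(rbind(atoms, gly))
  expect_false(99L %in% bc2$resno)
  ## sugar/phosphate proximity alone does not count as base contact
  far <- baseContactingResidues(unitFromFixture(fx), cutoff = 0.5)
  expect_identical(nrow(far), 0L)
})

test_that("the contact cutoff is monotone", {
  fx <- buildFixture(fixtureSpec("GGAATTCC", data.frame(
    strand = c(1, 2), index = c(2, 3), groove = "major", type = "ASN",
    outcome = c("bond", "near_miss_distance"))))
  unit <- unitFromFixture(fx)
  n30 <- nrow(baseContactingResidues(unit, cutoff = 3.0))
  n45 <- nrow(baseContactingResidues(unit, cutoff = 4.5))
  n60 <- nrow(baseContactingResidues(unit, cutoff = 6.0))
  expect_lte(n30, n45)
  expect_lte(n45, n60)
  ## the near-miss probe sits at 4.2 Angstrom: inside 4.5, outside 3.0
  expect_identical(n45, 2L)
  expect_identical(n30, 1L)
})
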