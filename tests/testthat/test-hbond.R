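test_that("mayoEnergy matches the closed-form 12-10 well", {
  ## well minimum: -V0 exactly at d = d0 with a perfect angular factor
  expect_identical(mayoEnergy(2.8, 1), -8)
  ## independent arithmetic at another distance
  r <- 2.8 / 3.2
  expect_equal(mayoEnergy(3.2, 1), 8 * (5 * r^12 - 6 * r^10),
               tolerance = 1e-12)
  ## linear in the angular factor
  expect_equal(mayoEnergy(3.0, 0.5), 0.5 * mayoEnergy(3.0, 1))
  ## far apart: essentially zero, and above the acceptance cutoff
  expect_lt(abs(mayoEnergy(10, 1)), 1e-3)
  ## even a perfectly aligned pair at 4.25 Angstrom is rejected
  expect_gt(mayoEnergy(4.25, 1), -0.6)
  expect_error(mayoEnergy(-1), "dDA")
})

test_that("detectorParams validates its arguments", {
  p <- detectorParams("energy")
  expect_identical(p$method, "energy")
  expect_identical(p$V0, 8)
  expect_identical(p$d0, 2.8)
  expect_identical(p$energyCutoff, -0.6)
  expect_error(detectorParams("geometric", maxDA = -1))
  expect_error(detectorParams("energy", energyCutoff = 0.5))
  expect_error(detectorParams("nonsense"))
})

test_that("polar hydrogens are placed with ideal counts and lengths", {
  fx <- buildFixture(fixtureSpec("GAATTC"))
  unit <- unitFromFixture(fx)
  unit <- placePolarHydrogens(unit)
  h <- unit@hydrogens
  atoms <- atomTable(unit)
  ## per-base hydrogen counts: DA N6 x2; DC N4 x2; DG N1 x1 + N2 x2;
  ## DT N3 x1.  GAATTC + complement GAATTC: 2 G, 2 C, 4 A, 4 T
  cnt <- function(resid, donor) sum(h$resid == resid & h$donor == donor)
  expect_identical(cnt("DA", "N6"), 8L)
  expect_identical(cnt("DC", "N4"), 4L)
  expect_identical(cnt("DG", "N1"), 2L)
  expect_identical(cnt("DG", "N2"), 4L)
  expect_identical(cnt("DT", "N3"), 4L)
  ## every N-H bond is 1.00 Angstrom
  for (i in seq_len(nrow(h))) {
    d <- atoms[atoms$chain == h$chain[i] & atoms$resno == h$resno[i] &
                 atoms$elety == h$donor[i], ]
    expect_equal(sqrt(sum((as.numeric(d[1, c("x", "y", "z")]) -
                             as.numeric(h[i, c("x", "y", "z")]))^2)),
                 1.00, tolerance = 1e-9)
  }
  ## serine hydroxyl hydrogens are 0.96 Angstrom
  fxs <- buildFixture(fixtureSpec("GAATTC", data.frame(
    strand = 1, index = 1, groove = "major", type = "SER",
    outcome = "bond")))
  us <- placePolarHydrogens(unitFromFixture(fxs))
  hs <- us@hydrogens[us@hydrogens$resid == "SER", ]
  expect_identical(nrow(hs), 1L)
  og <- atomTable(us)
  og <- og[og$resid == "SER" & og$elety == "OG", ]
  expect_equal(sqrt(sum((as.numeric(og[1, c("x", "y", "z")]) -
                           as.numeric(hs[1, c("x", "y", "z")]))^2)),
               0.96, tolerance = 1e-9)
})

test_that("a planted donor probe is found by both detectors", {
  fx <- buildFixture(fixtureSpec("GAATTC", data.frame(
    strand = 1, index = 1, groove = "major", type = "ASN",
    outcome = "bond")))
  unit <- unitFromFixture(fx)
  geo <- hbonds(detectHBonds(unit, detectorParams("geometric")))
  expect_identical(nrow(geo), 1L)
  expect_identical(geo$class, "sidechain-base")
  expect_identical(geo$groove, "major")
  expect_identical(geo$dna_atom, "O6")    # G major-groove acceptor
  expect_identical(geo$don_atom, "ND2")
  expect_equal(geo$d_da, 2.9, tolerance = 1e-6)
  expect_equal(geo$theta_dha, 180, tolerance = 1e-3)
  expect_true(is.na(geo$energy))
  en <- hbonds(detectHBonds(unit, detectorParams("energy")))
  expect_identical(nrow(en), 1L)
  expect_identical(en$dna_atom, "O6")
  expect_lt(en$energy, -0.6)
  ## head-on geometry at 2.9 Angstrom sits close to the well bottom
  expect_lt(en$energy, -7)
})

test_that("near-miss probes are rejected and recovered only when the
           violated criterion is relaxed", {
  ## distance near-miss: planted at 4.2 Angstrom donor-acceptor
  fxd <- buildFixture(fixtureSpec("GAATTC", data.frame(
    strand = 1, index = 1, groove = "major", type = "ASN",
    outcome = "near_miss_distance")))
  ud <- unitFromFixture(fxd)
  expect_identical(
    nrow(hbonds(detectHBonds(ud, detectorParams("geometric")))), 0L)
  expect_identical(
    nrow(hbonds(detectHBonds(ud, detectorParams("energy")))), 0L)
  ## a 4.2 Angstrom head-on approach implies H-A of about 3.2, so both
  ## distance limits must move to re-admit it
  rec <- hbonds(detectHBonds(ud, detectorParams("geometric",
                                                maxDA = 4.5,
                                                maxHA = 3.5)))
  expect_identical(nrow(rec), 1L)
  expect_equal(rec$d_da, 4.2, tolerance = 1e-6)
  expect_equal(rec$d_ha, 3.2, tolerance = 1e-6)

  ## angle near-miss: D-H-A tilted to 60 degrees at contact distance
  fxa <- buildFixture(fixtureSpec("GAATTC", data.frame(
    strand = 1, index = 1, groove = "major", type = "ASN",
    outcome = "near_miss_angle")))
  ua <- unitFromFixture(fxa)
  expect_identical(
    nrow(hbonds(detectHBonds(ua, detectorParams("geometric")))), 0L)
  expect_identical(
    nrow(hbonds(detectHBonds(ua, detectorParams("energy")))), 0L)
  ## the tilt also stretches H-A (to about 3.27 at theta = 60 with the
  ## donor held at 2.9), so recovery needs the angle minimum and the
  ## H-A cap relaxed together
  reca <- hbonds(detectHBonds(ua, detectorParams("geometric",
                                                 minDHA = 45,
                                                 minHAAA = 0,
                                                 maxHA = 3.4)))
  expect_gte(nrow(reca), 1L)
  expect_true("O6" %in% reca$dna_atom)
  expect_true(any(abs(reca$theta_dha - 60) < 1))
})

test_that("angle near-misses are refused for non-constructible probes", {
  dna <- generateBDNA("GAATTC")
  expect_error(plantProbe(dna, "B", 1, "major", "SER",
                          "near_miss_angle"), "not constructible")
  expect_error(plantProbe(dna, "B", 1, "major", "ASP",
                          "near_miss_angle"), "not constructible")
})

test_that("detector acceptance is monotone in its thresholds", {
  fx <- buildFixture(randomFixtureSpec(5))
  unit <- unitFromFixture(fx)
  nGeo <- function(...) nrow(hbonds(suppressWarnings(
    detectHBonds(unit, detectorParams("geometric", ...)))))
  nEn <- function(...) nrow(hbonds(suppressWarnings(
    detectHBonds(unit, detectorParams("energy", ...)))))
  base <- nGeo()
  expect_gt(base, 0)
  ## tightening any geometric threshold can only remove bonds
  expect_lte(nGeo(maxDA = 3.0), base)
  expect_lte(nGeo(maxHA = 2.0), base)
  expect_lte(nGeo(minDHA = 150), base)
  expect_lte(nGeo(minHAAA = 150), base)
  ## absurdly tight limits remove everything
  expect_identical(nGeo(maxDA = 1.0), 0L)
  ## loosening re-admits at least the defaults
  expect_gte(nGeo(maxDA = 4.5, maxHA = 3.5, minDHA = 0, minHAAA = 0),
             base)
  ## energy: a more negative cutoff keeps a subset
  baseE <- nEn()
  expect_lte(nEn(energyCutoff = -2), baseE)
  expect_identical(nEn(energyCutoff = -7.99), 0L)
  expect_gte(nEn(energyCutoff = -0.1), baseE)
})

test_that("detectors agree with the brute-force oracle on mixed fixtures", {
  for (seed in c(2, 7, 11)) {
    unit <- unitFromFixture(buildFixture(randomFixtureSpec(seed)))
    expect_oracle_agreement(unit, "geometric")
    expect_oracle_agreement(unit, "energy")
  }
})

test_that("classifyHBond assigns interaction class and groove", {
  expect_identical(classifyHBond("ASN", "ND2", "DG", "O6"),
                   list(class = "sidechain-base", groove = "major",
                        base = TRUE))
  expect_identical(classifyHBond("ASN", "N", "DG", "O6")$class,
                   "mainchain-base")
  expect_identical(classifyHBond("ASN", "ND2", "DG", "O1P"),
                   list(class = "sidechain-backbone", groove = "none",
                        base = FALSE))
  expect_identical(classifyHBond("GLY", "N", "DT", "O3'")$class,
                   "mainchain-backbone")
})
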