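test_that("ksEnergy matches direct arithmetic and symmetry", {
  ## mirror-symmetric placement about the C-O axis: r_ON = r_OH and
  ## r_CH = r_CN, so all four Coulomb terms cancel exactly
  expect_identical(
    ksEnergy(C = c(0, 0, 0), O = c(1, 0, 0),
             N = c(3, 2, 0), H = c(3, -2, 0)), 0)
  ## independent recomputation for an asymmetric placement
  C <- c(0, 0, 0); O <- c(1.23, 0, 0)
  N <- c(3.1, 1.2, -0.4); H <- c(2.4, 0.7, -0.2)
  d <- function(a, b) sqrt(sum((a - b)^2))
  expect_equal(ksEnergy(C, O, N, H),
               0.084 * 332 * (1 / d(O, N) + 1 / d(C, H) -
                                1 / d(O, H) - 1 / d(C, N)),
               tolerance = 1e-12)
  ## canonical alpha-helix i -> i+4 geometry is strongly bonded
  he <- buildPeptide("helix", 8)
  pos <- function(resno, nm)
    as.numeric(he[he$resno == resno & he$elety == nm, c("x", "y", "z")])
  Hpos <- pos(6, "N") + (pos(5, "C") - pos(5, "O")) /
    d(pos(5, "C"), pos(5, "O"))
  expect_lt(ksEnergy(pos(2, "C"), pos(2, "O"), pos(6, "N"), Hpos), -0.5)
})

test_that("an ideal helix is assigned H in its interior", {
  he <- buildPeptide("helix", 12)
  ss <- assignSecStruct(he)
  expect_identical(paste(ss$state8, collapse = ""), "-HHHHHHHHHH-")
  expect_true(all(ss$state3[2:11] == "helix"))
  ## planted labels agree on at least 90 percent of the interior
  planted <- attr(he, "planted")
  interior <- 3:10
  expect_gte(mean(ss$state3[interior] == planted[interior]), 0.9)
})

test_that("an ideal antiparallel sheet is assigned E in its interior", {
  sh <- buildBetaSheet(8)
  ss <- assignSecStruct(sh)
  for (ch in c("A", "B")) {
    sub <- ss[ss$chain == ch, ]
    expect_identical(nrow(sub), 8L)
    expect_true(all(sub$state8[2:6] == "E"))
    expect_true(all(sub$state3[2:6] == "strand"))
  }
  ## planted labels agree on at least 90 percent of the interior
  planted <- attr(sh, "planted")
  interior <- which(ss$resno %in% 3:6)
  expect_gte(mean(ss$state3[interior] == planted[interior]), 0.9)
})

test_that("an extended coil makes no backbone hydrogen bonds", {
  co <- buildPeptide("coil", 10)
  ss <- assignSecStruct(co)
  expect_true(all(ss$state3 == "coil"))
  expect_false(any(ss$state8 %in% c("H", "G", "I", "E", "B")))
})

test_that("mixed helix-coil-helix segments keep their identities", {
  pep <- buildPeptide(c("helix", "coil", "helix"), c(10, 6, 10))
  ss <- assignSecStruct(pep)
  expect_true(all(ss$state3[3:8] == "helix"))
  expect_true(all(ss$state3[19:24] == "helix"))
  ## the linker interior stays non-helical
  expect_true(all(ss$state3[13:15] != "helix"))
})

test_that("short chains and chain breaks are handled", {
  two <- buildPeptide("helix", 2)
  expect_true(all(assignSecStruct(two)$state3 == "coil"))
  ## 3-4 residue chains of isolated (far-apart) residues: all coil,
  ## and in particular no out-of-range indexing in the bend scan
  fx <- buildFixture(randomFixtureSpec(103))
  ss3 <- assignSecStruct(fx$atoms, chains = "A")
  expect_identical(nrow(ss3), 3L)
  expect_true(all(ss3$state3 == "coil"))
  ## breaking a helix in half (CA-CA > 4.5) removes cross-break bonds:
  ## the boundary residues lose their helical state and fewer residues
  ## are helical than in the intact helix (the 6-residue halves can
  ## still form short internal helices)
  he <- buildPeptide("helix", 12)
  broken <- he
  shift <- broken$resno > 6
  broken$x[shift] <- broken$x[shift] + 100
  ssb <- assignSecStruct(broken)
  ssi <- assignSecStruct(he)
  expect_false(ssb$state8[6] == "H")
  expect_false(ssb$state8[7] == "H")
  expect_lt(sum(ssb$state8 == "H"), sum(ssi$state8 == "H"))
})

test_that("reduceSS maps 8-state symbols to the 3 types", {
  expect_identical(
    reduceSS(c("H", "G", "I", "E", "B", "T", "S", "P", "-")),
    c("helix", "helix", "helix", "strand", "strand",
      "coil", "coil", "coil", "coil"))
})

test_that("readDSSP parses classic fixed columns and reduces states", {
  lines <- c(
    "==== Secondary Structure Definition, synthetic test header ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    sprintf("%5d%5d %s %s  %s", 1, 11, "A", "A", "H"),
    sprintf("%5d%5d %s %s  %s", 2, 12, "A", "A", "E"),
    sprintf("%5d%5d %s %s  %s", 3, 13, "A", "G", " "),
    sprintf("%5d%5d %s %s  %s", 4, 14, "A", "!", " "),   # chain break
    sprintf("%5d%5d %s %s  %s", 5, 21, "B", "V", "T"))
  tf <- tempfile(fileext = ".dssp")
  writeLines(lines, tf)
  out <- readDSSP(tf)
  expect_identical(nrow(out), 4L)   # break record skipped
  expect_identical(out$chain, c("A", "A", "A", "B"))
  expect_identical(out$resno, c(11L, 12L, 13L, 21L))
  expect_identical(out$state8, c("H", "E", "-", "T"))
  expect_identical(out$state3, c("helix", "strand", "coil", "coil"))
  expect_error(suppressWarnings(readDSSP(tempfile())),
               "cannot open|no lines|not a classic")
})

test_that("DSSP-format round trip agrees with in-memory assignment", {
  ## serialize this package's assignment in classic DSSP columns, read
  ## it back, and compare the 3-state reduction residue by residue
  pep <- buildPeptide(c("helix", "coil", "helix"), c(8, 4, 8))
  ss <- assignSecStruct(pep)
  lines <- c("synthetic header",
             "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
             vapply(seq_len(nrow(ss)), function(i)
               sprintf("%5d%5d %s %s  %s", i, ss$resno[i], ss$chain[i],
                       "A", ifelse(ss$state8[i] == "-", " ",
                                   ss$state8[i])),
               character(1)))
  tf <- tempfile(fileext = ".dssp")
  writeLines(lines, tf)
  rt <- readDSSP(tf)
  expect_identical(rt$resno, ss$resno)
  expect_identical(rt$state8, ss$state8)
  expect_identical(rt$state3, ss$state3)
})

test_that("proline contributes no amide hydrogen", {
  he <- buildPeptide("helix", 12)
  pro <- he
  pro$resid[pro$resno == 6] <- "PRO"
  ssP <- assignSecStruct(pro)
  ssA <- assignSecStruct(he)
  ## removing the donor at residue 6 can only lose helical residues
  expect_lte(sum(ssP$state8 == "H"), sum(ssA$state8 == "H"))
  expect_false(identical(ssP$state8, ssA$state8))
})
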