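## Watson-Crick duplex assembly and groove-edge classification.

## Hydrogen-bond-capable base edge atoms exposed in each groove of B-DNA.
## Watson-Crick edge atoms (A N1, G N1, C N3, T N3, plus the pairing-face
## carbonyls/amines engaged in the pair itself) are deliberately absent:
## groove labels are only consumed to classify protein-DNA hydrogen bonds.
.GROOVE_TABLE <- list(
  DA = c(N6 = "major", N7 = "major", N3 = "minor"),
  DG = c(O6 = "major", N7 = "major", N3 = "minor", N2 = "minor"),
  DC = c(N4 = "major", O2 = "minor"),
  DT = c(O4 = "major", O2 = "minor"))

.COMPLEMENT <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")

#' Groove label of a DNA atom
#'
#' Maps a base atom to the B-DNA groove in which it is exposed: `"major"`
#' for A-N6/N7, G-O6/N7, C-N4 and T-O4; `"minor"` for A-N3, G-N3/N2,
#' C-O2 and T-O2; `"none"` for all other base atoms (Watson-Crick edge,
#' ring carbons) and for every sugar/phosphate atom.
#'
#' @param resName DNA residue code(s), one of DA/DC/DG/DT.
#' @param atomName atom name(s), PDB convention.
#' @return character vector of `"major"`, `"minor"` or `"none"`.
#' @examples
#' grooveOfAtom("DG", "O6")   # "major"
#' grooveOfAtom("DT", "O2")   # "minor"
#' grooveOfAtom("DA", "N1")   # "none" (Watson-Crick edge)
#' @export
grooveOfAtom <- function(resName, atomName) {
  if (length(resName) == 1 && length(atomName) > 1)
    resName <- rep(resName, length(atomName))
  bad <- !(resName %in% .DNA4)
  if (any(bad)) stop("unknown DNA residue code(s): ",
                     paste(unique(resName[bad]), collapse = ", "))
  mapply(function(rn, an) {
    tab <- .GROOVE_TABLE[[rn]]
    if (an %in% names(tab)) unname(tab[an]) else "none"
  }, resName, atomName, USE.NAMES = FALSE)
}

.resKey <- function(df) paste(df$chain, df$resno, df$insert, sep = "\r")

## per-residue table (chain, resno, insert, resid) for one DNA chain,
## ordered by author numbering
.dnaResidues <- function(atoms, chain) {
  a <- atoms[atoms$chain == chain & atoms$kind == "nucleotide", ,
             drop = FALSE]
  res <- unique(a[, c("chain", "resno", "insert", "resid")])
  res[order(res$resno, res$insert), , drop = FALSE]
}

.atomPos <- function(atoms, chain, resno, insert, elety) {
  hit <- atoms$chain == chain & atoms$resno == resno &
    atoms$insert == insert & atoms$elety == elety
  if (!any(hit)) return(NULL)
  as.numeric(atoms[which(hit)[1], c("x", "y", "z")])
}

#' Detect Watson-Crick base pairs between two DNA chains
#'
#' A pair is accepted when the two bases are identity-complementary
#' (A-T or G-C), the purine N1 to pyrimidine N3 distance is at most
#' `maxN1N3` (default 3.5 Angstrom) and the C1'-C1' distance lies in
#' `c1c1Range` (default 9.0-11.5 Angstrom).  Conflicts are resolved
#' greedily by smallest N1-N3 distance so that each base joins at most
#' one pair.  Non-canonical (Hoogsteen, mismatch) pairs are intentionally
#' not detected.
#'
#' @param x an \linkS4class{AnalysisUnit}, \linkS4class{ProteinDNAComplex}
#'   or atom data.frame containing the two chains.
#' @param chains character(2): the DNA chain ids (strand 1 first); taken
#'   from the unit when `x` is an \linkS4class{AnalysisUnit}.
#' @param maxN1N3,c1c1Range geometric thresholds in Angstrom.
#' @return a \linkS4class{DNADuplex}.
#' @export
detectBasePairs <- function(x, chains = NULL, maxN1N3 = 3.5,
                            c1c1Range = c(9.0, 11.5)) {
  atoms <- if (is.data.frame(x)) x else atomTable(x)
  if (is.null(chains)) {
    if (is(x, "AnalysisUnit")) chains <- x@dnaChains
    else stop("chains must be given")
  }
  s1 <- .dnaResidues(atoms, chains[1])
  s2 <- .dnaResidues(atoms, chains[2])
  if (nrow(s1) == 0 || nrow(s2) == 0)
    stop("chain without nucleotide residues among ",
         paste(chains, collapse = ","))
  ## every analyzable base needs C1' and its WC-edge nitrogen
  wcAtom <- function(resid) if (resid %in% c("DA", "DG")) "N1" else "N3"
  getRes <- function(res) {
    lapply(seq_len(nrow(res)), function(i) {
      r <- res[i, ]
      list(key = .resKey(r), resid = r$resid, resno = r$resno,
           insert = r$insert, chain = r$chain,
           c1 = .atomPos(atoms, r$chain, r$resno, r$insert, "C1'"),
           wc = .atomPos(atoms, r$chain, r$resno, r$insert,
                         wcAtom(r$resid)))
    })
  }
  r1 <- getRes(s1); r2 <- getRes(s2)
  missing <- c(
    vapply(r1, function(r) is.null(r$c1) || is.null(r$wc), logical(1)),
    vapply(r2, function(r) is.null(r$c1) || is.null(r$wc), logical(1)))
  if (any(missing)) {
    allr <- c(r1, r2)[missing]
    stop("residues lacking C1' or Watson-Crick edge atoms: ",
         paste(vapply(allr, function(r)
           paste0(r$resid, "-", r$resno, "(", r$chain, ")"),
           character(1)), collapse = ", "))
  }
  cand <- list()
  for (i in seq_along(r1)) for (j in seq_along(r2)) {
    a <- r1[[i]]; b <- r2[[j]]
    if (.COMPLEMENT[[a$resid]] != b$resid) next
    d_wc <- vnorm(a$wc - b$wc)
    if (d_wc > maxN1N3) next
    d_c1 <- vnorm(a$c1 - b$c1)
    if (d_c1 < c1c1Range[1] || d_c1 > c1c1Range[2]) next
    cand[[length(cand) + 1]] <- data.frame(
      i = i, j = j, n1n3 = d_wc, c1c1 = d_c1)
  }
  pairs <- data.frame(chain1 = character(), resno1 = integer(),
                      insert1 = character(), resid1 = character(),
                      chain2 = character(), resno2 = integer(),
                      insert2 = character(), resid2 = character(),
                      pair_type = character(), n1n3 = numeric(),
                      c1c1 = numeric(), stringsAsFactors = FALSE)
  if (length(cand) > 0) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$n1n3), , drop = FALSE]
    used_i <- used_j <- integer(0)
    for (k in seq_len(nrow(cand))) {
      ci <- cand$i[k]; cj <- cand$j[k]
      if (ci %in% used_i || cj %in% used_j) next
      used_i <- c(used_i, ci); used_j <- c(used_j, cj)
      a <- r1[[ci]]; b <- r2[[cj]]
      pt <- if (a$resid %in% c("DA", "DT")) "AT" else "GC"
      pairs <- rbind(pairs, data.frame(
        chain1 = a$chain, resno1 = a$resno, insert1 = a$insert,
        resid1 = a$resid, chain2 = b$chain, resno2 = b$resno,
        insert2 = b$insert, resid2 = b$resid, pair_type = pt,
        n1n3 = cand$n1n3[k], c1c1 = cand$c1c1[k],
        stringsAsFactors = FALSE))
    }
    pairs <- pairs[order(pairs$resno1, pairs$insert1), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  new("DNADuplex", strand1 = s1, strand2 = s2, pairs = pairs)
}
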