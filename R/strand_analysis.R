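## Strand-level bookkeeping: per-strand bond/base counts, dominant
## strand, 50/50 cases, engaged bases and base-pair hydrogen bonds.

.bondsOf <- function(x) {
  if (is(x, "HBondSet")) hbonds(x) else x
}

## map each bond's DNA residue to strand 1/2 of the duplex; errors when
## a bond references a residue absent from both strands
.bondStrand <- function(bonds, duplex) {
  k1 <- .resKey(duplex@strand1)
  k2 <- .resKey(duplex@strand2)
  kb <- paste(bonds$dna_chain, bonds$dna_resno, bonds$dna_insert,
              sep = "\r")
  strand <- ifelse(kb %in% k1, 1L, ifelse(kb %in% k2, 2L, NA_integer_))
  if (anyNA(strand)) {
    bad <- unique(paste0(bonds$dna_resid[is.na(strand)], "-",
                         bonds$dna_resno[is.na(strand)], "(",
                         bonds$dna_chain[is.na(strand)], ")"))
    stop("hydrogen bonds reference DNA residues absent from the ",
         "duplex: ", paste(bad, collapse = ", "))
  }
  strand
}

#' Base pairs in which both bases are engaged
#'
#' A Watson-Crick pair is returned when each of its two bases forms at
#' least one side-chain-base hydrogen bond that passes the groove
#' filter.  With `grooveFilter = "major"` only bonds to major-groove
#' edge atoms count, etc.; `"both"` accepts any bond to a base atom.
#'
#' @param bonds an \linkS4class{HBondSet} or its bond data.frame.
#' @param duplex a \linkS4class{DNADuplex}.
#' @param grooveFilter `"both"`, `"major"` or `"minor"`.
#' @return data.frame: the qualifying rows of `basePairs(duplex)` plus a
#'   `groove_scope` column.
#' @export
findBasePairHbonds <- function(bonds, duplex,
                               grooveFilter = c("both", "major",
                                                "minor")) {
  grooveFilter <- match.arg(grooveFilter)
  b <- .bondsOf(bonds)
  pairs <- basePairs(duplex)
  pairs$groove_scope <- rep(grooveFilter, nrow(pairs))
  if (nrow(pairs) == 0 || nrow(b) == 0)
    return(pairs[integer(0), , drop = FALSE])
  b <- b[b$class == "sidechain-base", , drop = FALSE]
  if (grooveFilter != "both")
    b <- b[b$groove == grooveFilter, , drop = FALSE]
  if (nrow(b) == 0) return(pairs[integer(0), , drop = FALSE])
  engagedKeys <- unique(paste(b$dna_chain, b$dna_resno, b$dna_insert,
                              sep = "\r"))
  key1 <- paste(pairs$chain1, pairs$resno1, pairs$insert1, sep = "\r")
  key2 <- paste(pairs$chain2, pairs$resno2, pairs$insert2, sep = "\r")
  hit <- key1 %in% engagedKeys & key2 %in% engagedKeys
  out <- pairs[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize the strand-level hydrogen bonding of one complex
#'
#' Computes the per-strand counts of side-chain-base hydrogen bonds
#' (overall and split by groove), the counts of all other protein-DNA
#' bonds, the engaged bases, the dominant strand with its percentage
#' contribution, both 50/50 flags (equal bond counts; equal engaged-base
#' counts in the major groove) and the base pairs in which both bases
#' are engaged.  Ties in the dominant-strand comparison are resolved to
#' strand 1, with `is_5050_bonds` set, since either strand could equally
#' be called dominant.  Complexes without any side-chain-base bond get
#' `has_scb = FALSE` and an `NA` percentage so that they can be excluded
#' from percentage-based group statistics.
#'
#' @param bonds an \linkS4class{HBondSet} or its bond data.frame.
#' @param duplex a \linkS4class{DNADuplex} for the same two chains.
#' @param pdbID,group identifiers copied into the summary.
#' @param detector `"geometric"` or `"energy"`; defaulted from the
#'   \linkS4class{HBondSet} when available.
#' @return a \linkS4class{ComplexSummary}.
#' @examples
#' fx <- buildFixture(fixtureSpec("GGAATTCC", data.frame(
#'   strand = c(1, 2), index = c(3, 3), groove = "major",
#'   type = "ASN", outcome = "bond")))
#' unit <- new("AnalysisUnit", atoms = fx$atoms, proteinChain = "A",
#'             proteinRange = integer(0), dnaChains = c("B", "C"),
#'             scope = "chain", pdbID = "FX", group = "HS",
#'             hydrogens = data.frame())
#' hb <- detectHBonds(unit)
#' summarizeComplex(hb, detectBasePairs(fx$atoms, c("B", "C")),
#'                  pdbID = "FX", group = "HS")
#' @export
summarizeComplex <- function(bonds, duplex, pdbID = "", group = "",
                             detector = NULL) {
  if (is.null(detector))
    detector <- if (is(bonds, "HBondSet")) bonds@method else "geometric"
  b <- .bondsOf(bonds)
  if (nrow(b) > 0) b$strand <- .bondStrand(b, duplex)
  scb <- b[b$class == "sidechain-base", , drop = FALSE]
  nonscb <- b[b$class != "sidechain-base", , drop = FALSE]
  cnt <- function(df, s) sum(df$strand == s)
  cntG <- function(df, s, g) sum(df$strand == s & df$groove == g)
  ## engaged bases: distinct base residues with >=1 sidechain-base bond
  engaged <- if (nrow(scb) == 0)
    data.frame(strand = integer(), chain = character(),
               resno = integer(), insert = character(),
               resid = character(), major = logical(),
               minor = logical(), stringsAsFactors = FALSE)
  else {
    key <- paste(scb$strand, scb$dna_chain, scb$dna_resno,
                 scb$dna_insert, sep = "\r")
    idx <- !duplicated(key)
    data.frame(
      strand = scb$strand[idx], chain = scb$dna_chain[idx],
      resno = scb$dna_resno[idx], insert = scb$dna_insert[idx],
      resid = scb$dna_resid[idx],
      major = vapply(key[idx], function(k)
        any(scb$groove[key == k] == "major"), logical(1)),
      minor = vapply(key[idx], function(k)
        any(scb$groove[key == k] == "minor"), logical(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  nb <- function(s) sum(engaged$strand == s)
  nbg <- function(s, col) sum(engaged$strand == s & engaged[[col]])
  bpBoth <- findBasePairHbonds(b, duplex, "both")
  bpMajor <- findBasePairHbonds(b, duplex, "major")
  bpHB <- rbind(bpBoth, bpMajor)
  n1 <- cnt(scb, 1); n2 <- cnt(scb, 2)
  counts <- c(
    n_scb_strand1 = n1, n_scb_strand2 = n2,
    n_scb_major_s1 = cntG(scb, 1, "major"),
    n_scb_major_s2 = cntG(scb, 2, "major"),
    n_scb_minor_s1 = cntG(scb, 1, "minor"),
    n_scb_minor_s2 = cntG(scb, 2, "minor"),
    n_scb_none_s1 = cntG(scb, 1, "none"),
    n_scb_none_s2 = cntG(scb, 2, "none"),
    n_nonscb_s1 = cnt(nonscb, 1), n_nonscb_s2 = cnt(nonscb, 2),
    n_bases_s1 = nb(1), n_bases_s2 = nb(2),
    n_bases_major_s1 = nbg(1, "major"),
    n_bases_major_s2 = nbg(2, "major"),
    n_bases_minor_s1 = nbg(1, "minor"),
    n_bases_minor_s2 = nbg(2, "minor"),
    n_bp_hb = nrow(bpBoth),
    n_bp_hb_GC = sum(bpBoth$pair_type == "GC"),
    n_bp_hb_AT = sum(bpBoth$pair_type == "AT"),
    n_bp_hb_major = nrow(bpMajor))
  eSum <- function(df) {
    if (detector != "energy") return(NA_real_)
    if (nrow(df) == 0) return(0)
    sum(df$energy)
  }
  energies <- c(e_scb_s1 = eSum(scb[scb$strand == 1, , drop = FALSE]),
                e_scb_s2 = eSum(scb[scb$strand == 2, , drop = FALSE]))
  hasSCB <- n1 + n2 > 0
  flags <- c(
    has_scb = hasSCB,
    is_5050_bonds = hasSCB && n1 == n2,
    is_5050_bases_major = nbg(1, "major") == nbg(2, "major") &&
      nbg(1, "major") > 0,
    one_strand_only = xor(n1 > 0, n2 > 0))
  new("ComplexSummary", pdbID = pdbID, group = group,
      detector = detector, counts = counts,
      dominantStrand = if (n1 >= n2) "strand1" else "strand2",
      pctDominant = if (hasSCB) 100 * max(n1, n2) / (n1 + n2)
      else NA_real_,
      flags = flags, engagedBases = engaged, basePairHB = bpHB,
      energies = energies)
}

#' Summarize a specificity group
#'
#' Aggregates \linkS4class{ComplexSummary} objects of one group and one
#' detector into group-level counts: complexes with side-chain-base
#' bonds, equal (50/50) contributions, dominant-strand contribution of
#' no more than 75\% (inclusive), one-strand-only cases, 50/50 cases in
#' the engaged-major-groove-base sense and the subset of those that also
#' have major-groove base-pair hydrogen bonds, complexes with at least
#' one / at least two engaged base pairs, and the GC/AT totals of
#' engaged pairs.  Percentage-based counts use only complexes that have
#' at least one side-chain-base hydrogen bond.
#'
#' @param summaries list of \linkS4class{ComplexSummary}; all must share
#'   `group` and `detector`.
#' @return a \linkS4class{GroupSummary}.
#' @export
summarizeGroup <- function(summaries) {
  if (length(summaries) > 0) {
    groups <- unique(vapply(summaries, function(s) s@group,
                            character(1)))
    dets <- unique(vapply(summaries, function(s) s@detector,
                          character(1)))
    if (length(groups) > 1)
      stop("summaries mix groups: ", paste(groups, collapse = ", "))
    if (length(dets) > 1)
      stop("summaries mix detectors: ", paste(dets, collapse = ", "))
  } else {
    groups <- ""; dets <- ""
  }
  fl <- function(s, f) unname(s@flags[f])
  co <- function(s, f) unname(s@counts[f])
  withSCB <- Filter(function(s) fl(s, "has_scb"), summaries)
  nInt <- function(pred) sum(vapply(withSCB, pred, logical(1)))
  counts <- c(
    n_complexes = length(summaries),
    n_complexes_with_scb = length(withSCB),
    n_equal_contribution = nInt(function(s) fl(s, "is_5050_bonds")),
    n_dominant_le75 = nInt(function(s) s@pctDominant <= 75),
    n_one_strand_only = nInt(function(s) fl(s, "one_strand_only")),
    n_5050_bases_major = nInt(function(s)
      fl(s, "is_5050_bases_major")),
    n_5050_with_bp = nInt(function(s)
      fl(s, "is_5050_bases_major") && co(s, "n_bp_hb_major") >= 1),
    n_with_ge1_bp = nInt(function(s) co(s, "n_bp_hb") >= 1),
    n_with_ge2_bp = nInt(function(s) co(s, "n_bp_hb") >= 2),
    total_bp_GC = sum(vapply(withSCB, co, numeric(1), "n_bp_hb_GC")),
    total_bp_AT = sum(vapply(withSCB, co, numeric(1), "n_bp_hb_AT")))
  pct <- vapply(withSCB, function(s) s@pctDominant, numeric(1))
  new("GroupSummary", group = groups, detector = dets, counts = counts,
      pctDominant = sort(pct, decreasing = TRUE))
}

#' Flatten complex summaries to a data.frame
#'
#' One row per \linkS4class{ComplexSummary}, with all counts, flags,
#' energies and the dominant-strand call, suitable for TSV export and
#' for feeding [compareGroups()].
#'
#' @param summaries list of \linkS4class{ComplexSummary}.
#' @return data.frame with one row per summary.
#' @export
complexSummaryTable <- function(summaries) {
  rows <- lapply(summaries, function(s) {
    data.frame(pdb_id = s@pdbID, group = s@group, detector = s@detector,
               as.list(s@counts), dominant_strand = s@dominantStrand,
               pct_dominant = s@pctDominant,
               as.list(s@energies),
               has_scb = unname(s@flags["has_scb"]),
               is_5050_bonds = unname(s@flags["is_5050_bonds"]),
               is_5050_bases_major =
                 unname(s@flags["is_5050_bases_major"]),
               one_strand_only = unname(s@flags["one_strand_only"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
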