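#' @import methods
NULL

## Canonical atom-table columns used by every class that carries coordinates.
## One row per (non-hydrogen) atom; author chain ids and residue numbering.
.atomCols <- c("chain", "resno", "insert", "resid", "elety", "elesy",
               "x", "y", "z", "o", "kind")

.validAtoms <- function(atoms) {
  if (!is.data.frame(atoms)) return("atoms must be a data.frame")
  miss <- setdiff(.atomCols, names(atoms))
  if (length(miss) > 0)
    return(paste("atoms is missing columns:", paste(miss, collapse = ", ")))
  if (nrow(atoms) > 0) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    if (!all(is.finite(xyz))) return("atom coordinates must be finite")
    if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE))
      return("occupancy must lie in [0, 1]")
    if (!all(atoms$kind %in% c("amino_acid", "nucleotide", "other")))
      return("kind must be amino_acid, nucleotide or other")
  }
  TRUE
}

#' ProteinDNAComplex: a parsed protein-DNA complex structure
#'
#' Holds the atom table of one coordinate model (hydrogens stripped,
#' alternate locations resolved) together with the chain role assignment
#' (protein / dna / other).  Created by [parseStructure()].
#'
#' @slot atoms data.frame with one row per heavy atom (columns `chain`,
#'   `resno`, `insert`, `resid`, `elety`, `elesy`, `x`, `y`, `z`, `o`,
#'   `kind`).
#' @slot chainRoles data.frame with columns `chain` and `role`.
#' @slot pdbID character scalar, identifier of the source entry.
#'
#' @seealso [classifyChains()], [applySelector()]
#' @export
setClass("ProteinDNAComplex",
  representation(atoms = "data.frame", chainRoles = "data.frame",
                 pdbID = "character"),
  validity = function(object) {
    v <- .validAtoms(object@atoms)
    if (!isTRUE(v)) return(v)
    if (nrow(object@atoms) == 0) return("empty model: no atoms")
    cr <- object@chainRoles
    if (!all(c("chain", "role") %in% names(cr)))
      return("chainRoles needs columns chain, role")
    if (!all(cr$role %in% c("protein", "dna", "other")))
      return("chain roles must be protein, dna or other")
    TRUE
  })

#' AnalysisUnit: the protein selection plus its DNA duplex partner chains
#'
#' The unit of analysis of the pipeline: one protein chain (optionally
#' restricted to a domain residue range) together with exactly two DNA
#' chains.  Produced by [applySelector()]; consumed by the hydrogen-bond
#' detectors.  The `hydrogens` slot is empty until
#' [placePolarHydrogens()] is run.
#'
#' @slot atoms data.frame of selected heavy atoms (same columns as in
#'   \linkS4class{ProteinDNAComplex}).
#' @slot proteinChain character scalar.
#' @slot proteinRange integer(2) inclusive author-numbering range, or
#'   integer(0) for whole-chain scope.
#' @slot dnaChains character(2), strand 1 then strand 2.
#' @slot scope `"domain"` or `"chain"`.
#' @slot pdbID,group character scalars (group is HS/MS/NS or "").
#' @slot hydrogens data.frame of placed polar hydrogens (columns `chain`,
#'   `resno`, `insert`, `resid`, `donor`, `hname`, `x`, `y`, `z`).
#' @export
setClass("AnalysisUnit",
  representation(atoms = "data.frame", proteinChain = "character",
                 proteinRange = "integer", dnaChains = "character",
                 scope = "character", pdbID = "character",
                 group = "character", hydrogens = "data.frame"),
  validity = function(object) {
    v <- .validAtoms(object@atoms)
    if (!isTRUE(v)) return(v)
    if (length(object@dnaChains) != 2) return("need exactly two DNA chains")
    if (!object@scope %in% c("domain", "chain"))
      return("scope must be 'domain' or 'chain'")
    if (length(object@proteinRange) %in% c(0L, 2L) == FALSE)
      return("proteinRange must be empty or length 2")
    TRUE
  })

#' DNADuplex: Watson-Crick paired double helix
#'
#' Result of [detectBasePairs()]: the two strands (ordered by author
#' numbering) and the detected canonical Watson-Crick base pairs.
#'
#' @slot strand1,strand2 data.frames with one row per nucleotide (columns
#'   `chain`, `resno`, `insert`, `resid`).
#' @slot pairs data.frame with one row per detected pair: residue keys of
#'   both partners, `pair_type` (`"AT"`/`"GC"`), `n1n3` and `c1c1`
#'   distances in Angstrom.
#' @export
setClass("DNADuplex",
  representation(strand1 = "data.frame", strand2 = "data.frame",
                 pairs = "data.frame"),
  validity = function(object) {
    p <- object@pairs
    if (nrow(p) > 0) {
      if (!all(p$pair_type %in% c("AT", "GC")))
        return("pair_type must be AT or GC")
      if (anyDuplicated(p$resno1) || anyDuplicated(p$resno2))
        return("each base may participate in at most one pair")
    }
    TRUE
  })

#' HBondSet: detected protein-DNA hydrogen bonds
#'
#' One row per hydrogen bond between the protein selection and the DNA of
#' an \linkS4class{AnalysisUnit}, produced by [detectHBonds()].  Each bond
#' records donor and acceptor identity, geometry, the Mayo 12-10 energy
#' (energy detector only), the interaction class and the groove label.
#'
#' @slot bonds data.frame; see [detectHBonds()] for the column contract.
#' @slot method `"geometric"` or `"energy"`.
#' @slot params the [detectorParams()] list used.
#' @export
setClass("HBondSet",
  representation(bonds = "data.frame", method = "character",
                 params = "list"),
  validity = function(object) {
    if (!object@method %in% c("geometric", "energy"))
      return("method must be geometric or energy")
    b <- object@bonds
    if (nrow(b) > 0) {
      if (!all(b$class %in% c("sidechain-base", "sidechain-backbone",
                              "mainchain-base", "mainchain-backbone")))
        return("invalid interaction class")
      if (!all(b$groove %in% c("major", "minor", "none")))
        return("invalid groove label")
      if (any(b$groove != "none" & !b$dna_base))
        return("groove labels are only allowed on base atoms")
    }
    TRUE
  })

#' ComplexSummary: per-complex strand-level bookkeeping
#'
#' Output of [summarizeComplex()]: counts of side-chain-base hydrogen
#' bonds per DNA strand (overall and split by groove), engaged bases,
#' dominant strand, 50/50 flags and base-pair hydrogen bonds.
#'
#' @slot pdbID,group,detector character scalars.
#' @slot counts named numeric vector of per-strand bond/base counts.
#' @slot dominantStrand `"strand1"` or `"strand2"` (ties resolved to
#'   strand1 with the 50/50 flag set).
#' @slot pctDominant percentage in \[50, 100\] (NA when no bonds).
#' @slot flags named logical vector (`has_scb`, `is_5050_bonds`,
#'   `is_5050_bases_major`, `one_strand_only`).
#' @slot engagedBases data.frame of engaged bases (strand, residue key,
#'   groove flags).
#' @slot basePairHB data.frame of base pairs in which both bases are
#'   engaged (subset of the duplex pairs, plus `groove_scope`).
#' @slot energies named numeric: summed side-chain-base bond energy per
#'   strand (NA for the geometric detector).
#' @export
setClass("ComplexSummary",
  representation(pdbID = "character", group = "character",
                 detector = "character", counts = "numeric",
                 dominantStrand = "character", pctDominant = "numeric",
                 flags = "logical", engagedBases = "data.frame",
                 basePairHB = "data.frame", energies = "numeric"))

#' GroupSummary: group-level strand-contribution bookkeeping
#'
#' Output of [summarizeGroup()]: counts of 50/50 cases, dominant-strand
#' categories, one-strand-only cases and engaged base pairs over all
#' complexes of one specificity group, plus the descending
#' dominant-strand percentage vector used for strand-contribution plots.
#'
#' @slot group,detector character scalars.
#' @slot counts named numeric vector of group-level counts.
#' @slot pctDominant numeric vector of per-complex dominant-strand
#'   percentages, descending (complexes without side-chain-base bonds
#'   excluded).
#' @export
setClass("GroupSummary",
  representation(group = "character", detector = "character",
                 counts = "numeric", pctDominant = "numeric"),
  validity = function(object) {
    if (any(object@pctDominant < 50 | object@pctDominant > 100,
            na.rm = TRUE))
      return("dominant-strand percentages must lie in [50, 100]")
    if (is.unsorted(rev(object@pctDominant)))
      return("pctDominant must be in descending order")
    TRUE
  })

setMethod("show", "ProteinDNAComplex", function(object) {
  cr <- object@chainRoles
  cat("ProteinDNAComplex", object@pdbID, "\n")
  cat(" ", nrow(object@atoms), "atoms,", nrow(cr), "chains:",
      paste0(cr$chain, "(", cr$role, ")", collapse = " "), "\n")
})

setMethod("show", "AnalysisUnit", function(object) {
  rng <- if (length(object@proteinRange) == 2)
    paste0(" (", object@proteinRange[1], "-", object@proteinRange[2], ")")
  else ""
  cat("AnalysisUnit", object@pdbID,
      paste0("[", object@group, "]"), "\n")
  cat("  protein chain", paste0(object@proteinChain, rng),
      "+ DNA chains", paste(object@dnaChains, collapse = ","),
      paste0("(scope=", object@scope, ")"), "\n")
  cat(" ", nrow(object@atoms), "heavy atoms,",
      nrow(object@hydrogens), "placed hydrogens\n")
})

setMethod("show", "DNADuplex", function(object) {
  cat("DNADuplex:", nrow(object@strand1), "+", nrow(object@strand2),
      "nt,", nrow(object@pairs), "Watson-Crick pairs\n")
})

setMethod("show", "HBondSet", function(object) {
  b <- object@bonds
  cat("HBondSet (", object@method, " detector): ", nrow(b), " bonds",
      sep = "")
  if (nrow(b) > 0)
    cat(" [", sum(b$class == "sidechain-base"), " sidechain-base]",
        sep = "")
  cat("\n")
})

setMethod("show", "ComplexSummary", function(object) {
  cat("ComplexSummary", object@pdbID, paste0("[", object@group, "]"),
      object@detector, "\n")
  cat("  scb bonds strand1/strand2:", object@counts["n_scb_strand1"],
      "/", object@counts["n_scb_strand2"],
      " dominant:", object@dominantStrand,
      sprintf("(%.1f%%)", object@pctDominant), "\n")
  cat("  50/50 bonds:", object@flags["is_5050_bonds"],
      " 50/50 bases (major):", object@flags["is_5050_bases_major"],
      " base-pair HBs:", unname(object@counts["n_bp_hb"]), "\n")
})

setMethod("show", "GroupSummary", function(object) {
  co <- object@counts
  cat("GroupSummary", paste0("[", object@group, "]"), object@detector,
      "\n")
  cat(" ", co["n_complexes"], "complexes (", co["n_complexes_with_scb"],
      "with sidechain-base bonds )\n")
  cat("  equal contribution:", co["n_equal_contribution"],
      " dominant <=75%:", co["n_dominant_le75"],
      " one strand only:", co["n_one_strand_only"], "\n")
  cat("  50/50 (major-groove bases):", co["n_5050_bases_major"],
      " with base-pair HBs:", co["n_5050_with_bp"], "\n")
})

#' Accessors for strandHB objects
#'
#' `hbonds()` returns the per-bond data.frame of an
#' \linkS4class{HBondSet}; `basePairs()` the pair table of a
#' \linkS4class{DNADuplex}; `atomTable()` the heavy-atom table of a
#' \linkS4class{ProteinDNAComplex} or \linkS4class{AnalysisUnit};
#' `chainRoles()` the chain role table.
#'
#' @param x the object.
#' @return a data.frame.
#' @export
setGeneric("hbonds", function(x) standardGeneric("hbonds"))

#' @rdname hbonds
#' @export
setMethod("hbonds", "HBondSet", function(x) x@bonds)

#' @rdname hbonds
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' @rdname hbonds
#' @export
setMethod("basePairs", "DNADuplex", function(x) x@pairs)

#' @rdname hbonds
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname hbonds
#' @export
setMethod("atomTable", "ProteinDNAComplex", function(x) x@atoms)

#' @rdname hbonds
#' @export
setMethod("atomTable", "AnalysisUnit", function(x) x@atoms)

#' @rdname hbonds
#' @export
setGeneric("chainRoles", function(x) standardGeneric("chainRoles"))

#' @rdname hbonds
#' @export
setMethod("chainRoles", "ProteinDNAComplex", function(x) x@chainRoles)
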