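## Coordinate input, chain classification and selection.
## Parsing of PDB/mmCIF files is delegated to bio3d; everything downstream
## works on the canonical atom table defined in AllClasses.R.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")
.DNA4 <- c("DA", "DC", "DG", "DT")
.WATER <- c("HOH", "WAT", "DOD", "H2O")

## base-ring/edge atom names (per base); everything else in a nucleotide is
## sugar/phosphate backbone
.BASE_ATOMS <- list(
  DA = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  DG = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  DC = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  DT = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C5M", "C7", "C6"))

.MAINCHAIN_PROT <- c("N", "CA", "C", "O", "OXT")

.residueKind <- function(resid) {
  ifelse(resid %in% .AA3, "amino_acid",
         ifelse(resid %in% .DNA4, "nucleotide", "other"))
}

.isBaseAtom <- function(resid, elety) {
  out <- logical(length(resid))
  for (rn in .DNA4) {
    sel <- resid == rn
    if (any(sel)) out[sel] <- elety[sel] %in% .BASE_ATOMS[[rn]]
  }
  out
}

## normalise atom naming across PDB dialects
.normAtomName <- function(elety) {
  elety <- gsub("\\*", "'", elety)
  map <- c(OP1 = "O1P", OP2 = "O2P", OP3 = "O3P", C7 = "C5M")
  hit <- elety %in% names(map)
  elety[hit] <- map[elety[hit]]
  elety
}

#' Read a protein-DNA complex structure
#'
#' Parses a PDB or mmCIF coordinate file into a
#' \linkS4class{ProteinDNAComplex}.  Hydrogens present in the file are
#' discarded (the package re-places polar hydrogens at ideal geometry);
#' for alternate-location groups only the highest-occupancy conformer is
#' kept, ties broken by the alphabetically first altloc id.  Waters and
#' ligands are retained with `kind = "other"`.  Single-letter
#' deoxynucleotide codes (A/C/G/T) are normalised to DA/DC/DG/DT; other
#' modified nucleotides can be mapped to a parent base via `baseMap`,
#' else they stay `kind = "other"` and are excluded from base-level
#' analysis.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param baseMap optional named character vector mapping modified
#'   residue codes to parent bases, e.g. `c("5CM" = "DC")`.
#' @return a \linkS4class{ProteinDNAComplex}.
#' @examples
#' fx <- buildFixture(fixtureSpec("GAATTC"))
#' pdb <- file.path(tempdir(), "fx.pdb")
#' writeFixture(fx, pdb)
#' parseStructure(pdb)
#' @export
parseStructure <- function(path, format = c("auto", "pdb", "cif"),
                           baseMap = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format,
                             ": ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty model in ", path)
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)))
    elesy <- substr(gsub("[^A-Za-z].*", "", gsub("^[0-9]", "", at$elety)), 1, 1)
  elesy[is.na(elesy) | elesy == ""] <-
    substr(gsub("^[0-9']+", "", at$elety[is.na(elesy) | elesy == ""]), 1, 1)
  keep <- !(toupper(elesy) %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elesy <- elesy[keep]

  resid <- trimws(at$resid)
  onelet <- resid %in% c("A", "C", "G", "T")
  resid[onelet] <- paste0("D", resid[onelet])
  if (!is.null(baseMap)) {
    hit <- resid %in% names(baseMap)
    resid[hit] <- baseMap[resid[hit]]
  }
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    resid = resid,
    elety = .normAtomName(trimws(at$elety)),
    elesy = toupper(trimws(elesy)),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, pmin(1, pmax(0, at$o))),
    alt = ifelse(is.na(at$alt) | at$alt == "", "", as.character(at$alt)),
    stringsAsFactors = FALSE)

  ## altloc resolution: highest occupancy, alphabetical tie-break
  if (any(atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
                 sep = "\r")
    ord <- order(key, -atoms$o, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(match(paste(atoms$chain, atoms$resno, atoms$insert,
                                     atoms$elety, sep = "\r"), key)), ,
                   drop = FALSE]
    rownames(atoms) <- NULL
  }
  atoms$alt <- NULL
  atoms$kind <- .residueKind(atoms$resid)
  obj <- new("ProteinDNAComplex", atoms = atoms,
             chainRoles = data.frame(chain = character(),
                                     role = character()),
             pdbID = sub("\\.(pdb|ent|cif|mmcif)$", "",
                         basename(path), ignore.case = TRUE))
  obj@chainRoles <- classifyChains(obj)
  validObject(obj)
  obj
}

#' Classify chains as protein, DNA or other
#'
#' A chain is `protein` if at least `threshold` (default 80%) of its
#' non-water residues are amino acids, `dna` if at least that fraction
#' are deoxynucleotides, and `other` otherwise (waters, ligands, hybrids).
#'
#' @param x a \linkS4class{ProteinDNAComplex} or atom data.frame.
#' @param threshold majority fraction, default 0.8.
#' @return data.frame with columns `chain`, `role`.
#' @export
classifyChains <- function(x, threshold = 0.8) {
  atoms <- if (is(x, "ProteinDNAComplex")) x@atoms else x
  res <- unique(atoms[, c("chain", "resno", "insert", "resid", "kind")])
  res <- res[!(res$resid %in% .WATER), , drop = FALSE]
  chains <- unique(atoms$chain)
  role <- vapply(chains, function(ch) {
    r <- res[res$chain == ch, , drop = FALSE]
    if (nrow(r) == 0) return("other")
    fa <- mean(r$kind == "amino_acid")
    fd <- mean(r$kind == "nucleotide")
    if (fa >= threshold) "protein" else if (fd >= threshold) "dna"
    else "other"
  }, character(1))
  data.frame(chain = chains, role = unname(role), stringsAsFactors = FALSE)
}

#' Parse a protein selector string
#'
#' Selectors follow the `"D"` (whole chain) or `"D:3-226"` (inclusive
#' author-numbered residue range) convention of dataset manifests.
#'
#' @param sel selector string.
#' @return list with elements `chain` and `range` (integer(2) or NULL).
#' @export
parseSelector <- function(sel) {
  sel <- trimws(sel)
  if (grepl(":", sel, fixed = TRUE)) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    rng <- suppressWarnings(
      as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]]))
    if (length(rng) != 2 || any(is.na(rng)) || rng[2] < rng[1])
      stop("malformed selector range in '", sel, "'")
    list(chain = parts[1], range = rng)
  } else {
    list(chain = sel, range = NULL)
  }
}

#' Read a dataset manifest
#'
#' The manifest is a TSV with header columns `pdb_id`, `group`
#' (HS/MS/NS), `protein_selector` (e.g. `"A"` or `"D:3-226"`),
#' `dna_chains` (e.g. `"E,H"`) and `scope` (`domain`/`chain`).
#'
#' @param path TSV file path.
#' @return data.frame, one row per complex, with the selector parsed into
#'   `chain`, `range_lo`, `range_hi` columns.
#' @export
readManifest <- function(path) {
  m <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("pdb_id", "group", "protein_selector", "dna_chains", "scope")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0)
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  sels <- lapply(m$protein_selector, parseSelector)
  m$chain <- vapply(sels, function(s) s$chain, character(1))
  m$range_lo <- vapply(sels, function(s)
    if (is.null(s$range)) NA_integer_ else s$range[1], integer(1))
  m$range_hi <- vapply(sels, function(s)
    if (is.null(s$range)) NA_integer_ else s$range[2], integer(1))
  bad <- !(m$group %in% c("HS", "MS", "NS"))
  if (any(bad)) stop("unknown group label(s): ",
                     paste(unique(m$group[bad]), collapse = ", "))
  m
}

#' Select the analysis unit of a complex
#'
#' Restricts a parsed structure to one protein chain (whole chain or a
#' domain residue range) plus two DNA chains, yielding the
#' \linkS4class{AnalysisUnit} all downstream counting operates on.
#' Residues outside a domain range are excluded entirely.
#'
#' @param x a \linkS4class{ProteinDNAComplex}.
#' @param proteinSelector selector string (see [parseSelector()]).
#' @param dnaChains character(2): the two DNA chain ids (strand 1 first).
#' @param scope `"domain"` (apply the range) or `"chain"` (ignore it).
#' @param group specificity group label, default `""`.
#' @return an \linkS4class{AnalysisUnit}.
#' @export
applySelector <- function(x, proteinSelector, dnaChains,
                          scope = c("domain", "chain"), group = "") {
  stopifnot(is(x, "ProteinDNAComplex"))
  scope <- match.arg(scope)
  sel <- parseSelector(proteinSelector)
  dnaChains <- trimws(strsplit(paste(dnaChains, collapse = ","),
                               ",")[[1]])
  if (length(dnaChains) != 2)
    stop("need exactly two DNA chain ids, got: ",
         paste(dnaChains, collapse = ","))
  atoms <- x@atoms
  if (!sel$chain %in% atoms$chain)
    stop("protein chain '", sel$chain, "' not present in ", x@pdbID)
  missing_dna <- setdiff(dnaChains, atoms$chain)
  if (length(missing_dna) > 0)
    stop("DNA chain(s) not present: ", paste(missing_dna, collapse = ","))
  prot <- atoms[atoms$chain == sel$chain & atoms$kind == "amino_acid", ,
                drop = FALSE]
  rng <- integer(0)
  if (scope == "domain" && !is.null(sel$range)) {
    rng <- as.integer(sel$range)
    prot <- prot[prot$resno >= rng[1] & prot$resno <= rng[2], ,
                 drop = FALSE]
  }
  if (nrow(prot) == 0)
    stop("empty protein selection for ", proteinSelector, " in ", x@pdbID)
  dna <- atoms[atoms$chain %in% dnaChains & atoms$kind == "nucleotide", ,
               drop = FALSE]
  if (nrow(dna) == 0) stop("no nucleotide atoms in chains ",
                           paste(dnaChains, collapse = ","))
  unit <- new("AnalysisUnit",
              atoms = rbind(prot, dna),
              proteinChain = sel$chain, proteinRange = rng,
              dnaChains = dnaChains, scope = scope,
              pdbID = x@pdbID, group = group,
              hydrogens = data.frame())
  validObject(unit)
  unit
}

#' Write an atom table as a PDB file
#'
#' Minimal fixed-width ATOM-record writer used for fixtures and
#' round-trip checks.
#'
#' @param x \linkS4class{ProteinDNAComplex}, \linkS4class{AnalysisUnit}
#'   or canonical atom data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeComplexPDB <- function(x, path) {
  atoms <- if (is.data.frame(x)) x else atomTable(x)
  name <- ifelse(nchar(atoms$elety) >= 4, atoms$elety,
                 paste0(" ", atoms$elety))
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)) %% 100000, name, atoms$resid, atoms$chain,
    atoms$resno, ifelse(atoms$insert == "", " ", atoms$insert),
    atoms$x, atoms$y, atoms$z, atoms$o, 0, atoms$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
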