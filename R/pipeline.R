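## Orchestration: run the full strand-level analysis over a manifest of
## protein-DNA complexes and emit the per-bond, per-complex, per-group,
## propensity and comparison tables.

.findStructureFile <- function(structureDir, pdbID) {
  for (ext in c(".pdb", ".ent", ".cif", ".mmcif")) {
    p <- file.path(structureDir, paste0(pdbID, ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

## dominant-strand percentage from a pair of per-strand counts
.pctDom <- function(a, b) {
  if (a + b <= 0) return(NA_real_)
  100 * max(a, b) / (a + b)
}

## per-complex metric vectors for the group comparisons
.complexMetrics <- function(tab) {
  data.frame(
    pdb_id = tab$pdb_id, group = tab$group, detector = tab$detector,
    pct_dominant_both = tab$pct_dominant,
    pct_dominant_major = mapply(.pctDom, tab$n_scb_major_s1,
                                tab$n_scb_major_s2),
    pct_dominant_minor = mapply(.pctDom, tab$n_scb_minor_s1,
                                tab$n_scb_minor_s2),
    pct_dominant_nonscb = mapply(.pctDom, tab$n_nonscb_s1,
                                 tab$n_nonscb_s2),
    pct_bases_dominant = mapply(.pctDom, tab$n_bases_s1,
                                tab$n_bases_s2),
    stringsAsFactors = FALSE)
}

## pooled 3-state labels of a residue set within one complex
.stateOf <- function(resSet, ssTab) {
  if (nrow(resSet) == 0) return(character(0))
  key <- paste(resSet$chain, resSet$resno, resSet$insert, sep = "\r")
  skey <- paste(ssTab$chain, ssTab$resno, ssTab$insert, sep = "\r")
  st <- ssTab$state3[match(key, skey)]
  st[!is.na(st)]
}

#' Run the full analysis pipeline
#'
#' For every manifest entry and every requested detector: parse the
#' structure, apply the protein/DNA selection, assemble the
#' Watson-Crick duplex, detect hydrogen bonds and summarize strand
#' contributions.  Afterwards, per specificity group: group summaries,
#' pooled secondary-structure propensity tables (base-contacting and
#' side-chain-base-bonding residues against three backgrounds) and the
#' HS-vs-MS statistical comparisons of the dominant-strand percentages
#' (all grooves, major only, minor only, the non-side-chain-base
#' control, and engaged-base percentages).  Entries whose structure
#' file is missing or that fail are skipped with a logged message; if
#' no entry is analyzable the run fails.  Complexes without any
#' side-chain-base bond are kept in the per-complex table (flagged
#' `has_scb = FALSE`) but excluded from percentage-based statistics.
#'
#' @param manifest manifest path or the data.frame from
#'   [readManifest()].
#' @param structureDir directory holding `<pdb_id>.pdb` / `.cif` files.
#' @param detectors subset of `c("geometric", "energy")`.
#' @param scope `NULL` to use each entry's manifest scope, or
#'   `"domain"`/`"chain"` to override for all entries.
#' @param outDir optional output directory; when given, TSV tables
#'   (`bonds`, `complexes`, `groups`, `metrics`, `propensity`,
#'   `comparisons`), a JSON run report and the run log are written.
#' @param params named list of [detectorParams()] overrides per
#'   detector.
#' @return (invisibly when `outDir` is set) a list with `summaries`
#'   (ComplexSummary objects), `bonds`, `complexes`, `groups`,
#'   `metrics`, `propensity`, `comparisons` data.frames and the `log`
#'   character vector.
#' @export
runPipeline <- function(manifest, structureDir,
                        detectors = c("geometric", "energy"),
                        scope = NULL, outDir = NULL, params = list()) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  detectors <- match.arg(detectors, c("geometric", "energy"),
                         several.ok = TRUE)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  summaries <- list()
  bondRows <- list()
  propRows <- list()   # per-complex residue state pools
  for (i in seq_len(nrow(manifest))) {
    e <- manifest[i, ]
    sc <- if (is.null(scope)) e$scope else scope
    path <- .findStructureFile(structureDir, e$pdb_id)
    if (is.null(path)) {
      note("SKIP ", e$pdb_id, ": structure file not found in ",
           structureDir)
      next
    }
    res <- tryCatch({
      cpx <- parseStructure(path)
      unit <- applySelector(cpx, e$protein_selector, e$dna_chains,
                            scope = sc, group = e$group)
      dup <- detectBasePairs(unit)
      ss <- assignSecStruct(atomTable(unit),
                            chains = unit@proteinChain)
      bc <- baseContactingResidues(unit)
      protRes <- unique(atomTable(unit)[
        atomTable(unit)$kind == "amino_acid",
        c("chain", "resno", "insert", "resid")])
      perDet <- list()
      for (det in detectors) {
        p <- if (!is.null(params[[det]])) params[[det]]
        else detectorParams(det)
        hb <- suppressWarnings(detectHBonds(unit, p))
        b <- hbonds(hb)
        if (nrow(b) > 0)
          bondRows[[length(bondRows) + 1]] <- cbind(
            pdb_id = e$pdb_id, group = e$group, detector = det, b,
            stringsAsFactors = FALSE)
        s <- summarizeComplex(hb, dup, pdbID = e$pdb_id,
                              group = e$group, detector = det)
        protCols <- c("prot_chain", "prot_resno", "prot_insert")
        scbRes <- unique(b[b$class == "sidechain-base", protCols])
        scbResMajor <- unique(b[b$class == "sidechain-base" &
                                  b$groove == "major", protCols])
        anyRes <- unique(b[, protCols])
        names(scbRes) <- names(scbResMajor) <- names(anyRes) <-
          c("chain", "resno", "insert")
        perDet[[det]] <- list(
          summary = s,
          scb_state = .stateOf(scbRes, ss),
          scb_state_major = .stateOf(scbResMajor, ss),
          dnahb_state = .stateOf(anyRes, ss))
        summaries[[length(summaries) + 1]] <- s
      }
      propRows[[length(propRows) + 1]] <- list(
        pdb_id = e$pdb_id, group = e$group,
        all_state = .stateOf(protRes, ss),
        bc_state = .stateOf(bc, ss),
        perDet = perDet)
      note("OK   ", e$pdb_id, " (", e$group, ", scope=", sc, ")")
      TRUE
    }, error = function(err) {
      note("SKIP ", e$pdb_id, ": ", conditionMessage(err))
      FALSE
    })
  }
  if (length(summaries) == 0)
    stop("no analyzable manifest entries; log:\n",
         paste(log, collapse = "\n"))
  bonds <- if (length(bondRows)) do.call(rbind, bondRows)
  else data.frame()
  complexes <- complexSummaryTable(summaries)
  metrics <- .complexMetrics(complexes)
  ## group summaries per (group, detector)
  groupRows <- list()
  groupObjs <- list()
  for (g in unique(complexes$group)) for (det in detectors) {
    sub <- Filter(function(s) s@group == g && s@detector == det,
                  summaries)
    if (length(sub) == 0) next
    gs <- summarizeGroup(sub)
    groupObjs[[paste(g, det, sep = ".")]] <- gs
    groupRows[[length(groupRows) + 1]] <- data.frame(
      group = g, detector = det, as.list(gs@counts),
      stringsAsFactors = FALSE)
  }
  groups <- do.call(rbind, groupRows)
  ## propensity tables, pooled over the complexes of each group
  propensity <- .propensityTables(propRows, detectors)
  ## HS vs MS comparisons per detector and metric
  comparisons <- .groupComparisons(metrics, note)
  result <- list(summaries = summaries, groupSummaries = groupObjs,
                 bonds = bonds, complexes = complexes, groups = groups,
                 metrics = metrics, propensity = propensity,
                 comparisons = comparisons, log = log)
  if (!is.null(outDir)) {
    .writeBundle(result, outDir)
    return(invisible(result))
  }
  result
}

.propensityTables <- function(propRows, detectors) {
  out <- list()
  add <- function(group, detector, fg, bg, fgL, bgL, scope) {
    if (length(fg) == 0 || length(bg) == 0) return()
    tab <- computePropensity(fg, bg, fgLabel = fgL, bgLabel = bgL,
                             grooveScope = scope)
    out[[length(out) + 1]] <<- cbind(group = group, detector = detector,
                                     tab, stringsAsFactors = FALSE)
  }
  for (g in unique(vapply(propRows, `[[`, character(1), "group"))) {
    rows <- Filter(function(r) r$group == g, propRows)
    allS <- unlist(lapply(rows, `[[`, "all_state"))
    bcS <- unlist(lapply(rows, `[[`, "bc_state"))
    add(g, "-", bcS, allS, "base_contacting", "all_domain_residues",
        "both")
    for (det in detectors) {
      scbS <- unlist(lapply(rows, function(r)
        r$perDet[[det]]$scb_state))
      scbM <- unlist(lapply(rows, function(r)
        r$perDet[[det]]$scb_state_major))
      dnaS <- unlist(lapply(rows, function(r)
        r$perDet[[det]]$dnahb_state))
      add(g, det, scbS, allS, "scb_residues", "all_domain_residues",
          "both")
      add(g, det, scbS, bcS, "scb_residues", "base_contacting", "both")
      add(g, det, scbS, dnaS, "scb_residues", "all_dna_hbond_residues",
          "both")
      add(g, det, scbM, allS, "scb_residues", "all_domain_residues",
          "major")
    }
  }
  if (length(out) == 0) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.groupComparisons <- function(metrics, note) {
  out <- list()
  cols <- c("pct_dominant_both", "pct_dominant_major",
            "pct_dominant_minor", "pct_dominant_nonscb",
            "pct_bases_dominant")
  for (det in unique(metrics$detector)) for (m in cols) {
    a <- metrics[metrics$detector == det & metrics$group == "HS", m]
    b <- metrics[metrics$detector == det & metrics$group == "MS", m]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3 || length(b) < 3) {
      note("comparison skipped (", det, ", ", m,
           "): fewer than 3 observations per group")
      next
    }
    cmp <- compareGroups(a, b, metric = m, groupA = "HS",
                         groupB = "MS")
    out[[length(out) + 1]] <- cbind(detector = det, cmp,
                                    stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.writeBundle <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (is.null(df) || nrow(df) == 0) return()
    utils::write.table(df, file.path(outDir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(result$bonds, "bonds")
  wr(result$complexes, "complexes")
  wr(result$groups, "groups")
  wr(result$metrics, "metrics")
  wr(result$propensity, "propensity")
  wr(result$comparisons, "comparisons")
  writeLines(result$log, file.path(outDir, "run.log"))
  report <- list(
    n_entries_ok = sum(grepl("^OK", result$log)),
    n_entries_skipped = sum(grepl("^SKIP", result$log)),
    groups = result$groups,
    comparisons = result$comparisons)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(NULL)
}
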