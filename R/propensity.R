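## Secondary-structure propensities of DNA-interacting residues:
## foreground/background relative frequencies per 3-state type.

#' Protein residues contacting DNA bases
#'
#' A residue qualifies when at least one of its side-chain heavy atoms
#' (everything except N, CA, C, O, OXT) lies within `cutoff` Angstrom
#' (default 4.5) of at least one heavy atom of a DNA base (ring/edge
#' atoms only, never sugar or phosphate).  Glycine, whose only
#' non-backbone atom is CA, can never qualify.
#'
#' @param x an \linkS4class{AnalysisUnit} (or canonical atom
#'   data.frame) containing both the protein selection and the DNA.
#' @param cutoff contact distance in Angstrom.
#' @return data.frame of qualifying residues: `chain`, `resno`,
#'   `insert`, `resid`, `min_dist`.
#' @export
baseContactingResidues <- function(x, cutoff = 4.5) {
  atoms <- if (is.data.frame(x)) x else atomTable(x)
  prot <- atoms[atoms$kind == "amino_acid" &
                  !(atoms$elety %in% .MAINCHAIN_PROT), , drop = FALSE]
  dna <- atoms[atoms$kind == "nucleotide", , drop = FALSE]
  dna <- dna[.isBaseAtom(dna$resid, dna$elety), , drop = FALSE]
  empty <- data.frame(chain = character(), resno = integer(),
                      insert = character(), resid = character(),
                      min_dist = numeric(), stringsAsFactors = FALSE)
  if (nrow(prot) == 0 || nrow(dna) == 0) return(empty)
  baseXYZ <- as.matrix(dna[, c("x", "y", "z")])
  key <- .resKey(prot)
  rows <- list()
  for (k in unique(key)) {
    sub <- prot[key == k, , drop = FALSE]
    d <- min(vapply(seq_len(nrow(sub)), function(i)
      .minDistTo(as.numeric(sub[i, c("x", "y", "z")]), baseXYZ),
      numeric(1)))
    if (d <= cutoff)
      rows[[length(rows) + 1]] <- data.frame(
        chain = sub$chain[1], resno = sub$resno[1],
        insert = sub$insert[1], resid = sub$resid[1], min_dist = d,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Secondary-structure propensity of a residue set
#'
#' For each 3-state type `s`, the propensity is the ratio of relative
#' frequencies `[count_fg(s)/|fg|] / [count_bg(s)/|bg|]`.  Values above
#' 1 mean the foreground is enriched in that type relative to the
#' background.  When a type is absent from the background but present
#' in the foreground the ratio is undefined; it is reported as `Inf`
#' and flagged.
#'
#' @param fg,bg character vectors of 3-state labels
#'   (`helix`/`strand`/`coil`), one entry per residue occurrence.
#' @param fgLabel,bgLabel,grooveScope descriptive labels copied into
#'   the result.
#' @return data.frame with one row per 3-state type: counts, relative
#'   frequencies, `propensity` and `undefined` flag.
#' @examples
#' computePropensity(c("helix", "helix", "coil", "coil"),
#'                   c("helix", "helix", "strand", "coil"))
#' @export
computePropensity <- function(fg, bg, fgLabel = "", bgLabel = "",
                              grooveScope = "both") {
  states <- c("helix", "strand", "coil")
  stopifnot(all(fg %in% states), all(bg %in% states))
  if (length(fg) == 0) stop("empty foreground residue set")
  if (length(bg) == 0) stop("empty background residue set")
  cfg <- vapply(states, function(s) sum(fg == s), numeric(1))
  cbg <- vapply(states, function(s) sum(bg == s), numeric(1))
  ffg <- cfg / length(fg)
  fbg <- cbg / length(bg)
  prop <- ifelse(fbg > 0, ffg / fbg, ifelse(ffg > 0, Inf, NaN))
  data.frame(fg_label = fgLabel, bg_label = bgLabel,
             groove_scope = grooveScope, state3 = states,
             count_fg = cfg, count_bg = cbg, freq_fg = ffg,
             freq_bg = fbg, propensity = prop,
             undefined = fbg == 0, stringsAsFactors = FALSE,
             row.names = NULL)
}
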