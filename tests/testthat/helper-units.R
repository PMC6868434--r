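## Shared helpers for constructing analysis units from synthetic fixtures.

unitFromFixture <- function(fx, pdbID = "FX", group = "HS") {
  dnaChains <- if (!is.null(fx$dnaChains)) fx$dnaChains else c("B", "C")
  new("AnalysisUnit", atoms = fx$atoms, proteinChain = "A",
      proteinRange = integer(0), dnaChains = dnaChains, scope = "chain",
      pdbID = pdbID, group = group, hydrogens = data.frame())
}

extdataFile <- function(...) {
  p <- system.file("extdata", ..., package = "strandHB")
  if (!nzchar(p)) stop("extdata file not found: ", file.path(...))
  p
}

## minimal hand-written bond rows for arithmetic tests of the strand
## bookkeeping (only the columns summarizeComplex consumes)
mkBonds <- function(chain, resno, groove = "major",
                    class = "sidechain-base", energy = NA_real_) {
  n <- max(length(chain), length(resno), length(groove), length(class))
  data.frame(dna_chain = rep_len(chain, n),
             dna_resno = rep_len(as.integer(resno), n),
             dna_insert = "",
             dna_resid = "DA",
             class = rep_len(class, n),
             groove = rep_len(groove, n),
             energy = rep_len(energy, n),
             stringsAsFactors = FALSE)
}
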