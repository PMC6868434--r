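## Kabsch-Sander backbone hydrogen bonds, 8-state secondary-structure
## assignment and the 3-state reduction (helix / strand / coil).

.KS_Q <- 0.084 * 332   # partial-charge coupling constant, kcal/mol * A

#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic energy of a backbone C=O (acceptor residue) against an
#' H-N (donor residue):
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol.
#' A backbone hydrogen bond exists when `E < -0.5` kcal/mol.
#'
#' @param C,O carbonyl carbon and oxygen positions (numeric length 3).
#' @param N,H amide nitrogen and hydrogen positions.
#' @return energy in kcal/mol.
#' @examples
#' ## N/H mirror-symmetric about the C-O axis: r_ON = r_OH and
#' ## r_CH = r_CN, so the terms cancel exactly
#' ksEnergy(C = c(0, 0, 0), O = c(1, 0, 0),
#'          N = c(3, 2, 0), H = c(3, -2, 0))  # 0
#' @export
ksEnergy <- function(C, O, N, H) {
  .KS_Q * (1 / vnorm(O - N) + 1 / vnorm(C - H) -
             1 / vnorm(O - H) - 1 / vnorm(C - N))
}

## backbone table for one chain: one row per residue in author order,
## with N/CA/C/O coordinates (NA when missing)
.backboneTable <- function(atoms, chain) {
  a <- atoms[atoms$chain == chain & atoms$kind == "amino_acid", ,
             drop = FALSE]
  res <- unique(a[, c("chain", "resno", "insert", "resid")])
  res <- res[order(res$resno, res$insert), , drop = FALSE]
  get <- function(i, name) {
    p <- .atomPos(a, res$chain[i], res$resno[i], res$insert[i], name)
    if (is.null(p)) c(NA_real_, NA_real_, NA_real_) else p
  }
  n <- nrow(res)
  bb <- list(N = matrix(NA_real_, n, 3), CA = matrix(NA_real_, n, 3),
             C = matrix(NA_real_, n, 3), O = matrix(NA_real_, n, 3))
  for (i in seq_len(n)) for (nm in names(bb))
    bb[[nm]][i, ] <- get(i, nm)
  list(res = res, bb = bb)
}

## DSSP amide-hydrogen placement: H sits 1.0 Angstrom from N along the
## direction of the preceding residue's C -> O bond reversed
.amideH <- function(bb, i, newSeg) {
  if (i == 1 || newSeg[i]) return(NULL)
  Cp <- bb$C[i - 1, ]; Op <- bb$O[i - 1, ]
  N <- bb$N[i, ]
  if (anyNA(c(Cp, Op, N))) return(NULL)
  N + vunit(Cp - Op)
}

#' Assign secondary structure to protein chains
#'
#' Re-implementation of the Kabsch-Sander (DSSP) hydrogen-bond-based
#' assignment.  Amide hydrogens are placed along the preceding C=O
#' direction; a backbone hydrogen bond is a C=O / H-N pair with
#' [ksEnergy()] below -0.5 kcal/mol.  N-turns at offsets 3/4/5 yield
#' 3-10/alpha/pi helices (G/H/I, two consecutive turns required);
#' parallel and antiparallel bridges yield isolated bridges (B) or
#' ladders (E); remaining turn residues get T and tight bends (kappa >
#' 70 degrees) get S.  States are resolved per residue with priority
#' H > E > B > G > I > T > S; everything else is `-`.  Consecutive
#' residues whose CA-CA distance exceeds 4.5 Angstrom are treated as a
#' chain break.  Bulge-linked ladder merging is not performed, and
#' chains shorter than 3 residues are assigned all coil.
#'
#' @param atoms canonical atom data.frame (or an object with an
#'   [atomTable()] method) holding the protein coordinates.
#' @param chains chains to assign; default all chains with amino-acid
#'   residues.
#' @return data.frame with one row per residue: `chain`, `resno`,
#'   `insert`, `resid`, `state8`, `state3`.
#' @examples
#' helix <- buildPeptide("helix", 12)
#' table(assignSecStruct(helix)$state3)
#' @export
assignSecStruct <- function(atoms, chains = NULL) {
  if (!is.data.frame(atoms)) atoms <- atomTable(atoms)
  if (is.null(chains))
    chains <- unique(atoms$chain[atoms$kind == "amino_acid"])
  tabs <- lapply(chains, function(ch) .backboneTable(atoms, ch))
  res <- do.call(rbind, lapply(tabs, `[[`, "res"))
  bb <- list(N = do.call(rbind, lapply(tabs, function(t) t$bb$N)),
             CA = do.call(rbind, lapply(tabs, function(t) t$bb$CA)),
             C = do.call(rbind, lapply(tabs, function(t) t$bb$C)),
             O = do.call(rbind, lapply(tabs, function(t) t$bb$O)))
  n <- nrow(res)
  state8 <- rep("-", n)
  if (n >= 3) {
    ## segment starts: first residue per chain, or CA-CA break > 4.5 A
    chainOf <- res$chain
    newSeg <- c(TRUE, vapply(2:n, function(i) {
      chainOf[i] != chainOf[i - 1] ||
        anyNA(bb$CA[i, ]) || anyNA(bb$CA[i - 1, ]) ||
        vnorm(bb$CA[i, ] - bb$CA[i - 1, ]) > 4.5
    }, logical(1)))
    segId <- cumsum(newSeg)
    H <- lapply(seq_len(n), function(i) {
      if (res$resid[i] == "PRO") return(NULL)   # no amide hydrogen
      .amideH(bb, i, newSeg)
    })
    ## hb[a, d]: C=O of residue a accepts from H-N of residue d
    hb <- matrix(FALSE, n, n)
    for (a in seq_len(n)) {
      if (anyNA(bb$C[a, ]) || anyNA(bb$O[a, ])) next
      for (d in seq_len(n)) {
        if (d == a || is.null(H[[d]]) || anyNA(bb$N[d, ])) next
        if (vnorm(bb$CA[a, ] - bb$CA[d, ]) > 9.0) next
        e <- ksEnergy(bb$C[a, ], bb$O[a, ], bb$N[d, ], H[[d]])
        hb[a, d] <- e < -0.5
      }
    }
    sameSeg <- function(i, j) segId[i] == segId[j]
    turn <- function(nn) vapply(seq_len(n), function(i)
      i + nn <= n && sameSeg(i, i + nn) && hb[i, i + nn], logical(1))
    t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
    ## helices, strongest first (H over G over I on overlap)
    for (hdef in list(list(t4, 4L, "H"), list(t3, 3L, "G"),
                      list(t5, 5L, "I"))) {
      tn <- hdef[[1]]; nn <- hdef[[2]]; sym <- hdef[[3]]
      for (i in 2:n) if (tn[i - 1] && tn[i])
        for (k in i:min(n, i + nn - 1))
          if (state8[k] == "-") state8[k] <- sym
    }
    ## bridges: parallel / antiparallel, |i-j| > 2
    bridge <- matrix(FALSE, n, n)
    for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
      if (abs(i - j) <= 2) next
      par <- (hb[i - 1, j] && hb[j, i + 1]) ||
        (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
        (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) bridge[i, j] <- TRUE
    }
    inLadder <- rep(FALSE, n); inBridge <- rep(FALSE, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (!bridge[i, j]) next
      inBridge[i] <- TRUE
      ## ladder: a consecutive bridge at (i+1, j+1) or (i+1, j-1)
      lad <- (i > 1 && ((j > 1 && bridge[i - 1, j - 1]) ||
                          (j < n && bridge[i - 1, j + 1]))) ||
        (i < n && ((j > 1 && bridge[i + 1, j - 1]) ||
                     (j < n && bridge[i + 1, j + 1])))
      if (lad) inLadder[i] <- TRUE
    }
    for (i in seq_len(n)) {
      if (state8[i] == "H") next            # priority H > E > B
      if (inLadder[i]) state8[i] <- "E"
      else if (inBridge[i]) state8[i] <- "B"
    }
    ## remaining turn residues
    for (nn in 3:5) {
      tn <- list(t3, t4, t5)[[nn - 2]]
      for (i in seq_len(n)) if (tn[i])
        for (k in (i + 1):(i + nn - 1))
          if (k <= n && state8[k] == "-") state8[k] <- "T"
    }
    ## bends: kappa(CA[i-2], CA[i], CA[i+2]) > 70 degrees
    if (n >= 5) for (i in 3:(n - 2)) {
      if (state8[i] != "-") next
      if (!sameSeg(i - 2, i + 2)) next
      u <- bb$CA[i, ] - bb$CA[i - 2, ]
      v <- bb$CA[i + 2, ] - bb$CA[i, ]
      if (anyNA(c(u, v))) next
      kappa <- vangle(bb$CA[i - 2, ], bb$CA[i, ], bb$CA[i + 2, ])
      if (180 - kappa > 70) state8[i] <- "S"
    }
  }
  out <- data.frame(res, state8 = state8,
                    state3 = reduceSS(state8),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Reduce 8-state secondary structure to 3 types
#'
#' `H`, `G` and `I` map to `"helix"`; `E` and `B` to `"strand"`; every
#' other symbol (including `T`, `S`, `P` and `-`) to `"coil"`.
#'
#' @param state8 character vector of one-letter states.
#' @return character vector over `helix`/`strand`/`coil`.
#' @export
reduceSS <- function(state8) {
  ifelse(state8 %in% c("H", "G", "I"), "helix",
         ifelse(state8 %in% c("E", "B"), "strand", "coil"))
}

#' Read a classic DSSP output file
#'
#' Parses the per-residue block of a classic-format `.dssp` file (the
#' text format with the `#  RESIDUE AA STRUCTURE` header) and returns
#' the assigned states together with their 3-state reduction.  Chain
#' break records (`!`) are skipped.
#'
#' @param path path to the `.dssp` file.
#' @return data.frame: `chain`, `resno`, `insert`, `aa`, `state8`,
#'   `state3`.
#' @export
readDSSP <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("not a classic DSSP file: ", path)
  body <- lines[(hdr[1] + 1):length(lines)]
  rows <- list()
  for (ln in body) {
    if (nchar(ln) < 17) next
    aa <- substr(ln, 14, 14)
    if (aa == "!") next                      # chain break record
    resno <- suppressWarnings(as.integer(substr(ln, 6, 10)))
    if (is.na(resno)) next
    icode <- trimws(substr(ln, 11, 11))
    chain <- trimws(substr(ln, 12, 12))
    ss <- substr(ln, 17, 17)
    if (ss == " ") ss <- "-"
    rows[[length(rows) + 1]] <- data.frame(
      chain = chain, resno = resno, insert = icode, aa = aa,
      state8 = ss, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no residue records in ", path)
  out$state3 <- reduceSS(out$state8)
  rownames(out) <- NULL
  out
}
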