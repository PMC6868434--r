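## Protein-DNA hydrogen-bond detection.
##
## Two interchangeable detectors share one donor/acceptor chemistry table
## and one polar-hydrogen builder:
##   * geometric - HBPLUS-style distance/angle criteria;
##   * energy    - Mayo 12-10 potential with hybridization-dependent
##                 angular factors, bonds kept at E <= -0.6 kcal/mol.

## ---- donor / acceptor chemistry tables -------------------------------
## placement types: fixed1 = one in-plane H bisecting two heavy neighbours;
## fixed2 = two in-plane H at +/-120 deg from the single heavy neighbour
## (plane from `ref`); rot1/rot3 = rotatable OH / NH3 oriented toward the
## nearest acceptor; bb = backbone amide (neighbours CA and preceding C).

.DONOR_DEF <- list(
  ARG = list(list(atom = "NE",  nH = 1, hyb = "sp2", type = "fixed1", nb = c("CD", "CZ")),
             list(atom = "NH1", nH = 2, hyb = "sp2", type = "fixed2", nb = "CZ", ref = "NE"),
             list(atom = "NH2", nH = 2, hyb = "sp2", type = "fixed2", nb = "CZ", ref = "NE")),
  LYS = list(list(atom = "NZ",  nH = 3, hyb = "sp3", type = "rot3",   nb = "CE")),
  HIS = list(list(atom = "ND1", nH = 1, hyb = "sp2", type = "fixed1", nb = c("CG", "CE1")),
             list(atom = "NE2", nH = 1, hyb = "sp2", type = "fixed1", nb = c("CD2", "CE1"))),
  ASN = list(list(atom = "ND2", nH = 2, hyb = "sp2", type = "fixed2", nb = "CG", ref = "OD1")),
  GLN = list(list(atom = "NE2", nH = 2, hyb = "sp2", type = "fixed2", nb = "CD", ref = "OE1")),
  SER = list(list(atom = "OG",  nH = 1, hyb = "sp3", type = "rot1",   nb = "CB")),
  THR = list(list(atom = "OG1", nH = 1, hyb = "sp3", type = "rot1",   nb = "CB")),
  TYR = list(list(atom = "OH",  nH = 1, hyb = "sp2", type = "rot1",   nb = "CZ")),
  TRP = list(list(atom = "NE1", nH = 1, hyb = "sp2", type = "fixed1", nb = c("CD1", "CE2"))),
  DA  = list(list(atom = "N6",  nH = 2, hyb = "sp2", type = "fixed2", nb = "C6", ref = "N1")),
  DC  = list(list(atom = "N4",  nH = 2, hyb = "sp2", type = "fixed2", nb = "C4", ref = "N3")),
  DG  = list(list(atom = "N1",  nH = 1, hyb = "sp2", type = "fixed1", nb = c("C2", "C6")),
             list(atom = "N2",  nH = 2, hyb = "sp2", type = "fixed2", nb = "C2", ref = "N3")),
  DT  = list(list(atom = "N3",  nH = 1, hyb = "sp2", type = "fixed1", nb = c("C2", "C4"))))

## acceptors: ant = heavy antecedent(s) used for the H-A-antecedent angle;
## ref = third atom defining the sp2 plane (out-of-plane term)
.ACCEPTOR_DEF <- list(
  ASP = list(list(atom = "OD1", hyb = "sp2", ant = "CG", ref = "OD2"),
             list(atom = "OD2", hyb = "sp2", ant = "CG", ref = "OD1")),
  GLU = list(list(atom = "OE1", hyb = "sp2", ant = "CD", ref = "OE2"),
             list(atom = "OE2", hyb = "sp2", ant = "CD", ref = "OE1")),
  ASN = list(list(atom = "OD1", hyb = "sp2", ant = "CG", ref = "ND2")),
  GLN = list(list(atom = "OE1", hyb = "sp2", ant = "CD", ref = "NE2")),
  SER = list(list(atom = "OG",  hyb = "sp3", ant = "CB")),
  THR = list(list(atom = "OG1", hyb = "sp3", ant = "CB")),
  TYR = list(list(atom = "OH",  hyb = "sp2", ant = "CZ", ref = "CE1")),
  HIS = list(list(atom = "ND1", hyb = "sp2", ant = c("CG", "CE1"), ref = "CE1"),
             list(atom = "NE2", hyb = "sp2", ant = c("CD2", "CE1"), ref = "CE1")),
  DA  = list(list(atom = "N1",  hyb = "sp2", ant = c("C2", "C6"), ref = "C6"),
             list(atom = "N3",  hyb = "sp2", ant = c("C2", "C4"), ref = "C4"),
             list(atom = "N7",  hyb = "sp2", ant = c("C5", "C8"), ref = "C5")),
  DC  = list(list(atom = "O2",  hyb = "sp2", ant = "C2", ref = "N1"),
             list(atom = "N3",  hyb = "sp2", ant = c("C2", "C4"), ref = "C4")),
  DG  = list(list(atom = "O6",  hyb = "sp2", ant = "C6", ref = "C5"),
             list(atom = "N3",  hyb = "sp2", ant = c("C2", "C4"), ref = "C4"),
             list(atom = "N7",  hyb = "sp2", ant = c("C5", "C8"), ref = "C5")),
  DT  = list(list(atom = "O2",  hyb = "sp2", ant = "C2", ref = "N1"),
             list(atom = "O4",  hyb = "sp2", ant = "C4", ref = "C5")))

.DNA_BB_ACC <- list(
  list(atom = "O1P", hyb = "sp3", ant = "P"),
  list(atom = "O2P", hyb = "sp3", ant = "P"),
  list(atom = "O3'", hyb = "sp3", ant = "C3'"),
  list(atom = "O5'", hyb = "sp3", ant = "C5'"),
  list(atom = "O4'", hyb = "sp3", ant = "C1'"))

#' Donor and acceptor definition tables
#'
#' Returns the chemistry tables driving hydrogen placement and bond
#' detection: every polar side-chain group of Arg, Lys, His, Asn, Gln,
#' Ser, Thr, Tyr, Trp (donors) and Asp, Glu, Asn, Gln, Ser, Thr, Tyr,
#' His (acceptors); protein backbone N (donor, except proline) and O
#' (acceptor); all base-edge donors/acceptors of DA/DC/DG/DT; and DNA
#' phosphate (O1P/O2P), ester (O3'/O5') and sugar-ring (O4') oxygens as
#' acceptors.  Histidine nitrogens appear in both tables; protonation is
#' resolved per candidate bond (at most one bond per His nitrogen and
#' partner atom).
#'
#' @return list with elements `donors` and `acceptors` (nested lists
#'   keyed by residue code).
#' @export
donorAcceptorTables <- function() {
  list(donors = .DONOR_DEF,
       acceptors = c(.ACCEPTOR_DEF, list(.dna_backbone = .DNA_BB_ACC)))
}

#' Detector parameter set
#'
#' Bundles the tunable thresholds of both hydrogen-bond detectors.  The
#' geometric defaults are the documented HBPLUS defaults
#' (donor-acceptor <= 3.9 Angstrom, hydrogen-acceptor <= 2.5 Angstrom,
#' D-H-A and H-A-antecedent angles >= 90 degrees); the energy detector
#' uses the Mayo 12-10 well (depth `V0` = 8 kcal/mol at `d0` = 2.8
#' Angstrom) with bonds kept at `energyCutoff` = -0.6 kcal/mol.
#'
#' @param method `"geometric"` or `"energy"`.
#' @param maxDA,maxHA distance limits, Angstrom.
#' @param minDHA,minHAAA angle minima, degrees.
#' @param energyCutoff acceptance threshold, kcal/mol (must be negative).
#' @param V0,d0 well depth (kcal/mol) and equilibrium donor-acceptor
#'   distance (Angstrom) of the 12-10 potential.
#' @param prescreenDA candidate donor-acceptor distance cap for the
#'   energy detector, Angstrom.
#' @return named list of class `detectorParams`.
#' @export
detectorParams <- function(method = c("geometric", "energy"),
                           maxDA = 3.9, maxHA = 2.5, minDHA = 90,
                           minHAAA = 90, energyCutoff = -0.6,
                           V0 = 8.0, d0 = 2.8, prescreenDA = 4.5) {
  method <- match.arg(method)
  stopifnot(maxDA > 0, maxHA > 0, d0 > 0, V0 > 0, energyCutoff < 0)
  structure(list(method = method, maxDA = maxDA, maxHA = maxHA,
                 minDHA = minDHA, minHAAA = minHAAA,
                 energyCutoff = energyCutoff, V0 = V0, d0 = d0,
                 prescreenDA = prescreenDA),
            class = "detectorParams")
}

## ---- candidate extraction --------------------------------------------

.residueSplit <- function(atoms) {
  split(seq_len(nrow(atoms)),
        paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r"))
}

.atomInRes <- function(atoms, rows, name) {
  hit <- rows[atoms$elety[rows] == name]
  if (length(hit) == 0) return(NULL)
  as.numeric(atoms[hit[1], c("x", "y", "z")])
}

## enumerate donor heavy atoms (with placement recipes resolved to
## coordinates) and acceptor atoms present in the atom table
.collectDonors <- function(atoms) {
  out <- list()
  byres <- .residueSplit(atoms)
  ## order residues within chain for backbone connectivity
  resinfo <- do.call(rbind, lapply(names(byres), function(k) {
    i <- byres[[k]][1]
    data.frame(key = k, chain = atoms$chain[i], resno = atoms$resno[i],
               insert = atoms$insert[i], resid = atoms$resid[i],
               kind = atoms$kind[i], stringsAsFactors = FALSE)
  }))
  for (k in seq_len(nrow(resinfo))) {
    ri <- resinfo[k, ]
    rows <- byres[[ri$key]]
    defs <- .DONOR_DEF[[ri$resid]]
    if (!is.null(defs)) {
      for (d in defs) {
        D <- .atomInRes(atoms, rows, d$atom)
        if (is.null(D)) next
        nbs <- lapply(d$nb, function(nm) .atomInRes(atoms, rows, nm))
        if (any(vapply(nbs, is.null, logical(1)))) {
          warning("donor ", d$atom, " of ", ri$resid, "-", ri$resno,
                  "(", ri$chain, ") skipped: missing antecedent",
                  call. = FALSE)
          next
        }
        ref <- if (!is.null(d$ref)) .atomInRes(atoms, rows, d$ref) else NULL
        if (d$type == "fixed2" && is.null(ref)) {
          warning("donor ", d$atom, " of ", ri$resid, "-", ri$resno,
                  "(", ri$chain, ") skipped: missing plane reference",
                  call. = FALSE)
          next
        }
        out[[length(out) + 1]] <- list(
          chain = ri$chain, resno = ri$resno, insert = ri$insert,
          resid = ri$resid, atom = d$atom, hyb = d$hyb, type = d$type,
          side = if (ri$kind == "amino_acid") "protein" else "dna",
          D = D, nbs = nbs, ref = ref, olen = if (substr(d$atom, 1, 1) == "O") 0.96 else 1.00,
          nH = d$nH)
      }
    }
    ## backbone amide donor (not proline, needs preceding C)
    if (ri$kind == "amino_acid" && ri$resid != "PRO") {
      N <- .atomInRes(atoms, rows, "N")
      CA <- .atomInRes(atoms, rows, "CA")
      prevC <- NULL
      if (!is.null(N)) {
        prev <- which(resinfo$chain == ri$chain & resinfo$kind == "amino_acid" &
                        resinfo$resno < ri$resno)
        if (length(prev) > 0) {
          prev <- prev[which.max(resinfo$resno[prev])]
          pc <- .atomInRes(atoms, byres[[resinfo$key[prev]]], "C")
          if (!is.null(pc) && vnorm(pc - N) <= 2.5) prevC <- pc
        }
      }
      if (!is.null(N) && !is.null(CA) && !is.null(prevC)) {
        out[[length(out) + 1]] <- list(
          chain = ri$chain, resno = ri$resno, insert = ri$insert,
          resid = ri$resid, atom = "N", hyb = "sp2", type = "fixed1",
          side = "protein", D = N, nbs = list(CA, prevC), ref = NULL,
          olen = 1.00, nH = 1)
      }
    }
  }
  out
}

.collectAcceptors <- function(atoms) {
  out <- list()
  byres <- .residueSplit(atoms)
  for (k in names(byres)) {
    rows <- byres[[k]]
    i <- rows[1]
    resid <- atoms$resid[i]; kind <- atoms$kind[i]
    defs <- .ACCEPTOR_DEF[[resid]]
    if (kind == "nucleotide") defs <- c(defs, .DNA_BB_ACC)
    if (kind == "amino_acid") {
      defs <- c(defs, list(list(atom = "O", hyb = "sp2", ant = "C",
                                ref = "CA"),
                           list(atom = "OXT", hyb = "sp2", ant = "C",
                                ref = "O")))
    }
    if (is.null(defs)) next
    for (a in defs) {
      A <- .atomInRes(atoms, rows, a$atom)
      if (is.null(A)) next
      ants <- lapply(a$ant, function(nm) .atomInRes(atoms, rows, nm))
      ants <- ants[!vapply(ants, is.null, logical(1))]
      if (length(ants) == 0) next
      ref <- if (!is.null(a$ref)) .atomInRes(atoms, rows, a$ref) else NULL
      out[[length(out) + 1]] <- list(
        chain = atoms$chain[i], resno = atoms$resno[i],
        insert = atoms$insert[i], resid = resid, atom = a$atom,
        hyb = a$hyb, side = if (kind == "amino_acid") "protein" else "dna",
        A = A, ants = ants, ref = ref)
    }
  }
  out
}

## ---- hydrogen placement ----------------------------------------------

.placeDonorH <- function(d, accPos) {
  D <- d$D; len <- d$olen
  hs <- switch(d$type,
    fixed1 = {
      u <- -(vunit(d$nbs[[1]] - D) + vunit(d$nbs[[2]] - D))
      list(D + len * vunit(u))
    },
    fixed2 = {
      C <- d$nbs[[1]]
      n <- vunit(vcross(D - C, d$ref - C))
      u <- vunit(C - D)
      R1 <- rotmat(n, 120); R2 <- rotmat(n, -120)
      list(D + len * as.numeric(R1 %*% u),
           D + len * as.numeric(R2 %*% u))
    },
    rot1 = {
      C <- d$nbs[[1]]
      u <- vunit(C - D)
      tgt <- .nearestAcceptor(D, accPos, d)
      w <- if (is.null(tgt)) vperp(u) else {
        t <- vunit(tgt - D)
        wv <- t - sum(t * u) * u
        if (vnorm(wv) < 1e-6) vperp(u) else vunit(wv)
      }
      th <- 109.5 * pi / 180
      list(D + len * (cos(th) * u + sin(th) * w))
    },
    rot3 = {
      C <- d$nbs[[1]]
      u <- vunit(D - C)            # axis CE -> NZ
      tgt <- .nearestAcceptor(D, accPos, d)
      w <- if (is.null(tgt)) vperp(u) else {
        t <- vunit(tgt - D)
        wv <- t - sum(t * u) * u
        if (vnorm(wv) < 1e-6) vperp(u) else vunit(wv)
      }
      v2 <- vcross(u, w)
      th <- (180 - 109.5) * pi / 180   # angle between axis and N-H
      lapply(c(0, 120, 240), function(phi) {
        p <- phi * pi / 180
        D + len * (cos(th) * u +
                     sin(th) * (cos(p) * w + sin(p) * v2))
      })
    })
  hs
}

.nearestAcceptor <- function(D, accPos, d) {
  if (nrow(accPos) == 0) return(NULL)
  same <- accPos$chain == d$chain & accPos$resno == d$resno &
    accPos$insert == d$insert
  cand <- accPos[!same, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  dx <- cand$x - D[1]; dy <- cand$y - D[2]; dz <- cand$z - D[3]
  dd <- sqrt(dx * dx + dy * dy + dz * dz)
  i <- which.min(dd)
  if (dd[i] > 3.9) return(NULL)
  as.numeric(cand[i, c("x", "y", "z")])
}

#' Place polar hydrogens at ideal geometry
#'
#' X-ray structures generally lack hydrogens; this builds them on every
#' donor of [donorAcceptorTables()] present in the unit.  Fixed-geometry
#' donors (backbone amide, Arg, Asn, Gln, Trp, His, base amines and ring
#' imines) get in-plane hydrogens at ideal angles (N-H 1.00, O-H 0.96
#' Angstrom); rotatable donors (Ser/Thr/Tyr hydroxyl, Lys ammonium) are
#' oriented toward the nearest acceptor within 3.9 Angstrom, falling back
#' to a deterministic staggered position.  Donors with missing antecedent
#' atoms are skipped with a warning.
#'
#' @param unit an \linkS4class{AnalysisUnit}.
#' @return the unit with its `hydrogens` slot filled.
#' @export
placePolarHydrogens <- function(unit) {
  stopifnot(is(unit, "AnalysisUnit"))
  atoms <- unit@atoms
  donors <- .collectDonors(atoms)
  accs <- .collectAcceptors(atoms)
  accPos <- if (length(accs) == 0)
    data.frame(chain = character(), resno = integer(),
               insert = character(), x = numeric(), y = numeric(),
               z = numeric())
  else do.call(rbind, lapply(accs, function(a)
    data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
               x = a$A[1], y = a$A[2], z = a$A[3],
               stringsAsFactors = FALSE)))
  rows <- list()
  for (d in donors) {
    hs <- .placeDonorH(d, accPos)
    for (i in seq_along(hs)) {
      rows[[length(rows) + 1]] <- data.frame(
        chain = d$chain, resno = d$resno, insert = d$insert,
        resid = d$resid, donor = d$atom,
        hname = if (length(hs) == 1) "H" else paste0("H", i),
        x = hs[[i]][1], y = hs[[i]][2], z = hs[[i]][3],
        stringsAsFactors = FALSE)
    }
  }
  unit@hydrogens <- if (length(rows) == 0) data.frame()
  else do.call(rbind, rows)
  unit
}

## ---- energy model ----------------------------------------------------

#' Mayo 12-10 hydrogen-bond energy
#'
#' `V0 * (5 (d0/d)^12 - 6 (d0/d)^10) * angularFactor`: the distance is
#' the donor-acceptor separation, so the well minimum of -`V0` kcal/mol
#' sits at `d = d0` (2.8 Angstrom for N/O donors and acceptors) when the
#' angular factor is 1.
#'
#' @param dDA donor-acceptor distance(s), Angstrom.
#' @param angularFactor dimensionless factor in \[0, 1\].
#' @param params a [detectorParams()] list (for `V0`, `d0`).
#' @return energy in kcal/mol (vectorised over `dDA`).
#' @examples
#' mayoEnergy(2.8)          # -8 kcal/mol, the well minimum
#' mayoEnergy(10)           # essentially zero
#' @export
mayoEnergy <- function(dDA, angularFactor = 1,
                       params = detectorParams("energy")) {
  stopifnot(all(dDA > 0))
  r <- params$d0 / dDA
  params$V0 * (5 * r^12 - 6 * r^10) * angularFactor
}

## hybridization-dependent angular factor of the 12-10 potential.
## theta = D-H-A angle, phi = H-A-antecedent angle (degrees); gamma =
## out-of-plane angle of the H->A direction w.r.t. an sp2 acceptor plane.
.mayoAngular <- function(donHyb, accHyb, theta, phi, gamma = 0) {
  ct2 <- cos(theta * pi / 180)^2
  if (donHyb == "sp3" && accHyb == "sp3") {
    ct2 * cos((phi - 109.5) * pi / 180)^2
  } else if (donHyb == "sp3" && accHyb == "sp2") {
    ct2 * cos(phi * pi / 180)^2
  } else if (donHyb == "sp2" && accHyb == "sp3") {
    ct2 * ct2
  } else {
    ct2 * cos(max(phi, gamma) * pi / 180)^2
  }
}

## ---- detection -------------------------------------------------------

.classifyPair <- function(protResid, protAtom, dnaResid, dnaAtom) {
  sc <- !(protAtom %in% .MAINCHAIN_PROT)
  base <- .isBaseAtom(dnaResid, dnaAtom)
  class <- paste0(if (sc) "sidechain" else "mainchain", "-",
                  if (base) "base" else "backbone")
  groove <- if (base) grooveOfAtom(dnaResid, dnaAtom) else "none"
  list(class = class, groove = groove, base = base)
}

.emptyBonds <- function() {
  data.frame(don_chain = character(), don_resno = integer(),
             don_insert = character(), don_resid = character(),
             don_atom = character(), h_name = character(),
             acc_chain = character(), acc_resno = integer(),
             acc_insert = character(), acc_resid = character(),
             acc_atom = character(), d_da = numeric(), d_ha = numeric(),
             theta_dha = numeric(), energy = numeric(),
             donor_side = character(), prot_chain = character(),
             prot_resno = integer(), prot_insert = character(),
             prot_resid = character(), prot_atom = character(), dna_chain = character(),
             dna_resno = integer(), dna_insert = character(),
             dna_resid = character(), dna_atom = character(),
             dna_base = logical(), class = character(),
             groove = character(), stringsAsFactors = FALSE)
}

.detectCore <- function(unit, params) {
  if (nrow(unit@hydrogens) == 0) unit <- placePolarHydrogens(unit)
  atoms <- unit@atoms
  donors <- suppressWarnings(.collectDonors(atoms))
  accs <- .collectAcceptors(atoms)
  hyd <- unit@hydrogens
  maxd <- if (params$method == "geometric") params$maxDA
  else params$prescreenDA
  bonds <- list()
  for (d in donors) {
    hsel <- hyd$chain == d$chain & hyd$resno == d$resno &
      hyd$insert == d$insert & hyd$donor == d$atom
    hrows <- which(hsel)
    if (length(hrows) == 0) next
    for (a in accs) {
      if (a$side == d$side) next
      dda <- vnorm(a$A - d$D)
      if (dda > maxd) next
      if (a$chain == d$chain && a$resno == d$resno &&
          a$insert == d$insert && a$atom == d$atom) next
      for (hr in hrows) {
        H <- as.numeric(hyd[hr, c("x", "y", "z")])
        dha <- vnorm(a$A - H)
        theta <- vangle(d$D, H, a$A)
        if (theta < params$minDHA) next
        phis <- vapply(a$ants, function(ant) vangle(H, a$A, ant),
                       numeric(1))
        energy <- NA_real_
        if (params$method == "geometric") {
          if (dda > params$maxDA || dha > params$maxHA) next
          if (any(phis < params$minHAAA)) next
        } else {
          gamma <- 0
          if (a$hyb == "sp2" && !is.null(a$ref)) {
            nrm <- vcross(a$ants[[1]] - a$A, a$ref - a$A)
            if (vnorm(nrm) > 1e-9) {
              v <- a$A - H
              cg <- sum(vunit(v) * vunit(nrm))
              gamma <- abs(90 - acos(max(-1, min(1, cg))) * 180 / pi)
            }
          }
          f <- .mayoAngular(d$hyb, a$hyb, theta, phis[1], gamma)
          energy <- mayoEnergy(dda, f, params)
          if (energy > params$energyCutoff) next
        }
        prot <- if (d$side == "protein") d else a
        dna <- if (d$side == "dna") d else a
        cl <- .classifyPair(prot$resid, prot$atom, dna$resid, dna$atom)
        bonds[[length(bonds) + 1]] <- data.frame(
          don_chain = d$chain, don_resno = d$resno,
          don_insert = d$insert, don_resid = d$resid,
          don_atom = d$atom, h_name = hyd$hname[hr],
          acc_chain = a$chain, acc_resno = a$resno,
          acc_insert = a$insert, acc_resid = a$resid,
          acc_atom = a$atom, d_da = dda, d_ha = dha,
          theta_dha = theta, energy = energy, donor_side = d$side,
          prot_chain = prot$chain, prot_resno = prot$resno,
          prot_insert = prot$insert, prot_resid = prot$resid,
          prot_atom = prot$atom,
          dna_chain = dna$chain, dna_resno = dna$resno,
          dna_insert = dna$insert, dna_resid = dna$resid,
          dna_atom = dna$atom, dna_base = cl$base, class = cl$class,
          groove = cl$groove, stringsAsFactors = FALSE)
      }
    }
  }
  b <- if (length(bonds) == 0) .emptyBonds() else do.call(rbind, bonds)
  ## His nitrogens are scanned as both donor and acceptor; keep at most
  ## one bond per unordered (His N, partner atom) pair
  if (nrow(b) > 1) {
    hisd <- b$don_resid == "HIS" & b$don_atom %in% c("ND1", "NE2")
    hisa <- b$acc_resid == "HIS" & b$acc_atom %in% c("ND1", "NE2")
    key <- ifelse(hisd | hisa,
                  paste(pmin(paste(b$don_chain, b$don_resno, b$don_atom),
                             paste(b$acc_chain, b$acc_resno, b$acc_atom)),
                        pmax(paste(b$don_chain, b$don_resno, b$don_atom),
                             paste(b$acc_chain, b$acc_resno, b$acc_atom))),
                  paste(seq_len(nrow(b))))
    ord <- order(key, b$d_ha)
    b <- b[ord, , drop = FALSE]
    b <- b[!duplicated(key[ord]), , drop = FALSE]
    rownames(b) <- NULL
  }
  new("HBondSet", bonds = b, method = params$method,
      params = unclass(params))
}

#' Detect protein-DNA hydrogen bonds
#'
#' `detectHBonds()` dispatches on `params$method`;
#' `detectHBondsGeometric()` applies HBPLUS-style criteria (donor-
#' acceptor and hydrogen-acceptor distance limits plus D-H-A and
#' H-A-antecedent angle minima); `detectHBondsEnergy()` pre-screens
#' candidates at 4.5 Angstrom and a 90 degree D-H-A minimum, then keeps
#' pairs whose Mayo 12-10 energy is at or below the cutoff
#' (-0.6 kcal/mol by default), storing the energy on the bond.
#' Every bond connects exactly one protein and one DNA atom and carries
#' its interaction class (`sidechain-base`, `sidechain-backbone`,
#' `mainchain-base`, `mainchain-backbone`) and groove label.
#'
#' @param unit an \linkS4class{AnalysisUnit} (hydrogens are placed on
#'   demand).
#' @param params a [detectorParams()] list.
#' @return an \linkS4class{HBondSet}.
#' @export
detectHBonds <- function(unit, params = detectorParams()) {
  stopifnot(is(unit, "AnalysisUnit"), inherits(params, "detectorParams"))
  .detectCore(unit, params)
}

#' @rdname detectHBonds
#' @param ... passed to [detectorParams()].
#' @export
detectHBondsGeometric <- function(unit, ...) {
  detectHBonds(unit, detectorParams("geometric", ...))
}

#' @rdname detectHBonds
#' @export
detectHBondsEnergy <- function(unit, ...) {
  detectHBonds(unit, detectorParams("energy", ...))
}

#' Classify a protein-DNA atom pair
#'
#' Returns the interaction class and groove label used on detected
#' bonds: the protein side is `sidechain` unless the atom is one of
#' N/CA/C/O/OXT; the DNA side is `base` when the atom belongs to the
#' base ring/edge (not sugar or phosphate); the groove label comes from
#' [grooveOfAtom()] and is `"none"` for backbone atoms.
#'
#' @param protResid,protAtom protein residue code and atom name.
#' @param dnaResid,dnaAtom DNA residue code and atom name.
#' @return list with elements `class`, `groove`, `base`.
#' @export
classifyHBond <- function(protResid, protAtom, dnaResid, dnaAtom) {
  .classifyPair(protResid, protAtom, dnaResid, dnaAtom)
}
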