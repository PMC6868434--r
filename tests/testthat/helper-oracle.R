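## Independent brute-force hydrogen-bond oracle.
##
## Cross-checks the package detectors by enumerating EVERY placed polar
## hydrogen against EVERY acceptor on the opposite molecule and applying
## the acceptance criteria with its own vector arithmetic.  Only the
## chemistry tables (donorAcceptorTables) and the hydrogen coordinates
## are shared with the package; all geometry and energetics are
## recomputed here from first principles.

o_dist <- function(a, b) sqrt(sum((a - b)^2))

o_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cs <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(max(-1, min(1, cs))) * 180 / pi
}

o_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## backbone acceptor definitions (protein carbonyl / terminal carboxyl);
## these are implicit in the detector and therefore restated here
o_bb_acc_prot <- list(
  list(atom = "O", hyb = "sp2", ant = "C", ref = "CA"),
  list(atom = "OXT", hyb = "sp2", ant = "C", ref = "O"))

o_acceptors <- function(atoms) {
  tabs <- donorAcceptorTables()$acceptors
  bbDna <- tabs$.dna_backbone
  out <- list()
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  for (k in unique(key)) {
    sub <- atoms[key == k, , drop = FALSE]
    resid <- sub$resid[1]
    kind <- sub$kind[1]
    defs <- tabs[[resid]]
    if (kind == "nucleotide") defs <- c(defs, bbDna)
    if (kind == "amino_acid") defs <- c(defs, o_bb_acc_prot)
    if (is.null(defs) || length(defs) == 0) next
    pos <- function(nm) {
      i <- which(sub$elety == nm)
      if (length(i) == 0) NULL
      else as.numeric(sub[i[1], c("x", "y", "z")])
    }
    for (a in defs) {
      A <- pos(a$atom)
      if (is.null(A)) next
      ants <- Filter(Negate(is.null), lapply(a$ant, pos))
      if (length(ants) == 0) next
      ref <- if (!is.null(a$ref)) pos(a$ref) else NULL
      out[[length(out) + 1]] <- list(
        chain = sub$chain[1], resno = sub$resno[1],
        insert = sub$insert[1], resid = resid, atom = a$atom,
        hyb = a$hyb,
        side = if (kind == "amino_acid") "protein" else "dna",
        A = A, ants = ants, ref = ref)
    }
  }
  out
}

o_donor_hyb <- function(resid, atom) {
  if (atom == "N") return("sp2")       # backbone amide
  for (d in donorAcceptorTables()$donors[[resid]])
    if (d$atom == atom) return(d$hyb)
  stop("oracle: unknown donor ", resid, " ", atom)
}

o_angular <- function(donHyb, accHyb, theta, phi, gamma) {
  ct2 <- cos(theta * pi / 180)^2
  if (donHyb == "sp3" && accHyb == "sp3")
    ct2 * cos((phi - 109.5) * pi / 180)^2
  else if (donHyb == "sp3" && accHyb == "sp2")
    ct2 * cos(phi * pi / 180)^2
  else if (donHyb == "sp2" && accHyb == "sp3")
    ct2 * ct2
  else
    ct2 * cos(max(phi, gamma) * pi / 180)^2
}

oracleDetect <- function(unit, method) {
  unit <- suppressWarnings(placePolarHydrogens(unit))
  atoms <- atomTable(unit)
  hyd <- unit@hydrogens
  accs <- o_acceptors(atoms)
  rows <- list()
  if (nrow(hyd) > 0) for (hi in seq_len(nrow(hyd))) {
    h <- hyd[hi, ]
    di <- which(atoms$chain == h$chain & atoms$resno == h$resno &
                  atoms$insert == h$insert & atoms$elety == h$donor)
    D <- as.numeric(atoms[di[1], c("x", "y", "z")])
    dSide <- if (atoms$kind[di[1]] == "amino_acid") "protein" else "dna"
    dHyb <- o_donor_hyb(h$resid, h$donor)
    H <- as.numeric(h[c("x", "y", "z")])
    for (a in accs) {
      if (a$side == dSide) next
      if (a$chain == h$chain && a$resno == h$resno &&
          a$insert == h$insert && a$atom == h$donor) next
      dda <- o_dist(a$A, D)
      theta <- o_angle(D, H, a$A)
      dha <- o_dist(a$A, H)
      keep <- FALSE
      energy <- NA_real_
      if (method == "geometric") {
        phis <- vapply(a$ants, function(ant) o_angle(H, a$A, ant),
                       numeric(1))
        keep <- dda <= 3.9 && dha <= 2.5 && theta >= 90 &&
          all(phis >= 90)
      } else if (dda <= 4.5 && theta >= 90) {
        phi <- o_angle(H, a$A, a$ants[[1]])
        gamma <- 0
        if (a$hyb == "sp2" && !is.null(a$ref)) {
          nrm <- o_cross(a$ants[[1]] - a$A, a$ref - a$A)
          nn <- sqrt(sum(nrm * nrm))
          if (nn > 1e-9) {
            v <- a$A - H
            cg <- sum(v * nrm) / (sqrt(sum(v * v)) * nn)
            gamma <- abs(90 - acos(max(-1, min(1, cg))) * 180 / pi)
          }
        }
        f <- o_angular(dHyb, a$hyb, theta, phi, gamma)
        r <- 2.8 / dda
        energy <- 8 * (5 * r^12 - 6 * r^10) * f
        keep <- energy <= -0.6
      }
      if (keep)
        rows[[length(rows) + 1]] <- data.frame(
          don_chain = h$chain, don_resno = h$resno,
          don_atom = h$donor, h_name = h$hname,
          acc_chain = a$chain, acc_resno = a$resno, acc_atom = a$atom,
          don_resid = h$resid, acc_resid = a$resid,
          d_ha = dha, energy = energy, stringsAsFactors = FALSE)
    }
  }
  b <- if (length(rows) == 0) {
    data.frame(don_chain = character(), don_resno = integer(),
               don_atom = character(), h_name = character(),
               acc_chain = character(), acc_resno = integer(),
               acc_atom = character(), don_resid = character(),
               acc_resid = character(), d_ha = numeric(),
               energy = numeric(), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  ## His nitrogens appear as donor and acceptor; keep one bond per
  ## unordered (His N, partner) pair -- the closest approach
  if (nrow(b) > 1) {
    hisd <- b$don_resid == "HIS" & b$don_atom %in% c("ND1", "NE2")
    hisa <- b$acc_resid == "HIS" & b$acc_atom %in% c("ND1", "NE2")
    k1 <- paste(b$don_chain, b$don_resno, b$don_atom)
    k2 <- paste(b$acc_chain, b$acc_resno, b$acc_atom)
    key <- ifelse(hisd | hisa,
                  paste(pmin(k1, k2), pmax(k1, k2)),
                  as.character(seq_len(nrow(b))))
    ord <- order(key, b$d_ha)
    b <- b[ord, , drop = FALSE]
    b <- b[!duplicated(key[ord]), , drop = FALSE]
  }
  rownames(b) <- NULL
  b
}

o_bond_keys <- function(b) {
  if (nrow(b) == 0) return(character(0))
  sort(paste(b$don_chain, b$don_resno, b$don_atom, b$h_name,
             b$acc_chain, b$acc_resno, b$acc_atom, sep = "|"))
}

## expectation: package detector and oracle find the same bond set (and,
## for the energy detector, the same energies)
expect_oracle_agreement <- function(unit, method) {
  hb <- suppressWarnings(detectHBonds(unit, detectorParams(method)))
  pk <- hbonds(hb)
  or <- oracleDetect(unit, method)
  expect_identical(o_bond_keys(pk), o_bond_keys(or))
  if (method == "energy" && nrow(pk) > 0) {
    kp <- paste(pk$don_chain, pk$don_resno, pk$don_atom, pk$h_name,
                pk$acc_chain, pk$acc_resno, pk$acc_atom, sep = "|")
    ko <- paste(or$don_chain, or$don_resno, or$don_atom, or$h_name,
                or$acc_chain, or$acc_resno, or$acc_atom, sep = "|")
    expect_equal(pk$energy, or$energy[match(kp, ko)], tolerance = 1e-9)
  }
  invisible(list(package = pk, oracle = or))
}
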