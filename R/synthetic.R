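## Self-contained synthetic protein-DNA fixtures with planted ground
## truth.  An idealized B-form duplex is built by fiber-model stacking of
## standard-reference-frame base geometries; amino-acid probe fragments
## are planted at geometries that do (outcome "bond") or do not (outcome
## "near_miss") satisfy the hydrogen-bond criteria.

## Base heavy-atom coordinates (Angstrom) in the base-pair standard
## reference frame; the complementary strand-II base is generated by the
## (x, -y, -z) flip.  C1' is included so duplex detection is exercised.
.BASE_TEMPLATES <- list(
  DA = matrix(c(
    -2.479, 5.346, 0, -1.291, 4.498, 0,  0.024, 4.897, 0,
     0.877, 3.902, 0,  0.071, 2.771, 0,  0.369, 1.398, 0,
     1.611, 0.909, 0, -0.668, 0.532, 0, -1.912, 1.023, 0,
    -2.320, 2.290, 0, -1.267, 3.124, 0), ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1",
                      "C2", "N3", "C4"), NULL)),
  DG = matrix(c(
    -2.477, 5.399, 0, -1.289, 4.551, 0,  0.023, 4.962, 0,
     0.870, 3.969, 0,  0.071, 2.833, 0,  0.424, 1.460, 0,
     1.554, 0.955, 0, -0.700, 0.641, 0, -1.999, 1.087, 0,
    -2.949, 0.139, 0, -2.342, 2.364, 0, -1.265, 3.177, 0),
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1",
                      "C2", "N2", "N3", "C4"), NULL)),
  DC = matrix(c(
    -2.477, 5.402, 0, -1.285, 4.542, 0, -1.472, 3.158, 0,
    -2.628, 2.709, 0, -0.391, 2.344, 0,  0.837, 2.868, 0,
     1.875, 2.027, 0,  1.056, 4.275, 0, -0.023, 5.068, 0),
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5",
                      "C6"), NULL)),
  DT = matrix(c(
    -2.481, 5.354, 0, -1.284, 4.500, 0, -1.462, 3.135, 0,
    -2.562, 2.608, 0, -0.298, 2.407, 0,  0.994, 2.897, 0,
     1.944, 2.119, 0,  1.106, 4.338, 0,  2.466, 4.961, 0,
    -0.024, 5.057, 0), ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5",
                      "C5M", "C6"), NULL)))

.COMP1 <- c(A = "T", T = "A", G = "C", C = "G")

.elemOf <- function(elety) substr(gsub("^[0-9']+", "", elety), 1, 1)

#' Generate an idealized B-DNA duplex
#'
#' Builds a fiber-model double helix (default rise 3.38 Angstrom, twist
#' 36 degrees per step) from standard base-pair geometries.  Strand 1
#' (chain `chains[1]`) carries `sequence` 5'->3' with residues numbered
#' 1..n; strand 2 (chain `chains[2]`) is the antiparallel complement,
#' also numbered 1..n in its own 5'->3' direction, so residue `i` of
#' strand 1 pairs with residue `n+1-i` of strand 2.  Only base atoms and
#' C1' are generated.
#'
#' @param sequence string over A/C/G/T.
#' @param rise,twist helical step parameters (Angstrom, degrees).
#' @param chains character(2) chain ids, default B and C.
#' @return canonical atom data.frame.
#' @examples
#' dna <- generateBDNA("GAATTC")
#' basePairs(detectBasePairs(dna, chains = c("B", "C")))
#' @export
generateBDNA <- function(sequence, rise = 3.38, twist = 36,
                         chains = c("B", "C")) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters1) == 0) stop("sequence must be non-empty")
  bad <- !(letters1 %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("invalid character(s) in sequence: ",
                     paste(unique(letters1[bad]), collapse = ", "))
  n <- length(letters1)
  rows <- list()
  addBase <- function(chain, resno, code, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resno = as.integer(resno), insert = "", resid = code,
      elety = rownames(xyz), elesy = .elemOf(rownames(xyz)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
      kind = "nucleotide", stringsAsFactors = FALSE, row.names = NULL)
  }
  for (i in seq_len(n)) {
    R <- rotmat(c(0, 0, 1), (i - 1) * twist)
    shift <- c(0, 0, (i - 1) * rise)
    code1 <- paste0("D", letters1[i])
    t1 <- .BASE_TEMPLATES[[code1]]
    xyz1 <- sweep(t1 %*% t(R), 2, shift, "+")
    rownames(xyz1) <- rownames(t1)
    addBase(chains[1], i, code1, xyz1)
    code2 <- paste0("D", .COMP1[[letters1[i]]])
    t2 <- .BASE_TEMPLATES[[code2]]
    t2f <- t2 %*% diag(c(1, -1, -1))          # strand-II flip
    xyz2 <- sweep(t2f %*% t(R), 2, shift, "+")
    rownames(xyz2) <- rownames(t2)
    addBase(chains[2], n + 1 - i, code2, xyz2)
  }
  out <- do.call(rbind, rows)
  out[order(match(out$chain, chains), out$resno), , drop = FALSE]
}

## ---- probe targets ---------------------------------------------------

## which base atom a probe aims at, per (base, groove, probe role)
.TARGET_ACC <- list(DA = c(major = "N7", minor = "N3"),
                    DG = c(major = "O6", minor = "N3"),
                    DC = c(minor = "O2"),
                    DT = c(major = "O4", minor = "O2"))
.TARGET_DON <- list(DA = c(major = "N6"),
                    DC = c(major = "N4"),
                    DG = c(minor = "N2"))

## donor probes present a hydrogen; ASP presents a carboxylate acceptor
.PROBE_ROLE <- c(ASN = "donor", ARG = "donor", SER = "donor",
                 ASP = "acceptor")

.resAtoms <- function(atoms, chain, resno) {
  a <- atoms[atoms$chain == chain & atoms$resno == resno, , drop = FALSE]
  pos <- as.matrix(a[, c("x", "y", "z")])
  rownames(pos) <- a$elety
  pos
}

## approach geometry for a target base atom: the planted contact atom
## goes to `origin + dist * w`
.approachInfo <- function(atoms, chain, resno, groove, role) {
  res <- atoms[atoms$chain == chain & atoms$resno == resno, ,
               drop = FALSE]
  if (nrow(res) == 0) stop("no residue ", resno, " in chain ", chain)
  resid <- res$resid[1]
  pos <- .resAtoms(atoms, chain, resno)
  pickAtom <- if (role == "donor") .TARGET_ACC[[resid]]
  else .TARGET_DON[[resid]]
  if (is.null(pickAtom) || !(groove %in% names(pickAtom)))
    stop("no ", if (role == "donor") "acceptor" else "donor",
         " edge atom in the ", groove, " groove of ", resid)
  tname <- unname(pickAtom[groove])
  A <- pos[tname, ]
  if (role == "donor") {
    ## target is a base acceptor: outward lone-pair direction
    acc <- NULL
    for (a in .ACCEPTOR_DEF[[resid]]) if (a$atom == tname) acc <- a
    ants <- lapply(acc$ant, function(nm) pos[nm, ])
    w <- if (length(ants) == 1) vunit(A - ants[[1]])
    else vunit(vunit(A - ants[[1]]) + vunit(A - ants[[2]]))
    list(target = tname, origin = A, w = w, resid = resid,
         hpos = NULL)
  } else {
    ## target is a base amine donor: outward (anti) N-H direction
    don <- NULL
    for (d in .DONOR_DEF[[resid]]) if (d$atom == tname) don <- d
    D <- A
    C <- pos[don$nb[1], ]
    Rf <- pos[don$ref, ]
    np <- vunit(vcross(D - C, Rf - C))
    u <- vunit(C - D)
    dirs <- list(as.numeric(rotmat(np, 120) %*% u),
                 as.numeric(rotmat(np, -120) %*% u))
    ## the anti hydrogen points away from the rest of the DNA
    other <- as.matrix(atoms[, c("x", "y", "z")])
    score <- vapply(dirs, function(dd) {
      p <- D + 2.9 * dd
      min(sqrt(rowSums(sweep(other, 2, p)^2)))
    }, numeric(1))
    w <- dirs[[which.max(score)]]
    list(target = tname, origin = D, w = w, resid = resid,
         hpos = D + 1.0 * w)
  }
}

## ---- greedy probe construction ---------------------------------------

.minDistTo <- function(p, mat) {
  if (is.null(mat) || nrow(mat) == 0) return(Inf)
  min(sqrt(rowSums(sweep(mat, 2, p)^2)))
}

## candidate positions on a cone: base + bond * R(axis(psi), angle) dir0
.coneCands <- function(base, dir0, angle, bond, n = 12) {
  p1 <- vperp(dir0); p2 <- vcross(vunit(dir0), p1)
  lapply(seq(0, 2 * pi, length.out = n + 1)[-(n + 1)], function(psi) {
    axis <- cos(psi) * p1 + sin(psi) * p2
    base + bond * as.numeric(rotmat(axis, angle) %*% dir0)
  })
}

## hydrogen-bonding roles of probe atoms (backbone N of a stub has no
## hydrogen and is inert; carbons score on steric clearance only)
.PROBE_ATOM_ROLE <- c(ND2 = "donor", NH1 = "donor", NH2 = "donor",
                      NE = "donor", OG = "both", OD1 = "acceptor",
                      OD2 = "acceptor", O = "acceptor")

## DNA polar atoms, split by role, for interference-aware placement
.dnaPolarSets <- function(dnaAtoms) {
  don <- list(); acc <- list()
  for (i in seq_len(nrow(dnaAtoms))) {
    rn <- dnaAtoms$resid[i]; an <- dnaAtoms$elety[i]
    for (d in .DONOR_DEF[[rn]])
      if (d$atom == an) don[[length(don) + 1]] <- i
    for (a in .ACCEPTOR_DEF[[rn]])
      if (a$atom == an) acc[[length(acc) + 1]] <- i
  }
  xyz <- as.matrix(dnaAtoms[, c("x", "y", "z")])
  list(all = xyz,
       donors = xyz[unlist(don), , drop = FALSE],
       donorsMeta = dnaAtoms[unlist(don), c("chain", "resno", "elety")],
       acceptors = xyz[unlist(acc), , drop = FALSE],
       acceptorsMeta = dnaAtoms[unlist(acc), c("chain", "resno",
                                               "elety")])
}

.roleOf <- function(atom) {
  if (atom %in% names(.PROBE_ATOM_ROLE)) .PROBE_ATOM_ROLE[[atom]]
  else "inert"
}

## clearance score of a candidate position: polar probe atoms maximise
## distance to opposing DNA polar atoms (a donor must stay clear of DNA
## acceptors and vice versa); everything also avoids steric overlap.
## Covalently bonded / 1-3 fragment neighbours (< 2.4 Angstrom) are not
## counted as clashes.
.candScore <- function(p, role, env, placed) {
  opp <- switch(role,
    donor = env$acceptors,
    acceptor = env$donors,
    both = rbind(env$acceptors, env$donors),
    NULL)
  s <- .minDistTo(p, env$all) + 1.4
  if (!is.null(placed) && nrow(placed) > 0) {
    dpl <- sqrt(rowSums(sweep(placed, 2, p)^2))
    dpl <- dpl[dpl > 2.4]
    if (length(dpl) > 0) s <- min(s, min(dpl) + 1.4)
  }
  if (!is.null(opp)) s <- min(s, .minDistTo(p, opp))
  s
}

.pickCand <- function(cands, role, env, placed) {
  sc <- vapply(cands, .candScore, numeric(1), role = role, env = env,
               placed = placed)
  cands[[which.max(sc)]]
}

## greedy tail: atom bonded to b (angle at b w.r.t. a), dihedral scanned
.greedyNext <- function(ref, a, b, len, ang, role, env, placed) {
  cands <- lapply(c(0, 60, -60, 120, -120, 180, 30, -30, 150, -150),
                  function(dh) place_internal(ref, a, b, len, ang, dh))
  .pickCand(cands, role, env, placed)
}

#' Plant an amino-acid probe fragment against a DNA base
#'
#' Places a chemically sensible hydrogen-bond probe (Asn amide, Arg
#' guanidinium or Ser hydroxyl as donors; Asp carboxylate as acceptor
#' opposite a base amine) at a donor-acceptor distance of 2.9 Angstrom
#' with a collinear D-H...A approach for `outcome = "bond"`.  For
#' `outcome = "near_miss_distance"` the whole fragment is retracted to
#' 4.2 Angstrom; for `outcome = "near_miss_angle"` it is tilted so the
#' D-H-A angle is 60 degrees at an accepted distance.  Backbone stub
#' atoms (N, CA, C, O) are built at ideal internal geometry and steered
#' away from the DNA.
#'
#' @param dnaAtoms atom data.frame of the duplex (from [generateBDNA()]).
#' @param chain,resno target base (author numbering of its chain).
#' @param groove `"major"` or `"minor"`.
#' @param type probe residue: `"ASN"`, `"ARG"`, `"SER"` or `"ASP"`.
#' @param outcome `"bond"`, `"near_miss_distance"` or
#'   `"near_miss_angle"`.
#' @param probeResno residue number given to the planted fragment.
#' @param probeChain chain id of the fragment, default `"A"`.
#' @return list with `atoms` (the fragment) and `target` (chain, resno,
#'   atom name of the contacted base atom).
#' @export
plantProbe <- function(dnaAtoms, chain, resno, groove,
                       type = c("ASN", "ARG", "SER", "ASP"),
                       outcome = c("bond", "near_miss_distance",
                                   "near_miss_angle"),
                       probeResno = 1, probeChain = "A") {
  type <- match.arg(type)
  outcome <- match.arg(outcome)
  role <- .PROBE_ROLE[[type]]
  if (type == "SER" && outcome == "near_miss_angle")
    stop("angle near-miss is not constructible for a rotatable donor")
  if (type == "ASP" && outcome == "near_miss_angle")
    stop(paste("angle near-miss is not constructible for a carboxylate",
               "acceptor opposite a two-hydrogen base amine"))
  info <- .approachInfo(dnaAtoms, chain, resno, groove, role)
  env <- .dnaPolarSets(dnaAtoms)
  dist0 <- if (outcome == "near_miss_distance") 4.2 else 2.9
  if (role == "donor") {
    anchor <- info$origin + dist0 * info$w
    frag <- .buildDonorProbe(type, anchor, info$w, env)
    if (outcome == "near_miss_angle")
      frag <- .tiltForAngle(frag, type, anchor, info$w, info$origin)
  } else {
    anchor <- info$origin + dist0 * info$w
    frag <- .buildAspProbe(anchor, info$w, env)
  }
  atoms <- data.frame(
    chain = probeChain, resno = as.integer(probeResno), insert = "",
    resid = type,
    elety = names(frag), elesy = .elemOf(names(frag)),
    x = vapply(frag, `[`, numeric(1), 1),
    y = vapply(frag, `[`, numeric(1), 2),
    z = vapply(frag, `[`, numeric(1), 3),
    o = 1, kind = "amino_acid", stringsAsFactors = FALSE,
    row.names = NULL)
  list(atoms = atoms,
       target = list(chain = chain, resno = resno, atom = info$target,
                     groove = groove))
}

## jointly choose a planar head group: ring over the cone candidates for
## the carbon bonded to the contact atom, and over both in-plane
## positions of the second substituent; the third substituent position
## follows from planarity.  The combined score is the worst clearance
## score among the three derived atoms.
.pickHead <- function(anchor, w, env, cBond, sBond, sAngle, tBond,
                      sRole, tRole) {
  best <- NULL; bestsc <- -Inf
  for (cpos in .coneCands(anchor, -w, 120, cBond)) {
    np0 <- vcross(anchor - cpos, (anchor - w) - cpos)
    np <- if (vnorm(np0) < 1e-6) vperp(anchor - cpos) else vunit(np0)
    u <- vunit(anchor - cpos)
    for (sgn in c(1, -1)) {
      s2 <- cpos + sBond * as.numeric(rotmat(np, sgn * sAngle) %*% u)
      t3 <- cpos + tBond * vunit(-(u + vunit(s2 - cpos)))
      sc <- min(.candScore(cpos, "inert", env, matrix(anchor, 1)),
                .candScore(s2, sRole, env, rbind(anchor, cpos)),
                .candScore(t3, tRole, env, rbind(anchor, cpos, s2)))
      if (sc > bestsc) {
        bestsc <- sc
        best <- list(c = cpos, s = s2, t = t3)
      }
    }
  }
  best
}

## donor probes: contact atom at `anchor`, hydrogen to point along -w
.buildDonorProbe <- function(type, anchor, w, env) {
  placed <- NULL
  keep <- function(p) {
    placed <<- rbind(placed, p)
    p
  }
  tail4 <- function(out, a3, a2, a1) {
    ## CA (given), then N, C, O stub atoms
    out$N <- keep(.greedyNext(a3, a2, out$CA, 1.46, 110, "inert", env,
                              placed))
    out$C <- keep(.greedyNext(a2, out$N, out$CA, 1.52, 111, "inert",
                              env, placed))
    out$O <- keep(.greedyNext(out$N, out$CA, out$C, 1.23, 120,
                              "acceptor", env, placed))
    out
  }
  out <- list()
  if (type == "ASN") {
    out$ND2 <- keep(anchor)
    head <- .pickHead(anchor, w, env, cBond = 1.329, sBond = 1.231,
                      sAngle = 122, tBond = 1.52, sRole = "acceptor",
                      tRole = "inert")
    out$CG <- keep(head$c); out$OD1 <- keep(head$s)
    out$CB <- keep(head$t)
    out$CA <- keep(.greedyNext(out$ND2, out$CG, out$CB, 1.53, 114,
                               "inert", env, placed))
    out <- tail4(out, out$CG, out$CB, out$CA)
  } else if (type == "ARG") {
    out$NH1 <- keep(anchor)
    head <- .pickHead(anchor, w, env, cBond = 1.33, sBond = 1.33,
                      sAngle = 120, tBond = 1.33, sRole = "donor",
                      tRole = "donor")
    out$CZ <- keep(head$c); out$NE <- keep(head$s)
    out$NH2 <- keep(head$t)
    out$CD <- keep(.greedyNext(out$NH1, out$CZ, out$NE, 1.46, 124,
                               "inert", env, placed))
    out$CG <- keep(.greedyNext(out$CZ, out$NE, out$CD, 1.52, 112,
                               "inert", env, placed))
    out$CB <- keep(.greedyNext(out$NE, out$CD, out$CG, 1.52, 112,
                               "inert", env, placed))
    out$CA <- keep(.greedyNext(out$CD, out$CG, out$CB, 1.53, 114,
                               "inert", env, placed))
    out <- tail4(out, out$CG, out$CB, out$CA)
  } else if (type == "SER") {
    out$OG <- keep(anchor)
    cb <- .pickCand(.coneCands(anchor, -w, 109.5, 1.43), "inert", env,
                    placed)
    out$CB <- keep(cb)
    hdum <- anchor - w
    out$CA <- keep(.greedyNext(hdum, out$OG, out$CB, 1.53, 110,
                               "inert", env, placed))
    out <- tail4(out, out$OG, out$CB, out$CA)
  } else stop("unknown donor probe type ", type)
  out
}

## Asp carboxylate acceptor probe: OD1 at `anchor`, base H along -w
.buildAspProbe <- function(anchor, w, env) {
  placed <- NULL
  keep <- function(p) { placed <<- rbind(placed, p); p }
  out <- list()
  out$OD1 <- keep(anchor)
  head <- .pickHead(anchor, w, env, cBond = 1.25, sBond = 1.25,
                    sAngle = 122, tBond = 1.52, sRole = "acceptor",
                    tRole = "inert")
  out$CG <- keep(head$c); out$OD2 <- keep(head$s)
  out$CB <- keep(head$t)
  out$CA <- keep(.greedyNext(out$OD1, out$CG, out$CB, 1.53, 114,
                             "inert", env, placed))
  out$N <- keep(.greedyNext(out$CG, out$CB, out$CA, 1.46, 110, "inert",
                            env, placed))
  out$C <- keep(.greedyNext(out$CB, out$N, out$CA, 1.52, 111, "inert",
                            env, placed))
  out$O <- keep(.greedyNext(out$N, out$CA, out$C, 1.23, 120,
                            "acceptor", env, placed))
  out
}

## rigid tilt of a donor fragment about its contact atom until the
## D-H-A angle reaches 60 degrees.  The rotation axis lies in the plane
## of the planar head group, perpendicular to the approach direction:
## tilting out of that plane takes BOTH amide/guanidinium hydrogens
## (120 degrees apart in-plane) out of the acceptance cone, whereas an
## in-plane tilt would swing the second hydrogen into it.
.tiltForAngle <- function(frag, type, anchor, w, A) {
  cpos <- if (type == "ARG") frag$CZ else frag$CG
  np0 <- vcross(anchor - cpos, (anchor - w) - cpos)
  np <- if (vnorm(np0) < 1e-6) vperp(w) else vunit(np0)
  ax0 <- vcross(np, w)
  axis <- if (vnorm(ax0) < 1e-6) vperp(w) else vunit(ax0)
  hlen <- if (type == "SER") 0.96 else 1.00
  theta <- function(delta) {
    R <- rotmat(axis, delta)
    H <- anchor + hlen * as.numeric(R %*% (-w))
    vangle(anchor, H, A)
  }
  f <- function(delta) theta(delta) - 60
  delta <- stats::uniroot(f, c(1, 175))$root
  R <- rotmat(axis, delta)
  lapply(frag, function(p) anchor + as.numeric(R %*% (p - anchor)))
}

## ---- placement interference checks ------------------------------------

## TRUE when a planted fragment cannot form unintended protein-DNA
## hydrogen bonds: every donor-capable probe atom stays at least `clear`
## Angstrom from every DNA acceptor and every acceptor-capable probe
## atom from every DNA donor, the intended contact pair excepted.  At
## 4.25 Angstrom even a perfectly aligned donor-acceptor pair is outside
## the acceptance region of both detectors (geometric limit 3.9; the
## 12-10 energy at 4.25 Angstrom is above the -0.6 kcal/mol cutoff even
## with a perfect angular factor).
.fragClear <- function(fragAtoms, target, env, clear = 4.25) {
  dropTarget <- function(mat, meta) {
    if (is.null(mat) || nrow(mat) == 0) return(mat)
    hit <- meta$chain == target$chain & meta$resno == target$resno &
      meta$elety == target$atom
    mat[!hit, , drop = FALSE]
  }
  donMat <- dropTarget(env$donors, env$donorsMeta)
  accMat <- dropTarget(env$acceptors, env$acceptorsMeta)
  for (i in seq_len(nrow(fragAtoms))) {
    role <- .roleOf(fragAtoms$elety[i])
    if (role == "inert") next
    p <- as.numeric(fragAtoms[i, c("x", "y", "z")])
    if (role %in% c("donor", "both") && .minDistTo(p, accMat) < clear)
      return(FALSE)
    if (role %in% c("acceptor", "both") && .minDistTo(p, donMat) < clear)
      return(FALSE)
  }
  TRUE
}

## TRUE when two planted fragments neither clash sterically nor place an
## acceptor close enough to a serine hydroxyl to capture its rotatable
## hydrogen (orientation search radius 3.9 Angstrom)
.probePairCompatible <- function(a, b) {
  am <- as.matrix(a[, c("x", "y", "z")])
  bm <- as.matrix(b[, c("x", "y", "z")])
  dmin <- min(vapply(seq_len(nrow(am)), function(i)
    .minDistTo(am[i, ], bm), numeric(1)))
  if (dmin < 3.0) return(FALSE)
  ogAcc <- function(p, q) {
    og <- which(p$elety == "OG")
    acc <- which(q$elety %in% c("OD1", "OD2", "O", "OG"))
    if (length(og) == 0 || length(acc) == 0) return(Inf)
    min(vapply(og, function(i)
      .minDistTo(as.numeric(p[i, c("x", "y", "z")]),
                 as.matrix(q[acc, c("x", "y", "z"), drop = FALSE])),
      numeric(1)))
  }
  ogAcc(a, b) >= 3.95 && ogAcc(b, a) >= 3.95
}

## ---- fixture specs and assembly --------------------------------------

#' Describe and build a synthetic complex fixture
#'
#' `fixtureSpec()` bundles a DNA sequence with a probe list; `probes` is
#' a data.frame with columns `strand` (1 or 2), `index` (residue number
#' on that strand), `groove`, `type` and `outcome` (see [plantProbe()]).
#' `buildFixture()` generates the duplex, plants every probe and records
#' the implied ground truth (expected bonds, per-strand counts, engaged
#' bases, 50/50 flags, engaged base pairs).
#'
#' @param sequence string over A/C/G/T (strand 1, 5'->3').
#' @param probes probe data.frame (may be empty/NULL).
#' @param seed integer stored with the spec (for provenance of random
#'   specs).
#' @return `fixtureSpec()`: a list of class `fixtureSpec`;
#'   `buildFixture()`: a list with `atoms`, `spec` and `truth`.
#' @export
fixtureSpec <- function(sequence, probes = NULL, seed = NA_integer_) {
  n <- nchar(sequence)
  if (is.null(probes) || nrow(probes) == 0)
    probes <- data.frame(strand = integer(), index = integer(),
                         groove = character(), type = character(),
                         outcome = character(), stringsAsFactors = FALSE)
  stopifnot(all(probes$strand %in% c(1L, 2L)),
            all(probes$index >= 1 & probes$index <= n),
            all(probes$groove %in% c("major", "minor")),
            all(probes$outcome %in% c("bond", "near_miss_distance",
                                      "near_miss_angle")))
  structure(list(sequence = toupper(sequence), probes = probes,
                 seed = seed), class = "fixtureSpec")
}

#' @rdname fixtureSpec
#' @param spec a `fixtureSpec`.
#' @export
buildFixture <- function(spec) {
  stopifnot(inherits(spec, "fixtureSpec"))
  n <- nchar(spec$sequence)
  dna <- generateBDNA(spec$sequence)
  probes <- spec$probes
  fragList <- list()
  expected <- list()
  if (nrow(probes) > 0) {
    for (k in seq_len(nrow(probes))) {
      p <- probes[k, ]
      ch <- if (p$strand == 1) "B" else "C"
      pr <- plantProbe(dna, ch, p$index, p$groove, p$type, p$outcome,
                       probeResno = k)
      fragList[[k]] <- pr$atoms
      if (p$outcome == "bond") {
        expected[[length(expected) + 1]] <- data.frame(
          strand = p$strand, dna_chain = ch, dna_resno = p$index,
          dna_atom = pr$target$atom, groove = p$groove,
          prot_resno = k, prot_resid = p$type,
          stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- rbind(do.call(rbind, c(fragList, list(NULL))), dna)
  bonds <- if (length(expected) == 0)
    data.frame(strand = integer(), dna_chain = character(),
               dna_resno = integer(), dna_atom = character(),
               groove = character(), prot_resno = integer(),
               prot_resid = character(), stringsAsFactors = FALSE)
  else do.call(rbind, expected)
  n1 <- sum(bonds$strand == 1); n2 <- sum(bonds$strand == 2)
  engaged <- unique(bonds[, c("strand", "dna_chain", "dna_resno",
                              "groove")])
  ## base pairs with both partners engaged: strand-1 residue i pairs
  ## with strand-2 residue n+1-i
  step1 <- unique(bonds$dna_resno[bonds$strand == 1])
  step2 <- unique(n + 1 - bonds$dna_resno[bonds$strand == 2])
  bpBoth <- sort(intersect(step1, step2))
  majStep1 <- unique(bonds$dna_resno[bonds$strand == 1 &
                                       bonds$groove == "major"])
  majStep2 <- unique(n + 1 - bonds$dna_resno[bonds$strand == 2 &
                                               bonds$groove == "major"])
  bpBothMajor <- sort(intersect(majStep1, majStep2))
  seq1 <- strsplit(spec$sequence, "")[[1]]
  truth <- list(
    n_pairs = n,
    n_scb_strand1 = n1, n_scb_strand2 = n2,
    bonds = bonds,
    engaged = engaged,
    n_bases_s1 = length(unique(bonds$dna_resno[bonds$strand == 1])),
    n_bases_s2 = length(unique(bonds$dna_resno[bonds$strand == 2])),
    n_bases_major_s1 = length(majStep1),
    n_bases_major_s2 = length(majStep2),
    is_5050_bonds = (n1 == n2 && n1 > 0),
    is_5050_bases_major = (length(majStep1) == length(majStep2) &&
                             length(majStep1) > 0),
    one_strand_only = xor(n1 > 0, n2 > 0),
    pct_dominant = if (n1 + n2 > 0) 100 * max(n1, n2) / (n1 + n2)
    else NA_real_,
    dominant_strand = if (n1 >= n2) "strand1" else "strand2",
    bp_engaged_steps = bpBoth,
    bp_engaged_types = vapply(bpBoth, function(i)
      if (seq1[i] %in% c("A", "T")) "AT" else "GC", character(1)),
    bp_engaged_steps_major = bpBothMajor)
  list(atoms = atoms, spec = spec, truth = truth)
}

#' Write a fixture to disk
#'
#' Emits the fixture as a PDB file (protein chain A, DNA chains B and C)
#' plus, optionally, the ground truth as JSON next to it.
#'
#' @param fixture result of [buildFixture()] (a `fixtureSpec` is built
#'   on the fly).
#' @param path output PDB path.
#' @param truthPath optional JSON path for the ground-truth record.
#' @return `path`, invisibly.
#' @export
writeFixture <- function(fixture, path, truthPath = NULL) {
  if (inherits(fixture, "fixtureSpec")) fixture <- buildFixture(fixture)
  writeComplexPDB(fixture$atoms, path)
  if (!is.null(truthPath)) {
    tr <- fixture$truth
    tr$bonds <- as.list(tr$bonds)
    tr$engaged <- as.list(tr$engaged)
    jsonlite::write_json(tr, truthPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Draw a random fixture specification
#'
#' Samples a duplex sequence (6-10 bp) and up to three probes per strand
#' with mixed grooves, probe types and outcomes.  Placement constraints
#' keep planted probes from interfering with each other or with
#' untargeted DNA polar atoms: helix steps used on the same strand are
#' at least two steps apart; a step may host probes from both strands
#' (creating an engaged base pair) only via fixed-geometry donors; and
#' every candidate probe is actually built and kept only if all of its
#' donor/acceptor-capable atoms stay clear of untargeted DNA acceptors/
#' donors and of previously placed probes (so the planted bond list is
#' the exhaustive ground truth).
#'
#' @param seed integer seed; drives all sampling.
#' @return a `fixtureSpec`.
#' @export
randomFixtureSpec <- function(seed) {
  set.seed(seed)
  n <- sample(6:10, 1)
  seqn <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                collapse = "")
  seq1 <- strsplit(seqn, "")[[1]]
  dna <- generateBDNA(seqn)
  env <- .dnaPolarSets(dna)
  probes <- list()
  frags <- list()
  usedSteps <- list(`1` = integer(), `2` = integer())
  for (strand in 1:2) {
    k <- sample(0:3, 1)
    tries <- 0
    while (k > 0 && tries < 50) {
      tries <- tries + 1
      idx <- sample(seq_len(n), 1)
      step <- if (strand == 1) idx else n + 1 - idx
      if (any(abs(usedSteps[[as.character(strand)]] - step) < 2)) next
      other <- usedSteps[[as.character(3 - strand)]]
      sharing <- step %in% other
      base <- if (strand == 1) paste0("D", seq1[idx])
      else paste0("D", .COMP1[[seq1[step]]])
      groove <- sample(c("major", "minor"), 1)
      cand <- character()
      if (!is.null(.TARGET_ACC[[base]]) &&
          groove %in% names(.TARGET_ACC[[base]]))
        cand <- c(cand, "ASN", "ARG", if (!sharing) "SER")
      if (!is.null(.TARGET_DON[[base]]) &&
          groove %in% names(.TARGET_DON[[base]]) && !sharing)
        cand <- c(cand, "ASP")
      if (length(cand) == 0) next
      type <- sample(cand, 1)
      outcome <- sample(c("bond", "bond", "bond", "near_miss_distance",
                          if (type %in% c("ASN", "ARG"))
                            "near_miss_angle"), 1)
      ch <- if (strand == 1) "B" else "C"
      pr <- tryCatch(
        plantProbe(dna, ch, idx, groove, type, outcome,
                   probeResno = length(probes) + 1L),
        error = function(e) NULL)
      if (is.null(pr)) next
      if (!.fragClear(pr$atoms, pr$target, env)) next
      ok <- all(vapply(frags, .probePairCompatible, logical(1),
                       b = pr$atoms))
      if (!ok) next
      probes[[length(probes) + 1]] <- data.frame(
        strand = strand, index = idx, groove = groove, type = type,
        outcome = outcome, stringsAsFactors = FALSE)
      frags[[length(frags) + 1]] <- pr$atoms
      usedSteps[[as.character(strand)]] <-
        c(usedSteps[[as.character(strand)]], step)
      k <- k - 1
    }
  }
  fixtureSpec(seqn, if (length(probes)) do.call(rbind, probes) else NULL,
              seed = seed)
}

## ---- labelled synthetic stand-ins for published binding patterns ------

#' Synthetic stand-ins reproducing published engagement patterns
#'
#' Fully synthetic fixtures (idealized B-DNA plus planted probes) whose
#' strand/base-pair engagement pattern mirrors two published complexes,
#' for offline testing of the base-pair bookkeeping:
#'
#' * `syntheticNgoMIVLike()` mimics the qualitative pattern of the
#'   NgoMIV restriction endonuclease complex (PDB entry 4ABT, protein
#'   chain A with DNA chains E/H): three continuous Watson-Crick base
#'   pairs all engaged on both strands, including the pairs
#'   DC-9(E)&#183;DG-4(H) and DG-7(E)&#183;DC-6(H).
#' * `syntheticSigmaE4Like()` mimics the sigma(E)4-(-35 element)
#'   complex (PDB entry 2H27, protein chain A with DNA chains B/C):
#'   equal numbers of engaged bases on both strands but zero engaged
#'   base pairs.
#'
#' These are NOT the experimental structures; every coordinate is
#' generated.  They only reproduce the engagement topology, so that the
#' corresponding analyses can be exercised without structure downloads.
#'
#' @return list with `atoms` (canonical atom data.frame), `truth` (the
#'   planted ground truth) and `spec`.
#' @examples
#' fx <- syntheticNgoMIVLike()
#' basePairs(detectBasePairs(fx$atoms, c("E", "H")))
#' @export
syntheticNgoMIVLike <- function() {
  probes <- data.frame(
    strand = c(1, 1, 1, 2, 2, 2),
    index = c(3, 4, 5, 6, 5, 4),
    groove = c("major", "major", "minor", "minor", "major", "major"),
    type = "ASN", outcome = "bond", stringsAsFactors = FALSE)
  fx <- buildFixture(fixtureSpec("TAGACTTC", probes))
  ## author-style chain ids and numbering: strand 1 -> chain E
  ## (residues 5-12), strand 2 -> chain H (residues 1-8); helix step k
  ## then appears as pair E-(k+4) . H-(9-k)
  remap <- function(df) {
    if (is.null(df$dna_chain)) return(df)
    s1 <- df$dna_chain == "B"
    df$dna_resno[s1] <- df$dna_resno[s1] + 4L
    df$dna_chain[s1] <- "E"
    df$dna_chain[df$dna_chain == "C"] <- "H"
    df
  }
  a <- fx$atoms
  a$resno[a$chain == "B"] <- a$resno[a$chain == "B"] + 4L
  a$chain[a$chain == "B"] <- "E"
  a$chain[a$chain == "C"] <- "H"
  fx$atoms <- a
  fx$truth$bonds <- remap(fx$truth$bonds)
  fx$truth$engaged <- remap(fx$truth$engaged)
  fx$dnaChains <- c("E", "H")
  fx
}

#' @rdname syntheticNgoMIVLike
#' @export
syntheticSigmaE4Like <- function() {
  probes <- data.frame(
    strand = c(1, 1, 2, 2),
    index = c(2, 4, 3, 1),
    groove = "major", type = "ASN", outcome = "bond",
    stringsAsFactors = FALSE)
  fx <- buildFixture(fixtureSpec("AAAAAAAA", probes))
  fx$dnaChains <- c("B", "C")
  fx
}

## ---- ideal peptides for secondary-structure fixtures ------------------

.BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                 ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
                 ang_c_n_ca = 121.7, ang_ca_c_o = 120.5)

#' Build an ideal-geometry polyalanine peptide
#'
#' Constructs backbone coordinates (N, CA, C, O, CB) residue by residue
#' from ideal bond lengths/angles with per-segment phi/psi dihedrals:
#' helix (-57, -47), strand (-119, 113) or coil (-75, 150,
#' polyproline-II-like, which forms no backbone hydrogen bonds in an
#' isolated chain).
#'
#' @param segments character vector of segment types
#'   (`"helix"`/`"strand"`/`"coil"`).
#' @param lengths integer vector of segment lengths.
#' @param chain chain id, default `"A"`.
#' @param startRes first residue number.
#' @return canonical atom data.frame (plus the planted per-residue label
#'   as attribute `"planted"`).
#' @export
buildPeptide <- function(segments, lengths, chain = "A", startRes = 1L) {
  stopifnot(length(segments) == length(lengths),
            all(segments %in% c("helix", "strand", "coil")))
  phipsi <- list(helix = c(-57, -47), strand = c(-119, 113),
                 coil = c(-75, 150))
  labels <- rep(segments, lengths)
  nres <- length(labels)
  g <- .BB_GEOM
  rows <- list()
  ## seed residue
  N <- c(0, 0, 0); CA <- c(g$n_ca, 0, 0)
  C <- place_internal(c(0, 1, 0), N, CA, g$ca_c, g$ang_n_ca_c, 0)
  prev <- list(N = N, CA = CA, C = C)
  for (i in seq_len(nres)) {
    phi_psi <- phipsi[[labels[i]]]
    if (i > 1) {
      psi_prev <- phipsi[[labels[i - 1]]][2]
      N <- place_internal(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n,
                          psi_prev)
      CA <- place_internal(prev$CA, prev$C, N, g$n_ca, g$ang_c_n_ca, 180)
      C <- place_internal(prev$C, N, CA, g$ca_c, g$ang_n_ca_c,
                          phi_psi[1])
    }
    nxtN <- place_internal(N, CA, C, g$c_n, g$ang_ca_c_n, phi_psi[2])
    O <- place_internal(CA, nxtN, C, g$c_o, 121, 180)
    CB <- place_internal(C, N, CA, 1.53, 110.5, -120)
    resno <- startRes + i - 1L
    rows[[i]] <- data.frame(
      chain = chain, resno = resno, insert = "", resid = "ALA",
      elety = c("N", "CA", "C", "O", "CB"), elesy = c("N", "C", "C",
                                                      "O", "C"),
      x = c(N[1], CA[1], C[1], O[1], CB[1]),
      y = c(N[2], CA[2], C[2], O[2], CB[2]),
      z = c(N[3], CA[3], C[3], O[3], CB[3]),
      o = 1, kind = "amino_acid", stringsAsFactors = FALSE)
    prev <- list(N = N, CA = CA, C = C)
  }
  out <- do.call(rbind, rows)
  attr(out, "planted") <- labels
  out
}

#' Build an ideal two-strand antiparallel beta sheet
#'
#' Two ideal-geometry extended strands ([buildPeptide()] with
#' phi/psi -119/+113) related by a two-fold rotation about the sheet
#' normal.  The in-plane registry offsets (`su` along the strand axis,
#' `sw` toward the partner strand) were chosen once, by maximizing the
#' number of Kabsch-Sander backbone hydrogen bonds of the resulting
#' ladder over a geometric grid, and frozen; with the defaults every
#' interior residue is assigned extended strand (E).
#'
#' @param nres residues per strand.
#' @param chains chain ids of the two strands.
#' @param su,sw frozen registry offsets in Angstrom.
#' @return canonical atom data.frame of both strands, with the planted
#'   per-residue label (`"strand"`) as attribute `"planted"`.
#' @examples
#' table(assignSecStruct(buildBetaSheet(8))$state3)
#' @export
buildBetaSheet <- function(nres = 8, chains = c("A", "B"), su = -2.6,
                           sw = 2.2) {
  s1 <- buildPeptide("strand", nres, chain = chains[1])
  xyz <- function(resno, name)
    as.numeric(s1[s1$resno == resno & s1$elety == name,
                  c("x", "y", "z")])
  ca1 <- xyz(1, "CA"); can <- xyz(nres, "CA")
  u <- vunit(can - ca1)
  co <- xyz(2, "O") - xyz(2, "C")
  w <- vunit(co - sum(co * u) * u)
  nrm <- vcross(u, w)
  p0 <- (ca1 + can) / 2 + su * u + sw * w
  R <- rotmat(nrm, 180)
  m <- as.matrix(s1[, c("x", "y", "z")])
  s2 <- s1
  s2$chain <- chains[2]
  s2[, c("x", "y", "z")] <-
    t(apply(m, 1, function(p) p0 + as.numeric(R %*% (p - p0))))
  out <- rbind(s1, s2)
  attr(out, "planted") <- rep("strand", 2 * nres)
  out
}
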