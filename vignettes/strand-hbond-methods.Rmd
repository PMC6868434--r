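---
title: "Methods: strand-level hydrogen-bond analysis of protein-DNA complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-level hydrogen-bond analysis of protein-DNA complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandHB)
```

## Scientific background

Sequence-specific DNA-binding proteins achieve specificity largely
through hydrogen bonds between amino-acid side chains and the base
edges exposed in the grooves of double-stranded DNA. Because the two
strands present complementary but *different* atoms — in the major
groove a G·C pair offers O6/N7 of guanine on one strand and N4 of
cytosine on the other — the distribution of side-chain–base (scb)
hydrogen bonds over the two strands is informative in itself. This
package quantifies, per complex:

- the number of scb hydrogen bonds and engaged bases per strand;
- the *dominant-strand percentage* (share of scb bonds on the busier
  strand) and whether contributions are exactly equal ("50/50"), both
  in the bond-count sense and in the engaged-major-groove-base sense;
- the Watson–Crick base pairs whose two bases are *both* engaged by
  scb hydrogen bonds (`findBasePairHbonds`) — a pattern associated with
  high binding specificity;
- the secondary-structure propensities of the base-contacting residues;
- group-level contrasts (e.g. highly specific vs multi-specific
  binders) via a normality-gated two-sample test.

## Hydrogen-bond detection

### Polar hydrogen placement

Crystal structures rarely resolve hydrogens, so polar hydrogens are
constructed (`placePolarHydrogens`) from heavy-atom frames. Four
geometric classes are used: `fixed1`/`fixed2` for hydrogens fully
determined by the frame (e.g. amide N–H, the two N–H of Arg NH1/NH2),
`rot1` for a single rotatable hydrogen (hydroxyls: the O–H is pointed
at the best nearby acceptor), and `rot3` for sp3 ammonium groups (Lys
NZ). Bond lengths are 1.00 Å for N–H and 0.96 Å for O–H. A backbone
amide H requires the preceding carbonyl carbon within 2.5 Å (chain
continuity); proline has no amide hydrogen.

### The geometric (HBPLUS-style) detector

A donor–H / acceptor triple is a hydrogen bond when all of

- donor–acceptor distance ≤ 3.9 Å,
- hydrogen–acceptor distance ≤ 2.5 Å,
- angle D–H–A ≥ 90°,
- angle H–A–AA ≥ 90° for **every** acceptor antecedent AA

hold. These are the widely used HBPLUS defaults; all four thresholds
are exposed in `detectorParams("geometric", ...)`, and acceptance is
monotone in each (tightening any threshold can only remove bonds —
this invariance is tested).

### The Mayo 12-10 energy detector

The alternative detector scores each candidate with the Mayo
force-field hydrogen-bond term

$$ E = V_0 \left[ 5\left(\frac{d_0}{d}\right)^{12}
      - 6\left(\frac{d_0}{d}\right)^{10} \right] F(\theta,\phi,\gamma), $$

with well depth $V_0 = 8$ kcal/mol at the equilibrium donor–acceptor
distance $d_0 = 2.8$ Å, so `mayoEnergy(2.8, 1)` is exactly −8. The
angular factor $F$ depends on the donor and acceptor hybridizations
(four cases: sp3–sp3, sp3–sp2, sp2–sp3, sp2–sp2), using the D–H–A
angle $\theta$, the H–A–AA angle $\phi$ against the **first** acceptor
antecedent, and for sp2 acceptors the out-of-plane angle $\gamma$ of
the hydrogen with respect to the acceptor plane. Candidates are
prescreened at D–A ≤ 4.5 Å and $\theta \ge 90°$; a bond is kept when
$E \le -0.6$ kcal/mol. Histidine's two unordered tautomer donors are
deduplicated by the shorter H–A distance.

Both detectors share the same chemistry tables (donor/acceptor
definitions per residue and nucleotide, plus backbone and DNA-backbone
acceptors); `donorAcceptorTables()` exposes them.

## DNA model

Watson–Crick pairs are detected from coordinates alone
(`detectBasePairs`): complementary bases on the two chains with
N1–N3 (purine–pyrimidine) distance within tolerance and a plausible
C1′–C1′ separation, resolved greedily so every base joins at most one
pair. Base edge atoms are labelled major groove, minor groove, or
neither (`grooveOfAtom`) following the standard partition of the base
edge (e.g. guanine O6/N7 major, N3/N2 minor). `generateBDNA` builds an
idealized B-DNA fiber duplex (10 bp/turn, 3.38 Å rise) from per-pair
templates; pairing geometry is exactly regular within a pair type,
with small (< 0.1 Å) differences between the G·C and A·T templates.

## Secondary structure

`assignSecStruct` re-implements the Kabsch–Sander (DSSP) assignment:
the backbone hydrogen bond is electrostatic,
$E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol with a −0.5 kcal/mol threshold and the amide H placed along
the preceding C=O direction. N-turns at offsets 3/4/5 give G/H/I
helices (two consecutive turns required), bridge patterns give B/E,
remaining turn residues T, and tight bends (κ > 70°) S; the 3-state
reduction maps H/G/I to helix, E/B to strand, everything else to coil.
Known limitations relative to full DSSP: bulge-linked ladders are not
merged, π-helix assignment is rare by construction, and the first/last
residues of a segment are systematically coil. `readDSSP` parses
classic-format DSSP files so an external assignment can be substituted.

Propensities (`computePropensity`) are ratios of state frequencies in
a residue set (e.g. base-contacting residues,
`baseContactingResidues`, default heavy-atom cutoff 4.5 Å) over a
background set, with explicit `undefined`/`infinite` flags for empty
categories rather than silent smoothing.

## Group statistics

`compareGroups` mirrors the common gated procedure: Shapiro–Wilk on
each sample; when both p-values exceed `alphaNormality` (default 0.05)
a two-sided equal-variance t test is used, otherwise a two-sided
Wilcoxon rank-sum test. Constant samples (Shapiro–Wilk undefined) are
routed to the rank-sum branch; two identical constant samples yield
p = 1 by convention (the statistic's normal approximation is 0/0, and
all-tied data carry no evidence of a difference). The acceptance suite
verifies calibration: on 2000 null Gaussian simulations the rejection
rate at α = 0.05 stays within 0.05 ± 0.02.

## Synthetic fixtures with planted ground truth

Offline validation rests on a generator that *constructs* the answer
(`buildFixture`): side-chain probe fragments (ASN, GLN, SER, ARG, LYS,
ASP, GLU) are placed around an ideal B-DNA duplex at exact
hydrogen-bond geometry against a chosen base edge atom — or at
controlled near-misses: retracted to 4.2 Å (`near_miss_distance`), or
rigidly tilted to a 60° D–H–A angle (`near_miss_angle`; refused for
probes whose geometry cannot realize it). Placement is
interference-aware: a planted fragment must keep ≥ 4.25 Å clearance to
all non-target DNA polar atoms (outside both detectors' reach: past
the 3.9 Å geometric cap, and the 12-10 energy at 4.25 Å is above the
−0.6 cutoff even for perfect angles), fragments must not clash
sterically (≥ 3.0 Å), and no fragment may place a donor/acceptor
within 3.95 Å of another fragment's counterpart. Under these
constraints the planted bond list *is* the expected detector output,
and the generator records the complete downstream truth (per-strand
counts, flags, dominant percentages, engaged base pairs).

Realism and limits: probes are isolated side-chain fragments, not
folded chains — backbone-mediated effects, crowding, water-mediated
bonds and cooperativity are deliberately absent; the DNA is an ideal
fiber with no sequence-dependent deformation. The fixtures therefore
validate the *bookkeeping and detectors exactly*, not conformational
realism. Two bundled stand-ins (`synthetic_ngomiv_like.pdb`,
`synthetic_sigmae4_like.pdb`, both generated and labelled as such)
reproduce the strand-engagement topology of a restriction-enzyme-like
and a sigma-factor-like complex for the worked examples.

## Numerical choices

- All geometry is double precision; angle computations guard the
  `acos` argument into [−1, 1].
- Distance/angle thresholds are compared with plain `<=`/`>=`; planted
  fixtures place atoms a safe margin away from every threshold, so no
  epsilon layer is needed.
- Random fixture generation derives all choices from a single integer
  seed (`randomFixtureSpec`), making every fixture reproducible
  byte-for-byte through `writeFixture`.

## Limitations

- Only side-chain–base bonds enter the strand bookkeeping; backbone
  and sugar-phosphate contacts are classified but excluded from the
  specificity counts, matching the analysis the package implements.
- Water-mediated and bifurcated hydrogen bonds are not modelled.
- The duplex must be exactly two DNA chains; triplexes, quadruplexes
  and single strands are rejected.
- The DSSP re-implementation has the simplifications listed above.
- The Mayo angular term uses the first listed acceptor antecedent,
  which for carboxylates/phosphates is an arbitrary but fixed choice.
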