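---
title: "Methods: coiled-coil dimer analysis and variant impact calls"
author: "ccdimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coiled-coil dimer analysis and variant impact calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science behind its
functions: the models and rules implemented, the parameters that matter,
what the synthetic-structure generator does and does not emulate, and the
design decisions taken where the problem left genuine freedom.

## The system

The human PALB2 coiled-coil domain (residues 6–42) forms an antiparallel
homodimer through a leucine-zipper-like hydrophobic interface (heptad a/d
positions L17, L21, L24, Y28, T31, L35, A38 …), with an aromatic Y28–Y28′
pair at the centre; the same domain heterodimerizes with the BRCA1
coiled coil during homologous recombination. Missense variants in the
domain (K18R, L24S, Y28C, T31I, R37H, L35P) perturb the protomer fold, the
homodimer interface and the heterodimer interface to different degrees,
and the package's purpose is to quantify those perturbations from
structural ensembles.

## Contact analysis

Contacts are heavy-atom pairs within a distance cutoff. Two cutoffs are
used throughout and exposed as arguments: **7 Å** for intra- and
inter-protomer contact totals and **10 Å** for native contacts at a
mutation site. Atom-pair counts serve trajectory-style series; distinct
residue-pair counts serve interface totals (an interface of a few dozen
residue pairs has on the order of a thousand atom pairs at 7 Å, so the two
units must not be mixed). Intra-protomer counting excludes pairs within a
residue and between sequence neighbours (|i−j| < 2, configurable), so the
totals measure tertiary packing rather than covalent geometry.

The neighbour search uses a cell list (bins of edge = cutoff, 27-cell
neighbourhoods) and is required by tests to agree *exactly* with the
brute-force O(N²) scan; correctness is therefore guaranteed, and the cell
list only buys expected-linear scaling.

Classification precedence is salt bridge > hydrogen bond > hydrophobic >
van der Waals:

* salt bridge: Lys NZ / Arg NH1,NH2,NE against Asp OD* / Glu OE* / OXT at
  ≤ 4.0 Å;
* hydrogen bond: N/O–N/O at ≤ 3.5 Å with donor–H…acceptor ≥ 120°, the
  amide H built at 1.01 Å along the bisector of the N–CA and N–C(prev)
  directions when the structure carries no hydrogens (rotatable OH/SH
  donors, whose H cannot be placed from heavy atoms, fall back to the
  distance criterion);
* hydrophobic: two apolar side-chain carbons/sulfurs at ≤ 4.5 Å, where
  "apolar" is a per-residue atom list that excludes carbons bonded to N/O;
* anything else at ≤ 4.5 Å is van der Waals.

The 3.5 Å/120° and 4.5 Å values are standard geometric criteria; the
literature the counts are compared against names the bond types but no
thresholds, so these are package defaults, all configurable.

## Backbone hydrogen bonds and helicity

Backbone bonds use the Kabsch–Sander electrostatic model,
E = 0.084·332·(1/r~ON~ + 1/r~CH~ − 1/r~OH~ − 1/r~CN~) kcal/mol, with a
bond called at E < −0.5 kcal/mol, an energy floor of −9.9 for
near-overlap, and chain breaks declared when consecutive CA atoms are
> 4.5 Å apart. Each amide donates at most one counted bond (its
best-energy acceptor), which makes the ideal-helix ladder exactly N−4
bonds for N residues. Helix assignment uses the minimal DSSP α rule: a
4-turn at k when the amide of k+4 bonds the carbonyl of k; residue r is
"H" when turns exist at r−1 and r. 3₁₀/π helices and strands are folded
into "not helix" because only α-helicity is reported. Percentage helicity
is the fraction of residues labelled H over a selection, averaged over
models for an ensemble; the denominator includes every residue of the
selection (the disordered N-terminal residues 6–10 count against
helicity, matching a whole-construct reading).

Agreement with an external DSSP implementation, measured once on frozen
fixtures (the built homodimer and one partly unfolded chain), is 92% per
residue; the discrepancy concentrates at helix termini, where DSSP's
full rule set is more permissive than the minimal α rule.

## Geometry

Helix axes are fitted as the principal direction of sliding four-CA
centroids (at least 7 residues), signed N→C. The crossing angle is the
angle between two N→C directions; the dimer is antiparallel when it
exceeds 90°, and the packing angle min(θ, 180−θ) is reported alongside so
antiparallel crossing angles are comparable with the conventional
small-angle statement. Ring geometry fits least-squares planes through
the six-membered rings (five-membered for His), folds the interplanar
angle into [0°, 90°], and classes a pair parallel below 30°, edge-to-face
above 60°, in both cases only within 7.5 Å centroid distance — thresholds
from the π-stacking literature, configurable, since the analysis being
reproduced plots clusters without stating numeric class bounds.
Met–aromatic interactions are Met SD within 6.0 Å of a ring centroid;
CH–π interactions are apolar side-chain carbons within 4.5 Å of the
centroid and within 40° of the ring normal.

## Surface area and charge

SASA is Shrake–Rupley with Bondi radii (C 1.70, N 1.55, O 1.52, S 1.80 Å),
probe 1.4 Å, and a deterministic golden-spiral lattice of 960 points per
atom (doubling the lattice changes totals by < 1%). Buried surface area
is SASA(A) + SASA(B) − SASA(AB), heavy atoms only, both sides summed with
no division by two. This convention is stated prominently because printed
buried-area values in the literature are convention-sensitive; under this
standard definition a 37-residue dimer buries on the order of 1–2·10³ Å²,
and no attempt is made to reproduce conventions that report several-fold
larger numbers. Charge profiles assign +1 to Lys/Arg, −1 to Asp/Glu and 0
to His (termini excluded, since the construct is an internal fragment)
and bin the charges by CA projection onto the fitted helix axis.

## Superposition and fluctuations

Superposition is the Kabsch SVD solution with a determinant guard against
reflections. RMSF superposes all models onto an iteratively refined mean
(3 iterations, which converges at these sizes) over all CA atoms by
default. For the isotropic Gaussian generator (below) the expected RMSF
is σ√3; tests recover it within 5% on the full dimer. On very short
selections the six rigid-body degrees of freedom absorbed by the fit bias
RMSF visibly low — a property of the estimator worth remembering when
analysing fragments.

## The synthetic-structure generator

Every analysis stage is validated on structures with known ground truth,
generated in code:

* **Coiled-coil builder.** Each chain is an ideal minor helix built by
  NeRF from ideal bond geometry, with (φ, ψ) solved at build time so that
  the template twist plus the supercoil frame rotation gives exactly
  360°/residues-per-turn (default 3.5, an exact heptad) at the requested
  rise (default 1.51 Å); the chain is then wrapped onto a left-handed
  superhelix (default pitch 140 Å) and rotated so the mean CB phase of
  the heptad a/d positions faces the partner. Side chains come from a
  small built-in rotamer table (most-common χ sets) followed by greedy
  clash-driven rotamer relaxation; among equally clash-free rotamers,
  charged side chains (K/R/D/E) take the candidate farthest from the
  partner chain, a solvation proxy that prevents vacuum artifacts in
  which long charged side chains drape over the interface. The PALB2
  constructors use superhelix radius 5.5 Å — the smallest swept value at
  which rigid ideal rotamers pack without steric overlap (the canonical
  4.9 Å remains the generic default).
* **Register.** The antiparallel homodimer register centres the
  Y28–Y28′ aromatic pair on the dimer midpoint (ring centroids ≈ 5 Å,
  analysable stacking classes), with L24–L24′ in the flanking layer
  inside the 7 Å contact shell. With rigid rotamers a single register
  cannot simultaneously realise a 4 Å L24 Cδ–Cδ distance and the Y28
  stack; the aromatic pair was prioritised. The heterodimer pairs PALB2
  residue i with BRCA1 position 1435−i, which brings Y28 against
  M1411/L1407/L1404 and K18 within reach of D1419. The BRCA1-like chain
  is a *designed synthetic* sequence reproducing the documented interface
  residues and charge composition (4 positive, 7 negative, strongly
  negative C-end) — analyses of it validate machinery, not the native
  molecule.
* **Ensembles.** `perturb_ensemble` applies independent isotropic
  Gaussian rigid shifts per residue (per-atom mode behind a flag);
  `emulate_unfolding` rebuilds a growing C-terminal window with
  coil-region dihedrals (φ ∈ [−160°, −60°], ψ ∈ [90°, 175°]) under ideal
  bond geometry; `md_like_ensemble` combines terminal fraying (optionally
  transient, applied to a fraction of models), the Gaussian displacement
  field, and an optional rigid chain separation for destabilized dimers.
  All generators take mandatory seeds and restore the caller's RNG state.

What the generator does **not** emulate: force-field energetics, sterics
of the randomized coil (unfolded tails can pass through the partner —
the reason site metrics use retained *native* contacts, which a
pass-through cannot inflate), solvent, and realistic thermal
correlations. Rigid per-residue displacement also degrades hydrogen-bond
geometry faster than true thermal motion, so emulated ensemble helicities
(≈56% for the wild-type dimer at σ = 0.3 Å) sit below MD-derived values
(≈74%); the suite therefore carries *relative* claims (wild type above
unfolding mutant) rather than absolute percentages.

## Variant reports and the six-variant suite

For each context the headline metric is: protomer — intra-protomer
contacts at 7 Å (with backbone hydrogen bonds and helicity reported
alongside); homodimer — inter-protomer atom contacts at 7 Å; heterodimer
— retained native contacts at the mutation site at 10 Å, the native set
taken from each group's own reference model. Per-frame means per
replicate feed a pooled-variance two-sample *t*-test, one-tailed in the
observed direction (t = 0 gives p = 0.5 by symmetry), and the mutant
group mean is normalized by the wild-type group mean. Calls: reduced at
normalized ≤ 0.8, enhanced at ≥ 1.2, slightly enhanced at [1.05, 1.2),
all at p < 0.05, otherwise no effect. The source analyses state calls
qualitatively, so the band edges are package defaults, exposed as
arguments.

The six-variant suite (3 replicates; 8 models per replicate for
protomer/homodimer, 20 for the cheap heterodimer site metric) emulates
each variant's described phenotype. Most of the pattern needs no knobs at
all — it follows from the structural mutation itself (measured on static
models: L24S loses ~34% of site contacts to BRCA1-like partners, Y28C
~59%, T31I gains ~19%, K18R is neutral on the homodimer). The knobs that
exist each implement a described mechanism: L35P unfolds the C-terminus
(window from residue 32/33) and loosens the dimer (1 Å separation); Y28C
perturbs the protomer (unfolding from 29) and destabilizes the homodimer
(1.2 Å separation, 1.4× fluctuation); R37H orders the BRCA1-like
disordered N-terminal region (wild type disordered through 1401, R37H
through 1392); K18R's reinforced salt bridge tethers the BRCA1-like C-end
(wild-type fluctuation ×4.5 on residues 1421–1424, mutant ×1; the
multiplier was calibrated from a sweep so the effect lands mid-band,
~+11%). The resulting call pattern is stable across generator seeds.

## Numerical choices and degenerate inputs

Distances carry a 1e-9 Å tolerance at cutoff boundaries so equality is
inclusive. The pooled-variance test returns t = 0, p = 0.5 for identical
groups and p = 0 for separated groups with zero variance. Ring classes
require complete rings and raise geometry errors otherwise; helix-axis
fits refuse ranges under 7 residues or with chain breaks. Altloc
resolution keeps the highest-occupancy conformer (ties → "A"); waters and
hetero residues are dropped at load; blank element columns are inferred
from atom names with a message. Multi-model files with ragged atom lists
are rejected with a topology error naming the first differing atom.

## Problem sizes

Defaults are sized for interactive use: the full test suite runs in
about two minutes and the acceptance script in under two, with the
six-variant suite (~1,600 model analyses) the dominant cost. All
replicate counts and model counts are arguments.

## Known limitations

* The synthetic dimers are idealized: a single register, rigid rotamers,
  no backbone plasticity; their absolute contact counts and buried areas
  characterize the stand-in, not the deposited NMR ensemble.
* Only α-helicity is assigned; sheet-rich inputs will read as coil.
* Hydrogen-bond calling on structures without hydrogens waives the angle
  test for rotatable donors.
* The BRCA1-like chain is synthetic; conclusions about native
  PALB2–BRCA1 energetics require the real sequences and ensembles.
* Impact calls depend on the stated band edges; sensitivity to them
  should be checked when porting the thresholds to other systems.
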