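---
title: "Models and methods behind cycloscan"
author: "cycloscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cycloscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycloscan)
```

# The scientific problem

Human cyclophilins are peptidyl-prolyl isomerases (PPIases) whose
catalytic domains are nearly identical at the proline-binding (S1')
pocket, yet must discriminate among substrates.  The discriminating
element is an adjacent cavity, the S2 pocket, whose mouth is controlled
by a small set of "gatekeeper" residues — the positions equivalent to
PPIA Thr73 (gatekeeper 1), Lys82 (gatekeeper 2) and Ala103 (gatekeeper
3), together with the rim positions 81, 107, 110 and 111.  `cycloscan`
implements the two computational legs of that argument:

1. **Family-wide structural comparison.**  PPIase domains are read from
   PDB/mmCIF files, globally aligned in sequence, superposed by the
   Kabsch algorithm, and every member's residues are mapped onto PPIA
   reference numbering (`map_active_site()`).  On top of the map sit a
   cyclosporin-competence classifier for position 121 (Trp/His
   permissive; Tyr/Glu not), a three-loop conformational taxonomy
   (beta1-beta2 deletion, alpha1-beta3 length class, alpha2-beta8
   conformer), and a three-way S2-surface classification.
2. **An in silico specificity screen.**  All 400 tetrapeptides of the
   form X-Z-Gly-Pro (substrate positions P3-P2-P1-P1') are docked into a
   receptor by tethered Metropolis Monte-Carlo sampling with flexible
   P2/P3 and gatekeeper sidechains, and scored by a binding-energy
   estimate plus an S2-penetration distance metric, rendered as a 20x20
   P3 x P2 specificity array.

# The active-site map and derived classifiers

All cross-isoform semantics go through an `ActiveSiteMap` keyed by the
16 PPIA reference positions (55, 60, 61, 63, 73, 81, 82, 101, 103, 107,
110, 111, 113, 121, 122, 126); raw author numbering is never compared
between structures.  The map is produced by a global Needleman-Wunsch
alignment (BLOSUM62, affine gaps: opening 10, extension 0.5, via
Biostrings) of the one-letter domain sequences.  We deliberately do not
perform iterative structural outlier rejection: the comparison
replicated here is a single global superposition over all shared heavy
atoms of aligned residue pairs.  "All atoms" means all *heavy* atoms;
deposited crystal structures carry no hydrogens.

The surface classification is a pure function of two numbers:

* `gap_width` — the minimum heavy-atom distance between the gatekeeper-1
  and gatekeeper-3 sidechains (CA stands in for glycine), and
* `net_formal_charge` — the sum of formal sidechain charges at pH 7
  (Asp/Glu -1, Lys/Arg +1, His 0) over the seven rim positions.

A gap below the occlusion threshold gives *occluded* regardless of
charge (occlusion is a geometric override); otherwise a net charge at or
below the acidity threshold gives *acidic*, else *mixed-neutral*.  The
thresholds (5.5 Angstrom, -2) are not physical constants.  They were
chosen once so that the documented family grouping is reproduced (PPIA
mixed-neutral; SDCCAG-10, PPIC and PPWD1 acidic; NKTR occluded) and are
exposed in `cycloscan_thresholds()`.  Qualitative electrostatics is
replaced by formal-charge counting; continuum electrostatics is out of
scope.  Similarly, the alpha2-beta8 loop classes are separated by a
backbone-RMSD cutoff of 1.5 Angstrom after whole-domain superposition —
the literature gives classes but no number, so the number lives in
configuration, not in prose.

# The energy model

The reference scoring function (ICM) behind the original screen is
proprietary, so `cycloscan` documents its own and treats all energies as
an *internal scale*: only orderings and class-level contrasts are ever
compared with published results, never printed energy extremes.

For a pose with peptide atoms $i$ and receptor atoms $j$:

$$E_\mathrm{bind} = E_\mathrm{inter} + E_\mathrm{strain}$$

* $E_\mathrm{inter}$ (within an 8 Angstrom cutoff):
  * 6-12 Lennard-Jones with per-element parameters
    ($R_{min}/2$: C 1.9, N 1.8, O 1.7, S 2.0 Angstrom;
    $\epsilon$: 0.08, 0.17, 0.21, 0.25 kcal/mol), Lorentz-like
    combination ($R_{min,ij} = r_i + r_j$, $\epsilon_{ij} =
    \sqrt{\epsilon_i \epsilon_j}$), capped at the clash energy;
  * Coulomb with the distance-dependent dielectric
    $\varepsilon(r) = 4r$, i.e. $E = 332\,q_iq_j/(4r^2)$, over coarse
    partial charges (ionisable groups carry their formal charge spread
    over terminal heavy atoms, polar groups a local dipole);
  * a 10-12 hydrogen-bond term
    $\epsilon_{hb}\,[5(r_0/r)^{12} - 6(r_0/r)^{10}]\cos^2\theta$
    with $r_0 = 2.9$ Angstrom, $\epsilon_{hb} = 2$ kcal/mol, active for
    donor-acceptor heavy-atom pairs within 2.5-3.5 Angstrom whose
    base-donor-acceptor angle $\theta \ge 90^\circ$ (hydrogens are
    implicit; the donor's antecedent atom defines the direction).
* $E_\mathrm{strain}$, all terms non-negative:
  * a rotamer-deviation penalty $k_\chi \sum (1 - \cos(\chi - \chi_0))$
    ($k_\chi = 0.5$ kcal/mol) over the flexible torsions, measured from
    the template-placed state;
  * repulsive-only (WCA-shifted) intra-peptide sterics over atom pairs
    more than three bonds apart;
  * repulsive-only sterics of moved gatekeeper sidechains against the
    rest of the receptor, relative to the initial rotamers.

Two wrinkles deserve emphasis.  First, a pose with **no**
peptide-receptor pair inside the cutoff is the separated reference and
scores exactly 0 — not approximately.  Second, the self-sterics must be
repulsive-only: an earlier formulation (full LJ referenced to the
initial pose) let a peptide built with an internal clash convert its own
relaxation into hundreds of kcal/mol of spurious "binding".  With WCA
terms, internal relaxation can reach zero but never below.

Protonation is fixed: His neutral, Asp/Glu deprotonated, Lys/Arg
protonated, peptide termini neutral.  No pKa calculation is attempted.

# Tethered Monte-Carlo sampling

Each tetrapeptide is built with ideal internal geometry (idealised bond
lengths/angles; near-planar rings; proline's backbone phi forced to
-65 degrees because its ring is built with fixed internal torsions),
placed by superposing its Gly-Pro onto the template's bound Gly-Pro
after bringing template and receptor into one frame over the CA atoms of
commonly mapped active-site positions, and the receptor's catalytic
arginine is rebuilt on the template rotamer.  The Gly-Pro heavy atoms
are tethered harmonically ($k = 10$ kcal/mol/Angstrom^2) to that pose;
the tether enters Metropolis acceptance but is excluded from the
reported `E_bind`.

The move set is torsional: sidechain chi angles of P2 and P3, the P2/P3
backbone torsions that rotate only the N-terminal (non-anchored) side,
and the sidechain chis of the three gatekeepers (plus any residues named
in `extra_flexible`, e.g. the arginine unique to one paralog's S2
region).  Each move perturbs one torsion by a uniform step, re-evaluates
only the pair terms that involve moved atoms, and is accepted by the
Metropolis criterion.  The sampler is bit-reproducible: it uses its own
splitmix64 generator, and each peptide of a screen derives its seed from
the master seed and its own sequence, so the 400 runs are independent
and individually repeatable.

`mc_params()` defaults to the conventional constant 300 K schedule.
Screens, however, use `screen_params()`: a hot start (10,000 K
equivalent) annealed geometrically (factor 0.2, six stages) with a
60-degree maximum step.  The reason is the mandated extended start
conformation: a bulky P2 or P3 (tryptophan at both positions is the
worst case) begins overlapping the pocket walls, and with per-pair
energies capped at the clash energy the barrier out of that basin is a
few hundred kcal/mol — unreachable at 300 K in any realistic number of
moves, but crossed reliably during the hot stages.  The reported result
is always the minimum-total-energy pose seen, so the final cold stages
make the procedure effectively a stochastic minimisation, which is what
a "lowest-energy complex" readout requires.

Paper-scale runs use 200,000 iterations per peptide; the test suite and
examples use scaled-down counts (stated at each use) to stay inside
their time budgets.  The two readouts per peptide are `E_bind` and
`d_S2`, the minimum distance from any peptide heavy atom to the
gatekeeper-2 CA at the far end of the S2 pocket.  The peptide-side atom
of that distance is deliberately the *minimum* over heavy atoms — the
most permissive reading of "filling the pocket" — and the two metrics
are never fused into one score: a low-energy pose may or may not
penetrate the pocket, and the arrays report both.

# The synthetic world

`make_toy_receptor()` does not fold a protein.  It arranges idealised
residues and short strand fragments into a scaffold presenting exactly
the features the pipeline depends on: an S1' site with a
catalytic-arginine stand-in, an S2 groove of configurable depth running
away from the anchored Gly-Pro, walls and floor of a configurable
lining residue, and the seven rim positions (PPIA numbering) with
configurable identities, the gatekeeper-1/3 closest approach calibrated
to the configured `gap_width` within 0.1 Angstrom.  Residues are placed
tip-first relative to the path of an anchored reference peptide and
retracted until the *immovable* region (the tethered Gly-Pro and the P2
backbone) is clash-free; a final relaxation pass retracts movable parts
from one another.  The P3 region is intentionally not protected:
scenarios are allowed to obstruct it.

Ground truth is induced by shaping sterics and charge, never by editing
the energy function:

* **aromatic-S2** (default): a leucine-lined groove of width 10
  Angstrom; bulky aromatic P2 sidechains earn more Lennard-Jones
  contact than small ones.
* **occluded**: gap 3.5 Angstrom *plus* rigid bulky residues filling
  the deep groove.  The flexible gatekeeper copies cannot block the
  pocket on their own — one chi rotation swings them aside — whereas in
  the occluded isoform the occluding bulk is packed against the fold,
  which the rigid plug emulates.
* **acidic-P3**: the groove lining and a P3-flanking patch are
  arginine.  A cationic patch alone is not sufficient: basic P3
  sidechains otherwise rescue themselves by hydrogen-bonding to any
  exposed backbone carbonyl, so the entire P3-accessible lining must be
  positive for "acidic favored, basic disfavored" to emerge.

What a green synthetic test establishes is that the machinery recovers
a *designed* signal from geometry and charge; it does not establish
that the energy model ranks real cyclophilin substrates correctly.
Conversely, the accession-gated tests compare against deposited family
structures but need those files (a local cache via `CYCLOSCAN_PDB_DIR`,
or a live download); in a fully offline environment they fail at the
fetch step by design rather than being silently skipped.

# Numerical choices and degenerate inputs

* Alternate locations resolve to the highest-occupancy conformer, ties
  by altloc identifier; NMR ensembles use model 1.
* Kabsch superposition excludes reflections (determinant +1 enforced);
  fewer than three matched atoms is an error, not a warning.
* Pair distances below 0.5 Angstrom score the large finite clash energy
  (1000 kcal/mol) and set a flag; nothing returns infinity.
* Ties in `rank_top()` break lexicographically by peptide sequence.
* "Favored/disfavored" in `classify_preferences()` means the class
  median energy lies below/above the overall array median; exact ties
  are flagged neutral.
* The chemistry-class partition places His with basic and Cys/Met with
  aliphatic-small; these borderline placements are configuration, not
  doctrine.
* Identity fractions are computed over aligned non-gap columns of the
  global domain alignment; coverage is the aligned fraction of the
  reference.

# Known limitations

* The energy scale is internal; absolute values are not comparable to
  any published kcal/mol figures, and are only used for orderings.
* Receptor backbone flexibility, explicit solvent, entropy and pKa
  effects are out of scope.
* Sidechains are built from idealised internal coordinates; rings are
  near-planar approximations adequate for a model potential but not for
  crystallographic work.
* The synthetic scaffold has no tertiary fold; conclusions about real
  receptors always require the accession-gated paths.
* With extended starts, a small fraction of bulky peptides in heavily
  obstructed (occluded) scenarios can remain in clashed local minima at
  screen-scale iteration counts; their high energies are reported as
  observed, which is also the physically expected signature of an
  occluded pocket.
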