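---
title: "Backbone substates, helical twist and restraint analysis of 8-oxoguanine duplexes"
author: "oxoduplex"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

8-oxoguanine (oxoG) is the most common oxidative DNA lesion. Its
Watson-Crick edge is identical to guanine's — the modification adds an O8
carbonyl at C8 and a proton on N7, both on the Hoogsteen edge — so the
lesion pairs C normally and does not melt the duplex. Its functional
effects on proteins that do not touch the Hoogsteen edge must therefore run
through something subtler. The working hypothesis this package supports is
conformational: oxoG biases the sugar-phosphate backbone 3' of the lesion
from the common BI substate into BII, and unwinds the helix on the 5' side.
`oxoduplex` implements the complete structural-analysis layer needed to ask
that question of multi-model duplex coordinates: backbone torsions and
BI/BII calls, base-pair frames and twist, Watson-Crick hydrogen-bond
occupancy, NOESY-derived restraints and violation scoring, ensemble RMSD
statistics, and the enzyme-kinetics specificity ratios that quantify the
functional consequence.

## The BI/BII statistic

For nucleotide k, the phosphodiester linkage on its 3' side carries the
torsions epsilon (C4'-C3'-O3'-P) and zeta (C3'-O3'-P-O5'). Step k (spanning
nucleotides k and k+1) is classified from their difference, wrapped into
(-180, 180]:

* BI: eps - zeta <= 20 degrees (canonical value near -80; epsilon trans,
  zeta gauche-),
* BII: eps - zeta > 20 degrees (canonical value near +90; epsilon gauche-,
  zeta trans).

Named torsions are reported in [0, 360) and differenced with wrapping,
which puts both canonical substates on the correct side of the single
20-degree threshold. The boundary value itself classifies as BI: the
defining inequalities ("less than" for BI, "over" for BII) leave exactly 20
unassigned, and assigning the measure-zero boundary to the majority state
is the conservative choice. `classify_step()` is cross-checked in the test
suite against a direct enumeration of the rule on a 1-degree (eps, zeta)
grid.

## Frames and twist

Helical twist needs a reference frame per base. `base_frame()` superposes
an embedded idealized base geometry (standard-reference-frame convention:
x toward the major groove, y toward the sugar, z along the base normal)
onto the observed six-membered ring; 8-oxoguanine uses the guanine ring,
with O8 taking no part in the fit. `pair_frame()` flips the complementary
base's frame 180 degrees about x (the antiparallel correction) and takes
the rotation average, which for two frames is the geodesic midpoint (the
tests verify this against a quaternion-slerp oracle). `step_twist()`
measures the rotation between successive pair frames about their mean
normal and the rise as the projection of the origin displacement onto it —
a mid-step-triad convention in the 3DNA style. A global-helix-axis
definition (Curves+ style) was deliberately avoided: it needs axis-fitting
machinery, and the scientific claim being reproduced — a local twist dip at
the lesion — is robust to the convention. The convention is named in the
output metadata.

## Restraint compilation

The NOESY pipeline follows standard solution-NMR practice for duplexes:

1. **Calibration**: within each mixing-time set independently,
   `r_i = r_ref * (V_ref / V_i)^(1/6)` against the cytosine H5-H6 cross
   peak. The reference distance defaults to 2.45 angstrom (fixed covalent
   geometry); it is an argument, because the worked closure tests use the
   generator's exact H5-H6 distance instead.
2. **Merging**: a proton pair reliably present in every mixing-time set
   becomes a single "averaged" restraint (arithmetic mean); any other pair
   is taken from its highest-volume ("most reliable") single peak and
   labelled "non-averaged". Both operationalizations are package choices:
   the averaging scheme and the reliability criterion are not uniquely
   fixed by common practice, and both are deliberately simple.
3. **Grouping and bounds**: short (< 3 A), medium (3-5 A), long (> 5 A),
   with symmetric no-penalty tolerances of 0.4 / 0.7 / 1.0 angstrom and a
   +1.0 angstrom pseudoatom widening of the upper bound for
   methyl-containing restraints. These defaults are package configuration,
   overridable through `restraint_tolerances()`.
4. **Symmetry duplication**: for a self-complementary duplex every
   restraint holds at the sequence-equivalent position of the second
   strand. A subtlety worth stating: the lesion-bearing derivative of a
   palindrome still anneals with itself, because X pairs the C that faced
   the original G — so the physical sample carries one lesion per strand,
   and duplication remains exact. Duplicates carry provenance
   `"symmetry-copy"`; self-symmetric restraints are emitted once and
   flagged.
5. **Watson-Crick and dihedral restraints**: 3 heavy-atom distance
   restraints per G:C or oxoG:C pair and 2 per A:T, non-terminal pairs
   only; epsilon/zeta of every internal linkage restrained to a BI range
   (defaults epsilon 155-245, zeta 235-325), the lesion's linkage switched
   to the BII ranges epsilon 215-295 / zeta 155-205, and the two dihedrals
   on either side (gamma and delta of the lesion, alpha and beta of the
   next nucleotide) broadened by 20 degrees on each side of their parent
   ranges. The BI parent ranges are package defaults centered on the
   idealized template's torsions.

`violation_report()` scores any structure against both restraint types:
distance violations as excursions past the bounds, dihedral violations as
the circular distance outside the allowed arc.

`run_pipeline()` scores the restraints as measured (plus Watson-Crick and
dihedral restraints); symmetry duplicates are a restraint-generation
convenience for structure calculation and are exactly satisfied only by
dyad-symmetric coordinates, so scoring them is left as an explicit step.

## The synthetic generators

Every analysis stage is validated by parameter recovery against generators
with exact ground truth. Two builders exist because one cannot own both
ground truths at once:

* `build_helix()` places idealized base-pair templates on a straight screw
  axis with per-step twist and rise (defaults 36 degrees and 3.38
  angstrom). Twist/rise recovery is exact by construction; backbone
  torsions are emergent. The nucleotide template's internal coordinates
  were fitted numerically, once, so that stacking at the default screw
  yields a continuous strand (O3'-P 1.59 angstrom, sound junction angles),
  a comfortably BI backbone (eps - zeta near -65) and a C2'-endo sugar
  (ring phase near 162 degrees). With uniform twist the built duplex is
  exactly two-fold symmetric, which is what makes the symmetry-duplication
  closure test exact.
* `build_torsion_exact()` grows the strand by internal-coordinate chaining,
  so requested epsilon/zeta are realized exactly (to numerical precision);
  the default chain torsions are the values the ideal helix realizes, so
  the default build is again a proper B-helix (twist near 36, rise near
  3.4). `bii_at = k` switches the linkage 3' of position k to canonical
  BII (270/180). The complementary strand is placed per-residue from the
  fitted base frames, which makes Watson-Crick geometry exact but the
  second strand not an exact symmetric copy.

`make_ensemble()` adds iid Gaussian coordinate jitter under an explicit
seed; `synth_peaklist()` emits isolated-spin-pair volumes `c * r^-6` with
multiplicative log-normal noise, one record per mixing time (70/140/200 ms
by default), cytosine H5-H6 reference pairs always in range.

### What the generators do and do not emulate

The jitter is uncorrelated per atom. Real NMR/MD ensembles move
collectively: bonds stay rigid and torsion excursions are far smaller than
iid jitter of the same coordinate amplitude implies. Two consequences are
documented rather than hidden. First, the stand-in ensembles used in the
acceptance checks (13 and 14 models, lesion linkage built BII) use 0.05
angstrom jitter, chosen so per-model backbone dihedral excursions stay at
the ~11 degree scale that restraint-satisfying solution ensembles exhibit;
the resulting within-ensemble spread (max pairwise all-atom RMSD about
0.13 angstrom) sits comfortably inside the deposited-ensemble bound of
0.92 angstrom rather than reproducing its exact magnitude. Second, the
internal-coordinate builder propagates a mid-chain BII joint globally — the
helix kinks at the lesion instead of absorbing the change locally — so the
backbone RMSD between the two stand-in representatives is reported but
never compared to the deposited-structure value; it is a property of the
generator, not of lesion-bearing DNA. Passing tests on these synthetic
ensembles therefore demonstrate that the analysis operators are correct,
not that real oxoG duplexes behave this way; conclusions about real data
require the deposited coordinates.

## Kinetics

The enzyme-kinetics layer treats measured constants as inputs: the
packaged table carries K_M and V_max for cleavage of the undamaged and
lesion-containing recognition sites (and, where saturation was
unreachable, a directly measured specificity from the linear low-substrate
slope, as the record type allows). `specificity()` and
`relative_efficiency()` compute V_max/K_M and its ratio to the undamaged
reference. `mm_rate()`/`fit_mm()` exist to validate synthetic rate
fixtures by parameter recovery (self-starting `SSmicmen` nonlinear least
squares); they never re-derive the measured constants.

## Numerical choices and degenerate inputs

* Dihedrals use the atan2 formulation under the IUPAC sign convention;
  coincident or collinear points are errors, not NaNs. The test oracle is
  an independent projection-based route.
* Superposition is Kabsch via SVD with the reflection guard; the oracles
  are Horn's quaternion eigen-decomposition and an external fitted-RMSD
  implementation.
* Pseudorotation uses the standard phase/amplitude relations; when nu2 is
  about zero the phase is taken from the numerator alone and the result is
  flagged ambiguous instead of throwing.
* Conventional per-atom RMSD is used throughout; for iid jitter of sd
  sigma on both models the expected pairwise RMSD is sigma * sqrt(6),
  which is what the simulation tests assert.
* PDB numbering is normalized to 1-based per chain on read; altlocs other
  than A are dropped with a warning; models must share one atom topology.
* Angles at exactly the BI/BII boundary go to BI (see above).

## Problem sizes

The packaged checks run on dodecamer duplexes (about 760 atoms with
hydrogens), ensembles of 10-20 models, peak lists of about 1400 proton
pairs over three mixing times, and 20-replicate noise studies — sizes at
which every closure property is exact or tightly bounded and the whole
suite runs in a few minutes on one core.

## Worked example

```{r example}
library(oxoduplex)

# a lesion duplex with the backbone switched to BII 3' of position 4
s <- build_torsion_exact("CGCXAATTCGCG", bii_at = 4)
ens <- make_ensemble(s, sigma = 0.05, n = 13, seed = 1)

step_calls(representative(ens, "medoid"), "A", 1)
bii_frequency(ens, "A")
pairwise_rmsd(ens, "all")$max

map <- pair_duplex(ens, "CGCXAATTCGCG")
twist_profile(ens, map, model = 1)
hbond_occupancy(ens, site_keys(map, 4:9))

pk <- synth_peaklist(s, noise = 0.1, seed = 1)
dr <- compile_restraints(pk, ref = list(res_i = 3, atom_i = "H5",
                                        res_j = 3, atom_j = "H6"))
restraint_ledger(dr)
violation_report(s, duplicate_symmetry(dr, map),
                 backbone_dihedral_restraints("CGCXAATTCGCG"))
```

## Known limitations

* No mmCIF input; protein chains are passed through but not analyzed.
* Only twist and rise of the six step parameters are computed and tested.
* The representative-structure operation averages or picks the medoid; no
  force-field minimization is applied, so cross-checks against deposited
  "averaged minimized" coordinates should use the deposited frames.
* The NOE model is the isolated spin pair (r^-6) with log-normal noise; no
  spin diffusion or relaxation dynamics.
* The generators' iid jitter and global kink propagation, discussed above.
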