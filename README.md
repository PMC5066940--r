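# oxoduplex

Structural analysis of B-form DNA duplexes carrying 8-oxoguanine (oxoG),
the most abundant oxidative DNA lesion. The lesion leaves the Watson-Crick
edge of guanine untouched, yet measurably changes how enzymes treat the
duplex; the structural fingerprint is in the sugar-phosphate backbone. This
package is for structural biologists and modellers who want to quantify
that fingerprint in multi-model coordinate ensembles (solution-NMR or MD),
and to rebuild the restraint bookkeeping behind such ensembles.

## What it computes

**BI/BII backbone substates.** For the phosphodiester linkage 3' of
nucleotide k, with backbone torsions epsilon (C4'-C3'-O3'-P) and zeta
(C3'-O3'-P-O5') in [0, 360):

    step k is BII  if  wrap(eps - zeta) > 20 degrees
    step k is BI   otherwise            (canonical BI about -80, BII about +90)

**Helical twist.** Base-pair reference frames are fitted by least-squares
superposition of embedded standard base geometries onto the observed rings;
twist Omega is the rotation between successive pair frames about their mean
normal, rise the projected origin displacement (mid-step-triad convention).

**Restraints.** NOESY volume-to-distance calibration
(`r = r_ref (V_ref/V)^(1/6)` against cytosine H5-H6), mixing-time merging
(averaged / non-averaged), length grouping with tolerances, symmetry
duplication onto the second strand, Watson-Crick distance restraints,
BI/BII dihedral restraints (lesion linkage: eps 215-295, zeta 155-205), and
violation scoring of any structure against any restraint set.

**Ensembles.** Kabsch superposition, pairwise RMSD matrices,
medoid/mean-coordinate representatives.

**Kinetics.** Specificity constants V_max/K_M and efficiencies relative to
the undamaged substrate, from measured constants treated as inputs.

**Synthetic generators.** Ideal duplex builders with exact ground truth
(per-step twist/rise; exact epsilon/zeta with lesion injection), seeded
coordinate-jitter ensembles, and r^-6 synthetic peak lists — so every
analysis stage is validated by parameter recovery.

## Worked example

Build a lesion duplex with the backbone switched to BII 3' of position 4,
expand it into a 13-model ensemble, and analyze:

```r
library(oxoduplex)

s   <- build_torsion_exact("CGCXAATTCGCG", bii_at = 4)   # X = 8-oxoG
ens <- make_ensemble(s, sigma = 0.05, n = 13, seed = 1)

head(step_calls(representative(ens, "medoid"), "A", 1)[, -(1:2)])
#>   step epsilon  zeta eps_minus_zeta state
#> 1    1   185.3 251.1         -65.80    BI
#> 2    2   182.8 261.3         -78.49    BI
#> 3    3   177.6 253.8         -76.19    BI
#> 4    4   273.5 175.7          97.78   BII
#> 5    5   188.0 250.1         -62.09    BI
#> 6    6   182.1 259.7         -77.60    BI
```

The classifier flags exactly one BII step — the linkage 3' of the lesion —
and `bii_frequency(ens, "A")` shows it in 13 of 13 models (frequency 1 at
step 4, 0 elsewhere). The ensemble is tight:

```r
pairwise_rmsd(ens, "all")$max
#> [1] 0.128        # angstrom, all atoms
```

Compile restraints from a synthetic NOESY peak list with 10% volume noise
and score the source structure:

```r
pk <- synth_peaklist(s, noise = 0.1, seed = 1)
dr <- compile_restraints(pk, ref = list(res_i = 3, atom_i = "H5",
                                        res_j = 3, atom_j = "H6"))
unlist(restraint_ledger(dr))
#>     averaged non_averaged       methyl        total
#>          536            0           57          593
violation_report(s, dr, backbone_dihedral_restraints("CGCXAATTCGCG"))
#> <violation_report> 1 model(s)
#>   max distance violation: 0 A
#>   max dihedral violation: 0 deg
```

The ledger identity `averaged + non_averaged + methyl = total` always
holds (peaks present at every mixing time average; thinned peak lists
produce non-averaged entries). Enzyme-kinetics ratios from the packaged
measured constants:

```r
kinetics_table()[, c("site", "specificity_min", "relative")]
#>                  site specificity_min relative
#> 1 -GAATTCG-/-CTTAAGC-         0.01500   1.0000
#> 2 -XAATTCG-/-CTTAAGC-              NA       NA
#> 3 -GAATTCG-/-CTTAAXC-         0.00031   0.0207
#> 4 -GAATTCX-/-CTTAAGC-         0.00168   0.1117
```

The lesion inside the recognition site suppresses cleavage below
quantifiable saturation; 3' of the site it cuts the specificity constant
roughly nine-fold.

A full run (`run_pipeline()`, or `inst/scripts/run_pipeline.R` from a
shell) emits per-step TSV tables (torsions, BI/BII calls and frequencies,
twist/rise, hydrogen bonds and occupancy), violation and RMSD reports, and
a summary JSON, deterministically for a given config and seed.

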