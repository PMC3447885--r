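# zincluster

Tools for characterizing trinuclear zinc–thiolate (Zn₃Cys₉) clusters of the
kind found in CXC domains and pre-SET motifs of histone lysine
methyltransferases.

Cysteine-rich CXC domains fold around three Zn²⁺ ions coordinated by nine
invariant cysteines — six terminal (binding one metal) and three bridging
(binding two). Establishing such a cluster experimentally chains several
inferences: the metal count from native electrospray mass spectrometry, the
metal-to-cysteine connectivity from ¹H–¹¹³Cd correlation NMR (often
incomplete, because weak ³J couplings leave edges unobserved), completion
of the connectivity by constraint satisfaction and violation ranking,
coordination-restraint construction for structure refinement, and
structure-side verification of the cluster's topology and geometry. The
sequence signature of the resulting superfamily — nine ligands with bounded
spacing and an invariant Asn two residues past the last ligand — can then
be scanned across protein sequences. `zincluster` implements each of these
stages as composable, tested R functions, for structural biologists and
bioinformaticians working on metalloprotein clusters.

## What it computes

- **Mass stoichiometry** — neutral mass from a monoisotopic peak,
  `M = m/z·z − z·m_carrier` (carrier 1.0 Da by convention, proton mass
  optional); holo mass `M_apo + n·(m_isotope − z)` for divalent metal
  adducts; and the `n` minimizing `|M_obs − M_pred|` over `0..n_max`.
- **Connectivity completion** — exhaustive enumeration of assignments
  satisfying per-metal coordination numbers, ligand degrees in `[1, 2]`,
  the bridging-ligand count, and "each ²J-coupled metal pair shares exactly
  one ligand"; candidates ranked by externally supplied violation counts.
- **NMR observables** — per-residue chemical-shift perturbation
  `Δδ = δ_b − δ_a`; steady-state heteronuclear NOE `I_sat/I_ref` with noise
  propagation `σ_NOE = |NOE|·√((σ/I_sat)² + (σ/I_ref)²)`; H/D-exchange
  protection classes from a 3σ detection threshold.
- **Restraint tools** — NOE range classification (intra / sequential /
  medium / long / ambiguous), restraints-per-residue density, volume
  calibration `d = d_ref·(V_ref/V)^{1/6}` clamped to 2.2–6.0 Å, and
  tetrahedral coordination restraints (2.3 Å bonds, 109.5° angles).
- **Cluster geometry** — metal-site detection by distance cutoffs,
  renumbering-invariant topology fingerprints, coordination reports,
  Kabsch superposition (proper rotations only), iterative-mean ensemble
  RMSD, hydrogen-bond checks.
- **Motif scanning** — a variable-gap pattern grammar with the built-in
  superfamily consensus `CX[C/H]X2-13CX4-7CXCX5-60CX2-4CX1-2CX2-15CXN`,
  exhaustive registration enumeration, gap reports and tandem-domain
  detection.
- **Synthetic data** — seeded generators for every input class (ideal or
  noised cluster ensembles, partial connectivity tables, decay and NOE
  intensity tables, motif-bearing sequences) with ground truth attached.

## Worked example

```r
library(zincluster)

# 1. Metal stoichiometry from the +5 native-MS peak
peak_mass <- neutral_mass_from_peak(mz = 1165.8361, z = 5)
peak_mass
#> [1] 5824.181      # 5824.1805 Da
infer_stoichiometry(peak_mass, apo_mass = 5638.48, metal = zn_spec(),
                    n_max = 6, tolerance = 0.5)
#> Stoichiometry: n = 3 metal ion(s)
#>   predicted mass: 5824.2670 Da
#>   residual:       0.0865 Da (within tolerance)

# 2. Complete the partial Cd NMR connectivity (metal C has two unobserved
#    ligands) and rank candidates by distance violations against a
#    reference structure
cands <- enumerate_assignments(cxc_partial_dataset())
length(cands)
#> [1] 9
ens  <- make_cluster_coordinates(n_models = 1, noise = 0)
gt   <- attr(ens, "ground_truth"); model <- ensemble_model(ens)
mx   <- as.matrix(model[match(gt$metal_resno, model$resno), c("x","y","z")])
rownames(mx) <- names(gt$metal_resno)
sg   <- model[model$elety == "SG", ]
lx   <- as.matrix(sg[, c("x","y","z")]); rownames(lx) <- sg$resno
scorer <- distance_violation_scorer(mx, lx)
rk <- rank_by_violations(cands, vapply(cands, scorer, numeric(1)))
rk$selected
#>   A: 525, 527, 539, 544
#>   B: 525, 546, 553, 556
#>   C: 539, 553, 558, 561
#>   bridging: 525, 539, 553

# 3. Structure-side check: fingerprint and coordination geometry
cluster_topology(rk$selected)
#> cluster topology fingerprint
#>   metal 1: {1,2,3,4}
#>   metal 2: {1,5,6,7}
#>   metal 3: {3,6,8,9}
#>   bridging: {1,3,6}
site <- detect_metal_sites(model)[[1]]
coordination_report(site)$summary
#> $mean_bond
#> [1] 2.3
#> $mean_angle
#> [1] 109.4712
#> $rms_angle_deviation
#> [1] 0.02877937
```

The selected completion assigns Cys539 and Cys553 as the two unobserved
ligands of the third metal; the fingerprint shows three metals sharing
bridging ligands 1/3/6 (residues 525/539/553), each tetrahedrally
coordinated with 2.3 Å bonds.

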