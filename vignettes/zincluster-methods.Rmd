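---
title: "Methods: inferring and analysing Zn3Cys9 clusters with zincluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring and analysing Zn3Cys9 clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zincluster)
```

## The problem

CXC domains and the pre-SET motifs of SUV39/SET2/EZ histone lysine
methyltransferases fold around a trinuclear zinc–thiolate cluster: three
Zn²⁺ ions, each tetrahedrally coordinated by four cysteine Sγ atoms, with
nine cysteines in total — six *terminal* (degree 1) and three *bridging*
(degree 2). Establishing such a cluster from solution data is a chain of
small, individually checkable inferences, and `zincluster` implements each
link with explicit models and testable contracts. This vignette records
the models, the tunable parameters, and the design decisions taken where
the methodology was genuinely open.

## Metal stoichiometry from native mass spectrometry

For a peak at `m/z` with charge `z`, the neutral monoisotopic mass is

    M = (m/z)·z − z·m_carrier.

`m_carrier` defaults to **1.0 Da**: native-MS masses are conventionally
quoted with an integer subtraction per charge, and the package reproduces
that arithmetic exactly. The physically accurate proton mass
(1.007276 Da) is available behind the same argument; at `z = 5` the two
conventions differ by ~0.036 Da, which matters only when comparing against
sub-0.1 Da expectations.

A bound divalent metal contributes `m_isotope − z` Da in the default
(`"paper"`) mode — e.g. ⁶⁴Zn²⁺ contributes 63.929 − 2 = 61.929 Da,
compensating the two protons displaced on binding — or
`m_isotope − z·m_e` in `"accurate"` mode (electron mass only). The two
modes differ by `n·z·(1 − m_e)` Da for `n` metals.

`infer_stoichiometry()` scans `n = 0..n_max` (default 6) and returns the
residual-minimizing `n`, with ties broken toward smaller `n` (parsimony;
for metal masses far above twice the tolerance, ties cannot occur). A
residual above the tolerance (default 0.5 Da, appropriate for
monoisotopic-resolved native spectra) is *flagged*, not raised: a
best-effort answer with an honest quality bit is more useful in a pipeline
than an exception.

Two printed masses for the same trinuclear species can disagree in
primary sources (e.g. a results narrative quoting 5824.0875 Da where the
caption's own m/z arithmetic gives 5824.1805 Da). The package takes the
m/z→mass arithmetic as definitive, since it is internally consistent and
reproducible from the printed peak.

## Completing metal–ligand connectivity maps

¹H–¹¹³Cd correlation experiments yield direct metal–ligand edges, but
small ³J(Hβ–Cd) couplings can leave edges unobserved; missing edges are
treated as simply unobserved, with no attempt to model coupling
magnitudes. The solver's input (`connectivity_dataset`) carries:

- per-metal coordination numbers (default 4, tetrahedral);
- the candidate ligand pool (residue positions; histidines are allowed in
  the pool — ligand identity is positional, not hard-coded to Cys);
- confirmed edges;
- a maximum ligand degree (default 2);
- the bridging count (default `"auto"`: total coordination minus pool
  size, e.g. 3·4 − 9 = 3);
- optional metal–metal coupling evidence (²J(Cd–Cd) triplet splitting).

Coupling is interpreted as **"shares exactly one ligand"** per pair: a
pair sharing two ligands would push those ligands past degree 2 across a
coupled triangle, and one shared thiolate per pair is what the
triplet-splitting argument supports. `enumerate_assignments()` is an
exhaustive backtracking search over per-metal ligand combinations —
the spaces involved are tiny (tens of candidates), so completeness is
cheap and provable; output order is lexicographic in the added edges for
reproducibility.

Violation scores for ranking candidates are **injected, not computed**:
the package does not run structure refinement. `rank_by_violations()`
sorts ascending with stable ties and flags a candidate "selected" only
when it is the *unique* zero-violation completion; several zeros are all
flagged "ambiguous". For tests and demonstrations,
`distance_violation_scorer()` counts bonds deviating more than 0.5 Å from
the ideal 2.3 Å length against a reference coordinate set — a stand-in
with the same shape as refinement-derived NOE violation counts.

## Per-residue NMR observables

**Chemical-shift perturbation** is reported per nucleus and signed,
`Δδ = δ_b − δ_a` over shared `(residue, nucleus)` keys. Residues present
in only one table are reported as missing, never imputed as zero (prolines
and unassigned residues would otherwise masquerade as unperturbed). A
composite weighted distance is deliberately not the default output; the
per-nucleus form is what bar-plot comparisons of metal-substitution
effects use.

**Heteronuclear NOE** is `I_sat/I_ref` with first-order error propagation
from the spectrum background noise σ:
`σ_NOE = |NOE|·√((σ/I_sat)² + (σ/I_ref)²)`, computed in the algebraically
equivalent form `√(σ² + NOE²σ²)/|I_ref|` so that `I_sat = 0` is handled
gracefully. `I_ref = 0` yields a per-residue `undefined` flag.

**H/D exchange**: a residue is detected at a timepoint when its intensity
exceeds `threshold_multiple × σ`. The default threshold is **3σ** — the
conventional signal-to-noise floor; the methodology offers no sharper
prescription, and it is configurable. Protection classes are defined by
the last *class boundary* at which a residue is detected (boundaries
default to the first spectrum, 2 h and 24 h); intermediate timepoints
(30, 75, 160, 390 min in a typical series) are retained in the detection
matrix but do not define classes.

## Restraint bookkeeping

NOE restraints are classified by `|i − j|`: 0 intra-residue, 1 sequential,
2–4 medium-range, ≥5 long-range; ambiguous restraints (multiple assignment
options, a flag taken from the input) are counted only in their own
category, so the five categories partition the list.

Restraint density is `total/n_residues`, with nearest-integer reporting
using **round-half-to-even** (R's `round()`, IEC 60559). The residue count
defaults to the *construct span* (last − first + 1) rather than the count
of assigned residues: for a 520–570 construct that is 51 residues, and
(1322 + 56)/51 ≈ 27 restraints per residue. Whether a vector-derived
N-terminal residue should enter the denominator is genuinely ambiguous;
the span convention is adopted because it is the one a reader can
recompute from stated construct boundaries.

Volume calibration uses the isolated spin-pair relation `V ∝ d⁻⁶`, i.e.
`d = d_ref·(V_ref/V)^{1/6}`, clamped to the 2.2–6.0 Å window. "Exponential
calibration" in refinement-software documentation names this sixth-root
mode without a formula; the `d⁻⁶` interpretation is the standard one and
is documented here as an interpretation.

`build_metal_restraints()` emits one bond per metal–ligand edge (target
2.3 Å, the canonical Zn–Sγ length) and one angle per unordered ligand pair
within each metal (target 109.5°, `C(k,2)` per k-coordinate metal): 12
bonds and 18 angles for the Zn₃Cys₉ cluster.

## Structure-side analysis

**Site detection** takes Zn/Cd atoms as metals and Cys Sγ (optionally His
Nδ1/Nε2) as donors, with distance cutoffs of **2.9 Å for S and 2.5 Å for
N** — wider than the 2.3 Å restraint target, to tolerate coordinate
scatter in refined ensembles without capturing second-shell atoms. Metals
sharing a ligand merge into one polynuclear site. Non-conserved
histidines are excluded from ligand status by default.

**Topology fingerprints** relabel ligands 1..n by residue order and list
each metal's sorted ligand-index set (metals ordered lexicographically by
those sets), plus the bridging indices. The fingerprint is invariant
under rigid motion and uniform renumbering, making clusters from
different structures directly comparable (e.g. CXC vs pre-SET
domains: `{{1,2,3,4},{1,5,6,7},{3,6,8,9}}`, bridging `{1,3,6}`).

**Superposition** is least-squares rigid (Kabsch via SVD) with
**reflections explicitly excluded** — metal–thiolate cages are chiral, and
an improper "fit" would silently hide a handedness mismatch. Collinear or
near-collinear pairings raise a conditioning error. The implementation is
cross-checked in the test suite against an independent quaternion
(Horn-method) oracle and bio3d's fitted RMSD.

**Ensemble RMSD** iteratively superposes all models on the evolving mean
until the mean moves less than 10⁻⁶ Å, then reports each model's RMSD to
the converged mean. "Backbone" means N, CA, C (O available by option);
published ensemble statistics rarely state their atom convention, so
comparisons against printed RMSDs should carry a ±0.1 Å allowance.

**Hydrogen bonds** use a donor–acceptor heavy-atom cutoff of 3.5 Å, with
the D–H···A > 120° angle criterion applied only when an explicit hydrogen
is present — NMR-derived models may or may not carry protons.

## Synthetic data: what it emulates, and what it does not

All generators are seeded (one Mersenne–Twister stream per artifact) and
byte-deterministic: identical configurations produce identical files.

*Cluster coordinates.* Metals sit on an equilateral triangle with the
three bridging Sγ atoms on the edge bisectors; terminal Sγ directions
complete each metal's regular tetrahedron analytically. At zero noise
every bond is exactly 2.3 Å and every S–metal–S angle is exactly
arccos(−1/3) = 109.4712° — six pairwise angles of exactly 109.5° cannot
coexist in 3D (the Gram matrix of four unit vectors with equal pairwise
cosines is rank-3 only at cos θ = −1/3), so the conventional 109.5° target
is satisfiable only to ~0.03°, and the tetrahedrality deviation is
reported against 109.5° by convention. Each cysteine receives a plausible
N/CA/C/CB scaffold so backbone/heavy atom selections behave as in real
files; the scaffold is idealized, not energy-minimized — sufficient for
detection, reporting and RMSD code paths, not for chemical realism.
Gaussian coordinate noise is per-model and per-atom, with an optional
side-chain multiplier to emulate the larger side-chain variability of NMR
ensembles. For isotropic noise σ over N models, the expected RMSD to the
mean is √3·σ·√(1 − 1/N), which the test suite uses as a closed-form
oracle.

*Connectivity datasets* hide chosen or random edges from a ground-truth
assignment and derive coupling tags from its bridging structure. The
paper-style input (third metal with two unobserved ligands) is provided
as `cxc_partial_dataset()`.

*Intensity tables.* H/D decay rates are set analytically so that the
detection counts at the three class boundaries equal the requested
targets at the default 3σ threshold (most-protected residues decay to
10σ at 24 h, mid-class to 10σ at 2 h, first-spectrum-only to 0.3σ at 2 h,
undetected start at 0.3σ); class membership is drawn at random. The
defaults mirror a 51-residue construct observed at
0/30/75/120/160/390 min/24 h. NOE tables realize a requested profile
exactly at zero noise.

*Sequences.* Implants draw every gap uniformly within the pattern bounds
and embed the instance in a random background excluding C, H and N, so no
background position can serve as a ligand or signature — every tuple the
scanner reports is then built from implanted positions, which is what
makes implant-recovery a sharp closed-loop test. Real sequences, of
course, contain background Cys/His/Asn; on real data the scanner
enumerates *all* valid registrations (deduplicated by ligand tuple), and
downstream users must expect more than one.

Passing closed-loop tests on these generators demonstrates correctness of
the analysis code paths under the stated models; it does not validate the
models against experimental spectra, raw peak lists or refined ensembles.

## Motif grammar and scanning choices

The pattern grammar supports residue letters, `[A/B]` alternatives, `X`
(exactly one arbitrary residue) and `Xa-b` / typeset `X_a–b_` gaps;
adjacent gaps merge; inverted bounds are parse errors with offsets. The
built-in consensus is `CX[C/H]X2-13CX4-7CXCX5-60CX2-4CX1-2CX2-15CXN`
— 10 residue tokens (9 ligands plus the signature Asn) and 9 gaps. The
His alternative applies only at ligand 2, exactly as written. A terminal
single non-Cys residue token is auto-detected as the signature.

The scanner enumerates **all** distinct ligand tuples (bounded
backtracking over gap lengths), not just the leftmost or shortest
registration: variable gaps can legitimately yield multiple valid
registrations and downstream analyses need them all. Deduplication is by
ligand tuple, ordering by start position then lexicographic tuple. Input
is case-normalized; non-canonical letters (B, J, O, U, X, Z) never match
residue tokens but are accepted inside gaps. Overlapping matches are
allowed in `scan_motif()`; `tandem_scan()` requires non-overlap and a
spacer of at most `max_spacer` (0 = immediately adjacent, the EZ pre-SET
arrangement; 40–60 covers tesmin/TSO1-style spacing). Tandem units are
assumed not to share residues at the junction.

## Problem sizes and numerical tolerances

The shipped tests run the solver on datasets of up to 3 metals and 9
ligands against a brute-force subset oracle (hundreds of combinations),
superposition against the quaternion oracle at 48 atoms, ensemble RMSD on
12–20 model ensembles, and implant recovery on 40–100 sequences of
~100–200 residues — sizes at which the independent oracles are themselves
exhaustive and trustworthy, and the whole suite runs in seconds.
Floating-point equalities are asserted at 10⁻⁹ (construction-exact
quantities), 10⁻⁶ Å (superposition vs oracle) and 10% (stochastic
closed-form RMSD prediction).

## Known limitations

- No spectral processing, peak picking or resonance assignment; inputs
  are tabulated observables.
- No refinement engine: violation scores are injected, and coordination
  restraints are emitted, not imposed.
- The idealized cluster generator supports isolated metals, single-bridge
  pairs and the mutually bridged trinuclear triangle; exotic topologies
  (degree-3 ligands, longer bridge chains) are rejected rather than
  approximated.
- Site detection assumes Zn/Cd metals and S/N donors; other metals or
  donor chemistries would need new cutoffs.
- The scanner is pattern-based; it does not score degenerate sites the
  way a profile/HMM would, and structurally informed realignments (as
  needed for divergent pre-SET family members) must be supplied as
  patterns by the user.
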