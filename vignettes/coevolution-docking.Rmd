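---
title: "From paired alignments to docked complexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From paired alignments to docked complexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

coevodock implements an inference chain that is common in the structural
analysis of multi-subunit assemblies such as the Augmin/HAUS complex and its
NEDD1 partner: residue-residue coevolution between two protein families is
estimated by direct coupling analysis on a paralog-matched paired alignment,
the top-ranked pairs are validated against a reference structure by a
hypergeometric enrichment test and a surface-accessibility filter, and the
retained pairs drive a coarse-grained docking simulation. A crosslinking
mass-spectrometry module maps residue-pair restraints onto candidate models
under the 35 Å Cα-Cα criterion. Because the original sequence databases and
deposited coordinate sets are not shipped, every stage is exercised against
a synthetic-data module with known ground truth.

## The statistical model

### Potts model and mean-field DCA

A paired alignment (domain A columns `1..b`, domain B columns `b+1..L`) is
modeled by a q-state Potts distribution over the 20 amino acids plus gap
(q = 21; the gap is a coupled state, not missing data). Inference follows
the standard mean-field route:

1. **Reweighting.** Row m receives weight `w_m = 1/|{m' :
   identity(m, m') >= 0.8}|`; the effective depth is `M_eff = sum(w_m)`.
   The 0.8 threshold is the field-standard default; the source studies of
   this pipeline do not publish theirs.
2. **Pseudocount frequencies.** `f_i(a) = (λ/q + Σ_m w_m 1[a at i]) /
   (λ + M_eff)`, pair counts analogously with `λ/q²`. The default `λ =
   M_eff` weights data and prior equally — the classic mfDCA
   parameterization. Diagonal pair blocks are tied to the single-site
   frequencies.
3. **Couplings.** The connected correlation matrix `C_ij(a,b) = f_ij(a,b) −
   f_i(a) f_j(b)` over q−1 states (the gap is the reference state) is
   inverted: `e_ij(a,b) = −(C⁻¹)` blockwise. With λ > 0 the matrix is
   well-conditioned; λ = 0 raises an error pointing at the pseudocount.
4. **Direct Information.** For each pair, the two-site direct distribution
   `P_dir(a,b) ∝ exp(e_ij(a,b)) x_i(a) x_j(b)` is constructed with
   auxiliary fields fixed-point iterated until both marginals match `f_i`,
   `f_j` within 1e-4 (at most 200 iterations; non-convergent pairs get NaN
   and are excluded from ranking with a warning). `DI_ij` is the mutual
   information of `P_dir` against the product of its marginals, in nats.

Inter-domain pairs (`i <= b < j`) are ranked by raw DI, descending, with a
deterministic (i, j) tie-break. An average-product correction is available
(`apc = TRUE`) but off by default, since raw DI is what the downstream
retention step consumes. A minimum sequence separation is a concept for
intra-domain contact prediction only and is never applied across the
domain boundary — interface prediction is the point of the exercise.

DI computed this way is invariant under relabeling of alphabet states up to
the fixed-point tolerance, non-negative, exactly zero for independent
frequencies, and reproducible against an independent two-site oracle at
q = 2 (both properties are under test).

### Paralog matching

Two family alignments are concatenated species by species. Species present
in only one family are dropped; a species with `n_A` and `n_B` paralogs
contributes `min(n_A, n_B)` rows. Pairing within a species is progressive:
single-copy species pair trivially and seed a paired consensus profile;
multi-copy species are then processed in order of increasing paralog count,
scoring a candidate pair (A_p, B_q) by the **product** of the two percent
identities to the current consensus and solving the maximum-total-similarity
assignment — exhaustively for up to 6×6 paralogs (at most 720 permutations,
so enumeration is the exact solver), greedily beyond, with ties broken
toward lower row indices for determinism. Each paired species updates the
consensus.

The product (rather than the sum) of the two identities is deliberate: a sum
decomposes into independent per-family terms and makes every assignment
score identical, while the product is maximized exactly when the two
identity rankings are matched in order — which is the signal that related
paralog pairs carry. This is the package's reading of the progressive
paralog-matching idea; it is exact where cheap and deterministic
everywhere.

Gap-run filtering removes rows whose longest contiguous run of `-` exceeds
`ceiling(f·L)` (strictly greater removes; terminal runs count). The
published rules this mirrors state only "20%" and "50%" without defining
the boundary, so the ceiling-inclusive convention is a documented choice,
and the filter is idempotent and monotone in `f` by construction.

### Contact enrichment and surface filter

Given n top-ranked DI pairs, k of which are true contacts of a reference
model containing K contacts among N inter-domain residue pairs, the
enrichment p-value is the exact right-tailed hypergeometric tail
`P(X >= k)` — `stats::phyper`, no normal approximation. Retention keeps
`p <= 0.2` (inclusive), with the three-tier significance coloring (red
`p <= 0.05`, blue `<= 0.1`, black `<= 0.2`) reported alongside. No
multiple-testing correction is applied, mirroring the source procedure.

The universe N counts all inter-domain residue pairs **present in the
model**; unmodeled residues are excluded from N, K and k alike, so the three
numbers are always drawn from the same population. True contacts default to
8 Å (Cα-Cα on bead models, minimal heavy-atom where heavy atoms exist) —
the coevolution-literature convention; the cutoff and metric are arguments.

The surface filter computes per-residue Shrake-Rupley SASA (probe 1.4 Å,
960 golden-spiral points per atom, Bondi-type element radii) in the complex
context, sums it over a pair's two residues, and retains combined SASA
strictly greater than 100 Å². Units are Å² by assumption; the threshold's
source prints no unit. Cα-only bead models refuse SASA with a capability
error rather than returning garbage.

### Crosslink mapping

Residue-pair crosslink tables (simplified 4-column or xiFDR-style exports)
are deduplicated as unordered pairs with multiplicity. Mapping uses author
residue numbering: `author = sequence position + offset`, with per-protein
chain lists and offsets in a plain configuration list (expressed constructs
often start mid-sequence, hence the offsets). When a protein maps to
several chain copies — the two protomers of an anti-parallel dimer — the
copy pairing minimizing the Cα-Cα distance is chosen and recorded; this is
the standard XL-MS convention and never increases a distance relative to
any fixed assignment. Satisfaction is strict `< 35 Å` (the BS3 convention;
the boundary case is unknowable from published counts, so strictness is
declared). Unknown proteins (copurifying contaminants) pass through flagged
rather than erroring. The monomer/dimer comparison reports, for records
mapped in both assemblies, the distance delta and the count of strictly
negative deltas.

## The docking engine

The topology is a Cα structure-based (Gō-type) model in reduced units
(kB = 1, bead mass 1, ε = 1): per chain of N beads, N−1 harmonic bonds
(k = 100 ε/Å²), N−2 harmonic angles (k = 20 ε/rad²), N−3 cosine dihedrals
(1× and 3× terms, 1 and 0.5 ε; dihedrals with collinear native geometry are
skipped), native contacts for Cα pairs within 8 Å at sequence separation
> 3 modeled by the 12-10 well `ε[5(σ/r)¹² − 6(σ/r)¹⁰]` with σ the native
distance, and a shifted r⁻¹² excluded volume (σ_ex = 4 Å) between all
non-excluded pairs. These constants are documented internal defaults in the
SMOG tradition, not claims of equivalence to any server output. Inter-chain
native contacts are off by default so that docking is driven by the
injected coevolutionary restraints rather than by a memorized interface.

DCA restraints are the same 12-10 well at a target distance (default 8 Å,
consistent with the contact definition) **continued for r > σ by a
half-harmonic guiding tail with a force cap** (k = 0.2 ε/Å² over 5 Å, then
constant force 1 ε/Å; value and force continuous). The tail exists because
a bare 12-10 well is numerically zero at a 60 Å starting separation —
without a long-range term, "guiding" a ligand placed far away would be pure
diffusion. The cap keeps the pull gentle relative to the bonded terms. A
subset selector supports driving the simulation with part of the top-ranked
set (e.g. 5 of the top 10), as interface-modeling studies sometimes do.

Integration is BAOAB-discretized Langevin dynamics, dt = 5e-4, friction 1,
seeded through R's RNG (fixed seed ⇒ bitwise-identical trajectories). With
friction 0 the scheme is velocity Verlet; energy conservation in that limit
(drift < 0.1% over 1e5 steps) is the integrator's correctness test, and all
force routines were additionally validated against finite-difference
gradients. The receptor is tethered by weak harmonic restraints
(k = 0.02 ε/Å²) so the ligand does the moving. Divergence (|E| > 1e8)
aborts with a pointer at the timestep.

The ligand is placed at a 60 Å center-of-mass separation in a random seeded
direction, resampled until no inter-body bead pair is closer than 6 Å.
Docking quality is read over the final 10% of snapshots: the fraction of
restraint pairs within 1.2× their target, and the ligand RMSD after Kabsch
superposition of the receptor. The analysis workflow runs a search stage at
T = 0.5 followed by a short annealing stage at T = 0.2, which settles
thermal breathing of restraint distances around the formation threshold.

A known limitation: distance restraints alone do not fix chirality or
orientation — a ligand can satisfy all pairwise targets in a mirrored or
reversed pose, so contact fraction can be high while ligand RMSD is large.
The engine reports both rather than hiding the degeneracy.

## The synthetic-data module

The generator is first-class, tested code, and its defaults are the study
conditions, not dials:

* **Potts sampler.** Gibbs sampling with sequential per-site sweeps, 1000
  burn-in sweeps, 10 sweeps between records, on one long chain. Planted
  couplings are diagonal Potts terms `J·1[a = b]` on a sparse pair list.
  The benchmark for coupling recovery is q = 21, L_A = L_B = 30, 10 planted
  pairs at strength 1.5, 5000 records — depths real subunit-pair studies do
  not publish, so 2000-5000 was chosen once for statistical power. With
  zero couplings and fields, per-column frequencies are uniform within
  binomial error and inter-domain DI stays below 0.05 nats (both tested).
* **Species and paralogs.** One species per chain record; a species with p
  paralogs repeats its chain state with `(p−1)·k` random substitutions per
  domain (k = 10 by default). The paralog-matching benchmark uses
  `field_bias = 4` (per-site conservation ≈ 0.7) because an unconserved
  family gives identity-to-profile scoring nothing to work with — columns
  uniform over 20 states carry no mutation-load signal — whereas real
  protein families are conserved by definition of being families.
* **Gap runs** are inserted post hoc as contiguous `-` blocks in a stated
  fraction of rows. Gaps are an alphabet state downstream, so this mirrors
  real alignment gaps without modeling indel evolution.
* **Toy complexes** are virtual-Cα bead chains (3.6-4.0 Å consecutive
  spacing) with declared interface pairs realized at an exact target
  distance by parallel-chain anchoring; infeasible declarations raise a
  constructive-failure error instead of silently bending geometry.
* **Crosslink tables** mix true pairs (≤ 35 Å) and decoys (> 35 Å) with
  labels retained.

What passing these benchmarks does **not** show: robustness to
phylogenetic correlation between species (the sampler draws species
independently), to alignment errors, to indel-induced column misassignment,
or to the much shallower effective depths of real interface MSAs. The
synthetic data establishes correctness of the machinery, not field
performance.

## Problem sizes and reproducibility

The shipped analyses and tests run at deliberately desk-friendly sizes:
alignments of 50-5000 rows at L = 60, bead complexes of 20-60 residues, and
docking runs of 5-6×10⁵ steps, enough for every statistical property under
test to resolve. All randomness flows through explicit integer seeds; every
generator is a pure function of its seed. `scripts/acceptance.R` re-derives
the headline quantities (coupling-recovery precision, pairing recovery,
oracle agreement for the hypergeometric tail, DI, and SASA, crosslink
counts, docking contact fractions, NVE drift) from scratch at those sizes
and writes them as JSON; the numbered scripts under `analysis/` are the
same pipeline in narrative order, writing tables under `results/`.
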