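# coevodock

Coevolution-guided interface inference and coarse-grained docking for
multi-subunit protein assemblies, in R.

Large coiled-coil machines — the eight-subunit Augmin/HAUS complex that
recruits γ-TuRC for branched microtubule nucleation, and its NEDD1-WD
β-propeller partner, are the motivating case — resist high-resolution
structure determination at their flexible interfaces. Two orthogonal,
sequence- and chemistry-based lines of evidence help: residue-residue
**coevolution** between subunit families, and **crosslinking mass
spectrometry** (XL-MS) distance restraints. This package implements the
full inference chain connecting them to structural models, for
computational structural biologists who want each step as a tested,
scriptable function rather than a one-off pipeline:

1. **msa_kit** — alignment I/O (FASTA/Stockholm), gap-run filtering,
   species parsing, progressive paralog matching into paired alignments,
   species co-occurrence census.
2. **dca_core** — mean-field direct coupling analysis: identity
   reweighting, pseudocount frequencies, couplings by covariance inversion,
   Direct Information (DI), inter-domain pair ranking.
3. **struct_kit** — PDB/mmCIF models, Cα distances, contact maps,
   Shrake-Rupley solvent-accessible surface area.
4. **coevo_enrichment** — exact right-tailed hypergeometric contact
   enrichment, `p ≤ 0.2` retention with three-tier significance classes,
   combined-SASA > 100 Å² surface filter.
5. **xlink_map** — residue-pair crosslink tables mapped onto models
   (author-numbering offsets, multi-copy chain minimization), satisfaction
   under the strict `< 35 Å` Cα-Cα criterion, monomer-vs-dimer comparison.
6. **sbm_dock** — Cα structure-based (Gō) topologies with injected DCA
   distance restraints, seeded BAOAB Langevin dynamics, docking metrics.
7. **synthetic_data** — Potts-sampled paired alignments with planted
   couplings, toy bead complexes with known interfaces, labeled crosslink
   tables: every downstream stage is testable offline with ground truth.

## The statistic at the core

For a paired alignment with domains A and B, mean-field DCA infers
couplings `e_ij(a,b) = −(C⁻¹)` from the pseudocount-regularized connected
correlations `C_ij(a,b) = f_ij(a,b) − f_i(a) f_j(b)` (q = 21 states, gap
coupled, reweighting at 80% identity, λ = M_eff). Each pair is scored by
Direct Information,

    DI_ij = Σ_ab P_dir(a,b) ln [ P_dir(a,b) / (f_i(a) f_j(b)) ],
    P_dir(a,b) ∝ exp(e_ij(a,b)) x_i(a) x_j(b),

with the auxiliary fields x fixed so that `P_dir` reproduces the observed
marginals. Top inter-domain DI pairs are tested against a reference
structure with the exact hypergeometric right tail
`P(X ≥ k) = Σ_{x≥k} C(K,x) C(N−K, n−x) / C(N,n)` and, after a combined-SASA
filter, drive a restrained coarse-grained docking run. Details, defaults
and design rationale: `vignettes/coevolution-docking.Rmd`.

## Worked example

The numbered scripts under `analysis/` run the whole chain on synthetic
data with a planted ground truth (seed-fixed; a couple of minutes in
total):

```sh
Rscript analysis/01_simulate_inputs.R
Rscript analysis/02_dca.R
Rscript analysis/03_enrichment.R
Rscript analysis/04_xlink_mapping.R
Rscript analysis/05_docking.R
```

Step 2 filters the simulated families (20% gap-run rule), pairs them by
progressive paralog matching and runs DCA:

```
gap filter (20% rule): A 5000 -> 4500 rows, B 5000 -> 4500 rows
paired alignment: 4054 rows, boundary at column 30
M_eff = 4054.0 (identity threshold 0.8), lambda = M_eff
top-10 DI pairs: 10/10 are planted couplings (precision 1.00)
paralog matching: 100% of ground-truth pairings recovered
```

All ten planted inter-domain couplings surface as the ten best DI pairs.
Step 3 scores ranked pairs against the toy complex — with 20 true contacts
among N = 900 inter-domain pairs, finding 10 contacts in the top 10 is
astronomically enriched, and every tested set lands in the `red`
(`p ≤ 0.05`) class:

```
 n_top  k  K   N      p_value class
     5  5 20 900 3.186002e-09   red
    10 10 20 900 2.021753e-18   red
```

Step 4 maps the synthetic crosslink table (10 true + 10 decoys) and the
dimer fixture:

```
monomer: 20 records, 20 mapped, 10 (50%) with Ca-Ca < 35 A
dimer comparison: 5 of 5 mappable, 3 strictly shorter in the dimer
```

exactly the planted composition. Step 5 docks the ligand chain from a 60 Å
separation using only the top-10 DI restraints (search at T = 0.5, short
anneal at T = 0.2):

```
restraint contact fraction: median 0.90 over 5 seeds (>= 0.8 in 5)
no-restraint control: contact fraction 0.00, COM separation 59 A
```

The restraints pull the ligand in and form the planted interface; without
them the ligand stays where it was put. Tables land under `results/`
(`di_pairs.tsv`, `enrichment.tsv`, `xlink_mapped.tsv`,
`docking_metrics.tsv`, `docked_model.pdb`, ...).

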