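# coevdock

Predicting homodimeric protein complexes from sequence coevolution.

Residue pairs that coevolve across a protein family are usually in
contact, but for a homodimer the family alignment mixes two signals:
contacts *within* each monomer and contacts *across* the dimer
interface. `coevdock` separates them and uses the interface signal to
build the complex:

1. **mfDCA.** Mean-field direct coupling analysis on the alignment:
   similarity reweighting (θ = 0.8), pseudocount-regularised
   frequencies (λ = M_eff), inversion of the connected-correlation
   matrix, and ranking of position pairs by direct information
   DI_ij = Σ_ab P_dir(a,b) ln [ P_dir(a,b) / f_i(a) f_j(b) ].
2. **Filtering.** Drop pairs whose residues are all buried (relative
   SASA ≤ 50%, Shrake–Rupley), keep the top 100 by DI, then drop every
   pair that is already a contact in the monomer's 8 Å Cα map — what
   survives is the dimerization signal, symmetrized into inter-chain
   restraints (i_A, j_B) and (j_A, i_B).
3. **Docking.** A coarse-grained Cα structure-based model holds each
   monomer near-native (native-contact Gaussian wells, 100× stiffened
   dihedrals) while the restraints act as Gaussian contact wells
   V(r) = ε(σ/r)¹² − A ε exp(−(r − r^N)²/2w²) whose parameters follow a
   7-stage annealing schedule (r^N: 50 → 8 Å) that pulls the two
   chains from a separated, reoriented pose into a complex via Langevin
   dynamics.
4. **Scoring.** Dimer RMSD (chain-swap symmetric), CAPRI-style
   interfacial RMSD, best-frame selection and contact-map recovery
   against a reference structure.

A synthetic-data module (Potts-sampled alignments with planted
interface couplings, toy helix dimers with exactly known interfaces)
makes the entire pipeline testable offline; it is first-class, tested
code.

Intended users: structural bioinformaticians with a deep protein-family
alignment and a monomer (or dimer) crystal structure who want a
physics-based prediction of the homodimeric arrangement, or a testbed
for coevolution-guided docking protocols.

## Worked example

The synthetic route exercises every stage without downloads: build a
toy dimer, plant its interface into a Potts model, sample an alignment,
and let the pipeline recover the complex from sequences alone.

```r
library(coevdock)

cfg <- default_config(seed = 3)
cfg$synth$enabled <- TRUE          # toy dimer + sampled alignment
cfg$synth$M <- 2000                # sequences
cfg$filter$sasa_threshold <- 0     # toy beads: exposure filter off
cfg$filter$n_top <- 4              # the toy plants 4 distinct couplings;
                                   # top-100 is a real-family scale

res <- run_pipeline(cfg, mode = "validate", out_dir = "toy_run")
res$report
```

```
coev_report: RMSD_best = 1.91 A (frame 2772), final-stage mean = 2.7 A,
iRMSD_best = 1.6 A, contact recovery = 0.5
```

Reading: over the annealing trajectory the best-scoring frame is within
1.91 Å Cα RMSD of the toy native complex (interface-only RMSD 1.6 Å)
and the stage-7 average sits at 2.7 Å. Contact recovery counts native
inter-chain contacts reproduced within a strict 8 Å in the best frame;
because the final annealing stage centres its restraint wells at 8 Å,
recovered contacts straddle the cutoff and 0.5 here corresponds to all
contacts within 10 Å. The run directory contains
the DI table (`di_table.tsv`), the filtered restraints and their
per-pair provenance (`restraints.tsv`, `.provenance.jsonl`), the
serialized topology and schedule (`topology.json`), initial/final poses
and a thinned trajectory (PDB), per-frame energies, the evaluation
report (`report.json`) and a manifest that reproduces the run.

With real data, point `cfg$paths` at a FASTA/Stockholm family
alignment, a monomer PDB and (optionally) an `hmmscan`-derived
`aln_col / res_index` mapping table, and use `mode = "predict"` if no
native dimer exists; stage convergence is then monitored on the
restraint energy and the run emits `convergence.tsv` instead of RMSD
output. A thin CLI wraps the same functions:

```sh
exec/coevdock run --config cfg.yaml --mode validate --out run1
exec/coevdock synth --out fixtures --n 30 --interface 8 --m 2000
```

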