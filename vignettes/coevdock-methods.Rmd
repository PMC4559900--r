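---
title: "Coevolution-driven docking of homodimers: models, parameters and design choices"
author: "coevdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coevolution-driven docking of homodimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevdock)
```

# The problem

Residue pairs that coevolve across a protein family are usually in
physical contact. For a homodimer the catch is that one alignment mixes
two kinds of contact signal: pairs in contact *within* each monomer, and
pairs in contact *across* the dimer interface. `coevdock` implements a
pipeline that (i) infers directly coupled residue pairs from the family
alignment, (ii) strips the couplings explained by the known monomer
structure, and (iii) uses the surviving couplings as attractive
restraints that dock two copies of the monomer into a complex, which can
then be scored against a reference structure.

# Coupling inference (mfDCA)

Sequences are encoded over $q = 21$ states (20 amino acids plus gap;
lowercase insert states, `.` gaps and ambiguity codes all map to the gap
state). Redundancy is removed by similarity reweighting: sequence $s$
receives weight $1/m_s$ with $m_s$ the number of sequences at fractional
identity $\ge \theta$ to it (default $\theta = 0.8$); the effective
family size is $M_\mathrm{eff} = \sum_s w_s$. Frequencies are
regularised with a uniform pseudocount of total mass $\lambda$
(default $\lambda = M_\mathrm{eff}$, the conventional mean-field
choice):

$$f_i(a) = \frac{\lambda/q + \sum_s w_s\,\delta_{a,s_i}}{\lambda + M_\mathrm{eff}},
\qquad
f_{ij}(a,b) = \frac{\lambda/q^2 + \sum_s w_s\,\delta_{a,s_i}\delta_{b,s_j}}{\lambda + M_\mathrm{eff}}.$$

The mean-field couplings are $e_{ij}(a,b) = -(C^{-1})$ on the
off-diagonal blocks of the connected correlation matrix
$C = f_{ij} - f_i f_j$. The matrix is inverted over the $q-1$ non-gap
states; the gap state is the gauge and its couplings are fixed at zero.
The gauge choice does not affect the ranking score because the two-site
model used for scoring re-imposes the empirical marginals: for each pair
we build $P^{dir}_{ij}(a,b) \propto e^{e_{ij}(a,b)}\,x_i(a)\,x_j(b)$
with $x_i, x_j$ fixed by matching the marginals of $P^{dir}$ to
$f_i, f_j$ (fixed-point iteration, tolerance $10^{-6}$, at most 500
iterations, with 0.5 damping if the update oscillates — strongly coupled
toy models do oscillate). The direct information

$$DI_{ij} = \sum_{a,b} P^{dir}_{ij}(a,b)\,
\ln\frac{P^{dir}_{ij}(a,b)}{f_i(a) f_j(b)}$$

is a Kullback–Leibler divergence, hence nonnegative, and ranks pairs by
the strength of their *direct* statistical dependence.

Pairs closer than `min_separation` columns (default 2) are excluded from
the ranking. The default deliberately keeps near-diagonal pairs that the
conventional $|i-j| > 4$ intra-protein filter would discard: genuine
homodimer interface couplings can sit near the diagonal, and the
monomer-contact filter below — not a sequence-separation heuristic — is
the intended suppressor of intra-chain signal.

# Isolating the dimerization couplings

Three filters are applied, in this order:

1. **Exposure.** A pair survives only if at least one of its residues has
   relative solvent accessibility above 50% (strictly greater, the
   conventional minimum for "solvent accessible"; threshold 0 disables
   the filter). SASA is computed on a single monomer chain with a
   Shrake–Rupley sampler (probe 1.4 Å, 960 deterministic
   Fibonacci-lattice points per atom) and normalised by per-residue-type
   theoretical maxima (Tien et al. 2013). Buried, strongly coupled pairs
   are folding constraints, not interface candidates.
2. **Top-N.** The 100 highest-DI survivors are retained.
3. **Monomer contacts.** Any pair that is a contact in the monomer's
   C$_\alpha$ map at 8 Å (strict inequality at the boundary) is removed
   — it is explained by the monomer fold. An optional dilation margin
   `delta` also removes pairs within $8 + \delta$ Å for users who prefer
   a looser reading of "close to the monomeric map"; the default is
   exact membership, $\delta = 0$.

Each surviving intra-sequence pair $(i, j)$ is symmetrized into the two
inter-chain restraints $(i_A, j_B)$ and $(j_A, i_B)$ — for identical
chains the coupling cannot tell which copy carries which residue.
Mirrored self-pairs ($i = i$) carry no covariation signal and cannot
appear. Every input pair's fate (kept, or removed by exactly one named
filter) is recorded in a provenance table. On real families the
surviving count is typically 30–75; the pipeline warns outside
[10, 150].

# The docking model

Each monomer is a C$_\alpha$ bead chain with a structure-based energy
function whose minimum is the native monomer:

* bonds $\tfrac{1}{2}k_b(r - r^0)^2$ with $k_b = 200\,\varepsilon/\mathrm{Å}^2$,
* angles $\tfrac{1}{2}k_a(\theta - \theta^0)^2$ with $k_a = 40\,\varepsilon/\mathrm{rad}^2$,
* dihedrals $k_d[(1 - \cos\Delta\phi) + \tfrac{1}{2}(1 - \cos 3\Delta\phi)]$
  with $k_d$ **100×** a base constant of $1\,\varepsilon$ — the
  stiffened backbone keeps each monomer near-rigid during binding,
* native intra-chain contacts (8 Å map, $|i-j| \ge 4$) as narrow
  Gaussian wells ($A = 1$, $w = 0.5$ Å) centred at native distances,
* uniform excluded volume $\varepsilon(\sigma/r)^{12}$ with
  $\sigma = 4$ Å (value-shifted to zero at the $3\sigma$ cutoff),
* each DCA restraint as a Gaussian contact well

$$V(r) = \varepsilon\left(\frac{\sigma}{r}\right)^{12}
 - A\,\varepsilon\, e^{-(r - r^N)^2 / 2w^2}.$$

$w$ is interpreted as the Gaussian standard-deviation width — wider
wells admit more conformations at a given energy, which is what the
annealing exploits.

## The 7-stage annealing schedule

The restraint parameters $(r^N, A, w)$ change over seven stages:

| stage | $r^N$ (Å) | $A$ | $w$ (Å) |
|------:|----------:|----:|--------:|
| 1 | 50 | 1 | 10 |
| 2 | 38 | 1 | 8 |
| 3 | 28 | 1 | 6 |
| 4 | 20 | 1 | 5 |
| 5 | 14 | 2 | 4 |
| 6 | 10 | 3 | 3 |
| 7 | 8  | 4 | 1.5 |

The equilibrium distance interpolates geometrically between the two
anchored endpoints — the 50 Å initial separation and the 8 Å typical
native contact distance; the width shrinks as the target basin
sharpens; the amplitude ramps only over the last three stages to lock
the complex in place. All seven triples are plain config values, so a
user with a different stage table can reproduce it exactly.

The starting pose separates the two chains by 50 Å along the
inter-centroid axis and rotates the second chain 180° about that axis,
destroying the native relative orientation (no native inter-chain
contact at 8 Å survives; the axis can also be randomised).

## Dynamics and convergence

Dynamics are BAOAB Langevin with unit masses in reduced units
($\varepsilon = 1$, time unit $\tau$). Defaults: $dt = 0.002\,\tau$
(~1/220 of the stiffest bond period; measured NVE drift at
$\gamma = 0$ is $\sim 10^{-4}\,\varepsilon$ over $10^5$ steps),
$T = 0.5\,\varepsilon$ (well below the native wells' melting point, so
monomer internal RMSD stays under ~1 Å), and friction
$\gamma = 0.05/\tau$. The friction choice matters: with overdamped
friction ($\gamma \approx 1/\tau$) the inter-chain approach speed is
$F/(N\gamma) \approx 0.03$ Å/$\tau$ and the chains cannot traverse the
~12 Å between consecutive stage targets in any reasonable step budget;
underdamped Langevin is the standard operating regime for
structure-based models and lets the chains approach and reorient within
each stage.

A stage ends when the monitored series stabilises: sliding-window
(200 recorded frames, stride 100 steps) standard deviation below 2% of
the window mean or below an absolute floor of 0.3 (Å for the RMSD
monitor, $\varepsilon$ for the energy monitor — a purely relative
criterion can never fire once an RMSD series hovers near zero), or a
100 000-step cap. In validation mode (native
known) the monitored series is the RMSD to the native complex; in blind
prediction no reference exists, so the restraint energy — the observable
actually available — is monitored instead. Velocities carry across
stage boundaries (no re-thermalisation); a capped stage is recorded as
non-converged and the fixed 7-step protocol continues.

# Scoring

`superpose()` is a least-squares (Kabsch, SVD) rigid fit constrained to
proper rotations. `dimer_rmsd()` evaluates both chain assignments
(A→A/B→B and A→B/B→A) and returns the minimum — the labelling of
identical chains is arbitrary. `interfacial_rmsd()` uses a CAPRI-style
interface: native residues with any cross-chain C$_\alpha$ within 10 Å
(configurable; absolute iRMSD values depend on this cutoff),
superposed on the interface residues only, chain-swap minimised. The
"best" complex of a trajectory is the minimum-RMSD frame (validation
mode only); the final-stage mean is reported alongside. RMSDs are
superposed on the whole complex, not per chain. Contact recovery is the
fraction of native inter-chain 8 Å contacts reproduced within 8 Å in
the best frame, maximised over the two chain assignments like the
RMSDs. Because the final annealing stage centres its wells *at* 8 Å
rather than at each pair's native distance, a correctly docked complex
typically reproduces native contacts at distances straddling 8 Å: the
strict-8 recovery understates accuracy and is best read together with
the RMSD and a looser (e.g. 10 Å) recovery.

# What the synthetic data emulates — and what it does not

The package tests itself end to end without downloads via two
generators:

* **Potts alignments.** `sample_potts()` draws sequences from a q-state
  Potts model by single-site Gibbs sampling (burn-in 200 sweeps, one
  sequence every 10 sweeps). `plant_interface_couplings()` places
  diagonal-favouring couplings ($J(a,a) = J_0 = 1$, inverse temperature
  $\beta = 2$ — a strong, clearly detectable signal, matching the
  regime in which covariation methods are expected to work) on exactly
  the position pairs of a toy dimer's interface.
* **Toy dimers.** `build_toy_dimer()` packs two copies of an idealised
  C$_\alpha$ helix (rise 1.5 Å, radius 2.3 Å, 100° twist)
  anti-parallel, scanning the lateral separation until exactly the
  requested number of cross-chain contacts falls under 8 Å. The
  anti-parallel arrangement is deliberate: facing beads are
  sequence-distant ($i + j \approx n$), so the planted interface pairs
  are *not* monomer contacts and survive the monomer filter — in a
  parallel packing the mapped pairs would coincide with the monomer
  map and the filter would (correctly) delete the entire signal. Each
  bead carries a dummy 1.7 Å sphere so the SASA filter sees a
  nontrivial exposure bipartition (mid-chain beads partially buried,
  termini exposed, relative SASA ~0.46–0.72).

What passing these tests shows: the inference recovers planted direct
couplings, the filters implement their stated truth tables, and the
annealing engine reliably reassembles a complex whose interface is
correctly (if noisily) restrained. What they do not show: performance
on real families — phylogenetic correlation, gap structure, alignment
errors, flexible loops and non-ideal side-chain packing are all absent
from the generators. End-to-end toy tests disable the exposure filter
(threshold 0), exactly because the toy's exposure pattern is cruder
than a real protein's.

# Numerical choices and degenerate inputs

* Contact maps use strict `<` at the cutoff; documented because
  boundary pairs otherwise silently differ between implementations.
* The DI fixed point errors out (with iteration diagnostics) rather
  than returning a half-converged value.
* A singular correlation matrix (only possible at $\lambda = 0$ with
  degenerate data) produces an error advising a positive pseudocount.
* Collinear point sets make the superposition rotation ill-defined and
  are rejected.
* Alternate locations in PDB input resolve to the highest-occupancy
  conformer (first on ties); residues without a C$_\alpha$ are dropped
  with a warning; chain gaps are used as-is, with the gap-adjacent
  pseudo-bond taking its native length.
* All indices are 0-based with half-open intervals throughout;
  1-based residue numbers appear only in PDB I/O.
* One global seed is expanded into per-module seeds by the documented
  counter scheme `(seed * 7919 + k) mod (2^31 - 1)`, so every run is
  reproducible from its manifest.

Problem sizes used in the shipped tests and validation script — 2×30
beads, alignments of 400–3000 sequences, L = 30, five docking seeds at
100 000 steps per stage — were chosen as the smallest systems on which
the planted signal and the docking behaviour are unambiguous.

# Known limitations

* mfDCA only; no pseudolikelihood or Boltzmann-machine inference, and
  DI only — no APC-corrected Frobenius scores.
* Homodimers only: no paired-alignment matching for heterodimers and no
  interdomain restraint extraction for multidomain proteins.
* The monomer is treated as near-rigid; induced-fit binding and
  missing-loop modelling are out of scope (structures with gaps are
  used as-is).
* The mapping fallback is a consensus-vs-structure global alignment
  (match +1, mismatch −1, gap −2); for real Pfam families a
  profile-HMM-derived external mapping table is the recommended route.
* `iRMSD` values depend on the 10 Å interface definition; comparisons
  across tools must align that cutoff first.
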