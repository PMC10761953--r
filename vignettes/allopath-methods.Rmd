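---
title: "Methods: perturbation response scanning and allosteric pathway extraction"
author: "allopath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perturbation response scanning and allosteric pathway extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopath)
```

# Scope and model

`allopath` analyses allosteric communication at C-alpha resolution. The
chain of models is deliberately short:

1. an **anisotropic network model (ANM)** turns a CA trace into a 3N x 3N
   Hessian of identical pairwise springs;
2. its pseudo-inverse (or a covariance estimated from a superposed
   conformational ensemble) is the kernel of **linear response theory**,
   ΔR = (1/kT) C F;
3. **perturbation response scanning (PRS)** sweeps isotropic unit forces
   over every residue through that kernel and summarizes who moves whom;
4. a contact graph weighted by PRS couplings yields **shortest allosteric
   paths** and a **mediation profile** whose argmax is the most-mediated
   residue.

Alongside sit the standard trajectory stability metrics (RMSD, RMSF, Rg,
SASA, hydrogen bonds, clustering) and the MM-PBSA aggregation identities
as a bookkeeping layer. The package never runs molecular dynamics, solves
Poisson–Boltzmann, or assigns force-field energies.

## Assumptions worth stating

* **Harmonicity.** Everything downstream of the Hessian assumes small
  fluctuations about one minimum. PRS asks "if I push here, what moves?",
  not "what conformational transition follows?".
* **Uniform springs.** One `gamma` for every contact. Since the PRS
  response is row-normalized, the absolute spring constant and kT cancel;
  we default both to 1 and treat responses as relative quantities.
* **CA resolution.** Side-chain chemistry (H-bonds excepted) is invisible;
  pathways are geometric/elastic, not chemical.

# Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| ANM cutoff `cutoff` | 13 | Å | standard ANM practice for CA networks; connectivity check fails loudly below ~10 |
| spring `gamma`, `kT` | 1, 1 | arb. | cancel under row normalization |
| zero modes removed | exactly 6 | — | count-based, not threshold-based: any other count means disconnected/degenerate geometry and is an error, never silently inverted |
| PRS forces `M` | 100 | — | Fibonacci sphere; the `analytic` scheme is the exact M→∞ limit and doubles as the test oracle |
| key-residue z | 1.0 | — | exposed flag; a z-score is the only scale-free criterion available |
| contact cutoff (paths) | 10 | Å | paths must be physically contiguous; a complete PRS graph would make every route one hop |
| edge weight | −ln p, p clipped to [1e-6, 1] | — | additive weights = multiplicative couplings; the clip keeps weights finite without reordering strong couplings |
| H-bond | D–A ≤ 3.0 Å (inclusive), D–H–A ≥ 135° | Å, ° | the common geometric criterion of trajectory toolchains; both exposed |
| SASA | probe 1.4 Å, 960 sphere points | Å | Shrake–Rupley; 960→1920 points changes totals < 0.5% |
| histogram bins | 50 | — | equal-width over [min, max], right-most bin inclusive |
| k-means | k = 10, k-means++ seeding, Lloyd ≤ 500 iters | — | ten representatives per system is the conventional report |

Design choices where the field leaves options open:

* **Response magnitude is the mean *squared* displacement norm.** The
  squared form admits the exact closed form ⟨|A u|²⟩ = tr(AᵀA)/3 over the
  unit sphere, which gives an independent oracle for the sampled scan and
  makes the Fibonacci/analytic agreement a meaningful test rather than a
  tautology.
* **Normalization is row-wise by self-response.** The diagonal is exactly
  1; row i answers "relative to how much residue i moves itself, how much
  does it move j?". Both raw and normalized matrices are emitted, since
  published heatmaps rarely state their scaling.
* **Covariance provenance is explicit.** `CovarianceModel@source` records
  `"anm"` or `"ensemble"`; both feed PRS identically. When only a
  structure is available the ANM route is the default; when a trajectory
  is available the ensemble route needs no spring-model assumptions.
* **Stride subsampling anchors at the first residue** (positions 1,
  1+s, 1+2s, ...), giving floor((N−1)/s)+1 residues — a 1332-residue
  chain at s = 10 compresses to 134. This is the preprocessing used to
  fit residue-network methods with node-count caps.
* **One shortest path per pair, deterministic ties.** Ties break by fewer
  hops, then the lexicographically smallest node sequence, so outputs are
  byte-reproducible across platforms. No k-shortest-path enumeration.
* **Mediation counts interior nodes only.** Endpoints would otherwise
  dominate trivially; the conservation Σ counts = Σ (len−2) is asserted in
  tests.
* **MM-PBSA layer is identities plus audit, never solvers.** Entropy is
  an optional user-supplied scalar. The audit flags any printed subtotal
  that its own components cannot reproduce within 0.01 kJ/mol — it
  reports the discrepancy and deliberately does not "correct" the table.

# The synthetic generators

Every quantitative claim in the test suite runs on generated structures
with known ground truth; nothing is downloaded.

* `makeHelix(n)`: ideal α-helix CA trace (rise 1.5 Å, radius 2.3 Å,
  twist 100°/residue; consecutive CA–CA ≈ 3.83 Å). Smooth, connected,
  non-degenerate — the workhorse for ANM/PRS identities.
* `makeChain(n)`: straight 3.8 Å bead chain; deliberately collinear, used
  for subsampling counts and as the canonical *degenerate* ANM input.
* `makeDumbbell(nPerDomain, channelResidues, seed)`: two compact random
  domains joined by a bead channel, returning the ground-truth channel
  indices. Its defining property — removing the channel disconnects the
  domains at the 10 Å contact cutoff — is asserted at generation time.

The dumbbell embodies three geometric decisions that took iteration:

1. **Off-axis helical bead offsets (1.2 Å).** A perfectly collinear
   channel leaves perpendicular bead motions and inter-domain torsion
   with exactly zero spring energy, inflating the rigid-mode count.
2. **Bead spacing 0.58 x contact cutoff.** Next-nearest beads are then
   1.16 x cutoff apart, so at the contact cutoff the channel is a strict
   chain: no inter-domain path can skip a bead. Consequently every
   source→sink shortest path visits *every* channel bead, and the
   channel provably attains the maximum mediation count (a domain-side
   funnel residue can tie, never beat, when sources and sinks span the
   domains).
3. **Well-posedness is asserted at a larger bracing cutoff (18 Å).** A
   point bead transmits at most three spring constraints, so with springs
   reaching only one bead spacing the two domains retain floppy relative
   mechanisms (> 6 zero modes). Springs spanning two bead spacings brace
   the bottleneck; generation retries (bounded at 500) until the network
   has exactly 6 zero modes, and the dumbbell pipeline builds its ANM at
   that cutoff.

`sampleANMEnsemble` draws frames mean + Σ_k √(kT/λ_k) z_k v_k over the
internal modes, so the population covariance of the frames *is* the ANM
covariance — the generator and the estimator share no code path, which
makes the 10% Frobenius recovery check a genuine round trip.

**What the generators do not emulate:** real side-chain packing,
sequence heterogeneity, anharmonic transitions, solvent. Passing the
planted-channel tests shows the *inference machinery* is correct — that
shortest-path mediation recovers a bottleneck the geometry guarantees —
not that PRS finds allosteric residues in any particular real protein.
One empirical finding from the dumbbell is worth recording: the channel
beads are recovered by the *pathway/mediation* layer, but they are not
outliers of the PRS effector (or sensor) profile under uniform springs —
the bottleneck is the compliant element of the network, not a stiff
effector hub. Profile-based key-residue calling and path-based mediator
scoring answer different questions.

# Numerical choices

* **Zero modes are removed by count (exactly 6), tolerance 1e-8 x λmax.**
  Threshold-only removal silently absorbs floppy mechanisms into the
  covariance; the count check turns geometry problems into errors.
* **Superposition reference is the iterated mean** (two passes of
  mean → superpose → re-mean), removing frame-order dependence in RMSF
  and ensemble covariances.
* **Kabsch uses SVD with determinant sign correction**; collinear point
  sets are flagged. The test oracle is the independent quaternion
  (Horn) method.
* **Dijkstra runs on igraph distances; the reported path is
  reconstructed** over the tight-edge DAG by reverse BFS (minimum hops)
  plus a greedy lexicographic walk — this realizes the documented tie
  rules exactly, including through zero-weight edges (couplings clipped
  at 1).
* **Histogram boundaries:** bins are [e_k, e_{k+1}) with the last bin
  closed; a constant series occupies a single bin. H-bond and contact
  cutoffs are inclusive.
* **k-means on superposed flattened coordinates** approximates
  pairwise-RMSD clustering; exact RMSD-metric k-means has no clean
  centroid. Fixed-seed k-means++ seeding plus Lloyd iteration makes
  clustering bit-reproducible.
* **Degenerate inputs error loudly**: < 3 beads, collinear traces,
  disconnected contact graphs, zero self-response in PRS (named residue),
  unreachable source/sink pairs (named pair; all-pairs continues),
  unknown element radii in SASA.

# Problem sizes in the shipped tests

The suite is sized to run comfortably on one CPU: helices of 12–40
residues, dumbbells of 27 residues (12 per domain + 3 channel beads)
over 20 seeds, 100 random graphs of ≤ 8 nodes against exhaustive path
enumeration, 5000-frame mode-sampled ensembles for covariance recovery,
2000-frame jittered ensembles for the RMSF law-of-large-numbers check,
and 960–1920 sphere points for SASA convergence. These sizes were chosen
so each check is decisive (errors well below the asserted tolerances)
while the whole suite completes in well under a minute of compute per
module.

# Known limitations

* Uniform springs cannot represent a *stiff* channel or weighted
  contacts; per-edge spring constants are deliberately out of scope.
* PRS is linear response: large-amplitude or ligand-induced
  conformational changes are outside the model.
* The ensemble covariance assumes frames are conformers of one topology;
  no alignment/mapping across different chains.
* Mediation is restricted to the supplied source/sink sets (no global
  betweenness), matching the binding-site → active-site question it is
  meant to answer.
* SASA and H-bond detection need elements (and hydrogens) in the input;
  CA-only fixtures cannot exercise them, so those tests use small
  hand-built all-atom toys.
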