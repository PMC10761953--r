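# allopath

Coarse-grained analysis of allosteric communication in proteins:
perturbation response scanning (PRS) over elastic-network or ensemble
covariances, shortest-path extraction of allosteric routes with
mediator-residue scoring, trajectory stability metrics, and MM-PBSA
component bookkeeping.

## The problem

Non-competitive (allosteric) inhibitors act at sites distant from the
catalytic centre: a binding event at the surface reshapes the dynamics of
the active site without ever touching it. Mapping *how* that signal
travels — which residues carry it, and which single residues mediate most
routes — is the core question this package addresses, at the resolution of
a C-alpha bead model, for structural bioinformaticians who want a
download-free, scriptable toolchain rather than a simulation engine.

## The model

**Elastic network.** The CA trace becomes an anisotropic network model
(ANM): beads joined by identical Hookean springs for every pair within a
cutoff r_c (default 13 Å). The 3N x 3N Hessian has 3x3 super-elements

    H_ij = -γ (d_ij d_ij^T) / |d_ij|²   for contacts i≠j,

with diagonal blocks enforcing zero row sums. Its pseudo-inverse over the
3N−6 internal modes is the positional covariance C (`anmCovariance`);
alternatively C is estimated from a superposed conformational ensemble
(`ensembleCovariance`).

**Perturbation response scanning.** Linear response theory gives the
first-order displacement field under an external force: ΔR = (1/kT) C F.
PRS applies M = 100 quasi-uniform unit forces (a Fibonacci sphere) at each
residue in turn and records the mean squared displacement magnitude this
induces everywhere else:

    R_ij = (1/M) Σ_m |C_(j,i) u_m|² / kT²,

where C_(j,i) is the 3x3 covariance block coupling residues j and i. The
exact isotropic limit tr(C_(j,i)ᵀ C_(j,i))/3 is available as the
`analytic` scheme. Rows are normalized by the self-response (unit
diagonal); row/column means give effector and sensor profiles, and
z-score outliers of the effector profile are reported as key residues.

**Allosteric pathways.** Spatial contacts (CA–CA ≤ 10 Å) define a residue
graph; each contact edge is weighted −ln p_ij with p_ij the symmetrized,
clipped normalized PRS coupling, so strong coupling is a cheap edge and
path weights add as couplings multiply. Dijkstra's algorithm (with
deterministic tie-breaking) yields one shortest path per
binding-site/active-site pair, and the residue appearing most often as an
interior node of those paths is the most-mediated site.

**Trajectory metrics and energetics.** Kabsch superposition, RMSD/RMSF/Rg
series, Shrake–Rupley SASA, geometric hydrogen-bond counting, frequency
histograms, and k-means clustering with representative frames; plus the
MM-PBSA aggregation identities ΔG_gas = ΔE_ele + ΔE_vdW,
ΔG_solv = ΔG_PB + ΔG_SA, ΔG_total = ΔG_gas + ΔG_solv with a consistency
audit for published component tables.

## Worked example

```r
library(allopath)

## PRS on an ideal 20-residue helix
helix <- makeHelix(20)
cov   <- anmCovariance(buildANMHessian(helix, cutoff = 13))
res   <- prsScan(cov, fibonacciForceSet(100))
res
#> PRSResult: N=20 residues, scheme=fibonacci, M=100 forces
keyResidues(res, zThreshold = 1.0)
#>   residue   zscore
#> 1      17 1.352392
#> 2       4 1.349058
#> 3      18 1.200225
#> 4       3 1.196433

## shortest allosteric route end-to-end
g <- assignEdgeWeights(buildContactGraph(helix, contactCutoff = 10), res)
shortestPath(g, 1, 20)
#> AllostericPath: 1 -> 7 -> 13 -> 19 -> 20 (weight 8.1216)

## planted-ground-truth benchmark: two domains joined by a 3-bead channel
db <- makeDumbbell(12, 3, seed = 1)
n  <- nAtoms(db$model)
paths <- allPairsPaths(
  assignEdgeWeights(buildContactGraph(db$model, 10),
    prsScan(anmCovariance(buildANMHessian(db$model, 18)), analyticForceSet())),
  sources = 1:12, sinks = (n - 11):n)
mediationProfile(paths, n)
#> MediationProfile over 144 paths; most-mediated residue(s): 13, 14, 15 (count 144)
db$channel
#> [1] 13 14 15
```

The helix's top effectors sit a few turns in from each terminus (the
stiffest, best-connected region), the end-to-end route hops roughly one
helical turn per step, and on the dumbbell every one of the 144
domain-to-domain shortest paths is mediated by the planted channel beads —
the package recovers the ground truth exactly.

MM-PBSA bookkeeping on a published component column:

```r
combineComponents(eEle = -198.46, eVdw = -30.81, gPb = 215.38)
#> $gGas   -229.27
#> $gSolv   215.38
#> $gTotal  -13.89
```

## Command line

A thin wrapper over the same functions:

```sh
Rscript inst/scripts/allopath.R prs   --pdb model.pdb --nforces 100 --out prs_out
Rscript inst/scripts/allopath.R paths --pdb model.pdb --sources 646,652,803 \
        --sinks 802,880,914,1261 --out paths_out
Rscript inst/scripts/allopath.R metrics --traj traj.pdb --k 10 --out metrics_out
```

Every run echoes its effective configuration (`config.json`) and a log to
the output directory; outputs are staged and only published on success.

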