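---
title: "Graph-driven sampling of folding pathways: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-driven sampling of folding pathways: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

gdsfold generates ensembles of protein-folding pathways for coarse-grained
bead proteins by discrete optimization in the space of inter-residue
contact maps, bypassing time integration of the folding process itself.
This vignette documents the models, the numerical choices, and what the
synthetic test systems do and do not establish.

## The BLN force field

Each residue is a single bead labelled Hydrophobic (B), Hydrophilic (L) or
Neutral (N); each backbone dihedral carries a secondary-structure class
(Helix, Extended, Turn). The potential is

$$V(\mathbf r) = \sum_{\mathrm{bonds}} k_b (r - \sigma)^2
  + \sum_{\mathrm{angles}} \tfrac{k_\theta}{2}(\theta - \theta_0)^2
  + \sum_{\mathrm{dihedrals}} \big[A(1{+}\cos\phi) + B(1{+}\cos 3\phi)
      + C(1{+}\sin\phi)\big]
  + \sum_{|i-j|\ge 3} 4\epsilon S_1\Big[\big(\tfrac{\sigma}{r}\big)^{12}
      - S_2 \big(\tfrac{\sigma}{r}\big)^{6}\Big]$$

in reduced units (bead mass 1 mu, energy $\epsilon$, distance in
angstrom, time $\mathrm{tu} = \sqrt{\mathrm{mu}\,\text{\AA}^2/\epsilon}$),
with $k_b = 115.6\,\epsilon/\text{\AA}^2$ (note the full-prefactor
convention on the bond term, no 1/2), $\sigma = 3.8$ A,
$k_\theta = 10\,\epsilon/\mathrm{rad}^2$, $\theta_0 = 1.8326$ rad. Pairs
closer than three bonds are excluded from the nonbonded sum (bond and
angle terms cover them). Pair scalings follow the class rules
(B,B) $\to (1, 1)$ (attractive), (L,{B,L}) $\to (2/3, -1)$
(repulsive-only), (N,·) $\to (1, 0)$ (excluded volume only). The
$(A, B, C)$ dihedral coefficients per class default to values in the
Honeycutt–Thirumalai/Head-Gordon lineage of the model — helix
$(0, 0.2, 0.2)$, extended $(0.9, 1.2, 0)$, turn $(0, 0.2, 0)$ — and,
like the pair tables, are exposed through `bln_parameters()` and a
key-value override file, because bead-protein parameterizations are
defined per target native structure. Nothing downstream assumes these
particular values.

Dynamics are velocity-Verlet with an Andersen thermostat; "collision
frequency $10^{-3}$" is implemented as a per-step, per-bead probability of
resampling all three velocity components from the Maxwell–Boltzmann
distribution. Minimization is quasi-Newton (L-BFGS-B) converged on an RMS
gradient of $10^{-6}\,\epsilon/$A by default; energies that become
non-finite during line search are clamped to a large barrier so the
optimizer retreats, and a non-finite value at the output is recorded as a
numerical failure rather than raised.

## Contact maps and the SCH metric

A contact map sets $G_{ij} = 1$ iff $r_{ij} < r_c$ with $r_c = 8$ A
(strictly; ties are non-contacts). The shortest-contact-hop (SCH) distance
between maps $A$ and $B$ compares their all-pairs shortest-path matrices
$S^A, S^B$ on the contact graphs:

$$f_{\mathrm{SCH}}(A,B) = \frac{2}{N(N-1)} \sum_{i<j}
  \frac{|S^A_{ij} - S^B_{ij}|}{\max(S^A_{ij}, S^B_{ij})}.$$

The relative difference $|a-b|/\max(a,b)$ is a metric on positive
integers, so $f_{\mathrm{SCH}}$ is a metric; every summand lies in
$[0, 1)$; and differences at large hop counts (long real-space distances)
are down-weighted, which is what makes the metric track real-space
similarity better than the Hamming count of differing entries. Hop
matrices come from breadth-first search (compiled; the test suite
cross-checks against igraph). Disconnected pairs take the finite cap $N$,
which exceeds any achievable connected distance; bead chains are always
connected at $r_c = 8$ A since bonded neighbours sit at 3.8 A.

## Back-mapping contact maps to structures

The graph-restraining potential (GRP) used for reconstruction is a sum of
one-sided harmonics with a single force constant $k = 100\,\epsilon/$A$^2$:
contact pairs are pulled below $r^{\mathrm{con}} = 8$ A, non-contacts
pushed above it, and every nonbonded pair pushed above the steric floor
$r^{\mathrm{steric}} = 2$ A. Each term acts only when its constraint is
violated, so $W = 0$ exactly when the structure realizes the map, and the
potential is $C^1$ everywhere. The steric term is applied to all nonbonded
pairs; for non-contact pairs it is dominated by the $r^{\mathrm{con}}$
term and therefore inert, so the choice is inconsequential. The legacy
logistic GRP (harmonic wells $\kappa_1 = 1$, bounded repulsion
$\kappa_2 = 6$, $\gamma = 6$ A$^2$) is retained as a baseline only; its
repulsive branch uses the argument $(r_{\max}^2 - r^2)/\gamma$ for
dimensional consistency, with $r_{\min} = 2$, $r_{\max} = 8$ A defaults.
Its exact historical form is not recoverable, so no quantitative claims
are attached to it.

Two reconstruction routes are provided. `reconstruct_minimize()`
minimizes $V + W$ from a starting geometry and then $V$ alone, so the
output is a physical structure. `reconstruct_crankshaft()` runs Metropolis
Monte Carlo on $W$ with off-lattice crankshaft moves — a bead rotates by a
uniform angle in $[-\pi, \pi]$ about the axis through its two chain
neighbours (terminal beads pivot about the terminal bond), which preserves
both adjacent bond lengths exactly — rejecting any proposal that puts a
nonbonded pair under the steric floor, then minimizes $V$. The MC
temperature decays geometrically from 1.0 to 0.01 over the run
($10^5$ steps by default; the acceptance workloads use $3 \times 10^4$,
which reaches the same failure statistics). A reconstruction is counted
as a numerical failure if any energy or gradient becomes non-finite, the
optimizer aborts, or the output contains a pair distance below 0.5 A.

Three numerical refinements of the reconstruction routes matter in
practice.
First, the reconstruction routines enforce the restraints with a margin
(default 0.25 A): contacts are pulled below $r^{\mathrm{con}} - 0.25$ and
non-contacts pushed above $r^{\mathrm{con}} + 0.25$. Without it, pairs
settle exactly at the cutoff where the physical strain balances the
restraint force, and the final relaxation under $V$ alone lets them drift
back across 8 A, losing the map. `grp_new_config()` itself defaults to
margin zero (the plain one-sided form); the achieved map is always
evaluated at the plain 8 A cutoff. Second, `reconstruct_minimize()`
optionally restarts from crankshaft Monte Carlo walks on $W$ (`kicks`),
keeping the best result; this stochastic search along the map-feasible
manifold recovers exactly realizable maps whose basin the direct
projection misses. Third, the steric floor also covers next-nearest
(`|i-j| = 2`) pairs, and the final physical-stage minimization keeps the
map-independent steric floor alongside $V$: the coarse-grained $V$ has no
excluded volume between next-nearest beads (closing an angle entirely
costs only $(k_\theta/2)\theta_0^2 \approx 17\,\epsilon$, which map
restraints or dense packing can pay), and without these guards a few
reconstructions per thousand end with two beads collapsed onto each
other -- the only numerical-failure mode either route exhibits. The
guard is exactly zero, with zero gradient, for any structure free of
sub-2 A overlaps, so ordinary outputs remain exact minima of $V$. On top
of this, a failed reconstruction is retried from a jittered start
(Gaussian 0.05 A, twice) before a failure is reported.

How exactly a physically realizable map can be recovered depends on how
far the target is from the start. On the 10-bead test system, physical
targets (maps of structures obtained by a 10 tu burst at $T = 1$
followed by minimization) are recovered to their exact map in well over
90% of seeded trials with a handful of kicks. On the 56-bead system the
same burst melts the compact minima, the start-to-target SCH distances
grow to 0.05-0.2, and the restrained projection then lands in a nearby
physical basin whose map differs from the target by a few pairs: exact
recovery drops to tens of percent and is insensitive to margin
enforcement, force-constant escalation, gradual restraint release, or MC
kicks (all converge to the same non-target fixed points). What survives
at every scale is the contrast that motivates the two-route design:
physically realizable targets reconstruct with substantially smaller
SCH error than bit-flip-perturbed targets, which mix physical and
nonphysical maps.

## The sequence search

A folding path is a graph sequence $[G^0, \dots, G^{M+1}]$ with the
endpoint maps fixed to the unfolded and folded structures. Simulated
annealing perturbs a randomly chosen intermediate with $n_b \in \{1..5\}$
bit flips (uniformly drawn mutable pairs, $|i-j| \ge 3$), and scores

$$F = \sum_{i=1}^{M} |d(G^{i-1}, G^i) - d(G^i, G^{i+1})|
  + \lambda \sum_{j=1}^{M+1} H(d(G^{j-1}, G^j) - k_{\mathrm{cont}})$$

with $d = f_{\mathrm{SCH}}$, $H$ the Heaviside step ($H(0) = 0$),
$k_{\mathrm{cont}} = 0.15$ and $\lambda = 1$ — a single threshold
violation (cost 1) dominates typical equidistance residuals ($\lesssim
0.1$), so the default weight needs no tuning; a hinge variant
$H(d-k)(d-k)$ is available. Acceptance is standard Metropolis
$e^{-\Delta F/T}$ under a linear $T: 10^{-3} \to 0$ schedule with $10^4$
updates by default. Candidate maps can be corrected through
reconstruction at every update (the literal protocol; the corrected map —
the contact map of the back-mapped structure — is what enters the
sequence) or the search can run in pure contact-map space with a single
back-mapping of the final intermediates; both modes are exposed because
per-update correction costs a reconstruction per MC step, and the
ensemble workloads in the tests use the pure-graph mode with final
correction.

The number of intermediates defaults to
$M = \lceil d(G^I, G^F)/k_{\mathrm{cont}} \rceil - 1$: with fewer
transitions the metric property of $f_{\mathrm{SCH}}$ makes it impossible
for every consecutive step to stay below $k_{\mathrm{cont}}$.

**Initialization.** Intermediate $i$ starts as the unfolded map plus
$\lceil i K/(M{+}1) \rceil$ of the $K$ contacts gained in the folded map.
The order in which contacts are drawn matters. A plain random subset
produces intermediates whose first SCH step absorbs most of the total
distance (a handful of scattered long-range contacts collapses the hop
matrix — the small-world effect), leaving the cold annealer on a plateau
it cannot repair, and produces no coherent folding mechanism. The default
is therefore a cooperative growth ordering: a random nucleus contact is
drawn, and subsequent contacts are drawn from the frontier of contacts
sharing a bead with those already formed (with probability `p_adjacent`,
default 0.9; the ensemble workloads use 1.0 for fully committed growth).
This mirrors the spatial cooperativity of real contact formation, yields
far more even initial spacing, and — because the nucleus location varies
across seeded runs — seeds genuine mechanistic diversity (which hairpin
forms first) that the downstream clustering is designed to detect. The
plain random subset remains available as `method = "subset"`.

## Path refinement and ranking

Consecutive reconstructed intermediates are joined by the freezing-string
method: frontiers advance from both ends by linear-synchronous-transit
(LST) steps capped at 2 A RMSD, only the advancing image is relaxed
(three projected-descent steps perpendicular to the local tangent), a
frontier freezes when its RMS force exceeds $100\,\epsilon/$A, growth
stops at ten images per side, and the path is resampled to ten equidistant
images by LST. LST minimizes the squared deviation from linearly
interpolated internal distances with $1/\bar d^4$ weights (the weighting
of the original transit functional) plus a small ($10^{-6}$) Cartesian
regularization, seeded from Cartesian interpolation; on failure it falls
back to Cartesian interpolation with a warning.

Nudged-elastic-band refinement uses the energy-weighted upwind tangent,
spring constant $1\,\epsilon/$A$^2$ (not dictated by the method; exposed
in `neb_config()`), and QuickMin with time step 0.01, converged at RMS
force $10^{-4}$ and maximum force $10^{-2}\,\epsilon/$A per image within
$10^4$ iterations. Paths are ranked by the floored energy
$\Delta E^+ = \sum_k \max(0, E_{k+1} - E_k)$ over the concatenated image
profile; the lowest-$\Delta E^+$ paths are retained for analysis. Where
full NEB refinement is too heavy (the scaled ensemble workloads), the
floored energy of the five-point profile of intermediate energies is used
for the ranking; it is the same functional on a coarser profile.

## Order parameters, Fréchet distance, clustering

Hairpin formation is tracked by
$\chi = |P|^{-1} \sum_{(i,j) \in P} H(\mathrm{tol}_{ij} - |r_{ij} -
r_{ij}^{\mathrm{folded}}|)$ over the native contact pairs $P$ of each
declared hairpin range. The printed tolerance 0.2 is unitless; it is
interpreted by default as $0.2\sigma = 0.76$ A, with absolute-angstrom and
relative-to-native (20% of the native distance) modes exposed. The
ensemble analyses use the relative mode: back-mapped intermediates satisfy
the binary contact constraints of their maps but deviate from exact native
distances by more than 0.76 A even when a hairpin's topology is fully
formed, so the $\sigma$-based tolerance under-reports formation for
reconstructed (as opposed to dynamics-sampled) structures.

Paths are compared as $(\chi_{\beta_1}, \chi_{\beta_2})$ tracks with the
discrete Fréchet distance (dynamic programming, Euclidean point metric),
which respects time order but not step size; tracks are evaluated at the
sequence structures by default, or at all NEB images for denser tracks.
The pairwise Fréchet matrix is clustered with HDBSCAN (implemented in the
package: mutual-reachability single linkage, condensed tree at the given
minimum cluster size, excess-of-mass selection; no R implementation was
available to reuse), with minimum cluster size 5 and noise label −1. If
the condensed tree contains no viable split at all, all points form one
homogeneous cluster rather than all-noise. Transition segments between
the unfolded ($\chi_{\beta_1}, \chi_{\beta_2} < 0.4$) and folded (both
$> 0.8$) regimes are pruned for occupancy summaries, anchored at the last
unfolded exit so reversals are handled.

The TM-score utility ($d_0(L) = 1.24(L-15)^{1/3} - 1.8$, clamped at 0.5
for short chains, iterative Kabsch superposition on the converging
residue subset) serves as the real-space reference when validating that
SCH out-correlates Hamming on synthetic structure pairs; no sequence
alignment is performed.

## Synthetic systems and what they show

All inputs are generated in code. The canonical test protein is a 56-bead
chain with the architecture of a small alpha/beta domain: an N-terminal
beta-hairpin (strand 8, turn 2, strand 8), a 14-bead helix between
3-bead loops, and a C-terminal hairpin. Strands are all-B, turns and
loops N, and the helix carries a sparse amphipathic B stripe (pattern
LLBLLLLB): denser hydrophobic patterns were found to drive a global
molten-globule collapse (about 500 contacts, no distinct hairpin blocks),
whereas this design anneals to a native with both hairpin blocks formed
and no inter-hairpin contacts — the two-mechanism analysis requires the
two hairpin ranges to be structurally independent. The unfolded endpoint
is an almost-collinear chain with exact 3.8 A bonds and a tiny
deterministic precessing dither so no angle or dihedral is singular.

The native search anneals from a temperature ladder (10 $\epsilon$ halved
ten times, 10 tu per stage, dt $10^{-3}$), restarts re-seeded from the
current best until 20 restarts bring no improvement, and deduplicates
minima by energy ($10^{-6}\,\epsilon$) and superposed RMSD (0.1 A) —
both config-exposed implementation choices.

Scaled problem sizes used by the packaged workloads (stated here as the
package's own choices): the routine test suite anneals with reduced
restart budgets (12 restarts / stop at 6), benchmarks reconstruction on
80 five-flip targets per method, contrasts 40 physical (high-T MD)
against 40 bit-flip targets (plus 100 exact-recovery targets on the
10-bead system), validates the metric on 200 perturbed pairs,
and clusters a 120-path ensemble run with 500 SA updates per path in
pure-graph mode with final-only reconstruction. The acceptance script
uses the full 500-trial benchmark.

Because the generator emulates idealized conditions — a designed,
frustration-poor sequence; exact reduced-unit parameters; no solvent,
no misfolded trap states beyond what the BLN landscape provides — passing
tests demonstrate the correctness and robustness of the machinery
(metrics, search, back-mapping, refinement, clustering), not the
biophysical accuracy of any specific published bead protein. Reproducing
published energetics for a specific system additionally requires that
system's bead sequence and dihedral/pair tables, which can be supplied
through the sequence-file and parameter-override interfaces. For the same
reason the historical failure rate of the legacy GRP and printed
unfolded-folded SCH values of specific proteins are documented as
external-data targets: our synthetic protein reproduces the qualitative
contrast (the legacy form is fragile; the one-sided form is not), not
those exact numbers.

## Known limitations

- Pure-graph search with final-only correction can propose intermediates
  whose maps are not exactly realizable; the final back-mapping then
  substitutes the nearest realized map, which perturbs the optimized
  spacing.
- The crankshaft route uses local moves and struggles with targets far
  from the start, exactly as the gradient route does not; the benchmark
  quantifies this through the mean SCH-to-target rather than failures.
- HDBSCAN on small ensembles (tens of paths) of smoothly varying tracks
  legitimately returns a single cluster; mechanism separation needs both
  committed paths and enough of them.
- Single-chain systems only; no solvent, no replica exchange, no
  all-atom force fields.
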