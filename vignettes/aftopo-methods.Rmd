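---
title: "Topological phase-singularity analysis and virtual ablation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological phase-singularity analysis and virtual ablation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Reentry-driven atrial fibrillation is sustained by rotating waves —
functional rotors whose tips are phase singularities, and anatomical
reentries circulating around non-conductive obstacles (valve orifices,
vein ostia). Because the phase of the activation cycle is a circular
quantity, the winding number of the phase field along any closed curve is
an integer, and on a closed surface the total winding (the sum of all
singularity indices, counting each boundary as a potential host) must be
zero: singularities come in pairs of opposite chirality. `aftopo`
implements a detection, tracking and virtual-ablation toolchain built on
this index-conservation property, together with a desk-scale synthetic
electrophysiology module so that every stage can be exercised without
external data.

# Phase reconstruction

Transmembrane voltage is recorded every 5 ms. Local activation times
(LATs) are upward crossings of −40 mV with sub-sample linear
interpolation; crossings within 50 ms of the previous activation are
discarded (50 ms sits well below the ~90 ms lower end of clinical
fibrillation cycle lengths, so genuine activations are never merged).
The sawtooth phase between consecutive activations $t_k, t_{k+1}$ is

$$\varphi(t) = \pi - 2\pi\,\frac{t - t_k}{t_{k+1} - t_k} \in [-\pi, \pi],$$

so $+\pi$ marks the activation instant and $-\pi$ late diastole.

Outside a point's first/last activation two conventions are offered.
`extend = "mask"` leaves the phase undefined, which silently removes
every neighbor ring that touches such a point from charge detection.
The default, `extend = "clamp"`, continues the decay past the last
activation at the point's final cycle length until the phase reaches
$-\pi$ and holds it there, and extrapolates one cycle backwards before
the first activation. The clamp reflects the physiology (a point that has
stopped activating is at rest) and preserves the integer quantization of
ring sums mid-run; with masking, a rotor core that activates only
sporadically can hide the compensating charge of an active rotor and
spuriously break the pair accounting. When the tissue state was created
by phase-distribution induction, the induced cycle fraction of every node
is known exactly, and the analysis seeds each activation series with that
virtual pre-run activation instead of extrapolating — the first simulated
cycle is then phase-consistent across neighbors by construction.

# Discrete topological charge

The surface is subsampled to ~2 mm spacing by farthest-point sampling on
geodesic (edge-graph Dijkstra) distance; the geodesic Voronoi cells of the
samples define neighborhoods (two samples are neighbors when their cells
share a full-resolution edge). One synthetic node is added per boundary
loop at the loop centroid; its neighbors are the samples whose cells touch
the loop. Every node's neighbors are sorted counterclockwise (as seen from
outside the surface) in the tangent plane of its outward normal.

The charge at a node is the signed count of phase jumps along its closed
neighbor ring: consecutive ordered neighbors $i, j$ contribute
$J(\Delta\varphi_{ij})$ with $J = +1$ for a jump beyond $+\pi$, $-1$
beyond $-\pi$, $0$ otherwise (strict inequalities). The difference is
taken against the traversal direction so that the discrete count equals
the continuous winding number: a counterclockwise-increasing analytic
field yields $+1$. Rings containing any phase-undefined sample are skipped
whole and flagged — a partial ring is not a closed curve and its jump sum
is not quantized.

Cavity nodes are evaluated identically through their ring of
phase-bearing neighbors; this is what makes anatomical reentries
detectable by the same operator as functional ones. Their ring
orientation is chosen as the orientation of the *cap* that would close
the boundary (opposite to the boundary-loop traversal): an interior hole
keeps the counterclockwise ring and reads $+1$ when the phase winds
counterclockwise around it, while the outer rim of an open sheet reads
the compensating opposite charge. With this convention the cluster-level
index sum is conserved on closed surfaces and on open fixtures whose rim
is counted — which is why the pipeline includes every boundary loop when
analyzing sheet fixtures.

# Clustering, tracking, metrics

Detections at one timestep are clustered per chirality with a density
criterion at radius $\varepsilon = 2\mu_d$ ($\mu_d$ = mean geodesic
neighbor distance) and minimum cluster size one; with minimum size one
this is exactly the connected components of the $\varepsilon$-neighbor
graph, so no external clustering library is involved. Same-chirality
clusters in consecutive timesteps are linked when their minimum
inter-member geodesic distance is within $\varepsilon$; nearest fragments
continue a splitting track, and merges keep the nearest (then lowest-id)
track. Each cluster contributes its chirality once to the per-timestep
index sum; `f0` is the fraction of analyzed timesteps with zero sum and
`m_ind` the mean sum — the adherence metrics for the index theorem.
Complexity is summarized by track lifespans, the number of distinct
tracks, and the maximum simultaneous count (signs pooled). Spatial
similarity of singularity-count maps $S_c(p) = \sum_t |TC(p,t)|$ uses
global bivariate Moran's I with Gaussian kernel
$w_{ij} = e^{-d_{ij}^2/(2R^2)}$, $R = 2$ mm, $w_{ii} = 0$ (the kernel
denominator is configurable to $R^2$ since the typeset source of this
formula is ambiguous; $2R^2$ is the standard Gaussian reading).

# Virtual ablation

At a planning snapshot the cluster-index sum must be zero; if a detection
hiccup leaves it unbalanced the snapshot advances 5 ms at a time (up to
100 retries). Three line strategies connect the balanced opposite-chirality
cluster sets:

* **heuristic** — Dijkstra on the sampled graph with edge weight
  $d_{euc}(x,y)\,(\varphi_x + 1.1\pi)(\varphi_y + 1.1\pi)$, phases frozen
  at the snapshot. Tissue about to activate is nearly free, freshly
  activated tissue is heavily penalized, so lines run just ahead of
  wavefronts and block their path.
* **straight** — the same pairing logic under plain geodesic distance.
* **random** — a control: each straight pair is replaced by a uniformly
  drawn sample pair from the same geodesic-distance decile, so control
  lines have comparable lengths but arbitrary placement.

Pairing is an exact minimum-total-cost perfect matching (Hungarian
algorithm, $O(n^3)$); multi-member clusters also receive a closed block
loop through all members (nearest-neighbor tour). Interior anatomical
cavities are free to cross (their edge weight is zero under the
heuristic: the hole itself blocks conduction, so a line through it is
"free" ablation). The outer rim of an open sheet is different: passing
*through* the outside would realize as two disconnected cuts plus a
useless arc along the edge, partitioning the sheet and leaving each
rotor spinning in its own compartment. The rim node is therefore
endpoint-only in path searches — a rotor may be paired *with* the
boundary (a transecting cut to the edge), but no line may tunnel through
it. Lines are projected back to the full mesh by per-segment geodesic
paths; a vertex path whose consecutive vertices share a mesh edge is a
separating curve of the (planar) triangulation, so blocks are watertight
for the monodomain stencil by construction.

An ablation at $t_{abl}$ is evaluated on a 400 ms window at 10 ms
recording: success means all activity ceased inside the window, with the
three bookkeeping branches for spontaneously terminating runs (no
ablation after termination; termination beyond the window — success iff
$t_{abl} < t_{ai} < t_{end}$; termination inside the window — the
ablation must beat it by at least one 10 ms step).

# The synthetic electrophysiology module

Cells follow the Courtemanche–Ramirez–Nattel human atrial model with two
remodeling variants applied as conductance multipliers: AF-remodeled
($G_{Kur}\times0.5$, $G_{to}\times0.5$, $G_{CaL}\times0.3$) and fibrotic
($G_{Kur}\times0.5$, $G_{to}\times0.5$, $G_{CaL}\times0.5$,
$G_{Na}\times0.7$). Paced at 2 Hz these give APD90 near 194 ms and
233 ms respectively, and at equal coupling the fibrotic variant conducts
about 13–14% slower — the calibration anchors of the module. Gates are
integrated by Rush–Larsen with voltage lookup tables (0.1 mV grid),
voltage and concentrations by forward Euler; the single-cell default step
is 0.02 ms and tissue runs use 0.05 ms (0.1 ms remains stable and is used
for batch studies; it shifts APD90 by ~2 ms).

Tissue is a monodomain graph model: one cell per mesh vertex coupled by
the cotangent-Laplacian weights of the triangulated surface, which on the
regular right-triangle sheet reduce exactly to the 5-point stencil with
coupling $D/dx^2$. Blocked vertices are decoupled (no-flux) but keep
their local dynamics. The diffusion coefficient is calibrated on a 1D
cable (activation-time regression over the central half) — CV scales as
$\sqrt D$, so root-finding is well posed.

Reentry is seeded by phase distribution: each node's full state vector is
taken from a precomputed paced limit cycle at the cycle fraction
prescribed by a spatial phase pattern. The shipped patterns are a
counter-rotating pair (windings $+1$ and $-1$ about two in-plane centers
— the planar analogue of distributing phase around a Cartesian axis of a
closed surface, which places an antipodal pair) and a single axial
winding for closed fixtures. Reversing the pattern direction mirrors
every chirality.

## Desk-scale choices and what they imply

The default fixture is a 40×40 mm sheet at 0.5 mm spacing (6561 nodes)
with $D = 0.025$ mm²/ms. This coupling is deliberately low: the
reentrant wavelength must fit the sheet, and at physiological conduction
velocities (0.6–0.8 m/s) it would be three times the domain. Within the
narrow window of couplings that sustain reentry at all, 0.025 is the
value at which the canonical counter-rotating pair remains a *coherent
pair* (two to four simultaneous singularities) rather than degenerating
into dense multi-wavelet turbulence; at lower coupling the pair breaks
up and same-chirality detection clouds crowd within the clustering
radius $\varepsilon = 2\mu_d$, which miscounts clusters and is the
dominant source of index-sum noise at this scale. The price of the slow
conduction (~0.2 m/s) is a long fibrillation cycle length (median
~300–360 ms, above the 90–250 ms clinical band): the fixtures are
topologically representative (meandering rotors, wavebreak, boundary
interactions, paired chirality, spontaneous termination) but not
electrophysiologically scaled, so quantitative rates should not be read
against atrium-scale figures — the meaningful desk-scale ablation
readout is the *ordering* heuristic ≥ straight ≫ random.

Problem sizes used by the shipped checks: single-cell runs pace 20 beats
at 500 ms; cable calibrations use 160 cells at 0.25 mm; index-theorem
adherence pools the four canonical induction conditions
(horizontal/vertical pair × both chiralities) recorded on the full
3400 ms protocol and analyzed from 50 ms to spontaneous termination; the
strategy comparison uses twenty seeded fixtures run to 1300 ms with one
ablation snapshot at 800 ms and a 0.1 ms tissue step, with snapshots
falling after a spontaneous termination bookkept as not performed, as in
any early-termination case.

# Numerical and degenerate-input conventions

* Dijkstra ties are broken lexicographically by node id (the walk picks
  the smallest-id neighbor on the shortest-path set); zero-weight edges
  are floored at $10^{-6}$ of the largest weight inside the path
  extraction so the walk is strictly monotone.
* Farthest-point sampling is deterministic given the start vertex; ties
  on the farthest distance go to the smallest vertex id.
* A degenerate vertex normal flags the node and excludes it from
  detection; a ring with fewer than three phase-bearing members is
  likewise flagged.
* Zero-variance fields make Moran's I undefined (an error, not NaN).
* An empty analysis window (spontaneous termination before 50 ms)
  degrades to the single nearest timestep so reports stay well-formed.
* `match_pairs` with unreachable pairs uses infinite costs; if no finite
  perfect matching exists, planning fails loudly.

# Known limitations

* The fixtures are flat or holed sheets and spheres; no fiber
  anisotropy, no MRI-derived heterogeneity, no epi-endo structure.
* Cycle lengths and conduction velocity are not clinically scaled (see
  above); quantitative rate comparisons against atrium-scale studies are
  out of reach at desk scale.
* The detector shares the known failure modes of threshold-based jump
  counting: a disjointed wavefront can drop a jump below $\pi$ and
  transiently unbalance the index sum. These episodes last a few
  timesteps and are the reason `f0` is reported rather than asserted to
  be exactly 1.
* Acute termination within 400 ms is the only ablation endpoint;
  re-inducibility and long-term outcome are not modeled.
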