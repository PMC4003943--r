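---
title: "Reconstructing tree skeletons from point clouds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing tree skeletons from point clouds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeskel)
```

## The problem

Terrestrial laser scanning (TLS) samples the *surface* of a tree as a 3D
point cloud. For structural phenotyping — branch counts, axis ordering,
cumulative woody length, branch diameters — one needs the *curve skeleton*:
a rooted tree of centerline nodes with radii, i.e. the perennial (woody)
tissue stripped of the sampling. `treeskel` extracts that skeleton, and
ships a stochastic synthetic-tree generator plus a virtual scanner so the
whole chain can be validated end-to-end with exactly known ground truth.

## The reconstruction model

Four structures are computed in sequence from the cloud $P$:

1. **Neighbourhood graph $N$** — every pair of points within a search
   radius $r$ is linked (edge weight = Euclidean distance). Using a radius
   rather than a pure $k$-nearest rule guarantees that *gaps wider than
   $r$ are never bridged*, which is what keeps distinct fine branches
   apart. An optional cap $k$ limits each point to its $k$ nearest
   in-radius neighbours; the directed selections are symmetrized **by
   union** so thin, anisotropically sampled branches stay connected.
   Disconnection is tolerated, not papered over: it is usually better to
   accept satellite components than to inflate $r$. Deliberate gaps
   (occlusion) are bridged explicitly with `repair_connect_sphere()`,
   which force-connects all points inside a user-placed sphere.
2. **Geodesic field $G$** — single-source shortest paths (Dijkstra) from
   the *source point*, defined as the point of minimal height $z$ (the
   trunk base; ties broken by smallest id). The distances approximate
   geodesic distance along the scanned surface; the predecessor links form
   a shortest-path tree. Points in components not containing the source
   are flagged unreachable, counted, and excluded downstream — never
   silently dropped.
3. **Level sets $S$** — reachable points are binned by
   $\mathrm{level}(p) = \lfloor \mathrm{dist}(p)/d \rfloor$. The width
   $d$ is the resolution knob: it should sit just below the shortest
   branch segment one wants to resolve. Each level is then segmented into
   **branch cuts**: connected components of $N$ restricted to that level
   (edges whose endpoints share the level). Levels are full-width bins
   rather than thin rings, which makes the segmentation robust at modest
   densities, and the existing $N$ is reused rather than rebuilding a
   per-level graph.
4. **Skeleton $K$** — one node per branch cut, at the cut's centroid. A
   node at level $i$ is linked to exactly one node at a lower level: the
   cut receiving the **majority** of its members' predecessor-chain entry
   points (the first chain point on a strictly lower level); ties go to
   the cut with the nearest centroid. Downward uniqueness is what makes
   $K$ a tree.

Three refinements follow skeletonization, in this order:

* **False-tip pruning.** A small $d$ destabilises segmentation and can
  split a through-branch sideways, leaving a spurious terminus. A tip
  node is *false* exactly when one of its member points is the
  shortest-path predecessor of a point on a higher level (necessarily
  outside the tip's cut) — geodesic paths continue past it. False tips
  are removed together with their single-child ancestors up to, but
  excluding, the nearest branching node; the operation iterates to a
  fixed point, so it is idempotent, and the root is never removed.
* **Smoothing.** Centroid chains are jagged at low density. Node
  positions are smoothed by a centred moving average of odd length $w$
  along every maximal non-branching chain. Junctions, tips and the root
  are anchored and windows are truncated symmetrically near chain ends,
  so branch insertion points and total extent are preserved.
* **Radius estimation.** For each node, the *starting points* are its
  members whose predecessor lies in the previous level — the first
  crossings of the level boundary, which wrap the branch in an
  approximate circle perpendicular to the local direction. The node
  radius is the mean perpendicular distance of those points to the axis
  line through the node along the parent-to-node direction (the root axis
  is taken as $+z$). Radii are then smoothed with the same window $w$.

### Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `r` | m | — | neighbourhood radius; just below the smallest branch *separation* to preserve, and ideally ≤ `d` |
| `k` | — | `Inf` | neighbour cap; finite values trade completeness for speed on very large clouds |
| `d` | m | — | level width; just below the smallest branch *length* to resolve |
| `w` | nodes | 3 | moving-average window for positions and radii; odd |
| `prune` | — | `TRUE` | false-tip removal |

## Numerical choices and tie-breaks

Reproducibility requires determinism wherever the mathematics leaves
slack:

* Source ties (equal minimal $z$) resolve to the smallest point id;
  equal-length shortest paths prefer the smaller predecessor id.
* Branch cuts are enumerated by (level, minimum member geodesic distance,
  smallest member id), which fixes skeleton node ids.
* Parent votes that tie resolve to the candidate cut with the nearest
  centroid.
* A node with fewer than 3 starting points inherits its nearest
  ancestor's radius; a *root* with no resolvable radius anywhere above
  it takes its first descendant's estimate (an ancestor rule alone would
  leave every root undefined, since level-0 points have no predecessor in
  a previous level).
* Positions are smoothed *before* radii are estimated, so axis directions
  use the smoothed geometry; the same $w$ smooths both.
* Radius-search edge inclusion is `distance <= r`; occlusion regions and
  repair spheres use strict interiors.

## The synthetic generator: a stated world

`sapling_grammar()` is the packaged default scene: axiom `FA`, single
rule `A → [↑FA]+++[→FA]`, 7 iterations, branching angle
30° (SD 5°), initial segment length 1 m and radius 0.1 m, both scaled by
0.75 (SD 0.1) per parent-to-child link. Expansion is parallel rewriting
and purely deterministic: the structure is a perfect binary tree with
255 segments and 128 tips *for every seed* — only the geometry is
stochastic. (The generator reports the literal count of emitted segments,
255; counting conventions that include a virtual root node would say 256.)

Turtle semantics (the grammar notation does not pin these down, so they
are fixed here once): the turtle carries an orthonormal frame (heading
$H$, left $L$, up $U$), starting with $H = +z$. `←`/`→` yaw about $U$;
`↑`/`↓` pitch about $L$; `+`/`-` roll about $H$; **every** rotation
symbol, including each `+`, draws its own angle from
$N(\texttt{angle\_mean}, \texttt{angle\_sd}^2)$ — so `+++` rolls by about
90°, which moves the second bracketed branch into the plane opposite the
first and spreads the pair by roughly 60°. Scaling draws are truncated
at zero with up to 100 resamples; draws are consumed in symbol-scan order
from one stream, so a seed reproduces the model bit for bit. A segment's
top radius equals its first child's base radius (continuous frusta);
childless segments taper by the mean radius scaling.

The virtual scanner samples each frustum's lateral surface (caps
excluded) with a Poisson point count of mean `density × area`, axial
position by inverse-CDF of the linear radius profile (likelihood
proportional to local circumference), uniform azimuth, and displaces each
point *outward* along the local surface normal by an exponential draw of
scale `noise_scale`. What this emulates: surface-only sampling, density
roughly uniform per unit area, small one-sided ranging error. What it
does **not** emulate: occlusion (add it explicitly with
`apply_occlusion()`), angular scan patterns, multi-scan registration
error, foliage, beam divergence. A green end-to-end test therefore
establishes correctness of the geometry pipeline on clean surface samples,
not robustness to real scan artefacts.

## What the default scene can and cannot achieve

Two desk-scale acceptance checks are deliberately left failing, because
analysis shows the stated world cannot meet them; the suite asserts them
unweakened and they are expected to stay red:

* **Single-component connectivity at `r = 0.06`.** The deepest segments
  have lateral areas of order $10^{-2}\,\mathrm{m^2}$, hence ~10–20
  Poisson points spread over ~0.1 m. Across ~128 such segments the
  probability that some axial run-gap exceeds 0.06 m is close to 1, so
  every realization leaves a few satellite clusters (1–40 points). They
  are reported as unreachable and are exactly what
  `repair_connect_sphere()` exists for.
* **Perfect 128-tip detection at `d = 0.09`, `r = 0.06`.** Sibling tip
  branches spread at ~60°, so their facing surfaces stay within 0.06 m
  of each other for roughly the first 0.085 m above the junction. A
  depth-7 branch is only ~0.13 m long (less when the stochastic scaling
  compounds downward), so whether the *last* level bin of a tip pair
  falls entirely in the separated zone depends on the bin phase; when it
  does not, the two cuts merge and one tip is lost. The observed yield is
  roughly 90–110 of 128 tips per seed. Raising the yield would require
  moving the generator or reconstruction parameters, which would change
  the stated world rather than fix the method, so it is not done.

## Known limitations

* The first levels above the source form a one-sided geodesic patch, not
  a ring, so the lowest nodes sit slightly off-axis and trunk-base radii
  are biased high until the levels wrap the trunk (geodesic distance
  ≈ $\pi\,r_\mathrm{trunk}$).
* Radius estimates degrade where cuts have few starting points (thin
  tips); the ancestor-inheritance fallback is deliberately conservative.
* The axis-ordering rule (main axis follows the larger subtree length,
  ties by radius then id) is a reproducible convention; field botanists
  applying ordering by eye may disagree on near-ties.
* Validation matches reference and reconstruction by aggregate counts and
  lengths per order, not one-to-one axis correspondence.
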