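---
title: "Quantifying the planar orientation of basal dendritic arbors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the planar orientation of basal dendritic arbors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arborient)
```

## The problem

Pyramidal neurons extend basal dendrites sideways from the base of the
soma. Whether those arbors fill the space around the soma uniformly or
grow preferentially along particular anatomical axes matters for
connectivity: a dendritic field elongated along an axis is better placed
to intercept axonal systems running that way. Classical polar-histogram
tools describe a single cell's arbor in its own coordinates, but cannot
relate a *group* of cells to a *shared* anatomical frame, because the
absolute position and orientation of each cell within the sectioned
tissue is lost once cells are analysed individually.

`arborient` works on horizontal-section *maps*: each map carries the
section contour, the soma position of every labelled neuron, and four
reference points marking the posterior, dorsal, anterior and ventral
directions placed per brain-atlas convention. All neurons of one map are
analysed against the same frame, so their orientations are directly
comparable and can be aggregated.

## From reconstruction to angles

Reconstructions arrive as standard SWC files. Only basal-dendrite nodes
(type code 3) are used; apical dendrites and axons are dropped. Every
branch is resampled into points spaced exactly 0.5 µm apart in arc
length, so each point stands for one dendritic segment of fixed length
and point counts are proportional to dendritic length. A branch of
length $L$ yields $\lfloor L/0.5 \rfloor$ points; the residual shorter
than one step is discarded, keeping inter-point spacing exact. Arc
length is measured along the 3-D branch and the points are then
projected onto the section plane; sections are 150–200 µm thick, so a
`planar_arclength` switch offers the in-plane alternative for
sensitivity analysis. All angles are planar.

For neuron $i$ with soma $o_i$, the bearing of a sample point $g$ is the
signed angle

$$\alpha_{i,g} = \operatorname{atan2}\!\big(a_x v_y - a_y v_x,\;
a_x v_x + a_y v_y\big),$$

where $a = p_{\mathrm{post}} - o_i$ is the soma-to-posterior-reference
axis and $v = g - o_i$. Bearings are counterclockwise-positive with the
posterior ray at 0, so the frame travels with each neuron while staying
anchored to the section's anatomy.

## Sectors

The four rays from the soma to the reference points define the
anatomical directions *for that neuron*; their angles differ from neuron
to neuron because the reference points are far but not at infinity. The
circle is split into four sectors, one per direction. Two constructions
are supported:

* **bisector** (default): sector boundaries sit at the angular midpoints
  between circularly adjacent rays, so each direction's sector is the
  arc closest to its own ray and always contains it. This degrades
  gracefully when the rays are unevenly spaced.
* **rays**: the rays themselves bound the sectors (the arc from ray $j$
  counterclockwise to the next ray is labelled $j$), for sensitivity
  analysis against the literal reading of boundary lines drawn from the
  reference points.

Arcs are half-open: a bearing exactly on a boundary belongs to the
sector on the counterclockwise side, making assignment deterministic.
The arc fraction of sector $j$ is $PS_{i,j}$, with
$\sum_j PS_{i,j} = 1$ by construction. One geometric consequence worth
noting: moving the soma *toward* the anterior reference point tilts the
dorsal and ventral rays toward the posterior ray, so the posterior
sector narrows and the anterior sector widens.

## Two orientation callers

**Fisher-median method.** The Fisher circular median — the sample
bearing $\phi^\ast$ minimising $\sum_i d(\theta_i, \phi)$ with
$d(a,b) = \pi - |\pi - |a-b||$ — is the neuron's main direction, and the
neuron is called toward the sector containing it. If the median falls
exactly on a sector boundary the circular mean direction
$\operatorname{atan2}(S_n, C_n)$ takes over (flagged `fallback_used`).
We use the standard two-argument arctangent for the mean and minimise
the *sum* of circular distances for the median; these are the
conventional definitions matching the verbal description of both
estimators. Ties among median candidates go to the candidate closest to
the mean direction, then to the smallest angle. The median is computed
by a sorted prefix-sum algorithm in $O(n \log n)$ and is checked against
an exhaustive $O(n^2)$ scan in the test suite.

Per map, the per-direction call counts feed a tendency rule engine
(fractions $f_j$ of $n$ neurons): a direction with $f_j > 0.8$ makes the
map **oriented** toward $j$; a contiguous pair covering 100% with
members ≥ 50% and ≥ 30% is **oriented** toward the pair; the same pair
condition at > 80% coverage gives **partly oriented**; a single
direction with $f_j > 0.6$ gives **partly oriented**; otherwise the map
is **undetermined**. Full labels outrank partial ones and two-direction
tendencies outrank one-direction tendencies of equal strength — the
unique precedence consistent with the published per-map labels. Only
the four contiguous pairs (A-V, A-D, D-P, P-V) qualify; the opposite
pairs (A-P, D-V) never do. The packaged 44-map count table reproduces
43/44 published labels and exactly the seven fully oriented maps; the
one mismatch (map 6III, counts P2 D1 A0 V3) satisfies the stated
partly-pair rule for P-V exactly like three other maps published as
Partly P-V, and we follow the rules rather than special-case it.

**DLRM.** The dendritic length ratio method compares, per sector, the
fraction $TL_{i,j}$ of the neuron's sample points against the sector's
arc fraction: $TL_{i,j}/PS_{i,j} > t$ marks a growth-orientation
preference, with thresholds $t \in \{1.1, 1.2, 1.3\}$ spanning loose to
strict calls. Because both $TL$ and $PS$ sum to one, the $PS$-weighted
ratios always sum to one — hence at most three sectors can exceed 1, so
0–3 preferred directions is a theorem, not an assumption, and preferred
sets are nested as $t$ rises. Ratios in $(1, t)$ are reported as "weak"
but never count as preferences; both comparisons are strict, so a ratio
exactly equal to $t$ is not preferred and exactly 1 is not weak. The
preferred set determines the orientation type: single, contiguous
(adjacent pair), opposite (A-P or D-V), triple, or undetermined when
empty — a neuron whose ratios are all at most $t$ is undetermined even
if some are weak. Group results are reported as frequency tables per
class and threshold (by map and by layer); we deliberately do not
collapse DLRM groups to a single label, since the method's value is
precisely that it keeps the per-neuron detail.

## Visualisations

The **oriented circular histogram** (OCH) stacks one dot per 0.5 µm
segment at each of the 360 unit-degree bins, coloured by sector (blue =
posterior, orange = dorsal, purple = anterior, dark green = ventral),
with a red median arrow, a blue mean arrow, a light-green interquartile
arc, and DLRM results as sector wedges whose darkness encodes how many
thresholds are passed. The **expansion circular histogram** (ECH) is its
radial companion: concentric rings collect the points lying
$[25k, 25(k{+}1))$ µm from the soma (planar distance), showing how far
the oriented mass extends; the arrows and IQR are drawn from the first
ring only. Both functions always write a sidecar CSV of their bin
counts, so figures are testable by content rather than by pixels.

Quartiles for the IQR arc rotate all bearings so the median sits at 0,
take linear percentiles on $(-\pi, \pi]$, and rotate back. We use
$(n{+}1)p$ plotting positions (`stats::quantile` type 6) by default;
the rule is configurable, and any shift-equivariant choice preserves
rotation equivariance.

## The synthetic generator

No reconstruction data ship with the package, so validation rests on a
seeded generator that emulates the study material: maps with $6 \pm 2$
neurons (rounded normal, clipped at 1), each neuron growing 3–8 primary
basal branches of $100 \pm 25$ µm. A branch is a persistent-direction
walk: 1 µm steps whose direction is the branch's initial bearing plus an
AR(1) deviation (memory 0.7, per-step jitter sd 0.12 rad), so branches
wiggle locally but keep their course — an unbounded direction random
walk would forget its bearing and defeat the purpose of an orientation
dial. Branches bifurcate to depth 0–2 at a uniformly drawn position,
daughters splitting the remaining length and diverging by about 1 rad.
Initial bearings are drawn from a configurable von Mises mixture;
$\kappa = 0$ gives unoriented cells, a single concentrated component
gives single-orientation cells, two antipodal components give
opposite-type cells. Ground truth (mixture and intended label) is stored
with every generated map.

What the generator does *not* emulate: realistic branch-order
statistics, diameter taper, 3-D depth structure within the section,
spines, or any correlation between neighbouring neurons. Passing
recovery tests therefore show that the estimators read out the
orientation structure that the generator plants — not that real P14
arbors satisfy any particular model.

### What the uniform null actually does

A point worth stating explicitly, because it bounds what any user should
expect from small arbors: sample points along one branch are angularly
correlated, so the effective sample size of a neuron is its branch
count, not its point count. For an unoriented cell with 40 straight
branches, sector counts are Multinomial$(40, \tfrac14)$ and the chance
that *no* sector ratio exceeds 1.3 is only about 0.60; for a realistic
3–8-branch cell it drops below 0.1. Spurious "preferences" under the
uniform null are thus common at small branch counts — consistent with
the published finding that roughly 72% of real neurons received some
orientation call at $t = 1.3$. Our recovery experiment reflects this:
strongly biased cells ($\kappa = 8$, 40 branches) are recovered as
single-orientation in the seeded sector in essentially all replicates,
while unoriented cells are called undetermined in only a modest majority
(≈ 55–60%) — a sampling-noise floor of the method itself, not an
implementation artefact.

## Numerical choices and edge cases

* Resampling uses a `1e-9` tolerance on $L/\text{step}$ so branches
  whose length is an exact multiple of the step emit their final point
  despite floating-point summation.
* Degree binning adds `1e-7` degrees before flooring so whole-degree
  bearings stay in their intended bin.
* A zero resultant makes the mean direction undefined; it is reported as
  `NA` in summaries and raises a typed condition when requested
  directly. A neuron whose median lies on a boundary *and* whose mean is
  unusable is called `unclear` and excluded from map counts.
* Sample points coincident with the soma have no bearing; they are
  skipped with a warning.
* Somata coincident with a reference point, or two collinear reference
  rays, are geometry errors: the sector construction would be ambiguous.
* SWC parsing validates the 7-column format, unique ids, resolvable
  parents and acyclicity, and reports offending line numbers.
  Multi-point somata collapse to the centroid of the type-1 nodes.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything they
measure: 1000 random synthetic neurons for the conservation identities,
1000 random angle sets (n ≤ 50) for the median oracle, 1000 points for
the arc-membership oracle, 500 vector pairs for the angle oracle, and
200 replicates per condition for the recovery experiment (40 branches ×
100 µm at $\kappa \in \{0, 8\}$, $t = 1.3$). These sizes give
Monte-Carlo standard errors below 2 percentage points on the recovery
rates while keeping a full run in well under a minute.

## Known limitations

* The method is strictly planar; depth within the section is discarded
  after arc-length measurement, and no solid-angle generalisation is
  attempted.
* Reference points are inputs. They were placed by hand in the original
  material and are not inferable from a reconstruction; nothing in the
  package attempts to recover them.
* The tendency rule engine is a fixed-precedence rule set, not an
  inferential procedure; no hypothesis tests accompany either caller.
* DLRM thresholds are conventions. The 1.1/1.2/1.3 grid spans loose to
  strict, but there is no estimation of a data-driven threshold.
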