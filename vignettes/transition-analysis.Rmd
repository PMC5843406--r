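---
title: "Temporal transition analysis of co-activation patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal transition analysis of co-activation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Resting-state fMRI shows a brain that keeps reconfiguring: the correlation
structure of spontaneous BOLD fluctuations (resting-state functional
connectivity, RSFC) is not stationary but wanders between a repertoire of
characteristic spatial patterns. `captrans` asks the follow-up question:
are the *transitions* between those patterns random, or do they follow
preferred sequential orders?

The analysis rests on one empirical premise: the instantaneous BOLD
co-activation pattern of a single fMRI frame is a workable proxy for the
RSFC pattern the brain expresses at that moment. Given a library of $K$
reference patterns (group-level seed-correlation maps, one per parcel of
an RSFC-based parcellation), each frame is assigned the label of the
reference map with the highest spatial Pearson correlation to the frame,
provided that correlation clears a threshold $r_{\min}$. Frames that match
nothing, and frames censored for head motion, are labeled $0$. A run thus
becomes a label sequence in $\{0, 1, \dots, K\}$, and ordered transitions
$i \to j$ ($i \neq j$, both nonzero, adjacent frames) are tallied into a
$K \times K$ directed transition matrix. Pairs involving $0$ contribute
nothing, so a censored frame separates rather than bridges its neighbors.

Significance of individual transitions is assessed against an order-free
null: the label sequence is first *consolidated* (maximal runs of a
repeated label collapse to one token, removing dwell time), then the
tokens of each run are uniformly shuffled many times and transitions are
recounted. Entries surviving Benjamini–Hochberg FDR control become the
edges of a weighted directed transition network, whose community structure
(consensus Louvain) and hub scores summarize how the pattern repertoire is
organized in time.

## Pipeline stages and the parameters that matter

| Stage | Function | Key parameters (defaults) |
|---|---|---|
| Motion scrubbing | `scrub_frames()` | FD threshold 0.2 mm; neighbors censored; first 10 frames discarded |
| Nuisance removal | `nuisance_regress()`, `bandpass()` | band 0.01–0.1 Hz; FFT mask or Butterworth |
| Reference library | `build_pattern_library()` | 540-frame cap per run; subject-mean t maps, SE floor at the median |
| Frame matching | `match_frames()` | $r_{\min} = 0.1$ (coarse, $K \approx 40$) or 0.05 (fine, $K \approx 333$); ties to the lowest index |
| Transition counting | `count_transitions()`, `subject_matrices()` | runs summed within subject, subjects averaged |
| Permutation null | `permutation_test()` | 10000 shuffles, within-run, 0 tokens included |
| Thresholding | `threshold_matrix()` | BH at $q = 0.05$; survivors min–max rescaled; similarity regressed; $\epsilon = 10^{-6}$ weight floor |
| Graph analysis | `node_metrics()`, `hub_scores()`, `consensus_communities()` | edge length $1/w$; 20th-percentile hub criteria, hub $\ge 3$; Louvain $\times 1000$, co-assignment binarized at 0.9 |
| Motion controls | `transition_frame_fd()`, `transition_fd_matrix()`, `motion_split_test()` | median split on mean FD; 1000 random splits |

Units: FD is in mm (rotations converted to arc length at a configurable
head radius, 5 mm rat-scale by default, 50 mm human-scale); the band-pass
edges are in Hz; pattern maps are unit-variance over voxels.

## Numerical and design choices

**The permutation statistic is a transition share, not a raw count.** A
consolidated sequence contains no adjacent repeats by construction, but
its uniform shuffles do; shuffled sequences therefore always carry fewer
countable adjacencies than the observed one. Comparing raw counts against
such a null inflates every entry of the matrix (in a fully i.i.d.
simulation at $K = 5$, most entries come out "significant"). `captrans`
instead compares each cell's *share* of all counted transitions, computed
identically for observed and permuted sequences. This asks the question
the test is meant to ask — is $i \to j$ over-represented among the
transitions that occur? — and is calibrated: under i.i.d. label sequences
the fraction of FDR-surviving entries stays at or below the nominal rate
(the test suite measures this over 50 replicates). P-values use the
add-one estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)$,
so they are never zero.

**Permutations respect run boundaries.** Transitions never span runs in
the observed data, so each run's tokens are shuffled within the run and
matrices are aggregated afterwards; a concatenated shuffle would
manufacture cross-run adjacencies that cannot occur. The $0$ tokens are
kept and shuffled with the rest, preserving the expected number of
countable adjacencies.

**Thresholding.** BH-surviving cells are min–max rescaled to $[0, 1]$,
pattern similarity is regressed out of the surviving cells only, and
residuals are floored at $\epsilon = 10^{-6}$ so every surviving cell
carries a strictly positive edge weight (distance-based graph metrics need
positive weights). The edge set of the graph is therefore exactly the set
of FDR survivors.

**Similarity regression.** Spatially similar reference maps compete for
the same frames, which could inflate their mutual transition counts and
any reproducibility computed from them. Each ordered off-diagonal cell is
one observation regressed (with intercept) on the symmetric spatial
correlation of the two maps; residuals replace the entries. Because the
min–max normalization is affine and Pearson correlation is
affine-invariant, reproducibility values do not depend on the rescaling
constants.

**Group statistic.** The per-parcel group map is a voxelwise t statistic
of the Fisher-z seed correlations with subject as a random effect. The
default estimator averages runs within subject and applies a one-sample t
across subjects, which is exactly the balanced-design random-intercept
solution; a full `lme4` fit is available (`method = "lmm"`). When data are
nearly noiseless the plain t map degenerates — background voxels with
vanishing between-subject variance produce unbounded t — so the library
builder floors voxelwise standard errors at their median (a simple
variance moderation); `group_map()` itself defaults to the plain
statistic.

**Frame normalization** is the voxelwise z-score with the population
(denominator-$T$) standard deviation; the choice of denominator is
immaterial because spatial correlation is invariant to per-voxel affine
maps. Zero-variance voxels are zeroed and flagged rather than producing
NaNs. Exact matching ties (possible with duplicated reference maps)
resolve deterministically to the lowest pattern index. Signed correlation
is used throughout: a frame anticorrelated with every map is unmatched.

**Graph conventions.** Shortest paths run on edge lengths $1/w$;
betweenness and per-node characteristic path length (mean finite outgoing
distance) follow from those paths, with unreachable pairs excluded and
flagged. The local clustering coefficient is the directed weighted
cube-root-of-weights triangle formulation. Louvain uses directed
modularity (in/out-strength null model, resolution 1); because greedy
modularity optimization is order-dependent, it is repeated (1000 times by
default) over random node orders, and communities are the connected
components of the co-assignment matrix binarized at 0.9. Hub percentile
cutoffs use linearly interpolated quantiles with inclusive comparisons, so
ties at a cutoff count as meeting the criterion.

## The synthetic generator

`render_dataset()` plants a first-order Markov chain over $K$ spatial
patterns: every frame is its pattern map plus i.i.d. Gaussian noise, and
every run carries a framewise-displacement trace (half-normal baseline
$|N(0.04, 0.02)|$ mm — the scale reported for head-fixed rodents — with
spikes above the 0.2 mm censoring threshold at a configurable rate).
Defaults (8 patterns, 300 voxels, 4 subjects × 2 runs × 600 frames, noise
SD 0.5) give frame-matching accuracy above 95%, so every downstream stage
can be validated against known ground truth.

Two generator choices deserve explanation:

- *The planted transition matrix is doubly stochastic* (dwell 0.8 plus a
  weighted mixture of three random derangements). Transition counts
  estimate $\pi_i P_{ij}$, the occupancy-weighted probabilities; with a
  uniform stationary distribution ($\pi_i = 1/K$, guaranteed by double
  stochasticity) the counts are proportional to the planted $P_{ij}$
  themselves, which is the estimand the recovery checks compare against.
- *Seed parcels are the positive cores of each pattern's support block*
  (top 40% of loadings). Pattern loadings are zero-mean, so averaging a
  whole block would produce a seed time course blind to pattern occupancy;
  the positive core rises whenever its pattern is active, which is exactly
  the behavior a functional parcel's mean signal shows when its network
  activates.

What the generator does *not* emulate — hemodynamic convolution, temporal
autocorrelation, physiological confounds, spatial smoothness, anatomy —
bounds what passing tests show: they validate the estimation machinery
(matching, counting, null calibration, graph recovery), not robustness to
every artifact of real fMRI. Motion in the generator is independent of the
label chain by construction, which is what makes it a *null* reference for
the motion-control analyses.

## Problem sizes used in validation

The shipped validation uses deliberately desk-scale problems: planted
recovery at $8$ patterns and $4800$ frames; type-I calibration over 50
i.i.d. replicates of 2000 frames at $K = 5$ with 2000 permutations;
reproducibility cohorts of 40 label-chain subjects; graph oracles on
10-node random graphs (exhaustive Floyd–Warshall) and 6-token sequences
(full 720-arrangement enumeration). Larger $K$ and longer runs change
nothing structurally — the human-scale configuration is the same code with
$K = 333$ and $r_{\min} = 0.05$.

## Known limitations

- Single-label assignment is an approximation; a frame can genuinely
  express features of several patterns. Soft assignment is out of scope.
- The diagonal (dwell) is never interpreted; dwell-time modeling and
  dwell-conditional transition probabilities are out of scope.
- `graph_density()` and the hub criteria assume a simple directed graph
  without self-loops, as produced by `build_graph()`.
- The permutation null randomizes order only; it does not test against
  Markov-analytic or phase-randomized alternatives.
- With very sparse surviving edge sets the thresholded graph can be
  disconnected; path-based metrics then rest on the finite-distance
  convention and are flagged per node.

## A worked example

```{r, eval = FALSE}
library(captrans)

cfg <- synthetic_config(seed = 42)      # 8 patterns, 4 subjects x 2 runs
ds  <- render_dataset(cfg)
res <- run_pipeline(ds, out_dir = "captrans-demo")

# how well does the estimated structure recover the planted one?
P  <- cfg$transition_probs
od <- row(P) != col(P)
cor(unclass(res$group_norm)[od], P[od])

res$reproducibility$split_half          # split-half reproducibility
res$report[res$report$is_hub, ]         # hub patterns
table(res$communities)                  # community sizes
```
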