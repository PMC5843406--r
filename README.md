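# captrans

Temporal transition analysis of co-activation patterns in resting-state
fMRI.

Resting-state functional connectivity (RSFC) is not stationary: the brain
wanders between a repertoire of characteristic connectivity patterns.
`captrans` is for researchers who want to know whether those wanderings
are random or follow preferred sequential orders. It implements, as
tested reusable R functions, the full chain from 4D time series to a
directed *pattern-transition network*:

1. **Frame matching.** Using the premise that a single frame's BOLD
   co-activation pattern proxies its instantaneous RSFC pattern, every
   frame is labeled with the reference pattern $k \in \{1,\dots,K\}$
   maximizing the spatial Pearson correlation $r$ between frame and map,
   subject to $r > r_{\min}$ (default 0.1); censored or unmatched frames
   get label 0.
2. **Transition matrix.** Entry $(i, j)$ counts adjacent-frame pairs
   labeled $i \to j$ with $i \neq j$ and $i, j \neq 0$; pairs involving 0
   count nothing.
3. **Permutation null.** The label sequence is consolidated (runs of a
   repeated label collapse to one token, removing dwell time), tokens are
   shuffled within each run, and each cell's share of counted transitions
   is compared between observed and shuffled sequences:
   $p = (1 + \#\{\text{null} \ge \text{obs}\}) / (n_{perm} + 1)$.
4. **Transition network.** Benjamini–Hochberg FDR (q = 0.05) selects the
   edges; surviving weights are rescaled to [0, 1] and the spatial
   similarity between reference maps is regressed out. The directed
   weighted graph is characterized by consensus Louvain communities
   (1000 repetitions, co-assignment binarized at 0.9) and by hub scores
   (0–4: upper-20th-percentile strength and betweenness,
   lower-20th-percentile characteristic path length and clustering;
   score ≥ 3 marks a hub).

Supporting modules provide framewise-displacement scrubbing (FD > 0.2 mm
plus neighbors), nuisance regression, band-pass filtering (0.01–0.1 Hz),
seed-based reference-library construction with mixed-effects group maps,
split-half and individual-level reproducibility, head-motion control
analyses, and a synthetic-data generator that plants a known Markov
transition structure so the entire pipeline can be validated against
ground truth. See `vignettes/transition-analysis.Rmd` for the methods in
detail.

## Worked example

```r
library(captrans)

cfg <- synthetic_config(seed = 42)   # 8 patterns, 4 subjects x 2 runs x 600 frames
ds  <- render_dataset(cfg)
res <- run_pipeline(ds, out_dir = "captrans-demo", seed = 1)

P  <- cfg$transition_probs
od <- row(P) != col(P)
cor(unclass(res$group_norm)[od], P[od])
#> [1] 0.987
res$reproducibility$split_half
#> [1] 0.953
igraph::ecount(res$graph)
#> [1] 15
table(res$communities)
#> 1 2 3
#> 2 3 3
res$motion$fd_matrix$correlation
#> [1] -0.036
```

Reading the output: the estimated group-level transition matrix
correlates 0.987 with the planted transition probabilities, so the
pipeline recovers the planted temporal structure almost exactly; a random
20/20-style split of the cohort reproduces the off-diagonal structure at
r = 0.953; 15 directed transitions survive the permutation-FDR threshold
and organize into three communities — matching the three derangement
layers the default generator plants; and the mean FD during each
transition type is uncorrelated with how often that transition occurs
(−0.036), i.e. transitions are not motion events. `run_pipeline()` also
writes every stage artifact (label sequences, matrices at each processing
level, permutation p-values, node report, edge list, parameter log) to
the output directory as delimited text.

A thin command-line wrapper is installed at `inst/cli/captrans`
(`captrans simulate|all --out DIR [--seed S ...]`) for shell use.

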