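# posturecluster

Unsupervised analysis of how spinal posture *changes* under guided posture
training, for researchers working with multi-sensor tilt wearables. The
input is a database of snapshots — single frames of five lumbar forward
tilt angles (degrees, sensor 1 lowest), tagged with user, position
(standing / sitting / hip hinging), guidance label and timestamp. The
package pairs each user's earliest **unguided** snapshot (t0) with their
latest **guided** one (t1) and asks what kinds of change the guidance
induced, with no reference to any "normal" spine.

The core method, per posture pair:

1. **Spine curves.** Five tilt angles become a sagittal 2D curve of six
   points P0..P5 (P1 pinned at the origin), consecutive points joined by
   constant-curvature arcs of fixed length L whose tangent angle runs
   linearly between the sensor tilts.
2. **Change feature.** For j ∈ {0,2,3,4,5}:
   l_j = ‖P_j|t1 − P_j|t0‖₂ and d_j = (P_j|t1 − P_j|t0)/l_j — five lengths
   plus five unit directions, a 15-dimensional vector.
3. **Embedding.** PCA keeping ≥ 95% of variance, then exact t-SNE
   (perplexity 30, deterministic per seed) down to a 2D map.
4. **Clustering.** Euclidean minimum spanning tree of the map; cutting the
   k−1 heaviest edges leaves k connected components = clusters.
5. **Profiles.** Each cluster is summarized as a bundle of *offset spine
   shapes* (curves reconstructed from the t1−t0 angle differences) with
   1/25/50/75/99 percentile bands per point level, sign tallies and
   machine-readable geometric flags.

Alongside: Table-style database summaries, per-sensor descriptive
statistics, paired Wilcoxon signed-rank tests (exact up to n = 25,
tie-corrected normal approximation beyond), a synthetic database generator
with planted change archetypes, and a perplexity-stability sweep.

## Worked example

Simulate a standing database of 135 users with three planted change
archetypes, run the full pipeline, and compare the clusters against the
hidden truth:

```r
library(posturecluster)

cfg <- run_config(
  generator = generator_config("standing", n_users = 135,
    archetypes = list(
      archetype("anterior_shift",  c( 10,  8,  8,  8,  8), sd = 1),
      archetype("posterior_shift", c(-10, -8, -8, -8, -8), sd = 1),
      archetype("tilt_reversal",   c( 10,  6, -2, -10, -12), sd = 1)),
    seed = 1),
  seed = 1, k = 3)
res <- run_all(cfg)

res$clustering
#> mst_clustering: k = 3 , sizes: 54, 43, 38 , MST total weight 136.76

adjusted_rand(res$clustering$labels, res$truth$archetype)
#> [1] 1
```

ARI 1: the three planted archetypes are recovered exactly. The per-cluster
geometric flags read off what each cluster *is*, e.g.:

```r
attr(res$bundles, "flags")
#>   cluster base_sign_unanimous base_sign upper_slant_sign crossing_level n_crossings
#> 0       0                TRUE         -                -              4           1
#> 1       1                TRUE         -                +             NA           0
#> 2       2                TRUE         +                -             NA           0
```

Cluster 1 offsets anteriorly throughout (base posterior sign is the mirror
of sensor 1 tilting *more* forward — an anteversion gain), cluster 2
posteriorly throughout, and cluster 0's median offset curve crosses the
vertical between levels 4 and 5 — the tilt-reversal group. Per-sensor
paired Wilcoxon tests on the same data:

```r
subset(res$wilcoxon, position == "standing")
#>   sensor n_eff statistic p_display significant
#> 1      1   135      6637  6.97e-06        TRUE
#> 2      2   135      5975   0.00236        TRUE
#> 3      3   135      4083     0.266       FALSE
#> 4      4   135      1909   < 1e-06        TRUE
#> 5      5   135      1546   < 1e-06        TRUE
```

(Sensor 3 is where the mixture's mean change crosses zero, so its marginal
median change vanishes even though every individual user changed — exactly
why the clustering works on geometry rather than marginal angle shifts.)
Setting `out_dir` in `run_config()` writes every intermediate (pairs,
features, map, labels, bundles, statistics) as CSV plus a JSON provenance
manifest; `perplexity_sweep(cfg)` re-embeds at perplexities 25–40 and
reports cluster sizes and pairwise adjusted Rand indices between the runs.
A command-line wrapper lives at `inst/scripts/posture-pipeline.R`.

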