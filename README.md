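# palaeotax

Quantitative coherence testing of cultural taxonomic units from lithic
trait and outline data.

European Final Palaeolithic and earliest Mesolithic archaeology (roughly
15,000–11,000 cal BP) organizes its record into named archaeological
cultures (NACs, e.g. "Ahrensburgian", "Federmesser") and higher-order
macro-units (Magdalenian *s.l.*, Epigravettian *s.l.*, the arch-backed-point
complexes, FBT/LBI, the tanged-point complex, Mesolithic). Whether these
units are coherent — whether their members actually resemble each other more
than randomly assembled sets of NACs — is an empirical question. `palaeotax`
implements a full pipeline for answering it from three data domains:

* **Tools** — presence/absence/unknown toolkit-composition traits per NAC;
* **Technology** — presence/absence/unknown traits of lithic technological
  organisation;
* **Outlines** — closed 2D outlines of projectile armatures, analysed by
  elliptic Fourier analysis (EFA).

## The statistics at the core

**Coherence (SES).** For a group G of n entities with pairwise dissimilarity
matrix d, the observed statistic is the mean within-group distance
`Metric_obs = mean{ d(i,j) : i<j in G }`. The null distribution is built by
drawing groups of size n uniformly without replacement from the pool and
recomputing the statistic; then

```
SES = (Metric_obs − mean(Metric_null)) / sd(Metric_null)
```

SES ≤ −2 flags a group significantly *more* coherent than chance, SES ≥ 2
significantly *over-dispersed*; |SES| = 2 approximates the 5% level under
the central-limit normality of the null mean.

**Distances.** Gower dissimilarity on tri-state traits (mean absolute
difference over traits known in both rows — unknowns are pairwise-deleted,
never imputed); Euclidean distance over all PC scores of the elliptic
Fourier coefficients (outlines are smoothed, normalized, resampled to 500
tip-anchored semi-landmarks, and decomposed into as many harmonics as carry
99.9% of the cumulative harmonic power `P_n = (a_n²+b_n²+c_n²+d_n²)/2`);
haversine distance (R = 6371.0088 km) between sites or NAC regional
centroids; and time-slice rank distance over the four millennial bins
I–IV.

**Structure.** Ward (`ward.D2`) dendrograms with character bootstrap
(columns resampled, 1000 replicates, branches < 50% support collapsed),
tanglegram comparison of domain trees (shared clades + an entanglement
score), Mantel tests and Mantel correlograms over geographic distance
classes with Hochberg correction, disparity through time (per-slice sum of
PC-score variances with bootstrap CIs and permutation contrasts), and CART
(Gini, minimum-CV-error pruning, unknown-tolerant) trait importance for the
macro-units.

A seeded synthetic-data generator (`simulate_dataset()`) emulates the study
structure — 16 regions, 86 NACs in 7 macro-units, two trait domains with
archetype + flip-noise + missingness, spatially blocked units, and armature
outline families whose within-group dispersion follows a per-time-slice
schedule — so that every stage is testable end to end without any external
download.

## Worked example

```r
library(palaeotax)

ds <- simulate_dataset(generator_config(seed = 1))
tx <- expand_timeslices(ds$tools)          # 86 NACs -> 88 slice rows
d_tools <- gower_distance(tx)
mem <- setNames(tx$meta$macro_unit, rownames(tx$values))
ses_table(list(tools = d_tools), list(tools = mem),
          resamples = c(tools = 10000), seed = 7)
```

```
  domain         macro_unit  n    ses direction
1  tools   Magdalenian s.l. 24 -20.56  coherent
2  tools Epigravettian s.l.  5  -6.21  coherent
3  tools        ABP/Azilian 16 -15.24  coherent
4  tools            ABP/FMG 11 -10.61  coherent
5  tools            FBT/LBI  6  -5.94  coherent
6  tools                TPC 15 -13.51  coherent
7  tools         Mesolithic  9  -9.08  coherent
8  tools         unassigned  2   0.78        ns
```

Every planted macro-unit is recovered as strongly coherent (SES far below
−2: its NACs are much more alike than random NAC sets), while the two
deliberately unassigned generic NACs are indistinguishable from chance.

```r
pre   <- outline_set(lapply(ds$outlines, preprocess_outline))
nh    <- calibrate_harmonics(pre)          # 6 harmonics carry 99.9% power
space <- pca_shapespace(efa_coefficient_table(pre, nh))
disparity_by_timeslice(space, outline_meta(ds$outlines)$time_slice, seed = 8)
```

```
  time_slice n_outlines disparity ci_lower ci_upper
1          I        132   0.00688  0.00604  0.00753
2         II        132   0.00649  0.00571  0.00732
3        III        132   0.01524  0.01382  0.01656
4        IV         132   0.03187  0.02907  0.03444
```

Armature shape disparity (sum of PC-score variances per slice) is stable
across time-slices I–II, then roughly doubles into III and again into IV —
the diachronic diversification pattern the generator plants.

`run_pipeline(pipeline_config(...))` chains every stage (simulation or file
input, EFA/PCA, all distances, SES table, bootstrapped consensus trees,
tanglegram, Mantel tests and correlograms, time correlation, disparity,
CART) and writes CSV/Newick outputs plus a JSON manifest whose md5 hashes
reproduce exactly under a fixed seed.

## Vignette

`vignettes/palaeotax-methods.Rmd` documents the model and its assumptions,
every tunable parameter, what the synthetic generator does and does not
emulate, and the numerical choices (tolerances, tie-breaks, degenerate-input
handling).
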