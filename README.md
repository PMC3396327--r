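# chordscene

Prototype-based encoding of shapes and two-object scene layouts, with a
similarity-preserving associative memory and reproducible simulation
experiments, in base R.

## The problem

How can a visual system represent a *structured* scene — several objects in a
spatial arrangement — so that similar scenes are retrieved by content, novel
recombinations of familiar parts are still interpretable, and similarity
degrades gradually rather than categorically as the scene changes?

This package implements a concrete answer built entirely from one primitive,
the **chorus transform**: an input `x` in measurement space is encoded by its
scaled distances to a fixed, ordered set of prototypes `p_1 … p_n`,

    CT(x) = (1/sqrt(n)) * ( ||x − p_1||, …, ||x − p_n|| )'

a dimensionality reduction (for `n < d`) that approximately preserves
similarity relations.  Discretizing the code to the **rank order of
distances** (ROD) gives `n!` distinct symbols comparable by Spearman rank
correlation, and the same machinery yields locality-sensitive hash bits
(`sign(a' k_x − b)` over the distance vector), winner-take-all hashes via
random biases, and min-k signatures whose collisions track Jaccard
similarity.

Scenes are handled by a relational scheme: each 150 × 150 scene contains two
50 × 50 grayscale objects; regions of interest are detected by
Gaussian-convolution argmax, each ROI is Gabor-encoded (2 scales × 2
orientations, energy mean-pooled on a 5 × 5 grid) and chorus-coded against 10
shape prototypes, and the spatial arrangement is chorus-coded against 10
fixation-dependent layout prototypes (two-Gaussian-patch images).  A scene is
stored **redundantly**, once per fixation, in a multi-table hash index with
the fixated-ROI code as the key, and the dissimilarity of two scenes under a
fixation is the equal-weight sum

    Δ = ||ROI_fix,1 − ROI_fix,2|| + ||D_1 − D_2|| + ||ROI_other,1 − ROI_other,2||

averaged over the two fixations.

A seeded synthetic generator (eight parametric grayscale object families with
canonical orientations, per-exemplar texture, and controlled placements)
stands in for a photographic object database and drives three experiments:

1. **Productivity** — dissimilarity of the best retrieved match grows with
   the number of novel scene constituents (0, 1, 2), and a familiar scene is
   recalled exactly.
2. **Graded displacement** — moving one object in 10-px steps produces a
   gradual, near-linear increase in dissimilarity (simple OLS, `R² ≈ 0.73`,
   10 000 points).
3. **Qualitative change** — swapping the two objects (R) disrupts the
   representation far more than jointly translating them (T), with TR ≈ R;
   translation tolerance follows from fixation-centred layout coding.

## Worked example

```r
library(chordscene)

cfg <- chord_config()
enc <- chord_encoder(cfg, seed = 1)

# a two-object scene: an ellipse above a rectangle
sc <- make_scene(scene_spec(list(object_spec("ellipse", 7),
                                 object_spec("rectangle", 8)),
                            rbind(c(40, 75), c(110, 75)), id = "demo"),
                 cfg)

rep <- encode_scene(sc, "top", enc, mode = "ct")
rep
#> <scene_rep> fixation top, mode ct: fix 10 + other 10 + layout 10 dims

# store it with a few distractors and query it back
mem <- chord_memory(enc)
store_scene(mem, sc)
#> 2 records: one per fixation
for (i in 1:5)
  store_scene(mem, make_scene(scene_spec(list(object_spec("annulus", 20 + i),
                                              object_spec("triangle", 30 + i)),
                                         rbind(c(40, 75), c(110, 75)),
                                         id = paste0("d", i)), cfg))
query_scene(mem, sc, k = 3)
#> <chord_query> mode ct, composite dissimilarity 0.0000
#>   fixation rank scene_id stored_fixation        delta ...
#> 1      top    1     demo             top 2.980232e-08 ...
#> 2   bottom    1     demo          bottom 2.980232e-08 ...
```

The composite dissimilarity of an exactly stored scene is 0; replacing one
object or displacing it raises Δ in proportion to the change.

A scaled displacement experiment, with the numbers it prints:

```r
ex <- run_displacement(cfg, seed = 1, n_scenes = 200)
ex
#> <chord_experiment> displacement (seed 1, n = 1000 observations)
#>  level displacement      mean         ci   n
#>      1           10  2.210224 0.06028328 200
#>      2           20  4.810028 0.12397116 200
#>      3           30  7.368549 0.21094928 200
#>      4           40  9.557571 0.31412748 200
#>      5           50 10.881102 0.40255714 200
#>   OLS: delta = 0.3387 + 0.2209 * displacement; R^2 = 0.736, F(1, 998) = 2787, ...
plot(ex)                    # means with 95% confidence intervals
write_results(ex, "out")    # CSV + self-describing JSON + PNG figure
```

Mean dissimilarity rises with every 10-px displacement step and a straight
line explains about 74% of the variance over all scene × level points — graded,
not categorical, sensitivity to layout change.

`inst/scripts/chord.R` wraps the runners for shell use
(`Rscript chord.R experiment --which displacement --seed 1 --scale 0.1 --out out`).

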