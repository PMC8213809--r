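# smlmClassify

Prior-knowledge-free classification of structurally heterogeneous particles
in single-molecule localization microscopy (SMLM) data.

Particle fusion — registering many picked instances of a structure into a
common frame and pooling their localizations — assumes all particles are
copies of one structure. Real datasets mix structures: different designs,
mirrored adsorption orientations, rare symmetric variants (e.g. 9-fold
nuclear pore rings among 8-fold ones), continuous deformations. Fusing a
mixture blurs it. `smlmClassify` sorts the particles into structural classes
first, with no templates and no prior on the number of classes, and then
fuses per class.

## Method

For particles $a, b$ with localizations $\mathbf r$ and uncertainties
$\sigma$, every unordered pair is rigidly registered (Gaussian-mixture
overlap objective, multi-start simplex) and scored with the normalized
Bhattacharyya similarity

$$ S(a,b) = \frac{1}{K_a K_b}\sum_{i=1}^{K_a}\sum_{j=1}^{K_b}
   \frac{\exp\left(-\frac12\,\lVert\mathbf r_{a,i}-T(\mathbf r_{b,j})\rVert^2
   /(\sigma_{a,i}^2+\sigma_{b,j}^2)\right)}{\sigma_{a,i}^2+\sigma_{b,j}^2}. $$

Dissimilarities $D = \max(S) - S$ are embedded by metric MDS (SMACOF, 30
dimensions, stress $=\big(\sum_{i<j}(d_{ij}-\lVert\mathbf x_i-\mathbf
x_j\rVert)^2/\sum_{i<j}d_{ij}^2\big)^{1/2}$), clustered by multi-restart
k-means (best of 1000 restarts by within-cluster sum of squares), and each
cluster is fused into a reconstruction. Optionally, many small clusters are
merged into a few classes by projecting the aligned, normalized cluster
renderings onto their first eigen image (SVD via the small K×K Gram matrix)
and cutting an average-linkage dendrogram of the projection weights — the
mechanism that isolates rare subpopulations down to a few percent.

A synthetic particle generator (grids, N-fold rings, letter-like dot
patterns, 3D tetrahedra; underlabeling, Poisson localizations per site,
Gamma-distributed per-localization uncertainties, random pose, mirroring,
elliptical deformation) makes every stage testable without experimental
data. Ellipse fitting to ring-site medians and an orientation order
parameter quantify continuous shape variation of ring-like classes.

## Worked example

Detect a rare 9-fold subpopulation planted at 2% among 500 simulated 8-fold
NPC-like rings (DoL 0.7, ~6 localizations per site, σ ≈ 3 nm):

```r
library(smlmClassify)
trial <- rareClassTrial(seed = 2, rareCount = 10L, nParticles = 500L,
                        K = 40L)
trial$recall        # fraction of true 9-fold particles in the minority class
trial$minoritySize  # size of the minority output class
```

```
#> trial$recall
#> [1] 0.9
#> trial$minoritySize
#> [1] 9
```

Nine of the ten 9-fold particles form the minority output class; the tenth
sits in a k-means cluster that merged with the majority (detection across
repeated seeds succeeds whenever the minority class captures at least 80%
of the planted particles, which holds in most seeds at this 2% fraction).
The general-purpose entry point is `runPipeline()`:

```r
ps <- makeDataset(
  mixtureSpec(lapply(standardMixtureTemplates(),
                     function(t) list(template = t, fraction = 0.25)),
              nParticles = 100, seed = 7),
  acquisitionModel(dol = 0.7, locsPerSite = 6, sigmaMeanNm = 2))
res <- runPipeline(ps, pipelineConfig(
  scale = 0.03, K = 4L, seed = 7, outDir = "run1",
  registration = registrationConfig(maxLocsOptim = 32L,
                                    maxEvalCoarse = 100L)))
table(res$classLabels, trueClasses(ps))
```

```
#>    
#>      1  2  3  4
#>   1  0  0 30  0
#>   2  0 23  0  0
#>   3  0  0  0 20
#>   4 27  0  0  0
```

Each of the four templates (grid, T, 12-dot ring, X) lands in its own
cluster. `run1/` holds the labels, embedding, fusion renderings, merge map
and a YAML manifest; re-running with a different `K` or `C` there reuses
the cached registration.

See the vignette (`vignettes/classifying-smlm-particles.Rmd`) for the model,
parameter guidance and numerical choices.

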