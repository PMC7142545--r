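# aphidcoex

Morph-specific expression, mutual-information co-expression networks
and marker discovery for pea aphid transcriptomes.

The pea aphid (*Acyrthosiphon pisum*) produces five discrete morphs —
winged/wingless asexual females (WF/UWF), wingless sexual females
(SF), and winged/wingless males (WM/UWM) — and crossing these with
three genotypes (F1, I18, BK11) yields 15 sample types. Given a gene ×
sample FPKM matrix over such a design, this package identifies:

* **expressed genes** (max FPKM > 0.5 across types);
* **type-specific genes** via the tau index,
  τ = Σᵢ(1 − xᵢ)/(N − 1) with xᵢ = vᵢ/maxⱼvⱼ, calling genes at
  τ > 0.8;
* **highly variable genes** (type-level SD > 6) and their
  **co-expression network**: rank-binned plug-in mutual information
  with Miller–Madow correction, pruned by the data-processing
  inequality (the weakest edge of every triangle is presumed
  indirect), with **core genes** defined as ≥ 20 partners at edge
  MI > 0.4 and mean partner MI > 0.4;
* **six expression patterns** by k-means on z-scored type profiles,
  plus hierarchical gene/sample ordering for heatmaps;
* **morph markers**: the top 30 genes by random-forest mean decrease
  in Gini impurity, with mean decrease in accuracy reported alongside.

Because the real libraries live in an external repository, the package
ships a synthetic-data generator (`sim_config()`,
`generate_dataset()`) that reproduces the design's statistical
structure — planted type-specific genes, latent-factor co-expression
modules with hubs, morph markers and a broad sex-biased signature —
together with a machine-readable truth record, so every stage can be
validated against known ground truth. See the methods vignette
(`vignettes/aphidcoex-methods.Rmd`) for the models, estimator details
and design choices.

## Worked example

The numbered scripts under `analysis/` run the study end-to-end and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # synthetic 15-type dataset + truth
Rscript analysis/02_specificity.R   # FPKM filter, tau, specific calls
Rscript analysis/03_network.R       # HVG, MI, DPI, core genes
Rscript analysis/04_patterns.R      # k-means patterns, heatmap order
Rscript analysis/05_markers.R       # random-forest marker ranking
```

`analysis/02_specificity.R` prints:

```
987 of 1000 genes expressed (max FPKM > 0.5 across types)
59 genes called type-specific at tau > 0.8
specific genes per morph of the peak type:
 WF UWF  SF  WM UWM
 12   9  13  12  13
planted recovery: 40/40 called specific, 40/40 with the correct peak type
```

987 of the 1000 simulated genes pass the expression filter; all 40
planted specific genes are recovered at τ > 0.8 with the correct peak
type (the remaining 19 calls are background genes whose simulated
profiles genuinely exceed the cutoff). `analysis/03_network.R` prints:

```
412 highly variable genes (SD > 6 across the 15 types)
MI network: 84666 pairs, 1974 edges survive DPI, 165 above the 0.5 display cutoff
0 core genes at degree >= 20 and mean MI > 0.4
top genes by post-DPI degree (planted hubs marked *):
  g0091* degree 17, mean MI 0.76
  g0066* degree 15, mean MI 0.87
  ...
planted hubs in the top-5 by degree: 5/5
```

The five planted hubs are exactly the five highest-degree genes after
DPI pruning, well clear of every other gene (non-hub degrees ≤ 5
here). No gene reaches the core-gene degree floor of 20 at this module
size — the vignette discusses why. `analysis/05_markers.R` recovers
all 30 planted markers in the top-30 Gini list.

The same stages are available as one call:

```r
library(aphidcoex)
ds  <- generate_dataset(sim_config(seed = 1))
res <- run_pipeline(pipeline_config(seed = 1), expr = ds$expr,
                    out_dir = "results/pipeline")
res$manifest$counts$n_expressed   # 987
```

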