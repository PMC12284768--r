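# gaeclust

Two-stage clustering of single-cell RNA-seq expression profiles:

1. **Cell–gene graph embedding.** Cells and genes become the two node sets
   of one composite graph. A row-normalized k-nearest-neighbour graph `C`
   connects cells; the column-normalized expression matrix `B` supplies
   cell–gene edges; a mixing weight λ balances the two:

   ```
   A = | λ·C        (1−λ)·Bᵀ |        X = [X2; X1],  X2 = Bᵀ·X1
       | (1−λ)·B    0        |
   ```

   where `X1` holds PCA features of the gene rows of `B`. A graph
   autoencoder — stacked convolutions
   `X⁽ˡ⁺¹⁾ = BatchNorm(LeakyReLU(A·X⁽ˡ⁾W⁽ˡ⁾))` with an inner-product decoder
   `σ(ZZᵀ)` trained on the Frobenius reconstruction residual `‖A − Â‖_F` —
   embeds every node; K-means on the cell rows of `Z` gives preliminary
   labels.

2. **Adversarial refinement.** The cells nearest each cluster centroid
   (the first 30% per cluster by default) become labelled training data for
   an auxiliary-classifier GAN: a conditional generator (1024 → 512 → 256,
   tanh output) synthesizes pseudo-cells, and a two-headed discriminator
   learns real/fake and the K cell classes simultaneously. Afterwards every
   cell is re-labelled by the argmax of the discriminator's class head.

The package also ships a seeded negative-binomial + dropout count simulator
with planted cell groups, the four standard external clustering metrics
(ARI, ACC with optimal label matching via Hungarian assignment, NMI, FMI),
a λ-sweep experiment, a stage-1 vs stage-2 ablation, and a small CLI. All
network training (forward, backward, Adam, schedules) is implemented
natively in R on BLAS-backed matrix algebra and is exactly reproducible per
seed.

## Worked example

```r
library(gaeclust)

# simulate 600 cells x 600 genes with 3 planted groups
sim <- simulate_counts(synth_config(seed = 11))

# run both stages with the benchmark configuration
res <- run_pipeline(sim$expression, benchmark_config(K = 3, seed = 11),
                    truth = sim$labels, verbose = TRUE)
#> preprocess: 600 x 600 -> 600 x 600
#> graph: 600 cell + 600 gene nodes, h = 50, lambda = 0.3
#> gae: loss 887.052 -> 714.762 over 100 epochs
#> confidence: 180 / 600 cells selected
#> gan: D loss 0.051, G loss 5.897 at epoch 30

res$metrics$refined$ari
#> [1] 1
res$metrics$initial$ari
#> [1] 1
```

With a strongly separated simulation (marker fold change 8, the simulator
default) both the preliminary K-means labels and the refined labels recover
the planted partition exactly (ARI = 1). At moderate separation
(`fold_change = 2`) stage one is imperfect and the refinement step's
contribution becomes visible:

```r
sim2 <- simulate_counts(synth_config(fold_change = 2, seed = 11))
res2 <- run_pipeline(sim2$expression, benchmark_config(K = 3, seed = 11),
                     truth = sim2$labels)
round(c(initial = res2$metrics$initial$ari,
        refined = res2$metrics$refined$ari), 3)
#> initial refined
#>   0.235   0.322
```

The ARI values (1 = perfect agreement with the planted groups, ≈ 0 =
chance) are what the λ-sweep (`lambda_sweep()`) and GAN ablation
(`gan_ablation()`) report per condition.

### Command line

```sh
Rscript inst/cli/gaeclust.R simulate --outdir sim --seed 1
Rscript inst/cli/gaeclust.R run --input sim --k 3 \
    --truth sim/truth_labels.csv --seed 1 --outdir out
Rscript inst/cli/gaeclust.R evaluate --predicted out/labels.csv \
    --truth sim/truth_labels.csv
```

## Vignette

`vignettes/gaeclust-methods.Rmd` documents the model, every tunable
parameter with its default and rationale, what the synthetic benchmark does
and does not emulate, and the numerical design choices.
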