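# cocost

Contrastive graph feature representation for spatial transcriptomics.

## What problem this solves

Spatially resolved transcriptomics (10x Visium and similar platforms)
measures a gene expression vector at each spot of a tissue section. When
a *target* section (e.g. carcinogen-exposed lung) is profiled alongside a
*background* section (e.g. normal lung), the dominant, high-variance
spatial structures — major tissue compartments, depth gradients — are
common to both, and variance-maximizing embeddings like PCA spend their
leading components on them. Small lesions such as hyperplasia or early
adenoma foci carry far less variance and are masked.

`cocost` learns a projection `W` (genes × p, orthonormal columns) whose
components maximize graph-smoothed target variance *minus* η times
graph-smoothed background variance. Each slice gets a kNN heat-kernel
affinity graph (on expression profiles or spot coordinates) and a graph
Laplacian filter `H = I − μ·L̄`; `W` solves the symmetric eigenproblem

    (Xᵗ Hₜ Xᵗᵀ − η · Xᵇ H_b Xᵇᵀ) w = λ w ,

keeping the eigenvectors with the p algebraically largest eigenvalues.
With μ = 0 this is exactly contrastive PCA; with η = 0 it is a
graph-smoothed PCA of the target alone. A kernelized variant
(`cocost_kernel`) solves the analogous generalized eigenproblem over
Gram matrices with a ridge ρ. See `vignette("cocost-methods")` for the
model, its guarantees, and all design decisions.

Intended users: computational biologists analyzing paired spatial slices
who want target-enriched spatial domains and the gene programs that
drive them (`top_genes`), with readers for 10x-style MTX and delimited
matrices, a paired-slice simulator with planted domains, clustering
helpers, and a command-line interface.

## Worked example

Simulate the default paired-slice scenario — a dominant shared band
(variance 2, 10 latent factors) masking a 25-spot target-only hotspot
(variance 0.2) — then fit and check that the hotspot is recovered:

```r
library(cocost)

cfg  <- synthetic_config(seed = 7)
pair <- generate_pair(cfg)

bg <- standardize_genes(normalize_counts(pair$background, "log_cpm"))
tg <- standardize_genes(normalize_counts(pair$target, "log_cpm"))

fit <- cocost(bg, tg, eta = 1, mu1 = 0.5, mu2 = 0.5, p = 5)
fit
#> cocost_model: 150 genes -> 5 components (eta = 1, mu1 = 0.5, mu2 = 0.5, k = 15, molecular)
#>   leading eigenvalues: 1200, 632.2, 568.3, 542.3, 452.1

head(top_genes(fit, component = 1), 5)
#>      gene    weight sign
#> 1 gene080 0.2539393    +
#> 2 gene069 0.2245686    +
#> 3 gene064 0.2137732    +
#> 4 gene063 0.2073375    +
#> 5 gene078 0.2069000    +

Z   <- cocost_transform(fit, tg, scale = "eigenvalue")
hot <- as.integer(pair$labels_t == 2)
evaluate_recovery(Z, hot, n_clusters = 2, seed = 1)
#> $ari
#> [1] 1
#> $nmi
#> [1] 1
```

The top component's heaviest loadings are exactly the planted hotspot
program genes (the simulator puts that program on genes 61–80), and
k-means on the eigenvalue-scaled components separates the 25 hotspot
spots perfectly (adjusted Rand index 1). The identical protocol applied
to a PCA of the target alone stays at chance:

```r
pca <- cocost(tg, tg, eta = 0, mu1 = 0, mu2 = 0, p = 5)
Zp  <- cocost_transform(pca, tg, scale = "eigenvalue")
evaluate_recovery(Zp, hot, n_clusters = 2, seed = 1)
#> $ari
#> [1] -0.04635046
#> $nmi
#> [1] 0.06045634
```

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cocost.R", package = "cocost"))')
Rscript "$CLI" synth     --config scenario.yaml --out data/
Rscript "$CLI" fit       --config run.yaml      --out fit/
Rscript "$CLI" transform --model fit/model --matrix m.tsv --coords c.tsv --out Z.tsv
Rscript "$CLI" cluster   --embedding fit/Zt.tsv --n-clusters 6 --out domains.tsv
```

Every run writes a fully resolved parameter echo
(`config_resolved.yaml`) beside its outputs; identical config + seed
gives byte-identical files.

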