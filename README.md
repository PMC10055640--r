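# bspsvg

Detection of **spatially variable genes (SVGs)** in 2D and 3D spatially
resolved transcriptomics with the **big–small patch (BSP)** statistic — a
non-parametric, dimension-agnostic variance-ratio test — together with
labeled 2D/3D simulation benchmarks, a Moran's I baseline, and
power-versus-FDR evaluation. It is aimed at anyone analyzing spot- or
cell-level SRT data (Visium-style arrays, seqFISH/MERFISH panels, stacked
3D sections) who wants SVG calls without fitting a spatial covariance
model per gene.

## The statistic

Given M spots with coordinates and N genes, expression is min–max
normalized per gene and coordinates are rescaled by the spot density
(`(M/ΔXΔY)^(1/2)` in 2D, cube root in 3D) so typical spot spacing ≈ 1
unit. For each spot *i* and radius *D*, the patch *S_i* holds the spots
within distance *D*, with local mean

> X̂ᵢ(j) = Σ_{l∈Sᵢ} X_l(j) / |Sᵢ|

and σ_D(j) = varᵢ X̂ᵢ(j). The BSP score contrasts a big radius D₂ = 3
against a small radius D₁ = 1:

> r(j) = w_j · σ_{D₂}(j) / σ_{D₁}(j),  w_j = σ²_j / max_k σ²_k.

Spatially random genes lose local-mean variance fast as the patch grows;
coherently patterned genes keep it, giving large scores. Scores across
genes are rescaled into (0,1) and fitted with a two-parameter beta by
maximum likelihood; each gene's p-value is the fitted upper-tail
probability at its score. Small gene panels fall back to a null fitted on
permuted genes. See `vignette("bsp-methods")` for the full account.

## Worked example

Simulate a labeled 260-spot replicate (100 patterned genes at fold
change 4, log-scale noise 0.5, plus 900 spot-permuted nulls), run the
pipeline and measure power:

```r
library(bspsvg)
rep <- simulate_replicate_2d(sim2d_config(
  n_svg = 100, n_null = 900, fc = 4, tau = 0.5, seed = 42))
res <- run_bsp(rep$dataset, bsp_config(), verbose = TRUE)
#> BSP: 260 spots, 1000 genes; mean patch sizes 4 (D1=1) / 24.3 (D2=3)
#> BSP: 69/1000 genes called SVG at alpha = 0.05 (raw p)
head(res[order(res$p_value), c("gene_id", "score", "p_value")], 3)
#>    gene_id     score      p_value
#> 35   svg35 0.6295029 2.363929e-51
#> 86   svg86 0.6144270 1.303336e-09
#> 91   svg91 0.6015648 4.249118e-08
curve <- power_at_fdr(res$p_value, rep$truth$label)
curve[curve$fdr %in% c(0.01, 0.05, 0.1), c("fdr", "tpr")]
#>     fdr  tpr
#> 2  0.01 0.90
#> 6  0.05 0.97
#> 11 0.10 0.98
```

The top-ranked genes are all true SVGs; at a realized false discovery
rate of 5% the method recovers 97% of the patterned genes in this
replicate. 3D data works identically — a three-column coordinate matrix
switches every step to volumes and spheres (`simulate_replicate_3d()`
generates stacked-section benchmarks; `compare_power_3d()` pits BSP
against the Moran's I baseline).

Shell use, via the thin wrapper in `inst/scripts/bsp.R`:

```sh
Rscript inst/scripts/bsp.R simulate --mode 3d --pattern I --r 2.0 --fc 2.5 --sigma 1 --seed 7 --out-dir out
Rscript inst/scripts/bsp.R run --expr out/replicate_expression.tsv --coords out/replicate_coords.tsv --out out/results.tsv
Rscript inst/scripts/bsp.R evaluate --results out/results.tsv --truth out/replicate_truth.tsv --out out/power.tsv
```

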