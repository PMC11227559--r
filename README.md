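# dpmerge

Directional P-value merging for multi-omics gene prioritisation and
pathway enrichment.

## The problem

Joint analyses of transcriptomics, proteomics, epigenomics or survival
data produce, per gene, one P-value and one effect direction per dataset.
Combining the P-values (Fisher, Brown, Stouffer) prioritises genes with
evidence in several datasets, but ignores whether the directions make
joint sense — a gene upregulated at the transcript level and downregulated
at the protein level is a different finding from one upregulated in both.
`dpmerge` is for analysts who already have well-calibrated per-dataset
P-values and fold-change/hazard-ratio/correlation signs and want to fuse
them under an explicit directional hypothesis.

## The statistic

The user declares a *constraints vector* (CV) `e = (e_1, ..., e_k)`, one
sign per dataset (`0` = directionless). With observed unit signs `o_i` and
P-values `P_i`, the directional score of a gene is

    X_DPM = -2 * ( -| Σ_directional ln(P_i) o_i e_i | + Σ_directionless ln(P_i) )

Directional agreements accumulate log-evidence exactly as in Fisher's
method; conflicts cancel inside the absolute value and can only reduce
significance. The absolute value makes the CV globally sign invariant
(`[+1,-1] ≡ [-1,+1]`). The merged P-value refers `X_DPM / c` to a
chi-square with `k'` degrees of freedom, where `c` and `k'` are estimated
from the covariation of the input columns by the empirical Brown method,
so dependent datasets are merged conservatively. Fisher, empirical Brown,
and directional Stouffer/Strube combinations are included for reference,
and a ranked hypergeometric enrichment step turns the merged list into
pathway calls with per-dataset evidence attribution and enrichment-map
tables.

## Worked example

Knockdown (kd) and overexpression (oe) experiments of a regulator should
move its targets in opposite directions, encoded as `cv = c(-1, 1)`:

```r
library(dpmerge)
p <- matrix(c(2.8e-5, 1e-3, 0.01, 0.055,
              1.1e-4, 4e-3, 0.002, 0.41), ncol = 2,
            dimnames = list(c("CPED1","NEGR1","FAT1","STC1"), c("kd","oe")))
d <- matrix(c( 1,  1, -1,  1,
              -1,  1,  1, -1), ncol = 2, dimnames = dimnames(p))
fit <- dpm_merge(p, d, cv = c(-1, 1))
fit
#> Merged gene list (dpm method): 4 genes
#>   null: scaled chi-square, c = 0.6680, k' = 5.9880
#>   gene_id     score     merged_p
#> 1   CPED1 39.196672 8.228546e-11
#> 2   NEGR1  2.772589 6.548902e-01
#> 3    FAT1 21.639557 1.355122e-05
#> 4    STC1  7.584040 7.757961e-02
```

`CPED1` (up in kd, down in oe — compliant) keeps its full combined
evidence, identical to the non-directional Brown merge. `NEGR1` is
significant in both datasets but in the *same* direction, contradicting
the constraints: its Brown P-value of `1.6e-06` is penalised to `0.65`.
The null parameters here come from only four genes; in practice they are
estimated across the whole gene matrix.

At benchmark scale, merging two simulated signal-bearing datasets
(10,000 genes, ~26% of input P-values below 0.05) under full directional
agreement:

```r
cfg <- simulation_config(distributions = "exponential_like", seed = 1)
pm  <- simulate_pvalue_sets(cfg)
dm  <- assign_directions(cfg)
summary(dpm_merge(pm, dm$directions, dm$cv))
#> Merged gene list (dpm method), 10000 genes
#>   null: scaled chi-square, c = 0.9983, k' = 4.0068
#>   significant merged P-values:
#>     P < 0.2     7001  (70.01%)
#>     P < 0.1     5355  (53.55%)
#>     P < 0.05    3845  (38.45%)
#>     P < 0.01    1686  (16.86%)
```

About 39% of merged P-values fall below 0.05 — more than either input
alone, because both datasets contribute independent evidence. Downstream,
`run_enrichment()` tests a GMT gene-set library against the ranked merged
list and `build_enrichment_map()` exports node/edge tables; see the
vignette in `vignettes/directional-merging.Rmd` for the model, the
simulation design and the numerical conventions.

A thin command-line wrapper ships in `inst/scripts/dpmerge`
(`merge`, `enrich` and `benchmark` subcommands over TSV/GMT files).

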