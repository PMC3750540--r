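# geninter

Pairwise genotype–survival interaction scan: find pairs of genetic markers
(SNPs) whose genotype *combinations* have a synergistic effect on patient
survival, even when neither marker shows an effect on its own.

Single-marker survival scans (logrank tests) miss such pairs, and applying
the logrank test to all marker pairs runs into its known weaknesses when
the number of groups is large (up to nine genotype combinations per pair,
frequently crossing curves) and when cohorts are large.  `geninter`
instead ranks every pair by a normalized measure of how strongly the
combination separates the groups' Kaplan–Meier curves, and calibrates
significance by simulation.

## The statistic

For each marker pair, samples are grouped by genotype combination
(`AA/AB/BB` × `AA/AB/BB`) and one Kaplan–Meier curve is estimated per
observed group on a shared time grid.  Then:

1. **Area distance** between curves $c_j, c_k$ on the grid
   $t_1 = 0 < \dots < t_n$ (months):
   $D(c_j,c_k) = \sum_{i=2}^{n} (t_i - t_{i-1})\,|S_{c_j}(t_{i-1}) - S_{c_k}(t_{i-1})|$.
2. **Complete-linkage clustering** of the curves using these distances
   gives a dendrogram with leaf heights $H$ and last-common-ancestor
   heights $H_{max}$.
3. **Equivalence classes**: curves sharing a genotype at one marker are
   compared through the cluster-tree distance
   $d = |H_{max} - H_1 - H_2|$ (with the degenerate cases
   $|H_{max}-H_1|$, $|H_{max}-H_2|$, $0$ when heights coincide).  The
   partial rank $R_{M_j}$ of marker $j$ is the largest within-class
   distance, and the pair's rank is
   $\bar R = (R_{M_1} + R_{M_2}) / (2\,t_n) \in [0,1]$.

Ranks are scored against a gamma null distribution
($k=\hat\mu^2/\hat\sigma^2$, $\theta=\hat\sigma^2/\hat\mu$) fitted to the
ranks of a fully null simulated cohort of matching size, with
Benjamini–Hochberg correction for desk-scale scans.  The package also
ships the genotype–survival cohort simulator with known ground truth
(uniform null survival up to 360 months, exponential 22.5-month survival
for double-rare-homozygote carriers of affected pairs, 20% censoring)
and an ROC/operating-point harness comparing the rank scan to the
multi-group logrank comparator.

## Worked example

```r
library(geninter)

# six markers with minor allele frequency 0.35; one synergistic pair
maf <- rep(0.35, 6)
freqs <- cbind(AA = (1 - maf)^2, AB = 2 * maf * (1 - maf), BB = maf^2)
cohort <- simulate_cohort(sim_config(1000, genotype_freqs = freqs,
                                     n_affected_pairs = 1, seed = 7001))
cohort$truth
#>   marker_a marker_b
#> 1     M001     M004

null <- calibrate_null(1000, n_markers = 30, seed = 2)
fit <- geninter(cohort$genotypes, cohort$survival, null = null)
fit
#> Geninter pairwise survival-interaction scan
#>   6 markers, 1000 samples, 15 pair(s) reported
#>   rank normalization t_n = 358.06 months (cohort)
#>
#> Top pairs:
#>   marker_a marker_b   rank p_value fdr_p n_groups n_samples
#> 1     M001     M004 0.4429 0.09385 0.976        9      1000
#> 2     M001     M002 0.2510 0.31801 0.976        9      1000
#> 3     M001     M005 0.2180 0.38637 0.976        9      1000
#> 4     M002     M006 0.1557 0.54757 0.976        9      1000
#> 5     M003     M005 0.1423 0.58749 0.976        9      1000

single_marker_scan(cohort$genotypes, cohort$survival)[c(1, 4), ]
#>   marker chi_square df p_value fdr_p n_groups
#> 1   M001     0.0797  2   0.961 0.961        3
#> 4   M004     2.9776  2   0.226 0.451        3
```

The induced pair (M001, M004) tops the list with a rank of 0.44: its
genotype combinations separate the survival curves by 44% of the maximal
possible area within the follow-up horizon, while neither marker shows an
individual logrank effect (p = 0.96 and 0.23).  `p_value` is the upper
tail of the simulation-calibrated gamma null; at this small demonstration
size (15 pairs) the FDR-corrected values remain large.

A shell-level interface covering the same workflow (simulate / calibrate /
scan / roc) is available as `exec/geninter`.

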