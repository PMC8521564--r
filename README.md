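# recureig

Complexity analysis of movement time series by **recurrence eigenvalues**:
the largest eigenvalue of a convolutional fuzzy recurrence plot. The
package targets researchers in movement neuroscience and nonlinear
physiology who need a scalar complexity marker for cohorts of short scalar
series — *C. elegans* eigenworm amplitude traces (wild type vs mutant
strains) and human gait swing intervals (healthy controls vs Parkinson's,
Huntington's and ALS patients) are the two built-in case-study profiles.

## The statistic

For a series $t_1,\dots,t_N$:

1. **Embed**: $\mathbf{x}_i = (t_i, t_{i+\tau}, \dots, t_{i+(m-1)\tau})$,
   giving $M = N-(m-1)\tau$ phase-space vectors.
2. **Cluster**: fuzzy $c$-means memberships $\mu_{ij}$ (rows sum to 1).
3. **Fuzzy recurrence plot**: $\mu_{ik} = \max_j \min(\mu_{ij}, \mu_{kj})$,
   a symmetric $M \times M$ relation with unit diagonal.
4. **Reduce**: iterate (3×3 sharpening convolution → ReLU → 2×2 max
   pooling) until the matrix is $n \times n$ (default $2 \times 2$);
   each pass maps side $s \mapsto \lceil s/2 \rceil$.
5. **Report** $\lambda_{\max}$ of the final matrix.

Regular dynamics concentrate recurrence mass in coherent blocks; irregular
dynamics fragment it. $\lambda_{\max}$ summarizes the texture that survives
the multiscale reduction. A sample-entropy baseline, cohort statistics
(one-sample $t$ p-values, 95%/99% $t$-intervals) and UPGMA dendrograms over
cohort distances complete the published analysis surface. See the methods
vignette (`vignettes/recurrence-eigenvalues.Rmd`) for conventions and
design rationale.

## Worked example

```r
library(recureig)

# two regular and two noise-corrupted harmonic series, length 900
tab <- generate_synthetic_cohorts(
  spec = list(cohort_spec("regular",   noise_sd = 0.05, count = 2, length = 900),
              cohort_spec("irregular", noise_sd = 0.5,  count = 2, length = 900)),
  seed = 42)

for (i in seq_along(tab$values)) {
  r  <- recurrence_eigenvalue(tab$values[[i]], m = 1, tau = 1, c = 3, n = 2,
                              seed = 42 + i)
  se <- sample_entropy(tab$values[[i]], m = 2, delta_factor = 0.2)
  cat(sprintf("%-9s lambda_max = %9.1f   SampEn = %.4f\n",
              tab$label[i], r$lambda_max, se$value))
}
#> regular   lambda_max =  769380.3   SampEn = 0.4067
#> regular   lambda_max =  769991.4   SampEn = 0.3954
#> irregular lambda_max =  280038.4   SampEn = 1.8190
#> irregular lambda_max =  270142.6   SampEn = 1.7836
```

The noisy series drop to less than half the eigenvalue of the regular ones
(fragmented recurrence structure), while sample entropy rises — the two
statistics view the same regularity axis from opposite ends.
`lambda_max` is a relative measure: compare series only within one
configuration (same `m`, `c`, `n`, padding).

Cohort-level statistics reproduce published summary rows directly from
printed moments:

```r
summary_from_moments(5.9875, 1.0132, 16, "HC (LSI)")
#> HC (LSI): n = 16, mean = 5.9875 +/- 1.0132, p = 2.7668e-13
#>   95% CI (5.4476, 6.5274); 99% CI (5.2411, 6.7339)

lsi <- upgma(cohort_distance_matrix(list(
  summary_from_moments(5.9875, 1.0132, 16, "HC"),
  summary_from_moments(6.2174, 0.8175, 15, "PD"),
  summary_from_moments(6.4782, 0.9651, 20, "HD"),
  summary_from_moments(6.3764, 1.0848, 13, "ALS"))))
lsi
#> UPGMA tree: (HC:0.1849166667,(PD:0.10495,(HD:0.0509,ALS:0.0509):0.05405):0.07996666667);
```

HD and ALS join first and the healthy controls attach outermost — the
reported gait tree topology.

Batch runs go through `run_pipeline()` (commands `eig`, `sampen`, `cohort`,
`tree`, `synth`, `all`) or the thin CLI wrapper `inst/cli/recur-eig`;
outputs are per-series CSV, cohort-summary CSV, newick trees and a JSON run
manifest.

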