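---
title: "Recurrence eigenvalues of movement time series: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence eigenvalues of movement time series: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistic

`recureig` quantifies the complexity of a scalar movement time series — a
worm's first eigenworm amplitude, a patient's per-stride swing interval — by
a single number: the largest eigenvalue $\lambda_{\max}$ of a small matrix
distilled from the series' recurrence structure. The pipeline is

1. **Time-delay embedding.** A series $t_1,\dots,t_N$ is reconstructed as
   phase-space vectors
   $\mathbf{x}_i = (t_i, t_{i+\tau}, \dots, t_{i+(m-1)\tau})$,
   $i = 1,\dots,M$ with $M = N - (m-1)\tau$. The embedding dimension $m$ and
   delay $\tau$ are fixed by the analyst, not estimated: $m = 4$ for
   eigenworm traces (the four principal worm-shape modes), $m = 1$ for the
   univariate gait signals, $\tau = 1$ throughout.

2. **Fuzzy c-means (FCM).** The $M$ vectors are partitioned into $c$
   clusters with graded memberships $\mu_{ij} \in [0,1]$,
   $\sum_j \mu_{ij} = 1$. We use the standard alternating optimization with
   Euclidean distances and fuzzifier 2.

3. **Fuzzy recurrence plot (FRP).** Memberships are composed into a fuzzy
   similarity relation by the max–min rule
   $\mu_{ik} = \max_j \min(\mu_{ij}, \mu_{kj})$, with reflexivity
   ($\mu_{ii}=1$) imposed on the diagonal. The result is an $M \times M$
   symmetric matrix in $[0,1]$ — a grayscale recurrence image.

4. **Convolutional reduction.** While the matrix is larger than the target
   size $n$ (default 2), one pass of: convolution with the $3\times3$
   sharpening kernel
   $w = \begin{pmatrix} 0&-1&0\\ -1&5&-1\\ 0&-1&0 \end{pmatrix}$,
   rectification ($\max(0,\cdot)$), and $2\times2$/stride-2 max pooling.
   Each pass halves the side length (ceiling), so an $897$-sided FRP
   reaches $2 \times 2$ through
   $897 \to 449 \to 225 \to 113 \to 57 \to 29 \to 15 \to 8 \to 4 \to 2$.

5. **Eigenvalue.** $\lambda_{\max}$ of the final symmetric nonnegative
   $n \times n$ matrix (for $n=2$ the closed form
   $(a+d)/2 + \sqrt{((a-d)/2)^2 + b^2}$) is the complexity statistic.

The intuition: regular dynamics concentrate recurrence mass into large
coherent blocks, while irregular dynamics fragment it; the iterated
sharpen–rectify–pool loop summarizes that texture across scales, and the
leading eigenvalue measures the total "recurrence energy" that survives.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `m` (embedding) | 4 (worms), 1 (1-D signals) | samples | number of latent coordinates; the worm value mirrors the four principal posture modes |
| `tau` | 1 | samples | both case studies use unit delay |
| `c` (clusters) | 3 | – | 3, 5, 7 all behave consistently; 3 is the smallest stable choice |
| `fuzzifier` | 2.0 | – | the standard FCM exponent |
| FCM `tol` / `max_iter` | 1e-5 / 300 | – | stop when max absolute membership change falls below `tol` |
| `n` (final size) | 2 | – | deepest reduction; the eigenvalue then has a closed form |
| pooling `window`/`stride` | 2 / 2 | – | the standard halving choice; ceil mode lands exactly on `n = 2` from any side |
| `padding` | `"replicate"` | – | see "Numerical choices" |
| SampEn `m` | 4 (worms), 2 (gait) | samples | gait at `m = 1` produces infinite values (no extended template matches) |
| SampEn `delta_factor` | 0.2 (worms), 0.3 (gait) | × series SD | the conventional tolerance band 0.1–0.3σ |

## Numerical choices

**Convolution border.** The reduction keeps the matrix size fixed during
convolution ("same" output) so that only pooling changes the size and the
trajectory is predictable. The border needs a convention. With zero padding
the unit-sum sharpening kernel turns every matrix border into an artificial
edge: a corner of an all-ones matrix maps to 3, and because max pooling
propagates maxima, the amplification compounds every pass —
$\lambda_{\max}$ then grows geometrically with the number of passes, i.e.
with the input size, and the artifact swamps the data signal. Replicating
the nearest edge value instead makes constant regions exactly invariant
under the kernel (its entries sum to 1) and removes the border artifact
while preserving symmetry. The published per-cohort eigenvalue magnitudes
are nearly independent of input side (897-point worm embeddings vs 120-point
gait records), which is only consistent with a border convention that does
not amplify; `recureig` therefore defaults to `padding = "replicate"` and
keeps `padding = "zero"` available for comparison.

**Interior growth.** Even with a neutral border, genuinely sharp texture
(e.g. the unit diagonal cutting through low-membership background) is
amplified by sharpening and retained by max pooling, so $\lambda_{\max}$ is
a relative statistic: comparable across series analyzed under one
configuration, not an absolute scale.

**FCM initialization and determinism.** The membership matrix is drawn from
a uniform simplex (normalized exponentials) under a user-supplied seed;
every result is bitwise reproducible given the seed, and in practice
converged eigenvalues are insensitive to the seed (across restarts the
spread is orders of magnitude below between-series variation). Points that
coincide exactly with a cluster center get crisp membership split uniformly
across all coincident centers; fully degenerate inputs (all points
identical) converge to uniform memberships $1/c$ with a warning, and their
FRP has off-diagonal entries $1/c$.

**Ties and degenerate cohorts.** UPGMA resolves tied merge distances by
first index (the `hclust` convention). Cohorts with zero variance produce
zero-width confidence intervals and are flagged `degenerate`; infinite
sample entropies abort cohort averaging with an error — the remedy is a
longer template (`m = 2`), as in the gait analysis.

**Sample entropy conventions.** Chebyshev distance; both template lengths
counted over the shared start indices $1,\dots,N-m\tau$, so every
$(m{+}1)$-match is an $m$-match and SampEn $\ge 0$; self-matches excluded;
$\sigma$ computed with the $n-1$ denominator on the analyzed (preprocessed)
series; `A = 0` yields an explicit `Inf`, serialized as `"inf"`. Note that
SampEn is *not* monotone in the tolerance $\delta$ — raising $\delta$ can
add short-template matches without extended matches — only the match counts
are monotone.

## Cohort statistics

Per-cohort $\lambda_{\max}$ or SampEn values are summarized as mean,
standard deviation ($n-1$), a two-sided one-sample Student-$t$ test of the
mean against zero, and $t$-based confidence intervals
$\bar{x} \pm t_{n-1,(1+\ell)/2}\, s/\sqrt{n}$ for $\ell = 0.95, 0.99$. The
$t$ identification (not normal quantiles) reproduces the published gait
intervals, which at $n = 16$ require $t_{15,0.975} = 2.131$ rather than
1.96. `summary_from_moments()` applies the same formulas to printed
mean/SD/$n$ rows so published tables can be checked without raw data.
Dendrograms over cohorts use UPGMA on the absolute difference of cohort
means — the simplest distance consistent with the reported tree
descriptions; it is a configuration point, not a claim that no other
distance was used.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_cohorts()` produces labeled cohorts of scalar series
spanning the regularity axis the statistic targets: harmonic oscillations
with additive Gaussian noise (default: 30 "regular" series at noise SD 0.05
and 30 "irregular" at 0.5, length 900, random phases), plus AR(1) and
chaotic logistic-map families. These emulate the *shape* of the study —
labeled cohorts of equal-length scalar series with controllable
irregularity — but not real movement data: eigenworm traces have
autocorrelated, non-stationary amplitude modulation, and gait intervals are
positive, slowly drifting and artifact-prone. Passing the synthetic
discrimination test therefore demonstrates that the pipeline detects
regularity differences end to end, not that it reproduces any particular
organism's numbers. Under the 1-D profile the noisy class yields the
*smaller* eigenvalue (fragmented memberships dilute recurrence mass before
amplification); this direction is frozen as a regression expectation.

The synthetic study is analyzed with the `synthetic` profile ($m = 1$),
following the same rule as the gait case: the generator's series are
univariate signals without a known multi-mode latent structure, so the 1-D
embedding is the appropriate one (under the 4-D worm profile the class
effect, while present, is weak relative to between-series variation).

## Problem sizes

The test suite runs the full pipeline at the case-study geometry (series of
length 900, FRPs up to $897\times897$, reductions to $2\times2$) and the
complete synthetic two-class study (60 series of length 900); brute-force
oracle comparisons use matrices up to $12\times12$ and series up to length
50, where exhaustive enumeration is exact. The whole suite completes in
under a minute on one CPU.

## Known limitations

- $\lambda_{\max}$ magnitudes depend on the reduction conventions (padding,
  pooling geometry); comparisons are meaningful only within one
  configuration.
- No automatic selection of $m$, $\tau$ or $c$; the package deliberately
  fixes them per profile.
- No recurrence quantification analysis (determinism, laminarity, …) and no
  classifier; the package stops at the statistic and its cohort-level
  summaries.
- Readers cover the two public archive layouts (label-prefixed series
  tables; whitespace-delimited gait columns) but the package never
  downloads data; paths are user-supplied.
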