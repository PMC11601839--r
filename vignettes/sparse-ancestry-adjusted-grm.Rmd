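---
title: "Sparse ancestry-adjusted relatedness and mixed-model association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse ancestry-adjusted relatedness and mixed-model association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sparsekin)
```

## Model and assumptions

`sparsekin` targets quantitative-trait association in cohorts that mix
several ancestral populations and contain related individuals.  The
working model for a tested variant with genotype vector $G$ is

$$ Y = X\beta + G\gamma + b + \varepsilon, \qquad
   b \sim N(0, \tau^2 \Psi), \quad \varepsilon \sim N(0, \sigma^2 I), $$

where $X$ contains the intercept and the top ancestry PCs, and $\Psi$ is
the block-diagonal sparse ancestry-adjusted GRM.  The modeling premise is
a separation of scales: population structure is *finite-rank* (a handful
of ancestral populations mixed per individual), so it belongs in the
fixed effects through PCs, while family relatedness is *sparse but
high-rank* (many small blocks, growing in number with $N$), so it belongs
in the random-effect covariance.  Because the GRM's allele frequencies
are individualized by ancestry before correlation, its entries estimate
relatedness *conditional on* ancestry, and the two terms do not compete
for the same signal.  An unadjusted GRM in the same cohort puts large
positive values on all same-population pairs: thresholding it yields
population blocks, not families, with consequences for both sparsity and
calibration that the package's comparison utilities
(`compute_threshold_grm()`, `compare_grms()`) make measurable.

Assumptions worth keeping in mind: hard-call autosomal genotypes;
structure expressible by the top $K$ PCs (the per-variant frequency model
is linear in the PCs); quantitative phenotypes with approximately
Gaussian residuals after rank-inverse normalization; relatedness confined
to blocks small enough that per-block dense operations are cheap.

## The pipeline and its tunable parameters

1. **Related pairs.**  Default import of KING IBD-segment output, or the
   built-in exhaustive KING-robust sweep (`infer_related_pairs()`), which
   is quadratic in $N$ and intended for moderate cohorts.  `max_degree`
   (default 4) maps to the kinship cutoff $2^{-(d+1.5)}$; the default
   keeps pairs with kinship above $2^{-5.5} \approx 0.0221$.  No MAF or
   LD filtering is applied at this stage.  The built-in estimator's noise
   scales as $1/\sqrt{M}$; with fewer than roughly 20--30k variants,
   sporadic false pairs appear at the 4th-degree cutoff, so pair
   inference should use the largest variant set available.
2. **Ancestry divergence.**  `tau_k` (default $2^{-5.5}$) is the negative
   kinship bound below which a pair is called ancestrally divergent;
   `j_sub` (default 10,000) subsamples variants for this step.  One
   global subsample is drawn rather than per-pair resampling — cheaper,
   and the two choices agree in distribution under missing-completely-at-
   random genotypes.
3. **Unrelated extraction.**  Deterministic given the graph, the scores
   and a seed; ties beyond (relative count, divergence) are broken
   uniformly at random with the recorded seed, and the removal order is
   returned.
4. **Randomized PCA.**  `K` PCs (default 10), sketch width `L = 2K`,
   `R_iter = 10` power iterations, `C` variant blocks (a pure work
   partition; results are block-count invariant to floating-point
   rounding).  Standardization uses allele frequencies estimated in the
   unrelated set only; missing genotypes are mean-imputed (zero after
   centering); monomorphic-in-U variants are dropped.  The iterates are
   used exactly as produced (no intermediate re-orthogonalization): at
   ancestry-scale spectral gaps and $R = 10$, the aggregated sketch is
   numerically adequate, which the exact-SVD oracle test confirms.
5. **Score scale.**  The unrelated-set scores are returned as
   $P_U D$ (left singular vectors scaled by singular values — the usual
   PCA score convention), because the loading-norm projection
   $P_R = \tilde Z_R \tilde Z_U^\top P_U / \lVert\cdot\rVert$ used for
   related subjects lands exactly on that scale: a related subject whose
   genotypes duplicate an unrelated subject's receives identical scores.
   Mixing orthonormal scores for $U$ with norm-projected scores for $R$
   would put the two groups on scales differing by each PC's singular
   value and corrupt every downstream regression.
6. **Adjusted frequencies and the GRM.**  Per-variant OLS of dosage on
   (intercept + PCs), trained on the unrelated set (consistent with how
   the frequencies and PCs themselves were estimated; an option trains on
   all samples).  Fitted frequencies are clipped to
   $[\epsilon, 1-\epsilon]$ with $\epsilon = \max(10^{-4}, 1/(4N_{fit}))$,
   keeping Bernoulli variances away from zero.  The GRM is reported on
   the conventional GRM scale — twice the ancestry-adjusted kinship
   estimator — so the diagonal is $\approx 1$, full sibs are
   $\approx 0.5$, and $\tau^2$ reads directly as the familial variance
   share.  Self-relatedness is estimated for every subject (capturing
   inbreeding); `unit_diagonal = TRUE` forces exact ones.  Sparsity is
   purely structural (block membership); no magnitude thresholding is
   applied inside blocks.  Numerator and denominator are accumulated over
   variant chunks, so results are exactly chunk-size invariant.

## Null model fitting and score tests

AI-REML maximizes the restricted likelihood
$\ell_R = -\tfrac12(\log|\Sigma| + \log|X^\top\Sigma^{-1}X| + Y^\top P Y)$
with $\Sigma = \sigma^2 I + \tau^2\Psi$ and
$P = \Sigma^{-1} - \Sigma^{-1}X(X^\top\Sigma^{-1}X)^{-1}X^\top\Sigma^{-1}$.
Because $\Sigma$ inherits $\Psi$'s block structure, each block is
eigendecomposed once per GRM; every solve, trace and log-determinant then
follows exactly from the eigenvalues at any $(\sigma^2, \tau^2)$, which
makes refitting many phenotypes on one GRM nearly free.  Numerical
policy: initialization at $\mathrm{var}(Y)/2$ each; Newton steps
$\theta \leftarrow \theta + \mathrm{AI}^{-1}\nabla$ with step-halving (up
to 10) on likelihood decrease; proposals clamped at
$10^{-8}\,\mathrm{var}(Y)$; convergence at relative change $<10^{-6}$ or
$|\Delta\ell_R| < 10^{-8}$; if $\tau^2$ sits on the clamp for three
consecutive iterations the model is refitted with $\tau^2 \equiv 0$
(closed form) and flagged — small-sample REML can place the optimum on
the boundary even when the generating $\tau^2$ is positive.

The genome-wide scan uses $T = G^\top PY$ with the variance-ratio
approximation: the null variance $G^\top PG$ is replaced by
$r \cdot \lVert \mathrm{resid}_X(G)\rVert^2 / (\hat\sigma^2+\hat\tau^2)$,
the "flat" variance computed as if subjects were independent with the
same total variance, times the mean exact/flat ratio $r$ over 100
calibration variants (seeded random draw, minor allele count $\ge 20$).
Putting the fitted $\tau^2$ into the flat variance keeps the ratio near 1
in mostly-unrelated cohorts; the alternative convention (residual
variance only) is available via `flat_scale = "sigma2"`.  Exact
per-variant variances (`vr = NULL`) remain available for small panels.

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws ancestral frequencies uniformly on
[0.05, 0.5], population frequencies from the Balding–Nichols Beta
distribution parameterized by per-population (optionally per-variant)
drift, admixture proportions from a Dirichlet (default concentration 0.1:
mostly unadmixed individuals with occasional strong admixture, one draw
per family so relatives share ancestry), founder genotypes binomially,
and non-founders by Mendelian gene dropping.  Variants are split into 22
contiguous "autosomes"; odd chromosomes host the polygenic background and
the GRM/PC panel, even chromosomes are reserved for candidate tests, so
test variants are independent of the phenotype given ancestry and
pedigree.  `simulate_phenotype()` rescales each component (ancestry =
random PC combination; polygenic; single SNP; environment) so its
in-sample variance share equals the target exactly — heritability checks
are deterministic by construction.

Deliberate idealizations: no linkage disequilibrium beyond family
co-inheritance (every variant segregates independently), no genotyping
error, hard calls only, no X chromosome, drift without selection, and an
ancestry effect constructed from the *estimated* PCs (mirroring the
pipeline's own adjustment, rather than adding structure the PCs cannot
see).  Consequently, passing calibration here demonstrates correct
handling of population stratification and familial covariance, not
robustness to LD-induced test dependence, imputation dosage error, or
ancestry effects orthogonal to the top PCs.

## Study conditions used by the heavier checks

The calibration cohort is 2,000 samples (300 sib pairs, 50 trios —
about 37% of samples in a related pair), 3 populations, per-variant drift
$F \sim U(0.02, 0.5)$, 44,000 variants; phenotypes carry ancestry share
0.2 and polygenic share 0.4 over 20,000 odd-chromosome common variants
(a polygenic pool much larger than $N$ matters: with few background SNPs
the finite-pool polygenic covariance has a skewed spectrum that a
two-component model cannot absorb, and the statistic tails deflate).
Simulated phenotypes are Gaussian by construction and are analysed
untransformed — rank-inverse normalization is pre-processing for real,
non-normal traits, and re-normalizing an already-normal sample of this
size visibly truncates the extreme statistic tails.  Null tests pool the
even-chromosome panel over 100 phenotype replicates (about $2 \times
10^6$ tests); statistics of strongly PC-correlated variants are mutually
correlated within a phenotype, so many replicates are needed before the
pooled type-I estimator approaches its binomial precision.  Power comparisons add a causal-SNP
share of 0.01 and stratify candidates by the $R^2$ of dosage on the PCs
(cuts 0.2/0.4/0.6), with false-positive-rate-adjusted power at
$\alpha = 10^{-4}$ computed from each model's own null pool.  The
variance-component recovery experiment uses 4,000 samples with 800 sib
pairs and $(\sigma^2, \tau^2) = (0.6, 0.4)$.  These sizes were chosen as
the smallest at which the estimators' asymptotic behavior is visible;
the same code runs unchanged at larger sizes.

## Degenerate inputs and tie-breaks

Monomorphic variants are removed in QC and (if monomorphic only within
the unrelated set) before PCA; constant variants are "excluded" from
PC-$R^2$ categories; pairs with no heterozygous genotypes have undefined
kinship and are skipped with a warning; LD pruning keeps the earlier
variant of an offending pair (windows never span chromosomes; window 50 /
step 5 are free parameters — the estimator only fixes the $r^2 > 0.2$
rule); PC sign is fixed by making each PC's largest-magnitude loading
positive; component labels follow the smallest member index, and samples
within a block stay in input order.

One qualitative phenomenon of real multi-ancestry data is *not*
reproduced by this generator: the near-total power collapse of a
magnitude-thresholded unadjusted GRM on the most strongly PC-correlated
variants.  In real cohorts the thresholded GRM carries fine-scale
structure beyond the fitted PCs, which differentially inflates those
variants' null variances; the Balding-Nichols cohort's ancestry is
exactly finite-rank and fully spanned by the fitted PCs, so both models
remain comparably calibrated there and the power gap, while uniformly
favouring the ancestry-adjusted GRM, peaks in the intermediate
categories instead.

## Known limitations

The built-in pair sweep is $O(N^2 M)$ and warns above 20,000 samples —
at biobank scale an IBD-segment pair list should be imported instead.
Binary traits, saddlepoint corrections, rare-variant set tests,
leave-one-chromosome-out schemes and multiple random effects are out of
scope.  The dense comparison utilities (`compute_threshold_grm`,
`dense` oracles in the tests) materialize $N \times N$ matrices and are
meant for method evaluation at moderate $N$, not production use.
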