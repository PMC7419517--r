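---
title: "Randomized multi-component Haseman-Elston regression: models, choices, and what the simulations show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomized multi-component Haseman-Elston regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`rhemc` estimates how much phenotypic variance a set of genotyped SNPs
explains, and how that variance distributes across SNP categories. The model
is a multi-component linear mixed model on standardized genotypes: each of
the $M$ SNPs belongs to one (or, for overlapping annotations, several) of
$K$ categories, and

$$ y = \sum_{k=1}^K X_k \beta_k + \epsilon, \qquad
   \beta_k \sim \Big(0, \tfrac{\sigma^2_k}{M_k} I\Big), \qquad
   \epsilon \sim (0, \sigma^2_e I), $$

with no distributional assumption beyond the first two moments. Columns of
$X_k$ are standardized so that $\sum_n x_{nm} = 0$ and $\sum_n x_{nm}^2 = N$;
consequently every SNP in a category has the same expected heritability
share, which is precisely why categories (MAF bins, LD bins, functional
annotations) are the unit of modelling: they let per-SNP effect variance
depend on MAF and LD without parametrizing that dependence.

Method-of-moments estimation matches $yy^\top$ to
$\sum_k \sigma^2_k K_k + \sigma^2_e I$ with $K_k = X_k X_k^\top / M_k$,
yielding the bordered normal equations with $T_{kl} = \mathrm{tr}(K_k K_l)$,
$b_k = \mathrm{tr}(K_k) = N$ and $c_k = y^\top K_k y$. This is
Haseman-Elston regression generalized to $K$ components. Estimates are not
constrained to be non-negative: a negative $\hat\sigma^2_k$ is informative
about model fit and keeps the estimator unbiased; an optional `nonneg` flag
truncates point estimates after the fact for presentation only.

## The randomized trace estimator

Computing $T$ exactly costs $O(N^2 M)$. The package instead uses the
Hutchinson identity $E[z^\top C z] = \mathrm{tr}(C)$ for any $z$ with zero
mean and identity covariance, estimating

$$ \widehat T_{kl} = \frac{1}{B}\frac{1}{M_k M_l} \sum_{b=1}^B
   z_b^\top X_k X_k^\top X_l X_l^\top z_b $$

from $B$ standard-normal probe vectors (default $B = 10$; estimates are
insensitive to raising it, which the test suite checks). One shared sketch is
used for all components and jackknife blocks — this is required for the
cross-component terms to be consistent and for delete-block reassembly to be
exact. Everything reduces to products of genotype blocks with a few vectors,
so the estimator needs a single pass over the genotypes and never forms an
$N \times N$ matrix. Blockwise products use BLAS; the implementation is
block-size invariant (tested to $10^{-8}$ relative), and the base-3
matrix-multiplication tricks used by some implementations for 0/1/2 matrices
are deliberately out of scope at the cohort sizes this package targets.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `B` | 10 | sketch vectors; variance of $\widehat T$ scales as $1/B$ |
| `n_blocks` (J) | 100 | jackknife blocks, contiguous in genome order |
| `maf_breaks` | 0.05 | interior MAF breakpoints for binning |
| `ld_quantiles` | 4 | LD-score quantile bins per MAF bin |
| `ld_window_bp` | 1 Mb | window for in-sample LD scores |
| `max_missing`, `min_maf`, `hwe_alpha` | 0.01, 0.01, 1e-7 | SNP QC thresholds |
| `cond_tol` | 1e12 | condition-number cutoff before least-squares fallback |

The default `maf_breaks = 0.05` with quartiles gives the common 8-bin
scheme; `c(0.01, 0.02, 0.03, 0.04, 0.05)` the 24-bin scheme used for
small-cohort comparisons. The LD score of a SNP is the sum of its squared
correlations with neighbors within the window, including itself (minimum 1);
quantile edges are in-sample, ties go to the lower bin, and empty bins are
dropped (a zero-size component would make the normal equations singular).
The 1 Mb window is a choice, not a law; externally computed per-SNP scores
(e.g. LDAK weights, which this package never computes itself) can replace
in-sample LD scores via the `scores` argument.

## Covariates

Covariates enter by projection: $y$, the sketch vectors and the per-block
sketch images are all residualized against $[1, W]$, so every accumulated
moment refers to covariate-adjusted data, and $n_\mathrm{eff} = N -
\mathrm{rank}([1, W])$ replaces $N$ in the bordered system. An intercept is
always included, so phenotypes are at least centered. This projector
contract is symmetric and self-consistent; it treats the $O(1/N)$
distinction between $\mathrm{tr}(PK_kP)$ and $n_\mathrm{eff}$ as negligible,
which at the package's intended scales it is.

## Jackknife standard errors

SEs come from a delete-one-block jackknife over `J` contiguous SNP blocks
(contiguity keeps LD within blocks at realistic inputs). The accumulator
retains, per block, the sketch images $\sum_{m \in j,k} x_m x_m^\top z_b$,
the quadratic-form partials and the SNP counts, so each delete-block system
is reassembled by subtraction and re-solved without touching genotypes —
memory $O(NKBJ)$ reals, about 250 MB at the largest sizes used here. SNP
blocks (rather than individuals) are the resampling unit, matching standard
heritability practice. The enrichment test is $Z = (\hat e_k - 1)/SE_k$
against the null value 1.

## The simulator

`sim_genotypes()` draws allele counts Binomial(2, $f_m$) with
$f_m \sim U(0.01, 0.5)$ by default (a heavy-rare Beta spectrum can be
supplied as a function), either independently or with blockwise LD from a
thresholded latent AR process. `sim_phenotype()` implements the MAF/LD-coupled
architecture family

$$ \sigma^2_m = S\, c_m\, w_m^{b}\, [f_m(1-f_m)]^{a}, $$

with $S$ normalizing $\sum_m \sigma^2_m = h^2$, causal mask $c_m$, per-SNP
weights $w_m$ (default 1), and effects acting on standardized genotypes;
$y|\beta \sim N(X\beta, (1-h^2)I)$, so phenotypic variance is 1 in
expectation. $(a, b) = (0, 0)$ is the GCTA-style architecture, $(0.75, 1)$
the LDAK-style one. Because LDAK weights are external to this package, the
studies exercise the $b$ coupling with $w_m = 1/\ell_m$ (inverse in-sample
LD score), which reproduces the defining property of such weights — larger
values in low-LD regions. All randomness flows from one master seed through
`seed_streams()` (genotypes / causal mask / effects-and-noise are
independent streams).

What the generator emulates: allele-frequency spectra, missingness-free
hard calls, MAF- and weight-coupled effect-size variance, exchangeable
individuals. What it does not: realistic coalescent LD (the AR-block model
is a caricature), relatedness and population structure, imputation error,
binary/liability traits, and ascertainment. Passing the studies below
therefore says the estimator is correct under its own assumptions at desk
scale — not that real-cohort estimates are unbiased under structure or
relatedness, which this model family does not claim to handle.

## Study designs and replicate structure

The replication studies (`study_h2_bias()`,
`study_enrichment_calibration()`, `study_partition_specificity()`,
`study_jackknife_calibration()`) follow the classical design for this
estimator family: genotypes are drawn once (or a handful of times) and
phenotypes are re-simulated per replicate, which is also how the method is
evaluated against real biobank genotypes. Because the sketch images depend
only on genotypes and the sketch, replicates are batched against a shared
accumulator, and the sketch is refreshed per replicate group so that its
first-order error averages out across groups. Problem sizes were chosen as
the largest a single desk CPU handles comfortably: $N = 2000\text{-}4000$,
$M = 5000\text{-}8000$, 400-4000 replicates per condition, a few independent
genotype draws. Replicate counts above the documented floors exist purely to
shrink the Monte-Carlo error of the reported bias; they do not change the
estimand.

## Numerical choices and degenerate inputs

Standardization rescales by the empirical post-imputation column variance
(missing calls are mean-imputed first), which enforces the model constraint
$\sum_n x^2 = N$ exactly for any input; monomorphic or constant-after-
imputation columns are QC'd out, and passing one is an error, not a silent
repair. The bordered solve falls back to a minimum-norm least-squares
solution (SVD) when the condition number exceeds `cond_tol`, e.g. for
duplicated components — a warning, never a crash. A component emptied by a
block deletion is dropped from that delete-block fit and surfaces as NA.
The exact oracle (`exact_grm()`, `exact_mom_fit()`) refuses $N > 5000$ to
prevent accidental $O(N^2)$ blowups; it also verifies that the
normal-equation solution is a stationary point of the Frobenius matching
objective.

## A desk-scale limitation worth stating plainly

With $B = 10$ the sketch noise in $\widehat T$ is relatively large whenever
$N/M_k$ is large — i.e. for small bins. The variance-component solution is
nonlinear (a matrix inverse) in $\widehat T$, so this noise has second-order
consequences that do **not** average out over phenotype replicates. We
measured them with a true-moment control: solving the normal equations with
the exact expected moments while substituting hundreds of independent
sketched $\widehat T$ draws. At $N = 2000$, $M = 5000$ with 8 MAF/LD bins
this gives (i) an upward bias of $\hat h^2$ of about $+0.7\%$ relative
(substituting the exact $T$ gives $-0.03\%$; the effect shrinks like $1/B$
and is gone at $B = 100$); (ii) a leakage of roughly $+0.4$–$0.7\%$ of $h^2$
into bins that hold no causal variants (exactly 0 under the exact $T$); and
(iii) extra variance in small-bin enrichment estimates that the SNP-block
jackknife cannot see (the null enrichment $Z$ has SD $\approx 1.09$ at
$N = 4000$, $M = 8000$, inflating the nominal 5% rejection rate to roughly
7.5–8.5%). These effects scale like $(N/M_k)^3/(BN)$ and are negligible at
biobank scale ($N \sim 3 \times 10^5$, $M_k \sim 10^4\text{-}10^5$), which
is the regime the estimator is designed for; at desk scale they are
measurable, and the test suite reports them honestly rather than hiding
them. Users fitting many small components to small cohorts should raise `B`
or validate against `exact_mom_fit()`.

## Known limitations

- Individual-level data only; no summary-statistic mode.
- Hard-call PLINK 1 BED input; no VCF/BGEN, dosages, or multi-allelic sites.
- Continuous traits; binary traits are treated as continuous if supplied
  (no liability-scale or case-control ascertainment model).
- Relatedness and population structure are the user's responsibility
  (covariates/PCs can be projected out, but the model assumes exchangeable
  residuals).
- In-sample LD scores require materializing the standardized kept-SNP matrix;
  for inputs where that is infeasible, supply an external per-SNP score file.
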