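---
title: "Multi-collection genomic prediction: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-collection genomic prediction: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangoGP)
```

# The problem

Tree-crop breeding programs (the motivating case is mango, *Mangifera
indica*) maintain small, diverse germplasm collections in different
countries, each phenotyped with its own protocols. Pooling such collections
into one reference population can raise the power of genome-wide association
scans and the accuracy of genomic prediction — but only if the analysis
accounts for population structure, collection-specific genetic effects
(genotype-by-environment interaction, GxE), and heterogeneous phenotyping.
`mangoGP` implements the full analysis chain for this setting: genomic
relationships and diversity description, multiple-testing calibration for
dense SNP panels, variance-component estimation, a mixed-model association
scan, and a family of Bayesian kernel-regression prediction models evaluated
under cross-validation — together with a simulator that generates
multi-collection data with known truth, so that every stage is testable
without access to any particular breeding program's data.

# Genomic relationships

Dosages count ALT alleles (0/1/2); residual missingness is mean-imputed
(`impute_mean()`), a deliberate simplification: haplotype-aware imputation is
upstream tooling outside this package's scope, and the relationship matrix is
insensitive to the imputation rule at the low residual missing rates left
after `filter_variants()` (which applies, in order, the missingness cut
(default: drop markers with more than 20% missing calls), a minor-allele-count
floor, singleton removal, and a minor-allele-frequency floor).

`compute_grm()` builds the VanRaden method-1 matrix

$$G = \frac{W W^\top}{2\sum_k p_k(1-p_k)},\qquad
  W_{ik} = x_{ik} - 2p_k,$$

with allele frequencies estimated from the analyzed sample itself (the
common choice when no base-population frequencies exist). Under
Hardy–Weinberg equilibrium the diagonal averages one; clones have
off-diagonal entries equal to their diagonals, which is the property the
clone-handling logic relies on.

# Diversity and multiple-testing calibration

Structure is summarized by PCA of the double-centered GRM
(`pca_from_grm()`); the coordinates equal the individual scores of an SVD of
the centered dosage matrix, which the test suite asserts directly. LD is the
squared correlation of haplotype indicators when phase is available
("phased" r²) and the squared dosage correlation otherwise; the mode is
always recorded. The decay curve (`ld_decay()`) bins pairwise r² by physical
distance, and the crossing distance is read against a background threshold
(`background_threshold()`): the 99th percentile of r² among
inter-chromosomal (physically unlinked) pairs. Because single bins are
noisy, the curve is smoothed by a short running mean and then forced
non-increasing (a monotone envelope) before the crossing is read; a reported
"~15 kb" style crossing implies some smoothing, and the monotone envelope is
the least structured choice. Bin width, maximum distance and the number of
sampled SNPs per chromosome are exposed; defaults (100 bp bins to 100 kb,
10 000 SNPs/chromosome for decay, 1 000 for the background) suit dense
sequence data.

`effective_snp_count()` estimates the effective number of independent tests
Me with a block-wise eigenvalue correction of the Li–Ji/Galwey family:
markers are processed in consecutive within-chromosome blocks (default 200),
and each block contributes $m_b - \sum_{\lambda_i > 1} (\lambda_i - 1)$,
where $\lambda_i$ are the eigenvalues of the block's marker correlation
matrix. This member of the family has the right limits — independent markers
give Me = m, duplicated pairs give m/2 — and those limits are asserted with
exact combinatorial fixtures. The Bonferroni threshold is $\alpha/$Me and the
suggestive threshold $1/$Me (one expected false positive per scan); the pair
is consistent with published threshold pairs derived from this style of
correction.

# Variance components

`greml_single()` is average-information REML for
$y = X\beta + g + e$, $g \sim N(0, K\sigma^2_G)$. The GRM is eigendecomposed
once, after which every iteration is O(n). AI proposals that leave the
parameter space are projected onto the boundary, and any proposal that would
decrease the restricted likelihood is replaced by an EM step with halving, so
the accepted likelihood sequence is non-decreasing and boundary optima
(h² near 0 or 1) are reached cleanly; boundary fits are flagged. Variances are
constrained to at least `1e-8 * var(y)`, convergence is declared when the
log-likelihood moves by less than `1e-6`, and standard errors come from the
inverse AI matrix with a delta-method transform for h².

For genetic correlations, `greml_bivariate()` maximises the exact restricted
likelihood of the 2×2 genetic and residual covariance matrices directly
(quasi-Newton over Cholesky factors with log-diagonals) rather than by AI
iterations with projection steps: the Cholesky parameterisation enforces
positive semi-definiteness — hence $r_g \in [-1, 1]$ — by construction, which
removes the need for ad hoc PSD projections and makes the boundary case
$r_g = 1$ (a trait paired with itself) numerically clean. In the GRM
eigenbasis the rotated records decouple into per-individual 2×2 blocks, so
one likelihood evaluation is O(n) and the optimisation is fast enough for
replicated simulation studies. Standard errors use the numerical Hessian and
a delta-method transform to $r_g$. Traits enter the bivariate analysis only
if they pass `reliability_gate()`: the standard deviation of the univariate
h² estimate must not exceed the estimate itself (boundary included) — the
screen that excludes, for example, a fruit-weight trait with h² = 0.11 and
SD = 0.14.

# Association scan

`mlm_scan()` tests each marker in
$y = X\beta + s\beta_s + g + e$ with the polygenic term's covariance
proportional to the GRM. The default is P3D: variance components are
estimated once under the null and reused per marker, giving a rotated
generalized-least-squares test that is vectorised across markers; `"exact"`
mode re-optimises the variance ratio per marker by one-dimensional search
and is intended for small panels or spot checks — both modes are recorded in
the result, and the suite asserts they agree within 5% of a standard error
on polygenic data. Dataset-of-origin covariates should be passed through `X`
when collections are pooled. Wald p-values are used, matching the common
mixed-model-scan convention. Calibration (type-I error at 5%, genomic
inflation λ near 1) is asserted on a 10 000-marker polygenic null
simulation. `cluster_qtls()` groups passing markers into QTLs by positional
merging (default window 200 kb) — a deterministic rule chosen over LD-based
merging; the window is a declared free parameter because published QTL
counts rarely state their grouping rule.

# Prediction models

The model family is
$$y = \mu + E + G + T + GE + GT + \varepsilon$$
with record-level covariance kernels $V_E = Z_E Z_E^\top$,
$V_G = Z_G\,G\,Z_G^\top$, $V_T = Z_T Z_T^\top$ and Hadamard interaction
kernels $V_{GE} = V_G \odot V_E$, $V_{GT} = V_G \odot V_T$. Model IDs select
subsets: `Single` (G only, fitted per trait/environment cell), `EG` (E, G),
`GxE` (E, G, GE), `MT` (T, G), `MxT` (T, G, GT). The interaction kernel
$V_G \odot V_E$ is exactly the covariance induced by collection-specific
additive deviations, which is also how the simulator generates GxE — the
generative model and the analysis model are deliberately conjugate.

`fit_gibbs()` fits any kernel set by Bayesian kernel (RKHS) regression: each
kernel is eigendecomposed once and its effect sampled in the rotated basis
where the full conditionals are independent normals; variance components get
scaled-inverse-chi-square updates; masked records are imputed by data
augmentation each iteration, which is what defines GEBVs for validation
individuals. Priors follow the convention of setting each component's prior
mode to $\mathrm{var}(y) R^2 / K$ for $K$ kernels with $R^2 = 0.5$ and df 5.
The default chain is 5 000 burn-in + 5 000 sampling draws (thinning 5) —
a desk-scale profile; published analyses of this model family commonly use
25 000 + 25 000, available via `mcmc_config()`. The sampler core is compiled
(RcppArmadillo), and fits are bit-reproducible under `mcmc_config(seed=)`.
A caveat inherent to Bayesian variance estimation: under a true-null genetic
signal the *posterior mean* of $\sigma^2_G$ cannot collapse to zero — it is
bounded away from it by the prior (around 0.15 var(y) under the default
profile at a few hundred records). The test suite therefore checks the null
behaviour of the *GEBVs* (no correlation with any fixed vector) and checks
variance collapse under a weakly informative profile.

# Cross-validation and evaluation

`cv_scheme()` implements CV1 (mask whole individuals — new, unphenotyped
entries) and CV2 (mask 20% independently within every trait/environment
cell — incomplete records). Within a replicate all compared models see
identical masks, so model contrasts are paired; `compare_models()` runs the
paired two-sided t-test on per-replicate accuracies (pairing is the
defensible reading when replicates share masks), with explicit handling of
degenerate cases. Accuracy is the Pearson correlation of observed phenotype
and GEBV in the validation set, reported per collection for
multi-environment runs. `run_intercollection()` trains on reference
collections only and predicts whole held-out collections, the scenario
behind reference/validation accuracy tables; diagonal (within-collection)
cells are CV1 accuracies.

# The simulator

`simulate_genotypes()` uses Li–Stephens-style mosaic copying rather than a
coalescent: each haplotype copies from a pool of ancestral template
haplotypes, switching templates between markers with probability
$1 - e^{-\rho d}$ for gap $d$ and per-collection rate $\rho$. This gives
direct, per-collection control of LD decay (length scale ~$1/\rho$) at
trivial runtime — the analyses only need *differential* decay, not
demographic realism. Population structure comes from Balding–Nichols pool
frequencies (Fst 0.15) and admixture from per-individual Dirichlet ancestry;
the short-range LD plateau is roughly the reciprocal of the total template
count, so tests that need a clearly resolvable crossing distance use few
templates. Defaults emulate a three-collection setting of 225/224/161
individuals with a faster-decaying second collection and 20 clone pairs
shared between the first and third.

`simulate_phenotypes()` draws causal effects for all traits jointly from a
zero-mean multivariate normal matching the target genetic-correlation
matrix, adds collection-specific effect deviations scaled so the
collection-specific share of genetic variance equals the configured GxE
fraction (equivalently, cross-collection genetic correlation $1-g$), scales
genetic values so the mean within-collection genetic variance is
$h^2 \cdot \mathrm{phenotype\_sd}^2$, and calibrates residual variance per
collection so within-collection heritability hits its target. One causal set
is shared across traits so effects can be drawn jointly.

Recording protocols reproduce the key phenotyping-harmonisation hazard:
`mean_of_k` records the average of k per-fruit draws,
`max_of_k` their maximum. Per-fruit draws are the individual's expected
value plus noise with a configurable within-tree coefficient of variation
(default 0.15 — a free parameter, since source phenotyping protocols do not
report within-tree variance). The max-of-15 recorder carries roughly three
times the noise variance of a mean-of-10 recorder (variance of the maximum
of 15 standard normals ≈ 0.31 vs 1/10), plus a location bias, which is what
makes max-recorded traits reproducibly less heritable and poorly
transferable across collections — the suite demonstrates both effects in
silico. Protocol cells need positive collection means because within-tree
noise scales with the mean; give such traits a realistic scale
(`phenotype_sd` in the same units).

What the simulator does *not* emulate: coalescent demographic history,
recombination hotspots, dominance/epistasis, pedigree structure or
polyembryony, sequencing error, or genotype uncertainty. Passing tests
therefore show the estimators are correct and well-calibrated under the
assumed additive multi-collection model, not that any particular empirical
dataset satisfies those assumptions.

# Numerical choices and degenerate inputs

* Variances bounded below at `1e-8 * var(y)`; kernel eigenvalues below
  `1e-8` of the maximum are truncated (rank-reduced sampling basis).
* AI-REML convergence: log-likelihood change below `1e-6`; non-convergence
  is flagged on the result, not raised.
* Monomorphic markers: rejected by `compute_grm()` (direction: filter
  first); silently skipped, with counts, in LD computations; excluded with a
  message from `effective_snp_count()`.
* Zero-variance vectors: `accuracy()` returns `NA` with a reason attribute;
  `compare_models()` reports identical vectors as t = 0, p = 1 and a
  constant non-zero difference as p = 0 with a degenerate flag.
* h² is constrained to [0, 1] by the non-negativity of both variance
  components; boundary fits (e.g. h² estimated at 1) are flagged rather than
  silently accepted.
* `hue_angle()` and `pulp_percentage()` are implemented exactly as the
  source protocols print them; in particular the "pulp percentage" is a
  fruit/stone weight *ratio* (values well above 1), kept on its recorded
  scale and documented as such rather than silently converted.

# Problem sizes used by the test suite

The suite is sized for a single desk CPU: GREML recovery runs at n = 2 000
individuals × 5 000 markers (20 phenotype draws over 4 genotype panels);
bivariate genetic-correlation recovery at n = 800 × 3 000 markers × 20
draws; the GWAS calibration null at n = 300 × 10 000 markers; CV-based
model-structure checks at 300–800 records, 500–1 000 markers, chains of
1 500–3 000 burn-in plus equal sampling, 20 replicates. These are the
package's own desk-scale study conditions; all thresholds asserted by the
tests are stated in their source modules.

# Known limitations

* Mean imputation only; no haplotype-aware imputation or phasing.
* The bivariate REML path requires both traits on the same individuals;
  disjoint record sets would need the generic dense-likelihood path, which
  is not optimised.
* P3D underestimates per-marker variance-ratio variation for markers of
  large effect (use `method = "exact"` to verify top hits).
* Admixture-proportion inference (model-based clustering over K ancestral
  populations) is out of scope; structure is described by PCA only.
* The Me estimator is one member of the eigenvalue-correction family; its
  block size (default 200) trades accuracy against O(block²·n) cost and is
  logged in the result.
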