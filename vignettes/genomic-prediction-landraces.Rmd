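---
title: "Genomic prediction and core-set selection for gene-bank collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction and core-set selection for gene-bank collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genpred)
```

## The problem

Gene banks hold thousands of landrace accessions whose agronomic value is
largely unmeasured. Phenotyping everything is infeasible; genotyping
everything is cheap. Genomic prediction bridges the gap: phenotype a small,
well-chosen *core* of the collection, fit a whole-genome regression, and
predict the remaining accessions through their marker-derived relationships.
`genpred` implements that workflow end to end — spatial adjustment of the
raw field trials, genomic relationship matrices, population-structure
correction, single-environment GBLUP and reaction-norm G×E mixed models,
diversity- and prediction-based core selection, and the cross-validation
designs used to measure prediction accuracy — together with a synthetic-data
generator so that every stage can be validated at desk scale without any
external download.

## Models

### GBLUP and the reaction-norm family

For records $y_{ij}$ of accession $j$ in environment $i$ the package fits a
nested family of random-effect models:

* **SE-GBLUP** (one environment): $y_j = \mu + g_j + \varepsilon_j$, with
  $g \sim N(0, \mathbf{G}\sigma^2_g)$ and $\mathbf{G}$ the VanRaden
  centered/standardized genomic relationship matrix,
  $G_{jk} = \sum_m (x_{jm}-2p_m)(x_{km}-2p_m) / \sum_m 2p_m(1-p_m)$.
* **M1**: $y_{ij} = \mu + E_i + A_j + \varepsilon_{ij}$ — environment and
  *iid* accession effects only; no borrowing of information between
  accessions, so it cannot predict untested accessions.
* **M2**: adds $g_j$ with covariance $\mathbf{G}\sigma^2_g$.
* **M3**: adds the genomic-by-environment interaction $Eg_{ij}$ with
  record-level covariance
  $(\mathbf{Z}_g\mathbf{G}\mathbf{Z}_g')\circ(\mathbf{Z}_E\mathbf{Z}_E')\,\sigma^2_{Eg}$
  — the Hadamard product of the genetic covariance with the
  environment-block indicator, i.e. a reaction norm with independent
  intercepts and slopes.
* **M4**: adds the analogous *iid* accession-by-environment term
  $(\mathbf{Z}_A\mathbf{Z}_A')\circ(\mathbf{Z}_E\mathbf{Z}_E')\,\sigma^2_{EA}$.

Phenotypes are standardized (mean 0, variance 1 across records) before
fitting by default, so variance components are reported on the standardized
scale. Genomic heritability is $h^2 = \sigma^2_g/(\sigma^2_g +
\sigma^2_\varepsilon)$, and the within-environment decomposition reports
each non-environment component as a percentage of
$\sum_{t \neq E}\sigma^2_t$, i.e. of the total variance after removing the
environment main effect.

### Estimation

Two fitting paths share one internal representation. Every random term
$u_t \sim N(0, K_t\sigma^2_t)$ is re-parameterized in the orthonormal
eigenbasis of its record-level covariance, $u_t = Q_t w_t$ with
$w_t \sim N(0, \Lambda_t \sigma^2_t)$. Because $Q_t'Q_t = I$, the full
conditional of $w_t$ given everything else is diagonal, so a Gibbs update of
an entire term costs two dense matrix–vector products; the eigenbases are
obtained from accession-level (or per-environment-block) eigendecompositions
rather than the raw record-level matrices, so setup is $O(n_{acc}^3)$ per
term.

* `method = "gibbs"` (default) runs a blocked Gibbs sampler with
  scaled-inverse-$\chi^2$ priors on all variance components
  (defaults: 6000 iterations, 1000 burn-in, thinning 5, one integer seed;
  chains are initialized at small variance values and the posterior mean is
  reported).
* `method = "fixed"` solves Henderson's mixed-model equations exactly at
  user-supplied variance components in the same reduced basis. This is the
  oracle-checkable path (it matches the closed-form
  $\hat g = \sigma^2_g \mathbf{G}\mathbf{Z}'\mathbf{V}^{-1}(y-\hat\mu)$ to
  numerical precision) and the fast path for repeated cross-validation.

**Prior choice.** All variance components — including the residual — get the
same weakly-informative scaled-inverse-$\chi^2$ prior with 5 degrees of
freedom and mode at 2% of the phenotypic variance. We deliberately do not
give each term an "equal share" prior mode: the *iid* accession term and the
genomic term (and likewise G×E versus the residual) are only weakly
identified at moderate sample sizes, because $\mathbf{G}$ approaches the
identity as the marker-to-accession ratio grows. On that near-flat
likelihood ridge, equal-share prior modes prop up the posterior mean of
components the data do not support (e.g. $E[\sigma^2_A \mid y] \approx 0.12$
when the generating value is 0 at $n = 500 \times 2$, $p = 2000$), which in
turn biases $\sigma^2_g$ downward by a third. With symmetric small-scale
priors the attribution is decided by the likelihood and simulation recovery
of $(\sigma^2_g, \sigma^2_{Eg}, \sigma^2_\varepsilon)$ lands within the
band the package's acceptance checks require.

**Two-stage cross-validation.** `evaluate()` refits the model on every
training split. Running a full Gibbs chain inside each of 30 replicates is
wasteful; standard practice (as in EMMAX-style association pipelines) is to
estimate variance components once — `pilot_components()` runs one Gibbs fit
— and solve the mixed-model equations at those components in every
replicate. That is the default pattern in the package's own evaluation
scripts; passing a `method = "gibbs"` spec to `evaluate()` performs the full
re-estimation per replicate if desired.

**Prediction of untested accessions.** Accessions present in
$\mathbf{G}$ but absent from the training records are predicted through
the Gaussian-process coupling $\hat u_{new} = K_{new,obs} K_{obs}^{+}
\bar u_{obs}$ of each GRM-structured term; *iid* terms contribute 0 for
unseen levels. Under CV1 a test accession has records in no environment, so
prediction flows entirely through $\mathbf{G}$.

## Spatial adjustment of augmented field trials

Raw plot values from an augmented design (unreplicated test entries, a few
checks repeated along rows and columns) are corrected with
$y = X\beta + s + e$, where $s$ has the separable covariance
$\sigma^2_s\,AR1(\rho_{row})\otimes AR1(\rho_{col})$ and $e$ is a nugget.
Checks enter as fixed means; unreplicated entries appear only through the
intercept, so their genetic variance is absorbed by the nugget (in an
unreplicated design the two are confounded — only the checks separate
spatial trend from noise). Estimation is restricted maximum likelihood over
$(\rho_{row}, \rho_{col}, h)$ with $h = \sigma^2_s/(\sigma^2_s+\sigma^2_n)$
and the total variance profiled out; a coarse grid seeds `nlminb`. On a
complete grid each evaluation uses the Kronecker eigenstructure
($O(n_r^3 + n_c^3)$); incomplete grids fall back to dense Cholesky on the
observed plots only. The fitted surface is the BLUP
$\hat s = h R V^{-1}(y - X\hat\beta)$; `adjust_phenotypes()` subtracts it
and drops the checks.

Two numerical guards matter. First, when $\rho_{row} \approx \rho_{col}
\approx 0$ the "spatial" field is white noise and $(\rho, h)$ are
unidentified; the fit therefore keeps the spatial terms only if they beat
the pure-nugget model by a 5% likelihood-ratio test on 3 degrees of freedom,
otherwise it reports $\rho = 0$, $\sigma^2_s = 0$ and a zero surface (so
adjustment never subtracts shrunken residual noise). Second, adjustment is
idempotent in that limit: refitting adjusted data finds essentially no
spatial variance.

## Population structure

Structure is quantified by the eigendecomposition of $\mathbf{G}$ itself
(`eigen_grm()`, with the cumulative-variance scree), and phenotypes are
pre-residualized per trait-by-environment on an intercept plus the first
`n_axes` eigenvectors (default 5). Pre-residualization (rather than fixed
covariates inside the sampler) matches the deliberate design of correcting
the response once and feeding every downstream model the same adjusted
phenotype; per-environment projection is the default because environments
have different means (a `pool_environments` flag pools them). Removing
structure removes real (structure-aligned) genetic signal, so prediction
accuracy is expected to *drop* after adjustment — the package's acceptance
checks reproduce that direction on simulated structured collections.

## Core selection

**Diversity cores** follow the distance-based recipe: modified Rogers
distance $d_{ij} = \|q_i - q_j\|/\sqrt{m}$ on allele-frequency vectors
$q = \text{dosage}/2$ (a Euclidean metric bounded in $[0,1]$); Ward
minimum-variance clustering (`hclust(method = "ward.D2")`); cluster sample
sizes proportional to within-cluster mean MRD (D-method,
largest-remainder rounding, floor of one); 1000 stratified candidate
subsets; and the candidate with the highest mean pairwise MRD wins. The
number of clusters defaults to the cut in $[5, 30]$ with the largest
relative jump in merge height, mimicking the visual dendrogram choice, and
is overridable. Cluster members are ordered canonically by accession
identifier so the same seed selects the same core regardless of input row
order.

**Prediction cores** maximize the mean reliability
$\mathrm{diag}\,\mathbf{G}_{21}(\mathbf{G}_{11} + \frac{1-h^2}{h^2}I)^{-1}
\mathbf{G}_{21}'$ of the non-selected accessions, by greedy forward
selection with one exchange pass, using rank-one updates so each candidate
evaluation is $O(nk)$. For large collections the reliability is computed in
a rank-$k$ eigenspace of $\mathbf{G}$ (default $k = \min(100, n-1)$ leading
principal components). Plain truncation is *not* used: the bulk of the
spectrum (finite-marker Mendelian-sampling noise) is near-isotropic, and
discarding it overstates reliabilities by 10–25% at $n = 300$ and misleads
the optimizer. The package instead uses the trace-preserving decomposition
$\mathbf{G} \approx U_k(\Lambda_k - \bar d)U_k' + \bar d I$, where $\bar d$
solves $\sum_k \max(\lambda_k - \bar d, 0) + n\bar d = \mathrm{tr}\,
\mathbf{G}$; the isotropic part simply adds to the $(1-h^2)/h^2$ shift.
This agrees with exact dense reliabilities to about 1% in the regimes the
tests exercise. The heritability fed to the reliability defaults to 0.5
when no pilot estimate is supplied.

**Diversity indices** for comparing cores are per-locus biallelic closed
forms averaged over loci: $He = 2p(1-p)$ (max 0.5),
$Ae = 1/(p^2 + (1-p)^2)$ (max 2), and the Shannon index
$-(p\ln p + (1-p)\ln(1-p))$ (max $\ln 2$), computed from subset allele
frequencies. The Shannon convention (natural log per biallelic locus) is
stated here because published values near 0.5 imply a different, unstated
normalization; we document ours rather than asserting equality with
anyone else's.

## Evaluation designs

`make_partitions()` produces accession-level splits: random TRN20-TST80
replicates (default 30), CV1 (identical mechanics, named for the guarantee
that a test accession has records in *no* environment), and a single
core-as-training replicate. `evaluate()` fits on training records with the
full GRM, predicts test records, and reports Pearson correlations per
environment plus a pooled correlation computed after centering observed and
predicted values within environment — pooling raw values would inflate the
correlation through environment means, so both pooled versions are stored
but the centered one is the headline number. Core-as-training reports a
single correlation (no SD), matching how core columns are usually
summarized. `percent_change()` computes $100(\bar r_{ref} - \bar
r_{cand})/\bar r_{ref}$, positive when the candidate predicts worse.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions under
which the pipeline's claims are checked.

* **Genotypes**: Balding–Nichols structure. Each marker's ancestral
  frequency is uniform on `maf_range` (default 0.05–0.5); group frequencies
  are Beta-dispersed with variance $F\,p(1-p)$, where $F$ is the
  `divergence` argument; dosages are binomial(2) draws; missingness is
  completely at random. With 5 groups and divergence 0.2 the top-5
  eigenvectors of $\mathbf{G}$ carry roughly 25–30% of total variance,
  matching the strongly structured collections the package targets;
  unstructured defaults (`n_groups = 1`) are used where structure is not
  the point.
* **Phenotypes**: $y_{ij} = \mu + E_i + A_j + g_j + EA_{ij} + Eg_{ij} +
  \varepsilon_{ij}$ with $g = X_c\beta$, $\beta \sim N(0,
  \sigma^2_g/\sum 2p(1-p))$, and environment-specific marker-effect
  deviations $\delta_{k,i}$ scaled so $Var(Eg)$ matches the requested G×E
  component — the interaction is covariance-level in the model, so a
  generative mechanism had to be chosen, and environment-specific effect
  deviations are the natural one. Default variance components
  (`default_variance_components()`) are the magnitudes of a standardized
  two-environment days-to-heading analysis of a large landrace collection:
  a dominant environment main effect (0.635) and within-environment shares
  of roughly 12% accession, 28% genomic, 11% A×E, 24% G×E and 25% residual.
* **Field trials**: accessions on a serpentine grid with checks at evenly
  spaced plots cycling over `n_checks` entries (the design literature only
  requires checks spread along rows and columns); plot error is the
  AR1⊗AR1 Gaussian field plus a nugget; per-check means are drawn once from
  the trait distribution.

What the generator does *not* emulate: linkage disequilibrium between
markers (markers are independent given group frequencies), admixed
individuals (group membership is discrete), dominance/epistasis,
non-Gaussian trait distributions, and non-random missingness. Passing tests
therefore demonstrate correctness of the machinery under the stated
generative assumptions, not robustness to every feature of real DArTseq
data.

## Problem sizes and numerical choices

The package's validation scripts run at desk scale, chosen so each check is
statistically meaningful: oracle comparisons at $n = 20$–$50$; variance
recovery at $n = 500$ accessions × 2 environments with $p = 2000$ markers
over 10 seeds (Gibbs chains of 1500/500/5 — posterior means of variance
components stabilize well before the 6000-iteration default, which remains
the default for one-off analyses); cross-validation and core comparisons at
$n = 300$ with 10–20 data seeds; spatial recovery on 40×40 grids. Marker
filters default to MAF ≥ 0.05 and call rate ≥ 0.80 with mean imputation —
the thresholds are configurable and logged because published filtering is
rarely fully specified. Eigenvalues below $10^{-9}$ (relative) are treated
as null space; a `bend` helper adds $\varepsilon$ to the GRM diagonal if a
downstream solver needs strict positive definiteness. One integer seed
drives every stochastic step, with per-stage/per-replicate streams derived
arithmetically so replicates are individually reproducible.

## Known limitations

* M1–M4 require both environments to share the accession panel for the
  efficient per-block eigendecompositions to pay off; unbalanced panels
  work but cost more.
* The Gibbs sampler reports posterior means; on weakly identified ridges
  (iid-accession vs genomic at small $n$) posterior means of individual
  components remain gently shrunk toward each other even with the
  symmetric priors — sums of confounded components are estimated much
  better than their split.
* The AR1×AR1 fit models a single trial; multi-trial meta-analysis,
  spline trend surfaces and kriging are out of scope.
* Core selection is single-objective; allele-coverage (M-method) and
  multi-objective cores are out of scope.
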