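---
title: "Methods: mQTL mapping in BC1S3 NAM populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mQTL mapping in BC1S3 NAM populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nammqtl)
```

This vignette documents the statistical model behind `nammqtl`, the
numerical choices made where the design was genuinely open, what the
simulator emulates, and what the validation suite does and does not show
about real data.

## The study design

A nested association mapping (NAM) population of the HEB-25 type crosses
each of a set of wild donors to one shared elite recurrent parent,
backcrosses the F1 to the recurrent parent once, and selfs for three
generations (BC1S3). At a locus polymorphic between the parents the
expected genotype distribution of a BC1S3 line follows from enumerating
the crossing scheme: the BC1 plant is heterozygous with probability 1/2,
and each selfing halves the heterozygous mass, so residual heterozygosity
is (1/2)(1/2)^3 = 1/16 = 6.25%, homozygous-donor mass is 7/32 and the
expected donor-genome proportion 25%. These closed forms are the primary
correctness oracles for the simulator.

## The simulator

`simulate_nam()` and `simulate_bc1s3_family()` generate the population
that the rest of the package is validated on.

* **Meiosis.** Haldane model without interference: per chromosome the
  crossover count is Poisson with mean equal to the map length in
  Morgans, crossover positions are uniform on the centimorgan scale, and
  meioses are independent across lines and generations. HEB-25-type
  study descriptions specify no simulator, so this community-standard
  default was chosen.
* **Selfing** is single-seed descent without selection; real programmes
  select during line development, but no selection model is specified
  anywhere, so none is imposed.
* **Founders.** The recurrent parent carries the reference allele
  everywhere; each donor draws alternative alleles independently per SNP
  at a configurable rate (default 0.5). Real wild accessions share
  ancestry and haplotype structure; this generator does not emulate that,
  which mainly affects how often a marker is family-private.
* **Desk-scale defaults**: 25 families x 52 lines = 1300 lines and 2000
  SNPs on 7 chromosomes of 150 cM (4 Mb/cM, i.e. 600 Mb chromosomes),
  a deliberate scale-down of a 1400-line, 33k-SNP panel that keeps every
  statistical mechanism intact while fitting interactive runtimes.
* **Phenotypes.** A genetic value g is the sum of planted QTL effects
  times IBS dosages (with optional per-family multipliers); Gaussian
  noise is scaled so Var(g)/(Var(g)+sigma2_e) equals the target
  heritability exactly, and an optional `exp(z/sd(z))` link produces the
  positive, right-skewed distributions typical of metabolite peak areas,
  making the Box-Cox stage non-trivial. `simulate_mqtl_scenario()`
  plants three QTL on distinct chromosomes with phenotypic variance
  shares 0.30/0.20/0.10 summing to the default heritability 0.6, each
  comfortably above the 10% share where detection should be routine.

What passing simulator-based tests does **not** show: robustness to
genotyping error (only missingness is modelled), to shared donor
haplotypes, to field spatial effects, or to the upstream GC-MS
normalisation chain — those live outside the package's scope.

## Genotype preparation

Markers pass QC when polymorphic in at least one family, with a
missing-call rate below 10% and a heterozygous-call rate below 12.5%
(twice the BC1S3 expectancy of 6.25%; an excess flags unreliable
clustering). Both thresholds are applied as strict inequalities exactly
as printed, so a marker at exactly 10% missing fails; the heterozygosity
rate is computed over called genotypes only, since the rate of a call
state is naturally conditioned on calls.

IBS coding assigns 0/1/2 for homozygous-elite/heterozygous/homozygous-
wild. A SNP monomorphic within a family carries no contrast against the
recurrent allele there, so all of that family's lines are recoded to 0.
The convention is usually stated for the elite-monomorphic case; its
rationale — within such a family the marker behaves exactly like the
elite allele — applies equally when a family is fixed for the donor
homozygote, so the rule covers *any* within-family monomorphism, with every
recoded (SNP, family) pair reported in the `recoded` attribute. A family
with all calls missing at a SNP counts as monomorphic (conservative:
coded 0). Mean imputation uses population-wide column means (per-family
means are available via `by_family = TRUE` but off by default, matching
the whole-matrix MNI convention); the imputed-cell mask is retained so
that fractional imputed scores never count as heterozygotes downstream.

## Metabolite preparation

Columns with more than 10% missing values are dropped (strictly greater:
exactly 10% is retained); remaining missing values are replaced by the
column minimum — the stand-in for values below the limit of
quantification — *before* transformation, following the stated order of
operations. The Box-Cox transform maximises the profile log-likelihood
on the fixed grid λ ∈ {−3.00, −2.75, …, 3.00}; λ = 0 means log. Ties on
the grid break toward the λ closest to 1 (least distortion). Values that
are non-positive (possible only in raw-data mode) are shifted by
1 − min(y) first. Constant input is rejected because the likelihood is
undefined at zero variance.

One identifiability property matters for interpreting chosen λ values:
the Fisher information about λ scales with the squared coefficient of
variation of the data. For a trait with cv ≈ 0.05 the profile likelihood
is almost flat and the grid maximiser has a sampling standard deviation
around 0.5 even at n = 1000 — the chosen λ is then essentially
arbitrary (and harmless, since all near-optimal transforms are nearly
affine on such data). λ is a stable, meaningful choice only for traits
with substantial relative spread, such as the right-skewed metabolite
distributions the transform exists for.

## Variance components

`build_kernels()` constructs three line-by-line relationship matrices
from the imputed IBS matrix: a VanRaden-style additive kernel
A = ZcZc'/k from column-centred scores, a dominance kernel from centred
heterozygosity indicators (pre-imputation states only), and an
additive×additive epistatic kernel as the Hadamard square A∘A. Each is
normalised to mean diagonal 1, so variance components are on the
phenotype scale. The kernel formulas follow the conventions documented
by sommer, the mixed-model package most commonly used for this
decomposition in plant genetics, and are recorded in the output.

`estimate_h2_snp()` fits y = mu + g_A + g_D + g_I + e by REML:
two expectation–maximisation warm-up steps followed by
average-information updates, with step-halving on the restricted
likelihood, components constrained non-negative (boundary components are
pinned and dropped from the AI system — without this, convergence can
stall short of the optimum when a component hits zero), and convergence
declared after two successive likelihood changes below 1e-6. Estimates at
the boundary are reported as exactly 0. A test cross-checks the fit
against a brute-force grid search of the same restricted likelihood on a
single-kernel problem.

Two practical notes measured during development: heritability estimates
are honest only when the marker map is dense enough for stable kernels
(with a few hundred SNPs, null traits can show inflated h² through the
low-rank epistatic kernel; with 1000+ SNPs on this design the null
behaviour is clean), and the A+D+I decomposition slightly inflates null
estimates relative to an additive-only fit because three non-negative
components are summed.

Repeatability uses the one-way random-effects ANOVA expected mean
squares, with the unbalanced-design coefficient
n0 = (N − Σn_i²/N)/(g−1) in the role of the replication number r, V_G
truncated at zero, and the estimate clamped to [0, 1].

## The GWAS engine

Stepwise forward–backward regression over all SNPs: the forward step adds
the candidate with the smallest marginal-F p-value if below 0.001; after
every forward step, backward elimination runs to exhaustion, removing
the worst selected SNP while its marginal p (its partial F given all
other terms, i.e. a Type-II test) is at or above 0.001; coefficients are
refit jointly after every change. Scheduling details that stepwise
implementations usually leave unspecified were fixed as follows: ties on p-values break to the lowest
(chromosome, bp); a candidate whose inclusion would make the training
design numerically rank-deficient (residual-to-original sum-of-squares
ratio below 1e-10) is skipped for that step; and model size is capped at
min(50, n/10) to guarantee termination — in practice far above the sizes
selected at p < 0.001. Internally the forward scan maintains residualised
candidates under rank-1 updates, which is algebraically identical to
refitting every candidate model and is verified against a literal
lm()-based reference selector, set- and coefficient-exact, on randomised
instances.

Cross-validation follows the study design: within each family and
repetition, lines are dealt into 5 folds as evenly as possible (fold
sizes within a family differ by at most one; the fold receiving the
extra line rotates randomly), each of the 5 held-out folds is predicted
from a model selected on the other 4/5, and the whole procedure repeats
20 times — 100 runs. Prediction ability is the squared Pearson
correlation between observed and predicted validation values; a run
whose model is empty predicts a constant and scores 0, flagged. A SNP's
detection rate (DR) is its number of inclusions across the 100 final
models.

The significance threshold is calibrated by permutation: phenotype rows
are shuffled as whole records (preserving inter-metabolite correlation)
relative to the genotypes, the full cross-validation GWAS is rerun on
each of 3 shuffled matrices, and all per-SNP, per-metabolite DRs are
pooled. The threshold is the smallest integer t such that at least
99.99% of pooled null DRs lie strictly below t. On desk-scale pools
(fewer than 10^4 values) this reduces to one more than the largest null
DR. A property worth knowing: the null DR distribution is heavy-tailed,
because with ~1000 candidates the best chance correlate of a permuted
phenotype typically clears p < 0.001 in most training subsets and can be
retained in a large fraction of runs; the threshold therefore varies
between permutation draws, and single-trait thresholds at desk scale are
noticeably noisier than the pooled multi-metabolite calibration used at
full scale. For metabolite screening, the mean prediction ability must
exceed 0.2 before mQTL are reported (configurable).

## mQTL regions and family effects

No explicit grouping rule is given for turning significant SNPs into
mQTL; the implemented rule is positional: significant SNPs (DR at or
above the threshold) on one chromosome merge while consecutive ones are
at most 5 Mb apart (configurable), regions are numbered per chromosome
("3H-2", with an optional sampling-date suffix "3H-2_1"), and the peak
SNP has maximal DR with ties broken by |mean effect| and then map order.
Region explained variance refits *all* member SNPs jointly on the full
data set, not only the peak, with rank-guarded pruning
of collinear members.

The family-specific cumulated effect implements the cumulation approach
used in NAM analyses as: within each cross-validation run and family, sum 2·β̂ (the
homozygous-wild versus elite contrast) over region member SNPs that are
in that run's final model *and* segregate in that family; average over
all runs, counting runs without contributing SNPs as zero. "Segregates"
means the family's IBS scores span a range of at least 0.5 after
family-wise recoding, so imputed fractional scores cannot fake
segregation. Families with no segregating member SNP get an exact zero.
Variants of the approach weight by family allele frequency instead of
the fixed 2x contrast; the interpretation used here is recorded in the
output metadata.

## Validation scales and determinism

The test suite validates at deliberately chosen sizes: segregation laws
on 2000-line families; selector equivalence on 50 instances of n = 60,
20 SNPs; null and signal GWAS behaviour at the full desk scale of 1300
lines with 1000–2000 SNPs and 100 cross-validation runs; heritability
recovery at n = 1300 with 20 replicates per h2 level; and end-to-end
determinism on an 8-family, 600-SNP pipeline, where two runs under one
seed must produce byte-identical report bundles. All randomness flows
from explicit integer seeds; no step consults the clock or the
environment.

## Known limitations

* The permutation threshold at single-trait desk scale is a draw from a
  heavy-tailed null-maximum distribution (see above); pooled
  multi-metabolite calibration is strongly recommended.
* AI-REML reports a flagged best-found solution on non-convergence
  rather than failing; with very sparse maps the D and I kernels can be
  poorly identified.
* The simulator does not model genotyping error, donor haplotype
  sharing, selection during line development, or multi-environment
  structure.
* Kinship- or PCA-corrected mixed-model GWAS is intentionally out of
  scope: the design relies on multi-locus selection plus
  family-stratified folds instead.
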