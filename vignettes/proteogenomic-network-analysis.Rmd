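---
title: "Proteogenomic network analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteogenomic network analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pgnet` implements a three-phase proteogenomic framework for complex disease:
(1) case/control variant association and meta-analysis intersected with
protein quantitative trait loci (pQTLs); (2) network analysis on a
gene-score-weighted protein–protein interaction (PPI) graph; (3) causal and
regulatory follow-up (Mendelian randomization, colocalization, fine-mapping,
chromatin-loop mapping) with converging-evidence triangulation. This vignette
explains the models, the parameters that matter, and the design choices made
where the design was genuinely open. It states no empirical result that the
package's tests and acceptance script do not themselves compute.

## 1. The synthetic cohort generator

Real applications of this kind of pipeline consume biobank-scale genotype,
phenotype and plasma-proteome data that cannot ship with a package. The
generator in `simulate_cohort()` is therefore first-class, tested code that
produces every input the pipeline consumes, with the statistical structure
the downstream methods assume:

* **Genotypes.** Variants are partitioned into contiguous LD blocks, one
  block per chromosome. Each haplotype is a latent first-order
  autoregressive Gaussian within its block (`rho`, default 0.8 — adjacent-
  variant latent correlation typical of dense array data), thresholded at
  `qnorm(maf)` so Hardy–Weinberg holds per site; two independent haplotypes
  sum to a dosage in {0, 1, 2}. Blocks are mutually independent. This gives
  tunable r² without a haplotype panel. Minor-allele frequencies are uniform
  on `maf_range` (default 0.05–0.5).
* **Phenotype.** A liability-threshold model: a standardized causal-dosage
  score scaled to `h2_liability` (default 0.3), small fixed covariate
  loadings (age 0.005/yr, sex 0.10, PCs 0.02 — recorded in the truth
  object), and Gaussian noise; cases are the top `prevalence` fraction of
  the empirically standardized liability. Because the covariate loadings are
  small, `h2_liability` is the approximate liability-scale heritability.
* **Proteins.** NPX-like continuous abundances: one cis variant effect per
  protein drawn inside the protein's gene interval (`N(0, cis_effect_sd²)`,
  default SD 0.4 per allele), `n_trans_per_protein` trans effects elsewhere
  (default SD 0.2), covariate terms in age, age², sex and age·sex, and
  `N(0, noise_sd²)` noise. Proteins map 1:1 to genes by name, which is what
  lets pQTL proteins, gene scores and PPI nodes live in one namespace.
* **PPI.** Preferential attachment from a connected seed pair; node *t*
  attaches to `min(attach_m, t−1)` distinct nodes with probability
  proportional to degree, so the edge count is exactly
  `1 + sum(min(attach_m, t−1))`. A connected planted module is grown by
  breadth-first search and recorded; when `plant_in_module = TRUE` the
  disease-causal variants are drawn from SNPs inside the planted genes, so
  the module carries enriched low gene p-values by construction.

Randomness is controlled by a single master seed fanned out to per-stage
child seeds (`child_seed()`), so each stage can be regenerated independently
and every generator is a pure function of (spec, seed).

**What the generator does not emulate:** recombination maps and realistic LD
decay, population structure beyond PC covariates, imputation uncertainty,
batch and plate effects in proteomics, and the X chromosome. Passing tests
on these cohorts therefore demonstrate the correctness and calibration of
the estimators under their stated assumptions, not robustness to the
artifacts of real biobank data.

## 2. Association and meta-analysis

`logistic_assoc()` fits covariate-adjusted logistic regression per variant
(maximum likelihood via `stats::glm.fit`, or Firth's Jeffreys-prior
penalized score with tolerance 1e-8 and at most 100 damped Newton steps).
Firth's correction yields finite estimates under complete separation and
heavy case/control imbalance, which is why it is standard for biobank
case/control GWAS. A two-step whole-genome ridge (LOCO) machinery is
deliberately out of scope: at synthetic scale, with population structure
limited to PC covariates, plain covariate-adjusted regression is the
adequate and transparent choice. Missing dosages are dropped listwise by
default (mean imputation by flag).

QC defaults follow standard array practice: MAF > 0.1%, call rate > 0.95,
exact Hardy–Weinberg p > 1e-6 (conditional enumeration test), INFO > 0.8
when an INFO score is supplied. All four are strict inequalities and all are
knobs.

`meta_fixed()` is the classical fixed-effects inverse-variance combination
(`w = 1/se²`). Allele harmonization flips swapped effect/other alleles;
strand-ambiguous (A/T, C/G) variants are dropped when either study's
effect-allele frequency is within 0.08 of 0.5 and frequency-aligned
otherwise — the conventional compromise when strand information is absent.
Genome-wide significance is strict `p < 5e-8`.

## 3. Gene-based scores

`gene_test()` collapses SNP p-values in a gene to one score: each two-sided
p becomes a 1-df chi-square quantile, the statistic is their sum, and the
null is the quadratic form `sum(lambda_i * chisq_1)` with `lambda` the
eigenvalues of the SNP correlation matrix (taken from the generator's known
block structure or estimated from dosages and shrunk 1% toward the
identity). The SNP-wise sum model is the default model of the standard
gene-based tool this stage mirrors; the competitive gene-set machinery and
multi-model aggregation are not needed for node weighting and are omitted.

**Numerical choice.** The common two-moment (Satterthwaite) approximation of
the quadratic form is accurate near the center but its relative error grows
severely in the far tail under LD (tens of percent at p ≤ 1e-3). The
default here is the Lugannani–Rice saddlepoint tail of the quadratic form,
which keeps relative error at the percent level deep into the tail, costs
microseconds, and reduces exactly to the scaled chi-square when eigenvalues
are equal (so a single SNP returns its own p, and duplicating a SNP in
perfect LD changes nothing). At the exact distribution center — where the
saddlepoint equation degenerates — the two-moment value is kept; it is
accurate there. `method = "satterthwaite"` restores the pure two-moment
behavior.

Node weights are `z = qnorm(1 − p)` clamped to ±8.2 (≈ one-sided p = 1e-16)
so module scores stay finite; nodes without a score carry the minimum
clamped weight rather than being excluded, keeping the search space equal to
the full network.

## 4. Dense-module search

A module is a connected subgraph with locally maximal aggregate association
signal, scored `Zm = sum(z)/sqrt(k)`. From every seed node the greedy search
considers all nodes within graph distance `d` (default 2) of the current
module and admits the candidate maximizing the new `Zm` iff
`Zm_new > Zm_old * (1 + r)` with `r = 0.1` — both defaults are the
conventional settings for this algorithm family.

Distance-2 admission is ambiguous in the original description: this
implementation admits the candidate **together with one shortest-path
interior node** so the module stays connected, counts the interior node in
`k`, and chooses the interior that maximizes the resulting `Zm` (ties broken
lexicographically). All candidate ties break lexicographically by node name,
so the search is fully deterministic. `strict_adjacent = TRUE` restricts
candidates to direct neighbors (d = 1 semantics). Both behaviors are tested
against an independent step-by-step oracle.

Normalization draws `B_norm` (default 10,000) uniform random k-node sets per
module size and standardizes: `Zn = (Zm − mean_k)/sd_k`. A per-size null is
drawn for every size present — the draws are cheap, and pooling sizes would
mix null scales; when the null SD is zero (all weights equal) and the module
score equals the null mean, `Zn` is 0 by continuity rather than an error.
Top-module selection takes `ceiling(q·n)` modules (default top 1%) ordered
by `Zn`, ties by `Zm` then seed name.

The hypothesis-driven counterpart (`first_degree_network()`) extracts risk
loci and their direct PPI neighbors; `permutation_enrichment()` compares the
one-sided Fisher overlap p of that neighborhood with the pQTL protein set
against `B` (default 10,000) uniformly drawn node sets of equal size, with
the add-one empirical p convention `(1 + #{p_b ≤ p_obs})/(B + 1)` so the
p-value is never zero.

## 5. pQTL mapping

`pqtl_scan()` regresses every protein on every variant with the standard
plasma-proteomics covariate design (age, age², sex, age·sex, age²·sex, plus
PCs), computed by residualizing both matrices against the covariates and
regressing residual on residual with the correct degrees of freedom.
P-values are carried as −log10(p) throughout the module so associations far
beyond double underflow survive storage. The cis definition is same
chromosome and position within `window_bp` of the gene boundaries, inclusive
on both sides; the default window is 1 kb with the knob exposed
(`cis_window_bp`) because 1 kb is atypically narrow for pQTL work and 1 Mb
is common.

## 6. Causal inference

Instruments are significant cis-pQTLs (`p < 5e-8`), greedily LD-clumped at
r² < 0.001 in p-ascending order, and harmonized against the outcome (swap
flips, palindromic drop at |eaf − 0.5| < 0.08). The estimator follows the
instrument count: one SNP — Wald ratio with first-order delta SE; two —
fixed-effect IVW (weighted regression through the origin, weights
`1/se_out²`, identical to inverse-variance meta-analysis of per-SNP ratios);
three or more — IVW by default, weighted median on request (interpolated at
cumulative weight 0.5, weights `beta_exp²/se_out²`, SE by seeded parametric
bootstrap of 1,000 replicates). The weighted median is consistent when
instruments carrying at least half the weight are valid, which is what the
outlier-robustness test exercises. The global horizontal-pleiotropy test is
simulation-based: weighted residual sum of squares of outcome effects about
leave-one-out IVW fits, ranked against parametric simulations under no
pleiotropy (add-one convention); it requires ≥ 4 instruments and returns a
not-applicable marker otherwise. Outlier *removal* is intentionally not
implemented — only the test outcome is used downstream.

Colocalization uses per-variant Wakefield log approximate Bayes factors
(`lABF = 0.5·[log(V/(V+W)) + z²·W/(V+W)]`, prior effect variance
W = 0.15² for case/control traits and 0.2² for standardized quantitative
traits, both configurable) and enumerates the five hypotheses with priors
p1 = p2 = 1e-4, p12 = 1e-5. All hypothesis sums run in log space
(log-sum-exp), which makes the posteriors invariant to uniform rescaling of
the ABFs; a single shared variant forces PP.H3 = 0 identically because no
two-distinct-SNP configuration exists. PP.H4 > 0.75 is the default call
threshold (0.9 is the stricter variant; both appear in practice and both are
exposed).

Fine-mapping assumes a single causal variant per region (a documented
simplification — multi-signal regions will under-perform): PIPs are
normalized ABFs over a 500 kb default window around the index variant, and
the 95% credible set is the minimal descending-PIP prefix reaching 0.95.

## 7. Enrichment, triangulation and loop mapping

Pathway enrichment is an upper-tail hypergeometric test of the query against
each gene set **within the supplied panel background** — never the whole
genome by default, because assay panels are heavily curated and a genomic
background overstates enrichment. BH FDR is computed across tested sets;
sets overlapping the query in fewer than 3 genes are skipped.

Triangulation flags proteins across three target sets: (a) pQTL-associated
proteins, (b) top-module proteins that are pQTL-associated, (c)
pQTL-associated first-degree neighbors of risk loci. The default converging
rule is `a AND (b OR c)`; the strict three-way intersection is available and
is always a subset of the default — the choice is a knob because the
published description of "converging lines of evidence" does not pin down
the rule.

Genotype-stratified abundance uses ANCOVA (`abundance ~ genotype + age +
sex + age:sex`) with the genotype F-test against the covariate-only model
and all pairwise genotype contrasts; levels with fewer than 2 samples are
dropped with a warning. Carrier frequencies use the two-sided Fisher exact
test with the sample odds ratio (undefined marker when any cell is zero).

Loop mapping treats anchors as 0-based half-open intervals and variant
positions as 1-based (converted internally); a variant in one anchor links
to the genes of the other anchor, labeled by cell type, with chromosome
names normalized (`chr1` ≡ `1`).

## 8. The pipeline and problem sizes

`run_pipeline()` executes ten stages — simulate, gwas, meta, pqtl,
gene_scores, modules, neighbors, causal, enrichment, loops — each writing
TSVs plus a manifest entry (parameters, stage seed, md5, row count).
Completed stages are skipped unless `force = TRUE`; identical configurations
reproduce byte-identical outputs (the TSV writers emit doubles at %.17g
precision so values round-trip exactly). Two cohorts sharing one disease
architecture (same causal variants and effects, independent samples) feed
the meta-analysis.

The package's own tests and acceptance script run the demo configuration at
deliberately small sizes — hundreds of samples, a few hundred variants, tens
of proteins and PPI nodes of order 10²–10³, with permutation and
normalization draws of 500–10,000 — chosen so the whole suite exercises
every stage end to end in minutes while each statistical check retains the
power it needs (the calibration and coverage tests state their replicate
counts explicitly). The `alpha_loci` knob exists because a synthetic cohort
of hundreds of samples does not have biobank power: downstream locus
definitions use a configurable threshold while the genome-wide constant
5e-8 remains the default for significance calls.

## 9. Known limitations

* Single-causal-variant fine-mapping and colocalization; no multi-signal
  modeling.
* No MR-Egger, multivariable MR, or Steiger filtering; trans instruments
  are excluded by design.
* The gene test implements the SNP-wise sum model only.
* The generator's LD is blockwise AR(1); long-range LD and structure are
  absent, so harmonization edge cases involving real strand ambiguity are
  exercised only synthetically.
* Module search is exhaustive over seeds and therefore quadratic-ish in
  dense neighborhoods; it is sized for networks of order 10³–10⁴ nodes, not
  the full interactome at biobank scale in interactive time.
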