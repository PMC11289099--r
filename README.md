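# pgnet: proteogenomic network analysis of GWAS and pQTL signals

Genome-wide association studies nominate risk variants for complex diseases,
but most variants act indirectly — through the abundance of proteins they
regulate, and through the interaction partners of those proteins. `pgnet`
implements a three-phase framework to trace that chain for a case/control
trait and a population-scale plasma proteome:

1. **Proteogenomic analysis.** Per-variant QC and covariate-adjusted
   logistic association (Firth-penalized on request), fixed-effects
   inverse-variance meta-analysis of two studies
   (w<sub>i</sub> = 1/se<sub>i</sub>², β̂ = Σwβ/Σw, se = 1/√Σw),
   protein quantitative trait locus (pQTL) mapping with cis/trans
   classification, and intersection of genome-wide-significant variants
   (p < 5×10⁻⁸) with pQTLs.
2. **Network analysis.** LD-aware gene-based scores — the SNP-wise sum
   statistic T = Σ<sub>j</sub> χ²₁(p<sub>j</sub>) with null
   Σλ<sub>i</sub>χ²₁, λ the eigenvalues of the SNP correlation matrix,
   evaluated by a saddlepoint tail — weight the nodes of a protein–protein
   interaction (PPI) network with z = Φ⁻¹(1−p). A greedy dense-module
   search (neighbor order d = 2, increment rate r = 0.1) finds connected
   subgraphs with locally maximal Zm = Σz/√k; module scores are normalized
   against random node sets and the top 1% selected. A hypothesis-driven arm
   extracts first-degree neighbors of risk loci and tests their pQTL-protein
   enrichment by permutation (empirical p with the add-one convention).
3. **Causal and regulatory follow-up.** Two-sample Mendelian randomization
   from clumped cis-pQTL instruments (Wald ratio / IVW / weighted median,
   BH FDR), a simulation-based global horizontal-pleiotropy test,
   approximate-Bayes-factor colocalization (priors p1 = p2 = 10⁻⁴,
   p12 = 10⁻⁵; hypotheses H0–H4), single-causal-variant fine-mapping with
   95% credible sets, hypergeometric pathway enrichment against a panel
   background, variant→chromatin-loop→distal-gene mapping, and
   converging-evidence triangulation across the three target sets.

Because the real inputs are biobank-scale and access-controlled, the package
ships a first-class synthetic cohort generator (LD-blocked genotypes, a
liability-threshold binary trait, protein abundances with cis/trans genetic
effects and age/sex covariates, a scale-free PPI with a planted module) so
every stage is testable end to end with no download. The methods vignette
(`vignettes/proteogenomic-network-analysis.Rmd`) documents the models,
defaults and design choices.

## Worked example

```r
library(pgnet)

spec <- cohort_spec(n_samples = 2000, n_variants = 150, n_blocks = 10,
                    n_proteins = 25, n_genes = 50, ppi_nodes = 50,
                    planted_module_size = 6, h2_liability = 0.4,
                    prevalence = 0.2, n_causal_disease = 4,
                    cis_effect_sd = 0.5, seed = 42)
cohort <- simulate_cohort(spec)
cohort
#> Synthetic cohort: 2000 samples, 150 variants, 25 proteins
#>   cases: 404  controls: 1596
#>   causal variants: 4  true pQTL effects: 50
#>   PPI: 50 nodes, 97 edges; planted module size 6

covs <- cohort$covariates[, c("sex", "yob", paste0("pc", 1:10))]
gwas <- gwas_scan(cohort$genotypes, cohort$phenotype, cohort$variants,
                  covariates = covs)
hits <- genomewide_significant(gwas, alpha = 1e-6)
nrow(hits)
#> [1] 8

pqtl <- pqtl_scan(cohort$proteins, cohort$genotypes, cohort$covariates,
                  alpha = 5e-8)
pqtl <- classify_cis_trans(pqtl, cohort$variants, cohort$annotation,
                           window_bp = 1000)
architecture_summary(pqtl)
#> pQTL architecture: 61 associations, 49 pQTLs, 18 proteins
#>   proteins per pQTL:  1:38 2:10 3:1
#>   pQTLs per protein:  1:8 2:2 4:3 5:1 6:2 7:1 13:1
#>   protein status: cis_only=5 trans_only=6 both=7 unknown=0
#>   pQTLs trans-only: 18

snp_map <- assign_snps_to_genes(cohort$variants, cohort$annotation)
gs  <- gene_scores(gwas, snp_map, genotypes = cohort$genotypes)
ppi <- build_weighted_ppi(cohort$ppi$edges, gs)
mods <- dense_module_search(ppi, d = 2, r = 0.1)
mods <- normalize_modules(mods, ppi, B_norm = 2000, seed = 1)
mods
#> Dense-module search: 50 modules (d = 2 , r = 0.1 )
#>   sizes: 3-9  best Zm: 13.81
#>   best Zn: 5.674

top <- top_percent_modules(mods, q = 0.01)
top$modules$members[1]
#> [1] "G0011;G0032;G0033;G0034"
cohort$ppi$planted
#> [1] "G0005" "G0009" "G0011" "G0032" "G0033" "G0046"
```

The top-ranked module recovers three of the six planted disease genes: the
disease-causal variants were planted inside the module's gene bodies, the
gene scores pick up the association signal, and the search concentrates it.
The printed case count (404/2000) matches the 0.2 prevalence; 8 of 150
variants reach p < 10⁻⁶ because four causal variants sit in LD blocks. The
architecture summary partitions proteins by whether their significant pQTLs
are cis (within ±1 kb of the gene body), trans, or both.

The whole pipeline — simulation through loop mapping, with a manifest and
deterministic outputs — runs from one configuration:

```r
cfg <- pipeline_config(cohort = spec, seed = 11)
manifest <- run_pipeline(cfg, "out/")
```

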