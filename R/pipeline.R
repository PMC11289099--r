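#' Assemble a pipeline configuration
#'
#' One declarative object drives the whole three-phase pipeline. All
#' analysis defaults are the field-standard parameters: genome-wide 5e-8,
#' module search d = 2 / r = 0.1, top 1% of modules, 10,000 permutations,
#' clumping r^2 < 0.001, colocalization priors 1e-4/1e-4/1e-5, FDR 0.05,
#' 500 kb fine-mapping window. The demo defaults scale the cohort (not the
#' method parameters that have printed values) to synthetic size; the
#' GWAS-hit threshold used for downstream locus definitions is a knob
#' because a synthetic cohort's power differs from a biobank's.
#'
#' @param cohort a [cohort_spec()] (or list of its arguments).
#' @param seed master seed, fanned out per stage.
#' @param alpha GWAS/pQTL genome-wide significance threshold.
#' @param alpha_loci threshold defining "risk loci" for the network phases.
#' @param d,r,top_q module-search neighbor order, increment rate and top
#'   fraction.
#' @param B_perm,B_norm permutation iterations and normalization draws.
#' @param cis_window_bp cis definition window around gene boundaries.
#' @param r2_max LD-clumping threshold.
#' @param p1,p2,p12 colocalization priors.
#' @param fdr_max FDR threshold for MR and enrichment calls.
#' @param finemap_window_bp fine-mapping window flank.
#' @param firth use Firth-penalized logistic regression in the GWAS.
#' @param n_gene_sets synthetic gene-set collection size for the enrichment
#'   stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), seed = 1L, alpha = 5e-8,
                            alpha_loci = 1e-5, d = 2, r = 0.1, top_q = 0.01,
                            B_perm = 10000, B_norm = 10000,
                            cis_window_bp = 1000, r2_max = 0.001,
                            p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                            fdr_max = 0.05, finemap_window_bp = 500000,
                            firth = FALSE, n_gene_sets = 10) {
  if (is.list(cohort) && !inherits(cohort, "cohort_spec"))
    cohort <- do.call(cohort_spec, cohort)
  cfg <- list(cohort = cohort, seed = as.integer(seed), alpha = alpha,
              alpha_loci = alpha_loci, d = d, r = r, top_q = top_q,
              B_perm = B_perm, B_norm = B_norm,
              cis_window_bp = cis_window_bp, r2_max = r2_max,
              p1 = p1, p2 = p2, p12 = p12, fdr_max = fdr_max,
              finemap_window_bp = finemap_window_bp, firth = firth,
              n_gene_sets = n_gene_sets)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file; top-level keys are [pipeline_config()] arguments,
#'   with `cohort` a mapping of [cohort_spec()] arguments.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' Schema and range checks on every parameter; a non-empty issue list blocks
#' [run_pipeline()].
#'
#' @param config a [pipeline_config()].
#' @return Character vector of issues (empty when valid).
#' @export
validate_config <- function(config) {
  issues <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) issues <<- c(issues, msg)
  chk(inherits(config, "pipeline_config") || is.list(config),
      "config must be a pipeline_config list")
  chk(!is.null(config$cohort), "cohort: missing (simulation is the input)")
  if (!is.null(config$cohort))
    tryCatch(validate_cohort_spec(config$cohort),
             error = function(e) chk(FALSE, paste("cohort:", e$message)))
  chk(config$alpha > 0 && config$alpha < 1, "alpha: must be in (0, 1)")
  chk(config$alpha_loci > 0 && config$alpha_loci < 1,
      "alpha_loci: must be in (0, 1)")
  chk(config$d >= 1, "d: must be >= 1")
  chk(config$r > 0, "r: must be > 0")
  chk(config$top_q > 0 && config$top_q <= 1, "top_q: must be in (0, 1]")
  chk(config$B_perm >= 100, "B_perm: must be >= 100")
  chk(config$B_norm >= 100, "B_norm: must be >= 100")
  chk(config$cis_window_bp >= 0, "cis_window_bp: must be >= 0")
  chk(config$r2_max > 0 && config$r2_max <= 1, "r2_max: must be in (0, 1]")
  for (pr in c("p1", "p2", "p12"))
    chk(config[[pr]] > 0 && config[[pr]] < 1,
        paste0(pr, ": must be in (0, 1)"))
  chk(config$fdr_max > 0 && config$fdr_max <= 1, "fdr_max: in (0, 1]")
  chk(config$finemap_window_bp > 0, "finemap_window_bp: must be > 0")
  issues
}

manifest_entry <- function(stage, seed, params, files, n_rows) {
  data.frame(stage = stage, seed = seed,
             params = paste(names(params), unlist(params), sep = "=",
                            collapse = ";"),
             file = basename(files),
             md5 = unname(tools::md5sum(files)),
             n_rows = n_rows, stringsAsFactors = FALSE)
}

count_rows <- function(path) max(length(readLines(path)) - 1L, 0L)

#' Run the three-phase pipeline end to end
#'
#' Executes the stages in dependency order — simulate, gwas, meta, pqtl,
#' gene_scores, modules, neighbors, causal, enrichment, loops — writing each
#' stage's TSV outputs plus a manifest entry (parameters, seed, file hash,
#' row count). A re-run skips stages whose outputs already exist unless
#' `force = TRUE`. Every source of randomness derives from `config$seed`
#' through the per-stage fan-out, so identical configurations reproduce
#' byte-identical outputs. A stage failure halts the run with the failing
#' stage named; earlier outputs are retained.
#'
#' @param config a validated [pipeline_config()].
#' @param out_dir output directory.
#' @param force recompute stages whose outputs already exist.
#' @return Object of class `pg_manifest` (data.frame of manifest entries,
#'   with attribute `recomputed` naming the stages actually run).
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  issues <- validate_config(config)
  if (length(issues))
    stop("configuration invalid:\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  manifest <- list(); recomputed <- character(0)

  stage <- function(name, outputs, params, fun) {
    outputs <- p(outputs)
    if (!force && all(file.exists(outputs))) {
      message("[", name, "] up to date, skipped")
    } else {
      message("[", name, "] running")
      tryCatch(fun(), error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
      recomputed <<- c(recomputed, name)
    }
    manifest[[name]] <<- manifest_entry(
      name, child_seed(config$seed, name), params, outputs,
      vapply(outputs, count_rows, integer(1)))
  }

  spec_a <- config$cohort
  spec_a$seed <- child_seed(config$seed, "cohort_a")
  spec_b <- spec_a
  spec_b$seed <- child_seed(config$seed, "cohort_b")

  ## -- stage 1: simulate two cohorts sharing the disease architecture ------
  stage("simulate",
        c(file.path("cohort_a", c("genotypes.tsv", "variants.tsv",
                                  "phenotype.tsv", "proteins.tsv",
                                  "ppi_edges.tsv", "genes.tsv",
                                  "truth_pqtl.tsv", "truth_disease.tsv",
                                  "truth_module.tsv")),
          file.path("cohort_b", c("genotypes.tsv", "phenotype.tsv"))),
        list(n = spec_a$n_samples, m = spec_a$n_variants), function() {
    ca <- simulate_cohort(spec_a)
    write_cohort(ca, p("cohort_a"))
    gb <- simulate_genotypes(spec_b)
    pb <- simulate_phenotype(gb$genotypes, spec_b,
                             causal_variants = ca$truth$disease$causal_variants,
                             causal_effects = ca$truth$disease$effects)
    dir.create(p("cohort_b"), showWarnings = FALSE)
    write_tsv(data.frame(sample_id = rownames(gb$genotypes), gb$genotypes,
                         check.names = FALSE), p("cohort_b/genotypes.tsv"))
    write_tsv(cbind(pb$covariates, phenotype = pb$phenotype),
              p("cohort_b/phenotype.tsv"))
  })

  read_cohort_files <- function(sub) {
    g <- read_tsv(p(sub, "genotypes.tsv"))
    geno <- as.matrix(g[, -1]); rownames(geno) <- g$sample_id
    ph <- read_tsv(p(sub, "phenotype.tsv"))
    list(genotypes = geno, phenotype = ph$phenotype,
         covariates = ph[, setdiff(names(ph), "phenotype")])
  }

  variants <- function() read_tsv(p("cohort_a/variants.tsv"))
  annotation <- function() read_gene_annotation(p("cohort_a/genes.tsv"))

  ## -- stage 2: per-cohort GWAS (QC + covariate-adjusted logistic) ---------
  stage("gwas", c("gwas_a.tsv", "gwas_b.tsv"),
        list(firth = config$firth), function() {
    vt <- variants()
    for (sub in c("a", "b")) {
      co <- read_cohort_files(paste0("cohort_", sub))
      qc <- variant_qc_filter(co$genotypes)
      covs <- co$covariates[, c("sex", "yob", paste0("pc", 1:10))]
      ss <- gwas_scan(co$genotypes[, qc$keep, drop = FALSE], co$phenotype,
                      vt, covariates = covs, firth = config$firth,
                      mean_impute = TRUE)
      write_sumstats(ss, p(paste0("gwas_", sub, ".tsv")))
    }
  })

  ## -- stage 3: fixed-effects meta-analysis + hit list ---------------------
  stage("meta", c("meta.tsv", "gwas_hits.tsv"),
        list(alpha_loci = config$alpha_loci), function() {
    a <- read_sumstats(p("gwas_a.tsv")); b <- read_sumstats(p("gwas_b.tsv"))
    meta <- meta_fixed(a, b)
    # carry positions/alleles from study a for downstream region work
    meta <- merge(a[, c("variant_id", "chrom", "pos", "effect_allele",
                        "other_allele", "eaf", "n")], meta,
                  by = "variant_id")
    write_tsv(meta, p("meta.tsv"))
    hits <- genomewide_significant(meta, alpha = config$alpha_loci)
    write_tsv(hits, p("gwas_hits.tsv"))
  })

  ## -- stage 4: pQTL scan, cis/trans, GWAS intersection, architecture ------
  stage("pqtl", c("pqtl.tsv", "gwas_pqtl_pairs.tsv", "pqtl_proteins.txt",
                  "architecture.tsv"),
        list(alpha = config$alpha, cis_window = config$cis_window_bp),
        function() {
    co <- read_cohort_files("cohort_a")
    prot <- read_tsv(p("cohort_a/proteins.tsv"))
    pm <- as.matrix(prot[, -1]); rownames(pm) <- prot$sample_id
    rec <- pqtl_scan(pm, co$genotypes, co$covariates, alpha = config$alpha)
    rec <- classify_cis_trans(rec, variants(), annotation(),
                              window_bp = config$cis_window_bp)
    write_tsv(rec, p("pqtl.tsv"))
    hits <- read_tsv(p("gwas_hits.tsv"))
    ix <- intersect_gwas_pqtl(hits, rec)
    write_tsv(ix$pairs, p("gwas_pqtl_pairs.tsv"))
    writeLines(ix$proteins, p("pqtl_proteins.txt"))
    arch <- architecture_summary(rec)
    write_tsv(data.frame(metric = names(arch$protein_status),
                         value = as.integer(arch$protein_status)),
              p("architecture.tsv"))
  })

  ## -- stage 5: LD-aware gene-based scores ---------------------------------
  stage("gene_scores", "gene_scores.tsv", list(flank = 0), function() {
    co <- read_cohort_files("cohort_a")
    meta <- read_tsv(p("meta.tsv"))
    snp_map <- assign_snps_to_genes(variants(), annotation())
    gs <- gene_scores(meta, snp_map, genotypes = co$genotypes)
    write_tsv(gs, p("gene_scores.tsv"))
  })

  ## -- stage 6: dense-module search on the weighted PPI --------------------
  stage("modules", c("modules.tsv", "top_modules.tsv", "top_proteins.txt",
                     "module_pqtl_overlap.tsv"),
        list(d = config$d, r = config$r, top_q = config$top_q), function() {
    edges <- read_edge_list(p("cohort_a/ppi_edges.tsv"))
    gs <- read_tsv(p("gene_scores.tsv"))
    ppi <- build_weighted_ppi(edges, gs)
    mods <- dense_module_search(ppi, d = config$d, r = config$r)
    mods <- normalize_modules(mods, ppi, B_norm = config$B_norm,
                              seed = child_seed(config$seed, "modules"))
    write_tsv(as.data.frame(mods), p("modules.tsv"))
    top <- top_percent_modules(mods, q = config$top_q)
    write_tsv(as.data.frame(top$modules), p("top_modules.tsv"))
    writeLines(top$proteins, p("top_proteins.txt"))
    pqtl_prot <- readLines(p("pqtl_proteins.txt"))
    ov <- overlap_test(pqtl_prot, top$proteins,
                       universe_size = igraph::vcount(ppi))
    write_tsv(data.frame(overlap = ov$overlap, n_pqtl = ov$n_a,
                         n_top = ov$n_b, universe = ov$universe, p = ov$p,
                         odds_ratio = ov$odds_ratio),
              p("module_pqtl_overlap.tsv"))
  })

  risk_locus_genes <- function() {
    hits <- read_tsv(p("gwas_hits.tsv"))
    if (!nrow(hits)) return(character(0))
    snp_map <- assign_snps_to_genes(variants(), annotation())
    sort(unique(unlist(lapply(names(snp_map), function(g)
      if (any(snp_map[[g]] %in% hits$variant_id)) g else NULL))))
  }

  ## -- stage 7: first-degree neighborhood + permutation enrichment ---------
  stage("neighbors", c("neighbor_nodes.tsv", "neighbor_enrichment.tsv"),
        list(B = config$B_perm), function() {
    edges <- read_edge_list(p("cohort_a/ppi_edges.tsv"))
    gs <- read_tsv(p("gene_scores.tsv"))
    ppi <- build_weighted_ppi(edges, gs)
    loci <- risk_locus_genes()
    pqtl_prot <- readLines(p("pqtl_proteins.txt"))
    sub <- first_degree_network(ppi, loci, pqtl_proteins = pqtl_prot)
    write_tsv(data.frame(gene = igraph::V(sub)$name,
                         is_risk_locus = igraph::V(sub)$is_risk_locus,
                         is_pqtl = igraph::V(sub)$is_pqtl),
              p("neighbor_nodes.tsv"))
    neighbor_set <- setdiff(igraph::V(sub)$name, loci)
    pe <- permutation_enrichment(ppi, neighbor_set, pqtl_prot,
                                 B = config$B_perm,
                                 seed = child_seed(config$seed, "perm"))
    write_tsv(data.frame(p_obs = pe$p_obs, empirical_p = pe$empirical_p,
                         B = pe$B, overlap = pe$overlap),
              p("neighbor_enrichment.tsv"))
  })

  ## -- stage 8: MR + pleiotropy + colocalization + fine-mapping ------------
  stage("causal", c("mr.tsv", "coloc.tsv", "credible_sets.tsv"),
        list(r2 = config$r2_max, p12 = config$p12), function() {
    co <- read_cohort_files("cohort_a")
    prot <- read_tsv(p("cohort_a/proteins.tsv"))
    pm <- as.matrix(prot[, -1]); rownames(pm) <- prot$sample_id
    vt <- variants(); ann <- annotation()
    meta <- read_tsv(p("meta.tsv"))
    outcome <- data.frame(variant_id = meta$variant_id, chrom = meta$chrom,
                          pos = meta$pos,
                          effect_allele = meta$effect_allele,
                          other_allele = meta$other_allele, eaf = meta$eaf,
                          beta = meta$beta_meta, se = meta$se_meta,
                          p = meta$p_meta, n = meta$n,
                          stringsAsFactors = FALSE)
    pqtl <- read_tsv(p("pqtl.tsv"))
    cis_prot <- unique(pqtl$protein[pqtl$cis_flag == "cis"])
    exposures <- list()
    for (g in cis_prot) {
      a <- ann[ann$gene == g, ]
      win <- vt$variant_id[norm_chrom(vt$chrom) == norm_chrom(a$chrom) &
        vt$pos >= a$start + 1L - config$cis_window_bp &
        vt$pos <= a$end + config$cis_window_bp]
      if (!length(win)) next
      exposures[[g]] <- pqtl_sumstats(pm[, g],
                                      co$genotypes[, win, drop = FALSE],
                                      co$covariates, vt)
    }
    R <- if (ncol(co$genotypes) > 1)
      stats::cor(imputed_dosage(co$genotypes)) else NULL
    mr <- mr_analysis(exposures, outcome, R = R, r2_max = config$r2_max,
                      alpha_instrument = config$alpha,
                      seed = child_seed(config$seed, "mr"))
    if (is.null(mr))
      mr <- data.frame(protein = character(0), method = character(0),
                       n_snp = integer(0), beta = numeric(0),
                       se = numeric(0), p = numeric(0), fdr = numeric(0))
    pl <- attr(mr, "pleiotropy")
    mr$pleiotropy_p <- if (nrow(mr)) unname(pl[mr$protein]) else numeric(0)
    write_tsv(as.data.frame(mr), p("mr.tsv"))
    # colocalize the meta-GWAS with each MR protein's cis region
    cl <- lapply(names(exposures), function(g) {
      cc <- coloc_abf(outcome, exposures[[g]], p1 = config$p1,
                      p2 = config$p2, p12 = config$p12,
                      type1 = "cc", type2 = "quant", region = g)
      data.frame(region = g, t(cc$pp), n_snps = cc$n_snps)
    })
    cl <- if (length(cl)) do.call(rbind, cl) else
      data.frame(region = character(0))
    write_tsv(cl, p("coloc.tsv"))
    # fine-map a window around each GWAS hit
    hits <- read_tsv(p("gwas_hits.tsv"))
    fm <- lapply(hits$variant_id, function(v) {
      reg <- finemap_window(outcome, v, window_bp = config$finemap_window_bp)
      f <- finemap_single_causal(reg, type = "cc", region = v)
      cbind(region = v, f$pip)
    })
    fm <- if (length(fm)) do.call(rbind, fm) else
      data.frame(region = character(0), variant_id = character(0),
                 pip = numeric(0), in_cs = logical(0))
    write_tsv(fm, p("credible_sets.tsv"))
  })

  ## -- stage 9: pathway enrichment + evidence triangulation ----------------
  stage("enrichment", c("gene_sets.gmt", "enrichment.tsv", "evidence.tsv"),
        list(fdr_max = config$fdr_max, n_sets = config$n_gene_sets),
        function() {
    ann <- annotation()
    planted <- read_tsv(p("cohort_a/truth_module.tsv"))$gene
    set.seed(child_seed(config$seed, "gene_sets"))
    sets <- lapply(seq_len(config$n_gene_sets), function(i)
      sample(ann$gene, min(15, max(5, rpois(1, 10)))))
    names(sets) <- sprintf("SET%02d", seq_len(config$n_gene_sets))
    sets$PLANTED_MODULE <- planted
    write_gmt(sets, p("gene_sets.gmt"))
    pqtl_prot <- readLines(p("pqtl_proteins.txt"))
    enr <- pathway_enrichment(pqtl_prot, sets, background = ann$gene,
                              fdr_max = config$fdr_max)
    write_tsv(enr, p("enrichment.tsv"))
    top_prot <- readLines(p("top_proteins.txt"))
    nb <- read_tsv(p("neighbor_nodes.tsv"))
    ev <- triangulate(pqtl_prot,
                      intersect(top_prot, pqtl_prot),
                      intersect(nb$gene[!nb$is_risk_locus], pqtl_prot))
    write_tsv(as.data.frame(ev), p("evidence.tsv"))
  })

  ## -- stage 10: variant -> chromatin-loop -> distal-gene mapping ----------
  stage("loops", c("loops.tsv", "variant_loop_genes.tsv"), list(),
        function() {
    vt <- variants(); ann <- annotation()
    hits <- read_tsv(p("gwas_hits.tsv"))
    set.seed(child_seed(config$seed, "loops"))
    # synthetic loop anchors: anchor 1 over a hit variant, anchor 2 over a
    # distal gene on the same chromosome
    mk <- lapply(utils::head(hits$variant_id, 10), function(v) {
      i <- match(v, vt$variant_id)
      same_chr <- ann[norm_chrom(ann$chrom) == norm_chrom(vt$chrom[i]), ]
      distal <- same_chr[same_chr$start > vt$pos[i] + 2000 |
                           same_chr$end < vt$pos[i] - 2000, ]
      if (!nrow(distal)) return(NULL)
      gidx <- sample(nrow(distal), 1)
      data.frame(chrom1 = vt$chrom[i], start1 = vt$pos[i] - 500,
                 end1 = vt$pos[i] + 500, chrom2 = vt$chrom[i],
                 start2 = distal$start[gidx], end2 = distal$end[gidx],
                 celltype = sample(c("neuron", "microglia", "oligo"), 1),
                 genes1 = "", genes2 = distal$gene[gidx],
                 stringsAsFactors = FALSE)
    })
    loops <- do.call(rbind, mk)
    if (is.null(loops))
      loops <- data.frame(chrom1 = character(0), start1 = integer(0),
                          end1 = integer(0), chrom2 = character(0),
                          start2 = integer(0), end2 = integer(0),
                          celltype = character(0), genes1 = character(0),
                          genes2 = character(0))
    write_tsv(loops, p("loops.tsv"))
    if (nrow(loops)) {
      loops$genes1 <- lapply(strsplit(loops$genes1, ";"), norm_symbols)
      loops$genes2 <- lapply(strsplit(loops$genes2, ";"), norm_symbols)
      links <- map_variants_to_loops(vt, loops)
    } else {
      links <- data.frame(variant_id = character(0),
                          cell_type = character(0), gene = character(0),
                          anchor = integer(0))
    }
    write_tsv(links, p("variant_loop_genes.tsv"))
  })

  out <- do.call(rbind, manifest)
  rownames(out) <- NULL
  write_tsv(out, p("manifest.tsv"))
  attr(out, "recomputed") <- recomputed
  class(out) <- c("pg_manifest", "data.frame")
  out
}

#' @export
print.pg_manifest <- function(x, ...) {
  cat("Pipeline manifest:", length(unique(x$stage)), "stages,",
      nrow(x), "output files\n")
  cat("  recomputed this run:",
      if (length(attr(x, "recomputed")))
        paste(attr(x, "recomputed"), collapse = ", ") else "(none)", "\n")
  invisible(x)
}
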