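#' Specify a synthetic cohort
#'
#' Collects every knob of the synthetic-data generator in one validated list.
#' The generator emulates the statistical structure the downstream analyses
#' assume: LD-blocked genotypes, a liability-threshold binary trait with
#' sparse causal variants, protein abundances (NPX-like, log scale) carrying
#' cis and trans genetic effects plus age/sex covariate effects, and a
#' scale-free protein-protein interaction network with a planted module.
#'
#' @param n_samples number of individuals.
#' @param n_variants number of biallelic variants.
#' @param n_blocks number of mutually independent LD blocks; variants are
#'   partitioned into contiguous blocks, one block per chromosome.
#' @param rho within-block adjacent-variant latent correlation, in `[0, 1)`.
#' @param maf_range length-2 numeric, minor-allele frequency range in (0, 0.5].
#' @param n_causal_disease number of causal variants on the liability scale.
#' @param h2_liability liability-scale heritability, in `[0, 1)`.
#' @param prevalence case prevalence used to threshold the liability, (0, 1).
#' @param n_proteins number of assayed proteins (each mapped 1:1 to a gene).
#' @param n_genes number of annotated genes (defaults to `n_proteins`; must be
#'   at least `n_proteins`). Gene names double as PPI node names.
#' @param cis_effect_sd,trans_effect_sd scale of cis / trans genetic effects
#'   on protein abundance (per-allele NPX units; effects drawn N(0, sd^2)).
#' @param n_trans_per_protein number of trans effects per protein.
#' @param noise_sd residual abundance noise SD.
#' @param missing_rate genotype missingness injected uniformly at random.
#' @param ppi_nodes,ppi_attach_m,planted_module_size scale-free PPI size,
#'   preferential-attachment degree, and planted module size.
#' @param plant_in_module if `TRUE`, disease-causal variants are drawn from
#'   SNPs inside genes of the planted module, so the module carries enriched
#'   low gene p-values by construction.
#' @param seed master RNG seed, fanned out per stage via [child_seed()].
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 1000, n_variants = 200, n_blocks = 10,
                        rho = 0.8, maf_range = c(0.05, 0.5),
                        n_causal_disease = 5, h2_liability = 0.3,
                        prevalence = 0.1, n_proteins = 30, n_genes = NULL,
                        cis_effect_sd = 0.4, trans_effect_sd = 0.2,
                        n_trans_per_protein = 1, noise_sd = 1,
                        missing_rate = 0, ppi_nodes = NULL,
                        ppi_attach_m = 2, planted_module_size = 8,
                        plant_in_module = TRUE, seed = 1L) {
  n_genes <- n_genes %||% n_proteins
  ppi_nodes <- ppi_nodes %||% n_genes
  spec <- list(n_samples = n_samples, n_variants = n_variants,
               n_blocks = n_blocks, rho = rho, maf_range = maf_range,
               n_causal_disease = n_causal_disease,
               h2_liability = h2_liability, prevalence = prevalence,
               n_proteins = n_proteins, n_genes = n_genes,
               cis_effect_sd = cis_effect_sd, trans_effect_sd = trans_effect_sd,
               n_trans_per_protein = n_trans_per_protein, noise_sd = noise_sd,
               missing_rate = missing_rate, ppi_nodes = ppi_nodes,
               ppi_attach_m = ppi_attach_m,
               planted_module_size = planted_module_size,
               plant_in_module = plant_in_module, seed = as.integer(seed))
  validate_cohort_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
    if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
        maf_range[1] > maf_range[2])
      stop("maf_range must be an increasing pair in (0, 0.5]", call. = FALSE)
    if (n_causal_disease > n_variants)
      stop("n_causal_disease must not exceed n_variants", call. = FALSE)
    if (h2_liability < 0 || h2_liability >= 1)
      stop("h2_liability must be in [0, 1)", call. = FALSE)
    if (prevalence <= 0 || prevalence >= 1)
      stop("prevalence must be in (0, 1)", call. = FALSE)
    if (prevalence * n_samples < 1)
      stop("prevalence * n_samples must be >= 1", call. = FALSE)
    if (any(c(cis_effect_sd, trans_effect_sd, noise_sd) < 0))
      stop("effect and noise scales must be >= 0", call. = FALSE)
    if (missing_rate < 0 || missing_rate >= 1)
      stop("missing_rate must be in [0, 1)", call. = FALSE)
    if (n_genes < n_proteins)
      stop("n_genes must be >= n_proteins", call. = FALSE)
    if (ppi_attach_m >= ppi_nodes)
      stop("ppi_attach_m must be smaller than ppi_nodes", call. = FALSE)
    if (planted_module_size >= ppi_nodes)
      stop("planted_module_size must be smaller than ppi_nodes", call. = FALSE)
  })
  invisible(spec)
}

#' Simulate LD-blocked genotype dosages
#'
#' Two independent haplotypes per individual are generated as first-order
#' autoregressive latent Gaussians within each contiguous LD block
#' (blocks are mutually independent) and thresholded at the variant's allele
#' frequency, so Hardy-Weinberg holds at each site and adjacent variants are
#' correlated with a tunable strength. Dosage = sum of the two haplotypes.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `genotypes` (samples x variants integer matrix, NA for
#'   missing) and `variants` (data.frame: variant_id, chrom, pos,
#'   effect_allele, other_allele, frequency, block).
#' @export
simulate_genotypes <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(child_seed(spec$seed, "genotypes"))
  n <- spec$n_samples; m <- spec$n_variants
  maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  block <- sort(rep_len(seq_len(spec$n_blocks), m))
  thr <- stats::qnorm(maf)
  dosage <- matrix(0L, n, m)
  for (h in 1:2) {
    z <- matrix(stats::rnorm(n * m), n, m)
    for (b in unique(block)) {
      idx <- which(block == b)
      if (length(idx) > 1 && spec$rho > 0) {
        for (j in idx[-1])
          z[, j] <- spec$rho * z[, j - 1] + sqrt(1 - spec$rho^2) * z[, j]
      }
    }
    dosage <- dosage + (sweep(z, 2, thr, "<")) * 1L
  }
  storage.mode(dosage) <- "integer"
  if (spec$missing_rate > 0) {
    miss <- stats::runif(n * m) < spec$missing_rate
    dosage[miss] <- NA_integer_
  }
  pos_in_block <- stats::ave(seq_len(m), block, FUN = seq_along)
  variants <- data.frame(
    variant_id = sprintf("v%05d", seq_len(m)),
    chrom = as.character(block),
    pos = as.integer(pos_in_block * 1000L),
    effect_allele = "A", other_allele = "G",
    frequency = maf, block = block,
    stringsAsFactors = FALSE)
  colnames(dosage) <- variants$variant_id
  rownames(dosage) <- sprintf("s%05d", seq_len(n))
  list(genotypes = dosage, variants = variants)
}

#' Simulate a liability-threshold case/control phenotype with covariates
#'
#' Liability = standardized causal-dosage score scaled to the target
#' heritability, plus small fixed covariate loadings, plus Gaussian noise;
#' an individual is a case iff its (empirically standardized) liability
#' exceeds the `1 - prevalence` normal quantile.
#'
#' @param genotypes dosage matrix from [simulate_genotypes()].
#' @param spec a [cohort_spec()].
#' @param causal_variants optional character vector of column names to use as
#'   causal variants (defaults to a random draw of `n_causal_disease`).
#' @param causal_effects optional effect sizes for `causal_variants` (shared
#'   across replicate cohorts of the same disease architecture).
#' @return A list with `phenotype` (0/1 integer), `covariates` (data.frame:
#'   age, sex, yob, pc1..pc10) and `truth` (causal variants, effects,
#'   covariate loadings, threshold).
#' @export
simulate_phenotype <- function(genotypes, spec, causal_variants = NULL,
                               causal_effects = NULL) {
  set.seed(child_seed(spec$seed, "phenotype"))
  n <- nrow(genotypes)
  age <- stats::runif(n, 40, 70)
  sex <- stats::rbinom(n, 1, 0.5)
  yob <- as.integer(round(2006 - age))
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  loadings <- c(age = 0.005, sex = 0.10, pc = 0.02)
  cov_term <- (age - mean(age)) * loadings["age"] + sex * loadings["sex"] +
    rowSums(pcs) * loadings["pc"]

  if (spec$n_causal_disease > 0 && spec$h2_liability > 0) {
    causal <- causal_variants %||%
      sample(colnames(genotypes), spec$n_causal_disease)
    eff <- causal_effects %||% stats::rnorm(length(causal))
    g <- imputed_dosage(genotypes[, causal, drop = FALSE]) %*% eff
    g <- if (stats::sd(g) > 0) as.numeric(scale(g)) * sqrt(spec$h2_liability)
         else numeric(n)
  } else {
    causal <- character(0); eff <- numeric(0); g <- numeric(n)
  }
  liability <- g + cov_term + stats::rnorm(n, sd = sqrt(1 - spec$h2_liability))
  liability <- as.numeric(scale(liability))
  thr <- stats::qnorm(1 - spec$prevalence)
  phenotype <- as.integer(liability > thr)
  covariates <- data.frame(sample_id = rownames(genotypes), age = age,
                           sex = sex, yob = yob, pcs,
                           stringsAsFactors = FALSE)
  list(phenotype = phenotype, covariates = covariates,
       truth = list(causal_variants = causal, effects = eff,
                    covariate_loadings = loadings, threshold = thr))
}

# mean-impute missing dosages (used where a complete matrix is required)
imputed_dosage <- function(g) {
  g <- as.matrix(g); storage.mode(g) <- "double"
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu[idx[, 2]]
  }
  g
}

#' Tile gene annotation intervals over a simulated variant grid
#'
#' Genes are consecutive runs of variants within a chromosome, written in the
#' BED-like convention (0-based half-open). Every protein downstream maps 1:1
#' to the gene of the same name.
#'
#' @param variants variant table from [simulate_genotypes()].
#' @param n_genes number of genes to tile.
#' @return data.frame: chrom, start, end, gene (0-based half-open intervals).
#' @export
simulate_gene_annotation <- function(variants, n_genes) {
  m <- nrow(variants)
  if (n_genes > m) stop("n_genes may not exceed the number of variants",
                        call. = FALSE)
  grp <- sort(rep_len(seq_len(n_genes), m))
  # keep each gene inside one chromosome: re-cut runs at chromosome bounds,
  # assigning the gene to the chromosome holding most of its variants
  ann <- do.call(rbind, lapply(split(seq_len(m), grp), function(idx) {
    chrom <- names(sort(table(variants$chrom[idx]), decreasing = TRUE))[1]
    idx <- idx[variants$chrom[idx] == chrom]
    data.frame(chrom = chrom,
               start = min(variants$pos[idx]) - 500L,   # 0-based start
               end = max(variants$pos[idx]) + 500L,     # half-open end
               stringsAsFactors = FALSE)
  }))
  ann$gene <- sprintf("G%04d", seq_len(n_genes))
  rownames(ann) <- NULL
  ann[, c("chrom", "start", "end", "gene")]
}

#' Simulate protein abundances with cis and trans genetic effects
#'
#' Each protein's abundance is the sum of its true cis effects (variants
#' inside the protein's gene interval), trans effects (variants elsewhere),
#' covariate terms (age, age^2, sex, age*sex with small fixed loadings) and
#' Gaussian noise. The truth table records every nonzero effect.
#'
#' @param genotypes dosage matrix.
#' @param covariates covariate data.frame with `age` and `sex`.
#' @param spec a [cohort_spec()].
#' @param annotation gene annotation (BED-like) from
#'   [simulate_gene_annotation()]; the first `n_proteins` genes are assayed.
#' @param variants variant table (chrom/pos lookup).
#' @param truth optional pre-specified truth table (data.frame: variant_id,
#'   protein, beta, cis) overriding the random draw.
#' @return list with `proteins` (samples x proteins matrix, columns named by
#'   gene) and `truth` (the pQTL truth table).
#' @export
simulate_proteins <- function(genotypes, covariates, spec, annotation,
                              variants, truth = NULL) {
  set.seed(child_seed(spec$seed, "proteins"))
  prot_genes <- annotation$gene[seq_len(spec$n_proteins)]
  if (anyNA(prot_genes)) stop("protein without gene annotation", call. = FALSE)
  if (is.null(truth)) {
    rows <- list()
    for (g in prot_genes) {
      a <- annotation[annotation$gene == g, ]
      in_gene <- variants$variant_id[
        variants$chrom == a$chrom & variants$pos > a$start &
          variants$pos <= a$end]
      if (spec$cis_effect_sd > 0 && length(in_gene)) {
        v <- if (length(in_gene) == 1) in_gene else sample(in_gene, 1)
        rows[[length(rows) + 1]] <- data.frame(
          variant_id = v, protein = g,
          beta = stats::rnorm(1, 0, spec$cis_effect_sd), cis = TRUE)
      }
      out_gene <- setdiff(variants$variant_id, in_gene)
      if (spec$trans_effect_sd > 0 && spec$n_trans_per_protein > 0 &&
          length(out_gene)) {
        vs <- sample(out_gene, min(spec$n_trans_per_protein, length(out_gene)))
        rows[[length(rows) + 1]] <- data.frame(
          variant_id = vs, protein = g,
          beta = stats::rnorm(length(vs), 0, spec$trans_effect_sd), cis = FALSE)
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(variant_id = character(0), protein = character(0),
                 beta = numeric(0), cis = logical(0))
  }
  n <- nrow(genotypes)
  age <- covariates$age; sex <- covariates$sex
  loadings <- c(age = 0.01, age2 = 2e-4, sex = 0.2, age_sex = 0.002)
  cov_term <- (age - 55) * loadings["age"] + (age - 55)^2 * loadings["age2"] +
    sex * loadings["sex"] + (age - 55) * sex * loadings["age_sex"]
  gd <- imputed_dosage(genotypes)
  proteins <- matrix(stats::rnorm(n * spec$n_proteins, sd = spec$noise_sd),
                     n, spec$n_proteins,
                     dimnames = list(rownames(genotypes), prot_genes))
  proteins <- proteins + cov_term
  if (nrow(truth)) {
    for (k in seq_len(nrow(truth))) {
      proteins[, truth$protein[k]] <- proteins[, truth$protein[k]] +
        gd[, truth$variant_id[k]] * truth$beta[k]
    }
  }
  attr(truth, "covariate_loadings") <- loadings
  list(proteins = proteins, truth = truth)
}

#' Simulate a scale-free PPI network with a planted connected module
#'
#' Preferential attachment starting from a connected seed pair: node t
#' (t = 3..n) attaches to `min(attach_m, t - 1)` distinct existing nodes with
#' probability proportional to current degree, giving exactly
#' `1 + sum(min(attach_m, t - 1))` edges. A connected planted node set is
#' grown by breadth-first search from a random start and recorded.
#'
#' @param n_nodes,attach_m,planted_module_size construction parameters.
#' @param seed RNG seed.
#' @param gene_names optional node names (defaults to `G0001`...).
#' @return list with `edges` (two-column data.frame), `nodes` (character)
#'   and `planted` (character node set, connected).
#' @export
simulate_ppi <- function(n_nodes, attach_m = 2, planted_module_size = 8,
                         seed = 1L, gene_names = NULL) {
  if (attach_m >= n_nodes) stop("attach_m must be < n_nodes", call. = FALSE)
  if (planted_module_size >= n_nodes)
    stop("planted_module_size must be < n_nodes", call. = FALSE)
  set.seed(child_seed(seed, "ppi"))
  deg <- integer(n_nodes); deg[1:2] <- 1L
  from <- integer(0); to <- integer(0)
  from[1] <- 1L; to[1] <- 2L
  for (t in 3:n_nodes) {
    k <- min(attach_m, t - 1L)
    targets <- sample(seq_len(t - 1L), k, prob = deg[seq_len(t - 1L)])
    from <- c(from, rep(t, k)); to <- c(to, targets)
    deg[targets] <- deg[targets] + 1L; deg[t] <- k
  }
  nodes <- gene_names %||% sprintf("G%04d", seq_len(n_nodes))
  if (length(nodes) != n_nodes) stop("gene_names length mismatch", call. = FALSE)
  # grow a connected planted set by BFS from a random start
  adj <- split(c(to, from), c(from, to))
  start <- sample(n_nodes, 1)
  planted <- start; frontier <- start
  while (length(planted) < planted_module_size) {
    nbr <- setdiff(unique(unlist(adj[as.character(frontier)])), planted)
    if (!length(nbr)) { frontier <- planted; next }
    take <- utils::head(sample(nbr), planted_module_size - length(planted))
    planted <- c(planted, take); frontier <- take
  }
  list(edges = data.frame(from = nodes[from], to = nodes[to],
                          stringsAsFactors = FALSE),
       nodes = nodes, planted = sort(nodes[planted]))
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates genotypes, gene annotation, phenotype, proteins and the PPI
#' into one object. When `spec$plant_in_module` is `TRUE`, disease-causal
#' variants are drawn from SNPs inside genes of the planted PPI module, so
#' the module carries enriched low gene-based p-values by construction.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `pg_cohort`: genotypes, variants, phenotype,
#'   covariates, proteins, annotation, ppi, truth.
#' @export
simulate_cohort <- function(spec) {
  geno <- simulate_genotypes(spec)
  annotation <- simulate_gene_annotation(geno$variants, spec$n_genes)
  ppi <- simulate_ppi(spec$ppi_nodes, spec$ppi_attach_m,
                      spec$planted_module_size, seed = spec$seed,
                      gene_names = if (spec$ppi_nodes == spec$n_genes)
                        annotation$gene else NULL)
  causal <- NULL
  if (spec$plant_in_module && spec$n_causal_disease > 0) {
    set.seed(child_seed(spec$seed, "plant"))
    planted_ann <- annotation[annotation$gene %in% ppi$planted, ]
    pool <- unlist(lapply(seq_len(nrow(planted_ann)), function(i) {
      a <- planted_ann[i, ]
      geno$variants$variant_id[geno$variants$chrom == a$chrom &
        geno$variants$pos > a$start & geno$variants$pos <= a$end]
    }))
    pool <- unique(pool)
    if (length(pool) >= spec$n_causal_disease)
      causal <- sample(pool, spec$n_causal_disease)
  }
  pheno <- simulate_phenotype(geno$genotypes, spec, causal_variants = causal)
  prot <- simulate_proteins(geno$genotypes, pheno$covariates, spec,
                            annotation, geno$variants)
  out <- list(genotypes = geno$genotypes, variants = geno$variants,
              phenotype = pheno$phenotype, covariates = pheno$covariates,
              proteins = prot$proteins, annotation = annotation, ppi = ppi,
              truth = list(disease = pheno$truth, pqtl = prot$truth,
                           planted_module = ppi$planted),
              spec = spec)
  class(out) <- "pg_cohort"
  out
}

#' @export
print.pg_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$genotypes), "samples,",
      ncol(x$genotypes), "variants,", ncol(x$proteins), "proteins\n")
  cat("  cases:", sum(x$phenotype), " controls:", sum(1 - x$phenotype), "\n")
  cat("  causal variants:", length(x$truth$disease$causal_variants),
      " true pQTL effects:", nrow(x$truth$pqtl), "\n")
  cat("  PPI:", length(x$ppi$nodes), "nodes,", nrow(x$ppi$edges),
      "edges; planted module size", length(x$ppi$planted), "\n")
  invisible(x)
}
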