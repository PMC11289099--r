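# QC, exact HWE, logistic association (ML + Firth), fixed-effects meta.

test_that("exact HWE test matches enumeration oracle and edge cases", {
  expect_equal(hwe_test(25, 50, 25), 1.0)      # modal table
  expect_equal(hwe_test(100, 0, 0), 1.0)       # monomorphic
  expect_lt(hwe_test(0, 100, 0), 1e-6)         # extreme heterozygote excess
  # agreement with the independent choose()-based enumeration
  for (cnt in list(c(25, 50, 25), c(0, 100, 0), c(40, 20, 40),
                   c(7, 3, 1), c(5, 5, 5))) {
    expect_equal(hwe_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
  expect_error(hwe_test(0, 0, 0), "zero")
  expect_error(hwe_test(-1, 2, 3), "non-negative")
})

test_that("QC filter removes variants by each criterion with correct counts", {
  set.seed(1)
  n <- 2000
  g <- sapply(1:10, function(j) rbinom(n, 2, 0.3))
  colnames(g) <- paste0("v", 1:10)
  # v1 fails MAF, v2 fails call rate, v3 fails HWE; others clean
  g[, 1] <- rbinom(n, 2, 0.0004)
  g[sample(n, 150), 2] <- NA
  g[, 3] <- rep(1L, n)                      # all heterozygous: HWE fails
  res <- variant_qc_filter(g)
  expect_setequal(res$keep, paste0("v", 4:10))
  expect_identical(sum(res$report), 3L)
  expect_identical(unname(res$report["maf"]), 1L)
  expect_identical(unname(res$report["call_rate"]), 1L)
  expect_identical(unname(res$report["hwe"]), 1L)
  expect_match(res$qc$reason[1], "maf")
})

test_that("MAF 0.0005 fails the default 0.1% filter; zero thresholds retain
           everything", {
  set.seed(2)
  g <- cbind(v1 = rbinom(50000, 2, 0.0005), v2 = rbinom(50000, 2, 0.25))
  res <- variant_qc_filter(g)
  expect_false("v1" %in% res$keep)
  expect_match(res$qc$reason[res$qc$variant_id == "v1"], "maf")
  all_kept <- variant_qc_filter(g, maf_min = 0, cr_min = 0, hwe_min = 0)
  expect_setequal(all_kept$keep, c("v1", "v2"))
})

test_that("logistic association matches the closed-form 2x2 log odds ratio", {
  set.seed(3)
  x <- rbinom(3000, 1, 0.4)
  y <- rbinom(3000, 1, plogis(-1 + 0.8 * x))
  r <- logistic_assoc(y, x)
  tab <- table(x, y)
  log_or <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  expect_lt(abs(r$beta - log_or), 1e-6)
})

test_that("duplicated dosage as covariate is a rank-deficiency error", {
  set.seed(4)
  x <- rbinom(500, 2, 0.3)
  y <- rbinom(500, 1, 0.3)
  expect_error(logistic_assoc(y, x, covariates = cbind(dup = x)),
               "rank-deficient")
})

test_that("Firth regression returns finite estimates under complete
           separation", {
  x <- c(rep(0, 50), rep(2, 50))
  y <- c(rep(0, 50), rep(1, 50))
  expect_error(logistic_assoc(y, x, firth = FALSE), "separation")
  r <- logistic_assoc(y, x, firth = TRUE)
  expect_true(is.finite(r$beta) && is.finite(r$se))
  expect_identical(r$method, "firth")
})

test_that("logistic association type-I error is calibrated", {
  set.seed(5)
  n <- 2000
  hits <- 0L
  reps <- 200L
  covs <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  for (i in seq_len(reps)) {
    x <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, 0.2)
    r <- logistic_assoc(y, x, covariates = covs)
    if (r$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.02)
  expect_lte(hits / reps, 0.08)
})

test_that("fixed-effects meta matches hand-computed weighted means", {
  a <- make_sumstats("v1", beta = 0.5, se = 0.1)
  b <- make_sumstats("v1", beta = 0.5, se = 0.1)
  m <- meta_fixed(a, b)
  expect_equal(m$beta_meta, 0.5)
  expect_equal(m$se_meta, 0.1 / sqrt(2))
  a2 <- make_sumstats("v1", beta = 0.2, se = 0.1)
  b2 <- make_sumstats("v1", beta = 0.6, se = 0.3)
  m2 <- meta_fixed(a2, b2)
  expect_equal(m2$beta_meta, 0.24, tolerance = 1e-12)
  expect_equal(signif(m2$se_meta, 3), 0.0949)
  expect_identical(m2$direction, "++")
})

test_that("meta is an intersection, permutation-invariant, and equals the
           weighted-mean oracle", {
  set.seed(6)
  ids <- sprintf("v%02d", 1:20)
  a <- make_sumstats(c(ids, "only_a"), beta = rnorm(21), se = runif(21, .05, .2))
  b <- make_sumstats(c(ids, "only_b"), beta = rnorm(21), se = runif(21, .05, .2))
  m_ab <- meta_fixed(a, b)
  expect_setequal(m_ab$variant_id, ids)   # one-study variants absent
  m_ba <- meta_fixed(b, a)
  m_ba <- m_ba[match(m_ab$variant_id, m_ba$variant_id), ]
  expect_equal(m_ab$beta_meta, m_ba$beta_meta, tolerance = 1e-12)
  expect_equal(m_ab$se_meta, m_ba$se_meta, tolerance = 1e-12)
  # brute-force weighted-mean oracle
  for (v in ids[1:5]) {
    wa <- 1 / a$se[a$variant_id == v]^2
    wb <- 1 / b$se[b$variant_id == v]^2
    oracle <- (wa * a$beta[a$variant_id == v] +
                 wb * b$beta[b$variant_id == v]) / (wa + wb)
    expect_equal(m_ab$beta_meta[m_ab$variant_id == v], oracle,
                 tolerance = 1e-12)
  }
  # self-meta halves the variance
  m_aa <- meta_fixed(a, a)
  expect_equal(m_aa$se_meta,
               a$se[match(m_aa$variant_id, a$variant_id)] / sqrt(2),
               tolerance = 1e-12)
})

test_that("meta_fixed agrees with an independent fixed-effects meta-analysis
           implementation", {
  set.seed(7)
  a <- make_sumstats(sprintf("v%02d", 1:10), beta = rnorm(10),
                     se = runif(10, 0.05, 0.3))
  b <- make_sumstats(sprintf("v%02d", 1:10), beta = rnorm(10),
                     se = runif(10, 0.05, 0.3))
  m <- meta_fixed(a, b)
  for (v in m$variant_id) {
    fit <- metafor::rma(yi = c(a$beta[a$variant_id == v],
                               b$beta[b$variant_id == v]),
                        sei = c(a$se[a$variant_id == v],
                                b$se[b$variant_id == v]),
                        method = "FE")
    expect_equal(m$beta_meta[m$variant_id == v], unname(fit$beta[1]),
                 tolerance = 1e-10)
    expect_equal(m$se_meta[m$variant_id == v], unname(fit$se),
                 tolerance = 1e-10)
  }
})

test_that("allele harmonization flips swapped records and drops ambiguous or
           irreconcilable ones", {
  a <- make_sumstats("v1", beta = 0.3, se = 0.1,
                     effect_allele = "A", other_allele = "G", eaf = 0.3)
  b_sw <- make_sumstats("v1", beta = -0.3, se = 0.1,
                        effect_allele = "G", other_allele = "A", eaf = 0.7)
  m <- meta_fixed(a, b_sw)
  expect_equal(m$beta_meta, 0.3)
  # palindromic with eaf near 0.5 dropped
  a_p <- make_sumstats("v2", beta = 0.2, se = 0.1, effect_allele = "A",
                       other_allele = "T", eaf = 0.5)
  b_p <- make_sumstats("v2", beta = 0.2, se = 0.1, effect_allele = "A",
                       other_allele = "T", eaf = 0.5)
  expect_identical(nrow(suppressMessages(meta_fixed(a_p, b_p))), 0L)
  # irreconcilable alleles dropped
  b_bad <- make_sumstats("v1", beta = 0.3, se = 0.1,
                         effect_allele = "A", other_allele = "C")
  expect_identical(nrow(suppressMessages(meta_fixed(a, b_bad))), 0L)
})

test_that("genome-wide significance uses a strict threshold", {
  rec <- make_sumstats(c("v1", "v2", "v3"), beta = c(1, 1, 1), se = c(1, 1, 1))
  rec$p <- c(5e-8, 4.9e-8, 0.5)
  sig <- genomewide_significant(rec)
  expect_identical(sig$variant_id, "v2")
  empty <- genomewide_significant(rec[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("a null genome-wide scan produces no hits and uniform p-values", {
  spec <- test_spec(n_samples = 1200, n_variants = 200, n_blocks = 20,
                    h2_liability = 0, prevalence = 0.3, seed = 55)
  co <- simulate_cohort(spec)
  covs <- co$covariates[, c("sex", "yob", paste0("pc", 1:10))]
  ss <- gwas_scan(co$genotypes, co$phenotype, co$variants, covariates = covs)
  expect_identical(nrow(genomewide_significant(ss)), 0L)
  expect_gt(ks.test(ss$p, "punif")$p.value, 0.01)
})
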