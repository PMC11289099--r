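# LD clumping, harmonization, MR estimators, pleiotropy test, BH FDR.

test_that("LD clumping keeps the lowest-p variant of each correlated group", {
  R <- diag(3)
  dimnames(R) <- list(c("v1", "v2", "v3"), c("v1", "v2", "v3"))
  rec <- data.frame(variant_id = c("v1", "v2", "v3"), p = c(1e-8, 1e-6, 1e-4))
  # two correlated variants: lower p kept
  R2 <- R; R2["v1", "v2"] <- R2["v2", "v1"] <- sqrt(0.5)
  expect_setequal(ld_clump(rec, R2, r2_max = 0.001)$variant_id,
                  c("v1", "v3"))
  # all independent: all kept
  expect_identical(nrow(ld_clump(rec, R, r2_max = 0.001)), 3L)
  # chain: v1-v2 r2=0.9, v2-v3 r2=0.9, v1-v3 r2=0 -> keep v1 and v3
  Rc <- R
  Rc["v1", "v2"] <- Rc["v2", "v1"] <- sqrt(0.9)
  Rc["v2", "v3"] <- Rc["v3", "v2"] <- sqrt(0.9)
  expect_setequal(ld_clump(rec, Rc, r2_max = 0.001)$variant_id,
                  c("v1", "v3"))
  # variant missing from R dropped with message
  rec2 <- rbind(rec, data.frame(variant_id = "v9", p = 1e-9))
  expect_message(out <- ld_clump(rec2, R), "absent")
  expect_false("v9" %in% out$variant_id)
})

test_that("harmonization aligns swapped alleles and drops ambiguous or
           irreconcilable variants", {
  exp_rec <- make_sumstats("v1", beta = 0.3, se = 0.05,
                           effect_allele = "A", other_allele = "G", eaf = 0.3)
  out_sw <- make_sumstats("v1", beta = -0.3, se = 0.05,
                          effect_allele = "G", other_allele = "A", eaf = 0.7)
  h <- harmonize(exp_rec, out_sw)
  expect_equal(h$beta_outcome, 0.3)
  # palindromic at eaf 0.5: dropped
  exp_p <- make_sumstats("v2", beta = 0.2, se = 0.05, effect_allele = "A",
                         other_allele = "T", eaf = 0.50)
  expect_identical(nrow(suppressMessages(harmonize(exp_p, exp_p))), 0L)
  # A/G vs A/C: irreconcilable
  out_bad <- make_sumstats("v1", beta = 0.3, se = 0.05,
                           effect_allele = "A", other_allele = "C")
  expect_identical(nrow(suppressMessages(harmonize(exp_rec, out_bad))), 0L)
})

test_that("Wald ratio follows the delta-method algebra", {
  ins <- data.frame(variant_id = "v1", beta_exposure = 0.1,
                    se_exposure = 0.01, beta_outcome = 0.2,
                    se_outcome = 0.05)
  r <- mr_wald(ins, "P")
  expect_equal(r$beta, 2.0)
  expect_equal(r$se, 0.5)
  expect_identical(r$method, "Wald ratio")
  ins0 <- transform(ins, beta_outcome = 0)
  r0 <- mr_wald(ins0)
  expect_equal(r0$beta, 0)
  expect_equal(r0$p, 1)
  expect_error(mr_wald(transform(ins, beta_exposure = 0)), "zero")
})

test_that("IVW reduces to Wald for duplicated instruments and equals the
           ratio when ratios agree", {
  ins <- data.frame(variant_id = "v1", beta_exposure = 0.2,
                    se_exposure = 0.01, beta_outcome = 0.1,
                    se_outcome = 0.04)
  dup <- rbind(ins, transform(ins, variant_id = "v2"))
  r_w <- mr_wald(ins)
  r_i <- mr_ivw(dup)
  expect_equal(r_i$beta, r_w$beta)
  expect_equal(r_i$se, r_w$se / sqrt(2), tolerance = 1e-12)
  two <- data.frame(variant_id = c("a", "b"),
                    beta_exposure = c(0.2, 0.4), se_exposure = 0.01,
                    beta_outcome = c(0.1, 0.2), se_outcome = c(0.03, 0.05))
  expect_equal(mr_ivw(two)$beta, 0.5, tolerance = 1e-12)
})

test_that("IVW equals the fixed-effects meta-analysis of per-SNP Wald ratios
           with first-order weights", {
  ins <- make_instruments(8, theta = 0.25, seed = 40)
  r <- mr_ivw(ins)
  ratios <- ins$beta_outcome / ins$beta_exposure
  ses <- ins$se_outcome / abs(ins$beta_exposure)
  w <- 1 / ses^2
  expect_equal(r$beta, sum(w * ratios) / sum(w), tolerance = 1e-10)
  expect_equal(r$se, 1 / sqrt(sum(w)), tolerance = 1e-10)
})

test_that("weighted median interpolates ratios and matches the unweighted
           median under equal weights", {
  ins <- data.frame(variant_id = c("a", "b", "c"),
                    beta_exposure = 1, se_exposure = 0.01,
                    beta_outcome = c(1, 2, 9), se_outcome = 1)
  r <- mr_weighted_median(ins, n_boot = 200, seed = 2)
  expect_equal(r$beta, 2)
  # all ratios equal: estimate is the common ratio, bootstrap se small
  same <- data.frame(variant_id = c("a", "b", "c"),
                     beta_exposure = c(0.2, 0.3, 0.4), se_exposure = 1e-4,
                     beta_outcome = c(0.1, 0.15, 0.2), se_outcome = 1e-4)
  rs <- mr_weighted_median(same, n_boot = 200, seed = 2)
  expect_equal(rs$beta, 0.5, tolerance = 1e-3)
  expect_lt(rs$se, 0.01)
  # equal weights equal the unweighted median of ratios (odd n)
  set.seed(41)
  ratios <- rnorm(7)
  ins7 <- data.frame(variant_id = letters[1:7], beta_exposure = 1,
                     se_exposure = 0.01, beta_outcome = ratios,
                     se_outcome = 1)
  r7 <- mr_weighted_median(ins7, n_boot = 100, seed = 3)
  expect_equal(r7$beta, median(ratios), tolerance = 1e-10)
  expect_error(mr_weighted_median(ins7[1:2, ]), "at least 3")
})

test_that("weighted median resists pleiotropic outliers better than IVW", {
  wins <- 0L
  reps <- 100L
  for (i in seq_len(reps)) {
    ins <- make_instruments(10, theta = 0.3, seed = 7000 + i,
                            n_pleio = 3, pleio_shift = 0.3)
    est_wm <- mr_weighted_median(ins, n_boot = 50, seed = i)$beta
    est_ivw <- mr_ivw(ins)$beta
    if (abs(est_wm - 0.3) < abs(est_ivw - 0.3)) wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.80)
})

test_that("Wald-ratio type-I error is calibrated under the null", {
  set.seed(42)
  hits <- 0L
  reps <- 500L
  for (i in seq_len(reps)) {
    bx <- runif(1, 0.2, 0.5)
    ins <- data.frame(variant_id = "v", beta_exposure = rnorm(1, bx, 0.02),
                      se_exposure = 0.02,
                      beta_outcome = rnorm(1, 0, 0.05), se_outcome = 0.05)
    if (mr_wald(ins)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.03)
  expect_lte(hits / reps, 0.07)
})

test_that("pleiotropy global test is calibrated and powered", {
  # null: data exactly under the IVW model
  set.seed(43)
  p_null <- vapply(1:100, function(i) {
    ins <- make_instruments(8, theta = 0.3, seed = 5000 + i)
    pleiotropy_global_test(ins, n_sim = 200, seed = i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(p_null, "punif"))$p.value, 0.01)
  # power: one instrument inflated by 10 outcome SEs
  rejections <- vapply(1:50, function(i) {
    ins <- make_instruments(8, theta = 0.3, seed = 6000 + i)
    ins$beta_outcome[1] <- ins$beta_outcome[1] + 10 * ins$se_outcome[1]
    pleiotropy_global_test(ins, n_sim = 200, seed = i)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.90)
  # fewer than 4 instruments: not applicable
  ins1 <- make_instruments(1, theta = 0.3, seed = 1)
  res <- pleiotropy_global_test(ins1)
  expect_false(res$applicable)
  expect_true(is.na(res$p))
})

test_that("IVW recovers a planted causal effect from valid instruments", {
  ok <- 0L
  reps <- 100L
  for (i in seq_len(reps)) {
    ins <- make_instruments(10, theta = 0.3, seed = 8000 + i)
    if (abs(mr_ivw(ins)$beta - 0.3) < 0.1) ok <- ok + 1L
  }
  expect_gte(ok / reps, 0.90)
})

test_that("BH FDR matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  # q-values non-decreasing in ranked p order
  set.seed(44)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= p))
})

test_that("mr_analysis routes methods by instrument count and controls FDR
           end to end", {
  # one protein with a single strong instrument, one with several
  outcome <- make_sumstats(sprintf("v%02d", 1:12), beta = rep(0, 12),
                           se = 0.05)
  set.seed(45)
  exp1 <- make_sumstats("v01", beta = 0.5, se = 0.02)
  exp2 <- make_sumstats(sprintf("v%02d", 2:6),
                        beta = runif(5, 0.3, 0.5), se = 0.02)
  res <- mr_analysis(list(P1 = exp1, P2 = exp2), outcome,
                     alpha_instrument = 1e-4)
  expect_identical(res$method[res$protein == "P1"], "Wald ratio")
  expect_identical(res$method[res$protein == "P2"],
                   "Inverse variance weighted")
  expect_true(all(res$fdr >= res$p))
  # simulated mostly-null panel keeps the observed FDR near nominal
  false_disc <- 0L; disc <- 0L
  for (rep in 1:20) {
    set.seed(900 + rep)
    exps <- list(); effects <- c()
    for (k in 1:20) {
      theta <- if (k <= 1) 0.5 else 0   # 95% null proteins
      ids <- sprintf("p%02d_v%d", k, 1:3)
      bx <- runif(3, 0.3, 0.5)
      e <- make_sumstats(ids, beta = bx, se = 0.02)
      o <- make_sumstats(ids, beta = rnorm(3, theta * bx, 0.05), se = 0.05)
      exps[[paste0("P", k)]] <- e
      effects[paste0("P", k)] <- theta
      if (rep == 1 && k == 1) outcome_all <- o else
        outcome_all <- if (k == 1) o else rbind(outcome_all, o)
    }
    res <- mr_analysis(exps, outcome_all, alpha_instrument = 1e-4)
    sig <- res$protein[res$fdr < 0.05]
    disc <- disc + length(sig)
    false_disc <- false_disc + sum(effects[sig] == 0)
  }
  if (disc > 0) expect_lte(false_disc / disc, 0.10)
})
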