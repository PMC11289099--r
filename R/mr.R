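#' Greedy LD clumping of association records
#'
#' Records are sorted by p-value; a variant is accepted iff its r^2 with
#' every previously accepted variant is below `r2_max`. Variants absent from
#' the correlation matrix are dropped with a message.
#'
#' @param records data.frame with `variant_id` and `p`.
#' @param R correlation (not r^2) matrix with variant ids as dimnames.
#' @param r2_max clumping threshold (the conventional 0.001 keeps
#'   near-independent instruments).
#' @return The retained subset of `records`, p-ascending.
#' @export
ld_clump <- function(records, R, r2_max = 0.001) {
  in_R <- records$variant_id %in% rownames(R)
  if (any(!in_R))
    message(sum(!in_R), " variant(s) absent from the LD matrix dropped")
  records <- records[in_R, , drop = FALSE]
  records <- records[order(records$p), , drop = FALSE]
  kept <- character(0)
  for (v in records$variant_id) {
    if (!length(kept) || all(R[v, kept]^2 < r2_max)) kept <- c(kept, v)
  }
  records[records$variant_id %in% kept, , drop = FALSE]
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome records to the exposure's effect allele: swapped
#' effect/other alleles flip the outcome beta; palindromic (A/T, C/G)
#' variants with ambiguous frequency (within `eaf_ambiguous_band` of 0.5 on
#' either side) are dropped; irreconcilable allele pairs are dropped.
#'
#' @param exposure,outcome summary-statistics data.frames.
#' @param eaf_ambiguous_band ambiguity half-width around 0.5.
#' @return data.frame of harmonized instruments: variant_id, beta_exposure,
#'   se_exposure, p_exposure, beta_outcome, se_outcome, eaf_exposure,
#'   eaf_outcome; attribute `"dropped"` records exclusions.
#' @export
harmonize <- function(exposure, outcome, eaf_ambiguous_band = 0.08) {
  m <- harmonize_pair(exposure, outcome, eaf_ambiguous_band)
  dropped <- m[!is.na(m$drop_reason), c("variant_id", "drop_reason")]
  if (nrow(dropped))
    message("harmonize: dropped ", nrow(dropped), " variant(s)")
  m <- m[is.na(m$drop_reason), , drop = FALSE]
  out <- data.frame(variant_id = m$variant_id,
                    beta_exposure = m$beta_a, se_exposure = m$se_a,
                    p_exposure = m$p_a,
                    beta_outcome = m$beta_b_h, se_outcome = m$se_b,
                    eaf_exposure = m$eaf_a, eaf_outcome = m$eaf_b_h,
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

mr_result <- function(protein, method, n_snp, beta, se) {
  z <- beta / se
  data.frame(protein = protein, method = method, n_snp = n_snp,
             beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}

#' Wald-ratio Mendelian randomization (single instrument)
#'
#' `beta = beta_outcome / beta_exposure`; first-order delta-method SE
#' `se = se_outcome / |beta_exposure|`; two-sided normal p.
#'
#' @param instruments one-row harmonized instrument data.frame.
#' @param protein label carried into the result.
#' @return One-row MR result data.frame.
#' @export
mr_wald <- function(instruments, protein = NA_character_) {
  if (nrow(instruments) != 1) stop("Wald ratio needs exactly one instrument",
                                   call. = FALSE)
  if (instruments$beta_exposure == 0)
    stop("exposure effect is zero: Wald ratio undefined", call. = FALSE)
  beta <- instruments$beta_outcome / instruments$beta_exposure
  se <- instruments$se_outcome / abs(instruments$beta_exposure)
  mr_result(protein, "Wald ratio", 1L, beta, se)
}

#' Inverse-variance-weighted Mendelian randomization
#'
#' Fixed-effect IVW: weighted regression of the outcome effects on the
#' exposure effects through the origin with weights `1/se_outcome^2`,
#' equivalent to the inverse-variance meta-analysis of per-SNP Wald ratios
#' with first-order weights. Routes to the Wald ratio when only one
#' instrument is supplied.
#'
#' @param instruments harmonized instrument data.frame (>= 2 rows).
#' @param protein label.
#' @return One-row MR result data.frame.
#' @export
mr_ivw <- function(instruments, protein = NA_character_) {
  if (nrow(instruments) < 2) return(mr_wald(instruments, protein))
  bx <- instruments$beta_exposure; by <- instruments$beta_outcome
  w <- 1 / instruments$se_outcome^2
  beta <- sum(bx * by * w) / sum(bx^2 * w)
  se <- 1 / sqrt(sum(bx^2 * w))
  mr_result(protein, "Inverse variance weighted", nrow(instruments), beta, se)
}

weighted_median_est <- function(ratios, w) {
  o <- order(ratios)
  b <- ratios[o]; w <- w[o]
  cs <- (cumsum(w) - 0.5 * w) / sum(w)
  if (cs[1] >= 0.5) return(b[1])
  if (cs[length(cs)] <= 0.5) return(b[length(b)])
  i <- max(which(cs < 0.5))
  b[i] + (b[i + 1] - b[i]) * (0.5 - cs[i]) / (cs[i + 1] - cs[i])
}

#' Weighted-median Mendelian randomization
#'
#' Per-SNP Wald ratios ordered and combined at cumulative weight 0.5 (linear
#' interpolation between bracketing ratios) with weights
#' `beta_exposure^2 / se_outcome^2`; consistent when instruments carrying at
#' least half the weight are valid. SE by seeded parametric bootstrap
#' (resampling exposure and outcome effects from their normals).
#'
#' @param instruments harmonized instruments (>= 3 rows).
#' @param protein label.
#' @param n_boot bootstrap replicates for the SE.
#' @param seed RNG seed.
#' @return One-row MR result data.frame.
#' @export
mr_weighted_median <- function(instruments, protein = NA_character_,
                               n_boot = 1000, seed = 1L) {
  if (nrow(instruments) < 3)
    stop("weighted median needs at least 3 instruments", call. = FALSE)
  bx <- instruments$beta_exposure; by <- instruments$beta_outcome
  sx <- instruments$se_exposure; sy <- instruments$se_outcome
  est <- weighted_median_est(by / bx, bx^2 / sy^2)
  set.seed(child_seed(seed, "wm_boot"))
  boot <- vapply(seq_len(n_boot), function(b) {
    bxs <- stats::rnorm(length(bx), bx, sx)
    bys <- stats::rnorm(length(by), by, sy)
    weighted_median_est(bys / bxs, bxs^2 / sy^2)
  }, numeric(1))
  se <- stats::sd(boot)
  mr_result(protein, "Weighted median", nrow(instruments), est, se)
}

#' Global horizontal-pleiotropy test (simulation-based)
#'
#' Observed statistic: weighted residual sum of squares of the outcome
#' effects about leave-one-out IVW fits,
#' `RSS = sum_j w_j (beta_out_j - theta_(-j) * beta_exp_j)^2` with
#' `w_j = 1/se_out_j^2`. Compared against `n_sim` parametric simulations of
#' the same statistic under no pleiotropy (effects redrawn from their
#' standard errors around the leave-one-out fit); p uses the add-one rank
#' convention. Requires at least 4 instruments, otherwise returns a
#' not-applicable marker (`NA` p).
#'
#' @param instruments harmonized instruments.
#' @param n_sim parametric simulations.
#' @param seed RNG seed.
#' @return list: p, rss_obs, n_snp, applicable.
#' @export
pleiotropy_global_test <- function(instruments, n_sim = 1000, seed = 1L) {
  n <- nrow(instruments)
  if (n < 4)
    return(list(p = NA_real_, rss_obs = NA_real_, n_snp = n,
                applicable = FALSE))
  bx <- instruments$beta_exposure; by <- instruments$beta_outcome
  sx <- instruments$se_exposure; sy <- instruments$se_outcome
  w <- 1 / sy^2
  loo_theta <- vapply(seq_len(n), function(j)
    sum((bx * by * w)[-j]) / sum((bx^2 * w)[-j]), numeric(1))
  rss <- function(bx_, by_) {
    th <- vapply(seq_len(n), function(j)
      sum((bx_ * by_ * w)[-j]) / sum((bx_^2 * w)[-j]), numeric(1))
    sum(w * (by_ - th * bx_)^2)
  }
  rss_obs <- sum(w * (by - loo_theta * bx)^2)
  set.seed(child_seed(seed, "presso"))
  rss_sim <- vapply(seq_len(n_sim), function(s) {
    bxs <- stats::rnorm(n, bx, sx)
    bys <- stats::rnorm(n, loo_theta * bx, sy)
    rss(bxs, bys)
  }, numeric(1))
  p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  list(p = p, rss_obs = rss_obs, n_snp = n, applicable = TRUE)
}

#' Two-sample MR across proteins
#'
#' Per protein: clumps its cis instruments, harmonizes against the outcome,
#' and applies the method the instrument count admits (1 SNP: Wald ratio;
#' 2 SNPs: IVW; >= 3: IVW and weighted median, reporting `method_choice`).
#' Benjamini-Hochberg FDR is computed across the primary estimates.
#'
#' @param exposures named list of per-protein exposure summary statistics.
#' @param outcome outcome summary statistics.
#' @param R optional LD correlation matrix for clumping.
#' @param r2_max clumping threshold.
#' @param alpha_instrument instrument inclusion threshold on exposure p.
#' @param method_choice estimator when >= 3 instruments:
#'   `"ivw"` (default) or `"weighted_median"`.
#' @param seed RNG seed (weighted-median bootstrap).
#' @return Object of class `pg_mr`: MR results with `fdr`, plus a
#'   `pleiotropy` attribute of per-protein global-test p-values.
#' @export
mr_analysis <- function(exposures, outcome, R = NULL, r2_max = 0.001,
                        alpha_instrument = 5e-8,
                        method_choice = c("ivw", "weighted_median"),
                        seed = 1L) {
  method_choice <- match.arg(method_choice)
  rows <- list(); pleio <- list()
  for (protein in names(exposures)) {
    exp_rec <- exposures[[protein]]
    exp_rec <- exp_rec[exp_rec$p < alpha_instrument, , drop = FALSE]
    if (!nrow(exp_rec)) next
    if (!is.null(R)) exp_rec <- ld_clump(exp_rec, R, r2_max)
    if (!nrow(exp_rec)) next
    h <- harmonize(exp_rec, outcome)
    if (!nrow(h)) next
    res <- if (nrow(h) == 1) mr_wald(h, protein)
      else if (nrow(h) < 3 || method_choice == "ivw") mr_ivw(h, protein)
      else mr_weighted_median(h, protein, seed = seed)
    rows[[protein]] <- res
    pleio[[protein]] <- pleiotropy_global_test(h, seed = seed)$p
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$fdr <- bh_fdr(out$p)
  rownames(out) <- NULL
  attr(out, "pleiotropy") <- unlist(pleio)
  class(out) <- c("pg_mr", "data.frame")
  out
}

#' @export
print.pg_mr <- function(x, ...) {
  cat("Two-sample MR:", nrow(x), "proteins;",
      sum(x$fdr < 0.05), "significant at FDR < 0.05\n")
  print.data.frame(utils::head(x[order(x$p), ], 10), digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment with monotonicity enforcement (wraps
#' `stats::p.adjust(method = "BH")`).
#'
#' @param pvalues p-values in (0, 1].
#' @return q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues <= 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}
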