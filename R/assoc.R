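#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed table.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers).
#' @return Exact p-value in (0, 1].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)
  n_a <- 2 * n_aa + n_Aa            # minor-allele count by convention below
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_a, n_A)
  if (rare == 0) return(1)          # monomorphic: only one table possible
  # heterozygote counts share the parity of the rare-allele count
  het <- seq(rare %% 2, rare, by = 2)
  # log P(n_het | allele counts): n! / (nAA! nAa! naa!) * 2^het / C(2n, rare)
  log_p <- lgamma(n + 1) - lgamma((rare - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((2 * n - rare - het) / 2 + 1) + het * log(2) -
    (lgamma(2 * n + 1) - lgamma(rare + 1) - lgamma(2 * n - rare + 1))
  p_tab <- exp(log_p - logsumexp(log_p))   # normalize residual rounding
  obs <- p_tab[het == n_Aa]
  min(1, sum(p_tab[p_tab <= obs * (1 + 1e-12)]))
}

#' Per-variant quality-control filter
#'
#' A variant is retained iff MAF > `maf_min`, call rate > `cr_min`, exact HWE
#' p > `hwe_min`, and (when an INFO score is supplied) INFO > `info_min`.
#' Defaults follow standard array-GWAS practice (MAF > 0.1%, call rate >
#' 0.95, HWE p > 1e-6, INFO > 0.8).
#'
#' @param genotypes samples x variants dosage matrix (NA = missing).
#' @param info optional named numeric vector of imputation INFO scores.
#' @param maf_min,cr_min,hwe_min,info_min thresholds (strict inequalities).
#' @return list with `keep` (retained variant names), `qc` (per-variant
#'   metrics + reasons) and `report` (per-filter removal counts; a variant
#'   failing several filters is counted under each).
#' @export
variant_qc_filter <- function(genotypes, info = NULL, maf_min = 0.001,
                              cr_min = 0.95, hwe_min = 1e-6, info_min = 0.8) {
  g <- as.matrix(genotypes)
  ids <- colnames(g)
  cr <- colMeans(!is.na(g))
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j][!is.na(g[, j])]
    if (!length(x)) return(NA_real_)
    hwe_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  info_v <- if (is.null(info)) rep(NA_real_, ncol(g)) else info[ids]
  fail <- cbind(maf = !(maf > maf_min), call_rate = !(cr > cr_min),
                hwe = !(is.na(hwe) | hwe > hwe_min),
                info = !(is.na(info_v) | info_v > info_min))
  removed <- rowSums(fail) > 0
  qc <- data.frame(variant_id = ids, maf = maf, call_rate = cr, hwe_p = hwe,
                   info = info_v, retained = !removed,
                   reason = apply(fail, 1, function(f)
                     paste(colnames(fail)[f], collapse = ";")),
                   stringsAsFactors = FALSE)
  report <- stats::setNames(as.integer(colSums(fail)), colnames(fail))
  keep <- ids[!removed]
  if (!length(keep)) warning("QC removed every variant")
  list(keep = keep, qc = qc, report = report)
}

#' Single-variant case/control logistic association
#'
#' Logistic regression of case status on allele dosage plus covariates, by
#' maximum likelihood or with Firth's Jeffreys-prior penalty (which yields
#' finite estimates under complete separation and heavy case/control
#' imbalance). Missing dosages are dropped listwise by default.
#'
#' @param phenotype 0/1 vector.
#' @param dosage numeric dosage vector (NA = missing).
#' @param covariates optional data.frame/matrix of covariates.
#' @param firth use Firth-penalized logistic regression.
#' @param mean_impute mean-impute missing dosages instead of dropping them.
#' @return One-row data.frame: eaf, beta, se, z, p, n, converged, method.
#' @export
logistic_assoc <- function(phenotype, dosage, covariates = NULL,
                           firth = FALSE, mean_impute = FALSE) {
  y <- as.numeric(phenotype)
  x <- as.numeric(dosage)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (mean_impute && anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  y <- y[keep]; x <- x[keep]; if (!is.null(C)) C <- C[keep, , drop = FALSE]
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("need at least 2 cases and 2 controls", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, dosage = x, C)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design (dosage collinear with covariates)",
         call. = FALSE)
  if (firth) {
    fit <- firth_logistic(X, y)
    beta <- fit$beta["dosage"]; se <- fit$se["dosage"]
    converged <- fit$converged; method <- "firth"
    if (!converged)
      stop("Firth logistic regression failed to converge; trace: ",
           paste(signif(fit$trace, 4), collapse = " "), call. = FALSE)
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    separated <- any(fit$fitted.values > 1 - 1e-10) ||
      any(fit$fitted.values < 1e-10)
    if (separated || !fit$converged)
      stop("separation or non-convergence in ML logistic fit; ",
           "retry with firth = TRUE", call. = FALSE)
    V <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
    beta <- fit$coefficients["dosage"]
    se <- sqrt(diag(V))[which(colnames(X) == "dosage")]
    converged <- fit$converged; method <- "ml"
  }
  z <- beta / se
  data.frame(eaf = mean(x) / 2, beta = unname(beta), se = unname(se),
             z = unname(z), p = 2 * stats::pnorm(-abs(z)), n = length(y),
             converged = converged, method = method,
             stringsAsFactors = FALSE)
}

# Firth-penalized logistic regression: Newton iterations on the modified
# score U*(b) = X'(y - mu + h (0.5 - mu)), h = leverages of sqrt(W) X.
firth_logistic <- function(X, y, tol = 1e-8, max_iter = 100) {
  b <- numeric(ncol(X))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    XW <- X * sqrt(W)
    XtWX <- crossprod(XW)
    V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(V)) return(list(beta = b, se = rep(NA_real_, ncol(X)),
                                converged = FALSE, trace = trace))
    h <- rowSums((XW %*% V) * XW)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    delta <- drop(V %*% U)
    # dampen large steps for stability under separation
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    b <- b + delta
    trace <- c(trace, max(abs(delta)))
    if (max(abs(delta)) < tol) {
      names(b) <- colnames(X)
      se <- sqrt(diag(V)); names(se) <- colnames(X)
      return(list(beta = b, se = se, converged = TRUE, trace = trace,
                  iterations = it))
    }
  }
  list(beta = b, se = rep(NA_real_, ncol(X)), converged = FALSE, trace = trace)
}

#' Genome-wide per-variant association scan
#'
#' Runs [logistic_assoc()] on every column of a dosage matrix and returns a
#' summary-statistics table in the standard layout.
#'
#' @param genotypes samples x variants dosage matrix.
#' @param phenotype 0/1 vector.
#' @param variants variant table (variant_id, chrom, pos, alleles).
#' @param covariates optional covariate data.frame (used as numeric matrix).
#' @param firth,mean_impute passed to [logistic_assoc()].
#' @return Summary-statistics data.frame (one row per variant that could be
#'   tested; monomorphic or failing variants are skipped with a message).
#' @export
gwas_scan <- function(genotypes, phenotype, variants, covariates = NULL,
                      firth = FALSE, mean_impute = FALSE) {
  res <- lapply(colnames(genotypes), function(v) {
    x <- genotypes[, v]
    if (stats::var(x, na.rm = TRUE) %in% c(0, NA)) return(NULL)
    r <- tryCatch(logistic_assoc(phenotype, x, covariates, firth = firth,
                                 mean_impute = mean_impute),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    cbind(variant_id = v, r)
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  if (skipped) message(skipped, " variant(s) skipped in GWAS scan")
  res <- do.call(rbind, res)
  out <- merge(variants[, c("variant_id", "chrom", "pos", "effect_allele",
                            "other_allele")], res, by = "variant_id")
  out[match(colnames(genotypes)[colnames(genotypes) %in% out$variant_id],
            out$variant_id), ]
}

# Harmonize study-b records to study-a allele coding. Returns merged frame
# with harmonized beta_b/eaf_b and a drop reason column.
harmonize_pair <- function(a, b, eaf_ambiguous_band = 0.08) {
  m <- merge(a, b, by = "variant_id", suffixes = c("_a", "_b"))
  if (!nrow(m)) return(m)
  flip <- function(al) chartr("ACGT", "TGCA", al)
  same <- m$effect_allele_b == m$effect_allele_a &
    m$other_allele_b == m$other_allele_a
  swapped <- m$effect_allele_b == m$other_allele_a &
    m$other_allele_b == m$effect_allele_a
  ambiguous <- m$effect_allele_a == flip(m$other_allele_a)  # A/T or C/G
  m$beta_b_h <- ifelse(swapped, -m$beta_b, m$beta_b)
  m$eaf_b_h <- ifelse(swapped, 1 - m$eaf_b, m$eaf_b)
  m$drop_reason <- NA_character_
  m$drop_reason[!same & !swapped] <- "allele_mismatch"
  uninformative <- abs(m$eaf_a - 0.5) < eaf_ambiguous_band |
    abs(m$eaf_b_h - 0.5) < eaf_ambiguous_band
  m$drop_reason[ambiguous & uninformative & is.na(m$drop_reason)] <-
    "strand_ambiguous"
  # informative palindromic pair: align by frequency side
  fa <- ambiguous & !uninformative & is.na(m$drop_reason) &
    (sign(m$eaf_a - 0.5) != sign(m$eaf_b_h - 0.5))
  m$beta_b_h[fa] <- -m$beta_b_h[fa]
  m$eaf_b_h[fa] <- 1 - m$eaf_b_h[fa]
  m
}

#' Fixed-effects inverse-variance meta-analysis of two summary-statistic sets
#'
#' Classical inverse-SE-weighted meta-analysis: weights `w = 1/se^2`,
#' `beta_meta = sum(w * beta) / sum(w)`, `se_meta = 1/sqrt(sum(w))`. Only
#' variants present in both studies are emitted. Alleles are harmonized
#' first: effect/other swaps flip the sign; strand-ambiguous (A/T, C/G)
#' variants are dropped when either study's frequency is uninformative
#' (within `eaf_ambiguous_band` of 0.5), otherwise frequency-aligned;
#' irreconcilable allele pairs are dropped with a logged reason.
#'
#' @param records_a,records_b summary-statistics data.frames (see
#'   [read_sumstats()] for required columns).
#' @param eaf_ambiguous_band half-width of the uninformative frequency band.
#' @return data.frame: variant_id, beta_meta, se_meta, z_meta, p_meta,
#'   n_studies, direction; attribute `"dropped"` lists excluded variants.
#' @export
meta_fixed <- function(records_a, records_b, eaf_ambiguous_band = 0.08) {
  m <- harmonize_pair(records_a, records_b, eaf_ambiguous_band)
  dropped <- m[!is.na(m$drop_reason), c("variant_id", "drop_reason")]
  if (nrow(dropped))
    message("meta_fixed: dropped ", nrow(dropped), " variant(s): ",
            paste(unique(dropped$drop_reason), collapse = ", "))
  m <- m[is.na(m$drop_reason), ]
  w_a <- 1 / m$se_a^2; w_b <- 1 / m$se_b^2
  beta <- (w_a * m$beta_a + w_b * m$beta_b_h) / (w_a + w_b)
  se <- 1 / sqrt(w_a + w_b)
  z <- beta / se
  out <- data.frame(
    variant_id = m$variant_id, beta_meta = beta, se_meta = se, z_meta = z,
    p_meta = 2 * stats::pnorm(-abs(z)), n_studies = rep(2L, nrow(m)),
    direction = paste0(ifelse(m$beta_a >= 0, "+", "-"),
                       ifelse(m$beta_b_h >= 0, "+", "-")),
    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Genome-wide significant records
#'
#' Subset with `p < alpha` (strict inequality), the conventional genome-wide
#' threshold being 5e-8.
#'
#' @param records data.frame with a `p` (or `p_meta`) column.
#' @param alpha significance threshold.
#' @export
genomewide_significant <- function(records, alpha = 5e-8) {
  p <- records[["p"]] %||% records[["p_meta"]]
  if (is.null(p)) stop("records need a p or p_meta column", call. = FALSE)
  records[p < alpha, , drop = FALSE]
}
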