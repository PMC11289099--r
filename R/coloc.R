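# Wakefield approximate Bayes factors and their two applications:
# colocalization posteriors (H0-H4) and single-causal-variant fine-mapping.

#' Wakefield log approximate Bayes factor
#'
#' `lABF = 0.5 * (log(V/(V+W)) + z^2 * W/(V+W))` with `V = se^2` and prior
#' effect variance `W` (conventionally 0.15^2 for case/control log-odds
#' traits, 0.2^2 for standardized quantitative traits).
#'
#' @param beta,se effect estimates and standard errors.
#' @param W prior effect variance.
#' @return Vector of log-ABFs.
#' @export
wakefield_labf <- function(beta, se, W = 0.15^2) {
  V <- se^2
  z2 <- (beta / se)^2
  0.5 * (log(V / (V + W)) + z2 * W / (V + W))
}

prior_W <- function(type = c("cc", "quant"), W = NULL) {
  type <- match.arg(type)
  if (!is.null(W) && !is.na(W)) return(W)
  if (type == "cc") 0.15^2 else 0.2^2
}

#' Approximate-Bayes-factor colocalization of two traits in a region
#'
#' Enumerates the five hypotheses for a region shared by two traits —
#' H0 no association; H1/H2 one trait associated; H3 both, distinct causal
#' variants; H4 both, one shared causal variant — with per-hypothesis
#' evidence assembled from per-variant Wakefield ABFs and priors `p1`, `p2`,
#' `p12`. All sums run in log space.
#'
#' @param trait1,trait2 summary statistics sharing `variant_id` (with `beta`
#'   and `se`); the variant intersection is analyzed.
#' @param p1,p2,p12 prior probabilities that a variant is associated with
#'   trait 1 only, trait 2 only, or both.
#' @param type1,type2 trait types (`"cc"` or `"quant"`) setting the
#'   Wakefield prior variance; override with `W1`/`W2`.
#' @param W1,W2 optional explicit prior effect variances.
#' @param region label carried into the result.
#' @return Object of class `pg_coloc`: list with `pp` (named PP.H0..PP.H4,
#'   summing to 1), `n_snps`, `priors`, `region`.
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      type1 = "cc", type2 = "quant", W1 = NULL, W2 = NULL,
                      region = NA_character_) {
  m <- merge(trait1[, c("variant_id", "beta", "se")],
             trait2[, c("variant_id", "beta", "se")],
             by = "variant_id", suffixes = c("_1", "_2"))
  if (nrow(m) < 2)
    warning("fewer than 2 shared variants in the region")
  if (nrow(m) == 0) stop("no shared variants", call. = FALSE)
  l1 <- wakefield_labf(m$beta_1, m$se_1, prior_W(type1, W1))
  l2 <- wakefield_labf(m$beta_2, m$se_2, prior_W(type2, W2))
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lH0 <- 0
  lH1 <- log(p1) + ls1
  lH2 <- log(p2) + ls2
  # H3: both associated at two distinct variants = Sum1*Sum2 - same-SNP part
  lH3 <- if (nrow(m) == 1) -Inf else
    log(p1) + log(p2) + logdiffexp(ls1 + ls2, ls12)
  lH4 <- log(p12) + ls12
  lh <- c(lH0, lH1, lH2, lH3, lH4)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP.H", 0:4)
  out <- list(pp = pp, n_snps = nrow(m),
              priors = c(p1 = p1, p2 = p2, p12 = p12), region = region)
  class(out) <- "pg_coloc"
  out
}

#' @export
print.pg_coloc <- function(x, ...) {
  cat("Colocalization", if (!is.na(x$region)) paste0("(", x$region, ")"),
      "over", x$n_snps, "shared variants:\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' Single-causal-variant fine-mapping of a region
#'
#' Under the assumption of exactly one causal variant in the region, the
#' posterior inclusion probability of variant j is its Wakefield ABF
#' normalized over the region, and the 95% credible set is the minimal
#' descending-PIP prefix reaching cumulative mass >= `mass`.
#'
#' @param records region summary statistics (variant_id, beta, se).
#' @param type trait type for the prior variance (`"cc"` or `"quant"`).
#' @param W optional explicit prior effect variance.
#' @param mass credible-set mass (default 0.95).
#' @param region label.
#' @return list: region, pip (data.frame variant_id, pip, in_cs, ordered by
#'   descending PIP), credible_set (character), mass.
#' @export
finemap_single_causal <- function(records, type = "cc", W = NULL,
                                  mass = 0.95, region = NA_character_) {
  if (!nrow(records)) stop("empty region", call. = FALSE)
  labf <- wakefield_labf(records$beta, records$se, prior_W(type, W))
  pip <- exp(labf - logsumexp(labf))
  ord <- order(-pip, records$variant_id)
  cum <- cumsum(pip[ord])
  n_cs <- which(cum >= mass - 1e-12)[1]
  if (is.na(n_cs)) n_cs <- length(pip)
  df <- data.frame(variant_id = records$variant_id[ord], pip = pip[ord],
                   in_cs = seq_along(ord) <= n_cs, stringsAsFactors = FALSE)
  list(region = region, pip = df, credible_set = df$variant_id[df$in_cs],
       mass = mass)
}

#' Extract a fine-mapping window around an index variant
#'
#' Subsets region records to `window_bp` flanking the index variant on its
#' chromosome (the conventional window being 500 kb each side).
#'
#' @param records summary statistics with chrom/pos.
#' @param index_variant variant id at the window center.
#' @param window_bp flank size in bp.
#' @return The windowed records.
#' @export
finemap_window <- function(records, index_variant, window_bp = 500000) {
  i <- match(index_variant, records$variant_id)
  if (is.na(i)) stop("index variant not in records", call. = FALSE)
  records[norm_chrom(records$chrom) == norm_chrom(records$chrom[i]) &
            abs(records$pos - records$pos[i]) <= window_bp, , drop = FALSE]
}
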