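#' Build the pQTL covariate design
#'
#' Standard plasma-proteomics association covariates: age, age^2, sex,
#' age*sex, age^2*sex, plus any principal-component columns present.
#'
#' @param covariates data.frame with `age`, `sex` and optional `pc*` columns.
#' @return Numeric design matrix (no intercept column).
#' @export
pqtl_covariate_design <- function(covariates) {
  age <- covariates$age; sex <- covariates$sex
  X <- cbind(age = age, age2 = age^2, sex = sex, age_sex = age * sex,
             age2_sex = age^2 * sex)
  pcs <- grep("^pc[0-9]+$", names(covariates), value = TRUE)
  if (length(pcs)) X <- cbind(X, as.matrix(covariates[, pcs, drop = FALSE]))
  X
}

#' Scan all variant-protein pairs for pQTLs
#'
#' Ordinary least squares of each protein's abundance on each variant's
#' dosage plus the covariate design, computed efficiently by residualizing
#' both matrices against the covariates (Frisch-Waugh) and regressing
#' residual on residual with the correct degrees of freedom. P-values are
#' carried as -log10(p) so extreme associations survive floating-point
#' underflow. Records with p < `alpha` are emitted.
#'
#' @param proteins samples x proteins abundance matrix.
#' @param genotypes samples x variants dosage matrix (missing dosages are
#'   mean-imputed for the scan).
#' @param covariates covariate data.frame (see [pqtl_covariate_design()]).
#' @param alpha significance threshold on the p scale.
#' @return data.frame: variant_id, protein, beta, se, neg_log10_p. Constant
#'   proteins or dosages are skipped with a message.
#' @export
pqtl_scan <- function(proteins, genotypes, covariates, alpha = 5e-8) {
  P <- as.matrix(proteins)
  G <- imputed_dosage(genotypes)
  if (nrow(P) != nrow(G)) stop("sample mismatch", call. = FALSE)
  C <- cbind(1, pqtl_covariate_design(covariates))
  qrC <- qr(C)
  df <- nrow(P) - qrC$rank - 1L
  Pr <- qr.resid(qrC, P)
  Gr <- qr.resid(qrC, G)
  gss <- colSums(Gr^2)
  pss <- colSums(Pr^2)
  const_g <- gss < 1e-12; const_p <- pss < 1e-12
  if (any(const_g)) message(sum(const_g), " constant dosage column(s) skipped")
  if (any(const_p)) message(sum(const_p), " constant protein column(s) skipped")
  Gr <- Gr[, !const_g, drop = FALSE]; gss <- gss[!const_g]
  Pr <- Pr[, !const_p, drop = FALSE]; pss <- pss[!const_p]
  xy <- crossprod(Gr, Pr)                       # variants x proteins
  beta <- xy / gss
  rss <- pmax(matrix(pss, nrow(xy), ncol(xy), byrow = TRUE) - beta * xy, 0)
  se <- sqrt(rss / df / gss)
  tstat <- beta / se
  nlp <- neg_log10_p_from_t(tstat, df)
  nlp[!is.finite(nlp) & is.finite(beta)] <- 300   # exact-copy degenerate fit
  hit <- which(nlp > -log10(alpha), arr.ind = TRUE)
  out <- data.frame(variant_id = rownames(xy)[hit[, 1]],
                    protein = colnames(xy)[hit[, 2]],
                    beta = beta[hit], se = se[hit], neg_log10_p = nlp[hit],
                    stringsAsFactors = FALSE)
  out[order(out$protein, -out$neg_log10_p), ]
}

#' Per-variant exposure summary statistics for one protein
#'
#' Full (unthresholded) OLS summary statistics of one protein on every
#' variant, in the standard summary-statistics layout — the exposure side of
#' a two-sample MR or a colocalization region.
#'
#' @param protein abundance vector.
#' @param genotypes dosage matrix.
#' @param covariates covariate data.frame.
#' @param variants variant table.
#' @return Summary-statistics data.frame.
#' @export
pqtl_sumstats <- function(protein, genotypes, covariates, variants) {
  P <- matrix(protein, ncol = 1, dimnames = list(NULL, "p"))
  G <- imputed_dosage(genotypes)
  C <- cbind(1, pqtl_covariate_design(covariates))
  qrC <- qr(C)
  df <- nrow(G) - qrC$rank - 1L
  Pr <- qr.resid(qrC, P); Gr <- qr.resid(qrC, G)
  gss <- colSums(Gr^2)
  xy <- drop(crossprod(Gr, Pr))
  beta <- xy / gss
  rss <- pmax(sum(Pr^2) - beta * xy, 0)
  se <- sqrt(rss / df / gss)
  z <- beta / se
  idx <- match(colnames(G), variants$variant_id)
  data.frame(variant_id = colnames(G), chrom = variants$chrom[idx],
             pos = variants$pos[idx],
             effect_allele = variants$effect_allele[idx],
             other_allele = variants$other_allele[idx],
             eaf = colMeans(G) / 2, beta = beta, se = se,
             p = pmax(2 * stats::pt(-abs(z), df), 1e-300), n = nrow(G),
             stringsAsFactors = FALSE)
}

#' Classify pQTL records as cis or trans
#'
#' A record is cis iff the variant lies on the same chromosome as the
#' protein's coding gene and within `window_bp` of the gene boundaries
#' (inclusive on both sides, 1-based positions against 0-based half-open
#' gene intervals). Proteins without annotation are classified `"unknown"`.
#'
#' @param records pQTL records (variant_id, protein, ...).
#' @param variants variant table (variant_id, chrom, pos).
#' @param annotation gene annotation (chrom, start, end, gene).
#' @param window_bp flanking window around gene boundaries (default the
#'   printed 1 kb convention; 1 Mb is common elsewhere and is a knob).
#' @return `records` with a `cis_flag` column ("cis"/"trans"/"unknown").
#' @export
classify_cis_trans <- function(records, variants, annotation,
                               window_bp = 1000) {
  vi <- match(records$variant_id, variants$variant_id)
  gi <- match(records$protein, annotation$gene)
  vchrom <- norm_chrom(variants$chrom[vi]); vpos <- variants$pos[vi]
  gchrom <- norm_chrom(annotation$chrom[gi])
  glo <- annotation$start[gi] + 1L   # first 1-based position inside the gene
  ghi <- annotation$end[gi]          # last 1-based position inside the gene
  cis <- vchrom == gchrom & vpos >= glo - window_bp & vpos <= ghi + window_bp
  records$cis_flag <- ifelse(is.na(gi), "unknown",
                             ifelse(cis, "cis", "trans"))
  records
}

#' Intersect GWAS hits with pQTL records
#'
#' All (variant, protein) pairs where the variant is a GWAS-significant hit
#' and the pair is a significant pQTL, plus the distinct protein set.
#'
#' @param gwas_hits data.frame with `variant_id` (e.g. from
#'   [genomewide_significant()]).
#' @param pqtl_records pQTL records.
#' @return list with `pairs` (subset of `pqtl_records`) and `proteins`
#'   (sorted distinct protein names).
#' @export
intersect_gwas_pqtl <- function(gwas_hits, pqtl_records) {
  pairs <- pqtl_records[pqtl_records$variant_id %in% gwas_hits$variant_id, ,
                        drop = FALSE]
  pairs <- unique(pairs)
  list(pairs = pairs, proteins = sort(unique(pairs$protein)))
}

#' Summarize pQTL architecture
#'
#' Histograms of proteins per pQTL and pQTLs per protein, the partition of
#' proteins into cis-only / trans-only / both / unknown, and the number of
#' pQTLs associated only in trans.
#'
#' @param records classified pQTL records (see [classify_cis_trans()]).
#' @return An object of class `pqtl_architecture`.
#' @export
architecture_summary <- function(records) {
  if (!"cis_flag" %in% names(records))
    stop("records must be classified first (classify_cis_trans)",
         call. = FALSE)
  known <- records[records$cis_flag != "unknown", , drop = FALSE]
  as_hist <- function(x) stats::setNames(as.integer(x), names(x))
  per_variant <- as_hist(table(table(records$variant_id)))
  per_protein <- as_hist(table(table(records$protein)))
  status <- vapply(split(known$cis_flag, known$protein), function(f) {
    if (all(f == "cis")) "cis_only"
    else if (all(f == "trans")) "trans_only" else "both"
  }, character(1))
  unknown_prot <- setdiff(unique(records$protein), names(status))
  variant_trans_only <- vapply(split(known$cis_flag, known$variant_id),
                               function(f) all(f == "trans"), logical(1))
  out <- list(
    proteins_per_pqtl = per_variant,
    pqtls_per_protein = per_protein,
    protein_status = c(as_hist(table(factor(status, levels = c("cis_only",
                       "trans_only", "both")))),
                       unknown = length(unknown_prot)),
    n_pqtl_trans_only = as.integer(sum(variant_trans_only)),
    n_pqtls = length(unique(records$variant_id)),
    n_proteins = length(unique(records$protein)),
    n_records = nrow(records))
  stopifnot(sum(out$protein_status) == out$n_proteins)  # partition conserved
  class(out) <- "pqtl_architecture"
  out
}

#' @export
print.pqtl_architecture <- function(x, ...) {
  cat("pQTL architecture:", x$n_records, "associations,", x$n_pqtls,
      "pQTLs,", x$n_proteins, "proteins\n")
  cat("  proteins per pQTL: ",
      paste(names(x$proteins_per_pqtl), x$proteins_per_pqtl, sep = ":",
            collapse = " "), "\n")
  cat("  pQTLs per protein: ",
      paste(names(x$pqtls_per_protein), x$pqtls_per_protein, sep = ":",
            collapse = " "), "\n")
  cat("  protein status:", paste(names(x$protein_status), x$protein_status,
                                 sep = "=", collapse = " "), "\n")
  cat("  pQTLs trans-only:", x$n_pqtl_trans_only, "\n")
  invisible(x)
}
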