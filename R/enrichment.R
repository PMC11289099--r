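#' Hypergeometric pathway enrichment against a panel background
#'
#' Per gene set: upper-tail hypergeometric p of the overlap between the
#' query and the set within the supplied background (e.g. the assay panel —
#' never the whole genome by default), Benjamini-Hochberg FDR across tested
#' sets, and the enrichment ratio (observed/expected overlap). Query genes
#' outside the background are logged and intersected away. Sets overlapping
#' the query in fewer than `min_overlap` genes are skipped.
#'
#' @param query_genes character vector of gene symbols.
#' @param collection named list of gene sets (e.g. [read_gmt()]).
#' @param background character vector; the universe for the test.
#' @param fdr_max significance call threshold.
#' @param min_overlap minimum query/set overlap for a set to be tested.
#' @return data.frame: set, overlap, set_size, query_size, background_size,
#'   ratio, p, fdr, significant.
#' @export
pathway_enrichment <- function(query_genes, collection, background,
                               fdr_max = 0.05, min_overlap = 3) {
  background <- unique(norm_symbols(background))
  if (!length(background)) stop("empty background", call. = FALSE)
  query <- unique(norm_symbols(query_genes))
  outside <- setdiff(query, background)
  if (length(outside))
    message(length(outside), " query gene(s) outside the background dropped")
  query <- intersect(query, background)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(norm_symbols(collection[[nm]])), background)
    ov <- length(intersect(query, s))
    if (ov < min_overlap) return(NULL)
    # degenerate universe: no enrichment is possible when the set fills it
    p <- stats::phyper(ov - 1, length(s), length(background) - length(s),
                       length(query), lower.tail = FALSE)
    ratio <- (ov / length(query)) / (length(s) / length(background))
    data.frame(set = nm, overlap = ov, set_size = length(s),
               query_size = length(query),
               background_size = length(background),
               ratio = ratio, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      background_size = integer(0), ratio = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$fdr < fdr_max
  out[order(out$p), ]
}

#' Triangulate converging evidence across three target sets
#'
#' Builds the per-protein evidence table over three target sets — (a)
#' pQTL-associated proteins, (b) proteins in the top-scoring network modules
#' that are pQTL-associated, (c) pQTL-associated first-degree neighbors of
#' risk loci — and flags converging proteins. The default rule is
#' `a AND (b OR c)`; `rule = "strict"` requires all three.
#'
#' @param set_a,set_b,set_c character vectors of gene symbols.
#' @param rule `"default"` or `"strict"`.
#' @return Object of class `pg_evidence`: data.frame protein, in_set_a,
#'   in_set_b, in_set_c, converging.
#' @export
triangulate <- function(set_a, set_b, set_c, rule = c("default", "strict")) {
  rule <- match.arg(rule)
  a <- unique(norm_symbols(set_a)); b <- unique(norm_symbols(set_b))
  c_ <- unique(norm_symbols(set_c))
  proteins <- sort(unique(c(a, b, c_)))
  out <- data.frame(protein = proteins,
                    in_set_a = proteins %in% a,
                    in_set_b = proteins %in% b,
                    in_set_c = proteins %in% c_,
                    stringsAsFactors = FALSE)
  out$converging <- if (rule == "strict")
    out$in_set_a & out$in_set_b & out$in_set_c
  else out$in_set_a & (out$in_set_b | out$in_set_c)
  attr(out, "rule") <- rule
  class(out) <- c("pg_evidence", "data.frame")
  out
}

#' @export
print.pg_evidence <- function(x, ...) {
  cat("Evidence triangulation (rule:", attr(x, "rule"), "):",
      sum(x$converging), "converging of", nrow(x), "proteins\n")
  if (any(x$converging))
    cat("  converging:", paste(x$protein[x$converging], collapse = ", "),
        "\n")
  invisible(x)
}

#' Genotype-stratified abundance test (ANCOVA)
#'
#' Linear model `abundance ~ genotype + age + sex + age:sex`; F-test for
#' the genotype factor against the covariate-only model, plus all pairwise
#' genotype contrasts with two-sided t p-values. Genotype levels with fewer
#' than 2 samples are dropped with a warning.
#'
#' @param abundance numeric protein abundance (NPX-like).
#' @param genotype factor or vector coercible to factor (e.g. "CC","CT","TT").
#' @param age,sex covariates.
#' @return list: F (statistic), p (genotype F-test), contrasts (data.frame
#'   comparison, estimate, se, t, p), n, levels.
#' @export
genotype_ancova <- function(abundance, genotype, age, sex) {
  genotype <- factor(genotype)
  keep_lv <- names(which(table(genotype) >= 2))
  if (length(keep_lv) < length(levels(genotype)))
    warning("dropped genotype level(s) with < 2 samples: ",
            paste(setdiff(levels(genotype), keep_lv), collapse = ", "))
  keep <- genotype %in% keep_lv
  d <- data.frame(y = abundance[keep], g = droplevels(genotype[keep]),
                  age = age[keep], sex = sex[keep])
  if (nlevels(d$g) < 2) stop("need >= 2 genotype levels with >= 2 samples",
                             call. = FALSE)
  full <- stats::lm(y ~ g + age + sex + age:sex, data = d)
  reduced <- stats::lm(y ~ age + sex + age:sex, data = d)
  an <- stats::anova(reduced, full)
  lv <- levels(d$g)
  cf <- stats::coef(full); V <- stats::vcov(full)
  # coefficient position of each non-reference level
  pos <- stats::setNames(match(paste0("g", lv), names(cf)), lv)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  contrasts <- do.call(rbind, lapply(pairs, function(pr) {
    v <- numeric(length(cf))
    if (!is.na(pos[pr[2]])) v[pos[pr[2]]] <- 1
    if (!is.na(pos[pr[1]])) v[pos[pr[1]]] <- -1
    est <- sum(v * cf); se <- sqrt(drop(t(v) %*% V %*% v))
    tt <- est / se
    data.frame(comparison = paste(pr[2], "vs", pr[1]), estimate = est,
               se = se, t = tt,
               p = 2 * stats::pt(-abs(tt), stats::df.residual(full)),
               stringsAsFactors = FALSE)
  }))
  list(F = an$F[2], p = an$`Pr(>F)`[2], contrasts = contrasts,
       n = nrow(d), levels = lv)
}

#' Carrier-frequency 2x2 test
#'
#' Two-sided Fisher exact test on carrier/non-carrier counts in cases and
#' controls, plus the sample odds ratio (marked undefined when any cell is
#' zero).
#'
#' @param case_carriers,case_noncarriers,control_carriers,control_noncarriers
#'   non-negative counts.
#' @return list: odds_ratio (NA when undefined), p, table.
#' @export
carrier_frequency_test <- function(case_carriers, case_noncarriers,
                                   control_carriers, control_noncarriers) {
  counts <- c(case_carriers, case_noncarriers, control_carriers,
              control_noncarriers)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  tab <- matrix(counts, 2, 2,
                dimnames = list(c("carrier", "noncarrier"),
                                c("case", "control")))
  p <- stats::fisher.test(tab)$p.value
  or <- if (any(counts == 0)) NA_real_ else
    (case_carriers * control_noncarriers) /
    (case_noncarriers * control_carriers)
  list(odds_ratio = or, p = p, table = tab)
}

#' Map variants to distal genes through chromatin-loop anchors
#'
#' A variant falling inside anchor 1 of a loop (half-open interval test,
#' 0-based anchors against 1-based variant positions) is linked to the
#' genes annotated at anchor 2, and vice versa, labeled with the loop's
#' cell type. Chromosome names are normalized (`chr1` == `1`). Links are
#' deduplicated.
#'
#' @param variants data.frame: variant_id, chrom, pos (1-based).
#' @param loops loop table from [read_loops()] (or equivalent, with list
#'   columns genes1/genes2).
#' @return data.frame: variant_id, cell_type, gene, anchor (1 or 2 = the
#'   anchor the variant fell in), ordered by variant then gene.
#' @export
map_variants_to_loops <- function(variants, loops) {
  vchrom <- norm_chrom(variants$chrom)
  pos0 <- variants$pos - 1L  # 0-based coordinate of the variant base
  rows <- list()
  for (i in seq_len(nrow(loops))) {
    lchrom <- norm_chrom(loops$chrom1[i])
    on_chr <- vchrom == lchrom
    in1 <- on_chr & pos0 >= loops$start1[i] & pos0 < loops$end1[i]
    in2 <- on_chr & pos0 >= loops$start2[i] & pos0 < loops$end2[i]
    g1 <- loops$genes1[[i]]; g2 <- loops$genes2[[i]]
    if (any(in1) && length(g2))
      rows[[length(rows) + 1]] <- expand.grid(
        variant_id = variants$variant_id[in1], gene = g2,
        cell_type = loops$celltype[i], anchor = 1L,
        stringsAsFactors = FALSE)
    if (any(in2) && length(g1))
      rows[[length(rows) + 1]] <- expand.grid(
        variant_id = variants$variant_id[in2], gene = g1,
        cell_type = loops$celltype[i], anchor = 2L,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(variant_id = character(0), cell_type = character(0),
                      gene = character(0), anchor = integer(0)))
  out <- unique(do.call(rbind, rows)[, c("variant_id", "cell_type", "gene",
                                         "anchor")])
  out <- out[order(out$variant_id, out$gene, out$cell_type), ]
  rownames(out) <- NULL
  out
}

#' Formatted set-overlap report
#'
#' Thin wrapper over [overlap_test()] emitting shared / a-only / b-only
#' counts alongside the one-sided p and odds ratio.
#'
#' @param set_a,set_b character vectors.
#' @param universe_size size of the shared universe.
#' @return list: shared, a_only, b_only, n_a, n_b, p, odds_ratio.
#' @export
set_overlap_report <- function(set_a, set_b, universe_size) {
  t <- overlap_test(set_a, set_b, universe_size)
  list(shared = t$overlap, a_only = t$n_a - t$overlap,
       b_only = t$n_b - t$overlap, n_a = t$n_a, n_b = t$n_b,
       p = t$p, odds_ratio = t$odds_ratio)
}
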