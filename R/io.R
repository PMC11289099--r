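# Readers/writers for the pipeline's plain-text interchange formats.
# All TSV, gzip-transparent (file() handles .gz transparently on read;
# writers gzip when the path ends in .gz).

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

write_tsv <- function(df, path) {
  # full %.17g precision so doubles survive a write/read round trip bitwise
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  con <- open_out(path)
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "p", "n")

#' Read / write GWAS or pQTL summary statistics
#'
#' Tab-separated with required header columns `variant_id, chrom, pos,
#' effect_allele, other_allele, eaf, beta, se, p, n`. On read, each record's
#' p-value is checked for consistency with beta/se under a two-sided normal
#' test (10% relative tolerance on the z scale); inconsistencies warn but do
#' not fail.
#'
#' @param path file path; `.gz` handled transparently.
#' @param records data.frame with the required columns.
#' @return `read_sumstats`: the records data.frame; `write_sumstats`: the
#'   path, invisibly.
#' @export
read_sumstats <- function(path) {
  df <- read_tsv(path)
  missing <- setdiff(SUMSTATS_COLS, names(df))
  if (length(missing))
    stop("summary-statistics file lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ok <- df$se > 0 & df$p > 0 & df$p <= 1
  if (any(!ok)) stop("invalid se or p in summary statistics", call. = FALSE)
  z_imp <- abs(stats::qnorm(df$p / 2))
  z_obs <- abs(df$beta / df$se)
  inconsistent <- is.finite(z_imp) & z_imp > 0 &
    abs(z_obs - z_imp) / pmax(z_imp, 1e-12) > 0.10
  if (any(inconsistent))
    warning(sum(inconsistent),
            " record(s) have p inconsistent with beta/se (>10% on z scale)")
  df
}

#' @rdname read_sumstats
#' @export
write_sumstats <- function(records, path) {
  missing <- setdiff(SUMSTATS_COLS, names(records))
  if (length(missing))
    stop("records lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  write_tsv(records[, union(SUMSTATS_COLS, names(records))], path)
}

#' Read / write a gene annotation table (BED-like, 0-based half-open)
#'
#' Columns: chrom, start, end, gene.
#' @param path file path.
#' @param annotation data.frame with chrom, start, end, gene.
#' @export
read_gene_annotation <- function(path) {
  df <- read_tsv(path)
  need <- c("chrom", "start", "end", "gene")
  if (!all(need %in% names(df)))
    stop("gene annotation needs columns chrom, start, end, gene", call. = FALSE)
  if (any(df$start >= df$end)) stop("annotation has start >= end", call. = FALSE)
  df
}

#' @rdname read_gene_annotation
#' @export
write_gene_annotation <- function(annotation, path) write_tsv(annotation, path)

#' Read / write a PPI edge list (two-column TSV)
#' @param path file path.
#' @param edges data.frame with columns from, to.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv(path, header = TRUE)
  if (ncol(df) < 2) stop("edge list needs two columns", call. = FALSE)
  bad <- which(is.na(df[[1]]) | is.na(df[[2]]) | df[[1]] == "" | df[[2]] == "")
  if (length(bad))
    stop("malformed edge line(s): ", paste(bad + 1L, collapse = ", "),
         call. = FALSE)
  names(df)[1:2] <- c("from", "to")
  df[, 1:2]
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(edges, path) write_tsv(edges, path)

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name, description,
#' gene1, gene2, ...`. Symbols are uppercased and whitespace-stripped.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    norm_symbols(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  con <- open_out(path)
  on.exit(close(con))
  for (nm in names(sets))
    writeLines(paste(c(nm, nm, sets[[nm]]), collapse = "\t"), con)
  invisible(path)
}

#' Read paired chromatin-loop anchors
#'
#' BED-like paired-anchor TSV with columns `chrom1, start1, end1, chrom2,
#' start2, end2, celltype, genes1, genes2` (gene lists `;`-separated,
#' intervals 0-based half-open, both anchors on one chromosome).
#'
#' @param path file path.
#' @return data.frame with list columns `genes1`, `genes2`.
#' @export
read_loops <- function(path) {
  df <- read_tsv(path)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "celltype", "genes1", "genes2")
  if (!all(need %in% names(df)))
    stop("loop file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(norm_chrom(df$chrom1) != norm_chrom(df$chrom2)))
    stop("loop anchors must share a chromosome", call. = FALSE)
  if (any(df$start1 >= df$end1 | df$start2 >= df$end2))
    stop("loop anchors must have start < end", call. = FALSE)
  df$genes1 <- lapply(strsplit(df$genes1, ";", fixed = TRUE), norm_symbols)
  df$genes2 <- lapply(strsplit(df$genes2, ";", fixed = TRUE), norm_symbols)
  df
}

# uppercase + strip whitespace; no alias resolution
norm_symbols <- function(x) {
  x <- toupper(trimws(x))
  x[nzchar(x)]
}

#' Write all components of a synthetic cohort to a directory
#'
#' Emits the genotype dosage TSV, variant table, phenotype/covariates,
#' protein NPX matrix, PPI edge list, gene annotation and truth tables.
#'
#' @param cohort a `pg_cohort` from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  geno <- data.frame(sample_id = rownames(cohort$genotypes),
                     cohort$genotypes, check.names = FALSE)
  prot <- data.frame(sample_id = rownames(cohort$proteins),
                     cohort$proteins, check.names = FALSE)
  pheno <- cbind(cohort$covariates, phenotype = cohort$phenotype)
  paths <- c(
    genotypes = write_tsv(geno, p("genotypes.tsv")),
    variants = write_tsv(cohort$variants, p("variants.tsv")),
    phenotype = write_tsv(pheno, p("phenotype.tsv")),
    proteins = write_tsv(prot, p("proteins.tsv")),
    ppi = write_edge_list(cohort$ppi$edges, p("ppi_edges.tsv")),
    annotation = write_gene_annotation(cohort$annotation, p("genes.tsv")),
    truth_pqtl = write_tsv(cohort$truth$pqtl, p("truth_pqtl.tsv")),
    truth_disease = write_tsv(
      data.frame(variant_id = cohort$truth$disease$causal_variants,
                 effect = cohort$truth$disease$effects),
      p("truth_disease.tsv")),
    truth_module = write_tsv(
      data.frame(gene = cohort$truth$planted_module), p("truth_module.tsv")))
  invisible(paths)
}
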