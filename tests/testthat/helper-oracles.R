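# Independent oracles used to freeze expected values. Each is written
# directly from the mathematical definition, not from the package code.

# Expected dosage correlation between two variants whose haplotype alleles
# come from thresholding a bivariate normal with correlation rho at the
# qnorm(maf) quantile: numeric integration of the orthant probability.
dosage_cor_oracle <- function(rho, maf) {
  q <- qnorm(maf)
  joint <- stats::integrate(function(z)
    dnorm(z) * pnorm((q - rho * z) / sqrt(1 - rho^2)),
    lower = -Inf, upper = q, rel.tol = 1e-10)$value
  (joint - maf^2) / (maf * (1 - maf))
}

# Exact HWE p by direct enumeration with choose() arithmetic.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  rare <- min(na, 2 * n - na)
  if (rare == 0) return(1)
  het <- seq(rare %% 2, rare, by = 2)
  pr <- sapply(het, function(h) {
    nr <- (rare - h) / 2          # rare homozygotes
    nc <- n - nr - h              # common homozygotes
    exp(lchoose(n, nr) + lchoose(n - nr, h) + h * log(2) -
          lchoose(2 * n, rare))
  })
  pr <- pr / sum(pr)
  obs <- pr[het == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Upper-tail hypergeometric by brute-force summation of point masses.
hyper_tail_oracle <- function(overlap, n_a, n_b, universe) {
  sum(sapply(overlap:min(n_a, n_b), function(k)
    exp(lchoose(n_a, k) + lchoose(universe - n_a, n_b - k) -
          lchoose(universe, n_b))))
}

# Step-by-step greedy dense-module oracle on a plain adjacency matrix,
# applying the same growth rule as the search (distance-d candidates,
# interior bridge maximizing Zm, lexicographic tie-breaks, stop unless
# Zm_new > Zm_old * (1 + r)).
oracle_module_search <- function(edges, z, seed_node, d = 2, r = 0.1,
                                 max_size = 100) {
  nodes <- names(z)
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$from[i], edges$to[i]] <- TRUE
    A[edges$to[i], edges$from[i]] <- TRUE
  }
  nbrs <- function(vs) nodes[colSums(A[vs, , drop = FALSE]) > 0]
  members <- seed_node
  zm <- sum(z[members]) / sqrt(length(members))
  repeat {
    if (length(members) >= max_size) break
    n1 <- setdiff(nbrs(members), members)
    if (!length(n1)) break
    s <- sum(z[members]); k <- length(members)
    cand <- lapply(n1, function(v)
      list(node = v, add = v, zm = (s + z[[v]]) / sqrt(k + 1)))
    if (d >= 2) {
      n2 <- setdiff(nbrs(n1), c(members, n1))
      cand <- c(cand, lapply(n2, function(v) {
        ints <- intersect(nodes[A[v, ]], n1)
        zi <- unname(z[ints])
        pick <- sort(ints[zi == max(zi)])[1]
        list(node = v, add = c(v, pick),
             zm = (s + z[[v]] + z[[pick]]) / sqrt(k + 2))
      }))
    }
    zms <- vapply(cand, `[[`, numeric(1), "zm")
    nms <- vapply(cand, `[[`, character(1), "node")
    best <- cand[[order(-zms, nms)[1]]]
    if (!(best$zm > zm * (1 + r))) break
    members <- c(members, best$add)
    zm <- best$zm
  }
  list(members = sort(members), zm = zm)
}

# Random small graph + weights for fuzzing (n <= 8 nodes).
random_small_graph <- function(seed) {
  set.seed(seed)
  n <- sample(2:8, 1)
  nodes <- letters[seq_len(n)]
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < 0.45
  if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  z <- setNames(rnorm(n), nodes)
  list(edges = data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                          stringsAsFactors = FALSE), z = z, nodes = nodes)
}

# Build a summary-statistics data.frame with consistent p-values.
make_sumstats <- function(variant_id, beta, se,
                          effect_allele = "A", other_allele = "G",
                          eaf = 0.3, chrom = "1",
                          pos = seq_along(variant_id) * 1000L, n = 10000L) {
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se,
             p = pmax(2 * pnorm(-abs(beta / se)), 1e-300), n = n,
             stringsAsFactors = FALSE)
}

# Simulated harmonized instruments: n_valid instruments with true causal
# effect theta, plus optional pleiotropic outliers with extra outcome effect.
make_instruments <- function(n, theta, seed, se_exp = 0.02, se_out = 0.05,
                             n_pleio = 0, pleio_shift = 0) {
  set.seed(seed)
  bx_true <- runif(n, 0.15, 0.5)
  by_true <- theta * bx_true
  if (n_pleio > 0)
    by_true[seq_len(n_pleio)] <- by_true[seq_len(n_pleio)] + pleio_shift
  data.frame(variant_id = sprintf("v%03d", seq_len(n)),
             beta_exposure = rnorm(n, bx_true, se_exp),
             se_exposure = se_exp,
             beta_outcome = rnorm(n, by_true, se_out),
             se_outcome = se_out, stringsAsFactors = FALSE)
}

# Small default cohort spec used across tests.
test_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_samples = 500, n_variants = 60, n_blocks = 6,
                   n_proteins = 10, n_genes = 20, ppi_nodes = 20,
                   planted_module_size = 5, prevalence = 0.2,
                   h2_liability = 0.3, n_causal_disease = 3, seed = 42)
  do.call(cohort_spec, utils::modifyList(defaults, args))
}
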