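#' Build a gene-score-weighted PPI network
#'
#' Constructs a simple undirected igraph from an edge list: duplicate and
#' reversed edges are deduplicated and self-loops dropped (counts logged).
#' Node weights `z` come from the gene scores; nodes without a score carry
#' the most conservative clamped weight (`qnorm(0)` clamped to -8.2) so the
#' search space matches the full network.
#'
#' @param edges two-column data.frame (from, to).
#' @param gene_scores data.frame with `gene` and `z_gene` (or a named
#'   numeric vector of z weights).
#' @return An igraph with vertex attribute `z`.
#' @export
build_weighted_ppi <- function(edges, gene_scores = NULL) {
  if (!nrow(edges)) stop("edge list is empty", call. = FALSE)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  n_loops <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  if (n_loops || n_multi)
    message("dropped ", n_loops, " self-loop(s) and ", n_multi,
            " duplicate edge(s)")
  g <- igraph::simplify(g)
  z_min <- -8.2
  z <- rep(z_min, igraph::vcount(g))
  names(z) <- igraph::V(g)$name
  if (!is.null(gene_scores)) {
    w <- if (is.data.frame(gene_scores))
      stats::setNames(gene_scores$z_gene, gene_scores$gene) else gene_scores
    hit <- intersect(names(z), names(w))
    z[hit] <- w[hit]
  }
  igraph::V(g)$z <- unname(z)
  g
}

module_zm <- function(z) sum(z) / sqrt(length(z))

#' Greedy dense-module search on a weighted PPI
#'
#' For each seed node, grows a module greedily: at every step all nodes
#' within graph distance `d` of the current module are candidates; the
#' candidate maximizing the module score `Zm = sum(z)/sqrt(k)` is added iff
#' `Zm_new > Zm_old * (1 + r)`, otherwise the search stops. A candidate at
#' distance 2 is admitted together with a shortest-path interior node
#' (chosen to maximize the resulting Zm, ties broken lexicographically) so
#' the module stays connected; interior nodes count toward `k`. With
#' `strict_adjacent = TRUE` only direct neighbors are candidates. Candidate
#' ties break lexicographically by node name, making the search fully
#' deterministic.
#'
#' @param ppi weighted igraph from [build_weighted_ppi()].
#' @param d neighbor order (1 or 2).
#' @param r score increment rate required to accept a growth step.
#' @param seeds seed node names (default: every node).
#' @param max_size hard cap on module size.
#' @param strict_adjacent restrict candidates to distance-1 semantics.
#' @return Object of class `pg_modules`: data.frame with seed, members
#'   (`;`-joined), k, Zm, plus a `members_list` attribute.
#' @export
dense_module_search <- function(ppi, d = 2, r = 0.1, seeds = NULL,
                                max_size = 100, strict_adjacent = FALSE) {
  stopifnot(d >= 1, r > 0)
  nodes <- igraph::V(ppi)$name
  n <- length(nodes)
  z <- igraph::V(ppi)$z
  adj <- lapply(igraph::adjacent_vertices(ppi, seq_len(n)), as.integer)
  # lexicographic rank of node names for deterministic tie-breaking
  lexrank <- match(seq_len(n), order(nodes))
  seeds <- seeds %||% nodes
  seeds <- intersect(seeds, nodes)
  use_d2 <- d >= 2 && !strict_adjacent

  grow_one <- function(seed_idx) {
    members <- seed_idx
    in_mod <- logical(n); in_mod[seed_idx] <- TRUE
    zm <- z[seed_idx]
    repeat {
      if (length(members) >= max_size) break
      n1 <- unique(unlist(adj[members], use.names = FALSE))
      n1 <- n1[!in_mod[n1]]
      if (!length(n1)) break
      k <- length(members); s <- sum(z[members])
      cand_node <- n1
      cand_zm <- (s + z[n1]) / sqrt(k + 1)
      cand_int <- rep(NA_integer_, length(n1))
      if (use_d2) {
        is_n1 <- logical(n); is_n1[n1] <- TRUE
        n2 <- unique(unlist(adj[n1], use.names = FALSE))
        n2 <- n2[!in_mod[n2] & !is_n1[n2]]
        if (length(n2)) {
          ints2 <- integer(length(n2))
          for (i in seq_along(n2)) {
            ints <- adj[[n2[i]]]
            ints <- ints[is_n1[ints]]          # interior bridge nodes
            zi <- z[ints]
            top <- ints[zi == max(zi)]
            ints2[i] <- top[which.min(lexrank[top])]
          }
          cand_node <- c(cand_node, n2)
          cand_zm <- c(cand_zm, (s + z[n2] + z[ints2]) / sqrt(k + 2))
          cand_int <- c(cand_int, ints2)
        }
      }
      best <- order(-cand_zm, lexrank[cand_node])[1]
      if (!(cand_zm[best] > zm * (1 + r))) break
      add <- c(cand_node[best],
               if (!is.na(cand_int[best])) cand_int[best])
      members <- c(members, add)
      in_mod[add] <- TRUE
      zm <- cand_zm[best]
    }
    list(members = sort(nodes[members]), zm = zm)
  }

  res <- lapply(match(seeds, nodes), grow_one)
  out <- data.frame(
    seed = seeds,
    members = vapply(res, function(x) paste(x$members, collapse = ";"),
                     character(1)),
    k = vapply(res, function(x) length(x$members), integer(1)),
    Zm = vapply(res, function(x) x$zm, numeric(1)),
    stringsAsFactors = FALSE)
  attr(out, "members_list") <- lapply(res, `[[`, "members")
  attr(out, "params") <- list(d = d, r = r, strict_adjacent = strict_adjacent,
                              max_size = max_size)
  class(out) <- c("pg_modules", "data.frame")
  out
}

#' Member node sets of a module table
#' @param modules a `pg_modules` object.
#' @return list of character vectors.
#' @export
module_members <- function(modules) {
  attr(modules, "members_list") %||%
    strsplit(modules$members, ";", fixed = TRUE)
}

#' Normalize module scores against random node sets
#'
#' For every module size k present, draws `B_norm` uniform random k-node
#' sets from the network and standardizes each module's Zm against the mean
#' and SD of the random-set scores of its size: `Zn = (Zm - mean_k)/sd_k`.
#'
#' @param modules a `pg_modules` object.
#' @param ppi the weighted igraph the modules came from.
#' @param B_norm random sets per size stratum (>= 100).
#' @param seed RNG seed.
#' @return `modules` with a `Zn` column.
#' @export
normalize_modules <- function(modules, ppi, B_norm = 10000, seed = 1L) {
  stopifnot(B_norm >= 100)
  set.seed(child_seed(seed, "normalize"))
  z <- igraph::V(ppi)$z
  n <- length(z)
  sizes <- sort(unique(modules$k))
  stats_k <- lapply(sizes, function(k) {
    zm <- vapply(seq_len(B_norm),
                 function(b) sum(z[sample.int(n, k)]) / sqrt(k), numeric(1))
    c(mean = mean(zm), sd = stats::sd(zm))
  })
  names(stats_k) <- sizes
  mu <- vapply(as.character(modules$k), function(k) stats_k[[k]][["mean"]],
               numeric(1))
  sg <- vapply(as.character(modules$k), function(k) stats_k[[k]][["sd"]],
               numeric(1))
  degenerate <- sg == 0
  if (any(degenerate & abs(modules$Zm - mu) > 1e-12))
    stop("degenerate weights: null SD is zero for some module size",
         call. = FALSE)
  modules$Zn <- ifelse(degenerate, 0, (modules$Zm - mu) / sg)
  modules
}

#' Select the top fraction of modules by normalized score
#'
#' Takes the top `ceiling(q * n)` modules by Zn (ties broken by Zm, then
#' seed name) and returns them with the union of their member nodes.
#'
#' @param modules normalized `pg_modules`.
#' @param q fraction to keep (default top 1%).
#' @return list with `modules` (selected rows, ranked) and `proteins`
#'   (sorted union of member nodes).
#' @export
top_percent_modules <- function(modules, q = 0.01) {
  if (is.null(modules$Zn)) stop("modules must be normalized first",
                                call. = FALSE)
  n_sel <- ceiling(q * nrow(modules))
  ord <- order(-modules$Zn, -modules$Zm, modules$seed)
  sel <- modules[ord[seq_len(n_sel)], , drop = FALSE]
  sel$rank <- seq_len(nrow(sel))
  members <- module_members(modules)[ord[seq_len(n_sel)]]
  list(modules = sel, proteins = sort(unique(unlist(members))))
}

#' @export
print.pg_modules <- function(x, ...) {
  p <- attr(x, "params")
  cat("Dense-module search:", nrow(x), "modules (d =", p$d, ", r =", p$r,
      ")\n")
  cat("  sizes:", paste(range(x$k), collapse = "-"),
      " best Zm:", signif(max(x$Zm), 4), "\n")
  if (!is.null(x$Zn)) cat("  best Zn:", signif(max(x$Zn), 4), "\n")
  invisible(x)
}

#' One-sided overlap (hypergeometric / Fisher) test for two sets
#'
#' Upper-tail hypergeometric probability of the observed overlap between two
#' sets within a finite universe — identical to a one-sided Fisher exact
#' test on the 2x2 table — plus the sample odds ratio.
#'
#' @param set_a,set_b character vectors, or `NULL` when counts are given.
#' @param universe_size size of the universe both sets live in.
#' @param n_a,n_b,n_overlap optional counts overriding the sets.
#' @return list: overlap, n_a, n_b, universe, p (one-sided), odds_ratio.
#' @export
overlap_test <- function(set_a = NULL, set_b = NULL, universe_size,
                         n_a = NULL, n_b = NULL, n_overlap = NULL) {
  if (!is.null(set_a)) {
    set_a <- unique(set_a); set_b <- unique(set_b)
    n_a <- length(set_a); n_b <- length(set_b)
    n_overlap <- length(intersect(set_a, set_b))
  }
  if (n_a > universe_size || n_b > universe_size)
    stop("set larger than the universe", call. = FALSE)
  p <- stats::phyper(n_overlap - 1, n_a, universe_size - n_a, n_b,
                     lower.tail = FALSE)
  a <- n_overlap; b <- n_a - n_overlap; c_ <- n_b - n_overlap
  d <- universe_size - n_a - n_b + n_overlap
  or <- if (b * c_ > 0) (a * d) / (b * c_) else NA_real_
  list(overlap = n_overlap, n_a = n_a, n_b = n_b, universe = universe_size,
       p = p, odds_ratio = or)
}

#' First-degree neighborhood of risk loci in a PPI
#'
#' Induced subgraph on the risk loci present in the network plus all their
#' direct neighbors; optionally annotates which nodes are pQTL-associated
#' proteins.
#'
#' @param ppi igraph.
#' @param risk_loci character node names (absent loci are logged and
#'   skipped; none present is an error).
#' @param pqtl_proteins optional character vector for annotation.
#' @return igraph with vertex attributes `is_risk_locus` and `is_pqtl`.
#' @export
first_degree_network <- function(ppi, risk_loci, pqtl_proteins = NULL) {
  present <- intersect(risk_loci, igraph::V(ppi)$name)
  missing <- setdiff(risk_loci, present)
  if (length(missing))
    message(length(missing), " risk locus/loci not in the network: ",
            paste(utils::head(missing, 5), collapse = ", "))
  if (!length(present))
    stop("no risk locus present in the network", call. = FALSE)
  nbr <- unique(unlist(lapply(
    igraph::adjacent_vertices(ppi, present), function(v) v$name)))
  sub <- igraph::induced_subgraph(ppi, union(present, nbr))
  igraph::V(sub)$is_risk_locus <- igraph::V(sub)$name %in% present
  igraph::V(sub)$is_pqtl <- igraph::V(sub)$name %in% (pqtl_proteins %||%
                                                        character(0))
  sub
}

#' Permutation test for pQTL enrichment in a network neighborhood
#'
#' The observed statistic is the one-sided Fisher p for the overlap between
#' the neighbor set and the pQTL protein set within the whole network. For
#' each of B iterations a uniform random node set of the same size is drawn
#' and its Fisher p computed; the empirical p-value uses the add-one
#' convention `(1 + #{p_b <= p_obs}) / (B + 1)`.
#'
#' @param ppi igraph (the node universe).
#' @param neighbor_set character node set under test.
#' @param pqtl_proteins character reference set.
#' @param B permutation count.
#' @param seed RNG seed.
#' @return list: p_obs, empirical_p, B, overlap.
#' @export
permutation_enrichment <- function(ppi, neighbor_set, pqtl_proteins,
                                   B = 10000, seed = 1L) {
  nodes <- igraph::V(ppi)$name
  neighbor_set <- intersect(unique(neighbor_set), nodes)
  pqtl_proteins <- intersect(unique(pqtl_proteins), nodes)
  if (length(neighbor_set) > length(nodes))
    stop("neighbor set larger than the network", call. = FALSE)
  U <- length(nodes)
  obs <- overlap_test(neighbor_set, pqtl_proteins, U)
  set.seed(child_seed(seed, "permutation"))
  size <- length(neighbor_set)
  is_pqtl <- nodes %in% pqtl_proteins
  p_b <- vapply(seq_len(B), function(b) {
    ov <- sum(is_pqtl[sample.int(U, size)])
    stats::phyper(ov - 1, size, U - size, length(pqtl_proteins),
                  lower.tail = FALSE)
  }, numeric(1))
  emp <- (1 + sum(p_b <= obs$p)) / (B + 1)
  list(p_obs = obs$p, empirical_p = emp, B = B, overlap = obs$overlap)
}
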