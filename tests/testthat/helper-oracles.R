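# Independent oracles used by the property and acceptance tests. These are
# deliberately naive re-derivations (loops, enumeration, permutation draws)
# kept separate from the package's code paths.

# Literal Benjamini-Hochberg step-up: adj_i = min_{j: p_j >= p_i} min(1, m p_j / rank_j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ranked[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force k-core: for each k, repeatedly delete nodes of degree < k;
# survivors have core number >= k.
oracle_core_numbers <- function(nodes, from, to) {
  core <- setNames(integer(length(nodes)), nodes)
  for (k in seq_len(length(nodes))) {
    alive <- nodes
    ef <- from; et <- to
    repeat {
      deg <- setNames(integer(length(alive)), alive)
      tab <- table(c(ef, et))
      deg[names(tab)] <- as.integer(tab)
      drop <- alive[deg[alive] < k]
      if (!length(drop)) break
      alive <- setdiff(alive, drop)
      keep <- !(ef %in% drop | et %in% drop)
      ef <- ef[keep]; et <- et[keep]
      if (!length(alive)) break
    }
    if (!length(alive)) break
    core[alive] <- k
  }
  core
}

# group_network from bare edge lists (handles the zero-edge case)
net_from_edge_lists <- function(nodes, from, to, group = "control") {
  k <- length(from)
  edges <- data.frame(gene_a = pmin(from, to), gene_b = pmax(from, to),
                      r = rep(0.9, k), n = rep(9L, k),
                      p_value = rep(1e-5, k), fdr = rep(1e-4, k),
                      style = rep("Positive", k), stringsAsFactors = FALSE)
  coexscreen:::new_group_network(group, nodes, edges, 9L, 0.01)
}

# Erdos-Renyi edge list on node labels n1..nN
random_graph_edges <- function(n, p_edge) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  list(nodes = nodes, from = pairs[keep, 1L], to = pairs[keep, 2L])
}

# Hypergeometric upper tail by explicit enumeration with choose()
oracle_hyper_tail <- function(a, b, c, d) {
  N <- a + b + c + d
  s <- a + c     # set size
  k <- a + b     # DEGs drawn
  hi <- min(s, k)
  if (a > hi) return(0)
  sum(choose(s, a:hi) * choose(N - s, k - (a:hi))) / choose(N, k)
}

# Two-sided permutation p-value for a Pearson correlation, B random draws
perm_corr_pvalue <- function(x, y, B = 1e5) {
  n <- length(x)
  robs <- cor(x, y)
  ords <- apply(matrix(runif(n * B), n), 2, order)
  yp <- matrix(y[ords], n)
  xc <- x - mean(x)
  ypc <- yp - colMeans(yp)[col(yp)]
  rp <- colSums(xc * ypc) / (sqrt(sum(xc^2)) * sqrt(colSums(ypc^2)))
  mean(abs(rp) >= abs(robs) - 1e-12)
}

# The stated world of the end-to-end recovery criterion: one control-only
# 10-gene module (rho 0.9) plus a mid-hub anchor member (rho 0.6), 200
# background genes, 9 vs 18 samples, noise_sd 0.3.
recovery_world <- function(seed) {
  synthetic_spec(
    n_genes = 211, n_control = 9, n_case = 18,
    modules = list(module_spec(1:11, rho = c(rep(0.9, 10), 0.6),
                               active_in = "control")),
    deg_fraction = 0.1, deg_log2fc = 2, noise_sd = 0.3, seed = seed)
}

# End-to-end run of the screen on the recovery world; returns per-seed
# module-gene dif-degree sign fraction and candidate recovery.
run_recovery_seed <- function(seed) {
  spec <- recovery_world(seed)
  d <- generate_two_group_dataset(spec)
  go <- generate_fixture_genesets(d$truth, n_terms = 2, term_size = 40,
                                  p_deg = 0.7, prefix = "GO", seed = seed)
  pw <- generate_fixture_genesets(d$truth, n_terms = 2, term_size = 40,
                                  p_deg = 0.7, prefix = "PW",
                                  seed = seed + 1000L)
  deg <- run_differential_expression(d$matrix, d$design)
  called <- filter_degs(deg)$all
  rgo <- fisher_enrichment(called, deg$gene_id, go)
  rpw <- fisher_enrichment(called, deg$gene_id, pw)
  genes <- select_network_genes(rgo, rpw, deg, d$matrix, n_lnc = 0)
  nc <- build_group_network(d$matrix, d$design, "case", genes)
  nn <- build_group_network(d$matrix, d$design, "control", genes)
  topo <- differential_topology(nc, nn, genes)
  members <- sprintf("g%03d", 1:10)
  anchor <- "g011"
  dif <- setNames(rep(0L, 10L), members)
  hit <- intersect(members, topo$gene_id)
  dif[hit] <- topo$dif_degree[match(hit, topo$gene_id)]
  recovery <- if (anchor %in% topo$gene_id) {
    mean(members %in% select_candidates(topo, anchor)$candidates)
  } else {
    NA_real_
  }
  list(neg_fraction = mean(dif < 0), recovery = recovery,
       topology = topo, members = members, anchor = anchor)
}
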