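#' Per-gene degree in a group network
#'
#' @param network A `group_network` object.
#' @return Named integer vector over all network nodes; genes with no
#'   surviving edge get 0. Edge sign is ignored — positive and negative
#'   edges count equally.
#' @export
degrees <- function(network) {
  stopifnot(inherits(network, "group_network"))
  d <- stats::setNames(integer(length(network$nodes)), network$nodes)
  if (nrow(network$edges)) {
    tab <- table(c(network$edges$gene_a, network$edges$gene_b))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Per-gene core number in a group network
#'
#' Standard k-core decomposition by iterative peeling: nodes of degree < k
#' are removed for k = 1, 2, ...; a node's core number is the largest k at
#' which it survives. Isolated nodes have core number 0. Edge signs are
#' ignored.
#'
#' @param network A `group_network` object.
#' @return Named integer vector of core numbers over all network nodes.
#' @export
core_numbers <- function(network) {
  stopifnot(inherits(network, "group_network"))
  core_numbers_edges(network$nodes, network$edges$gene_a,
                     network$edges$gene_b)
}

# Peeling on an adjacency list; O(V + E) passes per shell, ample for the
# few-hundred-node networks this screen produces.
core_numbers_edges <- function(nodes, from, to) {
  core <- stats::setNames(integer(length(nodes)), nodes)
  if (length(from) == 0L) return(core)
  adj <- split(c(match(to, nodes), match(from, nodes)),
               c(match(from, nodes), match(to, nodes)))
  deg <- integer(length(nodes))
  deg[as.integer(names(adj))] <- lengths(adj)
  alive <- deg > 0L
  k <- 1L
  while (any(alive)) {
    repeat {
      peel <- which(alive & deg < k)
      if (length(peel) == 0L) break
      alive[peel] <- FALSE
      for (v in peel) {
        nb <- adj[[as.character(v)]]
        nb <- nb[alive[nb]]
        deg[nb] <- deg[nb] - 1L
      }
    }
    core[alive] <- k
    k <- k + 1L
  }
  core
}

#' Differential network topology per gene
#'
#' Tabulates degree and core number of every gene in the case and control
#' networks and their exact integer differences `dif_degree = degree_case -
#' degree_control` and `dif_kcore = kcore_case - kcore_control`. A gene
#' absent from one group's network contributes 0 there.
#'
#' @param case_net,control_net `group_network` objects.
#' @param gene_universe Genes to report; defaults to the union of the two
#'   node sets.
#' @return data.frame of class `topology_table` with columns `gene_id`,
#'   `degree_case`, `degree_control`, `kcore_case`, `kcore_control`,
#'   `dif_degree`, `dif_kcore`.
#' @export
differential_topology <- function(case_net, control_net,
                                  gene_universe = NULL) {
  stopifnot(inherits(case_net, "group_network"),
            inherits(control_net, "group_network"))
  if (is.null(gene_universe)) {
    gene_universe <- union(case_net$nodes, control_net$nodes)
  }
  pick <- function(v, ids) {
    out <- stats::setNames(integer(length(ids)), ids)
    hit <- intersect(ids, names(v))
    out[hit] <- v[hit]
    out
  }
  dc <- pick(degrees(case_net), gene_universe)
  dn <- pick(degrees(control_net), gene_universe)
  kc <- pick(core_numbers(case_net), gene_universe)
  kn <- pick(core_numbers(control_net), gene_universe)
  out <- data.frame(gene_id = gene_universe,
                    degree_case = unname(dc), degree_control = unname(dn),
                    kcore_case = unname(kc), kcore_control = unname(kn),
                    dif_degree = unname(dc - dn),
                    dif_kcore = unname(kc - kn),
                    stringsAsFactors = FALSE)
  class(out) <- c("topology_table", "data.frame")
  out
}

#' Construct a topology table from precomputed columns
#'
#' For working with externally tabulated degree/k-core values (dif columns
#' are recomputed, never trusted).
#'
#' @param gene_id,degree_case,degree_control,kcore_case,kcore_control
#'   Parallel per-gene vectors.
#' @return A `topology_table` data.frame.
#' @export
topology_table <- function(gene_id, degree_case, degree_control,
                           kcore_case, kcore_control) {
  out <- data.frame(gene_id = as.character(gene_id),
                    degree_case = as.integer(degree_case),
                    degree_control = as.integer(degree_control),
                    kcore_case = as.integer(kcore_case),
                    kcore_control = as.integer(kcore_control),
                    stringsAsFactors = FALSE)
  out$dif_degree <- out$degree_case - out$degree_control
  out$dif_kcore <- out$kcore_case - out$kcore_control
  class(out) <- c("topology_table", "data.frame")
  out
}

#' Top-k genes by differential hubness
#'
#' Deterministic ranking: `|dif_degree|` descending, then `|dif_kcore|`
#' descending, then gene id ascending.
#'
#' @param records A `topology_table` data.frame.
#' @param k Number of genes to keep, default 20; capped at the record count.
#' @return The first `k` rows in rank order.
#' @export
rank_top <- function(records, k = 20) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  ord <- order(-abs(records$dif_degree), -abs(records$dif_kcore),
               records$gene_id)
  out <- records[ord[seq_len(min(k, nrow(records)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anchor-relative candidate screen
#'
#' A gene is a candidate when its differential hubness dominates the
#' anchor's componentwise in magnitude: `|dif_degree| >= |anchor dif_degree|`
#' and `|dif_kcore| >= |anchor dif_kcore|`, ties allowed; the anchor itself
#' is never a candidate.
#'
#' @param records A `topology_table` data.frame.
#' @param anchor Gene id present in `records` (e.g. `"CD274"`).
#' @return List of class `candidate_selection` with `anchor`,
#'   `anchor_dif_degree`, `anchor_dif_kcore`, `candidates` (gene ids in
#'   [rank_top()] order) and `rule`.
#' @export
select_candidates <- function(records, anchor) {
  hit <- which(records$gene_id == anchor)
  if (length(hit) != 1L) {
    stop("anchor gene '", anchor, "' not found (or not unique) in records",
         call. = FALSE)
  }
  a_dd <- abs(records$dif_degree[hit])
  a_dk <- abs(records$dif_kcore[hit])
  ok <- abs(records$dif_degree) >= a_dd & abs(records$dif_kcore) >= a_dk &
    records$gene_id != anchor
  ranked <- rank_top(records[ok, , drop = FALSE],
                     k = max(1L, sum(ok)))
  structure(list(anchor = anchor,
                 anchor_dif_degree = records$dif_degree[hit],
                 anchor_dif_kcore = records$dif_kcore[hit],
                 candidates = if (sum(ok)) ranked$gene_id else character(0L),
                 rule = "abs(dif) componentwise >= anchor, ties allowed"),
            class = "candidate_selection")
}

#' @export
print.candidate_selection <- function(x, ...) {
  cat("Anchor ", x$anchor, " (dif-degree ", x$anchor_dif_degree,
      ", dif-kcore ", x$anchor_dif_kcore, "): ",
      length(x$candidates), " candidate(s)\n", sep = "")
  if (length(x$candidates)) {
    cat("  ", paste(x$candidates, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write a topology table
#' @param records A `topology_table` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_topology_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
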