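#' Gene-set over-representation by Fisher's exact and chi-square tests
#'
#' For each gene set, tabulates the 2x2 table over the analysis universe —
#' `a` = DEGs in the set, `b` = DEGs outside it, `c` = non-DEG set members,
#' `d` = neither — and scores over-representation with the one-sided
#' hypergeometric (Fisher) tail `P(X >= a)` and the 1-df Pearson chi-square
#' statistic (no continuity correction unless `correct = TRUE`). FDR is
#' Benjamini-Hochberg over all tested terms' Fisher p-values.
#'
#' @param deg_ids Character vector of called DEG ids (subset of the universe).
#' @param universe_ids Character vector: all genes eligible for membership
#'   counting. Set members are intersected with the universe before counting.
#' @param sets A `gene_sets` object (see [read_gmt()]).
#' @param correct Apply Yates continuity correction to the chi-square test.
#' @return data.frame with one row per tested term: `term_id`, `term_name`,
#'   `a`, `b`, `c`, `d`, `genes` (comma-separated `a`-cell members),
#'   `fisher_p`, `chisq_p`, `fdr`. Terms with zero in-universe members are
#'   skipped with a warning.
#' @export
fisher_enrichment <- function(deg_ids, universe_ids, sets, correct = FALSE) {
  universe_ids <- unique(as.character(universe_ids))
  if (length(universe_ids) == 0L) {
    stop("empty gene universe", call. = FALSE)
  }
  deg_ids <- unique(as.character(deg_ids))
  stray <- setdiff(deg_ids, universe_ids)
  if (length(stray)) {
    stop("DEG id(s) outside the universe: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  }
  stopifnot(inherits(sets, "gene_sets"))
  n_universe <- length(universe_ids)
  n_deg <- length(deg_ids)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]]$genes, universe_ids)
    if (length(members) == 0L) return(NULL)
    hits <- intersect(members, deg_ids)
    a <- length(hits)
    b <- n_deg - a
    cc <- length(members) - a
    d <- n_universe - a - b - cc
    data.frame(term_id = id, term_name = sets[[id]]$name,
               a = a, b = b, c = cc, d = d,
               genes = paste(sort(hits), collapse = ","),
               fisher_p = hyper_upper_tail(a, b, cc, d),
               chisq_p = chisq_2x2_p(a, b, cc, d, correct = correct),
               stringsAsFactors = FALSE)
  })
  skipped <- names(sets)[vapply(rows, is.null, logical(1L))]
  if (length(skipped)) {
    warning("skipped term(s) with no in-universe members: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), genes = character(0),
                      fisher_p = numeric(0), chisq_p = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE)
    return(out)
  }
  out$fdr <- bh_adjust(out$fisher_p)
  rownames(out) <- NULL
  out
}

# One-sided over-representation tail P(X >= a) for the table (a,b,c,d):
# X ~ Hypergeometric(white = a+c set members, black = b+d, drawn = a+b DEGs).
hyper_upper_tail <- function(a, b, c, d) {
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

# Pearson chi-square on a 2x2 table, 1 df; NA when a margin is empty.
chisq_2x2_p <- function(a, b, c, d, correct = FALSE) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(NA_real_)
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Select network genes from enrichment results
#'
#' A DEG enters the network gene set when it belongs to at least one GO-style
#' term and at least one pathway term that are each significant at
#' `fisher_p < p_max`. The `n_lnc` lncRNA-biotype genes with the largest
#' absolute log2 fold change (ties broken lexicographically by gene id) are
#' appended. The result is deduplicated and deterministically ordered:
#' qualifying DEGs sorted by gene id, then the lncRNA additions by decreasing
#' |log2fc|.
#'
#' @param go_records,pathway_records data.frames from [fisher_enrichment()]
#'   run on the GO-style and pathway collections.
#' @param degs A `deg_table`; its called DEGs define eligibility.
#' @param matrix Expression matrix carrying a `gene_biotype` attribute
#'   (required when `n_lnc > 0`).
#' @param p_max Raw Fisher significance gate, default 0.01 (strict `<`).
#' @param n_lnc Number of top-|log2fc| lncRNA genes to append, default 30.
#' @return Character vector of network gene ids.
#' @export
select_network_genes <- function(go_records, pathway_records, degs, matrix,
                                 p_max = 0.01, n_lnc = 30) {
  called <- filter_degs(degs)$all
  sig_members <- function(records) {
    if (is.null(records) || nrow(records) == 0L) return(character(0L))
    sig <- records[!is.na(records$fisher_p) & records$fisher_p < p_max, ,
                   drop = FALSE]
    unique(unlist(strsplit(sig$genes[nzchar(sig$genes)], ",", fixed = TRUE)))
  }
  in_go <- sig_members(go_records)
  in_pw <- sig_members(pathway_records)
  core <- sort(intersect(called, intersect(in_go, in_pw)))

  lnc <- character(0L)
  if (n_lnc > 0L) {
    biotype <- attr(matrix, "gene_biotype")
    if (is.null(biotype)) {
      stop("matrix carries no gene_biotype annotation; set n_lnc = 0 or ",
           "load the matrix with a biotype map", call. = FALSE)
    }
    lnc_ids <- names(biotype)[biotype == "lncRNA"]
    lnc_ids <- intersect(lnc_ids, degs$gene_id)
    if (length(lnc_ids)) {
      lfc <- abs(degs$log2fc[match(lnc_ids, degs$gene_id)])
      ord <- order(-lfc, lnc_ids)
      lnc <- lnc_ids[ord][seq_len(min(n_lnc, length(lnc_ids)))]
    }
  }
  unique(c(core, setdiff(lnc, core)))
}
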