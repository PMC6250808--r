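#' Pearson product-moment correlation of two sample vectors
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return The correlation, clamped to `[-1, 1]` against floating-point
#'   rounding; `NA` with a warning when either vector has zero variance (the
#'   pair is then excluded from network construction).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3 samples", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
  min(1, max(-1, r))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Analytic test under bivariate-normal sampling: `t = r * sqrt(n - 2) /
#' sqrt(1 - r^2)` referred to a t distribution with `n - 2` degrees of
#' freedom, two-sided. `|r| = 1` gives p = 0.
#'
#' @param r Correlation(s) in `[-1, 1]` (vectorized).
#' @param n Number of samples the correlation was computed from, `n >= 3`.
#' @return Two-sided p-value(s).
#' @export
correlation_pvalue <- function(r, n) {
  if (any(n < 3)) stop("correlation p-value needs n >= 3", call. = FALSE)
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must be <= 1", call. = FALSE)
  p <- rep(NA_real_, length(r))
  exact <- !is.na(r) & abs(r) == 1
  p[exact] <- 0
  ok <- !is.na(r) & !exact
  tt <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}

new_group_network <- function(group, nodes, edges, n_samples, fdr_max,
                              n_pairs_tested = NA_integer_,
                              n_pairs_skipped = 0L) {
  structure(list(group = group, nodes = nodes, edges = edges,
                 n_samples = n_samples, fdr_max = fdr_max,
                 n_pairs_tested = n_pairs_tested,
                 n_pairs_skipped = n_pairs_skipped),
            class = "group_network")
}

#' @export
print.group_network <- function(x, ...) {
  cat("Co-expression network [", x$group, "]: ", length(x$nodes),
      " nodes, ", nrow(x$edges), " edges (",
      sum(x$edges$style == "Positive"), " positive, ",
      sum(x$edges$style == "Negative"), " negative) at FDR < ",
      x$fdr_max, ", n = ", x$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Build one group's signed co-expression network
#'
#' Computes the Pearson correlation and its analytic p-value for every
#' unordered gene pair using only the chosen group's samples, applies
#' Benjamini-Hochberg correction across exactly that pair universe, and keeps
#' edges with `fdr < fdr_max` (strict). Edge style is `"Positive"` for
#' `r > 0` and `"Negative"` for `r < 0`. Pairs with undefined correlation
#' (zero variance in either gene) are excluded from both the test universe
#' and the edge set and counted in `n_pairs_skipped`. Genes with no surviving
#' edge remain in the node list with degree 0.
#'
#' @param matrix Numeric gene-by-sample matrix.
#' @param design A [sample_design()] object.
#' @param group `"control"` or `"case"`.
#' @param gene_ids Genes to network (subset of matrix rownames); defaults to
#'   all matrix genes.
#' @param fdr_max Edge significance threshold, default 0.01.
#' @return A `group_network` object; edges stored with
#'   `gene_a < gene_b` lexicographically, ordered by increasing p-value.
#' @export
build_group_network <- function(matrix, design, group = c("control", "case"),
                                gene_ids = rownames(matrix),
                                fdr_max = 0.01) {
  group <- match.arg(group)
  validate_expression_matrix(matrix)
  missing <- setdiff(gene_ids, rownames(matrix))
  if (length(missing)) {
    stop("gene id(s) not in matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  samples <- group_samples(matrix, design, group)
  n <- length(samples)
  if (n < 3L) stop("group '", group, "' has ", n, " samples; need >= 3",
                   call. = FALSE)
  sub <- matrix[gene_ids, samples, drop = FALSE]
  n_genes <- length(gene_ids)
  empty_edges <- data.frame(gene_a = character(0), gene_b = character(0),
                            r = numeric(0), n = integer(0),
                            p_value = numeric(0), fdr = numeric(0),
                            style = character(0), stringsAsFactors = FALSE)
  if (n_genes < 2L) {
    return(new_group_network(group, gene_ids, empty_edges, n, fdr_max, 0L))
  }
  sds <- apply(sub, 1L, stats::sd)
  flat <- sds == 0
  cormat <- suppressWarnings(stats::cor(t(sub)))
  cormat[cormat > 1] <- 1
  cormat[cormat < -1] <- -1
  idx <- which(upper.tri(cormat), arr.ind = TRUE)
  # drop pairs involving a zero-variance gene from the test universe
  defined <- !(flat[idx[, 1L]] | flat[idx[, 2L]])
  n_skipped <- sum(!defined)
  idx <- idx[defined, , drop = FALSE]
  if (nrow(idx) == 0L) {
    warning("all gene pairs skipped (zero variance); empty network",
            call. = FALSE)
    return(new_group_network(group, gene_ids, empty_edges, n, fdr_max,
                             0L, n_skipped))
  }
  r <- cormat[idx]
  p <- correlation_pvalue(r, n)
  # |r| = 1 gives p = 0; clamp to the smallest double so the BH step-up
  # (whose contract is p in (0, 1]) keeps such edges at any threshold
  fdr <- bh_adjust(pmax(p, .Machine$double.xmin))
  keep <- fdr < fdr_max
  ga <- gene_ids[idx[, 1L]]; gb <- gene_ids[idx[, 2L]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  edges <- data.frame(gene_a = ga[keep], gene_b = gb[keep],
                      r = r[keep], n = rep(n, sum(keep)),
                      p_value = p[keep],
                      fdr = fdr[keep],
                      style = ifelse(r[keep] > 0, "Positive", "Negative"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$p_value, edges$gene_a, edges$gene_b), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  new_group_network(group, gene_ids, edges, n, fdr_max,
                    n_pairs_tested = nrow(idx), n_pairs_skipped = n_skipped)
}
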