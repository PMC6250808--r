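#' Per-gene log2 fold change, case vs control
#'
#' @param matrix Numeric gene-by-sample matrix.
#' @param design A [sample_design()] object.
#' @param mode `"diff_of_logmeans"` (default; the matrix is already on a log2
#'   scale, so the fold change is the difference of group means) or
#'   `"ratio_of_means"` (`log2(mean_case / mean_control)` on linear-scale
#'   values).
#' @param pseudocount Added to both group means in ratio mode; 0 disables.
#' @return Named numeric vector of log2 fold changes, positive = higher in
#'   the case group. In ratio mode a gene whose (pseudocounted) group mean is
#'   not strictly positive gets `NA` with a warning rather than a fabricated
#'   value.
#' @export
compute_log2fc <- function(matrix, design,
                           mode = c("diff_of_logmeans", "ratio_of_means"),
                           pseudocount = 0) {
  mode <- match.arg(mode)
  validate_expression_matrix(matrix)
  ctrl <- group_samples(matrix, design, "control")
  case <- group_samples(matrix, design, "case")
  m_ctrl <- rowMeans(matrix[, ctrl, drop = FALSE])
  m_case <- rowMeans(matrix[, case, drop = FALSE])
  if (mode == "diff_of_logmeans") {
    lfc <- m_case - m_ctrl
  } else {
    m_ctrl <- m_ctrl + pseudocount
    m_case <- m_case + pseudocount
    bad <- m_ctrl <= 0 | m_case <= 0
    lfc <- rep(NA_real_, nrow(matrix))
    lfc[!bad] <- log2(m_case[!bad] / m_ctrl[!bad])
    if (any(bad)) {
      warning(sum(bad), " gene(s) with non-positive group mean in ",
              "ratio mode; log2fc set to NA (consider a pseudocount)",
              call. = FALSE)
    }
  }
  stats::setNames(as.numeric(lfc), rownames(matrix))
}

#' Welch two-sample test per gene
#'
#' The stand-in differential test of this pipeline: a two-sided Welch
#' (unequal-variance) t-test on the normalized, log-scale matrix, vectorized
#' over genes. Count-model alternatives can be supplied as a precomputed DEG
#' table via [read_deg_table()].
#'
#' @inheritParams compute_log2fc
#' @return Named numeric vector of two-sided p-values in (0, 1]. A degenerate
#'   gene (zero variance in both groups, equal means) gets p = 1; zero
#'   variance with unequal means gives p ~ 0.
#' @export
two_group_test <- function(matrix, design) {
  validate_expression_matrix(matrix)
  ctrl <- group_samples(matrix, design, "control")
  case <- group_samples(matrix, design, "case")
  if (length(ctrl) < 2L || length(case) < 2L) {
    stop("Welch test needs >= 2 samples per group; supply a precomputed ",
         "DEG table (read_deg_table) for designs this small", call. = FALSE)
  }
  x <- matrix[, ctrl, drop = FALSE]
  y <- matrix[, case, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # zero variance in both groups: p = 1 when means agree, -> 0 otherwise
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  stats::setNames(as.numeric(p), rownames(matrix))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values, all in (0, 1].
#' @return Adjusted values (FDR), same order as the input, capped at 1 and
#'   monotone nondecreasing in p rank; tied p-values share the adjusted value.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0L))
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must all lie in (0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / seq(m, 1L) * p[o]))[ro]
  names(adj) <- names(p_values)
  adj
}

#' Assemble a DEG table
#'
#' @param gene_id,log2fc,p_value,fdr Parallel per-gene vectors.
#' @param fdr_max Maximum FDR for a DEG call (strict `<`), default 0.05.
#' @param min_abs_log2fc Minimum absolute log2 fold change (strict `>`),
#'   default 1.
#' @return A data.frame of class `deg_table` with columns `gene_id`,
#'   `log2fc`, `p_value`, `fdr`, `direction` (`up`/`down`/`ns`) and the
#'   thresholds stored as attributes.
#' @export
deg_table <- function(gene_id, log2fc, p_value, fdr,
                      fdr_max = 0.05, min_abs_log2fc = 1.0) {
  stopifnot(length(gene_id) == length(log2fc),
            length(log2fc) == length(p_value),
            length(p_value) == length(fdr))
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene id(s) in DEG table", call. = FALSE)
  }
  called <- !is.na(fdr) & !is.na(log2fc) &
    fdr < fdr_max & abs(log2fc) > min_abs_log2fc
  direction <- ifelse(called, ifelse(log2fc > 0, "up", "down"), "ns")
  out <- data.frame(gene_id = as.character(gene_id),
                    log2fc = as.numeric(log2fc),
                    p_value = as.numeric(p_value),
                    fdr = as.numeric(fdr),
                    direction = direction,
                    stringsAsFactors = FALSE)
  attr(out, "fdr_max") <- fdr_max
  attr(out, "min_abs_log2fc") <- min_abs_log2fc
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Run the differential-expression stage
#'
#' Convenience composition: [compute_log2fc()] + [two_group_test()] +
#' [bh_adjust()] + DEG call.
#'
#' @inheritParams compute_log2fc
#' @inheritParams deg_table
#' @return A `deg_table` data.frame, one row per matrix gene, input order.
#' @export
run_differential_expression <- function(matrix, design,
                                        mode = c("diff_of_logmeans",
                                                 "ratio_of_means"),
                                        fdr_max = 0.05,
                                        min_abs_log2fc = 1.0,
                                        pseudocount = 0) {
  mode <- match.arg(mode)
  lfc <- compute_log2fc(matrix, design, mode = mode,
                        pseudocount = pseudocount)
  p <- two_group_test(matrix, design)
  deg_table(gene_id = rownames(matrix), log2fc = lfc, p_value = p,
            fdr = bh_adjust(p), fdr_max = fdr_max,
            min_abs_log2fc = min_abs_log2fc)
}

#' Called DEGs, partitioned by direction
#'
#' Applies the strict thresholds `fdr < fdr_max` and
#' `|log2fc| > min_abs_log2fc` — genes exactly at either boundary are not
#' called.
#'
#' @param table A `deg_table` data.frame.
#' @param fdr_max,min_abs_log2fc Thresholds; default to those stored in the
#'   table.
#' @return List with character vectors `up`, `down` and `all` (up then down,
#'   each in table order).
#' @export
filter_degs <- function(table, fdr_max = attr(table, "fdr_max"),
                        min_abs_log2fc = attr(table, "min_abs_log2fc")) {
  if (is.null(fdr_max)) fdr_max <- 0.05
  if (is.null(min_abs_log2fc)) min_abs_log2fc <- 1.0
  called <- !is.na(table$fdr) & !is.na(table$log2fc) &
    table$fdr < fdr_max & abs(table$log2fc) > min_abs_log2fc
  up <- table$gene_id[called & table$log2fc > 0]
  down <- table$gene_id[called & table$log2fc < 0]
  list(up = up, down = down, all = c(up, down))
}
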