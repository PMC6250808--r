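#' Read a gene-by-sample expression matrix
#'
#' Loads a delimited text file with gene identifiers in the first column and a
#' header row of sample identifiers. Values are expected to be normalized,
#' log-scale expression; the package performs no normalization of its own.
#'
#' @param path Path to a delimited text file (genes in rows, samples in
#'   columns, header row of sample ids, first column of gene ids).
#' @param delimiter Field delimiter, default tab.
#' @param uppercase_ids If `TRUE`, gene and sample identifiers are upper-cased
#'   on load. Identifier matching everywhere else in the package is exact and
#'   case-sensitive, so this is the only sanctioned normalization hook.
#' @param biotype Optional named character vector mapping gene ids to a
#'   biotype label (`"protein_coding"`, `"lncRNA"`, `"other"`); attached as the
#'   `gene_biotype` attribute and consumed by [select_network_genes()].
#' @return A numeric matrix (genes x samples) with unique dimnames, all values
#'   finite. Row and column order follow the file.
#' @details Duplicate gene or sample identifiers and non-numeric or
#'   missing/non-finite cells are load errors, never silently repaired.
#' @seealso [write_expression_matrix()], [read_sample_design()]
#' @export
read_expression_matrix <- function(path, delimiter = "\t",
                                   uppercase_ids = FALSE, biotype = NULL) {
  if (!file.exists(path)) {
    stop("expression matrix file not found: ", path, call. = FALSE)
  }
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          row.names = NULL, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("expression matrix must have a gene-id column plus >= 1 sample column",
         call. = FALSE)
  }
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  if (uppercase_ids) {
    gene_ids <- toupper(gene_ids)
    sample_ids <- toupper(sample_ids)
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicate gene id(s) in ", path, ": ",
         paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample id(s) in ", path, ": ",
         paste(dup_s, collapse = ", "), call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)), USE.NAMES = FALSE)
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(gene_ids, sample_ids))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric or non-finite expression value at gene '%s', sample '%s'",
      gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]), call. = FALSE)
  }
  validate_expression_matrix(vals)
  if (!is.null(biotype)) {
    attr(vals, "gene_biotype") <- check_biotype(biotype, gene_ids)
  }
  vals
}

#' Write an expression matrix
#'
#' @param matrix Numeric gene-by-sample matrix with dimnames.
#' @param path Output file path.
#' @param delimiter Field delimiter, default tab.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(matrix, path, delimiter = "\t") {
  validate_expression_matrix(matrix)
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

validate_expression_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix must carry gene ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(matrix))) {
    stop("duplicate gene id(s): ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(matrix))) {
    stop("duplicate sample id(s): ",
         paste(unique(colnames(matrix)[duplicated(colnames(matrix))]),
               collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(matrix))) {
    stop("expression matrix contains NA/NaN/Inf values", call. = FALSE)
  }
  invisible(matrix)
}

check_biotype <- function(biotype, gene_ids) {
  allowed <- c("protein_coding", "lncRNA", "other")
  if (is.null(names(biotype)) || !all(biotype %in% allowed)) {
    stop("biotype must be a named character vector with values in {",
         paste(allowed, collapse = ", "), "}", call. = FALSE)
  }
  out <- rep("other", length(gene_ids))
  names(out) <- gene_ids
  hit <- intersect(names(biotype), gene_ids)
  out[hit] <- biotype[hit]
  out
}

#' Construct a two-group sample design
#'
#' @param assignments Named character vector: `sample_id -> group label`.
#' @param control,case The two group labels; defaults `"control"` and
#'   `"case"`.
#' @return An object of class `sample_design`: list with `assignments`,
#'   `control`, `case`, `n_control`, `n_case`.
#' @details Exactly two group labels must occur and every label must be one of
#'   `control`/`case`. Downstream correlation p-values need `df = n - 2 >= 1`,
#'   so at least 3 samples per group are required.
#' @export
sample_design <- function(assignments, control = "control", case = "case") {
  if (is.null(names(assignments)) || anyDuplicated(names(assignments))) {
    stop("assignments must be a named vector with unique sample ids",
         call. = FALSE)
  }
  if (identical(control, case)) {
    stop("control and case labels must differ", call. = FALSE)
  }
  extra <- setdiff(unique(assignments), c(control, case))
  if (length(extra)) {
    stop("unknown group label(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  n_control <- sum(assignments == control)
  n_case <- sum(assignments == case)
  if (n_control < 3L || n_case < 3L) {
    stop("each group needs >= 3 samples (got ", n_control, " control, ",
         n_case, " case)", call. = FALSE)
  }
  structure(list(assignments = assignments, control = control, case = case,
                 n_control = n_control, n_case = n_case),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  cat("Two-group sample design: ", x$n_control, " '", x$control,
      "' vs ", x$n_case, " '", x$case, "' samples\n", sep = "")
  invisible(x)
}

#' Read a two-column sample design file
#'
#' @param path TSV with columns `sample_id` and `group` (header required).
#' @inheritParams sample_design
#' @return A [sample_design()] object.
#' @export
read_sample_design <- function(path, control = "control", case = "case") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(df))) {
    stop("design file must have columns 'sample_id' and 'group'",
         call. = FALSE)
  }
  assignments <- stats::setNames(df$group, df$sample_id)
  sample_design(assignments, control = control, case = case)
}

#' Write a sample design file
#' @param design A [sample_design()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_design <- function(design, path) {
  stopifnot(inherits(design, "sample_design"))
  utils::write.table(
    data.frame(sample_id = names(design$assignments),
               group = unname(design$assignments)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Samples of one group, in matrix column order.
group_samples <- function(matrix, design, group = c("control", "case")) {
  group <- match.arg(group)
  label <- if (group == "control") design$control else design$case
  wanted <- names(design$assignments)[design$assignments == label]
  missing <- setdiff(colnames(matrix), names(design$assignments))
  if (length(missing)) {
    stop("sample(s) in matrix but not in design: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  intersect(colnames(matrix), wanted)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per nonblank line, tab-separated fields
#' `term_id`, `description`, then one or more member gene ids.
#'
#' @param path Path to the GMT file.
#' @return A `gene_sets` object: named list, one element per term, each a list
#'   with `name` (description) and `genes` (character vector of members).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- list()
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop("GMT parse error at line ", i,
           ": need term, description and >= 1 member", call. = FALSE)
    }
    sets[[fields[1L]]] <- list(name = fields[2L],
                               genes = unique(fields[-(1:2)]))
  }
  structure(sets, class = "gene_sets")
}

#' Write a GMT gene-set file
#' @param sets A `gene_sets` object (see [read_gmt()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_sets"))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, sets[[id]]$name, sets[[id]]$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write a group co-expression network
#'
#' Serializes a [build_group_network()] result either as a TSV edge list
#' (columns `gene_a`, `gene_b`, `pearson_r`, `p_value`, `fdr`, `style`; each
#' undirected pair written once with `gene_a < gene_b` lexicographically;
#' `r` to 7 decimals, p and FDR in scientific notation to 6 significant
#' digits) or as GraphML with node attributes `degree`, `core_number` and edge
#' attributes `r`, `p`, `fdr`, `style`.
#'
#' @param network A `group_network` object.
#' @param path Output path.
#' @param format `"edge_tsv"` (default) or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_group_network <- function(network, path,
                                format = c("edge_tsv", "graphml")) {
  stopifnot(inherits(network, "group_network"))
  format <- match.arg(format)
  e <- network$edges
  if (format == "edge_tsv") {
    header <- paste(c("gene_a", "gene_b", "pearson_r", "p_value", "fdr",
                      "style"), collapse = "\t")
    rows <- character(0L)
    if (nrow(e)) {
      rows <- sprintf("%s\t%s\t%.7f\t%s\t%s\t%s",
                      e$gene_a, e$gene_b, e$r,
                      formatC(e$p_value, format = "e", digits = 5),
                      formatC(e$fdr, format = "e", digits = 5),
                      e$style)
    }
    writeLines(c(header, rows), path)
  } else {
    g <- network_to_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

# group_network -> igraph with the attribute schema of the GraphML interface
network_to_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network$nodes),
                            name = network$nodes)
  if (nrow(network$edges)) {
    idx <- rbind(match(network$edges$gene_a, network$nodes),
                 match(network$edges$gene_b, network$nodes))
    g <- igraph::add_edges(g, as.vector(idx),
                           r = network$edges$r,
                           p = network$edges$p_value,
                           fdr = network$edges$fdr,
                           style = network$edges$style)
  }
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::V(g)$core_number <- igraph::coreness(g)
  g
}

#' Read a group network from a TSV edge list
#'
#' Inverse of [write_group_network()] for the `edge_tsv` format. Nodes with no
#' surviving edge are not represented in an edge list, so `nodes` may be
#' supplied explicitly to restore them.
#'
#' @param path Edge-list TSV path.
#' @param group Group label to attach.
#' @param n_samples Number of samples the network was estimated from.
#' @param nodes Optional full node list (defaults to genes seen in edges).
#' @param fdr_max Edge significance threshold the file was built with.
#' @return A `group_network` object.
#' @export
read_group_network <- function(path, group = NA_character_,
                               n_samples = NA_integer_, nodes = NULL,
                               fdr_max = 0.01) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "pearson_r", "p_value", "fdr", "style")
  if (!all(need %in% colnames(df))) {
    stop("edge list must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  edges <- data.frame(gene_a = df$gene_a, gene_b = df$gene_b,
                      r = df$pearson_r, n = rep(n_samples, nrow(df)),
                      p_value = df$p_value, fdr = df$fdr,
                      style = df$style, stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  new_group_network(group = group, nodes = nodes, edges = edges,
                    n_samples = n_samples, fdr_max = fdr_max)
}

#' Write a DEG table
#' @param deg_table A `deg_table` data.frame (see [deg_table()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(deg_table, path) {
  utils::write.table(deg_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a precomputed DEG table
#'
#' Allows users to bypass the built-in Welch stage with differential
#' expression results from a dedicated count-based tool.
#'
#' @param path TSV with columns `gene_id`, `log2fc`, `p_value`, `fdr` and
#'   optionally `direction` (recomputed if absent).
#' @param fdr_max,min_abs_log2fc Call thresholds used to (re)derive
#'   `direction`; defaults mirror the pipeline defaults.
#' @return A `deg_table` data.frame.
#' @export
read_deg_table <- function(path, fdr_max = 0.05, min_abs_log2fc = 1.0) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "p_value", "fdr")
  if (!all(need %in% colnames(df))) {
    stop("DEG table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  deg_table(gene_id = df$gene_id, log2fc = df$log2fc, p_value = df$p_value,
            fdr = df$fdr, fdr_max = fdr_max,
            min_abs_log2fc = min_abs_log2fc)
}
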