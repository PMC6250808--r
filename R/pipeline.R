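#' Assemble and validate a pipeline configuration
#'
#' Every default equals the screen's canonical threshold, so a bare run on
#' user data mirrors the published settings: DEG call at FDR < 0.05 and
#' |log2FC| > 1, enrichment gate at raw Fisher P < 0.01 on both collections,
#' edge significance at FDR < 0.01, 30 lncRNA additions, top-20 ranking.
#'
#' @param matrix Path to the expression matrix TSV.
#' @param design Path to the two-column design TSV.
#' @param go_gmt,pathway_gmt Paths to the GO-style and pathway GMT files.
#' @param out_dir Output directory (created if missing).
#' @param anchor Anchor gene id (e.g. `"CD274"`).
#' @param deg_table Optional path to a precomputed DEG table; bypasses the
#'   Welch stage.
#' @param deg_fdr,deg_min_abs_log2fc,enrich_p,edge_fdr,n_lnc,top_k
#'   Stage thresholds (see description).
#' @param control,case Group labels in the design file.
#' @param biotype Optional path to a two-column TSV (`gene_id`, `biotype`)
#'   used for the lncRNA additions.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(matrix, design, go_gmt, pathway_gmt, out_dir,
                            anchor, deg_table = NULL,
                            deg_fdr = 0.05, deg_min_abs_log2fc = 1.0,
                            enrich_p = 0.01, edge_fdr = 0.01,
                            n_lnc = 30, top_k = 20,
                            control = "control", case = "case",
                            biotype = NULL, seed = 1L) {
  cfg <- list(matrix = matrix, design = design, go_gmt = go_gmt,
              pathway_gmt = pathway_gmt, out_dir = out_dir,
              anchor = anchor, deg_table = deg_table,
              deg_fdr = deg_fdr, deg_min_abs_log2fc = deg_min_abs_log2fc,
              enrich_p = enrich_p, edge_fdr = edge_fdr,
              n_lnc = n_lnc, top_k = top_k,
              control = control, case = case, biotype = biotype,
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  need <- c("matrix", "design", "go_gmt", "pathway_gmt", "out_dir", "anchor")
  miss <- need[!vapply(cfg[need], function(x) is.character(x) && nzchar(x),
                       logical(1L))]
  if (length(miss)) {
    stop("pipeline config missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("deg_fdr", "enrich_p", "edge_fdr")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1) {
      stop("config threshold '", f, "' must lie in (0, 1]", call. = FALSE)
    }
  }
  if (cfg$deg_min_abs_log2fc < 0) {
    stop("deg_min_abs_log2fc must be >= 0", call. = FALSE)
  }
  if (cfg$n_lnc < 0) stop("n_lnc must be >= 0", call. = FALSE)
  if (cfg$top_k < 1) stop("top_k must be >= 1", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are the arguments of
#'   [pipeline_config()]; relative paths are resolved against the file's
#'   directory.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("matrix", "design", "go_gmt", "pathway_gmt", "deg_table",
              "biotype", "out_dir")) {
    if (!is.null(raw[[f]]) && !grepl("^(/|[A-Za-z]:)", raw[[f]])) {
      raw[[f]] <- file.path(base, raw[[f]])
    }
  }
  do.call(pipeline_config, raw)
}

#' Run the candidate-gene screen end to end
#'
#' Stage order: differential expression (or a supplied DEG table) ->
#' enrichment on the GO-style and pathway collections -> network-gene
#' selection -> per-group signed co-expression networks -> differential
#' topology -> top-k ranking -> anchor-relative candidate selection. Every
#' intermediate table is written to `out_dir` (`deg.tsv`,
#' `enrichment_go.tsv`, `enrichment_pathway.tsv`, `network_case.tsv`,
#' `network_control.tsv` plus GraphML twins, `topology.tsv`,
#' `candidates.tsv`) together with `manifest.json` recording the config,
#' seed, package version and per-stage counts.
#'
#' @param config A `pipeline_config` (from [pipeline_config()] or
#'   [read_pipeline_config()]).
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with `deg`, `go`, `pathway`, `network_genes`,
#'   `net_case`, `net_control`, `topology`, `top`, `candidates`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_pipeline_config(unclass(config))
  say <- function(...) if (!quiet) message("[coexscreen] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  biotype <- NULL
  if (!is.null(config$biotype)) {
    bt <- utils::read.table(config$biotype, sep = "\t", header = TRUE,
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    biotype <- stats::setNames(bt[[2L]], bt[[1L]])
  }
  mat <- read_expression_matrix(config$matrix, biotype = biotype)
  design <- read_sample_design(config$design, control = config$control,
                               case = config$case)
  say("loaded ", nrow(mat), " genes x ", ncol(mat), " samples (",
      design$n_control, " control / ", design$n_case, " case)")

  if (!is.null(config$deg_table)) {
    deg <- read_deg_table(config$deg_table, fdr_max = config$deg_fdr,
                          min_abs_log2fc = config$deg_min_abs_log2fc)
    say("using precomputed DEG table: ", nrow(deg), " genes")
  } else {
    deg <- run_differential_expression(
      mat, design, fdr_max = config$deg_fdr,
      min_abs_log2fc = config$deg_min_abs_log2fc)
  }
  called <- filter_degs(deg)
  say("DEG call at FDR < ", config$deg_fdr, ", |log2FC| > ",
      config$deg_min_abs_log2fc, ": ", length(called$all), " genes (",
      length(called$up), " up, ", length(called$down), " down)")
  write_deg_table(deg, file.path(config$out_dir, "deg.tsv"))

  go_sets <- read_gmt(config$go_gmt)
  pw_sets <- read_gmt(config$pathway_gmt)
  go <- fisher_enrichment(called$all, deg$gene_id, go_sets)
  pw <- fisher_enrichment(called$all, deg$gene_id, pw_sets)
  say("enrichment: ", sum(go$fisher_p < config$enrich_p), "/", nrow(go),
      " GO-style and ", sum(pw$fisher_p < config$enrich_p), "/", nrow(pw),
      " pathway terms at P < ", config$enrich_p)
  utils::write.table(go, file.path(config$out_dir, "enrichment_go.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pw, file.path(config$out_dir, "enrichment_pathway.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  net_genes <- select_network_genes(go, pw, deg, mat,
                                    p_max = config$enrich_p,
                                    n_lnc = config$n_lnc)
  if (length(net_genes) < 2L) {
    stop("network-gene selection produced ", length(net_genes),
         " gene(s); cannot build a network", call. = FALSE)
  }
  say("network gene set: ", length(net_genes), " genes")

  net_case <- build_group_network(mat, design, "case", net_genes,
                                  fdr_max = config$edge_fdr)
  net_ctrl <- build_group_network(mat, design, "control", net_genes,
                                  fdr_max = config$edge_fdr)
  say("case network: ", nrow(net_case$edges), " edges; control network: ",
      nrow(net_ctrl$edges), " edges (FDR < ", config$edge_fdr, ")")
  for (nw in list(net_case, net_ctrl)) {
    stem <- file.path(config$out_dir, paste0("network_", nw$group))
    write_group_network(nw, paste0(stem, ".tsv"), "edge_tsv")
    write_group_network(nw, paste0(stem, ".graphml"), "graphml")
  }

  topo <- differential_topology(net_case, net_ctrl, net_genes)
  write_topology_table(topo, file.path(config$out_dir, "topology.tsv"))
  top <- rank_top(topo, k = config$top_k)

  if (!config$anchor %in% topo$gene_id) {
    stop("anchor gene '", config$anchor,
         "' is not in the network gene set; screen aborted", call. = FALSE)
  }
  cand <- select_candidates(topo, config$anchor)
  say("anchor ", config$anchor, ": ", length(cand$candidates),
      " candidate gene(s)")
  utils::write.table(
    data.frame(gene_id = cand$candidates,
               anchor = config$anchor, stringsAsFactors = FALSE),
    file.path(config$out_dir, "candidates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "coexscreen",
    version = as.character(utils::packageVersion("coexscreen")),
    seed = config$seed,
    config = unclass(config)[!vapply(unclass(config), is.null,
                                     logical(1L))],
    counts = list(genes_in = nrow(mat), samples = ncol(mat),
                  degs_called = length(called$all),
                  go_terms_significant = sum(go$fisher_p < config$enrich_p),
                  pathway_terms_significant =
                    sum(pw$fisher_p < config$enrich_p),
                  network_genes = length(net_genes),
                  edges_case = nrow(net_case$edges),
                  edges_control = nrow(net_ctrl$edges),
                  candidates = length(cand$candidates)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(deg = deg, go = go, pathway = pw,
                 network_genes = net_genes, net_case = net_case,
                 net_control = net_ctrl, topology = topo, top = top,
                 candidates = cand, manifest = manifest))
}
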