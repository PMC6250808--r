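#' Specify a synthetic two-group expression dataset
#'
#' Describes a stated world with known ground truth: per-gene log2-scale
#' baselines, optional correlated modules driven by a shared latent factor
#' (active in one or both groups), a planted mean shift for differential
#' genes, and Gaussian measurement noise.
#'
#' @param n_genes Total number of genes.
#' @param n_control,n_case Samples per group; defaults 9 and 18, the group
#'   sizes of the motivating skin-biopsy study design.
#' @param modules List of module descriptions from [module_spec()]. Modules
#'   must be disjoint unless `allow_overlap = TRUE`.
#' @param deg_fraction Fraction of genes given a planted case-group mean
#'   shift; module members are planted first (see Details), background genes
#'   fill the remainder.
#' @param deg_log2fc Planted shift magnitude in log2 units, default 2.
#' @param noise_sd Residual (measurement) standard deviation on the log2
#'   scale, default 0.3.
#' @param baseline_mean,baseline_sd Per-gene baseline distribution on the
#'   log2 scale (defaults 7 and 1.5, a typical normalized bulk profile).
#' @param count_mode If `TRUE`, values are exponentiated to the linear scale
#'   and Poisson-sampled, yielding integer counts; exercises robustness only.
#' @param allow_overlap Permit overlapping module membership.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `synthetic_spec` object (validated list).
#' @details Planted DEG ids are drawn module-first: members of every module
#'   are shifted before background genes are added to reach `deg_fraction`.
#'   The pipeline's network stage only sees genes that pass the DEG filter
#'   and the enrichment gate, so a world in which correlated disease modules
#'   are also differentially expressed is the one in which the screen's
#'   end-to-end behaviour is observable.
#' @export
synthetic_spec <- function(n_genes = 210, n_control = 9, n_case = 18,
                           modules = list(), deg_fraction = 0.1,
                           deg_log2fc = 2.0, noise_sd = 0.3,
                           baseline_mean = 7, baseline_sd = 1.5,
                           count_mode = FALSE, allow_overlap = FALSE,
                           seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (n_control < 3L || n_case < 3L) {
    stop("need >= 3 samples per group", call. = FALSE)
  }
  if (deg_fraction < 0 || deg_fraction > 1) {
    stop("deg_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  seen <- integer(0L)
  for (m in modules) {
    if (!inherits(m, "module_spec")) {
      stop("each module must come from module_spec()", call. = FALSE)
    }
    if (max(m$genes) > n_genes) {
      stop("module gene index exceeds n_genes", call. = FALSE)
    }
    if (!allow_overlap && length(intersect(seen, m$genes))) {
      stop("overlapping modules (set allow_overlap = TRUE to permit)",
           call. = FALSE)
    }
    seen <- union(seen, m$genes)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_control = as.integer(n_control),
                 n_case = as.integer(n_case),
                 modules = modules, deg_fraction = deg_fraction,
                 deg_log2fc = deg_log2fc, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 count_mode = isTRUE(count_mode),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Describe one planted correlation module
#'
#' Module members load on a single shared standard-Gaussian latent factor
#' drawn per sample; in samples of a group where the module is inactive the
#' factor contribution is absent, so within-module correlation collapses to
#' ~0 there. With loading `rho` and residual `noise_sd`, the expected
#' within-module correlation in an active group is
#' `rho^2 / (rho^2 + noise_sd^2)` for unit-variance loadings.
#'
#' @param genes Integer indices (into the spec's gene vector) of members.
#' @param rho Latent-factor loading in (0, 1); either a scalar or one value
#'   per member (reduced loadings create deliberate mid-hub members).
#' @param active_in `"control"`, `"case"` or `"both"`.
#' @return A `module_spec` object.
#' @export
module_spec <- function(genes, rho = 0.9,
                        active_in = c("both", "control", "case")) {
  active_in <- match.arg(active_in)
  genes <- as.integer(genes)
  if (length(genes) < 2L || anyDuplicated(genes)) {
    stop("a module needs >= 2 distinct gene indices", call. = FALSE)
  }
  if (!length(rho) %in% c(1L, length(genes)) ||
      any(rho <= 0) || any(rho >= 1)) {
    stop("rho must lie in (0, 1), scalar or one per member", call. = FALSE)
  }
  structure(list(genes = genes, rho = rep(rho, length.out = length(genes)),
                 active_in = active_in),
            class = "module_spec")
}

#' Generate a synthetic two-group dataset with ground truth
#'
#' Sampling model, per gene g and sample s on the log2 scale:
#' `x[g, s] = baseline[g] + rho[g] * z[module(g), s] * active(module, group(s))
#'  + deg_log2fc * deg(g) * is_case(s) + e[g, s]`,
#' with `z` a shared standard-Gaussian latent draw per (module, sample) and
#' `e ~ N(0, noise_sd^2)`. Identical spec and seed give bit-identical output.
#'
#' @param spec A [synthetic_spec()] object.
#' @return List with `matrix` (genes x samples, dimnames `g<i>` /
#'   `ctrl<i>`/`case<i>`), `design` (a [sample_design()]), and `truth`: list
#'   with `planted_deg_ids`, `module_of` (named integer, NA = background),
#'   `module_active_in`, `expected_hubs` (per group: members of modules
#'   active there), and `expected_differential_hubs` (members of modules
#'   active in exactly one group).
#' @export
generate_two_group_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  gene_ids <- sprintf("g%03d", seq_len(spec$n_genes))
  sample_ids <- c(sprintf("ctrl%02d", seq_len(spec$n_control)),
                  sprintf("case%02d", seq_len(spec$n_case)))
  is_case <- c(rep(FALSE, spec$n_control), rep(TRUE, spec$n_case))
  n_samples <- length(sample_ids)

  baseline <- stats::rnorm(spec$n_genes, spec$baseline_mean,
                           spec$baseline_sd)
  x <- matrix(baseline, nrow = spec$n_genes, ncol = n_samples,
              dimnames = list(gene_ids, sample_ids))

  module_of <- rep(NA_integer_, spec$n_genes)
  names(module_of) <- gene_ids
  for (mi in seq_along(spec$modules)) {
    m <- spec$modules[[mi]]
    module_of[m$genes] <- mi
    z <- stats::rnorm(n_samples)
    active <- switch(m$active_in,
                     both = rep(TRUE, n_samples),
                     control = !is_case,
                     case = is_case)
    contrib <- outer(m$rho, z * active)
    x[m$genes, ] <- x[m$genes, ] + contrib
  }

  # module-first DEG planting (see ?synthetic_spec Details)
  n_deg <- round(spec$deg_fraction * spec$n_genes)
  module_genes <- which(!is.na(module_of))
  background <- setdiff(seq_len(spec$n_genes), module_genes)
  deg_idx <- module_genes[seq_len(min(n_deg, length(module_genes)))]
  extra <- n_deg - length(deg_idx)
  if (extra > 0L) {
    deg_idx <- c(deg_idx, sample(background, extra))
  }
  if (length(deg_idx)) {
    x[deg_idx, is_case] <- x[deg_idx, is_case] + spec$deg_log2fc
  }

  if (spec$noise_sd > 0) {
    x <- x + matrix(stats::rnorm(length(x), 0, spec$noise_sd),
                    nrow = nrow(x))
  }
  if (spec$count_mode) {
    x <- matrix(stats::rpois(length(x), lambda = 2^x), nrow = nrow(x),
                dimnames = dimnames(x))
    storage.mode(x) <- "double"
  }

  design <- sample_design(
    stats::setNames(ifelse(is_case, "case", "control"), sample_ids))

  active_of <- vapply(spec$modules, `[[`, character(1L), "active_in")
  members <- function(groups) {
    idx <- which(active_of %in% groups)
    gene_ids[unlist(lapply(spec$modules[idx], `[[`, "genes"))]
  }
  truth <- list(
    planted_deg_ids = gene_ids[sort(deg_idx)],
    module_of = module_of,
    module_active_in = active_of,
    expected_hubs = list(control = members(c("control", "both")),
                         case = members(c("case", "both"))),
    expected_differential_hubs = list(control_only = members("control"),
                                      case_only = members("case")))
  list(matrix = x, design = design, truth = truth)
}

#' Generate gene-set fixtures enriched in planted DEGs
#'
#' Emits `n_terms` terms whose members are sampled preferentially from the
#' planted DEG list (enrichment strength `p_deg`) plus `n_background` terms
#' sampled uniformly from all genes, giving the enrichment stage a fixture
#' with known positives.
#'
#' @param truth The `truth` element of [generate_two_group_dataset()] output.
#' @param n_terms Number of enriched terms, >= 1.
#' @param n_background Number of unenriched background terms, default 20.
#' @param term_size Members per term, default 15.
#' @param p_deg Fraction of an enriched term's members drawn from planted
#'   DEGs, default 0.8.
#' @param prefix Term-id prefix (use different prefixes for the GO-style and
#'   pathway-style fixture collections).
#' @param seed Integer seed.
#' @return A `gene_sets` object.
#' @export
generate_fixture_genesets <- function(truth, n_terms, n_background = 20,
                                      term_size = 15, p_deg = 0.8,
                                      prefix = "T", seed = 1L) {
  if (n_terms < 1L) stop("n_terms must be >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  all_genes <- names(truth$module_of)
  degs <- truth$planted_deg_ids
  non_degs <- setdiff(all_genes, degs)
  sets <- list()
  for (i in seq_len(n_terms)) {
    n_hit <- min(length(degs), round(p_deg * term_size))
    members <- c(sample(degs, n_hit),
                 sample(non_degs, min(length(non_degs),
                                      term_size - n_hit)))
    sets[[sprintf("%s_ENRICHED_%02d", prefix, i)]] <-
      list(name = "planted enriched term", genes = sort(members))
  }
  for (i in seq_len(n_background)) {
    sets[[sprintf("%s_BG_%02d", prefix, i)]] <-
      list(name = "background term",
           genes = sort(sample(all_genes, min(length(all_genes),
                                              term_size))))
  }
  structure(sets, class = "gene_sets")
}
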