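#' Reported CD274 co-expression partners (worked example data)
#'
#' The package ships, as plain-text reference fixtures, the reported CD274
#' neighbourhood of a two-group skin transcriptome screen (psoriatic
#' lesional skin as case, n = 18; normal skin as control, n = 9): every gene
#' significantly correlated with CD274 in either group's co-expression
#' network, with the printed Pearson r, p-value, FDR and edge style.
#'
#' @return data.frame with columns `group` (`control`/`case`), `gene`,
#'   `pearson_r`, `p_value`, `fdr`, `style` and `n` (samples behind each
#'   correlation: 9 control, 18 case).
#' @seealso [load_cd274_topology()]
#' @export
load_cd274_partners <- function() {
  path <- system.file("extdata", "cd274_partners.tsv",
                      package = "coexscreen", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  df$n <- ifelse(df$group == "control", 9L, 18L)
  df
}

#' Reported top-20 differential-hubness table (worked example data)
#'
#' The reported degree and core number of the 20 genes with the largest
#' differential hubness around CD274 in the same two-group screen as
#' [load_cd274_partners()]. The `dif_degree`/`dif_kcore` columns are
#' recomputed from the per-group columns, never copied.
#'
#' @return A `topology_table` data.frame (see [topology_table()]).
#' @export
load_cd274_topology <- function() {
  path <- system.file("extdata", "cd274_topology_top20.tsv",
                      package = "coexscreen", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  topology_table(gene_id = df$gene,
                 degree_case = df$degree_case,
                 degree_control = df$degree_control,
                 kcore_case = df$kcore_case,
                 kcore_control = df$kcore_control)
}
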