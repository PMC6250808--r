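test_that("expression matrix load preserves shape and order, rejects bad input", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t1.5\t2\t3\t4",
               "g2\t0\t-1\t2.5\t3",
               "g3\t7\t8\t9\t10"), tsv)
  m <- read_expression_matrix(tsv)
  expect_identical(dim(m), c(3L, 4L))
  expect_identical(rownames(m), c("g1", "g2", "g3"))
  expect_identical(colnames(m), c("s1", "s2", "s3", "s4"))
  expect_equal(m["g2", "s2"], -1)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3",
               "g1\t1\t2\t3", "g1\t4\t5\t6"), dup)
  expect_error(read_expression_matrix(dup), "g1")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3",
               "g1\t1\tNA\t3"), bad)
  expect_error(read_expression_matrix(bad), "g1.*s2")
})

test_that("expression matrix and design survive a write/read round trip", {
  d <- generate_two_group_dataset(synthetic_spec(n_genes = 25, seed = 7))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(d$matrix, tsv)
  back <- read_expression_matrix(tsv)
  expect_identical(dimnames(back), dimnames(d$matrix))
  expect_equal(back, d$matrix, ignore_attr = TRUE, tolerance = 1e-12)

  dtsv <- withr::local_tempfile(fileext = ".tsv")
  write_sample_design(d$design, dtsv)
  d2 <- read_sample_design(dtsv)
  expect_identical(d2$assignments, d$design$assignments)
  expect_identical(d2$n_control, d$design$n_control)
})

test_that("sample design enforces two groups and minimum group size", {
  expect_error(sample_design(c(a = "control", b = "case", c = "weird")),
               "weird")
  expect_error(
    sample_design(setNames(rep(c("control", "case"), c(2, 5)),
                           paste0("s", 1:7))),
    ">= 3")
  des <- sample_design(setNames(rep(c("control", "case"), c(3, 4)),
                                paste0("s", 1:7)))
  expect_identical(des$n_control, 3L)
  expect_identical(des$n_case, 4L)
})

test_that("GMT parsing: members, empty files, malformed lines, round trip", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\ta\tb", "T2\tother\tx\ty\tz"), gmt)
  sets <- read_gmt(gmt)
  expect_named(sets, c("T1", "T2"))
  expect_setequal(sets$T1$genes, c("a", "b"))

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_length(read_gmt(empty), 0L)

  short <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\ta", "T2\tno-members"), short)
  expect_error(read_gmt(short), "line 2")

  d <- generate_two_group_dataset(synthetic_spec(n_genes = 60,
                                                 deg_fraction = 0.3,
                                                 seed = 3))
  fix <- generate_fixture_genesets(d$truth, n_terms = 5, seed = 11)
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(fix, out)
  back <- read_gmt(out)
  expect_identical(names(back), names(fix))
  for (id in names(fix)) {
    expect_setequal(back[[id]]$genes, fix[[id]]$genes)
  }
})

test_that("network edge_tsv: single edge, empty network, round trip", {
  des <- sample_design(setNames(rep(c("control", "case"), c(9, 18)),
                                sprintf("s%02d", 1:27)))
  set.seed(1)
  m <- matrix(rnorm(27 * 3), 3, dimnames = list(c("A", "B", "noise"),
                                                sprintf("s%02d", 1:27)))
  m["B", ] <- 2 * m["A", ]
  net <- build_group_network(m, des, "control")
  expect_identical(nrow(net$edges), 1L)
  lines <- {
    p <- withr::local_tempfile(fileext = ".tsv")
    write_group_network(net, p)
    readLines(p)
  }
  expect_match(lines[1], "^gene_a\tgene_b\tpearson_r\tp_value\tfdr\tstyle$")
  expect_match(lines[2], "^A\tB\t1\\.0000000\t.*Positive$")

  empty <- build_group_network(m, des, "control", fdr_max = 0)
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_group_network(empty, ep)
  expect_length(readLines(ep), 1L)

  d <- generate_two_group_dataset(synthetic_spec(
    n_genes = 30, modules = list(module_spec(1:8, rho = 0.95)), seed = 5))
  net2 <- build_group_network(d$matrix, d$design, "control")
  rp <- withr::local_tempfile(fileext = ".tsv")
  write_group_network(net2, rp)
  back <- read_group_network(rp, group = "control", n_samples = 9,
                             nodes = net2$nodes)
  key <- function(e) paste(e$gene_a, e$gene_b)
  expect_setequal(key(back$edges), key(net2$edges))
  expect_equal(back$edges$r[order(key(back$edges))],
               net2$edges$r[order(key(net2$edges))], tolerance = 1e-6)
})

test_that("GraphML export carries topology attributes and round trips", {
  d <- generate_two_group_dataset(synthetic_spec(
    n_genes = 20, modules = list(module_spec(1:6, rho = 0.95)), seed = 2))
  net <- build_group_network(d$matrix, d$design, "control")
  gp <- withr::local_tempfile(fileext = ".graphml")
  write_group_network(net, gp, format = "graphml")
  g <- igraph::read_graph(gp, format = "graphml")
  expect_setequal(igraph::V(g)$name, net$nodes)
  expect_identical(as.integer(igraph::ecount(g)), nrow(net$edges))
  expect_setequal(igraph::edge_attr_names(g),
                  c("r", "p", "fdr", "style"))
  deg <- setNames(igraph::V(g)$degree, igraph::V(g)$name)
  expect_equal(deg[names(degrees(net))], degrees(net),
               ignore_attr = TRUE)
})
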