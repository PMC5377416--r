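test_that("gene-set intersection is commutative, associative, idempotent", {
  a <- gene_set("a", c("A", "B", "C"))
  b <- gene_set("b", c("B", "C", "D"))
  c_ <- gene_set("c", c("C", "D", "E"))
  expect_equal(intersect_sets(a, b)$members, c("B", "C"))
  expect_equal(intersect_sets(a, b)$members, intersect_sets(b, a)$members)
  expect_equal(intersect_sets(intersect_sets(a, b), c_)$members,
               intersect_sets(a, intersect_sets(b, c_))$members)
  expect_equal(intersect_sets(a, a)$members, a$members)

  d <- gene_set("d", c("X", "Y"))
  expect_message(r <- intersect_sets(a, d), "disjoint")
  expect_length(r$members, 0)
})

test_that("synthetic disease/target lists overlap in exactly the planted genes", {
  planted <- readLines(fixture_path("overlap_genes"))
  expect_length(planted, 104)
  set.seed(131)
  disease <- gene_set("nlp", c(planted, sprintf("HCC%04d", 1:1696)))     # 1800
  targets <- gene_set("predicted", c(planted, sprintf("TGT%03d", 1:147))) # 251
  expect_length(disease$members, 1800)
  expect_length(targets$members, 251)
  ov <- intersect_sets(disease, targets)
  expect_length(ov$members, 104)
  expect_setequal(ov$members, planted)
})

test_that("pathway enrichment is the same tail probability as co-citation", {
  bg <- gene_set("universe", sprintf("G%02d", 1:20))
  pw <- gene_set("pw", sprintf("G%02d", 1:5))
  qry <- gene_set("q", c("G01", "G02", "G11", "G12"))
  r <- pathway_enrichment(qry, list(pw), background = bg)
  expect_equal(r$count, 2)
  expect_equal(r$p, cocitation_pvalue(cocitation_query(20, 5, 4, 2))$p,
               tolerance = 1e-12)
  expect_equal(r$p, 0.2487, tolerance = 1e-4)

  # zero overlap scores 1
  r0 <- pathway_enrichment(gene_set("q", c("G19", "G20")),
                           list(gene_set("pw", c("G01", "G02"))),
                           background = bg)
  expect_equal(r0$p, 1)

  expect_error(
    pathway_enrichment(qry, list(gene_set("pw", c("G01", "NOTINBG"))),
                       background = bg),
    "outside")
})

test_that("a planted pathway ranks first in the enrichment table", {
  qry <- gene_set("query", sprintf("Q%03d", 1:30))
  pws <- gen_pathways(qry$members, universe_size = 400, n_pathways = 12,
                      pathway_size = 20, planted_frac = 0.8, seed = 141)
  r <- pathway_enrichment(qry, pws)
  expect_identical(r$pathway[1], "planted_pathway")
  expect_true(!is.unsorted(r$p))
  expect_equal(r$count[1], length(strsplit(r$genes[1], ",")[[1]]))
})

test_that("hub degrees recomputed from the interaction fixture match the published table", {
  net <- read_sif(fixture_path("hub_edges"))
  hubs <- readLines(fixture_path("hub_genes"))
  expect_length(net$nodes, 20)
  expect_equal(nrow(net$edges), 34)
  ct <- connectivity_ztest(net, hub_genes = hubs)
  expect_equal(sum(ct$degree), 2 * nrow(net$edges))
  want <- table4_degrees()
  expect_equal(ct$degree, unname(want[ct$gene]))
})

test_that("hub z-test reproduces the published tail probabilities to 5 decimals", {
  net <- read_sif(fixture_path("hub_edges"))
  ct <- connectivity_ztest(net, hub_genes = readLines(fixture_path("hub_genes")))
  want <- table4_pvalues()
  for (d in names(want)) {
    got <- unique(round(ct$p[ct$degree == as.integer(d)], 6))
    expect_length(got, 1)
    expect_equal(got, want[[d]], tolerance = 1e-5)
  }
  # strictly decreasing p with increasing degree within one population
  agg <- unique(ct[, c("degree", "p")])
  agg <- agg[order(agg$degree), ]
  expect_true(all(diff(agg$p) < 0))
})

test_that("z-test degenerate and trivial cases behave", {
  net <- assemble_network(list(ppi = data.frame(from = c("A", "B", "C"),
                                                to = c("B", "C", "A"))))
  expect_error(connectivity_ztest(net), "degenerate")

  net2 <- assemble_network(list(ppi = data.frame(
    from = c("A", "A", "A", "B"), to = c("B", "C", "D", "C"))))
  ct <- connectivity_ztest(net2)
  mean_gene <- ct[abs(ct$degree - mean(ct$degree)) < 1e-9, ]
  expect_equal(mean_gene$z, rep(0, nrow(mean_gene)))
  expect_equal(mean_gene$p, rep(0.5, nrow(mean_gene)))
})

test_that("network assembly merges sources, drops self-loops, logs bad rows", {
  src1 <- data.frame(from = c("a", "b", "x"), to = c("b", "c", "x"))
  src2 <- data.frame(from = c("B", "d"), to = c("A", ""))
  expect_message(expect_message(
    net <- assemble_network(list(ppi = src1, literature = src2)),
    "self-loop"), "malformed")
  expect_equal(nrow(net$edges), 2)
  ab <- net$edges[net$edges$from == "A", ]
  expect_identical(ab$sources, "literature|ppi")   # shared edge, both tags
  expect_equal(sort(net$nodes), c("A", "B", "C"))

  empty <- assemble_network(list())
  expect_length(empty$nodes, 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("SIF and GraphML exports round-trip with tags preserved", {
  path3 <- assemble_network(list(ppi = data.frame(from = c("A", "B"),
                                                  to = c("B", "C"))))
  tf <- tempfile(fileext = ".sif")
  export_network(path3, tf, "sif")
  expect_length(readLines(tf), 2)

  net <- read_sif(fixture_path("hub_edges"))
  for (fmt in c("sif", "graphml")) {
    f <- tempfile()
    export_network(net, f, fmt)
    back <- import_network(f, fmt)
    expect_identical(back$nodes, net$nodes)
    expect_identical(back$edges$from, net$edges$from)
    expect_identical(back$edges$to, net$edges$to)
    expect_identical(back$edges$sources, net$edges$sources)
  }

  empty <- assemble_network(list())
  f <- tempfile(fileext = ".sif")
  export_network(empty, f, "sif")
  expect_identical(readLines(f), character(0))
  expect_error(export_network(net, tempfile(), "dot"), "arg")
})

test_that("GMT files round-trip", {
  sets <- list(gene_set("s1", c("A", "B")), gene_set("s2", c("C", "D", "E")))
  tf <- tempfile(fileext = ".gmt")
  write_gmt(sets, tf)
  back <- read_gmt(tf)
  expect_length(back, 2)
  expect_equal(back$s2$members, c("C", "D", "E"))
  writeLines("only_name\tdesc", tf)
  expect_error(read_gmt(tf), "malformed")
})
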