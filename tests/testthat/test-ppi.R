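# PPI topology: seed expansion, centralities (with independent oracles),
# the top-fraction tie rule, and the two-stage filtration cascade.

test_that("seed expansion takes seeds plus direct interactors with induced edges", {
  inter <- data.frame(node_a = c("A", "B"), node_b = c("B", "C"))
  g1 <- expand_seeds("A", inter)
  expect_setequal(igraph::V(g1)$name, c("A", "B"))
  expect_equal(igraph::ecount(g1), 1L)
  # B neighbours both seeds; the induced B-C edge is retained
  g2 <- expand_seeds(c("A", "C"), inter)
  expect_setequal(igraph::V(g2)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g2), 2L)
  # seeds-only induction
  g3 <- expand_seeds(c("A", "B"), inter, expansion = "seeds-only")
  expect_setequal(igraph::V(g3)$name, c("A", "B"))
  # absent seeds are reported; all-absent is a hard error
  expect_message(expand_seeds(c("A", "ZZ"), inter), "absent")
  expect_error(expand_seeds("ZZ", inter), "none of the")
  expect_true(all(igraph::V(g2)$is_seed == c(TRUE, FALSE, TRUE)[
    match(igraph::V(g2)$name, c("A", "B", "C"))]))
})

test_that("degree centrality equals adjacency row sums", {
  tri <- graph_from_spec(c("a-b", "b-c", "c-a"))
  expect_equal(unname(degree_centrality(tri)), c(2, 2, 2))
  star <- graph_from_spec(paste0("hub-", letters[1:5]))
  dc <- degree_centrality(star)
  expect_equal(unname(dc["hub"]), 5)
  expect_true(all(dc[letters[1:5]] == 1))
  set.seed(5)
  g <- random_test_graph(50, 0.1)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  expect_equal(unname(degree_centrality(g)), unname(rowSums(A)))
})

test_that("betweenness matches closed-form values on canonical graphs", {
  path3 <- graph_from_spec(c("a-b", "b-c"))
  bc <- betweenness_centrality(path3)
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))
  # 4-cycle: every opposite pair has two geodesics, each middle node carries 1/2
  cyc <- graph_from_spec(c("a-b", "b-c", "c-d", "d-a"))
  expect_equal(unname(betweenness_centrality(cyc)), rep(0.5, 4))
})

test_that("Brandes agrees with the BFS path-counting oracle and igraph", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    g <- random_test_graph(n, runif(1, 0.08, 0.4))
    bc <- betweenness_centrality(g)
    expect_equal(unname(bc), naive_bc(adj_list_of(g)), tolerance = 1e-10)
    expect_equal(unname(bc), unname(igraph::betweenness(g)),
                 tolerance = 1e-10)
  }
})

test_that("removing an isolated node leaves other betweenness unchanged", {
  g <- graph_from_spec(c("a-b", "b-c", "c-d"), isolated = "x")
  g2 <- igraph::delete_vertices(g, "x")
  b1 <- betweenness_centrality(g)
  b2 <- betweenness_centrality(g2)
  expect_equal(b1[names(b2)], b2)
  expect_equal(unname(b1["x"]), 0)
})

test_that("top-fraction filter implements ceil-with-ties semantics", {
  nodes <- sprintf("v%02d", 1:10)
  g <- igraph::make_empty_graph(10, directed = FALSE)
  igraph::V(g)$name <- nodes
  # distinct scores 1..10: keeps exactly the top 3
  s <- setNames(1:10, nodes)
  expect_setequal(igraph::V(top_fraction_filter(g, s, 0.3))$name,
                  c("v08", "v09", "v10"))
  # all equal: the tie rule keeps everything
  expect_equal(igraph::vcount(top_fraction_filter(g, setNames(rep(1, 10),
                                                              nodes), 0.3)),
               10L)
  # hand-evaluated tie case: cut = 5, three nodes at or above it
  s2 <- setNames(c(5, 5, 5, 4, 3, 2, 1, 1, 1, 1), nodes)
  kept <- top_fraction_filter(g, s2, 0.3)
  expect_setequal(igraph::V(kept)$name, c("v01", "v02", "v03"))
  expect_equal(attr(kept, "cut"), 5)
  expect_error(top_fraction_filter(g, s, 0), "fraction")
})

test_that("the filtration cascade nests and recomputes BC on the subnetwork", {
  # barbell-ish graph: two hubs H1, H2 joined, each with leaves; a separate
  # clique of mid-degree nodes; two extra degree-3 nodes a1, a2
  edges <- c("H1-H2",
             paste0("H1-a", 1:10), paste0("H2-b", 1:10),
             "a1-a2", "a1-a3", "a2-a4",
             "m1-m2", "m1-m3", "m1-m4", "m2-m3", "m2-m4", "m3-m4",
             "m1-b1", "m1-b2", "m2-b3", "m2-b4", "m3-b5", "m3-b6",
             "m4-b7", "m4-b8")
  g <- graph_from_spec(edges)
  seeds <- c("H1", "H2", "a3", "b1")
  igraph::V(g)$is_seed <- igraph::V(g)$name %in% seeds
  fr <- extract_core(g, fraction = 0.3)
  # nesting
  expect_true(all(igraph::V(fr$core)$name %in%
                    igraph::V(fr$subnetwork)$name))
  expect_true(all(igraph::V(fr$subnetwork)$name %in%
                    igraph::V(fr$full)$name))
  # crucial = seeds intersect core, and the engineered seed hubs are crucial
  expect_setequal(fr$crucial_genes,
                  intersect(seeds, igraph::V(fr$core)$name))
  expect_true(all(c("H1", "H2") %in% fr$crucial_genes))
  expect_false(any(c("a3", "b1") %in% fr$crucial_genes))
  # fraction = 1 is the identity limit
  fr1 <- extract_core(g, fraction = 1)
  expect_equal(igraph::vcount(fr1$core), igraph::vcount(g))
  expect_setequal(fr1$crucial_genes, seeds)
})

test_that("BC is recomputed on the induced subnetwork, not inherited", {
  # In the full graph, c is the sole bridge between the x-side and the hub
  # cluster; once the degree filter removes the x-side, c's betweenness in
  # the subnetwork collapses while hub-internal paths reorganize.
  edges <- c(paste0("h1-", c("h2", "h3", "h4", "h5", "c")),
             paste0("h2-", c("h3", "h4", "h5")),
             "h3-c", "c-x1", "x1-x2")
  g <- graph_from_spec(edges)
  full_bc <- betweenness_centrality(g)
  sub <- top_fraction_filter(g, degree_centrality(g), 0.5)
  sub_bc <- betweenness_centrality(sub)
  common <- intersect(names(full_bc), names(sub_bc))
  expect_false(isTRUE(all.equal(full_bc[common], sub_bc[common])))
})

test_that("centrality table flags seeds and sorts by degree", {
  g <- graph_from_spec(c("s-a", "s-b", "a-b", "b-c"))
  igraph::V(g)$is_seed <- igraph::V(g)$name == "s"
  tab <- centrality_table(g)
  expect_equal(names(tab), c("node", "dc", "bc", "is_seed"))
  expect_equal(tab$node[1], "b")      # degree 3
  expect_true(tab$is_seed[tab$node == "s"])
})

test_that("interactome SIF/TSV round-trips through the readers", {
  edges <- data.frame(node_a = c("A", "B"), node_b = c("B", "C"))
  sif <- withr::local_tempfile(fileext = ".sif")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_interactome(edges, sif, "sif")
  write_interactome(edges, tsv, "tsv")
  expect_equal(read_interactome(sif), edges, ignore_attr = TRUE)
  expect_equal(read_interactome(tsv), edges, ignore_attr = TRUE)
})
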