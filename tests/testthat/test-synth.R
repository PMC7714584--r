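# Synthetic-data generators: forced counts, determinism, structural
# properties of each artifact.

test_that("synth_config validates fields and names the offender", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(frac_de = 1.5), "frac_de")
  expect_error(synth_config(n_pairs = 2), "n_pairs")
  expect_error(synth_config(noise_sd = 0), "noise_sd")
  expect_error(synth_config(set_size_range = c(10, 5)), "set_size_range")
  expect_error(synth_config(interactome_nodes = 2, interactome_attach = 3),
               "interactome_nodes")
})

test_that("generate_expression produces the configured dimensions and truth set", {
  cfg <- synth_config(n_gene_total = 1000L, n_pairs = 17L, frac_de = 0.05,
                      seed = 1L)
  st <- generate_expression(cfg)
  expect_equal(dim(st$matrix), c(1000L, 34L))
  expect_equal(sum(st$truth), 50L)
  expect_equal(nrow(st$pairs), 17L)
  # signs balanced by construction
  expect_equal(sum(st$truth_sign == 1), 25L)
  expect_equal(sum(st$truth_sign == -1), 25L)
  # null config: empty truth set
  st0 <- generate_expression(synth_config(frac_de = 0, seed = 2L))
  expect_equal(sum(st0$truth), 0L)
})

test_that("spiked genes carry the configured mean shift", {
  cfg <- synth_config(n_gene_total = 500L, effect_log2fc = 2.0,
                      noise_sd = 0.5, seed = 7L)
  st <- generate_expression(cfg)
  D <- st$matrix[, st$pairs$case] - st$matrix[, st$pairs$control]
  shift <- rowMeans(D)
  de <- st$truth
  expect_equal(mean(abs(shift[de])), 2.0, tolerance = 0.05)
  expect_equal(mean(shift[!de]), 0, tolerance = 0.05)
})

test_that("generate_compounds forces exact pass and dedup counts", {
  cfg <- synth_config(herbs = letters[1:4], n_compounds_per_herb = 100L,
                      frac_bioactive = 0.3, n_shared = 0L, seed = 1L)
  cpds <- generate_compounds(cfg)
  expect_equal(nrow(cpds), 400L)
  kept <- suppressMessages(screen_bci(cpds))
  expect_equal(nrow(kept), 120L)

  # frac_bioactive = 1: everything passes
  cfg1 <- synth_config(herbs = c("x", "y"), n_compounds_per_herb = 10L,
                       frac_bioactive = 1, n_shared = 0L, seed = 1L)
  all_pass <- suppressMessages(screen_bci(generate_compounds(cfg1)))
  expect_equal(nrow(all_pass), 20L)

  # shared molecule IDs: dedup removes exactly n_shared from the union
  cfg5 <- synth_config(herbs = letters[1:4], n_compounds_per_herb = 100L,
                       frac_bioactive = 0.3, n_shared = 5L, seed = 1L)
  kept5 <- suppressMessages(screen_bci(generate_compounds(cfg5)))
  expect_equal(nrow(kept5), 120L)
  expect_equal(nrow(dedupe_bci(kept5)), 115L)
})

test_that("default compound catalogue mirrors a four-herb formula", {
  cpds <- generate_compounds(synth_config(seed = 3L))
  expect_equal(nrow(cpds), 489L)
  kept <- suppressMessages(screen_bci(cpds))
  expect_equal(nrow(kept), 146L)
  expect_equal(nrow(dedupe_bci(kept)), 140L)
})

test_that("generate_target_map wires the hub and covers the pool", {
  cfg <- tiny_cfg(hub_target_frac = 0.9, seed = 4L)
  st <- generate_expression(cfg)
  bcis <- dedupe_bci(suppressMessages(screen_bci(generate_compounds(cfg))))
  de <- names(st$truth)[st$truth]
  map <- generate_target_map(cfg, bcis, names(st$truth), de)
  hub <- attr(map, "hub_gene")
  n_mols <- length(unique(bcis$molecule_id))
  expect_equal(sum(map$gene_symbol == hub), round(0.9 * n_mols))
  expect_equal(length(unique(map$gene_symbol)), cfg$target_pool_size)
  expect_false(any(duplicated(map)))
  # every compound has at least one target
  expect_true(all(bcis$molecule_id %in% map$molecule_id))
  # hub_target_frac = 0: hub degree is just its background draw
  map0 <- generate_target_map(tiny_cfg(hub_target_frac = 0, seed = 4L),
                              bcis, names(st$truth), de)
  expect_lt(sum(map0$gene_symbol == attr(map0, "hub_gene")), 10)
  expect_error(generate_target_map(cfg, bcis, character(), de), "universe")
})

test_that("generate_interactome yields a connected simple scale-free graph", {
  cfg <- synth_config(interactome_nodes = 500L, interactome_attach = 3L,
                      seed = 1L)
  seeds <- sprintf("SEED%02d", 1:20)
  edges <- generate_interactome(cfg, seeds)
  # exact edge count from the attachment rule
  expect_equal(nrow(edges), (3 - 1) + (500 - 3) * 3)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  expect_equal(igraph::vcount(g), 500L)
  expect_true(igraph::is_connected(g))
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
  expect_true(all(seeds %in% igraph::V(g)$name))
  expect_error(generate_interactome(
    synth_config(interactome_nodes = 10L), sprintf("S%02d", 1:11)),
    "seed genes")
})

test_that("interactome degree distribution is heavy-tailed across seeds", {
  heavy <- vapply(1:50, function(s) {
    cfg <- synth_config(interactome_nodes = 500L, interactome_attach = 3L,
                        seed = s)
    edges <- generate_interactome(cfg, character())
    deg <- table(c(edges$node_a, edges$node_b))
    max(deg) > 3 * median(deg)
  }, logical(1))
  expect_true(all(heavy))
})

test_that("generate_gene_sets plants sets verbatim and validates the universe", {
  cfg <- tiny_cfg(seed = 5L)
  genes <- sprintf("G%03d", 1:300)
  planted <- list(pathX = genes[1:20])
  coll <- generate_gene_sets(cfg, genes, planted)
  expect_equal(length(coll$sets), cfg$n_gene_sets + 1L)
  expect_setequal(coll$sets$pathX, genes[1:20])
  sizes <- lengths(coll$sets)[seq_len(cfg$n_gene_sets)]
  expect_true(all(sizes >= 5 & sizes <= 15))
  # zero decoys, one planted set
  coll1 <- generate_gene_sets(tiny_cfg(n_gene_sets = 0L, seed = 5L),
                              genes, planted)
  expect_equal(length(coll1$sets), 1L)
  expect_error(generate_gene_sets(cfg, genes, list(bad = c("NOPE"))),
               "outside the universe")
})

test_that("GMT round-trip preserves the collection", {
  cfg <- tiny_cfg(seed = 6L)
  genes <- sprintf("G%03d", 1:300)
  coll <- generate_gene_sets(cfg, genes, list(px = genes[5:30]),
                             planted_categories = "CC")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path)
  expect_identical(back$sets, coll$sets)
  expect_identical(back$meta$category, coll$meta$category)
})

test_that("identical configs give byte-identical simulated inputs", {
  cfg <- tiny_cfg(seed = 11L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulate_inputs(cfg, d1)
  p2 <- simulate_inputs(cfg, d2)
  files <- c("expression.tsv", "samples.tsv", "compounds.tsv",
             "target_map.tsv", "interactome.sif", "truth.tsv",
             "sets_bp.gmt", "sets_cc.gmt", "sets_mf.gmt", "sets_pathway.gmt")
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # a different seed changes the data
  p3 <- simulate_inputs(tiny_cfg(seed = 12L), withr::local_tempdir())
  expect_false(identical(tools::md5sum(p1$expression)[[1]],
                         tools::md5sum(p3$expression)[[1]]))
})
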