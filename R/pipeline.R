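# End-to-end orchestration: differential expression -> ingredient screen ->
# target intersection -> pharmacological network -> PPI filtration ->
# enrichment, with a JSON run manifest recording inputs, thresholds and
# per-stage counts.

#' Assemble and validate a pipeline run configuration
#'
#' @param expression,samples paths to the expression matrix TSV and sample
#'   metadata TSV.
#' @param compounds path to the herb compound TSV.
#' @param target_map path to the compound-target TSV.
#' @param interactome path to the interactome SIF/TSV.
#' @param gene_sets named character vector of GMT paths; names are the
#'   categories (BP/CC/MF/pathway).
#' @param outdir output directory.
#' @param fc_min,alpha_deg DEG thresholds (|log2FC| >= fc_min, BH-adjusted
#'   p < alpha_deg).
#' @param ob_min,dl_min ADME screen thresholds.
#' @param fraction centrality filtration fraction.
#' @param alpha_ora enrichment adjusted-p threshold.
#' @param moderation `"none"` or `"eb"` for the paired test.
#' @param prior_df prior df for the moderated test.
#' @param expansion PPI seed expansion rule (`"direct"` or `"seeds-only"`).
#' @param bh_by_category adjust enrichment p-values within category.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return object of class `run_config`.
#' @export
run_config <- function(expression, samples, compounds, target_map,
                       interactome, gene_sets, outdir,
                       fc_min = 1.0, alpha_deg = 0.05,
                       ob_min = 30, dl_min = 0.18,
                       fraction = 0.30, alpha_ora = 0.05,
                       moderation = c("none", "eb"), prior_df = 4,
                       expansion = c("direct", "seeds-only"),
                       bh_by_category = TRUE, seed = 1L) {
  moderation <- match.arg(moderation)
  expansion <- match.arg(expansion)
  inputs <- c(expression = expression, samples = samples,
              compounds = compounds, target_map = target_map,
              interactome = interactome, gene_sets)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stopf("run_config: input file(s) not found: %s",
          paste(missing, collapse = ", "))
  if (fc_min <= 0) stopf("run_config: 'fc_min' must be positive")
  for (nm in c("alpha_deg", "alpha_ora")) {
    v <- get(nm)
    if (v < 0 || v > 1) stopf("run_config: '%s' must be in [0, 1]", nm)
  }
  if (fraction <= 0 || fraction > 1)
    stopf("run_config: 'fraction' must be in (0, 1]")
  structure(list(expression = expression, samples = samples,
                 compounds = compounds, target_map = target_map,
                 interactome = interactome, gene_sets = gene_sets,
                 outdir = outdir, fc_min = fc_min, alpha_deg = alpha_deg,
                 ob_min = ob_min, dl_min = dl_min, fraction = fraction,
                 alpha_ora = alpha_ora, moderation = moderation,
                 prior_df = prior_df, expansion = expansion,
                 bh_by_category = bh_by_category, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value document whose keys mirror the arguments of
#' [run_config()]; `gene_sets` is a mapping from category to GMT path.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$gene_sets <- unlist(y$gene_sets)
  do.call(run_config, y)
}

#' Run the full network-pharmacology pipeline
#'
#' Executes, in order: paired differential expression; OB/DL ingredient
#' screening and deduplication; target intersection, ingredient pruning and
#' bipartite network construction; PPI seed expansion and two-stage DC/BC
#' core extraction; hypergeometric enrichment and the target-pathway
#' network.  Every stage writes its outputs under `cfg$outdir` and the run
#' manifest (input hashes, thresholds, per-stage counts, package version)
#' is written as `manifest.json`.  A stage failure aborts with the stage
#' name and leaves a `FAILED` marker alongside any partial outputs.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "netpharm",
    version = as.character(utils::packageVersion("netpharm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    inputs = as.list(tools::md5sum(c(cfg$expression, cfg$samples,
                                     cfg$compounds, cfg$target_map,
                                     cfg$interactome, cfg$gene_sets))),
    thresholds = cfg[c("fc_min", "alpha_deg", "ob_min", "dl_min",
                       "fraction", "alpha_ora", "moderation", "prior_df",
                       "expansion", "bh_by_category")],
    counts = list()
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("FAILED at stage '%s': %s", name,
                         conditionMessage(e)),
                 file.path(cfg$outdir, "FAILED"))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # 1. differential expression
  degs <- stage("deg", {
    study <- read_expression(cfg$expression, cfg$samples)
    d <- call_degs(study, fc_min = cfg$fc_min, alpha = cfg$alpha_deg,
                   moderation = cfg$moderation, prior_df = cfg$prior_df)
    write.csv(d, file.path(cfg$outdir, "degs.csv"), row.names = FALSE)
    manifest$counts$n_genes <- length(study$genes)
    manifest$counts$n_pairs <- nrow(study$pairs)
    manifest$counts$n_degs <- nrow(d)
    manifest$counts$n_degs_up <- attr(d, "n_up")
    manifest$counts$n_degs_down <- attr(d, "n_down")
    d
  })

  # 2. ingredient screening
  bcis <- stage("ingredient_screen", {
    raw <- read_compounds(cfg$compounds)
    screened <- screen_bci(raw, ob_min = cfg$ob_min, dl_min = cfg$dl_min)
    b <- dedupe_bci(screened)
    write.csv(b, file.path(cfg$outdir, "bci.csv"), row.names = FALSE)
    manifest$counts$n_compounds <- nrow(raw)
    manifest$counts$n_screened <- nrow(screened)
    manifest$counts$n_bci <- nrow(b)
    b
  })

  # 3. target intersection and pharmacological network
  net_bits <- stage("target_network", {
    if (nrow(degs) == 0)
      stopf("no disease-specific genes passed the thresholds (fc_min = %g, alpha = %g); nothing to intersect",
            cfg$fc_min, cfg$alpha_deg)
    map <- read_tsv_plain(cfg$target_map)
    map <- map[map$molecule_id %in% bcis$molecule_id, , drop = FALSE]
    kept <- intersect_targets(map, degs)
    if (nrow(kept) == 0)
      stopf("the intersection of compound targets and disease-specific genes is empty")
    eff <- prune_ingredients(bcis, kept)
    net <- build_bipartite(eff, kept, degs)
    write_sif_bipartite(net, file.path(cfg$outdir, "pharmacology_net.sif"))
    write_graphml_bipartite(net, file.path(cfg$outdir,
                                           "pharmacology_net.graphml"))
    write.csv(bipartite_nodes(net),
              file.path(cfg$outdir, "pharmacology_nodes.csv"),
              row.names = FALSE)
    write.csv(multi_target_report(net),
              file.path(cfg$outdir, "multi_target_bcis.csv"),
              row.names = FALSE)
    manifest$counts$n_mapped_genes <- length(unique(map$gene_symbol))
    manifest$counts$n_target_genes <- nrow(net$right)
    manifest$counts$n_effective_bci <- nrow(net$left)
    manifest$counts$bipartite_edges <- nrow(net$edges)
    manifest$counts$max_target_degree <-
      if (nrow(net$right)) max(net$right$degree) else 0L
    list(net = net, targets = net$right$gene)
  })

  # 4. PPI expansion and centrality filtration
  filt <- stage("ppi_topology", {
    inter <- read_interactome(cfg$interactome)
    g <- expand_seeds(net_bits$targets, inter, expansion = cfg$expansion)
    fr <- extract_core(g, fraction = cfg$fraction)
    write_ppi(fr$full, file.path(cfg$outdir, "ppi_full.sif"),
              file.path(cfg$outdir, "ppi_full.graphml"))
    write_ppi(fr$subnetwork, file.path(cfg$outdir, "ppi_subnetwork.sif"))
    write_ppi(fr$core, file.path(cfg$outdir, "ppi_core.sif"),
              file.path(cfg$outdir, "ppi_core.graphml"))
    write.csv(centrality_table(fr$full),
              file.path(cfg$outdir, "ppi_centrality_full.csv"),
              row.names = FALSE)
    write.csv(centrality_table(fr$subnetwork),
              file.path(cfg$outdir, "ppi_centrality_subnetwork.csv"),
              row.names = FALSE)
    writeLines(fr$crucial_genes, file.path(cfg$outdir, "crucial_genes.txt"))
    manifest$counts$ppi_nodes <- igraph::vcount(fr$full)
    manifest$counts$ppi_edges <- igraph::ecount(fr$full)
    manifest$counts$subnetwork_nodes <- igraph::vcount(fr$subnetwork)
    manifest$counts$subnetwork_edges <- igraph::ecount(fr$subnetwork)
    manifest$counts$core_nodes <- igraph::vcount(fr$core)
    manifest$counts$core_edges <- igraph::ecount(fr$core)
    manifest$counts$n_crucial <- length(fr$crucial_genes)
    fr
  })

  # 5. enrichment and target-pathway network
  stage("enrichment", {
    collection <- read_gmt_multi(cfg$gene_sets)
    ora <- run_ora(net_bits$targets, collection, alpha = cfg$alpha_ora,
                   bh_by_category = cfg$bh_by_category)
    write.csv(ora$table, file.path(cfg$outdir, "enrichment_full.csv"),
              row.names = FALSE)
    write.csv(ora$significant,
              file.path(cfg$outdir, "enrichment_significant.csv"),
              row.names = FALSE)
    tp <- target_pathway_net(ora)
    write_sif_bipartite(tp, file.path(cfg$outdir, "target_pathway.sif"),
                        relation = "tp")
    sig_by_cat <- table(factor(ora$significant$category,
                               levels = c("BP", "CC", "MF", "pathway")))
    manifest$counts$sets_tested <- nrow(ora$table)
    manifest$counts$sig_bp <- unname(sig_by_cat[["BP"]])
    manifest$counts$sig_cc <- unname(sig_by_cat[["CC"]])
    manifest$counts$sig_mf <- unname(sig_by_cat[["MF"]])
    manifest$counts$sig_pathway <- unname(sig_by_cat[["pathway"]])
    NULL
  })

  # internal consistency of the stage chain
  stopifnot(manifest$counts$n_target_genes <= manifest$counts$n_degs,
            manifest$counts$n_effective_bci <= manifest$counts$n_bci,
            manifest$counts$n_bci <= manifest$counts$n_screened,
            manifest$counts$n_screened <= manifest$counts$n_compounds,
            manifest$counts$n_crucial <= manifest$counts$n_target_genes)

  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Locate a packaged reference table
#'
#' The package ships small curated reference tables for the Gegen Qinlian
#' decoction / colorectal cancer system: the multi-target bioactive
#' ingredients with their TCMSP OB/DL values, the 20 disease-specific
#' target genes with log2 fold changes and adjusted p-values, the top
#' up/down differential genes, and the enriched KEGG pathways.
#'
#' @param file file name under `extdata`; with no argument, lists the
#'   available files.
#' @return a path, or a character vector of file names.
#' @export
netpharm_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "netpharm"))
  } else {
    system.file("extdata", file, package = "netpharm", mustWork = TRUE)
  }
}
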