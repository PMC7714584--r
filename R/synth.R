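# Synthetic-data generators.  These emulate the statistical structure of the
# five pipeline inputs (paired expression study, herb compound table,
# compound-target map, interactome, gene-set collections) so that every
# downstream stage can be exercised and calibrated without any download.

#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data module into one validated object.
#' Defaults reproduce the study conditions the pipeline is designed for: a
#' 17-pair tumour/normal expression study, a four-herb formula
#' (Gegen/Huangqin/Huanglian/Gancao) with 489 catalogued compounds of which
#' ~30\% pass the OB/DL screen, a 240-gene target pool containing 20
#' disease-specific genes dominated by one hub target, a scale-free
#' interactome, and decoy-plus-planted gene-set collections.
#'
#' @param n_gene_total number of genes on the simulated array.
#' @param n_pairs number of matched case/control sample pairs (>= 3).
#' @param frac_de fraction of genes given a true expression shift.
#' @param effect_log2fc absolute log2 fold-change spiked into true DE genes;
#'   applied symmetrically (half up, half down).
#' @param noise_sd per-gene, per-sample residual SD on the log2 scale.
#' @param pair_sd SD of the shared per-pair random intercept (what makes the
#'   design genuinely paired).
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   expression.
#' @param herbs character vector of herb names.
#' @param n_compounds_per_herb integer vector (recycled to `length(herbs)`)
#'   of catalogued compounds per herb.
#' @param frac_bioactive fraction of each herb's compounds constructed to
#'   pass the OB >= 30, DL >= 0.18 screen.
#' @param n_shared number of bioactive molecule IDs duplicated across herbs
#'   (exercises deduplication).
#' @param target_pool_size size of the compound-target gene pool.
#' @param n_target_de number of truly differential genes placed in the
#'   target pool (the prospective disease-specific targets).
#' @param target_lambda Poisson mean of extra targets per compound beyond
#'   the guaranteed one.
#' @param hub_target_frac fraction of compounds wired to the designated hub
#'   target gene.
#' @param interactome_nodes,interactome_attach size and edges-per-new-node of
#'   the preferential-attachment interactome.
#' @param n_hub_seeds how many seed genes are placed on the oldest (hence
#'   highest-degree) interactome nodes.
#' @param n_gene_sets number of random decoy gene sets.
#' @param set_size_range integer length-2 vector, uniform range of set sizes.
#' @param seed single integer driving every generator substream.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_gene_total = 2000L,
                         n_pairs = 17L,
                         frac_de = 0.05,
                         effect_log2fc = 2.0,
                         noise_sd = 0.5,
                         pair_sd = 1.0,
                         baseline_mean = 7,
                         baseline_sd = 1.5,
                         herbs = c("Gegen", "Huangqin", "Huanglian", "Gancao"),
                         n_compounds_per_herb = c(18L, 143L, 48L, 280L),
                         frac_bioactive = 0.3,
                         n_shared = 6L,
                         target_pool_size = 240L,
                         n_target_de = 20L,
                         target_lambda = 0.6,
                         hub_target_frac = 0.9,
                         interactome_nodes = 500L,
                         interactome_attach = 3L,
                         n_hub_seeds = 2L,
                         n_gene_sets = 200L,
                         set_size_range = c(10L, 50L),
                         seed = 1L) {
  cfg <- list(
    n_gene_total = as.integer(n_gene_total),
    n_pairs = as.integer(n_pairs),
    frac_de = frac_de,
    effect_log2fc = effect_log2fc,
    noise_sd = noise_sd,
    pair_sd = pair_sd,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    herbs = as.character(herbs),
    n_compounds_per_herb = as.integer(rep_len(n_compounds_per_herb,
                                              length(herbs))),
    frac_bioactive = frac_bioactive,
    n_shared = as.integer(n_shared),
    target_pool_size = as.integer(target_pool_size),
    n_target_de = as.integer(n_target_de),
    target_lambda = target_lambda,
    hub_target_frac = hub_target_frac,
    interactome_nodes = as.integer(interactome_nodes),
    interactome_attach = as.integer(interactome_attach),
    n_hub_seeds = as.integer(n_hub_seeds),
    n_gene_sets = as.integer(n_gene_sets),
    set_size_range = as.integer(set_size_range),
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  chk_frac <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stopf("synth_config: field '%s' must be a fraction in [0, 1]", name)
  }
  chk_count <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min)
      stopf("synth_config: field '%s' must be a count >= %d", name, min)
  }
  chk_pos <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
      stopf("synth_config: field '%s' must be a positive real", name)
  }
  chk_frac(cfg$frac_de, "frac_de")
  chk_frac(cfg$frac_bioactive, "frac_bioactive")
  chk_frac(cfg$hub_target_frac, "hub_target_frac")
  chk_count(cfg$n_gene_total, "n_gene_total")
  chk_count(cfg$n_pairs, "n_pairs", min = 3L)
  chk_pos(cfg$effect_log2fc, "effect_log2fc")
  chk_pos(cfg$noise_sd, "noise_sd")
  if (cfg$pair_sd < 0) stopf("synth_config: field 'pair_sd' must be >= 0")
  if (!length(cfg$herbs)) stopf("synth_config: field 'herbs' must be nonempty")
  if (any(cfg$n_compounds_per_herb < 1))
    stopf("synth_config: field 'n_compounds_per_herb' must be counts >= 1")
  if (cfg$n_shared < 0)
    stopf("synth_config: field 'n_shared' must be a count >= 0")
  chk_count(cfg$target_pool_size, "target_pool_size")
  if (cfg$n_target_de < 0 || cfg$n_target_de > cfg$target_pool_size)
    stopf("synth_config: field 'n_target_de' must be in [0, target_pool_size]")
  if (cfg$target_lambda < 0)
    stopf("synth_config: field 'target_lambda' must be >= 0")
  chk_count(cfg$interactome_nodes, "interactome_nodes")
  chk_count(cfg$interactome_attach, "interactome_attach")
  if (cfg$interactome_nodes < cfg$interactome_attach + 1L)
    stopf("synth_config: field 'interactome_nodes' must exceed 'interactome_attach'")
  if (cfg$n_hub_seeds < 0)
    stopf("synth_config: field 'n_hub_seeds' must be a count >= 0")
  if (cfg$n_gene_sets < 0)
    stopf("synth_config: field 'n_gene_sets' must be a count >= 0")
  if (length(cfg$set_size_range) != 2 ||
      any(cfg$set_size_range < 1) ||
      cfg$set_size_range[1] > cfg$set_size_range[2])
    stopf("synth_config: field 'set_size_range' must be an increasing pair of counts")
  if (!is.finite(cfg$seed))
    stopf("synth_config: field 'seed' must be a finite integer")
  invisible(cfg)
}

#' Simulate a paired log2 expression study
#'
#' Generates a genes x (2 * n_pairs) log2 matrix with a shared per-pair
#' random intercept, independent Gaussian noise, and a recorded truth set of
#' `round(frac_de * n_gene_total)` genes whose case samples are shifted by
#' exactly +/- `effect_log2fc` (signs alternate so up- and down-regulation
#' are balanced).
#'
#' @param cfg a [synth_config()].
#' @return an [expression_study()] whose `truth` and `truth_sign` components
#'   flag the spiked genes.
#' @export
generate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_substream(cfg$seed + 101L, {
    n <- cfg$n_gene_total
    np <- cfg$n_pairs
    genes <- sprintf("GENE%05d", seq_len(n))
    n_de <- round(cfg$frac_de * n)
    de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer()
    sgn <- rep_len(c(1, -1), n_de)
    delta <- numeric(n)
    delta[de_idx] <- sgn * cfg$effect_log2fc

    base <- rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
    pairfx <- matrix(rnorm(n * np, 0, cfg$pair_sd), n, np)
    case <- base + pairfx + delta +
      matrix(rnorm(n * np, 0, cfg$noise_sd), n, np)
    ctrl <- base + pairfx +
      matrix(rnorm(n * np, 0, cfg$noise_sd), n, np)

    pair_id <- sprintf("P%02d", seq_len(np))
    case_names <- paste0(pair_id, "_case")
    ctrl_names <- paste0(pair_id, "_control")
    mat <- cbind(case, ctrl)
    rownames(mat) <- genes
    colnames(mat) <- c(case_names, ctrl_names)

    samples <- data.frame(
      sample = c(case_names, ctrl_names),
      pair_id = rep(pair_id, 2),
      condition = rep(c("case", "control"), each = np),
      stringsAsFactors = FALSE
    )
    truth <- setNames(logical(n), genes)
    truth[de_idx] <- TRUE
    truth_sign <- setNames(integer(n), genes)
    truth_sign[de_idx] <- as.integer(sgn)
    expression_study(mat, samples, truth = truth, truth_sign = truth_sign)
  })
}

#' Simulate a herb compound table with OB/DL values
#'
#' Each herb contributes its configured number of compounds; exactly
#' `round(frac_bioactive * n)` per herb are constructed to pass the screen
#' (OB drawn uniform on [30, 100] and DL uniform on [0.18, 1]), the rest are
#' constructed to fail both thresholds.  `n_shared` bioactive molecule IDs
#' are duplicated across herbs so that deduplication removes exactly
#' `n_shared` records from the screened union.
#'
#' @param cfg a [synth_config()].
#' @return data.frame with columns `molecule_id`, `molecule_name`, `herb`,
#'   `ob`, `dl`.
#' @export
generate_compounds <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_substream(cfg$seed + 202L, {
    herbs <- cfg$herbs
    counts <- cfg$n_compounds_per_herb
    total <- sum(counts)
    rows <- vector("list", length(herbs))
    idx0 <- 0L
    for (h in seq_along(herbs)) {
      ch <- counts[h]
      n_pass <- round(cfg$frac_bioactive * ch)
      pass <- sample(c(rep(TRUE, n_pass), rep(FALSE, ch - n_pass)))
      ob <- ifelse(pass, runif(ch, 30, 100), runif(ch, 0, 30 - 1e-9))
      dl <- ifelse(pass, runif(ch, 0.18, 1), runif(ch, 0, 0.18 - 1e-9))
      id <- sprintf("SMOL%06d", idx0 + seq_len(ch))
      rows[[h]] <- data.frame(
        molecule_id = id,
        molecule_name = paste0("compound-", id),
        herb = herbs[h],
        ob = round(ob, 2),
        dl = round(dl, 3),
        pass = pass,
        stringsAsFactors = FALSE
      )
      idx0 <- idx0 + ch
    }
    df <- do.call(rbind, rows)

    # duplicate n_shared bioactive molecules across herbs: the donor herb is
    # the one with the most passing compounds; recipients cycle over the
    # other herbs, overwriting one of their own passing records so per-herb
    # totals and pass counts are unchanged.
    if (cfg$n_shared > 0) {
      pass_by_herb <- split(which(df$pass), df$herb[df$pass])[herbs]
      donor <- herbs[which.max(lengths(pass_by_herb))]
      recipients <- setdiff(herbs, donor)
      recipients <- recipients[lengths(pass_by_herb[recipients]) > 0]
      if (!length(recipients))
        stopf("synth_config: n_shared requires passing compounds in >= 2 herbs")
      used <- setNames(rep(0L, length(herbs)), herbs)
      donor_rows <- pass_by_herb[[donor]]
      if (cfg$n_shared > length(donor_rows))
        stopf("synth_config: n_shared exceeds the donor herb's bioactive count")
      for (j in seq_len(cfg$n_shared)) {
        rec <- recipients[((j - 1L) %% length(recipients)) + 1L]
        used[rec] <- used[rec] + 1L
        if (used[rec] > length(pass_by_herb[[rec]]))
          stopf("synth_config: n_shared too large for herb '%s'", rec)
        src <- donor_rows[j]
        dst <- pass_by_herb[[rec]][used[rec]]
        df[dst, c("molecule_id", "molecule_name", "ob", "dl")] <-
          df[src, c("molecule_id", "molecule_name", "ob", "dl")]
      }
    }
    df$pass <- NULL
    rownames(df) <- NULL
    df
  })
}

#' Simulate a compound-to-target mapping
#'
#' Builds a target pool of `target_pool_size` genes containing
#' `n_target_de` truly differential genes (when `de_genes` is supplied); the
#' first of those is the designated hub target, wired to
#' `round(hub_target_frac * n_compounds)` compounds — a structure in which a
#' single target such as a prostaglandin synthase dominates the
#' ingredient-target network.  Every compound receives at least one target
#' and every pool gene is hit by at least one compound, so the mapped-gene
#' count equals `target_pool_size` exactly.
#'
#' @param cfg a [synth_config()].
#' @param compounds data.frame with a `molecule_id` column (typically the
#'   screened, deduplicated ingredients).
#' @param genes character vector, the candidate target gene universe.
#' @param de_genes character vector of truly differential genes from which
#'   the disease-specific part of the pool is drawn.
#' @return data.frame with columns `molecule_id`, `gene_symbol`; attributes
#'   `hub_gene` and `target_pool`.
#' @export
generate_target_map <- function(cfg, compounds, genes, de_genes = character()) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!length(genes)) stopf("generate_target_map: gene universe is empty")
  if (!nrow(compounds)) stopf("generate_target_map: compound table is empty")
  with_substream(cfg$seed + 303L, {
    mols <- unique(compounds$molecule_id)
    n_de_pool <- min(cfg$n_target_de, length(de_genes))
    de_pool <- if (n_de_pool > 0) sample(de_genes, n_de_pool) else character()
    bg <- setdiff(genes, de_genes)
    n_bg <- min(cfg$target_pool_size - n_de_pool, length(bg))
    pool <- c(de_pool, sample(bg, n_bg))
    hub <- pool[1]

    n_hub <- round(cfg$hub_target_frac * length(mols))
    hub_mols <- if (n_hub > 0) sample(mols, n_hub) else character()

    non_hub_pool <- setdiff(pool, hub)
    pick <- function(k) {
      if (k > 0) sample(non_hub_pool, min(k, length(non_hub_pool)))
      else character()
    }
    pairs <- vector("list", length(mols))
    for (i in seq_along(mols)) {
      m <- mols[i]
      extra <- rpois(1, cfg$target_lambda)
      need <- extra + if (m %in% hub_mols) 0L else 1L
      tg <- c(if (m %in% hub_mols) hub, pick(need))
      pairs[[i]] <- data.frame(molecule_id = m, gene_symbol = tg,
                               stringsAsFactors = FALSE)
    }
    map <- unique(do.call(rbind, pairs))

    # guarantee full pool coverage so the mapped-gene count is exact
    unhit <- setdiff(pool, map$gene_symbol)
    if (length(unhit)) {
      extra <- data.frame(molecule_id = sample(mols, length(unhit),
                                               replace = TRUE),
                          gene_symbol = unhit, stringsAsFactors = FALSE)
      map <- unique(rbind(map, extra))
    }
    rownames(map) <- NULL
    attr(map, "hub_gene") <- hub
    attr(map, "target_pool") <- pool
    map
  })
}

#' Simulate a scale-free interactome containing given seed genes
#'
#' Grows an undirected simple graph by preferential attachment: the first
#' `interactome_attach` nodes form a path, and every later node attaches to
#' `interactome_attach` distinct existing nodes with probability
#' proportional to degree + 1.  The resulting edge count is exactly
#' `(attach - 1) + (n - attach) * attach` and the graph is connected.  The
#' first `n_hub_seeds` seed genes are placed on the oldest (highest-degree)
#' nodes; the remaining seeds are placed on late, low-degree nodes.
#'
#' @param cfg a [synth_config()].
#' @param seed_genes character vector of gene symbols that must appear as
#'   nodes.
#' @return data.frame edge list with columns `node_a`, `node_b`.
#' @export
generate_interactome <- function(cfg, seed_genes) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$interactome_nodes
  m <- cfg$interactome_attach
  if (n < length(seed_genes))
    stopf("generate_interactome: interactome_nodes (%d) < number of seed genes (%d)",
          n, length(seed_genes))
  with_substream(cfg$seed + 404L, {
    n_edges <- (m - 1L) + (n - m) * m
    ea <- integer(n_edges)
    eb <- integer(n_edges)
    deg <- integer(n)
    k <- 0L
    if (m > 1) {
      for (i in seq_len(m - 1L)) {
        k <- k + 1L
        ea[k] <- i; eb[k] <- i + 1L
        deg[i] <- deg[i] + 1L; deg[i + 1L] <- deg[i + 1L] + 1L
      }
    }
    for (v in (m + 1L):n) {
      tg <- sample.int(v - 1L, m, prob = deg[seq_len(v - 1L)] + 1)
      for (t in tg) {
        k <- k + 1L
        ea[k] <- t; eb[k] <- v
        deg[t] <- deg[t] + 1L; deg[v] <- deg[v] + 1L
      }
    }
    labels <- sprintf("INT%05d", seq_len(n))
    ns <- length(seed_genes)
    if (ns > 0) {
      nh <- min(cfg$n_hub_seeds, ns)
      idx <- seq_len(nh)
      if (ns > nh) {
        late <- max(nh + 1L, floor(n / 2)):n
        idx <- c(idx, sample(late, ns - nh))
      }
      labels[idx] <- seed_genes
    }
    data.frame(node_a = labels[ea], node_b = labels[eb],
               stringsAsFactors = FALSE)
  })
}

#' Simulate gene-set collections with planted structure
#'
#' Generates `n_gene_sets` random decoy sets (sizes uniform in
#' `set_size_range`, categories assigned round-robin over BP/CC/MF/pathway)
#' and appends the supplied planted sets verbatim.
#'
#' @param cfg a [synth_config()].
#' @param genes character vector, the annotation gene universe.
#' @param planted named list of character vectors (member genes) to include
#'   verbatim; must be subsets of `genes`.
#' @param planted_categories character vector recycled over `planted`
#'   (default `"pathway"`).
#' @return a [gene_set_collection()].
#' @export
generate_gene_sets <- function(cfg, genes, planted = list(),
                               planted_categories = "pathway") {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(planted)) {
    bad <- !vapply(planted, function(g) all(g %in% genes), logical(1))
    if (any(bad))
      stopf("generate_gene_sets: planted set(s) contain genes outside the universe: %s",
            paste(names(planted)[bad], collapse = ", "))
    if (is.null(names(planted)) || any(!nzchar(names(planted))))
      stopf("generate_gene_sets: planted sets must be named")
  }
  with_substream(cfg$seed + 505L, {
    cats <- c("BP", "CC", "MF", "pathway")
    k <- cfg$n_gene_sets
    sets <- list()
    category <- character()
    if (k > 0) {
      sizes <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]),
                      k, replace = TRUE)
      sizes <- pmin(sizes, length(genes))
      sets <- lapply(sizes, function(s) sample(genes, s))
      names(sets) <- sprintf("RSET%04d", seq_len(k))
      category <- rep_len(cats, k)
    }
    if (length(planted)) {
      sets <- c(sets, planted)
      category <- c(category, rep_len(planted_categories, length(planted)))
    }
    gene_set_collection(sets, category = category, universe = genes)
  })
}

#' Write all synthetic pipeline inputs to a directory
#'
#' One call produces every file the pipeline consumes: the expression matrix
#' and sample metadata, the herb compound table, the compound-target map
#' (built over the screened, deduplicated ingredients), an interactome in
#' SIF format whose seed nodes are the disease-specific target-pool genes,
#' and one GMT file per gene-set category (with planted enrichable sets for
#' the prospective targets), plus the DE truth table for evaluation.
#'
#' @param cfg a [synth_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) a named list of file paths plus the `truth` table and
#'   the designated `hub_gene`.
#' @export
simulate_inputs <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  study <- generate_expression(cfg)
  compounds <- generate_compounds(cfg)
  bcis <- dedupe_bci(suppressMessages(screen_bci(compounds)))
  de_genes <- names(study$truth)[study$truth]
  map <- generate_target_map(cfg, bcis, names(study$truth), de_genes)
  pool <- attr(map, "target_pool")
  seed_pool <- pool[pool %in% de_genes]
  interactome <- generate_interactome(cfg, seed_pool)

  # planted gene sets: six pathway sets, one small CC set, a few BP/MF sets,
  # each seeded with disease-specific pool genes plus random filler
  genes <- names(study$truth)
  planted <- with_substream(cfg$seed + 606L, {
    mk <- function(n_core, size) {
      core <- sample(seed_pool, min(n_core, length(seed_pool)))
      filler <- sample(setdiff(genes, core), max(0, size - length(core)))
      c(core, filler)
    }
    p <- list()
    for (i in 1:6) p[[sprintf("PATH_SIM%02d", i)]] <- mk(4 + i, 30)
    p[["CC_SIM01"]] <- mk(3, 12)
    for (i in 1:3) p[[sprintf("BP_SIM%02d", i)]] <- mk(5, 25)
    for (i in 1:2) p[[sprintf("MF_SIM%02d", i)]] <- mk(4, 20)
    p
  })
  planted_cats <- c(rep("pathway", 6), "CC", rep("BP", 3), rep("MF", 2))
  sets <- generate_gene_sets(cfg, genes, planted, planted_cats)

  paths <- list(
    expression = file.path(outdir, "expression.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    compounds = file.path(outdir, "compounds.tsv"),
    target_map = file.path(outdir, "target_map.tsv"),
    interactome = file.path(outdir, "interactome.sif"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_expression(study, paths$expression, paths$samples)
  write_tsv_plain(compounds, paths$compounds)
  write_tsv_plain(map, paths$target_map)
  write_interactome(interactome, paths$interactome, format = "sif")
  truth_df <- data.frame(gene = names(study$truth),
                         is_de = unname(study$truth),
                         sign = unname(study$truth_sign),
                         stringsAsFactors = FALSE)
  write_tsv_plain(truth_df, paths$truth)

  gmt_paths <- character()
  for (cat in c("BP", "CC", "MF", "pathway")) {
    sub <- subset_collection(sets, cat)
    p <- file.path(outdir, sprintf("sets_%s.gmt", tolower(cat)))
    write_gmt(sub, p)
    gmt_paths[cat] <- p
  }
  paths$gene_sets <- gmt_paths
  paths$truth_table <- truth_df
  paths$hub_gene <- attr(map, "hub_gene")
  paths$seed_pool <- seed_pool
  invisible(paths)
}
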