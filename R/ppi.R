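# PPI topology: seed expansion against an interactome, degree and
# (Brandes) betweenness centrality, and the two-stage top-fraction
# filtration that extracts the core network and its crucial genes.

#' Read an interactome edge list
#'
#' Accepts SIF (`a<TAB>pp<TAB>b`) or two-column TSV (optionally with a
#' header line `node_a`/`node_b`).
#'
#' @param path input file.
#' @return data.frame with columns `node_a`, `node_b`.
#' @export
read_interactome <- function(path) {
  first <- readLines(path, n = 1)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(fields) == 3) {
    sif <- read_sif(path)
    data.frame(node_a = sif$edges$a, node_b = sif$edges$b,
               stringsAsFactors = FALSE)
  } else {
    header <- identical(tolower(fields[1]), "node_a")
    df <- read.delim(path, header = header, sep = "\t",
                     stringsAsFactors = FALSE)
    names(df)[1:2] <- c("node_a", "node_b")
    df[, c("node_a", "node_b")]
  }
}

#' Write an interactome edge list
#'
#' @param edges data.frame with columns `node_a`, `node_b`.
#' @param path output file.
#' @param format `"sif"` (`a<TAB>pp<TAB>b`) or `"tsv"`.
#' @return (invisibly) the path.
#' @export
write_interactome <- function(edges, path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    writeLines(sprintf("%s\tpp\t%s", edges$node_a, edges$node_b), path)
  } else {
    write_tsv_plain(edges, path)
  }
  invisible(path)
}

#' Expand seed genes into a PPI network
#'
#' With `expansion = "direct"` (default) the node set is the seeds present
#' in the interactome plus their direct interactors, and the edge set is
#' every interactome edge with both endpoints inside that node set (so
#' interactor-interactor edges within the neighbourhood are retained).
#' With `expansion = "seeds-only"` the graph is induced on the seeds alone.
#' Self-loops and duplicate edges are removed; seeds absent from the
#' interactome are reported by message.
#'
#' @param seeds character vector of seed gene symbols.
#' @param interactome data.frame edge list (`node_a`, `node_b`).
#' @param expansion expansion rule.
#' @return an undirected simple [igraph::igraph] with a logical `is_seed`
#'   vertex attribute.
#' @export
expand_seeds <- function(seeds, interactome,
                         expansion = c("direct", "seeds-only")) {
  expansion <- match.arg(expansion)
  if (!nrow(interactome)) stopf("expand_seeds: interactome is empty")
  g <- igraph::graph_from_data_frame(
    interactome[, c("node_a", "node_b")], directed = FALSE)
  g <- igraph::simplify(g)
  present <- intersect(seeds, igraph::V(g)$name)
  if (!length(present))
    stopf("expand_seeds: none of the %d seed gene(s) are present in the interactome",
          length(seeds))
  missing <- setdiff(seeds, present)
  if (length(missing))
    msgf("expand_seeds: %d seed gene(s) absent from the interactome: %s",
         length(missing), paste(missing, collapse = ", "))
  keep <- if (expansion == "direct") {
    nb <- unique(unlist(lapply(igraph::adjacent_vertices(g, present),
                               function(vs) vs$name)))
    union(present, nb)
  } else {
    present
  }
  sub <- igraph::induced_subgraph(g, keep)
  igraph::V(sub)$is_seed <- igraph::V(sub)$name %in% seeds
  sub
}

#' Degree centrality
#'
#' @param g an [igraph::igraph].
#' @return named integer vector, number of incident edges per node.
#' @export
degree_centrality <- function(g) {
  igraph::degree(g)
}

# Brandes' algorithm: one BFS per source with dependency accumulation along
# the shortest-path DAG; undirected pair counts are halved at the end.
brandes_bc <- function(adj) {
  n <- length(adj)
  bc <- numeric(n)
  if (n < 3) return(bc)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep.int(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    queue <- integer(n); queue[1] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      dv <- dist[v]
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dv + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dv + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (i in rev(seq_len(tail))) {
      w <- queue[i]
      coef <- (1 + delta[w]) / sigma[w]
      for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coef
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2
}

#' Betweenness centrality (Brandes)
#'
#' Unnormalized shortest-path betweenness for undirected, unweighted
#' graphs: `bc(v) = sum over unordered pairs s != v != t of
#' sigma_st(v) / sigma_st`, endpoints excluded, computed with Brandes'
#' dependency accumulation.  Disconnected graphs are handled per component.
#'
#' @param g an [igraph::igraph].
#' @param normalized divide by `(n-1)(n-2)/2` (default `FALSE`, matching
#'   the CytoNCA convention for undirected graphs).
#' @return named numeric vector of betweenness scores.
#' @export
betweenness_centrality <- function(g, normalized = FALSE) {
  n <- igraph::vcount(g)
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  bc <- brandes_bc(adj)
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  setNames(bc, igraph::V(g)$name)
}

#' Keep the top fraction of nodes by score
#'
#' `k = ceiling(fraction * n)`; the cut is the k-th largest score and every
#' node with score >= cut is kept (ties at the cut are all retained, so the
#' output may exceed k).  Returns the induced subgraph on the kept nodes.
#'
#' @param g an [igraph::igraph].
#' @param scores named numeric vector covering every node of `g`.
#' @param fraction fraction in (0, 1] (default 0.30).
#' @return the induced subgraph; attribute `cut` records the threshold.
#' @export
top_fraction_filter <- function(g, scores, fraction = 0.30) {
  if (fraction <= 0 || fraction > 1)
    stopf("top_fraction_filter: 'fraction' must be in (0, 1]")
  n <- igraph::vcount(g)
  if (n == 0) return(g)
  nm <- igraph::V(g)$name
  if (!all(nm %in% names(scores)))
    stopf("top_fraction_filter: scores missing for some node(s)")
  sc <- scores[nm]
  k <- ceiling(fraction * n)
  cut <- sort(unname(sc), decreasing = TRUE)[k]
  keep <- nm[sc >= cut]
  out <- igraph::induced_subgraph(g, keep)
  attr(out, "cut") <- cut
  out
}

#' Two-stage centrality filtration of a PPI network
#'
#' Stage 1 keeps the top `fraction` of nodes by degree centrality computed
#' on the full graph (the subnetwork).  Stage 2 recomputes betweenness
#' centrality on the induced subnetwork and keeps its top `fraction` (the
#' core network).  Crucial genes are the seed genes surviving into the
#' core.
#'
#' @param full an [igraph::igraph] with a logical `is_seed` vertex
#'   attribute (or supply `seeds`).
#' @param fraction filtration fraction (default 0.30).
#' @param seeds optional character vector of seed genes; defaults to the
#'   `is_seed` flags of `full`.
#' @return object of class `filtration_result` with components `full`,
#'   `subnetwork`, `core`, `crucial_genes`, `thresholds` (dc_cut, bc_cut)
#'   and `fraction`.
#' @export
extract_core <- function(full, fraction = 0.30, seeds = NULL) {
  if (igraph::vcount(full) == 0) stopf("extract_core: graph is empty")
  if (is.null(seeds)) {
    flag <- igraph::vertex_attr(full, "is_seed")
    seeds <- if (is.null(flag)) character() else igraph::V(full)$name[flag]
  }
  dc <- degree_centrality(full)
  subnet <- top_fraction_filter(full, dc, fraction)
  if (igraph::vcount(subnet) == 0)
    stopf("extract_core: degree filtration left an empty subnetwork")
  bc <- betweenness_centrality(subnet)
  core <- top_fraction_filter(subnet, bc, fraction)
  structure(list(
    full = full,
    subnetwork = subnet,
    core = core,
    crucial_genes = intersect(seeds, igraph::V(core)$name),
    thresholds = c(dc_cut = attr(subnet, "cut"), bc_cut = attr(core, "cut")),
    fraction = fraction
  ), class = "filtration_result")
}

#' @export
print.filtration_result <- function(x, ...) {
  fmt <- function(g) sprintf("%d nodes / %d edges",
                             igraph::vcount(g), igraph::ecount(g))
  cat("filtration_result (top ", x$fraction * 100, "% DC then BC)\n", sep = "")
  cat("  full:      ", fmt(x$full), "\n")
  cat("  subnetwork:", fmt(x$subnetwork),
      sprintf("(DC cut %.4g)", x$thresholds[["dc_cut"]]), "\n")
  cat("  core:      ", fmt(x$core),
      sprintf("(BC cut %.4g)", x$thresholds[["bc_cut"]]), "\n")
  cat("  crucial genes:", if (length(x$crucial_genes))
    paste(x$crucial_genes, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Centrality table of a PPI graph
#'
#' @param g an [igraph::igraph] (optionally with `is_seed` vertex flags).
#' @return data.frame (node, dc, bc, is_seed) sorted by degree descending.
#' @export
centrality_table <- function(g) {
  flag <- igraph::vertex_attr(g, "is_seed")
  out <- data.frame(
    node = igraph::V(g)$name,
    dc = unname(degree_centrality(g)),
    bc = unname(betweenness_centrality(g)),
    is_seed = if (is.null(flag)) FALSE else flag,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$dc, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a PPI graph as SIF and GraphML
#'
#' @param g an [igraph::igraph].
#' @param sif_path,graphml_path output files (either may be `NULL`).
#' @return (invisibly) `NULL`.
#' @export
write_ppi <- function(g, sif_path = NULL, graphml_path = NULL) {
  if (!is.null(sif_path)) {
    el <- igraph::as_edgelist(g)
    writeLines(sprintf("%s\tpp\t%s", el[, 1], el[, 2]), sif_path)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(NULL)
}
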