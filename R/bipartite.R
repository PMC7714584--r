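# Target intersection and the ingredient-target bipartite pharmacological
# network.  Networks are undirected and unweighted; ingredient nodes are
# keyed by molecule_id, target nodes by gene symbol, and exports carry
# "mol:" / "gene:" (or "set:") namespace prefixes to prevent collisions.

#' Construct a typed bipartite network
#'
#' @param left,right data.frames of node attributes whose first column is
#'   the node identifier.
#' @param edges data.frame with columns `left`, `right` referencing the two
#'   node sets; duplicate edges are collapsed.
#' @param left_type,right_type node-type labels (e.g. "ingredient",
#'   "target").
#' @return object of class `bipartite_net` with per-node degrees filled in.
#' @export
bipartite_net <- function(left, right, edges,
                          left_type = "ingredient", right_type = "target") {
  edges <- unique(edges[, c("left", "right")])
  if (nrow(edges)) {
    if (!all(edges$left %in% left[[1]]))
      stopf("bipartite_net: edge endpoint(s) missing from the left node set")
    if (!all(edges$right %in% right[[1]]))
      stopf("bipartite_net: edge endpoint(s) missing from the right node set")
  }
  left$degree <- as.integer(table(factor(edges$left, levels = left[[1]])))
  right$degree <- as.integer(table(factor(edges$right, levels = right[[1]])))
  rownames(left) <- rownames(right) <- rownames(edges) <- NULL
  structure(list(left = left, right = right, edges = edges,
                 left_type = left_type, right_type = right_type),
            class = "bipartite_net")
}

#' @export
print.bipartite_net <- function(x, ...) {
  cat(sprintf("bipartite_net: %d %s node(s), %d %s node(s), %d edge(s)\n",
              nrow(x$left), x$left_type, nrow(x$right), x$right_type,
              nrow(x$edges)))
  invisible(x)
}

#' Intersect compound targets with disease-specific genes
#'
#' Keeps the (molecule, gene) pairs whose gene is among the differential
#' genes; pairs are made unique.
#'
#' @param target_map data.frame with columns `molecule_id`, `gene_symbol`.
#' @param degs a DEG table with a `gene` column, or a character vector of
#'   gene symbols.
#' @return the surviving unique pairs.
#' @export
intersect_targets <- function(target_map, degs) {
  require_columns(target_map, c("molecule_id", "gene_symbol"), "target map")
  genes <- if (is.character(degs)) degs else degs$gene
  out <- unique(target_map[target_map$gene_symbol %in% genes,
                           c("molecule_id", "gene_symbol")])
  rownames(out) <- NULL
  out
}

#' Drop ingredients with no surviving target
#'
#' @param bcis data.frame of screened ingredients (`molecule_id`, ...).
#' @param kept_pairs output of [intersect_targets()].
#' @return the ingredients with at least one disease-specific target.
#' @export
prune_ingredients <- function(bcis, kept_pairs) {
  out <- bcis[bcis$molecule_id %in% unique(kept_pairs$molecule_id), ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the ingredient-target pharmacological network
#'
#' Ingredient nodes carry their source herbs; target nodes carry the
#' regulation direction and log2 fold change from the differential analysis.
#' Edges are the surviving (molecule, gene) pairs.
#'
#' @param bcis pruned ingredient table (`molecule_id`, `source_herbs` or
#'   `herb`).
#' @param kept_pairs output of [intersect_targets()]; every molecule must
#'   appear in `bcis`.
#' @param degs DEG table with columns `gene`, `log2fc`, `direction`.
#' @return a [bipartite_net()] (ingredients on the left, targets on the
#'   right).
#' @export
build_bipartite <- function(bcis, kept_pairs, degs) {
  mols <- unique(kept_pairs$molecule_id)
  if (!all(mols %in% bcis$molecule_id))
    stopf("build_bipartite: internal consistency error - pair(s) reference pruned molecules")
  genes <- unique(kept_pairs$gene_symbol)
  if (!all(genes %in% degs$gene))
    stopf("build_bipartite: target gene(s) missing from the DEG table")
  herb_col <- if ("source_herbs" %in% names(bcis)) "source_herbs" else "herb"
  left <- data.frame(
    molecule_id = mols,
    source_herbs = bcis[[herb_col]][match(mols, bcis$molecule_id)],
    stringsAsFactors = FALSE
  )
  right <- data.frame(
    gene = genes,
    direction = degs$direction[match(genes, degs$gene)],
    log2fc = degs$log2fc[match(genes, degs$gene)],
    stringsAsFactors = FALSE
  )
  edges <- data.frame(left = kept_pairs$molecule_id,
                      right = kept_pairs$gene_symbol,
                      stringsAsFactors = FALSE)
  bipartite_net(left, right, edges, "ingredient", "target")
}

#' Report ingredients with multiple targets
#'
#' @param net a [bipartite_net()].
#' @param k_min minimum degree for inclusion (default 2).
#' @return data.frame (molecule_id, degree, targets) sorted by degree
#'   descending then molecule_id.
#' @export
multi_target_report <- function(net, k_min = 2) {
  stopifnot(inherits(net, "bipartite_net"))
  keep <- net$left[net$left$degree >= k_min, , drop = FALSE]
  if (!nrow(keep)) {
    return(data.frame(molecule_id = character(), degree = integer(),
                      targets = character(), stringsAsFactors = FALSE))
  }
  targets <- vapply(keep[[1]], function(m) {
    paste(sort(net$edges$right[net$edges$left == m]), collapse = ";")
  }, "")
  out <- data.frame(molecule_id = keep[[1]], degree = keep$degree,
                    targets = unname(targets), stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$molecule_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# namespace prefixes used in exports
bip_prefixes <- function(net) {
  pref <- c(ingredient = "mol:", target = "gene:", pathway = "set:")
  c(pref[[net$left_type]] %||% "l:", pref[[net$right_type]] %||% "r:")
}

#' Convert a bipartite network to an igraph object
#'
#' Node names are namespace-prefixed (`mol:`, `gene:`, `set:`) and a logical
#' `is_left` vertex attribute distinguishes the two sides.
#'
#' @param net a [bipartite_net()].
#' @return an undirected [igraph::igraph] graph.
#' @export
bipartite_igraph <- function(net) {
  p <- bip_prefixes(net)
  verts <- data.frame(
    name = c(paste0(p[1], net$left[[1]]), paste0(p[2], net$right[[1]])),
    type = c(rep(net$left_type, nrow(net$left)),
             rep(net$right_type, nrow(net$right))),
    is_left = c(rep(TRUE, nrow(net$left)), rep(FALSE, nrow(net$right))),
    stringsAsFactors = FALSE
  )
  ed <- data.frame(from = paste0(p[1], net$edges$left),
                   to = paste0(p[2], net$edges$right),
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}

#' Write a bipartite network as SIF
#'
#' One line per edge: `left<TAB>relation<TAB>right`, node IDs prefixed with
#' their namespace.  Isolated nodes (degree 0) are emitted as single-column
#' lines so round-trips preserve the node sets.
#'
#' @param net a [bipartite_net()].
#' @param path output file.
#' @param relation interaction-type token (default "bt", BCI-target).
#' @return (invisibly) the path.
#' @export
write_sif_bipartite <- function(net, path, relation = "bt") {
  p <- bip_prefixes(net)
  lines <- sprintf("%s%s\t%s\t%s%s", p[1], net$edges$left, relation,
                   p[2], net$edges$right)
  iso <- c(paste0(p[1], net$left[[1]][net$left$degree == 0]),
           paste0(p[2], net$right[[1]][net$right$degree == 0]))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read a SIF file
#'
#' @param path SIF file (`a<TAB>relation<TAB>b`, or a single column for
#'   isolated nodes).
#' @return list with `edges` (data.frame a/relation/b) and `isolated`
#'   (character).
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  ed <- parts[n_fields >= 3]
  edges <- data.frame(
    a = vapply(ed, `[[`, "", 1),
    relation = vapply(ed, `[[`, "", 2),
    b = vapply(ed, `[[`, "", 3),
    stringsAsFactors = FALSE
  )
  list(edges = edges, isolated = vapply(parts[n_fields == 1], `[[`, "", 1))
}

#' Write a bipartite network as GraphML
#'
#' @param net a [bipartite_net()].
#' @param path output file.
#' @return (invisibly) the path.
#' @export
write_graphml_bipartite <- function(net, path) {
  igraph::write_graph(bipartite_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Node attribute table of a bipartite network
#'
#' @param net a [bipartite_net()].
#' @return data.frame with node ID, side type, degree and the side-specific
#'   attributes.
#' @export
bipartite_nodes <- function(net) {
  l <- net$left
  r <- net$right
  out <- data.frame(
    node = c(l[[1]], r[[1]]),
    type = c(rep(net$left_type, nrow(l)), rep(net$right_type, nrow(r))),
    degree = c(l$degree, r$degree),
    stringsAsFactors = FALSE
  )
  out
}
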