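# Hypergeometric over-representation analysis against GO-style and pathway
# gene sets, with Benjamini-Hochberg correction applied within each
# category (BP/CC/MF/pathway) by default, and the target-pathway network.

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (member genes).
#' @param category character vector recycled over sets, each one of
#'   `"BP"`, `"CC"`, `"MF"`, `"pathway"`.
#' @param universe gene universe; defaults to the union of all members.
#'   Every member gene must belong to it.
#' @return object of class `gene_set_collection` with components `sets`,
#'   `meta` (set_id, category, size) and `universe`.
#' @export
gene_set_collection <- function(sets, category = "pathway", universe = NULL) {
  if (!length(sets)) {
    return(structure(list(sets = list(),
                          meta = data.frame(set_id = character(),
                                            category = character(),
                                            size = integer(),
                                            stringsAsFactors = FALSE),
                          universe = universe %||% character()),
                     class = "gene_set_collection"))
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("gene_set_collection: sets must be named")
  if (anyDuplicated(names(sets)))
    stopf("gene_set_collection: duplicated set names")
  sets <- lapply(sets, unique)
  if (any(lengths(sets) < 1))
    stopf("gene_set_collection: empty set(s)")
  category <- rep_len(category, length(sets))
  bad_cat <- !category %in% c("BP", "CC", "MF", "pathway")
  if (any(bad_cat))
    stopf("gene_set_collection: unknown category: %s",
          paste(unique(category[bad_cat]), collapse = ", "))
  members <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) {
    universe <- members
  } else if (!all(members %in% universe)) {
    stopf("gene_set_collection: member gene(s) outside the universe")
  }
  meta <- data.frame(set_id = names(sets), category = category,
                     size = lengths(sets), stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  structure(list(sets = sets, meta = meta, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d set(s) over %d universe gene(s)\n",
              length(x$sets), length(x$universe)))
  if (nrow(x$meta)) print(table(x$meta$category))
  invisible(x)
}

#' Restrict a collection to one category
#'
#' @param collection a [gene_set_collection()].
#' @param category category to keep.
#' @return a [gene_set_collection()] (same universe).
#' @export
subset_collection <- function(collection, category) {
  keep <- collection$meta$set_id[collection$meta$category == category]
  gene_set_collection(collection$sets[keep],
                      category = rep(category, length(keep)),
                      universe = collection$universe)
}

#' Write a gene-set collection as GMT
#'
#' Standard GMT: `set_name<TAB>description<TAB>gene...`; the description
#' field carries the category token.
#'
#' @param collection a [gene_set_collection()].
#' @param path output file.
#' @return (invisibly) the path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(collection$meta$set_id[i], collection$meta$category[i],
            collection$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT file as a gene-set collection
#'
#' Membership is parsed with [fgsea::gmtPathways()]; the description column
#' supplies the category unless `category` is given.
#'
#' @param path GMT file.
#' @param category category assigned to every set in the file; if `NULL`
#'   the GMT description field is used.
#' @param universe optional explicit universe.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, category = NULL, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  if (is.null(category)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    category <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 2)
  }
  gene_set_collection(sets, category = category, universe = universe)
}

#' Read one GMT file per category
#'
#' @param paths named character vector of GMT paths; names are the
#'   categories.
#' @param universe optional explicit universe shared by all categories.
#' @return a combined [gene_set_collection()].
#' @export
read_gmt_multi <- function(paths, universe = NULL) {
  sets <- list()
  cats <- character()
  for (cat in names(paths)) {
    cc <- read_gmt(paths[[cat]], category = cat)
    sets <- c(sets, cc$sets)
    cats <- c(cats, rep(cat, length(cc$sets)))
  }
  gene_set_collection(sets, category = cats, universe = universe)
}

#' Hypergeometric upper-tail test
#'
#' Probability of observing at least `k` annotated genes in a query of size
#' `n`, when `K` of the `N` universe genes are annotated:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k overlap count.
#' @param n query size (in-universe).
#' @param K set size.
#' @param N universe size.
#' @return the upper-tail probability (vectorized over its arguments).
#' @export
hypergeom_test <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0) ||
      any(k > pmin(n, K)) || any(n > N) || any(K > N))
    stopf("hypergeom_test: inconsistent counts (need 0 <= k <= min(n, K) <= N)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Restricts the query to the universe (dropped genes are reported), tests
#' every set with at least one overlapping gene, applies Benjamini-Hochberg
#' within each category separately (pooled mode by flag), and reports both
#' the full table and the significant rows.
#'
#' @param query character vector of query genes.
#' @param collection a [gene_set_collection()].
#' @param alpha adjusted-p threshold (default 0.05).
#' @param universe optional custom universe (e.g. all measured genes);
#'   defaults to the collection's annotated universe.
#' @param bh_by_category adjust within category (default `TRUE`) or pooled.
#' @param min_set_size,max_set_size optional set-size filter applied to the
#'   in-universe set sizes (no filter by default).
#' @return object of class `ora_result`: `table` (all tested sets, sorted
#'   by adjusted p; columns set_id, category, k, n, K, N, gene_ratio,
#'   gene_ratio_raw, p_raw, p_adj, overlap_genes), `significant` (rows with
#'   `p_adj < alpha`), `alpha`, `query_in_universe`, `dropped`.
#' @export
run_ora <- function(query, collection, alpha = 0.05, universe = NULL,
                    bh_by_category = TRUE,
                    min_set_size = 1, max_set_size = Inf) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(query)) stopf("run_ora: query is empty")
  uni <- unique(universe %||% collection$universe)
  q <- unique(query)
  q_in <- intersect(q, uni)
  dropped <- setdiff(q, uni)
  if (!length(q_in))
    stopf("run_ora: no query gene is present in the universe")
  if (length(dropped))
    msgf("run_ora: %d query gene(s) outside the universe dropped", length(dropped))

  N <- length(uni)
  n <- length(q_in)
  rows <- lapply(seq_along(collection$sets), function(i) {
    members <- intersect(collection$sets[[i]], uni)
    K <- length(members)
    ov <- intersect(q_in, members)
    k <- length(ov)
    if (k < 1 || K < min_set_size || K > max_set_size) return(NULL)
    data.frame(set_id = collection$meta$set_id[i],
               category = collection$meta$category[i],
               k = k, n = n, K = K, N = N,
               gene_ratio = k / n,
               gene_ratio_raw = k / length(q),
               p_raw = hypergeom_test(k, n, K, N),
               overlap_genes = paste(sort(ov), collapse = "/"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(set_id = character(), category = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), gene_ratio = numeric(),
                      gene_ratio_raw = numeric(), p_raw = numeric(),
                      p_adj = numeric(), overlap_genes = character(),
                      stringsAsFactors = FALSE)
  } else {
    if (bh_by_category) {
      tab$p_adj <- NA_real_
      for (cat in unique(tab$category)) {
        idx <- tab$category == cat
        tab$p_adj[idx] <- bh_adjust(tab$p_raw[idx])
      }
    } else {
      tab$p_adj <- bh_adjust(tab$p_raw)
    }
    tab <- tab[order(tab$p_adj, tab$p_raw, tab$set_id), ,
               drop = FALSE]
    tab <- tab[, c("set_id", "category", "k", "n", "K", "N", "gene_ratio",
                   "gene_ratio_raw", "p_raw", "p_adj", "overlap_genes")]
    rownames(tab) <- NULL
  }
  structure(list(table = tab,
                 significant = tab[!is.na(tab$p_adj) & tab$p_adj < alpha, ,
                                   drop = FALSE],
                 alpha = alpha,
                 query_in_universe = q_in,
                 dropped = dropped),
            class = "ora_result")
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf("ora_result: %d set(s) tested, %d significant at adjusted p < %g\n",
              nrow(x$table), nrow(x$significant), x$alpha))
  if (nrow(x$significant)) {
    print(head(x$significant[, c("set_id", "category", "k", "K", "p_adj")], 10))
  }
  invisible(x)
}

#' Build the target-pathway bipartite network
#'
#' Left nodes are the target genes appearing in at least one significant
#' set, right nodes are the significant sets; one edge per membership.
#' Node degree encodes how many pathways a gene contributes to (and how
#' many genes a pathway contains).
#'
#' @param ora an `ora_result` (or a data.frame shaped like its
#'   `significant` table).
#' @param categories which categories to include (default `"pathway"`).
#' @return a [bipartite_net()] (targets on the left, pathways on the
#'   right).
#' @export
target_pathway_net <- function(ora, categories = "pathway") {
  rows <- if (inherits(ora, "ora_result")) ora$significant else ora
  rows <- rows[rows$category %in% categories, , drop = FALSE]
  if (!nrow(rows)) {
    return(bipartite_net(
      data.frame(gene = character(), stringsAsFactors = FALSE),
      data.frame(set_id = character(), stringsAsFactors = FALSE),
      data.frame(left = character(), right = character(),
                 stringsAsFactors = FALSE),
      "target", "pathway"))
  }
  edges <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    genes <- strsplit(rows$overlap_genes[i], "/", fixed = TRUE)[[1]]
    data.frame(left = genes, right = rows$set_id[i], stringsAsFactors = FALSE)
  }))
  left <- data.frame(gene = sort(unique(edges$left)), stringsAsFactors = FALSE)
  right <- data.frame(set_id = rows$set_id, p_adj = rows$p_adj,
                      stringsAsFactors = FALSE)
  bipartite_net(left, right, edges, "target", "pathway")
}
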