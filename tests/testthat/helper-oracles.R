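# Independent oracles used across the suite.  Each one is deliberately
# written by a different route than the package implementation it checks.

# Step-up BH by explicit sort / cumulative-minimum-from-the-right / unsort.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- pmin(1, m * sorted / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail by summing the exact pmf from binomial
# coefficients (no distribution functions).
enum_hypergeom <- function(k, n, K, N) {
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  if (k > hi) return(0)
  xs <- max(k, lo):hi
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Betweenness by all-pairs BFS distances and path counts:
# bc(v) = sum over s < t (s,t != v) of sigma_sv * sigma_vt / sigma_st
# restricted to pairs whose geodesic passes through v.
naive_bc <- function(adj) {
  n <- length(adj)
  d <- matrix(Inf, n, n)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    sig[s, s] <- 1
    q <- integer(n); q[1] <- s; head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- q[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          tail <- tail + 1L; q[tail] <- w
        }
        if (d[s, w] == d[s, v] + 1) sig[s, w] <- sig[s, w] + sig[s, v]
      }
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    S <- outer(d[, v], d[v, ], "+")
    ok <- is.finite(d) & (S == d)
    ok[v, ] <- FALSE; ok[, v] <- FALSE; diag(ok) <- FALSE
    W <- (sig[, v] %o% sig[v, ]) / ifelse(sig > 0, sig, 1)
    bc[v] <- sum(W[ok & upper.tri(d)])
  }
  bc
}

# adjacency list (integer indices) of an igraph object
adj_list_of <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

# random simple graph as an igraph object with letter-ish names
random_test_graph <- function(n, p = 0.2) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# igraph from an explicit undirected edge list given as a character vector
# c("a-b", "b-c", ...), plus optional isolated vertices
graph_from_spec <- function(edges, isolated = character()) {
  parts <- strsplit(edges, "-", fixed = TRUE)
  df <- data.frame(from = vapply(parts, `[[`, "", 1),
                   to = vapply(parts, `[[`, "", 2),
                   stringsAsFactors = FALSE)
  verts <- unique(c(df$from, df$to, isolated))
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = verts))
}

# small fast synth config for unit tests
tiny_cfg <- function(...) {
  defaults <- list(n_gene_total = 300L, n_pairs = 5L,
                   herbs = c("A", "B"), n_compounds_per_herb = 30L,
                   n_shared = 2L, target_pool_size = 40L, n_target_de = 5L,
                   interactome_nodes = 120L, n_gene_sets = 20L,
                   set_size_range = c(5L, 15L))
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}
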