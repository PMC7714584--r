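# Paired differential expression: hand-computed t oracle, degenerate-case
# policy, BH against the sort/cummin oracle, and the significance filter.

# build a study whose per-pair differences for one gene are exactly `diffs`
study_from_diffs <- function(diffs, n_genes = 1) {
  np <- length(diffs)
  ctrl <- matrix(5, n_genes, np)
  case <- ctrl + matrix(rep(diffs, each = n_genes), n_genes, np)
  mat <- cbind(case, ctrl)
  rownames(mat) <- sprintf("g%d", seq_len(n_genes))
  pid <- sprintf("P%02d", seq_len(np))
  colnames(mat) <- c(paste0(pid, "_case"), paste0(pid, "_control"))
  samples <- data.frame(sample = colnames(mat),
                        pair_id = rep(pid, 2),
                        condition = rep(c("case", "control"), each = np))
  expression_study(mat, samples)
}

test_that("paired t statistic matches the hand-computed formula", {
  st <- study_from_diffs(c(0.8, 1.2, 1.0, 1.4, 0.6))
  res <- paired_t_test(st, "g1")
  d <- c(0.8, 1.2, 1.0, 1.4, 0.6)
  t_hand <- mean(d) / (sd(d) / sqrt(5))   # = 1.0 / (0.3162 / sqrt(5))
  expect_equal(res$log2fc, 1.0)
  expect_equal(res$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(res$t_stat, 7.0710678, tolerance = 1e-6)
  expect_equal(res$p_raw, 2 * pt(-t_hand, df = 4), tolerance = 1e-12)
})

test_that("paired test agrees with t.test on random data", {
  set.seed(42)
  np <- 8
  mat <- matrix(rnorm(20 * 2 * np, mean = 6), 20, 2 * np)
  rownames(mat) <- sprintf("g%02d", 1:20)
  pid <- sprintf("P%02d", seq_len(np))
  colnames(mat) <- c(paste0(pid, "_case"), paste0(pid, "_control"))
  samples <- data.frame(sample = colnames(mat), pair_id = rep(pid, 2),
                        condition = rep(c("case", "control"), each = np))
  st <- expression_study(mat, samples)
  for (g in c("g01", "g07", "g20")) {
    ref <- t.test(mat[g, 1:np], mat[g, np + 1:np], paired = TRUE)
    res <- paired_t_test(st, g)
    expect_equal(res$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_raw, ref$p.value, tolerance = 1e-12)
    expect_equal(res$log2fc, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("degenerate paired differences follow the stated policy", {
  # constant nonzero differences: minimum-positive p with a warning
  st <- study_from_diffs(c(1, 1, 1, 1))
  expect_warning(res <- paired_t_test(st, "g1"), "zero paired-difference")
  expect_equal(res$log2fc, 1)
  expect_equal(res$p_raw, .Machine$double.xmin)
  # perfectly cancelling differences: t = 0, p = 1
  st0 <- study_from_diffs(c(-1, 1, -1, 1))
  res0 <- paired_t_test(st0, "g1")
  expect_equal(res0$log2fc, 0)
  expect_equal(res0$t_stat, 0)
  expect_equal(res0$p_raw, 1)
  expect_error(paired_t_test(st0, "nope"), "not found")
})

test_that("moderated mode shrinks variances by the fixed-prior formula", {
  set.seed(9)
  np <- 6
  mat <- matrix(rnorm(50 * 2 * np, 6), 50, 2 * np)
  rownames(mat) <- sprintf("g%02d", 1:50)
  pid <- sprintf("P%02d", seq_len(np))
  colnames(mat) <- c(paste0(pid, "_case"), paste0(pid, "_control"))
  samples <- data.frame(sample = colnames(mat), pair_id = rep(pid, 2),
                        condition = rep(c("case", "control"), each = np))
  st <- expression_study(mat, samples)
  D <- mat[, 1:np] - mat[, np + 1:np]
  s2 <- apply(D, 1, var)
  d0 <- 4
  s2t <- (d0 * mean(s2) + (np - 1) * s2) / (d0 + np - 1)
  t_exp <- rowMeans(D) / sqrt(s2t / np)
  res <- paired_t_test(st, "g03", moderation = "eb", prior_df = 4)
  expect_equal(res$t_stat, unname(t_exp["g03"]), tolerance = 1e-12)
  expect_equal(res$p_raw,
               2 * pt(-abs(t_exp[["g03"]]), df = d0 + np - 1),
               tolerance = 1e-12)
})

test_that("BH adjustment equals the independent sort/cummin oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.5), 0.5)
  set.seed(1)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), naive_bh(p), tolerance = 1e-14)
  }
  # order preservation: adjusted values are monotone when inputs sorted
  p <- sort(runif(30))
  expect_false(is.unsorted(bh_adjust(p)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("the significance filter applies >= to fold change and < to p", {
  tbl <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1.0, 0.5, -2.0, 1.5),
                    p_adj = c(0.049, 0.001, 0.01, 0.05))
  out <- deg_filter(tbl)
  # a: |fc| exactly 1 kept; b: fails fc; c: kept; d: p exactly alpha dropped
  expect_setequal(out$gene, c("a", "c"))
  expect_equal(out$direction[out$gene == "c"], "down")
  expect_equal(attr(out, "n_up"), 1L)
  expect_equal(attr(out, "n_down"), 1L)
  # sorted by |log2fc| descending
  expect_equal(out$gene, c("c", "a"))
})

test_that("call_degs is invariant to gene row order", {
  cfg <- tiny_cfg(seed = 21L)
  st <- generate_expression(cfg)
  d1 <- call_degs(st)
  perm <- sample(nrow(st$matrix))
  st2 <- expression_study(st$matrix[perm, ], st$samples)
  d2 <- call_degs(st2)
  expect_setequal(d1$gene, d2$gene)
  expect_equal(d1[order(d1$gene), c("log2fc", "p_adj")],
               d2[order(d2$gene), c("log2fc", "p_adj")],
               ignore_attr = TRUE)
})

test_that("rows with missing values are dropped on construction", {
  st <- study_from_diffs(c(0.5, 0.2, -0.1, 0.4), n_genes = 3)
  mat <- st$matrix
  mat[2, 3] <- NA
  expect_message(st2 <- expression_study(mat, st$samples), "1 gene row")
  expect_equal(length(st2$genes), 2L)
})

test_that("published characterization tables pass the filter intact", {
  targets <- read.delim(netpharm_example("gqd_target_genes.tsv"))
  out <- deg_filter(targets)
  expect_equal(nrow(out), 20L)
  expect_equal(attr(out, "n_up"), 13L)
  expect_equal(attr(out, "n_down"), 7L)
  top <- read.delim(netpharm_example("crc_top_degs.tsv"))
  out2 <- deg_filter(top)
  expect_equal(nrow(out2), 20L)
  expect_equal(attr(out2, "n_up"), 10L)
  expect_equal(attr(out2, "n_down"), 10L)
})
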