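# Paired differential expression: paired t statistics (plain or with
# fixed-prior empirical-Bayes variance moderation), Benjamini-Hochberg
# adjustment, and the |log2FC| / adjusted-p significance filter.

#' Construct a paired expression study
#'
#' Validates and assembles a log2-scale expression matrix with its paired
#' sample design.  Rows containing missing values are dropped (paired
#' statistics need complete pairs; imputation is out of scope) with a
#' message stating how many.
#'
#' @param mat numeric matrix, genes x samples, log2 scale, with row and
#'   column names.
#' @param samples data.frame with columns `sample`, `pair_id`, `condition`
#'   (`"case"` or `"control"`); every sample must belong to exactly one
#'   pair and every pair must contain one case and one control.
#' @param truth,truth_sign optional named logical/integer vectors flagging
#'   truly differential genes (synthetic studies only).
#' @return an object of class `expression_study` with components `genes`,
#'   `matrix`, `samples`, `pairs` (data.frame pair_id/case/control),
#'   `truth`, `truth_sign`.
#' @export
expression_study <- function(mat, samples, truth = NULL, truth_sign = NULL) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stopf("expression_study: 'mat' must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stopf("expression_study: 'mat' must have gene row names and sample column names")
  require_columns(samples, c("sample", "pair_id", "condition"), "sample table")
  if (!setequal(colnames(mat), samples$sample))
    stopf("expression_study: matrix columns and sample table disagree")
  if (anyDuplicated(samples$sample))
    stopf("expression_study: duplicated sample IDs")
  if (!all(samples$condition %in% c("case", "control")))
    stopf("expression_study: condition must be 'case' or 'control'")

  pieces <- split(samples, samples$pair_id)
  bad <- vapply(pieces, function(p) {
    nrow(p) != 2 || !setequal(p$condition, c("case", "control"))
  }, logical(1))
  if (any(bad))
    stopf("expression_study: pair(s) without exactly one case and one control: %s",
          paste(names(pieces)[bad], collapse = ", "))
  if (length(pieces) < 3)
    stopf("expression_study: at least 3 sample pairs are required")

  keep <- !apply(mat, 1, anyNA)
  if (any(!keep)) {
    msgf("expression_study: dropping %d gene row(s) with missing values",
         sum(!keep))
    mat <- mat[keep, , drop = FALSE]
  }
  pairs <- data.frame(
    pair_id = names(pieces),
    case = vapply(pieces, function(p) p$sample[p$condition == "case"], ""),
    control = vapply(pieces, function(p) p$sample[p$condition == "control"], ""),
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  genes <- rownames(mat)
  if (!is.null(truth)) truth <- truth[genes]
  if (!is.null(truth_sign)) truth_sign <- truth_sign[genes]
  structure(list(genes = genes, matrix = mat, samples = samples,
                 pairs = pairs, truth = truth, truth_sign = truth_sign),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes, %d sample pairs (%d samples)\n",
              length(x$genes), nrow(x$pairs), ncol(x$matrix)))
  if (!is.null(x$truth))
    cat(sprintf("  truth flags: %d truly differential genes\n", sum(x$truth)))
  invisible(x)
}

#' Read an expression study from TSV files
#'
#' @param matrix_path genes x samples TSV with a leading gene-ID column.
#' @param samples_path sample metadata TSV (`sample`, `pair_id`, `condition`).
#' @return an [expression_study()].
#' @export
read_expression <- function(matrix_path, samples_path) {
  raw <- read.delim(matrix_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- raw[[1]]
  samples <- read_tsv_plain(samples_path)
  expression_study(mat, samples)
}

#' Write an expression study to TSV files
#'
#' @param study an [expression_study()].
#' @param matrix_path,samples_path output paths.
#' @return (invisibly) the matrix path.
#' @export
write_expression <- function(study, matrix_path, samples_path) {
  df <- data.frame(gene = rownames(study$matrix),
                   round(study$matrix, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, matrix_path)
  write_tsv_plain(study$samples, samples_path)
  invisible(matrix_path)
}

#' Paired statistics for every gene
#'
#' Vectorized paired t statistics over the whole study, without any
#' thresholding: the per-gene log2 fold change (mean of per-pair
#' differences), t statistic and two-sided raw p.  See [paired_t_test()]
#' for the formulas and the degenerate-case policy.
#'
#' @inheritParams paired_t_test
#' @return data.frame (gene, log2fc, t_stat, p_raw) in study row order.
#' @export
deg_stats <- function(study, moderation = c("none", "eb"), prior_df = 4) {
  moderation <- match.arg(moderation)
  stopifnot(inherits(study, "expression_study"))
  D <- study$matrix[, study$pairs$case, drop = FALSE] -
    study$matrix[, study$pairs$control, drop = FALSE]
  n <- ncol(D)
  lfc <- rowMeans(D)
  s2 <- rowSums((D - lfc)^2) / (n - 1)

  if (moderation == "eb") {
    # shrink per-gene variances toward the study-wide mean variance with a
    # fixed prior df; an approximation to full empirical-Bayes moderation
    s2_tilde <- (prior_df * mean(s2) + (n - 1) * s2) / (prior_df + n - 1)
    df <- prior_df + n - 1
    t_stat <- lfc / sqrt(s2_tilde / n)
    p <- 2 * pt(-abs(t_stat), df)
  } else {
    df <- n - 1
    t_stat <- lfc / sqrt(s2 / n)
    p <- 2 * pt(-abs(t_stat), df)
    zero <- s2 == 0
    if (any(zero)) {
      flat <- zero & lfc == 0
      t_stat[flat] <- 0
      p[flat] <- 1
      shifted <- zero & lfc != 0
      if (any(shifted)) {
        warnf("%d gene(s) with zero paired-difference variance but nonzero shift; p set to the smallest positive double",
              sum(shifted))
        t_stat[shifted] <- sign(lfc[shifted]) * Inf
        p[shifted] <- .Machine$double.xmin
      }
    }
  }
  data.frame(gene = study$genes, log2fc = unname(lfc),
             t_stat = unname(t_stat), p_raw = unname(p),
             stringsAsFactors = FALSE)
}

#' Paired t-test for one gene
#'
#' Computes the per-pair case-minus-control differences and the paired
#' t-statistic for a single gene: `log2fc = mean(d)`,
#' `t = mean(d) / (sd(d) / sqrt(n))`, two-sided p from Student's t with
#' n - 1 df.  With `moderation = "eb"` the gene variance is shrunk toward
#' the study-wide mean variance with a fixed prior df:
#' `s2~ = (d0 * s2bar + (n-1) * s2) / (d0 + n - 1)` on `d0 + n - 1` df.
#'
#' Degenerate inputs (plain mode): zero variance with zero mean gives
#' `t = 0, p = 1`; zero variance with a nonzero mean gives the smallest
#' positive double as p, with a warning.
#'
#' @param study an [expression_study()].
#' @param gene gene identifier (row name).
#' @param moderation `"none"` (default) or `"eb"`.
#' @param prior_df prior degrees of freedom for the moderated mode.
#' @return named list with `log2fc`, `t_stat`, `p_raw`.
#' @export
paired_t_test <- function(study, gene, moderation = c("none", "eb"),
                          prior_df = 4) {
  moderation <- match.arg(moderation)
  if (!gene %in% study$genes)
    stopf("paired_t_test: gene '%s' not found in the study", gene)
  tbl <- deg_stats(study, moderation, prior_df)
  row <- tbl[tbl$gene == gene, ]
  list(log2fc = row$log2fc, t_stat = row$t_stat, p_raw = row$p_raw)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: sort ascending, `adj_i = min_{j >= i} m p_j / j`
#' clipped at 1, returned in input order.
#'
#' @param p_values numeric vector of probabilities in [0, 1].
#' @return adjusted probabilities, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values))
    stopf("bh_adjust: input must be numeric")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stopf("bh_adjust: p-values must lie in [0, 1] with no missing values")
  p.adjust(p_values, method = "BH")
}

#' Apply the fold-change / adjusted-p significance filter
#'
#' Keeps rows with `|log2fc| >= fc_min` and `p_adj < alpha` (inclusive on
#' fold change, strict on adjusted p), adds an up/down `direction` column,
#' and sorts by `|log2fc|` descending.  Works on any table carrying
#' `log2fc` and `p_adj` columns, e.g. a published characterization table.
#'
#' @param table data.frame with columns `log2fc` and `p_adj`.
#' @param fc_min minimum absolute log2 fold change (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return the filtered, annotated, sorted data.frame; attributes `n_up`
#'   and `n_down` carry the direction counts.
#' @export
deg_filter <- function(table, fc_min = 1.0, alpha = 0.05) {
  require_columns(table, c("log2fc", "p_adj"), "DEG table")
  if (fc_min < 0 || alpha < 0 || alpha > 1)
    stopf("deg_filter: thresholds out of range")
  keep <- abs(table$log2fc) >= fc_min & table$p_adj < alpha
  out <- table[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  out <- out[order(-abs(out$log2fc)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(out$direction == "up")
  attr(out, "n_down") <- sum(out$direction == "down")
  out
}

#' Call differentially expressed genes from a paired study
#'
#' Runs the paired test on every gene, adjusts with Benjamini-Hochberg, and
#' keeps genes with `|log2fc| >= fc_min` and adjusted p strictly below
#' `alpha`.
#'
#' @inheritParams paired_t_test
#' @param fc_min minimum absolute log2 fold change (default 1).
#' @param alpha BH-adjusted p threshold (default 0.05).
#' @return data.frame (gene, log2fc, t_stat, p_raw, p_adj, direction)
#'   sorted by `|log2fc|` descending, with `n_up`/`n_down` attributes.
#' @export
call_degs <- function(study, fc_min = 1.0, alpha = 0.05,
                      moderation = c("none", "eb"), prior_df = 4) {
  moderation <- match.arg(moderation)
  if (fc_min <= 0) stopf("call_degs: 'fc_min' must be positive")
  if (alpha < 0 || alpha > 1) stopf("call_degs: 'alpha' must be in [0, 1]")
  tbl <- deg_stats(study, moderation, prior_df)
  tbl$p_adj <- bh_adjust(tbl$p_raw)
  deg_filter(tbl, fc_min = fc_min, alpha = alpha)
}
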