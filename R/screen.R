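# ADME screening of herb compounds: oral bioavailability (OB, percent) and
# drug-likeness (DL, unitless) thresholds, and deduplication of molecules
# shared across herbs.

#' Read a herb compound table
#'
#' @param path TSV with columns `molecule_id`, `molecule_name`, `herb`,
#'   `ob`, `dl`.
#' @return data.frame of compound records.
#' @export
read_compounds <- function(path) {
  df <- read_tsv_plain(path)
  require_columns(df, c("molecule_id", "herb", "ob", "dl"), "compound table")
  df
}

#' Screen compounds to bioactive chemical ingredients
#'
#' Keeps records with `ob >= ob_min` and `dl >= dl_min` (both thresholds
#' inclusive; the conventional ADME criteria are OB >= 30\% and DL >= 0.18).
#' Records with a missing OB or DL are rejected with a warning; DL values
#' above 1 are flagged but not rejected.
#'
#' @param compounds data.frame of compound records (`molecule_id`, `herb`,
#'   `ob`, `dl`).
#' @param ob_min minimum oral bioavailability, percent (default 30).
#' @param dl_min minimum drug-likeness (default 0.18).
#' @return the retained records; attribute `dropped` holds the count of
#'   excluded records and per-herb kept counts are reported by message.
#' @export
screen_bci <- function(compounds, ob_min = 30, dl_min = 0.18) {
  require_columns(compounds, c("molecule_id", "ob", "dl"), "compound table")
  herb_col <- if ("herb" %in% names(compounds)) "herb" else "source_herbs"
  require_columns(compounds, herb_col, "compound table")
  if (!is.finite(ob_min) || !is.finite(dl_min))
    stopf("screen_bci: thresholds must be finite")
  if (any(!is.na(compounds$ob) & compounds$ob < 0))
    stopf("screen_bci: negative OB value(s)")
  bad <- is.na(compounds$ob) | is.na(compounds$dl)
  if (any(bad)) {
    warnf("screen_bci: %d record(s) with missing OB/DL rejected", sum(bad))
  }
  if (any(!is.na(compounds$dl) & compounds$dl > 1))
    warnf("screen_bci: DL value(s) above 1 encountered; kept as supplied")
  keep <- !bad & compounds$ob >= ob_min & compounds$dl >= dl_min
  out <- compounds[keep, , drop = FALSE]
  rownames(out) <- NULL
  per_herb <- table(factor(out[[herb_col]],
                           levels = unique(compounds[[herb_col]])))
  msgf("screen_bci: kept %d / %d records (%s)", nrow(out), nrow(compounds),
       paste(sprintf("%s: %d", names(per_herb), per_herb), collapse = ", "))
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Deduplicate compound records across herbs
#'
#' Molecules are keyed by `molecule_id` only (names vary in capitalization
#' between sources).  One record is kept per molecule; its `source_herbs`
#' field becomes the sorted, semicolon-joined union of the contributing
#' herbs.  Conflicting OB/DL values for one molecule keep the first record
#' encountered, with a warning.  Output is sorted by `molecule_id`.
#'
#' @param compounds data.frame of compound records.
#' @return deduplicated data.frame with a `source_herbs` column in place of
#'   `herb`.
#' @export
dedupe_bci <- function(compounds) {
  require_columns(compounds, c("molecule_id", "ob", "dl"), "compound table")
  herb_col <- if ("herb" %in% names(compounds)) "herb" else "source_herbs"
  ids <- unique(compounds$molecule_id)
  first <- compounds[match(ids, compounds$molecule_id), , drop = FALSE]

  conflict <- vapply(ids, function(id) {
    sub <- compounds[compounds$molecule_id == id, , drop = FALSE]
    nrow(sub) > 1 && (length(unique(sub$ob)) > 1 || length(unique(sub$dl)) > 1)
  }, logical(1))
  if (any(conflict))
    warnf("dedupe_bci: conflicting OB/DL for %d molecule ID(s); keeping first record",
          sum(conflict))

  sources <- vapply(ids, function(id) {
    h <- compounds[[herb_col]][compounds$molecule_id == id]
    paste(sort(unique(unlist(strsplit(h, ";", fixed = TRUE)))), collapse = ";")
  }, "")
  first[[herb_col]] <- NULL
  first$source_herbs <- unname(sources)
  first <- first[order(first$molecule_id), , drop = FALSE]
  rownames(first) <- NULL
  first
}
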