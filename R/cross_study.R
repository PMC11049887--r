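# Cross-cohort comparison: harmonize per-gene heritability summaries by
# Ensembl id, recompute BH-FDR within the common gene set, and report
# overlap (Venn pattern counts) and concordance (pairwise Pearson r of h2).

#' Harmonize study summaries by Ensembl id
#'
#' Strips ".N" version suffixes, case-normalizes, intersects the id sets of
#' all studies and emits a gene x study table of (h2, p).
#'
#' @param studies list of >= 2 [study_summary()] objects.
#' @return object of class `harmonized_studies`: `labels`, `common_ids`,
#'   and `table`, a data.frame with ensembl_id plus `h2.<label>` and
#'   `pvalue.<label>` columns.
#' @export
harmonize <- function(studies) {
  if (length(studies) < 2L)
    stop("need at least 2 studies to harmonize", call. = FALSE)
  if (!all(vapply(studies, inherits, logical(1), "study_summary")))
    stop("all elements must be study_summary objects", call. = FALSE)
  labels <- vapply(studies, function(s) s$label, character(1))
  if (anyDuplicated(labels))
    stop("study labels must be unique", call. = FALSE)
  for (s in studies) {
    ids <- strip_ensembl_version(s$table$ensembl_id)
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      stop("study ", s$label, " has duplicate gene id(s) after version stripping: ",
           paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  id_sets <- lapply(studies, function(s) strip_ensembl_version(s$table$ensembl_id))
  common <- Reduce(intersect, id_sets)
  if (length(common) == 0L)
    warning("studies share no genes; downstream overlap operations will refuse")
  common <- sort(common)
  tab <- data.frame(ensembl_id = common, stringsAsFactors = FALSE)
  for (s in studies) {
    ids <- strip_ensembl_version(s$table$ensembl_id)
    i <- match(common, ids)
    tab[[paste0("h2.", s$label)]] <- s$table$h2[i]
    tab[[paste0("pvalue.", s$label)]] <- s$table$pvalue[i]
  }
  structure(list(labels = labels, common_ids = common, table = tab),
            class = "harmonized_studies")
}

#' Recompute FDR within the common gene set
#'
#' Per study, BH over that study's p-values restricted to the common genes
#' (the multiplicity is the overlap size, not the full study size).
#'
#' @param harmonized a [harmonize()] result.
#' @param q_threshold significance threshold (default 0.05).
#' @return the harmonized object with `q.<label>` and `sig.<label>` columns
#'   added to its table.
#' @export
overlap_fdr <- function(harmonized, q_threshold = 0.05) {
  stopifnot(inherits(harmonized, "harmonized_studies"))
  if (length(harmonized$common_ids) < 2L)
    stop("fewer than 2 common genes; nothing to adjust", call. = FALSE)
  tab <- harmonized$table
  for (lab in harmonized$labels) {
    p <- tab[[paste0("pvalue.", lab)]]
    if (any(!is.finite(p)))
      stop("missing p-value(s) for common genes in study ", lab, call. = FALSE)
    q <- bh_adjust(p)
    tab[[paste0("q.", lab)]] <- q
    tab[[paste0("sig.", lab)]] <- q < q_threshold
  }
  harmonized$table <- tab
  harmonized$q_threshold <- q_threshold
  harmonized
}

#' Overlap and concordance report
#'
#' Venn pattern counts over the per-study significance flags (all 2^k - 1
#' nonempty membership patterns), pairwise Pearson correlations of h2 over
#' all common genes, and the table of genes significant in every study
#' ordered by the first study's h2.
#'
#' @param harmonized an [overlap_fdr()] result.
#' @param top_k rows of the everywhere-significant table to keep (default
#'   10; Inf for all).
#' @return object of class `overlap_report`: `n_common`, `venn_counts`
#'   (data.frame pattern/count), `pairwise_r` (symmetric matrix),
#'   `n_significant` (per study), `top_common` (data.frame).
#' @export
overlap_report <- function(harmonized, top_k = 10L) {
  stopifnot(inherits(harmonized, "harmonized_studies"))
  tab <- harmonized$table
  labels <- harmonized$labels
  sig_cols <- paste0("sig.", labels)
  if (!all(sig_cols %in% names(tab)))
    stop("run overlap_fdr() before overlap_report()", call. = FALSE)
  sig <- as.matrix(tab[, sig_cols, drop = FALSE])
  colnames(sig) <- labels

  # venn counts over nonempty membership patterns
  k <- length(labels)
  patterns <- list()
  for (size in seq_len(k)) {
    for (members in utils::combn(labels, size, simplify = FALSE)) {
      in_set <- rowSums(sig[, members, drop = FALSE]) == length(members)
      out_set <- if (length(members) == k) rep(FALSE, nrow(sig)) else
        rowSums(sig[, setdiff(labels, members), drop = FALSE]) > 0
      patterns[[paste(members, collapse = "&")]] <- sum(in_set & !out_set)
    }
  }
  venn_counts <- data.frame(pattern = names(patterns),
                            count = unlist(patterns, use.names = FALSE),
                            stringsAsFactors = FALSE)

  h2 <- as.matrix(tab[, paste0("h2.", labels), drop = FALSE])
  colnames(h2) <- labels
  pairwise_r <- stats::cor(h2, method = "pearson")

  all_sig <- rowSums(sig) == k
  top <- tab[all_sig, , drop = FALSE]
  top <- top[order(-top[[paste0("h2.", labels[1L])]]), , drop = FALSE]
  if (is.finite(top_k)) top <- utils::head(top, top_k)
  rownames(top) <- NULL

  structure(list(
    n_common = nrow(tab),
    venn_counts = venn_counts,
    pairwise_r = pairwise_r,
    n_significant = stats::setNames(colSums(sig), labels),
    n_significant_all = sum(all_sig),
    top_common = top
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Cross-study overlap:", x$n_common, "common genes;",
      x$n_significant_all, "significant in every study\n")
  cat("Per-study significant:",
      paste(names(x$n_significant), x$n_significant, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
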