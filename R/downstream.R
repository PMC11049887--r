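# Downstream analyses on gene-level results: Fisher's exact enrichment of
# user-supplied gene lists among FDR-significant genes, and Pearson
# correlation of heritability with gene features (GC content, length).

#' Fisher's exact gene-list enrichment
#'
#' Builds the 2x2 table (in-list / not) x (significant / not) over the
#' background and tests it with Fisher's exact test: two-sided p from
#' summing hypergeometric probabilities no larger than the observed one,
#' conditional-ML odds ratio with an exact 95% CI. List genes absent from
#' the background are dropped first, with a logged count. Zero cells give
#' an odds ratio of 0 or Inf with a one-sided CI bound, never an error.
#'
#' @param significant_genes character vector, a subset of the background.
#' @param list_genes character vector (the gene list being tested).
#' @param background_genes character vector of all analyzed genes.
#' @param conf_level CI level (default 0.95).
#' @param log optional provenance log.
#' @return object of class `enrichment_result`: `table` (2x2), `odds_ratio`,
#'   `or_ci_lo`, `or_ci_hi`, `pvalue`, `n_list_dropped`.
#' @export
fisher_enrichment <- function(significant_genes, list_genes, background_genes,
                              conf_level = 0.95, log = NULL) {
  background_genes <- unique(background_genes)
  significant_genes <- unique(significant_genes)
  list_genes <- unique(list_genes)
  if (!length(background_genes))
    stop("background gene set is empty", call. = FALSE)
  if (!length(significant_genes))
    stop("significant gene set is empty", call. = FALSE)
  out_of_bg <- setdiff(significant_genes, background_genes)
  if (length(out_of_bg))
    stop("significant gene(s) outside the background: ",
         paste(utils::head(out_of_bg, 5L), collapse = ", "), call. = FALSE)
  n_dropped <- length(setdiff(list_genes, background_genes))
  list_genes <- intersect(list_genes, background_genes)
  log_line(log, "enrichment: ", n_dropped,
           " list gene(s) missing from the background were dropped; ",
           length(list_genes), " used")

  in_list <- background_genes %in% list_genes
  sig <- background_genes %in% significant_genes
  tab <- matrix(c(sum(in_list & sig), sum(in_list & !sig),
                  sum(!in_list & sig), sum(!in_list & !sig)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(in_list = c("yes", "no"),
                                significant = c("yes", "no")))
  ft <- stats::fisher.test(tab, conf.level = conf_level)
  structure(list(table = tab,
                 odds_ratio = unname(ft$estimate),
                 or_ci_lo = ft$conf.int[1L],
                 or_ci_hi = ft$conf.int[2L],
                 pvalue = ft$p.value,
                 n_list_dropped = n_dropped),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Fisher enrichment: OR = %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$odds_ratio, x$or_ci_lo, x$or_ci_hi, x$pvalue))
  print(x$table)
  invisible(x)
}

#' Correlation of heritability with a gene feature
#'
#' Pearson correlation (two-sided p from the t transform) between gene
#' heritability and an annotation feature, by default restricted to
#' FDR-significant genes. Genes without the feature are dropped with a
#' logged count.
#'
#' @param gene_results result of [aggregate_genes()].
#' @param annotation probe annotation table (feature is taken from the
#'   gene's selected probe row).
#' @param feature "gc_percent" or "gene_length".
#' @param only_significant restrict to genes with q < `q_threshold`.
#' @param q_threshold FDR threshold (default 0.05).
#' @param log optional provenance log.
#' @return object of class `feature_correlation`: `feature`, `n`, `r`,
#'   `pvalue`.
#' @export
feature_correlation <- function(gene_results, annotation,
                                feature = c("gc_percent", "gene_length"),
                                only_significant = TRUE, q_threshold = 0.05,
                                log = NULL) {
  feature <- match.arg(feature)
  gr <- gene_results
  if (only_significant) gr <- gr[gr$q < q_threshold, , drop = FALSE]
  fv <- annotation[[feature]][match(gr$selected_probe_id, annotation$probe_id)]
  keep <- is.finite(gr$h2) & is.finite(fv)
  n_dropped <- sum(!keep)
  log_line(log, "correlation(", feature, "): ", n_dropped,
           " gene(s) without feature data dropped; n = ", sum(keep))
  h2 <- gr$h2[keep]
  fv <- fv[keep]
  if (length(h2) < 3L)
    stop("need at least 3 genes with both h2 and ", feature, call. = FALSE)
  if (stats::sd(h2) == 0 || stats::sd(fv) == 0)
    stop("zero variance in h2 or ", feature, call. = FALSE)
  ct <- stats::cor.test(h2, fv, method = "pearson")
  structure(list(feature = feature, n = length(h2),
                 r = unname(ct$estimate), pvalue = ct$p.value),
            class = "feature_correlation")
}

#' @export
print.feature_correlation <- function(x, ...) {
  cat(sprintf("Pearson correlation of h2 with %s: r = %.3f (n = %d, p = %.4g)\n",
              x$feature, x$r, x$n, x$pvalue))
  invisible(x)
}
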