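# Genome-wide scan: run the twin model across all probes, BH-FDR, gene-level
# aggregation by the maximum-probe rule, and chromosome summaries.

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p-values ascending, takes `q_i = min_{j >= i} p_j * m / j`, caps at
#' 1 and restores the input order. Inputs must lie in (0, 1]; exclude
#' missing entries before calling.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop("p-values must all lie in (0, 1]", call. = FALSE)
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  # p * m / j for j = m can round a hair below p; the true q never does
  pmax(q, p)
}

#' Scan configuration
#'
#' @param covariates metadata columns to residualize on.
#' @param detection_filter apply [detection_filter()] (requires a detection
#'   matrix); set FALSE to skip explicitly.
#' @param detection_alpha,detection_min_samples filter parameters.
#' @param int apply the inverse normal transform.
#' @param ci per-probe CI method: "profile", "bootstrap" or "none".
#' @param boot_B bootstrap replicates when `ci = "bootstrap"`.
#' @param q_threshold FDR significance threshold.
#' @param seed RNG seed for optimizer restarts / bootstrap.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(covariates = c("age", "sex", "batch", "rin", "wbc"),
                        detection_filter = TRUE, detection_alpha = 0.05,
                        detection_min_samples = 3L, int = TRUE,
                        ci = c("profile", "bootstrap", "none"),
                        boot_B = 1000L, q_threshold = 0.05, seed = 1L) {
  structure(list(covariates = covariates,
                 detection_filter = detection_filter,
                 detection_alpha = detection_alpha,
                 detection_min_samples = as.integer(detection_min_samples),
                 int = int, ci = match.arg(ci), boot_B = as.integer(boot_B),
                 q_threshold = q_threshold, seed = as.integer(seed)),
            class = "scan_config")
}

#' Per-probe heritability scan
#'
#' For every retained probe: residualize on the covariates, inverse-normal
#' transform, fit the four twin models, select the best by AIC, and test
#' heritability by AE-vs-E. Probe-level q-values are a BH pass over the
#' converged probes' p-values; numerically failed probes are flagged,
#' excluded from the FDR denominator and counted in the log, never fatal.
#'
#' @param bundle a [study_bundle()].
#' @param cfg a [scan_config()].
#' @param log optional provenance log environment.
#' @return data.frame of class `probe_results`: probe_id, gene_symbol,
#'   chromosome, best_model, h2, ci_lo, ci_hi, pvalue, q, converged.
#' @export
scan <- function(bundle, cfg = scan_config(), log = NULL) {
  stopifnot(inherits(bundle, "study_bundle"))
  samples <- bundle$samples
  n_pairs_z <- table(samples$zygosity[!duplicated(samples$pair_id)])
  if (any(!c("MZ", "DZ") %in% names(n_pairs_z)) || any(n_pairs_z < 2L))
    stop("scan requires at least 2 complete pairs per zygosity", call. = FALSE)

  probes <- rownames(bundle$expression)
  if (isTRUE(cfg$detection_filter)) {
    probes <- detection_filter(bundle, cfg$detection_alpha,
                               cfg$detection_min_samples)
    log_line(log, "detection filter: ", length(probes), " of ",
             nrow(bundle$expression), " probes retained")
  }
  design <- covariate_design(samples, cfg$covariates)

  rows <- vector("list", length(probes))
  n_singletons <- NA_integer_
  for (i in seq_along(probes)) {
    pid <- probes[i]
    row <- tryCatch({
      ph <- make_phenotype(bundle$expression[pid, ], samples, design,
                           int = cfg$int)
      n_singletons <- ph$n_singletons
      seed_i <- derive_seed(cfg$seed, pid)
      fits <- fit_all_models(ph$pairs, seed = seed_i)
      sel <- compare_models(fits)
      ht <- heritability_test(
        ph$pairs, ci = if (cfg$ci == "profile") "profile" else "none",
        seed = seed_i, ae_fit = fits$AE, e_fit = fits$E)
      lo <- ht$ci_lo; hi <- ht$ci_hi
      if (cfg$ci == "bootstrap") {
        bs <- bootstrap_ci(ph$pairs, B = cfg$boot_B, seed = seed_i)
        lo <- bs$lo; hi <- bs$hi
      }
      data.frame(probe_id = pid, best_model = sel$best_model, h2 = ht$h2,
                 ci_lo = lo, ci_hi = hi, pvalue = ht$pvalue,
                 converged = ht$converged && all(vapply(fits, function(f)
                   f$converged, logical(1))),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(probe_id = pid, best_model = NA_character_, h2 = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, pvalue = NA_real_,
                 converged = FALSE, stringsAsFactors = FALSE)
    })
    rows[[i]] <- row
  }
  res <- do.call(rbind, rows)

  ok <- res$converged & is.finite(res$pvalue)
  res$q <- NA_real_
  if (any(ok)) res$q[ok] <- bh_adjust(res$pvalue[ok])
  n_failed <- sum(!ok)
  log_line(log, "scan: ", sum(ok), " probes analyzed, ", n_failed,
           " flagged as failed; ", n_singletons, " singleton sample(s) dropped")

  ann <- bundle$annotation
  res$gene_symbol <- ann$gene_symbol[match(res$probe_id, ann$probe_id)]
  res$chromosome <- ann$chromosome[match(res$probe_id, ann$probe_id)]
  res <- res[, c("probe_id", "gene_symbol", "chromosome", "best_model",
                 "h2", "ci_lo", "ci_hi", "pvalue", "q", "converged")]
  class(res) <- c("probe_results", "data.frame")
  res
}

#' Aggregate probe results to genes
#'
#' Gene heritability is the maximum h2 over the gene's probes; the selected
#' probe's p-value carries to the gene, and gene-level q is a fresh BH pass
#' over those per-gene p-values. Ties on h2 resolve to the smaller p-value,
#' then the lexicographically smaller probe id. Non-converged probes are
#' excluded before aggregation.
#'
#' @param probe_results result of [scan()].
#' @param annotation probe annotation table (for ensembl ids); every
#'   converged probe must be present.
#' @param q_threshold FDR threshold used for the `n_significant_probes`
#'   count (default 0.05).
#' @return data.frame of class `gene_results`.
#' @export
aggregate_genes <- function(probe_results, annotation, q_threshold = 0.05) {
  pr <- probe_results[probe_results$converged & is.finite(probe_results$h2) &
                        is.finite(probe_results$pvalue), , drop = FALSE]
  missing <- setdiff(pr$probe_id, annotation$probe_id)
  if (length(missing))
    stop("probe(s) missing from annotation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pr$ensembl_id <- annotation$ensembl_id[match(pr$probe_id,
                                               annotation$probe_id)]
  # deterministic tie-break: max h2, then min p, then probe id
  pr <- pr[order(pr$gene_symbol, -pr$h2, pr$pvalue, pr$probe_id), ,
           drop = FALSE]
  sel <- pr[!duplicated(pr$gene_symbol), , drop = FALSE]
  n_probes <- table(pr$gene_symbol)
  n_sig <- tapply(pr$q < q_threshold, pr$gene_symbol, sum)
  out <- data.frame(
    gene_symbol = sel$gene_symbol,
    ensembl_id = strip_ensembl_version(sel$ensembl_id),
    chromosome = sel$chromosome,
    selected_probe_id = sel$probe_id,
    h2 = sel$h2,
    ci_lo = sel$ci_lo, ci_hi = sel$ci_hi,
    pvalue = sel$pvalue,
    q = bh_adjust(sel$pvalue),
    n_probes = as.integer(n_probes[sel$gene_symbol]),
    n_significant_probes = as.integer(n_sig[sel$gene_symbol]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("gene_results", "data.frame")
  out
}

#' Per-chromosome summary of gene results
#'
#' @param gene_results result of [aggregate_genes()].
#' @param q_threshold FDR threshold defining significance.
#' @return data.frame: chromosome, n_genes, n_significant, proportion,
#'   mean_h2_significant (NA where no gene is significant).
#' @export
chromosome_summary <- function(gene_results, q_threshold = 0.05) {
  sig <- gene_results$q < q_threshold
  chrs <- unique(gene_results$chromosome)
  # natural chromosome order where numeric
  suppressWarnings(num <- as.numeric(chrs))
  chrs <- chrs[order(is.na(num), num, chrs)]
  rows <- lapply(chrs, function(ch) {
    in_ch <- gene_results$chromosome == ch
    n_sig <- sum(sig & in_ch)
    data.frame(
      chromosome = ch,
      n_genes = sum(in_ch),
      n_significant = n_sig,
      proportion = n_sig / sum(in_ch),
      mean_h2_significant = if (n_sig > 0)
        mean(gene_results$h2[sig & in_ch]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
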