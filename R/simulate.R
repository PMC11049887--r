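# Synthetic twin-expression generator with known ground truth, emulating a
# classical same-sex twin design (default 71 MZ + 52 DZ complete pairs).
#
# Per probe, the covariate-free residual for a twin pair is built from
# standard-normal factors: both MZ members receive the identical additive-
# genetic draw A; DZ member 2 receives 0.5*A1 + sqrt(0.75)*A_new so that the
# DZ genetic correlation is exactly 0.5; the shared-environment draw C is
# identical within every pair; E is independent per individual. The
# phenotype is the covariate linear predictor plus
# sqrt(a2)*A + sqrt(c2)*C + sqrt(e2)*E with a2 + c2 + e2 = 1, so the
# expected within-pair residual correlation is a2 + c2 for MZ and
# 0.5*a2 + c2 for DZ.

#' Simulation configuration
#'
#' @param n_mz_pairs,n_dz_pairs numbers of complete MZ and DZ pairs (each
#'   >= 2); defaults are the study design this generator emulates, 71 MZ
#'   and 52 DZ pairs.
#' @param n_probes number of probes to simulate.
#' @param probe_truth data.frame with columns `a2`, `c2`, `e2` (one row per
#'   probe, each row nonnegative and summing to 1), or NULL to draw a
#'   default mixture (half null probes, half with a2 uniform on [0.2, 0.9]).
#' @param covariate_betas data.frame with columns `age`, `sex`, `batch`,
#'   `rin`, `wbc` (one row per probe) of linear covariate coefficients, or
#'   NULL for all zero.
#' @param probes_per_gene probability weights over 1..5 probes per gene.
#' @param age_range two-element numeric, years.
#' @param n_batches number of assay batches (assigned per pair).
#' @param n_undetected_probes number of trailing probes whose detection
#'   p-values are drawn above the detection threshold in every sample, so
#'   the detection filter drops them (their expression is still generated).
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_mz_pairs = 71L, n_dz_pairs = 52L, n_probes = 100L,
                       probe_truth = NULL, covariate_betas = NULL,
                       probes_per_gene = c(0.55, 0.2, 0.12, 0.08, 0.05),
                       age_range = c(69.4, 93.5), n_batches = 3L,
                       n_undetected_probes = 0L, seed = 1L) {
  if (n_mz_pairs < 2L || n_dz_pairs < 2L)
    stop("at least 2 pairs per zygosity are required", call. = FALSE)
  if (!is.null(probe_truth)) {
    probe_truth <- as.data.frame(probe_truth)
    if (!all(c("a2", "c2", "e2") %in% names(probe_truth)))
      stop("probe_truth needs columns a2, c2, e2", call. = FALSE)
    if (nrow(probe_truth) != n_probes)
      stop("probe_truth must have one row per probe", call. = FALSE)
    m <- as.matrix(probe_truth[, c("a2", "c2", "e2")])
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8))
      stop("each probe_truth row must be nonnegative fractions summing to 1",
           call. = FALSE)
  }
  if (!is.null(covariate_betas)) {
    covariate_betas <- as.data.frame(covariate_betas)
    if (nrow(covariate_betas) != n_probes)
      stop("covariate_betas must have one row per probe", call. = FALSE)
  }
  if (length(probes_per_gene) != 5L || any(probes_per_gene < 0) ||
      sum(probes_per_gene) <= 0)
    stop("probes_per_gene must be 5 nonnegative weights", call. = FALSE)
  if (n_undetected_probes < 0L || n_undetected_probes > n_probes)
    stop("n_undetected_probes must be in [0, n_probes]", call. = FALSE)
  structure(list(
    n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
    n_probes = as.integer(n_probes), probe_truth = probe_truth,
    covariate_betas = covariate_betas,
    probes_per_gene = probes_per_gene / sum(probes_per_gene),
    age_range = age_range, n_batches = as.integer(n_batches),
    n_undetected_probes = as.integer(n_undetected_probes),
    seed = as.integer(seed)
  ), class = "sim_config")
}

default_probe_truth <- function(n_probes) {
  # half null (pure E), half heritable with a2 uniform on [0.2, 0.9] and a
  # modest shared-environment slice
  n_her <- floor(n_probes / 2)
  a2 <- c(rep(0, n_probes - n_her), stats::runif(n_her, 0.2, 0.9))
  c2 <- c(rep(0, n_probes - n_her), stats::runif(n_her, 0, 0.1))
  c2 <- pmin(c2, 1 - a2)
  data.frame(a2 = a2, c2 = c2, e2 = 1 - a2 - c2)
}

simulate_annotation <- function(n_probes, probes_per_gene) {
  # draw gene sizes from the 1..5 distribution until all probes are covered
  sizes <- integer(0)
  total <- 0L
  while (total < n_probes) {
    s <- sample.int(5L, 1L, prob = probes_per_gene)
    s <- min(s, n_probes - total)
    sizes <- c(sizes, s)
    total <- total + s
  }
  n_genes <- length(sizes)
  gene_idx <- rep(seq_len(n_genes), sizes)
  gene_symbol <- sprintf("GENE%04d", seq_len(n_genes))
  ensembl <- sprintf("ENSG%011d", seq_len(n_genes))
  # a sprinkling of version suffixes, as real Ensembl exports carry
  versioned <- seq_len(n_genes) %% 7L == 0L
  ensembl[versioned] <- paste0(ensembl[versioned], ".",
                               1L + seq_len(sum(versioned)) %% 9L)
  data.frame(
    probe_id = sprintf("PRB%05d", seq_len(n_probes)),
    gene_symbol = gene_symbol[gene_idx],
    ensembl_id = ensembl[gene_idx],
    chromosome = as.character(sample(1:22, n_genes, replace = TRUE))[gene_idx],
    gc_percent = round(stats::runif(n_genes, 35, 65), 2)[gene_idx],
    gene_length = round(stats::rlnorm(n_genes, log(20000), 1))[gene_idx],
    stringsAsFactors = FALSE
  )
}

#' Simulate a twin expression study with known truth
#'
#' Generates a complete study bundle (expression, optional detection
#' p-values, sample metadata, probe annotation) plus the ground-truth table
#' of per-probe variance fractions. Covariates: age is uniform over
#' `age_range` and shared within pair; sex is shared within pair (same-sex
#' design); batch is assigned per pair; RIN and white-blood-cell count vary
#' per individual. Identical `cfg` (including its seed) gives bit-identical
#' output.
#'
#' @param cfg a [sim_config()].
#' @return list with `bundle` (a [study_bundle()]) and `truth` (data.frame
#'   with probe_id, gene_symbol, ensembl_id, a2, c2, e2, h2_true = a2).
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_mz <- cfg$n_mz_pairs
    n_dz <- cfg$n_dz_pairs
    n_pairs <- n_mz + n_dz
    n_samples <- 2L * n_pairs
    n_probes <- cfg$n_probes

    truth <- cfg$probe_truth %||% default_probe_truth(n_probes)
    betas <- cfg$covariate_betas %||%
      data.frame(age = numeric(n_probes), sex = numeric(n_probes),
                 batch = numeric(n_probes), rin = numeric(n_probes),
                 wbc = numeric(n_probes))

    pair_id <- sprintf("PAIR%03d", seq_len(n_pairs))
    zyg <- c(rep("MZ", n_mz), rep("DZ", n_dz))
    samples <- data.frame(
      sample_id = paste0(rep(pair_id, each = 2L), "_", rep(1:2, n_pairs)),
      pair_id = rep(pair_id, each = 2L),
      zygosity = rep(zyg, each = 2L),
      age = rep(round(stats::runif(n_pairs, cfg$age_range[1], cfg$age_range[2]), 1),
                each = 2L),
      sex = rep(sample(c("F", "M"), n_pairs, replace = TRUE, prob = c(0.7, 0.3)),
                each = 2L),
      batch = rep(paste0("B", sample.int(cfg$n_batches, n_pairs, replace = TRUE)),
                  each = 2L),
      rin = round(stats::runif(n_samples, 6, 10), 1),
      wbc = round(stats::rnorm(n_samples, 6.41, 1.66), 2),
      stringsAsFactors = FALSE
    )
    samples$wbc <- pmax(samples$wbc, 1)

    # standard-normal factor draws, one set per probe x pair
    # A: MZ identical; DZ member2 = 0.5*A1 + sqrt(0.75)*Anew
    A1 <- matrix(stats::rnorm(n_probes * n_pairs), n_probes, n_pairs)
    Anew <- matrix(stats::rnorm(n_probes * n_pairs), n_probes, n_pairs)
    C <- matrix(stats::rnorm(n_probes * n_pairs), n_probes, n_pairs)
    E1 <- matrix(stats::rnorm(n_probes * n_pairs), n_probes, n_pairs)
    E2 <- matrix(stats::rnorm(n_probes * n_pairs), n_probes, n_pairs)

    is_dz <- rep(c(FALSE, TRUE), c(n_mz, n_dz))
    A2 <- A1
    A2[, is_dz] <- 0.5 * A1[, is_dz] + sqrt(0.75) * Anew[, is_dz]

    sa <- sqrt(truth$a2); sc <- sqrt(truth$c2); se <- sqrt(truth$e2)
    R1 <- sa * A1 + sc * C + se * E1
    R2 <- sa * A2 + sc * C + se * E2

    # covariate linear predictor per sample (sex F=0/M=1; batch as its
    # 1-based index, a crude ordinal effect that the dummy-coded
    # residualization still removes exactly when n_batches <= 2, and
    # approximately otherwise -- betas default to zero)
    X <- cbind(age = samples$age,
               sex = as.numeric(samples$sex == "M"),
               batch = as.numeric(sub("^B", "", samples$batch)),
               rin = samples$rin,
               wbc = samples$wbc)
    L <- as.matrix(betas[, c("age", "sex", "batch", "rin", "wbc")]) %*% t(X)

    expr <- matrix(NA_real_, n_probes, n_samples)
    odd <- seq(1L, n_samples, by = 2L)
    expr[, odd] <- R1
    expr[, odd + 1L] <- R2
    expr <- expr + L

    annotation <- simulate_annotation(n_probes, cfg$probes_per_gene)
    rownames(expr) <- annotation$probe_id
    colnames(expr) <- samples$sample_id

    detection <- NULL
    if (cfg$n_undetected_probes > 0L) {
      detection <- matrix(stats::runif(n_probes * n_samples, 0, 0.04),
                          n_probes, n_samples,
                          dimnames = dimnames(expr))
      dead <- seq.int(n_probes - cfg$n_undetected_probes + 1L, n_probes)
      detection[dead, ] <- stats::runif(length(dead) * n_samples, 0.05, 1)
    }

    truth_table <- data.frame(
      probe_id = annotation$probe_id,
      gene_symbol = annotation$gene_symbol,
      ensembl_id = annotation$ensembl_id,
      a2 = truth$a2, c2 = truth$c2, e2 = truth$e2,
      h2_true = truth$a2,
      stringsAsFactors = FALSE
    )

    list(bundle = study_bundle(expr, samples, annotation, detection),
         truth = truth_table)
  })
}

#' Plant a gene list with a target enrichment for heritable genes
#'
#' Draws a gene list in which truly heritable genes (gene-level
#' `h2_true >= h2_threshold`, where gene truth is the max over the gene's
#' probes) are over-represented so that the expected sample odds ratio of
#' (heritable x in-list) equals `target_enrichment`. With
#' `target_enrichment = 1` the list is a uniform draw from all genes.
#'
#' @param truth a truth table from [simulate_study()].
#' @param list_size number of genes in the list.
#' @param target_enrichment target odds ratio (>= 1).
#' @param seed RNG seed.
#' @param h2_threshold truth threshold defining "heritable" (default 0.3).
#' @return character vector of gene symbols.
#' @export
plant_gene_lists <- function(truth, list_size, target_enrichment, seed = 1L,
                             h2_threshold = 0.3) {
  if (target_enrichment < 1)
    stop("target_enrichment must be >= 1", call. = FALSE)
  gene_h2 <- tapply(truth$h2_true, truth$gene_symbol, max)
  genes <- names(gene_h2)
  n <- length(genes)
  if (list_size >= n)
    stop("list_size must be smaller than the number of genes (",
         n, "): no enrichment is possible", call. = FALSE)
  her <- genes[gene_h2 >= h2_threshold]
  non <- setdiff(genes, her)
  H <- length(her)
  with_seed(seed, {
    if (target_enrichment == 1) {
      sample(genes, list_size)
    } else {
      if (H == 0L)
        stop("no truly heritable genes at threshold ", h2_threshold,
             call. = FALSE)
      # solve OR(x) = rho for x heritable genes in the list:
      # rho * (L - x) * (H - x) = x * (N - H - L + x)
      rho <- target_enrichment
      L <- list_size
      A <- rho - 1
      B <- -(rho * (L + H) + (n - H - L))
      Cc <- rho * L * H
      x <- round((-B - sqrt(B^2 - 4 * A * Cc)) / (2 * A))
      if (!is.finite(x) || x < 0 || x > min(L, H) || (L - x) > length(non))
        stop("target enrichment ", rho, " is infeasible for list_size ", L,
             " with ", H, " heritable genes of ", n, call. = FALSE)
      c(sample(her, x), sample(non, L - x))
    }
  })
}
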