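# Probe filtering, covariate residualization, and the rank-based inverse
# normal transform that produces the phenotype analyzed by the twin model.

#' Detection filter
#'
#' A probe is retained when its detection p-value is strictly below `alpha`
#' in at least `min_samples` samples, the usual "expressed in >= k samples"
#' microarray rule. A sample at exactly `alpha` does not count.
#'
#' @param bundle a [study_bundle()] with a detection matrix.
#' @param alpha detection p-value threshold (default 0.05, strict `<`).
#' @param min_samples minimum number of detected samples (default 3).
#' @return character vector of retained probe ids.
#' @export
detection_filter <- function(bundle, alpha = 0.05, min_samples = 3L) {
  stopifnot(inherits(bundle, "study_bundle"))
  if (is.null(bundle$detection))
    stop("bundle has no detection matrix; pass detection_filter = FALSE to scan() ",
         "to skip this filter explicitly", call. = FALSE)
  n_detected <- rowSums(bundle$detection < alpha)
  rownames(bundle$detection)[n_detected >= min_samples]
}

#' Ordinary least-squares residualization
#'
#' Residuals of `y` on the given covariate columns plus an always-included
#' intercept, pooled across all individuals (within-pair dependence is
#' handled downstream by the twin covariance model, not here).
#'
#' @param y numeric response vector.
#' @param covariates numeric matrix or data.frame of design columns (may
#'   have zero columns for intercept-only), rows aligned to `y`.
#' @return numeric residual vector, orthogonal to every design column.
#' @export
residualize <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  X <- if (is.null(covariates) || NCOL(covariates) == 0L) {
    matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n)
      stop("covariate rows must align with y", call. = FALSE)
    cbind("(Intercept)" = 1, cv)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  as.numeric(qr.resid(qr_x, y))
}

#' Build a covariate design matrix from sample metadata
#'
#' Sex is coded 0/1 (F = 0); batch is expanded to treatment-coded dummy
#' columns dropping the first level; age, rin and wbc enter linearly.
#' Single-level factors contribute no columns rather than a constant one.
#'
#' @param samples sample table from a [study_bundle()].
#' @param covariates character vector of metadata columns to use.
#' @return numeric design matrix (no intercept; [residualize()] adds it).
#' @export
covariate_design <- function(samples,
                             covariates = c("age", "sex", "batch", "rin", "wbc")) {
  cols <- list()
  for (cv in covariates) {
    if (!cv %in% names(samples))
      stop("unknown covariate: ", cv, call. = FALSE)
    x <- samples[[cv]]
    if (cv %in% c("sex", "batch") || is.character(x) || is.factor(x)) {
      f <- factor(x)
      if (nlevels(f) > 1L) {
        d <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
        colnames(d) <- paste0(cv, levels(f)[-1L])
        cols[[cv]] <- d
      }
    } else {
      cols[[cv]] <- matrix(as.numeric(x), ncol = 1L,
                           dimnames = list(NULL, cv))
    }
  }
  if (!length(cols)) return(matrix(numeric(0), nrow(samples), 0L))
  do.call(cbind, unname(cols))
}

#' Rank-based inverse normal transform
#'
#' Blom-offset transform `qnorm((rank - 3/8) / (n + 1/4))` with average
#' ranks for ties: order-preserving, approximately standard normal, the
#' marginal the Gaussian twin likelihood assumes.
#'
#' @param v numeric vector, length >= 3, not all values identical.
#' @param offset rank offset (default 3/8).
#' @return transformed numeric vector.
#' @export
rank_inverse_normal <- function(v, offset = 3 / 8) {
  v <- as.numeric(v)
  n <- length(v)
  if (n < 3L) stop("need at least 3 values", call. = FALSE)
  if (any(!is.finite(v))) stop("values must be finite", call. = FALSE)
  if (length(unique(v)) == 1L)
    stop("all values identical: no ordering information to transform",
         call. = FALSE)
  r <- rank(v, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Assemble the per-probe twin phenotype
#'
#' Residualizes one probe's expression on the covariate design, applies the
#' inverse normal transform, and splits the result into complete MZ/DZ
#' pairs. Samples whose co-twin is absent (singletons) are dropped.
#'
#' @param y per-sample expression values aligned to `samples` rows.
#' @param samples sample table.
#' @param design covariate design from [covariate_design()] (NULL for
#'   intercept-only).
#' @param int apply the inverse normal transform (default TRUE).
#' @return list with `pairs` (a [twin_pairs()]), `phenotype` (transformed
#'   per-sample values) and `n_singletons`.
#' @export
make_phenotype <- function(y, samples, design = NULL, int = TRUE) {
  res <- residualize(y, design)
  ph <- if (int) rank_inverse_normal(res) else res
  split_pairs(ph, samples)
}

split_pairs <- function(ph, samples) {
  idx <- split(seq_along(ph), samples$pair_id)
  complete <- vapply(idx, length, integer(1)) == 2L
  n_singletons <- sum(!complete)
  idx <- idx[complete]
  zyg <- vapply(idx, function(i) samples$zygosity[i[1L]], character(1))
  pick <- function(z) {
    if (!any(zyg == z)) return(matrix(numeric(0), 0L, 2L))
    t(vapply(idx[zyg == z], function(i) ph[i], numeric(2)))
  }
  list(pairs = twin_pairs(pick("MZ"), pick("DZ")),
       phenotype = ph, n_singletons = n_singletons)
}
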