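# Classical-twin variance-components model: bivariate-normal likelihood of
# MZ/DZ pairs under ACE and its sub-models, ML fitting, model comparison,
# the AE-vs-E heritability test, and profile-likelihood / bootstrap CIs.
#
# For a pair (y1, y2) with common mean mu the model covariance is
#   Sigma_MZ = [[v, a2 + c2], [a2 + c2, v]]
#   Sigma_DZ = [[v, a2/2 + c2], [a2/2 + c2, v]]     v = a2 + c2 + e2
# because MZ co-twins share all additive-genetic variation and DZ co-twins
# half of it, while the shared environment C is common to both members.

#' Construct a twin pair set
#'
#' Bundles complete MZ and DZ phenotype pairs, the unit of likelihood
#' evaluation for the twin model. Pairs with missing or non-finite values
#' are rejected; order of members within a pair is irrelevant
#' (exchangeability).
#'
#' @param mz two-column numeric matrix (or data.frame) of MZ pair values.
#' @param dz two-column numeric matrix (or data.frame) of DZ pair values.
#' @return an object of class `twin_pairs`.
#' @export
twin_pairs <- function(mz, dz) {
  as_pair_mat <- function(x, lab) {
    x <- as.matrix(x)
    if (ncol(x) != 2L)
      stop(lab, " pairs must have exactly two columns", call. = FALSE)
    storage.mode(x) <- "double"
    if (any(!is.finite(x)))
      stop(lab, " pairs contain non-finite values; only complete pairs are allowed",
           call. = FALSE)
    x
  }
  mz <- as_pair_mat(mz, "MZ")
  dz <- as_pair_mat(dz, "DZ")
  if (nrow(mz) < 2L || nrow(dz) < 2L)
    stop("at least 2 complete pairs per zygosity are required", call. = FALSE)
  structure(list(mz = mz, dz = dz), class = "twin_pairs")
}

#' @export
print.twin_pairs <- function(x, ...) {
  cat("Twin pair set:", nrow(x$mz), "MZ and", nrow(x$dz), "DZ pairs\n")
  invisible(x)
}

#' Variance components of the twin model
#'
#' @param a2,c2,e2 additive-genetic, shared-environment and unique-environment
#'   variances (not fractions); all must be >= 0 and `e2 > 0` at any
#'   likelihood evaluation.
#' @param mu common mean across twin order and zygosity.
#' @return an object of class `variance_components` with an `h2` field,
#'   `a2 / (a2 + c2 + e2)`.
#' @export
variance_components <- function(a2, c2, e2, mu = 0) {
  if (any(c(a2, c2, e2) < 0))
    stop("variance components must be nonnegative", call. = FALSE)
  v <- a2 + c2 + e2
  structure(list(a2 = a2, c2 = c2, e2 = e2, mu = mu,
                 total = v, h2 = if (v > 0) a2 / v else NA_real_),
            class = "variance_components")
}

model_free_params <- c(ACE = 4L, AE = 3L, CE = 3L, E = 2L)

# Sufficient statistics: the likelihood depends on the data only through
# per-zygosity pair counts, sums, sums of squares and cross-products, which
# makes each objective evaluation O(1) regardless of sample size.
pair_stats <- function(pairs) {
  one <- function(m) {
    list(n = nrow(m), s1 = sum(m), ss = sum(m^2), sp = sum(m[, 1] * m[, 2]))
  }
  list(mz = one(pairs$mz), dz = one(pairs$dz))
}

# Negative log-likelihood from sufficient statistics. cov_mz = a2 + c2,
# cov_dz = a2/2 + c2, v = a2 + c2 + e2. Returns +Inf for non-PD Sigma so
# optimizers can probe the boundary safely.
negloglik_stats <- function(st, v, cov_mz, cov_dz, mu) {
  total <- 0
  for (z in c("mz", "dz")) {
    s <- st[[z]]
    cv <- if (z == "mz") cov_mz else cov_dz
    det2 <- v * v - cv * cv
    if (!is.finite(det2) || det2 <= 0 || v <= 0) return(Inf)
    # centered sums: S2 = sum(d1^2 + d2^2), S11 = sum(d1 * d2)
    S2 <- s$ss - 2 * mu * s$s1 + 2 * s$n * mu^2
    S11 <- s$sp - mu * s$s1 + s$n * mu^2
    total <- total + s$n * log(2 * pi) + s$n * 0.5 * log(det2) +
      0.5 * (v * S2 - 2 * cv * S11) / det2
  }
  total
}

#' Negative log-likelihood of a twin pair set
#'
#' Sum over all pairs of the bivariate-normal negative log-density with
#' common mean and the zygosity-specific exchangeable covariance implied by
#' the variance components.
#'
#' @param pairs a [twin_pairs()] object.
#' @param vc a [variance_components()] object.
#' @param model one of "ACE", "AE", "CE", "E"; components the model fixes at
#'   zero must be zero in `vc`.
#' @return total negative log-likelihood; `Inf` when the implied covariance
#'   is not positive definite (never an error, so optimizers can probe the
#'   boundary).
#' @export
pair_negloglik <- function(pairs, vc, model = c("ACE", "AE", "CE", "E")) {
  model <- match.arg(model)
  stopifnot(inherits(pairs, "twin_pairs"), inherits(vc, "variance_components"))
  fixed_zero <- switch(model, ACE = character(0), AE = "c2", CE = "a2",
                       E = c("a2", "c2"))
  for (f in fixed_zero)
    if (vc[[f]] != 0)
      stop("model ", model, " requires ", f, " = 0", call. = FALSE)
  st <- pair_stats(pairs)
  negloglik_stats(st, v = vc$a2 + vc$c2 + vc$e2,
                  cov_mz = vc$a2 + vc$c2, cov_dz = 0.5 * vc$a2 + vc$c2,
                  mu = vc$mu)
}

# Data fingerprint so compare_models can verify all fits share one dataset.
pairs_fingerprint <- function(pairs) {
  st <- pair_stats(pairs)
  format_hash(paste(unlist(st), collapse = ","))
}

# Closed-form ML fit of the E model: all 2n values i.i.d. N(mu, e2).
fit_E <- function(pairs, st) {
  n_tot <- 2 * (st$mz$n + st$dz$n)
  mu <- (st$mz$s1 + st$dz$s1) / n_tot
  e2 <- (st$mz$ss + st$dz$ss) / n_tot - mu^2
  if (e2 <= 0) e2 <- .Machine$double.eps
  ll <- -negloglik_stats(st, v = e2, cov_mz = 0, cov_dz = 0, mu = mu)
  list(a2 = 0, c2 = 0, e2 = e2, mu = mu, loglik = ll, converged = TRUE)
}

# Closed-form ML mean given the covariance parameters: setting the mu score
# to zero gives a precision-weighted mean across zygosity groups,
#   mu_hat = sum_z s1_z / (v + cov_z)  /  sum_z 2 n_z / (v + cov_z).
profile_mu <- function(st, v, cov_mz, cov_dz) {
  num <- st$mz$s1 / (v + cov_mz) + st$dz$s1 / (v + cov_dz)
  den <- 2 * st$mz$n / (v + cov_mz) + 2 * st$dz$n / (v + cov_dz)
  num / den
}

# Moment summaries used to seed the optimizer.
moment_start <- function(st) {
  n_tot <- 2 * (st$mz$n + st$dz$n)
  mu <- (st$mz$s1 + st$dz$s1) / n_tot
  v <- max((st$mz$ss + st$dz$ss) / n_tot - mu^2, .Machine$double.eps)
  r_z <- function(s) {
    # within-pair correlation of centered values
    num <- s$sp / s$n - (s$s1 / (2 * s$n))^2
    den <- s$ss / (2 * s$n) - (s$s1 / (2 * s$n))^2
    if (den <= 0) 0 else max(min(num / den, 0.99), -0.99)
  }
  list(mu = mu, v = v, r_mz = r_z(st$mz), r_dz = r_z(st$dz))
}

#' Fit one twin model by maximum likelihood
#'
#' Optimizes unconstrained path coefficients (a, c, e) whose squares are the
#' variances, with the common mean profiled out in closed form at every
#' objective evaluation, and multiple starts: five fixed dispersed points
#' (including a Falconer-style moment start) plus three seeded random
#' points. The E model has a closed-form ML solution and is computed
#' directly.
#'
#' @param pairs a [twin_pairs()] object.
#' @param model one of "ACE", "AE", "CE", "E".
#' @param seed seed for the random restarts (default 1); fits are
#'   deterministic given `(pairs, model, seed)`.
#' @param extra_starts optional list of additional numeric start vectors
#'   `c(a2, c2, e2)` (used internally by the bootstrap for warm starts).
#' @param light if TRUE use only the moment start plus `extra_starts`
#'   (bootstrap refits); the converged optimum is indistinguishable in
#'   practice and an order of magnitude cheaper.
#' @return an object of class `twin_fit`: fields `model`, `components`
#'   ([variance_components()]), `loglik`, `n_free`, `aic`, `converged`,
#'   `fingerprint`.
#' @export
fit_model <- function(pairs, model = c("ACE", "AE", "CE", "E"), seed = 1L,
                      extra_starts = NULL, light = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(pairs, "twin_pairs"))
  st <- pair_stats(pairs)

  if (model == "E") {
    f <- fit_E(pairs, st)
    return(new_twin_fit(model, f, pairs))
  }

  ms <- moment_start(st)
  # Falconer moment decomposition, clipped into the admissible cone
  a2_f <- max(min(2 * (ms$r_mz - ms$r_dz), 1), 0)
  c2_f <- max(min(2 * ms$r_dz - ms$r_mz, 1 - a2_f), 0)
  e2_f <- max(1 - a2_f - c2_f, 0.05)
  fracs <- rbind(c(a2_f, c2_f, e2_f))
  if (!light) {
    fracs <- rbind(
      fracs,
      c(1 / 3, 1 / 3, 1 / 3),
      c(0.6, 0.2, 0.2),
      c(0.2, 0.6, 0.2),
      c(0.05, 0.05, 0.9),
      with_seed(derive_seed(seed, paste0("fit:", model)), {
        m <- matrix(stats::rexp(9L), ncol = 3L)
        m / rowSums(m)
      })
    )
  }

  free <- switch(model, ACE = c("a", "c", "e"), AE = c("a", "e"), CE = c("c", "e"))
  obj <- function(theta) {
    a2 <- if ("a" %in% free) theta[[match("a", free)]]^2 else 0
    c2 <- if ("c" %in% free) theta[[match("c", free)]]^2 else 0
    e2 <- theta[[length(free)]]^2
    v <- a2 + c2 + e2
    cmz <- a2 + c2
    cdz <- 0.5 * a2 + c2
    if (v <= 0 || e2 <= 0) return(Inf)
    mu <- profile_mu(st, v, cmz, cdz)
    negloglik_stats(st, v = v, cov_mz = cmz, cov_dz = cdz, mu = mu)
  }

  idx <- match(free, c("a", "c", "e"))
  starts <- lapply(seq_len(nrow(fracs)), function(i) {
    comp <- fracs[i, ] * ms$v
    comp[3] <- max(comp[3], 1e-6 * ms$v)
    sqrt(comp[idx])
  })
  for (es in extra_starts %||% list()) {
    comp <- pmax(es[1:3], c(0, 0, 1e-8))
    starts <- c(starts, list(sqrt(comp[idx])))
  }

  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 2000L)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    any_conv <- any_conv || opt$convergence == 0L
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("all optimizer starts failed for model ", model, call. = FALSE)
  # polish the winner once more from its own optimum
  opt2 <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 2000L))
  if (is.finite(opt2$value) && opt2$value <= best$value) best <- opt2

  theta <- best$par
  a2 <- if ("a" %in% free) theta[[match("a", free)]]^2 else 0
  c2 <- if ("c" %in% free) theta[[match("c", free)]]^2 else 0
  e2 <- theta[[length(free)]]^2
  f <- list(
    a2 = a2, c2 = c2, e2 = e2,
    mu = profile_mu(st, a2 + c2 + e2, a2 + c2, 0.5 * a2 + c2),
    loglik = -best$value,
    converged = any_conv && is.finite(best$value)
  )
  new_twin_fit(model, f, pairs)
}

new_twin_fit <- function(model, f, pairs) {
  k <- model_free_params[[model]]
  structure(list(
    model = model,
    components = variance_components(f$a2, f$c2, f$e2, f$mu),
    loglik = f$loglik,
    n_free = k,
    aic = -2 * f$loglik + 2 * k,
    converged = isTRUE(f$converged),
    fingerprint = pairs_fingerprint(pairs)
  ), class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, ...) {
  vc <- x$components
  cat(sprintf("%s fit: a2=%.4f c2=%.4f e2=%.4f mu=%.4f  logLik=%.4f AIC=%.4f%s\n",
              x$model, vc$a2, vc$c2, vc$e2, vc$mu, x$loglik, x$aic,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' Fit all four twin models
#'
#' @inheritParams fit_model
#' @return named list of [fit_model()] results for ACE, AE, CE and E.
#' @export
fit_all_models <- function(pairs, seed = 1L) {
  fits <- lapply(c("ACE", "AE", "CE", "E"), function(m)
    fit_model(pairs, m, seed = seed))
  names(fits) <- c("ACE", "AE", "CE", "E")
  fits
}

#' Compare the four twin model fits
#'
#' Emits the AIC table and the likelihood-ratio tests between nested models.
#' LRT statistics are clipped at zero; p-values use the central chi-square
#' with df equal to the difference in free parameter counts (the boundary
#' mixture correction is documented but not applied). The best model is the
#' lowest AIC, ties broken toward fewer free parameters.
#'
#' @param fits named list with elements ACE, AE, CE, E from [fit_model()],
#'   all fitted to the same data.
#' @return list with `aic_table` (data.frame), `lrt_table` (data.frame) and
#'   `best_model` (character).
#' @export
compare_models <- function(fits) {
  need <- c("ACE", "AE", "CE", "E")
  if (!all(need %in% names(fits)))
    stop("fits must contain models ", paste(need, collapse = ", "), call. = FALSE)
  fps <- vapply(fits[need], function(f) f$fingerprint, character(1))
  if (length(unique(fps)) != 1L)
    stop("model fits were computed on different data (fingerprint mismatch)",
         call. = FALSE)

  aic_table <- data.frame(
    model = need,
    loglik = vapply(fits[need], function(f) f$loglik, numeric(1)),
    n_free = vapply(fits[need], function(f) f$n_free, integer(1)),
    aic = vapply(fits[need], function(f) f$aic, numeric(1)),
    converged = vapply(fits[need], function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE
  )
  rownames(aic_table) <- NULL

  lrt_one <- function(full, reduced) {
    df <- fits[[full]]$n_free - fits[[reduced]]$n_free
    lambda <- max(0, 2 * (fits[[full]]$loglik - fits[[reduced]]$loglik))
    data.frame(full = full, reduced = reduced, df = df, lambda = lambda,
               pvalue = stats::pchisq(lambda, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  lrt_table <- do.call(rbind, list(
    lrt_one("ACE", "AE"), lrt_one("ACE", "CE"), lrt_one("AE", "E"),
    lrt_one("CE", "E"), lrt_one("ACE", "E")
  ))

  # lowest AIC wins; ties (within 1e-10) resolve toward fewer parameters
  ord <- order(round(aic_table$aic, 10), aic_table$n_free)
  list(aic_table = aic_table, lrt_table = lrt_table,
       best_model = aic_table$model[ord[1L]])
}

# Profile log-likelihood of h2 under the AE model: for fixed h2, maximize
# over total variance v (1-D, with mu profiled in closed form) with
# cov_mz = h2*v, cov_dz = h2*v/2.
profile_loglik_h2 <- function(st, h2, start_v) {
  obj <- function(lv) {
    v <- exp(lv)
    mu <- profile_mu(st, v, h2 * v, 0.5 * h2 * v)
    negloglik_stats(st, v = v, cov_mz = h2 * v, cov_dz = 0.5 * h2 * v, mu = mu)
  }
  opt <- stats::optimize(obj, interval = log(start_v) + c(-6, 6), tol = 1e-10)
  -opt$objective
}

# Profile-likelihood 95% CI for h2 under AE, clipped to [0, 1]. When the
# joint maximum is numerically inconsistent with the profile (near-singular
# fits with e2 ~ 0 spike the likelihood), the threshold is recalibrated
# against the profile's own maximum.
profile_ci_h2 <- function(pairs, ae_fit, level = 0.95) {
  st <- pair_stats(pairs)
  eps <- 1e-6
  v_hat <- ae_fit$components$total
  h0 <- min(max(ae_fit$components$h2, eps), 1 - eps)
  ll_max <- ae_fit$loglik
  half_q <- stats::qchisq(level, 1) / 2
  pr_raw <- function(h2) profile_loglik_h2(st, h2, v_hat)

  if (!is.finite(ll_max) || pr_raw(h0) < ll_max - half_q) {
    opt <- stats::optimize(pr_raw, c(0, 1 - eps), maximum = TRUE, tol = 1e-6)
    if (opt$objective >= pr_raw(h0)) h0 <- opt$maximum
    ll_max <- max(opt$objective, pr_raw(h0))
  }
  pr <- function(h2) pr_raw(h2) - (ll_max - half_q)

  lo <- if (pr(0) >= 0) 0 else
    stats::uniroot(pr, lower = 0, upper = h0, tol = 1e-6)$root
  hi <- if (h0 >= 1 - 2 * eps || pr(1 - eps) >= 0) 1 else
    stats::uniroot(pr, lower = h0, upper = 1 - eps, tol = 1e-6)$root
  # the interval always contains the point estimate
  h2_hat <- ae_fit$components$h2
  c(lo = max(0, min(lo, h2_hat)), hi = min(1, max(hi, h2_hat)))
}

#' Heritability test under the AE model
#'
#' The heritability point estimate is `a2 / (a2 + e2)` from the AE fit; the
#' p-value comes from the AE-vs-E likelihood-ratio statistic referred to a
#' central chi-square with 1 df (clipped at zero at the boundary). The
#' default 95% interval inverts the profile likelihood; [bootstrap_ci()] is
#' the resampling alternative.
#'
#' @param pairs a [twin_pairs()] object.
#' @param ci one of "profile" or "none".
#' @param level confidence level (default 0.95).
#' @param seed optimizer restart seed.
#' @param ae_fit,e_fit optional precomputed [fit_model()] results for the AE
#'   and E models on `pairs` (the genome scan passes these to avoid
#'   refitting).
#' @return object of class `heritability_test`: `h2`, `lambda`, `pvalue`,
#'   `ci_lo`, `ci_hi`, `converged`, plus the underlying `ae_fit` and `e_fit`.
#' @export
heritability_test <- function(pairs, ci = c("profile", "none"), level = 0.95,
                              seed = 1L, ae_fit = NULL, e_fit = NULL) {
  ci <- match.arg(ci)
  ae <- ae_fit %||% fit_model(pairs, "AE", seed = seed)
  e <- e_fit %||% fit_model(pairs, "E", seed = seed)
  lambda <- max(0, 2 * (ae$loglik - e$loglik))
  pvalue <- stats::pchisq(lambda, 1, lower.tail = FALSE)
  h2 <- ae$components$h2
  bounds <- if (ci == "profile" && ae$converged)
    profile_ci_h2(pairs, ae, level = level)
  else c(lo = NA_real_, hi = NA_real_)
  structure(list(h2 = h2, lambda = lambda, pvalue = pvalue,
                 ci_lo = unname(bounds["lo"]), ci_hi = unname(bounds["hi"]),
                 converged = ae$converged, ae_fit = ae, e_fit = e),
            class = "heritability_test")
}

#' @export
print.heritability_test <- function(x, ...) {
  cat(sprintf("AE-model heritability: h2=%.3f (95%% CI %.3f-%.3f), LRT=%.3f, p=%.3g\n",
              x$h2, x$ci_lo, x$ci_hi, x$lambda, x$pvalue))
  invisible(x)
}

#' Stratified pair bootstrap confidence interval for heritability
#'
#' Resamples pairs with replacement within each zygosity stratum, refits the
#' AE model on every replicate (warm-started from the full-data MLE), and
#' returns the percentile interval of the replicate h2 values.
#'
#' @param pairs a [twin_pairs()] object.
#' @param B number of bootstrap replicates (>= 100).
#' @param level confidence level.
#' @param seed RNG seed; identical `(pairs, B, level, seed)` gives identical
#'   intervals.
#' @return list with `lo`, `hi`, `h2_boot` (replicate estimates) and
#'   `n_failed`.
#' @export
bootstrap_ci <- function(pairs, B = 1000L, level = 0.95, seed = 1L) {
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  full <- fit_model(pairs, "AE", seed = seed)
  warm <- with(full$components, c(a2, c2, e2))
  n_mz <- nrow(pairs$mz)
  n_dz <- nrow(pairs$dz)
  h2_boot <- rep(NA_real_, B)
  with_seed(derive_seed(seed, "bootstrap"), {
    for (b in seq_len(B)) {
      bp <- structure(list(
        mz = pairs$mz[sample.int(n_mz, n_mz, replace = TRUE), , drop = FALSE],
        dz = pairs$dz[sample.int(n_dz, n_dz, replace = TRUE), , drop = FALSE]
      ), class = "twin_pairs")
      fit <- tryCatch(
        fit_model(bp, "AE", seed = seed, extra_starts = list(warm),
                  light = TRUE),
        error = function(e) NULL)
      if (!is.null(fit) && fit$converged) h2_boot[b] <- fit$components$h2
    }
  })
  n_failed <- sum(is.na(h2_boot))
  if (n_failed > 0.1 * B)
    stop(sprintf("%d of %d bootstrap replicates failed to converge; increase B or flag this probe",
                 n_failed, B), call. = FALSE)
  alpha <- (1 - level) / 2
  qs <- stats::quantile(h2_boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(lo = max(0, min(qs[1L], 1)), hi = max(0, min(qs[2L], 1)),
       h2_boot = h2_boot, n_failed = n_failed)
}
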