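test_that("pair_negloglik matches closed forms and the generic MVN oracle", {
  # one MZ pair y=(0,0), identity covariance -> log(2*pi)
  p1 <- structure(list(mz = rbind(c(0, 0)), dz = matrix(numeric(0), 0, 2)),
                  class = "twin_pairs")
  vc <- variance_components(0, 0, 1, mu = 0)
  expect_equal(pair_negloglik(p1, vc, "E"), log(2 * pi), tolerance = 1e-12)
  # y=(1,1): adds the quadratic form 1
  p2 <- structure(list(mz = rbind(c(1, 1)), dz = matrix(numeric(0), 0, 2)),
                  class = "twin_pairs")
  expect_equal(pair_negloglik(p2, vc, "E"), log(2 * pi) + 1,
               tolerance = 1e-12)

  # 1000 random configurations against the generic MVN density oracle
  set.seed(2024)
  worst <- 0
  for (i in 1:1000) {
    n_mz <- sample(2:6, 1); n_dz <- sample(2:6, 1)
    pr <- twin_pairs(matrix(rnorm(2 * n_mz), ncol = 2),
                     matrix(rnorm(2 * n_dz), ncol = 2))
    a2 <- runif(1, 0, 2); c2 <- runif(1, 0, 2); e2 <- runif(1, 0.05, 2)
    mu <- rnorm(1)
    ours <- pair_negloglik(pr, variance_components(a2, c2, e2, mu), "ACE")
    oracle <- mvn_negloglik_oracle(pr, a2, c2, e2, mu)
    worst <- max(worst, abs(ours - oracle))
  }
  expect_lt(worst, 1e-10)

  # model/vc consistency and PD failure behavior
  expect_error(pair_negloglik(p1, variance_components(0.5, 0, 0.5), "E"),
               "requires")
  expect_equal(pair_negloglik(p1, variance_components(1, 0, 0), "AE"), Inf)
})

test_that("E-model fit equals the i.i.d. normal closed form", {
  # pooled values are {1,2,3,4} twice: ML mean 2.5, ML variance 1.25
  pr <- twin_pairs(rbind(c(1, 2), c(3, 4)), rbind(c(1, 3), c(2, 4)))
  f <- fit_model(pr, "E")
  expect_equal(f$components$mu, 2.5, tolerance = 1e-12)
  expect_equal(f$components$e2, 1.25, tolerance = 1e-12)
  expect_equal(f$loglik, 2 * sum(dnorm(1:4, 2.5, sqrt(1.25), log = TRUE)),
               tolerance = 1e-10)
  expect_equal(f$aic, -2 * f$loglik + 4)
})

test_that("fit_model matches a grid-search oracle on small instances", {
  set.seed(33)
  for (rep in 1:3) {
    pr <- twin_pairs(matrix(rnorm(8, sd = 1.2), ncol = 2),
                     matrix(rnorm(8, sd = 1.2), ncol = 2))
    for (model in c("ACE", "AE")) {
      fit <- fit_model(pr, model)
      oracle <- grid_fit_oracle(pr, model)
      # optimizer must be at least as good as the refined grid, within 1e-4
      expect_lt(-fit$loglik, oracle$negloglik + 1e-4)
    }
  }
})

test_that("fit_model recovers simulated variance components", {
  pr <- sim_pairs(0.6, 0, n_mz = 2000, n_dz = 2000, seed = 5)
  fit <- fit_model(pr, "AE")
  expect_true(fit$converged)
  expect_lt(abs(fit$components$a2 - 0.6), 0.05)
  expect_lt(abs(fit$components$e2 - 0.4), 0.05)
})

test_that("likelihood nesting and invariance properties hold", {
  set.seed(12)
  for (i in 1:5) {
    pr <- sim_pairs(runif(1, 0, 0.8), runif(1, 0, 0.15), n_mz = 40,
                    n_dz = 30, seed = 100 + i)
    fits <- fit_all_models(pr)
    ll <- vapply(fits, function(f) f$loglik, numeric(1))
    expect_gte(ll["ACE"], max(ll["AE"], ll["CE"]) - 1e-6)
    expect_gte(min(ll["AE"], ll["CE"]), ll["E"] - 1e-6)

    # location-scale invariance of h2
    fit0 <- fits$AE
    shifted <- structure(list(mz = pr$mz * 3.7 + 11, dz = pr$dz * 3.7 + 11),
                         class = "twin_pairs")
    fit1 <- fit_model(shifted, "AE")
    expect_equal(fit1$components$h2, fit0$components$h2, tolerance = 1e-4)

    # exchangeability: swapping members within every pair changes nothing
    swapped <- structure(list(mz = pr$mz[, 2:1], dz = pr$dz[, 2:1]),
                         class = "twin_pairs")
    fit2 <- fit_model(swapped, "AE")
    expect_equal(fit2$loglik, fit0$loglik, tolerance = 1e-8)
    expect_equal(fit2$components$h2, fit0$components$h2, tolerance = 1e-6)
  }
})

test_that("compare_models applies the AIC definition and tie-break", {
  pr <- sim_pairs(0.4, 0, seed = 42)
  fits <- fit_all_models(pr)
  # hand-set logliks: AIC (208, 208, 212, 224); tie resolves to AE
  hand <- fits
  lls <- c(ACE = -100, AE = -101, CE = -103, E = -110)
  for (m in names(lls)) {
    hand[[m]]$loglik <- lls[[m]]
    hand[[m]]$aic <- -2 * lls[[m]] + 2 * hand[[m]]$n_free
  }
  sel <- compare_models(hand)
  expect_equal(sel$aic_table$aic, c(208, 208, 212, 224))
  expect_equal(sel$best_model, "AE")
  lrt <- sel$lrt_table
  expect_equal(lrt$lambda[lrt$full == "ACE" & lrt$reduced == "AE"], 2)
  expect_equal(lrt$df[lrt$full == "ACE" & lrt$reduced == "E"], 2)
  # nested boundary case: loglik(ACE) == loglik(AE) -> lambda 0, p 1,
  # AE preferred (AIC lower by 2)
  eq <- fits
  eq$ACE$loglik <- eq$AE$loglik
  eq$ACE$aic <- -2 * eq$ACE$loglik + 2 * eq$ACE$n_free
  sel2 <- compare_models(eq)
  lrt2 <- sel2$lrt_table
  expect_equal(lrt2$lambda[lrt2$full == "ACE" & lrt2$reduced == "AE"], 0)
  expect_equal(lrt2$pvalue[lrt2$full == "ACE" & lrt2$reduced == "AE"], 1)
  expect_equal(eq$AE$aic, eq$ACE$aic - 2)
  # mismatched data is a hard error
  other <- fit_all_models(sim_pairs(0.4, 0, seed = 43))
  bad <- fits; bad$AE <- other$AE
  expect_error(compare_models(bad), "fingerprint")
})

test_that("heritability_test behaves at the limits", {
  # all MZ pairs identical within pair, DZ correlation ~ 0.5 -> h2 -> 1
  set.seed(8)
  mzv <- rnorm(60)
  mz <- cbind(mzv, mzv)
  g <- rnorm(60); e <- rnorm(60)
  dz <- cbind(sqrt(0.5) * g + sqrt(0.5) * e,
              sqrt(0.5) * (0.5 * g + sqrt(0.75) * rnorm(60)) +
                sqrt(0.5) * rnorm(60))
  ht <- heritability_test(twin_pairs(mz, dz))
  expect_gt(ht$h2, 0.95)
  expect_lt(ht$pvalue, 1e-10)
  expect_true(ht$ci_lo <= ht$h2 && ht$h2 <= ht$ci_hi)
  expect_true(ht$ci_lo >= 0 && ht$ci_hi <= 1)

  # null data: small h2, p typically large
  ht0 <- heritability_test(sim_pairs(0, 0, seed = 19))
  expect_lt(ht0$h2, 0.35)
  expect_gt(ht0$pvalue, 0.01)
  expect_gte(ht0$lambda, 0)
})

test_that("bootstrap_ci is deterministic and brackets the estimate", {
  pr <- sim_pairs(0.6, 0, n_mz = 100, n_dz = 80, seed = 31)
  b1 <- bootstrap_ci(pr, B = 200, seed = 9)
  b2 <- bootstrap_ci(pr, B = 200, seed = 9)
  expect_identical(b1[c("lo", "hi")], b2[c("lo", "hi")])
  expect_lte(b1$lo, median(b1$h2_boot))
  expect_lte(median(b1$h2_boot), b1$hi)
  expect_error(bootstrap_ci(pr, B = 50), "at least 100")

  # degenerate near-perfect MZ duplication: interval concentrated near 1
  set.seed(77)
  mzv <- rnorm(80)
  mz <- cbind(mzv, mzv + rnorm(80, sd = 0.02))
  g <- rnorm(80)
  dz <- cbind(0.7 * g + 0.7 * rnorm(80),
              0.7 * (0.5 * g + sqrt(0.75) * rnorm(80)) + 0.7 * rnorm(80))
  bd <- bootstrap_ci(twin_pairs(mz, dz), B = 200, seed = 4)
  expect_gt(bd$lo, 0.9)
})
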