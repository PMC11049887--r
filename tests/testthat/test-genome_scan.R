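test_that("bh_adjust matches the step-up definition and oracles", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  # brute-force oracle and stats::p.adjust on random inputs
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    p[p == 0] <- 1e-12
    q <- bh_adjust(p)
    expect_lt(max(abs(q - bh_oracle(p))), 1e-12)
    expect_lt(max(abs(q - p.adjust(p, "BH"))), 1e-12)
    # monotone in p
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
    expect_true(all(q >= p) && all(q <= 1))
  }
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.1, NA)), "0, 1")
})

make_probe_results <- function(df) {
  df$converged <- df$converged %||% TRUE
  df$ci_lo <- df$ci_lo %||% NA_real_
  df$ci_hi <- df$ci_hi %||% NA_real_
  df$chromosome <- df$chromosome %||% "1"
  df$q <- bh_adjust(df$pvalue)
  class(df) <- c("probe_results", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("aggregate_genes applies the max-probe rule with tie-breaks", {
  ann <- data.frame(
    probe_id = c("P1", "P2", "P3", "P4", "P5"),
    gene_symbol = c("G1", "G1", "G2", "G3", "G3"),
    ensembl_id = c("ENSG1.2", "ENSG1.2", "ENSG2", "ENSG3", "ENSG3"),
    chromosome = c("1", "1", "2", "2", "2"),
    gc_percent = 50, gene_length = 1000, stringsAsFactors = FALSE)
  pr <- make_probe_results(data.frame(
    probe_id = c("P1", "P2", "P3", "P4", "P5"),
    gene_symbol = c("G1", "G1", "G2", "G3", "G3"),
    h2 = c(0.3, 0.5, 0.7, 0.4, 0.4),
    pvalue = c(0.2, 0.01, 0.001, 0.06, 0.04),
    stringsAsFactors = FALSE))
  gr <- aggregate_genes(pr, ann)
  expect_equal(nrow(gr), 3L)
  g1 <- gr[gr$gene_symbol == "G1", ]
  expect_equal(g1$h2, 0.5)
  expect_equal(g1$selected_probe_id, "P2")
  expect_equal(g1$n_probes, 2L)
  # single-probe gene keeps its probe values
  g2 <- gr[gr$gene_symbol == "G2", ]
  expect_equal(g2$h2, 0.7)
  expect_equal(g2$pvalue, 0.001)
  # tie on h2 resolves to the smaller p
  g3 <- gr[gr$gene_symbol == "G3", ]
  expect_equal(g3$selected_probe_id, "P5")
  # ensembl version stripped
  expect_equal(g1$ensembl_id, "ENSG1")
  # gene-level q is a fresh BH pass over selected probes
  expect_equal(gr$q, bh_adjust(gr$pvalue))
  # gene h2 is never below the max of its probes
  expect_true(all(gr$h2 >= tapply(pr$h2, pr$gene_symbol, max)[gr$gene_symbol] -
                    1e-12))
  # exact h2 tie and p tie -> lexicographically smaller probe id
  pr2 <- make_probe_results(data.frame(
    probe_id = c("PB", "PA"), gene_symbol = "G", h2 = 0.4, pvalue = 0.04,
    stringsAsFactors = FALSE))
  ann2 <- data.frame(probe_id = c("PB", "PA"), gene_symbol = "G",
                     ensembl_id = "E", chromosome = "1", gc_percent = 50,
                     gene_length = 10, stringsAsFactors = FALSE)
  expect_equal(aggregate_genes(pr2, ann2)$selected_probe_id, "PA")
  # probe missing from annotation is a hard error naming it
  expect_error(aggregate_genes(pr, ann[-3, ]), "P3")
})

test_that("chromosome_summary counts and conserves significance", {
  gr <- data.frame(gene_symbol = paste0("G", 1:5),
                   chromosome = c("1", "1", "1", "1", "2"),
                   h2 = c(0.6, 0.5, 0.2, 0.1, 0.8),
                   q = c(0.01, 0.04, 0.2, 0.9, 0.001))
  cs <- chromosome_summary(gr)
  expect_equal(cs$proportion[cs$chromosome == "1"], 0.5)
  expect_equal(cs$proportion[cs$chromosome == "2"], 1.0)
  expect_equal(sum(cs$n_significant), sum(gr$q < 0.05))
  expect_equal(cs$mean_h2_significant[cs$chromosome == "1"], 0.55)
  # degenerate: nothing significant
  gr$q <- 0.9
  cs0 <- chromosome_summary(gr)
  expect_true(all(cs0$proportion == 0))
  expect_true(all(is.na(cs0$mean_h2_significant)))
})

test_that("scan produces one row per retained probe and valid FDR", {
  cfg <- sim_config(n_probes = 12, n_mz_pairs = 40, n_dz_pairs = 30,
                    probe_truth = data.frame(a2 = rep(c(0, 0.8), 6),
                                             c2 = 0, e2 = rep(c(1, 0.2), 6)),
                    n_undetected_probes = 2, seed = 21)
  sim <- simulate_study(cfg)
  log <- twinherit:::start_log()
  res <- scan(sim$bundle, scan_config(ci = "none", seed = 3), log = log)
  # 2 undetected probes filtered
  expect_equal(nrow(res), 10L)
  expect_true(all(c("probe_id", "gene_symbol", "chromosome", "best_model",
                    "h2", "ci_lo", "ci_hi", "pvalue", "q", "converged")
                  %in% names(res)))
  ok <- res$converged
  expect_equal(res$q[ok], bh_adjust(res$pvalue[ok]))
  expect_true(all(res$q[ok] >= res$pvalue[ok]))
  expect_true(any(grepl("detection filter", log$lines)))

  # heritable probes get high h2, null probes low, on average
  truth <- sim$truth[match(res$probe_id, sim$truth$probe_id), ]
  expect_gt(mean(res$h2[truth$a2 > 0]), mean(res$h2[truth$a2 == 0]))

  # probe input order does not change results (modulo row order)
  perm <- sample(nrow(sim$bundle$expression))
  b2 <- study_bundle(sim$bundle$expression[perm, ], sim$bundle$samples,
                     sim$bundle$annotation[perm, ],
                     sim$bundle$detection[perm, ])
  res2 <- scan(b2, scan_config(ci = "none", seed = 3))
  res2 <- res2[match(res$probe_id, res2$probe_id), ]
  expect_equal(res$h2, res2$h2, tolerance = 1e-8)
  expect_equal(res$pvalue, res2$pvalue, tolerance = 1e-8)
})

test_that("scan without detection matrix requires the explicit skip", {
  cfg <- sim_config(n_probes = 3, n_mz_pairs = 10, n_dz_pairs = 10, seed = 2)
  sim <- simulate_study(cfg)
  expect_error(scan(sim$bundle, scan_config(ci = "none")), "detection")
  res <- scan(sim$bundle, scan_config(ci = "none", detection_filter = FALSE))
  expect_equal(nrow(res), 3L)
})
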