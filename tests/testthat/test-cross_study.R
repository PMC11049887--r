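mk_summary <- function(label, ids, h2, p) {
  study_summary(data.frame(ensembl_id = ids, h2 = h2, pvalue = p,
                           stringsAsFactors = FALSE), label)
}

test_that("harmonize intersects by version-stripped Ensembl id", {
  s1 <- mk_summary("one", c("A", "B", "C"), c(0.1, 0.2, 0.3), c(0.5, 0.1, 0.2))
  s2 <- mk_summary("two", c("B", "C", "D"), c(0.4, 0.5, 0.6), c(0.3, 0.01, 0.9))
  s3 <- mk_summary("three", c("C", "B"), c(0.7, 0.8), c(0.05, 0.2))
  h <- harmonize(list(s1, s2, s3))
  expect_equal(sort(h$common_ids), c("B", "C"))
  expect_equal(h$table$h2.three[h$table$ensembl_id == "B"], 0.8)

  # version suffix is ignored
  sv1 <- mk_summary("x", "ENSG00000164308.5", 0.8, 0.01)
  sv2 <- mk_summary("y", "ENSG00000164308", 0.7, 0.02)
  hv <- harmonize(list(sv1, sv2))
  expect_equal(hv$common_ids, "ENSG00000164308")

  # order invariance over study permutations
  h2_perm <- harmonize(list(s3, s1, s2))
  expect_equal(sort(h2_perm$common_ids), sort(h$common_ids))
  expect_equal(h2_perm$table$h2.one, h$table$h2.one)

  # disjoint studies warn and downstream refuses
  d1 <- mk_summary("a", c("A", "B"), c(0.1, 0.2), c(0.5, 0.5))
  d2 <- mk_summary("b", c("C", "D"), c(0.1, 0.2), c(0.5, 0.5))
  expect_warning(hd <- harmonize(list(d1, d2)), "no genes")
  expect_error(overlap_fdr(hd), "fewer than 2")
  expect_error(harmonize(list(s1)), "at least 2")
})

test_that("overlap_fdr recomputes BH within the common set only", {
  s1 <- mk_summary("one", paste0("G", 1:6), runif(6, 0.1, 0.9),
                   c(0.01, 0.02, 0.03, 0.04, 0.5, 0.9))
  s2 <- mk_summary("two", paste0("G", 1:4), runif(4, 0.1, 0.9), rep(1, 4))
  h <- overlap_fdr(harmonize(list(s1, s2)))
  # common set is G1..G4; study one's q computed with m = 4, not 6
  expect_equal(h$table$q.one, bh_adjust(c(0.01, 0.02, 0.03, 0.04)))
  expect_true(all(h$table$sig.one))
  # p all 1 -> nothing significant
  expect_true(all(!h$table$sig.two))
  # brute-force subset oracle
  expect_equal(h$table$q.one, bh_oracle(h$table$pvalue.one))
})

test_that("overlap_report counts venn patterns and correlations", {
  # g1, g2 significant in all three; g3 only in study one
  ids <- c("g1", "g2", "g3", "g4")
  p_sig <- c(1e-4, 1e-4, 1e-4, 0.9)
  p_ns <- c(1e-4, 1e-4, 0.9, 0.9)
  s1 <- mk_summary("one", ids, c(0.9, 0.8, 0.7, 0.1), p_sig)
  s2 <- mk_summary("two", ids, c(0.85, 0.75, 0.2, 0.1), p_ns)
  s3 <- mk_summary("three", ids, c(0.8, 0.7, 0.3, 0.2), p_ns)
  rep <- overlap_report(overlap_fdr(harmonize(list(s1, s2, s3))))
  vc <- setNames(rep$venn_counts$count, rep$venn_counts$pattern)
  expect_equal(unname(vc["one&two&three"]), 2)
  expect_equal(unname(vc["one"]), 1)
  expect_equal(rep$n_significant_all, 2)
  # sum of venn counts = genes significant in >= 1 study
  expect_equal(sum(rep$venn_counts$count), 3)
  # per-study marginal consistency
  for (lab in c("one", "two", "three")) {
    pats <- grepl(paste0("\\b", lab, "\\b"),
                  gsub("&", " ", rep$venn_counts$pattern))
    expect_equal(sum(rep$venn_counts$count[pats]),
                 unname(rep$n_significant[lab]))
  }
  # identical h2 columns -> pairwise r = 1
  t1 <- mk_summary("p", ids, c(0.9, 0.8, 0.7, 0.1), p_sig)
  t2 <- mk_summary("q", ids, c(0.9, 0.8, 0.7, 0.1), p_sig)
  rep2 <- overlap_report(overlap_fdr(harmonize(list(t1, t2))))
  expect_equal(unname(rep2$pairwise_r["p", "q"]), 1)
  # top table ordered by first-study h2 (ids are case-normalized to upper)
  expect_equal(rep$top_common$ensembl_id[1], "G1")
})

test_that("flags are invariant to monotone gene id relabeling", {
  ids <- paste0("G", 1:8)
  set.seed(3)
  h2 <- runif(8); p <- runif(8)
  s1 <- mk_summary("a", ids, h2, p)
  s2 <- mk_summary("b", ids, rev(h2), rev(p))
  r1 <- overlap_fdr(harmonize(list(s1, s2)))
  relabel <- setNames(sprintf("ZZ%02d", 1:8), ids)  # monotone in id order
  s1r <- mk_summary("a", unname(relabel[ids]), h2, p)
  s2r <- mk_summary("b", unname(relabel[ids]), rev(h2), rev(p))
  r2 <- overlap_fdr(harmonize(list(s1r, s2r)))
  expect_equal(r1$table$sig.a, r2$table$sig.a)
  expect_equal(r1$table$sig.b, r2$table$sig.b)
})

test_that("cohorts sharing truth show positive h2 correlations", {
  # three cohorts: shared true a2 per gene, independent estimation noise
  set.seed(9)
  n <- 300
  a2 <- runif(n, 0, 0.9)
  mk <- function(lab) {
    h2 <- pmin(pmax(a2 + rnorm(n, 0, 0.15), 0), 1)
    p <- pmin(pmax(pchisq((h2 / 0.15)^2, 1, lower.tail = FALSE), 1e-12), 1)
    mk_summary(lab, sprintf("ENSG%05d", 1:n), h2, p)
  }
  rep <- overlap_report(overlap_fdr(harmonize(list(mk("s1"), mk("s2"),
                                                   mk("s3")))))
  off <- rep$pairwise_r[upper.tri(rep$pairwise_r)]
  expect_true(all(off > 0.2))
})
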