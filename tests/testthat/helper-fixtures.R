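# Shared fixtures and independent oracles used across test files.

# Tiny hand-built bundle: 3 probes x 4 samples (1 MZ + 1 DZ pair).
tiny_bundle_tables <- function() {
  expr <- matrix(round(rnorm(12), 4), 3, 4,
                 dimnames = list(c("PRB1", "PRB2", "PRB3"),
                                 c("S1", "S2", "S3", "S4")))
  samples <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    pair_id = c("P1", "P1", "P2", "P2"),
    zygosity = c("MZ", "MZ", "DZ", "DZ"),
    age = c(70, 70, 80, 80), sex = c("F", "F", "M", "M"),
    batch = "B1", rin = c(7, 8, 9, 7.5), wbc = c(6, 5, 7, 6.5),
    stringsAsFactors = FALSE
  )
  annotation <- data.frame(
    probe_id = c("PRB1", "PRB2", "PRB3"),
    gene_symbol = c("G1", "G1", "G2"),
    ensembl_id = c("ENSG1", "ENSG1", "ENSG2"),
    chromosome = c("1", "1", "2"),
    gc_percent = c(40, 45, 50), gene_length = c(1000, 1000, 2000),
    stringsAsFactors = FALSE
  )
  list(expr = expr, samples = samples, annotation = annotation)
}

write_tiny_study <- function(dir) {
  tb <- tiny_bundle_tables()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(probe_id = rownames(tb$expr), tb$expr,
                         check.names = FALSE),
              file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(tb$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tb$annotation, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dir
}

# Simulate a single-probe twin pair set with known variance fractions.
sim_pairs <- function(a2, c2, n_mz = 71, n_dz = 52, seed = 1) {
  cfg <- sim_config(n_mz_pairs = n_mz, n_dz_pairs = n_dz, n_probes = 1,
                    probe_truth = data.frame(a2 = a2, c2 = c2,
                                             e2 = 1 - a2 - c2),
                    seed = seed)
  sim <- simulate_study(cfg)
  make_phenotype(sim$bundle$expression[1, ], sim$bundle$samples, NULL,
                 int = FALSE)$pairs
}

# Oracle 1: generic bivariate-normal negative log-density via matrix algebra,
# independent of the package's exchangeable-covariance shortcut.
mvn_negloglik_oracle <- function(pairs, a2, c2, e2, mu) {
  v <- a2 + c2 + e2
  nll_block <- function(m, cv) {
    S <- matrix(c(v, cv, cv, v), 2, 2)
    Sinv <- solve(S)
    ld <- determinant(S, logarithm = TRUE)$modulus
    tot <- 0
    for (i in seq_len(nrow(m))) {
      d <- m[i, ] - mu
      tot <- tot + log(2 * pi) + 0.5 * ld + 0.5 * drop(t(d) %*% Sinv %*% d)
    }
    tot
  }
  nll_block(pairs$mz, a2 + c2) + nll_block(pairs$dz, 0.5 * a2 + c2)
}

# Oracle 2: coarse-to-fine grid search over (a2, c2, e2) with the mean at
# its closed-form optimum, refined until the step reaches `final_step`.
# Keeps the top `keep` cells at every level to dodge local optima.
grid_fit_oracle <- function(pairs, model = "ACE", final_step = 0.001,
                            keep = 5) {
  v0 <- stats::var(c(pairs$mz, pairs$dz))
  hi <- 3 * v0
  mu_hat <- function(a2, c2, e2) {
    v <- a2 + c2 + e2
    cmz <- a2 + c2; cdz <- 0.5 * a2 + c2
    s1m <- sum(pairs$mz); s1d <- sum(pairs$dz)
    (s1m / (v + cmz) + s1d / (v + cdz)) /
      (2 * nrow(pairs$mz) / (v + cmz) + 2 * nrow(pairs$dz) / (v + cdz))
  }
  nll <- function(a2, c2, e2) {
    if (e2 <= 0) return(Inf)
    mvn_negloglik_oracle(pairs, a2, c2, e2, mu_hat(a2, c2, e2))
  }
  ax <- function(center, step, lo = 0) {
    unique(pmax(lo, center + step * (-10:10)))
  }
  a_grid <- if (model %in% c("ACE", "AE")) seq(0, hi, length.out = 13) else 0
  c_grid <- if (model %in% c("ACE", "CE")) seq(0, hi, length.out = 13) else 0
  e_grid <- seq(hi / 50, hi, length.out = 13)
  step <- hi / 12
  cells <- expand.grid(a2 = a_grid, c2 = c_grid, e2 = e_grid)
  repeat {
    vals <- mapply(nll, cells$a2, cells$c2, cells$e2)
    ord <- order(vals)
    best <- cells[ord[seq_len(min(keep, nrow(cells)))], , drop = FALSE]
    if (step <= final_step) {
      top <- best[1, ]
      return(list(negloglik = min(vals),
                  a2 = top$a2, c2 = top$c2, e2 = top$e2))
    }
    step <- step / 4
    cells <- unique(do.call(rbind, lapply(seq_len(nrow(best)), function(i) {
      expand.grid(
        a2 = if (model %in% c("ACE", "AE")) ax(best$a2[i], step) else 0,
        c2 = if (model %in% c("ACE", "CE")) ax(best$c2[i], step) else 0,
        e2 = ax(best$e2[i], step, lo = 1e-6))
    })))
  }
}

# Oracle 3: brute-force BH step-up, literal definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j_set <- i:m
    q[ord[i]] <- min(1, min(p[ord[j_set]] * m / j_set))
  }
  q
}

# Oracle 4: two-sided Fisher p by enumerating all tables with the observed
# margins and summing hypergeometric point probabilities <= observed
# (relative tolerance guard 1 + 1e-7).
fisher_p_oracle <- function(tab) {
  x <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(x, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
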