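test_that("FPKM follows its unit definition and scaling laws", {
  m <- matrix(c(1000L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  f <- compute_fpkm(m, gene_lengths = c(1000, 500), library_sizes = 1e6)
  expect_equal(unname(f$values["g1", 1]), 1000)
  expect_equal(unname(f$values["g2", 1]), 0)
  # linear in counts, inverse-linear in library size (random matrices)
  set.seed(1)
  for (i in 1:5) {
    counts <- matrix(rpois(20, 50), 4, 5,
                     dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
    len <- runif(4, 300, 3000); lib <- runif(5, 1e6, 5e7)
    f1 <- compute_fpkm(counts, len, lib)$values
    expect_equal(compute_fpkm(3 * counts, len, lib)$values, 3 * f1)
    expect_equal(compute_fpkm(counts, len, 2 * lib)$values, f1 / 2)
  }
  expect_error(compute_fpkm(m, c(0, 500), 1e6), "positive")
  expect_error(compute_fpkm(m, c(1000, 500), 0), "positive")
})

test_that("log transform uses the documented pseudocount", {
  m <- matrix(c(1, 0, 3), 3, 1, dimnames = list(paste0("g", 1:3), "s"))
  lt <- log_transform(m)$values
  expect_equal(unname(lt[, 1]), c(1, 0, 2))
  expect_equal(unname(log_transform(m, pseudocount = 0.5)$values[2, 1]), -1)
})

test_that("GC profile is flat for unbiased data and corrects a planted bias", {
  set.seed(7)
  G <- 10000
  gc <- rbeta(G, 5, 5)
  base <- rpois(G, 200)
  unbiased <- cbind(s1 = base, s2 = rpois(G, 200))
  rownames(unbiased) <- paste0("g", 1:G)
  prof <- gc_correction(unbiased, gc)$profile
  expect_true(all(prof$F > 0.95 & prof$F < 1.05))

  # sample 2 counts inflated by (1 + GC): enrichment must rise with GC and
  # correction must flatten it
  biased <- cbind(s1 = base, s2 = rpois(G, 200 * (1 + gc)))
  rownames(biased) <- paste0("g", 1:G)
  res <- gc_correction(biased, gc)
  f2 <- log2(res$profile$F[, "s2"])
  expect_gt(cor(res$profile$bin_gc, f2), 0.95)   # monotone increasing profile
  reprof <- gc_correction(round(res$corrected), gc)$profile
  expect_lt(max(abs(log2(reprof$F))), 0.1)
  # totals preserved
  expect_equal(colSums(res$corrected), colSums(biased))
})

test_that("GC correction with a single bin is a global scalar", {
  set.seed(8)
  counts <- matrix(rpois(40, 100), 20, 2,
                   dimnames = list(paste0("g", 1:20), c("a", "b")))
  gc <- rep(0.5, 20) + rnorm(20, 0, 1e-9)
  res <- gc_correction(counts, gc, n_bins = 1)
  ratio <- res$corrected / counts
  expect_lt(diff(range(ratio[counts > 0])), 1e-6)
})

test_that("expression-mode mixture recovers well-separated modes", {
  set.seed(21)
  lab <- rbinom(5000, 1, 0.5)
  x <- rnorm(5000, mean = ifelse(lab == 1, 3, 0), sd = 0.3)
  fit <- expression_mode_mixture(x)
  expect_lt(abs(fit$means[1] - 0), 0.05)
  expect_lt(abs(fit$means[2] - 3), 0.05)
  called_repressed <- fit$posterior_repressed > 0.5
  expect_gt(mean(called_repressed == (lab == 0)), 0.99)
  # EM log-likelihood is non-decreasing throughout
  expect_true(all(diff(fit$loglik_trace) > -1e-7))
  # far-left point is confidently repressed
  xx <- c(x, -20)
  fit2 <- expression_mode_mixture(xx)
  expect_gt(fit2$posterior_repressed[length(xx)], 0.999)
  expect_error(expression_mode_mixture(rep(1, 100)), "no mixture")
})

test_that("mixture posterior is ~0.5 at the symmetric midpoint", {
  set.seed(22)
  x <- c(rnorm(3000, -2, 0.5), rnorm(3000, 2, 0.5), 0)
  fit <- expression_mode_mixture(x)
  expect_lt(abs(fit$posterior_repressed[length(x)] - 0.5), 0.05)
})

test_that("correlation ordering places duplicates adjacent and separates donor blocks", {
  set.seed(31)
  m <- matrix(rnorm(5000 * 4), 5000, 4,
              dimnames = list(NULL, c("a", "b", "c", "a_dup")))
  m[, "a_dup"] <- m[, "a"]
  res <- correlation_heatmap_order(m)
  expect_equal(res$cor["a", "a_dup"], 1)
  pos <- match(c("a", "a_dup"), res$order)
  expect_equal(abs(diff(pos)), 1)
  # independent samples: near-zero off-diagonal correlation
  r <- correlation_heatmap_order(m[, c("a", "b", "c")])$cor
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  # donor-block structure from the generator: within-donor r above between
  cfg <- simulation_config(n_genes = 2000,
                           ve = c(adult_tissue = 0, ips_vs_es = 0, origin = 0,
                                  donor_adult = 0.5, donor_ipsc = 0.5, batch = 0),
                           seed = 32)
  sim <- simulate_study(cfg)
  rr <- correlation_heatmap_order(sim$log2fpkm)$cor
  meta <- sim$meta
  ix <- meta$cell_class == "iPSC"
  ids <- meta$sample_id[ix]
  sub <- rr[ids, ids]
  same <- outer(meta$donor[ix], meta$donor[ix], "==") & !diag(sum(ix))
  expect_gt(mean(sub[same]), mean(sub[!same & !diag(sum(ix))]))
})

test_that("gene precision inverts within-group variance with capping", {
  m <- rbind(g_const = rep(5, 6),
             g_half = c(1, 2, 1, 2, 1, 2),     # pooled within-pair var 0.5
             g_noisy = c(0, 3, 0, 3, 0, 3))
  colnames(m) <- paste0("s", 1:6)
  groups <- rep(c("A", "B", "C"), each = 2)
  tau <- gene_precision(m, groups, cap_quantile = 1)
  expect_equal(unname(tau["g_half"]), 2)
  expect_true(attr(tau, "capped")["g_const"])   # zero variance -> capped
  expect_equal(unname(tau["g_const"]), max(tau[c("g_half", "g_noisy")]))
  # heteroscedastic simulation: tau rank-tracks the true precision
  set.seed(41)
  G <- 2000; reps <- 5
  tau_true <- exp(rnorm(G, 0, 1.5))
  x <- matrix(rnorm(G * reps, 0, rep(1 / sqrt(tau_true), reps)), G, reps)
  tau_hat <- gene_precision(x, rep("g1", reps))
  expect_gt(cor(tau_hat, tau_true, method = "spearman"), 0.8)
})

test_that("top-expressed filtering matches a sort oracle", {
  set.seed(51)
  m <- matrix(rpois(100 * 3, 20), 100, 3,
              dimnames = list(sprintf("g%03d", 1:100), c("a", "b", "c")))
  expect_identical(filter_top_expressed(m, 0), m)
  f1 <- filter_top_expressed(m, 1)
  expect_equal(nrow(f1), 99)
  for (pct in c(1, 5, 10)) {
    kept <- rownames(filter_top_expressed(m, pct))
    k <- floor(100 * pct / 100)
    oracle_removed <- names(sort(rowMeans(m), decreasing = TRUE))[seq_len(k)]
    expect_setequal(kept, setdiff(rownames(m), oracle_removed))
  }
})
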