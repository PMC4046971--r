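test_that("size factors and dispersion trend are recovered from NB counts", {
  set.seed(81)
  G <- 5000; m <- 12
  sf_true <- exp(rnorm(m, 0, 0.2)); sf_true <- sf_true / exp(mean(log(sf_true)))
  mu <- exp(rnorm(G, 5, 1))
  a1 <- 0.1
  alpha <- 1 / mu + a1
  counts <- matrix(rnbinom(G * m, mu = mu %o% sf_true, size = 1 / alpha), G, m)
  sf <- size_factors(counts)
  expect_lt(max(abs(sf - sf_true)), 0.05)
  disp <- estimate_dispersions(counts, sf = sf)
  expect_gt(disp$trend[["a1"]], 0.07)
  expect_lt(disp$trend[["a1"]], 0.13)
  # Poisson counts: asymptotic dispersion near zero
  pois <- matrix(rpois(G * m, mu %o% sf_true), G, m)
  dp <- estimate_dispersions(pois, sf = sf_true)
  expect_lt(dp$trend[["a1"]], 0.01)
})

test_that("likelihoods are nested and match a brute-force NB evaluation", {
  sim <- simulate_three_way_counts(100, proportions = c(IE = 0.5, CR = 0.2,
                                                        TM = 0.2, AR = 0.05,
                                                        CX = 0.05), seed = 82)
  cls <- classify_three_way(sim$counts, sim$class)
  expect_true(all(cls$ll_CX >= cls$ll_CR - 1e-6))
  expect_true(all(cls$ll_CX >= cls$ll_TM - 1e-6))
  expect_true(all(cls$ll_CX >= cls$ll_AR - 1e-6))
  expect_true(all(pmin(cls$ll_CR, cls$ll_TM, cls$ll_AR) >= cls$ll_H0 - 1e-6))
  expect_true(all(cls$min_p >= 0 & cls$min_p <= 1))

  # brute force: per-gene sum of NB log pmfs via lgamma, at the fitted means
  sf <- size_factors(sim$counts)
  brute <- function(k, mu_vec, alpha) {
    r <- 1 / alpha
    sum(lgamma(k + r) - lgamma(r) - lgamma(k + 1) +
        r * log(r / (r + mu_vec)) + k * log(mu_vec / (r + mu_vec)))
  }
  qfit <- cbind(adult = cls$q_A, iPSC = cls$q_I, ESC = cls$q_E)
  for (g in sample.int(100, 20)) {
    mu_vec <- qfit[g, sim$class] * sf
    want <- brute(sim$counts[g, ], mu_vec, cls$alpha[g])
    expect_equal(cls$ll_CX[g], want, tolerance = 1e-8)
  }
})

test_that("swapping adult and ESC labels swaps CR and TM exactly", {
  sim <- simulate_three_way_counts(400, proportions = c(IE = 0.6, CR = 0.15,
                                                        TM = 0.15, AR = 0.05,
                                                        CX = 0.05),
                                   n_per_class = c(adult = 5, iPSC = 7, ESC = 5),
                                   seed = 83)
  cls <- classify_three_way(sim$counts, sim$class, p_threshold = 0.001)
  swapped_class <- c(adult = "ESC", iPSC = "iPSC", ESC = "adult")[sim$class]
  cls2 <- classify_three_way(sim$counts, swapped_class, p_threshold = 0.001)
  swap <- c(IE = "IE", CR = "TM", TM = "CR", AR = "AR", PTM = "PTM", PAR = "PAR")
  expect_identical(unname(swap[cls$category]), cls2$category)
  expect_equal(cls$p_CR, cls2$p_TM, tolerance = 1e-9)
  expect_equal(cls$p_AR, cls2$p_AR, tolerance = 1e-9)
})

test_that("exactly equal fitted means give zero likelihood ratios", {
  counts <- matrix(rep(c(10L, 20L, 30L, 40L), 8), 2, 16, byrow = TRUE)[, 1:12]
  counts <- rbind(g1 = rep(25L, 12), g2 = rep(c(10L, 40L), 6))
  class <- rep(c("adult", "iPSC", "ESC"), each = 4)
  cls <- classify_three_way(counts, class, sf = rep(1, 12),
                            alpha = c(0.1, 0.1), p_threshold = 0.05)
  expect_equal(cls$ll_CX, cls$ll_H0, tolerance = 1e-6)
  expect_equal(cls$min_p, c(1, 1))
  expect_identical(cls$category, c("IE", "IE"))
})

test_that("planted signals are classified correctly with high power", {
  sim <- simulate_three_way_counts(600, proportions = c(IE = 0.5, CR = 1 / 6,
                                                        TM = 1 / 6, AR = 1 / 6,
                                                        CX = 0),
                                   depth = 500, seed = 84)
  cls <- classify_three_way(sim$counts, sim$class, p_threshold = 1e-4)
  planted <- sim$truth$category != "IE"
  acc <- mean(cls$category[planted] == sim$truth$category[planted])
  expect_gt(acc, 0.95)
})

test_that("permutation FDR machinery respects its contracts", {
  sim <- simulate_three_way_counts(300, proportions = c(IE = 1, CR = 0, TM = 0,
                                                        AR = 0, CX = 0),
                                   seed = 85)
  cls <- classify_three_way(sim$counts, sim$class)
  expect_error(permutation_fdr(cls, sim$counts, sim$class, n_perm = 5),
               "at least 20")
  fdr <- permutation_fdr(cls, sim$counts, sim$class, n_perm = 25, seed = 85)
  expect_true(all(fdr$q >= 0 & fdr$q <= 1))
  # all-null data: expect no discoveries; q-values near 1 for typical genes
  expect_equal(fdr$n_significant, sum(cls$min_p <= fdr$threshold))
  # q-values are monotone in min_p
  ord <- order(cls$min_p)
  expect_true(all(diff(fdr$q[ord]) >= -1e-12))
})

test_that("Table-1-style counting applies the fold-change bound inclusively", {
  cls <- data.frame(
    gene_id = paste0("g", 1:5),
    q_A = c(100, 100, 100, 100, 100),
    q_I = c(150, 120, 300, 50, 160),
    q_E = c(100, 100, 100, 100, 240),
    category = c("TM", "TM", "AR", "PAR", "PTM"),
    stringsAsFactors = FALSE
  )
  q <- c(0.01, 0.01, 0.01, 0.01, 0.2)
  res <- significant_genes(cls, q)
  # gene 1: fold exactly 1.5 -> included; gene 2: fold 1.2 -> excluded;
  # gene 5: significant fold but q above threshold -> excluded
  expect_setequal(res$genes$gene_id, c("g1", "g3", "g4"))
  expect_equal(sum(res$table), 3)
  expect_equal(unname(res$table["activation", "TM"]), 1)
  expect_equal(unname(res$table["activation", "AR"]), 1)
  expect_equal(unname(res$table["silencing", "PAR"]), 1)
})

test_that("hierarchical EM recovers proportions and increases its objective", {
  sim <- simulate_three_way_counts(4000,
    proportions = c(IE = 0.9, CR = 0.04, TM = 0.03, AR = 0.02, CX = 0.01),
    seed = 86)
  cls <- classify_three_way(sim$counts, sim$class)
  hp <- hierarchical_proportions(cls)
  expect_true(hp$converged)
  expect_true(all(diff(hp$objective_trace) >= -1e-9))
  expect_equal(sum(hp$pi), 1, tolerance = 1e-9)
  truth <- c(IE = 0.9, CR = 0.04, TM = 0.03, AR = 0.02, CX = 0.01)
  expect_lt(max(abs(hp$pi - truth)), 0.02)
  # an all-invariant dataset concentrates on IE
  sim0 <- simulate_three_way_counts(2000, proportions = c(IE = 1, CR = 0,
                                                          TM = 0, AR = 0,
                                                          CX = 0), seed = 87)
  cls0 <- classify_three_way(sim0$counts, sim0$class)
  expect_gte(hierarchical_proportions(cls0)$pi[["IE"]], 0.95)
  # BIC fallback still runs
  hp_bic <- hierarchical_proportions(cls, n_samples = length(sim$class),
                                     method = "bic")
  expect_equal(sum(hp_bic$pi), 1, tolerance = 1e-9)
})
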