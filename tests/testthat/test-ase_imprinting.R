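test_that("gene-level aggregation sums haplotype counts and applies filters", {
  counts <- data.frame(
    sample_id = "s1", gene_id = c("g1", "g1", "g2"),
    snp_id = c("r1", "r2", "r3"),
    hap1_count = c(10L, 20L, 5L), hap2_count = c(0L, 2L, 7L),
    stringsAsFactors = FALSE)
  ase <- aggregate_gene_ase(counts, min_coverage = 20)
  expect_equal(nrow(ase), 1)                  # g2 has coverage 12 < 20
  expect_equal(attr(ase, "n_excluded"), 1)
  expect_equal(ase$ai, 30 / 32)
  expect_equal(ase$n_snps, 2)
  # aggregation is invariant to SNP order and additive over partitions
  ase_rev <- aggregate_gene_ase(counts[c(3, 2, 1), ], min_coverage = 20)
  expect_equal(ase_rev$ai, ase$ai)
  half1 <- counts[1, ]; half2 <- counts[2, ]
  a1 <- aggregate_gene_ase(half1, min_coverage = 1)
  a2 <- aggregate_gene_ase(half2, min_coverage = 1)
  expect_equal(a1$paternal_total + a2$paternal_total, 30)
})

test_that("exact binomial imbalance test matches brute-force pmf summation", {
  # independent oracle: two-sided p sums all outcomes with pmf <= observed pmf
  brute_p <- function(k, n) {
    pmf <- dbinom(0:n, n, 0.5)
    sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
  }
  set.seed(101)
  for (i in 1:60) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    ase <- data.frame(paternal_total = k, maternal_total = n - k,
                      ai = k / n, ci_low = 0, ci_high = 1)
    got <- test_imbalance(ase)$p_imbalance
    expect_equal(got, brute_p(k, n), tolerance = 1e-12)
  }
  # documented cases
  a <- data.frame(paternal_total = c(30L, 20L, 40L),
                  maternal_total = c(10L, 20L, 0L),
                  ai = c(0.75, 0.5, 1), ci_low = 0, ci_high = 1)
  p <- test_imbalance(a)$p_imbalance
  expect_equal(p[1], brute_p(30, 40), tolerance = 1e-12)
  expect_equal(round(p[1], 4), 0.0022)
  expect_equal(p[2], 1)
  expect_equal(p[3], 2 * 0.5^40, tolerance = 1e-12)
})

test_that("imprinting classification follows the declared cutoffs", {
  mk <- function(pat, mat) {
    tot <- pat + mat
    ci <- binom.test(pat, tot)$conf.int
    data.frame(sample_id = "s", gene_id = "g", paternal_total = pat,
               maternal_total = mat, n_snps = 2, ai = pat / tot,
               ci_low = ci[1], ci_high = ci[2])
  }
  expect_equal(classify_imprinting(mk(196, 4))$status, "mono-allelic")
  expect_equal(classify_imprinting(mk(4, 196))$status, "mono-allelic")
  expect_equal(classify_imprinting(mk(100, 100))$status, "bi-allelic")
  expect_equal(classify_imprinting(mk(14, 6))$status, "ambiguous")
  # LOI: adult mono-allelic, majority of lines bi-allelic
  expect_true(loss_of_imprinting("mono-allelic",
                                 c("bi-allelic", "bi-allelic", "bi-allelic",
                                   "mono-allelic")))
  expect_false(loss_of_imprinting("mono-allelic",
                                  c("bi-allelic", "mono-allelic",
                                    "mono-allelic", "ambiguous")))
  expect_false(loss_of_imprinting("bi-allelic",
                                  c("bi-allelic", "bi-allelic")))
})

test_that("imprinting status is recovered accurately from deep synthetic data", {
  set.seed(102)
  spec <- data.frame(gene_id = sprintf("G%02d", 1:60),
                     p_adult = sample(c(0.02, 0.5, 0.98), 60, replace = TRUE))
  spec$p_ipsc <- spec$p_adult
  sim <- simulate_allelic_counts(spec, donors = "S2", n_ipsc_lines = 2,
                                 depth = 150, seed = 103)
  ase <- classify_imprinting(aggregate_gene_ase(sim$counts))
  truth <- ifelse(spec$p_adult == 0.5, "bi-allelic", "mono-allelic")
  names(truth) <- spec$gene_id
  expect_gt(mean(ase$status == truth[ase$gene_id]), 0.95)
  # a loss-of-imprinting gene flips from adult mono to iPSC bi
  loi_spec <- data.frame(gene_id = "ZDBF2like", p_adult = 0.97, p_ipsc = 0.5)
  lsim <- simulate_allelic_counts(loi_spec, donors = "S2", n_ipsc_lines = 4,
                                  depth = 200, seed = 104)
  lase <- classify_imprinting(aggregate_gene_ase(lsim$counts))
  adult_status <- lase$status[grepl("^adult", lase$sample_id)]
  ipsc_status <- lase$status[grepl("^iPSC", lase$sample_id)]
  expect_true(loss_of_imprinting(adult_status, ipsc_status))
})

test_that("adult-iPSC concordance is perfect for identical profiles, near zero for independent ones", {
  genes <- sprintf("G%02d", 1:50)
  set.seed(105)
  p <- runif(50, 0.1, 0.9)
  mk_ase <- function(p_vec, sample_id, depth = 4000) {
    pat <- rbinom(50, depth, p_vec)
    data.frame(sample_id = sample_id, gene_id = genes, paternal_total = pat,
               maternal_total = depth - pat, n_snps = 3, ai = pat / depth,
               ci_low = NA, ci_high = NA, stringsAsFactors = FALSE)
  }
  adult <- mk_ase(p, "adult-S2")
  ipsc <- mk_ase(p, "iPSC-S2-1")
  cc <- imprinting_concordance(adult, ipsc)
  expect_gt(cc$r2, 0.95)        # same true p, deep coverage
  indep <- mk_ase(sample(p), "iPSC-S2-1")
  cc0 <- imprinting_concordance(adult, indep)
  expect_lt(cc0$r2, 0.1)
  expect_error(imprinting_concordance(adult[1:2, ], ipsc[1:2, ]), "fewer than 3")
})

test_that("concordance attenuation matches the analytic binomial prediction", {
  set.seed(106)
  G <- 400; depth <- 100
  p <- rbeta(G, 0.4, 0.4) * 0.96 + 0.02   # spread of true allelic fractions
  genes <- sprintf("G%03d", seq_len(G))
  mk <- function(sample_id) {
    pat <- rbinom(G, depth, p)
    data.frame(sample_id = sample_id, gene_id = genes, paternal_total = pat,
               maternal_total = depth - pat, n_snps = 1, ai = pat / depth,
               ci_low = NA, ci_high = NA, stringsAsFactors = FALSE)
  }
  cc <- imprinting_concordance(mk("adult-S2"), mk("iPSC-S2-1"))
  vp <- var(p)
  noise <- mean(p * (1 - p)) / depth
  attenuated_r2 <- (vp / (vp + noise))^2
  expect_lt(abs(cc$r2 - attenuated_r2), 0.1)
})
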