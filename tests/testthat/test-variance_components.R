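test_that("design matrices carry the documented level structure", {
  des <- build_design(default_study_design())
  expect_equal(dim(des$Z$Z2), c(47, 5))
  expect_equal(sum(rowSums(des$Z$Z3) > 0), 25)    # only iPSC rows
  expect_equal(dim(des$Z$Z5), c(47, 2))
  # every nonzero row of every Z sums to 1
  for (Z in des$Z) expect_true(all(rowSums(Z) %in% c(0, 1)))
  # ESC rows carry no donor effect even though a donor label is present
  esc <- des$meta$cell_class == "ESC"
  expect_true(all(des$Z$Z4[esc, ] == 0))
  # single-sample design: one row everywhere
  one <- default_study_design()[1, ]
  d1 <- build_design(one)
  for (Z in d1$Z) expect_equal(nrow(Z), 1)
  # adult vs iPSC donor levels map to distinct variance parameters
  expect_setequal(unique(des$param$Z4), c("delta4_adult", "delta4_ipsc"))
})

test_that("pooled log-likelihood equals a dense multivariate-normal evaluation", {
  meta <- toy_meta_6()
  design <- build_design(meta)
  set.seed(61)
  Y <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, meta$sample_id))
  for (i in 1:50) {
    delta <- setNames(exp(runif(4, log(0.05), log(2))),
                      c("delta2_pluri", "delta3_origin", "delta4_ipsc",
                        "delta5_batch"))
    sigma2 <- c(all = exp(runif(1, log(0.1), log(2))))
    got <- mixed_model_loglik(Y, design, delta, sigma2, "homo")
    want <- dense_pooled_loglik(Y, meta, delta, sigma2)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("variance parameters are recovered on the full study design", {
  cfg <- simulation_config(n_genes = 2000, seed = 71)
  sim <- simulate_study(cfg)
  fit <- fit_mixed_model(sim$log2fpkm, sim$design, "homo")
  true_ve <- cfg$delta / (cfg$delta + 1)
  names(true_ve) <- names(ipscvar:::component_param)[
    match(names(cfg$delta), ipscvar:::component_param)]
  for (cp in names(fit$ve))
    expect_lt(abs(fit$ve[cp] - true_ve[cp]), 0.05)
})

test_that("a null simulation yields near-zero variance components", {
  cfg <- simulation_config(n_genes = 2000,
                           ve = c(adult_tissue = 0, ips_vs_es = 0, origin = 0,
                                  donor_adult = 0, donor_ipsc = 0, batch = 0),
                           seed = 72)
  sim <- simulate_study(cfg)
  fit <- fit_mixed_model(sim$log2fpkm, sim$design, "homo")
  expect_true(all(fit$params < 0.02))
})

test_that("adding a component never decreases the maximized log-likelihood", {
  cfg <- simulation_config(n_genes = 500, seed = 73)
  sim <- simulate_study(cfg)
  full <- fit_mixed_model(sim$log2fpkm, sim$design, "homo")
  reduced <- fit_mixed_model(sim$log2fpkm, sim$design, "homo", drop = "donor")
  expect_gte(full$loglik, reduced$loglik - 1e-6)
  nobatch <- fit_mixed_model(sim$log2fpkm, sim$design, "homo", drop = "batch")
  expect_gte(full$loglik, nobatch$loglik - 1e-6)
})

test_that("variance explained follows its definition on a synthetic fit", {
  des <- build_design(default_study_design())
  fake <- structure(list(
    params = c(delta2_adult = 1, delta2_pluri = 0, delta3_origin = 3,
               delta4_adult = 0.5, delta4_ipsc = 0.5, delta5_batch = 0),
    sigma2 = c(all = 1), design = des, residual_model = "homo"),
    class = "varcomp_fit")
  expect_equal(variance_explained(fake, "adult_tissue"), 0.5)
  expect_equal(variance_explained(fake, "ips_vs_es"), 0)
  expect_equal(variance_explained(fake, "origin"), 0.75)
  # heteroscedastic: sigma_rel is the weighted mean over acted-on samples
  fake2 <- fake
  fake2$residual_model <- "het1"
  fake2$sigma2 <- c(adult = 2, iPSC = 1, ESC = 4)
  expect_equal(variance_explained(fake2, "adult_tissue"), 1 / 3)
  expect_equal(variance_explained(fake2, "origin"), 0.75)
  n_i <- sum(des$meta$cell_class == "iPSC"); n_e <- 4
  srel <- (n_i * 1 + n_e * 4) / (n_i + n_e)
  expect_equal(variance_explained(fake2, "ips_vs_es"), 0 / (0 + srel))
})

test_that("covariance layers sum to the model-implied covariance", {
  cfg <- simulation_config(n_genes = 300, seed = 74)
  sim <- simulate_study(cfg)
  fit <- fit_mixed_model(sim$log2fpkm, sim$design, "het1")
  layers <- covariance_layers(fit)
  manual <- Reduce(`+`, layers[names(fit$params)]) + layers$residual
  expect_equal(layers$total, manual, tolerance = 1e-12)
  # donor layer is nonzero only within same-donor same-class pairs
  L4 <- layers$delta4_ipsc
  meta <- sim$meta
  ipsc <- meta$cell_class == "iPSC"
  same <- outer(meta$donor, meta$donor, "==") & outer(ipsc, ipsc, "&")
  expect_true(all(L4[!same] == 0))
  expect_true(all(L4[same] > 0))
  # a zero-variance component gives a (near) zero layer
  fitd <- fit_mixed_model(sim$log2fpkm, sim$design, "homo", drop = "batch")
  expect_false("delta5_batch" %in% names(covariance_layers(fitd)))
})

test_that("dropping donor on a confounded design inflates origin VE", {
  meta <- confounded_study_design()
  cfg <- simulation_config(n_genes = 1000, design = meta,
                           delta = c(delta2_pluri = 0.2, delta3_origin = 0,
                                     delta4_ipsc = 0.6, delta5_batch = 0.02),
                           sigma2 = 1, seed = 75)
  sim <- simulate_study(cfg)
  cmp <- refit_excluding(sim$log2fpkm, sim$design, "donor")
  expect_gt(cmp$ve_without["origin"], cmp$ve_with["origin"] + 0.05)
  # dropping a truly zero component leaves other VEs unchanged
  cfg2 <- simulation_config(n_genes = 1000, seed = 76,
                            ve = c(adult_tissue = 0.3, ips_vs_es = 0.01,
                                   origin = 0.04, donor_adult = 0.4,
                                   donor_ipsc = 0.4, batch = 0))
  sim2 <- simulate_study(cfg2)
  cmp2 <- refit_excluding(sim2$log2fpkm, sim2$design, "batch")
  shared <- intersect(names(cmp2$ve_with), names(cmp2$ve_without))
  expect_lt(max(abs(cmp2$ve_with[shared] - cmp2$ve_without[shared])), 0.01)
  # and costs a vanishing per-gene amount of likelihood
  expect_lt(abs(cmp2$fit_with$loglik - cmp2$fit_without$loglik),
            0.01 * cmp2$fit_with$n_genes)
})

test_that("the finer heteroscedastic model reduces to the coarser one", {
  cfg <- simulation_config(n_genes = 400,
                           sigma2 = c(adult = 1, iPSC = 0.5, ESC = 1),
                           residual_model = "het1", seed = 77)
  sim <- simulate_study(cfg)
  fit1 <- fit_mixed_model(sim$log2fpkm, sim$design, "het1")
  s <- fit1$sigma2
  sig7 <- c("fibroblast-adult" = s[["adult"]],
            "keratinocyte-adult" = s[["adult"]], "EPC-adult" = s[["adult"]],
            "F-iPSC" = s[["iPSC"]], "K-iPSC" = s[["iPSC"]],
            "E-iPSC" = s[["iPSC"]], ESC = s[["ESC"]])
  ll1 <- mixed_model_loglik(sim$log2fpkm, sim$design, fit1$params, s, "het1")
  ll2 <- mixed_model_loglik(sim$log2fpkm, sim$design, fit1$params, sig7, "het2")
  expect_equal(ll1, ll2, tolerance = 1e-6)
  expect_equal(ll1, fit1$loglik, tolerance = 1e-6)
})

test_that("zero-variance genes are dropped with a message", {
  cfg <- simulation_config(n_genes = 50, seed = 78)
  sim <- simulate_study(cfg)
  m <- sim$log2fpkm$values
  m[1, ] <- 7
  expect_message(fit <- fit_mixed_model(m, sim$design, "homo"),
                 "zero-variance")
  expect_equal(fit$n_genes, 49)
})
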