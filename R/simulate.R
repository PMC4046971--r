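# Synthetic-study generator: complete datasets with known ground truth for
# every downstream stage (variance decomposition, DE classification, ASE /
# imprinting, eQTL replication), emulating the reference design of 4 donors,
# 3 somatic tissues, 25 iPSC lines, 18 adult samples, 4 ESC samples and 2
# sequencing batches.

# deterministic fan-out of one global seed into per-component child seeds
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483563) + 1L
}

#' Simulation configuration
#'
#' Collects the true parameter values of a synthetic study. Defaults place
#' the variance components in the regime the downstream analyses are designed
#' for: donor variance dominating among iPSCs (VE 0.38) and adult samples
#' (0.42), small tissue-of-origin (0.04), iPSC-vs-ESC (0.01) and batch (0.02)
#' components, with adult-tissue differences at 0.30 and unit residual
#' variance.
#'
#' @param n_genes number of genes.
#' @param design sample-metadata table (default [default_study_design()]).
#' @param ve named true variance-explained fractions per component
#'   (converted to variance parameters delta^2 = ve/(1-ve) at unit residual).
#' @param delta optional named variance parameters, overriding `ve`.
#' @param sigma2 residual variance(s): a single value (homoscedastic) or a
#'   named vector over the groups of `residual_model`.
#' @param residual_model grouping for `sigma2` (default `"homo"`).
#' @param intercept_mean,intercept_sd distribution of per-gene baseline
#'   log2 FPKM (defaults 4 and 1.5).
#' @param nb_trend dispersion trend parameters `c(a0, a1)` of
#'   alpha(mu) = a0/mu + a1 (defaults 1 and 0.01).
#' @param size_factor_sd log-normal spread of per-sample size factors
#'   (default 0.1).
#' @param base_library_size mapped fragments for a size factor of 1
#'   (default 2e7).
#' @param seed global seed; fans out deterministically to each component.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000, design = default_study_design(),
                              ve = c(adult_tissue = 0.30, ips_vs_es = 0.01,
                                     origin = 0.04, donor_adult = 0.42,
                                     donor_ipsc = 0.38, batch = 0.02),
                              delta = NULL, sigma2 = 1,
                              residual_model = "homo",
                              intercept_mean = 4, intercept_sd = 1.5,
                              nb_trend = c(a0 = 1, a1 = 0.01),
                              size_factor_sd = 0.1,
                              base_library_size = 2e7, seed = 1) {
  if (n_genes <= 0) stop("n_genes must be positive")
  if (is.null(delta)) {
    if (any(ve < 0 | ve >= 1)) stop("ve fractions must lie in [0, 1)")
    delta <- ve / (1 - ve) * mean(sigma2)
    names(delta) <- component_param[names(ve)]
  }
  if (any(delta < 0) || any(sigma2 < 0)) stop("variance parameters must be >= 0")
  validate_metadata(design)
  groups <- residual_groups(design, residual_model)
  if (length(sigma2) == 1) {
    sigma2 <- stats::setNames(rep(sigma2, length(unique(groups))),
                              sort(unique(groups)))
  } else if (!setequal(names(sigma2), unique(groups))) {
    stop("sigma2 must be named with the residual groups: ",
         paste(sort(unique(groups)), collapse = ", "))
  }
  structure(list(n_genes = as.integer(n_genes), design = design,
                 delta = delta, sigma2 = sigma2,
                 residual_model = residual_model,
                 intercept_mean = intercept_mean, intercept_sd = intercept_sd,
                 nb_trend = nb_trend, size_factor_sd = size_factor_sd,
                 base_library_size = base_library_size, seed = seed),
            class = "sim_config")
}

#' Simulate a complete expression study
#'
#' Per gene j the latent log2 mean is
#' intercept_j + Z2 b2 + Z3 b3 + Z4 b4 + Z5 b5 + e, with b_k ~ N(0, D_k)
#' drawn independently per gene and residuals N(0, sigma^2_group). Counts are
#' NB with mean 2^latent x gene length (kb) x library size (millions) and
#' dispersion alpha(mu) = a0/mu + a1; FPKM then recovers 2^latent in
#' expectation.
#'
#' @param config a `sim_config` from [simulation_config()].
#' @return list: `counts`, `fpkm`, `log2fpkm` (`expression_matrix` objects),
#'   `meta`, `design` (the `design_set`), `gene_lengths`, `library_sizes`,
#'   `size_factors`, and `truth` (latent matrix, delta, sigma2, intercepts).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  meta <- config$design
  design <- build_design(meta)
  G <- config$n_genes; n <- nrow(meta)
  gid <- sprintf("G%05d", seq_len(G))

  set.seed(child_seed(config$seed, 1))
  intercept <- stats::rnorm(G, config$intercept_mean, config$intercept_sd)

  set.seed(child_seed(config$seed, 2))
  latent <- matrix(intercept, G, n)
  for (zn in names(design$Z)) {
    Z <- design$Z[[zn]]
    sds <- sqrt(config$delta[design$param[[zn]]])
    sds[is.na(sds)] <- 0   # parameters absent from config carry no effect
    B <- matrix(stats::rnorm(G * ncol(Z)), G, ncol(Z)) *
         rep(sds, each = G)
    latent <- latent + B %*% t(Z)
  }
  groups <- residual_groups(meta, config$residual_model)
  set.seed(child_seed(config$seed, 3))
  latent <- latent + matrix(stats::rnorm(G * n), G, n) *
            rep(sqrt(config$sigma2[groups]), each = G)

  set.seed(child_seed(config$seed, 4))
  gene_lengths <- pmax(round(stats::rlnorm(G, log(1500), 0.4)), 200)
  size_factors <- stats::rlnorm(n, 0, config$size_factor_sd)
  library_sizes <- round(size_factors * config$base_library_size)

  mu <- 2^latent * (gene_lengths / 1e3) %o% (library_sizes / 1e6)
  a0 <- config$nb_trend[["a0"]]; a1 <- config$nb_trend[["a1"]]
  alpha <- pmax(a0 / mu + a1, 1e-8)
  set.seed(child_seed(config$seed, 5))
  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = 1 / alpha), G, n,
                   dimnames = list(gid, meta$sample_id))
  dimnames(latent) <- dimnames(counts)

  cm <- expression_matrix(counts, "counts", gene_lengths, library_sizes)
  fpkm <- compute_fpkm(cm)
  list(counts = cm, fpkm = fpkm, log2fpkm = log_transform(fpkm),
       meta = meta, design = design,
       gene_lengths = stats::setNames(gene_lengths, gid),
       library_sizes = stats::setNames(library_sizes, meta$sample_id),
       size_factors = stats::setNames(size_factors, meta$sample_id),
       truth = list(latent = latent, delta = config$delta,
                    sigma2 = config$sigma2, intercept = intercept,
                    residual_model = config$residual_model))
}

#' Simulate a three-way (adult, iPSC, ESC) count triple with known categories
#'
#' Categories are assigned in exact proportions. Non-null categories shift
#' class means by the effect size: CR shifts the adult mean; TM shifts the
#' ESC mean; AR shifts the iPSC mean; CX places all three apart, with the
#' iPSC mean strictly between adult and ESC for half the CX genes (PTM
#' truth) and outside for the other half (PAR truth).
#'
#' @param n_genes number of genes.
#' @param n_per_class named sample counts, default c(adult = 6, iPSC = 9,
#'   ESC = 4).
#' @param depth baseline mean count per gene (default 500).
#' @param proportions named true category fractions over IE, CR, TM, AR, CX
#'   (must sum to 1).
#' @param effect_log2fc log2 effect size for non-null categories (default 2,
#'   i.e. 4-fold).
#' @param nb_trend dispersion trend `c(a0, a1)` (defaults 1, 0.01).
#' @param size_factor_sd log-normal spread of size factors.
#' @param seed RNG seed.
#' @return list: `counts` (genes x samples), `class` (per-sample labels),
#'   `size_factors` (true), `truth` (`data.frame` gene_id, category — with
#'   CX split into PTM/PAR —, sign), `means` (true class means).
#' @export
simulate_three_way_counts <- function(n_genes,
                                      n_per_class = c(adult = 6, iPSC = 9, ESC = 4),
                                      depth = 500,
                                      proportions = c(IE = 0.97, CR = 0.01,
                                                      TM = 0.01, AR = 0.005,
                                                      CX = 0.005),
                                      effect_log2fc = 2,
                                      nb_trend = c(a0 = 1, a1 = 0.01),
                                      size_factor_sd = 0.1, seed = 1) {
  if (n_genes <= 0) stop("n_genes must be positive")
  proportions <- proportions[c("IE", "CR", "TM", "AR", "CX")]
  proportions[is.na(proportions)] <- 0
  names(proportions) <- c("IE", "CR", "TM", "AR", "CX")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  cum <- round(cumsum(proportions) * n_genes)
  n_cat <- diff(c(0, cum))
  category <- rep(names(proportions), n_cat)

  set.seed(child_seed(seed, 1))
  G <- n_genes
  base <- depth * 2^stats::rnorm(G, 0, 0.5)
  sgn <- sample(c(-1, 1), G, replace = TRUE)
  e <- effect_log2fc
  qA <- qI <- qE <- base
  shift <- function(b, s) b * 2^(s * e)
  i <- category == "CR"; qA[i] <- shift(base[i], sgn[i])
  i <- category == "TM"; qE[i] <- shift(base[i], sgn[i])
  i <- category == "AR"; qI[i] <- shift(base[i], sgn[i])
  cxi <- which(category == "CX")
  subtype <- category
  if (length(cxi) > 0) {
    ptm <- cxi[seq_len(ceiling(length(cxi) / 2))]
    par_ <- setdiff(cxi, ptm)
    subtype[ptm] <- "PTM"; subtype[par_] <- "PAR"
    qA[cxi] <- shift(base[cxi], sgn[cxi])
    qE[cxi] <- shift(base[cxi], -sgn[cxi])
    qI[ptm] <- base[ptm]                       # strictly between A and E
    qI[par_] <- base[par_] * 2^(2 * e * sgn[par_])  # outside the interval
  }
  class <- rep(names(n_per_class), n_per_class)
  m <- length(class)
  set.seed(child_seed(seed, 2))
  sf <- stats::rlnorm(m, 0, size_factor_sd)
  qmat <- cbind(adult = qA, iPSC = qI, ESC = qE)
  mu <- qmat[, class] * rep(sf, each = G)
  a0 <- nb_trend[["a0"]]; a1 <- nb_trend[["a1"]]
  alpha <- pmax(a0 / mu + a1, 1e-8)
  set.seed(child_seed(seed, 3))
  counts <- matrix(stats::rnbinom(G * m, mu = mu, size = 1 / alpha), G, m,
                   dimnames = list(sprintf("G%05d", seq_len(G)),
                                   sprintf("%s_%d", class, seq_len(m))))
  list(counts = counts, class = class, size_factors = sf,
       truth = data.frame(gene_id = rownames(counts), category = category,
                          subtype = subtype, sign = sgn,
                          stringsAsFactors = FALSE),
       means = qmat)
}

#' Simulate phased allelic counts with imprinting states
#'
#' Per donor and gene, heterozygous SNP counts are generated for one adult
#' sample and several derived iPSC lines: the total per SNP is Poisson and
#' the paternal (haplotype 1) count binomial with the class's true paternal
#' fraction. A matching phased VCF table ("0|1" at every het site, haplotype
#' 1 = reference = paternal) is returned.
#'
#' @param imprinting_spec `data.frame`: `gene_id`, `p_adult`, `p_ipsc` (true
#'   paternal fractions per cell class).
#' @param donors donor ids (default S2, S4, S7).
#' @param n_ipsc_lines derived iPSC lines per donor (default 4).
#' @param depth expected total coverage per (sample, gene) (default 100).
#' @param n_snps heterozygous SNPs per gene (default 3).
#' @param seed RNG seed.
#' @return list: `counts` (allelic count table: sample_id, gene_id, snp_id,
#'   hap1_count, hap2_count), `samples` (sample_id, donor, cell_class),
#'   `sites`, `genotypes` (inputs for [write_phased_vcf()]), `truth`
#'   (the spec).
#' @export
simulate_allelic_counts <- function(imprinting_spec, donors = c("S2", "S4", "S7"),
                                    n_ipsc_lines = 4, depth = 100, n_snps = 3,
                                    seed = 1) {
  stopifnot(all(c("gene_id", "p_adult", "p_ipsc") %in% names(imprinting_spec)))
  samples <- do.call(rbind, lapply(donors, function(d) {
    data.frame(sample_id = c(paste0("adult-", d),
                             sprintf("iPSC-%s-%d", d, seq_len(n_ipsc_lines))),
               donor = d,
               cell_class = c("adult", rep("iPSC", n_ipsc_lines)),
               stringsAsFactors = FALSE)
  }))
  genes <- imprinting_spec$gene_id
  sites <- data.frame(
    chrom = "chr1",
    pos = as.integer(1e6 + seq_len(length(genes) * n_snps) * 1000L),
    snp_id = as.vector(t(outer(genes, seq_len(n_snps),
                               function(g, k) sprintf("%s_snp%d", g, k)))),
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  gt <- matrix("0|1", nrow(sites), length(donors),
               dimnames = list(NULL, donors))
  set.seed(child_seed(seed, 1))
  rows <- list()
  for (si in seq_len(nrow(samples))) {
    s <- samples[si, ]
    p <- if (s$cell_class == "adult") imprinting_spec$p_adult
         else imprinting_spec$p_ipsc
    for (gi in seq_along(genes)) {
      tot <- stats::rpois(n_snps, depth / n_snps)
      pat <- stats::rbinom(n_snps, tot, p[gi])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s$sample_id, gene_id = genes[gi],
        snp_id = sprintf("%s_snp%d", genes[gi], seq_len(n_snps)),
        hap1_count = pat, hap2_count = tot - pat,
        stringsAsFactors = FALSE)
    }
  }
  list(counts = do.call(rbind, rows), samples = samples,
       sites = sites, genotypes = gt, truth = imprinting_spec)
}

#' Simulate eSNP genotypes and expression with a known variance fraction
#'
#' Per gene, donor genotypes (dosage of the high-expression allele) are drawn
#' binomially at the given allele frequency (monomorphic draws rejected), and
#' donor-level expression is beta x dosage + N(0, sigma_e^2) with beta set so
#' that var(beta G) / (var(beta G) + sigma_e^2) equals `fraction` at the
#' population genotype variance 2 maf (1 - maf). Line-level samples add small
#' replicate noise.
#'
#' @param n_genes number of eQTL genes.
#' @param fraction true fraction of donor variance explained by dosage.
#' @param donors donor ids (default S2, S4, S5, S7).
#' @param maf high-expression-allele frequency (default 0.3).
#' @param sigma_e donor-level residual sd (default 1).
#' @param n_lines_per_donor iPSC lines per donor (default 6).
#' @param sigma_line line-level replicate sd (default 0.2).
#' @param seed RNG seed.
#' @return list: `expr` (genes x samples log2 expression), `meta`
#'   (sample_id, donor), `eqtls` (gene_id, esnp_id, chrom, pos, high_allele,
#'   ascert_p, one dosage column per donor), `truth` (beta, fraction,
#'   genotypes).
#' @export
simulate_eqtl <- function(n_genes, fraction, donors = c("S2", "S4", "S5", "S7"),
                          maf = 0.3, sigma_e = 1, n_lines_per_donor = 6,
                          sigma_line = 0.2, seed = 1) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  nd <- length(donors)
  set.seed(child_seed(seed, 1))
  G <- n_genes
  geno <- matrix(stats::rbinom(G * nd, 2, maf), G, nd,
                 dimnames = list(sprintf("E%05d", seq_len(G)), donors))
  for (g in seq_len(G)) {
    tries <- 0
    while (length(unique(geno[g, ])) < 2 && tries < 100) {
      geno[g, ] <- stats::rbinom(nd, 2, maf)
      tries <- tries + 1
    }
  }
  # per-gene effect scaled to the realized donor genotype variance, so
  # var(beta G) / (var(beta G) + sigma_e^2) equals `fraction` exactly per gene
  vg <- apply(geno, 1, stats::var)
  beta <- if (fraction >= 1) {
    if (sigma_e > 0) stop("fraction 1 requires sigma_e = 0")
    rep(1, G)
  } else sigma_e * sqrt(fraction / ((1 - fraction) * vg))
  if (fraction == 0) beta <- rep(0, G)
  set.seed(child_seed(seed, 2))
  donor_val <- beta * geno + matrix(stats::rnorm(G * nd, 0, sigma_e), G, nd)
  meta <- data.frame(
    sample_id = as.vector(t(outer(donors, seq_len(n_lines_per_donor),
                                  function(d, l) sprintf("iPSC-%s-%d", d, l)))),
    donor = rep(donors, each = n_lines_per_donor),
    stringsAsFactors = FALSE)
  set.seed(child_seed(seed, 3))
  expr <- donor_val[, meta$donor, drop = FALSE] +
          matrix(stats::rnorm(G * nrow(meta), 0, sigma_line), G, nrow(meta))
  colnames(expr) <- meta$sample_id
  rownames(expr) <- rownames(geno)
  set.seed(child_seed(seed, 4))
  eqtls <- data.frame(gene_id = rownames(geno),
                      esnp_id = sprintf("rs%06d", seq_len(G)),
                      chrom = "chr1", pos = seq_len(G) * 1000L,
                      high_allele = "ALT",
                      ascert_p = 10^(-stats::runif(G, 2, 20)),
                      stringsAsFactors = FALSE)
  eqtls <- cbind(eqtls, as.data.frame(geno))
  list(expr = expr, meta = meta, eqtls = eqtls,
       truth = list(beta = beta, fraction = fraction, genotypes = geno))
}
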