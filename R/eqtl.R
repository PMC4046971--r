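# Replication of externally ascertained eQTLs in iPSC expression.
#
# With only four donors, per-gene inference is meaningless; every statistic
# here is pooled across genes (directional concordance of genotype with
# expression, allelic imbalance at heterozygous eSNPs, and mean variance
# explained by lead-eSNP dosage).

#' Pooled genotype-expression concordance at ascertained eQTLs
#'
#' iPSC expression is averaged within donor (genotype is a donor property),
#' standardized per gene, pooled across genes and correlated with the dosage
#' of the ascertained high-expression allele.
#'
#' @param expr genes x samples log2 FPKM matrix (iPSC samples).
#' @param eqtls `data.frame`: `gene_id`, `esnp_id`, plus dosage columns (one
#'   per donor, named by donor) giving the count of the high-expression
#'   allele (0/1/2).
#' @param meta sample metadata for the expression columns (`sample_id`,
#'   `donor`).
#' @return list: `r`, `p` (pooled Pearson correlation test), `slopes`
#'   (per-gene sign of the dosage regression slope), `n_genes`,
#'   `n_dropped` (genes monomorphic across donors or absent from `expr`).
#' @export
genotype_expression_concordance <- function(expr, eqtls, meta) {
  prep <- eqtl_donor_means(expr, eqtls, meta)
  if (prep$n_genes == 0) stop("no testable genes (all monomorphic or missing)")
  # standardize both expression and dosage per gene so every gene contributes
  # equally and a perfect linear relationship pools to r = 1
  z <- t(scale(t(prep$means)))
  g <- t(scale(t(prep$dosage)))
  ct <- stats::cor.test(as.numeric(z), as.numeric(g))
  slopes <- vapply(seq_len(nrow(prep$means)), function(i) {
    sign(stats::cov(prep$dosage[i, ], prep$means[i, ]))
  }, 0)
  list(r = unname(ct$estimate), p = ct$p.value, slopes = slopes,
       n_genes = prep$n_genes, n_dropped = prep$n_dropped)
}

# donor-mean expression and dosage matrices aligned over testable genes
eqtl_donor_means <- function(expr, eqtls, meta) {
  donors <- sort(unique(meta$donor))
  dos_cols <- intersect(donors, names(eqtls))
  if (length(dos_cols) < 2) stop("eQTL table lacks dosage columns for the donors")
  dmeans <- sapply(dos_cols, function(d)
    rowMeans(expr[, meta$sample_id[meta$donor == d], drop = FALSE]))
  keep <- eqtls$gene_id %in% rownames(expr)
  eq <- eqtls[keep, , drop = FALSE]
  dosage <- as.matrix(eq[, dos_cols, drop = FALSE])
  if (any(!dosage %in% 0:2)) stop("dosages must be 0, 1 or 2")
  poly <- apply(dosage, 1, function(g) length(unique(g)) >= 2)
  expr_sd <- apply(dmeans[eq$gene_id, , drop = FALSE], 1, stats::sd)
  ok <- poly & expr_sd > 0
  list(means = dmeans[eq$gene_id[ok], , drop = FALSE],
       dosage = dosage[ok, , drop = FALSE],
       gene_id = eq$gene_id[ok],
       n_genes = sum(ok), n_dropped = sum(!keep) + sum(!ok))
}

#' Allelic imbalance at heterozygous eSNPs
#'
#' For donors heterozygous at an ascertained eSNP, the gene's phased ASE is
#' oriented to the high-expression haplotype; per-gene high-haplotype read
#' fractions (averaged over heterozygous donors with coverage weights) are
#' tested against 0.5 with a one-sample t-test across genes.
#'
#' @param fractions per-gene high-expression-haplotype read fraction (already
#'   oriented and aggregated; one value per gene).
#' @return list: `mean_fraction`, `t`, `p` (one-sample t vs 0.5), `n_genes`.
#' @export
allelic_imbalance_at_esnps <- function(fractions) {
  fractions <- fractions[is.finite(fractions)]
  if (length(fractions) < 2)
    stop("t-test undefined with fewer than 2 genes")
  if (stats::sd(fractions) == 0) {
    # degenerate spread: t is 0 when centered on the null, infinite otherwise
    off <- mean(fractions) - 0.5
    return(list(mean_fraction = mean(fractions),
                t = if (off == 0) 0 else sign(off) * Inf,
                p = if (off == 0) 1 else 0, n_genes = length(fractions)))
  }
  tt <- stats::t.test(fractions, mu = 0.5)
  list(mean_fraction = mean(fractions), t = unname(tt$statistic),
       p = tt$p.value, n_genes = length(fractions))
}

#' Orient gene-level ASE to the high-expression haplotype of an eSNP
#'
#' @param ase gene-level ASE rows (donor-heterozygous samples), with `ai`
#'   being the haplotype-1 fraction.
#' @param high_on_hap1 logical per row: is the high-expression allele on
#'   haplotype 1 for that sample's donor?
#' @return numeric vector of high-haplotype fractions, per row.
#' @export
orient_to_high_haplotype <- function(ase, high_on_hap1) {
  ifelse(high_on_hap1, ase$ai, 1 - ase$ai)
}

#' Variance explained by lead eSNP dosage
#'
#' Per gene, ordinary least squares of donor-mean expression on dosage. With
#' four donors the raw per-gene R^2 is strongly biased upward (E\[R^2\] =
#' 1/(n-1) under the null), so the headline figure `mean_ve` pools unbiased
#' variance components across genes before taking the ratio:
#' 1 - mean_g(RSS_g/(n-2)) / mean_g(TSS_g/(n-1)). The raw mean R^2, the
#' per-gene small-sample-adjusted R^2 and a permutation null mean are
#' reported alongside for reference.
#'
#' @inheritParams genotype_expression_concordance
#' @param n_null_perm dosage permutations for the null reference
#'   (default 1000, pooled over genes).
#' @param seed RNG seed for the permutation null.
#' @return list: `mean_ve` (pooled variance-explained estimate), `mean_r2`,
#'   `mean_adj_r2`, `null_mean_r2`, `r2` (per-gene raw), `adj_r2`,
#'   `n_genes`.
#' @export
esnp_variance_explained <- function(expr, eqtls, meta, n_null_perm = 1000,
                                    seed = 1) {
  prep <- eqtl_donor_means(expr, eqtls, meta)
  if (prep$n_genes == 0) stop("no testable genes")
  nd <- ncol(prep$means)
  if (nd < 3) stop("need at least 3 donors for the dosage regression")
  r2_of <- function(y, g) {
    if (stats::sd(g) == 0) return(NA_real_)
    stats::cor(y, g)^2
  }
  r2 <- vapply(seq_len(prep$n_genes), function(i)
    r2_of(prep$means[i, ], prep$dosage[i, ]), 0)
  adj <- 1 - (1 - r2) * (nd - 1) / (nd - 2)
  tss <- apply(prep$means, 1, function(y) sum((y - mean(y))^2))
  rss <- (1 - r2) * tss
  mean_ve <- 1 - mean(rss / (nd - 2)) / mean(tss / (nd - 1))
  set.seed(seed)
  null_r2 <- replicate(n_null_perm, {
    i <- sample.int(prep$n_genes, 1)
    r2_of(prep$means[i, ], sample(prep$dosage[i, ]))
  })
  list(mean_ve = mean_ve, mean_r2 = mean(r2, na.rm = TRUE),
       mean_adj_r2 = mean(adj, na.rm = TRUE),
       null_mean_r2 = mean(null_r2, na.rm = TRUE),
       r2 = r2, adj_r2 = adj, n_genes = prep$n_genes)
}

#' Donor variance explained in top vs bottom ascertainment-p gene strata
#'
#' Runs the variance-component fit separately on the genes with the
#' strongest and weakest ascertainment p-values and reports the donor-iPSC
#' variance explained in each stratum.
#'
#' @param expr genes x samples log2 FPKM over the iPSC (and other) samples.
#' @param design a `design_set` over those samples.
#' @param ascertainment_p named per-gene ascertainment p-values.
#' @param k stratum size (default: half the genes, capped at 3000).
#' @param ... passed to [fit_mixed_model()].
#' @return list: `ve_top`, `ve_bottom` (donor-iPSC variance explained),
#'   `fit_top`, `fit_bottom`, `k`.
#' @export
stratified_donor_ve <- function(expr, design, ascertainment_p, k = NULL, ...) {
  genes <- intersect(names(ascertainment_p), rownames(expr))
  if (is.null(k)) k <- min(3000L, floor(length(genes) / 2))
  if (k < 2) stop("too few genes to stratify")
  ord <- genes[order(ascertainment_p[genes])]
  top <- ord[seq_len(k)]
  bottom <- rev(ord)[seq_len(k)]
  fit_top <- fit_mixed_model(expr[top, , drop = FALSE], design, ...)
  fit_bottom <- fit_mixed_model(expr[bottom, , drop = FALSE], design, ...)
  list(ve_top = variance_explained(fit_top, "donor_ipsc"),
       ve_bottom = variance_explained(fit_bottom, "donor_ipsc"),
       fit_top = fit_top, fit_bottom = fit_bottom, k = k)
}
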