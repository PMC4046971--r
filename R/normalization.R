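#' Compute FPKM from fragment counts
#'
#' FPKM\[g, i\] = counts\[g, i\] / (gene length in kb x library size in
#' millions of mapped fragments).
#'
#' @param counts genes x samples count matrix (or `expression_matrix`).
#' @param gene_lengths per-gene exonic length in bp (> 0).
#' @param library_sizes per-sample mapped fragments (> 0).
#' @return an `expression_matrix` of kind `"fpkm"`.
#' @export
compute_fpkm <- function(counts, gene_lengths = NULL, library_sizes = NULL) {
  if (inherits(counts, "expression_matrix")) {
    if (is.null(gene_lengths)) gene_lengths <- counts$gene_lengths
    if (is.null(library_sizes)) library_sizes <- counts$library_sizes
    counts <- counts$values
  }
  if (is.null(gene_lengths) || is.null(library_sizes))
    stop("gene_lengths and library_sizes are required for FPKM")
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  fpkm <- counts / (gene_lengths / 1e3)
  fpkm <- sweep(fpkm, 2, library_sizes / 1e6, "/")
  expression_matrix(fpkm, "fpkm", gene_lengths, library_sizes)
}

#' log2-transform an FPKM matrix
#'
#' @param fpkm FPKM matrix or `expression_matrix`.
#' @param pseudocount added before the log (default 1, so an FPKM of 0 maps
#'   to 0 and an FPKM of 1 maps to 1).
#' @return an `expression_matrix` of kind `"log2fpkm"`.
#' @export
log_transform <- function(fpkm, pseudocount = 1) {
  gl <- NULL; ls <- NULL
  if (inherits(fpkm, "expression_matrix")) {
    gl <- fpkm$gene_lengths; ls <- fpkm$library_sizes; fpkm <- fpkm$values
  }
  expression_matrix(log2(fpkm + pseudocount), "log2fpkm", gl, ls)
}

#' GC-content bias profile and spline correction
#'
#' Genes are binned by GC fraction into approximately equal-occupancy bins.
#' For sample i and bin l, the relative enrichment is
#' F_il = (sample i's share of counts in bin l) / (pooled share in bin l).
#' A cubic smoothing spline of log2 F_il against bin-mean GC is fitted per
#' sample and counts are divided by the predicted enrichment at each gene's
#' GC, then rescaled to preserve each sample's total.
#'
#' @param counts genes x samples count matrix.
#' @param gene_gc per-gene GC fraction in (0, 1).
#' @param n_bins number of GC bins (default 25).
#' @param spline_df degrees of freedom of the smoothing spline (default 5).
#' @return list: `corrected` (count matrix), `profile` (list with `bin_gc`,
#'   `F` — samples in columns —, `bin_edges`), `enrichment` (genes x samples
#'   predicted enrichment).
#' @export
gc_correction <- function(counts, gene_gc, n_bins = 25, spline_df = 5) {
  stopifnot(length(gene_gc) == nrow(counts))
  if (any(gene_gc <= 0 | gene_gc >= 1)) stop("GC fractions must lie in (0,1)")
  edges <- unique(stats::quantile(gene_gc, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(edges) < 3) {
    # single usable bin: correction degenerates to a global scalar
    bin <- rep(1L, length(gene_gc))
  } else {
    bin <- cut(gene_gc, edges, include.lowest = TRUE, labels = FALSE)
  }
  nb <- max(bin)
  tot_i <- colSums(counts)
  bin_counts <- rowsum(counts, bin)                  # bins x samples
  # merge empty bins (no pooled counts) with the previous bin
  pooled <- rowSums(bin_counts)
  if (any(pooled == 0)) {
    empty <- which(pooled == 0)
    message(length(empty), " empty GC bin(s) merged with neighbors")
    for (e in empty) bin[bin == e] <- if (e > 1) e - 1L else e + 1L
    bin <- as.integer(factor(bin))
    nb <- max(bin)
    bin_counts <- rowsum(counts, bin)
    pooled <- rowSums(bin_counts)
  }
  share <- sweep(bin_counts, 2, tot_i, "/")
  pooled_share <- pooled / sum(tot_i)
  Fil <- sweep(share, 1, pooled_share, "/")          # bins x samples
  bin_gc <- tapply(gene_gc, bin, mean)
  enrich <- matrix(1, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  if (nb >= 4) {
    for (i in seq_len(ncol(counts))) {
      sp <- stats::smooth.spline(bin_gc, log2(pmax(Fil[, i], 1e-8)),
                                 df = min(spline_df, nb - 1))
      enrich[, i] <- 2^stats::predict(sp, gene_gc)$y
    }
  } else {
    enrich <- matrix(rep(2^colMeans(log2(pmax(Fil, 1e-8))), each = nrow(counts)),
                     nrow(counts), ncol(counts), dimnames = dimnames(counts))
  }
  corrected <- counts / enrich
  corrected <- sweep(corrected, 2, tot_i / colSums(corrected), "*")
  list(corrected = corrected,
       profile = list(bin_gc = as.numeric(bin_gc), F = Fil, bin = bin),
       enrichment = enrich)
}

#' Two-component Gaussian mixture over expression levels
#'
#' Fits a two-component normal mixture to a per-sample vector of
#' log10(FPKM + 1) by EM and returns the posterior probability that each gene
#' belongs to the lower-mean ("repressed") component. The EM log-likelihood is
#' checked to be non-decreasing at every iteration.
#'
#' @param x numeric vector (one sample's log-expression values).
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter iteration cap.
#' @return list: `posterior_repressed`, `means`, `sds`, `weights` (ordered
#'   repressed then active), `loglik`, `loglik_trace`, `n_iter`.
#' @export
expression_mode_mixture <- function(x, tol = 1e-8, max_iter = 2000) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 3 || stats::sd(x) == 0)
    stop("no mixture: degenerate input")
  q <- stats::quantile(x, c(0.25, 0.75))
  mu <- as.numeric(q); if (mu[1] == mu[2]) mu <- mu + c(-1, 1) * stats::sd(x) / 2
  sg <- rep(max(stats::sd(x) / 2, 1e-3), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf; trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # log-space E step so extreme tail points stay numerically finite
    l1 <- log(w[1]) + stats::dnorm(x, mu[1], sg[1], log = TRUE)
    l2 <- log(w[2]) + stats::dnorm(x, mu[2], sg[2], log = TRUE)
    lmax <- pmax(l1, l2)
    ltot <- lmax + log(exp(l1 - lmax) + exp(l2 - lmax))
    ll <- sum(ltot)
    if (ll < ll_old - 1e-6 * max(1, abs(ll_old)))
      stop("EM log-likelihood decreased; numerical failure")
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    g1 <- exp(l1 - ltot)
    n1 <- sum(g1); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) stop("no mixture: a component vanished")
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    sg <- sqrt(pmax(c(sum(g1 * (x - mu[1])^2) / n1,
                      sum((1 - g1) * (x - mu[2])^2) / n2), 1e-6))
    w <- c(n1, n2) / length(x)
  }
  # order components so the first is the repressed (lower-mean) mode
  ord <- order(mu)
  l1 <- log(w[ord[1]]) + stats::dnorm(x, mu[ord[1]], sg[ord[1]], log = TRUE)
  l2 <- log(w[ord[2]]) + stats::dnorm(x, mu[ord[2]], sg[ord[2]], log = TRUE)
  lmax <- pmax(l1, l2)
  list(posterior_repressed = exp(l1 - lmax) / (exp(l1 - lmax) + exp(l2 - lmax)),
       means = mu[ord], sds = sg[ord], weights = w[ord],
       loglik = trace[length(trace)], loglik_trace = trace, n_iter = length(trace))
}

#' Sample correlation matrix and complete-linkage leaf order
#'
#' Pearson correlation between samples over all genes; hierarchical clustering
#' of the distance 1 - r with complete linkage. Samples are processed in
#' lexicographic id order so the leaf order is deterministic under ties.
#'
#' @param log2fpkm genes x samples matrix or `expression_matrix`.
#' @return list: `cor` (sample correlation matrix), `order` (leaf order,
#'   sample ids), `hclust` (the clustering object).
#' @export
correlation_heatmap_order <- function(log2fpkm) {
  m <- if (inherits(log2fpkm, "expression_matrix")) log2fpkm$values else log2fpkm
  m <- m[, order(colnames(m)), drop = FALSE]
  r <- stats::cor(m)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "complete")
  list(cor = r, order = colnames(m)[hc$order], hclust = hc)
}

#' Per-gene precision from replicate groups
#'
#' tau_j = 1 / (pooled within-group variance of gene j's log2 FPKM).
#' Genes with zero pooled variance would give infinite precision; their tau is
#' capped at the 99th percentile of the finite values.
#'
#' @param log2fpkm genes x samples matrix.
#' @param groups replicate-group label per sample.
#' @param cap_quantile quantile used for capping (default 0.99).
#' @return numeric vector `tau` (per gene), with attribute `capped` (logical).
#' @export
gene_precision <- function(log2fpkm, groups, cap_quantile = 0.99) {
  m <- if (inherits(log2fpkm, "expression_matrix")) log2fpkm$values else log2fpkm
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(m))
  ss <- 0; df <- 0
  for (g in levels(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    sub <- m[, cols, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + length(cols) - 1
  }
  if (df == 0) stop("no replicate group has >= 2 samples")
  v <- ss / df
  tau <- 1 / v
  finite <- is.finite(tau)
  if (!any(finite)) stop("all genes have zero within-group variance")
  cap <- stats::quantile(tau[finite], cap_quantile)
  capped <- !finite | tau > cap
  tau[capped] <- cap
  attr(tau, "capped") <- capped
  tau
}

#' Drop the top-percentile most highly expressed genes
#'
#' @param m genes x samples matrix or `expression_matrix`.
#' @param percentile percentage of genes to remove from the top by mean
#'   expression (0 = identity).
#' @return the matrix without the top-k genes (k = floor(G * percentile/100)).
#' @export
filter_top_expressed <- function(m, percentile) {
  em <- NULL
  if (inherits(m, "expression_matrix")) { em <- m; m <- m$values }
  k <- floor(nrow(m) * percentile / 100)
  if (k > 0) {
    drop <- order(rowMeans(m), decreasing = TRUE)[seq_len(k)]
    m <- m[-drop, , drop = FALSE]
  }
  if (!is.null(em))
    return(expression_matrix(m, em$value_kind,
                             em$gene_lengths[rownames(m)], em$library_sizes))
  m
}
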