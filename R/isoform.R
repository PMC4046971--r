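# Splicing-memory test on the ratio of the top two isoforms.
#
# Per gene, the count of the most abundant isoform out of the top-two total
# is modeled beta-binomially with an isoform-1 fraction p per sample class
# and a per-gene overdispersion rho shared across classes. The same five
# constraint patterns as the expression classifier apply to p, with LR
# chi-square p-values and permutation FDR. Only genes where two independent
# quantifiers agree on the top-two isoform ranking are tested.

#' Quantifier-agreement filter for the top two isoforms
#'
#' @param q1,q2 `data.frame`s with columns `gene_id`, `transcript_id`,
#'   `abundance` (mean abundance per transcript from each quantifier).
#' @return list: `genes` (gene ids where both quantifiers rank the same two
#'   transcripts in the same order, genes with >= 2 transcripts only),
#'   `n_excluded` (genes with >= 2 transcripts whose ranking disagrees).
#' @export
isoform_agreement <- function(q1, q2) {
  top2 <- function(df) {
    df <- df[order(df$gene_id, -df$abundance, df$transcript_id), ]
    sp <- split(df$transcript_id, df$gene_id)
    sp <- sp[vapply(sp, length, 1L) >= 2]
    lapply(sp, utils::head, 2)
  }
  t1 <- top2(q1); t2 <- top2(q2)
  shared <- intersect(names(t1), names(t2))
  agree <- vapply(shared, function(g) identical(t1[[g]], t2[[g]]), TRUE)
  list(genes = shared[agree], n_excluded = sum(!agree))
}

# beta-binomial log pmf with fraction p and overdispersion rho
bb_logpmf <- function(x, n, p, rho) {
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  if (rho < 1e-8) return(stats::dbinom(x, n, p, log = TRUE))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}

# ML isoform-1 fraction for one merged class (1-D optimization on p)
bb_ml_p <- function(x, n, rho) {
  if (sum(n) == 0) return(0.5)
  p0 <- sum(x) / sum(n)
  if (rho < 1e-8) return(p0)
  opt <- stats::optimize(function(p) -sum(bb_logpmf(x, n, p, rho)),
                         interval = c(1e-6, 1 - 1e-6), tol = 1e-9)
  opt$minimum
}

# moment estimate of rho from within-class spread of per-sample fractions
bb_mom_rho <- function(x, n, class) {
  f <- x / pmax(n, 1)
  num <- 0; den <- 0; binom <- 0
  for (cl in unique(class)) {
    ix <- which(class == cl & n > 0)
    if (length(ix) < 2) next
    p <- mean(f[ix])
    if (p <= 0 || p >= 1) next
    num <- num + sum((f[ix] - p)^2)
    den <- den + (length(ix) - 1) * p * (1 - p) * (1 - mean(1 / n[ix]))
    binom <- binom + (length(ix) - 1) * p * (1 - p) * mean(1 / n[ix])
  }
  if (den <= 0) return(1e-8)
  rho <- (num - binom) / den
  min(max(rho, 1e-8), 0.9)
}

#' Classify genes by three-way top-two-isoform-ratio outcome
#'
#' @param x genes x samples counts of the most abundant isoform.
#' @param n genes x samples totals of the top two isoforms.
#' @param class per-sample class (`"adult"`, `"iPSC"`, `"ESC"`).
#' @param rho optional per-gene overdispersion (default: moment estimate
#'   under the full-means model, held fixed across hypothesis fits).
#' @param p_threshold optional min-p threshold for immediate category
#'   assignment.
#' @return a `gene_classification`-style `data.frame` with log-likelihoods,
#'   p-values, `min_p`, fitted fractions `p_A`, `p_I`, `p_E`, `rho`,
#'   `best_alt`, `category`.
#' @export
isoform_ratio_classify <- function(x, n, class, rho = NULL, p_threshold = NULL) {
  stopifnot(all(dim(x) == dim(n)), ncol(x) == length(class), all(x <= n))
  class <- as.character(class)
  G <- nrow(x)
  if (is.null(rho))
    rho <- vapply(seq_len(G), function(g) bb_mom_rho(x[g, ], n[g, ], class), 0)
  merged <- list(A = "adult", I = "iPSC", E = "ESC",
                 AI = c("adult", "iPSC"), AE = c("adult", "ESC"),
                 IE = c("iPSC", "ESC"), AIE = c("adult", "iPSC", "ESC"))
  fit_ll <- function(g, cl) {
    ix <- which(class %in% cl)
    p <- bb_ml_p(x[g, ix], n[g, ix], rho[g])
    c(ll = sum(bb_logpmf(x[g, ix], n[g, ix], p, rho[g])), p = p)
  }
  ll <- matrix(NA_real_, G, length(merged), dimnames = list(NULL, names(merged)))
  pfit <- matrix(NA_real_, G, 3, dimnames = list(NULL, c("A", "I", "E")))
  for (g in seq_len(G)) {
    for (nm in names(merged)) {
      r <- fit_ll(g, merged[[nm]])
      ll[g, nm] <- r["ll"]
      if (nm %in% c("A", "I", "E")) pfit[g, nm] <- r["p"]
    }
  }
  out <- data.frame(
    gene_id = rownames(x) %||% as.character(seq_len(G)),
    ll_H0 = ll[, "AIE"],
    ll_CR = ll[, "A"] + ll[, "IE"],
    ll_TM = ll[, "AI"] + ll[, "E"],
    ll_AR = ll[, "AE"] + ll[, "I"],
    ll_CX = ll[, "A"] + ll[, "I"] + ll[, "E"],
    p_A = pfit[, "A"], p_I = pfit[, "I"], p_E = pfit[, "E"],
    rho = rho, stringsAsFactors = FALSE
  )
  for (k in names(triple_df)) {
    lr <- pmax(2 * (out[[paste0("ll_", k)]] - out$ll_H0), 0)
    out[[paste0("p_", k)]] <- stats::pchisq(lr, df = triple_df[k],
                                            lower.tail = FALSE)
  }
  pm <- as.matrix(out[, paste0("p_", names(triple_df))])
  out$min_p <- apply(pm, 1, min)
  llm <- as.matrix(out[, paste0("ll_", names(triple_df))])
  pick <- apply(cbind(pm, llm), 1, function(z) {
    p <- z[1:4]; l <- z[5:8]
    cand <- which(p == min(p))
    cand[which.max(l[cand])]
  })
  best <- names(triple_df)[pick]
  cx <- best == "CX"
  between <- (out$p_I > pmin(out$p_A, out$p_E)) &
             (out$p_I < pmax(out$p_A, out$p_E))
  best[cx] <- ifelse(between[cx], "PTM", "PAR")
  out$best_alt <- best
  out$category <- NA_character_
  class(out) <- c("gene_classification", "data.frame")
  if (!is.null(p_threshold)) out <- assign_categories(out, p_threshold)
  out
}

#' Isoform-ratio test with quantifier filter and permutation FDR
#'
#' @param x,n as in [isoform_ratio_classify()]; rows must be named by gene.
#' @param class per-sample class labels.
#' @param q1,q2 transcript-abundance tables for the agreement filter (omit
#'   both to test all genes).
#' @param n_perm,seed,target permutation FDR settings.
#' @return list: `classification`, `q`, `threshold`, `fdr_curve`,
#'   `n_significant`, `n_excluded_by_agreement`.
#' @export
isoform_ratio_test <- function(x, n, class, q1 = NULL, q2 = NULL,
                               n_perm = 100, seed = 1, target = 0.05) {
  n_excl <- 0L
  if (!is.null(q1) && !is.null(q2)) {
    ag <- isoform_agreement(q1, q2)
    keep <- rownames(x) %in% ag$genes
    n_excl <- sum(!keep)
    x <- x[keep, , drop = FALSE]
    n <- n[keep, , drop = FALSE]
  }
  if (nrow(x) == 0) stop("no genes left after the quantifier-agreement filter")
  cls <- isoform_ratio_classify(x, n, class)
  if (n_perm < 20) stop("n_perm must be at least 20 for a stable FDR estimate")
  perm_minp <- matrix(NA_real_, nrow(x), n_perm)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    pclass <- sample(class)
    perm_minp[, b] <- isoform_ratio_classify(x, n, pclass, rho = cls$rho)$min_p
  }
  res <- fdr_from_min_p(cls, cls$min_p, perm_minp, target)
  res$n_excluded_by_agreement <- n_excl
  res
}
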