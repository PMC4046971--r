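# Vectorized negative-binomial fitting across genes.
#
# Counts k_gi ~ NB(mean = s_i * mu_g, variance = m + alpha_g m^2). For fixed
# per-gene dispersion alpha and size factors s, the ML group mean solves
#   sum_i s_i (k_gi - m_gi) / (m_gi (1 + alpha_g m_gi)) = 0,  m_gi = s_i mu_g,
# which is found by damped Fisher scoring, vectorized over all genes at once
# (this is what makes permutation FDR over thousands of genes tractable).

# ML mean per gene for one group of samples.
# K: genes x m counts, sf: length-m size factors, alpha: per-gene dispersions.
nb_ml_mean <- function(K, sf, alpha, max_iter = 50, tol = 1e-10) {
  if (is.null(dim(K))) K <- matrix(K, ncol = length(sf))
  tot <- rowSums(K)
  mu <- tot / sum(sf)                      # Poisson ML start (exact at alpha=0)
  zero <- tot == 0
  mu[zero] <- 0
  act <- which(!zero)
  info <- rep(NA_real_, length(mu))
  if (length(act) > 0) {
    for (it in seq_len(max_iter)) {
      M <- mu[act] %o% sf
      W <- 1 / (M * (1 + alpha[act] * M))
      score <- rowSums(sweep((K[act, , drop = FALSE] - M) * W, 2, sf, "*"))
      fi <- rowSums(sweep(W, 2, sf^2, "*"))
      step <- score / fi
      # damp: never move by more than half the current mean downward
      step <- pmax(step, -mu[act] / 2)
      mu[act] <- mu[act] + step
      if (max(abs(step) / pmax(mu[act], 1e-8)) < tol) break
    }
    M <- mu[act] %o% sf
    info[act] <- rowSums(sweep(1 / (M * (1 + alpha[act] * M)), 2, sf^2, "*"))
  }
  # Fisher information for log2 mu (delta method): I_log2mu = mu^2 I_mu ln(2)^2
  attr(mu, "var_log2") <- 1 / (info * mu^2 * log(2)^2)
  mu
}

# pooled NB log-likelihood of a genes x m count block at per-gene mean mu
nb_block_loglik <- function(K, sf, alpha, mu) {
  if (is.null(dim(K))) K <- matrix(K, ncol = length(sf))
  M <- pmax(mu, 1e-12) %o% sf
  ll <- stats::dnbinom(K, size = 1 / pmax(alpha, 1e-8), mu = M, log = TRUE)
  # mu = 0 with all-zero counts: P = 1 exactly
  ll[mu == 0, ] <- 0
  rowSums(ll)
}

#' DESeq-style median-of-ratios size factors
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of size factors (geometric-mean normalized).
#' @export
size_factors <- function(counts) {
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) stop("no gene has all-positive counts; cannot compute size factors")
  sf <- apply(counts, 2, function(k) exp(stats::median((log(k) - logg)[use & k > 0])))
  sf / exp(mean(log(sf)))
}

#' Estimate per-gene NB dispersions with trend shrinkage
#'
#' Method-of-moments dispersion per gene on size-factor-normalized counts,
#' a fitted mean-dispersion trend alpha(mu) = a0/mu + a1, and per-gene
#' shrinkage of log dispersion toward the trend.
#'
#' @param counts genes x samples integer counts.
#' @param sf size factors (default: computed by [size_factors()]).
#' @param groups optional sample-group labels; when given, the
#'   method-of-moments variance is the pooled within-group variance (i.e. the
#'   dispersion is estimated under the full-means model, so group mean
#'   differences do not inflate it).
#' @param min_alpha dispersion floor (default 1e-8).
#' @param shrink_weight weight on the per-gene estimate in log space; the
#'   default m/(m+10) grows with the number of samples m.
#' @return list: `alpha` (shrunk per-gene dispersions), `alpha_raw`,
#'   `trend` (c(a0, a1)), `mu` (mean normalized counts), `excluded`
#'   (all-zero genes, logical).
#' @export
estimate_dispersions <- function(counts, sf = NULL, groups = NULL,
                                 min_alpha = 1e-8, shrink_weight = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  m <- ncol(counts)
  if (is.null(shrink_weight)) shrink_weight <- m / (m + 10)
  q <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(q)
  excluded <- mu == 0
  if (any(excluded))
    message(sum(excluded), " all-zero gene(s) excluded from dispersion estimation")
  if (is.null(groups)) {
    v <- apply(q, 1, stats::var)
  } else {
    groups <- as.factor(groups)
    ss <- 0; df <- 0
    for (g in levels(groups)) {
      cols <- which(groups == g)
      if (length(cols) < 2) next
      sub <- q[, cols, drop = FALSE]
      ss <- ss + rowSums((sub - rowMeans(sub))^2)
      df <- df + length(cols) - 1
    }
    if (df == 0) stop("no group has >= 2 samples for dispersion estimation")
    v <- ss / df
  }
  # MoM: var(q) ~ mu * mean(1/s) + alpha * mu^2
  araw <- (v - mu * mean(1 / sf)) / mu^2
  araw[!is.finite(araw)] <- NA
  araw <- pmax(araw, min_alpha)
  use <- !excluded & !is.na(araw) & mu > 0
  if (sum(use) >= 10) {
    fit <- stats::lm(araw[use] ~ I(1 / mu[use]))
    a0 <- max(stats::coef(fit)[2], 0)
    a1 <- max(stats::coef(fit)[1], min_alpha)
  } else {
    a0 <- 0
    a1 <- max(stats::median(araw[use], na.rm = TRUE), min_alpha)
  }
  atrend <- pmax(a0 / mu + a1, min_alpha)
  alpha <- exp((1 - shrink_weight) * log(atrend) + shrink_weight * log(araw))
  single <- is.na(araw) & !excluded
  alpha[single] <- atrend[single]
  alpha[excluded] <- NA
  alpha <- pmax(alpha, min_alpha)
  atrend[excluded] <- NA
  list(alpha = alpha, alpha_trend = atrend, alpha_raw = araw,
       trend = c(a0 = a0, a1 = a1), mu = mu, excluded = excluded, sf = sf)
}
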