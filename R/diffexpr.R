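# Three-way classification of reprogramming outcomes.
#
# For one somatic tissue, counts from (adult progenitor, derived iPSC, ESC)
# samples are compared gene by gene under five NB mean constraints:
#   H0 (invariant):            q_A = q_I = q_E
#   CR (correctly reprogrammed): q_I = q_E       (adult differs)
#   TM (transcriptional memory): q_A = q_I       (ESC differs)
#   AR (aberrant reprogramming): q_A = q_E       (iPSC differs)
#   CX (complex):               all free
# The dispersion is held fixed across the five fits per gene (estimated once
# under the full-means model), so likelihood ratios are comparable. Because
# CX nests every other alternative its raw likelihood always wins; genes are
# therefore classified by the minimum p-value (LR with chi-square df penalty)
# among the four alternatives.

triple_partitions <- list(
  H0 = list(c("adult", "iPSC", "ESC")),
  CR = list("adult", c("iPSC", "ESC")),
  TM = list(c("adult", "iPSC"), "ESC"),
  AR = list(c("adult", "ESC"), "iPSC"),
  CX = list("adult", "iPSC", "ESC")
)
triple_df <- c(CR = 1, TM = 1, AR = 1, CX = 2)
triple_nparams <- c(H0 = 1, CR = 2, TM = 2, AR = 2, CX = 3)

#' Classify genes by three-way reprogramming outcome
#'
#' @param counts genes x samples integer counts for one tissue's triple.
#' @param class per-sample class label: `"adult"`, `"iPSC"` or `"ESC"`
#'   (at least 2 samples per class).
#' @param sf size factors (default median-of-ratios across the triple).
#' @param alpha per-gene NB dispersions (default: estimated under the
#'   full-means model with trend shrinkage).
#' @param p_threshold optional minimum-p threshold; when supplied, categories
#'   are assigned immediately (see [assign_categories()]).
#' @return `data.frame` (class `gene_classification`) with per-gene columns:
#'   log-likelihoods `ll_H0 .. ll_CX`, p-values `p_CR .. p_CX`, `min_p`,
#'   fitted class means `q_A`, `q_I`, `q_E`, `alpha`, `log2fc` (iPSC vs ESC),
#'   `best_alt` (argmin-p alternative with CX split into PTM/PAR) and
#'   `category` (NA until a threshold is applied).
#' @export
classify_three_way <- function(counts, class, sf = NULL, alpha = NULL,
                               p_threshold = NULL) {
  stopifnot(ncol(counts) == length(class))
  class <- as.character(class)
  bad <- setdiff(unique(class), c("adult", "iPSC", "ESC"))
  if (length(bad) > 0) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  if (any(table(factor(class, c("adult", "iPSC", "ESC"))) < 2))
    stop("each class needs at least 2 samples")
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(alpha)) {
    # trend-evaluated dispersion: at a dozen samples per triple the per-gene
    # MoM deviations are noise-dominated and degrade LR calibration, so the
    # classifier uses the fitted mean-dispersion trend (estimated under the
    # full-means model so true group differences do not inflate it)
    disp <- estimate_dispersions(counts, sf = sf, groups = class)
    alpha <- disp$alpha_trend
    alpha[is.na(alpha)] <- 1e-8
  }
  ll <- triple_logliks(counts, class, sf, alpha)
  G <- nrow(counts)
  out <- data.frame(gene_id = rownames(counts) %||% as.character(seq_len(G)),
                    ll$ll, ll$means, alpha = alpha,
                    stringsAsFactors = FALSE)
  for (k in names(triple_df)) {
    lr <- pmax(2 * (ll$ll[[paste0("ll_", k)]] - ll$ll$ll_H0), 0)
    out[[paste0("p_", k)]] <- stats::pchisq(lr, df = triple_df[k],
                                            lower.tail = FALSE)
  }
  pm <- as.matrix(out[, paste0("p_", names(triple_df))])
  out$min_p <- apply(pm, 1, min)
  # argmin-p alternative; ties broken toward the larger likelihood ratio
  llm <- as.matrix(ll$ll[paste0("ll_", names(triple_df))])
  pick <- apply(cbind(pm, llm), 1, function(z) {
    p <- z[1:4]; l <- z[5:8]
    cand <- which(p == min(p))
    cand[which.max(l[cand])]
  })
  best <- names(triple_df)[pick]
  cx <- best == "CX"
  between <- (out$q_I > pmin(out$q_A, out$q_E)) &
             (out$q_I < pmax(out$q_A, out$q_E))
  best[cx] <- ifelse(between[cx], "PTM", "PAR")
  out$best_alt <- best
  out$log2fc <- log2(out$q_I / out$q_E)
  out$category <- NA_character_
  attr(out, "group_fits") <- ll$groups
  class(out) <- c("gene_classification", "data.frame")
  if (!is.null(p_threshold)) out <- assign_categories(out, p_threshold)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# block log-likelihoods under the five constraint patterns, sharing the seven
# unique merged-group fits; per-group ML means, log-likelihoods and log2-mean
# sampling variances are retained for the hierarchical (Bayes-factor) model
triple_logliks <- function(counts, class, sf, alpha) {
  cols <- function(cl) which(class %in% cl)
  merged <- list(A = "adult", I = "iPSC", E = "ESC",
                 AI = c("adult", "iPSC"), AE = c("adult", "ESC"),
                 IE = c("iPSC", "ESC"), AIE = c("adult", "iPSC", "ESC"))
  G <- nrow(counts)
  gmu <- gll <- gv <- matrix(NA_real_, G, length(merged),
                             dimnames = list(NULL, names(merged)))
  for (nm in names(merged)) {
    ix <- cols(merged[[nm]])
    mu <- nb_ml_mean(counts[, ix, drop = FALSE], sf[ix], alpha)
    gmu[, nm] <- mu
    gv[, nm] <- attr(mu, "var_log2")
    gll[, nm] <- nb_block_loglik(counts[, ix, drop = FALSE], sf[ix], alpha, mu)
  }
  ll <- data.frame(
    ll_H0 = gll[, "AIE"],
    ll_CR = gll[, "A"] + gll[, "IE"],
    ll_TM = gll[, "AI"] + gll[, "E"],
    ll_AR = gll[, "AE"] + gll[, "I"],
    ll_CX = gll[, "A"] + gll[, "I"] + gll[, "E"]
  )
  means <- data.frame(q_A = gmu[, "A"], q_I = gmu[, "I"], q_E = gmu[, "E"])
  list(ll = ll, means = means,
       groups = list(mu = gmu, ll = gll, var_log2 = gv))
}

#' Assign final categories at a minimum-p threshold
#'
#' A gene is invariant (`IE`) iff its minimum alternative p-value is at or
#' above the threshold; otherwise it takes its best alternative (CX already
#' split into PTM/PAR by whether the fitted iPSC mean lies strictly between
#' the adult and ESC means).
#'
#' @param cls a `gene_classification` from [classify_three_way()].
#' @param p_threshold the operating threshold on `min_p`.
#' @return `cls` with the `category` column filled.
#' @export
assign_categories <- function(cls, p_threshold) {
  cls$category <- ifelse(cls$min_p >= p_threshold, "IE", cls$best_alt)
  cls
}

#' Permutation-calibrated FDR for the three-way classification
#'
#' Class labels are permuted across the triple's samples (size factors stay
#' attached to samples); for each threshold t on the minimum p-value,
#' FDR(t) = (mean permuted count of min_p <= t) / (observed count), clipped
#' to \[0,1\] and monotonized into per-gene q-values. The operating threshold
#' is the largest t with FDR(t) <= `target`.
#'
#' @inheritParams classify_three_way
#' @param cls the observed classification (from [classify_three_way()]).
#' @param n_perm number of permutations (>= 20 required).
#' @param seed RNG seed for the permutation stream.
#' @param target FDR level (default 0.05).
#' @return list: `q` (per-gene q-values), `threshold` (operating min-p
#'   threshold, 0 if no discoveries at `target`), `fdr_curve`
#'   (`data.frame` t, fdr, q, n_obs, n_perm_mean), `classification` (with
#'   categories assigned at the threshold), `n_significant`.
#' @export
permutation_fdr <- function(cls, counts, class, sf = NULL, alpha = NULL,
                            n_perm = 100, seed = 1, target = 0.05) {
  if (n_perm < 20) stop("n_perm must be at least 20 for a stable FDR estimate")
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(alpha)) alpha <- cls$alpha
  perm_minp <- matrix(NA_real_, nrow(counts), n_perm)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    pclass <- sample(class)
    perm_minp[, b] <- triple_min_p(counts, pclass, sf, alpha)
  }
  fdr_from_min_p(cls, cls$min_p, perm_minp, target)
}

# minimum alternative p-value only (fast path for the permutation loop)
triple_min_p <- function(counts, class, sf, alpha) {
  ll <- triple_logliks(counts, class, sf, alpha)$ll
  minp <- rep(1, nrow(counts))
  for (k in names(triple_df)) {
    lr <- pmax(2 * (ll[[paste0("ll_", k)]] - ll$ll_H0), 0)
    minp <- pmin(minp, stats::pchisq(lr, df = triple_df[k], lower.tail = FALSE))
  }
  minp
}

# shared FDR-curve machinery (used by the expression and isoform tests)
fdr_from_min_p <- function(cls, obs, perm_minp, target = 0.05) {
  ts <- sort(unique(obs))
  n_obs <- vapply(ts, function(t) sum(obs <= t), 0)
  n_perm_mean <- vapply(ts, function(t) mean(colSums(perm_minp <= t)), 0)
  fdr <- ifelse(n_obs > 0, pmin(n_perm_mean / n_obs, 1), 1)
  q_at_t <- rev(cummin(rev(fdr)))            # monotonize: q non-decreasing in t
  q <- q_at_t[match(obs, ts)]
  ok <- which(q_at_t <= target)
  threshold <- if (length(ok) > 0) ts[max(ok)] else 0
  cls <- assign_categories(cls, if (threshold > 0) threshold * (1 + 1e-12) else 0)
  list(q = q, threshold = threshold,
       fdr_curve = data.frame(t = ts, fdr = fdr, q = q_at_t,
                              n_obs = n_obs, n_perm_mean = n_perm_mean),
       classification = cls,
       n_significant = sum(obs <= threshold))
}

#' Significant genes and Table-1-style category counts
#'
#' A gene is reported iff its q-value is at or below `q_threshold` and the
#' fitted iPSC/ESC fold change is at least `min_fold` (inclusive bound, in
#' either direction). Counts are tabulated over the memory/aberrant
#' categories by direction (activation iff the fitted iPSC mean exceeds the
#' ESC mean).
#'
#' @param cls classification with categories assigned.
#' @param q per-gene q-values (from [permutation_fdr()]).
#' @param q_threshold FDR level (default 0.05).
#' @param min_fold minimum iPSC-vs-ESC fold change (default 1.5).
#' @return list: `genes` (the significant subset with `direction`), `table`
#'   (counts: AR/PAR/TM/PTM x activation/silencing).
#' @export
significant_genes <- function(cls, q, q_threshold = 0.05, min_fold = 1.5) {
  fold <- pmax(cls$q_I / cls$q_E, cls$q_E / cls$q_I)
  sig <- !is.na(cls$category) & cls$category != "IE" &
         q <= q_threshold & fold >= min_fold
  genes <- cls[sig, , drop = FALSE]
  genes$q_value <- q[sig]
  genes$direction <- ifelse(genes$q_I > genes$q_E, "activation", "silencing")
  cats <- c("AR", "PAR", "TM", "PTM")
  tab <- matrix(0L, 2, length(cats),
                dimnames = list(c("activation", "silencing"), cats))
  for (ct in cats) for (dr in rownames(tab))
    tab[dr, ct] <- sum(genes$category == ct & genes$direction == dr)
  list(genes = genes, table = tab)
}

#' Hierarchical mixture model for category proportions
#'
#' Estimates the true proportions of genes in each of the five hypothesis
#' classes without any significance threshold, by EM on
#' sum_g log sum_k pi_k Lambda_gk over the mixing proportions pi.
#'
#' The per-gene weights Lambda_gk are approximate marginal likelihoods. The
#' default (`method = "abf"`) places a normal prior (sd `prior_sd`, averaged
#' over a grid) on each merged group's log2 mean offset from the pooled mean
#' and integrates it out with the Wakefield approximation, so a null gene's
#' Bayes factor has expectation one and null genes do not leak mass into the
#' alternative categories. `method = "bic"` uses BIC weights
#' exp(ll_gk - 0.5 k_k log m) instead (simpler, but heavier-tailed under the
#' null).
#'
#' @param cls a `gene_classification` from [classify_three_way()].
#' @param n_samples number of samples in the triple (BIC sample size; only
#'   used by `method = "bic"`).
#' @param method `"abf"` (default when group fits are available) or `"bic"`.
#' @param prior_sd grid of prior standard deviations on log2 group offsets
#'   (default 0.5, 1, 2; Bayes factors are averaged over the grid).
#' @param tol EM convergence tolerance on the objective (default 1e-8).
#' @param max_iter iteration cap; oscillation beyond it raises an error.
#' @return list: `pi` (named over IE, CR, TM, AR, CX), `posterior`
#'   (genes x 5), `objective_trace`, `converged`, `n_iterations`.
#' @export
hierarchical_proportions <- function(cls, n_samples = NULL,
                                     method = c("abf", "bic"),
                                     prior_sd = c(1, 2, 4), tol = 1e-8,
                                     max_iter = 10000) {
  method <- match.arg(method)
  gf <- attr(cls, "group_fits")
  if (method == "abf" && is.null(gf)) {
    warning("group fits unavailable; falling back to BIC weights")
    method <- "bic"
  }
  hyps <- c("H0", "CR", "TM", "AR", "CX")
  if (method == "abf") {
    logLam <- abf_log_marginals(gf, prior_sd)
  } else {
    if (is.null(n_samples)) stop("n_samples is required for method = 'bic'")
    L <- as.matrix(cls[, paste0("ll_", hyps)])
    pen <- 0.5 * triple_nparams[hyps] * log(n_samples)
    logLam <- sweep(L, 2, pen, "-")
  }
  logLam <- logLam - apply(logLam, 1, max)     # per-gene shift, EM-invariant
  Lam <- exp(logLam)
  K <- ncol(Lam)
  pi <- rep(1 / K, K)
  obj_old <- -Inf; trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    num <- sweep(Lam, 2, pi, "*")
    den <- rowSums(num)
    obj <- sum(log(den))
    if (obj < obj_old - 1e-9)
      stop("EM objective decreased at iteration ", it, " (trace length ",
           length(trace), ")")
    trace <- c(trace, obj)
    w <- num / den
    pi_new <- colMeans(w)
    converged <- is.finite(obj_old) && (obj - obj_old) < tol
    pi <- pi_new
    if (converged) break
    obj_old <- obj
  }
  if (!converged)
    stop("hierarchical EM did not converge within ", max_iter,
         " iterations (last objective ", format(trace[length(trace)]), ")")
  names(pi) <- c("IE", "CR", "TM", "AR", "CX")
  num <- sweep(Lam, 2, pi, "*")
  posterior <- num / rowSums(num)
  colnames(posterior) <- names(pi)
  list(pi = pi, posterior = posterior, objective_trace = trace,
       converged = converged, n_iterations = length(trace))
}

# Wakefield-style approximate log marginal likelihoods per hypothesis.
# Each hypothesis is a partition into merged groups; every merged group's
# log2 mean carries an independent N(0, sd^2) prior on its offset from the
# pooled (H0) mean, integrated with the Gaussian approximation around the ML
# fit:  log m_c = ll_c + 0.5 log(v_c/(v_c+sd^2)) - bhat_c^2/(2 (v_c+sd^2)),
# with bhat_c the fitted log2 offset and v_c its sampling variance. Marginals
# are averaged over the prior-sd grid on the likelihood scale.
abf_log_marginals <- function(gf, prior_sd) {
  partitions <- list(H0 = "AIE", CR = c("A", "IE"), TM = c("AI", "E"),
                     AR = c("AE", "I"), CX = c("A", "I", "E"))
  mu <- gf$mu; v <- gf$var_log2; ll <- gf$ll
  G <- nrow(mu)
  # uninformative placeholders for groups with no counts (flat likelihood)
  v[!is.finite(v)] <- 1e6
  lmu <- log2(pmax(mu, 1e-6))
  bhat <- lmu - lmu[, "AIE"]
  out <- matrix(NA_real_, G, length(partitions),
                dimnames = list(NULL, names(partitions)))
  for (k in names(partitions)) {
    per_sigma <- sapply(prior_sd, function(s) {
      m <- 0
      for (cgrp in partitions[[k]]) {
        b <- if (cgrp == "AIE") 0 else bhat[, cgrp]
        m <- m + ll[, cgrp] + 0.5 * log(v[, cgrp] / (v[, cgrp] + s^2)) -
             b^2 / (2 * (v[, cgrp] + s^2))
      }
      m
    })
    mx <- apply(per_sigma, 1, max)
    out[, k] <- mx + log(rowMeans(exp(per_sigma - mx)))
  }
  out
}
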