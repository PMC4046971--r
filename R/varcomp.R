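# Pooled linear mixed model for variance decomposition of expression.
#
# Per gene j, the standardized log2 FPKM vector y_j is modeled as
#   y_j = b1 1 + Z2 b2 + Z3 b3 + Z4 b4 + Z5 b5 + e,   b_k ~ N(0, D_k),
# with D_k diagonal (sub-component structure: adult-tissue vs pluripotent
# levels of Z2; adult-donor vs iPSC-donor levels of Z4) and residual variance
# either shared (homoscedastic) or per sample group (heteroscedastic).
# The intercept b1 is removed exactly by working in an orthonormal basis of
# the contrast space (the orthogonal complement of the ones vector), so the
# pooled likelihood over genes is
#   sum_j log N(K' y_j ; 0, K' V(theta) K),  V = sum_k Z_k D_k Z_k' + R.
# With S = (1/J) sum_j (K'y_j)(K'y_j)', this equals
#   -J/2 [ (n-1) log 2pi + log det V* + tr(V*^{-1} S) ],
# which makes each likelihood evaluation O(n^3) regardless of gene count.

#' Orthonormal basis of the contrast space
#'
#' Returns an n x (n-1) matrix K with orthonormal columns orthogonal to the
#' ones vector; used to profile out the per-gene intercept exactly.
#'
#' @param n number of samples.
#' @return n x (n-1) matrix.
#' @export
contrast_basis <- function(n) {
  qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
}

# Assemble the per-parameter covariance layers in contrast space.
# Returns list(M = named list of (n-1)x(n-1) matrices for variance params,
#              B = named list for residual groups, ...)
varcomp_layers <- function(design, residual_model, drop = NULL) {
  meta <- design$meta
  n <- nrow(meta)
  K <- contrast_basis(n)
  params <- unique(unlist(design$param))
  if (!is.null(drop)) {
    drop_params <- expand_drop(drop)
    params <- setdiff(params, drop_params)
  }
  M <- list()
  for (p in params) {
    cols <- NULL
    for (zn in names(design$Z)) {
      sel <- design$param[[zn]] == p
      if (any(sel)) cols <- cbind(cols, design$Z[[zn]][, sel, drop = FALSE])
    }
    A <- tcrossprod(cols)
    if (all(A == 0)) next  # component absent from this design (no such samples)
    M[[p]] <- crossprod(K, A %*% K)
  }
  groups <- residual_groups(meta, residual_model)
  B <- list()
  for (g in sort(unique(groups))) {
    idx <- which(groups == g)
    B[[g]] <- crossprod(K[idx, , drop = FALSE])
  }
  list(M = M, B = B, K = K, groups = groups, params = names(M))
}

# map user-facing component names to variance-parameter names to drop
expand_drop <- function(drop) {
  out <- character(0)
  for (d in drop) {
    out <- c(out, switch(d,
      donor = c("delta4_adult", "delta4_ipsc"),
      origin = "delta3_origin",
      batch = "delta5_batch",
      cell_class = c("delta2_adult", "delta2_pluri"),
      if (d %in% unname(component_param)) d
      else if (d %in% names(component_param)) unname(component_param[d])
      else stop("unknown component to drop: ", d)))
  }
  unique(out)
}

# Standardize genes and return the contrast-space scatter matrix S.
#
# Each gene is centered and divided by its per-gene precision scale: the
# moderated within-replicate-group standard deviation (replicate groups =
# samples sharing every design level, i.e. donor x cell class x tissue x
# batch). Scaling by the replicate-level variance adapts to per-gene scale
# heterogeneity (tau_j) while staying independent of the gene's own
# random-effect draws; scaling by the TOTAL per-gene variance instead would
# couple the scale to those draws and systematically shrink the estimated
# share of low-effective-df components (donor especially). When the design
# has no replicate groups at all, total-variance scaling is the fallback.
# The moderation (prior df 4 toward the mean variance) tames genes with tiny
# replicate variance.
varcomp_scatter <- function(Y, meta, K, prior_df = 4) {
  m <- if (inherits(Y, "expression_matrix")) Y$values else Y
  if (!all(meta$sample_id %in% colnames(m)))
    stop("expression matrix is missing samples present in the metadata")
  m <- m[, meta$sample_id, drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  keep <- sds > 0
  if (any(!keep))
    message(sum(!keep), " zero-variance gene(s) dropped before fitting")
  if (sum(keep) < 2) stop("fewer than 2 genes with variance; cannot fit")
  m <- m[keep, , drop = FALSE]

  rep_group <- interaction(meta$donor, meta$cell_class, meta$adult_tissue,
                           meta$tissue_of_origin, meta$batch, drop = TRUE)
  ss <- 0; df <- 0
  for (g in levels(rep_group)) {
    cols <- which(rep_group == g)
    if (length(cols) < 2) next
    sub <- m[, cols, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + length(cols) - 1
  }
  if (df > 0) {
    v <- ss / df
    scale2 <- (df * v + prior_df * mean(v)) / (df + prior_df)
    if (mean(v) == 0) scale2 <- sds[keep]^2   # degenerate: no replicate noise
  } else {
    scale2 <- sds[keep]^2
  }
  Ys <- (m - rowMeans(m)) / sqrt(scale2)
  U <- Ys %*% K
  list(S = crossprod(U) / nrow(U), J = nrow(U),
       dropped = names(sds)[!keep] %||% character(0))
}

# negative pooled log-likelihood at log-parameters theta
varcomp_negll <- function(theta, layers, S, J) {
  nm <- c(names(layers$M), names(layers$B))
  v <- exp(theta)
  names(v) <- nm
  V <- 0
  for (p in names(layers$M)) V <- V + v[p] * layers$M[[p]]
  for (g in names(layers$B)) V <- V + v[g] * layers$B[[g]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    V <- V + diag(1e-8, nrow(V))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e12)
  }
  logdet <- 2 * sum(log(diag(ch)))
  Vinv <- chol2inv(ch)
  0.5 * J * ((nrow(V)) * log(2 * pi) + logdet + sum(Vinv * S))
}

#' Fit the five-component variance decomposition
#'
#' Maximizes the pooled log-likelihood over genes by L-BFGS-B on the
#' log-variance scale, from several deterministic starting points, keeping the
#' best converged fit. Genes are centered and scaled to unit variance first,
#' so the fitted variance parameters are fractions of per-gene variance and
#' the percent variance explained is comparable across genes.
#'
#' @param Y genes x samples log2 FPKM matrix (or `expression_matrix`).
#' @param design a `design_set` from [build_design()].
#' @param residual_model `"homo"`, `"het1"` or `"het2"` (see
#'   [residual_groups()]).
#' @param drop optional component(s) to exclude from the model (e.g.
#'   `"donor"`, `"origin"`, `"batch"`).
#' @param n_restarts number of deterministic restarts (>= 5 recommended).
#' @param maxit optimizer iteration cap per restart.
#' @return object of class `varcomp_fit`: `params` (named variance
#'   parameters), `sigma2` (per residual group), `ve` (variance explained per
#'   component), `loglik`, `convergence` (per-restart codes), `design`,
#'   `residual_model`, `n_genes`, `dropped_genes`.
#' @export
fit_mixed_model <- function(Y, design, residual_model = c("homo", "het1", "het2"),
                            drop = NULL, n_restarts = 5, maxit = 1000) {
  residual_model <- match.arg(residual_model)
  layers <- varcomp_layers(design, residual_model, drop)
  sc <- varcomp_scatter(Y, design$meta, layers$K)
  np <- length(layers$M); ng <- length(layers$B)
  starts <- varcomp_starts(np, ng, n_restarts)
  best <- NULL; codes <- integer(0)
  for (s in starts) {
    fit <- stats::optim(log(s), varcomp_negll, layers = layers, S = sc$S, J = sc$J,
                        method = "L-BFGS-B", lower = log(1e-8), upper = log(1e3),
                        control = list(maxit = maxit, factr = 1e4))
    codes <- c(codes, fit$convergence)
    if (fit$convergence == 0 && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("variance-component model failed to converge after ", length(starts),
         " restarts (optim codes: ", paste(codes, collapse = ","), ")")
  v <- exp(best$par)
  names(v) <- c(names(layers$M), names(layers$B))
  delta <- v[names(layers$M)]
  sigma2 <- v[names(layers$B)]
  out <- structure(list(
    params = delta, sigma2 = sigma2, loglik = -best$value,
    design = design, residual_model = residual_model, drop = drop,
    n_genes = sc$J, dropped_genes = sc$dropped, convergence = codes
  ), class = "varcomp_fit")
  present <- design$components[component_param[design$components] %in% names(delta)]
  out$ve <- vapply(present, function(cp) variance_explained(out, cp), 0)
  out
}

varcomp_starts <- function(np, ng, n_restarts) {
  base <- list(rep(0.1, np + ng),
               rep(0.5, np + ng),
               c(rep(0.05, np), rep(1, ng)),
               c(rep(1, np), rep(0.5, ng)),
               rep(0.3, np + ng))
  extra <- 0
  while (length(base) < n_restarts) {
    extra <- extra + 1
    base[[length(base) + 1]] <- rep(0.02 * extra + 0.15, np + ng)
  }
  base[seq_len(max(n_restarts, 1))]
}

#' Evaluate the pooled mixed-model log-likelihood at given parameters
#'
#' Intended for likelihood comparisons (e.g. checking that the finer
#' heteroscedastic model reduces to the coarser one under equality
#' constraints) and for validation against direct multivariate-normal
#' evaluation.
#'
#' @inheritParams fit_mixed_model
#' @param delta named variance parameters (subset of the model's parameters).
#' @param sigma2 named residual variances per residual group.
#' @return the pooled log-likelihood (a scalar).
#' @export
mixed_model_loglik <- function(Y, design, delta, sigma2,
                               residual_model = c("homo", "het1", "het2"),
                               drop = NULL) {
  residual_model <- match.arg(residual_model)
  layers <- varcomp_layers(design, residual_model, drop)
  sc <- varcomp_scatter(Y, design$meta, layers$K)
  if (!setequal(names(delta), names(layers$M)))
    stop("delta must be named with: ", paste(names(layers$M), collapse = ", "))
  if (!setequal(names(sigma2), names(layers$B)))
    stop("sigma2 must be named with: ", paste(names(layers$B), collapse = ", "))
  theta <- log(c(delta[names(layers$M)], sigma2[names(layers$B)]))
  -varcomp_negll(theta, layers, sc$S, sc$J)
}

#' Variance explained by one component
#'
#' ve = delta^2_k / (delta^2_k + sigma^2_rel), where sigma^2_rel is the
#' residual variance of the samples the component acts on (for
#' heteroscedastic fits, the sample-weighted mean of the group residual
#' variances over those samples).
#'
#' @param fit a `varcomp_fit`.
#' @param component one of `"adult_tissue"`, `"ips_vs_es"`, `"origin"`,
#'   `"donor_adult"`, `"donor_ipsc"`, `"batch"`.
#' @return fraction in \[0, 1\].
#' @export
variance_explained <- function(fit, component) {
  p <- component_param[component]
  if (is.na(p)) stop("unknown component: ", component)
  if (!p %in% names(fit$params))
    stop("component ", component, " not present in this fit")
  delta <- fit$params[[p]]
  meta <- fit$design$meta
  idx <- component_samples(component, meta)
  groups <- residual_groups(meta, fit$residual_model)
  sigma_rel <- mean(fit$sigma2[groups[idx]])
  unname(delta / (delta + sigma_rel))
}

#' Refit the model without one component and compare variance explained
#'
#' Quantifies confounding: when a dropped component (typically donor) is
#' partially confounded with a retained one (tissue of origin), the retained
#' component's variance explained inflates.
#'
#' @inheritParams fit_mixed_model
#' @param component_to_drop component name understood by `drop` (e.g.
#'   `"donor"`).
#' @return list: `fit_with`, `fit_without`, `ve_with`, `ve_without` (named
#'   vectors over the components present in both fits).
#' @export
refit_excluding <- function(Y, design, component_to_drop,
                            residual_model = "homo", ...) {
  fit_with <- fit_mixed_model(Y, design, residual_model, drop = NULL, ...)
  fit_without <- fit_mixed_model(Y, design, residual_model,
                                 drop = component_to_drop, ...)
  shared <- intersect(names(fit_with$ve), names(fit_without$ve))
  list(fit_with = fit_with, fit_without = fit_without,
       ve_with = fit_with$ve[shared], ve_without = fit_without$ve[shared])
}

#' Per-component covariance layers of a fit
#'
#' layer_k = Z_k D_k Z_k' in the original sample space; their sum plus the
#' residual diagonal equals the model-implied sample covariance.
#'
#' @param fit a `varcomp_fit`.
#' @return list of sample x sample matrices, one per variance parameter, plus
#'   `residual` (diagonal matrix) and `total`.
#' @export
covariance_layers <- function(fit) {
  design <- fit$design
  meta <- design$meta
  layers <- list()
  for (p in names(fit$params)) {
    cols <- NULL
    for (zn in names(design$Z)) {
      sel <- design$param[[zn]] == p
      if (any(sel)) cols <- cbind(cols, design$Z[[zn]][, sel, drop = FALSE])
    }
    layers[[p]] <- fit$params[[p]] * tcrossprod(cols)
  }
  groups <- residual_groups(meta, fit$residual_model)
  layers$residual <- diag(as.numeric(fit$sigma2[groups]), nrow(meta))
  dimnames(layers$residual) <- list(meta$sample_id, meta$sample_id)
  layers$total <- Reduce(`+`, layers)
  layers
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("Variance-component fit (", x$residual_model, " residuals, ",
      x$n_genes, " genes)\n", sep = "")
  cat("log-likelihood:", format(x$loglik), "\n")
  cat("variance parameters:\n")
  print(round(x$params, 4))
  cat("residual variances:\n")
  print(round(x$sigma2, 4))
  cat("variance explained (%):\n")
  print(round(100 * x$ve, 2))
  invisible(x)
}
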