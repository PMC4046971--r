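# Phased allele-specific expression, allelic-imbalance testing, imprinting
# classification and adult-to-iPSC imprinting concordance.

#' Aggregate phased SNP-level allelic counts to gene-level ASE
#'
#' Haplotype counts are summed over the heterozygous SNPs of each gene within
#' each sample; entries with insufficient total coverage or too few SNPs are
#' excluded and counted. The allelic-imbalance fraction `ai` is the paternal
#' (haplotype-1) share, with an exact binomial 95% confidence interval.
#'
#' @param counts `data.frame` with columns `sample_id`, `gene_id`, `snp_id`,
#'   `hap1_count`, `hap2_count` (haplotype 1 = paternal by convention when
#'   the phasing labels are known; the label is carried, not inferred).
#' @param min_coverage minimum summed coverage per (sample, gene)
#'   (default 20).
#' @param min_snps minimum number of het SNPs per (sample, gene) (default 1).
#' @return `data.frame`: `sample_id`, `gene_id`, `paternal_total`,
#'   `maternal_total`, `n_snps`, `ai`, `ci_low`, `ci_high`; attribute
#'   `n_excluded` counts entries failing the coverage/SNP filters.
#' @export
aggregate_gene_ase <- function(counts, min_coverage = 20, min_snps = 1) {
  need <- c("sample_id", "gene_id", "snp_id", "hap1_count", "hap2_count")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(counts$hap1_count < 0 | counts$hap2_count < 0))
    stop("negative allelic counts")
  key <- paste(counts$sample_id, counts$gene_id, sep = "\r")
  pat <- rowsum(counts$hap1_count, key)
  mat <- rowsum(counts$hap2_count, key)
  nsnp <- rowsum(rep(1L, nrow(counts)), key)
  ks <- strsplit(rownames(pat), "\r", fixed = TRUE)
  out <- data.frame(
    sample_id = vapply(ks, `[[`, "", 1L),
    gene_id = vapply(ks, `[[`, "", 2L),
    paternal_total = as.integer(pat), maternal_total = as.integer(mat),
    n_snps = as.integer(nsnp), stringsAsFactors = FALSE
  )
  tot <- out$paternal_total + out$maternal_total
  keep <- tot >= min_coverage & out$n_snps >= min_snps
  n_excluded <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  tot <- tot[keep]
  out$ai <- ifelse(tot > 0, out$paternal_total / tot, NA_real_)
  ci <- t(vapply(seq_len(nrow(out)), function(i) {
    bt <- stats::binom.test(out$paternal_total[i], tot[i])
    as.numeric(bt$conf.int)
  }, c(0, 0)))
  out$ci_low <- ci[, 1]; out$ci_high <- ci[, 2]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Exact binomial test of allelic imbalance against 0.5
#'
#' @param ase gene-level ASE table from [aggregate_gene_ase()].
#' @return `ase` with a `p_imbalance` column (two-sided exact binomial).
#' @export
test_imbalance <- function(ase) {
  ase$p_imbalance <- vapply(seq_len(nrow(ase)), function(i) {
    stats::binom.test(ase$paternal_total[i],
                      ase$paternal_total[i] + ase$maternal_total[i],
                      p = 0.5)$p.value
  }, 0)
  ase
}

#' Adult-to-iPSC imprinting concordance for one donor
#'
#' For genes testable in both the donor's adult cells and at least one
#' derived iPSC line, correlates the adult allelic-imbalance fraction with
#' the coverage-weighted mean fraction across the derived lines.
#'
#' @param adult_ase gene-level ASE rows for the donor's adult samples.
#' @param ipsc_ase gene-level ASE rows for the donor's derived iPSC lines.
#' @return list: `r2`, `r`, `p` (correlation test), `genes`
#'   (`data.frame` gene_id, ai_adult, ai_ipsc), `n_genes`.
#' @export
imprinting_concordance <- function(adult_ase, ipsc_ase) {
  wmean <- function(df) {
    w <- df$paternal_total + df$maternal_total
    tapply(seq_len(nrow(df)), df$gene_id,
           function(ix) stats::weighted.mean(df$ai[ix], w[ix]))
  }
  a <- wmean(adult_ase); b <- wmean(ipsc_ase)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) stop("fewer than 3 genes testable in both cell classes")
  ct <- stats::cor.test(a[shared], b[shared])
  list(r2 = unname(ct$estimate^2), r = unname(ct$estimate), p = ct$p.value,
       genes = data.frame(gene_id = shared, ai_adult = as.numeric(a[shared]),
                          ai_ipsc = as.numeric(b[shared]),
                          stringsAsFactors = FALSE),
       n_genes = length(shared))
}

#' Classify imprinting status from gene-level ASE
#'
#' Mono-allelic: allelic fraction at or beyond 0.9/0.1 with the 95% CI
#' excluding 0.5. Bi-allelic: CI contained in (0.2, 0.8). Otherwise
#' ambiguous. The numeric cutoffs are declared defaults, configurable.
#'
#' @param ase gene-level ASE table.
#' @param mono_ai mono-allelic fraction cutoff (default 0.9).
#' @param bi_bounds CI containment interval for bi-allelic calls
#'   (default c(0.2, 0.8)).
#' @return `ase` with a `status` column (`mono-allelic`, `bi-allelic`,
#'   `ambiguous`).
#' @export
classify_imprinting <- function(ase, mono_ai = 0.9, bi_bounds = c(0.2, 0.8)) {
  mono <- (ase$ai >= mono_ai | ase$ai <= 1 - mono_ai) &
          (ase$ci_low > 0.5 | ase$ci_high < 0.5)
  bi <- ase$ci_low > bi_bounds[1] & ase$ci_high < bi_bounds[2]
  ase$status <- ifelse(mono, "mono-allelic",
                       ifelse(bi, "bi-allelic", "ambiguous"))
  ase
}

#' Flag loss of imprinting
#'
#' A gene shows loss of imprinting for a donor when its adult status is
#' mono-allelic and the majority of the donor's derived iPSC lines are
#' bi-allelic.
#'
#' @param adult_status the adult-cell status (a single string).
#' @param ipsc_statuses statuses across the donor's derived iPSC lines.
#' @return logical flag.
#' @export
loss_of_imprinting <- function(adult_status, ipsc_statuses) {
  length(ipsc_statuses) > 0 &&
    adult_status == "mono-allelic" &&
    mean(ipsc_statuses == "bi-allelic") > 0.5
}
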