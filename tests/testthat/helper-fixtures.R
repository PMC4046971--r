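# Shared fixtures: small synthetic inputs built in code at test time.

# random read-pair table covering all filter rule boundaries
random_pairs <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    read_id = sprintf("r%04d", seq_len(n)),
    chrom1 = sample(c("chr1", "chr2"), n, replace = TRUE),
    chrom2 = sample(c("chr1", "chr2"), n, replace = TRUE),
    mapq1 = sample(0:60, n, replace = TRUE),
    mapq2 = sample(0:60, n, replace = TRUE),
    mismatches1 = sample(0:6, n, replace = TRUE),
    mismatches2 = sample(0:6, n, replace = TRUE),
    has_gap1 = sample(c(TRUE, FALSE), n, replace = TRUE),
    has_gap2 = sample(c(TRUE, FALSE), n, replace = TRUE),
    insert_size = sample(c(0, 50, 149, 150, 151, 1000, 999999, 1e6, 1e6 + 1, 2e6),
                         n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# a tiny SAM file with a header and the given alignment rows
write_test_sam <- function(path, rows) {
  hdr <- c("@HD\tVN:1.6\tSO:queryname",
           "@SQ\tSN:chr1\tLN:248956422", "@SQ\tSN:chr2\tLN:242193529")
  writeLines(c(hdr, rows), path)
}

sam_row <- function(qname, flag, rname, pos, mapq, cigar, rnext, tlen, nm = 0) {
  paste(qname, flag, rname, pos, mapq, cigar, rnext, 1, tlen,
        "ACGT", "IIII", sprintf("NM:i:%d", nm), sep = "\t")
}

# small toy metadata without replicate groups (all singleton design cells)
toy_meta_6 <- function() {
  data.frame(
    sample_id = c("i1", "i2", "i3", "i4", "e1", "e2"),
    donor = c("D1", "D2", "D3", "D4", "H9", "Val9"),
    cell_class = c(rep("iPSC", 4), "ESC", "ESC"),
    adult_tissue = "none",
    tissue_of_origin = c("F", "F", "E", "E", "none", "none"),
    batch = as.character(c(1, 2, 1, 2, 1, 2)),
    replicate_label = "1",
    stringsAsFactors = FALSE
  )
}

# independent dense multivariate-normal evaluation of the pooled mixed-model
# likelihood on a design without replicate groups (total-sd standardization)
dense_pooled_loglik <- function(Y, meta, delta, sigma2) {
  n <- nrow(meta)
  ind <- function(labels) {
    lev <- sort(unique(labels[!is.na(labels)]))
    Z <- matrix(0, n, length(lev))
    hit <- !is.na(labels)
    Z[cbind(which(hit), match(labels[hit], lev))] <- 1
    Z
  }
  class5 <- ifelse(meta$cell_class == "adult", meta$adult_tissue, meta$cell_class)
  Z2 <- ind(class5)
  Z3 <- ind(ifelse(meta$cell_class == "iPSC", meta$tissue_of_origin, NA))
  Z4 <- ind(ifelse(meta$cell_class == "ESC", NA,
                   paste(meta$cell_class, meta$donor)))
  Z5 <- ind(meta$batch)
  V <- delta[["delta2_pluri"]] * tcrossprod(Z2) +
       delta[["delta3_origin"]] * tcrossprod(Z3) +
       delta[["delta4_ipsc"]] * tcrossprod(Z4) +
       delta[["delta5_batch"]] * tcrossprod(Z5) +
       diag(sigma2, n)
  K <- contrast_basis(n)
  Vs <- t(K) %*% V %*% K
  ll <- 0
  for (j in seq_len(nrow(Y))) {
    y <- Y[j, ]
    y <- (y - mean(y)) / stats::sd(y)
    u <- as.numeric(t(K) %*% y)
    ll <- ll - 0.5 * (length(u) * log(2 * pi) +
                      determinant(Vs, logarithm = TRUE)$modulus +
                      sum(u * solve(Vs, u)))
  }
  as.numeric(ll)
}
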