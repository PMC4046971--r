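#' Read a gene-by-sample expression matrix from TSV
#'
#' The file must have a header row of sample ids and a first column of gene
#' ids. Values are validated against the declared kind: counts must be
#' non-negative integers; FPKM and log2 FPKM must be finite (FPKM
#' non-negative).
#'
#' @param path TSV file path.
#' @param value_kind one of `"counts"`, `"fpkm"`, `"log2fpkm"`.
#' @return An `expression_matrix`: list with `values` (numeric matrix,
#'   genes x samples), `value_kind`, and optional `gene_lengths`,
#'   `library_sizes` attached by the caller.
#' @export
read_expression_matrix <- function(path, value_kind = c("counts", "fpkm", "log2fpkm")) {
  value_kind <- match.arg(value_kind)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene-id column plus samples")
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 gene_ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  if (value_kind %in% c("counts", "fpkm")) {
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg) > 0)
      stop(sprintf("negative value at gene '%s', sample '%s'",
                   gene_ids[neg[1, 1]], colnames(m)[neg[1, 2]]))
  }
  if (value_kind == "counts" && any(m != round(m))) {
    w <- which(m != round(m), arr.ind = TRUE)
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 gene_ids[w[1, 1]], colnames(m)[w[1, 2]]))
  }
  expression_matrix(m, value_kind)
}

#' Construct an expression_matrix object
#'
#' @param values numeric genes x samples matrix with dimnames.
#' @param value_kind `"counts"`, `"fpkm"` or `"log2fpkm"`.
#' @param gene_lengths optional per-gene length in bp.
#' @param library_sizes optional per-sample mapped-fragment totals.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, value_kind, gene_lengths = NULL,
                              library_sizes = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (!is.null(gene_lengths)) {
    stopifnot(length(gene_lengths) == nrow(values), all(gene_lengths > 0))
    names(gene_lengths) <- rownames(values)
  }
  if (!is.null(library_sizes)) {
    stopifnot(length(library_sizes) == ncol(values), all(library_sizes > 0))
    names(library_sizes) <- colnames(values)
  }
  structure(list(values = values, value_kind = value_kind,
                 gene_lengths = gene_lengths, library_sizes = library_sizes),
            class = "expression_matrix")
}

#' Write an expression matrix to TSV
#'
#' Round-trips bit-identically with [read_expression_matrix()] for values that
#' print exactly (counts always do).
#'
#' @param em an `expression_matrix` (or bare matrix).
#' @param path output TSV path.
#' @export
write_expression_matrix <- function(em, path) {
  m <- if (inherits(em, "expression_matrix")) em$values else em
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-metadata TSV
#'
#' @param path TSV with the exact columns of the metadata schema (see
#'   [default_study_design()]).
#' @return validated metadata `data.frame`.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  validate_metadata(meta)
  meta
}

#' Write a sample-metadata TSV
#' @param meta metadata `data.frame`.
#' @param path output path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- SAM read-pair QC filter -------------------------------------------------

#' Parse read pairs from a name-sorted SAM file
#'
#' Reads a SAM text stream and assembles primary-alignment mate pairs by query
#' name (consecutive records). Secondary/supplementary alignments (FLAG 0x100
#' or 0x800) are skipped. A record without a same-name mate is reported as
#' `unpaired`.
#'
#' @param path SAM file.
#' @param mismatches optional named integer vector (by read id) supplying
#'   mismatch counts when NM tags are absent.
#' @return A `data.frame` of pair records: `read_id`, `chrom1`, `chrom2`,
#'   `mapq1`, `mapq2`, `mismatches1`, `mismatches2`, `has_gap1`, `has_gap2`,
#'   `insert_size`, plus `n_unpaired` as an attribute together with the
#'   unpaired ids.
#' @export
read_sam_pairs <- function(path, mismatches = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    out <- empty_pair_table()
    attr(out, "unpaired") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 11))
    stop("unparseable SAM record at line ", which(nf < 11)[1],
         " (fewer than 11 fields)")
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  if (anyNA(flag)) stop("unparseable FLAG at line ", which(is.na(flag))[1])
  keep <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  fields <- fields[keep]; qname <- qname[keep]; flag <- flag[keep]
  rname <- vapply(fields, `[[`, "", 3L)
  mapq <- as.integer(vapply(fields, `[[`, "", 5L))
  cigar <- vapply(fields, `[[`, "", 6L)
  tlen <- as.integer(vapply(fields, `[[`, "", 9L))
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag) == 0) NA_integer_ else as.integer(sub("^NM:i:", "", tag[1]))
  }, 1L)
  if (anyNA(nm)) {
    if (is.null(mismatches))
      stop("NM tag missing for read(s) ", paste(utils::head(qname[is.na(nm)], 3),
           collapse = ", "), " and no side-band mismatch counts supplied")
    nm[is.na(nm)] <- mismatches[qname[is.na(nm)]]
    if (anyNA(nm)) stop("mismatch count unavailable for some reads")
  }
  has_gap <- grepl("[IDN]", cigar)
  first <- bitwAnd(flag, 0x40L) != 0L

  # name-sorted: pair consecutive records sharing a qname
  r <- rle(qname)
  unpaired <- r$values[r$lengths == 1]
  pair_idx <- which(r$lengths == 2)
  starts <- cumsum(c(1L, r$lengths))[pair_idx]
  if (any(r$lengths > 2))
    stop("more than two primary alignments for read ",
         r$values[r$lengths > 2][1])
  if (length(starts) == 0) {
    out <- empty_pair_table()
  } else {
    i1 <- starts; i2 <- starts + 1L
    swap <- !first[i1] & first[i2]
    a <- ifelse(swap, i2, i1); b <- ifelse(swap, i1, i2)
    out <- data.frame(
      read_id = qname[a], chrom1 = rname[a], chrom2 = rname[b],
      mapq1 = mapq[a], mapq2 = mapq[b],
      mismatches1 = nm[a], mismatches2 = nm[b],
      has_gap1 = has_gap[a], has_gap2 = has_gap[b],
      insert_size = abs(tlen[a]), stringsAsFactors = FALSE
    )
  }
  attr(out, "unpaired") <- unpaired
  out
}

empty_pair_table <- function() {
  data.frame(read_id = character(0), chrom1 = character(0), chrom2 = character(0),
             mapq1 = integer(0), mapq2 = integer(0),
             mismatches1 = integer(0), mismatches2 = integer(0),
             has_gap1 = logical(0), has_gap2 = logical(0),
             insert_size = integer(0), stringsAsFactors = FALSE)
}

#' QC-filter aligned read pairs
#'
#' A pair is kept iff at least one mate is well aligned (MAPQ > 10, no
#' insertion/deletion/skip in its CIGAR, at most 3 mismatches) AND both mates
#' map to the same chromosome AND the absolute template length is between
#' 150 bp and 1 Mb inclusive. Rejection reasons are assigned with priority
#' quality > trans_chromosomal > insert so that the stats partition the input.
#'
#' @param pairs pair table from [read_sam_pairs()] (or equivalent columns).
#' @param min_insert,max_insert insert-size bounds in bp.
#' @param min_mapq kept mates must exceed this MAPQ.
#' @param max_mismatches maximum mismatch count for a qualifying mate.
#' @return list with `kept` (logical vector), `pairs` (the kept subset) and
#'   `stats` (named counts: kept, quality, trans_chromosomal, insert,
#'   unpaired).
#' @export
filter_read_pairs <- function(pairs, min_insert = 150, max_insert = 1e6,
                              min_mapq = 10, max_mismatches = 3) {
  ok1 <- pairs$mapq1 > min_mapq & !pairs$has_gap1 & pairs$mismatches1 <= max_mismatches
  ok2 <- pairs$mapq2 > min_mapq & !pairs$has_gap2 & pairs$mismatches2 <= max_mismatches
  quality_ok <- ok1 | ok2
  same_chrom <- pairs$chrom1 == pairs$chrom2
  insert_ok <- pairs$insert_size >= min_insert & pairs$insert_size <= max_insert
  kept <- quality_ok & same_chrom & insert_ok
  reason <- rep("kept", nrow(pairs))
  reason[!insert_ok] <- "insert"
  reason[!same_chrom] <- "trans_chromosomal"
  reason[!quality_ok] <- "quality"
  unpaired <- attr(pairs, "unpaired")
  stats <- c(kept = sum(kept),
             quality = sum(reason == "quality"),
             trans_chromosomal = sum(reason == "trans_chromosomal"),
             insert = sum(reason == "insert"),
             unpaired = length(unpaired))
  list(kept = kept, pairs = pairs[kept, , drop = FALSE], stats = stats)
}

#' Filter a SAM file and write the kept pairs
#'
#' Convenience wrapper: parses, filters and writes the surviving alignment
#' lines (plus the original header) to `out`.
#'
#' @param path input SAM; @param out output SAM path; @param stats_path
#'   optional JSON path for the rejection statistics.
#' @inheritParams filter_read_pairs
#' @return the filter stats, invisibly.
#' @export
filter_sam_file <- function(path, out, stats_path = NULL, min_insert = 150,
                            max_insert = 1e6, min_mapq = 10, max_mismatches = 3) {
  pairs <- read_sam_pairs(path)
  res <- filter_read_pairs(pairs, min_insert, max_insert, min_mapq, max_mismatches)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  qn <- vapply(strsplit(body, "\t", fixed = TRUE), `[[`, "", 1L)
  writeLines(c(hdr, body[qn %in% res$pairs$read_id]), out)
  if (!is.null(stats_path))
    writeLines(paste0("{", paste(sprintf('"%s": %d', names(res$stats),
                                         res$stats), collapse = ", "), "}"),
               stats_path)
  invisible(res$stats)
}

# ---- phased VCF --------------------------------------------------------------

#' Read phased genotypes for selected donors from a VCF
#'
#' For each requested donor, returns the heterozygous sites with which allele
#' lies on haplotype 1 vs haplotype 2. The paternal/maternal designation of
#' the haplotypes is a label carried by the caller, not inferred here.
#' Unphased heterozygous genotypes ("0/1") are skipped and counted.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param donors character vector of sample columns to extract.
#' @return named list per donor of `data.frame`s with `snp_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `hap1`, `hap2` (allele codes 0 = ref, 1 = alt);
#'   attribute `n_unphased` counts skipped het sites per donor.
#' @export
read_phased_vcf <- function(path, donors) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  miss <- setdiff(donors, colnames(gt))
  if (length(miss) > 0)
    stop("donor column(s) missing from VCF: ", paste(miss, collapse = ", "))
  fix <- vcfR::getFIX(vcf)
  snp_id <- fix[, "ID"]
  no_id <- is.na(snp_id) | snp_id == "."
  snp_id[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  out <- list()
  n_unphased <- integer(length(donors))
  names(n_unphased) <- donors
  for (d in donors) {
    g <- gt[, d]
    phased <- grepl("|", g, fixed = TRUE)
    parts <- strsplit(g, "[|/]")
    a1 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
    a2 <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2) p[[2]] else NA_character_, "")))
    het <- !is.na(a1) & !is.na(a2) & a1 != a2
    skipped <- het & !phased
    n_unphased[d] <- sum(skipped)
    if (any(skipped))
      warning(sum(skipped), " unphased heterozygous site(s) skipped for donor ", d)
    use <- het & phased
    out[[d]] <- data.frame(
      snp_id = snp_id[use], chrom = fix[use, "CHROM"],
      pos = as.integer(fix[use, "POS"]),
      ref = fix[use, "REF"], alt = fix[use, "ALT"],
      hap1 = a1[use], hap2 = a2[use],
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  attr(out, "n_unphased") <- n_unphased
  out
}

#' Write a minimal phased VCF
#'
#' Emits a small VCF 4.2 text file with phased GT fields, as produced by the
#' synthetic-data generator and consumed by [read_phased_vcf()].
#'
#' @param sites `data.frame` with `chrom`, `pos`, `snp_id`, `ref`, `alt`.
#' @param genotypes character matrix (sites x donors) of GT strings like
#'   `"0|1"`.
#' @param path output path.
#' @export
write_phased_vcf <- function(sites, genotypes, path) {
  stopifnot(nrow(sites) == nrow(genotypes))
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(genotypes)), collapse = "\t"))
  body <- paste(sites$chrom, sites$pos, sites$snp_id, sites$ref, sites$alt,
                ".", "PASS", ".", "GT",
                apply(genotypes, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
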