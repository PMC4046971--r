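#' The default 47-sample study design
#'
#' Builds the sample-metadata table for the reference study layout: 18 adult
#' samples (6 fibroblast, 3 keratinocyte, 9 endothelial progenitor cell (EPC)
#' passages), 25 iPSC lines (9 fibroblast-derived, 6 keratinocyte-derived,
#' 10 EPC-derived) and 4 embryonic stem cell (ESC) samples from the H9 and
#' Val9 lines, spread over four donors (S2, S5, S7 male; S4 female) and two
#' sequencing batches.
#'
#' The donor-to-sample assignment within each tissue is fixed here (the tissue
#' totals determine it only partially); ESC donors are not study donors and
#' therefore carry no donor random effect downstream.
#'
#' @return A `data.frame` with columns `sample_id`, `donor`, `cell_class`
#'   (`adult`/`iPSC`/`ESC`), `adult_tissue` (`fibroblast`/`keratinocyte`/
#'   `EPC`/`none`), `tissue_of_origin` (`F`/`K`/`E`/`none`), `batch`
#'   (`"1"`/`"2"`) and `replicate_label`.
#' @export
default_study_design <- function() {
  rows <- list()
  add <- function(donor, cell_class, adult_tissue, origin, n, prefix) {
    for (i in seq_len(n)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sprintf("%s-%s-%d", prefix, donor, i),
        donor = donor, cell_class = cell_class,
        adult_tissue = adult_tissue, tissue_of_origin = origin,
        batch = NA_character_, replicate_label = sprintf("p%d", i),
        stringsAsFactors = FALSE
      )
    }
  }
  # adult passages: 6 fibroblast (2 donors), 3 keratinocyte (1), 9 EPC (3)
  add("S2", "adult", "fibroblast", "none", 3, "Fib")
  add("S7", "adult", "fibroblast", "none", 3, "Fib")
  add("S2", "adult", "keratinocyte", "none", 3, "Ker")
  add("S2", "adult", "EPC", "none", 3, "EPC")
  add("S5", "adult", "EPC", "none", 3, "EPC")
  add("S7", "adult", "EPC", "none", 3, "EPC")
  # iPSC lines: 9 F-iPSC, 6 K-iPSC, 10 E-iPSC
  add("S2", "iPSC", "none", "F", 3, "F-iPSC")
  add("S4", "iPSC", "none", "F", 3, "F-iPSC")
  add("S7", "iPSC", "none", "F", 3, "F-iPSC")
  add("S2", "iPSC", "none", "K", 3, "K-iPSC")
  add("S4", "iPSC", "none", "K", 3, "K-iPSC")
  add("S2", "iPSC", "none", "E", 3, "E-iPSC")
  add("S5", "iPSC", "none", "E", 3, "E-iPSC")
  add("S7", "iPSC", "none", "E", 4, "E-iPSC")
  # ESC: two lines, two growths each; donors are not study donors
  add("H9", "ESC", "none", "none", 2, "ESC")
  add("Val9", "ESC", "none", "none", 2, "ESC")
  meta <- do.call(rbind, rows)
  # two sequencing batches, interleaved across the classes
  meta$batch <- as.character(rep_len(c(1L, 2L), nrow(meta)))
  rownames(meta) <- NULL
  validate_metadata(meta)
  meta
}

#' A donor-nested-in-origin confounded design
#'
#' Builds a design in which every iPSC tissue of origin is represented by its
#' own disjoint set of donors (plus ESC samples), i.e. donor genetic
#' background is perfectly nested within tissue of origin. On data simulated
#' from such a design with no true origin effect, dropping the donor
#' component from the variance decomposition reattributes donor variance to
#' tissue of origin — the confounding pattern that inflates apparent
#' epigenetic-memory signal in designs without shared donors.
#'
#' @param donors_per_origin donors per tissue of origin (default 2).
#' @param lines_per_donor iPSC lines per donor (default 3).
#' @param n_esc ESC samples (default 4).
#' @return a metadata `data.frame` (see [default_study_design()]).
#' @export
confounded_study_design <- function(donors_per_origin = 2, lines_per_donor = 3,
                                    n_esc = 4) {
  rows <- list()
  origins <- rep(c("F", "K", "E"), each = donors_per_origin)
  donors <- sprintf("D%d", seq_along(origins))
  for (i in seq_along(donors)) {
    for (l in seq_len(lines_per_donor)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("iPSC-%s-%d", donors[i], l), donor = donors[i],
        cell_class = "iPSC", adult_tissue = "none",
        tissue_of_origin = origins[i], batch = NA_character_,
        replicate_label = as.character(l), stringsAsFactors = FALSE)
    }
  }
  esc_lines <- rep(c("H9", "Val9"), length.out = n_esc)
  for (l in seq_len(n_esc)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("ESC-%d", l), donor = esc_lines[l],
      cell_class = "ESC", adult_tissue = "none", tissue_of_origin = "none",
      batch = NA_character_, replicate_label = as.character(l),
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, rows)
  meta$batch <- as.character(rep_len(c(1L, 2L), nrow(meta)))
  rownames(meta) <- NULL
  validate_metadata(meta)
  meta
}

#' Validate a sample-metadata table
#'
#' Checks the structural invariants of the design: adult samples have an adult
#' tissue and no tissue of origin, iPSC samples have a tissue of origin, ESC
#' samples have neither.
#'
#' @param meta a metadata `data.frame` as returned by [default_study_design()].
#' @return `meta`, invisibly, or an error.
#' @export
validate_metadata <- function(meta) {
  need <- c("sample_id", "donor", "cell_class", "adult_tissue",
            "tissue_of_origin", "batch", "replicate_label")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0)
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  ok_class <- meta$cell_class %in% c("adult", "iPSC", "ESC")
  if (!all(ok_class))
    stop("unknown cell_class: ",
         paste(unique(meta$cell_class[!ok_class]), collapse = ", "))
  adult <- meta$cell_class == "adult"
  ipsc <- meta$cell_class == "iPSC"
  esc <- meta$cell_class == "ESC"
  if (any(adult & (meta$adult_tissue == "none" | meta$tissue_of_origin != "none")))
    stop("adult samples must have adult_tissue set and tissue_of_origin = none")
  if (any(ipsc & (meta$tissue_of_origin == "none" | meta$adult_tissue != "none")))
    stop("iPSC samples must have tissue_of_origin set and adult_tissue = none")
  if (any(esc & (meta$adult_tissue != "none" | meta$tissue_of_origin != "none")))
    stop("ESC samples must have adult_tissue = tissue_of_origin = none")
  bad_t <- !(meta$adult_tissue %in% c("fibroblast", "keratinocyte", "EPC", "none"))
  if (any(bad_t)) stop("unknown adult_tissue values")
  bad_o <- !(meta$tissue_of_origin %in% c("F", "K", "E", "none"))
  if (any(bad_o)) stop("unknown tissue_of_origin values")
  invisible(meta)
}

#' Build the random-effect design matrices for the variance-component model
#'
#' Constructs the four indicator design matrices of the mixed model (the
#' intercept is profiled out at fit time, so no explicit intercept design is
#' returned):
#' \describe{
#'   \item{Z2}{5-level cell-class factor: the three adult tissues, iPSC, ESC.
#'     The adult-tissue levels share one variance (`delta2_adult`), the two
#'     pluripotent levels another (`delta2_pluri`) — the latter is what
#'     separates iPSCs from ESCs.}
#'   \item{Z3}{iPSC tissue of origin (F/K/E); rows are zero for non-iPSC
#'     samples. Variance `delta3_origin`.}
#'   \item{Z4}{donor within cell class: separate donor levels for adult and
#'     iPSC samples (`delta4_adult`, `delta4_ipsc`); ESC rows are zero because
#'     ESC donors are not study donors.}
#'   \item{Z5}{sequencing batch, variance `delta5_batch`.}
#' }
#'
#' @param meta sample metadata (see [default_study_design()]).
#' @return An object of class `design_set`: a list with elements `Z` (named
#'   list of indicator matrices), `param` (named list mapping each column of
#'   each Z to its variance-parameter name), `meta`, and `components` (the
#'   component names usable for variance-explained summaries).
#' @export
build_design <- function(meta) {
  validate_metadata(meta)
  n <- nrow(meta)
  ind <- function(labels, levels) {
    Z <- matrix(0, n, length(levels), dimnames = list(meta$sample_id, levels))
    hit <- labels %in% levels
    Z[cbind(which(hit), match(labels[hit], levels))] <- 1
    Z
  }
  class5 <- ifelse(meta$cell_class == "adult", meta$adult_tissue, meta$cell_class)
  Z2 <- ind(class5, c("fibroblast", "keratinocyte", "EPC", "iPSC", "ESC"))
  p2 <- c(rep("delta2_adult", 3), rep("delta2_pluri", 2))

  origin <- ifelse(meta$cell_class == "iPSC", meta$tissue_of_origin, NA)
  Z3 <- ind(origin, c("F", "K", "E"))
  p3 <- rep("delta3_origin", 3)

  donor_cc <- ifelse(meta$cell_class == "ESC", NA,
                     paste(meta$cell_class, meta$donor, sep = ":"))
  lev4 <- sort(unique(donor_cc[!is.na(donor_cc)]))
  Z4 <- ind(donor_cc, lev4)
  p4 <- ifelse(startsWith(lev4, "adult:"), "delta4_adult", "delta4_ipsc")

  Z5 <- ind(meta$batch, sort(unique(meta$batch)))
  p5 <- rep("delta5_batch", ncol(Z5))

  out <- list(
    Z = list(Z2 = Z2, Z3 = Z3, Z4 = Z4, Z5 = Z5),
    param = list(Z2 = p2, Z3 = p3, Z4 = p4, Z5 = p5),
    meta = meta,
    components = c("adult_tissue", "ips_vs_es", "origin",
                   "donor_adult", "donor_ipsc", "batch")
  )
  class(out) <- "design_set"
  out
}

# component name -> variance-parameter name
component_param <- c(
  adult_tissue = "delta2_adult", ips_vs_es = "delta2_pluri",
  origin = "delta3_origin", donor_adult = "delta4_adult",
  donor_ipsc = "delta4_ipsc", batch = "delta5_batch"
)

# component name -> which samples it acts on (logical over meta rows)
component_samples <- function(component, meta) {
  switch(component,
    adult_tissue = meta$cell_class == "adult",
    ips_vs_es = meta$cell_class %in% c("iPSC", "ESC"),
    origin = meta$cell_class == "iPSC",
    donor_adult = meta$cell_class == "adult",
    donor_ipsc = meta$cell_class == "iPSC",
    batch = rep(TRUE, nrow(meta)),
    stop("unknown component: ", component)
  )
}

#' Residual-variance grouping for a residual model
#'
#' @param meta sample metadata.
#' @param residual_model `"homo"` (single error term), `"het1"` (adult / iPSC /
#'   ESC error terms) or `"het2"` (separate terms per adult tissue and per iPSC
#'   tissue of origin, plus ESC: seven groups on the default design).
#' @return A character vector of residual-group labels, one per sample.
#' @export
residual_groups <- function(meta, residual_model = c("homo", "het1", "het2")) {
  residual_model <- match.arg(residual_model)
  switch(residual_model,
    homo = rep("all", nrow(meta)),
    het1 = meta$cell_class,
    het2 = ifelse(meta$cell_class == "adult",
                  paste0(meta$adult_tissue, "-adult"),
                  ifelse(meta$cell_class == "iPSC",
                         paste0(meta$tissue_of_origin, "-iPSC"), "ESC"))
  )
}
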