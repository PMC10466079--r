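#' Build PTM-site identifiers from a modified-peptide table
#'
#' Modification-specific proteomics tests abundance per modified site, not
#' per protein, so features are re-identified by
#' `"PROTEIN_<aa><position>_M<multiplicity>"` (e.g. `"P04637_S15_M1"`).
#' Rows whose site fields are missing are dropped (count recorded in the
#' attribute `"dropped"`); duplicate keys are disambiguated with
#' [make_unique()], so rows quantified at different multiplicities stay
#' distinct features.
#'
#' @param qt a modified-peptide `QuantTable`.
#' @param protein_col,position_col,aa_col annotation columns holding the
#'   protein accession, residue position and amino acid (MaxQuant sites
#'   defaults `"Protein"`, `"Position"`, `"Amino acid"`).
#' @param multiplicity_col optional annotation column with the number of
#'   modifications on the peptide; absent means multiplicity 1.
#' @return the `QuantTable` with SiteKey-based `feature_id`/`name`.
#' @export
build_site_ids <- function(qt, protein_col = "Protein",
                           position_col = "Position",
                           aa_col = "Amino acid",
                           multiplicity_col = NULL) {
  stopifnot(inherits(qt, "QuantTable"))
  ann <- qt$annotations
  for (col in c(protein_col, position_col, aa_col))
    if (!col %in% colnames(ann))
      stop("site column '", col, "' not found in annotations")
  protein <- trimws(as.character(ann[[protein_col]]))
  pos_raw <- trimws(as.character(ann[[position_col]]))
  aa <- trimws(as.character(ann[[aa_col]]))
  mult <- if (!is.null(multiplicity_col) &&
              multiplicity_col %in% colnames(ann))
    trimws(as.character(ann[[multiplicity_col]])) else rep("1", nrow(ann))
  mult[is.na(mult) | !nzchar(mult)] <- "1"
  complete <- !is.na(protein) & nzchar(protein) &
    !is.na(pos_raw) & nzchar(pos_raw) & !is.na(aa) & nzchar(aa)
  bad_pos <- complete & !grepl("^[0-9]+$", pos_raw)
  if (any(bad_pos))
    stop("unparseable position(s) in row(s): ",
         paste(which(bad_pos), collapse = ", "))
  pos <- suppressWarnings(as.integer(pos_raw))
  if (any(complete & pos < 1L))
    stop("positions must be positive integers")
  dropped <- sum(!complete)
  keep <- which(complete)
  ids <- sprintf("%s_%s%d_M%s", protein[keep], aa[keep], pos[keep],
                 mult[keep])
  ids <- make_unique(ids, ids)
  out <- quant_table(feature_id = ids, name = ids,
                     raw_ids = qt$raw_ids[keep],
                     intensities = qt$intensities[keep, , drop = FALSE],
                     annotations = ann[keep, , drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

#' Localization-probability filter for PTM sites
#'
#' Keeps sites whose localization probability meets the threshold (class-I
#' convention 0.75).  A column that is entirely empty disables the filter
#' (recorded in the attribute `"skipped"`).
#'
#' @param qt a site-level `QuantTable`.
#' @param prob_col annotation column with localization probabilities.
#' @param threshold minimum probability (default 0.75).
#' @return the filtered `QuantTable`.
#' @export
filter_localization <- function(qt, prob_col = "Localization prob",
                                threshold = 0.75) {
  stopifnot(inherits(qt, "QuantTable"))
  if (!prob_col %in% colnames(qt$annotations))
    stop("probability column '", prob_col, "' not found")
  prob <- suppressWarnings(as.numeric(as.character(qt$annotations[[prob_col]])))
  if (all(is.na(prob))) {
    attr(qt, "skipped") <- TRUE
    return(qt)
  }
  out <- subset_features(qt, !is.na(prob) & prob >= threshold)
  attr(out, "skipped") <- FALSE
  out
}

#' PTM-site differential-analysis pipeline
#'
#' The modification-specific pipeline: optional localization filter, then
#' the identical stage chain used for protein groups (missing-occupancy
#' filter, normalization, imputation, moderated t-tests), operating on
#' site features.  All stages are identifier-agnostic, so site-level output
#' equals protein-level output on the same numeric matrix.
#'
#' @param qt a site-level `QuantTable` (see [build_site_ids()]).
#' @param design design table, see [parse_design()].
#' @param contrasts character vector of `"condA_vs_condB"` strings.
#' @param prob_col optional localization-probability annotation column;
#'   `NULL` disables the filter.
#' @param prob_threshold localization threshold (default 0.75).
#' @param filter_thr missing-occupancy threshold, see [filter_missing()].
#' @param normalize `"vsn"`, `"median"` or `"none"`.
#' @param impute_method,impute_seed passed to [impute()].
#' @param alpha,lfc significance gates.
#' @return list with `qm` (the processed QuantMatrix) and `results`
#'   (the `ContrastResult` data.frame).
#' @export
run_ptm_pipeline <- function(qt, design, contrasts,
                             prob_col = NULL, prob_threshold = 0.75,
                             filter_thr = 0L,
                             normalize = c("vsn", "median", "none"),
                             impute_method = "left-shifted",
                             impute_seed = 1L,
                             alpha = 0.05, lfc = 1) {
  normalize <- match.arg(normalize)
  if (!is.null(prob_col))
    qt <- filter_localization(qt, prob_col, prob_threshold)
  run_quant_chain(qt, design, contrasts, filter_thr = filter_thr,
                  normalize = normalize, impute_method = impute_method,
                  impute_seed = impute_seed, alpha = alpha, lfc = lfc)
}

# shared stage chain: bind design -> occupancy filter -> normalize ->
# impute -> moderated tests
run_quant_chain <- function(qt, design, contrasts, filter_thr = 0L,
                            normalize = "vsn", impute_method = "left-shifted",
                            impute_seed = 1L, alpha = 0.05, lfc = 1) {
  qm <- bind_design(qt, design)
  qm <- filter_missing(qm, thr = filter_thr)
  qm <- switch(normalize,
    vsn = normalize_vsn(qm),
    median = normalize_median(log2_transform(qm)),
    none = log2_transform(qm))
  qm <- impute(qm, method = impute_method, seed = impute_seed)
  results <- test_diff(qm, contrasts, alpha = alpha, lfc = lfc)
  list(qm = qm, results = results)
}
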