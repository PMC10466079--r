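#' Quantification table (pre-design container)
#'
#' A `QuantTable` holds a feature-by-sample intensity matrix together with
#' feature identifiers and annotation columns, before an experimental design
#' is bound.  It is the common product of [read_wide_table()] and
#' [reshape_long()].
#'
#' @param feature_id character vector of unique feature identifiers.
#' @param name character vector of display names (gene/site labels), made
#'   unique with [make_unique()].
#' @param raw_ids character vector of original identifiers; protein groups
#'   keep the full `";"`-separated string.
#' @param intensities numeric matrix (features x samples) of non-negative
#'   intensities; missing values are `NA` (never 0).
#' @param annotations data.frame of per-feature annotation columns
#'   (sequence, protein, position, QC flags ...), one row per feature.
#'
#' @return An object of class `QuantTable`: a list with elements
#'   `feature_id`, `name`, `raw_ids`, `annotations`, `intensities`,
#'   `sample_names`.
#' @export
quant_table <- function(feature_id, name, raw_ids, intensities,
                        annotations = NULL) {
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id))
    stop("feature_id values must be pairwise distinct")
  if (!is.matrix(intensities))
    intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) != length(feature_id))
    stop("intensities must have one row per feature_id")
  if (is.null(colnames(intensities)))
    stop("intensities must carry sample names as column names")
  if (anyDuplicated(colnames(intensities)))
    stop("duplicate sample names in intensity matrix")
  if (any(intensities < 0, na.rm = TRUE))
    stop("negative intensities are not allowed on the raw scale")
  if (is.null(annotations))
    annotations <- data.frame(row.names = seq_along(feature_id))
  rownames(intensities) <- feature_id
  structure(
    list(feature_id = feature_id,
         name = as.character(name),
         raw_ids = as.character(raw_ids),
         annotations = annotations,
         intensities = intensities,
         sample_names = colnames(intensities)),
    class = "QuantTable")
}

#' @export
print.QuantTable <- function(x, ...) {
  cat(sprintf("QuantTable: %d features x %d samples\n",
              nrow(x$intensities), ncol(x$intensities)))
  cat("samples:", paste(utils::head(x$sample_names, 8), collapse = ", "),
      if (length(x$sample_names) > 8) "..." else "", "\n")
  cat(sprintf("missing cells: %d (%.1f%%)\n", sum(is.na(x$intensities)),
              100 * mean(is.na(x$intensities))))
  if (ncol(x$annotations))
    cat("annotations:", paste(colnames(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' Dimensions of a QuantTable
#' @param x a `QuantTable`.
#' @return integer vector `c(features, samples)`.
#' @export
dim.QuantTable <- function(x) dim(x$intensities)

#' Subset a QuantTable by feature
#' @param qt a `QuantTable`.
#' @param keep logical or integer index over features.
#' @return the subsetted `QuantTable`.
#' @export
subset_features <- function(qt, keep) {
  stopifnot(inherits(qt, "QuantTable"))
  quant_table(qt$feature_id[keep], qt$name[keep], qt$raw_ids[keep],
              qt$intensities[keep, , drop = FALSE],
              qt$annotations[keep, , drop = FALSE])
}

#' Parse an experimental design table
#'
#' Validates a sample/condition/replicate table.  Conditions represented by a
#' single replicate are flagged with a warning (variance cannot be estimated
#' within them).
#'
#' @param table a data.frame with columns `sample`, `condition`, `replicate`,
#'   or a path to a TSV/CSV file with those columns.
#' @return a validated design data.frame with character `sample`/`condition`
#'   and integer `replicate`.
#' @export
parse_design <- function(table) {
  if (is.character(table) && length(table) == 1L) {
    sep <- if (grepl("\\.csv$", table, ignore.case = TRUE)) "," else "\t"
    table <- utils::read.table(table, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE, check.names = FALSE)
  }
  need <- c("sample", "condition", "replicate")
  if (!all(need %in% colnames(table)))
    stop("design must have columns sample, condition, replicate")
  design <- data.frame(sample = as.character(table$sample),
                       condition = as.character(table$condition),
                       replicate = as.integer(table$replicate),
                       stringsAsFactors = FALSE)
  if (anyNA(design$replicate) || any(design$replicate < 1L))
    stop("replicate must be a positive integer")
  key <- paste(design$condition, design$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- key[duplicated(key)][1]
    stop("duplicated (condition, replicate) pair: ",
         gsub("\r", ", ", bad, fixed = TRUE))
  }
  if (anyDuplicated(design$sample))
    stop("duplicated sample names in design")
  singletons <- names(which(table(design$condition) == 1L))
  if (length(singletons))
    warning("condition(s) with a single replicate: ",
            paste(singletons, collapse = ", "))
  design
}

#' Bind a design to a QuantTable, producing a QuantMatrix
#'
#' A `QuantMatrix` is a [SummarizedExperiment::SummarizedExperiment] whose
#' single assay `"quant"` carries the intensity matrix, whose `colData` is the
#' experimental design, and whose metadata records the intensity scale
#' (`"raw"`, `"log2"` or `"glog2"`) and an ordered history of processing
#' steps.  Columns are reordered to match the design.
#'
#' @param qt a `QuantTable`.
#' @param design a design data.frame as returned by [parse_design()].
#' @return a `SummarizedExperiment` ("QuantMatrix").
#' @export
bind_design <- function(qt, design) {
  stopifnot(inherits(qt, "QuantTable"))
  design <- parse_design(design)
  missing_samples <- setdiff(design$sample, qt$sample_names)
  if (length(missing_samples))
    stop("design sample(s) not found among intensity columns: ",
         paste(missing_samples, collapse = ", "))
  X <- qt$intensities[, design$sample, drop = FALSE]
  rd <- S4Vectors::DataFrame(name = qt$name, raw_ids = qt$raw_ids,
                             row.names = qt$feature_id)
  if (ncol(qt$annotations))
    rd <- cbind(rd, S4Vectors::DataFrame(qt$annotations, check.names = FALSE))
  qm <- SummarizedExperiment::SummarizedExperiment(
    assays = list(quant = X),
    colData = S4Vectors::DataFrame(design, row.names = design$sample),
    rowData = rd)
  S4Vectors::metadata(qm)$scale <- "raw"
  S4Vectors::metadata(qm)$history <- list()
  add_history(qm, "bind_design",
              list(samples = ncol(qm), conditions =
                     length(unique(design$condition))),
              nrow(qm), nrow(qm))
}

#' @name quant-accessors
#' @rdname quant-accessors
#' @title Accessors for QuantMatrix objects
#' @description Small helpers around the `SummarizedExperiment` slots:
#'   `quant()` returns the intensity matrix, `design()` the design
#'   data.frame, `quant_scale()` the current intensity scale, `history()` the
#'   ordered list of processing-step records.
#' @param qm a QuantMatrix (`SummarizedExperiment`).
#' @return `quant()`: numeric matrix; `design()`: data.frame;
#'   `quant_scale()`: character scalar; `history()`: list of records.
NULL

#' @rdname quant-accessors
#' @export
quant <- function(qm) SummarizedExperiment::assay(qm, "quant")

#' @rdname quant-accessors
#' @export
design <- function(qm)
  as.data.frame(SummarizedExperiment::colData(qm))[, c("sample", "condition",
                                                       "replicate")]

#' @rdname quant-accessors
#' @export
quant_scale <- function(qm) S4Vectors::metadata(qm)$scale

#' @rdname quant-accessors
#' @export
history <- function(qm) S4Vectors::metadata(qm)$history

set_quant <- function(qm, X, scale = NULL) {
  dimnames(X) <- dimnames(qm)
  SummarizedExperiment::assay(qm, "quant", withDimnames = FALSE) <- X
  if (!is.null(scale))
    S4Vectors::metadata(qm)$scale <- scale
  qm
}

# Every mutating operation appends exactly one record.
add_history <- function(qm, op, params, n_in, n_out) {
  rec <- list(op = op, params = params,
              features_in = as.integer(n_in), features_out = as.integer(n_out))
  S4Vectors::metadata(qm)$history <-
    c(S4Vectors::metadata(qm)$history, list(rec))
  qm
}
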