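#' Read a wide quantification table (MaxQuant-style dialect)
#'
#' Reads a tab-separated proteinGroups/peptides/modified-peptide table and
#' extracts the per-sample intensity columns sharing a common prefix.  In
#' this dialect a 0 intensity encodes a missing value and is converted to
#' `NA`; the strings `"NaN"`, `"NA"` and `"Filtered"` are also read as
#' missing.  All rows are retained, including flagged decoys/contaminants —
#' QC filtering happens later in [filter_flags()].
#'
#' @param path path to a tab-separated file with a header row.
#' @param intensity_prefix common prefix of the intensity columns, stripped
#'   to obtain sample names (e.g. `"LFQ intensity "`).
#' @param id_column column holding the (possibly `";"`-separated) feature
#'   identifier.
#' @param name_column column holding the display name (gene symbol etc.);
#'   empty names fall back to the identifier and duplicates are resolved with
#'   [make_unique()].  May be `NULL`.
#' @param flag_columns character vector of QC flag columns (e.g.
#'   `c("Reverse", "Potential contaminant")`) to carry into the annotations.
#' @param annotation_columns further annotation columns to keep.
#' @return a [quant_table()] object.
#' @export
read_wide_table <- function(path, intensity_prefix, id_column,
                            name_column = NULL,
                            flag_columns = character(),
                            annotation_columns = character()) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  int_cols <- colnames(tab)[startsWith(colnames(tab), intensity_prefix)]
  if (!length(int_cols))
    stop("no column matches intensity prefix '", intensity_prefix, "'")
  samples <- substring(int_cols, nchar(intensity_prefix) + 1L)
  if (anyDuplicated(samples))
    stop("duplicate sample names after stripping prefix: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (!id_column %in% colnames(tab))
    stop("id column '", id_column, "' not found")
  X <- as.matrix(vapply(tab[int_cols], parse_intensity, numeric(nrow(tab))))
  if (nrow(tab) == 1L) X <- matrix(X, nrow = 1L)
  X[!is.na(X) & X == 0] <- NA_real_  # MaxQuant dialect: 0 means not observed
  colnames(X) <- samples
  raw_ids <- as.character(tab[[id_column]])
  nm <- if (!is.null(name_column) && name_column %in% colnames(tab))
    as.character(tab[[name_column]]) else rep("", nrow(tab))
  name <- make_unique(nm, raw_ids)
  keep_ann <- intersect(c(flag_columns, annotation_columns), colnames(tab))
  missing_flags <- setdiff(flag_columns, colnames(tab))
  if (length(missing_flags))
    stop("flag column(s) not found: ", paste(missing_flags, collapse = ", "))
  ann <- tab[, keep_ann, drop = FALSE]
  quant_table(feature_id = make_unique(name, raw_ids), name = name,
              raw_ids = raw_ids, intensities = X, annotations = ann)
}

parse_intensity <- function(v) {
  if (is.numeric(v)) return(as.numeric(v))
  v <- trimws(as.character(v))
  v[v %in% c("NaN", "NA", "Filtered", "")] <- NA_character_
  suppressWarnings(as.numeric(v))
}

#' Reshape a long-format (DIA-style) report into a QuantTable
#'
#' DIA-NN/Spectronaut-style reports carry one row per feature x sample.
#' Feature/sample/value column names are explicit arguments since DIA
#' software dialects differ.  (feature, sample) pairs absent from the long
#' table become missing cells; the wide matrix keeps features and samples in
#' first-appearance order.
#'
#' @param rows a long data.frame, or a path to a tab-separated file.
#' @param feature_key,sample_key,value_key column names for the feature
#'   identifier, the sample identifier and the quantity.
#' @param duplicate_policy what to do when a (feature, sample) pair occurs
#'   more than once: `"error"` (default), `"max"` or `"sum"`.
#' @param name_key optional column with display names.
#' @return a [quant_table()] object (raw scale, `NA` for absent pairs).
#' @export
reshape_long <- function(rows, feature_key, sample_key, value_key,
                         duplicate_policy = c("error", "max", "sum"),
                         name_key = NULL) {
  duplicate_policy <- match.arg(duplicate_policy)
  if (is.character(rows) && length(rows) == 1L)
    rows <- utils::read.delim(rows, header = TRUE, sep = "\t",
                              check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(feature_key, sample_key, value_key))
    if (!col %in% colnames(rows)) stop("column '", col, "' not found")
  feat <- as.character(rows[[feature_key]])
  samp <- as.character(rows[[sample_key]])
  val <- parse_intensity(rows[[value_key]])
  key <- paste(feat, samp, sep = "\r")
  if (anyDuplicated(key)) {
    if (duplicate_policy == "error") {
      bad <- strsplit(key[duplicated(key)][1], "\r", fixed = TRUE)[[1]]
      stop("duplicate (feature, sample) pair: (", bad[1], ", ", bad[2],
           "); set duplicate_policy to 'max' or 'sum' to aggregate")
    }
    fun <- if (duplicate_policy == "max") function(x) max(x, na.rm = TRUE)
           else function(x) sum(x, na.rm = TRUE)
    agg <- tapply(val, key, function(x)
      if (all(is.na(x))) NA_real_ else fun(x))
    first <- !duplicated(key)
    feat <- feat[first]; samp <- samp[first]
    val <- as.numeric(agg[paste(feat, samp, sep = "\r")])
  }
  features <- unique(feat)
  samples <- unique(samp)
  X <- matrix(NA_real_, length(features), length(samples),
              dimnames = list(features, samples))
  X[cbind(match(feat, features), match(samp, samples))] <- val
  nm <- if (!is.null(name_key) && name_key %in% colnames(rows)) {
    as.character(rows[[name_key]])[match(features, as.character(rows[[feature_key]]))]
  } else rep("", length(features))
  quant_table(feature_id = make_unique(make_unique(nm, features), features),
              name = make_unique(nm, features), raw_ids = features,
              intensities = X)
}

#' Melt a QuantTable to long format
#'
#' Inverse of [reshape_long()]: one row per observed (feature, sample) cell;
#' missing cells are omitted, matching the DIA convention that absence
#' encodes missingness.
#'
#' @param qt a `QuantTable`.
#' @return data.frame with columns `feature`, `sample`, `intensity`.
#' @export
melt_quant <- function(qt) {
  stopifnot(inherits(qt, "QuantTable"))
  X <- qt$intensities
  idx <- which(!is.na(X), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(feature = rownames(X)[idx[, 1]],
             sample = colnames(X)[idx[, 2]],
             intensity = X[idx],
             stringsAsFactors = FALSE)
}

#' Make feature names unique
#'
#' Empty or missing names are replaced by the corresponding fallback
#' identifier; duplicates are suffixed deterministically (`"A"`, `"A.1"`,
#' `"A.2"`, ...).  The operation is idempotent.
#'
#' @param names character vector of display names (may contain `""`/`NA`).
#' @param fallback_ids character vector of the same length used when a name
#'   is empty.
#' @return character vector of pairwise-distinct names.
#' @export
make_unique <- function(names, fallback_ids) {
  names <- as.character(names)
  fallback_ids <- as.character(fallback_ids)
  if (length(names) != length(fallback_ids))
    stop("names and fallback_ids must have equal length")
  empty <- is.na(names) | !nzchar(trimws(names))
  names[empty] <- fallback_ids[empty]
  still <- is.na(names) | !nzchar(trimws(names))
  if (any(still))
    stop("row(s) with both name and fallback id empty: ",
         paste(which(still), collapse = ", "))
  base::make.unique(names, sep = ".")
}

#' Write a QuantTable as a wide MaxQuant-style TSV
#'
#' Missing cells are written as 0 per the MaxQuant dialect, so the file
#' round-trips through [read_wide_table()].
#'
#' @param qt a `QuantTable`.
#' @param path output file path.
#' @param intensity_prefix prefix prepended to sample names.
#' @return `path`, invisibly.
#' @export
write_wide_table <- function(qt, path, intensity_prefix = "LFQ intensity ") {
  stopifnot(inherits(qt, "QuantTable"))
  X <- qt$intensities
  X[is.na(X)] <- 0
  colnames(X) <- paste0(intensity_prefix, colnames(X))
  out <- data.frame(ID = qt$raw_ids, `Gene names` = qt$name,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(qt$annotations))
    out <- cbind(out, qt$annotations)
  out <- cbind(out, as.data.frame(X, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
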