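#' Parse a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; `[section]`
#' headers are allowed and prefix their keys as `section.key`.  Values stay
#' strings; consumers coerce.
#'
#' @param path path to the config file.
#' @return named list of character values.
#' @export
parse_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- ""
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line: '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    out[[key]] <- val
  }
  out
}

cfg_get <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]] else default
}

cfg_num <- function(config, key, default)
  as.numeric(cfg_get(config, key, default))

cfg_split <- function(config, key, default = character()) {
  v <- cfg_get(config, key)
  if (is.null(v) || !nzchar(v)) return(default)
  trimws(strsplit(v, ",", fixed = TRUE)[[1]])
}

# Fork a per-stage seed from the global seed by stable stage-name hashing,
# so inserting a stage does not perturb later stages' random streams.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.integer(seed) + h) %% .Machine$integer.max)
}

file_digest <- function(path) {
  if (!file.exists(path)) return(NA_character_)
  as.character(tools::md5sum(path))
}

#' Run a differential-analysis pipeline end to end
#'
#' Orchestrates one of three pipelines — `"protein"` (protein-group tables),
#' `"ptm"` (modified-peptide tables with site identifiers) or
#' `"peptide-aggregate"` (peptide tables re-aggregated to proteins) — and
#' writes the processed matrix, one TSV per contrast, a combined wide TSV,
#' optional downstream outputs (over-representation analysis, fuzzy
#' clustering, induced subnetwork) and a JSON run log recording input
#' digests, every stage's parameters and feature counts, the seed, and the
#' output files.  Any stage error aborts with the stage name after writing
#' the partial log.
#'
#' @param config named list of configuration values (see the package
#'   vignette), or a path to a key=value file for [parse_config()].
#' @param overrides named list overriding config entries (CLI flags).
#' @return invisibly, a list with `qm`, `results` and `runlog`.
#' @export
run_pipeline <- function(config, overrides = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- parse_config(config)
  config[names(overrides)] <- overrides
  pipeline <- cfg_get(config, "pipeline")
  if (is.null(pipeline) ||
      !pipeline %in% c("protein", "ptm", "peptide-aggregate"))
    stop("config must set pipeline to one of protein, ptm, peptide-aggregate")
  input <- cfg_get(config, "input")
  design_path <- cfg_get(config, "design")
  outdir <- cfg_get(config, "outdir", ".")
  contrasts <- cfg_split(config, "contrasts")
  if (is.null(input) || is.null(design_path) || !length(contrasts))
    stop("config must set input, design and contrasts")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg_num(config, "seed", 1))
  runlog <- list(
    package = "proteopipe",
    version = as.character(utils::packageVersion("proteopipe")),
    pipeline = pipeline,
    seed = seed,
    inputs = list(quant = list(path = input, md5 = file_digest(input)),
                  design = list(path = design_path,
                                md5 = file_digest(design_path))),
    parameters = config[setdiff(names(config), c("input", "design"))],
    stages = list(),
    results = list(),
    outputs = character())
  log_path <- file.path(outdir, "runlog.json")
  note <- function(stage, params, n_in, n_out) {
    runlog$stages[[length(runlog$stages) + 1L]] <<-
      list(stage = stage, params = params,
           features_in = n_in, features_out = n_out)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      runlog$error <<- list(stage = stage, message = conditionMessage(e))
      write_runlog(runlog, log_path)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- ingest ---------------------------------------------------------
  qt <- run_stage("ingest", {
    if (identical(cfg_get(config, "input_format", "wide"), "long")) {
      reshape_long(input,
                   feature_key = cfg_get(config, "feature_key", "feature"),
                   sample_key = cfg_get(config, "sample_key", "sample"),
                   value_key = cfg_get(config, "value_key", "intensity"),
                   duplicate_policy = cfg_get(config, "duplicate_policy",
                                              "error"))
    } else {
      read_wide_table(input,
                      intensity_prefix = cfg_get(config, "intensity_prefix",
                                                 "LFQ intensity "),
                      id_column = cfg_get(config, "id_column", "ID"),
                      name_column = cfg_get(config, "name_column",
                                            "Gene names"),
                      flag_columns = cfg_split(config, "flag_columns"),
                      annotation_columns = cfg_split(config,
                                                     "annotation_columns"))
    }
  })
  note("ingest", list(input = input), NA_integer_, nrow(qt$intensities))
  dsg <- run_stage("design", parse_design(design_path))

  flag_cols <- cfg_split(config, "flag_columns")
  if (length(flag_cols)) {
    n_in <- nrow(qt$intensities)
    qt <- run_stage("filter_flags", filter_flags(qt, flag_cols))
    note("filter_flags", list(flag_columns = flag_cols), n_in,
         nrow(qt$intensities))
  }
  if (pipeline == "ptm") {
    n_in <- nrow(qt$intensities)
    qt <- run_stage("build_site_ids", build_site_ids(
      qt,
      protein_col = cfg_get(config, "protein_col", "Protein"),
      position_col = cfg_get(config, "position_col", "Position"),
      aa_col = cfg_get(config, "aa_col", "Amino acid"),
      multiplicity_col = cfg_get(config, "multiplicity_col")))
    note("build_site_ids", list(dropped = attr(qt, "dropped")), n_in,
         nrow(qt$intensities))
    prob_col <- cfg_get(config, "prob_col")
    if (!is.null(prob_col) && nzchar(prob_col)) {
      n_in <- nrow(qt$intensities)
      thr <- cfg_num(config, "prob_threshold", 0.75)
      qt <- run_stage("filter_localization",
                      filter_localization(qt, prob_col, thr))
      note("filter_localization",
           list(threshold = thr, skipped = isTRUE(attr(qt, "skipped"))),
           n_in, nrow(qt$intensities))
    }
  }

  # --- processing chain ----------------------------------------------
  qm <- run_stage("bind_design", bind_design(qt, dsg))
  qm <- run_stage("filter_missing",
                  filter_missing(qm, thr = as.integer(cfg_num(config,
                                                              "filter_thr", 0))))
  normalize <- cfg_get(config, "normalize", "vsn")
  qm <- run_stage("normalize", switch(normalize,
    vsn = normalize_vsn(qm),
    median = normalize_median(log2_transform(qm)),
    none = log2_transform(qm),
    stop("unknown normalization '", normalize, "'")))
  qm <- run_stage("impute", impute(
    qm,
    method = cfg_get(config, "impute_method", "left-shifted"),
    shift = cfg_num(config, "impute_shift", 1.8),
    width = cfg_num(config, "impute_width", 0.3),
    quantile = cfg_num(config, "impute_q", 0.01),
    k = as.integer(cfg_num(config, "impute_k", 10)),
    seed = stage_seed(seed, "impute")))
  if (pipeline == "peptide-aggregate") {
    qm <- run_stage("aggregate", aggregate_peptides(
      qm,
      grouping_key = cfg_get(config, "grouping_key", "Protein group"),
      method = cfg_get(config, "aggregate_method", "median-polish"),
      huber_k = cfg_num(config, "huber_k", 1.345)))
  }
  alpha <- cfg_num(config, "alpha", 0.05)
  lfc <- cfg_num(config, "lfc", 1)
  results <- run_stage("test_diff",
                       test_diff(qm, contrasts, alpha = alpha, lfc = lfc))
  for (rec in history(qm))
    note(rec$op, rec$params, rec$features_in, rec$features_out)
  note("test_diff", list(contrasts = contrasts, alpha = alpha, lfc = lfc),
       nrow(qm), nrow(qm))

  # --- outputs --------------------------------------------------------
  emit <- function(name, df) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    runlog$outputs <<- c(runlog$outputs, name)
    path
  }
  mat_df <- data.frame(feature_id = rownames(quant(qm)),
                       as.data.frame(quant(qm), check.names = FALSE),
                       check.names = FALSE, stringsAsFactors = FALSE)
  emit("processed_matrix.tsv", mat_df)
  sig_counts <- list()
  for (cn in unique(results$contrast_name)) {
    sub <- results[results$contrast_name == cn, , drop = FALSE]
    emit(paste0("contrast_", gsub("[^A-Za-z0-9_.-]", "_", cn), ".tsv"), sub)
    sig_counts[[cn]] <- sum(sub$significant, na.rm = TRUE)
  }
  wide <- stats::reshape(
    results[, c("feature_id", "contrast_name", "log2fc", "padj",
                "significant")],
    direction = "wide", idvar = "feature_id", timevar = "contrast_name")
  emit("results_wide.tsv", wide)
  sig_features <- unique(results$feature_id[results$significant])
  runlog$results$significant <- sig_counts
  runlog$results$n_significant_features <- length(sig_features)

  # --- optional downstream -------------------------------------------
  gmt <- cfg_get(config, "gmt")
  if (!is.null(gmt) && nzchar(gmt) && !length(sig_features)) {
    note("ora", list(skipped = "no significant features"), 0L, 0L)
    gmt <- NULL
  }
  if (!is.null(gmt) && nzchar(gmt)) {
    ora <- run_stage("ora", {
      gsc <- read_gmt(gmt)
      names_map <- SummarizedExperiment::rowData(qm)$name
      sig_names <- names_map[rownames(qm) %in% sig_features]
      ora_hypergeometric(sig_names, names_map, gsc,
                         min_size = as.integer(cfg_num(config,
                                                       "min_set_size", 5)),
                         max_size = as.integer(cfg_num(config,
                                                       "max_set_size", 500)))
    })
    emit("enrichment_ora.tsv", ora)
    runlog$results$top_sets <- utils::head(ora$set_name, 5L)
    note("ora", list(gmt = gmt), length(sig_features), nrow(ora))
  }
  cluster_k <- cfg_get(config, "cluster_k")
  if (!is.null(cluster_k) && nzchar(cluster_k) &&
      length(sig_features) <= as.integer(cluster_k)) {
    note("cluster", list(skipped = "fewer significant features than clusters"),
         length(sig_features), 0L)
    cluster_k <- NULL
  }
  if (!is.null(cluster_k) && nzchar(cluster_k)) {
    cl <- run_stage("cluster", {
      Z <- standardize_profiles(condition_means(qm, sig_features))
      fuzzy_cmeans(Z, k = as.integer(cluster_k),
                   m = cfg_num(config, "fuzzifier", 2),
                   seed = stage_seed(seed, "cluster"))
    })
    emit("clusters.tsv",
         data.frame(feature_id = rownames(cl$membership),
                    cluster = cl$cluster,
                    max_membership = apply(cl$membership, 1L, max),
                    stringsAsFactors = FALSE))
    note("cluster", list(k = as.integer(cluster_k)),
         length(sig_features), nrow(cl$membership))
  }
  network <- cfg_get(config, "network")
  if (!is.null(network) && nzchar(network)) {
    sub_g <- run_stage("network", {
      g <- load_network(network,
                        score_threshold = as.integer(
                          cfg_num(config, "network_threshold", 400)))
      names_map <- SummarizedExperiment::rowData(qm)$name
      induced_subnetwork(g, names_map[rownames(qm) %in% sig_features])
    })
    emit("network_edges.tsv", sub_g$edges)
    note("network", list(path = network, nodes = length(sub_g$nodes)),
         length(sig_features), nrow(sub_g$edges))
  }

  write_runlog(runlog, log_path)
  runlog$outputs <- c(runlog$outputs, "runlog.json")
  report_path <- file.path(outdir, "report.txt")
  write_report(log_path, report_path)
  invisible(list(qm = qm, results = results, runlog = runlog))
}

write_runlog <- function(runlog, path) {
  jsonlite::write_json(runlog, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Write a human-readable run report
#'
#' Regenerates the summary purely from the saved JSON run log: one line per
#' executed stage with feature counts, significant features per contrast,
#' and the top enriched sets when enrichment ran.
#'
#' @param runlog a run-log list or a path to `runlog.json`.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_report <- function(runlog, path) {
  if (is.character(runlog) && length(runlog) == 1L)
    runlog <- jsonlite::read_json(runlog, simplifyVector = FALSE)
  lines <- c(
    sprintf("proteopipe %s run report", runlog$version),
    sprintf("pipeline: %s (seed %s)", runlog$pipeline, runlog$seed),
    "",
    "stages:")
  for (st in runlog$stages) {
    nin <- st$features_in
    if (is.null(nin) || length(nin) != 1L || is.na(nin)) nin <- "-"
    nout <- st$features_out
    if (is.null(nout) || length(nout) != 1L || is.na(nout)) nout <- "-"
    lines <- c(lines, sprintf("  %-22s %s -> %s features",
                              st$stage, nin, nout))
  }
  lines <- c(lines, "", "significant features per contrast:")
  for (cn in names(runlog$results$significant))
    lines <- c(lines, sprintf("  %-22s %s", cn,
                              runlog$results$significant[[cn]]))
  if (!is.null(runlog$results$top_sets) &&
      length(runlog$results$top_sets))
    lines <- c(lines, "", "top enriched sets:",
               paste0("  ", unlist(runlog$results$top_sets)))
  if (!is.null(runlog$error))
    lines <- c(lines, "", sprintf("ERROR at stage '%s': %s",
                                  runlog$error$stage, runlog$error$message))
  writeLines(lines, path)
  invisible(path)
}
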