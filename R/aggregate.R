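#' Tukey median polish of a peptide-by-sample matrix
#'
#' Decomposes `Y` into overall + peptide (row) effect + sample (column)
#' effect + residual by alternately sweeping row and column medians,
#' stopping when the maximal absolute change of any effect is below `tol`.
#' The protein abundance in sample `s` is `overall + col_effects[s]` —
#' resistant to outlying peptide measurements, unlike a mean.
#'
#' @param Y complete numeric matrix (peptides x samples), log2 scale.
#' @param max_iter maximum number of sweep pairs (default 50).
#' @param tol convergence tolerance on effect changes (default 1e-6).
#' @return list with `overall` (scalar), `row_effects`, `col_effects`,
#'   `residuals` (matrix) and `converged` (logical).
#' @export
median_polish <- function(Y, max_iter = 50L, tol = 1e-6) {
  Y <- as.matrix(Y)
  if (!length(Y)) stop("median_polish: empty matrix")
  if (anyNA(Y)) stop("median_polish requires a complete matrix; impute first")
  P <- nrow(Y); S <- ncol(Y)
  overall <- 0
  row_eff <- numeric(P)
  col_eff <- numeric(S)
  R <- Y
  converged <- FALSE
  # Tukey's sweep pairing: after the row sweep, the median of the column
  # effects moves to the overall term, and vice versa
  for (it in seq_len(max_iter)) {
    old <- c(overall, row_eff, col_eff)
    rm_ <- apply(R, 1L, stats::median)
    row_eff <- row_eff + rm_
    R <- R - rm_  # column-major recycling subtracts rm_[i] from row i
    m <- stats::median(col_eff)
    col_eff <- col_eff - m
    overall <- overall + m
    cm_ <- apply(R, 2L, stats::median)
    col_eff <- col_eff + cm_
    R <- sweep(R, 2L, cm_, "-")
    m <- stats::median(row_eff)
    row_eff <- row_eff - m
    overall <- overall + m
    if (max(abs(c(overall, row_eff, col_eff) - old)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(overall = overall, row_effects = row_eff, col_effects = col_eff,
       residuals = R, converged = converged)
}

#' Robust peptide-to-protein summarization by Huber regression
#'
#' Fits the two-way model `y_ps = mu_s + pi_p + e_ps` (sample effects plus
#' peptide effects under a sum-to-zero constraint) by iteratively reweighted
#' least squares with Huber weights, so that outlying peptide measurements
#' are down-weighted rather than averaged in.  With the sum-to-zero
#' constraint `mu_s` is the group-average abundance of the protein in sample
#' `s`, directly comparable with the other aggregation methods.
#'
#' @param Y complete numeric matrix (peptides x samples), log2 scale.
#' @param huber_k Huber tuning constant in residual-scale units
#'   (default 1.345; `Inf` gives ordinary least squares).
#' @param max_iter maximum IRLS iterations (default 50).
#' @param tol convergence tolerance on coefficient change (default 1e-6).
#' @return numeric vector of per-sample protein abundances `mu_s`.
#' @export
robust_summary <- function(Y, huber_k = 1.345, max_iter = 50L, tol = 1e-6) {
  Y <- as.matrix(Y)
  if (!length(Y)) stop("robust_summary: empty matrix")
  if (anyNA(Y)) stop("robust_summary requires a complete matrix; impute first")
  P <- nrow(Y); S <- ncol(Y)
  if (P == 1L) return(stats::setNames(as.numeric(Y[1L, ]), colnames(Y)))
  samp <- factor(rep(seq_len(S), each = P))
  pep <- factor(rep(seq_len(P), times = S))
  y <- as.numeric(Y)
  M <- stats::model.matrix(~ 0 + samp + pep,
                           contrasts.arg = list(pep = "contr.sum"))
  w <- rep(1, length(y))
  coefs <- rep(0, ncol(M))
  s <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.wfit(M, y, w)
    delta <- max(abs(fit$coefficients - coefs))
    coefs <- fit$coefficients
    if (it > 1L && delta < tol) {
      converged <- TRUE
      break
    }
    r <- y - as.numeric(M %*% coefs)
    # MAD residual scale, re-estimated early then frozen so the fixed-scale
    # reweighting iteration cannot oscillate
    if (it <= 10L) s <- stats::median(abs(r)) / 0.6745
    if (is.infinite(huber_k) || !is.finite(s) || s < 1e-10) {
      w <- rep(1, length(y))
      if (it > 1L) {
        converged <- TRUE
        break
      }
      next
    }
    u <- abs(r / s)
    w <- ifelse(u <= huber_k, 1, huber_k / u)
  }
  if (!converged)
    warning("robust_summary IRLS did not converge in ", max_iter,
            " iterations; returning the last iterate")
  mu <- coefs[seq_len(S)]
  stats::setNames(as.numeric(mu), colnames(Y))
}

#' Total-sum peptide aggregation
#'
#' Sums peptide intensities per sample on the raw scale — the only scale on
#' which summing quantities is meaningful — then returns log2 of the sums
#' for downstream testing.  Missing peptide cells contribute 0.
#'
#' @param Y_raw numeric matrix (peptides x samples) of raw intensities;
#'   `NA` allowed.
#' @return numeric vector: `log2(colSums(Y_raw))` per sample (`NA` where a
#'   sample has no observed peptide).
#' @export
sum_aggregate <- function(Y_raw) {
  Y_raw <- as.matrix(Y_raw)
  if (!length(Y_raw)) stop("sum_aggregate: empty matrix")
  tot <- colSums(Y_raw, na.rm = TRUE)
  tot[colSums(!is.na(Y_raw)) == 0L] <- NA_real_
  stats::setNames(ifelse(tot > 0, log2(tot), NA_real_), colnames(Y_raw))
}

#' Aggregate a peptide-level QuantMatrix to protein level
#'
#' Groups peptide features by a protein-group key in the row annotations and
#' summarizes each group with one of three strategies: `"median-polish"`
#' (overall + sample effects), `"robust"` (Huber IRLS two-way fit) or
#' `"sum"` (raw-scale total, then log2).  The first two require an imputed
#' (complete) log-scale matrix; `"sum"` operates on raw intensities —
#' when the input is on log2 scale it is un-logged first (a `glog2` matrix
#' cannot be un-logged, so normalize after aggregation in that case).
#'
#' @param qm a peptide-level QuantMatrix.
#' @param grouping_key rowData column holding the protein-group identifier.
#' @param method `"median-polish"`, `"robust"` or `"sum"`.
#' @param max_iter,tol,huber_k passed to the group summarizers.
#' @return a protein-level QuantMatrix; rowData carries the group id and the
#'   peptide count `n_peptides`, and the history is appended.
#' @export
aggregate_peptides <- function(qm, grouping_key,
                               method = c("median-polish", "robust", "sum"),
                               max_iter = 50L, tol = 1e-6, huber_k = 1.345) {
  method <- match.arg(method)
  rd <- SummarizedExperiment::rowData(qm)
  if (!grouping_key %in% colnames(rd))
    stop("grouping key '", grouping_key, "' not found in feature annotations")
  groups <- as.character(rd[[grouping_key]])
  valid <- !is.na(groups) & nzchar(groups)
  n_dropped <- sum(!valid)
  X <- quant(qm)
  scale <- quant_scale(qm)
  if (method == "sum") {
    if (identical(scale, "log2")) X <- 2^X
    else if (!identical(scale, "raw"))
      stop("'sum' aggregation needs raw or log2 intensities, not '", scale,
           "'; aggregate before glog2 normalization or use another method")
  } else if (identical(scale, "raw")) {
    stop("'", method, "' aggregation expects log-scale data")
  }
  prot <- unique(groups[valid])
  out <- matrix(NA_real_, length(prot), ncol(X),
                dimnames = list(prot, colnames(X)))
  n_pep <- integer(length(prot))
  for (g in seq_along(prot)) {
    Y <- X[valid & groups == prot[g], , drop = FALSE]
    n_pep[g] <- nrow(Y)
    out[g, ] <- switch(method,
      "median-polish" = {
        mp <- median_polish(Y, max_iter = max_iter, tol = tol)
        mp$overall + mp$col_effects
      },
      "robust" = robust_summary(Y, huber_k = huber_k, max_iter = max_iter,
                                tol = tol),
      "sum" = sum_aggregate(Y))
  }
  agg <- SummarizedExperiment::SummarizedExperiment(
    assays = list(quant = out),
    colData = SummarizedExperiment::colData(qm),
    rowData = S4Vectors::DataFrame(name = prot, raw_ids = prot,
                                   n_peptides = n_pep, row.names = prot))
  S4Vectors::metadata(agg)$scale <- if (method == "sum") "log2" else scale
  S4Vectors::metadata(agg)$history <- history(qm)
  add_history(agg, "aggregate_peptides",
              list(method = method, grouping_key = grouping_key,
                   peptides_without_group = n_dropped),
              nrow(qm), nrow(agg))
}
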