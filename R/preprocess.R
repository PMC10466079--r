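#' Filter features on identification QC flags
#'
#' Removes rows marked `"+"` in any of the given flag columns (MaxQuant
#' convention for decoy `Reverse` hits and `Potential contaminant` entries).
#'
#' @param qt a `QuantTable`.
#' @param flag_columns character vector of annotation columns to inspect;
#'   empty vector means no filtering.
#' @return the filtered `QuantTable`, with attribute `"removed"` holding the
#'   per-column removal counts.
#' @export
filter_flags <- function(qt, flag_columns = character()) {
  stopifnot(inherits(qt, "QuantTable"))
  if (!length(flag_columns)) {
    attr(qt, "removed") <- integer()
    return(qt)
  }
  unknown <- setdiff(flag_columns, colnames(qt$annotations))
  if (length(unknown))
    stop("unknown flag column(s): ", paste(unknown, collapse = ", "))
  flagged <- vapply(flag_columns,
                    function(col) trimws(as.character(qt$annotations[[col]])) == "+",
                    logical(nrow(qt$intensities)))
  if (nrow(qt$intensities) == 1L)
    flagged <- matrix(flagged, nrow = 1L)
  drop <- apply(flagged, 1L, any)
  drop[is.na(drop)] <- FALSE
  out <- subset_features(qt, !drop)
  attr(out, "removed") <- colSums(flagged, na.rm = TRUE)
  out
}

#' Filter features on missing occupancy
#'
#' Default mode `"per-condition"` keeps a feature if, in at least one
#' condition, it has at most `thr` missing values — i.e. a feature must be
#' (nearly) fully observed somewhere, the criterion suited to on/off
#' regulation.  Mode `"overall-fraction"` keeps features whose overall
#' observed fraction is at least `fraction`.
#'
#' @param qm a QuantMatrix.
#' @param thr maximum number of missing values tolerated within the best
#'   condition (default 0: fully observed in at least one condition).
#' @param mode `"per-condition"` or `"overall-fraction"`.
#' @param fraction minimum observed fraction for `"overall-fraction"` mode.
#' @return the filtered QuantMatrix (history appended).
#' @export
filter_missing <- function(qm, thr = 0L,
                           mode = c("per-condition", "overall-fraction"),
                           fraction = 0.7) {
  mode <- match.arg(mode)
  X <- quant(qm)
  cond <- design(qm)$condition
  if (mode == "per-condition") {
    max_reps <- max(table(cond))
    if (thr >= max_reps)
      warning("thr >= largest condition size; the filter keeps everything")
    n_miss <- vapply(unique(cond), function(cc)
      rowSums(is.na(X[, cond == cc, drop = FALSE])), numeric(nrow(X)))
    if (nrow(X) == 1L) n_miss <- matrix(n_miss, nrow = 1L)
    keep <- apply(n_miss, 1L, min) <= thr
  } else {
    keep <- rowMeans(!is.na(X)) >= fraction
  }
  out <- qm[keep, ]
  add_history(out, "filter_missing",
              list(mode = mode, thr = thr, fraction = fraction),
              nrow(qm), nrow(out))
}

#' Log2-transform a raw-scale QuantMatrix
#'
#' @param qm a QuantMatrix on the raw scale; all observed values must be
#'   strictly positive.
#' @return the QuantMatrix on log2 scale; missing entries preserved.
#' @export
log2_transform <- function(qm) {
  if (!identical(quant_scale(qm), "raw"))
    stop("log2_transform expects a raw-scale matrix (scale is '",
         quant_scale(qm), "')")
  X <- quant(qm)
  if (any(X <= 0, na.rm = TRUE))
    stop("non-positive observed intensity found; log2_transform requires ",
         "strictly positive raw intensities")
  qm <- set_quant(qm, log2(X), scale = "log2")
  add_history(qm, "log2_transform", list(), nrow(qm), nrow(qm))
}

#' Generalized log2 (arsinh-based)
#'
#' `glog2(y) = log2(y + sqrt(y^2 + 1))`.  Behaves like `log2(2 * y)` for
#' large `y` and is linear (and defined) around and below zero, which is what
#' makes it the natural scale for variance-stabilized intensities.
#'
#' @param y numeric vector.
#' @return numeric vector of transformed values.
#' @export
glog2 <- function(y) asinh(y) / log(2)

#' Variance-stabilizing normalization
#'
#' Fits, per sample \eqn{i}, affine parameters \eqn{(a_i, b_i)} of the
#' transform \eqn{h_i(x) = glog2((x - a_i) / b_i)} by iterative maximum
#' likelihood under the model that transformed intensities of a feature are
#' equal across samples up to noise of common variance.  Robustness against
#' differentially abundant features comes from least-trimmed-squares
#' trimming: each round the cells with the largest squared residuals are
#' excluded from the fit (default keeps 90%).  The multiplicative-noise
#' regime of raw MS intensities (SD proportional to the mean) is compressed
#' to roughly constant variance on the glog2 scale.
#'
#' @param qm a QuantMatrix on the raw scale with at least 2 samples and at
#'   least 30 features carrying 2 or more observations.
#' @param trim fraction of cells trimmed from the fit (default 0.1).
#' @param tol convergence tolerance on the parameter change (default 1e-8).
#' @param max_iter maximum outer iterations (default 100).
#' @return the QuantMatrix on `"glog2"` scale; the fitted parameters are
#'   stored in the metadata and retrievable with [vsn_params()].
#' @export
normalize_vsn <- function(qm, trim = 0.1, tol = 1e-8, max_iter = 100L) {
  if (!identical(quant_scale(qm), "raw"))
    stop("normalize_vsn expects a raw-scale matrix")
  X <- quant(qm)
  if (ncol(X) < 2L) stop("normalize_vsn needs at least 2 samples")
  if (sum(rowSums(!is.na(X)) >= 2L) < 30L)
    stop("normalize_vsn needs at least 30 features with >= 2 observations")
  fit <- vsn_fit(X, trim = trim, tol = tol, max_iter = max_iter)
  H <- vsn_transform(X, fit$a, fit$b)
  qm <- set_quant(qm, H, scale = "glog2")
  S4Vectors::metadata(qm)$vsn_params <-
    list(a = fit$a, b = fit$b, iterations = fit$iterations)
  add_history(qm, "normalize_vsn",
              list(trim = trim, tol = tol, iterations = fit$iterations),
              nrow(qm), nrow(qm))
}

#' @rdname normalize_vsn
#' @param qm a QuantMatrix previously normalized with [normalize_vsn()].
#' @export
vsn_params <- function(qm) S4Vectors::metadata(qm)$vsn_params

vsn_transform <- function(X, a, b)
  glog2(sweep(sweep(X, 2L, a, "-"), 2L, b, "/"))

# Profile negative log-likelihood of the equal-variance-after-transform
# model, with the glog Jacobian term; `keep` is the current LTS cell set.
vsn_nll <- function(par, X, s, obs, keep) {
  S <- ncol(X)
  a <- par[seq_len(S)] * s
  b <- exp(pmin(par[S + seq_len(S)], 500)) * s
  Y <- sweep(sweep(X, 2L, a, "-"), 2L, b, "/")
  H <- glog2(Y)
  mu <- rowMeans(H, na.rm = TRUE)
  R <- H - mu
  # -log h'(x) = log(b) + 0.5*log(y^2+1) (+const); overflow-safe for |y|>>1
  L2 <- ifelse(abs(Y) > 1e150, log(abs(Y)), 0.5 * log1p(Y * Y))
  LJ <- sweep(L2, 2L, log(b), "+")
  r2 <- R[keep]^2
  n <- length(r2)
  val <- n / 2 * log(sum(r2)) + sum(LJ[keep])
  if (!is.finite(val)) val <- 1e10
  val
}

vsn_fit <- function(X, trim = 0.1, tol = 1e-8, max_iter = 100L) {
  S <- ncol(X)
  obs <- !is.na(X)
  s <- apply(X, 2L, stats::median, na.rm = TRUE)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("each sample needs positive observed intensities for the VSN fit")
  par <- c(rep(0, S), rep(0, S))          # a_i = 0, b_i = median_i
  n_keep <- max(ceiling((1 - trim) * sum(obs)), S + 1L)
  keep <- which(obs)                       # first round: everything
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fit <- stats::optim(par, vsn_nll, X = X, s = s, obs = obs, keep = keep,
                        method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-12))
    delta <- max(abs(fit$par - par))
    par <- fit$par
    trace <- c(trace, fit$value)
    # refresh the trimmed cell set under the new parameters
    a <- par[seq_len(S)] * s
    b <- exp(par[S + seq_len(S)]) * s
    H <- vsn_transform(X, a, b)
    R2 <- (H - rowMeans(H, na.rm = TRUE))^2
    new_keep <- which(obs)[order(R2[obs])[seq_len(min(n_keep, sum(obs)))]]
    stable <- identical(sort(new_keep), sort(keep))
    keep <- new_keep
    if (delta < tol || (stable && it > 1L &&
        abs(diff(utils::tail(trace, 2))) < 1e-10 * (1 + abs(fit$value)))) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("VSN fit did not converge within ", max_iter,
         " iterations; objective trace: ",
         paste(signif(trace, 8), collapse = ", "))
  list(a = par[seq_len(S)] * s, b = exp(par[S + seq_len(S)]) * s,
       iterations = length(trace))
}

#' Median normalization on the log2 scale
#'
#' A simpler alternative to [normalize_vsn()]: centers every sample on its
#' median.  Provided for comparison; not the default in the pipelines.
#'
#' @param qm a QuantMatrix on log2 scale.
#' @return the centered QuantMatrix.
#' @export
normalize_median <- function(qm) {
  if (identical(quant_scale(qm), "raw"))
    stop("normalize_median expects a log-scale matrix; log2_transform first")
  X <- quant(qm)
  med <- apply(X, 2L, stats::median, na.rm = TRUE)
  qm <- set_quant(qm, sweep(X, 2L, med - mean(med), "-"))
  add_history(qm, "normalize_median", list(), nrow(qm), nrow(qm))
}
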