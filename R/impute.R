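#' Impute missing quantification values
#'
#' Replaces every missing cell of a log-scale QuantMatrix under an MNAR
#' (left-censored) or MAR assumption.  Observed values are never touched.
#'
#' Methods (all per-sample statistics, since detection limits are
#' run-specific):
#' \describe{
#'   \item{`left-shifted`}{MNAR. Draw from
#'     `Normal(mean_s - shift * sd_s, (width * sd_s)^2)` for sample `s` —
#'     the down-shifted Gaussian familiar from Perseus.}
#'   \item{`min-det`}{MNAR, deterministic. Replace by the per-sample
#'     `quantile` of observed values (a minimum-of-detection proxy).}
#'   \item{`min-prob`}{MNAR. Draw from a Gaussian centered at that quantile
#'     with SD `width * sd_s`.}
#'   \item{`knn`}{MAR. Average of the `k` nearest feature rows (Euclidean
#'     distance on shared observed columns, scaled by the number of shared
#'     columns) among features observed at the missing cell's column; ties
#'     broken by feature order.  A cell with no eligible neighbour falls
#'     back to the feature's row mean (recorded in the history).}
#'   \item{`zero`}{Replace by 0.}
#' }
#'
#' Random draws use one seeded stream and cells are visited in row-major
#' order, so results are reproducible and insensitive to how many cells
#' earlier features needed.
#'
#' @param qm a QuantMatrix on log2/glog2 scale.
#' @param method one of `"left-shifted"`, `"min-det"`, `"min-prob"`,
#'   `"knn"`, `"zero"`.
#' @param shift down-shift in per-sample SD units (default 1.8).
#' @param width imputation spread in per-sample SD units (default 0.3).
#' @param quantile per-sample quantile for the min-det/min-prob center
#'   (default 0.01).
#' @param k number of neighbours for `"knn"` (default 10).
#' @param seed integer seed for the stochastic methods.
#' @return the QuantMatrix with no missing entries (history appended).
#' @export
impute <- function(qm, method = c("left-shifted", "min-det", "min-prob",
                                  "knn", "zero"),
                   shift = 1.8, width = 0.3, quantile = 0.01, k = 10L,
                   seed = NULL) {
  method <- match.arg(method)
  stopifnot(width > 0, quantile > 0, quantile < 1, k >= 1L)
  if (identical(quant_scale(qm), "raw"))
    stop("impute expects a log-scale matrix; transform/normalize first")
  X <- quant(qm)
  miss <- is.na(X)
  n_miss <- sum(miss)
  fallback_rows <- character(0)
  if (n_miss > 0L) {
    if (method %in% c("left-shifted", "min-det", "min-prob")) {
      n_obs <- colSums(!miss)
      if (any(n_obs == 0L))
        stop("sample(s) with no observed values: ",
             paste(colnames(X)[n_obs == 0L], collapse = ", "))
      if (any(n_obs < 2L))
        stop("SD-based imputation needs >= 2 observed values per sample")
      mu <- colMeans(X, na.rm = TRUE)
      sd_s <- apply(X, 2L, stats::sd, na.rm = TRUE)
      q_s <- apply(X, 2L, stats::quantile, probs = quantile, na.rm = TRUE,
                   names = FALSE)
      # row-major cell order gives one reproducible draw stream
      idx <- which(t(miss))
      cols <- (idx - 1L) %/% nrow(t(miss)) + 1L   # row of original matrix
      rows_t <- (idx - 1L) %% nrow(t(miss)) + 1L  # column of original matrix
      ord_col <- rows_t
      if (!is.null(seed)) set.seed(as.integer(seed))
      vals <- switch(method,
        "left-shifted" = stats::rnorm(length(idx),
                                      mean = (mu - shift * sd_s)[ord_col],
                                      sd = (width * sd_s)[ord_col]),
        "min-det" = q_s[ord_col],
        "min-prob" = stats::rnorm(length(idx), mean = q_s[ord_col],
                                  sd = (width * sd_s)[ord_col]))
      Xt <- t(X)
      Xt[idx] <- vals
      X <- t(Xt)
    } else if (method == "zero") {
      X[miss] <- 0
    } else { # knn
      filled <- knn_impute(X, k = k)
      X <- filled$X
      fallback_rows <- filled$fallback_rows
    }
  }
  qm <- set_quant(qm, X)
  params <- list(method = method, seed = seed)
  if (method == "left-shifted") params <- c(params, shift = shift, width = width)
  if (method %in% c("min-det", "min-prob"))
    params <- c(params, quantile = quantile, width = width)
  if (method == "knn") {
    params <- c(params, k = k)
    if (length(fallback_rows))
      params$row_mean_fallback <- fallback_rows
  }
  add_history(qm, "impute", c(params, list(cells_imputed = n_miss)),
              nrow(qm), nrow(qm))
}

knn_impute <- function(X, k) {
  obs <- !is.na(X)
  out <- X
  fallback <- character(0)
  for (i in which(rowSums(obs) < ncol(X))) {
    oi <- obs[i, ]
    for (j in which(!oi)) {
      # neighbours must be observed at column j and share >= 1 column with i
      cand <- which(obs[, j] & (obs %*% oi) > 0)
      cand <- setdiff(cand, i)
      if (!length(cand)) {
        out[i, j] <- mean(X[i, ], na.rm = TRUE)
        fallback <- c(fallback, rownames(X)[i])
        next
      }
      d <- vapply(cand, function(p) {
        shared <- oi & obs[p, ]
        sqrt(sum((X[i, shared] - X[p, shared])^2) / sum(shared))
      }, numeric(1))
      nb <- cand[order(d, cand)][seq_len(min(k, length(cand)))]
      out[i, j] <- mean(X[nb, j])
    }
  }
  list(X = out, fallback_rows = unique(fallback))
}
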