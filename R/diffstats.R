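#' Per-feature linear models for condition contrasts
#'
#' Fits, per feature, the cell-means (group-means) model by ordinary least
#' squares: condition means, pooled residual variance
#' `s2 = RSS / df` with `df = n_observed - #conditions-with-data`, and for
#' every requested contrast `A_vs_B` the estimate `beta = mean_A - mean_B`
#' with unscaled standard-error factor `u = sqrt(1/n_A + 1/n_B)`.
#'
#' @param qm a QuantMatrix (normally complete after [impute()]; features
#'   with missing cells use their observed values).
#' @param contrasts character vector of `"condA_vs_condB"` strings.
#' @return an object of class `FitResult`: list with `feature_id`, matrices
#'   `beta` and `u` (features x contrasts), vectors `s2` and `df_resid`,
#'   plus the parsed contrast table.
#' @export
fit_linear_models <- function(qm, contrasts) {
  X <- quant(qm)
  cond <- design(qm)$condition
  conds <- unique(cond)
  parsed <- parse_contrasts(contrasts, conds)
  grp <- lapply(conds, function(cc) which(cond == cc))
  names(grp) <- conds
  n_feat <- nrow(X)
  means <- matrix(NA_real_, n_feat, length(conds),
                  dimnames = list(rownames(X), conds))
  nobs <- means
  for (cc in conds) {
    Xi <- X[, grp[[cc]], drop = FALSE]
    means[, cc] <- rowMeans(Xi, na.rm = TRUE)
    nobs[, cc] <- rowSums(!is.na(Xi))
  }
  means[nobs == 0] <- NA_real_
  fitted <- means[, cond, drop = FALSE]
  rss <- rowSums((X - fitted)^2, na.rm = TRUE)
  df <- rowSums(!is.na(X)) - rowSums(nobs > 0)
  s2 <- ifelse(df > 0, rss / df, NA_real_)
  beta <- u <- matrix(NA_real_, n_feat, nrow(parsed),
                      dimnames = list(rownames(X), parsed$name))
  for (i in seq_len(nrow(parsed))) {
    A <- parsed$a[i]; B <- parsed$b[i]
    beta[, i] <- means[, A] - means[, B]
    u[, i] <- sqrt(1 / nobs[, A] + 1 / nobs[, B])
  }
  structure(list(feature_id = rownames(X), beta = beta, u = u,
                 s2 = as.numeric(s2), df_resid = as.numeric(df),
                 contrasts = parsed),
            class = "FitResult")
}

parse_contrasts <- function(contrasts, conds) {
  parts <- strsplit(contrasts, "_vs_", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("contrast(s) not of the form 'condA_vs_condB': ",
         paste(contrasts[bad], collapse = ", "))
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  unknown <- setdiff(c(a, b), conds)
  if (length(unknown))
    stop("contrast names unknown condition(s): ",
         paste(unknown, collapse = ", "))
  data.frame(name = contrasts, a = a, b = b, stringsAsFactors = FALSE)
}

#' Estimate the variance prior by empirical Bayes (method of moments)
#'
#' Models per-feature residual variances as draws from a scaled inverse
#' chi-square prior with `d0` degrees of freedom and location `s0_2`, and
#' estimates both hyperparameters from the moments of `log(s2)`:
#' with `e_g = log(s2_g) - digamma(df_g/2) + log(df_g/2)`, `d0` solves
#' `trigamma(d0/2) = var(e) - mean(trigamma(df_g/2))` (by a monotone Newton
#' iteration on the trigamma inverse) and
#' `s0_2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`.  When the observed
#' spread of `log(s2)` is no larger than expected from chi-square sampling
#' alone, `d0 = Inf` and `s0_2 = exp(mean(e))`.
#'
#' Zero variances (features fitted exactly) are floored at 1e-12 before the
#' log-moment step, since the digamma moments are undefined at 0.
#'
#' @param s2 per-feature residual variances.
#' @param df per-feature residual degrees of freedom.
#' @return list of class `ShrinkageParams` with elements `d0` and `s0_2`.
#' @export
squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & is.finite(df) & df > 0
  if (!any(ok)) stop("no feature with positive residual degrees of freedom")
  if (sum(ok) < 10L)
    warning("fewer than 10 features inform the variance prior; ",
            "the estimate may be unstable")
  s2w <- pmax(s2[ok], 1e-12)
  dfw <- df[ok]
  e <- log(s2w) - digamma(dfw / 2) + log(dfw / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  target <- evar - mean(trigamma(dfw / 2))
  if (!is.finite(target) || target <= 0) {
    # no excess spread beyond chi-square sampling: infinite prior df, and
    # the pooled variance is simply the average
    prior <- list(d0 = Inf, s0_2 = mean(s2w))
  } else {
    half_d0 <- trigamma_inverse(target)
    d0 <- 2 * half_d0
    prior <- list(d0 = d0, s0_2 = exp(emean + digamma(half_d0) -
                                        log(half_d0)))
  }
  structure(prior, class = "ShrinkageParams")
}

# Solve trigamma(x) = y for x > 0 by Newton iteration on 1/trigamma,
# which is nearly linear; monotone and quadratically convergent.
trigamma_inverse <- function(y) {
  stopifnot(is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (it in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Moderated t-tests on fitted contrasts
#'
#' Shrinks each feature's variance toward the prior,
#' `s2_tilde = (d0 * s0_2 + df * s2) / (d0 + df)`, and computes the
#' moderated statistic `t = beta / (u * sqrt(s2_tilde))` with two-sided
#' p-values from the t distribution on `d0 + df` degrees of freedom.
#' `d0 = 0` reproduces the ordinary t-test; `d0 = Inf` gives the normal
#' reference with `s2_tilde = s0_2`.  Features whose contrast is not
#' estimable (non-finite `u`) are reported with missing statistics.
#'
#' @param fit a `FitResult` from [fit_linear_models()].
#' @param prior a `ShrinkageParams` from [squeeze_var()].
#' @return a `ContrastResult` data.frame with one row per feature x
#'   contrast: `feature_id`, `contrast_name`, `log2fc`, `t_mod`, `df_total`,
#'   `p`, and placeholder columns `padj`/`significant` filled by
#'   [adjust_bh()] and [add_rejections()].
#' @export
moderated_test <- function(fit, prior) {
  stopifnot(inherits(fit, "FitResult"), inherits(prior, "ShrinkageParams"))
  d0 <- prior$d0; s0_2 <- prior$s0_2
  res <- lapply(seq_len(nrow(fit$contrasts)), function(i) {
    beta <- fit$beta[, i]
    u <- fit$u[, i]
    if (is.infinite(d0)) {
      s2_tilde <- rep(s0_2, length(beta))
      df_total <- rep(Inf, length(beta))
    } else {
      s2_tilde <- (d0 * s0_2 + fit$df_resid * fit$s2) / (d0 + fit$df_resid)
      df_total <- d0 + fit$df_resid
    }
    t_mod <- beta / (u * sqrt(s2_tilde))
    estimable <- is.finite(u) & is.finite(beta)
    t_mod[!estimable] <- NA_real_
    p <- 2 * stats::pt(-abs(t_mod), df = df_total)
    data.frame(feature_id = fit$feature_id,
               contrast_name = fit$contrasts$name[i],
               log2fc = as.numeric(beta), t_mod = as.numeric(t_mod),
               df_total = as.numeric(df_total), p = as.numeric(p),
               padj = NA_real_, significant = NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`adj_i = min_{j >= i} p_(j) * n / j`, capped at
#' 1, returned in the input order), delegated to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return adjusted p-values in the input order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gate significance on FDR and effect size
#'
#' Sets `significant = (padj <= alpha) & (|log2fc| >= lfc)` per row — the
#' flag consumed by the enrichment, clustering and network modules.
#'
#' @param results a `ContrastResult` data.frame with `padj` filled in.
#' @param alpha FDR threshold (default 0.05).
#' @param lfc minimal absolute log2 fold-change (default 1).
#' @return the data.frame with the `significant` column set.
#' @export
add_rejections <- function(results, alpha = 0.05, lfc = 1) {
  if (all(is.na(results$padj)))
    stop("padj has not been computed; run adjust_bh first")
  results$significant <- !is.na(results$padj) & results$padj <= alpha &
    !is.na(results$log2fc) & abs(results$log2fc) >= lfc
  results
}

#' Full differential-testing chain
#'
#' Convenience wrapper: [fit_linear_models()] -> [squeeze_var()] ->
#' [moderated_test()] -> [adjust_bh()] (per contrast by default) ->
#' [add_rejections()].
#'
#' @param qm a QuantMatrix.
#' @param contrasts character vector of `"condA_vs_condB"` strings.
#' @param alpha,lfc significance gates, see [add_rejections()].
#' @param pool_adjust adjust p-values across all contrasts jointly instead
#'   of per contrast (default `FALSE`).
#' @return a `ContrastResult` data.frame; the estimated prior is attached as
#'   attribute `"prior"`.
#' @export
test_diff <- function(qm, contrasts, alpha = 0.05, lfc = 1,
                      pool_adjust = FALSE) {
  fit <- fit_linear_models(qm, contrasts)
  prior <- squeeze_var(fit$s2, fit$df_resid)
  res <- moderated_test(fit, prior)
  if (pool_adjust) {
    res$padj <- adjust_bh(res$p)
  } else {
    for (cn in unique(res$contrast_name)) {
      sel <- res$contrast_name == cn
      res$padj[sel] <- adjust_bh(res$p[sel])
    }
  }
  res <- add_rejections(res, alpha = alpha, lfc = lfc)
  attr(res, "prior") <- prior
  res
}
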