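#' Row-standardize expression profiles
#'
#' Centers and scales each feature's per-condition mean profile to mean 0 /
#' SD 1, so that clustering groups by pattern shape rather than absolute
#' abundance.  Constant rows carry no pattern and are dropped (their ids
#' returned in the attribute `"dropped"`).
#'
#' @param X numeric matrix, features x conditions (>= 2 conditions).
#' @return the standardized matrix.
#' @export
standardize_profiles <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 conditions to form a profile")
  mu <- rowMeans(X)
  sd_ <- apply(X, 1L, stats::sd)
  keep <- is.finite(sd_) & sd_ > 0
  Z <- (X[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
  attr(Z, "dropped") <- rownames(X)[!keep]
  Z
}

#' Per-condition mean profiles of a QuantMatrix
#'
#' @param qm a QuantMatrix.
#' @param features optional character vector restricting to a feature
#'   subset (e.g. significant features from [add_rejections()]).
#' @return matrix of condition means, features x conditions.
#' @export
condition_means <- function(qm, features = NULL) {
  X <- quant(qm)
  if (!is.null(features)) X <- X[rownames(X) %in% features, , drop = FALSE]
  cond <- design(qm)$condition
  conds <- unique(cond)
  out <- vapply(conds, function(cc)
    rowMeans(X[, cond == cc, drop = FALSE], na.rm = TRUE),
    numeric(nrow(X)))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1L,
                                   dimnames = list(rownames(X), conds))
  out
}

#' Fuzzy c-means clustering of expression patterns
#'
#' Bezdek's alternating optimization: memberships
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` and centers
#' `c_k = sum_i u_ik^m x_i / sum_i u_ik^m`, iterated until the largest
#' center displacement falls below `tol`.  Soft memberships suit regulated
#' proteins that follow several temporal patterns at once.  A feature at
#' zero distance from a center receives membership 1 there.  Centers are
#' initialized from `k` distinct data rows drawn with the given seed, so a
#' run is fully reproducible.
#'
#' @param X standardized profile matrix (see [standardize_profiles()]).
#' @param k number of clusters (2 <= k < number of features).
#' @param m fuzzifier (> 1, default 2; m -> 1 approaches hard k-means).
#' @param tol convergence tolerance on center displacement (default 1e-6).
#' @param max_iter maximum iterations (default 300).
#' @param seed integer seed for center initialization.
#' @return list of class `ClusterResult`: `membership` (features x k, rows
#'   sum to 1), `centers` (k x conditions), `cluster` (hard assignment),
#'   `m`, and the non-increasing `objective` trace.
#' @export
fuzzy_cmeans <- function(X, k, m = 2, tol = 1e-6, max_iter = 300L,
                         seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2L) stop("k must be at least 2")
  if (k >= n) stop("k must be smaller than the number of features")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  C <- X[sample.int(n, k), , drop = FALSE]
  rownames(C) <- paste0("cluster_", seq_len(k))
  objective <- numeric(0)
  U <- NULL
  for (it in seq_len(max_iter)) {
    D2 <- outer(rowSums(X^2), rep(1, k)) + outer(rep(1, n), rowSums(C^2)) -
      2 * X %*% t(C)
    D2[D2 < 0] <- 0
    U <- cmeans_membership(D2, m)
    Um <- U^m
    C_new <- (t(Um) %*% X) / colSums(Um)
    objective <- c(objective, sum(Um * D2))
    shift <- max(abs(C_new - C))
    C <- C_new
    rownames(C) <- paste0("cluster_", seq_len(k))
    if (shift < tol) break
  }
  structure(list(membership = U, centers = C,
                 cluster = max.col(U, ties.method = "first"),
                 m = m, objective = objective),
            class = "ClusterResult")
}

cmeans_membership <- function(D2, m) {
  n <- nrow(D2); k <- ncol(D2)
  U <- matrix(0, n, k, dimnames = dimnames(D2))
  zero <- D2 <= .Machine$double.eps
  has_zero <- rowSums(zero) > 0
  if (any(has_zero))
    U[has_zero, ] <- zero[has_zero, , drop = FALSE] /
      rowSums(zero[has_zero, , drop = FALSE])
  if (any(!has_zero)) {
    P <- D2[!has_zero, , drop = FALSE]^(-1 / (m - 1))
    U[!has_zero, ] <- P / rowSums(P)
  }
  U
}

#' Load a STRING-style scored interaction network
#'
#' Reads a whitespace-separated `protein1 protein2 combined_score` edge
#' list (the STRING protein-links format; combined_score is an integer
#' confidence on 0-1000).  Species prefixes of the form `"NNNN."` are
#' stripped; edges below the score threshold are dropped; the two
#' orientations of an undirected edge are merged keeping the maximum score;
#' self-loops are removed.
#'
#' @param path path to the edge-list file (optional header line allowed).
#' @param score_threshold minimum combined score (default 400, STRING's
#'   "medium confidence").
#' @return a `NetworkGraph`: list with `nodes` (character) and `edges`
#'   (data.frame `from`, `to`, `combined_score`).
#' @export
load_network <- function(path, score_threshold = 400L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(structure(list(nodes = character(),
                          edges = empty_edges()), class = "NetworkGraph"))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  start <- 1L
  if (tolower(fields[[1]][1]) %in% c("protein1", "node1", "from"))
    start <- 2L
  from <- to <- character(length(fields) - start + 1L)
  score <- integer(length(from))
  for (i in seq(start, length(fields))) {
    f <- fields[[i]]
    sc <- suppressWarnings(as.numeric(f[3]))
    if (length(f) != 3L || is.na(sc))
      stop("malformed network line ", i, ": '", lines[i], "'")
    j <- i - start + 1L
    from[j] <- strip_species_prefix(f[1])
    to[j] <- strip_species_prefix(f[2])
    score[j] <- as.integer(round(sc))
  }
  keep <- score >= score_threshold & from != to
  from <- from[keep]; to <- to[keep]; score <- score[keep]
  # canonical orientation, then merge duplicates keeping the max score
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -score)
  first <- !duplicated(key[ord])
  edges <- data.frame(from = a[ord][first], to = b[ord][first],
                      combined_score = score[ord][first],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$from, edges$to))),
                 edges = edges),
            class = "NetworkGraph")
}

empty_edges <- function()
  data.frame(from = character(), to = character(),
             combined_score = integer(), stringsAsFactors = FALSE)

strip_species_prefix <- function(x) sub("^[0-9]+\\.", "", x)

#' Induced subnetwork on a gene list
#'
#' Restricts a `NetworkGraph` to the given genes (matched
#' case-insensitively): edges with both endpoints in the list are kept, and
#' queried nodes present in the graph but without surviving edges are
#' retained as isolated nodes.
#'
#' @param g a `NetworkGraph` from [load_network()].
#' @param genes character vector of gene/protein symbols.
#' @return the induced `NetworkGraph`.
#' @export
induced_subnetwork <- function(g, genes) {
  stopifnot(inherits(g, "NetworkGraph"))
  sel <- g$nodes[tolower(g$nodes) %in% tolower(unique(genes))]
  keep <- g$edges$from %in% sel & g$edges$to %in% sel
  structure(list(nodes = sort(sel),
                 edges = g$edges[keep, , drop = FALSE]),
            class = "NetworkGraph")
}

#' @export
print.NetworkGraph <- function(x, ...) {
  cat(sprintf("NetworkGraph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d features, %d clusters (m = %g, %d iterations)\n",
              nrow(x$membership), ncol(x$membership), x$m,
              length(x$objective)))
  invisible(x)
}
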