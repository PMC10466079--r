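#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set exchange format (one set per line:
#' name, description, then member symbols).  GO/Reactome/MSigDB exports are
#' consumed this way; no online retrieval is performed.
#'
#' @param path path to a `.gmt` file.
#' @return a `GeneSetCollection`: named list of
#'   `list(description =, members =)` entries; duplicate members within a
#'   set are deduplicated.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop("GMT line ", i, " has no members")
    if (fields[1] %in% names(sets))
      stop("duplicate set name '", fields[1], "' at line ", i)
    sets[[fields[1]]] <- list(description = fields[2], members = members)
  }
  structure(sets, class = "GeneSetCollection")
}

#' Write a GeneSetCollection to GMT
#' @param gsc a `GeneSetCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc), function(nm)
    paste(c(nm, gsc[[nm]]$description, gsc[[nm]]$members), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis (hypergeometric test)
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected by chance when drawing `n` genes from the universe of size
#' `N`: the upper-tail hypergeometric probability `P(X >= k)` with `K` set
#' members in the universe.  The universe should be the genes actually
#' quantified/tested (background correction), not the whole annotation.
#'
#' @param query character vector of significant gene symbols.
#' @param universe character vector of all tested gene symbols.
#' @param gsc a `GeneSetCollection`.
#' @param min_size,max_size set-size bounds after intersection with the
#'   universe (defaults 5 and 500).
#' @return data.frame (`EnrichmentResult`) with one row per tested set:
#'   `set_name`, `k`, `K`, `n`, `N`, `p`, `padj`, ordered by `p`.
#' @export
ora_hypergeometric <- function(query, universe, gsc, min_size = 5L,
                               max_size = 500L) {
  universe <- unique(universe)
  query0 <- unique(query)
  query <- intersect(query0, universe)
  if (length(query) < length(query0))
    warning(length(query0) - length(query),
            " query gene(s) outside the universe were dropped")
  if (!length(query))
    stop("empty query after intersection with the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gsc), function(nm) {
    members <- intersect(gsc[[nm]]$members, universe)
    K <- length(members)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_name = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      padj = numeric(), stringsAsFactors = FALSE))
  out$padj <- adjust_bh(out$p)
  out[order(out$p, out$set_name), , drop = FALSE]
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted Kolmogorov-Smirnov-like running-sum statistic over
#' a ranked gene list: walking down the ranking, hits increment the sum by
#' `|score|^weight_exponent` (normalized to total 1 within the set) and
#' misses decrement it by `1/(N - K)`; the enrichment score ES is the
#' signed maximal deviation.  The null is gene-label permutation — set
#' memberships are redrawn uniformly — appropriate when only a ranked list
#' (e.g. moderated t statistics) is available.  NES is ES divided by the
#' mean of same-sign permutation scores and `perm_p` the fraction of
#' same-sign permutation scores at least as extreme.
#'
#' @param ranked named numeric vector of finite scores (names = unique gene
#'   symbols); sorted in decreasing order internally.
#' @param gsc a `GeneSetCollection`.
#' @param weight_exponent weight on `|score|` (default 1; 0 gives the
#'   unweighted KS statistic).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked list.
#' @return data.frame (`EnrichmentResult`) with `set_name`, `K`, `es`,
#'   `nes`, `perm_p`, `padj`; sets with no ranked member are skipped.
#' @export
gsea <- function(ranked, gsc, weight_exponent = 1, n_perm = 1000L,
                 seed = NULL, min_size = 5L, max_size = 500L) {
  if (anyDuplicated(names(ranked)))
    stop("ranked gene names must be unique")
  if (any(!is.finite(ranked)))
    stop("ranked scores must be finite")
  ord <- order(ranked, decreasing = TRUE)
  ranked <- ranked[ord]
  genes <- names(ranked)
  N <- length(ranked)
  w_all <- abs(ranked)^weight_exponent
  if (!is.null(seed)) set.seed(as.integer(seed))
  rows <- lapply(names(gsc), function(nm) {
    pos <- sort(match(intersect(gsc[[nm]]$members, genes), genes))
    K <- length(pos)
    if (K == 0L || K < min_size || K > max_size || K == N) return(NULL)
    es <- running_sum_es(pos, w_all, N)
    perm <- vapply(seq_len(n_perm), function(i)
      running_sum_es(sort(sample.int(N, K)), w_all, N), numeric(1))
    same <- perm[sign(perm) == sign(es)]
    if (length(same)) {
      nes <- es / abs(mean(same))   # sign of ES preserved
      perm_p <- mean(abs(same) >= abs(es))
    } else {
      nes <- NA_real_
      perm_p <- 0
    }
    data.frame(set_name = nm, K = K, es = es, nes = nes, perm_p = perm_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_name = character(), K = integer(), es = numeric(),
                      nes = numeric(), perm_p = numeric(), padj = numeric(),
                      stringsAsFactors = FALSE))
  out$padj <- adjust_bh(out$perm_p)
  out[order(out$perm_p, -abs(out$nes), out$set_name), , drop = FALSE]
}

# ES from sorted hit positions: evaluate the running sum at its only
# candidate extremes (just before and just after each hit).
running_sum_es <- function(pos, w_all, N) {
  K <- length(pos)
  w <- w_all[pos]
  tot <- sum(w)
  w <- if (tot <= 0) rep(1 / K, K) else w / tot  # degenerate all-zero scores
  miss <- 1 / (N - K)
  cw <- cumsum(w)
  after <- cw - (pos - seq_len(K)) * miss
  before <- c(0, cw[-K]) - (pos - 1 - (seq_len(K) - 1)) * miss
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}
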