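# Shared fixture builders; everything is generated in code at test time.

toy_wide_file <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small complete QuantTable with the given matrix
qt_from_matrix <- function(X, annotations = NULL) {
  ids <- if (is.null(rownames(X))) sprintf("F%03d", seq_len(nrow(X)))
         else rownames(X)
  rownames(X) <- ids
  quant_table(feature_id = ids, name = ids, raw_ids = ids,
              intensities = X, annotations = annotations)
}

# bound log2-scale QuantMatrix from a log2 matrix (bypasses transform)
qm_from_log2 <- function(X, design) {
  qt <- qt_from_matrix(2^X)
  qm <- suppressWarnings(bind_design(qt, design))
  proteopipe:::set_quant(qm, X, scale = "log2")
}

random_design <- function(n_conditions = 2, n_reps = 3)
  default_design(n_conditions, n_reps)

# brute-force BH step-up, O(n^2): adj_i = min over j with p_j >= p_i of
# p_(j) * n / rank_j, evaluated straight from the definition
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    adj_sorted[i] <- min(1, min(p[ord][i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj_sorted
  out
}

# naive long-run median polish: a fixed number of full sweeps, written
# straight from the definition with no convergence logic
medpolish_longrun <- function(Y, sweeps = 500) {
  t0 <- 0
  r <- numeric(nrow(Y))
  cc <- numeric(ncol(Y))
  z <- Y
  for (s in seq_len(sweeps)) {
    rd <- apply(z, 1, median)
    z <- z - matrix(rd, nrow(Y), ncol(Y))
    r <- r + rd
    d <- median(cc); cc <- cc - d; t0 <- t0 + d
    cd <- apply(z, 2, median)
    z <- z - matrix(cd, nrow(Y), ncol(Y), byrow = TRUE)
    cc <- cc + cd
    d <- median(r); r <- r - d; t0 <- t0 + d
  }
  list(abundance = t0 + cc, residuals = z)
}

# exact hypergeometric upper tail by enumeration
hyper_tail_enum <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# brute-force GSEA running sum over the whole ranking
es_bruteforce <- function(pos, scores, exponent) {
  N <- length(scores)
  hit <- rep(FALSE, N)
  hit[pos] <- TRUE
  w <- abs(scores)^exponent
  w <- w * hit
  if (sum(w) > 0) w <- w / sum(w) else w[hit] <- 1 / sum(hit)
  step <- ifelse(hit, w, -1 / (N - sum(hit)))
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}
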