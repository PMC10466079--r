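#' Simulate a peptide-level LFQ dataset with known ground truth
#'
#' Generates a two-condition label-free experiment from the bottom up:
#' protein log2 abundances ~ Normal(25, 2^2); peptide ionization offsets ~
#' Normal(0, 1); replicate noise ~ Normal(0, sigma^2); a fraction of
#' proteins receives +/- `effect_size` in condition B.  Gross outliers add
#' U(5, 10) log2 units to `outlier_rate` of cells.  Missingness combines a
#' soft left-censoring MNAR mechanism — cell at log2 intensity `x` in
#' sample `s` is observed with probability
#' `logistic((x - (mu_s - mnar_shift * sd_s)) / 0.5)` — with uniform MAR
#' dropout at `mar_rate`.  Raw intensities are `2^x`.
#'
#' Defaults emulate a routine deep LFQ comparison: 100 protein groups
#' quantified by 7 peptides each, 4 replicates per condition, 10% regulated
#' proteins at one log2 unit, replicate CV around 20% (sigma 0.3) and ~5%
#' contaminated cells.
#'
#' @param n_proteins number of proteins (default 100).
#' @param peptides_per_protein peptides per protein (default 7).
#' @param n_reps_per_group replicates in each of conditions A and B
#'   (default 4).
#' @param effect_size absolute log2 fold-change of regulated proteins
#'   (default 1).
#' @param regulated_fraction fraction of proteins regulated in B
#'   (default 0.1; signs alternate).
#' @param sigma replicate noise SD on log2 scale (default 0.3).
#' @param mnar_shift left-censoring threshold in per-sample SD units below
#'   the sample mean (default 2; `Inf` disables MNAR).
#' @param mar_rate uniform random dropout rate (default 0.05).
#' @param outlier_rate fraction of cells receiving a gross positive outlier
#'   (default 0.05).
#' @param seed integer seed; the generator is a pure function of its
#'   parameters and the seed.
#' @return list with `table` (raw-scale peptide `QuantTable`, protein group
#'   in annotation column `"Protein group"`), `design` (data.frame), and
#'   `truth` (list: per-protein `base`, `true_log2fc` (B - A),
#'   `regulated`, per-peptide `protein` map, true per-sample protein
#'   log2 profiles `protein_profiles`, and the missingness parameters).
#' @export
simulate_peptide_dataset <- function(n_proteins = 100L,
                                     peptides_per_protein = 7L,
                                     n_reps_per_group = 4L,
                                     effect_size = 1,
                                     regulated_fraction = 0.1,
                                     sigma = 0.3,
                                     mnar_shift = 2,
                                     mar_rate = 0.05,
                                     outlier_rate = 0.05,
                                     seed = 1L) {
  stopifnot(n_proteins >= 1L, peptides_per_protein >= 1L,
            n_reps_per_group >= 1L, sigma > 0,
            regulated_fraction >= 0, regulated_fraction <= 1,
            mar_rate >= 0, mar_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1)
  set.seed(as.integer(seed))
  n_pep <- n_proteins * peptides_per_protein
  n_samp <- 2L * n_reps_per_group
  samples <- c(paste0("A_", seq_len(n_reps_per_group)),
               paste0("B_", seq_len(n_reps_per_group)))
  condition <- rep(c("A", "B"), each = n_reps_per_group)
  prot_ids <- sprintf("P%04d", seq_len(n_proteins))
  base <- stats::rnorm(n_proteins, mean = 25, sd = 2)
  n_reg <- round(regulated_fraction * n_proteins)
  regulated <- rep(FALSE, n_proteins)
  regulated[seq_len(n_reg)] <- TRUE
  sign_fc <- rep(c(1, -1), length.out = max(n_reg, 1L))
  true_fc <- numeric(n_proteins)
  if (n_reg > 0) true_fc[seq_len(n_reg)] <- sign_fc[seq_len(n_reg)] * effect_size
  # true protein-level log2 profile per sample (no noise)
  profiles <- outer(base, rep(1, n_samp)) +
    outer(true_fc, as.numeric(condition == "B"))
  dimnames(profiles) <- list(prot_ids, samples)
  pep_protein <- rep(prot_ids, each = peptides_per_protein)
  pep_offset <- stats::rnorm(n_pep, 0, 1)
  X <- profiles[pep_protein, , drop = FALSE] + pep_offset +
    matrix(stats::rnorm(n_pep * n_samp, 0, sigma), n_pep, n_samp)
  out_mask <- matrix(stats::runif(n_pep * n_samp) < outlier_rate,
                     n_pep, n_samp)
  X[out_mask] <- X[out_mask] + stats::runif(sum(out_mask), 5, 10)
  # missingness: soft left-censoring (MNAR) plus uniform dropout (MAR)
  mu_s <- colMeans(X)
  sd_s <- apply(X, 2L, stats::sd)
  thresh <- mu_s - mnar_shift * sd_s
  p_obs <- stats::plogis(sweep(X, 2L, thresh, "-") / 0.5)
  obs <- matrix(stats::runif(n_pep * n_samp) < p_obs, n_pep, n_samp)
  obs <- obs & matrix(stats::runif(n_pep * n_samp) >= mar_rate,
                      n_pep, n_samp)
  raw <- 2^X
  raw[!obs] <- NA_real_
  pep_ids <- sprintf("%s_pep%02d", pep_protein,
                     rep(seq_len(peptides_per_protein), times = n_proteins))
  colnames(raw) <- samples
  ann <- data.frame(`Protein group` = pep_protein,
                    Reverse = "", `Potential contaminant` = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
  qt <- quant_table(feature_id = pep_ids, name = pep_ids,
                    raw_ids = pep_protein, intensities = raw,
                    annotations = ann)
  design <- data.frame(sample = samples, condition = condition,
                       replicate = rep(seq_len(n_reps_per_group), 2L),
                       stringsAsFactors = FALSE)
  truth <- list(protein = prot_ids, base = base, true_log2fc = true_fc,
                regulated = regulated, peptide_protein = pep_protein,
                protein_profiles = profiles, outlier_mask = out_mask,
                mnar_shift = mnar_shift, mar_rate = mar_rate,
                sigma = sigma)
  list(table = qt, design = design, truth = truth)
}

#' Simulate a global-null log2 dataset
#'
#' Every feature has the same mean in every condition; used to check
#' type-I-error calibration of the moderated test.
#'
#' @param n_features number of features (default 2000).
#' @param design design data.frame (default 2 conditions x 3 replicates).
#' @param sigma noise SD (default 0.3).
#' @param mean common log2 mean (default 25).
#' @param seed integer seed.
#' @return list with `qm` (complete log2-scale QuantMatrix) and `design`.
#' @export
simulate_null_dataset <- function(n_features = 2000L,
                                  design = default_design(2L, 3L),
                                  sigma = 0.3, mean = 25, seed = 1L) {
  stopifnot(n_features >= 1L, sigma > 0)
  set.seed(as.integer(seed))
  design <- parse_design(design)
  n_samp <- nrow(design)
  X <- matrix(stats::rnorm(n_features * n_samp, mean, sigma),
              n_features, n_samp,
              dimnames = list(sprintf("F%05d", seq_len(n_features)),
                              design$sample))
  qt <- quant_table(feature_id = rownames(X), name = rownames(X),
                    raw_ids = rownames(X), intensities = 2^X)
  qm <- bind_design(qt, design)
  qm <- set_quant(qm, X, scale = "log2")
  qm <- add_history(qm, "simulate_null_dataset",
                    list(sigma = sigma, mean = mean, seed = seed),
                    n_features, n_features)
  list(qm = qm, design = design)
}

#' Default two-factor design helper
#' @param n_conditions number of conditions (labelled A, B, C, ...).
#' @param n_reps replicates per condition.
#' @return a design data.frame.
#' @export
default_design <- function(n_conditions = 2L, n_reps = 3L) {
  conds <- LETTERS[seq_len(n_conditions)]
  data.frame(sample = paste0(rep(conds, each = n_reps), "_",
                             rep(seq_len(n_reps), n_conditions)),
             condition = rep(conds, each = n_reps),
             replicate = rep(seq_len(n_reps), n_conditions),
             stringsAsFactors = FALSE)
}

#' Simulate clustered expression profiles
#'
#' Draws `k` template profiles with pairwise Euclidean distance at least
#' `separation`, then scatters `n_per_cluster` members around each with
#' isotropic Gaussian noise.
#'
#' @param n_per_cluster members per cluster.
#' @param k number of clusters (>= 2).
#' @param n_conditions profile length.
#' @param separation minimum pairwise template distance.
#' @param noise member noise SD.
#' @param seed integer seed.
#' @return list with `X` (matrix, `k * n_per_cluster` x `n_conditions`),
#'   `labels` (integer) and `templates` (k x `n_conditions`).
#' @export
simulate_profiles <- function(n_per_cluster, k, n_conditions,
                              separation, noise, seed = 1L) {
  stopifnot(k >= 2L, n_per_cluster >= 1L, n_conditions >= 2L,
            separation > 0, noise >= 0)
  set.seed(as.integer(seed))
  templates <- NULL
  for (try in 1:200) {
    cand <- matrix(stats::rnorm(k * n_conditions, 0, separation),
                   k, n_conditions)
    dmin <- min(stats::dist(cand))
    if (dmin >= separation) {
      templates <- cand
      break
    }
  }
  if (is.null(templates)) {  # rescale the last draw to enforce separation
    templates <- cand * (separation / dmin) * 1.01
  }
  labels <- rep(seq_len(k), each = n_per_cluster)
  X <- templates[labels, , drop = FALSE] +
    matrix(stats::rnorm(k * n_per_cluster * n_conditions, 0, noise),
           k * n_per_cluster, n_conditions)
  rownames(X) <- sprintf("F%04d", seq_along(labels))
  colnames(X) <- paste0("T", seq_len(n_conditions))
  rownames(templates) <- paste0("template_", seq_len(k))
  list(X = X, labels = labels, templates = templates)
}
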