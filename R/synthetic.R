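#' Configuration for the synthetic cohort generator
#'
#' Defaults state the world the analysis targets: a 30-case / 29-control
#' whole-blood cohort with ~600 semi-quantitative log-normal metabolites,
#' 20 targeted quantitative pathway measurements plus 5 nutritional markers,
#' two binary genotype variables, five latent correlated clusters of 8-15
#' affected metabolites with case/control mean ratios in 0.63-0.87 (the
#' depressed-cluster range), a handful of affected-but-independent "orphan"
#' features, and left-censoring at a low quantile of the null abundance
#' distribution.
#'
#' @param n_case,n_control group sizes (default 30 / 29, each >= 4).
#' @param n_features number of broad-metabolomics features (default 600).
#' @param n_clusters number of latent correlated clusters (default 5).
#' @param cluster_size_range min/max features per cluster (default 8-15).
#' @param effect_ratio_range case/control mean-ratio range for affected
#'   features (default 0.63-0.87).
#' @param within_cluster_r target range of pairwise Pearson correlation
#'   within a cluster (default 0.4-0.9).
#' @param cv per-feature coefficient of variation of the broad metabolites
#'   on the abundance scale (default 0.5).
#' @param censor_quantile left-censoring point as a quantile of each
#'   feature's null distribution, in `[0, 0.5)` (default 0.05).
#' @param genotype_freqs carrier probabilities for the two binary genotype
#'   features (default `c(0.31, 0.33)`).
#' @param n_orphans affected features outside every cluster (default 5).
#' @param n_targeted,n_nutritional targeted-panel sizes (default 20 / 5).
#' @param targeted_cv coefficient of variation of the targeted quantitative
#'   measurements (default 0.12).
#' @param seed integer RNG seed or `NULL`.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_case = 30, n_control = 29, n_features = 600,
                             n_clusters = 5, cluster_size_range = c(8, 15),
                             effect_ratio_range = c(0.63, 0.87),
                             within_cluster_r = c(0.4, 0.9),
                             cv = 0.5, censor_quantile = 0.05,
                             genotype_freqs = c(0.31, 0.33),
                             n_orphans = 5, n_targeted = 20,
                             n_nutritional = 5, targeted_cv = 0.12,
                             seed = NULL) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_features = as.integer(n_features),
              n_clusters = as.integer(n_clusters),
              cluster_size_range = as.integer(cluster_size_range),
              effect_ratio_range = as.numeric(effect_ratio_range),
              within_cluster_r = as.numeric(within_cluster_r),
              cv = cv, censor_quantile = censor_quantile,
              genotype_freqs = as.numeric(genotype_freqs),
              n_orphans = as.integer(n_orphans),
              n_targeted = as.integer(n_targeted),
              n_nutritional = as.integer(n_nutritional),
              targeted_cv = targeted_cv,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (cfg$n_case < 4L || cfg$n_control < 4L)
    stop("group sizes must be >= 4")
  if (cfg$censor_quantile < 0 || cfg$censor_quantile >= 0.5)
    stop("censor_quantile must be in [0, 0.5)")
  if (any(cfg$effect_ratio_range <= 0))
    stop("effect ratios must be positive")
  if (length(cfg$cluster_size_range) != 2L ||
      cfg$cluster_size_range[1] > cfg$cluster_size_range[2])
    stop("cluster_size_range must be an increasing pair")
  if (cfg$n_clusters * cfg$cluster_size_range[2] + cfg$n_orphans > cfg$n_features)
    stop("clusters plus orphans exceed n_features")
  class(cfg) <- "generator_config"
  cfg
}

#' Generate a synthetic case-control cohort with known ground truth
#'
#' Broad metabolites follow a log-normal abundance model: each feature has a
#' latent log-scale Gaussian with baseline drawn uniformly on
#' log(1e4)-log(1e8) (matching the dynamic range of semi-quantitative
#' intensities) and log-sd derived from `cv`. Cluster members load on a
#' shared per-participant latent factor (loading `l` gives pairwise
#' correlation `l_i l_j`, targeted at `within_cluster_r`), and case-group
#' means of affected features are multiplied by a cluster-level ratio drawn
#' from `effect_ratio_range`. Orphan features receive an independent effect
#' with no cluster membership. Targeted panel features are null quantitative
#' measurements; two independent Bernoulli genotype columns are added.
#' Values below each feature's `censor_quantile` null quantile are flagged
#' censored (value `NA` until imputation). Deterministic under a fixed
#' `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return list with `cohort` (a [cohort_matrix()]) and `truth` (list:
#'   `cluster_membership` named integer/NA per feature, `true_ratio` named
#'   numeric per feature, `orphan_features`, `cluster_ratio`).
#' @export
generate_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_case + cfg$n_control
  is_case <- c(rep(TRUE, cfg$n_case), rep(FALSE, cfg$n_control))

  met_names <- sprintf("met_%04d", seq_len(cfg$n_features))
  sizes <- sample(seq(cfg$cluster_size_range[1], cfg$cluster_size_range[2]),
                  cfg$n_clusters, replace = TRUE)
  picked <- sample(cfg$n_features, sum(sizes) + cfg$n_orphans)
  membership <- rep(NA_integer_, cfg$n_features)
  names(membership) <- met_names
  pos <- 1L
  for (k in seq_len(cfg$n_clusters)) {
    membership[picked[pos:(pos + sizes[k] - 1L)]] <- k
    pos <- pos + sizes[k]
  }
  orphan_idx <- if (cfg$n_orphans > 0) picked[pos:(pos + cfg$n_orphans - 1L)]
                else integer(0)

  sigma <- sqrt(log(1 + cfg$cv^2))
  mu <- stats::runif(cfg$n_features, log(1e4), log(1e8))
  cluster_ratio <- stats::runif(cfg$n_clusters, cfg$effect_ratio_range[1],
                                cfg$effect_ratio_range[2])
  true_ratio <- rep(1, cfg$n_features)
  names(true_ratio) <- met_names
  in_cluster <- !is.na(membership)
  true_ratio[in_cluster] <- cluster_ratio[membership[in_cluster]]
  true_ratio[orphan_idx] <- stats::runif(length(orphan_idx),
                                         cfg$effect_ratio_range[1],
                                         cfg$effect_ratio_range[2])
  loading <- rep(0, cfg$n_features)
  loading[in_cluster] <- stats::runif(sum(in_cluster),
                                      sqrt(cfg$within_cluster_r[1]),
                                      sqrt(cfg$within_cluster_r[2]))

  factors <- matrix(stats::rnorm(n * cfg$n_clusters), n, cfg$n_clusters)
  eps <- matrix(stats::rnorm(n * cfg$n_features), n, cfg$n_features)
  logX <- matrix(0, n, cfg$n_features)
  for (j in seq_len(cfg$n_features)) {
    l <- loading[j]
    z <- if (in_cluster[j]) l * factors[, membership[j]] + sqrt(1 - l^2) * eps[, j]
         else eps[, j]
    logX[, j] <- mu[j] + sigma * z + is_case * log(true_ratio[j])
  }
  met <- exp(logX)

  # left-censor at the null-distribution quantile of each feature
  cen_met <- matrix(FALSE, n, cfg$n_features)
  if (cfg$censor_quantile > 0) {
    thr <- exp(mu + sigma * stats::qnorm(cfg$censor_quantile))
    cen_met <- sweep(met, 2, thr, "<")
    met[cen_met] <- NA_real_
  }

  tg_names <- c(sprintf("focm_ts_%02d", seq_len(cfg$n_targeted)),
                sprintf("nutritional_%02d", seq_len(cfg$n_nutritional)))
  sig_t <- sqrt(log(1 + cfg$targeted_cv^2))
  mu_t <- stats::runif(length(tg_names), log(0.2), log(500))
  targeted <- exp(matrix(stats::rnorm(n * length(tg_names)), n) %*%
                    diag(sig_t, length(tg_names)) +
                  matrix(mu_t, n, length(tg_names), byrow = TRUE))

  geno <- cbind(stats::rbinom(n, 1, cfg$genotype_freqs[1]),
                stats::rbinom(n, 1, cfg$genotype_freqs[2]))
  colnames(geno) <- c("mthfr_A1298C", "mthfr_C677T")

  values <- cbind(targeted, geno, met)
  censored <- cbind(matrix(FALSE, n, ncol(targeted) + 2L), cen_met)
  feats <- rbind(
    feature_meta(sprintf("focm_ts_%02d", seq_len(cfg$n_targeted)), "focm_ts"),
    feature_meta(sprintf("nutritional_%02d", seq_len(cfg$n_nutritional)),
                 "nutritional"),
    feature_meta(colnames(geno), "mthfr_binary", kind = "binary"),
    feature_meta(met_names, "metabolon",
                 confirmed_standard = stats::runif(cfg$n_features) > 0.2))
  groups <- factor(ifelse(is_case, "ASD-M", "TD-M"),
                   levels = c("ASD-M", "TD-M"))
  ids <- c(sprintf("ASD_%02d", seq_len(cfg$n_case)),
           sprintf("TD_%02d", seq_len(cfg$n_control)))
  cohort <- cohort_matrix(values, groups, feats, participants = ids,
                          censored = censored, case_label = "ASD-M")
  truth <- list(cluster_membership = membership,
                true_ratio = true_ratio,
                orphan_features = met_names[orphan_idx],
                cluster_ratio = cluster_ratio)
  list(cohort = cohort, truth = truth)
}

#' Recovery of the generator's ground truth by the analysis
#'
#' Measures how well the univariate screen's joint significance rule
#' recovers the generator's affected features (sensitivity/specificity) and,
#' optionally, how well correlation clustering recovers the generated
#' clusters (per-cluster recall against the best-matching core's member
#' list).
#'
#' @param m the generated [cohort_matrix()].
#' @param truth the `truth` element returned by [generate_cohort()].
#' @param screen a `univariate_screen` computed on `m`.
#' @param clusters optional `correlation_clusters` computed on `m`.
#' @return list with `sensitivity`, `specificity`, `n_affected`, `n_null`,
#'   and (if `clusters` given) `cluster_recall` (per generated cluster) and
#'   `mean_cluster_recall`.
#' @export
parameter_recovery_report <- function(m, truth, screen, clusters = NULL) {
  met <- names(truth$true_ratio)
  if (!all(met %in% screen$feature))
    stop("screen does not cover the generated metabolite features")
  affected <- met[truth$true_ratio != 1]
  nulls <- setdiff(met, affected)
  flagged <- screen$feature[screen$significant]
  out <- list(sensitivity = if (length(affected))
                mean(affected %in% flagged) else NA_real_,
              specificity = if (length(nulls))
                mean(!(nulls %in% flagged)) else NA_real_,
              n_affected = length(affected), n_null = length(nulls))
  if (!is.null(clusters)) {
    member_sets <- lapply(clusters$clusters, function(cl)
      c(cl$core, cl$members$feature))
    ks <- sort(unique(truth$cluster_membership[!is.na(truth$cluster_membership)]))
    recall <- vapply(ks, function(k) {
      feats <- met[!is.na(truth$cluster_membership) &
                     truth$cluster_membership == k]
      max(vapply(member_sets, function(s) mean(feats %in% s), numeric(1)))
    }, numeric(1))
    names(recall) <- paste0("cluster_", ks)
    out$cluster_recall <- recall
    out$mean_cluster_recall <- mean(recall)
  }
  out
}
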