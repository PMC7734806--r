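# in-code fixtures shared across test files

# minimal continuous cohort from an explicit matrix
toy_cohort <- function(X, n_case, panel = "metabolon", kind = "continuous",
                       censored = NULL) {
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  cohort_matrix(X, rep(c("ASD-M", "TD-M"), c(n_case, n - n_case)),
                feature_meta(colnames(X), panel, kind),
                censored = censored)
}

# two-group Gaussian cohort, shifted means on the first `n_sig` features
gaussian_cohort <- function(n1 = 30, n2 = 29, p = 10, n_sig = 0, delta = 0,
                            seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  X <- matrix(rnorm(n * p), n)
  if (n_sig > 0)
    X[seq_len(n1), seq_len(n_sig)] <- X[seq_len(n1), seq_len(n_sig)] + delta
  X <- X - min(X) + 0.1   # keep abundances positive
  colnames(X) <- sprintf("f%02d", seq_len(p))
  toy_cohort(X, n1)
}

# small generator config that satisfies the cluster/feature arithmetic
small_config <- function(...) {
  defaults <- list(n_features = 80, n_clusters = 2, cluster_size_range = c(5, 8),
                   n_orphans = 1, n_targeted = 6, n_nutritional = 2,
                   censor_quantile = 0.02, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(generator_config, args)
}

# exact permutation two-sided p for the Mann-Whitney U statistic
perm_mw_p <- function(x, y) {
  v <- c(x, y); n1 <- length(x); n2 <- length(y)
  r <- rank(v)
  center <- n1 * n2 / 2
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 - center)
  idx <- utils::combn(length(v), n1)
  stat <- apply(idx, 2, function(ii)
    abs(sum(r[ii]) - n1 * (n1 + 1) / 2 - center))
  mean(stat >= obs - 1e-9)
}
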