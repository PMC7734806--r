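# Anderson-Darling normality test (mean and variance estimated from the
# sample), with Stephens' small-sample correction and the standard piecewise
# p-value approximation. Not in base R; implemented here because the
# adaptive test-selection tree depends on it.
ad_normality <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 4L) stop("Anderson-Darling test needs n >= 4")
  s <- stats::sd(x)
  if (s == 0) stop("Anderson-Darling test undefined for a constant sample")
  z <- stats::pnorm((x - mean(x)) / s)
  # clamp to keep the logs finite for extreme observations
  z <- pmin(pmax(z, .Machine$double.eps), 1 - .Machine$double.eps)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(z) + log(1 - rev(z)))) # note mean = /n
  Astar <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (Astar >= 0.6) {
    exp(1.2937 - 5.709 * Astar + 0.0186 * Astar^2)
  } else if (Astar >= 0.34) {
    exp(0.9177 - 4.279 * Astar - 1.38 * Astar^2)
  } else if (Astar > 0.2) {
    1 - exp(-8.318 + 42.796 * Astar - 59.938 * Astar^2)
  } else {
    1 - exp(-13.436 + 101.14 * Astar - 223.73 * Astar^2)
  }
  list(statistic = Astar, p = min(max(p, 0), 1))
}

.SCENARIOS <- c("t_eq", "t_neq", "mw", "t_neq_dagger", "chi2")

#' Select the two-sample test scenario for one feature
#'
#' Reproduces the adaptive pre-analysis: Anderson-Darling normality on each
#' group; if both look normal, an F-test decides between the pooled Student
#' t (`t_eq`) and the Welch t (`t_neq`); otherwise a two-sample
#' Kolmogorov-Smirnov test on *median-centered* samples decides between the
#' Mann-Whitney U test (`mw`, same shape) and a Welch t flagged as applied
#' without the normality premise (`t_neq_dagger`). Median-centering makes
#' the KS step a shape comparison, so a pure location shift of a common
#' shape still routes to `mw`. The KS p-value uses the asymptotic
#' distribution (ties after centering make the exact computation
#' ill-defined, and the resampling score re-runs this tree thousands of
#' times).
#'
#' @param x,y numeric samples (case, control), each of length >= 4.
#' @param alpha level used for all pre-tests (default 0.05).
#' @return one of `"t_eq"`, `"t_neq"`, `"mw"`, `"t_neq_dagger"`.
#' @export
select_test <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 4L || length(y) < 4L)
    stop("select_test needs at least 4 observations per group")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant sample: Anderson-Darling undefined, falling back to Mann-Whitney")
    return("mw")
  }
  norm_x <- ad_normality(x)$p > alpha
  norm_y <- ad_normality(y)$p > alpha
  if (norm_x && norm_y) {
    # two-sided F-test for equal variances (as var.test)
    Fstat <- stats::var(x) / stats::var(y)
    pf1 <- stats::pf(Fstat, length(x) - 1L, length(y) - 1L)
    p_f <- 2 * min(pf1, 1 - pf1)
    if (p_f > alpha) "t_eq" else "t_neq"
  } else {
    ks <- suppressWarnings(stats::ks.test(x - stats::median(x),
                                          y - stats::median(y),
                                          exact = FALSE))
    if (ks$p.value > alpha) "mw" else "t_neq_dagger"
  }
}

# Welch / pooled t statistics by closed form so degenerate inputs (zero
# variance) are handled explicitly rather than erroring inside t.test().
.t_two_sample <- function(x, y, pooled) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    df <- if (se2 > 0)
      se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)) else 1
  }
  if (se == 0) {
    # zero pooled variance: equal means -> indistinguishable (p = 1)
    if (m1 == m2) return(list(statistic = 0, p = 1))
    return(list(statistic = sign(m1 - m2) * Inf, p = 0))
  }
  tt <- (m1 - m2) / se
  list(statistic = tt, p = 2 * stats::pt(-abs(tt), df))
}

.mw_two_sample <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  tie_len <- rle(sort(c(x, y)))$lengths
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_len^3 - tie_len) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = U, p = 1)) # everything tied
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)               # no continuity correction
  list(statistic = U, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-sample p-value under a selected scenario
#'
#' @param x,y numeric samples (case, control).
#' @param scenario as returned by [select_test()]: `"t_eq"` (pooled Student
#'   t, df n1+n2-2), `"t_neq"` / `"t_neq_dagger"` (Welch t,
#'   Welch-Satterthwaite df) or `"mw"` (Mann-Whitney U, normal
#'   approximation with tie correction, no continuity correction).
#' @return list with `statistic` and two-sided `p`.
#' @export
two_sample_p <- function(x, y, scenario) {
  scenario <- match.arg(scenario, setdiff(.SCENARIOS, "chi2"))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  switch(scenario,
         t_eq = .t_two_sample(x, y, pooled = TRUE),
         t_neq = .t_two_sample(x, y, pooled = FALSE),
         t_neq_dagger = .t_two_sample(x, y, pooled = FALSE),
         mw = .mw_two_sample(x, y))
}

#' Pooled Student t-test from printed summary statistics
#'
#' Recomputes the two-sided pooled-variance t-test from group means,
#' standard deviations and sizes, as printed in summary tables.
#'
#' @param mean1,sd1,n1 case-group summaries.
#' @param mean2,sd2,n2 control-group summaries.
#' @param var_equal pooled variance (default) or Welch.
#' @return list with `statistic`, `df` and two-sided `p`.
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = TRUE) {
  v1 <- sd1^2; v2 <- sd2^2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (mean1 - mean2) / se
  list(statistic = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Pearson chi-square test of independence (2 x k)
#'
#' Without continuity correction, df = k - 1.
#'
#' @param table 2 x k matrix of counts with strictly positive margins.
#' @return list with `statistic`, `df` and `p`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L) stop("expected a 2 x k contingency table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate contingency table: zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' ROC area under the curve via the Mann-Whitney identity
#'
#' AUC = U / (n1 * n2) with half credit for ties, oriented as
#' `max(A, 1 - A)` so the reported AUC is always >= 0.5 regardless of the
#' direction of the group difference.
#'
#' @param x,y numeric samples (case, control).
#' @return AUC in `[0.5, 1]`.
#' @export
roc_auc <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("roc_auc needs non-empty samples")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  A <- U / (n1 * n2)
  max(A, 1 - A)
}

# shared core: recompute scenario + p on a pooled leave-k-out enumeration.
# test_fun(x, y) must return a p-value. Returns the vector of resampled p.
.lko_pvals <- function(vals, is_case, depths, test_fun) {
  n <- length(vals)
  depths <- sort(unique(as.integer(depths)))
  n1 <- sum(is_case); n2 <- n - n1
  if (any(depths < 1L)) stop("leave-out depths must be >= 1")
  if (any(depths >= min(n1, n2)))
    stop("leave-out depth must be smaller than the smaller group")
  if (n - max(depths) < 8L)
    stop("too few participants left after deletion (need >= 8)")
  ps <- vector("list", length(depths))
  skipped <- 0L
  for (k in seq_along(depths)) {
    d <- depths[k]
    combos <- utils::combn(n, d)
    pk <- numeric(ncol(combos))
    keepmask <- rep(TRUE, n)
    for (j in seq_len(ncol(combos))) {
      drop <- combos[, j]
      keepmask[drop] <- FALSE
      x <- vals[keepmask & is_case]
      y <- vals[keepmask & !is_case]
      keepmask[drop] <- TRUE
      if (length(x) < 4L || length(y) < 4L) { pk[j] <- NA_real_; skipped <- skipped + 1L; next }
      pk[j] <- test_fun(x, y)
    }
    ps[[k]] <- pk
  }
  if (skipped > 0L)
    warning(skipped, " deletion(s) skipped: a group fell below n = 4")
  unlist(ps, use.names = FALSE)
}

# scenario re-selection + p, silenced, for resampling loops (skips the
# match.arg dispatch of the public two_sample_p)
.select_and_p <- function(x, y, alpha) {
  sc <- suppressWarnings(select_test(x, y, alpha))
  switch(sc,
         t_eq = .t_two_sample(x, y, pooled = TRUE)$p,
         mw = .mw_two_sample(x, y)$p,
         .t_two_sample(x, y, pooled = FALSE)$p)
}

#' Leave-k-out resampling robustness score ("FDR")
#'
#' For every subset of `d` participants (d in `depths`) removed from the
#' pooled cohort, the test scenario is re-selected and the two-sample
#' p-value recomputed on the remaining participants. The returned score is
#' the fraction of those resampled p-values *exceeding* `alpha`, i.e. the
#' fraction of deletions under which the feature is no longer significant:
#' 0 means the finding survives every deletion, 1 means it never reaches
#' significance. (With n = 59 and `depths = c(1, 2)` the enumeration has
#' C(59,1) + C(59,2) = 1770 subsets.) This is a jackknife stability score,
#' not a Benjamini-Hochberg rate.
#'
#' @param x,y numeric samples (case, control).
#' @param alpha significance level applied to each resampled p-value.
#' @param depths vector of leave-out sizes (default `c(1, 2)`).
#' @return fraction in `[0, 1]`, with attribute `n_subsets` (number of
#'   evaluated deletions).
#' @export
leave_k_out_fdr <- function(x, y, alpha = 0.05, depths = c(1, 2)) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  vals <- c(x, y)
  is_case <- c(rep(TRUE, length(x)), rep(FALSE, length(y)))
  ps <- .lko_pvals(vals, is_case, depths,
                   function(a, b) .select_and_p(a, b, alpha))
  ps <- ps[!is.na(ps)]
  fdr <- mean(ps > alpha)
  attr(fdr, "n_subsets") <- length(ps)
  fdr
}

# chi-square analogue for binary features inside the screen
.lko_fdr_chi2 <- function(vals, is_case, alpha, depths) {
  ps <- .lko_pvals(vals, is_case, depths, function(a, b) {
    tab <- rbind(table(factor(a, levels = sort(unique(c(a, b))))),
                 table(factor(b, levels = sort(unique(c(a, b))))))
    if (ncol(tab) < 2L || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(1)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
  })
  ps <- ps[!is.na(ps)]
  fdr <- mean(ps > alpha)
  attr(fdr, "n_subsets") <- length(ps)
  fdr
}

#' Univariate screen over all features of a cohort
#'
#' Runs, per feature: adaptive test selection and the two-sample test
#' (chi-square for binary features), the leave-k-out robustness score, AUC,
#' group summaries and the case/control mean ratio. A feature is flagged
#' significant iff `p <= alpha` *and* `fdr <= fdr_threshold` (joint rule; no
#' multiplicity adjustment is applied anywhere). Results are sorted by AUC
#' descending.
#'
#' @param m an imputed [cohort_matrix()].
#' @param alpha significance level (default 0.05).
#' @param fdr_threshold robustness-score threshold (default 0.1).
#' @param depths leave-out sizes for the resampling score; set to `NULL` to
#'   skip the (expensive) resampling and report `fdr = NA`.
#' @return data frame of class `univariate_screen`, one row per feature:
#'   `feature`, `scenario`, `statistic`, `p`, `fdr`, `auc`, `mean_case`,
#'   `sd_case`, `mean_control`, `sd_control`, `ratio`, `significant`.
#' @export
run_screen <- function(m, alpha = 0.05, fdr_threshold = 0.1,
                       depths = c(1, 2)) {
  stopifnot(inherits(m, "cohort_matrix"))
  if (any(is.na(m$values) & m$censored))
    stop("cohort has unimputed censored cells; run impute_below_detection() first")
  cm <- case_mask(m)
  nf <- ncol(m$values)
  rows <- vector("list", nf)
  for (j in seq_len(nf)) {
    nm <- m$features$name[j]
    kind <- m$features$kind[j]
    v <- m$values[, j]
    keep <- !is.na(v)
    x <- v[cm & keep]; y <- v[!cm & keep]
    auc <- roc_auc(x, y)
    msd <- c(mean(x), stats::sd(x), mean(y), stats::sd(y))
    ratio <- if (msd[3] != 0) msd[1] / msd[3] else NA_real_
    if (kind %in% c("binary", "ordinal") && length(unique(v[keep])) <= 6L) {
      lev <- sort(unique(v[keep]))
      tab <- rbind(table(factor(x, levels = lev)), table(factor(y, levels = lev)))
      if (ncol(tab) < 2L) {
        sc <- "chi2"; stat <- 0; p <- 1
      } else {
        res <- chi_square_independence(tab)
        sc <- "chi2"; stat <- res$statistic; p <- res$p
      }
      fdr <- if (is.null(depths)) NA_real_ else
        as.numeric(.lko_fdr_chi2(v[keep], cm[keep], alpha, depths))
    } else {
      if (stats::sd(v[keep]) == 0) {
        sc <- "mw"; stat <- length(x) * length(y) / 2; p <- 1
        fdr <- if (is.null(depths)) NA_real_ else 1
      } else {
        sc <- suppressWarnings(select_test(x, y, alpha))
        tp <- two_sample_p(x, y, sc)
        stat <- tp$statistic; p <- tp$p
        fdr <- if (is.null(depths)) NA_real_ else
          as.numeric(suppressWarnings(leave_k_out_fdr(x, y, alpha, depths)))
      }
    }
    rows[[j]] <- data.frame(feature = nm, scenario = sc, statistic = stat,
                            p = p, fdr = fdr, auc = auc,
                            mean_case = msd[1], sd_case = msd[2],
                            mean_control = msd[3], sd_control = msd[4],
                            ratio = ratio, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p <= alpha & !is.na(out$fdr) & out$fdr <= fdr_threshold
  out <- out[order(-out$auc, out$p, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("univariate_screen", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "depths") <- depths
  out
}
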