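# Pearson r and two-sided t-based p for one pair of complete vectors
.pearson_rp <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3L || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(a, b)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  c(r = r, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

#' Correlation clusters around core features
#'
#' For each core feature, computes the Pearson correlation (on the pooled
#' case + control samples) with every candidate feature and keeps the
#' candidates with two-sided p <= `p_threshold` as cluster members, sorted
#' by r descending. A candidate may belong to several cores' member lists.
#' The core-by-core correlation table is computed with the same code path.
#' p-values are unadjusted.
#'
#' @param m an imputed [cohort_matrix()].
#' @param cores character vector of core feature names.
#' @param candidates candidate feature names (default: all continuous
#'   features of `m`).
#' @param p_threshold membership threshold on the unadjusted p (default
#'   0.05).
#' @return object of class `correlation_clusters`: list with `clusters`
#'   (per core: `core`, `members` data frame with `feature`, `r`, `p`) and
#'   `core_cor` (data frame of core-pair r and p).
#' @export
correlate_with_cores <- function(m, cores, candidates = NULL,
                                 p_threshold = 0.05) {
  stopifnot(inherits(m, "cohort_matrix"))
  if (is.null(candidates))
    candidates <- m$features$name[m$features$kind == "continuous"]
  unknown <- setdiff(c(cores, candidates), m$features$name)
  if (length(unknown)) stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  if (!all(cores %in% candidates) && !all(cores %in% m$features$name))
    stop("cores must be features of the cohort")
  clusters <- lapply(cores, function(core) {
    cv <- m$values[, core]
    others <- setdiff(candidates, core)
    rp <- t(vapply(others, function(f) .pearson_rp(cv, m$values[, f]),
                   numeric(3)))
    bad <- is.na(rp[, "r"])
    if (any(bad))
      warning("constant/degenerate candidate(s) skipped for core '", core,
              "': ", paste(others[bad], collapse = ", "))
    rp <- rp[!bad, , drop = FALSE]
    keep <- rp[, "p"] <= p_threshold
    members <- data.frame(feature = rownames(rp)[keep],
                          r = rp[keep, "r"], p = rp[keep, "p"],
                          stringsAsFactors = FALSE)
    members <- members[order(-members$r), , drop = FALSE]
    rownames(members) <- NULL
    list(core = core, members = members)
  })
  names(clusters) <- cores
  pairs <- if (length(cores) >= 2L) utils::combn(cores, 2L) else
    matrix(character(0), 2, 0)
  core_cor <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    rp <- .pearson_rp(m$values[, pairs[1, j]], m$values[, pairs[2, j]])
    data.frame(core_a = pairs[1, j], core_b = pairs[2, j],
               r = rp[["r"]], p = rp[["p"]], stringsAsFactors = FALSE)
  }))
  structure(list(clusters = clusters, core_cor = core_cor,
                 p_threshold = p_threshold),
            class = "correlation_clusters")
}

#' @export
print.correlation_clusters <- function(x, ...) {
  cat("<correlation_clusters> ", length(x$clusters), " cores\n", sep = "")
  for (cl in x$clusters)
    cat("  ", cl$core, ": ", nrow(cl$members), " members\n", sep = "")
  invisible(x)
}

#' Orphan features: significant but uncorrelated with every core
#'
#' Orphans are features flagged significant by the univariate screen that
#' appear in no core's member list and are not cores themselves. Their
#' pairwise correlation table is returned to check whether they form an
#' additional correlated group of their own.
#'
#' @param m the imputed [cohort_matrix()] both inputs were computed on.
#' @param screen a `univariate_screen` from [run_screen()].
#' @param clusters a `correlation_clusters` from [correlate_with_cores()].
#' @return list with `orphans` (character) and `pairwise` (data frame of
#'   orphan-orphan r and p; symmetric information, each pair once).
#' @export
find_orphans <- function(m, screen, clusters) {
  sig <- screen$feature[screen$significant]
  cores <- vapply(clusters$clusters, function(cl) cl$core, "")
  members <- unique(unlist(lapply(clusters$clusters,
                                  function(cl) cl$members$feature)))
  orphans <- setdiff(sig, c(cores, members))
  pairs <- if (length(orphans) >= 2L) utils::combn(orphans, 2L) else
    matrix(character(0), 2, 0)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    rp <- .pearson_rp(m$values[, pairs[1, j]], m$values[, pairs[2, j]])
    data.frame(feature_a = pairs[1, j], feature_b = pairs[2, j],
               r = rp[["r"]], p = rp[["p"]], stringsAsFactors = FALSE)
  }))
  if (is.null(pairwise))
    pairwise <- data.frame(feature_a = character(0), feature_b = character(0),
                           r = numeric(0), p = numeric(0))
  list(orphans = orphans, pairwise = pairwise)
}
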