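# fit + predict one LOOCV fold; returns held-out label and score/probability
.fit_predict_fold <- function(Xtr, ytr_case, xte, classifier, pos, neg) {
  if (classifier == "fda") {
    mod <- suppressWarnings(
      fda_fit(Xtr[ytr_case, , drop = FALSE], Xtr[!ytr_case, , drop = FALSE],
              positive_label = pos, negative_label = neg))
    mod <- balance_confidence(mod, Xtr[ytr_case, , drop = FALSE],
                              Xtr[!ytr_case, , drop = FALSE])
    s <- fda_scores(mod, matrix(xte, nrow = 1))
    list(label = if (s <= mod$boundary) pos else neg, score = s)
  } else {
    mod <- suppressWarnings(
      logistic_fit(Xtr, factor(ifelse(ytr_case, pos, neg), levels = c(pos, neg))))
    pr <- logistic_prob(mod, matrix(xte, nrow = 1))
    list(label = if (pr > 0.5) pos else neg, score = pr)
  }
}

#' Leave-one-out cross-validation of one feature panel
#'
#' Fits `n` models, each excluding exactly one participant, and predicts the
#' held-out participant. Everything — standardization constants, the FDA
#' direction, the KDE boundary and its balanced confidence level — is
#' re-derived inside each fold, so no information from the held-out row
#' leaks into its prediction. Type I error is the fraction of controls
#' labelled positive, type II the fraction of cases labelled negative.
#'
#' @param m an imputed [cohort_matrix()].
#' @param features character vector of feature names (complete, no missing
#'   cells).
#' @param classifier `"fda"` (continuous features only) or `"logistic"`.
#' @return object of class `panel_evaluation`: list with `features`,
#'   `classifier`, `type1`, `type2`, `sensitivity`, `specificity` and a
#'   `per_sample` data frame (participant, group, predicted label,
#'   score/probability).
#' @export
loocv_evaluate <- function(m, features, classifier = c("fda", "logistic")) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(m, "cohort_matrix"))
  miss <- setdiff(features, m$features$name)
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  kinds <- m$features$kind[match(features, m$features$name)]
  if (classifier == "fda" && any(kinds == "binary"))
    stop("FDA cannot use binary features (",
         paste(features[kinds == "binary"], collapse = ", "),
         "); use classifier = \"logistic\"")
  X <- m$values[, features, drop = FALSE]
  if (anyNA(X))
    stop("panel features contain missing or unimputed cells")
  is_case <- case_mask(m)
  pos <- levels(m$groups)[1L]; neg <- levels(m$groups)[2L]
  n <- nrow(X)
  labels <- character(n); score <- numeric(n)
  for (i in seq_len(n)) {
    pred <- .fit_predict_fold(X[-i, , drop = FALSE], is_case[-i], X[i, ],
                              classifier, pos, neg)
    labels[i] <- pred$label
    score[i] <- pred$score
  }
  type1 <- mean(labels[!is_case] == pos)
  type2 <- mean(labels[is_case] == neg)
  structure(list(features = features, classifier = classifier,
                 type1 = type1, type2 = type2,
                 sensitivity = 1 - type2, specificity = 1 - type1,
                 per_sample = data.frame(participant = m$participants,
                                         group = as.character(m$groups),
                                         predicted = labels, score = score,
                                         stringsAsFactors = FALSE)),
            class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat("<panel_evaluation> [", x$classifier, "] ",
      paste(x$features, collapse = " + "), "\n", sep = "")
  cat(sprintf("  type I %.0f%%  type II %.0f%%  (sens %.0f%%, spec %.0f%%)\n",
              100 * x$type1, 100 * x$type2,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

.rank_panels <- function(df) {
  key <- paste(vapply(df$features, paste, "", collapse = "|"))
  df[order(df$type1 + df$type2, abs(df$type1 - df$type2), key), , drop = FALSE]
}

.eval_combo_df <- function(m, combos, classifier) {
  rows <- lapply(combos, function(fs) {
    ev <- loocv_evaluate(m, fs, classifier)
    data.frame(size = length(fs), type1 = ev$type1, type2 = ev$type2,
               total = ev$type1 + ev$type2,
               sensitivity = ev$sensitivity, specificity = ev$specificity)
  })
  df <- do.call(rbind, rows)
  df$features <- combos
  df[, c("features", "size", "type1", "type2", "total",
         "sensitivity", "specificity")]
}

#' Search feature combinations of a subset by cross-validated error
#'
#' Evaluates feature combinations of the given sizes by [loocv_evaluate()]
#' and ranks them by total misclassification (type I + type II) ascending,
#' ties broken by |type I - type II| ascending, then lexicographically by
#' feature names. `"exhaustive"` enumerates every combination (guarded by
#' `budget`); `"beam"` grows panels one feature per round, keeping the
#' `beam_width` best prefixes — the documented scaled-down surrogate when
#' exhaustive enumeration is infeasible (e.g. 2-10 out of 76 variables).
#'
#' @param m an imputed [cohort_matrix()].
#' @param subset a `subset_spec` (or character vector of feature names).
#' @param sizes combination sizes, within 2..10 (default `2:5`).
#' @param classifier `"fda"` or `"logistic"`.
#' @param strategy `"exhaustive"` or `"beam"`.
#' @param budget maximum number of combinations an exhaustive search may
#'   evaluate (error above it, naming the count).
#' @param beam_width beam search width (default 50).
#' @return object of class `panel_ranking`: a ranked data frame with list
#'   column `features` and columns `size`, `type1`, `type2`, `total`,
#'   `sensitivity`, `specificity`.
#' @export
search_panels <- function(m, subset, sizes = 2:5,
                          classifier = c("fda", "logistic"),
                          strategy = c("exhaustive", "beam"),
                          budget = 20000, beam_width = 50) {
  classifier <- match.arg(classifier)
  strategy <- match.arg(strategy)
  feats <- if (inherits(subset, "subset_spec")) subset$feature_names
           else as.character(subset)
  feats <- sort(feats)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 2L) || any(sizes > 10L))
    stop("combination sizes must be within 2..10")
  sizes <- sizes[sizes <= length(feats)]
  if (!length(sizes)) stop("no feasible combination size for ",
                           length(feats), " features")
  if (strategy == "exhaustive") {
    count <- sum(choose(length(feats), sizes))
    if (count > budget)
      stop("exhaustive search would evaluate ", count,
           " combinations (budget ", budget, "); use strategy = \"beam\"")
    combos <- unlist(lapply(sizes, function(s)
      utils::combn(feats, s, simplify = FALSE)), recursive = FALSE)
    df <- .eval_combo_df(m, combos, classifier)
  } else {
    seen <- new.env(hash = TRUE)
    results <- list()
    # round 1: all pairs, ranked; subsequent rounds extend the beam by one
    pairs <- utils::combn(feats, 2L, simplify = FALSE)
    df <- .eval_combo_df(m, pairs, classifier)
    df <- .rank_panels(df)
    if (2L %in% sizes) results[[length(results) + 1L]] <- df
    beam <- df$features[seq_len(min(beam_width, nrow(df)))]
    s <- 2L
    while (s < max(sizes)) {
      s <- s + 1L
      cand <- list()
      for (b in beam) for (f in setdiff(feats, b)) {
        ext <- sort(c(b, f))
        key <- paste(ext, collapse = "|")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        cand[[length(cand) + 1L]] <- ext
      }
      if (!length(cand)) break
      df <- .eval_combo_df(m, cand, classifier)
      df <- .rank_panels(df)
      if (s %in% sizes) results[[length(results) + 1L]] <- df
      beam <- df$features[seq_len(min(beam_width, nrow(df)))]
    }
    df <- do.call(rbind, results)
  }
  df <- .rank_panels(df)
  rownames(df) <- NULL
  class(df) <- c("panel_ranking", "data.frame")
  attr(df, "classifier") <- classifier
  attr(df, "strategy") <- strategy
  df
}

#' @export
print.panel_ranking <- function(x, n = 5L, ...) {
  cat("<panel_ranking> ", nrow(x), " combinations [",
      attr(x, "classifier"), ", ", attr(x, "strategy"), "]\n", sep = "")
  top <- utils::head(x, n)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %d. %s  (type I %.0f%%, type II %.0f%%)\n", i,
                paste(top$features[[i]], collapse = " + "),
                100 * top$type1[i], 100 * top$type2[i]))
  invisible(x)
}

#' Report the best panels with near-ties
#'
#' @param ranking a `panel_ranking` from [search_panels()].
#' @param k number of top combinations to report (default 1).
#' @param margin also include every combination whose total error is within
#'   `margin` of the best (default 0.02).
#' @return data frame of the selected rows with an added `rank` column and
#'   percent errors rounded to whole percent (display convention).
#' @export
report_best <- function(ranking, k = 1L, margin = 0.02) {
  if (!nrow(ranking)) stop("empty ranking")
  df <- .rank_panels(ranking)
  best <- df$total[1L]
  take <- seq_len(nrow(df)) <= k | df$total <= best + margin + 1e-12
  out <- df[take, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$type1_pct <- round(100 * out$type1)
  out$type2_pct <- round(100 * out$type2)
  rownames(out) <- NULL
  out
}
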