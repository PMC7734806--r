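# standardization constants from training rows only (leakage-safe: LOOCV
# folds recompute these without the held-out row)
.standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  list(center = ctr, scale = scl)
}

.apply_standardizer <- function(X, std) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

#' Fit a two-group Fisher discriminant model
#'
#' Finds the unit-length projection direction p maximizing
#' J = (t1bar - t2bar)^2 / (s1^2 + s2^2), where t = X p are the projected
#' scores and s_g^2 are the unbiased projected group variances. The
#' closed-form maximizer is proportional to the inverse of the summed
#' within-group covariance matrices applied to the mean difference. Features
#' are z-scored with pooled training mean/sd before fitting (raw abundances
#' span several orders of magnitude); the sign of p is chosen so the case
#' group projects to the *lower* scores.
#'
#' @param X_case,X_control numeric matrices (rows = participants, columns =
#'   the same ordered features), >= 2 rows each.
#' @param standardize z-score features using pooled training statistics
#'   (default `TRUE`).
#' @param ridge relative ridge added to the within-group covariance sum when
#'   it is numerically singular (epsilon = `ridge` x trace).
#' @param positive_label,negative_label group names carried into
#'   classifications.
#' @return object of class `fda_model` with elements `direction` (unit
#'   vector), `J`, `mean_scores`, `score_vars`, the standardization
#'   constants, and a `boundary`/`confidence` slot filled by
#'   [balance_confidence()] or [kde_boundary()].
#' @export
fda_fit <- function(X_case, X_control, standardize = TRUE, ridge = 1e-6,
                    positive_label = "ASD-M", negative_label = "TD-M") {
  X_case <- as.matrix(X_case); X_control <- as.matrix(X_control)
  if (nrow(X_case) < 2L || nrow(X_control) < 2L)
    stop("fda_fit needs at least 2 rows per group")
  if (ncol(X_case) != ncol(X_control)) stop("feature dimension mismatch")
  feats <- colnames(X_case)
  Xall <- rbind(X_case, X_control)
  const <- apply(Xall, 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(Xall)[const], collapse = ", "))
    X_case <- X_case[, !const, drop = FALSE]
    X_control <- X_control[, !const, drop = FALSE]
    Xall <- Xall[, !const, drop = FALSE]
    feats <- feats[!const]
  }
  if (ncol(Xall) == 0L) stop("no non-constant features left")
  std <- if (standardize) .standardizer(Xall) else
    list(center = rep(0, ncol(Xall)), scale = rep(1, ncol(Xall)))
  Z1 <- .apply_standardizer(X_case, std)
  Z2 <- .apply_standardizer(X_control, std)
  m1 <- colMeans(Z1); m2 <- colMeans(Z2)
  diff <- m1 - m2
  ridged <- FALSE
  if (sum(diff^2) == 0) {
    # degenerate: identical group means; any direction gives J = 0
    p <- c(1, rep(0, length(diff) - 1))
  } else {
    W <- stats::cov(Z1) + stats::cov(Z2)   # s1^2 + s2^2 structure
    w <- tryCatch(solve(W, diff), error = function(e) NULL)
    if (is.null(w)) {
      ridged <- TRUE
      W <- W + diag(ridge * sum(diag(W)), ncol(W))
      w <- tryCatch(solve(W, diff),
                    error = function(e)
                      stop("within-group covariance singular even with ridge ",
                           ridge, " x trace; increase ridge"))
    }
    p <- w / sqrt(sum(w^2))
  }
  t1 <- drop(Z1 %*% p); t2 <- drop(Z2 %*% p)
  if (mean(t1) > mean(t2)) { p <- -p; t1 <- -t1; t2 <- -t2 }
  s1 <- stats::var(t1); s2 <- stats::var(t2)
  J <- if (s1 + s2 > 0) (mean(t1) - mean(t2))^2 / (s1 + s2) else 0
  if (sum((m1 - m2)^2) == 0) J <- 0
  structure(list(direction = p, features = feats,
                 center = std$center, scale = std$scale,
                 mean_scores = c(case = mean(t1), control = mean(t2)),
                 score_vars = c(case = s1, control = s2),
                 J = J, ridged = ridged,
                 boundary = NULL, confidence = NULL,
                 positive_label = positive_label,
                 negative_label = negative_label),
            class = "fda_model")
}

#' Project observations onto a fitted discriminant direction
#'
#' @param model an `fda_model`.
#' @param X matrix (or vector) of raw feature values in training feature
#'   order.
#' @return numeric vector of scores.
#' @export
fda_scores <- function(model, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (!is.null(colnames(X)) && all(model$features %in% colnames(X)))
    X <- X[, model$features, drop = FALSE]
  if (ncol(X) != length(model$direction))
    stop("feature dimension mismatch: model has ", length(model$direction),
         ", input has ", ncol(X))
  Z <- .apply_standardizer(X, list(center = model$center, scale = model$scale))
  drop(Z %*% model$direction)
}

# KDE of the case scores; returns a quantile function confidence -> threshold
# (computed once, cheap to evaluate on a grid of confidence levels)
.kde_quantile_fun <- function(case_scores, n_grid = 2048) {
  if (length(unique(case_scores)) == 1L) {
    v <- case_scores[1L]
    return(function(conf) rep(v, length(conf)))
  }
  bw <- stats::bw.nrd0(case_scores)
  d <- stats::density(case_scores, bw = bw, n = n_grid,
                      from = min(case_scores) - 4 * bw,
                      to = max(case_scores) + 4 * bw)
  dx <- d$x[2L] - d$x[1L]
  cdf <- cumsum(d$y) * dx
  cdf <- cdf / cdf[length(cdf)]
  # make the cdf strictly increasing for interpolation
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approxfun(cdf[keep], d$x[keep], rule = 2)   # vectorized in conf
}

#' Kernel-density decision boundary on discriminant scores
#'
#' Gaussian-kernel density (Silverman's rule-of-thumb bandwidth) of the
#' positive-group scores, evaluated on a 2048-point grid spanning four
#' bandwidths beyond the data range; the boundary is the score at which the
#' cumulative KDE mass equals the one-sided confidence level. Cases sit on
#' the low-score side, so a score <= boundary is labelled positive.
#'
#' @param case_scores numeric vector of >= 5 positive-group scores (a
#'   degenerate all-equal vector returns that value).
#' @param confidence one-sided level in `[0.5, 1)`.
#' @param n_grid grid resolution (default 2048).
#' @return scalar threshold.
#' @export
kde_boundary <- function(case_scores, confidence, n_grid = 2048) {
  if (length(case_scores) < 5L && length(unique(case_scores)) > 1L)
    stop("kde_boundary needs at least 5 scores")
  if (confidence < 0.5 || confidence >= 1)
    stop("confidence must be in [0.5, 1)")
  .kde_quantile_fun(case_scores, n_grid)(confidence)
}

#' Choose the boundary confidence level balancing type I/II error
#'
#' Grid search over one-sided confidence levels 0.50, 0.51, ..., 0.99. For
#' each level the KDE boundary on the training case scores is computed and
#' training type I (controls labelled positive) and type II (cases labelled
#' negative) errors are evaluated; the chosen level minimizes
#' |typeI - typeII|, ties broken toward the smaller total error, then the
#' smaller confidence.
#'
#' @param model a fitted `fda_model`.
#' @param X_case,X_control raw training matrices (same feature order as the
#'   fit).
#' @param grid confidence levels to search.
#' @return the model with `boundary`, `confidence`, `train_type1`,
#'   `train_type2` filled in.
#' @export
balance_confidence <- function(model, X_case, X_control,
                               grid = seq(0.50, 0.99, by = 0.01)) {
  t1s <- fda_scores(model, X_case)
  t2s <- fda_scores(model, X_control)
  qf <- .kde_quantile_fun(t1s)
  thr <- qf(grid)
  # counts of scores <= threshold, vectorized over the confidence grid
  typeI <- findInterval(thr, sort(t2s)) / length(t2s)       # controls -> positive
  typeII <- 1 - findInterval(thr, sort(t1s)) / length(t1s)  # cases -> negative
  # min |typeI - typeII|; ties -> smaller total error, then smaller confidence
  pick <- order(round(abs(typeI - typeII), 12), round(typeI + typeII, 12),
                grid)[1L]
  model$confidence <- grid[pick]
  model$boundary <- thr[pick]
  model$train_type1 <- typeI[pick]
  model$train_type2 <- typeII[pick]
  model
}

#' Fit a (ridge-stabilized) logistic regression classifier
#'
#' Maximum-likelihood logistic regression of case membership on the given
#' features (z-scored with pooled training statistics). Under complete or
#' quasi-complete separation the ML estimate diverges; the fit then falls
#' back to a small ridge penalty (`ridge` on the squared slope norm,
#' intercept unpenalized) and the model is flagged `separable`.
#'
#' @param X numeric matrix (rows = participants) of continuous and/or 0/1
#'   binary features.
#' @param labels factor (first level = positive/case class) or logical
#'   vector of case membership.
#' @param ridge penalty used on separation fallback (default 1e-4).
#' @param standardize z-score features (default `TRUE`; binary features are
#'   standardized too, which only rescales their coefficients).
#' @return object of class `logistic_model`.
#' @export
logistic_fit <- function(X, labels, ridge = 1e-4, standardize = TRUE) {
  X <- as.matrix(X)
  if (is.logical(labels)) {
    y <- as.numeric(labels)
    pos <- "case"; neg <- "control"
  } else {
    labels <- as.factor(labels)
    if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
    y <- as.numeric(labels == levels(labels)[1L])
    pos <- levels(labels)[1L]; neg <- levels(labels)[2L]
  }
  if (sum(y) < 2L || sum(1 - y) < 2L)
    stop("logistic_fit needs at least 2 participants per group")
  feats <- colnames(X)
  if (is.null(feats)) feats <- paste0("V", seq_len(ncol(X)))
  const <- apply(X, 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant feature(s): ", paste(feats[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
    feats <- feats[!const]
  }
  std <- if (standardize && ncol(X) > 0) .standardizer(X) else
    list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  Z <- if (ncol(X) > 0) .apply_standardizer(X, std) else X
  separable <- FALSE
  fit_ok <- TRUE
  withCallingHandlers(
    gfit <- stats::glm.fit(cbind(1, Z), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w)))
        separable <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- gfit$coefficients
  if (anyNA(beta)) separable <- TRUE
  if (separable) {
    beta <- .ridge_logistic(cbind(1, Z), y, ridge)
    if (anyNA(beta)) stop("ridge-penalized logistic fit failed to converge")
  }
  names(beta) <- c("(Intercept)", feats)
  structure(list(coefficients = beta, features = feats,
                 center = std$center, scale = std$scale,
                 separable = separable,
                 positive_label = pos, negative_label = neg),
            class = "logistic_model")
}

# Newton-Raphson IRLS for the ridge-penalized logistic log-likelihood
# (penalty lambda/2 * ||beta_slopes||^2; intercept unpenalized)
.ridge_logistic <- function(X1, y, lambda, maxit = 200, tol = 1e-10) {
  p <- ncol(X1)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X1, y - mu)) - pen %*% beta
    H <- crossprod(X1 * w, X1) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) return(rep(NA_real_, p))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Predicted case probability from a logistic model
#'
#' @param model a `logistic_model`.
#' @param X matrix (or vector) of raw feature values in training feature
#'   order.
#' @return numeric vector of probabilities of the positive class.
#' @export
logistic_prob <- function(model, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (!is.null(colnames(X)) && all(model$features %in% colnames(X)))
    X <- X[, model$features, drop = FALSE]
  if (ncol(X) != length(model$features))
    stop("feature dimension mismatch: model has ", length(model$features),
         ", input has ", ncol(X))
  Z <- .apply_standardizer(X, list(center = model$center, scale = model$scale))
  drop(stats::plogis(cbind(1, Z) %*% model$coefficients))
}

#' Classify observations with a fitted model
#'
#' FDA: a score less than or equal to the boundary is labelled positive
#' (case). Logistic: the label is the class with the higher predicted
#' probability; a probability of exactly 0.5 goes to the negative class
#' (strict argmax for the positive class).
#'
#' @param model an `fda_model` (with boundary set) or `logistic_model`.
#' @param X raw feature matrix or single feature vector.
#' @return data frame with columns `label` and `score` (FDA projection
#'   coordinate or positive-class probability).
#' @export
classify <- function(model, X) UseMethod("classify")

#' @export
classify.fda_model <- function(model, X) {
  if (is.null(model$boundary))
    stop("model has no decision boundary; run balance_confidence() or set ",
         "one with kde_boundary()")
  s <- fda_scores(model, X)
  data.frame(label = ifelse(s <= model$boundary, model$positive_label,
                            model$negative_label),
             score = s, stringsAsFactors = FALSE)
}

#' @export
classify.logistic_model <- function(model, X) {
  pr <- logistic_prob(model, X)
  data.frame(label = ifelse(pr > 0.5, model$positive_label,
                            model$negative_label),
             score = pr, stringsAsFactors = FALSE)
}

#' @export
print.fda_model <- function(x, ...) {
  cat("<fda_model> ", length(x$direction), " features, J = ",
      signif(x$J, 4), "\n", sep = "")
  if (!is.null(x$boundary))
    cat("  boundary ", signif(x$boundary, 4), " at one-sided confidence ",
        x$confidence, "\n", sep = "")
  invisible(x)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("<logistic_model> ", length(x$features), " features",
      if (x$separable) " (ridge fallback: separable data)", "\n", sep = "")
  invisible(x)
}

#' Export a fitted model to JSON
#'
#' Serializes direction/coefficients, standardization constants and the
#' decision boundary so a fitted model can be reloaded elsewhere.
#'
#' @param model an `fda_model` or `logistic_model`.
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
export_model <- function(model, path) {
  obj <- unclass(model)
  obj$model_class <- class(model)[1L]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Import a model exported with [export_model()]
#'
#' @param path JSON file written by [export_model()].
#' @return the restored model object.
#' @export
import_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$model_class
  obj$model_class <- NULL
  for (nm in c("direction", "center", "scale", "coefficients",
               "mean_scores", "score_vars"))
    if (!is.null(obj[[nm]])) obj[[nm]] <- unlist(obj[[nm]])
  structure(obj, class = cls)
}
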