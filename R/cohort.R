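#' @keywords internal
"_PACKAGE"

.PANELS <- c("focm_ts", "nutritional", "mthfr_binary", "metabolon", "diet", "symptom")
.KINDS <- c("continuous", "binary", "ordinal")

#' Feature metadata table
#'
#' Builds the per-feature metadata data frame used by [cohort_matrix()].
#' `panel` records which assay block a feature belongs to (targeted FOCM/TS
#' pathway panel, nutritional markers, MTHFR genotype indicators, broad
#' metabolomics, diet or symptom variables) and drives the assembly of the
#' nested classification subsets i-iv. `confirmed_standard = FALSE` marks
#' semi-quantitative identifications not confirmed against a chemical
#' standard.
#'
#' @param name character vector of unique feature names.
#' @param panel one of `"focm_ts"`, `"nutritional"`, `"mthfr_binary"`,
#'   `"metabolon"`, `"diet"`, `"symptom"` (recycled).
#' @param kind `"continuous"`, `"binary"` or `"ordinal"` (recycled).
#' @param confirmed_standard logical (recycled).
#' @return data frame with columns `name`, `panel`, `kind`,
#'   `confirmed_standard`.
#' @export
feature_meta <- function(name, panel = "metabolon", kind = "continuous",
                         confirmed_standard = TRUE) {
  name <- as.character(name)
  if (anyDuplicated(name))
    stop("duplicate feature name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  panel <- match.arg(rep_len(as.character(panel), length(name)),
                     .PANELS, several.ok = TRUE)
  kind <- match.arg(rep_len(as.character(kind), length(name)),
                    .KINDS, several.ok = TRUE)
  data.frame(name = name,
             panel = rep_len(panel, length(name)),
             kind = rep_len(kind, length(name)),
             confirmed_standard = rep_len(as.logical(confirmed_standard),
                                          length(name)),
             stringsAsFactors = FALSE)
}

#' Participants-by-features cohort container
#'
#' The central data structure: a numeric abundance matrix (participants in
#' rows, features in columns), a two-level group factor, per-feature
#' metadata, and a logical mask of cells that were below the detection
#' limit. Censored cells hold `NA` until [impute_below_detection()] is
#' applied; `NA` cells that are *not* censored represent measurements that
#' were never collected (missing data).
#'
#' @param values numeric matrix, participants x features; non-negative where
#'   observed.
#' @param groups factor (or character coercible to factor) of length
#'   `nrow(values)` with exactly two levels; the first level is the positive
#'   (case) class.
#' @param features feature metadata as from [feature_meta()]; row order must
#'   match the columns of `values`.
#' @param participants optional character IDs (default taken from rownames).
#' @param censored logical matrix, same shape as `values`; `TRUE` marks
#'   below-detection-limit cells.
#' @param case_label which group level is the case/positive class
#'   (default: first level of `groups`).
#' @return an object of class `cohort_matrix`.
#' @export
cohort_matrix <- function(values, groups, features, participants = NULL,
                          censored = NULL, case_label = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  groups <- as.factor(groups)
  if (is.null(case_label)) case_label <- levels(groups)[1L]
  if (!case_label %in% levels(groups))
    stop("case_label '", case_label, "' is not a group level")
  groups <- stats::relevel(groups, ref = case_label)
  if (nlevels(groups) != 2L)
    stop("groups must have exactly two levels, got ", nlevels(groups))
  if (anyNA(groups)) stop("missing group label for at least one participant")
  if (length(groups) != nrow(values))
    stop("row count (", nrow(values), ") != number of group labels (",
         length(groups), ")")
  if (!is.data.frame(features) ||
      !all(c("name", "panel", "kind", "confirmed_standard") %in% names(features)))
    stop("features must be a data frame as produced by feature_meta()")
  if (nrow(features) != ncol(values))
    stop("column count (", ncol(values), ") != number of feature rows (",
         nrow(features), ")")
  if (anyDuplicated(features$name))
    stop("duplicate feature name(s): ",
         paste(unique(features$name[duplicated(features$name)]), collapse = ", "))
  if (is.null(participants)) {
    participants <- rownames(values)
    if (is.null(participants)) participants <- sprintf("S%03d", seq_len(nrow(values)))
  }
  if (is.null(censored)) {
    censored <- matrix(FALSE, nrow(values), ncol(values))
  } else {
    censored <- as.matrix(censored)
    if (!identical(dim(censored), dim(values)))
      stop("censored mask shape does not match values")
    storage.mode(censored) <- "logical"
    censored[is.na(censored)] <- FALSE
  }
  if (any(values < 0, na.rm = TRUE))
    stop("abundance values must be non-negative")
  dimnames(values) <- list(participants, features$name)
  dimnames(censored) <- dimnames(values)
  structure(list(values = values, censored = censored, groups = groups,
                 features = features, participants = as.character(participants)),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat("<cohort_matrix> ", nrow(x$values), " participants x ",
      ncol(x$values), " features\n", sep = "")
  cat("  groups: ", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = " vs "),
      "  [case = ", levels(x$groups)[1L], "]\n", sep = "")
  cat("  panels: ", paste(sprintf("%s:%d", names(table(x$features$panel)),
                                  table(x$features$panel)), collapse = " "), "\n",
      sep = "")
  ncen <- sum(x$censored)
  if (ncen > 0)
    cat("  ", ncen, " below-detection-limit cells (",
        if (anyNA(x$values[x$censored])) "not yet imputed" else "imputed",
        ")\n", sep = "")
  invisible(x)
}

# case (positive) group mask
case_mask <- function(m) m$groups == levels(m$groups)[1L]

#' Split one feature into case and control samples
#'
#' @param m a [cohort_matrix()].
#' @param feature feature name.
#' @param drop_na drop missing cells (pairwise-complete behaviour).
#' @return list with numeric vectors `case` and `control`.
#' @export
feature_samples <- function(m, feature, drop_na = TRUE) {
  v <- m$values[, feature]
  cm <- case_mask(m)
  x <- v[cm]; y <- v[!cm]
  if (drop_na) { x <- x[!is.na(x)]; y <- y[!is.na(y)] }
  list(case = x, control = y)
}

#' Read a cohort from wide CSV files
#'
#' Expects a wide table with one row per participant: an ID column, a group
#' column, and one column per feature; plus a feature-metadata CSV with
#' columns `name`, `panel`, `kind`, `confirmed_standard`. Continuous cells
#' equal to a censoring token (default `"BDL"` or the empty string) are
#' recorded in the censored mask and set to `NA` pending imputation.
#'
#' @param path cohort CSV path.
#' @param metadata_path feature metadata CSV path.
#' @param group_col name of the group column (default `"group"`).
#' @param id_col name of the participant ID column (default `"participant"`).
#' @param censor_tokens character tokens marking below-detection-limit cells.
#' @param case_label case/positive group label (default `"ASD-M"` when
#'   present, otherwise the first level).
#' @return a [cohort_matrix()].
#' @export
read_cohort <- function(path, metadata_path, group_col = "group",
                        id_col = "participant",
                        censor_tokens = c("BDL", ""),
                        case_label = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  meta <- utils::read.csv(metadata_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("name", "panel", "kind", "confirmed_standard")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  meta <- feature_meta(meta$name, meta$panel, meta$kind,
                       as.logical(meta$confirmed_standard))
  if (!group_col %in% names(raw))
    stop("group column '", group_col, "' not found in ", path)
  if (!id_col %in% names(raw))
    stop("participant ID column '", id_col, "' not found in ", path)
  grp <- raw[[group_col]]
  if (any(is.na(grp) | grp == ""))
    stop("missing group label for participant(s): ",
         paste(raw[[id_col]][is.na(grp) | grp == ""], collapse = ", "))
  missing_feats <- setdiff(meta$name, names(raw))
  if (length(missing_feats))
    stop("features in metadata but absent from cohort file: ",
         paste(missing_feats, collapse = ", "))
  n <- nrow(raw)
  vals <- matrix(NA_real_, n, nrow(meta))
  cen <- matrix(FALSE, n, nrow(meta))
  for (j in seq_len(nrow(meta))) {
    cell <- raw[[meta$name[j]]]
    is_cen <- !is.na(cell) & cell %in% censor_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_cen & !is.na(cell) & cell != "NA" & is.na(num)
    if (any(bad))
      stop("non-numeric value '", cell[bad][1L], "' in feature '",
           meta$name[j], "' (not a recognised censoring token)")
    num[is_cen] <- NA_real_
    vals[, j] <- num
    cen[, j] <- is_cen
  }
  if (is.null(case_label))
    case_label <- if ("ASD-M" %in% grp) "ASD-M" else sort(unique(grp))[1L]
  cohort_matrix(vals, grp, meta, participants = raw[[id_col]],
                censored = cen, case_label = case_label)
}

#' Write a cohort to wide CSV files
#'
#' Inverse of [read_cohort()]: censored cells are written as the token
#' (default `"BDL"`), missing cells as empty `NA`.
#'
#' @param m a [cohort_matrix()].
#' @param path cohort CSV path.
#' @param metadata_path feature metadata CSV path.
#' @param censor_token token to write for censored cells.
#' @return invisibly, `path`.
#' @export
write_cohort <- function(m, path, metadata_path, censor_token = "BDL") {
  vals <- m$values
  out <- as.data.frame(vals, check.names = FALSE)
  # format() would pad; keep plain decimal representation
  for (j in seq_along(out)) {
    col <- as.character(vals[, j])
    col[m$censored[, j]] <- censor_token
    out[[j]] <- col
  }
  out <- cbind(participant = m$participants,
               group = as.character(m$groups), out,
               stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  utils::write.csv(m$features, metadata_path, row.names = FALSE)
  invisible(path)
}

#' Impute below-detection-limit cells
#'
#' For every feature with censored cells, each censored cell is replaced by
#' the minimum of that feature's uncensored values divided by sqrt(2) — the
#' conventional left-censoring fill-in for semi-quantitative metabolomics
#' intensities. Uncensored cells are untouched; the censored mask is kept so
#' the operation is idempotent.
#'
#' @param m a [cohort_matrix()].
#' @return the cohort with all censored cells filled in.
#' @export
impute_below_detection <- function(m) {
  stopifnot(inherits(m, "cohort_matrix"))
  for (j in seq_len(ncol(m$values))) {
    cen <- m$censored[, j]
    if (!any(cen)) next
    unc <- m$values[!cen, j]
    unc <- unc[!is.na(unc)]
    if (!length(unc))
      stop("feature '", m$features$name[j],
           "' is entirely censored; cannot impute a detection limit")
    m$values[cen, j] <- min(unc) / sqrt(2)
  }
  m
}

#' Assemble a nested classification subset
#'
#' Subsets follow the study layout: (i) the targeted FOCM/TS pathway panel;
#' (ii) i plus the nutritional markers; (iii) ii plus the binary MTHFR
#' genotype indicators; (iv) iii plus the top `top_n` broad-metabolomics
#' features ranked by univariate AUC (descending, ties broken by feature
#' name ascending). Features with missing (never-collected) cells are
#' dropped from classification subsets. The union for iv is deduplicated by
#' name; pass `expected_size` to assert the resulting count (e.g. 76 for
#' the original study layout, where one marker is shared between blocks).
#'
#' @param m a [cohort_matrix()].
#' @param id subset id: `"i"`, `"ii"`, `"iii"` or `"iv"`.
#' @param auc named numeric vector of per-feature AUC values (required for
#'   `id = "iv"`; must cover all metabolon-panel features).
#' @param top_n number of top-AUC broad-metabolomics features for subset iv.
#' @param expected_size optional integer; error if the final subset size
#'   differs.
#' @param drop_incomplete drop features with missing (non-censored `NA`)
#'   cells.
#' @return object of class `subset_spec`: list with `id` and
#'   `feature_names`.
#' @export
build_subset <- function(m, id = c("i", "ii", "iii", "iv"), auc = NULL,
                         top_n = 50L, expected_size = NULL,
                         drop_incomplete = TRUE) {
  id <- match.arg(id)
  f <- m$features
  focm <- f$name[f$panel == "focm_ts"]
  nutr <- f$name[f$panel == "nutritional"]
  mthfr <- f$name[f$panel == "mthfr_binary"]
  feats <- switch(id,
                  i = focm,
                  ii = c(focm, nutr),
                  iii = c(focm, nutr, mthfr),
                  iv = {
                    met <- f$name[f$panel == "metabolon"]
                    if (length(met) < top_n)
                      stop("subset iv needs at least ", top_n,
                           " metabolon features; cohort has ", length(met))
                    if (is.null(auc))
                      stop("subset iv requires per-feature AUC values")
                    if (!all(met %in% names(auc)))
                      stop("auc table does not cover all metabolon features")
                    a <- auc[met]
                    ord <- order(-a, met)
                    c(focm, nutr, mthfr, met[ord][seq_len(top_n)])
                  })
  feats <- unique(feats)
  if (drop_incomplete) {
    miss <- vapply(feats, function(nm) {
      j <- match(nm, f$name)
      any(is.na(m$values[, j]) & !m$censored[, j])
    }, logical(1))
    feats <- feats[!miss]
  }
  if (!is.null(expected_size) && length(feats) != expected_size)
    stop("subset ", id, " has ", length(feats), " features; expected ",
         expected_size)
  structure(list(id = id, feature_names = feats), class = "subset_spec")
}

#' @export
print.subset_spec <- function(x, ...) {
  cat("<subset_spec ", x$id, "> ", length(x$feature_names), " features\n",
      sep = "")
  invisible(x)
}
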