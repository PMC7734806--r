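#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis. Round-trips
#' losslessly through its JSON file representation
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param alpha univariate significance level (default 0.05).
#' @param fdr_threshold leave-k-out robustness threshold (default 0.1).
#' @param depths leave-out sizes for the resampling score (default
#'   `c(1, 2)`; `NULL` disables resampling).
#' @param subsets which classification subsets to search (default all of
#'   i-iv).
#' @param sizes panel sizes to search (default `2:5`).
#' @param classifier_map classifier per subset (default: FDA for i-ii,
#'   logistic for iii-iv).
#' @param strategy_map search strategy per subset (default: exhaustive for
#'   i-iii, beam for iv).
#' @param budget exhaustive-search budget (combinations).
#' @param beam_width beam width (default 50).
#' @param top_n_auc broad-metabolomics features entering subset iv
#'   (default 50).
#' @param expected_iv_size optional assertion on |subset iv|.
#' @param seed integer seed for any stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, fdr_threshold = 0.1, depths = c(1, 2),
                       subsets = c("i", "ii", "iii", "iv"), sizes = 2:5,
                       classifier_map = c(i = "fda", ii = "fda",
                                          iii = "logistic", iv = "logistic"),
                       strategy_map = c(i = "exhaustive", ii = "exhaustive",
                                        iii = "exhaustive", iv = "beam"),
                       budget = 20000, beam_width = 50, top_n_auc = 50,
                       expected_iv_size = NULL, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("fdr_threshold must be in (0, 1)")
  subsets <- match.arg(subsets, c("i", "ii", "iii", "iv"), several.ok = TRUE)
  structure(list(alpha = alpha, fdr_threshold = fdr_threshold,
                 depths = if (is.null(depths)) NULL else as.integer(depths),
                 subsets = subsets, sizes = as.integer(sizes),
                 classifier_map = classifier_map,
                 strategy_map = strategy_map,
                 budget = as.integer(budget),
                 beam_width = as.integer(beam_width),
                 top_n_auc = as.integer(top_n_auc),
                 expected_iv_size = expected_iv_size,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write a run configuration to JSON
#' @param cfg a [run_config()].
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  obj <- unclass(cfg)
  # named vectors must go out as JSON objects, not bare arrays
  obj$classifier_map <- as.list(obj$classifier_map)
  obj$strategy_map <- as.list(obj$strategy_map)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path JSON path written by [write_run_config()].
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$classifier_map <- unlist(obj$classifier_map)
  obj$strategy_map <- unlist(obj$strategy_map)
  do.call(run_config, obj)
}

.write_screen_csv <- function(screen, path) {
  utils::write.csv(as.data.frame(screen), path, row.names = FALSE)
}

.ranking_to_df <- function(rk) {
  data.frame(features = vapply(rk$features, paste, "", collapse = " + "),
             size = rk$size, type1 = rk$type1, type2 = rk$type2,
             total = rk$total, sensitivity = rk$sensitivity,
             specificity = rk$specificity, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes, in order: below-detection-limit imputation, the univariate
#' screen, assembly of the nested classification subsets (subset iv takes
#' the top-AUC broad metabolites from the screen), cross-validated panel
#' search per subset, and the correlation-cluster decomposition around the
#' best panel of the last searched subset. All stage tables are written as
#' CSV under `out_dir` together with a JSON manifest (package version,
#' seed, config, stage files and their md5 digests). Deterministic: the
#' seed fixes every output byte.
#'
#' @param cfg a [run_config()].
#' @param cohort a [cohort_matrix()] (censored cells may be unimputed).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_all <- function(cfg, cohort, out_dir) {
  stopifnot(inherits(cfg, "run_config"), inherits(cohort, "cohort_matrix"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stage <- "impute"
  files <- character(0)
  res <- tryCatch({
    m <- impute_below_detection(cohort)

    stage <- "screen"
    screen <- run_screen(m, alpha = cfg$alpha,
                         fdr_threshold = cfg$fdr_threshold,
                         depths = cfg$depths)
    f <- file.path(out_dir, "screen.csv")
    .write_screen_csv(screen, f); files <- c(files, f)

    stage <- "subsets"
    auc <- stats::setNames(screen$auc, screen$feature)
    specs <- list()
    for (id in cfg$subsets) {
      specs[[id]] <- build_subset(
        m, id, auc = auc, top_n = cfg$top_n_auc,
        expected_size = if (id == "iv") cfg$expected_iv_size else NULL)
    }
    f <- file.path(out_dir, "subsets.json")
    jsonlite::write_json(lapply(specs, function(s) s$feature_names), f,
                         auto_unbox = FALSE)
    files <- c(files, f)

    stage <- "panel_search"
    rankings <- list()
    for (id in cfg$subsets) {
      rk <- search_panels(m, specs[[id]], sizes = cfg$sizes,
                          classifier = cfg$classifier_map[[id]],
                          strategy = cfg$strategy_map[[id]],
                          budget = cfg$budget, beam_width = cfg$beam_width)
      rankings[[id]] <- rk
      f <- file.path(out_dir, paste0("panels_", id, ".csv"))
      utils::write.csv(.ranking_to_df(rk), f, row.names = FALSE)
      files <- c(files, f)
    }
    last <- cfg$subsets[length(cfg$subsets)]
    best <- rankings[[last]]$features[[1L]]
    best_eval <- loocv_evaluate(m, best, cfg$classifier_map[[last]])
    f <- file.path(out_dir, "best_panel_per_sample.csv")
    utils::write.csv(cbind(data.frame(
      panel = paste(best, collapse = " + "),
      classifier = cfg$classifier_map[[last]]), best_eval$per_sample),
      f, row.names = FALSE)
    files <- c(files, f)

    stage <- "correlation"
    candidates <- if ("iv" %in% names(specs)) {
      kinds <- cohort$features$kind[match(specs[["iv"]]$feature_names,
                                          cohort$features$name)]
      specs[["iv"]]$feature_names[kinds == "continuous"]
    } else NULL
    clusters <- suppressWarnings(
      correlate_with_cores(m, cores = best, candidates = candidates,
                           p_threshold = cfg$alpha))
    orphans <- find_orphans(m, screen, clusters)
    mem <- do.call(rbind, lapply(clusters$clusters, function(cl)
      if (nrow(cl$members)) cbind(core = cl$core, cl$members) else NULL))
    if (is.null(mem))
      mem <- data.frame(core = character(0), feature = character(0),
                        r = numeric(0), p = numeric(0))
    f <- file.path(out_dir, "correlation_members.csv")
    utils::write.csv(mem, f, row.names = FALSE); files <- c(files, f)
    f <- file.path(out_dir, "correlation_cores.csv")
    utils::write.csv(clusters$core_cor, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "orphans.json")
    jsonlite::write_json(list(orphans = orphans$orphans,
                              pairwise = orphans$pairwise), f,
                         auto_unbox = FALSE, digits = NA)
    files <- c(files, f)
    list(screen = screen, subsets = specs, rankings = rankings,
         best_panel = best, best_eval = best_eval,
         clusters = clusters, orphans = orphans)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest <- list(package = "metpanel",
                   version = as.character(utils::packageVersion("metpanel")),
                   seed = cfg$seed,
                   config = unclass(cfg),
                   stages = c("impute", "screen", "subsets", "panel_search",
                              "correlation"),
                   outputs = files,
                   md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(res, list(manifest = manifest)))
}
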