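# Repeated-holdout validation driver: split -> train extractor -> extract
# features -> build graph -> train GCN -> evaluate, once per repeat.

#' Run repeated-holdout cross-validation of the full pipeline
#'
#' For every split repeat in the dataset: trains the extractor on the
#' training partition, extracts features for all segments, builds the
#' feature graph (training partition only by default, avoiding test
#' leakage), trains the GCN on training features and evaluates on the held
#' out segments.
#'
#' @param ds a [segment_dataset()] with splits from [make_splits()].
#' @param extractor_cfg an [extractor_config()].
#' @param gcn_cfg a [gcn_config()].
#' @param graph_data `"train"` (default) or `"all"`: which rows feed the
#'   Pearson matrix. `"all"` replicates protocols that estimate the graph
#'   from the overall data, at the cost of information leaking from the
#'   test partition into the graph.
#' @param repeats which split columns to run (default all).
#' @param verbose print stage progress.
#' @return list with `reports` (one [evaluate_predictions()] result per
#'   repeat) and `summary` (median and quartiles of each metric across
#'   repeats, quartiles by linear interpolation).
#' @export
run_crossval <- function(ds, extractor_cfg, gcn_cfg,
                         graph_data = c("train", "all"),
                         repeats = NULL, verbose = FALSE) {
  graph_data <- match.arg(graph_data)
  if (is.null(ds$splits)) stop("dataset has no splits; call make_splits() first")
  if (is.null(repeats)) repeats <- seq_len(ncol(ds$splits))
  reports <- vector("list", length(repeats))
  for (ri in seq_along(repeats)) {
    r <- repeats[ri]
    res <- tryCatch(
      run_single_fold(ds, extractor_cfg, gcn_cfg, graph_data, r, verbose),
      error = function(e) stop("repeat ", r, " failed: ", conditionMessage(e),
                               call. = FALSE))
    reports[[ri]] <- res$report
  }
  list(reports = reports, summary = crossval_summary(reports))
}

run_single_fold <- function(ds, extractor_cfg, gcn_cfg, graph_data,
                            repeat_id, verbose = FALSE) {
  train_idx <- which(ds$splits[, repeat_id] == "train")
  test_idx <- which(ds$splits[, repeat_id] == "test")
  if (verbose) message("repeat ", repeat_id, ": training extractor on ",
                       length(train_idx), " segments")
  extractor <- train_extractor(ds, extractor_cfg, train_idx,
                               verbose = verbose)
  ft <- extract_features(ds, extractor)
  graph_rows <- if (graph_data == "train") train_idx else
    seq_len(nrow(ft$features))
  graph <- build_feature_graph(ft$features[graph_rows, , drop = FALSE])
  if (verbose) message("repeat ", repeat_id, ": training GCN")
  gcn <- train_gcn(ft, graph, gcn_cfg, train_idx = train_idx,
                   verbose = verbose)
  probs <- gcn_forward(gcn, ft$features[test_idx, , drop = FALSE])
  report <- evaluate_predictions(ft$labels[test_idx],
                                 max.col(probs) - 1L, probs)
  list(report = report, extractor = extractor, gcn = gcn, graph = graph,
       features = ft, train_idx = train_idx, test_idx = test_idx)
}

crossval_summary <- function(reports) {
  metrics <- c("gaa", "kappa", "precision", "recall", "f1", "auc")
  rows <- lapply(metrics, function(m) {
    v <- vapply(reports, function(r) {
      x <- r[[m]]
      if (is.null(x)) NA_real_ else x
    }, numeric(1))
    data.frame(metric = m,
               median = stats::median(v, na.rm = TRUE),
               q1 = unname(stats::quantile(v, 0.25, na.rm = TRUE)),
               q3 = unname(stats::quantile(v, 0.75, na.rm = TRUE)),
               min = suppressWarnings(min(v, na.rm = TRUE)),
               max = suppressWarnings(max(v, na.rm = TRUE)))
  })
  do.call(rbind, rows)
}
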