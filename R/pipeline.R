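# End-to-end pipeline -----------------------------------------------------
#
# preprocess -> clustering forest -> proximity -> Ward -> cut(k) ->
# assignment model -> per covariate mode: base models + NNLS stacking ->
# evaluation on the held-out test split. Test patients never reach filter
# statistics, forest fitting, clustering, assignment fitting, CV folds or
# NNLS; they are only scored at the end.

# Per-stage seeds derived from the master seed, kept below 2^31.
stage_seed <- function(master, stage) {
  (as.integer(master) %% 100000L) * 7919L + stage * 104729L
}

#' Pipeline configuration
#'
#' @param cohort either a `cohort` (pre-generated data) or a
#'   [cohort_config()] simulate block, in which case the generator seed is
#'   derived from `seed`.
#' @param k_clusters number of patient clusters (2-4).
#' @param top_k features used by the assignment model.
#' @param covariate_modes subset of `"clinical"`, `"clinical+ajcc"`,
#'   `"clinical+clusters"`, `"clinical+rsf_top_N"` (N an integer),
#'   `"clinical+cox"`.
#' @param horizon evaluation horizon in months (default 60).
#' @param n_folds stacking CV folds.
#' @param n_trees trees in the clustering forest.
#' @param min_node_size terminal-node size of the clustering forest.
#' @param ward_dialect `"ward.D"` or `"ward.D2"` (see [ward_agglomerate()]).
#' @param n_trees_rsf,n_trees_rf base-model forest sizes.
#' @param seed master seed; every stage draws a seed derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            k_clusters = 2, top_k = 10,
                            covariate_modes = c("clinical",
                                                "clinical+clusters"),
                            horizon = 60, n_folds = 5,
                            n_trees = 1000, min_node_size = 5,
                            ward_dialect = "ward.D",
                            n_trees_rsf = 1000, n_trees_rf = 500,
                            seed = 1L) {
  stopifnot(k_clusters %in% 2:4,
            inherits(cohort, "cohort") || inherits(cohort, "cohort_config"))
  structure(list(cohort = cohort, k_clusters = as.integer(k_clusters),
                 top_k = as.integer(top_k),
                 covariate_modes = covariate_modes,
                 horizon = horizon, n_folds = as.integer(n_folds),
                 n_trees = as.integer(n_trees),
                 min_node_size = as.integer(min_node_size),
                 ward_dialect = ward_dialect,
                 n_trees_rsf = as.integer(n_trees_rsf),
                 n_trees_rf = as.integer(n_trees_rf),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

parse_mode <- function(mode) {
  if (mode == "clinical") return(list(type = "clinical"))
  if (mode == "clinical+ajcc") return(list(type = "ajcc"))
  if (mode == "clinical+clusters") return(list(type = "clusters"))
  m <- regmatches(mode, regexec("^clinical\\+rsf_top_([0-9]+)$", mode))[[1]]
  if (length(m)) return(list(type = "rsf", n = as.integer(m[2])))
  if (mode == "clinical+cox") return(list(type = "cox"))
  stop("unknown covariate mode: ", mode)
}

#' Run the full stratification pipeline
#'
#' Executes feature filtering, survival-forest proximity clustering,
#' test-set cluster assignment, and stacked-ensemble fitting/evaluation for
#' each requested covariate mode. Every random stage is seeded from the
#' master seed, so a rerun with the same configuration is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for artifacts (filter report,
#'   proximity matrix, dendrogram, cluster labels, assignment model, KM
#'   tables, metrics report).
#' @param verbose emit per-stage progress messages.
#' @return list of class `pipeline_report`: filter summary, cluster sizes,
#'   log-rank stratification tests, per-mode metrics (C-index and horizon
#'   AUC, train and test) and stacking weights.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  cohort <- config$cohort
  if (inherits(cohort, "cohort_config")) {
    cohort$seed <- stage_seed(config$seed, 1L)
    cohort <- generate_cohort(cohort)
  }
  if (is.null(cohort$split))
    stop("cohort has no train/test split; run split_cohort() first")
  train_mask <- cohort$split == "train"
  tr <- cohort_data(cohort, "train")
  te <- cohort_data(cohort, "test")
  say("cohort: %d train / %d test, %.1f%% events",
      nrow(tr$features), nrow(te$features), 100 * mean(cohort$event))

  filt <- filter_features(cohort$features, train_mask)
  say("filter: %d -> %d features", filt$report$n_input, filt$report$n_output)
  x_tr <- filt$features[train_mask, , drop = FALSE]
  x_te <- filt$features[!train_mask, , drop = FALSE]

  forest <- fit_survival_forest(x_tr, tr$time_months, tr$event,
                                n_trees = config$n_trees,
                                min_node_size = config$min_node_size,
                                seed = stage_seed(config$seed, 2L))
  prox <- inbag_proximity(forest)
  hc <- ward_agglomerate(proximity_to_dissimilarity(prox),
                         dialect = config$ward_dialect)
  train_labels <- cut_dendrogram(hc, config$k_clusters)
  sizes <- table(as.integer(train_labels))
  say("clusters (train): %s", paste(sizes, collapse = "/"))
  if (any(sizes < 0.05 * length(train_labels)))
    warning("smallest cluster holds < 5% of training patients; ",
            "k may be too large for the cohort")

  importance <- variable_importance_frequency(forest)
  amodel <- fit_assignment_model(x_tr, train_labels, importance,
                                 top_k = config$top_k)
  test_labels <- assign_clusters(amodel, x_te)
  say("clusters (test, assigned): %s",
      paste(table(factor(as.integer(test_labels),
                         levels = seq_len(config$k_clusters))),
            collapse = "/"))

  safe_logrank <- function(labels, time, event) {
    if (length(unique(as.integer(labels))) < 2) {
      warning("only one occupied cluster; log-rank test undefined")
      return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_))
    }
    logrank_test(labels, time, event)
  }
  lr_train <- safe_logrank(train_labels, tr$time_months, tr$event)
  lr_test <- safe_logrank(test_labels, te$time_months, te$event)
  km_train <- km_curves_by_group(train_labels, tr$time_months, tr$event)
  km_test <- km_curves_by_group(test_labels, te$time_months, te$event)

  outcome_tr <- ipcw_weights(tr$time_months, tr$event, config$horizon)
  outcome_te <- ipcw_weights(te$time_months, te$event, config$horizon)

  fs_importance <- NULL
  modes <- list()
  for (mode in config$covariate_modes) {
    spec <- parse_mode(mode)
    extra_tr <- extra_te <- NULL
    cl_tr <- cl_te <- NULL
    include_ajcc <- FALSE
    if (spec$type == "ajcc") include_ajcc <- TRUE
    if (spec$type == "clusters") {
      cl_tr <- as.integer(train_labels); cl_te <- as.integer(test_labels)
    }
    if (spec$type == "rsf") {
      if (is.null(fs_importance)) {
        fs_forest <- fit_survival_forest(
          x_tr, tr$time_months, tr$event, n_trees = config$n_trees,
          min_node_size = 2, seed = stage_seed(config$seed, 3L))
        fs_importance <- variable_importance_frequency(fs_forest)
      }
      top <- head(fs_importance$feature, spec$n)
      extra_tr <- x_tr[, top, drop = FALSE]
      extra_te <- x_te[, top, drop = FALSE]
    }
    if (spec$type == "cox") {
      sel <- coxnet_select(x_tr, tr$time_months, tr$event,
                           n_folds = config$n_folds,
                           seed = stage_seed(config$seed, 4L))
      if (length(sel)) {
        extra_tr <- x_tr[, sel, drop = FALSE]
        extra_te <- x_te[, sel, drop = FALSE]
      }
    }
    d_tr <- design_matrix(tr$clinical, cl_tr, extra_tr, include_ajcc)
    d_te <- design_matrix(te$clinical, cl_te, extra_te, include_ajcc)
    ens <- fit_stacked_ensemble(d_tr, tr$time_months, tr$event,
                                horizon = config$horizon,
                                n_folds = config$n_folds,
                                seed = stage_seed(config$seed, 5L),
                                n_trees_rsf = config$n_trees_rsf,
                                n_trees_rf = config$n_trees_rf)
    risk_tr <- ensemble_predict(ens, d_tr)
    risk_te <- ensemble_predict(ens, d_te)
    modes[[mode]] <- list(
      stack_weights = ens$stack_weights,
      c_index_train = harrell_c_index(risk_tr, tr$time_months, tr$event),
      c_index_test = harrell_c_index(risk_te, te$time_months, te$event),
      auc_train = auc_horizon(risk_tr, outcome_tr),
      auc_test = auc_horizon(risk_te, outcome_te))
    say("mode %s: C test %.3f, AUC test %.3f; weights %s", mode,
        modes[[mode]]$c_index_test, modes[[mode]]$auc_test,
        paste(sprintf("%.2f", ens$stack_weights), collapse = "/"))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(
        modes[[mode]][c("stack_weights", "c_index_train", "c_index_test",
                        "auc_train", "auc_test")],
        file.path(out_dir, sprintf("ensemble_%s.json",
                                   gsub("[^a-z0-9]+", "_", mode))),
        auto_unbox = TRUE, digits = NA)
    }
  }

  report <- structure(
    list(seed = config$seed,
         n_train = nrow(x_tr), n_test = nrow(x_te),
         filter = filt$report,
         cluster_sizes_train = as.integer(sizes),
         cluster_sizes_test = as.integer(
           table(factor(as.integer(test_labels),
                        levels = seq_len(config$k_clusters)))),
         train_labels = as.integer(train_labels),
         test_labels = as.integer(test_labels),
         logrank_train = lr_train, logrank_test = lr_test,
         modes = modes),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    write_clustering(prox, hc, train_labels, out_dir)
    write_assignment_model(amodel, file.path(out_dir,
                                             "assignment_model.json"))
    write_km_tables(km_train, out_dir, "km_train")
    write_km_tables(km_test, out_dir, "km_test")
    jsonlite::write_json(
      list(n_input = filt$report$n_input, n_output = filt$report$n_output,
           dropped_zero_variance = filt$report$dropped_zero_variance,
           dropped_pairwise = filt$report$dropped_pairwise,
           dropped_anchor = filt$report$dropped_anchor),
      file.path(out_dir, "filter_report.json"),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(seed = config$seed,
           cluster_sizes_train = report$cluster_sizes_train,
           cluster_sizes_test = report$cluster_sizes_test,
           logrank_train = lr_train, logrank_test = lr_test,
           modes = modes),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d train / %d test; clusters %s\n",
              x$n_train, x$n_test,
              paste(x$cluster_sizes_train, collapse = "/")))
  cat(sprintf("  log-rank: train p = %.3g, test p = %.3g\n",
              x$logrank_train$p, x$logrank_test$p))
  for (m in names(x$modes))
    cat(sprintf("  %-22s C-index %.3f/%.3f  AUC %.3f/%.3f (train/test)\n",
                m, x$modes[[m]]$c_index_train, x$modes[[m]]$c_index_test,
                x$modes[[m]]$auc_train, x$modes[[m]]$auc_test))
  invisible(x)
}
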