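#' Configuration for an end-to-end mixture-QSAR run
#'
#' Bundles every stage's settings with explicit seeds so a run is a pure
#' function of its configuration. Either a synthetic-data configuration or
#' input file paths must be supplied.
#'
#' @param synthetic A [synthetic_config()], or NULL to read data from files.
#' @param components_csv,design_csv Paths to a component descriptor table and
#'   a mixture design table (used when `synthetic` is NULL).
#' @param plate_csv Optional path to a plate absorbance table
#'   (`sample_id`, `a_exp`, `a_control`, `a_blank`); viability is computed
#'   from it. Alternatively `viability_csv` with `sample_id`, `viability`.
#' @param viability_csv See `plate_csv`.
#' @param weighting Descriptor-mixing mode, see [mix_descriptors()].
#' @param backends Pooled-model backends to fit (subset of
#'   `"pls"`, `"random_forest"`, `"adaboost"`).
#' @param estimator_range,seed_range Grid-search axes.
#' @param objective Grid-search objective, see [grid_search_fit()].
#' @param split_ratio Train:test ratio.
#' @param split_seed Seed for the pooled random split; per-category splits
#'   use `split_seed + category`.
#' @param clustering Run the k-means categorization track (per-category
#'   models and cross-category predictions).
#' @param k Number of categories.
#' @param cluster_seed,n_restarts K-means settings.
#' @param select_threshold Importance cutoff for descriptor selection.
#' @param corr_prefilter,corr_threshold Optional correlated-descriptor
#'   pre-filter, see [prefilter_correlated()].
#' @param yrand_n_iter Y-randomization iterations per model (0 skips it).
#' @param yrand_seed Seed for the permutations.
#' @param out_dir Directory for run artifacts, or NULL to keep everything in
#'   memory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       components_csv = NULL, design_csv = NULL,
                       plate_csv = NULL, viability_csv = NULL,
                       weighting = c("fraction", "concentration"),
                       backends = c("pls", "random_forest", "adaboost"),
                       estimator_range = 1:30, seed_range = 1:10,
                       objective = c("test_r2", "cv"),
                       split_ratio = 3, split_seed = 1L,
                       clustering = TRUE, k = 2L,
                       cluster_seed = 1L, n_restarts = 10L,
                       select_threshold = 0.1,
                       corr_prefilter = FALSE, corr_threshold = 0.95,
                       yrand_n_iter = 10L, yrand_seed = 1L,
                       out_dir = NULL) {
  weighting <- match.arg(weighting)
  objective <- match.arg(objective)
  backends <- match.arg(backends, backend_names(), several.ok = TRUE)
  if (is.null(synthetic) &&
      (is.null(components_csv) || is.null(design_csv))) {
    stop("either a synthetic config or components/design CSV paths required",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

#' @keywords internal
load_run_data <- function(config) {
  if (!is.null(config$synthetic)) {
    sim <- simulate_mixture_study(config$synthetic,
                                  weighting = config$weighting)
    panel <- sim$panel
    mixed <- sim$mixed
    co_name <- config$synthetic$co_component$name
    return(list(panel = panel, mixed = mixed, co_name = co_name,
                truth = sim$truth))
  }
  panel <- utils::read.csv(config$components_csv, stringsAsFactors = FALSE)
  design <- utils::read.csv(config$design_csv, stringsAsFactors = FALSE)
  mixed <- mix_design(panel, design, weighting = config$weighting)
  if (!is.null(config$plate_csv)) {
    plate <- utils::read.csv(config$plate_csv, stringsAsFactors = FALSE)
    plate <- plate[match(mixed$sample_id, plate$sample_id), ]
    mixed$viability <- compute_viability(plate$a_exp, plate$a_control,
                                         plate$a_blank)
  } else if (!is.null(config$viability_csv)) {
    v <- utils::read.csv(config$viability_csv, stringsAsFactors = FALSE)
    mixed$viability <- v$viability[match(mixed$sample_id, v$sample_id)]
  } else {
    stop("plate_csv or viability_csv required for file-based runs",
         call. = FALSE)
  }
  list(panel = panel, mixed = mixed,
       co_name = mixed$co_component[1], truth = NULL)
}

#' @keywords internal
fit_track <- function(split, backend, config, cross_label = NULL) {
  yrand <- if (config$yrand_n_iter > 0)
    list(n_iter = config$yrand_n_iter, seed = config$yrand_seed,
         estimator_range = config$estimator_range,
         seed_range = config$seed_range) else NULL
  if (backend == "pls") {
    fitted <- fit_pls(split)
    model <- fitted$model
    grid <- NULL
    retained <- model$features
  } else {
    gs <- grid_search_fit(split, backend = backend,
                          estimator_range = config$estimator_range,
                          seed_range = config$seed_range,
                          objective = config$objective)
    if (is.null(cross_label)) {
      sel <- select_features(gs$model, split,
                             threshold = config$select_threshold,
                             estimator_range = config$estimator_range,
                             seed_range = config$seed_range,
                             objective = config$objective)
      model <- sel$model; grid <- sel$grid; retained <- sel$retained
    } else {
      # cross-category models are not descriptor-selected: their fit is too
      # poor for selection to be meaningful
      model <- gs$model; grid <- gs$grid; retained <- gs$model$features
    }
  }
  validation <- validate_model(model, split, yrand = yrand)
  ad <- williams_report(model, split)
  list(model = model, grid = grid, retained = retained,
       validation = validation, ad = ad, split = split)
}

#' Run the full mixture-QSAR workflow
#'
#' Data (simulated or loaded) -> descriptor mixing -> pooled 3:1 split ->
#' pooled PLS/random-forest/AdaBoost models with grid search and
#' importance-threshold descriptor selection -> k-means categorization of the
#' components with per-category models (A, B) and cross-category predictions
#' (C, D) -> validation battery and applicability-domain analysis per model
#' -> ranked comparison.
#'
#' @param config A [run_config()].
#' @return Object of class `run_report`: `models` (named list of track
#'   results, each with `model`, `grid`, `validation`, `ad`, `split`),
#'   `assignment` (the `cluster_assignment`, when clustering is on),
#'   `comparison` (ranked metric table), `config`, and `data`
#'   (panel + mixed table).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dat <- load_run_data(config)
  panel_var <- dat$panel[dat$panel$name != dat$co_name, , drop = FALSE]
  desc <- descriptor_names()
  if (config$corr_prefilter) {
    dt0 <- build_design_table(dat$mixed)
    desc <- prefilter_correlated(dt0$X, dt0$y,
                                 threshold = config$corr_threshold)
  }
  dt <- build_design_table(dat$mixed, descriptors = desc)
  split <- split_train_test(dt$X, dt$y, ratio = config$split_ratio,
                            seed = config$split_seed)
  models <- list()
  for (b in config$backends) {
    label <- c(pls = "pls", random_forest = "rf", adaboost = "adaboost")[[b]]
    models[[label]] <- fit_track(split, b, config)
  }
  assignment <- NULL
  if (config$clustering) {
    assignment <- kmeans_components(panel_var, k = config$k,
                                    seed = config$cluster_seed,
                                    n_restarts = config$n_restarts)
    groups <- assign_mixtures(assignment, dat$mixed)
    cat_splits <- vector("list", config$k)
    for (g in seq_len(config$k)) {
      idx <- groups[[g]]
      cat_splits[[g]] <- split_train_test(
        dt$X[idx, , drop = FALSE], dt$y[idx],
        ratio = config$split_ratio,
        seed = config$split_seed + g)
      models[[paste0("model_", LETTERS[g])]] <-
        fit_track(cat_splits[[g]], "random_forest", config)
    }
    if (config$k >= 2L) {
      # cross-category tracks: train on one category, test on the other's
      # test partition
      cross_pairs <- list(C = c(1L, 2L), D = c(2L, 1L))
      for (nm in names(cross_pairs)) {
        tr <- cross_pairs[[nm]][1]; te <- cross_pairs[[nm]][2]
        xs <- cat_splits[[tr]]
        xs$X_test <- cat_splits[[te]]$X_test
        xs$y_test <- cat_splits[[te]]$y_test
        models[[paste0("model_", nm)]] <-
          fit_track(xs, "random_forest", config, cross_label = nm)
      }
    }
  }
  comparison <- compare_models(lapply(models, `[[`, "validation"))
  report <- structure(list(models = models, assignment = assignment,
                           comparison = comparison, config = config,
                           data = dat),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Ranked comparison of validation reports
#'
#' @param reports Named list of `validation_report` objects sharing the same
#'   metrics.
#' @return Data frame, one row per model, with all metrics, the number of
#'   criteria passed, ranked by (criteria passed, then test R2), best first.
#' @export
compare_models <- function(reports) {
  if (!length(reports)) stop("at least one report required", call. = FALSE)
  cols <- c("r2_train", "r2_test", "rmse_train", "rmse_test", "q2_loo",
            "r2_yrand", "q2_yrand", "qf1", "qf2", "qf3", "ccc")
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    if (!all(cols %in% names(r))) {
      stop("report '", nm, "' is missing metrics", call. = FALSE)
    }
    vals <- as.data.frame(r[cols])
    crit <- tryCatch(evaluate_criteria(r), error = function(e) NULL)
    vals$criteria_passed <- if (is.null(crit)) NA_integer_ else
      sum(crit[names(crit) != "overall"])
    cbind(data.frame(model = nm, n_train = r$n_train, n_test = r$n_test),
          vals)
  })
  out <- do.call(rbind, rows)
  out[order(-ifelse(is.na(out$criteria_passed), -1L, out$criteria_passed),
            -out$r2_test), , drop = FALSE]
}

#' Write run artifacts to disk
#'
#' One directory per run: the mixed design table, cluster assignment, the
#' per-model validation/AD tables, and a JSON summary.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$data$mixed, file.path(dir, "mixed.csv"),
                   row.names = FALSE)
  if (!is.null(report$assignment)) {
    jsonlite::write_json(
      list(k = report$assignment$k,
           labels = as.list(report$assignment$labels),
           inertia = report$assignment$inertia,
           scaled = report$assignment$scaled),
      file.path(dir, "assign.json"), auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(report$comparison, file.path(dir, "comparison.csv"),
                   row.names = FALSE)
  summary <- lapply(report$models, function(tr) {
    v <- tr$validation
    list(backend = v$backend,
         hyperparameters = v$hyperparameters,
         features = v$features,
         importance = as.list(tr$model$importance),
         metrics = v[c("r2_train", "r2_test", "rmse_train", "rmse_test",
                       "q2_loo", "r2_yrand", "q2_yrand",
                       "qf1", "qf2", "qf3", "ccc")],
         criteria_pass = as.list(v$criteria_pass),
         h_star = tr$ad$h_star,
         n_outside_domain = as.list(tr$ad$n_outside))
  })
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(report$models)) {
    tr <- report$models[[nm]]
    sub <- file.path(dir, nm)
    dir.create(sub, showWarnings = FALSE)
    pred <- data.frame(
      partition = rep(c("train", "test"),
                      c(length(tr$split$y_train), length(tr$split$y_test))),
      observed = c(tr$split$y_train, tr$split$y_test),
      predicted = c(tr$validation$predicted_train,
                    tr$validation$predicted_test))
    utils::write.csv(pred, file.path(sub, "pred.csv"), row.names = FALSE)
    utils::write.csv(tr$ad$samples, file.path(sub, "ad.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Mixture-QSAR run:", length(x$models), "model track(s)\n")
  if (!is.null(x$assignment)) {
    tab <- table(x$assignment$labels)
    cat("  component categories:",
        paste(sprintf("category %s: %d", names(tab), tab), collapse = "; "),
        "\n")
  }
  print(x$comparison[, c("model", "n_train", "n_test", "r2_test",
                         "rmse_test", "q2_loo", "ccc", "criteria_passed")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
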