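#' Default experiment configuration
#'
#' One nested list drives the whole experimental loop: synthesize signals,
#' extract and normalize features, split, train the three model families
#' (plain ELM, wrapper feature selection + ELM, KTGEL), and evaluate.
#' Every stochastic stage receives `global seed + stage offset`:
#' synth +0 (the generator internally uses seed and seed+1), split +100,
#' ELM layer +200, wrapper search +300, weight-pruning search +400.
#'
#' @param preset Ambiguity preset name for [fmg_preset()].
#' @param seed Global integer seed.
#' @param out_dir Artifact directory.
#' @param synth Named overrides for [gen_config()] fields.
#' @param n_hidden Hidden-layer size for all models.
#' @param test_frac Held-out test fraction.
#' @param folds CV folds used inside fitness functions.
#' @param pop_size,max_iter,k Optimizer budget.
#' @param models Character subset of `c("elm", "ktgelm", "ktgel")`.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(preset = "middle", seed = 1, out_dir = "ktgel-run",
                       synth = list(), n_hidden = 200, test_frac = 0.2,
                       folds = 5, pop_size = 12, max_iter = 12, k = 3,
                       models = c("elm", "ktgelm", "ktgel"),
                       log_level = "info") {
  structure(
    list(preset = preset, seed = as.integer(seed), out_dir = out_dir,
         synth = synth, n_hidden = as.integer(n_hidden),
         test_frac = test_frac, folds = as.integer(folds),
         pop_size = as.integer(pop_size), max_iter = as.integer(max_iter),
         k = as.integer(k), models = models, log_level = log_level),
    class = "run_config"
  )
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$synth <- as.list(raw$synth)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

log_msg <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full experimental loop
#'
#' Executes synth -> features -> split -> models -> eval and writes all
#' artifacts into `config$out_dir`: per-model reports
#' (`elm_report.json`, `ktgelm_report.json`, `ktgel_report.json`),
#' optimizer traces (`trace.csv` for the KTGEL search,
#' `ktgelm_trace.csv` for the wrapper), a comparison table
#' (`comparison.csv` with features/hidden nodes in and out, accuracy,
#' precision, sensitivity), and `manifest.json` recording the config, its
#' hash, derived seeds and the package version. Reports contain no
#' timestamps, so re-running an identical config reproduces them
#' byte-for-byte.
#'
#' @param config A [run_config()] (or path to its JSON form).
#' @return The artifact directory path, invisibly.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "synth"
  result <- tryCatch({
    seeds <- list(synth = config$seed, split = config$seed + 100L,
                  elm = config$seed + 200L, wrapper = config$seed + 300L,
                  prune = config$seed + 400L)

    log_msg(config, "stage synth: preset '%s'", config$preset)
    cfg <- do.call(fmg_preset,
                   c(list(name = config$preset, seed = seeds$synth), config$synth))
    gen <- generate_fmg(cfg)

    stage <- "features"
    log_msg(config, "stage features: %d windows", length(gen$windows))
    data <- windows_to_features(gen$windows, cfg$class_names)

    stage <- "split"
    split <- stratified_holdout(data$y, config$test_frac, seeds$split)
    norm <- minmax_fit(data$X[split$train_idx, , drop = FALSE])
    Xn <- minmax_apply(data$X, norm)
    train <- labeled_feature_set(Xn[split$train_idx, , drop = FALSE],
                                 data$y[split$train_idx], cfg$class_names)
    test_X <- Xn[split$test_idx, , drop = FALSE]
    test_y <- data$y[split$test_idx]

    elm_cfg <- elm_config(config$n_hidden, seeds$elm)
    rows <- list()
    report_of <- function(pred) eval_report(test_y, pred, data$n_classes, cfg$class_names)

    if ("elm" %in% config$models) {
      stage <- "elm"
      log_msg(config, "stage elm: L = %d", config$n_hidden)
      elm <- train_elm(train, config$n_hidden, seeds$elm)
      rep_elm <- report_of(predict(elm, test_X))
      write_eval_report(rep_elm, file.path(config$out_dir, "elm_report.json"))
      write_elm_model(elm, file.path(config$out_dir, "elm_model.json"))
      rows$elm <- data.frame(
        model = "ELM", feature_selection = "no",
        features_in = ncol(Xn), features_out = ncol(Xn),
        hidden_in = config$n_hidden, hidden_out = config$n_hidden,
        accuracy = rep_elm$accuracy, precision = rep_elm$micro_p,
        sensitivity = rep_elm$micro_r
      )
    }

    goa <- goa_params(pop_size = config$pop_size, max_iter = config$max_iter,
                      k = config$k, seed = seeds$wrapper)
    if ("ktgelm" %in% config$models) {
      stage <- "ktgelm"
      log_msg(config, "stage ktgelm: wrapper feature selection")
      fs <- select_features(train, goa, elm_cfg, config$folds)
      write_selection_json(fs, file.path(config$out_dir, "ktgelm_selection.json"),
                           file.path(config$out_dir, "ktgelm_trace.csv"))
      sel_train <- labeled_feature_set(train$X[, fs$selected, drop = FALSE],
                                       train$y, cfg$class_names)
      elm_fs <- train_elm(sel_train, config$n_hidden, seeds$elm)
      rep_fs <- report_of(predict(elm_fs, test_X[, fs$selected, drop = FALSE]))
      write_eval_report(rep_fs, file.path(config$out_dir, "ktgelm_report.json"))
      rows$ktgelm <- data.frame(
        model = "KTGELM+ELM", feature_selection = "yes",
        features_in = ncol(Xn), features_out = length(fs$selected),
        hidden_in = config$n_hidden, hidden_out = config$n_hidden,
        accuracy = rep_fs$accuracy, precision = rep_fs$micro_p,
        sensitivity = rep_fs$micro_r
      )
    }

    if ("ktgel" %in% config$models) {
      stage <- "ktgel"
      log_msg(config, "stage ktgel: weight-pruning search over %d bits",
              ncol(Xn) * config$n_hidden)
      goa_p <- goa_params(pop_size = config$pop_size, max_iter = config$max_iter,
                          k = config$k, seed = seeds$prune)
      kt <- train_ktgel(train, config$n_hidden, goa_p, elm_cfg, config$folds)
      rep_kt <- report_of(predict(kt, test_X))
      write_eval_report(rep_kt, file.path(config$out_dir, "ktgel_report.json"))
      write_ktgel_model(kt, file.path(config$out_dir, "ktgel_model.json"))
      write_trace_csv(kt$history, file.path(config$out_dir, "trace.csv"))
      rows$ktgel <- data.frame(
        model = "KTGEL", feature_selection = "no (implicit)",
        features_in = ncol(Xn), features_out = length(kt$active_features),
        hidden_in = config$n_hidden, hidden_out = length(kt$active_nodes),
        accuracy = rep_kt$accuracy, precision = rep_kt$micro_p,
        sensitivity = rep_kt$micro_r
      )
    }

    stage <- "manifest"
    comparison <- do.call(rbind, rows)
    utils::write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
                     row.names = FALSE)
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
    tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
    manifest <- list(
      config = unclass(config),
      config_md5 = unname(tools::md5sum(tmp)),
      seeds = seeds,
      package_version = as.character(utils::packageVersion("ktgel")),
      r_version = R.version.string
    )
    unlink(tmp)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_msg(config, "done: artifacts in %s", config$out_dir)
    config$out_dir
  }, error = function(e) {
    stop(sprintf("experiment failed at stage '%s': %s (partial artifacts kept in %s)",
                 stage, conditionMessage(e), config$out_dir), call. = FALSE)
  })
  invisible(result)
}
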