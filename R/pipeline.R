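#' Full experiment configuration
#'
#' One nested configuration object driving the end-to-end pipeline. Every
#' default is the standard protocol constant; a single global seed
#' deterministically derives all per-stage seeds.
#'
#' @param protocol [protocol_spec()] arguments as a list
#' @param activation [make_activation_matrix()] arguments (dimensions come
#'   from the protocol)
#' @param frontend [frontend_spec()] arguments
#' @param segmentation [segmentation_spec()] arguments
#' @param features [feature_spec()] arguments
#' @param lambda ridge coefficient for [fit_ovo()] (`NULL` = automatic)
#' @param motion_test [motion_test_config()] arguments
#' @param n_subjects simulated subjects per condition group (default 6, two
#'   groups of six as in the independent-group comparisons)
#' @param conditions named list of channel-index vectors defining the
#'   compared conditions; default the 16-channel condition vs the equally
#'   spaced 8-channel subset
#' @param paired whether the conditions are measured on the same simulated
#'   subjects (paired tests) or on independent groups
#' @param stats_m Bonferroni family size (default 5: the five metrics per
#'   configuration pair)
#' @param seed global RNG seed
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(protocol = list(), activation = list(),
                            frontend = list(), segmentation = list(),
                            features = list(), lambda = NULL,
                            motion_test = list(), n_subjects = 6,
                            conditions = NULL, paired = TRUE,
                            stats_m = 5, seed = 1) {
  structure(list(protocol = protocol, activation = activation,
                 frontend = frontend, segmentation = segmentation,
                 features = features, lambda = lambda,
                 motion_test = motion_test, n_subjects = n_subjects,
                 conditions = conditions, paired = paired,
                 stats_m = stats_m, seed = seed),
            class = "pipeline_config")
}

# Instantiate the stage objects (validating every section) from a config.
build_stages <- function(config) {
  protocol <- do.call(protocol_spec, config$protocol %||% list())
  activation_args <- config$activation %||% list()
  activation_args$n_movements <- length(protocol$movements)
  activation_args$n_channels <- protocol$n_channels
  list(protocol = protocol,
       activation_args = activation_args,
       frontend = do.call(frontend_spec, config$frontend %||% list()),
       segmentation = do.call(segmentation_spec, config$segmentation %||% list()),
       features = do.call(feature_spec, config$features %||% list()),
       motion_test = do.call(motion_test_config, config$motion_test %||% list()),
       conditions = config$conditions %||% {
         full <- seq_len(protocol$n_channels)
         half <- seq(1, protocol$n_channels, by = 2)
         stats::setNames(list(full, half),
                         paste0("ch", c(length(full), length(half))))
       })
}

#' Validate a pipeline configuration
#'
#' Checks every section's invariants and returns a report of violations
#' (field path + message) instead of stopping at the first one.
#'
#' @param config a [pipeline_config()], a plain list, or the path of a JSON
#'   config file
#' @return data.frame with columns `field` and `message`; zero rows when the
#'   configuration is valid (`attr(report, "ok")` is `TRUE`)
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  violations <- list()
  note <- function(field, e) {
    msg <- conditionMessage(e)
    violations[[length(violations) + 1]] <<- data.frame(
      field = field, message = msg)
  }
  tryCatch(do.call(protocol_spec, as_arglist(config$protocol)),
           error = function(e) note("protocol", e))
  tryCatch({
    p <- tryCatch(do.call(protocol_spec, as_arglist(config$protocol)),
                  error = function(e) protocol_spec())
    args <- as_arglist(config$activation)
    args$n_movements <- length(p$movements)
    args$n_channels <- p$n_channels
    do.call(make_activation_matrix, args)
  }, error = function(e) note("activation", e))
  tryCatch(do.call(frontend_spec, as_arglist(config$frontend)),
           error = function(e) note("frontend", e))
  tryCatch(do.call(segmentation_spec, as_arglist(config$segmentation)),
           error = function(e) note("segmentation", e))
  tryCatch(do.call(feature_spec, as_arglist(config$features)),
           error = function(e) note("features", e))
  tryCatch(do.call(motion_test_config, as_arglist(config$motion_test)),
           error = function(e) note("motion_test", e))
  if (!is.null(config$stats_m))
    tryCatch(check_scalar_num(config$stats_m, "stats_m", lower = 1,
                              integer = TRUE),
             error = function(e) note("stats_m", e))
  if (!is.null(config$n_subjects))
    tryCatch(check_scalar_num(config$n_subjects, "n_subjects", lower = 1,
                              integer = TRUE),
             error = function(e) note("n_subjects", e))
  report <- if (length(violations)) do.call(rbind, violations)
            else data.frame(field = character(0), message = character(0))
  attr(report, "ok") <- nrow(report) == 0
  report
}

as_arglist <- function(x) {
  if (is.null(x)) return(list())
  x <- as.list(x)
  x[!vapply(x, is.null, logical(1))]
}

#' Run the full simulated experiment
#'
#' Mirrors the structure of a configuration-comparison study: for each
#' simulated subject a synthetic recording session is generated; for each
#' condition (channel subset) a classifier is trained on the 40/20/40 split,
#' offline accuracy is measured, and the Motion Test is run; the
#' per-subject metric table is then compared across conditions with the
#' configured Wilcoxon test and Bonferroni correction. Deterministic for a
#' fixed seed; every artifact records the config hash.
#'
#' @param config a [pipeline_config()]
#' @param out_dir optional output directory for CSV/JSON reports
#' @return an `experiment_result`: list with `metric_table` (one row per
#'   subject x condition), `summary` (per-condition mean/SE), `comparisons`
#'   (adjusted p-values), `config_hash`, `seed`
#' @export
run_experiment <- function(config = pipeline_config(), out_dir = NULL) {
  stages <- build_stages(config)
  hash <- config_hash(unclass(config))
  seed <- config$seed %||% 1
  conditions <- stages$conditions
  n_sub <- config$n_subjects %||% 6
  paired <- isTRUE(config$paired %||% TRUE)

  rows <- list()
  for (s_i in seq_len(n_sub)) {
    for (c_i in seq_along(conditions)) {
      cond <- names(conditions)[c_i]
      # independent groups get distinct simulated subjects per condition
      subject_tag <- if (paired) s_i else s_i + 1000L * c_i
      subj_seed <- derive_seed(seed, 10L * subject_tag)
      act_args <- stages$activation_args
      act_args$seed <- subj_seed
      model <- do.call(make_activation_matrix, act_args)
      session <- generate_session(stages$protocol, model, stages$frontend,
                                  seed = derive_seed(subj_seed, 1))
      sub <- select_channels(session, conditions[[c_i]])
      sub_model <- model
      sub_model$activation <- model$activation[, conditions[[c_i]], drop = FALSE]
      ws <- windows_from_session(sub, stages$segmentation)
      fm <- extract_features(ws, stages$features)
      split <- split_sets(fm, seed = derive_seed(subj_seed, 2))
      clf <- fit_ovo(fm, split, lambda = config$lambda)
      acc <- offline_accuracy(clf, fm, split)
      sub_protocol <- sub$protocol
      mt <- run_motion_test(clf, sub_protocol, sub_model, stages$frontend,
                            stages$motion_test, stages$features,
                            seed = derive_seed(subj_seed, 3))
      a <- mt$aggregates
      rows[[length(rows) + 1]] <- data.frame(
        subject = s_i, condition = cond,
        completion_pct = a$completion_pct,
        realtime_accuracy = unname(a$realtime_accuracy["mean"]),
        completion_time_s = unname(a$completion_time_s["mean"]),
        selection_time_s = unname(a$selection_time_s["mean"]),
        offline_accuracy = acc)
    }
  }
  metric_table <- do.call(rbind, rows)

  metrics <- c("completion_pct", "realtime_accuracy", "completion_time_s",
               "selection_time_s", "offline_accuracy")
  summary <- do.call(rbind, lapply(names(conditions), function(cond) {
    tab <- metric_table[metric_table$condition == cond, metrics]
    cbind(condition = cond, summarize_metrics(tab))
  }))
  comparisons <- NULL
  if (length(conditions) == 2) {
    ta <- metric_table[metric_table$condition == names(conditions)[1], metrics]
    tb <- metric_table[metric_table$condition == names(conditions)[2], metrics]
    comparisons <- suppressWarnings(
      compare_conditions(ta, tb, paired = paired,
                         m = config$stats_m %||% length(metrics)))
    comparisons <- cbind(
      comparison = paste(names(conditions), collapse = "_vs_"), comparisons)
  }
  result <- structure(list(metric_table = metric_table, summary = summary,
                           comparisons = comparisons, config_hash = hash,
                           seed = seed),
                      class = "experiment_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cbind(metric_table, config_hash = hash),
                     file.path(out_dir, "metric_table.csv"), row.names = FALSE)
    utils::write.csv(cbind(summary, config_hash = hash),
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
    if (!is.null(comparisons))
      utils::write.csv(cbind(comparisons, config_hash = hash),
                       file.path(out_dir, "comparisons.csv"), row.names = FALSE)
    jsonlite::write_json(list(config = unclass(config), config_hash = hash,
                              seed = seed),
                         file.path(out_dir, "run.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d rows, config %s, seed %s\n",
              nrow(x$metric_table), substr(x$config_hash, 1, 8),
              format(x$seed)))
  if (!is.null(x$comparisons)) {
    cat("comparisons:\n")
    print(x$comparisons[, c("metric", "test", "p_raw", "p_adjusted",
                            "significant")])
  }
  invisible(x)
}
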