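#' Validate an experiment configuration
#'
#' Configurations are plain-text YAML with blocks `cohort` (preset name
#' plus optional [cohort_spec()] overrides), `plan` (training-set sizes,
#' validation size, Monte-Carlo iterations), `protocol`
#' ([training_protocol()] fields), `strategies`, optional `quantize_bits`,
#' optional `out_dir`, and a single global `seed` from which every stage
#' seed is derived. Validation is strict: unknown keys are rejected and
#' all violations are reported together.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return the validated config as a named list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_param("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_param("config must be a list or a YAML path")
  errors <- character(0)
  note <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))

  top_known <- c("schema_version", "seed", "cohort", "plan", "protocol",
                 "strategies", "quantize_bits", "out_dir")
  unknown <- setdiff(names(config), top_known)
  if (length(unknown)) note("unknown top-level keys: %s",
                            paste(unknown, collapse = ", "))

  defaults <- list(schema_version = 1, seed = 1,
                   cohort = list(preset = "ukb_like"),
                   plan = list(sizes = c(150, 300, 600, 1200, 2400),
                               n_val = 1200, mc_iterations = 10),
                   protocol = list(),
                   strategies = c("central", "fl", "tm"),
                   quantize_bits = NULL, out_dir = NULL)
  cfg <- utils::modifyList(defaults, config[names(config) %in% top_known])

  cohort_known <- c("preset", names(formals(cohort_spec)))
  unknown <- setdiff(names(cfg$cohort), cohort_known)
  if (length(unknown)) note("unknown cohort keys: %s",
                            paste(unknown, collapse = ", "))
  if (!is.null(cfg$cohort$preset) &&
      !cfg$cohort$preset %in% c("ukb_like", "brset_like")) {
    note("cohort.preset must be 'ukb_like' or 'brset_like'")
  }
  for (nm in c("site_sd", "eye_sd", "noise_sd", "age_sd", "baseline_sd")) {
    v <- cfg$cohort[[nm]]
    if (!is.null(v) && (!is.numeric(v) || v < 0)) {
      note("cohort.%s must be a non-negative number", nm)
    }
  }

  plan_known <- c("sizes", "n_val", "mc_iterations", "train_centers",
                  "test_centers")
  unknown <- setdiff(names(cfg$plan), plan_known)
  if (length(unknown)) note("unknown plan keys: %s",
                            paste(unknown, collapse = ", "))
  if (!is.numeric(cfg$plan$sizes) || any(cfg$plan$sizes < 1)) {
    note("plan.sizes must be positive training-set sizes")
  }

  proto_known <- setdiff(names(formals(training_protocol)), "seed")
  unknown <- setdiff(names(cfg$protocol), proto_known)
  if (length(unknown)) note("unknown protocol keys: %s",
                            paste(unknown, collapse = ", "))
  proto <- utils::modifyList(
    list(fl_clients_per_round = 32), cfg$protocol)
  if (is.numeric(cfg$plan$sizes) &&
      proto$fl_clients_per_round > min(cfg$plan$sizes)) {
    note(paste0("protocol.fl_clients_per_round (%d) exceeds the smallest ",
                "plan.sizes entry (%d)"),
         proto$fl_clients_per_round, min(cfg$plan$sizes))
  }

  bad <- setdiff(cfg$strategies, c("central", "fl", "tm"))
  if (length(bad)) note("unknown strategies: %s", paste(bad, collapse = ", "))
  if (!is.null(cfg$quantize_bits)) {
    if (!is.numeric(cfg$quantize_bits) || length(cfg$quantize_bits) != 1 ||
        cfg$quantize_bits < 2 || cfg$quantize_bits > 16) {
      note("quantize_bits must be a single integer in 2..16")
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    note("seed must be a single integer")
  }

  if (length(errors)) {
    stop(paste0("invalid configuration:\n  - ",
                paste(errors, collapse = "\n  - ")), call. = FALSE)
  }
  cfg
}

# internal: cohort_spec from a validated config block
config_cohort_spec <- function(cohort_cfg, seed) {
  preset <- cohort_cfg$preset
  overrides <- cohort_cfg[setdiff(names(cohort_cfg), "preset")]
  if (!is.null(preset)) {
    do.call(cohort_preset, c(list(name = preset, seed = seed), overrides))
  } else {
    do.call(cohort_spec, utils::modifyList(overrides, list(seed = seed)))
  }
}

#' Run a full Monte-Carlo experiment
#'
#' For each Monte-Carlo iteration and each training-set size, builds the
#' role assignment once and trains every requested strategy on identical
#' data (so strategy comparisons are paired), evaluating internal
#' validation MAE and external-test MAE (healthy external clients). Fully
#' reproducible from the config's single seed: the cohort seed, every
#' split and every training run use seeds derived from it.
#'
#' @param config a config list or YAML path (see [validate_config()]).
#' @return object of class `fedgap_experiment`: list with `results` (one
#'   row per iteration x size x strategy: MAEs, best round, local-update
#'   and transfer accounting), `summary` (mean +/- sd of validation MAE
#'   per size and strategy), `comparisons` (per-size
#'   [compare_strategies()] output), `config`, and the generated `cohort`
#'   and `network` (invisibly reusable for RAG analyses).
#' @export
run_experiment <- function(config) {
  cfg <- validate_config(config)
  spec <- config_cohort_spec(cfg$cohort, derive_seed(cfg$seed, "cohort"))
  cohort <- generate_cohort(spec)
  if (!is.null(cfg$quantize_bits)) {
    cohort$features <- quantize_dequantize(cohort$features,
                                           cfg$quantize_bits)
  }
  network <- build_network(cohort)

  plan_args <- cfg$plan
  sizes <- as.integer(plan_args$sizes)
  engines <- list(central = train_centralized, fl = train_federated,
                  tm = train_traveling)
  rows <- list()
  for (iter in seq_len(plan_args$mc_iterations)) {
    for (n_train in sizes) {
      plan <- split_plan(
        n_train = n_train,
        n_val = plan_args$n_val %||% 1200,
        train_centers = plan_args$train_centers %||% sprintf("C%d", 1:5),
        test_centers = plan_args$test_centers %||% sprintf("C%d", 6:8),
        mc_iterations = plan_args$mc_iterations,
        seed = derive_seed(cfg$seed, sprintf("splits/%d", n_train)))
      split <- monte_carlo_split(network, plan, iter)
      ext_ids <- network$subjects$subject_id[
        network$subjects$subject_id %in% split$external &
          network$subjects$group == "healthy"]
      ext <- pool_records(network, ext_ids)
      for (strategy in cfg$strategies) {
        # per-strategy protocol defaults: federated clients run two local
        # passes over their record pair per round (FedAvg-style local
        # epochs); the traveling model carries its optimizer state from
        # client to client. Both are overridable through config$protocol.
        strat_defaults <- switch(strategy,
                                 fl = list(local_epochs = 2),
                                 tm = list(carry_state = TRUE),
                                 list())
        proto <- do.call(training_protocol, utils::modifyList(
          utils::modifyList(strat_defaults, cfg$protocol),
          list(seed = derive_seed(
            cfg$seed, sprintf("train/%s/%d/%d", strategy, n_train, iter)))))
        fit <- engines[[strategy]](network, split, proto)
        rows[[length(rows) + 1L]] <- data.frame(
          iteration = iter, n_train = n_train, strategy = strategy,
          val_mae = fit$best_val_mae,
          ext_mae = evaluate_mae(fit$head, ext$X, ext$y),
          best_round = fit$best_round, rounds_run = fit$rounds_run,
          updates_at_best = fit$updates_at_best,
          updates_per_client = fit$updates_at_best / length(split$train),
          train_flops = fit$ledger$train_flops,
          transfers = fit$ledger$transfers,
          bytes = fit$ledger$bytes,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)

  summary <- do.call(rbind, lapply(split(
    results, list(results$n_train, results$strategy)), function(g) {
      data.frame(n_train = g$n_train[1L], strategy = g$strategy[1L],
                 mean_val_mae = mean(g$val_mae),
                 sd_val_mae = stats::sd(g$val_mae),
                 mean_ext_mae = mean(g$ext_mae),
                 sd_ext_mae = stats::sd(g$ext_mae),
                 label = sprintf("%.2f ± %.2f", mean(g$val_mae),
                                 stats::sd(g$val_mae)),
                 stringsAsFactors = FALSE)
    }))
  summary <- summary[order(summary$n_train, summary$strategy), ]
  row.names(summary) <- NULL

  comparisons <- NULL
  if (length(cfg$strategies) > 1L && plan_args$mc_iterations > 1L) {
    comparisons <- lapply(split(results, results$n_train), function(g) {
      compare_strategies(data.frame(iteration = g$iteration,
                                    strategy = g$strategy, mae = g$val_mae))
    })
  }

  out <- structure(list(results = results, summary = summary,
                        comparisons = comparisons, config = cfg,
                        cohort = cohort, network = network),
                   class = "fedgap_experiment")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_experiment_report(out, file.path(cfg$out_dir, "report.json"))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fedgap_experiment <- function(x, ...) {
  cat("Monte-Carlo experiment\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  n_train %4d  %-8s val MAE %s y\n",
                x$summary$n_train[i], x$summary$strategy[i],
                x$summary$label[i]))
  }
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' Serializes results, per-size summaries, strategy comparisons and the
#' config at full numeric precision (display rounding is left to the
#' caller). The cohort itself is not embedded; it is reproducible from the
#' config.
#'
#' @param experiment a [run_experiment()] result.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_experiment_report <- function(experiment, path) {
  stopifnot(inherits(experiment, "fedgap_experiment"))
  comp <- lapply(experiment$comparisons, function(cmp) {
    list(summary = cmp$summary, pairwise = cmp$pairwise, anova = cmp$anova)
  })
  obj <- list(schema_version = 1,
              config = experiment$config[
                setdiff(names(experiment$config), "out_dir")],
              results = experiment$results,
              summary = experiment$summary,
              comparisons = comp)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_experiment_report
#' @export
read_experiment_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
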