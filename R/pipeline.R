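#' Pipeline configuration
#'
#' Loads and validates the YAML configuration driving the
#' simulate -> fit -> select -> predict -> report pipeline. Times are given
#' in minutes (`design.times_min`, matching the 0/30/60/120/240 presentation
#' of the measurements) and converted to seconds internally. A seed is
#' mandatory for every stochastic stage.
#'
#' @param config Path to a YAML file, or an equivalent list.
#' @return A validated `sigburst_config` list.
#' @export
pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  d <- cfg$design %||% list()
  if (is.null(d$seed)) {
    rlang::abort("design.seed is mandatory", class = "sigburst_error_config")
  }
  design <- synthetic_design(
    conditions = d$conditions %||% conditions(),
    times = (d$times_min %||% c(0, 30, 60, 120, 240)) * 60,
    replicates = d$replicates %||% 4,
    cells_per_replicate = d$cells_per_replicate %||% 500,
    seed = d$seed)
  models <- purrr::map(cfg$models %||% list("CM1", "CM2"), function(m) {
    if (is.character(m) && m %in% c("CM1", "CM2")) cm_model(m)
    else if (is.character(m)) read_model_config(m)
    else model_from_config(m)
  })
  names(models) <- purrr::map_chr(models, "name")
  if (anyDuplicated(names(models))) {
    rlang::abort("model names must be unique", class = "sigburst_error_config")
  }
  opt_cfg <- cfg$optimizer %||% list()
  fsp <- cfg$fsp %||% list()
  structure(list(
    design = design, models = models,
    simulate_model = cfg$simulate$model %||% names(models)[1],
    fsp_args = purrr::compact(list(tol = fsp$tol %||% 1e-4,
      max_count = fsp$max_count, rtol = fsp$rtol %||% 1e-8)),
    optimizer = list(n_starts = opt_cfg$n_starts %||% 20,
      maxit = opt_cfg$maxit %||% 500,
      method = opt_cfg$method %||% "neldermead",
      seed = opt_cfg$seed %||% d$seed,
      fixed = opt_cfg$fixed %||% character()),
    full_screen = isTRUE(cfg$screen$full),
    screen_top = cfg$screen$top %||% 3L,
    out_dir = cfg$out_dir %||% "sigburst_out"),
    class = "sigburst_config")
}

stage_manifest <- function(cfg, stage, extra = list()) {
  c(list(stage = stage, package = "sigburst",
    version = as.character(utils::packageVersion("sigburst")),
    config_hash = rlang::hash(cfg), seed = cfg$design$seed), extra)
}

write_manifest <- function(cfg, stage, path, extra = list()) {
  jsonlite::write_json(stage_manifest(cfg, stage, extra), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

#' Pipeline stage: simulate a synthetic count table
#'
#' Generates the configured design from the configured model and writes
#' `counts.csv` plus a manifest JSON recording the seed and a model hash.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (defaults to the configured one).
#' @return The count table, invisibly; artifacts on disk.
#' @export
run_simulate <- function(cfg, out_dir = cfg$out_dir) {
  stopifnot(inherits(cfg, "sigburst_config"))
  ensure_dir(out_dir)
  model <- cfg$models[[cfg$simulate_model]]
  if (is.null(model)) {
    rlang::abort(sprintf("simulate.model '%s' not among the configured models",
      cfg$simulate_model), class = "sigburst_error_config")
  }
  tab <- generate_dataset(cfg$design, model)
  write_count_table(tab, file.path(out_dir, "counts.csv"))
  write_manifest(cfg, "simulate", file.path(out_dir, "simulate_manifest.json"),
    list(model = model$name, model_hash = rlang::hash(model),
      n_rows = nrow(tab)))
  invisible(tab)
}

#' Pipeline stage: fit models to the training conditions
#'
#' Fits every configured model to the table's training conditions (the
#' combined-drug condition is excluded by construction; a table containing
#' only `both` is refused). Optionally runs the two-stage screen first:
#' each of the 6 single-gene mechanisms is fitted to each gene's
#' inhibitor-free data and ranked by BIC, and the top `screen_top` (default
#' 3) per gene define the combinatorial candidates (3 x 3 = 9 models;
#' `full_screen` keeps all 6 per gene, 36 models).
#'
#' @param cfg A [pipeline_config()].
#' @param table Count table (tibble or CSV path).
#' @param screen If `TRUE`, build candidates by the BIC screen instead of
#'   fitting the configured models.
#' @param out_dir Output directory.
#' @return Named list of `sigburst_fit`s, invisibly; per-model JSON on disk.
#' @export
run_fit <- function(cfg, table, screen = FALSE, out_dir = cfg$out_dir) {
  stopifnot(inherits(cfg, "sigburst_config"))
  if (is.character(table)) table <- read_count_table(table)
  conds <- intersect(training_conditions(), unique(table$condition))
  if (length(conds) == 0) {
    rlang::abort(paste("refusing to train: the table contains only the",
      "held-out combined-inhibitor condition"),
      class = "sigburst_error_training")
  }
  ensure_dir(out_dir)
  o <- cfg$optimizer
  opt <- opt_config(n_starts = o$n_starts, method = o$method, maxit = o$maxit,
    seed = o$seed, fixed = o$fixed, fsp_args = cfg$fsp_args)
  templates <- if (screen) {
    screened_templates(cfg, table, conds, opt)
  } else {
    cfg$models
  }
  fits <- purrr::imap(templates, function(m, nm) {
    fit <- fit_model(m, table, conds = conds, opt = opt)
    write_fit_json(fit, file.path(out_dir, paste0("fit_", nm, ".json")))
    fit
  })
  write_manifest(cfg, "fit", file.path(out_dir, "fit_manifest.json"),
    list(models = names(fits), conditions = conds,
      optimizer_seed = o$seed))
  invisible(fits)
}

screened_templates <- function(cfg, table, conds, opt) {
  genes <- grep("_count$", names(table), value = TRUE)
  genes <- sub("_count$", "", genes)
  signal0 <- cfg$models[[1]]$signal
  keep <- purrr::map(rlang::set_names(genes), function(g) {
    sc <- screen_single_gene(table, g, signal = signal0, opt = opt,
      conds = intersect("none", conds))
    n_keep <- if (cfg$full_screen) nrow(sc) else min(cfg$screen_top, nrow(sc))
    purrr::map(sc$topology[seq_len(n_keep)],
      function(nm) enumerate_single_gene_topologies()[[nm]])
  })
  enumerate_combinatorial_models(keep, signal0)
}

#' Pipeline stage: rank fits by combined fit + prediction score
#'
#' @param cfg A [pipeline_config()].
#' @param fits Named list of `sigburst_fit`s (from [run_fit()]).
#' @param table Count table containing the `both` condition.
#' @param out_dir Output directory.
#' @return The ranking tibble, invisibly; `ranking.tsv` on disk.
#' @export
run_select <- function(cfg, fits, table, out_dir = cfg$out_dir) {
  stopifnot(inherits(cfg, "sigburst_config"))
  if (is.character(table)) table <- read_count_table(table)
  ensure_dir(out_dir)
  ranking <- rank_models(fits, table)
  utils::write.table(ranking, file.path(out_dir, "ranking.tsv"), sep = "\t",
    row.names = FALSE, quote = FALSE)
  write_manifest(cfg, "select", file.path(out_dir, "select_manifest.json"),
    list(best = ranking$model[1]))
  invisible(ranking)
}

#' Pipeline stage: predict the combined-drug condition
#'
#' @param cfg A [pipeline_config()].
#' @param fit The winning `sigburst_fit`.
#' @param out_dir Output directory.
#' @return The `sigburst_prediction`, invisibly; JSON + TSV on disk.
#' @export
run_predict <- function(cfg, fit, out_dir = cfg$out_dir) {
  stopifnot(inherits(cfg, "sigburst_config"))
  ensure_dir(out_dir)
  pred <- predict_combined(fit, times = cfg$design$times,
    fsp_args = cfg$fsp_args)
  write_prediction(pred, file.path(out_dir, paste0("predict_",
    fit$model$name)))
  write_manifest(cfg, "predict", file.path(out_dir, "predict_manifest.json"),
    list(model = fit$model$name))
  invisible(pred)
}

#' Pipeline stage: summary report of a fitted model
#'
#' Emits mean/SD-versus-time tables, gene-state occupancy and mean
#' transcription-rate tables for every condition, and the headline rate
#' ratios, as TSVs plus a JSON report.
#'
#' @param cfg A [pipeline_config()].
#' @param fit A `sigburst_fit` (or [combinatorial_model()]).
#' @param out_dir Output directory.
#' @return Invisibly, a list of the report tables.
#' @export
run_report <- function(cfg, fit, out_dir = cfg$out_dir) {
  stopifnot(inherits(cfg, "sigburst_config"))
  ensure_dir(out_dir)
  model <- as_sigburst_model(fit)
  conds <- cfg$design$conditions
  sols <- purrr::map(rlang::set_names(names(model$genes)), function(g) {
    purrr::map(rlang::set_names(conds), function(cond) {
      do.call(fsp_solve, c(list(gene = model$genes[[g]], condition = cond,
        sp = model$signal, times = cfg$design$times), cfg$fsp_args))
    })
  })
  collect <- function(fun) {
    purrr::imap_dfr(sols, function(bycond, g) {
      purrr::imap_dfr(bycond, function(sol, cond) {
        dplyr::mutate(fun(sol), gene = g, condition = cond, .before = 1)
      })
    })
  }
  tabs <- list(
    moments = collect(fsp_moments),
    occupancy = collect(state_occupancy),
    mean_rate = collect(mean_transcription_rate),
    ratios = summarize_rates(model))
  for (nm in names(tabs)) {
    utils::write.table(tabs[[nm]], file.path(out_dir,
      paste0("report_", nm, ".tsv")), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
  jsonlite::write_json(c(stage_manifest(cfg, "report",
    list(model = model$name)), list(ratios = tabs$ratios)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(tabs)
}

#' Run the full pipeline
#'
#' simulate -> fit -> select -> predict -> report, writing every stage's
#' artifacts under the configured output directory.
#'
#' @param config Path to a YAML config, or a config list.
#' @param screen Use the two-stage topology screen in the fit stage.
#' @return Invisibly, a list with the table, fits, ranking, prediction and
#'   report tables.
#' @export
run_pipeline <- function(config, screen = FALSE) {
  cfg <- pipeline_config(config)
  tab <- run_simulate(cfg)
  fits <- run_fit(cfg, dplyr::filter(tab, .data$condition != "both"),
    screen = screen)
  ranking <- run_select(cfg, fits, tab)
  best <- fits[[ranking$model[1]]]
  pred <- run_predict(cfg, best)
  report <- run_report(cfg, best)
  invisible(list(table = tab, fits = fits, ranking = ranking,
    prediction = pred, report = report))
}
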