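# Configuration and run I/O: JSON model configs, run manifests, and the
# calibrate / simulate / design command entry points used by the CLI script.

#' Read / write a culture model configuration
#'
#' The model config is a JSON document with fields `V0`, `seed_density`,
#' `secretion` (kind + parameters) and `groups` (id, members, expression
#' weight, CD34 flag, growth correlation kind + parameters). Malformed
#' configs raise errors naming the offending field.
#'
#' @param path JSON file path.
#' @return A [culture_model()] (reader); the path, invisibly (writer).
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  for (f in c("V0", "seed_density", "groups", "secretion"))
    if (is.null(cfg[[f]]))
      stop(sprintf("model config '%s': missing field '%s'", path, f),
           call. = FALSE)
  groups <- lapply(cfg$groups, function(g) {
    for (f in c("id", "w", "growth"))
      if (is.null(g[[f]]))
        stop(sprintf("model config group entry missing field '%s'", f),
             call. = FALSE)
    gc <- g$growth
    corr <- if (identical(gc$kind, "exponential")) {
      growth_correlation("exponential", a = gc$a, b = gc$b,
                         domain = if (!is.null(gc$domain)) unlist(gc$domain))
    } else if (identical(gc$kind, "spline")) {
      growth_correlation("spline", knots_conc = unlist(gc$knots_conc),
                         knots_rate = unlist(gc$knots_rate),
                         domain = if (!is.null(gc$domain)) unlist(gc$domain))
    } else stop(sprintf("unknown growth correlation kind '%s'", gc$kind),
                call. = FALSE)
    phenotype_group(g$id, corr, w = g$w, is_cd34 = isTRUE(g$is_cd34),
                    members = if (!is.null(g$members)) unlist(g$members)
                              else character())
  })
  sec <- cfg$secretion
  secretion <- if (identical(sec$kind, "constant_per_cell")) {
    secretion_correlation("constant_per_cell", s = sec$s)
  } else if (identical(sec$kind, "spline")) {
    secretion_correlation("spline", knots_cells = unlist(sec$knots_cells),
                          knots_rate = unlist(sec$knots_rate))
  } else stop(sprintf("unknown secretion correlation kind '%s'", sec$kind),
              call. = FALSE)
  culture_model(groups, secretion, V0 = cfg$V0,
                seed_density = cfg$seed_density)
}

#' @rdname read_model_config
#' @param model A [culture_model()].
#' @export
write_model_config <- function(model, path) {
  groups <- lapply(model$groups, function(g) {
    gc <- g$growth
    growth <- if (gc$kind == "exponential")
      list(kind = "exponential", a = gc$a, b = gc$b, domain = gc$domain)
    else
      list(kind = "spline", knots_conc = gc$knots_conc,
           knots_rate = gc$knots_rate, domain = gc$domain)
    list(id = g$id, members = g$members, w = g$w, is_cd34 = g$is_cd34,
         growth = growth)
  })
  sec <- model$secretion
  secretion <- if (sec$kind == "constant_per_cell")
    list(kind = "constant_per_cell", s = sec$s)
  else
    list(kind = "spline", knots_cells = sec$knots_cells,
         knots_rate = sec$knots_rate)
  cfg <- list(V0 = model$V0, seed_density = model$seed_density,
              groups = unname(groups), secretion = secretion)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.config_hash <- function(obj) {
  # stable content fingerprint without extra dependencies
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, force = TRUE)
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(as.character(s))) %% 97 + 1)) %% 1e9
}

.write_manifest <- function(dir, seed, config) {
  manifest <- list(package = "hspcfeed",
                   version = as.character(utils::packageVersion("hspcfeed")),
                   seed = seed, config_hash = .config_hash(config),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Calibrate a model from time-course CSVs (command entry point)
#'
#' Reads one CSV per dilution scheme, runs [calibrate_model()], and writes
#' the fitted model config plus a JSON fit report.
#'
#' @param timecourse_paths Character vector of time-course CSV paths.
#' @param weights Named numeric vector of per-group expression weights.
#' @param cd34_groups Character vector of CD34+ group ids.
#' @param out_model Path for the fitted model JSON.
#' @param growth_kind,secretion_kind Passed to [calibrate_model()].
#' @param V0,seed_density Seeding parameters for the fitted model.
#' @return The fitted [culture_model()], invisibly.
#' @export
cmd_calibrate <- function(timecourse_paths, weights, cd34_groups, out_model,
                          growth_kind = "auto",
                          secretion_kind = "constant_per_cell",
                          V0 = 1, seed_density = 1e5) {
  tables <- lapply(timecourse_paths, read_timecourse_csv)
  model <- calibrate_model(tables, weights, cd34_groups,
                           growth_kind = growth_kind,
                           secretion_kind = secretion_kind,
                           V0 = V0, seed_density = seed_density)
  write_model_config(model, out_model)
  rep_path <- sub("\\.json$", "_fit_report.json", out_model)
  jsonlite::write_json(attr(model, "fit_report"), rep_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(model)
}

#' Simulate a run config (command entry point)
#'
#' Runs one simulation (or a replicate ensemble when `n > 1`), writing the
#' tidy trajectory CSV, the event log CSV and a manifest (seed, config
#' hash, package version) to `out_dir`.
#'
#' @param model A [culture_model()] or path to a model config JSON.
#' @param schedule A [feeding_schedule()].
#' @param out_dir Output directory (created if needed).
#' @param n Number of replicates; 1 uses the model's nominal even-split
#'   seeding, `> 1` draws initial populations from `sampler`.
#' @param sampler A [population_sampler()] (required when `n > 1`).
#' @param seed Integer seed.
#' @param horizon,mm,dt_max Passed to [run_simulation()].
#' @return The `simulation_result` (or list of them), invisibly.
#' @export
cmd_simulate <- function(model, schedule, out_dir, n = 1, sampler = NULL,
                         seed = 1, horizon = 16, mm = measurement_model(),
                         dt_max = 0.01) {
  if (is.character(model)) model <- read_model_config(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (n == 1) {
    res <- run_simulation(model, schedule, horizon = horizon, mm = mm,
                          dt_max = dt_max, seed = seed)
    utils::write.csv(res$trajectory, file.path(out_dir, "trajectory.csv"),
                     row.names = FALSE)
    utils::write.csv(res$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
  } else {
    if (is.null(sampler))
      stop("replicate simulation requires a population sampler", call. = FALSE)
    res <- run_replicates(model, sampler, schedule, n = n, base_seed = seed,
                          horizon = horizon, mm = mm, dt_max = dt_max)
    for (i in seq_along(res)) {
      utils::write.csv(res[[i]]$trajectory,
                       file.path(out_dir, sprintf("trajectory_%03d.csv", i)),
                       row.names = FALSE)
    }
  }
  .write_manifest(out_dir, seed, list(schedule = schedule$kind,
                                      horizon = horizon, n = n))
  invisible(res)
}

#' Design-space evaluation (command entry point)
#'
#' Thin wrapper over the design module: `subcommand` selects
#' `"compare"` ([compare_strategies()]), `"sweep"` ([sweep_design()]),
#' `"minfold"` ([minimum_fold_volume()]) or `"tune"` ([tune_pid()]).
#' Results are written as CSV (plus manifest) to `out_dir` and returned.
#'
#' @param subcommand One of `"compare"`, `"sweep"`, `"minfold"`, `"tune"`.
#' @param model A [culture_model()] or model config path.
#' @param sampler A [population_sampler()].
#' @param out_dir Output directory.
#' @param seed Integer base seed.
#' @param ... Arguments forwarded to the selected design function.
#' @return The design function's value, invisibly.
#' @export
cmd_design <- function(subcommand = c("compare", "sweep", "minfold", "tune"),
                       model, sampler, out_dir, seed = 1, ...) {
  subcommand <- match.arg(subcommand)
  if (is.character(model)) model <- read_model_config(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(subcommand,
    compare = compare_strategies(model, sampler, base_seed = seed, ...),
    sweep = sweep_design(model, sampler, base_seed = seed, ...),
    minfold = minimum_fold_volume(model, sampler, base_seed = seed, ...),
    tune = tune_pid(model, sampler, base_seed = seed, ...))
  out <- switch(subcommand,
    compare = res,
    sweep = res,
    minfold = attr(res, "diagnostics"),
    tune = attr(res, "picks"))
  utils::write.csv(out, file.path(out_dir, paste0(subcommand, ".csv")),
                   row.names = FALSE)
  .write_manifest(out_dir, seed, list(subcommand = subcommand))
  invisible(res)
}
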