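# Bioprocess design evaluation: volumetric efficiency, the differentiation
# constraints derived from retrospective fed-batch cultures, and the design
# sweeps (set point, sampling period, fold-volume budget, strategy ranking).

#' Differentiation-avoidance design constraints
#'
#' Retrospective analysis of fed-batch cultures showed two predictors of
#' end-of-culture CD34+ loss: a high final concentration and long cumulative
#' exposure to high concentrations. A design passes when the endpoint
#' concentration stays below `endpoint_max_conc` and the fraction of culture
#' time above `high_conc_threshold` does not exceed `max_fraction_above`.
#'
#' @param high_conc_threshold High-exposure concentration, pg/mL (default
#'   150).
#' @param max_fraction_above Maximum tolerated fraction of culture time above
#'   the high threshold (default 0.15).
#' @param endpoint_max_conc Maximum endpoint concentration, pg/mL (default
#'   400).
#' @param required_replicate_pass_fraction Fraction of replicates that must
#'   pass for a design to be feasible (default 0.85).
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(high_conc_threshold = 150,
                               max_fraction_above = 0.15,
                               endpoint_max_conc = 400,
                               required_replicate_pass_fraction = 0.85) {
  stopifnot(high_conc_threshold > 0, endpoint_max_conc > 0,
            max_fraction_above > 0, max_fraction_above <= 1,
            required_replicate_pass_fraction > 0,
            required_replicate_pass_fraction <= 1)
  structure(list(high_conc_threshold = high_conc_threshold,
                 max_fraction_above = max_fraction_above,
                 endpoint_max_conc = endpoint_max_conc,
                 required_replicate_pass_fraction =
                   required_replicate_pass_fraction),
            class = "design_constraints")
}

#' Fraction of time a piecewise-linear trajectory spends above a threshold
#'
#' Computes the exact occupancy of `{C > threshold}` under linear
#' interpolation between trajectory points, including partial segments at
#' threshold crossings.
#'
#' @param time,C Trajectory samples (equal length, `time` non-decreasing).
#' @param threshold Threshold value.
#' @return Fraction of `[min(time), max(time)]` spent strictly above the
#'   threshold.
#' @export
time_above_fraction <- function(time, C, threshold) {
  stopifnot(length(time) == length(C), length(time) >= 2)
  total <- time[length(time)] - time[1]
  if (total <= 0) return(0)
  above <- 0
  for (i in seq_len(length(time) - 1L)) {
    dt <- time[i + 1L] - time[i]
    if (dt <= 0) next
    c1 <- C[i]; c2 <- C[i + 1L]
    if (c1 > threshold && c2 > threshold) {
      above <- above + dt
    } else if (c1 > threshold || c2 > threshold) {
      tc <- (threshold - c1) / (c2 - c1)  # crossing fraction within segment
      above <- above + dt * if (c1 > threshold) tc else (1 - tc)
    }
  }
  above / total
}

#' Time-averaged concentration during the controller action phase
#'
#' The action phase runs from the first to the last controller-triggered
#' media delivery (positive-volume `pid_bolus`, `pid_flow` or `rtc_bolus`
#' event). The mean is time-weighted (trapezoidal) over the dense simulated
#' trajectory.
#'
#' @param result A [run_simulation()] result from a feedback schedule.
#' @return Mean concentration, pg/mL (`NA` if the controller never fired).
#' @export
action_phase_mean_conc <- function(result) {
  ev <- result$events
  fired <- ev$type %in% c("pid_bolus", "pid_flow", "rtc_bolus") & ev$volume > 0
  if (!any(fired)) return(NA_real_)
  t1 <- min(ev$time[fired]); t2 <- max(ev$time[fired])
  if (t2 <= t1) return(result$trajectory$C[which(result$trajectory$time >= t1)[1]])
  tr <- result$trajectory[result$trajectory$time >= t1 - 1e-9 &
                          result$trajectory$time <= t2 + 1e-9, ]
  tt <- tr$time; cc <- tr$C
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2) /
    (tt[length(tt)] - tt[1])
}

#' Bioprocess metrics of one simulated culture
#'
#' Fold expansions are end-of-horizon over day-0 ratios; the CD34+
#' compartment is the sum over groups flagged `is_cd34`. Volumetric
#' efficiency is fold CD34+ expansion divided by fold volume increase — the
#' cost-efficiency objective (HSPC output per unit of media).
#'
#' @param result A [run_simulation()] result.
#' @param model The [culture_model()] used (defaults to the one stored in
#'   `result`).
#' @param constraints A [design_constraints()] used for the pass flag.
#' @return An object of class `strategy_metrics` (a list): fold_total_expansion,
#'   fold_cd34_expansion, fold_volume_increase, volumetric_efficiency,
#'   time_above_fraction, endpoint_conc, media_used, constraint_pass.
#' @export
compute_metrics <- function(result, model = result$model,
                            constraints = design_constraints()) {
  traj <- result$trajectory
  ids <- group_ids(model)
  cd34 <- ids[cd34_flags(model)]
  n0 <- as.numeric(traj[1, ids, drop = TRUE])
  n1 <- as.numeric(traj[nrow(traj), ids, drop = TRUE])
  cd0 <- sum(as.numeric(traj[1, cd34, drop = TRUE]))
  cd1 <- sum(as.numeric(traj[nrow(traj), cd34, drop = TRUE]))
  if (cd0 <= 0) stop("zero initial CD34+ cells: metrics undefined", call. = FALSE)
  fold_volume <- traj$V[nrow(traj)] / traj$V[1]
  m <- list(
    fold_total_expansion = sum(n1) / sum(n0),
    fold_cd34_expansion = cd1 / cd0,
    fold_volume_increase = fold_volume,
    volumetric_efficiency = (cd1 / cd0) / fold_volume,
    time_above_fraction = time_above_fraction(traj$time, traj$C,
                                              constraints$high_conc_threshold),
    endpoint_conc = traj$C[nrow(traj)],
    media_used = result$state$media_used + traj$V[1]
  )
  m$constraint_pass <- check_constraints(m, constraints)$pass
  structure(m, class = "strategy_metrics")
}

#' Check the differentiation-avoidance constraints
#'
#' Boundary conventions: "more than 15% of the time" fails strictly above
#' `max_fraction_above` (a fraction of exactly 0.15 passes); "exceed 400
#' pg/mL by the endpoint" fails at or above `endpoint_max_conc`.
#'
#' @param metrics A [compute_metrics()] result (or any list with
#'   `endpoint_conc` and `time_above_fraction`).
#' @param constraints A [design_constraints()].
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   violated clauses, empty on pass).
#' @export
check_constraints <- function(metrics, constraints = design_constraints()) {
  reasons <- character()
  if (metrics$endpoint_conc >= constraints$endpoint_max_conc)
    reasons <- c(reasons, sprintf("endpoint concentration %.3g >= %g pg/mL",
                                  metrics$endpoint_conc,
                                  constraints$endpoint_max_conc))
  if (metrics$time_above_fraction > constraints$max_fraction_above)
    reasons <- c(reasons,
                 sprintf("time above %g pg/mL is %.3g > %.3g of culture time",
                         constraints$high_conc_threshold,
                         metrics$time_above_fraction,
                         constraints$max_fraction_above))
  list(pass = length(reasons) == 0, reasons = reasons)
}

.ensemble_metrics <- function(runs, model, constraints = design_constraints()) {
  do.call(rbind, lapply(runs, function(r) {
    m <- compute_metrics(r, model, constraints)
    data.frame(fold_total = m$fold_total_expansion,
               fold_cd34 = m$fold_cd34_expansion,
               fold_volume = m$fold_volume_increase,
               efficiency = m$volumetric_efficiency,
               time_above = m$time_above_fraction,
               endpoint_conc = m$endpoint_conc,
               media_used = m$media_used,
               pass = m$constraint_pass)
  }))
}

#' Minimum feasible fold-volume budget for a PID design
#'
#' Walks an ascending grid of fold-volume saturation limits and returns the
#' smallest one whose replicate ensemble satisfies the constraints in at
#' least `required_replicate_pass_fraction` of runs.
#'
#' @param model A [culture_model()].
#' @param sampler A [population_sampler()].
#' @param cfg A [pid_config()] (its `max_fold_volume` is overridden by each
#'   grid entry).
#' @param fold_grid Ascending fold-volume candidates.
#' @param n Replicates per candidate.
#' @param constraints A [design_constraints()].
#' @param base_seed,horizon,mm,dt_max Passed to [run_replicates()].
#' @return The minimal feasible fold (numeric), or `NA` if none passes; the
#'   per-fold pass fractions are attached as `attr(, "diagnostics")`.
#' @export
minimum_fold_volume <- function(model, sampler, cfg, fold_grid, n = 20,
                                constraints = design_constraints(),
                                base_seed = 1, horizon = 16,
                                mm = measurement_model(), dt_max = 0.01) {
  stopifnot(!is.unsorted(fold_grid))
  diag <- data.frame()
  feasible <- NA_real_
  for (fold in fold_grid) {
    cfg_f <- cfg
    cfg_f$max_fold_volume <- fold
    runs <- run_replicates(model, sampler,
                           feeding_schedule("pid", controller = cfg_f,
                                            V0 = model$V0, horizon = horizon),
                           n = n, base_seed = base_seed, horizon = horizon,
                           mm = mm, dt_max = dt_max)
    em <- .ensemble_metrics(runs, model, constraints)
    frac <- mean(em$pass)
    diag <- rbind(diag, data.frame(fold = fold, pass_fraction = frac))
    if (is.na(feasible) && frac >= constraints$required_replicate_pass_fraction)
      feasible <- fold
  }
  structure(feasible, diagnostics = diag)
}

#' Full-factorial design sweep
#'
#' Runs a replicate ensemble for every (set point, sampling period,
#' fold-volume) cell and summarises fold CD34+ expansion and volumetric
#' efficiency as mean and SD.
#'
#' @param model A [culture_model()].
#' @param sampler A [population_sampler()].
#' @param setpoint_grid,Ts_grid,fold_grid Nonempty design grids.
#' @param n Replicates per cell.
#' @param Kp,Kd,N,derivative_scheme,output_mode Controller settings held
#'   fixed across the sweep.
#' @param base_seed,horizon,mm,dt_max Passed to [run_replicates()].
#' @return Data frame, one row per design cell, with the argmax (by mean
#'   CD34 expansion) attached as `attr(, "best")`.
#' @export
sweep_design <- function(model, sampler, setpoint_grid, Ts_grid, fold_grid,
                         n = 20, Kp = 1, Kd = 0, N = 1,
                         derivative_scheme = "forward", output_mode = "bolus",
                         base_seed = 1, horizon = 16,
                         mm = measurement_model(), dt_max = 0.01) {
  if (!length(setpoint_grid) || !length(Ts_grid) || !length(fold_grid))
    stop("design grids must be nonempty", call. = FALSE)
  cells <- expand.grid(setpoint = setpoint_grid, Ts = Ts_grid,
                       fold = fold_grid)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cfg <- pid_config(Kp = Kp, Kd = Kd, N = N, Ts = cells$Ts[i],
                      setpoint = cells$setpoint[i],
                      max_fold_volume = cells$fold[i],
                      derivative_scheme = derivative_scheme,
                      output_mode = output_mode)
    runs <- run_replicates(model, sampler,
                           feeding_schedule("pid", controller = cfg,
                                            V0 = model$V0, horizon = horizon),
                           n = n, base_seed = base_seed, horizon = horizon,
                           mm = mm, dt_max = dt_max)
    em <- .ensemble_metrics(runs, model)
    data.frame(setpoint = cells$setpoint[i], Ts = cells$Ts[i],
               fold = cells$fold[i], n = n,
               mean_fold_cd34 = mean(em$fold_cd34),
               sd_fold_cd34 = stats::sd(em$fold_cd34),
               mean_efficiency = mean(em$efficiency),
               sd_efficiency = stats::sd(em$efficiency),
               base_seed = base_seed)
  }))
  attr(out, "best") <- out[which.max(out$mean_fold_cd34), , drop = FALSE]
  out
}

#' Compare feeding strategies on a common replicate ensemble
#'
#' Simulates every strategy on the same initial populations (shared seeds,
#' so comparisons are paired), summarises the metrics, and ranks by
#' media-normalised CD34+ output (fold CD34+ expansion per mL of total
#' media used). Pairwise two-sided Welch t statistics on fold CD34+
#' expansion are attached as descriptive statistics.
#'
#' @param model A [culture_model()].
#' @param sampler A [population_sampler()].
#' @param strategies Named list of [feeding_schedule()]s.
#' @param horizon Culture duration, days.
#' @param n Replicates per strategy.
#' @param base_seed,mm,dt_max Passed to [run_replicates()].
#' @return Data frame ranked by media-normalised CD34+ output, with the
#'   pairwise Welch p-value matrix in `attr(, "welch_p")` and per-strategy
#'   metric ensembles in `attr(, "ensembles")`.
#' @export
compare_strategies <- function(model, sampler, strategies, horizon = 16,
                               n = 20, base_seed = 1,
                               mm = measurement_model(), dt_max = 0.01) {
  stopifnot(is.list(strategies), length(strategies) >= 1,
            !is.null(names(strategies)))
  ens <- lapply(strategies, function(s) {
    runs <- run_replicates(model, sampler, s, n = n, base_seed = base_seed,
                           horizon = horizon, mm = mm, dt_max = dt_max)
    .ensemble_metrics(runs, model)
  })
  tab <- do.call(rbind, lapply(names(ens), function(nm) {
    em <- ens[[nm]]
    data.frame(strategy = nm, n = n,
               mean_fold_cd34 = mean(em$fold_cd34),
               sd_fold_cd34 = stats::sd(em$fold_cd34),
               mean_fold_total = mean(em$fold_total),
               mean_efficiency = mean(em$efficiency),
               mean_media_used = mean(em$media_used),
               cd34_per_ml_media = mean(em$fold_cd34 / em$media_used),
               base_seed = base_seed)
  }))
  tab <- tab[order(-tab$cd34_per_ml_media), , drop = FALSE]
  rownames(tab) <- NULL
  nm <- names(ens)
  pmat <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  if (length(nm) > 1 && n > 1) {
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (i == j) next
      x <- ens[[i]]$fold_cd34; y <- ens[[j]]$fold_cd34
      pmat[i, j] <- tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
                             error = function(e) NA_real_)
    }
  }
  attr(tab, "welch_p") <- pmat
  attr(tab, "ensembles") <- ens
  tab
}
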