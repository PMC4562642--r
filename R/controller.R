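# Discrete PID control law for feedback dilution: proportional + filtered
# derivative (integral fixed at zero for this non-steady-state process),
# with forward/backward Euler discretizations of the derivative filter,
# flow-to-bolus conversion and a permanent volume-saturation latch.

#' PID controller configuration
#'
#' The control law acts on the error `e_k = C_k - setpoint` (so
#' above-set-point concentrations drive dilution) and outputs a media flow
#' rate `U_k = max(0, Kp * e_k + d_k)` — media can be added but never
#' removed. The derivative term `d_k` is the discretization of the filtered
#' derivative `Kd * N * s / (s + N)`:
#' * backward Euler: `d_k = (d_{k-1} + Kd * N * (e_k - e_{k-1})) / (1 + N * h)`
#' * forward Euler:  `d_k = (1 - N * h) * d_{k-1} + Kd * N * (e_k - e_{k-1})`
#'
#' with `h` the sampling period in days. The forward scheme requires
#' `N * h < 1` (filter stability). The integral gain is fixed at zero:
#' cumulative error does not help a process that never reaches steady state.
#'
#' @param Kp Proportional gain, (mL/day)/(pg/mL), `> 0`.
#' @param Kd Derivative gain, (mL/day)/((pg/mL)/day), `>= 0`.
#' @param N Derivative filter coefficient, 1/day, `> 0`.
#' @param Ts Sampling period, hours, `> 0`.
#' @param setpoint Target concentration, pg/mL.
#' @param max_fold_volume Saturation limit: the controller latches off
#'   permanently once `V >= max_fold_volume * V0`. `> 1`.
#' @param derivative_scheme `"forward"` or `"backward"` Euler.
#' @param output_mode `"bolus"` (flow converted to a bolus each sample) or
#'   `"flow"` (constant inflow over the sampling interval).
#' @return An object of class `pid_config`.
#' @export
pid_config <- function(Kp, Kd = 0, N = 1, Ts = 12, setpoint = 85,
                       max_fold_volume = 50,
                       derivative_scheme = c("forward", "backward"),
                       output_mode = c("bolus", "flow")) {
  derivative_scheme <- match.arg(derivative_scheme)
  output_mode <- match.arg(output_mode)
  stopifnot(is.finite(Kp), Kp > 0, is.finite(Kd), Kd >= 0,
            is.finite(N), N > 0, is.finite(Ts), Ts > 0,
            is.finite(setpoint), setpoint >= 0,
            is.finite(max_fold_volume), max_fold_volume > 1)
  if (derivative_scheme == "forward" && N * Ts / 24 >= 1)
    stop("forward Euler derivative filter is unstable: need N * Ts/24 < 1",
         call. = FALSE)
  structure(list(Kp = Kp, Ki = 0, Kd = Kd, N = N, Ts = Ts,
                 setpoint = setpoint, max_fold_volume = max_fold_volume,
                 derivative_scheme = derivative_scheme,
                 output_mode = output_mode),
            class = "pid_config")
}

#' @export
print.pid_config <- function(x, ...) {
  cat(sprintf("pid_config: Kp = %g, Kd = %g, N = %g /day, Ts = %g h, setpoint = %g pg/mL\n",
              x$Kp, x$Kd, x$N, x$Ts, x$setpoint))
  cat(sprintf("  %s derivative, %s output, saturation at %g-fold volume\n",
              x$derivative_scheme, x$output_mode, x$max_fold_volume))
  invisible(x)
}

#' PID controller memory
#'
#' Holds the previous error, the previous filtered-derivative term and the
#' activity latch. Once deactivated by volume saturation the controller
#' never reactivates.
#'
#' @param e_prev,d_prev Initial recurrence memory (defaults 0).
#' @return An object of class `pid_state`.
#' @export
pid_state <- function(e_prev = 0, d_prev = 0) {
  structure(list(e_prev = e_prev, d_prev = d_prev, active = TRUE,
                 t_on = NA_real_, t_off = NA_real_),
            class = "pid_state")
}

#' One PID controller update
#'
#' Computes the new filtered-derivative term, the raw output
#' `Kp * e_k + d_k` and the clipped flow `U_k = max(0, raw)`, and advances
#' the recurrence memory.
#'
#' @param cfg A [pid_config()].
#' @param st A [pid_state()] (must be active).
#' @param measured Measured concentration, pg/mL.
#' @param h Step length in days (the sampling period `Ts / 24`).
#' @return List with `U` (mL/day), `e`, `d`, and the updated `state`.
#' @export
pid_step <- function(cfg, st, measured, h) {
  stopifnot(inherits(cfg, "pid_config"), inherits(st, "pid_state"), h > 0)
  if (!st$active) return(list(U = 0, e = NA_real_, d = NA_real_, state = st))
  if (cfg$derivative_scheme == "forward" && cfg$N * h >= 1)
    stop("forward Euler derivative filter is unstable: need N * h < 1",
         call. = FALSE)
  e <- measured - cfg$setpoint
  de <- e - st$e_prev
  d <- if (cfg$derivative_scheme == "backward")
    (st$d_prev + cfg$Kd * cfg$N * de) / (1 + cfg$N * h)
  else
    (1 - cfg$N * h) * st$d_prev + cfg$Kd * cfg$N * de
  U <- max(0, cfg$Kp * e + d)
  st$e_prev <- e
  st$d_prev <- d
  list(U = U, e = e, d = d, state = st)
}

#' Convert a controller flow rate to a bolus volume
#'
#' The flow rate held over one sampling interval: `bolus = U * Ts / 24` mL.
#'
#' @param U Flow rate, mL/day, `>= 0`.
#' @param Ts Sampling period, hours.
#' @return Bolus volume, mL.
#' @export
flow_to_bolus <- function(U, Ts) {
  stopifnot(U >= 0, Ts > 0)
  U * Ts / 24
}

#' Volume-saturation latch
#'
#' Deactivates the controller permanently once the culture volume has
#' reached `max_fold_volume * V0`. Bolus truncation so the limit is never
#' exceeded is handled by the simulator at delivery time.
#'
#' @param state A [culture_state()].
#' @param cfg A [pid_config()].
#' @param st A [pid_state()].
#' @param V0 Initial culture volume, mL.
#' @return The (possibly deactivated) `pid_state`.
#' @export
check_saturation <- function(state, cfg, st, V0 = state$V - state$V_added) {
  if (st$active && state$V >= cfg$max_fold_volume * V0 - 1e-9) {
    st$active <- FALSE
    st$t_off <- state$t
  }
  st
}

#' Simple threshold ("real-time control") comparator
#'
#' The prior feedback rule used as a baseline: whenever the measured
#' concentration exceeds `threshold`, dilute back down to `target` in one
#' bolus.
#'
#' @param threshold Trigger concentration, pg/mL.
#' @param target Post-dilution target, pg/mL, `<= threshold`.
#' @param Ts Sampling period, hours.
#' @return An object of class `rtc_config`.
#' @export
rtc_config <- function(threshold = 85, target = 85, Ts = 24) {
  stopifnot(threshold > 0, target > 0, Ts > 0)
  if (target > threshold)
    stop("rtc target must be <= threshold", call. = FALSE)
  structure(list(threshold = threshold, target = target, Ts = Ts),
            class = "rtc_config")
}

#' One threshold-controller update
#'
#' @param cfg An [rtc_config()].
#' @param state A [culture_state()].
#' @param measured Measured concentration, pg/mL.
#' @return Bolus volume, mL (`V * (C/target - 1)` when triggered, else 0).
#' @export
rtc_step <- function(cfg, state, measured) {
  stopifnot(inherits(cfg, "rtc_config"))
  if (measured > cfg$threshold) state$V * (measured / cfg$target - 1) else 0
}

#' Tune the PID gains by staged grid search
#'
#' Mirrors manual tuning practice: (1) find the best proportional gain with
#' the derivative off, scoring each candidate by the ensemble mean
#' volumetric efficiency; (2) holding that `Kp`, search the
#' `(Kd, N)` grid. The exercise is repeated for every fold-volume budget in
#' `fold_grid`; because factor accumulation is identical across budgets up
#' to the saturation time, the per-budget optima typically coincide and the
#' consensus (modal) gains are returned.
#'
#' @param model A [culture_model()].
#' @param sampler A [population_sampler()].
#' @param fold_grid Fold-volume budgets to repeat the exercise over.
#' @param Kp_grid,Kd_grid,N_grid Candidate gains.
#' @param n Replicates per candidate.
#' @param base_seed Ensemble seed (shared across candidates, so comparisons
#'   are paired).
#' @param setpoint,Ts,derivative_scheme,output_mode Fixed design settings.
#' @param horizon,mm,dt_max Passed to [run_replicates()].
#' @return The consensus [pid_config()]; the full objective surface is
#'   attached as `attr(, "surface")`.
#' @export
tune_pid <- function(model, sampler, fold_grid = 50,
                     Kp_grid, Kd_grid = 0, N_grid = 1,
                     n = 10, base_seed = 1,
                     setpoint = 85, Ts = 12,
                     derivative_scheme = "forward", output_mode = "bolus",
                     horizon = 16, mm = measurement_model(), dt_max = 0.01) {
  if (!length(Kp_grid) || !length(Kd_grid) || !length(N_grid) ||
      !length(fold_grid))
    stop("tuning grids must be nonempty", call. = FALSE)

  score <- function(cfg) {
    runs <- run_replicates(model, sampler,
                           feeding_schedule("pid", controller = cfg,
                                            V0 = model$V0, horizon = horizon),
                           n = n, base_seed = base_seed, horizon = horizon,
                           mm = mm, dt_max = dt_max)
    mean(vapply(runs, function(r)
      compute_metrics(r, model)$volumetric_efficiency, 0))
  }

  surface <- list()
  picks <- data.frame()
  for (fold in fold_grid) {
    # stage 1: proportional only
    s1 <- vapply(Kp_grid, function(kp)
      score(pid_config(Kp = kp, Kd = 0, N = min(N_grid), Ts = Ts,
                       setpoint = setpoint, max_fold_volume = fold,
                       derivative_scheme = derivative_scheme,
                       output_mode = output_mode)), 0)
    kp_best <- Kp_grid[which.max(s1)]
    # stage 2: derivative + filter
    grid2 <- expand.grid(Kd = Kd_grid, N = N_grid)
    s2 <- vapply(seq_len(nrow(grid2)), function(j)
      score(pid_config(Kp = kp_best, Kd = grid2$Kd[j], N = grid2$N[j],
                       Ts = Ts, setpoint = setpoint, max_fold_volume = fold,
                       derivative_scheme = derivative_scheme,
                       output_mode = output_mode)), 0)
    jb <- which.max(s2)
    surface[[as.character(fold)]] <-
      list(stage1 = data.frame(Kp = Kp_grid, score = s1),
           stage2 = cbind(grid2, score = s2))
    picks <- rbind(picks, data.frame(fold = fold, Kp = kp_best,
                                     Kd = grid2$Kd[jb], N = grid2$N[jb],
                                     score = s2[jb]))
  }
  consensus <- function(v) as.numeric(names(sort(table(v), decreasing = TRUE))[1])
  cfg <- pid_config(Kp = consensus(picks$Kp), Kd = consensus(picks$Kd),
                    N = consensus(picks$N), Ts = Ts, setpoint = setpoint,
                    max_fold_volume = max(fold_grid),
                    derivative_scheme = derivative_scheme,
                    output_mode = output_mode)
  attr(cfg, "surface") <- surface
  attr(cfg, "picks") <- picks
  cfg
}
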