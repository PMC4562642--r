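# Event-driven fed-batch simulator: continuous growth/secretion dynamics
# integrated with fixed-step RK4, punctuated by instantaneous boluses, media
# exchanges and controller sampling instants.

# Compile a culture_model into fast closures evaluated once per RK4 stage.
.compile_model <- function(model) {
  gfuns <- lapply(model$groups, function(g) {
    corr <- g$growth
    if (corr$kind == "exponential") {
      a <- corr$a; b <- corr$b
      lo <- corr$domain[1]; hi <- corr$domain[2]
      function(C) a * exp(b * min(max(C, lo), hi))
    } else {
      f <- .spline_fun(corr$knots_conc, corr$knots_rate)
      lo <- max(corr$domain[1], min(corr$knots_conc))
      hi <- min(corr$domain[2], max(corr$knots_conc))
      function(C) f(min(max(C, lo), hi))
    }
  })
  sec <- model$secretion
  if (sec$kind == "constant_per_cell") {
    s <- sec$s
    sfun <- function(a) s * a
  } else {
    f <- .spline_fun(sec$knots_cells, sec$knots_rate)
    lo <- min(sec$knots_cells); hi <- max(sec$knots_cells)
    sfun <- function(a) max(f(min(max(a, lo), hi)), 0)
  }
  list(gfuns = gfuns, w = group_weights(model), sfun = sfun,
       ng = length(gfuns), ids = group_ids(model))
}

# RHS on the packed vector y = c(N_1..N_g, M, V).
.rhs <- function(y, cm, inflow) {
  ng <- cm$ng
  V <- y[ng + 2L]
  C <- y[ng + 1L] / V
  rates <- numeric(ng)
  for (i in seq_len(ng)) rates[i] <- cm$gfuns[[i]](C)
  adj <- sum(cm$w * y[seq_len(ng)])
  c(rates * y[seq_len(ng)], cm$sfun(adj), inflow)
}

.rk4_segment <- function(y, t1, t2, dt_max, cm, inflow = 0, record = TRUE) {
  span <- t2 - t1
  if (span <= 0) return(list(y = y, traj = NULL))
  nstep <- max(1L, ceiling(span / dt_max - 1e-9))
  h <- span / nstep
  traj <- if (record) matrix(NA_real_, nstep, length(y) + 1L) else NULL
  for (k in seq_len(nstep)) {
    k1 <- .rhs(y, cm, inflow)
    k2 <- .rhs(y + h / 2 * k1, cm, inflow)
    k3 <- .rhs(y + h / 2 * k2, cm, inflow)
    k4 <- .rhs(y + h * k3, cm, inflow)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (record) traj[k, ] <- c(t1 + k * h, y)
    if (any(!is.finite(y)))
      stop(sprintf("integration produced non-finite state near t = %.4g (component %d)",
                   t1 + k * h, which(!is.finite(y))[1]), call. = FALSE)
  }
  list(y = y, traj = traj)
}

.pack <- function(state, cm) c(as.numeric(state$N[cm$ids]), state$M, state$V)
.unpack <- function(y, t, cm, state) {
  state$t <- t
  state$N <- stats::setNames(y[seq_len(cm$ng)], cm$ids)
  state$M <- y[cm$ng + 1L]
  state$V <- y[cm$ng + 2L]
  state
}

#' Integrate culture dynamics between events
#'
#' Advances the coupled cell-number / factor-amount system from `state$t` to
#' `t_end` with a fixed-step 4th-order Runge-Kutta scheme (step `<= dt_max`).
#' Between events the volume changes only by the (constant) `inflow`.
#'
#' @param state A [culture_state()].
#' @param model A [culture_model()].
#' @param t_end Target time, days, `>= state$t`.
#' @param dt_max Maximum step, days.
#' @param inflow Constant media inflow over the interval, mL/day.
#' @return The state advanced to `t_end`.
#' @export
integrate_between_events <- function(state, model, t_end, dt_max = 0.01,
                                     inflow = 0) {
  stopifnot(t_end >= state$t, dt_max > 0)
  cm <- .compile_model(model)
  out <- .rk4_segment(.pack(state, cm), state$t, t_end, dt_max, cm,
                      inflow = inflow, record = FALSE)
  st <- .unpack(out$y, t_end, cm, state)
  st$V_added <- st$V_added + inflow * (t_end - state$t)
  st$media_used <- st$media_used + inflow * (t_end - state$t)
  st
}

#' Apply an instantaneous media bolus
#'
#' Adds fresh (factor-free) media: volume increases, factor amount and cell
#' numbers are unchanged, so the concentration strictly decreases for any
#' positive bolus.
#'
#' @param state A [culture_state()].
#' @param added Added volume, mL, `>= 0`.
#' @return The diluted state.
#' @export
apply_bolus <- function(state, added) {
  if (!is.finite(added) || added < 0) stop("bolus volume must be >= 0", call. = FALSE)
  state$V <- state$V + added
  state$V_added <- state$V_added + added
  state$media_used <- state$media_used + added
  state
}

#' Apply a complete media exchange
#'
#' Replaces all conditioned media with fresh media at constant volume: the
#' factor amount resets to zero, cells and volume are unchanged. The full
#' current volume counts toward media consumption.
#'
#' @param state A [culture_state()].
#' @return The exchanged state.
#' @export
apply_media_exchange <- function(state) {
  state$M <- 0
  state$media_used <- state$media_used + state$V
  state
}

#' Feeding schedule
#'
#' Defines how and when fresh media enters the culture:
#' * `none_exchange` — no addition; complete media exchange every
#'   `period` days ("no dilution", D = 0).
#' * `linear` — `D` unit volumes (`D * V0` mL) added every 24 h.
#' * `exponential` / `logarithmic` — daily boluses proportional to
#'   `exp(k * day)` or `log(1 + k * day)`, normalised so the total added over
#'   the horizon equals `(fold_volume - 1) * V0`.
#' * `rtc` — threshold dilute-to-target feedback (see [rtc_config()]).
#' * `pid` — discrete PID feedback (see [pid_config()]); the controller is
#'   the only feeder in this mode.
#'
#' @param kind One of the kinds above.
#' @param D Dilution rate (unit volumes/day) for `linear`.
#' @param period Exchange period, days, for `none_exchange`.
#' @param k Shape parameter for `exponential` / `logarithmic`.
#' @param fold_volume Total fold-volume budget for shaped schedules.
#' @param controller A [pid_config()] or [rtc_config()] for feedback kinds.
#' @param V0 Unit volume, mL (the culture's initial volume).
#' @param horizon Culture duration, days (fixes the budget normalisation).
#' @return An object of class `feeding_schedule`.
#' @export
feeding_schedule <- function(kind = c("none_exchange", "linear", "exponential",
                                      "logarithmic", "rtc", "pid"),
                             D = 1, period = 4, k = 0.2, fold_volume = 16,
                             controller = NULL, V0 = 1, horizon = 16) {
  kind <- match.arg(kind)
  if (kind == "none_exchange" && period <= 0)
    stop("exchange period must be > 0", call. = FALSE)
  if (kind == "linear" && D < 0)
    stop("dilution rate D must be >= 0", call. = FALSE)
  if (kind %in% c("exponential", "logarithmic")) {
    if (fold_volume <= 1) stop("fold_volume must be > 1", call. = FALSE)
    if (k <= 0) stop("shape parameter k must be > 0", call. = FALSE)
  }
  if (kind == "pid" && !inherits(controller, "pid_config"))
    stop("pid schedule requires a pid_config controller", call. = FALSE)
  if (kind == "rtc" && !inherits(controller, "rtc_config"))
    stop("rtc schedule requires an rtc_config controller", call. = FALSE)
  structure(list(kind = kind, D = D, period = period, k = k,
                 fold_volume = fold_volume, controller = controller,
                 V0 = V0, horizon = horizon),
            class = "feeding_schedule")
}

#' Scheduled bolus volume for a given culture day
#'
#' Open-loop schedules only; feedback kinds deliver through their
#' controllers and return 0 here.
#'
#' @param schedule A [feeding_schedule()].
#' @param day Integer culture day, `>= 1`.
#' @return Bolus volume, mL.
#' @export
scheduled_bolus_volume <- function(schedule, day) {
  stopifnot(inherits(schedule, "feeding_schedule"), day >= 1)
  days <- seq_len(schedule$horizon - 1)
  switch(schedule$kind,
    none_exchange = 0,
    rtc = 0,
    pid = 0,
    linear = schedule$D * schedule$V0,
    exponential = {
      shape <- exp(schedule$k * days)
      budget <- (schedule$fold_volume - 1) * schedule$V0
      if (!day %in% days) 0 else budget * shape[day] / sum(shape)
    },
    logarithmic = {
      shape <- log(1 + schedule$k * days)
      budget <- (schedule$fold_volume - 1) * schedule$V0
      if (!day %in% days) 0 else budget * shape[day] / sum(shape)
    },
    stop("unknown schedule kind", call. = FALSE)
  )
}

#' Measurement model for the concentration sensor
#'
#' Abstracts the microbead surrogate assay used as the controller input:
#' an affine surrogate map (default identity), multiplicative lognormal
#' noise with a given CV (mean-preserving), and a lower detection limit at
#' which smaller readings are censored.
#'
#' @param cv Coefficient of variation of the multiplicative noise, `>= 0`.
#' @param detection_limit Lower detection limit, pg/mL; readings below it are
#'   reported at the limit.
#' @param scale,offset Surrogate calibration `measured = scale * C + offset`.
#' @return An object of class `measurement_model`.
#' @export
measurement_model <- function(cv = 0, detection_limit = 0, scale = 1,
                              offset = 0) {
  stopifnot(cv >= 0, detection_limit >= 0)
  structure(list(cv = cv, detection_limit = detection_limit,
                 scale = scale, offset = offset),
            class = "measurement_model")
}

#' Measure the factor concentration
#'
#' Draws one noisy sensor reading of the current concentration. Uses R's
#' global RNG; with `cv = 0` the true (surrogate-mapped) concentration is
#' returned.
#'
#' @param state A [culture_state()].
#' @param mm A [measurement_model()].
#' @return Measured concentration, pg/mL.
#' @export
measure_concentration <- function(state, mm = measurement_model()) {
  m <- mm$scale * concentration(state) + mm$offset
  if (mm$cv > 0) {
    sigma <- sqrt(log(1 + mm$cv^2))
    m <- m * exp(stats::rnorm(1, -sigma^2 / 2, sigma))
  }
  max(m, mm$detection_limit)
}

.event_row <- function(time, type, volume = 0, measured = NA_real_,
                       U = NA_real_, e = NA_real_, d = NA_real_) {
  data.frame(time = time, type = type, volume = volume,
             measured_C = measured, U = U, e = e, d = d,
             stringsAsFactors = FALSE)
}

#' Run one fed-batch culture simulation
#'
#' Alternates RK4 integration of the growth/secretion dynamics with discrete
#' events: daily scheduled boluses (open-loop schedules), periodic media
#' exchanges (`none_exchange`), or controller sampling instants (`rtc`,
#' `pid`). Daily boluses land on integer days 1 through `horizon - 1`; the
#' day-`horizon` readout is taken before any feed, so a linear `D = 1`
#' schedule reaches exactly `horizon`-fold volume at a 16-day horizon.
#' Under `pid` the controller samples every `Ts` hours, converts its output
#' flow to a bolus (or delivers it as constant inflow in `flow` mode), and is
#' latched off permanently once the volume saturation limit is reached.
#'
#' @param model A [culture_model()].
#' @param schedule A [feeding_schedule()].
#' @param N0 Optional initial per-group counts (defaults to an even split of
#'   `seed_density * V0`).
#' @param horizon Culture duration, days.
#' @param mm A [measurement_model()] for controller inputs.
#' @param dt_max Maximum integrator step, days.
#' @param seed Optional integer seed (sets the global RNG for
#'   reproducibility); identical seeds give bit-identical results.
#' @return An object of class `simulation_result`: `trajectory` (data frame
#'   of time, per-group counts, `M`, `V`, `C`), `events` (event log),
#'   `state` (final state), plus the inputs.
#' @export
run_simulation <- function(model, schedule, N0 = NULL, horizon = 16,
                           mm = measurement_model(), dt_max = 0.01,
                           seed = NULL) {
  stopifnot(inherits(model, "culture_model"),
            inherits(schedule, "feeding_schedule"), horizon > 0)
  if (!is.null(seed)) set.seed(seed)
  cm <- .compile_model(model)
  state <- initial_state(model, N0)
  V0 <- state$V

  # event times
  feed_days <- if (schedule$kind %in% c("linear", "exponential", "logarithmic"))
    seq_len(ceiling(horizon) - 1) else numeric()
  feed_days <- feed_days[feed_days < horizon]
  exch_days <- if (schedule$kind == "none_exchange")
    seq(schedule$period, horizon - 1e-9, by = schedule$period) else numeric()
  ctrl <- schedule$controller
  samp_times <- if (schedule$kind %in% c("rtc", "pid")) {
    h <- ctrl$Ts / 24
    seq(h, horizon - 1e-9, by = h)
  } else numeric()

  ev <- rbind(
    if (length(feed_days)) data.frame(time = feed_days, what = "feed"),
    if (length(exch_days)) data.frame(time = exch_days, what = "exchange"),
    if (length(samp_times)) data.frame(time = samp_times, what = "sample")
  )
  ev <- if (is.null(ev)) data.frame(time = numeric(), what = character())
        else ev[order(ev$time), , drop = FALSE]

  pid_st <- if (schedule$kind == "pid") pid_state() else NULL
  Vmax <- if (schedule$kind == "pid") ctrl$max_fold_volume * V0 else Inf
  h_days <- if (schedule$kind %in% c("rtc", "pid")) ctrl$Ts / 24 else NA_real_

  traj <- list(matrix(c(state$t, .pack(state, cm)), 1))
  events <- list()
  y <- .pack(state, cm)
  t_now <- 0
  inflow <- 0  # pending constant inflow for flow-mode PID

  advance <- function(t_to) {
    if (t_to <= t_now) return(invisible())
    seg <- .rk4_segment(y, t_now, t_to, dt_max, cm, inflow = inflow)
    y <<- seg$y
    if (!is.null(seg$traj)) traj[[length(traj) + 1L]] <<- seg$traj
    if (inflow > 0) {
      added <- inflow * (t_to - t_now)
      state$V_added <<- state$V_added + added
      state$media_used <<- state$media_used + added
    }
    t_now <<- t_to
  }

  for (i in seq_len(nrow(ev))) {
    t_ev <- ev$time[i]
    # flow-mode saturation: split the segment at the volume-limit hitting time
    if (inflow > 0 && is.finite(Vmax)) {
      V_now <- y[cm$ng + 2L]
      t_hit <- t_now + (Vmax - V_now) / inflow
      if (t_hit < t_ev - 1e-12) {
        advance(t_hit)
        inflow <- 0
        pid_st$active <- FALSE
        pid_st$t_off <- t_hit
        events[[length(events) + 1L]] <- .event_row(t_hit, "controller_off")
      }
    }
    advance(t_ev)
    state <- .unpack(y, t_ev, cm, state)
    if (schedule$kind %in% c("rtc", "pid")) inflow <- 0

    if (ev$what[i] == "feed") {
      vol <- scheduled_bolus_volume(schedule, as.integer(round(t_ev)))
      state <- apply_bolus(state, vol)
      events[[length(events) + 1L]] <- .event_row(t_ev, "bolus", vol)
    } else if (ev$what[i] == "exchange") {
      events[[length(events) + 1L]] <- .event_row(t_ev, "exchange",
                                                  volume = state$V)
      state <- apply_media_exchange(state)
    } else if (ev$what[i] == "sample" && schedule$kind == "rtc") {
      measured <- measure_concentration(state, mm)
      vol <- rtc_step(ctrl, state, measured)
      if (vol > 0) state <- apply_bolus(state, vol)
      events[[length(events) + 1L]] <- .event_row(t_ev, "rtc_bolus", vol,
                                                  measured = measured)
    } else if (ev$what[i] == "sample" && schedule$kind == "pid") {
      if (pid_st$active) {
        measured <- measure_concentration(state, mm)
        stp <- pid_step(ctrl, pid_st, measured, h_days)
        pid_st <- stp$state
        if (ctrl$output_mode == "bolus") {
          vol <- flow_to_bolus(stp$U, ctrl$Ts)
          avail <- Vmax - state$V
          if (vol >= avail - 1e-12) {
            vol <- max(avail, 0)
            pid_st$active <- FALSE
            pid_st$t_off <- t_ev
          }
          if (vol > 0) state <- apply_bolus(state, vol)
          events[[length(events) + 1L]] <-
            .event_row(t_ev, "pid_bolus", vol, measured = measured,
                       U = stp$U, e = stp$e, d = stp$d)
          if (!pid_st$active)
            events[[length(events) + 1L]] <- .event_row(t_ev, "controller_off")
        } else {  # flow mode: constant inflow until the next sample
          inflow <- stp$U
          events[[length(events) + 1L]] <-
            .event_row(t_ev, "pid_flow", inflow * h_days, measured = measured,
                       U = stp$U, e = stp$e, d = stp$d)
        }
        pid_st <- check_saturation(state, ctrl, pid_st)
        if (!pid_st$active) inflow <- 0
      }
    }
    y <- .pack(state, cm)
    traj[[length(traj) + 1L]] <- matrix(c(t_ev, y), 1)
  }
  # saturation can also be hit in the tail segment under flow mode
  if (inflow > 0 && is.finite(Vmax)) {
    V_now <- y[cm$ng + 2L]
    t_hit <- t_now + (Vmax - V_now) / inflow
    if (t_hit < horizon) {
      advance(t_hit)
      inflow <- 0
      pid_st$active <- FALSE
      pid_st$t_off <- t_hit
      events[[length(events) + 1L]] <- .event_row(t_hit, "controller_off")
    }
  }
  advance(horizon)
  state <- .unpack(y, horizon, cm, state)

  tm <- do.call(rbind, traj)
  trajectory <- as.data.frame(tm)
  names(trajectory) <- c("time", cm$ids, "M", "V")
  trajectory$C <- trajectory$M / trajectory$V
  events <- if (length(events)) do.call(rbind, events) else .event_row(numeric())[0, ]

  structure(list(trajectory = trajectory, events = events, state = state,
                 model = model, schedule = schedule, horizon = horizon,
                 dt_max = dt_max, seed = seed, pid_state = pid_st),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %s schedule, %g days, final V = %.3g mL, C = %.3g pg/mL\n",
              x$schedule$kind, x$horizon, x$state$V, concentration(x$state)))
  cat(sprintf("  %d trajectory points, %d events\n",
              nrow(x$trajectory), nrow(x$events)))
  invisible(x)
}

#' Run an ensemble of replicate simulations
#'
#' Draws `n` independent initial populations from a [population_sampler()]
#' (emulating unit-to-unit cord-blood variability) and simulates each one.
#' Per-replicate seeds are derived reproducibly from `base_seed`, so the
#' ensemble is deterministic as a whole.
#'
#' @param model A [culture_model()].
#' @param sampler A [population_sampler()].
#' @param schedule A [feeding_schedule()].
#' @param n Number of replicates, `>= 1`.
#' @param base_seed Integer seed for the ensemble.
#' @inheritParams run_simulation
#' @return List of `simulation_result`s (with per-replicate seeds attached).
#' @export
run_replicates <- function(model, sampler, schedule, n, base_seed = 1,
                           horizon = 16, mm = measurement_model(),
                           dt_max = 0.01) {
  stopifnot(n >= 1)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    set.seed(seeds[i])
    N0 <- sample_initial_population(sampler)
    res <- run_simulation(model, schedule, N0 = N0, horizon = horizon,
                          mm = mm, dt_max = dt_max, seed = NULL)
    res$seed <- seeds[i]
    res
  })
}
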