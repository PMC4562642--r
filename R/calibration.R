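# Calibration pipeline: turns time-course culture tables (cell counts per
# phenotype group, factor concentration, volume) into the growth-rate and
# secretion-rate correlations that drive the model, plus expression-weight
# normalization between microarray data sets.

#' Time-course culture table
#'
#' One table per dilution scheme: sampling times (typically days 0, 4, 8,
#' 12, 16), per-time cell counts per phenotype group, measured factor
#' concentration and culture volume. For a media-exchange scheme
#' (`"D0"`), a complete exchange is assumed to follow each recorded
#' measurement, so the factor amount restarts from zero after every
#' sampling time.
#'
#' @param time_days Strictly increasing sampling times, days.
#' @param counts Data frame or matrix of cell counts, one column per group.
#' @param conc_pg_ml Factor concentrations, pg/mL.
#' @param volume_ml Culture volumes, mL.
#' @param scheme Scheme label, e.g. `"D0"`, `"D1"`, `"D3"`.
#' @return A data frame of class `timecourse_table` with columns
#'   `time_days`, `count_<group>`, `conc_pg_ml`, `volume_ml`, `scheme`.
#' @export
timecourse_table <- function(time_days, counts, conc_pg_ml, volume_ml,
                             scheme = "D1") {
  counts <- as.data.frame(counts)
  n <- length(time_days)
  stopifnot(nrow(counts) == n, length(conc_pg_ml) == n,
            length(volume_ml) == n, length(scheme) == 1)
  if (n < 2 || any(diff(time_days) <= 0))
    stop("time_days must be strictly increasing with >= 2 points", call. = FALSE)
  if (any(conc_pg_ml < 0) || any(volume_ml < 0) || any(as.matrix(counts) < 0))
    stop("counts, concentrations and volumes must be >= 0", call. = FALSE)
  names(counts) <- paste0("count_", names(counts))
  out <- cbind(data.frame(time_days = time_days), counts,
               data.frame(conc_pg_ml = conc_pg_ml, volume_ml = volume_ml,
                          scheme = scheme, stringsAsFactors = FALSE))
  class(out) <- c("timecourse_table", "data.frame")
  out
}

.tt_groups <- function(table) {
  sub("^count_", "", grep("^count_", names(table), value = TRUE))
}

.is_exchange_scheme <- function(table) {
  table$scheme[1] %in% c("D0", "none_exchange", "exchange")
}

#' Read / write a time-course table as CSV
#'
#' The CSV dialect has columns `time_days`, `count_<group>` (one per
#' phenotype group), `conc_pg_ml`, `volume_ml`, `scheme`.
#'
#' @param path File path.
#' @return A `timecourse_table` (for the reader); the path, invisibly (for
#'   the writer).
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_days", "conc_pg_ml", "volume_ml", "scheme")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("timecourse CSV '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  counts <- df[, grep("^count_", names(df)), drop = FALSE]
  if (!ncol(counts))
    stop(sprintf("timecourse CSV '%s' has no count_<group> columns", path),
         call. = FALSE)
  names(counts) <- sub("^count_", "", names(counts))
  timecourse_table(df$time_days, counts, df$conc_pg_ml, df$volume_ml,
                   df$scheme[1])
}

#' @rdname read_timecourse_csv
#' @param table A `timecourse_table`.
#' @export
write_timecourse_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Interval growth rates for one phenotype group
#'
#' For each consecutive sampling interval, the percent change in cell
#' number per day: `(N(t2) - N(t1)) / (N(t1) * (t2 - t1)) * 100`, reported
#' at the interval midpoint (days 2, 6, 10 for 4-day sampling over 12
#' days). Intervals starting from a zero count are skipped with a warning.
#'
#' @param table A [timecourse_table()].
#' @param group Group id (a `count_<group>` column must exist).
#' @return Data frame with columns `midpoint_day`, `rate_pct_per_day`,
#'   `dt_days`, `scheme`.
#' @export
interval_growth_rates <- function(table, group) {
  col <- paste0("count_", group)
  if (!col %in% names(table))
    stop(sprintf("group '%s' not present in table", group), call. = FALSE)
  N <- table[[col]]
  t <- table$time_days
  out <- data.frame()
  for (i in seq_len(length(t) - 1L)) {
    if (N[i] <= 0) {
      warning(sprintf("group '%s': zero count at day %g, interval skipped",
                      group, t[i]), call. = FALSE)
      next
    }
    dt <- t[i + 1L] - t[i]
    out <- rbind(out, data.frame(
      midpoint_day = (t[i] + t[i + 1L]) / 2,
      rate_pct_per_day = (N[i + 1L] - N[i]) / (N[i] * dt) * 100,
      dt_days = dt, scheme = table$scheme[1], stringsAsFactors = FALSE))
  }
  out
}

#' Interval mean concentrations
#'
#' Arithmetic mean of the interval-endpoint concentrations, reported at the
#' interval midpoint. For a media-exchange table the interval-start
#' concentration is the post-exchange value (zero), since the recorded
#' measurement precedes the exchange; the interval endpoints are returned
#' alongside the mean so fitters can model within-interval variation.
#'
#' @param table A [timecourse_table()].
#' @return Data frame with columns `midpoint_day`, `mean_conc_pg_ml`,
#'   `conc_start`, `conc_end`, `dt_days`, `scheme`.
#' @export
interval_mean_concentration <- function(table) {
  t <- table$time_days
  C <- table$conc_pg_ml
  i <- seq_len(length(t) - 1L)
  c1 <- if (.is_exchange_scheme(table)) rep(0, length(i)) else C[i]
  c2 <- C[i + 1L]
  data.frame(midpoint_day = (t[i] + t[i + 1L]) / 2,
             mean_conc_pg_ml = (c1 + c2) / 2,
             conc_start = c1, conc_end = c2,
             dt_days = diff(t), scheme = table$scheme[1],
             stringsAsFactors = FALSE)
}

#' Interval factor secretion rates
#'
#' Converts concentrations to amounts (`M = C * V`) and differences them
#' over each interval: `rate = (M(t2) - M(t1)) / (t2 - t1)` pg/day. For a
#' media-exchange table the amount is reset to zero immediately after each
#' recorded measurement, so each interval rate uses the post-exchange
#' baseline `M(t1+) = 0`.
#'
#' @param table A [timecourse_table()].
#' @return Data frame with columns `midpoint_day`, `rate_pg_per_day`,
#'   `dt_days`, `scheme`.
#' @export
interval_secretion_rates <- function(table) {
  if (is.null(table$volume_ml) || any(is.na(table$volume_ml)))
    stop("secretion rates require recorded volumes at every time", call. = FALSE)
  t <- table$time_days
  M <- table$conc_pg_ml * table$volume_ml
  exch <- .is_exchange_scheme(table)
  i <- seq_len(length(t) - 1L)
  M1 <- if (exch) rep(0, length(i)) else M[i]
  data.frame(midpoint_day = (t[i] + t[i + 1L]) / 2,
             rate_pg_per_day = (M[i + 1L] - M1) / diff(t),
             dt_days = diff(t), scheme = table$scheme[1],
             stringsAsFactors = FALSE)
}

#' Fit a growth-rate dose-response to pooled correlation points
#'
#' Points pair interval mean concentrations (pg/mL) with interval growth
#' rates (%/day), pooled across dilution schemes. `"exponential"` fits
#' `a * exp(b * C)` by nonlinear least squares (log-linear start, refined
#' numerically); `"spline"` interpolates through the concentration-ordered
#' points (duplicate concentrations are averaged); `"auto"` chooses
#' exponential when the Spearman rank correlation of (C, rate) is negative,
#' else spline. The returned correlation stores rates as fractions/day.
#'
#' When the points carry interval endpoint concentrations (`conc_start`,
#' `conc_end`), the exponential fit models each observation as the average
#' of `a * exp(b * C)` along a linear concentration path between the
#' endpoints, `a * (exp(b*c2) - exp(b*c1)) / (b * (c2 - c1))`, which removes
#' most of the bias that within-interval concentration drift puts on a
#' pointwise fit at the interval mean.
#'
#' @param points Data frame with columns `conc` (pg/mL) and `rate_pct`
#'   (%/day); optionally `conc_start` and `conc_end`.
#' @param kind `"auto"`, `"exponential"` or `"spline"`.
#' @return A [growth_correlation()] with the fit report in
#'   `attr(, "fit")`.
#' @export
fit_growth_correlation <- function(points, kind = c("auto", "exponential",
                                                    "spline")) {
  kind <- match.arg(kind)
  stopifnot(all(c("conc", "rate_pct") %in% names(points)))
  points <- points[is.finite(points$conc) & is.finite(points$rate_pct), ]
  x <- points$conc
  y <- points$rate_pct
  if (kind == "auto") {
    rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
    kind <- if (is.finite(rho) && rho < 0) "exponential" else "spline"
  }
  if (kind == "exponential") {
    if (length(x) < 3)
      stop("exponential fit requires >= 3 points", call. = FALSE)
    pos <- y > 0
    if (sum(pos) < 2)
      stop("exponential fit requires >= 2 positive rates", call. = FALSE)
    start <- stats::coef(stats::lm(log(y[pos]) ~ x[pos]))
    a0 <- exp(start[1]); b0 <- start[2]
    interval_aware <- all(c("conc_start", "conc_end") %in% names(points))
    pred <- if (interval_aware) {
      c1 <- points$conc_start; c2 <- points$conc_end
      function(a, b) {
        # average of a*exp(b*C) along a linear path c1 -> c2
        same <- abs(c2 - c1) < 1e-9 | abs(b) < 1e-12
        out <- a * (exp(b * c2) - exp(b * c1)) / (b * (c2 - c1))
        out[same] <- (a * exp(b * (c1 + c2) / 2))[same]
        out
      }
    } else function(a, b) a * exp(b * x)
    fit <- tryCatch(
      stats::nls(y ~ pred(a, b), start = list(a = a0, b = b0),
                 control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      a_hat <- cf[["a"]]; b_hat <- cf[["b"]]
    } else {
      # zero-residual or otherwise nls-hostile data: refine by direct SS
      ss <- function(p) sum((y - pred(p[1], p[2]))^2)
      op <- stats::optim(c(a0, b0), ss, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-14))
      a_hat <- op$par[1]; b_hat <- op$par[2]
    }
    resid <- y - pred(a_hat, b_hat)
    if (!all(is.finite(c(a_hat, b_hat))) ||
        sum(resid^2) > sum((y - mean(y))^2) * 1.5 + 1e-12)
      stop(sprintf("exponential growth fit did not converge (RSS %.3g)",
                   sum(resid^2)), call. = FALSE)
    out <- growth_correlation("exponential", a = a_hat / 100, b = b_hat,
                              domain = c(0, max(x)))
    attr(out, "fit") <- list(kind = "exponential", n = length(x),
                             rss = sum(resid^2), residuals = resid)
    out
  } else {
    if (length(x) < 2) stop("spline fit requires >= 2 points", call. = FALSE)
    agg <- stats::aggregate(list(y = y), list(x = x), mean)
    agg <- agg[order(agg$x), ]
    out <- growth_correlation("spline", knots_conc = agg$x,
                              knots_rate = agg$y / 100)
    attr(out, "fit") <- list(kind = "spline", n = length(x),
                             knots = nrow(agg))
    out
  }
}

#' Fit the secretion correlation
#'
#' `"constant_per_cell"` fits a least-squares slope through the origin
#' (pg per adjusted cell per day); `"spline"` interpolates through the
#' (adjusted cells, pg/day) points.
#'
#' @param points Data frame with columns `adjusted` and `rate_pg_per_day`.
#' @param kind `"constant_per_cell"` or `"spline"`.
#' @return A [secretion_correlation()].
#' @export
fit_secretion_correlation <- function(points,
                                      kind = c("constant_per_cell", "spline")) {
  kind <- match.arg(kind)
  stopifnot(all(c("adjusted", "rate_pg_per_day") %in% names(points)))
  x <- points$adjusted
  y <- points$rate_pg_per_day
  if (kind == "constant_per_cell") {
    if (all(x == 0))
      stop("cannot fit a per-cell rate to all-zero adjusted counts",
           call. = FALSE)
    s <- sum(x * y) / sum(x^2)
    out <- secretion_correlation("constant_per_cell", s = max(s, 0))
    attr(out, "fit") <- list(kind = kind, n = length(x),
                             rss = sum((y - s * x)^2))
    out
  } else {
    if (length(x) < 2) stop("spline fit requires >= 2 points", call. = FALSE)
    agg <- stats::aggregate(list(y = y), list(x = x), mean)
    agg <- agg[order(agg$x), ]
    secretion_correlation("spline", knots_cells = agg$x,
                          knots_rate = pmax(agg$y, 0))
  }
}

#' Normalise expression signals between two data sets
#'
#' Rescales set B so the shared anchor phenotype (the proB compartment in
#' the reference analysis) has equal signal in both sets, then merges:
#' phenotypes present in both sets get the mean of the two (rescaled)
#' signals.
#'
#' @param setA,setB Named numeric vectors: phenotype -> expression signal.
#' @param anchor Phenotype id present in both sets with signal `> 0`.
#' @return Named numeric vector over the union of phenotypes.
#' @export
normalize_expression_weights <- function(setA, setB, anchor) {
  if (!(anchor %in% names(setA)) || !(anchor %in% names(setB)))
    stop(sprintf("anchor phenotype '%s' must be present in both sets", anchor),
         call. = FALSE)
  if (setA[[anchor]] <= 0 || setB[[anchor]] <= 0)
    stop("anchor signal must be > 0 in both sets", call. = FALSE)
  setB <- setB * setA[[anchor]] / setB[[anchor]]
  all <- union(names(setA), names(setB))
  out <- vapply(all, function(p) {
    vals <- c(if (p %in% names(setA)) setA[[p]],
              if (p %in% names(setB)) setB[[p]])
    mean(vals)
  }, 0)
  stats::setNames(out, all)
}

#' Average phenotype signals into group weights
#'
#' @param signals Named numeric vector: phenotype -> signal.
#' @param groups Named list: group id -> character vector of member
#'   phenotypes.
#' @return Named numeric vector of per-group weights (mean member signal).
#' @export
group_expression_weights <- function(signals, groups) {
  vapply(groups, function(members) {
    present <- members[members %in% names(signals)]
    if (!length(present))
      stop("group has no member phenotype with an expression signal",
           call. = FALSE)
    mean(signals[present])
  }, 0)
}

.schedule_from_scheme <- function(scheme, V0, horizon, period = 4) {
  if (scheme %in% c("D0", "none_exchange", "exchange"))
    return(feeding_schedule("none_exchange", period = period, V0 = V0,
                            horizon = horizon))
  d <- suppressWarnings(as.numeric(sub("^D", "", scheme)))
  if (!is.finite(d))
    stop(sprintf("cannot infer a feeding schedule from scheme '%s'", scheme),
         call. = FALSE)
  feeding_schedule("linear", D = d, V0 = V0, horizon = horizon)
}

# Trapezoid average of exp(b * C) along a sampled concentration path.
.path_mean_exp <- function(tt, cc, b) {
  w <- diff(tt)
  v <- exp(b * cc)
  sum(w * (utils::head(v, -1) + utils::tail(v, -1)) / 2) / (tt[length(tt)] - tt[1])
}

# Exponential dose-response fit against measured continuous-equivalent
# rates, with the predicted rate averaged over simulated within-interval
# concentration paths.
.fit_exponential_paths <- function(y, paths, a0, b0) {
  pred <- function(a, b) a * vapply(paths, function(p)
    .path_mean_exp(p$t, p$C, b), 0)
  ss <- function(p) sum((y - pred(p[1], p[2]))^2)
  op <- stats::optim(c(a0, b0), ss, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-13))
  list(a = op$par[1], b = op$par[2], rss = op$value)
}

#' Calibrate a culture model from time-course tables
#'
#' Runs the full correlation pipeline: per group, interval growth rates
#' (linear %/day) are converted to continuous-equivalent rates
#' (`log(1 + r * dt) / dt`, exact when the concentration is constant over
#' the interval), paired with interval mean concentrations and pooled
#' across schemes before fitting the dose-response. Secretion rates are
#' amount differences paired with the interval log-mean adjusted cell
#' number (the exact time average under exponential growth).
#'
#' With `refine > 0`, the fitted model is then simulated under each table's
#' scheme and the exponential dose-responses are refit against the
#' simulated within-interval concentration paths (predicted interval rate
#' `a * mean(exp(b * C(t)))` instead of a pointwise evaluation at the mean
#' concentration), iterating. The generating model is a fixed point of this
#' loop, which removes the discretization bias that 4-day sampling puts on
#' the exponential parameters.
#'
#' @param tables List of [timecourse_table()]s (one per scheme).
#' @param weights Named numeric vector of per-group expression weights.
#' @param cd34_groups Character vector of group ids forming the CD34+
#'   readout compartment.
#' @param growth_kind Single kind (`"auto"`, `"exponential"`, `"spline"`)
#'   or named vector per group.
#' @param secretion_kind Passed to [fit_secretion_correlation()].
#' @param V0,seed_density Culture seeding parameters for the returned model.
#' @param refine Number of simulation-refit iterations for the exponential
#'   dose-responses (default 2; 0 disables).
#' @param dt_max Integrator step for the refinement simulations.
#' @return A [culture_model()] with a per-group fit report in
#'   `attr(, "fit_report")`.
#' @export
calibrate_model <- function(tables, weights, cd34_groups,
                            growth_kind = "auto",
                            secretion_kind = "constant_per_cell",
                            V0 = 1, seed_density = 1e5,
                            refine = 2, dt_max = 0.02) {
  stopifnot(is.list(tables), length(tables) >= 1)
  ids <- .tt_groups(tables[[1]])
  if (!setequal(names(weights), ids))
    stop("weights must be named by the tables' group ids", call. = FALSE)
  if (!all(cd34_groups %in% ids))
    stop("cd34_groups must be a subset of the group ids", call. = FALSE)
  if (length(growth_kind) == 1)
    growth_kind <- stats::setNames(rep(growth_kind, length(ids)), ids)

  groups <- list()
  report <- list()
  pts_by_group <- list()
  for (g in ids) {
    pts <- do.call(rbind, lapply(seq_along(tables), function(ti) {
      tb <- tables[[ti]]
      gr <- interval_growth_rates(tb, g)
      cc <- interval_mean_concentration(tb)
      out <- merge(gr, cc, by = c("midpoint_day", "dt_days", "scheme"))
      out$table_idx <- ti
      out
    }))
    # linear interval rate -> continuous-equivalent rate, still in %/day
    grow_arg <- 1 + pts$rate_pct_per_day / 100 * pts$dt_days
    keep <- grow_arg > 0
    if (!all(keep))
      warning(sprintf("group '%s': %d interval(s) with >100%% loss dropped",
                      g, sum(!keep)), call. = FALSE)
    pts <- pts[keep, ]
    pts$rate_cont <- 100 * log(grow_arg[keep]) / pts$dt_days
    pts_by_group[[g]] <- pts
    corr <- fit_growth_correlation(
      data.frame(conc = pts$mean_conc_pg_ml, rate_pct = pts$rate_cont,
                 conc_start = pts$conc_start, conc_end = pts$conc_end),
      kind = growth_kind[[g]])
    groups[[g]] <- phenotype_group(g, corr, w = weights[[g]],
                                   is_cd34 = g %in% cd34_groups)
    report[[g]] <- attr(corr, "fit")
  }

  sec_pts <- do.call(rbind, lapply(tables, function(tb) {
    sr <- interval_secretion_rates(tb)
    cnt <- as.matrix(tb[, paste0("count_", ids), drop = FALSE])
    adj <- as.numeric(cnt %*% weights[ids])
    i <- seq_len(nrow(tb) - 1L)
    a1 <- adj[i]; a2 <- adj[i + 1L]
    logmean <- ifelse(a1 > 0 & a2 > 0 & abs(a2 - a1) > 1e-12 * pmax(a1, a2),
                      (a2 - a1) / log(a2 / a1), (a1 + a2) / 2)
    data.frame(adjusted = logmean, rate_pg_per_day = sr$rate_pg_per_day)
  }))
  secretion <- fit_secretion_correlation(sec_pts, kind = secretion_kind)
  report$secretion <- attr(secretion, "fit")

  model <- culture_model(groups, secretion, V0 = V0,
                         seed_density = seed_density)

  exp_groups <- ids[vapply(groups, function(g) g$growth$kind, "") == "exponential"]
  if (refine > 0 && length(exp_groups)) {
    horizon <- max(vapply(tables, function(tb) max(tb$time_days), 0))
    for (it in seq_len(refine)) {
      # simulate the current fit under each scheme, seeded at the observed
      # day-0 counts, to recover within-interval concentration paths
      sims <- lapply(tables, function(tb) {
        N0 <- stats::setNames(as.numeric(tb[1, paste0("count_", ids)]), ids)
        sched <- .schedule_from_scheme(tb$scheme[1], V0 = tb$volume_ml[1],
                                       horizon = horizon)
        run_simulation(model, sched, N0 = N0, horizon = horizon,
                       dt_max = dt_max)$trajectory
      })
      for (g in exp_groups) {
        pts <- pts_by_group[[g]]
        paths <- lapply(seq_len(nrow(pts)), function(i) {
          tr <- sims[[pts$table_idx[i]]]
          t1 <- pts$midpoint_day[i] - pts$dt_days[i] / 2
          t2 <- pts$midpoint_day[i] + pts$dt_days[i] / 2
          sel <- tr$time >= t1 - 1e-9 & tr$time <= t2 + 1e-9
          list(t = tr$time[sel], C = tr$C[sel])
        })
        cur <- model$groups[[g]]$growth
        fitp <- .fit_exponential_paths(pts$rate_cont, paths,
                                       a0 = cur$a * 100, b0 = cur$b)
        corr <- growth_correlation("exponential", a = fitp$a / 100,
                                   b = fitp$b,
                                   domain = c(0, max(pts$conc_end)))
        model$groups[[g]]$growth <- corr
        report[[g]] <- list(kind = "exponential", n = nrow(pts),
                            rss = fitp$rss, refined = it)
      }
    }
  }
  attr(model, "fit_report") <- report
  model
}
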