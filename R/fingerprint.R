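#' Per-cell run velocity
#'
#' Mean of |v_tang| over the frames labeled RUN, i.e. the speed of the cell
#' while it is actually migrating.
#'
#' @param vel A `velocity_series`.
#' @param segments Segment table from [segment_states()] for the same cell;
#'   per-frame labels are taken from its `frame_label` attribute when
#'   present, otherwise frames are assigned to the segment containing them.
#'
#' @return The run velocity (um/h), or `NA` if the cell has no RUN frame.
#' @export
run_velocity <- function(vel, segments) {
  stopifnot(inherits(vel, "velocity_series"))
  fl <- attr(segments, "frame_label")
  if (is.null(fl)) fl <- .frame_labels_from_segments(vel$times, segments)
  run <- fl == "RUN"
  if (!any(run)) return(NA_real_)
  mean(abs(vel$v_tang[run]))
}

.frame_labels_from_segments <- function(times, segments) {
  idx <- findInterval(times, segments$start)
  idx[idx < 1L] <- 1L
  segments$label[idx]
}

#' Per-cell run-time fraction
#'
#' Time spent in RUN segments divided by the total track duration.
#'
#' @param segments Segment table of one cell (must tile the track).
#' @return Fraction in \[0, 1\].
#' @export
run_fraction <- function(segments) {
  total <- sum(segments$duration)
  if (total <= 0) stop("zero-duration track")
  sum(segments$duration[segments$label == "RUN"]) / total
}

#' Path persistence q of a trajectory
#'
#' Ratio of the maximum angular range covered to the total angular path
#' length: 1 for strictly one-directional motion, near 0 for a cell that
#' wiggles without getting anywhere.
#'
#' @param traj A [trajectory()] or a numeric vector of positions.
#' @return q in \[0, 1\], or `NA` (with a warning) for a numerically
#'   immobile cell whose path length is zero.
#' @export
persistence_q <- function(traj) {
  phi <- if (inherits(traj, "lane_trajectory")) traj$phi else as.numeric(traj)
  if (length(phi) < 2L) stop("persistence needs at least 2 positions")
  path <- sum(abs(diff(phi)))
  if (path == 0) {
    warning("zero path length: persistence undefined")
    return(NA_real_)
  }
  (max(phi) - min(phi)) / path
}

#' Collect dwell times for survival analysis
#'
#' Applies the censoring-horizon rule: a state contributes its duration
#' only if it starts at least `censor_horizon` hours before the end of its
#' cell track, so that every contributed state could in principle have been
#' observed for the full fitting range. States still ongoing at track end
#' are kept with their observed duration and flagged censored (such states
#' then necessarily exceed the horizon, leaving the survival function on
#' `[0, censor_horizon]` unaffected). States touching the track start are
#' kept: their start time is known and the rule conditions only on the
#' distance to the track end.
#'
#' @param segments Segment table (may hold several cells, distinguished by
#'   `cell_id`); must tile each cell's track.
#' @param censor_horizon Horizon in hours (default 16).
#'
#' @return Data frame with columns `cell_id`, `label`, `duration`,
#'   `censored`.
#' @export
collect_dwell_times <- function(segments, censor_horizon = 16) {
  track_end <- stats::ave(segments$end, segments$cell_id, FUN = max)
  keep <- (track_end - segments$start) >= censor_horizon - 1e-9
  data.frame(cell_id = segments$cell_id[keep],
             label = segments$label[keep],
             duration = segments$duration[keep],
             censored = segments$ends_at_track_end[keep],
             stringsAsFactors = FALSE)
}

#' Empirical survival function of state durations
#'
#' S(t) = P(T > t), evaluated on the regular grid t = 0, dt, 2*dt, ...,
#' horizon.
#'
#' @param durations Numeric vector of state durations (h).
#' @param dt Grid spacing in hours (normally the sampling interval).
#' @param horizon Last grid point (h).
#'
#' @return Data frame with columns `t` and `S`; attribute `n_states` holds
#'   the sample size.
#' @export
survival_function <- function(durations, dt, horizon = 16) {
  durations <- durations[is.finite(durations)]
  n <- length(durations)
  if (n < 1L) stop("cannot estimate a survival function from an empty sample")
  grid <- seq(0, horizon, by = dt)
  sorted <- sort(durations)
  # durations from segmentation are exact grid multiples; the 1e-9 guard
  # keeps "duration > t" stable against last-ulp arithmetic noise
  S <- (n - findInterval(grid + 1e-9, sorted)) / n
  out <- data.frame(t = grid, S = S)
  attr(out, "n_states") <- n
  out
}

#' Fit the state lifetime tau from the log survival function
#'
#' Least-squares fit of `log(S(t))` against `t` on the grid points inside
#' `fit_range` with `S(t) > 0`, following the model
#' `log S(t) = -(1/tau) t + c`. Very small times are excluded by the lower
#' end of the fit range because empirical dwell distributions deviate from
#' an exponential there; the intercept `c` absorbs the early-time offset.
#' By default each point is weighted by the (delta-method) inverse
#' variance of `log S(t)`, `n S / (1 - S)`, which keeps the handful of
#' noisy, survivor-starved grid points in the far tail from dominating the
#' slope; `weighting = "ols"` gives every grid point equal weight. The
#' confidence interval of tau is obtained by propagating the
#' t-distribution confidence bounds of the slope (tau = -1/slope is
#' monotone in the slope; an upper slope bound at or above zero yields an
#' infinite upper tau bound). [fingerprint()] replaces this interval with
#' a bootstrap over cells, which also reflects the correlation between
#' grid points of one empirical survival curve.
#'
#' @param surv Survival table from [survival_function()].
#' @param fit_range Two-element numeric, fitting window in hours.
#' @param conf_level Confidence level for the interval (default 0.99).
#' @param weighting `"inverse_variance"` (default) or `"ols"`.
#'
#' @return Object of class `tau_fit`: list with `tau`, `intercept`,
#'   `ci` (lower/upper, h), `conf_level`, `fit_range`, `n_states`,
#'   `n_points`, `slope`, `ci_method`.
#' @export
fit_tau <- function(surv, fit_range = c(2, 16), conf_level = 0.99,
                    weighting = c("inverse_variance", "ols")) {
  stopifnot(length(fit_range) == 2L, fit_range[1L] < fit_range[2L])
  weighting <- match.arg(weighting)
  use <- surv$t >= fit_range[1L] - 1e-9 & surv$t <= fit_range[2L] + 1e-9 &
    surv$S > 0
  if (sum(use) < 3L) {
    stop("fewer than 3 usable survival points inside the fit range")
  }
  dat <- surv[use, ]
  n <- attr(surv, "n_states")
  w <- if (weighting == "inverse_variance") {
    if (is.null(n)) n <- 1
    n * dat$S / pmax(1 - dat$S, 1e-12)
  } else {
    rep(1, nrow(dat))
  }
  fit <- stats::lm(log(S) ~ t, data = dat, weights = w)
  slope <- unname(stats::coef(fit)["t"])
  if (slope >= 0) {
    stop("non-negative log-survival slope: tau undefined (degenerate fit)")
  }
  # suppress the "essentially perfect fit" note: exact exponential input
  # is legitimate and its interval degenerates to the point estimate
  cb <- suppressWarnings(stats::confint(fit, "t", level = conf_level))
  ci_low <- -1 / cb[1L]
  ci_high <- if (cb[2L] >= 0) Inf else -1 / cb[2L]
  structure(list(tau = -1 / slope,
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 ci = c(lower = ci_low, upper = ci_high),
                 conf_level = conf_level,
                 fit_range = fit_range,
                 n_states = attr(surv, "n_states"),
                 n_points = sum(use),
                 slope = slope,
                 weighting = weighting,
                 ci_method = "slope_ci"),
            class = "tau_fit")
}

# weighted log-survival slope on the fit grid; NA when degenerate.
# closed form (no lm) for use inside bootstrap loops.
.tau_slope <- function(durations, dt, fit_range, horizon) {
  n <- length(durations)
  if (n < 1L) return(NA_real_)
  grid <- seq(0, horizon, by = dt)
  S <- (n - findInterval(grid + 1e-9, sort(durations))) / n
  use <- grid >= fit_range[1L] - 1e-9 & grid <= fit_range[2L] + 1e-9 & S > 0
  if (sum(use) < 3L) return(NA_real_)
  x <- grid[use]
  y <- log(S[use])
  w <- S[use] / pmax(1 - S[use], 1e-12)
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  if (!is.finite(slope) || slope >= 0) return(NA_real_)
  -1 / slope
}

#' @export
print.tau_fit <- function(x, ...) {
  cat(sprintf("tau = %.3f h  [%.0f%% CI %.3f, %.3f]  (c = %.3f, %s states, %d fit points)\n",
              x$tau, 100 * x$conf_level, x$ci[1L], x$ci[2L], x$intercept,
              ifelse(is.null(x$n_states), "?", x$n_states), x$n_points))
  invisible(x)
}

#' Fraction of fully resting cells
#'
#' A cell counts as immobile when its whole track is one single REST
#' segment, i.e. it never entered a run state for the duration of the
#' experiment.
#'
#' @param segments Segment table of one or more cells.
#' @return Fraction of cells in \[0, 1\].
#' @export
immobile_fraction <- function(segments) {
  if (nrow(segments) == 0L) stop("cannot estimate immobile fraction without cells")
  n_seg <- table(segments$cell_id)
  single <- names(n_seg)[n_seg == 1L]
  all_rest <- segments$cell_id %in% single & segments$label == "REST"
  length(unique(segments$cell_id[all_rest])) / length(n_seg)
}

.se <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# percentile bootstrap over cells for the lifetime CIs; internally seeded
# so identical input gives identical intervals. Returns list(RUN=, REST=).
.boot_tau_ci <- function(dwell, mobile_ids, dt, fit_range, censor_horizon,
                         conf_level, B) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(19073486L)
  n <- length(mobile_ids)
  by_cell <- list(RUN = split(dwell$duration[dwell$label == "RUN"],
                              dwell$cell_id[dwell$label == "RUN"]),
                  REST = split(dwell$duration[dwell$label == "REST"],
                               dwell$cell_id[dwell$label == "REST"]))
  draws <- list(RUN = rep(NA_real_, B), REST = rep(NA_real_, B))
  for (b in seq_len(B)) {
    ids <- sample(mobile_ids, n, replace = TRUE)
    for (lab in c("RUN", "REST")) {
      d <- unlist(by_cell[[lab]][ids], use.names = FALSE)
      draws[[lab]][b] <- .tau_slope(d, dt, fit_range, censor_horizon)
    }
  }
  alpha <- (1 - conf_level) / 2
  out <- lapply(draws, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 0.5 * B) return(NULL)   # too many degenerate resamples
    ci <- stats::quantile(x, c(alpha, 1 - alpha), names = FALSE)
    c(lower = ci[1L], upper = ci[2L])
  })
  out
}

#' Five-parameter motility fingerprint of a cell population
#'
#' Runs the full analysis chain — tangential velocity, run/rest
#' segmentation, dwell-time censoring, survival fits — and assembles the
#' population fingerprint: run velocity `v_run`, state lifetimes `tau_run`
#' and `tau_rest`, run-time fraction `p_run`, path persistence `q`, plus
#' the immobile-cell fraction. `v_run`, `p_run` and `q` average per-cell
#' values (each cell weighted equally) and carry standard errors over
#' cells; the lifetimes come from population-level log-survival fits and
#' carry 99% confidence intervals. A failing lifetime fit is reported as a
#' missing value with a diagnostic message rather than aborting the other
#' parameters.
#'
#' Cells that rest for their entire track contribute to `immobile_fraction`
#' (and to `p_run` as zeros) but are excluded from the dwell-time sample:
#' their single whole-track "rest" duration is set by the observation
#' window, not by rest-state turnover, and would flatten the survival tail
#' of genuinely alternating cells.
#'
#' The lifetime confidence intervals are percentile bootstrap intervals
#' over cells (`ci_boot` resamples, internally seeded so repeated runs on
#' identical input are identical): resampling whole cells respects both
#' the correlation between grid points of one empirical survival curve and
#' the clustering of states within cells, which a naive regression
#' interval on the survival grid ignores. Set `ci_boot = 0` to keep the
#' propagated slope interval from [fit_tau()] instead.
#'
#' @param collection A [trajectory_collection()] with at least two cells.
#' @param seg_params [segmentation_params()].
#' @param fit_range Fitting window for the lifetime fits (h).
#' @param censor_horizon Dwell-time inclusion horizon (h).
#' @param conf_level Confidence level for the lifetime intervals.
#' @param ci_boot Number of cell-level bootstrap resamples for the
#'   lifetime confidence intervals (0 disables the bootstrap and keeps the
#'   propagated slope interval).
#'
#' @return Object of class `motility_fingerprint`: list with `per_cell`
#'   (data frame of per-cell parameters), `estimates` (population values
#'   with uncertainties), `tau_run`/`tau_rest` ([fit_tau()] objects or
#'   `NULL`), `dwell` (censored dwell-time table), `segments` (full
#'   segment table), `n_cells`, `diagnostics`.
#' @export
fingerprint <- function(collection, seg_params = segmentation_params(),
                        fit_range = c(2, 16), censor_horizon = 16,
                        conf_level = 0.99, ci_boot = 400) {
  stopifnot(inherits(collection, "trajectory_collection"))
  trajs <- collection$trajectories
  if (length(trajs) < 2L) stop("fingerprint needs at least 2 cells")
  geom <- collection$geometry

  seg_list <- vector("list", length(trajs))
  v_run_i <- p_run_i <- q_i <- numeric(length(trajs))
  immobile_i <- logical(length(trajs))
  n_run_i <- n_rest_i <- integer(length(trajs))
  zero_path <- 0L
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    vel <- tangential_velocity(tr, geom, seg_params$smooth_window)
    fl <- classify_frames(tr, geom, seg_params)
    seg <- attr(fl, "segments")
    seg_list[[i]] <- seg
    v_run_i[i] <- if (any(fl == "RUN")) {
      mean(abs(vel$v_tang[fl == "RUN"]))
    } else NA_real_
    p_run_i[i] <- run_fraction(seg)
    q_i[i] <- withCallingHandlers(
      persistence_q(tr),
      warning = function(w) {
        zero_path <<- zero_path + 1L
        invokeRestart("muffleWarning")
      })
    immobile_i[i] <- nrow(seg) == 1L && seg$label[1L] == "REST"
    n_run_i[i] <- sum(seg$label == "RUN")
    n_rest_i[i] <- sum(seg$label == "REST")
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL
  per_cell <- data.frame(
    cell_id = vapply(trajs, `[[`, character(1), "cell_id"),
    v_run = v_run_i, p_run = p_run_i, q = q_i,
    n_run_states = n_run_i, n_rest_states = n_rest_i,
    immobile = immobile_i, stringsAsFactors = FALSE, row.names = NULL)

  mobile_ids <- per_cell$cell_id[!per_cell$immobile]
  dwell <- collect_dwell_times(segments[segments$cell_id %in% mobile_ids, ],
                               censor_horizon)
  diagnostics <- character(0)
  fit_one <- function(lab) {
    d <- dwell$duration[dwell$label == lab]
    tryCatch({
      s <- survival_function(d, collection$dt, censor_horizon)
      fit_tau(s, fit_range, conf_level)
    }, error = function(e) {
      diagnostics <<- c(diagnostics,
                        sprintf("tau_%s fit failed: %s", tolower(lab),
                                conditionMessage(e)))
      NULL
    })
  }
  tau_run <- fit_one("RUN")
  tau_rest <- fit_one("REST")
  if (ci_boot > 0L && (!is.null(tau_run) || !is.null(tau_rest))) {
    boot <- .boot_tau_ci(dwell, mobile_ids, collection$dt, fit_range,
                         censor_horizon, conf_level, ci_boot)
    if (!is.null(tau_run) && !is.null(boot$RUN)) {
      tau_run$ci <- boot$RUN
      tau_run$ci_method <- "cell_bootstrap"
    }
    if (!is.null(tau_rest) && !is.null(boot$REST)) {
      tau_rest$ci <- boot$REST
      tau_rest$ci_method <- "cell_bootstrap"
    }
  }
  if (zero_path > 0L) {
    diagnostics <- c(diagnostics,
                     sprintf("%d cell(s) with zero path length excluded from q",
                             zero_path))
  }

  mobile_v <- v_run_i[is.finite(v_run_i)]
  estimates <- list(
    v_run = list(value = mean(mobile_v), se = .se(v_run_i), n = length(mobile_v)),
    tau_run = if (is.null(tau_run)) list(value = NA_real_, ci = c(NA, NA)) else
      list(value = tau_run$tau, ci = tau_run$ci, n = tau_run$n_states),
    tau_rest = if (is.null(tau_rest)) list(value = NA_real_, ci = c(NA, NA)) else
      list(value = tau_rest$tau, ci = tau_rest$ci, n = tau_rest$n_states),
    p_run = list(value = mean(p_run_i), se = .se(p_run_i), n = length(p_run_i)),
    q = list(value = mean(q_i, na.rm = TRUE), se = .se(q_i),
             n = sum(is.finite(q_i))),
    immobile_fraction = list(value = mean(immobile_i), n = length(immobile_i))
  )
  structure(list(per_cell = per_cell, estimates = estimates,
                 tau_run = tau_run, tau_rest = tau_rest,
                 dwell = dwell, segments = segments,
                 n_cells = length(trajs), diagnostics = diagnostics,
                 seg_params = seg_params, fit_range = fit_range,
                 censor_horizon = censor_horizon),
            class = "motility_fingerprint")
}

#' @export
print.motility_fingerprint <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("motility fingerprint (%d cells):\n", x$n_cells))
  cat(sprintf("  v_run    %7.2f um/h (se %.2f, n = %d mobile)\n",
              e$v_run$value, e$v_run$se, e$v_run$n))
  fmt_tau <- function(nm, tt) {
    if (is.na(tt$value)) {
      cat(sprintf("  %-8s fit failed\n", nm))
    } else {
      cat(sprintf("  %-8s %7.2f h    (99%% CI %.2f-%.2f, %d states)\n",
                  nm, tt$value, tt$ci[1L], tt$ci[2L], tt$n))
    }
  }
  fmt_tau("tau_run", e$tau_run)
  fmt_tau("tau_rest", e$tau_rest)
  cat(sprintf("  p_run    %7.3f      (se %.3f)\n", e$p_run$value, e$p_run$se))
  cat(sprintf("  q        %7.3f      (se %.3f, n = %d)\n",
              e$q$value, e$q$se, e$q$n))
  cat(sprintf("  immobile %7.3f\n", e$immobile_fraction$value))
  if (length(x$diagnostics)) {
    cat("  diagnostics:\n")
    for (d in x$diagnostics) cat("   - ", d, "\n", sep = "")
  }
  invisible(x)
}
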