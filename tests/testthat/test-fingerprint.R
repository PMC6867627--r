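test_that("run velocity averages |v_tang| over run frames only", {
  vel <- make_vel(rep(20, 24))
  seg <- segment_states(vel, segmentation_params())
  expect_equal(run_velocity(vel, seg), 20)

  # sign changes inside runs do not cancel: absolute value inside the mean
  vel2 <- make_vel(rep(c(20, -20), 12))
  seg2 <- segment_states(vel2, segmentation_params())
  expect_equal(run_velocity(vel2, seg2), 20)

  # rest frames are excluded
  vel3 <- make_vel(c(rep(20, 12), rep(0, 12)))
  seg3 <- segment_states(vel3, segmentation_params())
  expect_equal(run_velocity(vel3, seg3), 20)

  # no run frames at all
  vel4 <- make_vel(rep(0, 12))
  expect_true(is.na(run_velocity(vel4, segment_states(vel4))))
})

test_that("dwell-time collection applies the censor-horizon start rule", {
  seg <- data.frame(
    cell_id = "a",
    label = c("RUN", "REST", "RUN", "REST", "RUN", "REST"),
    start = c(0, 1, 20, 28, 35, 40),
    end = c(1, 20, 28, 35, 40, 48),
    duration = c(1, 19, 8, 7, 5, 8),
    direction = c(1L, 0L, 1L, 0L, -1L, 0L),
    starts_at_track_start = c(TRUE, rep(FALSE, 5)),
    ends_at_track_end = c(rep(FALSE, 5), TRUE),
    stringsAsFactors = FALSE)
  dw <- collect_dwell_times(seg, censor_horizon = 16)
  # run states start at 0, 20, 35 h on a 48 h track: the 35 h start is
  # only 13 h before the end and is dropped
  expect_equal(dw$duration[dw$label == "RUN"], c(1, 8))
  expect_equal(dw$censored, c(FALSE, FALSE, FALSE, FALSE))

  # a 12 h track contributes nothing
  seg12 <- data.frame(cell_id = "b", label = c("RUN", "REST"),
                      start = c(0, 5), end = c(5, 12), duration = c(5, 7),
                      direction = c(1L, 0L),
                      starts_at_track_start = c(TRUE, FALSE),
                      ends_at_track_end = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(collect_dwell_times(seg12, 16)), 0L)

  # states ongoing at track end are kept and flagged censored
  seg_c <- seg
  seg_c$start[6] <- 30; seg_c$end[5] <- 30; seg_c$duration[6] <- 18
  dw_c <- collect_dwell_times(seg_c, 16)
  expect_true(dw_c$censored[nrow(dw_c)])
  expect_gte(dw_c$duration[nrow(dw_c)], 16)
})

test_that("censored dwell sample reproduces the true survival on [0, 16] h", {
  p <- simulation_params(n_cells = 300, seed = 31, immobile_fraction = 0)
  sim <- simulate_population(p)
  tru <- sim$truth$segments
  starts <- unlist(tapply(tru$duration, tru$cell_id,
                          function(d) cumsum(c(0, d[-length(d)]))))
  keep <- (p$duration - starts) >= 16
  for (lab in c("RUN", "REST")) {
    tau <- if (lab == "RUN") p$tau_run else p$tau_rest
    d <- tru$duration[keep & tru$label == lab]
    s <- survival_function(d, p$dt, 16)
    n <- length(d)
    # binomial-error envelope around the exponential truth
    band <- 3.5 * sqrt(exp(-s$t / tau) * (1 - exp(-s$t / tau)) / n) + 2 / n
    expect_true(all(abs(s$S - exp(-s$t / tau)) <= band))
  }
})

test_that("empirical survival counts exceedances on the grid", {
  s <- survival_function(c(1, 2, 3), dt = 0.5, horizon = 4)
  expect_equal(s$S[s$t == 0], 1)
  expect_equal(s$S[s$t == 1.5], 2 / 3)
  expect_equal(s$S[s$t == 2.5], 1 / 3)
  expect_equal(s$S[s$t == 3.5], 0)

  s5 <- survival_function(rep(5, 8), dt = 1, horizon = 6)
  expect_equal(s5$S, ifelse(s5$t < 5, 1, 0))

  expect_error(survival_function(numeric(0), 0.5), "empty")
})

test_that("survival of exponential draws converges to exp(-t/tau)", {
  set.seed(12)
  d <- rexp(5000, 1 / 3)
  s <- survival_function(d, dt = 1 / 6, horizon = 16)
  expect_lt(max(abs(s$S - exp(-s$t / 3))), 0.02)
})

test_that("fit_tau is exact on tabulated exponential survival", {
  grid <- seq(0, 16, by = 1 / 6)
  for (tau in c(1, 4, 10)) {
    for (c0 in c(1, 0.8)) {
      surv <- data.frame(t = grid, S = c0 * exp(-grid / tau))
      attr(surv, "n_states") <- 1000L
      for (w in c("inverse_variance", "ols")) {
        f <- fit_tau(surv, c(2, 16), weighting = w)
        expect_equal(f$tau, tau, tolerance = 1e-9)
        expect_equal(f$intercept, log(c0), tolerance = 1e-9)
        expect_true(f$ci[1] <= f$tau && f$tau <= f$ci[2])
      }
    }
  }
})

test_that("fit_tau rejects degenerate inputs", {
  grid <- seq(0, 16, by = 1)
  up <- data.frame(t = grid, S = pmin(1, 0.01 * exp(grid / 5)))
  expect_error(fit_tau(up), "non-negative")

  few <- data.frame(t = c(0, 3, 16), S = c(1, 0.5, 0))
  expect_error(fit_tau(few), "fewer than 3")
})

test_that("fit_tau recovers tau from finite exponential samples", {
  set.seed(2024)
  d <- rexp(5000, 1 / 3)
  s <- survival_function(d, 1 / 6, 16)
  f <- fit_tau(s)
  expect_gt(f$tau, 2.8)
  expect_lt(f$tau, 3.2)
  f_ols <- fit_tau(s, weighting = "ols")
  expect_gt(f_ols$tau, 2.8)
  expect_lt(f_ols$tau, 3.2)
})

test_that("run fraction is run time over track time", {
  seg <- data.frame(cell_id = "a", label = c("RUN", "REST"),
                    start = c(0, 6), end = c(6, 8), duration = c(6, 2),
                    direction = c(1L, 0L),
                    starts_at_track_start = c(TRUE, FALSE),
                    ends_at_track_end = c(FALSE, TRUE),
                    stringsAsFactors = FALSE)
  expect_equal(run_fraction(seg), 0.75)

  rest_only <- seg[2, ]
  expect_equal(run_fraction(rest_only), 0)
})

test_that("persistence q: range over path length", {
  expect_equal(persistence_q(seq(0, 5, by = 0.25)), 1)        # monotone
  expect_equal(persistence_q(c(seq(0, 2, by = 0.25),
                               seq(1.75, 0, by = -0.25))), 0.5)  # out and back
  expect_warning(q0 <- persistence_q(rep(1, 10)), "zero path")
  expect_true(is.na(q0))
})

test_that("q matches a brute-force oracle on random walks and stays small", {
  set.seed(55)
  qs <- replicate(200, {
    steps <- sample(c(-1, 1), 1000, replace = TRUE)
    phi <- cumsum(c(0, steps)) * 0.01
    q_pkg <- persistence_q(phi)
    # brute force: explicit loop over points
    mx <- -Inf; mn <- Inf; path <- 0
    for (i in seq_along(phi)) {
      if (phi[i] > mx) mx <- phi[i]
      if (phi[i] < mn) mn <- phi[i]
      if (i > 1) path <- path + abs(phi[i] - phi[i - 1])
    }
    expect_equal(q_pkg, (mx - mn) / path, tolerance = 1e-12)
    q_pkg
  })
  expect_lt(mean(qs), 0.2)
})

test_that("immobile fraction counts single whole-track rest cells", {
  segs <- do.call(rbind, lapply(1:10, function(i) {
    if (i <= 3) {
      data.frame(cell_id = paste0("c", i), label = "REST", start = 0,
                 end = 48, duration = 48, direction = 0L,
                 starts_at_track_start = TRUE, ends_at_track_end = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cell_id = paste0("c", i), label = c("RUN", "REST"),
                 start = c(0, 24), end = c(24, 48), duration = c(24, 24),
                 direction = c(1L, 0L),
                 starts_at_track_start = c(TRUE, FALSE),
                 ends_at_track_end = c(FALSE, TRUE),
                 stringsAsFactors = FALSE)
    }
  }))
  expect_equal(immobile_fraction(segs), 0.3)
  expect_equal(immobile_fraction(segs[segs$cell_id %in% paste0("c", 4:10), ]), 0)
  expect_error(immobile_fraction(segs[0, ]), "without cells")
})

test_that("fingerprint requires at least two cells and stays consistent", {
  sim <- simulate_population(simulation_params(n_cells = 1, seed = 2))
  expect_error(fingerprint(sim$collection), "at least 2")

  sim2 <- simulate_population(simulation_params(n_cells = 200, seed = 42))
  fp <- fingerprint(sim2$collection, ci_boot = 0)
  pc <- fp$per_cell
  # per-cell run + rest time fractions sum to one
  rest_frac <- vapply(split(fp$segments, fp$segments$cell_id), function(s) {
    sum(s$duration[s$label == "REST"]) / sum(s$duration)
  }, numeric(1))
  expect_equal(unname(rest_frac[pc$cell_id]) + pc$p_run, rep(1, nrow(pc)),
               tolerance = 1e-9)
  expect_true(all(pc$q >= 0 & pc$q <= 1, na.rm = TRUE))
  expect_true(all(pc$p_run >= 0 & pc$p_run <= 1))

  # two disjoint halves agree within 2 combined standard errors
  ids <- pc$cell_id
  h1 <- trajectory_collection(sim2$collection$trajectories[ids[1:100]],
                              sim2$collection$geometry)
  h2 <- trajectory_collection(sim2$collection$trajectories[ids[101:200]],
                              sim2$collection$geometry)
  f1 <- fingerprint(h1, ci_boot = 0)
  f2 <- fingerprint(h2, ci_boot = 0)
  for (par in c("v_run", "p_run", "q")) {
    d <- abs(f1$estimates[[par]]$value - f2$estimates[[par]]$value)
    se <- sqrt(f1$estimates[[par]]$se^2 + f2$estimates[[par]]$se^2)
    expect_lt(d, 2.5 * se)
  }
})

test_that("all motility estimators are invariant under phi -> -phi", {
  sim <- simulate_population(simulation_params(n_cells = 30, seed = 13))
  geom <- sim$collection$geometry
  mirrored <- trajectory_collection(
    lapply(sim$collection$trajectories, function(tr) {
      trajectory(tr$cell_id, tr$times, -tr$phi, geometry = geom)
    }), geom)
  fa <- fingerprint(sim$collection)
  fb <- fingerprint(mirrored)
  expect_equal(fb$per_cell$v_run, fa$per_cell$v_run, tolerance = 1e-9)
  expect_equal(fb$per_cell$p_run, fa$per_cell$p_run, tolerance = 1e-9)
  expect_equal(fb$per_cell$q, fa$per_cell$q, tolerance = 1e-9)
  expect_equal(fb$tau_run$tau, fa$tau_run$tau, tolerance = 1e-9)
  expect_equal(fb$tau_rest$tau, fa$tau_rest$tau, tolerance = 1e-9)
})

test_that("comparing a fingerprint with itself finds no differences", {
  sim <- simulate_population(simulation_params(n_cells = 40, seed = 4))
  fp <- fingerprint(sim$collection)
  cmp <- compare_fingerprints(fp, fp)
  cells <- cmp$table[cmp$table$method == "welch_t", ]
  expect_equal(cells$difference, rep(0, 3))
  expect_equal(cells$p_value, rep(1, 3))
  expect_equal(cmp$lower_motility_count, 0)
})

test_that("swapping comparison arguments negates the differences", {
  a <- fingerprint(simulate_population(simulation_params(n_cells = 40, seed = 5))$collection)
  b <- fingerprint(simulate_population(simulation_params(n_cells = 40, seed = 6))$collection)
  ab <- compare_fingerprints(a, b)
  ba <- compare_fingerprints(b, a)
  expect_equal(ab$table$difference, -ba$table$difference, tolerance = 1e-9)
  expect_equal(ab$table$p_value[1:3], ba$table$p_value[1:3], tolerance = 1e-9)
})
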