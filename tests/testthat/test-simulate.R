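test_that("simulation parameters are validated", {
  expect_error(simulation_params(tau_run = -1), "positive")
  expect_error(simulation_params(reversal_prob = 1.5), "0, 1")
  expect_error(simulation_params(dt = 1, tau_run = 2, tau_rest = 2), "resolve")
  p <- simulation_params()
  expect_s3_class(p, "simulation_params")
  expect_equal(p$dt, 1 / 6)
})

test_that("the same seed reproduces the simulation bitwise", {
  p <- simulation_params(n_cells = 5, seed = 321)
  a <- simulate_population(p)
  b <- simulate_population(p)
  for (id in names(a$collection$trajectories)) {
    expect_identical(a$collection$trajectories[[id]]$phi,
                     b$collection$trajectories[[id]]$phi)
  }
  expect_identical(a$truth$segments, b$truth$segments)
  expect_identical(a$truth$frame_states, b$truth$frame_states)
})

test_that("noise-free runs are ballistic at exactly the cell speed", {
  p <- simulation_params(run_speed_jitter = 0, rest_wiggle_sd = 0,
                         reversal_prob = 0, immobile_fraction = 0,
                         speed_log_sd = 0, n_cells = 1, duration = 24,
                         seed = 9)
  sim <- simulate_population(p)
  tr <- sim$collection$trajectories[[1]]
  st <- sim$truth$frame_states[1, ]
  steps <- diff(tr$phi) * 75 / p$dt
  run_steps <- steps[st[-length(st)] == "RUN"]
  rest_steps <- steps[st[-length(st)] == "REST"]
  expect_equal(abs(run_steps), rep(30, length(run_steps)), tolerance = 1e-9)
  expect_equal(rest_steps, rep(0, length(rest_steps)))
  # without reversals or wiggle, phi is monotone
  expect_true(all(diff(tr$phi) >= 0) || all(diff(tr$phi) <= 0))
})

test_that("run-state renewal rate matches duration over cycle time", {
  p <- simulation_params(n_cells = 500, seed = 17, immobile_fraction = 0)
  sim <- simulate_population(p)
  segs <- sim$truth$segments
  # expected number of run starts strictly inside (0, duration):
  # duration / (tau_run + tau_rest) for a stationary alternating renewal
  n_starts <- vapply(split(segs, segs$cell_id), function(s) {
    sum(s$label == "RUN") - as.integer(s$label[1] == "RUN")
  }, numeric(1))
  expected <- p$duration / (p$tau_run + p$tau_rest)
  expect_lt(abs(mean(n_starts) / expected - 1), 0.05)
})

test_that("true dwell times under the horizon rule are exponential", {
  # completed-only durations are length-bias selected (long states
  # preferentially overrun the track end), so the exponential property is
  # asserted for the horizon-rule sample: states starting >= 16 h before
  # track end, censored ones kept with their observed duration
  p <- simulation_params(n_cells = 400, seed = 23, immobile_fraction = 0)
  sim <- simulate_population(p)
  segs <- sim$truth$segments
  starts <- unlist(tapply(segs$duration, segs$cell_id,
                          function(d) cumsum(c(0, d[-length(d)]))))
  keep <- (p$duration - starts) >= 16
  for (lab in c("RUN", "REST")) {
    tau <- if (lab == "RUN") p$tau_run else p$tau_rest
    d <- segs$duration[keep & segs$label == lab]
    s <- survival_function(d, p$dt, 16)
    band <- 4 * sqrt(exp(-s$t / tau) * (1 - exp(-s$t / tau)) / length(d)) +
      2 / length(d)
    expect_true(all(abs(s$S - exp(-s$t / tau)) <= band))
  }
})

test_that("per-cell speeds follow the configured lognormal", {
  p <- simulation_params(n_cells = 1000, seed = 71, immobile_fraction = 0,
                         duration = 2, dt = 1 / 6, tau_run = 1, tau_rest = 1)
  sim <- simulate_population(p)
  sp <- sim$truth$cells$cell_speed
  expect_lt(abs(median(sp) / p$speed_median - 1), 0.05)
  expect_lt(abs(sd(log(sp)) / p$speed_log_sd - 1), 0.1)
})

test_that("degenerate parameter settings behave as documented", {
  sim1 <- simulate_population(simulation_params(n_cells = 6, seed = 3,
                                                immobile_fraction = 1))
  expect_true(all(sim1$truth$frame_states == "REST"))
  expect_true(all(sim1$truth$cells$immobile))

  sim2 <- simulate_population(simulation_params(n_cells = 6, seed = 3,
                                                immobile_fraction = 0,
                                                speed_log_sd = 0))
  expect_equal(sim2$truth$cells$cell_speed, rep(30, 6))
})

test_that("emitted angles and true labels are mutually consistent", {
  p <- simulation_params(n_cells = 50, seed = 47, immobile_fraction = 0)
  sim <- simulate_population(p)
  run_means <- rest_means <- numeric(0)
  for (i in seq_len(50)) {
    tr <- sim$collection$trajectories[[i]]
    st <- sim$truth$frame_states[i, ]
    steps <- diff(tr$phi) * 75
    run_steps <- steps[st[-length(st)] == "RUN"]
    spd <- sim$truth$cells$cell_speed[i]
    if (length(run_steps) > 5) {
      run_means <- c(run_means, mean(abs(run_steps)) / p$dt / spd)
    }
    rest_steps <- steps[st[-length(st)] == "REST"]
    if (length(rest_steps) > 5) rest_means <- c(rest_means, mean(rest_steps))
  }
  expect_equal(mean(run_means), 1, tolerance = 0.02)
  expect_lt(abs(mean(rest_means)), 0.05)
})

test_that("a simulation round-trips through its manifest", {
  p <- simulation_params(n_cells = 4, seed = 88)
  sim <- simulate_population(p)
  dir <- withr::local_tempdir()
  tracks <- file.path(dir, "tracks.csv")
  truth <- file.path(dir, "truth.csv")
  manifest <- file.path(dir, "manifest.json")
  write_simulation(sim, tracks, truth, manifest)

  p2 <- read_manifest(manifest)
  sim2 <- simulate_population(p2)
  tracks2 <- file.path(dir, "tracks2.csv")
  write_simulation(sim2, tracks2)
  expect_identical(readLines(tracks), readLines(tracks2))

  tt <- read.csv(truth)
  expect_equal(nrow(tt), 4 * (48 * 6 + 1))
  expect_setequal(unique(tt$true_state), unique(as.vector(sim$truth$frame_states)))
})
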