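test_that("latent-module copies with full participation and no jitter are exact", {
  cfg <- sim_config(
    n_cells = 3, background_rate = 0, shock_cells = integer(0),
    modules = list(ensemble_module(1:3, rate = 4, participation = 1,
                                   jitter_sd = 0, sessions = "A2")),
    seed = 4)
  tr <- generate_event_trains(cfg, "A2")
  expect_gt(nrow(tr$trains[[1]]), 0)
  expect_equal(tr$trains[[2]]$time_s, tr$trains[[1]]$time_s)
  expect_equal(tr$trains[[3]]$time_s, tr$trains[[1]]$time_s)
  # and the planted raster is perfectly correlated after binarization
  R <- correlation_matrix(binarize_events(tr))
  expect_equal(R[1, 2], 1)
  expect_equal(R[2, 3], 1)
})

test_that("background event counts follow the Poisson mean", {
  lambda <- 2 # events/min
  cfg <- sim_config(n_cells = 2, background_rate = lambda, modules = list(),
                    shock_cells = integer(0), seed = 1)
  counts <- vapply(1:1000, function(s) {
    tr <- generate_event_trains(cfg, "A2", seed = s)
    mean(vapply(tr$trains, nrow, integer(1L)))
  }, numeric(1L))
  expected <- lambda * 180 / 60
  se <- sqrt(expected / (1000 * 2))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("event counts scale linearly with duration and rate", {
  mean_count <- function(rate, dur, seeds = 1:400) {
    sessions <- list(X = session_timeline("X", dur))
    cfg <- sim_config(n_cells = 2, sessions = sessions, background_rate = rate,
                      modules = list(), shock_cells = integer(0), seed = 1)
    mean(vapply(seeds, function(s) {
      mean(vapply(generate_event_trains(cfg, "X", seed = s)$trains, nrow,
                  integer(1L)))
    }, numeric(1L)))
  }
  m1 <- mean_count(2, 60)
  m2 <- mean_count(4, 60)
  m3 <- mean_count(2, 120)
  se <- sqrt(4 / (400 * 2))
  expect_lt(abs(m2 - 2 * m1), 3 * 2 * se)
  expect_lt(abs(m3 - 2 * m1), 3 * 2 * se)
})

test_that("shock cells get the configured in-window rate elevation", {
  # 5x multiplier over the 6-s response window, background 1/min:
  # expected in-window count = 5 * (1/60) * 6 = 0.5
  cfg <- sim_config(n_cells = 1, background_rate = 1, modules = list(),
                    shock_cells = 1L, shock_rate_multiplier = 5, seed = 1)
  w <- shock_response_window(cfg$sessions$A1)
  counts <- vapply(1:1000, function(s) {
    tr <- generate_event_trains(cfg, "A1", seed = s)
    sum(tr$trains[[1]]$time_s >= w[1] & tr$trains[[1]]$time_s < w[2])
  }, numeric(1L))
  expect_lt(abs(mean(counts) - 0.5), 3 * sqrt(0.5 / 1000))
})

test_that("unknown session labels and invalid configs are rejected", {
  cfg <- sim_config(seed = 1)
  expect_error(generate_event_trains(cfg, "nope"), "unknown session")
  expect_error(sim_config(background_rate = -1))
  expect_error(ensemble_module(1:3, participation = 1.2))
  expect_error(sim_config(n_cells = 4,
                          modules = list(ensemble_module(1:9))),
               "module members")
})

test_that("rendered kernels have the planted amplitude and half-time decay", {
  cfg <- sim_config(n_cells = 1, background_rate = 0, modules = list(),
                    shock_cells = integer(0), noise_sd = 0, fps = 20, seed = 1)
  # event at a frame center so discretization is exact
  t0 <- 50 + 0.5 / 20
  tr <- generate_event_trains(cfg, "A2", seed = 1)
  tr$trains[[1]] <- data.frame(time_s = t0, amplitude_sd = 3)
  tx <- render_traces(tr, cfg)
  expect_equal(max(tx$values), 3)
  peak_frame <- which.max(tx$values[1, ])
  expect_equal(unname(tx$values[1, peak_frame + 4]), 1.5)  # 200 ms later
})

test_that("overlapping kernels sum", {
  cfg <- sim_config(n_cells = 1, background_rate = 0, modules = list(),
                    shock_cells = integer(0), noise_sd = 0, fps = 20, seed = 1)
  t0 <- 50 + 0.5 / 20
  tr <- generate_event_trains(cfg, "A2", seed = 1)
  tr$trains[[1]] <- data.frame(time_s = c(t0, t0 + 0.2), amplitude_sd = c(2, 2))
  tx <- render_traces(tr, cfg)
  f2 <- which(abs((seq_len(ncol(tx$values)) - 0.5) / 20 - (t0 + 0.2)) < 1e-9)
  expect_equal(unname(tx$values[1, f2]), 2 + 2 * 2^-1)  # peak + decayed first
})

test_that("generation and rendering are seed-deterministic", {
  cfg <- sim_config(n_cells = 10, seed = 9)
  a <- generate_event_trains(cfg, "A1")
  b <- generate_event_trains(cfg, "A1")
  expect_identical(a, b)
  expect_identical(render_traces(a, cfg)$values, render_traces(b, cfg)$values)
  d1 <- simulate_animal(cfg)
  d2 <- simulate_animal(cfg)
  expect_identical(d1$traces[["A2"]]$values, d2$traces[["A2"]]$values)
  expect_identical(d1$timelines[["A2"]]$freezing, d2$timelines[["A2"]]$freezing)
})

test_that("freezing bouts approximate the configured fraction", {
  cfg <- sim_config(n_cells = 2, freezing = list(A1 = 0.05, A2 = 0.4, B = 0.1),
                    seed = 2)
  fr <- vapply(1:50, function(s) {
    d <- simulate_animal(cfg, seed = s)
    percent_freezing(d$timelines[["A2"]]) / 100
  }, numeric(1L))
  expect_lt(abs(mean(fr) - 0.4), 0.08)
  # bouts respect the 1-s minimum
  d <- simulate_animal(cfg, seed = 3)
  fz <- d$timelines[["A2"]]$freezing
  expect_true(all(fz[, 2] - fz[, 1] >= 1 - 1e-9))
})

test_that("cohort generator encodes the planted strength-freezing relation", {
  # no effect, no noise: planted strengths identical
  co0 <- simulate_cohort(n_animals = 6, slope = 0, noise_sd = 0, seed = 1)
  expect_equal(var(co0$summary$planted_strength), 0)
  # exact line: downstream regression recovers the slope exactly
  co <- simulate_cohort(n_animals = 12, slope = 0.5, noise_sd = 0, seed = 2)
  fit <- suppressWarnings(  # lm flags the deliberately exact fit
    regress_deltas_on_freezing(co$summary, delta_col = "planted_strength"))
  expect_equal(fit$slope, 0.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_error(simulate_cohort(n_animals = 2), ">= 3")
})

test_that("rendered cohort datasets vary participation with planted strength", {
  co <- simulate_cohort(n_animals = 3, slope = 0.5, noise_sd = 0.05,
                        config = sim_config(n_cells = 20), seed = 5,
                        render = TRUE)
  expect_length(co$datasets, 3)
  p <- vapply(co$datasets,
              function(d) d$config$modules[[1]]$participation, numeric(1L))
  ord <- order(co$summary$planted_strength)
  expect_equal(order(p), ord)
})
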