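#' Default 3-day contextual fear conditioning session plan
#'
#' Context A encoding (`A1`, 184 s: 3 min exploration, 2-s foot shock at
#' 178-180 s, session extended to contain the 6-s shock-response window),
#' context retrieval (`A2`, 180 s) and novel context (`B`, 180 s, or 360 s
#' with three 20-s tones at minutes 3/4/5 when `tones = TRUE`).
#'
#' @param tones Include the day-3 tone-retrieval variant of session B.
#' @return Named list of [session_timeline()] objects.
#' @export
cfc_sessions <- function(tones = FALSE) {
  b <- if (tones) {
    session_timeline("B", 360,
                     tones = rbind(c(180, 200), c(240, 260), c(300, 320)))
  } else {
    session_timeline("B", 180)
  }
  list(
    A1 = session_timeline("A1", 184, shock = c(178, 180)),
    A2 = session_timeline("A2", 180),
    B = b
  )
}

#' Homecage opto pulse session
#'
#' Six 30-s amber-LED ON epochs interleaved with seven 60-s OFF epochs
#' (600 s total), the paradigm used to identify opto-modulated cells.
#'
#' @return A [session_timeline()] labeled `"homecage"`.
#' @export
opto_session <- function() {
  on <- 60 + (0:5) * 90
  session_timeline("homecage", 600, opto = cbind(on, on + 30))
}

#' Latent-source ensemble module specification
#'
#' A module is a latent Poisson event train shared by its member cells:
#' each latent event is copied into each member with probability
#' `participation` and jittered by a Gaussian of s.d. `jitter_sd` seconds.
#' With 1-s raster bins, the default 0.2-s jitter keeps most co-events in
#' the same bin, producing the correlated pairs the graph analysis detects.
#'
#' @param cells Integer indices of member cells.
#' @param rate Latent event rate, events/min.
#' @param participation Copy probability per member per latent event.
#' @param jitter_sd Gaussian jitter s.d., seconds.
#' @param sessions Session labels in which the module is active.
#' @return A `module_spec` list.
#' @export
ensemble_module <- function(cells, rate = 4, participation = 0.8,
                            jitter_sd = 0.2, sessions = "A2") {
  stopifnot(length(cells) >= 2L, all(cells == floor(cells)), all(cells >= 1L),
            rate >= 0, participation >= 0, participation <= 1, jitter_sd >= 0)
  structure(list(cells = as.integer(cells), rate = rate,
                 participation = participation, jitter_sd = jitter_sd,
                 sessions = sessions),
            class = "module_spec")
}

#' Simulation configuration
#'
#' Ground-truthed generative model for a multi-session imaging dataset:
#' per-cell homogeneous Poisson background events, latent-source correlated
#' modules, shock-responsive cells with an elevated rate inside the
#' shock-response window of A1, GCaMP-like transient kernels (linear rise,
#' exponential decay with 200-ms half-time), additive white Gaussian trace
#' noise, and freezing bouts with per-session target fractions.
#'
#' Event amplitudes are drawn i.i.d. per event in units of the trace noise
#' s.d. (default mean 4, s.d. 1) so that detection at the 2-s.d. threshold
#' is exercised near threshold.
#'
#' @param n_cells Number of cells in the field of view.
#' @param sessions Named list of [session_timeline()]s (default [cfc_sessions()]).
#' @param background_rate Background event rate, events/min per cell.
#' @param modules List of [ensemble_module()]s (members must be `<= n_cells`).
#' @param shock_cells Indices of shock-responsive cells.
#' @param shock_rate_multiplier In-window rate multiplier (`>= 1`) applied to
#'   shock cells during the shock-response window of sessions with a shock.
#' @param kernel Named numeric `(rise, decay_half)` in seconds; the decay
#'   half-time default 0.2 s matches GCaMP6f kinetics.
#' @param noise_sd Additive white trace noise s.d. (the amplitude unit).
#' @param amplitude_mean,amplitude_sd Event amplitude distribution in
#'   noise-s.d. units.
#' @param fps Rendered sampling rate, frames/s (acquisition-like; default 20).
#' @param freezing Named list of target freezing fractions per session.
#' @param fov_size Field-of-view side length (micrometers) for centroids.
#' @param seed Base seed; all stages derive their seeds from it.
#' @return A validated `sim_config` object.
#' @export
#' @examples
#' cfg <- sim_config(n_cells = 25, seed = 1)
#' tr <- generate_event_trains(cfg, "A1")
#' length(tr$trains)
sim_config <- function(n_cells = 70,
                       sessions = cfc_sessions(),
                       background_rate = 2,
                       modules = default_modules(n_cells, shock_cells),
                       shock_cells = seq_len(min(6L, n_cells)),
                       shock_rate_multiplier = 10,
                       kernel = c(rise = 0.2, decay_half = 0.2),
                       noise_sd = 1,
                       amplitude_mean = 4,
                       amplitude_sd = 1,
                       fps = 20,
                       freezing = list(A1 = 0.05, A2 = 0.30, B = 0.10),
                       fov_size = 300,
                       seed = 1L) {
  stopifnot(n_cells >= 1L, background_rate >= 0, shock_rate_multiplier >= 1,
            noise_sd >= 0, amplitude_sd >= 0, fps > 0, fov_size > 0,
            all(c("rise", "decay_half") %in% names(kernel)),
            all(kernel > 0))
  stopifnot(is.list(sessions), length(sessions) >= 1L,
            all(vapply(sessions, inherits, logical(1L), "ca_timeline")))
  if (is.null(names(sessions)))
    names(sessions) <- vapply(sessions, `[[`, character(1L), "label")
  shock_cells <- as.integer(shock_cells)
  stopifnot(all(shock_cells >= 1L), all(shock_cells <= n_cells))
  for (m in modules) {
    stopifnot(inherits(m, "module_spec"))
    if (any(m$cells > n_cells))
      stop("module members must be cell indices <= n_cells", call. = FALSE)
  }
  stopifnot(all(vapply(freezing, function(f) f >= 0 && f <= 1, logical(1L))))
  structure(list(
    n_cells = as.integer(n_cells), sessions = sessions,
    background_rate = background_rate, modules = modules,
    shock_cells = shock_cells, shock_rate_multiplier = shock_rate_multiplier,
    kernel = kernel, noise_sd = noise_sd,
    amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
    fps = fps, freezing = freezing, fov_size = fov_size,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default planted ensemble for the standard cohort
#'
#' One A2-only module joining a subset of the shock cells to a set of
#' prospective "shock partner" cells: during retrieval these members share
#' latent events and become correlated, while the remaining shock cells and
#' all other cells do not. Mirrors the observation that only part of the
#' shock population joins the retrieval ensemble.
#'
#' @param n_cells,shock_cells As in [sim_config()].
#' @return List with one [ensemble_module()] (empty if the FOV is too small).
#' @export
default_modules <- function(n_cells, shock_cells = seq_len(min(6L, n_cells))) {
  n_shock_in <- min(3L, length(shock_cells))
  partners <- setdiff(seq_len(n_cells), shock_cells)
  n_partners <- min(9L, length(partners))
  members <- c(shock_cells[seq_len(n_shock_in)], partners[seq_len(n_partners)])
  if (length(members) < 2L) return(list())
  list(ensemble_module(members, rate = 4, participation = 0.8,
                       jitter_sd = 0.2, sessions = "A2"))
}

cell_ids_for <- function(n) sprintf("cell_%03d", seq_len(n))

#' Generate ground-truthed event trains for one session
#'
#' Each cell's train is the union of background homogeneous Poisson events,
#' latent-module copies (kept with probability `participation`, jittered),
#' and, for shock cells in a session with a shock, extra events inside the
#' shock-response window bringing the in-window rate to
#' `background_rate * shock_rate_multiplier`. Event amplitudes are drawn
#' i.i.d. from the configured distribution (floored at 0.2 noise s.d.).
#'
#' @param config A [sim_config()].
#' @param session Session label present in `config$sessions`.
#' @param seed Seed (default derived from `config$seed` and the session).
#' @return A `ca_event_trains` object: per-cell data frames of sorted peak
#'   times (s) and amplitudes (noise-s.d. units), plus a `ground_truth`
#'   element (per-event source, module assignment, shock flags).
#' @export
generate_event_trains <- function(config, session, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!session %in% names(config$sessions))
    stop(sprintf("unknown session label '%s'", session), call. = FALSE)
  tl <- config$sessions[[session]]
  dur <- tl$duration
  if (is.null(seed))
    seed <- derive_seed(config$seed, 7L * match(session, names(config$sessions)))
  ids <- cell_ids_for(config$n_cells)

  with_seed(seed, {
    ev <- replicate(config$n_cells,
                    data.frame(time_s = numeric(0), amplitude_sd = numeric(0),
                               source = character(0)),
                    simplify = FALSE)
    add <- function(cell, times, source) {
      if (!length(times)) return()
      amps <- pmax(stats::rnorm(length(times), config$amplitude_mean,
                                config$amplitude_sd), 0.2)
      ev[[cell]] <<- rbind(ev[[cell]],
                           data.frame(time_s = times, amplitude_sd = amps,
                                      source = source))
    }
    ## background Poisson events
    lam_bg <- config$background_rate * dur / 60
    for (i in seq_len(config$n_cells)) {
      n <- stats::rpois(1L, lam_bg)
      add(i, stats::runif(n, 0, dur), "background")
    }
    ## latent-source module events
    module_of <- rep(NA_integer_, config$n_cells)
    for (k in seq_along(config$modules)) {
      m <- config$modules[[k]]
      module_of[m$cells] <- k
      if (!session %in% m$sessions) next
      n_lat <- stats::rpois(1L, m$rate * dur / 60)
      latent <- stats::runif(n_lat, 0, dur)
      for (cell in m$cells) {
        keep <- latent[stats::runif(n_lat) < m$participation]
        if (length(keep)) {
          t <- keep + stats::rnorm(length(keep), 0, m$jitter_sd)
          t <- t[t >= 0 & t < dur]
          add(cell, t, paste0("module", k))
        }
      }
    }
    ## shock-window elevation
    if (!is.null(tl$shock) && config$shock_rate_multiplier > 1 &&
        length(config$shock_cells)) {
      w <- shock_response_window(tl)
      lam_extra <- config$background_rate * (config$shock_rate_multiplier - 1) *
        (w[2L] - w[1L]) / 60
      for (cell in config$shock_cells) {
        n <- stats::rpois(1L, lam_extra)
        add(cell, stats::runif(n, w[1L], w[2L]), "shock")
      }
    }
    trains <- lapply(ev, function(d) {
      d <- d[order(d$time_s), , drop = FALSE]
      rownames(d) <- NULL
      d[, c("time_s", "amplitude_sd")]
    })
    names(trains) <- ids
    gt_events <- lapply(ev, function(d) {
      d <- d[order(d$time_s), , drop = FALSE]
      rownames(d) <- NULL
      d
    })
    names(gt_events) <- ids
    structure(list(
      trains = trains, cell_ids = ids, session = session, duration = dur,
      ground_truth = list(
        events = gt_events,
        module = stats::setNames(module_of, ids),
        shock_cell = stats::setNames(seq_len(config$n_cells) %in%
                                       config$shock_cells, ids)
      )
    ), class = "ca_event_trains")
  })
}

#' @export
print.ca_event_trains <- function(x, ...) {
  n_ev <- sum(vapply(x$trains, nrow, integer(1L)))
  cat(sprintf("<ca_event_trains> %d cells, session %s (%.0f s), %d events\n",
              length(x$trains), x$session %||% "?", x$duration, n_ev))
  invisible(x)
}

## transient kernel sampled at times t (s) relative to an event at t0
## with amplitude A: linear rise over `rise` s, then exponential decay with
## half-time `half` s
kernel_value <- function(t, t0, A, rise, half) {
  dt <- t - t0
  out <- numeric(length(t))
  up <- dt >= -rise & dt < 0
  out[up] <- A * (1 + dt[up] / rise)
  dn <- dt >= 0
  out[dn] <- A * 2^(-dt[dn] / half)
  out
}

#' Render fluorescence traces from event trains
#'
#' Each event contributes a transient kernel (linear rise to its amplitude
#' over the configured rise time, then exponential decay with the configured
#' half-time); overlapping kernels sum. White Gaussian noise of s.d.
#' `config$noise_sd` is added. Frames are sampled at frame centers.
#'
#' @param trains A `ca_event_trains` object.
#' @param config The [sim_config()] used to generate them.
#' @param seed Seed for the noise (default derived from `config$seed`).
#' @return A `ca_traces` object (cells x frames matrix plus `fps`).
#' @export
render_traces <- function(trains, config, seed = NULL) {
  stopifnot(inherits(trains, "ca_event_trains"), inherits(config, "sim_config"))
  if (is.null(seed))
    seed <- derive_seed(config$seed,
                        101L + match(trains$session, names(config$sessions),
                                     nomatch = 0L))
  fps <- config$fps
  n_frames <- round(trains$duration * fps)
  t_frames <- (seq_len(n_frames) - 0.5) / fps
  rise <- config$kernel[["rise"]]
  half <- config$kernel[["decay_half"]]
  ## decay is negligible (< 1/2^12 of peak) after 12 half-times
  tail_s <- 12 * half
  vals <- matrix(0, nrow = length(trains$trains), ncol = n_frames,
                 dimnames = list(trains$cell_ids, NULL))
  for (i in seq_along(trains$trains)) {
    d <- trains$trains[[i]]
    for (j in seq_len(nrow(d))) {
      t0 <- d$time_s[j]
      f1 <- max(1L, ceiling((t0 - rise) * fps))
      f2 <- min(n_frames, ceiling((t0 + tail_s) * fps))
      if (f2 < f1) next
      idx <- f1:f2
      vals[i, idx] <- vals[i, idx] +
        kernel_value(t_frames[idx], t0, d$amplitude_sd[j], rise, half)
    }
  }
  if (config$noise_sd > 0) {
    vals <- vals + with_seed(seed,
      matrix(stats::rnorm(length(vals), 0, config$noise_sd), nrow = nrow(vals)))
  }
  ca_traces(vals, fps = fps, cell_ids = trains$cell_ids,
            session = trains$session)
}

## freezing bouts targeting fraction f: alternating exponential mobile /
## freeze intervals (freeze bouts mean 4 s, floored at the 1-s minimum)
generate_freezing <- function(duration, fraction, seed = NULL) {
  if (fraction <= 0) return(matrix(numeric(0), ncol = 2L))
  with_seed(seed, {
    mean_frz <- 4
    mean_mob <- max(mean_frz * (1 - fraction) / fraction, 0.5)
    t <- stats::rexp(1L, 1 / mean_mob)  # start mobile
    bouts <- NULL
    while (t < duration) {
      len <- max(1, stats::rexp(1L, 1 / mean_frz))
      bouts <- rbind(bouts, c(t, min(t + len, duration)))
      t <- t + len + stats::rexp(1L, 1 / mean_mob)
    }
    merge_intervals(bouts)
  })
}

#' Simulate one animal (all sessions)
#'
#' Generates event trains, rendered traces, timelines with freezing bouts,
#' and cell centroids for every session in the configuration. Module member
#' centroids are spatially clustered (Gaussian, 30 um s.d.) so that
#' correlated pairs are closer than non-correlated pairs, as observed in
#' tissue.
#'
#' @param config A [sim_config()].
#' @param seed Base seed (default `config$seed`).
#' @return A `ca_dataset`: lists `trains`, `traces`, `timelines` keyed by
#'   session, a `centroids` data frame, and the `config`.
#' @export
simulate_animal <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  sessions <- names(config$sessions)
  trains <- traces <- timelines <- list()
  for (s in seq_along(sessions)) {
    lab <- sessions[s]
    tr <- generate_event_trains(config, lab, seed = derive_seed(seed, 7L * s))
    trains[[lab]] <- tr
    traces[[lab]] <- render_traces(tr, config, seed = derive_seed(seed, 101L + s))
    tl <- config$sessions[[lab]]
    frz <- config$freezing[[lab]] %||% 0
    timelines[[lab]] <- session_timeline(
      tl$label, tl$duration, shock = tl$shock,
      tones = tl$tones, opto = tl$opto,
      freezing = generate_freezing(tl$duration, frz,
                                   seed = derive_seed(seed, 211L + s)))
  }
  centroids <- with_seed(derive_seed(seed, 307L), {
    xy <- matrix(stats::runif(2L * config$n_cells, 0, config$fov_size),
                 ncol = 2L)
    for (m in config$modules) {
      ctr <- stats::runif(2L, 0.2 * config$fov_size, 0.8 * config$fov_size)
      xy[m$cells, ] <- matrix(rep(ctr, each = length(m$cells)), ncol = 2L) +
        matrix(stats::rnorm(2L * length(m$cells), 0, 30), ncol = 2L)
      xy <- pmin(pmax(xy, 0), config$fov_size)
    }
    data.frame(cell_id = cell_ids_for(config$n_cells), x = xy[, 1L], y = xy[, 2L])
  })
  structure(list(trains = trains, traces = traces, timelines = timelines,
                 centroids = centroids, config = config, seed = seed),
            class = "ca_dataset")
}

#' @export
print.ca_dataset <- function(x, ...) {
  cat(sprintf("<ca_dataset> %d cells, sessions: %s\n",
              x$config$n_cells, paste(names(x$trains), collapse = ", ")))
  invisible(x)
}

#' Simulate a cohort with a planted strength-freezing relation
#'
#' Per-animal freezing change (A2 - A1, as a fraction of session time) is
#' drawn uniformly from `freezing_range`; the planted ensemble strength
#' follows `strength = slope * freezing_change + N(0, noise_sd)`. Strength is
#' in the units of the downstream regression response (mean graph-metric
#' change of the shock + partner network), so regressing planted strength on
#' freezing change recovers `slope`. With `render = TRUE`, full per-animal
#' datasets are built in which the A2 module participation is a clamped
#' monotone map of strength and the A2 freezing target equals
#' `baseline + freezing_change`.
#'
#' @param n_animals Number of animals (`>= 3`).
#' @param slope True slope linking freezing change to planted strength.
#' @param noise_sd Gaussian noise s.d. on planted strength.
#' @param freezing_range Range of per-animal freezing change (fractions).
#' @param config Template [sim_config()] used when rendering.
#' @param seed Cohort seed.
#' @param render Build full datasets (slow) or just the planted summary.
#' @return List with `summary` (animal, freezing_change, planted_strength),
#'   `slope`, and (if rendered) `datasets`.
#' @export
simulate_cohort <- function(n_animals = 12, slope = 0.5, noise_sd = 0.1,
                            freezing_range = c(0.05, 0.45),
                            config = sim_config(), seed = 1L,
                            render = FALSE) {
  if (n_animals < 3L) stop("n_animals must be >= 3", call. = FALSE)
  stopifnot(inherits(config, "sim_config"))
  summary <- with_seed(derive_seed(seed, 401L), {
    f <- stats::runif(n_animals, freezing_range[1L], freezing_range[2L])
    s <- slope * f + stats::rnorm(n_animals, 0, noise_sd)
    data.frame(animal = sprintf("animal_%02d", seq_len(n_animals)),
               freezing_change = f, planted_strength = s)
  })
  out <- list(summary = summary, slope = slope)
  if (render) {
    out$datasets <- lapply(seq_len(n_animals), function(a) {
      p <- min(max(4 * summary$planted_strength[a], 0.05), 0.95)
      mods <- lapply(config$modules, function(m) {
        m$participation <- p
        m
      })
      frz <- config$freezing
      base_a1 <- frz$A1 %||% 0.05
      frz$A2 <- min(base_a1 + summary$freezing_change[a], 0.95)
      cfg <- sim_config(
        n_cells = config$n_cells, sessions = config$sessions,
        background_rate = config$background_rate, modules = mods,
        shock_cells = config$shock_cells,
        shock_rate_multiplier = config$shock_rate_multiplier,
        kernel = config$kernel, noise_sd = config$noise_sd,
        amplitude_mean = config$amplitude_mean,
        amplitude_sd = config$amplitude_sd, fps = config$fps,
        freezing = frz, fov_size = config$fov_size,
        seed = derive_seed(seed, 500L + a))
      simulate_animal(cfg)
    })
    names(out$datasets) <- summary$animal
  }
  out
}
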