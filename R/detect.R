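#' Fluorescence trace matrix
#'
#' Container for extracted per-cell fluorescence traces: a cells x frames
#' numeric matrix, the sampling rate, stable cell identifiers and a session
#' label. Frame times are taken at frame centers, `(f - 0.5) / fps` seconds.
#'
#' @param values Numeric cells x frames matrix (finite).
#' @param fps Sampling rate, frames/s.
#' @param cell_ids Character ids, one per row (default from rownames).
#' @param session Optional session label.
#' @return A `ca_traces` object.
#' @export
ca_traces <- function(values, fps, cell_ids = rownames(values), session = NULL) {
  values <- as.matrix(values)
  stop_if_not_scalar_pos(fps, "fps")
  if (is.null(cell_ids)) cell_ids <- cell_ids_for(nrow(values))
  stopifnot(length(cell_ids) == nrow(values))
  rownames(values) <- cell_ids
  structure(list(values = values, fps = fps, cell_ids = cell_ids,
                 session = session),
            class = "ca_traces")
}

#' @export
print.ca_traces <- function(x, ...) {
  cat(sprintf("<ca_traces> %d cells x %d frames @ %g fps (%s)\n",
              nrow(x$values), ncol(x$values), x$fps, x$session %||% "unlabeled"))
  invisible(x)
}

frame_times <- function(traces) (seq_len(ncol(traces$values)) - 0.5) / traces$fps

#' Assemble event trains from per-cell peak times
#'
#' Builds the `ca_event_trains` container used throughout the package from
#' a named list of per-cell event tables (or numeric vectors of peak
#' times), e.g. when importing events produced by other software.
#'
#' @param trains Named list; each element a data frame with `time_s` (and
#'   optionally `amplitude_sd`) or a numeric vector of peak times.
#' @param duration Session duration, seconds.
#' @param session Optional session label.
#' @return A `ca_event_trains` object.
#' @export
event_trains <- function(trains, duration, session = NULL) {
  stop_if_not_scalar_pos(duration, "duration")
  stopifnot(is.list(trains))
  ids <- names(trains) %||% cell_ids_for(length(trains))
  trains <- lapply(trains, function(t) {
    d <- if (is.data.frame(t)) {
      stopifnot("time_s" %in% names(t))
      if (is.null(t$amplitude_sd))
        t$amplitude_sd <- rep(NA_real_, nrow(t))
      t[, c("time_s", "amplitude_sd")]
    } else {
      data.frame(time_s = as.numeric(t), amplitude_sd = NA_real_)
    }
    d <- d[order(d$time_s), , drop = FALSE]
    if (nrow(d) && (d$time_s[1L] < 0 || d$time_s[nrow(d)] >= duration))
      stop("event times must lie in [0, duration)", call. = FALSE)
    rownames(d) <- NULL
    d
  })
  names(trains) <- ids
  structure(list(trains = trains, cell_ids = ids, session = session,
                 duration = as.numeric(duration)),
            class = "ca_event_trains")
}

#' Transient detection parameters
#'
#' Defaults follow the published event-detection settings: transients must
#' exceed a 2-s.d. amplitude from a 0.5-s.d. baseline and last a minimum
#' duration given by the GCaMP6f decay half-time (200 ms) and the reference
#' amplitude `a0 = 0.5`; additional rising peaks inside a multi-peaked
#' transient require 1.5-s.d. prominence and 1-s separation; traces are
#' analyzed at 5 frames/s; the silent-timepoint threshold is the pooled
#' 0.50 quantile of all fluorescence values in the field of view.
#'
#' @param amp_threshold Peak amplitude threshold, s.d. units.
#' @param baseline Envelope baseline, s.d. units.
#' @param a0 Reference amplitude in the minimum-duration rule.
#' @param t_half Indicator decay half-time, seconds.
#' @param peak_prominence Secondary-peak prominence, s.d. units.
#' @param min_peak_distance Minimum secondary-peak separation, seconds.
#' @param silent_quantile Pooled quantile defining silent timepoints.
#' @param target_fps Analysis frame rate after downsampling.
#' @return A `detection_params` list.
#' @export
detection_params <- function(amp_threshold = 2, baseline = 0.5, a0 = 0.5,
                             t_half = 0.2, peak_prominence = 1.5,
                             min_peak_distance = 1, silent_quantile = 0.5,
                             target_fps = 5) {
  p <- list(amp_threshold = amp_threshold, baseline = baseline, a0 = a0,
            t_half = t_half, peak_prominence = peak_prominence,
            min_peak_distance = min_peak_distance,
            silent_quantile = silent_quantile, target_fps = target_fps)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L || v <= 0,
                 logical(1L))))
    stop("all detection parameters must be positive scalars", call. = FALSE)
  if (amp_threshold <= baseline)
    stop("amp_threshold must exceed baseline", call. = FALSE)
  if (silent_quantile >= 1) stop("silent_quantile must be < 1", call. = FALSE)
  structure(p, class = "detection_params")
}

#' Temporally downsample traces by block averaging
#'
#' Frames are averaged in non-overlapping blocks of `fps / target_fps`
#' (which must be a whole number); a trailing partial block is dropped.
#'
#' @param traces A [ca_traces()] object.
#' @param target_fps Output rate, frames/s.
#' @return A [ca_traces()] at `target_fps`.
#' @export
#' @examples
#' tr <- ca_traces(matrix(1:4, nrow = 1), fps = 4)
#' downsample_traces(tr, 1)$values  # 2.5
downsample_traces <- function(traces, target_fps) {
  stopifnot(inherits(traces, "ca_traces"))
  stop_if_not_scalar_pos(target_fps, "target_fps")
  if (traces$fps < target_fps)
    stop("target_fps exceeds the trace sampling rate", call. = FALSE)
  factor <- traces$fps / target_fps
  if (abs(factor - round(factor)) > 1e-8)
    stop(sprintf(
      "fps (%g) must be divisible by target_fps (%g) for block averaging",
      traces$fps, target_fps), call. = FALSE)
  factor <- as.integer(round(factor))
  if (factor == 1L) return(traces)
  nb <- ncol(traces$values) %/% factor
  if (nb < 1L) stop("trace too short to downsample", call. = FALSE)
  v <- traces$values[, seq_len(nb * factor), drop = FALSE]
  grp <- rep(seq_len(nb), each = factor)
  out <- t(rowsum(t(v), grp, reorder = TRUE)) / factor
  ca_traces(out, fps = target_fps, cell_ids = traces$cell_ids,
            session = traces$session)
}

## robust Gaussian noise level of a trace (MAD-based; insensitive to sparse
## positive transients)
noise_level <- function(x) stats::mad(x)

#' Z-score traces against a silent-timepoint baseline
#'
#' Silent timepoints are frames whose fluorescence falls below the pooled
#' `silent_quantile` (default 0.50) of all values from all cells in the
#' field of view. Each cell is scaled by a robust estimate of its Gaussian
#' noise level (1.4826 x MAD) and centered on its silent-timepoint mean.
#' Because the mean of a sub-quantile subset of symmetric noise is biased
#' low by `sd * dnorm(qnorm(q)) / q`, that truncated-Gaussian correction is
#' applied, so a pure-noise trace maps to approximately zero-mean,
#' unit-s.d. z units.
#'
#' Cells whose silent timepoints have zero variance (degenerate traces) are
#' excluded with a warning and recorded in `attr(, "excluded")`.
#'
#' @param traces A [ca_traces()] object.
#' @param params A [detection_params()] list.
#' @return A [ca_traces()] in z units, with attributes `silent_threshold`,
#'   `baseline_mean`, `noise_sd` and `excluded`.
#' @export
zscore_traces <- function(traces, params = detection_params()) {
  stopifnot(inherits(traces, "ca_traces"), inherits(params, "detection_params"))
  v <- traces$values
  if (!all(is.finite(v))) stop("traces must be finite", call. = FALSE)
  if (length(unique(as.vector(v))) < 2L)
    stop("need at least two distinct fluorescence values", call. = FALSE)
  thr <- stats::quantile(as.vector(v), probs = params$silent_quantile,
                         names = FALSE, type = 7)
  n <- nrow(v)
  mu <- sdv <- rep(NA_real_, n)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    x <- v[i, ]
    silent <- x[x < thr]
    s <- noise_level(x)
    if (length(silent) < 2L || s <= 0 || stats::var(silent) == 0) {
      keep[i] <- FALSE
      next
    }
    q <- length(silent) / length(x)
    mu[i] <- mean(silent) + s * stats::dnorm(stats::qnorm(q)) / q
    sdv[i] <- s
  }
  if (!all(keep))
    warning(sprintf("excluding %d degenerate cell(s): %s", sum(!keep),
                    paste(traces$cell_ids[!keep], collapse = ", ")))
  z <- (v[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  out <- ca_traces(z, fps = traces$fps, cell_ids = traces$cell_ids[keep],
                   session = traces$session)
  attr(out, "silent_threshold") <- thr
  attr(out, "baseline_mean") <- stats::setNames(mu[keep], traces$cell_ids[keep])
  attr(out, "noise_sd") <- stats::setNames(sdv[keep], traces$cell_ids[keep])
  attr(out, "excluded") <- traces$cell_ids[!keep]
  out
}

#' Minimum transient duration for a given amplitude
#'
#' Time for an exponential with half-time `t_half` to decay from amplitude
#' `A` to the reference level `a0`: `t_half * log2(A / a0)`, floored at 0.
#' A transient of peak amplitude `A` must remain above baseline at least
#' this long to be accepted.
#'
#' @param A Peak amplitude(s), s.d. units; must be `>=` the baseline.
#' @param params A [detection_params()] list.
#' @return Duration(s) in seconds; nondecreasing in `A`.
#' @export
#' @examples
#' min_duration(c(0.5, 1, 2))  # 0, 0.2, 0.4
min_duration <- function(A, params = detection_params()) {
  stopifnot(is.numeric(A))
  if (any(A < params$baseline))
    stop("amplitude below baseline has no defined duration", call. = FALSE)
  pmax(params$t_half * log2(A / params$a0), 0)
}

## MATLAB-style peak prominence within a window: drop to the higher of the
## two bases (minima between the peak and the nearest higher point or edge)
peak_prominence_in <- function(w, j) {
  L <- length(w)
  left <- if (j == 1L) w[j] else {
    k <- j - 1L
    while (k > 1L && w[k] <= w[j]) k <- k - 1L
    min(w[k:(j - 1L)])
  }
  right <- if (j == L) w[j] else {
    k <- j + 1L
    while (k < L && w[k] <= w[j]) k <- k + 1L
    min(w[(j + 1L):k])
  }
  w[j] - max(left, right)
}

## supra-baseline duration of a run of frames, with the baseline crossing
## times linearly interpolated between the boundary frames (frame centers);
## counting whole frames instead would bias the duration low by up to one
## frame and reject genuine transients whose decay is exactly at the
## indicator half-time
envelope_duration <- function(v, i1, i2, b, dt) {
  n <- length(v)
  t_of <- function(i) (i - 0.5) * dt
  t_up <- if (i1 == 1L) t_of(1L) - dt / 2 else
    t_of(i1 - 1L) + dt * (b - v[i1 - 1L]) / (v[i1] - v[i1 - 1L])
  t_dn <- if (i2 == n) t_of(n) + dt / 2 else
    t_of(i2) + dt * (v[i2] - b) / (v[i2] - v[i2 + 1L])
  t_dn - t_up
}

## detect events in one z-scored trace; returns peak indices and a logical
## mask of frames belonging to accepted transients
detect_cell <- function(v, fps, params) {
  dt <- 1 / fps
  above <- v > params$baseline
  mask <- logical(length(v))
  peaks <- integer(0)
  if (!any(above)) return(list(peaks = peaks, mask = mask))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i1 <- starts[k]; i2 <- ends[k]
    w <- v[i1:i2]
    m <- max(w)
    if (m < params$amp_threshold) next
    if (envelope_duration(v, i1, i2, params$baseline, dt) <
        min_duration(m, params) - 1e-9) next
    mask[i1:i2] <- TRUE
    ## candidate local maxima inside the envelope (first frame of plateaus)
    L <- length(w)
    cand <- if (L == 1L) 1L else {
      up <- c(TRUE, diff(w) > 0)
      dn <- c(diff(w) <= 0, TRUE)
      which(up & dn)
    }
    main <- which.max(w)
    cand <- union(main, cand)
    cand <- cand[order(-w[cand])]
    kept <- integer(0)
    for (j in cand) {
      if (j == main) {
        kept <- c(kept, j)
        next
      }
      if (length(kept) &&
          min(abs(j - kept)) * dt < params$min_peak_distance - 1e-9) next
      if (peak_prominence_in(w, j) < params$peak_prominence) next
      kept <- c(kept, j)
    }
    peaks <- c(peaks, i1 - 1L + sort(kept))
  }
  list(peaks = peaks, mask = mask)
}

#' Detect Ca2+ transient events in z-scored traces
#'
#' A candidate transient spans an upward crossing of the baseline to the
#' return below it. It is accepted when its maximum reaches the amplitude
#' threshold and its supra-baseline duration reaches [min_duration()] of
#' that maximum. Within an accepted envelope, additional rising peaks with
#' sufficient prominence and separation are emitted as further events.
#' Event time is the peak frame time; amplitude is the peak z value.
#'
#' @param ztraces A [ca_traces()] object in z units at the analysis rate.
#' @param params A [detection_params()] list.
#' @return A `ca_event_trains` object (times sorted, amplitudes in s.d.).
#' @export
detect_events <- function(ztraces, params = detection_params()) {
  stopifnot(inherits(ztraces, "ca_traces"), inherits(params, "detection_params"))
  v <- ztraces$values
  bad <- apply(v, 1L, function(x) all(is.na(x)))
  if (any(bad))
    stop(sprintf("all-NaN trace(s): %s",
                 paste(ztraces$cell_ids[bad], collapse = ", ")), call. = FALSE)
  tf <- frame_times(ztraces)
  trains <- lapply(seq_len(nrow(v)), function(i) {
    det <- detect_cell(v[i, ], ztraces$fps, params)
    data.frame(time_s = tf[det$peaks], amplitude_sd = v[i, det$peaks])
  })
  names(trains) <- ztraces$cell_ids
  structure(list(trains = trains, cell_ids = ztraces$cell_ids,
                 session = ztraces$session,
                 duration = ncol(v) / ztraces$fps),
            class = "ca_event_trains")
}

#' Mask of frames belonging to accepted transients
#'
#' Logical cells x frames matrix marking frames inside accepted transient
#' envelopes; used to pre-filter non-transient timepoints to zero baseline
#' before averaging activity (e.g. for the opto response heatmap).
#'
#' @inheritParams detect_events
#' @return Logical matrix, same shape as `ztraces$values`.
#' @export
transient_mask <- function(ztraces, params = detection_params()) {
  stopifnot(inherits(ztraces, "ca_traces"))
  v <- ztraces$values
  out <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  for (i in seq_len(nrow(v)))
    out[i, ] <- detect_cell(v[i, ], ztraces$fps, params)$mask
  out
}

#' Full detection pipeline: z-score, downsample, detect
#'
#' Noise is estimated and traces z-scored at the acquisition rate, where
#' the robust noise estimate is cleanest; block averaging to `target_fps`
#' then suppresses frame noise before envelope detection, so the 2-s.d.
#' amplitude threshold is conservative with respect to residual noise.
#'
#' @param traces A [ca_traces()] object (raw fluorescence or z units).
#' @param params A [detection_params()] list.
#' @return A `ca_event_trains` object.
#' @export
detect_transients <- function(traces, params = detection_params()) {
  z <- zscore_traces(traces, params)
  if (z$fps > params$target_fps) z <- downsample_traces(z, params$target_fps)
  detect_events(z, params)
}

#' Event rate within a window
#'
#' Number of event peaks in `[start, end)` scaled to events per minute.
#'
#' @param train Data frame with a `time_s` column (one cell's events), or a
#'   numeric vector of peak times.
#' @param window Length-2 numeric `(start, end)`, `end > start`.
#' @return Events/min.
#' @export
#' @examples
#' event_rate(data.frame(time_s = c(10, 50, 100)), c(0, 180))  # 1
event_rate <- function(train, window) {
  times <- if (is.data.frame(train)) train$time_s else train
  stopifnot(is.numeric(window), length(window) == 2L)
  if (window[2L] <= window[1L])
    stop("window must have positive length", call. = FALSE)
  60 * sum(times >= window[1L] & times < window[2L]) /
    (window[2L] - window[1L])
}
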