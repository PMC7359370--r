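## shuffle event times uniformly over the session (count preserved);
## returns an n_shuffles x n_events matrix
shuffle_event_times <- function(times, duration, n_shuffles,
                                method = c("uniform", "rotate")) {
  method <- match.arg(method)
  n <- length(times)
  if (n == 0L) return(matrix(numeric(0), nrow = n_shuffles, ncol = 0L))
  if (method == "uniform") {
    matrix(stats::runif(n_shuffles * n, 0, duration), nrow = n_shuffles)
  } else {
    off <- stats::runif(n_shuffles, 0, duration)
    (matrix(rep(times, each = n_shuffles), nrow = n_shuffles) + off) %% duration
  }
}

#' Classify a cell as responsive to a set of windows against a shuffle null
#'
#' The observed statistic is the pooled event rate over all windows. The
#' null distribution is built by shuffling the cell's event times across
#' the session (event count preserved) and recomputing the pooled rate.
#' The cell is flagged responsive when the observed rate exceeds the null
#' mean by `sd_threshold` null standard deviations.
#'
#' @param train One cell's events (data frame with `time_s`, or numeric
#'   vector of peak times).
#' @param windows One window `(start, end)` or a list/matrix of windows,
#'   all within the session.
#' @param duration Session duration, seconds.
#' @param n_shuffles Shuffle iterations (default 1000).
#' @param sd_threshold Null-s.d. criterion (default 1).
#' @param seed RNG seed.
#' @param method Shuffle scheme: `"uniform"` re-draw or circular `"rotate"`.
#' @return List with `flag` (0/1), `observed_rate`, `null_mean`, `null_sd`
#'   and the vector `null_rates` (events/min throughout). A cell with no
#'   events gets flag 0 and a degenerate all-zero null.
#' @export
classify_window_responsive <- function(train, windows, duration,
                                       n_shuffles = 1000, sd_threshold = 1,
                                       seed = NULL,
                                       method = c("uniform", "rotate")) {
  method <- match.arg(method)
  times <- if (is.data.frame(train)) train$time_s else train
  windows <- as_window_list(windows)
  if (!length(windows)) stop("at least one window is required", call. = FALSE)
  for (w in windows) {
    stopifnot(length(w) == 2L, w[2L] > w[1L])
    if (w[1L] < 0 || w[2L] > duration + 1e-9)
      stop("window outside session", call. = FALSE)
  }
  W <- sum(vapply(windows, function(w) w[2L] - w[1L], numeric(1L)))
  obs <- 60 * count_in_windows(times, windows) / W
  if (length(times) == 0L) {
    return(list(flag = 0L, observed_rate = 0, null_mean = 0, null_sd = 0,
                null_rates = rep(0, n_shuffles)))
  }
  null_rates <- with_seed(seed, {
    sh <- shuffle_event_times(times, duration, n_shuffles, method)
    counts <- rowSums(
      Reduce(`+`, lapply(windows, function(w) sh >= w[1L] & sh < w[2L])))
    60 * counts / W
  })
  mu <- mean(null_rates)
  s <- stats::sd(null_rates)
  list(flag = as.integer(obs > mu + sd_threshold * s),
       observed_rate = obs, null_mean = mu, null_sd = s,
       null_rates = null_rates)
}

#' Classify every cell in a field of view
#'
#' Applies [classify_window_responsive()] to each cell with per-cell seeds
#' derived from `seed`, returning a label table.
#'
#' @param trains A `ca_event_trains` object.
#' @param windows Windows passed to [classify_window_responsive()].
#' @param duration Session duration (default from `trains`).
#' @param label Column name for the flag (e.g. `"shock_cell"`).
#' @inheritParams classify_window_responsive
#' @return Data frame: `cell_id`, `<label>`, `observed_rate`, `null_mean`,
#'   `null_sd`.
#' @export
classify_cells <- function(trains, windows, duration = NULL,
                           label = "responsive", n_shuffles = 1000,
                           sd_threshold = 1, seed = NULL,
                           method = c("uniform", "rotate")) {
  stopifnot(inherits(trains, "ca_event_trains"))
  duration <- duration %||% trains$duration
  res <- lapply(seq_along(trains$trains), function(i) {
    classify_window_responsive(trains$trains[[i]], windows, duration,
                               n_shuffles = n_shuffles,
                               sd_threshold = sd_threshold,
                               seed = derive_seed(seed, i), method = method)
  })
  out <- data.frame(
    cell_id = trains$cell_ids,
    flag = vapply(res, `[[`, integer(1L), "flag"),
    observed_rate = vapply(res, `[[`, numeric(1L), "observed_rate"),
    null_mean = vapply(res, `[[`, numeric(1L), "null_mean"),
    null_sd = vapply(res, `[[`, numeric(1L), "null_sd"),
    row.names = NULL)
  names(out)[2L] <- label
  out
}

#' Shock-cell classification
#'
#' Flags cells whose event rate in the shock-response window (shock onset
#' to onset + 6 s by default; see [shock_response_window()]) exceeds the
#' shuffle-null mean by 1 s.d.
#'
#' @param trains `ca_event_trains` for the shock session (A1).
#' @param timeline The session's [session_timeline()] (with shock).
#' @param extend Seconds after shock onset (default 6).
#' @param ... Passed to [classify_cells()].
#' @return Label table with column `shock_cell`.
#' @export
classify_shock_cells <- function(trains, timeline, extend = 6, ...) {
  classify_cells(trains, shock_response_window(timeline, extend),
                 duration = timeline$duration, label = "shock_cell", ...)
}

#' Tone-cell classification (pooled 20-s tone windows)
#'
#' @param trains `ca_event_trains` for the tone session.
#' @param timeline Timeline with tone intervals.
#' @param ... Passed to [classify_cells()].
#' @return Label table with column `tone_cell`.
#' @export
classify_tone_cells <- function(trains, timeline, ...) {
  if (!nrow(timeline$tones)) stop("timeline has no tones", call. = FALSE)
  classify_cells(trains, timeline$tones, duration = timeline$duration,
                 label = "tone_cell", ...)
}

#' Opto-stim cell classification (first 6 s of each LED pulse)
#'
#' @param trains `ca_event_trains` for the homecage pulse session.
#' @param timeline Timeline with opto epochs.
#' @param lead Seconds from each epoch onset (default 6).
#' @param ... Passed to [classify_cells()].
#' @return Label table with column `opto_stim`.
#' @export
classify_opto_cells <- function(trains, timeline, lead = 6, ...) {
  classify_cells(trains, opto_onset_windows(timeline, lead),
                 duration = timeline$duration, label = "opto_stim", ...)
}

#' Opto response heatmap
#'
#' Per-cell average of transient-filtered calcium activity in 200-ms bins
#' over the 6 s preceding and the first 6 s of each LED ON pulse (60 bins),
#' min-max normalized (single global max/min by default, per-row
#' optionally), with rows sorted by the average ON - OFF change. Onsets too
#' close to the recording edges are dropped with a warning.
#'
#' @param traces Event-filtered z traces at the analysis rate (non-transient
#'   timepoints pre-zeroed; see [transient_mask()]).
#' @param led_onsets LED ON onset times, seconds.
#' @param pre,post Seconds before/after each onset (defaults 6 and 6).
#' @param bin_width Bin width, seconds (default 0.2; must be a whole number
#'   of frames).
#' @param normalize `"global"` or `"row"` min-max normalization.
#' @return List: `heatmap` (sorted cells x bins, values in `[0, 1]`),
#'   `change` (named ON - OFF change, pre-normalization), `order`,
#'   `n_bins_off`, `onsets_used`.
#' @export
opto_response_heatmap <- function(traces, led_onsets, pre = 6, post = 6,
                                  bin_width = 0.2,
                                  normalize = c("global", "row")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(traces, "ca_traces"), length(led_onsets) >= 1L)
  fpb <- traces$fps * bin_width
  if (abs(fpb - round(fpb)) > 1e-8 || fpb < 1)
    stop("bin_width must be a whole number of frames", call. = FALSE)
  fpb <- as.integer(round(fpb))
  total_s <- ncol(traces$values) / traces$fps
  ok <- led_onsets - pre >= 0 & led_onsets + post <= total_s + 1e-9
  if (!all(ok)) {
    warning(sprintf("%d onset(s) too close to the recording edge; dropped",
                    sum(!ok)))
    led_onsets <- led_onsets[ok]
  }
  if (!length(led_onsets)) stop("no usable LED onsets", call. = FALSE)
  nb <- as.integer(round((pre + post) / bin_width))
  nb_off <- as.integer(round(pre / bin_width))
  acc <- matrix(0, nrow(traces$values), nb)
  for (on in led_onsets) {
    f0 <- round((on - pre) * traces$fps)
    seg <- traces$values[, f0 + seq_len(nb * fpb), drop = FALSE]
    grp <- rep(seq_len(nb), each = fpb)
    acc <- acc + t(rowsum(t(seg), grp, reorder = TRUE)) / fpb
  }
  acc <- acc / length(led_onsets)
  change <- rowMeans(acc[, (nb_off + 1L):nb, drop = FALSE]) -
    rowMeans(acc[, seq_len(nb_off), drop = FALSE])
  names(change) <- traces$cell_ids
  hm <- if (normalize == "global") {
    rng <- range(acc)
    if (diff(rng) == 0) acc * 0 else (acc - rng[1L]) / diff(rng)
  } else {
    t(apply(acc, 1L, function(x) {
      r <- range(x)
      if (diff(r) == 0) x * 0 else (x - r[1L]) / diff(r)
    }))
  }
  ord <- order(change, decreasing = TRUE)
  rownames(hm) <- traces$cell_ids
  list(heatmap = hm[ord, , drop = FALSE], change = change, order = ord,
       n_bins_off = nb_off, onsets_used = led_onsets)
}
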