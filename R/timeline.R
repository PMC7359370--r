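#' Session timeline
#'
#' Labeled behavioral windows over one imaging session: the foot-shock
#' interval, tone periods, optogenetic LED epochs, and scored freezing bouts.
#' All times are seconds from session start; intervals are half-open
#' `[start, end)`.
#'
#' @param label Session label, e.g. `"A1"`, `"A2"`, `"B"`, `"homecage"`.
#' @param duration Session duration in seconds.
#' @param shock Length-2 numeric `(on, off)` for the foot shock, or `NULL`.
#' @param tones List/matrix of tone intervals, or `NULL`.
#' @param opto List/matrix of LED ON epochs, or `NULL`.
#' @param freezing List/matrix of scored freezing intervals, or `NULL`.
#'   Overlapping bouts are merged with a warning.
#' @return A `ca_timeline` object.
#' @export
#' @examples
#' tl <- session_timeline("A1", 184, shock = c(178, 180))
#' shock_response_window(tl)
session_timeline <- function(label, duration, shock = NULL, tones = NULL,
                             opto = NULL, freezing = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  stop_if_not_scalar_pos(duration, "duration")
  check_iv <- function(iv, what) {
    if (nrow(iv) && (any(iv[, 1L] < 0) || any(iv[, 2L] > duration + 1e-9)))
      stop(sprintf("%s intervals must lie within [0, duration]", what), call. = FALSE)
    iv
  }
  tl <- structure(list(
    label = label,
    duration = as.numeric(duration),
    shock = if (!is.null(shock)) {
      stopifnot(length(shock) == 2L, shock[2L] > shock[1L])
      check_iv(matrix(as.numeric(shock), ncol = 2L), "shock")[1L, ]
    },
    tones = check_iv(merge_intervals(tones), "tone"),
    opto = check_iv(merge_intervals(opto), "opto"),
    freezing = check_iv(merge_intervals(freezing, warn_overlap = TRUE), "freezing")
  ), class = "ca_timeline")
  tl
}

#' @export
print.ca_timeline <- function(x, ...) {
  cat(sprintf("<ca_timeline> session %s, %.0f s", x$label, x$duration))
  if (!is.null(x$shock)) cat(sprintf(", shock %g-%g s", x$shock[1L], x$shock[2L]))
  if (nrow(x$tones)) cat(sprintf(", %d tone(s)", nrow(x$tones)))
  if (nrow(x$opto)) cat(sprintf(", %d opto epoch(s)", nrow(x$opto)))
  if (nrow(x$freezing)) cat(sprintf(", %d freezing bout(s)", nrow(x$freezing)))
  cat("\n")
  invisible(x)
}

#' Shock response window of a session
#'
#' The window used both to plant elevated event rates in simulated shock
#' cells and to classify shock-responsive cells: from shock onset to
#' `onset + extend` seconds (default 6 s, matching the 6-s optogenetic
#' silencing window that brackets the 2-s shock), clipped to the session.
#'
#' @param timeline A `ca_timeline` with a shock interval.
#' @param extend Seconds after shock onset included in the window.
#' @return Length-2 numeric `(start, end)`.
#' @export
shock_response_window <- function(timeline, extend = 6) {
  stopifnot(inherits(timeline, "ca_timeline"))
  if (is.null(timeline$shock)) stop("timeline has no shock interval", call. = FALSE)
  c(timeline$shock[1L], min(timeline$shock[1L] + extend, timeline$duration))
}

#' Opto classification windows
#'
#' First `lead` seconds of each LED ON epoch (the window over which
#' opto-modulated cells are defined).
#'
#' @param timeline A `ca_timeline` with opto epochs.
#' @param lead Seconds from each epoch onset.
#' @return List of `(start, end)` windows.
#' @export
opto_onset_windows <- function(timeline, lead = 6) {
  stopifnot(inherits(timeline, "ca_timeline"))
  if (!nrow(timeline$opto)) stop("timeline has no opto epochs", call. = FALSE)
  lapply(seq_len(nrow(timeline$opto)), function(i) {
    on <- timeline$opto[i, 1L]
    c(on, min(on + lead, timeline$opto[i, 2L]))
  })
}

#' Percent time freezing
#'
#' Fraction of a window (default: the whole session) spent in scored
#' freezing bouts, as a percentage.
#'
#' @param timeline A `ca_timeline`.
#' @param window Optional `(start, end)` restriction.
#' @return Percent freezing in `[0, 100]`.
#' @export
#' @examples
#' tl <- session_timeline("A2", 180, freezing = rbind(c(0, 90)))
#' percent_freezing(tl)  # 50
percent_freezing <- function(timeline, window = NULL) {
  stopifnot(inherits(timeline, "ca_timeline"))
  if (is.null(window)) window <- c(0, timeline$duration)
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  100 * interval_time(timeline$freezing, window) / (window[2L] - window[1L])
}

#' Freeze / non-freeze bin masks
#'
#' Flags each 1-s raster bin as frozen when more than `min_overlap` of the
#' bin overlaps a freezing bout; the non-freeze mask is the complement.
#' Masks feed [binarize_events()] for state-restricted correlation graphs.
#'
#' @param timeline A `ca_timeline`.
#' @param bin_width Bin width in seconds (default 1, matching the raster).
#' @param min_overlap Fraction of a bin that must be frozen (default 0.5,
#'   strict `>`).
#' @return List with logical vectors `freeze` and `non_freeze`.
#' @export
state_masks <- function(timeline, bin_width = 1, min_overlap = 0.5) {
  stopifnot(inherits(timeline, "ca_timeline"))
  stop_if_not_scalar_pos(bin_width, "bin_width")
  nbins <- floor(timeline$duration / bin_width + 1e-9)
  starts <- (seq_len(nbins) - 1L) * bin_width
  overlap <- numeric(nbins)
  fz <- timeline$freezing
  for (i in seq_len(nrow(fz))) {
    overlap <- overlap +
      pmax(pmin(fz[i, 2L], starts + bin_width) - pmax(fz[i, 1L], starts), 0)
  }
  frozen <- overlap > min_overlap * bin_width
  list(freeze = frozen, non_freeze = !frozen)
}
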