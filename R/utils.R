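#' @keywords internal
"_PACKAGE"

## NULL coalescing
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG to `seed`, runs `code`, and restores the previous RNG state,
#' so seeded helpers do not disturb the caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a child seed from a base seed and a stage offset, kept within
## the 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

## ---- interval helpers (all times in seconds from session start) ----

## normalize an intervals matrix: 2 columns (start, end), sorted, merged
merge_intervals <- function(x, warn_overlap = FALSE) {
  if (is.null(x) || length(x) == 0L) return(matrix(numeric(0), ncol = 2L))
  if (is.list(x) && !is.matrix(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- matrix(as.numeric(unlist(x)), ncol = 2L,
              byrow = !is.matrix(x) && !is.data.frame(x))
  if (is.data.frame(x)) x <- as.matrix(x)
  stopifnot(ncol(x) == 2L, all(is.finite(x)), all(x[, 2L] >= x[, 1L]))
  x <- x[order(x[, 1L]), , drop = FALSE]
  if (nrow(x) <= 1L) return(unname(x))
  out <- x[1L, , drop = FALSE]
  overlapped <- FALSE
  for (i in seq_len(nrow(x))[-1L]) {
    j <- nrow(out)
    if (x[i, 1L] <= out[j, 2L]) {
      if (x[i, 1L] < out[j, 2L]) overlapped <- TRUE
      out[j, 2L] <- max(out[j, 2L], x[i, 2L])
    } else {
      out <- rbind(out, x[i, , drop = FALSE])
    }
  }
  if (overlapped && warn_overlap) warning("overlapping intervals merged")
  unname(out)
}

## total length of intervals clipped to a window
interval_time <- function(intervals, window = NULL) {
  if (length(intervals) == 0L) return(0)
  iv <- merge_intervals(intervals)
  if (!is.null(window)) {
    lo <- pmax(iv[, 1L], window[1L])
    hi <- pmin(iv[, 2L], window[2L])
  } else {
    lo <- iv[, 1L]
    hi <- iv[, 2L]
  }
  sum(pmax(hi - lo, 0))
}

## count of event times falling in [start, end) over a list of windows
count_in_windows <- function(times, windows) {
  if (length(times) == 0L) return(0L)
  total <- 0L
  for (w in windows) total <- total + sum(times >= w[1L] & times < w[2L])
  total
}

as_window_list <- function(windows) {
  if (is.null(windows)) return(list())
  if (is.matrix(windows)) return(lapply(seq_len(nrow(windows)), function(i) windows[i, ]))
  if (is.numeric(windows) && length(windows) == 2L) return(list(windows))
  stopifnot(is.list(windows))
  windows
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive scalar", name), call. = FALSE)
  invisible(x)
}
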