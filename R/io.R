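## Plain-text formats: traces as CSV with a JSON sidecar; events, edges,
## metrics and labels as TSV with headers; timelines, ground truth and
## reports as JSON. All writers are deterministic (no timestamps in data
## files) so a fixed-seed run is byte-reproducible.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = NA)
}

#' Write / read a trace matrix (CSV + JSON sidecar)
#'
#' CSV layout: one row per cell, first column `cell_id`, remaining columns
#' the frame index; the sidecar (`<path>.json`) stores `fps` and the
#' session label.
#'
#' @param traces A [ca_traces()] object.
#' @param path CSV path.
#' @return `path`, invisibly (writer); a [ca_traces()] (reader).
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "ca_traces"))
  df <- data.frame(cell_id = traces$cell_ids,
                   traces$values, check.names = FALSE)
  colnames(df) <- c("cell_id", seq_len(ncol(traces$values)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fps = traces$fps,
                            session = traces$session,
                            n_cells = nrow(traces$values),
                            n_frames = ncol(traces$values)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing input: %s", path), call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar: %s", sidecar), call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(vals) <- NULL
  ca_traces(vals, fps = meta$fps, cell_ids = as.character(df[[1L]]),
            session = meta$session)
}

#' Write / read event trains (TSV: cell_id, time_s, amplitude_sd)
#'
#' Cells without events have no rows; pass `cell_ids` to the reader to
#' restore them as empty trains.
#'
#' @param trains A `ca_event_trains` object.
#' @param path TSV path.
#' @param cell_ids Optional full cell roster for the reader.
#' @param session,duration Session metadata for the reader.
#' @return `path`, invisibly (writer); a `ca_event_trains` (reader).
#' @export
write_events_tsv <- function(trains, path) {
  stopifnot(inherits(trains, "ca_event_trains"))
  rows <- lapply(seq_along(trains$trains), function(i) {
    d <- trains$trains[[i]]
    if (!nrow(d)) return(NULL)
    data.frame(cell_id = trains$cell_ids[i], time_s = d$time_s,
               amplitude_sd = d$amplitude_sd)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(cell_id = character(0), time_s = numeric(0),
                     amplitude_sd = numeric(0))
  write_tsv(df, path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path, cell_ids = NULL, session = NULL,
                            duration = NULL) {
  if (!file.exists(path)) stop(sprintf("missing input: %s", path), call. = FALSE)
  df <- read_tsv(path)
  ids <- cell_ids %||% unique(df$cell_id)
  trains <- lapply(ids, function(id) {
    d <- df[df$cell_id == id, c("time_s", "amplitude_sd"), drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(trains) <- ids
  structure(list(trains = trains, cell_ids = ids, session = session,
                 duration = duration %||%
                   (if (nrow(df)) ceiling(max(df$time_s)) else 0)),
            class = "ca_event_trains")
}

#' Write / read a session timeline (JSON)
#'
#' @param timeline A [session_timeline()].
#' @param path JSON path.
#' @return `path`, invisibly (writer); a [session_timeline()] (reader).
#' @export
write_timeline_json <- function(timeline, path) {
  stopifnot(inherits(timeline, "ca_timeline"))
  iv <- function(m) if (nrow(m)) lapply(seq_len(nrow(m)), function(i) m[i, ]) else list()
  jsonlite::write_json(list(
    label = timeline$label, duration = timeline$duration,
    shock = timeline$shock, tones = iv(timeline$tones),
    opto = iv(timeline$opto), freezing = iv(timeline$freezing)
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_timeline_json
#' @export
read_timeline_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing input: %s", path), call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_iv <- function(v) if (length(v)) do.call(rbind, lapply(v, as.numeric)) else NULL
  session_timeline(x$label, x$duration,
                   shock = if (length(x$shock)) as.numeric(x$shock),
                   tones = as_iv(x$tones), opto = as_iv(x$opto),
                   freezing = as_iv(x$freezing))
}

#' Write a correlation graph as an edge-list TSV
#'
#' One row per tested cell pair: `cell_i`, `cell_j`, `r`, `threshold`,
#' `significant`.
#'
#' @param graph A `ca_graph`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "ca_graph"))
  ut <- which(upper.tri(graph$R), arr.ind = TRUE)
  thr <- if (is.matrix(graph$threshold)) graph$threshold[ut]
  else rep(graph$threshold, nrow(ut))
  df <- data.frame(cell_i = graph$cell_ids[ut[, 1L]],
                   cell_j = graph$cell_ids[ut[, 2L]],
                   r = graph$R[ut], threshold = thr,
                   significant = as.integer(graph$adj[ut]))
  write_tsv(df, path)
}

#' Write node metrics / labels / partition tables (TSV)
#'
#' @param metrics A [node_metrics()] table.
#' @param session Session label column value.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, session, path) {
  df <- cbind(metrics[, "cell_id", drop = FALSE], session = session,
              metrics[, setdiff(names(metrics), "cell_id"), drop = FALSE])
  write_tsv(df, path)
}

#' Write the ground truth of a simulated dataset (JSON)
#'
#' @param dataset A `ca_dataset` from [simulate_animal()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(dataset, path) {
  stopifnot(inherits(dataset, "ca_dataset"))
  gt <- lapply(dataset$trains, function(tr) {
    list(events = lapply(tr$ground_truth$events, function(d)
      list(time_s = d$time_s, amplitude_sd = d$amplitude_sd,
           source = d$source)),
      module = as.list(tr$ground_truth$module),
      shock_cell = as.list(tr$ground_truth$shock_cell))
  })
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
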