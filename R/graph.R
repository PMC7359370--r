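#' Binarize event trains into a 1-s raster
#'
#' Each cell's activity becomes a binary time series indicating the timing
#' of transient peaks: bin `b` is 1 when at least one peak falls in
#' `[b, b+1)` seconds (occupancy, not counts). An optional bin mask (e.g.
#' from [state_masks()]) drops masked-out bins before correlation.
#'
#' @param trains A `ca_event_trains` object, or a named list of per-cell
#'   data frames with a `time_s` column.
#' @param duration Session duration, seconds (taken from `trains` if present).
#' @param bin_width Bin width, seconds (default 1).
#' @param mask Optional logical vector over bins; `FALSE` bins are dropped.
#' @return Binary cells x bins matrix of class `ca_raster` with attributes
#'   `bin_width`, `kept_bins` and `session`.
#' @export
#' @examples
#' r <- binarize_events(list(c1 = data.frame(time_s = c(0.2, 0.7, 1.0))),
#'                      duration = 3)
#' as.vector(r)  # 1 1 0
binarize_events <- function(trains, duration = NULL, bin_width = 1,
                            mask = NULL) {
  if (inherits(trains, "ca_event_trains")) {
    duration <- duration %||% trains$duration
    session <- trains$session
    trains <- trains$trains
  } else {
    session <- NULL
  }
  stopifnot(is.list(trains), !is.null(duration))
  stop_if_not_scalar_pos(bin_width, "bin_width")
  nbins <- floor(duration / bin_width + 1e-9)
  if (nbins < 1L) stop("duration shorter than one bin", call. = FALSE)
  ids <- names(trains) %||% cell_ids_for(length(trains))
  m <- matrix(0L, nrow = length(trains), ncol = nbins,
              dimnames = list(ids, NULL))
  for (i in seq_along(trains)) {
    t <- trains[[i]]
    times <- if (is.data.frame(t)) t$time_s else t
    if (length(times) == 0L) next
    if (any(times < 0 | times >= duration))
      stop(sprintf("events outside [0, %g) s in cell %s", duration, ids[i]),
           call. = FALSE)
    b <- floor(times / bin_width) + 1L
    b <- b[b <= nbins]  # peaks in a trailing partial bin carry no full bin
    m[i, unique(b)] <- 1L
  }
  kept <- seq_len(nbins)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), length(mask) == nbins)
    m <- m[, mask, drop = FALSE]
    kept <- kept[mask]
  }
  structure(m, bin_width = bin_width, kept_bins = kept, session = session,
            class = c("ca_raster", "matrix", "array"))
}

#' Pearson correlation matrix of a binarized raster
#'
#' Standard Pearson coefficient between the binary series of each cell
#' pair. Pairs involving a constant series (silent or saturated cells)
#' have no defined coefficient and are returned as `NA` (no edge
#' possible); the diagonal is `NA` (self-pairs excluded).
#'
#' @param raster A `ca_raster` (or any cells x bins numeric matrix).
#' @return Symmetric matrix of Pearson `R` values with `NA` diagonal.
#' @export
correlation_matrix <- function(raster) {
  m <- unclass(raster)
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  R <- suppressWarnings(stats::cor(t(m)))
  diag(R) <- NA_real_
  R
}

## redraw each cell's occupied bins uniformly among all bins (event count
## preserved); "rotate" circularly shifts each row by a random offset
shuffle_raster <- function(raster, method = c("redraw", "rotate")) {
  method <- match.arg(method)
  m <- unclass(raster)
  nb <- ncol(m)
  out <- matrix(0L, nrow(m), nb)
  for (i in seq_len(nrow(m))) {
    k <- sum(m[i, ] != 0)
    if (k == 0L) next
    if (method == "redraw") {
      out[i, sample.int(nb, k)] <- 1L
    } else {
      off <- sample.int(nb, 1L) - 1L
      out[i, ] <- m[i, (((seq_len(nb) - 1L - off) %% nb) + 1L)]
    }
  }
  out
}

#' Shuffle-calibrated per-pair R thresholds
#'
#' For each pair of cells, event timing is shuffled (default: each cell's
#' occupied bins are re-drawn uniformly, preserving event counts), the
#' Pearson coefficient recomputed per iteration, and the per-pair threshold
#' taken as the `1 - alpha` quantile of that null distribution. In
#' Bonferroni mode the level is divided by the number of testable pair
#' comparisons in the field of view. Pairs with a constant series are
#' untestable (`NA` threshold, never significant).
#'
#' @param raster A `ca_raster`.
#' @param n_shuffles Number of shuffle iterations (`>= 100`; default 1000).
#' @param alpha Significance level (default 0.05).
#' @param bonferroni Divide `alpha` by the number of pair comparisons.
#' @param seed RNG seed for reproducible thresholds.
#' @param method `"redraw"` (uniform re-draw of occupied bins) or
#'   `"rotate"` (random circular shift).
#' @return List with `thresholds` (symmetric matrix, `NA` = untestable),
#'   `alpha`, `alpha_effective`, `n_pairs`, `n_shuffles`, `method`.
#' @export
shuffle_r_thresholds <- function(raster, n_shuffles = 1000, alpha = 0.05,
                                 bonferroni = FALSE, seed = NULL,
                                 method = c("redraw", "rotate")) {
  method <- match.arg(method)
  m <- unclass(raster)
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  if (n_shuffles < 100L) stop("n_shuffles must be >= 100", call. = FALSE)
  n <- nrow(m)
  testable <- apply(m, 1L, function(x) stats::var(x) > 0)
  n_pairs <- choose(sum(testable), 2L)
  a_eff <- if (bonferroni && n_pairs > 0L) alpha / n_pairs else alpha
  null <- array(NA_real_, c(n, n, n_shuffles))
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      null[, , s] <- suppressWarnings(stats::cor(t(shuffle_raster(m, method))))
    }
  })
  thr <- apply(null, c(1L, 2L), function(x) {
    if (all(is.na(x))) NA_real_
    else stats::quantile(x, probs = 1 - a_eff, na.rm = TRUE, names = FALSE,
                         type = 7)
  })
  diag(thr) <- NA_real_
  thr[!testable, ] <- NA_real_
  thr[, !testable] <- NA_real_
  dimnames(thr) <- list(rownames(m), rownames(m))
  list(thresholds = thr, alpha = alpha, alpha_effective = a_eff,
       n_pairs = n_pairs, n_shuffles = n_shuffles, method = method)
}

#' Build a thresholded correlation graph
#'
#' Draws an (undirected, unweighted) edge between every cell pair whose
#' Pearson coefficient strictly exceeds its threshold: the fixed
#' `R > 0.3` rule by default, or per-pair shuffle-calibrated thresholds
#' from [shuffle_r_thresholds()]. Pairs with undefined `R` or `NA`
#' thresholds never form edges; there are no self-edges.
#'
#' @param R Symmetric Pearson matrix from [correlation_matrix()].
#' @param threshold Scalar fixed threshold (default 0.3) or a matrix of
#'   per-pair thresholds (or the list returned by [shuffle_r_thresholds()]).
#' @param cell_ids Cell identifiers (default from `R` dimnames).
#' @return A `ca_graph`: list with `cell_ids`, `R`, logical adjacency
#'   `adj`, `mode` and `threshold`.
#' @export
build_graph <- function(R, threshold = 0.3, cell_ids = rownames(R)) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (is.null(cell_ids)) cell_ids <- cell_ids_for(nrow(R))
  mode <- "fixed"
  if (is.list(threshold) && !is.null(threshold$thresholds)) {
    mode <- if (threshold$alpha_effective < threshold$alpha)
      "shuffle-bonferroni" else "shuffle"
    threshold <- threshold$thresholds
  }
  if (is.matrix(threshold)) {
    stopifnot(dim(threshold) == dim(R))
    if (mode == "fixed") mode <- "shuffle"
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
  }
  adj <- !is.na(R) & !is.na(threshold) & R > threshold
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  dimnames(adj) <- list(cell_ids, cell_ids)
  structure(list(cell_ids = cell_ids, R = R, adj = adj, mode = mode,
                 threshold = threshold),
            class = "ca_graph")
}

#' @export
print.ca_graph <- function(x, ...) {
  cat(sprintf("<ca_graph> %d cells, %d edges (%s threshold)\n",
              length(x$cell_ids), sum(x$adj[upper.tri(x$adj)]), x$mode))
  invisible(x)
}

#' One-call correlation graph for a session
#'
#' Binarized raster to Pearson matrix to thresholded graph, enforcing the
#' field-of-view inclusion rule (at least `min_cells` cells; sparse FOVs
#' under-sample potential correlation partners). Set `min_cells = 0` to
#' override.
#'
#' @param trains A `ca_event_trains` object.
#' @param mode `"fixed"`, `"shuffle"` or `"shuffle-bonferroni"`.
#' @param r_threshold Fixed-mode threshold (default 0.3).
#' @param mask Optional bin mask (see [binarize_events()]).
#' @param min_cells FOV inclusion minimum (default 20).
#' @param ... Passed to [shuffle_r_thresholds()] in shuffle modes
#'   (`n_shuffles`, `alpha`, `seed`, `method`).
#' @return A `ca_graph`.
#' @export
correlation_graph <- function(trains, mode = c("fixed", "shuffle",
                                               "shuffle-bonferroni"),
                              r_threshold = 0.3, mask = NULL,
                              min_cells = 20, ...) {
  mode <- match.arg(mode)
  raster <- binarize_events(trains, mask = mask)
  if (nrow(raster) < min_cells)
    stop(sprintf(
      "FOV has %d cells, below the inclusion minimum of %d (override with min_cells = 0)",
      nrow(raster), min_cells), call. = FALSE)
  R <- correlation_matrix(raster)
  thr <- if (mode == "fixed") r_threshold
  else shuffle_r_thresholds(raster,
                            bonferroni = (mode == "shuffle-bonferroni"), ...)
  build_graph(R, thr, cell_ids = rownames(raster))
}

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adj, mode = "undirected",
                                      diag = FALSE)
}

#' Per-cell graph metrics
#'
#' The three node metrics of the correlation-graph analysis:
#' * correlated pair ratio: a cell's number of correlated pairs divided by
#'   the total number of cells in the FOV;
#' * clustering coefficient: edges among the cell's neighbors over possible
#'   edges among them (0 when the cell has fewer than 2 neighbors);
#' * component membership: 1 when the cell belongs to a connected component
#'   containing at least two other neurons (size >= 3).
#'
#' The FOV-level component probability (proportion of FOV cells in a
#' component) is attached as attribute `component_probability`. Cells
#' counted in `n_cells_fov` but absent from the graph contribute to the
#' denominators as edgeless cells.
#'
#' @param graph A `ca_graph`.
#' @param n_cells_fov Total cells in the FOV (`>=` graph node count).
#' @return Data frame `cell_id`, `degree`, `pair_ratio`, `clustering`,
#'   `component_member`, with attribute `component_probability`.
#' @export
#' @examples
#' R <- matrix(1, 3, 3); diag(R) <- NA  # triangle
#' g <- build_graph(R, 0.3)
#' node_metrics(g)$clustering  # 1 1 1
node_metrics <- function(graph, n_cells_fov = length(graph$cell_ids)) {
  stopifnot(inherits(graph, "ca_graph"))
  n <- length(graph$cell_ids)
  if (n_cells_fov < n)
    stop("n_cells_fov must be at least the graph node count", call. = FALSE)
  adj <- graph$adj
  deg <- rowSums(adj)
  ## edges among neighbors, counted from the adjacency matrix: diag(A^3)
  ## gives twice that count per cell
  tri2 <- diag(adj %*% adj %*% adj)
  cc <- ifelse(deg < 2L, 0, tri2 / (deg * (deg - 1L)))
  comp <- igraph::components(as_igraph(graph))
  member <- as.integer(comp$csize[comp$membership] >= 3L)
  out <- data.frame(cell_id = graph$cell_ids, degree = as.integer(deg),
                    pair_ratio = deg / n_cells_fov, clustering = cc,
                    component_member = member, row.names = NULL)
  attr(out, "component_probability") <- sum(member) / n_cells_fov
  out
}

graph_edge_keys <- function(graph) {
  idx <- which(graph$adj & upper.tri(graph$adj), arr.ind = TRUE)
  if (!nrow(idx)) return(character(0))
  a <- graph$cell_ids[idx[, 1L]]
  b <- graph$cell_ids[idx[, 2L]]
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Fraction of correlated pairs persisting across sessions
#'
#' Of the reference session's edges, the fraction also present in the
#' target session (cells are tracked by id across sessions).
#'
#' @param reference,target `ca_graph` objects over shared cell ids.
#' @return Persistence fraction in `[0, 1]`, or `NA` (with a message) when
#'   the reference has no edges.
#' @export
pair_persistence <- function(reference, target) {
  stopifnot(inherits(reference, "ca_graph"), inherits(target, "ca_graph"))
  shared <- intersect(reference$cell_ids, target$cell_ids)
  if (!length(shared)) stop("no shared cell ids", call. = FALSE)
  ref <- graph_edge_keys(reference)
  ref <- ref[vapply(strsplit(ref, "|", fixed = TRUE),
                    function(p) all(p %in% shared), logical(1L))]
  if (!length(ref)) {
    message("reference session has no correlated pairs; persistence undefined")
    return(NA_real_)
  }
  tgt <- graph_edge_keys(target)
  length(intersect(ref, tgt)) / length(ref)
}

#' Centroid distances of correlated vs non-correlated pairs
#'
#' Euclidean centroid distance for every cell pair, partitioned by edge
#' membership. Cells without a centroid are excluded with a warning.
#'
#' @param graph A `ca_graph`.
#' @param centroids Data frame with columns `cell_id`, `x`, `y`.
#' @return List with numeric vectors `correlated` and `non_correlated` and
#'   a `means` summary.
#' @export
pair_distances <- function(graph, centroids) {
  stopifnot(inherits(graph, "ca_graph"),
            all(c("cell_id", "x", "y") %in% names(centroids)))
  have <- graph$cell_ids %in% centroids$cell_id
  if (!all(have)) {
    warning(sprintf("no centroid for %d cell(s); excluded",
                    sum(!have)))
  }
  ids <- graph$cell_ids[have]
  if (length(ids) < 2L) stop("fewer than two cells with centroids", call. = FALSE)
  xy <- as.matrix(centroids[match(ids, centroids$cell_id), c("x", "y")])
  D <- as.matrix(stats::dist(xy))
  adj <- graph$adj[have, have, drop = FALSE]
  ut <- upper.tri(D)
  corr <- D[ut & adj]
  noncorr <- D[ut & !adj]
  list(correlated = corr, non_correlated = noncorr,
       means = c(correlated = mean(corr), non_correlated = mean(noncorr)))
}
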