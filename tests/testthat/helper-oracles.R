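# Brute-force graph-metric oracle, independent of the package's igraph
# implementation: clustering by explicit neighbor-pair enumeration,
# connected components by boolean reachability (matrix powers).
oracle_node_metrics <- function(adj, n_fov = nrow(adj)) {
  n <- nrow(adj)
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    if (length(nb) < 2L) next
    e <- 0L
    tot <- 0L
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b) {
          tot <- tot + 1L
          if (adj[nb[a], nb[b]]) e <- e + 1L
        }
      }
    }
    cc[i] <- e / tot
  }
  reach <- diag(n) > 0 | adj
  for (k in seq_len(n)) reach <- (reach %*% reach) > 0
  csize <- rowSums(reach)
  member <- as.integer(csize >= 3L)
  list(pair_ratio = deg / n_fov, clustering = cc, component_member = member,
       component_probability = sum(member) / n_fov)
}

random_adjacency <- function(n, p) {
  adj <- matrix(stats::runif(n * n) < p, n, n)
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  adj <- adj | t(adj)
  adj
}

# one-to-one greedy matching of detected to ground-truth event times
match_event_times <- function(detected, truth, tol = 0.6) {
  used <- rep(FALSE, length(truth))
  hits <- 0L
  for (t in detected) {
    d <- abs(truth - t)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}

# recall / precision of a detected train set against planted ground truth
detection_scores <- function(detected, ground_truth, tol = 0.6) {
  tp <- nd <- ng <- 0L
  for (i in seq_along(detected$trains)) {
    det <- detected$trains[[i]]$time_s
    gt <- ground_truth$events[[i]]$time_s
    tp <- tp + match_event_times(det, gt, tol)
    nd <- nd + length(det)
    ng <- ng + length(gt)
  }
  c(recall = tp / ng, precision = tp / nd)
}

# independent homogeneous Poisson event trains (no modules, no shock)
poisson_trains <- function(n_cells, rate_per_min, duration, seed) {
  set.seed(seed)
  trains <- lapply(seq_len(n_cells), function(i) {
    n <- stats::rpois(1L, rate_per_min * duration / 60)
    data.frame(time_s = sort(stats::runif(n, 0, duration)))
  })
  names(trains) <- sprintf("cell_%03d", seq_len(n_cells))
  event_trains(trains, duration = duration)
}

# md5 digest of every file under a directory except the run log
dir_digest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "run.log"]
  md5 <- tools::md5sum(files)
  names(md5) <- sub(paste0("^", dir, "/?"), "", files)
  md5
}
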