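test_that("binarization marks 1-s occupancy with half-open bins", {
  r <- binarize_events(list(c1 = data.frame(time_s = c(0.2, 0.7))),
                       duration = 3)
  expect_equal(as.vector(r), c(1, 0, 0))       # occupancy, not count 2
  r2 <- binarize_events(list(c1 = data.frame(time_s = 1.0)), duration = 3)
  expect_equal(as.vector(r2), c(0, 1, 0))      # boundary peak in bin [1, 2)
  r3 <- binarize_events(poisson_trains(4, 2, 180, seed = 1))
  expect_equal(ncol(r3), 180)
  expect_error(binarize_events(list(c1 = data.frame(time_s = 200)),
                               duration = 180), "outside")
})

test_that("bin masks drop columns before correlation", {
  tr <- poisson_trains(5, 3, 60, seed = 2)
  mask <- rep(c(TRUE, FALSE), length.out = 60)
  r <- binarize_events(tr, mask = mask)
  expect_equal(ncol(r), 30)
  full <- binarize_events(tr)
  expect_equal(unclass(r), unclass(full)[, mask],
               ignore_attr = TRUE)
})

test_that("Pearson matrix matches hand computations", {
  m <- rbind(a = c(1, 0, 1, 0), b = c(0, 1, 0, 1), c = c(1, 1, 0, 0),
             d = c(1, 0, 1, 0))
  R <- correlation_matrix(m)
  expect_equal(R["a", "b"], -1)
  expect_equal(R["a", "d"], 1)
  expect_equal(R["c", "d"], 0)       # covariance cancels exactly
  expect_true(all(is.na(diag(R))))
  # constant series have undefined R, recorded as NA
  m2 <- rbind(x = c(1, 0, 1), y = c(0, 0, 0))
  expect_true(is.na(correlation_matrix(m2)["x", "y"]))
})

test_that("edges require R strictly above the threshold", {
  R <- matrix(NA_real_, 3, 3)
  R[1, 2] <- R[2, 1] <- 0.5
  R[1, 3] <- R[3, 1] <- 0.3        # exactly at threshold: no edge
  R[2, 3] <- R[3, 2] <- -0.2
  g <- build_graph(R, 0.3)
  expect_true(g$adj[1, 2])
  expect_false(g$adj[1, 3])
  expect_false(g$adj[2, 3])
  expect_false(any(diag(g$adj)))
})

test_that("node metrics match the published definitions on canonical graphs", {
  tri <- matrix(TRUE, 3, 3); diag(tri) <- FALSE
  R <- ifelse(tri, 0.9, NA_real_)
  g <- build_graph(R, 0.3)
  m <- node_metrics(g)
  expect_equal(m$pair_ratio, rep(2 / 3, 3))
  expect_equal(m$clustering, rep(1, 3))
  expect_equal(m$component_member, rep(1L, 3))
  expect_equal(attr(m, "component_probability"), 1)

  # star: center + 3 leaves; no edges among the center's neighbors
  R <- matrix(NA_real_, 4, 4)
  R[1, 2:4] <- R[2:4, 1] <- 0.9
  ms <- node_metrics(build_graph(R, 0.3))
  expect_equal(ms$clustering[1], 0)
  expect_equal(attr(ms, "component_probability"), 1)

  # single dyad in a FOV of 5: component size 2 < 3 so no membership
  R <- matrix(NA_real_, 5, 5)
  R[1, 2] <- R[2, 1] <- 0.9
  md <- node_metrics(build_graph(R, 0.3))
  expect_equal(md$component_member, c(0L, 0L, 0L, 0L, 0L))
  expect_equal(attr(md, "component_probability"), 0)
  expect_equal(md$pair_ratio[1:2], c(1 / 5, 1 / 5))

  # empty graph: all metrics zero
  me <- node_metrics(build_graph(matrix(NA_real_, 3, 3), 0.3))
  expect_true(all(me$pair_ratio == 0 & me$clustering == 0 &
                    me$component_member == 0))
})

test_that("node metrics equal brute-force enumeration on random graphs", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    adj <- random_adjacency(n, runif(1, 0.05, 0.6))
    R <- ifelse(adj, 0.9, -0.1); diag(R) <- NA
    m <- node_metrics(build_graph(R, 0.3))
    o <- oracle_node_metrics(adj)
    expect_equal(m$pair_ratio, o$pair_ratio)
    expect_equal(m$clustering, o$clustering)
    expect_equal(m$component_member, o$component_member)
    expect_equal(attr(m, "component_probability"), o$component_probability)
  }
})

test_that("the edge set is invariant under cell reordering", {
  tr <- poisson_trains(10, 4, 120, seed = 3)
  r <- binarize_events(tr)
  R <- correlation_matrix(r)
  g <- build_graph(R, 0.1, cell_ids = rownames(r))
  perm <- sample(10)
  Rp <- R[perm, perm]
  gp <- build_graph(Rp, 0.1, cell_ids = rownames(r)[perm])
  expect_setequal(caensemble:::graph_edge_keys(g),
                  caensemble:::graph_edge_keys(gp))
})

test_that("shuffle thresholds are reproducible and flag identical trains", {
  tr <- poisson_trains(6, 4, 120, seed = 4)
  tr$trains[[2]] <- tr$trains[[1]]      # duplicate train: R = 1
  r <- binarize_events(tr)
  th1 <- shuffle_r_thresholds(r, n_shuffles = 200, seed = 11)
  th2 <- shuffle_r_thresholds(r, n_shuffles = 200, seed = 11)
  expect_identical(th1$thresholds, th2$thresholds)
  R <- correlation_matrix(r)
  g <- build_graph(R, th1)
  expect_true(g$adj[1, 2])
  expect_equal(g$mode, "shuffle")
  # Bonferroni mode tightens the per-pair level
  thb <- shuffle_r_thresholds(r, n_shuffles = 200, seed = 11,
                              bonferroni = TRUE)
  expect_lt(thb$alpha_effective, th1$alpha_effective)
  expect_true(all(thb$thresholds >= th1$thresholds, na.rm = TRUE))
  expect_error(shuffle_r_thresholds(r, n_shuffles = 50), ">= 100")
})

test_that("constant cells are untestable but stay in the FOV denominator", {
  tr <- poisson_trains(5, 3, 120, seed = 5)
  tr$trains[[3]] <- data.frame(time_s = numeric(0))   # silent cell
  r <- binarize_events(tr)
  th <- shuffle_r_thresholds(r, n_shuffles = 100, seed = 1)
  expect_true(all(is.na(th$thresholds[3, ])))
  R <- correlation_matrix(r)
  g <- build_graph(R, 0.3)
  expect_false(any(g$adj[3, ]))
  m <- node_metrics(g, n_cells_fov = 5)
  expect_equal(m$pair_ratio[3], 0)
})

test_that("pair persistence is the shared fraction of reference edges", {
  mk <- function(edges, ids = letters[1:5]) {
    R <- matrix(NA_real_, 5, 5, dimnames = list(ids, ids))
    for (e in edges) R[e[1], e[2]] <- R[e[2], e[1]] <- 0.9
    build_graph(R, 0.3, cell_ids = ids)
  }
  g1 <- mk(list(c(1, 2), c(2, 3), c(4, 5)))
  expect_equal(pair_persistence(g1, g1), 1)
  expect_equal(pair_persistence(g1, mk(list(c(1, 3)))), 0)
  expect_equal(pair_persistence(g1, mk(list(c(1, 2)))), 1 / 3)
  expect_message(p <- pair_persistence(mk(list()), g1), "no correlated pairs")
  expect_true(is.na(p))
})

test_that("correlated module pairs are spatially closer than chance pairs", {
  expect_equal(
    pair_distances(build_graph(rbind(c(NA, 0.9), c(0.9, NA)), 0.3,
                               cell_ids = c("a", "b")),
                   data.frame(cell_id = c("a", "b"), x = c(0, 3),
                              y = c(0, 4)))$correlated,
    5)
  cfg <- sim_config(seed = 6)
  ds <- simulate_animal(cfg)
  g <- correlation_graph(ds$trains[["A2"]], min_cells = 0)
  pd <- pair_distances(g, ds$centroids)
  expect_lt(pd$means["correlated"], pd$means["non_correlated"])
  # missing centroids excluded with a warning
  expect_warning(pair_distances(g, ds$centroids[-1, ]), "excluded")
})

test_that("sparse FOVs are refused unless overridden", {
  tr <- poisson_trains(10, 3, 120, seed = 7)
  expect_error(correlation_graph(tr), "inclusion minimum")
  expect_s3_class(correlation_graph(tr, min_cells = 0), "ca_graph")
})
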