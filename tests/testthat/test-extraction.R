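test_that("grid index candidates agree with brute force within the cell size", {
  nw <- cached_network()
  idx <- build_grid_index(nw, cell_m = 100)
  o <- nw$origin
  polys <- lapply(nw$polylines, function(p) project_lonlat(p[, 1], p[, 2], o))
  set.seed(40)
  # random query points scattered over the network bounding box
  allxy <- do.call(rbind, polys)
  qx <- runif(200, min(allxy[, 1]) - 150, max(allxy[, 1]) + 150)
  qy <- runif(200, min(allxy[, 2]) - 150, max(allxy[, 2]) + 150)
  for (i in seq_along(qx)) {
    d <- vapply(polys, function(p) {
      point_polyline_dist(cbind(qx[i], qy[i]), p)
    }, 1.0)
    brute <- which(d <= 100)
    cand <- grid_candidates(idx, qx[i], qy[i])
    # every segment within one cell of the point must be a candidate
    expect_true(all(brute %in% cand))
    # and filtering candidates by distance reproduces brute force exactly
    expect_setequal(cand[d[cand] <= 100], brute)
  }
})

test_that("points on a centerline match their segment at distance zero", {
  nw <- cached_network()
  idx <- build_grid_index(nw)
  mid <- t(vapply(seq_len(10), function(s) {
    p <- nw$polylines[[s]]
    colMeans(p)
  }, c(0, 0)))
  m <- match_point(mid[, 1], mid[, 2], idx)
  expect_identical(m$segment_id, 1:10)
  expect_true(all(m$dist_m < 1e-6))
})

test_that("far points are unmatched and ties break to the lower id", {
  nw <- toy_network(c(200, 200), parallel = 80)  # segment 3 parallel at 80 m
  idx <- build_grid_index(nw)
  far <- pt_at(100, 5000, nw$origin)
  expect_true(is.na(match_point(far[1], far[2], idx)$segment_id))
  # equidistant between segment 1 (y=0) and segment 3 (y=80)
  tie <- pt_at(100, 40, nw$origin)
  expect_identical(match_point(tie[1], tie[2], idx)$segment_id, 1L)
})

test_that("jittered points match their generating segment", {
  nw <- cached_network()
  idx <- build_grid_index(nw)
  o <- nw$origin
  set.seed(41)
  hit <- 0L
  n <- 400L
  for (i in seq_len(n)) {
    s <- sample(nrow(nw$segments), 1)
    p <- project_lonlat(nw$polylines[[s]][, 1], nw$polylines[[s]][, 2], o)
    at <- polyline_point_at(p, runif(1, 0, nw$segments$length_m[s]))
    jit <- at + rnorm(2, 0, 5)  # well under half the 40 m separation
    ll <- unproject_xy(jit[1], jit[2], o)
    got <- match_point(ll[1], ll[2], idx)$segment_id
    # points near junctions are legitimately ambiguous; count distance wins
    d_own <- point_polyline_dist(matrix(jit, 1), p)
    d_got <- point_polyline_dist(matrix(jit, 1),
      project_lonlat(nw$polylines[[got]][, 1], nw$polylines[[got]][, 2], o))
    expect_lte(d_got, d_own + 1e-9)
    if (got == s) hit <- hit + 1L
  }
  expect_gt(hit / n, 0.9)
})

test_that("intersection exclusion drops strictly inside the radius only", {
  nw <- toy_network(c(200, 200))
  int1 <- nw$intersections[1, ]  # junction at x = 200
  o <- nw$origin
  lon <- c(pt_at(200 - 29.99, 0, o)[1], pt_at(200 - 30, 0, o)[1],
           pt_at(200 - 100, 0, o)[1])
  lat <- c(pt_at(200 - 29.99, 0, o)[2], pt_at(200 - 30, 0, o)[2],
           pt_at(200 - 100, 0, o)[2])
  keep <- exclude_intersection_zone(lon, lat, nw$intersections, 30, o)
  expect_identical(keep, c(FALSE, TRUE, TRUE))
  expect_true(all(exclude_intersection_zone(lon, lat, nw$intersections, 0, o)))
  expect_error(exclude_intersection_zone(lon, lat, nw$intersections, -1, o),
               "radius_m")
})

test_that("exclusion equals the quadratic distance filter", {
  nw <- cached_network()
  set.seed(42)
  o <- nw$origin
  allxy <- do.call(rbind, lapply(nw$polylines, function(p) {
    project_lonlat(p[, 1], p[, 2], o)
  }))
  qx <- runif(300, min(allxy[, 1]), max(allxy[, 1]))
  qy <- runif(300, min(allxy[, 2]), max(allxy[, 2]))
  ll <- unproject_xy(qx, qy, o)
  keep <- exclude_intersection_zone(ll[, 1], ll[, 2], nw$intersections, 30, o)
  ints <- project_lonlat(nw$intersections[, 1], nw$intersections[, 2], o)
  brute <- vapply(seq_along(qx), function(i) {
    all(sqrt((ints[, 1] - qx[i])^2 + (ints[, 2] - qy[i])^2) >= 30)
  }, TRUE)
  expect_identical(keep, brute)
})

test_that("pairwise speeds match the haversine oracle within 0.1%", {
  skip_if_not_installed("geosphere")
  set.seed(43)
  lon1 <- runif(100, 104.04, 104.13)
  lat1 <- runif(100, 30.65, 30.73)
  lon2 <- lon1 + runif(100, -0.003, 0.003)
  lat2 <- lat1 + runif(100, -0.003, 0.003)
  dt <- runif(100, 5, 30)
  v <- pairwise_speed(lon1, lat1, 0, lon2, lat2, dt)
  d_oracle <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                       r = 6371008.8)
  expect_equal(v, 3.6 * d_oracle / dt, tolerance = 1e-3)
  expect_identical(pairwise_speed(104, 30, 0, 104, 30, 10), 0)
  expect_error(pairwise_speed(104, 30, 10, 104.001, 30, 10), "increasing")
})

test_that("classification thresholds are strict at the limit and at 20% over", {
  expect_identical(classify_pairwise(40, 40), "none")
  expect_identical(classify_pairwise(40.001, 40), "speeding")
  expect_identical(classify_pairwise(48, 40), "speeding")
  expect_identical(classify_pairwise(48.01, 40), "serious")
  expect_identical(classify_pairwise(59, 60), "none")
  expect_identical(classify_pairwise(72, 60), "speeding")
  expect_identical(classify_pairwise(72.01, 60), "serious")
  expect_error(classify_pairwise(50, 0), "speed_limit")
  # serious always implies the speeding condition across a scan
  v <- seq(30, 90, by = 0.25)
  cls <- classify_pairwise(v, 60)
  expect_true(all(v[cls == "serious"] > 60))
})

test_that("anomaly screening flags reversals and planted U-turns only", {
  o <- c(104.086, 30.69)
  straight <- unproject_xy(seq(0, 1000, by = 100), rep(0, 11), o)
  nw <- toy_network(c(1100))
  idx <- build_grid_index(nw)
  xy <- project_lonlat(straight[, 1], straight[, 2], o)
  expect_true(!any(screen_anomalies(xy, rep(1L, 10), idx)))
  # a reversal: forward then straight back
  rev_x <- c(0, 100, 200, 100, 0)
  xy2 <- cbind(rev_x, 0)
  flags <- screen_anomalies(xy2, rep(1L, 4), idx)
  expect_identical(which(flags), 3:4)  # the reversal pair and its wrong-way tail
  # one planted U-turn among many straight pairs: exactly the turn is flagged
  x <- c(seq(0, 5000, by = 100), seq(4900, 4000, by = -100))
  xy3 <- cbind(x, 0)
  pair_seg <- rep(NA_integer_, length(x) - 1)  # direction check off
  flags3 <- screen_anomalies(xy3, pair_seg, idx)
  expect_identical(which(flags3), 51L)
})

test_that("event merging follows the worked patterns", {
  mk <- function(cls, valid = TRUE) {
    data.frame(start_index = seq_along(cls), classification = cls,
               valid = rep(valid, length.out = length(cls)), segment_id = 1L)
  }
  # [S,S,S] merges to one event spanning points (i, i+3)
  e <- merge_events(mk(c("speeding", "speeding", "speeding")))
  expect_identical(nrow(e[e$class == "total", ]), 1L)
  expect_identical(e$start_index[1], 1L)
  expect_identical(e$end_index[1], 4L)
  expect_identical(e$n_pairwise[1], 3L)
  # isolated [N,S,N] is still one complete event
  e2 <- merge_events(mk(c("none", "speeding", "none")))
  expect_identical(nrow(e2[e2$class == "total", ]), 1L)
  expect_identical(e2$n_pairwise, 1L)
  # [S,N,S] are two events
  e3 <- merge_events(mk(c("speeding", "none", "speeding")))
  expect_identical(nrow(e3[e3$class == "total", ]), 2L)
  # invalid pairs break runs instead of bridging them
  p <- mk(c("speeding", "speeding", "speeding"))
  p$valid[2] <- FALSE
  e4 <- merge_events(p)
  expect_identical(nrow(e4[e4$class == "total", ]), 2L)
  # serious runs merge independently and sit inside total spans
  e5 <- merge_events(mk(c("speeding", "serious", "serious", "speeding")))
  tot <- e5[e5$class == "total", ]
  ser <- e5[e5$class == "serious", ]
  expect_identical(nrow(tot), 1L)
  expect_identical(nrow(ser), 1L)
  expect_true(ser$start_index >= tot$start_index &&
              ser$end_index <= tot$end_index)
})

test_that("count aggregation conserves events and rejects unknown segments", {
  nw <- toy_network(c(100, 100, 100))
  ev <- data.frame(vehicle_id = "v", segment_id = c(1L, 1L, 3L),
                   start_index = 1L, end_index = 2L,
                   class = c("total", "total", "serious"), n_pairwise = 1L)
  counts <- aggregate_counts(ev, nw)
  expect_identical(counts$y_total, c(2L, 0L, 0L))
  expect_identical(counts$y_serious, c(0L, 0L, 1L))
  expect_identical(sum(counts$y_total), sum(ev$class == "total"))
  empty <- aggregate_counts(ev[0, ], nw)
  expect_true(all(empty$y_total == 0L) && all(empty$y_serious == 0L))
  ev$segment_id[1] <- 99L
  expect_error(aggregate_counts(ev, nw), "unknown segment")
})

test_that("lowering a speed limit never decreases recovered totals", {
  nw <- cached_network()
  plan <- plan_episodes(nw, 4, 2, seed = 60)
  sim <- simulate_trajectories(nw, plan, seed = 61)
  base <- extract_events(sim$trajectories, nw)$counts
  low <- nw
  low$segments$speed_limit_kmh <- pmax(10, low$segments$speed_limit_kmh - 20)
  lowc <- extract_events(sim$trajectories, low)$counts
  expect_true(all(lowc$y_total >= base$y_total))
})

test_that("VIF matches the direct R-squared oracle", {
  set.seed(70)
  n <- 120
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + rnorm(n, 0, 0.5)
  x3 <- rnorm(n)
  X <- cbind(x1, x2, x3)
  v <- vif(X)
  oracle <- vapply(1:3, function(k) {
    r2 <- summary(lm(X[, k] ~ X[, -k]))$r.squared
    1 / (1 - r2)
  }, 1.0)
  expect_equal(unname(v), oracle, tolerance = 1e-8)
  # exactly uncorrelated (zero-mean orthogonal) columns give VIF 1
  Q <- cbind(rep(c(1, -1), 10), rep(c(1, 1, -1, -1), 5),
             rep(c(1, -1, -1, 1), 5))
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-8)
  # duplicated column is infinite, not an error
  expect_identical(unname(vif(cbind(x1, x1, x3))[1]), Inf)
  expect_error(vif(cbind(x1, rep(1, n))), "constant")
  expect_error(vif(X[1:4, ]), "rows")
})
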