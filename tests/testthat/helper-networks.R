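# Fixtures are built in code: a hand-made road_network constructor for
# geometric edge cases, plus small cached generator outputs.

# Straight horizontal multi-segment road: segments laid end to end on y = 0,
# with optional parallel road at y = offset. Lengths in meters.
toy_network <- function(lengths, origin = c(104.086, 30.69),
                        parallel = NULL, speed_limit = 60) {
  xs <- c(0, cumsum(lengths))
  n <- length(lengths)
  polys <- lapply(seq_len(n), function(i) {
    unproject_xy(c(xs[i], xs[i + 1]), c(0, 0), origin)
  })
  seg <- data.frame(segment_id = seq_len(n), length_m = lengths,
                    speed_limit_kmh = rep(speed_limit, length.out = n),
                    node_a = seq_len(n), node_b = seq_len(n) + 1L)
  if (!is.null(parallel)) {
    # one extra segment parallel to the first, offset in +y
    polys <- c(polys, list(unproject_xy(c(xs[1], xs[2]),
                                        c(parallel, parallel), origin)))
    seg <- rbind(seg, data.frame(segment_id = n + 1L, length_m = lengths[1],
                                 speed_limit_kmh = speed_limit[1],
                                 node_a = n + 2L, node_b = n + 3L))
    n <- n + 1L
  }
  W <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (any(c(seg$node_a[i], seg$node_b[i]) %in%
              c(seg$node_a[j], seg$node_b[j]))) {
        W[i, j] <- W[j, i] <- 1L
      }
    }
  }
  # interior chain nodes are intersections (shared by two segments)
  shared <- intersect(seq_len(max(seg$node_b)),
                      names(which(table(c(seg$node_a, seg$node_b)) >= 2)))
  ints <- if (length(shared)) {
    unproject_xy(xs[as.integer(shared)], rep(0, length(shared)), origin)
  } else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("lon", "lat")))
  structure(list(segments = seg, polylines = polys, adjacency = W,
                 intersections = ints, origin = origin, covariates = NULL),
            class = "road_network")
}

# place a lon/lat point at planar (x, y) meters from the origin
pt_at <- function(x, y, origin = c(104.086, 30.69)) {
  as.numeric(unproject_xy(x, y, origin))
}

# small generated network reused across tests
cached_network <- local({
  nw <- NULL
  function() {
    if (is.null(nw)) {
      nw <<- generate_covariates(generate_road_network(60, seed = 101),
                                 seed = 102)
    }
    nw
  }
})
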