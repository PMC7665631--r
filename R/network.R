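#' Study-condition covariate marginals
#'
#' Target means of the ten road-segment variables used by the synthetic
#' generator: nine road-characteristic variables (eight binary indicators and
#' a speed-camera count with range 0--4) plus continuous segment length.
#' Values correspond to the descriptive statistics of the urban arterial
#' network the models were designed for.
#'
#' @return Named list of target means; `length_m` holds `c(mean, sd, min, max)`
#'   in meters.
#' @export
table1_marginals <- function() {
  list(
    speed_limit_ind   = 0.21,   # 1 if posted limit <= 40 km/h
    n_cameras         = 0.625,  # count, 0..4
    n_lanes_ind       = 0.231,  # 1 if <= 4 lanes
    cross_section_ind = 0.555,  # 1 if no divider
    one_way_ind       = 0.043,
    non_motor_ind     = 0.891,
    bus_lane_ind      = 0.625,
    viaduct_ind       = 0.090,
    work_zone_ind     = 0.102,
    length_m          = c(mean = 162.412, sd = 88.586, min = 4.386, max = 489.948)
  )
}

.indicator_names <- c(
  "speed_limit_ind", "n_lanes_ind", "cross_section_ind", "one_way_ind",
  "non_motor_ind", "bus_lane_ind", "viaduct_ind", "work_zone_ind"
)

#' Covariate column order used throughout the package
#' @return character vector of the ten covariate names.
#' @export
covariate_names <- function() {
  c("speed_limit_ind", "n_cameras", "n_lanes_ind", "cross_section_ind",
    "one_way_ind", "non_motor_ind", "bus_lane_ind", "viaduct_ind",
    "work_zone_ind", "length_m")
}

# truncated-normal draws by rejection; bounds well inside the bulk so this is cheap
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic road-segment network
#'
#' Lays road segments in a rectilinear planar spine-and-branch layout: a
#' horizontal arterial divided into segments at junctions, with perpendicular
#' branch segments hanging off interior junctions on alternating sides. Two
#' segments are adjacent when they share a junction node. Every segment's
#' length is drawn independently from the study marginal (mean 162.4 m,
#' s.d. 88.6 m) truncated to \[40, 489.948\] m -- inside the study range of
#' 4.386--489.948 m, with the 40 m floor keeping distinct parallel
#' centerlines at least 40 m apart so map matching of GPS points with up to
#' 20 m positional error stays well posed. Independent per-segment lengths
#' (rather than lengths tied to shared grid spacings) keep the length
#' covariate from aliasing the smooth spatial field.
#'
#' @param n_segments number of road segments (>= 2).
#' @param seed integer RNG seed.
#' @param origin projection reference `c(lon, lat)` in degrees.
#' @return A `road_network` object: list with `segments` (data.frame:
#'   `segment_id`, `length_m`, `speed_limit_kmh`, `node_a`, `node_b`),
#'   `polylines` (list of lon/lat matrices), `adjacency` (binary symmetric
#'   matrix), `intersections` (lon/lat matrix of nodes shared by >= 2
#'   segments), `origin`, and `covariates` (`NULL` until
#'   [generate_covariates()] is called).
#' @export
generate_road_network <- function(n_segments, seed = 1L,
                                  origin = c(104.0859, 30.6905)) {
  if (!is.numeric(n_segments) || length(n_segments) != 1 || n_segments < 2 ||
      n_segments != round(n_segments)) {
    stop("n_segments must be a single integer >= 2")
  }
  n_segments <- as.integer(n_segments)
  set.seed(seed)
  lm <- table1_marginals()$length_m
  S <- n_segments

  n_sp <- as.integer(ceiling((S + 1) / 2))  # spine segments
  n_br <- S - n_sp                          # branches at interior junctions
  len <- .rtruncnorm(S, lm["mean"], lm["sd"], 40, lm["max"])

  # nodes: spine nodes 1..n_sp+1 on y = 0, then one tip node per branch
  xs <- c(0, cumsum(len[seq_len(n_sp)]))
  node_xy <- cbind(x = xs, y = rep(0, n_sp + 1L))
  sel <- cbind(seq_len(n_sp), seq_len(n_sp) + 1L, len[seq_len(n_sp)])
  if (n_br > 0) {
    junctions <- seq(2L, n_sp)[sample.int(n_sp - 1L, n_br)]  # interior nodes
    for (b in seq_len(n_br)) {
      L <- len[n_sp + b]
      side <- if (b %% 2L == 1L) 1 else -1
      node_xy <- rbind(node_xy, c(node_xy[junctions[b], 1], side * L))
      sel <- rbind(sel, c(junctions[b], nrow(node_xy), L))
    }
  }
  # recenter so the origin is the network centroid-ish
  ctr <- c(mean(range(node_xy[, 1])), mean(range(node_xy[, 2])))
  node_xy <- sweep(node_xy, 2, ctr)
  polylines <- vector("list", S)
  for (s in seq_len(S)) {
    a <- node_xy[sel[s, 1], ]
    b <- node_xy[sel[s, 2], ]
    polylines[[s]] <- unproject_xy(c(a[1], b[1]), c(a[2], b[2]), origin)
  }

  speed_limit <- ifelse(stats::runif(S) < 0.21, 40, 60)
  segments <- data.frame(
    segment_id = seq_len(S),
    length_m = sel[, 3],
    speed_limit_kmh = speed_limit,
    node_a = as.integer(sel[, 1]),
    node_b = as.integer(sel[, 2])
  )

  adjacency <- matrix(0L, S, S)
  for (s in seq_len(S - 1L)) {
    for (t in (s + 1L):S) {
      if (any(sel[s, 1:2] %in% sel[t, 1:2])) {
        adjacency[s, t] <- 1L
        adjacency[t, s] <- 1L
      }
    }
  }

  node_use <- tabulate(c(sel[, 1], sel[, 2]), nrow(node_xy))
  inter_nodes <- which(node_use >= 2L)
  intersections <- unproject_xy(node_xy[inter_nodes, 1], node_xy[inter_nodes, 2],
                                origin)

  structure(
    list(segments = segments, polylines = polylines, adjacency = adjacency,
         intersections = intersections, origin = origin, covariates = NULL),
    class = "road_network"
  )
}

#' @export
print.road_network <- function(x, ...) {
  S <- nrow(x$segments)
  cat("road_network:", S, "segments,",
      sum(x$adjacency) / 2, "adjacencies,",
      nrow(x$intersections), "intersections\n")
  cat("  segment length [m]:", sprintf("%.1f-%.1f", min(x$segments$length_m),
                                       max(x$segments$length_m)),
      " covariates:", if (is.null(x$covariates)) "not generated" else "filled", "\n")
  invisible(x)
}

#' Validate road_network invariants
#'
#' Checks symmetry and zero diagonal of the adjacency, binary entries, polyline
#' sanity and positive lengths. Called by downstream entry points.
#'
#' @param network a `road_network`.
#' @return invisibly `TRUE`; stops on violation.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "road_network"))
  W <- network$adjacency
  if (!isTRUE(all.equal(W, t(W)))) stop("adjacency must be symmetric")
  if (any(diag(W) != 0)) stop("adjacency diagonal must be zero")
  if (!all(W %in% c(0, 1))) stop("adjacency entries must be 0/1")
  if (nrow(W) != nrow(network$segments)) stop("adjacency does not match segments")
  if (any(network$segments$length_m <= 0)) stop("segment lengths must be positive")
  if (any(vapply(network$polylines, nrow, 1L) < 2L)) {
    stop("every polyline needs >= 2 vertices")
  }
  invisible(TRUE)
}

#' Fill the ten segment covariates
#'
#' Draws the eight binary indicators as independent Bernoulli variables with
#' the supplied target means, the speed-camera count as Binomial(4, mean/4),
#' and copies the length covariate from the geometry. The speed-limit
#' indicator is drawn here and the segment's `speed_limit_kmh` is set
#' consistently (40 km/h when the indicator is 1, 60 km/h otherwise), so the
#' covariate table and the limits used for event classification always agree.
#'
#' @param network a `road_network`.
#' @param marginals named list of target means, as [table1_marginals()].
#' @param seed integer RNG seed.
#' @return the network with `covariates` filled (data.frame, one row per
#'   segment, columns [covariate_names()]).
#' @export
generate_covariates <- function(network, marginals = table1_marginals(),
                                seed = 1L) {
  validate_network(network)
  for (nm in .indicator_names) {
    p <- marginals[[nm]]
    if (is.null(p) || !is.numeric(p) || p <= 0 || p >= 1) {
      stop("indicator marginal '", nm, "' must lie strictly in (0, 1)")
    }
  }
  cam <- marginals$n_cameras
  if (is.null(cam) || cam <= 0 || cam >= 4) {
    stop("n_cameras mean must lie in (0, 4)")
  }
  set.seed(seed)
  S <- nrow(network$segments)
  cov <- data.frame(row.names = seq_len(S))
  for (nm in .indicator_names) {
    cov[[nm]] <- stats::rbinom(S, 1L, marginals[[nm]])
  }
  cov$n_cameras <- stats::rbinom(S, 4L, cam / 4)
  cov$length_m <- network$segments$length_m
  cov <- cov[, covariate_names()]
  network$covariates <- cov
  network$segments$speed_limit_kmh <- ifelse(cov$speed_limit_ind == 1, 40, 60)
  network
}

#' Connected components of an adjacency matrix
#' @param adjacency binary symmetric matrix.
#' @return integer vector of component labels (1-based).
#' @export
graph_components <- function(adjacency) {
  S <- nrow(adjacency)
  comp <- integer(S)
  cur <- 0L
  for (s in seq_len(S)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        u <- queue[1]
        queue <- queue[-1]
        nb <- which(adjacency[u, ] != 0 & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}
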