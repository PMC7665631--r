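#' Build a grid spatial index over road centerlines
#'
#' Registers every segment polyline in the square grid cells its sub-segments
#' cover (bounding-box registration: a superset of the cells a line actually
#' crosses, which can only add candidates, never lose one). Queries return the
#' segments registered in a point's cell or its eight neighbors; because the
#' cell side equals the maximum matching distance, every segment within
#' `cell_m` of a point is guaranteed to be among its candidates.
#'
#' @param network a `road_network`.
#' @param cell_m grid cell side in meters (> 0); also the maximum matching
#'   distance used by [match_point()].
#' @return a `grid_index` object.
#' @export
build_grid_index <- function(network, cell_m = 100) {
  validate_network(network)
  if (cell_m <= 0) stop("cell_m must be > 0")
  if (nrow(network$segments) == 0) stop("empty network")
  origin <- network$origin
  polys <- lapply(network$polylines, function(p) {
    project_lonlat(p[, 1], p[, 2], origin)
  })
  cells <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seq_along(polys)) {
    p <- polys[[s]]
    for (j in seq_len(nrow(p) - 1L)) {
      i0 <- floor(min(p[j:(j + 1L), 1]) / cell_m)
      i1 <- floor(max(p[j:(j + 1L), 1]) / cell_m)
      k0 <- floor(min(p[j:(j + 1L), 2]) / cell_m)
      k1 <- floor(max(p[j:(j + 1L), 2]) / cell_m)
      for (ci in i0:i1) {
        for (ck in k0:k1) {
          key <- paste(ci, ck)
          cells[[key]] <- c(cells[[key]], s)
        }
      }
    }
  }
  structure(list(cells = cells, cell_m = cell_m, origin = origin,
                 polylines_xy = polys,
                 segment_id = network$segments$segment_id),
            class = "grid_index")
}

#' Candidate segments for a projected point
#' @param index a `grid_index`.
#' @param x,y projected point coordinates (m).
#' @return integer vector of segment row positions (may be empty).
#' @export
grid_candidates <- function(index, x, y) {
  ci <- floor(x / index$cell_m)
  ck <- floor(y / index$cell_m)
  out <- integer(0)
  for (di in -1:1) {
    for (dk in -1:1) {
      key <- paste(ci + di, ck + dk)
      out <- c(out, index$cells[[key]])
    }
  }
  sort(unique(out))
}

#' Match GPS points to the nearest road centerline
#'
#' For each point, searches the grid index candidates and returns the segment
#' minimizing the planar point-to-polyline distance under the local
#' equirectangular projection ("adjusted Euclidean" matching). Points farther
#' than `index$cell_m` from every candidate are unmatched (`NA`). Exact ties
#' (within 1e-9 m) resolve to the lower segment id.
#'
#' @param lon,lat numeric vectors, degrees.
#' @param index a `grid_index` built over the network.
#' @return data.frame `segment_id` (NA when unmatched) and `dist_m`.
#' @export
match_point <- function(lon, lat, index) {
  xy <- project_lonlat(lon, lat, index$origin)
  n <- nrow(xy)
  seg <- rep(NA_integer_, n)
  dst <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cand <- grid_candidates(index, xy[i, 1], xy[i, 2])
    if (!length(cand)) next
    d <- vapply(cand, function(s) {
      point_polyline_dist(xy[i, , drop = FALSE], index$polylines_xy[[s]])
    }, 1.0)
    ok <- d <= index$cell_m
    if (!any(ok)) next
    cand <- cand[ok]
    d <- d[ok]
    best <- which(d <= min(d) + 1e-9)
    pick <- best[which.min(index$segment_id[cand][best])]
    seg[i] <- index$segment_id[cand][pick]
    dst[i] <- d[pick]
  }
  data.frame(segment_id = seg, dist_m = dst)
}

#' Drop GPS points inside intersection buffer zones
#'
#' Removes every point strictly closer than `radius_m` to any intersection;
#' points at exactly the radius are retained.
#'
#' @param lon,lat numeric vectors, degrees.
#' @param intersections two-column lon/lat matrix.
#' @param radius_m exclusion radius in meters (>= 0).
#' @param origin projection reference `c(lon, lat)`.
#' @return logical vector, `TRUE` for retained points.
#' @export
exclude_intersection_zone <- function(lon, lat, intersections, radius_m = 30,
                                      origin) {
  if (radius_m < 0) stop("radius_m must be >= 0")
  if (is.null(intersections) || nrow(intersections) == 0 || radius_m == 0) {
    return(rep(TRUE, length(lon)))
  }
  pts <- project_lonlat(lon, lat, origin)
  ints <- project_lonlat(intersections[, 1], intersections[, 2], origin)
  keep <- rep(TRUE, length(lon))
  for (j in seq_len(nrow(ints))) {
    d <- sqrt((pts[, 1] - ints[j, 1])^2 + (pts[, 2] - ints[j, 2])^2)
    # nanometre slack so a point at exactly the radius survives the
    # degree-projection round trip
    keep <- keep & (d >= radius_m - 1e-9)
  }
  keep
}

#' Average speed between adjacent GPS points
#'
#' \eqn{V_{i,i+1} = \Delta D_{i,i+1} / \Delta T_{i,i+1}}, with the driving
#' distance measured as the planar distance under a local equirectangular
#' projection about the mean latitude of each pair (great-circle-equivalent
#' at city scale), converted to km/h.
#'
#' @param lon1,lat1,lon2,lat2 coordinates of the two points, degrees.
#' @param t1,t2 timestamps (POSIXct or numeric seconds); `t2` must be later.
#' @return numeric vector of speeds in km/h.
#' @export
pairwise_speed <- function(lon1, lat1, t1, lon2, lat2, t2) {
  dt <- as.numeric(t2) - as.numeric(t1)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  rad <- pi / 180
  latbar <- (lat1 + lat2) / 2 * rad
  dx <- .earth_radius_m * (lon2 - lon1) * rad * cos(latbar)
  dy <- .earth_radius_m * (lat2 - lat1) * rad
  3.6 * sqrt(dx^2 + dy^2) / dt
}

#' Classify a point pair against the posted speed limit
#'
#' Speeding when the average speed strictly exceeds the limit; serious when it
#' strictly exceeds 120% of the limit (the legal serious-speeding criterion).
#' Serious implies speeding; the boundary cases `v == limit` and
#' `v == 1.2 * limit` are "none" and "speeding" respectively.
#'
#' @param v_kmh average pair speed, km/h.
#' @param speed_limit_kmh posted limit (> 0), km/h.
#' @return character vector: "none", "speeding" or "serious".
#' @export
classify_pairwise <- function(v_kmh, speed_limit_kmh) {
  if (any(speed_limit_kmh <= 0, na.rm = TRUE)) {
    stop("speed_limit_kmh must be > 0")
  }
  out <- rep("none", length(v_kmh))
  out[v_kmh > speed_limit_kmh] <- "speeding"
  out[v_kmh > 1.2 * speed_limit_kmh] <- "serious"
  out
}

#' Flag anomalous point pairs (U-turn / wrong-way proxies)
#'
#' A pair is flagged when the heading change from the previous displacement
#' vector exceeds `threshold_deg` (U-turn proxy), or when its displacement
#' opposes the matched segment's declared direction (first to last polyline
#' vertex) by more than `threshold_deg` (wrong-way proxy). The behaviours are
#' named in the processing protocol; the angular threshold is this package's
#' configurable operationalization.
#'
#' @param xy two-column projected coordinate matrix of one vehicle's
#'   time-sorted points (m).
#' @param pair_segment integer vector (length `nrow(xy) - 1`): row position
#'   of each pair's matched segment, NA when unmatched.
#' @param index a `grid_index` (supplies segment polylines).
#' @param threshold_deg angular threshold in degrees (default 150).
#' @return logical vector, `TRUE` for anomalous pairs.
#' @export
screen_anomalies <- function(xy, pair_segment, index, threshold_deg = 150) {
  n <- nrow(xy) - 1L
  if (n < 1L) return(logical(0))
  disp <- xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE]
  ang <- function(a, b) {
    na <- sqrt(sum(a^2))
    nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    acos(pmin(1, pmax(-1, sum(a * b) / (na * nb)))) * 180 / pi
  }
  flag <- logical(n)
  for (i in seq_len(n)) {
    if (i > 1L && ang(disp[i - 1L, ], disp[i, ]) > threshold_deg) {
      flag[i] <- TRUE
      next
    }
    s <- pair_segment[i]
    if (!is.na(s)) {
      poly <- index$polylines_xy[[s]]
      dir <- poly[nrow(poly), ] - poly[1, ]
      if (ang(dir, disp[i, ]) > threshold_deg) flag[i] <- TRUE
    }
  }
  flag
}

#' Merge classified point pairs into complete speeding events
#'
#' Each maximal run of consecutive valid speeding pairs becomes one total
#' event (an isolated speeding pair is itself an event); maximal runs of
#' serious pairs are merged independently into serious events. Invalid pairs
#' (excluded, unmatched or anomalous) break runs rather than bridging them.
#' An event is attributed to the matched segment of its first pair.
#'
#' @param pairs data.frame for one vehicle, time-ordered, with columns
#'   `start_index`, `classification`, `valid` (logical), `segment_id`.
#' @param vehicle_id identifier copied onto the events.
#' @return data.frame of events: `vehicle_id`, `segment_id`, `start_index`,
#'   `end_index`, `class` ("total"/"serious"), `n_pairwise`.
#' @export
merge_events <- function(pairs, vehicle_id = "vehicle") {
  runs_of <- function(qualifies) {
    ev <- list()
    i <- 1L
    n <- nrow(pairs)
    while (i <= n) {
      if (qualifies[i]) {
        j <- i
        while (j < n && qualifies[j + 1L] &&
               pairs$start_index[j + 1L] == pairs$start_index[j] + 1L) {
          j <- j + 1L
        }
        ev[[length(ev) + 1L]] <- c(i, j)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
    ev
  }
  mk <- function(ev, cls) {
    if (!length(ev)) {
      return(data.frame(vehicle_id = character(0), segment_id = integer(0),
                        start_index = integer(0), end_index = integer(0),
                        class = character(0), n_pairwise = integer(0)))
    }
    do.call(rbind, lapply(ev, function(e) {
      data.frame(vehicle_id = vehicle_id,
                 segment_id = pairs$segment_id[e[1]],
                 start_index = pairs$start_index[e[1]],
                 end_index = pairs$start_index[e[2]] + 1L,
                 class = cls,
                 n_pairwise = e[2] - e[1] + 1L)
    }))
  }
  speeding <- pairs$valid & pairs$classification %in% c("speeding", "serious")
  serious <- pairs$valid & pairs$classification == "serious"
  rbind(mk(runs_of(speeding), "total"), mk(runs_of(serious), "serious"))
}

#' Aggregate events into per-segment counts
#'
#' @param events data.frame as returned by [merge_events()].
#' @param network a `road_network`.
#' @return data.frame `segment_id`, `y_total`, `y_serious` covering every
#'   segment (zero where no events).
#' @export
aggregate_counts <- function(events, network) {
  ids <- network$segments$segment_id
  if (nrow(events) > 0 && !all(events$segment_id %in% ids)) {
    stop("events reference unknown segment ids: ",
         paste(setdiff(events$segment_id, ids), collapse = ", "))
  }
  tab <- function(cls) {
    e <- events[events$class == cls, ]
    out <- integer(length(ids))
    if (nrow(e)) {
      t <- table(factor(e$segment_id, levels = ids))
      out <- as.integer(t)
    }
    out
  }
  data.frame(segment_id = ids, y_total = tab("total"), y_serious = tab("serious"))
}

#' Extract per-segment speeding counts from raw trajectories
#'
#' Full extraction protocol: sort each vehicle's points by time, grid-match
#' every point to its nearest centerline, suspend points inside the
#' intersection buffer, flag anomalous pairs, compute pairwise average speeds,
#' classify them against the matched segment's posted limit (strict
#' thresholds, serious at 20% over), merge maximal runs into complete events
#' and aggregate per segment.
#'
#' @param trajectories data.frame `vehicle_id`, `timestamp`, `lon`, `lat`.
#' @param network a `road_network`.
#' @param cell_m grid cell side / maximum matching distance (m).
#' @param intersection_radius_m intersection exclusion radius (m).
#' @param heading_threshold_deg anomaly screening angle (degrees).
#' @return list: `counts` (per-segment data.frame), `events`, `pairs`
#'   (audit trail of every evaluated pair).
#' @export
extract_events <- function(trajectories, network, cell_m = 100,
                           intersection_radius_m = 30,
                           heading_threshold_deg = 150) {
  validate_network(network)
  need <- c("vehicle_id", "timestamp", "lon", "lat")
  if (!all(need %in% names(trajectories))) {
    stop("trajectories must have columns ", paste(need, collapse = ", "))
  }
  index <- build_grid_index(network, cell_m)
  all_events <- list()
  all_pairs <- list()
  for (vid in unique(trajectories$vehicle_id)) {
    tr <- trajectories[trajectories$vehicle_id == vid, ]
    tr <- tr[order(tr$timestamp), ]
    if (any(diff(as.numeric(tr$timestamp)) <= 0)) {
      stop("non-increasing timestamps for vehicle ", vid)
    }
    if (nrow(tr) < 2L) next
    m <- match_point(tr$lon, tr$lat, index)
    keep <- exclude_intersection_zone(tr$lon, tr$lat, network$intersections,
                                      intersection_radius_m, network$origin)
    xy <- project_lonlat(tr$lon, tr$lat, network$origin)
    n <- nrow(tr) - 1L
    seg_row <- match(m$segment_id, network$segments$segment_id)
    pair_seg_row <- seg_row[-length(seg_row)]  # pair takes its first point's match
    anom <- screen_anomalies(xy, pair_seg_row, index, heading_threshold_deg)
    v <- pairwise_speed(tr$lon[-nrow(tr)], tr$lat[-nrow(tr)],
                        tr$timestamp[-nrow(tr)],
                        tr$lon[-1], tr$lat[-1], tr$timestamp[-1])
    valid <- keep[-length(keep)] & keep[-1] & !anom & !is.na(pair_seg_row)
    limit <- network$segments$speed_limit_kmh[pair_seg_row]
    cls <- rep("none", n)
    cls[valid] <- classify_pairwise(v[valid], limit[valid])
    pairs <- data.frame(
      start_index = seq_len(n),
      delta_t_s = diff(as.numeric(tr$timestamp)),
      v_kmh = v,
      segment_id = network$segments$segment_id[pair_seg_row],
      classification = cls,
      valid = valid
    )
    all_pairs[[vid]] <- cbind(vehicle_id = vid, pairs)
    all_events[[vid]] <- merge_events(pairs, vid)
  }
  events <- if (length(all_events)) do.call(rbind, all_events) else
    merge_events(data.frame(start_index = integer(0),
                            classification = character(0),
                            valid = logical(0), segment_id = integer(0)))
  rownames(events) <- NULL
  list(counts = aggregate_counts(events, network), events = events,
       pairs = if (length(all_pairs)) do.call(rbind, all_pairs) else NULL)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from the ordinary
#' least-squares regression of covariate k on all the others. Perfectly
#' collinear columns report `Inf` rather than raising an error.
#'
#' @param X numeric matrix or data.frame of covariates.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  m <- ncol(X)
  if (nrow(X) < m + 2L) stop("need at least m + 2 rows")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant column in covariates")
  out <- numeric(m)
  for (k in seq_len(m)) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, k] - mean(X[, k]))^2)
    r2 <- 1 - rss / tss
    out[k] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  names(out) <- colnames(X)
  out
}
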