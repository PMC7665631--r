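#' Plan speeding episodes on feasible segments
#'
#' Chooses segments long enough to host planted episodes and distributes the
#' requested number of total-speeding and serious-speeding episodes among
#' them. With a 10 s sampling interval an above-limit point pair spans at
#' least the limit-speed travel distance (111 m at 40 km/h), so an episode is
#' feasible only on segments where that pair fits while staying `margin_m`
#' away from both endpoints (keeping intersection exclusion clear of the
#' planted run). Each episode is carried by its own vehicle, so any number of
#' episodes fits on a feasible segment; a cap of 3 per segment keeps plans
#' spread out.
#'
#' @param network a `road_network`.
#' @param n_total number of total-speeding (but not serious) episodes.
#' @param n_serious number of serious-speeding episodes.
#' @param sampling_interval_s GPS sampling interval (s).
#' @param seed integer RNG seed.
#' @param margin_m clearance kept from segment endpoints (m).
#' @param serious_frac planted serious episode speed as a fraction of the limit.
#' @return data.frame `segment_id`, `n_total`, `n_serious` (planned episodes).
#' @export
plan_episodes <- function(network, n_total = 8L, n_serious = 4L,
                          sampling_interval_s = 10, seed = 1L,
                          margin_m = 55, serious_frac = 1.35) {
  set.seed(seed)
  seg <- network$segments
  ep_d <- serious_frac * seg$speed_limit_kmh / 3.6 * sampling_interval_s
  capacity <- ifelse(seg$length_m - 2 * margin_m >= ep_d, 3L, 0L)
  if (sum(capacity) < n_total + n_serious) {
    stop("network cannot host ", n_total + n_serious, " episodes (capacity ",
         sum(capacity), "); use fewer episodes or longer segments")
  }
  slots <- rep(seg$segment_id, capacity)
  pick <- sample(slots, n_total + n_serious)
  cls <- sample(rep(c("total", "serious"), c(n_total, n_serious)))
  out <- data.frame(segment_id = seg$segment_id, n_total = 0L, n_serious = 0L)
  for (i in seq_along(pick)) {
    row <- match(pick[i], out$segment_id)
    if (cls[i] == "total") out$n_total[row] <- out$n_total[row] + 1L
    else out$n_serious[row] <- out$n_serious[row] + 1L
  }
  out
}

.draw_jitter <- function(n, sd_m, max_m) {
  out <- matrix(0, n, 2)
  if (sd_m <= 0) return(out)
  for (i in seq_len(n)) {
    repeat {
      j <- stats::rnorm(2, 0, sd_m)
      if (sqrt(sum(j^2)) <= max_m) break
    }
    out[i, ] <- j
  }
  out
}

#' Simulate GPS trajectories with planted speeding episodes
#'
#' Emits GPS points along segment centerlines at a fixed sampling interval.
#' Each planned episode is one point pair whose true average speed is strictly
#' above the posted limit (serious episodes strictly above 1.2x the limit);
#' every other emitted pair travels strictly below the limit. Each episode is
#' driven by a dedicated vehicle whose trajectory stays on one segment, with a
#' leading/trailing below-limit point added when the segment is long enough,
#' so downstream extraction recovers exactly the planted per-segment event
#' counts. Recorded positions carry isotropic Gaussian jitter truncated at
#' `jitter_max_m` to exercise map matching; the planted speed fractions leave
#' margins wide relative to the jitter scale so classification is unaffected.
#'
#' @param network a `road_network`.
#' @param episode_plan data.frame `segment_id`, `n_total`, `n_serious` (see
#'   [plan_episodes()]).
#' @param sampling_interval_s GPS sampling interval in seconds (> 0).
#' @param seed integer RNG seed.
#' @param jitter_sd_m per-coordinate jitter standard deviation (m).
#' @param jitter_max_m truncation radius of the jitter (m).
#' @param cruise_frac,total_frac,serious_frac planted speeds as fractions of
#'   the posted limit for below-limit, total-speeding and serious-speeding
#'   pairs; must satisfy `cruise_frac < 1 < total_frac <= 1.2 < serious_frac`.
#' @param margin_m clearance from segment endpoints (m); must exceed the
#'   intersection-exclusion radius plus `jitter_max_m`.
#' @param background also emit below-limit-only trajectories on unplanned
#'   segments long enough to host them?
#' @param t0 start time (POSIXct, UTC).
#' @return list: `trajectories` (data.frame `vehicle_id`, `timestamp`, `lon`,
#'   `lat`), `planted` (data.frame `segment_id`, `y_total`, `y_serious`: the
#'   expected per-segment event counts, serious runs also counting toward the
#'   total class), and the `plan` used.
#' @export
simulate_trajectories <- function(network, episode_plan,
                                  sampling_interval_s = 10, seed = 1L,
                                  jitter_sd_m = 2, jitter_max_m = 20,
                                  cruise_frac = 0.75, total_frac = 1.10,
                                  serious_frac = 1.35, margin_m = 55,
                                  background = TRUE,
                                  t0 = as.POSIXct("2016-11-01 00:00:00",
                                                  tz = "UTC")) {
  validate_network(network)
  if (sampling_interval_s <= 0) stop("sampling_interval_s must be > 0")
  if (total_frac <= 1 || total_frac > 1.2 || serious_frac <= 1.2 ||
      cruise_frac >= 1) {
    stop("need cruise_frac < 1 < total_frac <= 1.2 < serious_frac")
  }
  set.seed(seed)
  seg <- network$segments
  origin <- network$origin
  rows <- list()
  veh <- 0L

  emit_vehicle <- function(poly_xy, start_m, dists, t_start) {
    pos <- start_m + cumsum(c(0, dists))
    xy <- polyline_point_at(poly_xy, pos)
    xy <- xy + .draw_jitter(nrow(xy), jitter_sd_m, jitter_max_m)
    ll <- unproject_xy(xy[, 1], xy[, 2], origin)
    veh <<- veh + 1L
    data.frame(
      vehicle_id = sprintf("veh%04d", veh),
      timestamp = t_start + seq(0, by = sampling_interval_s,
                                length.out = nrow(ll)),
      lon = ll[, 1], lat = ll[, 2]
    )
  }

  plan <- merge(data.frame(segment_id = seg$segment_id), episode_plan,
                all.x = TRUE)
  plan$n_total[is.na(plan$n_total)] <- 0L
  plan$n_serious[is.na(plan$n_serious)] <- 0L
  plan <- plan[order(plan$segment_id), ]

  for (i in seq_len(nrow(plan))) {
    s <- plan$segment_id[i]
    row <- match(s, seg$segment_id)
    limit <- seg$speed_limit_kmh[row]
    L <- seg$length_m[row]
    poly_xy <- project_lonlat(network$polylines[[row]][, 1],
                              network$polylines[[row]][, 2], origin)
    cruise_d <- cruise_frac * limit / 3.6 * sampling_interval_s
    window <- L - 2 * margin_m
    fracs <- c(rep(total_frac, plan$n_total[i]),
               rep(serious_frac, plan$n_serious[i]))
    for (f in fracs) {
      ep_d <- f * limit / 3.6 * sampling_interval_s
      if (window < ep_d) {
        stop("episode plan infeasible on segment ", s, ": a planted pair of ",
             round(ep_d, 1), " m exceeds the ", round(window, 1),
             " m intersection-free window")
      }
      dists <- ep_d
      if (window >= ep_d + cruise_d) dists <- c(cruise_d, dists)
      if (window >= ep_d + 2 * cruise_d) dists <- c(dists, cruise_d)
      rows[[length(rows) + 1L]] <- emit_vehicle(poly_xy, margin_m, dists,
                                                t0 + 3600 * veh)
    }
    if (length(fracs) == 0L && background && L > 2 * cruise_d) {
      dists <- rep(cruise_d, floor(L / cruise_d) - 1L)
      rows[[length(rows) + 1L]] <- emit_vehicle(poly_xy, 0, dists,
                                                t0 + 3600 * veh)
    }
  }

  planted <- data.frame(
    segment_id = plan$segment_id,
    y_total = plan$n_total + plan$n_serious,
    y_serious = plan$n_serious
  )
  list(trajectories = do.call(rbind, rows), planted = planted, plan = plan)
}
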