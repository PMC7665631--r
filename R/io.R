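#' Write trajectories to CSV
#'
#' Columns `vehicle_id`, `timestamp` (ISO-8601, UTC), `lon`, `lat`;
#' coordinates at full precision so a read-back is lossless.
#'
#' @param trajectories data.frame as produced by [simulate_trajectories()].
#' @param path output file.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  out <- data.frame(
    vehicle_id = trajectories$vehicle_id,
    timestamp = format(trajectories$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                       tz = "UTC"),
    lon = sprintf("%.12f", trajectories$lon),
    lat = sprintf("%.12f", trajectories$lat)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trajectories from CSV
#' @param path CSV file written by [write_trajectories_csv()] (or matching
#'   its schema).
#' @return data.frame `vehicle_id`, `timestamp` (POSIXct), `lon`, `lat`.
#' @export
read_trajectories_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = c(vehicle_id = "character"))
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ",
                            tz = "UTC")
  d
}

#' Write a road network as GeoJSON
#'
#' One LineString feature per segment carrying `segment_id`, `length_m`,
#' `speed_limit_kmh` and covariate properties, plus one Point feature per
#' intersection. The projection origin is stored as a foreign top-level
#' member so a read-back reconstructs the same planar frame. The adjacency
#' matrix travels separately (see [write_adjacency_csv()]).
#'
#' @param network a `road_network`.
#' @param path output file.
#' @export
write_network_geojson <- function(network, path) {
  feats <- lapply(seq_len(nrow(network$segments)), function(s) {
    props <- as.list(network$segments[s, c("segment_id", "length_m",
                                           "speed_limit_kmh")])
    if (!is.null(network$covariates)) {
      props <- c(props, as.list(network$covariates[s, ]))
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "LineString",
                         coordinates = unname(apply(network$polylines[[s]], 1,
                                                    as.numeric,
                                                    simplify = FALSE))))
  })
  ints <- lapply(seq_len(nrow(network$intersections)), function(i) {
    list(type = "Feature", properties = list(kind = "intersection"),
         geometry = list(type = "Point",
                         coordinates = as.numeric(network$intersections[i, ])))
  })
  gj <- list(type = "FeatureCollection", origin = network$origin,
             features = c(feats, ints))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a road network written by [write_network_geojson()]
#' @param path GeoJSON file.
#' @param adjacency optional adjacency matrix (e.g. from
#'   [read_adjacency_csv()]); identity adjacency of zeros when omitted.
#' @return a `road_network`.
#' @export
read_network_geojson <- function(path, adjacency = NULL) {
  gj <- jsonlite::read_json(path)
  lines <- Filter(function(f) f$geometry$type == "LineString", gj$features)
  pts <- Filter(function(f) f$geometry$type == "Point", gj$features)
  seg <- do.call(rbind, lapply(lines, function(f) {
    data.frame(segment_id = f$properties$segment_id,
               length_m = f$properties$length_m,
               speed_limit_kmh = f$properties$speed_limit_kmh)
  }))
  polylines <- lapply(lines, function(f) {
    do.call(rbind, lapply(f$geometry$coordinates, function(c) {
      cbind(lon = c[[1]], lat = c[[2]])
    }))
  })
  covnames <- covariate_names()
  has_cov <- all(covnames %in% names(lines[[1]]$properties))
  covariates <- if (has_cov) {
    as.data.frame(do.call(rbind, lapply(lines, function(f) {
      unlist(f$properties[covnames])
    })))
  } else NULL
  intersections <- if (length(pts)) {
    do.call(rbind, lapply(pts, function(f) {
      cbind(lon = f$geometry$coordinates[[1]], lat = f$geometry$coordinates[[2]])
    }))
  } else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("lon", "lat")))
  S <- nrow(seg)
  if (is.null(adjacency)) adjacency <- matrix(0L, S, S)
  structure(list(segments = cbind(seg, node_a = NA_integer_,
                                  node_b = NA_integer_),
                 polylines = polylines, adjacency = adjacency,
                 intersections = intersections,
                 origin = as.numeric(unlist(gj$origin)),
                 covariates = covariates),
            class = "road_network")
}

#' Write an adjacency matrix as a CSV edge list
#'
#' Rows `from,to` for each unordered adjacent pair (`from < to`); the header
#' comment row carries the vertex count so isolated vertices survive the
#' round trip.
#'
#' @param adjacency binary symmetric matrix.
#' @param path output file.
#' @export
write_adjacency_csv <- function(adjacency, path) {
  idx <- which(upper.tri(adjacency) & adjacency != 0, arr.ind = TRUE)
  con <- file(path, "w")
  writeLines(paste0("# n_vertices=", nrow(adjacency)), con)
  writeLines("from,to", con)
  if (nrow(idx)) {
    writeLines(paste(idx[, 1], idx[, 2], sep = ","), con)
  }
  close(con)
  invisible(path)
}

#' Read an adjacency edge list written by [write_adjacency_csv()]
#' @param path CSV file.
#' @return binary symmetric matrix.
#' @export
read_adjacency_csv <- function(path) {
  first <- readLines(path, n = 1)
  n <- as.integer(sub("# n_vertices=", "", first))
  d <- utils::read.csv(path, comment.char = "#")
  W <- matrix(0L, n, n)
  if (nrow(d)) {
    for (i in seq_len(nrow(d))) {
      W[d$from[i], d$to[i]] <- 1L
      W[d$to[i], d$from[i]] <- 1L
    }
  }
  W
}

#' Write ground truth as JSON
#' @param truth truth list (see [default_truth()]).
#' @param path output file.
#' @export
write_ground_truth_json <- function(truth, path) {
  if (!is.null(names(truth$beta))) truth$beta <- as.list(truth$beta)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read ground truth written by [write_ground_truth_json()]
#' @param path JSON file.
#' @return truth list.
#' @export
read_ground_truth_json <- function(path) {
  t <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(t$beta)) t$beta <- unlist(t$beta)
  t
}

#' Write per-segment counts CSV
#' @param counts data.frame `segment_id`, `y_total`, `y_serious`.
#' @param path output file.
#' @export
write_counts_csv <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-segment counts CSV
#' @param path CSV file.
#' @return data.frame.
#' @export
read_counts_csv <- function(path) {
  utils::read.csv(path)
}

#' Serialize model and prior specifications to a YAML block
#' @param spec a [model_spec()].
#' @param priors a [prior_spec()].
#' @param path output file.
#' @export
write_model_config <- function(spec, priors, path) {
  yaml::write_yaml(list(model = unclass(spec), priors = unclass(priors)), path)
  invisible(path)
}

#' Read a YAML model/prior configuration
#' @param path YAML file written by [write_model_config()].
#' @return list with `spec` and `priors` objects.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  spec <- model_spec(cfg$model$family, cfg$model$spatial, cfg$model$m,
                     isTRUE(cfg$model$shared_r))
  priors <- do.call(prior_spec, cfg$priors[setdiff(names(cfg$priors), NULL)])
  list(spec = spec, priors = priors)
}
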