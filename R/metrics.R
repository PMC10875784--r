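# --- local planar frame ----------------------------------------------------

# project lon/lat (deg) to km in an equirectangular frame about a reference
to_plane <- function(lon, lat, ref) {
  km_per_deg <- pi * EARTH_RADIUS_KM / 180
  cbind(x = (lon - ref[1]) * km_per_deg * cos(ref[2] * pi / 180),
        y = (lat - ref[2]) * km_per_deg)
}

# proper intersection of segments p1-p2 and q1-q2; returns c(u, v, x, y)
# (params along each segment, point) or NULL
seg_intersect <- function(p1, p2, q1, q2) {
  p1 <- unname(p1); p2 <- unname(p2); q1 <- unname(q1); q2 <- unname(q2)
  r <- p2 - p1
  s <- q2 - q1
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < 1e-15) return(NULL)  # parallel/collinear: no switch
  qp <- q1 - p1
  u <- (qp[1] * s[2] - qp[2] * s[1]) / denom
  v <- (qp[1] * r[2] - qp[2] * r[1]) / denom
  if (u < -1e-12 || u > 1 + 1e-12 || v < -1e-12 || v > 1 + 1e-12) return(NULL)
  c(u = u, v = v, x = p1[1] + u * r[1], y = p1[2] + u * r[2])
}

#' Median trajectory of an ensemble of tracks
#'
#' Intersection-switching median: follow one track until it crosses
#' another, then follow the other, and so on. Every vertex of the result
#' lies on some input track, and the result is bounded by the outermost
#' tracks. The walk starts on the track whose start point is nearest the
#' centroid of all start points; at an intersection the switch target is
#' the track crossed first in arc-length order along the current track,
#' ties broken by lowest track index. Intersections are computed exactly
#' in a local planar (km) frame.
#'
#' @param tracks list of data.frames with columns `lon`, `lat` (ordered
#'   in time); one element per agent.
#' @return object of class `median_trajectory`: data.frame with `lon`,
#'   `lat`, `track` (index of the contributing input track).
#' @export
median_trajectory <- function(tracks) {
  if (length(tracks) == 0) stop("median_trajectory() needs >= 1 track")
  starts <- t(vapply(tracks, function(d) c(d$lon[1], d$lat[1]), numeric(2)))
  ref <- c(mean(vapply(tracks, function(d) mean(d$lon), numeric(1))),
           mean(vapply(tracks, function(d) mean(d$lat), numeric(1))))
  P <- lapply(tracks, function(d) to_plane(d$lon, d$lat, ref))
  ctr <- colMeans(to_plane(starts[, 1], starts[, 2], ref))
  cur <- which.min(vapply(P, function(m) sum((m[1, ] - ctr)^2), numeric(1)))

  seg <- 1L           # current segment index on track `cur`
  u0 <- 0             # param position along that segment
  pos <- P[[cur]][1, ]
  out_xy <- list(pos)
  out_tr <- cur
  guard <- 10L * sum(vapply(P, nrow, integer(1)))

  while (guard > 0) {
    guard <- guard - 1L
    if (seg >= nrow(P[[cur]])) break
    a <- P[[cur]][seg, ]
    b <- P[[cur]][seg + 1L, ]
    best <- NULL
    for (j in seq_along(P)) {
      if (j == cur) next
      Q <- P[[j]]
      for (sq in seq_len(nrow(Q) - 1L)) {
        hit <- seg_intersect(a, b, Q[sq, ], Q[sq + 1L, ])
        if (is.null(hit)) next
        if (hit["u"] <= u0 + 1e-9) next  # behind/at current position
        if (is.null(best) || hit["u"] < best$u - 1e-12) {
          best <- list(u = hit["u"], j = j, sq = sq, v = hit["v"],
                       pt = c(hit["x"], hit["y"]))
        }
      }
    }
    if (is.null(best)) {
      out_xy[[length(out_xy) + 1L]] <- b
      out_tr <- c(out_tr, cur)
      seg <- seg + 1L
      u0 <- 0
    } else {
      out_xy[[length(out_xy) + 1L]] <- best$pt
      out_tr <- c(out_tr, best$j)
      cur <- best$j
      seg <- best$sq
      u0 <- best$v
    }
  }
  xy <- do.call(rbind, out_xy)
  km_per_deg <- pi * EARTH_RADIUS_KM / 180
  res <- data.frame(
    lon = ref[1] + xy[, 1] / (km_per_deg * cos(ref[2] * pi / 180)),
    lat = ref[2] + xy[, 2] / km_per_deg,
    track = out_tr
  )
  class(res) <- c("median_trajectory", "data.frame")
  res
}

#' Extract per-agent tracks from a trajectory set
#' @param ts a `trajectory_set`.
#' @return list of data.frames (t, lon, lat), one per agent id.
#' @export
agent_tracks <- function(ts) {
  lapply(split(ts$data, ts$data$id), function(d) {
    d[order(d$t), c("t", "lon", "lat")]
  })
}

#' Spatial spread region of an ensemble
#'
#' Bins all recorded positions on a lon/lat grid and normalizes to
#' relative frequencies; the region is the set of bins whose frequency
#' meets the threshold.
#'
#' @param ensemble a `trajectory_ensemble` (or list of trajectory sets).
#' @param bin_size bin edge length, degrees (default 0.25).
#' @param threshold per-bin relative-frequency threshold (default 0.05).
#' @return object of class `spread_region`: list with `bins` (data.frame
#'   lon, lat, freq, included), `bin_size`, `threshold`.
#' @export
spread_region <- function(ensemble, bin_size = 0.25, threshold = 0.05) {
  stopifnot(bin_size > 0)
  lon <- unlist(lapply(ensemble, function(ts) ts$data$lon))
  lat <- unlist(lapply(ensemble, function(ts) ts$data$lat))
  bl <- floor(lon / bin_size)
  bb <- floor(lat / bin_size)
  key <- paste(bl, bb)
  tab <- table(key)
  freq <- as.numeric(tab) / length(key)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  bins <- data.frame(
    lon = (as.numeric(parts[, 1]) + 0.5) * bin_size,
    lat = (as.numeric(parts[, 2]) + 0.5) * bin_size,
    freq = freq,
    included = freq >= threshold
  )
  structure(list(bins = bins, bin_size = bin_size, threshold = threshold),
            class = "spread_region")
}

# shared time axis of an ensemble (stamps are shared across repeats)
ensemble_times <- function(ensemble) sort(unique(ensemble[[1]]$data$t))

# across-repeat sd; a single repeat has zero spread by convention
repeat_sd <- function(x) if (sum(!is.na(x)) < 2) 0 else stats::sd(x, na.rm = TRUE)

#' Arrivals over time
#'
#' Number of whales that have reached the target by each time point:
#' initial count minus the mean number remaining, with the
#' across-repeat standard deviation.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @return data.frame with `t`, `mean`, `sd` and one `repeat_k` column
#'   per realisation.
#' @export
arrivals_over_time <- function(ensemble) {
  times <- ensemble_times(ensemble)
  per <- vapply(ensemble, function(ts) {
    vapply(times, function(tt) {
      sum(ts$data$arrived[ts$data$t == tt])
    }, numeric(1))
  }, numeric(length(times)))
  per <- matrix(per, nrow = length(times))
  data.frame(t = times, mean = rowMeans(per),
             sd = apply(per, 1, repeat_sd),
             per_repeat = I(per))
}

#' Mean distance from population centre to target
#'
#' Per repeat and time point, the centroid of the still-migrating
#' (non-arrived) whales and its great-circle distance to the target;
#' when no whales remain the last value is carried forward. Averaged
#' across repeats with standard deviation.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param target `c(lon, lat)`; defaults to the first repeat's config.
#' @return data.frame with `t`, `mean`, `sd`, `per_repeat`.
#' @export
mean_distance_to_target <- function(ensemble,
                                    target = ensemble[[1]]$config$target) {
  times <- ensemble_times(ensemble)
  per <- vapply(ensemble, function(ts) {
    d <- ts$data
    out <- numeric(length(times))
    last <- NA_real_
    for (k in seq_along(times)) {
      rows <- d[d$t == times[k] & !d$arrived, ]
      if (nrow(rows) > 0) {
        last <- haversine_km(mean(rows$lon), mean(rows$lat),
                             target[1], target[2])
      }
      out[k] <- last
    }
    out
  }, numeric(length(times)))
  per <- matrix(per, nrow = length(times))
  data.frame(t = times, mean = rowMeans(per),
             sd = apply(per, 1, repeat_sd),
             per_repeat = I(per))
}

#' Mean number of detected conspecifics per simulation day
#'
#' For each simulation day, the mean of the per-step detectable counts
#' over all live (non-arrived) whales and all steps of that day, then
#' averaged across repeats.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @return data.frame with `day` (1-based), `mean`, `sd`.
#' @export
mean_detected_whales <- function(ensemble) {
  days <- sort(unique(floor(ensemble_times(ensemble) / 24)))
  per <- vapply(ensemble, function(ts) {
    d <- ts$data[!ts$data$arrived, ]
    vapply(days, function(dd) {
      rows <- d$n_detected[floor(d$t / 24) == dd]
      if (length(rows) == 0) NA_real_ else mean(rows)
    }, numeric(1))
  }, numeric(length(days)))
  per <- matrix(per, nrow = length(days))
  data.frame(day = days + 1L, mean = rowMeans(per, na.rm = TRUE),
             sd = apply(per, 1, repeat_sd))
}

#' Write ensemble metrics to JSON
#'
#' Emits arrivals, mean distance to target and daily detected-whale
#' series (mean and sd arrays) for downstream plotting.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param path output JSON file.
#' @export
write_metrics_json <- function(ensemble, path) {
  arr <- arrivals_over_time(ensemble)
  dist <- mean_distance_to_target(ensemble)
  det <- mean_detected_whales(ensemble)
  jsonlite::write_json(
    list(
      arrivals = list(t = arr$t, mean = arr$mean, sd = arr$sd),
      distance_to_target_km = list(t = dist$t, mean = dist$mean,
                                   sd = dist$sd),
      detected_whales = list(day = det$day, mean = det$mean, sd = det$sd)
    ),
    path, digits = NA
  )
  invisible(path)
}
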