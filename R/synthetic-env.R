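#' Generate a synthetic sea
#'
#' Builds consistent idealized environmental layers (bathymetry-derived
#' land, wind noise floor, optional uniform current) standing in for
#' real gridded ocean products. Four canned geographies:
#'
#' * `"open"` — uniformly deep open water.
#' * `"island"` — deep water with one conical island (land-avoidance
#'   exercises); depth rises linearly to above sea level inside the
#'   island radius.
#' * `"strait"` — an east-west land wall pierced by one channel; the
#'   channel floor is deepest on its centreline.
#' * `"basin"` — radially symmetric basin, deepest at the centre
#'   (analytic gradient checks).
#'
#' @param kind geography name.
#' @param lon_range,lat_range domain extents, degrees.
#' @param resolution grid spacing, degrees (default 0.25).
#' @param depth_deep open-water depth, m (default 100).
#' @param wind_level wind noise floor, dB (default 60: quiet enough that
#'   the minimum received level, not masking, caps communication range).
#' @param current `NULL`, or `c(u_east, v_north)` km/h applied uniformly.
#' @param island_centre,island_radius_deg island geometry (`"island"`).
#' @param wall_lat,wall_halfwidth_deg wall centre latitude and half
#'   thickness (`"strait"`).
#' @param gap_lon,gap_halfwidth_deg channel centre longitude and half
#'   width (`"strait"`).
#' @param basin_centre basin centre (`"basin"`).
#' @param times time axis for the time-varying layers, hours.
#' @return a [whale_env]; its `noise` layer is the wind floor (combine
#'   with sources via [render_noise_map()]).
#' @export
make_synthetic_sea <- function(kind = c("open", "island", "strait", "basin"),
                               lon_range = c(0, 9), lat_range = c(51.5, 59.5),
                               resolution = 0.25,
                               depth_deep = 100, wind_level = 60,
                               current = NULL,
                               island_centre = NULL, island_radius_deg = 0.75,
                               wall_lat = NULL, wall_halfwidth_deg = 0.25,
                               gap_lon = NULL, gap_halfwidth_deg = 0.5,
                               basin_centre = NULL,
                               times = 0) {
  kind <- match.arg(kind)
  if (diff(lon_range) <= 0 || diff(lat_range) <= 0) {
    stop("inconsistent extents: ranges must be increasing")
  }
  lon <- seq(lon_range[1], lon_range[2], by = resolution)
  lat <- seq(lat_range[1], lat_range[2], by = resolution)
  lonm <- matrix(lon, length(lat), length(lon), byrow = TRUE)
  latm <- matrix(lat, length(lat), length(lon))

  depth <- switch(
    kind,
    open = matrix(depth_deep, length(lat), length(lon)),
    island = {
      ic <- if (is.null(island_centre)) c(mean(lon_range), mean(lat_range))
      else island_centre
      r <- sqrt(((lonm - ic[1]) * cos(ic[2] * pi / 180))^2 +
                  (latm - ic[2])^2)
      # linear cone: negative (land) inside the radius, depth_deep at 2x
      pmin(depth_deep, depth_deep * (r - island_radius_deg) /
             island_radius_deg)
    },
    strait = {
      wl <- if (is.null(wall_lat)) mean(lat_range) else wall_lat
      gl <- if (is.null(gap_lon)) mean(lon_range) else gap_lon
      d <- matrix(depth_deep, length(lat), length(lon))
      in_wall <- abs(latm - wl) <= wall_halfwidth_deg
      # channel: deepest on the centreline, shoaling to 0 at its edges
      chan <- depth_deep * (1 - abs(lonm - gl) / gap_halfwidth_deg)
      d[in_wall] <- pmax(chan[in_wall], -10)
      d
    },
    basin = {
      bc <- if (is.null(basin_centre)) c(mean(lon_range), mean(lat_range))
      else basin_centre
      r <- sqrt(((lonm - bc[1]) * cos(bc[2] * pi / 180))^2 +
                  (latm - bc[2])^2)
      rmax <- max(r)
      depth_deep * (1.5 - r / rmax)  # deepest at centre, never land
    }
  )

  depth_field <- grid_field(lon, lat, 0,
                            array(depth, c(1, length(lat), length(lon))),
                            units = "m")
  wind <- constant_field(wind_level, lon, lat, times = times, units = "dB")
  cur <- NULL
  if (!is.null(current)) {
    vals <- array(NA_real_, c(length(times), length(lat), length(lon), 2))
    vals[, , , 1] <- current[1]
    vals[, , , 2] <- current[2]
    cur <- grid_field(lon, lat, times, vals, units = "km/h")
  }
  whale_env(noise = wind, depth = depth_field, current = cur)
}
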