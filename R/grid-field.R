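#' Time-gridded environmental field
#'
#' A `grid_field` holds a scalar or 2-vector layer (ambient noise in dB,
#' depth in m, current velocity in km/h east/north) on a regular lon/lat
#' grid with one or more time slices. Static layers (bathymetry) carry a
#' single time slice.
#'
#' @param lon strictly increasing longitudes, degrees, length >= 2.
#' @param lat strictly increasing latitudes, degrees, length >= 2.
#' @param times strictly increasing times, hours since simulation start;
#'   a single value for static fields.
#' @param values numeric array. Scalar fields: dim (time, lat, lon).
#'   Vector fields: dim (time, lat, lon, 2) with components (east, north).
#' @param units unit tag, e.g. "dB", "m", "km/h".
#' @return object of class `grid_field`.
#' @export
grid_field <- function(lon, lat, times, values, units = "") {
  check_axis(lon, -180, 180, "lon")
  check_axis(lat, -90, 90, "lat")
  if (length(times) < 1 || is.unsorted(times, strictly = TRUE)) {
    stop("times must be non-empty and strictly increasing")
  }
  vector_field <- length(dim(values)) == 4
  expected <- c(length(times), length(lat), length(lon))
  if (vector_field) expected <- c(expected, 2L)
  if (!identical(as.integer(dim(values)), as.integer(expected))) {
    stop(sprintf(
      "values dim must be (%s); got (%s)",
      paste(expected, collapse = ", "),
      paste(dim(values), collapse = ", ")
    ))
  }
  if (anyNA(values)) stop("values must not contain NA")
  structure(
    list(lon = as.numeric(lon), lat = as.numeric(lat),
         times = as.numeric(times), values = values,
         units = units, vector = vector_field),
    class = "grid_field"
  )
}

check_axis <- function(x, lo, hi, name) {
  if (length(x) < 2) stop(name, " axis needs length >= 2")
  if (is.unsorted(x, strictly = TRUE)) stop(name, " axis must be strictly increasing")
  if (any(x < lo | x > hi)) stop(name, " axis outside [", lo, ", ", hi, "]")
  invisible(TRUE)
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf(
    "<grid_field %s> %d x %d grid, %d time slice(s), lon [%g, %g], lat [%g, %g] [%s]\n",
    if (x$vector) "vector" else "scalar",
    length(x$lat), length(x$lon), length(x$times),
    min(x$lon), max(x$lon), min(x$lat), max(x$lat), x$units
  ))
  invisible(x)
}

#' Uniform constant field helper
#' @param value scalar value everywhere.
#' @inheritParams grid_field
#' @export
constant_field <- function(value, lon, lat, times = 0, units = "") {
  grid_field(lon, lat, times,
             array(value, c(length(times), length(lat), length(lon))),
             units = units)
}

# fractional index of q on axis ax; error outside with coordinate name
axis_locate <- function(ax, q, name) {
  if (q < ax[1] || q > ax[length(ax)]) {
    stop(sprintf("position outside grid: %s = %g not in [%g, %g]",
                 name, q, ax[1], ax[length(ax)]))
  }
  i <- findInterval(q, ax, rightmost.closed = TRUE)
  i <- min(i, length(ax) - 1L)
  frac <- (q - ax[i]) / (ax[i + 1L] - ax[i])
  list(i = i, frac = frac)
}

#' Interpolate a field at a position and time
#'
#' Bilinear in space, linear in time between the bracketing slices;
#' vector fields are interpolated componentwise. Times outside the field's
#' range are clamped to the nearest slice with a warning.
#'
#' @param field a [grid_field].
#' @param lon,lat query position, degrees (must lie inside the grid).
#' @param t query time, hours.
#' @param warn_clamp warn when t falls outside the time range.
#' @return scalar, or length-2 vector (east, north) for vector fields.
#' @export
interpolate_field <- function(field, lon, lat, t = 0, warn_clamp = TRUE) {
  lo <- axis_locate(field$lon, lon, "lon")
  la <- axis_locate(field$lat, lat, "lat")
  tm <- field$times
  nt <- length(tm)
  if (nt == 1L || t <= tm[1]) {
    if (warn_clamp && t < tm[1]) {
      warning(sprintf("time %g before field range; clamped to %g", t, tm[1]))
    }
    ti <- 1L; tf <- 0
  } else if (t >= tm[nt]) {
    if (warn_clamp && t > tm[nt]) {
      warning(sprintf("time %g after field range; clamped to %g", t, tm[nt]))
    }
    ti <- nt - 1L; tf <- 1
  } else {
    ti <- findInterval(t, tm)
    tf <- (t - tm[ti]) / (tm[ti + 1L] - tm[ti])
  }

  comp <- function(k) {
    slice <- function(it) {
      v <- if (is.na(k)) {
        field$values[it, la$i + c(0L, 1L), lo$i + c(0L, 1L)]
      } else {
        field$values[it, la$i + c(0L, 1L), lo$i + c(0L, 1L), k]
      }
      dim(v) <- c(2L, 2L)  # (lat, lon)
      v00 <- v[1, 1]; v01 <- v[1, 2]; v10 <- v[2, 1]; v11 <- v[2, 2]
      (1 - la$frac) * ((1 - lo$frac) * v00 + lo$frac * v01) +
        la$frac * ((1 - lo$frac) * v10 + lo$frac * v11)
    }
    a <- slice(ti)
    if (tf == 0) a else (1 - tf) * a + tf * slice(ti + 1L)
  }
  if (field$vector) c(comp(1L), comp(2L)) else comp(NA_integer_)
}

# central-difference spatial gradient of a scalar field, per km,
# evaluated at native grid spacing; offsets clamped to the grid interior.
field_gradient <- function(field, lon, lat, t = 0) {
  dlon <- mean(diff(field$lon))
  dlat <- mean(diff(field$lat))
  km_per_deg <- pi * EARTH_RADIUS_KM / 180
  lon_m <- max(lon - dlon, field$lon[1])
  lon_p <- min(lon + dlon, field$lon[length(field$lon)])
  lat_m <- max(lat - dlat, field$lat[1])
  lat_p <- min(lat + dlat, field$lat[length(field$lat)])
  fe <- interpolate_field(field, lon_p, lat, t, warn_clamp = FALSE)
  fw <- interpolate_field(field, lon_m, lat, t, warn_clamp = FALSE)
  fn <- interpolate_field(field, lon, lat_p, t, warn_clamp = FALSE)
  fs <- interpolate_field(field, lon, lat_m, t, warn_clamp = FALSE)
  dx_km <- (lon_p - lon_m) * km_per_deg * cos(lat * pi / 180)
  dy_km <- (lat_p - lat_m) * km_per_deg
  c(east = (fe - fw) / dx_km, north = (fn - fs) / dy_km)
}

# tolerance defining a "flat" gradient, field units per km
GRADIENT_TOL <- 1e-9

#' Direction of deepest water (bathotaxis)
#'
#' Heading of steepest increase of the depth surface at a position, from
#' central finite differences of the interpolated field. Returns `NULL`
#' when the bathymetry is locally flat.
#'
#' @param depth a [grid_field] of water depth in m (positive = water).
#' @param lon,lat query position, degrees.
#' @return heading (radians CCW from east), or `NULL` if flat.
#' @export
deepest_water_direction <- function(depth, lon, lat) {
  g <- field_gradient(depth, lon, lat)
  if (sqrt(sum(g^2)) < GRADIENT_TOL) return(NULL)
  wrap_angle(atan2(g["north"], g["east"]))
}

#' Direction of steepest noise decrease (negative phonotaxis)
#'
#' Heading pointing down the ambient-noise gradient at a position and
#' time. Returns `NULL` when the noise field is locally uniform.
#'
#' @param noise a [grid_field] of noise levels in dB.
#' @param lon,lat query position, degrees.
#' @param t query time, hours.
#' @return heading (radians CCW from east), or `NULL` if flat.
#' @export
noise_descent_direction <- function(noise, lon, lat, t = 0) {
  g <- field_gradient(noise, lon, lat, t)
  if (sqrt(sum(g^2)) < GRADIENT_TOL) return(NULL)
  wrap_angle(atan2(-g["north"], -g["east"]))
}

#' Land test from bathymetry
#'
#' A position counts as land when the nearest grid cell of the depth layer
#' has depth <= 0 m. Nearest-cell semantics (rather than interpolation)
#' keep the coastline crisp for the move-abort failsafe.
#'
#' @param depth a [grid_field] of water depth in m.
#' @param lon,lat position, degrees.
#' @return logical.
#' @export
is_land <- function(depth, lon, lat) {
  i <- which.min(abs(depth$lat - lat))
  j <- which.min(abs(depth$lon - lon))
  depth$values[1L, i, j] <= 0
}

#' Write a field to long-form CSV
#'
#' Plain-text interchange format: columns `t_hours, lat, lon, value` for
#' scalar fields or `t_hours, lat, lon, u_east, v_north` for vector
#' fields, one row per node per time slice.
#'
#' @param field a [grid_field].
#' @param path output file.
#' @export
write_grid_csv <- function(field, path) {
  g <- expand.grid(lon = field$lon, lat = field$lat, t_hours = field$times,
                   KEEP.OUT.ATTRS = FALSE)
  # values array is (time, lat, lon[, comp]); expand.grid varies lon fastest
  perm <- if (field$vector) aperm(field$values, c(3, 2, 1, 4)) else
    aperm(field$values, c(3, 2, 1))
  if (field$vector) {
    df <- data.frame(t_hours = g$t_hours, lat = g$lat, lon = g$lon,
                     u_east = as.vector(perm[, , , 1]),
                     v_north = as.vector(perm[, , , 2]))
  } else {
    df <- data.frame(t_hours = g$t_hours, lat = g$lat, lon = g$lon,
                     value = as.vector(perm))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a field from long-form CSV
#'
#' Inverse of [write_grid_csv()]. The grid is reconstructed from the
#' unique sorted coordinates; every (t, lat, lon) combination must be
#' present exactly once.
#'
#' @param path CSV file written by [write_grid_csv()].
#' @param units unit tag to attach.
#' @return a [grid_field].
#' @export
read_grid_csv <- function(path, units = "") {
  df <- utils::read.csv(path)
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  times <- sort(unique(df$t_hours))
  vector_field <- "u_east" %in% names(df)
  n <- c(length(times), length(lat), length(lon))
  if (nrow(df) != prod(n)) stop("incomplete grid in ", path)
  o <- order(df$t_hours, df$lat, df$lon)
  if (vector_field) {
    vals <- array(NA_real_, c(n, 2L))
    vals[, , , 1] <- aperm(array(df$u_east[o], c(n[3], n[2], n[1])), c(3, 2, 1))
    vals[, , , 2] <- aperm(array(df$v_north[o], c(n[3], n[2], n[1])), c(3, 2, 1))
  } else {
    vals <- aperm(array(df$value[o], c(n[3], n[2], n[1])), c(3, 2, 1))
  }
  grid_field(lon, lat, times, vals, units = units)
}
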