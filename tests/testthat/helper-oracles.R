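# Independent oracles: implemented from first principles, deliberately not
# sharing code paths with the package internals they check.

# initial great-circle bearing via 3-D tangent vectors (radians CCW from
# east, matching the package convention)
oracle_bearing <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  l1 <- lon1 * to_rad; p1 <- lat1 * to_rad
  l2 <- lon2 * to_rad; p2 <- lat2 * to_rad
  a <- cbind(cos(p1) * cos(l1), cos(p1) * sin(l1), sin(p1))
  b <- cbind(cos(p2) * cos(l2), cos(p2) * sin(l2), sin(p2))
  dotab <- rowSums(a * b)
  tvec <- b - dotab * a                       # tangent at a toward b
  east <- cbind(-sin(l1), cos(l1), 0)
  north <- cbind(-sin(p1) * cos(l1), -sin(p1) * sin(l1), cos(p1))
  atan2(rowSums(tvec * north), rowSums(tvec * east))
}

# great-circle distance via the spherical law of cosines (km)
oracle_distance_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  p1 <- lat1 * to_rad; p2 <- lat2 * to_rad
  dl <- (lon2 - lon1) * to_rad
  cosc <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  6371 * acos(pmin(1, pmax(-1, cosc)))
}

# Rayleigh test p-value (large-sample approximation) for circular
# uniformity of a sample of angles
rayleigh_p <- function(theta) {
  n <- length(theta)
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  z <- n * rbar^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# circular mean of a sample
circ_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

# absolute angular difference on the circle
ang_diff <- function(a, b) abs(whalenav::wrap_angle(a - b))

# small quiet open-sea fixture shared across simulator tests
quiet_env <- function(...) make_synthetic_sea("open", ...)

# compact scenario for fast runs; any field can be overridden
quick_config <- function(...) {
  defaults <- list(n_whales = 5, start_box = c(4.5, 5.5, 53, 54),
                   target = c(5, 56.75), duration_h = 24, dt = 0.25,
                   n_repeats = 2)
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}

# does point p lie on segment a-b (planar lon/lat, tolerance in degrees)?
point_on_segment <- function(p, a, b, tol = 1e-8) {
  ab <- b - a
  ap <- p - a
  cross <- ab[1] * ap[2] - ab[2] * ap[1]
  if (abs(cross) > tol) return(FALSE)
  dot <- sum(ap * ab)
  dot >= -tol && dot <= sum(ab^2) + tol
}
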