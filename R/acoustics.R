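#' Acoustic parameters
#'
#' Source level, spreading loss coefficient and the two detection
#' thresholds. Defaults follow median estimates for minke whale pulse
#' trains: calls at 178 dB re 1 uPa at 1 m, a spreading coefficient of
#' 17.8 (between cylindrical 10 and spherical 20), a minimum
#' signal-to-noise ratio of -5 dB, and a minimum received level of 88 dB,
#' which together yield a pristine communication range of ~114 km.
#'
#' @param source_level call source level, dB re 1 uPa at 1 m.
#' @param gamma spreading coefficient, in [10, 20].
#' @param snr_min minimum detectable signal-to-noise ratio, dB.
#' @param rl_min minimum detectable received level, dB.
#' @param enabled if `FALSE`, conspecific detection is switched off
#'   entirely (solitary-navigation control).
#' @return object of class `acoustic_params`.
#' @export
acoustic_params <- function(source_level = 178, gamma = 17.8,
                            snr_min = -5, rl_min = 88, enabled = TRUE) {
  if (gamma < 10 || gamma > 20) stop("gamma must lie in [10, 20]")
  if (source_level <= rl_min) stop("source_level must exceed rl_min")
  structure(list(source_level = source_level, gamma = gamma,
                 snr_min = snr_min, rl_min = rl_min, enabled = enabled),
            class = "acoustic_params")
}

#' Received level after spreading loss
#'
#' RL = SL - gamma * log10(r), with r in metres. Ranges below the 1 m
#' reference distance clamp to 1 m (the source level is referenced to
#' 1 m, and the loss term diverges as r -> 0).
#'
#' @param source_level source level, dB re 1 uPa at 1 m.
#' @param r_m range in metres; vectorized.
#' @param gamma spreading coefficient.
#' @return received level, dB.
#' @export
received_level <- function(source_level, r_m, gamma = 17.8) {
  source_level - gamma * log10(pmax(r_m, 1))
}

#' Is a call detectable at a receiver?
#'
#' Detection requires both SNR = RL - N >= snr_min and RL >= rl_min
#' (both inclusive), where N is the ambient noise at the receiver.
#'
#' @param source_level caller source level, dB.
#' @param r_m caller-receiver range, metres.
#' @param noise_receiver ambient noise at the receiver, dB.
#' @param params an [acoustic_params].
#' @return logical; vectorized over `r_m` and `noise_receiver`.
#' @export
is_detectable <- function(source_level, r_m, noise_receiver, params) {
  rl <- received_level(source_level, r_m, params$gamma)
  (rl - noise_receiver >= params$snr_min) & (rl >= params$rl_min)
}

#' Detection range of a call in given ambient noise
#'
#' Solves the detection condition for range: the binding threshold is
#' max(N + snr_min, rl_min), so in quiet conditions the minimum received
#' level caps the range (the "pristine plateau") and in loud conditions
#' masking shrinks it. Floored at 1 m.
#'
#' @param noise ambient noise at the receiver, dB; vectorized.
#' @param params an [acoustic_params].
#' @return range in km.
#' @export
detection_range <- function(noise, params = acoustic_params()) {
  thresh <- pmax(noise + params$snr_min, params$rl_min)
  r_m <- 10^((params$source_level - thresh) / params$gamma)
  pmax(r_m, 1) / 1000
}

#' Incoherent combination of sound levels
#'
#' Power-sums decibel levels: 10 log10 sum(10^(L/10)).
#'
#' @param levels non-empty numeric vector of dB levels.
#' @return combined level, dB.
#' @export
combine_levels <- function(levels) {
  if (length(levels) == 0) stop("combine_levels() needs a non-empty list of levels")
  10 * log10(sum(10^(levels / 10)))
}

#' An acoustic noise source
#'
#' Fixed sources (e.g. pile driving) sit at one position; mobile sources
#' (vessels) move piecewise-linearly in lon/lat between time-stamped
#' waypoints. Activity is a daily schedule of active-hour windows; a
#' source outside its active window contributes nothing to the
#' soundscape.
#'
#' @param kind "fixed" or "mobile".
#' @param source_level dB re 1 uPa at 1 m.
#' @param lon,lat position (fixed) or waypoint coordinates (mobile).
#' @param times waypoint times in hours (mobile only), strictly
#'   increasing, same length as lon/lat. Mobile sources hold their first/
#'   last waypoint outside the time range.
#' @param active_hours numeric `c(start, end)` hours-of-day in [0, 24];
#'   `NULL` means always active. A source is active when
#'   start <= (t mod 24) < end.
#' @param level_reduction dB subtracted from the source level (e.g. a
#'   slowdown-zone mitigation); default 0.
#' @return object of class `noise_source`.
#' @export
noise_source <- function(kind = c("fixed", "mobile"), source_level,
                         lon, lat, times = NULL, active_hours = NULL,
                         level_reduction = 0) {
  kind <- match.arg(kind)
  if (kind == "mobile") {
    if (is.null(times) || length(times) != length(lon)) {
      stop("mobile sources need waypoint times matching lon/lat")
    }
    if (is.unsorted(times, strictly = TRUE)) {
      stop("waypoint times must be strictly increasing")
    }
  } else if (length(lon) != 1L) {
    stop("fixed sources have a single position")
  }
  if (!is.null(active_hours)) {
    if (length(active_hours) != 2L || any(active_hours < 0 | active_hours > 24)) {
      stop("active_hours must be c(start, end) within [0, 24]")
    }
  }
  structure(list(kind = kind, source_level = source_level,
                 lon = lon, lat = lat, times = times,
                 active_hours = active_hours,
                 level_reduction = level_reduction),
            class = "noise_source")
}

source_is_active <- function(src, t) {
  if (is.null(src$active_hours)) return(TRUE)
  h <- t %% 24
  h >= src$active_hours[1] && h < src$active_hours[2]
}

source_position <- function(src, t) {
  if (src$kind == "fixed") return(c(src$lon, src$lat))
  tm <- src$times
  n <- length(tm)
  if (t <= tm[1]) return(c(src$lon[1], src$lat[1]))
  if (t >= tm[n]) return(c(src$lon[n], src$lat[n]))
  i <- findInterval(t, tm)
  f <- (t - tm[i]) / (tm[i + 1] - tm[i])
  c(src$lon[i] + f * (src$lon[i + 1] - src$lon[i]),
    src$lat[i] + f * (src$lat[i + 1] - src$lat[i]))
}

#' Render a synthetic ambient-noise map
#'
#' At every grid node and time slice, incoherently combines the wind
#' noise floor with the received level from each source active at that
#' time (mobile source positions interpolated along their waypoints),
#' using the spreading-loss model of [received_level()].
#'
#' @param sources list of [noise_source] objects (may be empty).
#' @param wind_floor a scalar [grid_field], the wind noise floor in dB.
#' @param times time slices (hours) at which to render; defaults to the
#'   wind floor's own time axis.
#' @param gamma spreading coefficient.
#' @param slowdown_zone optional `c(lon_min, lon_max, lat_min, lat_max)`
#'   box; mobile sources inside it have their level reduced by
#'   `slowdown_db` (vessel slowdown mitigation).
#' @param slowdown_db level reduction inside the zone, dB (default 10).
#' @return a scalar [grid_field] of ambient noise in dB.
#' @export
render_noise_map <- function(sources, wind_floor, times = wind_floor$times,
                             gamma = 17.8, slowdown_zone = NULL,
                             slowdown_db = 10) {
  lon <- wind_floor$lon; lat <- wind_floor$lat
  nlon <- length(lon); nlat <- length(lat); nt <- length(times)
  vals <- array(NA_real_, c(nt, nlat, nlon))
  lonm <- matrix(lon, nlat, nlon, byrow = TRUE)
  latm <- matrix(lat, nlat, nlon)
  for (it in seq_len(nt)) {
    t <- times[it]
    wind <- vapply(seq_len(nlat), function(i) {
      vapply(seq_len(nlon), function(j) {
        interpolate_field(wind_floor, lon[j], lat[i], t, warn_clamp = FALSE)
      }, numeric(1))
    }, numeric(nlon))  # (lon, lat)
    power <- 10^(t(wind) / 10)  # (lat, lon)
    for (src in sources) {
      if (!source_is_active(src, t)) next
      p <- source_position(src, t)
      sl <- src$source_level - src$level_reduction
      if (!is.null(slowdown_zone) && src$kind == "mobile" &&
          p[1] >= slowdown_zone[1] && p[1] <= slowdown_zone[2] &&
          p[2] >= slowdown_zone[3] && p[2] <= slowdown_zone[4]) {
        sl <- sl - slowdown_db
      }
      r_m <- haversine_km(lonm, latm, p[1], p[2]) * 1000
      rl <- received_level(sl, r_m, gamma)
      power <- power + 10^(rl / 10)
    }
    vals[it, , ] <- 10 * log10(power)
  }
  grid_field(lon, lat, times, vals, units = "dB")
}
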