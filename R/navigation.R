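#' Core navigation parameters
#'
#' @param kappa_base baseline inherent-information concentration
#'   (default 1: enough to navigate alone, with clear room for a
#'   collective boost).
#' @param alpha weight on own heading when fusing mean directions.
#' @param beta weight on own heading when fusing concentrations.
#' @param speed swimming speed, km/h (default 6).
#' @param lambda reorientation rate, events per hour (default 1).
#' @return object of class `nav_params`.
#' @export
nav_params <- function(kappa_base = 1, alpha = 0.5, beta = 0.5,
                       speed = 6, lambda = 1) {
  stopifnot(kappa_base >= 0, alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            speed >= 0, lambda > 0)
  structure(list(kappa_base = kappa_base, alpha = alpha, beta = beta,
                 speed = speed, lambda = lambda), class = "nav_params")
}

#' Noise-avoidance response parameters
#'
#' @param n_threshold noise level of equal weighting between avoidance
#'   and migration, dB (scenario-dependent: 120, 115, 110 or 105).
#' @param n_s transition scale, dB. Not printed in the source material's
#'   main text; the default 5 dB gives near-step behaviour over about
#'   +/- 10 dB around the threshold.
#' @return object of class `noise_response_params`.
#' @export
noise_response_params <- function(n_threshold = 120, n_s = 5) {
  stopifnot(n_s > 0)
  structure(list(n_threshold = n_threshold, n_s = n_s),
            class = "noise_response_params")
}

#' Land-avoidance response parameters
#'
#' @param d_threshold depth of equal weighting between land avoidance
#'   and migration, m (default 30).
#' @param slope sigmoid slope, 1/m (0.5, as printed).
#' @return object of class `land_response_params`.
#' @export
land_response_params <- function(d_threshold = 30, slope = 0.5) {
  stopifnot(d_threshold > 0)
  structure(list(d_threshold = d_threshold, slope = slope),
            class = "land_response_params")
}

#' Noise-dependent information-loss parameters
#'
#' @param enabled whether inherent information degrades with noise;
#'   when `FALSE` the concentration stays at its baseline.
#' @param kappa_min residual concentration at extreme noise (default 0).
#' @param n_il noise level at which half of the losable inherent
#'   information is lost, dB (110 or 100 in the loss scenarios).
#' @param slope tanh slope, 1/dB (0.1, as printed; deliberately gentler
#'   than the avoidance sigmoids).
#' @return object of class `info_loss_params`.
#' @export
info_loss_params <- function(enabled = FALSE, kappa_min = 0, n_il = 110,
                             slope = 0.1) {
  stopifnot(kappa_min >= 0)
  structure(list(enabled = enabled, kappa_min = kappa_min, n_il = n_il,
                 slope = slope), class = "info_loss_params")
}

#' Inherent-information concentration under noise
#'
#' kappa(N) = kappa_min + (kappa_base - kappa_min) *
#' (0.5 - 0.5 tanh(slope (N - N_IL))): the concentration of the inherent
#' heading distribution decreases from its baseline toward kappa_min as
#' ambient noise rises, with half of the losable information gone at
#' N = N_IL. With loss disabled, returns the baseline.
#'
#' @param noise ambient noise at the individual's position, dB.
#' @param nav a [nav_params].
#' @param loss an [info_loss_params].
#' @return concentration; vectorized over `noise`.
#' @export
inherent_kappa <- function(noise, nav = nav_params(),
                           loss = info_loss_params()) {
  if (!loss$enabled) return(rep(nav$kappa_base, length(noise)))
  loss$kappa_min + (nav$kappa_base - loss$kappa_min) *
    (0.5 - 0.5 * tanh(loss$slope * (noise - loss$n_il)))
}

#' Sample an inherent heading toward the target
#'
#' One von Mises draw centred on the target bearing, with concentration
#' set by the local level of inherent information.
#'
#' @param target_bearing bearing to the target, radians CCW from east.
#' @param kappa concentration, >= 0.
#' @return one heading in (-pi, pi].
#' @export
sample_inherent_heading <- function(target_bearing, kappa) {
  rvonmises(1, target_bearing, kappa)
}

#' Noise-avoidance weight
#'
#' w_na(N) = 0.5 + 0.5 tanh((N - N_threshold) / N_s): the proportion of
#' motion devoted to negative phonotaxis, rising from ~0 in quiet water
#' through 0.5 at the threshold to ~1 (panic response) in extreme noise.
#'
#' @param noise ambient noise, dB; vectorized.
#' @param p a [noise_response_params].
#' @return weight in (0, 1).
#' @export
noise_avoidance_weight <- function(noise, p = noise_response_params()) {
  0.5 + 0.5 * tanh((noise - p$n_threshold) / p$n_s)
}

#' Land-avoidance weight
#'
#' w_la(d) = 0.5 - 0.5 tanh(slope (d - d_threshold)): the proportion of
#' motion devoted to bathotaxis, ~1 in very shallow water, 0.5 at the
#' threshold depth, ~0 in deep water.
#'
#' @param depth water depth at the individual's position, m; vectorized.
#' @param p a [land_response_params].
#' @return weight in (0, 1).
#' @export
land_avoidance_weight <- function(depth, p = land_response_params()) {
  0.5 - 0.5 * tanh(p$slope * (depth - p$d_threshold))
}

#' Combine navigation, noise-avoidance and land-avoidance headings
#'
#' If the avoidance weights sum to more than one they are rescaled
#' proportionally so the total weight is exactly one (navigation then
#' receives zero weight); otherwise navigation takes the remainder. The
#' resolved heading is the argument of the weighted sum of unit vectors.
#' A missing avoidance direction (locally flat field) surrenders its
#' weight back to navigation. A zero resultant is tie-broken uniformly
#' at random.
#'
#' @param nav_heading the fused navigation heading, radians.
#' @param noise_dir noise-descent heading or `NULL`.
#' @param land_dir deepest-water heading or `NULL`.
#' @param w_na,w_la avoidance weights in [0, 1].
#' @return one heading in (-pi, pi].
#' @export
resolve_behaviour <- function(nav_heading, noise_dir, land_dir, w_na, w_la) {
  stopifnot(w_na >= 0, w_na <= 1, w_la >= 0, w_la <= 1)
  if (is.null(noise_dir)) w_na <- 0
  if (is.null(land_dir)) w_la <- 0
  tot <- w_na + w_la
  if (tot > 1) {
    w_na <- w_na / tot
    w_la <- w_la / tot
  }
  w_nav <- 1 - w_na - w_la
  v <- w_nav * c(cos(nav_heading), sin(nav_heading))
  if (w_na > 0) v <- v + w_na * c(cos(noise_dir), sin(noise_dir))
  if (w_la > 0) v <- v + w_la * c(cos(land_dir), sin(land_dir))
  if (sqrt(sum(v^2)) < 1e-12) return(stats::runif(1, -pi, pi))
  wrap_angle(atan2(v[2], v[1]))
}

#' Headings of detectable conspecifics
#'
#' Returns the current active headings of every other live individual
#' whose call is detectable at the receiver: the received level after
#' spreading loss over the pair's great-circle range must clear both the
#' SNR threshold against the ambient noise at the receiver's position
#' and the minimum received level. Observed headings carry no added
#' error. With detection disabled, returns none.
#'
#' @param self_lon,self_lat receiver position, degrees.
#' @param noise_at_self ambient noise at the receiver, dB.
#' @param others_lon,others_lat,others_heading other live individuals'
#'   positions and headings (parallel vectors; may be empty).
#' @param params an [acoustic_params].
#' @return numeric vector of detectable headings (possibly empty).
#' @export
detectable_neighbours <- function(self_lon, self_lat, noise_at_self,
                                  others_lon, others_lat, others_heading,
                                  params = acoustic_params()) {
  if (!params$enabled || length(others_lon) == 0) return(numeric(0))
  r_m <- haversine_km(self_lon, self_lat, others_lon, others_lat) * 1000
  ok <- is_detectable(params$source_level, r_m, noise_at_self, params)
  others_heading[ok]
}
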