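SCENARIO_PRESETS <- c("pristine", "current_synthetic", "avoidance_sweep",
                      "info_loss", "traffic_increase", "slowdown",
                      "construction")

# default vessel fleet on straight shipping lanes crossing the corridor:
# each lane carries vessels shuttling end to end over the duration
synthetic_fleet <- function(lon_range, lat_range, duration_h,
                            n_per_lane = 2, source_level = 185,
                            multiplier = 1) {
  lanes <- list(
    list(lat = lat_range[1] + 0.45 * diff(lat_range)),
    list(lat = lat_range[1] + 0.60 * diff(lat_range))
  )
  n_per_lane <- max(1L, round(n_per_lane * multiplier))
  fleet <- list()
  for (li in seq_along(lanes)) {
    for (v in seq_len(n_per_lane)) {
      # stagger departures; one full crossing per ~48 h, back and forth
      leg <- 48
      n_legs <- max(2L, ceiling(duration_h / leg) + 1L)
      tw <- seq(0, by = leg, length.out = n_legs) - (v - 1) * leg / n_per_lane
      ends <- rep(c(lon_range[1], lon_range[2]),
                  length.out = n_legs)
      if (li %% 2 == 0) ends <- rev(rep(c(lon_range[2], lon_range[1]),
                                        length.out = n_legs))
      fleet[[length(fleet) + 1L]] <- noise_source(
        "mobile", source_level = source_level,
        lon = ends, lat = rep(lanes[[li]]$lat, n_legs), times = tw
      )
    }
  }
  fleet
}

#' Build a scenario from a preset
#'
#' Resolves a named scenario family to a fully parameterized
#' configuration plus a generated synthetic environment. Presets:
#'
#' * `pristine` — wind noise floor only, avoidance threshold 120 dB.
#' * `current_synthetic` — wind floor plus a small synthetic vessel
#'   fleet on straight shipping lanes (threshold 120 dB).
#' * `avoidance_sweep` — returns a list of three scenarios with
#'   avoidance thresholds 105, 110 and 115 dB over the synthetic
#'   current soundscape.
#' * `info_loss` — pristine soundscape with noise-dependent loss of
#'   inherent information enabled (N_IL 110 dB by default).
#' * `traffic_increase` — vessel fleet scaled by 1.5 (a 50% traffic
#'   increase), threshold 115 dB.
#' * `slowdown` — the current fleet with a 10 dB source-level reduction
#'   inside a slowdown zone covering the corridor, threshold 115 dB.
#' * `construction` — a fixed 200 dB duty-cycled construction source
#'   near the corridor (12 active hours/day by default), threshold
#'   115 dB.
#'
#' Reduced-scale defaults (10 whales, 72 h, dt 0.25 h, 2 repeats, a
#' compact synthetic domain) keep every preset desk-runnable; pass
#' `scale = "paper"` for the reference scale (100 whales, 744 h,
#' 10 repeats).
#'
#' @param preset preset name.
#' @param overrides named list applied to the [scenario_config] fields
#'   last (e.g. `list(n_whales = 20)`).
#' @param scale `"reduced"` or `"paper"`.
#' @param construction_hours active construction hours per day (0, 5, 8
#'   or 12; `construction` preset).
#' @param n_il information-loss threshold, dB (`info_loss` preset).
#' @return object of class `scenario`: list with `name`, `config`,
#'   `env`, `sources`. `avoidance_sweep` returns a list of three such
#'   objects.
#' @export
build_scenario <- function(preset, overrides = list(),
                           scale = c("reduced", "paper"),
                           construction_hours = 12, n_il = 110) {
  if (!preset %in% SCENARIO_PRESETS) {
    stop("unknown preset '", preset, "'; valid presets: ",
         paste(SCENARIO_PRESETS, collapse = ", "))
  }
  scale <- match.arg(scale)
  bad <- setdiff(names(overrides), names(formals(scenario_config)))
  if (length(bad)) {
    stop("unknown config parameter(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(names(formals(scenario_config)), collapse = ", "))
  }

  if (preset == "avoidance_sweep") {
    return(lapply(c(105, 110, 115), function(th) {
      ov <- utils::modifyList(
        list(noise_response = noise_response_params(n_threshold = th)),
        overrides
      )
      sc <- build_scenario("current_synthetic", ov, scale = scale)
      sc$name <- sprintf("avoidance_sweep_%d", th)
      sc
    }))
  }

  if (scale == "reduced") {
    lon_range <- c(0, 9); lat_range <- c(51.5, 59.5); res <- 0.25
    base <- list(n_whales = 10, start_box = c(4.5, 5.5, 53, 54),
                 target = c(3.5, 57.5), duration_h = 72, dt = 0.25,
                 n_repeats = 2)
  } else {
    lon_range <- c(-11, 9); lat_range <- c(51, 63); res <- 0.5
    base <- list(n_whales = 100, start_box = c(4.5, 5.5, 53.5, 54.5),
                 target = c(-5, 61), duration_h = 744, dt = 0.1,
                 n_repeats = 10)
  }
  duration <- if (!is.null(overrides$duration_h)) overrides$duration_h
  else base$duration_h
  noise_times <- seq(0, duration, by = 1)  # hourly noise re-rendering

  sources <- list()
  slowdown_zone <- NULL
  n_threshold <- 120
  info <- info_loss_params()

  if (preset %in% c("current_synthetic", "traffic_increase", "slowdown")) {
    mult <- if (preset == "traffic_increase") 1.5 else 1
    sources <- synthetic_fleet(lon_range, lat_range, duration,
                               multiplier = mult)
    if (preset != "current_synthetic") n_threshold <- 115
    if (preset == "slowdown") {
      mid <- c(mean(lon_range), mean(lat_range))
      slowdown_zone <- c(mid[1] - 2, mid[1] + 2, mid[2] - 1.5, mid[2] + 1.5)
    }
  } else if (preset == "construction") {
    n_threshold <- 115
    if (construction_hours > 0) {
      # effective broadband level chosen so the avoidance footprint under
      # the single-coefficient spreading model is O(60 km), not basin-wide
      sources <- list(noise_source(
        "fixed", source_level = 200,
        lon = mean(lon_range) - 0.5,
        lat = lat_range[1] + 0.55 * diff(lat_range),
        active_hours = c(0, construction_hours)
      ))
    }
  } else if (preset == "info_loss") {
    info <- info_loss_params(enabled = TRUE, n_il = n_il)
  }

  env <- make_synthetic_sea("open", lon_range = lon_range,
                            lat_range = lat_range, resolution = res,
                            times = if (length(sources)) noise_times else 0)
  if (length(sources)) {
    env$noise <- render_noise_map(sources, env$noise, times = noise_times,
                                  slowdown_zone = slowdown_zone)
  }

  args <- utils::modifyList(base, list(
    noise_response = noise_response_params(n_threshold = n_threshold),
    info_loss = info
  ))
  args <- utils::modifyList(args, overrides)
  config <- do.call(scenario_config, args)
  structure(list(name = preset, config = config, env = env,
                 sources = sources),
            class = "scenario")
}

# --- config round-trip -----------------------------------------------------

#' Save a scenario configuration as JSON
#' @param config a [scenario_config].
#' @param path output file.
#' @export
save_scenario_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a scenario configuration from JSON
#'
#' Inverse of [save_scenario_config()]: `load_scenario_config(
#' save_scenario_config(config))` reproduces the configuration.
#'
#' @param path JSON file.
#' @return a [scenario_config].
#' @export
load_scenario_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario_config(
    n_whales = x$n_whales, start_box = x$start_box, target = x$target,
    arrival_radius_km = x$arrival_radius_km, duration_h = x$duration_h,
    dt = x$dt, n_repeats = x$n_repeats, base_seed = x$base_seed,
    nav = do.call(nav_params, x$nav),
    noise_response = do.call(noise_response_params, x$noise_response),
    land_response = do.call(land_response_params, x$land_response),
    info_loss = do.call(info_loss_params, x$info_loss),
    acoustics = do.call(acoustic_params, x$acoustics)
  )
}
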