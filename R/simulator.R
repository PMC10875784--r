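#' Bundle of environmental layers
#'
#' @param noise scalar [grid_field], ambient noise dB.
#' @param depth scalar [grid_field], water depth m (positive = water);
#'   a single (static) time slice.
#' @param current vector [grid_field] of (east, north) km/h, or `NULL`
#'   for still water.
#' @return object of class `whale_env`.
#' @export
whale_env <- function(noise, depth, current = NULL) {
  stopifnot(inherits(noise, "grid_field"), inherits(depth, "grid_field"))
  if (!is.null(current) && !current$vector) {
    stop("current must be a vector field")
  }
  structure(list(noise = noise, depth = depth, current = current),
            class = "whale_env")
}

#' Scenario configuration
#'
#' Full parameterization of one simulation. Defaults follow the
#' reference migration: 100 whales released in a 1 degree box in the
#' southern North Sea, a target in the North Atlantic at (5 W, 61 N),
#' arrival within 50 km, 744 h (31 days) duration, 10 repeats.
#'
#' @param n_whales population size.
#' @param start_box `c(lon_min, lon_max, lat_min, lat_max)` degrees.
#' @param target `c(lon, lat)` degrees.
#' @param arrival_radius_km arrival radius, km.
#' @param duration_h simulated hours.
#' @param dt integration time step, hours (<= 1).
#' @param n_repeats ensemble size.
#' @param base_seed integer seed; repeat k uses base_seed + k - 1.
#' @param nav a [nav_params].
#' @param noise_response a [noise_response_params].
#' @param land_response a [land_response_params].
#' @param info_loss an [info_loss_params].
#' @param acoustics an [acoustic_params].
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_whales = 100,
                            start_box = c(4.5, 5.5, 53.5, 54.5),
                            target = c(-5, 61),
                            arrival_radius_km = 50,
                            duration_h = 744,
                            dt = 0.1,
                            n_repeats = 10,
                            base_seed = 1,
                            nav = nav_params(),
                            noise_response = noise_response_params(),
                            land_response = land_response_params(),
                            info_loss = info_loss_params(),
                            acoustics = acoustic_params()) {
  stopifnot(dt > 0, dt <= 1, n_repeats >= 1, duration_h >= 0)
  structure(list(n_whales = n_whales, start_box = start_box,
                 target = target, arrival_radius_km = arrival_radius_km,
                 duration_h = duration_h, dt = dt, n_repeats = n_repeats,
                 base_seed = base_seed, nav = nav,
                 noise_response = noise_response,
                 land_response = land_response, info_loss = info_loss,
                 acoustics = acoustics),
            class = "scenario_config")
}

# polynomial rolling hash over the canonical JSON serialization;
# provenance tag only, not cryptographic
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Initialize a whale population
#'
#' Positions uniform in the start box, initial headings toward the
#' target, first reorientation times exponentially distributed with the
#' configured rate. Errors if the start box or target touches land.
#'
#' @param config a [scenario_config].
#' @param env a [whale_env].
#' @return data.frame of agent states (one row per whale).
#' @export
initialize_population <- function(config, env) {
  n <- config$n_whales
  b <- config$start_box
  if (is_land(env$depth, config$target[1], config$target[2])) {
    stop("target position is on land")
  }
  corners <- expand.grid(lon = b[1:2], lat = b[3:4])
  for (i in seq_len(nrow(corners))) {
    if (is_land(env$depth, corners$lon[i], corners$lat[i])) {
      stop("start region overlaps land")
    }
  }
  if (n == 0) {
    return(data.frame(id = integer(0), lon = numeric(0), lat = numeric(0),
                      heading = numeric(0), next_reorient = numeric(0),
                      arrived = logical(0), arrival_time = numeric(0)))
  }
  lon <- stats::runif(n, b[1], b[2])
  lat <- stats::runif(n, b[3], b[4])
  for (i in seq_len(n)) {
    if (is_land(env$depth, lon[i], lat[i])) stop("start region overlaps land")
  }
  heading <- bearing(lon, lat, config$target[1], config$target[2])
  data.frame(id = seq_len(n), lon = lon, lat = lat, heading = heading,
             next_reorient = stats::rexp(n, config$nav$lambda),
             arrived = FALSE, arrival_time = NA_real_)
}

# ambient noise at each live agent's position (NA for arrived or for
# agents outside the grid; the stepper raises the identifying error)
agent_noise <- function(pop, env, t) {
  nf <- env$noise
  out <- rep(NA_real_, nrow(pop))
  for (i in seq_len(nrow(pop))) {
    if (pop$arrived[i]) next
    if (pop$lon[i] < nf$lon[1] || pop$lon[i] > nf$lon[length(nf$lon)] ||
        pop$lat[i] < nf$lat[1] || pop$lat[i] > nf$lat[length(nf$lat)]) next
    out[i] <- interpolate_field(nf, pop$lon[i], pop$lat[i], t,
                                warn_clamp = FALSE)
  }
  out
}

# per-agent count of detectable conspecifics among live agents
detection_counts <- function(pop, noise_at, params) {
  n <- nrow(pop)
  counts <- rep(0L, n)
  if (!params$enabled || n < 2) return(counts)
  live <- which(!pop$arrived)
  for (i in live) {
    j <- setdiff(live, i)
    if (length(j) == 0) next
    r_m <- haversine_km(pop$lon[i], pop$lat[i], pop$lon[j], pop$lat[j]) * 1000
    counts[i] <- sum(is_detectable(params$source_level, r_m, noise_at[i],
                                   params))
  }
  counts
}

#' Advance the population by one time step
#'
#' Each live agent, in id order: if its reorientation clock has fired,
#' it runs the full heading selection (inherent von Mises draw toward
#' the target with noise-dependent concentration, fusion with detectable
#' neighbours' headings, behavioural weighting against negative
#' phonotaxis and bathotaxis) and redraws its exponential clock. It then
#' moves by speed * dt along its heading plus the local current * dt.
#' A move whose destination cell is land is aborted with an immediate
#' reorientation scheduled. Agents within the arrival radius of the
#' target at step end are marked arrived.
#'
#' @param pop agent data.frame from [initialize_population()].
#' @param env a [whale_env].
#' @param config a [scenario_config].
#' @param t current time, hours.
#' @param dt step, hours.
#' @param noise_at optional precomputed per-agent noise (from
#'   [agent_noise()]); computed if missing.
#' @return updated agent data.frame.
#' @export
step_population <- function(pop, env, config, t, dt, noise_at = NULL) {
  stopifnot(dt > 0)
  if (is.null(noise_at)) noise_at <- agent_noise(pop, env, t)
  nav <- config$nav
  # work on plain vectors: per-element data.frame writes are costly
  s <- as.list(pop)
  # snapshot of headings at step start: observations within the step are
  # simultaneous
  snap_lon <- s$lon; snap_lat <- s$lat
  snap_heading <- s$heading; snap_arrived <- s$arrived
  dom <- function(lon, lat) {
    lon >= env$depth$lon[1] && lon <= env$depth$lon[length(env$depth$lon)] &&
      lat >= env$depth$lat[1] && lat <= env$depth$lat[length(env$depth$lat)]
  }
  for (i in seq_along(s$id)) {
    if (s$arrived[i]) next
    if (!dom(s$lon[i], s$lat[i])) {
      stop(sprintf("agent %d outside environment domain at t = %g h",
                   s$id[i], t))
    }
    N <- noise_at[i]
    if (t >= s$next_reorient[i]) {
      d <- interpolate_field(env$depth, s$lon[i], s$lat[i], t,
                             warn_clamp = FALSE)
      kap <- inherent_kappa(N, nav, config$info_loss)
      tb <- bearing(s$lon[i], s$lat[i], config$target[1], config$target[2])
      own <- sample_inherent_heading(tb, kap)
      live <- which(!snap_arrived & s$id != s$id[i])
      neigh <- detectable_neighbours(
        s$lon[i], s$lat[i], N,
        snap_lon[live], snap_lat[live], snap_heading[live],
        config$acoustics
      )
      fh <- fuse_headings(own, neigh, nav$alpha, nav$beta)
      nav_heading <- rvonmises(1, fh$mu, fh$kappa)
      w_na <- noise_avoidance_weight(N, config$noise_response)
      w_la <- land_avoidance_weight(d, config$land_response)
      noise_dir <- if (w_na > 1e-6) {
        noise_descent_direction(env$noise, s$lon[i], s$lat[i], t)
      }
      land_dir <- if (w_la > 1e-6) {
        deepest_water_direction(env$depth, s$lon[i], s$lat[i])
      }
      s$heading[i] <- resolve_behaviour(nav_heading, noise_dir, land_dir,
                                        w_na, w_la)
      s$next_reorient[i] <- t + stats::rexp(1, nav$lambda)
    }
    dx <- nav$speed * dt * cos(s$heading[i])
    dy <- nav$speed * dt * sin(s$heading[i])
    if (!is.null(env$current)) {
      v <- interpolate_field(env$current, s$lon[i], s$lat[i], t,
                             warn_clamp = FALSE)
      dx <- dx + v[1] * dt
      dy <- dy + v[2] * dt
    }
    dist <- sqrt(dx^2 + dy^2)
    if (dist > 0) {
      newp <- displace(s$lon[i], s$lat[i], atan2(dy, dx), dist)
      # the domain edge blocks like a coastline; agents cannot leave the
      # gridded world mid-run
      blocked <- !dom(newp$lon, newp$lat) ||
        is_land(env$depth, newp$lon, newp$lat)
      if (blocked) {
        # failsafe: abort landward motion, reorient immediately
        s$next_reorient[i] <- t
      } else {
        s$lon[i] <- newp$lon
        s$lat[i] <- newp$lat
      }
    }
    if (haversine_km(s$lon[i], s$lat[i], config$target[1],
                     config$target[2]) <= config$arrival_radius_km) {
      s$arrived[i] <- TRUE
      s$arrival_time[i] <- t + dt
    }
  }
  pop$lon <- s$lon; pop$lat <- s$lat; pop$heading <- s$heading
  pop$next_reorient <- s$next_reorient
  pop$arrived <- s$arrived; pop$arrival_time <- s$arrival_time
  pop
}

#' Run one simulation realisation
#'
#' Fixed-step explicit Euler integration of the velocity-jump walk over
#' the configured duration, recording every agent's state and
#' detectable-conspecific count at every time step. Reproducible: the
#' seed initializes one RNG stream for the whole repeat.
#'
#' @param config a [scenario_config].
#' @param env a [whale_env].
#' @param seed integer seed for this realisation.
#' @return object of class `trajectory_set`: list with `data` (long
#'   data.frame: t, id, lon, lat, heading, n_detected, arrived), `seed`,
#'   `config_hash` and `config`.
#' @export
run_simulation <- function(config, env, seed = config$base_seed) {
  set.seed(seed)
  pop <- initialize_population(config, env)
  dt <- config$dt
  nsteps <- if (config$duration_h == 0) 0L else
    as.integer(ceiling(config$duration_h / dt - 1e-9))
  nrec <- (nsteps + 1L) * nrow(pop)
  rec <- list(t = numeric(nrec), id = integer(nrec), lon = numeric(nrec),
              lat = numeric(nrec), heading = numeric(nrec),
              n_detected = integer(nrec), arrived = logical(nrec))
  fill <- function(k, t, pop, ndet) {
    idx <- seq.int(k * nrow(pop) + 1L, length.out = nrow(pop))
    rec$t[idx] <<- t
    rec$id[idx] <<- pop$id
    rec$lon[idx] <<- pop$lon
    rec$lat[idx] <<- pop$lat
    rec$heading[idx] <<- pop$heading
    rec$n_detected[idx] <<- ndet
    rec$arrived[idx] <<- pop$arrived
  }
  for (k in 0:nsteps) {
    t <- k * dt
    if (nrow(pop) > 0) {
      noise_at <- agent_noise(pop, env, t)
      fill(k, t, pop, detection_counts(pop, noise_at, config$acoustics))
      if (k < nsteps) {
        pop <- step_population(pop, env, config, t, dt, noise_at)
      }
    }
    if (nrow(pop) == 0 && k == 0) break
  }
  structure(list(data = as.data.frame(rec), seed = seed,
                 config_hash = config_hash(config), config = config,
                 final = pop),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set> %d whales, %d time points, seed %d, config %s; %d arrived\n",
    length(unique(x$data$id)), length(unique(x$data$t)), x$seed,
    x$config_hash, sum(x$final$arrived)
  ))
  invisible(x)
}

#' Run an ensemble of realisations
#'
#' Repeat k (1-based) uses seed `base_seed + k - 1`; repeats are
#' independent realisations of the same scenario.
#'
#' @param config a [scenario_config].
#' @param env a [whale_env].
#' @return list of [run_simulation()] results (class
#'   `trajectory_ensemble`).
#' @export
run_ensemble <- function(config, env) {
  out <- lapply(seq_len(config$n_repeats), function(k) {
    run_simulation(config, env, seed = config$base_seed + k - 1L)
  })
  class(out) <- "trajectory_ensemble"
  out
}

#' Write a trajectory set to CSV
#' @param ts a `trajectory_set`.
#' @param path output file.
#' @export
write_trajectories_csv <- function(ts, path) {
  df <- ts$data
  df$repeat_seed <- ts$seed
  df$heading_rad <- df$heading
  df$t_hours <- df$t
  utils::write.csv(
    df[, c("repeat_seed", "id", "t_hours", "lon", "lat", "heading_rad",
           "n_detected", "arrived")],
    path, row.names = FALSE
  )
  invisible(path)
}
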