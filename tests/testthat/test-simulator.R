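test_that("initialize_population: size, determinism, clock distribution", {
  env <- quiet_env()
  cfg <- quick_config()

  set.seed(1)
  expect_equal(nrow(initialize_population(
    scenario_config(n_whales = 0, start_box = cfg$start_box,
                    target = cfg$target), env)), 0)

  set.seed(42); a <- initialize_population(cfg, env)
  set.seed(42); b <- initialize_population(cfg, env)
  expect_identical(a, b)
  # positions inside the box, headings toward the target
  expect_true(all(a$lon >= 4.5 & a$lon <= 5.5 & a$lat >= 53 & a$lat <= 54))
  expect_equal(a$heading, bearing(a$lon, a$lat, 5, 56.75))

  # reorientation gaps are Exponential(lambda): mean within 3 s.e.
  set.seed(7)
  big <- initialize_population(
    scenario_config(n_whales = 1e4, start_box = cfg$start_box,
                    target = cfg$target, nav = nav_params(lambda = 2)), env)
  expect_lt(abs(mean(big$next_reorient) - 0.5), 3 * 0.5 / sqrt(1e4))
})

test_that("initialize_population rejects starts on land", {
  env <- make_synthetic_sea("island", lon_range = c(0, 4),
                            lat_range = c(50, 54), island_centre = c(2, 52))
  cfg <- scenario_config(n_whales = 3, start_box = c(1.8, 2.2, 51.8, 52.2),
                         target = c(0.5, 53.5))
  set.seed(1)
  expect_error(initialize_population(cfg, env), "land")
  cfg2 <- scenario_config(n_whales = 3, start_box = c(0.2, 0.6, 50.2, 50.6),
                          target = c(2, 52))
  set.seed(1)
  expect_error(initialize_population(cfg2, env), "target")
})

test_that("step_population: active swim, passive drift, arrival threshold", {
  env <- quiet_env()
  cfg <- quick_config(n_whales = 1)
  set.seed(1)
  pop <- initialize_population(cfg, env)
  pop$heading <- 0                  # due east
  pop$next_reorient <- 1e9          # clock never fires
  p0 <- c(pop$lon, pop$lat)
  pop2 <- step_population(pop, env, cfg, 0, 1)
  moved <- haversine_km(p0[1], p0[2], pop2$lon, pop2$lat)
  expect_equal(moved, 6, tolerance = 1e-3)
  expect_gt(pop2$lon, p0[1])
  expect_equal(pop2$lat, p0[2], tolerance = 1e-6)

  # passive limit: speed 0, uniform 1 km/h eastward current
  envc <- quiet_env(current = c(1, 0))
  cfg0 <- quick_config(n_whales = 1, nav = nav_params(speed = 0))
  set.seed(2)
  popc <- initialize_population(cfg0, envc)
  popc$next_reorient <- 1e9
  q0 <- c(popc$lon, popc$lat)
  popc <- step_population(popc, envc, cfg0, 0, 1)
  drift <- haversine_km(q0[1], q0[2], popc$lon, popc$lat)
  expect_equal(drift, 1, tolerance = 1e-3)

  # agent ending a step 49 km from target is marked arrived
  cfg1 <- quick_config(n_whales = 1)
  set.seed(3)
  popa <- initialize_population(cfg1, env)
  near <- displace(5, 56.75, pi, 49)    # 49 km south of target
  popa$lon <- near$lon; popa$lat <- near$lat
  popa$next_reorient <- 1e9
  popa <- step_population(popa, env, cfg1, 0, 0.25)
  expect_true(popa$arrived)
  expect_equal(popa$arrival_time, 0.25)
})

test_that("landward motion is aborted with an immediate reorientation", {
  env <- make_synthetic_sea("island", lon_range = c(0, 4),
                            lat_range = c(50, 54), island_centre = c(2, 52),
                            island_radius_deg = 1)
  cfg <- scenario_config(n_whales = 1, start_box = c(0.25, 0.35, 51.9, 52.1),
                         target = c(0.3, 53.8), dt = 0.25,
                         land_response = land_response_params(d_threshold = 1e-6))
  # agent right at the shoreline heading straight at the island;
  # near-zero d_threshold disables the soft response so only the failsafe acts
  pop <- data.frame(id = 1L, lon = 0.36, lat = 52, heading = 0,
                    next_reorient = 1e9, arrived = FALSE,
                    arrival_time = NA_real_)
  pop2 <- step_population(pop, env, cfg, 0, 0.25)
  expect_equal(c(pop2$lon, pop2$lat), c(0.36, 52))
  expect_equal(pop2$next_reorient, 0)   # immediate reorientation
})

test_that("no recorded position is ever on land", {
  env <- make_synthetic_sea("island", lon_range = c(0, 4),
                            lat_range = c(50, 54.5), island_centre = c(2, 52.4),
                            island_radius_deg = 0.6)
  cfg <- scenario_config(n_whales = 6, start_box = c(1.5, 2.5, 50.3, 50.8),
                         target = c(2, 54.2), duration_h = 48, dt = 0.25)
  ts <- run_simulation(cfg, env, 5)
  on_land <- mapply(function(lon, lat) is_land(env$depth, lon, lat),
                    ts$data$lon, ts$data$lat)
  expect_false(any(on_land))
})

test_that("run_simulation: duration zero, determinism, straight-line bound", {
  env <- quiet_env()
  cfg0 <- quick_config(duration_h = 0)
  ts <- run_simulation(cfg0, env, 1)
  expect_equal(unique(ts$data$t), 0)

  cfg <- quick_config(duration_h = 6)
  a <- run_simulation(cfg, env, 9)
  b <- run_simulation(cfg, env, 9)
  expect_identical(a$data, b$data)

  # near-certain navigation, no obstacles: arrival ~ straight-line time.
  # start ~300 km from target; 5 km arrival radius keeps the straight-line
  # bound at 295/6 = 49.2 h
  start <- displace(3, 55, -pi / 2, 300)
  cfgk <- scenario_config(
    n_whales = 4, start_box = c(start$lon - 0.05, start$lon + 0.05,
                                start$lat - 0.05, start$lat + 0.05),
    target = c(3, 55), arrival_radius_km = 5, duration_h = 90, dt = 0.25,
    nav = nav_params(kappa_base = 1e4),
    acoustics = acoustic_params(enabled = FALSE))
  envk <- make_synthetic_sea("open", lon_range = c(0, 6),
                             lat_range = c(50, 57))
  tsk <- run_simulation(cfgk, envk, 2)
  expect_true(all(tsk$final$arrived))
  expect_equal(mean(tsk$final$arrival_time), 300 / 6, tolerance = 0.1)
})

test_that("active displacement magnitude is exactly speed * dt", {
  env <- quiet_env()
  cfg <- quick_config(n_whales = 3, duration_h = 10, dt = 0.5)
  ts <- run_simulation(cfg, env, 3)
  d <- ts$data[order(ts$data$id, ts$data$t), ]
  for (id in unique(d$id)) {
    tr <- d[d$id == id & !d$arrived, ]
    step_km <- haversine_km(tr$lon[-nrow(tr)], tr$lat[-nrow(tr)],
                            tr$lon[-1], tr$lat[-1])
    expect_lt(max(abs(step_km - 6 * 0.5)), 6 * 0.5 * 1e-3)
  }
})

test_that("run_ensemble: seeds, independence, monotone arrivals", {
  env <- quiet_env()
  cfg <- quick_config(n_repeats = 1, duration_h = 4)
  ens1 <- run_ensemble(cfg, env)
  expect_length(ens1, 1)

  cfg3 <- quick_config(n_repeats = 3, duration_h = 12, base_seed = 21)
  ens <- run_ensemble(cfg3, env)
  expect_equal(vapply(ens, function(x) x$seed, numeric(1)), c(21, 22, 23))
  # any pair differs
  expect_false(identical(ens[[1]]$data$lon, ens[[2]]$data$lon))
  expect_false(identical(ens[[2]]$data$lon, ens[[3]]$data$lon))
  # per-repeat arrivals are monotone nondecreasing
  for (ts in ens) {
    arr <- tapply(ts$data$arrived, ts$data$t, sum)
    expect_true(all(diff(arr[order(as.numeric(names(arr)))]) >= 0))
  }
})

test_that("an agent outside the domain raises an identifying error", {
  env <- make_synthetic_sea("open", lon_range = c(4, 6),
                            lat_range = c(53, 55))
  cfg <- scenario_config(n_whales = 1, start_box = c(4.8, 5.2, 53.4, 53.6),
                         target = c(5, 54.9))
  set.seed(8)
  pop <- initialize_population(cfg, env)
  pop$lon <- 7                       # inconsistent state: off the grid
  expect_error(step_population(pop, env, cfg, 0, 0.25), "agent 1 outside")

  # within a run the domain edge blocks like a coastline instead
  cfg2 <- scenario_config(n_whales = 2, start_box = c(4.3, 5.7, 53.1, 54.9),
                          target = c(5, 54.999), arrival_radius_km = 0.001,
                          duration_h = 24, dt = 0.5,
                          land_response = land_response_params(d_threshold = 1e-6))
  env2 <- make_synthetic_sea("open", lon_range = c(4.2, 5.8),
                             lat_range = c(53, 55))
  ts <- run_simulation(cfg2, env2, 8)
  expect_true(all(ts$data$lon >= 4.2 & ts$data$lon <= 5.8 &
                    ts$data$lat >= 53 & ts$data$lat <= 55))
})
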