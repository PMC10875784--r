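# hand-built trajectory sets let the metric contracts be checked exactly
fake_ts <- function(df, target = c(0, 55), seed = 1) {
  structure(list(data = df, seed = seed, config = list(target = target),
                 config_hash = "fixture"),
            class = "trajectory_set")
}
fake_ens <- function(...) structure(list(...), class = "trajectory_ensemble")

test_that("median_trajectory: identity, crossing switch, parallel tracks", {
  t1 <- data.frame(lon = c(0, 1, 2), lat = c(50, 50.5, 52))
  expect_equal(as.data.frame(median_trajectory(list(t1)))[, c("lon", "lat")],
               t1)

  # two straight tracks crossing once at (1, 51): follow 1, switch to 2
  a <- data.frame(lon = c(0, 2), lat = c(50, 52))
  b <- data.frame(lon = c(0, 2), lat = c(52, 50))
  med <- median_trajectory(list(a, b))
  expect_equal(med$lon, c(0, 1, 2), tolerance = 1e-9)
  expect_equal(med$lat, c(50, 51, 50), tolerance = 1e-9)
  expect_equal(med$track, c(1, 2, 2))

  # parallel tracks never switch; the start nearest the centroid wins
  par <- lapply(c(0, 1, 2), function(x) {
    data.frame(lon = rep(x, 3), lat = c(50, 51, 52))
  })
  medp <- median_trajectory(list(par[[1]], par[[2]], par[[3]]))
  expect_equal(unique(medp$track), 2)
  expect_equal(medp$lon, rep(1, 3))

  expect_error(median_trajectory(list()), ">= 1")
})

test_that("median trajectory vertices lie on input tracks", {
  env <- quiet_env()
  cfg <- quick_config(n_whales = 6, duration_h = 18)
  ts <- run_simulation(cfg, env, 13)
  tracks <- agent_tracks(ts)
  med <- median_trajectory(tracks)
  for (v in seq_len(nrow(med))) {
    tr <- tracks[[med$track[v]]]
    hit <- FALSE
    for (sgm in seq_len(nrow(tr) - 1)) {
      if (point_on_segment(c(med$lon[v], med$lat[v]),
                           c(tr$lon[sgm], tr$lat[sgm]),
                           c(tr$lon[sgm + 1], tr$lat[sgm + 1]),
                           tol = 1e-6)) {
        hit <- TRUE
        break
      }
    }
    expect_true(hit, label = sprintf("vertex %d on its source track", v))
  }
})

test_that("spread_region thresholds the occupancy histogram", {
  one <- fake_ts(data.frame(t = 0:4, id = 1, lon = rep(0.1, 5),
                            lat = rep(50.1, 5), heading = 0,
                            n_detected = 0, arrived = FALSE))
  sr <- spread_region(fake_ens(one), bin_size = 0.25)
  expect_equal(sum(sr$bins$included), 1)
  expect_equal(sr$bins$freq, 1)

  # uniform occupancy over 10 bins: every bin at 0.1 >= 0.05
  unif <- fake_ts(data.frame(t = 1:10, id = 1,
                             lon = seq(0.125, 2.375, by = 0.25),
                             lat = 50.1, heading = 0, n_detected = 0,
                             arrived = FALSE))
  sru <- spread_region(fake_ens(unif), bin_size = 0.25)
  expect_equal(nrow(sru$bins), 10)
  expect_true(all(sru$bins$included))

  # threshold 1 with several occupied bins excludes everything
  sr1 <- spread_region(fake_ens(unif), bin_size = 0.25, threshold = 1)
  expect_false(any(sr1$bins$included))
})

test_that("arrivals_over_time counts initial minus remaining", {
  mk <- function(arr2) {
    data.frame(t = rep(c(0, 1, 2), each = 2), id = rep(1:2, 3),
               lon = 0, lat = 50, heading = 0, n_detected = 0,
               arrived = c(FALSE, FALSE, TRUE, FALSE, TRUE, arr2))
  }
  ens <- fake_ens(fake_ts(mk(TRUE)), fake_ts(mk(FALSE), seed = 2))
  arr <- arrivals_over_time(ens)
  expect_equal(arr$t, c(0, 1, 2))
  expect_equal(arr$mean, c(0, 1, 1.5))
  expect_equal(arr$sd, c(0, 0, stats::sd(c(2, 1))))

  # no arrivals: all-zero series
  none <- fake_ens(fake_ts(mk(TRUE)[mk(TRUE)$t == 0, ]))
  expect_equal(arrivals_over_time(none)$mean, 0)
})

test_that("starting inside the arrival radius empties at the first step", {
  env <- quiet_env()
  cfg <- scenario_config(n_whales = 4, start_box = c(4.9, 5.1, 56.7, 56.8),
                         target = c(5, 56.75), duration_h = 1, dt = 0.25)
  ens <- run_ensemble(cfg, env)
  arr <- arrivals_over_time(ens)
  expect_equal(arr$mean[1], 0)
  expect_equal(arr$mean[2], 4)
  # arrivals + remaining = population at every time point, per repeat
  for (ts in ens) {
    for (tt in unique(ts$data$t)) {
      rows <- ts$data[ts$data$t == tt, ]
      expect_equal(sum(rows$arrived) + sum(!rows$arrived), 4)
    }
  }
})

test_that("mean_distance_to_target tracks the live-population centroid", {
  single <- fake_ts(data.frame(t = c(0, 1), id = 1, lon = c(0, 0),
                               lat = c(54, 54.5), heading = 0,
                               n_detected = 0, arrived = FALSE))
  md <- mean_distance_to_target(fake_ens(single), target = c(0, 55))
  expect_equal(md$mean, haversine_km(0, c(54, 54.5), 0, 55))
  expect_equal(md$sd, c(0, 0))

  # two agents symmetric about the target: centroid distance ~ 0
  sym <- fake_ts(data.frame(t = 0, id = 1:2, lon = 0, lat = c(54, 56),
                            heading = 0, n_detected = 0, arrived = FALSE))
  mds <- mean_distance_to_target(fake_ens(sym), target = c(0, 55))
  expect_lt(mds$mean, 0.5)   # meridian symmetry; spherical centroid ~ target

  # once everyone has arrived the last value is carried forward
  done <- fake_ts(data.frame(t = rep(c(0, 1), each = 1), id = 1,
                             lon = 0, lat = c(54, 54.9), heading = 0,
                             n_detected = 0, arrived = c(FALSE, TRUE)))
  mdc <- mean_distance_to_target(fake_ens(done), target = c(0, 55))
  expect_equal(mdc$mean[2], mdc$mean[1])
})

test_that("mean_detected_whales averages per day and ignores labels", {
  mk <- function(ids) {
    data.frame(t = rep(c(0, 12, 24, 36), each = 2), id = rep(ids, 4),
               lon = 0, lat = 50, heading = 0,
               n_detected = c(1, 1, 3, 3, 5, 5, 7, 7), arrived = FALSE)
  }
  a <- mean_detected_whales(fake_ens(fake_ts(mk(1:2))))
  b <- mean_detected_whales(fake_ens(fake_ts(mk(c(9, 4)))))
  expect_equal(a$day, c(1, 2))
  expect_equal(a$mean, c(2, 6))
  expect_equal(a, b)   # relabelling invariance

  # complete graph: k mutually-detectable agents each hear k - 1
  env <- quiet_env()
  cfg <- scenario_config(n_whales = 3, start_box = c(4.9, 5.1, 53.4, 53.6),
                         target = c(5, 56.75), duration_h = 2, dt = 0.5)
  ts <- run_simulation(cfg, env, 4)
  expect_true(all(ts$data$n_detected[!ts$data$arrived] == 2))
  det <- mean_detected_whales(fake_ens(ts))
  expect_equal(det$mean, 2)
})

test_that("fully masked detection yields an all-zero daily series", {
  lon <- seq(4, 6, 0.25); lat <- seq(53, 55, 0.25)
  env <- whale_env(noise = constant_field(200, lon, lat, units = "dB"),
                   depth = constant_field(100, lon, lat, units = "m"))
  cfg <- scenario_config(n_whales = 3, start_box = c(4.9, 5.1, 53.4, 53.6),
                         target = c(5, 54.9), duration_h = 2, dt = 0.5,
                         noise_response = noise_response_params(n_threshold = 1000))
  ts <- run_simulation(cfg, env, 4)
  expect_true(all(ts$data$n_detected == 0))
})

test_that("metrics JSON export round-trips", {
  env <- quiet_env()
  cfg <- quick_config(duration_h = 6)
  ens <- run_ensemble(cfg, env)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(ens, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_named(back, c("arrivals", "distance_to_target_km",
                       "detected_whales"))
  expect_equal(back$arrivals$mean, arrivals_over_time(ens)$mean)
})
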