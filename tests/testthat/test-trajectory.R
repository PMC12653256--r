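test_that("event selection keeps exactly the nights at or above threshold", {
  traps <- data.frame(site_id = "s1", lat = 27, lon = 111,
                      date = c("2024-05-01", "2024-05-02", "2024-05-03", "2024-05-04"),
                      count = c(5, 12, 30, 10))
  ev <- select_events(traps)
  expect_equal(ev$date, c("2024-05-02", "2024-05-03", "2024-05-04"))  # 10 is inclusive
  expect_equal(nrow(select_events(transform(traps, count = 0))), 0)
  expect_error(select_events(transform(traps, count = c(-1, 2, 3, 4))),
               "non-negative integers")
})

test_that("uniform-wind backward endpoint matches the closed-form advection oracle", {
  f <- uniform_field(u = 10, v = 0, T = 20)
  tr <- backward_trajectory(f, 25, 112, "2024-05-05 07:00")
  expect_identical(attr(tr, "status"), "complete")
  expect_equal(format(attr(tr, "takeoff_time"), "%H"), "19")
  # 12 h at 10 m/s westward: delta lon = 432 km / (111.32 km/deg * cos 25)
  dlon_expect <- 432000 / (111320 * cos(25 * pi / 180))
  ep <- tr[nrow(tr), ]
  expect_equal(ep$lat, 25)
  expect_equal(ep$lon, 112 - dlon_expect, tolerance = 0.005 * dlon_expect / 112)
  err_pct <- abs((112 - ep$lon) - dlon_expect) / dlon_expect * 100
  expect_lt(err_pct, 0.5)
  # timestamps strictly decreasing, uniform spacing
  expect_true(all(diff(as.numeric(tr$time)) == -360))
})

test_that("zero wind leaves the endpoint at the start and finds same-day dusk", {
  f <- uniform_field(u = 0, v = 0)
  tr <- backward_trajectory(f, 25, 112, "2024-05-05 22:00")
  expect_equal(tr$lat[nrow(tr)], 25)
  expect_equal(tr$lon[nrow(tr)], 112)
  expect_equal(format(attr(tr, "takeoff_time"), "%Y-%m-%d %H"), "2024-05-05 19")
  expect_equal(nrow(tr), 31)  # 3 h at 6-min steps, inclusive
})

test_that("temperature below the 16.5 C flight floor truncates immediately", {
  f <- uniform_field(T = 10)
  tr <- backward_trajectory(f, 25, 112, "2024-05-05 07:00")
  expect_identical(attr(tr, "status"), "truncated_temp")
  expect_equal(nrow(tr), 1)
  expect_equal(nrow(takeoff_endpoints(list(tr))), 0)
})

test_that("trajectories leaving the spatial domain are flagged", {
  f <- gen_windfield("uniform", u = 30, v = 0, T_base = 20,
                     lat_range = c(24, 26), lon_range = c(111, 113),
                     time_range = c("2024-05-01 00:00", "2024-05-08 00:00"))
  tr <- backward_trajectory(f, 25, 112, "2024-05-05 07:00")
  expect_identical(attr(tr, "status"), "exited_domain")
})

test_that("forward re-integration returns to the landing point (time reversal)", {
  # sheared rotational flow: position-dependent, so the scheme is exercised
  f <- gen_windfield("rotational", omega = 2e-5, center = c(25, 109),
                     time_range = c("2024-05-01 00:00", "2024-05-08 00:00"))
  tr <- backward_trajectory(f, 26.5, 111, "2024-05-05 05:00")
  expect_identical(attr(tr, "status"), "complete")
  ep <- tr[nrow(tr), ]
  fw <- forward_position(f, ep$lat, ep$lon,
                         attr(tr, "takeoff_time"), attr(tr, "landing_time"))
  expect_lt(planar_km(fw$lat, fw$lon, 26.5, 111), 2)
})

test_that("per-event launches cover the landing hours with durations 1-11 h", {
  f <- uniform_field(u = 5, v = 5)
  ev <- data.frame(site_id = "s", lat = 26.5, lon = 111,
                   date = "2024-05-05", count = 40)
  trs <- trajectories_for_event(f, ev)
  expect_length(trs, 11)
  durs <- vapply(trs, function(tr)
    as.numeric(attr(tr, "landing_time") - attr(tr, "takeoff_time"), units = "hours"),
    numeric(1))
  expect_equal(sort(unname(durs)), 1:11)
  expect_true(all(durs <= 24))
  eps <- takeoff_endpoints(trs, "e1")
  expect_equal(nrow(eps), 11)
  # southwesterly wind: all endpoints southwest of the trap
  expect_true(all(eps$lat < 26.5 & eps$lon < 111))
  # single landing hour
  cfg1 <- flight_config(landing_hours = 20)
  expect_length(trajectories_for_event(f, ev, cfg1), 1)
  # full window extends to 24 h
  cfgf <- flight_config(full_window = TRUE)
  durf <- vapply(trajectories_for_event(f, ev, cfgf), function(tr)
    as.numeric(attr(tr, "landing_time") - attr(tr, "takeoff_time"), units = "hours"),
    numeric(1))
  expect_equal(max(durf), 24)
})

test_that("endpoints come only from complete trajectories", {
  f <- uniform_field()
  ok <- backward_trajectory(f, 25, 112, "2024-05-05 22:00")
  cold <- backward_trajectory(uniform_field(T = 10), 25, 112, "2024-05-05 22:00")
  eps <- takeoff_endpoints(list(a = ok, b = cold), "mix")
  expect_equal(nrow(eps), 1)
  expect_equal(eps$landing_hour, "a")
  expect_equal(nrow(takeoff_endpoints(list())), 0)
})

test_that("takeoff always lands on the configured dusk hour across landing times", {
  f <- uniform_field(u = 3, v = 2)
  for (lt in c("2024-05-05 20:00", "2024-05-05 23:00", "2024-05-06 03:00",
               "2024-05-06 18:00", "2024-05-06 19:30")) {
    tr <- backward_trajectory(f, 26, 110, lt)
    expect_equal(format(attr(tr, "takeoff_time"), "%H:%M"), "19:00")
    dur <- as.numeric(attr(tr, "landing_time") - attr(tr, "takeoff_time"),
                      units = "hours")
    expect_true(dur > 0 && dur <= 24)
  }
})
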