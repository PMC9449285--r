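# Synthetic world generator: landscape coverage, user panel, log quirks,
# generative step model.

small_world <- function(seed = 77) {
  world_config(
    n_users = 10,
    dates = seq(as.Date("2019-10-01"), as.Date("2019-10-05"), by = 1),
    step_report_fraction = 0.3,
    seed = seed
  )
}

test_that("the landscape types every 100 m cell in the extent exactly once", {
  cfg <- small_world()
  land <- generate_landscape(cfg)
  ext <- cfg$extent
  n_expected <- round((ext$north - ext$south) * 1200) * round((ext$east - ext$west) * 800)
  expect_equal(nrow(land), n_expected)
  expect_equal(dplyr::n_distinct(land$mesh_code_100m), n_expected)
  expect_setequal(unique(land$reclassified_type), landuse_types())
  expect_equal(reclassify_landuse(land$original_type), land$reclassified_type)
  # the city core is high-rise
  clat <- (ext$south + ext$north) / 2
  clon <- (ext$west + ext$east) / 2
  core <- land[haversine_m(land$lat, land$lon, clat, clon) < 500, ]
  expect_true(mean(core$reclassified_type %in% c("high_rise", "roads", "railways")) > 0.9)
  # reproducible for a fixed config
  expect_identical(generate_landscape(cfg), land)
  # too-small extent is rejected
  tiny <- world_config(extent = list(south = 38.15, north = 38.16,
                                     west = 140.70, east = 140.72))
  expect_error(generate_landscape(tiny), class = "stepscape_config_error")
})

test_that("users get planted homes with doorsteps outside the masked cell", {
  cfg <- small_world()
  land <- generate_landscape(cfg)
  users <- generate_users(cfg, land)
  expect_equal(nrow(users), cfg$n_users)
  expect_equal(sum(users$reports_steps), round(cfg$step_report_fraction * cfg$n_users))
  # home point is the centroid of the planted 250 m cell
  expect_equal(mesh_code(users$home_lat, users$home_lon, "250m"),
               users$home_code_250m)
  # doorstep: same 250 m cell, different 100 m cell
  expect_equal(mesh_code(users$door_lat, users$door_lon, "250m"),
               users$home_code_250m)
  expect_true(all(mesh_code(users$door_lat, users$door_lon, "100m") !=
                    mesh_code(users$home_lat, users$home_lon, "100m")))
})

test_that("generated logs respect masking, ordering, and the sampling rate", {
  cfg <- small_world()
  land <- generate_landscape(cfg)
  users <- generate_users(cfg, land)
  logs <- generate_logs(users, cfg)
  # privacy masking: no emitted log in any user's home 100 m cell
  home100 <- mesh_code(users$home_lat, users$home_lon, "100m")
  log100 <- mesh_code(logs$lat, logs$lon, "100m")
  expect_false(any(log100 == home100[match(logs$uuid, users$uuid)]))
  # timestamps non-decreasing within a user
  by_user <- split(logs$timestamp, logs$uuid)
  expect_true(all(vapply(by_user, function(t) !is.unsorted(t), logical(1))))
  # mean logs per user-day within 10% of the configured mean
  per_day <- logs |>
    dplyr::count(.data$uuid, date = as.Date(.data$timestamp, tz = "UTC"))
  expect_lt(abs(mean(per_day$n) - cfg$mean_logs_per_day) / cfg$mean_logs_per_day, 0.1)
  # day-start/day-end logs concentrate in the home 250 m cell so residence
  # recovery is possible
  first_last <- logs |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$uuid, .data$date) |>
    dplyr::slice(c(1, dplyr::n())) |>
    dplyr::ungroup()
  at_home <- mesh_code(first_last$lat, first_last$lon, "250m") ==
    users$home_code_250m[match(first_last$uuid, users$uuid)]
  expect_gt(mean(at_home), 0.6)
})

test_that("step generation follows the model equation and its variances", {
  zero <- function(x) rep(0, length(x))
  flat <- stats::setNames(rep(list(zero), 8), landuse_types())
  mk_records <- function(uuid, n) {
    recs <- tibble::tibble(uuid = uuid,
                           date = seq(as.Date("2019-10-01"), by = 1, length.out = n))
    for (tt in landuse_types()) recs[[tt]] <- 0L
    recs
  }
  # no noise, zero smooths, no attributes: y = beta0 exactly
  cfg0 <- world_config(alpha = 7000, beta_sex = 0, beta_age = 0,
                       sigma_l1 = 0, sigma_l2 = 0, smooths = flat, seed = 5)
  users <- tibble::tibble(uuid = "u1", sex = "unknown", age_group = "unknown",
                          beta0 = 7000)
  out <- generate_steps(mk_records("u1", 5), users, cfg0)
  expect_equal(out$steps, rep(7000, 5))

  # attribute contributions enter linearly
  cfgb <- world_config(alpha = 7000, beta_sex = -800, beta_age = -20,
                       sigma_l1 = 0, sigma_l2 = 0, smooths = flat, seed = 5)
  users_f <- tibble::tibble(uuid = "u1", sex = "female", age_group = "40s",
                            beta0 = 7000)
  recs <- mk_records("u1", 2)
  recs$sex <- "female"; recs$age_group <- "40s"
  out_f <- generate_steps(recs, users_f, cfgb)
  expect_equal(out_f$steps, rep(7000 - 800 - 20 * 40, 2))

  # within-user daily variance approximates sigma_l1^2 (Monte-Carlo)
  cfg1 <- world_config(alpha = 20000, beta_sex = 0, beta_age = 0,
                       sigma_l1 = 2000, sigma_l2 = 0, smooths = flat, seed = 6)
  out1 <- generate_steps(mk_records("u1", 1000), users, cfg1)
  expect_lt(abs(var(out1$steps) - 2000^2) / 2000^2, 0.1)

  # across users, the variance of user means decomposes as
  # var(beta0) + sigma_l1^2 / n_days
  set.seed(8)
  n_u <- 400; n_d <- 20
  users_m <- tibble::tibble(uuid = sprintf("u%03d", 1:n_u),
                            sex = "unknown", age_group = "unknown",
                            beta0 = rnorm(n_u, 20000, 500))
  recs_m <- dplyr::bind_rows(lapply(users_m$uuid, function(u) mk_records(u, n_d)))
  out_m <- generate_steps(recs_m, users_m, cfg1)
  user_means <- tapply(out_m$steps, out_m$uuid, mean)
  expected <- var(users_m$beta0) + 2000^2 / n_d
  expect_lt(abs(var(user_means) - expected) / expected, 0.1)
})

test_that("the parametric exposure generator is reproducible and complete", {
  sim1 <- simulate_exposure_records(n_users = 20, n_days = 5,
                                    config = world_config(seed = 33))
  sim2 <- simulate_exposure_records(n_users = 20, n_days = 5,
                                    config = world_config(seed = 33))
  expect_identical(sim1$records, sim2$records)
  expect_equal(nrow(sim1$records), 100L)
  expect_true(all(!is.na(sim1$records$steps)))
  expect_true(all(sim1$records$steps >= 0))
  expect_true(all(sim1$records$sex %in% c("male", "female")))
})
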