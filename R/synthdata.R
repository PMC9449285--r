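# Synthetic world generator: a concentric city landscape on the 100 m
# grid, users with planted homes, GPS logs with the quirks of commercial
# data (irregular minute sampling, duplicate minutes, accuracy noise with a
# heavy tail, home-grid privacy masking), and daily step counts drawn from
# the step model used generatively.

# run expr with a fixed RNG state, restoring the caller's state after
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' True land-use partial-effect shapes used by the generator
#'
#' Piecewise-linear functions of `x = ln(count + 1)` giving each type's
#' contribution to daily steps: rising for high-rise, parks/public and
#' railway exposure, falling beyond a threshold for low-rise and factory
#' exposure, rise-then-fall for dense low-rise, flat for roads and other.
#' These are documented generator constants.
#'
#' @return Named list of 8 vectorized functions.
#' @export
true_smooths <- function() {
  list(
    high_rise      = function(x) 800 * pmax(x - 1, 0),
    dense_low_rise = function(x) 500 * pmin(x, 1.5) - 450 * pmax(x - 1.5, 0),
    low_rise       = function(x) -600 * pmax(x - 1, 0),
    factories      = function(x) -600 * pmax(x - 0.7, 0),
    parks_public   = function(x) 600 * x,
    roads          = function(x) rep(0, length(x)),
    railways       = function(x) 500 * x,
    other          = function(x) rep(0, length(x))
  )
}

#' Configuration of a synthetic world
#'
#' Bundles the study conditions: the spatial extent, the user panel, the
#' study dates, the true step-model parameters, and the sampling quirks of
#' the emulated commercial GPS feed. Defaults emulate a regional city
#' observed for one month with a storm on the second weekend.
#'
#' @param n_users Number of users; default 200.
#' @param dates Study dates; default October 1-31, 2019.
#' @param extent Named list `south, north, west, east` (degrees); default a
#'   24 km x 24 km box.
#' @param seed Base RNG seed for the whole world.
#' @param alpha,beta_sex,beta_age Grand mean and parametric coefficients of
#'   the true step model (steps; steps per SEX unit; steps per AGE decade).
#' @param sigma_l1,sigma_l2 Residual and between-user standard deviations
#'   (steps).
#' @param smooths Named list of true partial-effect functions; default
#'   [true_smooths()].
#' @param step_report_fraction Fraction of users carrying daily step counts
#'   with complete attributes; default 0.15.
#' @param mean_logs_per_day Mean raw logs per user-day; default 60.
#' @param noise_sd_m GPS positional noise standard deviation (m).
#' @param dup_rate Probability that a log minute is duplicated.
#' @param accuracy_tail_frac Fraction of logs with accuracy above the
#'   200 m filter threshold.
#' @param travel_radius_m Scale of daily destination distances (m).
#' @param storm_weekend Index (1-4) of the weekend whose mobility is
#'   suppressed, or `NA` for none; default 2.
#' @param storm_suppression Multiplier applied to travel distances on the
#'   storm weekend; default 0.25.
#' @param day_start_min,day_end_min Activity window, minutes from
#'   midnight; default 07:00-21:30.
#' @return A `world_config` list.
#' @export
world_config <- function(n_users = 200,
                         dates = seq(as.Date("2019-10-01"), as.Date("2019-10-31"), by = 1),
                         extent = list(south = 38.15, north = 38.35,
                                       west = 140.70, east = 141.00),
                         seed = 1,
                         alpha = 7700, beta_sex = -867.5, beta_age = -19.67,
                         sigma_l1 = 2000, sigma_l2 = 500,
                         smooths = true_smooths(),
                         step_report_fraction = 0.15,
                         mean_logs_per_day = 60,
                         noise_sd_m = 25,
                         dup_rate = 0.05,
                         accuracy_tail_frac = 0.08,
                         travel_radius_m = 4000,
                         storm_weekend = 2,
                         storm_suppression = 0.25,
                         day_start_min = 420, day_end_min = 1290) {
  stopifnot(sigma_l1 >= 0, sigma_l2 >= 0)
  structure(
    list(
      n_users = n_users, dates = dates, extent = extent, seed = seed,
      alpha = alpha, beta_sex = beta_sex, beta_age = beta_age,
      sigma_l1 = sigma_l1, sigma_l2 = sigma_l2, smooths = smooths,
      step_report_fraction = step_report_fraction,
      mean_logs_per_day = mean_logs_per_day,
      noise_sd_m = noise_sd_m, dup_rate = dup_rate,
      accuracy_tail_frac = accuracy_tail_frac,
      travel_radius_m = travel_radius_m,
      storm_weekend = storm_weekend, storm_suppression = storm_suppression,
      day_start_min = day_start_min, day_end_min = day_end_min
    ),
    class = "world_config"
  )
}

# metre offsets to degree offsets at a latitude
.m_to_deg_lat <- function(m) m / (.EARTH_RADIUS_M * pi / 180)
.m_to_deg_lon <- function(m, lat) m / (.EARTH_RADIUS_M * pi / 180 * cos(lat * pi / 180))

# representative original labels per reclassified type, so generated
# land-use tables exercise the reclassification step
.ORIGINAL_OF <- list(
  high_rise = "High-rise buildings",
  dense_low_rise = "Dense low-rise buildings",
  low_rise = "Low-rise buildings",
  factories = "Factories",
  parks_public = c("Public facilities", "Parks and green spaces"),
  roads = "Roads",
  railways = "Railways",
  other = c("Forests", "Rice fields", "Vacant lands", "Other fields")
)

#' Generate the synthetic land-use landscape
#'
#' A concentric city on the full 100 m lattice of the configured extent: a
#' high-rise core, a dense low-rise ring, a low-rise periphery, four radial
#' railway lines with high-rise station clusters, seeded park and factory
#' patches, a 1 km road lattice, and `other` elsewhere. Every 100 m cell in
#' the extent is typed exactly once.
#'
#' @param config A [world_config()].
#' @return A tibble `mesh_code_100m`, `original_type`, `reclassified_type`,
#'   `lat`, `lon` (cell centroids).
#' @export
generate_landscape <- function(config) {
  ext <- config$extent
  if ((ext$north - ext$south) * 120 < 20 || (ext$east - ext$west) * 80 < 20) {
    rlang::abort("extent must cover at least 20 x 20 one-km cells",
      class = "stepscape_config_error")
  }
  .with_seed(config$seed + 11L, {
    r0 <- floor(ext$south * 1200 + .MESH_EPS)
    r1 <- floor(ext$north * 1200 - .MESH_EPS)
    c0 <- floor(ext$west * 800 + .MESH_EPS)
    c1 <- floor(ext$east * 800 - .MESH_EPS)
    rows <- rep(r0:r1, times = c1 - c0 + 1L)
    cols <- rep(c0:c1, each = r1 - r0 + 1L)
    lat <- (rows + 0.5) / 1200
    lon <- (cols + 0.5) / 800
    clat <- (ext$south + ext$north) / 2
    clon <- (ext$west + ext$east) / 2
    d <- haversine_m(lat, lon, clat, clon)

    type <- rep("other", length(rows))
    type[d < 7000] <- "low_rise"
    type[d < 3000] <- "dense_low_rise"
    type[d < 1200] <- "high_rise"
    # 1 km road lattice
    type[rows %% 10L == 5L | cols %% 10L == 5L] <- "roads"
    # factory patches in the periphery
    n_fact <- 3L
    fd <- runif(n_fact, 5500, 8500)
    fth <- runif(n_fact, 0, 2 * pi)
    flat <- clat + .m_to_deg_lat(fd * sin(fth))
    flon <- clon + .m_to_deg_lon(fd * cos(fth), clat)
    for (i in seq_len(n_fact)) {
      type[haversine_m(lat, lon, flat[i], flon[i]) < 400] <- "factories"
    }
    # park / public-space patches
    n_park <- 10L
    pd <- runif(n_park, 1000, 7000)
    pth <- runif(n_park, 0, 2 * pi)
    plat <- clat + .m_to_deg_lat(pd * sin(pth))
    plon <- clon + .m_to_deg_lon(pd * cos(pth), clat)
    for (i in seq_len(n_park)) {
      type[haversine_m(lat, lon, plat[i], plon[i]) < 220] <- "parks_public"
    }
    # radial railways with station clusters every ~1.6 km
    rc <- floor(clat * 1200 + .MESH_EPS)
    cc <- floor(clon * 800 + .MESH_EPS)
    on_line <- (rows == rc | cols == cc) & d <= 9000
    stations <- expand.grid(k = c(-5:-1, 1:5), axis = c("ns", "ew"))
    st_rows <- ifelse(stations$axis == "ns", rc + 16L * stations$k, rc)
    st_cols <- ifelse(stations$axis == "ns", cc, cc + 16L * stations$k)
    near_station <- rep(FALSE, length(rows))
    for (i in seq_along(st_rows)) {
      near_station <- near_station |
        (abs(rows - st_rows[i]) <= 1L & abs(cols - st_cols[i]) <= 1L)
    }
    type[near_station] <- "high_rise"
    type[on_line] <- "railways"

    original <- vapply(type, function(tt) {
      opts <- .ORIGINAL_OF[[tt]]
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, character(1), USE.NAMES = FALSE)

    tibble::tibble(
      mesh_code_100m = .mesh_from_indices(rows, cols, "100m"),
      original_type = original,
      reclassified_type = type,
      lat = lat, lon = lon
    )
  })
}

#' Generate the synthetic user panel
#'
#' Homes are planted in residential (dense low-rise / low-rise) 250 m grid
#' squares between 1.5 and 6.5 km from the city centre; the home point is
#' the centroid of the planted 250 m cell and the "doorstep" anchor is
#' ~110 m away, inside the same 250 m cell but outside the home 100 m cell,
#' so day-start/day-end logs survive the privacy masking and make residence
#' recovery possible. A configured fraction of users
#' reports daily step counts with complete sex/age; the remainder is mostly
#' attribute-missing.
#'
#' @param config A [world_config()].
#' @param landscape Output of [generate_landscape()].
#' @return A tibble: `uuid`, `home_code_250m`, `home_lat`, `home_lon`,
#'   `door_lat`, `door_lon`, `sex`, `age_group`, `reports_steps`, `beta0`.
#' @export
generate_users <- function(config, landscape) {
  .with_seed(config$seed + 23L, {
    ext <- config$extent
    clat <- (ext$south + ext$north) / 2
    clon <- (ext$west + ext$east) / 2
    resid <- landscape |>
      dplyr::filter(.data$reclassified_type %in% c("dense_low_rise", "low_rise")) |>
      dplyr::mutate(d = haversine_m(.data$lat, .data$lon, clat, clon)) |>
      dplyr::filter(.data$d >= 1500, .data$d <= 6500)
    # homes cluster in residential neighborhoods around sampled anchors,
    # emulating clustered housing density (otherwise no 500 m grid would
    # reach the disclosure threshold at desk scale)
    n_hood <- 12L
    anchors <- resid[sample.int(nrow(resid), n_hood), ]
    hood <- sample.int(n_hood, config$n_users, replace = TRUE)
    hlat <- anchors$lat[hood] + .m_to_deg_lat(rnorm(config$n_users, 0, 150))
    hlon <- anchors$lon[hood] +
      .m_to_deg_lon(rnorm(config$n_users, 0, 150), anchors$lat[hood])
    home_code <- mesh_code(hlat, hlon, "250m")
    ctr <- mesh_centroid(home_code, "250m")

    # doorstep: nearest cardinal offset that leaves the home 100 m cell but
    # stays inside the home 250 m cell
    door <- purrr::map(seq_len(nrow(ctr)), function(i) {
      hlat <- ctr$lat[i]; hlon <- ctr$lon[i]
      home100 <- mesh_code(hlat, hlon, "100m")
      cand <- list(
        c(hlat, hlon + .m_to_deg_lon(110, hlat)),
        c(hlat + .m_to_deg_lat(95), hlon),
        c(hlat, hlon - .m_to_deg_lon(110, hlat)),
        c(hlat - .m_to_deg_lat(95), hlon)
      )
      for (p in cand) {
        if (mesh_code(p[1], p[2], "100m") != home100 &&
            mesh_code(p[1], p[2], "250m") == home_code[i]) return(p)
      }
      cand[[1]]
    })
    door <- do.call(rbind, door)

    n <- config$n_users
    n_wc <- round(config$step_report_fraction * n)
    reports_steps <- rep(FALSE, n)
    reports_steps[sample.int(n, n_wc)] <- TRUE
    sex <- ifelse(runif(n) < 0.6, "unknown",
                  ifelse(runif(n) < 0.55, "male", "female"))
    age_group <- rep("unknown", n)
    wc <- which(reports_steps)
    sex[wc] <- ifelse(runif(n_wc) < 0.55, "male", "female")
    age_group[wc] <- sample(c("10s", "20s", "30s", "40s", "50s", "60s"),
                            n_wc, replace = TRUE,
                            prob = c(0.06, 0.30, 0.28, 0.22, 0.10, 0.04))
    # a few awkward records so attribute filters have work to do
    if (n_wc >= 10L) {
      age_group[wc[1]] <- "70plus"
      sex[wc[2]] <- "unknown"
    }
    tibble::tibble(
      uuid = sprintf("u%04d", seq_len(n)),
      home_code_250m = home_code,
      home_lat = ctr$lat, home_lon = ctr$lon,
      door_lat = door[, 1], door_lon = door[, 2],
      sex = sex, age_group = age_group,
      reports_steps = reports_steps,
      beta0 = rnorm(n, config$alpha, config$sigma_l2)
    )
  })
}

# dates of the storm weekend under this config, or empty
.storm_dates <- function(config) {
  if (is.na(config$storm_weekend)) return(as.Date(character(0)))
  pairs <- default_weekend_pairs()
  if (config$storm_weekend < 1 || config$storm_weekend > length(pairs)) {
    return(as.Date(character(0)))
  }
  pairs[[config$storm_weekend]]
}

# one user-day of raw logs; returns a data frame or NULL
.day_logs <- function(user, date, config, clat, clon) {
  t0 <- config$day_start_min
  t1 <- config$day_end_min
  window <- t1 - t0
  suppress <- if (date %in% .storm_dates(config)) config$storm_suppression else 1

  # anchor schedule: doorstep -> destinations -> doorstep
  n_dest <- sample(1:3, 1L)
  dest <- matrix(0, n_dest, 2)
  for (j in seq_len(n_dest)) {
    if (runif(1) < 0.5) { # downtown trip
      dest[j, ] <- c(clat + .m_to_deg_lat(rnorm(1, 0, 700)),
                     clon + .m_to_deg_lon(rnorm(1, 0, 700), clat))
    } else {
      dd <- runif(1, 500, config$travel_radius_m)
      th <- runif(1, 0, 2 * pi)
      dest[j, ] <- c(user$door_lat + .m_to_deg_lat(dd * sin(th)),
                     user$door_lon + .m_to_deg_lon(dd * cos(th), user$door_lat))
    }
  }
  # storm suppression contracts the day's travel toward the doorstep
  dest[, 1] <- user$door_lat + (dest[, 1] - user$door_lat) * suppress
  dest[, 2] <- user$door_lon + (dest[, 2] - user$door_lon) * suppress
  morning <- t0 + runif(1, 30, 70)
  evening <- t1 - runif(1, 30, 70)
  travel <- 35
  away <- evening - morning - travel * (n_dest + 1)
  dwell <- away * as.vector(stats::rmultinom(1, 100, rep(1, n_dest))) / 100
  wt <- c(t0, morning)
  wlat <- c(user$door_lat, user$door_lat)
  wlon <- c(user$door_lon, user$door_lon)
  cur <- morning
  for (j in seq_len(n_dest)) {
    cur <- cur + travel
    wt <- c(wt, cur); wlat <- c(wlat, dest[j, 1]); wlon <- c(wlon, dest[j, 2])
    cur <- cur + dwell[j]
    wt <- c(wt, cur); wlat <- c(wlat, dest[j, 1]); wlon <- c(wlon, dest[j, 2])
  }
  wt <- c(wt, evening, t1)
  wlat <- c(wlat, user$door_lat, user$door_lat)
  wlon <- c(wlon, user$door_lon, user$door_lon)

  # irregular minute sampling: geometric gaps with the configured mean
  mean_gap <- window / config$mean_logs_per_day
  n_draw <- ceiling(config$mean_logs_per_day * 2.5)
  gaps <- 1L + stats::rgeom(n_draw, 1 / mean_gap)
  minutes <- t0 + cumsum(gaps)
  minutes <- minutes[minutes <= t1]
  if (!length(minutes)) return(NULL)

  lat <- stats::approx(wt, wlat, xout = minutes, rule = 2)$y
  lon <- stats::approx(wt, wlon, xout = minutes, rule = 2)$y

  # duplicate minutes
  dup <- which(runif(length(minutes)) < config$dup_rate)
  minutes <- c(minutes, minutes[dup])
  lat <- c(lat, lat[dup])
  lon <- c(lon, lon[dup])
  ord <- order(minutes)
  minutes <- minutes[ord]; lat <- lat[ord]; lon <- lon[ord]

  m <- length(minutes)
  lat <- lat + .m_to_deg_lat(rnorm(m, 0, config$noise_sd_m))
  lon <- lon + .m_to_deg_lon(rnorm(m, 0, config$noise_sd_m), lat)
  acc <- ifelse(runif(m) < config$accuracy_tail_frac,
                runif(m, 200, 500),
                stats::rlnorm(m, log(30), 0.5))
  data.frame(minute_of_day = minutes, lat = lat, lon = lon, accuracy_m = acc)
}

#' Generate raw GPS logs for the user panel
#'
#' Emits minute-resolution logs along anchor-based daily paths (doorstep ->
#' destinations -> doorstep) with irregular geometric gaps, Gaussian
#' positional noise, duplicate minutes, accuracy values with a tail above
#' the 200 m filter threshold, and home-grid privacy masking: no emitted
#' log lies inside the 100 m grid square containing the user's home point.
#'
#' @param users Output of [generate_users()].
#' @param config A [world_config()].
#' @return A raw-log tibble (`uuid`, `timestamp`, `lat`, `lon`,
#'   `accuracy_m`, `sex`, `age_group`, `daily_steps` = NA).
#' @export
generate_logs <- function(users, config) {
  ext <- config$extent
  clat <- (ext$south + ext$north) / 2
  clon <- (ext$west + ext$east) / 2
  .with_seed(config$seed + 37L, {
    out <- vector("list", nrow(users) * length(config$dates))
    idx <- 0L
    for (i in seq_len(nrow(users))) {
      user <- users[i, ]
      home100 <- mesh_code(user$home_lat, user$home_lon, "100m")
      for (d in seq_along(config$dates)) {
        date <- config$dates[d]
        day <- .day_logs(user, date, config, clat, clon)
        if (is.null(day)) next
        # privacy masking: drop logs inside the home 100 m grid square
        keep <- mesh_code(day$lat, day$lon, "100m") != home100
        day <- day[keep, , drop = FALSE]
        if (!nrow(day)) next
        idx <- idx + 1L
        day$uuid <- user$uuid
        day$date <- date
        out[[idx]] <- day
      }
    }
    all <- dplyr::bind_rows(out[seq_len(idx)])
    tibble::tibble(
      uuid = all$uuid,
      timestamp = lubridate::as_datetime(all$date) + 60 * all$minute_of_day,
      lat = all$lat, lon = all$lon,
      accuracy_m = all$accuracy_m,
      sex = users$sex[match(all$uuid, users$uuid)],
      age_group = users$age_group[match(all$uuid, users$uuid)],
      daily_steps = NA_real_
    )
  })
}

#' Generate daily step counts from the true model
#'
#' Applies the generative step model to per user-day exposure counts:
#' `y = b0_u + b1 SEX + b2 AGE + sum_k s_k(ln(count_k + 1)) + eps`, with
#' `eps ~ N(0, sigma_l1^2)` per day, floored at zero. Missing sex/age
#' contribute nothing.
#'
#' @param records Exposure-count tibble (`uuid`, `date`, 8 count columns,
#'   plus `sex`, `age_group` if present).
#' @param users User tibble carrying `beta0` (and `sex`, `age_group` used
#'   as fallback).
#' @param config A [world_config()].
#' @return The records with a `steps` column.
#' @export
generate_steps <- function(records, users, config) {
  .with_seed(config$seed + 53L, {
    m <- match(records$uuid, users$uuid)
    beta0 <- users$beta0[m]
    sexv <- if ("sex" %in% names(records)) records$sex else users$sex[m]
    agev <- if ("age_group" %in% names(records)) records$age_group else users$age_group[m]
    sx <- .sex_code(sexv)
    ag <- .age_code(agev)
    sx[is.na(sx)] <- 0
    ag[is.na(ag)] <- 0
    mu <- beta0 + config$beta_sex * sx + config$beta_age * ag
    for (type in landuse_types()) {
      mu <- mu + config$smooths[[type]](log(records[[type]] + 1))
    }
    records$steps <- pmax(0, mu + rnorm(nrow(records), 0, config$sigma_l1))
    records
  })
}

#' Simulate a complete synthetic world
#'
#' Generates the landscape, the user panel, and the raw log table; computes
#' the step-reporting users' true daily exposure from their own emitted
#' logs against the landscape; draws their daily step counts from the true
#' model; and stamps those counts onto their logs.
#'
#' @param config A [world_config()].
#' @return A list: `logs` (raw log tibble), `landuse` (land-use tibble),
#'   `users` (truth: planted homes, attributes, `beta0`), `config`.
#' @export
simulate_world <- function(config = world_config()) {
  landscape <- generate_landscape(config)
  users <- generate_users(config, landscape)
  logs <- generate_logs(users, config)

  wc_ids <- users$uuid[users$reports_steps]
  wc_logs <- dplyr::filter(logs, .data$uuid %in% wc_ids)
  index <- build_cell_index(landscape)
  pts <- dedupe_minute(wc_logs)
  true_exposure <- compute_exposure(pts, index)
  true_exposure <- generate_steps(true_exposure, users, config)

  logs <- logs |>
    dplyr::mutate(date = .log_date(.data$timestamp)) |>
    dplyr::left_join(dplyr::select(true_exposure, "uuid", "date", "steps"),
                     by = c("uuid", "date")) |>
    dplyr::mutate(daily_steps = .data$steps) |>
    dplyr::select(-"steps", -"date")

  list(
    logs = logs,
    landuse = dplyr::select(landscape, "mesh_code_100m", "original_type"),
    users = users,
    true_exposure = true_exposure,
    config = config
  )
}

#' Simulate exposure records directly (no trajectories)
#'
#' Draws per user-day exposure counts from negative-binomial distributions
#' and daily steps from the true model -- the fast generator used for
#' model parameter-recovery studies where the trajectory machinery is not
#' under test.
#'
#' @param n_users,n_days Panel dimensions.
#' @param config A [world_config()] supplying the model truth.
#' @param count_means Named per-type negative-binomial means.
#' @param nb_size Negative-binomial dispersion parameter.
#' @return A list: `records` (exposure records with `steps`, `sex`,
#'   `age_group`), `users` (with `beta0`).
#' @export
simulate_exposure_records <- function(n_users = 200, n_days = 20,
                                      config = world_config(),
                                      count_means = c(
                                        high_rise = 12, dense_low_rise = 18,
                                        low_rise = 25, factories = 4,
                                        parks_public = 6, roads = 40,
                                        railways = 5, other = 60
                                      ),
                                      nb_size = 1.2) {
  .with_seed(config$seed + 71L, {
    users <- tibble::tibble(
      uuid = sprintf("u%04d", seq_len(n_users)),
      sex = ifelse(runif(n_users) < 0.45, "female", "male"),
      age_group = sample(c("10s", "20s", "30s", "40s", "50s", "60s"),
                         n_users, replace = TRUE),
      beta0 = rnorm(n_users, config$alpha, config$sigma_l2)
    )
    n <- n_users * n_days
    records <- tibble::tibble(
      uuid = rep(users$uuid, each = n_days),
      date = rep(seq(as.Date("2019-10-01"), by = 1, length.out = n_days),
                 times = n_users),
      sex = rep(users$sex, each = n_days),
      age_group = rep(users$age_group, each = n_days)
    )
    for (type in landuse_types()) {
      records[[type]] <- rnbinom(n, mu = count_means[[type]], size = nb_size)
    }
    records <- generate_steps(records, users, config)
    records <- dplyr::relocate(records, "uuid", "date", "steps", "sex", "age_group")
    list(records = records, users = users)
  })
}

#' Write a raw-log tibble as a delimited log table
#'
#' Writes the external log-table schema (`uuid, year, month, day, hour,
#' minute, lat, lon, accuracy_m, sex, age_group, daily_steps`).
#'
#' @param logs In-memory raw-log tibble.
#' @param path Output path (csv).
#' @return The path, invisibly.
#' @export
write_gps_logs <- function(logs, path) {
  out <- tibble::tibble(
    uuid = logs$uuid,
    year = lubridate::year(logs$timestamp),
    month = lubridate::month(logs$timestamp),
    day = lubridate::mday(logs$timestamp),
    hour = lubridate::hour(logs$timestamp),
    minute = lubridate::minute(logs$timestamp),
    lat = logs$lat, lon = logs$lon,
    accuracy_m = logs$accuracy_m,
    sex = logs$sex, age_group = logs$age_group,
    daily_steps = logs$daily_steps
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
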