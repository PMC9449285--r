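# Step-count GAM: exposure transform, OLS reduction, null-model behaviour,
# fixed-effects prediction, smooth extraction, tidiers.

# small parametric worlds for model tests
null_config <- function(seed = 1) {
  zero <- function(x) rep(0, length(x))
  world_config(
    seed = seed, alpha = 7000, beta_sex = 0, beta_age = 0,
    sigma_l1 = 2000, sigma_l2 = 0,
    smooths = stats::setNames(rep(list(zero), 8), landuse_types())
  )
}

test_that("exposure transform is ln(count + 1)", {
  recs <- tibble::tibble(uuid = "u", date = as.Date("2019-10-01"))
  for (tt in landuse_types()) recs[[tt]] <- 0L
  recs$high_rise <- 1L
  recs$parks_public <- 10L
  out <- transform_exposure(recs)
  expect_equal(out$x_high_rise, log(2))
  expect_equal(out$x_parks_public, log(11))
  expect_equal(out$x_roads, 0)
  # monotone
  expect_gt(out$x_parks_public, out$x_high_rise)
  recs$roads <- -1L
  expect_error(transform_exposure(recs), class = "stepscape_domain_error")
})

test_that("without random intercept and a single linear term the fit is OLS", {
  set.seed(41)
  n <- 120
  recs <- tibble::tibble(
    uuid = sprintf("u%02d", rep(1:12, each = 10)),
    date = rep(seq(as.Date("2019-10-01"), by = 1, length.out = 10), 12),
    sex = "male", age_group = "30s"
  )
  for (tt in landuse_types()) recs[[tt]] <- 5L  # constant -> drops out
  recs$parks_public <- sample(c(0L, 2L, 7L), n, replace = TRUE)  # 3 values -> linear
  x <- log(recs$parks_public + 1)
  recs$steps <- 6000 + 800 * x + rnorm(n, 0, 300)
  fit <- fit_step_model(recs, include_sex_age = FALSE, random_intercept = FALSE)
  ols <- stats::lm(recs$steps ~ x)
  pred <- predict_fixed(fit, recs)
  expect_equal(pred$predicted_steps, unname(stats::fitted(ols)), tolerance = 1e-6)
  expect_equal(fit$term_kind[["parks_public"]], "linear")
  expect_equal(fit$term_kind[["high_rise"]], "constant")
})

test_that("a null world fits near-zero smooths and near-zero deviance explained", {
  sim <- simulate_exposure_records(n_users = 80, n_days = 10, config = null_config(3))
  fit <- fit_step_model(sim$records)
  expect_lt(fit$deviance_explained, 0.05)
  expect_gte(fit$deviance_explained, 0)
  for (tt in landuse_types()) {
    cur <- smooth_curve(fit, tt)
    # smooths stay below a noise-scaled tolerance at this panel size
    expect_lt(max(abs(cur$estimate)), 0.3 * sqrt(fit$sigma2_l1))
    expect_true(all(is.finite(cur$lower) & is.finite(cur$upper)))
  }
  # with 8 smooths at the 5% level, at most a couple can be spuriously
  # significant on null data
  td <- tidy(fit)
  expect_lte(sum(td$significant[td$kind == "smooth"]), 2L)
  # refitting the same data gives identical coefficients (determinism)
  fit2 <- fit_step_model(sim$records)
  expect_equal(coef(fit$gam), coef(fit2$gam), tolerance = 1e-10)
})

test_that("fixed-effects predictions ignore user, sex, age, and record order", {
  sim <- simulate_exposure_records(n_users = 40, n_days = 8,
                                   config = world_config(seed = 9))
  fit <- fit_step_model(sim$records)
  recs <- sim$records[1:20, ]
  base <- predict_fixed(fit, recs)
  # relabelling users does not change predictions
  relab <- dplyr::mutate(recs, uuid = rev(.data$uuid))
  expect_equal(predict_fixed(fit, relab)$predicted_steps, base$predicted_steps)
  # changing sex/age does not change predictions
  reattr <- dplyr::mutate(recs, sex = "female", age_group = "60s")
  expect_equal(predict_fixed(fit, reattr)$predicted_steps, base$predicted_steps)
  # permuting record order permutes predictions identically
  perm <- sample(nrow(recs))
  expect_equal(predict_fixed(fit, recs[perm, ])$predicted_steps,
               base$predicted_steps[perm])
  # identical exposure counts give identical predictions for any user
  dup <- recs[c(1, 1), ]
  dup$uuid <- c("zz1", "zz2")
  pd <- predict_fixed(fit, dup)
  expect_equal(pd$predicted_steps[1], pd$predicted_steps[2])

  # linear-algebra oracle: alpha + smooth columns of the design matrix
  g <- fit$gam
  dat <- transform_exposure(recs)
  newdat <- data.frame(SEX = 0, AGE = 0,
                       uuid = factor(fit$user_intercepts$uuid[1],
                                     levels = fit$user_intercepts$uuid))
  newdat <- newdat[rep(1, nrow(dat)), , drop = FALSE]
  for (tt in landuse_types()) newdat[[paste0("x_", tt)]] <- dat[[paste0("x_", tt)]]
  Xp <- predict(g, newdata = newdat, type = "lpmatrix")
  keep <- grepl("^s\\(x_", colnames(Xp)) | colnames(Xp) %in% paste0("x_", landuse_types())
  manual <- fit$alpha + unname(drop(Xp[, keep, drop = FALSE] %*% coef(g)[keep]))
  expect_equal(base$predicted_steps, manual, tolerance = 1e-8)

  expect_error(predict_fixed(list(), recs), class = "stepscape_state_error")
})

test_that("smooth curves have finite bands that widen toward sparse range edges", {
  sim <- simulate_exposure_records(n_users = 60, n_days = 10,
                                   config = world_config(seed = 13))
  fit <- fit_step_model(sim$records)
  cur <- smooth_curve(fit, "high_rise")
  expect_true(all(is.finite(cur$estimate) & is.finite(cur$se)))
  expect_true(all(cur$upper >= cur$lower))
  # negative-binomial draws are dense at low x and sparse near the top of
  # the range, so the band at the upper edge exceeds the band at the median
  mid_se <- cur$se[which.min(abs(cur$x - stats::median(log(sim$records$high_rise + 1))))]
  expect_gt(cur$se[nrow(cur)], mid_se)
})

test_that("deviance explained rises when a truly informative smooth is added", {
  sim <- simulate_exposure_records(n_users = 60, n_days = 10,
                                   config = world_config(seed = 17))
  full <- fit_step_model(sim$records)
  flat <- sim$records
  flat$high_rise <- 3L  # remove the strongest signal
  flat$parks_public <- 3L
  flat$railways <- 3L
  reduced <- fit_step_model(flat)
  expect_gte(full$deviance_explained, reduced$deviance_explained)
  expect_true(full$deviance_explained >= 0 && full$deviance_explained <= 1)
})

test_that("tidy and glance report terms, variance components, and significance", {
  sim <- simulate_exposure_records(n_users = 60, n_days = 10,
                                   config = world_config(seed = 19))
  fit <- fit_step_model(sim$records)
  td <- tidy(fit)
  expect_setequal(td$term[td$kind == "parametric"], c("SEX", "AGE"))
  expect_equal(sum(td$kind == "smooth"), 8L)
  expect_equal(td$significant, td$p.value < 0.05)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_gt(gl$sigma_l1, 0)
  expect_gte(gl$sigma_l2, 0)
  expect_equal(gl$n_users, 60)
  # serialization round trip
  path <- withr::local_tempfile(fileext = ".rds")
  write_step_model(fit, path)
  fit2 <- read_step_model(path)
  expect_equal(glance(fit2), gl)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
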