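# Random-intercept GAM of daily steps on land-use exposure:
#   y_ud = b0_u + b1 SEX + b2 AGE + sum_k s_k(x_udk) + eps_ud
#   eps_ud ~ N(0, sigma2_L1),  b0_u ~ N(alpha, sigma2_L2),
#   x_udk = ln(LANDUSE_udk + 1)
# Fitted by penalized likelihood (REML) with centered penalized cubic
# regression splines per land-use type and the user intercept as a Gaussian
# variance component.

#' Log-transform exposure counts
#'
#' Adds the exposure index `x_<type> = ln(count + 1)` for each of the 8
#' land-use types.
#'
#' @param records Exposure-record tibble with the 8 count columns.
#' @return The tibble with 8 additional `x_*` columns.
#' @export
transform_exposure <- function(records) {
  for (type in landuse_types()) {
    cnt <- records[[type]]
    if (any(cnt < 0, na.rm = TRUE)) {
      rlang::abort(paste0("negative exposure count in '", type, "'"),
        class = "stepscape_domain_error")
    }
    records[[paste0("x_", type)]] <- log(cnt + 1)
  }
  records
}

#' Fit the step-count model
#'
#' Fits the Gaussian random-intercept GAM of daily steps on log exposure.
#' Each land-use type gets a centered penalized cubic regression spline on
#' `ln(count + 1)`; the per-user intercept is a Gaussian random effect;
#' smoothing parameters and variance components are selected by REML.
#' A type whose exposure index has too few distinct values for a spline
#' basis enters linearly instead, and a constant index drops out (its
#' smooth is identically zero).
#'
#' @param records Model-set exposure records ([split_model_data()]
#'   `$with_steps`): observed `steps`, known `sex` and `age_group`
#'   (70 years and over excluded).
#' @param k Spline basis dimension per smooth; default 10.
#' @param bs mgcv smooth basis class; default `"cr"` (cubic regression
#'   spline).
#' @param include_sex_age Include the parametric SEX (1 = female, 0 = male)
#'   and AGE (10..60) terms; default `TRUE`.
#' @param random_intercept Include the per-user Gaussian random intercept;
#'   default `TRUE`. With `FALSE` the between-user variance component is
#'   fixed at zero and the model is purely fixed-effects.
#' @return A `step_model` object; see [glance.step_model()] and
#'   [tidy.step_model()].
#' @export
fit_step_model <- function(records, k = 10, bs = "cr", include_sex_age = TRUE,
                           random_intercept = TRUE) {
  records <- transform_exposure(records)
  if (random_intercept && dplyr::n_distinct(records$uuid) < 2L) {
    rlang::abort("need at least two users to estimate a random intercept",
      class = "stepscape_state_error")
  }
  dat <- data.frame(
    steps = records$steps,
    SEX = .sex_code(records$sex),
    AGE = .age_code(records$age_group),
    uuid = factor(records$uuid)
  )
  term_kind <- character(0)
  terms <- character(0)
  for (type in landuse_types()) {
    xn <- paste0("x_", type)
    dat[[xn]] <- records[[xn]]
    nu <- dplyr::n_distinct(records[[xn]])
    if (nu >= 4L) {
      kt <- min(k, nu - 1L)
      terms <- c(terms, sprintf("s(%s, bs = \"%s\", k = %d)", xn, bs, kt))
      term_kind[type] <- "smooth"
    } else if (nu >= 2L) {
      terms <- c(terms, xn)
      term_kind[type] <- "linear"
    } else {
      term_kind[type] <- "constant"
    }
  }
  fixed <- if (include_sex_age) c("SEX", "AGE") else character(0)
  re_term <- if (random_intercept) "s(uuid, bs = \"re\")" else character(0)
  rhs <- paste(c(fixed, terms, re_term), collapse = " + ")
  fml <- stats::as.formula(paste("steps ~", rhs))
  g <- mgcv::gam(fml, data = dat, method = "REML")
  if (any(!is.finite(coef(g)))) {
    bad <- names(coef(g))[!is.finite(coef(g))]
    rlang::abort(paste0("rank-deficient design; unidentifiable terms: ",
                        paste(unique(bad), collapse = ", ")),
      class = "stepscape_state_error")
  }
  sp_re <- g$sp[grepl("s\\(uuid\\)", names(g$sp))]
  sigma2_l2 <- if (length(sp_re)) unname(g$sig2 / sp_re) else 0
  re_idx <- grep("^s\\(uuid\\)", names(coef(g)))
  alpha <- unname(coef(g)[["(Intercept)"]])
  user_int <- tibble::tibble(
    uuid = levels(dat$uuid),
    intercept = alpha + if (length(re_idx)) unname(coef(g)[re_idx]) else 0
  )
  ranges <- purrr::map(stats::setNames(landuse_types(), landuse_types()),
                       \(type) range(dat[[paste0("x_", type)]]))
  structure(
    list(
      gam = g,
      term_kind = term_kind,
      alpha = alpha,
      beta_sex = if (include_sex_age) unname(coef(g)[["SEX"]]) else NA_real_,
      beta_age = if (include_sex_age) unname(coef(g)[["AGE"]]) else NA_real_,
      sigma2_l1 = unname(g$sig2),
      sigma2_l2 = sigma2_l2,
      user_intercepts = user_int,
      deviance_explained = unname(summary(g)$dev.expl),
      train_ranges = ranges,
      n_users = dplyr::n_distinct(records$uuid),
      n_obs = nrow(records)
    ),
    class = "step_model"
  )
}

#' @export
print.step_model <- function(x, ...) {
  cat("<step_model> random-intercept GAM of daily steps on land-use exposure\n")
  cat(sprintf("  %d records of %d users\n", x$n_obs, x$n_users))
  cat(sprintf("  deviance explained: %.1f%%\n", 100 * x$deviance_explained))
  cat(sprintf("  sigma_L1 (residual sd): %.1f steps\n", sqrt(x$sigma2_l1)))
  cat(sprintf("  sigma_L2 (between-user sd): %.1f steps\n", sqrt(x$sigma2_l2)))
  invisible(x)
}

# smooth label for a land-use type, e.g. "s(x_high_rise)"
.smooth_label <- function(type) paste0("s(x_", type, ")")

#' Fixed-effects step-count prediction
#'
#' Predicts daily steps for exposure records using only the grand
#' intercept and the land-use smooths: `alpha + sum_k s_k(x_k)`. Sex, age,
#' and user intercepts are ignored, so predictions depend on exposure
#' alone and apply to users without step data. Exposure indices outside the
#' training range are evaluated by the spline's natural extrapolation, with
#' a warning stating how many values fell outside.
#'
#' @param fit A `step_model`.
#' @param records Exposure-record tibble (counts required; `steps` may be
#'   absent or missing).
#' @return A tibble `uuid`, `date`, `predicted_steps`.
#' @export
predict_fixed <- function(fit, records) {
  if (!inherits(fit, "step_model")) {
    rlang::abort("predict_fixed needs a fitted step_model",
      class = "stepscape_state_error")
  }
  records <- transform_exposure(records)
  n_out <- 0L
  n <- nrow(records)
  newdat <- data.frame(
    SEX = rep(0, n), AGE = rep(0, n),
    uuid = factor(rep(fit$user_intercepts$uuid[1], n),
                  levels = fit$user_intercepts$uuid)
  )
  for (type in landuse_types()) {
    xn <- paste0("x_", type)
    x <- records[[xn]]
    r <- fit$train_ranges[[type]]
    n_out <- n_out + sum(x < r[1] | x > r[2])
    newdat[[xn]] <- x
  }
  if (n_out > 0) {
    rlang::warn(paste0(n_out, " exposure value(s) outside the training range; ",
                       "spline extrapolation used"))
  }
  tm <- predict(fit$gam, newdata = newdat, type = "terms")
  keep <- colnames(tm) %in% c(.smooth_label(landuse_types()),
                              paste0("x_", landuse_types()))
  pred <- fit$alpha + rowSums(tm[, keep, drop = FALSE])
  tibble::tibble(
    uuid = records$uuid,
    date = records$date,
    predicted_steps = unname(pred)
  )
}

#' Evaluate a fitted land-use smooth with confidence band
#'
#' @param fit A `step_model`.
#' @param type One of [landuse_types()].
#' @param x Grid of exposure-index values; default 100 points over the
#'   training range.
#' @return A tibble `x`, `estimate`, `se`, `lower`, `upper` (pointwise 95%
#'   band from the coefficient covariance).
#' @export
smooth_curve <- function(fit, type, x = NULL) {
  type <- match.arg(type, landuse_types())
  if (is.null(x)) {
    r <- fit$train_ranges[[type]]
    x <- seq(r[1], r[2], length.out = 100)
  }
  xn <- paste0("x_", type)
  kind <- fit$term_kind[[type]]
  g <- fit$gam
  if (kind == "smooth") {
    labels <- vapply(g$smooth, function(s) s$label, character(1))
    sm <- g$smooth[[match(.smooth_label(type), labels)]]
    df <- stats::setNames(data.frame(x), xn)
    X <- mgcv::PredictMat(sm, df)
    idx <- sm$first.para:sm$last.para
    est <- drop(X %*% coef(g)[idx])
    se <- sqrt(pmax(0, rowSums((X %*% g$Vp[idx, idx, drop = FALSE]) * X)))
  } else if (kind == "linear") {
    b <- coef(g)[[xn]]
    se_b <- sqrt(diag(g$Vp))[[match(xn, names(coef(g)))]]
    est <- b * x
    se <- abs(x) * se_b
  } else {
    est <- rep(0, length(x))
    se <- rep(0, length(x))
  }
  tibble::tibble(x = x, estimate = est, se = se,
                 lower = est - 1.96 * se, upper = est + 1.96 * se)
}

#' Tidy the step-count model
#'
#' One row per model term: parametric SEX/AGE coefficients with Wald
#' confidence intervals, and one row per land-use smooth with effective
#' degrees of freedom and the approximate p-value (Wald-type test on the
#' penalized coefficients; a smooth is flagged significant at p < 0.05).
#'
#' @param x A `step_model`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `kind`, `estimate`, `std.error`,
#'   `edf`, `statistic`, `p.value`, `significant`.
#' @export
tidy.step_model <- function(x, ...) {
  s <- summary(x$gam)
  pt <- s$p.table
  par_terms <- intersect(rownames(pt), c("SEX", "AGE"))
  par <- tibble::tibble(
    term = par_terms,
    kind = "parametric",
    estimate = pt[par_terms, "Estimate"],
    std.error = pt[par_terms, "Std. Error"],
    edf = NA_real_,
    statistic = pt[par_terms, "t value"],
    p.value = pt[par_terms, "Pr(>|t|)"]
  )
  st <- s$s.table
  sm_terms <- setdiff(rownames(st), "s(uuid)")
  sm <- tibble::tibble(
    term = sm_terms,
    kind = "smooth",
    estimate = NA_real_,
    std.error = NA_real_,
    edf = st[sm_terms, "edf"],
    statistic = st[sm_terms, "F"],
    p.value = st[sm_terms, "p-value"]
  )
  out <- dplyr::bind_rows(par, sm)
  out$significant <- out$p.value < 0.05
  out
}

#' One-row model summary
#'
#' @param x A `step_model`.
#' @param ... Unused.
#' @return A one-row tibble: `deviance_explained`, `alpha`, `beta_sex`,
#'   `beta_age`, `sigma_l1`, `sigma_l2`, `n_users`, `n_obs`.
#' @export
glance.step_model <- function(x, ...) {
  tibble::tibble(
    deviance_explained = x$deviance_explained,
    alpha = x$alpha,
    beta_sex = x$beta_sex,
    beta_age = x$beta_age,
    sigma_l1 = sqrt(x$sigma2_l1),
    sigma_l2 = sqrt(x$sigma2_l2),
    n_users = x$n_users,
    n_obs = x$n_obs
  )
}

#' Plot the fitted land-use smooths
#'
#' @param object A `step_model`.
#' @param ... Unused.
#' @return A ggplot faceting the 8 fitted smooths with 95% bands.
#' @export
autoplot.step_model <- function(object, ...) {
  curves <- purrr::map_dfr(stats::setNames(landuse_types(), landuse_types()),
                           \(type) smooth_curve(object, type), .id = "type")
  curves$type <- factor(curves$type, levels = landuse_types())
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~type, scales = "free_x") +
    ggplot2::labs(x = "ln(visit frequency + 1)", y = "partial effect on daily steps")
}

#' Serialize / restore a fitted step model
#'
#' The file is a single self-describing artifact holding the fitted model,
#' training ranges, and variance components.
#'
#' @param fit A `step_model`.
#' @param path File path.
#' @return `read_step_model` returns the `step_model`.
#' @export
write_step_model <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_step_model
#' @export
read_step_model <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "step_model")) {
    rlang::abort("file does not contain a step_model", class = "stepscape_state_error")
  }
  fit
}
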