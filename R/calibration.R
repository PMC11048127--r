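#' Construct a calibration curve from known coefficients
#'
#' An affine concentration-to-frequency map `y = slope * x + intercept`
#' with `x` in cells/mL and `y` in GHz. Use [fit_calibration()] to
#' estimate one from data; this constructor builds one directly from
#' published or assumed coefficients (fit diagnostics are then `NA`).
#'
#' @param slope GHz per cells/mL.
#' @param intercept GHz.
#' @param r_squared,residual_sd,n_points Optional fit diagnostics.
#' @return An object of class `calibration_curve`.
#' @examples
#' calibration_curve(-0.02506e-6, -1.65475)
#' @export
calibration_curve <- function(slope, intercept, r_squared = NA_real_,
                              residual_sd = NA_real_,
                              n_points = NA_integer_) {
  check_scalar(slope, "slope")
  check_scalar(intercept, "intercept")
  structure(
    list(
      slope = slope, intercept = intercept,
      r_squared = r_squared, residual_sd = residual_sd,
      n_points = n_points,
      sensitivity_hz = abs(slope) * 1e9,
      x_mean = NA_real_, s_xx = NA_real_, fit = NULL
    ),
    class = "calibration_curve"
  )
}

#' Reference calibration of the evaporation-endpoint assay
#'
#' The published concentration-frequency line of the K562
#' evaporation-endpoint assay this package models:
#' `y = -0.02506e-6 * x - 1.65475` (GHz, cells/mL), i.e. a sensitivity
#' of 25.06 Hz per cells/mL at 1 uL sample volume. The two linearity
#' figures quoted alongside it (r^2 of 0.99748 and 0.98464) are carried
#' as metadata only — the raw replicate measurements behind them are
#' not available, so neither is recomputable here.
#'
#' @return A [calibration_curve()] with attribute
#'   `r_squared_reported`.
#' @examples
#' sensitivity_hz(reference_calibration()) # 25.06
#' @export
reference_calibration <- function() {
  cc <- calibration_curve(slope = -0.02506e-6, intercept = -1.65475)
  attr(cc, "r_squared_reported") <- c(abstract = 0.99748, fit = 0.98464)
  cc
}

#' Fit the concentration-frequency calibration line
#'
#' Ordinary least squares of endpoint resonant frequency on cell
#' concentration. Replicates enter individually by default;
#' `average_replicates = TRUE` regresses per-concentration means
#' instead. `r^2` is the squared Pearson correlation of observed and
#' fitted response.
#'
#' @param data A data frame with columns `concentration_cells_per_ml`
#'   and `f_res_ghz` (a `replicate` column is allowed and ignored by
#'   the fit), e.g. from [simulate_endpoint_dataset()] or
#'   [read_measurement_csv()].
#' @param average_replicates Fit per-concentration means instead of
#'   individual replicates.
#' @return A `calibration_curve` carrying slope (GHz per cells/mL),
#'   intercept (GHz), `r_squared`, `residual_sd`, `n_points`,
#'   `sensitivity_hz`, and the underlying `lm` fit.
#' @examples
#' tbl <- simulate_endpoint_dataset(endpoint_sim_config(noise_sd = 0))
#' fit_calibration(tbl)$sensitivity_hz # 25.06
#' @export
fit_calibration <- function(data, average_replicates = FALSE) {
  stopifnot(is.data.frame(data))
  need <- c("concentration_cells_per_ml", "f_res_ghz")
  if (!all(need %in% names(data))) {
    abort(paste("`data` must contain columns:", paste(need, collapse = ", ")))
  }
  if (average_replicates) {
    data <- data |>
      dplyr::group_by(.data$concentration_cells_per_ml) |>
      dplyr::summarise(f_res_ghz = mean(.data$f_res_ghz), .groups = "drop")
  }
  x <- data$concentration_cells_per_ml
  y <- data$f_res_ghz
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("non-finite values in the measurement table.")
  }
  if (length(unique(x)) < 2L) {
    abort("rank-deficient calibration: need >= 2 distinct concentrations.")
  }
  fit <- lm(f_res_ghz ~ concentration_cells_per_ml, data = data)
  cf <- coef(fit)
  n <- nrow(data)
  resid_sd <- if (n > 2L) sqrt(sum(fit$residuals^2) / (n - 2L)) else 0
  r2 <- stats::cor(y, fitted(fit))^2
  if (stats::var(fitted(fit)) == 0) r2 <- NA_real_
  out <- calibration_curve(
    slope = unname(cf[2L]), intercept = unname(cf[1L]),
    r_squared = r2, residual_sd = resid_sd, n_points = n
  )
  out$x_mean <- mean(x)
  out$s_xx <- sum((x - mean(x))^2)
  out$fit <- fit
  out
}

#' Assay sensitivity in Hz per cells/mL
#'
#' The absolute calibration slope converted from GHz to Hz per unit
#' concentration; sign-insensitive.
#'
#' @param curve A `calibration_curve`.
#' @return Sensitivity (Hz per cells/mL).
#' @examples
#' sensitivity_hz(calibration_curve(-1e-8, 0)) # 10
#' @export
sensitivity_hz <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  abs(curve$slope) * 1e9
}

#' Predict endpoint frequency from concentration
#'
#' @param curve A `calibration_curve`.
#' @param concentration Cells/mL, finite and >= 0, vectorised.
#' @return Predicted frequency (GHz).
#' @examples
#' predict_frequency(reference_calibration(), 1e6) # -1.67981
#' @export
predict_frequency <- function(curve, concentration) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    abort("`concentration` must be finite and >= 0.")
  }
  curve$slope * concentration + curve$intercept
}

#' Invert a measured frequency to a concentration estimate
#'
#' Inverse prediction `x_hat = (y_obs - intercept) / slope` with a
#' first-order (delta-method) confidence interval propagating the
#' residual standard deviation and design moments of the fit:
#' `Var(x_hat) ~ (s^2 / slope^2) * (1 + 1/n + (x_hat - x_bar)^2 / S_xx)`
#' with a t quantile on `n - 2` degrees of freedom. Curves built
#' directly from coefficients (no fit) return `NA` intervals. Negative
#' estimates are clipped to 0 and flagged; the unclipped value and
#' interval are retained.
#'
#' @param curve A `calibration_curve`; `|slope|` must exceed `tol`.
#' @param y_obs Observed frequency(ies), GHz.
#' @param level Confidence level, default 0.95.
#' @param tol Smallest invertible `|slope|`.
#' @return A tibble: `y_obs_ghz`, `estimate`, `estimate_raw`,
#'   `conf_low`, `conf_high`, `clipped`.
#' @examples
#' cc <- reference_calibration()
#' invert_concentration(cc, predict_frequency(cc, 2e6))$estimate # 2e6
#' @export
invert_concentration <- function(curve, y_obs, level = 0.95, tol = 1e-300) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || abs(curve$slope) <= tol) {
    abort("non-invertible calibration: |slope| is below tolerance.")
  }
  if (any(!is.finite(y_obs))) abort("`y_obs` must be finite.")
  x_hat <- (y_obs - curve$intercept) / curve$slope
  se <- rep(NA_real_, length(x_hat))
  q <- NA_real_
  has_fit <- !is.null(curve$fit) && is.finite(curve$residual_sd) &&
    is.finite(curve$s_xx) && curve$s_xx > 0 && curve$n_points > 2L
  if (has_fit) {
    n <- curve$n_points
    se <- (curve$residual_sd / abs(curve$slope)) *
      sqrt(1 + 1 / n + (x_hat - curve$x_mean)^2 / curve$s_xx)
    q <- qt(1 - (1 - level) / 2, df = n - 2L)
  }
  tibble(
    y_obs_ghz = y_obs,
    estimate = pmax(x_hat, 0),
    estimate_raw = x_hat,
    conf_low = x_hat - q * se,
    conf_high = x_hat + q * se,
    clipped = x_hat < 0
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve>\n")
  cat(sprintf("  y (GHz) = %.6g * x (cells/mL) + %.6g\n", x$slope, x$intercept))
  cat(sprintf("  sensitivity: %.4g Hz per cells/mL\n", x$sensitivity_hz))
  if (is.finite(x$r_squared)) {
    cat(sprintf("  r^2 = %.5f on %d points (residual SD %.3g GHz)\n",
                x$r_squared, x$n_points, x$residual_sd))
  }
  invisible(x)
}

#' Tidiers for calibration curves
#'
#' `tidy()` returns per-coefficient estimates (with standard errors
#' when the curve was fitted); `glance()` returns one-row model
#' diagnostics including the derived sensitivity.
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  if (!is.null(x$fit)) {
    sm <- summary(x$fit)$coefficients
    tibble(
      term = c("intercept", "slope"),
      estimate = unname(sm[, 1]),
      std.error = unname(sm[, 2]),
      statistic = unname(sm[, 3]),
      p.value = unname(sm[, 4])
    )
  } else {
    tibble(
      term = c("intercept", "slope"),
      estimate = c(x$intercept, x$slope),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
    )
  }
}

#' @rdname tidy.calibration_curve
#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, sigma = x$residual_sd,
    nobs = x$n_points, slope = x$slope, intercept = x$intercept,
    sensitivity_hz = x$sensitivity_hz
  )
}

#' Plot a fitted calibration curve
#'
#' @param object A fitted `calibration_curve`.
#' @param ... Unused.
#' @return A ggplot of the replicate measurements and the fitted line.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  if (is.null(object$fit)) {
    abort("autoplot needs a fitted curve (see fit_calibration()).")
  }
  df <- as_tibble(object$fit$model)
  ggplot2::ggplot(df, ggplot2::aes(.data$concentration_cells_per_ml,
                                   .data$f_res_ghz)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept) +
    ggplot2::labs(x = "Concentration (cells/mL)",
                  y = "Endpoint resonant frequency (GHz)")
}
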