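#' Baranyi–Roberts growth model
#'
#' Log-density at time `t` under the Baranyi–Roberts model with explicit lag.
#' The adjusted time is
#' \deqn{A(t) = t + \frac{1}{\mu_{max}} \ln\!\left(e^{-\mu_{max} t} +
#'   e^{-h_0} - e^{-\mu_{max} t - h_0}\right)}
#' and the log-density
#' \deqn{y(t) = y_0 + \mu_{max} A(t) - \ln\!\left(1 +
#'   \frac{e^{\mu_{max} A(t)} - 1}{e^{y_{max} - y_0}}\right).}
#' The lag time is the standard identity `h0 / mu_max`.
#'
#' @param t_h time(s) in hours.
#' @param mu_max maximum specific growth rate, 1/h (must be >= 0).
#' @param h0 dimensionless lag parameter (product of lag and `mu_max`).
#' @param y0_ln,ymax_ln natural log of initial and maximal OD600.
#' @return numeric vector of ln(OD600) values; `y(0) = y0_ln`, monotone
#'   non-decreasing, approaching `ymax_ln` as `t` grows.
#' @examples
#' baranyi_log_od(0:24, mu_max = 0.5, h0 = 0.5 * 8.9,
#'                y0_ln = log(0.01), ymax_ln = log(1.5))
#' @export
baranyi_log_od <- function(t_h, mu_max, h0, y0_ln, ymax_ln) {
  check_number(t_h, "t_h", min = 0)
  check_scalar(mu_max, "mu_max", min = 0)
  check_scalar(h0, "h0", min = 0)
  check_scalar(y0_ln, "y0_ln")
  check_scalar(ymax_ln, "ymax_ln")
  if (ymax_ln < y0_ln) abort("`ymax_ln` must be >= `y0_ln`")
  baranyi_core(t_h, mu_max, h0, y0_ln, ymax_ln)
}

# unchecked model evaluation, shared with the optimizer (which may probe
# parameter combinations the public interface rejects)
baranyi_core <- function(t_h, mu_max, h0, y0_ln, ymax_ln) {
  if (mu_max == 0) return(rep(y0_ln, length(t_h)))
  at <- t_h + log(exp(-mu_max * t_h) + exp(-h0) - exp(-mu_max * t_h - h0)) /
    mu_max
  b <- mu_max * at
  # log(1 + (e^b - 1)/E) evaluated in log space so late times do not
  # overflow: equals logsumexp(log(E - 1), b) - log(E)
  log_e <- ymax_ln - y0_ln
  if (log_e <= 0) return(rep(ymax_ln, length(t_h)))
  log_em1 <- log(expm1(log_e))
  m <- pmax(log_em1, b)
  term <- m + log(exp(log_em1 - m) + exp(b - m)) - log_e
  y0_ln + b - term
}

#' Predict ln(OD600) from a fitted growth model
#'
#' @param fit a `growth_fit` object from [fit_growth()].
#' @param t_h times in hours.
#' @return numeric vector of predicted ln(OD600).
#' @export
baranyi_predict <- function(fit, t_h) {
  stopifnot(inherits(fit, "growth_fit"))
  baranyi_log_od(t_h, fit$mu_max_per_h, fit$h0, fit$y0_ln, fit$ymax_ln)
}

#' Fit the Baranyi–Roberts model to an OD600 time series
#'
#' Nonlinear least squares on ln(OD600) with multi-start initial values, used
#' to extract the maximum specific growth rate and lag time from droplet or
#' bulk growth curves. Lag is reported as `h0 / mu_max`. A series with no
#' detectable growth is returned as `mu_max = 0` with `constant = TRUE` and
#' lag reported as 0.
#'
#' @param data data frame with one row per time point.
#' @param time,od column names (unquoted) holding times in hours and OD600.
#' @return a `growth_fit` object: fields `mu_max_per_h`, `lag_h`, `y0_ln`,
#'   `ymax_ln`, `h0`, `rss`, `n`, `constant`. `tidy()` and `glance()` methods
#'   are provided.
#' @examples
#' tb <- generate_growth_series(
#'   strain_params("pm", lag_h = 8.9, mu_max_per_h = 0.6),
#'   times_h = seq(0, 48, by = 2), noise_sd = 0, seed = 1)
#' fit_growth(tb)
#' @export
fit_growth <- function(data, time = time_h, od = od600) {
  t_h <- dplyr::pull(data, {{ time }})
  od_v <- dplyr::pull(data, {{ od }})
  check_number(t_h, "time", min = 0)
  check_number(od_v, "od", min = .Machine$double.xmin)
  if (length(t_h) < 6) abort("need at least 6 time points to fit growth")
  if (is.unsorted(t_h, strictly = TRUE)) abort("times must be strictly increasing")
  y <- log(od_v)

  if (sd(y) < 1e-8 || diff(range(y)) < 1e-6) {
    return(new_growth_fit(mu_max = 0, h0 = 0, y0_ln = mean(y),
                          ymax_ln = mean(y), rss = sum((y - mean(y))^2),
                          n = length(y), constant = TRUE))
  }

  # slope scan over successive segments gives mu and lag starting values
  slopes <- diff(y) / diff(t_h)
  mu0 <- max(slopes)
  i_max <- which.max(slopes)
  t_mid <- (t_h[i_max] + t_h[i_max + 1]) / 2
  y_mid <- (y[i_max] + y[i_max + 1]) / 2
  lag0 <- max(t_mid - (y_mid - min(y)) / mu0, 0)

  starts <- expand.grid(mu = mu0 * c(0.5, 1, 2),
                        lag = c(lag0, max(lag0 * 0.25, 0.1),
                                lag0 + diff(range(t_h)) * 0.1))
  y0s <- min(y)
  ymaxs <- max(y)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(mu = starts$mu[i], h0 = starts$mu[i] * starts$lag[i],
               y0_ln = y0s, ymax_ln = ymaxs)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ baranyi_core(t_h, mu, h0, y0_ln, ymax_ln),
        start = st,
        lower = c(mu = 1e-6, h0 = 0, y0_ln = y0s - 5, ymax_ln = y0s),
        upper = c(mu = 100, h0 = 1e4, y0_ln = ymaxs, ymax_ln = ymaxs + 5),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(coef = coef(fit), rss = rss)
    }
  }
  if (is.null(best)) abort("growth fit failed to converge from all starts")
  cf <- best$coef
  new_growth_fit(mu_max = unname(cf["mu"]), h0 = unname(cf["h0"]),
                 y0_ln = unname(cf["y0_ln"]), ymax_ln = unname(cf["ymax_ln"]),
                 rss = best$rss, n = length(y), constant = FALSE)
}

new_growth_fit <- function(mu_max, h0, y0_ln, ymax_ln, rss, n, constant) {
  structure(list(mu_max_per_h = mu_max,
                 lag_h = if (mu_max > 0) h0 / mu_max else 0,
                 h0 = h0, y0_ln = y0_ln, ymax_ln = ymax_ln,
                 rss = rss, n = n, constant = constant),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Baranyi-Roberts growth fit\n")
  cat(sprintf("  mu_max: %.4f /h   lag: %.2f h   h0: %.3f\n",
              x$mu_max_per_h, x$lag_h, x$h0))
  cat(sprintf("  y0 (OD): %.4f   ymax (OD): %.4f   RSS: %.3g   n: %d%s\n",
              exp(x$y0_ln), exp(x$ymax_ln), x$rss, x$n,
              if (x$constant) "   [no growth detected]" else ""))
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("mu_max_per_h", "lag_h", "h0", "y0_ln", "ymax_ln"),
         estimate = c(x$mu_max_per_h, x$lag_h, x$h0, x$y0_ln, x$ymax_ln))
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, constant = x$constant)
}

#' @describeIn fit_growth plot the data with the fitted curve overlaid.
#' @param object a `growth_fit`.
#' @param data optional data frame of observed points (`time_h`, `od600`).
#' @param ... ignored.
#' @export
autoplot.growth_fit <- function(object, data = NULL, ...) {
  tt <- seq(0, if (!is.null(data)) max(data$time_h) else
              4 * object$lag_h + 10, length.out = 200)
  curve_tb <- tibble(time_h = tt, od600 = exp(baranyi_predict(object, tt)))
  p <- ggplot2::ggplot(curve_tb, ggplot2::aes(.data$time_h, .data$od600)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "OD600",
                  title = sprintf("mu_max = %.3f /h, lag = %.1f h",
                                  object$mu_max_per_h, object$lag_h))
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = data)
  }
  p
}
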