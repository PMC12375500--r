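## CETSA melt-curve analysis: Boltzmann sigmoid fitting of soluble fraction
## vs temperature, melting-temperature (Tm) confidence intervals, and
## between-condition shift assessment. The Tm is always reported as the
## inflection temperature of the fitted sigmoid.

#' Fit a Boltzmann melt curve
#'
#' Least-squares fit of
#' `f(T) = bottom + (top - bottom)/(1 + exp((T - tm)/slope))` to soluble
#' fraction vs temperature (nonlinear least squares with Levenberg-
#' Marquardt; initial values from the data extremes, the temperature
#' nearest the half-height, and a small grid over slopes). The melting
#' temperature is the inflection point `tm`; its confidence interval is
#' asymptotic (t quantile on the fit covariance).
#'
#' @param data data frame with `temperature` and `fraction` columns
#'   (>= 5 points, non-constant, showing a descending transition).
#' @param conf_level confidence level for the Tm interval (default 0.95).
#' @param ci_method `"asymptotic"` (default) or `"bootstrap"`
#'   (residual resampling).
#' @param n_boot bootstrap draws when `ci_method = "bootstrap"`.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `melt_fit`: list with `top`, `bottom`, `tm`,
#'   `slope`, `tm_se`, `tm_ci`, `r2`, `fitted`, `residuals`, `data`,
#'   `conf_level`.
#' @export
fit_melt <- function(data, conf_level = 0.95,
                     ci_method = c("asymptotic", "bootstrap"),
                     n_boot = 499, seed = 1) {
  ci_method <- match.arg(ci_method)
  if (!all(c("temperature", "fraction") %in% names(data)))
    stop("data needs 'temperature' and 'fraction' columns")
  ## average duplicate temperatures are allowed; fit uses all points
  tt <- data$temperature
  ff <- data$fraction
  ok <- is.finite(tt) & is.finite(ff)
  tt <- tt[ok]; ff <- ff[ok]
  if (length(tt) < 5) stop("need at least 5 data points to fit a melt curve")
  if (stats::sd(ff) == 0) stop("fractions are constant; no melt transition to fit")
  mono <- stats::aggregate(ff, list(tt), mean)
  mono <- mono[order(mono[[1]]), ]
  if (all(diff(mono$x) >= 0))
    stop("fractions increase with temperature; no melting transition")

  top0 <- max(ff); bottom0 <- min(ff)
  mid <- (top0 + bottom0) / 2
  tm0 <- tt[which.min(abs(ff - mid))]
  df_fit <- data.frame(T = tt, y = ff)

  best <- NULL
  for (sl in c(0.5, 1, 2, 4)) {
    for (tmi in unique(c(tm0, stats::quantile(tt, c(0.25, 0.5, 0.75))))) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + exp((T - tm) / slope)),
          data = df_fit,
          start = list(top = top0, bottom = bottom0, tm = tmi, slope = sl),
          lower = c(top = -Inf, bottom = -Inf, tm = min(tt), slope = 1e-3),
          upper = c(top = Inf, bottom = Inf, tm = max(tt), slope = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss - 1e-12)
          best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) stop("melt-curve fit failed to converge")
  fit <- best$fit
  cf <- stats::coef(fit)
  if (cf[["bottom"]] > cf[["top"]]) {
    ## negative-slope parameterisation reached the mirrored optimum; reject
    stop("fit converged to an ascending curve; no melting transition")
  }
  rss <- best$rss
  tss <- sum((ff - mean(ff))^2)
  r2 <- 1 - rss / tss
  dfree <- length(ff) - 4L
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  tm_se <- if (!is.null(vc)) sqrt(vc["tm", "tm"]) else NA_real_

  if (ci_method == "asymptotic") {
    tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = max(dfree, 1))
    ci <- cf[["tm"]] + c(-1, 1) * tcrit * tm_se
  } else {
    set.seed(seed)
    res <- stats::resid(fit)
    fitted0 <- stats::fitted(fit)
    tms <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      yb <- fitted0 + sample(res, replace = TRUE)
      fb <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + exp((T - tm) / slope)),
          data = data.frame(T = tt, y = yb),
          start = as.list(cf),
          lower = c(top = -Inf, bottom = -Inf, tm = min(tt), slope = 1e-3),
          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (!is.null(fb)) tms[b] <- stats::coef(fb)[["tm"]]
    }
    ci <- unname(stats::quantile(tms, c((1 - conf_level) / 2,
                                        1 - (1 - conf_level) / 2), na.rm = TRUE))
  }

  out <- list(
    top = unname(cf[["top"]]), bottom = unname(cf[["bottom"]]),
    tm = unname(cf[["tm"]]), slope = unname(cf[["slope"]]),
    tm_se = unname(tm_se), tm_ci = c(lower = ci[1], upper = ci[2]),
    r2 = r2, rss = rss,
    fitted = stats::fitted(fit), residuals = stats::resid(fit),
    data = data.frame(temperature = tt, fraction = ff),
    conf_level = conf_level
  )
  class(out) <- "melt_fit"
  out
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("Boltzmann melt-curve fit\n")
  cat(sprintf("  Tm     : %.2f degC (%d%% CI %.2f - %.2f)\n", x$tm,
              round(100 * x$conf_level), x$tm_ci[1], x$tm_ci[2]))
  cat(sprintf("  slope  : %.3f degC\n", x$slope))
  cat(sprintf("  top    : %.3f   bottom : %.3f\n", x$top, x$bottom))
  cat(sprintf("  r^2    : %.4f on %d points\n", x$r2, nrow(x$data)))
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom, tm = object$tm,
    slope = object$slope)
}

#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$data$temperature else newdata$temperature
  boltzmann(tt, object$top, object$bottom, object$tm, object$slope)
}

#' @export
plot.melt_fit <- function(x, ...) {
  tt <- seq(min(x$data$temperature), max(x$data$temperature), length.out = 200)
  plot(x$data$temperature, x$data$fraction,
       xlab = "Temperature (degC)", ylab = "Soluble fraction", ...)
  graphics::lines(tt, boltzmann(tt, x$top, x$bottom, x$tm, x$slope))
  graphics::abline(v = x$tm, lty = 2)
  invisible(x)
}

#' Compare two melting temperatures
#'
#' `delta_tm = tm_b - tm_a`; the conditions' Tm confidence intervals are
#' checked for overlap, and `stabilized` is `TRUE` when the shift is
#' positive with non-overlapping intervals.
#'
#' @param fit_a,fit_b `melt_fit` objects (or lists with `tm` and `tm_ci`).
#' @return list: `tm_a`, `tm_b`, `delta_tm`, `ci_overlap`, `stabilized`.
#' @export
compare_tm <- function(fit_a, fit_b) {
  delta <- fit_b$tm - fit_a$tm
  overlap <- fit_a$tm_ci[1] <= fit_b$tm_ci[2] && fit_b$tm_ci[1] <= fit_a$tm_ci[2]
  list(tm_a = fit_a$tm, tm_b = fit_b$tm, delta_tm = delta,
       ci_overlap = unname(overlap),
       stabilized = unname(delta > 0 && !overlap))
}
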