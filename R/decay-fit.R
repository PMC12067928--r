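#' Half-lifetime from a first-order decay rate
#'
#' Under the one-phase decay model `I(t) = amplitude * exp(-k * t) + plateau`
#' the signal falls halfway to its plateau in `T_1/2 = ln(2) / k` minutes.
#'
#' @param rate_k Decay rate constant, per minute; must be > 0.
#' @return Half-lifetime in minutes.
#' @export
#' @examples
#' half_life_from_rate(log(2) / 10)  # 10 minutes
half_life_from_rate <- function(rate_k) {
  if (!is.numeric(rate_k) || any(!is.finite(rate_k)) || any(rate_k <= 0))
    stop("rate_k must be a positive finite decay rate (per minute)")
  log(2) / rate_k
}

#' Control parameters for the decay fitter
#'
#' @param sse_tol Relative tolerance on the residual sum of squares used as
#'   the convergence criterion of the Levenberg-Marquardt optimizer.
#' @param max_evals Maximum number of model evaluations.
#' @return A list of class `decay_control`.
#' @export
decay_control <- function(sse_tol = 1e-10, max_evals = 10000L) {
  stopifnot(sse_tol > 0, max_evals >= 1)
  structure(list(sse_tol = sse_tol, max_evals = as.integer(max_evals)),
            class = "decay_control")
}

# Derivative-free starting values: plateau from the trace minimum, amplitude
# from the span, rate from the log-linear slope of the first half of the
# background-subtracted trace.
.decay_start <- function(times, intensities) {
  p0 <- min(intensities)
  a0 <- max(intensities) - p0
  n <- length(times)
  half <- seq_len(max(4L, ceiling(n / 2)))
  y <- intensities[half] - p0
  ok <- y > 0
  k0 <- NA_real_
  if (sum(ok) >= 2) {
    tt <- times[half][ok]; ly <- log(y[ok])
    sl <- sum((tt - mean(tt)) * (ly - mean(ly))) / sum((tt - mean(tt))^2)
    if (is.finite(sl) && sl < 0) k0 <- -sl
  }
  if (!is.finite(k0) || k0 <= 0) k0 <- log(2) / (diff(range(times)) / 4)
  c(amplitude = a0, rate_k = k0, plateau = p0)
}

#' Fit the one-phase decay model to a chemiluminescence trace
#'
#' Fits `I(t) = amplitude * exp(-rate_k * t) + plateau` to a single well's
#' intensity time series by unweighted nonlinear least squares
#' (Levenberg-Marquardt, via \pkg{minpack.lm}) and reports the decay
#' half-lifetime `T_1/2 = ln(2) / rate_k`, the feature used throughout the
#' downstream screening and classification stages.
#'
#' The amplitude is constrained to be non-negative and the rate positive;
#' the plateau is unconstrained in sign since detector baselines can dip
#' below zero. Optimizer failures are reported through `converged = FALSE`
#' (with the optimizer message retained), never as an exception; genuinely
#' unusable inputs — fewer than 4 points, non-finite intensities, or a flat
#' trace whose rate is not identifiable — are errors.
#'
#' @param times Acquisition times in minutes, strictly increasing, >= 0.
#'   Alternatively a list or data frame with components `times`/`time_min`
#'   and `intensities`/`intensity`, in which case `intensities` is ignored.
#' @param intensities Chemiluminescence intensities (arbitrary units), same
#'   length as `times`.
#' @param control A [decay_control()] list.
#' @return An object of class `decay_fit` with components `amplitude`,
#'   `plateau`, `rate_k` (per minute), `half_life` (minutes), `rss`,
#'   `converged`, `message`, fitted values and residuals. Supported methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
#'   `simulate`, `deviance`.
#' @export
#' @examples
#' t <- seq(5, 180, by = 5)
#' fit <- fit_decay(t, 1000 * exp(-log(2) / 10 * t) + 50)
#' fit$half_life  # 10 minutes
fit_decay <- function(times, intensities = NULL, control = decay_control()) {
  if (is.list(times) && is.null(intensities)) {
    intensities <- if (!is.null(times$intensities)) times$intensities
                   else times$intensity
    times <- if (!is.null(times$times)) times$times else times$time_min
  }
  times <- as.numeric(times); intensities <- as.numeric(intensities)
  if (length(times) != length(intensities))
    stop("times and intensities must have the same length")
  if (length(times) < 4L)
    stop("input error: at least 4 time points are required")
  if (any(!is.finite(times)) || any(!is.finite(intensities)))
    stop("input error: times and intensities must be finite")
  if (any(diff(times) <= 0))
    stop("input error: times must be strictly increasing")
  if (diff(range(intensities)) == 0)
    stop("non-identifiable rate: intensity trace is constant")

  start <- .decay_start(times, intensities)
  resfn <- function(par) par[[1L]] * exp(-par[[2L]] * times) + par[[3L]] -
    intensities
  jacfn <- function(par) {
    e <- exp(-par[[2L]] * times)
    cbind(e, -par[[1L]] * times * e, 1)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(start[["amplitude"]], start[["rate_k"]], start[["plateau"]]),
      lower = c(0, .Machine$double.xmin, -Inf),
      fn = resfn, jac = jacfn,
      control = minpack.lm::nls.lm.control(
        ftol = control$sse_tol, ptol = control$sse_tol,
        maxfev = control$max_evals, maxiter = 1024L)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    par <- c(start[["amplitude"]], start[["rate_k"]], start[["plateau"]])
    converged <- FALSE
    msg <- conditionMessage(fit)
    fit <- NULL
  } else {
    par <- fit$par
    # info codes 1-3 are the ftol/ptol convergence criteria of MINPACK
    converged <- fit$info %in% 1:3 && par[[2L]] > 0
    msg <- fit$message
  }
  fitted_vals <- par[[1L]] * exp(-par[[2L]] * times) + par[[3L]]
  out <- list(amplitude = par[[1L]], plateau = par[[3L]],
              rate_k = par[[2L]],
              half_life = log(2) / par[[2L]],
              rss = sum((intensities - fitted_vals)^2),
              converged = converged, message = msg,
              fitted.values = fitted_vals,
              residuals = intensities - fitted_vals,
              times = times, intensities = intensities,
              control = control, optim = fit)
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat("One-phase decay fit: I(t) = amplitude * exp(-k t) + plateau\n")
  cat(sprintf("  half-life: %s min   rate k: %s /min\n",
              format(x$half_life, digits = digits),
              format(x$rate_k, digits = digits)))
  cat(sprintf("  amplitude: %s   plateau: %s   RSS: %s\n",
              format(x$amplitude, digits = digits),
              format(x$plateau, digits = digits),
              format(x$rss, digits = digits)))
  if (!x$converged) cat("  NOT converged:", x$message, "\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(amplitude = object$amplitude, rate_k = object$rate_k,
    plateau = object$plateau)
}

#' @export
deviance.decay_fit <- function(object, ...) object$rss

#' @export
fitted.decay_fit <- function(object, ...) object$fitted.values

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' @export
predict.decay_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted.values)
  object$amplitude * exp(-object$rate_k * times) + object$plateau
}

#' @export
summary.decay_fit <- function(object, ...) {
  n <- length(object$times)
  s2 <- object$rss / max(1L, n - 3L)
  tab <- cbind(Estimate = coef(object))
  if (object$converged && n > 3L) {
    e <- exp(-object$rate_k * object$times)
    J <- cbind(e, -object$amplitude * object$times * e, 1)
    se <- tryCatch(sqrt(diag(s2 * solve(crossprod(J))))[c(1L, 2L, 3L)],
                   error = function(err) NULL)
    if (!is.null(se)) tab <- cbind(tab, `Std. Error` = se)
  }
  structure(list(coefficients = tab, half_life = object$half_life,
                 sigma = sqrt(s2), n = n, rss = object$rss,
                 converged = object$converged, message = object$message),
            class = "summary.decay_fit")
}

#' @export
print.summary.decay_fit <- function(x, digits = 4, ...) {
  cat("One-phase chemiluminescence decay fit\n\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("\nHalf-life: %s min on %d points; residual SD %s%s\n",
              format(x$half_life, digits = digits), x$n,
              format(x$sigma, digits = digits),
              if (x$converged) "" else paste0(" [NOT converged: ", x$message, "]")))
  invisible(x)
}

#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$times, x$intensities, xlab = "time (min)",
                 ylab = "intensity (a.u.)", pch = 16, ...)
  tt <- seq(min(x$times), max(x$times), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  graphics::legend("topright", bty = "n",
                   legend = sprintf("T1/2 = %.2f min", x$half_life))
}

#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$times)
  sd <- sqrt(object$rss / max(1L, n - 3L))
  out <- replicate(nsim, object$fitted.values + stats::rnorm(n, 0, sd))
  as.data.frame(out)
}

#' Fit the decay model to every well of a plate
#'
#' Applies [fit_decay()] to each well record and collects the half-lifetime
#' feature table. Per-well failures (flat traces, optimizer breakdowns) are
#' reported as `converged = FALSE` rows with `NA` half-life; the plate is
#' never aborted. Replicates are fitted independently; averaging across
#' replicates happens downstream, in the screening stage.
#'
#' @param records A `well_records` collection from [read_plate()] or
#'   [simulate_experiment()].
#' @param control A [decay_control()] list.
#' @return A data frame with one row per well: `well_id`, `sample_id`,
#'   `compound_id`, `replicate`, `half_life`, `rate_k`, `amplitude`,
#'   `plateau`, `rss`, `converged`.
#' @export
fit_plate <- function(records, control = decay_control()) {
  if (length(records) == 0L) stop("empty record collection")
  n <- length(records)
  half <- rate <- amp <- plat <- rss <- rep(NA_real_, n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    r <- records[[i]]
    fit <- tryCatch(fit_decay(r$times, r$intensities, control = control),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      rss[i] <- fit$rss
      if (fit$converged) {
        ok[i] <- TRUE
        half[i] <- fit$half_life; rate[i] <- fit$rate_k
        amp[i] <- fit$amplitude; plat[i] <- fit$plateau
      }
    }
  }
  data.frame(
    well_id = vapply(records, `[[`, character(1), "well_id"),
    sample_id = vapply(records, `[[`, character(1), "sample_id"),
    compound_id = vapply(records, `[[`, character(1), "compound_id"),
    replicate = vapply(records, `[[`, integer(1), "replicate"),
    half_life = half, rate_k = rate, amplitude = amp, plateau = plat,
    rss = rss, converged = ok, row.names = NULL)
}
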