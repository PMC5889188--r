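# Damped-oscillation fitting of measured vibration traces (e.g. curvature
# change after a slip-off), and a synthetic trace generator for testing and
# calibration.

#' Synthesize a damped-sinusoid vibration trace
#'
#' Samples \eqn{v(t) = A \sin(\tilde\omega t + \phi)\, e^{-\alpha t/2}} with
#' \eqn{\tilde\omega = \sqrt{\omega^2 - (\alpha/2)^2}}, plus optional i.i.d.
#' Gaussian noise. Deterministic for a given seed; the generator state of the
#' caller is left untouched.
#'
#' @param A amplitude (arbitrary units).
#' @param omega undamped angular frequency (rad/s); must exceed
#'   \code{alpha/2}.
#' @param alpha damping constant (rad/s).
#' @param phase phase at t = 0 (rad).
#' @param duration trace length (s).
#' @param rate sampling rate (Hz).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed (noise only).
#' @return object of class \code{"vibration_trace"}: data.frame with columns
#'   \code{t}, \code{v} and provenance attributes.
#' @examples
#' tr <- synth_vibration_trace(omega = 962, alpha = 430, noise_sd = 0.05,
#'                             seed = 1)
#' @export
synth_vibration_trace <- function(A = 1, omega = 962, alpha = 430,
                                  phase = 0.3, duration = 20e-3,
                                  rate = 40e3, noise_sd = 0, seed = NULL) {
  if (omega <= alpha / 2) stop("under-damping requires omega > alpha/2")
  omt <- sqrt(omega^2 - (alpha / 2)^2)
  if (rate < 8 * omt / (2 * pi))
    stop("sampling rate below 8 samples per period")
  t <- seq(0, duration, by = 1 / rate)
  v <- A * sin(omt * t + phase) * exp(-alpha * t / 2)
  if (noise_sd > 0) {
    rng <- get0(".Random.seed", envir = globalenv())
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(length(t), sd = noise_sd)
    if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv())
  }
  out <- data.frame(t = t, v = v)
  attr(out, "meta") <- list(provenance = "synthetic", seed = seed,
                            rate = rate,
                            params = c(A = A, omega = omega, alpha = alpha,
                                       phase = phase, noise_sd = noise_sd))
  class(out) <- c("vibration_trace", "data.frame")
  out
}

#' Read / write a two-column vibration trace CSV
#'
#' Plain CSV with a one-line header \code{t,v} ('.' decimal separator);
#' comment lines starting with \code{#} are skipped on read and used for a
#' provenance header on write.
#'
#' @param path file path.
#' @return a \code{"vibration_trace"} data.frame.
#' @export
read_vibration_trace <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("t", "v") %in% names(d)))
    stop("trace file must have columns 't' and 'v'")
  if (any(diff(d$t) <= 0)) stop("sample times must be strictly increasing")
  attr(d, "meta") <- list(provenance = "measured", path = path)
  class(d) <- c("vibration_trace", "data.frame")
  d
}

#' @rdname read_vibration_trace
#' @param trace a \code{"vibration_trace"} data.frame.
#' @export
write_vibration_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(list(kind = "vibration_trace",
                                    meta = attr(trace, "meta"))), con)
  utils::write.csv(as.data.frame(trace)[c("t", "v")], con, row.names = FALSE)
  invisible(path)
}

# spectral + envelope initialization for the damped-sinusoid fit
init_damped_fit <- function(t, v) {
  dtm <- stats::median(diff(t))
  tu <- seq(min(t), max(t), by = dtm)
  vu <- stats::approx(t, v, xout = tu)$y
  vu <- vu - mean(vu)
  sp <- Mod(stats::fft(vu))^2
  n <- length(vu)
  freqs <- (seq_len(n) - 1) / (n * dtm)
  half <- 2:floor(n / 2)
  omt0 <- 2 * pi * freqs[half][which.max(sp[half])]
  # damping from log-envelope regression on local maxima of |v|
  a <- abs(v)
  pk <- which(diff(sign(diff(a))) < 0) + 1L
  pk <- pk[a[pk] > 0.05 * max(a)]
  alpha0 <- if (length(pk) >= 3) {
    sl <- stats::coef(stats::lm(log(a[pk]) ~ t[pk]))[2]
    max(-2 * sl, 0)
  } else 0
  # amplitude/phase by linear least squares at (omt0, alpha0)
  Xb <- cbind(sin(omt0 * t), cos(omt0 * t)) * exp(-alpha0 * t / 2)
  bc <- stats::coef(stats::lm.fit(Xb, v))
  A0 <- sqrt(sum(bc^2))
  ph0 <- atan2(bc[2], bc[1])
  c(A = unname(A0), omega = unname(sqrt(omt0^2 + (alpha0 / 2)^2)),
    alpha = unname(alpha0), phase = unname(ph0))
}

#' Fit a damped oscillation to a vibration trace
#'
#' Least-squares fit of \eqn{v(t) = A \sin\big(\sqrt{\omega^2 -
#' (\alpha/2)^2}\, t + \phi\big) e^{-\alpha t / 2}} by the
#' Levenberg-Marquardt algorithm, with 0.95 confidence intervals from the
#' local curvature of the objective at the optimum
#' (observed-information standard errors). Starting values, when not given,
#' come from the spectral peak (frequency) and a log-envelope regression
#' (damping). A residual-bootstrap CI option is available for irregularly
#' sampled traces.
#'
#' @param trace a \code{"vibration_trace"} data.frame, or anything with
#'   columns \code{t} and \code{v}.
#' @param init optional named vector of starting values
#'   \code{c(A, omega, alpha, phase)}.
#' @param ci \code{"curvature"} (default) or \code{"bootstrap"}.
#' @param n_boot bootstrap replicates when \code{ci = "bootstrap"}.
#' @return object of class \code{"dampedosc_fit"} with components
#'   \code{coefficients} (A, omega, alpha, phase), \code{ci} (0.95 intervals),
#'   \code{rss}, \code{fitted}, \code{residuals}, and the underlying
#'   \code{nls} fit. Supported methods: \code{print}, \code{summary},
#'   \code{coef}, \code{confint}, \code{predict}, \code{fitted},
#'   \code{residuals}, \code{simulate}, \code{plot}.
#' @examples
#' tr <- synth_vibration_trace(omega = 962, alpha = 430, noise_sd = 0.02,
#'                             seed = 2)
#' f <- fit_damped_oscillation(tr)
#' coef(f)["omega"] / (2 * pi)   # frequency in Hz
#' @export
fit_damped_oscillation <- function(trace, init = NULL,
                                   ci = c("curvature", "bootstrap"),
                                   n_boot = 200) {
  ci <- match.arg(ci)
  d <- as.data.frame(trace)
  if (!all(c("t", "v") %in% names(d)))
    stop("trace must have columns 't' and 'v'")
  t <- d$t; v <- d$v
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing")
  if (is.null(init)) init <- init_damped_fit(t, v)
  init <- stats::setNames(as.numeric(init[c("A", "omega", "alpha", "phase")]),
                          c("A", "omega", "alpha", "phase"))
  omt0 <- sqrt(max(init["omega"]^2 - (init["alpha"] / 2)^2, 0))
  if (stats::median(diff(t)) > (2 * pi / omt0) / 8)
    stop("fewer than 8 samples per expected period; trace too sparse to fit")

  dd <- data.frame(t = t, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ A * sin(sqrt(omega^2 - (alpha / 2)^2) * t + phase) *
        exp(-alpha * t / 2),
      data = dd, start = as.list(init),
      lower = c(A = 0, omega = 1e-9, alpha = 0, phase = -2 * pi),
      upper = c(A = Inf, omega = Inf, alpha = Inf, phase = 2 * pi),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("damped-oscillation fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  overdamped <- cf["omega"] <= cf["alpha"] / 2 * (1 + 1e-12)
  se <- summary(fit)$coefficients[, "Std. Error"]
  dfree <- length(t) - 4L
  if (ci == "curvature") {
    qv <- stats::qt(0.975, dfree)
    cimat <- cbind(lower = cf - qv * se, upper = cf + qv * se)
  } else {
    res <- stats::residuals(fit)
    fitv <- stats::fitted(fit)
    bs <- replicate(n_boot, {
      vb <- fitv + sample(res, replace = TRUE)
      fb <- try(minpack.lm::nlsLM(
        v ~ A * sin(sqrt(omega^2 - (alpha / 2)^2) * t + phase) *
          exp(-alpha * t / 2),
        data = data.frame(t = t, v = vb), start = as.list(cf),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
      if (inherits(fb, "try-error")) rep(NA_real_, 4) else stats::coef(fb)
    })
    cimat <- t(apply(bs, 1, stats::quantile, c(0.025, 0.975), na.rm = TRUE))
    colnames(cimat) <- c("lower", "upper")
  }
  structure(list(coefficients = cf, se = se, ci = cimat,
                 rss = sum(stats::residuals(fit)^2),
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 overdamped = isTRUE(unname(overdamped)),
                 data = dd, nls = fit, df.residual = dfree),
            class = "dampedosc_fit")
}

#' @export
coef.dampedosc_fit <- function(object, ...) object$coefficients

#' @export
confint.dampedosc_fit <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95)
    warning("intervals were computed at 0.95; returning those")
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
residuals.dampedosc_fit <- function(object, ...) object$residuals

#' @export
fitted.dampedosc_fit <- function(object, ...) object$fitted

#' @export
predict.dampedosc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  t <- if (is.data.frame(newdata)) newdata$t else as.numeric(newdata)
  cf <- object$coefficients
  omt <- sqrt(cf["A"] * 0 + cf["omega"]^2 - (cf["alpha"] / 2)^2)
  unname(cf["A"] * sin(omt * t + cf["phase"]) * exp(-cf["alpha"] * t / 2))
}

#' @export
simulate.dampedosc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sd <- sqrt(object$rss / object$df.residual)
  cf <- object$coefficients
  lapply(seq_len(nsim), function(i)
    synth_vibration_trace(A = cf["A"], omega = cf["omega"],
                          alpha = cf["alpha"], phase = cf["phase"],
                          duration = max(object$data$t),
                          rate = 1 / stats::median(diff(object$data$t)),
                          noise_sd = sd,
                          seed = if (is.null(seed)) NULL else seed + i - 1L))
}

#' @export
print.dampedosc_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Damped-oscillation fit: A sin(omega_t t + phase) exp(-alpha t / 2)\n")
  cat(sprintf("  omega = %.4g rad/s (%.4g Hz), alpha = %.4g rad/s\n",
              cf["omega"], cf["omega"] / (2 * pi), cf["alpha"]))
  cat(sprintf("  A = %.4g, phase = %.4g rad, RSS = %.4g\n",
              cf["A"], cf["phase"], x$rss))
  if (x$overdamped) cat("  WARNING: optimum is not under-damped\n")
  invisible(x)
}

#' @export
summary.dampedosc_fit <- function(object, ...) {
  tab <- cbind(estimate = object$coefficients, se = object$se, object$ci)
  out <- list(table = tab, rss = object$rss,
              sigma = sqrt(object$rss / object$df.residual),
              f_hz = object$coefficients[["omega"]] / (2 * pi),
              overdamped = object$overdamped)
  class(out) <- "summary.dampedosc_fit"
  out
}

#' @export
print.summary.dampedosc_fit <- function(x, ...) {
  cat("Damped-oscillation fit (0.95 CI)\n")
  print(round(x$table, 6))
  cat(sprintf("frequency %.2f Hz, residual sigma %.4g\n", x$f_hz, x$sigma))
  invisible(x)
}

#' @export
plot.dampedosc_fit <- function(x, ...) {
  graphics::plot(x$data$t * 1e3, x$data$v, pch = 16, cex = 0.4,
                 col = "grey50", xlab = "time (ms)", ylab = "signal",
                 main = "damped-oscillation fit", ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 800)
  graphics::lines(tt * 1e3, predict(x, tt), col = "firebrick", lwd = 1.5)
  invisible(x)
}

#' Young's modulus from a fitted free-vibration frequency
#'
#' Delegates to [young_modulus_from_frequency()] with the fitted undamped
#' \code{omega}, using the first dimensionless root of the chosen free
#' boundary case. A 0.95 CI on E is propagated from the CI on \code{omega}
#' through the quadratic map \eqn{E \propto \omega^2}.
#'
#' @param fit a [fit_damped_oscillation()] result (under-damped).
#' @param L,R,rho whisker length (m), base radius (m), density (kg/m^3).
#' @param case \code{"free_full"} (default) or \code{"free_truncated"}.
#' @param l_frac truncation fraction when \code{case = "free_truncated"}.
#' @return list with \code{E} (Pa), \code{E_ci}, \code{f_hz}, \code{beta1}.
#' @examples
#' \donttest{
#' tr <- synth_vibration_trace(omega = 962, alpha = 430)
#' f <- fit_damped_oscillation(tr)
#' estimate_modulus(f, L = 17.14e-3, R = 37.15e-6, rho = 1000)$E / 1e9
#' }
#' @export
estimate_modulus <- function(fit, L, R, rho, case = c("free_full",
                                                      "free_truncated"),
                             l_frac = 0) {
  stopifnot(inherits(fit, "dampedosc_fit"))
  if (fit$overdamped) stop("fit is not under-damped; no real frequency")
  case <- match.arg(case)
  beta1 <- if (case == "free_full") free_full_beta1()
           else find_eigenvalues("free_truncated", list(l_frac = l_frac), 1)
  om <- fit$coefficients[["omega"]]
  E <- young_modulus_from_frequency(L, R, rho, om, beta1)
  ci <- fit$ci["omega", ]
  list(E = E,
       E_ci = young_modulus_from_frequency(L, R, rho, pmax(ci, 1e-12), beta1),
       f_hz = om / (2 * pi), beta1 = beta1)
}
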