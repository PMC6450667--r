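#' Signed circular difference between a response and a target
#'
#' Computes the wrapped error `response - target` on a 360-degree circle,
#' returned in the half-open interval (-180, 180]. This is the error measure
#' for continuous-report memory tasks (color wheel, panorama position): an
#' error of 0 means a perfect reproduction, +/-180 the diametrically opposite
#' value. The boundary case of exactly half a circle maps to +180, not -180.
#'
#' @param response Response angle(s) in degrees.
#' @param target Target (encoded) angle(s) in degrees. Recycled against
#'   `response`.
#' @return Numeric vector of wrapped errors in degrees, in (-180, 180].
#'   `NA` inputs propagate to `NA` (a missing response stays missing).
#' @examples
#' wrap_error(10, 350)  # 20
#' wrap_error(180, 0)   # 180
#' @export
wrap_error <- function(response, target) {
  if (!is.numeric(response) || !is.numeric(target)) {
    stop("`response` and `target` must be numeric (degrees)")
  }
  if (any(is.infinite(response)) || any(is.infinite(target))) {
    stop("angles must be finite")
  }
  e <- (response - target) %% 360
  ifelse(e > 180, e - 360, e)
}

#' Zero-mean von Mises density for angular errors
#'
#' Density of the von Mises distribution with mean 0 and concentration
#' `kappa`, evaluated at an angular error given in degrees. The density is
#' per radian, so it integrates to 1 over (-pi, pi]. `kappa = 0` reduces to
#' the circular uniform density 1/(2*pi). Evaluation is done on the log scale
#' with the exponentially scaled Bessel function, so large concentrations
#' (precise memory) do not overflow.
#'
#' @param error_deg Angular error(s) in degrees.
#' @param kappa Concentration parameter, >= 0.
#' @param log If `TRUE` return the log density.
#' @return Density per radian (or its log).
#' @export
von_mises_pdf <- function(error_deg, kappa, log = FALSE) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0) {
    stop("`kappa` must be a single non-negative number")
  }
  theta <- error_deg * pi / 180
  # log I0(kappa) computed stably: besselI(.., expon.scaled) * exp(kappa)
  log_i0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  ld <- kappa * cos(theta) - log(2 * pi) - log_i0
  if (log) ld else exp(ld)
}

#' Draw angular errors from a zero-mean von Mises distribution
#'
#' Best-Fisher rejection sampler. Returned in degrees, wrapped to
#' (-180, 180]. `kappa = 0` falls back to uniform draws on the circle.
#'
#' @param n Number of draws.
#' @param kappa Concentration, >= 0.
#' @return Numeric vector of errors in degrees.
#' @export
rvonmises_deg <- function(n, kappa) {
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) {
    return(wrap_error(stats::runif(n, 0, 360), 0))
  }
  # Best & Fisher (1979) wrapped-Cauchy envelope
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- n - filled
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cval <- kappa * (r - f)
    u2 <- stats::runif(m)
    accept <- (cval * (2 - cval) - u2 > 0) | (log(cval / u2) + 1 - cval >= 0)
    ok <- which(accept)
    if (length(ok)) {
      theta <- sign(stats::runif(length(ok)) - 0.5) * acos(f[ok])
      out[(filled + 1L):(filled + length(ok))] <- theta
      filled <- filled + length(ok)
    }
  }
  wrap_error(out * 180 / pi, 0)
}

mixture_negloglik <- function(par, err_rad) {
  kappa <- par[1L]
  gamma <- par[2L]
  log_i0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  dvm <- exp(kappa * cos(err_rad) - log(2 * pi) - log_i0)
  ll <- sum(log((1 - gamma) * dvm + gamma / (2 * pi)))
  -ll
}

#' Fit the von Mises + uniform mixture model to angular errors
#'
#' Models continuous-report errors as a mixture of a zero-mean von Mises
#' component (responses that carry target information, with concentration
#' `kappa`) and a circular uniform component (guesses, with weight `gamma`):
#' \deqn{p(e) = (1 - \gamma)\,\phi_\kappa(e) + \gamma / (2\pi).}
#' Parameters are estimated by maximum likelihood with a bounded
#' quasi-Newton optimizer from a grid of starting values
#' (kappa in \{1, 4, 16, 64\} x gamma in \{0.1, 0.5, 0.9\}), because the
#' likelihood surface can be multimodal for small samples. The fit is
#' deterministic given the data.
#'
#' @param errors_deg Wrapped angular errors in degrees; at least 10
#'   non-missing values are required.
#' @param kappa_bounds Lower/upper box bounds for the concentration.
#' @return An object of class `mixture_fit`: list with `kappa`, `gamma`,
#'   `loglik`, `n`, `converged`, and `boundary` (TRUE when the optimum sits
#'   on a parameter bound, e.g. for degenerate all-identical samples).
#' @export
fit_mixture <- function(errors_deg, kappa_bounds = c(0.01, 500)) {
  errors_deg <- errors_deg[!is.na(errors_deg)]
  if (length(errors_deg) < 10L) {
    stop("fit_mixture needs at least 10 non-missing errors")
  }
  err_rad <- errors_deg * pi / 180
  starts <- expand.grid(kappa = c(1, 4, 16, 64), gamma = c(0.1, 0.5, 0.9))
  lower <- c(kappa_bounds[1L], 0)
  upper <- c(kappa_bounds[2L], 1)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(
        par = c(starts$kappa[i], starts$gamma[i]),
        fn = mixture_negloglik, err_rad = err_rad,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(factr = 1e-8 / .Machine$double.eps, maxit = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  if (is.null(best)) stop("mixture optimization failed from every start")
  on_bound <- best$par[1L] <= lower[1L] + 1e-9 || best$par[1L] >= upper[1L] - 1e-9
  structure(
    list(
      kappa = best$par[1L],
      gamma = best$par[2L],
      loglik = -best$value,
      n = length(errors_deg),
      converged = best$convergence == 0L,
      boundary = on_bound
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "von Mises + uniform mixture fit (n = %d)\n  kappa = %.3f, gamma = %.3f, logLik = %.2f%s\n",
    x$n, x$kappa, x$gamma, x$loglik,
    if (isTRUE(x$boundary)) " [boundary]" else ""
  ))
  invisible(x)
}

#' Posterior probability that an error came from the target component
#'
#' Given a fitted mixture, returns the probability that an observed error
#' was generated by the von Mises (target memory) component rather than the
#' uniform (guess) component:
#' \deqn{P = (1-\gamma)\phi_\kappa(e) / [(1-\gamma)\phi_\kappa(e) + \gamma/(2\pi)].}
#'
#' @param error_deg Angular error(s) in degrees.
#' @param fit A `mixture_fit`, or any list with `kappa` and `gamma`.
#' @return Probabilities in \[0, 1\].
#' @export
posterior_target_prob <- function(error_deg, fit) {
  kappa <- fit$kappa
  gamma <- fit$gamma
  if (is.null(kappa) || is.null(gamma)) stop("`fit` must carry kappa and gamma")
  if (gamma <= 0) return(rep(1, length(error_deg)))
  if (gamma >= 1) return(rep(0, length(error_deg)))
  num <- (1 - gamma) * von_mises_pdf(error_deg, kappa)
  num / (num + gamma / (2 * pi))
}

#' Absolute-error threshold where the target posterior crosses 50%
#'
#' The |error| at which an observation is equally likely to come from the
#' von Mises as from the uniform component; errors at or below it are
#' classified as successful retrieval ("at least a 50% chance" counts as
#' correct). Solved in closed form from
#' \eqn{\cos(e^*) = \log[\gamma I_0(\kappa) / (1-\gamma)] / \kappa}:
#' when the right-hand side exceeds 1 the posterior never reaches 0.5 and
#' the threshold is 0 degrees; below -1 it never falls under 0.5 and the
#' threshold is 180 degrees.
#'
#' @param fit A `mixture_fit` (or list with `kappa` > 0, `gamma` in (0,1)).
#' @return Threshold in degrees, in \[0, 180\].
#' @export
success_threshold <- function(fit) {
  kappa <- fit$kappa
  gamma <- fit$gamma
  if (is.null(kappa) || is.null(gamma) || is.na(kappa) || is.na(gamma)) {
    stop("`fit` must be a fitted mixture with kappa and gamma")
  }
  if (gamma <= 0) return(180)
  if (gamma >= 1) return(0)
  if (kappa <= 0) {
    # uniform component with zero-concentration target: posterior is flat
    return(if (1 - gamma >= gamma) 180 else 0)
  }
  log_i0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  arg <- (log(gamma / (1 - gamma)) + log_i0) / kappa
  if (arg > 1) return(0)
  if (arg < -1) return(180)
  acos(arg) * 180 / pi
}

#' Expected absolute wrapped error under uniform guessing
#'
#' Chance level for continuous-report tasks: a guess uniform on the circle
#' has expected |wrapped error| of exactly 90 degrees. Optionally verified
#' by Monte Carlo.
#'
#' @param n_mc If > 0, estimate by that many uniform draws instead of the
#'   closed form (used for cross-checks).
#' @return Expected absolute error in degrees.
#' @export
uniform_abs_error <- function(n_mc = 0L) {
  if (n_mc > 0L) {
    mean(abs(wrap_error(stats::runif(n_mc, 0, 360), 0)))
  } else {
    90
  }
}
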