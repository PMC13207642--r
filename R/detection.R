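#' Sensitivity regression of a detection metric against breach fraction
#'
#' Ordinary least squares of metric values on the breach fraction theta
#' across Monte-Carlo realizations, giving the sensitivity slope `b1`, the
#' residual standard deviation `sigma` (n - 2 denominator) and their ratio,
#' the noise-to-sensitivity ratio `NSR = sigma / b1` — the dimensionless
#' figure of merit of a sensor configuration.
#'
#' @param data a data frame of realizations, or `NULL` to pass bare vectors.
#' @param theta,value column names (tidy evaluation) when `data` is given,
#'   otherwise numeric vectors of breach fractions and metric values.
#' @return an object of class `zra_sensitivity_fit` with fields `b1`,
#'   `intercept`, `sigma`, `nsr`, `n_points` and the underlying `lm` fit.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' fit <- fit_sensitivity(theta = rep(c(0, .1, .2, .5), each = 5),
#'                        value = 2 * rep(c(0, .1, .2, .5), each = 5) + 1)
#' fit$b1       # 2
#' theta_det(fit, N = 30)
#' @export
fit_sensitivity <- function(data = NULL, theta, value) {
  if (!is.null(data)) {
    th <- rlang::eval_tidy(rlang::enquo(theta), data)
    y <- rlang::eval_tidy(rlang::enquo(value), data)
  } else {
    th <- theta; y <- value
  }
  ok <- is.finite(th) & is.finite(y)
  th <- th[ok]; y <- y[ok]
  if (length(th) < 3) abort("sensitivity fit needs at least 3 points.")
  if (length(unique(th)) < 2) {
    abort("sensitivity fit needs at least 2 distinct breach fractions.")
  }
  fit <- lm(y ~ th)
  s <- summary(fit)$sigma
  b1 <- unname(coef(fit)[2])
  structure(list(b1 = b1, intercept = unname(coef(fit)[1]), sigma = s,
                 nsr = if (b1 > 0) s / b1 else NA_real_,
                 n_points = length(th), model = fit,
                 data = tibble(theta = th, value = y)),
            class = "zra_sensitivity_fit")
}

#' @export
print.zra_sensitivity_fit <- function(x, ...) {
  cat(sprintf(paste0("<zra_sensitivity_fit> n = %d\n",
                     "  slope b1 = %.4g, sigma = %.4g, NSR = %.4g\n"),
              x$n_points, x$b1, x$sigma, x$nsr))
  invisible(x)
}

#' @export
tidy.zra_sensitivity_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = c("intercept", "theta"),
         estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.zra_sensitivity_fit <- function(x, ...) {
  tibble(b1 = x$b1, intercept = x$intercept, sigma = x$sigma,
         nsr = x$nsr, n_points = x$n_points,
         r.squared = summary(x$model)$r.squared)
}

#' Minimum statistically detectable breach fraction
#'
#' Detection threshold from a two-sample test comparing `N` measurements
#' against `N` intact baseline recordings at significance `alpha`:
#' \deqn{\theta_{det}(N) = t_{\alpha/2,\nu}\,\frac{\sigma}{b_1}\sqrt{2/N},
#'   \qquad \nu = 2N - 2.}
#' `rule = "z"` replaces the critical t-value by the normal quantile (the
#' large-N limit).
#'
#' @param fit a `zra_sensitivity_fit`, or a list/vector with elements
#'   `b1` and `sigma`.
#' @param N number of recordings per arm (vectorized, N >= 2).
#' @param alpha significance level.
#' @param rule degrees-of-freedom convention, `"t"` (nu = 2N - 2) or `"z"`.
#' @return breach fraction(s), same length as `N`.
#' @export
theta_det <- function(fit, N, alpha = 0.05, rule = c("t", "z")) {
  rule <- match.arg(rule)
  b1 <- fit$b1 %||% fit[["b1"]]
  sigma <- fit$sigma %||% fit[["sigma"]]
  if (is.null(b1) || is.null(sigma)) abort("`fit` must supply `b1` and `sigma`.")
  if (!is.finite(b1) || b1 <= 0) {
    abort("slope b1 <= 0: this configuration is undetectable.")
  }
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (any(N < 2)) abort("`N` must be at least 2.")
  crit <- if (rule == "t") qt(1 - alpha / 2, df = 2 * N - 2) else {
    stats::qnorm(1 - alpha / 2)
  }
  crit * (sigma / b1) * sqrt(2 / N)
}

#' Smallest number of recordings resolving a target breach
#'
#' Smallest integer `N >= 2` with `theta_det(N) <= theta_target`
#' (`theta_det` is strictly decreasing in `N`, so a monotone scan suffices).
#'
#' @inheritParams theta_det
#' @param theta_target target breach fraction (> 0).
#' @param N_max search cap.
#' @return integer `N`.
#' @export
min_recordings <- function(fit, theta_target, alpha = 0.05, rule = c("t", "z"),
                           N_max = 1e6) {
  if (theta_target <= 0) abort("`theta_target` must be > 0.")
  rule <- match.arg(rule)
  lo <- 2L
  repeat {
    hi <- min(N_max, lo * 1024L)
    N <- lo:hi
    th <- theta_det(fit, N, alpha, rule)
    ok <- which(th <= theta_target)
    if (length(ok) > 0) return(N[ok[1]])
    if (hi >= N_max) abort("no N up to `N_max` reaches the target breach fraction.")
    lo <- hi + 1L
  }
}

#' Detection-threshold curve
#'
#' @inheritParams theta_det
#' @param N vector of recording counts.
#' @return a tibble of class `zra_detection_curve` with columns `N` and
#'   `theta_det`.
#' @export
detection_curve <- function(fit, N = 2:500, alpha = 0.05, rule = c("t", "z")) {
  rule <- match.arg(rule)
  out <- tibble(N = as.integer(N), theta_det = theta_det(fit, N, alpha, rule))
  class(out) <- c("zra_detection_curve", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "rule") <- rule
  out
}
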