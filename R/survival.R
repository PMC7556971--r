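## Time grid: one model cycle is 28 days; survival curves are parameterized in
## months with 30.4375 days/month, so a cycle is 28/30.4375 = 0.91993 months.
months_per_cycle <- function(cycle_days = 28, days_per_month = 30.4375) {
  cycle_days / days_per_month
}

#' Weibull overall-survival curve
#'
#' Two-parameter Weibull survival function `S(t) = exp(-(t/scale)^shape)` with
#' time in months; the extrapolation model for overall survival. `shape = 1`
#' is the exponential special case; `shape > 1` gives an increasing hazard.
#'
#' @param shape Dimensionless shape `k > 0`.
#' @param scale Scale `lambda > 0`, months.
#' @return Object of class `weibull_survival`.
#' @seealso [weibull_from_median()], [fit_weibull_km()], [cycle_death_prob()]
#' @export
weibull_survival <- function(shape, scale) {
  stopifnot(is.numeric(shape), is.numeric(scale), length(shape) == 1,
            length(scale) == 1)
  if (!(shape > 0 && scale > 0)) stop("shape and scale must be > 0")
  structure(list(shape = shape, scale = scale), class = "weibull_survival")
}

#' @export
print.weibull_survival <- function(x, ...) {
  cat(sprintf("Weibull survival: shape %.4f, scale %.4f months (median %.3f months)\n",
              x$shape, x$scale, x$scale * log(2)^(1 / x$shape)))
  invisible(x)
}

#' Evaluate a survival curve
#'
#' @param curve A [weibull_survival()] object.
#' @param t Time(s) in months, `>= 0`.
#' @return Survival fraction(s) in (0, 1]; `S(0) = 1`.
#' @export
#' @examples
#' survival_at(weibull_from_median(6.6, 1), 6.6)  # 0.5 by construction
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "weibull_survival"))
  if (any(t < 0)) stop("t must be >= 0")
  exp(-(t / curve$scale)^curve$shape)
}

#' Weibull curve anchored at a survival median
#'
#' Returns the Weibull curve with the given shape whose median equals the
#' supplied value: `scale = median / log(2)^(1/shape)`. This is the default
#' calibration path when only a trial's median overall survival is available.
#'
#' @param median Median survival, months, `> 0`.
#' @param shape Weibull shape `> 0`.
#' @return A [weibull_survival()] object with `S(median) = 0.5`.
#' @export
#' @examples
#' weibull_from_median(9.3, 1.4)
weibull_from_median <- function(median, shape) {
  if (!(median > 0)) stop("median must be > 0")
  if (!(shape > 0)) stop("shape must be > 0")
  weibull_survival(shape, median / log(2)^(1 / shape))
}

#' Fit a Weibull curve to Kaplan-Meier coordinates
#'
#' Least-squares fit on the complementary-log-log scale: for Weibull survival,
#' `log(-log S(t)) = shape * log t - shape * log scale`, so an ordinary linear
#' regression of `log(-log S)` on `log t` over the Kaplan-Meier points
#' recovers the parameters. Points with survival exactly 0 or 1 are excluded
#' (their transform is infinite); the number excluded is reported via
#' `message()`.
#'
#' Intended for users who supply digitized Kaplan-Meier coordinates; the
#' packaged base case anchors curves on published medians instead
#' ([weibull_from_median()]) because no coordinates are published.
#'
#' @param km Data frame with columns `time_months` (strictly increasing, > 0)
#'   and `survival` (non-increasing, in \[0, 1\]).
#' @return A [weibull_survival()] object.
#' @export
#' @examples
#' tt <- 1:24
#' km <- data.frame(time_months = tt,
#'                  survival = survival_at(weibull_survival(1.3, 10), tt))
#' fit_weibull_km(km)  # recovers shape 1.3, scale 10
fit_weibull_km <- function(km) {
  stopifnot(is.data.frame(km), all(c("time_months", "survival") %in% names(km)))
  if (any(diff(km$time_months) <= 0)) stop("times must be strictly increasing")
  if (any(diff(km$survival) > 1e-12)) stop("survival must be non-increasing")
  usable <- km$survival > 0 & km$survival < 1 & km$time_months > 0
  dropped <- sum(!usable)
  if (dropped > 0)
    message(dropped, " point(s) with survival at 0 or 1 excluded from Weibull fit")
  if (sum(usable) < 3)
    stop("need at least 3 Kaplan-Meier points with survival strictly in (0, 1)")
  x <- log(km$time_months[usable])
  y <- log(-log(km$survival[usable]))
  fit <- stats::lm.fit(cbind(1, x), y)
  k <- fit$coefficients[[2]]
  if (!(k > 0)) stop("fitted shape is not positive; curve is not Weibull-like")
  weibull_survival(k, exp(-fit$coefficients[[1]] / k))
}

#' Per-cycle death probability from a survival curve
#'
#' Converts a survival curve into the conditional probability of dying during
#' cycle `t`, `P(t) = 1 - S(t+1)/S(t)` with cycle endpoints at `t * delta` and
#' `(t+1) * delta` months (`delta` = cycle length in months). Telescoping these
#' probabilities reconstructs `S` exactly, so cohort mortality in the Markov
#' engine follows the fitted curve without discretization drift.
#'
#' @param curve A [weibull_survival()] object.
#' @param t Cycle index (vectorized), non-negative integers.
#' @param cycle_days Cycle length in days (default 28).
#' @param days_per_month Day/month conversion (default 30.4375).
#' @return Probability(ies) in \[0, 1).
#' @export
#' @examples
#' cycle_death_prob(weibull_from_median(6.6, 1), 0:3)  # constant: exponential
cycle_death_prob <- function(curve, t, cycle_days = 28, days_per_month = 30.4375) {
  if (any(t < 0)) stop("cycle index must be >= 0")
  delta <- months_per_cycle(cycle_days, days_per_month)
  1 - survival_at(curve, (t + 1) * delta) / survival_at(curve, t * delta)
}

#' Exponential time-on-treatment distribution
#'
#' Treatment discontinuation (progression, toxicity or intolerance) is modeled
#' as exponentially distributed time on treatment with the given median, i.e.
#' a constant per-cycle stopping probability (memoryless).
#'
#' @param median Median time on treatment, months, `> 0`.
#' @return Object of class `exponential_duration` with fields `median` and
#'   `rate` (`log(2)/median` per month).
#' @export
exponential_duration <- function(median) {
  if (!(median > 0)) stop("median must be > 0")
  structure(list(median = median, rate = log(2) / median),
            class = "exponential_duration")
}

#' @export
print.exponential_duration <- function(x, ...) {
  cat(sprintf("Exponential duration: median %.3f months (rate %.4f /month)\n",
              x$median, x$rate))
  invisible(x)
}

#' Per-cycle treatment discontinuation probability
#'
#' Constant per-cycle probability `1 - exp(-rate * delta)` implied by an
#' exponential time-on-treatment distribution.
#'
#' @param duration An [exponential_duration()] object.
#' @inheritParams cycle_death_prob
#' @return A single probability in (0, 1).
#' @export
#' @examples
#' discontinuation_prob(exponential_duration(3.7))  # about 0.158 per cycle
discontinuation_prob <- function(duration, cycle_days = 28,
                                 days_per_month = 30.4375) {
  stopifnot(inherits(duration, "exponential_duration"))
  1 - exp(-duration$rate * months_per_cycle(cycle_days, days_per_month))
}
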