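#' Generate pseudo individual-patient survival data
#'
#' Draws `n` Weibull event times and applies administrative censoring at a
#' fixed follow-up time, emulating arm-level overall-survival data with the
#' statistical structure the model assumes (no dropout process). Used to test
#' the Kaplan-Meier and Weibull-fitting path without any external data.
#'
#' @param shape,scale Weibull parameters of the event-time distribution
#'   (months).
#' @param n Number of patients, `>= 1`.
#' @param censor_time Administrative censoring time in months (default `Inf`,
#'   no censoring).
#' @param seed Optional integer seed; when supplied the RNG state is restored
#'   on exit and the dataset is reproducible bit-identically.
#' @return Data frame of class `pseudo_ipd` with columns `time_months` and
#'   `event` (1 death, 0 censored); the generating parameters are stored in
#'   attribute `metadata`.
#' @export
#' @examples
#' ipd <- generate_pseudo_ipd(1.3, 10, n = 100, censor_time = 24, seed = 7)
#' table(ipd$event)
generate_pseudo_ipd <- function(shape, scale, n, censor_time = Inf,
                                seed = NULL) {
  stopifnot(n >= 1)
  if (!(shape > 0 && scale > 0 && censor_time > 0))
    stop("shape, scale and censor_time must be > 0")
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  t_event <- stats::rweibull(n, shape = shape, scale = scale)
  event <- as.integer(t_event <= censor_time)
  out <- data.frame(time_months = pmin(t_event, censor_time), event = event)
  structure(out, class = c("pseudo_ipd", "data.frame"),
            metadata = list(shape = shape, scale = scale, n = n,
                            censor_time = censor_time, seed = seed))
}

#' Kaplan-Meier curve from pseudo individual-patient data
#'
#' Product-limit estimate (via [survival::survfit()]) evaluated at the event
#' times, in the two-column form consumed by [fit_weibull_km()].
#'
#' @param ipd Data frame with columns `time_months` and `event` (1 death,
#'   0 censored); at least one event required.
#' @return Data frame with columns `time_months` (event times) and `survival`.
#' @export
#' @examples
#' ipd <- generate_pseudo_ipd(1.3, 10, n = 500, seed = 7)
#' km <- km_from_ipd(ipd)
#' fit_weibull_km(km)
km_from_ipd <- function(ipd) {
  stopifnot(is.data.frame(ipd),
            all(c("time_months", "event") %in% names(ipd)))
  if (sum(ipd$event) == 0) stop("no events in the data; cannot estimate survival")
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                           data = as.data.frame(ipd))
  keep <- fit$n.event > 0
  data.frame(time_months = fit$time[keep], survival = fit$surv[keep])
}

#' Write pseudo-IPD with its metadata sidecar
#'
#' @param ipd A `pseudo_ipd` data frame.
#' @param file CSV output path; the generating parameters go to
#'   `<file>.meta.json`.
#' @return `file`, invisibly.
#' @export
write_pseudo_ipd <- function(ipd, file) {
  utils::write.csv(as.data.frame(ipd), file, row.names = FALSE)
  meta <- attr(ipd, "metadata")
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE,
                         null = "null")
  invisible(file)
}
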