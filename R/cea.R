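## Economic evaluation for a fixed pair of traces and a named vector of
## parameter values. All sampled/varied parameters are economic, so sensitivity
## analyses re-run only this function; the traces are computed once.
evaluate_economics <- function(values, traces,
                               scenario = c("post_negotiation", "pre_negotiation"),
                               concurrent_bsc = TRUE, cost_cycle0 = FALSE) {
  scenario <- match.arg(scenario)
  v <- function(name) unname(values[[name]])

  ae_treated <- ae_burden(
    probability = c(v("p_ae_hypertension_fruq"), v("p_ae_hfs_fruq"),
                    v("p_ae_diarrhea_fruq"), v("p_ae_platelet_fruq")),
    cost = c(v("cost_ae_hypertension"), v("cost_ae_hfs"),
             v("cost_ae_diarrhea"), v("cost_ae_platelet")),
    disutility = c(v("disu_ae_hypertension"), v("disu_ae_hfs"),
                   v("disu_ae_diarrhea"), v("disu_ae_platelet")),
    duration_days = c(0, v("dur_ae_hfs"), v("dur_ae_diarrhea"), 0))
  ae_bsc <- ae_burden(probability = v("p_ae_hypertension_bsc"),
                      cost = v("cost_ae_hypertension"),
                      disutility = 0, duration_days = 0)

  drug_unit <- if (scenario == "post_negotiation") v("cost_fruq_post")
               else v("cost_fruq_pre")
  schedule <- drug_cost_schedule(scenario, drug_unit)

  treated <- accumulate_arm(traces$treated, drug_cost = schedule,
                            bsc_cost = v("cost_bsc_per_cycle"),
                            utility = v("utility_baseline"),
                            annual_rate = v("discount_rate"),
                            ae = ae_treated, concurrent_bsc = concurrent_bsc,
                            cost_cycle0 = cost_cycle0)
  comparator <- accumulate_arm(traces$bsc_only, drug_cost = NULL,
                               bsc_cost = v("cost_bsc_per_cycle"),
                               utility = v("utility_baseline"),
                               annual_rate = v("discount_rate"),
                               ae = ae_bsc, concurrent_bsc = concurrent_bsc,
                               cost_cycle0 = cost_cycle0)
  compute_icer(treated, comparator)
}

## Survival curves and cohort traces for both arms under a given calibration.
build_traces <- function(shapes, constants, order = "death_first") {
  os_f <- weibull_from_median(constants$median_os_fruq, shapes$treated)
  os_p <- weibull_from_median(constants$median_os_bsc, shapes$bsc_only)
  disc <- exponential_duration(constants$median_tx_duration)
  list(
    curves = list(treated = os_f, bsc_only = os_p),
    treated = run_cohort(os_f, disc, max_cycles = constants$max_cycles,
                         stop_threshold = constants$stop_threshold,
                         cycle_days = constants$cycle_days,
                         days_per_month = constants$days_per_month,
                         order = order),
    bsc_only = run_cohort(os_p, NULL, max_cycles = constants$max_cycles,
                          stop_threshold = constants$stop_threshold,
                          cycle_days = constants$cycle_days,
                          days_per_month = constants$days_per_month,
                          order = order))
}

#' Fit the fruquintinib-vs-BSC cost-effectiveness model
#'
#' Builds and evaluates the complete decision model for one pricing scenario:
#' Weibull overall-survival curves anchored on the trial medians (9.3 months
#' fruquintinib, 6.6 months best supportive care) with calibrated shapes,
#' exponential treatment discontinuation (median 3.7 months), the 4-week-cycle
#' lifetime Markov cohort simulation, and discounted cost/QALY accumulation
#' with one-off adverse-event burdens.
#'
#' The two scenarios differ only in the drug cost schedule: a constant
#' 1128.8 USD per treatment cycle after the national price negotiation, or
#' 3408.5 USD charged in the 1st, 2nd and 5th treatment cycles (manufacturer
#' donation scheme) before it. Everything else — survival, discontinuation,
#' utilities, BSC and AE costs — is shared, so the scenarios have identical
#' QALYs by construction.
#'
#' @param scenario `"post_negotiation"` (default) or `"pre_negotiation"`.
#' @param params Parameter registry ([default_parameters()] or the
#'   `parameters` element of [load_parameters()]).
#' @param constants Structural constants ([model_constants()]).
#' @param calibration Survival calibration: list with `shapes` (per-arm
#'   Weibull shapes, elements `treated` and `bsc_only`) and optionally
#'   `median_tx_duration` (months; overrides the constants' entry). Defaults
#'   to the frozen calibration ([frozen_calibration()]).
#' @param concurrent_bsc Charge supportive-care cost to on-treatment patients
#'   too (default `TRUE`).
#' @param cost_cycle0 Bill per-cycle costs at model entry as well (default
#'   `FALSE`: costs are billed at the end of each completed cycle).
#' @param order Within-cycle event order, see [run_cohort()].
#' @return Object of class `fruq_cea` with elements `ce` (the
#'   [compute_icer()] result), `traces`, `curves`, `params`, `constants`,
#'   `scenario`, and the convention flags. Methods: `print`, `summary`,
#'   `coef`, `simulate` (probabilistic sensitivity analysis), `plot`.
#' @seealso [tornado()], [ceac_curve()], [validate_model()]
#' @export
#' @examples
#' m <- cea_model()
#' m
#' coef(m)
cea_model <- function(scenario = c("post_negotiation", "pre_negotiation"),
                      params = default_parameters(),
                      constants = model_constants(),
                      calibration = frozen_calibration(),
                      concurrent_bsc = TRUE, cost_cycle0 = FALSE,
                      order = "death_first") {
  scenario <- match.arg(scenario)
  validate_parameters(params)
  if (is.null(calibration$shapes))
    stop("calibration must be a list with a 'shapes' element; see frozen_calibration()")
  if (!is.null(calibration$median_tx_duration))
    constants$median_tx_duration <- calibration$median_tx_duration
  traces <- build_traces(calibration$shapes, constants, order)
  values <- stats::setNames(as.list(params$base), params$name)
  ce <- evaluate_economics(values, traces, scenario,
                           concurrent_bsc = concurrent_bsc,
                           cost_cycle0 = cost_cycle0)
  structure(list(ce = ce, traces = traces[c("treated", "bsc_only")],
                 curves = traces$curves, params = params,
                 constants = constants, calibration = calibration,
                 scenario = scenario,
                 concurrent_bsc = concurrent_bsc, cost_cycle0 = cost_cycle0,
                 order = order),
            class = "fruq_cea")
}

#' @export
print.fruq_cea <- function(x, ...) {
  cat("Fruquintinib vs best supportive care, Markov cohort CEA\n")
  cat(sprintf("Scenario: %s\n\n", gsub("_", " ", x$scenario)))
  tab <- data.frame(
    row.names = c("Fruquintinib", "BSC"),
    `Cost (USD)` = c(x$ce$arm_a$cost, x$ce$arm_b$cost),
    `Effect (QALY)` = c(x$ce$arm_a$qaly, x$ce$arm_b$qaly),
    check.names = FALSE)
  print(round(tab, 4))
  cat(sprintf("\nIC  %10.1f USD\nIE  %10.5f QALY\n", x$ce$ic, x$ce$ie))
  if (is.na(x$ce$icer)) {
    cat("ICER undefined:", x$ce$dominance, "\n")
  } else {
    cat(sprintf("ICER %9.1f USD/QALY\n", x$ce$icer))
  }
  wtp <- x$constants$wtp_threshold
  nmb <- net_monetary_benefit(x$ce, wtp)
  cat(sprintf("NMB at WTP %.0f USD/QALY: %.1f USD (%scost-effective)\n",
              wtp, nmb, if (nmb > 0) "" else "not "))
  invisible(x)
}

#' @export
summary.fruq_cea <- function(object, ...) {
  med_f <- median_survival_from_trace(object$traces$treated)
  med_p <- median_survival_from_trace(object$traces$bsc_only)
  out <- list(model = object,
              median_os = c(treated = med_f, bsc_only = med_p),
              implied_hr = implied_hazard_ratio(object$curves$treated,
                                                object$curves$bsc_only,
                                                object$constants$median_os_fruq),
              horizon_cycles = c(treated = nrow(object$traces$treated) - 1,
                                 bsc_only = nrow(object$traces$bsc_only) - 1))
  class(out) <- "summary.fruq_cea"
  out
}

#' @export
print.summary.fruq_cea <- function(x, ...) {
  print(x$model)
  cat(sprintf("\nSimulated median OS: %.2f months (fruquintinib), %.2f months (BSC)\n",
              x$median_os[["treated"]], x$median_os[["bsc_only"]]))
  cat(sprintf("Implied cumulative-hazard ratio at %.1f months: %.3f\n",
              x$model$constants$median_os_fruq, x$implied_hr))
  cat(sprintf("Horizon used: %d / %d cycles\n",
              x$horizon_cycles[["treated"]], x$horizon_cycles[["bsc_only"]]))
  invisible(x)
}

#' @export
coef.fruq_cea <- function(object, ...) {
  c(shape_fruquintinib = object$curves$treated$shape,
    scale_fruquintinib = object$curves$treated$scale,
    shape_bsc = object$curves$bsc_only$shape,
    scale_bsc = object$curves$bsc_only$scale,
    median_tx_duration = object$constants$median_tx_duration)
}

#' Plot a fitted cost-effectiveness model
#'
#' Base-graphics display of the modeled overall-survival curves (lines) and
#' the simulated cohort alive fractions (points), the internal-verification
#' view of the model.
#'
#' @param x A `fruq_cea` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fruq_cea <- function(x, ...) {
  tr_f <- x$traces$treated
  tr_p <- x$traces$bsc_only
  tmax <- max(tr_f$months, tr_p$months)
  tt <- seq(0, tmax, length.out = 200)
  graphics::plot(tt, survival_at(x$curves$treated, tt), type = "l", lwd = 2,
                 xlab = "Months", ylab = "Overall survival", ylim = c(0, 1),
                 ...)
  graphics::lines(tt, survival_at(x$curves$bsc_only, tt), lwd = 2, lty = 2)
  graphics::points(tr_f$months, tr_f$on_treatment + tr_f$bsc, pch = 1, cex = 0.5)
  graphics::points(tr_p$months, tr_p$on_treatment + tr_p$bsc, pch = 2, cex = 0.5)
  graphics::legend("topright", c("Fruquintinib", "BSC"), lty = c(1, 2), lwd = 2,
                   bty = "n")
  invisible(x)
}

## Cumulative-hazard ratio of the two fitted curves at time t months; equals
## the hazard ratio exactly only under proportional hazards (equal shapes).
implied_hazard_ratio <- function(curve_a, curve_b, t) {
  log(survival_at(curve_a, t)) / log(survival_at(curve_b, t))
}
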