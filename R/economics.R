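#' Per-cycle discount factor
#'
#' Continuous-by-cycle discounting: `(1 + r)^(-t * cycle_days / 365.25)`.
#' Cycle 0 (model entry) is undiscounted.
#'
#' @param t Cycle index (vectorized), `>= 0`.
#' @param annual_rate Annual discount rate `r >= 0` (default 0.03).
#' @param cycle_days Cycle length in days (default 28).
#' @return Factor(s) in (0, 1].
#' @export
#' @examples
#' discount_factor(13, 0.03)  # one year out, about 0.971
discount_factor <- function(t, annual_rate = 0.03, cycle_days = 28) {
  if (annual_rate < 0) stop("annual_rate must be >= 0")
  (1 + annual_rate)^(-(t * cycle_days / 365.25))
}

#' One-off adverse-event burden of an arm
#'
#' Expected per-patient cost and QALY loss from grade 3/4 adverse events,
#' applied once at model entry: each event contributes its management cost and
#' its duration-adjusted disutility (`disutility * duration_days / 365.25`),
#' weighted by the trial incidence. Hypertension and platelet count decreased
#' carry zero disutility.
#'
#' @param probability Incidences in \[0, 1\] (one per event).
#' @param cost One-off management costs, USD.
#' @param disutility Disutility magnitudes (positive decrements), utility
#'   units.
#' @param duration_days Event durations, days.
#' @return List with `cost` (USD) and `qaly_loss` (QALY), both `>= 0`.
#' @export
#' @examples
#' ae_burden(c(0.212, 0.108), c(59.1, 134.4), c(0, 0.116), c(0, 14))
ae_burden <- function(probability, cost, disutility, duration_days) {
  stopifnot(length(probability) == length(cost),
            length(cost) == length(disutility),
            length(disutility) == length(duration_days))
  if (any(probability < 0 | probability > 1))
    stop("AE probabilities must lie in [0, 1]")
  if (any(disutility < 0)) stop("disutilities are stored as magnitudes >= 0")
  list(cost = sum(probability * cost),
       qaly_loss = sum(probability * disutility * duration_days / 365.25))
}

#' Drug cost schedule per billing cycle
#'
#' Drug acquisition cost as a function of the (1-based) billing cycle. After
#' the price negotiation the cost is a constant per treatment cycle. Before
#' the negotiation the manufacturer's donation scheme means patients pay only
#' in their 1st, 2nd and 5th cycles of treatment; other cycles are free.
#'
#' @param scenario `"post_negotiation"` or `"pre_negotiation"`.
#' @param cost_per_cycle USD per (paid) treatment cycle.
#' @param paid_cycles For the pre-negotiation donation scheme, the 1-based
#'   treatment cycles that are paid (default `c(1, 2, 5)`).
#' @return Function mapping a vector of billing-cycle indices (1-based) to
#'   USD.
#' @export
drug_cost_schedule <- function(scenario = c("post_negotiation", "pre_negotiation"),
                               cost_per_cycle, paid_cycles = c(1, 2, 5)) {
  scenario <- match.arg(scenario)
  if (scenario == "post_negotiation") {
    function(cycle) rep(cost_per_cycle, length(cycle))
  } else {
    function(cycle) ifelse(cycle %in% paid_cycles, cost_per_cycle, 0)
  }
}

#' Accumulate discounted cost and QALYs over a state trace
#'
#' Maps a cohort trace to the arm's discounted totals. QALYs accrue to the
#' standing cohort: every cycle `t = 0..T` contributes
#' `df(t) * alive(t) * utility * cycle_days / 365.25`, minus the one-off
#' adverse-event QALY loss. Costs are billed in arrears for completed cycles
#' of care: at the end of each cycle `t = 1..T` the cohort is charged
#' `df(t) * [on_treatment(t) * drug_cost(t) + bsc_occupancy * bsc_cost]`, so
#' model entry itself incurs only the one-off adverse-event cost. Patients on
#' fruquintinib receive supportive care concurrently by default
#' (`concurrent_bsc = TRUE`), in which case the BSC cost applies to all alive
#' patients rather than the BSC state only. `cost_cycle0 = TRUE` switches to
#' charging per-cycle costs from cycle 0 with the same occupancy weights as
#' QALYs.
#'
#' @param trace A `state_trace` from [run_cohort()].
#' @param drug_cost Function of 1-based billing cycle returning USD (see
#'   [drug_cost_schedule()]), or a single number, or `NULL`/0 for an untreated
#'   arm.
#' @param bsc_cost Best-supportive-care cost per cycle, USD.
#' @param utility Health-state utility in \[0, 1\].
#' @param annual_rate Annual discount rate (default 0.03).
#' @param ae Result of [ae_burden()] (defaults to zero burden).
#' @param concurrent_bsc Charge BSC cost to on-treatment patients too
#'   (default `TRUE`).
#' @param cost_cycle0 Also bill per-cycle costs at model entry (default
#'   `FALSE`; see Details).
#' @return List of class `arm_result`: `cost` (USD), `qaly`,
#'   `life_years` (discounted), plus a breakdown (`drug_cost`, `bsc_cost`,
#'   `ae_cost`, `ae_qaly_loss`).
#' @export
accumulate_arm <- function(trace, drug_cost = NULL, bsc_cost, utility,
                           annual_rate = 0.03,
                           ae = list(cost = 0, qaly_loss = 0),
                           concurrent_bsc = TRUE, cost_cycle0 = FALSE) {
  stopifnot(inherits(trace, "state_trace"))
  if (!(utility >= 0 && utility <= 1)) stop("utility must lie in [0, 1]")
  if (is.null(drug_cost)) drug_cost <- function(cycle) rep(0, length(cycle))
  if (is.numeric(drug_cost)) {
    dc <- drug_cost
    drug_cost <- function(cycle) rep(dc, length(cycle))
  }
  if (attr(trace, "arm") == "bsc_only" && any(drug_cost(1:5) != 0))
    stop("non-zero drug cost supplied for an arm with no on-treatment state")

  cycle_days <- attr(trace, "cycle_days")
  df <- discount_factor(trace$cycle, annual_rate, cycle_days)
  alive <- trace$on_treatment + trace$bsc
  cycle_years <- cycle_days / 365.25

  life_years <- sum(df * alive) * cycle_years
  qaly <- sum(df * alive) * utility * cycle_years - ae$qaly_loss

  bill <- if (cost_cycle0) seq_along(df) else seq_along(df)[-1]
  drug_total <- sum(df[bill] * trace$on_treatment[bill] * drug_cost(trace$cycle[bill]))
  bsc_base <- if (concurrent_bsc) alive else trace$bsc
  bsc_total <- sum(df[bill] * bsc_base[bill]) * bsc_cost

  structure(list(cost = drug_total + bsc_total + ae$cost,
                 qaly = qaly,
                 life_years = life_years,
                 drug_cost = drug_total, bsc_cost = bsc_total,
                 ae_cost = ae$cost, ae_qaly_loss = ae$qaly_loss),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm result: cost %.1f USD, %.4f QALYs (%.4f discounted life-years)\n",
              x$cost, x$qaly, x$life_years))
  invisible(x)
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes incremental cost `IC = cost_a - cost_b`, incremental effectiveness
#' `IE = qaly_a - qaly_b`, and the ICER `IC/IE`. When either increment is not
#' positive the ICER is undefined and the comparison is labelled by its
#' cost-effectiveness-plane quadrant instead (`"a_dominant"` when a is cheaper
#' and more effective, `"b_dominant"` for the reverse, `"indifferent"` when
#' both increments are zero).
#'
#' @param a,b `arm_result` objects (`a` is the intervention, `b` the
#'   comparator).
#' @return List of class `ce_result`: `arm_a`, `arm_b`, `ic`, `ie`, `icer`
#'   (`NA` when undefined), and `dominance` label.
#' @export
#' @examples
#' a <- structure(list(cost = 20750.9, qaly = 0.6404), class = "arm_result")
#' b <- structure(list(cost = 12042.2, qaly = 0.4776), class = "arm_result")
#' compute_icer(a, b)
compute_icer <- function(a, b) {
  ic <- a$cost - b$cost
  ie <- a$qaly - b$qaly
  dominance <- if (ic > 0 && ie > 0) "tradeoff_a_more_costly_more_effective"
  else if (ic < 0 && ie < 0) "tradeoff_a_cheaper_less_effective"
  else if (ic <= 0 && ie >= 0 && !(ic == 0 && ie == 0)) "a_dominant"
  else if (ic >= 0 && ie <= 0 && !(ic == 0 && ie == 0)) "b_dominant"
  else "indifferent"
  icer <- if (ic > 0 && ie > 0 || ic < 0 && ie < 0) ic / ie else NA_real_
  structure(list(arm_a = a, arm_b = b, ic = ic, ie = ie, icer = icer,
                 dominance = dominance),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("Incremental cost %.1f USD, incremental effect %.5f QALY\n",
              x$ic, x$ie))
  if (is.na(x$icer)) {
    cat("ICER undefined:", x$dominance, "\n")
  } else {
    cat(sprintf("ICER %.1f USD/QALY\n", x$icer))
  }
  invisible(x)
}

#' Net monetary benefit of a comparison
#'
#' `NMB(wtp) = wtp * IE - IC`; positive NMB means the intervention is
#' cost-effective at that willingness-to-pay threshold. This is the decision
#' statistic behind the cost-effectiveness acceptability curve.
#'
#' @param ce A `ce_result` from [compute_icer()], or a list with `ic`/`ie`.
#' @param wtp Willingness-to-pay threshold(s), USD/QALY, `>= 0`.
#' @return NMB in USD (vectorized over `wtp`).
#' @export
net_monetary_benefit <- function(ce, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  wtp * ce$ie - ce$ic
}
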