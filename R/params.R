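#' Default model parameter registry
#'
#' Returns the registry of every economic and utility input of the model: the
#' grade 3/4 adverse-event (AE) incidences observed in the pivotal trial, the
#' one-off AE management costs, per-cycle drug and best-supportive-care (BSC)
#' costs under the post- and pre-price-negotiation scenarios, the baseline
#' health-state utility, AE disutilities with their durations, and the annual
#' discount rate. Each row carries a base value, a deterministic
#' sensitivity-analysis range, and the distribution family used when the
#' parameter is sampled in probabilistic sensitivity analysis.
#'
#' Disutilities are stored as positive magnitudes and subtracted during QALY
#' accounting, so the `beta` family applies to them directly. Hypertension and
#' thrombocytopenia (platelet count decreased) carry a disutility of zero and
#' are held fixed. The discount rate has no sampling distribution: it is varied
#' only in one-way sensitivity analysis over 0.00-0.05.
#'
#' Grade 3/4 proteinuria is named among the AEs whose incidence differed
#' between arms, but no incidence, cost, or disutility is published for it;
#' the registry therefore carries the four costed fruquintinib AEs plus
#' hypertension in the BSC arm.
#'
#' @return A data frame of class `cea_parameters` with columns `name`, `base`,
#'   `low`, `high`, `distribution` (`"beta"`, `"gamma"` or `"fixed"`),
#'   `units`, and `label`.
#' @seealso [load_parameters()] to read a modified registry from a YAML/JSON
#'   config, [beta_from_point_and_range()] and [gamma_from_point_and_range()]
#'   for the distribution construction.
#' @export
#' @examples
#' p <- default_parameters()
#' p[p$name == "cost_bsc_per_cycle", ]
default_parameters <- function() {
  row <- function(name, base, low, high, distribution, units, label) {
    data.frame(name = name, base = base, low = low, high = high,
               distribution = distribution, units = units, label = label,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("p_ae_hypertension_fruq", 0.212, 0.170, 0.254, "beta",
        "probability", "Grade 3/4 hypertension incidence, fruquintinib"),
    row("p_ae_hfs_fruq", 0.108, 0.086, 0.130, "beta",
        "probability", "Grade 3/4 hand-foot syndrome incidence, fruquintinib"),
    row("p_ae_diarrhea_fruq", 0.029, 0.0232, 0.0348, "beta",
        "probability", "Grade 3/4 diarrhea incidence, fruquintinib"),
    row("p_ae_platelet_fruq", 0.025, 0.02, 0.03, "beta",
        "probability", "Grade 3/4 platelet count decreased incidence, fruquintinib"),
    row("p_ae_hypertension_bsc", 0.022, 0.0176, 0.0264, "beta",
        "probability", "Grade 3/4 hypertension incidence, BSC"),
    row("cost_bsc_per_cycle", 1415.4, 1022.8, 2021.5, "gamma",
        "USD per cycle", "Cost of best supportive care"),
    row("cost_fruq_post", 1128.8, 903.0, 1354.5, "gamma",
        "USD per cycle", "Cost of fruquintinib after price negotiation"),
    row("cost_fruq_pre", 3408.5, 2726.8, 4090.2, "gamma",
        "USD per paid cycle", "Cost of fruquintinib before price negotiation"),
    row("cost_ae_hypertension", 59.1, 47.28, 70.92, "gamma",
        "USD one-off", "Management cost, grade 3/4 hypertension"),
    row("cost_ae_hfs", 134.4, 107.58, 161.3, "gamma",
        "USD one-off", "Management cost, grade 3/4 hand-foot syndrome"),
    row("cost_ae_diarrhea", 844.3, 828.5, 1054.6, "gamma",
        "USD one-off", "Management cost, grade 3/4 diarrhea"),
    row("cost_ae_platelet", 3551.7, 3156.8, 3980.2, "gamma",
        "USD one-off", "Management cost, grade 3/4 platelet count decreased"),
    row("utility_baseline", 0.66, 0.59, 0.735, "beta",
        "utility", "Baseline health-state utility"),
    row("dur_ae_hfs", 14, 11.2, 16.8, "gamma",
        "days", "Duration, grade 3/4 hand-foot syndrome"),
    row("dur_ae_diarrhea", 5, 4, 6, "gamma",
        "days", "Duration, grade 3/4 diarrhea"),
    row("disu_ae_hfs", 0.116, 0.093, 0.139, "beta",
        "utility decrement", "Disutility magnitude, hand-foot syndrome"),
    row("disu_ae_diarrhea", 0.103, 0.082, 0.123, "beta",
        "utility decrement", "Disutility magnitude, diarrhea"),
    row("disu_ae_hypertension", 0, 0, 0, "fixed",
        "utility decrement", "Disutility magnitude, hypertension (assumed 0)"),
    row("disu_ae_platelet", 0, 0, 0, "fixed",
        "utility decrement", "Disutility magnitude, platelet count decreased (assumed 0)"),
    row("discount_rate", 0.03, 0.00, 0.05, "fixed",
        "annual rate", "Annual discount rate for costs and QALYs")
  )
  class(out) <- c("cea_parameters", "data.frame")
  validate_parameters(out)
}

#' Structural model constants
#'
#' Constants that define the model's time grid, survival calibration anchors
#' and decision threshold, as opposed to the sampled economic parameters of
#' [default_parameters()].
#'
#' * `cycle_days` (28): one model cycle, 21 dosing days plus a 7-day break.
#' * `dosing_days` (21): days of fruquintinib dosing per cycle.
#' * `days_per_month` (30.4375): day/month conversion (365.25 / 12).
#' * `median_os_fruq`, `median_os_bsc`: trial median overall survival,
#'   9.3 and 6.6 months.
#' * `os_hazard_ratio` (0.65): trial OS hazard ratio, used as a calibration
#'   cross-check only.
#' * `median_tx_duration` (3.7 months): median time on fruquintinib, assumed
#'   exponential; defaults to the trial median progression-free survival.
#' * `unit_drug_cost_post` / `unit_drug_cost_pre`: USD per 5 mg capsule,
#'   53.8 after and 162.3 before the price negotiation.
#' * `wtp_threshold` (27130 USD/QALY): three times 2018 Chinese per-capita
#'   GDP, stored rather than derived.
#' * `max_cycles` (260) and `stop_threshold` (1e-3): the lifetime horizon, 20
#'   years of 4-week cycles or a residual alive fraction below 0.1%.
#'
#' @param ... Named overrides for any constant.
#' @return Named list of constants.
#' @export
model_constants <- function(...) {
  const <- list(
    cycle_days = 28,
    dosing_days = 21,
    days_per_month = 30.4375,
    median_os_fruq = 9.3,
    median_os_bsc = 6.6,
    os_hazard_ratio = 0.65,
    median_tx_duration = 3.7,
    unit_drug_cost_post = 53.8,
    unit_drug_cost_pre = 162.3,
    wtp_threshold = 27130,
    max_cycles = 260,
    stop_threshold = 1e-3
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(const))
    if (length(unknown))
      stop("unknown model constant(s): ", paste(unknown, collapse = ", "))
    const[names(dots)] <- dots
  }
  if (!isTRUE(all.equal(const$cycle_days, const$dosing_days + 7)))
    stop("cycle_days must equal dosing_days + 7 rest days")
  const
}

#' Validate a parameter registry
#'
#' Checks the registry invariants: `low <= base <= high`; beta-distributed
#' quantities (probabilities, utilities, disutility magnitudes) bounded in
#' \[0, 1\]; gamma-distributed quantities strictly positive at the lower bound;
#' no duplicated names.
#'
#' @param params A `cea_parameters` data frame.
#' @return The registry, invisibly unchanged, or an error naming the offending
#'   parameter and rule.
#' @export
validate_parameters <- function(params) {
  need <- c("name", "base", "low", "high", "distribution", "units")
  missing_cols <- setdiff(need, names(params))
  if (length(missing_cols))
    stop("parameter table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(params$name))
    stop("duplicated parameter name(s): ",
         paste(unique(params$name[duplicated(params$name)]), collapse = ", "))
  if (!all(params$distribution %in% c("beta", "gamma", "fixed")))
    stop("distribution must be one of beta, gamma, fixed")
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    if (!(p$low <= p$base && p$base <= p$high))
      stop(sprintf("parameter '%s' violates low <= base <= high", p$name))
    if (p$distribution == "beta" && !(p$low >= 0 && p$high <= 1))
      stop(sprintf("parameter '%s': beta-distributed values must lie in [0, 1]", p$name))
    if (p$distribution == "gamma" && !(p$low > 0))
      stop(sprintf("parameter '%s': gamma-distributed values require low > 0", p$name))
  }
  invisible(params)
}

#' Load a parameter registry from a config file
#'
#' Reads a YAML or JSON config whose `parameters` section lists blocks
#' `{name, base, low, high, distribution, units}`. Entries override the
#' matching rows of [default_parameters()]; omitted parameters keep their
#' defaults; unknown names are a hard error. The optional `constants` section
#' overrides [model_constants()] entries the same way.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for the
#'   packaged defaults.
#' @return A list with elements `parameters` (validated `cea_parameters`
#'   data frame), `constants` (list, see [model_constants()]) and
#'   `calibration` (frozen survival calibration, see [frozen_calibration()];
#'   taken from the config's `calibration` block when present).
#' @export
#' @examples
#' cfg <- load_parameters(system.file("extdata", "default_config.yaml",
#'                                    package = "fruqcea"))
#' cfg$constants$wtp_threshold
load_parameters <- function(path = NULL) {
  params <- default_parameters()
  const_over <- list()
  calibration <- frozen_calibration()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    }
    for (blk in cfg$parameters) {
      if (is.null(blk$name)) stop("config parameter block lacks a name")
      idx <- match(blk$name, params$name)
      if (is.na(idx)) stop("unknown parameter name in config: ", blk$name)
      for (fld in intersect(names(blk), c("base", "low", "high")))
        params[[fld]][idx] <- as.numeric(blk[[fld]])
      if (!is.null(blk$distribution))
        params$distribution[idx] <- as.character(blk$distribution)
      if (!is.null(blk$units)) params$units[idx] <- as.character(blk$units)
    }
    if (!is.null(cfg$constants)) const_over <- cfg$constants
    if (!is.null(cfg$calibration)) {
      cal <- cfg$calibration
      if (is.null(cal$shapes$treated) || is.null(cal$shapes$bsc_only))
        stop("config calibration block needs shapes: {treated, bsc_only}")
      calibration <- list(
        shapes = list(treated = as.numeric(cal$shapes$treated),
                      bsc_only = as.numeric(cal$shapes$bsc_only)),
        median_tx_duration = if (is.null(cal$median_tx_duration)) NULL
                             else as.numeric(cal$median_tx_duration))
    }
  }
  validate_parameters(params)
  list(parameters = params,
       constants = do.call(model_constants, const_over),
       calibration = calibration)
}

## Base value lookup by name; errors on unknown names so typos never become
## silent zeros.
param_base <- function(params, name) {
  idx <- match(name, params$name)
  if (anyNA(idx)) stop("unknown parameter name(s): ",
                       paste(name[is.na(idx)], collapse = ", "))
  stats::setNames(params$base[idx], name)
}

#' Method-of-moments Beta distribution from a point estimate and range
#'
#' Constructs the Beta distribution whose mean equals the base value and whose
#' standard deviation is `(high - low) / 3.92`, treating the deterministic
#' sensitivity range as a 95% interval. This is the construction used for all
#' beta-family parameters (AE probabilities, utility, disutility magnitudes)
#' in probabilistic sensitivity analysis.
#'
#' @param base Mean, strictly inside (0, 1).
#' @param low,high Range endpoints, `low < high`.
#' @param z Divisor converting range width to SD; 3.92 treats the range as a
#'   95% normal interval, 4 is a common alternative.
#' @return Named numeric vector `c(shape1, shape2)` for [stats::rbeta()].
#' @export
#' @examples
#' beta_from_point_and_range(0.5, 0.304, 0.696)  # shape1 = shape2 = 12
beta_from_point_and_range <- function(base, low, high, z = 3.92) {
  if (!(base > 0 && base < 1)) stop("beta mean must lie strictly in (0, 1)")
  if (!(low < high)) stop("need low < high")
  v <- ((high - low) / z)^2
  if (v >= base * (1 - base))
    stop(sprintf("infeasible Beta: implied variance %.4g >= mean(1-mean) = %.4g",
                 v, base * (1 - base)))
  nu <- base * (1 - base) / v - 1
  c(shape1 = base * nu, shape2 = (1 - base) * nu)
}

#' Method-of-moments Gamma distribution from a point estimate and range
#'
#' Gamma distribution with mean `base` and SD `(high - low) / 3.92`
#' (shape = mean^2/var, scale = var/mean); used for all cost and duration
#' parameters in probabilistic sensitivity analysis.
#'
#' @inheritParams beta_from_point_and_range
#' @param base Mean, strictly positive.
#' @return Named numeric vector `c(shape, scale)` for [stats::rgamma()].
#' @export
#' @examples
#' gamma_from_point_and_range(1415.4, 1022.8, 2021.5)
gamma_from_point_and_range <- function(base, low, high, z = 3.92) {
  if (!(base > 0)) stop("gamma mean must be > 0")
  if (!(low < high)) stop("need low < high")
  v <- ((high - low) / z)^2
  c(shape = base^2 / v, scale = v / base)
}

## One random draw function per registry row. Fixed rows (and zero-width
## ranges) return the base value.
parameter_sampler <- function(p, z = 3.92) {
  if (p$distribution == "fixed" || p$high <= p$low) {
    base <- p$base
    return(function(n) rep(base, n))
  }
  if (p$distribution == "beta") {
    sh <- tryCatch(beta_from_point_and_range(p$base, p$low, p$high, z),
                   error = function(e) stop(sprintf(
                     "parameter '%s': %s", p$name, conditionMessage(e)), call. = FALSE))
    function(n) stats::rbeta(n, sh[["shape1"]], sh[["shape2"]])
  } else {
    sh <- tryCatch(gamma_from_point_and_range(p$base, p$low, p$high, z),
                   error = function(e) stop(sprintf(
                     "parameter '%s': %s", p$name, conditionMessage(e)), call. = FALSE))
    function(n) stats::rgamma(n, shape = sh[["shape"]], scale = sh[["scale"]])
  }
}
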