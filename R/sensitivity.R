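#' One-way deterministic sensitivity analysis (tornado)
#'
#' Recomputes the full ICER with each registry parameter set to its low and
#' then its high bound, all others held at base, and returns the entries
#' sorted by swing (`|icer_high - icer_low|`) — the data behind a tornado
#' diagram. Ranges are the registry's printed ranges: plus/minus 20% of the
#' base for most parameters, 0.59-0.735 for utility, 0.00-0.05 for the
#' discount rate. Parameters that do not enter the active scenario (e.g. the
#' pre-negotiation drug cost in the post-negotiation scenario) appear with
#' zero swing.
#'
#' @param model A fitted [cea_model()].
#' @param parameters Names of registry parameters to vary (default: all with
#'   a non-degenerate range).
#' @return Data frame of class `cea_tornado`, columns `parameter`,
#'   `icer_base`, `icer_low`, `icer_high`, `swing`, sorted by decreasing
#'   swing.
#' @export
#' @examples
#' head(tornado(cea_model()), 3)
tornado <- function(model, parameters = NULL) {
  stopifnot(inherits(model, "fruq_cea"))
  params <- model$params
  if (is.null(parameters))
    parameters <- params$name[params$high > params$low]
  unknown <- setdiff(parameters, params$name)
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))

  base_values <- stats::setNames(as.list(params$base), params$name)
  icer_at <- function(values) {
    evaluate_economics(values, model$traces, model$scenario,
                       concurrent_bsc = model$concurrent_bsc,
                       cost_cycle0 = model$cost_cycle0)$icer
  }
  rows <- lapply(parameters, function(nm) {
    i <- match(nm, params$name)
    lo <- base_values; lo[[nm]] <- params$low[i]
    hi <- base_values; hi[[nm]] <- params$high[i]
    data.frame(parameter = nm, icer_base = model$ce$icer,
               icer_low = icer_at(lo), icer_high = icer_at(hi))
  })
  out <- do.call(rbind, rows)
  out$swing <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  class(out) <- c("cea_tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' `simulate()` on a fitted model draws `nsim` independent parameter vectors
#' from the registry's Beta/Gamma distributions (method of moments from base
#' value and range, see [beta_from_point_and_range()]), holds fixed-family
#' parameters (discount rate, zero disutilities) and the survival curves at
#' their base calibration, re-evaluates the economic model per draw, and
#' returns one row per draw.
#'
#' @param object A fitted [cea_model()].
#' @param nsim Number of Monte Carlo draws (default 1000).
#' @param seed Optional integer seed for reproducibility; when supplied the
#'   RNG state is restored on exit, as for [stats::simulate()].
#' @param ... Unused.
#' @return Data frame of class `cea_psa` with columns `cost_treated`,
#'   `qaly_treated`, `cost_bsc`, `qaly_bsc`, `ic`, `ie`, the drawn parameter
#'   values as attribute `draws`, and the base-case `ce_result` as attribute
#'   `base_ce`.
#' @seealso [ceac_curve()]
#' @export
#' @examples
#' psa <- simulate(cea_model(), nsim = 50, seed = 1)
#' colMeans(psa[, c("ic", "ie")])
simulate.fruq_cea <- function(object, nsim = 1000, seed = NULL, ...) {
  stopifnot(nsim >= 1)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  params <- object$params
  draws <- matrix(NA_real_, nrow = nsim, ncol = nrow(params),
                  dimnames = list(NULL, params$name))
  for (i in seq_len(nrow(params)))
    draws[, i] <- parameter_sampler(params[i, ])(nsim)

  res <- matrix(NA_real_, nrow = nsim, ncol = 6,
                dimnames = list(NULL, c("cost_treated", "qaly_treated",
                                        "cost_bsc", "qaly_bsc", "ic", "ie")))
  for (s in seq_len(nsim)) {
    ce <- evaluate_economics(as.list(draws[s, ]), object$traces,
                             object$scenario,
                             concurrent_bsc = object$concurrent_bsc,
                             cost_cycle0 = object$cost_cycle0)
    res[s, ] <- c(ce$arm_a$cost, ce$arm_a$qaly, ce$arm_b$cost, ce$arm_b$qaly,
                  ce$ic, ce$ie)
  }
  out <- as.data.frame(res)
  structure(out, class = c("cea_psa", "data.frame"),
            draws = as.data.frame(draws), base_ce = object$ce,
            wtp_threshold = object$constants$wtp_threshold,
            scenario = object$scenario)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with positive
#' net monetary benefit `wtp * IE - IC`.
#'
#' @param psa A `cea_psa` data frame from [simulate()] (or any data frame
#'   with columns `ic` and `ie`).
#' @param wtp Grid of willingness-to-pay thresholds, USD/QALY (default 0 to
#'   120,000 by 1,000).
#' @return Data frame of class `cea_ceac` with columns `wtp` and
#'   `probability_cost_effective`.
#' @export
#' @examples
#' psa <- simulate(cea_model(), nsim = 100, seed = 1)
#' ceac_curve(psa, wtp = c(27130, 54000))
ceac_curve <- function(psa, wtp = seq(0, 120000, by = 1000)) {
  if (!all(c("ic", "ie") %in% names(psa)))
    stop("psa must have columns 'ic' and 'ie'")
  if (nrow(psa) == 0) stop("empty PSA sample")
  prob <- vapply(wtp, function(w) mean(w * psa$ie - psa$ic > 0), numeric(1))
  structure(data.frame(wtp = wtp, probability_cost_effective = prob),
            class = c("cea_ceac", "data.frame"))
}

#' @export
plot.cea_psa <- function(x, wtp = seq(0, 120000, by = 1000), ...) {
  cc <- ceac_curve(x, wtp)
  graphics::plot(cc$wtp, cc$probability_cost_effective, type = "l", lwd = 2,
                 xlab = "Willingness to pay (USD/QALY)",
                 ylab = "Probability cost-effective", ylim = c(0, 1), ...)
  thr <- attr(x, "wtp_threshold")
  if (!is.null(thr)) graphics::abline(v = thr, lty = 3)
  invisible(x)
}

#' @export
plot.cea_tornado <- function(x, n = 10, ...) {
  y <- utils::head(x, n)
  y <- y[rev(seq_len(nrow(y))), ]
  rng <- range(c(y$icer_low, y$icer_high, y$icer_base))
  graphics::plot(NA, xlim = rng, ylim = c(0.5, nrow(y) + 0.5),
                 xlab = "ICER (USD/QALY)", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(y)), labels = y$parameter, las = 1,
                 cex.axis = 0.7)
  graphics::segments(y$icer_low, seq_len(nrow(y)), y$icer_high,
                     seq_len(nrow(y)), lwd = 6, col = "grey50")
  graphics::abline(v = y$icer_base[1], lty = 2)
  invisible(x)
}
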