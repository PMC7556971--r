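## Shared fixtures: the frozen base-case models are deterministic, so build
## them once per test run.
.fixture_env <- new.env(parent = emptyenv())

base_model <- function(scenario = "post_negotiation") {
  key <- paste0("model_", scenario)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- cea_model(scenario)
  .fixture_env[[key]]
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}

## Published base-case outputs (post-negotiation table, pre-negotiation
## scenario, trial medians) used across tests.
published <- list(
  cost_treated = 20750.9, cost_bsc = 12042.2,
  qaly_treated = 0.6404, qaly_bsc = 0.4776,
  ic_post = 8708.7, ic_pre = 11547.8, ie = 0.16275,
  icer_post = 53508.7, icer_pre = 70952.6,
  cost_treated_pre = 23590.0,
  median_os = c(treated = 9.3, bsc = 6.6),
  wtp = 27130
)
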