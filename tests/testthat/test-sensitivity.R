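test_that("tornado entries are sorted and keep the base ICER fixed", {
  torn <- tornado(base_model())
  expect_s3_class(torn, "cea_tornado")
  expect_true(all(diff(torn$swing) <= 1e-9))
  expect_equal(unique(torn$icer_base), base_model()$ce$icer)
  # every varied parameter appears exactly once
  expect_false(anyDuplicated(torn$parameter) > 0)
})

test_that("the dominant one-way drivers are BSC cost, drug cost and utility", {
  torn <- tornado(base_model())
  expect_setequal(torn$parameter[1:3],
                  c("cost_bsc_per_cycle", "cost_fruq_post", "utility_baseline"))
  # AE durations and disutilities sit at the bottom of the diagram
  minor <- c("dur_ae_hfs", "dur_ae_diarrhea", "disu_ae_hfs", "disu_ae_diarrhea")
  expect_true(all(match(minor, torn$parameter) > 5))
})

test_that("one-way ICERs never cross the willingness-to-pay threshold", {
  torn <- tornado(base_model())
  expect_gt(min(c(torn$icer_low, torn$icer_high)), published$wtp)
})

test_that("a parameter outside the active scenario has zero swing", {
  torn <- tornado(base_model())  # post-negotiation
  expect_equal(torn$swing[torn$parameter == "cost_fruq_pre"], 0)
  torn_pre <- tornado(base_model("pre_negotiation"))
  expect_equal(torn_pre$swing[torn_pre$parameter == "cost_fruq_post"], 0)
  expect_gt(torn_pre$swing[torn_pre$parameter == "cost_fruq_pre"], 0)
})

test_that("ICER responds linearly to linear-in-cost parameters", {
  m <- base_model()
  torn <- tornado(m, parameters = "cost_bsc_per_cycle")
  p <- m$params[m$params$name == "cost_bsc_per_cycle", ]
  # two-point linearity: interpolating low/high at the base value recovers
  # the base ICER
  w <- (p$base - p$low) / (p$high - p$low)
  expect_equal((1 - w) * torn$icer_low + w * torn$icer_high, m$ce$icer,
               tolerance = 1e-9)
})

test_that("unknown tornado parameters are a hard error", {
  expect_error(tornado(base_model(), parameters = "no_such_knob"),
               "no_such_knob")
})

test_that("PSA is reproducible under a seed and leaves the RNG state alone", {
  m <- base_model()
  set.seed(999); marker <- runif(1)
  a <- simulate(m, nsim = 50, seed = 7)
  b <- simulate(m, nsim = 50, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  set.seed(999)
  expect_identical(runif(1), marker)  # seed handling restored the state
  c2 <- simulate(m, nsim = 50, seed = 8)
  expect_false(identical(a$ic, c2$ic))
})

test_that("degenerate distributions collapse the PSA onto the base case", {
  params <- default_parameters()
  params$distribution[] <- "fixed"
  m <- cea_model(params = params)
  psa <- simulate(m, nsim = 5, seed = 1)
  expect_equal(psa$ic, rep(m$ce$ic, 5), tolerance = 1e-12)
  expect_equal(psa$ie, rep(m$ce$ie, 5), tolerance = 1e-12)
})

test_that("sampled parameters keep their registry means", {
  params <- default_parameters()
  set.seed(31)
  bsc <- fruqcea:::parameter_sampler(
    params[params$name == "cost_bsc_per_cycle", ])(1e5)
  expect_rel_equal(mean(bsc), 1415.4, 0.005)

  psa <- simulate(base_model(), nsim = 500, seed = 31)
  draws <- attr(psa, "draws")
  # supports respected: probabilities and utilities in [0,1], costs positive
  expect_true(all(draws$utility_baseline > 0 & draws$utility_baseline < 1))
  expect_true(all(draws$p_ae_hfs_fruq >= 0 & draws$p_ae_hfs_fruq <= 1))
  expect_true(all(draws$cost_fruq_post > 0))
  # fixed rows never vary
  expect_equal(unique(draws$discount_rate), 0.03)
})

test_that("PSA means converge to the base case (mean-preserving sampling)", {
  psa <- simulate(base_model(), nsim = 4000, seed = 13)
  ce <- base_model()$ce
  expect_rel_equal(mean(psa$ic), ce$ic, 0.02)
  expect_rel_equal(mean(psa$ie), ce$ie, 0.02)
})

test_that("the acceptability curve is a proper CDF-like summary of NMB", {
  psa <- simulate(base_model(), nsim = 500, seed = 5)
  cc <- ceac_curve(psa)
  expect_true(all(cc$probability_cost_effective >= 0 &
                  cc$probability_cost_effective <= 1))
  # all draws gain QALYs, so the curve is non-decreasing with limits
  # fraction(IC < 0) at zero WTP and 1 as WTP grows without bound
  expect_true(all(psa$ie > 0))
  expect_true(all(diff(cc$probability_cost_effective) >= 0))
  expect_equal(cc$probability_cost_effective[cc$wtp == 0], mean(psa$ic < 0))
  expect_equal(ceac_curve(psa, 1e9)$probability_cost_effective,
               mean(psa$ie > 0))
  expect_error(ceac_curve(psa[0, ]), "empty")
})
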