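test_that("discount factors follow the day-fraction exponent", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(0:50, 0), rep(1, 51))
  # 13 cycles is 364 days, one day short of a year
  expect_equal(discount_factor(13, 0.03), 1.03^(-364 / 365.25),
               tolerance = 1e-12)
  expect_equal(discount_factor(13, 0.03), 0.970972, tolerance = 1e-5)
  expect_error(discount_factor(1, -0.01), ">= 0")
})

test_that("adverse-event burdens sum incidence-weighted costs and disutilities", {
  # fruquintinib arm: four costed events, two with non-zero disutility
  b <- ae_burden(probability = c(0.212, 0.108, 0.029, 0.025),
                 cost = c(59.1, 134.4, 844.3, 3551.7),
                 disutility = c(0, 0.116, 0.103, 0),
                 duration_days = c(0, 14, 5, 0))
  expect_equal(b$cost, 140.3216, tolerance = 1e-6)
  expect_equal(b$qaly_loss, 5.21087e-4, tolerance = 1e-5)

  # BSC arm: hypertension only, no disutility
  b2 <- ae_burden(0.022, 59.1, 0, 0)
  expect_equal(b2$cost, 1.3002, tolerance = 1e-6)
  expect_equal(b2$qaly_loss, 0)

  expect_error(ae_burden(1.2, 1, 0, 0), "\\[0, 1\\]")
  expect_error(ae_burden(0.5, 1, -0.1, 1), "magnitudes")
})

test_that("drug cost schedules encode the two pricing scenarios", {
  post <- drug_cost_schedule("post_negotiation", 1128.8)
  expect_equal(post(1:6), rep(1128.8, 6))
  pre <- drug_cost_schedule("pre_negotiation", 3408.5)
  expect_equal(pre(1:6), c(3408.5, 3408.5, 0, 0, 3408.5, 0))
})

test_that("accumulation matches a hand-built one-cycle example", {
  # full occupancy in BSC for one completed cycle, undiscounted
  tr <- run_cohort(weibull_from_median(1e9, 1), NULL, max_cycles = 1,
                   stop_threshold = 0)
  res <- accumulate_arm(tr, NULL, bsc_cost = 1415.4, utility = 0.66,
                        annual_rate = 0)
  # one billed cycle of BSC; QALYs accrue at cycles 0 and 1
  expect_equal(res$cost, 1415.4, tolerance = 1e-6)
  expect_equal(res$qaly, 2 * 0.66 * 28 / 365.25, tolerance = 1e-6)
  # with entry billing enabled, cycle 0 is charged as well
  res0 <- accumulate_arm(tr, NULL, bsc_cost = 1415.4, utility = 0.66,
                         annual_rate = 0, cost_cycle0 = TRUE)
  expect_equal(res0$cost, 2 * 1415.4, tolerance = 1e-6)

  # zero utility and zero costs give a zero result
  z <- accumulate_arm(tr, NULL, bsc_cost = 0, utility = 0, annual_rate = 0.03)
  expect_equal(z$cost, 0)
  expect_equal(z$qaly, 0)
})

test_that("accumulation rejects a drug schedule on an untreated arm", {
  tr <- run_cohort(weibull_from_median(6.6, 1.2))
  expect_error(accumulate_arm(tr, 1128.8, bsc_cost = 1415.4, utility = 0.66),
               "no on-treatment state")
  expect_error(accumulate_arm(tr, NULL, bsc_cost = 1415.4, utility = 1.2),
               "\\[0, 1\\]")
})

test_that("QALYs are bounded by utility-weighted discounted life-years", {
  m <- base_model()
  for (arm in list(m$ce$arm_a, m$ce$arm_b)) {
    expect_lte(arm$qaly, 0.66 * arm$life_years + 1e-12)
    expect_gte(arm$cost, 0)
    expect_gte(arm$qaly, 0)
  }
})

test_that("removing adverse events raises QALYs and lowers cost", {
  params <- default_parameters()
  ae_rows <- grepl("^p_ae_", params$name)
  params$base[ae_rows] <- 0
  params$low[ae_rows] <- 0
  params$high[ae_rows] <- 0
  params$distribution[ae_rows] <- "fixed"
  no_ae <- cea_model(params = params)
  m <- base_model()
  expect_gt(no_ae$ce$arm_a$qaly, m$ce$arm_a$qaly)
  expect_lt(no_ae$ce$arm_a$cost, m$ce$arm_a$cost)
  expect_lt(no_ae$ce$arm_b$cost, m$ce$arm_b$cost)
})

test_that("raising the discount rate weakly lowers every arm total", {
  params <- default_parameters()
  params$base[params$name == "discount_rate"] <- 0.05
  high_r <- cea_model(params = params)
  m <- base_model()
  expect_lt(high_r$ce$arm_a$cost, m$ce$arm_a$cost)
  expect_lt(high_r$ce$arm_a$qaly, m$ce$arm_a$qaly)
  expect_lt(high_r$ce$arm_b$cost, m$ce$arm_b$cost)
  expect_lt(high_r$ce$arm_b$qaly, m$ce$arm_b$qaly)
})

test_that("ICER computation handles trade-offs, dominance and ties", {
  a <- structure(list(cost = 20750.9, qaly = 0.6404), class = "arm_result")
  b <- structure(list(cost = 12042.2, qaly = 0.4776), class = "arm_result")
  ce <- compute_icer(a, b)
  expect_equal(ce$ic, 8708.7, tolerance = 1e-10)
  expect_equal(ce$ie, 0.1628, tolerance = 1e-10)
  expect_equal(ce$icer, 8708.7 / 0.1628, tolerance = 1e-10)

  # antisymmetry: swapping arms negates increments, keeps the ICER
  sw <- compute_icer(b, a)
  expect_equal(sw$ic, -ce$ic)
  expect_equal(sw$ie, -ce$ie)
  expect_equal(sw$icer, ce$icer)

  tie <- compute_icer(a, a)
  expect_true(is.na(tie$icer))
  expect_equal(tie$dominance, "indifferent")

  cheap_better <- compute_icer(
    structure(list(cost = 100, qaly = 1), class = "arm_result"),
    structure(list(cost = 200, qaly = 0.5), class = "arm_result"))
  expect_true(is.na(cheap_better$icer))
  expect_equal(cheap_better$dominance, "a_dominant")
})

test_that("net monetary benefit is linear in WTP with the defining roots", {
  ce <- base_model()$ce
  expect_equal(net_monetary_benefit(ce, 0), -ce$ic)
  expect_equal(net_monetary_benefit(ce, ce$icer), 0, tolerance = 1e-6)
  expect_lt(net_monetary_benefit(ce, 27130), 0)  # not cost-effective at 3x GDP
  expect_error(net_monetary_benefit(ce, -5), ">= 0")
})
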