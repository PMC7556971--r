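test_that("default registry carries every published input exactly once", {
  p <- default_parameters()
  expect_s3_class(p, "cea_parameters")
  expect_false(anyDuplicated(p$name) > 0)

  expect_row <- function(name, base, low, high, dist) {
    i <- match(name, p$name)
    expect_false(is.na(i), label = paste("registry row", name))
    expect_equal(unname(unlist(p[i, c("base", "low", "high")])),
                 c(base, low, high))
    expect_identical(p$distribution[i], dist)
  }
  expect_row("cost_bsc_per_cycle", 1415.4, 1022.8, 2021.5, "gamma")
  expect_row("p_ae_hypertension_fruq", 0.212, 0.170, 0.254, "beta")
  expect_row("p_ae_hfs_fruq", 0.108, 0.086, 0.130, "beta")
  expect_row("p_ae_diarrhea_fruq", 0.029, 0.0232, 0.0348, "beta")
  expect_row("p_ae_platelet_fruq", 0.025, 0.02, 0.03, "beta")
  expect_row("p_ae_hypertension_bsc", 0.022, 0.0176, 0.0264, "beta")
  expect_row("cost_fruq_post", 1128.8, 903.0, 1354.5, "gamma")
  expect_row("cost_fruq_pre", 3408.5, 2726.8, 4090.2, "gamma")
  expect_row("utility_baseline", 0.66, 0.59, 0.735, "beta")
  expect_row("disu_ae_hfs", 0.116, 0.093, 0.139, "beta")
  expect_row("disu_ae_diarrhea", 0.103, 0.082, 0.123, "beta")
  expect_row("dur_ae_hfs", 14, 11.2, 16.8, "gamma")
  expect_row("dur_ae_diarrhea", 5, 4, 6, "gamma")
  expect_row("discount_rate", 0.03, 0.00, 0.05, "fixed")

  # zero-disutility events are fixed at zero
  expect_identical(p$distribution[p$name == "disu_ae_hypertension"], "fixed")
  expect_equal(p$base[p$name == "disu_ae_platelet"], 0)
})

test_that("registry validation rejects broken invariants", {
  p <- default_parameters()
  bad <- p
  bad$low[bad$name == "utility_baseline"] <- 0.7  # low > base
  expect_error(validate_parameters(bad), "low <= base <= high")

  bad <- p
  bad$high[bad$name == "p_ae_hfs_fruq"] <- 1.2
  expect_error(validate_parameters(bad), "\\[0, 1\\]")

  bad <- p
  bad$low[bad$name == "cost_bsc_per_cycle"] <- 0
  bad$base[bad$name == "cost_bsc_per_cycle"] <- 0.5
  expect_error(validate_parameters(bad), "low > 0")

  bad <- rbind(p, p[1, ])
  expect_error(validate_parameters(bad), "duplicated")
})

test_that("config loading overrides defaults and rejects unknown names", {
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(parameters = list(
    list(name = "cost_bsc_per_cycle", base = 1200))), cfg_file)
  cfg <- load_parameters(cfg_file)
  expect_equal(cfg$parameters$base[cfg$parameters$name == "cost_bsc_per_cycle"],
               1200)
  # untouched rows keep their defaults; calibration falls back to frozen
  expect_equal(cfg$parameters$base[cfg$parameters$name == "utility_baseline"],
               0.66)
  expect_equal(cfg$calibration, frozen_calibration())

  bad_file <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(parameters = list(
    list(name = "not_a_parameter", base = 1))), bad_file)
  expect_error(load_parameters(bad_file), "not_a_parameter")

  viol_file <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(parameters = list(
    list(name = "utility_baseline", base = 0.5))), viol_file)  # low 0.59 > base
  expect_error(load_parameters(viol_file), "utility_baseline")
})

test_that("packaged default config reproduces the in-code registry", {
  path <- system.file("extdata", "default_config.yaml", package = "fruqcea")
  expect_true(nzchar(path))
  cfg <- load_parameters(path)
  ref <- default_parameters()
  expect_equal(cfg$parameters$name, ref$name)
  expect_equal(cfg$parameters$base, ref$base)
  expect_equal(cfg$parameters$low, ref$low)
  expect_equal(cfg$parameters$high, ref$high)
  expect_equal(cfg$constants$wtp_threshold, 27130)
  expect_equal(cfg$constants$cycle_days, 28)
})

test_that("beta construction matches the method-of-moments closed form", {
  # symmetric case solvable by hand: mean 0.5, SD 0.1 -> shape1 = shape2 = 12
  sh <- beta_from_point_and_range(0.5, 0.304, 0.696)
  expect_equal(unname(sh), c(12, 12), tolerance = 1e-12)

  # utility row: mean 0.66, SD 0.145/3.92
  sh <- beta_from_point_and_range(0.66, 0.59, 0.735)
  m <- sh[["shape1"]] / sum(sh)
  v <- prod(sh) / (sum(sh)^2 * (sum(sh) + 1))
  expect_equal(m, 0.66, tolerance = 1e-12)
  expect_equal(sqrt(v), (0.735 - 0.59) / 3.92, tolerance = 1e-12)
  expect_equal(unname(sh), c(107.584, 55.422), tolerance = 1e-4)

  expect_error(beta_from_point_and_range(0.5, 0, 1e9), "infeasible")
  expect_error(beta_from_point_and_range(1.2, 0.1, 0.9), "strictly in")
})

test_that("gamma construction matches the method-of-moments closed form", {
  sh <- gamma_from_point_and_range(1415.4, 1022.8, 2021.5)
  expect_equal(sh[["shape"]] * sh[["scale"]], 1415.4, tolerance = 1e-12)
  expect_equal(sqrt(sh[["shape"]]) * sh[["scale"]],
               (2021.5 - 1022.8) / 3.92, tolerance = 1e-12)
  expect_equal(unname(sh), c(30.8646, 45.8584), tolerance = 1e-4)

  sh <- gamma_from_point_and_range(1, 0.608, 1.392)
  expect_equal(unname(sh), c(25, 0.04), tolerance = 1e-12)

  expect_error(gamma_from_point_and_range(0, 0, 1), "> 0")
})

test_that("constructed distributions reproduce their moments under sampling", {
  # mean-and-SD round trip within 0.5% at 1e6 draws, for one beta and one
  # gamma row of the registry
  set.seed(101)
  sh <- beta_from_point_and_range(0.66, 0.59, 0.735)
  x <- rbeta(1e6, sh[["shape1"]], sh[["shape2"]])
  expect_rel_equal(mean(x), 0.66, 0.005)
  expect_rel_equal(sd(x), (0.735 - 0.59) / 3.92, 0.005)

  sh <- gamma_from_point_and_range(1415.4, 1022.8, 2021.5)
  y <- rgamma(1e6, shape = sh[["shape"]], scale = sh[["scale"]])
  expect_rel_equal(mean(y), 1415.4, 0.005)
  expect_rel_equal(sd(y), (2021.5 - 1022.8) / 3.92, 0.005)
})

test_that("model constants enforce the cycle structure", {
  const <- model_constants()
  expect_equal(const$cycle_days, const$dosing_days + 7)
  expect_equal(const$wtp_threshold, 27130)
  expect_error(model_constants(cycle_days = 30), "rest days")
  expect_error(model_constants(nonsense = 1), "unknown")
})
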