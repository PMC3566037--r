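test_that("all-zero structure gives mutually uncorrelated variables", {
  zero <- c(a_H = 0, a_L = 0, a_F = 0, b_H = 0, b_L = 0)
  zb <- c(b_H = 0, b_L = 0, b_F = 0, b_C = 0)
  cfg <- generator_config(n = c(male = 2000, female = 2000),
                          loadings = list(male = zero, female = zero),
                          beta = list(sbp = list(male = zb, female = zb),
                                      dbp = list(male = zb, female = zb)),
                          bp_noise_cor = 0,
                          outlier = list(rate = 0, min_sd = 8, max_sd = 15),
                          missingness = c(bw_kg = 0))
  coh <- generate_cohort(cfg, seed = 123)
  m <- coh[coh$sex == "male",
           c("truth_bwz", "truth_cwv", "truth_hz", "truth_lmr", "truth_fmr",
             "truth_sbpz")]
  cm <- cor(m)
  expect_lt(max(abs(cm[upper.tri(cm)])), 3 / sqrt(2000))
})

test_that("structural variables have unit variance and the planted pattern", {
  cfg <- calibrate_default_config(n = c(male = 2500, female = 2500))
  coh <- generate_cohort(cfg, seed = 7)
  n <- 2500
  for (s in c("male", "female")) {
    cs <- coh[coh$sex == s, ]
    for (col in c("truth_bwz", "truth_cwv", "truth_hz", "truth_lmr",
                  "truth_fmr", "truth_sbpz", "truth_dbpz")) {
      expect_lt(abs(var(cs[[col]]) - 1), 5 / sqrt(n))
    }
    # capacity correlates with height and relative lean mass but not
    # relative fat mass; velocity correlates with all three loads
    expect_lt(abs(cor(cs$truth_bwz, cs$truth_fmr)), 3 / sqrt(n))
    expect_gt(cor(cs$truth_bwz, cs$truth_hz), 0.1)
    expect_gt(cor(cs$truth_bwz, cs$truth_lmr), 0.1)
    for (load in c("truth_hz", "truth_lmr", "truth_fmr")) {
      expect_gt(cor(cs$truth_cwv, cs[[load]]), 0.25)
    }
  }
  # raw-scale calibration: male SBP near its target mean
  ms <- coh$sbp[coh$sex == "male" & !coh$truth_outlier]
  expect_lt(abs(mean(ms) - 102.5), 3 * sd(ms) / sqrt(length(ms)))
  expect_lt(abs(sd(ms) - 9.0), 0.5)
  # raw body size plausibly near calibration
  expect_lt(abs(mean(coh$ht9_cm[coh$sex == "male"]) - 140), 0.5)
  expect_lt(abs(mean(coh$lm9_kg[coh$sex == "female"]) - 23.6), 0.5)
})

test_that("identical seed and config give a bit-identical cohort", {
  cfg <- calibrate_default_config(n = c(male = 200, female = 200))
  a <- generate_cohort(cfg, seed = 42)
  b <- generate_cohort(cfg, seed = 42)
  expect_identical(a, b)
  c2 <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a$bw_kg, c2$bw_kg))
  # simulate() draws nsim cohorts with consecutive seeds
  sims <- simulate(cfg, nsim = 2, seed = 42)
  expect_identical(sims[[1]]$bw_kg, a$bw_kg)
})

test_that("implied coefficients obey the DAG algebra identities", {
  cfg <- calibrate_default_config()
  # cancellation: with b_C = -(beta_H b_H + beta_L b_L) the marginal capacity
  # effect is exactly zero
  ld <- cfg$loadings$male
  bt <- cfg$beta$sbp$male
  bC <- -(bt[["b_H"]] * ld[["b_H"]] + bt[["b_L"]] * ld[["b_L"]])
  cfg2 <- cfg
  cfg2$beta$sbp$male[["b_C"]] <- bC
  expect_equal(implied_coefficients(cfg2, "marginal_growth", "sbp", "male")[["bw_z"]],
               0, tolerance = 1e-12)
  # full mediation: the joint-model velocity coefficient is exactly zero
  expect_equal(implied_coefficients(cfg, "joint_full", "sbp", "male")[["cwv"]],
               0, tolerance = 1e-12)
  # a direct velocity path shows up untouched in the joint model
  cfg3 <- cfg
  cfg3$beta$sbp$male <- c(cfg$beta$sbp$male, b_G = 0.07)
  expect_equal(implied_coefficients(cfg3, "joint_full", "sbp", "male")[["cwv"]],
               0.07, tolerance = 1e-12)
  expect_equal(implied_coefficients(cfg3, "marginal_growth", "sbp", "male")[["cwv"]] -
                 implied_coefficients(cfg, "marginal_growth", "sbp", "male")[["cwv"]],
               0.07, tolerance = 1e-12)
  # marginal load coefficients solve the 3x3 system; spot-check via lm on a
  # huge noiseless-algebra draw is overkill: verify internal consistency
  ml <- implied_coefficients(cfg, "marginal_load", "sbp", "male")
  expect_length(ml, 3)
})

test_that("default calibration reproduces the target systolic algebra", {
  cfg <- calibrate_default_config()
  mg_m <- implied_coefficients(cfg, "marginal_growth", "sbp", "male")
  mg_f <- implied_coefficients(cfg, "marginal_growth", "sbp", "female")
  expect_equal(mg_m[["cwv"]], 0.40, tolerance = 1e-9)
  expect_equal(mg_f[["cwv"]], 0.44, tolerance = 1e-9)
  expect_equal(mg_m[["bw_z"]], 0.00, tolerance = 1e-9)
  expect_equal(mg_f[["bw_z"]], 0.03, tolerance = 1e-9)
  expect_equal(implied_coefficients(cfg, "joint_full", "sbp", "male")[["bw_z"]],
               -0.10, tolerance = 1e-9)
  expect_equal(implied_coefficients(cfg, "joint_full", "sbp", "female")[["bw_z"]],
               -0.09, tolerance = 1e-9)
  # diastolic: velocity and conditional capacity targets
  expect_equal(implied_coefficients(cfg, "marginal_growth", "dbp", "male")[["cwv"]],
               0.15, tolerance = 1e-9)
  expect_equal(implied_coefficients(cfg, "joint_full", "dbp", "male")[["bw_z"]],
               -0.04, tolerance = 1e-9)
})

test_that("infeasible configurations raise calibration errors", {
  big <- c(a_H = 0.9, a_L = 0.5, a_F = 0.4, b_H = 0.6, b_L = 0.2)
  zb <- c(b_H = 0, b_L = 0, b_F = 0, b_C = 0)
  expect_error(generator_config(loadings = list(male = big, female = big),
                                beta = list(sbp = list(male = zb, female = zb))),
               "infeasible unit-variance")
  ok <- c(a_H = 0.6, a_L = 0.55, a_F = 0.4, b_H = 0.2, b_L = 0.2)
  huge <- c(b_H = 0.9, b_L = 0.5, b_F = 0.5, b_C = -0.4)
  expect_error(generator_config(loadings = list(male = ok, female = ok),
                                beta = list(sbp = list(male = huge, female = huge))),
               "structural variance")
  expect_error(generator_config(n = c(male = 10, female = 10),
                                loadings = list(male = ok, female = ok),
                                beta = list(sbp = list(male = zb, female = zb))),
               "at least 50")
})

test_that("outlier injection plants detectable gross errors at the set rate", {
  cfg <- calibrate_default_config(n = c(male = 1500, female = 1500),
                                  outlier = list(rate = 0.004, min_sd = 8,
                                                 max_sd = 15),
                                  missingness = c(bw_kg = 0))
  coh <- generate_cohort(cfg, seed = 17)
  expect_equal(sum(coh$truth_outlier), round(0.004 * 3000))
  d <- build_predictor_set(coh, cfg$reference)
  caught <- coh$id[coh$truth_outlier] %in% attr(d, "excluded_ids")
  expect_gte(mean(caught), 0.9)
  # displaced anthropometry stays positive (fat mass is exempt: its Gaussian
  # marginal is a documented simplification and may graze zero)
  for (col in c("bw_kg", "wt7_kg", "ht9_cm", "lm9_kg")) {
    expect_true(all(coh[[col]] > 0, na.rm = TRUE))
  }
})

test_that("plant_logistic hits the requested prevalence and structure", {
  cfg <- calibrate_default_config(n = c(male = 2000, female = 2000))
  coh <- generate_cohort(cfg, seed = 5)
  d <- plant_logistic(coh, or = c(truth_cwv = 1.5, truth_bwz = 0.8),
                      prevalence = 0.1, seed = 6)
  expect_true(all(d$higher_bp %in% c(0L, 1L, NA)))
  p <- mean(d$higher_bp, na.rm = TRUE)
  expect_lt(abs(p - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(d)))
  expect_error(plant_logistic(coh, or = c(nope = 2), 0.1, 1), "absent")
})
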