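test_that("SRR values match an independent normal-equations evaluation", {
  # 12-record hand table
  tab <- data.frame(
    id = sprintf("H%02d", 1:12), sex = "male",
    x = c(130, 134, 138, 141, 129, 136, 144, 127, 139, 133, 146, 131),
    y = c(24.1, 25.0, 26.2, 27.8, 23.5, 25.9, 29.0, 22.8, 26.9, 24.6, 30.1, 23.9))
  rv <- standardized_residual(tab, "y", "x", stratify_by_sex = FALSE,
                              alpha_outlier = 0)
  X <- cbind(1, tab$x)
  beta <- solve(t(X) %*% X, t(X) %*% tab$y)     # normal equations, by hand
  res <- tab$y - X %*% beta
  expect_equal(rv$fit_meta$all$slope, beta[2], tolerance = 1e-12)
  expect_equal(rv$fit_meta$all$intercept, beta[1], tolerance = 1e-12)
  expect_equal(rv$values, drop(res / sd(res)), tolerance = 1e-12)
})

test_that("SRRs are standardized and orthogonal to the regressor per stratum", {
  for (seed in 1:4) {
    df <- make_srr_cohort(n = 150, seed = seed,
                          slope = c(male = 1.5, female = 2.5), noise = 2)
    rv <- standardized_residual(df, "y", "x")
    for (s in c("male", "female")) {
      v <- rv$values[df$sex == s]
      x <- df$x[df$sex == s]
      ok <- !is.na(v)
      expect_lt(abs(mean(v[ok])), 1e-9)
      expect_lt(abs(sd(v[ok]) - 1), 1e-9)
      expect_lt(abs(cor(v[ok], x[ok])), 1e-9)
    }
  }
})

test_that("degenerate and ill-posed inputs raise errors", {
  df <- make_srr_cohort(n = 50, seed = 2)
  df$y2 <- df$y
  expect_error(standardized_residual(df, "y2", "y", alpha_outlier = 0),
               "zero-variance residuals")
  df$const <- 5
  expect_error(standardized_residual(df, "y", "const", alpha_outlier = 0),
               "zero variance")
  expect_error(standardized_residual(df, "y", "zzz"), "column not found")
  tiny <- df[df$sex == "male", ][1:5, ]
  expect_error(standardized_residual(tiny, "y", "x"), "fewer than 10")
})

test_that("independent outcome gives near-zero slope and standardized outcome", {
  set.seed(77)
  df <- data.frame(sex = "male", x = rnorm(500), y = rnorm(500))
  rv <- standardized_residual(df, "y", "x", alpha_outlier = 0)
  expect_lt(abs(rv$fit_meta$male$slope), 3 / sqrt(500))
  expect_lt(abs(cor(rv$values, df$x)), 1e-9)
  expect_gt(cor(rv$values, scale(df$y)), 0.99)
})

test_that("conditional velocity recovers planted tracking and rejects identity", {
  set.seed(55)
  n <- 3000
  r <- 0.5
  bw <- rnorm(n)
  df <- data.frame(sex = rep(c("male", "female"), length.out = n),
                   bw_z = bw, wt7_z = r * bw + sqrt(1 - r^2) * rnorm(n))
  cv <- conditional_velocity(df, "wt7_z", "bw_z")
  for (s in c("male", "female")) {
    expect_lt(abs(cv$fit_meta[[s]]$slope - r), 3 / sqrt(n / 2))
    v <- cv$values[df$sex == s]
    expect_lt(abs(cor(v[!is.na(v)], df$bw_z[df$sex == s][!is.na(v)])), 1e-9)
  }
  dfe <- data.frame(sex = "male", a = rnorm(50))
  dfe$b <- dfe$a
  expect_error(conditional_velocity(dfe, "b", "a", alpha_outlier = 0),
               "zero-variance residuals")
})

test_that("sex stratification changes SRRs when slopes differ by sex", {
  df <- make_srr_cohort(n = 200, seed = 9, slope = c(male = 1, female = 3))
  strat <- standardized_residual(df, "y", "x", stratify_by_sex = TRUE,
                                 alpha_outlier = 0)
  pooled <- standardized_residual(df, "y", "x", stratify_by_sex = FALSE,
                                  alpha_outlier = 0)
  expect_gt(max(abs(strat$values - pooled$values), na.rm = TRUE), 0.2)
  # pooled residuals correlate with x within sex; stratified ones do not
  m <- df$sex == "male"
  expect_gt(abs(cor(pooled$values[m], df$x[m])), 0.05)
  expect_lt(abs(cor(strat$values[m], df$x[m])), 1e-9)
})

test_that("pulse pressure is per-record SBP minus DBP, exactly linear in means", {
  d <- small_derived()
  expect_equal(d$pp, d$sbp - d$dbp, tolerance = 1e-12)
  expect_equal(mean(d$pp), mean(d$sbp) - mean(d$dbp), tolerance = 1e-12)
  # a child measured at the male cohort means: SBP 102.5, DBP 57.2 -> PP 45.3
  expect_equal(102.5 - 57.2, 45.3, tolerance = 1e-12)
})

test_that("the derived predictor set satisfies every SRR invariant", {
  d <- small_derived()
  for (col in c("wr_h", "lmr_h", "fmr_h", "fmr_lm", "cwv", "chv")) {
    reg <- switch(col, wr_h = , lmr_h = , fmr_h = "ht9_cm",
                  fmr_lm = "lm9_kg", cwv = "bw_z", chv = "blen_z")
    for (s in c("male", "female")) {
      rows <- d$sex == s & !is.na(d[[col]])
      expect_gt(sum(rows), 300)
      expect_lt(abs(mean(d[[col]][rows])), 1e-9)
      expect_lt(abs(sd(d[[col]][rows]) - 1), 1e-9)
      expect_lt(abs(cor(d[[col]][rows], d[[reg]][rows])), 1e-9)
    }
  }
  # birth and BP z-scores recover the planted structural values exactly on
  # the undisplaced records
  ok <- !is.na(d$bw_z) & !d$truth_outlier
  expect_equal(d$bw_z[ok], d$truth_bwz[ok], tolerance = 1e-9)
  expect_equal(d$sbp_z, d$truth_sbpz, tolerance = 1e-9)
})

test_that("schema violations and term-fallback behave as documented", {
  d <- small_derived()
  cfg <- attr(d, "cfg")
  coh <- generate_cohort(cfg, seed = 100)
  expect_error(build_predictor_set(coh[setdiff(names(coh), "sbp")],
                                   cfg$reference),
               "sbp")
  expect_error(build_predictor_set(coh[setdiff(names(coh), "lm9_kg")],
                                   cfg$reference, predictors = "lmr_h"),
               "lm9_kg")
  # missing gestational age falls back to the term reference entry
  coh2 <- coh[1:200, ]
  coh2$gest_age_wk[1] <- NA
  expect_message(
    d2 <- build_predictor_set(coh2, cfg$reference, predictors = "cwv"),
    "referenced at term")
  expect_equal(d2$bw_z[1],
               lms_zscore(coh2$bw_kg[1], 40, coh2$sex[1], "bw", cfg$reference),
               tolerance = 1e-12)
})
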