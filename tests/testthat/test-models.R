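test_that("OLS fits equal the normal-equations oracle on small instances", {
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(15:30, 1)
    df <- data.frame(sex = "male",
                     y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
    spec <- model_spec("y", c("a", "b", "c"), family = "linear",
                       stratify_by_sex = FALSE)
    fit <- fit_capload(df, spec)$strata$pooled
    X <- as.matrix(cbind(1, df[c("a", "b", "c")]))
    beta <- solve(t(X) %*% X, t(X) %*% df$y)
    expect_equal(unname(fit$coefficients$estimate), unname(drop(beta)),
                 tolerance = 1e-9)
    rss <- sum((df$y - X %*% beta)^2)
    se <- sqrt(diag(solve(t(X) %*% X)) * rss / (n - 4))
    expect_equal(fit$coefficients$se, unname(se), tolerance = 1e-9)
    expect_equal(fit$coefficients$ci_hi - fit$coefficients$estimate,
                 qnorm(0.975) * fit$coefficients$se, tolerance = 1e-12)
    expect_equal(fit$r_squared,
                 1 - rss / sum((df$y - mean(df$y))^2), tolerance = 1e-9)
  }
})

test_that("a noiseless predictor yields beta 1, vanishing CI and r2 of 1", {
  df <- data.frame(sex = "male", y = rnorm(40))
  df$x <- df$y
  # lm warns about the essentially perfect fit; that is the point here
  fit <- suppressWarnings(
    fit_capload(df, model_spec("y", "x", stratify_by_sex = FALSE)))
  tab <- fit$strata$pooled$coefficients
  expect_equal(tab$estimate[tab$term == "x"], 1, tolerance = 1e-9)
  expect_lt(tab$ci_hi[2] - tab$ci_lo[2], 1e-9)
  expect_equal(fit$strata$pooled$r_squared, 1, tolerance = 1e-9)
})

test_that("logistic fits satisfy the score equations and the 2x2 identity", {
  set.seed(3)
  n <- 400
  df <- data.frame(sex = rep(c("male", "female"), n / 2),
                   x = rnorm(n))
  df$higher_bp <- rbinom(n, 1, plogis(-1 + 0.8 * df$x))
  spec <- model_spec("ignored", "x", family = "logistic",
                     stratify_by_sex = FALSE)
  fit <- fit_capload(df, spec)$strata$pooled
  # gradient of the log-likelihood at the optimum: X'(y - p) ~ 0
  X <- cbind(1, df$x)
  b <- fit$coefficients$estimate
  g <- t(X) %*% (df$higher_bp - plogis(drop(X %*% b)))
  expect_lt(max(abs(g)), 1e-8)

  # 2x2 contingency: the fitted OR equals the ad/bc cross-product ratio
  tab <- expand.grid(x = c(0, 1), y = c(0, 1))
  counts <- c(40, 12, 25, 30)      # a=40 (x0y0), b=12, c=25, d=30
  d2 <- tab[rep(1:4, counts), ]
  d2$sex <- "male"
  d2$higher_bp <- d2$y
  f2 <- fit_capload(d2, model_spec("ignored", "x", family = "logistic",
                                   stratify_by_sex = FALSE))
  or <- f2$strata$pooled$coefficients$or[2]
  expect_equal(or, (40 * 30) / (12 * 25), tolerance = 1e-6)
})

test_that("higher-BP classification is inclusive at the reference threshold", {
  z <- c(-1, 0, 1.6, qnorm(0.95), 1.7, NA)
  cl <- classify_higher_bp(data.frame(z = z), "z", 0.95)
  expect_identical(cl$flags, c(0L, 0L, 0L, 1L, 1L, NA))
  expect_equal(cl$n_high, 2)
  expect_error(classify_higher_bp(data.frame(z = z), "z", 1.5), "centile")
  # all below threshold
  expect_equal(classify_higher_bp(data.frame(z = rnorm(50)), "z", 0.9999)$n_high, 0)
  # standard-normal flag fraction near 5%
  set.seed(10)
  zz <- data.frame(z = rnorm(10000))
  frac <- classify_higher_bp(zz, "z", 0.95)$n_high / 10000
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("degenerate model inputs raise the documented errors", {
  set.seed(2)
  df <- data.frame(sex = "male", y = rnorm(30), a = rnorm(30))
  df$b <- 2 * df$a
  expect_error(fit_capload(df, model_spec("y", c("a", "b"),
                                          stratify_by_sex = FALSE)),
               "collinear")
  # complete separation
  ds <- data.frame(sex = "male", x = c(rnorm(20, -3), rnorm(20, 3)),
                   higher_bp = rep(0:1, each = 20))
  expect_error(fit_capload(ds, model_spec("ignored", "x", family = "logistic",
                                          stratify_by_sex = FALSE)),
               "separation|converge")
  # single outcome class
  d1 <- data.frame(sex = "male", x = rnorm(30), higher_bp = 0L)
  expect_error(fit_capload(d1, model_spec("ignored", "x", family = "logistic",
                                          stratify_by_sex = FALSE)),
               "single class")
  expect_error(model_spec("y", character(0)), "nonempty")
  expect_error(fit_capload(df, model_spec("y", "zzz")), "absent")
})

test_that("Frisch-Waugh: the M2 velocity coefficient equals its simple slope", {
  d <- small_derived()
  for (s in c("male", "female")) {
    ds <- d[d$sex == s, ]
    joint <- coef(lm(sbp_z ~ bw_z + cwv, data = ds))[["cwv"]]
    keep <- complete.cases(ds[c("sbp_z", "bw_z", "cwv")])
    simple <- coef(lm(sbp_z ~ cwv, data = ds[keep, ]))[["cwv"]]
    expect_equal(joint, simple, tolerance = 1e-6)
  }
})

test_that("the capload object exposes the standard modelling interface", {
  d <- small_derived()
  fit <- capload(d, outcome = "sbp_z")
  expect_s3_class(fit, "capload")
  expect_named(fit$models, c("model1", "model2", "model3"))
  cf <- coef(fit, model = "model3")
  expect_true(all(c("ht9_z", "lmr_h", "fmr_lm", "bw_z", "cwv") %in% rownames(cf)))
  expect_identical(colnames(cf), c("male", "female"))
  ci <- confint(fit, model = "model2")
  expect_true(all(ci$ci_lo <= ci$estimate & ci$estimate <= ci$ci_hi))
  pr <- predict(fit, newdata = d[1:10, ])
  expect_length(pr, 10)
  rs <- residuals(fit)
  expect_named(rs, c("male", "female"))
  expect_true(all(nobs(fit) > 400))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.capload")
  expect_true(all(sm$table$r_squared >= 0 & sm$table$r_squared <= 1))
  expect_output(print(fit), "model3")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf))

  lfit <- capload(d, outcome = "sbp_z", family = "logistic")
  tab <- lfit$models$model2$strata$pooled$coefficients
  expect_true(all(tab$or > 0))
  expect_true("sex_male" %in% tab$term)

  inter <- sex_interaction_test(d, "sbp_z")
  expect_gte(inter$p_value, 0)
  expect_lte(inter$p_value, 1)
})

test_that("null structural configurations give ~95% CI coverage of zero", {
  zero <- c(a_H = 0, a_L = 0, a_F = 0, b_H = 0, b_L = 0)
  zb <- c(b_H = 0, b_L = 0, b_F = 0, b_C = 0)
  cfg <- generator_config(n = c(male = 150, female = 150),
                          loadings = list(male = zero, female = zero),
                          beta = list(sbp = list(male = zb, female = zb),
                                      dbp = list(male = zb, female = zb)),
                          outlier = list(rate = 0, min_sd = 8, max_sd = 15),
                          missingness = c(bw_kg = 0))
  covered <- 0L; total <- 0L
  for (seed in 1:30) {
    coh <- generate_cohort(cfg, seed = 1000 + seed)
    d <- build_predictor_set(coh, cfg$reference,
                             predictors = c("lmr_h", "fmr_lm", "cwv"),
                             alpha_outlier = 0)
    fit <- capload(d, outcome = "sbp_z", models = "model3")
    ci <- confint(fit, model = "model3")
    ci <- ci[ci$term != "(Intercept)", ]
    covered <- covered + sum(ci$ci_lo <= 0 & 0 <= ci$ci_hi)
    total <- total + nrow(ci)
  }
  rate <- covered / total
  expect_lt(abs(rate - 0.95), 3 * sqrt(0.95 * 0.05 / total) + 0.02)
})
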