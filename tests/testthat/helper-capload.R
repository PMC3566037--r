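# shared fixtures, built in code

# single-measurement reference with gentle trends, both sexes
make_test_ref <- function(L = 0.8, measurement = "wt") {
  grid <- seq(60, 150, by = 10)
  rows <- do.call(rbind, lapply(c("male", "female"), function(s) {
    data.frame(measurement = measurement, sex = s, age = grid, L = L,
               M = 20 + 0.12 * (grid - 60) * (if (s == "male") 1 else 0.97),
               S = 0.12 + 2e-4 * (grid - 60))
  }))
  lms_reference(rows, age_units = setNames("months", measurement))
}

# small two-sex table with a linear outcome/regressor relation per stratum
make_srr_cohort <- function(n = 120, seed = 1, slope = c(male = 2, female = 2),
                            noise = 1) {
  set.seed(seed)
  sex <- rep(c("male", "female"), each = n)
  x <- rnorm(2 * n, mean = 10, sd = 2)
  y <- ifelse(sex == "male", slope[["male"]], slope[["female"]]) * x +
    rnorm(2 * n, sd = noise)
  data.frame(id = sprintf("R%04d", seq_len(2 * n)), sex = sex, x = x, y = y,
             stringsAsFactors = FALSE)
}

# a small calibrated cohort with derived predictors, memoised per session
small_derived <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- calibrate_default_config(n = c(male = 600, female = 600))
      coh <- generate_cohort(cfg, seed = 99)
      cache <<- build_predictor_set(coh, cfg$reference)
      attr(cache, "cfg") <<- cfg
    }
    cache
  }
})
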