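#' Raw-scale calibration block (cohort summary moments by sex)
#'
#' Per-sex means and SDs of the raw measurements that the synthetic cohort
#' generator reproduces: gestational age, birth weight and length, weight
#' and height at the mid-childhood visit, weight/height/lean mass/fat mass
#' and blood pressures at the outcome visit.  These anchor both the
#' synthetic reference tables and the raw-scale back-construction.
#'
#' @return nested list: `$male` / `$female`, each with `$mean` and `$sd`
#'   named vectors.
#' @export
table1_calibration <- function() {
  list(
    male = list(
      mean = c(gest_age_wk = 39.4, bw_kg = 3.49, blen_cm = 51.1,
               age7_mo = 89.7, wt7_kg = 25.5, ht7_cm = 126.0,
               age9_mo = 118.5, wt9_kg = 34.3, ht9_cm = 140, lm9_kg = 25.5,
               fm9_kg = 7.3, sbp = 102.5, dbp = 57.2, pp = 45.3),
      sd = c(gest_age_wk = 1.8, bw_kg = 0.55, blen_cm = 2.4,
             age7_mo = 2.1, wt7_kg = 4.1, ht7_cm = 5.2,
             age9_mo = 3.9, wt9_kg = 6.8, ht9_cm = 6, lm9_kg = 2.9,
             fm9_kg = 4.6, sbp = 9.0, dbp = 6.4, pp = 7.6)),
    female = list(
      mean = c(gest_age_wk = 39.6, bw_kg = 3.39, blen_cm = 50.4,
               age7_mo = 89.7, wt7_kg = 25.6, ht7_cm = 125.1,
               age9_mo = 118.4, wt9_kg = 34.9, ht9_cm = 139, lm9_kg = 23.6,
               fm9_kg = 9.6, sbp = 102.9, dbp = 57.7, pp = 45.2),
      sd = c(gest_age_wk = 1.7, bw_kg = 0.49, blen_cm = 2.2,
             age7_mo = 2.1, wt7_kg = 4.4, ht7_cm = 5.3,
             age9_mo = 3.9, wt9_kg = 7.5, ht9_cm = 6, lm9_kg = 3.1,
             fm9_kg = 4.9, sbp = 9.6, dbp = 6.4, pp = 7.9))
  )
}

# relative fetal growth shapes (value at 40 weeks = 1), linearly
# interpolated; gentle, monotone
fetal_shape <- function(measurement) {
  switch(measurement,
         bw = list(age = seq(30, 44, by = 2),
                   rel = c(0.42, 0.54, 0.67, 0.80, 0.92, 1.00, 1.06, 1.10)),
         blen = list(age = seq(30, 44, by = 2),
                     rel = c(0.82, 0.86, 0.90, 0.94, 0.975, 1.00, 1.015, 1.025)))
}

#' Generate a smooth synthetic growth/BP reference
#'
#' Emits an [lms_reference()] with series for birth weight (`bw`) and birth
#' length (`blen`) on a gestational-week grid and childhood weight (`wt`),
#' height (`ht`) and blood pressures (`sbp`, `dbp`, `pp`) on a
#' postnatal-month grid.  Medians follow smooth monotone trends anchored at
#' the calibration block's means at its mean ages, so a cohort drawn from
#' the calibration moments has z-score means near 0 against this reference.
#' Heights and blood pressures use `L = 1` (near-Gaussian); childhood
#' weight uses `L = -0.2` (right skew).  This is a synthetic stand-in with
#' the format, not the values, of national references; real LMS tables are
#' pluggable via [read_lms_reference()].
#'
#' @param calibration a [table1_calibration()]-shaped block.
#' @return an [lms_reference()].
#' @export
synthetic_reference <- function(calibration = table1_calibration()) {
  rows <- list()
  add <- function(measurement, sex, age, L, M, S) {
    rows[[length(rows) + 1L]] <<- data.frame(
      measurement = measurement, sex = sex, age = age, L = L, M = M, S = S)
  }
  for (sex in c("male", "female")) {
    cal <- calibration[[sex]]
    mu <- cal$mean; sd <- cal$sd
    # birth measurements, gestational-week grid
    for (m in c("bw", "blen")) {
      col <- if (m == "bw") "bw_kg" else "blen_cm"
      sh <- fetal_shape(m)
      rel_at_mean <- approx(sh$age, sh$rel, xout = mu[["gest_age_wk"]])$y
      M <- mu[[col]] * sh$rel / rel_at_mean
      add(m, sex, sh$age, L = 1, M = M, S = sd[[col]] / mu[[col]])
    }
    # childhood measurements, monthly grid through both visits
    grid <- seq(60, 150, by = 10)
    lin <- function(col7, col9, age7, age9) {
      slope <- (mu[[col9]] - mu[[col7]]) / (age9 - age7)
      list(M = mu[[col9]] + slope * (grid - age9),
           S7 = sd[[col7]] / mu[[col7]], S9 = sd[[col9]] / mu[[col9]],
           slopeS = (sd[[col9]] / mu[[col9]] - sd[[col7]] / mu[[col7]]) /
             (age9 - age7),
           age9 = age9)
    }
    a7 <- mu[["age7_mo"]]; a9 <- mu[["age9_mo"]]
    wt <- lin("wt7_kg", "wt9_kg", a7, a9)
    add("wt", sex, grid, L = -0.2, M = wt$M,
        S = pmax(0.05, wt$S9 + wt$slopeS * (grid - a9)))
    ht <- lin("ht7_cm", "ht9_cm", a7, a9)
    add("ht", sex, grid, L = 1, M = ht$M,
        S = pmax(0.02, ht$S9 + ht$slopeS * (grid - a9)))
    # blood pressures: gentle age trends centred at the outcome-visit mean
    bp_slope <- c(sbp = 0.05, dbp = 0.02, pp = 0.03)
    for (m in c("sbp", "dbp", "pp")) {
      add(m, sex, grid, L = 1, M = mu[[m]] + bp_slope[[m]] * (grid - a9),
          S = sd[[m]] / mu[[m]])
    }
  }
  lms_reference(do.call(rbind, rows),
                age_units = c(bw = "weeks_gestation", blen = "weeks_gestation",
                              wt = "months", ht = "months", sbp = "months",
                              dbp = "months", pp = "months"))
}

# ---- structural configuration ---------------------------------------------

sexes <- c("male", "female")

#' Structural configuration for the synthetic cohort generator
#'
#' Defines the data-generating DAG of the capacity-load model: per sex,
#' birth-weight z (capacity, `C`) and conditional weight velocity (`G`) are
#' independent standard normals; the three load components are
#' `height z = b_H*C + a_H*G + e_H`, `LMr/H = b_L*C + a_L*G + e_L` and
#' `FMr/LM = a_F*G + e_F` (no capacity loading on relative fat, matching the
#' observed near-zero correlation), each noise scaled so the structural
#' variable has unit variance; blood-pressure z-scores are
#' `beta_H*height z + beta_L*LMr/H + beta_F*FMr/LM + beta_C*C +
#' beta_G*G + e_BP`, with `e_BP` scaled for unit variance and `beta_G = 0`
#' by default (full mediation of postnatal growth through load).
#'
#' @param n named integer vector, records per sex.
#' @param loadings per-sex named vectors `a_H, a_L, a_F, b_H, b_L`.
#' @param beta per-outcome (`sbp`, `dbp`) per-sex named vectors
#'   `b_H, b_L, b_F, b_C` and optional `b_G` (direct velocity path).
#' @param tracking list: `weight`/`length` birth-to-childhood z correlation
#'   per sex, `blen_bw_r` (birth length vs weight z), `chv_cwv_r`
#'   (velocity correlation).
#' @param body_cor target raw correlations `lm_ht` (lean mass vs height)
#'   and `fm_lm` (fat vs lean mass).
#' @param bp_noise_cor correlation of the systolic and diastolic noises.
#' @param calibration raw-scale moments, see [table1_calibration()].
#' @param reference [lms_reference()] used for raw back-construction.
#' @param outlier list `rate` (fraction of records replaced by gross
#'   outliers), `min_sd`, `max_sd` (displacement range, robust SD units).
#' @param missingness named per-column missingness rates.
#' @param seed default seed used by [generate_cohort()]/`simulate()`.
#' @return validated list of class `capload_config`.
#' @seealso [calibrate_default_config()] for the default calibrated to the
#'   published systolic coefficients; [implied_coefficients()] for the
#'   closed-form expected regression coefficients.
#' @export
generator_config <- function(n = c(male = 3000, female = 3000),
                             loadings,
                             beta,
                             tracking = list(weight = c(male = 0.55, female = 0.55),
                                             length = c(male = 0.55, female = 0.55),
                                             blen_bw_r = 0.6, chv_cwv_r = 0.5),
                             body_cor = c(lm_ht = 0.78, fm_lm = 0.65),
                             bp_noise_cor = 0.5,
                             calibration = table1_calibration(),
                             reference = NULL,
                             outlier = list(rate = 0.003, min_sd = 8, max_sd = 15),
                             missingness = c(bw_kg = 0.011, blen_cm = 0.20,
                                             wt7_kg = 0.114, ht7_cm = 0.113),
                             seed = NULL) {
  if (any(n < 50)) stop("need at least 50 records per sex")
  for (s in sexes) {
    ld <- loadings[[s]]
    need <- c("a_H", "a_L", "a_F", "b_H", "b_L")
    if (!all(need %in% names(ld))) {
      stop("loadings$", s, " must name ", paste(need, collapse = ", "))
    }
    chk <- c(`height z` = ld[["b_H"]]^2 + ld[["a_H"]]^2,
             `LMr/H` = ld[["b_L"]]^2 + ld[["a_L"]]^2,
             `FMr/LM` = ld[["a_F"]]^2)
    bad <- names(chk)[chk >= 1]
    if (length(bad) > 0L) {
      stop("infeasible unit-variance decomposition for ", paste(bad, collapse = ", "),
           " (", s, "): loadings imply variance > 1")
    }
  }
  cfg <- structure(
    list(n = n, loadings = loadings, beta = beta, tracking = tracking,
         body_cor = body_cor, bp_noise_cor = bp_noise_cor,
         calibration = calibration,
         reference = if (is.null(reference)) synthetic_reference(calibration)
                     else reference,
         outlier = outlier, missingness = missingness, seed = seed),
    class = "capload_config")
  # BP noise SDs must exist: unit-variance feasibility of each outcome
  for (o in names(beta)) {
    for (s in sexes) {
      v <- structural_bp_variance(cfg, o, s)
      if (v >= 1) {
        stop("calibration error: structural variance of ", o, " (", s,
             ") is ", round(v, 3), " >= 1; reduce coefficients")
      }
    }
  }
  cfg
}

#' @export
print.capload_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  n:", paste(names(x$n), x$n, sep = "=", collapse = ", "), "\n")
  for (s in sexes) {
    cat(sprintf("  %s loadings: %s\n", s,
                paste(names(x$loadings[[s]]),
                      round(x$loadings[[s]], 4), sep = "=", collapse = " ")))
  }
  for (o in names(x$beta)) {
    for (s in sexes) {
      cat(sprintf("  beta[%s,%s]: %s\n", o, s,
                  paste(names(x$beta[[o]][[s]]),
                        round(x$beta[[o]][[s]], 4), sep = "=", collapse = " ")))
    }
  }
  cat("  outlier rate:", x$outlier$rate, " missingness:",
      paste(names(x$missingness), x$missingness, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# covariance matrix of the structural variables (Hz, L, F, C, G) for one sex
structural_cov <- function(config, sex) {
  ld <- config$loadings[[sex]]
  a_H <- ld[["a_H"]]; a_L <- ld[["a_L"]]; a_F <- ld[["a_F"]]
  b_H <- ld[["b_H"]]; b_L <- ld[["b_L"]]
  S <- diag(5)
  dimnames(S) <- list(c("ht9_z", "lmr_h", "fmr_lm", "bw_z", "cwv"),
                      c("ht9_z", "lmr_h", "fmr_lm", "bw_z", "cwv"))
  S["ht9_z", "lmr_h"] <- S["lmr_h", "ht9_z"] <- b_H * b_L + a_H * a_L
  S["ht9_z", "fmr_lm"] <- S["fmr_lm", "ht9_z"] <- a_H * a_F
  S["lmr_h", "fmr_lm"] <- S["fmr_lm", "lmr_h"] <- a_L * a_F
  S["ht9_z", "bw_z"] <- S["bw_z", "ht9_z"] <- b_H
  S["lmr_h", "bw_z"] <- S["bw_z", "lmr_h"] <- b_L
  S["ht9_z", "cwv"] <- S["cwv", "ht9_z"] <- a_H
  S["lmr_h", "cwv"] <- S["cwv", "lmr_h"] <- a_L
  S["fmr_lm", "cwv"] <- S["cwv", "fmr_lm"] <- a_F
  S
}

beta_vector <- function(config, outcome, sex) {
  b <- config$beta[[outcome]][[sex]]
  c(ht9_z = b[["b_H"]], lmr_h = b[["b_L"]], fmr_lm = b[["b_F"]],
    bw_z = b[["b_C"]], cwv = if ("b_G" %in% names(b)) b[["b_G"]] else 0)
}

structural_bp_variance <- function(config, outcome, sex) {
  S <- structural_cov(config, sex)
  b <- beta_vector(config, outcome, sex)
  as.numeric(t(b) %*% S %*% b)
}

#' Closed-form expected regression coefficients implied by a configuration
#'
#' For jointly Gaussian structural variables the large-sample OLS
#' coefficients of any subset regression follow from the covariance algebra
#' of the DAG.  This is the analytic oracle against which fitted
#' coefficients on generated cohorts are checked.
#'
#' \describe{
#'   \item{`marginal_growth`}{BP z on (birth weight z, CWV): birth
#'     coefficient `b_C + beta_H*b_H + beta_L*b_L` (direct plus mediated),
#'     CWV coefficient `beta_H*a_H + beta_L*a_L + beta_F*a_F (+ b_G)`.}
#'   \item{`joint_full`}{BP z on all five structural variables: the
#'     structural coefficients themselves (CWV `b_G`, 0 under full
#'     mediation).}
#'   \item{`marginal_load`}{BP z on (height z, LMr/H, FMr/LM).}
#' }
#'
#' @param config a [generator_config()].
#' @param model which regression, see Details.
#' @param outcome `"sbp"` or `"dbp"`.
#' @param sex `"male"` or `"female"`.
#' @return named vector of expected coefficients.
#' @export
implied_coefficients <- function(config,
                                 model = c("marginal_growth", "joint_full",
                                           "marginal_load"),
                                 outcome = "sbp", sex = "male") {
  model <- match.arg(model)
  S <- structural_cov(config, sex)
  b <- beta_vector(config, outcome, sex)
  cols <- switch(model,
                 marginal_growth = c("bw_z", "cwv"),
                 joint_full = colnames(S),
                 marginal_load = c("ht9_z", "lmr_h", "fmr_lm"))
  cov_xy <- as.numeric(S %*% b)[match(cols, colnames(S))]
  drop(solve(S[cols, cols], cov_xy))
}

#' Default configuration calibrated to the published systolic coefficients
#'
#' Solves the structural coefficients so that the implied regression
#' coefficients reproduce the headline systolic values: marginal CWV 0.40
#' (male) / 0.44 (female), marginal birth weight 0.00 / 0.03, and
#' fully-adjusted (conditional) birth weight -0.10 / -0.09.  With the load
#' loadings `a_H, a_L, a_F`, the capacity loading on relative lean mass
#' `b_L`, and the load coefficients `beta_L, beta_F` fixed, the solution is
#' closed-form: `beta_H` from the marginal CWV target, `beta_C` equal to the
#' conditional birth-weight target, and `b_H` from the marginal birth-weight
#' target (the cancellation of direct and mediated capacity paths).  The
#' diastolic suite is calibrated analogously to its marginal CWV (0.15 /
#' 0.16) and conditional birth weight (-0.04) targets; its marginal
#' birth-weight coefficient is then implied (about -0.01), since `b_H` is
#' already pinned by the systolic solve.
#'
#' @param n records per sex.
#' @param targets per-outcome, per-sex named vectors `cwv_marginal`,
#'   `bw_conditional` and (systolic only) `bw_marginal`.
#' @param loadings_base named vector `a_H, a_L, a_F, b_L` shared by both
#'   sexes before the `b_H` solve.
#' @param beta_load per-outcome named vectors `b_L, b_F` (the relative lean
#'   and fat mass coefficients, taken near the published fully-adjusted
#'   values).
#' @param ... further arguments passed to [generator_config()].
#' @return a calibrated `capload_config`; the solved coefficients round-trip
#'   through [implied_coefficients()] to the targets within 1e-9.
#' @export
calibrate_default_config <- function(n = c(male = 3000, female = 3000),
                                     targets = list(
                                       sbp = list(
                                         male = c(cwv_marginal = 0.40,
                                                  bw_marginal = 0.00,
                                                  bw_conditional = -0.10),
                                         female = c(cwv_marginal = 0.44,
                                                    bw_marginal = 0.03,
                                                    bw_conditional = -0.09)),
                                       dbp = list(
                                         male = c(cwv_marginal = 0.15,
                                                  bw_conditional = -0.04),
                                         female = c(cwv_marginal = 0.16,
                                                    bw_conditional = -0.04))),
                                     loadings_base = c(a_H = 0.60, a_L = 0.55,
                                                       a_F = 0.40, b_L = 0.20),
                                     beta_load = list(sbp = c(b_L = 0.15, b_F = 0.30),
                                                      dbp = c(b_L = 0.02, b_F = 0.14)),
                                     ...) {
  a_H <- loadings_base[["a_H"]]; a_L <- loadings_base[["a_L"]]
  a_F <- loadings_base[["a_F"]]; b_L <- loadings_base[["b_L"]]
  loadings <- list()
  beta <- lapply(targets, function(x) list())
  for (s in sexes) {
    solve_beta_H <- function(outcome) {
      tg <- targets[[outcome]][[s]]
      bl <- beta_load[[outcome]]
      (tg[["cwv_marginal"]] - bl[["b_L"]] * a_L - bl[["b_F"]] * a_F) / a_H
    }
    beta_H_sbp <- solve_beta_H("sbp")
    tg_sbp <- targets$sbp[[s]]
    beta_C_sbp <- tg_sbp[["bw_conditional"]]
    b_H <- (tg_sbp[["bw_marginal"]] - beta_C_sbp -
              beta_load$sbp[["b_L"]] * b_L) / beta_H_sbp
    if (abs(b_H) >= 1 || b_H^2 + a_H^2 >= 1) {
      stop("calibration error: solved b_H = ", round(b_H, 4),
           " infeasible for unit-variance height z")
    }
    loadings[[s]] <- c(a_H = a_H, a_L = a_L, a_F = a_F, b_H = b_H, b_L = b_L)
    for (o in names(targets)) {
      beta_H <- solve_beta_H(o)
      beta[[o]][[s]] <- c(b_H = beta_H, b_L = beta_load[[o]][["b_L"]],
                          b_F = beta_load[[o]][["b_F"]],
                          b_C = targets[[o]][[s]][["bw_conditional"]])
    }
  }
  cfg <- generator_config(n = n, loadings = loadings, beta = beta, ...)
  # round-trip guard: the algebra must reproduce its own targets
  for (s in sexes) {
    mg <- implied_coefficients(cfg, "marginal_growth", "sbp", s)
    jf <- implied_coefficients(cfg, "joint_full", "sbp", s)
    tg <- targets$sbp[[s]]
    stopifnot(abs(mg[["cwv"]] - tg[["cwv_marginal"]]) < 1e-9,
              abs(mg[["bw_z"]] - tg[["bw_marginal"]]) < 1e-9,
              abs(jf[["bw_z"]] - tg[["bw_conditional"]]) < 1e-9)
  }
  cfg
}

# ---- cohort generation ----------------------------------------------------

# standardise to exact sample mean 0 / SD 1 is NOT done: structural draws
# keep their sampling noise.  in-sample orthogonalised residual, used so the
# raw-scale back-construction inverts the derived-variable definitions
orth_std <- function(y, x) {
  b <- cov(x, y) / var(x)
  r <- y - mean(y) - b * (x - mean(x))
  r / sd(r)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

generate_sex <- function(config, sex, id_offset) {
  n <- config$n[[sex]]
  ld <- config$loadings[[sex]]
  cal <- config$calibration[[sex]]
  mu <- cal$mean; sdv <- cal$sd
  ref <- config$reference

  gest <- rnorm_trunc(n, mu[["gest_age_wk"]], sdv[["gest_age_wk"]], 31, 43.5)
  age7 <- rnorm_trunc(n, mu[["age7_mo"]], sdv[["age7_mo"]], 62, 148)
  age9 <- rnorm_trunc(n, mu[["age9_mo"]], sdv[["age9_mo"]], 62, 148)

  C <- rnorm(n)                      # capacity: birth weight z
  G <- rnorm(n)                      # early load: conditional weight velocity
  e_H <- rnorm(n, sd = sqrt(1 - ld[["b_H"]]^2 - ld[["a_H"]]^2))
  e_L <- rnorm(n, sd = sqrt(1 - ld[["b_L"]]^2 - ld[["a_L"]]^2))
  e_F <- rnorm(n, sd = sqrt(1 - ld[["a_F"]]^2))
  Hz <- ld[["b_H"]] * C + ld[["a_H"]] * G + e_H
  L <- ld[["b_L"]] * C + ld[["a_L"]] * G + e_L
  Fv <- ld[["a_F"]] * G + e_F

  # blood pressures, correlated noises, unit-variance z-scores
  v_s <- structural_bp_variance(config, "sbp", sex)
  v_d <- structural_bp_variance(config, "dbp", sex)
  z1 <- rnorm(n); z2 <- rnorm(n)
  rho <- config$bp_noise_cor
  e_s <- sqrt(1 - v_s) * z1
  e_d <- sqrt(1 - v_d) * (rho * z1 + sqrt(1 - rho^2) * z2)
  bs <- beta_vector(config, "sbp", sex)
  bd <- beta_vector(config, "dbp", sex)
  Xs <- cbind(Hz, L, Fv, C, G)
  sbp_z <- drop(Xs %*% bs) + e_s
  dbp_z <- drop(Xs %*% bd) + e_d

  # growth tracking and the length path
  r_w <- config$tracking$weight[[sex]]
  wt7_z <- r_w * C + sqrt(1 - r_w^2) * G
  r_bl <- config$tracking$blen_bw_r
  blen_z <- r_bl * C + sqrt(1 - r_bl^2) * rnorm(n)
  r_cc <- config$tracking$chv_cwv_r
  CHV <- r_cc * G + sqrt(1 - r_cc^2) * rnorm(n)
  r_l <- config$tracking$length[[sex]]
  ht7_z <- r_l * blen_z + sqrt(1 - r_l^2) * CHV

  # raw-scale back-construction through the reference
  bw <- lms_value(C, gest, sex, "bw", ref)
  blen <- lms_value(blen_z, gest, sex, "blen", ref)
  wt7 <- lms_value(wt7_z, age7, sex, "wt", ref)
  ht7 <- lms_value(ht7_z, age7, sex, "ht", ref)
  ht9 <- lms_value(Hz, age9, sex, "ht", ref)
  sbp <- lms_value(sbp_z, age9, sex, "sbp", ref)
  dbp <- lms_value(dbp_z, age9, sex, "dbp", ref)

  # body composition: linear in its regressor plus the planted residual, so
  # the pipeline's unexplained-residual step inverts the construction
  rho_lh <- config$body_cor[["lm_ht"]]
  L_orth <- orth_std(L, ht9)
  lm9 <- mu[["lm9_kg"]] + rho_lh * sdv[["lm9_kg"]] / sdv[["ht9_cm"]] *
    (ht9 - mean(ht9)) + sdv[["lm9_kg"]] * sqrt(1 - rho_lh^2) * L_orth
  rho_fl <- config$body_cor[["fm_lm"]]
  F_orth <- orth_std(Fv, lm9)
  fm9 <- mu[["fm9_kg"]] + rho_fl * sdv[["fm9_kg"]] / sdv[["lm9_kg"]] *
    (lm9 - mean(lm9)) + sdv[["fm9_kg"]] * sqrt(1 - rho_fl^2) * F_orth
  wt9 <- lm9 + fm9 +
    rnorm(n, mu[["wt9_kg"]] - mu[["lm9_kg"]] - mu[["fm9_kg"]], 0.4)

  data.frame(
    id = sprintf("S%06d", id_offset + seq_len(n)),
    sex = sex, gest_age_wk = gest, bw_kg = bw, blen_cm = blen,
    wt7_kg = wt7, ht7_cm = ht7, age7_mo = age7,
    wt9_kg = wt9, ht9_cm = ht9, lm9_kg = lm9, fm9_kg = fm9, age9_mo = age9,
    sbp = sbp, dbp = dbp,
    truth_bwz = C, truth_cwv = G, truth_hz = Hz, truth_lmr = L,
    truth_fmr = Fv, truth_lmr_orth = L_orth, truth_fmr_orth = F_orth,
    truth_chv = CHV, truth_sbpz = sbp_z, truth_dbpz = dbp_z,
    truth_outlier = FALSE,
    stringsAsFactors = FALSE)
}

# gross-error injection: displace a random screened pair by 8-15 robust SDs
outlier_pairs <- list(c("bw_kg", "wt7_kg"), c("ht9_cm", "lm9_kg"),
                      c("lm9_kg", "fm9_kg"), c("ht9_cm", "wt9_kg"),
                      c("blen_cm", "ht7_cm"))

inject_outliers <- function(df, outlier) {
  k <- round(outlier$rate * nrow(df))
  if (k == 0L) return(df)
  rows <- sample(nrow(df), k)
  pair_idx <- sample(length(outlier_pairs), k, replace = TRUE)
  theta <- stats::runif(k, 0, 2 * pi)
  mag <- stats::runif(k, outlier$min_sd, outlier$max_sd)
  for (j in seq_len(k)) {
    pr <- outlier_pairs[[pair_idx[j]]]
    for (d in 1:2) {
      col <- pr[d]
      rsd <- stats::mad(df[[col]], na.rm = TRUE)
      shift <- mag[j] * (if (d == 1) cos(theta[j]) else sin(theta[j])) * rsd
      val <- df[[col]][rows[j]] + shift
      if (val <= 0.05 * median(df[[col]], na.rm = TRUE)) {
        val <- df[[col]][rows[j]] + abs(shift)   # keep physical quantities positive
      }
      df[[col]][rows[j]] <- val
    }
  }
  df$truth_outlier[rows] <- TRUE
  df
}

#' Generate a synthetic cohort from a structural configuration
#'
#' Draws the structural variables of the capacity-load DAG per sex,
#' back-constructs the raw-scale cohort columns through the reference
#' tables and the calibration block (so the full z-scoring and
#' residualisation pipeline, not just the model stage, is exercised
#' end-to-end), then injects gross outliers and item-level missingness.
#' Hidden truth columns (`truth_*`) carry the structural values and outlier
#' flags for verification; the analysis pipeline never reads them.
#'
#' @param config a [generator_config()] /
#'   [calibrate_default_config()].
#' @param seed integer seed (defaults to `config$seed`); identical seed and
#'   config give a bit-identical cohort.
#' @return data.frame of class `capload_cohort` with the documented raw
#'   columns plus truth columns; the configuration echo and seed are
#'   attached as attributes.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "capload_config"))
  if (is.null(seed)) stop("a seed is required (config$seed or the seed argument)")
  set.seed(seed)
  df <- rbind(generate_sex(config, "male", 0L),
              generate_sex(config, "female", config$n[["male"]]))
  df <- inject_outliers(df, config$outlier)
  for (col in names(config$missingness)) {
    rate <- config$missingness[[col]]
    if (rate > 0) df[[col]][stats::runif(nrow(df)) < rate] <- NA
  }
  attr(df, "config") <- config
  attr(df, "seed") <- seed
  class(df) <- c("capload_cohort", "data.frame")
  df
}

#' @export
#' @rdname generate_cohort
#' @param object,nsim,... `simulate()` interface: `nsim` cohorts drawn with
#'   seeds `seed, seed + 1, ...`.
simulate.capload_config <- function(object, nsim = 1, seed = object$seed, ...) {
  if (is.null(seed)) stop("a seed is required")
  out <- lapply(seq_len(nsim) - 1L, function(k) generate_cohort(object, seed + k))
  if (nsim == 1L) out[[1L]] else out
}

#' Plant a logistic outcome with specified odds ratios
#'
#' Adds a binary `higher_bp` column drawn from a logistic model with the
#' given per-unit odds ratios on existing columns, with the intercept solved
#' so the expected prevalence matches `prevalence`.  Used to verify that the
#' logistic suite recovers known odds-ratio structures.
#'
#' @param data cohort table.
#' @param or named vector of odds ratios; names are columns of `data`.
#' @param prevalence target expected event fraction.
#' @param seed integer seed.
#' @return `data` with a `higher_bp` column; the planted intercept and
#'   odds ratios are attached as `attr(, "planted_logistic")`.
#' @export
plant_logistic <- function(data, or, prevalence, seed) {
  absent <- setdiff(names(or), names(data))
  if (length(absent) > 0L) stop("columns absent: ", paste(absent, collapse = ", "))
  X <- as.matrix(as.data.frame(data)[names(or)])
  keep <- complete.cases(X)
  lp <- drop(X[keep, , drop = FALSE] %*% log(or))
  a <- uniroot(function(a) mean(plogis(a + lp)) - prevalence,
               interval = c(-30, 30))$root
  set.seed(seed)
  flags <- rep(NA_integer_, nrow(data))
  flags[keep] <- rbinom(sum(keep), 1L, plogis(a + lp))
  data$higher_bp <- flags
  attr(data, "planted_logistic") <- list(intercept = a, or = or,
                                         prevalence = prevalence)
  data
}
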