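#' Standardised unexplained-residual predictors (SRRs)
#'
#' Builds a predictor as the part of one variable not linearly explained by
#' another — the "unexplained residuals" device used to separate correlated
#' body-composition components.  Within each stratum (by default each sex)
#' the `(regressor, outcome)` pairs are screened for multivariate outliers
#' with [hadi_outliers()], a least-squares line is fitted to the retained
#' records, and the residuals are divided by their standard deviation.  The
#' result has mean 0 and SD 1 within stratum and is exactly uncorrelated
#' with the regressor; records flagged as outliers or missing either
#' variable carry `NA`.
#'
#' @param data data.frame holding the cohort.
#' @param outcome,regressor names of the conditioned and conditioning
#'   columns.
#' @param name label for the derived variable (e.g. `"LMr/H"`).
#' @param stratify_by_sex fit separate lines (and SDs) per level of the
#'   `sex` column; when `FALSE` a single pooled fit is used.
#' @param alpha_outlier significance level for the Hadi screen; set to 0 to
#'   skip screening.
#' @param pooled_sd divide both strata by the pooled residual SD instead of
#'   the within-stratum SD (the within-stratum default matches fitting "by
#'   sex"; pooling is offered because a single common SD is an equally
#'   defensible reading).  Under pooling the per-stratum SD-1 property no
#'   longer holds.
#' @param sd_denominator `"n-1"` (default) or `"n"` for the residual SD.
#' @return An object of class `residual_variable`: list with `values`
#'   (full-length, `NA` for missing/flagged records), `name`, `outcome`,
#'   `regressor`, `fit_meta` (per-stratum slope, intercept, residual SD, n,
#'   outliers removed), and `flagged` (row indices screened out).
#' @export
standardized_residual <- function(data, outcome, regressor, name = NULL,
                                  stratify_by_sex = TRUE, alpha_outlier = 0.05,
                                  pooled_sd = FALSE, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  for (col in c(outcome, regressor)) {
    if (!col %in% names(data)) stop("column not found: ", col)
  }
  if (is.null(name)) name <- paste0(outcome, "|", regressor)
  n <- nrow(data)
  strata <- if (stratify_by_sex) {
    if (!"sex" %in% names(data)) stop("stratify_by_sex requires a 'sex' column")
    split(seq_len(n), data$sex)
  } else {
    list(all = seq_len(n))
  }

  values <- rep(NA_real_, n)
  raw_resid <- rep(NA_real_, n)
  fit_meta <- list()
  flagged_all <- integer(0)

  for (s in names(strata)) {
    rows <- strata[[s]]
    x <- data[[regressor]][rows]
    y <- data[[outcome]][rows]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) == 0L) stop("stratum '", s, "' has no complete records for ", name)
    if (sum(ok) < 10L) {
      stop("stratum '", s, "' has fewer than 10 complete records for ", name)
    }
    flagged <- integer(0)
    if (alpha_outlier > 0) {
      X <- cbind(x, y)[ok, , drop = FALSE]
      colnames(X) <- c(regressor, outcome)
      rep_s <- hadi_outliers(X, alpha = alpha_outlier)
      flagged <- rows[ok][rep_s$flags]
      flagged_all <- c(flagged_all, flagged)
    }
    use <- rows[ok]
    use <- setdiff(use, flagged)
    xs <- data[[regressor]][use]
    ys <- data[[outcome]][use]
    if (var(xs) < .Machine$double.eps * max(1, mean(xs)^2)) {
      stop("degenerate fit for ", name, " in stratum '", s,
           "': regressor '", regressor, "' has zero variance")
    }
    slope <- cov(xs, ys) / var(xs)
    intercept <- mean(ys) - slope * mean(xs)
    res <- ys - intercept - slope * xs
    denom <- if (sd_denominator == "n-1") length(res) - 1L else length(res)
    rsd <- sqrt(sum((res - mean(res))^2) / denom)
    if (rsd < 1e-12) {
      stop("degenerate fit for ", name, " in stratum '", s,
           "': zero-variance residuals (outcome collinear with regressor)")
    }
    raw_resid[use] <- res
    if (!pooled_sd) values[use] <- res / rsd
    fit_meta[[s]] <- list(slope = slope, intercept = intercept,
                          residual_sd = rsd, n = length(use),
                          n_outliers = length(flagged))
  }

  if (pooled_sd) {
    use <- which(!is.na(raw_resid))
    denom <- if (sd_denominator == "n-1") length(use) - 1L else length(use)
    rsd <- sqrt(sum(raw_resid[use]^2) / denom)
    if (rsd < 1e-12) stop("degenerate fit for ", name, ": zero-variance residuals")
    values[use] <- raw_resid[use] / rsd
    for (s in names(fit_meta)) fit_meta[[s]]$pooled_sd <- rsd
  }

  structure(
    list(name = name, values = values, outcome = outcome, regressor = regressor,
         sex_stratified = stratify_by_sex, fit_meta = fit_meta,
         flagged = sort(flagged_all)),
    class = "residual_variable")
}

#' @export
print.residual_variable <- function(x, ...) {
  cat(sprintf("SRR '%s': %s ~ %s%s\n", x$name, x$outcome, x$regressor,
              if (x$sex_stratified) " (by sex)" else ""))
  for (s in names(x$fit_meta)) {
    m <- x$fit_meta[[s]]
    cat(sprintf("  %-7s slope %.4f, intercept %.4f, resid SD %.4f, n %d, outliers %d\n",
                s, m$slope, m$intercept, m$residual_sd, m$n, m$n_outliers))
  }
  invisible(x)
}

#' Conditional growth velocity
#'
#' The standardised residual of a later z-score conditioned on the
#' corresponding birth z-score: growth faster or slower than predicted from
#' birth size.  Conditional weight velocity (CWV) conditions the childhood
#' weight z-score on the birth-weight z-score; conditional height velocity
#' (CHV) conditions the childhood height z-score on the birth-length
#' z-score.  By construction the velocity is uncorrelated with the birth
#' measure.
#'
#' @inheritParams standardized_residual
#' @param z_later,z_birth names of the later-age and birth z-score columns.
#' @return A `residual_variable` (see [standardized_residual()]).
#' @export
conditional_velocity <- function(data, z_later, z_birth, name = "CWV",
                                 stratify_by_sex = TRUE, alpha_outlier = 0.05,
                                 pooled_sd = FALSE) {
  standardized_residual(data, outcome = z_later, regressor = z_birth,
                        name = name, stratify_by_sex = stratify_by_sex,
                        alpha_outlier = alpha_outlier, pooled_sd = pooled_sd)
}

# derived-variable recipes: outcome ~ regressor, in the screening order the
# sequential exclusions follow
srr_recipes <- list(
  wr_h   = list(outcome = "wt9_kg", regressor = "ht9_cm", label = "Wr/H"),
  lmr_h  = list(outcome = "lm9_kg", regressor = "ht9_cm", label = "LMr/H"),
  fmr_h  = list(outcome = "fm9_kg", regressor = "ht9_cm", label = "FMr/H"),
  fmr_lm = list(outcome = "fm9_kg", regressor = "lm9_kg", label = "FMr/LM"),
  cwv    = list(outcome = "wt7_z", regressor = "bw_z",   label = "CWV"),
  chv    = list(outcome = "ht7_z", regressor = "blen_z", label = "CHV")
)

#' Build the full derived predictor set for the capacity-load models
#'
#' Runs the whole data-preparation stage on a raw cohort table: reference
#' z-scores for anthropometry and blood pressure, pulse pressure, the
#' standardised-residual body-composition predictors (Wr/H, LMr/H, FMr/H,
#' FMr/LM) and the conditional growth velocities (CWV, CHV).  Outlier
#' screening happens per derived variable, sequentially in the order listed,
#' and every record flagged at any step is excluded from the entire derived
#' set (its SRR columns are set `NA`), mirroring cohort practice of
#' removing all screened outliers from the analysis.  The per-step
#' exclusion ledger is attached as `attr(, "ledger")`.
#'
#' @param data raw cohort table with the documented column dictionary
#'   (`id, sex, gest_age_wk, bw_kg, blen_cm, wt7_kg, ht7_cm, age7_mo,
#'   wt9_kg, ht9_cm, lm9_kg, fm9_kg, age9_mo, sbp, dbp`).
#' @param ref an [lms_reference()] providing series `bw`, `blen`, `wt`,
#'   `ht`, `sbp`, `dbp`, `pp`.
#' @param predictors which derived SRR columns to build (default all of
#'   `wr_h, lmr_h, fmr_h, fmr_lm, cwv, chv`); z-scores and pulse pressure
#'   are always added.
#' @param alpha_outlier Hadi screen level per step (0 disables screening).
#' @param gestation_adjusted compute birth z-scores at the recorded
#'   gestational age; records missing gestational age (or all records, when
#'   `FALSE`) are referenced at term (40 weeks), with a message.
#' @param pooled_sd see [standardized_residual()].
#' @return `data` extended with columns `bw_z, blen_z, wt7_z, ht7_z, ht9_z,
#'   sbp_z, dbp_z, pp, pp_z` and the requested SRR columns, plus a
#'   `sex_male` indicator; attributes `ledger` (per-step exclusion table)
#'   and `excluded_ids`.
#' @export
build_predictor_set <- function(data, ref,
                                predictors = c("wr_h", "lmr_h", "fmr_h",
                                               "fmr_lm", "cwv", "chv"),
                                alpha_outlier = 0.05,
                                gestation_adjusted = TRUE,
                                pooled_sd = FALSE) {
  predictors <- match.arg(predictors, several.ok = TRUE)
  need_raw <- c("id", "sex", "age9_mo", "ht9_cm", "sbp", "dbp")
  if ("wr_h" %in% predictors) need_raw <- c(need_raw, "wt9_kg")
  absent <- setdiff(need_raw, names(data))
  if (length(absent) > 0L) {
    stop("cohort table lacks required columns: ", paste(absent, collapse = ", "))
  }
  out <- as.data.frame(data)
  n <- nrow(out)

  # --- reference z-scores -------------------------------------------------
  ga <- if ("gest_age_wk" %in% names(out)) out$gest_age_wk else rep(NA_real_, n)
  if (!gestation_adjusted) ga[] <- NA_real_
  at_term <- is.na(ga)
  if (any(at_term) && any(c("bw_kg", "blen_cm") %in% names(out))) {
    message(sum(at_term), " record(s) referenced at term (40 wk) for birth z-scores")
  }
  ga[at_term] <- 40
  if ("bw_kg" %in% names(out)) {
    out$bw_z <- lms_zscore(out$bw_kg, ga, out$sex, "bw", ref)
  }
  if ("blen_cm" %in% names(out)) {
    out$blen_z <- lms_zscore(out$blen_cm, ga, out$sex, "blen", ref)
  }
  if (all(c("wt7_kg", "age7_mo") %in% names(out))) {
    out$wt7_z <- lms_zscore(out$wt7_kg, out$age7_mo, out$sex, "wt", ref)
  }
  if (all(c("ht7_cm", "age7_mo") %in% names(out))) {
    out$ht7_z <- lms_zscore(out$ht7_cm, out$age7_mo, out$sex, "ht", ref)
  }
  out$ht9_z <- lms_zscore(out$ht9_cm, out$age9_mo, out$sex, "ht", ref)
  out$sbp_z <- lms_zscore(out$sbp, out$age9_mo, out$sex, "sbp", ref)
  out$dbp_z <- lms_zscore(out$dbp, out$age9_mo, out$sex, "dbp", ref)
  out$pp <- out$sbp - out$dbp
  out$pp_z <- lms_zscore(out$pp, out$age9_mo, out$sex, "pp", ref)
  out$sex_male <- as.integer(out$sex == "male")

  # --- sequential SRR construction with cumulative exclusion --------------
  ledger <- data.frame(step = character(0), n_considered = integer(0),
                       n_flagged = integer(0), ids = character(0),
                       stringsAsFactors = FALSE)
  excluded <- rep(FALSE, n)
  meta <- list()
  for (key in names(srr_recipes)[names(srr_recipes) %in% predictors]) {
    rec <- srr_recipes[[key]]
    if (!all(c(rec$outcome, rec$regressor) %in% names(out))) {
      stop("cannot build ", rec$label, ": missing column ",
           paste(setdiff(c(rec$outcome, rec$regressor), names(out)), collapse = ", "))
    }
    work <- out
    work[[rec$outcome]][excluded] <- NA  # already-excluded records sit out
    rv <- standardized_residual(work, rec$outcome, rec$regressor,
                                name = rec$label, stratify_by_sex = TRUE,
                                alpha_outlier = alpha_outlier,
                                pooled_sd = pooled_sd)
    out[[key]] <- rv$values
    meta[[key]] <- rv$fit_meta
    new_flags <- rv$flagged
    ledger <- rbind(ledger, data.frame(
      step = rec$label,
      n_considered = sum(!is.na(work[[rec$outcome]]) & !is.na(work[[rec$regressor]])),
      n_flagged = length(new_flags),
      ids = paste(out$id[new_flags], collapse = ","),
      stringsAsFactors = FALSE))
    excluded[new_flags] <- TRUE
  }

  # global exclusion: a record flagged at any step leaves the analysis
  # entirely, so every SRR is recomputed on the retained records (keeping the
  # mean-0 / SD-1 / orthogonality construction exact on the analysis set)
  if (any(excluded)) {
    work <- out
    for (key in names(srr_recipes)[names(srr_recipes) %in% predictors]) {
      rec <- srr_recipes[[key]]
      work[[rec$outcome]][excluded] <- NA
      rv <- standardized_residual(work, rec$outcome, rec$regressor,
                                  name = rec$label, stratify_by_sex = TRUE,
                                  alpha_outlier = 0, pooled_sd = pooled_sd)
      out[[key]] <- rv$values
      for (s in names(rv$fit_meta)) {
        rv$fit_meta[[s]]$n_outliers <- meta[[key]][[s]]$n_outliers
      }
      meta[[key]] <- rv$fit_meta
    }
  }
  attr(out, "ledger") <- ledger
  attr(out, "excluded_ids") <- out$id[excluded]
  attr(out, "srr_meta") <- meta
  class(out) <- c("capload_cohort", "data.frame")
  out
}
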