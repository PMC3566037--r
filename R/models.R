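#' Specify one capacity-load regression model
#'
#' @param outcome outcome column: a BP z-score (`sbp_z`, `dbp_z`, `pp_z`)
#'   for linear models, or the z-score a higher-BP flag is derived from for
#'   logistic models.
#' @param predictors ordered character vector of predictor columns.
#' @param family `"linear"` (OLS on the z-score) or `"logistic"`
#'   (maximum-likelihood logit on the higher-BP flag).
#' @param stratify_by_sex fit separately per sex (the linear convention) or
#'   pool sexes; pooled logistic fits add a `sex_male` indicator.
#' @param higher_bp_centile reference centile defining the higher-BP flag
#'   (logistic only).
#' @return list of class `capload_spec`.
#' @export
model_spec <- function(outcome, predictors, family = c("linear", "logistic"),
                       stratify_by_sex = family == "linear",
                       higher_bp_centile = 0.95) {
  family <- match.arg(family)
  force(stratify_by_sex)
  if (length(predictors) == 0L) stop("predictors must be nonempty")
  if (anyDuplicated(predictors)) stop("duplicate predictors")
  if (family == "logistic" &&
      (higher_bp_centile <= 0 || higher_bp_centile >= 1)) {
    stop("higher_bp_centile must lie in (0, 1)")
  }
  structure(list(outcome = outcome, predictors = predictors, family = family,
                 stratify_by_sex = stratify_by_sex,
                 higher_bp_centile = higher_bp_centile),
            class = "capload_spec")
}

#' Dichotomise blood pressure at a reference centile
#'
#' Flags records at or above the stated centile of the external reference
#' distribution (`z >= qnorm(centile)`, inclusive at the boundary).  This is
#' the "higher BP" grouping of a single-occasion measurement, not a clinical
#' hypertension diagnosis.
#'
#' @param data cohort table.
#' @param bp_column_z name of the BP z-score column.
#' @param centile reference centile in (0, 1); default the 95th.
#' @param sample_percentile use the sample's own empirical percentile
#'   instead of the external-reference quantile (sensitivity mode).
#' @return list with `flags` (integer 0/1, `NA` where the z-score is
#'   missing), `threshold` (on the z scale), `n_high`, `n_normal`.
#' @export
classify_higher_bp <- function(data, bp_column_z, centile = 0.95,
                               sample_percentile = FALSE) {
  if (centile <= 0 || centile >= 1) stop("centile must lie in (0, 1)")
  z <- data[[bp_column_z]]
  if (is.null(z)) stop("column not found: ", bp_column_z)
  thr <- if (sample_percentile) {
    as.numeric(quantile(z, centile, na.rm = TRUE, type = 7))
  } else {
    qnorm(centile)
  }
  flags <- ifelse(is.na(z), NA_integer_, as.integer(z >= thr))
  list(flags = flags, threshold = thr,
       n_high = sum(flags == 1L, na.rm = TRUE),
       n_normal = sum(flags == 0L, na.rm = TRUE))
}

# ---- single-model fitting -------------------------------------------------

z95 <- qnorm(0.975)  # Wald multiplier, 1.959964...

fit_one_stratum <- function(df, outcome, predictors, family) {
  form <- stats::reformulate(predictors, response = outcome)
  if (family == "linear") {
    fit <- lm(form, data = df)
    if (anyNA(coef(fit))) {
      stop("collinear predictors: ",
           paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
    }
    sm <- summary(fit)
    est <- sm$coefficients[, "Estimate"]
    se <- sm$coefficients[, "Std. Error"]
    tab <- data.frame(term = rownames(sm$coefficients), estimate = est,
                      se = se, ci_lo = est - z95 * se, ci_hi = est + z95 * se,
                      row.names = NULL, stringsAsFactors = FALSE)
    list(fit = fit, coefficients = tab, r_squared = sm$r.squared,
         n = stats::nobs(fit))
  } else {
    y <- df[[outcome]]
    if (length(unique(na.omit(y))) < 2L) {
      stop("logistic outcome '", outcome, "' has a single class")
    }
    fit <- suppressWarnings(glm(form, data = df, family = binomial()))
    if (anyNA(coef(fit))) {
      stop("collinear predictors: ",
           paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
    }
    if (!fit$converged || any(abs(coef(fit)) > 15)) {
      stop("logistic fit did not converge (possible complete separation)")
    }
    sm <- summary(fit)
    est <- sm$coefficients[, "Estimate"]
    se <- sm$coefficients[, "Std. Error"]
    tab <- data.frame(term = rownames(sm$coefficients), estimate = est,
                      se = se, ci_lo = est - z95 * se, ci_hi = est + z95 * se,
                      or = exp(est), or_lo = exp(est - z95 * se),
                      or_hi = exp(est + z95 * se),
                      row.names = NULL, stringsAsFactors = FALSE)
    mf <- stats::model.frame(fit)
    list(fit = fit, coefficients = tab, n = stats::nobs(fit),
         n_high = sum(mf[[1L]] == 1), n_normal = sum(mf[[1L]] == 0))
  }
}

#' Fit a single capacity-load regression model
#'
#' Ordinary least squares (linear family, Wald 95% CIs
#' `beta +/- 1.959964 * SE`, r-squared) or maximum-likelihood logistic
#' regression (odds ratios with exponentiated Wald CIs) for one
#' [model_spec()], stratified by sex or pooled as the spec demands.
#' Logistic models derive the higher-BP flag from the spec's outcome
#' z-score via [classify_higher_bp()] unless a `higher_bp` column already
#' exists.
#'
#' @param data cohort table with derived predictors (see
#'   [build_predictor_set()]).
#' @param spec a [model_spec()].
#' @return object of class `capload_fit`: per-stratum coefficient tables,
#'   r-squared / class counts, n, and the underlying `lm`/`glm` fits.
#' @export
fit_capload <- function(data, spec) {
  stopifnot(inherits(spec, "capload_spec"))
  df <- as.data.frame(data)
  outcome <- spec$outcome
  predictors <- spec$predictors
  if (spec$family == "logistic") {
    if (!"higher_bp" %in% names(df)) {
      if (!spec$outcome %in% names(df)) {
        stop("columns absent from table: ", spec$outcome)
      }
      cl <- classify_higher_bp(df, spec$outcome, spec$higher_bp_centile)
      df$higher_bp <- cl$flags
    }
    outcome <- "higher_bp"
    if (!spec$stratify_by_sex && "sex_male" %in% names(df) &&
        !"sex_male" %in% predictors) {
      predictors <- c(predictors, "sex_male")
    }
  }
  absent <- setdiff(c(if (spec$family == "linear") outcome, predictors),
                    names(df))
  if (length(absent) > 0L) {
    stop("columns absent from table: ", paste(absent, collapse = ", "))
  }
  strata <- if (spec$stratify_by_sex) {
    lev <- intersect(c("male", "female"), unique(df$sex))
    lev <- c(lev, setdiff(unique(df$sex), lev))
    split(df, factor(df$sex, levels = lev))
  } else {
    list(pooled = df)
  }
  res <- lapply(strata, function(d) {
    keep <- complete.cases(d[c(outcome, predictors)])
    d <- d[keep, , drop = FALSE]
    if (nrow(d) <= length(predictors) + 2L) {
      stop("too few complete records (", nrow(d), ") to fit ", spec$outcome,
           " ~ ", paste(predictors, collapse = " + "))
    }
    fit_one_stratum(d, outcome, predictors, spec$family)
  })
  structure(list(spec = spec, strata = res), class = "capload_fit")
}

#' @export
print.capload_fit <- function(x, digits = 2, ...) {
  s <- x$spec
  cat(sprintf("%s model: %s ~ %s\n", s$family, s$outcome,
              paste(s$predictors, collapse = " + ")))
  for (nm in names(x$strata)) {
    st <- x$strata[[nm]]
    extra <- if (s$family == "linear") {
      sprintf("r2 = %.2f", st$r_squared)
    } else {
      sprintf("%d high / %d normal", st$n_high, st$n_normal)
    }
    cat(sprintf("-- %s (n = %d, %s)\n", nm, st$n, extra))
    tab <- st$coefficients
    if (s$family == "linear") {
      for (i in seq_len(nrow(tab))) {
        cat(sprintf("   %-12s %6.*f (%.*f; %.*f)\n", tab$term[i],
                    digits, tab$estimate[i], digits, tab$ci_lo[i],
                    digits, tab$ci_hi[i]))
      }
    } else {
      for (i in seq_len(nrow(tab))) {
        if (tab$term[i] == "(Intercept)") next
        cat(sprintf("   %-12s OR %6.*f (%.*f; %.*f)\n", tab$term[i],
                    digits, tab$or[i], digits, tab$or_lo[i],
                    digits, tab$or_hi[i]))
      }
    }
  }
  invisible(x)
}

# ---- the three-model suite ------------------------------------------------

model_predictors <- function(model, growth) {
  load_set <- c("ht9_z", "lmr_h", "fmr_lm")
  growth_set <- if (growth == "weight") c("bw_z", "cwv") else c("blen_z", "chv")
  switch(model,
         model1 = load_set,
         model2 = growth_set,
         model3 = c(load_set, growth_set))
}

#' Fit the capacity-load model suite for one blood-pressure outcome
#'
#' The central fitting function of the package.  For one BP outcome it fits
#' the three nested regression models that the capacity-load analysis
#' contrasts:
#' \describe{
#'   \item{Model 1 (current load)}{height z-score + LMr/H + FMr/LM;}
#'   \item{Model 2 (early growth)}{birth z-score + conditional velocity
#'     (birth weight z + CWV on the weight path, birth length z + CHV on the
#'     length path);}
#'   \item{Model 3 (joint)}{all five predictors.}
#' }
#' Linear fits are sex-stratified; logistic fits pool the sexes with a
#' `sex_male` indicator and model the odds of BP at or above the reference
#' centile.  The headline capacity-load signature is the contrast between
#' Model 2 and Model 3: a positive velocity coefficient that attenuates to
#' the null once current load is held constant, and a birth-size coefficient
#' that moves from null to negative.
#'
#' @param data cohort table carrying the derived predictor set
#'   (see [build_predictor_set()]).
#' @param outcome BP z-score column (`"sbp_z"`, `"dbp_z"` or `"pp_z"`).
#' @param family `"linear"` or `"logistic"`.
#' @param growth `"weight"` (birth weight z + CWV) or `"length"`
#'   (birth length z + CHV).
#' @param models which of the three models to fit.
#' @param higher_bp_centile reference centile for the logistic flag.
#' @return Object of class `capload` with `print()`, `summary()`,
#'   `coef()`, `confint()`, `predict()`, `residuals()`, `nobs()` and
#'   `plot()` methods.
#' @examples
#' cfg <- calibrate_default_config(n = c(male = 400, female = 400))
#' coh <- build_predictor_set(generate_cohort(cfg, seed = 7), cfg$reference,
#'                            predictors = c("lmr_h", "fmr_lm", "cwv"))
#' fit <- capload(coh, outcome = "sbp_z")
#' fit
#' coef(fit, model = "model3")
#' @export
capload <- function(data, outcome = "sbp_z",
                    family = c("linear", "logistic"),
                    growth = c("weight", "length"),
                    models = c("model1", "model2", "model3"),
                    higher_bp_centile = 0.95) {
  family <- match.arg(family)
  growth <- match.arg(growth)
  models <- match.arg(models, several.ok = TRUE)
  fits <- lapply(setNames(models, models), function(m) {
    spec <- model_spec(outcome, model_predictors(m, growth), family = family,
                       higher_bp_centile = higher_bp_centile)
    fit_capload(data, spec)
  })
  structure(list(outcome = outcome, family = family, growth = growth,
                 models = fits, call = match.call()),
            class = "capload")
}

#' @export
print.capload <- function(x, digits = 2, ...) {
  cat(sprintf("Capacity-load %s suite for %s (growth path: %s)\n",
              x$family, x$outcome, x$growth))
  for (m in names(x$models)) {
    cat(sprintf("== %s ==\n", m))
    print(x$models[[m]], digits = digits)
  }
  invisible(x)
}

#' @export
coef.capload <- function(object, model = "model3", ...) {
  f <- object$models[[model]]
  if (is.null(f)) stop("model not fitted: ", model)
  out <- lapply(f$strata, function(s) setNames(s$coefficients$estimate,
                                               s$coefficients$term))
  terms <- unique(unlist(lapply(out, names)))
  mat <- sapply(out, function(v) v[terms])
  rownames(mat) <- terms
  mat
}

#' @export
confint.capload <- function(object, parm, level = 0.95, model = "model3", ...) {
  if (level != 0.95) stop("only 95% Wald intervals are tabulated")
  f <- object$models[[model]]
  if (is.null(f)) stop("model not fitted: ", model)
  out <- do.call(rbind, lapply(names(f$strata), function(nm) {
    tab <- f$strata[[nm]]$coefficients
    data.frame(stratum = nm, term = tab$term, estimate = tab$estimate,
               ci_lo = tab$ci_lo, ci_hi = tab$ci_hi,
               stringsAsFactors = FALSE)
  }))
  if (!missing(parm)) out <- out[out$term %in% parm, , drop = FALSE]
  out
}

#' @export
summary.capload <- function(object, ...) {
  rows <- list()
  for (m in names(object$models)) {
    f <- object$models[[m]]
    for (nm in names(f$strata)) {
      st <- f$strata[[nm]]
      tab <- st$coefficients
      tab$model <- m
      tab$stratum <- nm
      tab$n <- st$n
      tab$r_squared <- if (object$family == "linear") st$r_squared else NA_real_
      rows[[paste(m, nm)]] <- tab
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(outcome = object$outcome, family = object$family,
                 table = out), class = "summary.capload")
}

#' @export
print.summary.capload <- function(x, ...) {
  cat(sprintf("Capacity-load %s suite, outcome %s\n", x$family, x$outcome))
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
predict.capload <- function(object, newdata, model = "model3", ...) {
  f <- object$models[[model]]
  if (is.null(f)) stop("model not fitted: ", model)
  if (length(f$strata) == 1L) {
    return(predict(f$strata[[1L]]$fit, newdata = newdata, ...))
  }
  out <- rep(NA_real_, nrow(newdata))
  for (nm in names(f$strata)) {
    rows <- which(newdata$sex == nm)
    if (length(rows) > 0L) {
      out[rows] <- predict(f$strata[[nm]]$fit,
                           newdata = newdata[rows, , drop = FALSE], ...)
    }
  }
  out
}

#' @export
residuals.capload <- function(object, model = "model3", ...) {
  f <- object$models[[model]]
  if (is.null(f)) stop("model not fitted: ", model)
  lapply(f$strata, function(s) residuals(s$fit))
}

#' @export
nobs.capload <- function(object, model = "model3", ...) {
  f <- object$models[[model]]
  vapply(f$strata, function(s) as.integer(s$n), integer(1))
}

#' @export
plot.capload <- function(x, terms = NULL, ...) {
  rows <- confint(x, model = names(x$models)[length(x$models)])
  for (m in rev(setdiff(names(x$models), names(x$models)[length(x$models)]))) {
    rows <- rbind(rows, confint(x, model = m))
  }
  rows <- rows[rows$term != "(Intercept)", , drop = FALSE]
  if (!is.null(terms)) rows <- rows[rows$term %in% terms, , drop = FALSE]
  lab <- paste(rows$stratum, rows$term)
  k <- nrow(rows)
  old <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(old))
  plot(rows$estimate, seq_len(k), xlim = range(rows$ci_lo, rows$ci_hi, 0),
       yaxt = "n", ylab = "", pch = 19,
       xlab = if (x$family == "linear") "coefficient (95% CI)"
              else "log-odds (95% CI)",
       main = paste("capacity-load suite:", x$outcome), ...)
  graphics::segments(rows$ci_lo, seq_len(k), rows$ci_hi, seq_len(k))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(k), labels = lab, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Fit the full reporting suite across BP outcomes
#'
#' Runs [capload()] for every requested linear outcome (systolic, diastolic
#' and pulse-pressure z-scores) and logistic outcome (odds of higher BP),
#' and performs the pooled sex-interaction check on the relative lean-mass
#' term.
#'
#' @param data cohort table carrying the derived predictor set.
#' @param linear_outcomes,logistic_outcomes BP z-score columns for each
#'   family.
#' @param growth `"weight"` or `"length"` growth path.
#' @param higher_bp_centile reference centile for the logistic flag.
#' @param interaction_term predictor whose sex interaction is tested in the
#'   pooled load model (`NULL` to skip).
#' @return object of class `capload_suite`: list of `capload` fits plus the
#'   interaction p-value.
#' @export
run_suite <- function(data, linear_outcomes = c("sbp_z", "dbp_z", "pp_z"),
                      logistic_outcomes = c("sbp_z", "dbp_z"),
                      growth = c("weight", "length"),
                      higher_bp_centile = 0.95,
                      interaction_term = "lmr_h") {
  growth <- match.arg(growth)
  linear <- lapply(setNames(linear_outcomes, linear_outcomes), function(o) {
    capload(data, outcome = o, family = "linear", growth = growth)
  })
  logistic <- lapply(setNames(logistic_outcomes, logistic_outcomes), function(o) {
    capload(data, outcome = o, family = "logistic", growth = growth,
            higher_bp_centile = higher_bp_centile)
  })
  inter <- if (!is.null(interaction_term)) {
    sex_interaction_test(data, outcome = linear_outcomes[1L],
                         term = interaction_term)
  }
  structure(list(linear = linear, logistic = logistic,
                 sex_interaction = inter, growth = growth),
            class = "capload_suite")
}

#' Pooled sex-interaction check
#'
#' Fits the pooled current-load model with a sex main effect and a
#' sex-by-term interaction, returning the Wald p-value for the interaction
#' (used to justify, or not, collapsing the sexes).
#'
#' @param data cohort table with derived predictors.
#' @param outcome BP z-score column.
#' @param term load predictor whose sex interaction is tested.
#' @return list with `term`, `estimate`, `p_value`, `n`.
#' @export
sex_interaction_test <- function(data, outcome = "sbp_z", term = "lmr_h") {
  df <- as.data.frame(data)
  preds <- c("ht9_z", "lmr_h", "fmr_lm", "sex_male")
  absent <- setdiff(c(outcome, preds, term), names(df))
  if (length(absent) > 0L) {
    stop("columns absent from table: ", paste(absent, collapse = ", "))
  }
  form <- stats::as.formula(paste(
    outcome, "~", paste(preds, collapse = " + "),
    "+ sex_male:", term))
  keep <- complete.cases(df[c(outcome, preds)])
  fit <- lm(form, data = df[keep, , drop = FALSE])
  sm <- summary(fit)$coefficients
  row <- grep(":", rownames(sm))
  list(term = term, estimate = sm[row, "Estimate"],
       p_value = sm[row, "Pr(>|t|)"], n = stats::nobs(fit))
}

#' @export
print.capload_suite <- function(x, digits = 2, ...) {
  cat("Capacity-load reporting suite (growth path:", x$growth, ")\n\n")
  for (o in names(x$linear)) {
    print(x$linear[[o]], digits = digits)
    cat("\n")
  }
  for (o in names(x$logistic)) {
    print(x$logistic[[o]], digits = digits)
    cat("\n")
  }
  if (!is.null(x$sex_interaction)) {
    cat(sprintf("sex x %s interaction: p = %.2f (n = %d)\n",
                x$sex_interaction$term, x$sex_interaction$p_value,
                x$sex_interaction$n))
  }
  invisible(x)
}
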