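#' Cohort column dictionary
#'
#' The documented cohort CSV dialect: one record per child with identifier,
#' sex, gestational age (weeks), birth weight (kg) and length (cm),
#' mid-childhood weight (kg), height (cm) and age (months), outcome-visit
#' weight/height/lean mass/fat mass and age, and systolic/diastolic BP
#' (mmHg).
#'
#' @return character vector of column names; mandatory ones are marked by
#'   `attr(, "mandatory")`.
#' @export
cohort_schema <- function() {
  cols <- c("id", "sex", "gest_age_wk", "bw_kg", "blen_cm", "wt7_kg",
            "ht7_cm", "age7_mo", "wt9_kg", "ht9_cm", "lm9_kg", "fm9_kg",
            "age9_mo", "sbp", "dbp")
  attr(cols, "mandatory") <- c("id", "sex", "age9_mo", "ht9_cm", "sbp", "dbp")
  cols
}

na_tokens <- c("NA", "", ".", "NaN")

#' Read a cohort table from CSV
#'
#' Parses the documented cohort dialect.  The header is matched
#' order-insensitively; `NA`, empty, and `.` cells are missing; any other
#' non-numeric token in a numeric column becomes missing and is logged with
#' its line number.  Validations (unique ids, positive physical quantities,
#' SBP > DBP) are logged on the attached parse log — violating records are
#' kept, never silently dropped, so downstream outlier screens see them.
#'
#' @param path CSV file path.
#' @return data.frame of class `capload_cohort` with a `parse_log`
#'   attribute (list of per-issue counts and line numbers).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(raw) == 0L) stop("cohort file is empty: ", path)
  schema <- cohort_schema()
  mandatory <- attr(schema, "mandatory")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent) > 0L) {
    stop("cohort file lacks mandatory columns: ", paste(absent, collapse = ", "))
  }
  log <- list(malformed = list(), violations = list())
  out <- data.frame(id = raw$id, stringsAsFactors = FALSE)
  sex <- tolower(trimws(raw$sex))
  sex[sex %in% c("m", "male", "1")] <- "male"
  sex[sex %in% c("f", "female", "2")] <- "female"
  bad_sex <- which(!sex %in% c("male", "female"))
  if (length(bad_sex) > 0L) {
    stop("unrecognised sex values at line(s) ",
         paste(utils::head(bad_sex + 1L, 5), collapse = ", "))
  }
  out$sex <- sex
  for (col in setdiff(intersect(schema, names(raw)), c("id", "sex"))) {
    txt <- trimws(raw[[col]])
    txt[txt %in% na_tokens] <- NA
    val <- suppressWarnings(as.numeric(txt))
    mal <- which(!is.na(txt) & is.na(val))
    if (length(mal) > 0L) {
      log$malformed[[col]] <- mal + 1L  # header is line 1
    }
    out[[col]] <- val
  }
  if (anyDuplicated(out$id)) stop("duplicate record ids in ", path)
  phys <- setdiff(intersect(schema, names(out)), c("id", "sex"))
  for (col in phys) {
    neg <- which(!is.na(out[[col]]) & out[[col]] <= 0)
    if (length(neg) > 0L) log$violations[[col]] <- neg + 1L
  }
  swap <- which(!is.na(out$sbp) & !is.na(out$dbp) & out$sbp <= out$dbp)
  if (length(swap) > 0L) log$violations$sbp_not_above_dbp <- swap + 1L
  n_mal <- sum(lengths(log$malformed))
  n_vio <- sum(lengths(log$violations))
  if (n_mal + n_vio > 0L) {
    message("read_cohort: ", n_mal, " malformed cell(s) set missing, ",
            n_vio, " invariant violation(s) logged (records kept)")
  }
  attr(out, "parse_log") <- log
  class(out) <- c("capload_cohort", "data.frame")
  out
}

#' @rdname read_cohort
#' @param data cohort table to write.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "NA",
                   quote = FALSE)
  invisible(path)
}

#' Run the full capacity-load analysis pipeline
#'
#' End-to-end driver: read (or accept) a cohort and reference, build the
#' derived predictor set with sequential outlier screening, fit the linear
#' and logistic model suites, and bundle the results with the exclusion
#' ledger.  With `out_dir` set, machine-readable results (JSON), rendered
#' coefficient tables (TSV) and the ledger are written there.
#'
#' @param cohort cohort table or CSV path.
#' @param reference [lms_reference()] or reference CSV path.
#' @param config optional list (or YAML file path) overriding
#'   `linear_outcomes`, `logistic_outcomes`, `growth`, `higher_bp_centile`,
#'   `alpha_outlier`, `predictors`.
#' @param out_dir optional output directory.
#' @param seed seed recorded in the result metadata (the pipeline itself is
#'   deterministic; the seed matters when the cohort was simulated
#'   upstream).
#' @return object of class `capload_results`: list with the fitted `suite`,
#'   `ledger`, `n_input`, `n_excluded`, `n_used` (largest fitted model),
#'   `seed`, and the configuration echo.
#' @export
run_pipeline <- function(cohort, reference, config = NULL, out_dir = NULL,
                         seed = NULL) {
  if (is.character(reference)) reference <- read_lms_reference(reference)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(linear_outcomes = c("sbp_z", "dbp_z", "pp_z"),
                   logistic_outcomes = c("sbp_z", "dbp_z"),
                   growth = "weight", higher_bp_centile = 0.95,
                   alpha_outlier = 0.05,
                   predictors = c("wr_h", "lmr_h", "fmr_h", "fmr_lm",
                                  "cwv", "chv"))
  cfg <- utils::modifyList(defaults, if (is.null(config)) list() else config)
  if (nrow(cohort) < 50L) {
    warning("cohort has only ", nrow(cohort),
            " records; confidence intervals will be unstable")
  }
  derived <- build_predictor_set(cohort, reference,
                                 predictors = cfg$predictors,
                                 alpha_outlier = cfg$alpha_outlier)
  suite <- run_suite(derived, linear_outcomes = cfg$linear_outcomes,
                     logistic_outcomes = cfg$logistic_outcomes,
                     growth = cfg$growth,
                     higher_bp_centile = cfg$higher_bp_centile)
  ledger <- attr(derived, "ledger")
  n_used <- max(vapply(suite$linear, function(f)
    max(vapply(f$models, function(m)
      sum(vapply(m$strata, function(s) s$n, numeric(1))), numeric(1))),
    numeric(1)))
  res <- structure(
    list(suite = suite, derived = derived, ledger = ledger,
         n_input = nrow(cohort),
         n_excluded = length(attr(derived, "excluded_ids")),
         n_used = n_used, seed = seed, config = cfg),
    class = "capload_results")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- lapply(c(res$suite$linear, res$suite$logistic), function(f) {
    summary(f)$table
  })
  machine <- list(
    meta = list(seed = res$seed, n_input = res$n_input,
                n_excluded = res$n_excluded, n_used = res$n_used,
                config = res$config),
    ledger = res$ledger,
    models = tabs,
    sex_interaction = res$suite$sex_interaction)
  jsonlite::write_json(machine, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  jsonlite::write_json(res$ledger, file.path(out_dir, "ledger.json"),
                       auto_unbox = TRUE, dataframe = "rows")
  all_tab <- do.call(rbind, lapply(names(tabs), function(o) {
    t <- tabs[[o]]; t$outcome <- o; t
  }))
  utils::write.table(all_tab, file.path(out_dir, "tables.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' @export
print.capload_results <- function(x, ...) {
  cat("Capacity-load pipeline results\n")
  cat(sprintf("  input records: %d; excluded as outliers: %d; largest model n: %d\n",
              x$n_input, x$n_excluded, x$n_used))
  cat("  exclusion ledger:\n")
  lg <- x$ledger
  for (i in seq_len(nrow(lg))) {
    cat(sprintf("    %-7s considered %5d, flagged %d\n",
                lg$step[i], lg$n_considered[i], lg$n_flagged[i]))
  }
  print(x$suite, ...)
  invisible(x)
}
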