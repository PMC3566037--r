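#' LMS growth-reference tables
#'
#' An `lms_reference` stores age- and sex-indexed L (Box-Cox power),
#' M (median) and S (coefficient of variation) triples for one or more
#' measurements, the representation popularised by Cole's LMS method for
#' growth references.  Raw measurements are converted to standard deviation
#' scores (SDS, "z-scores") against such a table with [lms_zscore()], and
#' z-scores or centiles are mapped back to the raw scale with [lms_value()]
#' and [bp_centile_cutoff()].  Blood-pressure centile references are held in
#' the same container with `L = 1` (a Gaussian approximation).
#'
#' @param table data.frame with columns `measurement`, `sex`, `age`,
#'   `L`, `M`, `S`; one row per age-grid point.  Ages must be strictly
#'   increasing within each (measurement, sex) series, `M > 0`, `S > 0`,
#'   `L` finite.
#' @param age_units named character vector mapping each measurement to its
#'   age unit (e.g. `c(bw = "weeks_gestation", ht = "months")`).  Purely
#'   descriptive metadata; recycled to `"unspecified"` when absent.
#' @return An object of class `lms_reference`.
#' @examples
#' ref <- lms_reference(data.frame(
#'   measurement = "wt", sex = "male", age = c(80, 100, 120),
#'   L = 1, M = c(22, 27, 33), S = 0.12))
#' lms_zscore(27, age = 100, sex = "male", measurement = "wt", ref = ref)
#' @export
lms_reference <- function(table, age_units = NULL) {
  required <- c("measurement", "sex", "age", "L", "M", "S")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0L) {
    stop("reference table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  table <- as.data.frame(table)[required]
  table$measurement <- as.character(table$measurement)
  table$sex <- as.character(table$sex)
  if (!all(table$sex %in% c("male", "female"))) {
    stop("reference sex must be 'male' or 'female'")
  }
  for (col in c("age", "L", "M", "S")) table[[col]] <- as.numeric(table[[col]])
  if (anyNA(table)) stop("reference table contains missing values")
  if (!all(is.finite(table$L))) stop("L must be finite")
  if (any(table$M <= 0)) stop("M must be positive everywhere")
  if (any(table$S <= 0)) stop("S must be positive everywhere")
  key <- interaction(table$measurement, table$sex, drop = TRUE)
  for (k in levels(key)) {
    a <- table$age[key == k]
    if (is.unsorted(a, strictly = TRUE)) {
      stop("ages must be strictly increasing within series ", k)
    }
  }
  meas <- unique(table$measurement)
  units <- setNames(rep("unspecified", length(meas)), meas)
  if (!is.null(age_units)) units[names(age_units)] <- age_units
  structure(list(table = table, age_units = units), class = "lms_reference")
}

#' @export
print.lms_reference <- function(x, ...) {
  tab <- x$table
  cat("LMS reference:", length(unique(tab$measurement)), "measurement(s),",
      nrow(tab), "grid rows\n")
  for (m in unique(tab$measurement)) {
    sub <- tab[tab$measurement == m, ]
    cat(sprintf("  %-6s [%s] age %g..%g, sexes: %s\n", m,
                x$age_units[[m]], min(sub$age), max(sub$age),
                paste(unique(sub$sex), collapse = "/")))
  }
  invisible(x)
}

# Interpolate L, M, S at `age` for one (measurement, sex) series.
# Linear interpolation in each parameter separately; errors outside the grid.
lms_params <- function(ref, age, sex, measurement) {
  stopifnot(inherits(ref, "lms_reference"))
  tab <- ref$table
  sub <- tab[tab$measurement == measurement & tab$sex == sex, ]
  if (nrow(sub) == 0L) {
    stop("no reference series for measurement '", measurement, "', sex '", sex, "'")
  }
  lo <- min(sub$age); hi <- max(sub$age)
  bad <- !is.na(age) & (age < lo | age > hi)
  if (any(bad)) {
    stop(sprintf(
      "age %g outside reference grid [%g, %g] for %s/%s (no extrapolation)",
      age[which(bad)[1L]], lo, hi, measurement, sex))
  }
  list(L = approx(sub$age, sub$L, xout = age)$y,
       M = approx(sub$age, sub$M, xout = age)$y,
       S = approx(sub$age, sub$S, xout = age)$y)
}

#' Convert a raw measurement to an LMS z-score
#'
#' Applies the LMS transform `z = ((x/M)^L - 1) / (L * S)` (or
#' `z = log(x/M) / S` when `L = 0`), with L, M and S linearly interpolated
#' in age.  Vectorised over `x`, `age` and `sex`; missing measurements
#' yield `NA` z-scores.
#'
#' @param x raw measurement values (positive; `NA` allowed).
#' @param age age at measurement, in the units of the reference series.
#'   Ages outside the reference grid are an error (no extrapolation).
#' @param sex `"male"`/`"female"`, recycled against `x`.
#' @param measurement which reference series to use.
#' @param ref an [lms_reference()].
#' @return numeric vector of standard deviation scores.
#' @export
lms_zscore <- function(x, age, sex, measurement, ref) {
  n <- max(length(x), length(age), length(sex))
  x <- rep_len(as.numeric(x), n)
  age <- rep_len(as.numeric(age), n)
  sex <- rep_len(as.character(sex), n)
  if (any(!is.na(x) & x <= 0)) stop("measurements must be positive")
  out <- rep(NA_real_, n)
  for (s in unique(sex)) {
    i <- which(sex == s & !is.na(x) & !is.na(age))
    if (length(i) == 0L) next
    p <- lms_params(ref, age[i], s, measurement)
    r <- x[i] / p$M
    z <- ifelse(abs(p$L) < 1e-12,
                log(r) / p$S,
                (r ^ p$L - 1) / (p$L * p$S))
    out[i] <- z
  }
  out
}

#' Invert an LMS z-score to the raw measurement scale
#'
#' Exact inverse of [lms_zscore()]: `x = M * (1 + L*S*z)^(1/L)` (or
#' `M * exp(S*z)` when `L = 0`).  Used to build raw-scale synthetic cohorts
#' and raw centile thresholds.
#'
#' @inheritParams lms_zscore
#' @param z standard deviation scores (finite; `NA` allowed).
#' @return numeric vector of raw measurement values.
#' @export
lms_value <- function(z, age, sex, measurement, ref) {
  n <- max(length(z), length(age), length(sex))
  z <- rep_len(as.numeric(z), n)
  age <- rep_len(as.numeric(age), n)
  sex <- rep_len(as.character(sex), n)
  out <- rep(NA_real_, n)
  for (s in unique(sex)) {
    i <- which(sex == s & !is.na(z) & !is.na(age))
    if (length(i) == 0L) next
    p <- lms_params(ref, age[i], s, measurement)
    base <- 1 + p$L * p$S * z[i]
    bad <- abs(p$L) >= 1e-12 & base <= 0
    if (any(bad)) {
      stop(sprintf(
        "inverse LMS undefined for z = %g (1 + L*S*z = %g <= 0)",
        z[i][bad][1L], base[bad][1L]))
    }
    out[i] <- ifelse(abs(p$L) < 1e-12,
                     p$M * exp(p$S * z[i]),
                     p$M * base ^ (1 / p$L))
  }
  out
}

#' Raw-scale centile threshold from a reference
#'
#' Maps a reference centile (e.g. the 95th used to define "higher" blood
#' pressure) to the raw measurement scale via the normal quantile and the
#' inverse LMS transform.
#'
#' @inheritParams lms_zscore
#' @param centile probability in (0, 1).
#' @return raw-scale threshold value(s).
#' @export
bp_centile_cutoff <- function(ref, centile, age, sex, measurement) {
  if (any(centile <= 0 | centile >= 1)) stop("centile must lie in (0, 1)")
  lms_value(qnorm(centile), age = age, sex = sex,
            measurement = measurement, ref = ref)
}

#' Read / write a reference table in the documented CSV dialect
#'
#' The dialect is a UTF-8 CSV with header
#' `measurement,sex,age,L,M,S`, one row per grid point.  Age units are
#' carried in a leading comment line of the form
#' `# age_units: bw=weeks_gestation,ht=months`.
#'
#' @param path file path.
#' @return [read_lms_reference()] returns an [lms_reference()];
#'   `write_lms_reference()` returns `path` invisibly.
#' @export
read_lms_reference <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  first <- readLines(path, n = 1L)
  units <- NULL
  if (startsWith(first, "# age_units:")) {
    spec <- trimws(sub("^# age_units:", "", first))
    if (nzchar(spec)) {
      parts <- strsplit(strsplit(spec, ",")[[1]], "=")
      units <- setNames(vapply(parts, `[`, "", 2L),
                        vapply(parts, `[`, "", 1L))
    }
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  lms_reference(tab, age_units = units)
}

#' @rdname read_lms_reference
#' @param ref an [lms_reference()] to write.
#' @export
write_lms_reference <- function(ref, path) {
  stopifnot(inherits(ref, "lms_reference"))
  units <- paste(names(ref$age_units), ref$age_units, sep = "=", collapse = ",")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# age_units: ", units), con)
  utils::write.csv(ref$table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
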