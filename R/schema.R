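#' @keywords internal
"_PACKAGE"

## Canonical microdata schema ------------------------------------------------

# Levels for the categorical survey variables. Kept as plain character
# vectors (not factors) so CSV round-trips are exact.
.gender_levels <- c("female", "male")
.marital_levels <- c("with_partner", "single")
.job_levels <- c("employed", "unemployed", "retired", "homemaker",
                 "sick_disabled", "other")
.sphus_levels <- c("excellent", "good", "fair", "poor", "very_poor")
.lifehap_levels <- c("often", "sometimes", "rarely", "never")
.gali_levels <- c("limited", "not_limited")
.education_sentinels <- c("never_in_school", "still_studying")

#' Microdata schema for one survey respondent
#'
#' Returns the canonical column schema for person-level microdata: one row
#' per field with its storage type, admissible range or level set, and
#' whether missing values are tolerated. Every reader and the synthetic
#' generator validate against this table, so no record violating a range
#' constraint ever reaches the indicator, clustering or shock modules.
#'
#' The only field where `NA` is admissible is `isco` (occupation code):
#' retirees and persons who never worked have none, and a missing code only
#' disables the sector job-loss shock rule for that person.
#'
#' @return A data.frame with columns `field`, `type` (`"character"`,
#'   `"integer"` or `"numeric"`), `levels` (comma-separated admissible
#'   levels, or `""`), `min`, `max` (numeric bounds, `NA` if unbounded) and
#'   `na_ok` (logical).
#' @examples
#' share_schema()$field
#' @export
share_schema <- function() {
  f <- function(field, type, levels = "", min = NA_real_, max = NA_real_,
                na_ok = FALSE) {
    data.frame(field = field, type = type, levels = levels,
               min = min, max = max, na_ok = na_ok,
               stringsAsFactors = FALSE)
  }
  rbind(
    f("person_id", "character"),
    f("country", "character"),
    f("weight", "numeric", min = 0),     # strictly positive, checked below
    f("gender", "character", paste(.gender_levels, collapse = ",")),
    f("age_years", "integer", min = 50),
    f("marital_status", "character", paste(.marital_levels, collapse = ",")),
    f("education_years", "character"),   # integer string or sentinel; special-cased
    f("hh_income", "numeric", min = 0),
    f("n_adults", "integer", min = 1),
    f("n_children", "integer", min = 0),
    f("job_situation", "character", paste(.job_levels, collapse = ",")),
    f("isco", "character", na_ok = TRUE),
    f("fdistress", "integer", min = 1, max = 4),
    f("legeggs", "integer", min = 0, max = 4),
    f("meat", "integer", min = 0, max = 4),
    f("sphus", "character", paste(.sphus_levels, collapse = ",")),
    f("chronic", "integer", min = 0),
    f("eurod", "integer", min = 0, max = 12),
    f("lifesat", "integer", min = 0, max = 10),
    f("lifehap", "character", paste(.lifehap_levels, collapse = ",")),
    f("gali", "character", paste(.gali_levels, collapse = ",")),
    f("mobility", "integer", min = 0, max = 10),
    f("adl", "integer", min = 0, max = 6),
    f("iadl", "integer", min = 0, max = 9),
    f("bmi", "numeric", min = 0),
    f("doctor_visits", "integer", min = 0),
    f("hospital_nights", "integer", min = 0)
  )
}

.is_education_valid <- function(x) {
  ok_sentinel <- x %in% .education_sentinels
  ok_int <- grepl("^[0-9]+$", x)
  ok_sentinel | ok_int
}

.is_isco_valid <- function(x) {
  is.na(x) | x == "" | grepl("^[0-9]{4}$", x)
}

#' Validate a microdata table against the respondent schema
#'
#' Checks column presence (case-insensitive), storage types, categorical
#' level sets and numeric ranges row by row. Rows with missing mandatory
#' values are flagged as `incomplete` (the pipeline keeps complete cases
#' only); rows with out-of-range or mis-coded values are flagged as
#' `invalid`.
#'
#' @param df A data.frame of raw microdata.
#' @return A list with `records` (the rows passing all checks, types
#'   coerced to the schema), `diagnostics` (data.frame `row`, `field`,
#'   `problem`, `value`), `incomplete_rows` and `invalid_rows` (integer row
#'   indices into `df`).
#' @export
validate_microdata <- function(df) {
  stopifnot(is.data.frame(df))
  sch <- share_schema()
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(sch$field, names(df))
  if (length(missing_cols) > 0L) {
    stop("microdata is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, sch$field, drop = FALSE]
  n <- nrow(df)
  diags <- list()
  note <- function(rows, field, problem, values) {
    if (length(rows) == 0L) return()
    diags[[length(diags) + 1L]] <<- data.frame(
      row = rows, field = field, problem = problem,
      value = as.character(values), stringsAsFactors = FALSE)
  }

  incomplete <- rep(FALSE, n)
  invalid <- rep(FALSE, n)
  for (i in seq_len(nrow(sch))) {
    fld <- sch$field[i]
    x <- df[[fld]]
    if (fld == "isco") {
      x <- as.character(x)
      x[!is.na(x) & x == ""] <- NA_character_
      bad <- which(!.is_isco_valid(x))
      note(bad, fld, "not a 4-digit occupation code", x[bad])
      invalid[bad] <- TRUE
      df[[fld]] <- x
      next
    }
    miss <- which(is.na(x) | (is.character(x) & !is.na(x) & x == ""))
    note(miss, fld, "missing mandatory value", x[miss])
    incomplete[miss] <- TRUE
    present <- !is.na(x)
    if (fld == "education_years") {
      x <- as.character(x)
      bad <- which(present & !.is_education_valid(x))
      note(bad, fld, "not a non-negative integer or recognised sentinel", x[bad])
      invalid[bad] <- TRUE
      df[[fld]] <- x
      next
    }
    if (sch$type[i] %in% c("integer", "numeric")) {
      xn <- suppressWarnings(as.numeric(x))
      conv_bad <- which(present & is.na(xn))
      note(conv_bad, fld, "not numeric", x[conv_bad])
      invalid[conv_bad] <- TRUE
      if (sch$type[i] == "integer") {
        frac_bad <- which(!is.na(xn) & xn != round(xn))
        note(frac_bad, fld, "not an integer", x[frac_bad])
        invalid[frac_bad] <- TRUE
      }
      lo <- sch$min[i]; hi <- sch$max[i]
      strict_lo <- fld %in% c("weight", "bmi")  # must be > 0, not >= 0
      if (!is.na(lo)) {
        bad <- which(!is.na(xn) & if (strict_lo) xn <= lo else xn < lo)
        note(bad, fld, sprintf("below admissible minimum (%s %s)",
                               if (strict_lo) ">" else ">=", lo), x[bad])
        invalid[bad] <- TRUE
      }
      if (!is.na(hi)) {
        bad <- which(!is.na(xn) & xn > hi)
        note(bad, fld, sprintf("above admissible maximum (<= %s)", hi), x[bad])
        invalid[bad] <- TRUE
      }
      df[[fld]] <- if (sch$type[i] == "integer") as.integer(round(xn)) else xn
    } else {
      x <- as.character(x)
      lv <- strsplit(sch$levels[i], ",", fixed = TRUE)[[1]]
      if (length(lv) > 0L) {
        bad <- which(present & !(x %in% lv))
        note(bad, fld, paste0("not one of {", sch$levels[i], "}"), x[bad])
        invalid[bad] <- TRUE
      }
      df[[fld]] <- x
    }
  }

  dup <- which(duplicated(df$person_id) & !is.na(df$person_id))
  note(dup, "person_id", "duplicate identifier", df$person_id[dup])
  invalid[dup] <- TRUE

  diagnostics <- if (length(diags)) do.call(rbind, diags) else
    data.frame(row = integer(), field = character(), problem = character(),
               value = character(), stringsAsFactors = FALSE)
  keep <- !(incomplete | invalid)
  list(records = df[keep, , drop = FALSE],
       diagnostics = diagnostics,
       incomplete_rows = which(incomplete),
       invalid_rows = which(invalid))
}

## Bundle construction -------------------------------------------------------

#' Assemble validated records and poverty thresholds into a dataset bundle
#'
#' The bundle is the unit every downstream module consumes: validated
#' respondent records, the per-country at-risk-of-poverty threshold table,
#' and a provenance label. Construction fails if any record's country lacks
#' a threshold, if person identifiers are not unique, or if the total
#' calibration weight is not positive.
#'
#' @param records data.frame of schema-conforming respondent records.
#' @param thresholds data.frame with columns `country` and `threshold_eur`
#'   (60%-of-median equivalised income poverty lines, EUR/year).
#' @param provenance Free-text label (file path or synthetic seed tag).
#' @return An object of class `vuln_bundle`: a list with elements
#'   `records`, `thresholds`, `provenance`.
#' @export
vuln_bundle <- function(records, thresholds, provenance = "unspecified") {
  stopifnot(is.data.frame(records), is.data.frame(thresholds))
  if (!all(c("country", "threshold_eur") %in% names(thresholds)))
    stop("thresholds must have columns country, threshold_eur")
  if (anyDuplicated(records$person_id))
    stop("person_id values must be unique")
  if (nrow(records) > 0L && sum(records$weight) <= 0)
    stop("total calibration weight must be positive")
  if (any(thresholds$threshold_eur <= 0))
    stop("poverty thresholds must be positive")
  absent <- setdiff(unique(records$country), thresholds$country)
  if (length(absent) > 0L)
    stop("no poverty threshold for country: ", paste(absent, collapse = ", "))
  structure(list(records = records, thresholds = thresholds,
                 provenance = provenance),
            class = "vuln_bundle")
}

#' @export
print.vuln_bundle <- function(x, ...) {
  cat("<vuln_bundle>\n")
  cat("  records:   ", nrow(x$records), " respondents, ",
      length(unique(x$records$country)), " countries\n", sep = "")
  cat("  population:", format(round(sum(x$records$weight)), big.mark = ","),
      "persons represented\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

## Readers / writers ----------------------------------------------------------

#' Read person-level microdata and assemble a validated bundle
#'
#' Reads a delimited text file (one row per respondent, header names as in
#' [share_schema()], case-insensitive), validates every row, drops rows
#' with missing mandatory values (complete-case rule) with a warning, and
#' aborts with row-indexed diagnostics if any row carries an out-of-range
#' or mis-coded value.
#'
#' @param path Path to the microdata file.
#' @param thresholds Either a data.frame (`country`, `threshold_eur`) or a
#'   path to a CSV with those columns.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A [vuln_bundle()].
#' @export
read_microdata <- function(path, thresholds, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE,
                          colClasses = "character",
                          na.strings = c("NA", ""))
  if (nrow(df) == 0L) {
    warning("microdata file has a header but no data rows: ", path)
  }
  v <- validate_microdata(df)
  if (length(v$invalid_rows) > 0L) {
    d <- v$diagnostics
    d <- d[d$row %in% v$invalid_rows, , drop = FALSE]
    msg <- paste(sprintf("row %d, field %s: %s (value '%s')",
                         d$row, d$field, d$problem, d$value),
                 collapse = "\n  ")
    stop("invalid microdata in ", path, ":\n  ", msg)
  }
  if (length(v$incomplete_rows) > 0L) {
    warning(length(v$incomplete_rows),
            " row(s) dropped for missing mandatory values (complete-case rule)")
  }
  if (is.character(thresholds)) thresholds <- read_thresholds(thresholds)
  vuln_bundle(v$records, thresholds, provenance = path)
}

#' Read a per-country poverty-threshold table
#'
#' @param path CSV with columns `country`, `threshold_eur`.
#' @return data.frame with those two columns.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("country", "threshold_eur") %in% names(df)))
    stop("threshold table must have columns country, threshold_eur")
  df$threshold_eur <- as.numeric(df$threshold_eur)
  df
}

#' Write a tabular artifact to CSV at full precision
#'
#' Reals are serialized with `format(..., digits = 17)` semantics (via
#' `write.csv` on unrounded doubles), so `read(write(x))` reproduces `x`
#' field for field.
#'
#' @param rows data.frame to write.
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  if (is.null(rows)) stop("rows must be non-null")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Write the microdata records of a bundle to CSV
#' @param bundle A [vuln_bundle()].
#' @param path Output path.
#' @export
write_microdata <- function(bundle, path) {
  stopifnot(inherits(bundle, "vuln_bundle"))
  write_table(bundle$records, path)
}

#' Serialize a fitted cluster model to JSON
#'
#' Stores k, lambda, the numeric centers and categorical modes of every
#' prototype, the variable names, seed, cost and convergence state.
#' Assignments are stored as an integer vector aligned with the training
#' person ids.
#'
#' @param model A `kproto_model` from [kproto_fit()].
#' @param path Output path (JSON).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "kproto_model"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    k = model$k,
    lambda = model$lambda,
    numeric_vars = model$numeric_vars,
    categorical_vars = model$categorical_vars,
    numeric_centers = model$numeric_centers,
    categorical_modes = model$categorical_modes,
    cost = model$cost,
    n_iter = model$n_iter,
    seed = model$seed,
    converged = model$converged,
    person_id = model$person_id,
    assignments = model$assignments
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Reload a cluster model written by [write_model()]
#' @param path JSON path.
#' @return A `kproto_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- list(
    k = as.integer(p$k),
    lambda = as.numeric(p$lambda),
    numeric_vars = as.character(p$numeric_vars),
    categorical_vars = as.character(p$categorical_vars),
    numeric_centers = matrix(as.numeric(unlist(p$numeric_centers)),
                             nrow = as.integer(p$k),
                             dimnames = list(NULL, as.character(p$numeric_vars))),
    categorical_modes = matrix(as.character(unlist(p$categorical_modes)),
                               nrow = as.integer(p$k),
                               dimnames = list(NULL, as.character(p$categorical_vars))),
    cost = as.numeric(p$cost),
    n_iter = as.integer(p$n_iter),
    seed = as.integer(p$seed),
    converged = as.logical(p$converged),
    person_id = as.character(p$person_id),
    assignments = as.integer(p$assignments)
  )
  # write_json flattens 1-column matrices; restore dimensions
  if (length(m$numeric_vars) > 0)
    dim(m$numeric_centers) <- c(m$k, length(m$numeric_vars))
  if (length(m$categorical_vars) > 0)
    dim(m$categorical_modes) <- c(m$k, length(m$categorical_vars))
  colnames(m$numeric_centers) <- m$numeric_vars
  colnames(m$categorical_modes) <- m$categorical_vars
  structure(m, class = "kproto_model")
}

#' Serialize a shock audit to JSON
#' @param audit A `shock_audit` list from [apply_shock()].
#' @param path Output path.
#' @export
write_audit <- function(audit, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(audit), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Reload a shock audit written by [write_audit()]
#' @param path JSON path.
#' @export
read_audit <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = FALSE)
}
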