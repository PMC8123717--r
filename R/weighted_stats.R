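## Survey-weighted descriptive statistics.
##
## All estimators treat the calibration weight w_i as the number of persons
## the respondent represents. They satisfy weight-splitting invariance:
## replacing (x, w) by two copies (x, w/2) changes nothing.

#' Weighted mean
#'
#' @param x Numeric values.
#' @param w Positive weights, same length.
#' @return `sum(w*x)/sum(w)`.
#' @export
wmean <- function(x, w) {
  .check_sample(x, w)
  sum(w * x) / sum(w)
}

#' Weighted variance (population form)
#'
#' `sum(w*(x - wmean)^2)/sum(w)` — the dispersion of the represented
#' population, not an unbiased sample estimator.
#' @inheritParams wmean
#' @export
wvar <- function(x, w) {
  .check_sample(x, w)
  m <- sum(w * x) / sum(w)
  sum(w * (x - m)^2) / sum(w)
}

#' Design-based standard error of the weighted mean
#'
#' Under independent weighted sampling,
#' `se = sqrt(sum(w^2 * (x - wmean)^2)) / sum(w)`.
#' @inheritParams wmean
#' @export
wse <- function(x, w) {
  .check_sample(x, w)
  m <- sum(w * x) / sum(w)
  sqrt(sum(w^2 * (x - m)^2)) / sum(w)
}

#' Weighted quantile (left-continuous inverse CDF)
#'
#' Returns the smallest observed value whose cumulative normalized weight
#' reaches `q`. No interpolation is performed, so quantiles of a discrete
#' indicator always land on attainable values, and with integer weights the
#' result equals the type-1 quantile of the weight-expanded list.
#'
#' @inheritParams wmean
#' @param q Probability (vectorised), each in \[0, 1\].
#' @return Numeric vector, one quantile per element of `q`.
#' @export
wquantile <- function(x, w, q) {
  .check_sample(x, w)
  stopifnot(all(q >= 0 & q <= 1))
  o <- order(x)
  xs <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(q, function(p) {
    if (p == 0) return(xs[1L])
    # guard against floating-point undershoot at exact atoms
    xs[which(cw >= p - 1e-12)[1L]]
  }, numeric(1))
}

#' Weighted median
#' @inheritParams wmean
#' @export
wmedian <- function(x, w) wquantile(x, w, 0.5)

#' Weighted frequency table
#'
#' Shares of total weight per category, in lexicographic category order.
#' @param x Category labels.
#' @param w Positive weights.
#' @return Named numeric vector of shares summing to 1.
#' @export
wtable <- function(x, w) {
  .check_sample(rep(0, length(x)), w)
  s <- tapply(w, factor(x, levels = sort(unique(as.character(x)))), sum)
  s[is.na(s)] <- 0
  stats::setNames(as.numeric(s / sum(s)), names(s))
}

.check_sample <- function(x, w) {
  if (length(x) == 0L) stop("empty sample")
  if (length(x) != length(w)) stop("values and weights differ in length")
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive and finite")
  if (sum(w) <= 0) stop("total weight must be positive")
  invisible(TRUE)
}

## Grouped summaries ----------------------------------------------------------

#' Default assignment of survey countries to four European regions
#'
#' Region archetypes: `southern`, `eastern`, `northern` (continental
#' central/western Europe) and `scandinavian_ch` (Nordics plus
#' Switzerland). The assignment is a plain data.frame and fully
#' configurable; straddling cases (e.g. Finland, Czechia) are placed once
#' and documented rather than duplicated.
#'
#' @return data.frame with columns `country`, `region`.
#' @export
default_region_map <- function() {
  reg <- list(
    southern = c("ES", "IT", "PT", "GR", "CY", "MT"),
    eastern = c("PL", "CZ", "HU", "SI", "SK", "EE", "LV", "LT", "HR",
                "BG", "RO"),
    northern = c("DE", "FR", "BE", "NL", "LU", "AT"),
    scandinavian_ch = c("DK", "SE", "FI", "CH")
  )
  data.frame(country = unlist(reg, use.names = FALSE),
             region = rep(names(reg), lengths(reg)),
             stringsAsFactors = FALSE)
}

#' Age band of a respondent
#'
#' Four bands: `<60` = \[50, 60), `60-70` = \[60, 70), `70-80` = \[70, 80),
#' `>80` = \[80, Inf).
#' @param age_years Integer ages.
#' @return Character vector of band labels.
#' @export
age_group <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 59.5, 69.5, 79.5, Inf),
      labels = c("<60", "60-70", "70-80", ">80")) |> as.character()
}

#' Education band of a respondent
#'
#' Years of schooling grouped into `0-9`, `10-12` and `>12`, with the two
#' sentinel answers `never_in_school` and `still_studying` kept as their
#' own groups.
#' @param education_years Character vector: integer strings or sentinels.
#' @return Character vector of group labels.
#' @export
education_group <- function(education_years) {
  out <- character(length(education_years))
  sent <- education_years %in% c("never_in_school", "still_studying")
  out[sent] <- education_years[sent]
  yrs <- suppressWarnings(as.numeric(education_years[!sent]))
  out[!sent] <- ifelse(yrs <= 9, "0-9", ifelse(yrs <= 12, "10-12", ">12"))
  out
}

.group_order <- list(
  gender = c("female", "male"),
  marital_status = c("with_partner", "single"),
  age_group = c("<60", "60-70", "70-80", ">80"),
  education_group = c("never_in_school", "0-9", "10-12", ">12",
                      "still_studying")
)

#' Survey-weighted summaries of indicators by demographic group
#'
#' For each group and each requested value column, computes the unweighted
#' count, total weight, weighted mean and its design-based standard error,
#' weighted quartiles (left-continuous rule) and Tukey boxplot whiskers
#' (most extreme observed values within 1.5 IQR of the weighted quartiles).
#'
#' @param scores data.frame containing the value columns and `person_id`.
#' @param records data.frame of respondent records (supplies `weight` and
#'   the grouping fields), joined to `scores` on `person_id`.
#' @param by Grouping variable: one of `"country"`, `"region"`,
#'   `"gender"`, `"marital_status"`, `"age_group"`, `"education_group"`.
#' @param value_cols Columns of `scores` to summarise (default: the two
#'   indicators).
#' @param region_map data.frame `country`/`region`; required when
#'   `by = "region"`.
#' @return data.frame, one row per group x value column, ordered by the
#'   group key (documented category order for demographics, alphabetical
#'   for country/region).
#' @export
group_summaries <- function(scores, records, by,
                            value_cols = c("economic_indicator",
                                           "health_indicator"),
                            region_map = default_region_map()) {
  stopifnot(by %in% c("country", "region", "gender", "marital_status",
                      "age_group", "education_group"))
  m <- match(scores$person_id, records$person_id)
  if (anyNA(m)) stop("scores contain person_id values absent from records")
  rec <- records[m, , drop = FALSE]
  key <- switch(by,
    country = rec$country,
    region = {
      r <- region_map$region[match(rec$country, region_map$country)]
      if (anyNA(r)) {
        stop("country not in region map: ",
             paste(sort(unique(rec$country[is.na(r)])), collapse = ", "))
      }
      r
    },
    gender = rec$gender,
    marital_status = rec$marital_status,
    age_group = age_group(rec$age_years),
    education_group = education_group(rec$education_years))

  lev <- if (by %in% names(.group_order)) {
    intersect(.group_order[[by]], unique(key))
  } else sort(unique(key))

  out <- list()
  for (g in lev) {
    idx <- which(key == g)
    w <- rec$weight[idx]
    for (vc in value_cols) {
      x <- scores[[vc]][idx]
      qs <- wquantile(x, w, c(0.25, 0.5, 0.75))
      iqr <- qs[3] - qs[1]
      lo_fence <- qs[1] - 1.5 * iqr
      hi_fence <- qs[3] + 1.5 * iqr
      inside <- x[x >= lo_fence & x <= hi_fence]
      out[[length(out) + 1L]] <- data.frame(
        group = g, variable = vc,
        n = length(idx), wsum = sum(w),
        mean = wmean(x, w), se_mean = wse(x, w),
        q1 = qs[1], median = qs[2], q3 = qs[3],
        whisker_low = min(inside), whisker_high = max(inside),
        n_outliers = sum(x < lo_fence | x > hi_fence),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  names(res)[1] <- by
  res
}
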