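## Composite vulnerability indicators.
##
## Eight subindicators (four economic binaries, four health counts) built
## by fixed binarization rules, then aggregated and linearly rescaled to
## 0-10 with maximum anchoring: economic = raw * 10/4, health = raw * 10/12.
## 0 means no vulnerability, 10 the maximum the instrument can register.

#' Equivalised household income (OECD-modified scale)
#'
#' Divides total household net income by the OECD-modified equivalence
#' scale: 1 for the household head, 0.5 for each additional member aged 14
#' or over, 0.3 for each child under 14.
#'
#' @param hh_income Household net income, EUR/year.
#' @param n_adults Household members aged >= 14 including the head (>= 1).
#' @param n_children Household members under 14 (>= 0).
#' @return Income per equivalent adult, EUR/year. Vectorised.
#' @examples
#' equivalised_income(18000, 2, 0) # 12000
#' equivalised_income(21000, 2, 2) # 10000
#' @export
equivalised_income <- function(hh_income, n_adults, n_children) {
  if (any(n_adults < 1)) stop("n_adults must be >= 1")
  if (any(n_children < 0)) stop("n_children must be >= 0")
  hh_income / (1 + 0.5 * (n_adults - 1) + 0.3 * n_children)
}

#' Monetary-poverty subindicator
#'
#' 1 iff equivalised income is strictly below the country's
#' at-risk-of-poverty line (60% of national median equivalised income
#' after social transfers); income exactly at the line scores 0.
#'
#' @param records data.frame of respondent records.
#' @param thresholds data.frame `country`/`threshold_eur`.
#' @return Integer 0/1 vector.
#' @export
score_monetary_poverty <- function(records, thresholds) {
  thr <- thresholds$threshold_eur[match(records$country, thresholds$country)]
  if (anyNA(thr)) {
    stop("no poverty threshold for country: ",
         paste(sort(unique(records$country[is.na(thr)])), collapse = ", "))
  }
  eq <- equivalised_income(records$hh_income, records$n_adults,
                           records$n_children)
  as.integer(eq < thr)
}

#' Unemployment subindicator
#'
#' 1 iff current job situation is `unemployed`; retirees and all other
#' situations score 0.
#' @param records data.frame of respondent records.
#' @export
score_unemployment <- function(records) {
  as.integer(records$job_situation == "unemployed")
}

#' Financial-distress subindicator
#'
#' 1 iff the household makes ends meet "with great difficulty" (1) or
#' "with some difficulty" (2) on the 1-4 ordinal.
#' @param records data.frame of respondent records.
#' @export
score_financial_distress <- function(records) {
  as.integer(records$fdistress <= 2)
}

#' Weekly food-consumption subindicator
#'
#' The two 0-4 food-frequency codes (legumes/beans/eggs and
#' meat/fish/poultry) are summed; 1 iff the sum is at most 2.
#' @param records data.frame of respondent records.
#' @export
score_weekly_consumption <- function(records) {
  as.integer(records$legeggs + records$meat <= 2)
}

#' General-health subindicator (0-2)
#'
#' One point for self-perceived health of fair, poor or very poor; one
#' point for two or more chronic diseases.
#' @param records data.frame of respondent records.
#' @export
score_general_health <- function(records) {
  as.integer(records$sphus %in% c("fair", "poor", "very_poor")) +
    as.integer(records$chronic >= 2)
}

#' Mental-health subindicator (0-3)
#'
#' One point each for: EURO-D depression score of 5 or more (the "4 or
#' less is not depressed" cutoff), life satisfaction below 7 on the 0-10
#' scale, and looking back on life with happiness only rarely or never.
#'
#' @param records data.frame of respondent records.
#' @param eurod_cutoff Smallest EURO-D value counted as depressed
#'   (default 5).
#' @export
score_mental_health <- function(records, eurod_cutoff = 5) {
  as.integer(records$eurod >= eurod_cutoff) +
    as.integer(records$lifesat < 7) +
    as.integer(records$lifehap %in% c("rarely", "never"))
}

#' Physical-health subindicator (0-5)
#'
#' One point each for: global activity limitation (GALI), at least one
#' mobility difficulty (0-10 count), at least one ADL limitation, at least
#' one IADL limitation, and a BMI outside the normal band
#' \[18.5, 25) kg/m2 (underweight, overweight or obese).
#' @param records data.frame of respondent records.
#' @export
score_physical_health <- function(records) {
  as.integer(records$gali == "limited") +
    as.integer(records$mobility >= 1) +
    as.integer(records$adl >= 1) +
    as.integer(records$iadl >= 1) +
    as.integer(records$bmi < 18.5 | records$bmi >= 25)
}

#' Health-care subindicator (0-2)
#'
#' One point for an extreme number of doctor contacts in the last year
#' (none at all, or 52+ i.e. weekly on average); one point for at least
#' one hospital night.
#' @param records data.frame of respondent records.
#' @export
score_health_care <- function(records) {
  as.integer(records$doctor_visits == 0 | records$doctor_visits >= 52) +
    as.integer(records$hospital_nights >= 1)
}

#' Build all subindicators and both composite indicators
#'
#' One row per respondent: the eight subindicator values, the raw sums
#' (economic 0-4, health 0-12) and the two rescaled indicators,
#' `economic_indicator = 2.5 * economic_raw` (values 0, 2.5, 5, 7.5, 10)
#' and `health_indicator = (10/12) * health_raw`.
#'
#' @param bundle A [vuln_bundle()] (or a list with `records` and
#'   `thresholds`).
#' @param eurod_cutoff Passed to [score_mental_health()].
#' @return data.frame of per-person scores.
#' @export
build_indicators <- function(bundle, eurod_cutoff = 5) {
  rec <- bundle$records
  thr <- bundle$thresholds
  s <- data.frame(
    person_id = rec$person_id,
    monetary_poverty = score_monetary_poverty(rec, thr),
    unemployment = score_unemployment(rec),
    financial_distress = score_financial_distress(rec),
    weekly_consumption = score_weekly_consumption(rec),
    general_health = score_general_health(rec),
    mental_health = score_mental_health(rec, eurod_cutoff),
    physical_health = score_physical_health(rec),
    health_care = score_health_care(rec),
    stringsAsFactors = FALSE)
  s$economic_raw <- s$monetary_poverty + s$unemployment +
    s$financial_distress + s$weekly_consumption
  s$health_raw <- s$general_health + s$mental_health +
    s$physical_health + s$health_care
  s$economic_indicator <- s$economic_raw * (10 / 4)
  s$health_indicator <- s$health_raw * (10 / 12)
  s
}
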