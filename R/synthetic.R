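## Synthetic survey-microdata generator.
##
## Emulates a cross-national 50+ survey: per-country calibrated
## cross-sectional weights, four regional archetypes with distinct
## subindicator prevalences, and a planted latent-profile structure (four
## vulnerability profiles with characteristic demographics and severity
## levels). Raw variables are synthesised *backwards* from target
## binarized prevalences, so running the indicator module on the output
## recovers the planted parameters up to Monte-Carlo error.

#' Default regional archetypes
#'
#' Four archetypes with per-subindicator prevalence parameters (economic
#' binaries as probabilities; health subindicators as mean counts),
#' country lists, a design median of equivalised income (`income_meanlog`,
#' log EUR/year), an employment rate among the non-unemployed, and the
#' fraction of the employed holding shock-eligible (tourism/retail)
#' occupation codes. The default prevalences reproduce the qualitative
#' regional ordering of European survey data: the eastern archetype
#' dominates the Nordic one on every health subindicator.
#'
#' @return Named list of four archetype lists (`southern`, `eastern`,
#'   `northern`, `scandinavian_ch`), each with fields `name`, `countries`,
#'   `subind_prev`, `income_meanlog`, `employment_rate`,
#'   `tourism_retail_share`.
#' @export
default_archetypes <- function() {
  arch <- function(name, countries, prev, income_meanlog, employment_rate,
                   tourism_retail_share) {
    list(name = name, countries = countries, subind_prev = prev,
         income_meanlog = income_meanlog, employment_rate = employment_rate,
         tourism_retail_share = tourism_retail_share)
  }
  list(
    southern = arch("southern", c("ES", "IT", "PT", "GR"),
      c(unemployment = 0.04, monetary_poverty = 0.22,
        weekly_consumption = 0.01, financial_distress = 0.83,
        general_health = 0.65, mental_health = 1.26,
        health_care = 0.25, physical_health = 1.68),
      income_meanlog = log(15000), employment_rate = 0.22,
      tourism_retail_share = 0.30),
    eastern = arch("eastern", c("PL", "CZ", "HU", "EE", "LV", "RO"),
      c(unemployment = 0.04, monetary_poverty = 0.29,
        weekly_consumption = 0.00, financial_distress = 0.91,
        general_health = 0.85, mental_health = 1.57,
        health_care = 0.33, physical_health = 2.06),
      income_meanlog = log(9000), employment_rate = 0.25,
      tourism_retail_share = 0.15),
    northern = arch("northern", c("DE", "FR", "BE", "AT"),
      c(unemployment = 0.03, monetary_poverty = 0.16,
        weekly_consumption = 0.01, financial_distress = 0.56,
        general_health = 0.67, mental_health = 1.15,
        health_care = 0.23, physical_health = 1.87),
      income_meanlog = log(22000), employment_rate = 0.30,
      tourism_retail_share = 0.12),
    scandinavian_ch = arch("scandinavian_ch", c("DK", "SE", "CH"),
      c(unemployment = 0.01, monetary_poverty = 0.16,
        weekly_consumption = 0.01, financial_distress = 0.37,
        general_health = 0.46, mental_health = 0.89,
        health_care = 0.26, physical_health = 1.49),
      income_meanlog = log(28000), employment_rate = 0.35,
      tourism_retail_share = 0.10)
  )
}

#' Default planted latent-profile specification
#'
#' Four vulnerability profiles ordered from least (1) to most (4)
#' vulnerable. Each profile has a severity multiplier applied to every
#' region's subindicator component probabilities (mixture-mean preserving,
#' so regional prevalences stay at their archetype values), a modal
#' category for each clustering demographic, and a shared concentration:
#' the probability that a respondent shows the modal category of their
#' profile (deviations are uniform over the remaining categories).
#'
#' @param multipliers Severity multipliers, one per profile; must average
#'   to 1 under `mix`.
#' @param mix Profile mixing proportions (sum to 1).
#' @param concentration Probability of the modal demographic category.
#' @return List with `multipliers`, `mix`, `concentration`, `demographics`
#'   (data.frame: one row per profile with modal `gender`,
#'   `marital_status`, `age_group`, `education_group`).
#' @export
default_profiles <- function(multipliers = c(0.30, 0.75, 1.25, 1.70),
                             mix = rep(0.25, 4),
                             concentration = 0.85) {
  demographics <- data.frame(
    profile = 1:4,
    gender = c("female", "male", "male", "female"),
    marital_status = c("with_partner", "with_partner", "with_partner",
                       "single"),
    age_group = c("<60", "60-70", "<60", "70-80"),
    education_group = c(">12", ">12", "10-12", "0-9"),
    stringsAsFactors = FALSE)
  list(multipliers = multipliers, mix = mix,
       concentration = concentration, demographics = demographics)
}

#' Default national target populations (persons aged 50+)
#' @return Named numeric vector, persons per country.
#' @export
default_target_population <- function() {
  c(ES = 16e6, IT = 22e6, PT = 4e6, GR = 4e6,
    PL = 13e6, CZ = 4e6, HU = 3.5e6, EE = 0.5e6, LV = 0.8e6, RO = 7e6,
    DE = 35e6, FR = 25e6, BE = 4e6, AT = 3.3e6,
    DK = 2.2e6, SE = 3.8e6, CH = 3.2e6)
}

#' Assemble and validate a generator configuration
#'
#' @param n_records Number of respondents to draw.
#' @param seed Integer seed; the whole draw is deterministic given it.
#' @param archetypes List of regional archetypes ([default_archetypes()]).
#' @param profiles Latent-profile spec ([default_profiles()]).
#' @param target_population Named vector of per-country population totals;
#'   must cover every archetype country.
#' @param weight_sdlog Log-sd of the pre-calibration lognormal weight draw.
#' @param sentinel_rates Probabilities of the `never_in_school` /
#'   `still_studying` education answers.
#' @return Validated `generator_config` list.
#' @export
generator_config <- function(n_records = 20000L, seed = 1L,
                             archetypes = default_archetypes(),
                             profiles = default_profiles(),
                             target_population = default_target_population(),
                             weight_sdlog = 0.5,
                             sentinel_rates = c(never_in_school = 0.02,
                                                still_studying = 0.005)) {
  stopifnot(n_records >= 1, length(archetypes) >= 1)
  for (a in archetypes) {
    econ <- a$subind_prev[c("unemployment", "monetary_poverty",
                            "weekly_consumption", "financial_distress")]
    if (anyNA(econ) || any(econ < 0 | econ > 1))
      stop("archetype ", a$name,
           ": economic subindicator prevalences must be probabilities in [0,1]")
    hl <- a$subind_prev[c("general_health", "mental_health",
                          "health_care", "physical_health")]
    hmax <- c(general_health = 2, mental_health = 3, health_care = 2,
              physical_health = 5)
    if (anyNA(hl) || any(hl < 0) || any(hl > hmax))
      stop("archetype ", a$name,
           ": health subindicator means must lie in their count ranges")
    if (a$employment_rate < 0 || a$employment_rate > 1)
      stop("archetype ", a$name, ": employment_rate must be in [0,1]")
    if (a$tourism_retail_share < 0 || a$tourism_retail_share > 1)
      stop("archetype ", a$name, ": tourism_retail_share must be in [0,1]")
    if (length(setdiff(a$countries, names(target_population))) > 0)
      stop("archetype ", a$name, ": countries missing from target_population")
  }
  if (abs(sum(profiles$mix) - 1) > 1e-9)
    stop("profile mixing proportions must sum to 1")
  if (abs(sum(profiles$mix * profiles$multipliers) - 1) > 1e-9)
    stop("profile multipliers must average to 1 under the mixing proportions")
  if (profiles$concentration < 0 || profiles$concentration > 1)
    stop("concentration must be in [0,1]")
  structure(list(n_records = as.integer(n_records), seed = as.integer(seed),
                 archetypes = archetypes, profiles = profiles,
                 target_population = target_population,
                 weight_sdlog = weight_sdlog,
                 sentinel_rates = sentinel_rates),
            class = "generator_config")
}

## Mixture-mean-preserving profile probabilities ------------------------------

# Per-profile Bernoulli probabilities with planted marginal q:
# start from q * multiplier, clip at 1, and rescale the unclipped
# profiles so the mixture mean stays exactly q.
.profile_probs <- function(q, mult, mix) {
  if (q <= 0) return(rep(0, length(mult)))
  if (q >= 1) return(rep(1, length(mult)))
  p <- q * mult
  for (i in seq_len(20L)) {
    over <- p >= 1
    if (!any(p > 1)) break
    p[p > 1] <- 1
    free <- p < 1
    target_free <- q - sum(mix[!free])
    cur_free <- sum(mix[free] * p[free])
    if (target_free < 0) stop("infeasible prevalence/multiplier combination")
    if (cur_free > 0) p[free] <- p[free] * target_free / cur_free
  }
  pmin(pmax(p, 0), 1)
}

# Binary components behind each subindicator, their parent subindicator
# and how many components the parent has.
.component_map <- function() {
  data.frame(
    component = c("monetary_poverty", "unemployment", "financial_distress",
                  "weekly_consumption",
                  "c_sphus", "c_chronic",
                  "c_eurod", "c_lifesat", "c_lifehap",
                  "c_gali", "c_mobility", "c_adl", "c_iadl", "c_bmi",
                  "c_doctor", "c_hospital"),
    subindicator = c("monetary_poverty", "unemployment",
                     "financial_distress", "weekly_consumption",
                     rep("general_health", 2), rep("mental_health", 3),
                     rep("physical_health", 5), rep("health_care", 2)),
    n_comp = c(1, 1, 1, 1, 2, 2, 3, 3, 3, 5, 5, 5, 5, 5, 2, 2),
    stringsAsFactors = FALSE)
}

# list: region -> (profiles x components) probability matrix
.component_probs <- function(config) {
  cm <- .component_map()
  pr <- config$profiles
  out <- list()
  for (a in config$archetypes) {
    P <- matrix(0, length(pr$multipliers), nrow(cm),
                dimnames = list(NULL, cm$component))
    for (i in seq_len(nrow(cm))) {
      q <- a$subind_prev[[cm$subindicator[i]]] / cm$n_comp[i]
      P[, i] <- .profile_probs(q, pr$multipliers, pr$mix)
    }
    out[[a$name]] <- P
  }
  out
}

#' Planted moments of the subindicators, by region
#'
#' The exact mean and per-record variance of each subindicator implied by
#' the generator configuration (mixture over profiles of independent
#' component Bernoullis). Used as the Monte-Carlo oracle when checking
#' prevalence recovery through the indicator pipeline.
#'
#' @param config A [generator_config()].
#' @return data.frame with columns `region`, `subindicator`, `mean`,
#'   `var` (variance of one record's subindicator value).
#' @export
planted_moments <- function(config) {
  cp <- .component_probs(config)
  cm <- .component_map()
  mix <- config$profiles$mix
  out <- list()
  for (region in names(cp)) {
    P <- cp[[region]]
    for (s in unique(cm$subindicator)) {
      comp <- cm$component[cm$subindicator == s]
      m_g <- rowSums(P[, comp, drop = FALSE])                 # per-profile mean
      v_g <- rowSums(P[, comp, drop = FALSE] * (1 - P[, comp, drop = FALSE]))
      mu <- sum(mix * m_g)
      v <- sum(mix * v_g) + sum(mix * (m_g - mu)^2)
      out[[length(out) + 1L]] <- data.frame(
        region = region, subindicator = s, mean = mu, var = v,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## Raw-variable synthesis -----------------------------------------------------

# sample one value per row from `values`, with the same probabilities
.vs <- function(n, values, prob = NULL) {
  if (n == 0L) return(values[0])
  values[sample.int(length(values), n, replace = TRUE, prob = prob)]
}

#' Generate a synthetic microdata bundle with planted structure
#'
#' Draws `n_records` respondents: countries in (near-)equal national
#' sample sizes, a latent vulnerability profile per respondent, profile-
#' and region-dependent binary component states, and raw survey variables
#' consistent with those states after binarization. Weights are drawn
#' lognormal and ratio-calibrated so per-country weight sums equal the
#' national target populations exactly. Poverty states are made
#' self-consistent with [generate_thresholds()]: poor incomes sit well
#' below, non-poor well above, 60% of the country's design median.
#'
#' The latent profile of each respondent is returned in a sidecar table,
#' never in the microdata itself.
#'
#' @param config A [generator_config()].
#' @return List with `bundle` (a [vuln_bundle()], thresholds computed from
#'   the generated records) and `true_profiles` (data.frame `person_id`,
#'   `true_profile`).
#' @export
generate_microdata <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_records
  pr <- config$profiles
  arch <- config$archetypes

  countries <- unlist(lapply(arch, `[[`, "countries"))
  region_of <- rep(vapply(arch, `[[`, "", "name"), lengths(lapply(arch, `[[`, "countries")))
  names(region_of) <- countries
  # near-equal national sample sizes, as in multi-country survey designs
  base <- n %/% length(countries)
  extra <- n %% length(countries)
  n_c <- stats::setNames(rep(base, length(countries)), countries)
  if (extra > 0) n_c[seq_len(extra)] <- n_c[seq_len(extra)] + 1L
  if (any(n_c == 0L)) stop("n_records too small to cover every country")
  country <- rep(countries, n_c)
  region <- region_of[country]
  n <- length(country)

  profile <- sample.int(length(pr$mix), n, replace = TRUE, prob = pr$mix)
  cp <- .component_probs(config)
  comp_names <- colnames(cp[[1]])
  region_idx <- match(region, names(cp))
  # component states: Bernoulli with region x profile probability
  B <- matrix(0L, n, length(comp_names), dimnames = list(NULL, comp_names))
  for (cn in comp_names) {
    # stack the per-region probability matrices and index rows in one go
    pm <- vapply(cp, function(P) P[, cn], numeric(length(pr$mix)))
    p <- pm[cbind(profile, region_idx)]
    B[, cn] <- stats::rbinom(n, 1L, p)
  }

  draw_demo <- function(var) {
    modal <- pr$demographics[[var]][profile]
    lev_all <- switch(var,
      gender = c("female", "male"),
      marital_status = c("with_partner", "single"),
      age_group = c("<60", "60-70", "70-80", ">80"),
      education_group = c("0-9", "10-12", ">12"))
    dev <- stats::runif(n) > pr$concentration
    out <- modal
    if (any(dev)) {
      out[dev] <- vapply(modal[dev], function(m) {
        alt <- setdiff(lev_all, m)
        alt[sample.int(length(alt), 1L)]
      }, character(1))
    }
    out
  }
  gender <- draw_demo("gender")
  marital <- draw_demo("marital_status")
  ageband <- draw_demo("age_group")
  eduband <- draw_demo("education_group")

  age_years <- integer(n)
  for (bnd in c("<60", "60-70", "70-80", ">80")) {
    idx <- which(ageband == bnd)
    rng <- switch(bnd, "<60" = 50:59, "60-70" = 60:69,
                  "70-80" = 70:79, ">80" = 80:95)
    age_years[idx] <- .vs(length(idx), rng)
  }

  education_years <- character(n)
  for (bnd in c("0-9", "10-12", ">12")) {
    idx <- which(eduband == bnd)
    rng <- switch(bnd, "0-9" = 1:9, "10-12" = 10:12, ">12" = 13:20)
    education_years[idx] <- as.character(.vs(length(idx), rng))
  }
  u <- stats::runif(n)
  sr <- config$sentinel_rates
  education_years[u < sr[["never_in_school"]]] <- "never_in_school"
  education_years[u >= sr[["never_in_school"]] &
                  u < sum(sr)] <- "still_studying"

  n_adults <- ifelse(marital == "with_partner",
                     ifelse(stats::runif(n) < 0.9, 2L, 3L),
                     ifelse(stats::runif(n) < 0.9, 1L, 2L))
  n_children <- ifelse(stats::runif(n) < 0.95, 0L, 1L)

  # income: anchored so that 0.6 x (weighted median equivalised income)
  # reproduces the design threshold T_c = 0.6 * exp(income_meanlog)
  meanlog_r <- vapply(arch, `[[`, numeric(1), "income_meanlog")
  names(meanlog_r) <- vapply(arch, `[[`, "", "name")
  Tc <- 0.6 * exp(meanlog_r[region])
  pov_r <- vapply(arch, function(a) a$subind_prev[["monetary_poverty"]],
                  numeric(1))
  names(pov_r) <- names(meanlog_r)
  pov_marg <- pov_r[region]
  q_med <- (0.5 - pov_marg) / (1 - pov_marg)   # median's rank among non-poor
  rate <- -log(1 - q_med) / (1 / 0.6 - 1.05)
  equiv <- ifelse(B[, "monetary_poverty"] == 1L,
                  Tc * stats::runif(n, 0.25, 0.90),
                  Tc * (1.05 + stats::rexp(n) / rate))
  scale_oecd <- 1 + 0.5 * (n_adults - 1) + 0.3 * n_children
  hh_income <- equiv * scale_oecd

  emp_r <- vapply(arch, `[[`, numeric(1), "employment_rate")
  names(emp_r) <- names(meanlog_r)
  tour_r <- vapply(arch, `[[`, numeric(1), "tourism_retail_share")
  names(tour_r) <- names(meanlog_r)
  job <- character(n)
  unemp <- B[, "unemployment"] == 1L
  job[unemp] <- "unemployed"
  u_emp <- stats::runif(n)
  emp <- !unemp & u_emp < emp_r[region]
  job[emp] <- "employed"
  rest <- which(!unemp & !emp)
  job[rest] <- .vs(length(rest),
                   c("retired", "homemaker", "sick_disabled", "other"),
                   prob = c(0.80, 0.08, 0.07, 0.05))
  isco <- rep(NA_character_, n)
  emp_idx <- which(emp)
  in_tour <- stats::runif(length(emp_idx)) < tour_r[region[emp_idx]]
  tpfx <- .vs(sum(in_tour), c("51", "52"))
  opfx <- .vs(sum(!in_tour), c("11", "21", "22", "23", "24", "31", "32",
                               "34", "41", "42", "61", "71", "72", "81",
                               "91", "93"))
  sfx <- function(m) sprintf("%02d", .vs(m, 0:99))
  isco[emp_idx[in_tour]] <- paste0(tpfx, sfx(sum(in_tour)))
  isco[emp_idx[!in_tour]] <- paste0(opfx, sfx(sum(!in_tour)))

  fd1 <- B[, "financial_distress"] == 1L
  fdistress <- integer(n)
  fdistress[fd1] <- .vs(sum(fd1), 1:2, prob = c(0.45, 0.55))
  fdistress[!fd1] <- .vs(sum(!fd1), 3:4, prob = c(0.55, 0.45))

  wc1 <- B[, "weekly_consumption"] == 1L
  lowpairs <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1, 0, 2, 2, 0), ncol = 2,
                     byrow = TRUE)
  hipairs <- matrix(c(1, 2, 2, 1, 2, 2, 3, 2, 2, 3, 3, 3, 4, 3, 3, 4, 4, 4,
                      1, 4, 4, 1), ncol = 2, byrow = TRUE)
  li <- .vs(sum(wc1), seq_len(nrow(lowpairs)))
  hi <- .vs(sum(!wc1), seq_len(nrow(hipairs)),
            prob = c(1, 1, 2, 3, 3, 3, 4, 4, 4, 1, 1))
  legeggs <- integer(n); meat <- integer(n)
  legeggs[wc1] <- lowpairs[li, 1]; meat[wc1] <- lowpairs[li, 2]
  legeggs[!wc1] <- hipairs[hi, 1]; meat[!wc1] <- hipairs[hi, 2]

  sp1 <- B[, "c_sphus"] == 1L
  sphus <- character(n)
  sphus[sp1] <- .vs(sum(sp1), c("fair", "poor", "very_poor"),
                    prob = c(0.60, 0.30, 0.10))
  sphus[!sp1] <- .vs(sum(!sp1), c("excellent", "good"), prob = c(0.35, 0.65))

  ch1 <- B[, "c_chronic"] == 1L
  chronic <- integer(n)
  chronic[ch1] <- .vs(sum(ch1), 2:6, prob = c(0.40, 0.28, 0.17, 0.10, 0.05))
  chronic[!ch1] <- .vs(sum(!ch1), 0:1, prob = c(0.55, 0.45))

  eu1 <- B[, "c_eurod"] == 1L
  eurod <- integer(n)
  eurod[eu1] <- .vs(sum(eu1), 5:12, prob = c(8:1))
  eurod[!eu1] <- .vs(sum(!eu1), 0:4, prob = c(5, 4, 3, 2, 1))

  ls1 <- B[, "c_lifesat"] == 1L
  lifesat <- integer(n)
  lifesat[ls1] <- .vs(sum(ls1), 0:6, prob = c(1, 1, 2, 3, 4, 5, 6))
  lifesat[!ls1] <- .vs(sum(!ls1), 7:10, prob = c(4, 3, 2, 1))

  lh1 <- B[, "c_lifehap"] == 1L
  lifehap <- character(n)
  lifehap[lh1] <- .vs(sum(lh1), c("rarely", "never"), prob = c(0.7, 0.3))
  lifehap[!lh1] <- .vs(sum(!lh1), c("often", "sometimes"), prob = c(0.6, 0.4))

  gali <- ifelse(B[, "c_gali"] == 1L, "limited", "not_limited")
  mb1 <- B[, "c_mobility"] == 1L
  mobility <- integer(n)
  mobility[mb1] <- .vs(sum(mb1), 1:10, prob = 10:1)
  ad1 <- B[, "c_adl"] == 1L
  adl <- integer(n)
  adl[ad1] <- .vs(sum(ad1), 1:6, prob = 6:1)
  ia1 <- B[, "c_iadl"] == 1L
  iadl <- integer(n)
  iadl[ia1] <- .vs(sum(ia1), 1:9, prob = 9:1)

  bm1 <- B[, "c_bmi"] == 1L
  bmi <- numeric(n)
  under <- bm1 & stats::runif(n) < 0.15
  bmi[bm1 & !under] <- stats::runif(sum(bm1 & !under), 25.0, 38.0)
  bmi[under] <- stats::runif(sum(under), 15.0, 18.4)
  bmi[!bm1] <- stats::runif(sum(!bm1), 18.6, 24.8)
  bmi <- round(bmi, 1)

  dv1 <- B[, "c_doctor"] == 1L
  doctor_visits <- integer(n)
  none <- dv1 & stats::runif(n) < 0.7
  doctor_visits[none] <- 0L
  doctor_visits[dv1 & !none] <- .vs(sum(dv1 & !none), 52:80)
  doctor_visits[!dv1] <- .vs(sum(!dv1), 1:12, prob = 12:1)

  hn1 <- B[, "c_hospital"] == 1L
  hospital_nights <- integer(n)
  hospital_nights[hn1] <- .vs(sum(hn1), 1:15, prob = 15:1)

  # calibrated cross-sectional weights: lognormal draw, ratio-calibrated
  # per country so weight sums equal the national target populations
  weight <- stats::rlnorm(n, meanlog = 0, sdlog = config$weight_sdlog)
  for (cc in countries) {
    idx <- which(country == cc)
    weight[idx] <- weight[idx] *
      (config$target_population[[cc]] / sum(weight[idx]))
  }

  records <- data.frame(
    person_id = sprintf("P%06d", seq_len(n)),
    country = country, weight = weight, gender = gender,
    age_years = age_years, marital_status = marital,
    education_years = education_years, hh_income = hh_income,
    n_adults = as.integer(n_adults), n_children = as.integer(n_children),
    job_situation = job, isco = isco, fdistress = fdistress,
    legeggs = legeggs, meat = meat, sphus = sphus, chronic = chronic,
    eurod = eurod, lifesat = lifesat, lifehap = lifehap, gali = gali,
    mobility = mobility, adl = adl, iadl = iadl, bmi = bmi,
    doctor_visits = doctor_visits, hospital_nights = hospital_nights,
    stringsAsFactors = FALSE)

  thresholds <- generate_thresholds(records)
  bundle <- vuln_bundle(records, thresholds,
                        provenance = paste0("synthetic:seed=", config$seed))
  true_profiles <- data.frame(person_id = records$person_id,
                              true_profile = profile,
                              stringsAsFactors = FALSE)
  list(bundle = bundle, true_profiles = true_profiles)
}

#' Compute per-country poverty thresholds from generated records
#'
#' The at-risk-of-poverty line of each country: 60% of the weighted median
#' (left-continuous rule) of equivalised income among that country's
#' records. Doubling every income doubles every threshold.
#'
#' @param records data.frame of respondent records (or a [vuln_bundle()]).
#' @return data.frame `country`, `threshold_eur`.
#' @export
generate_thresholds <- function(records) {
  if (inherits(records, "vuln_bundle")) records <- records$records
  eq <- equivalised_income(records$hh_income, records$n_adults,
                           records$n_children)
  out <- lapply(sort(unique(records$country)), function(cc) {
    idx <- which(records$country == cc)
    if (sum(records$weight[idx]) <= 0)
      stop("country ", cc, " has zero total weight")
    data.frame(country = cc,
               threshold_eur = 0.6 * wmedian(eq[idx], records$weight[idx]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
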