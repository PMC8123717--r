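## Deterministic pandemic shock cascade.
##
## A rule system that edits raw survey variables to emulate the joint
## health and labour-market impact of a COVID-19-style pandemic. The
## cascade is defined sequentially (chronic disease -> job loss and worse
## self-perceived health -> sector job losses -> financial distress and
## food consumption -> mental health) but eligibility is always evaluated
## on the pre-shock snapshot and all edits materialize simultaneously.
## No rule ever decreases a vulnerability subindicator.

#' Shock configuration
#'
#' @param chronic_trigger_min Minimum chronic-disease count that triggers
#'   the chronic rule (default 1; deliberately decoupled from the
#'   indicator's >= 2 vulnerability threshold).
#' @param shock_isco_prefixes Occupation-code prefixes defining the
#'   shock-exposed sectors; default `c("51", "52")` (personal/protective
#'   services and sales occupations — tourism and retail).
#' @param apply_to_employed_only If `TRUE` (default) job-loss rules only
#'   hit the currently employed; retirees cannot lose a job.
#' @return A `shock_config` list.
#' @export
shock_config <- function(chronic_trigger_min = 1L,
                         shock_isco_prefixes = c("51", "52"),
                         apply_to_employed_only = TRUE) {
  stopifnot(chronic_trigger_min >= 1, length(shock_isco_prefixes) >= 1)
  structure(list(chronic_trigger_min = as.integer(chronic_trigger_min),
                 shock_isco_prefixes = as.character(shock_isco_prefixes),
                 apply_to_employed_only = isTRUE(apply_to_employed_only)),
            class = "shock_config")
}

.sphus_rank <- c(excellent = 1, good = 2, fair = 3, poor = 4, very_poor = 5)

#' Apply the pandemic shock cascade to a dataset
#'
#' Rules (eligibility on the pre-shock state; edits simultaneous):
#' \describe{
#' \item{R1_chronic_job_loss}{chronic count at or above the trigger and
#'   employed (per config): job situation becomes `unemployed`.}
#' \item{R1_chronic_sphus}{chronic trigger: self-perceived health worsens
#'   to at least `fair` (already fair/poor/very poor is left unchanged).}
#' \item{R2_sector_job_loss}{employed with an occupation code in a
#'   shock-exposed sector: job situation becomes `unemployed`. A missing
#'   occupation code simply never matches.}
#' \item{R3_new_distress}{newly unemployed (by R1/R2) who previously made
#'   ends meet fairly easily or easily: `fdistress` becomes 2.}
#' \item{R3_new_consumption}{newly unemployed whose weekly-consumption
#'   subindicator was 0: food-frequency codes become (1, 1), flipping the
#'   binary to 1.}
#' \item{R4_unemployment_mental}{newly unemployed who, after R3, are in
#'   financial distress and consumption-vulnerable: `lifehap` becomes
#'   `never`, `eurod` rises to at least 5, `lifesat` falls to at most 6.}
#' \item{R4_chronic_mental}{chronic-trigger respondents whose
#'   self-perceived health was actually worsened by R1: the same three
#'   mental-health edits.}
#' }
#'
#' The shock is idempotent: applying it to its own output changes nothing.
#'
#' @param bundle A [vuln_bundle()].
#' @param config A [shock_config()].
#' @return List with `bundle` (shocked copy) and `audit` (class
#'   `shock_audit`): one entry per affected person with `person_id`,
#'   `fired_rules` and field-level `pre`/`post` diffs.
#' @export
apply_shock <- function(bundle, config = shock_config()) {
  stopifnot(inherits(bundle, "vuln_bundle"))
  pre <- bundle$records
  post <- pre
  n <- nrow(pre)

  employed <- pre$job_situation == "employed"
  chronic_trig <- pre$chronic >= config$chronic_trigger_min
  isco_pfx <- substr(ifelse(is.na(pre$isco), "", pre$isco), 1, 2)
  in_sector <- isco_pfx %in% config$shock_isco_prefixes

  r1_job <- chronic_trig & pre$job_situation != "unemployed" &
    (if (config$apply_to_employed_only) employed else rep(TRUE, n))
  r2_job <- employed & in_sector
  newly_unemployed <- (r1_job | r2_job) & pre$job_situation != "unemployed"
  post$job_situation[newly_unemployed] <- "unemployed"

  r1_sphus <- chronic_trig & .sphus_rank[pre$sphus] < .sphus_rank[["fair"]]
  post$sphus[r1_sphus] <- "fair"

  r3_dist <- newly_unemployed & pre$fdistress >= 3
  post$fdistress[r3_dist] <- 2L
  pre_cons0 <- (pre$legeggs + pre$meat) > 2
  r3_cons <- newly_unemployed & pre_cons0
  post$legeggs[r3_cons] <- 1L
  post$meat[r3_cons] <- 1L

  post_distress1 <- post$fdistress <= 2
  post_cons1 <- (post$legeggs + post$meat) <= 2
  r4a <- newly_unemployed & post_distress1 & post_cons1
  r4b <- chronic_trig & r1_sphus
  r4 <- r4a | r4b
  mh_lifehap <- r4 & pre$lifehap != "never"
  mh_eurod <- r4 & pre$eurod < 5
  mh_lifesat <- r4 & pre$lifesat > 6
  post$lifehap[mh_lifehap] <- "never"
  post$eurod[mh_eurod] <- 5L
  post$lifesat[mh_lifesat] <- 6L

  rule_mat <- cbind(
    R1_chronic_job_loss = r1_job & newly_unemployed,
    R1_chronic_sphus = r1_sphus,
    R2_sector_job_loss = r2_job & newly_unemployed,
    R3_new_distress = r3_dist,
    R3_new_consumption = r3_cons,
    R4_unemployment_mental = r4a,
    R4_chronic_mental = r4b)

  affected <- which(rowSums(rule_mat) > 0)
  fields <- c("job_situation", "sphus", "fdistress", "legeggs", "meat",
              "lifehap", "eurod", "lifesat")
  audit <- lapply(affected, function(i) {
    diffs <- list()
    for (f in fields) {
      if (!identical(pre[[f]][i], post[[f]][i])) {
        diffs[[f]] <- list(pre = pre[[f]][i], post = post[[f]][i])
      }
    }
    list(person_id = pre$person_id[i],
         fired_rules = colnames(rule_mat)[rule_mat[i, ]],
         changes = diffs)
  })
  shocked <- vuln_bundle(post, bundle$thresholds,
                         provenance = paste0(bundle$provenance, "+shock"))
  list(bundle = shocked, audit = structure(audit, class = "shock_audit"))
}

#' @export
print.shock_audit <- function(x, ...) {
  cat("<shock_audit>", length(x), "affected respondent(s)\n")
  if (length(x) > 0) {
    rules <- table(unlist(lapply(x, `[[`, "fired_rules")))
    for (r in names(rules)) cat(sprintf("  %-24s %d\n", r, rules[[r]]))
  }
  invisible(x)
}

#' Compare pre- and post-shock indicators by group
#'
#' Per group: weighted pre mean, post mean, absolute delta and relative
#' growth in percent. Asserts the shock contract that no individual score
#' decreased.
#'
#' @param pre_scores,post_scores Score tables from [build_indicators()],
#'   aligned on `person_id`.
#' @param records Respondent records supplying weights and grouping
#'   fields (pre-shock demographics).
#' @param by Grouping variable as in [group_summaries()].
#' @param value_cols Score columns to compare.
#' @param region_map Used when `by = "region"`.
#' @return data.frame: group, variable, `pre_mean`, `post_mean`, `delta`,
#'   `growth_pct` (100 * delta / pre_mean; `NA` when the pre mean is 0).
#' @export
shock_report <- function(pre_scores, post_scores, records, by = "country",
                         value_cols = c("economic_indicator",
                                        "health_indicator"),
                         region_map = default_region_map()) {
  if (!identical(pre_scores$person_id, post_scores$person_id))
    stop("pre and post score tables are not aligned on person_id")
  for (vc in value_cols) {
    if (any(post_scores[[vc]] < pre_scores[[vc]] - 1e-12))
      stop("post-shock ", vc, " decreased for at least one person; ",
           "shock contract violated")
  }
  pre_s <- group_summaries(pre_scores, records, by, value_cols, region_map)
  post_s <- group_summaries(post_scores, records, by, value_cols, region_map)
  out <- data.frame(group = pre_s[[by]], variable = pre_s$variable,
                    pre_mean = pre_s$mean, post_mean = post_s$mean,
                    stringsAsFactors = FALSE)
  out$delta <- out$post_mean - out$pre_mean
  out$growth_pct <- ifelse(out$pre_mean > 0,
                           100 * out$delta / out$pre_mean, NA_real_)
  names(out)[1] <- by
  out
}
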