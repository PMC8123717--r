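## Profile ordering, population shares and pipeline orchestration.

#' Order clusters into vulnerability profiles
#'
#' Clusters are ranked from least (1) to most (k) vulnerable by the sum
#' of the within-cluster weighted mean economic and health indicators;
#' ties break by the economic mean, then by cluster id.
#'
#' @param model A fitted `kproto_model`.
#' @param scores Score table aligned with the model's training records
#'   (matched on `person_id`).
#' @param weights Record weights in model order (default: the model's).
#' @return data.frame with one row per cluster: `cluster`,
#'   `economic_mean`, `health_mean`, `ordering_key`, `profile_rank`.
#' @export
rank_profiles <- function(model, scores, weights = model$weights) {
  m <- match(model$person_id, scores$person_id)
  if (anyNA(m)) stop("scores are missing person_id values from the model")
  econ <- scores$economic_indicator[m]
  hlth <- scores$health_indicator[m]
  out <- do.call(rbind, lapply(seq_len(model$k), function(j) {
    idx <- which(model$assignments == j)
    data.frame(cluster = j,
               economic_mean = wmean(econ[idx], weights[idx]),
               health_mean = wmean(hlth[idx], weights[idx]),
               stringsAsFactors = FALSE)
  }))
  out$ordering_key <- out$economic_mean + out$health_mean
  o <- order(out$ordering_key, out$economic_mean, out$cluster)
  out$profile_rank <- NA_integer_
  out$profile_rank[o] <- seq_len(model$k)
  out
}

#' Weighted population share of each profile, by country
#'
#' `share(country, rank) = sum of weights assigned to that profile /
#' total country weight`; shares over profiles sum to 1 per country.
#' Countries absent from `records` are omitted, never zero-filled.
#'
#' @param assignments Integer cluster ids, aligned with `records` rows.
#' @param profile_map Output of [rank_profiles()] (or any data.frame with
#'   `cluster` and `profile_rank`).
#' @param records Respondent records (`country`, `weight`).
#' @param scenario Label stored in the output (`"pre"` or `"post"`).
#' @return data.frame `country`, `profile_rank`, `share`, `scenario`.
#' @export
profile_shares <- function(assignments, profile_map, records,
                           scenario = "pre") {
  stopifnot(length(assignments) == nrow(records))
  rank_of <- profile_map$profile_rank[match(assignments,
                                            profile_map$cluster)]
  if (anyNA(rank_of)) stop("assignment refers to a cluster not in profile_map")
  ranks <- sort(unique(profile_map$profile_rank))
  out <- list()
  for (cc in sort(unique(records$country))) {
    idx <- which(records$country == cc)
    tot <- sum(records$weight[idx])
    for (r in ranks) {
      out[[length(out) + 1L]] <- data.frame(
        country = cc, profile_rank = r,
        share = sum(records$weight[idx][rank_of[idx] == r]) / tot,
        scenario = scenario, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# clustering frame: the two indicators plus the four demographic groups
.cluster_frame <- function(records, scores) {
  m <- match(records$person_id, scores$person_id)
  if (anyNA(m)) stop("scores are missing person_id values from records")
  data.frame(
    economic_indicator = scores$economic_indicator[m],
    health_indicator = scores$health_indicator[m],
    gender = records$gender,
    marital_status = records$marital_status,
    age_group = age_group(records$age_years),
    education_group = education_group(records$education_years),
    stringsAsFactors = FALSE)
}

#' Run the full vulnerability-profiling pipeline
#'
#' Orchestrates: data (synthetic generation or file input) -> indicator
#' construction -> weighted k-prototypes clustering (fixed k or elbow
#' scan) -> profile ranking -> population shares -> optional pandemic
#' shock -> post-shock re-scoring and profile prediction against the
#' pre-shock model -> demographic summary tables. All artifacts are
#' written under `out_dir` and listed, with their MD5 hashes, every seed
#' and every parameter, in `manifest.json`; rerunning the same config
#' reproduces every artifact byte for byte.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   \describe{
#'   \item{data}{either `list(source = "synthetic", n_records, seed)` or
#'     `list(source = "file", microdata, thresholds)`.}
#'   \item{cluster}{`list(k = 4)` or `list(scan = c(2, 8))`, plus optional
#'     `lambda` (number or `"auto"`), `restarts`, `seed`, `max_iter`.}
#'   \item{shock}{optional: arguments for [shock_config()]; omit for a
#'     pre-only run.}
#'   \item{out_dir}{output directory.}
#'   }
#' @return The manifest, invisibly (list of parameters and artifact
#'   hashes).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(name) {
    artifacts <<- c(artifacts, name)
    file.path(out_dir, name)
  }
  stage <- "data"
  res <- tryCatch({
    dcfg <- config$data
    true_profiles <- NULL
    if (identical(dcfg$source, "synthetic")) {
      gcfg <- generator_config(
        n_records = dcfg$n_records %||% 20000L,
        seed = dcfg$seed %||% 1L)
      gen <- generate_microdata(gcfg)
      bundle <- gen$bundle
      true_profiles <- gen$true_profiles
      write_microdata(bundle, emit("microdata.csv"))
      write_table(bundle$thresholds, emit("thresholds.csv"))
      write_table(true_profiles, emit("true_profiles.csv"))
    } else if (identical(dcfg$source, "file")) {
      bundle <- read_microdata(dcfg$microdata, dcfg$thresholds)
    } else stop("config$data$source must be 'synthetic' or 'file'")

    stage <- "indicators"
    scores_pre <- build_indicators(bundle)
    write_table(scores_pre, emit("scores_pre.csv"))

    stage <- "cluster"
    ccfg <- config$cluster %||% list()
    cl_seed <- ccfg$seed %||% (dcfg$seed %||% 1L)
    restarts <- ccfg$restarts %||% 10L
    max_iter <- ccfg$max_iter %||% 100L
    lambda <- ccfg$lambda
    if (is.null(lambda) || identical(lambda, "auto")) lambda <- NULL
    frame <- .cluster_frame(bundle$records, scores_pre)
    if (!is.null(ccfg$scan)) {
      scan <- elbow_scan(frame, seq(ccfg$scan[[1]], ccfg$scan[[2]]),
                         lambda = lambda, weights = bundle$records$weight,
                         seed = cl_seed, max_iter = max_iter,
                         n_restarts = restarts)
      write_table(data.frame(k = scan$k_range, cost = scan$costs),
                  emit("elbow.csv"))
      k_use <- ccfg$k %||% scan$suggested_k
      model <- scan$models[[match(k_use, scan$k_range)]]
    } else {
      k_use <- ccfg$k %||% 4L
      model <- kproto_fit(frame, k_use, lambda = lambda,
                          weights = bundle$records$weight, seed = cl_seed,
                          max_iter = max_iter, n_restarts = restarts,
                          person_id = bundle$records$person_id)
    }
    write_model(model, emit("model.json"))

    stage <- "profiles"
    pmap <- rank_profiles(model, scores_pre,
                          weights = bundle$records$weight)
    jsonlite::write_json(pmap, emit("profile_map.json"), digits = NA)
    shares_pre <- profile_shares(model$assignments, pmap, bundle$records,
                                 scenario = "pre")
    write_table(shares_pre, emit("shares_pre.csv"))

    stage <- "summaries"
    for (by in c("gender", "marital_status", "age_group",
                 "education_group", "country", "region")) {
      write_table(group_summaries(scores_pre, bundle$records, by),
                  emit(paste0("summary_by_", by, ".csv")))
    }

    post <- NULL
    if (!is.null(config$shock)) {
      stage <- "shock"
      scfg <- do.call(shock_config, config$shock[
        intersect(names(config$shock),
                  c("chronic_trigger_min", "shock_isco_prefixes",
                    "apply_to_employed_only"))])
      sh <- apply_shock(bundle, scfg)
      write_microdata(sh$bundle, emit("shocked.csv"))
      write_audit(sh$audit, emit("audit.json"))
      scores_post <- build_indicators(sh$bundle)
      write_table(scores_post, emit("scores_post.csv"))
      post_assign <- predict(model, .cluster_frame(sh$bundle$records,
                                                   scores_post))
      shares_post <- profile_shares(post_assign, pmap, sh$bundle$records,
                                    scenario = "post")
      write_table(shares_post, emit("shares_post.csv"))
      write_table(shock_report(scores_pre, scores_post, bundle$records,
                               by = "country"),
                  emit("shock_report_by_country.csv"))
      post <- list(scores = scores_post, shares = shares_post)
    }

    list(bundle = bundle, scores_pre = scores_pre, model = model,
         profile_map = pmap, shares_pre = shares_pre, post = post,
         true_profiles = true_profiles)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  # artifact paths are relative to the manifest's own directory, so the
  # output location is not part of the recorded configuration: identical
  # configs give byte-identical manifests wherever they are written
  cfg_rec <- config
  cfg_rec$out_dir <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("vulnprofiles")),
    config = cfg_rec,
    artifacts = lapply(stats::setNames(artifacts, artifacts), function(a) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, a))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
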