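fake_model <- function(assignments, k = max(assignments),
                       weights = rep(1, length(assignments))) {
  structure(list(k = as.integer(k), assignments = as.integer(assignments),
                 person_id = sprintf("P%d", seq_along(assignments)),
                 weights = weights),
            class = "kproto_model")
}

test_that("clusters are ranked by combined indicator severity", {
  # cluster ordering keys (2, 5, 9, 7) -> ranks (1, 2, 4, 3)
  m <- fake_model(1:4)
  scores <- data.frame(person_id = sprintf("P%d", 1:4),
                       economic_indicator = c(1, 2, 4, 3),
                       health_indicator = c(1, 3, 5, 4))
  pm <- rank_profiles(m, scores)
  expect_equal(pm$ordering_key, c(2, 5, 9, 7))
  expect_equal(pm$profile_rank, c(1, 2, 4, 3))
  # k = 1 trivially gets rank 1
  m1 <- fake_model(rep(1, 3), k = 1)
  s1 <- data.frame(person_id = sprintf("P%d", 1:3),
                   economic_indicator = 1:3, health_indicator = 1:3)
  expect_equal(rank_profiles(m1, s1)$profile_rank, 1L)
  # ties on the key break by the economic mean
  mt <- fake_model(1:2)
  st <- data.frame(person_id = c("P1", "P2"),
                   economic_indicator = c(3, 1),
                   health_indicator = c(1, 3))
  pt <- rank_profiles(mt, st)
  expect_equal(pt$profile_rank, c(2L, 1L))
})

test_that("profile shares are weighted shares summing to one per country", {
  rec <- make_records(
    make_record(country = "ES", weight = 100),
    make_record(country = "ES", weight = 100),
    make_record(country = "DE", weight = 70))
  pm <- data.frame(cluster = 1:2, profile_rank = c(2L, 1L))
  sh <- profile_shares(c(1L, 2L, 1L), pm, rec, scenario = "pre")
  es <- sh[sh$country == "ES", ]
  expect_equal(es$share[es$profile_rank == 1], 0.5)
  expect_equal(es$share[es$profile_rank == 2], 0.5)
  de <- sh[sh$country == "DE", ]
  expect_equal(de$share[de$profile_rank == 2], 1)
  agg <- tapply(sh$share, sh$country, sum)
  expect_equal(as.numeric(agg), rep(1, 2), tolerance = 1e-9)
  # integer-weight toy equals expansion counting
  rec5 <- make_records(
    make_record(country = "ES", weight = 3), make_record(country = "ES", weight = 1),
    make_record(country = "ES", weight = 1), make_record(country = "ES", weight = 2),
    make_record(country = "ES", weight = 3))
  asg <- c(1L, 2L, 1L, 2L, 1L)
  sh5 <- profile_shares(asg, pm, rec5)
  counts <- tapply(rec5$weight, asg, sum)  # expanded persons per cluster
  expect_equal(sh5$share[sh5$profile_rank == 2], counts[["1"]] / 10)
  expect_equal(sh5$share[sh5$profile_rank == 1], counts[["2"]] / 10)
})

test_that("planted severity order is recovered end to end", {
  g <- generate_microdata(generator_config(n_records = 3000, seed = 23))
  b <- g$bundle
  s <- build_indicators(b)
  frame <- data.frame(
    economic_indicator = s$economic_indicator,
    health_indicator = s$health_indicator,
    gender = b$records$gender,
    marital_status = b$records$marital_status,
    age_group = age_group(b$records$age_years),
    education_group = education_group(b$records$education_years),
    stringsAsFactors = FALSE)
  m <- kproto_fit(frame, 4, weights = b$records$weight, seed = 23,
                  n_restarts = 5, person_id = b$records$person_id)
  pm <- rank_profiles(m, s, b$records$weight)
  # the modal true profile within each cluster ascends with the rank
  modal <- sapply(seq_len(4), function(j) {
    tp <- g$true_profiles$true_profile[m$assignments == j]
    as.integer(names(which.max(table(tp))))
  })
  expect_equal(modal[order(pm$profile_rank)], 1:4)
  # predicting the training data reproduces the fitted assignments
  expect_equal(predict(m, frame), m$assignments)
})

test_that("the pipeline runs end to end, writes artifacts and reproduces itself", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- list(data = list(source = "synthetic", n_records = 800, seed = 29),
              cluster = list(k = 4, restarts = 3),
              shock = list(),
              out_dir = out1)
  res <- run_pipeline(cfg)
  expected <- c("microdata.csv", "thresholds.csv", "true_profiles.csv",
                "scores_pre.csv", "model.json", "profile_map.json",
                "shares_pre.csv", "shocked.csv", "audit.json",
                "scores_post.csv", "shares_post.csv",
                "shock_report_by_country.csv", "manifest.json")
  expect_true(all(file.exists(file.path(out1, expected))))
  cfg$out_dir <- out2
  run_pipeline(cfg)
  f <- sort(list.files(out1))
  h1 <- tools::md5sum(file.path(out1, f))
  h2 <- tools::md5sum(file.path(out2, f))
  expect_true(all(unname(h1) == unname(h2)))
  # post-shock: the top profile's share never decreases in any country
  top <- max(res$shares_pre$profile_rank)
  pre <- res$shares_pre[res$shares_pre$profile_rank == top, ]
  post <- res$post$shares[res$post$shares$profile_rank == top, ]
  expect_equal(pre$country, post$country)
  expect_true(all(post$share >= pre$share - 1e-12))
})

test_that("a config without a shock section yields pre-only artifacts", {
  out <- withr::local_tempdir()
  cfg <- list(data = list(source = "synthetic", n_records = 300, seed = 31),
              cluster = list(k = 3, restarts = 2),
              out_dir = out)
  run_pipeline(cfg)
  expect_true(file.exists(file.path(out, "shares_pre.csv")))
  expect_false(file.exists(file.path(out, "shocked.csv")))
  expect_false(file.exists(file.path(out, "scores_post.csv")))
})

test_that("a stage failure names the stage", {
  out <- withr::local_tempdir()
  cfg <- list(data = list(source = "file", microdata = "does-not-exist.csv",
                          thresholds = "nope.csv"),
              out_dir = out)
  expect_error(run_pipeline(cfg), "stage 'data'")
})
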