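test_that("a retiree without chronic disease is untouched", {
  b <- vuln_bundle(make_record(job_situation = "retired", chronic = 0L),
                   toy_thresholds())
  sh <- apply_shock(b)
  expect_identical(sh$bundle$records, b$records)
  expect_length(sh$audit, 0)
})

test_that("hand-traced cascade: employed cook loses job, then distress, food and mental health", {
  cook <- make_record(job_situation = "employed", isco = "5122",
                      chronic = 0L, fdistress = 4L, legeggs = 3L, meat = 3L,
                      lifesat = 9L, eurod = 1L, lifehap = "often")
  b <- vuln_bundle(cook, toy_thresholds())
  sh <- apply_shock(b)
  post <- sh$bundle$records
  expect_equal(post$job_situation, "unemployed")
  expect_equal(post$fdistress, 2L)
  expect_equal(post$legeggs, 1L)
  expect_equal(post$meat, 1L)
  expect_equal(post$lifehap, "never")
  expect_equal(post$eurod, 5L)
  expect_equal(post$lifesat, 6L)
  s0 <- build_indicators(b)
  s1 <- build_indicators(sh$bundle)
  expect_equal(s0$economic_raw, 0L)
  expect_equal(s1$economic_raw, 3L)
  expect_setequal(sh$audit[[1]]$fired_rules,
                  c("R2_sector_job_loss", "R3_new_distress",
                    "R3_new_consumption", "R4_unemployment_mental"))
})

test_that("hand-traced cascade: chronic employed person loses job, health worsens, mental edits follow", {
  p <- make_record(job_situation = "employed", isco = "2211",
                   chronic = 3L, sphus = "good", fdistress = 4L,
                   legeggs = 4L, meat = 4L, lifesat = 9L, eurod = 1L,
                   lifehap = "often")
  b <- vuln_bundle(p, toy_thresholds())
  sh <- apply_shock(b)
  post <- sh$bundle$records
  expect_equal(post$job_situation, "unemployed")
  expect_equal(post$sphus, "fair")
  expect_equal(post$lifehap, "never")
  expect_equal(post$eurod, 5L)
  expect_equal(post$lifesat, 6L)
  expect_setequal(sh$audit[[1]]$fired_rules,
                  c("R1_chronic_job_loss", "R1_chronic_sphus",
                    "R3_new_distress", "R3_new_consumption",
                    "R4_chronic_mental", "R4_unemployment_mental"))
})

test_that("already-vulnerable self-perceived health is left unchanged", {
  p <- make_record(job_situation = "retired", chronic = 2L, sphus = "poor")
  sh <- apply_shock(vuln_bundle(p, toy_thresholds()))
  expect_equal(sh$bundle$records$sphus, "poor")
  # no sphus worsening, so the chronic mental rule does not fire
  expect_false("R4_chronic_mental" %in%
                 unlist(lapply(sh$audit, `[[`, "fired_rules")))
})

test_that("job-loss rules can be opened to the non-employed by config", {
  p <- make_record(job_situation = "retired", chronic = 2L, sphus = "poor")
  b <- vuln_bundle(p, toy_thresholds())
  sh <- apply_shock(b, shock_config(apply_to_employed_only = FALSE))
  expect_equal(sh$bundle$records$job_situation, "unemployed")
  sh2 <- apply_shock(b)
  expect_equal(sh2$bundle$records$job_situation, "retired")
})

test_that("the shock never decreases a score and is idempotent", {
  g <- generate_microdata(generator_config(n_records = 2000, seed = 13))
  b <- g$bundle
  sh <- apply_shock(b)
  s0 <- build_indicators(b)
  s1 <- build_indicators(sh$bundle)
  expect_true(all(s1$economic_raw >= s0$economic_raw))
  expect_true(all(s1$health_raw >= s0$health_raw))
  sh2 <- apply_shock(sh$bundle)
  expect_identical(sh2$bundle$records, sh$bundle$records)
  expect_length(sh2$audit, 0)
})

test_that("audit diffs reconstruct exactly the record changes", {
  g <- generate_microdata(generator_config(n_records = 1000, seed = 17))
  b <- g$bundle
  sh <- apply_shock(b)
  pre <- b$records; post <- sh$bundle$records
  changed <- which(!vapply(seq_len(nrow(pre)), function(i)
    identical(pre[i, ], post[i, ]), logical(1)))
  audited <- match(vapply(sh$audit, `[[`, "", "person_id"), pre$person_id)
  # every changed record is audited (audits may also log rule firings
  # whose edits were already in place)
  expect_true(all(changed %in% audited))
  for (a in sh$audit) {
    i <- match(a$person_id, pre$person_id)
    for (f in names(a$changes)) {
      expect_identical(a$changes[[f]]$pre, pre[[f]][i])
      expect_identical(a$changes[[f]]$post, post[[f]][i])
    }
    # reconstruct the record from pre + diffs
    rebuilt <- pre[i, ]
    for (f in names(a$changes)) rebuilt[[f]] <- a$changes[[f]]$post
    expect_identical(rebuilt, post[i, ])
  }
})

test_that("shock report computes deltas and growth per group", {
  pre <- data.frame(person_id = c("A", "B"),
                    economic_indicator = c(2.5, 0),
                    health_indicator = c(0, 2))
  post <- data.frame(person_id = c("A", "B"),
                     economic_indicator = c(5.0, 0),
                     health_indicator = c(0, 2))
  rec <- make_records(make_record(country = "ES", weight = 1),
                      make_record(country = "DE", weight = 1))
  rec$person_id <- c("A", "B")
  rep_ <- shock_report(pre, post, rec, by = "country")
  es <- rep_[rep_$country == "ES" & rep_$variable == "economic_indicator", ]
  expect_equal(es$growth_pct, 100)
  de <- rep_[rep_$country == "DE", ]
  expect_equal(de$delta, c(0, 0))
  # a decreased score violates the contract
  bad <- post; bad$health_indicator[2] <- 1
  expect_error(shock_report(pre, bad, rec), "decreased")
  expect_error(shock_report(pre, post[2:1, ], rec), "aligned")
})

test_that("a high-tourism region takes a larger economic hit than a zero-tourism twin", {
  arch <- default_archetypes()[c("southern", "northern")]
  arch$southern$tourism_retail_share <- 0.6
  arch$northern <- arch$southern
  arch$northern$name <- "northern"
  arch$northern$countries <- c("DE", "FR", "BE", "AT")
  arch$northern$tourism_retail_share <- 0
  cfg <- generator_config(n_records = 4000, seed = 19, archetypes = arch)
  g <- generate_microdata(cfg)
  b <- g$bundle
  sh <- apply_shock(b)
  s0 <- build_indicators(b); s1 <- build_indicators(sh$bundle)
  rmap <- default_region_map()
  rep_ <- shock_report(s0, s1, b$records, by = "region", region_map = rmap)
  d_tour <- rep_$delta[rep_$region == "southern" &
                         rep_$variable == "economic_indicator"]
  d_none <- rep_$delta[rep_$region == "northern" &
                         rep_$variable == "economic_indicator"]
  expect_gt(d_tour, d_none)
})
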