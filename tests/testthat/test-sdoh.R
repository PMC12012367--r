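instr <- default_instruments()

test_that("instrument scoring follows each scoring rule", {
  bhls <- instr$brief_health_literacy_screen
  expect_equal(score_instrument(bhls, c(bhls_help_reading = "5",
                                        bhls_confident_forms = "5",
                                        bhls_difficulty_understanding = "5")),
               15)
  expect_equal(score_instrument(bhls, c(bhls_help_reading = "1",
                                        bhls_confident_forms = "1",
                                        bhls_difficulty_understanding = "1")),
               3)
  hvs <- instr$hunger_vital_sign
  expect_equal(score_instrument(hvs, c(hvs_food_run_out = "Never true",
                                       hvs_food_not_last = "Never true")),
               "negative")
  expect_equal(score_instrument(hvs, c(hvs_food_run_out = "Sometimes true",
                                       hvs_food_not_last = "Never true")),
               "positive")
  mos <- instr$mos_social_support
  resp <- setNames(rep("4", 8), names(mos$items))
  expect_equal(score_instrument(mos, resp), 4.0)
  ## unknown level behaves as a missing item
  bad <- c(bhls_help_reading = "5", bhls_confident_forms = "banana",
           bhls_difficulty_understanding = "5")
  expect_true(is.na(score_instrument(bhls, bad)))
})

test_that("top box requires the most favorable response to every item", {
  bhls <- instr$brief_health_literacy_screen
  all_fav <- c(bhls_help_reading = "5", bhls_confident_forms = "5",
               bhls_difficulty_understanding = "5")
  expect_equal(top_box(bhls, all_fav), 1L)
  one_below <- all_fav; one_below[2] <- "4"
  expect_equal(top_box(bhls, one_below), 0L)
  expect_true(is.na(top_box(bhls, c(bhls_help_reading = NA))))
  partial <- c(bhls_help_reading = "5")
  expect_equal(top_box(bhls, partial), 0L)
})

test_that("top box is monotone in item favorability", {
  set.seed(4)
  for (nm in c("brief_health_literacy_screen", "neighborhood_disorder",
               "mos_social_support")) {
    spec <- instr[[nm]]
    for (rep in 1:20) {
      resp <- vapply(spec$items, function(it) sample(it$levels, 1), "")
      base <- top_box(spec, resp)
      ## degrade one answered item to a strictly less favorable level
      j <- sample(seq_along(resp), 1)
      it <- spec$items[[j]]
      worse_pool <- setdiff(it$levels, it$favorable)
      worse <- resp
      worse[j] <- sample(worse_pool, 1)
      degraded <- top_box(spec, worse)
      expect_lte(degraded, base)
    }
  }
})

test_that("composite unmet need follows the any/all/missing truth table", {
  expect_equal(composite_unmet_need(0L, 0L, 0L), 0L)
  expect_equal(composite_unmet_need(NA, 1L, 0L), 1L)
  expect_true(is.na(composite_unmet_need(NA, 0L, 0L)))
  expect_equal(composite_unmet_need(1L, NA, NA), 1L)
  ## symmetric in its three arguments
  for (f in list(c(0L, 1L, NA), c(NA, NA, 0L), c(1L, 0L, 0L))) {
    perms <- list(f, f[c(2, 3, 1)], f[c(3, 1, 2)], f[c(2, 1, 3)])
    vals <- vapply(perms, function(p)
      composite_unmet_need(p[1], p[2], p[3]), integer(1))
    expect_true(length(unique(vals[!is.na(vals)])) <= 1)
    expect_true(all(is.na(vals)) || all(!is.na(vals)))
  }
})

test_that("quintiles use cohort percentiles with ties going lower", {
  q <- assign_quintiles(1:100)
  expect_equal(q[81], 5L)
  expect_equal(q[80], 4L)  # exactly at the boundary -> lower quintile
  expect_equal(q[1], 1L)
  expect_warning(qq <- assign_quintiles(rep(2.5, 10)), "identical")
  expect_true(all(qq == 1L))
  ## brute-force percentile check at n = 10000
  set.seed(8)
  x <- runif(10000)
  q <- assign_quintiles(x)
  expect_true(all(abs(table(q) - 2000) <= 1))
  cut <- quantile(x, c(0.2, 0.4, 0.6, 0.8))
  naive <- 1L + (x > cut[1]) + (x > cut[2]) + (x > cut[3]) + (x > cut[4])
  expect_equal(q, as.integer(naive))
})

test_that("fold enrichment reduces to c5/c1 with flagged degenerate cases", {
  expect_equal(fold_enrichment(c(10, 10, 10, 10, 10)), 1.0)
  expect_equal(fold_enrichment(c(10, 10, 10, 10, 50)), 5.0)
  fe <- fold_enrichment(c(0, 5, 5, 5, 5))
  expect_true(is.na(fe))
  expect_equal(attr(fe, "reason"), "undefined (zero reference)")
  expect_error(fold_enrichment(c(0, 0, 0, 0, 0)), "zero")
  ## scale invariance
  set.seed(2)
  for (i in 1:10) {
    counts <- sample(1:50, 5)
    k <- sample(c(2, 3, 10), 1)
    expect_equal(fold_enrichment(counts * k), fold_enrichment(counts))
  }
})

test_that("cohort scoring matches per-person scoring on a small cohort", {
  co <- generate_cohort(sim_config(n_persons = 150, seed = 31))
  prof <- score_survey_profiles(co$dataset)
  surveys <- co$dataset$surveys
  set.seed(5)
  for (pid in sample(prof$person_id, 20)) {
    rows <- surveys[surveys$person_id == pid &
                      surveys$instrument == "brief_health_literacy_screen", ]
    expected <- if (nrow(rows) == 0) NA_real_ else
      score_instrument(instr$brief_health_literacy_screen, rows)
    expect_equal(prof$brief_health_literacy_screen[prof$person_id == pid],
                 expected)
    rows_h <- surveys[surveys$person_id == pid &
                        surveys$instrument == "hunger_vital_sign", ]
    expected_h <- if (nrow(rows_h) == 0) NA_integer_ else {
      s <- score_instrument(instr$hunger_vital_sign, rows_h)
      if (is.na(s)) NA_integer_ else as.integer(s == "positive")
    }
    expect_equal(prof$barrier_hunger_vital_sign[prof$person_id == pid],
                 expected_h)
  }
})

test_that("profiles recover generator barrier truth and composite flag", {
  co <- generate_cohort(sim_config(n_persons = 800, seed = 17,
                                   missingness_model = NULL))
  prof <- score_survey_profiles(co$dataset)
  m <- dplyr::inner_join(prof, co$truth, by = "person_id",
                         suffix = c("", ".truth"))
  expect_equal(m$food_insecurity, m$food)
  expect_equal(m$housing_instability_flag, m$housing)
  expect_equal(m$delayed_or_cant_afford_care_flag, m$care)
  expect_equal(m$unmet_social_need, m$unmet_social_need.truth)
  expect_equal(m$income, m$income_level)
  expect_equal(m$deprivation_quintile, m$deprivation_quintile.truth)
})
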