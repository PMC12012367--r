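test_that("cohort table summarises, tests, and suppresses correctly", {
  frame <- tibble::tibble(
    grp = rep(c("a", "b"), c(60, 43)),
    flag = c(rep(1, 30), rep(0, 30), rep(1, 25), rep(0, 18)),
    score = c(rnorm(60, 5), rnorm(43, 5)))
  ct <- build_cohort_table(frame, group = "grp")
  flag_tests <- ct$tests[ct$tests$variable == "flag", ]
  expect_equal(flag_tests$test, "Pearson chi-squared")
  expect_false(is.na(flag_tests$p))
  expect_equal(ct$tests$test[ct$tests$variable == "score"],
               "Wilcoxon rank-sum")
  cells <- ct$cells
  ## cell of 18 is suppressed; cells over 20 are not
  expect_true(cells$suppressed[cells$variable == "flag" & cells$level == "0" &
                                 cells$group == "b"])
  expect_false(cells$suppressed[cells$variable == "flag" & cells$level == "1" &
                                  cells$group == "a"])
  ## suppression is idempotent and display masks the value
  s1 <- apply_suppression(ct)
  s2 <- apply_suppression(s1)
  expect_identical(s1, s2)
  fmt <- format_cohort_table(s1)
  expect_true(any(fmt$b == "—"))
})

test_that("percentages are computed on stated denominators and sum to 100", {
  set.seed(6)
  frame <- tibble::tibble(
    grp = sample(c("a", "b", "c"), 400, TRUE),
    cat = sample(c("x", "y", "z"), 400, TRUE))
  frame$cat[sample(400, 40)] <- NA
  ct <- build_cohort_table(frame, group = "grp")
  sums <- tapply(ct$cells$pct, ct$cells$group, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  ## three groups use Kruskal-Wallis for continuous variables
  frame$val <- rnorm(400)
  ct2 <- build_cohort_table(frame, group = "grp", variables = "val")
  expect_equal(ct2$tests$test, "Kruskal-Wallis")
})

test_that("identical group distributions give uniform Kruskal-Wallis p", {
  set.seed(12)
  ps <- replicate(1000, {
    g <- rep(c("a", "b", "c"), each = 15)
    kruskal.test(rnorm(45), factor(g))$p.value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("all-missing variables are emitted as missing rows with a note", {
  frame <- tibble::tibble(grp = rep(c("a", "b"), 30), gone = NA_real_)
  ct <- build_cohort_table(frame, group = "grp")
  expect_true(all(ct$cells$note == "all values missing"))
})

test_that("imputation respects the 20% threshold and never alters complete data", {
  set.seed(20)
  n <- 400
  frame <- tibble::tibble(
    a = rnorm(n), b = rnorm(n),
    heavy = ifelse(runif(n) < 0.25, NA, rnorm(n)))
  res <- impute_covariates(frame, c("a", "b", "heavy"))
  expect_equal(res$frame$a, frame$a)
  expect_equal(res$report$status[res$report$variable == "heavy"],
               "skipped_threshold")
  expect_true(anyNA(res$frame$heavy))
  none <- impute_covariates(tibble::tibble(x = rnorm(50), y = rnorm(50)))
  expect_true(all(none$report$status == "complete"))
})

test_that("bagged-tree imputation beats a median fill on correlated data", {
  set.seed(30)
  n <- 1500
  x <- rnorm(n)
  y_true <- 2 * x + rnorm(n, sd = 0.5)
  holes <- runif(n) < 0.10  # 10% MCAR
  frame <- tibble::tibble(x = x, y = ifelse(holes, NA, y_true))
  res <- impute_covariates(frame, c("x", "y"), seed = 30)
  rmse_bag <- sqrt(mean((res$frame$y[holes] - y_true[holes])^2))
  rmse_med <- sqrt(mean((median(y_true[!holes]) - y_true[holes])^2))
  expect_lt(rmse_bag, rmse_med)
  expect_equal(res$report$method[res$report$variable == "y"], "bagged_trees")
})

test_that("predictor filters drop constants, duplicates and rare levels", {
  set.seed(40)
  n <- 2000
  frame <- tibble::tibble(
    const = rep(3.3, n),
    a = rnorm(n),
    sex = factor(c(rep("female", 1200), rep("male", 796), rep("other", 4)),
                 levels = c("female", "male", "other")))
  frame$dup <- frame$a
  res <- filter_predictors(frame)
  expect_false("const" %in% names(res$frame))
  expect_true(xor("a" %in% names(res$frame), "dup" %in% names(res$frame)))
  expect_true(any(grepl("zero variance", res$dropped$reason)))
  expect_true(any(grepl("\\|r\\|", res$dropped$reason)))
  ## 0.2% 'other' level collapses into the reference
  expect_false("other" %in% levels(res$frame$sex))
  expect_equal(sum(res$frame$sex == "female"), 1204)
  ## a near-constant factor (ratio > 19) is dropped entirely
  rare <- tibble::tibble(f = factor(c(rep("no", 1970), rep("yes", 30))),
                         z = rnorm(2000))
  res2 <- filter_predictors(rare)
  expect_false("f" %in% names(res2$frame))
})

test_that("design VIF is exactly 1 for an orthogonal design", {
  X <- cbind(a = rep(c(1, -1), 50), b = rep(c(1, 1, -1, -1), 25),
             c = rep(c(1, -1, -1, 1), 25))
  v <- design_vif(X)
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-10)
  ## collinear columns inflate
  Y <- cbind(a = rnorm(100))
  Y <- cbind(Y, b = Y[, 1] * 0.95 + rnorm(100, sd = 0.1))
  expect_gt(max(design_vif(Y)), 5)
})

test_that("the severity model recovers reference levels and is order-invariant", {
  f <- simulate_model_frame(6000, seed = 77)
  m1 <- fit_severity_model(f, seed = 1)
  expect_true(all(m1$terms$ci_low <= m1$terms$odds_ratio + 1e-12))
  expect_true(all(m1$terms$odds_ratio <= m1$terms$ci_high + 1e-12))
  expect_true(all(m1$terms$odds_ratio > 0))
  expect_equal(nrow(m1$interaction_p), 4)  # 2 income + 2 education terms
  expect_false(m1$separation_flag)
  set.seed(2)
  m2 <- fit_severity_model(f[sample.int(nrow(f)), ], seed = 1)
  expect_equal(m2$terms$odds_ratio, m1$terms$odds_ratio, tolerance = 1e-8)
})

test_that("separation is flagged, not silently clipped", {
  f <- tibble::tibble(
    outcome = rep(c(0L, 1L), each = 30),
    unmet_social_need = rep(c(0L, 1L), each = 30),  # perfect separation
    age = rnorm(60, 60), sex_at_birth = rep(c("female", "male"), 30),
    bmi = rnorm(60, 30), charlson_index = rpois(60, 2),
    income = sample(divertiphen:::INCOME_LEVELS, 60, TRUE),
    education = sample(divertiphen:::EDUCATION_LEVELS, 60, TRUE),
    insurance = sample(divertiphen:::INSURANCE_LEVELS, 60, TRUE))
  m <- fit_severity_model(f, impute = FALSE, filters = FALSE)
  expect_true(m$separation_flag)
})

test_that("sensitivity variants nest and empty variant lists are empty", {
  co <- generate_cohort(sim_config(n_persons = 4000, seed = 55))
  ds <- co$dataset
  a <- assign_phenotypes(ds)
  profiles <- score_survey_profiles(ds)
  expect_equal(run_sensitivity(a, ds$persons, profiles, variants = list()),
               list())
  sens <- run_sensitivity(a, ds$persons, profiles,
                          variants = list(
                            list(window_years = 5,
                                 inclusion_survey = "earliest"),
                            list(window_years = 2.5,
                                 inclusion_survey = "earliest")))
  expect_lt(sens[[2]]$n_cases, sens[[1]]$n_cases)
})
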