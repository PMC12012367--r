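## Seeded synthetic EHR/survey generator. Produces persons, event timelines,
## encounters, and item-level survey responses with known ground-truth
## severity classes (built as the inverse of the phenotyping rules, so the
## phenotyper must recover them exactly), quintile-graded social barriers,
## and a configurable logistic outcome model for the severe-versus-
## diverticulosis contrast. Default calibration follows the published cohort
## tables: ~5% of the modeled (diverticulosis + severe) pool in the severe
## class, ~40% composite unmet-need prevalence, and differentially greater
## survey missingness at lower income and education.

## Concrete demo-registry codes used when constructing timelines.
GEN_OSIS_CODES <- data.frame(vocabulary = c("ICD10CM", "ICD10CM", "ICD9CM"),
                             code = c("K57.30", "K57.90", "562.10"))
GEN_ITIS_CODES <- data.frame(vocabulary = c("ICD10CM", "ICD10CM", "ICD9CM"),
                             code = c("K57.32", "K57.92", "562.11"))
GEN_CT_CODES <- c("74176", "74177", "74178")
GEN_ENDO_CODES <- c("45378", "45330")
GEN_PROC_CODES <- c("44140", "44204", "49406", "44660")
GEN_DECOY_DX <- c("I10", "E11.9", "J45.909", "M54.5")

#' Default quintile-graded barrier probabilities
#'
#' One probability per deprivation quintile (least to most deprived) for
#' each social barrier. Levels are chosen so that the composite unmet-need
#' prevalence is roughly 40% and every barrier is enriched in the most
#' deprived quintile.
#'
#' @return Named list of length-5 probability vectors.
#' @export
default_barrier_probabilities <- function() {
  list(
    food_insecurity = c(0.06, 0.08, 0.10, 0.13, 0.18),
    housing_instability = c(0.13, 0.15, 0.18, 0.21, 0.27),
    delayed_or_cant_afford_care = c(0.18, 0.20, 0.23, 0.26, 0.30),
    housing_quality = c(0.12, 0.15, 0.17, 0.20, 0.26),
    insurance = c(0.06, 0.07, 0.08, 0.10, 0.13),
    english_proficiency = c(0.005, 0.008, 0.012, 0.02, 0.05),
    employment = c(0.04, 0.05, 0.06, 0.07, 0.09),
    education = c(0.033, 0.045, 0.06, 0.08, 0.12),
    income_low = c(0.28, 0.34, 0.40, 0.47, 0.55),
    health_literacy = c(0.30, 0.33, 0.36, 0.40, 0.46),
    neighborhood_disorder = c(0.55, 0.60, 0.65, 0.72, 0.80),
    social_support = c(0.68, 0.71, 0.74, 0.78, 0.83)
  )
}

#' Default outcome model for the severe-versus-diverticulosis contrast
#'
#' Log-odds coefficients on the adjusted-model covariate set. The unmet-need
#' coefficient defaults to `log(1.61)`; interaction coefficients default to
#' zero. The intercept `"auto"` is calibrated at generation time so the
#' marginal severe fraction matches the configured target.
#'
#' @param unmet_or Odds ratio for the unmet-social-need term (default 1.61).
#' @return List with `intercept` and named `coefficients`.
#' @export
default_outcome_model <- function(unmet_or = 1.61) {
  list(intercept = "auto",
       coefficients = c(unmet_social_need = log(unmet_or),
                        age = -0.005, sex_male = -0.15, sex_other = 0,
                        bmi = 0.01, charlson_index = 0.08,
                        income_lt50k = 0.15, income_50to100k = 0.05,
                        education_lt_hs = 0.2, education_hs = 0.05,
                        insurance_none = 0.05,
                        unmet_x_income_lt50k = 0, unmet_x_income_50to100k = 0,
                        unmet_x_education_lt_hs = 0, unmet_x_education_hs = 0))
}

#' Default survey-missingness model
#'
#' Missing-at-random masking of the three unmet-need component instruments,
#' with higher missingness odds for low-income and low-education persons so
#' the published missing-versus-available contrast is reproducible in
#' expectation.
#'
#' @return List with `variables`, `rate`, `mode` (`"mcar"` or `"mar"`), and
#'   the MAR log-odds shifts.
#' @export
default_missingness_model <- function() {
  list(variables = c("hunger_vital_sign", "housing_instability",
                     "delayed_or_cant_afford_care"),
       rate = 0.30, mode = "mar", joint = TRUE,
       log_or_low_income = 0.65, log_or_low_education = 0.5)
}

#' Simulation configuration
#'
#' @param n_persons Cohort size.
#' @param class_mix Named probabilities over the five phenotype classes
#'   (must sum to 1). The default puts ~5% of the modeled
#'   diverticulosis+severe pool in the severe class.
#' @param survey_lag_days Length-2 range (days) of the uniform lag between
#'   the earliest survey and the index diagnosis date.
#' @param barrier_probabilities See [default_barrier_probabilities()].
#' @param outcome_model See [default_outcome_model()].
#' @param missingness_model See [default_missingness_model()]; `NULL`
#'   disables missingness.
#' @param seed Integer seed; the full output is reproducible per
#'   (seed, n_persons).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_persons = 20000,
                       class_mix = c(control = 0.645, diverticulosis = 0.24,
                                     mild_diverticulitis = 0.05,
                                     operative_or_recurrent = 0.0125,
                                     excluded = 0.0525),
                       survey_lag_days = c(-1460, 1460),
                       barrier_probabilities = default_barrier_probabilities(),
                       outcome_model = default_outcome_model(),
                       missingness_model = default_missingness_model(),
                       seed = 1L) {
  if (!setequal(names(class_mix), PHENOTYPE_LEVELS)) {
    stop("class_mix must name all five phenotype classes", call. = FALSE)
  }
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1", call. = FALSE)
  if (any(class_mix < 0 | class_mix > 1)) {
    stop("class_mix probabilities must lie in [0,1]", call. = FALSE)
  }
  for (p in barrier_probabilities) {
    if (length(p) != 5 || any(p < 0 | p > 1)) {
      stop("barrier probabilities must be length-5 vectors in [0,1]", call. = FALSE)
    }
  }
  if (!is.null(missingness_model)) {
    if (any(missingness_model$rate < 0 | missingness_model$rate > 1)) {
      stop("missingness rates must lie in [0,1]", call. = FALSE)
    }
  }
  structure(list(n_persons = as.integer(n_persons),
                 class_mix = class_mix[PHENOTYPE_LEVELS],
                 survey_lag_days = survey_lag_days,
                 barrier_probabilities = barrier_probabilities,
                 outcome_model = outcome_model,
                 missingness_model = missingness_model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## ---- covariates and social variables --------------------------------------

draw_covariates <- function(n) {
  tibble(
    age = pmin(pmax(round(rnorm(n, 66, 10)), 22), 95),
    sex_at_birth = sample(c("female", "male", "other"), n, TRUE,
                          prob = c(0.577, 0.420, 0.003)),
    bmi = round(pmin(pmax(rnorm(n, 30, 6), 16), 60), 1),
    charlson_index = rpois(n, 2.8),
    deprivation_index = round(runif(n), 4)
  )
}

draw_social <- function(quintile, probs) {
  n <- length(quintile)
  pq <- function(nm) probs[[nm]][quintile]
  draw <- function(p) as.integer(runif(n) < p)
  income_low <- draw(pq("income_low"))
  income_mid <- as.integer(income_low == 0L & runif(n) < 0.27 / (1 - pq("income_low")))
  income_level <- ifelse(income_low == 1L, INCOME_LEVELS[3],
                         ifelse(income_mid == 1L, INCOME_LEVELS[2],
                                INCOME_LEVELS[1]))
  edu_low <- draw(pq("education"))
  edu_hs <- as.integer(edu_low == 0L & runif(n) < 0.13 / (1 - pq("education")))
  education_level <- ifelse(edu_low == 1L, EDUCATION_LEVELS[3],
                            ifelse(edu_hs == 1L, EDUCATION_LEVELS[2],
                                   EDUCATION_LEVELS[1]))
  employment_out <- draw(pq("employment"))
  employed <- as.integer(employment_out == 0L & runif(n) < 0.45)
  employment_level <- ifelse(employment_out == 1L, "Out of work",
                             ifelse(employed == 1L, "Employed", "Other"))
  tibble(
    income_level = income_level,
    education_level = education_level,
    employment_level = employment_level,
    insurance_level = ifelse(draw(pq("insurance")) == 1L,
                             INSURANCE_LEVELS[2], INSURANCE_LEVELS[1]),
    english_level = ifelse(draw(pq("english_proficiency")) == 1L,
                           "Not well", "Well"),
    food = draw(pq("food_insecurity")),
    housing = draw(pq("housing_instability")),
    care = draw(pq("delayed_or_cant_afford_care")),
    housing_quality = draw(pq("housing_quality")),
    health_literacy = draw(pq("health_literacy")),
    neighborhood_disorder = draw(pq("neighborhood_disorder")),
    social_support = draw(pq("social_support"))
  )
}

coef_of <- function(coefs, nm) if (nm %in% names(coefs)) coefs[[nm]] else 0

model_linear_predictor <- function(frame, coefs) {
  unmet <- as.numeric(frame$unmet_social_need)
  inc_low <- as.numeric(frame$income == INCOME_LEVELS[3])
  inc_mid <- as.numeric(frame$income == INCOME_LEVELS[2])
  edu_low <- as.numeric(frame$education == EDUCATION_LEVELS[3])
  edu_hs <- as.numeric(frame$education == EDUCATION_LEVELS[2])
  coef_of(coefs, "age") * frame$age +
    coef_of(coefs, "sex_male") * (frame$sex_at_birth == "male") +
    coef_of(coefs, "sex_other") * (frame$sex_at_birth == "other") +
    coef_of(coefs, "bmi") * frame$bmi +
    coef_of(coefs, "charlson_index") * frame$charlson_index +
    coef_of(coefs, "income_lt50k") * inc_low +
    coef_of(coefs, "income_50to100k") * inc_mid +
    coef_of(coefs, "education_lt_hs") * edu_low +
    coef_of(coefs, "education_hs") * edu_hs +
    coef_of(coefs, "insurance_none") * (frame$insurance == INSURANCE_LEVELS[2]) +
    coef_of(coefs, "unmet_social_need") * unmet +
    coef_of(coefs, "unmet_x_income_lt50k") * unmet * inc_low +
    coef_of(coefs, "unmet_x_income_50to100k") * unmet * inc_mid +
    coef_of(coefs, "unmet_x_education_lt_hs") * unmet * edu_low +
    coef_of(coefs, "unmet_x_education_hs") * unmet * edu_hs
}

calibrate_intercept <- function(lp0, target) {
  if (!is.finite(target) || target <= 0 || target >= 1) {
    stop("infeasible outcome model: implied prevalence ", target, call. = FALSE)
  }
  f <- function(c0) mean(plogis(lp0 + c0)) - target
  if (f(-40) > 0 || f(40) < 0) {
    stop("infeasible outcome model: cannot reach target prevalence", call. = FALSE)
  }
  uniroot(f, c(-40, 40), tol = 1e-8)$root
}

social_to_frame <- function(cov, social) {
  tibble(
    age = cov$age,
    sex_at_birth = factor(cov$sex_at_birth, levels = c("female", "male", "other")),
    bmi = cov$bmi,
    charlson_index = cov$charlson_index,
    income = factor(social$income_level, levels = INCOME_LEVELS),
    education = factor(social$education_level, levels = EDUCATION_LEVELS),
    insurance = factor(social$insurance_level, levels = INSURANCE_LEVELS),
    unmet_social_need = composite_unmet_need(social$food, social$housing,
                                             social$care)
  )
}

#' Simulate a covariate/outcome frame for the severity model
#'
#' Generates the modeled pool (diverticulosis versus operative/recurrent)
#' directly at the covariate level: covariates and quintile-graded social
#' barriers are drawn with the same machinery as [generate_cohort()], the
#' outcome is drawn from the configured logistic model, and the intercept is
#' calibrated so the marginal outcome prevalence matches `prevalence`.
#' Intended for parameter-recovery and coverage studies where per-person
#' event timelines are not needed.
#'
#' @param n Number of persons in the modeled pool.
#' @param outcome_model See [default_outcome_model()].
#' @param prevalence Target marginal outcome prevalence (default 0.05).
#' @param seed Integer seed.
#' @return A tibble ready for [fit_severity_model()]: `outcome` (0/1),
#'   `unmet_social_need`, `age`, `sex_at_birth`, `bmi`, `charlson_index`,
#'   `income`, `education`, `insurance`.
#' @export
simulate_model_frame <- function(n, outcome_model = default_outcome_model(),
                                 prevalence = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cov <- draw_covariates(n)
  quintile <- assign_quintiles(cov$deprivation_index)
  social <- draw_social(quintile, default_barrier_probabilities())
  frame <- social_to_frame(cov, social)
  lp0 <- model_linear_predictor(frame, outcome_model$coefficients)
  c0 <- if (identical(outcome_model$intercept, "auto")) {
    calibrate_intercept(lp0, prevalence)
  } else {
    outcome_model$intercept
  }
  p <- plogis(lp0 + c0)
  if (mean(p) < 1e-6 || mean(p) > 1 - 1e-6) {
    stop("infeasible outcome model: implied prevalence ~", signif(mean(p), 3),
         call. = FALSE)
  }
  frame$outcome <- rbinom(n, 1, p)
  attr(frame, "intercept") <- c0
  frame[, c("outcome", "unmet_social_need", "age", "sex_at_birth", "bmi",
            "charlson_index", "income", "education", "insurance")]
}

## ---- event timelines ------------------------------------------------------

gen_events <- function(person_id, event_date, code, vocabulary, event_class,
                       encounter_id = NA_character_) {
  tibble(person_id = person_id, event_date = event_date, code = code,
         vocabulary = vocabulary, event_class = event_class,
         encounter_id = encounter_id)
}

sample_codes <- function(codes_df, n) {
  i <- sample.int(nrow(codes_df), n, replace = TRUE)
  list(code = codes_df$code[i], vocabulary = codes_df$vocabulary[i])
}

confirm_events <- function(pids, dates) {
  is_ct <- runif(length(pids)) < 0.5
  code <- ifelse(is_ct, sample(GEN_CT_CODES, length(pids), TRUE),
                 sample(GEN_ENDO_CODES, length(pids), TRUE))
  gen_events(pids, dates, code, "CPT", ifelse(is_ct, "imaging", "procedure"))
}

decoy_dx_events <- function(pids, anchors, k_max = 3L) {
  k <- sample.int(k_max, length(pids), replace = TRUE)
  pid <- rep(pids, k)
  anchor <- rep(anchors, k)
  gen_events(pid, anchor + sample(-400:400, length(pid), TRUE),
             sample(GEN_DECOY_DX, length(pid), TRUE), "ICD10CM", "diagnosis")
}

## Build events + encounters for all persons of one target class.
## Each template is an inverse of one branch of the decision rules, so the
## phenotyper is guaranteed to assign exactly the target class.
simulate_class_tables <- function(pids, anchors, class) {
  n <- length(pids)
  ev <- list()
  enc <- list()
  if (n == 0) return(list(events = empty_events(), encounters = empty_encounters()))

  if (class == "control") {
    ev$decoy <- decoy_dx_events(pids, anchors)
    has_ct <- runif(n) < 0.3
    if (any(has_ct)) {
      ev$ct <- gen_events(pids[has_ct],
                          anchors[has_ct] + sample(-300:300, sum(has_ct), TRUE),
                          sample(GEN_CT_CODES, sum(has_ct), TRUE), "CPT",
                          "imaging")
    }
  } else if (class == "excluded") {
    mix <- runif(n) < 0.5
    dx <- sample_codes(GEN_ITIS_CODES, n)
    osis <- sample_codes(GEN_OSIS_CODES, n)
    dx$code[mix] <- osis$code[mix]
    dx$vocabulary[mix] <- osis$vocabulary[mix]
    linked <- runif(n) < 0.5
    enc_id <- ifelse(linked, paste0(pids, "-V1"), NA_character_)
    ev$dx <- gen_events(pids, anchors, dx$code, dx$vocabulary, "diagnosis",
                        enc_id)
    if (any(linked)) {
      enc$out <- tibble(encounter_id = paste0(pids[linked], "-V1"),
                        person_id = pids[linked], start_date = anchors[linked],
                        end_date = anchors[linked], setting = "outpatient")
    }
    late_ct <- runif(n) < 0.5  # confirmation AFTER the code: directional rule
    if (any(late_ct)) {
      ev$ct <- gen_events(pids[late_ct], anchors[late_ct] + 14L,
                          sample(GEN_CT_CODES, sum(late_ct), TRUE), "CPT",
                          "imaging")
    }
  } else {
    ## all confirmed-case classes share the index pair construction
    off <- sample(0:7, n, TRUE)
    dx_date <- anchors + off
    ev$confirm <- confirm_events(pids, anchors)
    dx <- if (class == "diverticulosis") sample_codes(GEN_OSIS_CODES, n)
          else sample_codes(GEN_ITIS_CODES, n)

    if (class == "diverticulosis") {
      ev$dx <- gen_events(pids, dx_date, dx$code, dx$vocabulary, "diagnosis",
                          paste0(pids, "-V1"))
      enc$out <- tibble(encounter_id = paste0(pids, "-V1"), person_id = pids,
                        start_date = dx_date, end_date = dx_date,
                        setting = "outpatient")
      extra <- runif(n) < 0.4
      if (any(extra)) {
        more <- sample_codes(GEN_OSIS_CODES, sum(extra))
        ev$extra <- gen_events(pids[extra], dx_date[extra] + 90L, more$code,
                               more$vocabulary, "diagnosis")
      }
    } else if (class == "mild_diverticulitis") {
      inpat <- runif(n) < 0.4
      ev$dx <- gen_events(pids, dx_date, dx$code, dx$vocabulary, "diagnosis",
                          paste0(pids, "-V1"))
      enc$v1 <- tibble(encounter_id = paste0(pids, "-V1"), person_id = pids,
                       start_date = dx_date,
                       end_date = dx_date + ifelse(inpat, 3L, 0L),
                       setting = ifelse(inpat, "inpatient", "outpatient"))
      ed <- runif(n) < 0.3  # ED visits never count as inpatient admissions
      if (any(ed)) {
        ed_dx <- sample_codes(GEN_ITIS_CODES, sum(ed))
        ev$ed_dx <- gen_events(pids[ed], dx_date[ed], ed_dx$code,
                               ed_dx$vocabulary, "diagnosis",
                               paste0(pids[ed], "-V2"))
        enc$ed <- tibble(encounter_id = paste0(pids[ed], "-V2"),
                         person_id = pids[ed], start_date = dx_date[ed],
                         end_date = dx_date[ed], setting = "emergency")
      }
    } else if (class == "operative_or_recurrent") {
      ev$dx <- gen_events(pids, dx_date, dx$code, dx$vocabulary, "diagnosis",
                          paste0(pids, "-V1"))
      enc$v1 <- tibble(encounter_id = paste0(pids, "-V1"), person_id = pids,
                       start_date = dx_date, end_date = dx_date + 4L,
                       setting = "inpatient")
      recurrent <- runif(n) < 0.5
      if (any(recurrent)) {
        dx2 <- sample_codes(GEN_ITIS_CODES, sum(recurrent))
        d2 <- dx_date[recurrent] + 60L
        ev$dx2 <- gen_events(pids[recurrent], d2, dx2$code, dx2$vocabulary,
                             "diagnosis", paste0(pids[recurrent], "-V2"))
        enc$v2 <- tibble(encounter_id = paste0(pids[recurrent], "-V2"),
                         person_id = pids[recurrent], start_date = d2,
                         end_date = d2 + 3L, setting = "inpatient")
      }
      operative <- !recurrent
      if (any(operative)) {
        ev$proc <- gen_events(pids[operative],
                              dx_date[operative] +
                                sample(0:20, sum(operative), TRUE),
                              sample(GEN_PROC_CODES, sum(operative), TRUE),
                              "CPT", "procedure")
      }
    }
    decoy <- runif(n) < 0.5
    if (any(decoy)) ev$dec <- decoy_dx_events(pids[decoy], anchors[decoy], 2L)
  }
  list(events = bind_rows(c(list(empty_events()), ev)),
       encounters = bind_rows(c(list(empty_encounters()), enc)))
}

#' Generate a timeline guaranteed to be assigned a target class
#'
#' Constructs events and encounters from the inverse of the decision rules
#' (e.g. mild = CT/endoscopy plus a diverticulitis code at an offset of 0-7
#' days and at most one inpatient admission; operative/recurrent = two
#' disjoint coded inpatient admissions or a linked procedure), so
#' [assign_phenotype()] under the default registry returns `target_class`.
#'
#' @param target_class One of the five phenotype classes.
#' @param person_id Person identifier for the timeline.
#' @param index_date Anchor date for the index events.
#' @param seed Optional integer seed.
#' @return An `event_timeline`.
#' @export
generate_events_for_class <- function(target_class, person_id = "SIM1",
                                      index_date = as.Date("2018-06-15"),
                                      seed = NULL) {
  target_class <- match.arg(target_class, PHENOTYPE_LEVELS)
  if (!is.null(seed)) set.seed(seed)
  tabs <- simulate_class_tables(person_id, index_date, target_class)
  person <- tibble(person_id = person_id, birth_date = index_date - 20000L,
                   sex_at_birth = "female")
  event_timeline(person, tabs$events, tabs$encounters)
}

## ---- survey responses -----------------------------------------------------

## Build item-level responses consistent with drawn barrier flags: barrier
## absent -> every item at its most favorable level; barrier present -> at
## least one item off the top box (scored scales get plausible spreads).
make_survey_responses <- function(pids, social) {
  n <- length(pids)
  rows <- list()
  add <- function(instrument, item, response) {
    rows[[length(rows) + 1]] <<- tibble(person_id = pids,
                                        instrument = instrument, item = item,
                                        response = response)
  }
  lv <- function(flag, bad, good) ifelse(flag == 1L, bad, good)

  hvs_risk <- sample(c("Often true", "Sometimes true"), n, TRUE, c(0.3, 0.7))
  add("hunger_vital_sign", "hvs_food_run_out",
      lv(social$food, hvs_risk, "Never true"))
  add("hunger_vital_sign", "hvs_food_not_last",
      lv(social$food, sample(c("Sometimes true", "Never true"), n, TRUE),
         "Never true"))

  add("brief_health_literacy_screen", "bhls_help_reading",
      lv(social$health_literacy, as.character(sample(2:4, n, TRUE)), "5"))
  for (it in c("bhls_confident_forms", "bhls_difficulty_understanding")) {
    add("brief_health_literacy_screen", it,
        lv(social$health_literacy, as.character(sample(3:5, n, TRUE)), "5"))
  }

  add("neighborhood_disorder", "nds_graffiti",
      lv(social$neighborhood_disorder, as.character(sample(2:3, n, TRUE)), "1"))
  for (it in c("nds_vandalism", "nds_vacant", "nds_trash", "nds_noise",
               "nds_crime")) {
    add("neighborhood_disorder", it,
        lv(social$neighborhood_disorder, as.character(sample(1:3, n, TRUE,
                                                             c(0.5, 0.3, 0.2))),
           "1"))
  }

  add("mos_social_support", "mos_help_sick",
      lv(social$social_support, as.character(sample(2:4, n, TRUE)), "5"))
  for (it in c("mos_confide", "mos_advice", "mos_love", "mos_good_time",
               "mos_understand", "mos_chores", "mos_distract")) {
    add("mos_social_support", it,
        lv(social$social_support, as.character(sample(3:5, n, TRUE)), "5"))
  }

  add("housing_instability", "housing_worried_losing",
      lv(social$housing, "Yes", "No"))
  add("housing_quality", "housing_quality_concern",
      lv(social$housing_quality, "Yes", "No"))

  both <- runif(n) < 0.3
  add("delayed_or_cant_afford_care", "care_delayed",
      lv(social$care, ifelse(both | runif(n) < 0.5, "Yes", "No"), "No"))
  add("delayed_or_cant_afford_care", "care_cant_afford",
      lv(social$care, ifelse(both, "Yes",
                             ifelse(runif(n) < 0.5, "Yes", "No")), "No"))

  add("insurance", "insurance_status", social$insurance_level)
  add("income", "annual_income", social$income_level)
  add("education", "highest_education", social$education_level)
  add("english_proficiency", "english_spoken", social$english_level)
  add("employment", "employment_status", social$employment_level)
  out <- bind_rows(rows)
  ## guarantee the care barrier: at least one of the two items endorsed
  care1 <- out$instrument == "delayed_or_cant_afford_care" &
    out$item == "care_delayed"
  care2 <- out$instrument == "delayed_or_cant_afford_care" &
    out$item == "care_cant_afford"
  neither <- out$response[care1] == "No" & out$response[care2] == "No" &
    social$care == 1L
  out$response[which(care1)[neither]] <- "Yes"
  out
}

## ---- cohort assembly ------------------------------------------------------

#' Generate a full synthetic cohort
#'
#' Draws covariates and quintile-graded social barriers, assigns ground-truth
#' phenotype classes (severe versus diverticulosis within the case pool is
#' drawn from the configured logistic outcome model, with the intercept
#' calibrated to the class-mix target), constructs event timelines per class,
#' builds item-level survey responses, and applies the missingness model.
#' Fully reproducible per seed.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_cohort`: list with `dataset` (an `ehr_dataset`),
#'   `truth` (per-person ground truth: class, barrier flags, unmet need,
#'   income/education levels, quintile), and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_persons
  pids <- sprintf("P%06d", seq_len(n))
  cov <- draw_covariates(n)
  quintile <- assign_quintiles(cov$deprivation_index)
  social <- draw_social(quintile, config$barrier_probabilities)
  frame <- social_to_frame(cov, social)

  ## survey dates
  survey_earliest <- as.Date("2018-06-01") + sample(-365:365, n, TRUE)
  survey_earliest[runif(n) < 0.03] <- as.Date(NA)
  has_ha <- runif(n) < 0.8
  survey_ha <- survey_earliest + sample(0:200, n, TRUE)
  survey_ha[!has_ha] <- as.Date(NA)
  has_sdoh <- runif(n) < 0.7
  survey_sdoh <- survey_earliest + sample(0:400, n, TRUE)
  survey_sdoh[!has_sdoh] <- as.Date(NA)

  ## ground-truth classes: control/mild/excluded from the mix, severe vs
  ## diverticulosis within the case pool from the logistic outcome model
  mix <- config$class_mix
  p_pool <- mix[["diverticulosis"]] + mix[["operative_or_recurrent"]]
  u <- runif(n)
  cls <- rep("pool", n)
  cls[u < mix[["control"]]] <- "control"
  cls[u >= mix[["control"]] & u < mix[["control"]] + mix[["mild_diverticulitis"]]] <-
    "mild_diverticulitis"
  cls[u >= mix[["control"]] + mix[["mild_diverticulitis"]] &
        u < mix[["control"]] + mix[["mild_diverticulitis"]] + mix[["excluded"]]] <-
    "excluded"
  pool <- cls == "pool"
  if (p_pool > 0 && any(pool)) {
    target <- mix[["operative_or_recurrent"]] / p_pool
    lp0 <- model_linear_predictor(frame[pool, , drop = FALSE],
                                  config$outcome_model$coefficients)
    c0 <- if (identical(config$outcome_model$intercept, "auto")) {
      calibrate_intercept(lp0, target)
    } else {
      config$outcome_model$intercept
    }
    p_sev <- plogis(lp0 + c0)
    if (mean(p_sev) < 1e-6 || mean(p_sev) > 1 - 1e-6) {
      stop("infeasible outcome model: implied severe prevalence ~",
           signif(mean(p_sev), 3), call. = FALSE)
    }
    severe <- rbinom(sum(pool), 1, p_sev) == 1
    cls[pool] <- ifelse(severe, "operative_or_recurrent", "diverticulosis")
  }

  ## anchor (index) dates: lag relative to the earliest survey
  lag <- round(runif(n, config$survey_lag_days[1], config$survey_lag_days[2]))
  base_date <- survey_earliest
  base_date[is.na(base_date)] <- as.Date("2018-06-01")
  anchors <- base_date + lag

  events <- list(); encounters <- list()
  for (k in PHENOTYPE_LEVELS) {
    sel <- cls == k
    tabs <- simulate_class_tables(pids[sel], anchors[sel], k)
    events[[k]] <- tabs$events
    encounters[[k]] <- tabs$encounters
  }
  persons <- tibble(
    person_id = pids,
    birth_date = base_date - round(cov$age * 365.25) - sample(0:364, n, TRUE),
    sex_at_birth = cov$sex_at_birth,
    bmi = cov$bmi,
    charlson_index = cov$charlson_index,
    deprivation_index = cov$deprivation_index,
    survey_date_earliest = survey_earliest,
    survey_date_healthcare_access = survey_ha,
    survey_date_sdoh = survey_sdoh
  )
  surveys <- make_survey_responses(pids, social)
  truth <- tibble(person_id = pids, class = cls,
                  unmet_social_need = as.integer(frame$unmet_social_need),
                  food = social$food, housing = social$housing,
                  care = social$care,
                  income_level = social$income_level,
                  education_level = social$education_level,
                  deprivation_quintile = quintile)
  cohort <- structure(list(
    dataset = ehr_dataset(persons, bind_rows(events), bind_rows(encounters),
                          surveys),
    truth = truth, config = config), class = "synthetic_cohort")
  if (!is.null(config$missingness_model)) {
    cohort <- plant_missingness(cohort, config$missingness_model)
  }
  cohort
}

#' Mask survey responses according to a missingness model
#'
#' MCAR masking removes each (person, instrument) block with the configured
#' rate; MAR masking shifts the masking log-odds upward for low-income and
#' low-education persons, reproducing in expectation the published pattern
#' of greater missingness at lower socioeconomic levels. With
#' `joint = TRUE` (the default model) a single per-person draw masks all
#' listed variables together — emulating a skipped survey block, which keeps
#' the conditional distribution of composites over the remaining complete
#' responders undistorted; with `joint = FALSE` each variable is masked
#' independently.
#'
#' @param cohort A `synthetic_cohort`.
#' @param model See [default_missingness_model()]; `rate` may be a scalar or
#'   a vector named by variable (per-variable rates force independent
#'   masking).
#' @param seed Optional seed (defaults to continuing the current stream).
#' @return The cohort with masked survey rows removed; the masked
#'   person-variable pairs are recorded in `cohort$masked`.
#' @export
plant_missingness <- function(cohort, model = default_missingness_model(),
                              seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!is.null(seed)) set.seed(seed)
  if (any(model$rate < 0 | model$rate > 1)) {
    stop("missingness rates must lie in [0,1]", call. = FALSE)
  }
  surveys <- cohort$dataset$surveys
  truth <- cohort$truth
  low_inc <- truth$income_level == INCOME_LEVELS[3]
  low_edu <- truth$education_level == EDUCATION_LEVELS[3]
  joint <- isTRUE(model$joint) && length(model$rate) == 1
  mask_prob <- function(rate) {
    if (identical(model$mode, "mar")) {
      plogis(qlogis(rate) + model$log_or_low_income * low_inc +
               model$log_or_low_education * low_edu)
    } else {
      rep(rate, nrow(truth))
    }
  }
  masked <- list()
  joint_hit <- if (joint && model$rate > 0) {
    runif(nrow(truth)) < mask_prob(model$rate)
  } else {
    NULL
  }
  for (v in model$variables) {
    rate <- if (length(model$rate) > 1) model$rate[[v]] else model$rate
    if (rate == 0) next
    hit <- if (joint) joint_hit else runif(nrow(truth)) < mask_prob(rate)
    if (any(hit)) {
      masked[[v]] <- tibble(person_id = truth$person_id[hit], variable = v)
      drop <- surveys$instrument == v &
        surveys$person_id %in% truth$person_id[hit]
      surveys <- surveys[!drop, , drop = FALSE]
    }
  }
  cohort$dataset$surveys <- surveys
  cohort$masked <- bind_rows(masked)
  cohort
}

#' Write a synthetic cohort to CSV files
#'
#' Emits the standard extract (persons, condition/procedure/visit/survey
#' CSVs) plus `truth.csv` with the generator's ground truth.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  write_ehr_dataset(cohort$dataset, dir)
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}
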