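reg <- default_codesets()

test_that("index pair requires a diagnosis 0..7 days after confirmation", {
  ct <- make_event("P1", "2019-01-01", "74176", "CPT", "imaging")
  pair3 <- find_index_pair(make_timeline(dplyr::bind_rows(
    ct, make_event("P1", "2019-01-04", "K57.30"))), reg)
  expect_equal(pair3$day_offset, 3L)
  expect_null(find_index_pair(make_timeline(dplyr::bind_rows(
    ct, make_event("P1", "2019-01-09", "K57.30"))), reg))
  ## "after" is directional: diagnosis preceding the scan never qualifies
  expect_null(find_index_pair(make_timeline(dplyr::bind_rows(
    make_event("P1", "2019-01-03", "K57.30"),
    make_event("P1", "2019-01-05", "74176", "CPT", "imaging"))), reg))
  ## same-day coding counts (offset 0)
  expect_equal(find_index_pair(make_timeline(dplyr::bind_rows(
    ct, make_event("P1", "2019-01-01", "K57.32"))), reg)$day_offset, 0L)
})

test_that("earliest pair selection matches brute force over all pairs", {
  ## CT day 0 with dx day 7, endoscopy day 10 with dx day 10
  ev <- dplyr::bind_rows(
    make_event("P1", "2019-01-01", "74176", "CPT", "imaging"),
    make_event("P1", "2019-01-08", "K57.32"),
    make_event("P1", "2019-01-11", "45378", "CPT", "procedure"),
    make_event("P1", "2019-01-11", "K57.92"))
  pair <- find_index_pair(make_timeline(ev), reg)
  expect_equal(pair$confirm_event$code, "74176")
  expect_equal(pair$dx_event$event_date, d("2019-01-08"))
  bf <- brute_force_index_pair(ev, reg)
  expect_equal(pair$dx_event$event_date, bf$dx_date)
  expect_equal(pair$confirm_event$event_date, bf$confirm_date)
  ## randomized fixtures: vectorised selection == brute force
  set.seed(42)
  for (i in 1:30) {
    n_c <- sample(1:3, 1); n_d <- sample(1:3, 1)
    ev <- dplyr::bind_rows(
      make_event("P1", d("2019-01-01") + sample(0:20, n_c, TRUE), "74176",
                 "CPT", "imaging"),
      make_event("P1", d("2019-01-01") + sample(0:20, n_d, TRUE),
                 sample(c("K57.30", "K57.32"), n_d, TRUE)))
    got <- find_index_pair(make_timeline(ev), reg)
    bf <- brute_force_index_pair(ev, reg)
    if (is.null(bf)) {
      expect_null(got)
    } else {
      expect_equal(got$dx_event$event_date, bf$dx_date)
      expect_equal(got$day_offset, bf$day_offset)
    }
  }
})

test_that("admission counting uses distinct merged inpatient stays", {
  two_stays <- make_timeline(
    dplyr::bind_rows(make_event("P1", "2019-01-02", "K57.32",
                                encounter_id = "V1"),
                     make_event("P1", "2019-03-02", "K57.32",
                                encounter_id = "V2")),
    dplyr::bind_rows(make_encounter("V1", "P1", "2019-01-01", "2019-01-05",
                                    "inpatient"),
                     make_encounter("V2", "P1", "2019-03-01", "2019-03-05",
                                    "inpatient")))
  expect_equal(count_inpatient_diverticulitis_admissions(two_stays, reg), 2L)

  five_codes <- make_timeline(
    make_event("P1", paste0("2019-01-0", 1:5), c("K57.32", "K57.33", "K57.92",
                                                 "K57.20", "K57.32"),
               encounter_id = "V1"),
    make_encounter("V1", "P1", "2019-01-01", "2019-01-05", "inpatient"))
  expect_equal(count_inpatient_diverticulitis_admissions(five_codes, reg), 1L)

  ## overlapping stays (days 1-5 and 5-9) merge into one admission
  overlapping <- make_timeline(
    dplyr::bind_rows(make_event("P1", "2019-01-01", "K57.32",
                                encounter_id = "A"),
                     make_event("P1", "2019-01-05", "K57.32",
                                encounter_id = "B")),
    dplyr::bind_rows(make_encounter("A", "P1", "2019-01-01", "2019-01-05",
                                    "inpatient"),
                     make_encounter("B", "P1", "2019-01-05", "2019-01-09",
                                    "inpatient")))
  expect_equal(count_inpatient_diverticulitis_admissions(overlapping, reg), 1L)

  ## random stays vs the naive interval-merge oracle
  set.seed(7)
  for (i in 1:25) {
    k <- sample(1:5, 1)
    starts <- d("2019-01-01") + sample(0:60, k, TRUE)
    ends <- starts + sample(0:10, k, TRUE)
    enc <- make_encounter(paste0("V", 1:k), "P1", starts, ends, "inpatient")
    ev <- make_event("P1", starts, "K57.32", encounter_id = paste0("V", 1:k))
    got <- count_inpatient_diverticulitis_admissions(make_timeline(ev, enc), reg)
    expect_equal(got, brute_force_merge_count(starts, ends))
  }
})

test_that("ED visits and unlinked codes never create admissions", {
  ed_only <- make_timeline(
    make_event("P1", "2019-01-01", "K57.32", encounter_id = "E1"),
    make_encounter("E1", "P1", "2019-01-01", "2019-01-01", "emergency"))
  expect_equal(count_inpatient_diverticulitis_admissions(ed_only, reg), 0L)
  unlinked <- make_timeline(make_event("P1", "2019-01-01", "K57.32"))
  expect_equal(count_inpatient_diverticulitis_admissions(unlinked, reg), 0L)
})

test_that("procedure linkage accepts same encounter or +/-30 days exactly", {
  same_enc <- make_timeline(
    dplyr::bind_rows(make_event("P1", "2019-01-02", "K57.32",
                                encounter_id = "V1"),
                     make_event("P1", "2019-01-03", "44140", "CPT",
                                "procedure", encounter_id = "V1")),
    make_encounter("V1", "P1", "2019-01-01", "2019-01-09", "inpatient"))
  expect_false(is.null(find_qualifying_procedure(same_enc, reg)))

  far <- make_timeline(dplyr::bind_rows(
    make_event("P1", "2019-01-01", "K57.32"),
    make_event("P1", "2019-02-15", "44140", "CPT", "procedure")))
  expect_null(find_qualifying_procedure(far, reg))  # 45 days, window 30

  ## exhaustive check of the acceptance region over offsets -40..+40
  for (off in -40:40) {
    tl <- make_timeline(dplyr::bind_rows(
      make_event("P1", d("2019-04-10") + off, "K57.32"),
      make_event("P1", "2019-04-10", "49406", "CPT", "procedure")))
    q <- find_qualifying_procedure(tl, reg, link_window_days = 30L)
    expect_equal(!is.null(q), abs(off) <= 30,
                 label = paste("offset", off))
  }
})

test_that("each decision branch is hit by exactly one branch fixture", {
  ds <- branch_fixture_dataset()
  a <- assign_phenotypes(ds, reg)
  got <- setNames(as.character(a$phenotype), a$person_id)
  expect_equal(got[["B1"]], "control")
  expect_equal(got[["B2"]], "diverticulosis")
  expect_equal(got[["B3"]], "mild_diverticulitis")
  ## exactly one inpatient encounter stays mild
  expect_equal(got[["B4"]], "mild_diverticulitis")
  ## more than one inpatient admission is operative/recurrent
  expect_equal(got[["B5"]], "operative_or_recurrent")
  expect_equal(got[["B6"]], "excluded")
  ## partition: every person gets exactly one class
  expect_equal(sort(a$person_id), paste0("B", 1:6))
  expect_false(any(is.na(a$phenotype)))
})

test_that("a qualifying procedure promotes a confirmed case to severe", {
  tl <- make_timeline(
    dplyr::bind_rows(make_event("P1", "2019-01-01", "74176", "CPT", "imaging"),
                     make_event("P1", "2019-01-03", "K57.32"),
                     make_event("P1", "2019-01-20", "44140", "CPT",
                                "procedure")))
  expect_equal(as.character(assign_phenotype(tl, reg)$phenotype),
               "operative_or_recurrent")
})

test_that("any diverticulitis code removes a person from diverticulosis", {
  ## index pair is on a diverticulosis code, but an old diverticulitis code
  ## exists: the 'only diverticulosis codes' condition is global
  tl <- make_timeline(dplyr::bind_rows(
    make_event("P1", "2015-06-01", "K57.92"),
    make_event("P1", "2019-01-01", "74176", "CPT", "imaging"),
    make_event("P1", "2019-01-03", "K57.30")))
  expect_equal(as.character(assign_phenotype(tl, reg)$phenotype),
               "mild_diverticulitis")
})

test_that("assignment is deterministic under input row permutation", {
  co <- generate_cohort(sim_config(n_persons = 300, seed = 9))
  base <- assign_phenotypes(co$dataset, reg)
  set.seed(1)
  ds2 <- ehr_dataset(co$dataset$persons,
                     co$dataset$events[sample.int(nrow(co$dataset$events)), ],
                     co$dataset$encounters[
                       sample.int(nrow(co$dataset$encounters)), ])
  again <- assign_phenotypes(ds2, reg)
  expect_equal(as.data.frame(again[order(again$person_id), ]),
               as.data.frame(base[order(base$person_id), ]))
})

test_that("adding a disjoint coded inpatient admission never lowers severity", {
  co <- generate_cohort(sim_config(n_persons = 200, seed = 13))
  base <- assign_phenotypes(co$dataset, reg)
  last_date <- max(co$dataset$events$event_date)
  extra_enc <- make_encounter(paste0(co$truth$person_id, "-EXTRA"),
                              co$truth$person_id, last_date + 500,
                              last_date + 503, "inpatient")
  extra_dx <- make_event(co$truth$person_id, last_date + 500, "K57.32",
                         encounter_id = paste0(co$truth$person_id, "-EXTRA"))
  ds2 <- ehr_dataset(co$dataset$persons,
                     dplyr::bind_rows(co$dataset$events, extra_dx),
                     dplyr::bind_rows(co$dataset$encounters, extra_enc))
  bumped <- assign_phenotypes(ds2, reg)
  m <- merge(base[, c("person_id", "phenotype")],
             bumped[, c("person_id", "phenotype")], by = "person_id")
  expect_true(all(severity_rank(m$phenotype.y) >= severity_rank(m$phenotype.x)))
})

test_that("inclusion window keeps/drops cases at the year boundary", {
  persons <- dplyr::bind_rows(lapply(c("P1", "P2", "P3"), make_person))
  persons$survey_date_earliest <- d("2015-01-01")
  persons$survey_date_healthcare_access <- c(d("2015-02-01"), d(NA), d(NA))
  a <- tibble::tibble(
    person_id = c("P1", "P2", "P3"),
    phenotype = factor(c("mild_diverticulitis", "mild_diverticulitis",
                         "control"), levels = divertiphen:::PHENOTYPE_LEVELS),
    assignment_date = c(d("2015-01-01") + round(4.9 * 365.25),
                        d("2015-01-01") + round(2.6 * 365.25), d(NA)))
  kept5 <- apply_inclusion_window(a, persons, window_years = 5)
  expect_setequal(kept5$person_id, c("P1", "P2", "P3"))
  kept25 <- apply_inclusion_window(a, persons, window_years = 2.5)
  expect_false("P1" %in% kept25$person_id)
  expect_false("P2" %in% kept25$person_id)
  expect_true("P3" %in% kept25$person_id)  # controls only need the survey
  ## switching the inclusion survey behaves exactly like a naive recompute
  kept_ha <- apply_inclusion_window(a, persons, window_years = 5,
                                    inclusion_survey = "healthcare_access")
  naive <- vapply(seq_len(nrow(a)), function(i) {
    sd <- persons$survey_date_healthcare_access[
      persons$person_id == a$person_id[i]]
    if (is.na(sd)) return(FALSE)
    if (!a$phenotype[i] %in% c("diverticulosis", "mild_diverticulitis",
                               "operative_or_recurrent")) return(TRUE)
    abs(as.numeric(a$assignment_date[i] - sd)) <= 365.25 * 5
  }, logical(1))
  expect_setequal(kept_ha$person_id, a$person_id[naive])
  expect_equal(attr(kept_ha, "n_dropped_no_survey"), 2L)
})
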