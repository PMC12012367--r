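## Shared fixture builders and independent brute-force oracles. Oracles here
## deliberately re-derive quantities with naive loops so the vectorised
## implementations are checked against a second, independent route.

d <- function(x) as.Date(x)

make_person <- function(id = "P1") {
  tibble::tibble(person_id = id, birth_date = d("1955-01-01"),
                 sex_at_birth = "female")
}

make_event <- function(pid, date, code, vocabulary = "ICD10CM",
                       event_class = "diagnosis", encounter_id = NA_character_) {
  tibble::tibble(person_id = pid, event_date = d(date), code = code,
                 vocabulary = vocabulary, event_class = event_class,
                 encounter_id = encounter_id)
}

make_encounter <- function(id, pid, start, end = start, setting = "outpatient") {
  tibble::tibble(encounter_id = id, person_id = pid, start_date = d(start),
                 end_date = d(end), setting = setting)
}

make_timeline <- function(events, encounters = NULL, pid = "P1") {
  event_timeline(make_person(pid), events,
                 if (is.null(encounters)) divertiphen:::empty_encounters()
                 else encounters)
}

## Naive index-pair search: all confirm x dx pairs, filter to the window,
## order by dx date then confirm date then codes.
brute_force_index_pair <- function(events, registry) {
  confirm <- events[event_matches(registry$abdominal_ct, events) |
                      event_matches(registry$lower_gi_endoscopy, events), ]
  dx <- events[event_matches(registry$diverticular_any_dx, events) &
                 events$event_class == "diagnosis", ]
  best <- NULL
  for (i in seq_len(nrow(confirm))) {
    for (j in seq_len(nrow(dx))) {
      off <- as.integer(dx$event_date[j] - confirm$event_date[i])
      if (off >= 0 && off <= 7) {
        cand <- list(confirm_date = confirm$event_date[i],
                     confirm_code = confirm$code[i],
                     dx_date = dx$event_date[j], dx_code = dx$code[j],
                     day_offset = off)
        if (is.null(best) ||
            cand$dx_date < best$dx_date ||
            (cand$dx_date == best$dx_date &&
               cand$confirm_date < best$confirm_date) ||
            (cand$dx_date == best$dx_date &&
               cand$confirm_date == best$confirm_date &&
               cand$dx_code < best$dx_code)) {
          best <- cand
        }
      }
    }
  }
  best
}

## Naive interval merge for admission counting (gap 0 = merge).
brute_force_merge_count <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  n <- 0; cur_end <- -Inf
  for (i in seq_along(starts)) {
    if (as.numeric(starts[i]) > cur_end) {
      n <- n + 1
      cur_end <- as.numeric(ends[i])
    } else {
      cur_end <- max(cur_end, as.numeric(ends[i]))
    }
  }
  n
}

## Naive one-vs-rest PPV/NPV from labels.
brute_force_ppv_npv <- function(algorithm, reference, class) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(algorithm)) {
    if (algorithm[i] == class) {
      if (reference[i] == class) tp <- tp + 1 else fp <- fp + 1
    } else {
      if (reference[i] == class) fn <- fn + 1 else tn <- tn + 1
    }
  }
  list(ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

severity_rank <- function(phenotype) {
  unname(c(control = 0, excluded = 0, diverticulosis = 1,
           mild_diverticulitis = 2, operative_or_recurrent = 3)[
             as.character(phenotype)])
}

## A tiny six-person dataset hitting every decision branch exactly once.
branch_fixture_dataset <- function() {
  ev <- dplyr::bind_rows(
    ## B1 control: no diverticular codes (decoy dx + CT)
    make_event("B1", "2019-01-01", "I10"),
    make_event("B1", "2019-02-01", "74176", "CPT", "imaging"),
    ## B2 diverticulosis: CT + diverticulosis code at day 3
    make_event("B2", "2019-01-01", "74176", "CPT", "imaging"),
    make_event("B2", "2019-01-04", "K57.30"),
    ## B3 mild, outpatient only: endoscopy + diverticulitis at day 2
    make_event("B3", "2019-01-01", "45378", "CPT", "procedure"),
    make_event("B3", "2019-01-03", "K57.32", encounter_id = "B3-V1"),
    ## B4 mild with exactly one inpatient admission
    make_event("B4", "2019-01-01", "74177", "CPT", "imaging"),
    make_event("B4", "2019-01-02", "K57.32", encounter_id = "B4-V1"),
    ## B5 severe: two disjoint coded inpatient admissions
    make_event("B5", "2019-01-01", "74177", "CPT", "imaging"),
    make_event("B5", "2019-01-02", "K57.32", encounter_id = "B5-V1"),
    make_event("B5", "2019-03-01", "K57.92", encounter_id = "B5-V2"),
    ## B6 excluded: diverticulitis code never within 7 days after CT
    make_event("B6", "2019-01-10", "K57.32"),
    make_event("B6", "2019-01-24", "74176", "CPT", "imaging")
  )
  enc <- dplyr::bind_rows(
    make_encounter("B3-V1", "B3", "2019-01-03"),
    make_encounter("B4-V1", "B4", "2019-01-02", "2019-01-05", "inpatient"),
    make_encounter("B5-V1", "B5", "2019-01-02", "2019-01-06", "inpatient"),
    make_encounter("B5-V2", "B5", "2019-03-01", "2019-03-04", "inpatient")
  )
  persons <- dplyr::bind_rows(lapply(paste0("B", 1:6), make_person))
  ehr_dataset(persons, ev, enc)
}
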