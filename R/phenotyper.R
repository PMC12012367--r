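## The severity phenotyper. Case ascertainment requires imaging/endoscopic
## confirmation: a diverticular diagnosis code dated 0..7 days (inclusive)
## AFTER an abdominal CT or lower GI endoscopy. Confirmed cases are split
## into diverticulosis (no diverticulitis codes anywhere), mild
## diverticulitis (at most one inpatient diverticulitis admission, no
## qualifying procedure), and operative/recurrent inpatient diverticulitis
## (more than one inpatient admission for diverticulitis, after merging
## overlapping or date-adjacent stays, or a colectomy/percutaneous-drain/
## fistula-repair procedure performed for diverticulitis). Persons with
## diverticular codes but no confirming pair land in an explicit `excluded`
## bucket rather than being relabelled as controls, so that NPV-style
## evaluations of the control class are not contaminated by unconfirmed
## cases.

INDEX_WINDOW_DAYS <- 7L

tag_events <- function(events, registry) {
  events$.confirm <- event_matches(registry$abdominal_ct, events) |
    event_matches(registry$lower_gi_endoscopy, events)
  events$.any_dx <- event_matches(registry$diverticular_any_dx, events) &
    events$event_class == "diagnosis"
  events$.osis <- event_matches(registry$diverticulosis_dx, events) &
    events$event_class == "diagnosis"
  events$.itis <- event_matches(registry$diverticulitis_dx, events) &
    events$event_class == "diagnosis"
  proc_set <- rep(NA_character_, nrow(events))
  for (nm in c("colectomy", "percutaneous_drain", "fistula_repair")) {
    hit <- event_matches(registry[[nm]], events) & is.na(proc_set)
    proc_set[hit] <- nm
  }
  events$.proc_set <- proc_set
  events
}

## Earliest (by diagnosis date, then confirmation date) confirm/dx pair with
## 0 <= dx - confirm <= 7 days, per person. Ties beyond that are broken by
## code text so the result is deterministic under input permutation.
find_index_pairs_vec <- function(tagged) {
  confirms <- tagged[tagged$.confirm, c("person_id", "event_date", "code")]
  names(confirms) <- c("person_id", "confirm_date", "confirm_code")
  dxs <- tagged[tagged$.any_dx, c("person_id", "event_date", "code")]
  names(dxs) <- c("person_id", "dx_date", "dx_code")
  if (nrow(confirms) == 0 || nrow(dxs) == 0) {
    return(tibble(person_id = character(), confirm_date = as.Date(character()),
                  confirm_code = character(), dx_date = as.Date(character()),
                  dx_code = character(), day_offset = integer()))
  }
  pairs <- inner_join(dxs, confirms, by = "person_id",
                      relationship = "many-to-many")
  pairs$day_offset <- as.integer(pairs$dx_date - pairs$confirm_date)
  pairs <- pairs[pairs$day_offset >= 0L & pairs$day_offset <= INDEX_WINDOW_DAYS, ,
                 drop = FALSE]
  if (nrow(pairs) == 0) return(pairs[, c("person_id", "confirm_date",
                                         "confirm_code", "dx_date", "dx_code",
                                         "day_offset")])
  ord <- order(pairs$person_id, pairs$dx_date, pairs$confirm_date,
               pairs$dx_code, pairs$confirm_code)
  pairs <- pairs[ord, , drop = FALSE]
  pairs <- pairs[!duplicated(pairs$person_id), , drop = FALSE]
  pairs[, c("person_id", "confirm_date", "confirm_code", "dx_date", "dx_code",
            "day_offset")]
}

## Distinct inpatient admissions carrying a linked diverticulitis code, after
## merging overlapping or adjacent (gap 0 days) stays so transfers cannot
## fabricate recurrence. Returns one row per person with the merged count;
## unlinked diverticulitis codes are tallied separately for diagnostics.
count_admissions_vec <- function(tagged, encounters) {
  itis <- tagged[tagged$.itis, , drop = FALSE]
  unlinked <- itis[is.na(itis$encounter_id), , drop = FALSE]
  unlinked_counts <- count(unlinked, .data$person_id, name = "n_unlinked")
  linked <- itis[!is.na(itis$encounter_id),
                 c("person_id", "encounter_id"), drop = FALSE]
  linked <- distinct(linked)
  inp <- encounters[encounters$setting == "inpatient", , drop = FALSE]
  coded <- inner_join(linked, inp, by = c("person_id", "encounter_id"))
  if (nrow(coded) == 0) {
    return(list(counts = tibble(person_id = character(), n_admissions = integer()),
                unlinked = unlinked_counts))
  }
  iv <- distinct(coded[, c("person_id", "start_date", "end_date")])
  iv <- iv[order(iv$person_id, iv$start_date, iv$end_date), , drop = FALSE]
  counts <- iv |>
    group_by(.data$person_id) |>
    mutate(prev_max = lag(cummax(as.numeric(.data$end_date))),
           new_admission = is.na(.data$prev_max) |
             as.numeric(.data$start_date) > .data$prev_max) |>
    summarise(n_admissions = as.integer(sum(.data$new_admission)),
              .groups = "drop")
  list(counts = counts, unlinked = unlinked_counts)
}

## Earliest procedure from {colectomy, percutaneous_drain, fistula_repair}
## that is "for diverticulitis": a diverticulitis diagnosis in the same
## encounter, or dated within +/- link_window_days of the procedure.
find_qualifying_procedures_vec <- function(tagged, link_window_days = 30L) {
  procs <- tagged[!is.na(tagged$.proc_set),
                  c("person_id", "event_date", "code", "encounter_id", ".proc_set")]
  names(procs) <- c("person_id", "proc_date", "proc_code", "proc_encounter",
                    "proc_set")
  dxs <- tagged[tagged$.itis, c("person_id", "event_date", "code", "encounter_id")]
  names(dxs) <- c("person_id", "dx_date", "dx_code", "dx_encounter")
  empty <- tibble(person_id = character(), proc_date = as.Date(character()),
                  proc_code = character(), proc_set = character(),
                  dx_date = as.Date(character()), dx_code = character())
  if (nrow(procs) == 0 || nrow(dxs) == 0) return(empty)
  j <- inner_join(procs, dxs, by = "person_id", relationship = "many-to-many")
  same_encounter <- !is.na(j$proc_encounter) & !is.na(j$dx_encounter) &
    j$proc_encounter == j$dx_encounter
  off <- abs(as.integer(j$dx_date - j$proc_date))
  j <- j[same_encounter | off <= link_window_days, , drop = FALSE]
  if (nrow(j) == 0) return(empty)
  j$abs_off <- abs(as.integer(j$dx_date - j$proc_date))
  ord <- order(j$person_id, j$proc_date, j$abs_off, j$dx_date, j$proc_code,
               j$dx_code)
  j <- j[ord, , drop = FALSE]
  j <- j[!duplicated(j$person_id), , drop = FALSE]
  j[, c("person_id", "proc_date", "proc_code", "proc_set", "dx_date", "dx_code")]
}

#' Assign severity phenotypes to every person in a dataset
#'
#' Applies the full rule set in a fixed decision order: (1) no diverticular
#' diagnosis codes at all -> `control`; (2) diverticular codes but no
#' confirming CT/endoscopy pair within the 7-day window -> `excluded`;
#' (3) no diverticulitis codes ever -> `diverticulosis`; (4) a qualifying
#' procedure or more than one merged inpatient diverticulitis admission ->
#' `operative_or_recurrent`; (5) otherwise `mild_diverticulitis`.
#'
#' @param ds An `ehr_dataset`.
#' @param registry A `codeset_registry` (default: shipped demo registry).
#' @param link_window_days Days either side of a procedure within which a
#'   diverticulitis code marks it as performed for diverticulitis (same
#'   encounter always qualifies). Default 30.
#' @return A tibble with one row per person: `person_id`, `phenotype`
#'   (factor over the five classes), `assignment_date` (index diagnosis date
#'   for cases, first diverticular code date for excluded, `NA` for
#'   controls), the index-pair evidence columns, the merged inpatient
#'   admission count, and the qualifying-procedure evidence. Unlinked
#'   diverticulitis codes (no encounter) are reported in the `diagnostics`
#'   attribute; they count toward no admission.
#' @export
assign_phenotypes <- function(ds, registry = default_codesets(),
                              link_window_days = 30L) {
  stopifnot(inherits(ds, "ehr_dataset"))
  tagged <- tag_events(ds$events, registry)
  per_person <- tagged |>
    group_by(.data$person_id) |>
    summarise(has_any_dx = any(.data$.any_dx),
              has_itis = any(.data$.itis),
              first_any_dx = if (any(.data$.any_dx))
                min(.data$event_date[.data$.any_dx]) else as.Date(NA),
              .groups = "drop")
  out <- tibble(person_id = ds$persons$person_id) |>
    left_join(per_person, by = "person_id") |>
    mutate(has_any_dx = coalesce(.data$has_any_dx, FALSE),
           has_itis = coalesce(.data$has_itis, FALSE))

  pairs <- find_index_pairs_vec(tagged)
  adm <- count_admissions_vec(tagged, ds$encounters)
  qp <- find_qualifying_procedures_vec(tagged, link_window_days)

  out <- out |>
    left_join(rename(pairs, index_confirm_date = "confirm_date",
                     index_confirm_code = "confirm_code",
                     index_dx_date = "dx_date", index_dx_code = "dx_code",
                     index_day_offset = "day_offset"),
              by = "person_id") |>
    left_join(adm$counts, by = "person_id") |>
    left_join(rename(qp, procedure_date = "proc_date",
                     procedure_code = "proc_code", procedure_set = "proc_set",
                     procedure_dx_date = "dx_date",
                     procedure_dx_code = "dx_code"),
              by = "person_id") |>
    mutate(inpatient_dx_admissions = coalesce(.data$n_admissions, 0L),
           n_admissions = NULL)

  has_pair <- !is.na(out$index_dx_date)
  has_proc <- !is.na(out$procedure_date)
  phenotype <- case_when(
    !out$has_any_dx ~ "control",
    !has_pair ~ "excluded",
    !out$has_itis ~ "diverticulosis",
    has_proc | out$inpatient_dx_admissions > 1L ~ "operative_or_recurrent",
    TRUE ~ "mild_diverticulitis"
  )
  out$phenotype <- factor(phenotype, levels = PHENOTYPE_LEVELS)
  assignment_date <- out$first_any_dx
  assignment_date[has_pair] <- out$index_dx_date[has_pair]
  assignment_date[phenotype == "control"] <- as.Date(NA)
  out$assignment_date <- assignment_date
  out <- out[, c("person_id", "phenotype", "assignment_date",
                 "index_confirm_date", "index_confirm_code", "index_dx_date",
                 "index_dx_code", "index_day_offset",
                 "inpatient_dx_admissions", "procedure_date", "procedure_code",
                 "procedure_set", "procedure_dx_date", "procedure_dx_code")]
  attr(out, "diagnostics") <- list(unlinked_diverticulitis = adm$unlinked)
  out
}

#' Find the index confirmation/diagnosis pair for one timeline
#'
#' @param timeline An `event_timeline`.
#' @param registry A `codeset_registry`.
#' @return `NULL` if no pair exists, otherwise a list with `confirm_event`
#'   and `dx_event` (one-row event tibbles) and `day_offset` in 0..7. The
#'   earliest pair by diagnosis date, then confirmation date, is returned.
#' @export
find_index_pair <- function(timeline, registry = default_codesets()) {
  tagged <- tag_events(timeline$events, registry)
  p <- find_index_pairs_vec(tagged)
  if (nrow(p) == 0) return(NULL)
  ev <- timeline$events
  pick <- function(date, code) {
    ev[ev$event_date == date & ev$code == code, , drop = FALSE][1, , drop = FALSE]
  }
  list(confirm_event = pick(p$confirm_date, p$confirm_code),
       dx_event = pick(p$dx_date, p$dx_code),
       day_offset = p$day_offset)
}

#' Count distinct inpatient diverticulitis admissions for one timeline
#'
#' Overlapping or date-adjacent inpatient stays are merged into a single
#' admission before counting; diverticulitis codes without an encounter link
#' count toward no admission.
#'
#' @inheritParams find_index_pair
#' @return Non-negative integer.
#' @export
count_inpatient_diverticulitis_admissions <- function(timeline,
                                                      registry = default_codesets()) {
  tagged <- tag_events(timeline$events, registry)
  adm <- count_admissions_vec(tagged, timeline$encounters)
  if (nrow(adm$counts) == 0) 0L else adm$counts$n_admissions[1]
}

#' Find the earliest procedure performed for diverticulitis in one timeline
#'
#' @inheritParams find_index_pair
#' @param link_window_days Linkage window in days (default 30).
#' @return `NULL`, or a list with `procedure_event` and `linked_dx_event`.
#' @export
find_qualifying_procedure <- function(timeline, registry = default_codesets(),
                                      link_window_days = 30L) {
  tagged <- tag_events(timeline$events, registry)
  q <- find_qualifying_procedures_vec(tagged, link_window_days)
  if (nrow(q) == 0) return(NULL)
  ev <- timeline$events
  list(procedure_event = ev[ev$event_date == q$proc_date & ev$code == q$proc_code, ,
                            drop = FALSE][1, , drop = FALSE],
       linked_dx_event = ev[ev$event_date == q$dx_date & ev$code == q$dx_code, ,
                            drop = FALSE][1, , drop = FALSE])
}

#' Assign a severity phenotype to one timeline
#'
#' @inheritParams find_qualifying_procedure
#' @return A one-row tibble in the format of [assign_phenotypes()].
#' @export
assign_phenotype <- function(timeline, registry = default_codesets(),
                             link_window_days = 30L) {
  assign_phenotypes(timeline_as_dataset(timeline), registry, link_window_days)
}

#' Restrict assignments to cases near survey completion
#'
#' Keeps persons who completed the chosen inclusion survey, and among them
#' keeps cases whose assignment date lies within `window_years` (365.25 days
#' per year) of that survey date, in either direction. Controls and excluded
#' persons are retained whenever they have the survey date. Counts of persons
#' dropped for a missing survey date and of cases dropped by the window are
#' attached as attributes `n_dropped_no_survey` and `n_dropped_window`.
#'
#' @param assignments Output of [assign_phenotypes()].
#' @param persons Persons tibble with the `survey_date_*` columns.
#' @param window_years Inclusion window half-width in years (default 5).
#' @param inclusion_survey Which survey date anchors the window:
#'   `"earliest"`, `"healthcare_access"` or `"sdoh"`.
#' @return Filtered assignments with an added `survey_date` column.
#' @export
apply_inclusion_window <- function(assignments, persons, window_years = 5,
                                   inclusion_survey = c("earliest",
                                                        "healthcare_access",
                                                        "sdoh")) {
  inclusion_survey <- match.arg(inclusion_survey)
  col <- paste0("survey_date_", inclusion_survey)
  if (!col %in% names(persons)) {
    stop("persons table lacks column ", col, call. = FALSE)
  }
  x <- left_join(assignments,
                 tibble(person_id = persons$person_id,
                        survey_date = persons[[col]]),
                 by = "person_id")
  no_survey <- is.na(x$survey_date)
  x <- x[!no_survey, , drop = FALSE]
  is_case <- x$phenotype %in% CASE_LEVELS
  lag_days <- abs(as.numeric(x$assignment_date - x$survey_date))
  in_window <- !is_case | (!is.na(lag_days) & lag_days <= 365.25 * window_years)
  out <- x[in_window, , drop = FALSE]
  attr(out, "n_dropped_no_survey") <- sum(no_survey)
  attr(out, "n_dropped_window") <- sum(!in_window)
  attr(out, "inclusion_survey") <- inclusion_survey
  attr(out, "window_years") <- window_years
  out
}
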