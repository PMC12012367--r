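## Event-level data model: persons, clinical events, encounters, and the
## CSV readers/writers every other module consumes. Dates are calendar dates
## (no times) and every interval in the package is measured in whole days;
## "within N days after" windows are inclusive on both ends.

#' Default table schema for an OMOP-style CSV extract
#'
#' Describes the expected input files, the mapping from raw column names to
#' the canonical column names used internally, and the mapping from raw visit
#' setting values to the three care-setting classes. Every element can be
#' overridden (e.g. via [load_schema()]) so extracts with different column
#' names or visit vocabularies can be read without editing the files.
#'
#' @return A nested list with one entry per table (`persons`,
#'   `condition_occurrence`, `procedure_occurrence`, `visit_occurrence`,
#'   `survey_responses`) plus `setting_map`, a named character vector mapping
#'   raw setting strings (lower-cased) to `inpatient`/`outpatient`/`emergency`.
#'   Raw settings absent from the map are treated as outpatient with a logged
#'   diagnostic, so unknown settings can never create the inpatient-admission
#'   evidence required for the most severe phenotype class.
#' @export
default_schema <- function() {
  list(
    persons = list(
      file = "persons.csv",
      columns = c(person_id = "person_id", birth_date = "birth_date",
                  sex_at_birth = "sex_at_birth", bmi = "bmi",
                  charlson_index = "charlson_index",
                  deprivation_index = "deprivation_index",
                  survey_date_earliest = "survey_date_earliest",
                  survey_date_healthcare_access = "survey_date_healthcare_access",
                  survey_date_sdoh = "survey_date_sdoh"),
      required = c("person_id", "birth_date", "sex_at_birth")
    ),
    condition_occurrence = list(
      file = "condition_occurrence.csv",
      columns = c(person_id = "person_id", event_date = "condition_date",
                  code = "code", vocabulary = "vocabulary",
                  encounter_id = "encounter_id"),
      required = c("person_id", "condition_date", "code", "vocabulary")
    ),
    procedure_occurrence = list(
      file = "procedure_occurrence.csv",
      columns = c(person_id = "person_id", event_date = "procedure_date",
                  code = "code", vocabulary = "vocabulary",
                  event_class = "event_class", encounter_id = "encounter_id"),
      required = c("person_id", "procedure_date", "code", "vocabulary")
    ),
    visit_occurrence = list(
      file = "visit_occurrence.csv",
      columns = c(encounter_id = "visit_id", person_id = "person_id",
                  start_date = "start_date", end_date = "end_date",
                  setting = "setting"),
      required = c("visit_id", "person_id", "start_date", "end_date", "setting")
    ),
    survey_responses = list(
      file = "survey_responses.csv",
      columns = c(person_id = "person_id", instrument = "instrument",
                  item = "item", response = "response"),
      required = c("person_id", "instrument", "item", "response")
    ),
    setting_map = c(inpatient = "inpatient", outpatient = "outpatient",
                    emergency = "emergency", ip = "inpatient",
                    op = "outpatient", er = "emergency", ed = "emergency",
                    ambulatory = "outpatient")
  )
}

#' Load a schema configuration from a YAML file
#'
#' The file may override any subset of [default_schema()]; unspecified keys
#' keep their defaults. This is the hook for supplying a custom visit-setting
#' mapping (e.g. collapsing a local visit vocabulary to
#' inpatient/outpatient/emergency) and custom column names.
#'
#' @param path Path to a YAML file.
#' @return A schema list as produced by [default_schema()].
#' @export
load_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  user <- yaml::read_yaml(path)
  sch <- default_schema()
  for (tab in intersect(names(user), names(sch))) {
    if (tab == "setting_map") {
      sch$setting_map <- unlist(user$setting_map)
    } else {
      for (k in intersect(names(user[[tab]]), c("file", "required"))) {
        sch[[tab]][[k]] <- unlist(user[[tab]][[k]])
      }
      if (!is.null(user[[tab]]$columns)) {
        cur <- sch[[tab]]$columns
        ov <- unlist(user[[tab]]$columns)
        cur[names(ov)] <- ov
        sch[[tab]]$columns <- cur
      }
    }
  }
  sch
}

#' Signed whole-day difference between two calendar dates
#'
#' @param a,b Dates (or strings coercible with `as.Date`).
#' @return Integer `b - a` in days; antisymmetric, `days_between(d, d) == 0`.
#' @examples
#' days_between(as.Date("2020-01-01"), as.Date("2020-01-08")) # 7
#' @export
days_between <- function(a, b) {
  as.integer(as.Date(b) - as.Date(a))
}

parse_date_strict <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

sort_events <- function(events) {
  ## date, then event class, then code; the encounter link participates only
  ## as a final key so the order is total for any permutation of input rows
  events[order(events$person_id, events$event_date, events$event_class,
               events$code, events$encounter_id, na.last = TRUE,
               method = "radix"), , drop = FALSE]
}

empty_events <- function() {
  tibble(person_id = character(), event_date = as.Date(character()),
         code = character(), vocabulary = character(),
         event_class = character(), encounter_id = character())
}

empty_encounters <- function() {
  tibble(encounter_id = character(), person_id = character(),
         start_date = as.Date(character()), end_date = as.Date(character()),
         setting = character())
}

empty_rejects <- function() {
  tibble(table = character(), row = integer(), reason = character())
}

empty_diagnostics <- function() {
  tibble(table = character(), kind = character(), person_id = character(),
         detail = character())
}

read_raw_table <- function(path, spec, table_name) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(spec$required, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("schema error: table '%s' is missing required column '%s'",
                 table_name, missing_cols[1]), call. = FALSE)
  }
  out <- tibble(.rows = nrow(raw))
  for (canon in names(spec$columns)) {
    rawname <- spec$columns[[canon]]
    out[[canon]] <- if (rawname %in% names(raw)) raw[[rawname]] else NA_character_
  }
  out$.row <- seq_len(nrow(out))
  out
}

#' Assemble an in-memory EHR dataset from component tables
#'
#' Constructor used by tests and the synthetic generator; performs the same
#' integrity checks as [read_ehr_dataset()] (sorted timelines, resolvable
#' encounter links) but assumes columns are already typed.
#'
#' @param persons Tibble with at least `person_id`; optional `birth_date`,
#'   `sex_at_birth`, `bmi`, `charlson_index`, `deprivation_index` and the
#'   three `survey_date_*` columns.
#' @param events Tibble of clinical events (`person_id`, `event_date`, `code`,
#'   `vocabulary`, `event_class`, `encounter_id`).
#' @param encounters Tibble of visits (`encounter_id`, `person_id`,
#'   `start_date`, `end_date`, `setting`).
#' @param surveys Optional tibble of item-level survey responses.
#' @return An object of class `ehr_dataset`.
#' @export
ehr_dataset <- function(persons, events = empty_events(),
                        encounters = empty_encounters(), surveys = NULL) {
  persons <- as_tibble(persons)
  events <- as_tibble(events)
  encounters <- as_tibble(encounters)
  if (anyDuplicated(persons$person_id) > 0) {
    stop("person_id must be unique within a dataset", call. = FALSE)
  }
  for (col in c("bmi", "charlson_index", "deprivation_index")) {
    if (!col %in% names(persons)) persons[[col]] <- NA_real_
  }
  for (col in c("survey_date_earliest", "survey_date_healthcare_access",
                "survey_date_sdoh")) {
    if (!col %in% names(persons)) persons[[col]] <- as.Date(NA)
  }
  if (!"encounter_id" %in% names(events)) events$encounter_id <- NA_character_
  diagnostics <- empty_diagnostics()

  ## Null out event->encounter links that do not resolve to a visit of the
  ## same person; each dangling link is one diagnostic row.
  if (nrow(events) > 0) {
    key_enc <- paste(encounters$person_id, encounters$encounter_id)
    linked <- !is.na(events$encounter_id)
    dangling <- linked &
      !(paste(events$person_id, events$encounter_id) %in% key_enc)
    if (any(dangling)) {
      diagnostics <- bind_rows(diagnostics, tibble(
        table = "events", kind = "dangling_encounter",
        person_id = events$person_id[dangling],
        detail = paste0("encounter_id '", events$encounter_id[dangling],
                        "' does not resolve; link nulled")))
      events$encounter_id[dangling] <- NA_character_
      warning(sum(dangling), " event(s) referenced unknown encounters; links nulled",
              call. = FALSE)
    }
    events <- sort_events(events)
  }
  structure(list(persons = persons, events = events, encounters = encounters,
                 surveys = if (is.null(surveys)) NULL else as_tibble(surveys),
                 rejects = empty_rejects(), diagnostics = diagnostics),
            class = "ehr_dataset")
}

#' Read an OMOP-style CSV extract into an EHR dataset
#'
#' Reads persons, condition occurrences, procedure occurrences, visits and
#' (optionally) survey responses. Malformed rows are never silently dropped:
#' each one becomes a row of the rejects report with its original data-row
#' number and a reason. Events whose encounter link does not resolve are
#' accepted with the link nulled and a diagnostic logged.
#'
#' @param dir Directory containing the CSV files named in the schema.
#' @param schema Schema list from [default_schema()] or [load_schema()].
#' @return An `ehr_dataset` whose `rejects` element is the rejects report
#'   (columns `table`, `row`, `reason`) and whose `diagnostics` element
#'   records non-fatal repairs (dangling encounter links, unknown settings).
#' @export
read_ehr_dataset <- function(dir, schema = default_schema()) {
  path_of <- function(tab) file.path(dir, schema[[tab]]$file)
  if (!file.exists(path_of("persons"))) {
    stop("persons file not found: ", path_of("persons"), call. = FALSE)
  }
  rejects <- empty_rejects()
  diagnostics <- empty_diagnostics()
  add_rejects <- function(tab, rows, reason) {
    if (length(rows) > 0) {
      rejects <<- bind_rows(rejects, tibble(table = tab, row = as.integer(rows),
                                            reason = reason))
    }
  }

  ## persons ----
  p <- read_raw_table(path_of("persons"), schema$persons, "persons")
  p$birth_date_parsed <- parse_date_strict(p$birth_date)
  bad_date <- !is.na(p$birth_date) & is.na(p$birth_date_parsed)
  add_rejects("persons", p$.row[bad_date], "unparseable date")
  p <- p[!bad_date, , drop = FALSE]
  dup <- duplicated(p$person_id)
  add_rejects("persons", p$.row[dup], "duplicate person_id")
  p <- p[!dup, , drop = FALSE]
  depr <- suppressWarnings(as.numeric(p$deprivation_index))
  bad_depr <- !is.na(depr) & (depr < 0 | depr > 1)
  add_rejects("persons", p$.row[bad_depr], "deprivation_index outside [0,1]")
  p <- p[!bad_depr, , drop = FALSE]
  persons <- tibble(
    person_id = p$person_id,
    birth_date = p$birth_date_parsed,
    sex_at_birth = ifelse(tolower(p$sex_at_birth) %in% SEX_LEVELS,
                          tolower(p$sex_at_birth), "unknown"),
    bmi = suppressWarnings(as.numeric(p$bmi)),
    charlson_index = suppressWarnings(as.integer(p$charlson_index)),
    deprivation_index = suppressWarnings(as.numeric(p$deprivation_index)),
    survey_date_earliest = parse_date_strict(p$survey_date_earliest),
    survey_date_healthcare_access = parse_date_strict(p$survey_date_healthcare_access),
    survey_date_sdoh = parse_date_strict(p$survey_date_sdoh)
  )

  ## visits ----
  encounters <- empty_encounters()
  if (file.exists(path_of("visit_occurrence"))) {
    v <- read_raw_table(path_of("visit_occurrence"), schema$visit_occurrence,
                        "visit_occurrence")
    v$start <- parse_date_strict(v$start_date)
    v$end <- parse_date_strict(v$end_date)
    bad <- is.na(v$start) | is.na(v$end)
    add_rejects("visit_occurrence", v$.row[bad], "unparseable date")
    v <- v[!bad, , drop = FALSE]
    bad <- v$end < v$start
    add_rejects("visit_occurrence", v$.row[bad], "end_date before start_date")
    v <- v[!bad, , drop = FALSE]
    bad <- !(v$person_id %in% persons$person_id)
    add_rejects("visit_occurrence", v$.row[bad], "unknown person_id")
    v <- v[!bad, , drop = FALSE]
    raw_setting <- tolower(trimws(v$setting))
    mapped <- unname(schema$setting_map[raw_setting])
    unknown <- is.na(mapped)
    if (any(unknown)) {
      diagnostics <- bind_rows(diagnostics, tibble(
        table = "visit_occurrence", kind = "unknown_setting",
        person_id = v$person_id[unknown],
        detail = paste0("setting '", v$setting[unknown],
                        "' not in setting_map; treated as outpatient")))
      warning(sum(unknown),
              " visit(s) had unmapped settings; treated as outpatient",
              call. = FALSE)
      mapped[unknown] <- "outpatient"
    }
    encounters <- tibble(encounter_id = v$encounter_id, person_id = v$person_id,
                         start_date = v$start, end_date = v$end,
                         setting = mapped)
  }

  ## events (conditions + procedures/imaging) ----
  read_events <- function(tab, default_class) {
    if (!file.exists(path_of(tab))) return(empty_events())
    e <- read_raw_table(path_of(tab), schema[[tab]], tab)
    e$date <- parse_date_strict(e$event_date)
    bad <- is.na(e$date)
    add_rejects(tab, e$.row[bad], "unparseable date")
    e <- e[!bad, , drop = FALSE]
    bad <- is.na(e$code) | trimws(e$code) == ""
    add_rejects(tab, e$.row[bad], "empty code")
    e <- e[!bad, , drop = FALSE]
    bad <- !(e$person_id %in% persons$person_id)
    add_rejects(tab, e$.row[bad], "unknown person_id")
    e <- e[!bad, , drop = FALSE]
    cls <- if ("event_class" %in% names(e)) {
      ifelse(!is.na(e$event_class) & e$event_class %in% EVENT_CLASSES,
             e$event_class, default_class)
    } else {
      rep(default_class, nrow(e))
    }
    tibble(person_id = e$person_id, event_date = e$date, code = e$code,
           vocabulary = toupper(e$vocabulary), event_class = cls,
           encounter_id = if ("encounter_id" %in% names(e)) e$encounter_id
                          else NA_character_)
  }
  events <- bind_rows(read_events("condition_occurrence", "diagnosis"),
                      read_events("procedure_occurrence", "procedure"))

  ## surveys ----
  surveys <- NULL
  if (file.exists(path_of("survey_responses"))) {
    s <- read_raw_table(path_of("survey_responses"), schema$survey_responses,
                        "survey_responses")
    bad <- !(s$person_id %in% persons$person_id)
    add_rejects("survey_responses", s$.row[bad], "unknown person_id")
    s <- s[!bad, , drop = FALSE]
    surveys <- tibble(person_id = s$person_id, instrument = s$instrument,
                      item = s$item, response = s$response)
  }

  ds <- ehr_dataset(persons, events, encounters, surveys)
  ds$rejects <- rejects
  ds$diagnostics <- bind_rows(diagnostics, ds$diagnostics)
  ds
}

#' Write an EHR dataset back to CSV files
#'
#' Inverse of [read_ehr_dataset()] under the default schema: the accepted rows
#' round-trip bit-identically modulo column order.
#'
#' @param ds An `ehr_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ehr_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "ehr_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- ds$persons
  readr::write_csv(p, file.path(dir, "persons.csv"), na = "")
  ev <- ds$events
  cond <- ev[ev$event_class == "diagnosis", , drop = FALSE]
  readr::write_csv(
    tibble(person_id = cond$person_id, condition_date = cond$event_date,
           code = cond$code, vocabulary = cond$vocabulary,
           encounter_id = cond$encounter_id),
    file.path(dir, "condition_occurrence.csv"), na = "")
  proc <- ev[ev$event_class != "diagnosis", , drop = FALSE]
  readr::write_csv(
    tibble(person_id = proc$person_id, procedure_date = proc$event_date,
           code = proc$code, vocabulary = proc$vocabulary,
           event_class = proc$event_class, encounter_id = proc$encounter_id),
    file.path(dir, "procedure_occurrence.csv"), na = "")
  enc <- ds$encounters
  readr::write_csv(
    tibble(visit_id = enc$encounter_id, person_id = enc$person_id,
           start_date = enc$start_date, end_date = enc$end_date,
           setting = enc$setting),
    file.path(dir, "visit_occurrence.csv"), na = "")
  if (!is.null(ds$surveys)) {
    readr::write_csv(ds$surveys, file.path(dir, "survey_responses.csv"), na = "")
  }
  if (nrow(ds$rejects) > 0) {
    readr::write_csv(ds$rejects, file.path(dir, "rejects.csv"), na = "")
  }
  invisible(dir)
}

#' Extract one person's event timeline
#'
#' @param ds An `ehr_dataset`.
#' @param person_id Person identifier.
#' @return An `event_timeline`: list with `person` (one-row tibble), `events`
#'   (date-ordered, ties broken by event class then code) and `encounters`.
#' @export
person_timeline <- function(ds, person_id) {
  stopifnot(inherits(ds, "ehr_dataset"))
  if (!person_id %in% ds$persons$person_id) {
    stop("unknown person_id: ", person_id, call. = FALSE)
  }
  event_timeline(ds$persons[ds$persons$person_id == person_id, , drop = FALSE],
                 ds$events[ds$events$person_id == person_id, , drop = FALSE],
                 ds$encounters[ds$encounters$person_id == person_id, , drop = FALSE])
}

#' Construct an event timeline for a single person
#'
#' @param person One-row tibble with at least `person_id`.
#' @param events Events belonging to that person.
#' @param encounters Encounters belonging to that person.
#' @return An `event_timeline` object with events in the canonical total
#'   order (date, then event class, then code), which is deterministic for
#'   any permutation of the input rows.
#' @export
event_timeline <- function(person, events = empty_events(),
                           encounters = empty_encounters()) {
  person <- as_tibble(person)
  stopifnot(nrow(person) == 1)
  events <- as_tibble(events)
  if (nrow(events) > 0 && any(events$person_id != person$person_id)) {
    stop("all events must belong to the timeline's person", call. = FALSE)
  }
  if (!"encounter_id" %in% names(events)) events$encounter_id <- NA_character_
  structure(list(person = person, events = sort_events(events),
                 encounters = as_tibble(encounters)),
            class = "event_timeline")
}

## Wrap a single timeline back into a dataset so per-timeline operations can
## share the vectorised cohort implementations.
timeline_as_dataset <- function(timeline) {
  stopifnot(inherits(timeline, "event_timeline"))
  suppressWarnings(ehr_dataset(timeline$person, timeline$events,
                               timeline$encounters))
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat("<ehr_dataset> ", nrow(x$persons), " persons, ", nrow(x$events),
      " events, ", nrow(x$encounters), " encounters",
      if (!is.null(x$surveys)) paste0(", ", nrow(x$surveys), " survey rows"),
      "\n", sep = "")
  if (nrow(x$rejects) > 0) cat("  rejects: ", nrow(x$rejects), " row(s)\n", sep = "")
  if (nrow(x$diagnostics) > 0) {
    cat("  diagnostics: ", nrow(x$diagnostics), " row(s)\n", sep = "")
  }
  invisible(x)
}
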