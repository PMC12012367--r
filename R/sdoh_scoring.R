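## Survey instrument scoring, top-box conversion, the composite
## unmet-social-need flag, deprivation-index quintiles, and quintile fold
## enrichment. A "top box" (1) means the most favorable response to every
## item of an instrument; any less favorable answered item, or any missing
## item among answered ones, yields 0, and an instrument with all items
## missing is missing. Barrier flags are oriented so 1 = barrier present.

BARRIER_VARIABLES <- c("hunger_vital_sign", "income", "housing_instability",
                       "education", "delayed_or_cant_afford_care", "insurance",
                       "brief_health_literacy_screen", "neighborhood_disorder",
                       "housing_quality", "mos_social_support",
                       "english_proficiency", "employment")

#' Define a survey instrument
#'
#' @param name Instrument name.
#' @param scoring One of `"sum"`, `"mean"`, `"categorical"`, `"screen"`.
#' @param items Named list: for each item id, a list with `levels` (ordered
#'   response levels), optional `values` (numeric scoring values aligned with
#'   levels; defaults to `seq_along(levels)`), `favorable` (the single most
#'   favorable level; defaults to the last level), and for screen-type
#'   instruments `at_risk` (levels that endorse the screen).
#' @param barrier_levels For categorical instruments, the level(s) whose
#'   endorsement constitutes the social barrier (e.g. income below 50k).
#' @return An `instrument_spec`.
#' @export
instrument_spec <- function(name, scoring, items, barrier_levels = NULL) {
  scoring <- match.arg(scoring, c("sum", "mean", "categorical", "screen"))
  items <- lapply(items, function(it) {
    it$levels <- as.character(it$levels)
    if (is.null(it$values)) it$values <- seq_along(it$levels)
    if (is.null(it$favorable)) it$favorable <- it$levels[length(it$levels)]
    if (length(it$favorable) != 1 || !it$favorable %in% it$levels) {
      stop("each item needs exactly one most-favorable level drawn from its levels",
           call. = FALSE)
    }
    it
  })
  structure(list(name = name, scoring = scoring, items = items,
                 barrier_levels = barrier_levels),
            class = "instrument_spec")
}

## Long lookup table: one row per (item, level) with value/favorable/at-risk
## flags, used for vectorised scoring of whole cohorts.
instrument_level_table <- function(spec) {
  bind_rows(lapply(names(spec$items), function(id) {
    it <- spec$items[[id]]
    tibble(item = id, response = it$levels,
           value = as.numeric(it$values),
           favorable = it$levels == it$favorable,
           at_risk = if (!is.null(it$at_risk)) it$levels %in% it$at_risk
                     else FALSE)
  }))
}

as_response_vector <- function(responses) {
  if (is.data.frame(responses)) {
    setNames(as.character(responses$response), responses$item)
  } else {
    r <- unlist(responses)
    setNames(as.character(r), names(r))
  }
}

#' Score one person's responses to an instrument
#'
#' Unknown levels are treated as missing items; by default any missing item
#' makes the instrument score missing. Screen-type instruments (the Hunger
#' Vital Sign) are positive iff any item is endorsed at an at-risk level.
#'
#' @param spec An `instrument_spec`.
#' @param responses Named character vector (or tibble with `item`/`response`)
#'   of item responses.
#' @return Numeric score for `sum`/`mean` scoring, the response level for
#'   `categorical`, `"positive"`/`"negative"` for `screen`; `NA` when the
#'   instrument is missing.
#' @export
score_instrument <- function(spec, responses) {
  stopifnot(inherits(spec, "instrument_spec"))
  r <- as_response_vector(responses)
  ids <- names(spec$items)
  lv <- lapply(ids, function(id) spec$items[[id]])
  resp <- r[ids]
  known <- mapply(function(x, it) !is.na(x) && x %in% it$levels, resp, lv)
  if (spec$scoring == "screen") {
    if (!any(known)) return(NA_character_)
    endorsed <- mapply(function(x, it) {
      !is.na(x) && !is.null(it$at_risk) && x %in% it$at_risk
    }, resp, lv)
    if (any(endorsed)) return("positive")
    if (all(known)) return("negative")
    return(NA_character_)
  }
  if (!all(known)) {
    if (spec$scoring == "categorical" && length(ids) == 1) return(NA_character_)
    return(NA_real_)
  }
  if (spec$scoring == "categorical") {
    return(unname(resp[1]))
  }
  vals <- mapply(function(x, it) it$values[match(x, it$levels)], resp, lv)
  if (spec$scoring == "sum") sum(vals) else mean(vals)
}

#' Top-box conversion of one person's responses
#'
#' @inheritParams score_instrument
#' @return `1` iff every item is answered at its most favorable level, `0`
#'   if any answered item is less favorable or any item is missing while
#'   others are answered, `NA` iff all items are missing. `1` means *no*
#'   barrier.
#' @export
top_box <- function(spec, responses) {
  stopifnot(inherits(spec, "instrument_spec"))
  r <- as_response_vector(responses)
  ids <- names(spec$items)
  resp <- r[ids]
  known <- mapply(function(x, it) !is.na(x) && x %in% it$levels,
                  resp, spec$items[ids])
  if (!any(known)) return(NA_integer_)
  if (!all(known)) return(0L)
  fav <- mapply(function(x, it) x == it$favorable, resp, spec$items[ids])
  as.integer(all(fav))
}

#' Composite unmet-social-need flag
#'
#' Any endorsed component (food insecurity, housing instability, delayed or
#' can't afford care) dominates; absence can only be certified when all
#' three components are observed absent.
#'
#' @param food,housing,care Vectors in \{0, 1, NA\}.
#' @return Integer vector: 1 if any component is 1; 0 if all three are 0;
#'   NA otherwise. Symmetric in its three arguments.
#' @export
composite_unmet_need <- function(food, housing, care) {
  any1 <- (coalesce(food, 0L) == 1L) | (coalesce(housing, 0L) == 1L) |
    (coalesce(care, 0L) == 1L)
  all0 <- !is.na(food) & !is.na(housing) & !is.na(care) &
    food == 0L & housing == 0L & care == 0L
  ifelse(any1, 1L, ifelse(all0, 0L, NA_integer_))
}

#' Assign deprivation-index quintiles
#'
#' Boundaries default to the 20/40/60/80th percentiles of the analyzed
#' cohort's non-missing values; quintile 5 is the most deprived (highest
#' index) and ties at a boundary go to the lower quintile. Fixed external
#' cut points can be supplied instead of cohort-empirical ones.
#'
#' @param index_values Numeric vector (NA allowed).
#' @param cutpoints Optional numeric vector of 4 increasing boundaries.
#' @return Integer vector of quintiles 1..5 (NA preserved).
#' @export
assign_quintiles <- function(index_values, cutpoints = NULL) {
  x <- index_values
  nn <- x[!is.na(x)]
  if (is.null(cutpoints)) {
    if (length(nn) < 5) stop("need at least 5 non-missing index values",
                             call. = FALSE)
    if (length(unique(nn)) == 1) {
      warning("all index values identical; assigning quintile 1 to all",
              call. = FALSE)
      out <- rep(NA_integer_, length(x))
      out[!is.na(x)] <- 1L
      return(out)
    }
    cutpoints <- unname(quantile(nn, c(0.2, 0.4, 0.6, 0.8), names = FALSE))
  }
  stopifnot(length(cutpoints) == 4)
  q <- 1L + (x > cutpoints[1]) + (x > cutpoints[2]) + (x > cutpoints[3]) +
    (x > cutpoints[4])
  as.integer(q)
}

#' Fold enrichment of a barrier across deprivation quintiles
#'
#' The within-variable proportions cancel, so the ratio of the fifth (most
#' deprived) quintile's share to the first quintile's share reduces to
#' `counts[5] / counts[1]`. Scale-invariant in the counts.
#'
#' @param counts Five non-negative barrier counts, quintile 1 to 5.
#' @return The fold enrichment; when quintile 1 has zero count the value is
#'   `NA` with attribute `reason = "undefined (zero reference)"`.
#' @export
fold_enrichment <- function(counts) {
  stopifnot(length(counts) == 5, all(counts >= 0, na.rm = TRUE))
  if (sum(counts) == 0) stop("all quintile counts are zero", call. = FALSE)
  if (counts[1] == 0) {
    return(structure(NA_real_, reason = "undefined (zero reference)"))
  }
  counts[5] / counts[1]
}

## ---- cohort-level scoring -------------------------------------------------

## Vectorised per-instrument scoring over the long survey table.
score_instrument_cohort <- function(surveys, spec) {
  rows <- surveys[surveys$instrument == spec$name, , drop = FALSE]
  n_items <- length(spec$items)
  empty <- tibble(person_id = character(), score_num = numeric(),
                  score_chr = character(), top_box = integer(),
                  barrier = integer())
  if (nrow(rows) == 0) return(empty)
  lut <- instrument_level_table(spec)
  rows <- left_join(rows, lut, by = c("item", "response"))
  ## unknown levels behave as missing items
  rows$known <- !is.na(rows$favorable)
  pf <- factor(rows$person_id)
  rs <- function(x) as.vector(rowsum(as.numeric(x), pf))
  n_known <- rs(rows$known)
  agg <- tibble(
    person_id = levels(pf),
    n_known = n_known,
    all_fav = rs(rows$known & rows$favorable %in% TRUE) == n_items &
      n_known == n_items,
    any_at_risk = rs(rows$known & rows$at_risk %in% TRUE) > 0,
    sum_val = rs(ifelse(rows$known, rows$value, 0)),
    any_barrier_level = if (!is.null(spec$barrier_levels))
      rs(rows$known & rows$response %in% spec$barrier_levels) > 0
    else rep(FALSE, nlevels(pf))
  )
  agg$mean_val <- ifelse(agg$n_known > 0, agg$sum_val / agg$n_known, NA_real_)
  known_rows <- rows[rows$known, , drop = FALSE]
  first_idx <- !duplicated(known_rows$person_id)
  agg$first_level <- known_rows$response[first_idx][
    match(agg$person_id, known_rows$person_id[first_idx])]
  agg$top_box <- ifelse(agg$n_known == 0, NA_integer_,
                        as.integer(agg$n_known == n_items & agg$all_fav))
  complete <- agg$n_known == n_items
  agg$score_num <- NA_real_
  agg$score_chr <- NA_character_
  if (spec$scoring == "sum") agg$score_num[complete] <- agg$sum_val[complete]
  if (spec$scoring == "mean") agg$score_num[complete] <- agg$mean_val[complete]
  if (spec$scoring == "categorical") {
    agg$score_chr[complete] <- agg$first_level[complete]
  }
  if (spec$scoring == "screen") {
    agg$score_chr <- ifelse(agg$any_at_risk & agg$n_known > 0, "positive",
                            ifelse(agg$n_known == n_items, "negative",
                                   NA_character_))
  }
  ## barrier orientation: 1 = barrier present
  agg$barrier <- if (spec$scoring == "screen") {
    ifelse(is.na(agg$score_chr), NA_integer_,
           as.integer(agg$score_chr == "positive"))
  } else if (!is.null(spec$barrier_levels)) {
    ifelse(agg$any_barrier_level, 1L,
           ifelse(agg$n_known == n_items, 0L, NA_integer_))
  } else {
    ifelse(is.na(agg$top_box), NA_integer_, 1L - agg$top_box)
  }
  agg[, c("person_id", "score_num", "score_chr", "top_box", "barrier")]
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Score all instruments and build per-person survey profiles
#'
#' Scores each instrument, binarizes barriers (top-box complement for scored
#' scales, screen positivity for the Hunger Vital Sign, designated barrier
#' levels for categorical items), builds the composite unmet-social-need
#' flag from food insecurity, housing instability, and delayed/can't-afford
#' care, and assigns deprivation quintiles on the cohort's empirical index
#' distribution.
#'
#' @param ds An `ehr_dataset` with a `surveys` table, or `NULL` if `surveys`
#'   and `persons` are given directly.
#' @param instruments Named list of `instrument_spec`s
#'   (default [default_instruments()]).
#' @param surveys,persons Optional explicit tables overriding `ds`.
#' @param quintile_cutpoints Optional fixed cut points for
#'   [assign_quintiles()].
#' @return A tibble with one row per person: instrument scores, per-variable
#'   barrier flags (`barrier_*`), the component flags `food_insecurity`,
#'   `housing_instability`, `delayed_or_cant_afford_care`,
#'   `unmet_social_need`, categorical levels for income/education/insurance/
#'   employment, and `deprivation_quintile`.
#' @export
score_survey_profiles <- function(ds = NULL, instruments = default_instruments(),
                                  surveys = NULL, persons = NULL,
                                  quintile_cutpoints = NULL) {
  if (!is.null(ds)) {
    stopifnot(inherits(ds, "ehr_dataset"))
    surveys <- surveys %||% ds$surveys
    persons <- persons %||% ds$persons
  }
  if (is.null(surveys)) stop("no survey responses available", call. = FALSE)
  profiles <- tibble(person_id = persons$person_id)
  for (nm in names(instruments)) {
    spec <- instruments[[nm]]
    sc <- score_instrument_cohort(surveys, spec)
    keep <- tibble(person_id = sc$person_id)
    if (spec$scoring %in% c("sum", "mean")) {
      keep[[nm]] <- sc$score_num
    } else {
      keep[[nm]] <- sc$score_chr
    }
    keep[[paste0("barrier_", nm)]] <- sc$barrier
    profiles <- left_join(profiles, keep, by = "person_id")
  }
  profiles$food_insecurity <- profiles$barrier_hunger_vital_sign
  profiles$housing_instability_flag <- profiles$barrier_housing_instability
  profiles$delayed_or_cant_afford_care_flag <-
    profiles$barrier_delayed_or_cant_afford_care
  profiles$unmet_social_need <- composite_unmet_need(
    profiles$food_insecurity, profiles$housing_instability_flag,
    profiles$delayed_or_cant_afford_care_flag)
  if (!is.null(persons$deprivation_index) &&
      sum(!is.na(persons$deprivation_index)) >= 5) {
    profiles$deprivation_quintile <- assign_quintiles(
      persons$deprivation_index, quintile_cutpoints)
  } else {
    profiles$deprivation_quintile <- NA_integer_
  }
  profiles
}

#' Within-variable barrier proportions by deprivation quintile
#'
#' For each barrier variable, divides the barrier count in each quintile by
#' the variable's total barrier count across quintiles (the heatmap of the
#' quintile-distribution output), and reports the fold enrichment
#' `count[Q5] / count[Q1]`.
#'
#' @param profiles Output of [score_survey_profiles()].
#' @param variables Barrier variables to tabulate (default: the twelve
#'   standard ones).
#' @return A list with `heatmap` (tibble: variable, quintile, count,
#'   proportion) and `enrichment` (tibble: variable, counts q1..q5,
#'   fold_enrichment, note).
#' @export
barrier_enrichment <- function(profiles, variables = BARRIER_VARIABLES) {
  stopifnot("deprivation_quintile" %in% names(profiles))
  heat <- list()
  enr <- list()
  for (v in variables) {
    col <- paste0("barrier_", v)
    if (!col %in% names(profiles)) next
    ok <- !is.na(profiles[[col]]) & !is.na(profiles$deprivation_quintile)
    counts <- vapply(1:5, function(q) {
      sum(profiles[[col]][ok] == 1L & profiles$deprivation_quintile[ok] == q)
    }, numeric(1))
    total <- sum(counts)
    heat[[v]] <- tibble(variable = v, quintile = 1:5, count = counts,
                        proportion = if (total > 0) counts / total
                                     else rep(NA_real_, 5))
    fe <- if (total > 0) fold_enrichment(counts) else NA_real_
    enr[[v]] <- tibble(variable = v, q1 = counts[1], q2 = counts[2],
                       q3 = counts[3], q4 = counts[4], q5 = counts[5],
                       fold_enrichment = as.numeric(fe),
                       note = attr(fe, "reason") %||% NA_character_)
  }
  list(heatmap = bind_rows(heat), enrichment = bind_rows(enr))
}

#' Load instrument definitions from a YAML file
#'
#' @param path YAML file; defaults to the definitions shipped with the
#'   package (Hunger Vital Sign, Brief Health Literacy Screen, Ross-Mirowsky
#'   neighborhood disorder subscale, modified MOS Social Support Survey,
#'   housing instability/quality items, delayed or can't-afford-care items,
#'   insurance, income, education, English proficiency, employment).
#' @return Named list of `instrument_spec`s.
#' @export
load_instruments <- function(path = system.file("extdata", "instruments.yaml",
                                                package = "divertiphen")) {
  if (!file.exists(path)) stop("instrument file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$instruments)) {
    stop("configuration error: no 'instruments' block in ", path, call. = FALSE)
  }
  out <- lapply(names(cfg$instruments), function(nm) {
    blk <- cfg$instruments[[nm]]
    instrument_spec(nm, blk$scoring, blk$items,
                    barrier_levels = unlist(blk$barrier_levels))
  })
  setNames(out, names(cfg$instruments))
}

#' The instrument definitions shipped with the package
#' @return Named list of `instrument_spec`s.
#' @export
default_instruments <- function() {
  load_instruments()
}
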