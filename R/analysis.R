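## Descriptive cohort tables with small-cell suppression, group-comparison
## tests, bagged-tree imputation, near-zero-variance and correlation filters,
## the adjusted interaction logistic model for severe-versus-diverticulosis
## disease, and the sensitivity-analysis driver.

## ---- cohort tables --------------------------------------------------------

#' Build a descriptive cohort table with group comparisons
#'
#' Continuous variables are summarised as median (IQR) and compared with the
#' Kruskal-Wallis rank-sum test (Wilcoxon rank-sum for two groups);
#' categorical variables as frequency (percent of the variable's non-missing
#' denominator within each group) with Pearson's chi-squared test. Counts
#' between 1 and the suppression threshold (default 20) are flagged for
#' suppression; internal computation always uses true counts, and
#' suppression only affects displayed output ([apply_suppression()],
#' [format_cohort_table()]). Zero counts are displayed: the masking exists to
#' protect small non-zero cells.
#'
#' @param frame Per-person analysis tibble.
#' @param group Name of the grouping column.
#' @param variables Character vector of columns to summarise (default: all
#'   except the group and `person_id`). Numeric columns whose non-missing
#'   values are all 0/1 are treated as categorical.
#' @param suppression_threshold Cells with `1 <= n <= threshold` are flagged.
#' @return A `cohort_table`: list with `cells`, `tests`, `group`, and
#'   `suppression_threshold`.
#' @export
build_cohort_table <- function(frame, group = "phenotype", variables = NULL,
                               suppression_threshold = 20) {
  stopifnot(group %in% names(frame))
  g <- droplevels(factor(frame[[group]]))
  if (is.null(variables)) {
    variables <- setdiff(names(frame), c(group, "person_id"))
  }
  groups <- levels(g)
  cells <- list(); tests <- list()
  for (v in variables) {
    x <- frame[[v]]
    if (all(is.na(x))) {
      cells[[v]] <- tibble(variable = v, level = NA_character_,
                           group = groups, n = NA_integer_, denom = NA_integer_,
                           pct = NA_real_, median = NA_real_, q1 = NA_real_,
                           q3 = NA_real_, suppressed = FALSE,
                           note = "all values missing")
      tests[[v]] <- tibble(variable = v, test = NA_character_,
                           statistic = NA_real_, p = NA_real_)
      next
    }
    binaryish <- is.numeric(x) && all(na.omit(unique(x)) %in% c(0, 1))
    if (is.numeric(x) && !binaryish) {
      cells[[v]] <- bind_rows(lapply(groups, function(gr) {
        xv <- x[g == gr & !is.na(x)]
        q <- if (length(xv) > 0) quantile(xv, c(0.25, 0.5, 0.75), names = FALSE)
             else rep(NA_real_, 3)
        tibble(variable = v, level = NA_character_, group = gr,
               n = length(xv), denom = length(xv), pct = NA_real_,
               median = q[2], q1 = q[1], q3 = q[3], suppressed = FALSE,
               note = NA_character_)
      }))
      ok <- !is.na(x) & !is.na(g)
      tst <- if (length(groups) == 2) {
        w <- suppressWarnings(wilcox.test(x[ok] ~ droplevels(g[ok])))
        tibble(variable = v, test = "Wilcoxon rank-sum",
               statistic = unname(w$statistic), p = w$p.value)
      } else {
        k <- kruskal.test(x[ok], droplevels(g[ok]))
        tibble(variable = v, test = "Kruskal-Wallis",
               statistic = unname(k$statistic), p = k$p.value)
      }
      tests[[v]] <- tst
    } else {
      xf <- factor(x)
      tab <- table(g, xf)
      denom <- rowSums(tab)
      cells[[v]] <- bind_rows(lapply(levels(xf), function(lev) {
        n_cell <- as.integer(tab[groups, lev])
        dn <- as.integer(denom[groups])
        tibble(variable = v, level = lev, group = groups,
               n = n_cell, denom = dn,
               pct = 100 * n_cell / ifelse(dn > 0, dn, NA_integer_),
               median = NA_real_, q1 = NA_real_, q3 = NA_real_,
               suppressed = FALSE, note = NA_character_)
      }))
      tst <- tryCatch({
        ch <- suppressWarnings(chisq.test(tab))
        tibble(variable = v, test = "Pearson chi-squared",
               statistic = unname(ch$statistic), p = ch$p.value)
      }, error = function(e) tibble(variable = v, test = "Pearson chi-squared",
                                    statistic = NA_real_, p = NA_real_))
      tests[[v]] <- tst
    }
  }
  cells <- bind_rows(cells)
  cells$suppressed <- !is.na(cells$n) & cells$n >= 1 &
    cells$n <= suppression_threshold
  structure(list(cells = cells, tests = bind_rows(tests), group = group,
                 suppression_threshold = suppression_threshold),
            class = "cohort_table")
}

#' Mask suppressed cells in a cohort table
#'
#' Replaces counts and percentages of flagged cells with `NA`. Idempotent:
#' suppressing an already-suppressed table changes nothing.
#'
#' @param ct A `cohort_table`.
#' @return The table with masked cell values.
#' @export
apply_suppression <- function(ct) {
  stopifnot(inherits(ct, "cohort_table"))
  s <- ct$cells$suppressed
  ct$cells$n[s] <- NA_integer_
  ct$cells$pct[s] <- NA_real_
  ct
}

#' Format a cohort table for display
#'
#' @param ct A `cohort_table`.
#' @return A tibble with one formatted column per group; suppressed cells
#'   print as `"—"` (values `<=` the threshold are not shown).
#' @export
format_cohort_table <- function(ct) {
  stopifnot(inherits(ct, "cohort_table"))
  cells <- ct$cells
  cells$text <- ifelse(cells$suppressed, "—",
                       ifelse(!is.na(cells$median),
                              sprintf("%.1f (%.1f, %.1f)", cells$median,
                                      cells$q1, cells$q3),
                              ifelse(is.na(cells$n), "",
                                     sprintf("%d (%.1f%%)", cells$n,
                                             cells$pct))))
  wide <- pivot_wider(cells[, c("variable", "level", "group", "text")],
                      names_from = "group", values_from = "text")
  left_join(wide, ct$tests[, c("variable", "test", "p")], by = "variable")
}

## ---- imputation -----------------------------------------------------------

#' Impute covariates with bagged regression/classification trees
#'
#' Covariates with a missing fraction strictly below `max_missing_frac`
#' (default 0.20) are imputed by an ensemble of bootstrap-aggregated
#' decision trees trained on the complete covariates; covariates at or above
#' the threshold are left untouched and flagged. The outcome and exposure
#' are never passed to this function by the model driver.
#'
#' @param frame Analysis tibble.
#' @param covariates Columns eligible for imputation.
#' @param max_missing_frac Threshold missing fraction (default 0.20).
#' @param n_trees Trees per ensemble (default 25).
#' @param seed Optional seed.
#' @return List with `frame` (imputed) and `report` (tibble: variable,
#'   missing_frac, status, method).
#' @export
impute_covariates <- function(frame, covariates = NULL,
                              max_missing_frac = 0.20, n_trees = 25,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(covariates)) covariates <- names(frame)
  covariates <- intersect(covariates, names(frame))
  miss_frac <- unname(vapply(covariates, function(v) mean(is.na(frame[[v]])),
                             numeric(1)))
  complete_vars <- covariates[miss_frac == 0]
  report <- tibble(variable = covariates, missing_frac = miss_frac,
                   status = ifelse(miss_frac == 0, "complete",
                                   ifelse(miss_frac < max_missing_frac,
                                          "imputed", "skipped_threshold")),
                   method = NA_character_)
  targets <- covariates[miss_frac > 0 & miss_frac < max_missing_frac]
  for (v in targets) {
    y <- frame[[v]]
    obs <- !is.na(y)
    predictors <- setdiff(complete_vars, v)
    if (length(predictors) == 0) {
      ## no complete predictor: median/mode fallback
      warning("no complete predictors; falling back to median/mode for ", v,
              call. = FALSE)
      fill <- if (is.numeric(y)) median(y[obs]) else names(which.max(table(y[obs])))
      frame[[v]][!obs] <- fill
      report$method[report$variable == v] <- "median_mode_fallback"
      next
    }
    dat <- frame[, predictors, drop = FALSE]
    dat <- as.data.frame(lapply(dat, function(col) {
      if (is.character(col)) factor(col) else col
    }))
    is_num <- is.numeric(y)
    dat$.target <- if (is_num) y else factor(y)
    train_all <- dat[obs, , drop = FALSE]
    newdata <- dat[!obs, predictors, drop = FALSE]
    preds <- matrix(NA_character_, nrow = sum(!obs), ncol = n_trees)
    num_preds <- matrix(NA_real_, nrow = sum(!obs), ncol = n_trees)
    for (b in seq_len(n_trees)) {
      boot <- train_all[sample.int(nrow(train_all), replace = TRUE), ,
                        drop = FALSE]
      fit <- rpart::rpart(.target ~ ., data = boot,
                          method = if (is_num) "anova" else "class",
                          control = rpart::rpart.control(cp = 0.001,
                                                         minbucket = 10))
      if (is_num) {
        num_preds[, b] <- predict(fit, newdata)
      } else {
        preds[, b] <- as.character(predict(fit, newdata, type = "class"))
      }
    }
    if (is_num) {
      frame[[v]][!obs] <- rowMeans(num_preds)
    } else {
      vote <- apply(preds, 1, function(r) names(which.max(table(r))))
      if (is.factor(y)) vote <- factor(vote, levels = levels(y))
      frame[[v]][!obs] <- vote
    }
    report$method[report$variable == v] <- "bagged_trees"
  }
  list(frame = frame, report = report)
}

## ---- predictor filters ----------------------------------------------------

#' Filter near-zero-variance and highly correlated predictors
#'
#' Numeric columns with zero variance are dropped. A factor whose dominant
#' level outnumbers its second level by more than `nzv_freq_ratio` is
#' near-constant and dropped; individual factor levels below
#' `nzv_prevalence` are collapsed into the factor's reference (first) level.
#' Among the numeric/indicator expansion, one member of any pair with
#' absolute correlation above `corr_threshold` is removed (the later column;
#' both members are reported).
#'
#' @param frame Covariate tibble (factors and numerics).
#' @param nzv_prevalence Minimum level prevalence (default 0.01).
#' @param nzv_freq_ratio Maximum dominant/second frequency ratio (default 19).
#' @param corr_threshold Absolute-correlation cutoff (default 0.90).
#' @param exempt Columns never dropped (levels may still be collapsed).
#' @return List with `frame` and `dropped` (tibble: column, level, reason).
#' @export
filter_predictors <- function(frame, nzv_prevalence = 0.01,
                              nzv_freq_ratio = 19, corr_threshold = 0.90,
                              exempt = character()) {
  dropped <- list()
  note <- function(column, level, reason) {
    dropped[[length(dropped) + 1]] <<- tibble(column = column, level = level,
                                              reason = reason)
  }
  for (v in setdiff(names(frame), exempt)) {
    x <- frame[[v]]
    if (is.numeric(x)) {
      xs <- x[!is.na(x)]
      if (length(unique(xs)) <= 1) {
        note(v, NA_character_, "zero variance")
        frame[[v]] <- NULL
      }
    } else {
      xf <- droplevels(factor(x))
      tab <- sort(table(xf), decreasing = TRUE)
      if (length(tab) <= 1) {
        note(v, NA_character_, "single level")
        frame[[v]] <- NULL
        next
      }
      if (tab[1] / tab[2] > nzv_freq_ratio) {
        note(v, NA_character_,
             sprintf("near-zero variance (freq ratio %.1f > %.0f)",
                     tab[1] / tab[2], nzv_freq_ratio))
        frame[[v]] <- NULL
        next
      }
      prev <- table(xf) / length(xf[!is.na(xf)])
      rare <- names(prev)[prev < nzv_prevalence & prev > 0]
      rare <- setdiff(rare, levels(xf)[1])  # never collapse the reference
      if (length(rare) > 0) {
        for (lev in rare) {
          note(v, lev, sprintf("level prevalence %.2f%% < %.0f%%; collapsed to reference",
                               100 * prev[[lev]], 100 * nzv_prevalence))
        }
        x2 <- as.character(xf)
        x2[x2 %in% rare] <- levels(xf)[1]
        frame[[v]] <- factor(x2, levels = setdiff(levels(xf), rare))
      }
    }
  }
  ## pairwise-correlation filter on the numeric/indicator expansion
  num <- list()
  owner <- character()
  for (v in names(frame)) {
    x <- frame[[v]]
    if (is.numeric(x)) {
      num[[v]] <- as.numeric(x)
      owner[v] <- v
    } else {
      xf <- factor(x)
      for (lev in levels(xf)[-1]) {
        nm <- paste0(v, ":", lev)
        num[[nm]] <- as.numeric(xf == lev)
        owner[nm] <- v
      }
    }
  }
  if (length(num) >= 2) {
    M <- do.call(cbind, num)
    cm <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))
    cm[is.na(cm)] <- 0
    cols <- colnames(M)
    removed <- character()
    for (i in seq_along(cols)) {
      for (j in seq_along(cols)) {
        if (j <= i) next
        if (owner[cols[i]] == owner[cols[j]]) next
        if (cols[j] %in% removed || cols[i] %in% removed) next
        if (abs(cm[i, j]) > corr_threshold) {
          victim <- owner[cols[j]]  # drop the later column
          if (victim %in% exempt || !(victim %in% names(frame))) next
          note(victim, NA_character_,
               sprintf("|r| = %.3f with '%s' > %.2f", abs(cm[i, j]),
                       owner[cols[i]], corr_threshold))
          frame[[victim]] <- NULL
          removed <- c(removed, cols[owner[cols] == victim])
        }
      }
    }
  }
  list(frame = frame,
       dropped = if (length(dropped) > 0) bind_rows(dropped)
                 else tibble(column = character(), level = character(),
                             reason = character()))
}

#' Variance inflation factors from a design matrix
#'
#' Classical VIF: `1 / (1 - R^2)` of each column regressed on the others
#' (plus an intercept). Exactly 1 for an orthogonal design.
#'
#' @param X Numeric design matrix without an intercept column.
#' @return Named numeric vector of VIFs.
#' @export
design_vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) return(setNames(rep(1, ncol(X)), colnames(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- lm.fit(Z, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss < .Machine$double.eps) return(NA_real_)
    r2 <- 1 - rss / tss
    1 / max(1 - r2, .Machine$double.eps)
  }, numeric(1))
  setNames(out, colnames(X))
}

## ---- the adjusted model ---------------------------------------------------

relevel_model_factors <- function(frame) {
  as_factor <- function(x, levels) {
    f <- factor(as.character(x), levels = levels)
    droplevels(f)
  }
  if (!is.factor(frame$sex_at_birth) || levels(frame$sex_at_birth)[1] != "female") {
    frame$sex_at_birth <- as_factor(frame$sex_at_birth,
                                    c("female", "male", "other", "unknown"))
  }
  frame$income <- as_factor(frame$income, INCOME_LEVELS)
  frame$education <- as_factor(frame$education, EDUCATION_LEVELS)
  frame$insurance <- as_factor(frame$insurance, INSURANCE_LEVELS)
  frame$unmet_social_need <- as.numeric(frame$unmet_social_need)
  frame
}

#' Fit the adjusted severity model
#'
#' Maximum-likelihood logistic regression of operative/recurrent inpatient
#' diverticulitis versus diverticulosis (the reference outcome; mild and
#' control persons are excluded) on a binary unmet-social-need indicator,
#' age, sex at birth, BMI, Charlson Comorbidity Index, insurance, highest
#' education and annual income, with unmet-need-by-income and
#' unmet-need-by-education interaction terms. Covariates with under 20%
#' missingness are imputed with bagged trees; near-zero-variance levels and
#' |r| > 0.90 predictor pairs are filtered before fitting; VIFs are computed
#' on the pre-interaction design matrix. Reference levels: no unmet need,
#' female, income more than 100k, at least some college, insured.
#'
#' @param frame Tibble with either an `outcome` column (1 =
#'   operative/recurrent) or a `phenotype` column, plus the covariates.
#' @param conf_level Confidence level for the odds-ratio intervals.
#' @param ci_method `"wald"` (default) or `"profile"` likelihood.
#' @param impute,filters Logical switches for the preprocessing stages.
#' @param seed Optional seed for the imputation ensembles.
#' @return A `severity_model`: list with `terms` (term, odds_ratio, ci_low,
#'   ci_high, p), `interaction_p`, `vif`, `n_used`, `n_events`,
#'   `imputation_report`, `dropped_predictors`, `converged` and
#'   `separation_flag` (separation is reported, never silently clipped).
#' @export
fit_severity_model <- function(frame, conf_level = 0.95,
                               ci_method = c("wald", "profile"),
                               impute = TRUE, filters = TRUE, seed = NULL) {
  ci_method <- match.arg(ci_method)
  if (!"outcome" %in% names(frame)) {
    if (!"phenotype" %in% names(frame)) {
      stop("frame needs an 'outcome' or 'phenotype' column", call. = FALSE)
    }
    frame <- frame[frame$phenotype %in% c("diverticulosis",
                                          "operative_or_recurrent"), ,
                   drop = FALSE]
    frame$outcome <- as.integer(frame$phenotype == "operative_or_recurrent")
  }
  covars <- c("age", "sex_at_birth", "bmi", "charlson_index", "insurance",
              "education", "income")
  missing_cols <- setdiff(c("outcome", "unmet_social_need", covars),
                          names(frame))
  if (length(missing_cols) > 0) {
    stop("frame lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  frame <- relevel_model_factors(frame)

  imputation_report <- NULL
  if (impute) {
    imp <- impute_covariates(frame, covars, seed = seed)
    frame <- imp$frame
    imputation_report <- imp$report
  }
  dropped <- tibble(column = character(), level = character(),
                    reason = character())
  if (filters) {
    fp <- filter_predictors(frame[, covars, drop = FALSE])
    frame[covars] <- NULL
    frame <- bind_cols(frame, fp$frame)
    covars <- names(fp$frame)
    dropped <- fp$dropped
  }
  keep <- complete.cases(frame[, c("outcome", "unmet_social_need", covars),
                               drop = FALSE])
  frame <- frame[keep, , drop = FALSE]
  n_used <- nrow(frame)
  n_events <- sum(frame$outcome == 1)

  main_rhs <- paste(c("unmet_social_need", covars), collapse = " + ")
  inter <- c(if ("income" %in% covars && nlevels(frame$income) > 1)
               "unmet_social_need:income",
             if ("education" %in% covars && nlevels(frame$education) > 1)
               "unmet_social_need:education")
  fml <- as.formula(paste("outcome ~", paste(c(main_rhs, inter),
                                             collapse = " + ")))
  ## VIFs are assessed on the pre-interaction design
  X <- model.matrix(as.formula(paste("~", main_rhs)), data = frame)[, -1,
                                                                    drop = FALSE]
  vifs <- design_vif(X)

  fit <- suppressWarnings(glm(fml, data = frame, family = binomial()))
  cf <- summary(fit)$coefficients
  separation <- !fit$converged || any(abs(coef(fit)) > 15, na.rm = TRUE) ||
    any(cf[, "Std. Error"] > 100)
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  if (ci_method == "wald") {
    lo <- est - z * se
    hi <- est + z * se
  } else {
    ci <- suppressWarnings(suppressMessages(confint(fit, level = conf_level)))
    lo <- ci[, 1]; hi <- ci[, 2]
  }
  terms_tbl <- tibble(term = rownames(cf), estimate = unname(est),
                      odds_ratio = exp(unname(est)),
                      ci_low = exp(unname(lo)), ci_high = exp(unname(hi)),
                      p = unname(cf[, "Pr(>|z|)"]))
  terms_tbl <- terms_tbl[terms_tbl$term != "(Intercept)", , drop = FALSE]
  interaction_p <- terms_tbl[grepl(":", terms_tbl$term),
                             c("term", "p"), drop = FALSE]
  structure(list(terms = terms_tbl, interaction_p = interaction_p,
                 vif = tibble(term = names(vifs), vif = unname(vifs)),
                 n_used = n_used, n_events = n_events,
                 imputation_report = imputation_report,
                 dropped_predictors = dropped,
                 converged = fit$converged, separation_flag = separation,
                 formula = deparse(fml)),
            class = "severity_model")
}

#' @export
print.severity_model <- function(x, ...) {
  cat("<severity_model> n =", x$n_used, "(", x$n_events, "events )\n")
  if (x$separation_flag) cat("  WARNING: possible separation / non-convergence\n")
  main <- x$terms[!grepl(":", x$terms$term), , drop = FALSE]
  for (i in seq_len(nrow(main))) {
    cat(sprintf("  %-55s OR %5.2f [%4.2f-%5.2f] p=%.3g\n", main$term[i],
                main$odds_ratio[i], main$ci_low[i], main$ci_high[i],
                main$p[i]))
  }
  if (nrow(x$interaction_p) > 0) {
    for (i in seq_len(nrow(x$interaction_p))) {
      cat(sprintf("  P_interaction %-45s %.3g\n", x$interaction_p$term[i],
                  x$interaction_p$p[i]))
    }
  }
  invisible(x)
}

#' Join phenotypes, persons and survey profiles into a model frame
#'
#' Age is computed at the inclusion-survey date. Income, education and
#' insurance come from the scored survey profiles; the composite
#' unmet-social-need flag is the exposure.
#'
#' @param assignments Output of [apply_inclusion_window()] (or
#'   [assign_phenotypes()] joined with a `survey_date` column).
#' @param persons Persons tibble.
#' @param profiles Output of [score_survey_profiles()].
#' @return Analysis tibble for [fit_severity_model()] /
#'   [build_cohort_table()].
#' @export
build_analysis_frame <- function(assignments, persons, profiles) {
  x <- assignments |>
    left_join(persons[, c("person_id", "birth_date", "sex_at_birth", "bmi",
                          "charlson_index", "deprivation_index")],
              by = "person_id") |>
    left_join(profiles, by = "person_id")
  ref_date <- if ("survey_date" %in% names(x)) x$survey_date else
    persons$survey_date_earliest[match(x$person_id, persons$person_id)]
  x$age <- floor(as.numeric(ref_date - x$birth_date) / 365.25)
  x$outcome <- ifelse(x$phenotype %in% c("diverticulosis",
                                         "operative_or_recurrent"),
                      as.integer(x$phenotype == "operative_or_recurrent"),
                      NA_integer_)
  x
}

#' Refit the severity model under sensitivity variants
#'
#' Each variant rebuilds the cohort from the raw assignments (inclusion
#' window width and/or inclusion survey), reassembles the frame and refits.
#' Variants whose cohort cannot support the fit are reported as
#' not-estimable rather than erroring.
#'
#' @param assignments Raw output of [assign_phenotypes()].
#' @param persons,profiles As in [build_analysis_frame()].
#' @param variants List of lists with `window_years` and `inclusion_survey`;
#'   the default set mirrors the primary sensitivity analyses (2.5-year
#'   window; healthcare-access and SDOH inclusion surveys).
#' @param ... Passed to [fit_severity_model()].
#' @return A list, one element per variant, each with `variant`, `n_cases`,
#'   and `result` (a `severity_model` or a character note).
#' @export
run_sensitivity <- function(assignments, persons, profiles,
                            variants = list(
                              list(window_years = 2.5,
                                   inclusion_survey = "earliest"),
                              list(window_years = 5,
                                   inclusion_survey = "healthcare_access"),
                              list(window_years = 5,
                                   inclusion_survey = "sdoh")),
                            ...) {
  lapply(variants, function(vt) {
    filtered <- apply_inclusion_window(assignments, persons,
                                       window_years = vt$window_years,
                                       inclusion_survey = vt$inclusion_survey)
    frame <- build_analysis_frame(filtered, persons, profiles)
    modeled <- frame[!is.na(frame$outcome), , drop = FALSE]
    res <- tryCatch(fit_severity_model(modeled, ...),
                    error = function(e) paste("not estimable:",
                                              conditionMessage(e)))
    list(variant = vt, n_cases = nrow(modeled), result = res)
  })
}
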