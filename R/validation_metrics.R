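## Chart-review concordance statistics: per-class PPV/NPV against a
## reference labelling, Cohen's kappa between two raters, percent
## differential classification among reviewers, and seeded per-class chart
## sampling for blinded review.

#' Bundle algorithm assignments with reviewer labels
#'
#' @param assignments Tibble with `person_id` and `algorithm_label` (or a
#'   `phenotype` column, which is renamed).
#' @param reviews Long tibble with `person_id`, `reviewer_id`, `label`.
#' @return A `review_set` object; every record must carry at least one
#'   reviewer label.
#' @export
review_set <- function(assignments, reviews) {
  a <- as_tibble(assignments)
  if (!"algorithm_label" %in% names(a) && "phenotype" %in% names(a)) {
    a$algorithm_label <- a$phenotype
  }
  stopifnot(all(c("person_id", "algorithm_label") %in% names(a)),
            all(c("person_id", "reviewer_id", "label") %in% names(reviews)))
  a$algorithm_label <- as.character(a$algorithm_label)
  reviews <- as_tibble(reviews)
  reviews$label <- as.character(reviews$label)
  missing_review <- setdiff(a$person_id, reviews$person_id)
  if (length(missing_review) > 0) {
    stop("record(s) without any reviewer label: ",
         paste(utils::head(missing_review, 3), collapse = ", "), call. = FALSE)
  }
  structure(list(assignments = a[, c("person_id", "algorithm_label")],
                 reviews = reviews[, c("person_id", "reviewer_id", "label")]),
            class = "review_set")
}

#' Consensus reference labels for a review set
#'
#' Majority vote across reviewers; remaining ties are resolved by the
#' first reviewer's label (reviewers ordered by id) and flagged — the
#' original iterative review-and-discussion consensus process is not
#' mechanizable.
#'
#' @param review A `review_set`.
#' @return Tibble `person_id`, `label`, `tie` (logical flag).
#' @export
consensus_labels <- function(review) {
  stopifnot(inherits(review, "review_set"))
  per_person <- split(review$reviews, review$reviews$person_id)
  label <- vapply(per_person, function(r) {
    tab <- table(r$label)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1) winners else r$label[order(r$reviewer_id)][1]
  }, character(1))
  tie <- vapply(per_person, function(r) {
    tab <- table(r$label)
    length(tab) > 1 && sum(tab == max(tab)) > 1
  }, logical(1))
  tibble(person_id = names(per_person), label = unname(label),
         tie = unname(tie))
}

#' Per-class positive and negative predictive values
#'
#' One-vs-rest for each class in the label alphabet: PPV is computed over the
#' records the algorithm assigned to the class, NPV over those it withheld.
#' Metrics with a zero denominator are reported as `NA` with a reason, never
#' as 0.
#'
#' @param review A `review_set`.
#' @param reference `"consensus"` (default) or a reviewer id whose labels
#'   serve as the reference.
#' @return Tibble with one row per class: `class`, `ppv`, `npv`, confusion
#'   counts `tp`/`fp`/`tn`/`fn`, and `note` naming any undefined metric.
#' @export
per_class_ppv_npv <- function(review, reference = "consensus") {
  stopifnot(inherits(review, "review_set"))
  ref <- if (identical(reference, "consensus")) {
    consensus_labels(review)
  } else {
    r <- review$reviews[review$reviews$reviewer_id == reference, , drop = FALSE]
    if (nrow(r) == 0) stop("unknown reviewer id: ", reference, call. = FALSE)
    tibble(person_id = r$person_id, label = r$label)
  }
  m <- inner_join(review$assignments, ref, by = "person_id")
  classes <- sort(unique(c(m$algorithm_label, m$label)))
  bind_rows(lapply(classes, function(cl) {
    assigned <- m$algorithm_label == cl
    truly <- m$label == cl
    tp <- sum(assigned & truly); fp <- sum(assigned & !truly)
    fn <- sum(!assigned & truly); tn <- sum(!assigned & !truly)
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    note <- c(if (tp + fp == 0) "PPV undefined: class never assigned",
              if (tn + fn == 0) "NPV undefined: class always assigned")
    tibble(class = cl, ppv = ppv, npv = npv, tp = tp, fp = fp, tn = tn,
           fn = fn, note = paste(note, collapse = "; ") %||% "")
  }))
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement from the product of the raters' marginal distributions. When
#' both raters agree everywhere, 1 is returned even if the marginals make
#' `p_e = 1`; `p_e = 1` with imperfect agreement is undefined and flagged.
#'
#' @param labels_a,labels_b Equal-length label vectors (length >= 2) over a
#'   shared category space.
#' @return Kappa in \[-1, 1\]; `NA` with attribute `reason` when undefined.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) >= 2)
  cats <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(labels_a, levels = cats)
  b <- factor(labels_b, levels = cats)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_o >= 1) return(1)
  if (1 - p_e < .Machine$double.eps^0.5) {
    return(structure(NA_real_, reason = "p_e = 1 with imperfect agreement"))
  }
  (p_o - p_e) / (1 - p_e)
}

#' Percent differential classification among reviewers, by class
#'
#' For each algorithm-assigned class, the percentage of records (with at
#' least two reviewers) on which the reviewers disagreed with each other.
#' Single-reviewer records are excluded and counted.
#'
#' @param review A `review_set`.
#' @return Tibble `class`, `n_records`, `n_disagree`, `pct`; attribute
#'   `n_excluded_single_reviewer`.
#' @export
differential_classification_pct <- function(review) {
  stopifnot(inherits(review, "review_set"))
  per_rec <- review$reviews |>
    group_by(.data$person_id) |>
    summarise(n_reviewers = n_distinct(.data$reviewer_id),
              disagree = n_distinct(.data$label) > 1, .groups = "drop")
  m <- inner_join(review$assignments, per_rec, by = "person_id")
  excluded <- sum(m$n_reviewers < 2)
  m <- m[m$n_reviewers >= 2, , drop = FALSE]
  out <- m |>
    group_by(class = .data$algorithm_label) |>
    summarise(n_records = n(), n_disagree = sum(.data$disagree),
              pct = 100 * sum(.data$disagree) / n(), .groups = "drop")
  attr(out, "n_excluded_single_reviewer") <- excluded
  out
}

#' Draw a seeded per-class chart sample for blinded review
#'
#' Uniform sampling without replacement within each class; the returned rows
#' are shuffled so the review order carries no information about the
#' algorithm's label (the label column is retained for later scoring, not
#' for the reviewer's copy).
#'
#' @param assignments Output of [assign_phenotypes()] (or any tibble with
#'   `person_id` and `phenotype`/`algorithm_label`).
#' @param per_class_n Charts per class (classes smaller than this are taken
#'   whole, with a warning).
#' @param seed Integer seed; the same seed reproduces the same sample.
#' @return Tibble `person_id`, `algorithm_label` — a review-set skeleton.
#' @export
sample_for_review <- function(assignments, per_class_n = 200, seed = 1L) {
  a <- as_tibble(assignments)
  if (!"algorithm_label" %in% names(a)) a$algorithm_label <- as.character(a$phenotype)
  set.seed(seed)
  picked <- lapply(split(a, a$algorithm_label), function(g) {
    if (nrow(g) < per_class_n) {
      warning("class '", g$algorithm_label[1], "' has only ", nrow(g),
              " record(s); sampling all of them", call. = FALSE)
      g
    } else {
      g[sample.int(nrow(g), per_class_n), , drop = FALSE]
    }
  })
  out <- bind_rows(picked)
  out <- out[sample.int(nrow(out)), c("person_id", "algorithm_label"),
             drop = FALSE]
  out
}
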