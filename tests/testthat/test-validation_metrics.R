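mk_review <- function(algorithm, reference, extra_reviewers = list()) {
  n <- length(algorithm)
  ids <- sprintf("C%03d", seq_len(n))
  reviews <- tibble::tibble(person_id = ids, reviewer_id = "R1",
                            label = reference)
  for (nm in names(extra_reviewers)) {
    reviews <- dplyr::bind_rows(reviews, tibble::tibble(
      person_id = ids, reviewer_id = nm, label = extra_reviewers[[nm]]))
  }
  review_set(tibble::tibble(person_id = ids, algorithm_label = algorithm),
             reviews)
}

test_that("PPV/NPV reproduce a hand-tallied confusion matrix", {
  ## class X: algorithm assigns 10 (9 truly X), withholds 90 (88 truly not X)
  algorithm <- c(rep("X", 10), rep("Y", 90))
  reference <- c(rep("X", 9), "Y", rep("Y", 88), "X", "X")
  res <- per_class_ppv_npv(mk_review(algorithm, reference), reference = "R1")
  x <- res[res$class == "X", ]
  expect_equal(x$ppv, 0.90)
  expect_equal(x$npv, 88 / 90, tolerance = 1e-12)
  expect_equal(x$tp + x$fp + x$tn + x$fn, 100)
  ## perfect agreement gives (1, 1)
  perfect <- per_class_ppv_npv(mk_review(algorithm, algorithm), "R1")
  expect_true(all(perfect$ppv == 1 & perfect$npv == 1))
})

test_that("zero denominators are reported as undefined, not zero", {
  algorithm <- rep("A", 10)
  reference <- c(rep("A", 8), "B", "B")
  res <- per_class_ppv_npv(mk_review(algorithm, reference), "R1")
  b <- res[res$class == "B", ]
  expect_true(is.na(b$ppv))
  expect_match(b$note, "PPV undefined")
  expect_false(is.na(b$npv))
  a <- res[res$class == "A", ]
  expect_true(is.na(a$npv))  # class always assigned
})

test_that("vectorised PPV/NPV agrees with a brute-force loop on 100 fixtures", {
  classes <- divertiphen:::PHENOTYPE_LEVELS[1:4]
  for (s in 1:100) {
    set.seed(s)
    algorithm <- sample(classes, 50, TRUE)
    reference <- ifelse(runif(50) < 0.8, algorithm, sample(classes, 50, TRUE))
    res <- per_class_ppv_npv(mk_review(algorithm, reference), "R1")
    for (cl in unique(algorithm)) {
      bf <- brute_force_ppv_npv(algorithm, reference, cl)
      row <- res[res$class == cl, ]
      expect_equal(row$ppv, bf$ppv)
      expect_equal(row$npv, bf$npv)
    }
  }
})

test_that("kappa matches hand computation and its conventions", {
  expect_equal(cohens_kappa(c("A", "B", "A"), c("A", "B", "A")), 1)
  ## p_o = 0.75, p_e = 0.5 -> kappa = 0.5
  expect_equal(cohens_kappa(c("A", "A", "B", "B"), c("A", "B", "B", "B")), 0.5)
  ## disjoint marginals with p_e < 1: kappa can go negative
  expect_lt(cohens_kappa(c("A", "B"), c("B", "A")), 0)
  ## degenerate marginals: all one category on both sides -> 1 by convention
  ## (p_e = 1 with imperfect agreement cannot occur: p_e = 1 forces both
  ## raters onto the same single category, hence p_o = 1)
  expect_equal(cohens_kappa(c("A", "A"), c("A", "A")), 1)
  ## one constant rater, agreement at chance level -> kappa 0
  expect_equal(cohens_kappa(c("A", "A", "A"), c("A", "A", "B")), 0)
})

test_that("kappa tends to zero for independent labels", {
  set.seed(99)
  a <- sample(c("X", "Y"), 10000, TRUE)
  b <- sample(c("X", "Y"), 10000, TRUE)
  expect_lt(abs(cohens_kappa(a, b)), 0.05)
})

test_that("kappa is invariant under relabeling of the class alphabet", {
  set.seed(3)
  a <- sample(letters[1:4], 200, TRUE)
  b <- ifelse(runif(200) < 0.7, a, sample(letters[1:4], 200, TRUE))
  k1 <- cohens_kappa(a, b)
  perm <- setNames(c("w", "x", "y", "z"), letters[1:4])
  expect_equal(cohens_kappa(perm[a], perm[b]), k1)
})

test_that("differential classification recovers planted disagreement rates", {
  ## 50 records in one class with exactly 1 planted disagreement -> 2%
  algorithm <- rep("mild", 50)
  r1 <- rep("mild", 50)
  r2 <- r1; r2[17] <- "severe"
  res <- differential_classification_pct(
    mk_review(algorithm, r1, list(R2 = r2)))
  expect_equal(res$pct, 2.0)
  ## all agree -> 0% in every class
  res0 <- differential_classification_pct(
    mk_review(c(rep("a", 30), rep("b", 20)), rep("x", 50),
              list(R2 = rep("x", 50))))
  expect_true(all(res0$pct == 0))
  ## planted per-class rates on a 4-class set
  set.seed(11)
  algorithm <- rep(c("c1", "c2", "c3", "c4"), each = 50)
  r1 <- algorithm
  rates <- c(c1 = 0.10, c2 = 0.02, c3 = 0.20, c4 = 0)
  flip <- unlist(lapply(names(rates), function(cl) {
    f <- rep(FALSE, 50); f[seq_len(round(50 * rates[[cl]]))] <- TRUE; f
  }))
  r2 <- ifelse(flip, "other", r1)
  res4 <- differential_classification_pct(
    mk_review(algorithm, r1, list(R2 = r2)))
  expect_equal(setNames(res4$pct, res4$class),
               c(c1 = 10, c2 = 2, c3 = 20, c4 = 0))
  ## single-reviewer records are excluded with a count
  rs <- review_set(
    tibble::tibble(person_id = c("A", "B"), algorithm_label = "c1"),
    tibble::tibble(person_id = c("A", "A", "B"),
                   reviewer_id = c("R1", "R2", "R1"),
                   label = c("c1", "c1", "c1")))
  res1 <- differential_classification_pct(rs)
  expect_equal(attr(res1, "n_excluded_single_reviewer"), 1L)
})

test_that("consensus uses majority vote with flagged first-reviewer ties", {
  rs <- review_set(
    tibble::tibble(person_id = c("A", "B"), algorithm_label = "c1"),
    tibble::tibble(person_id = rep(c("A", "B"), each = 3),
                   reviewer_id = rep(c("R1", "R2", "R3"), 2),
                   label = c("x", "y", "y",   # majority y
                             "x", "y", "z"))) # 3-way tie -> first reviewer
  cons <- consensus_labels(rs)
  expect_equal(cons$label[cons$person_id == "A"], "y")
  expect_false(cons$tie[cons$person_id == "A"])
  expect_equal(cons$label[cons$person_id == "B"], "x")
  expect_true(cons$tie[cons$person_id == "B"])
})

test_that("review sampling is seeded, per-class, and blind-shuffled", {
  co <- generate_cohort(sim_config(n_persons = 3000, seed = 21))
  a <- assign_phenotypes(co$dataset)
  s1 <- sample_for_review(a, per_class_n = 30, seed = 5)
  s2 <- sample_for_review(a, per_class_n = 30, seed = 5)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 5 * 30)
  expect_true(all(table(s1$algorithm_label) == 30))
  ## degenerate class: sample the whole class and warn
  small <- a[a$phenotype %in% c("control", "operative_or_recurrent"), ]
  small <- dplyr::bind_rows(utils::head(small[small$phenotype == "control", ], 10),
                            utils::head(small[small$phenotype ==
                                                "operative_or_recurrent", ], 3))
  expect_warning(s3 <- sample_for_review(small, per_class_n = 5, seed = 1),
                 "only 3")
  expect_equal(sum(s3$algorithm_label == "operative_or_recurrent"), 3)
})
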