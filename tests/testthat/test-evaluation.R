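# Agreement statistics, F1, area ratios, tumor matching and effect sizes.

test_that("kappa hits its algebraic anchors", {
  id2 <- confusion_matrix(matrix(c(5, 0, 0, 5), 2, 2,
                                 dimnames = list(c("a", "b"), c("a", "b"))))
  anti <- confusion_matrix(matrix(c(0, 5, 5, 0), 2, 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(cohens_kappa(id2)$kappa, 1)
  expect_equal(cohens_kappa(anti)$kappa, -1)
  # with two categories linear weighting changes nothing
  set.seed(2)
  m <- matrix(rpois(4, 20), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  cm <- confusion_matrix(m)
  expect_equal(cohens_kappa(cm, "linear")$kappa, cohens_kappa(cm)$kappa)
})

test_that("kappa is invariant under simultaneous row/column permutation and
           matches the e1071 oracle", {
  set.seed(8)
  m <- matrix(rpois(16, 15), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  cm <- confusion_matrix(m)
  k1 <- cohens_kappa(cm)$kappa
  perm <- c(3, 1, 4, 2)
  cmp <- confusion_matrix(m[perm, perm])
  expect_equal(cohens_kappa(cmp, categories = letters[1:4][perm])$kappa, k1)

  skip_if_not_installed("e1071")
  expect_equal(k1, e1071::classAgreement(m)$kappa, tolerance = 1e-12)
})

test_that("the bundled rater table reproduces the published agreement
           statistics", {
  cm <- table1_fixture()
  expect_equal(unname(rowSums(cm$counts)), c(26, 727, 419, 768, 18))
  expect_equal(unname(colSums(cm$counts)), c(754, 441, 744, 19))
  expect_equal(cm$n, 1958)

  plain <- cohens_kappa(cm, "none")
  weighted <- cohens_kappa(cm, "linear")
  expect_equal(round(plain$kappa, 3), 0.782)
  expect_equal(round(weighted$kappa, 3), 0.835)
  expect_equal(round(plain$ci95, 3), c(0.759, 0.806), tolerance = 1e-12)
})

test_that("per-class and micro F1 follow the area formulas and zero
           denominators are missing, not zero", {
  f <- per_class_f1(pred_area = c(a = 3, b = 10, c = 0),
                    true_area = c(a = 3, b = 10, c = 0),
                    overlap_area = c(a = 2, b = 10, c = 0))
  expect_equal(f$per_class$f1[1], 2 / 3)
  expect_equal(f$per_class$f1[2], 1)
  expect_true(is.na(f$per_class$f1[3]))
  # micro pools exclude the absent class
  expect_equal(f$micro$precision, 12 / 13)
  expect_equal(f$micro$recall, 12 / 13)

  perfect <- per_class_f1(c(a = 5), c(a = 5), c(a = 5))
  expect_equal(perfect$per_class$f1, 1)
  expect_error(per_class_f1(c(a = 1), c(a = 1), c(a = 2)), "overlap")
})

test_that("micro-F1 equals pixel accuracy for single-label maps", {
  set.seed(9)
  truth <- grade_map(matrix(sample(1:6, 400, TRUE), 20, 20))
  pred <- grade_map(matrix(sample(1:6, 400, TRUE), 20, 20))
  tal <- map_area_tallies(pred, truth)
  f <- per_class_f1(tal$pred_area, tal$true_area, tal$overlap_area)
  expect_equal(f$micro$f1, mean(unclass(pred) == unclass(truth)))
})

test_that("area ratios divide predicted by manual area and flag zero
           manual area as missing", {
  expect_equal(unname(area_ratio(c(g1 = 131), c(g1 = 100))), 1.31)
  r <- area_ratio(c(g1 = 5, g2 = 4), c(g1 = 5, g2 = 0))
  expect_equal(unname(r[1]), 1)
  expect_true(is.na(r[2]))
})

test_that("match_tumors detects by graded pixels, grades by the 10% rule,
           and records normal calls for misses", {
  m <- matrix(1L, 30, 30)
  m[2:11, 2:11] <- 5L                 # graded region
  m[4, 4] <- 6L                       # some grade 4 inside
  gm <- grade_map(m)
  region <- function(rows, cols, grade)
    list(pixels = as.matrix(expand.grid(row = rows, col = cols)),
         grade = grade)
  manual <- list(
    region(1:11, 1:11, "grade3"),     # overlaps the tumor
    region(15:20, 15:20, "grade1")    # pure normal alveoli
  )
  res <- match_tumors(manual, gm)
  expect_equal(res$detected, c(TRUE, FALSE))
  expect_equal(res$call[2], "normal_alveoli")
  expect_equal(res$call[1], "grade3")   # grade 4 is <10% of the region

  # a region with >=10% grade-4 pixels is called grade 4
  m2 <- matrix(1L, 20, 20)
  m2[1:10, 1:10] <- 5L
  m2[1:10, 1] <- 6L                    # 10% of the region's graded pixels
  res2 <- match_tumors(list(region(0:9, 0:9, "grade3")), grade_map(m2))
  expect_equal(res2$call, "grade4")

  expect_error(match_tumors(list(list(pixels = cbind(40, 2), grade = "grade1")),
                            gm), "bounds")
})

test_that("match_confusion lays out calls as rows against manual grades", {
  matches <- data.frame(
    manual_grade = c("grade1", "grade1", "grade2", "grade4"),
    detected = c(TRUE, FALSE, TRUE, TRUE),
    call = c("grade1", "normal_alveoli", "grade3", "grade4"))
  cm <- match_confusion(matches)
  expect_equal(cm$n, 4)
  expect_equal(cm$counts["Normal", "Grade 1"], 1)
  expect_equal(cm$counts["Grade 3", "Grade 2"], 1)
  expect_equal(cm$counts["Grade 4", "Grade 4"], 1)
})

test_that("effect sizes follow the printed formulas", {
  expect_equal(cohens_d(1, 0, 1), 1)
  expect_equal(cohens_d(3, 3, 2), 0)
  expect_error(cohens_d(1, 0, 0), "positive")
  expect_equal(effect_size_r(3, 10, 10), 0.15)
  expect_error(effect_size_r(1, 0, 0), "positive")
})

test_that("confusion matrices round-trip through CSV", {
  cm <- table1_fixture()
  p <- withr::local_tempfile(fileext = ".csv")
  write_confusion_matrix(cm, p)
  back <- read_confusion_matrix(p)
  expect_equal(unname(back$counts), unname(cm$counts))
  expect_equal(back$n, cm$n)
})
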