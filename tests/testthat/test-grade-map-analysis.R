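# Tumor segmentation, the >=10% overall-grade rule, Shannon diversity and
# slide summaries.

test_that("segment_tumors separates blobs severed by normal tissue and
           honors connectivity", {
  m <- matrix(1L, 12, 12)
  m[2:4, 2:4] <- 4L          # grade-2 blob
  m[8:10, 8:10] <- 4L        # second grade-2 blob
  gm <- grade_map(m)
  expect_length(segment_tumors(gm), 2)

  # diagonal contact: one tumor under 8-connectivity, two under 4
  m <- matrix(1L, 10, 10)
  m[2:4, 2:4] <- 5L
  m[5:7, 5:7] <- 6L
  gm <- grade_map(m)
  expect_length(segment_tumors(gm, connectivity = 8), 1)
  expect_length(segment_tumors(gm, connectivity = 4), 2)

  expect_length(segment_tumors(grade_map(matrix(1L, 6, 6))), 0)
})

test_that("connected components agree with the EBImage oracle on random
           masks", {
  skip_if_not_installed("EBImage")
  set.seed(14)
  for (q in 1:5) {
    mask <- matrix(as.integer(runif(40 * 40) < 0.35), 40, 40)
    lab <- luadgrader:::cpp_label_components(mask, 4L)
    # EBImage::bwlabel is 4-connected
    ref <- EBImage::bwlabel(mask)
    expect_equal(max(lab), max(ref))
  }
})

test_that("segmentation partitions the graded pixels", {
  slide <- get_demo_slide()
  tumors <- segment_tumors(slide$mask)
  expect_equal(sum(vapply(tumors, `[[`, integer(1), "pixel_count")),
               sum(unclass(slide$mask) %in% GRADE_CODES))
  # ids ordered by topmost-then-leftmost pixel
  tops <- t(vapply(tumors, function(tm)
    c(min(tm$pixels[, 1]),
      min(tm$pixels[tm$pixels[, 1] == min(tm$pixels[, 1]), 2])),
    numeric(2)))
  expect_false(is.unsorted(order(tops[, 1], tops[, 2])))
})

test_that("the overall-grade rule takes the highest grade holding at least
           10% of the area, boundary inclusive", {
  expect_equal(assign_overall_grade(c(grade2 = 0.50, grade3 = 0.39,
                                      grade4 = 0.11)),
               CLASS_CODES[["grade4"]])
  expect_equal(assign_overall_grade(c(grade3 = 0.91, grade4 = 0.09)),
               CLASS_CODES[["grade3"]])
  expect_equal(assign_overall_grade(c(grade3 = 0.90, grade4 = 0.10)),
               CLASS_CODES[["grade4"]])
  expect_error(assign_overall_grade(c(grade1 = 0, grade2 = 0, grade3 = 0,
                                      grade4 = 0)), "all-zero")
})

test_that("the overall-grade rule agrees with a brute-force oracle on 1e4
           random compositions", {
  brute <- function(comp, thr = 0.10) {
    ok <- which(comp >= thr)
    if (length(ok) == 0L) ok <- which.max(comp)
    GRADE_CODES[[max(ok)]]
  }
  set.seed(7)
  for (q in 1:10000) {
    raw <- runif(4)^2
    comp <- raw / sum(raw)
    names(comp) <- names(GRADE_CODES)
    expect_identical(assign_overall_grade(comp), brute(comp))
  }
})

test_that("Shannon diversity matches closed forms and its bounds", {
  expect_equal(shannon_diversity(rep(0.25, 4)), log(4))
  expect_equal(shannon_diversity(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_diversity(c(0.5, 0.5)), log(2))
  set.seed(3)
  for (q in 1:200) {
    comp <- runif(4); comp <- comp / sum(comp)
    s <- shannon_diversity(comp)
    expect_gte(s, 0)
    expect_lte(s, log(4) + 1e-12)
    expect_equal(s, shannon_diversity(rev(comp)))  # label permutation
  }
})

test_that("slide_summary conserves area across both attribution schemes", {
  m <- matrix(1L, 20, 20)            # 400 lung pixels
  m[2:5, 2:5] <- 5L                  # 16 px grade 3
  m[2:3, 2] <- 4L                    # 2 of them grade 2
  gm <- grade_map(m, microns_per_pixel = 1)
  tumors <- segment_tumors(gm)
  s <- slide_summary(gm, tumors)
  expect_equal(s$lung_area_um2, 400)
  expect_equal(s$tumor_area_um2, 16)
  expect_equal(s$burden_fraction, 16 / 400)
  expect_equal(sum(s$tumor_area_by_overall_grade),
               sum(s$tumor_area_by_pixel_grade))
  expect_equal(sum(s$tumor_area_by_overall_grade), s$tumor_area_um2)
  expect_equal(unname(s$tumor_area_by_pixel_grade[c("grade2", "grade3")]),
               c(2, 14))
  # the tumor is overall grade 3 (12.5% grade 2, 87.5% grade 3)
  expect_equal(unname(s$tumor_area_by_overall_grade[["grade3"]]), 16)
  expect_error(slide_summary(grade_map(matrix(0L, 4, 4)), list()), "lung")
})

test_that("grade_area_within matches direct pixel counting on a hand-built
           cohort", {
  mk <- function(gp, og) {
    comp <- gp / sum(gp)
    list(tumor_id = 1L, grade_pixels = gp, composition = comp,
         overall_grade = og, area_um2 = sum(gp), pixels = cbind(0, 0))
  }
  gp1 <- c(grade1 = 0, grade2 = 60, grade3 = 40, grade4 = 0)
  gp2 <- c(grade1 = 0, grade2 = 30, grade3 = 170, grade4 = 0)
  gp3 <- c(grade1 = 0, grade2 = 10, grade3 = 0, grade4 = 90)
  tumors <- list(mk(gp1, CLASS_CODES[["grade3"]]),
                 mk(gp2, CLASS_CODES[["grade3"]]),
                 mk(gp3, CLASS_CODES[["grade4"]]))
  expect_equal(grade_area_within(tumors, "grade2", "grade3"),
               (60 + 30) / (60 + 30 + 10))
  expect_equal(grade_area_within(tumors, "grade4", "grade4"), 1.0)
  expect_equal(grade_area_within(tumors, "grade4", "grade3"), 0.0)
  expect_true(is.na(grade_area_within(tumors, "grade1", "grade3")))
})

test_that("size_distribution yields the empirical CDF and the half-area
           count", {
  mk <- function(a) list(tumor_id = 1L, area_um2 = a)
  sd3 <- size_distribution(list(mk(1), mk(1), mk(2)))
  expect_equal(sd3$table$area_um2, c(1, 1, 2))
  expect_equal(sd3$table$cum_freq, c(1 / 3, 2 / 3, 1))
  expect_false(is.unsorted(sd3$table$cum_freq))
  expect_equal(tail(sd3$table$cum_freq, 1), 1)

  # one tumor holding 60% of the area -> one tumor holds half
  sd2 <- size_distribution(list(mk(60), mk(20), mk(20)))
  expect_equal(sd2$n_half_area, 1)
})

test_that("per-tumor tables carry compositions that sum to one", {
  slide <- get_demo_slide()
  tumors <- segment_tumors(slide$mask)
  tab <- tumor_table(tumors)
  expect_equal(nrow(tab), length(tumors))
  expect_true(all(abs(rowSums(tab[, c("g1", "g2", "g3", "g4")]) - 1) < 1e-9))
  expect_true(all(tab$sdi >= 0 & tab$sdi <= log(4) + 1e-12))
})
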