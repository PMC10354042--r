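# Registration, cell detection, projection, exclusion filters, and the
# staining G-test.

test_that("global registration recovers identity and planted rigid
           transforms", {
  slide <- get_demo_slide()
  he <- slide$image

  reg0 <- register_global(he, he, downsample = 4)
  expect_lt(abs(reg0$rigid$rotation), 0.3)
  expect_lt(max(abs(reg0$rigid$translation)), 4)

  # planted pull transform P: ihc(p) = he(P p), so the forward map is P
  ctr <- (c(256, 256) + 1) / 2 - 1
  P <- luadgrader:::rigid_matrix(5, c(10, 5), ctr)
  ihc <- luadgrader:::cpp_warp_affine(he, P, 256L, 256L, TRUE, 255)
  reg <- register_global(ihc, he, downsample = 4)
  pts <- cbind(c(80, 128, 170), c(90, 128, 150))
  err <- sqrt(rowSums((luadgrader:::apply_affine(reg$affine, pts) -
                       luadgrader:::apply_affine(P, pts))^2))
  expect_lt(mean(err), 2)
  expect_lt(abs(reg$rigid$rotation - 5), 0.5)

  expect_error(register_global(array(128, c(64, 64, 3)), he),
               "featureless")
})

test_that("local registration recovers a per-tumor shift and leaves aligned
           tumors at zero", {
  slide <- get_demo_slide()
  he <- slide$image
  tumors <- segment_tumors(slide$mask, min_pixels = 200)
  # build an "IHC" copy in which tumor 1 is locally shifted by (+8, +6)
  ihc <- he
  tm <- tumors[[1]]
  bb <- c(range(tm$pixels[, 1]) + 1L, range(tm$pixels[, 2]) + 1L)
  src <- he[(bb[1]:bb[2]) - 8, (bb[3]:bb[4]) - 6, , drop = FALSE]
  ihc[bb[1]:bb[2], bb[3]:bb[4], ] <- src
  reg <- register_global(ihc, he, downsample = 4)
  reg <- register_local(reg, ihc, he, tumors, radius = 15)
  lo <- reg$local_offsets
  shifted <- lo[lo$tumor_id == tm$tumor_id, ]
  others <- lo[lo$tumor_id != tm$tumor_id, ]
  expect_lt(abs(shifted$dr - 8) + abs(shifted$dc - 6), 4)
  expect_true(all(abs(others$dr) <= 1 & abs(others$dc) <= 1))
})

test_that("cell detection recovers the rendered fixture's counts and
           positivity", {
  gmap <- grade_map(matrix(5L, 200, 200))
  ihcp <- make_ihc_pattern(gmap, ihc_pattern_spec(cells_per_mm2 = 6000,
                                                  baseline = 0.4, seed = 2))
  det <- detect_cells(ihcp$image)
  truth <- ihcp$cells
  expect_lt(abs(nrow(det) - nrow(truth)) / nrow(truth), 0.1)
  expect_lt(abs(sum(det$positive) - sum(truth$positive)), 3)

  blank <- array(255, c(64, 64, 3))
  expect_equal(nrow(detect_cells(blank)), 0)
})

test_that("projection assigns classes and tumors through the composed
           transform and drops out-of-bounds cells", {
  slide <- get_demo_slide()
  tumors <- segment_tumors(slide$mask, min_pixels = 200)
  gm <- slide$mask
  # identity registration
  reg <- structure(list(rigid = list(rotation = 0, translation = c(0, 0)),
                        affine = luadgrader:::affine_identity(),
                        local_offsets = data.frame(tumor_id = integer(0),
                                                   dr = numeric(0),
                                                   dc = numeric(0),
                                                   ncc = numeric(0),
                                                   accepted = logical(0)),
                        residual = 0),
                   class = "registration")
  tm <- tumors[[1]]
  inside <- tm$pixels[5, ]
  cells <- data.frame(row = c(inside[1], 0, 500),
                      col = c(inside[2], 0, 500),
                      positive = c(TRUE, FALSE, TRUE))
  proj <- project_cells(cells, reg, gm, tumors)
  expect_equal(proj$dropped, 1)
  expect_equal(nrow(proj$cells), 2)
  expect_equal(proj$cells$tumor_id[1], tm$tumor_id)
  expect_equal(proj$cells$assigned_class[1],
               unclass(gm)[inside[1] + 1, inside[2] + 1])
  expect_equal(proj$cells$tumor_id[2], 0L)     # background corner
})

test_that("the IHC exclusion filter applies both boundaries inclusively", {
  mk <- function(id, area) list(tumor_id = id, area_um2 = area,
                                pixels = cbind(0, 0))
  cells_for <- function(id, n) data.frame(tumor_id = rep(id, n))
  tumors <- list(mk(1L, 1999.9), mk(2L, 2500), mk(3L, 2500), mk(4L, 2000))
  cells <- rbind(cells_for(1L, 60), cells_for(2L, 49), cells_for(3L, 50),
                 cells_for(4L, 50))
  kept <- filter_tumors_for_ihc(tumors, cells)
  expect_equal(vapply(kept, `[[`, integer(1), "tumor_id"), c(3L, 4L))
})

test_that("the staining G-test matches its closed form and the chi-squared
           tail oracle", {
  tm <- list(tumor_id = 1L,
             composition = c(grade1 = 0, grade2 = 0.5, grade3 = 0.5,
                             grade4 = 0),
             area_um2 = 5000, pixels = cbind(0, 0))
  cells <- data.frame(tumor_id = 1L,
                      assigned_class = rep(c(4L, 5L), c(30, 10)),
                      positive = TRUE)
  g <- staining_g_test(tm, cells)
  expect_equal(g$G, 2 * (30 * log(30 / 20) + 10 * log(10 / 20)),
               tolerance = 1e-10)
  expect_equal(g$df, 1L)
  expect_equal(g$p, pchisq(g$G, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(g$p, 4), 0.0012)
  expect_true(g$significant)
  expect_equal(sum(g$E, na.rm = TRUE), g$total_positive)

  # O proportional to E -> G = 0, p = 1
  cells_prop <- data.frame(tumor_id = 1L,
                           assigned_class = rep(c(4L, 5L), c(20, 20)),
                           positive = TRUE)
  g0 <- staining_g_test(tm, cells_prop)
  expect_equal(g0$G, 0, tolerance = 1e-12)
  expect_equal(g0$p, 1)

  # single-grade tumor or zero positives -> not testable
  tm1 <- tm; tm1$composition <- c(grade1 = 0, grade2 = 1, grade3 = 0,
                                  grade4 = 0)
  expect_false(staining_g_test(tm1, cells)$testable)
  none <- cells; none$positive <- FALSE
  expect_false(staining_g_test(tm, none)$testable)
})

test_that("G approximates the chi-squared statistic for small deviations
           and is invariant to grade relabeling", {
  set.seed(6)
  for (q in 1:20) {
    E <- runif(3, 50, 150)
    O <- round(E * runif(3, 0.95, 1.05))
    comp <- E / sum(E)
    tm <- list(tumor_id = 1L,
               composition = c(grade1 = comp[1], grade2 = comp[2],
                               grade3 = comp[3], grade4 = 0),
               area_um2 = 1e4, pixels = cbind(0, 0))
    cells <- data.frame(tumor_id = 1L,
                        assigned_class = rep(c(3L, 4L, 5L), O),
                        positive = TRUE)
    g <- staining_g_test(tm, cells)
    Ei <- sum(O) * comp
    chi2 <- sum((O - Ei)^2 / Ei)
    if (chi2 > 1e-4)
      expect_lt(abs(g$G - chi2) / chi2, 0.05)
    # relabeling the grades leaves G unchanged
    tm2 <- tm
    tm2$composition <- c(grade1 = 0, grade2 = comp[1], grade3 = comp[2],
                         grade4 = comp[3])
    cells2 <- cells
    cells2$assigned_class <- cells2$assigned_class + 1L
    expect_equal(staining_g_test(tm2, cells2)$G, g$G, tolerance = 1e-10)
  }
})

test_that("planted grade-4 enrichment is flagged by the G-test and shows in
           the likelihood ratios", {
  spec <- slide_layout_spec(
    canvas = c(600, 600),
    tumors = list(list(center = c(300, 300), radius = 230,
                       composition = c(grade2 = 0.4, grade3 = 0.3,
                                       grade4 = 0.3))),
    n_airways = 0, seed = 3)
  mask <- make_synthetic_slide(spec)$mask
  tumors <- segment_tumors(mask)
  expect_length(tumors, 1)
  expect_gte(tumors[[1]]$area_um2, 2000)

  hits <- 0; lr4 <- lr_low <- numeric(0)
  for (s in 1:10) {
    ih <- make_ihc_pattern(mask,
                           ihc_pattern_spec(cells_per_mm2 = 6000,
                                            baseline = 0.15,
                                            enrichment = c(grade4 = 3),
                                            seed = s))
    cells <- ih$cells
    cells$tumor_id <- 1L
    cells$assigned_class <- cells$class
    expect_gte(sum(cells$class %in% GRADE_CODES), 200)
    g <- staining_g_test(tumors[[1]], cells)
    hits <- hits + isTRUE(g$significant)
    lr4 <- c(lr4, g$lr[["grade4"]])
    lr_low <- c(lr_low, g$lr[["grade2"]])
  }
  expect_gte(hits / 10, 0.8)
  expect_gt(mean(lr4), 1)
  expect_lt(mean(lr_low), 1)
})

test_that("positivity_by_grade classifies stained tumors by the positive
           fraction and tabulates enrichment of significant tumors", {
  mk <- function(id, og) list(tumor_id = id, overall_grade = og,
                              area_um2 = 3000, pixels = cbind(0, 0),
                              composition = c(grade1 = 0, grade2 = 0.5,
                                              grade3 = 0.5, grade4 = 0))
  tumors <- list(mk(1L, CLASS_CODES[["grade3"]]),
                 mk(2L, CLASS_CODES[["grade3"]]),
                 mk(3L, CLASS_CODES[["grade4"]]))
  cells <- rbind(
    data.frame(tumor_id = 1L, assigned_class = 5L,
               positive = rep(c(TRUE, FALSE), c(10, 90))),
    data.frame(tumor_id = 2L, assigned_class = 5L,
               positive = rep(c(TRUE, FALSE), c(2, 98))),
    data.frame(tumor_id = 3L, assigned_class = 6L,
               positive = rep(c(TRUE, FALSE), c(50, 50))))
  stats <- lapply(tumors, staining_g_test, cells = cells)
  out <- positivity_by_grade(tumors, cells, stats)
  g3 <- out$by_grade[out$by_grade$overall_grade == "grade3", ]
  g4 <- out$by_grade[out$by_grade$overall_grade == "grade4", ]
  expect_equal(g3$fraction_positive, 0.5)   # 10% yes, 2% no
  expect_equal(g4$fraction_positive, 1.0)
  expect_true(all(out$by_grade$fraction_positive >= 0 &
                  out$by_grade$fraction_positive <= 1))
})
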