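# Registration of IHC serial sections to H&E, DAB-positive cell detection,
# projection of cells onto the grade map, and the likelihood-ratio G-test for
# unequal staining across grade regions.
#
# Transforms are stored as forward 2x3 affine matrices mapping IHC (row, col)
# coordinates to H&E coordinates; image warping uses the inverse (pull) form.

affine_identity <- function() cbind(diag(2), c(0, 0))

rigid_matrix <- function(theta_deg, translation, center) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  cbind(R, center + translation - R %*% center)
}

invert_affine <- function(A) {
  Rinv <- solve(A[, 1:2])
  cbind(Rinv, -Rinv %*% A[, 3])
}

apply_affine <- function(A, pts) {
  # pts: n x 2 (row, col); returns n x 2
  t(A[, 1:2] %*% t(pts) + A[, 3])
}

# block-mean downsample of a matrix by integer factor
downsample_mean <- function(m, f) {
  H <- (nrow(m) %/% f) * f; W <- (ncol(m) %/% f) * f
  m <- m[seq_len(H), seq_len(W)]
  arr <- array(m, c(f, H / f, f, W / f))
  apply(arr, c(2, 4), mean)
}

warp_gray <- function(img, pull, out_h, out_w, fill = 255) {
  cpp_warp_affine(array(img, c(dim(img), 1)), pull, out_h, out_w, TRUE,
                  fill)[, , 1]
}

masked_mse <- function(a, b) {
  # squared difference where the warped image landed (fill regions excluded)
  ok <- is.finite(a) & is.finite(b)
  mean((a[ok] - b[ok])^2)
}

#' Global (rigid then affine) registration of an IHC section to H&E
#'
#' The rigid stage is a multi-resolution grayscale correlation search
#' (rotation within `rotation_range` degrees, full translation) on
#' downsampled images; the affine stage refines it by a small, capped number
#' of gradient steps to avoid undesired deformation.
#'
#' @param ihc,he RGB (H, W, 3) arrays of the IHC and H&E sections.
#' @param rotation_range maximum absolute rotation searched, degrees.
#' @param downsample integer downsampling factor for the search.
#' @param affine_iters iteration cap for the affine refinement (default 20).
#' @return A `registration` object: `rigid` (rotation degrees, translation
#'   px), `affine` (forward 2x3 matrix, IHC -> H&E), `local_offsets` (empty
#'   until [register_local()]), `residual` (mean absolute grayscale error).
#' @export
register_global <- function(ihc, he, rotation_range = 15, downsample = 8,
                            affine_iters = 20) {
  stopifnot_rgb(ihc); stopifnot_rgb(he)
  gi <- downsample_mean(rgb_to_gray(ihc), downsample)
  gh <- downsample_mean(rgb_to_gray(he), downsample)
  if (sd(gi) < 1e-6 || sd(gh) < 1e-6)
    stop("registration failure: featureless image")
  ctr_small <- (dim(gi) + 1) / 2

  margin <- pmax(2L, floor(pmin(nrow(gi), ncol(gi)) / 5))
  score_rotation <- function(theta) {
    pull <- invert_affine(rigid_matrix(theta, c(0, 0), ctr_small - 1))
    rot <- warp_gray(gi, pull, nrow(gh), ncol(gh), fill = mean(gi))
    tpl <- rot[(margin + 1):(nrow(rot) - margin),
               (margin + 1):(ncol(rot) - margin)]
    off <- cpp_ncc_offset(tpl, gh)
    list(theta = theta, dr = off$dr, dc = off$dc, ncc = off$ncc)
  }
  coarse <- lapply(seq(-rotation_range, rotation_range, by = 1),
                   score_rotation)
  best <- coarse[[which.max(vapply(coarse, function(x) x$ncc, numeric(1)))]]
  fine <- lapply(seq(best$theta - 1, best$theta + 1, by = 0.2),
                 score_rotation)
  best <- fine[[which.max(vapply(fine, function(x) x$ncc, numeric(1)))]]

  rigid <- list(rotation = best$theta,
                translation = c(best$dr, best$dc) * downsample)
  ctr_full <- (c(nrow(ihc), ncol(ihc)) + 1) / 2
  A_full <- rigid_matrix(best$theta, rigid$translation, ctr_full - 1)

  # affine refinement on the downsampled pair: a few damped gradient steps on
  # the pull transform, capped at affine_iters
  scale_pull <- function(P_full) {
    cbind(P_full[, 1:2], P_full[, 3] / downsample)
  }
  unscale_pull <- function(P_small) {
    cbind(P_small[, 1:2], P_small[, 3] * downsample)
  }
  P <- scale_pull(invert_affine(A_full))
  loss_of <- function(P) {
    w <- warp_gray(gi, P, nrow(gh), ncol(gh), fill = NA)
    masked_mse(w, gh)
  }
  cur <- loss_of(P)
  step <- c(rep(1e-4, 4), rep(0.05, 2))   # linear part vs translation
  for (it in seq_len(affine_iters)) {
    g <- numeric(6)
    for (q in 1:6) {
      Pq <- P; Pq[q] <- Pq[q] + step[q]
      g[q] <- (loss_of(Pq) - cur) / step[q]
    }
    gn <- sqrt(sum((g * step)^2))
    if (gn < 1e-10) break
    cand <- P - matrix(0.5 * g * step^2 / gn, 2, 3)
    cl <- loss_of(cand)
    if (cl < cur) { P <- cand; cur <- cl } else break
  }
  A_ref <- invert_affine(unscale_pull(P))
  if (det(A_ref[, 1:2]) <= 0) A_ref <- A_full  # never accept a reflection

  w <- warp_gray(gi, invert_affine(cbind(A_ref[, 1:2],
                                         A_ref[, 3] / downsample)),
                 nrow(gh), ncol(gh), fill = NA)
  structure(list(rigid = rigid, affine = A_ref,
                 local_offsets = data.frame(tumor_id = integer(0),
                                            dr = numeric(0), dc = numeric(0),
                                            ncc = numeric(0),
                                            accepted = logical(0)),
                 residual = mean(abs(w - gh), na.rm = TRUE),
                 downsample = downsample),
            class = "registration")
}

#' @export
print.registration <- function(x, ...) {
  cat(sprintf("<registration> rigid: %.2f deg, (%.1f, %.1f) px; residual %.3f\n",
              x$rigid$rotation, x$rigid$translation[1], x$rigid$translation[2],
              x$residual))
  if (nrow(x$local_offsets)) print(x$local_offsets)
  invisible(x)
}

#' Per-tumor local registration refinement
#'
#' For each tumor region, the globally warped IHC image is matched against
#' the H&E image by normalized cross-correlation within `radius` pixels; weak
#' or out-of-range matches are rejected (the global transform is kept for
#' those tumors).
#'
#' @param registration result of [register_global()].
#' @param ihc,he the same image pair.
#' @param tumors tumors from [segment_tumors()] on the H&E grade map.
#' @param radius search radius in pixels.
#' @param min_ncc minimum correlation to accept a local offset.
#' @return The `registration` with `local_offsets` filled in: `dr`/`dc` are
#'   the per-tumor shifts (H&E frame) such that the cell mapping for that
#'   tumor is `affine(q) - (dr, dc)`.
#' @export
register_local <- function(registration, ihc, he, tumors, radius = 50,
                           min_ncc = 0.2) {
  gi <- rgb_to_gray(ihc); gh <- rgb_to_gray(he)
  pull <- invert_affine(registration$affine)
  warped <- warp_gray(gi, pull, nrow(gh), ncol(gh), fill = mean(gi))
  rows <- list()
  for (tm in tumors) {
    r0 <- min(tm$pixels[, 1]) + 1L; r1 <- max(tm$pixels[, 1]) + 1L
    c0 <- min(tm$pixels[, 2]) + 1L; c1 <- max(tm$pixels[, 2]) + 1L
    if (r0 - radius < 1 || r1 + radius > nrow(gh) ||
        c0 - radius < 1 || c1 + radius > ncol(gh)) {
      warning("tumor ", tm$tumor_id, " too close to the border; skipped")
      rows[[length(rows) + 1L]] <-
        data.frame(tumor_id = tm$tumor_id, dr = 0, dc = 0, ncc = NA_real_,
                   accepted = FALSE)
      next
    }
    tpl <- gh[r0:r1, c0:c1]
    img <- warped[(r0 - radius):(r1 + radius), (c0 - radius):(c1 + radius)]
    off <- cpp_ncc_offset(tpl, img)
    ok <- is.finite(off$ncc) && off$ncc >= min_ncc
    # tpl(HE) matches warped at shift s: HE(p) ~ IHC(pull(p + s)), so the
    # forward map for this tumor is affine(q) - s
    rows[[length(rows) + 1L]] <-
      data.frame(tumor_id = tm$tumor_id,
                 dr = if (ok) off$dr else 0, dc = if (ok) off$dc else 0,
                 ncc = off$ncc, accepted = ok)
  }
  registration$local_offsets <- do.call(rbind, rows)
  registration
}

#' Detect cells in a DAB + hematoxylin IHC image
#'
#' The image is color-deconvolved with standard H-DAB stain vectors; nuclei
#' are local maxima of the smoothed hematoxylin + DAB density with a minimum
#' separation, and a cell is positive iff the mean DAB density in a small
#' disk around its centre exceeds `dab_threshold`.
#'
#' @param ihc RGB (H, W, 3) array.
#' @param dab_threshold positivity threshold on mean DAB OD (default 0.2).
#' @param min_separation minimum centre-to-centre distance, px.
#' @param peak_threshold detection threshold on the smoothed nuclear density.
#' @param blur_sigma Gaussian smoothing sigma, px.
#' @param disk_radius radius of the positivity disk, px.
#' @return data.frame: `row`, `col` (0-based, IHC frame), `positive`.
#' @export
detect_cells <- function(ihc, dab_threshold = 0.2, min_separation = 5,
                         peak_threshold = 0.15, blur_sigma = 2,
                         disk_radius = 3) {
  stopifnot_rgb(ihc)
  od <- matrix(rgb_to_od(ihc)$od, ncol = 3)
  conc <- od %*% HDAB_VECTORS %*% solve(crossprod(HDAB_VECTORS))
  conc[conc < 0] <- 0
  H <- dim(ihc)[1]; W <- dim(ihc)[2]
  hmap <- matrix(conc[, 1], H, W)
  dmap <- matrix(conc[, 2], H, W)

  k <- ceiling(3 * blur_sigma)
  kern <- exp(-(seq(-k, k))^2 / (2 * blur_sigma^2))
  kern <- kern / sum(kern)
  smooth <- cpp_blur_sep(hmap + dmap, kern)
  peaks <- cpp_local_maxima(smooth, peak_threshold,
                            as.integer(min_separation))
  if (length(peaks$row) == 0L)
    return(data.frame(row = integer(0), col = integer(0),
                      positive = logical(0)))
  dab <- cpp_disk_mean(dmap, peaks$row, peaks$col, disk_radius)
  data.frame(row = peaks$row, col = peaks$col,
             positive = dab > dab_threshold)
}

# integer raster of tumor ids (0 = none) from a tumor list
tumor_label_raster <- function(tumors, dims) {
  lab <- matrix(0L, dims[1], dims[2])
  for (tm in tumors)
    lab[cbind(tm$pixels[, 1] + 1L, tm$pixels[, 2] + 1L)] <- tm$tumor_id
  lab
}

#' Project detected cells onto the grade map
#'
#' Cell centroids are mapped from the IHC frame to the H&E frame by the
#' composed global (and, where accepted, per-tumor local) transform, assigned
#' the grade-map class at the mapped pixel, and associated with the
#' containing tumor. Out-of-bounds cells are dropped and counted.
#'
#' @param cells data.frame from [detect_cells()].
#' @param registration a `registration` (global, optionally with local
#'   offsets).
#' @param grade_map a [grade_map()].
#' @param tumors tumors from [segment_tumors()] on that map.
#' @return List: `cells` (data.frame row, col, positive, he_row, he_col,
#'   assigned_class, tumor_id), `dropped` (out-of-bounds count).
#' @export
project_cells <- function(cells, registration, grade_map, tumors) {
  H <- nrow(grade_map); W <- ncol(grade_map)
  tlab <- tumor_label_raster(tumors, c(H, W))
  he <- apply_affine(registration$affine, cbind(cells$row, cells$col))
  # first lookup with the global transform, then per-tumor local correction
  lo <- registration$local_offsets
  if (nrow(lo)) {
    ri <- round(he[, 1]) + 1L; ci <- round(he[, 2]) + 1L
    inb <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    tid0 <- rep(0L, nrow(he))
    tid0[inb] <- tlab[cbind(ri[inb], ci[inb])]
    shift <- lo[match(tid0, lo$tumor_id), c("dr", "dc")]
    shift$dr[is.na(shift$dr)] <- 0; shift$dc[is.na(shift$dc)] <- 0
    he <- he - as.matrix(shift)
  }
  ri <- round(he[, 1]) + 1L; ci <- round(he[, 2]) + 1L
  inb <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  out <- cells[inb, , drop = FALSE]
  out$he_row <- ri[inb] - 1L
  out$he_col <- ci[inb] - 1L
  out$assigned_class <- unclass(grade_map)[cbind(ri[inb], ci[inb])]
  out$tumor_id <- tlab[cbind(ri[inb], ci[inb])]
  rownames(out) <- NULL
  list(cells = out, dropped = sum(!inb))
}

#' Exclusion filter for IHC analysis
#'
#' Keeps tumors with area >= 2000 square microns AND at least 50 total cells
#' assigned from the IHC slide (both boundaries inclusive), excluding small
#' tumors and sparse registrations that would distort the enrichment test.
#'
#' @param tumors tumors from [segment_tumors()].
#' @param cells projected cells (with `tumor_id`).
#' @param min_area_um2 area floor (default 2000).
#' @param min_cells cell-count floor (default 50).
#' @return The eligible subset of `tumors`.
#' @export
filter_tumors_for_ihc <- function(tumors, cells, min_area_um2 = 2000,
                                  min_cells = 50) {
  counts <- table(cells$tumor_id)
  keep <- vapply(tumors, function(tm) {
    ncells <- if (as.character(tm$tumor_id) %in% names(counts))
      counts[[as.character(tm$tumor_id)]] else 0L
    tm$area_um2 >= min_area_um2 && ncells >= min_cells
  }, logical(1))
  tumors[keep]
}

#' Likelihood-ratio G-test for uneven staining across grade regions
#'
#' With O_i the observed positive-cell count in the grade-i region of a tumor
#' and E_i the expected count (total positives times the grade-i share of the
#' tumor's graded area), `G = 2 * sum(O_i * log(O_i / E_i))` (0 log 0 := 0)
#' is referred to a chi-squared distribution with (number of grades present)
#' - 1 degrees of freedom; significance at p < 0.01.
#'
#' @param tumor a tumor from [segment_tumors()].
#' @param cells projected cells of this tumor (`assigned_class`, `positive`).
#' @param alpha significance level (default 0.01).
#' @return List: `tumor_id`, `total_cells`, `total_positive`, `O`, `E`, `lr`
#'   (O/E), `G`, `df`, `p`, `significant`, `testable`.
#' @export
staining_g_test <- function(tumor, cells, alpha = 0.01) {
  cells <- cells[cells$tumor_id == tumor$tumor_id, , drop = FALSE]
  graded <- cells$assigned_class %in% GRADE_CODES
  pos <- cells$positive & graded
  O <- vapply(GRADE_CODES, function(g)
    sum(pos & cells$assigned_class == g), numeric(1))
  present <- tumor$composition > 0
  total_pos <- sum(O)
  out <- list(tumor_id = tumor$tumor_id, total_cells = nrow(cells),
              total_positive = total_pos,
              O = O, E = rep(NA_real_, 4), lr = rep(NA_real_, 4),
              G = NA_real_, df = sum(present) - 1L, p = NA_real_,
              significant = FALSE, testable = FALSE)
  names(out$E) <- names(out$lr) <- names(GRADE_CODES)
  if (total_pos == 0 || sum(present) < 2L) return(out)
  E <- total_pos * tumor$composition
  lr <- ifelse(present, O / E, NA_real_)
  terms <- ifelse(present & O > 0, O * log(O / E), 0)
  G <- 2 * sum(terms[present])
  df <- sum(present) - 1L
  p <- pchisq(G, df = df, lower.tail = FALSE)
  modifyList(out, list(E = E, lr = lr, G = G, df = df, p = p,
                       significant = p < alpha, testable = TRUE))
}

#' Positivity and enrichment summary per overall grade
#'
#' A tumor counts as positively stained iff its positive-cell fraction is at
#' least `positivity_threshold`. Returns the positive fraction of tumors per
#' overall grade and the per-grade likelihood ratios of tumors whose G-test
#' is significant.
#'
#' @param tumors eligible tumors (after [filter_tumors_for_ihc()]).
#' @param cells projected cells.
#' @param stats list of [staining_g_test()] results for `tumors`.
#' @param positivity_threshold minimum positive-cell fraction (default 0.05).
#' @return List: `by_grade` (data.frame overall_grade, n_tumors, n_positive,
#'   fraction_positive), `enrichment` (data.frame tumor_id, overall_grade,
#'   grade-region lr columns) for significant tumors.
#' @export
positivity_by_grade <- function(tumors, cells, stats,
                                positivity_threshold = 0.05) {
  grade_of <- vapply(tumors, function(tm) class_name(tm$overall_grade),
                     character(1))
  pos_frac <- vapply(tumors, function(tm) {
    cc <- cells[cells$tumor_id == tm$tumor_id, , drop = FALSE]
    if (nrow(cc) == 0L) return(NA_real_)
    mean(cc$positive)
  }, numeric(1))
  is_pos <- !is.na(pos_frac) & pos_frac >= positivity_threshold

  by_grade <- do.call(rbind, lapply(names(GRADE_CODES), function(g) {
    sel <- grade_of == g
    if (!any(sel)) return(NULL)
    data.frame(overall_grade = g, n_tumors = sum(sel),
               n_positive = sum(is_pos[sel]),
               fraction_positive = mean(is_pos[sel]))
  }))

  sig <- vapply(stats, function(s) isTRUE(s$significant), logical(1))
  enrichment <- do.call(rbind, lapply(which(sig), function(q) {
    lr <- stats[[q]]$lr
    data.frame(tumor_id = stats[[q]]$tumor_id,
               overall_grade = grade_of[q],
               lr_g1 = lr[["grade1"]], lr_g2 = lr[["grade2"]],
               lr_g3 = lr[["grade3"]], lr_g4 = lr[["grade4"]])
  }))
  list(by_grade = by_grade, enrichment = enrichment)
}
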