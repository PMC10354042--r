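# Rater-agreement and detection metrics: confusion matrices, Cohen's kappa
# (plain and linear-weighted) with an asymptotic 95% CI, per-class and
# micro-averaged F1, annotated-area ratios, manual-tumor detection matching,
# and the effect sizes used in downstream statistics.

#' Construct a rater confusion matrix
#'
#' Rows are one rater's categories, columns the other's; the two sets may
#' differ (e.g. one rater has a "Normal" call the other lacks).
#'
#' @param counts nonnegative integer matrix with dimnames.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry row and column category names")
  structure(list(counts = counts, n = sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> n = %d\n", x$n))
  print(x$counts)
  invisible(x)
}

#' Write / read a confusion matrix as CSV
#' @param cm a [confusion_matrix()].
#' @param path CSV path (row labels in the first column).
#' @export
write_confusion_matrix <- function(cm, path) {
  write.csv(cm$counts, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_confusion_matrix
#' @export
read_confusion_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  confusion_matrix(as.matrix(df))
}

# embed both raters' category sets into a common ordered list; absent
# categories get zero marginals
embed_square <- function(cm, categories = NULL) {
  if (is.null(categories))
    categories <- union(rownames(cm$counts), colnames(cm$counts))
  sq <- matrix(0, length(categories), length(categories),
               dimnames = list(categories, categories))
  sq[rownames(cm$counts), colnames(cm$counts)] <- cm$counts
  sq
}

#' Cohen's kappa (plain and linear-weighted)
#'
#' Both raters' category sets are embedded in a common ordered category list
#' (absent categories receive zero marginals); with linear weighting the
#' credit for a disagreement is `1 - |i - j| / (k - 1)` over the ordered
#' categories. The standard error is the asymptotic (Fleiss-Cohen-Everitt)
#' weighted-kappa SE with a normal-approximation 95% CI.
#'
#' @param cm a [confusion_matrix()].
#' @param weighting `"none"` or `"linear"`.
#' @param categories optional ordered common category list; defaults to row
#'   categories followed by unseen column categories.
#' @return List: `p_o`, `p_e`, `kappa`, `se`, `ci95` (length 2),
#'   `weighting`, `n`.
#' @export
cohens_kappa <- function(cm, weighting = c("none", "linear"),
                         categories = NULL) {
  weighting <- match.arg(weighting)
  sq <- embed_square(cm, categories)
  n <- sum(sq)
  if (n == 0) stop("empty confusion matrix")
  k <- nrow(sq)
  p <- sq / n
  r <- rowSums(p); c_ <- colSums(p)

  w <- if (weighting == "linear" && k > 1) {
    1 - abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  } else diag(k)

  p_o <- sum(w * p)
  p_e <- sum(w * outer(r, c_))
  if (abs(1 - p_e) < 1e-12)
    return(list(p_o = p_o, p_e = p_e, kappa = NA_real_, se = NA_real_,
                ci95 = c(NA_real_, NA_real_), weighting = weighting, n = n))
  kappa <- (p_o - p_e) / (1 - p_e)

  # asymptotic SE of weighted kappa (identity weights give the unweighted SE)
  wbar_i <- as.vector(w %*% c_)   # row-wise expected weight
  wbar_j <- as.vector(r %*% w)    # column-wise expected weight
  term <- sum(p * (w - outer(wbar_i, wbar_j, `+`) * (1 - kappa))^2)
  se <- sqrt(max(term - (kappa - p_e * (1 - kappa))^2, 0)) /
    ((1 - p_e) * sqrt(n))
  ci <- kappa + c(-1, 1) * qnorm(0.975) * se
  list(p_o = p_o, p_e = p_e, kappa = kappa, se = se, ci95 = ci,
       weighting = weighting, n = n)
}

#' Per-class and micro-averaged F1 from area tallies
#'
#' Precision = overlap / predicted area, recall = overlap / true area, F1
#' their harmonic mean. Micro-averaged versions pool numerators and
#' denominators over classes. Classes with a zero denominator are reported as
#' NA and excluded from the micro pool (a class absent from both maps carries
#' no signal).
#'
#' @param pred_area,true_area,overlap_area named nonnegative vectors on the
#'   same classes; `overlap <= min(pred, true)` per class.
#' @return List with `per_class` (data.frame class, precision, recall, f1)
#'   and `micro` (precision, recall, f1).
#' @export
per_class_f1 <- function(pred_area, true_area, overlap_area) {
  classes <- names(pred_area)
  if (is.null(classes)) classes <- as.character(seq_along(pred_area))
  if (any(overlap_area > pmin(pred_area, true_area) + 1e-9))
    stop("overlap exceeds min(pred, true) for some class")
  prec <- ifelse(pred_area > 0, overlap_area / pred_area, NA_real_)
  rec <- ifelse(true_area > 0, overlap_area / true_area, NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec), NA_real_)
  f1[!is.na(prec) & !is.na(rec) & (prec + rec) == 0] <- NA_real_
  keep <- pred_area > 0 | true_area > 0
  mp <- sum(overlap_area[keep]) / sum(pred_area[keep])
  mr <- sum(overlap_area[keep]) / sum(true_area[keep])
  list(per_class = data.frame(class = classes, precision = prec,
                              recall = rec, f1 = f1, row.names = NULL),
       micro = list(precision = mp, recall = mr,
                    f1 = if (mp + mr > 0) 2 * mp * mr / (mp + mr)
                         else NA_real_))
}

#' Area tallies of two congruent label rasters
#'
#' Convenience helper feeding [per_class_f1()] from a predicted
#' [grade_map()] and a truth [label_mask()].
#'
#' @param pred,truth congruent class-code matrices.
#' @param classes class codes to tally (default the six target classes).
#' @return List of named vectors `pred_area`, `true_area`, `overlap_area`
#'   (pixel counts).
#' @export
map_area_tallies <- function(pred, truth, classes = CLASS_CODES[-1]) {
  if (!all(dim(pred) == dim(truth))) stop("maps are not congruent")
  p <- unclass(pred); t_ <- unclass(truth)
  tal <- function(f) vapply(classes, f, numeric(1))
  list(pred_area = tal(function(k) sum(p == k)),
       true_area = tal(function(k) sum(t_ == k)),
       overlap_area = tal(function(k) sum(p == k & t_ == k)))
}

#' Predicted-to-manual area ratio per class
#'
#' @param pred_area,manual_area named nonnegative area vectors.
#' @return Named vector pred / manual; NA where the manual area is zero.
#' @export
area_ratio <- function(pred_area, manual_area) {
  ifelse(manual_area > 0, pred_area / manual_area, NA_real_)
}

#' Match manually annotated tumors against a grade map
#'
#' A manual tumor is detected iff at least one pixel inside its region is
#' graded (Grade 1-4). Detected tumors receive the overall grade of the grade
#' composition inside the manual region (>= 10% rule); undetected tumors are
#' recorded with the modal normal-class call inside the region.
#'
#' @param manual list of regions, each `list(pixels = 0-based (row, col)
#'   matrix, grade = manual grade name or code)`.
#' @param grade_map a [grade_map()].
#' @param threshold overall-grade threshold.
#' @return data.frame: manual_grade, detected, call (grade or normal-class
#'   name).
#' @export
match_tumors <- function(manual, grade_map, threshold = 0.10) {
  H <- nrow(grade_map); W <- ncol(grade_map)
  rows <- lapply(manual, function(region) {
    px <- region$pixels
    if (is.null(px) || nrow(px) == 0L) stop("empty manual region")
    if (any(px < 0) || any(px[, 1] >= H) || any(px[, 2] >= W))
      stop("manual region outside map bounds")
    codes <- unclass(grade_map)[cbind(px[, 1] + 1L, px[, 2] + 1L)]
    gp <- vapply(GRADE_CODES, function(g) sum(codes == g), numeric(1))
    if (sum(gp) > 0) {
      call <- class_name(assign_overall_grade(gp / sum(gp), threshold))
      detected <- TRUE
    } else {
      normal <- codes[codes %in% c(1L, 2L)]
      call <- if (length(normal))
        class_name(as.integer(names(sort(-table(normal)))[1]))
      else "background"
      detected <- FALSE
    }
    data.frame(manual_grade = as_grade_name(region$grade),
               detected = detected, call = call)
  })
  do.call(rbind, rows)
}

#' Confusion matrix of manual grades vs map-derived calls
#'
#' Rows are the pipeline's calls (Normal plus Grades 1-4, in that order),
#' columns the manual grades, mirroring the published comparison layout:
#' undetected tumors fall in the "Normal" row.
#'
#' @param matches data.frame from [match_tumors()].
#' @return A [confusion_matrix()].
#' @export
match_confusion <- function(matches) {
  call_cat <- ifelse(matches$detected,
                     c(grade1 = "Grade 1", grade2 = "Grade 2",
                       grade3 = "Grade 3", grade4 = "Grade 4")[matches$call],
                     "Normal")
  manual_cat <- c(grade1 = "Grade 1", grade2 = "Grade 2",
                  grade3 = "Grade 3", grade4 = "Grade 4")[matches$manual_grade]
  counts <- table(factor(call_cat, levels = c("Normal", "Grade 1", "Grade 2",
                                              "Grade 3", "Grade 4")),
                  factor(manual_cat, levels = c("Grade 1", "Grade 2",
                                                "Grade 3", "Grade 4")))
  confusion_matrix(unclass(counts))
}

#' Effect sizes
#'
#' `cohens_d` is the standardized mean difference `(x1 - x2) / s` with the
#' pooled standard deviation; `effect_size_r` is the standardized effect size
#' `r = z / (n1 + n2)` used with rank-based tests.
#'
#' @param xbar1,xbar2 group means.
#' @param s_pooled pooled standard deviation (> 0).
#' @export
cohens_d <- function(xbar1, xbar2, s_pooled) {
  if (s_pooled <= 0) stop("pooled SD must be positive")
  (xbar1 - xbar2) / s_pooled
}

#' @rdname cohens_d
#' @param z test statistic z-value.
#' @param n1,n2 group sizes (n1 + n2 > 0).
#' @export
effect_size_r <- function(z, n1, n2) {
  if (n1 + n2 <= 0) stop("n1 + n2 must be positive")
  z / (n1 + n2)
}
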