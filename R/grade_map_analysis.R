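# Tumor-level analytics on a grade map: connected-component tumor
# segmentation, overall-grade assignment by the >= 10% rule, Shannon
# diversity of the grade composition, and slide-level burden summaries.

#' Segment tumors from a grade map
#'
#' Tumors are connected components of the union of Grade 1-4 pixels (a tumor
#' is a mosaic of grades; the normal classes and Background sever
#' components). Component ids are deterministic, ordered by the component's
#' topmost-then-leftmost pixel.
#'
#' @param grade_map a [grade_map()].
#' @param connectivity 4 or 8 (default 8).
#' @param min_pixels drop components smaller than this (default 1 = keep
#'   all).
#' @return List of `tumor` objects: `tumor_id`, `pixels` (0-based (row, col)
#'   matrix), `pixel_count`, `area_um2`, `centroid`, `grade_pixels` (counts
#'   for grade1..grade4), `composition` (fractions summing to 1),
#'   `overall_grade` (class code), `sdi` (nats).
#' @export
segment_tumors <- function(grade_map, connectivity = 8, min_pixels = 1) {
  mpp <- mpp_of(grade_map)
  mask <- matrix(0L, nrow(grade_map), ncol(grade_map))
  mask[unclass(grade_map) %in% GRADE_CODES] <- 1L
  lab <- cpp_label_components(mask, as.integer(connectivity))
  n <- max(lab)
  tumors <- list()
  if (n == 0L) return(tumors)
  for (id in seq_len(n)) {
    idx <- which(lab == id)
    if (length(idx) < min_pixels) next
    rows <- (idx - 1L) %% nrow(lab)
    cols <- (idx - 1L) %/% nrow(lab)
    codes <- unclass(grade_map)[idx]
    gp <- vapply(GRADE_CODES, function(g) sum(codes == g), numeric(1))
    comp <- gp / sum(gp)
    tumors[[length(tumors) + 1L]] <- structure(list(
      tumor_id = length(tumors) + 1L,
      pixels = cbind(row = rows, col = cols),
      pixel_count = length(idx),
      area_um2 = length(idx) * mpp^2,
      centroid = c(row = mean(rows), col = mean(cols)),
      grade_pixels = gp,
      composition = comp,
      overall_grade = assign_overall_grade(comp),
      sdi = shannon_diversity(comp)
    ), class = "tumor")
  }
  tumors
}

#' Assign an overall tumor grade
#'
#' The overall grade is the highest grade whose share of the tumor's graded
#' area is at least `threshold` (default 10%, boundary inclusive).
#'
#' @param composition nonnegative fractions over grade1..grade4 (named or in
#'   grade order), summing to 1.
#' @param threshold minimum area share (default 0.10).
#' @return The overall grade as a class code (3..6 for Grades 1..4).
#' @export
assign_overall_grade <- function(composition, threshold = 0.10) {
  comp <- normalize_composition(composition)
  if (all(comp == 0)) stop("all-zero composition")
  ok <- which(comp >= threshold - 1e-12)
  if (length(ok) == 0L) ok <- which.max(comp)  # unreachable when sum == 1
  GRADE_CODES[[max(ok)]]
}

normalize_composition <- function(composition) {
  comp <- numeric(4)
  names(comp) <- names(GRADE_CODES)
  if (!is.null(names(composition)) &&
      all(names(composition) %in% names(GRADE_CODES))) {
    comp[names(composition)] <- composition
  } else if (length(composition) == 4L) {
    comp[] <- composition
  } else stop("composition must be named grade1..grade4 or length 4")
  if (any(comp < 0)) stop("composition fractions must be nonnegative")
  comp
}

#' Shannon diversity of a grade composition
#'
#' `-sum(p_i * ln(p_i))` over the grades present (p > 0), in nats;
#' 0 for a monomorphic tumor, `ln(4)` at the uniform maximum.
#'
#' @param composition nonnegative fractions summing to 1.
#' @return Diversity in nats.
#' @export
shannon_diversity <- function(composition) {
  p <- composition[composition > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log(p))
}

#' Summarize a graded slide
#'
#' Lung area is all non-Background pixels. Tumor area is reported two ways:
#' attributed per overall grade (each tumor's full area credited to its
#' overall grade) and per raw pixel grade; both sum to the same total.
#'
#' @param grade_map a [grade_map()].
#' @param tumors tumors from [segment_tumors()] on the same map.
#' @return List: `tumor_count_total`, `tumor_count_by_grade`,
#'   `lung_area_um2`, `tumor_area_um2`, `tumor_area_by_overall_grade`,
#'   `tumor_area_by_pixel_grade`, `burden_fraction`.
#' @export
slide_summary <- function(grade_map, tumors) {
  mpp <- mpp_of(grade_map)
  lung_px <- sum(unclass(grade_map) > 0L)
  if (lung_px == 0L) stop("zero lung area")
  grade_names <- names(GRADE_CODES)

  count_by <- area_overall <- area_pixel <-
    structure(numeric(4), names = grade_names)
  for (tm in tumors) {
    g <- class_name(tm$overall_grade)
    count_by[g] <- count_by[g] + 1
    area_overall[g] <- area_overall[g] + tm$area_um2
    area_pixel <- area_pixel + tm$grade_pixels * mpp^2
  }
  tumor_area <- sum(area_overall)
  list(tumor_count_total = length(tumors),
       tumor_count_by_grade = count_by,
       lung_area_um2 = lung_px * mpp^2,
       tumor_area_um2 = tumor_area,
       tumor_area_by_overall_grade = area_overall,
       tumor_area_by_pixel_grade = area_pixel,
       burden_fraction = tumor_area / (lung_px * mpp^2))
}

#' Share of a pixel grade's area lying in tumors of a given overall grade
#'
#' E.g. the fraction of all Grade 2 pixel area that sits inside Grade 3
#' tumors.
#'
#' @param tumors tumors from [segment_tumors()].
#' @param pixel_grade,overall_grade grade names ("grade1".."grade4") or class
#'   codes.
#' @return A fraction, or NA when no tumor contains the pixel grade.
#' @export
grade_area_within <- function(tumors, pixel_grade, overall_grade) {
  if (length(tumors) == 0L) stop("empty tumor set")
  pg <- as_grade_name(pixel_grade)
  og <- as_grade_code(overall_grade)
  total <- sum(vapply(tumors, function(tm) tm$grade_pixels[[pg]], numeric(1)))
  if (total == 0) return(NA_real_)
  inside <- sum(vapply(tumors, function(tm)
    if (tm$overall_grade == og) tm$grade_pixels[[pg]] else 0, numeric(1)))
  inside / total
}

as_grade_name <- function(g) {
  if (is.character(g)) return(match.arg(g, names(GRADE_CODES)))
  class_name(g)
}
as_grade_code <- function(g) {
  if (is.character(g)) return(GRADE_CODES[[match.arg(g, names(GRADE_CODES))]])
  as.integer(g)
}

#' Cumulative size distribution of tumors
#'
#' @param tumors nonempty tumor list.
#' @return List with `table` (data.frame area_um2, cum_freq: the empirical
#'   CDF at each sorted area) and `n_half_area`: the minimal number of
#'   (largest) tumors jointly holding at least half the total tumor area.
#' @export
size_distribution <- function(tumors) {
  if (length(tumors) == 0L) stop("empty tumor set")
  areas <- sort(vapply(tumors, function(tm) tm$area_um2, numeric(1)))
  cdf <- seq_along(areas) / length(areas)
  desc <- rev(areas)
  n_half <- which(cumsum(desc) >= sum(areas) / 2)[1]
  list(table = data.frame(area_um2 = areas, cum_freq = cdf),
       n_half_area = n_half)
}

#' Per-tumor table
#'
#' @param tumors tumors from [segment_tumors()].
#' @param path optional CSV path.
#' @return data.frame, one row per tumor.
#' @export
tumor_table <- function(tumors, path = NULL) {
  df <- data.frame(
    tumor_id = vapply(tumors, function(tm) tm$tumor_id, integer(1)),
    centroid_row = vapply(tumors, function(tm) tm$centroid[["row"]], numeric(1)),
    centroid_col = vapply(tumors, function(tm) tm$centroid[["col"]], numeric(1)),
    pixel_count = vapply(tumors, function(tm) tm$pixel_count, integer(1)),
    area_um2 = vapply(tumors, function(tm) tm$area_um2, numeric(1)),
    g1 = vapply(tumors, function(tm) tm$composition[["grade1"]], numeric(1)),
    g2 = vapply(tumors, function(tm) tm$composition[["grade2"]], numeric(1)),
    g3 = vapply(tumors, function(tm) tm$composition[["grade3"]], numeric(1)),
    g4 = vapply(tumors, function(tm) tm$composition[["grade4"]], numeric(1)),
    overall_grade = class_name(vapply(tumors, function(tm) tm$overall_grade,
                                      numeric(1))),
    sdi = vapply(tumors, function(tm) tm$sdi, numeric(1))
  )
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
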