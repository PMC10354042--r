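# Conversion of annotated slides into a patch library: tiling with
# reflection padding, dominant-class grouping, slide-disjoint 60/20/20
# splits, and area-balancing augmentation.

reflect_index <- function(n_out, n_in) {
  # 1-based reflected indices covering 1..n_out for a source of length n_in
  idx <- seq_len(n_out)
  period <- max(2L * n_in - 2L, 1L)
  idx <- (idx - 1L) %% period
  ifelse(idx < n_in, idx + 1L, 2L * n_in - idx - 1L)
}

#' Tile a slide into patches
#'
#' Divides an annotated slide into `size` x `size` patches on a regular grid.
#' Right/bottom remainders are covered by reflection-padding the image; label
#' pixels in the padded band are set to Background. The dominant class of each
#' patch is computed with [dominant_class()].
#'
#' @param image numeric (H, W, 3) RGB array.
#' @param mask a [label_mask()] congruent with `image`.
#' @param size patch side length in pixels (default 224).
#' @param stride grid stride in pixels (default `size`, non-overlapping).
#' @param slide_id identifier recorded on every patch.
#' @return List of patches; each patch is a list with `rgb`, `labels`,
#'   `slide_id`, `origin` (0-based c(row, col)) and `dominant_class`.
#' @export
tile_slide <- function(image, mask, size = 224, stride = size,
                       slide_id = "slide") {
  stopifnot_rgb(image)
  if (size < 1 || stride < 1) stop("size and stride must be >= 1")
  if (nrow(mask) != dim(image)[1] || ncol(mask) != dim(image)[2])
    stop("image and mask are not congruent")
  H <- dim(image)[1]; W <- dim(image)[2]
  origins_r <- seq(0L, max(H - 1L, 0L), by = stride)
  origins_c <- seq(0L, max(W - 1L, 0L), by = stride)

  Hp <- max(origins_r) + size
  Wp <- max(origins_c) + size
  ri <- reflect_index(Hp, H)
  ci <- reflect_index(Wp, W)
  padded <- image[ri, ci, , drop = FALSE]
  padlab <- matrix(0L, Hp, Wp)
  padlab[seq_len(H), seq_len(W)] <- unclass(mask)[, , drop = FALSE]

  patches <- list()
  for (orow in origins_r) {
    for (ocol in origins_c) {
      rs <- orow + seq_len(size)
      cs <- ocol + seq_len(size)
      lab <- padlab[rs, cs]
      patches[[length(patches) + 1L]] <- list(
        rgb = padded[rs, cs, , drop = FALSE],
        labels = lab,
        slide_id = slide_id,
        origin = c(orow, ocol),
        dominant_class = dominant_class(lab),
        augmented = FALSE
      )
    }
  }
  patches
}

#' Dominant class of a label raster
#'
#' The modal non-Background class. Ties are broken toward the higher class
#' code, i.e. toward the higher grade (and airway over alveoli), so rare
#' high-grade patches are not diluted into lower bins.
#'
#' @param labels integer matrix of class codes.
#' @return A class code (0 only when the raster is all Background).
#' @export
dominant_class <- function(labels) {
  if (length(labels) == 0L) stop("empty label raster")
  counts <- tabulate(labels[labels > 0L] + 0L, nbins = 6L)
  if (all(counts == 0L)) return(CLASS_CODES[["background"]])
  best <- max(counts)
  max(which(counts == best))    # highest code among tied modes
}

#' Build a patch library from annotated slides
#'
#' Slides are first assigned to train/validation/test splits (greedy by
#' annotated pixel count to approximate the requested fractions by area, in
#' seeded random order), so that no slide ever contributes patches to more
#' than one split. All slides are then tiled, all-Background patches dropped,
#' and up to `quota_per_class` patches selected per dominant class without
#' replacement.
#'
#' @param slides list of `list(image, mask, slide_id)`.
#' @param quota_per_class target patch count per class (default 6000).
#' @param split_fractions train/validation/test fractions, summing to 1.
#' @param size,stride tiling geometry.
#' @param seed RNG seed; the same seed yields an identical library.
#' @return A `patch_library`: list with `patches`, parallel `split` vector,
#'   and a `class_area` pixel tally (split x class).
#' @export
build_library <- function(slides, quota_per_class = 6000,
                          split_fractions = c(train = 0.6, validation = 0.2,
                                              test = 0.2),
                          size = 224, stride = size, seed = 1) {
  if (length(slides) < 3L)
    stop("need at least 3 slides (one per split)")
  if (abs(sum(split_fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  split_names <- c("train", "validation", "test")

  for (i in seq_along(slides)) {
    if (is.null(slides[[i]]$slide_id)) slides[[i]]$slide_id <- paste0("s", i)
  }
  weights <- vapply(slides, function(s) sum(unclass(s$mask) > 0L), numeric(1))
  total <- sum(weights)

  with_seed(seed, {
    ord <- sample(seq_along(slides))
    assigned <- character(length(slides))
    got <- c(train = 0, validation = 0, test = 0)
    target <- split_fractions * total
    for (i in ord) {
      deficit <- target - got
      pick <- split_names[which.max(deficit)]
      assigned[i] <- pick
      got[pick] <- got[pick] + weights[i]
    }
    # every split must own at least one slide
    for (s in split_names) {
      if (!any(assigned == s)) {
        donor <- names(which.max(table(assigned)))
        assigned[which(assigned == donor)[1]] <- s
      }
    }

    patches <- list(); splits <- character(0)
    for (i in seq_along(slides)) {
      ps <- tile_slide(slides[[i]]$image, slides[[i]]$mask, size = size,
                       stride = stride, slide_id = slides[[i]]$slide_id)
      keep <- vapply(ps, function(p) p$dominant_class > 0L, logical(1))
      ps <- ps[keep]
      patches <- c(patches, ps)
      splits <- c(splits, rep(assigned[i], length(ps)))
    }

    dom <- vapply(patches, function(p) p$dominant_class, integer(1))
    sel <- logical(length(patches))
    for (cls in 1:6) {
      idx <- which(dom == cls)
      if (length(idx) == 0L) {
        warning("no patches available for class ", class_name(cls))
        next
      }
      if (length(idx) > quota_per_class)
        idx <- sample(idx, quota_per_class)
      else if (length(idx) < quota_per_class)
        message("class ", class_name(cls), ": only ", length(idx),
                " patches available (quota ", quota_per_class, ")")
      sel[idx] <- TRUE
    }
    lib <- structure(list(patches = patches[sel], split = splits[sel],
                          size = size, seed = seed),
                     class = "patch_library")
    lib$class_area <- library_class_area(lib)
    lib
  })
}

# per-split, per-class pixel tallies over the six target classes
library_class_area <- function(library) {
  splits <- c("train", "validation", "test")
  area <- matrix(0, length(splits), 6,
                 dimnames = list(splits, CLASS_NAMES[-1]))
  for (i in seq_along(library$patches)) {
    counts <- tabulate(library$patches[[i]]$labels, nbins = 6L)
    area[library$split[i], ] <- area[library$split[i], ] + counts
  }
  area
}

#' @export
print.patch_library <- function(x, ...) {
  cat(sprintf("<patch_library> %d patches (%d px)\n",
              length(x$patches), x$size))
  print(table(split = x$split,
              class = class_name(vapply(x$patches,
                                        function(p) p$dominant_class,
                                        integer(1)))))
  invisible(x)
}

# random geometric augmentation applied jointly to rgb (bilinear) and labels
# (nearest); translation <= size/4, shear <= 10 deg, rotation in
# {90, 180, 270} +/- 10 deg; out-of-frame samples use reflection fill
augment_patch <- function(patch) {
  size <- nrow(patch$labels)
  theta <- (sample(c(90, 180, 270), 1) + runif(1, -10, 10)) * pi / 180
  shear <- runif(1, -10, 10) * pi / 180
  shift <- runif(2, -size / 4, size / 4)

  ctr <- (size + 1) / 2
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2,
              byrow = TRUE)
  S <- matrix(c(1, tan(shear), 0, 1), 2, 2, byrow = TRUE)
  M <- R %*% S                       # output -> input linear part
  m <- ceiling(size / 2)             # reflection margin
  ri <- reflect_index(size + 2 * m, size)
  pad_rgb <- patch$rgb[ri, ri, , drop = FALSE]
  pad_lab <- array(patch$labels[ri, ri] * 1.0, c(size + 2 * m, size + 2 * m, 1))
  # 0-based pull transform into the padded frame
  offset <- c(ctr - 1 + m, ctr - 1 + m) - M %*% c(ctr - 1, ctr - 1) +
    shift
  A <- cbind(M, offset)
  new_rgb <- cpp_warp_affine(pad_rgb, A, size, size, TRUE, 255)
  new_lab <- cpp_warp_affine(pad_lab, A, size, size, FALSE, 0)

  out <- patch
  out$rgb <- new_rgb
  out$labels <- matrix(as.integer(round(new_lab[, , 1])), size, size)
  out$dominant_class <- dominant_class(out$labels)
  out$augmented <- TRUE
  out
}

#' Balance class areas within each split by augmentation
#'
#' Within each split, augmented copies (random shift, shear, rotation applied
#' jointly to image and labels) of patches whose dominant class is the
#' underrepresented class are appended until every target class's total pixel
#' area is within `tolerance` of the largest class area in that split.
#' Original patches are always retained.
#'
#' @param library a `patch_library`.
#' @param tolerance allowed relative shortfall (default 0.05).
#' @param seed RNG seed.
#' @param max_rounds safety cap on augmentation passes per class.
#' @return A `patch_library` with appended augmented patches and an updated
#'   `class_area` tally.
#' @export
balance_by_area <- function(library, tolerance = 0.05, seed = 1,
                            max_rounds = 2000) {
  if (length(library$patches) == 0L) stop("empty library")
  with_seed(seed, {
    for (split in unique(library$split)) {
      unbalanceable <- integer(0)
      # the balancing target is fixed at entry: augmented copies of one class
      # carry collateral pixels of others, so a moving maximum would inflate
      # the library without bound
      target <- (1 - tolerance) * max(library_class_area(library)[split, ])
      repeat {
        area <- library_class_area(library)[split, ]
        present <- area > 0
        deficient <- setdiff(which(area < target & present), unbalanceable)
        if (length(deficient) == 0L) break
        cls <- as.integer(deficient[which.min(area[deficient])])
        in_split <- which(library$split == split)
        pool <- in_split[vapply(library$patches[in_split],
                                function(p) p$dominant_class == cls,
                                logical(1))]
        if (length(pool) == 0L) {
          warning("split ", split, ": no source patches for class ",
                  class_name(cls), "; left unbalanced")
          unbalanceable <- c(unbalanceable, cls)
          next
        }
        rounds <- 0L
        while (area[cls] < target && rounds < max_rounds) {
          rounds <- rounds + 1L
          src <- library$patches[[if (length(pool) == 1L) pool else
            sample(pool, 1)]]
          aug <- augment_patch(src)
          # a transform can push the class of interest out of frame; such a
          # copy contributes nothing and is discarded
          if (tabulate(aug$labels, nbins = 6L)[cls] == 0L) next
          library$patches[[length(library$patches) + 1L]] <- aug
          library$split <- c(library$split, split)
          area <- area + tabulate(aug$labels, nbins = 6L)
        }
        if (rounds >= max_rounds) break
      }
    }
    library$class_area <- library_class_area(library)
    library
  })
}

#' Write / read a patch-library manifest
#'
#' The manifest records one row per patch: slide id, origin, dominant class
#' and split assignment.
#'
#' @param library a `patch_library`.
#' @param path CSV path.
#' @return `library_manifest` returns the manifest data.frame invisibly after
#'   writing.
#' @export
library_manifest <- function(library, path = NULL) {
  df <- data.frame(
    slide_id = vapply(library$patches, function(p) p$slide_id, character(1)),
    origin_row = vapply(library$patches, function(p) p$origin[1], numeric(1)),
    origin_col = vapply(library$patches, function(p) p$origin[2], numeric(1)),
    dominant_class = class_name(vapply(library$patches,
                                       function(p) p$dominant_class,
                                       integer(1))),
    split = library$split,
    augmented = vapply(library$patches, function(p) isTRUE(p$augmented),
                       logical(1))
  )
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  invisible(df)
}
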