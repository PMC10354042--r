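# Deterministic generators of class-textured slides, ground-truth label
# masks, and DAB-like IHC renderings, so the whole pipeline is testable with
# no slide archive.
#
# Textures are engineered to be cleanly separable (distinct stain chemistry
# and spatial motifs per class) so that network benchmarks test the pipeline
# machinery rather than representational capacity. H&E rendering and IHC
# rendering go through the same Beer-Lambert compositing used by the stain
# modules, so color-deconvolution oracles are exact by construction.

# evaluate code under a temporary RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# H-DAB stain vectors (Ruifrok & Johnston convention), unit columns
HDAB_VECTORS <- local({
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  cbind(hematoxylin = h / sqrt(sum(h^2)), dab = d / sqrt(sum(d^2)))
})

# composite concentration fields through stain vectors into 0..255 RGB
render_stains <- function(conc_list, vectors, I0 = 255) {
  d <- dim(conc_list[[1]])
  od <- array(0, c(d, 3))
  for (s in seq_along(conc_list)) {
    for (ch in 1:3) od[, , ch] <- od[, , ch] + conc_list[[s]] * vectors[ch, s]
  }
  od_to_rgb(od, I0 = I0)
}

# stamp gaussian-ish nuclei disks onto a concentration field (in place-ish)
stamp_nuclei <- function(field, rows, cols, radius, amplitude) {
  H <- nrow(field); W <- ncol(field)
  r <- ceiling(radius)
  span <- -r:r
  disk <- outer(span, span, function(a, b) {
    d2 <- a^2 + b^2
    ifelse(d2 <= radius^2, exp(-d2 / (2 * (radius / 1.6)^2)), 0)
  })
  for (q in seq_along(rows)) {
    ri <- (rows[q] + span); ci <- (cols[q] + span)
    ok_r <- ri >= 1 & ri <= H; ok_c <- ci >= 1 & ci <= W
    field[ri[ok_r], ci[ok_c]] <-
      field[ri[ok_r], ci[ok_c]] + amplitude * disk[ok_r, ok_c]
  }
  field
}

# per-class texture recipes: eosin background, hematoxylin nuclei whose
# density/intensity increase monotonically from Grade 1 to Grade 4
TEXTURE_RECIPES <- list(
  normal_alveoli = list(kind = "lattice", e_base = 0.04, e_wall = 0.55,
                        pitch = 22, nuc_density = 0.0006, nuc_amp = 0.5,
                        nuc_rad = 2.0),
  normal_airway  = list(kind = "rings", e_base = 0.30, e_ring = 0.55,
                        period = 9, nuc_density = 0.002, nuc_amp = 0.5,
                        nuc_rad = 2.0),
  grade1 = list(kind = "tumor", e_base = 0.22, nuc_density = 0.004,
                nuc_amp = 0.50, nuc_rad = 2.2),
  grade2 = list(kind = "tumor", e_base = 0.34, nuc_density = 0.010,
                nuc_amp = 0.70, nuc_rad = 2.4),
  grade3 = list(kind = "tumor", e_base = 0.46, nuc_density = 0.018,
                nuc_amp = 0.90, nuc_rad = 2.6),
  grade4 = list(kind = "tumor", e_base = 0.58, nuc_density = 0.030,
                nuc_amp = 1.10, nuc_rad = 2.8)
)

#' Generate a procedural texture tile for one pixel class
#'
#' Each non-background class has a visually and chromatically distinct
#' procedural texture: a sparse eosin lattice for normal alveoli, concentric
#' eosin rings for normal airway, and tumor textures whose hematoxylin
#' (nuclear) density and intensity increase strictly from Grade 1 to Grade 4.
#'
#' @param class class code (1..6) or name; Background (0) is rejected.
#' @param size tile side length in pixels.
#' @param seed RNG seed; the same (class, seed) always yields the same tile.
#' @param stain_matrix 3x2 H&E stain vectors used for rendering.
#' @return Numeric (size, size, 3) RGB array in 0..255.
#' @export
make_texture_tile <- function(class, size = 64, seed = 1,
                              stain_matrix = MACENKO_REFERENCE$stain_matrix) {
  if (is.character(class)) class <- CLASS_CODES[[class]]
  class <- as.integer(class)
  if (class == CLASS_CODES[["background"]])
    stop("Background has no texture; pick a class in 1..6")
  if (is.na(class) || class < 1L || class > 6L) stop("unknown class code")
  rec <- TEXTURE_RECIPES[[class_name(class)]]

  with_seed(seed * 7L + class, {
    e <- matrix(rec$e_base, size, size)
    if (rec$kind == "lattice") {
      ph <- sample.int(rec$pitch, 2)
      wall <- ((row(e) + ph[1]) %% rec$pitch < 2) |
              ((col(e) + ph[2]) %% rec$pitch < 2)
      e <- e + rec$e_wall * wall
    } else if (rec$kind == "rings") {
      ctr <- runif(2, 0.25 * size, 0.75 * size)
      dist <- sqrt((row(e) - ctr[1])^2 + (col(e) - ctr[2])^2)
      e <- e + rec$e_ring * (sin(2 * pi * dist / rec$period)^2 > 0.75)
    }
    e <- e * matrix(runif(size^2, 0.9, 1.1), size, size)

    h_base <- if (is.null(rec$h_base)) 0.02 else rec$h_base
    h <- matrix(h_base, size, size)
    n_nuc <- max(1L, round(rec$nuc_density * size^2))
    rows <- sample.int(size, n_nuc, replace = TRUE)
    cols <- sample.int(size, n_nuc, replace = TRUE)
    h <- stamp_nuclei(h, rows, cols, rec$nuc_rad, rec$nuc_amp)
    render_stains(list(h, e), stain_matrix)
  })
}

#' Specify and generate a synthetic annotated slide
#'
#' `slide_layout_spec` describes an elliptical "lung" of alveolar texture on a
#' white background, optional airway rings, and circular tumor blobs whose
#' per-grade composition is laid out as angular sectors (so the realized
#' composition matches the requested one up to pixel discretization).
#' `make_synthetic_slide` renders it to an RGB image plus ground-truth
#' [label_mask()].
#'
#' @param canvas height/width in pixels (length 2).
#' @param tumors list of blobs, each `list(center = c(r, c), radius = px,
#'   composition = named fractions over "grade1".."grade4" summing to 1)`.
#' @param n_airways number of airway rings to place.
#' @param seed RNG seed (textures and airway placement).
#' @param microns_per_pixel physical resolution.
#' @return `make_synthetic_slide` returns `list(image, mask, spec)`.
#' @export
slide_layout_spec <- function(canvas = c(256, 256), tumors = list(),
                              n_airways = 1, seed = 1,
                              microns_per_pixel = REFERENCE_MPP) {
  for (tm in tumors) {
    comp <- tm$composition
    if (abs(sum(comp) - 1) > 1e-6) stop("tumor composition must sum to 1")
    if (!all(names(comp) %in% names(GRADE_CODES)))
      stop("composition names must be grade1..grade4")
  }
  list(canvas = canvas, tumors = tumors, n_airways = n_airways, seed = seed,
       microns_per_pixel = microns_per_pixel)
}

#' @rdname slide_layout_spec
#' @param spec a `slide_layout_spec()`.
#' @export
make_synthetic_slide <- function(spec) {
  H <- spec$canvas[1]; W <- spec$canvas[2]
  labels <- matrix(0L, H, W)
  ctr <- c(H, W) / 2
  rad <- c(H, W) * 0.45
  rr <- row(labels); cc <- col(labels)
  inside <- ((rr - ctr[1]) / rad[1])^2 + ((cc - ctr[2]) / rad[2])^2 <= 1
  labels[inside] <- CLASS_CODES[["normal_alveoli"]]

  with_seed(spec$seed, {
    for (q in seq_len(spec$n_airways)) {
      ar <- runif(1, 0.08, 0.13) * min(H, W)
      # keep airways clear of tumor blobs so both survive intact
      for (try in 1:25) {
        ac <- ctr + runif(2, -0.35, 0.35) * c(H, W)
        clear <- all(vapply(spec$tumors, function(tm)
          sqrt(sum((ac - tm$center)^2)) > ar + tm$radius, logical(1)))
        if (clear) break
      }
      d <- sqrt((rr - ac[1])^2 + (cc - ac[2])^2)
      ring <- d <= ar & inside
      labels[ring] <- CLASS_CODES[["normal_airway"]]
    }
  })

  for (tm in spec$tumors) {
    d <- sqrt((rr - tm$center[1])^2 + (cc - tm$center[2])^2)
    blob <- d <= tm$radius & inside
    ang <- atan2(cc - tm$center[2], rr - tm$center[1])  # -pi..pi
    frac <- (ang + pi) / (2 * pi)
    cum <- cumsum(tm$composition)
    sector <- findInterval(frac, c(0, cum), rightmost.closed = TRUE)
    sector[sector > length(cum)] <- length(cum)
    codes <- GRADE_CODES[names(tm$composition)]
    labels[blob] <- codes[sector[blob]]          # later blob wins on overlap
  }

  image <- array(255, c(H, W, 3))
  for (cls in 1:6) {
    sel <- labels == cls
    if (!any(sel)) next
    tile <- make_texture_tile(cls, size = max(H, W), seed = spec$seed)
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[sel] <- tile[, , ch][cbind(rr[sel], cc[sel])]
      image[, , ch] <- plane
    }
  }
  list(image = image,
       mask = label_mask(labels, spec$microns_per_pixel),
       spec = spec)
}

#' Specify and render a DAB-like IHC point pattern over a grade map
#'
#' Cells are placed by seeded Poisson sampling over tissue pixels; each cell
#' is positive with probability `baseline * enrichment[class]` (clipped to
#' 0..1). Nuclei are rendered as hematoxylin disks, positives with an added
#' DAB disk, through the same H-DAB vectors used by [detect_cells()].
#'
#' @param cells_per_mm2 expected cell density over tissue.
#' @param baseline baseline positive fraction.
#' @param enrichment named multipliers per class name (missing classes get 1).
#' @param nucleus_radius nucleus radius in pixels.
#' @param seed RNG seed.
#' @return `make_ihc_pattern` returns `list(image, cells)`, where `cells` is a
#'   data.frame (row, col, positive, class) of ground truth (0-based coords).
#' @export
ihc_pattern_spec <- function(cells_per_mm2 = 3000, baseline = 0.2,
                             enrichment = c(), nucleus_radius = 3, seed = 1) {
  if (cells_per_mm2 <= 0) stop("cell density must be positive")
  list(cells_per_mm2 = cells_per_mm2, baseline = baseline,
       enrichment = enrichment, nucleus_radius = nucleus_radius, seed = seed)
}

#' @rdname ihc_pattern_spec
#' @param grade_map a [grade_map()] giving tissue and class layout.
#' @param spec an `ihc_pattern_spec()`.
#' @export
make_ihc_pattern <- function(grade_map, spec) {
  H <- nrow(grade_map); W <- ncol(grade_map)
  mpp <- mpp_of(grade_map)
  tissue_idx <- which(grade_map > 0L)
  if (length(tissue_idx) == 0L) stop("grade map has no tissue")
  area_mm2 <- length(tissue_idx) * (mpp / 1000)^2

  enr <- rep(1, 7)
  names(enr) <- CLASS_NAMES
  if (length(spec$enrichment))
    enr[names(spec$enrichment)] <- spec$enrichment

  with_seed(spec$seed, {
    n <- rpois(1, spec$cells_per_mm2 * area_mm2)
    # hard-core thinning: nuclei keep at least ~a diameter of separation, as
    # real cell nuclei do; this also makes the detection oracle exact
    pick <- sample(tissue_idx, n, replace = TRUE)
    r_all <- (pick - 1L) %% H
    c_all <- (pick - 1L) %/% H
    min_d2 <- (2 * spec$nucleus_radius - 1)^2
    keep <- integer(0)
    for (q in seq_len(n)) {
      if (length(keep) == 0L ||
          all((r_all[keep] - r_all[q])^2 +
              (c_all[keep] - c_all[q])^2 >= min_d2))
        keep <- c(keep, q)
    }
    n <- length(keep)
    rows <- r_all[keep]
    cols <- c_all[keep]
    cls <- grade_map[pick[keep]]
    p <- pmin(pmax(spec$baseline * enr[cls + 1L], 0), 1)
    positive <- rbinom(n, 1, p) == 1

    h <- matrix(0.015, H, W)
    d <- matrix(0, H, W)
    h <- stamp_nuclei(h, rows + 1L, cols + 1L, spec$nucleus_radius, 0.9)
    if (any(positive))
      d <- stamp_nuclei(d, rows[positive] + 1L, cols[positive] + 1L,
                        spec$nucleus_radius + 0.5, 0.9)
    image <- render_stains(list(h, d), HDAB_VECTORS)
    list(image = image,
         cells = data.frame(row = rows, col = cols, positive = positive,
                            class = cls))
  })
}

#' Generate the benchmark slide set
#'
#' A fixed family of synthetic annotated slides used for the desk-scale
#' network benchmark: each slide carries four tumor blobs whose compositions
#' cycle through a list covering all four grades (pure and mixed), plus
#' airway rings and the alveolar lung background.
#'
#' @param n number of slides.
#' @param canvas slide side length, px.
#' @param seed RNG seed.
#' @return List of `list(image, mask, slide_id)` ready for
#'   [build_library()].
#' @export
make_benchmark_slides <- function(n = 6, canvas = 320, seed = 1) {
  # every slide carries all four grades: one pure blob (rotating with the
  # slide index) plus three fixed mixed blobs that jointly cover grades 1-4
  comps_pure <- list(c(grade1 = 1.0), c(grade2 = 1.0), c(grade3 = 1.0),
                     c(grade4 = 1.0))
  comps_mixed <- list(c(grade2 = 0.5, grade3 = 0.5),
                      c(grade3 = 0.6, grade4 = 0.4),
                      c(grade1 = 0.5, grade2 = 0.5))
  lapply(seq_len(n), function(i) {
    sl <- with_seed(seed * 1000 + i, {
      picks <- c(comps_pure[(i - 1) %% 4 + 1L], comps_mixed)
      tum <- lapply(1:4, function(q) {
        list(center = runif(2, 0.25 * canvas, 0.75 * canvas),
             radius = runif(1, 0.09, 0.14) * canvas,
             composition = picks[[q]])
      })
      spec <- slide_layout_spec(canvas = c(canvas, canvas), tumors = tum,
                                n_airways = 3, seed = seed * 1000 + i)
      make_synthetic_slide(spec)
    })
    list(image = sl$image, mask = sl$mask, slide_id = paste0("bench", i))
  })
}

#' The bundled rater-agreement confusion matrix
#'
#' The published count table comparing overall tumor grades assigned by the
#' automated pipeline (rows: Normal call plus Grades 1-4) against an expert
#' human rater (columns: Grades 1-4) over 1958 manually segmented tumors.
#'
#' @return A [confusion_matrix()].
#' @export
table1_fixture <- function() {
  counts <- matrix(
    c(26,   0,   0,  0,
      649, 66,  12,  0,
      56, 322,  40,  1,
      23,  53, 690,  2,
      0,    0,   2, 16),
    nrow = 5, byrow = TRUE,
    dimnames = list(c("Normal", "Grade 1", "Grade 2", "Grade 3", "Grade 4"),
                    c("Grade 1", "Grade 2", "Grade 3", "Grade 4"))
  )
  confusion_matrix(counts)
}
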