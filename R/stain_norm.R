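# Macenko stain-vector estimation and normalization of H&E images.
#
# Working space is base-10 optical density (Beer-Lambert): stain
# concentrations are linear in OD, so an H&E pixel is modelled as
# od = M %*% c with M the 3x2 matrix of unit stain vectors and c >= 0 the
# per-stain concentrations. Macenko estimates M from the extreme percentile
# directions of tissue pixels projected into the top-2 singular plane of the
# OD point cloud.

# widely used reference H&E stain profile (columns hematoxylin, eosin) and
# 99th-percentile concentrations, used as the normalization target when no
# fitted reference is supplied
MACENKO_REFERENCE <- list(
  stain_matrix = matrix(c(0.5626, 0.7201, 0.4062,
                          0.2159, 0.8012, 0.5581), 3, 2),
  max_concentration = c(1.9705, 1.0308),
  I0 = c(255, 255, 255)
)

#' Convert an RGB image to optical density
#'
#' OD is computed per channel as `-log10(max(I, 1) / I0)`; pixels at the white
#' level have OD exactly 0. The inverse is [od_to_rgb()].
#'
#' @param image numeric (H, W, 3) array, channels in 0..255.
#' @param I0 background (white) intensity per channel, length 1 or 3, > 0.
#' @return List with `od` (H, W, 3 array, dimensionless, base 10) and
#'   `source_white` (length-3 I0).
#' @export
rgb_to_od <- function(image, I0 = 255) {
  stopifnot_rgb(image)
  if (any(I0 <= 0)) stop("I0 must be positive")
  I0 <- rep(I0, length.out = 3L)
  od <- image
  for (ch in 1:3) od[, , ch] <- -log10(pmax(image[, , ch], 1) / I0[ch])
  od[od < 0] <- 0
  list(od = od, source_white = I0)
}

#' @rdname rgb_to_od
#' @param od optical-density array as produced by `rgb_to_od`.
#' @export
od_to_rgb <- function(od, I0 = 255) {
  I0 <- rep(I0, length.out = 3L)
  out <- od
  for (ch in 1:3) out[, , ch] <- I0[ch] * 10^(-od[, , ch])
  pmin(pmax(out, 0), 255)
}

#' Estimate an H&E stain model by the Macenko method
#'
#' Tissue pixels (OD norm above `beta_od_floor`) are projected onto the plane
#' of the top two right-singular vectors of the OD cloud; the stain vectors
#' are the `alpha` and `100 - alpha` percentile directions of the projection
#' angles. Columns are unit vectors ordered hematoxylin first (larger
#' blue-channel OD component). Concentrations are obtained by least-squares
#' unmixing and summarized by their 99th percentile per stain.
#'
#' @param image numeric (H, W, 3) RGB array in 0..255.
#' @param alpha percentile (in percent) for the extreme-angle estimate.
#' @param beta_od_floor minimum OD Euclidean norm for a pixel to count as
#'   tissue.
#' @param I0 white level per channel.
#' @param min_pixels minimum number of tissue pixels required.
#' @return A `stain_model`: list with `stain_matrix` (3x2, unit columns),
#'   `max_concentration` (length 2) and `I0`.
#' @export
estimate_stain_model <- function(image, alpha = 1, beta_od_floor = 0.15,
                                 I0 = 255, min_pixels = 100) {
  odi <- rgb_to_od(image, I0)
  od <- matrix(odi$od, ncol = 3L)          # pixels x channels
  tissue <- od[sqrt(rowSums(od^2)) > beta_od_floor, , drop = FALSE]
  if (nrow(tissue) < min_pixels)
    stop("degenerate input: only ", nrow(tissue), " tissue pixels (OD norm > ",
         beta_od_floor, "), need ", min_pixels)

  sv <- svd(tissue, nu = 0, nv = 3)
  if (sv$d[2] < 1e-6 * sv$d[1] || sv$d[2] < 1e-9)
    stop("collinearity: OD cloud is rank-1 (single stain or grayscale input)")
  V <- sv$v[, 1:2, drop = FALSE]
  # orient the plane so projections fall in a consistent half-space
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]
  proj <- tissue %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  q <- quantile(phi, c(alpha / 100, 1 - alpha / 100), names = FALSE)
  v1 <- V %*% rbind(cos(q[1]), sin(q[1]))
  v2 <- V %*% rbind(cos(q[2]), sin(q[2]))
  fix_sign <- function(v) if (sum(v) < 0) -v else v
  v1 <- fix_sign(v1); v2 <- fix_sign(v2)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  v1 <- v1 / sqrt(sum(v1^2)); v2 <- v2 / sqrt(sum(v2^2))
  # hematoxylin (blue stain) absorbs red light most strongly, so it is the
  # column with the larger red-channel OD component
  M <- if (v1[1] >= v2[1]) cbind(v1, v2) else cbind(v2, v1)
  dimnames(M) <- list(c("R", "G", "B"), c("hematoxylin", "eosin"))

  conc <- unmix_concentrations(od, M)
  maxc <- apply(conc, 2, quantile, probs = 0.99, names = FALSE)
  structure(list(stain_matrix = M, max_concentration = maxc,
                 I0 = rep(I0, length.out = 3L)),
            class = "stain_model")
}

# least-squares unmixing of OD pixels (n x 3) against a 3 x 2 stain matrix,
# concentrations clipped to be nonnegative
unmix_concentrations <- function(od, M) {
  conc <- od %*% M %*% solve(crossprod(M))
  conc[conc < 0] <- 0
  conc
}

#' Normalize an H&E image to a reference stain profile
#'
#' The source image's stain model is estimated, its concentrations are
#' rescaled so that each stain's 99th percentile matches the reference
#' `max_concentration`, and the image is re-composited with the reference
#' stain matrix.
#'
#' @inheritParams estimate_stain_model
#' @param reference a `stain_model`; defaults to the built-in reference
#'   H&E profile.
#' @return Normalized RGB (H, W, 3) array in 0..255.
#' @export
normalize_to_reference <- function(image, reference = NULL, I0 = 255,
                                   alpha = 1, beta_od_floor = 0.15) {
  if (is.null(reference)) reference <- default_stain_reference()
  if (any(reference$max_concentration <= 0))
    stop("reference max_concentration must be positive")
  src <- estimate_stain_model(image, alpha = alpha,
                              beta_od_floor = beta_od_floor, I0 = I0)
  d <- dim(image)
  od <- matrix(rgb_to_od(image, I0)$od, ncol = 3L)
  conc <- unmix_concentrations(od, src$stain_matrix)
  scale <- reference$max_concentration /
    pmax(src$max_concentration, 1e-8)
  conc <- sweep(conc, 2, scale, `*`)
  od_new <- conc %*% t(reference$stain_matrix)
  od_to_rgb(array(od_new, d), I0 = reference$I0)
}

#' @rdname normalize_to_reference
#' @export
default_stain_reference <- function() {
  structure(MACENKO_REFERENCE, class = "stain_model")
}

#' Serialize a stain model to / from JSON
#'
#' @param model a `stain_model`.
#' @param path JSON file path.
#' @return `read_stain_model` returns a `stain_model`.
#' @export
write_stain_model <- function(model, path) {
  jsonlite::write_json(
    list(stain_matrix = unname(as.matrix(model$stain_matrix)),
         max_concentration = model$max_concentration,
         I0 = model$I0),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_stain_model
#' @export
read_stain_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(stain_matrix = matrix(unlist(x$stain_matrix), 3, 2),
                 max_concentration = as.numeric(x$max_concentration),
                 I0 = as.numeric(x$I0)),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model>\n")
  print(round(x$stain_matrix, 4))
  cat("max concentration:", round(x$max_concentration, 4), "\n")
  invisible(x)
}

# angular distance in degrees between unit vectors (used by tests and QC)
stain_angle_deg <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  acos(pmin(pmax(abs(sum(u * v)), -1), 1)) * 180 / pi
}
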