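# Network construction, differentiation, training and slide inference.

test_that("convolution and transposed-convolution gradients match finite
           differences", {
  set.seed(42)
  x <- array(rnorm(7 * 8 * 2 * 2), c(7, 8, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
  b <- rnorm(3) * 0.1
  dy <- NULL
  fwd <- function(x., w., b.)
    sum(luadgrader:::cpp_conv_fwd(x., w., b., 2L, 1L, 1L) * dy)
  dy <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  bw <- luadgrader:::cpp_conv_bwd(x, w, dy, 2L, 1L, 1L)
  for (i in sample(length(x), 4))
    expect_equal(num_grad(function(a) fwd(a, w, b), x, i), bw$dx[i],
                 tolerance = 1e-5)
  for (i in sample(length(w), 4))
    expect_equal(num_grad(function(a) fwd(x, a, b), w, i), bw$dw[i],
                 tolerance = 1e-5)
  expect_equal(num_grad(function(a) fwd(x, w, a), b, 2), bw$db[2],
               tolerance = 1e-5)

  xt <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  wt <- array(rnorm(4 * 4 * 2 * 3) * 0.3, c(4, 4, 2, 3))
  bt <- rnorm(2) * 0.1
  dyt <- array(rnorm(8 * 10 * 2 * 2), c(8, 10, 2, 2))
  fwdt <- function(x., w., b.)
    sum(luadgrader:::cpp_convt_fwd(x., w., b., 2L, 1L) * dyt)
  bwt <- luadgrader:::cpp_convt_bwd(xt, wt, dyt, 2L, 1L)
  for (i in sample(length(xt), 4))
    expect_equal(num_grad(function(a) fwdt(a, wt, bt), xt, i), bwt$dx[i],
                 tolerance = 1e-5)
  for (i in sample(length(wt), 4))
    expect_equal(num_grad(function(a) fwdt(xt, a, bt), wt, i), bwt$dw[i],
                 tolerance = 1e-5)
})

test_that("the full network backward pass matches finite differences", {
  net <- build_network(grader_spec("desk", input_size = 8, base_width = 4),
                       seed = 3)
  set.seed(4)
  x <- array(rnorm(8 * 8 * 3 * 2) * 0.3, c(8, 8, 3, 2))
  y <- array(sample(0:6, 128, TRUE), c(8, 8, 2))
  fw <- luadgrader:::net_forward(net, x)
  sm <- luadgrader:::cpp_softmax_ce(fw$logits, y)
  gr <- luadgrader:::net_backward(net, fw$caches, sm$grad)
  paths <- luadgrader:::param_paths(net$layers)
  loss_of <- function(layers) {
    n2 <- net; n2$layers <- layers
    luadgrader:::cpp_softmax_ce(
      luadgrader:::net_forward(n2, x, FALSE)$logits, y)$loss
  }
  for (p in paths[round(seq(1, length(paths), length.out = 8))]) {
    w <- luadgrader:::get_path(net$layers, p)
    g <- luadgrader:::get_path(gr, p)
    i <- sample(length(w), 1)
    up <- function(v) luadgrader:::set_path(net$layers, p,
                                            { w2 <- w; w2[i] <- v; w2 })
    eps <- 1e-6
    num <- (loss_of(up(w[i] + eps)) - loss_of(up(w[i] - eps))) / (2 * eps)
    expect_equal(num, g[i], tolerance = 1e-4)
  }
})

test_that("forward pass emits a per-pixel probability simplex at input
           resolution", {
  net <- build_network(grader_spec("desk", input_size = 32), seed = 1)
  set.seed(1)
  patch <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  pr <- predict_patch(net, patch)
  expect_equal(dim(pr), c(32, 32, 6))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_lt(max(abs(apply(pr, c(1, 2), sum) - 1)), 1e-5)
  expect_error(predict_patch(net, array(0, c(16, 16, 3))), "no implicit")
})

test_that("atrous rate counts skipped pixels: a 3x3 filter at rate 4 spans
           11 pixels", {
  expect_equal(atrous_span(3, 4), 11)
  expect_equal(atrous_span(3, 0), 3)
  expect_equal(atrous_span(3, 1), 5)
})

test_that("the desk preset stays small and the spec validates its inputs", {
  net <- build_network(grader_spec("desk", input_size = 64), seed = 2)
  expect_lt(n_params(net), 2e5)
  expect_error(grader_spec(base_width = 0), "width")
  expect_error(grader_spec(input_size = 100, encoder_depth = 3), "divisible")
  expect_error(training_config(lr = 0), "config")
  expect_error(training_config(epochs = 0), "config")
})

test_that("weight initialization and training are deterministic under a
           fixed seed", {
  n1 <- build_network(grader_spec("desk", input_size = 16), seed = 5)
  n2 <- build_network(grader_spec("desk", input_size = 16), seed = 5)
  expect_identical(n1$layers, n2$layers)

  slides <- make_benchmark_slides(3, 128, seed = 2)
  lib <- suppressMessages(suppressWarnings(
    build_library(slides, quota_per_class = 6, size = 16, stride = 16,
                  seed = 3)))
  cfg <- training_config(epochs = 2, minibatch = 4, lr = 0.002, seed = 5)
  f1 <- train_network(build_network(grader_spec("desk", input_size = 16),
                                    seed = 5), lib, cfg)
  f2 <- train_network(build_network(grader_spec("desk", input_size = 16),
                                    seed = 5), lib, cfg)
  expect_equal(f1$log, f2$log, tolerance = 1e-12)
})

test_that("a single-patch library is overfit to perfect accuracy", {
  tile <- make_texture_tile(CLASS_CODES[["grade4"]], 32, seed = 8)
  patch <- list(rgb = tile, labels = matrix(6L, 32, 32), slide_id = "s",
                origin = c(0, 0), dominant_class = 6L, augmented = FALSE)
  lib <- structure(list(patches = list(patch, patch),
                        split = c("train", "validation"), size = 32,
                        seed = 1),
                   class = "patch_library")
  fit <- train_network(build_network(grader_spec("desk", input_size = 32),
                                     seed = 1), lib,
                       training_config(epochs = 40, minibatch = 1,
                                       lr = 0.005, seed = 1))
  expect_equal(max(fit$log$val_acc), 1.0)
})

test_that("networks are equivariant to spatial transposition", {
  net <- build_network(grader_spec("desk", input_size = 16), seed = 7)
  nett <- luadgrader:::transpose_network(net)
  set.seed(2)
  x <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  xt <- aperm(x, c(2, 1, 3))
  p1 <- predict_patch(net, x)
  p2 <- predict_patch(nett, xt)
  expect_equal(aperm(p1, c(2, 1, 3)), p2, tolerance = 1e-10)
})

test_that("checkpoints round-trip through save/load", {
  net <- build_network(grader_spec("desk", input_size = 16), seed = 9)
  p <- withr::local_tempfile(fileext = ".ckpt")
  save_network(net, p)
  back <- load_network(p)
  expect_identical(back$layers, net$layers)
  expect_identical(unclass(back$spec), unclass(net$spec))
})

test_that("grade_slide masks non-tissue, matches input geometry, and equals
           patchwise inference at stride = patch on tile interiors", {
  net <- build_network(grader_spec("desk", input_size = 32), seed = 3)

  white <- array(255, c(40, 52, 3))
  gm <- grade_slide(net, white, stride = 32, smooth_window = 1)
  expect_equal(dim(gm), c(40, 52))
  expect_true(all(unclass(gm) == 0))

  slide <- get_demo_slide()
  img <- slide$image[1:64, 1:64, ]
  gm1 <- grade_slide(net, img, stride = 32, smooth_window = 1)
  pw <- matrix(0L, 64, 64)
  for (orow in c(0, 32)) for (ocol in c(0, 32)) {
    pr <- predict_patch(net, img[orow + 1:32, ocol + 1:32, ])
    pw[orow + 1:32, ocol + 1:32] <- apply(pr, c(1, 2), which.max)
  }
  od <- rgb_to_od(img)$od
  tissue <- sqrt(od[, , 1]^2 + od[, , 2]^2 + od[, , 3]^2) > 0.15
  pw[!tissue] <- 0L
  expect_equal(unclass(gm1), pw, ignore_attr = TRUE)

  expect_error(grade_slide(net, img, stride = 64), "stride")
})

test_that("overlap averaging plus modal smoothing suppresses tile-seam
           flips on a uniform texture", {
  b <- get_desk_benchmark()
  tile <- make_texture_tile(CLASS_CODES[["grade3"]], 160, seed = 33)
  gm_overlap <- grade_slide(b$net, tile, stride = 32, smooth_window = 5)
  gm_seamy <- grade_slide(b$net, tile, stride = 64, smooth_window = 1)
  on <- unclass(gm_overlap); sn <- unclass(gm_seamy)
  expect_gte(mean(on[on > 0] == CLASS_CODES[["grade3"]]),
             mean(sn[sn > 0] == CLASS_CODES[["grade3"]]))
  expect_gte(mean(on[on > 0] == CLASS_CODES[["grade3"]]), 0.95)
})

test_that("a converged network reads a uniform grade-3 texture patch as
           grade 3 wherever its receptive field sees the texture", {
  b <- get_desk_benchmark()
  tile <- make_texture_tile(CLASS_CODES[["grade3"]], 64, seed = 101)
  pr <- predict_patch(b$net, tile)
  cls <- apply(pr, c(1, 2), which.max)
  interior <- cls[9:56, 9:56]
  expect_gte(mean(interior == CLASS_CODES[["grade3"]]), 0.9)
})
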