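# The per-pixel six-class grading network: residual encoder with ReLU-only
# pre-activation, an atrous context layer plus atrous spatial pyramid pooling
# (ASPP), and a transposed-convolution decoder back to input resolution.
# Forward/backward passes run through the package's im2col convolution
# kernels; training uses pixelwise cross-entropy and Adam.
#
# Dilation convention: a "rate" here is the number of pixels *skipped*
# between samples (sample spacing rate + 1), so a 3x3 filter at rate 4 spans
# an 11x11 region. Conventional dilation = rate + 1.

#' Effective receptive span of a dilated kernel
#'
#' With `rate` pixels skipped between successive samples, a `k` x `k` filter
#' spans `(k - 1) * (rate + 1) + 1` pixels; e.g. a 3x3 filter at rate 4 spans
#' 11 x 11.
#'
#' @param k kernel size.
#' @param rate number of skipped pixels between samples.
#' @return Span in pixels.
#' @export
atrous_span <- function(k, rate) (k - 1L) * (rate + 1L) + 1L

#' Specify a grading network
#'
#' @param preset `"desk"` (small widths for CPU training) or `"faithful"`
#'   (ResNet18-like stage widths 64/128/256/512).
#' @param input_size patch side length the network is trained/run on.
#' @param n_classes number of target classes (6: two normal + four grades).
#' @param base_width channels in the first encoder stage.
#' @param encoder_depth number of residual stages (total downsampling
#'   `2^encoder_depth`).
#' @param atrous_rate rate (skipped pixels) of the single atrous context
#'   layer.
#' @param aspp_rates rates of the parallel ASPP branches.
#' @return A `grader_spec` list.
#' @export
grader_spec <- function(preset = c("desk", "faithful"), input_size = 224,
                        n_classes = 6, base_width = NULL, encoder_depth = NULL,
                        atrous_rate = 4, aspp_rates = c(2, 4, 8)) {
  preset <- match.arg(preset)
  if (is.null(base_width))
    base_width <- if (preset == "desk") 8L else 64L
  if (is.null(encoder_depth))
    encoder_depth <- if (preset == "desk") 2L else 4L
  if (base_width < 1 || encoder_depth < 1) stop("invalid width/depth")
  if (any(aspp_rates < 0) || atrous_rate < 0) stop("rates must be >= 0")
  if (input_size %% 2^encoder_depth != 0)
    stop("input_size must be divisible by 2^encoder_depth")
  structure(list(preset = preset, input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 base_width = as.integer(base_width),
                 encoder_depth = as.integer(encoder_depth),
                 atrous_rate = atrous_rate, aspp_rates = aspp_rates),
            class = "grader_spec")
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

new_conv <- function(k, cin, cout, stride = 1L, rate = 0, act = "relu") {
  dil <- as.integer(rate + 1)
  list(type = "conv", W = he_init(k, cin, cout), b = numeric(cout),
       stride = as.integer(stride), pad = as.integer(dil * (k - 1) / 2),
       dil = dil, act = act)
}

new_resblock <- function(cin, cout, stride = 1L) {
  proj <- NULL
  if (stride != 1L || cin != cout)
    proj <- list(W = he_init(1, cin, cout), b = numeric(cout))
  list(type = "resblock",
       conv1 = list(W = he_init(3, cin, cout), b = numeric(cout)),
       conv2 = list(W = he_init(3, cout, cout), b = numeric(cout)),
       proj = proj, stride = as.integer(stride))
}

new_aspp <- function(cin, rates) {
  branches <- lapply(rates, function(r) {
    dil <- as.integer(r + 1)
    list(W = he_init(3, cin, cin), b = numeric(cin), dil = dil,
         pad = as.integer(dil))
  })
  list(type = "aspp", branches = branches,
       combine = list(W = he_init(1, cin * length(rates), cin),
                      b = numeric(cin)))
}

new_convt <- function(cin, cout) {
  # weights in the conv-equivalent shape (k, k, Cout, Cin); k = 4, stride 2
  W <- array(rnorm(4 * 4 * cout * cin, sd = sqrt(2 / (4 * 4 * cin))),
             c(4, 4, cout, cin))
  list(type = "convt", W = W, b = numeric(cout), stride = 2L, pad = 1L)
}

#' Build a grading network
#'
#' Constructs the encoder (stem convolution plus pre-activation residual
#' stages), the atrous + ASPP context block, the transposed-convolution
#' decoder and the 6-way per-pixel classification head, with seeded
#' He-initialized weights.
#'
#' @param spec a [grader_spec()].
#' @param seed RNG seed for weight initialization.
#' @return A `grader_network`.
#' @export
build_network <- function(spec = grader_spec(), seed = 1) {
  widths <- spec$base_width * 2^(seq_len(spec$encoder_depth) - 1L)
  with_seed(seed, {
    layers <- list()
    layers$stem <- new_conv(3, 3, widths[1], stride = 2L)
    for (i in seq_len(spec$encoder_depth)) {
      cin <- if (i == 1) widths[1] else widths[i - 1]
      layers[[paste0("stage", i)]] <-
        new_resblock(cin, widths[i], stride = if (i == 1) 1L else 2L)
    }
    wd <- widths[length(widths)]
    layers$atrous <- new_conv(3, wd, wd, rate = spec$atrous_rate)
    layers$aspp <- new_aspp(wd, spec$aspp_rates)
    dec_in <- wd
    for (j in seq_len(spec$encoder_depth)) {
      dec_out <- max(spec$base_width, dec_in %/% 2L)
      layers[[paste0("up", j)]] <- new_convt(dec_in, dec_out)
      dec_in <- dec_out
    }
    layers$head <- new_conv(1, dec_in, spec$n_classes, act = "none")
    structure(list(spec = spec, layers = layers, version = "luadgrader-net-1"),
              class = "grader_network")
  })
}

#' @export
print.grader_network <- function(x, ...) {
  cat(sprintf("<grader_network> preset=%s input=%dpx depth=%d width=%d, %d parameters\n",
              x$spec$preset, x$spec$input_size, x$spec$encoder_depth,
              x$spec$base_width, n_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param net a `grader_network`.
#' @export
n_params <- function(net) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$W)) n <<- n + length(x$W) + length(x$b)
      for (el in x) if (is.list(el)) walk(el)
    }
  }
  walk(net$layers)
  n
}

relu <- function(x) { x[x < 0] <- 0; x }

# ---- forward / backward -----------------------------------------------------

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      y <- cpp_conv_fwd(x, layer$W, layer$b, layer$stride, layer$pad,
                        layer$dil)
      pre <- if (layer$act == "relu") y else NULL
      if (layer$act == "relu") y <- relu(y)
      list(y = y, cache = list(x = x, pre = pre))
    },
    resblock = {
      a <- relu(x)
      c1 <- cpp_conv_fwd(a, layer$conv1$W, layer$conv1$b, layer$stride, 1L, 1L)
      h1 <- relu(c1)
      h2 <- cpp_conv_fwd(h1, layer$conv2$W, layer$conv2$b, 1L, 1L, 1L)
      sc <- if (is.null(layer$proj)) a else
        cpp_conv_fwd(a, layer$proj$W, layer$proj$b, layer$stride, 0L, 1L)
      list(y = h2 + sc, cache = list(x = x, a = a, c1 = c1, h1 = h1))
    },
    aspp = {
      branches <- lapply(layer$branches, function(br)
        cpp_conv_fwd(x, br$W, br$b, 1L, br$pad, br$dil))
      acts <- lapply(branches, relu)
      d <- dim(acts[[1]])
      z <- array(0, c(d[1], d[2], d[3] * length(acts), d[4]))
      for (q in seq_along(acts))
        z[, , (q - 1) * d[3] + seq_len(d[3]), ] <- acts[[q]]
      cz <- cpp_conv_fwd(z, layer$combine$W, layer$combine$b, 1L, 0L, 1L)
      list(y = relu(cz), cache = list(x = x, branches = branches, z = z,
                                      cz = cz))
    },
    convt = {
      y <- cpp_convt_fwd(x, layer$W, layer$b, layer$stride, layer$pad)
      list(y = relu(y), cache = list(x = x, pre = y))
    },
    stop("unknown layer type")
  )
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      if (layer$act == "relu") dy <- dy * (cache$pre > 0)
      bw <- cpp_conv_bwd(cache$x, layer$W, dy, layer$stride, layer$pad,
                         layer$dil)
      list(dx = bw$dx, grads = list(W = bw$dw, b = bw$db))
    },
    resblock = {
      # dy flows into h2 and the shortcut
      bw2 <- cpp_conv_bwd(cache$h1, layer$conv2$W, dy, 1L, 1L, 1L)
      dc1 <- bw2$dx * (cache$c1 > 0)
      bw1 <- cpp_conv_bwd(cache$a, layer$conv1$W, dc1, layer$stride, 1L, 1L)
      da <- bw1$dx
      grads <- list(conv1 = list(W = bw1$dw, b = bw1$db),
                    conv2 = list(W = bw2$dw, b = bw2$db))
      if (is.null(layer$proj)) {
        da <- da + dy
      } else {
        bwp <- cpp_conv_bwd(cache$a, layer$proj$W, dy, layer$stride, 0L, 1L)
        da <- da + bwp$dx
        grads$proj <- list(W = bwp$dw, b = bwp$db)
      }
      list(dx = da * (cache$x > 0), grads = grads)
    },
    aspp = {
      dcz <- dy * (relu(cache$cz) > 0)
      bwc <- cpp_conv_bwd(cache$z, layer$combine$W, dcz, 1L, 0L, 1L)
      dz <- bwc$dx
      d <- dim(cache$branches[[1]])
      dx <- 0
      grads <- list(branches = vector("list", length(layer$branches)),
                    combine = list(W = bwc$dw, b = bwc$db))
      for (q in seq_along(layer$branches)) {
        dbr <- dz[, , (q - 1) * d[3] + seq_len(d[3]), , drop = FALSE]
        dbr <- dbr * (cache$branches[[q]] > 0)
        bw <- cpp_conv_bwd(cache$x, layer$branches[[q]]$W, dbr, 1L,
                           layer$branches[[q]]$pad, layer$branches[[q]]$dil)
        dx <- dx + bw$dx
        grads$branches[[q]] <- list(W = bw$dw, b = bw$db)
      }
      list(dx = dx, grads = grads)
    },
    convt = {
      dy <- dy * (cache$pre > 0)
      bw <- cpp_convt_bwd(cache$x, layer$W, dy, layer$stride, layer$pad)
      list(dx = bw$dx, grads = list(W = bw$dw, b = bw$db))
    }
  )
}

net_forward <- function(net, x, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    out <- layer_forward(net$layers[[i]], x)
    x <- out$y
    if (keep_cache) caches[[i]] <- out$cache
  }
  list(logits = x, caches = caches)
}

net_backward <- function(net, caches, dlogits) {
  grads <- vector("list", length(net$layers))
  names(grads) <- names(net$layers)
  dy <- dlogits
  for (i in rev(seq_along(net$layers))) {
    bw <- layer_backward(net$layers[[i]], caches[[i]], dy)
    grads[[i]] <- bw$grads
    dy <- bw$dx
  }
  grads
}

# flatten/unflatten parameter arrays for the optimizer; paths are stable
param_paths <- function(layers) {
  paths <- list()
  rec <- function(x, path) {
    if (!is.list(x)) return()
    if (!is.null(x$W)) {
      paths[[length(paths) + 1L]] <<- c(path, list("W"))
      paths[[length(paths) + 1L]] <<- c(path, list("b"))
    }
    if (is.null(names(x))) {
      for (q in seq_along(x)) rec(x[[q]], c(path, list(q)))
    } else {
      for (nm in names(x)) {
        if (nm %in% c("W", "b")) next
        if (is.list(x[[nm]])) rec(x[[nm]], c(path, list(nm)))
      }
    }
  }
  rec(layers, list())
  paths
}

get_path <- function(x, path) {
  for (p in path) x <- x[[p]]
  x
}
set_path <- function(x, path, value) {
  if (length(path) == 1L) { x[[path[[1]]]] <- value; return(x) }
  x[[path[[1]]]] <- set_path(x[[path[[1]]]], path[-1], value)
  x
}

#' Training configuration
#'
#' Defaults mirror the published training recipe: 20 epochs of Adam
#' (adaptive moment estimation) on 128-patch minibatches with initial
#' learning rate 0.01 (held fixed).
#'
#' @param epochs number of epochs (>= 1).
#' @param minibatch minibatch size (>= 1).
#' @param lr initial learning rate (> 0).
#' @param lr_decay multiplicative decay applied to the learning rate in the
#'   final third of training (1 = constant rate).
#' @param clip_norm global gradient-norm clipping threshold.
#' @param seed RNG seed controlling shuffling.
#' @export
training_config <- function(epochs = 20, minibatch = 128, lr = 0.01,
                            lr_decay = 1, clip_norm = 5, seed = 1) {
  if (epochs < 1 || minibatch < 1 || lr <= 0 || lr_decay <= 0 || lr_decay > 1)
    stop("invalid training config")
  if (clip_norm <= 0) stop("clip_norm must be positive")
  list(epochs = as.integer(epochs), minibatch = as.integer(minibatch),
       lr = lr, lr_decay = lr_decay, clip_norm = clip_norm,
       seed = as.integer(seed))
}

patches_to_tensors <- function(patches, input_size) {
  n <- length(patches)
  x <- array(0, c(input_size, input_size, 3, n))
  y <- array(0L, c(input_size, input_size, n))
  for (i in seq_len(n)) {
    if (!all(dim(patches[[i]]$rgb)[1:2] == input_size))
      stop("patch size ", nrow(patches[[i]]$labels),
           " does not match network input size ", input_size)
    x[, , , i] <- patches[[i]]$rgb / 255 - 0.5
    y[, , i] <- patches[[i]]$labels
  }
  list(x = x, y = y)
}

#' Train a grading network
#'
#' Minimizes pixelwise cross-entropy (Background pixels ignored) on the
#' train split with Adam, logs per-epoch training loss and validation pixel
#' accuracy, and returns the weights of the best-validation epoch.
#'
#' @param net a `grader_network`.
#' @param library a `patch_library` with non-empty train and validation
#'   splits.
#' @param config a [training_config()].
#' @param verbose print per-epoch progress.
#' @return List with `net` (best weights) and `log` (data.frame epoch,
#'   train_loss, train_acc, val_acc).
#' @export
train_network <- function(net, library, config = training_config(),
                          verbose = FALSE) {
  tr <- which(library$split == "train")
  va <- which(library$split == "validation")
  if (length(tr) == 0L || length(va) == 0L)
    stop("library must have non-empty train and validation splits")
  size <- net$spec$input_size
  dtr <- patches_to_tensors(library$patches[tr], size)
  dva <- patches_to_tensors(library$patches[va], size)

  paths <- param_paths(net$layers)
  mstate <- lapply(paths, function(p) 0)
  vstate <- lapply(paths, function(p) 0)
  step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    train_acc = numeric(0), val_acc = numeric(0))
  best <- list(acc = -Inf, layers = net$layers)

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr_epoch <- config$lr *
        if (epoch > ceiling(2 * config$epochs / 3)) config$lr_decay else 1
      ord <- sample(length(tr))
      ep_loss <- 0; ep_correct <- 0; ep_valid <- 0; nb <- 0
      for (start in seq(1, length(ord), by = config$minibatch)) {
        idx <- ord[start:min(start + config$minibatch - 1, length(ord))]
        xb <- dtr$x[, , , idx, drop = FALSE]
        yb <- array(dtr$y[, , idx], c(size, size, length(idx)))
        fw <- net_forward(net, xb)
        sm <- cpp_softmax_ce(fw$logits, yb)
        if (sm$n_valid == 0) next  # minibatch of only Background pixels
        if (!is.finite(sm$loss))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        grads <- net_backward(net, fw$caches, sm$grad)
        # global gradient-norm clipping stabilizes the un-normalized network
        gnorm2 <- 0
        for (q in seq_along(paths))
          gnorm2 <- gnorm2 + sum(get_path(grads, paths[[q]])^2)
        clip <- if (sqrt(gnorm2) > config$clip_norm)
          config$clip_norm / sqrt(gnorm2) else 1
        step <- step + 1L
        for (q in seq_along(paths)) {
          g <- get_path(grads, paths[[q]]) * clip
          mstate[[q]] <- beta1 * mstate[[q]] + (1 - beta1) * g
          vstate[[q]] <- beta2 * vstate[[q]] + (1 - beta2) * g^2
          mhat <- mstate[[q]] / (1 - beta1^step)
          vhat <- vstate[[q]] / (1 - beta2^step)
          w <- get_path(net$layers, paths[[q]])
          net$layers <- set_path(net$layers, paths[[q]],
                                 w - lr_epoch * mhat / (sqrt(vhat) + eps))
        }
        ep_loss <- ep_loss + sm$loss
        ep_correct <- ep_correct + sm$n_correct
        ep_valid <- ep_valid + sm$n_valid
        nb <- nb + 1
      }
      val_acc <- evaluate_pixel_accuracy(net, dva$x, dva$y)
      log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                   train_acc = ep_correct / ep_valid,
                                   val_acc = val_acc))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f train acc %.3f val acc %.3f",
                        epoch, ep_loss / nb, ep_correct / ep_valid, val_acc))
      if (val_acc > best$acc) best <- list(acc = val_acc, layers = net$layers)
    }
  })
  net$layers <- best$layers
  list(net = net, log = log)
}

# pixel accuracy of a net on (x, y) tensors, ignoring Background pixels
evaluate_pixel_accuracy <- function(net, x, y, minibatch = 32L) {
  n <- dim(x)[4]
  size <- dim(x)[1]
  correct <- 0; valid <- 0
  for (start in seq(1, n, by = minibatch)) {
    idx <- start:min(start + minibatch - 1, n)
    logits <- net_forward(net, x[, , , idx, drop = FALSE],
                          keep_cache = FALSE)$logits
    sm <- cpp_softmax_ce(logits, array(y[, , idx],
                                       c(size, size, length(idx))))
    correct <- correct + sm$n_correct
    valid <- valid + sm$n_valid
  }
  correct / valid
}

#' Per-pixel class probabilities for one patch
#'
#' @param net a `grader_network`.
#' @param patch numeric (S, S, 3) RGB array where S is the network's
#'   `input_size` (no implicit resizing).
#' @return (S, S, n_classes) array of per-pixel probabilities summing to 1.
#' @export
predict_patch <- function(net, patch) {
  stopifnot_rgb(patch)
  s <- net$spec$input_size
  if (dim(patch)[1] != s || dim(patch)[2] != s)
    stop("patch is ", dim(patch)[1], "x", dim(patch)[2],
         " but the network expects ", s, "x", s, " (no implicit resize)")
  x <- array(patch / 255 - 0.5, c(s, s, 3, 1))
  logits <- net_forward(net, x, keep_cache = FALSE)$logits
  probs <- cpp_softmax(logits)
  array(probs, dim(probs)[1:3])
}

#' Grade a whole slide
#'
#' Runs overlapping-tile inference (per-pixel probability averaging across
#' overlaps), takes the per-pixel argmax, applies a modal smoothing filter to
#' suppress patch-edge artifacts, and masks non-tissue pixels (OD norm below
#' `beta_od_floor`) to Background.
#'
#' @param net a trained `grader_network`.
#' @param image numeric (H, W, 3) RGB array.
#' @param stride tile stride in pixels (default half the input size; must not
#'   exceed the input size).
#' @param smooth_window modal-filter window (odd; 1 disables smoothing).
#' @param beta_od_floor tissue threshold on OD Euclidean norm.
#' @param microns_per_pixel resolution recorded on the output map.
#' @param batch tiles per inference batch.
#' @return A [grade_map()] congruent with `image`.
#' @export
grade_slide <- function(net, image, stride = NULL, smooth_window = 5,
                        beta_od_floor = 0.15,
                        microns_per_pixel = REFERENCE_MPP, batch = 16L) {
  stopifnot_rgb(image)
  s <- net$spec$input_size
  if (is.null(stride)) stride <- s %/% 2L
  if (stride > s) stop("stride must not exceed the patch size")
  H <- dim(image)[1]; W <- dim(image)[2]

  od <- rgb_to_od(image)$od
  tissue <- sqrt(od[, , 1]^2 + od[, , 2]^2 + od[, , 3]^2) > beta_od_floor

  origins_r <- seq(0L, max(H - 1L, 0L), by = stride)
  origins_c <- seq(0L, max(W - 1L, 0L), by = stride)
  # drop origins made redundant by an earlier fully-covering tile
  origins_r <- origins_r[c(TRUE, origins_r[-1] < H - 0)]
  origins_c <- origins_c[c(TRUE, origins_c[-1] < W - 0)]
  Hp <- max(origins_r) + s
  Wp <- max(origins_c) + s
  padded <- image[reflect_index(Hp, H), reflect_index(Wp, W), , drop = FALSE]

  prob <- array(0, c(Hp, Wp, net$spec$n_classes))
  hits <- matrix(0, Hp, Wp)
  tiles <- expand.grid(r = origins_r, c = origins_c)
  for (start in seq(1, nrow(tiles), by = batch)) {
    idx <- start:min(start + batch - 1, nrow(tiles))
    x <- array(0, c(s, s, 3, length(idx)))
    for (q in seq_along(idx)) {
      orow <- tiles$r[idx[q]]; ocol <- tiles$c[idx[q]]
      x[, , , q] <- padded[orow + seq_len(s), ocol + seq_len(s), ] / 255 - 0.5
    }
    logits <- net_forward(net, x, keep_cache = FALSE)$logits
    probs <- cpp_softmax(logits)
    for (q in seq_along(idx)) {
      orow <- tiles$r[idx[q]]; ocol <- tiles$c[idx[q]]
      rs <- orow + seq_len(s); cs <- ocol + seq_len(s)
      prob[rs, cs, ] <- prob[rs, cs, ] + probs[, , , q]
      hits[rs, cs] <- hits[rs, cs] + 1
    }
  }
  cls <- matrix(0L, Hp, Wp)
  cls[] <- max.col(matrix(prob, ncol = net$spec$n_classes), "first")
  cls <- cls[seq_len(H), seq_len(W), drop = FALSE]
  if (smooth_window > 1)
    cls <- cpp_modal_filter(cls, as.integer(smooth_window))
  cls[!tissue] <- 0L
  grade_map(cls, microns_per_pixel = microns_per_pixel)
}

#' Save / load a network checkpoint
#'
#' Single-file, version-stamped archive of the architecture spec and weight
#' tensors.
#'
#' @param net a `grader_network`.
#' @param path checkpoint file path.
#' @export
save_network <- function(net, path) {
  saveRDS(list(version = net$version, spec = unclass(net$spec),
               layers = net$layers), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  x <- readRDS(path)
  if (!identical(x$version, "luadgrader-net-1"))
    stop("unrecognized checkpoint version: ", x$version)
  structure(list(spec = structure(x$spec, class = "grader_spec"),
                 layers = x$layers, version = x$version),
            class = "grader_network")
}

#' Run the desk-scale synthetic benchmark
#'
#' Builds a patch library from the synthetic benchmark slides
#' ([make_benchmark_slides()]), area-balances it, trains a desk-preset
#' network, and reports held-out (test-split) pixel accuracy. This is the
#' package's CPU-scale end-to-end check that the architecture and training
#' loop learn a separable six-class texture problem.
#'
#' @param seed RNG seed driving slide synthesis, library assembly and
#'   training.
#' @param n_slides,canvas benchmark slide set geometry.
#' @param patch_size patch side length, px.
#' @param quota_per_class patch quota per class.
#' @param epochs,minibatch,lr training recipe.
#' @return List: `net` (trained), `library`, `log` (training log),
#'   `test_accuracy` (held-out pixel accuracy), `elapsed_min`.
#' @export
run_desk_benchmark <- function(seed = 1, n_slides = 6, canvas = 480,
                               patch_size = 64, quota_per_class = 40,
                               epochs = 50, minibatch = 8, lr = 0.003,
                               lr_decay = 0.3) {
  t0 <- proc.time()[["elapsed"]]
  slides <- make_benchmark_slides(n_slides, canvas, seed)
  lib <- suppressMessages(suppressWarnings(
    build_library(slides, quota_per_class = quota_per_class,
                  size = patch_size, stride = patch_size %/% 2L,
                  seed = seed)))
  lib <- suppressWarnings(balance_by_area(lib, seed = seed))
  net <- build_network(grader_spec("desk", input_size = patch_size),
                       seed = seed)
  fit <- train_network(net, lib,
                       training_config(epochs = epochs,
                                       minibatch = minibatch, lr = lr,
                                       lr_decay = lr_decay,
                                       seed = seed))
  te <- which(lib$split == "test")
  d <- patches_to_tensors(lib$patches[te], patch_size)
  acc <- evaluate_pixel_accuracy(fit$net, d$x, d$y)
  list(net = fit$net, library = lib, log = fit$log, test_accuracy = acc,
       elapsed_min = (proc.time()[["elapsed"]] - t0) / 60)
}

# transpose a network's kernels (swap kernel rows/cols); used by the spatial
# transposition equivariance check
transpose_network <- function(net) {
  paths <- param_paths(net$layers)
  for (p in paths) {
    if (p[[length(p)]] == "W") {
      w <- get_path(net$layers, p)
      if (length(dim(w)) == 4L)
        net$layers <- set_path(net$layers, p, aperm(w, c(2, 1, 3, 4)))
    }
  }
  net
}
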