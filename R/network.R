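#' Network configuration
#'
#' @param num_classes number of output classes `N >= 2` (background included).
#' @param width_multiplier factor in `(0, 1]` scaling every channel count;
#'   1 reproduces the full-width architecture, fractions give desk-scale
#'   networks with identical shape behaviour.
#' @param dropout dropout rate after the two fully-convolutional fc layers.
#' @export
network_config <- function(num_classes = 2L, width_multiplier = 1, dropout = 0.5) {
  stopifnot(num_classes >= 2L, width_multiplier > 0, width_multiplier <= 1,
            dropout >= 0, dropout < 1)
  structure(list(num_classes = as.integer(num_classes),
                 width_multiplier = width_multiplier, dropout = dropout),
            class = "slfcn_config")
}

#' Training configuration
#'
#' The full-scale defaults are the method defaults (SGD with momentum
#' 0.99, base learning rate 1e-10, weight decay 5e-4) which pairs with
#' sum-reduced loss. The desk-scale profile used in the examples and tests
#' is mean-reduction with lr 1e-3 and momentum 0.9.
#'
#' @param optimizer one of [optimizer_registry()].
#' @param lr positive base learning rate.
#' @param momentum momentum in `[0, 1)` (sgd_momentum / nag).
#' @param weight_decay L2 penalty added to every parameter gradient.
#' @param steps number of single-tile update steps.
#' @param seed integer seed controlling shuffling and dropout.
#' @param reduction loss reduction, `"sum"` (the historical FCN pairing) or `"mean"`.
#' @export
train_config <- function(optimizer = "sgd_momentum", lr = 1e-10,
                         momentum = 0.99, weight_decay = 5e-4,
                         steps = 100L, seed = 1L,
                         reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (!optimizer %in% optimizer_registry()) {
    stop("unknown optimizer '", optimizer, "'; see optimizer_registry()")
  }
  stopifnot(lr > 0, momentum >= 0, momentum < 1, weight_decay >= 0, steps >= 1)
  structure(list(optimizer = optimizer, lr = lr, momentum = momentum,
                 weight_decay = weight_decay, steps = as.integer(steps),
                 seed = as.integer(seed), reduction = reduction),
            class = "slfcn_train_config")
}

MIN_INPUT_SIDE <- 26L
CROP_OFFSET <- 19L

scaled_channels <- function(config) {
  ch <- function(n) max(1L, as.integer(round(n * config$width_multiplier)))
  list(c1 = ch(64), c2 = ch(128), c3 = ch(256), c4 = ch(512), c5 = ch(512),
       fc = ch(4096))
}

#' Analytic layer-shape trace
#'
#' Propagates spatial sizes through the architecture: the first 3x3
#' convolution pads the input by 100 (the only padding consistent with the
#' reference 512-710-17-576 feature trace), every other 3x3
#' convolution pads 1, all five max-pools are 2x2 stride 2 with ceil
#' rounding, fc6 is a 7x7 valid convolution, the deconvolution has kernel
#' 64 and stride 32, and the crop recovers the input size at offset 19.
#'
#' @param input_side input spatial side length (square input), at least 26.
#' @param config a [network_config()].
#' @return Tibble with columns `layer`, `side`, `channels`.
#' @export
layer_shape_trace <- function(input_side, config = network_config()) {
  input_side <- as.integer(input_side)
  if (input_side < MIN_INPUT_SIDE) {
    stop("input side ", input_side, " is too small: the 7x7 fc6 convolution ",
         "requires at least ", MIN_INPUT_SIDE, " pixels per side")
  }
  ch <- scaled_channels(config)
  rows <- list(list("input", input_side, 3L))
  s <- input_side
  add <- function(rows, name, side, channels) {
    c(rows, list(list(name, as.integer(side), as.integer(channels))))
  }
  s <- s + 198L                         # pad-100 3x3 convolution
  rows <- add(rows, "conv1_1", s, ch$c1); rows <- add(rows, "conv1_2", s, ch$c1)
  s <- ceiling(s / 2); rows <- add(rows, "pool1", s, ch$c1)
  rows <- add(rows, "conv2_1", s, ch$c2); rows <- add(rows, "conv2_2", s, ch$c2)
  s <- ceiling(s / 2); rows <- add(rows, "pool2", s, ch$c2)
  for (nm in c("conv3_1", "conv3_2", "conv3_3")) rows <- add(rows, nm, s, ch$c3)
  s <- ceiling(s / 2); rows <- add(rows, "pool3", s, ch$c3)
  for (nm in c("conv4_1", "conv4_2", "conv4_3")) rows <- add(rows, nm, s, ch$c4)
  s <- ceiling(s / 2); rows <- add(rows, "pool4", s, ch$c4)
  for (nm in c("conv5_1", "conv5_2", "conv5_3")) rows <- add(rows, nm, s, ch$c5)
  s <- ceiling(s / 2); rows <- add(rows, "pool5", s, ch$c5)
  s <- s - 6L; rows <- add(rows, "fc6", s, ch$fc)
  rows <- add(rows, "fc7", s, ch$fc)
  rows <- add(rows, "score", s, config$num_classes)
  s <- (s - 1L) * 32L + 64L; rows <- add(rows, "deconv", s, config$num_classes)
  rows <- add(rows, "crop", input_side, config$num_classes)
  tibble::tibble(layer = vapply(rows, `[[`, character(1), 1L),
                 side = vapply(rows, `[[`, integer(1), 2L),
                 channels = vapply(rows, `[[`, integer(1), 3L))
}

conv_layer <- function(name, cin, cout, k, pad, relu) {
  list(name = name, type = "conv", cin = cin, cout = cout, k = k, pad = pad,
       relu = relu, W = matrix(0, k * k * cin, cout), b = numeric(cout))
}

#' Build the soft-label FCN
#'
#' VGG16-lineage FCN-32s: five conv stages (2+2+3+3+3 3x3 convolutions with
#' ReLU, each followed by a 2x2 stride-2 ceil-mode max-pool), fc6 (7x7) and
#' fc7 (1x1) as convolutions with dropout, a 1x1 score layer to N classes,
#' a 64x64 stride-32 deconvolution and a centre crop back to the input
#' size. Parameters start at zero; see [init_network()].
#'
#' @param config a [network_config()].
#' @return Object of class `slfcn_network`.
#' @export
build_slfcn <- function(config = network_config()) {
  stopifnot(inherits(config, "slfcn_config"))
  ch <- scaled_channels(config)
  N <- config$num_classes
  layers <- list(
    conv_layer("conv1_1", 3L, ch$c1, 3L, 100L, TRUE),
    conv_layer("conv1_2", ch$c1, ch$c1, 3L, 1L, TRUE),
    list(name = "pool1", type = "pool"),
    conv_layer("conv2_1", ch$c1, ch$c2, 3L, 1L, TRUE),
    conv_layer("conv2_2", ch$c2, ch$c2, 3L, 1L, TRUE),
    list(name = "pool2", type = "pool"),
    conv_layer("conv3_1", ch$c2, ch$c3, 3L, 1L, TRUE),
    conv_layer("conv3_2", ch$c3, ch$c3, 3L, 1L, TRUE),
    conv_layer("conv3_3", ch$c3, ch$c3, 3L, 1L, TRUE),
    list(name = "pool3", type = "pool"),
    conv_layer("conv4_1", ch$c3, ch$c4, 3L, 1L, TRUE),
    conv_layer("conv4_2", ch$c4, ch$c4, 3L, 1L, TRUE),
    conv_layer("conv4_3", ch$c4, ch$c4, 3L, 1L, TRUE),
    list(name = "pool4", type = "pool"),
    conv_layer("conv5_1", ch$c4, ch$c5, 3L, 1L, TRUE),
    conv_layer("conv5_2", ch$c5, ch$c5, 3L, 1L, TRUE),
    conv_layer("conv5_3", ch$c5, ch$c5, 3L, 1L, TRUE),
    list(name = "pool5", type = "pool"),
    conv_layer("fc6", ch$c5, ch$fc, 7L, 0L, TRUE),
    list(name = "drop6", type = "dropout", rate = config$dropout),
    conv_layer("fc7", ch$fc, ch$fc, 1L, 0L, TRUE),
    list(name = "drop7", type = "dropout", rate = config$dropout),
    conv_layer("score", ch$fc, N, 1L, 0L, FALSE),
    list(name = "deconv", type = "deconv", cin = N, cout = N, k = 64L,
         stride = 32L, W = array(0, c(64L, 64L, N, N))),
    list(name = "crop", type = "crop", offset = CROP_OFFSET)
  )
  structure(list(layers = layers, config = config), class = "slfcn_network")
}

#' @export
print.slfcn_network <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) {
    length(l$W) + length(l$b)
  }, numeric(1)))
  cat(sprintf("<slfcn_network> N=%d, width x%.3g, %s parameters\n",
              x$config$num_classes, x$config$width_multiplier,
              format(np, big.mark = ",")))
  invisible(x)
}

#' Bilinear upsampling kernel
#'
#' The separable triangle kernel that makes a stride-`s` transposed
#' convolution perform bilinear interpolation (the standard FCN
#' deconvolution initializer).
#'
#' @param k kernel side length.
#' @return `k x k` numeric matrix.
#' @export
bilinear_kernel <- function(k) {
  f <- ceiling(k / 2)
  ctr <- if (k %% 2L == 1L) f - 1 else f - 0.5
  v <- 1 - abs((0:(k - 1)) - ctr) / f
  outer(v, v)
}

#' Set the deconvolution to fixed bilinear upsampling
#' @param network an `slfcn_network`.
#' @export
init_bilinear_deconv <- function(network) {
  li <- which(vapply(network$layers, function(l) l$type == "deconv", logical(1)))
  l <- network$layers[[li]]
  W <- array(0, dim(l$W))
  kern <- bilinear_kernel(l$k)
  for (c in seq_len(l$cin)) W[, , c, c] <- kern
  network$layers[[li]]$W <- W
  network
}

#' Zero the classifier (score) layer
#' @param network an `slfcn_network`.
#' @export
zero_score_layer <- function(network) {
  li <- which(vapply(network$layers, function(l) l$name == "score", logical(1)))
  network$layers[[li]]$W[] <- 0
  network$layers[[li]]$b[] <- 0
  network
}

#' Initialize network parameters
#'
#' Schemes: `"kaiming"` (He normal, gain for ReLU), `"xavier"` (Glorot
#' uniform), `"random"` (small Gaussian), applied to every parameterised
#' layer including the deconvolution; `"vgg16_transfer"` copies supplied
#' VGG16 convolution weights where shapes match (full width only), fixes
#' the deconvolution at bilinear upsampling and zeroes the score layer.
#' When no weight bundle is supplied the transfer scheme falls back to
#' Kaiming for the convolutions (with a warning) while keeping the
#' bilinear/zero conventions.
#'
#' @param network an `slfcn_network`.
#' @param scheme initialization scheme name.
#' @param seed integer seed; the same seed reproduces parameters exactly.
#' @param vgg_weights optional named list (layer name -> list(W, b)) of
#'   pretrained convolution parameters for `"vgg16_transfer"`.
#' @export
init_network <- function(network, scheme = c("kaiming", "xavier", "random",
                                             "vgg16_transfer"),
                         seed = 1L, vgg_weights = NULL) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  if (scheme == "vgg16_transfer") {
    if (network$config$width_multiplier != 1) {
      stop("unsupported combination: vgg16_transfer requires width_multiplier = 1")
    }
    missing_layers <- character(0)
    for (li in seq_along(network$layers)) {
      l <- network$layers[[li]]
      if (l$type != "conv") next
      src <- vgg_weights[[l$name]]
      if (!is.null(src) && identical(dim(src$W), dim(l$W))) {
        network$layers[[li]]$W <- src$W
        network$layers[[li]]$b <- src$b
      } else {
        network$layers[[li]]$W[] <- rnorm(length(l$W), 0, sqrt(2 / (l$k^2 * l$cin)))
        network$layers[[li]]$b[] <- 0
        missing_layers <- c(missing_layers, l$name)
      }
    }
    if (length(missing_layers)) {
      warning("no pretrained weights for ",
              paste(missing_layers, collapse = ", "),
              "; these layers fall back to Kaiming initialization")
    }
    network <- init_bilinear_deconv(network)
    network <- zero_score_layer(network)
    return(network)
  }
  for (li in seq_along(network$layers)) {
    l <- network$layers[[li]]
    if (l$type == "conv") {
      fan_in <- l$k^2 * l$cin
      fan_out <- l$k^2 * l$cout
      network$layers[[li]]$W[] <- switch(scheme,
        kaiming = rnorm(length(l$W), 0, sqrt(2 / fan_in)),
        xavier = runif(length(l$W), -1, 1) * sqrt(6 / (fan_in + fan_out)),
        random = rnorm(length(l$W), 0, 0.01))
      network$layers[[li]]$b[] <- 0
    } else if (l$type == "deconv") {
      fan_in <- l$k^2 * l$cin
      fan_out <- l$k^2 * l$cout
      network$layers[[li]]$W[] <- switch(scheme,
        kaiming = rnorm(length(l$W), 0, sqrt(2 / fan_in)),
        xavier = runif(length(l$W), -1, 1) * sqrt(6 / (fan_in + fan_out)),
        random = rnorm(length(l$W), 0, 0.01))
    }
  }
  network
}

# Centre the image and promote grayscale to 3 channels.
prepare_image <- function(image) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
  image - 0.5
}

slfcn_forward <- function(net, x, train = FALSE) {
  d <- dim(x)
  if (d[1L] < MIN_INPUT_SIDE || d[2L] < MIN_INPUT_SIDE) {
    stop("input side below the minimum of ", MIN_INPUT_SIDE, " pixels")
  }
  cache <- vector("list", length(net$layers))
  cur <- x
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    if (l$type == "conv") {
      inp <- cur
      cur <- cpp_conv_forward(inp, l$W, l$b, l$pad, l$relu)
      cache[[li]] <- list(input = inp, out = cur)
    } else if (l$type == "pool") {
      cache[[li]] <- list(input_dim = dim(cur))
      r <- cpp_maxpool_forward(cur)
      cache[[li]]$idx <- r$idx
      cur <- r$out
    } else if (l$type == "dropout") {
      if (train && l$rate > 0) {
        mask <- array((runif(length(cur)) >= l$rate) / (1 - l$rate), dim(cur))
        cur <- cur * mask
        cache[[li]] <- list(mask = mask)
      }
    } else if (l$type == "deconv") {
      inp <- cur
      cur <- cpp_deconv_forward(inp, as.vector(l$W), l$k, l$stride, l$cout)
      cache[[li]] <- list(input = inp)
    } else if (l$type == "crop") {
      off <- l$offset
      cache[[li]] <- list(full_dim = dim(cur))
      cur <- cur[(off + 1L):(off + d[1L]), (off + 1L):(off + d[2L]), , drop = FALSE]
    }
  }
  list(out = cur, cache = cache)
}

slfcn_backward <- function(net, cache, dout) {
  grads <- vector("list", length(net$layers))
  dcur <- dout
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]
    if (l$type == "crop") {
      fd <- cache[[li]]$full_dim
      full <- array(0, fd)
      off <- l$offset
      d <- dim(dcur)
      full[(off + 1L):(off + d[1L]), (off + 1L):(off + d[2L]), ] <- dcur
      dcur <- full
    } else if (l$type == "deconv") {
      r <- cpp_deconv_backward(cache[[li]]$input, as.vector(l$W), dcur,
                               l$k, l$stride)
      grads[[li]] <- list(W = array(r$dW, dim(l$W)))
      dcur <- r$dx
    } else if (l$type == "dropout") {
      if (!is.null(cache[[li]]$mask)) dcur <- dcur * cache[[li]]$mask
    } else if (l$type == "pool") {
      idim <- cache[[li]]$input_dim
      dcur <- cpp_maxpool_backward(dcur, cache[[li]]$idx, idim[1L], idim[2L])
    } else if (l$type == "conv") {
      r <- cpp_conv_backward(cache[[li]]$input, l$W, dcur, cache[[li]]$out,
                             l$pad, l$relu, need_dx = li > 1L)
      grads[[li]] <- list(W = r$dW, b = as.numeric(r$db))
      dcur <- r$dx
    }
  }
  grads
}

apply_updates <- function(net, grads, opt_state, tc) {
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (field in names(g)) {
      theta <- net$layers[[li]][[field]]
      grad <- g[[field]] + tc$weight_decay * theta
      key <- paste0(li, ".", field)
      st <- opt_state[[key]]
      upd <- opt_step_one(tc$optimizer, theta, grad, st, tc)
      net$layers[[li]][[field]] <- upd$theta
      assign(key, upd$state, envir = opt_state)
    }
  }
  net
}

#' Train the network
#'
#' Single-tile stochastic updates: each step draws the next sample from a
#' seeded per-epoch shuffle, runs forward + soft-weight softmax loss +
#' backward, and applies the configured optimizer. Deterministic given the
#' seed (single-threaded).
#'
#' @param network an initialized `slfcn_network`.
#' @param dataset list of samples, each `list(image, labels, weights)`:
#'   `image` is `H x W x 3` in `[0, 1]`, `labels` an integer matrix of
#'   0-based target classes (NA = ignored), `weights` the per-pixel loss
#'   weight map (omit or NULL for unweighted training).
#' @param tc a [train_config()].
#' @return List with the trained `network` and a `history` tibble
#'   (`step`, `loss`).
#' @export
fit_slfcn <- function(network, dataset, tc = train_config()) {
  stopifnot(inherits(network, "slfcn_network"), length(dataset) >= 1L)
  set.seed(tc$seed)
  opt_state <- new.env(parent = emptyenv())
  losses <- numeric(tc$steps)
  n <- length(dataset)
  order <- integer(0)
  for (step in seq_len(tc$steps)) {
    if (!length(order)) order <- sample.int(n)
    s <- dataset[[order[1L]]]
    order <- order[-1L]
    fw <- slfcn_forward(network, prepare_image(s$image), train = TRUE)
    lg <- sws_loss_grad(fw$out, s$labels, s$weights, reduction = tc$reduction)
    if (!is.finite(lg$loss)) {
      stop("training aborted: non-finite loss at step ", step,
           " (try a lower learning rate or mean reduction)")
    }
    grads <- slfcn_backward(network, fw$cache, lg$grad)
    network <- apply_updates(network, grads, opt_state, tc)
    losses[step] <- lg$loss
  }
  list(network = network,
       history = tibble::tibble(step = seq_len(tc$steps), loss = losses))
}

argmax_labels <- function(scores) {
  d <- dim(scores)
  best <- scores[, , 1L]
  lab <- matrix(0L, d[1L], d[2L])
  for (t in seq_len(d[3L])[-1L]) {
    upd <- scores[, , t] > best   # strict: ties go to the lowest class index
    best[upd] <- scores[, , t][upd]
    lab[upd] <- t - 1L
  }
  lab
}

#' Predict a label map for an image
#'
#' Images larger than `tile_side` are tiled (stride = tile side, reflected
#' borders), per-tile class scores are stitched back with averaging in
#' overlaps, and labels are the per-pixel argmax with ties broken toward
#' the lowest class index. Images below the minimum network input are
#' reflect-padded up and cropped back.
#'
#' @param object a trained `slfcn_network`.
#' @param image `H x W x 3` array in `[0, 1]` (or a grayscale matrix).
#' @param tile_side tile side length for large inputs (default 512).
#' @param ... unused.
#' @return List with `labels` (integer matrix, 0-based) and `scores`
#'   (`H x W x N` array).
#' @export
predict.slfcn_network <- function(object, image, tile_side = 512L, ...) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  d <- dim(image)
  if (d[1L] <= tile_side && d[2L] <= tile_side) {
    ph <- max(0L, MIN_INPUT_SIDE - d[1L])
    pw <- max(0L, MIN_INPUT_SIDE - d[2L])
    x <- if (ph > 0L || pw > 0L) pad_reflect(image, ph, pw) else image
    out <- slfcn_forward(object, prepare_image(x), train = FALSE)$out
    scores <- out[seq_len(d[1L]), seq_len(d[2L]), , drop = FALSE]
  } else {
    tiles <- tile_image(image, tile_side)
    score_tiles <- lapply(tiles, function(tl) {
      out <- slfcn_forward(object, prepare_image(tl$block), train = FALSE)$out
      tl$block <- out
      tl
    })
    scores <- stitch_tiles(score_tiles, d[1:2])
  }
  list(labels = argmax_labels(scores), scores = scores)
}
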