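tiny_cfg <- network_config(num_classes = 2L, width_multiplier = 1 / 16)

tiny_net <- function(seed = 1L) {
  net <- build_slfcn(tiny_cfg)
  net <- init_network(net, "kaiming", seed = seed)
  net <- init_bilinear_deconv(net)
  zero_score_layer(net)
}

test_that("the 512-input shape trace reproduces the reference architecture", {
  tr <- layer_shape_trace(512L)
  side <- function(nm) tr$side[tr$layer == nm]
  expect_equal(side("conv1_1"), 710L)
  expect_equal(side("pool1"), 355L)
  expect_equal(side("pool2"), 178L)
  expect_equal(side("pool3"), 89L)
  expect_equal(side("pool4"), 45L)
  expect_equal(side("pool5"), 23L)
  expect_equal(side("fc6"), 17L)
  expect_equal(side("fc7"), 17L)
  expect_equal(side("score"), 17L)
  expect_equal(side("deconv"), 576L)
  expect_equal(side("crop"), 512L)
  ch <- function(nm) tr$channels[tr$layer == nm]
  expect_equal(ch("conv1_1"), 64L)
  expect_equal(ch("fc6"), 4096L)
  expect_equal(ch("deconv"), 2L)
})

test_that("the shape trace handles other sizes and rejects tiny inputs", {
  tr <- layer_shape_trace(352L)
  side <- function(nm) tr$side[tr$layer == nm]
  expect_equal(side("conv1_1"), 550L)
  expect_equal(unname(vapply(paste0("pool", 1:5), side, integer(1))),
               c(275L, 138L, 69L, 35L, 18L))
  expect_equal(side("fc6"), 12L)
  expect_equal(side("deconv"), 416L)
  expect_equal(side("crop"), 352L)
  expect_error(layer_shape_trace(16L), "at least 26")
  expect_no_error(layer_shape_trace(26L))
})

test_that("forward-pass shapes equal the analytic trace", {
  net <- tiny_net()
  for (s in c(32L, 64L)) {
    tr <- layer_shape_trace(s, tiny_cfg)
    x <- array(runif(s * s * 3) - 0.5, c(s, s, 3))
    fw <- slfcn:::slfcn_forward(net, x)
    expect_equal(dim(fw$out), c(s, s, 2L))
    for (li in seq_along(net$layers)) {
      l <- net$layers[[li]]
      if (l$type != "conv") next
      nm <- if (l$name == "score") "score" else l$name
      expect_equal(dim(fw$cache[[li]]$out)[1L], tr$side[tr$layer == nm],
                   info = nm)
      expect_equal(dim(fw$cache[[li]]$out)[3L], tr$channels[tr$layer == nm],
                   info = nm)
    }
  }
  expect_error(slfcn:::slfcn_forward(net, array(0, c(16, 16, 3))), "minimum")
})

test_that("width scaling preserves the channel ratios", {
  net8 <- build_slfcn(network_config(2L, 1 / 8))
  expect_equal(net8$layers[[1]]$cout, 8L)
  expect_equal(dim(net8$layers[[1]]$W), c(27L, 8L))
  tr <- layer_shape_trace(512L, network_config(2L, 1 / 8))
  expect_equal(tr$channels[tr$layer == "fc6"], 512L)
  expect_error(network_config(2L, 0), "width_multiplier")
})

test_that("initialization schemes are seeded and reproducible", {
  a <- init_network(build_slfcn(tiny_cfg), "kaiming", seed = 7L)
  b <- init_network(build_slfcn(tiny_cfg), "kaiming", seed = 7L)
  expect_identical(a$layers[[1]]$W, b$layers[[1]]$W)
  c_ <- init_network(build_slfcn(tiny_cfg), "kaiming", seed = 8L)
  expect_false(identical(a$layers[[1]]$W, c_$layers[[1]]$W))
  for (scheme in c("xavier", "random")) {
    n <- init_network(build_slfcn(tiny_cfg), scheme, seed = 1L)
    expect_true(stats::sd(n$layers[[1]]$W) > 0)
  }
  expect_error(init_network(build_slfcn(tiny_cfg), "vgg16_transfer"),
               "unsupported combination")
})

test_that("transfer-style initialization zeroes the score layer and sets bilinear deconv", {
  net <- build_slfcn(network_config(2L, 1))
  vw <- list(conv1_1 = list(W = matrix(0.25, 27, 64), b = rep(0.5, 64)))
  expect_warning(
    net <- init_network(net, "vgg16_transfer", seed = 3L, vgg_weights = vw),
    "fall back")
  expect_true(all(net$layers[[1]]$W == 0.25))
  expect_true(all(net$layers[[1]]$b == 0.5))
  sc <- which(vapply(net$layers, function(l) l$name == "score", logical(1)))
  expect_true(all(net$layers[[sc]]$W == 0) && all(net$layers[[sc]]$b == 0))
  dc <- which(vapply(net$layers, function(l) l$type == "deconv", logical(1)))
  expect_equal(net$layers[[dc]]$W[, , 1, 1], bilinear_kernel(64L))
  expect_true(all(net$layers[[dc]]$W[, , 1, 2] == 0))
  rm(net); gc(verbose = FALSE)
})

test_that("the bilinear deconvolution interpolates exactly on interior pixels", {
  k <- 64L; s <- 32L
  W <- array(0, c(k, k, 1L, 1L)); W[, , 1, 1] <- bilinear_kernel(k)
  # constant input: partition of unity away from the border
  x <- array(1, c(5L, 5L, 1L))
  out <- slfcn:::cpp_deconv_forward(x, as.vector(W), k, s, 1L)
  interior <- out[48:(dim(out)[1] - 48), 48:(dim(out)[2] - 48), 1]
  expect_equal(interior, matrix(1, nrow(interior), ncol(interior)),
               tolerance = 1e-12)
  # linear ramp input: bilinear interpolation of a linear field is linear
  xr <- array(rep(1:5, each = 5), c(5L, 5L, 1L)) # constant along rows
  outr <- slfcn:::cpp_deconv_forward(xr, as.vector(W), k, s, 1L)
  mid <- outr[100, 48:(dim(outr)[2] - 48), 1]
  expect_equal(diff(mid), rep(diff(mid)[1], length(mid) - 1), tolerance = 1e-9)
})

test_that("optimizer updates match their closed forms", {
  expect_setequal(optimizer_registry(),
                  c("sgd_momentum", "adam", "adagrad", "adadelta", "nag",
                    "rmsprop"))
  tc <- list(lr = 0.1, momentum = 0.9)
  theta <- 2; g <- 0.5
  s1 <- slfcn:::opt_step_one("sgd_momentum", theta, g, NULL, tc)
  expect_equal(s1$theta, 2 - 0.1 * 0.5)                   # v = -lr*g
  s2 <- slfcn:::opt_step_one("sgd_momentum", s1$theta, g, s1$state, tc)
  v2 <- 0.9 * (-0.05) - 0.1 * 0.5
  expect_equal(s2$theta, s1$theta + v2)
  # adam first step has magnitude ~ lr against the gradient sign
  a1 <- slfcn:::opt_step_one("adam", theta, g, NULL, tc)
  expect_equal(a1$theta, theta - 0.1, tolerance = 1e-6)
  # all optimizers move against the gradient on the first step
  for (nm in optimizer_registry()) {
    st <- slfcn:::opt_step_one(nm, theta, g, NULL, tc)
    expect_lte(st$theta, theta)
  }
})

test_that("training is seeded-deterministic and lr controls updates", {
  set.seed(1)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  lab <- matrix(0L, 32, 32); lab[10:25, 10:25] <- 1L
  ds <- list(list(image = img, labels = lab,
                  weights = matrix(1.5, 32, 32)))
  net <- tiny_net()
  tc <- train_config(lr = 1e-3, momentum = 0.9, steps = 3L, seed = 5L,
                     reduction = "mean")
  f1 <- fit_slfcn(net, ds, tc)
  f2 <- fit_slfcn(net, ds, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$network$layers[[1]]$W, f2$network$layers[[1]]$W)
  # weight decay scales with lr in SGD, so tiny lr leaves parameters ~fixed
  tc0 <- train_config(lr = 1e-300, momentum = 0, weight_decay = 0,
                      steps = 2L, seed = 5L, reduction = "mean")
  f0 <- fit_slfcn(net, ds, tc0)
  expect_equal(f0$network$layers[[1]]$W, net$layers[[1]]$W, tolerance = 1e-14)
  expect_error(train_config(optimizer = "sgd"), "unknown optimizer")
})

test_that("prediction takes the argmax with low-index tie-breaking", {
  sc <- array(0, c(3, 3, 3))
  sc[, , 3] <- 1
  expect_equal(slfcn:::argmax_labels(sc), matrix(2L, 3, 3))
  tie <- array(0, c(2, 2, 2))
  expect_equal(slfcn:::argmax_labels(tie), matrix(0L, 2, 2))
  tie[, , 2] <- c(1, 0, 0, 0)
  expect_equal(slfcn:::argmax_labels(tie)[1, 1], 1L)
  # constant-color image: spatially constant prediction away from the border
  net <- tiny_net()
  img <- array(0.5, c(48, 48, 3))
  pr <- predict(net, img)
  expect_equal(dim(pr$scores), c(48L, 48L, 2L))
  inner <- pr$labels[16:32, 16:32]
  expect_true(all(inner == inner[1, 1]))
  # an undersized image is padded and cropped back
  small <- array(0.5, c(20, 20, 3))
  expect_equal(dim(predict(net, small)$labels), c(20L, 20L))
})
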