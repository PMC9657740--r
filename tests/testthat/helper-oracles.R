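# Independent oracles and small fixture builders used across the suite.

# Brute-force sliding min/max filter over a kappa x kappa window,
# outside-image treated as background.
bf_morph <- function(mask, kappa, op = c("erode", "dilate")) {
  op <- match.arg(op)
  h <- (kappa - 1L) %/% 2L
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L * h, W + 2L * h)
  pad[(h + 1L):(h + H), (h + 1L):(h + W)] <- as.logical(mask)
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      win <- pad[i:(i + 2L * h), j:(j + 2L * h)]
      out[i, j] <- if (op == "erode") all(win) else any(win)
    }
  }
  out
}

# Solid axis-aligned block instance: rows r0..r1, cols c0..c1 (0-based).
block_instance <- function(c0, r0, c1, r1, class_label = "sig", id = 1L) {
  px <- as.matrix(expand.grid(i = c0:c1, j = r0:r1))
  instance_annotation(px, class_label, id)
}

# Random blob-ish instance inside an H x W grid.
random_instance <- function(H, W, id, class_label = "sig") {
  r0 <- sample.int(H - 3L, 1L); c0 <- sample.int(W - 3L, 1L)
  r1 <- min(H, r0 + sample.int(6L, 1L)); c1 <- min(W, c0 + sample.int(6L, 1L))
  block_instance(c0 - 1L, r0 - 1L, c1 - 1L, r1 - 1L, class_label, id)
}

# Central finite differences of the weighted softmax loss w.r.t. scores.
num_grad_loss <- function(scores, labels, weights, reduction, eps = 1e-6) {
  g <- array(0, dim(scores))
  for (e in seq_along(scores)) {
    sp <- scores; sp[e] <- sp[e] + eps
    sm <- scores; sm[e] <- sm[e] - eps
    lp <- soft_weight_softmax_loss(sp, labels, weights, reduction = reduction)
    lm <- soft_weight_softmax_loss(sm, labels, weights, reduction = reduction)
    g[e] <- (as.numeric(lp) - as.numeric(lm)) / (2 * eps)
  }
  g
}

# Fixture parameters used by the desk-scale learning experiments: one
# large blurry-edged nucleus per 128x128 field, so the pooled median
# bounding-box diagonal exceeds 100 and the derived kernels are (3, 7).
learning_params <- function(seed, blur_sigma = 1.5) {
  synth_params(image_size = c(128L, 128L), n_nuclei = 1L,
               nucleus_radius = c(36, 48), blur_sigma = blur_sigma,
               dots_dark = 4L, dots_red = 2L, dot_radius = c(2, 4),
               noise_sigma = 0.04, style = "dish", seed = seed)
}

# Desk-scale training profile; returns mean held-out foreground F1.
train_and_score <- function(seed, mode = "soft", n_train = 12L, n_test = 4L,
                            width = 1 / 16, steps = 150L, blur_sigma = 3) {
  params <- learning_params(seed, blur_sigma = blur_sigma)
  ds <- generate_dataset(n_train, n_test, params)
  is_train <- ds$manifest$split == "train"
  ann <- lapply(ds$fields, function(f) filter_classes(f$annotations, "nucleus"))
  kern <- if (mode == "hard") list(kappa_e = 1L, kappa_d = 1L) else NULL
  soft <- soften_dataset(ann[is_train], class_table = "nucleus", kernels = kern)
  samples <- make_training_samples(ds$fields[is_train], soft)
  net <- build_slfcn(network_config(2L, width))
  net <- init_network(net, "kaiming", seed = seed)
  net <- init_bilinear_deconv(net)
  net <- zero_score_layer(net)
  tc <- train_config(optimizer = "sgd_momentum", lr = 1e-3, momentum = 0.9,
                     steps = steps, seed = seed, reduction = "mean")
  fit <- fit_slfcn(net, samples, tc)
  f1 <- vapply(which(!is_train), function(k) {
    pr <- predict(fit$network, ds$fields[[k]]$image)
    ref <- build_target_labels(ann[[k]], class_table = "nucleus")
    row <- evaluate_labels(pr$labels, ref, classes = 1L)
    row$f1[row$class == "foreground"]
  }, numeric(1))
  mean(f1)
}
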