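test_that("bounding boxes use literal min/max extents", {
  ins <- instance_annotation(rbind(c(2, 3), c(5, 3), c(2, 4)), "sig", 1L)
  expect_equal(bounding_box(ins),
               list(x_min = 2L, y_min = 3L, width = 3L, height = 1L))
  single <- instance_annotation(cbind(7L, 7L), "sig", 2L)
  expect_equal(bounding_box(single),
               list(x_min = 7L, y_min = 7L, width = 0L, height = 0L))
  block <- block_instance(0L, 0L, 4L, 4L)
  expect_equal(bounding_box(block),
               list(x_min = 0L, y_min = 0L, width = 4L, height = 4L))
  expect_error(instance_annotation(matrix(integer(0), 0, 2), "sig", 3L),
               "empty pixel set")
})

test_that("diagonals and their median follow the literal extent formulas", {
  expect_equal(bbox_diagonal(list(width = 3, height = 4)), 5)
  expect_equal(bbox_diagonal(list(width = 0, height = 0)), 0)
  expect_equal(bbox_diagonal(list(width = 4, height = 4)), sqrt(32))
  expect_equal(median_diagonal(c(5, 3, 4)), 4)
  expect_equal(median_diagonal(c(6, 3, 5, 4)), 4.5)
  expect_equal(median_diagonal(7), 7)
  expect_error(median_diagonal(numeric(0)), "empty")
  # order irrelevance against a sort-based oracle
  set.seed(11)
  for (rep in 1:25) {
    v <- runif(sample.int(9L, 1L), 0, 300)
    s <- sort(v); k <- length(s)
    oracle <- if (k %% 2L == 1L) s[(k + 1L) / 2L] else mean(s[k / 2L + 0:1])
    expect_equal(median_diagonal(v[sample.int(length(v))]), oracle)
  }
})

test_that("kernel sizes scale with the median diagonal", {
  expect_equal(kernel_sizes(0), list(kappa_e = 1L, kappa_d = 1L))
  expect_equal(kernel_sizes(100), list(kappa_e = 3L, kappa_d = 7L))
  expect_equal(kernel_sizes(300), list(kappa_e = 5L, kappa_d = 13L))
  expect_error(kernel_sizes(-1), "non-negative")
  # at defaults both sizes are odd, kd = 3*ke - 2, monotone in psi
  set.seed(7)
  psis <- sort(runif(60, 0, 800))
  ks <- vapply(psis, function(p) unlist(kernel_sizes(p)), numeric(2))
  expect_true(all(ks %% 2 == 1))
  expect_true(all(ks[2, ] == 3 * ks[1, ] - 2))
  expect_true(all(diff(ks[1, ]) >= 0) && all(diff(ks[2, ]) >= 0))
  # alternative region-scale presets
  half <- soft_label_params(preset = "half")
  expect_equal(c(half$upsilon, half$tau), c(1L, 3L))
  dbl <- soft_label_params(preset = "double")
  expect_equal(c(dbl$upsilon, dbl$tau), c(4L, 12L))
  expect_equal(kernel_sizes(300, dbl), list(kappa_e = 9L, kappa_d = 25L))
})

test_that("square-kernel morphology matches its contracts", {
  m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE
  er <- erode_mask(m, 3L)
  expect_equal(sum(er), 9)
  expect_true(all(which(er) %in% which(m)))
  expect_equal(erode_mask(m, 1L), m)
  expect_equal(dilate_mask(m, 1L), m)
  d <- matrix(FALSE, 9, 9); d[4:6, 4:6] <- TRUE
  expect_equal(sum(dilate_mask(d, 3L)), 25)
  expect_error(erode_mask(m, 4L), "odd")
  expect_error(dilate_mask(m, 2L), "odd")
})

test_that("morphology agrees with a brute-force min/max filter", {
  set.seed(42)
  for (case in 1:100) {
    mask <- matrix(runif(16 * 16) < 0.5, 16, 16)
    kappa <- sample(c(1L, 3L, 5L), 1L)
    expect_identical(erode_mask(mask, kappa), bf_morph(mask, kappa, "erode"))
    expect_identical(dilate_mask(mask, kappa), bf_morph(mask, kappa, "dilate"))
  }
})

test_that("region partition reproduces hand-computed band sizes", {
  ins <- block_instance(5L, 5L, 9L, 9L)           # 5x5 block in 15x15
  part <- region_partition(list(ins), list(kappa_e = 3L, kappa_d = 7L),
                           c(15L, 15L))
  expect_equal(sum(part$core), 9)
  expect_equal(sum(part$soft_band), 72)
  expect_equal(sum(part$background), 15 * 15 - 81)
  # identity kernels: hard-label limit
  part1 <- region_partition(list(ins), list(kappa_e = 1L, kappa_d = 1L),
                            c(15L, 15L))
  expect_equal(sum(part1$core), 25)
  expect_equal(sum(part1$soft_band), 0)
  # instance that erodes away becomes all soft band
  tiny <- block_instance(3L, 3L, 4L, 4L)
  p2 <- region_partition(list(tiny), list(kappa_e = 3L, kappa_d = 7L),
                         c(12L, 12L))
  expect_equal(sum(p2$core), 0)
  expect_equal(sum(p2$soft_band), 4)
})

test_that("border-touching instances erode from the image edge", {
  ins <- block_instance(0L, 0L, 3L, 3L)           # 4x4 flush with the corner
  part <- region_partition(list(ins), list(kappa_e = 3L, kappa_d = 3L),
                           c(10L, 10L))
  core <- matrix(FALSE, 10, 10); core[2:3, 2:3] <- TRUE
  expect_identical(part$core, core)
})

test_that("partition invariants hold over random instance sets", {
  set.seed(99)
  for (case in 1:20) {
    H <- 20L; W <- 24L
    n <- sample.int(4L, 1L)
    instances <- lapply(seq_len(n), function(k) random_instance(H, W, k))
    ke <- sample(c(1L, 3L, 5L), 1L)
    kd <- sample(c(1L, 3L, 5L, 7L), 1L)
    part <- region_partition(instances, list(kappa_e = ke, kappa_d = kd), c(H, W))
    expect_false(any(part$core & part$soft_band))
    expect_false(any(part$core & part$background))
    expect_false(any(part$soft_band & part$background))
    expect_equal(sum(part$core) + sum(part$soft_band) + sum(part$background),
                 H * W)
    ann_union <- Reduce(`|`, lapply(instances, function(i) {
      m <- matrix(FALSE, H, W)
      m[cbind(i$pixels[, "j"] + 1L, i$pixels[, "i"] + 1L)] <- TRUE
      m
    }))
    expect_true(all(which(part$core) %in% which(ann_union)))
    # growing the dilation kernel can only grow core | soft coverage
    part2 <- region_partition(instances, list(kappa_e = ke, kappa_d = kd + 2L),
                              c(H, W))
    cov1 <- part$core | part$soft_band
    cov2 <- part2$core | part2$soft_band
    expect_true(all(which(cov1) %in% which(cov2)))
  }
})

test_that("weight maps take exactly the three configured tiers", {
  ins <- block_instance(5L, 5L, 9L, 9L)
  part <- region_partition(list(ins), list(kappa_e = 3L, kappa_d = 7L),
                           c(15L, 15L))
  w <- weight_map(part)
  expect_equal(w[8, 8], 2)        # core pixel
  expect_equal(w[6, 8], 1.5)      # erosion-band pixel
  expect_equal(w[1, 1], 1)        # far background
  expect_true(all(w %in% c(2, 1.5, 1)))
  # empty image: constant background weight
  p0 <- region_partition(list(), list(kappa_e = 3L, kappa_d = 7L), c(6L, 6L))
  expect_equal(weight_map(p0), matrix(1, 6, 6))
  # alternative triple
  w2 <- weight_map(part, weight_params(preset = "low_background"))
  expect_true(all(w2 %in% c(2, 1, 0.1)))
})

test_that("target labels stay hard and reject cross-class overlap", {
  a <- block_instance(1L, 1L, 3L, 3L, "her2", 1L)
  b <- block_instance(6L, 6L, 8L, 8L, "cen17", 2L)
  lab <- build_target_labels(list(a, b), c(10L, 10L), c("her2", "cen17"))
  expect_equal(lab[2, 2], 1L)
  expect_equal(lab[7, 7], 2L)
  expect_equal(sum(lab == 1L), 9)
  expect_equal(sum(lab == 2L), 9)
  expect_equal(lab[10, 10], 0L)
  clash <- block_instance(2L, 2L, 4L, 4L, "cen17", 3L)
  expect_error(build_target_labels(list(a, clash), c(10L, 10L),
                                   c("her2", "cen17")),
               "annotation conflict.*3.*1|annotation conflict")
  # dilation-band pixels keep the background class
  part <- region_partition(list(a), list(kappa_e = 3L, kappa_d = 7L),
                           c(10L, 10L))
  lab1 <- build_target_labels(list(a), c(10L, 10L), "her2")
  expect_true(all(lab1[part$soft_band & lab1 == 0L] == 0L))
  band_outside <- part$soft_band & !matrix(lab1 == 1L, 10, 10)
  expect_true(sum(band_outside) > 0)
  expect_true(all(lab1[band_outside] == 0L))
})

test_that("dataset softening pools the median over all images", {
  # three instances with diagonals 5, 3, 4 spread over two images
  i1 <- instance_annotation(rbind(c(0, 0), c(3, 4)), "sig", 1L)  # diag 5
  i2 <- instance_annotation(rbind(c(0, 0), c(0, 3)), "sig", 2L)  # diag 3
  i3 <- instance_annotation(rbind(c(10, 2), c(14, 2)), "sig", 3L) # diag 4
  ds <- list(img1 = annotation_set(list(i1, i2), c(20L, 20L)),
             img2 = annotation_set(list(i3), c(20L, 20L)))
  out <- soften_dataset(ds)
  expect_equal(out$psi_star, 4)
  expect_equal(out$kernels, kernel_sizes(4))
  expect_named(out$maps, c("img1", "img2"))
  expect_error(soften_dataset(list()), "empty")

  # 128x128 image with one 80x80 square: the full worked example
  sq <- block_instance(24L, 24L, 103L, 103L, "tumor", 1L)
  ds2 <- list(img = annotation_set(list(sq), c(128L, 128L)))
  out2 <- soften_dataset(ds2)
  expect_equal(out2$psi_star, 79 * sqrt(2), tolerance = 1e-12)
  expect_equal(out2$kernels, list(kappa_e = 3L, kappa_d = 7L))
  w <- out2$maps$img$weights
  expect_equal(w[64, 64], 2)
  expect_equal(w[25, 64], 1.5)
  expect_equal(w[1, 1], 1)

  # determinism: identical inputs give bit-identical outputs
  again <- soften_dataset(ds2)
  expect_identical(out2, again)
})
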