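# Seeded generator of FISH/DISH-like fixtures: nucleus-like blobs carrying
# punctate two-class signals, rendered crisply, then blurred — so the image
# is soft while the ground-truth instance masks stay exact. Visual realism
# is not the goal; the generator reproduces the statistical structure the
# soft-label method targets (blurry appearance over crisp truth).

#' Synthetic fixture parameters
#'
#' @param image_size integer `(height, width)`, default 256 x 256.
#' @param n_nuclei number of nucleus-like blobs.
#' @param nucleus_radius `(min, max)` semi-axis range in pixels.
#' @param blur_sigma Gaussian blur applied to the rendered image (pixels);
#'   the difficulty dial — larger values give blurrier boundaries.
#' @param dots_dark dark ("HER2-like") dots per nucleus.
#' @param dots_red red ("CEN17-like") dots per nucleus.
#' @param dot_radius `(min, max)` dot radius range in pixels.
#' @param noise_sigma additive Gaussian pixel noise after blurring.
#' @param style `"dish"` (brightfield: light background, dark/red signals)
#'   or `"fish"` (fluorescence: dark background, bright nuclei).
#' @param seed mandatory integer seed; the same seed reproduces the field
#'   bit-identically.
#' @export
synth_params <- function(image_size = c(256L, 256L), n_nuclei = 5L,
                         nucleus_radius = c(20, 40), blur_sigma = 1.5,
                         dots_dark = 4L, dots_red = 2L, dot_radius = c(2, 4),
                         noise_sigma = 0.04, style = c("dish", "fish"), seed) {
  if (missing(seed)) stop("a seed is mandatory for synthetic fixtures")
  style <- match.arg(style)
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  stopifnot(n_nuclei >= 0L, dots_dark >= 0L, dots_red >= 0L,
            all(nucleus_radius >= 1), all(dot_radius >= 1),
            blur_sigma >= 0, noise_sigma >= 0)
  structure(list(image_size = as.integer(image_size),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = nucleus_radius, blur_sigma = blur_sigma,
                 dots_dark = as.integer(dots_dark), dots_red = as.integer(dots_red),
                 dot_radius = dot_radius, noise_sigma = noise_sigma,
                 style = style, seed = as.integer(seed)),
            class = "synth_params")
}

# Separable Gaussian blur with symmetric border handling.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  blur_rows <- function(m) {
    H <- nrow(m)
    rr <- min(r, H)
    kk <- dnorm(-rr:rr, sd = sigma)
    kk <- kk / sum(kk)
    pad <- m[c(rev(seq_len(rr)),              # symmetric top mirror
               seq_len(H),
               H - seq_len(rr) + 1L),         # symmetric bottom mirror
             , drop = FALSE]
    out <- 0 * m
    for (t in seq_along(kk)) out <- out + kk[t] * pad[t:(t + H - 1L), , drop = FALSE]
    out
  }
  t(blur_rows(t(blur_rows(m))))
}

ellipse_pixels <- function(cx, cy, a, b, phi, H, W) {
  rmax <- ceiling(max(a, b))
  xs <- max(0L, floor(cx - rmax)):min(W - 1L, ceiling(cx + rmax))
  ys <- max(0L, floor(cy - rmax)):min(H - 1L, ceiling(cy + rmax))
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, length(xs))
  dx <- gx - cx; dy <- gy - cy
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  keep <- u^2 + v^2 <= 1
  cbind(i = gx[keep], j = gy[keep])
}

disk_pixels <- function(cx, cy, r, H, W) {
  ellipse_pixels(cx, cy, r, r, 0, H, W)
}

paint <- function(image, px, color) {
  for (ch in 1:3) {
    pl <- image[, , ch]
    pl[cbind(px[, "j"] + 1L, px[, "i"] + 1L)] <- color[ch]
    image[, , ch] <- pl
  }
  image
}

#' Generate one synthetic field with exact ground truth
#'
#' Renders a textured background, nucleus-like ellipses and punctate
#' two-class dots, records every shape as an [instance_annotation()]
#' (classes `"nucleus"`, `"her2"`, `"cen17"`), then blurs the image and
#' adds noise. Dots lie fully inside the image; dots never overlap each
#' other. Deterministic given the seed.
#'
#' @param params a [synth_params()].
#' @return Object of class `slfcn_field`: `list(image, annotations, params)`.
#' @export
generate_field <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  H <- params$image_size[1L]; W <- params$image_size[2L]
  dish <- params$style == "dish"
  bg <- if (dish) c(0.88, 0.85, 0.87) else c(0.06, 0.06, 0.10)
  nuc_col <- if (dish) c(0.58, 0.52, 0.66) else c(0.15, 0.22, 0.55)
  dark_col <- if (dish) c(0.10, 0.09, 0.10) else c(0.95, 0.55, 0.10)
  red_col <- if (dish) c(0.70, 0.15, 0.18) else c(0.90, 0.12, 0.12)

  tex <- gaussian_blur(matrix(rnorm(H * W, 0, 1), H, W), 4)
  tex <- 0.04 * tex / max(1e-9, stats::sd(tex))
  image <- array(0, c(H, W, 3L))
  for (ch in 1:3) image[, , ch] <- bg[ch] + tex

  instances <- list()
  next_id <- 1L
  nuc_centers <- matrix(numeric(0), 0, 3)  # cx, cy, rmax
  for (k in seq_len(params$n_nuclei)) {
    placed <- FALSE
    for (try in 1:200) {
      a <- runif(1, params$nucleus_radius[1L], params$nucleus_radius[2L])
      b <- runif(1, params$nucleus_radius[1L], params$nucleus_radius[2L])
      phi <- runif(1, 0, pi)
      rmax <- max(a, b)
      if (W - 2 * rmax < 2 || H - 2 * rmax < 2) next
      cx <- runif(1, rmax, W - 1 - rmax); cy <- runif(1, rmax, H - 1 - rmax)
      if (nrow(nuc_centers) > 0) {
        dmin <- sqrt((nuc_centers[, 1] - cx)^2 + (nuc_centers[, 2] - cy)^2)
        if (any(dmin < 0.9 * (nuc_centers[, 3] + rmax))) next
      }
      px <- ellipse_pixels(cx, cy, a, b, phi, H, W)
      if (nrow(px) == 0L) next
      jitter <- runif(3, -0.04, 0.04)
      image <- paint(image, px, pmin(1, pmax(0, nuc_col + jitter)))
      instances[[next_id]] <- instance_annotation(px, "nucleus", next_id)
      nuc_centers <- rbind(nuc_centers, c(cx, cy, rmax))
      next_id <- next_id + 1L
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible packing: could not place nucleus ", k,
                      " after bounded retries")
  }

  for (nk in seq_len(nrow(nuc_centers))) {
    ctr <- nuc_centers[nk, ]
    dot_centers <- matrix(numeric(0), 0, 3)
    classes <- c(rep("her2", params$dots_dark), rep("cen17", params$dots_red))
    for (cls in classes) {
      placed <- FALSE
      for (try in 1:100) {
        r <- runif(1, params$dot_radius[1L], params$dot_radius[2L])
        ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, max(0, ctr[3] - r - 1))
        cx <- ctr[1] + rad * cos(ang); cy <- ctr[2] + rad * sin(ang)
        # dots must not cross the image border
        if (cx - r < 0 || cx + r > W - 1 || cy - r < 0 || cy + r > H - 1) next
        if (nrow(dot_centers) > 0) {
          d <- sqrt((dot_centers[, 1] - cx)^2 + (dot_centers[, 2] - cy)^2)
          if (any(d < dot_centers[, 3] + r + 1.5)) next
        }
        px <- disk_pixels(cx, cy, r, H, W)
        if (nrow(px) == 0L) next
        image <- paint(image, px, if (cls == "her2") dark_col else red_col)
        instances[[next_id]] <- instance_annotation(px, cls, next_id)
        next_id <- next_id + 1L
        dot_centers <- rbind(dot_centers, c(cx, cy, r))
        placed <- TRUE
        break
      }
      if (!placed) stop("infeasible packing: could not place a '", cls,
                        "' dot after bounded retries")
    }
  }

  for (ch in 1:3) image[, , ch] <- gaussian_blur(image[, , ch], params$blur_sigma)
  if (params$noise_sigma > 0) {
    image <- image + array(rnorm(length(image), 0, params$noise_sigma), dim(image))
  }
  image <- array(pmin(pmax(image, 0), 1), c(H, W, 3L))
  structure(list(image = image,
                 annotations = annotation_set(instances, c(H, W)),
                 params = params),
            class = "slfcn_field")
}

#' @export
print.slfcn_field <- function(x, ...) {
  cat(sprintf("<slfcn_field> %dx%d (%s), %d instances, seed %d\n",
              x$params$image_size[1], x$params$image_size[2], x$params$style,
              length(x$annotations$instances), x$params$seed))
  invisible(x)
}

#' Generate a train/test fixture dataset
#'
#' Each image gets its own seed derived from the master seed, so the
#' manifest regenerates identically. Optionally writes images, annotation
#' maps and the manifest to disk in the package's file formats.
#'
#' @param n_train,n_test number of training / held-out images.
#' @param params a [synth_params()]; its seed is the master seed.
#' @param out_dir optional directory; when given, files are written and
#'   the manifest records their paths.
#' @return List with `manifest` (tibble: id, split, seed, paths) and
#'   `fields` (list of [generate_field()] results).
#' @export
generate_dataset <- function(n_train, n_test, params, out_dir = NULL) {
  stopifnot(n_train >= 1L, n_test >= 0L)
  n <- n_train + n_test
  seeds <- (params$seed + 9973L * seq_len(n)) %% .Machine$integer.max
  ids <- sprintf("img%03d", seq_len(n))
  split <- rep(c("train", "test"), c(n_train, n_test))
  fields <- lapply(seq_len(n), function(k) {
    p <- params; p$seed <- as.integer(seeds[k])
    generate_field(p)
  })
  image_path <- ann_path <- rep(NA_character_, n)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "annotations"), recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(n)) {
      image_path[k] <- file.path(out_dir, "images", paste0(ids[k], ".png"))
      ann_path[k] <- file.path(out_dir, "annotations", paste0(ids[k], ".png"))
      write_image(fields[[k]]$image, image_path[k])
      write_annotations(fields[[k]]$annotations, ann_path[k])
    }
  }
  manifest <- tibble::tibble(id = ids, split = split, seed = as.integer(seeds),
                             image = image_path, annotation = ann_path)
  if (!is.null(out_dir)) write_manifest(manifest, file.path(out_dir, "manifest.json"))
  list(manifest = manifest, fields = fields)
}
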