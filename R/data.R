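# Tiling, stitching, augmentation and file bindings.

reflect_idx <- function(n_extra, n) {
  # symmetric (edge-repeating) mirror indices for padding past position n
  idx <- n - seq_len(n_extra) + 1L
  pmax(1L, pmin(n, idx))
}

pad_reflect <- function(image, ph, pw) {
  d <- dim(image)
  ridx <- c(seq_len(d[1L]), reflect_idx(ph, d[1L]))
  cidx <- c(seq_len(d[2L]), reflect_idx(pw, d[2L]))
  if (length(d) == 3L) image[ridx, cidx, , drop = FALSE] else image[ridx, cidx]
}

#' Cut an image into fixed-size tiles
#'
#' Tiles of side `tile_side` on a regular grid with the given stride
#' (default: non-overlapping). Right/bottom borders are reflect-padded so
#' every tile is full size; at `stride = tile_side` every source pixel is
#' covered exactly once.
#'
#' @param image `H x W x C` array or matrix.
#' @param tile_side tile side length (default 512, the network input size).
#' @param stride grid stride; must not exceed `tile_side` (gaps).
#' @return List of tiles: `list(block, x0, y0, valid_h, valid_w)` with
#'   0-based source origins and the extent of non-padded content.
#' @export
tile_image <- function(image, tile_side = 512L, stride = tile_side) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (stride > tile_side) stop("stride larger than the tile side leaves gaps")
  nt_r <- ceiling(max(d[1L] - tile_side, 0L) / stride) + 1L
  nt_c <- ceiling(max(d[2L] - tile_side, 0L) / stride) + 1L
  need_h <- (nt_r - 1L) * stride + tile_side
  need_w <- (nt_c - 1L) * stride + tile_side
  padded <- pad_reflect(image, need_h - d[1L], need_w - d[2L])
  tiles <- list()
  for (tc_ in seq_len(nt_c) - 1L) {
    for (tr in seq_len(nt_r) - 1L) {
      y0 <- tr * stride; x0 <- tc_ * stride
      block <- padded[(y0 + 1L):(y0 + tile_side), (x0 + 1L):(x0 + tile_side), ,
                      drop = FALSE]
      tiles[[length(tiles) + 1L]] <- list(
        block = block, x0 = x0, y0 = y0,
        valid_h = min(tile_side, d[1L] - y0),
        valid_w = min(tile_side, d[2L] - x0))
    }
  }
  tiles
}

#' Reassemble per-tile maps into a full-size map
#'
#' Tile blocks (e.g. per-class score maps) are placed back at their source
#' origins; overlapping contributions are averaged and padded regions
#' outside the source are discarded.
#'
#' @param tiles list of tiles as produced by [tile_image()] (with `block`
#'   possibly replaced by a same-sized map, any channel count).
#' @param source_shape integer `(height, width)` of the source image.
#' @return `H x W x C` array (or matrix for C = 1... kept as array).
#' @export
stitch_tiles <- function(tiles, source_shape) {
  H <- source_shape[1L]; W <- source_shape[2L]
  C <- dim(tiles[[1L]]$block)[3L]
  acc <- array(0, c(H, W, C))
  cnt <- matrix(0, H, W)
  for (tl in tiles) {
    nr <- min(dim(tl$block)[1L], H - tl$y0)
    nc <- min(dim(tl$block)[2L], W - tl$x0)
    if (nr <= 0L || nc <= 0L) next
    rr <- (tl$y0 + 1L):(tl$y0 + nr); cc <- (tl$x0 + 1L):(tl$x0 + nc)
    acc[rr, cc, ] <- acc[rr, cc, , drop = FALSE] +
      tl$block[seq_len(nr), seq_len(nc), , drop = FALSE]
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  if (any(cnt == 0)) stop("tile coverage gap: some source pixels received no tile")
  acc / array(cnt, c(H, W, C))
}

#' Augmentation plan
#'
#' The default plan follows the training recipe: five small rotations in
#' 5-degree steps, the three right-angle rotations, and horizontal plus
#' vertical flips — 11 samples per input including the original.
#'
#' @param small_angles numeric degrees in (0, 360); empty to disable.
#' @param right_angles subset of `c(90, 180, 270)`.
#' @param flips subset of `c("horizontal", "vertical")`.
#' @export
augmentation_plan <- function(small_angles = c(5, 10, 15, 20, 25),
                              right_angles = c(90, 180, 270),
                              flips = c("horizontal", "vertical")) {
  stopifnot(all(small_angles > 0 & small_angles < 360),
            all(right_angles %in% c(90, 180, 270)),
            all(flips %in% c("horizontal", "vertical")))
  structure(list(small_angles = small_angles, right_angles = right_angles,
                 flips = flips), class = "augmentation_plan")
}

rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]
rot180 <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]
rot270_ccw <- function(m) t(m)[, nrow(m):1, drop = FALSE]

apply_planes <- function(x, f) {
  if (is.matrix(x)) return(f(x))
  d3 <- dim(x)[3L]
  slices <- lapply(seq_len(d3), function(k) f(x[, , k]))
  array(unlist(slices), c(dim(slices[[1L]]), d3))
}

# Inverse-mapped rotation about the image centre; angle in degrees CCW.
rotate_plane <- function(m, angle, method = c("bilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  th <- angle * pi / 180
  H <- nrow(m); W <- ncol(m)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- matrix(rep(seq_len(H), W), H); cc <- matrix(rep(seq_len(W), each = H), H)
  sr <- cy + cos(th) * (r - cy) + sin(th) * (cc - cx)
  sc <- cx - sin(th) * (r - cy) + cos(th) * (cc - cx)
  out <- matrix(fill, H, W)
  if (method == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out[ok] <- m[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    ok <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W
    g <- function(dr, dc) m[cbind(r0[ok] + dr, c0[ok] + dc)]
    out[ok] <- g(0, 0) * (1 - fr[ok]) * (1 - fc[ok]) +
      g(1, 0) * fr[ok] * (1 - fc[ok]) +
      g(0, 1) * (1 - fr[ok]) * fc[ok] +
      g(1, 1) * fr[ok] * fc[ok]
  }
  out
}

transform_sample <- function(sample, f_image, f_plane, weight_fill) {
  list(image = apply_planes(sample$image, f_image),
       labels = {
         lab <- f_plane(sample$labels)
         storage.mode(lab) <- "integer"
         lab
       },
       weights = if (is.null(sample$weights)) NULL else f_plane(sample$weights))
}

#' Augment one training sample
#'
#' Applies the plan identically to image, label field and weight map.
#' Right-angle rotations and flips are exact pixel permutations; small
#' rotations interpolate the image bilinearly and the categorical planes
#' (labels, weights) with nearest neighbour. Out-of-frame regions are
#' filled with black / background class 0 / `weight_fill` (the background
#' weight).
#'
#' @param sample `list(image, labels, weights)`.
#' @param plan an [augmentation_plan()].
#' @param weight_fill fill value for rotated-in weight pixels (default 1,
#'   the default background weight).
#' @return List of samples; the first element is the original.
#' @export
augment_sample <- function(sample, plan = augmentation_plan(), weight_fill = 1) {
  out <- list(sample)
  for (a in plan$small_angles) {
    out[[length(out) + 1L]] <- list(
      image = apply_planes(sample$image,
                           function(m) rotate_plane(m, a, "bilinear", 0)),
      labels = {
        lab <- rotate_plane(sample$labels, a, "nearest", 0L)
        storage.mode(lab) <- "integer"; lab
      },
      weights = if (is.null(sample$weights)) NULL else
        rotate_plane(sample$weights, a, "nearest", weight_fill))
  }
  rots <- list(`90` = rot90_ccw, `180` = rot180, `270` = rot270_ccw)
  for (a in plan$right_angles) {
    f <- rots[[as.character(a)]]
    out[[length(out) + 1L]] <- transform_sample(sample, f, f, weight_fill)
  }
  flips <- list(horizontal = function(m) m[, ncol(m):1, drop = FALSE],
                vertical = function(m) m[nrow(m):1, , drop = FALSE])
  for (fl in plan$flips) {
    f <- flips[[fl]]
    out[[length(out) + 1L]] <- transform_sample(sample, f, f, weight_fill)
  }
  out
}

# ---- file bindings -------------------------------------------------------

#' Image, label-map and weight-map readers/writers
#'
#' Images are 8-bit RGB PNG; label maps are 8-bit indexed PNG (0 =
#' background, 1..N-1 classes); weight maps are single-channel 32-bit
#' float TIFF. All pairs round-trip losslessly (weight maps within float32).
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param path file path.
#' @name slfcn_io
#' @export
write_image <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname slfcn_io
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L) img <- img[, , 1:3]
  img
}

#' @rdname slfcn_io
#' @param labels integer matrix of class indices in 0..255.
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 255L) stop("label indices exceed the 8-bit range")
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname slfcn_io
#' @export
read_label_map <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' @rdname slfcn_io
#' @param weights numeric matrix of per-pixel loss weights.
#' @export
write_weight_map <- function(weights, path) {
  # 32-bit single-channel TIFF; TIFF storage here is unit-range, so the map
  # is stored divided by its maximum with the scale in a JSON sidecar.
  # 32-bit quantisation error (~2^-32 relative) is far below float32 eps.
  scale <- max(1, max(weights))
  tiff::writeTIFF(weights / scale, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(scale = scale), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname slfcn_io
#' @export
read_weight_map <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  scale <- jsonlite::fromJSON(paste0(path, ".json"))$scale
  m * scale
}

#' Dataset manifest I/O
#'
#' A manifest is a table of per-image records (`id`, `split`, file paths,
#' seed) serialised as JSON.
#'
#' @param manifest data frame / tibble of records.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}
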