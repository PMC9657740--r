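#' Soft-label construction parameters
#'
#' Controls how the erosion/dilation kernel sizes are derived from the
#' dataset-wide median bounding-box diagonal \eqn{\psi^*}:
#' \eqn{\kappa_e = \upsilon \lfloor (\phi\psi^* + 1)/2 \rfloor + 1} and
#' \eqn{\kappa_d = \tau \lfloor (\phi\psi^* + 1)/2 \rfloor + 1}.
#'
#' @param phi positive scale applied to the median diagonal (default 0.01).
#' @param upsilon positive integer erosion multiplier (default 2).
#' @param tau positive integer dilation multiplier (default 6).
#' @param preset optional named preset instead of explicit values:
#'   `"default"` (\eqn{\upsilon=2,\tau=6}), `"half"` (1, 3), `"double"` (4, 12).
#' @return An object of class `soft_label_params`.
#' @export
soft_label_params <- function(phi = 0.01, upsilon = 2L, tau = 6L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("default", "half", "double"))
    ut <- switch(preset, default = c(2L, 6L), half = c(1L, 3L), double = c(4L, 12L))
    upsilon <- ut[1L]; tau <- ut[2L]
  }
  stopifnot(is.numeric(phi), phi > 0,
            upsilon >= 1, upsilon == as.integer(upsilon),
            tau >= 1, tau == as.integer(tau))
  structure(list(phi = phi, upsilon = as.integer(upsilon), tau = as.integer(tau)),
            class = "soft_label_params")
}

#' Three-tier loss weights
#'
#' @param psi core weight \eqn{\Psi} (default 2).
#' @param pi_ soft-band weight \eqn{\Pi} (default 1.5).
#' @param aleph background weight \eqn{\aleph} (default 1).
#' @param preset optional: `"default"` (2, 1.5, 1), `"low_background"`
#'   (2, 1, 0.1), `"high_core"` (4, 2, 1).
#' @export
weight_params <- function(psi = 2, pi_ = 1.5, aleph = 1, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("default", "low_background", "high_core"))
    v <- switch(preset, default = c(2, 1.5, 1),
                low_background = c(2, 1, 0.1), high_core = c(4, 2, 1))
    psi <- v[1L]; pi_ <- v[2L]; aleph <- v[3L]
  }
  stopifnot(is.finite(psi), psi > 0, is.finite(pi_), pi_ > 0,
            is.finite(aleph), aleph > 0)
  structure(list(psi = psi, pi = pi_, aleph = aleph), class = "weight_params")
}

#' Bounding box of an instance annotation
#'
#' Width and height are `max - min` of the respective coordinate (a single
#' pixel has width = height = 0).
#'
#' @param instance an [instance_annotation()].
#' @return List with `x_min`, `y_min`, `width`, `height`.
#' @export
bounding_box <- function(instance) {
  if (!inherits(instance, "slfcn_instance")) stop("not an instance annotation")
  i <- instance$pixels[, "i"]; j <- instance$pixels[, "j"]
  list(x_min = min(i), y_min = min(j),
       width = max(i) - min(i), height = max(j) - min(j))
}

#' Euclidean diagonal of a bounding box
#' @param box a bounding box as returned by [bounding_box()].
#' @export
bbox_diagonal <- function(box) {
  sqrt(box$width^2 + box$height^2)
}

#' Median of bounding-box diagonals
#'
#' Sorted-ascending median: the middle element for odd counts, the mean of
#' the two middle elements for even counts.
#'
#' @param diagonals numeric vector, length at least 1.
#' @export
median_diagonal <- function(diagonals) {
  if (length(diagonals) == 0L) stop("empty dataset: no bounding-box diagonals")
  s <- sort(unname(diagonals))
  k <- length(s)
  if (k %% 2L == 1L) s[(k + 1L) / 2L] else (s[k / 2L] + s[k / 2L + 1L]) / 2
}

#' Erosion and dilation kernel sizes from the median diagonal
#'
#' @param psi_star non-negative median diagonal \eqn{\psi^*}.
#' @param params a [soft_label_params()].
#' @return List with odd positive integers `kappa_e` and `kappa_d`.
#' @export
kernel_sizes <- function(psi_star, params = soft_label_params()) {
  if (!is.numeric(psi_star) || psi_star < 0) {
    stop("psi_star must be a non-negative number")
  }
  half <- floor((params$phi * psi_star + 1) / 2)
  list(kappa_e = as.integer(params$upsilon * half + 1L),
       kappa_d = as.integer(params$tau * half + 1L))
}

check_kappa <- function(kappa) {
  if (kappa < 1L || kappa %% 2L == 0L) {
    stop("morphology kernel size must be an odd integer >= 1, got ", kappa)
  }
  as.integer(kappa)
}

#' Binary morphology with a square structuring element
#'
#' Erosion/dilation with the all-ones `kappa` x `kappa` square, origin at
#' its centre. Pixels outside the image are treated as background, so an
#' instance touching the border erodes from that side too and dilation is
#' clipped to the image. `kappa = 1` is the identity.
#'
#' @param mask logical (or 0/1) matrix.
#' @param kappa odd positive integer side length.
#' @return Logical matrix of the same shape.
#' @export
erode_mask <- function(mask, kappa) {
  shift_combine(mask, check_kappa(kappa), all_of = TRUE)
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, kappa) {
  shift_combine(mask, check_kappa(kappa), all_of = FALSE)
}

# AND (erosion) or OR (dilation) over all kappa^2 shifts, zero padded.
shift_combine <- function(mask, kappa, all_of) {
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (kappa == 1L) return(m)
  h <- (kappa - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L * h, W + 2L * h)
  pad[(h + 1L):(h + H), (h + 1L):(h + W)] <- m
  out <- if (all_of) matrix(TRUE, H, W) else matrix(FALSE, H, W)
  for (dj in 0:(kappa - 1L)) {
    for (di in 0:(kappa - 1L)) {
      v <- pad[(1L + di):(di + H), (1L + dj):(dj + W)]
      out <- if (all_of) out & v else out | v
    }
  }
  out
}

#' Core / soft-band / background partition of an image grid
#'
#' Per instance the annotation is eroded to a core (`r_c`), the core is
#' dilated to an outer region (`r_o`); the erosion band is the annotation
#' minus its core and the dilation band the outer region minus the
#' annotation. The soft band is the union of both bands over all instances.
#' Where instances overlap, core takes priority over soft band.
#'
#' @param instances list of [instance_annotation()] or an [annotation_set()].
#' @param kernels list with `kappa_e`, `kappa_d` (see [kernel_sizes()]).
#' @param image_shape integer `(height, width)`; taken from the annotation
#'   set when one is supplied.
#' @return An object of class `region_partition` with logical masks `core`,
#'   `soft_band`, `background` and `image_shape`.
#' @export
region_partition <- function(instances, kernels, image_shape = NULL) {
  if (inherits(instances, "slfcn_annotations")) {
    if (is.null(image_shape)) image_shape <- instances$shape
    instances <- instances$instances
  }
  stopifnot(!is.null(image_shape), length(image_shape) == 2L)
  H <- as.integer(image_shape[1L]); W <- as.integer(image_shape[2L])
  ke <- check_kappa(kernels$kappa_e); kd <- check_kappa(kernels$kappa_d)
  margin <- (ke - 1L) %/% 2L + (kd - 1L) %/% 2L + 1L

  core <- matrix(FALSE, H, W)
  soft <- matrix(FALSE, H, W)
  for (ins in instances) {
    px <- ins$pixels
    r0 <- max(1L, min(px[, "j"]) + 1L - margin); r1 <- min(H, max(px[, "j"]) + 1L + margin)
    c0 <- max(1L, min(px[, "i"]) + 1L - margin); c1 <- min(W, max(px[, "i"]) + 1L + margin)
    loc <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    loc[cbind(px[, "j"] + 2L - r0, px[, "i"] + 2L - c0)] <- TRUE
    # Border semantics: the local window is clipped at the image border, so
    # outside-image stays background; elsewhere the margin guarantees the
    # window fully contains the morphological reach of the instance.
    rc <- erode_mask(loc, ke)
    ro <- dilate_mask(rc, kd)
    rs <- (loc & !rc) | (ro & !loc)
    core[r0:r1, c0:c1] <- core[r0:r1, c0:c1] | rc
    soft[r0:r1, c0:c1] <- soft[r0:r1, c0:c1] | rs
  }
  soft <- soft & !core
  structure(list(core = core, soft_band = soft,
                 background = !(core | soft),
                 image_shape = c(H, W)),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> %dx%d: |core|=%d |soft_band|=%d |background|=%d\n",
              x$image_shape[1], x$image_shape[2],
              sum(x$core), sum(x$soft_band), sum(x$background)))
  invisible(x)
}

#' Per-pixel loss-weight map from a region partition
#'
#' Every pixel gets exactly one of the three configured weights:
#' \eqn{\Psi} on the core, \eqn{\Pi} on the soft band, \eqn{\aleph}
#' elsewhere.
#'
#' @param partition a [region_partition()].
#' @param weights a [weight_params()].
#' @return Numeric matrix of per-pixel weights.
#' @export
weight_map <- function(partition, weights = weight_params()) {
  stopifnot(inherits(partition, "region_partition"))
  w <- matrix(weights$aleph, partition$image_shape[1L], partition$image_shape[2L])
  w[partition$soft_band] <- weights$pi
  w[partition$core] <- weights$psi
  w
}

#' Hard per-pixel target classes from instance annotations
#'
#' Targets stay hard: softening acts on the loss weights, not the labels.
#' Background is class 0; annotated pixels get the 1-based index of their
#' class in `class_table`. Dilation-band pixels outside any annotation keep
#' the background class. Overlapping instances of different classes are
#' rejected.
#'
#' @param instances list of [instance_annotation()] or an [annotation_set()].
#' @param image_shape integer `(height, width)`.
#' @param class_table character vector of foreground class labels; their
#'   position defines the class index.
#' @return Integer matrix of class indices (0 = background).
#' @export
build_target_labels <- function(instances, image_shape = NULL, class_table) {
  if (inherits(instances, "slfcn_annotations")) {
    if (is.null(image_shape)) image_shape <- instances$shape
    instances <- instances$instances
  }
  H <- as.integer(image_shape[1L]); W <- as.integer(image_shape[2L])
  labels <- matrix(0L, H, W)
  owner <- matrix(0L, H, W)
  for (ins in instances) {
    cls <- match(ins$class_label, class_table)
    if (is.na(cls)) stop("class '", ins$class_label, "' not in class table")
    idx <- cbind(ins$pixels[, "j"] + 1L, ins$pixels[, "i"] + 1L)
    prev <- labels[idx]
    clash <- prev != 0L & prev != cls
    if (any(clash)) {
      stop("annotation conflict: instance ", ins$instance_id,
           " (class ", ins$class_label, ") overlaps instance(s) ",
           paste(unique(owner[idx][clash]), collapse = ", "),
           " of a different class")
    }
    labels[idx] <- cls
    owner[idx] <- ins$instance_id
  }
  labels
}

#' Soften a whole training dataset
#'
#' The median bounding-box diagonal \eqn{\psi^*} is pooled over every
#' instance in the dataset (not per image), a single kernel pair is derived
#' from it, and each image's region partition, weight map and label field
#' are built with those kernels. A per-image median is available behind
#' `per_image = TRUE` for experimentation.
#'
#' @param dataset named list of [annotation_set()] objects, one per image.
#' @param sl_params a [soft_label_params()].
#' @param w_params a [weight_params()].
#' @param class_table foreground classes for the label fields; defaults to
#'   the sorted set of class labels present.
#' @param per_image logical; compute \eqn{\psi^*} per image instead of
#'   pooling (non-default, experimental).
#' @param kernels optional explicit kernel pair overriding the derived
#'   sizes; `list(kappa_e = 1, kappa_d = 1)` reproduces the hard-label
#'   setting exactly (empty soft band).
#' @return List with `psi_star`, `kernels`, and `maps`: per image a list of
#'   `weights`, `labels`, `partition`.
#' @export
soften_dataset <- function(dataset, sl_params = soft_label_params(),
                           w_params = weight_params(),
                           class_table = NULL, per_image = FALSE,
                           kernels = NULL) {
  if (length(dataset) == 0L) stop("empty dataset")
  n_inst <- sum(vapply(dataset, function(a) length(a$instances), integer(1)))
  if (n_inst == 0L) stop("empty dataset: no instances to soften")
  if (is.null(class_table)) {
    class_table <- sort(unique(unlist(lapply(dataset, function(a) {
      vapply(a$instances, function(i) i$class_label, character(1))
    }))))
  }
  all_diags <- function(aset) {
    vapply(aset$instances, function(i) bbox_diagonal(bounding_box(i)), numeric(1))
  }
  psi_star <- if (per_image) NA_real_ else median_diagonal(unlist(lapply(dataset, all_diags)))
  if (is.null(kernels) && !per_image) kernels <- kernel_sizes(psi_star, sl_params)
  forced <- kernels
  maps <- lapply(dataset, function(aset) {
    k <- if (!is.null(forced)) forced
         else kernel_sizes(median_diagonal(all_diags(aset)), sl_params)
    part <- region_partition(aset, k)
    list(weights = weight_map(part, w_params),
         labels = build_target_labels(aset, class_table = class_table),
         partition = part)
  })
  list(psi_star = psi_star, kernels = kernels, maps = maps,
       class_table = class_table)
}

#' Display a weight map
#'
#' @param w numeric weight matrix from [weight_map()].
#' @param ... passed to [graphics::image()].
#' @export
plot_weight_map <- function(w, ...) {
  graphics::image(t(w)[, nrow(w):1], col = grDevices::gray.colors(64),
                  axes = FALSE, asp = nrow(w) / ncol(w), ...)
  invisible(w)
}
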