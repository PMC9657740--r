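#' Create a single instance annotation
#'
#' An instance annotation is one annotated region: a set of pixel
#' coordinates plus a class label and an instance id. Coordinates are
#' 0-based with `i` the x/column index and `j` the y/row index.
#'
#' @param pixels two-column matrix (or data.frame) of integer `(i, j)`
#'   coordinates, 0-based.
#' @param class_label character scalar, e.g. `"her2"`, `"cen17"`,
#'   `"nucleus"`.
#' @param instance_id positive integer, unique within an image.
#' @return An object of class `slfcn_instance`.
#' @export
instance_annotation <- function(pixels, class_label, instance_id) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) {
    stop("invalid annotation: instance ", instance_id, " has an empty pixel set")
  }
  if (ncol(pixels) != 2L) stop("pixels must be a two-column (i, j) matrix")
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L)) stop("pixel coordinates must be non-negative (0-based)")
  colnames(pixels) <- c("i", "j")
  structure(
    list(pixels = pixels, class_label = as.character(class_label),
         instance_id = as.integer(instance_id)),
    class = "slfcn_instance"
  )
}

#' Bundle instance annotations for one image
#'
#' @param instances list of [instance_annotation()] objects.
#' @param shape integer `(height, width)` of the annotated image.
#' @return An object of class `slfcn_annotations`.
#' @export
annotation_set <- function(instances, shape) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  for (ins in instances) {
    stopifnot(inherits(ins, "slfcn_instance"))
    if (any(ins$pixels[, "j"] >= shape[1L]) || any(ins$pixels[, "i"] >= shape[2L])) {
      stop("instance ", ins$instance_id, " has pixels outside the image bounds")
    }
  }
  ids <- vapply(instances, function(x) x$instance_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate instance ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  structure(list(shape = shape, instances = instances), class = "slfcn_annotations")
}

#' @export
print.slfcn_annotations <- function(x, ...) {
  cls <- table(vapply(x$instances, function(i) i$class_label, character(1)))
  cat(sprintf("<slfcn_annotations> %dx%d, %d instances (%s)\n",
              x$shape[1], x$shape[2], length(x$instances),
              paste(names(cls), cls, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Keep only instances of the given classes
#' @param annotations an [annotation_set()].
#' @param classes character vector of class labels to keep.
#' @export
filter_classes <- function(annotations, classes) {
  keep <- vapply(annotations$instances,
                 function(i) i$class_label %in% classes, logical(1))
  annotation_set(annotations$instances[keep], annotations$shape)
}

#' Convert an annotation set to a 16-bit style instance-id matrix
#'
#' Later instances overwrite earlier ones where they overlap (overlap is
#' recorded faithfully in the per-instance pixel sets, not the id map).
#'
#' @param annotations an [annotation_set()].
#' @return Integer matrix, 0 = background, otherwise the instance id.
#' @export
as_id_map <- function(annotations) {
  m <- matrix(0L, annotations$shape[1L], annotations$shape[2L])
  for (ins in annotations$instances) {
    m[cbind(ins$pixels[, "j"] + 1L, ins$pixels[, "i"] + 1L)] <- ins$instance_id
  }
  m
}

#' Rebuild instance annotations from an instance-id matrix
#'
#' @param id_map integer matrix, 0 = background, positive values instance ids.
#' @param class_map named character vector (or list) mapping instance id
#'   (as character) to class label.
#' @export
instances_from_id_map <- function(id_map, class_map) {
  ids <- sort(unique(id_map[id_map > 0L]))
  instances <- lapply(ids, function(id) {
    w <- which(id_map == id, arr.ind = TRUE)
    cls <- class_map[[as.character(id)]]
    if (is.null(cls)) stop("no class recorded for instance id ", id)
    instance_annotation(cbind(i = w[, 2L] - 1L, j = w[, 1L] - 1L), cls, id)
  })
  annotation_set(instances, dim(id_map))
}

#' Write / read instance annotations as 16-bit-range PNG plus a JSON sidecar
#'
#' The id map (0 = background) is stored losslessly in a two-channel PNG —
#' high byte and low byte of the 16-bit instance id — and the id-to-class
#' mapping as `<path>.json` with an `"instances"` list. Round trips are
#' lossless for ids below 65536.
#'
#' @param annotations an [annotation_set()].
#' @param path PNG file path.
#' @export
write_annotations <- function(annotations, path) {
  m <- as_id_map(annotations)
  if (max(m) > 65535L) stop("instance ids exceed the 16-bit range")
  enc <- array(0, c(nrow(m), ncol(m), 2L))
  enc[, , 1L] <- (m %/% 256L) / 255
  enc[, , 2L] <- (m %% 256L) / 255
  png::writePNG(enc, path)
  side <- list(instances = lapply(annotations$instances, function(i) {
    list(id = i$instance_id, class = i$class_label)
  }))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  m <- png::readPNG(path)
  stopifnot(length(dim(m)) == 3L, dim(m)[3L] >= 2L)
  id_map <- matrix(as.integer(round(m[, , 1L] * 255) * 256L +
                              round(m[, , 2L] * 255)),
                   dim(m)[1L], dim(m)[2L])
  side <- jsonlite::read_json(paste0(path, ".json"))
  class_map <- list()
  for (rec in side$instances) class_map[[as.character(rec$id)]] <- rec$class
  instances_from_id_map(id_map, class_map)
}
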