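#' Per-pixel softmax probabilities
#'
#' Scores are an `H x W x N` array of class scores (`N >= 2`). The
#' per-pixel maximum is subtracted before exponentiation; this is
#' mathematically identical to the plain softmax and keeps the
#' exponentials bounded.
#'
#' @param scores numeric `H x W x N` array of finite class scores.
#' @return `H x W x N` array of probabilities; each pixel's slice sums to 1.
#' @export
softmax_probabilities <- function(scores) {
  check_scores(scores)
  d <- dim(scores)
  zm <- apply(scores, c(1, 2), max)
  e <- exp(scores - array(zm, d))
  s <- array(0, d[1:2])
  for (t in seq_len(d[3L])) s <- s + e[, , t, drop = FALSE][, , 1L]
  e / array(s, d)
}

check_scores <- function(scores) {
  if (length(dim(scores)) != 3L || dim(scores)[3L] < 2L) {
    stop("scores must be an H x W x N array with N >= 2")
  }
  if (!all(is.finite(scores))) stop("non-finite values in score field")
  invisible(scores)
}

check_labels <- function(scores, labels) {
  d <- dim(scores)
  if (!identical(dim(labels), d[1:2])) {
    stop("label field shape ", paste(dim(labels), collapse = "x"),
         " does not match score field ", paste(d[1:2], collapse = "x"))
  }
  ok <- is.na(labels) | (labels >= 0L & labels <= d[3L] - 1L)
  if (!all(ok)) stop("labels must be class indices in 0..N-1 (or the ignore value)")
  invisible(labels)
}

# -log probability of the target class, per pixel; NA where ignored.
neglog_target <- function(scores, labels) {
  p <- softmax_probabilities(scores)
  d <- dim(scores)
  n_px <- d[1L] * d[2L]
  flat <- matrix(p, n_px, d[3L])
  lab <- as.vector(labels)
  out <- rep(NA_real_, n_px)
  keep <- !is.na(lab)
  out[keep] <- -log(flat[cbind(which(keep), lab[keep] + 1L)])
  matrix(out, d[1L], d[2L])
}

#' Mean softmax (cross-entropy) loss
#'
#' Mean over pixels of minus the natural log of the target-class
#' probability. Labels are 0-based class indices; `NA` labels (e.g. padded
#' tile borders) contribute nothing and are excluded from the pixel count.
#'
#' @param scores numeric `H x W x N` array.
#' @param labels integer `H x W` matrix of target classes in `0..N-1`.
#' @param reduction `"mean"` (divide by the number of contributing pixels)
#'   or `"sum"`.
#' @return Scalar loss with attribute `M`, the number of contributing pixels.
#' @export
softmax_loss <- function(scores, labels, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  check_labels(check_scores(scores), labels)
  nl <- neglog_target(scores, labels)
  m <- sum(!is.na(nl))
  val <- sum(nl, na.rm = TRUE)
  if (reduction == "mean") val <- val / m
  structure(val, M = m)
}

#' Soft-weight softmax loss
#'
#' The weighted form of [softmax_loss()]: each pixel's `-log p` term is
#' scaled by its loss weight from the three-tier weight map before the
#' `1/M` mean (the normaliser is the pixel count,
#' not the weight total). With unit weights this equals [softmax_loss()].
#'
#' @inheritParams softmax_loss
#' @param weights positive numeric `H x W` matrix of per-pixel weights.
#' @return Scalar loss with attribute `M`.
#' @export
soft_weight_softmax_loss <- function(scores, labels, weights,
                                     reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  check_labels(check_scores(scores), labels)
  if (!identical(dim(weights), dim(scores)[1:2])) {
    stop("weight map shape does not match the score field")
  }
  if (any(weights <= 0)) stop("loss weights must be positive")
  nl <- neglog_target(scores, labels)
  m <- sum(!is.na(nl))
  val <- sum(weights * nl, na.rm = TRUE)
  if (reduction == "mean") val <- val / m
  structure(val, M = m)
}

#' Loss value and score gradient in one pass
#'
#' Analytic gradient of the (weighted) softmax loss with respect to the
#' scores: \eqn{\omega_m (p_m^t - [t = n_m]) / M} for mean reduction, the
#' unnormalised form for sum reduction. Ignored (`NA`) pixels get zero
#' gradient.
#'
#' @inheritParams soft_weight_softmax_loss
#' @return List with `loss` (scalar), `grad` (`H x W x N` array) and `M`.
#' @export
sws_loss_grad <- function(scores, labels, weights = NULL,
                          reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  check_labels(check_scores(scores), labels)
  d <- dim(scores)
  p <- softmax_probabilities(scores)
  n_px <- d[1L] * d[2L]
  lab <- as.vector(labels)
  keep <- !is.na(lab)
  m <- sum(keep)
  w <- if (is.null(weights)) rep(1, n_px) else as.vector(weights)
  if (!is.null(weights) && any(weights <= 0)) stop("loss weights must be positive")

  flat <- matrix(p, n_px, d[3L])
  pt <- rep(NA_real_, n_px)
  pt[keep] <- flat[cbind(which(keep), lab[keep] + 1L)]
  loss <- sum((w * -log(pt))[keep])

  grad <- flat
  grad[cbind(which(keep), lab[keep] + 1L)] <- pt[keep] - 1
  grad <- grad * w
  grad[!keep, ] <- 0
  if (reduction == "mean") {
    loss <- loss / m
    grad <- grad / m
  }
  list(loss = loss, grad = array(grad, d), M = m)
}
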