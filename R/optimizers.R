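#' Available optimizers
#'
#' The registry mirrors the ablation space: SGD with momentum (the
#' default), Adam, Adagrad, AdaDelta, Nesterov's accelerated gradient,
#' and RMSprop.
#'
#' @return Character vector of optimizer names.
#' @export
optimizer_registry <- function() {
  c("sgd_momentum", "adam", "adagrad", "adadelta", "nag", "rmsprop")
}

# One parameter-array update. `theta` and `grad` are arrays of equal shape,
# `st` the optimizer state for this parameter (NULL on the first call).
# sgd_momentum follows v <- mu*v - lr*g; theta <- theta + v.
opt_step_one <- function(name, theta, grad, st, tc) {
  eps <- 1e-8
  switch(name,
    sgd_momentum = {
      v <- if (is.null(st)) 0 * grad else st$v
      v <- tc$momentum * v - tc$lr * grad
      list(theta = theta + v, state = list(v = v))
    },
    nag = {
      v_old <- if (is.null(st)) 0 * grad else st$v
      v <- tc$momentum * v_old - tc$lr * grad
      # look-ahead form: theta + v + mu*(v - v_old)
      list(theta = theta + (1 + tc$momentum) * v - tc$momentum * v_old,
           state = list(v = v))
    },
    adam = {
      b1 <- 0.9; b2 <- 0.999
      if (is.null(st)) st <- list(m = 0 * grad, v = 0 * grad, t = 0)
      t <- st$t + 1
      m <- b1 * st$m + (1 - b1) * grad
      v <- b2 * st$v + (1 - b2) * grad^2
      mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
      list(theta = theta - tc$lr * mh / (sqrt(vh) + eps),
           state = list(m = m, v = v, t = t))
    },
    adagrad = {
      acc <- if (is.null(st)) 0 * grad else st$acc
      acc <- acc + grad^2
      list(theta = theta - tc$lr * grad / (sqrt(acc) + eps),
           state = list(acc = acc))
    },
    adadelta = {
      rho <- 0.95
      if (is.null(st)) st <- list(eg = 0 * grad, ex = 0 * grad)
      eg <- rho * st$eg + (1 - rho) * grad^2
      dx <- -sqrt(st$ex + eps) / sqrt(eg + eps) * grad
      ex <- rho * st$ex + (1 - rho) * dx^2
      list(theta = theta + tc$lr * dx, state = list(eg = eg, ex = ex))
    },
    rmsprop = {
      alpha <- 0.9
      acc <- if (is.null(st)) 0 * grad else st$acc
      acc <- alpha * acc + (1 - alpha) * grad^2
      list(theta = theta - tc$lr * grad / (sqrt(acc) + eps),
           state = list(acc = acc))
    },
    stop("unknown optimizer '", name, "'")
  )
}
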