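# Single-hidden-layer feed-forward network trained with
# Levenberg-Marquardt and validation-based early stopping. For the small
# networks used here (4 inputs, 4-20 sigmoid units, linear output) LM
# finds far better least-squares solutions than generic gradient descent,
# which matters because the perturbation statistic probes secondary
# features of the fitted surface, not just overall fit.

mlp_unpack <- function(w, d, h) {
  n1 <- h * (d + 1)
  # unit-major order: row k of W1 holds unit k's (bias, input weights),
  # matching the Jacobian column layout
  list(W1 = matrix(w[seq_len(n1)], h, d + 1, byrow = TRUE),
       w2 = w[(n1 + 1):(n1 + h + 1)])
}

mlp_forward <- function(w, Xb, d, h) {
  p <- mlp_unpack(w, d, h)
  H <- stats::plogis(Xb %*% t(p$W1))
  list(f = as.numeric(cbind(1, H) %*% p$w2), H = H)
}

# Jacobian of the network output with respect to all weights.
mlp_jacobian <- function(w, Xb, H, d, h) {
  p <- mlp_unpack(w, d, h)
  n <- nrow(Xb)
  J <- matrix(0, n, h * (d + 1) + h + 1)
  Hd <- H * (1 - H)
  for (k in seq_len(h)) {
    dk <- p$w2[k + 1] * Hd[, k]
    J[, ((k - 1) * (d + 1) + 1):(k * (d + 1))] <- Xb * dk
  }
  J[, (h * (d + 1) + 1):ncol(J)] <- cbind(1, H)
  J
}

#' Fit a feed-forward network by Levenberg-Marquardt
#'
#' One hidden layer of `hidden` logistic units with a linear output,
#' minimizing the squared error on the training rows. After each accepted
#' LM step the validation error is evaluated; training stops when it has
#' not improved for `max_fail` consecutive steps (early stopping) or after
#' `max_epochs` iterations, and the weights with the lowest validation
#' error are returned.
#'
#' @param x Numeric predictor matrix (standardized).
#' @param y Numeric response.
#' @param i_train,i_val Row indices of the training and validation
#'   portions.
#' @param hidden Hidden-layer size.
#' @param max_epochs Iteration cap (default 1000).
#' @param max_fail Patience of the validation stop (default 6).
#' @return List of class `mlp`: `weights`, `hidden`, `d`, `val_mse`,
#'   `epochs`, `converged`.
#' @export
mlp_train <- function(x, y, i_train, i_val, hidden = 10, max_epochs = 1000,
                      max_fail = 6) {
  x <- as.matrix(x)
  d <- ncol(x)
  h <- hidden
  Xb_tr <- cbind(1, x[i_train, , drop = FALSE])
  y_tr <- y[i_train]
  Xb_va <- cbind(1, x[i_val, , drop = FALSE])
  y_va <- y[i_val]
  np <- h * (d + 1) + h + 1
  # Nguyen-Widrow initialization: hidden-unit active regions spread over
  # the (standardized, roughly +/-2.5) input range
  scale <- 0.7 * h^(1 / d) / 2.5
  V <- matrix(stats::runif(h * d, -1, 1), h, d)
  V <- V / sqrt(rowSums(V^2)) * scale
  b1 <- stats::runif(h, -1, 1) * scale *
    sign(stats::runif(h) - 0.5)
  w <- c(as.numeric(t(cbind(b1, V))), stats::rnorm(h + 1, 0, 0.3))
  mu <- 1e-3
  fw <- mlp_forward(w, Xb_tr, d, h)
  sse <- sum((y_tr - fw$f)^2)
  best_w <- w
  best_val <- mean((y_va - mlp_forward(w, Xb_va, d, h)$f)^2)
  fails <- 0L
  epoch <- 0L
  while (epoch < max_epochs && mu < 1e10) {
    epoch <- epoch + 1L
    J <- mlp_jacobian(w, Xb_tr, fw$H, d, h)
    JtJ <- crossprod(J)
    g <- crossprod(J, y_tr - fw$f)
    accepted <- FALSE
    while (mu < 1e10) {
      delta <- tryCatch(solve(JtJ + mu * diag(np), g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        w_new <- w + as.numeric(delta)
        fw_new <- mlp_forward(w_new, Xb_tr, d, h)
        sse_new <- sum((y_tr - fw_new$f)^2)
        if (is.finite(sse_new) && sse_new < sse) {
          w <- w_new; fw <- fw_new; sse <- sse_new
          mu <- max(mu * 0.1, 1e-12)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!accepted) break
    val <- mean((y_va - mlp_forward(w, Xb_va, d, h)$f)^2)
    if (val < best_val - 1e-12) {
      best_val <- val; best_w <- w; fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= max_fail) break
    }
  }
  structure(list(weights = best_w, hidden = h, d = d, val_mse = best_val,
                 epochs = epoch, converged = epoch < max_epochs),
            class = "mlp")
}

#' @export
predict.mlp <- function(object, newdata, ...) {
  Xb <- cbind(1, as.matrix(newdata))
  mlp_forward(object$weights, Xb, object$d, object$hidden)$f
}

#' @export
print.mlp <- function(x, ...) {
  cat(sprintf("LM-trained MLP: %d-%d-1, %d epochs, val MSE %.4f\n",
              x$d, x$hidden, x$epochs, x$val_mse))
  invisible(x)
}
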