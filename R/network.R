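#' Swish activation
#'
#' `A(x) = x / (1 + exp(-beta x))`; smooth everywhere, near-linear around 0
#' for moderate `beta`.
#'
#' @param x numeric input.
#' @param beta inverse-temperature parameter (> 0, default 3).
#' @return numeric of the same shape.
#' @export
swish <- function(x, beta = 3) {
  stopifnot(beta > 0)
  x / (1 + exp(-beta * x))
}

swish_deriv <- function(x, beta = 3) {
  s <- 1 / (1 + exp(-beta * x))
  s + beta * x * s * (1 - s)
}

#' Dense scalar-output network
#'
#' A fully connected network with four Swish hidden layers and a linear
#' scalar output, plus input/output standardization statistics carried with
#' the weights so trained models are portable.  Weights are He-initialized
#' from the supplied seed.
#'
#' @param n_in input width (feature count).
#' @param hidden hidden-layer widths; exactly four layers.
#' @param beta Swish inverse temperature (> 0).
#' @param seed integer seed for the weight initialization.
#' @param init weight scale multiplier (use small values for near-zero nets).
#' @return an object of class `aq_network`.
#' @export
dense_network <- function(n_in, hidden = c(64, 64, 64, 64), beta = 3,
                          seed = 1L, init = 1) {
  stopifnot(length(hidden) == 4, beta > 0)
  widths <- c(n_in, hidden, 1L)
  set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(widths) - 1)) {
    fan_in <- widths[l]
    W[[l]] <- matrix(rnorm(widths[l + 1] * fan_in, sd = init *
                             sqrt(2 / fan_in)), widths[l + 1], fan_in)
    b[[l]] <- rep(0, widths[l + 1])
  }
  structure(list(W = W, b = b, beta = beta, widths = widths,
                 x_center = rep(0, n_in), x_scale = rep(1, n_in),
                 y_center = 0, y_scale = 1),
            class = "aq_network")
}

#' Network forward pass
#'
#' Deterministic evaluation of the scalar output for one or more feature
#' vectors (rows of `X`); the stored standardization is applied to the input
#' and undone on the output.
#'
#' @param net an [dense_network()].
#' @param X numeric vector (one sample) or matrix with one sample per row.
#' @return numeric vector of outputs.
#' @export
forward_charge <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  if (ncol(X) != net$widths[1])
    stop("feature width ", ncol(X), " does not match network input width ",
         net$widths[1])
  as.numeric(cpp_nn_forward(unclass(net), X))
}

#' Reverse-mode input gradient
#'
#' Exact derivative of the scalar output with respect to every input slot,
#' obtained by back-propagation (including the standardization scaling).
#'
#' @inheritParams forward_charge
#' @return matrix of gradients, one row per sample.
#' @export
charge_input_gradient <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  if (ncol(X) != net$widths[1])
    stop("feature width ", ncol(X), " does not match network input width ",
         net$widths[1])
  cpp_nn_input_grad(unclass(net), X)
}

# batched R forward pass on standardized inputs, returning activations for
# backprop; X already standardized, rows = samples
nn_fwd_std <- function(net, Z) {
  L <- length(net$W)
  acts <- vector("list", L + 1); pres <- vector("list", L)
  acts[[1]] <- Z
  for (l in seq_len(L)) {
    P <- acts[[l]] %*% t(net$W[[l]])
    P <- sweep(P, 2, net$b[[l]], "+")
    pres[[l]] <- P
    acts[[l + 1]] <- if (l < L) swish(P, net$beta) else P
  }
  list(acts = acts, pres = pres)
}

#' Train a network on features and labels
#'
#' Minibatch Adam on the mean squared error, with standardization of inputs
#' and labels learned from the training split, a plateau learning-rate decay,
#' and early stopping as a hard cap of `epochs` epochs with restoration of
#' the best-validation weights.
#'
#' @param net an [dense_network()].
#' @param X,y training features (rows = samples) and labels.
#' @param X_val,y_val validation split used for early stopping.
#' @param epochs maximum number of epochs (default 200).
#' @param batch minibatch size.
#' @param lr initial Adam learning rate.
#' @param patience epochs without validation improvement before the learning
#'   rate is halved.
#' @param decay decoupled L2 weight decay; keeps the learned charge surface
#'   smooth, which matters for energy conservation in MD.
#' @param seed seed for shuffling.
#' @param verbose print progress.
#' @return the trained network, with a `history` attribute of per-epoch
#'   losses.
#' @export
train_network <- function(net, X, y, X_val = NULL, y_val = NULL,
                          epochs = 200, batch = 128, lr = 1e-3,
                          patience = 15, decay = 1e-4, seed = 1L,
                          verbose = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  net$x_center <- colMeans(X)
  sds <- apply(X, 2, sd)
  # floor the per-slot scale at 2% of the largest slot spread: near-constant
  # descriptors would otherwise be amplified into high-curvature input
  # directions, making the predicted charge (and hence the forces) needlessly
  # rough in configuration space
  smax <- max(sds)
  net$x_scale <- if (smax < 1e-12) rep(1, length(sds)) else
    pmax(sds, 0.02 * smax)
  net$y_center <- mean(y)
  ysd <- sd(y)
  net$y_scale <- if (!is.finite(ysd) || ysd < 1e-12) 1 else ysd
  Z <- sweep(sweep(X, 2, net$x_center), 2, net$x_scale, "/")
  t_ <- (y - net$y_center) / net$y_scale
  haveval <- !is.null(X_val)
  if (haveval) {
    Zv <- sweep(sweep(as.matrix(X_val), 2, net$x_center), 2, net$x_scale, "/")
    tv <- (as.numeric(y_val) - net$y_center) / net$y_scale
  }
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; it <- 0
  best <- Inf; bestW <- net$W; bestb <- net$b; since <- 0
  hist_tr <- hist_va <- numeric(0)
  set.seed(seed)
  n <- nrow(Z)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = batch)) {
      idx <- ord[s:min(s + batch - 1, n)]
      fw <- nn_fwd_std(net, Z[idx, , drop = FALSE])
      pred <- fw$acts[[L + 1]][, 1]
      delta <- matrix(2 * (pred - t_[idx]) / length(idx), ncol = 1)
      it <- it + 1
      for (l in L:1) {
        gW <- t(delta) %*% fw$acts[[l]]
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% net$W[[l]]) *
            swish_deriv(fw$pres[[l - 1]], net$beta)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        cor1 <- 1 - beta1^it; cor2 <- 1 - beta2^it
        net$W[[l]] <- net$W[[l]] - lr * ((mW[[l]] / cor1) /
          (sqrt(vW[[l]] / cor2) + eps) + decay * net$W[[l]])
        net$b[[l]] <- net$b[[l]] - lr * (mb[[l]] / cor1) /
          (sqrt(vb[[l]] / cor2) + eps)
      }
    }
    fw <- nn_fwd_std(net, Z)
    tr_loss <- mean((fw$acts[[L + 1]][, 1] - t_)^2)
    hist_tr <- c(hist_tr, tr_loss)
    mon <- tr_loss
    if (haveval) {
      fv <- nn_fwd_std(net, Zv)
      va_loss <- mean((fv$acts[[L + 1]][, 1] - tv)^2)
      hist_va <- c(hist_va, va_loss)
      mon <- va_loss
    }
    if (mon < best - 1e-12) {
      best <- mon; bestW <- net$W; bestb <- net$b; since <- 0
    } else {
      since <- since + 1
      if (since >= patience) { lr <- lr / 2; since <- 0 }
    }
    if (verbose && ep %% 10 == 0)
      message(sprintf("epoch %d  train %.3e  monitor %.3e  lr %.1e",
                      ep, tr_loss, mon, lr))
  }
  net$W <- bestW; net$b <- bestb
  attr(net, "history") <- list(train = hist_tr, val = hist_va)
  net
}

#' Save / load network weights
#'
#' Self-describing plain-text JSON archive: layer shapes, weights, Swish
#' `beta`, standardization statistics and the feature-layout label.  Numbers
#' are written with 17 significant digits, so a save/load round trip restores
#' every double bit-for-bit.
#'
#' @param net an [dense_network()].
#' @param path file path.
#' @param layout optional feature-layout descriptor stored in the header.
#' @export
save_network <- function(net, path, layout = NULL) {
  obj <- list(format = "aquann-dense-network", version = 1L,
              layout = layout, widths = net$widths, beta = net$beta,
              W = lapply(net$W, identity), b = net$b,
              x_center = net$x_center, x_scale = net$x_scale,
              y_center = net$y_center, y_scale = net$y_scale)
  writeLines(jsonlite::serializeJSON(obj, digits = 17), path)
  invisible(path)
}

#' @rdname save_network
#' @return `load_network` returns the restored network.
#' @export
load_network <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  net <- structure(list(W = obj$W, b = obj$b, beta = obj$beta,
                        widths = obj$widths, x_center = obj$x_center,
                        x_scale = obj$x_scale, y_center = obj$y_center,
                        y_scale = obj$y_scale),
                   class = "aq_network")
  attr(net, "layout") <- obj$layout
  net
}
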