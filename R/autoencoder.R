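#' Autoencoder architecture and training specification
#'
#' Describes the feed-forward autoencoder used to integrate stacked omics
#' features: an odd number of hidden layers (default 2000, 500, 2000) whose
#' middle layer is the bottleneck, tanh activations, a batch-normalization
#' layer after every hidden dense layer, mean-squared-error reconstruction
#' loss, and Adam optimization for a fixed number of epochs (default 32, no
#' early stopping and no validation split).
#'
#' @param hidden_sizes integer vector of hidden layer widths; must have odd
#'   length, the middle entry is the bottleneck.
#' @param activation hidden activation, `"tanh"` (default) or `"relu"`.
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param batch_norm append a batch-normalization layer after each hidden
#'   dense layer.
#' @param seed integer seed; together with the data it determines the
#'   trained weights (per device).
#' @return a list of class `ae_spec`.
#' @export
ae_spec <- function(hidden_sizes = c(2000L, 500L, 2000L),
                    activation = c("tanh", "relu"),
                    epochs = 32L, batch_size = 32L, learning_rate = 1e-3,
                    batch_norm = TRUE, seed = 1L) {
  activation <- match.arg(activation)
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) %% 2 != 1)
    stop("ae_spec: need an odd number of hidden layers (middle = bottleneck)")
  if (any(hidden_sizes < 1)) stop("ae_spec: hidden sizes must be positive")
  if (epochs < 1) stop("ae_spec: epochs must be >= 1")
  if (batch_size < 1) stop("ae_spec: batch_size must be >= 1")
  if (learning_rate <= 0) stop("ae_spec: learning_rate must be positive")
  structure(list(hidden_sizes = hidden_sizes, activation = activation,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 batch_norm = isTRUE(batch_norm), seed = as.integer(seed)),
            class = "ae_spec")
}

glorot_init <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

act_fun <- function(name) {
  switch(name,
         tanh = list(f = tanh, grad = function(a) 1 - a * a),
         relu = list(f = function(z) pmax(z, 0),
                     grad = function(a) (a > 0) * 1))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# forward through all hidden layers; each hidden block is
# dense -> activation -> batch norm (the normalization layer is appended
# after the hidden layer, so the layer's own activation h is the
# representation and the normalized value y feeds the next layer).
# training=TRUE uses batch statistics and updates the running mean/var.
ae_forward <- function(par, x, activation, batch_norm, training) {
  act <- act_fun(activation)
  L <- length(par$W) - 1L
  a <- x
  cache <- vector("list", L)
  for (l in seq_len(L)) {
    z <- a %*% par$W[[l]] + rep(par$b[[l]], each = nrow(a))
    h <- act$f(z)
    if (batch_norm) {
      if (training) {
        mu <- colMeans(h)
        hc <- sweep(h, 2, mu)
        va <- colMeans(hc * hc)
        par$rmean[[l]] <- BN_MOMENTUM * par$rmean[[l]] + (1 - BN_MOMENTUM) * mu
        par$rvar[[l]] <- BN_MOMENTUM * par$rvar[[l]] + (1 - BN_MOMENTUM) * va
      } else {
        mu <- par$rmean[[l]]
        va <- par$rvar[[l]]
        hc <- sweep(h, 2, mu)
      }
      s <- sqrt(va + BN_EPS)
      xhat <- sweep(hc, 2, s, "/")
      y <- sweep(sweep(xhat, 2, par$gamma[[l]], "*"), 2, par$beta[[l]], "+")
    } else {
      xhat <- NULL
      s <- NULL
      y <- h
    }
    cache[[l]] <- list(a_prev = a, h = h, xhat = xhat, s = s)
    a <- y
  }
  xrec <- a %*% par$W[[L + 1L]] + rep(par$b[[L + 1L]], each = nrow(a))
  list(par = par, xrec = xrec, cache = cache, top = a)
}

ae_backward <- function(par, x, fw, activation, batch_norm) {
  act <- act_fun(activation)
  L <- length(par$W) - 1L
  nb <- nrow(x)
  g <- list(W = vector("list", L + 1L), b = vector("list", L + 1L),
            gamma = vector("list", L), beta = vector("list", L))
  dxrec <- 2 * (fw$xrec - x) / (nb * ncol(x))
  g$W[[L + 1L]] <- crossprod(fw$top, dxrec)
  g$b[[L + 1L]] <- colSums(dxrec)
  da <- tcrossprod(dxrec, par$W[[L + 1L]])   # grad wrt the block output y
  for (l in rev(seq_len(L))) {
    cc <- fw$cache[[l]]
    if (batch_norm) {
      dy <- da
      xhat <- cc$xhat
      g$gamma[[l]] <- colSums(dy * xhat)
      g$beta[[l]] <- colSums(dy)
      gam_s <- par$gamma[[l]] / cc$s
      dh <- sweep(dy, 2, colMeans(dy)) -
        xhat * rep(colMeans(dy * xhat), each = nb)
      dh <- sweep(dh, 2, gam_s, "*")
    } else {
      dh <- da
    }
    dz <- dh * act$grad(cc$h)
    g$W[[l]] <- crossprod(cc$a_prev, dz)
    g$b[[l]] <- colSums(dz)
    if (l > 1) da <- tcrossprod(dz, par$W[[l]])
  }
  g
}

adam_step <- function(par, g, state, lr, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  # bias correction folded into the step size (same update, fewer passes);
  # the C kernel updates parameters and moments in place
  lr_t <- lr * sqrt(1 - b2^t) / (1 - b1^t)
  for (slot in names(g)) {
    for (l in seq_along(g[[slot]])) {
      gr <- g[[slot]][[l]]
      if (is.null(gr)) next
      .Call(C_adam_update, par[[slot]][[l]], state$m[[slot]][[l]],
            state$v[[slot]][[l]], gr, b1, b2, lr_t, eps)
    }
  }
  list(par = par, state = state)
}

#' Train the multiomics autoencoder
#'
#' Fits a symmetric feed-forward autoencoder (input -> hidden layers ->
#' output of input width) by minibatch Adam on the mean-squared
#' reconstruction error. Hidden layers wider than the input are shrunk to
#' the input width with a warning, preserving a strictly narrower
#' bottleneck where possible. Training is deterministic given
#' `spec$seed` on one device.
#'
#' @param x an `omics_matrix` (or numeric matrix), samples x features, no
#'   missing values.
#' @param spec an [ae_spec()].
#' @return a list of class `trained_autoencoder` with the weights, the
#'   per-epoch training `history`, the (possibly shrunk) layer sizes and
#'   the training feature ids.
#' @export
train_autoencoder <- function(x, spec = ae_spec()) {
  stopifnot(inherits(spec, "ae_spec"))
  v <- if (inherits(x, "omics_matrix")) as_bare_matrix(x) else x
  if (!is.matrix(v) || !is.numeric(v)) stop("x must be a numeric matrix")
  if (nrow(v) < 2) stop("need at least 2 samples")
  if (anyNA(v) || any(!is.finite(v))) stop("non-finite values in input")
  p <- ncol(v)
  hs <- spec$hidden_sizes
  if (any(hs > p)) {
    hs <- pmin(hs, p)
    warning(sprintf("hidden sizes shrunk to input width %d", p))
  }
  sizes <- c(p, hs, p)
  L <- length(hs)
  set.seed(spec$seed)
  par <- list(W = vector("list", L + 1L), b = vector("list", L + 1L),
              gamma = vector("list", L), beta = vector("list", L),
              rmean = vector("list", L), rvar = vector("list", L))
  for (l in seq_len(L + 1L)) {
    par$W[[l]] <- glorot_init(sizes[l], sizes[l + 1L])
    par$b[[l]] <- numeric(sizes[l + 1L])
  }
  for (l in seq_len(L)) {
    par$gamma[[l]] <- rep(1, sizes[l + 1L])
    par$beta[[l]] <- numeric(sizes[l + 1L])
    par$rmean[[l]] <- numeric(sizes[l + 1L])
    par$rvar[[l]] <- rep(1, sizes[l + 1L])
  }
  zero_like <- function(slots) lapply(slots, function(s)
    lapply(par[[s]], function(z) z * 0))
  state <- list(m = zero_like(c("W", "b", "gamma", "beta")),
                v = zero_like(c("W", "b", "gamma", "beta")))
  names(state$m) <- names(state$v) <- c("W", "b", "gamma", "beta")

  n <- nrow(v)
  history <- numeric(spec$epochs)
  t_step <- 0L
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = spec$batch_size)
    ep_loss <- 0
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + spec$batch_size - 1L, n)]
      xb <- v[idx, , drop = FALSE]
      fw <- ae_forward(par, xb, spec$activation, spec$batch_norm,
                       training = TRUE)
      par <- fw$par
      ep_loss <- ep_loss + sum((xb - fw$xrec)^2)
      g <- ae_backward(par, xb, fw, spec$activation, spec$batch_norm)
      t_step <- t_step + 1L
      upd <- adam_step(par, g, state, spec$learning_rate, t_step)
      par <- upd$par
      state <- upd$state
    }
    history[ep] <- ep_loss / (n * p)
  }
  structure(list(spec = spec, par = par, history = history,
                 sizes = sizes, hidden_sizes = hs,
                 feature_ids = colnames(v)),
            class = "trained_autoencoder")
}

#' @export
print.trained_autoencoder <- function(x, ...) {
  cat(sprintf("autoencoder %s, %d epochs, final MSE %.4g\n",
              paste(x$sizes, collapse = "-"), length(x$history),
              x$history[length(x$history)]))
  invisible(x)
}

check_ae_features <- function(model, v) {
  if (is.null(colnames(v)) || !identical(colnames(v), model$feature_ids)) {
    missing <- setdiff(model$feature_ids, colnames(v))
    extra <- setdiff(colnames(v), model$feature_ids)
    stop(sprintf(paste0("feature mismatch with training input ",
                        "(%d missing: %s...; %d extra: %s...)"),
                 length(missing), paste(utils::head(missing, 3),
                                        collapse = ","),
                 length(extra), paste(utils::head(extra, 3),
                                      collapse = ",")))
  }
}

#' Encode samples to the bottleneck representation
#'
#' Deterministic forward pass to the middle hidden layer, with
#' batch-normalization layers in inference mode (running statistics).
#' The representation is the middle layer's own activation — taken
#' before that layer's appended batch-normalization — so tanh networks
#' yield features strictly inside (-1, 1).
#'
#' @param model a `trained_autoencoder`.
#' @param x matrix with exactly the training features, in order.
#' @return numeric matrix, samples x bottleneck width, with bottleneck
#'   feature names `BN001...`.
#' @export
encode <- function(model, x) {
  v <- if (inherits(x, "omics_matrix")) as_bare_matrix(x) else x
  check_ae_features(model, v)
  act <- act_fun(model$spec$activation)
  L <- length(model$hidden_sizes)
  mid <- (L + 1L) %/% 2L
  a <- v
  for (l in seq_len(mid)) {
    z <- a %*% model$par$W[[l]] + rep(model$par$b[[l]], each = nrow(a))
    h <- act$f(z)
    if (l == mid) {
      a <- h
      break
    }
    if (model$spec$batch_norm) {
      s <- sqrt(model$par$rvar[[l]] + BN_EPS)
      h <- sweep(sweep(h, 2, model$par$rmean[[l]]), 2, s, "/")
      h <- sweep(sweep(h, 2, model$par$gamma[[l]], "*"), 2,
                 model$par$beta[[l]], "+")
    }
    a <- h
  }
  colnames(a) <- sprintf("BN%03d", seq_len(ncol(a)))
  rownames(a) <- rownames(v)
  a
}

#' Reconstruct inputs through the trained autoencoder
#'
#' Full inference-mode forward pass; useful for inspecting reconstruction
#' error on held-out or permuted data.
#'
#' @inheritParams encode
#' @return reconstructed matrix of the same shape as `x`.
#' @export
ae_reconstruct <- function(model, x) {
  v <- if (inherits(x, "omics_matrix")) as_bare_matrix(x) else x
  check_ae_features(model, v)
  fw <- ae_forward(model$par, v, model$spec$activation,
                   model$spec$batch_norm, training = FALSE)
  out <- fw$xrec
  dimnames(out) <- dimnames(v)
  out
}
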