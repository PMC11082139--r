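# Minimal fully-connected softmax network with an SGD + Nesterov momentum
# trainer. This is the learnable part of every desk-scale backbone in the
# package (domain classifier, task classifier). Training follows the recipe
# used for the monitored grading model: cross-entropy loss, Nesterov
# momentum, multiplicative learning-rate decay per epoch, flip augmentation,
# and final-model selection by validation loss.
#
# Inputs are pooled pixel features (see features.R); standardization
# statistics are estimated on the training fold and stored in the model.

relu <- function(x) x * (x > 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_init <- function(d_in, hidden, d_out, seed) {
  sizes <- c(d_in, hidden, d_out)
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                    sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

# Forward pass; returns activations for backprop.
mlp_forward <- function(par, x) {
  L <- length(par$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- x
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    acts[[l + 1L]] <- if (l < L) relu(z) else z
  }
  acts
}

# Mean cross-entropy of logits vs integer labels in 1..C.
xent_loss <- function(logits, y) {
  p <- softmax_rows(logits)
  -mean(log(pmax(p[cbind(seq_along(y), y)], 1e-12)))
}

mlp_gradients <- function(par, acts, y) {
  L <- length(par$W)
  n <- nrow(acts[[1L]])
  p <- softmax_rows(acts[[L + 1L]])
  delta <- p
  delta[cbind(seq_len(n), y)] <- delta[cbind(seq_len(n), y)] - 1
  delta <- delta / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(par$W[[l]])) * (acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

#' Train a small fully-connected softmax network
#'
#' Stochastic gradient descent with Nesterov momentum, multiplicative
#' learning-rate decay per epoch, optional minibatch augmentation, and
#' selection of the final weights by validation loss. Deterministic given
#' the seed.
#'
#' @param x n x d training feature matrix.
#' @param y Integer class labels in `1..n_classes`.
#' @param n_classes Number of output classes.
#' @param hidden Integer vector of hidden-layer widths (may be empty for a
#'   linear softmax model).
#' @param epochs Training epochs (default 30).
#' @param batch Minibatch size (default 32).
#' @param lr Initial learning rate (default 0.1; the desk-scale networks are
#'   tiny, so the rate is larger than what full-size vision backbones use).
#' @param momentum Nesterov momentum coefficient (default 0.9).
#' @param lr_decay Multiplicative decay applied to the learning rate after
#'   every epoch (default 0.9).
#' @param weight_decay L2 penalty coefficient (default 1e-4).
#' @param val One of: `NULL` (hold out `val_frac` of the rows for
#'   validation), or a list `list(x=, y=)` with an explicit validation set.
#' @param val_frac Fraction held out when `val` is NULL (default 0.1).
#' @param augment Optional function applied to each minibatch's feature rows
#'   (e.g. `augment_flips` for pooled image features).
#' @param seed Integer seed.
#' @return Object of class `fs_mlp` with weights, standardization stats and
#'   the validation-loss trajectory.
#' @keywords internal
mlp_train <- function(x, y, n_classes, hidden = 16L, epochs = 30L,
                      batch = 32L, lr = 0.1, momentum = 0.9, lr_decay = 0.9,
                      weight_decay = 1e-4, val = NULL, val_frac = 0.1,
                      augment = NULL, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y), all(y %in% seq_len(n_classes)))
  ctr <- colMeans(x)
  scl <- pmax(apply(x, 2, stats::sd), 1e-8)
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  seeds <- derive_seeds(seed, 3L)
  if (is.null(val)) {
    n <- nrow(xs)
    ord <- with_seed(seeds[1L], sample.int(n))
    n_val <- max(1L, floor(val_frac * n))
    vi <- ord[seq_len(n_val)]; ti <- ord[-seq_len(n_val)]
    xv <- xs[vi, , drop = FALSE]; yv <- y[vi]
    xt <- xs[ti, , drop = FALSE]; yt <- y[ti]
  } else {
    xv <- sweep(sweep(val$x, 2, ctr), 2, scl, "/"); yv <- val$y
    xt <- xs; yt <- y
  }

  par <- mlp_init(ncol(x), hidden, n_classes, seeds[2L])
  vel <- lapply(par, function(g) lapply(g, function(m) m * 0))
  best <- list(loss = Inf, par = par, epoch = 0L)
  traj <- numeric(epochs)
  n_tr <- nrow(xt)

  with_seed(seeds[3L], {
    rate <- lr
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_tr)
      for (start in seq(1L, n_tr, by = batch)) {
        bi <- ord[start:min(start + batch - 1L, n_tr)]
        xb <- xt[bi, , drop = FALSE]
        if (!is.null(augment)) xb <- augment(xb)
        # Nesterov: evaluate the gradient at the look-ahead point
        look <- par
        for (l in seq_along(par$W)) {
          look$W[[l]] <- par$W[[l]] + momentum * vel$W[[l]]
          look$b[[l]] <- par$b[[l]] + momentum * vel$b[[l]]
        }
        acts <- mlp_forward(look, xb)
        gr <- mlp_gradients(look, acts, yt[bi])
        for (l in seq_along(par$W)) {
          gW <- gr$W[[l]] + weight_decay * par$W[[l]]
          vel$W[[l]] <- momentum * vel$W[[l]] - rate * gW
          par$W[[l]] <- par$W[[l]] + vel$W[[l]]
          vel$b[[l]] <- momentum * vel$b[[l]] - rate * gr$b[[l]]
          par$b[[l]] <- par$b[[l]] + vel$b[[l]]
        }
      }
      vl <- xent_loss(mlp_forward(par, xv)[[length(par$W) + 1L]], yv)
      traj[ep] <- vl
      if (vl < best$loss) best <- list(loss = vl, par = par, epoch = ep)
      rate <- rate * lr_decay
    }
  })

  structure(list(par = best$par, center = ctr, scale = scl,
                 n_classes = n_classes, hidden = hidden,
                 val_loss = traj, best_epoch = best$epoch, seed = seed),
            class = "fs_mlp")
}

# Logits (pre-softmax) in evaluation mode.
mlp_logits <- function(model, x) {
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  mlp_forward(model$par, xs)[[length(model$par$W) + 1L]]
}

mlp_softmax <- function(model, x) softmax_rows(mlp_logits(model, x))
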