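# Internal neural-network machinery: convolution via im2col + GEMM (BLAS),
# fused batch-norm + ReLU kernels in C++, softmax cross-entropy and the
# full backward pass. Feature maps are (N*H*W) x C matrices, rows ordered
# batch-major, then image row, then image column (see src/kernels.cpp).
# Conv stages carry no additive bias: batch normalization directly follows
# each convolution and absorbs any constant shift.

conv_out_dim <- function(d, k = 3L, stride = 2L, pad = 1L) {
  (d + 2L * pad - k) %/% stride + 1L
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# Forward pass through the encoder. X0: (N*H*W) x 3 in [0, 1].
# Returns per-position class scores ((N*Ho*Wo) x K) plus caches for the
# backward pass when `training`.
nn_forward <- function(model, X0, N, H, W, training = FALSE, drop_p = 0) {
  X <- X0; h <- H; w <- W
  caches <- vector("list", 3L)
  for (l in 1:3) {
    layer <- model$layers[[l]]
    P <- .im2col_nhwc(X, N, h, w, 3L, 2L, 1L)
    A <- P %*% layer$W
    bn <- .bn_relu_forward(A, layer$gamma, layer$beta, layer$rmean,
                           layer$rvar, model$bn_eps, model$bn_momentum,
                           training)
    if (training) {
      model$layers[[l]]$rmean <- bn$rmean
      model$layers[[l]]$rvar <- bn$rvar
    }
    caches[[l]] <- list(P = P, xhat = bn$xhat, invstd = bn$invstd,
                        y = bn$y, in_dims = c(h, w))
    X <- bn$y
    h <- conv_out_dim(h); w <- conv_out_dim(w)
  }
  drop_mask <- NULL
  if (training && drop_p > 0) {
    drop_mask <- (matrix(stats::runif(length(X)), nrow(X)) >= drop_p) /
      (1 - drop_p)
    X <- X * drop_mask
  }
  head <- model$layers$head
  Z <- add_bias(X %*% head$W, head$b)
  list(Z = Z, feat = X, caches = caches, drop_mask = drop_mask,
       out_dims = c(h, w), N = N, model = model)
}

# Numerically stable row-softmax.
row_softmax <- function(Z) {
  m <- Z - apply(Z, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# Weighted multinomial cross-entropy on annotated positions and the full
# backward pass. y: 0-based labels (sentinel = excluded), length nrow(Z).
nn_loss_grad <- function(model, fw, y, class_w) {
  Z <- fw$Z
  valid <- which(y != unannotated_id())
  if (length(valid) == 0L) stop("batch contains no annotated positions")
  Zv <- Z[valid, , drop = FALSE]
  p <- row_softmax(Zv)
  yv <- y[valid]
  w <- class_w[yv + 1L]
  picked <- p[cbind(seq_along(valid), yv + 1L)]
  loss <- -sum(w * log(pmax(picked, 1e-12))) / sum(w)
  acc <- mean(max.col(p, ties.method = "first") == yv + 1L)

  dZv <- p
  dZv[cbind(seq_along(valid), yv + 1L)] <-
    dZv[cbind(seq_along(valid), yv + 1L)] - 1
  dZv <- dZv * (w / sum(w))
  dZ <- matrix(0, nrow(Z), ncol(Z))
  dZ[valid, ] <- dZv

  grads <- nn_backward(model, fw, dZ)
  list(loss = loss, acc = acc, grads = grads)
}

nn_backward <- function(model, fw, dZ) {
  head <- model$layers$head
  # grads mirrors model$layers positionally: conv stages 1..3, then head
  grads <- vector("list", 4L)
  names(grads) <- c("", "", "", "head")
  grads[[4L]] <- list(W = crossprod(fw$feat, dZ), b = colSums(dZ))
  dX <- tcrossprod(dZ, head$W)
  if (!is.null(fw$drop_mask)) dX <- dX * fw$drop_mask
  for (l in 3:1) {
    cache <- fw$caches[[l]]
    layer <- model$layers[[l]]
    bnb <- .bn_relu_backward(dX, cache$y, cache$xhat, cache$invstd,
                             layer$gamma)
    dA <- bnb$dx
    grads[[l]] <- list(
      W = crossprod(cache$P, dA),
      gamma = bnb$dgamma,
      beta = bnb$dbeta
    )
    if (l > 1L) {
      dP <- tcrossprod(dA, layer$W)
      dX <- .col2im_nhwc(dP, fw$N, cache$in_dims[1], cache$in_dims[2],
                         nrow(layer$W) %/% 9L, 3L, 2L, 1L)
    }
  }
  grads
}

# Convert an H x W x 3 byte-or-unit array into the row-major feature matrix.
image_to_matrix <- function(px) {
  d <- dim(px)
  x <- if (is.integer(px)) px / 255 else px
  matrix(aperm(x, c(2, 1, 3)), d[1] * d[2], 3L)
}

# Row-major label vector matching the network's output ordering.
labels_to_vector <- function(lab) as.integer(t(lab))

vector_to_matrix <- function(v, h, w) t(matrix(v, w, h))
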