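#' Training configuration
#'
#' Hyperparameters for [train_model()]. The learning rate adapts within
#' `[lr_min, lr_max]` (defaults 5e-7 and 5e-4) by a plateau rule: training
#' starts at `lr_max` and the rate is halved whenever the loss has not
#' improved for `patience` steps, never dropping below `lr_min`. Momentum
#' SGD is used (0.9 by default; 0.99 is the other supported setting).
#' Dropout on the last feature map is bounded to `[0, 0.1]`. One "epoch"
#' is one optimizer step on a freshly sampled batch.
#'
#' @param patch_size Training patch size `(w, h)` in pixels; recorded for
#'   provenance (tiles are prepared upstream, e.g. by the synthetic
#'   generator or [extract_patches()]).
#' @param batch_size Tiles per optimizer step.
#' @param lr_min,lr_max Learning-rate bounds (positive, `lr_min <= lr_max`).
#' @param momentum SGD momentum in `(0, 1)`.
#' @param dropout Dropout probability in `[0, 0.1]`.
#' @param epochs Number of optimizer steps.
#' @param augmentations Character subset of `"flip"`, `"rot90"`,
#'   `"brightness"`, `"saturation"`.
#' @param class_balancing Use inverse-frequency class weights in the loss.
#' @param seed Integer seed governing sampling, augmentation and dropout.
#' @param val_fraction Fraction of tiles held out for accuracy monitoring.
#' @param val_every Steps between validation evaluations (the last value is
#'   carried forward in the history between evaluations).
#' @param patience Plateau patience in steps.
#' @param lr_factor Multiplicative LR decay on plateau.
#' @return A `train_config` object.
#' @export
train_config <- function(patch_size = c(512L, 1024L),
                         batch_size = 8L,
                         lr_min = 5e-7, lr_max = 5e-4,
                         momentum = 0.9,
                         dropout = 0,
                         epochs = 500L,
                         augmentations = c("flip", "rot90", "brightness",
                                           "saturation"),
                         class_balancing = TRUE,
                         seed = 1L,
                         val_fraction = 0.1,
                         val_every = 10L,
                         patience = 25L,
                         lr_factor = 0.5) {
  if (lr_min <= 0 || lr_max <= 0 || lr_min > lr_max) {
    stop("need 0 < lr_min <= lr_max")
  }
  if (momentum <= 0 || momentum >= 1) stop("momentum must be in (0, 1)")
  if (dropout < 0 || dropout > 0.1) stop("dropout must be in [0, 0.1]")
  if (epochs < 1L) stop("epochs must be positive")
  structure(
    list(patch_size = as.integer(rep_len(patch_size, 2L)),
         batch_size = as.integer(batch_size),
         lr_min = lr_min, lr_max = lr_max, momentum = momentum,
         dropout = dropout, epochs = as.integer(epochs),
         augmentations = augmentations,
         class_balancing = isTRUE(class_balancing),
         seed = as.integer(seed),
         val_fraction = val_fraction, val_every = as.integer(val_every),
         patience = as.integer(patience), lr_factor = lr_factor),
    class = "train_config"
  )
}

#' Train the encoder-only segmentation network
#'
#' Optimises pixel-wise multinomial cross-entropy on the annotated
#' positions of the 8x output grid. Full-resolution ground-truth masks are
#' majority-downsampled to the output grid first (see [downsample_mask()]);
#' positions carrying the unannotated sentinel contribute nothing to the
#' loss. With `class_balancing` the loss weights each class by damped
#' inverse pixel frequency, countering the extreme rarity of classes such
#' as regenerating epithelium. Each step samples a fresh batch, applies
#' the configured random transforms (flips, right-angle rotations, mild
#' brightness/saturation jitter), and takes one momentum-SGD step with the
#' plateau-adapted learning rate. Seeded and reproducible up to
#' floating-point associativity.
#'
#' @param model A `seg_model` from [build_model()].
#' @param dataset A list of records with `image` (a [section_image()]) and
#'   `mask` (a [label_mask()], full resolution or already at the output
#'   grid). All tiles must share the same dimensions, divisible by 8.
#' @param cfg A [train_config()].
#' @return A list with `model` (trained) and `history` (a data frame with
#'   one row per step: `step`, `loss`, `train_acc`, `val_acc`, `lr`).
#' @export
train_model <- function(model, dataset, cfg = train_config()) {
  stopifnot(inherits(model, "seg_model"))
  if (length(dataset) == 0L) stop("empty dataset")
  schema <- model$schema
  K <- model$class_count

  items <- lapply(dataset, function(rec) {
    img <- rec$image$pixels
    msk <- rec$mask
    d <- dim(img)[1:2]
    if (any(d %% 8L != 0L)) stop("tile dimensions must be divisible by 8")
    g8 <- if (msk$downsample_factor == 1L) {
      downsample_mask(msk, 8L, schema)$labels
    } else {
      msk$labels
    }
    list(x = img / 255, y = g8)
  })
  dims <- dim(items[[1]]$x)[1:2]
  if (!all(vapply(items, function(it) identical(dim(it$x)[1:2], dims),
                  logical(1)))) {
    stop("all training tiles must share the same dimensions")
  }

  all_y <- unlist(lapply(items, function(it) it$y))
  all_y <- all_y[all_y != unannotated_id()]
  if (length(all_y) == 0L) stop("dataset has no annotated pixels")
  if (length(unique(all_y)) == 1L) {
    warning("dataset contains a single class; the model cannot discriminate")
  }
  class_w <- rep(1, K)
  if (cfg$class_balancing) {
    counts <- tabulate(all_y + 1L, nbins = K)
    present <- counts > 0L
    w <- rep(1, K)
    w[present] <- sqrt(sum(counts) / (sum(present) * counts[present]))
    w <- pmin(pmax(w, 0.2), 10)
    class_w <- w / mean(w[present])
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(cfg$seed)

  n <- length(items)
  n_val <- if (n >= 2L) max(1L, floor(cfg$val_fraction * n)) else 0L
  val_idx <- if (n_val > 0L) (n - n_val + 1L):n else 1L
  train_idx <- if (n_val > 0L) seq_len(n - n_val) else 1L

  velocity <- init_velocity(model$layers)
  lr <- cfg$lr_max
  best_loss <- Inf
  last_improve <- 0L
  hist <- data.frame(step = seq_len(cfg$epochs), loss = NA_real_,
                     train_acc = NA_real_, val_acc = NA_real_, lr = NA_real_)
  last_val <- NA_real_

  for (step in seq_len(cfg$epochs)) {
    idx <- sample(train_idx, cfg$batch_size,
                  replace = length(train_idx) < cfg$batch_size)
    batch <- lapply(items[idx], augment_tile, ops = cfg$augmentations)
    X0 <- do.call(rbind, lapply(batch, function(b) image_to_matrix(b$x)))
    y <- unlist(lapply(batch, function(b) labels_to_vector(b$y)))

    fw <- nn_forward(model, X0, length(batch), dims[1], dims[2],
                     training = TRUE, drop_p = cfg$dropout)
    model <- fw$model
    lg <- nn_loss_grad(model, fw, y, class_w)

    upd <- sgd_update(model$layers, velocity, lg$grads, lr, cfg$momentum)
    model$layers <- upd$layers
    velocity <- upd$velocity

    if (lg$loss < best_loss - 1e-4) {
      best_loss <- lg$loss
      last_improve <- step
    } else if (step - last_improve >= cfg$patience) {
      lr <- max(cfg$lr_min, lr * cfg$lr_factor)
      last_improve <- step
    }

    if (n_val > 0L && (step %% cfg$val_every == 0L || step == cfg$epochs)) {
      last_val <- eval_accuracy(model, items[val_idx], dims)
    }
    hist$loss[step] <- lg$loss
    hist$train_acc[step] <- lg$acc
    hist$val_acc[step] <- last_val
    hist$lr[step] <- lr
  }
  model$trained <- TRUE
  list(model = model, history = hist)
}

init_velocity <- function(layers) {
  lapply(layers, function(l) lapply(l[intersect(names(l),
                                                c("W", "b", "gamma", "beta"))],
                                    function(p) p * 0))
}

sgd_update <- function(layers, velocity, grads, lr, momentum) {
  for (l in seq_along(layers)) {
    g <- grads[[l]]
    if (is.null(g)) next
    for (p in names(g)) {
      velocity[[l]][[p]] <- momentum * velocity[[l]][[p]] - lr * g[[p]]
      layers[[l]][[p]] <- layers[[l]][[p]] + velocity[[l]][[p]]
    }
  }
  list(layers = layers, velocity = velocity)
}

# Pixel accuracy of argmax predictions on held-out tiles, at the 8x grid.
eval_accuracy <- function(model, val_items, dims) {
  correct <- 0L; total <- 0L
  for (it in val_items) {
    fw <- nn_forward(model, image_to_matrix(it$x), 1L, dims[1], dims[2],
                     training = FALSE)
    pred <- max.col(fw$Z, ties.method = "first") - 1L
    y <- labels_to_vector(it$y)
    valid <- y != unannotated_id()
    correct <- correct + sum(pred[valid] == y[valid])
    total <- total + sum(valid)
  }
  if (total == 0L) return(NA_real_)
  correct / total
}

# Random transforms applied jointly to an image tile (values in [0, 1])
# and its output-grid label matrix. Flips and right-angle rotations
# commute with 8x8 blocks, so the coarse labels transform alongside.
augment_tile <- function(item, ops) {
  x <- item$x; y <- item$y
  if ("flip" %in% ops) {
    if (stats::runif(1) < 0.5) {
      x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
      y <- y[, rev(seq_len(ncol(y))), drop = FALSE]
    }
    if (stats::runif(1) < 0.5) {
      x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
      y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
    }
  }
  if ("rot90" %in% ops && dim(x)[1] == dim(x)[2]) {
    k <- sample(0:3, 1L)
    for (i in seq_len(k)) {
      x <- aperm(x, c(2, 1, 3))[rev(seq_len(dim(x)[2])), , , drop = FALSE]
      y <- t(y)[rev(seq_len(ncol(y))), , drop = FALSE]
    }
  }
  if ("brightness" %in% ops) {
    x[] <- pmin(1, pmax(0, x * stats::runif(1, 0.9, 1.1)))
  }
  if ("saturation" %in% ops) {
    s <- stats::runif(1, 0.8, 1.2)
    gray <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
    for (ch in 1:3) x[, , ch] <- pmin(1, pmax(0, gray + s * (x[, , ch] - gray)))
  }
  list(x = x, y = y)
}
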