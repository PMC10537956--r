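#' Build the encoder-only segmentation network
#'
#' Constructs the descending half of a U-Net: three stacked blocks of
#' 3x3 convolution (stride 2), batch normalization and ReLU, followed by a
#' 1x1 projection to K class score channels. No decoder or upsampling
#' layers are included, so the per-position class scores sit on a grid
#' eight times coarser than the input — an input of 512 x 1024 yields a
#' 64 x 128 x K score grid. Weights use seeded He initialisation.
#'
#' @param schema A [class_schema()]; K = `n_classes(schema)` (>= 2).
#' @param width_multiplier Scales the stage channel widths (default stages
#'   16, 32, 64).
#' @param base_widths Integer channel widths of the three stages.
#' @param seed Integer seed for weight initialisation.
#' @return A `seg_model` handle: network parameters (opaque), the bound
#'   schema, stage widths and `output_stride = 8`.
#' @export
build_model <- function(schema = default_class_schema(),
                        width_multiplier = 1,
                        base_widths = c(16L, 32L, 64L),
                        seed = 1L) {
  K <- n_classes(schema)
  if (K < 2L) stop("need at least 2 classes")
  widths <- pmax(2L, as.integer(round(base_widths * width_multiplier)))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  make_conv <- function(cin, cout) {
    fan_in <- 9L * cin
    # no conv bias: batch norm follows immediately and absorbs it
    list(
      W = matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                 fan_in, cout),
      gamma = rep(1, cout),
      beta = rep(0, cout),
      rmean = rep(0, cout),
      rvar = rep(1, cout)
    )
  }
  layers <- list(
    make_conv(3L, widths[1]),
    make_conv(widths[1], widths[2]),
    make_conv(widths[2], widths[3]),
    head = list(
      W = matrix(stats::rnorm(widths[3] * K, sd = sqrt(2 / widths[3])),
                 widths[3], K),
      b = rep(0, K)
    )
  )
  structure(
    list(schema = schema, class_count = K, output_stride = 8L,
         depth = 3L, widths = widths, layers = layers,
         bn_eps = 1e-5, bn_momentum = 0.1, trained = FALSE),
    class = "seg_model"
  )
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf(
    "seg_model: encoder-only, stride %dx, widths %s -> %d classes, %s\n",
    x$output_stride, paste(x$widths, collapse = "/"), x$class_count,
    if (x$trained) "trained" else "untrained"))
  cat("parameters:", count_params(x), "\n")
  invisible(x)
}

#' Number of trainable parameters in a model
#'
#' @param model A `seg_model`.
#' @return Integer parameter count (weights, biases, BN scale/shift).
#' @export
count_params <- function(model) {
  sum(vapply(model$layers, function(l) {
    length(l$W) + length(l$b) +
      (if (!is.null(l$gamma)) length(l$gamma) + length(l$beta) else 0L)
  }, numeric(1)))
}

#' Per-position class probabilities for one image
#'
#' Runs the encoder in inference mode (batch-norm running statistics) and
#' returns softmax-normalised class probabilities on the 8x output grid.
#' Exposed mainly for score inspection; use [predict_mask()] for labels.
#'
#' @param model A trained `seg_model`.
#' @param image A [section_image()] with height and width divisible by 8.
#' @return An `(H/8) x (W/8) x K` array of probabilities summing to 1 over
#'   the class axis.
#' @export
predict_scores <- function(model, image) {
  d <- dim(image)
  if (any(d %% 8L != 0L)) stop("image dimensions must be divisible by 8")
  if (dim(image$pixels)[3] != 3L) stop("expected a 3-channel image")
  X0 <- image_to_matrix(image$pixels)
  fw <- nn_forward(model, X0, 1L, d[1], d[2], training = FALSE)
  p <- row_softmax(fw$Z)
  ho <- fw$out_dims[1]; wo <- fw$out_dims[2]
  out <- array(0, c(ho, wo, model$class_count))
  for (k in seq_len(model$class_count)) {
    out[, , k] <- vector_to_matrix(p[, k], ho, wo)
  }
  out
}

#' Predict an 8x-downsampled label mask for a section
#'
#' Processes the section tile-wise (edge tiles are clipped and padded by
#' edge replication up to a multiple of 8, then cropped back), accumulates
#' class probabilities on the global 8x grid — overlapping tile regions are
#' averaged — and assigns each position the argmax class, ties broken by
#' the lowest class id. Deterministic given the model state.
#'
#' @param model A trained `seg_model`.
#' @param image A [section_image()].
#' @param tile_size Processing tile edge in pixels (multiple of 8).
#' @param overlap Tile overlap in pixels (multiple of 8, < `tile_size`).
#' @return A [label_mask()] with `downsample_factor = 8` covering
#'   `ceiling(H/8) x ceiling(W/8)` positions.
#' @export
predict_mask <- function(model, image, tile_size = 256L, overlap = 0L) {
  stopifnot(inherits(model, "seg_model"), inherits(image, "section_image"))
  if (dim(image$pixels)[3] != 3L) stop("expected a 3-channel image")
  if (tile_size %% 8L != 0L || overlap %% 8L != 0L) {
    stop("tile_size and overlap must be multiples of 8")
  }
  if (overlap >= tile_size) stop("overlap must be smaller than tile_size")
  d <- dim(image)
  K <- model$class_count
  ho <- ceiling(d[1] / 8L); wo <- ceiling(d[2] / 8L)
  acc <- array(0, c(ho, wo, K))
  cnt <- matrix(0, ho, wo)
  stride <- tile_size - overlap
  g <- patch_grid(d[2], d[1], tile_size, stride, policy = "clip")
  for (i in seq_len(nrow(g))) {
    rows <- (g$y[i] + 1L):(g$y[i] + g$h[i])
    cols <- (g$x[i] + 1L):(g$x[i] + g$w[i])
    tile <- image$pixels[rows, cols, , drop = FALSE]
    h8 <- ceiling(g$h[i] / 8L) * 8L
    w8 <- ceiling(g$w[i] / 8L) * 8L
    if (h8 > g$h[i] || w8 > g$w[i]) {       # pad by edge replication
      tile <- tile[c(seq_len(g$h[i]), rep(g$h[i], h8 - g$h[i])),
                   c(seq_len(g$w[i]), rep(g$w[i], w8 - g$w[i])), ,
                   drop = FALSE]
    }
    fw <- nn_forward(model, image_to_matrix(tile), 1L, h8, w8,
                     training = FALSE)
    p <- row_softmax(fw$Z)
    tho <- ceiling(g$h[i] / 8L); two <- ceiling(g$w[i] / 8L)
    oi <- g$y[i] %/% 8L; oj <- g$x[i] %/% 8L
    for (k in seq_len(K)) {
      pk <- vector_to_matrix(p[, k], h8 %/% 8L, w8 %/% 8L)
      acc[oi + seq_len(tho), oj + seq_len(two), k] <-
        acc[oi + seq_len(tho), oj + seq_len(two), k] +
        pk[seq_len(tho), seq_len(two), drop = FALSE]
    }
    cnt[oi + seq_len(tho), oj + seq_len(two)] <-
      cnt[oi + seq_len(tho), oj + seq_len(two)] + 1
  }
  flat <- matrix(acc, ho * wo, K)
  lab <- matrix(max.col(flat, ties.method = "first") - 1L, ho, wo)
  label_mask(lab, downsample_factor = 8L, origin = image$origin)
}

#' Nearest-neighbour upsampling of a label mask
#'
#' Replicates every label over a `factor x factor` block, bridging the 8x
#' network output back to full-resolution quantification. Class pixel
#' proportions are preserved exactly. Note that upsampling a
#' majority-downsampled mask does not recover the original mask: block
#' majority discards within-block detail.
#'
#' @param mask A [label_mask()].
#' @param factor Positive integer replication factor; must divide the
#'   mask's `downsample_factor`.
#' @return A [label_mask()] with `downsample_factor` divided by `factor`.
#' @export
upsample_mask <- function(mask, factor = 8L) {
  if (factor != as.integer(factor) || factor < 1L) {
    stop("factor must be a positive integer")
  }
  factor <- as.integer(factor)
  if (mask$downsample_factor %% factor != 0L) {
    stop("factor must divide the mask's downsample_factor")
  }
  lab <- mask$labels
  out <- lab[rep(seq_len(nrow(lab)), each = factor),
             rep(seq_len(ncol(lab)), each = factor), drop = FALSE]
  label_mask(out, mask$downsample_factor %/% factor, mask$origin)
}

#' Majority-vote downsampling of a label mask
#'
#' Collapses each `factor x factor` block to the majority class among its
#' annotated pixels (ties to the lowest class id). Blocks where fewer than
#' half the pixels are annotated become [unannotated_id()], preserving
#' sparse-annotation semantics at the coarse grid.
#'
#' @param mask A full-resolution [label_mask()] with dimensions divisible
#'   by `factor`.
#' @param factor Block edge (default 8, the network output stride).
#' @param schema A [class_schema()].
#' @return A [label_mask()] with `downsample_factor = factor`.
#' @export
downsample_mask <- function(mask, factor = 8L,
                            schema = default_class_schema()) {
  if (mask$downsample_factor != 1L) {
    stop("mask is already downsampled")
  }
  d <- dim(mask)
  if (any(d %% factor != 0L)) {
    stop("mask dimensions must be divisible by the factor")
  }
  lab <- .block_majority(mask$labels, as.integer(factor),
                         n_classes(schema), unannotated_id())
  label_mask(lab, as.integer(factor), mask$origin)
}

#' Save or load a model checkpoint
#'
#' The checkpoint is an RDS file of the full parameter state plus a JSON
#' metadata sidecar (class names, stage widths, output stride, parameter
#' count) so checkpoints remain inspectable without loading them.
#'
#' @param model A `seg_model`.
#' @param path Checkpoint path (`.rds`); the sidecar is `path` + `.json`.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored `seg_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(classes = model$schema$name, widths = model$widths,
         output_stride = model$output_stride,
         parameters = count_params(model), trained = model$trained),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "seg_model"))
  model
}
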