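#' Regular patch grid over a section
#'
#' Computes the patch footprints of a regular grid with the given size and
#' stride. Coordinates are 0-based and half-open: a patch at `(x, y)` with
#' width `w` covers columns `[x, x + w)`. With `policy = "clip"` edge
#' patches are shrunk so every pixel is covered exactly once when
#' `stride == size` (the convention used for quantification and heatmaps);
#' with `policy = "drop_partial"` incomplete edge patches are dropped (an
#' option for training).
#'
#' @param width,height Section size in pixels.
#' @param size Patch size, a single value or `(w, h)`.
#' @param stride Grid stride, a single value or `(sx, sy)`; defaults to
#'   `size`.
#' @param policy `"clip"` or `"drop_partial"`.
#' @return A data frame with columns `x`, `y`, `w`, `h`.
#' @examples
#' nrow(patch_grid(1024, 1024, 512))            # 4 patches
#' patch_grid(1000, 1000, 512)$w                # edge patches of 488 px
#' @export
patch_grid <- function(width, height, size, stride = size,
                       policy = c("clip", "drop_partial")) {
  policy <- match.arg(policy)
  size <- rep_len(as.integer(size), 2L)
  stride <- rep_len(as.integer(stride), 2L)
  if (any(stride <= 0L)) stop("stride must be positive")
  if (any(size <= 0L)) stop("patch size must be positive")
  if (width < 1L || height < 1L) stop("empty image")
  xs <- seq.int(0L, width - 1L, by = stride[1])
  ys <- seq.int(0L, height - 1L, by = stride[2])
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  g$w <- pmin(size[1], width - g$x)
  g$h <- pmin(size[2], height - g$y)
  if (policy == "drop_partial") {
    g <- g[g$w == size[1] & g$h == size[2], , drop = FALSE]
    rownames(g) <- NULL
  }
  g
}

#' Extract aligned image/mask patches
#'
#' Cuts a section image and its full-resolution mask into spatially aligned
#' patches on a regular stride grid. Patch origins are recorded so patches
#' can be traced back to parent-section coordinates.
#'
#' @param image A [section_image()].
#' @param mask A [label_mask()] with `downsample_factor = 1` on the same
#'   grid, or `NULL` for image-only extraction.
#' @param size Patch size `(w, h)` in pixels.
#' @param stride Grid stride `(sx, sy)`; defaults to `size`.
#' @param policy Edge policy, see [patch_grid()].
#' @return A list of records, each with `image`, `mask` (or `NULL`) and
#'   the patch footprint `x`, `y`, `w`, `h`.
#' @export
extract_patches <- function(image, mask = NULL, size, stride = size,
                            policy = c("clip", "drop_partial")) {
  policy <- match.arg(policy)
  d <- dim(image)
  if (!is.null(mask)) {
    if (mask$downsample_factor != 1L) {
      stop("patch extraction needs a full-resolution mask")
    }
    if (!identical(dim(mask), d)) stop("image and mask grids differ")
  }
  g <- patch_grid(d[2], d[1], size, stride, policy)
  lapply(seq_len(nrow(g)), function(i) {
    rows <- (g$y[i] + 1L):(g$y[i] + g$h[i])
    cols <- (g$x[i] + 1L):(g$x[i] + g$w[i])
    rec <- list(
      image = section_image(image$pixels[rows, cols, , drop = FALSE],
                            image$microns_per_pixel,
                            origin = image$origin + c(g$x[i], g$y[i])),
      mask = NULL,
      x = g$x[i], y = g$y[i], w = g$w[i], h = g$h[i]
    )
    if (!is.null(mask)) {
      rec$mask <- label_mask(mask$labels[rows, cols, drop = FALSE], 1L,
                             origin = mask$origin + c(g$x[i], g$y[i]))
    }
    rec
  })
}
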