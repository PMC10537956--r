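#' Section image and label mask containers
#'
#' A `section_image` holds an RGB raster of a (portion of a) histology
#' section: an H x W x 3 integer array of byte values, the physical scale in
#' microns per pixel, and the 0-based `(x, y)` origin of the raster within
#' its parent section. A `label_mask` holds the matching integer class
#' labels, either at full resolution (`downsample_factor = 1`, ground truth)
#' or on the 8x-coarser network output grid (`downsample_factor = 8`).
#'
#' Pixel coordinates are 0-based throughout the package and pixel intervals
#' are half-open: pixel `x` covers `[x, x + 1)`.
#'
#' @param pixels H x W x 3 numeric array of byte values (0..255).
#' @param microns_per_pixel Physical scale, microns per pixel (> 0).
#' @param origin Integer `(x, y)` offset in parent-section pixels.
#' @return A `section_image` object.
#' @export
section_image <- function(pixels, microns_per_pixel = 0.504,
                          origin = c(0L, 0L)) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (any(dim(pixels)[1:2] < 1L)) stop("image dimensions must be >= 1")
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("microns_per_pixel must be positive")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, microns_per_pixel = microns_per_pixel,
         origin = as.integer(origin)),
    class = "section_image"
  )
}

#' @rdname section_image
#' @param labels H x W integer matrix of class ids (plus possibly the
#'   [unannotated_id()] sentinel).
#' @param downsample_factor 1 for ground truth, 8 for network output.
#' @export
label_mask <- function(labels, downsample_factor = 1L, origin = c(0L, 0L)) {
  stopifnot(is.matrix(labels))
  if (!downsample_factor %in% c(1L, 8L)) {
    stop("downsample_factor must be 1 or 8")
  }
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, downsample_factor = as.integer(downsample_factor),
         origin = as.integer(origin)),
    class = "label_mask"
  )
}

#' @export
dim.section_image <- function(x) dim(x$pixels)[1:2]

#' @export
dim.label_mask <- function(x) dim(x$labels)

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("section_image: %d x %d px, %.3f um/px, origin (%d, %d)\n",
              d[2], d[1], x$microns_per_pixel, x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("label_mask: %d x %d positions, downsample %dx, origin (%d, %d)\n",
              d[2], d[1], x$downsample_factor, x$origin[1], x$origin[2]))
  tab <- table(x$labels)
  cat("labels:", paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                       collapse = " "), "\n")
  invisible(x)
}

#' Check that a mask only uses ids defined in a schema
#'
#' @param mask A [label_mask()].
#' @param schema A [class_schema()].
#' @param allow_unannotated Accept the [unannotated_id()] sentinel.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_mask <- function(mask, schema, allow_unannotated = TRUE) {
  ids <- unique(as.vector(mask$labels))
  ok <- ids %in% schema$id | (allow_unannotated & ids == unannotated_id())
  if (!all(ok)) {
    stop("mask contains ids not in schema: ",
         paste(ids[!ok], collapse = ", "))
  }
  invisible(TRUE)
}

#' Read and write section images and label masks
#'
#' Images are written as RGB PNG or TIFF (by file extension); masks as
#' single-channel 8-bit rasters. Both round-trip bit-identically for byte
#' data. The physical scale and origin are not stored in the raster; pass
#' them on read if they matter downstream.
#'
#' @param image A [section_image()].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return Writers return `path` invisibly; readers return the object.
#' @export
write_section_image <- function(image, path) {
  arr <- image$pixels / 255
  write_raster(arr, path)
}

#' @rdname write_section_image
#' @param microns_per_pixel,origin Metadata to attach on read.
#' @export
read_section_image <- function(path, microns_per_pixel = 0.504,
                               origin = c(0L, 0L)) {
  arr <- read_raster(path)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  section_image(round(arr * 255), microns_per_pixel, origin)
}

#' @rdname write_section_image
#' @param mask A [label_mask()]; ids must fit in a byte.
#' @export
write_label_mask <- function(mask, path) {
  if (any(mask$labels < 0L | mask$labels > 255L)) {
    stop("mask ids must fit in one byte to be written as 8-bit raster")
  }
  write_raster(mask$labels / 255, path)
}

#' @rdname write_section_image
#' @param downsample_factor Factor to attach on read (1 or 8).
#' @export
read_label_mask <- function(path, downsample_factor = 1L,
                            origin = c(0L, 0L)) {
  arr <- read_raster(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  label_mask(matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr)),
             downsample_factor, origin)
}

write_raster <- function(arr, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else {
    stop("unsupported raster extension: ", ext)
  }
  invisible(path)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported raster extension: ", ext)
  }
}

#' Render a label mask as an RGB overlay image
#'
#' Paints every mask position with its class colour from the schema;
#' unannotated positions are painted mid-grey.
#'
#' @param mask A [label_mask()].
#' @param schema A [class_schema()].
#' @return A [section_image()] at the mask's grid resolution.
#' @export
colorize_mask <- function(mask, schema) {
  pal <- schema_palette(schema)
  lab <- mask$labels
  idx <- match(as.vector(lab), schema$id)
  h <- nrow(lab); w <- ncol(lab)
  px <- array(128L, c(h, w, 3L))
  ok <- !is.na(idx)
  for (ch in 1:3) {
    plane <- matrix(128L, h, w)
    plane[ok] <- pal[idx[ok], ch]
    px[, , ch] <- plane
  }
  section_image(px, microns_per_pixel = 0.504 * mask$downsample_factor,
                origin = mask$origin)
}
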