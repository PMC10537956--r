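#' Per-class pixel areas of a label mask
#'
#' Counts mask positions per class. For masks on the 8x output grid, counts
#' are scaled by `downsample_factor^2` when `full_res_equivalent` so areas
#' are comparable to full-resolution masks. Unannotated sentinel positions
#' are excluded.
#'
#' @param mask A [label_mask()].
#' @param schema A [class_schema()].
#' @param full_res_equivalent Scale counts to full-resolution pixels.
#' @return Named numeric vector of pixel counts, one entry per class.
#' @export
class_areas <- function(mask, schema = default_class_schema(),
                        full_res_equivalent = TRUE) {
  validate_mask(mask, schema)
  lab <- as.vector(mask$labels)
  lab <- lab[lab != unannotated_id()]
  counts <- tabulate(lab + 1L, nbins = n_classes(schema))
  if (full_res_equivalent) counts <- counts * mask$downsample_factor^2
  names(counts) <- schema$name
  counts
}

#' CNN-style injury score of a section
#'
#' All classified positions except background are summed as the kidney
#' surface; each class is expressed as a percentage of that surface, and
#' the score is the combined percentage of the configured pathological
#' score classes — by default intratubular casts and tubular necrosis
#' (regenerating epithelium is quantified but excluded from the score, its
#' segmentation being too unreliable to contribute). A fully healthy
#' section scores 0.
#'
#' @param mask A [label_mask()] (full resolution or 8x grid; the score is
#'   identical under nearest-neighbour upsampling).
#' @param schema A [class_schema()].
#' @param score_classes Integer ids forming the score; must be a subset of
#'   the schema's pathological ids.
#' @return An `injury_score` object: `per_class_pixels`,
#'   `kidney_surface_pixels`, `per_class_percent` (non-background classes,
#'   summing to 100), and `score_percent`.
#' @examples
#' m <- label_mask(matrix(c(rep(3L, 80), rep(7L, 15), rep(8L, 5)), 10, 10))
#' injury_score(m)$score_percent  # 20
#' @export
injury_score <- function(mask, schema = default_class_schema(),
                         score_classes = default_score_classes(schema)) {
  if (!all(score_classes %in% pathological_ids(schema))) {
    stop("score_classes must be pathological class ids")
  }
  counts <- class_areas(mask, schema, full_res_equivalent = TRUE)
  nb <- schema$role != "background"
  surface <- sum(counts[nb])
  if (surface == 0) {
    stop("mask contains no non-background pixels; injury score undefined")
  }
  percent <- counts[nb] / surface * 100
  score <- sum(percent[schema$id[nb] %in% score_classes])
  structure(
    list(per_class_pixels = counts,
         kidney_surface_pixels = surface,
         per_class_percent = percent,
         score_percent = score,
         score_class_ids = as.integer(score_classes)),
    class = "injury_score"
  )
}

#' Default score classes: casts and necrosis
#'
#' @param schema A [class_schema()].
#' @return Integer ids of intratubular casts and tubular necrosis.
#' @export
default_score_classes <- function(schema = default_class_schema()) {
  class_id(schema, c("intratubular casts", "tubular necrosis"))
}

#' @export
print.injury_score <- function(x, ...) {
  cat(sprintf("injury_score: %.2f%% of %d kidney-surface pixels\n",
              x$score_percent, x$kidney_surface_pixels))
  pc <- x$per_class_percent
  for (nm in names(pc)) cat(sprintf("  %-32s %8.3f%%\n", nm, pc[nm]))
  invisible(x)
}

#' @export
as.data.frame.injury_score <- function(x, ...) {
  data.frame(class = names(x$per_class_pixels),
             pixels = as.numeric(x$per_class_pixels),
             percent_of_surface = c(NA_real_,
                                    as.numeric(x$per_class_percent)),
             row.names = NULL)
}

#' Grid heatmap of one pathological class
#'
#' Overlays a grid of patches (default 512 x 512 full-resolution pixels,
#' clip edge policy so every position is counted once) and computes, per
#' patch, the percentage of the whole patch area occupied by the class.
#' Note the denominator: the full patch including background, matching the
#' rendering convention of injury heatmaps — unlike the injury score,
#' whose denominator is the non-background surface.
#'
#' @param mask A [label_mask()]; `patch_size` must be a multiple of its
#'   `downsample_factor`.
#' @param schema A [class_schema()].
#' @param class_ids Integer id(s) of the class(es) quantified per patch
#'   (multiple ids are summed).
#' @param patch_size Patch edge in full-resolution pixels (>= 8).
#' @return A `heatmap_grid`: a data frame with patch footprints (`x`, `y`,
#'   `w`, `h`, full-resolution pixels), `pixels` (patch area) and
#'   `percent`, with the class and patch size as attributes.
#' @export
injury_heatmap <- function(mask, schema = default_class_schema(),
                           class_ids = default_score_classes(schema),
                           patch_size = 512L) {
  if (patch_size < 8L) stop("patch_size must be >= 8")
  if (!all(class_ids %in% schema$id)) stop("unknown class id")
  f <- mask$downsample_factor
  if (patch_size %% f != 0L) {
    stop("patch_size must be a multiple of the mask's downsample factor")
  }
  step <- patch_size %/% f
  d <- dim(mask)
  g <- patch_grid(d[2], d[1], step, policy = "clip")
  hit <- matrix(mask$labels %in% class_ids, d[1], d[2])
  pix <- integer(nrow(g)); cls <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    rows <- (g$y[i] + 1L):(g$y[i] + g$h[i])
    cols <- (g$x[i] + 1L):(g$x[i] + g$w[i])
    pix[i] <- g$w[i] * g$h[i]
    cls[i] <- sum(hit[rows, cols])
  }
  out <- data.frame(x = g$x * f, y = g$y * f, w = g$w * f, h = g$h * f,
                    pixels = pix * f^2, class_pixels = cls * f^2,
                    percent = 100 * cls / pix)
  structure(out, class = c("heatmap_grid", "data.frame"),
            class_ids = as.integer(class_ids), patch_size = patch_size,
            downsample_factor = f)
}

#' Continuous blue-to-red heatmap colormap
#'
#' Maps `t = 0` to deep blue and `t = 1` to red with a monotone hue sweep,
#' the palette used for injury heatmaps.
#'
#' @param t Numeric vector in `[0, 1]`.
#' @return A `length(t) x 3` matrix of RGB bytes.
#' @export
heatmap_colormap <- function(t) {
  t <- pmin(1, pmax(0, t))
  hue <- (2 / 3) * (1 - t)          # 240 deg (blue) down to 0 deg (red)
  val <- 0.70 + 0.30 * t            # deep blue at 0, bright red at 1
  cols <- grDevices::hsv(hue, s = 1, v = val)
  m <- t(grDevices::col2rgb(cols))
  colnames(m) <- c("r", "g", "b")
  m
}

#' Render a heatmap grid as an image
#'
#' Paints every patch with the blue-to-red colormap at its percentage
#' (0% deep blue, 100% red) on a reduced-scale canvas.
#'
#' @param grid A `heatmap_grid` from [injury_heatmap()].
#' @param cell_px Rendered edge length of a full patch, in output pixels.
#' @return A [section_image()] of the rendered heatmap.
#' @export
render_heatmap <- function(grid, cell_px = 16L) {
  if (nrow(grid) == 0L) stop("empty heatmap grid")
  ps <- attr(grid, "patch_size")
  scale <- cell_px / ps
  wout <- ceiling((max(grid$x + grid$w)) * scale)
  hout <- ceiling((max(grid$y + grid$h)) * scale)
  img <- array(0L, c(hout, wout, 3L))
  cols <- heatmap_colormap(grid$percent / 100)
  for (i in seq_len(nrow(grid))) {
    r0 <- floor(grid$y[i] * scale) + 1L
    r1 <- min(hout, ceiling((grid$y[i] + grid$h[i]) * scale))
    c0 <- floor(grid$x[i] * scale) + 1L
    c1 <- min(wout, ceiling((grid$x[i] + grid$w[i]) * scale))
    for (ch in 1:3) img[r0:r1, c0:c1, ch] <- cols[i, ch]
  }
  section_image(img, microns_per_pixel = 0.504 / scale)
}

#' Write a heatmap as PNG plus JSON sidecar
#'
#' The sidecar records the quantified class ids, patch size, colormap
#' endpoints and the per-patch percentages, so the rendering stays
#' interpretable.
#'
#' @param grid A `heatmap_grid`.
#' @param path Output PNG path; the sidecar is `path` + `.json`.
#' @param cell_px Rendered patch edge, see [render_heatmap()].
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(grid, path, cell_px = 16L) {
  img <- render_heatmap(grid, cell_px)
  write_section_image(img, path)
  jsonlite::write_json(
    list(class_ids = attr(grid, "class_ids"),
         patch_size = attr(grid, "patch_size"),
         colormap = list(`0` = "deep blue", `100` = "red"),
         patches = as.data.frame(grid)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-section scores and per-patch percentages as CSV
#'
#' @param score An [injury_score()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_csv <- function(score, path) {
  df <- as.data.frame(score)
  df$score_percent <- score$score_percent
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
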