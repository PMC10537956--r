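#' Polygon annotation sets
#'
#' An `annotation_set` holds manually drawn ground-truth regions: closed
#' polygons in 0-based full-resolution pixel coordinates, each carrying a
#' class id. Annotation is sparse — regions cover only part of a section —
#' so rasterization marks unannotated pixels with the [unannotated_id()]
#' sentinel rather than the background class.
#'
#' @param regions A list of records, each a list with `polygon` (an n x 2
#'   numeric matrix of x, y vertices, n >= 3, not necessarily repeated at
#'   the end) and `class_id` (integer).
#' @param schema Optional [class_schema()] to validate class ids against.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(regions, schema = NULL) {
  if (length(regions) == 0L) stop("empty annotation set")
  regions <- lapply(regions, function(r) {
    poly <- as.matrix(r$polygon)
    if (ncol(poly) != 2L || nrow(poly) < 3L) {
      stop("polygons need at least 3 (x, y) vertices")
    }
    # drop an explicitly repeated closing vertex
    n <- nrow(poly)
    if (all(poly[1, ] == poly[n, ]) && n > 3L) poly <- poly[-n, , drop = FALSE]
    if (!is.null(schema) && !(r$class_id %in% schema$id)) {
      stop("invalid class id in annotation: ", r$class_id)
    }
    list(polygon = poly, class_id = as.integer(r$class_id))
  })
  structure(list(regions = regions), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cls <- vapply(x$regions, `[[`, integer(1), "class_id")
  cat("annotation_set:", length(x$regions), "regions over",
      length(unique(cls)), "classes\n")
  invisible(x)
}

#' Rasterize polygon annotations to a sparse label mask
#'
#' Pixels whose centre falls inside a polygon (even-odd rule) receive the
#' polygon's class id; pixels covered by no polygon receive the
#' [unannotated_id()] sentinel. Where polygons overlap, later-listed
#' regions win. Polygons extending beyond the raster are clipped.
#'
#' @param ann An [annotation_set()].
#' @param width,height Output raster size in pixels.
#' @param schema A [class_schema()] used to validate ids.
#' @return A [label_mask()] with `downsample_factor = 1`.
#' @export
rasterize_annotations <- function(ann, width, height,
                                  schema = default_class_schema()) {
  stopifnot(inherits(ann, "annotation_set"))
  lab <- matrix(unannotated_id(), height, width)
  for (r in ann$regions) {
    if (!(r$class_id %in% schema$id)) {
      stop("invalid class id in annotation: ", r$class_id)
    }
    poly <- r$polygon
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    j0 <- max(1L, floor(xr[1]) + 1L); j1 <- min(width, ceiling(xr[2]))
    i0 <- max(1L, floor(yr[1]) + 1L); i1 <- min(height, ceiling(yr[2]))
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    px <- rep(jj - 0.5, each = length(ii))
    py <- rep(ii - 0.5, times = length(jj))
    inside <- point_in_polygon(px, py, poly)
    if (any(inside)) {
      block <- lab[ii, jj, drop = FALSE]
      block[matrix(inside, length(ii), length(jj))] <- r$class_id
      lab[ii, jj] <- block
    }
  }
  label_mask(lab, 1L)
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Balance annotation counts across classes
#'
#' Classes with more regions than `target_per_class` are randomly
#' subsampled down to the target (seeded, reproducible); classes with fewer
#' are kept in full. This mirrors the practice of balancing training
#' annotations to a common median count per class. Relative region order is
#' preserved so overlap precedence is unchanged.
#'
#' @param ann An [annotation_set()].
#' @param target_per_class Target region count per class (>= 1).
#' @param seed Integer RNG seed for the subsampling.
#' @return A balanced [annotation_set()].
#' @examples
#' # 10 classes with >= 288 regions each balance to 2880 regions in total
#' @export
balance_annotations <- function(ann, target_per_class = 288L, seed = 1L) {
  stopifnot(inherits(ann, "annotation_set"))
  if (target_per_class < 1L) stop("target_per_class must be >= 1")
  cls <- vapply(ann$regions, `[[`, integer(1), "class_id")
  keep <- logical(length(cls))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  for (k in sort(unique(cls))) {
    idx <- which(cls == k)
    if (length(idx) > target_per_class) {
      idx <- sort(sample(idx, target_per_class))
    }
    keep[idx] <- TRUE
  }
  annotation_set(ann$regions[keep])
}

#' Read and write annotations as GeoJSON
#'
#' Annotations interchange as a GeoJSON `FeatureCollection` of `Polygon`
#' features in pixel coordinates, each with a `class_name` (and `class_id`)
#' property resolved against the schema.
#'
#' @param ann An [annotation_set()].
#' @param path Output `.geojson`/`.json` path.
#' @param schema A [class_schema()].
#' @return `write_annotations_geojson()` returns `path` invisibly;
#'   `read_annotations_geojson()` returns an [annotation_set()].
#' @export
write_annotations_geojson <- function(ann, path,
                                      schema = default_class_schema()) {
  feats <- lapply(ann$regions, function(r) {
    poly <- rbind(r$polygon, r$polygon[1, ])  # GeoJSON rings are closed
    list(
      type = "Feature",
      properties = list(
        class_id = r$class_id,
        class_name = schema$name[match(r$class_id, schema$id)]
      ),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(poly)),
                                  function(i) c(poly[i, 1], poly[i, 2])))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations_geojson
#' @export
read_annotations_geojson <- function(path, schema = default_class_schema()) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  regions <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop("only Polygon features are supported")
    }
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    cid <- f$properties$class_id
    if (is.null(cid)) cid <- class_id(schema, f$properties$class_name)
    list(polygon = poly, class_id = as.integer(cid))
  })
  annotation_set(regions, schema)
}
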