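#' Annotation class schema
#'
#' A `class_schema` describes the label classes used throughout the package:
#' integer ids (contiguous from 0), human-readable names, a biological role
#' (`background`, `healthy` or `pathological`) and an RGB overlay colour.
#' Exactly one class must carry the `background` role and it must be id 0.
#'
#' @param classes A data frame with columns `id` (non-negative integer),
#'   `name` (character), `role` (one of `"background"`, `"healthy"`,
#'   `"pathological"`), and `r`, `g`, `b` (integers in 0..255).
#' @return An object of class `class_schema` (a validated data frame).
#' @seealso [default_class_schema()]
#' @export
class_schema <- function(classes) {
  stopifnot(is.data.frame(classes))
  required <- c("id", "name", "role", "r", "g", "b")
  missing <- setdiff(required, names(classes))
  if (length(missing) > 0L) {
    stop("schema is missing columns: ", paste(missing, collapse = ", "))
  }
  classes <- as.data.frame(classes)[required]
  classes$id <- as.integer(classes$id)
  classes$name <- as.character(classes$name)
  classes$role <- as.character(classes$role)
  for (ch in c("r", "g", "b")) classes[[ch]] <- as.integer(classes[[ch]])
  classes <- classes[order(classes$id), , drop = FALSE]
  rownames(classes) <- NULL
  validate_schema(classes)
  structure(classes, class = c("class_schema", "data.frame"))
}

validate_schema <- function(classes) {
  k <- nrow(classes)
  if (k < 2L) stop("a schema needs at least two classes")
  if (!identical(classes$id, seq_len(k) - 1L)) {
    stop("class ids must be unique and contiguous starting at 0")
  }
  if (anyDuplicated(classes$name)) stop("class names must be unique")
  if (!all(classes$role %in% c("background", "healthy", "pathological"))) {
    stop("roles must be background, healthy or pathological")
  }
  bg <- which(classes$role == "background")
  if (length(bg) != 1L || classes$id[bg] != 0L) {
    stop("exactly one class must have role 'background' and it must be id 0")
  }
  rgb_ok <- vapply(c("r", "g", "b"), function(ch) {
    all(classes[[ch]] >= 0L & classes[[ch]] <= 255L)
  }, logical(1))
  if (!all(rgb_ok)) stop("colour channels must be bytes in 0..255")
  invisible(classes)
}

#' The ten-class kidney IRI annotation schema
#'
#' The default schema covers the structures annotated in PAS-stained mouse
#' kidney sections after ischaemia-reperfusion injury: the slide background,
#' six healthy renal structures, and the three pathological changes of acute
#' IRI (intratubular casts, tubular necrosis, regenerating epithelium).
#' Colours are the overlay palette used when rendering masks.
#'
#' @return A [class_schema()] with 10 classes, ids 0..9.
#' @examples
#' sch <- default_class_schema()
#' pathological_ids(sch)
#' @export
default_class_schema <- function() {
  class_schema(data.frame(
    id = 0:9,
    name = c(
      "background",
      "adipose tissue",
      "glomeruli",
      "proximal tubules",
      "distal tubules/collecting ducts",
      "stroma",
      "transitional epithelium",
      "intratubular casts",
      "tubular necrosis",
      "regenerating epithelium"
    ),
    role = c(
      "background",
      "healthy", "healthy", "healthy", "healthy", "healthy", "healthy",
      "pathological", "pathological", "pathological"
    ),
    r = c(248, 228, 196, 226, 238, 210, 160, 190, 170, 120),
    g = c(247, 224, 120, 140, 180, 200, 120,  40, 150, 150),
    b = c(245, 230, 170, 150, 190, 220, 180,  80, 130, 200)
  ))
}

#' Sentinel id for unannotated pixels
#'
#' Sparse ground truth labels only the annotated regions; every other pixel
#' carries this sentinel (255), which is distinct from the background class
#' (id 0) and is excluded from training loss and evaluation counts.
#'
#' @return The integer 255.
#' @export
unannotated_id <- function() 255L

#' @rdname schema-accessors
#' @title Schema accessors
#' @description Convenience accessors for a [class_schema()]:
#'   `n_classes()` the number of classes K, `background_id()` the background
#'   class id, `pathological_ids()` / `healthy_ids()` the ids with the
#'   respective role, `class_id()` id lookup by name, and `schema_palette()`
#'   the K x 3 colour matrix.
#' @param schema A [class_schema()].
#' @export
n_classes <- function(schema) nrow(schema)

#' @rdname schema-accessors
#' @export
background_id <- function(schema) schema$id[schema$role == "background"]

#' @rdname schema-accessors
#' @export
pathological_ids <- function(schema) schema$id[schema$role == "pathological"]

#' @rdname schema-accessors
#' @export
healthy_ids <- function(schema) schema$id[schema$role == "healthy"]

#' @rdname schema-accessors
#' @param name Character vector of class names.
#' @export
class_id <- function(schema, name) {
  idx <- match(name, schema$name)
  if (anyNA(idx)) {
    stop("unknown class name(s): ", paste(name[is.na(idx)], collapse = ", "))
  }
  schema$id[idx]
}

#' @rdname schema-accessors
#' @export
schema_palette <- function(schema) {
  m <- as.matrix(schema[, c("r", "g", "b")])
  rownames(m) <- schema$name
  m
}

#' Read or write a class schema as JSON
#'
#' The sidecar format stores one record per class with fields `id`, `name`,
#' `role` and `color` (RGB byte triple), so masks can be interpreted by
#' other tools.
#'
#' @param schema A [class_schema()].
#' @param path File path of the JSON sidecar.
#' @return `write_class_schema()` returns `path` invisibly;
#'   `read_class_schema()` returns a [class_schema()].
#' @export
write_class_schema <- function(schema, path) {
  recs <- lapply(seq_len(nrow(schema)), function(i) {
    list(
      id = schema$id[i], name = schema$name[i], role = schema$role[i],
      color = c(schema$r[i], schema$g[i], schema$b[i])
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_class_schema
#' @export
read_class_schema <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  class_schema(data.frame(
    id = vapply(recs, function(x) as.integer(x$id), integer(1)),
    name = vapply(recs, function(x) as.character(x$name), character(1)),
    role = vapply(recs, function(x) as.character(x$role), character(1)),
    r = vapply(recs, function(x) as.integer(x$color[[1]]), integer(1)),
    g = vapply(recs, function(x) as.integer(x$color[[2]]), integer(1)),
    b = vapply(recs, function(x) as.integer(x$color[[3]]), integer(1))
  ))
}

#' @export
print.class_schema <- function(x, ...) {
  cat("Class schema with", nrow(x), "classes:\n")
  print.data.frame(x, ...)
  invisible(x)
}
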