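#' Specification for a synthetic pseudo-PAS kidney section
#'
#' Describes one synthetic section: raster size, physical scale, the target
#' area fraction of each tissue class (as a fraction of the non-background
#' kidney surface), the combined injury fraction, texture noise, and the RNG
#' seed. The generator draws a kidney-shaped silhouette on a near-white
#' slide background and fills it with stylised, chromatically separable
#' tissue textures, so segmentation models can be trained and evaluated
#' against exact ground truth.
#'
#' By default the injury budget is split equally between intratubular casts
#' and tubular necrosis, and regenerating epithelium is a rare class scaled
#' as 2% of the injury fraction (zero in healthy sections, always well under
#' 1% of the section). If `target_class_fractions` names the casts and
#' necrosis fractions explicitly, `injury_fraction` is their sum. Proximal
#' tubules absorb whatever surface is left after all other quotas, mirroring
#' their dominance in renal cortex. When the injury budget is large, the
#' named healthy fractions are scaled down proportionally so the total stays
#' below 1.
#'
#' @param width,height Raster size in pixels (>= 64 recommended).
#' @param microns_per_pixel Physical scale (default 0.504, the 20x scanner
#'   resolution of the emulated slides).
#' @param injury_fraction Combined casts + necrosis target fraction of the
#'   non-background surface, in `[0, 1]`.
#' @param target_class_fractions Optional named numeric vector of per-class
#'   target fractions (names from the schema) overriding the defaults.
#' @param texture_noise_sd Global multiplier on the per-class texture noise
#'   (1 = default appearance; 0 = flat colours).
#' @param seed Integer RNG seed; generation is fully deterministic given it.
#' @param cell_spacing Mean spacing in pixels of the tubular tessellation;
#'   `NULL` picks `max(12, min(width, height) / 48)`.
#' @return A `synthetic_section_spec` object.
#' @export
synthetic_section_spec <- function(width = 1024L, height = 1024L,
                                   microns_per_pixel = 0.504,
                                   injury_fraction = 0,
                                   target_class_fractions = NULL,
                                   texture_noise_sd = 1,
                                   seed = 1L,
                                   cell_spacing = NULL) {
  if (width < 1 || height < 1) stop("dimensions must be positive")
  if (microns_per_pixel <= 0) stop("microns_per_pixel must be positive")
  if (texture_noise_sd < 0) stop("texture_noise_sd must be non-negative")

  user <- target_class_fractions
  if (!is.null(user)) {
    if (is.null(names(user)) || any(!nzchar(names(user)))) {
      stop("target_class_fractions must be a named vector")
    }
    if (any(user < 0)) stop("target fractions must be non-negative")
  }
  casts_nm <- "intratubular casts"; necr_nm <- "tubular necrosis"
  if (!is.null(user) && all(c(casts_nm, necr_nm) %in% names(user))) {
    implied <- unname(user[casts_nm] + user[necr_nm])
    if (!missing(injury_fraction) &&
        abs(implied - injury_fraction) > 1e-8) {
      stop("injury_fraction must equal casts + necrosis target fractions")
    }
    injury_fraction <- implied
  }
  if (injury_fraction < 0 || injury_fraction > 1) {
    stop("injury_fraction must be in [0, 1]")
  }

  fr <- default_target_fractions(injury_fraction)
  if (!is.null(user)) fr[names(user)] <- user
  if (sum(fr) > 1 + 1e-8) {
    stop("non-background class fractions sum to more than 1")
  }

  if (is.null(cell_spacing)) {
    cell_spacing <- max(12L, round(min(width, height) / 48))
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         microns_per_pixel = microns_per_pixel,
         injury_fraction = injury_fraction,
         target_class_fractions = fr,
         texture_noise_sd = texture_noise_sd,
         seed = as.integer(seed),
         cell_spacing = as.integer(cell_spacing)),
    class = "synthetic_section_spec"
  )
}

# Default class quotas as fractions of the non-background kidney surface.
# Healthy quotas are scaled down when injury is heavy so the sum stays < 1;
# proximal tubules (the unnamed remainder) stay the filler class.
default_target_fractions <- function(injury_fraction) {
  regen <- 0.02 * injury_fraction
  healthy <- c(
    "glomeruli" = 0.05,
    "adipose tissue" = 0.02,
    "distal tubules/collecting ducts" = 0.20,
    "stroma" = 0.08,
    "transitional epithelium" = 0.015
  )
  available <- 1 - injury_fraction - regen
  scale <- min(1, 0.95 * available / sum(healthy))
  c(healthy * scale,
    "intratubular casts" = injury_fraction / 2,
    "tubular necrosis" = injury_fraction / 2,
    "regenerating epithelium" = regen)
}

#' Generate one synthetic kidney section with paired ground truth
#'
#' Draws a kidney-shaped foreground (an elliptical silhouette with low
#' frequency boundary wobble and a hilar notch) surrounded by near-white
#' slide background, tessellates the parenchyma into tubule-scale cells,
#' stamps glomeruli as compact round blobs, places a spatially clustered
#' injury focus for the pathological classes, and renders each class with
#' its own base colour and texture: homogeneous strongly stained lumen fills
#' for casts, fragmented debris texture for necrosis, brush-border speckle
#' for proximal tubules. The realized per-class area fraction of the
#' non-background surface tracks the spec's targets to within half a
#' tessellation cell.
#'
#' Generation is bit-deterministic given `spec$seed`; the caller's RNG
#' state is saved and restored.
#'
#' @param spec A [synthetic_section_spec()].
#' @param schema A [class_schema()]; the default ten-class kidney schema.
#' @return A list with elements `image` (a [section_image()]) and `mask`
#'   (a [label_mask()] at full resolution).
#' @examples
#' sec <- generate_section(synthetic_section_spec(256, 256, seed = 1,
#'                                                injury_fraction = 0.2))
#' table(sec$mask$labels)
#' @export
generate_section <- function(spec, schema = default_class_schema()) {
  stopifnot(inherits(spec, "synthetic_section_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  W <- spec$width; H <- spec$height
  xv <- rep(seq_len(W) - 0.5, each = H)
  yv <- rep(seq_len(H) - 0.5, times = W)

  ## --- silhouette: wobbly ellipse minus a hilar notch -------------------
  cx <- W / 2; cy <- H / 2
  a <- 0.40 * W; b <- 0.44 * H
  ph <- stats::runif(2, 0, 2 * pi)
  dxe <- (xv - cx) / a; dye <- (yv - cy) / b
  theta <- atan2(dye, dxe)
  wob <- 1 + 0.05 * sin(3 * theta + ph[1]) + 0.03 * sin(5 * theta + ph[2])
  fg <- (dxe^2 + dye^2) <= wob^2
  notch <- (((xv - (cx - 0.92 * a)) / (0.22 * a))^2 +
              ((yv - cy) / (0.24 * b))^2) <= 1
  fg <- fg & !notch
  fg_idx <- which(fg)
  n_fg <- length(fg_idx)
  if (n_fg < 100L) stop("section too small for a kidney silhouette")

  lab <- rep(0L, H * W)          # background id 0
  lab[fg_idx] <- -1L             # unassigned parenchyma
  rid <- rep(0L, H * W)          # region id map (for membrane rendering)

  quotas <- round(spec$target_class_fractions * n_fg)

  ## --- glomeruli: compact round blobs ----------------------------------
  glom_id <- class_id(schema, "glomeruli")
  q_glom <- quotas[["glomeruli"]]
  r_g <- max(4, round(0.018 * min(W, H)))
  placed <- 0L; tries <- 0L; disk_n <- 0L
  while (placed < q_glom - ceiling(pi * r_g^2 / 2) && tries < 500L) {
    tries <- tries + 1L
    ctr <- fg_idx[sample.int(n_fg, 1L)]
    ci <- ((ctr - 1L) %% H) + 1L; cj <- ((ctr - 1L) %/% H) + 1L
    rr <- r_g
    if (q_glom - placed < pi * r_g^2) {
      rr <- max(2, floor(sqrt((q_glom - placed) / pi)))
    }
    ii <- max(1L, ci - rr):min(H, ci + rr)
    jj <- max(1L, cj - rr):min(W, cj + rr)
    di <- outer(ii - ci, jj - cj, function(u, v) u^2 + v^2)
    pick <- which(di <= rr^2)
    cand <- as.vector(outer(ii, (jj - 1L) * H, `+`))[pick]
    cand <- cand[lab[cand] == -1L]
    if (length(cand) < 0.6 * pi * rr^2) next   # overlaps edge or other blob
    lab[cand] <- glom_id
    disk_n <- disk_n + 1L
    rid[cand] <- 1000000L + disk_n
    placed <- placed + length(cand)
  }

  ## --- tubular tessellation (jittered-grid Voronoi) ---------------------
  s <- spec$cell_spacing
  gu <- ceiling(W / s); gv <- ceiling(H / s)
  sx <- matrix((seq_len(gu) - 0.5) * s, gu, gv) +
    matrix(stats::runif(gu * gv, -0.38 * s, 0.38 * s), gu, gv)
  sy <- matrix(rep((seq_len(gv) - 0.5) * s, each = gu), gu, gv) +
    matrix(stats::runif(gu * gv, -0.38 * s, 0.38 * s), gu, gv)
  cu <- pmin(gu, pmax(1L, ceiling(xv / s)))
  cv <- pmin(gv, pmax(1L, ceiling(yv / s)))
  best_d <- rep(Inf, H * W); cell <- integer(H * W)
  for (du in -1:1) {
    nu <- pmin(gu, pmax(1L, cu + du))
    for (dv in -1:1) {
      nv <- pmin(gv, pmax(1L, cv + dv))
      k <- (nv - 1L) * gu + nu
      d2 <- (xv - sx[k])^2 + (yv - sy[k])^2
      upd <- d2 < best_d
      best_d[upd] <- d2[upd]
      cell[upd] <- k[upd]
    }
  }
  free <- fg_idx[lab[fg_idx] == -1L]
  rid[free] <- cell[free]
  cells <- split(free, cell[free])
  cell_sizes <- lengths(cells)

  ## --- quota assignment over cells --------------------------------------
  assign_cells <- function(order_idx, quota, id) {
    got <- 0L
    for (ci in order_idx) {
      if (taken[ci]) next
      sz <- cell_sizes[ci]
      if (got + sz > quota + sz / 2) next
      lab[cells[[ci]]] <<- id
      taken[ci] <<- TRUE
      got <- got + sz
      if (got >= quota) break
    }
    got
  }
  taken <- rep(FALSE, length(cells))

  # pathological classes cluster around a random injury focus (OSOM-like)
  seed_x <- sx[as.integer(names(cells))]
  seed_y <- sy[as.integer(names(cells))]
  if (spec$injury_fraction > 0) {
    fi <- sample.int(length(cells), 1L)
    dfoc <- (seed_x - seed_x[fi])^2 + (seed_y - seed_y[fi])^2
    by_dist <- order(dfoc)
    assign_cells(by_dist, quotas[["tubular necrosis"]],
                 class_id(schema, "tubular necrosis"))
    assign_cells(by_dist, quotas[["regenerating epithelium"]],
                 class_id(schema, "regenerating epithelium"))
    assign_cells(by_dist, quotas[["intratubular casts"]],
                 class_id(schema, "intratubular casts"))
  }

  shuffled <- sample.int(length(cells))
  for (nm in c("adipose tissue", "transitional epithelium", "stroma",
               "distal tubules/collecting ducts")) {
    assign_cells(shuffled, quotas[[nm]], class_id(schema, nm))
  }
  # proximal tubules absorb the remainder
  left <- fg_idx[lab[fg_idx] == -1L]
  lab[left] <- class_id(schema, "proximal tubules")

  ## --- render ------------------------------------------------------------
  img <- render_section(lab, rid, H, W, schema, spec$texture_noise_sd)

  list(
    image = section_image(img, spec$microns_per_pixel),
    mask = label_mask(matrix(lab, H, W), downsample_factor = 1L)
  )
}

# Per-class texture noise (sd in byte units at texture_noise_sd = 1) and
# speckle rules that make classes separable by colour plus local texture.
render_section <- function(lab, rid, H, W, schema, noise_mult) {
  pal <- schema_palette(schema)
  noise_sd <- c(2, 6, 12, 9, 8, 8, 9, 3, 18, 9)[lab + 1L] * noise_mult

  mult <- rep(1, H * W)
  speckle <- function(id, prob, factor) {
    px <- which(lab == id)
    if (length(px) == 0L) return(invisible())
    hit <- px[stats::runif(length(px)) < prob]
    mult[hit] <<- mult[hit] * factor
  }
  speckle(class_id(schema, "proximal tubules"), 0.04, 0.75)   # brush border
  speckle(class_id(schema, "glomeruli"), 0.10, 0.80)          # capillary tuft
  speckle(class_id(schema, "tubular necrosis"), 0.25, 0.70)   # debris
  speckle(class_id(schema, "tubular necrosis"), 0.15, 1.30)
  speckle(class_id(schema, "regenerating epithelium"), 0.08, 0.80)

  # darker membranes along tessellation / blob boundaries
  rm_ <- matrix(rid, H, W)
  edge <- matrix(FALSE, H, W)
  edge[, -W] <- edge[, -W] | (rm_[, -W] != rm_[, -1])
  edge[-H, ] <- edge[-H, ] | (rm_[-H, ] != rm_[-1, ])
  edge_v <- as.vector(edge) & lab > 0L
  mult[edge_v] <- mult[edge_v] * 0.82

  img <- array(0L, c(H, W, 3L))
  noise <- stats::rnorm(3L * H * W)
  for (ch in 1:3) {
    base <- pal[lab + 1L, ch] * mult +
      noise[((ch - 1L) * H * W + 1L):(ch * H * W)] * noise_sd
    img[, , ch] <- matrix(as.integer(pmax(0, pmin(255, round(base)))), H, W)
  }
  img
}

#' Generate a cohort of synthetic sections
#'
#' Produces `n` sections from a base spec, cycling the given injury grades
#' across sections and deriving a per-section seed deterministically from
#' the master seed, so every section differs in content while the whole
#' cohort is reproducible. When `n >= 3` at least one healthy (zero-injury)
#' control section is always included.
#'
#' @param n Number of sections (>= 1).
#' @param base_spec A [synthetic_section_spec()] used as the template.
#' @param injury_grades Numeric vector of injury fractions cycled across
#'   sections.
#' @param seed Master integer seed.
#' @param schema A [class_schema()].
#' @return A list of `n` records, each with `id`, `image`, `mask`, `spec`,
#'   `injury_fraction` and `seed`.
#' @export
generate_dataset <- function(n, base_spec = synthetic_section_spec(),
                             injury_grades = c(0, 0.1, 0.2, 0.3, 0.4),
                             seed = 1L,
                             schema = default_class_schema()) {
  if (n < 1L) stop("n must be >= 1")
  grades <- rep_len(injury_grades, n)
  if (n >= 3L && !any(grades == 0)) grades[1L] <- 0
  lapply(seq_len(n), function(i) {
    sp <- base_spec
    sp$seed <- derive_seed(seed, i)
    fr <- default_target_fractions(grades[i])
    sp$injury_fraction <- grades[i]
    sp$target_class_fractions <- fr
    sec <- generate_section(sp, schema)
    list(id = i, image = sec$image, mask = sec$mask, spec = sp,
         injury_fraction = grades[i], seed = sp$seed)
  })
}

# Deterministic per-item seed derivation, kept inside 32-bit integer range.
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i * 1000003) %% 2147483647)
}

#' Realized per-class fractions of the non-background surface
#'
#' @param mask A [label_mask()].
#' @param schema A [class_schema()].
#' @return Named numeric vector over non-background classes, summing to 1
#'   for any mask containing parenchyma.
#' @export
realized_class_fractions <- function(mask, schema) {
  counts <- class_areas(mask, schema, full_res_equivalent = FALSE)
  nb <- counts[schema$role != "background"]
  if (sum(nb) == 0) stop("mask has no non-background pixels")
  nb / sum(nb)
}

#' Write or read a synthetic dataset on disk
#'
#' Writes paired image/mask rasters (PNG), the schema JSON sidecar and a
#' CSV manifest (`section`, `image`, `mask`, `injury_fraction`, `seed`).
#'
#' @param dataset A list of records from [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @param schema A [class_schema()].
#' @return `write_dataset()` returns the manifest path invisibly;
#'   `read_dataset()` returns a list of records with `id`, `image`, `mask`,
#'   `injury_fraction`, `seed`.
#' @export
write_dataset <- function(dataset, dir, schema = default_class_schema()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_class_schema(schema, file.path(dir, "schema.json"))
  rows <- lapply(dataset, function(rec) {
    img_p <- sprintf("section_%03d.png", rec$id)
    msk_p <- sprintf("section_%03d_mask.png", rec$id)
    write_section_image(rec$image, file.path(dir, img_p))
    write_label_mask(rec$mask, file.path(dir, msk_p))
    data.frame(section = rec$id, image = img_p, mask = msk_p,
               injury_fraction = rec$injury_fraction, seed = rec$seed)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    list(
      id = manifest$section[i],
      image = read_section_image(file.path(dir, manifest$image[i])),
      mask = read_label_mask(file.path(dir, manifest$mask[i])),
      injury_fraction = manifest$injury_fraction[i],
      seed = manifest$seed[i]
    )
  })
}

#' @export
print.synthetic_section_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_section_spec: %d x %d px, %.3f um/px, injury %.3f, seed %d\n",
    x$width, x$height, x$microns_per_pixel, x$injury_fraction, x$seed))
  fr <- x$target_class_fractions
  cat("targets:", paste(sprintf("%s=%.3f", names(fr), fr), collapse = ", "),
      "\n")
  invisible(x)
}
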