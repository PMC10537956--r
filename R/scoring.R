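#' Ordinal grade of one field of view
#'
#' Converts the damaged-area fraction of a field of view (FOV) into the
#' 0-4 ordinal grade of the Wang-style semi-quantitative scale:
#' 0 for exactly 0%, 1 for (0, 25%], 2 for (25%, 50%], 3 for (50%, 75%],
#' 4 for (75%, 100%]. (The published scale's grade-2/grade-3 bins overlap
#' as printed; the bins here are the unique disjoint, exhaustive reading.)
#'
#' @param damage_fraction Numeric vector in `[0, 1]`.
#' @return Integer vector of grades in 0..4; monotone in the fraction.
#' @examples
#' grade_fov(c(0, 0.1, 0.6, 1))  # 0 1 3 4
#' @export
grade_fov <- function(damage_fraction) {
  if (any(damage_fraction < 0 | damage_fraction > 1, na.rm = TRUE)) {
    stop("damage_fraction must be in [0, 1]")
  }
  ifelse(damage_fraction == 0, 0L,
         pmin(4L, as.integer(ceiling(damage_fraction * 4))))
}

#' Semi-quantitative FOV scoring of a section
#'
#' Emulates the traditional pathologist workflow: `n_fov` square fields of
#' view are drawn at seeded random positions whose centres lie on the
#' kidney (non-background) footprint — or within an optional region mask
#' emulating the restriction to the outer stripe of the outer medulla and
#' cortex. Within each FOV the damage fraction is the share of score-class
#' pixels among non-background pixels; each FOV is graded 0-4 with
#' [grade_fov()] and the section score is the arithmetic mean of the
#' grades.
#'
#' @param mask A full-resolution ground-truth [label_mask()] (an 8x mask
#'   works too; coordinates then refer to its grid times the factor).
#' @param schema A [class_schema()].
#' @param n_fov Number of fields of view (default 10).
#' @param fov_size FOV edge in full-resolution pixels.
#' @param seed Integer seed for FOV placement.
#' @param region_mask Optional logical matrix on the mask grid restricting
#'   allowed FOV centres.
#' @param score_classes Ids counted as damage (defaults to casts +
#'   necrosis; the pathologist's criteria list further changes, such as
#'   brush-border loss, that have no mask class — a documented limitation).
#' @return A `semiquant_score`: `fov_grades` (integer vector), `mean_grade`,
#'   `fov_origins` (n x 2 matrix of 0-based x, y), `fov_size`, `seed`.
#' @export
semiquant_score <- function(mask, schema = default_class_schema(),
                            n_fov = 10L, fov_size = 512L, seed = 1L,
                            region_mask = NULL,
                            score_classes = default_score_classes(schema)) {
  f <- mask$downsample_factor
  fs <- fov_size %/% f
  d <- dim(mask)
  if (fs < 1L || fs > min(d)) stop("FOV larger than the section")
  lab <- mask$labels
  allowed <- lab != background_id(schema) & lab != unannotated_id()
  if (!is.null(region_mask)) {
    if (!identical(dim(region_mask), d)) {
      stop("region mask grid does not match the label mask")
    }
    allowed <- allowed & region_mask
  }
  centre_idx <- which(allowed)
  if (length(centre_idx) == 0L) stop("allowed region is empty")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  picks <- centre_idx[sample.int(length(centre_idx), n_fov,
                                 replace = length(centre_idx) < n_fov)]
  ci <- ((picks - 1L) %% d[1]) + 1L
  cj <- ((picks - 1L) %/% d[1]) + 1L
  # clamp the FOV window inside the section
  i0 <- pmax(1L, pmin(ci - fs %/% 2L, d[1] - fs + 1L))
  j0 <- pmax(1L, pmin(cj - fs %/% 2L, d[2] - fs + 1L))

  grades <- integer(n_fov)
  for (k in seq_len(n_fov)) {
    win <- lab[i0[k]:(i0[k] + fs - 1L), j0[k]:(j0[k] + fs - 1L)]
    nb <- win != background_id(schema) & win != unannotated_id()
    denom <- sum(nb)
    frac <- if (denom == 0L) 0 else sum(win[nb] %in% score_classes) / denom
    grades[k] <- grade_fov(frac)
  }
  structure(
    list(fov_grades = grades, mean_grade = mean(grades),
         fov_origins = cbind(x = (j0 - 1L) * f, y = (i0 - 1L) * f),
         fov_size = fov_size, seed = as.integer(seed)),
    class = "semiquant_score"
  )
}

#' @export
print.semiquant_score <- function(x, ...) {
  cat(sprintf("semiquant_score: mean grade %.2f over %d FOVs (%s)\n",
              x$mean_grade, length(x$fov_grades),
              paste(x$fov_grades, collapse = " ")))
  invisible(x)
}

#' Correlate CNN-based and semi-quantitative scores
#'
#' Spearman's rank correlation is computed as the Pearson correlation of
#' average-ranked data (ties receive mean ranks), with the p-value from
#' the t approximation on `n - 2` degrees of freedom; plain Pearson uses
#' the same t test on the raw values. Both methods are available because
#' both conventions are used for scorer agreement; Spearman is the default
#' headline, being invariant to the monotone but non-linear relation
#' between a 0-4 ordinal mean and a 0-100% area score.
#'
#' @param x Either a data frame of score pairs (columns
#'   `cnn_score_percent` and `semiquant_mean_grade`) or a numeric vector.
#' @param y Numeric vector when `x` is a vector.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A `score_correlation`: `method`, `estimate`, `p_value`, `n`.
#' @export
correlate_scores <- function(x, y = NULL,
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.data.frame(x)) {
    y <- x$semiquant_mean_grade
    x <- x$cnn_score_percent
  }
  if (length(x) != length(y)) stop("score vectors differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 finite score pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("scores are constant; correlation undefined")
  }
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(method = method, estimate = r, p_value = p, n = n),
            class = "score_correlation")
}

#' @export
print.score_correlation <- function(x, ...) {
  cat(sprintf("%s correlation: %.4f (p = %.3g, n = %d)\n",
              x$method, x$estimate, x$p_value, x$n))
  invisible(x)
}

#' End-to-end cohort comparison of the two scoring systems
#'
#' For every section of a cohort, computes the CNN-style injury score
#' (from the model's predicted mask when a trained model is supplied,
#' otherwise from the ground-truth mask) and the semi-quantitative mean
#' grade (always from the ground-truth mask, standing in for the
#' pathologist reading the section itself), then correlates the two.
#'
#' @param dataset A list of records with `image` and `mask` (e.g. from
#'   [generate_dataset()] or [read_dataset()]).
#' @param model Optional trained `seg_model`; `NULL` scores ground truth.
#' @param schema A [class_schema()].
#' @param score_classes Ids forming both scores.
#' @param n_fov,fov_size Semi-quantitative scoring parameters.
#' @param seed Master seed for FOV placement (per-section seeds derived).
#' @param method Correlation method, see [correlate_scores()].
#' @return A list with `pairs` (data frame: `section`, `cnn_score_percent`,
#'   `semiquant_mean_grade`) and `correlation` (a `score_correlation`).
#' @export
compare_cohort <- function(dataset, model = NULL,
                           schema = default_class_schema(),
                           score_classes = default_score_classes(schema),
                           n_fov = 10L, fov_size = 512L, seed = 1L,
                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(dataset) == 0L) stop("empty dataset manifest")
  rows <- lapply(seq_along(dataset), function(i) {
    rec <- dataset[[i]]
    score_mask <- if (is.null(model)) rec$mask else
      predict_mask(model, rec$image)
    cnn <- injury_score(score_mask, schema, score_classes)$score_percent
    semi <- semiquant_score(rec$mask, schema, n_fov = n_fov,
                            fov_size = fov_size,
                            seed = derive_seed(seed, i),
                            score_classes = score_classes)$mean_grade
    data.frame(section = if (is.null(rec$id)) i else rec$id,
               cnn_score_percent = cnn, semiquant_mean_grade = semi)
  })
  pairs <- do.call(rbind, rows)
  corr <- tryCatch(
    correlate_scores(pairs, method = method),
    error = function(e) {
      structure(list(method = method, estimate = NA_real_,
                     p_value = NA_real_, n = nrow(pairs),
                     note = conditionMessage(e)),
                class = "score_correlation")
    }
  )
  list(pairs = pairs, correlation = corr)
}
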