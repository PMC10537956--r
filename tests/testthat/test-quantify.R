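sch <- default_class_schema()

test_that("class areas partition the mask and scale with the grid factor", {
  m <- label_mask(matrix(0L, 10, 10), 1L)
  a <- class_areas(m, sch)
  expect_equal(unname(a["background"]), 100)
  expect_equal(sum(a), 100)

  lab <- matrix(0L, 10, 10); lab[1:25] <- 2L
  m8 <- label_mask(lab, downsample_factor = 8L)
  a8 <- class_areas(m8, sch)
  expect_equal(unname(a8["glomeruli"]), 25 * 64)
  expect_equal(sum(a8), 100 * 64)
  expect_equal(sum(class_areas(m8, sch, full_res_equivalent = FALSE)), 100)
})

test_that("injury score is the pathological percentage of the kidney surface", {
  lab <- matrix(c(rep(3L, 80), rep(7L, 15), rep(8L, 5)), 10, 10)
  s <- injury_score(label_mask(lab, 1L), sch)
  expect_equal(s$score_percent, 20)
  expect_equal(s$kidney_surface_pixels, 100)
  expect_equal(sum(s$per_class_percent), 100)

  healthy <- injury_score(label_mask(matrix(3L, 10, 10), 1L), sch)
  expect_equal(healthy$score_percent, 0)

  expect_error(injury_score(label_mask(matrix(0L, 10, 10), 1L), sch),
               "no non-background")
  expect_error(injury_score(label_mask(lab, 1L), sch, score_classes = 3L),
               "pathological")
})

test_that("regenerating epithelium is quantified but excluded from the score", {
  lab <- matrix(c(rep(3L, 90), rep(9L, 10)), 10, 10)
  s <- injury_score(label_mask(lab, 1L), sch)
  expect_equal(s$score_percent, 0)
  expect_equal(unname(s$per_class_percent["regenerating epithelium"]), 10)
  s2 <- injury_score(label_mask(lab, 1L), sch,
                     score_classes = class_id(sch, "regenerating epithelium"))
  expect_equal(s2$score_percent, 10)
})

test_that("the score is exactly invariant under 8x nearest-neighbour upsampling", {
  for (seed in c(3, 17)) {
    m8 <- random_mask(16, 16, seed)
    m8$downsample_factor <- 8L
    up <- upsample_mask(m8, 8L)
    expect_identical(injury_score(m8, sch)$score_percent,
                     injury_score(up, sch)$score_percent)
  }
})

test_that("generator round-trip: targeted injury is recovered by the score", {
  sec <- generate_section(synthetic_section_spec(512, 512, seed = 12,
                                                 injury_fraction = 0.2), sch)
  s <- injury_score(sec$mask, sch)
  expect_gt(s$score_percent, 16)
  expect_lt(s$score_percent, 24)
})

test_that("heatmap percentages use the whole patch as denominator", {
  lab <- matrix(0L, 32, 32)
  lab[1:16, 1:16] <- 7L           # one full patch of casts
  lab[1:8, 17:32] <- 7L           # half of the second patch, rest background
  g <- injury_heatmap(label_mask(lab, 1L), sch, class_ids = 7L,
                      patch_size = 16L)
  expect_equal(nrow(g), 4L)
  val <- function(x, y) g$percent[g$x == x & g$y == y]
  expect_equal(val(0, 0), 100)
  expect_equal(val(16, 0), 50)    # background counted in the denominator
  expect_equal(val(0, 16), 0)
  expect_error(injury_heatmap(label_mask(lab, 1L), sch, class_ids = 99L),
               "unknown class")
  expect_error(injury_heatmap(label_mask(lab, 1L), sch, patch_size = 4L),
               ">= 8")
})

test_that("patch-weighted mean heatmap percent equals the global percent", {
  for (seed in c(5, 9)) {
    m <- random_mask(100, 100, seed)          # non-divisible: clip edges
    g <- injury_heatmap(m, sch, class_ids = 8L, patch_size = 32L)
    weighted <- sum(g$percent * g$pixels) / sum(g$pixels)
    global <- 100 * mean(m$labels == 8L)
    expect_equal(weighted, global, tolerance = 1e-12)
  }
})

test_that("heatmaps work on the 8x output grid", {
  m8 <- random_mask(64, 64, 2)
  m8$downsample_factor <- 8L
  g <- injury_heatmap(m8, sch, class_ids = 7:8, patch_size = 64L)
  expect_equal(unique(g$w), 64L)
  expect_true(all(g$percent >= 0 & g$percent <= 100))
  expect_error(injury_heatmap(m8, sch, patch_size = 12L), "multiple")
})

test_that("the colormap runs from deep blue to red with monotone hue", {
  cm <- heatmap_colormap(c(0, 0.5, 1))
  expect_true(cm[1, "b"] > cm[1, "r"])       # 0% -> blue dominant
  expect_true(cm[3, "r"] > cm[3, "b"])       # 100% -> red dominant
  expect_equal(cm[3, "g"], 0L, ignore_attr = TRUE)
  ts <- seq(0, 1, length.out = 21)
  hues <- grDevices::rgb2hsv(t(heatmap_colormap(ts)))["h", ]
  expect_true(all(diff(hues) <= 1e-9))       # monotone hue sweep
})

test_that("rendering paints patches with their colormap colour", {
  lab <- matrix(0L, 32, 32)
  g0 <- injury_heatmap(label_mask(lab, 1L), sch, class_ids = 7L,
                       patch_size = 16L)
  img <- render_heatmap(g0, cell_px = 4L)
  deep_blue <- heatmap_colormap(0)
  for (ch in 1:3) {
    expect_true(all(img$pixels[, , ch] == deep_blue[1, ch]))
  }
  path <- tempfile(fileext = ".png")
  write_heatmap(g0, path)
  expect_true(file.exists(path) && file.exists(paste0(path, ".json")))
})
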