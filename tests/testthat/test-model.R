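sch <- default_class_schema()

test_that("the encoder maps H x W inputs to H/8 x W/8 score grids", {
  model <- build_model(sch, base_widths = c(4L, 4L, 4L), seed = 1)
  expect_equal(model$output_stride, 8L)
  img <- section_image(array(128L, c(128, 128, 3)))
  sc <- predict_scores(model, img)
  expect_equal(dim(sc), c(16L, 16L, 10L))
  img2 <- section_image(array(128L, c(64, 128, 3)))
  expect_equal(dim(predict_scores(model, img2))[1:2], c(8L, 16L))
  expect_error(predict_scores(model, section_image(array(0L, c(65, 64, 3)))),
               "divisible by 8")
})

test_that("normalized scores sum to one at every position", {
  model <- build_model(sch, base_widths = c(4L, 4L, 4L), seed = 2)
  img <- generate_section(synthetic_section_spec(64, 64, seed = 3), sch)$image
  sc <- predict_scores(model, img)
  sums <- apply(sc, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
})

test_that("width multiplier scales parameters but not output shape", {
  m1 <- build_model(sch, width_multiplier = 1, seed = 1)
  m2 <- build_model(sch, width_multiplier = 2, seed = 1)
  expect_gt(count_params(m2), count_params(m1))
  img <- section_image(array(100L, c(64, 64, 3)))
  expect_equal(dim(predict_scores(m1, img)), dim(predict_scores(m2, img)))
  expect_error(build_model(class_schema(data.frame(
    id = 0, name = "background", role = "background",
    r = 0, g = 0, b = 0))), "at least two")
})

test_that("nearest-neighbour upsampling replicates labels and proportions", {
  m <- label_mask(matrix(1:4, 2, 2, byrow = TRUE), downsample_factor = 8L)
  up <- upsample_mask(m, 8L)
  expect_equal(dim(up), c(16L, 16L))
  expect_equal(up$downsample_factor, 1L)
  expect_equal(as.vector(table(up$labels)), rep(64L, 4L))
  pre <- table(factor(m$labels, levels = 1:4)) / 4
  post <- table(factor(up$labels, levels = 1:4)) / 256
  expect_equal(as.vector(pre), as.vector(post))
  expect_error(upsample_mask(m, 3L), "divide")
  expect_error(upsample_mask(m, 1.5), "integer")
})

test_that("majority downsampling excludes sparse blocks and breaks ties low", {
  lab <- matrix(unannotated_id(), 16, 16)
  lab[1:8, 1:8] <- 3L                      # fully annotated block
  lab[1:8, 9:16] <- c(rep(5L, 32), rep(2L, 32))  # tie 32/32 -> lowest id 2
  lab[9:16, 1:8][1:20] <- 4L               # 20/64 annotated -> sentinel
  m <- downsample_mask(label_mask(lab, 1L), 8L, sch)
  expect_equal(m$labels[1, 1], 3L)
  expect_equal(m$labels[1, 2], 2L)
  expect_equal(m$labels[2, 1], unannotated_id())
  expect_equal(m$labels[2, 2], unannotated_id())
})

test_that("toy training overfits linearly separable colours", {
  res <- toy_trained_model()
  h <- res$history
  expect_equal(nrow(h), 200L)
  expect_gt(tail(h$train_acc, 1), 0.9)
  expect_true(all(h$lr >= 5e-7 & h$lr <= 5e-4))
  expect_true(all(is.finite(h$loss)))
  expect_lt(tail(h$loss, 1), h$loss[1])
})

test_that("an overfit model labels a pure-background image as background", {
  res <- toy_trained_model()
  pal <- schema_palette(sch)
  px <- array(0L, c(64, 64, 3))
  for (ch in 1:3) px[, , ch] <- pal["background", ch]
  pm <- predict_mask(res$model, section_image(px), tile_size = 64L)
  expect_equal(pm$downsample_factor, 8L)
  expect_equal(dim(pm), c(8L, 8L))
  expect_gte(mean(pm$labels == 0L), 0.95)
})

test_that("prediction is deterministic and tiles merge seamlessly", {
  res <- toy_trained_model()
  tiles <- make_two_class_tiles(n = 1L, size = 64L, seed = 123L)
  a <- predict_mask(res$model, tiles[[1]]$image, tile_size = 64L)
  b <- predict_mask(res$model, tiles[[1]]$image, tile_size = 64L)
  expect_identical(a$labels, b$labels)
  # non-multiple-of-8 sections are padded and cropped to ceiling(H/8)
  px <- tiles[[1]]$image$pixels[1:60, 1:52, , drop = FALSE]
  pm <- predict_mask(res$model, section_image(px), tile_size = 64L)
  expect_equal(dim(pm), c(8L, 7L))
})

test_that("training is seeded and reproducible at step one", {
  tiles <- make_two_class_tiles(n = 4L, size = 64L, seed = 55L)
  model <- build_model(sch, base_widths = c(4L, 4L, 4L), seed = 9)
  cfg <- train_config(batch_size = 2L, epochs = 2L, seed = 31L)
  r1 <- train_model(model, tiles, cfg)
  r2 <- train_model(model, tiles, cfg)
  expect_identical(r1$history$loss[1], r2$history$loss[1])
  expect_identical(r1$history$loss[2], r2$history$loss[2])
})

test_that("degenerate training sets are handled as contracted", {
  expect_error(train_model(build_model(sch), list()), "empty")
  lab <- matrix(unannotated_id(), 64, 64)
  img <- section_image(array(100L, c(64, 64, 3)))
  expect_error(
    train_model(build_model(sch),
                list(list(image = img, mask = label_mask(lab, 1L))),
                train_config(epochs = 1L)),
    "no annotated"
  )
  one <- list(list(image = img, mask = label_mask(matrix(3L, 64, 64), 1L)))
  expect_warning(
    train_model(build_model(sch, base_widths = c(2L, 2L, 2L)), one,
                train_config(epochs = 1L, batch_size = 1L)),
    "single class"
  )
})

test_that("train_config enforces the supported hyperparameter ranges", {
  expect_error(train_config(lr_min = 1e-3, lr_max = 5e-4), "lr_min")
  expect_error(train_config(dropout = 0.5), "dropout")
  expect_error(train_config(momentum = 1.2), "momentum")
  cfg <- train_config(momentum = 0.99, dropout = 0.1)
  expect_equal(cfg$lr_min, 5e-7)
  expect_equal(cfg$lr_max, 5e-4)
})

test_that("model checkpoints round-trip through disk", {
  res <- toy_trained_model()
  path <- tempfile(fileext = ".rds")
  save_model(res$model, path)
  back <- load_model(path)
  expect_identical(back$layers, res$model$layers)
  expect_true(file.exists(paste0(path, ".json")))
  tiles <- make_two_class_tiles(n = 1L, size = 64L, seed = 7L)
  expect_identical(predict_mask(back, tiles[[1]]$image, tile_size = 64L)$labels,
                   predict_mask(res$model, tiles[[1]]$image,
                                tile_size = 64L)$labels)
})
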