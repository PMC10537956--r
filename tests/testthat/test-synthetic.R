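sch <- default_class_schema()

test_that("spec construction enforces fraction invariants", {
  expect_error(synthetic_section_spec(0, 100), "positive")
  expect_error(synthetic_section_spec(injury_fraction = 1.2), "\\[0, 1\\]")
  expect_error(
    synthetic_section_spec(target_class_fractions = c(
      "intratubular casts" = 0.8, "tubular necrosis" = 0.8)),
    "\\[0, 1\\]"
  )
  expect_error(
    synthetic_section_spec(target_class_fractions = c(
      "glomeruli" = 0.5,
      "intratubular casts" = 0.4, "tubular necrosis" = 0.4)),
    "more than 1"
  )
  expect_error(
    synthetic_section_spec(injury_fraction = 0.5,
                           target_class_fractions = c(
                             "intratubular casts" = 0.1,
                             "tubular necrosis" = 0.1)),
    "must equal"
  )
  sp <- synthetic_section_spec(target_class_fractions = c(
    "intratubular casts" = 0.15, "tubular necrosis" = 0.05))
  expect_equal(sp$injury_fraction, 0.2)
})

test_that("generation is bit-deterministic and leaves the caller's RNG alone", {
  sp <- synthetic_section_spec(192, 192, injury_fraction = 0.25, seed = 17)
  set.seed(1); before <- runif(1)
  a <- generate_section(sp, sch)
  b <- generate_section(sp, sch)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask$labels, b$mask$labels)
  set.seed(1)
  expect_identical(runif(1), before)
})

test_that("mask and image agree in shape; kidney sits on a white slide", {
  sec <- generate_section(synthetic_section_spec(256, 256, seed = 8,
                                                 injury_fraction = 0.1), sch)
  expect_identical(dim(sec$mask), dim(sec$image))
  lab <- sec$mask$labels
  # corners are slide background and rendered near-white
  border <- rbind(sec$image$pixels[1, , ], sec$image$pixels[256, , ])
  expect_true(all(lab[1, ] == 0L), info = "top row background")
  expect_true(all(lab[, 1] == 0L))
  expect_gt(mean(border), 240)
  # and there is a substantial foreground
  expect_gt(mean(lab != 0L), 0.3)
})

test_that("healthy sections contain no pathological pixels", {
  sec <- generate_section(synthetic_section_spec(192, 192, seed = 5,
                                                 injury_fraction = 0), sch)
  expect_equal(sum(sec$mask$labels %in% pathological_ids(sch)), 0L)
})

test_that("asymmetric casts/necrosis targets are recovered by pixel count", {
  sp <- synthetic_section_spec(512, 512, seed = 21,
                               target_class_fractions = c(
                                 "intratubular casts" = 0.15,
                                 "tubular necrosis" = 0.05))
  sec <- generate_section(sp, sch)
  fr <- realized_class_fractions(sec$mask, sch)
  path_fr <- sum(fr[c("intratubular casts", "tubular necrosis")])
  expect_gte(path_fr, 0.16)
  expect_lte(path_fr, 0.24)
})

test_that("every targeted class fraction is realized within tolerance", {
  for (seed in c(2, 31)) {
    sp <- synthetic_section_spec(512, 512, seed = seed,
                                 injury_fraction = 0.3)
    fr <- realized_class_fractions(generate_section(sp, sch)$mask, sch)
    targets <- sp$target_class_fractions
    for (nm in names(targets)) {
      tg <- targets[[nm]]
      if (tg < 0.01) next
      tol <- max(0.2 * tg, 0.005)
      expect_lt(abs(fr[[nm]] - tg), tol,
                label = sprintf("class %s seed %d realized %.4f target %.4f",
                                nm, seed, fr[[nm]], tg))
    }
  }
})

test_that("datasets cycle grades, include a healthy control, derive seeds", {
  base <- synthetic_section_spec(96, 96)
  ds <- generate_dataset(4, base, injury_grades = c(0, 0.1, 0.3), seed = 13)
  expect_length(ds, 4L)
  expect_equal(vapply(ds, `[[`, numeric(1), "injury_fraction"),
               c(0, 0.1, 0.3, 0))
  # sections 1 and 4 share the grade but differ in content
  expect_false(identical(ds[[1]]$mask$labels, ds[[4]]$mask$labels))
  # no zero grade supplied: one is forced in for n >= 3
  ds2 <- generate_dataset(3, base, injury_grades = c(0.2, 0.4), seed = 13)
  expect_true(any(vapply(ds2, `[[`, numeric(1), "injury_fraction") == 0))
  # changing the master seed changes at least one mask
  ds3 <- generate_dataset(4, base, injury_grades = c(0, 0.1, 0.3), seed = 14)
  expect_false(all(vapply(seq_along(ds), function(i) {
    identical(ds[[i]]$mask$labels, ds3[[i]]$mask$labels)
  }, logical(1))))
})

test_that("dataset rasters round-trip bit-identically through disk", {
  ds <- generate_dataset(2, synthetic_section_spec(96, 96),
                         injury_grades = c(0, 0.2), seed = 3)
  dir <- tempfile("ds")
  write_dataset(ds, dir, sch)
  back <- read_dataset(dir)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_identical(back[[i]]$image$pixels, ds[[i]]$image$pixels)
    expect_identical(back[[i]]$mask$labels, ds[[i]]$mask$labels)
  }
  expect_true(file.exists(file.path(dir, "schema.json")))
  unlink(dir, recursive = TRUE)
})
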