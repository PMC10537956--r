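# Shared fixtures built in code. The toy model is trained once per test run
# and memoised, since several tests probe the same overfit behaviour.

.fixture_env <- new.env(parent = emptyenv())

# Flat-colour tiles of background (id 0) and intratubular casts (id 7):
# linearly separable colours, the minimal learnable segmentation problem.
make_two_class_tiles <- function(n = 6L, size = 64L, seed = 99L) {
  sch <- default_class_schema()
  pal <- schema_palette(sch)
  withr_seed <- function(expr) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    lapply(seq_len(n), function(i) {
      split_at <- sample(seq(16L, size - 16L, by = 8L), 1L)
      lab <- matrix(0L, size, size)
      lab[, seq_len(split_at)] <- 7L
      px <- array(0L, c(size, size, 3L))
      for (ch in 1:3) {
        base <- matrix(pal["background", ch], size, size)
        base[, seq_len(split_at)] <- pal["intratubular casts", ch]
        px[, , ch] <- as.integer(pmax(0, pmin(255,
          round(base + stats::rnorm(size * size, sd = 4)))))
      }
      list(image = section_image(px), mask = label_mask(lab, 1L))
    })
  })
}

# A small overfit model on the two-class tiles, trained once and cached.
toy_trained_model <- function() {
  if (is.null(.fixture_env$toy)) {
    tiles <- make_two_class_tiles()
    model <- build_model(default_class_schema(),
                         base_widths = c(8L, 12L, 16L), seed = 4L)
    .fixture_env$toy <- train_model(
      model, tiles,
      train_config(batch_size = 4L, epochs = 200L, seed = 4L,
                   dropout = 0, val_every = 50L)
    )
  }
  .fixture_env$toy
}

# Random label mask over the full schema (plus optional sentinel pixels).
random_mask <- function(h, w, seed, p_unannotated = 0) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  ids <- sample(0:9, h * w, replace = TRUE)
  if (p_unannotated > 0) {
    drop <- stats::runif(h * w) < p_unannotated
    ids[drop] <- unannotated_id()
  }
  label_mask(matrix(as.integer(ids), h, w), 1L)
}
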