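# Shared fixtures: deterministic phantom generators and lazily trained toy
# models, cached across test files within one run.

.aigs_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .aigs_test_cache)) {
    assign(name, force(expr), envir = .aigs_test_cache)
  }
  get(name, envir = .aigs_test_cache)
}

tiny_side <- function() 64L

tiny_cfg <- function(heads = "classification", input_channels = 3L,
                     fc_widths = c(64L, 32L)) {
  arch_config(
    input_side = tiny_side(), input_channels = input_channels,
    base_channels = 8L, encoder_stages = 3L, bna_out_channels = 8L,
    fc_widths = fc_widths, dropout_rates = c(0.1, 0.1), heads = heads,
    stem_kernel = 5L, channel_cap = 64L, se_reduction = 4L
  )
}

tiny_mtl_cfg <- function() {
  arch_config(
    input_side = tiny_side(), base_channels = 8L, encoder_stages = 3L,
    bna_out_channels = 8L, fc_widths = c(32L, 16L),
    dropout_rates = c(0.1, 0.1), heads = c("segmentation", "classification"),
    stem_kernel = 5L, channel_cap = 64L, se_reduction = 4L
  )
}

# in-memory phantom cohort at the test scale; larger discs for the
# classification cohorts so the class difference spans enough pixels
phantom_dataset <- function(n, seed, side = tiny_side(), with_masks = TRUE,
                            disc_semi_major = c(36, 46)) {
  set.seed(seed)
  seeds <- sample.int(1e8, 2 * n)
  gl <- rep_len(c(FALSE, TRUE), n)
  imgs <- array(0, c(side, side, 3, n))
  msks <- if (with_masks) array(0, c(side, side, 3, n)) else NULL
  for (i in seq_len(n)) {
    sp <- random_phantom_spec(seeds[2 * i - 1],
      image_side = side,
      glaucoma = gl[i], disc_semi_major = disc_semi_major
    )
    ph <- generate_phantom(sp, seed = seeds[2 * i])
    imgs[, , , i] <- ph$image
    if (with_masks) {
      msks[, , 1, i] <- ph$mask$disc
      msks[, , 2, i] <- ph$mask$cup
      msks[, , 3, i] <- ph$mask$fovea
    }
  }
  list(images = imgs, masks = msks, labels = as.integer(gl))
}

# morphometry sweep scene: disc max diameter >= 200 px at a 512 side, with
# the fovea (and its heatmap patch) guaranteed inside the frame
sweep_spec <- function(seed, image_side = 512) {
  set.seed(seed)
  a <- runif(1, 100, 128)
  b <- a * runif(1, 0.8, 0.98)
  rot <- runif(1, -90, 90)
  cdr <- runif(1, 0.3, 0.9)
  cup_a <- cdr * a
  cup_b <- min(cdr * b * runif(1, 0.94, 1.04), 0.97 * b, 0.999 * cup_a)
  max_off <- 0.8 * min(a - cup_a, b - cup_b)
  off <- runif(2, -max_off / 2, max_off / 2)
  lo_c <- 1.05 * a
  hi_c <- image_side - 1 - 1.05 * a
  lo_f <- 60
  hi_f <- image_side - 1 - 60
  ctr <- c(runif(1, lo_c, hi_c), runif(1, lo_c, hi_c))
  fov <- NULL
  for (tr in 1:100) {
    ctr <- c(runif(1, lo_c, hi_c), runif(1, lo_c, hi_c))
    th <- runif(1, 0, 2 * pi)
    u <- c(cos(th), sin(th))
    tmax <- Inf
    for (k in 1:2) {
      if (u[k] > 1e-9) tmax <- min(tmax, (hi_f - ctr[k]) / u[k])
      if (u[k] < -1e-9) tmax <- min(tmax, (lo_f - ctr[k]) / u[k])
    }
    if (tmax < 1.4 * a) next
    fov <- ctr + min(runif(1, 1.3, 1.9) * 2 * a, 0.97 * tmax) * u
    break
  }
  phantom_spec(
    image_side = image_side, disc_center = ctr, disc_semi_axes = c(a, b),
    disc_rotation = rot, cup_semi_axes = c(cup_a, cup_b),
    cup_center_offset = off, fovea_center = fov,
    vessel_seed = seed + 1, background_seed = seed + 2
  )
}

# lazily trained toy models (shared by smoke and pipeline tests)

trained_segmenter <- function() {
  cached("segmenter", {
    tr <- phantom_dataset(50, seed = 101)
    m <- build_lwbna_unet(tiny_cfg("segmentation"), seed = 1)
    train_segmenter(m, tr$images, tr$masks,
      epochs = 30, seed = 1, lr = 1e-3,
      batch_size = 8
    )
  })
}

trained_classifier <- function() {
  cached("classifier", {
    tr <- phantom_dataset(100,
      seed = 303, with_masks = FALSE,
      disc_semi_major = c(90, 110)
    )
    m <- build_binary_classifier(tiny_cfg(), seed = 2)
    train_classifier(m, tr$images, tr$labels,
      epochs = 20, seed = 2, lr = 1e-3,
      batch_size = 16
    )
  })
}

trained_fusion <- function() {
  cached("fusion", {
    grid <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
    x <- grid[rep(1:16, 40), ]
    y <- as.integer(rowSums(x) > 0)
    m <- build_ffcn(4, dropout = 0.05, seed = 3)
    train_classifier(m, x, y, epochs = 60, seed = 3, lr = 1e-2, batch_size = 32)
  })
}

trained_mtl <- function() {
  cached("mtl", {
    tr <- phantom_dataset(30, seed = 505, disc_semi_major = c(60, 80))
    m <- build_mtl_unet(tiny_mtl_cfg(), seed = 4)
    train_mtl(m, tr$images, tr$masks, tr$labels,
      epochs = 12, seed = 4,
      lr = 1e-3, batch_size = 8
    )
  })
}

# cupping FFCN trained on analytic disc parameters of a small cohort
trained_cupping <- function() {
  cached("cupping", {
    set.seed(77)
    seeds <- sample.int(1e8, 160)
    gl <- rep_len(c(FALSE, TRUE), 80)
    feats <- matrix(0, 80, 9)
    for (i in 1:80) {
      sp <- random_phantom_spec(seeds[i],
        image_side = 512, glaucoma = gl[i],
        disc_semi_major = c(60, 80)
      )
      a <- analytic_morphometry(sp)
      feats[i, ] <- c(
        a$vcdr, a$hcdr, a$acdr, a$pcdr, a$cdr_major,
        a$disc_size_index, a$circularity_disc, a$circularity_cup, a$nrra_da
      )
    }
    m <- build_ffcn(9, dropout = 0.05, seed = 5)
    train_classifier(m, feats, as.integer(gl),
      epochs = 80, seed = 5, lr = 5e-3,
      batch_size = 16
    )
  })
}

toy_bundle <- function() {
  cached("bundle", {
    list(
      mtl = trained_mtl(),
      cupping_ffcn = trained_cupping(),
      dh_seg = trained_segmenter(),
      dh_cls = build_binary_classifier(tiny_cfg(input_channels = 6L), seed = 6),
      rnfld = trained_classifier(),
      fusion = trained_fusion(),
      thresholds = default_thresholds(),
      escalation = default_escalation()
    )
  })
}
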