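test_that("phantom spec invariants are enforced with informative errors", {
  base <- function(...) {
    phantom_spec(
      image_side = 256, disc_center = c(80, 128),
      disc_semi_axes = c(40, 35), cup_semi_axes = c(20, 18),
      fovea_center = c(200, 128), ...
    )
  }
  expect_s3_class(base(), "phantom_spec")
  expect_error(
    phantom_spec(
      image_side = 256, disc_center = c(80, 128),
      disc_semi_axes = c(40, 35), cup_semi_axes = c(39, 38),
      fovea_center = c(200, 128)
    ),
    "cup ellipse"
  )
  expect_error(
    phantom_spec(
      image_side = 256, disc_center = c(80, 128),
      disc_semi_axes = c(40, 35), cup_semi_axes = c(20, 18),
      fovea_center = c(85, 128)
    ),
    "fovea_center"
  )
  expect_error(
    phantom_spec(
      image_side = 32, disc_center = c(10, 16),
      disc_semi_axes = c(4, 4), cup_semi_axes = c(2, 2),
      fovea_center = c(28, 16)
    ),
    "image_side"
  )
  expect_error(
    phantom_spec(
      image_side = 256, disc_center = c(80, 128),
      disc_semi_axes = c(40, -1), cup_semi_axes = c(20, 18),
      fovea_center = c(200, 128)
    ),
    "semi-axes"
  )
  expect_error(
    base(dh_blobs = list(list(
      center = c(250, 250), radius = 5,
      color = c(0.4, 0.05, 0.05)
    ))),
    "dh blob"
  )
})

test_that("rasterisation is deterministic and respects mask geometry", {
  sp <- phantom_spec(
    image_side = 256, disc_center = c(90, 128),
    disc_semi_axes = c(50, 50), cup_semi_axes = c(25, 25),
    fovea_center = c(220, 128)
  )
  p1 <- generate_phantom(sp, seed = 7)
  p2 <- generate_phantom(sp, seed = 7)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask$disc, p2$mask$disc)

  # three non-empty planes, cup contained in disc
  expect_gt(sum(p1$mask$disc), 0)
  expect_gt(sum(p1$mask$cup), 0)
  expect_gt(sum(p1$mask$fovea >= 0.5), 0)
  bin <- aigs:::mask_binary(p1$mask)
  expect_true(all(bin$disc[bin$cup]))

  # rasterised cup/disc area ratio close to the analytic 0.25
  expect_equal(sum(bin$cup) / sum(bin$disc), 0.25, tolerance = 0.02)

  # labels consistent with the scene content
  expect_false(p1$truth$labels$dh_positive)
  expect_false(p1$truth$labels$rnfld_positive)
  sp_dh <- random_phantom_spec(3, image_side = 256, dh_positive = TRUE)
  expect_true(sp_dh$labels$dh_positive)
  expect_gt(length(sp_dh$dh_blobs), 0)
})

test_that("analytic morphometry matches closed-form geometry", {
  sp <- phantom_spec(
    image_side = 512, disc_center = c(150, 256),
    disc_semi_axes = c(100, 100), cup_semi_axes = c(50, 50),
    fovea_center = c(450, 256)
  )
  a <- analytic_morphometry(sp)
  expect_equal(a$vcdr, 0.5)
  expect_equal(a$hcdr, 0.5)
  expect_equal(a$cdr_major, 0.5)
  expect_equal(a$acdr, 0.25)
  expect_equal(a$pcdr, 0.5)
  expect_equal(a$nrra_da, 0.75)
  expect_equal(a$circularity_disc, 1, tolerance = 1e-10)
  expect_equal(a$disc_size_index, 300 / 200)
  expect_equal(a$disc_fovea_angle, 0)
  expect_equal(unname(a$sector_ratios[c("S", "I", "N", "T")]),
    rep(0.75 / 4, 4),
    tolerance = 1e-3
  )

  # definition check: distance 600 over max diameter 200 -> index 3
  sp2 <- phantom_spec(
    image_side = 1024, disc_center = c(200, 500),
    disc_semi_axes = c(100, 90), cup_semi_axes = c(40, 36),
    fovea_center = c(800, 500)
  )
  expect_equal(analytic_morphometry(sp2)$disc_size_index, 3.0)
})

test_that("rotated-ellipse extents agree with dense boundary sampling", {
  a <- 120
  b <- 80
  th <- 30 * pi / 180
  # independent oracle: maximize y over densely sampled boundary points
  t <- seq(0, 2 * pi, length.out = 2e5)
  ys <- a * cos(t) * sin(th) + b * sin(t) * cos(th)
  xs <- a * cos(t) * cos(th) - b * sin(t) * sin(th)
  sp <- phantom_spec(
    image_side = 512, disc_center = c(180, 256),
    disc_semi_axes = c(a, b), disc_rotation = 30,
    cup_semi_axes = c(50, 40), fovea_center = c(470, 256)
  )
  am <- analytic_morphometry(sp)
  v_extent <- 2 * sqrt((a * sin(th))^2 + (b * cos(th))^2)
  expect_equal(v_extent, diff(range(ys)), tolerance = 1e-6)
  expect_equal(2 * sqrt((a * cos(th))^2 + (b * sin(th))^2), diff(range(xs)),
    tolerance = 1e-6
  )
  # the same bounding-box formula drives the analytic VCDR/HCDR
  expect_equal(
    am$vcdr,
    (2 * sqrt((50 * sin(th))^2 + (40 * cos(th))^2)) / v_extent
  )
})

test_that("cohorts are reproducible with prevalence-consistent labels", {
  d1 <- withr::local_tempdir()
  t1 <- generate_cohort(30,
    prevalence = c(glaucoma = 0.5), seed = 11,
    out_dir = d1, image_side = 64, write_images = FALSE, assess = FALSE
  )
  t2 <- generate_cohort(30,
    prevalence = c(glaucoma = 0.5), seed = 11,
    out_dir = withr::local_tempdir(), image_side = 64,
    write_images = FALSE, assess = FALSE
  )
  expect_identical(t1$glaucoma, t2$glaucoma)

  t0 <- generate_cohort(40,
    prevalence = c(glaucoma = 0), seed = 5,
    out_dir = withr::local_tempdir(), image_side = 64,
    write_images = FALSE, assess = FALSE
  )
  expect_equal(sum(t0$glaucoma), 0)

  # binomial 99% interval around 60 positives at n = 200, p = 0.3
  t3 <- generate_cohort(200,
    prevalence = c(glaucoma = 0.3), seed = 21,
    out_dir = withr::local_tempdir(), image_side = 64,
    write_images = FALSE, assess = FALSE
  )
  bounds <- stats::qbinom(c(0.005, 0.995), 200, 0.3)
  expect_gte(sum(t3$glaucoma), bounds[1])
  expect_lte(sum(t3$glaucoma), bounds[2])
})

test_that("cohort label frequencies converge to requested prevalences", {
  n <- 4000
  tr <- generate_cohort(n,
    prevalence = c(glaucoma = 0.4, dh = 0.1, rnfld = 0.2),
    seed = 31, out_dir = withr::local_tempdir(), image_side = 64,
    write_images = FALSE, assess = FALSE
  )
  for (pair in list(
    c("glaucoma", 0.4), c("dh_positive", 0.1),
    c("rnfld_positive", 0.2)
  )) {
    p <- as.numeric(pair[2])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(tr[[pair[1]]]) - p), 3 * se)
  }
})

test_that("cohort files pair up and masks satisfy containment", {
  d <- withr::local_tempdir()
  tr <- generate_cohort(6,
    prevalence = c(glaucoma = 0.5, dh = 0.3, rnfld = 0.3),
    seed = 41, out_dir = d, image_side = 64
  )
  expect_true(file.exists(file.path(d, "truth.csv")))
  man <- build_manifest(d)
  expect_equal(nrow(man), 6)
  for (i in seq_len(nrow(man))) {
    m <- decode_mask(man$mask[i])
    bin <- aigs:::mask_binary(m)
    expect_true(all(bin$disc[bin$cup]))
    if (sum(bin$fovea)) {
      fc <- decode_fovea_center(m$fovea)
      qf <- aigs:::ellipse_qf(
        fc[1], fc[2], c(tr$disc_x[i], tr$disc_y[i]),
        c(tr$disc_a[i], tr$disc_b[i]), tr$disc_rotation[i]
      )
      expect_gt(qf, 1) # fovea outside the disc
    }
  }
})
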