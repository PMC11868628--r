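circle_mask <- function(S, cx, cy, r) {
  Y <- matrix(0:(S - 1), S, S)
  X <- t(Y)
  ((X - cx)^2 + (Y - cy)^2 <= r^2) * 1
}

test_that("fovea heatmap follows the Gaussian definition on a 20% grid", {
  hm <- fovea_heatmap(c(256, 256), sigma = 40, image_side = 512)
  expect_equal(hm$grid_side, 102) # round(0.2 * 512)
  expect_equal(max(hm$values), 1)
  # value at the exact center pixel
  ci <- 256 - hm$x0 + 1
  expect_equal(hm$values[ci, ci], 1)
  # at Euclidean distance sigma from the center: exp(-1/2)
  expect_equal(hm$values[ci, ci + 40], exp(-0.5))
  expect_equal(hm$values[ci + 40, ci], exp(-0.5))
  # radially symmetric
  expect_equal(hm$values[ci + 13, ci], hm$values[ci - 13, ci])
  expect_error(fovea_heatmap(c(10, 10), sigma = 0, image_side = 512), "sigma")
  # grid scales with the image side
  expect_equal(fovea_heatmap(c(32, 32), 5, 320)$grid_side, 64)
})

test_that("fovea center decoding is accurate and reports absence", {
  plane <- aigs:::fovea_heatmap_plane(256, c(170.3, 90.7), 12)
  dec <- decode_fovea_center(plane)
  expect_lt(sqrt(sum((dec - c(170.3, 90.7))^2)), 0.5)
  expect_null(decode_fovea_center(matrix(0, 64, 64)))
  expect_null(decode_fovea_center(matrix(0.15, 64, 64)))

  # Monte-Carlo: additive uniform noise of amplitude 0.1 moves the decoded
  # center by less than 2 px
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- pmin(plane + matrix(runif(256^2, 0, 0.1), 256), 1)
    sqrt(sum((decode_fovea_center(noisy) - c(170.3, 90.7))^2))
  }, numeric(1))
  expect_lt(max(errs), 2)
})

test_that("circle fitting recovers radius and center", {
  m <- circle_mask(512, 200, 256, 100)
  f <- fit_disc_circle(m)
  expect_lt(abs(f$radius - 100), 1)
  expect_lt(sqrt(sum((f$center - c(200, 256))^2)), 1)
  expect_error(fit_disc_circle(matrix(0, 64, 64)), "no disc")

  # ellipse: fitted radius bounded by the semi-axes; center within 1 px up
  # to axis ratio 1.5
  S <- 512
  Y <- matrix(0:(S - 1), S, S)
  X <- t(Y)
  for (ratio in c(1.1, 1.3, 1.5)) {
    b <- 80
    a <- b * ratio
    m2 <- round(aigs:::raster_ellipse(X, Y, c(250, 260), c(a, b), 20))
    f2 <- fit_disc_circle(m2)
    expect_gt(f2$radius, b - 1)
    expect_lt(f2$radius, a + 1)
    expect_lt(sqrt(sum((f2$center - c(250, 260))^2)), 1)
  }
})

test_that("moment ellipse fit recovers axes and rotation", {
  S <- 512
  Y <- matrix(0:(S - 1), S, S)
  X <- t(Y)
  circ <- circle_mask(S, 250, 250, 90)
  fc <- fit_ellipse(circ)
  expect_equal(fc$semi_axes[["a"]] / fc$semi_axes[["b"]], 1, tolerance = 0.01)

  m <- round(aigs:::raster_ellipse(X, Y, c(250, 250), c(120, 80), 0))
  f <- fit_ellipse(m)
  expect_equal(f$semi_axes[["a"]] / f$semi_axes[["b"]], 1.5, tolerance = 0.02)

  for (rot in c(-60, -25, 15, 70)) {
    mr <- round(aigs:::raster_ellipse(X, Y, c(250, 250), c(110, 80), rot))
    fr <- fit_ellipse(mr)
    expect_lt(abs(fr$rotation - rot), 3)
  }
  expect_error(fit_ellipse(matrix(0, 32, 32)), "empty")
})

test_that("cup-to-disc ratios behave at the degenerate corners", {
  disc <- circle_mask(512, 256, 256, 100)
  cup <- circle_mask(512, 256, 256, 50)
  fov <- aigs:::fovea_heatmap_plane(512, c(460, 256), 20)
  m <- seg_mask(disc, cup, fov)
  cd <- compute_cdrs(m)
  for (f in c("vcdr", "hcdr", "pcdr", "cdr_major")) {
    expect_equal(cd[[f]], 0.5, tolerance = 0.02)
  }
  expect_equal(cd$acdr, 0.25, tolerance = 0.02)

  # cup equal to disc
  m2 <- seg_mask(disc, disc, fov)
  cd2 <- compute_cdrs(m2)
  expect_true(all(unlist(cd2) == 1))
  # and all sector rim ratios collapse to 0
  sec <- compute_sector_rims(m2, fovea_center = c(460, 256))
  expect_true(all(sec == 0))

  # empty cup -> all zero; empty disc -> no-disc condition
  m3 <- seg_mask(disc, disc * 0, fov)
  expect_true(all(unlist(compute_cdrs(m3)) == 0))
  m4 <- seg_mask(disc * 0, disc * 0, fov)
  expect_error(compute_cdrs(m4), class = "aigs_no_disc")
})

test_that("sector frame is fovea-anchored and symmetric", {
  disc <- circle_mask(512, 256, 256, 100)
  cup <- circle_mask(512, 256, 256, 50)
  fov_plane <- aigs:::fovea_heatmap_plane(512, c(460, 256), 20)
  m <- seg_mask(disc, cup, fov_plane)
  sec <- compute_sector_rims(m, fovea_center = c(460, 256))
  acdr <- 0.25
  for (s in c("S", "I", "N", "T")) {
    expect_equal(sec[[s]], (1 - acdr) / 4, tolerance = 0.02 * (1 - acdr))
  }
  # quadrants partition the rim
  expect_equal(sum(sec[c("S", "I", "N", "T")]), 1 - compute_cdrs(m)$acdr,
    tolerance = 1e-12
  )

  # cup shifted nasally (away from the fovea) leaves more temporal rim
  cup_nasal <- circle_mask(512, 226, 256, 50) # fovea at +x, shift -x
  mn <- seg_mask(disc, cup_nasal, fov_plane)
  sn <- compute_sector_rims(mn, fovea_center = c(460, 256))
  expect_gt(sn[["T"]], sn[["N"]])
})

test_that("assessment ratios are invariant to translation and rotation", {
  sp <- sweep_spec(1234)
  ph <- generate_phantom(sp, seed = 99)
  m <- ph$mask
  base <- compute_disc_assessment(m)

  shift <- function(x, dx, dy) {
    out <- matrix(0, nrow(x), ncol(x))
    out[(1 + dy):nrow(x), (1 + dx):ncol(x)] <-
      x[1:(nrow(x) - dy), 1:(ncol(x) - dx)]
    out
  }
  mt <- seg_mask(
    shift(m$disc, 15, 9), shift(m$cup, 15, 9),
    shift(m$fovea, 15, 9)
  )
  tra <- compute_disc_assessment(mt)
  rot90 <- function(x) t(x)[, nrow(x):1] # 90 degree rotation
  mr <- seg_mask(rot90(m$disc), rot90(m$cup), rot90(m$fovea))
  rot <- compute_disc_assessment(mr)

  for (f in c(
    "vcdr", "hcdr", "acdr", "pcdr", "nrra_da", "myopic_factor",
    "disc_size_index", "circularity_disc"
  )) {
    expect_equal(tra[[f]], base[[f]], tolerance = 0.01)
    if (!(f %in% c("vcdr", "hcdr"))) {
      # vertical/horizontal swap under rotation; the rest are frame-free
      expect_equal(rot[[f]], base[[f]], tolerance = 0.01)
    }
  }
  expect_equal(rot$vcdr, base$hcdr, tolerance = 0.01)
  expect_equal(rot$hcdr, base$vcdr, tolerance = 0.01)
  # sector frame re-derivation: temporal/nasal wedges follow the rotated
  # disc-fovea axis unchanged, while the superior/inferior labels (anchored
  # to image-up, which does not rotate with the scene) swap consistently
  expect_equal(rot$sector_ratios[["T"]], base$sector_ratios[["T"]], tolerance = 0.01)
  expect_equal(rot$sector_ratios[["N"]], base$sector_ratios[["N"]], tolerance = 0.01)
  expect_equal(
    sort(unname(rot$sector_ratios[c("S", "I")])),
    sort(unname(base$sector_ratios[c("S", "I")])),
    tolerance = 0.01
  )
  expect_equal(
    sort(unname(rot$sector_ratios[c("ST", "IT")])),
    sort(unname(base$sector_ratios[c("ST", "IT")])),
    tolerance = 0.01
  )
})

test_that("mask color encoding round-trips in both dialects", {
  disc <- circle_mask(128, 50, 64, 30)
  cup <- circle_mask(128, 50, 64, 14)
  fov <- circle_mask(128, 110, 64, 5)
  m <- seg_mask(disc, cup, fov)
  for (dialect in c("training", "output")) {
    path <- withr::local_tempfile(fileext = ".png")
    encode_mask(m, path, dialect = dialect)
    dec <- decode_mask(path)
    expect_equal(dec$dialect, dialect)
    expect_identical(dec$disc, disc)
    expect_identical(dec$cup, cup)
    expect_identical(dec$fovea, fov)
  }

  # all-black image decodes to three empty planes
  blank_path <- withr::local_tempfile(fileext = ".png")
  write_fundus_image(array(0, c(64, 64, 3)), blank_path)
  db <- decode_mask(blank_path)
  expect_equal(sum(db$disc) + sum(db$cup) + sum(db$fovea), 0)

  # unknown colors are rejected with the offending pixel count
  bad <- array(0, c(64, 64, 3))
  bad[10:12, 10:12, 3] <- 1 # pure blue, not in either dialect
  expect_error(decode_mask(bad), "9 pixels")
})

test_that("area identities hold exactly in pixel arithmetic", {
  sp <- sweep_spec(555)
  ph <- generate_phantom(sp, seed = 3)
  a <- compute_disc_assessment(ph$mask)
  expect_identical(a$nrra_da + a$acdr, 1)
  expect_equal(sum(a$sector_ratios[c("S", "I", "N", "T")]), a$nrra_da,
    tolerance = 1e-12
  )
})
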