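# Synthetic macula-centered fundus phantoms with analytic ground truth.
#
# A phantom is an analytic scene description (ellipses, blobs, arcs) that is
# rasterised on demand. Because disc/cup/fovea geometry is known in closed
# form, every downstream stage (segmentation, morphometry, screening,
# statistics) can be tested against exact expected values without any
# clinical data.
#
# Coordinate convention (package-wide): x = column, y = row, 0-based, origin
# at the top-left pixel center. Internally rasters are [row, col] matrices.

#' Analytic description of a synthetic fundus scene
#'
#' @param image_side Side of the square image in pixels (>= 64).
#' @param disc_center Optic disc center `c(x, y)` in pixels.
#' @param disc_semi_axes Disc ellipse semi-axes `c(a, b)` in pixels (a = major).
#' @param disc_rotation Disc (and cup) rotation in degrees, counterclockwise
#'   in image coordinates.
#' @param cup_semi_axes Cup ellipse semi-axes `c(a, b)` in pixels.
#' @param cup_center_offset Cup center minus disc center, `c(dx, dy)` pixels.
#' @param fovea_center Fovea center `c(x, y)` in pixels; must lie outside the
#'   disc ellipse.
#' @param laterality `"right"` or `"left"`; mirrors the temporal direction.
#' @param vessel_seed,background_seed Integers seeding the procedural vessel
#'   tree and background texture.
#' @param dh_blobs List of disc-hemorrhage blobs, each
#'   `list(center = c(x, y), radius = r, color = c(r, g, b))`; centers must
#'   lie within twice the maximum disc diameter of the disc center.
#' @param rnfld_arcs List of nerve-fiber-layer-defect bands, each
#'   `list(span = degrees, width = pixels, contrast = fraction)`; rendered as
#'   a multiplicative arcuate darkening from the disc margin toward the fovea.
#' @param glaucoma Logical ground-truth glaucoma label.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_side = 512L,
                         disc_center = c(140, 256),
                         disc_semi_axes = c(42, 38),
                         disc_rotation = 0,
                         cup_semi_axes = c(18, 16),
                         cup_center_offset = c(0, 0),
                         fovea_center = c(360, 256),
                         laterality = c("right", "left"),
                         vessel_seed = 1L, background_seed = 1L,
                         dh_blobs = list(), rnfld_arcs = list(),
                         glaucoma = FALSE) {
  laterality <- match.arg(laterality)
  spec <- structure(list(
    image_side = as.integer(image_side), disc_center = as.numeric(disc_center),
    disc_semi_axes = as.numeric(disc_semi_axes),
    disc_rotation = as.numeric(disc_rotation),
    cup_semi_axes = as.numeric(cup_semi_axes),
    cup_center_offset = as.numeric(cup_center_offset),
    fovea_center = as.numeric(fovea_center), laterality = laterality,
    vessel_seed = as.integer(vessel_seed),
    background_seed = as.integer(background_seed),
    dh_blobs = dh_blobs, rnfld_arcs = rnfld_arcs,
    labels = list(
      glaucoma = isTRUE(glaucoma),
      dh_positive = length(dh_blobs) > 0,
      rnfld_positive = length(rnfld_arcs) > 0
    )
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# signed ellipse quadratic form: <= 1 inside
ellipse_qf <- function(x, y, center, semi_axes, rotation_deg) {
  th <- rotation_deg * pi / 180
  dx <- x - center[1]
  dy <- y - center[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2
}

validate_phantom_spec <- function(spec) {
  if (spec$image_side < 64) stop("invariant violated: image_side must be >= 64")
  if (any(spec$disc_semi_axes <= 0) || any(spec$cup_semi_axes <= 0)) {
    stop("invariant violated: all semi-axes must be > 0")
  }
  cup_c <- spec$disc_center + spec$cup_center_offset
  # cup boundary sampled densely; every point must be inside the disc
  t <- seq(0, 2 * pi, length.out = 361L)[-361L]
  th <- spec$disc_rotation * pi / 180
  bx <- cup_c[1] + spec$cup_semi_axes[1] * cos(t) * cos(th) -
    spec$cup_semi_axes[2] * sin(t) * sin(th)
  by <- cup_c[2] + spec$cup_semi_axes[1] * cos(t) * sin(th) +
    spec$cup_semi_axes[2] * sin(t) * cos(th)
  qf <- ellipse_qf(bx, by, spec$disc_center, spec$disc_semi_axes, spec$disc_rotation)
  if (any(qf > 1 + 1e-9)) {
    stop("invariant violated: cup ellipse must be wholly contained in the disc ellipse")
  }
  qf_f <- ellipse_qf(
    spec$fovea_center[1], spec$fovea_center[2],
    spec$disc_center, spec$disc_semi_axes, spec$disc_rotation
  )
  if (qf_f <= 1) stop("invariant violated: fovea_center must lie outside the disc ellipse")
  max_diam <- 2 * max(spec$disc_semi_axes)
  for (blob in spec$dh_blobs) {
    d <- sqrt(sum((blob$center - spec$disc_center)^2))
    if (d > 2 * max_diam) {
      stop("invariant violated: dh blob center beyond 2x disc max diameter of disc_center")
    }
  }
  invisible(spec)
}

# temporal unit vector: from disc toward fovea side; falls back to laterality
temporal_axis <- function(spec) {
  v <- spec$fovea_center - spec$disc_center
  n <- sqrt(sum(v^2))
  if (n < 1e-9) {
    v <- if (spec$laterality == "right") c(-1, 0) else c(1, 0)
    n <- 1
  }
  v / n
}

#' Draw a random phantom scene description
#'
#' Samples scene parameters emulating a macula-centered fundus photograph:
#' the fovea sits near the image center, the disc on the nasal side at 2.4 to
#' 3.4 disc diameters (the plausible disc size index range), glaucomatous
#' eyes get enlarged, slightly decentred cups, hemorrhage-positive eyes one
#' or two dark blobs at the disc margin, and defect-positive eyes one or two
#' arcuate darkening bands.
#'
#' @param seed RNG seed; a fixed seed reproduces the spec exactly.
#' @param image_side Image side in pixels.
#' @param glaucoma,dh_positive,rnfld_positive Ground-truth labels.
#' @param disc_semi_major Range the disc semi-major axis is drawn from
#'   (pixels, at `image_side = 512`; scaled proportionally otherwise).
#' @return A `phantom_spec`.
#' @export
random_phantom_spec <- function(seed, image_side = 512L, glaucoma = FALSE,
                                dh_positive = FALSE, rnfld_positive = FALSE,
                                disc_semi_major = c(36, 46)) {
  set.seed(seed)
  s <- image_side / 512
  laterality <- sample(c("right", "left"), 1)
  a <- stats::runif(1, disc_semi_major[1], disc_semi_major[2]) * s
  b <- a * stats::runif(1, 0.82, 0.98)
  rot <- stats::runif(1, -20, 20)
  dsi <- stats::runif(1, 2.4, 3.4) # disc size index
  fovea <- c(
    image_side / 2 + stats::runif(1, -0.02, 0.02) * image_side,
    image_side / 2 + stats::runif(1, -0.04, 0.04) * image_side
  )
  dir_x <- if (laterality == "right") 1 else -1
  ang <- stats::runif(1, -8, 8) * pi / 180
  disc_c <- fovea + dsi * 2 * a * c(dir_x * cos(ang), sin(ang))
  # translate the whole scene rigidly so the disc fits in the frame,
  # preserving the disc-fovea geometry (and hence the disc size index)
  margin <- min(1.3 * a, (image_side - 1) / 2 - 1)
  shift <- pmin(pmax(disc_c, margin), image_side - 1 - margin) - disc_c
  disc_c <- disc_c + shift
  fovea <- fovea + shift
  cdr <- if (glaucoma) stats::runif(1, 0.65, 0.88) else stats::runif(1, 0.30, 0.55)
  cup_a <- cdr * a
  cup_b <- cdr * b * stats::runif(1, 0.94, 1.04)
  cup_b <- min(cup_b, 0.97 * b, 0.999 * cup_a)
  max_off <- 0.8 * min(a - cup_a, b - cup_b)
  off <- stats::runif(2, -max_off / 2, max_off / 2)
  dh <- list()
  if (dh_positive) {
    for (i in seq_len(sample(1:2, 1))) {
      th <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 1.0, 1.25)
      dh[[i]] <- list(
        center = disc_c + rad * c(a * cos(th), b * sin(th)),
        radius = stats::runif(1, 0.10, 0.22) * a,
        color = c(0.42, 0.05, 0.06)
      )
    }
  }
  arcs <- list()
  if (rnfld_positive) {
    for (i in seq_len(sample(1:2, 1))) {
      arcs[[i]] <- list(
        span = stats::runif(1, 12, 25),
        width = stats::runif(1, 0.5, 0.9) * a,
        contrast = stats::runif(1, 0.05, 0.2),
        direction = sample(c(-1, 1), 1) * stats::runif(1, 30, 70)
      )
    }
  }
  phantom_spec(
    image_side = image_side, disc_center = disc_c,
    disc_semi_axes = c(a, b), disc_rotation = rot,
    cup_semi_axes = c(cup_a, cup_b), cup_center_offset = off,
    fovea_center = fovea, laterality = laterality,
    vessel_seed = sample.int(1e6, 1), background_seed = sample.int(1e6, 1),
    dh_blobs = dh, rnfld_arcs = arcs, glaucoma = glaucoma
  )
}

# soft-edged indicator of an ellipse on the pixel grid (~1 px transition)
raster_ellipse <- function(X, Y, center, semi_axes, rotation_deg, edge = 1) {
  qf <- ellipse_qf(X, Y, center, semi_axes, rotation_deg)
  # approximate signed distance from qf: d ~ (1 - sqrt(qf)) * min(axes)
  d <- (1 - sqrt(pmax(qf, 1e-12))) * min(semi_axes)
  pmin(pmax(d / edge + 0.5, 0), 1)
}

render_vessels <- function(S, spec) {
  set.seed(spec$vessel_seed)
  W <- matrix(0, S, S)
  tdir <- temporal_axis(spec)
  ndir <- -tdir
  n_vessel <- sample(5:7, 1)
  a <- max(spec$disc_semi_axes)
  for (v in seq_len(n_vessel)) {
    up <- sample(c(-1, 1), 1)
    # quadratic Bezier: out of the disc, arching around the macula
    p0 <- spec$disc_center + c(stats::runif(1, -0.3, 0.3) * a, up * stats::runif(1, 0, 0.5) * a)
    p1 <- spec$disc_center + tdir * stats::runif(1, 0.5, 1.5) * a +
      c(0, up * stats::runif(1, 2.5, 4.5) * a)
    p2 <- spec$fovea_center + tdir * stats::runif(1, 0.5, 2.5) * a +
      c(0, up * stats::runif(1, 2.0, 5.0) * a)
    tt <- seq(0, 1, length.out = 220L)
    px <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
    py <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
    wid <- stats::runif(1, 1.2, 2.6) * (1 - 0.5 * tt)
    for (i in seq_along(tt)) {
      cx <- round(px[i])
      cy <- round(py[i])
      r <- ceiling(wid[i]) + 1L
      if (cx + r < 0 || cx - r > S - 1 || cy + r < 0 || cy - r > S - 1) next
      xs <- max(0, cx - r):min(S - 1, cx + r)
      ys <- max(0, cy - r):min(S - 1, cy + r)
      dd <- outer((ys - py[i])^2, (xs - px[i])^2, "+")
      blk <- pmin(1, pmax(0, wid[i] - sqrt(dd) + 0.5))
      W[ys + 1, xs + 1] <- pmax(W[ys + 1, xs + 1], blk)
    }
  }
  W
}

render_background <- function(S, spec) {
  set.seed(spec$background_seed)
  base <- c(0.80, 0.42, 0.22)
  coarse <- array(stats::rnorm(8 * 8 * 3, 0, 0.03), c(8, 8, 3))
  cx <- (S - 1) / 2
  Y <- matrix(0:(S - 1), S, S)
  X <- t(Y)
  vign <- 1 - 0.35 * (((X - cx)^2 + (Y - cx)^2) / (2 * cx^2))
  img <- array(0, c(S, S, 3))
  for (ch in 1:3) {
    noise <- EBImage::resize(coarse[, , ch], w = S, h = S)
    img[, , ch] <- pmin(1, pmax(0, base[ch] * vign + noise))
  }
  img
}

#' Rasterise a phantom: image, mask, and truth record
#'
#' Renders the scene to an 8-bit-range RGB raster and its 3-plane
#' segmentation mask (disc, cup, fovea heatmap), and returns the analytic
#' truth record. Identical `(spec, seed)` give byte-identical outputs.
#'
#' @param spec A [phantom_spec()].
#' @param seed Seed controlling rendering noise.
#' @param fovea_sigma Standard deviation of the fovea heatmap, as a fraction
#'   of the image side.
#' @return `list(image, mask, truth)`: image is an (S, S, 3) array in
#'   `[0, 1]`, mask a [seg_mask()], truth a list with the spec, the analytic
#'   [disc_assessment], and the binary labels.
#' @export
generate_phantom <- function(spec, seed = 1L, fovea_sigma = 0.08) {
  validate_phantom_spec(spec)
  S <- spec$image_side
  Y <- matrix(0:(S - 1), S, S)
  X <- t(Y)
  img <- render_background(S, spec)

  # vessels darken multiplicatively
  vw <- render_vessels(S, spec)
  vcol <- c(0.50, 0.16, 0.12)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - vw) + vcol[ch] * vw

  # RNFLD: arcuate multiplicative darkening from the disc margin toward fovea
  for (arc in spec$rnfld_arcs) {
    dirn <- if (is.null(arc$direction)) 45 else arc$direction
    band <- rnfld_band(X, Y, spec, dirn, arc$span, arc$width)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - arc$contrast * band)
  }

  # disc then cup (cup on top, brighter)
  disc_m <- raster_ellipse(X, Y, spec$disc_center, spec$disc_semi_axes, spec$disc_rotation)
  cup_c <- spec$disc_center + spec$cup_center_offset
  cup_m <- raster_ellipse(X, Y, cup_c, spec$cup_semi_axes, spec$disc_rotation)
  dcol <- c(0.96, 0.80, 0.50)
  ccol <- c(1.00, 0.94, 0.72)
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - disc_m) + dcol[ch] * disc_m
    img[, , ch] <- img[, , ch] * (1 - cup_m) + ccol[ch] * cup_m
  }

  # fovea: local darkening
  fs <- 0.025 * S
  fd <- exp(-((X - spec$fovea_center[1])^2 + (Y - spec$fovea_center[2])^2) / (2 * fs^2))
  for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.30 * fd)

  # disc hemorrhages
  for (blob in spec$dh_blobs) {
    bm <- raster_ellipse(X, Y, blob$center, c(blob$radius, 0.7 * blob$radius),
      rotation_deg = atan2(
        blob$center[2] - spec$disc_center[2],
        blob$center[1] - spec$disc_center[1]
      ) * 180 / pi + 90
    )
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.88 * bm) + blob$color[ch] * 0.88 * bm
  }

  # pixel noise
  set.seed(seed)
  img <- img + array(stats::rnorm(S * S * 3, 0, 0.008), c(S, S, 3))
  img <- pmin(pmax(img, 0), 1)
  # quantise to 8-bit levels so in-memory equals PNG round trip
  img <- round(img * 255) / 255

  fovea_plane <- fovea_heatmap_plane(S, spec$fovea_center, fovea_sigma * S)
  mask <- seg_mask(
    disc = round(disc_m), cup = round(pmin(cup_m, disc_m)),
    fovea = fovea_plane
  )
  truth <- list(
    spec = spec,
    assessment = analytic_morphometry(spec),
    labels = spec$labels
  )
  list(image = img, mask = mask, truth = truth)
}

# arcuate band: annular wedge around the disc, opening toward the fovea side
rnfld_band <- function(X, Y, spec, direction_deg, span_deg, width_px) {
  tdir <- temporal_axis(spec)
  sup <- c(0, -1)
  sup <- sup - sum(sup * tdir) * tdir
  sn <- sqrt(sum(sup^2))
  sup <- if (sn < 1e-9) c(0, -1) else sup / sn
  dx <- X - spec$disc_center[1]
  dy <- Y - spec$disc_center[2]
  ang <- atan2(dx * sup[1] + dy * sup[2], dx * tdir[1] + dy * tdir[2]) * 180 / pi
  r <- sqrt(dx^2 + dy^2)
  qf <- ellipse_qf(X, Y, spec$disc_center, spec$disc_semi_axes, spec$disc_rotation)
  r_margin <- r / sqrt(pmax(qf, 1e-12)) # radius of disc boundary along each ray
  reach <- sqrt(sum((spec$fovea_center - spec$disc_center)^2))
  in_ang <- pmin(1, pmax(0, (span_deg / 2 - abs(ang - direction_deg)) / 3 + 0.5))
  radial <- pmin(1, pmax(0, (r - r_margin) / 2 + 0.5)) *
    pmin(1, pmax(0, (r_margin + width_px + reach * 0.5 - r) / (0.3 * reach) + 0.5))
  in_ang * radial
}

#' Generate a phantom cohort on disk
#'
#' Emits `n` phantom image/mask PNG pairs plus one truth table CSV holding
#' the scene parameters, binary labels, and all analytic disc-assessment
#' values. Reproducible under a fixed seed.
#'
#' @param n Number of phantoms (>= 1).
#' @param prevalence Named numeric vector of label prevalences in `[0, 1]`:
#'   `glaucoma`, `dh`, `rnfld`.
#' @param seed RNG seed.
#' @param out_dir Output directory (created if missing).
#' @param image_side Image side in pixels.
#' @param write_images If `FALSE`, only the truth table is written.
#' @param assess If `FALSE`, skip the analytic morphometry columns (faster
#'   for large label-only cohorts).
#' @param ... Passed to [random_phantom_spec()].
#' @return The truth table data.frame, invisibly; written to
#'   `file.path(out_dir, "truth.csv")`.
#' @export
generate_cohort <- function(n, prevalence = c(glaucoma = 0.5, dh = 0.1, rnfld = 0.15),
                            seed = 1L, out_dir, image_side = 512L,
                            write_images = TRUE, assess = TRUE, ...) {
  if (n < 1) stop("n must be at least 1")
  if (any(prevalence < 0 | prevalence > 1)) stop("prevalences must lie in [0, 1]")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  prev <- function(nm) if (nm %in% names(prevalence)) prevalence[[nm]] else 0
  set.seed(seed)
  item_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  lab_g <- stats::runif(n) < prev("glaucoma")
  lab_d <- stats::runif(n) < prev("dh")
  lab_r <- stats::runif(n) < prev("rnfld")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- random_phantom_spec(item_seeds[2 * i - 1],
      image_side = image_side,
      glaucoma = lab_g[i], dh_positive = lab_d[i], rnfld_positive = lab_r[i], ...
    )
    img_path <- file.path(out_dir, sprintf("phantom_%04d.png", i))
    mask_path <- file.path(out_dir, sprintf("phantom_%04d_mask.png", i))
    if (write_images) {
      ph <- generate_phantom(spec, seed = item_seeds[2 * i])
      write_fundus_image(ph$image, img_path)
      encode_mask(ph$mask, mask_path)
    }
    a <- if (assess) analytic_morphometry(spec) else NULL
    row <- data.frame(
      id = i, image = basename(img_path), mask = basename(mask_path),
      spec_seed = item_seeds[2 * i - 1], render_seed = item_seeds[2 * i],
      glaucoma = lab_g[i], dh_positive = lab_d[i], rnfld_positive = lab_r[i],
      disc_x = spec$disc_center[1], disc_y = spec$disc_center[2],
      disc_a = spec$disc_semi_axes[1], disc_b = spec$disc_semi_axes[2],
      disc_rotation = spec$disc_rotation,
      cup_a = spec$cup_semi_axes[1], cup_b = spec$cup_semi_axes[2],
      fovea_x = spec$fovea_center[1], fovea_y = spec$fovea_center[2],
      laterality = spec$laterality
    )
    if (assess) {
      row <- cbind(row, as.data.frame(as.list(unlist(a[assessment_numeric_fields()]))))
    }
    rows[[i]] <- row
  }
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}

#' Closed-form disc assessment of a phantom
#'
#' Computes every disc-assessment parameter from ellipse geometry: areas as
#' `pi*a*b`, extents from the rotated-ellipse bounding box, perimeters by
#' complete elliptic integrals, and sector rim areas by polar quadrature of
#' exact ray-ellipse intersections. Serves as the oracle the pixel-based
#' morphometry is validated against.
#'
#' @param spec A [phantom_spec()].
#' @return A `disc_assessment` list (see [compute_disc_assessment()]).
#' @export
analytic_morphometry <- function(spec) {
  validate_phantom_spec(spec)
  a_d <- spec$disc_semi_axes[1]
  b_d <- spec$disc_semi_axes[2]
  a_c <- spec$cup_semi_axes[1]
  b_c <- spec$cup_semi_axes[2]
  th <- spec$disc_rotation * pi / 180
  cup_center <- spec$disc_center + spec$cup_center_offset

  # rotated-ellipse bounding box extents
  wid <- function(a, b) 2 * sqrt((a * cos(th))^2 + (b * sin(th))^2)
  hei <- function(a, b) 2 * sqrt((a * sin(th))^2 + (b * cos(th))^2)
  perim <- function(a, b) {
    aa <- max(a, b)
    bb <- min(a, b)
    4 * aa * pracma::ellipke(1 - (bb / aa)^2)$e
  }

  area_d <- pi * a_d * b_d
  area_c <- pi * a_c * b_c
  acdr <- area_c / area_d
  dfv <- spec$fovea_center - spec$disc_center
  dist_f <- sqrt(sum(dfv^2))
  max_diam <- 2 * a_d
  dsi <- dist_f / max_diam
  ang <- atan2(dfv[2], dfv[1]) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180

  sectors <- analytic_sector_rims(spec)

  structure(list(
    disc_center = spec$disc_center, cup_center = cup_center,
    fovea_center = spec$fovea_center,
    disc_size_index = dsi,
    disc_size_class = disc_size_class(dsi),
    disc_fovea_angle = ang,
    cdr_major = a_c / a_d,
    vcdr = hei(a_c, b_c) / hei(a_d, b_d),
    hcdr = wid(a_c, b_c) / wid(a_d, b_d),
    acdr = acdr,
    pcdr = perim(a_c, b_c) / perim(a_d, b_d),
    nrra_da = 1 - acdr,
    circularity_disc = 4 * pi * area_d / perim(a_d, b_d)^2,
    circularity_cup = 4 * pi * area_c / perim(a_c, b_c)^2,
    myopic_factor = a_d / b_d,
    sector_ratios = sectors
  ), class = "disc_assessment")
}

# exact ray-ellipse chord [t1, t2] of an ellipse from origin point p along unit u
ray_ellipse_chord <- function(p, u, center, semi_axes, th) {
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2) # rotation by -th rows
  d <- c(
    (p[1] - center[1]) * cos(th) + (p[2] - center[2]) * sin(th),
    -(p[1] - center[1]) * sin(th) + (p[2] - center[2]) * cos(th)
  )
  ur <- c(
    u[1] * cos(th) + u[2] * sin(th),
    -u[1] * sin(th) + u[2] * cos(th)
  )
  A <- (ur[1] / semi_axes[1])^2 + (ur[2] / semi_axes[2])^2
  B <- 2 * (d[1] * ur[1] / semi_axes[1]^2 + d[2] * ur[2] / semi_axes[2]^2)
  C <- (d[1] / semi_axes[1])^2 + (d[2] / semi_axes[2])^2 - 1
  disc <- B^2 - 4 * A * C
  if (disc <= 0) {
    return(c(0, 0))
  }
  sq <- sqrt(disc)
  t1 <- (-B - sq) / (2 * A)
  t2 <- (-B + sq) / (2 * A)
  c(max(t1, 0), max(t2, 0))
}

# rim area per sector wedge by polar quadrature about the disc center,
# in the fovea-anchored frame (0 deg = temporal, +90 deg = superior)
analytic_sector_rims <- function(spec, n_theta = 2880L) {
  tdir <- temporal_axis(spec)
  sup <- c(0, -1)
  sup <- sup - sum(sup * tdir) * tdir
  sup <- sup / sqrt(sum(sup^2))
  th <- spec$disc_rotation * pi / 180
  cup_center <- spec$disc_center + spec$cup_center_offset
  thetas <- (seq_len(n_theta) - 0.5) / n_theta * 360 - 180 # frame angle, degrees
  dtheta <- 2 * pi / n_theta
  area_d <- pi * prod(spec$disc_semi_axes)
  rim_w <- numeric(n_theta)
  for (i in seq_len(n_theta)) {
    t_rad <- thetas[i] * pi / 180
    u <- cos(t_rad) * tdir + sin(t_rad) * sup
    rd <- ray_ellipse_chord(spec$disc_center, u, spec$disc_center, spec$disc_semi_axes, th)[2]
    ct <- ray_ellipse_chord(spec$disc_center, u, cup_center, spec$cup_semi_axes, th)
    rim_w[i] <- rd^2 / 2 - (ct[2]^2 - ct[1]^2) / 2
  }
  sec <- sector_of_angle(thetas)
  ratios <- vapply(
    c("S", "I", "N", "T"),
    function(s) sum(rim_w[sec$quadrant == s]) * dtheta / area_d, numeric(1)
  )
  it <- sum(rim_w[sec$it]) * dtheta / area_d
  st <- sum(rim_w[sec$st]) * dtheta / area_d
  c(ratios, IT = it, ST = st)
}

# sector assignment in the fovea-anchored frame (degrees in (-180, 180])
sector_of_angle <- function(theta) {
  q <- character(length(theta))
  q[theta > -45 & theta <= 45] <- "T"
  q[theta > 45 & theta <= 135] <- "S"
  q[theta > 135 | theta <= -135] <- "N"
  q[theta > -135 & theta <= -45] <- "I"
  list(
    quadrant = q,
    st = theta > 45 & theta <= 90, # straddles the T-S boundary
    it = theta > -90 & theta <= -45 # straddles the T-I boundary
  )
}

disc_size_class <- function(dsi, small_above = 3.0, large_below = 2.4) {
  if (dsi > small_above) "small" else if (dsi < large_below) "large" else "normal"
}

assessment_numeric_fields <- function() {
  c(
    "disc_size_index", "disc_fovea_angle", "cdr_major", "vcdr", "hcdr",
    "acdr", "pcdr", "nrra_da", "circularity_disc", "circularity_cup",
    "myopic_factor", "sector_ratios"
  )
}

#' Read / write a fundus image PNG
#'
#' Thin wrappers around EBImage keeping the package's `[row, col]` array
#' convention (EBImage stores `[x, y]`).
#'
#' @param img (S, S, 3) array in `[0, 1]`.
#' @param path PNG file path.
#' @return `read_fundus_image` returns the array; `write_fundus_image` the
#'   path, invisibly.
#' @export
write_fundus_image <- function(img, path) {
  EBImage::writeImage(EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color"), path)
  invisible(path)
}

#' @rdname write_fundus_image
#' @export
read_fundus_image <- function(path) {
  im <- EBImage::readImage(path)
  d <- dim(im)
  a <- EBImage::imageData(im)
  if (length(d) == 2) a <- array(rep(a, 3), c(d[1], d[2], 3))
  if (length(dim(a)) == 3 && dim(a)[3] > 3) a <- a[, , 1:3]
  aperm(a, c(2, 1, 3))
}
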