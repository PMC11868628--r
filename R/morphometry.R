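# Segmentation-mask handling and optic-disc morphometry.
#
# A SegMask holds three probabilistic planes (disc, cup, fovea) in [0,1];
# measurements are taken on views binarised at 0.5, keeping the largest
# connected component per plane. The cup is always intersected with the disc
# so the containment invariant holds by construction.

#' Three-plane segmentation mask
#'
#' @param disc,cup,fovea Numeric matrices of identical shape with values in
#'   `[0, 1]`. The fovea plane is typically a Gaussian heatmap.
#' @param pixel_scale Source pixels per mask pixel.
#' @param dialect Mask color dialect for encoding: `"training"` (cup yellow)
#'   or `"output"` (cup green).
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(disc, cup, fovea, pixel_scale = 1, dialect = "training") {
  stopifnot(
    identical(dim(disc), dim(cup)), identical(dim(disc), dim(fovea)),
    pixel_scale > 0
  )
  structure(
    list(
      disc = disc, cup = cup, fovea = fovea,
      pixel_scale = pixel_scale, dialect = dialect
    ),
    class = "seg_mask"
  )
}

# binarised views; cup constrained inside disc
mask_binary <- function(mask, threshold = 0.5) {
  disc <- mask$disc >= threshold
  cup <- (mask$cup >= threshold) & disc
  list(disc = disc, cup = cup, fovea = mask$fovea >= threshold)
}

no_disc_error <- function(msg = "no disc detected in mask") {
  stop(structure(
    class = c("aigs_no_disc", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# largest connected component of a logical matrix as a logical matrix;
# smaller components are dropped
largest_component <- function(bin) {
  if (!any(bin)) {
    return(NULL)
  }
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which.max(tab)
  EBImage::imageData(lab) == keep
}

# pixel coordinates (0-based x = col, y = row) of TRUE entries
pixel_coords <- function(bin) {
  idx <- which(bin, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

# outer boundary polygon of the largest component, 0-based (x, y)
component_contour <- function(bin) {
  oc <- EBImage::ocontour(EBImage::Image(bin * 1))
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  # our matrices are [row, col] = [y, x]; EBImage indexes [dim1, dim2] = (y, x) here
  cbind(x = pts[, 2], y = pts[, 1])
}

# perimeter of a pixelated boundary: polygon length after subsampling the
# boundary chain (~96 vertices), which suppresses staircase overestimation
contour_perimeter <- function(contour, n_vertices = 96L) {
  n <- nrow(contour)
  stride <- max(1L, round(n / n_vertices))
  pts <- contour[seq(1, n, by = stride), , drop = FALSE]
  d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  sum(sqrt(rowSums(d^2)))
}

#' Gaussian fovea heatmap
#'
#' `H(x, y) = exp(-((x - a)^2 + (y - b)^2) / (2 sigma^2))` evaluated on a
#' square patch whose side is 20% of the image side (rounded), centered on
#' the fovea. The maximum value 1 is attained at the center.
#'
#' @param center Fovea center `c(x, y)` in image pixels.
#' @param sigma Heatmap standard deviation in pixels (> 0).
#' @param image_side Side of the source image; the patch side is
#'   `round(0.2 * image_side)`.
#' @return Object of class `fovea_heatmap`: `values` (patch matrix,
#'   `[row, col]`), patch origin `x0`, `y0`, `center`, `sigma`, `grid_side`.
#' @export
fovea_heatmap <- function(center, sigma, image_side) {
  if (sigma <= 0) stop("sigma must be > 0")
  g <- round(0.2 * image_side)
  x0 <- round(center[1]) - g %/% 2
  y0 <- round(center[2]) - g %/% 2
  xs <- x0 + 0:(g - 1)
  ys <- y0 + 0:(g - 1)
  H <- exp(-(outer((ys - center[2])^2, (xs - center[1])^2, "+")) / (2 * sigma^2))
  structure(
    list(
      values = H, x0 = x0, y0 = y0, center = center, sigma = sigma,
      grid_side = g
    ),
    class = "fovea_heatmap"
  )
}

# full-plane raster with the heatmap patch stamped in (zeros elsewhere)
fovea_heatmap_plane <- function(image_side, center, sigma) {
  hm <- fovea_heatmap(center, sigma, image_side)
  plane <- matrix(0, image_side, image_side)
  xs <- hm$x0 + 0:(hm$grid_side - 1)
  ys <- hm$y0 + 0:(hm$grid_side - 1)
  keep_x <- xs >= 0 & xs < image_side
  keep_y <- ys >= 0 & ys < image_side
  plane[ys[keep_y] + 1, xs[keep_x] + 1] <- hm$values[keep_y, keep_x]
  plane
}

#' Recover the fovea center from a heatmap plane
#'
#' Intensity-weighted centroid of the connected region around the global
#' maximum, over pixels at or above half the maximum. The fovea is reported
#' absent (`NULL`) when the plane maximum is below 0.2.
#'
#' @param plane Numeric matrix in `[0, 1]`.
#' @return `c(x, y)` in pixels, or `NULL` when absent.
#' @export
decode_fovea_center <- function(plane) {
  mx <- max(plane)
  if (mx < 0.2) {
    return(NULL)
  }
  bin <- plane >= 0.5 * mx
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  peak <- which.max(plane)
  region <- EBImage::imageData(lab) == EBImage::imageData(lab)[peak]
  w <- plane[region]
  pc <- pixel_coords(region)
  c(
    x = sum(pc[, "x"] * w) / sum(w),
    y = sum(pc[, "y"] * w) / sum(w)
  )
}

#' Least-squares circle fit of the disc contour
#'
#' Fits a circle (Kasa least squares) to the outer contour of the largest
#' connected component of the binarised disc plane, as used to define the
#' region of interest for hemorrhage detection.
#'
#' @param disc_plane Numeric matrix in `[0, 1]`.
#' @return `list(center = c(x, y), radius)`.
#' @export
fit_disc_circle <- function(disc_plane) {
  comp <- largest_component(disc_plane >= 0.5)
  if (is.null(comp)) no_disc_error()
  ct <- component_contour(comp)
  x <- ct[, "x"]
  y <- ct[, "y"]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) rep(NA_real_, 3))
  center <- sol[1:2]
  radius <- sqrt(max(sol[3] + sum(center^2), 0))
  if (!all(is.finite(c(center, radius))) || radius <= 0) {
    # degenerate contour: fall back to centroid + area-equivalent radius
    pc <- pixel_coords(comp)
    center <- colMeans(pc)
    radius <- sqrt(nrow(pc) / pi)
  }
  list(center = c(x = center[[1]], y = center[[2]]), radius = radius)
}

#' Moment-based ellipse fit
#'
#' Fits an ellipse to the largest connected component of a binarised plane
#' via second-order moments (with the 1/12 pixel-quantisation correction).
#'
#' @param plane Numeric matrix in `[0, 1]`.
#' @return `list(center, semi_axes = c(a, b) with a >= b, rotation)` with
#'   rotation in degrees in `(-90, 90]`.
#' @export
fit_ellipse <- function(plane) {
  comp <- largest_component(plane >= 0.5)
  if (is.null(comp)) no_disc_error("empty plane: no component to fit")
  pc <- pixel_coords(comp)
  mu <- colMeans(pc)
  cv <- stats::cov(pc) - diag(1 / 12, 2)
  eg <- eigen(cv, symmetric = TRUE)
  a <- 2 * sqrt(max(eg$values[1], 1e-9))
  b <- 2 * sqrt(max(eg$values[2], 1e-9))
  rot <- atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi
  if (rot > 90) rot <- rot - 180
  if (rot <= -90) rot <- rot + 180
  list(center = c(x = mu[["x"]], y = mu[["y"]]), semi_axes = c(a = a, b = b), rotation = rot)
}

#' Cup-to-disc ratios from a segmentation mask
#'
#' Vertical/horizontal CDRs are ratios of pixel extents, the area CDR a
#' pixel-count ratio, the perimeter CDR a contour arc-length ratio, and the
#' major-axis CDR the ratio of extents along the disc's fitted major axis.
#'
#' @param mask A [seg_mask()].
#' @return Named list `cdr_major`, `vcdr`, `hcdr`, `acdr`, `pcdr`.
#' @export
compute_cdrs <- function(mask) {
  bin <- mask_binary(mask)
  disc <- largest_component(bin$disc)
  if (is.null(disc)) no_disc_error()
  if (!any(bin$cup)) {
    return(list(cdr_major = 0, vcdr = 0, hcdr = 0, acdr = 0, pcdr = 0))
  }
  cup <- largest_component(bin$cup & disc)
  if (is.null(cup)) {
    return(list(cdr_major = 0, vcdr = 0, hcdr = 0, acdr = 0, pcdr = 0))
  }
  pd <- pixel_coords(disc)
  pc <- pixel_coords(cup)
  extent <- function(v) diff(range(v)) + 1
  fe <- fit_ellipse(mask$disc)
  u <- c(
    cos(fe$rotation * pi / 180),
    sin(fe$rotation * pi / 180)
  )
  proj_extent <- function(p) extent(p[, "x"] * u[1] + p[, "y"] * u[2])
  list(
    cdr_major = proj_extent(pc) / proj_extent(pd),
    vcdr = extent(pc[, "y"]) / extent(pd[, "y"]),
    hcdr = extent(pc[, "x"]) / extent(pd[, "x"]),
    acdr = nrow(pc) / nrow(pd),
    pcdr = contour_perimeter(component_contour(cup)) /
      contour_perimeter(component_contour(disc))
  )
}

#' Disc-level indices from a segmentation mask
#'
#' Disc size index (disc-to-fovea distance over the maximum disc caliper
#' diameter), size class, disc-fovea angle (degrees to the image horizontal,
#' positive when the fovea lies below the disc), circularity indices
#' (`4 pi area / perimeter^2`), neuroretinal-rim-to-disc area ratio, and the
#' myopic (disc ovality) factor.
#'
#' @param mask A [seg_mask()].
#' @param fovea_center `c(x, y)` or `NULL`; when `NULL` it is decoded from
#'   the mask's fovea plane, and indices requiring it are `NA` if absent.
#' @return Named list of indices.
#' @export
compute_disc_indices <- function(mask, fovea_center = NULL) {
  bin <- mask_binary(mask)
  disc <- largest_component(bin$disc)
  if (is.null(disc)) no_disc_error()
  if (is.null(fovea_center)) fovea_center <- decode_fovea_center(mask$fovea)
  pd <- pixel_coords(disc)
  ctr <- colMeans(pd)
  contour <- component_contour(disc)
  hull <- contour[grDevices::chull(contour), , drop = FALSE]
  dd <- as.matrix(stats::dist(hull))
  max_diam <- max(dd) + 1
  per_d <- contour_perimeter(contour)
  area_d <- nrow(pd)
  fe <- fit_ellipse(mask$disc)
  cup_exists <- any(bin$cup & disc)
  per_c <- area_c <- circ_c <- NA_real_
  if (cup_exists) {
    cupc <- largest_component(bin$cup & disc)
    area_c <- sum(cupc)
    per_c <- contour_perimeter(component_contour(cupc))
    circ_c <- 4 * pi * area_c / per_c^2
  }
  acdr <- if (cup_exists) area_c / area_d else 0
  if (is.null(fovea_center)) {
    dsi <- ang <- NA_real_
    cls <- NA_character_
  } else {
    dfv <- fovea_center - ctr
    dsi <- sqrt(sum(dfv^2)) / max_diam
    ang <- atan2(dfv[[2]], dfv[[1]]) * 180 / pi
    if (ang > 90) ang <- ang - 180
    if (ang <= -90) ang <- ang + 180
    cls <- disc_size_class(dsi)
  }
  list(
    disc_center = c(x = ctr[["x"]], y = ctr[["y"]]),
    fovea_center = fovea_center,
    disc_size_index = dsi, disc_size_class = cls, disc_fovea_angle = ang,
    circularity_disc = 4 * pi * area_d / per_d^2,
    circularity_cup = circ_c,
    nrra_da = 1 - acdr,
    myopic_factor = fe$semi_axes[["a"]] / fe$semi_axes[["b"]],
    max_disc_diameter = max_diam
  )
}

#' Neuroretinal rim sector ratios
#'
#' The rim (disc minus cup) is split into angular wedges about the disc
#' center in a frame whose 0 degree axis points at the fovea (temporal) and
#' whose +90 degree axis points superior (image-up). Quadrants T/S/N/I are
#' 90-degree wedges; IT and ST are 45-degree wedges straddling the T-I and
#' T-S boundaries. Each ratio is rim pixels in the wedge over total disc
#' pixels.
#'
#' @param mask A [seg_mask()].
#' @param fovea_center `c(x, y)`; decoded from the mask when `NULL`.
#' @param laterality `"right"` or `"left"` (used only when the fovea is
#'   missing, to orient the temporal axis).
#' @return Named vector `S, I, N, T, IT, ST`, or `NA`s if no fovea.
#' @export
compute_sector_rims <- function(mask, fovea_center = NULL, laterality = "right") {
  bin <- mask_binary(mask)
  disc <- largest_component(bin$disc)
  if (is.null(disc)) no_disc_error()
  if (is.null(fovea_center)) fovea_center <- decode_fovea_center(mask$fovea)
  if (is.null(fovea_center)) {
    return(c(S = NA, I = NA, N = NA, T = NA, IT = NA, ST = NA))
  }
  pd <- pixel_coords(disc)
  ctr <- colMeans(pd)
  tdir <- fovea_center - ctr
  n <- sqrt(sum(tdir^2))
  tdir <- if (n < 1e-9) {
    if (laterality == "right") c(-1, 0) else c(1, 0)
  } else {
    tdir / n
  }
  sup <- c(0, -1)
  sup <- sup - sum(sup * tdir) * tdir
  sup <- sup / sqrt(sum(sup^2))
  rim <- disc & !(bin$cup & disc)
  pr <- pixel_coords(rim)
  dx <- pr[, "x"] - ctr[["x"]]
  dy <- pr[, "y"] - ctr[["y"]]
  theta <- atan2(dx * sup[1] + dy * sup[2], dx * tdir[1] + dy * tdir[2]) * 180 / pi
  sec <- sector_of_angle(theta)
  nd <- nrow(pd)
  out <- vapply(
    c("S", "I", "N", "T"),
    function(s) sum(sec$quadrant == s) / nd, numeric(1)
  )
  c(out, IT = sum(sec$it) / nd, ST = sum(sec$st) / nd)
}

#' Full pixel-based disc assessment
#'
#' Aggregates [compute_cdrs()], [compute_disc_indices()], and
#' [compute_sector_rims()] into the same structure as the analytic oracle
#' [analytic_morphometry()].
#'
#' @param mask A [seg_mask()].
#' @param laterality `"right"` or `"left"`.
#' @param fovea_center Optional known fovea center; decoded otherwise.
#' @return A `disc_assessment` list.
#' @export
compute_disc_assessment <- function(mask, laterality = "right",
                                    fovea_center = NULL) {
  if (is.null(fovea_center)) fovea_center <- decode_fovea_center(mask$fovea)
  cdrs <- compute_cdrs(mask)
  idx <- compute_disc_indices(mask, fovea_center)
  sec <- compute_sector_rims(mask, fovea_center, laterality)
  cup_center <- tryCatch(fit_ellipse(mask$cup)$center, error = function(e) c(x = NA, y = NA))
  structure(list(
    disc_center = idx$disc_center, cup_center = cup_center,
    fovea_center = fovea_center,
    disc_size_index = idx$disc_size_index,
    disc_size_class = idx$disc_size_class,
    disc_fovea_angle = idx$disc_fovea_angle,
    cdr_major = cdrs$cdr_major, vcdr = cdrs$vcdr, hcdr = cdrs$hcdr,
    acdr = cdrs$acdr, pcdr = cdrs$pcdr,
    nrra_da = idx$nrra_da,
    circularity_disc = idx$circularity_disc,
    circularity_cup = idx$circularity_cup,
    myopic_factor = idx$myopic_factor,
    sector_ratios = sec
  ), class = "disc_assessment")
}

#' @export
print.disc_assessment <- function(x, ...) {
  cat("Disc assessment\n")
  cat(sprintf(
    "  disc center (%.1f, %.1f); fovea %s\n",
    x$disc_center[1], x$disc_center[2],
    if (is.null(x$fovea_center) || any(is.na(x$fovea_center))) {
      "absent"
    } else {
      sprintf("(%.1f, %.1f)", x$fovea_center[1], x$fovea_center[2])
    }
  ))
  cat(sprintf(
    "  disc size index %.3f (%s); disc-fovea angle %.1f deg\n",
    x$disc_size_index, x$disc_size_class, x$disc_fovea_angle
  ))
  cat(sprintf(
    "  CDR major %.3f V %.3f H %.3f area %.3f perim %.3f; NRRA/DA %.3f\n",
    x$cdr_major, x$vcdr, x$hcdr, x$acdr, x$pcdr, x$nrra_da
  ))
  cat(sprintf(
    "  circularity disc %.3f cup %.3f; myopic factor %.3f\n",
    x$circularity_disc, x$circularity_cup, x$myopic_factor
  ))
  cat("  sector rim ratios: ", paste(sprintf(
    "%s=%.3f", names(x$sector_ratios),
    x$sector_ratios
  ), collapse = " "), "\n")
  invisible(x)
}

# ---- mask encoding ---------------------------------------------------------

#' Encode / decode a segmentation mask as an RGB PNG
#'
#' Encoding draws the binarised planes: disc-only pixels red, cup pixels
#' yellow (training dialect) or green (output dialect), fovea pixels white.
#' Decoding inverts the mapping (either dialect), intersects the cup with
#' the disc, and rejects images containing unknown colors, reporting the
#' offending pixel count. The round trip is lossless for binarised planes.
#'
#' @param mask A [seg_mask()].
#' @param path PNG path (or, for `decode_mask`, an (S, S, 3) array).
#' @param dialect `"training"` or `"output"`; `decode_mask` auto-detects.
#' @return `decode_mask` returns a `seg_mask` with binary planes and the
#'   detected dialect recorded.
#' @export
encode_mask <- function(mask, path, dialect = mask$dialect) {
  bin <- mask_binary(mask)
  S <- dim(bin$disc)
  img <- array(0, c(S[1], S[2], 3))
  cup_col <- if (dialect == "training") c(1, 1, 0) else c(0, 1, 0)
  r <- g <- b <- matrix(0, S[1], S[2])
  r[bin$disc] <- 1
  r[bin$cup] <- cup_col[1]
  g[bin$cup] <- cup_col[2]
  b[bin$cup] <- cup_col[3]
  r[bin$fovea] <- 1
  g[bin$fovea] <- 1
  b[bin$fovea] <- 1
  img[, , 1] <- r
  img[, , 2] <- g
  img[, , 3] <- b
  write_fundus_image(img, path)
  invisible(path)
}

#' @rdname encode_mask
#' @export
decode_mask <- function(path, dialect = NULL) {
  img <- if (is.character(path)) read_fundus_image(path) else path
  r <- img[, , 1] >= 0.5
  g <- img[, , 2] >= 0.5
  b <- img[, , 3] >= 0.5
  white <- r & g & b
  red <- r & !g & !b
  yellow <- r & g & !b
  green <- !r & g & !b
  black <- !r & !g & !b
  unknown <- !(white | red | yellow | green | black)
  if (any(unknown)) {
    stop(sprintf("mask contains %d pixels of unknown color", sum(unknown)))
  }
  if (is.null(dialect)) {
    dialect <- if (any(green) && !any(yellow)) "output" else "training"
  }
  cup <- if (dialect == "output") green else yellow
  disc <- red | cup
  seg_mask(
    disc = disc * 1, cup = (cup & disc) * 1, fovea = white * 1,
    dialect = dialect
  )
}
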