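# Image normalisation and region-of-interest preparation: CLAHE on the
# luminance channel, squaring/resampling to the model input size, and
# disc-centered ROI cropping with an invertible coordinate record.

check_rgb8 <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("expected an (H, W, 3) RGB raster")
  }
  if (min(image) < 0 || max(image) > 1) {
    stop("expected 8-bit RGB values scaled to [0, 1]")
  }
  invisible(image)
}

rgb_to_ycbcr <- function(image) {
  Y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  list(
    Y = Y,
    Cb = (image[, , 3] - Y) * 0.564 + 0.5,
    Cr = (image[, , 1] - Y) * 0.713 + 0.5
  )
}

ycbcr_to_rgb <- function(Y, Cb, Cr) {
  out <- array(0, c(dim(Y), 3))
  out[, , 1] <- Y + 1.403 * (Cr - 0.5)
  out[, , 2] <- Y - 0.714 * (Cr - 0.5) - 0.344 * (Cb - 0.5)
  out[, , 3] <- Y + 1.773 * (Cb - 0.5)
  pmin(pmax(out, 0), 1)
}

#' Contrast-limited adaptive histogram equalisation (luminance only)
#'
#' Applies CLAHE to the luminance channel of a luminance/chroma
#' decomposition, preserving chroma, then recombines. Defaults follow common
#' practice: clip limit 2, 8 x 8 tile grid.
#'
#' @param image (H, W, 3) RGB array in `[0, 1]` (8-bit scale).
#' @param clip_limit CLAHE clip limit.
#' @param tile_grid Integer `c(rows, cols)` tile grid.
#' @return RGB array of the same shape and range.
#' @export
apply_clahe <- function(image, clip_limit = 2, tile_grid = c(8, 8)) {
  check_rgb8(image)
  yc <- rgb_to_ycbcr(image)
  ye <- EBImage::clahe(EBImage::Image(t(yc$Y)),
    nx = tile_grid[2], ny = tile_grid[1], limit = clip_limit
  )
  ycbcr_to_rgb(t(EBImage::imageData(ye)), yc$Cb, yc$Cr)
}

resize_rgb <- function(image, side, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  im <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(im,
    w = side, h = side,
    filter = if (method == "bilinear") "bilinear" else "none"
  )
  aperm(EBImage::imageData(out), c(2, 1, 3))
}

#' Square an image for model input
#'
#' Non-square inputs are center-padded with black to a square, then
#' resampled (bilinear) to the requested side. A square input already at the
#' requested side is passed through bit-identically.
#'
#' @param image (H, W, 3) RGB array.
#' @param side Output side in pixels (>= 64).
#' @return `list(image, pad = c(left, top), scale)` where
#'   `source = (output + 0.5) / scale - 0.5 - pad` maps output to source
#'   coordinates.
#' @export
to_model_square <- function(image, side = 512L) {
  if (side < 64) stop("side must be at least 64")
  check_rgb8(image)
  d <- dim(image)
  if (d[1] == side && d[2] == side) {
    return(list(image = image, pad = c(left = 0, top = 0), scale = 1))
  }
  sq <- max(d[1], d[2])
  top <- (sq - d[1]) %/% 2
  left <- (sq - d[2]) %/% 2
  padded <- array(0, c(sq, sq, 3))
  padded[top + seq_len(d[1]), left + seq_len(d[2]), ] <- image
  list(
    image = resize_rgb(padded, side),
    pad = c(left = left, top = top),
    scale = side / sq
  )
}

#' Crop a square region of interest around the optic disc
#'
#' The crop side is `round(factor * 2 * disc_radius)` (about twice the disc
#' diameter at the default factor), black-padded where it leaves the image,
#' and resampled to `out_side`. The returned `roi_crop` records the inverse
#' mapping between ROI and source coordinates.
#'
#' @param image (H, W, 3) RGB array.
#' @param disc_center `c(x, y)` in source pixels.
#' @param disc_radius Disc radius in source pixels (> 0).
#' @param factor Crop side as a multiple of the disc diameter.
#' @param out_side Output side in pixels.
#' @return `list(image, roi)` with `roi` an object of class `roi_crop`.
#' @export
crop_disc_roi <- function(image, disc_center, disc_radius, factor = 2.0,
                          out_side = 512L) {
  check_rgb8(image)
  if (disc_radius <= 0) stop("disc_radius must be > 0")
  d <- dim(image)
  if (disc_center[1] < 0 || disc_center[1] > d[2] - 1 ||
    disc_center[2] < 0 || disc_center[2] > d[1] - 1) {
    stop("disc_center must lie inside the image")
  }
  disc_center <- as.numeric(disc_center)
  cs <- round(factor * 2 * disc_radius)
  if (cs > 4 * max(d[1:2])) stop("crop side exceeds 4x the image side")
  x0 <- round(disc_center[1]) - cs %/% 2
  y0 <- round(disc_center[2]) - cs %/% 2
  roi <- structure(list(
    crop_box = c(x0 = x0, y0 = y0, x1 = x0 + cs, y1 = y0 + cs),
    disc_center = disc_center, disc_radius = disc_radius,
    scale = out_side / cs, out_side = as.integer(out_side)
  ), class = "roi_crop")
  list(image = crop_with_roi(image, roi), roi = roi)
}

#' Apply a recorded ROI crop to a raster
#'
#' Crops and resamples another raster (for example the matching mask) with
#' the exact transform recorded in a `roi_crop`, so image and mask stay
#' aligned pixel for pixel.
#'
#' @param image (H, W, C) array.
#' @param roi A `roi_crop`.
#' @param method `"bilinear"` for images, `"nearest"` for label masks.
#' @return (out_side, out_side, C) array.
#' @export
crop_with_roi <- function(image, roi, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(image)
  if (length(d) == 2) {
    image <- array(image, c(d, 1))
    d <- dim(image)
  }
  bb <- roi$crop_box
  cs <- unname(bb[["x1"]] - bb[["x0"]])
  patch <- array(0, c(cs, cs, d[3]))
  ys <- (bb["y0"]:(bb["y1"] - 1))
  xs <- (bb["x0"]:(bb["x1"] - 1))
  keep_y <- ys >= 0 & ys < d[1]
  keep_x <- xs >= 0 & xs < d[2]
  patch[which(keep_y), which(keep_x), ] <-
    image[ys[keep_y] + 1, xs[keep_x] + 1, , drop = FALSE]
  im <- EBImage::Image(aperm(patch, c(2, 1, 3)),
    colormode = if (d[3] == 3) "Color" else "Grayscale"
  )
  out <- EBImage::resize(im,
    w = roi$out_side, h = roi$out_side,
    filter = if (method == "bilinear") "bilinear" else "none"
  )
  a <- EBImage::imageData(out)
  if (length(dim(a)) == 2) a <- array(a, c(dim(a), 1))
  aperm(a, c(2, 1, 3))
}

#' Map points between ROI and source coordinates
#'
#' @param roi A `roi_crop`.
#' @param pts Matrix (or length-2 vector) of `(x, y)` points.
#' @return Matrix of mapped points.
#' @export
roi_to_source <- function(roi, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1)
  sweep((pts + 0.5) / roi$scale - 0.5, 2, c(roi$crop_box["x0"], roi$crop_box["y0"]), "+")
}

#' @rdname roi_to_source
#' @export
source_to_roi <- function(roi, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1)
  (sweep(pts, 2, c(roi$crop_box["x0"], roi$crop_box["y0"]), "-") + 0.5) * roi$scale - 0.5
}

#' @export
as.data.frame.roi_crop <- function(x, ...) {
  data.frame(
    x0 = x$crop_box[["x0"]], y0 = x$crop_box[["y0"]],
    x1 = x$crop_box[["x1"]], y1 = x$crop_box[["y1"]],
    disc_x = x$disc_center[1], disc_y = x$disc_center[2],
    disc_radius = x$disc_radius, scale = x$scale, out_side = x$out_side
  )
}

#' Stack an ROI image and its mask into a six-channel raster
#'
#' Channel order is fixed: image R, G, B then mask R, G, B, matching the
#' mask-assisted hemorrhage classifier input.
#'
#' @param roi_rgb,mask_rgb (H, W, 3) arrays of identical spatial size.
#' @return (H, W, 6) array.
#' @export
stack_six_channel <- function(roi_rgb, mask_rgb) {
  if (!identical(dim(roi_rgb)[1:2], dim(mask_rgb)[1:2])) {
    stop(sprintf(
      "image and mask sizes differ: %s vs %s",
      paste(dim(roi_rgb), collapse = "x"), paste(dim(mask_rgb), collapse = "x")
    ))
  }
  out <- array(0, c(dim(roi_rgb)[1:2], 6))
  out[, , 1:3] <- roi_rgb
  out[, , 4:6] <- mask_rgb
  out
}

#' @rdname stack_six_channel
#' @param six (H, W, 6) array.
#' @export
split_six_channel <- function(six) {
  list(
    image = six[, , 1:3, drop = FALSE],
    mask = six[, , 4:6, drop = FALSE]
  )
}
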