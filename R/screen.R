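# Decision fusion and screening reports: OR-referral labeling, FFCN fusion,
# the adjustable escalation rule that upgrades borderline normals to
# glaucoma suspects, and the end-to-end screening pipeline that turns one
# fundus image into an overlay report plus a CSV row.

#' Default per-model decision thresholds
#'
#' Operating thresholds of the sub-models (Youden-optimal points of the
#' reference study): multi-task direct prediction 0.5245, cupping-parameter
#' FFCN 0.4638, hemorrhage classifier 0.4373, mask-assisted hemorrhage
#' classifier 0.4004; the nerve-fiber-defect classifier defaults to 0.5 and
#' the fusion head to 0.5. All configurable.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(
    mtl = 0.5245, cupping = 0.4638, dh = 0.4373, dh_mask = 0.4004,
    rnfld = 0.5, fusion = 0.5
  )
}

#' Default escalation thresholds of the adjusted screening rule
#'
#' A fused-negative case is escalated to glaucoma suspect when the cupping
#' probability exceeds 0.65, the nerve-fiber-defect probability 0.8, or the
#' hemorrhage probability 0.75 (strict inequalities).
#'
#' @return Named numeric vector.
#' @export
default_escalation <- function() {
  c(cupping = 0.65, rnfld = 0.8, dh = 0.75)
}

#' OR-referral label over the four sub-model decisions
#'
#' A case is labeled positive (referral) if any of the four model decisions
#' (direct multi-task prediction, cupping-based FFCN, hemorrhage, nerve
#' fiber layer defect) is positive.
#'
#' @param d_mtl,d_cup,d_dh,d_rnfld Binary (0/1) decisions; vectorised.
#' @return Integer 0/1 vector.
#' @export
referral_label <- function(d_mtl, d_cup, d_dh, d_rnfld) {
  as.integer(d_mtl | d_cup | d_dh | d_rnfld)
}

#' Fuse sub-model decisions with the fusion FFCN
#'
#' @param inputs Numeric matrix (rows = cases) or vector of fusion features;
#'   by default the four binary sub-model decisions.
#' @param fusion_ffcn A trained FFCN model.
#' @param threshold Decision threshold on the fused probability.
#' @return `list(probability, decision)`.
#' @export
fuse_predictions <- function(inputs, fusion_ffcn, threshold = 0.5) {
  if (is.null(fusion_ffcn)) stop("fusion model missing or untrained")
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1)
  prob <- model_forward(fusion_ffcn, inputs)[, 2]
  # softmax output is strictly inside (0, 1); keep it there numerically so
  # the extreme thresholds 0 and 1 behave as always/never positive
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  list(probability = prob, decision = as.integer(prob >= threshold))
}

#' Apply the adjusted-screening escalation rule
#'
#' A positive fused decision is never downgraded (it stays a referral). A
#' negative fused decision is escalated to `glaucoma_suspect` when any
#' sub-model probability strictly exceeds its escalation threshold;
#' otherwise it remains `normal`. Setting every escalation threshold to 1
#' disables adjustment exactly.
#'
#' @param fused_decision Binary (0/1) fused decision; vectorised.
#' @param probs Named list or matrix with `cupping`, `rnfld`, `dh`
#'   probabilities.
#' @param escalation Named thresholds, see [default_escalation()].
#' @return Character vector in `c("normal", "glaucoma_suspect", "referral")`.
#' @export
adjust_decision <- function(fused_decision, probs,
                            escalation = default_escalation()) {
  if (is.list(probs)) probs <- do.call(cbind, probs[c("cupping", "rnfld", "dh")])
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1, dimnames = list(NULL, c("cupping", "rnfld", "dh")))
  esc <- probs[, "cupping"] > escalation[["cupping"]] |
    probs[, "rnfld"] > escalation[["rnfld"]] |
    probs[, "dh"] > escalation[["dh"]]
  ifelse(fused_decision == 1, "referral",
    ifelse(esc, "glaucoma_suspect", "normal")
  )
}

#' Bundle sub-model probabilities into decisions
#'
#' @param probs Named list of probabilities: `mtl`, `cupping`, `dh`, `rnfld`.
#' @param fusion_ffcn Trained fusion FFCN.
#' @param thresholds Per-model thresholds, see [default_thresholds()].
#' @param escalation Escalation thresholds, see [default_escalation()].
#' @return Object of class `prediction_bundle` with probabilities, per-model
#'   decisions, fused probability/decision, and the three-level adjusted
#'   decision.
#' @export
prediction_bundle <- function(probs, fusion_ffcn,
                              thresholds = default_thresholds(),
                              escalation = default_escalation()) {
  dec <- list(
    mtl = as.integer(probs$mtl >= thresholds$mtl),
    cupping = as.integer(probs$cupping >= thresholds$cupping),
    dh = as.integer(probs$dh >= thresholds$dh_mask),
    rnfld = as.integer(probs$rnfld >= thresholds$rnfld)
  )
  fused <- fuse_predictions(
    cbind(dec$mtl, dec$cupping, dec$dh, dec$rnfld),
    fusion_ffcn, thresholds$fusion
  )
  adj <- adjust_decision(
    fused$decision,
    list(cupping = probs$cupping, rnfld = probs$rnfld, dh = probs$dh),
    escalation
  )
  structure(list(
    probabilities = probs, decisions = dec,
    fused_probability = fused$probability, fused_decision = fused$decision,
    adjusted_decision = adj
  ), class = "prediction_bundle")
}

mask_from_seg_output <- function(seg) {
  seg_mask(
    disc = seg[, , 1], cup = pmin(seg[, , 2], seg[, , 1]),
    fovea = seg[, , 3], dialect = "output"
  )
}

#' Screen one fundus image with a model bundle
#'
#' Runs the full pipeline: squaring + CLAHE, multi-task segmentation and
#' direct prediction, disc morphometry, cupping FFCN on the disc parameters,
#' hemorrhage segmentation followed by mask-assisted classification on the
#' disc ROI, nerve-fiber-defect classification, FFCN fusion, and the
#' escalation rule. When no fovea is found the morphometry fields that need
#' it are absent and the pipeline continues with the remaining models; when
#' no disc is found the image is reported ungradable.
#'
#' @param image (H, W, 3) RGB array in `[0, 1]`.
#' @param bundle Model bundle: list with `mtl`, `cupping_ffcn`, `dh_seg`,
#'   `dh_cls`, `rnfld`, `fusion`, and optionally `thresholds`, `escalation`.
#' @param config Run configuration, see [default_config()].
#' @return `list(bundle = prediction_bundle, report = screening_report,
#'   assessment, mask)`; for ungradable images, a list with
#'   `gradable = FALSE` and the failure reason.
#' @export
screen_image <- function(image, bundle, config = default_config()) {
  side <- bundle$mtl$cfg$input_side
  sq <- to_model_square(image, side)
  x <- apply_clahe(
    sq$image, config$clahe$clip_limit,
    unlist(config$clahe$tile_grid)
  )
  mt <- model_forward(bundle$mtl, x)
  seg <- mt$seg[, , , 1]
  p_mtl <- mt$prob[1, 2]
  mask <- mask_from_seg_output(seg)
  res <- tryCatch(
    {
      assessment <- compute_disc_assessment(mask)
      feats <- assessment_features(assessment)
      p_cup <- model_forward(bundle$cupping_ffcn, matrix(feats, nrow = 1))[1, 2]
      circ <- fit_disc_circle(mask$disc)
      circ$radius <- min(max(circ$radius, 2), side / 2)
      circ$center <- pmin(pmax(circ$center, 0), side - 1)
      roi <- crop_disc_roi(x, circ$center, circ$radius,
        factor = config$roi_factor, out_side = side
      )
      dh_seg <- model_forward(bundle$dh_seg, roi$image)[, , , 1]
      six <- stack_six_channel(roi$image, dh_seg)
      p_dh <- model_forward(bundle$dh_cls, six)[1, 2]
      p_rnfld <- model_forward(bundle$rnfld, x)[1, 2]
      list(
        assessment = assessment, p_cup = p_cup, p_dh = p_dh,
        p_rnfld = p_rnfld, roi = roi$roi, dh_seg = dh_seg
      )
    },
    aigs_no_disc = function(e) NULL
  )
  if (is.null(res)) {
    return(list(gradable = FALSE, reason = "no disc detected"))
  }
  probs <- list(
    mtl = p_mtl, cupping = res$p_cup, dh = res$p_dh,
    rnfld = res$p_rnfld
  )
  pb <- prediction_bundle(probs, bundle$fusion,
    thresholds = bundle$thresholds %||% default_thresholds(),
    escalation = bundle$escalation %||% default_escalation()
  )
  report <- render_report(x, mask, res$assessment, pb,
    dh_seg = res$dh_seg,
    roi = res$roi
  )
  list(
    gradable = TRUE, bundle = pb, report = report,
    assessment = res$assessment, mask = mask
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the 9 numeric cupping features fed to the parameter-based FFCN;
# absent parameters (e.g. disc size index without a fovea) enter as 0
assessment_features <- function(a) {
  f <- c(
    a$vcdr, a$hcdr, a$acdr, a$pcdr, a$cdr_major, a$disc_size_index,
    a$circularity_disc, a$circularity_cup, a$nrra_da
  )
  f[!is.finite(f)] <- 0
  f
}

draw_contour <- function(img, bin, color, thick = 1L) {
  comp <- largest_component(bin)
  if (is.null(comp)) {
    return(img)
  }
  ct <- component_contour(comp)
  S <- dim(img)[1:2]
  for (t in -thick:thick) {
    xs <- pmin(pmax(ct[, "x"] + 1, 1), S[2])
    ys <- pmin(pmax(ct[, "y"] + 1 + t, 1), S[1])
    for (ch in 1:3) img[cbind(ys, xs, ch)] <- color[ch]
    ys2 <- pmin(pmax(ct[, "y"] + 1, 1), S[1])
    xs2 <- pmin(pmax(ct[, "x"] + 1 + t, 1), S[2])
    for (ch in 1:3) img[cbind(ys2, xs2, ch)] <- color[ch]
  }
  img
}

#' Render the screening report
#'
#' Draws the disc and cup boundaries, a fovea marker, and (if present)
#' hemorrhage outlines mapped back from the ROI onto the squared image, and
#' serialises the numeric results to a fixed-schema CSV row.
#'
#' @param image Squared RGB array the assessment was computed on.
#' @param mask The [seg_mask()] produced by the segmenter.
#' @param assessment A `disc_assessment`.
#' @param pb A `prediction_bundle`.
#' @param dh_seg Optional hemorrhage segmentation (ROI frame).
#' @param roi Optional `roi_crop` mapping the ROI back to image coordinates.
#' @return Object of class `screening_report`: `overlay` (RGB array) and
#'   `csv_row` (one-row data.frame).
#' @export
render_report <- function(image, mask, assessment, pb, dh_seg = NULL,
                          roi = NULL) {
  if (!identical(dim(image)[1:2], dim(mask$disc))) {
    stop("image and mask coordinate frames differ")
  }
  bin <- mask_binary(mask)
  ov <- image
  ov <- draw_contour(ov, bin$disc, c(1, 0, 0))
  if (any(bin$cup)) ov <- draw_contour(ov, bin$cup, c(0, 1, 0))
  fc <- assessment$fovea_center
  if (!is.null(fc) && !any(is.na(fc))) {
    S <- dim(ov)[1:2]
    xs <- round(fc[1]) + (-4:4)
    ys <- round(fc[2]) + (-4:4)
    xs <- pmin(pmax(xs + 1, 1), S[2])
    ys <- pmin(pmax(ys + 1, 1), S[1])
    for (ch in 1:3) {
      ov[cbind(round(fc[2]) + 1, xs, ch)] <- 1
      ov[cbind(ys, round(fc[1]) + 1, ch)] <- 1
    }
  }
  dh_detected <- FALSE
  if (!is.null(dh_seg) && !is.null(roi) && any(dh_seg >= 0.5)) {
    dh_detected <- TRUE
    comp <- largest_component(dh_seg >= 0.5)
    ct <- component_contour(comp)
    src <- roi_to_source(roi, ct)
    S <- dim(ov)[1:2]
    keep <- src[, 1] >= 0 & src[, 1] < S[2] & src[, 2] >= 0 & src[, 2] < S[1]
    src <- round(src[keep, , drop = FALSE])
    if (nrow(src)) {
      ov[cbind(src[, 2] + 1, src[, 1] + 1, 1)] <- 0
      ov[cbind(src[, 2] + 1, src[, 1] + 1, 2)] <- 0.6
      ov[cbind(src[, 2] + 1, src[, 1] + 1, 3)] <- 1
    }
  }
  rec <- switch(pb$adjusted_decision,
    referral = "Referral to an ophthalmologist is recommended.",
    glaucoma_suspect = "Glaucoma suspect: follow-up examination recommended.",
    normal = "No referral recommended."
  )
  sec <- assessment$sector_ratios
  csv_row <- data.frame(
    disc_x = assessment$disc_center[[1]], disc_y = assessment$disc_center[[2]],
    cup_x = assessment$cup_center[[1]], cup_y = assessment$cup_center[[2]],
    fovea_x = if (is.null(fc)) NA_real_ else fc[[1]],
    fovea_y = if (is.null(fc)) NA_real_ else fc[[2]],
    disc_size_index = assessment$disc_size_index,
    disc_size_class = assessment$disc_size_class,
    disc_fovea_angle = assessment$disc_fovea_angle,
    cdr_major = assessment$cdr_major, vcdr = assessment$vcdr,
    hcdr = assessment$hcdr, acdr = assessment$acdr, pcdr = assessment$pcdr,
    nrra_da = assessment$nrra_da,
    circularity_disc = assessment$circularity_disc,
    circularity_cup = assessment$circularity_cup,
    myopic_factor = assessment$myopic_factor,
    sector_S = sec[["S"]], sector_I = sec[["I"]], sector_N = sec[["N"]],
    sector_T = sec[["T"]], sector_IT = sec[["IT"]], sector_ST = sec[["ST"]],
    prob_mtl = pb$probabilities$mtl, prob_cupping = pb$probabilities$cupping,
    prob_dh = pb$probabilities$dh, prob_rnfld = pb$probabilities$rnfld,
    dec_mtl = pb$decisions$mtl, dec_cupping = pb$decisions$cupping,
    dec_dh = pb$decisions$dh, dec_rnfld = pb$decisions$rnfld,
    fused_probability = pb$fused_probability,
    fused_decision = pb$fused_decision,
    adjusted_decision = pb$adjusted_decision,
    dh_outlined = dh_detected,
    fovea_found = !(is.null(fc) || any(is.na(fc))),
    recommendation = rec
  )
  structure(list(overlay = ov, csv_row = csv_row), class = "screening_report")
}
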