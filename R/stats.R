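# Evaluation statistics for screening studies: Dice, ROC/AUC with bootstrap
# confidence intervals, Youden operating points, DeLong tests for correlated
# AUCs, Bland-Altman agreement, threshold sweeps, correlation-structure
# comparisons, and histogram summaries.

#' Dice coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)` on masks binarised at 0.5. Two empty masks are
#' taken as perfectly overlapping (Dice 1).
#'
#' @param pred,truth Arrays of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth) {
  stopifnot(identical(dim(pred), dim(truth)))
  a <- pred >= 0.5
  b <- truth >= 0.5
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0) {
    return(1)
  }
  2 * sum(a & b) / (sa + sb)
}

# Mann-Whitney AUC (equals the trapezoidal ROC area, ties handled by
# midranks)
auc_mw <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_curve <- function(scores, labels) {
  ths <- sort(unique(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  tpr <- vapply(ths, function(t) sum(scores >= t & labels == 1) / n1, numeric(1))
  fpr <- vapply(ths, function(t) sum(scores >= t & labels == 0) / n0, numeric(1))
  data.frame(threshold = c(ths, Inf), tpr = c(tpr, 0), fpr = c(fpr, 0))
}

#' Youden-optimal threshold
#'
#' Maximises J = sensitivity + specificity - 1 over the observed score
#' values (decision rule: score >= threshold is positive); ties are broken
#' toward the larger threshold.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return `list(threshold, j)`.
#' @export
youden_threshold <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  j <- rc$tpr - rc$fpr
  best <- max(j)
  pick <- max(which(j == best)) # largest threshold among ties
  list(threshold = rc$threshold[pick], j = best)
}

metrics_at <- function(scores, labels, threshold) {
  pos <- scores >= threshold
  c(
    sensitivity = sum(pos & labels == 1) / sum(labels == 1),
    specificity = sum(!pos & labels == 0) / sum(labels == 0),
    accuracy = mean((pos & labels == 1) | (!pos & labels == 0))
  )
}

#' ROC analysis with bootstrap confidence intervals
#'
#' Trapezoidal AUC, the Youden-optimal operating point, sensitivity /
#' specificity / accuracy there, and percentile-bootstrap confidence
#' intervals for each metric.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed for resampling.
#' @param conf Confidence level.
#' @return Object of class `roc_result`.
#' @export
roc_analysis <- function(scores, labels, n_boot = 2000L, seed = 1L,
                         conf = 0.95) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  curve <- roc_curve(scores, labels)
  auc <- auc_mw(scores, labels)
  yt <- youden_threshold(scores, labels)
  point <- metrics_at(scores, labels, yt$threshold)
  set.seed(seed)
  n <- length(scores)
  boots <- matrix(NA_real_, n_boot, 4,
    dimnames = list(NULL, c("auc", "sensitivity", "specificity", "accuracy"))
  )
  for (bi in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    lb <- labels[idx]
    if (length(unique(lb)) < 2) next
    sc <- scores[idx]
    boots[bi, "auc"] <- auc_mw(sc, lb)
    boots[bi, 2:4] <- metrics_at(sc, lb, yt$threshold)
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boots, 2, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  structure(list(
    curve = curve, auc = auc,
    youden_threshold = yt$threshold, youden_j = yt$j,
    sensitivity = point[["sensitivity"]], specificity = point[["specificity"]],
    accuracy = point[["accuracy"]],
    ci = ci, n_boot = n_boot, conf = conf
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.4f (%.0f%% CI %.4f-%.4f), Youden threshold %.4f (J %.4f)\n",
    x$auc, 100 * x$conf, x$ci[1, "auc"], x$ci[2, "auc"],
    x$youden_threshold, x$youden_j
  ))
  cat(sprintf(
    "  at threshold: sens %.4f spec %.4f acc %.4f\n",
    x$sensitivity, x$specificity, x$accuracy
  ))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr,
    type = "l", xlab = "1 - specificity",
    ylab = "sensitivity", ...
  )
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric z-test on the difference of the AUCs of two score vectors
#' evaluated on the same labels, using the DeLong placement-value covariance
#' estimate. The DeLong AUC equals the trapezoidal AUC. When the variance of
#' the difference is zero (for instance identical scores), p = 1 by
#' convention.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Common 0/1 labels.
#' @return `list(auc_a, auc_b, z, p)`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores_a) == length(labels), length(scores_b) == length(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  pos <- labels == 1
  placements <- function(s) {
    x <- s[pos]
    y <- s[!pos]
    m <- length(x)
    n <- length(y)
    r <- rank(c(x, y))
    rx <- rank(x)
    ry <- rank(y)
    v10 <- (r[1:m] - rx) / n # per-positive placement values
    v01 <- 1 - (r[(m + 1):(m + n)] - ry) / m # per-negative
    list(v10 = v10, v01 = v01, auc = sum(r[1:m] - rx) / (m * n))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  m <- sum(pos)
  n <- sum(!pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_diff <= 0 || !is.finite(var_diff)) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1))
  }
  z <- (pa$auc - pb$auc) / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Bland-Altman agreement analysis
#'
#' Differences are computed as `a - b`. Limits of agreement are
#' `bias +/- 1.96 sd` of the differences.
#'
#' @param a,b Paired measurement vectors.
#' @return Object of class `agreement_result`: `bias`, `sd`, `loa`
#'   (lower/upper), `pct_within` (percent of points within the limits),
#'   `mean_ab` and `diff` for plotting.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  if (is.na(s)) s <- 0
  loa <- c(lower = bias - 1.96 * s, upper = bias + 1.96 * s)
  structure(list(
    bias = bias, sd = s, loa = loa,
    pct_within = 100 * mean(d >= loa[1] & d <= loa[2]),
    mean_ab = (a + b) / 2, diff = d
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.4f, sd %.4f, limits [%.4f, %.4f], %.1f%% within\n",
    x$bias, x$sd, x$loa[1], x$loa[2], x$pct_within
  ))
  invisible(x)
}

#' @export
plot.agreement_result <- function(x, ...) {
  graphics::plot(x$mean_ab, x$diff, xlab = "mean", ylab = "difference", ...)
  graphics::abline(h = c(x$bias, x$loa), lty = c(1, 2, 2))
  invisible(x)
}

#' Sensitivity/specificity/accuracy across a threshold grid
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param grid Thresholds to evaluate (default: 101 points over the score
#'   range padded by one step).
#' @return data.frame with threshold, sensitivity, specificity, accuracy.
#' @export
threshold_sweep <- function(scores, labels, grid = NULL) {
  labels <- as.integer(labels)
  if (is.null(grid)) {
    grid <- seq(min(scores) - 0.01, max(scores) + 0.01, length.out = 101L)
  }
  m <- t(vapply(grid, function(t) metrics_at(scores, labels, t), numeric(3)))
  data.frame(threshold = grid, m)
}

# Shapiro-Wilk normality check, subsampled for large n
is_normalish <- function(x, alpha = 0.05, max_n = 5000L, seed = 1L) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || stats::sd(x) == 0) {
    return(FALSE)
  }
  if (length(x) > max_n) {
    set.seed(seed)
    x <- sample(x, max_n)
  }
  stats::shapiro.test(x)$p.value >= alpha
}

#' Compare correlation structure between two groups
#'
#' Builds per-group correlation matrices (Pearson where all four involved
#' columns pass a Shapiro-Wilk normality check at the 5% level, Spearman
#' otherwise), the difference matrix, and a bootstrap two-sided p-value for
#' each pairwise difference, with significance stars at 0.05 / 0.01 / 0.001.
#' Constant columns yield `NA` entries and are flagged.
#'
#' @param features_a,features_b data.frames with identical numeric columns.
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @return Object of class `correlation_comparison` with `cor_a`, `cor_b`,
#'   `method`, `diff`, `p`, `stars`, `constant_columns`.
#' @export
correlation_compare <- function(features_a, features_b, n_boot = 2000L,
                                seed = 1L) {
  stopifnot(identical(names(features_a), names(features_b)))
  nms <- names(features_a)
  k <- length(nms)
  A <- as.matrix(features_a)
  B <- as.matrix(features_b)
  const <- nms[apply(A, 2, stats::sd) == 0 | apply(B, 2, stats::sd) == 0]
  mk <- function() {
    matrix(NA_real_, k, k, dimnames = list(nms, nms))
  }
  cor_a <- mk()
  cor_b <- mk()
  diffm <- mk()
  pm <- mk()
  method <- matrix(NA_character_, k, k, dimnames = list(nms, nms))
  diag(cor_a) <- diag(cor_b) <- 1
  diag(diffm) <- 0
  diag(pm) <- 1
  normal_col_a <- vapply(seq_len(k), function(i) is_normalish(A[, i], seed = seed), logical(1))
  normal_col_b <- vapply(seq_len(k), function(i) is_normalish(B[, i], seed = seed), logical(1))
  set.seed(seed)
  ia_mat <- matrix(sample.int(nrow(A), nrow(A) * n_boot, replace = TRUE), nrow(A))
  ib_mat <- matrix(sample.int(nrow(B), nrow(B) * n_boot, replace = TRUE), nrow(B))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (nms[i] %in% const || nms[j] %in% const) next
      meth <- if (normal_col_a[i] && normal_col_a[j] &&
        normal_col_b[i] && normal_col_b[j]) {
        "pearson"
      } else {
        "spearman"
      }
      ra <- stats::cor(A[, i], A[, j], method = meth)
      rb <- stats::cor(B[, i], B[, j], method = meth)
      dstar <- numeric(n_boot)
      for (bi in seq_len(n_boot)) {
        ia <- ia_mat[, bi]
        ib <- ib_mat[, bi]
        dstar[bi] <- stats::cor(A[ia, i], A[ia, j], method = meth) -
          stats::cor(B[ib, i], B[ib, j], method = meth)
      }
      p <- 2 * min(mean(dstar <= 0), mean(dstar >= 0))
      p <- min(max(p, 1 / n_boot), 1)
      cor_a[i, j] <- cor_a[j, i] <- ra
      cor_b[i, j] <- cor_b[j, i] <- rb
      diffm[i, j] <- diffm[j, i] <- ra - rb
      pm[i, j] <- pm[j, i] <- p
      method[i, j] <- method[j, i] <- meth
    }
  }
  stars <- matrix("", k, k, dimnames = list(nms, nms))
  stars[!is.na(pm) & pm < 0.05] <- "*"
  stars[!is.na(pm) & pm < 0.01] <- "**"
  stars[!is.na(pm) & pm < 0.001] <- "***"
  structure(list(
    cor_a = cor_a, cor_b = cor_b, method = method, diff = diffm, p = pm,
    stars = stars, constant_columns = const
  ), class = "correlation_comparison")
}

#' Histogram summary with peak and full width at half maximum
#'
#' Normalised histogram (probabilities summing to 1), cumulative
#' probability, modal bin center, and the FWHM obtained by linear
#' interpolation of the half-maximum crossings. Constant data yield a single
#' occupied bin with FWHM equal to the bin width by convention.
#'
#' @param values Numeric vector.
#' @param bins Number of bins.
#' @return `list(mids, prob, cumulative, peak, fwhm, bin_width)`.
#' @export
histogram_summary <- function(values, bins = 50L) {
  values <- values[is.finite(values)]
  if (stats::sd(values) == 0 || length(unique(values)) == 1) {
    bw <- if (length(values) > 1) diff(range(values)) else 0
    if (bw == 0) bw <- max(abs(values[1]) * 1e-3, 1e-3)
    return(list(
      mids = values[1], prob = 1, cumulative = 1, peak = values[1],
      fwhm = bw, bin_width = bw
    ))
  }
  h <- graphics::hist(values, breaks = bins, plot = FALSE)
  prob <- h$counts / sum(h$counts)
  dens <- h$density
  half <- max(dens) / 2
  mids <- h$mids
  peak_i <- which.max(dens)
  cross <- function(side) {
    idx <- if (side == "left") seq_len(peak_i) else peak_i:length(dens)
    d <- dens[idx]
    below <- which(d < half)
    if (!length(below)) {
      return(mids[idx[if (side == "left") 1 else length(idx)]])
    }
    if (side == "left") {
      k <- max(below)
      i1 <- idx[k]
      i2 <- idx[min(k + 1, length(idx))]
    } else {
      k <- min(below)
      i2 <- idx[k]
      i1 <- idx[max(k - 1, 1)]
    }
    if (dens[i2] == dens[i1]) {
      return(mids[i1])
    }
    mids[i1] + (half - dens[i1]) / (dens[i2] - dens[i1]) * (mids[i2] - mids[i1])
  }
  list(
    mids = mids, prob = prob, cumulative = cumsum(prob),
    peak = mids[peak_i], fwhm = cross("right") - cross("left"),
    bin_width = diff(h$breaks[1:2])
  )
}
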