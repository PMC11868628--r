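test_that("dice coefficient satisfies its identities", {
  a <- matrix(0, 20, 20)
  a[1:10, 1:10] <- 1
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(0, 20, 20)
  b[11:20, 11:20] <- 1
  expect_equal(dice_coefficient(a, b), 0)
  expect_equal(dice_coefficient(b * 0, a * 0), 1) # both empty, by convention

  # 100-px and 60-px regions overlapping in 30 px
  x <- matrix(0, 40, 40)
  x[1:10, 1:10] <- 1
  y <- matrix(0, 40, 40)
  y[4:9, 1:10] <- 1 # 60 px, overlap 60? no: rows 4..9 fully inside x
  y <- matrix(0, 40, 40)
  y[8:13, 1:10] <- 1 # 60 px, overlap rows 8..10 = 30 px
  expect_equal(dice_coefficient(x, y), 2 * 30 / (100 + 60))
})

test_that("ROC analysis recovers separation, chance level, and degeneracy", {
  lab <- rep(c(0L, 1L), each = 50)
  perfect <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  r <- roc_analysis(perfect, lab, n_boot = 200, seed = 1)
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_error(roc_analysis(perfect, rep(1L, 100)), "both classes")

  set.seed(2)
  lab2 <- rbinom(2000, 1, 0.5)
  noise <- runif(2000)
  r2 <- roc_analysis(noise, lab2, n_boot = 100, seed = 2)
  expect_lt(abs(r2$auc - 0.5), 0.03)

  # all-equal scores: AUC exactly 1/2 with a zero-width bootstrap interval
  r3 <- roc_analysis(rep(0.7, 100), lab, n_boot = 100, seed = 3)
  expect_equal(r3$auc, 0.5)
  expect_equal(unname(r3$ci[1, "auc"]), 0.5)
  expect_equal(unname(r3$ci[2, "auc"]), 0.5)
})

test_that("Youden threshold matches an exhaustive sweep oracle", {
  scores <- c(0.1, 0.25, 0.3, 0.45, 0.5, 0.65, 0.8, 0.9)
  labels <- c(0, 0, 1, 0, 1, 1, 0, 1)
  # brute-force oracle over every candidate cut
  cand <- sort(unique(c(scores, Inf)))
  j_or <- vapply(cand, function(t) {
    pos <- scores >= t
    sum(pos & labels == 1) / sum(labels) -
      sum(pos & labels == 0) / sum(labels == 0)
  }, numeric(1))
  yt <- youden_threshold(scores, labels)
  expect_equal(yt$j, max(j_or))
  best <- cand[j_or == max(j_or)]
  expect_equal(yt$threshold, max(best)) # tie toward the larger threshold
  expect_gte(yt$j, 0)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  lab <- rbinom(300, 1, 0.45)
  sc <- rnorm(300) + lab
  base <- aigs:::auc_mw(sc, lab)
  for (f in list(function(x) exp(x), function(x) plogis(x), function(x) rank(x), function(x) x^3 + 2 * x)) {
    expect_equal(aigs:::auc_mw(f(sc), lab), base, tolerance = 1e-12)
  }
})

test_that("DeLong test matches the trapezoidal AUC and the reference implementation", {
  set.seed(11)
  lab <- rep(0:1, each = 60)
  a <- rnorm(120) + lab * 1.2
  b <- 0.6 * a + rnorm(120, sd = 0.8)
  dl <- delong_test(a, b, lab)
  expect_equal(dl$auc_a, aigs:::auc_mw(a, lab), tolerance = 1e-12)
  expect_equal(dl$auc_b, aigs:::auc_mw(b, lab), tolerance = 1e-12)

  # identical scores: zero-variance difference resolved as p = 1
  expect_equal(delong_test(a, a, lab)$p, 1)

  # cross-check against pROC's DeLong implementation
  ra <- pROC::roc(lab, a, quiet = TRUE)
  rb <- pROC::roc(lab, b, quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong")
  expect_equal(dl$p, unname(ref$p.value), tolerance = 1e-9)

  # agreement in sign with a bootstrap AUC-difference test
  set.seed(12)
  dstar <- replicate(400, {
    idx <- sample.int(120, replace = TRUE)
    if (length(unique(lab[idx])) < 2) {
      return(NA_real_)
    }
    aigs:::auc_mw(a[idx], lab[idx]) - aigs:::auc_mw(b[idx], lab[idx])
  })
  expect_equal(sign(mean(dstar, na.rm = TRUE)), sign(dl$auc_a - dl$auc_b))
})

test_that("Bland-Altman agreement captures bias, offsets, and coverage", {
  x <- runif(100)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(same$sd, 0)
  expect_equal(same$pct_within, 100)

  shifted <- bland_altman(x, x + 0.3)
  expect_equal(shifted$bias, -0.3)
  expect_equal(shifted$sd, 0)

  set.seed(13)
  a <- runif(500)
  noisy <- bland_altman(a, a + rnorm(500, 0, 0.05))
  expect_gte(noisy$pct_within, 93)
  expect_lte(noisy$pct_within, 97)
  expect_equal(unname(diff(noisy$loa)), 2 * 1.96 * noisy$sd)
})

test_that("threshold sweeps are piecewise constant with correct extremes", {
  set.seed(17)
  sc <- round(runif(60), 2)
  lab <- rbinom(60, 1, 0.5)
  sw <- threshold_sweep(sc, lab, grid = seq(-0.1, 1.1, by = 0.001))
  expect_equal(sw$sensitivity[1], 1)
  expect_equal(sw$specificity[1], 0)
  n <- nrow(sw)
  expect_equal(sw$sensitivity[n], 0)
  expect_equal(sw$specificity[n], 1)
  # curves may only change when the threshold crosses an observed score
  changes <- which(diff(sw$sensitivity) != 0 | diff(sw$specificity) != 0)
  crossed <- vapply(changes, function(i) {
    any(sc >= sw$threshold[i] & sc < sw$threshold[i + 1])
  }, logical(1))
  expect_true(all(crossed))
})

test_that("correlation comparison selects methods and detects group differences", {
  set.seed(19)
  n <- 300
  z <- rnorm(n)
  A <- data.frame(u = z + rnorm(n, sd = 0.6), v = z + rnorm(n, sd = 0.6), w = rnorm(n))
  same <- correlation_compare(A, A, n_boot = 300, seed = 4)
  expect_true(all(abs(same$diff[upper.tri(same$diff)]) < 1e-12))
  expect_true(all(same$p[upper.tri(same$p)] > 0.5))
  expect_true(all(diag(same$cor_a) == 1))

  # perfectly linear pair
  B <- data.frame(u = 1:50 + 0, v = 2 * (1:50) + 3, w = rnorm(50))
  lin <- correlation_compare(B, B, n_boot = 100, seed = 5)
  expect_equal(lin$cor_a["u", "v"], 1, tolerance = 1e-9)

  # skewed columns force the rank-based method
  C1 <- data.frame(u = exp(rnorm(n, sd = 1.5)), v = rnorm(n))
  skew <- correlation_compare(C1, C1, n_boot = 100, seed = 6)
  expect_equal(skew$method["u", "v"], "spearman")

  # constant column flagged, not crashed
  D1 <- data.frame(u = rnorm(50), v = rep(1, 50))
  cc <- correlation_compare(D1, D1, n_boot = 100, seed = 7)
  expect_true("v" %in% cc$constant_columns)
  expect_true(is.na(cc$cor_a["u", "v"]))

  # power: correlation 0.8 vs 0.2 at n = 500 is detected across seeds
  detect <- vapply(1:10, function(s) {
    set.seed(s + 100)
    mk <- function(r) {
      x <- rnorm(500)
      data.frame(u = x, v = r * x + sqrt(1 - r^2) * rnorm(500))
    }
    cmp <- correlation_compare(mk(0.8), mk(0.2), n_boot = 300, seed = s)
    cmp$p["u", "v"] < 0.05
  }, logical(1))
  expect_gte(sum(detect), 9)
})

test_that("histogram summaries recover the Gaussian width", {
  set.seed(23)
  h <- histogram_summary(rnorm(1e5), bins = 80)
  expect_equal(h$fwhm, 2 * sqrt(2 * log(2)), tolerance = 0.05)
  expect_equal(h$cumulative[length(h$cumulative)], 1)
  expect_lt(abs(h$peak), 0.25)

  hc <- histogram_summary(rep(3.2, 50))
  expect_equal(hc$peak, 3.2)
  expect_equal(hc$fwhm, hc$bin_width)
})
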