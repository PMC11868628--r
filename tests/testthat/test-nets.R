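dense_count <- function(nin, nout) nin * nout + nout

test_that("parameter counting matches hand audits", {
  # single dense layer 10 -> 2
  lay <- list(aigs:::nn_dense("d", 10, 2, "softmax"))
  m <- structure(
    list(kind = "ffcn", layers = lay, params = aigs:::init_params(lay)),
    class = "aigs_model"
  )
  expect_equal(count_parameters(m), 22)

  # FFCN(9): widths 16, 32, 64, 128, 64, 32, 16 then 2-way output
  widths <- c(16, 32, 64, 128, 64, 32, 16)
  ins <- c(9, widths)
  audit <- sum(mapply(dense_count, ins, c(widths, 2)))
  expect_equal(count_parameters(build_ffcn(9)), audit)

  # reference binary classifier reproduces the published total
  expect_equal(count_parameters(build_binary_classifier(arch_config())), 1718770)
})

test_that("architecture shapes trace to the published checkpoints", {
  tr <- trace_shapes(build_binary_classifier(arch_config()))
  expect_equal(tr$out[tr$name == "pool5"], "16 x 16 x 256")
  expect_equal(tr$out[tr$name == "bna5.narrow"], "16 x 16 x 8")
  expect_equal(tr$out[tr$name == "head.out"], "N x 2")

  trm <- trace_shapes(build_mtl_unet(mtl_config()))
  expect_equal(trm$out[trm$name == "branch.point"], "32 x 32 x 16")
  expect_equal(trm$out[trm$name == "seg.out"], "512 x 512 x 3")

  f <- build_ffcn(9)
  trf <- trace_shapes(f)
  dens <- trf[trf$type == "dense", "out"]
  expect_equal(dens, paste0("N x ", c(16, 32, 64, 128, 64, 32, 16, 2)))
})

test_that("builders reject invalid configurations", {
  expect_error(build_bna_module(8, 16), "smaller")
  expect_error(build_ffcn(0), "at least 1")
  expect_error(arch_config(input_side = 100, encoder_stages = 3), "divisible")
  expect_error(arch_config(fc_widths = c(0, 10)), "positive")
  expect_error(
    build_binary_classifier(arch_config(heads = "segmentation")),
    "classification"
  )
  expect_error(build_mtl_unet(arch_config(heads = "classification")), "both")
})

test_that("BNA module narrows channels with sigmoid-bounded attention", {
  layers <- build_bna_module(64, 8, se_reduction = 4)
  params <- local({
    set.seed(1)
    aigs:::init_params(layers)
  })
  x <- array(runif(8 * 8 * 64 * 2), c(8, 8, 64, 2))
  fw <- aigs:::seq_fw(layers, params, x)
  expect_equal(dim(fw$y), c(8, 8, 8, 2))
  # every attention step produced per-channel gates strictly inside (0, 1)
  att_idx <- which(vapply(layers, function(l) l$type == "se_att", logical(1)))
  for (i in att_idx) {
    a <- fw$caches[[i]]$a
    expect_true(all(a > 0 & a < 1))
  }
  # layer-wise audit: the block accounts for exactly its closed-form count
  m <- build_binary_classifier(arch_config())
  bna_count <- sum(lengths(m$params[grepl("^bna", names(m$params))]))
  se <- function(c, r = 4) 2 * c * (c %/% r) + (c %/% r) + c
  narrow <- function(c) c * (c %/% 2) + c %/% 2
  audit <- sum(vapply(c(256, 128, 64, 32, 16), function(c) se(c) + narrow(c), numeric(1)))
  expect_equal(bna_count, audit)
})

test_that("models produce calibrated output shapes and probabilities", {
  set.seed(5)
  x <- array(runif(64 * 64 * 3 * 3), c(64, 64, 3, 3))
  cl <- build_binary_classifier(tiny_cfg(), seed = 7)
  p <- model_forward(cl, x)
  expect_equal(dim(p), c(3, 2))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-12)

  u <- build_lwbna_unet(tiny_cfg("segmentation"), seed = 8)
  s <- model_forward(u, x)
  expect_equal(dim(s), c(64, 64, 3, 3))
  expect_true(all(s >= 0 & s <= 1))

  mt <- build_mtl_unet(tiny_mtl_cfg(), seed = 9)
  r <- model_forward(mt, x)
  expect_equal(dim(r$seg), c(64, 64, 3, 3))
  expect_equal(rowSums(r$prob), rep(1, 3), tolerance = 1e-12)

  ff <- build_ffcn(4, seed = 10)
  pf <- model_forward(ff, matrix(runif(8), 2, 4))
  expect_equal(rowSums(pf), rep(1, 2), tolerance = 1e-12)
})

test_that("loss functions satisfy their analytic identities", {
  pred <- array(rbinom(16 * 16 * 3 * 2, 1, 0.4), c(16, 16, 3, 2))
  expect_equal(dice_loss(pred, pred, eps = 0), 0)
  truth <- array(1, c(16, 16, 3, 2))
  near_one <- dice_loss(array(0, c(16, 16, 3, 2)), truth, eps = 1)
  expect_gt(near_one, 0.99)
  expect_lt(near_one, 1)

  onehot <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(cross_entropy(onehot, onehot), 0, tolerance = 1e-9)
  uniform <- matrix(0.5, 2, 2)
  expect_equal(cross_entropy(uniform, onehot), log(2))
})

test_that("stratified five-fold splits are disjoint, exhaustive, balanced", {
  labels <- rep(c(0L, 1L), each = 5)
  folds <- five_fold_split(labels, seed = 3)
  val_idx <- unlist(lapply(folds, `[[`, "val"))
  expect_equal(sort(val_idx), 1:10)
  for (f in folds) {
    expect_length(intersect(f$train, f$val), 0)
    expect_equal(sum(labels[f$val] == 1), 1)
    expect_equal(sum(labels[f$val] == 0), 1)
  }
  expect_error(five_fold_split(c(0, 1, 0), seed = 1), "at least")

  # 20% positive ratio: per-fold positive fraction within 1/fold-size
  lab2 <- c(rep(1L, 20), rep(0L, 80))
  folds2 <- five_fold_split(lab2, seed = 9)
  for (f in folds2) {
    frac <- mean(lab2[f$val])
    expect_lte(abs(frac - 0.2), 1 / length(f$val))
  }
})

test_that("training is seeded-reproducible and improves an untrained net", {
  tr <- phantom_dataset(8, seed = 881)
  cfg <- tiny_cfg("segmentation")
  m1 <- train_segmenter(build_lwbna_unet(cfg, seed = 2), tr$images, tr$masks,
    epochs = 2, seed = 11, lr = 1e-3, batch_size = 4
  )
  m2 <- train_segmenter(build_lwbna_unet(cfg, seed = 2), tr$images, tr$masks,
    epochs = 2, seed = 11, lr = 1e-3, batch_size = 4
  )
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  # a trained model no longer matches the untrained one
  u0 <- build_lwbna_unet(cfg, seed = 2)
  x <- tr$images[, , , 1:2]
  expect_false(isTRUE(all.equal(model_forward(u0, x), model_forward(m1, x))))
  expect_error(train_segmenter(u0, tr$images[, , , 0, drop = FALSE],
    tr$masks[, , , 0, drop = FALSE],
    epochs = 1
  ), "empty")
})

test_that("dice training loss decreases over early epochs across seeds", {
  tr <- phantom_dataset(20, seed = 991)
  ok <- 0
  for (s in 1:5) {
    m <- build_lwbna_unet(tiny_cfg("segmentation"), seed = s)
    m <- train_segmenter(m, tr$images, tr$masks,
      epochs = 5, seed = s,
      lr = 1e-3, batch_size = 8
    )
    if (all(diff(m$history$loss) < 0)) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("model bundles round-trip through serialisation unchanged", {
  m <- trained_fusion()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  probe <- matrix(runif(40), 10, 4)
  expect_identical(model_forward(m, probe), model_forward(m2, probe))
})
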