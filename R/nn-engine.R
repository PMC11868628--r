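# Minimal training engine for the lightweight attention-bottleneck model family.
#
# Tensors are column-major R arrays with dim (H, W, C, N); dense activations
# are N x D matrices. Heavy kernels (convolution, pooling, upsampling) are
# compiled (src/convops.cpp); the rest is plain R so that every layer stays
# inspectable. All stochastic steps (init, dropout, shuffling) draw from R's
# RNG so a single set.seed() makes runs reproducible.

# ---- layer descriptors -----------------------------------------------------

nn_conv <- function(name, k, cin, cout, act = "relu") {
  list(type = "conv", name = name, k = k, cin = cin, cout = cout, act = act)
}
nn_pool <- function(name) list(type = "pool", name = name)
nn_upsample <- function(name) list(type = "upsample", name = name)
nn_se_att <- function(name, c, r = 4L) {
  list(type = "se_att", name = name, c = c, ch = max(1L, c %/% r))
}
nn_flatten <- function(name) list(type = "flatten", name = name)
nn_dense <- function(name, nin, nout, act = "relu") {
  list(type = "dense", name = name, nin = nin, nout = nout, act = act)
}
nn_dropout <- function(name, rate) list(type = "dropout", name = name, rate = rate)

# He-uniform initialisation; seeded by the caller
init_layer_params <- function(layer) {
  he <- function(fan_in, n) {
    lim <- sqrt(6 / fan_in)
    stats::runif(n, -lim, lim)
  }
  switch(layer$type,
    conv = {
      k <- layer$k
      n <- k * k * layer$cin * layer$cout
      list(
        W = array(he(k * k * layer$cin, n), c(k, k, layer$cin, layer$cout)),
        b = numeric(layer$cout)
      )
    },
    se_att = list(
      W1 = matrix(he(layer$c, layer$c * layer$ch), layer$c, layer$ch),
      b1 = numeric(layer$ch),
      W2 = matrix(he(layer$ch, layer$ch * layer$c), layer$ch, layer$c),
      b2 = numeric(layer$c)
    ),
    dense = list(
      W = matrix(he(layer$nin, layer$nin * layer$nout), layer$nin, layer$nout),
      b = numeric(layer$nout)
    ),
    NULL
  )
}

init_params <- function(layers) {
  params <- list()
  for (layer in layers) {
    p <- init_layer_params(layer)
    if (!is.null(p)) {
      names(p) <- paste(layer$name, names(p), sep = ".")
      params <- c(params, p)
    }
  }
  params
}

n_params <- function(params) sum(vapply(params, length, integer(1)))

# ---- activations -----------------------------------------------------------

act_fw <- function(z, act) {
  switch(act,
    relu = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    linear = z,
    softmax = {
      z <- z - apply(z, 1, max)
      e <- exp(z)
      e / rowSums(e)
    },
    stop("unknown activation: ", act)
  )
}

# gradient wrt pre-activation given output y and upstream dy
# (softmax is only used fused with cross-entropy; see loss_ce_grad)
act_bw <- function(dy, y, act) {
  switch(act,
    relu = dy * (y > 0),
    sigmoid = dy * y * (1 - y),
    linear = dy,
    stop("no standalone backward for activation: ", act)
  )
}

gap_fw <- function(x) {
  d <- dim(x)
  s <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
  t(matrix(s, d[3], d[4])) # N x C
}

# ---- layer forward/backward ------------------------------------------------

layer_fw <- function(layer, params, x, training = FALSE) {
  nm <- layer$name
  switch(layer$type,
    conv = {
      z <- cpp_conv2d_fw(x, params[[paste0(nm, ".W")]], params[[paste0(nm, ".b")]])
      y <- act_fw(z, layer$act)
      list(y = y, cache = list(x = x, y = y))
    },
    pool = {
      r <- cpp_maxpool2_fw(x)
      list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)))
    },
    upsample = list(y = cpp_upsample2_fw(x), cache = NULL),
    se_att = {
      s <- gap_fw(x) # N x C
      z1 <- sweep(s %*% params[[paste0(nm, ".W1")]], 2, params[[paste0(nm, ".b1")]], "+")
      h <- pmax(z1, 0)
      z2 <- sweep(h %*% params[[paste0(nm, ".W2")]], 2, params[[paste0(nm, ".b2")]], "+")
      a <- 1 / (1 + exp(-z2)) # N x C gates in (0,1)
      d <- dim(x)
      ax <- rep(t(a), each = d[1] * d[2]) # broadcast over H,W
      y <- x * array(ax, d)
      list(y = y, cache = list(x = x, s = s, h = h, a = a))
    },
    flatten = {
      d <- dim(x)
      list(y = t(matrix(x, prod(d[1:3]), d[4])), cache = list(xdim = d))
    },
    dense = {
      z <- sweep(x %*% params[[paste0(nm, ".W")]], 2, params[[paste0(nm, ".b")]], "+")
      y <- act_fw(z, layer$act)
      list(y = y, cache = list(x = x, y = y))
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (stats::runif(length(x)) >= layer$rate) / (1 - layer$rate)
        dim(mask) <- dim(x)
        list(y = x * mask, cache = list(mask = mask))
      } else {
        list(y = x, cache = list(mask = NULL))
      }
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_bw <- function(layer, params, cache, dy) {
  nm <- layer$name
  switch(layer$type,
    conv = {
      dz <- act_bw(dy, cache$y, layer$act)
      g <- cpp_conv2d_bw(cache$x, params[[paste0(nm, ".W")]], dz)
      grads <- list(g$dw, g$db)
      names(grads) <- paste0(nm, c(".W", ".b"))
      list(dx = g$dx, grads = grads)
    },
    pool = list(dx = cpp_maxpool2_bw(cache$idx, dy, cache$xdim), grads = list()),
    upsample = list(dx = cpp_upsample2_bw(dy), grads = list()),
    se_att = {
      x <- cache$x
      d <- dim(x)
      a <- cache$a
      HW <- d[1] * d[2]
      ax <- array(rep(t(a), each = HW), d)
      # da[n,c] = sum_hw dy * x
      da <- t(matrix(colSums(matrix(dy * x, HW, d[3] * d[4])), d[3], d[4]))
      dz2 <- da * a * (1 - a)
      W2 <- params[[paste0(nm, ".W2")]]
      W1 <- params[[paste0(nm, ".W1")]]
      dW2 <- t(cache$h) %*% dz2
      db2 <- colSums(dz2)
      dh <- dz2 %*% t(W2)
      dz1 <- dh * (cache$h > 0)
      dW1 <- t(cache$s) %*% dz1
      db1 <- colSums(dz1)
      ds <- dz1 %*% t(W1) # N x C
      dx <- dy * ax + array(rep(t(ds / HW), each = HW), d)
      grads <- list(dW1, db1, dW2, db2)
      names(grads) <- paste0(nm, c(".W1", ".b1", ".W2", ".b2"))
      list(dx = dx, grads = grads)
    },
    flatten = {
      dx <- t(dy)
      dim(dx) <- cache$xdim
      list(dx = dx, grads = list())
    },
    dense = {
      dz <- if (layer$act == "softmax") dy else act_bw(dy, cache$y, layer$act)
      W <- params[[paste0(nm, ".W")]]
      grads <- list(t(cache$x) %*% dz, colSums(dz))
      names(grads) <- paste0(nm, c(".W", ".b"))
      list(dx = dz %*% t(W), grads = grads)
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = list())
      else list(dx = dy * cache$mask, grads = list())
    }
  )
}

seq_fw <- function(layers, params, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fw(layers[[i]], params, x, training)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

seq_bw <- function(layers, params, caches, dy) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    r <- layer_bw(layers[[i]], params, caches[[i]], dy)
    dy <- r$dx
    grads <- c(grads, r$grads)
  }
  list(dx = dy, grads = grads)
}

concat_channels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

split_channels <- function(dy, c1) {
  d <- dim(dy)
  list(
    a = array(dy[, , seq_len(c1), ], c(d[1], d[2], c1, d[4])),
    b = array(dy[, , (c1 + 1):d[3], ], c(d[1], d[2], d[3] - c1, d[4]))
  )
}

# ---- losses ----------------------------------------------------------------

#' Soergel-smoothed Dice loss between predicted and reference masks
#'
#' Computes `1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) + eps)` averaged over
#' samples and mask planes, the segmentation loss used to train the U-net
#' models. The smoothing constant keeps the loss defined (and near 0) when
#' both masks are empty.
#'
#' @param pred Predicted mask array, dim (H, W, planes, N), values in `[0, 1]`.
#' @param truth Reference mask array of the same dim.
#' @param eps Smoothing constant added to numerator and denominator.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, truth, eps = 1) {
  d <- dim(pred)
  stopifnot(identical(d, dim(truth)))
  HW <- d[1] * d[2]
  m <- d[3] * d[4]
  p <- matrix(pred, HW, m)
  t <- matrix(truth, HW, m)
  num <- 2 * colSums(p * t) + eps
  den <- colSums(p) + colSums(t) + eps
  mean(1 - num / den)
}

dice_loss_grad <- function(pred, truth, eps = 1) {
  d <- dim(pred)
  HW <- d[1] * d[2]
  m <- d[3] * d[4]
  p <- matrix(pred, HW, m)
  t <- matrix(truth, HW, m)
  num <- 2 * colSums(p * t) + eps
  den <- colSums(p) + colSums(t) + eps
  # d/dp_i [num/den] = (2 t_i * den - num) / den^2
  g <- -(sweep(2 * t, 2, den, "*") - matrix(num, HW, m, byrow = TRUE)) /
    matrix(den^2, HW, m, byrow = TRUE) / m
  array(g, d)
}

#' Categorical cross-entropy for one-hot labels
#'
#' @param prob N x K matrix of predicted class probabilities (rows sum to 1).
#' @param onehot N x K one-hot label matrix.
#' @return Mean negative log-likelihood.
#' @export
cross_entropy <- function(prob, onehot) {
  -mean(log(pmax(rowSums(prob * onehot), 1e-12)))
}

# gradient wrt the softmax pre-activation (fused softmax + CE)
loss_ce_grad <- function(prob, onehot) (prob - onehot) / nrow(prob)

# ---- optimiser -------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

accumulate_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
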