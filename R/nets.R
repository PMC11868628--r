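# Model family: binary classifier (encoder + BNA + FC head), LWBNA-style
# U-net segmenter, multi-task variant with a classification branch off the
# bottleneck, and the feedforward fully connected network (FFCN) used for
# numeric-feature decisions and final fusion.

#' Architecture configuration for the attention-bottleneck model family
#'
#' Describes one member of the lightweight model family. The encoder opens
#' with a `stem_kernel` x `stem_kernel` convolution to `base_channels`
#' filters, then repeats (3x3 convolution doubling the channel count up to
#' `channel_cap`, 2x2 max-pool) `encoder_stages` times. The bottleneck
#' narrowing-with-attention (BNA) block then halves the channel count step by
#' step down to `bna_out_channels`, gating each step with squeeze-excitation
#' channel attention. Classification heads flatten the BNA output and apply
#' two fully-connected + dropout blocks before a 2-way softmax.
#'
#' At the reference setting (512 input, 16 base channels, 5 stages) the
#' encoder terminal is 16x16x256 and the BNA output 16x16x8; the reference
#' multi-task setting (4 stages, BNA to 16 channels) branches at 32x32x16.
#'
#' @param input_side Input image side in pixels (square input).
#' @param input_channels Number of input channels (3 for RGB, 6 for
#'   mask-assisted classification).
#' @param base_channels Filters produced by the stem convolution.
#' @param encoder_stages Number of conv + max-pool stages.
#' @param bna_out_channels Channel count at the BNA output.
#' @param fc_widths Widths of the two fully-connected head layers.
#' @param dropout_rates Dropout rates after each head layer.
#' @param heads Character vector, subset of `c("classification",
#'   "segmentation")`.
#' @param stem_kernel Kernel side of the stem convolution.
#' @param channel_cap Maximum channel count reached by doubling.
#' @param se_reduction Reduction ratio of the squeeze-excitation attention.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(input_side = 512L, input_channels = 3L,
                        base_channels = 16L, encoder_stages = 5L,
                        bna_out_channels = 8L, fc_widths = c(288L, 196L),
                        dropout_rates = c(0.2, 0.2),
                        heads = "classification", stem_kernel = 5L,
                        channel_cap = 256L, se_reduction = 4L) {
  input_side <- as.integer(input_side)
  encoder_stages <- as.integer(encoder_stages)
  if (input_side %% 2L^encoder_stages != 0L) {
    stop("input_side must be divisible by 2^encoder_stages")
  }
  terminal_side <- input_side %/% 2L^encoder_stages
  if (terminal_side < 2L) stop("encoder terminal side below 2 px; reduce encoder_stages")
  ch <- base_channels
  enc_channels <- integer(encoder_stages)
  for (i in seq_len(encoder_stages)) {
    ch <- min(2L * ch, as.integer(channel_cap))
    enc_channels[i] <- ch
  }
  terminal_channels <- enc_channels[encoder_stages]
  if (bna_out_channels >= terminal_channels) {
    stop("bna_out_channels must be below the encoder terminal channel count")
  }
  if (any(fc_widths <= 0)) stop("fc widths must be positive")
  if (!all(heads %in% c("classification", "segmentation"))) {
    stop("heads must be a subset of classification/segmentation")
  }
  structure(list(
    input_side = input_side, input_channels = as.integer(input_channels),
    base_channels = as.integer(base_channels),
    encoder_stages = encoder_stages,
    enc_channels = enc_channels,
    encoder_terminal = c(side = terminal_side, channels = terminal_channels),
    bna_out_channels = as.integer(bna_out_channels),
    fc_widths = as.integer(fc_widths), dropout_rates = dropout_rates,
    heads = heads, stem_kernel = as.integer(stem_kernel),
    channel_cap = as.integer(channel_cap),
    se_reduction = as.integer(se_reduction)
  ), class = "arch_config")
}

#' Reference configuration of the multi-task model
#'
#' Four encoder stages (terminal 32x32x256 at a 512 input) with the BNA
#' narrowing to 16 channels, so the classification branch taps a 32x32x16
#' bottleneck output.
#'
#' @param input_side Input side in pixels.
#' @param base_channels Stem filter count.
#' @param fc_widths Widths of the branch head layers.
#' @param ... Passed on to [arch_config()].
#' @return An `arch_config`.
#' @export
mtl_config <- function(input_side = 512L, base_channels = 16L,
                       fc_widths = c(64L, 32L), ...) {
  arch_config(
    input_side = input_side, base_channels = base_channels,
    encoder_stages = 4L, bna_out_channels = 16L, fc_widths = fc_widths,
    heads = c("segmentation", "classification"), ...
  )
}

# chain of channel counts through the BNA block (halving down to out)
bna_chain <- function(cin, cout) {
  ch <- cin
  chain <- integer(0)
  while (ch > cout) {
    ch <- max(ch %/% 2L, cout)
    chain <- c(chain, ch)
  }
  chain
}

#' Build a bottleneck-narrowing-with-attention (BNA) block
#'
#' The block keeps the spatial size and progressively halves the channel
#' count down to `out_channels`. Each narrowing step applies
#' squeeze-excitation channel attention (global average pool, a reduction
#' dense layer, and a sigmoid gate per channel) to its input, then a 1x1
#' convolution halving the channels.
#'
#' @param in_channels Channel count entering the block.
#' @param out_channels Channel count at the output; must be smaller than
#'   `in_channels`.
#' @param se_reduction Reduction ratio of the attention dense layer.
#' @param prefix Name prefix for the layers.
#' @return A list of layer descriptors.
#' @export
build_bna_module <- function(in_channels, out_channels, se_reduction = 4L,
                             prefix = "bna") {
  if (out_channels >= in_channels) {
    stop("out_channels must be smaller than in_channels")
  }
  chain <- bna_chain(in_channels, out_channels)
  layers <- list()
  cin <- in_channels
  for (i in seq_along(chain)) {
    layers <- c(layers, list(
      nn_se_att(sprintf("%s%d.att", prefix, i), cin, se_reduction),
      nn_conv(sprintf("%s%d.narrow", prefix, i), 1L, cin, chain[i], act = "relu")
    ))
    cin <- chain[i]
  }
  layers
}

encoder_layers <- function(cfg) {
  layers <- list(nn_conv("stem", cfg$stem_kernel, cfg$input_channels,
    cfg$base_channels,
    act = "relu"
  ))
  cin <- cfg$base_channels
  for (i in seq_len(cfg$encoder_stages)) {
    cout <- cfg$enc_channels[i]
    layers <- c(layers, list(
      nn_conv(sprintf("enc%d", i), 3L, cin, cout, act = "relu"),
      nn_pool(sprintf("pool%d", i))
    ))
    cin <- cout
  }
  layers
}

head_layers <- function(flat_dim, fc_widths, dropout_rates, prefix = "head") {
  list(
    nn_flatten(paste0(prefix, ".flatten")),
    nn_dense(paste0(prefix, "1"), flat_dim, fc_widths[1], act = "relu"),
    nn_dropout(paste0(prefix, "1.drop"), dropout_rates[1]),
    nn_dense(paste0(prefix, "2"), fc_widths[1], fc_widths[2], act = "relu"),
    nn_dropout(paste0(prefix, "2.drop"), dropout_rates[2]),
    nn_dense(paste0(prefix, ".out"), fc_widths[2], 2L, act = "softmax")
  )
}

new_model <- function(kind, cfg, layers, params, extra = list()) {
  structure(c(list(kind = kind, cfg = cfg, layers = layers, params = params),
    extra
  ), class = "aigs_model")
}

#' Build the binary classification model
#'
#' Encoder + BNA bottleneck, flattened into two fully-connected + dropout
#' blocks and a 2-way softmax. At the reference configuration
#' ([arch_config()] defaults) the trainable parameter count is 1,718,770.
#'
#' @param cfg An [arch_config()] with a classification head only.
#' @param seed Seed for weight initialisation.
#' @return An `aigs_model`.
#' @export
build_binary_classifier <- function(cfg = arch_config(), seed = 1L) {
  if (!identical(cfg$heads, "classification")) {
    stop("cfg must request the classification head only")
  }
  term <- cfg$encoder_terminal
  layers <- c(
    encoder_layers(cfg),
    build_bna_module(term["channels"], cfg$bna_out_channels, cfg$se_reduction),
    head_layers(
      term["side"]^2 * cfg$bna_out_channels, cfg$fc_widths,
      cfg$dropout_rates
    )
  )
  set.seed(seed)
  new_model("classifier", cfg, layers, init_params(layers))
}

decoder_plan <- function(cfg) {
  # decoder step i rebuilds the resolution of encoder stage i (pre-pool);
  # channels: half the skip width, floored at base_channels
  S <- cfg$encoder_stages
  skips <- cfg$enc_channels
  data.frame(
    stage = S:1,
    skip_channels = skips[S:1],
    out_channels = pmax(cfg$base_channels, skips[S:1] %/% 2L)
  )
}

unet_layers <- function(cfg) {
  plan <- decoder_plan(cfg)
  dec <- list()
  cin <- cfg$bna_out_channels
  for (r in seq_len(nrow(plan))) {
    st <- plan$stage[r]
    dec[[r]] <- nn_conv(sprintf("dec%d", st), 3L, cin + plan$skip_channels[r],
      plan$out_channels[r],
      act = "relu"
    )
    cin <- plan$out_channels[r]
  }
  list(
    dec = dec,
    final = nn_conv("seg.out", 1L, cin, 3L, act = "sigmoid")
  )
}

#' Build the lightweight attention-bottleneck U-net segmenter
#'
#' Encoder and BNA as in the classifier, plus a decoder that mirrors the
#' encoder (nearest-neighbour upsampling, concatenation with the stage's
#' pre-pool feature map, 3x3 convolution) and a final 1x1 convolution to a
#' 3-plane sigmoid map (disc, cup, fovea heatmap).
#'
#' @param cfg An [arch_config()] with a segmentation head.
#' @param seed Seed for weight initialisation.
#' @return An `aigs_model` of kind `"unet"`.
#' @export
build_lwbna_unet <- function(cfg = arch_config(heads = "segmentation"),
                             seed = 1L) {
  if (!"segmentation" %in% cfg$heads) stop("cfg must request a segmentation head")
  term <- cfg$encoder_terminal
  enc <- encoder_layers(cfg)
  bna <- build_bna_module(term["channels"], cfg$bna_out_channels, cfg$se_reduction)
  un <- unet_layers(cfg)
  all_layers <- c(enc, bna, un$dec, list(un$final))
  set.seed(seed)
  new_model("unet", cfg, all_layers, init_params(all_layers),
    extra = list(enc = enc, bna = bna, dec = un$dec, final = un$final)
  )
}

#' Build the multi-task segmentation + classification model
#'
#' The U-net of [build_lwbna_unet()] with a classification branch taken from
#' the BNA output (the bottleneck between encoder and decoder): flatten, two
#' fully-connected + dropout blocks, 2-way softmax. At the reference
#' multi-task configuration ([mtl_config()]) the branch point is 32x32x16.
#'
#' @param cfg An [arch_config()] requesting both heads (see [mtl_config()]).
#' @param seed Seed for weight initialisation.
#' @return An `aigs_model` of kind `"mtl"`.
#' @export
build_mtl_unet <- function(cfg = mtl_config(), seed = 1L) {
  if (!all(c("segmentation", "classification") %in% cfg$heads)) {
    stop("cfg must request both heads")
  }
  term <- cfg$encoder_terminal
  enc <- encoder_layers(cfg)
  bna <- build_bna_module(term["channels"], cfg$bna_out_channels, cfg$se_reduction)
  un <- unet_layers(cfg)
  branch <- head_layers(
    term["side"]^2 * cfg$bna_out_channels, cfg$fc_widths,
    cfg$dropout_rates,
    prefix = "branch"
  )
  all_layers <- c(enc, bna, un$dec, list(un$final), branch)
  set.seed(seed)
  new_model("mtl", cfg, all_layers, init_params(all_layers),
    extra = list(
      enc = enc, bna = bna, dec = un$dec, final = un$final,
      branch = branch
    )
  )
}

#' Build the feedforward fully connected network (FFCN)
#'
#' Seven dense layers of widths 16, 32, 64, 128, 64, 32, 16, each followed by
#' dropout, closed by a 2-way softmax. Used both for the cupping-parameter
#' decision and for the final fusion decision.
#'
#' @param n_inputs Number of input features.
#' @param dropout Dropout rate after each dense layer.
#' @param seed Seed for weight initialisation.
#' @return An `aigs_model` of kind `"ffcn"`.
#' @export
build_ffcn <- function(n_inputs, dropout = 0.1, seed = 1L) {
  if (n_inputs < 1) stop("n_inputs must be at least 1")
  widths <- c(16L, 32L, 64L, 128L, 64L, 32L, 16L)
  layers <- list()
  cin <- as.integer(n_inputs)
  for (i in seq_along(widths)) {
    layers <- c(layers, list(
      nn_dense(sprintf("fc%d", i), cin, widths[i], act = "relu"),
      nn_dropout(sprintf("fc%d.drop", i), dropout)
    ))
    cin <- widths[i]
  }
  layers <- c(layers, list(nn_dense("fc.out", cin, 2L, act = "softmax")))
  set.seed(seed)
  new_model("ffcn", NULL, layers, init_params(layers),
    extra = list(n_inputs = as.integer(n_inputs), widths = widths)
  )
}

#' Count trainable parameters of a model
#'
#' Sums all weights and biases over every trainable layer.
#'
#' @param model An `aigs_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  as.integer(n_params(model$params))
}

# ---- forward passes --------------------------------------------------------

unet_fw <- function(model, x, training = FALSE, with_branch = FALSE) {
  params <- model$params
  cfg <- model$cfg
  r <- layer_fw(model$enc[[1]], params, x, training) # stem
  caches <- list(stem = r$cache)
  xs <- r$y
  skips <- vector("list", cfg$encoder_stages)
  enc_caches <- vector("list", cfg$encoder_stages)
  pool_caches <- vector("list", cfg$encoder_stages)
  li <- 1
  for (i in seq_len(cfg$encoder_stages)) {
    rc <- layer_fw(model$enc[[li + 1]], params, xs, training)
    skips[[i]] <- rc$y
    enc_caches[[i]] <- rc$cache
    rp <- layer_fw(model$enc[[li + 2]], params, rc$y, training)
    xs <- rp$y
    pool_caches[[i]] <- rp$cache
    li <- li + 2
  }
  rb <- seq_fw(model$bna, params, xs, training)
  bna_out <- rb$y
  # decoder
  xs <- bna_out
  dec_caches <- vector("list", length(model$dec))
  up_c <- integer(length(model$dec))
  for (r_i in seq_along(model$dec)) {
    up <- cpp_upsample2_fw(xs)
    stage <- cfg$encoder_stages - r_i + 1L
    up_c[r_i] <- dim(up)[3]
    cat_in <- concat_channels(up, skips[[stage]])
    rc <- layer_fw(model$dec[[r_i]], params, cat_in, training)
    dec_caches[[r_i]] <- rc$cache
    xs <- rc$y
  }
  rf <- layer_fw(model$final, params, xs, training)
  out <- list(
    seg = rf$y, bna_out = bna_out,
    caches = list(
      stem = caches$stem, enc = enc_caches, pool = pool_caches,
      bna = rb$caches, dec = dec_caches, final = rf$cache, up_c = up_c
    )
  )
  if (with_branch) {
    rb2 <- seq_fw(model$branch, params, bna_out, training)
    out$prob <- rb2$y
    out$caches$branch <- rb2$caches
  }
  out
}

unet_bw <- function(model, fw, dseg, dprob = NULL) {
  params <- model$params
  cfg <- model$cfg
  ca <- fw$caches
  grads <- list()
  r <- layer_bw(model$final, params, ca$final, dseg)
  grads <- accumulate_grads(grads, r$grads)
  d <- r$dx
  dskips <- vector("list", cfg$encoder_stages)
  for (r_i in rev(seq_along(model$dec))) {
    stage <- cfg$encoder_stages - r_i + 1L
    rb <- layer_bw(model$dec[[r_i]], params, ca$dec[[r_i]], d)
    grads <- accumulate_grads(grads, rb$grads)
    sp <- split_channels(rb$dx, ca$up_c[r_i])
    dskips[[stage]] <- sp$b
    d <- cpp_upsample2_bw(sp$a)
  }
  # d is now the gradient at the BNA output
  if (!is.null(dprob)) {
    rb2 <- seq_bw(model$branch, params, ca$branch, dprob)
    grads <- accumulate_grads(grads, rb2$grads)
    d <- d + rb2$dx
  }
  rb <- seq_bw(model$bna, params, ca$bna, d)
  grads <- accumulate_grads(grads, rb$grads)
  d <- rb$dx
  for (i in rev(seq_len(cfg$encoder_stages))) {
    d <- cpp_maxpool2_bw(ca$pool[[i]]$idx, d, ca$pool[[i]]$xdim)
    d <- d + dskips[[i]]
    rc <- layer_bw(model$enc[[1 + 2 * i - 1]], params, ca$enc[[i]], d)
    grads <- accumulate_grads(grads, rc$grads)
    d <- rc$dx
  }
  rs <- layer_bw(model$enc[[1]], params, ca$stem, d)
  grads <- accumulate_grads(grads, rs$grads)
  grads
}

#' Run a model forward
#'
#' @param model An `aigs_model`.
#' @param x Input batch: an array (H, W, C, N) for convolutional models (a
#'   single (H, W, C) image is promoted to a batch of one) or a numeric
#'   matrix N x D for the FFCN.
#' @param batch_size Inputs processed per forward chunk.
#' @return Classifier/FFCN: N x 2 probability matrix. U-net: (H, W, 3, N)
#'   sigmoid map. Multi-task model: list with `seg` and `prob`.
#' @export
model_forward <- function(model, x, batch_size = 8L) {
  if (model$kind == "ffcn") {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    return(seq_fw(model$layers, model$params, x, training = FALSE)$y)
  }
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  outs <- lapply(chunks, function(idx) {
    xb <- x[, , , idx, drop = FALSE]
    switch(model$kind,
      classifier = seq_fw(model$layers, model$params, xb, training = FALSE)$y,
      unet = unet_fw(model, xb)$seg,
      mtl = {
        fw <- unet_fw(model, xb, with_branch = TRUE)
        list(seg = fw$seg, prob = fw$prob)
      }
    )
  })
  if (model$kind == "classifier") {
    do.call(rbind, outs)
  } else if (model$kind == "unet") {
    abind4(outs)
  } else {
    list(
      seg = abind4(lapply(outs, `[[`, "seg")),
      prob = do.call(rbind, lapply(outs, `[[`, "prob"))
    )
  }
}

abind4 <- function(lst) {
  d <- dim(lst[[1]])
  n <- sum(vapply(lst, function(a) dim(a)[4], numeric(1)))
  out <- array(0, c(d[1:3], n))
  at <- 1L
  for (a in lst) {
    k <- dim(a)[4]
    out[, , , at:(at + k - 1L)] <- a
    at <- at + k
  }
  out
}

# ---- shape tracing ---------------------------------------------------------

#' Trace output shapes through a model
#'
#' Walks the layer graph analytically and reports the output shape of every
#' layer, for structural audits (encoder terminal, BNA output, branch point,
#' head widths) without running a forward pass.
#'
#' @param model An `aigs_model`.
#' @return A data.frame with layer name, type, and output shape string.
#' @export
trace_shapes <- function(model) {
  if (model$kind == "ffcn") {
    shp <- model$n_inputs
    rows <- lapply(model$layers, function(l) {
      if (l$type == "dense") shp <<- l$nout
      data.frame(name = l$name, type = l$type, out = paste0("N x ", shp))
    })
    return(do.call(rbind, rows))
  }
  cfg <- model$cfg
  side <- cfg$input_side
  ch <- cfg$input_channels
  flat <- NA_integer_
  trace_one <- function(l) {
    if (l$type == "conv") {
      ch <<- l$cout
    } else if (l$type == "pool") {
      side <<- side %/% 2L
    } else if (l$type == "upsample") {
      side <<- side * 2L
    } else if (l$type == "flatten") {
      flat <<- side^2 * ch
    } else if (l$type == "dense") {
      flat <<- l$nout
    }
    out <- if (l$type %in% c("flatten", "dense", "dropout") && !is.na(flat)) {
      paste0("N x ", flat)
    } else {
      sprintf("%d x %d x %d", side, side, ch)
    }
    data.frame(name = l$name, type = l$type, out = out)
  }
  if (model$kind == "classifier") {
    return(do.call(rbind, lapply(model$layers, trace_one)))
  }
  # unet / mtl: encoder + bna, then decoder, then branch from the bna output
  rows <- lapply(c(model$enc, model$bna), trace_one)
  bna_side <- side
  bna_ch <- ch
  for (i in seq_along(model$dec)) {
    side <- side * 2L
    skip_ch <- cfg$enc_channels[cfg$encoder_stages - i + 1L]
    rows <- c(rows, list(data.frame(
      name = sprintf("up%d+skip", i), type = "upsample/concat",
      out = sprintf("%d x %d x %d", side, side, ch + skip_ch)
    )))
    ch <- model$dec[[i]]$cout
    rows <- c(rows, list(data.frame(
      name = model$dec[[i]]$name, type = "conv",
      out = sprintf("%d x %d x %d", side, side, ch)
    )))
  }
  ch <- 3L
  rows <- c(rows, list(data.frame(
    name = "seg.out", type = "conv",
    out = sprintf("%d x %d x %d", side, side, ch)
  )))
  if (model$kind == "mtl") {
    side <- bna_side
    ch <- bna_ch
    flat <- side^2 * ch
    rows <- c(rows, list(data.frame(
      name = "branch.point", type = "tap",
      out = sprintf("%d x %d x %d", side, side, ch)
    )))
    for (l in model$branch) rows <- c(rows, list(trace_one(l)))
  }
  do.call(rbind, rows)
}

#' Architecture manifest
#'
#' JSON-serialisable summary of a model: layer table, per-layer parameter
#' counts, and the trainable total, for cross-checking builds.
#'
#' @param model An `aigs_model`.
#' @return A list with `kind`, `layers`, `param_counts`, `n_params`.
#' @export
model_manifest <- function(model) {
  list(
    kind = model$kind,
    layers = trace_shapes(model),
    param_counts = vapply(model$params, length, integer(1)),
    n_params = count_parameters(model)
  )
}

# ---- training --------------------------------------------------------------

slice_batch <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[, , , idx, drop = FALSE]
}

onehot2 <- function(labels) {
  y <- matrix(0, length(labels), 2)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

#' Train a segmentation model with Dice loss
#'
#' Minimises `1 - Dice` with Adam. The run is deterministic for a fixed seed
#' on one machine: shuffling and dropout draw from R's RNG.
#'
#' @param model An `aigs_model` of kind `"unet"`.
#' @param images Array (H, W, C, N) of training images.
#' @param masks Array (H, W, 3, N) of reference masks.
#' @param epochs Training epochs.
#' @param seed RNG seed.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param validation Optional list(images, masks) evaluated each epoch.
#' @return The model with trained parameters and a `history` data.frame
#'   (epoch, loss, val_loss).
#' @export
train_segmenter <- function(model, images, masks, epochs = 10L, seed = 1L,
                            lr = 1e-4, batch_size = 8L, validation = NULL) {
  n <- dim(images)[4]
  if (is.null(n) || n < 1) stop("empty dataset")
  set.seed(seed)
  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), loss = numeric(0), val_loss = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- slice_batch(images, idx)
      tb <- slice_batch(masks, idx)
      fw <- unet_fw(model, xb, training = TRUE)
      loss <- dice_loss(fw$seg, tb)
      dseg <- dice_loss_grad(fw$seg, tb)
      grads <- unet_bw(model, fw, dseg)
      st <- adam_step(model$params, grads, state, lr = lr)
      model$params <- st$params
      state <- st$state
      ep_loss <- ep_loss + loss
      nb <- nb + 1
    }
    val <- NA_real_
    if (!is.null(validation)) {
      pred <- model_forward(model, validation$images)
      val <- dice_loss(pred, validation$masks)
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_loss / nb,
      val_loss = val
    ))
  }
  model$history <- history
  model
}

#' Train a classification model with categorical cross-entropy
#'
#' Works for the encoder-based binary classifier and for the FFCN.
#'
#' @param model An `aigs_model` of kind `"classifier"` or `"ffcn"`.
#' @param x Inputs: array (H, W, C, N) or matrix N x D for the FFCN.
#' @param labels Integer vector of 0/1 labels.
#' @param epochs Training epochs.
#' @param seed RNG seed.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param validation Optional list(x, labels) evaluated each epoch.
#' @return The model with trained parameters and a `history` data.frame.
#' @export
train_classifier <- function(model, x, labels, epochs = 10L, seed = 1L,
                             lr = 1e-4, batch_size = 16L, validation = NULL) {
  n <- if (is.matrix(x)) nrow(x) else dim(x)[4]
  if (is.null(n) || n < 1) stop("empty dataset")
  stopifnot(length(labels) == n)
  set.seed(seed)
  y <- onehot2(labels)
  state <- adam_init(model$params)
  history <- data.frame()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- slice_batch(x, idx)
      fw <- seq_fw(model$layers, model$params, xb, training = TRUE)
      loss <- cross_entropy(fw$y, y[idx, , drop = FALSE])
      dy <- loss_ce_grad(fw$y, y[idx, , drop = FALSE])
      bw <- seq_bw(model$layers, model$params, fw$caches, dy)
      st <- adam_step(model$params, bw$grads, state, lr = lr)
      model$params <- st$params
      state <- st$state
      ep_loss <- ep_loss + loss
      nb <- nb + 1
    }
    val <- NA_real_
    if (!is.null(validation)) {
      pv <- model_forward(model, validation$x)
      val <- cross_entropy(pv, onehot2(validation$labels))
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_loss / nb,
      val_loss = val
    ))
  }
  model$history <- history
  model
}

#' Train the multi-task model (Dice + cross-entropy)
#'
#' @param model An `aigs_model` of kind `"mtl"`.
#' @param images,masks,labels Training data.
#' @param epochs,seed,lr,batch_size Training controls.
#' @param lambda_cls Weight of the classification loss term.
#' @return Trained model with `history`.
#' @export
train_mtl <- function(model, images, masks, labels, epochs = 10L, seed = 1L,
                      lr = 1e-4, batch_size = 8L, lambda_cls = 1) {
  n <- dim(images)[4]
  if (is.null(n) || n < 1) stop("empty dataset")
  set.seed(seed)
  y <- onehot2(labels)
  state <- adam_init(model$params)
  history <- data.frame()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- slice_batch(images, idx)
      tb <- slice_batch(masks, idx)
      fw <- unet_fw(model, xb, training = TRUE, with_branch = TRUE)
      loss <- dice_loss(fw$seg, tb) +
        lambda_cls * cross_entropy(fw$prob, y[idx, , drop = FALSE])
      dseg <- dice_loss_grad(fw$seg, tb)
      dprob <- lambda_cls * loss_ce_grad(fw$prob, y[idx, , drop = FALSE])
      grads <- unet_bw(model, fw, dseg, dprob)
      st <- adam_step(model$params, grads, state, lr = lr)
      model$params <- st$params
      state <- st$state
      ep_loss <- ep_loss + loss
      nb <- nb + 1
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / nb))
  }
  model$history <- history
  model
}

#' Stratified five-fold cross-validation split
#'
#' Folds are disjoint, exhaustive, and stratified: the positive count per
#' fold deviates from the global ratio by at most one item.
#'
#' @param labels Integer 0/1 labels.
#' @param seed RNG seed.
#' @param k Number of folds.
#' @return List of k elements, each `list(train = idx, val = idx)`.
#' @export
five_fold_split <- function(labels, seed = 1L, k = 5L) {
  n <- length(labels)
  if (n < k) stop("need at least k items")
  set.seed(seed)
  fold_of <- integer(n)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), val = which(fold_of == f))
  })
}

# ---- persistence -----------------------------------------------------------

#' Save / load a model or model bundle
#'
#' Models are plain R lists; serialisation is RDS. A reloaded model produces
#' identical outputs on a fixed input.
#'
#' @param model An `aigs_model` or bundle list.
#' @param path File path.
#' @return `load_model` returns the model; `save_model` its path, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
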