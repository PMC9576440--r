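#' Model configuration for the 2D ResUnet
#'
#' A U-shaped encoder-decoder whose convolutional blocks concatenate their
#' input feature maps with their convolved output ("Res" blocks), on top of
#' the usual U-Net skip connections. Activations are Leaky-ReLU, each
#' convolution is followed by batch normalization, downsampling is 2x2
#' max-pooling, upsampling is bilinear followed by a 1x1 convolution, and
#' dropout is applied at the two deepest levels. The final 1x1 projection
#' feeds a sigmoid, so the output is a per-pixel lung probability map.
#'
#' @param in_channels input channels (CT slices: 1).
#' @param base_channels convolved channels of the first encoder block
#'   (default 32; reduce for small studies).
#' @param depth number of down/up levels (>= 1; input side must be divisible
#'   by `2^depth`).
#' @param leaky_slope negative-slope coefficient of Leaky-ReLU.
#' @param dropout_rate dropout probability in \[0, 1\], applied at the
#'   deepest encoder level and the bottleneck during training.
#' @param out_channels output channels (1, sigmoid probability).
#' @param residual if `TRUE` (default) blocks concatenate input with
#'   convolved features; `FALSE` gives a plain U-Net block (ablation
#'   baseline).
#' @param hu_window HU window used to normalize inputs before the network.
#' @return object of class `model_config`.
#' @export
model_config <- function(in_channels = 1, base_channels = 32, depth = 4,
                         leaky_slope = 0.01, dropout_rate = 0.2,
                         out_channels = 1, residual = TRUE,
                         hu_window = c(-1000, 400)) {
  check_scalar(in_channels, "in_channels", lower = 1, integer = TRUE)
  check_scalar(base_channels, "base_channels", lower = 1, integer = TRUE)
  check_scalar(depth, "depth", lower = 1, integer = TRUE)
  check_scalar(leaky_slope, "leaky_slope", lower = 0, upper = 1)
  check_scalar(dropout_rate, "dropout_rate", lower = 0, upper = 1)
  check_scalar(out_channels, "out_channels", lower = 1, integer = TRUE)
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), leaky_slope = leaky_slope,
                 dropout_rate = dropout_rate,
                 out_channels = as.integer(out_channels),
                 residual = isTRUE(residual), hu_window = hu_window),
            class = "model_config")
}

init_conv <- function(P, pfx, k, cin, cout, slope) {
  ini <- conv_init(k, cin, cout, slope)
  P[[paste0(pfx, ".W")]] <- ini$W
  P[[paste0(pfx, ".b")]] <- ini$b
}

init_conv_bn <- function(P, B, pfx, k, cin, cout, slope) {
  init_conv(P, pfx, k, cin, cout, slope)
  P[[paste0(pfx, ".g")]] <- rep(1, cout)
  P[[paste0(pfx, ".be")]] <- rep(0, cout)
  B[[paste0(pfx, ".rm")]] <- rep(0, cout)
  B[[paste0(pfx, ".rv")]] <- rep(1, cout)
}

init_resblock <- function(P, B, pfx, cin, ch, slope) {
  init_conv_bn(P, B, paste0(pfx, ".c1"), 3L, cin, ch, slope)
  init_conv_bn(P, B, paste0(pfx, ".c2"), 3L, ch, ch, slope)
}

# conv -> batchnorm -> leaky-relu unit
cbl_fwd <- function(net, pfx, x, mode) {
  P <- net$P; B <- net$B
  y1 <- conv_fwd(x, P[[paste0(pfx, ".W")]], P[[paste0(pfx, ".b")]])
  bn <- bn_fwd(y1, P[[paste0(pfx, ".g")]], P[[paste0(pfx, ".be")]],
               B[[paste0(pfx, ".rm")]], B[[paste0(pfx, ".rv")]], mode)
  if (mode == "train") {
    B[[paste0(pfx, ".rm")]] <- bn$rm
    B[[paste0(pfx, ".rv")]] <- bn$rv
  }
  a <- lrelu_fwd(bn$y, net$cfg$leaky_slope)
  list(out = a, cache = list(x = x, z = bn$y, bn = bn$cache))
}

cbl_bwd <- function(net, pfx, dout, cache, G) {
  P <- net$P
  dz <- lrelu_bwd(dout, cache$z, net$cfg$leaky_slope)
  bnb <- bn_bwd(dz, cache$bn, P[[paste0(pfx, ".g")]])
  acc_grad(G, paste0(pfx, ".g"), bnb$dgamma)
  acc_grad(G, paste0(pfx, ".be"), bnb$dbeta)
  cb <- conv_bwd(cache$x, P[[paste0(pfx, ".W")]], bnb$dx)
  acc_grad(G, paste0(pfx, ".W"), cb$dw)
  acc_grad(G, paste0(pfx, ".b"), cb$db)
  cb$dx
}

acc_grad <- function(G, name, g) {
  if (is.null(G[[name]])) G[[name]] <- g else G[[name]] <- G[[name]] + g
}

resblock_fwd <- function(net, pfx, x, mode) {
  x <- as_nhwc(x)
  c1 <- cbl_fwd(net, paste0(pfx, ".c1"), x, mode)
  c2 <- cbl_fwd(net, paste0(pfx, ".c2"), c1$out, mode)
  out <- if (net$cfg$residual) concat_c(x, c2$out) else c2$out
  list(out = out,
       cache = list(c1 = c1$cache, c2 = c2$cache, cin = dim(x)[3]))
}

resblock_bwd <- function(net, pfx, dout, cache, G) {
  if (net$cfg$residual) {
    sp <- split_c(dout, cache$cin)
    dx_direct <- sp$a
    da2 <- sp$b
  } else {
    dx_direct <- 0
    da2 <- dout
  }
  da1 <- cbl_bwd(net, paste0(pfx, ".c2"), da2, cache$c2, G)
  dx <- cbl_bwd(net, paste0(pfx, ".c1"), da1, cache$c1, G)
  dx + dx_direct
}

#' Build a ResUnet (or plain U-Net) segmentation network
#'
#' Constructs the parameter set of the encoder-decoder described in
#' [model_config()]: `depth` encoder levels (block + 2x2 max-pool), a
#' bottleneck block, `depth` decoder levels (bilinear upsample + 1x1
#' convolution + skip concatenation + block), and a final 1x1 projection
#' with sigmoid. Channel bookkeeping is audited at construction: with
#' residual (concatenating) blocks, every block's output channel count is
#' the sum of its input and convolved channels.
#'
#' @param cfg a [model_config()].
#' @param seed optional integer seed for weight initialization.
#' @return object of class `resunet`.
#' @export
build_resunet <- function(cfg = model_config(), seed = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  P <- new.env(parent = emptyenv())
  B <- new.env(parent = emptyenv())
  depth <- cfg$depth
  res <- cfg$residual
  sl <- cfg$leaky_slope
  plan <- list(enc = vector("list", depth), dec = vector("list", depth))
  cin <- cfg$in_channels
  for (d in seq_len(depth)) {
    m <- cfg$base_channels * 2L^(d - 1L)
    out <- if (res) cin + m else m
    init_resblock(P, B, sprintf("enc%d", d), cin, m, sl)
    plan$enc[[d]] <- list(cin = cin, m = m, out = out)
    cin <- out
  }
  mb <- cfg$base_channels * 2L^depth
  init_resblock(P, B, "bott", cin, mb, sl)
  plan$bott <- list(cin = cin, m = mb, out = if (res) cin + mb else mb)
  prev <- plan$bott$out
  for (d in rev(seq_len(depth))) {
    m <- plan$enc[[d]]$m
    init_conv(P, sprintf("up%d", d), 1L, prev, m, sl)
    cat_ch <- m + plan$enc[[d]]$out
    init_resblock(P, B, sprintf("dec%d", d), cat_ch, m, sl)
    plan$dec[[d]] <- list(up_in = prev, up_out = m, cat = cat_ch,
                          out = if (res) cat_ch + m else m)
    prev <- plan$dec[[d]]$out
  }
  init_conv(P, "final", 1L, prev, cfg$out_channels, sl)
  structure(list(cfg = cfg, P = P, B = B, plan = plan), class = "resunet")
}

#' Number of trainable parameters of a network
#' @param net a `resunet`.
#' @return integer parameter count.
#' @export
count_parameters <- function(net) {
  sum(vapply(ls(net$P), function(n) length(net$P[[n]]), numeric(1)))
}

#' Forward pass of the network
#'
#' @param net a `resunet`.
#' @param x input array (H, W, C) or batch (H, W, C, N), already normalized
#'   to \[0, 1\].
#' @param mode `"train"` (batch statistics, dropout active) or `"eval"`
#'   (running statistics, deterministic).
#' @param want_cache keep the activation caches needed for a backward pass.
#' @return list with `prob` ((H, W, out_channels, N) probability array in
#'   \[0, 1\]) and, if requested, `cache`.
#' @export
resunet_forward <- function(net, x, mode = c("eval", "train"),
                            want_cache = FALSE) {
  mode <- match.arg(mode)
  x <- as_nhwc(x)
  cfg <- net$cfg
  side <- dim(x)[1:2]
  if (any(side %% 2L^cfg$depth != 0))
    stop(sprintf(
      "configuration error: input side %dx%d not divisible by 2^depth = %d",
      side[1], side[2], 2L^cfg$depth), call. = FALSE)
  depth <- cfg$depth

  rec <- function(d, x) {
    if (d > depth) {
      rb <- resblock_fwd(net, "bott", x, mode)
      dp <- dropout_fwd(rb$out, cfg$dropout_rate, mode)
      return(list(out = dp$y,
                  cache = if (want_cache) list(rb = rb$cache,
                                               dmask = dp$mask)))
    }
    e <- resblock_fwd(net, sprintf("enc%d", d), x, mode)
    eo <- e$out
    dmask <- NULL
    if (d == depth) {
      dp <- dropout_fwd(eo, cfg$dropout_rate, mode)
      eo <- dp$y
      dmask <- dp$mask
    }
    p <- maxpool_fwd(eo)
    inner <- rec(d + 1L, p$y)
    up <- upsample_fwd(inner$out)
    upc <- conv_fwd(up, net$P[[sprintf("up%d.W", d)]],
                    net$P[[sprintf("up%d.b", d)]])
    cat <- concat_c(eo, upc)
    dec <- resblock_fwd(net, sprintf("dec%d", d), cat, mode)
    list(out = dec$out,
         cache = if (want_cache)
           list(enc = e$cache, dmask = dmask, pool_idx = p$idx,
                enc_dim = dim(eo), inner = inner$cache,
                inner_dim = dim(inner$out), up = up, enc_ch = dim(eo)[3],
                dec = dec$cache))
  }
  r <- rec(1L, x)
  z <- conv_fwd(r$out, net$P[["final.W"]], net$P[["final.b"]])
  prob <- 1 / (1 + exp(-z))
  list(prob = prob,
       cache = if (want_cache) list(body = r$cache, body_out = r$out))
}

# Backward pass: dz is the gradient w.r.t. the pre-sigmoid logits.
resunet_backward <- function(net, dz, cache, G) {
  cfg <- net$cfg
  depth <- cfg$depth
  cb <- conv_bwd(cache$body_out, net$P[["final.W"]], dz)
  acc_grad(G, "final.W", cb$dw)
  acc_grad(G, "final.b", cb$db)

  rec <- function(d, dout, cache) {
    if (d > depth) {
      if (!is.null(cache$dmask)) dout <- dout * cache$dmask
      return(resblock_bwd(net, "bott", dout, cache$rb, G))
    }
    dcat <- resblock_bwd(net, sprintf("dec%d", d), dout, cache$dec, G)
    sp <- split_c(dcat, cache$enc_ch)
    denc_skip <- sp$a
    ub <- conv_bwd(cache$up, net$P[[sprintf("up%d.W", d)]], sp$b)
    acc_grad(G, sprintf("up%d.W", d), ub$dw)
    acc_grad(G, sprintf("up%d.b", d), ub$db)
    dinner <- upsample_bwd(ub$dx, cache$inner_dim)
    dpool <- rec(d + 1L, dinner, cache$inner)
    denc <- maxpool_bwd(dpool, cache$pool_idx, cache$enc_dim) + denc_skip
    if (!is.null(cache$dmask)) denc <- denc * cache$dmask
    resblock_bwd(net, sprintf("enc%d", d), denc, cache$enc, G)
  }
  rec(1L, cb$dx, cache$body)
}

#' Apply a concatenative residual block
#'
#' The building block of the ResUnet: the input feature map is passed
#' through two (convolution + batch norm + Leaky-ReLU) units and the result
#' is concatenated with the unmodified input along the channel axis, so the
#' output has `in_channels + channels` channels and unchanged spatial size.
#'
#' @param x input array (H, W, C) or (H, W, C, N).
#' @param block parameters from [res_block_params()].
#' @param mode `"train"` (batch statistics) or `"eval"`.
#' @return array with `C + channels` channels.
#' @export
res_block <- function(x, block, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  x4 <- as_nhwc(x)
  if (dim(x4)[3] != block$in_channels)
    stop(sprintf("input has %d channels; block expects %d", dim(x4)[3],
                 block$in_channels), call. = FALSE)
  out <- resblock_fwd(block$net, "rb", x4, mode)$out
  if (length(dim(x)) == 3L) dim(out) <- dim(out)[1:3]
  out
}

#' @rdname res_block
#' @param in_channels channels of the block input.
#' @param channels channels produced by the convolved branch.
#' @param leaky_slope Leaky-ReLU negative slope.
#' @param seed optional seed for weight initialization.
#' @export
res_block_params <- function(in_channels, channels, leaky_slope = 0.01,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  P <- new.env(parent = emptyenv())
  B <- new.env(parent = emptyenv())
  init_resblock(P, B, "rb", in_channels, channels, leaky_slope)
  cfg <- list(leaky_slope = leaky_slope, residual = TRUE)
  list(in_channels = in_channels, channels = channels,
       net = list(cfg = cfg, P = P, B = B))
}

#' Predict the lung mask of a preprocessed case
#'
#' Runs every slice of a cropped, zoomed CT volume through the network
#' independently (evaluation mode, so the result is deterministic),
#' binarizes the probability maps at `threshold`, and stacks them into a
#' mask volume.
#'
#' @param net a trained `resunet` (or a fit from [train_segmentation()]).
#' @param volume `ct_volume` (HU) at the network's working resolution.
#' @param threshold binarization threshold in (0, 1), default 0.5.
#' @param batch slices per forward chunk.
#' @return `mask_volume` of per-slice predictions.
#' @export
predict_case <- function(net, volume, threshold = 0.5, batch = 8L) {
  if (inherits(net, "resunet_fit")) net <- net$net
  check_scalar(threshold, "threshold", lower = 0, upper = 1)
  v <- as_voxels(volume)
  d <- dim(v)
  out <- array(0, d)
  x <- normalize_hu(v, net$cfg$hu_window)
  for (i0 in seq(1L, d[3], by = batch)) {
    i1 <- min(d[3], i0 + batch - 1L)
    xb <- array(x[, , i0:i1], c(d[1], d[2], 1L, i1 - i0 + 1L))
    pr <- resunet_forward(net, xb, mode = "eval")$prob
    out[, , i0:i1] <- as.numeric(pr > threshold)
  }
  id <- if (inherits(volume, "ct_volume")) volume$case_id else "case"
  mask_volume(out, case_id = id)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the model configuration together with all
#' parameters and batch-norm running statistics.
#'
#' @param net a `resunet` or `resunet_fit`.
#' @param path file path.
#' @return `load_model` returns a `resunet`.
#' @export
save_model <- function(net, path) {
  if (inherits(net, "resunet_fit")) net <- net$net
  saveRDS(list(cfg = net$cfg, params = as.list(net$P),
               buffers = as.list(net$B), plan = net$plan), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  P <- list2env(ck$params, parent = emptyenv())
  B <- list2env(ck$buffers, parent = emptyenv())
  structure(list(cfg = ck$cfg, P = P, B = B, plan = ck$plan),
            class = "resunet")
}

#' @export
print.resunet <- function(x, ...) {
  cat(sprintf(
    "<resunet depth %d, base %d, %s blocks, %d parameters>\n",
    x$cfg$depth, x$cfg$base_channels,
    if (x$cfg$residual) "residual (concat)" else "plain",
    count_parameters(x)))
  invisible(x)
}
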