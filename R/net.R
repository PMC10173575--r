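# The dual-path attention-gated U-shaped network.
#
# Encoder: path 1 alternates feature blocks and 2x2 max pooling; path 2 max
# pools the raw input stack at every level and concatenates it with the
# pooled path-1 features to form the next level's block input.  Decoder:
# path 1 mirrors the encoder with bilinear 2x upsampling (plus a 1x1
# channel-setting convolution), attention-gated skip connections and a
# feature block; path 2 upsamples the running fused tensor and concatenates
# it with the path-1 result, so the segmentation head sees features from
# every resolution level ("multi-level feature fusion").

#' Network configuration
#'
#' @param in_channels number of input channels = the 2.5D stack size k.
#' @param num_classes output classes (2 coarse kidney-vs-background, 3
#'   KiTS19 fine, 4 KiTS21 fine).
#' @param depth number of resolution levels (>= 2).  Input height/width must
#'   be divisible by `2^(depth-1)`.
#' @param base_width channels of the first level; doubled per level, capped
#'   at 512.
#' @param block_type `"resconv"` (residual-sum block) or `"plain"` (ordinary
#'   double 3x3 convolution, the ablation baseline).
#' @param attention gate the skip connections (default TRUE).
#' @return list of class `ns_net_config`.
#' @export
net_config <- function(in_channels = 3L, num_classes = 2L, depth = 3L,
                       base_width = 16L, block_type = c("resconv", "plain"),
                       attention = TRUE) {
  block_type <- match.arg(block_type)
  if (depth < 2L) stop("depth must be >= 2")
  if (base_width < 1L) stop("base_width must be >= 1")
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (in_channels < 1L || in_channels %% 2L == 0L)
    stop("in_channels (the stack size k) must be a positive odd integer")
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 block_type = block_type, attention = isTRUE(attention)),
            class = "ns_net_config")
}

net_widths <- function(config) {
  pmin(config$base_width * 2L^(seq_len(config$depth) - 1L), 512L)
}

# Channels of the fused decoder tensor at each level (level 1 feeds the head).
net_fused_channels <- function(config) {
  w <- net_widths(config)
  cf <- integer(config$depth)
  cf[config$depth] <- w[config$depth]
  for (l in rev(seq_len(config$depth - 1L))) cf[l] <- w[l] + cf[l + 1L]
  cf
}

#' Initialise network parameters
#'
#' He-normal weights, zero biases, unit batch-norm scale.
#'
#' @param config an [net_config()].
#' @param seed optional integer seed for reproducible initialisation.
#' @return list of class `ns_net` with `config` and `params`.
#' @export
net_init <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- config$depth
  w <- net_widths(config)
  cf <- net_fused_channels(config)
  k <- config$in_channels
  enc <- vector("list", d)
  for (l in seq_len(d)) {
    cin <- if (l == 1L) k else w[l - 1L] + k
    enc[[l]] <- block_param(config$block_type, cin, w[l])
  }
  dec <- vector("list", d - 1L)
  for (l in seq_len(d - 1L)) {
    dec[[l]] <- list(up = conv_param(1, 1, cf[l + 1L], w[l]),
                     block = block_param(config$block_type, 2L * w[l], w[l]))
    if (config$attention) dec[[l]]$gate <- gate_param(w[l], cf[l + 1L])
  }
  head <- conv_param(1, 1, cf[1L], config$num_classes, scale = 0.01)
  structure(list(config = config,
                 params = list(enc = enc, dec = dec, head = head)),
            class = "ns_net")
}

#' @export
print.ns_net <- function(x, ...) {
  cat(sprintf(
    "<ns_net %s depth=%d base_width=%d k=%d classes=%d attention=%s  (%d parameters)>\n",
    x$config$block_type, x$config$depth, x$config$base_width,
    x$config$in_channels, x$config$num_classes, x$config$attention,
    net_n_params(x$params)))
  invisible(x)
}

net_n_params <- function(p) {
  if (is.numeric(p)) return(length(p))
  if (is.list(p)) return(sum(vapply(p, net_n_params, 0)))
  0L
}

check_divisible <- function(config, H, W) {
  f <- 2L^(config$depth - 1L)
  if (H %% f != 0L || W %% f != 0L)
    stop("input extent ", H, "x", W, " not divisible by 2^(depth-1) = ", f)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_ch <- function(g, c1) {
  d <- dim(g)
  list(a = g[, , seq_len(c1), , drop = FALSE],
       b = g[, , (c1 + 1):d[3], , drop = FALSE])
}

#' Full network forward pass
#'
#' @param x input tensor, array (H, W, k, N).
#' @param net an `ns_net`.
#' @param bn_mode `"train"` (batch statistics), `"eval"` (running
#'   statistics) or `"identity"` (no normalization; analytic tests).
#' @param keep_cache keep intermediate activations for [net_backward()].
#' @return list with `scores` (H, W, num_classes, N) and (optionally) `cache`.
#' @export
net_forward <- function(x, net, bn_mode = "eval", keep_cache = FALSE) {
  config <- net$config; p <- net$params
  d <- dim(x)
  if (length(d) != 4L) stop("input must be a (H, W, C, N) array")
  if (d[3] != config$in_channels)
    stop("input has ", d[3], " channels, config expects ", config$in_channels)
  check_divisible(config, d[1], d[2])
  depth <- config$depth
  enc_c <- vector("list", depth)
  pools <- vector("list", depth)      # maxpool caches of path-1 features
  raw_pools <- vector("list", depth)  # maxpool caches of the raw stream
  e <- vector("list", depth)
  inp <- x; raw <- x
  for (l in seq_len(depth)) {
    if (l > 1L) {
      mp <- cpp_maxpool2_fw(e[[l - 1L]])
      rp <- cpp_maxpool2_fw(raw)
      pools[[l]] <- mp; raw_pools[[l]] <- rp
      raw <- rp$y
      inp <- concat_ch(mp$y, raw)
    }
    fb <- block_fw(config$block_type, inp, p$enc[[l]], bn_mode)
    e[[l]] <- fb$out
    enc_c[[l]] <- fb$cache
  }
  fused <- e[[depth]]
  dec_c <- vector("list", depth - 1L)
  for (l in rev(seq_len(depth - 1L))) {
    u0 <- cpp_upsample2_fw(fused)
    fu <- conv_fw(u0, p$dec[[l]]$up, 0L)
    if (config$attention) {
      fg <- gate_fw(e[[l]], fused, p$dec[[l]]$gate)
      xh <- fg$out
    } else { fg <- NULL; xh <- e[[l]] }
    cat_in <- concat_ch(fu$out, xh)
    fb <- block_fw(config$block_type, cat_in, p$dec[[l]]$block, bn_mode)
    dec_c[[l]] <- list(fused_in = fused, u0 = u0, fu = fu, fg = fg,
                       block = fb$cache)
    fused <- concat_ch(fb$out, u0)
  }
  fh <- conv_fw(fused, p$head, 0L)
  res <- list(scores = fh$out)
  if (keep_cache)
    res$cache <- list(x = x, enc = enc_c, pools = pools,
                      raw_pools = raw_pools, e = e, dec = dec_c, fh = fh,
                      dims = d, bn_mode = bn_mode)
  res
}

#' Full network backward pass
#'
#' @param gy gradient of the loss w.r.t. the scores, same shape as `scores`.
#' @param net the `ns_net` used in the forward pass.
#' @param cache the cache from `net_forward(..., keep_cache = TRUE)`.
#' @return parameter-gradient tree shaped like `net$params`.
#' @export
net_backward <- function(gy, net, cache) {
  config <- net$config
  depth <- config$depth
  w <- net_widths(config)
  g <- list(enc = vector("list", depth), dec = vector("list", depth - 1L))
  bh <- conv_bw(cache$fh, gy)
  g$head <- bh$g
  gfused <- bh$gx
  ge <- vector("list", depth)  # gradients flowing into encoder outputs
  for (l in seq_len(depth - 1L)) {
    dc <- cache$dec[[l]]
    sp <- split_ch(gfused, w[l])      # fused = concat(block_out, u0)
    gblock_out <- sp$a
    gu0 <- sp$b
    bb <- block_bw(config$block_type, dc$block, gblock_out)
    g$dec[[l]]$block <- bb$g
    spc <- split_ch(bb$gx, w[l])      # cat_in = concat(up_conv_out, xh)
    gup_out <- spc$a
    gxh <- spc$b
    bu <- conv_bw(dc$fu, gup_out)
    g$dec[[l]]$up <- bu$g
    gu0 <- gu0 + bu$gx
    din <- dim(dc$fused_in)
    g_fused_in <- cpp_upsample2_bw(gu0, din[1], din[2])
    if (config$attention) {
      bg <- gate_bw(dc$fg$cache, gxh)
      g$dec[[l]]$gate <- bg$g
      ge[[l]] <- bg$gx_l
      g_fused_in <- g_fused_in + bg$gg
    } else {
      ge[[l]] <- gxh
    }
    gfused <- g_fused_in
  }
  # gfused is now the gradient into e[[depth]] via the decoder entry point
  ge[[depth]] <- if (is.null(ge[[depth]])) gfused else ge[[depth]] + gfused
  graw <- NULL  # gradient into the raw (path-2) stream at the current level
  for (l in rev(seq_len(depth))) {
    bb <- block_bw(config$block_type, cache$enc[[l]], ge[[l]])
    g$enc[[l]] <- bb$g
    if (l > 1L) {
      k <- config$in_channels
      sp <- split_ch(bb$gx, w[l - 1L])  # inp = concat(pooled e, pooled raw)
      graw_here <- sp$b
      if (!is.null(graw)) graw_here <- graw_here + graw
      din <- dim(cache$e[[l - 1L]])
      gpool <- cpp_maxpool2_bw(sp$a, cache$pools[[l]]$idx, din[1], din[2])
      ge[[l - 1L]] <- if (is.null(ge[[l - 1L]])) gpool else ge[[l - 1L]] + gpool
      dprev <- dim(cache$raw_pools[[l]]$idx)
      graw <- cpp_maxpool2_bw(graw_here, cache$raw_pools[[l]]$idx,
                              2L * dprev[1], 2L * dprev[2])
    }
  }
  g
}

# After a train-mode forward pass, fold the freshly computed running
# batch-norm statistics back into the parameter tree.
net_commit_running <- function(params, cache) {
  take <- function(pblk, cblk) {
    for (nm in names(pblk)) {
      if (identical(nm, "gate")) next
      if (!is.null(pblk[[nm]]$rm)) {
        # bn params are named bn1/bn2; their caches fb1/fb2
        bnc <- cblk[[sub("^bn", "fb", nm)]]
        if (!is.null(bnc$cache$new_running)) {
          pblk[[nm]]$rm <- bnc$cache$new_running$rm
          pblk[[nm]]$rv <- bnc$cache$new_running$rv
        }
      }
    }
    pblk
  }
  for (l in seq_along(params$enc))
    params$enc[[l]] <- take(params$enc[[l]], cache$enc[[l]])
  for (l in seq_along(params$dec))
    params$dec[[l]]$block <- take(params$dec[[l]]$block, cache$dec[[l]]$block)
  params
}

#' Residual-sum block forward
#'
#' The defining feature block: a 1x1 channel-setting projection, then two
#' additive residual units built from 3x3 convolution + batch normalization
#' + ReLU, whose outputs are both summed into the block output:
#' `x0 = Conv1x1(x)`, `x1 = ReLU(BN(Conv3x3(x0))) + x0`,
#' `x2 = ReLU(BN(Conv3x3(x1))) + x1`, `output = x1 + x2`.
#'
#' @param x input tensor (H, W, C_in, N).
#' @param block parameters from [new_resconv_block()].
#' @param bn_mode `"train"`, `"eval"` or `"identity"`.
#' @return output tensor (H, W, width, N).
#' @export
resconv_forward <- function(x, block, bn_mode = "train") {
  if (dim(x)[3] != dim(block$proj$w)[3])
    stop("input has ", dim(x)[3], " channels, block expects ",
         dim(block$proj$w)[3])
  resconv_fw(x, block, bn_mode)$out
}

#' Create residual-sum block parameters
#'
#' @param in_channels input channels.
#' @param width block width (output channels of the 1x1 projection and of
#'   both residual units).
#' @export
new_resconv_block <- function(in_channels, width) {
  resconv_param(in_channels, width)
}

#' Attention gate forward
#'
#' Gates an encoder skip feature `x_l` by decoder context `g` (at half the
#' spatial extent): both are projected by 1x1 convolutions to a shared
#' intermediate width, summed, passed through ReLU, reduced to one channel,
#' squashed by a sigmoid, bilinearly resampled to `x_l`'s extent, and the
#' resulting weight map multiplies `x_l` channel-wise.
#'
#' @param x_l encoder feature (H, W, C_x, N).
#' @param g decoder gating feature (H/2, W/2, C_g, N).
#' @param gate parameters from [new_attention_gate()].
#' @param return_alpha also return the attention map.
#' @return the gated tensor, or `list(out, alpha)` if `return_alpha`.
#' @export
attention_gate <- function(x_l, g, gate, return_alpha = FALSE) {
  r <- gate_fw(x_l, g, gate)
  if (return_alpha)
    list(out = r$out, alpha = r$cache$albc[, , 1, , drop = FALSE])
  else r$out
}

#' Create attention-gate parameters
#'
#' @param c_x channels of the skip feature.
#' @param c_g channels of the gating feature.
#' @export
new_attention_gate <- function(c_x, c_g) gate_param(c_x, c_g)

#' Predict the middle-slice mask for one 2.5D stack
#'
#' Per-pixel argmax over the class scores; deterministic given weights.
#'
#' @param stack a stack from [make_stacks()].
#' @param net an `ns_net`.
#' @return H x W integer mask with values in `0..num_classes-1`.
#' @export
predict_slice <- function(stack, net) {
  x <- stacks_to_tensor(list(stack))
  s <- net_forward(x, net, bn_mode = "eval")$scores
  argmax_classes(s)[, , 1]
}

argmax_classes <- function(scores) {
  d <- dim(scores)
  best <- array(0L, dim = c(d[1], d[2], d[4]))
  bestv <- scores[, , 1, , drop = FALSE]
  dim(bestv) <- c(d[1], d[2], d[4])
  if (d[3] > 1) for (c in 2:d[3]) {
    v <- scores[, , c, , drop = FALSE]
    dim(v) <- c(d[1], d[2], d[4])
    upd <- v > bestv
    best[upd] <- c - 1L
    bestv[upd] <- v[upd]
  }
  best
}

#' Segment a whole volume slice-by-slice
#'
#' Runs the 2.5D scheme over every axial slice and reassembles the per-slice
#' argmax masks into a label volume.
#'
#' @param volume an `ns_volume` (already normalized for the network).
#' @param net an `ns_net`.
#' @param k stack size; defaults to the network's `in_channels`.
#' @param vocabulary vocabulary of the returned label volume.
#' @param batch_size slices forwarded per batch.
#' @export
predict_volume <- function(volume, net, k = net$config$in_channels,
                           vocabulary = "KITS21", batch_size = 8L) {
  if (k != net$config$in_channels)
    stop("k = ", k, " does not match the network's in_channels = ",
         net$config$in_channels)
  stacks <- make_stacks(volume, NULL, k = k)
  d <- dim(volume$intensities)
  preds <- vector("list", length(stacks))
  i <- 1L
  while (i <= length(stacks)) {
    j <- min(i + batch_size - 1L, length(stacks))
    x <- stacks_to_tensor(stacks[i:j])
    s <- net_forward(x, net, bn_mode = "eval")$scores
    am <- argmax_classes(s)
    for (n in seq_len(j - i + 1L))
      preds[[i + n - 1L]] <- list(center_index = stacks[[i + n - 1L]]$center_index,
                                  mask = am[, , n])
    i <- j + 1L
  }
  reassemble(preds, d[1], vocabulary = vocabulary, spacing = volume$spacing,
             affine = volume$affine, id = volume$id)
}
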