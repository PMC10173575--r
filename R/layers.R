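# Differentiable layer primitives.
#
# Every *_fw returns list(out, cache); every *_bw takes (cache, gy) and
# returns list(gx = input gradient, g = parameter-gradient subtree shaped
# like the parameter subtree).  Tensors are (H, W, C, N) arrays.

conv_param <- function(kh, kw, cin, cout, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (kh * kw * cin))  # He init
  list(w = array(rnorm(kh * kw * cin * cout, sd = scale),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

bn_param <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       rm = numeric(c), rv = rep(1, c))
}

conv_fw <- function(x, p, pad) {
  out <- cpp_conv2d_fw(x, p$w, p$b, pad)
  list(out = out, cache = list(x = x, p = p, pad = pad))
}

# Backward passes take the full forward result (out + cache) so call sites
# can pass the stored forward object directly.
conv_bw <- function(f, gy) {
  cache <- f$cache
  r <- cpp_conv2d_bw(cache$x, cache$p$w, gy, cache$pad)
  list(gx = r$gx, g = list(w = r$gw, b = r$gb))
}

relu_fw <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bw <- function(cache, gy) gy * cache

# Batch normalization over (H, W, N) per channel.
#   mode "train":    batch statistics (population variance), updates running
#                    stats as a side value returned in cache$new_running.
#   mode "eval":     running statistics.
#   mode "identity": pass-through (used by the analytic block identities).
bn_fw <- function(x, p, mode = "train", momentum = 0.1, eps = 1e-5) {
  if (mode == "identity")
    return(list(out = x, cache = list(mode = mode, p = p)))
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- H * W * N
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)   # (H*W*N) x C
  if (mode == "train") {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    var <- colMeans(xc * xc)
    new_rm <- (1 - momentum) * p$rm + momentum * mu
    new_rv <- (1 - momentum) * p$rv + momentum * var
  } else {
    mu <- p$rm; var <- p$rv
    xc <- sweep(xm, 2, mu)
    new_rm <- p$rm; new_rv <- p$rv
  }
  istd <- 1 / sqrt(var + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  ym <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  out <- aperm(array(ym, dim = c(H, W, N, C)), c(1, 2, 4, 3))
  list(out = out,
       cache = list(mode = mode, p = p, xhat = xhat, istd = istd,
                    dims = d, m = m,
                    new_running = list(rm = new_rm, rv = new_rv)))
}

bn_bw <- function(f, gy) {
  cache <- f$cache
  if (cache$mode == "identity")
    return(list(gx = gy, g = list(gamma = numeric(length(cache$p$gamma)),
                                  beta = numeric(length(cache$p$beta)))))
  d <- cache$dims
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  gym <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = C)
  ggamma <- colSums(gym * cache$xhat)
  gbeta <- colSums(gym)
  if (cache$mode == "eval") {
    gxm <- sweep(gym, 2, cache$p$gamma * cache$istd, `*`)
  } else {
    m <- cache$m
    gxhat <- sweep(gym, 2, cache$p$gamma, `*`)
    t1 <- sweep(gxhat, 2, colMeans(gxhat))
    t2 <- sweep(cache$xhat, 2, colMeans(gxhat * cache$xhat), `*`)
    gxm <- sweep(t1 - t2, 2, cache$istd, `*`)
  }
  gx <- aperm(array(gxm, dim = c(H, W, N, C)), c(1, 2, 4, 3))
  list(gx = gx, g = list(gamma = ggamma, beta = gbeta))
}

# --- ResConv block ---------------------------------------------------------
# x0 = Conv1x1(input); x1 = ReLU(BN(Conv3x3(x0))) + x0;
# x2 = ReLU(BN(Conv3x3(x1))) + x1; output = x1 + x2.
# The final sum of BOTH residual units' outputs is the block's defining
# feature (not x2 alone).

resconv_param <- function(cin, width) {
  list(proj = conv_param(1, 1, cin, width),
       c1 = conv_param(3, 3, width, width), bn1 = bn_param(width),
       c2 = conv_param(3, 3, width, width), bn2 = bn_param(width))
}

resconv_fw <- function(x, p, bn_mode = "train") {
  f0 <- conv_fw(x, p$proj, 0L); x0 <- f0$out
  fc1 <- conv_fw(x0, p$c1, 1L)
  fb1 <- bn_fw(fc1$out, p$bn1, bn_mode)
  fr1 <- relu_fw(fb1$out)
  x1 <- fr1$out + x0
  fc2 <- conv_fw(x1, p$c2, 1L)
  fb2 <- bn_fw(fc2$out, p$bn2, bn_mode)
  fr2 <- relu_fw(fb2$out)
  x2 <- fr2$out + x1
  list(out = x1 + x2,
       cache = list(f0 = f0, fc1 = fc1, fb1 = fb1, fr1 = fr1,
                    fc2 = fc2, fb2 = fb2, fr2 = fr2))
}

resconv_bw <- function(cache, gy) {
  # out = x1 + x2; x2 = r2 + x1  =>  d out/d r2 = gy, d out/d x1 = 2*gy
  gr2 <- gy
  gx1 <- 2 * gy
  b2 <- bn_bw(cache$fb2, relu_bw(cache$fr2$cache, gr2))
  c2 <- conv_bw(cache$fc2, b2$gx)
  gx1 <- gx1 + c2$gx
  # x1 = r1 + x0
  gr1 <- gx1
  gx0 <- gx1
  b1 <- bn_bw(cache$fb1, relu_bw(cache$fr1$cache, gr1))
  c1 <- conv_bw(cache$fc1, b1$gx)
  gx0 <- gx0 + c1$gx
  p0 <- conv_bw(cache$f0, gx0)
  list(gx = p0$gx,
       g = list(proj = p0$g, c1 = c1$g, bn1 = b1$g, c2 = c2$g, bn2 = b2$g))
}

# --- Plain double-conv block (the "original conv" ablation) ----------------

plain_param <- function(cin, width) {
  list(c1 = conv_param(3, 3, cin, width), bn1 = bn_param(width),
       c2 = conv_param(3, 3, width, width), bn2 = bn_param(width))
}

plain_fw <- function(x, p, bn_mode = "train") {
  fc1 <- conv_fw(x, p$c1, 1L)
  fb1 <- bn_fw(fc1$out, p$bn1, bn_mode)
  fr1 <- relu_fw(fb1$out)
  fc2 <- conv_fw(fr1$out, p$c2, 1L)
  fb2 <- bn_fw(fc2$out, p$bn2, bn_mode)
  fr2 <- relu_fw(fb2$out)
  list(out = fr2$out,
       cache = list(fc1 = fc1, fb1 = fb1, fr1 = fr1,
                    fc2 = fc2, fb2 = fb2, fr2 = fr2))
}

plain_bw <- function(cache, gy) {
  b2 <- bn_bw(cache$fb2, relu_bw(cache$fr2$cache, gy))
  c2 <- conv_bw(cache$fc2, b2$gx)
  b1 <- bn_bw(cache$fb1, relu_bw(cache$fr1$cache, c2$gx))
  c1 <- conv_bw(cache$fc1, b1$gx)
  list(gx = c1$gx,
       g = list(c1 = c1$g, bn1 = b1$g, c2 = c2$g, bn2 = b2$g))
}

block_param <- function(block_type, cin, width) {
  switch(block_type, resconv = resconv_param(cin, width),
         plain = plain_param(cin, width),
         stop("unknown block_type: ", block_type))
}

block_fw <- function(block_type, x, p, bn_mode) {
  switch(block_type, resconv = resconv_fw(x, p, bn_mode),
         plain = plain_fw(x, p, bn_mode))
}

block_bw <- function(block_type, cache, gy) {
  switch(block_type, resconv = resconv_bw(cache, gy),
         plain = plain_bw(cache, gy))
}

# --- Attention gate --------------------------------------------------------
# x_l: skip feature at full level extent; g: gating feature at half extent.
# A = Wg g ; B = Wx avgpool2(x_l) ; C = A + B ; D = ReLU(C) ;
# E = psi(D) (1 channel) ; F = sigmoid(E) ; alpha = bilinear-up(F) ;
# output = alpha * x_l (broadcast over channels).

gate_param <- function(c_x, c_g) {
  f_int <- max(1L, c_x %/% 2L)
  list(wg = conv_param(1, 1, c_g, f_int),
       wx = conv_param(1, 1, c_x, f_int),
       psi = conv_param(1, 1, f_int, 1))
}

gate_fw <- function(x_l, g, p) {
  dx <- dim(x_l); dg <- dim(g)
  if (!(dx[1] == 2L * dg[1] && dx[2] == 2L * dg[2]))
    stop("attention gate: g must be at half the spatial extent of x_l (",
         dx[1], "x", dx[2], " vs ", dg[1], "x", dg[2], ")")
  xd <- cpp_avgpool2_fw(x_l)
  fa <- conv_fw(g, p$wg, 0L)
  fb <- conv_fw(xd, p$wx, 0L)
  cc <- fa$out + fb$out
  fd <- relu_fw(cc)
  fe <- conv_fw(fd$out, p$psi, 0L)
  f_sig <- 1 / (1 + exp(-fe$out))
  alpha <- cpp_upsample2_fw(f_sig)
  # broadcast single-channel alpha over x_l's channels
  al <- array(alpha, dim = c(dx[1], dx[2], 1, dx[4]))
  albc <- array(0, dim = dx)
  for (c in seq_len(dx[3])) albc[, , c, ] <- al[, , 1, ]
  list(out = albc * x_l,
       cache = list(x_l = x_l, fa = fa, fb = fb, fd = fd, fe = fe,
                    f_sig = f_sig, albc = albc, dx = dx))
}

gate_bw <- function(cache, gy) {
  dx <- cache$dx
  g_alpha_bc <- gy * cache$x_l
  gx_l_direct <- gy * cache$albc
  # sum broadcast gradient over channels -> single-channel alpha gradient
  g_alpha <- array(0, dim = c(dx[1], dx[2], 1, dx[4]))
  for (c in seq_len(dx[3])) g_alpha[, , 1, ] <- g_alpha[, , 1, ] + g_alpha_bc[, , c, ]
  gf <- cpp_upsample2_bw(g_alpha, dx[1] %/% 2L, dx[2] %/% 2L)
  ge <- gf * cache$f_sig * (1 - cache$f_sig)
  bpsi <- conv_bw(cache$fe, ge)
  gc <- relu_bw(cache$fd$cache, bpsi$gx)
  ba <- conv_bw(cache$fa, gc)
  bb <- conv_bw(cache$fb, gc)
  gxd <- cpp_avgpool2_bw(bb$gx, dx[1], dx[2])
  list(gx_l = gx_l_direct + gxd, gg = ba$gx,
       g = list(wg = ba$g, wx = bb$g, psi = bpsi$g))
}
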