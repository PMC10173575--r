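# Network blocks, attention gate, full forward/backward.

zero_block_residuals <- function(block) {
  # zero both residual units' conv weights/biases; BN handled by identity mode
  for (nm in c("c1", "c2")) {
    block[[nm]]$w[] <- 0
    block[[nm]]$b[] <- 0
  }
  block
}

test_that("residual-sum block: analytic identity, shape contract, literal oracle", {
  set.seed(10)
  # (1) zeroed residual branches + identity normalization -> output = 2 * Conv1x1(x)
  blk <- zero_block_residuals(new_resconv_block(3L, 5L))
  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  out <- resconv_forward(x, blk, bn_mode = "identity")
  x0 <- nephroseg:::cpp_conv2d_fw(x, blk$proj$w, blk$proj$b, 0L)
  expect_lt(max(abs(out - 2 * x0)), 1e-6)
  # (2) shape contract: (C_in, 32, 32) -> (W, 32, 32)
  blk2 <- new_resconv_block(4L, 7L)
  y <- resconv_forward(array(rnorm(32 * 32 * 4), c(32, 32, 4, 1)), blk2,
                       bn_mode = "identity")
  expect_identical(dim(y), c(32L, 32L, 7L, 1L))
  expect_error(resconv_forward(array(0, c(8, 8, 2, 1)), blk2), "channels")
  # (3) literal step-by-step recomputation of the four equations with an
  # independent dense convolution, identity normalization
  blk3 <- new_resconv_block(2L, 2L)
  xs <- array(rnorm(6 * 6 * 2 * 1), c(6, 6, 2, 1))
  x0 <- naive_conv2d(xs, blk3$proj$w, blk3$proj$b, 0)
  x1 <- pmax(naive_conv2d(x0, blk3$c1$w, blk3$c1$b, 1), 0) + x0
  x2 <- pmax(naive_conv2d(x1, blk3$c2$w, blk3$c2$b, 1), 0) + x1
  expect_lt(max(abs(resconv_forward(xs, blk3, bn_mode = "identity") -
                      (x1 + x2))), 1e-10)
})

test_that("attention gate: neutrality, sigmoid range, multiplicative zeroing", {
  set.seed(11)
  gate <- new_attention_gate(4L, 6L)
  x_l <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  g <- array(rnorm(4 * 4 * 6 * 2), c(4, 4, 6, 2))
  # zeroed gate parameters -> E = 0 -> F = 0.5 -> output = 0.5 * x_l
  gz <- gate
  for (nm in names(gz)) { gz[[nm]]$w[] <- 0; gz[[nm]]$b[] <- 0 }
  expect_lt(max(abs(attention_gate(x_l, g, gz) - 0.5 * x_l)), 1e-6)
  # alpha strictly inside (0, 1)
  r <- attention_gate(x_l, g, gate, return_alpha = TRUE)
  expect_true(all(r$alpha > 0 & r$alpha < 1))
  # multiplicative gating: zero skip input -> zero output, any g
  expect_true(all(attention_gate(array(0, dim(x_l)), g, gate) == 0))
  expect_error(attention_gate(x_l, array(0, c(3, 3, 6, 2)), gate), "extent")
})

test_that("forward pass is shape-stable over random configurations", {
  set.seed(12)
  for (i in 1:6) {
    depth <- sample(2:3, 1)
    cfg <- net_config(in_channels = sample(c(1L, 3L, 5L), 1),
                      num_classes = sample(2:4, 1), depth = depth,
                      base_width = sample(2:4, 1),
                      block_type = sample(c("resconv", "plain"), 1),
                      attention = sample(c(TRUE, FALSE), 1))
    net <- net_init(cfg, seed = i)
    H <- as.integer(8L * 2L^(depth - 2L))
    x <- array(rnorm(H * H * cfg$in_channels * 2), c(H, H, cfg$in_channels, 2))
    s <- net_forward(x, net, bn_mode = "train")$scores
    expect_identical(dim(s), c(H, H, cfg$num_classes, 2L))
  }
  cfg <- net_config(depth = 4L)
  expect_error(net_forward(array(0, c(12, 12, 3, 1)), net_init(cfg, 1)),
               "divisible")
})

test_that("encoder channel bookkeeping matches the config arithmetic", {
  cfg <- net_config(in_channels = 3L, num_classes = 2L, depth = 3L,
                    base_width = 4L)
  w <- nephroseg:::net_widths(cfg)
  expect_equal(w, c(4L, 8L, 16L))
  # concatenated input of level l = path-1 channels + raw stack channels
  net <- net_init(cfg, seed = 3)
  expect_equal(dim(net$params$enc[[2]]$proj$w)[3], w[1] + 3L)
  expect_equal(dim(net$params$enc[[3]]$proj$w)[3], w[2] + 3L)
  # fused decoder tensor accumulates one width per level
  expect_equal(nephroseg:::net_fused_channels(cfg), c(4L + 8L + 16L, 8L + 16L, 16L))
  expect_equal(dim(net$params$head$w)[3], 28L)
})

test_that("attention off vs zero-weight gates: gating halves the skip branch", {
  set.seed(13)
  cfg_on <- net_config(in_channels = 1L, num_classes = 2L, depth = 2L,
                       base_width = 2L, attention = TRUE)
  cfg_off <- cfg_on; cfg_off$attention <- FALSE
  net_on <- net_init(cfg_on, seed = 5)
  net_off <- net_init(cfg_off, seed = 5)
  # align shared weights (init order differs), then zero the gate
  net_on$params$enc <- net_off$params$enc
  net_on$params$dec[[1]]$up <- net_off$params$dec[[1]]$up
  net_on$params$dec[[1]]$block <- net_off$params$dec[[1]]$block
  net_on$params$head <- net_off$params$head
  for (nm in names(net_on$params$dec[[1]]$gate)) {
    net_on$params$dec[[1]]$gate[[nm]]$w[] <- 0
    net_on$params$dec[[1]]$gate[[nm]]$b[] <- 0
  }
  x <- array(rnorm(8 * 8 * 1 * 1), c(8, 8, 1, 1))
  s_on <- net_forward(x, net_on, bn_mode = "identity")$scores
  # manual halved-skip forward: scale the skip tensor by 0.5 via a wrapper
  # network with attention off is NOT generally equal, but with the gate
  # zeroed the gated skip is exactly 0.5 * skip; verify against a direct
  # recomputation using the off-network internals.
  fw_off <- net_forward(x, net_off, bn_mode = "identity")$scores
  # halve the skip by temporarily scaling the encoder output contribution:
  # recompute with attention-on equals off-network where skip was halved.
  # We verify via the block input equality instead: run the on-network and
  # an off-network whose decode concatenates 0.5 * skip.
  halved <- local({
    net2 <- net_off
    # emulate by scaling: forward manually
    p <- net2$params
    e1 <- nephroseg:::block_fw("resconv", x, p$enc[[1]], "identity")$out
    mp <- nephroseg:::cpp_maxpool2_fw(e1)
    rp <- nephroseg:::cpp_maxpool2_fw(x)
    e2 <- nephroseg:::block_fw("resconv",
                               nephroseg:::concat_ch(mp$y, rp$y),
                               p$enc[[2]], "identity")$out
    u0 <- nephroseg:::cpp_upsample2_fw(e2)
    u <- nephroseg:::conv_fw(u0, p$dec[[1]]$up, 0L)$out
    y <- nephroseg:::block_fw("resconv",
                              nephroseg:::concat_ch(u, 0.5 * e1),
                              p$dec[[1]]$block, "identity")$out
    nephroseg:::conv_fw(nephroseg:::concat_ch(y, u0), p$head, 0L)$out
  })
  expect_lt(max(abs(s_on - halved)), 1e-8)
  expect_gt(max(abs(s_on - fw_off)), 1e-8)  # gating genuinely differs
})

test_that("every parameter receives gradient; analytic grads match finite differences", {
  set.seed(14)
  cfg <- net_config(in_channels = 3L, num_classes = 2L, depth = 2L,
                    base_width = 2L)
  net <- net_init(cfg, seed = 7)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  tgt <- array(sample(0:1, 8 * 8 * 2, TRUE), c(8, 8, 2))
  fw <- net_forward(x, net, bn_mode = "train", keep_cache = TRUE)
  lo <- seg_loss(fw$scores, tgt)
  g <- net_backward(lo$grad, net, fw$cache)
  # (a) no dead paths: every trainable leaf has at least one nonzero entry
  check_nonzero <- function(p, path = "") {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (nm %in% c("rm", "rv")) next
        check_nonzero(p[[nm]], paste0(path, "$", nm))
      }
      return(invisible())
    }
    expect_gt(max(abs(p)), 0, label = paste0("gradient", path))
  }
  check_nonzero(g)
  # (b) finite-difference agreement on a random parameter subset
  flat <- function(p, path = "") {
    if (is.list(p)) {
      out <- list()
      for (nm in names(p)) {
        if (nm %in% c("rm", "rv")) next
        out <- c(out, flat(p[[nm]], paste0(path, "$", nm)))
      }
      return(out)
    }
    list(list(path = path, val = p))
  }
  lp <- flat(net$params); lg <- flat(g)
  loss_at <- function(n2) {
    s <- net_forward(x, n2, bn_mode = "train")$scores
    seg_loss(s, tgt)$loss
  }
  eps <- 1e-5
  for (t in 1:12) {
    li <- sample(length(lp), 1)
    el <- sample(length(lp[[li]]$val), 1)
    pert <- function(d) {
      n2 <- net
      expr <- sprintf("n2$params%s[%d] <- n2$params%s[%d] + %.10e",
                      lp[[li]]$path, el, lp[[li]]$path, el, d)
      eval(parse(text = expr))
      loss_at(n2)
    }
    num <- (pert(eps) - pert(-eps)) / (2 * eps)
    ana <- lg[[li]]$val[el]
    expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4,
              label = paste0("grad at ", lp[[li]]$path, "[", el, "]"))
  }
})

test_that("slice prediction is deterministic with masks in the class range", {
  set.seed(15)
  cs <- tiny_case(seed = 9)
  stats <- compute_foreground_stats(cs$volume, cs$labels)
  vol <- normalize_volume(cs$volume, stats)
  st <- make_stacks(vol, k = 3)[[6]]
  net <- net_init(net_config(in_channels = 3L, num_classes = 4L, depth = 2L,
                             base_width = 2L), seed = 4)
  m1 <- predict_slice(st, net)
  m2 <- predict_slice(st, net)
  expect_identical(m1, m2)
  expect_true(all(m1 %in% 0:3))
  expect_identical(dim(m1), c(32L, 32L))
})
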