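# Splitting, the early-stopping rule, loss gradients, optimizer plumbing and
# a small end-to-end training run.

test_that("case splitting is disjoint, exhaustive and reproducible", {
  ids <- sprintf("case_%05d", 0:9)
  sp <- split_cases(ids, fraction = 0.2, seed = 5)
  expect_length(sp$test, 2L)
  expect_length(sp$train, 8L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(split_cases(ids, 0.2, seed = 5), sp)
  expect_false(identical(split_cases(ids, 0.2, seed = 6)$test, sp$test))
  expect_error(split_cases(ids, 1.2, seed = 1), "fraction")
  expect_error(split_cases(ids[1], 0.2, seed = 1), "at least 2")
})

test_that("early stopping fires at the earliest epoch the rule permits", {
  # scripted, frozen monitor with patience 1: epoch 1 improves (baseline),
  # epoch 2 fails to improve -> stop after epoch 2
  r <- run_epochs(function(e) NULL, function(e) 0.5, max_epochs = 100,
                  patience = 1)
  expect_equal(r$stopped_epoch, 2L)
  expect_true(r$early_stopped)
  # scripted monitor sequence driven externally
  seq_vals <- c(0.3, 0.5, 0.49, 0.6, 0.4, 0.9, 0.1, 0.1, 0.1)
  r2 <- run_epochs(function(e) NULL, function(e) seq_vals[e],
                   max_epochs = 9, patience = 3)
  expect_equal(r2$best_epoch, 6L)
  expect_equal(r2$stopped_epoch, 9L)   # bad run of 3 after epoch 6
  expect_true(r2$early_stopped)
  # improvement below min_delta does not reset the countdown
  r3 <- run_epochs(function(e) NULL, function(e) 0.5 + e * 1e-7,
                   max_epochs = 50, patience = 4)
  expect_equal(r3$stopped_epoch, 5L)
})

test_that("loss gradients match finite differences; background predictor arithmetic", {
  set.seed(40)
  d <- c(5L, 4L, 3L, 2L)
  scores <- array(rnorm(prod(d)), d)
  tgt <- array(sample(0:2, d[1] * d[2] * d[4], TRUE), c(d[1], d[2], d[4]))
  for (ln in c("ce", "dice", "ce_dice")) {
    r <- seg_loss(scores, tgt, loss_name = ln)
    eps <- 1e-6
    for (t in 1:8) {
      i <- sample(prod(d), 1)
      sp <- scores; sp[i] <- sp[i] + eps
      sm <- scores; sm[i] <- sm[i] - eps
      num <- (seg_loss(sp, tgt, ln)$loss - seg_loss(sm, tgt, ln)$loss) / (2 * eps)
      expect_lt(abs(num - r$grad[i]) / max(1e-8, abs(num) + abs(r$grad[i])),
                1e-4, label = paste("loss grad", ln))
    }
  }
  # an all-background predictor scores 1/(|A|+1) on the tumor HEC, per case
  lab <- array(0L, c(4, 6, 6)); lab[2, 2:4, 2:4] <- 2L
  pred <- array(0L, c(4, 6, 6))
  expect_equal(mean_dice(list(list(label = lab, prediction = pred)),
                         hec_definitions("KITS21")$tumor),
               1 / (9 + 1))
})

test_that("Adam updates trainable leaves and leaves running stats alone", {
  set.seed(41)
  cfg <- net_config(in_channels = 1L, num_classes = 2L, depth = 2L,
                    base_width = 2L)
  net <- net_init(cfg, seed = 2)
  x <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  tgt <- array(sample(0:1, 8 * 8 * 2, TRUE), c(8, 8, 2))
  fw <- net_forward(x, net, bn_mode = "train", keep_cache = TRUE)
  lo <- seg_loss(fw$scores, tgt)
  g <- net_backward(lo$grad, net, fw$cache)
  r <- nephroseg:::adam_step(net$params, g, NULL, 1e-3, 1)
  expect_false(identical(r$p$enc[[1]]$proj$w, net$params$enc[[1]]$proj$w))
  expect_identical(r$p$enc[[1]]$bn1$rm, net$params$enc[[1]]$bn1$rm)
  expect_identical(r$p$enc[[1]]$bn1$rv, net$params$enc[[1]]$bn1$rv)
  # all Adam moments shaped like their parameters
  expect_identical(dim(r$s$enc[[1]]$c1$w$m), dim(net$params$enc[[1]]$c1$w))
})

test_that("a tiny network trains: loss decreases and the run is deterministic", {
  cs <- tiny_case(seed = 42)
  stats <- compute_foreground_stats(cs$volume, cs$labels)
  vol <- normalize_volume(cs$volume, stats)
  lab <- cs$labels$labels; lab[lab > 0L] <- 1L
  case <- list(volume = vol,
               labels = new_label_volume(lab, "KITS19",
                                         spacing = cs$labels$spacing))
  cfg <- net_config(in_channels = 3L, num_classes = 2L, depth = 2L,
                    base_width = 4L)
  tc <- train_config(max_epochs = 2L, patience = 2L, batch_size = 2L,
                     seed = 7L, steps_per_epoch = 6L)
  f1 <- train_stage(list(case), cfg, tc)
  expect_s3_class(f1, "ns_fit")
  expect_equal(nrow(f1$history), f1$stopped_epoch)
  expect_lte(f1$stopped_epoch, 2L)
  f2 <- train_stage(list(case), cfg, tc)
  expect_equal(f1$history$monitor, f2$history$monitor, tolerance = 1e-12)
  # wiring sanity: loss on one fixed batch decreases over 50 Adam steps
  st <- make_stacks(case$volume, case$labels, k = 3L)[[6]]
  x <- nephroseg:::stacks_to_tensor(list(st))
  tgt <- array(st$target, c(32, 32, 1))
  net <- net_init(cfg, seed = 3)
  state <- NULL
  losses <- numeric(50)
  for (s in 1:50) {
    fw <- net_forward(x, net, bn_mode = "train", keep_cache = TRUE)
    lo <- seg_loss(fw$scores, tgt)
    losses[s] <- lo$loss
    g <- net_backward(lo$grad, net, fw$cache)
    r <- nephroseg:::adam_step(net$params, g, state, 1e-3, s)
    net$params <- r$p; state <- r$s
  }
  expect_lt(mean(losses[41:50]), mean(losses[1:10]))
})

test_that("checkpoints round trip config and weights", {
  dir <- withr::local_tempdir()
  net <- net_init(net_config(in_channels = 3L, depth = 2L, base_width = 2L),
                  seed = 9)
  p <- file.path(dir, "net.rds")
  save_checkpoint(net, p)
  back <- load_checkpoint(p)
  expect_identical(back$config, net$config)
  expect_identical(back$params$head$w, net$params$head$w)
})

test_that("evaluate_run with oracle predictors reports exactly 1.0 everywhere", {
  cases <- lapply(36:37, function(s) {
    cs <- generate_case(tiny_spec(seed = s, cyst = TRUE))
    list(volume = cs$volume, labels = cs$labels)
  })
  rep <- evaluate_run(oracle_coarse(cases[[1]]$labels),
                      oracle_fine(cases[[1]]$labels),
                      cases[1], vocabulary = "KITS21", tolerance_mm = 1)
  expect_equal(nrow(rep$per_case), 1L)
  expect_true(all(abs(rep$mean - 1) < 1e-12))
})
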