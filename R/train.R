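# Training: Adam over the parameter tree, epoch scheduling with early
# stopping, foreground-biased slice sampling, checkpointing, evaluation.

TRAINABLE_KEYS <- c("w", "b", "gamma", "beta")

# Recursive map over trainable leaves of a parameter tree.  f(param_leaf,
# grad_leaf, state_leaf) -> list(p =, s =).  Running BN statistics (rm/rv)
# are carried through untouched.
walk_params <- function(p, g, s, f) {
  if (is.list(p)) {
    out_p <- p
    out_s <- if (is.null(s)) vector("list", length(p)) else s
    nms <- names(p)
    if (!is.null(nms)) names(out_s) <- nms
    for (i in seq_along(p)) {
      nm <- if (is.null(nms)) "" else nms[i]
      if (nm %in% c("rm", "rv")) next
      gi <- if (nzchar(nm)) g[[nm]] else if (i <= length(g)) g[[i]] else NULL
      si <- if (nzchar(nm)) {
        if (nm %in% names(s)) s[[nm]] else NULL
      } else if (i <= length(s)) s[[i]] else NULL
      r <- walk_params(p[[i]], gi, si, f)
      out_p[[i]] <- r$p
      out_s[[i]] <- r$s
    }
    return(list(p = out_p, s = out_s))
  }
  f(p, g, s)
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  f <- function(p, g, s) {
    if (is.null(g)) return(list(p = p, s = s))
    if (is.null(s)) s <- list(m = p * 0, v = p * 0)
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk_params(params, grads, state, f)
}

#' Training configuration
#'
#' @param max_epochs upper bound on epochs (default 100).
#' @param patience consecutive epochs without monitor improvement before
#'   stopping (default 30).  "Improvement" means exceeding the best value so
#'   far by at least `min_delta`.
#' @param batch_size slice stacks per gradient step.
#' @param learning_rate Adam step size.
#' @param seed RNG seed for sampling and initialisation.
#' @param loss_name `"ce_dice"`, `"ce"` or `"dice"`.
#' @param fg_ratio fraction of sampled stacks whose centre slice contains
#'   foreground (class-imbalance control).
#' @param steps_per_epoch gradient steps per epoch; `NULL` = one pass over
#'   all stacks.
#' @param min_delta improvement threshold for the early-stopping rule.
#' @param monitor_max_stacks cap on the number of stacks scored by the
#'   per-epoch monitor (a deterministic subsample keeps monitoring cheap on
#'   large cohorts); `Inf` scores everything.
#' @export
train_config <- function(max_epochs = 100L, patience = 30L, batch_size = 4L,
                         learning_rate = 1e-3, seed = 1L,
                         loss_name = "ce_dice", fg_ratio = 0.7,
                         steps_per_epoch = NULL, min_delta = 1e-5,
                         monitor_max_stacks = 64L) {
  if (patience > max_epochs) stop("patience must be <= max_epochs")
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 loss_name = loss_name, fg_ratio = fg_ratio,
                 steps_per_epoch = steps_per_epoch, min_delta = min_delta,
                 monitor_max_stacks = monitor_max_stacks),
            class = "ns_train_config")
}

#' Split case ids into train and test sets
#'
#' Reproducible random split; the test set holds `round(fraction * n)` cases.
#'
#' @param case_ids character or integer vector, length >= 2.
#' @param fraction test fraction in (0, 1); 0.2 reproduces the 80/20 split.
#' @param seed RNG seed.
#' @return list with `train` and `test`.
#' @export
split_cases <- function(case_ids, fraction = 0.2, seed = 1L) {
  if (length(case_ids) < 2L) stop("need at least 2 cases to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_test <- max(1L, round(fraction * length(case_ids)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test <- sort(sample(seq_along(case_ids), n_test))
  list(train = case_ids[-test], test = case_ids[test])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Generic epoch loop with early stopping
#'
#' Factored out so the stopping rule is testable against scripted monitors:
#' runs `step_fn(epoch)` then `monitor_fn(epoch)`, tracks the best monitor
#' value, and stops once `patience` consecutive epochs fail to beat the best
#' by at least `min_delta`.
#'
#' @param step_fn function(epoch) doing one epoch of work (may be a no-op).
#' @param monitor_fn function(epoch) returning the monitored scalar
#'   (higher is better).
#' @param max_epochs,patience,min_delta early-stopping parameters.
#' @param on_best optional function(epoch) called when the monitor improves.
#' @return list: `history` (epochs x monitor), `best_epoch`, `best_value`,
#'   `stopped_epoch`, `early_stopped`.
#' @export
run_epochs <- function(step_fn, monitor_fn, max_epochs = 100L,
                       patience = 30L, min_delta = 1e-5, on_best = NULL) {
  best <- -Inf; best_epoch <- 0L; bad <- 0L
  hist <- numeric(0)
  stopped <- 0L; early <- FALSE
  for (epoch in seq_len(max_epochs)) {
    step_fn(epoch)
    val <- monitor_fn(epoch)
    hist[epoch] <- val
    stopped <- epoch
    if (is.finite(val) && val > best + min_delta) {
      best <- val; best_epoch <- epoch; bad <- 0L
      if (!is.null(on_best)) on_best(epoch)
    } else {
      bad <- bad + 1L
      if (bad >= patience) { early <- TRUE; break }
    }
  }
  list(history = hist, best_epoch = best_epoch, best_value = best,
       stopped_epoch = stopped, early_stopped = early)
}

# Monitor: mean foreground smoothed Dice of argmax predictions on a set of
# stacks (eval-mode forward).
monitor_fg_dice <- function(net, stacks, batch_size = 8L) {
  scores <- numeric(length(stacks))
  key <- vapply(stacks, function(s)
    paste(dim(s$channels)[2:3], collapse = "x"), "")
  i <- 1L
  while (i <= length(stacks)) {
    j <- min(i + batch_size - 1L, length(stacks))
    while (any(key[i:j] != key[i])) j <- j - 1L  # same-shape batches only
    x <- stacks_to_tensor(stacks[i:j])
    s <- net_forward(x, net, bn_mode = "eval")$scores
    am <- argmax_classes(s)
    for (n in seq_len(j - i + 1L))
      scores[i + n - 1L] <- smoothed_dice(am[, , n] > 0,
                                          stacks[[i + n - 1L]]$target > 0)
    i <- j + 1L
  }
  mean(scores)
}

#' Train one cascade stage
#'
#' Runs Adam over mini-batches of 2.5D stacks with foreground-biased
#' sampling, monitors mean foreground smoothed Dice each epoch, stops early
#' after `tc$patience` non-improving epochs, and returns the best-epoch
#' weights.
#'
#' @param cases list of `list(volume =, labels =)`, already normalized and
#'   with labels in the stage's vocabulary (binary for the coarse stage).
#' @param config an [net_config()].
#' @param tc a [train_config()].
#' @param monitor_cases optional held-out cases for the monitor; defaults to
#'   the training cases.
#' @param verbose print per-epoch log lines.
#' @return list of class `ns_fit`: `net`, `history` (data.frame with epoch,
#'   loss, monitor), `best_epoch`, `early_stopped`.
#' @export
train_stage <- function(cases, config, tc = train_config(),
                        monitor_cases = NULL, verbose = FALSE) {
  if (length(cases) < 1L) stop("need at least one training case")
  set.seed(tc$seed)
  net <- net_init(config, seed = tc$seed)
  k <- config$in_channels
  stacks <- unlist(lapply(cases, function(cs)
    make_stacks(cs$volume, cs$labels, k = k)), recursive = FALSE)
  has_fg <- vapply(stacks, function(s) any(s$target > 0L), TRUE)
  fg_idx <- which(has_fg); bg_idx <- which(!has_fg)
  mon_stacks <- if (is.null(monitor_cases)) stacks else
    unlist(lapply(monitor_cases, function(cs)
      make_stacks(cs$volume, cs$labels, k = k)), recursive = FALSE)
  if (length(mon_stacks) > tc$monitor_max_stacks) {
    # deterministic evenly spaced subsample, foreground slices first
    ord <- order(!vapply(mon_stacks, function(s) any(s$target > 0L), TRUE))
    keep <- ord[round(seq(1, length(ord), length.out = tc$monitor_max_stacks))]
    mon_stacks <- mon_stacks[sort(unique(keep))]
  }
  n_steps <- tc$steps_per_epoch
  if (is.null(n_steps)) n_steps <- ceiling(length(stacks) / tc$batch_size)
  adam_state <- NULL
  t_global <- 0L
  epoch_loss <- NA_real_
  best_params <- net$params
  # ROI crops differ in extent across cases, so a batch is drawn within one
  # spatial-shape group.
  shape_key <- vapply(stacks, function(s)
    paste(dim(s$channels)[2:3], collapse = "x"), "")
  sample_batch <- function() {
    idx <- integer(tc$batch_size)
    use_fg <- length(fg_idx) > 0 && (length(bg_idx) == 0 || runif(1) < tc$fg_ratio)
    pool <- if (use_fg) fg_idx else bg_idx
    idx[1] <- pool[sample.int(length(pool), 1L)]
    key <- shape_key[idx[1]]
    for (b in seq_len(tc$batch_size)[-1]) {
      use_fg <- length(fg_idx) > 0 && (length(bg_idx) == 0 || runif(1) < tc$fg_ratio)
      pool <- if (use_fg) fg_idx else bg_idx
      pool <- pool[shape_key[pool] == key]
      if (!length(pool)) pool <- which(shape_key == key)
      idx[b] <- pool[sample.int(length(pool), 1L)]
    }
    idx
  }
  step_fn <- function(epoch) {
    losses <- numeric(n_steps)
    for (s in seq_len(n_steps)) {
      idx <- sample_batch()
      x <- stacks_to_tensor(stacks[idx])
      tgt <- array(0L, dim = c(dim(x)[1], dim(x)[2], length(idx)))
      for (n in seq_along(idx)) tgt[, , n] <- stacks[[idx[n]]]$target
      fw <- net_forward(x, net, bn_mode = "train", keep_cache = TRUE)
      lo <- seg_loss(fw$scores, tgt, loss_name = tc$loss_name)
      if (!is.finite(lo$loss))
        stop("divergent loss (non-finite) at epoch ", epoch, " step ", s)
      g <- net_backward(lo$grad, net, fw$cache)
      net$params <<- net_commit_running(net$params, fw$cache)
      t_global <<- t_global + 1L
      r <- adam_step(net$params, g, adam_state, tc$learning_rate, t_global)
      net$params <<- r$p
      adam_state <<- r$s
      losses[s] <- lo$loss
    }
    epoch_loss <<- mean(losses)
  }
  monitor_fn <- function(epoch) {
    v <- monitor_fg_dice(net, mon_stacks)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  fg-dice %.4f", epoch,
                      epoch_loss, v))
    v
  }
  res <- run_epochs(step_fn, monitor_fn, max_epochs = tc$max_epochs,
                    patience = tc$patience, min_delta = tc$min_delta,
                    on_best = function(e) best_params <<- net$params)
  net$params <- best_params
  history <- data.frame(epoch = seq_along(res$history),
                        monitor = res$history)
  structure(list(net = net, history = history, best_epoch = res$best_epoch,
                 best_value = res$best_value,
                 stopped_epoch = res$stopped_epoch,
                 early_stopped = res$early_stopped),
            class = "ns_fit")
}

#' Save / load a network checkpoint
#'
#' A single-file archive holding the architecture config, the weights and
#' the training history.
#'
#' @param fit an `ns_fit` (or a bare `ns_net`).
#' @param path destination `.rds` path.
#' @export
save_checkpoint <- function(fit, path) {
  net <- if (inherits(fit, "ns_net")) fit else fit$net
  history <- if (inherits(fit, "ns_fit")) fit$history else NULL
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(config = net$config, params = net$params, history = history,
               package_version = as.character(utils::packageVersion("nephroseg"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(config = x$config, params = x$params), class = "ns_net")
}

#' Evaluate a cascade on test cases
#'
#' Runs the two-stage cascade on every test case and scores all HEC
#' (hierarchical evaluation class) Dice and Surface Dice values.
#'
#' @param coarse_net,fine_net `ns_net` objects or oracle predictor functions
#'   (`function(volume) -> ns_labels`).
#' @param cases list of `list(volume =, labels =)`; volumes already
#'   normalized for the networks.
#' @param vocabulary `"KITS19"` or `"KITS21"`.
#' @param tolerance_mm Surface Dice tolerance.
#' @param ... passed to [run_cascade()].
#' @return `ns_dice_report`: `per_case` data.frame and `mean` named vector.
#' @export
evaluate_run <- function(coarse_net, fine_net, cases, vocabulary = "KITS21",
                         tolerance_mm = 2, ...) {
  hecs <- hec_definitions(vocabulary)
  rows <- lapply(cases, function(cs) {
    pred <- run_cascade(cs$volume, coarse_net, fine_net,
                        vocabulary = vocabulary, ...)
    row <- list(case = cs$volume$id)
    for (h in names(hecs)) {
      a <- cs$labels$labels %in% hecs[[h]]
      b <- pred$labels %in% hecs[[h]]
      dim(a) <- dim(cs$labels$labels); dim(b) <- dim(pred$labels)
      row[[paste0(h, "_dice")]] <- smoothed_dice(a, b)
      row[[paste0(h, "_sd")]] <- surface_dice(a, b, cs$volume$spacing,
                                              tolerance_mm)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  per_case <- do.call(rbind, rows)
  means <- colMeans(per_case[, -1, drop = FALSE])
  structure(list(per_case = per_case, mean = means,
                 vocabulary = vocabulary, tolerance_mm = tolerance_mm),
            class = "ns_dice_report")
}

#' @export
print.ns_dice_report <- function(x, ...) {
  cat("<ns_dice_report ", nrow(x$per_case), " case(s), ", x$vocabulary,
      ", SD tolerance ", x$tolerance_mm, " mm>\n", sep = "")
  print(round(x$mean, 4))
  invisible(x)
}
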