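# Shared fixtures and independent oracles, regenerated in code (no stored
# binaries).

# A small, fast phantom for plumbing tests: 12 slices, 32x32 in-plane.
tiny_spec <- function(seed = 1L, tumor = TRUE, cyst = FALSE) {
  phantom_spec(shape = c(12L, 32L, 32L), spacing = c(3, 1, 1),
               kidney_axes = c(4, 6, 4),
               kidney_centers = list(c(6, 16, 9), c(6, 16, 23)),
               tumor = if (tumor) list(center = c(6, 20, 10),
                                       radii = c(2, 3, 3)) else NULL,
               cyst = if (cyst) list(center = c(6, 13, 22),
                                     radii = c(1.5, 2.5, 2.5)) else NULL,
               noise_sd = 10, seed = seed)
}

tiny_case <- function(seed = 1L, ...) generate_case(tiny_spec(seed = seed, ...))

# Independent dense 2D convolution oracle (stride 1, symmetric padding).
naive_conv2d <- function(x, w, b, pad) {
  d <- dim(x); k <- dim(w)
  y <- array(0, c(d[1], d[2], k[4], d[4]))
  for (n in seq_len(d[4])) for (o in seq_len(k[4])) {
    acc <- matrix(b[o], d[1], d[2])
    for (ci in seq_len(d[3])) for (i in seq_len(k[1])) for (j in seq_len(k[2])) {
      sh <- i - 1 - pad; sw <- j - 1 - pad
      for (hh in seq_len(d[1])) for (ww in seq_len(d[2])) {
        ih <- hh + sh; iw <- ww + sw
        if (ih >= 1 && ih <= d[1] && iw >= 1 && iw <= d[2])
          acc[hh, ww] <- acc[hh, ww] + x[ih, iw, ci, n] * w[i, j, ci, o]
      }
    }
    y[, , o, n] <- acc
  }
  y
}

# Brute-force all-pairs surface-distance oracle for Surface Dice.
naive_surface_dice <- function(a, b, spacing, tol) {
  bnd <- function(m) {
    d <- dim(m)
    out <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (!m[i, j, k]) next
      nb_bg <- FALSE
      for (sft in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                       c(0,0,1), c(0,0,-1))) {
        p <- c(i, j, k) + sft
        if (any(p < 1) || any(p > d) || !m[p[1], p[2], p[3]]) { nb_bg <- TRUE; break }
      }
      if (nb_bg) out <- rbind(out, c(i, j, k))
    }
    out
  }
  pa <- bnd(a); pb <- bnd(b)
  na <- if (is.null(pa)) 0L else nrow(pa)
  nb <- if (is.null(pb)) 0L else nrow(pb)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  mm_a <- sweep(pa, 2, spacing, `*`)
  mm_b <- sweep(pb, 2, spacing, `*`)
  mind <- function(p, q) {
    apply(p, 1, function(r) sqrt(min(colSums((t(q) - r)^2))))
  }
  matched_a <- sum(mind(mm_a, mm_b) <= tol + 1e-9)
  matched_b <- sum(mind(mm_b, mm_a) <= tol + 1e-9)
  (matched_a + matched_b) / (na + nb)
}

# Random blob mask generator for metric property tests.
random_mask <- function(shape, n_seeds = 3L, radius = 2.5) {
  m <- array(FALSE, shape)
  for (s in seq_len(n_seeds)) {
    ctr <- sapply(shape, function(e) sample.int(e, 1))
    for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
      for (k in seq_len(shape[3]))
        if (sum((c(i, j, k) - ctr)^2) <= radius^2) m[i, j, k] <- TRUE
  }
  m
}

# Oracle predictor factories for cascade plumbing tests: perfect networks
# backed by the ground truth.
oracle_coarse <- function(truth) {
  function(volume) {
    lab <- array(as.integer(truth$labels > 0L), dim(truth$labels))
    new_label_volume(lab, "KITS19", spacing = volume$spacing,
                     affine = volume$affine, id = volume$id)
  }
}

oracle_fine <- function(truth, vocabulary = "KITS21") {
  full <- truth$labels
  function(volume) {
    # locate the crop inside the full volume via the affine translation
    off <- round(solve(truth$affine[1:3, 1:3]) %*%
                   (volume$affine[1:3, 4] - truth$affine[1:3, 4]))
    d <- dim(volume$intensities)
    idx <- lapply(1:3, function(ax) off[ax] + seq_len(d[ax]))
    sub <- full[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    new_label_volume(sub, vocabulary, spacing = volume$spacing,
                     affine = volume$affine, id = volume$id)
  }
}
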