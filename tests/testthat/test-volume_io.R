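# NIfTI round trips, case reading, preprocessing and in-plane resampling.

test_that("NIfTI round trip is voxel-exact for labels and tolerance-exact for affine", {
  dir <- withr::local_tempdir()
  set.seed(3)
  lab <- array(sample(0:3, 16 * 8 * 8, replace = TRUE), c(16L, 8L, 8L))
  aff <- rbind(cbind(diag(c(3, 0.8, 0.8)), c(-120.5, 30.25, -4)), c(0, 0, 0, 1))
  p <- file.path(dir, "seg.nii.gz")
  write_nifti(lab, p, spacing = c(3, 0.8, 0.8), affine = aff, datatype = "uint8")
  rt <- read_nifti(p)
  expect_identical(array(as.integer(rt$data), dim(rt$data)),
                   array(as.integer(lab), dim(lab)))
  expect_lt(max(abs(rt$affine - aff)), 1e-6)
  expect_equal(rt$spacing, c(3, 0.8, 0.8), tolerance = 1e-6)

  # float32 intensities round trip to float32 precision; empty label too
  img <- array(rnorm(16 * 8 * 8, sd = 200), c(16L, 8L, 8L))
  p2 <- file.path(dir, "img.nii")
  write_nifti(img, p2, datatype = "float32")
  expect_lt(max(abs(read_nifti(p2)$data - img)), 1e-3)
  z <- array(0L, c(4L, 4L, 4L))
  p3 <- file.path(dir, "zero.nii.gz")
  write_nifti(z, p3, datatype = "uint8")
  expect_true(all(read_nifti(p3)$data == 0))
})

test_that("NIfTI writer/reader agree with the nibabel oracle", {
  dir <- withr::local_tempdir()
  py <- Sys.which("python")
  set.seed(4)
  lab <- array(sample(0:3, 6 * 5 * 4, replace = TRUE), c(6L, 5L, 4L))
  p <- file.path(dir, "ours.nii.gz")
  write_nifti(lab, p, spacing = c(3, 0.8, 0.8), datatype = "uint8")
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import nibabel, numpy as np, sys",
    sprintf("im = nibabel.load(r'%s')", p),
    "d = np.asanyarray(im.dataobj)",
    "print(','.join(map(str, d.shape)))",
    "print(int(d.sum()))",
    "print(','.join('%.6f' % v for v in im.affine.ravel()))",
    # nibabel writes a file our reader must parse back
    sprintf("out = r'%s'", file.path(dir, "theirs.nii.gz")),
    "arr = (np.arange(60) % 4).reshape(3, 4, 5).astype(np.int16)",
    "aff = np.diag([3.0, 0.8, 0.8, 1.0])",
    "nibabel.save(nibabel.Nifti1Image(arr, aff), out)"
  ), script)
  res <- system2(py, script, stdout = TRUE)
  expect_equal(res[1], "6,5,4")
  expect_equal(as.integer(res[2]), sum(lab))
  their_aff <- matrix(as.numeric(strsplit(res[3], ",")[[1]]), 4, 4, byrow = TRUE)
  expect_lt(max(abs(their_aff - diag(c(3, 0.8, 0.8, 1)))), 1e-5)
  theirs <- read_nifti(file.path(dir, "theirs.nii.gz"))
  # Fortran-order memory layout matches: value at (i,j,k) is (i-1+... ) %% 4
  expect_identical(dim(theirs$data), c(3L, 4L, 5L))
  arr <- array((seq_len(60) - 1L) %% 4L, c(3L, 4L, 5L))  # C-order fill
  arr_c <- aperm(array((seq_len(60) - 1L) %% 4L, c(5L, 4L, 3L)), c(3, 2, 1))
  expect_identical(array(as.integer(theirs$data), dim(theirs$data)), arr_c)
})

test_that("read_case validates vocabulary and shape", {
  dir <- withr::local_tempdir()
  cs <- tiny_case(seed = 2, cyst = TRUE)
  img <- file.path(dir, "imaging.nii.gz")
  seg <- file.path(dir, "segmentation.nii.gz")
  write_volume(cs$volume, img)
  write_label(cs$labels, cs$volume, seg)
  got <- read_case(img, seg, vocabulary = "KITS21")
  expect_identical(dim(got$volume$intensities), dim(cs$volume$intensities))
  expect_identical(got$labels$labels, cs$labels$labels)
  # same labels with the KiTS19 vocabulary: value 3 must be named
  expect_error(read_case(img, seg, vocabulary = "KITS19"), "3")
  # shape mismatch
  seg2 <- file.path(dir, "bad.nii.gz")
  write_nifti(cs$labels$labels[, , 1:30], seg2, datatype = "uint8")
  expect_error(read_case(img, seg2), "mismatch")
  expect_error(read_case(file.path(dir, "nope.nii.gz")), "cannot read")
})

test_that("foreground statistics follow the population convention", {
  lab <- array(0L, c(2L, 4L, 4L))
  lab[1, 1:2, 1] <- 1L
  labs <- new_label_volume(lab, "KITS19", spacing = c(1, 1, 1))
  v <- array(100, c(2L, 4L, 4L))
  vol <- new_volume(v, spacing = c(1, 1, 1))
  st <- compute_foreground_stats(vol, labs)
  expect_equal(st$mean, 100)
  expect_equal(st$std, 1e-6)  # epsilon floor on a constant region

  v[1, 1, 1] <- 0; v[1, 2, 1] <- 10
  vol2 <- new_volume(v, spacing = c(1, 1, 1))
  st2 <- compute_foreground_stats(vol2, labs)
  expect_equal(st2$mean, 5)
  expect_equal(st2$std, 5)  # population sd of {0, 10}

  empty <- new_label_volume(array(0L, c(2L, 4L, 4L)), "KITS19",
                            spacing = c(1, 1, 1))
  expect_error(compute_foreground_stats(vol, empty), "foreground")
})

test_that("normalization is exact and invertible on the clipped range", {
  st <- structure(list(mean = 50, std = 10, clip_low = -200, clip_high = 500),
                  class = "ns_norm_stats")
  v <- array(c(50, 60, 900, -500), c(1L, 2L, 2L))
  vol <- new_volume(v, spacing = c(1, 1, 1))
  out <- normalize_volume(vol, st)$intensities
  expect_equal(out[1, 1, 1], 0)
  expect_equal(out[1, 2, 1], 1)
  expect_equal(out[1, 1, 2], (500 - 50) / 10)   # clipped to clip_high
  expect_equal(out[1, 2, 2], (-200 - 50) / 10)  # clipped to clip_low
  # invertible: x' * std + mean reproduces the clipped intensities
  clipped <- pmin(pmax(v, -200), 500)
  expect_equal(out * 10 + 50, clipped)
})

test_that("in-plane resampling: identity, constant and checkerboard oracle", {
  cs <- tiny_case(seed = 5)
  same <- resample_inplane(cs$labels, c(32L, 32L))
  expect_identical(same$labels, cs$labels$labels)  # nearest identity is bitwise
  const <- new_volume(array(7, c(4L, 8L, 8L)), spacing = c(1, 1, 1))
  up <- resample_inplane(const, c(16L, 12L))
  expect_true(all(abs(up$intensities - 7) < 1e-12))
  expect_identical(dim(up$intensities), c(4L, 16L, 12L))
  # 2x nearest-neighbour upsample duplicates each checkerboard cell 2x2
  chk <- array(0L, c(1L, 4L, 4L))
  chk[1, , ] <- outer(1:4, 1:4, function(i, j) (i + j) %% 2L)
  lab <- new_label_volume(chk, "KITS19", spacing = c(1, 1, 1))
  up2 <- resample_inplane(lab, c(8L, 8L))$labels
  oracle <- chk[1, rep(1:4, each = 2), rep(1:4, each = 2)]
  expect_identical(up2[1, , ], oracle)
  expect_error(resample_inplane(cs$volume, c(0L, 8L)), "positive")
})
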