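# Case-level I/O and intensity preprocessing.

#' Read a KiTS-layout case
#'
#' Loads an imaging NIfTI and (optionally) its segmentation, validating the
#' segmentation against a label vocabulary and against the image shape.
#'
#' @param image_path path to the imaging NIfTI.
#' @param label_path optional path to the segmentation NIfTI.
#' @param vocabulary `"KITS19"` or `"KITS21"`.
#' @param id case identifier; defaults to the image's directory name.
#' @return list with `volume` ([new_volume()]) and `labels`
#'   ([new_label_volume()] or `NULL`).
#' @export
read_case <- function(image_path, label_path = NULL, vocabulary = "KITS21",
                      id = basename(dirname(normalizePath(image_path,
                                                          mustWork = FALSE)))) {
  img <- read_nifti(image_path)
  vol <- new_volume(img$data, spacing = img$spacing, affine = img$affine,
                    id = id)
  lab <- NULL
  if (!is.null(label_path)) {
    seg <- read_nifti(label_path)
    if (!identical(dim(seg$data), dim(img$data)))
      stop("image/label shape mismatch for case '", id, "': ",
           paste(dim(img$data), collapse = "x"), " vs ",
           paste(dim(seg$data), collapse = "x"))
    lab <- new_label_volume(seg$data, vocabulary = vocabulary,
                            spacing = seg$spacing, affine = seg$affine,
                            id = id)
  }
  list(volume = vol, labels = lab)
}

#' Read a `case_XXXXX/` directory
#'
#' Expects `imaging.nii.gz` and optionally `segmentation.nii.gz`, mirroring
#' the KiTS repositories.
#'
#' @param case_dir directory path.
#' @inheritParams read_case
#' @export
read_case_dir <- function(case_dir, vocabulary = "KITS21") {
  img <- file.path(case_dir, "imaging.nii.gz")
  seg <- file.path(case_dir, "segmentation.nii.gz")
  read_case(img, if (file.exists(seg)) seg else NULL, vocabulary,
            id = basename(case_dir))
}

#' Foreground intensity statistics
#'
#' Mean and standard deviation of the image intensities over all nonzero-label
#' ("normal foreground") voxels, after clipping to an HU window.  The standard
#' deviation uses the population convention (divide by N) and is floored at
#' 1e-6 so constant regions remain usable.
#'
#' @param volume an `ns_volume`.
#' @param labels an `ns_labels` with at least one nonzero voxel.
#' @param window `c(clip_low, clip_high)` HU clipping window applied before
#'   the statistics and again in [normalize_volume()].
#' @return list of class `ns_norm_stats`: `mean`, `std`, `clip_low`,
#'   `clip_high`.
#' @export
compute_foreground_stats <- function(volume, labels, window = c(-200, 500)) {
  stopifnot(inherits(volume, "ns_volume"), inherits(labels, "ns_labels"))
  if (window[1] >= window[2]) stop("window must satisfy clip_low < clip_high")
  fg <- labels$labels > 0L
  if (!any(fg)) stop("no foreground voxels: label volume is all background")
  v <- pmin(pmax(volume$intensities[fg], window[1]), window[2])
  n <- length(v)
  m <- mean(v)
  s <- sqrt(sum((v - m)^2) / n)
  structure(list(mean = m, std = max(s, 1e-6),
                 clip_low = window[1], clip_high = window[2]),
            class = "ns_norm_stats")
}

#' Normalize a volume
#'
#' Clips intensities to the stats' window, then standardises:
#' `(clip(x) - mean) / std`.  Shape, spacing and affine are preserved.
#'
#' @param volume an `ns_volume`.
#' @param stats an `ns_norm_stats` from [compute_foreground_stats()] (or
#'   constructed manually).
#' @export
normalize_volume <- function(volume, stats) {
  stopifnot(inherits(volume, "ns_volume"))
  if (stats$std <= 0) stop("stats$std must be > 0")
  if (stats$clip_low >= stats$clip_high) stop("invalid clip window")
  x <- pmin(pmax(volume$intensities, stats$clip_low), stats$clip_high)
  new_volume((x - stats$mean) / stats$std, spacing = volume$spacing,
             affine = volume$affine, id = volume$id)
}

#' Resample axial slices in-plane
#'
#' Resamples every axial slice to a target height/width: bilinear
#' interpolation for intensities (`ns_volume`), nearest-neighbour for labels
#' (`ns_labels`).  In-plane spacing is rescaled accordingly.
#'
#' @param x an `ns_volume` or `ns_labels`.
#' @param target_hw integer `c(height, width)`, both >= 1.
#' @export
resample_inplane <- function(x, target_hw) {
  target_hw <- as.integer(target_hw)
  if (length(target_hw) != 2L || any(target_hw < 1L))
    stop("target_hw must be two positive integers")
  if (inherits(x, "ns_volume")) {
    d <- dim(x$intensities)
    y <- cpp_resize_inplane(array(as.numeric(x$intensities), d),
                            target_hw[1], target_hw[2], FALSE)
    dim(y) <- c(d[1], target_hw)
    sp <- c(x$spacing[1], x$spacing[2] * d[2] / target_hw[1],
            x$spacing[3] * d[3] / target_hw[2])
    new_volume(y, spacing = sp, affine = x$affine, id = x$id)
  } else if (inherits(x, "ns_labels")) {
    d <- dim(x$labels)
    storage.mode(d) <- "integer"
    y <- cpp_resize_inplane(array(as.numeric(x$labels), d),
                            target_hw[1], target_hw[2], TRUE)
    dim(y) <- c(d[1], target_hw)
    sp <- c(x$spacing[1], x$spacing[2] * d[2] / target_hw[1],
            x$spacing[3] * d[3] / target_hw[2])
    new_label_volume(y, vocabulary = x$vocabulary, spacing = sp,
                     affine = x$affine, id = x$id)
  } else stop("resample_inplane expects an ns_volume or ns_labels")
}

#' Write a label volume as NIfTI
#'
#' Writes with the reference volume's affine and spacing so predictions align
#' with their source image.  Round trips voxel-exactly through [read_case()].
#'
#' @param labels an `ns_labels`, same shape as `reference`.
#' @param reference an `ns_volume` supplying affine/spacing.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_label <- function(labels, reference, path) {
  stopifnot(inherits(labels, "ns_labels"), inherits(reference, "ns_volume"))
  if (!identical(dim(labels$labels), dim(reference$intensities)))
    stop("label shape does not match reference volume")
  write_nifti(labels$labels, path, spacing = reference$spacing,
              affine = reference$affine, datatype = "uint8")
}

#' Write a volume as NIfTI
#'
#' @param volume an `ns_volume`.
#' @param path output path.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ns_volume"))
  write_nifti(volume$intensities, path, spacing = volume$spacing,
              affine = volume$affine, datatype = "float32")
}
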