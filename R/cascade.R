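# Coarse-to-fine cascade: whole-volume kidney localisation, ROI extraction,
# fine-stage lesion segmentation inside the crop, paste-back and merging.

#' Extract a kidney region-of-interest box
#'
#' Tight bounding box of all foreground voxels of a (coarse) mask, expanded
#' by a per-axis margin and clamped to the volume bounds.  Bounds are stored
#' 1-based inclusive.
#'
#' @param mask an `ns_labels` or a 3D array; foreground is any value > 0.
#' @param margin voxels added per side on each axis (length 1 or 3).
#'   Default: 4 slices axially, 16 voxels in-plane.
#' @return list of class `ns_roi`: `lo`, `hi` (1-based inclusive), `margin`,
#'   `source_shape`.
#' @export
extract_roi <- function(mask, margin = c(4L, 16L, 16L)) {
  arr <- if (inherits(mask, "ns_labels")) mask$labels else mask
  if (length(margin) == 1L) margin <- rep(margin, 3L)
  shp <- dim(arr)
  fg <- which(arr > 0L, arr.ind = TRUE)
  if (nrow(fg) == 0L)
    stop("no-kidney-found: mask has no foreground voxels")
  lo <- pmax(apply(fg, 2, min) - margin, 1L)
  hi <- pmin(apply(fg, 2, max) + margin, shp)
  structure(list(lo = as.integer(lo), hi = as.integer(hi),
                 margin = as.integer(margin),
                 source_shape = as.integer(shp)),
            class = "ns_roi")
}

#' @export
print.ns_roi <- function(x, ...) {
  cat(sprintf("<ns_roi [%s] - [%s] of %s (margin %s)>\n",
              paste(x$lo, collapse = ","), paste(x$hi, collapse = ","),
              paste(x$source_shape, collapse = "x"),
              paste(x$margin, collapse = ",")))
  invisible(x)
}

roi_extent <- function(box) box$hi - box$lo + 1L

# Grow a box (within the source bounds) so in-plane extents are divisible by
# `mult`, as required by a depth-limited network.
roi_pad_to_multiple <- function(box, mult) {
  mult <- as.integer(mult)
  for (ax in 2:3) {
    e <- box$hi[ax] - box$lo[ax] + 1L
    need <- (mult - e %% mult) %% mult
    if (need == 0L) next
    if (e + need > box$source_shape[ax])
      stop("cannot pad ROI axis ", ax, " to a multiple of ", mult)
    grow_hi <- min(need, box$source_shape[ax] - box$hi[ax])
    box$hi[ax] <- box$hi[ax] + grow_hi
    box$lo[ax] <- box$lo[ax] - (need - grow_hi)
  }
  box
}

#' Crop a volume or label volume to an ROI box
#'
#' @param x an `ns_volume` or `ns_labels`.
#' @param box an `ns_roi` valid for `x`'s shape.
#' @export
crop <- function(x, box) {
  arr <- if (inherits(x, "ns_volume")) x$intensities else x$labels
  if (!identical(dim(arr), as.integer(box$source_shape)))
    stop("ROI box was built for shape ",
         paste(box$source_shape, collapse = "x"), ", input is ",
         paste(dim(arr), collapse = "x"))
  sub <- arr[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3],
             drop = FALSE]
  aff <- x$affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% (box$lo - 1L)
  if (inherits(x, "ns_volume"))
    new_volume(sub, spacing = x$spacing, affine = aff, id = x$id)
  else
    new_label_volume(sub, vocabulary = x$vocabulary, spacing = x$spacing,
                     affine = aff, id = x$id)
}

#' Paste a fine-stage mask back into full-volume coordinates
#'
#' @param fine an `ns_labels` whose shape equals the box extent.
#' @param box the `ns_roi` the crop came from.
#' @return full-shape `ns_labels`: fine labels inside the box, background
#'   outside.
#' @export
paste_back <- function(fine, box) {
  if (!identical(dim(fine$labels), as.integer(roi_extent(box))))
    stop("fine mask extent ", paste(dim(fine$labels), collapse = "x"),
         " does not match ROI extent ",
         paste(roi_extent(box), collapse = "x"))
  out <- array(0L, dim = box$source_shape)
  out[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <-
    fine$labels
  aff <- fine$affine
  aff[1:3, 4] <- aff[1:3, 4] - aff[1:3, 1:3] %*% (box$lo - 1L)
  new_label_volume(out, vocabulary = fine$vocabulary, spacing = fine$spacing,
                   affine = aff, id = fine$id)
}

# Predict with either an ns_net or an oracle function(volume) -> ns_labels.
predict_with <- function(net, volume, vocabulary, k = NULL) {
  if (is.function(net)) return(net(volume))
  predict_volume(volume, net, vocabulary = vocabulary)
}

#' Run the two-stage cascade on a volume
#'
#' Stage 1 segments kidney-vs-background over the whole volume; a margin-
#' expanded bounding box of the kidney mask is cropped; stage 2 classifies
#' tumor (and cyst) inside the crop; fine labels are pasted back.  Where the
#' fine net predicts background but the coarse net found kidney, the voxel is
#' kept as kidney (`merge_keep_kidney`, on by default).
#'
#' If the coarse stage finds no kidney at all the result is all background
#' with attribute `no_kidney_found = TRUE`.
#'
#' @param volume an `ns_volume`, already normalized for the networks.
#' @param coarse_net,fine_net `ns_net` objects, or oracle predictor
#'   functions `function(volume) -> ns_labels` (used by the plumbing tests).
#' @param margin ROI margin per axis (axial, height, width).
#' @param vocabulary vocabulary of the fine stage / output.
#' @param merge_keep_kidney keep coarse kidney voxels the fine net left
#'   unclassified.
#' @return an `ns_labels` over `vocabulary`.
#' @export
run_cascade <- function(volume, coarse_net, fine_net,
                        margin = c(4L, 16L, 16L), vocabulary = "KITS21",
                        merge_keep_kidney = TRUE) {
  coarse <- predict_with(coarse_net, volume, vocabulary = "KITS19")
  coarse_bin <- coarse$labels > 0L
  if (!any(coarse_bin)) {
    out <- new_label_volume(array(0L, dim = dim(volume$intensities)),
                            vocabulary = vocabulary,
                            spacing = volume$spacing, affine = volume$affine,
                            id = volume$id)
    attr(out, "no_kidney_found") <- TRUE
    warning("cascade: coarse stage found no kidney; returning background")
    return(out)
  }
  box <- extract_roi(coarse, margin = margin)
  if (!is.function(fine_net))
    box <- roi_pad_to_multiple(box, 2L^(fine_net$config$depth - 1L))
  fine <- predict_with(fine_net, crop(volume, box), vocabulary = vocabulary)
  full <- paste_back(fine, box)
  if (merge_keep_kidney) {
    lab <- full$labels
    keep <- lab == 0L & coarse_bin
    lab[keep] <- 1L
    full <- new_label_volume(lab, vocabulary = vocabulary,
                             spacing = full$spacing, affine = volume$affine,
                             id = volume$id)
  }
  attr(full, "no_kidney_found") <- FALSE
  full
}
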