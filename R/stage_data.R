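# Preparing per-stage training data: normalization with frozen training-set
# foreground statistics, coarse binary relabelling, fine-stage ROI crops
# derived from ground-truth kidney boxes.

#' Compute frozen normalization statistics over a training split
#'
#' Pools the foreground voxels of all training cases, mirroring "statistics
#' computed once over the training split and frozen".
#'
#' @param cases list of `list(volume =, labels =)`.
#' @param window HU clipping window.
#' @export
cohort_foreground_stats <- function(cases, window = c(-200, 500)) {
  vals <- unlist(lapply(cases, function(cs) {
    fg <- cs$labels$labels > 0L
    pmin(pmax(cs$volume$intensities[fg], window[1]), window[2])
  }))
  if (!length(vals)) stop("no foreground voxels in the training cases")
  m <- mean(vals)
  s <- sqrt(sum((vals - m)^2) / length(vals))
  structure(list(mean = m, std = max(s, 1e-6),
                 clip_low = window[1], clip_high = window[2]),
            class = "ns_norm_stats")
}

#' Prepare cases for one cascade stage
#'
#' Coarse stage: normalizes the volume and maps every foreground label to 1
#' (kidney-vs-background, KITS19 vocabulary).  Fine stage: crops both volume
#' and labels to the ground-truth kidney ROI (margin-expanded, padded so the
#' in-plane extent divides `2^(depth-1)`), keeping the native vocabulary.
#'
#' @param cases list of `list(volume =, labels =)`.
#' @param stage `"coarse"` or `"fine"`.
#' @param stats frozen `ns_norm_stats` (from [cohort_foreground_stats()]).
#' @param margin fine-stage ROI margin.
#' @param depth network depth (for in-plane divisibility of fine crops).
#' @export
prepare_stage_cases <- function(cases, stage = c("coarse", "fine"), stats,
                                margin = c(4L, 16L, 16L), depth = 3L) {
  stage <- match.arg(stage)
  lapply(cases, function(cs) {
    vol <- normalize_volume(cs$volume, stats)
    if (stage == "coarse") {
      lab <- cs$labels$labels
      lab[lab > 0L] <- 1L
      list(volume = vol,
           labels = new_label_volume(lab, vocabulary = "KITS19",
                                     spacing = cs$labels$spacing,
                                     affine = cs$labels$affine,
                                     id = cs$labels$id))
    } else {
      box <- extract_roi(cs$labels, margin = margin)
      box <- roi_pad_to_multiple(box, 2L^(depth - 1L))
      list(volume = crop(vol, box), labels = crop(cs$labels, box),
           roi = box)
    }
  })
}
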