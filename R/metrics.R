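# Evaluation metrics: smoothed Dice, tolerance-based Surface Dice, and the
# KiTS hierarchical evaluation class (HEC) foreground compositions.

#' HEC foreground definitions
#'
#' KiTS21: kidney = \{1,2,3\}, mass = \{2,3\}, tumor = \{2\}, cyst = \{3\}.
#' KiTS19: kidney = \{1,2\}, tumor = \{2\}.
#'
#' @param vocabulary `"KITS19"` or `"KITS21"`.
#' @return named list of integer foreground label sets.
#' @export
hec_definitions <- function(vocabulary = "KITS21") {
  switch(match.arg(vocabulary, c("KITS19", "KITS21")),
         KITS21 = list(kidney = c(1L, 2L, 3L), mass = c(2L, 3L),
                       tumor = 2L, cyst = 3L),
         KITS19 = list(kidney = c(1L, 2L), tumor = 2L))
}

#' Smoothed Dice coefficient
#'
#' Per-image Dice with +1 smoothing in numerator and denominator:
#' `(2|A intersect B| + 1) / (|A| + |B| + 1)`.  Two empty masks therefore
#' score 1.  Converges to the classical Dice for large masks.
#'
#' @param a,b logical (or 0/1) arrays of identical shape.
#' @return scalar in (0, 1].
#' @export
smoothed_dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("smoothed_dice: shape mismatch (",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"), ")")
  a <- as.logical(a); b <- as.logical(b)
  (2 * sum(a & b) + 1) / (sum(a) + sum(b) + 1)
}

#' Mean smoothed Dice over cases for one HEC
#'
#' Binarizes label and prediction by the HEC's foreground label set, scores
#' each case with [smoothed_dice()], and averages.
#'
#' @param cases list of `list(label =, prediction =)`; each element an
#'   `ns_labels` or a 3D integer array.
#' @param foreground_labels integer set defining the HEC foreground (e.g. an
#'   element of [hec_definitions()]).
#' @export
mean_dice <- function(cases, foreground_labels) {
  if (length(cases) < 1L) stop("mean_dice: empty case list")
  as_arr <- function(x) if (inherits(x, "ns_labels")) x$labels else x
  mean(vapply(cases, function(cs) {
    a <- as_arr(cs$label); b <- as_arr(cs$prediction)
    am <- array(a %in% foreground_labels, dim = dim(a))
    bm <- array(b %in% foreground_labels, dim = dim(b))
    smoothed_dice(am, bm)
  }, 0))
}

#' Boundary voxels of a binary mask
#'
#' A foreground voxel is a boundary voxel if at least one of its 6
#' face-adjacent neighbours is background; voxels on the volume edge count
#' as boundary (outside is background).
#'
#' @param mask 3D logical array.
#' @return 3D logical array of boundary voxels.
#' @export
mask_boundary <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  shift_and <- function(m, ax, by) {
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by == 1L) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(1L, -1L))
    interior <- interior & shift_and(mask, ax, by)
  mask & !interior
}

#' Tolerance-based Surface Dice
#'
#' Extracts the 6-connectivity boundary voxels of both masks and scores the
#' fraction of boundary voxels of each mask lying within `tolerance_mm` of
#' the other mask's boundary (distances between voxel centres, honouring
#' anisotropic spacing, computed with an exact Euclidean distance
#' transform):
#' `(|dA within tol of dB| + |dB within tol of dA|) / (|dA| + |dB|)`.
#' Both masks empty scores 1; exactly one empty scores 0.
#'
#' @param a,b 3D logical (or 0/1) arrays of identical shape.
#' @param spacing voxel size per axis in mm.
#' @param tolerance_mm non-negative distance tolerance in mm.
#' @return scalar in [0, 1].
#' @export
surface_dice <- function(a, b, spacing = c(1, 1, 1), tolerance_mm = 1) {
  if (!identical(dim(a), dim(b))) stop("surface_dice: shape mismatch")
  if (tolerance_mm < 0) stop("tolerance must be >= 0")
  a <- array(as.logical(a), dim = dim(a))
  b <- array(as.logical(b), dim = dim(b))
  ba <- mask_boundary(a); bb <- mask_boundary(b)
  na <- sum(ba); nb <- sum(bb)
  if (na == 0L && nb == 0L) return(1)
  if (na == 0L || nb == 0L) return(0)
  tol_sq <- tolerance_mm^2 + 1e-9  # float slack on the squared comparison
  dt_b <- cpp_edt_sq(bb, as.numeric(spacing))
  dt_a <- cpp_edt_sq(ba, as.numeric(spacing))
  matched_a <- sum(dt_b[ba] <= tol_sq)
  matched_b <- sum(dt_a[bb] <= tol_sq)
  (matched_a + matched_b) / (na + nb)
}
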