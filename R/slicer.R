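# 2.5D slice stacking: k adjacent axial slices in, the middle slice's mask
# out, and the inverse reassembly of per-slice predictions into a 3D volume.

#' Build 2.5D slice stacks
#'
#' For every axial slice of the volume, builds a stack of the `k` adjacent
#' slices centred on it (channels ordered by increasing axial index), paired
#' with the centre slice's label mask when labels are given.  Neighbour
#' indices outside the volume are handled by `edge_policy`: `"replicate"`
#' repeats the boundary slice, `"zero"` inserts a zero slice.
#'
#' @param volume an `ns_volume`.
#' @param labels optional `ns_labels` of the same shape.
#' @param k odd stack size >= 1 (3 and 5 are the usual variants).
#' @param edge_policy `"replicate"` (default) or `"zero"`.
#' @return list of stacks; each has `channels` (array k x H x W),
#'   `center_index` (1-based axial index), `case_id`, and `target`
#'   (H x W integer mask or `NULL`).
#' @export
make_stacks <- function(volume, labels = NULL, k = 3L,
                        edge_policy = c("replicate", "zero")) {
  edge_policy <- match.arg(edge_policy)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k %% 2L == 0L) stop("k must be odd, got ", k)
  d <- dim(volume$intensities)
  if (k > 2L * d[1] - 1L) stop("k = ", k, " too large for ", d[1], " slices")
  if (!is.null(labels) && !identical(dim(labels$labels), d))
    stop("labels shape does not match volume")
  half <- (k - 1L) %/% 2L
  lapply(seq_len(d[1]), function(center) {
    ch <- array(0, dim = c(k, d[2], d[3]))
    for (j in seq_len(k)) {
      src <- center - half + (j - 1L)
      if (src >= 1L && src <= d[1]) {
        ch[j, , ] <- volume$intensities[src, , ]
      } else if (edge_policy == "replicate") {
        ch[j, , ] <- volume$intensities[min(max(src, 1L), d[1]), , ]
      } # "zero": leave as 0
    }
    list(channels = ch, center_index = center, case_id = volume$id,
         target = if (!is.null(labels)) labels$labels[center, , ] else NULL)
  })
}

#' Reassemble per-slice predictions into a label volume
#'
#' The inverse of the 2.5D scheme: each prediction fills the axial slice at
#' its centre index.  Every index `1..num_slices` must appear exactly once.
#'
#' @param predictions list of `list(center_index =, mask =)` entries (the
#'   stacks from [make_stacks()] with `target` also work, using the target as
#'   the mask).
#' @param num_slices axial extent of the output.
#' @param vocabulary label vocabulary of the output volume.
#' @param spacing,affine,id metadata for the output volume.
#' @return an `ns_labels`.
#' @export
reassemble <- function(predictions, num_slices, vocabulary = "KITS21",
                       spacing = c(3, 0.8, 0.8),
                       affine = diag(c(spacing, 1)), id = "case") {
  idx <- vapply(predictions, function(p) as.integer(p$center_index), 1L)
  missing_i <- setdiff(seq_len(num_slices), idx)
  if (length(missing_i))
    stop("missing prediction for slice index(es): ",
         paste(missing_i, collapse = ", "))
  dup <- unique(idx[duplicated(idx)])
  if (length(dup))
    stop("duplicate prediction for slice index(es): ",
         paste(dup, collapse = ", "))
  get_mask <- function(p) if (!is.null(p$mask)) p$mask else p$target
  m1 <- get_mask(predictions[[1]])
  if (is.null(m1)) stop("predictions carry neither $mask nor $target")
  hw <- dim(m1)
  out <- array(0L, dim = c(num_slices, hw[1], hw[2]))
  for (p in predictions) {
    m <- get_mask(p)
    if (!identical(dim(m), hw)) stop("inconsistent prediction shapes")
    out[p$center_index, , ] <- as.integer(m)
  }
  new_label_volume(out, vocabulary = vocabulary, spacing = spacing,
                   affine = affine, id = id)
}

# Stack a list of slice stacks into the (H, W, C, N) tensor the network eats.
stacks_to_tensor <- function(stacks) {
  k <- dim(stacks[[1]]$channels)[1]
  H <- dim(stacks[[1]]$channels)[2]
  W <- dim(stacks[[1]]$channels)[3]
  x <- array(0, dim = c(H, W, k, length(stacks)))
  for (n in seq_along(stacks))
    x[, , , n] <- aperm(stacks[[n]]$channels, c(2, 3, 1))
  x
}
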