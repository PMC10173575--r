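# Volume and label containers.
#
# A volume is a 3D scalar grid with axis 1 = axial slices (the KiTS
# num_slices-height-width layout), plus voxel spacing (mm) and a 4x4 NIfTI
# affine.  A label volume additionally declares its label vocabulary.

#' Label vocabularies
#'
#' KiTS19 codes background/kidney/tumor as 0/1/2; KiTS21 adds cyst = 3.
#'
#' @param vocabulary `"KITS19"` or `"KITS21"`.
#' @return integer vector of admissible voxel values.
#' @export
vocab_values <- function(vocabulary) {
  switch(match.arg(vocabulary, c("KITS19", "KITS21")),
         KITS19 = 0:2, KITS21 = 0:3)
}

#' Construct a CT volume
#'
#' @param intensities 3D numeric array, shape (num_slices, height, width),
#'   values in Hounsfield units (or normalized units after [normalize_volume()]).
#' @param spacing voxel size per axis in mm, strictly positive.
#' @param affine 4x4 voxel-to-world matrix.
#' @param id case identifier string.
#' @return object of class `ns_volume`.
#' @export
new_volume <- function(intensities, spacing = c(3, 0.8, 0.8),
                       affine = diag(c(spacing, 1)), id = "case") {
  if (length(dim(intensities)) != 3L || any(dim(intensities) < 1L))
    stop("intensities must be a 3D array with all extents >= 1")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values")
  structure(list(intensities = intensities, spacing = as.numeric(spacing),
                 affine = affine, id = id),
            class = "ns_volume")
}

#' Construct a label volume
#'
#' @param labels 3D integer array over the vocabulary's values.
#' @param vocabulary `"KITS19"` or `"KITS21"`.
#' @inheritParams new_volume
#' @return object of class `ns_labels`.
#' @export
new_label_volume <- function(labels, vocabulary = "KITS21",
                             spacing = c(3, 0.8, 0.8),
                             affine = diag(c(spacing, 1)), id = "case") {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  vals <- vocab_values(vocabulary)
  bad <- setdiff(unique(as.vector(labels)), vals)
  if (length(bad))
    stop("label value(s) ", paste(sort(bad), collapse = ", "),
         " outside vocabulary ", vocabulary,
         " {", paste(vals, collapse = ","), "}")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, vocabulary = vocabulary,
                 spacing = as.numeric(spacing), affine = affine, id = id),
            class = "ns_labels")
}

#' @export
print.ns_volume <- function(x, ...) {
  cat(sprintf("<ns_volume '%s'  %s  spacing %s mm  range [%.1f, %.1f]>\n",
              x$id, paste(dim(x$intensities), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
print.ns_labels <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<ns_labels '%s'  %s  %s  counts: %s>\n",
              x$id, paste(dim(x$labels), collapse = "x"), x$vocabulary,
              paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}

#' @export
dim.ns_volume <- function(x) dim(x$intensities)

#' @export
dim.ns_labels <- function(x) dim(x$labels)
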