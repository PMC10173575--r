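# Deterministic KiTS-like synthetic phantoms: two ellipsoidal kidneys,
# optional spherical tumor/cyst embedded in a kidney, HU-like class means
# plus Gaussian noise, written in the KiTS case layout.  Entirely offline;
# every sampled parameter is recorded so cohorts regenerate bit-identically.

#' Phantom specification
#'
#' Geometry is expressed in voxel units (per-axis semi-radii and centres in
#' the (slice, height, width) axis order); intensities in HU.  Class means
#' follow the contrast ordering of contrast-enhanced CT (kidney > tumor >
#' cyst > background) but are configuration values, not anatomical claims.
#'
#' @param shape volume extent `(num_slices, height, width)`.
#' @param spacing voxel size in mm (KiTS-like anisotropy by default).
#' @param kidney_axes per-axis semi-radii of both kidneys, voxels.
#' @param kidney_centers list of two centres (left, right).
#' @param tumor `NULL` or `list(center =, radii =)` (voxels).
#' @param cyst `NULL` or `list(center =, radii =)`.
#' @param means named list of class mean intensities (HU).
#' @param noise_sd additive Gaussian noise standard deviation (HU).
#' @param seed RNG seed for the noise.
#' @export
phantom_spec <- function(shape = c(24L, 96L, 96L),
                         spacing = c(3, 0.8, 0.8),
                         kidney_axes = c(6, 16, 10),
                         kidney_centers = list(c(12, 48, 28), c(12, 48, 68)),
                         tumor = list(center = c(12, 60, 31),
                                      radii = c(3, 7, 7)),
                         cyst = list(center = c(12, 38, 66),
                                     radii = c(2, 5, 5)),
                         means = list(background = -50, kidney = 120,
                                      tumor = 60, cyst = 10),
                         noise_sd = 15, seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               kidney_axes = as.numeric(kidney_axes),
               kidney_centers = lapply(kidney_centers, as.numeric),
               tumor = tumor, cyst = cyst, means = means,
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "ns_phantom_spec"
  spec
}

ellipsoid_mask <- function(shape, center, axes) {
  if (any(axes <= 0)) stop("phantom: semi-radii must be positive")
  if (any(center < 1) || any(center > shape))
    stop("phantom: centre out of bounds")
  d1 <- ((seq_len(shape[1]) - center[1]) / axes[1])^2
  d2 <- ((seq_len(shape[2]) - center[2]) / axes[2])^2
  d3 <- ((seq_len(shape[3]) - center[3]) / axes[3])^2
  outer(outer(d1, d2, `+`), d3, `+`) <= 1
}

#' Generate one synthetic case
#'
#' Analytic ellipsoid membership defines the labels (precedence cyst >
#' tumor > kidney); intensities are the class means plus seeded Gaussian
#' noise.  A lesion that misses both kidneys entirely is a spec error.
#'
#' @param spec a [phantom_spec()].
#' @param id case identifier for the generated volumes.
#' @return list with `volume` (`ns_volume`) and `labels` (`ns_labels`,
#'   KITS21 vocabulary), plus the kidney mask under `kidney_mask`.
#' @export
generate_case <- function(spec, id = sprintf("case_%05d", spec$seed)) {
  shp <- spec$shape
  kid <- ellipsoid_mask(shp, spec$kidney_centers[[1]], spec$kidney_axes) |
    ellipsoid_mask(shp, spec$kidney_centers[[2]], spec$kidney_axes)
  labels <- array(0L, dim = shp)
  labels[kid] <- 1L
  for (lesion in c("tumor", "cyst")) {
    le <- spec[[lesion]]
    if (is.null(le)) next
    m <- ellipsoid_mask(shp, le$center, le$radii)
    if (!any(m & kid))
      stop("phantom: ", lesion, " lies entirely outside both kidneys")
    labels[m] <- if (lesion == "tumor") 2L else 3L
  }
  means_map <- c(spec$means$background, spec$means$kidney,
                 spec$means$tumor, spec$means$cyst)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  intens <- means_map[labels + 1L]
  if (spec$noise_sd > 0)
    intens <- intens + rnorm(length(intens), sd = spec$noise_sd)
  dim(intens) <- shp
  aff <- diag(c(spec$spacing, 1))
  list(volume = new_volume(intens, spacing = spec$spacing, affine = aff,
                           id = id),
       labels = new_label_volume(labels, vocabulary = "KITS21",
                                 spacing = spec$spacing, affine = aff,
                                 id = id),
       kidney_mask = kid)
}

# Sample one jittered spec from the base spec.  Deterministic given the
# case seed; retries lesion placement until it overlaps a kidney.
sample_case_spec <- function(base, case_seed, p_tumor = 0.8, p_cyst = 0.5,
                             center_jitter = c(1, 4, 4),
                             radius_jitter = 0.15) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(case_seed)
  spec <- base
  spec$seed <- as.integer(case_seed)
  jit <- function(x, j) x + round(runif(length(x), -1, 1) * j)
  scl <- function(x) x * runif(length(x), 1 - radius_jitter, 1 + radius_jitter)
  spec$kidney_axes <- pmax(2, scl(base$kidney_axes))
  spec$kidney_centers <- lapply(base$kidney_centers, function(ctr) {
    pmin(pmax(jit(ctr, center_jitter), base$kidney_axes + 1),
         base$shape - base$kidney_axes - 1)
  })
  place_lesion <- function(radii) {
    for (try in 1:20) {
      kc <- spec$kidney_centers[[sample.int(2L, 1L)]]
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      f <- runif(1, 0.2, 0.7)
      ctr <- round(kc + f * spec$kidney_axes * dir)
      ctr <- pmin(pmax(ctr, radii + 1), spec$shape - radii)
      le <- list(center = ctr, radii = radii)
      m <- ellipsoid_mask(spec$shape, ctr, radii)
      kid <- ellipsoid_mask(spec$shape, spec$kidney_centers[[1]],
                            spec$kidney_axes) |
        ellipsoid_mask(spec$shape, spec$kidney_centers[[2]], spec$kidney_axes)
      if (any(m & kid)) return(le)
    }
    stop("phantom: could not place lesion inside a kidney")
  }
  # fall back to kidney-relative radii when the base spec has no such lesion
  tumor_radii <- if (is.null(base$tumor)) base$kidney_axes * 0.4
                 else base$tumor$radii
  cyst_radii <- if (is.null(base$cyst)) base$kidney_axes * 0.3
                else base$cyst$radii
  spec$tumor <- if (runif(1) < p_tumor)
    place_lesion(pmax(1.5, scl(tumor_radii))) else NULL
  spec$cyst <- if (runif(1) < p_cyst)
    place_lesion(pmax(1, scl(cyst_radii))) else NULL
  spec
}

#' Generate a cohort of synthetic cases on disk
#'
#' Writes `case_00000/imaging.nii.gz` + `segmentation.nii.gz` per case in
#' the KiTS layout plus a `manifest.json` recording every sampled parameter;
#' [cohort_from_manifest()] regenerates the tree bit-identically.
#'
#' @param n number of cases (>= 1).
#' @param out_dir output directory.
#' @param base_spec base [phantom_spec()] jittered per case.
#' @param seed master seed; each case derives its own.
#' @param p_tumor,p_cyst lesion presence probabilities.
#' @param center_jitter,radius_jitter jitter amplitudes (voxels /
#'   multiplicative fraction).
#' @return the manifest (invisibly), as a list.
#' @export
generate_cohort <- function(n, out_dir, base_spec = phantom_spec(),
                            seed = 1L, p_tumor = 0.8, p_cyst = 0.5,
                            center_jitter = c(1, 4, 4),
                            radius_jitter = 0.15) {
  if (n < 1L) stop("n must be >= 1")
  if (p_tumor < 0 || p_tumor > 1 || p_cyst < 0 || p_cyst > 1)
    stop("lesion probabilities must lie in [0, 1]")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    case_seed <- (abs(seed) %% 1000003L) * 2000L + i
    spec <- sample_case_spec(base_spec, case_seed, p_tumor, p_cyst,
                             center_jitter, radius_jitter)
    id <- sprintf("case_%05d", i - 1L)
    cs <- generate_case(spec, id = id)
    cdir <- file.path(out_dir, id)
    write_volume(cs$volume, file.path(cdir, "imaging.nii.gz"))
    write_label(cs$labels, cs$volume, file.path(cdir, "segmentation.nii.gz"))
    entries[[i]] <- list(id = id, spec = unclass(spec))
  }
  manifest <- list(n = n, seed = seed, p_tumor = p_tumor, p_cyst = p_cyst,
                   cases = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Regenerate a cohort from its manifest
#'
#' @param manifest_path path to a cohort `manifest.json`.
#' @param out_dir destination directory.
#' @export
cohort_from_manifest <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  for (e in man$cases) {
    spec <- e$spec
    kc <- spec$kidney_centers  # JSON simplification may yield a 2x3 matrix
    spec$kidney_centers <- if (is.matrix(kc))
      lapply(seq_len(nrow(kc)), function(i) as.numeric(kc[i, ]))
    else lapply(kc, as.numeric)
    for (lesion in c("tumor", "cyst"))
      if (!is.null(spec[[lesion]]) && length(spec[[lesion]]) == 0)
        spec[[lesion]] <- NULL
    spec$shape <- as.integer(spec$shape)
    spec$seed <- as.integer(spec$seed)
    class(spec) <- "ns_phantom_spec"
    cs <- generate_case(spec, id = e$id)
    cdir <- file.path(out_dir, e$id)
    write_volume(cs$volume, file.path(cdir, "imaging.nii.gz"))
    write_label(cs$labels, cs$volume, file.path(cdir, "segmentation.nii.gz"))
  }
  invisible(out_dir)
}

#' Load every case directory under a cohort root
#'
#' @param root cohort directory containing `case_*` subdirectories.
#' @param vocabulary label vocabulary.
#' @return named list of `list(volume =, labels =)`.
#' @export
load_cohort <- function(root, vocabulary = "KITS21") {
  dirs <- sort(list.dirs(root, recursive = FALSE))
  dirs <- dirs[grepl("^case_", basename(dirs))]
  if (!length(dirs)) stop("no case_* directories under ", root)
  cases <- lapply(dirs, read_case_dir, vocabulary = vocabulary)
  names(cases) <- basename(dirs)
  cases
}
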