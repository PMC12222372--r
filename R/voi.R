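#' Image geometry
#'
#' Shape, voxel size and voxel-to-world affine of a 3D image grid. When only
#' voxel sizes are given, the affine is diagonal with a zero origin. Voxel
#' indices are 0-based in the affine convention (as in NIfTI).
#'
#' @param dim integer vector of 3 voxel counts.
#' @param voxel_size numeric vector of 3 voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world matrix; overrides `voxel_size` placement.
#' @return An object of class `image_geometry`.
#' @export
image_geometry <- function(dim, voxel_size = c(1, 1, 1), affine = NULL) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L)) stop("dim must be 3 positive counts")
  if (is.null(affine)) {
    if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(dim = dim, voxel_size = voxel_size, affine = affine),
            class = "image_geometry")
}

#' @export
print.image_geometry <- function(x, ...) {
  cat(sprintf("<image_geometry: %s voxels, %s mm>\n",
              paste(x$dim, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

#' Volume-of-interest mask
#'
#' A binary 3D mask tied to an [image_geometry()] and a VOI role label.
#'
#' @param mask logical (or 0/1) 3D array.
#' @param geometry the mask's [image_geometry()].
#' @param label role tag (see [frame_tac()]).
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask, geometry, label = "model") {
  stopifnot(inherits(geometry, "image_geometry"))
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(mask)) != 3L || !all(dim(mask) == geometry$dim))
    stop("mask dimensions must match the geometry")
  label <- match.arg(label, voi_labels)
  structure(list(mask = mask, geometry = geometry, label = label),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask '%s': %d voxels of %s>\n", x$label,
              sum(x$mask), paste(x$geometry$dim, collapse = "x")))
  invisible(x)
}

# The 13 lexicographically positive offsets of the 26-neighbourhood; each
# unordered neighbour pair is generated exactly once.
offsets_26 <- function() {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
    (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0)
  o[keep, , drop = FALSE]
}

#' Keep only the largest connected component of a mask
#'
#' Segmentation tools occasionally mark spurious voxels outside the target
#' structure; restricting a VOI to its greatest connected component removes
#' them. Connectivity is the 26-neighbourhood. Ties are broken in favour of
#' the component containing the lowest linear voxel index.
#'
#' @param voi a [voi_mask()].
#' @return A [voi_mask()] containing a single component.
#' @export
largest_connected_component <- function(voi) {
  stopifnot(inherits(voi, "voi_mask"))
  m <- voi$mask
  nvox <- sum(m)
  if (nvox == 0L) stop("empty mask")
  d <- dim(m)
  ids <- array(0L, d)
  ids[m] <- seq_len(nvox)

  edges <- list()
  offs <- offsets_26()
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    xs <- seq.int(max(1L, 1L - off[1]), min(d[1], d[1] - off[1]))
    ys <- seq.int(max(1L, 1L - off[2]), min(d[2], d[2] - off[2]))
    zs <- seq.int(max(1L, 1L - off[3]), min(d[3], d[3] - off[3]))
    a <- ids[xs, ys, zs, drop = FALSE]
    b <- ids[xs + off[1], ys + off[2], zs + off[3], drop = FALSE]
    both <- a > 0L & b > 0L
    if (any(both)) edges[[length(edges) + 1L]] <- cbind(a[both], b[both])
  }
  g <- igraph::make_empty_graph(n = nvox, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    # tie: component holding the smallest linear voxel index
    first_idx <- vapply(biggest, function(cc)
      min(which(m)[comp$membership == cc]), numeric(1))
    biggest <- biggest[which.min(first_idx)]
  }
  keep <- array(FALSE, d)
  keep[which(m)[comp$membership == biggest]] <- TRUE
  voi_mask(keep, voi$geometry, voi$label)
}

#' Resample a mask onto another grid
#'
#' Nearest-neighbour resampling through the affines: a target-grid voxel is
#' inside the resampled mask iff its centre maps into an inside voxel of the
#' source mask. Used to carry CT-grid segmentation masks onto the PET grid.
#'
#' @param voi a [voi_mask()].
#' @param target target [image_geometry()] (same world frame as the source).
#' @return A [voi_mask()] on the target grid.
#' @export
resample_mask <- function(voi, target) {
  stopifnot(inherits(voi, "voi_mask"), inherits(target, "image_geometry"))
  td <- target$dim
  grid <- as.matrix(expand.grid(x = seq_len(td[1]) - 1L,
                                y = seq_len(td[2]) - 1L,
                                z = seq_len(td[3]) - 1L))
  world <- target$affine %*% rbind(t(grid), 1)
  src <- solve(voi$geometry$affine) %*% world
  ijk <- round(t(src[1:3, , drop = FALSE]))
  sd3 <- voi$geometry$dim
  inb <- ijk[, 1] >= 0 & ijk[, 1] < sd3[1] &
    ijk[, 2] >= 0 & ijk[, 2] < sd3[2] &
    ijk[, 3] >= 0 & ijk[, 3] < sd3[3]
  inside <- logical(nrow(ijk))
  if (any(inb)) {
    lin <- 1L + ijk[inb, 1] + sd3[1] * (ijk[inb, 2] + sd3[2] * ijk[inb, 3])
    inside[inb] <- voi$mask[lin]
  }
  if (!any(inside))
    warning("resampled mask is empty: non-overlapping fields of view?")
  voi_mask(array(inside, td), target, voi$label)
}

frame_values <- function(pet4d, mask) {
  d <- dim(pet4d)
  if (length(d) != 4L) stop("expected a 4D PET array")
  if (!all(d[1:3] == dim(mask))) stop("mask is not on the PET grid")
  nvox3 <- prod(d[1:3])
  idx <- which(mask)
  lapply(seq_len(d[4]), function(fr) pet4d[(fr - 1L) * nvox3 + idx])
}

#' Mean time-activity curve of a VOI
#'
#' Per-frame arithmetic mean of the in-mask voxel values of a 4D dynamic PET
#' array.
#'
#' @param pet4d 4D numeric array (x, y, z, frame), Bq/mL.
#' @param voi a [voi_mask()] on the PET grid.
#' @param schedule the acquisition [frame_schedule()].
#' @return A [frame_tac()].
#' @export
mean_tac <- function(pet4d, voi, schedule) {
  stopifnot(inherits(voi, "voi_mask"), inherits(schedule, "frame_schedule"))
  if (sum(voi$mask) == 0L) stop("empty mask")
  vals <- vapply(frame_values(pet4d, voi$mask), mean, numeric(1))
  frame_tac(schedule, vals, voi$label, allow_negative = TRUE)
}

#' Upper-percentile time-activity curve of a VOI
#'
#' Per frame, computes the q-th percentile of the in-mask values (linear
#' interpolation between order statistics) and returns the mean of the
#' voxels at or above that threshold. The thresholding is per frame, so the
#' contributing voxel set may change between frames. Intended for small
#' vessels such as the hepatic portal vein, where the plain mean
#' underestimates the blood concentration; `q = 0` reduces exactly to
#' [mean_tac()]. Masks smaller than 10 voxels fall back to the per-frame
#' maximum with a warning.
#'
#' @inheritParams mean_tac
#' @param q percentile in \[0, 100); default 90.
#' @return A [frame_tac()].
#' @export
percentile_tac <- function(pet4d, voi, schedule, q = 90) {
  stopifnot(inherits(voi, "voi_mask"), inherits(schedule, "frame_schedule"))
  nvox <- sum(voi$mask)
  if (nvox == 0L) stop("empty mask")
  fv <- frame_values(pet4d, voi$mask)
  if (nvox < 10L) {
    warning("mask smaller than 10 voxels; using the per-frame maximum")
    vals <- vapply(fv, max, numeric(1))
  } else {
    vals <- vapply(fv, function(v) {
      thr <- stats::quantile(v, q / 100, names = FALSE, type = 7)
      mean(v[v >= thr])
    }, numeric(1))
  }
  frame_tac(schedule, vals, voi$label, allow_negative = TRUE)
}

#' Read images and masks from NIfTI files
#'
#' Thin wrappers around \pkg{RNifti}. `read_pet_image()` returns the 4D
#' array plus its [image_geometry()]; `read_label_masks()` splits an
#' integer-label volume into [voi_mask()] objects according to a label map
#' (a named list such as `list(aorta = 52, liver = 5)`).
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @return `read_pet_image()`: a list with `data` (4D array) and `geometry`;
#'   `read_label_masks()`: a named list of [voi_mask()] objects.
#' @export
read_pet_image <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  geom <- image_geometry(dim(arr)[1:3],
                         affine = unclass(RNifti::xform(img)))
  list(data = arr, geometry = geom)
}

#' @rdname read_pet_image
#' @param label_map named list mapping role tags to integer label values.
#' @export
read_label_masks <- function(path, label_map) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D label volume")
  geom <- image_geometry(dim(arr), affine = unclass(RNifti::xform(img)))
  out <- lapply(names(label_map), function(lab) {
    voi_mask(arr == label_map[[lab]], geom, lab)
  })
  stats::setNames(out, names(label_map))
}

#' Extract the four study TACs from a PET image and label masks
#'
#' Applies the preprocessing rules used throughout the package: each mask is
#' reduced to its largest connected component, the aorta, liver and spleen
#' TACs are plain VOI means, and the portal-vein TAC is the
#' `pv_percentile`-th upper-percentile mean (see [percentile_tac()]).
#'
#' @param pet4d 4D PET array, Bq/mL.
#' @param masks named list of [voi_mask()] objects with names among
#'   `aorta`, `portal_vein`, `liver`, `spleen`.
#' @param schedule the acquisition [frame_schedule()].
#' @param pv_percentile percentile for the portal-vein rule; default 90.
#' @return A named list of [frame_tac()] objects.
#' @export
extract_study_tacs <- function(pet4d, masks, schedule, pv_percentile = 90) {
  out <- lapply(names(masks), function(lab) {
    m <- largest_connected_component(masks[[lab]])
    if (lab == "portal_vein")
      percentile_tac(pet4d, m, schedule, q = pv_percentile)
    else mean_tac(pet4d, m, schedule)
  })
  stats::setNames(out, names(masks))
}
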