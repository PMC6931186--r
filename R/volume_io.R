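#' @title 3D volume containers and NIfTI input/output
#' @name volume_io
#' @description
#' Volumes are held in canonical anatomical order: array axis 1 runs
#' inferior-to-superior (IS), axis 2 posterior-to-anterior (PA) and axis 3
#' left-to-right (LR). A 192x224x192 MNI-space scan therefore arrives as an
#' array whose axial slices are `vol$data[i, , ]` (224 x 192). Registration,
#' resampling and skull stripping are upstream responsibilities; the package
#' validates aligned inputs but never performs them.
NULL

.canonical_axes <- c("IS", "PA", "LR")

#' Construct a brain volume
#'
#' @param data 3D numeric array of intensities in canonical (IS, PA, LR)
#'   axis order.
#' @param spacing voxel size in mm along each array axis.
#' @param axis_labels character vector naming the anatomical direction of
#'   each array axis; the canonical order is `c("IS", "PA", "LR")`.
#' @param reference optional `RNifti` image carrying the source header
#'   geometry, used when writing derived masks.
#' @return An object of class `brain_volume` with fields `data`, `spacing`,
#'   `shape` and `axis_labels`.
#' @export
brain_volume <- function(data, spacing = c(1, 1, 1),
                         axis_labels = .canonical_axes, reference = NULL) {
  if (length(dim(data)) != 3L)
    stopf("brain_volume: 'data' must be a 3D array, got %d dims",
          length(dim(data)))
  if (any(spacing <= 0)) stopf("brain_volume: spacing must be positive")
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stopf("brain_volume: %d non-finite voxel(s) in input", n_bad)
  structure(list(data = data, spacing = as.numeric(spacing),
                 shape = dim(data), axis_labels = axis_labels,
                 reference = reference),
            class = "brain_volume")
}

#' Construct a binary lesion mask
#'
#' @param data 3D array over \{0, 1\} in canonical axis order.
#' @param spacing voxel size in mm per axis.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    stopf("lesion_mask: 'data' must be a 3D array")
  if (!all(data %in% c(0, 1)))
    stopf("lesion_mask: mask voxels must all be 0 or 1")
  structure(list(data = data, spacing = as.numeric(spacing),
                 shape = dim(data)),
            class = "lesion_mask")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(sprintf("<brain_volume> %s voxels, spacing %s mm, axes %s\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              paste(x$axis_labels, collapse = "/")))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s voxels, %d foreground\n",
              paste(x$shape, collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Target grid specification
#'
#' The fixed tensor geometry every volume is conformed to before slicing.
#' Each dimension must be divisible by `divisibility` so that four rounds of
#' 2x2 pooling can be undone exactly by four stride-2 deconvolutions.
#'
#' @param target_shape integer vector (D, H, W); default full-scale MNI grid.
#' @param divisibility required divisor of every target dimension.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(target_shape = c(192L, 224L, 192L), divisibility = 16L) {
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L)
    stopf("grid_spec: target_shape must have 3 dimensions")
  if (any(target_shape %% divisibility != 0L))
    stopf("grid_spec: target dims (%s) must be divisible by %d",
          paste(target_shape, collapse = ","), divisibility)
  structure(list(target_shape = target_shape,
                 divisibility = as.integer(divisibility)),
            class = "grid_spec")
}

.read_nifti_canonical <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stopf("'%s' is %dD; expected a 3D volume", path, length(d))
  ot <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (is.character(ot) && !is.na(ot) && nchar(ot) == 3L && ot != "RAS")
    RNifti::orientation(img) <- "RAS"
  arr <- as.array(img)
  n_bad <- sum(!is.finite(arr))
  if (n_bad > 0L)
    stopf("'%s' contains %d non-finite voxel(s)", path, n_bad)
  pd <- RNifti::pixdim(img)[seq_len(3)]
  # RAS stores (LR, PA, IS); permute to canonical (IS, PA, LR)
  list(data = aperm(arr, c(3L, 2L, 1L)), spacing = rev(pd), ref = img)
}

#' Read a NIfTI volume
#'
#' Reads a (possibly gzipped) NIfTI-1 file, reorients it to the canonical
#' (IS, PA, LR) axis order when the header carries orientation information,
#' and validates that all voxels are finite.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [brain_volume].
#' @export
read_volume <- function(path) {
  x <- .read_nifti_canonical(path)
  brain_volume(x$data, spacing = x$spacing, reference = x$ref)
}

#' Read and binarize a NIfTI lesion mask
#'
#' Values at or above `threshold` map to 1, values below to 0 -- ties go to
#' lesion, mirroring the rounding rule applied to network predictions.
#'
#' @param path path to a NIfTI file.
#' @param threshold binarization cut; default 0.5.
#' @return A [lesion_mask].
#' @export
read_mask <- function(path, threshold = 0.5) {
  x <- .read_nifti_canonical(path)
  lesion_mask((x$data >= threshold) * 1, spacing = x$spacing)
}

#' Write a lesion mask as NIfTI
#'
#' The mask is written with the reference volume's header geometry so that
#' `read_mask(write_mask(m))` round-trips voxelwise exactly.
#'
#' @param mask a [lesion_mask].
#' @param reference the [brain_volume] the mask is aligned to.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_mask <- function(mask, reference, path) {
  if (!identical(dim(mask$data), dim(reference$data)))
    stopf("write_mask: mask shape (%s) does not match reference (%s)",
          paste(dim(mask$data), collapse = ","),
          paste(dim(reference$data), collapse = ","))
  arr <- aperm(mask$data, c(3L, 2L, 1L)) # canonical -> RAS storage order
  if (!is.null(reference$reference)) {
    img <- RNifti::asNifti(arr, reference = reference$reference)
  } else {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rev(reference$spacing)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

.conform_axis <- function(n_in, n_out) {
  # returns source and destination index ranges for centre crop / pad
  if (n_in >= n_out) {
    lo <- floor((n_in - n_out) / 2)
    list(src = seq.int(lo + 1L, lo + n_out), dst = seq_len(n_out))
  } else {
    lo <- floor((n_out - n_in) / 2)
    list(src = seq_len(n_in), dst = seq.int(lo + 1L, lo + n_in))
  }
}

#' Conform a volume to a target grid
#'
#' Axes larger than the target are centre-cropped; axes smaller are
#' symmetrically padded with `fill` (the extra plane goes to the trailing
#' side when the difference is odd). Voxel values inside the overlap region
#' are preserved exactly.
#'
#' @param vol a [brain_volume] or [lesion_mask].
#' @param grid a [grid_spec].
#' @param fill pad value; default 0 (skull-stripped background).
#' @return An object of the same class as `vol` on the target grid.
#' @export
conform_to_grid <- function(vol, grid = grid_spec(), fill = 0) {
  if (!inherits(grid, "grid_spec")) grid <- grid_spec(grid)
  tgt <- grid$target_shape
  d <- dim(vol$data)
  ax <- lapply(seq_len(3), function(a) .conform_axis(d[a], tgt[a]))
  out <- array(fill, dim = tgt)
  out[ax[[1]]$dst, ax[[2]]$dst, ax[[3]]$dst] <-
    vol$data[ax[[1]]$src, ax[[2]]$src, ax[[3]]$src]
  if (inherits(vol, "lesion_mask")) {
    lesion_mask(out, spacing = vol$spacing)
  } else {
    brain_volume(out, spacing = vol$spacing, axis_labels = vol$axis_labels,
                 reference = vol$reference)
  }
}

#' Flip a volume left-right
#'
#' Reverses the array along the left-right axis only. With a single
#' modality, the flipped scan serves as an augmented synthetic second
#' modality for the dual-encoder networks.
#'
#' @param vol a [brain_volume] or [lesion_mask].
#' @return The flipped object; spacing and all other axes unchanged.
#' @export
flip_lr <- function(vol) {
  labs <- vol$axis_labels %||% .canonical_axes
  lr <- which(labs == "LR")
  if (length(lr) != 1L)
    stopf("flip_lr: cannot resolve the left-right axis from labels (%s)",
          paste(labs, collapse = ","))
  d <- dim(vol$data)
  idx <- rep(list(quote(expr = )), 3)
  idx[[lr]] <- rev(seq_len(d[lr]))
  flipped <- do.call(`[`, c(list(vol$data), idx, list(drop = FALSE)))
  out <- vol
  out$data <- array(flipped, dim = d)
  out
}
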