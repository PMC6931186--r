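#' @title Nine-view construction: planes x normalization schemes
#' @name view_normalization
#' @description
#' Each volume pair is turned into nine path inputs: 2D slice stacks along
#' the axial, sagittal and coronal planes, each under three normalization
#' schemes -- z-scored within each slice (`in_plane`), z-scored per pixel
#' along the slicing axis (`across_third`), or the first followed by the
#' second (`both`). Statistics are computed over non-background (nonzero)
#' voxels only, so skull-stripped zero background never dilutes the moments
#' and remains exactly zero.
NULL

#' The three slicing planes
#' @return Character vector `c("axial", "coronal", "sagittal")`.
#' @export
path_planes <- function() c("axial", "coronal", "sagittal")

#' The three normalization schemes
#' @return Character vector `c("in_plane", "across_third", "both")`.
#' @export
norm_schemes <- function() c("in_plane", "across_third", "both")

# canonical (IS, PA, LR) array axis along which each plane slices
.plane_axis <- c(axial = 1L, coronal = 2L, sagittal = 3L)

# permutation bringing the slicing axis first
.plane_perm <- list(axial = c(1L, 2L, 3L), coronal = c(2L, 1L, 3L),
                    sagittal = c(3L, 1L, 2L))

#' Extract the 2D slice stack of a volume along a plane
#'
#' @param vol a [brain_volume], [lesion_mask], or plain 3D array in
#'   canonical (IS, PA, LR) order.
#' @param plane one of `"axial"`, `"coronal"`, `"sagittal"`.
#' @return A 3D array `(n_slices, a, b)` whose `[i, , ]` element is slice i.
#' @export
extract_slices <- function(vol, plane = path_planes()) {
  plane <- match.arg(plane)
  arr <- if (is.list(vol)) vol$data else vol
  aperm(arr, .plane_perm[[plane]])
}

#' Reassemble a slice stack into a volume
#'
#' Inverse of [extract_slices]: restacking along the same plane reconstructs
#' the volume exactly.
#'
#' @param stack array `(n_slices, a, b)` from [extract_slices].
#' @param plane the plane the stack was extracted along.
#' @return A 3D array in canonical (IS, PA, LR) order.
#' @export
stack_to_volume <- function(stack, plane = path_planes()) {
  plane <- match.arg(plane)
  aperm(stack, order(.plane_perm[[plane]]))
}

.ZVAR_TOL <- 1e-8 # foreground sd below this => slice/profile treated constant

#' Normalize each slice independently (scheme 1)
#'
#' Every 2D slice is standardized to zero mean and unit variance over its
#' non-background (nonzero) voxels; background stays exactly zero and
#' constant or empty slices map to all-zero.
#'
#' @param stack slice stack `(n, a, b)`.
#' @return Normalized stack of the same shape.
#' @export
normalize_in_plane <- function(stack) {
  d <- dim(stack)
  out <- array(0, d)
  for (i in seq_len(d[1])) {
    s <- stack[i, , ]
    fg <- s != 0
    n_fg <- sum(fg)
    if (n_fg < 2L) next
    v <- s[fg]
    sdv <- sd(v)
    if (!is.finite(sdv) || sdv < .ZVAR_TOL) next
    s[fg] <- (v - mean(v)) / sdv
    out[i, , ] <- s
  }
  out
}

#' Normalize across the third plane (scheme 2)
#'
#' For each in-slice pixel position, the 1D intensity profile along the
#' slicing axis is standardized to zero mean, unit variance over its
#' non-background entries. Constant profiles (including every profile of a
#' single-slice stack) map to zero.
#'
#' @param stack slice stack `(n, a, b)`.
#' @return Normalized stack of the same shape.
#' @export
normalize_across_third <- function(stack) {
  d <- dim(stack)
  X <- matrix(stack, nrow = d[1])     # profiles in columns
  F <- X != 0
  cnt <- colSums(F)
  Xf <- X * F
  s1 <- colSums(Xf)
  s2 <- colSums(Xf * Xf)
  mu <- ifelse(cnt > 0, s1 / cnt, 0)
  varv <- ifelse(cnt > 1, pmax(s2 - cnt * mu^2, 0) / (cnt - 1), 0)
  sdv <- sqrt(varv)
  ok <- cnt >= 2 & sdv >= .ZVAR_TOL
  Z <- sweep(X, 2, mu, "-")
  Z <- sweep(Z, 2, ifelse(ok, sdv, 1), "/")
  Z[, !ok] <- 0
  Z[!F] <- 0
  array(Z, d)
}

.apply_scheme <- function(stack, scheme) {
  switch(scheme,
         in_plane = normalize_in_plane(stack),
         across_third = normalize_across_third(stack),
         both = normalize_across_third(normalize_in_plane(stack)),
         stopf("unknown normalization scheme '%s'", scheme))
}

#' Path input constructor
#'
#' @param plane slicing plane.
#' @param scheme normalization scheme.
#' @param primary,auxiliary normalized slice stacks `(n, a, b)`.
#' @return An object of class `path_input`.
#' @export
path_input <- function(plane, scheme, primary, auxiliary) {
  if (!identical(dim(primary), dim(auxiliary)))
    stopf("path_input: primary and auxiliary stacks differ in shape")
  structure(list(plane = plane, scheme = scheme, primary = primary,
                 auxiliary = auxiliary,
                 slice_index_map = seq_len(dim(primary)[1])),
            class = "path_input")
}

#' Build the nine (plane, scheme) path inputs for a volume pair
#'
#' The auxiliary volume is either the left-right flipped primary (single
#' modality) or a co-registered second modality such as FLAIR. Both
#' modalities are normalized identically; the `both` scheme composes
#' [normalize_in_plane] then [normalize_across_third].
#'
#' @param primary a [brain_volume] (or 3D array).
#' @param auxiliary a [brain_volume] (or 3D array) of identical shape.
#' @return A list of 9 [path_input] objects named `<plane>.<scheme>`.
#' @export
build_nine_views <- function(primary, auxiliary) {
  p <- if (is.list(primary)) primary$data else primary
  a <- if (is.list(auxiliary)) auxiliary$data else auxiliary
  if (!identical(dim(p), dim(a)))
    stopf("build_nine_views: volume shapes differ (%s vs %s)",
          paste(dim(p), collapse = ","), paste(dim(a), collapse = ","))
  out <- list()
  for (pl in path_planes()) {
    sp <- extract_slices(p, pl)
    sa <- extract_slices(a, pl)
    for (sc in norm_schemes()) {
      out[[paste(pl, sc, sep = ".")]] <-
        path_input(pl, sc, .apply_scheme(sp, sc), .apply_scheme(sa, sc))
    }
  }
  out
}
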