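#' @title Combining the nine path predictions into one 3D mask
#' @name fusion_postprocessor
#' @description
#' Three fusion strategies are provided: voxelwise union, majority vote
#' (at least 5 of 9 paths), and a 3D convolutional post-processor. For the
#' latter, each path's binarized prediction volume is stacked with the
#' original input volume giving an 18-channel tensor, which is passed
#' through an 18 -> 36 -> 9 -> 9 -> 2 chain of 3x3x3 convolutions (padding
#' 1, ReLU between layers) and a per-voxel softmax over the two output
#' channels; the hard mask takes channel 1 >= 0.5 (ties go to lesion).
NULL

#' Stack nine binarized path predictions with the input volume
#'
#' Each soft prediction is binarized at 0.5 and paired with the
#' (unnormalized, canonical-grid) input volume, giving channels
#' `2 * n_paths = 18`: odd channels hold predictions, even channels the
#' image.
#'
#' @param preds list of 9 soft prediction arrays sharing `vol`'s shape.
#' @param vol the input [brain_volume] (or 3D array).
#' @return An array of dim `(D, H, W, 18)` with class `stacked_paths`
#'   (channels stored last; the logical tensor is `18 x D x H x W`).
#' @export
assemble_stack <- function(preds, vol) {
  v <- .as_arr(vol)
  if (length(preds) != 9L)
    stopf("assemble_stack: expected 9 path predictions, got %d",
          length(preds))
  d <- dim(v)
  out <- array(0, c(d, 18L))
  for (j in seq_len(9L)) {
    pj <- .as_arr(preds[[j]])
    if (!identical(dim(pj), d))
      stopf("assemble_stack: prediction %d shape (%s) differs from volume (%s)",
            j, paste(dim(pj), collapse = ","), paste(d, collapse = ","))
    out[, , , 2L * j - 1L] <- (pj >= 0.5) * 1
    out[, , , 2L * j] <- v
  }
  structure(out, class = c("stacked_paths", "array"), n_paths = 9L)
}

.check_mask_list <- function(masks) {
  arrs <- lapply(masks, .as_arr)
  d <- dim(arrs[[1]])
  for (a in arrs)
    if (!identical(dim(a), d)) stopf("fusion: mask shapes differ")
  arrs
}

#' Union fusion
#'
#' A voxel is lesion if at least one path predicts lesion there.
#'
#' @param masks list of binary prediction volumes of identical shape.
#' @return A [lesion_mask].
#' @export
fuse_union <- function(masks) {
  arrs <- .check_mask_list(masks)
  lesion_mask((Reduce(`+`, arrs) >= 1) * 1)
}

#' Majority-vote fusion
#'
#' A voxel is lesion iff more than half of the paths (at least
#' `ceiling(n/2)` of an odd count n, i.e. 5 of 9) predict lesion there.
#'
#' @param masks list of binary prediction volumes; the count must be odd
#'   (the tie rule is undefined for even ensembles).
#' @return A [lesion_mask].
#' @export
fuse_majority <- function(masks) {
  n <- length(masks)
  if (n %% 2L == 0L)
    stopf("fuse_majority: even path count (%d) leaves the tie rule undefined", n)
  arrs <- .check_mask_list(masks)
  lesion_mask((Reduce(`+`, arrs) >= (n + 1) / 2) * 1)
}

#' Construct the 3D convolutional post-processor
#'
#' Channel plan 18 -> 36 -> 9 -> 9 -> 2, all 3x3x3 kernels with padding 1
#' (dims preserved), ReLU between layers and softmax over the final two
#' channels.
#'
#' @param n_paths ensemble size; the first layer expects `2 * n_paths`
#'   input channels.
#' @param seed optional integer seed for weight initialization.
#' @param init `"vote"` (default) warm-starts the network at the
#'   majority-vote operating point: one filter per layer carries the vote
#'   count of the 9 prediction channels through centre-tap identities, and
#'   the output layer maps it to logits `+/-(votes - 4.5)`, so the initial
#'   soft output is a smoothed majority vote that gradient descent then
#'   refines; all remaining weights are small random. `"random"` is plain
#'   uniform fan-in initialization throughout.
#' @return An object of class `fuser_net`.
#' @export
fuser_net <- function(n_paths = 9L, seed = NULL, init = c("vote", "random")) {
  init <- match.arg(init)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  cin <- 2L * n_paths
  plan <- list(c(cin, 36L), c(36L, 9L), c(9L, 9L), c(9L, 2L))
  layers <- lapply(plan, function(pl) {
    fan <- pl[1] * 27L
    list(w = .init_mat(pl[2], fan, fan), b = numeric(pl[2]))
  })
  if (init == "vote") {
    centre <- function(ch) (ch - 1L) * 27L + 14L # (0,0,0) tap of channel ch
    for (l in 1:4) layers[[l]]$w <- layers[[l]]$w * 0.1
    # filter 1 of layer 1 counts the votes of the 9 prediction channels
    layers[[1]]$w[1, ] <- 0
    layers[[1]]$w[1, centre(seq(1L, cin, by = 2L))] <- 1
    # identity pass-through of the vote count in layers 2 and 3
    for (l in 2:3) {
      layers[[l]]$w[1, ] <- 0
      layers[[l]]$w[1, centre(1L)] <- 1
    }
    # output logits +/- (votes - n_paths/2)
    half <- n_paths / 2
    layers[[4]]$w[, centre(1L)] <- c(1, -1)
    layers[[4]]$b <- c(-half, half)
  }
  structure(list(n_paths = as.integer(n_paths), layers = layers,
                 trace = NULL),
            class = "fuser_net")
}

#' @export
print.fuser_net <- function(x, ...) {
  ch <- vapply(x$layers, function(l) nrow(l$w), integer(1))
  cat(sprintf("<fuser_net> 3x3x3 conv chain %d -> %s\n",
              2L * x$n_paths, paste(ch, collapse = " -> ")))
  invisible(x)
}

.fuser_fwd <- function(net, stack, keep = FALSE) {
  x <- unclass(stack)
  ys <- vector("list", 4L)
  h <- x
  for (l in 1:3) {
    h <- conv3d_fwd(h, net$layers[[l]]$w, net$layers[[l]]$b, TRUE)
    ys[[l]] <- h
  }
  logits <- conv3d_fwd(h, net$layers[[4]]$w, net$layers[[4]]$b, FALSE)
  d <- dim(logits)[1:3]
  p <- array(1 / (1 + exp(logits[, , , 2] - logits[, , , 1])), d)
  if (!keep) return(list(p = p))
  list(p = p, x = x, ys = ys, logits = logits)
}

.fuser_bwd <- function(net, fwd, gp) {
  p <- fwd$p
  g1 <- gp * p * (1 - p)
  glog <- array(0, dim(fwd$logits))
  glog[, , , 1] <- g1
  glog[, , , 2] <- -g1
  grads <- vector("list", 4L)
  b4 <- conv3d_bwd(fwd$ys[[3]], net$layers[[4]]$w, fwd$logits, glog, FALSE)
  grads[[4]] <- list(w = b4$gw, b = as.numeric(b4$gb))
  g <- b4$gx
  for (l in 3:1) {
    xin <- if (l == 1L) fwd$x else fwd$ys[[l - 1L]]
    bl <- conv3d_bwd(xin, net$layers[[l]]$w, fwd$ys[[l]], g, TRUE)
    grads[[l]] <- list(w = bl$gw, b = as.numeric(bl$gb))
    g <- bl$gx
  }
  grads
}

#' Fuse path predictions with the 3D convolutional post-processor
#'
#' @param stack a `stacked_paths` tensor from [assemble_stack].
#' @param net a [fuser_net] whose first layer matches the stack's channels.
#' @return A list of class `two_channel_pred` with soft channels `p`
#'   (lesion) and `q = 1 - p` (complement) and the hard `mask`
#'   (`p >= 0.5`).
#' @export
fuse_cnn3d <- function(stack, net) {
  cin <- dim(stack)[4]
  if (cin != ncol(net$layers[[1]]$w) / 27L)
    stopf("fuse_cnn3d: stack has %d channels but the fuser expects %d",
          cin, ncol(net$layers[[1]]$w) / 27L)
  fw <- .fuser_fwd(net, stack, keep = FALSE)
  structure(list(p = fw$p, q = 1 - fw$p,
                 mask = lesion_mask((fw$p >= 0.5) * 1)),
            class = "two_channel_pred")
}

#' @export
print.two_channel_pred <- function(x, ...) {
  cat(sprintf("<two_channel_pred> %s voxels, %d predicted lesion\n",
              paste(dim(x$p), collapse = "x"), sum(x$mask$data)))
  invisible(x)
}
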