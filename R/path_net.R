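#' @title Per-path dual-encoder 2D segmentation network
#' @name dual_unet_path
#' @description
#' Each of the nine paths is a U-shaped 2D network with two encoders (one
#' per modality view), multi-scale feature fusion, and a decoder:
#' \itemize{
#'   \item Encoder: five convolutional blocks (each two 3x3 convolutions,
#'     stride 1, padding 1, ReLU after each) with 2x2 average pooling,
#'     stride 2, after blocks 1-4; block 5 is the bottleneck at 1/16 scale.
#'   \item Fusion: at every pyramid level, the two encoders' feature maps
#'     (each `filters` x x x y) are stacked along a new depth axis and merged
#'     by a 2x1x1 convolution (per-channel weight pair plus bias), then
#'     squeezed back to `filters` x x x y.
#'   \item Decoder: four 2x2 stride-2 deconvolutions, each doubling both
#'     spatial dims; the fused skip feature at the matching scale is added
#'     (not multiplied) and ReLU follows the addition, then a convolutional
#'     block. A final 1x1 projection to 2 channels with per-pixel softmax
#'     yields the lesion / complement probability pair.
#' }
#' Channel width is constant at `filters` (default 32) across all levels and
#' no batch or instance normalization is used.
NULL

.relu <- function(x) { x[x < 0] <- 0; x }

# PyTorch-style uniform fan-in init: U(-1/sqrt(fan), 1/sqrt(fan))
.init_mat <- function(nr, nc, fan) {
  matrix(runif(nr * nc, -1, 1) / sqrt(fan), nr, nc)
}

.conv_block_params <- function(cin, f) {
  list(wa = .init_mat(f, cin * 9L, cin * 9L), ba = numeric(f),
       wb = .init_mat(f, f * 9L, f * 9L), bb = numeric(f))
}

#' Construct an untrained path network
#'
#' @param in_shape 2D slice shape `(h, w)`; both dims must be divisible by
#'   16 (= 2^4 pooling steps) so the decoder restores them exactly.
#' @param filters channel width at every level; default 32.
#' @param seed optional integer seed for the weight initialization.
#' @return An object of class `path_net` holding the parameter list, the
#'   configuration, and (after training) a per-epoch loss trace.
#' @export
path_net <- function(in_shape, filters = 32L, seed = NULL) {
  in_shape <- as.integer(in_shape)
  if (length(in_shape) != 2L || any(in_shape %% 16L != 0L))
    stopf("path_net: in_shape (%s) must be 2D with both dims divisible by 16",
          paste(in_shape, collapse = ","))
  f <- as.integer(filters)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  enc <- lapply(1:2, function(m) {
    lapply(1:5, function(b) .conv_block_params(if (b == 1L) 1L else f, f))
  })
  fuse <- lapply(1:5, function(b) {
    list(w = .init_mat(f, 2L, 2L), b = numeric(f))
  })
  dec <- lapply(1:4, function(t) {
    c(list(wd = .init_mat(f * 4L, f, f), bd = numeric(f)),
      .conv_block_params(f, f))
  })
  head <- list(w = .init_mat(2L, f, f), b = numeric(2))
  structure(list(filters = f, in_shape = in_shape,
                 params = list(enc = enc, fuse = fuse, dec = dec, head = head),
                 trace = NULL),
            class = "path_net")
}

#' @export
print.path_net <- function(x, ...) {
  cat(sprintf(
    "<path_net> dual encoder (5 blocks) + fusion + decoder (4 blocks), %d filters, slices %s\n",
    x$filters, paste(x$in_shape, collapse = "x")))
  if (!is.null(x$trace))
    cat(sprintf("  trained %d epochs, final mean loss %.4f\n",
                length(x$trace), x$trace[length(x$trace)]))
  invisible(x)
}

#' Convolutional block: two padded 3x3 convolutions, each followed by ReLU
#'
#' Spatial dimensions are preserved (3x3 kernel, stride 1, padding 1).
#'
#' @param x feature map `(h, w, c_in)`.
#' @param block parameter list with `wa`, `ba`, `wb`, `bb` as produced
#'   inside [path_net].
#' @return Feature map `(h, w, filters)`, elementwise non-negative.
#' @export
conv_block <- function(x, block) {
  conv2d_fwd(conv2d_fwd(x, block$wa, block$ba, TRUE), block$wb, block$bb, TRUE)
}

#' Encode one slice into a five-level feature pyramid
#'
#' @param net a [path_net].
#' @param slice 2D matrix with the network's `in_shape`.
#' @param encoder which encoder to use (1 = primary, 2 = auxiliary).
#' @return A list of 5 feature maps at scales 1, 1/2, 1/4, 1/8, 1/16, each
#'   with `filters` channels.
#' @export
encode <- function(net, slice, encoder = 1L) {
  if (!identical(dim(slice), as.integer(net$in_shape)))
    stopf("encode: slice shape (%s) does not match net in_shape (%s)",
          paste(dim(slice), collapse = ","),
          paste(net$in_shape, collapse = ","))
  pe <- net$params$enc[[encoder]]
  h <- array(slice, c(dim(slice), 1L))
  levels <- vector("list", 5L)
  for (b in 1:5) {
    levels[[b]] <- conv_block(h, pe[[b]])
    if (b < 5L) h <- avgpool2_fwd(levels[[b]])
  }
  levels
}

#' Fuse two same-scale feature maps with a 2x1x1 kernel
#'
#' The maps are stacked along a new depth axis of size 2 and merged by a
#' per-channel 2x1x1 convolution; the singleton depth is squeezed away. The
#' operation is linear: with weights (0.5, 0.5) and zero bias it is the
#' elementwise mean.
#'
#' @param a,b feature maps `(x, y, c)` of identical shape.
#' @param w `c x 2` weight matrix (one pair per channel).
#' @param bias per-channel bias.
#' @return Fused feature map `(x, y, c)`.
#' @export
fuse_features <- function(a, b, w, bias = numeric(nrow(w))) {
  if (!identical(dim(a), dim(b)))
    stopf("fuse_features: shapes differ (%s vs %s)",
          paste(dim(a), collapse = ","), paste(dim(b), collapse = ","))
  hw <- dim(a)[1] * dim(a)[2]
  array(as.vector(a) * rep(w[, 1], each = hw) +
        as.vector(b) * rep(w[, 2], each = hw) +
        rep(bias, each = hw), dim(a))
}

.fuse_bwd <- function(a, b, w, gf) {
  hw <- dim(a)[1] * dim(a)[2]
  C <- dim(a)[3]
  gfv <- as.vector(gf)
  ga <- array(gfv * rep(w[, 1], each = hw), dim(a))
  gb <- array(gfv * rep(w[, 2], each = hw), dim(a))
  gfm <- matrix(gfv, hw, C)
  gw <- cbind(colSums(gfm * matrix(as.vector(a), hw, C)),
              colSums(gfm * matrix(as.vector(b), hw, C)))
  list(ga = ga, gb = gb, gw = gw, gbias = colSums(gfm))
}

# full forward pass over one slice pair, optionally retaining every
# intermediate needed by .path_bwd_slice
.path_fwd_slice <- function(pp, x1, x2, keep = FALSE) {
  encs <- vector("list", 2L)
  for (m in 1:2) {
    x <- if (m == 1L) x1 else x2
    h <- array(x, c(dim(x), 1L))
    levels <- vector("list", 5L)
    cach <- vector("list", 5L)
    for (b in 1:5) {
      blk <- pp$enc[[m]][[b]]
      a1 <- conv2d_fwd(h, blk$wa, blk$ba, TRUE)
      a2 <- conv2d_fwd(a1, blk$wb, blk$bb, TRUE)
      levels[[b]] <- a2
      if (keep) cach[[b]] <- list(xin = h, a1 = a1)
      if (b < 5L) h <- avgpool2_fwd(a2)
    }
    encs[[m]] <- list(levels = levels, cache = cach)
  }
  fused <- vector("list", 5L)
  for (b in 1:5)
    fused[[b]] <- fuse_features(encs[[1]]$levels[[b]], encs[[2]]$levels[[b]],
                                pp$fuse[[b]]$w, pp$fuse[[b]]$b)
  z <- fused[[5]]
  dcache <- vector("list", 4L)
  for (t in 1:4) {
    blk <- pp$dec[[t]]
    d <- deconv2_fwd(z, blk$wd, blk$bd)
    s <- d + fused[[5L - t]]
    u <- .relu(s)
    a1 <- conv2d_fwd(u, blk$wa, blk$ba, TRUE)
    a2 <- conv2d_fwd(a1, blk$wb, blk$bb, TRUE)
    if (keep) dcache[[t]] <- list(zin = z, u = u, a1 = a1, a2 = a2)
    z <- a2
  }
  hw <- prod(dim(z)[1:2])
  Z <- matrix(z, hw, dim(z)[3])
  logits <- sweep(Z %*% t(pp$head$w), 2, pp$head$b, "+")
  p <- matrix(1 / (1 + exp(logits[, 2] - logits[, 1])), dim(z)[1], dim(z)[2])
  if (!keep) return(list(p = p))
  list(p = p, encs = encs, fused = fused, dcache = dcache, z = z)
}

# backward pass; gp = dL/dp. Returns grads with the same nesting as params.
.path_bwd_slice <- function(pp, fwd, gp) {
  p <- fwd$p
  g1 <- gp * p * (1 - p)                 # dL/dlogit1; dL/dlogit2 = -g1
  z <- fwd$z
  hw <- prod(dim(z)[1:2])
  Fc <- dim(z)[3]
  Z <- matrix(z, hw, Fc)
  GL <- cbind(as.vector(g1), -as.vector(g1))
  g_head_w <- t(GL) %*% Z
  g_head_b <- colSums(GL)
  gz <- array(GL %*% pp$head$w, dim(z))
  gfused <- vector("list", 5L)
  gdec <- vector("list", 4L)
  for (t in 4:1) {
    blk <- pp$dec[[t]]
    dc <- fwd$dcache[[t]]
    b2 <- conv2d_bwd(dc$a1, blk$wb, dc$a2, gz, TRUE)
    b1 <- conv2d_bwd(dc$u, blk$wa, dc$a1, b2$gx, TRUE)
    gs <- b1$gx * (dc$u > 0)             # ReLU after the skip addition
    gfused[[5L - t]] <- gs
    bd <- deconv2_bwd(dc$zin, blk$wd, gs)
    gz <- bd$gx
    gdec[[t]] <- list(wd = bd$gw, bd = as.numeric(bd$gb),
                      wa = b1$gw, ba = as.numeric(b1$gb),
                      wb = b2$gw, bb = as.numeric(b2$gb))
  }
  gfused[[5]] <- gz
  gfuse <- vector("list", 5L)
  glev <- list(vector("list", 5L), vector("list", 5L))
  for (b in 1:5) {
    fb <- .fuse_bwd(fwd$encs[[1]]$levels[[b]], fwd$encs[[2]]$levels[[b]],
                    pp$fuse[[b]]$w, gfused[[b]])
    gfuse[[b]] <- list(w = fb$gw, b = fb$gbias)
    glev[[1]][[b]] <- fb$ga
    glev[[2]][[b]] <- fb$gb
  }
  genc <- vector("list", 2L)
  for (m in 1:2) {
    genc[[m]] <- vector("list", 5L)
    gh_next <- NULL
    for (b in 5:1) {
      blk <- pp$enc[[m]][[b]]
      ca <- fwd$encs[[m]]$cache[[b]]
      a2 <- fwd$encs[[m]]$levels[[b]]
      gout <- glev[[m]][[b]]
      if (b < 5L) gout <- gout + avgpool2_bwd(gh_next)
      b2 <- conv2d_bwd(ca$a1, blk$wb, a2, gout, TRUE)
      b1 <- conv2d_bwd(ca$xin, blk$wa, ca$a1, b2$gx, TRUE)
      gh_next <- b1$gx
      genc[[m]][[b]] <- list(wa = b1$gw, ba = as.numeric(b1$gb),
                             wb = b2$gw, bb = as.numeric(b2$gb))
    }
  }
  list(enc = genc, fuse = gfuse, dec = gdec,
       head = list(w = g_head_w, b = g_head_b))
}

#' Predict the two-channel probability map for one slice pair
#'
#' Runs both encoders, per-level fusion and the decoder; the two output
#' channels are softmax-paired so `prob + comp = 1` at every pixel.
#'
#' @param net a [path_net].
#' @param primary,auxiliary 2D matrices with the network's `in_shape`.
#' @return List with `prob` (soft lesion map in `[0,1]`) and `comp`.
#' @export
decode_slice <- function(net, primary, auxiliary) {
  fw <- .path_fwd_slice(net$params, primary, auxiliary, keep = FALSE)
  list(prob = fw$p, comp = 1 - fw$p)
}

#' Run a path network over a full slice stack
#'
#' Applies the network to every slice pair of a [path_input] and reassembles
#' the per-slice soft lesion maps into a 3D volume in the source geometry.
#'
#' @param input a [path_input].
#' @param net a [path_net] whose `in_shape` matches the input's slices.
#' @return A 3D soft prediction array (values in `[0,1]`) in canonical
#'   (IS, PA, LR) order.
#' @export
path_forward <- function(input, net) {
  d <- dim(input$primary)
  if (!identical(as.integer(d[2:3]), as.integer(net$in_shape)))
    stopf("path_forward: slice shape (%s) does not match net in_shape (%s)",
          paste(d[2:3], collapse = ","), paste(net$in_shape, collapse = ","))
  soft <- array(0, d)
  for (i in seq_len(d[1])) {
    fw <- .path_fwd_slice(net$params, input$primary[i, , ],
                          input$auxiliary[i, , ], keep = FALSE)
    soft[input$slice_index_map[i], , ] <- fw$p
  }
  stack_to_volume(soft, input$plane)
}
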