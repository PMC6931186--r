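# Small programmatic fixtures shared across the suite.

# a smooth 3D test volume with exact-zero background outside an ellipsoid
tiny_volume <- function(shape = c(16L, 16L, 16L), seed = 1L) {
  set.seed(seed)
  g <- lapply(shape, function(n) ((seq_len(n) - (n + 1) / 2) / (0.45 * n))^2)
  support <- outer(outer(g[[1]], g[[2]], `+`), g[[3]], `+`) <= 1
  arr <- (1 + array(rnorm(prod(shape), sd = 0.1), shape)) * support
  brain_volume(arr)
}

# write an array to a temporary NIfTI file, returning the path
write_tmp_nifti <- function(arr, gz = FALSE, spacing = c(1, 1, 1)) {
  path <- tempfile(fileext = if (gz) ".nii.gz" else ".nii")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  path
}

# a random binary mask array
random_mask <- function(shape, p = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rbinom(prod(shape), 1, p), shape)
}

# independent brute-force Dice from Eq.-style counting
brute_dice <- function(pred, truth) {
  TP <- sum(pred == 1 & truth == 1)
  FP <- sum(pred == 1 & truth == 0)
  FN <- sum(pred == 0 & truth == 1)
  if (2 * TP + FP + FN == 0) 1 else 2 * TP / (2 * TP + FP + FN)
}

# exact two-sided Wilcoxon rank-sum p-value by enumerating all
# choose(n_x + n_y, n_x) rank assignments (tie-free samples only)
enum_wilcoxon <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2 # Mann-Whitney U of x
  combos <- utils::combn(nx + ny, nx)
  all_r <- seq_len(nx + ny)
  us <- apply(combos, 2, function(ix) sum(all_r[ix]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  sum(abs(us - mu) >= abs(w_obs - mu) - 1e-9) / ncol(combos)
}

# a minimal 2-case path dataset of noisy discs for training smoke tests
disc_slice_data <- function(n_cases = 2L, n_slices = 6L, hw = c(32L, 32L),
                            seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_cases), function(ci) {
    prim <- array(0, c(n_slices, hw))
    mask <- array(0, c(n_slices, hw))
    for (i in seq_len(n_slices)) {
      cx <- sample(10:22, 1); cy <- sample(10:22, 1); rr <- sample(3:6, 1)
      d2 <- outer((seq_len(hw[1]) - cx)^2, (seq_len(hw[2]) - cy)^2, `+`)
      disc <- d2 <= rr^2
      prim[i, , ] <- rnorm(prod(hw), sd = 0.3) + disc * 2
      mask[i, , ] <- disc * 1
    }
    list(input = path_input("axial", "in_plane", prim, prim),
         mask = mask)
  })
}
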