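#' Fit the multi-path 2.5D lesion segmentation model
#'
#' Trains the full system on a set of aligned, skull-stripped cases: nine
#' dual-encoder 2D path networks (one per plane x normalization scheme,
#' each trained independently on the two-channel soft-Dice loss), then the
#' 3D convolutional fusion post-processor on the frozen paths' stacked
#' binarized outputs. When a case has no `flair` volume, the left-right
#' flipped T1 serves as the auxiliary modality.
#'
#' @param cases list of training cases; each a list with `t1` (a
#'   [brain_volume]), optional `flair`, `mask` (a [lesion_mask]) and an
#'   `id`. All cases must share one grid whose dims are divisible by 16.
#' @param filters channel width of every path network; default 32.
#' @param control a [train_control] for the path networks.
#' @param fuser_control a [train_control] for the post-processor; defaults
#'   to `control`.
#' @param verbose print per-path progress.
#' @return An object of class `lesionfuse`: the nine trained [path_net]s
#'   (named `<plane>.<scheme>`), the trained [fuser_net], the controls and
#'   loss traces. Use [predict.lesionfuse] to segment new volumes.
#' @seealso [predict.lesionfuse], [evaluate_cases], [cross_study_eval]
#' @export
lesionfuse <- function(cases, filters = 32L, control = train_control(),
                       fuser_control = control, verbose = FALSE) {
  if (length(cases) == 0L) stopf("lesionfuse: no training cases")
  sh <- dim(cases[[1]]$t1$data)
  if (any(sh %% 16L != 0L))
    stopf("lesionfuse: grid (%s) must be divisible by 16; conform_to_grid() first",
          paste(sh, collapse = ","))
  for (cs in cases) {
    if (!identical(dim(cs$t1$data), sh) || !identical(dim(cs$mask$data), sh))
      stopf("lesionfuse: all cases must share the grid %s",
            paste(sh, collapse = ","))
  }
  path_names <- as.vector(outer(path_planes(), norm_schemes(), paste, sep = "."))
  paths <- list()
  for (j in seq_along(path_names)) {
    nm <- path_names[j]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (verbose) message(sprintf("training path %d/9: %s", j, nm))
    data <- lapply(cases, function(cs) {
      aux <- cs$flair %||% flip_lr(cs$t1)
      sp <- extract_slices(cs$t1, parts[1])
      sa <- extract_slices(aux, parts[1])
      list(input = path_input(parts[1], parts[2],
                              .apply_scheme(sp, parts[2]),
                              .apply_scheme(sa, parts[2])),
           mask = extract_slices(cs$mask, parts[1]))
    })
    d <- dim(data[[1]]$input$primary)
    net <- path_net(d[2:3], filters = filters, seed = control$seed + j)
    paths[[nm]] <- train_path(data, control, net)
  }
  if (verbose) message("training 3D fusion post-processor")
  fuser <- train_fuser(paths, cases, fuser_control,
                       fuser_net(seed = fuser_control$seed + 100L))
  structure(list(paths = paths, fuser = fuser, filters = as.integer(filters),
                 grid = sh, control = control,
                 fuser_control = fuser_control, n_cases = length(cases),
                 call = match.call()),
            class = "lesionfuse")
}

#' Segment a new case with a fitted model
#'
#' Runs the nine path networks over the case's views and combines their
#' binarized predictions with the requested fusion strategy.
#'
#' @param object a fitted [lesionfuse] model.
#' @param newdata a case (list with `t1` and optional `flair`), or a bare
#'   [brain_volume].
#' @param fusion `"cnn3d"` (trained 3D post-processor), `"majority"`, or
#'   `"union"`.
#' @param type `"mask"` for the hard [lesion_mask], `"prob"` to also get
#'   the soft channels and per-path predictions.
#' @param ... unused.
#' @return A [lesion_mask], or (for `type = "prob"`) a list with `mask`,
#'   `p`, and `paths` (the nine soft volumes).
#' @export
predict.lesionfuse <- function(object, newdata, fusion = c("cnn3d", "majority", "union"),
                               type = c("mask", "prob"), ...) {
  fusion <- match.arg(fusion)
  type <- match.arg(type)
  case <- if (inherits(newdata, "brain_volume")) list(t1 = newdata) else newdata
  preds <- path_ensemble_predict(case, object$paths)
  hard <- lapply(preds, function(p) (p >= 0.5) * 1)
  if (fusion == "cnn3d") {
    stack <- assemble_stack(preds, case$t1)
    out <- fuse_cnn3d(stack, object$fuser)
    mask <- out$mask
    p <- out$p
  } else {
    mask <- if (fusion == "majority") fuse_majority(hard) else fuse_union(hard)
    p <- mask$data
  }
  if (type == "mask") mask else list(mask = mask, p = p, paths = preds)
}

#' @export
print.lesionfuse <- function(x, ...) {
  cat("Multi-path 2.5D lesion segmentation model\n")
  cat(sprintf("  grid: %s  |  paths: %d x dual-encoder U-Net (%d filters)\n",
              paste(x$grid, collapse = "x"), length(x$paths), x$filters))
  cat(sprintf("  fuser: 3x3x3 conv chain %s\n",
              paste(c(18, vapply(x$fuser$layers, function(l) nrow(l$w),
                                 integer(1))), collapse = " -> ")))
  cat(sprintf("  trained on %d cases, %d path epochs, %d fuser epochs\n",
              x$n_cases, x$control$epochs, x$fuser_control$epochs))
  invisible(x)
}

#' @export
summary.lesionfuse <- function(object, ...) {
  n_par <- function(p) if (is.list(p)) sum(vapply(p, n_par, numeric(1))) else length(p)
  final_losses <- vapply(object$paths,
                         function(p) p$trace[length(p$trace)] %||% NA_real_,
                         numeric(1))
  out <- list(
    grid = object$grid,
    filters = object$filters,
    params_per_path = n_par(object$paths[[1]]$params),
    params_fuser = n_par(object$fuser$layers),
    final_path_losses = final_losses,
    fuser_trace = object$fuser$trace
  )
  class(out) <- "summary.lesionfuse"
  out
}

#' @export
print.summary.lesionfuse <- function(x, ...) {
  cat(sprintf("grid %s, %d filters; %s parameters per path, %s in the fuser\n",
              paste(x$grid, collapse = "x"), x$filters,
              format(x$params_per_path, big.mark = ","),
              format(x$params_fuser, big.mark = ",")))
  cat("final per-path training losses (2 - soft Dice pair):\n")
  print(round(x$final_path_losses, 4))
  if (!is.null(x$fuser_trace))
    cat("fuser loss trace:", paste(round(x$fuser_trace, 4), collapse = " "), "\n")
  invisible(x)
}

#' Plot training loss traces
#'
#' @param x a fitted [lesionfuse] model.
#' @param ... passed to [graphics::matplot].
#' @importFrom graphics matplot legend lines
#' @export
plot.lesionfuse <- function(x, ...) {
  tr <- vapply(x$paths, function(p) p$trace, numeric(length(x$paths[[1]]$trace)))
  matplot(seq_len(nrow(tr)), tr, type = "l", lty = 1,
          xlab = "epoch", ylab = "mean two-channel soft-Dice loss",
          main = "Path training losses", ...)
  legend("topright", legend = colnames(tr) %||% names(x$paths),
         col = seq_len(ncol(tr)), lty = 1, cex = 0.6)
  if (!is.null(x$fuser$trace))
    lines(seq_along(x$fuser$trace), x$fuser$trace, lwd = 2, col = "black")
  invisible(x)
}

#' Save / load a fitted model
#'
#' One checkpoint file per path network plus one for the fuser, with a
#' config echo, under `dir`.
#'
#' @param object a fitted [lesionfuse] model.
#' @param dir checkpoint directory (created if missing).
#' @return `save_lesionfuse` the directory, invisibly; `load_lesionfuse`
#'   the restored model.
#' @export
save_lesionfuse <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(object$paths))
    saveRDS(object$paths[[nm]], file.path(dir, paste0("path_", nm, ".rds")))
  saveRDS(object$fuser, file.path(dir, "fuser.rds"))
  meta <- object
  meta$paths <- NULL; meta$fuser <- NULL
  saveRDS(meta, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_lesionfuse
#' @export
load_lesionfuse <- function(dir) {
  meta <- readRDS(file.path(dir, "model.rds"))
  pf <- list.files(dir, pattern = "^path_.*\\.rds$", full.names = TRUE)
  paths <- lapply(pf, readRDS)
  names(paths) <- sub("^path_(.*)\\.rds$", "\\1", basename(pf))
  nm <- as.vector(outer(path_planes(), norm_schemes(), paste, sep = "."))
  meta$paths <- paths[nm]
  meta$fuser <- readRDS(file.path(dir, "fuser.rds"))
  class(meta) <- "lesionfuse"
  meta
}
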