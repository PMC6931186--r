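#' @title Optimization and evaluation harnesses
#' @name training_eval
#' @description
#' All networks are trained with stochastic gradient descent with Nesterov
#' momentum 0.9 and weight decay 1e-4, batch size 32 slices, starting from
#' learning rate 0.01 decayed by 3% after each epoch, for 50 epochs. A
#' reduced desk-scale profile (smaller grid, batch and epoch count) is used
#' throughout the test suite; see the package vignette.
NULL

#' Training configuration
#'
#' @param momentum Nesterov momentum coefficient.
#' @param weight_decay L2 penalty added to every gradient.
#' @param batch_size slices per mini-batch (volumes, for the 3D fuser).
#' @param lr0 initial learning rate.
#' @param lr_decay multiplicative learning-rate decay per epoch (0.03 means
#'   each epoch's rate is 97% of the previous).
#' @param epochs number of passes; 0 is allowed and performs no updates.
#' @param steps_per_epoch mini-batches drawn per epoch; `NULL` covers the
#'   dataset once.
#' @param seed integer seed controlling batch sampling.
#' @return An object of class `train_control`.
#' @export
train_control <- function(momentum = 0.9, weight_decay = 1e-4,
                          batch_size = 32L, lr0 = 0.01, lr_decay = 0.03,
                          epochs = 50L, steps_per_epoch = NULL, seed = 1L) {
  if (lr0 < 0) stopf("train_control: lr0 must be non-negative")
  if (lr_decay < 0 || lr_decay >= 1)
    stopf("train_control: lr_decay must lie in [0, 1)")
  if (epochs < 0) stopf("train_control: epochs must be >= 0")
  structure(list(momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 lr_decay = lr_decay, epochs = as.integer(epochs),
                 steps_per_epoch = steps_per_epoch,
                 seed = as.integer(seed)),
            class = "train_control")
}

#' Learning-rate schedule
#'
#' Geometric decay: `lr0 * (1 - lr_decay)^epoch` with `epoch` counted from
#' 0, so epoch 0 trains at `lr0` and each later epoch at 97% (by default)
#' of the one before.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @param cfg a [train_control].
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, cfg = train_control()) {
  if (any(epoch < 0) || any(epoch >= cfg$epochs))
    stopf("lr_schedule: epoch must lie in [0, %d)", cfg$epochs)
  cfg$lr0 * (1 - cfg$lr_decay)^epoch
}

# ---- recursive parameter-tree helpers -----------------------------------

.zero_like <- function(p) {
  if (is.list(p)) lapply(p, .zero_like) else p * 0
}

.tree_add <- function(a, b) {
  if (is.list(a)) Map(.tree_add, a, b) else a + b
}

.tree_scale <- function(a, s) {
  if (is.list(a)) lapply(a, .tree_scale, s = s) else a * s
}

# one SGD + Nesterov momentum update (PyTorch convention):
#   g <- grad + wd * w;  v <- mu * v + g;  w <- w - lr * (g + mu * v)
.sgd_step <- function(p, g, v, lr, mu, wd) {
  if (is.list(p)) {
    out_p <- p; out_v <- v
    for (k in seq_along(p)) {
      r <- .sgd_step(p[[k]], g[[k]], v[[k]], lr, mu, wd)
      out_p[[k]] <- r$p; out_v[[k]] <- r$v
    }
    list(p = out_p, v = out_v)
  } else {
    gg <- g + wd * p
    v <- mu * v + gg
    list(p = p - lr * (gg + mu * v), v = v)
  }
}

# loss and parameter gradients for one slice pair
.path_slice_grad <- function(pp, x1, x2, r) {
  fw <- .path_fwd_slice(pp, x1, x2, keep = TRUE)
  loss <- two_channel_loss(fw$p, r)
  gp <- .two_channel_loss_grad(fw$p, r)
  list(loss = loss, grads = .path_bwd_slice(pp, fw, gp))
}

#' Train one path network
#'
#' Mini-batch stochastic gradient descent on the two-channel soft-Dice
#' loss. Slices are sampled uniformly across cases within the path's plane;
#' slices with empty masks are retained (the complement channel keeps the
#' loss informative). With a fixed seed the loss trace is reproducible.
#'
#' @param data list of cases, each a list with `input` (a [path_input]) and
#'   `mask` (the matching binary slice stack `(n, h, w)`).
#' @param cfg a [train_control].
#' @param net a [path_net]; a fresh one is built from the data shape when
#'   omitted.
#' @return The trained [path_net] with `$trace` holding the per-epoch mean
#'   loss.
#' @export
train_path <- function(data, cfg = train_control(), net = NULL) {
  if (length(data) == 0L) stopf("train_path: empty training data")
  d <- dim(data[[1]]$input$primary)
  if (is.null(net))
    net <- path_net(d[2:3], seed = cfg$seed)
  index <- do.call(rbind, lapply(seq_along(data), function(ci) {
    cbind(ci, seq_len(dim(data[[ci]]$input$primary)[1]))
  }))
  n_slices <- nrow(index)
  steps <- cfg$steps_per_epoch %||% ceiling(n_slices / cfg$batch_size)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  pp <- net$params
  vel <- .zero_like(pp)
  trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_schedule(ep - 1L, cfg)
    ep_loss <- 0; ep_n <- 0L
    for (st in seq_len(steps)) {
      rows <- index[sample.int(n_slices, min(cfg$batch_size, n_slices)), ,
                    drop = FALSE]
      gacc <- NULL
      bloss <- 0
      for (k in seq_len(nrow(rows))) {
        ci <- rows[k, 1]; si <- rows[k, 2]
        sg <- .path_slice_grad(pp,
                               data[[ci]]$input$primary[si, , ],
                               data[[ci]]$input$auxiliary[si, , ],
                               data[[ci]]$mask[si, , ])
        bloss <- bloss + sg$loss
        gacc <- if (is.null(gacc)) sg$grads else .tree_add(gacc, sg$grads)
      }
      gacc <- .tree_scale(gacc, 1 / nrow(rows))
      upd <- .sgd_step(pp, gacc, vel, lr, cfg$momentum, cfg$weight_decay)
      pp <- upd$p; vel <- upd$v
      ep_loss <- ep_loss + bloss
      ep_n <- ep_n + nrow(rows)
    }
    trace[ep] <- ep_loss / ep_n
  }
  net$params <- pp
  net$trace <- trace
  net
}

#' Train the 3D fusion post-processor on frozen path outputs
#'
#' The nine trained path networks are run once over every training case to
#' build the stacked 18-channel tensors (paths stay frozen; only the fuser
#' receives gradients), then the fuser is optimized on the two-channel
#' soft-Dice loss against the 3D masks, one volume per update.
#'
#' @param path_nets named list of 9 trained [path_net]s (names
#'   `<plane>.<scheme>`).
#' @param cases list of cases, each with `t1` ([brain_volume]), optional
#'   `flair`, and `mask` ([lesion_mask]).
#' @param cfg a [train_control] (its `batch_size` is ignored; volumes are
#'   processed singly).
#' @param fuser a [fuser_net]; fresh when omitted.
#' @return The trained [fuser_net] with a per-epoch loss trace.
#' @export
train_fuser <- function(path_nets, cases, cfg = train_control(),
                        fuser = NULL) {
  if (length(cases) == 0L) stopf("train_fuser: empty training data")
  if (is.null(fuser)) fuser <- fuser_net(seed = cfg$seed)
  stacks <- lapply(cases, function(cs) path_ensemble_stack(cs, path_nets))
  masks <- lapply(cases, function(cs) cs$mask$data)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed + 1L)
  vel <- .zero_like(fuser$layers)
  trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_schedule(ep - 1L, cfg)
    ord <- sample.int(length(stacks))
    ep_loss <- 0
    for (ci in ord) {
      fw <- .fuser_fwd(fuser, stacks[[ci]], keep = TRUE)
      r <- masks[[ci]]
      ep_loss <- ep_loss + two_channel_loss(fw$p, r)
      gp <- .two_channel_loss_grad(fw$p, r)
      grads <- .fuser_bwd(fuser, fw, gp)
      upd <- .sgd_step(fuser$layers, grads, vel, lr, cfg$momentum,
                       cfg$weight_decay)
      fuser$layers <- upd$p; vel <- upd$v
    }
    trace[ep] <- ep_loss / length(stacks)
  }
  fuser$trace <- trace
  fuser
}

#' Run the nine paths on a case and assemble the stacked tensor
#'
#' @param case list with `t1` ([brain_volume]), optional `flair`, and any
#'   other fields (ignored).
#' @param path_nets named list of 9 trained [path_net]s.
#' @return A `stacked_paths` tensor (see [assemble_stack]).
#' @export
path_ensemble_stack <- function(case, path_nets) {
  preds <- path_ensemble_predict(case, path_nets)
  assemble_stack(preds, case$t1)
}

#' Soft predictions of all nine paths for one case
#'
#' @inheritParams path_ensemble_stack
#' @return Named list of 9 soft prediction volumes.
#' @export
path_ensemble_predict <- function(case, path_nets) {
  aux <- case$flair %||% flip_lr(case$t1)
  views <- build_nine_views(case$t1, aux)
  lapply(names(path_nets), function(nm) path_forward(views[[nm]], path_nets[[nm]])) |>
    stats::setNames(names(path_nets))
}
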