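#' End-to-end phantom benchmark
#'
#' Generates a phantom training and held-out test set, fits the full
#' nine-path + 3D-fuser pipeline at the desk-scale profile, and evaluates
#' held-out Dice under all three fusion strategies. This is the package's
#' self-contained system test: it exercises every stage (I/O containers,
#' nine views, path training, stacking, fuser training, metrics) without
#' external data.
#'
#' The default profile -- 48 x 64 x 48 grid, 30 training / 10 test cases,
#' 16 filters, 5 epochs of 20 batches of 8 slices per path, 3 fuser epochs
#' -- is chosen so the whole run completes in minutes on one CPU; see the
#' vignette for the reasoning behind each number.
#'
#' @param seed master seed for data generation and training.
#' @param n_train,n_test phantom counts.
#' @param filters path network width.
#' @param epochs,steps_per_epoch,batch_size path training profile.
#' @param lr0 initial learning rate of the desk profile; larger than the
#'   full-scale default because only a few hundred updates are taken.
#' @param fuser_lr0 initial learning rate for the post-processor, which
#'   starts at the majority-vote operating point and only needs stable
#'   fine-tuning; the full-scale default rate works.
#' @param fuser_epochs post-processor epochs.
#' @param size_mix fraction of small lesions in both sets.
#' @param verbose print progress.
#' @return List with the fitted `model`, per-case tables `cnn3d`,
#'   `majority`, `union`, and `summary` (mean held-out Dice per strategy).
#' @export
phantom_benchmark <- function(seed = 1L, n_train = 30L, n_test = 10L,
                              filters = 16L, epochs = 5L,
                              steps_per_epoch = 20L, batch_size = 8L,
                              lr0 = 0.2, fuser_lr0 = 0.01, fuser_epochs = 3L,
                              size_mix = 0.5, verbose = FALSE) {
  train <- generate_dataset(n_train, size_mix = size_mix, seed = seed,
                            id_prefix = "train")
  test <- generate_dataset(n_test, size_mix = size_mix, seed = seed + 10000L,
                           id_prefix = "test")
  ctl <- train_control(batch_size = batch_size, epochs = epochs,
                       steps_per_epoch = steps_per_epoch, lr0 = lr0,
                       seed = seed)
  fctl <- train_control(batch_size = 1L, epochs = fuser_epochs,
                        lr0 = fuser_lr0, seed = seed)
  model <- lesionfuse(train, filters = filters, control = ctl,
                      fuser_control = fctl, verbose = verbose)
  tabs <- lapply(c(cnn3d = "cnn3d", majority = "majority", union = "union"),
                 function(f) evaluate_cases(model, test, fusion = f))
  summary <- vapply(tabs, function(t) mean(t$dice), numeric(1))
  names(summary) <- paste0("mean_dice_", names(tabs))
  list(model = model, cnn3d = tabs$cnn3d, majority = tabs$majority,
       union = tabs$union, summary = summary, n_test = n_test)
}
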