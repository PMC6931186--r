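#' @title k-fold and cross-study evaluation
#' @name evaluation
NULL

#' Balanced k-fold split of case identifiers
#'
#' Deterministic given the seed; folds are disjoint, exhaustive, and their
#' sizes differ by at most one.
#'
#' @param case_ids vector of unique case identifiers.
#' @param k number of folds.
#' @param seed integer seed.
#' @return An object of class `fold_plan`: list with `n_cases`, `k`,
#'   `assignments` (named integer vector case -> fold) and `seed`.
#' @export
kfold_split <- function(case_ids, k = 5L, seed = 1L) {
  n <- length(case_ids)
  if (anyDuplicated(case_ids)) stopf("kfold_split: duplicated case ids")
  if (k > n) stopf("kfold_split: k = %d exceeds the %d cases", k, n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ord <- sample.int(n)
  fold <- integer(n)
  fold[ord] <- rep(seq_len(k), length.out = n)
  names(fold) <- as.character(case_ids)
  structure(list(n_cases = n, k = as.integer(k), assignments = fold,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d cases in %d folds (sizes %s), seed %d\n",
              x$n_cases, x$k,
              paste(tabulate(x$assignments, x$k), collapse = ","), x$seed))
  invisible(x)
}

#' Per-case evaluation table
#'
#' Predicts every case with the fitted model and tabulates overlap counts,
#' Dice, and the small/large size class of the true lesion.
#'
#' @param object a fitted [lesionfuse] model.
#' @param cases list of cases with `t1`, optional `flair`, `mask`, and an
#'   `id` field.
#' @param fusion fusion strategy passed to [predict.lesionfuse].
#' @return A data frame with columns `id`, `TP`, `FP`, `FN`, `dice`,
#'   `size_class`.
#' @export
evaluate_cases <- function(object, cases, fusion = "cnn3d") {
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    pred <- predict(object, cs, fusion = fusion)
    dr <- dice_coefficient(pred$data, cs$mask$data)
    data.frame(id = as.character(cs$id %||% i),
               TP = dr$TP, FP = dr$FP, FN = dr$FN, dice = dr$dice,
               size_class = classify_lesion_size(cs$mask),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.dice_summary <- function(tab) {
  by_size <- tapply(tab$dice, tab$size_class, mean)
  list(mean_dice = mean(tab$dice), median_dice = median(tab$dice),
       n = nrow(tab),
       mean_dice_small = unname(by_size["small"]),
       mean_dice_large = unname(by_size["large"]))
}

#' Cross-study evaluation: train on one dataset, test on another
#'
#' Fits the full pipeline on the training cases only and evaluates the
#' Dice coefficient per held-out case; any identifier appearing in both
#' sets raises a leakage error before any training happens.
#'
#' @param train_cases,test_cases lists of cases (`t1`, optional `flair`,
#'   `mask`, `id`); their id sets must be disjoint.
#' @param fusion fusion strategy used at test time.
#' @param ... passed on to [lesionfuse] (network and training settings).
#' @return List with the fitted `model`, the per-case `table`, and a
#'   `summary` (mean/median Dice, size-stratified means).
#' @export
cross_study_eval <- function(train_cases, test_cases, fusion = "cnn3d", ...) {
  tr_ids <- vapply(seq_along(train_cases),
                   function(i) as.character(train_cases[[i]]$id %||% paste0("train", i)),
                   character(1))
  te_ids <- vapply(seq_along(test_cases),
                   function(i) as.character(test_cases[[i]]$id %||% paste0("test", i)),
                   character(1))
  common <- intersect(tr_ids, te_ids)
  if (length(common) > 0L)
    stopf("cross_study_eval: leakage - case id(s) %s appear in both sets",
          paste(common, collapse = ", "))
  model <- lesionfuse(train_cases, ...)
  tab <- evaluate_cases(model, test_cases, fusion = fusion)
  list(model = model, table = tab, summary = .dice_summary(tab))
}

#' Write a per-case metrics table as CSV
#'
#' @param tab data frame from [evaluate_cases].
#' @param path output path.
#' @export
write_metrics_csv <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' k-fold cross-validation of the full pipeline
#'
#' For each fold, fits the nine-path + fuser system on the remaining
#' folds and evaluates the held-out cases, pooling the per-case tables.
#'
#' @param cases list of cases with `t1`, optional `flair`, `mask`, `id`.
#' @param k number of folds.
#' @param seed seed for the fold assignment.
#' @param fusion fusion strategy at test time.
#' @param ... passed on to [lesionfuse].
#' @return List with the pooled per-case `table`, a `summary`, and the
#'   [kfold_split] `plan`.
#' @export
kfold_crossval <- function(cases, k = 5L, seed = 1L, fusion = "cnn3d", ...) {
  ids <- vapply(seq_along(cases),
                function(i) as.character(cases[[i]]$id %||% i), character(1))
  plan <- kfold_split(ids, k = k, seed = seed)
  tabs <- lapply(seq_len(k), function(f) {
    hold <- plan$assignments[ids] == f
    model <- lesionfuse(cases[!hold], ...)
    cbind(evaluate_cases(model, cases[hold], fusion = fusion), fold = f)
  })
  tab <- do.call(rbind, tabs)
  list(table = tab, summary = .dice_summary(tab), plan = plan)
}
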