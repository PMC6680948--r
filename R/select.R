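#' Forward selection of features under block-wise cross-validation
#'
#' Greedily grows a feature subset, at each step adding the feature that
#' maximizes the mean cross-validated balanced accuracy of the regularized
#' linear discriminant, and stopping at `max_size` features or when no
#' addition improves the score by more than `tolerance`. The empty model
#' scores 0.5 (chance balanced accuracy). Ties break to the lowest feature
#' id, making selection deterministic.
#'
#' @param dataset A [labeled_dataset()].
#' @param folds Fold assignment from [blockwise_folds()] over the dataset
#'   rows.
#' @param max_size Maximum number of selected features (device cap: 16).
#' @param tolerance Minimum absolute score improvement to accept a step.
#' @param lambda Covariance shrinkage weight of the discriminant.
#' @param candidates Optional feature ids to restrict the search to (e.g. the
#'   retained set of [aed_stability_screen()]).
#' @return Object of class `selection_result`: list with `selected` (ordered
#'   feature ids), `score` (final CV balanced accuracy), `path` (per-step
#'   data frame) and `elimination_log`.
#' @export
forward_select <- function(dataset, folds, max_size = 16, tolerance = 0.002,
                           lambda = 0.1, candidates = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  x <- dataset$x; y <- dataset$y
  if (!any(y == 1L) || !any(y == 0L))
    stop("dataset must contain both classes", call. = FALSE)
  ids <- feature_ids(dataset)
  pool <- if (is.null(candidates)) ids else intersect(ids, sort(candidates))
  if (length(pool) == 0) stop("no candidate features", call. = FALSE)
  st <- fold_stats(x, y, folds)
  sel <- integer(0)
  score <- 0.5
  path <- data.frame(step = integer(0), feature_id = integer(0),
                     score = numeric(0))
  repeat {
    if (length(sel) >= max_size) break
    cand <- setdiff(pool, sel)
    if (length(cand) == 0) break
    cidx <- match(cand, ids)
    sidx <- match(sel, ids)
    subsets <- lapply(cidx, function(j) c(sidx, j))
    sc <- cv_balanced_accuracy(x, y, folds, st, subsets, lambda)
    best <- which.max(sc)                       # first max = lowest id
    if (sc[best] <= score + tolerance) break
    sel <- c(sel, cand[best])
    score <- sc[best]
    path <- rbind(path, data.frame(step = length(sel),
                                   feature_id = cand[best], score = score))
  }
  structure(list(selected = sel, score = score, path = path,
                 elimination_log = data.frame(feature_id = integer(0),
                                              score_after = numeric(0))),
            class = "selection_result")
}

#' Backward elimination of a selected feature set
#'
#' Iteratively drops the feature whose removal least harms (or most helps)
#' the cross-validated score, as long as the score does not fall by more than
#' `tolerance`; at least one feature is always retained. Redundant features
#' (e.g. duplicated columns) are removed here.
#'
#' @inheritParams forward_select
#' @param selection A `selection_result` from [forward_select()].
#' @return The pruned `selection_result` with an updated `elimination_log`.
#' @export
backward_eliminate <- function(selection, dataset, folds, tolerance = 0.002,
                               lambda = 0.1) {
  stopifnot(inherits(selection, "selection_result"),
            inherits(dataset, "labeled_dataset"))
  if (length(selection$selected) == 0) stop("empty selection", call. = FALSE)
  if (length(selection$selected) == 1) return(selection)
  x <- dataset$x; y <- dataset$y
  ids <- feature_ids(dataset)
  st <- fold_stats(x, y, folds)
  sel <- selection$selected
  score <- selection$score
  log <- selection$elimination_log
  while (length(sel) > 1) {
    ord <- sort(sel)                            # scan in id order for ties
    subsets <- lapply(ord, function(j) match(setdiff(sel, j), ids))
    sc <- cv_balanced_accuracy(x, y, folds, st, subsets, lambda)
    best <- which.max(sc)
    if (sc[best] < score - tolerance) break
    dropped <- ord[best]
    sel <- setdiff(sel, dropped)
    score <- sc[best]
    log <- rbind(log, data.frame(feature_id = dropped, score_after = score))
  }
  structure(list(selected = selection$selected[selection$selected %in% sel],
                 score = score, path = selection$path,
                 elimination_log = log),
            class = "selection_result")
}

feature_ids <- function(dataset) {
  as.integer(sub("^f", "", colnames(dataset$x)))
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d feature(s), CV balanced accuracy %.3f\n",
              length(x$selected), x$score))
  if (length(x$selected))
    cat("  ids:", paste(x$selected, collapse = ", "), "\n")
  if (nrow(x$elimination_log))
    cat(sprintf("  %d feature(s) removed by backward elimination\n",
                nrow(x$elimination_log)))
  invisible(x)
}
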