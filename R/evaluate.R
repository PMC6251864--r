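#' Confusion counts from binary calls
#'
#' @param predicted Logical/0-1 vector of calls.
#' @param actual Logical/0-1 vector of true labels.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(predicted, actual) {
  predicted <- as.logical(predicted)
  actual <- as.logical(actual)
  stopifnot(length(predicted) == length(actual))
  tibble::tibble(
    tp = sum(predicted & actual),
    fp = sum(predicted & !actual),
    tn = sum(!predicted & !actual),
    fn = sum(!predicted & actual)
  )
}

#' Sensitivity and specificity
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP). A zero
#' denominator yields `NA` with a warning rather than a silent 0.
#'
#' @param counts One-row confusion tibble (from [confusion_counts()]) or a
#'   named list with `tp`, `fp`, `tn`, `fn`.
#' @return A single number in `[0, 1]`, or `NA` when undefined.
#' @examples
#' sensitivity(confusion_counts(c(1, 1, 0), c(1, 1, 1)))
#' @export
sensitivity <- function(counts) {
  denom <- counts$tp + counts$fn
  if (denom == 0) {
    warning("Sensitivity undefined: no positive samples (TP + FN = 0)",
            call. = FALSE)
    return(NA_real_)
  }
  counts$tp / denom
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  denom <- counts$tn + counts$fp
  if (denom == 0) {
    warning("Specificity undefined: no negative samples (TN + FP = 0)",
            call. = FALSE)
    return(NA_real_)
  }
  counts$tn / denom
}

check_two_classes <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("Labels must be 0/1", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("ROC/AUC need both classes present", call. = FALSE)
  }
  labels
}

#' ROC curve with tie-grouped steps
#'
#' Sweeps the decision threshold over the unique observed scores (high to
#' low), emitting one (FPR, TPR) point per threshold with the endpoints
#' (0, 0) and (1, 1) included. Tied scores move as one group, producing a
#' diagonal segment rather than an arbitrary step order, which makes the
#' trapezoidal area identical to the Mann-Whitney concordance statistic.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 vector, 1 = positive.
#' @return An object of class `m5c_roc`: list with `points` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(0.9, 0.1), c(1, 0))
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group tied scores into single steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)[!duplicated(grp, fromLast = TRUE)]
  fp <- cumsum(1L - l)[!duplicated(grp, fromLast = TRUE)]
  thr <- s[!duplicated(grp)]
  points <- tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                 utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "m5c_roc")
}

#' @export
print.m5c_roc <- function(x, ...) {
  cat("<m5c_roc> AUC = ", format(x$auc, digits = 4), " (",
      x$n_pos, " positives, ", x$n_neg, " negatives, ",
      nrow(x$points), " curve points)\n", sep = "")
  invisible(x)
}

#' @method tidy m5c_roc
#' @export
tidy.m5c_roc <- function(x, ...) x$points

#' @method glance m5c_roc
#' @export
glance.m5c_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
                 n_points = nrow(x$points))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computes the AUC as the pairwise concordance statistic: the probability
#' that a random positive outscores a random negative, with ties counting
#' one half. Implemented through midranks, so it is exactly the trapezoidal
#' area of the tie-grouped ROC curve.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))  # 0.75
#' @export
auc <- function(scores, labels) {
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Represent a fixed-threshold predictor as a single ROC point
#'
#' Tools exposing only a binary yes/no call occupy one (FPR, TPR) point
#' rather than a curve; this helper computes that point from their calls.
#'
#' @param predicted,actual Binary vectors as in [confusion_counts()].
#' @return A one-row tibble with `fpr` and `tpr`.
#' @export
roc_point <- function(predicted, actual) {
  cc <- confusion_counts(predicted, actual)
  tibble::tibble(fpr = 1 - specificity(cc), tpr = sensitivity(cc))
}

#' Intra- and inter-tissue AUC benchmark
#'
#' Scores every tissue-specific predictor on every tissue's independent test
#' set. Cell (i, j) holds predictor i's AUC on tissue j's test set; the
#' diagonal is the intra-tissue performance. A missing test set leaves the
#' cell `NA` (absent), never zero.
#'
#' @param predictors Named list of `m5c_predictor` objects (names = tissue).
#' @param test_sets Named list of labelled window tibbles (names = tissue).
#' @return An object of class `m5c_tissue_matrix`: a tibble with columns
#'   `predictor_tissue`, `test_tissue`, `auc`, `n_pos`, `n_neg`, `intra`,
#'   carrying the square AUC matrix in attribute `"matrix"`.
#' @export
cross_tissue_benchmark <- function(predictors, test_sets) {
  tissues <- names(predictors)
  if (is.null(tissues) || any(!nzchar(tissues))) {
    stop("predictors must be a named list (names = tissue tags)",
         call. = FALSE)
  }
  if (length(intersect(tissues, names(test_sets))) == 0L) {
    stop("No overlap between predictor tissues and test-set tissues",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(predictor_tissue = tissues,
                             test_tissue = tissues)
  cells <- purrr::pmap_dfr(grid, function(predictor_tissue, test_tissue) {
    ts <- test_sets[[test_tissue]]
    if (is.null(ts)) {
      return(tibble::tibble(predictor_tissue = predictor_tissue,
                            test_tissue = test_tissue, auc = NA_real_,
                            n_pos = NA_integer_, n_neg = NA_integer_))
    }
    scores <- predict_scores(predictors[[predictor_tissue]], ts)
    tibble::tibble(
      predictor_tissue = predictor_tissue, test_tissue = test_tissue,
      auc = auc(scores, ts$label),
      n_pos = sum(ts$label == 1L), n_neg = sum(ts$label == 0L)
    )
  })
  cells$intra <- cells$predictor_tissue == cells$test_tissue
  m <- matrix(cells$auc, nrow = length(tissues), byrow = TRUE,
              dimnames = list(predictor = tissues, test = tissues))
  structure(cells, class = c("m5c_tissue_matrix", class(cells)),
            matrix = m)
}

#' Summarise a cross-tissue benchmark
#'
#' @param object An `m5c_tissue_matrix`.
#' @param ... Unused.
#' @return A one-row tibble with `diagonal_mean` and `off_diagonal_mean`.
#' @export
summary.m5c_tissue_matrix <- function(object, ...) {
  tibble::tibble(
    diagonal_mean = mean(object$auc[object$intra], na.rm = TRUE),
    off_diagonal_mean = mean(object$auc[!object$intra], na.rm = TRUE)
  )
}

#' Export a cross-tissue matrix as TSV
#'
#' @param x An `m5c_tissue_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tissue_matrix <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
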