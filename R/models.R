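BUNDLE_FORMAT_VERSION <- 1L

default_hyperparameters <- function(algorithm) {
  switch(algorithm,
    random_forest = list(n_tree = 300L),
    decision_tree = list(min_split = 35L, complexity = 0.00001,
                         max_depth = 30L),
    logistic_regression = list(),
    naive_bayes = list(laplace = 0),
    stop("Unknown algorithm: ", algorithm, call. = FALSE)
  )
}

#' Train an m5C site predictor
#'
#' Fits one of four classifiers on a labelled window dataset: a random forest
#' (the preferred learner; default 300 trees, the cross-validated optimum,
#' grown as a probability forest so each tree contributes terminal-node
#' class proportions rather than a bare vote),
#' logistic regression, naive Bayes, or a decision tree (defaults
#' `min_split = 35`, `complexity = 0.00001`, `max_depth = 30`). All learners
#' are wrapped to emit an estimated probability of the positive class in
#' `[0, 1]`, because the stringency thresholds need a continuous score.
#' Training is reproducible under a fixed seed.
#'
#' @param data Labelled window tibble (columns `window` and `label` in
#'   `{0, 1}`; as produced by the dataset builders).
#' @param algorithm One of `"random_forest"`, `"logistic_regression"`,
#'   `"naive_bayes"`, `"decision_tree"`.
#' @param scheme Encoding scheme, `"one_hot"` (default) or `"feng"`.
#' @param w Flank size of the windows (inferred from `data` when available).
#' @param hyperparameters Named list overriding the algorithm defaults
#'   (e.g. `list(n_tree = 100)`).
#' @param tissue Tissue tag stored with the model (inferred from `data` when
#'   present).
#' @param seed Integer RNG seed.
#' @return An object of class `m5c_predictor`.
#' @export
train_predictor <- function(data,
                            algorithm = c("random_forest",
                                          "logistic_regression",
                                          "naive_bayes", "decision_tree"),
                            scheme = c("one_hot", "feng"), w = NULL,
                            hyperparameters = list(), tissue = NULL,
                            seed = 1L) {
  algorithm <- match.arg(algorithm)
  scheme <- match.arg(scheme)
  data <- tibble::as_tibble(data)
  stopifnot(all(c("window", "label") %in% names(data)))
  y <- as.integer(data$label)
  if (length(unique(y)) < 2L) {
    stop("Training data must contain both classes", call. = FALSE)
  }
  if (is.null(w)) w <- attr(data, "w")
  if (is.null(w)) w <- flank_of(nchar(data$window[[1]]))
  w <- as.integer(w)
  hp <- utils::modifyList(default_hyperparameters(algorithm), hyperparameters)
  x <- encode_windows(data$window, scheme = scheme, w = w)
  yf <- factor(y, levels = c(0L, 1L))
  fit <- local_seed(seed, switch(algorithm,
    random_forest = ranger::ranger(
      x = x, y = yf, num.trees = hp$n_tree, probability = TRUE,
      seed = as.integer(seed), num.threads = 1L),
    logistic_regression = {
      df <- as.data.frame(x)
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()))
    },
    naive_bayes = e1071::naiveBayes(x = x, y = yf, laplace = hp$laplace),
    decision_tree = {
      df <- as.data.frame(x)
      df$.y <- yf
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     minsplit = hp$min_split, cp = hp$complexity,
                     maxdepth = hp$max_depth))
    }
  ))
  if (is.null(tissue)) {
    tissue <- if ("tissue" %in% names(data)) unique(data$tissue)[1] else "unspecified"
  }
  structure(list(
    algorithm = algorithm,
    hyperparameters = hp,
    scheme = scheme,
    w = w,
    tissue = tissue,
    seed = as.integer(seed),
    n_train = nrow(data),
    n_positive = sum(y == 1L),
    thresholds = NULL,
    fit = fit
  ), class = "m5c_predictor")
}

#' @export
print.m5c_predictor <- function(x, ...) {
  cat("<m5c_predictor>\n",
      "  algorithm: ", x$algorithm, "\n",
      "  encoding:  ", x$scheme, " (w = ", x$w, ")\n",
      "  tissue:    ", x$tissue, "\n",
      "  trained on ", x$n_train, " windows (", x$n_positive,
      " positives)\n", sep = "")
  if (!is.null(x$thresholds)) {
    cat("  thresholds:",
        paste(sprintf("%s=%.4f", names(x$thresholds$levels),
                      unlist(x$thresholds$levels)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score candidate windows with a trained predictor
#'
#' @param predictor An `m5c_predictor`.
#' @param windows Character vector of window strings, or a tibble with a
#'   `window` column. Window width must match the predictor's `w`.
#' @return Numeric vector of positive-class probabilities in `[0, 1]`, in
#'   input order.
#' @export
predict_scores <- function(predictor, windows) {
  stopifnot(inherits(predictor, "m5c_predictor"))
  if (is.data.frame(windows)) windows <- windows$window
  if (length(windows) == 0L) return(numeric(0))
  widths <- unique(nchar(windows))
  expected <- 2L * predictor$w + 1L
  if (length(widths) != 1L || widths != expected) {
    stop("Window width ", paste(widths, collapse = "/"),
         " does not match the predictor's expected width ", expected,
         call. = FALSE)
  }
  x <- encode_windows(windows, scheme = predictor$scheme, w = predictor$w)
  scores <- switch(predictor$algorithm,
    random_forest = stats::predict(predictor$fit, data = x,
                                   num.threads = 1L)$predictions[, "1"],
    # one-hot columns sum to 1 within each position, so the design is
    # rank-deficient by construction; predict.lm's warning about it is noise
    logistic_regression = suppressWarnings(
      stats::predict(predictor$fit, newdata = as.data.frame(x),
                     type = "response")),
    naive_bayes = stats::predict(predictor$fit, x, type = "raw")[, "1"],
    decision_tree = stats::predict(predictor$fit,
                                   newdata = as.data.frame(x),
                                   type = "prob")[, "1"]
  )
  unname(pmin(1, pmax(0, as.numeric(scores))))
}

# threshold for one nominal FPR level from sorted calibration scores
threshold_from_scores <- function(alpha, scores, convention = "nearest") {
  n <- length(scores)
  if (convention == "conservative") {
    return(scores[ceiling((1 - alpha) * n)])
  }
  uniq <- unique(scores)
  attained <- vapply(uniq, function(t) mean(scores > t), numeric(1))
  gap <- abs(attained - alpha)
  best <- which(gap == min(gap))
  # on a tie, the larger threshold (lower attained FPR) is stricter
  uniq[max(best)]
}

#' Calibrate stringency thresholds at fixed false-positive rates
#'
#' Scores a calibration set of negative windows and, for each nominal FPR
#' level `alpha`, picks a score threshold whose attained false-positive rate
#' (fraction of calibration negatives scoring strictly above it) matches
#' `alpha`. The defaults are the three published stringency levels: high
#' (1%), medium (5%), low (10%).
#'
#' Scores can carry ties (tree-ensemble outputs are averages over a finite
#' forest), so the attained FPR moves in discrete jumps and may not hit
#' `alpha` exactly. Two conventions are offered:
#'
#' * `"nearest"` (default): the observed score whose attained FPR is closest
#'   to `alpha` (ties broken toward the stricter threshold), so the realised
#'   FPR tracks the nominal level as closely as the score granularity
#'   allows.
#' * `"conservative"`: the smallest score `t` with attained FPR at most
#'   `alpha` -- the `ceiling((1 - alpha) * n)`-th order statistic. This
#'   guarantees FPR `<= alpha` but can undershoot visibly when an atom of
#'   tied scores spans the `alpha` quantile.
#'
#' @param predictor An `m5c_predictor`.
#' @param calibration_negatives Character vector or window tibble of
#'   negative-class windows, ideally drawn from training-side transcripts so
#'   the evaluation protocol stays leak-free.
#' @param fpr_levels Named numeric vector of nominal FPRs, decreasingly
#'   stringent.
#' @param convention `"nearest"` or `"conservative"` (see above).
#' @return The predictor with a `thresholds` field: a list with `levels`
#'   (named thresholds), `fpr_levels`, `calibration_size` and `convention`.
#' @export
calibrate_thresholds <- function(predictor, calibration_negatives,
                                 fpr_levels = c(high = 0.01, medium = 0.05,
                                                low = 0.10),
                                 convention = c("nearest", "conservative")) {
  stopifnot(inherits(predictor, "m5c_predictor"))
  convention <- match.arg(convention)
  if (is.data.frame(calibration_negatives)) {
    calibration_negatives <- calibration_negatives$window
  }
  n <- length(calibration_negatives)
  if (n == 0L) stop("Calibration negatives are empty", call. = FALSE)
  if (n < 1 / min(fpr_levels)) {
    warning("Only ", n, " calibration negatives; the strictest level (",
            min(fpr_levels), ") cannot be resolved reliably", call. = FALSE)
  }
  scores <- sort(predict_scores(predictor, calibration_negatives))
  levels <- vapply(fpr_levels, threshold_from_scores, numeric(1),
                   scores = scores, convention = convention)
  # enforce monotonicity in the face of tied order statistics
  levels <- rev(cummax(rev(levels)))
  predictor$thresholds <- list(
    levels = as.list(levels),
    fpr_levels = as.list(fpr_levels),
    calibration_size = n,
    convention = convention
  )
  predictor
}

#' Tabulate scores against calibrated stringency calls
#'
#' @param predictor A calibrated `m5c_predictor`.
#' @param windows Window tibble with `transcript_id`, `position`, `window`.
#' @return A tibble `transcript_id, position, score, call_high, call_medium,
#'   call_low` (a call is `TRUE` when the score strictly exceeds that level's
#'   threshold).
#' @export
predict_sites <- function(predictor, windows) {
  if (is.null(predictor$thresholds)) {
    stop("Predictor has no calibrated thresholds; run calibrate_thresholds()",
         call. = FALSE)
  }
  windows <- tibble::as_tibble(windows)
  scores <- predict_scores(predictor, windows)
  thr <- predictor$thresholds$levels
  tibble::tibble(
    transcript_id = windows$transcript_id,
    position = windows$position,
    score = scores,
    call_high = scores > thr$high,
    call_medium = scores > thr$medium,
    call_low = scores > thr$low
  )
}

#' Save / load a predictor bundle
#'
#' A bundle is a directory holding `manifest.json` (algorithm,
#' hyperparameters, encoding, flank size, tissue, seed, thresholds, format
#' version, and an md5 checksum of the serialized learner) plus `model.rds`
#' with the fitted state. `load_predictor()` verifies the format version and
#' the checksum, so tampering or version drift fails loudly instead of
#' silently mispredicting.
#'
#' @param predictor An `m5c_predictor`.
#' @param path Bundle directory.
#' @return `save_predictor()`: `path` invisibly; `load_predictor()`: the
#'   restored `m5c_predictor`.
#' @export
save_predictor <- function(predictor, path) {
  stopifnot(inherits(predictor, "m5c_predictor"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  model_file <- file.path(path, "model.rds")
  # the RDS holds the full predictor so numeric state (thresholds, fit)
  # round-trips bit-exactly; the manifest mirrors it for human inspection
  saveRDS(predictor, model_file, version = 3)
  manifest <- list(
    format_version = BUNDLE_FORMAT_VERSION,
    tool_version = as.character(utils::packageVersion("m5cpred")),
    algorithm = predictor$algorithm,
    hyperparameters = predictor$hyperparameters,
    scheme = predictor$scheme,
    w = predictor$w,
    tissue = predictor$tissue,
    seed = predictor$seed,
    n_train = predictor$n_train,
    n_positive = predictor$n_positive,
    thresholds = predictor$thresholds,
    model_md5 = unname(tools::md5sum(model_file))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  manifest_file <- file.path(path, "manifest.json")
  model_file <- file.path(path, "model.rds")
  if (!file.exists(manifest_file) || !file.exists(model_file)) {
    stop("Not a predictor bundle (missing manifest.json or model.rds): ",
         path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_file, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  if (is.null(manifest$format_version) ||
      manifest$format_version != BUNDLE_FORMAT_VERSION) {
    stop("Incompatible bundle format version: ",
         manifest$format_version %||% "<missing>", " (expected ",
         BUNDLE_FORMAT_VERSION, ")", call. = FALSE)
  }
  md5 <- unname(tools::md5sum(model_file))
  if (!identical(md5, manifest$model_md5)) {
    stop("Checksum mismatch for ", model_file,
         ": bundle is corrupt or was tampered with", call. = FALSE)
  }
  predictor <- readRDS(model_file)
  if (!inherits(predictor, "m5c_predictor")) {
    stop("model.rds does not contain an m5c_predictor", call. = FALSE)
  }
  predictor
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted predictor
#'
#' `tidy()` returns one row per hyperparameter; `glance()` returns a one-row
#' model summary.
#'
#' @param x An `m5c_predictor`.
#' @param ... Unused.
#' @method tidy m5c_predictor
#' @export
tidy.m5c_predictor <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$hyperparameters),
    value = as.numeric(unlist(x$hyperparameters))
  )
}

#' @rdname tidy.m5c_predictor
#' @method glance m5c_predictor
#' @export
glance.m5c_predictor <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    scheme = x$scheme,
    w = x$w,
    tissue = x$tissue,
    n_train = x$n_train,
    n_positive = x$n_positive,
    calibrated = !is.null(x$thresholds)
  )
}
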