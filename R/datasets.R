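#' Enumerate negative candidate positions on a transcript
#'
#' Every cytosine that is not a known modified site is a potential negative
#' sample. Returns all 1-based positions of `C` on the transcript excluding
#' the given positive positions.
#'
#' @param transcript A sequence string or one-row transcript tibble.
#' @param positive_positions Integer vector of known positive positions.
#' @return Sorted integer vector of candidate negative positions (possibly
#'   empty).
#' @examples
#' enumerate_negative_candidates("CCC", positive_positions = 2)
#' @export
enumerate_negative_candidates <- function(transcript,
                                          positive_positions = integer()) {
  seq <- if (is.data.frame(transcript)) transcript$sequence[[1]] else transcript
  cpos <- c_positions(seq)
  sort(setdiff(cpos, as.integer(positive_positions)))
}

c_positions <- function(seq) {
  which(strsplit(seq, "", fixed = TRUE)[[1]] == "C")
}

#' Split sites into training and independent-test partitions
#'
#' Randomly assigns a fraction of the sites (default one quarter) to an
#' independent test partition, the rest to training. The partition is a
#' disjoint, exhaustive split of the input rows and is reproducible for a
#' given seed.
#'
#' @param sites Site tibble.
#' @param test_fraction Fraction held out for testing, in (0, 1); default 0.25.
#' @param seed Integer RNG seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_sites <- function(sites, test_fraction = 0.25, seed = 1L) {
  sites <- tibble::as_tibble(sites)
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- nrow(sites)
  if (n == 0L) stop("Cannot split an empty site table", call. = FALSE)
  n_test <- round(test_fraction * n)
  if (n_test < 1L) {
    warning("Too few sites for test_fraction = ", test_fraction,
            "; forcing one test site", call. = FALSE)
    n_test <- 1L
  }
  if (n_test >= n) n_test <- n - 1L
  idx <- local_seed(seed, sample.int(n, n_test))
  list(train = sites[-idx, , drop = FALSE],
       test  = sites[sort(idx), , drop = FALSE])
}

# evaluate expr under a temporary RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Sample negatives at a fixed positive:negative ratio
#'
#' Draws `min(k * n_pos, length(candidates))` positions uniformly without
#' replacement from the candidate pool, warning when the pool caps the draw.
#' A 1:30 ratio is the cross-validated optimum for training sets; test sets
#' instead use every remaining candidate ("1:all").
#'
#' @param candidates Vector of candidate negative positions (or any keys).
#' @param n_pos Number of positives the draw is matched to.
#' @param ratio Integer `k` of the `1:k` design (default 30).
#' @param seed Integer RNG seed.
#' @return A vector of sampled candidates.
#' @export
sample_negatives <- function(candidates, n_pos, ratio = 30L, seed = 1L) {
  stopifnot(n_pos >= 1L, ratio >= 1L)
  if (length(candidates) == 0L) {
    stop("No negative candidates available: training impossible",
         call. = FALSE)
  }
  want <- ratio * n_pos
  if (length(candidates) < want) {
    warning("Only ", length(candidates), " negative candidates for requested ",
            want, " (1:", ratio, " with ", n_pos, " positives); using all",
            call. = FALSE)
    want <- length(candidates)
  }
  local_seed(seed, candidates[sample.int(length(candidates), want)])
}

# All candidate C's on the given transcripts, excluding `exclude` keys.
# Returns a tibble(transcript_id, position).
enumerate_candidate_table <- function(transcripts, transcript_ids,
                                      exclude = NULL) {
  transcripts <- new_transcripts(transcripts)
  keep <- transcripts[transcripts$id %in% unique(transcript_ids), , drop = FALSE]
  out <- purrr::map2_dfr(keep$id, keep$sequence, function(id, seq) {
    tibble::tibble(transcript_id = id, position = c_positions(seq))
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(transcript_id = character(), position = integer())
  }
  if (!is.null(exclude) && nrow(out) > 0L && nrow(exclude) > 0L) {
    out <- dplyr::anti_join(out, exclude[, c("transcript_id", "position")],
                            by = c("transcript_id", "position"))
  }
  out
}

site_key <- function(df) paste(df$transcript_id, df$position, sep = "@")

# Assemble one labelled train/test dataset pair for a set of positive sites.
# Training negatives: 1:k sample from candidate C's on train-side transcripts.
# Test negatives: all remaining candidate C's on transcripts carrying test
# positives ("1:all"), minus anything used on the training side.
build_one_dataset <- function(positives, transcripts, tissue,
                              test_fraction = 0.25, ratio = 30L, seed = 1L,
                              w = 10L) {
  positives <- dplyr::distinct(positives, .data$transcript_id, .data$position,
                               .keep_all = TRUE)
  split <- split_sites(positives, test_fraction = test_fraction,
                       seed = seed)
  all_pos <- positives[, c("transcript_id", "position")]

  train_pool <- enumerate_candidate_table(
    transcripts, split$train$transcript_id, exclude = all_pos)
  if (nrow(train_pool) == 0L) {
    stop("No negative candidates on training transcripts for tissue '",
         tissue, "'", call. = FALSE)
  }
  n_pos_train <- nrow(split$train)
  neg_idx <- sample_negatives(seq_len(nrow(train_pool)), n_pos_train,
                              ratio = ratio, seed = seed + 1L)
  train_neg <- train_pool[sort(neg_idx), , drop = FALSE]

  test_pool <- enumerate_candidate_table(
    transcripts, split$test$transcript_id, exclude = all_pos)
  test_neg <- dplyr::anti_join(test_pool, train_neg,
                               by = c("transcript_id", "position"))

  assemble <- function(pos, neg, role) {
    df <- dplyr::bind_rows(
      dplyr::mutate(pos[, c("transcript_id", "position")], label = 1L),
      dplyr::mutate(neg[, c("transcript_id", "position")], label = 0L)
    )
    df$tissue <- tissue
    df$role <- role
    df
  }
  train <- assemble(split$train, train_neg, "train")
  test <- assemble(split$test, test_neg, "test")
  list(train = finalize_dataset(train, transcripts, w, ratio = ratio),
       test  = finalize_dataset(test, transcripts, w, ratio = "all"))
}

finalize_dataset <- function(df, transcripts, w, ratio) {
  out <- extract_windows(df, transcripts, w = w)
  attr(out, "ratio") <- ratio
  out
}

#' Build tissue-specific training and test datasets
#'
#' For each tissue: positives are split (default one quarter to test), the
#' training set pairs them with a `1:ratio` negative sample, and the test set
#' uses every remaining candidate C on test-side transcripts (`1:all`).
#' Afterwards, each tissue's test set discards any `(transcript_id, position)`
#' that appears in any *other* tissue's training set, so inter-tissue
#' evaluation never scores samples another predictor was trained on.
#'
#' @param sites Site tibble covering one or more tissues (`label ==
#'   "positive"` rows define the positives; other rows are ignored because
#'   negatives are enumerated from the transcripts).
#' @param transcripts Transcript tibble.
#' @param test_fraction,ratio,seed,w Dataset-construction parameters; see
#'   [split_sites()] and [sample_negatives()]. `w` is the window flank size.
#' @return A named list (one element per tissue) of lists with labelled
#'   window tibbles `train` and `test` (columns `transcript_id`, `position`,
#'   `label` in {0,1}, `tissue`, `role`, `window`, `pad_count`).
#' @export
build_tissue_datasets <- function(sites, transcripts, test_fraction = 0.25,
                                  ratio = 30L, seed = 1L, w = 10L) {
  sites <- validate_sites(sites)
  tissues <- unique(sites$tissue)
  out <- list()
  for (i in seq_along(tissues)) {
    tis <- tissues[i]
    pos <- sites[sites$tissue == tis & sites$label == "positive", ,
                 drop = FALSE]
    if (nrow(pos) == 0L) {
      warning("Tissue '", tis, "' has no positive sites; skipped",
              call. = FALSE)
      next
    }
    out[[tis]] <- build_one_dataset(pos, transcripts, tis,
                                    test_fraction = test_fraction,
                                    ratio = ratio, seed = seed + 1000L * i,
                                    w = w)
  }
  # cross-tissue exclusion: test rows used to train any OTHER tissue's model
  train_keys <- lapply(out, function(d) site_key(d$train))
  for (tis in names(out)) {
    other <- unlist(train_keys[setdiff(names(out), tis)], use.names = FALSE)
    if (length(other)) {
      tst <- out[[tis]]$test
      keep <- !(site_key(tst) %in% other)
      out[[tis]]$test <- tst[keep, , drop = FALSE]
      attr(out[[tis]]$test, "ratio") <- "all"
      attr(out[[tis]]$test, "w") <- as.integer(w)
      attr(out[[tis]]$test, "n_excluded") <- sum(!keep)
    }
  }
  out
}

#' Build the comprehensive (all-tissue) dataset
#'
#' Pools positives across tissues, de-duplicating on
#' `(transcript_id, position)` so a site shared between tissues counts once,
#' then constructs train/test sets exactly as for a single tissue.
#'
#' @inheritParams build_tissue_datasets
#' @return A list with labelled window tibbles `train` and `test`, tagged
#'   with tissue `"comprehensive"`.
#' @export
build_comprehensive_dataset <- function(sites, transcripts,
                                        test_fraction = 0.25, ratio = 30L,
                                        seed = 1L, w = 10L) {
  sites <- validate_sites(sites)
  pos <- sites[sites$label == "positive", , drop = FALSE]
  if (nrow(pos) == 0L) stop("No positive sites supplied", call. = FALSE)
  build_one_dataset(pos, transcripts, "comprehensive",
                    test_fraction = test_fraction, ratio = ratio,
                    seed = seed, w = w)
}

#' Serialize a labelled dataset to disk
#'
#' Writes the dataset as a site-table TSV plus a JSON manifest recording the
#' construction parameters, next to the transcript FASTA the caller provides.
#'
#' @param dataset Labelled window tibble.
#' @param dir Output directory (created if needed).
#' @param name Stem for the output files.
#' @param manifest Named list of extra manifest fields (seed, ratio, ...).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir, name = "dataset", manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tbl <- dataset
  tbl$label <- ifelse(tbl$label == 1L, "positive", "negative")
  readr::write_tsv(
    tbl[, c("transcript_id", "position", "label", "tissue")],
    file.path(dir, paste0(name, ".sites.tsv")), progress = FALSE)
  manifest <- c(manifest, list(
    ratio = attr(dataset, "ratio"),
    w = attr(dataset, "w"),
    n_positive = sum(dataset$label == 1L),
    n_negative = sum(dataset$label == 0L)
  ))
  jsonlite::write_json(manifest, file.path(dir, paste0(name, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
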