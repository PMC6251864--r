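#' Sample negative candidate windows outside a used-key set
#'
#' Utility for threshold calibration and FPR audits: draws `n` candidate
#' cytosines uniformly from the given transcripts, excluding any
#' `(transcript_id, position)` already used (e.g. training rows, known
#' positives, previously drawn calibration sets), and extracts their windows.
#'
#' @param transcripts Transcript tibble.
#' @param n Number of windows to draw.
#' @param exclude Tibble with `transcript_id`/`position` columns to avoid
#'   (or NULL).
#' @param seed Integer RNG seed.
#' @param w Flank size.
#' @return A window tibble of `n` rows (fewer, with a warning, if the pool
#'   is exhausted).
#' @export
sample_negative_windows <- function(transcripts, n, exclude = NULL,
                                    seed = 1L, w = 10L) {
  pool <- enumerate_candidate_table(transcripts, transcripts$id,
                                    exclude = exclude)
  if (nrow(pool) < n) {
    warning("Only ", nrow(pool), " candidate negatives available (asked ",
            n, ")", call. = FALSE)
    n <- nrow(pool)
  }
  idx <- local_seed(seed, sample.int(nrow(pool), n))
  drawn <- pool[sort(idx), , drop = FALSE]
  drawn$label <- 0L
  extract_windows(drawn, transcripts, w = w)
}

#' Run the full simulate-train-calibrate-evaluate pipeline
#'
#' End-to-end driver: simulates a synthetic benchmark, builds the
#' comprehensive and per-tissue datasets, trains a predictor per dataset,
#' calibrates stringency thresholds on fresh training-side negatives,
#' evaluates every predictor on its independent test set, and runs the
#' cross-tissue benchmark. All artefacts (manifests, metrics TSVs, model
#' bundles) land under `out_dir` and are a pure function of the
#' configuration and seeds.
#'
#' @param spec A [synthetic_spec()] describing the simulation.
#' @param out_dir Output directory (created). NULL keeps everything
#'   in memory only.
#' @param ratio Training positive:negative ratio (1:`ratio`).
#' @param test_fraction Held-out fraction of positive sites.
#' @param n_tree Random-forest tree count.
#' @param scheme Encoding scheme.
#' @param w Window flank size.
#' @param n_calibration Negatives drawn for threshold calibration.
#' @param fpr_levels Nominal stringency FPR levels.
#' @param seed Master seed for dataset construction and training.
#' @return A list: `sim`, `datasets` (per-tissue + comprehensive),
#'   `predictors`, `metrics` (tibble of per-dataset AUCs), `tissue_matrix`.
#' @export
run_pipeline <- function(spec = synthetic_spec(), out_dir = NULL,
                         ratio = 30L, test_fraction = 0.25, n_tree = 300L,
                         scheme = c("one_hot", "feng"), w = 10L,
                         n_calibration = 2000L,
                         fpr_levels = c(high = 0.01, medium = 0.05,
                                        low = 0.10),
                         seed = 1L) {
  scheme <- match.arg(scheme)
  sim <- simulate_m5c(spec)

  datasets <- build_tissue_datasets(sim$sites, sim$transcripts,
                                    test_fraction = test_fraction,
                                    ratio = ratio, seed = seed, w = w)
  datasets$comprehensive <- build_comprehensive_dataset(
    sim$sites, sim$transcripts, test_fraction = test_fraction,
    ratio = ratio, seed = seed, w = w)

  predictors <- list()
  metrics <- list()
  for (tis in names(datasets)) {
    d <- datasets[[tis]]
    p <- train_predictor(d$train, algorithm = "random_forest",
                         scheme = scheme, w = w,
                         hyperparameters = list(n_tree = n_tree),
                         tissue = tis, seed = seed)
    # calibration negatives come from training-side transcripts and never
    # overlap training rows or known positives; with 1:all test sets they
    # may coincide with test negatives, which the model never saw either
    used <- dplyr::bind_rows(
      d$train[, c("transcript_id", "position")],
      d$test[d$test$label == 1L, c("transcript_id", "position")]
    )
    train_tx <- sim$transcripts[
      sim$transcripts$id %in% unique(d$train$transcript_id), , drop = FALSE]
    calib <- sample_negative_windows(train_tx, n_calibration,
                                     exclude = used, seed = seed + 7L,
                                     w = w)
    p <- calibrate_thresholds(p, calib, fpr_levels = fpr_levels)
    predictors[[tis]] <- p
    test_scores <- predict_scores(p, d$test)
    metrics[[tis]] <- tibble::tibble(
      tissue = tis,
      auc = auc(test_scores, d$test$label),
      n_test_pos = sum(d$test$label == 1L),
      n_test_neg = sum(d$test$label == 0L)
    )
  }
  metrics <- dplyr::bind_rows(metrics)

  tissue_only <- setdiff(names(datasets), "comprehensive")
  tissue_matrix <- cross_tissue_benchmark(
    predictors[tissue_only],
    purrr::map(datasets[tissue_only], "test"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_simulation(sim, file.path(out_dir, "simulation"))
    for (tis in names(datasets)) {
      write_dataset(datasets[[tis]]$train, file.path(out_dir, "datasets"),
                    name = paste0(tis, ".train"),
                    manifest = list(seed = seed, tissue = tis,
                                    test_fraction = test_fraction))
      write_dataset(datasets[[tis]]$test, file.path(out_dir, "datasets"),
                    name = paste0(tis, ".test"),
                    manifest = list(seed = seed, tissue = tis,
                                    test_fraction = test_fraction))
      save_predictor(predictors[[tis]],
                     file.path(out_dir, "models", tis))
    }
    readr::write_tsv(metrics, file.path(out_dir, "metrics.tsv"),
                     progress = FALSE)
    write_tissue_matrix(tissue_matrix,
                        file.path(out_dir, "tissue_matrix.tsv"))
    jsonlite::write_json(
      list(seed = seed, ratio = ratio, test_fraction = test_fraction,
           n_tree = n_tree, scheme = scheme, w = w,
           n_calibration = n_calibration,
           fpr_levels = as.list(fpr_levels),
           tool_version = as.character(utils::packageVersion("m5cpred"))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }

  list(sim = sim, datasets = datasets, predictors = predictors,
       metrics = metrics, tissue_matrix = tissue_matrix)
}

#' Scan and score every cytosine in a set of transcripts
#'
#' Realises prediction on raw FASTA input: every `C` in every sequence is a
#' candidate, scored and called at the three calibrated stringency levels.
#'
#' @param predictor A calibrated `m5c_predictor`.
#' @param transcripts Transcript tibble (e.g. from [read_fasta()]).
#' @param sites Optional site tibble restricting scoring to listed
#'   positions.
#' @return Prediction tibble from [predict_sites()]; zero rows (with a
#'   warning) when the input contains no cytosine.
#' @export
scan_transcripts <- function(predictor, transcripts, sites = NULL) {
  transcripts <- new_transcripts(transcripts)
  cand <- if (is.null(sites)) {
    enumerate_candidate_table(transcripts, transcripts$id)
  } else {
    validate_sites(sites)[, c("transcript_id", "position")]
  }
  if (nrow(cand) == 0L) {
    warning("No candidate cytosines in input", call. = FALSE)
    return(tibble::tibble(transcript_id = character(), position = integer(),
                          score = numeric(), call_high = logical(),
                          call_medium = logical(), call_low = logical()))
  }
  windows <- extract_windows(cand, transcripts, w = predictor$w)
  predict_sites(predictor, windows)
}
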