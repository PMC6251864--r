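test_that("negative candidate enumeration finds exactly the unlabelled C's", {
  expect_equal(enumerate_negative_candidates("CCC", 2), c(1L, 3L))
  expect_equal(enumerate_negative_candidates("AGT"), integer(0))
  set.seed(9)
  for (rep in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "T"), sample(10:80, 1), TRUE),
                 collapse = "")
    cpos <- which(strsplit(seq, "")[[1]] == "C")
    pos <- sample(cpos, min(length(cpos), sample(0:4, 1)))
    got <- enumerate_negative_candidates(seq, pos)
    # conservation: negatives + labelled C's account for every C
    expect_equal(length(got) + length(intersect(pos, cpos)), length(cpos))
    expect_true(all(strsplit(seq, "")[[1]][got] == "C"))
  }
})

test_that("splitting holds out the requested fraction, deterministically and
           exhaustively", {
  sites <- tibble::tibble(
    transcript_id = paste0("t", 1:1000), position = 1:1000,
    label = "positive", tissue = "x")
  sp <- split_sites(sites, test_fraction = 0.25, seed = 3)
  expect_equal(nrow(sp$test), 250L)
  expect_equal(nrow(sp$train), 750L)
  # conservation and disjointness
  key <- function(df) paste(df$transcript_id, df$position)
  expect_setequal(c(key(sp$train), key(sp$test)), key(sites))
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  # determinism
  sp2 <- split_sites(sites, test_fraction = 0.25, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp$test,
                         split_sites(sites, 0.25, seed = 4)$test))
})

test_that("splitting a tiny site table warns but still yields a test site", {
  sites <- tibble::tibble(transcript_id = "t", position = 1:2,
                          label = "positive", tissue = "x")
  expect_warning(sp <- split_sites(sites, 0.25, seed = 1), "one test site")
  expect_equal(nrow(sp$test), 1L)
  expect_equal(nrow(sp$train), 1L)
})

test_that("negative sampling returns exactly min(k * n_pos, available)", {
  expect_length(sample_negatives(1:500, 10, ratio = 30, seed = 1), 300L)
  expect_warning(res <- sample_negatives(1:120, 10, ratio = 30, seed = 1),
                 "using all")
  expect_length(res, 120L)
  expect_error(sample_negatives(integer(0), 10, 30, 1), "impossible")
})

test_that("negative sampling is seed-reproducible and without replacement", {
  a <- sample_negatives(1:1000, 5, 30, seed = 7)
  b <- sample_negatives(1:1000, 5, 30, seed = 7)
  expect_identical(a, b)
  expect_false(identical(sort(a), sort(sample_negatives(1:1000, 5, 30, 8))))
  expect_equal(anyDuplicated(a), 0L)
})

test_that("per-tissue datasets respect the 1:k train design and 1:all tests", {
  sim <- small_sim()
  ds <- build_tissue_datasets(sim$sites, sim$transcripts, ratio = 5,
                              seed = 2, w = 10)
  for (tis in names(ds)) {
    train <- ds[[tis]]$train
    test <- ds[[tis]]$test
    n_pos <- sum(train$label == 1L)
    expect_lte(sum(train$label == 0L), 5 * n_pos)
    # every window is centred on C
    expect_true(all(substr(train$window, 11, 11) == "C"))
    expect_true(all(substr(test$window, 11, 11) == "C"))
    # train and test never share a site
    key <- function(df) paste(df$transcript_id, df$position)
    expect_length(intersect(key(train), key(test)), 0L)
    expect_equal(attr(test, "ratio"), "all")
  }
})

test_that("each tissue's test set excludes other tissues' training samples
           but never its own (set-algebra oracle)", {
  sim <- small_sim()
  ds <- build_tissue_datasets(sim$sites, sim$transcripts, ratio = 5,
                              seed = 2, w = 10)
  key <- function(df) paste(df$transcript_id, df$position)
  tissues <- names(ds)
  for (tis in tissues) {
    other_train <- unlist(lapply(setdiff(tissues, tis),
                                 function(o) key(ds[[o]]$train)))
    expect_length(intersect(key(ds[[tis]]$test), other_train), 0L)
    # own training rows are untouched by the exclusion
    expect_length(intersect(key(ds[[tis]]$train), key(ds[[tis]]$test)), 0L)
    expect_gt(nrow(ds[[tis]]$train), 0L)
  }
})

test_that("single-tissue input makes cross-tissue exclusion a no-op", {
  sim <- small_sim()
  one <- sim$sites[sim$sites$tissue == "tisA", ]
  ds1 <- build_tissue_datasets(one, sim$transcripts, ratio = 5, seed = 2)
  ds2 <- build_tissue_datasets(sim$sites[sim$sites$tissue == "tisA", ],
                               sim$transcripts, ratio = 5, seed = 2)
  expect_identical(ds1$tisA$test$position, ds2$tisA$test$position)
  expect_equal(attr(ds1$tisA$test, "n_excluded") %||% 0L, 0L)
})

test_that("a tissue without positives is skipped with a warning", {
  sim <- small_sim()
  sites <- dplyr::bind_rows(
    sim$sites,
    tibble::tibble(transcript_id = sim$transcripts$id[1], position = NA,
                   label = "negative", tissue = "empty_tissue") |>
      dplyr::mutate(position = enumerate_negative_candidates(
        sim$transcripts$sequence[1])[1]))
  expect_warning(ds <- build_tissue_datasets(sites, sim$transcripts,
                                             ratio = 5, seed = 2),
                 "no positive")
  expect_false("empty_tissue" %in% names(ds))
})

test_that("comprehensive dataset de-duplicates shared sites before the split", {
  tx <- tibble::tibble(id = "t1", gene_id = "g", biotype = "mRNA",
                       sequence = paste(rep("ACT", 40), collapse = ""),
                       description = NA)
  # same three positives recorded in two tissues
  pos <- tibble::tibble(transcript_id = "t1",
                        position = c(38L, 59L, 80L, 101L),
                        label = "positive")
  sites <- dplyr::bind_rows(dplyr::mutate(pos, tissue = "A"),
                            dplyr::mutate(pos, tissue = "B"))
  ds <- suppressWarnings(build_comprehensive_dataset(sites, tx, ratio = 2,
                                                     seed = 1))
  expect_equal(sum(ds$train$label) + sum(ds$test$label), nrow(pos))
})

test_that("dataset construction is a pure function of inputs and seed", {
  sim <- small_sim()
  a <- build_comprehensive_dataset(sim$sites, sim$transcripts, seed = 5,
                                   ratio = 5)
  b <- build_comprehensive_dataset(sim$sites, sim$transcripts, seed = 5,
                                   ratio = 5)
  expect_identical(a, b)
})

test_that("dataset serialization writes site TSV plus JSON manifest", {
  sim <- small_sim()
  ds <- build_comprehensive_dataset(sim$sites, sim$transcripts, seed = 5,
                                    ratio = 5)
  dir <- tempfile()
  write_dataset(ds$train, dir, "comp.train", manifest = list(seed = 5))
  sites <- read_site_table(file.path(dir, "comp.train.sites.tsv"))
  expect_equal(nrow(sites), nrow(ds$train))
  man <- jsonlite::read_json(file.path(dir, "comp.train.manifest.json"))
  expect_equal(man$seed, 5L)
  expect_equal(man$n_positive, sum(ds$train$label == 1L))
})
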