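# Shared test fixtures and independent oracles, built in code.

# write a FASTA string to a temp file
tmp_fasta <- function(text) {
  f <- tempfile(fileext = ".fa")
  writeLines(text, f)
  f
}

# write a site table to a temp TSV
tmp_sites <- function(df) {
  f <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, f, progress = FALSE)
  f
}

toy_transcripts <- function() {
  tibble::tibble(
    id = c("t1", "t2"),
    gene_id = c("g1", "g1"),
    biotype = c("mRNA", "mRNA"),
    sequence = c("AACGTACGTCCA", "CCGTACCC"),
    description = NA_character_
  )
}

# independent AUC oracle: brute-force pairwise concordance
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# independent Feng fourth-bit oracle: direct definition, per position
feng_freq_oracle <- function(window) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  vapply(seq_along(chars), function(i) {
    if (chars[i] == "N") return(0)
    prefix <- chars[1:i]
    prefix <- prefix[prefix != "N"]
    sum(prefix == chars[i]) / length(prefix)
  }, numeric(1))
}

# a tiny two-tissue corpus with deterministic motif positives, for dataset
# construction tests where counts must be exact
small_sim <- function(seed = 42L) {
  spec <- synthetic_spec(
    n_transcripts = 12L, length_range = c(300L, 400L),
    tissues = c("tisA", "tisB"),
    motif_per_tissue = c(tisA = "AGGTCAAGG", tisB = "TTCACGTTC"),
    positive_rate = 3, seed = seed)
  simulate_m5c(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
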