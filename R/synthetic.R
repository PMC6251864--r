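#' Specification for the synthetic m5C benchmark generator
#'
#' Describes a corpus of random transcripts with tissue-specific sequence
#' motifs implanted around positive m5C sites, so the full pipeline --
#' dataset construction, training, calibration, evaluation -- can be
#' exercised end to end without any external data. Background sequence is
#' i.i.d. from `base_composition`; each tissue writes its consensus motif
#' (which must contain a `C` at the declared anchor offset) over the
#' background at sampled loci and records the anchor as a positive site.
#' Every non-implanted `C` is an implicit negative.
#'
#' The defaults are fixed study conditions, not tuning knobs: 60 transcripts
#' of 800-1200 nt with a mildly AT-rich composition give roughly 200-260
#' candidate cytosines per transcript against ~2 implanted positives per
#' tissue, i.e. dozens of negative C's per positive even after pooling the
#' three tissues, so the 1:30 training-ratio machinery is exercised under a
#' realistic class imbalance while leaving candidates over for the 1:all
#' test sets. The three tissue tags carry mutually distinct strong motifs,
#' which is what makes intra-tissue predictors beat inter-tissue transfer.
#'
#' @param n_transcripts Number of transcripts.
#' @param length_range Min/max transcript length (nt).
#' @param base_composition Named probabilities for A, C, G, T (sum to 1).
#' @param tissues Character vector of tissue tags.
#' @param motif_per_tissue Named list/vector tissue -> consensus motif over
#'   `{A,C,G,T,N}` (`N` = leave background base untouched).
#' @param motif_anchor Named integer vector (or single integer, recycled):
#'   1-based offset of the anchor C within each motif.
#' @param positive_rate Expected implanted positives per transcript per
#'   tissue (Poisson-distributed count).
#' @param label_noise Probability that a recorded site label is flipped,
#'   in `[0, 0.5)`.
#' @param seed Integer RNG seed.
#' @return A validated list of class `m5c_synthetic_spec`.
#' @export
synthetic_spec <- function(n_transcripts = 60L,
                           length_range = c(800L, 1200L),
                           base_composition = c(A = 0.30, C = 0.22,
                                                G = 0.22, T = 0.26),
                           tissues = c("mouse_Brain", "mouse_Heart",
                                       "human_Hela"),
                           motif_per_tissue = c(
                             mouse_Brain = "AGGTCAAGG",
                             mouse_Heart = "TTCACGTTC",
                             human_Hela  = "GACGCGTAG"),
                           motif_anchor = 5L,
                           positive_rate = 2,
                           label_noise = 0,
                           seed = 1L) {
  stopifnot(n_transcripts >= 1L, length(length_range) == 2L,
            length_range[1] <= length_range[2])
  if (abs(sum(base_composition) - 1) > 1e-9) {
    stop("base_composition must sum to 1", call. = FALSE)
  }
  if (!setequal(names(base_composition), c("A", "C", "G", "T"))) {
    stop("base_composition must be named A, C, G, T", call. = FALSE)
  }
  if (base_composition[["C"]] <= 0) {
    stop("base_composition['C'] must be positive: without cytosines there ",
         "are no candidate sites", call. = FALSE)
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("label_noise must be in [0, 0.5)", call. = FALSE)
  }
  motif_per_tissue <- as.list(motif_per_tissue)
  if (!all(tissues %in% names(motif_per_tissue))) {
    stop("motif_per_tissue must define a motif for every tissue",
         call. = FALSE)
  }
  anchors <- if (length(motif_anchor) == 1L) {
    stats::setNames(rep(as.integer(motif_anchor), length(tissues)), tissues)
  } else {
    motif_anchor[tissues]
  }
  for (tis in tissues) {
    motif <- motif_per_tissue[[tis]]
    a <- anchors[[tis]]
    if (is.na(a) || a < 1L || a > nchar(motif) ||
        substr(motif, a, a) != "C") {
      stop("Motif for tissue '", tis, "' must carry a C at anchor offset ",
           a, call. = FALSE)
    }
    if (grepl("[^ACGTN]", motif)) {
      stop("Motif for tissue '", tis, "' has characters outside {A,C,G,T,N}",
           call. = FALSE)
    }
  }
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    length_range = as.integer(length_range),
    base_composition = base_composition[c("A", "C", "G", "T")],
    tissues = tissues,
    motif_per_tissue = motif_per_tissue[tissues],
    motif_anchor = anchors,
    positive_rate = positive_rate,
    label_noise = label_noise,
    seed = as.integer(seed)
  ), class = "m5c_synthetic_spec")
}

#' Generate random background transcripts
#'
#' @param spec An [synthetic_spec()] object.
#' @return A transcript tibble (ids `synth_0001`, ...), deterministic under
#'   the spec's seed.
#' @export
generate_transcripts <- function(spec) {
  stopifnot(inherits(spec, "m5c_synthetic_spec"))
  local_seed(spec$seed, {
    span <- spec$length_range[2] - spec$length_range[1] + 1L
    lens <- spec$length_range[1] +
      sample.int(span, spec$n_transcripts, replace = TRUE) - 1L
    seqs <- vapply(lens, function(n) {
      paste(sample(names(spec$base_composition), n, replace = TRUE,
                   prob = spec$base_composition), collapse = "")
    }, character(1))
    new_transcripts(tibble::tibble(
      id = sprintf("synth_%04d", seq_len(spec$n_transcripts)),
      gene_id = sprintf("gene_%04d", seq_len(spec$n_transcripts)),
      biotype = "mRNA",
      sequence = seqs,
      description = "synthetic transcript"
    ))
  })
}

#' Implant tissue-specific motifs and derive site tables
#'
#' For each tissue, samples motif loci on each transcript (count ~
#' Poisson(`positive_rate`), non-overlapping within a transcript), overwrites
#' the background bases with the motif (positions where the motif has `N`
#' keep the background base), and records the anchor C as a positive site.
#' All remaining cytosines become negative records. With `label_noise > 0`,
#' each recorded label flips independently at that rate.
#'
#' Implantation overwrites sequence rather than rejection-sampling existing
#' matches, which keeps the positive rate exact and the generator simple.
#'
#' @param transcripts A transcript tibble from [generate_transcripts()].
#' @param spec The same [synthetic_spec()].
#' @return A list: `transcripts` (with motifs written in) and `sites`
#'   (tibble `transcript_id`, `position`, `label`, `tissue`).
#' @export
implant_sites <- function(transcripts, spec) {
  stopifnot(inherits(spec, "m5c_synthetic_spec"))
  transcripts <- new_transcripts(transcripts)
  min_len <- min(nchar(transcripts$sequence))
  max_motif <- max(nchar(unlist(spec$motif_per_tissue)))
  if (max_motif > min_len) {
    stop("Motif length ", max_motif, " exceeds shortest transcript (",
         min_len, " nt)", call. = FALSE)
  }
  local_seed(spec$seed + 1L, {
    seqs <- transcripts$sequence
    site_rows <- list()
    # reserve implanted spans across tissues so motifs never collide
    taken <- lapply(seqs, function(s) logical(nchar(s)))
    for (tis in spec$tissues) {
      motif <- spec$motif_per_tissue[[tis]]
      mlen <- nchar(motif)
      anchor <- spec$motif_anchor[[tis]]
      mchars <- strsplit(motif, "", fixed = TRUE)[[1]]
      for (i in seq_along(seqs)) {
        n <- nchar(seqs[i])
        k <- stats::rpois(1L, spec$positive_rate)
        if (k == 0L) next
        starts <- integer(0)
        tries <- 0L
        while (length(starts) < k && tries < 50L * k) {
          cand <- sample.int(n - mlen + 1L, 1L)
          span <- cand:(cand + mlen - 1L)
          if (!any(taken[[i]][span])) {
            starts <- c(starts, cand)
            taken[[i]][span] <- TRUE
          }
          tries <- tries + 1L
        }
        for (st in starts) {
          chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
          write_idx <- which(mchars != "N")
          chars[st + write_idx - 1L] <- mchars[write_idx]
          seqs[i] <- paste(chars, collapse = "")
          site_rows[[length(site_rows) + 1L]] <- tibble::tibble(
            transcript_id = transcripts$id[i],
            position = st + anchor - 1L,
            label = "positive",
            tissue = tis
          )
        }
      }
    }
    positives <- if (length(site_rows)) dplyr::bind_rows(site_rows) else
      tibble::tibble(transcript_id = character(), position = integer(),
                     label = character(), tissue = character())
    transcripts$sequence <- seqs
    # implicit negatives: every remaining C, per tissue
    negatives <- purrr::map_dfr(spec$tissues, function(tis) {
      pos_t <- positives[positives$tissue == tis, , drop = FALSE]
      purrr::map2_dfr(transcripts$id, transcripts$sequence,
                      function(id, s) {
        cand <- enumerate_negative_candidates(
          s, pos_t$position[pos_t$transcript_id == id])
        tibble::tibble(transcript_id = id, position = cand,
                       label = "negative", tissue = tis)
      })
    })
    sites <- dplyr::bind_rows(positives, negatives)
    if (spec$label_noise > 0 && nrow(sites) > 0L) {
      flip <- stats::runif(nrow(sites)) < spec$label_noise
      sites$label[flip] <- ifelse(sites$label[flip] == "positive",
                                  "negative", "positive")
    }
    list(transcripts = transcripts, sites = sites)
  })
}

#' Simulate a complete synthetic m5C benchmark
#'
#' Convenience wrapper: [generate_transcripts()] then [implant_sites()].
#'
#' @param spec An [synthetic_spec()]; default spec if omitted.
#' @return A list with `transcripts`, `sites` and the `spec` used.
#' @export
simulate_m5c <- function(spec = synthetic_spec()) {
  transcripts <- generate_transcripts(spec)
  out <- implant_sites(transcripts, spec)
  out$spec <- spec
  out
}

#' Persist a simulation to FASTA + site TSV + JSON spec
#'
#' @param sim Result of [simulate_m5c()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$transcripts, file.path(dir, "transcripts.fa"))
  write_site_table(sim$sites, file.path(dir, "sites.tsv"))
  spec <- sim$spec
  spec$base_composition <- as.list(spec$base_composition)
  spec$motif_anchor <- as.list(spec$motif_anchor)
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
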