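#' Read transcripts from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file into a transcript
#' table. Sequences are upper-cased and `U` is normalised to `T`, so downstream
#' code works on a single DNA-style alphabet `{A, C, G, T, N}` regardless of
#' whether the input was written with RNA or DNA semantics. The header token
#' before the first whitespace becomes the transcript `id`; the remainder is
#' kept as `description`.
#'
#' @param path Path to a FASTA file.
#' @param gene_id,biotype Optional character vectors (recycled) giving gene
#'   linkage and biotype for each record; default `NA` / `"mRNA"`.
#' @return A tibble with columns `id`, `gene_id`, `biotype`, `sequence`,
#'   `description`, one row per FASTA record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 demo", "ACGU"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, gene_id = NA_character_, biotype = "mRNA") {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(trimws(first), ">")) {
    stop("Malformed FASTA (no '>' header before sequence) at line 1 of ",
         path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), NA_character_)
  if (anyDuplicated(ids)) {
    stop("Duplicate transcript id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- normalize_sequence(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("Transcript(s) with characters outside {A,C,G,T,U,N}: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  new_transcripts(tibble::tibble(
    id = ids,
    gene_id = rep_len(gene_id, length(ids)),
    biotype = rep_len(biotype, length(ids)),
    sequence = unname(seqs),
    description = desc
  ))
}

#' Write transcripts to a FASTA file
#'
#' @param transcripts A transcript tibble as returned by [read_fasta()] or
#'   [generate_transcripts()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path) {
  transcripts <- new_transcripts(transcripts)
  set <- Biostrings::BStringSet(transcripts$sequence)
  names(set) <- ifelse(
    is.na(transcripts$description) | transcripts$description == "",
    transcripts$id,
    paste(transcripts$id, transcripts$description)
  )
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# uppercase + U->T; keeps alphabet checks to callers
normalize_sequence <- function(x) {
  chartr("Uu", "Tt", toupper(x))
}

# validate the transcript-table contract shared by seqio consumers
new_transcripts <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("id", "sequence")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("Transcript table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"gene_id" %in% names(df)) df$gene_id <- NA_character_
  if (!"biotype" %in% names(df)) df$biotype <- "mRNA"
  if (!"description" %in% names(df)) df$description <- NA_character_
  if (any(!nzchar(df$id)) || anyNA(df$id)) {
    stop("Transcript ids must be non-empty", call. = FALSE)
  }
  if (any(nchar(df$sequence) < 1L)) {
    stop("Transcript sequences must have length >= 1", call. = FALSE)
  }
  df
}

#' Read a site-annotation table
#'
#' Sites are candidate cytosines with a curated modification label and a tissue
#' tag. The expected format is a headered TSV with columns `transcript_id`,
#' `position` (1-based, on the transcript), `label` (`positive`/`negative`) and
#' `tissue`.
#'
#' @param path Path to a tab-separated site table.
#' @return A tibble with columns `transcript_id` (character), `position`
#'   (integer), `label` (character), `tissue` (character).
#' @export
read_site_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    position = readr::col_integer(),
    label = readr::col_character(),
    tissue = readr::col_character()
  ), progress = FALSE)
  validate_sites(df)
}

#' Write a site-annotation table
#'
#' @param sites A site tibble (see [read_site_table()] for the schema).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  sites <- validate_sites(sites)
  readr::write_tsv(sites[, c("transcript_id", "position", "label", "tissue")],
                   path, progress = FALSE)
  invisible(path)
}

validate_sites <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("transcript_id", "position", "label", "tissue")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("Site table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$position <- as.integer(df$position)
  bad_pos <- which(is.na(df$position) | df$position < 1L)
  if (length(bad_pos)) {
    stop("Site positions must be integers >= 1 (1-based); offending row(s): ",
         paste(utils::head(bad_pos, 5L), collapse = ", "), call. = FALSE)
  }
  bad_lab <- which(!df$label %in% c("positive", "negative"))
  if (length(bad_lab)) {
    stop("Unknown site label(s) (expected 'positive'/'negative') in row(s): ",
         paste(utils::head(bad_lab, 5L), collapse = ", "), call. = FALSE)
  }
  df
}

#' Extract a fixed-width sequence window around one candidate cytosine
#'
#' Returns the `2w + 1` bases centred on `position` (1-based, fully closed
#' transcript coordinates). Windows that run past either transcript end are
#' padded with `N`; `pad_count` records how many positions were padded. The
#' base at `position` must be `C` -- anything else signals a corrupt site
#' table and raises an error.
#'
#' @param transcript Either a single sequence string or a one-row transcript
#'   tibble.
#' @param position 1-based position of the candidate C.
#' @param w Flank size; the window spans `position - w` to `position + w`.
#'   Default 10 (a 21-nt window).
#' @return A one-row tibble with columns `position`, `window`, `pad_count`.
#' @examples
#' extract_window("AACGT", 3, w = 2)
#' @export
extract_window <- function(transcript, position, w = 10L) {
  seq <- if (is.data.frame(transcript)) transcript$sequence[[1]] else transcript
  out <- extract_window_chr(seq, position, w)
  tibble::tibble(position = as.integer(position),
                 window = out$window, pad_count = out$pad_count)
}

# scalar core shared by extract_window / extract_windows
extract_window_chr <- function(seq, position, w) {
  n <- nchar(seq)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > n) {
    stop("Position ", position, " out of range for transcript of length ", n,
         call. = FALSE)
  }
  centre <- substr(seq, position, position)
  if (centre != "C") {
    stop("Base at position ", position, " is '", centre,
         "', not C: not a candidate site", call. = FALSE)
  }
  lo <- position - w
  hi <- position + w
  left_pad <- max(0L, 1L - lo)
  right_pad <- max(0L, hi - n)
  core <- substr(seq, max(1L, lo), min(n, hi))
  list(
    window = paste0(strrep("N", left_pad), core, strrep("N", right_pad)),
    pad_count = left_pad + right_pad
  )
}

#' Extract windows for a table of sites
#'
#' Vectorised companion to [extract_window()]: joins sites to transcripts and
#' extracts one window per site, preserving row order.
#'
#' @param sites Site tibble with `transcript_id` and `position` columns
#'   (extra columns such as `label`/`tissue` are carried through).
#' @param transcripts Transcript tibble.
#' @param w Flank size (default 10).
#' @return `sites` with `window` and `pad_count` columns appended; the flank
#'   size is recorded in attribute `"w"`.
#' @export
extract_windows <- function(sites, transcripts, w = 10L) {
  sites <- tibble::as_tibble(sites)
  transcripts <- new_transcripts(transcripts)
  idx <- match(sites$transcript_id, transcripts$id)
  if (anyNA(idx)) {
    stop("Site(s) reference unknown transcript id(s): ",
         paste(unique(sites$transcript_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- transcripts$sequence[idx]
  ext <- purrr::map2(seqs, sites$position, extract_window_chr, w = w)
  sites$window <- purrr::map_chr(ext, "window")
  sites$pad_count <- purrr::map_int(ext, ~ as.integer(.x$pad_count))
  attr(sites, "w") <- as.integer(w)
  sites
}

#' Pick one representative transcript per gene
#'
#' When a gene has several transcripts, keeps the mRNA-biotype transcript
#' carrying the most modification sites, so that site density (data quality)
#' drives the choice. Ties break by longer sequence, then lexicographically
#' smaller id, so the selection is deterministic. If a gene has no
#' mRNA-biotype transcript, all biotypes are considered, with a warning.
#'
#' @param transcripts Transcript tibble with a `site_count` column (or supply
#'   `site_counts` separately).
#' @param site_counts Optional numeric vector parallel to `transcripts` rows.
#' @return A one-row-per-gene transcript tibble (rows with `gene_id = NA` are
#'   treated as singleton genes keyed by their own id).
#' @export
select_representative_transcript <- function(transcripts, site_counts = NULL) {
  transcripts <- new_transcripts(transcripts)
  if (!is.null(site_counts)) transcripts$site_count <- site_counts
  if (!"site_count" %in% names(transcripts)) {
    stop("select_representative_transcript() needs a site_count column ",
         "or the site_counts argument", call. = FALSE)
  }
  key <- ifelse(is.na(transcripts$gene_id), transcripts$id,
                transcripts$gene_id)
  pick_one <- function(df, gene) {
    mrna <- df[df$biotype == "mRNA", , drop = FALSE]
    if (nrow(mrna) == 0L) {
      warning("Gene '", gene,
              "' has no mRNA-biotype transcript; considering all biotypes",
              call. = FALSE)
      mrna <- df
    }
    ord <- order(-mrna$site_count, -nchar(mrna$sequence), mrna$id)
    mrna[ord[1L], , drop = FALSE]
  }
  picked <- purrr::imap(split(transcripts, key), pick_one)
  out <- dplyr::bind_rows(picked)
  out[order(match(out$id, transcripts$id)), , drop = FALSE]
}
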