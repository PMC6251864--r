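#' @name encoding-schemes
#' @title Sequence-window encodings
#'
#' @description
#' Two per-position encodings turn a `2w + 1` nucleotide window into a numeric
#' feature vector of length `(2w + 1) * 4`:
#'
#' * **one-hot**: each base becomes a 4-bit indicator in fixed column order
#'   A, G, C, T -- `A = (1,0,0,0)`, `G = (0,1,0,0)`, `C = (0,0,1,0)`,
#'   `T = (0,0,0,1)`. `N` (padding / ambiguity) encodes as `(0,0,0,0)`.
#' * **feng**: the first three bits are fixed physicochemical indicators
#'   (ring number, chemical functionality, hydrogen-bond count):
#'   `A = (1,1,1)`, `G = (1,0,0)`, `C = (0,1,0)`, `T = (0,0,1)`. The fourth
#'   bit is the accumulated occurrence frequency of that nucleotide among
#'   window positions `1..i`, reading 5' to 3'. `N` encodes as `(0,0,0,0)`
#'   and is excluded from the frequency denominators of later positions, so
#'   frequencies stay fractions of observed bases.
#'
#' Frequencies are accumulated over the extracted window only, not the full
#' transcript, which keeps encoding local to what a predictor actually sees;
#' `feng_encode(..., over = )` exposes the full-sequence alternative.
#'
#' Feature order is position-major: all four components of the leftmost
#' position, then the next, and so on; columns are named `p-10.A ... p+10.T`
#' for `w = 10`.
NULL

.onehot_rows <- rbind(
  A = c(1, 0, 0, 0), G = c(0, 1, 0, 0),
  C = c(0, 0, 1, 0), T = c(0, 0, 0, 1), N = c(0, 0, 0, 0)
)
.feng_triples <- rbind(
  A = c(1, 1, 1), G = c(1, 0, 0),
  C = c(0, 1, 0), T = c(0, 0, 1), N = c(0, 0, 0)
)

encoding_schemes <- c("one_hot", "feng")

split_window <- function(window) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  bad <- !chars %in% c("A", "C", "G", "T", "N")
  if (any(bad)) {
    stop("Window contains unexpected character(s): ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  }
  chars
}

#' One-hot encode a single window
#'
#' @param window A window string over `{A,C,G,T,N}`.
#' @return Named numeric vector of length `4 * nchar(window)`.
#' @examples
#' one_hot_encode("A")
#' one_hot_encode("NNCGT")
#' @export
one_hot_encode <- function(window) {
  chars <- split_window(window)
  v <- as.vector(t(.onehot_rows[chars, , drop = FALSE]))
  names(v) <- feature_names(flank_of(nchar(window)))
  v
}

#' Feng-style encode a single window
#'
#' @inheritParams one_hot_encode
#' @param over Sequence over which the accumulated frequency is computed.
#'   Defaults to the window itself; pass a longer sequence (with the window as
#'   prefix-consistent positions) to accumulate over the full input instead.
#' @return Named numeric vector of length `4 * nchar(window)`.
#' @examples
#' feng_encode("A")    # frequency of the first A is 1/1
#' feng_encode("AAC")  # third position: (0,1,0, 1/3)
#' @export
feng_encode <- function(window, over = window) {
  chars <- split_window(window)
  base_chars <- if (identical(over, window)) chars else split_window(over)
  n <- length(chars)
  out <- matrix(0, nrow = n, ncol = 4L)
  out[, 1:3] <- .feng_triples[chars, , drop = FALSE]
  seen <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  observed <- 0L
  for (i in seq_len(length(base_chars))) {
    b <- base_chars[i]
    if (b != "N") {
      seen[[b]] <- seen[[b]] + 1L
      observed <- observed + 1L
      if (i <= n) out[i, 4L] <- seen[[b]] / observed
    }
  }
  v <- as.vector(t(out))
  names(v) <- feature_names(flank_of(n))
  v
}

flank_of <- function(len) {
  stopifnot(len >= 1L)
  (len - 1L) / 2L
}

# stable column names, position-major: p-10.A p-10.G p-10.C p-10.T ... p+10.T
feature_names <- function(w) {
  if (w != floor(w)) {
    # even-length test-harness windows get plain positional names
    len <- as.integer(2 * w + 1)
    pos <- paste0("p", seq_len(len))
  } else {
    off <- seq.int(-w, w)
    pos <- paste0("p", ifelse(off > 0, "+", ""), off)
  }
  as.vector(t(outer(pos, c("A", "G", "C", "T"), paste, sep = ".")))
}

#' Encode a batch of windows into a feature matrix
#'
#' @param windows Either a character vector of window strings or a tibble with
#'   a `window` column (as produced by [extract_windows()]).
#' @param scheme `"one_hot"` (default) or `"feng"`.
#' @return A numeric matrix, one row per window in input order, with stable
#'   position-major column names. An empty input yields a 0-row matrix whose
#'   width is `(2w + 1) * 4` when `w` can be inferred (attribute or `w`
#'   argument), else 0.
#' @param w Flank size used only to shape the empty-input case; inferred from
#'   the `windows` attribute or the strings themselves otherwise.
#' @export
encode_windows <- function(windows, scheme = c("one_hot", "feng"), w = NULL) {
  scheme <- match.arg(scheme)
  if (is.data.frame(windows)) {
    if (is.null(w)) w <- attr(windows, "w")
    windows <- windows$window
  }
  if (length(windows) == 0L) {
    ncols <- if (is.null(w)) 0L else (2L * as.integer(w) + 1L) * 4L
    m <- matrix(numeric(0), nrow = 0L, ncol = ncols)
    if (ncols > 0L) colnames(m) <- feature_names(as.integer(w))
    return(m)
  }
  lens <- nchar(windows)
  if (length(unique(lens)) != 1L) {
    stop("All windows in a batch must share the same width; got widths ",
         paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
  }
  enc <- switch(scheme, one_hot = one_hot_encode, feng = feng_encode)
  m <- do.call(rbind, lapply(windows, enc))
  rownames(m) <- NULL
  m
}

#' Export a feature matrix as headered TSV
#'
#' @param features Matrix from [encode_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  df <- tibble::as_tibble(features, .name_repair = "minimal")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Decode a one-hot feature matrix back to window strings
#'
#' Inverse of `encode_windows(scheme = "one_hot")`; used mainly for
#' round-trip checking.
#'
#' @param features One-hot numeric matrix.
#' @return Character vector of windows.
#' @export
one_hot_decode <- function(features) {
  stopifnot(ncol(features) %% 4L == 0L)
  npos <- ncol(features) / 4L
  apply(features, 1L, function(row) {
    paste(vapply(seq_len(npos), function(i) {
      quad <- row[(4L * (i - 1L) + 1L):(4L * i)]
      if (all(quad == 0)) "N" else c("A", "G", "C", "T")[which(quad == 1)]
    }, character(1)), collapse = "")
  })
}
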