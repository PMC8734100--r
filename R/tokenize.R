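#' Word vocabulary over the DNA alphabet
#'
#' Words of length `|w|` over `{A,C,G,T}` are mapped bijectively to integer
#' ids in `[0, 4^|w|)` by base-4 positional encoding (A=0, C=1, G=2, T=3,
#' most-significant base first).
#'
#' @param word_length word length `|w|` in `[1, 8]`.
#' @return an object of class `vocabulary` with fields `word_length`, `size`.
#' @export
vocabulary <- function(word_length = 4L) {
  structure(list(word_length = as.integer(word_length),
                 size = vocab_size(word_length)),
            class = "vocabulary")
}

#' Vocabulary size for a word length
#'
#' @param w word length in `[1, 8]`.
#' @return `4^w`.
#' @export
vocab_size <- function(w) {
  if (!is.numeric(w) || length(w) != 1L || w != round(w) || w < 1 || w > 8)
    stop("word length must be an integer in [1, 8]")
  as.integer(4^w)
}

#' Encode words as integer ids
#' @param words character vector of equal-length words over `{A,C,G,T}`.
#' @param vocab a [vocabulary].
#' @return integer ids in `[0, size)`.
#' @export
encode_words <- function(words, vocab) {
  w <- vocab$word_length
  if (any(nchar(words) != w)) stop("all words must have length ", w)
  ids <- cpp_encode_chunks(words, w, 1L)
  vapply(ids, function(x) x[1L], integer(1))
}

#' Decode integer ids back to words
#' @param ids integer ids in `[0, size)`.
#' @param vocab a [vocabulary].
#' @return character vector of words.
#' @export
decode_ids <- function(ids, vocab) {
  w <- vocab$word_length
  if (any(ids < 0 | ids >= vocab$size)) stop("id out of range")
  bases <- c("A", "C", "G", "T")
  vapply(ids, function(v) {
    out <- character(w)
    for (j in w:1) { out[j] <- bases[v %% 4 + 1]; v <- v %/% 4 }
    paste0(out, collapse = "")
  }, character(1))
}

#' Cut reads into fixed-length overlapping chunks
#'
#' Chunks start at offsets `0, chunk_stride, 2*chunk_stride, ...` within each
#' read; a final window shorter than `chunk_len` is trimmed.  Reads shorter
#' than `chunk_len` yield the whole read as a single chunk (short-read
#' libraries would otherwise produce nothing).  Chunks containing `N` are
#' dropped: an ambiguous base carries no learnable signal.
#'
#' @param rs a [read_set].
#' @param chunk_len chunk length in bases (default 100).
#' @param chunk_stride sliding-window step in bases (default 50).
#' @return data frame with columns `read` (1-based read index), `offset`
#'   (0-based start within the read), `chunk` (the substring).
#' @export
chunk_reads <- function(rs, chunk_len = 100L, chunk_stride = 50L) {
  stopifnot(inherits(rs, "read_set"))
  chunk_len <- as.integer(chunk_len); chunk_stride <- as.integer(chunk_stride)
  if (chunk_len < 1L) stop("chunk_len must be >= 1")
  if (chunk_stride < 1L || chunk_stride > chunk_len)
    stop("chunk_stride must be in [1, chunk_len]")
  lens <- nchar(rs$seq)
  n_per <- ifelse(lens < chunk_len, 1L, (lens - chunk_len) %/% chunk_stride + 1L)
  read_idx <- rep.int(seq_along(lens), n_per)
  offset <- unlist(lapply(seq_along(lens), function(i) {
    if (lens[i] < chunk_len) 0L
    else seq.int(0L, by = chunk_stride, length.out = n_per[i])
  }), use.names = FALSE)
  if (!length(read_idx))
    return(data.frame(read = integer(), offset = integer(),
                      chunk = character(), stringsAsFactors = FALSE))
  end <- pmin(offset + chunk_len, lens[read_idx])
  chunk <- substring(rs$seq[read_idx], offset + 1L, end)
  keep <- !grepl("N", chunk, fixed = TRUE)
  data.frame(read = read_idx[keep], offset = offset[keep],
             chunk = chunk[keep], stringsAsFactors = FALSE)
}

#' Overlapping words of a chunk
#'
#' Slides a window of length `w` with step `word_stride` across the chunk:
#' `"AATCGGCGCT"` with `w = 4`, stride 1 gives
#' `AATC ATCG TCGG CGGC GGCG GCGC CGCT`.
#'
#' @param chunk a string over `{A,C,G,T}`.
#' @param w word length.
#' @param word_stride step between successive words (default 1).
#' @return character vector of `floor((nchar - w)/word_stride) + 1` words;
#'   empty when the chunk is shorter than `w`.
#' @export
words_from_chunk <- function(chunk, w, word_stride = 1L) {
  stopifnot(is.character(chunk), length(chunk) == 1L)
  L <- nchar(chunk)
  if (L < w) return(character())
  starts <- seq.int(1L, L - w + 1L, by = word_stride)
  substring(chunk, starts, starts + w - 1L)
}

#' Chunk, tokenize and integer-encode a read set
#'
#' Each chunk becomes one independent token sequence; sequences are never
#' concatenated across chunks or reads, so no window ever crosses a read
#' boundary.
#'
#' @inheritParams chunk_reads
#' @param w word length `|w|` (default 4).
#' @param word_stride step between words inside a chunk (default 1).
#' @return an object of class `token_corpus`: fields `vocab`, `sequences`
#'   (list of 0-based integer id vectors), `provenance` (data frame mapping
#'   chunk to read index and offset), tokenizer parameters, `n_tokens`.
#' @export
encode_corpus <- function(rs, w = 4L, chunk_len = 100L, chunk_stride = 50L,
                          word_stride = 1L) {
  if (w > chunk_len) stop("word length exceeds chunk_len")
  vocab <- vocabulary(w)
  ch <- chunk_reads(rs, chunk_len, chunk_stride)
  keep <- nchar(ch$chunk) >= w
  ch <- ch[keep, , drop = FALSE]
  sequences <- if (nrow(ch)) cpp_encode_chunks(ch$chunk, as.integer(w),
                                               as.integer(word_stride))
               else list()
  structure(list(vocab = vocab, sequences = sequences,
                 provenance = ch[, c("read", "offset")],
                 chunk_len = as.integer(chunk_len),
                 chunk_stride = as.integer(chunk_stride),
                 word_stride = as.integer(word_stride),
                 n_tokens = sum(lengths(sequences))),
            class = "token_corpus")
}

#' @export
print.token_corpus <- function(x, ...) {
  cat(sprintf(paste0("token_corpus: %d chunk(s), %d tokens, |w|=%d ",
                     "(|V|=%d), chunk %d/stride %d\n"),
              length(x$sequences), x$n_tokens, x$vocab$word_length,
              x$vocab$size, x$chunk_len, x$chunk_stride))
  invisible(x)
}

#' Build a token corpus directly from integer id sequences
#'
#' Mainly for calibration studies (e.g. i.i.d. uniform token streams, whose
#' perplexity floor is the vocabulary size) and unit tests.
#'
#' @param sequences list of integer vectors with ids in `[0, 4^w)`.
#' @param w word length defining the vocabulary.
#' @return a `token_corpus`.
#' @export
token_corpus_from_ids <- function(sequences, w = 4L) {
  vocab <- vocabulary(w)
  stopifnot(all(vapply(sequences, function(s)
    all(s >= 0 & s < vocab$size), logical(1))))
  sequences <- lapply(sequences, as.integer)
  structure(list(vocab = vocab, sequences = sequences,
                 provenance = data.frame(read = seq_along(sequences),
                                         offset = 0L),
                 chunk_len = NA_integer_, chunk_stride = NA_integer_,
                 word_stride = 1L,
                 n_tokens = sum(lengths(sequences))),
            class = "token_corpus")
}

#' Dump a token corpus as plain text
#'
#' One chunk per line, space-separated words.
#' @param corpus a `token_corpus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tokens <- function(corpus, path) {
  lines <- vapply(corpus$sequences, function(ids)
    paste(decode_ids(ids, corpus$vocab), collapse = " "), character(1))
  writeLines(lines, path)
  invisible(path)
}
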