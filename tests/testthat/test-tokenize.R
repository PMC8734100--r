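test_that("vocabulary size follows 4^w and encoding is a bijection", {
  expect_identical(vocab_size(1), 4L)
  expect_identical(vocab_size(4), 256L)
  expect_identical(vocab_size(5), 1024L)
  expect_error(vocab_size(0), "\\[1, 8\\]")
  expect_error(vocab_size(9), "\\[1, 8\\]")

  v <- vocabulary(3)
  words <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 3)), 1, paste,
                 collapse = "")
  ids <- encode_words(words, v)
  expect_setequal(ids, 0:63)
  expect_equal(decode_ids(ids, v), unname(words))
  expect_equal(encode_words("AAA", v), 0L)
  expect_equal(encode_words("TTT", v), 63L)
  expect_equal(encode_words("ACG", v), 0L * 16 + 1L * 4 + 2L)
})

test_that("chunk windows follow the stride arithmetic and trim residue", {
  mk <- function(len) read_set("r", strrep("A", len))
  ch <- chunk_reads(mk(250), 100, 50)
  expect_equal(ch$offset, c(0, 50, 100, 150))
  expect_equal(nchar(ch$chunk), rep(100L, 4))

  ch <- chunk_reads(mk(230), 100, 50)
  expect_equal(ch$offset, c(0, 50, 100))  # bases 200-229 trimmed

  ch <- chunk_reads(mk(60), 100, 50)     # short read: whole-read chunk
  expect_equal(nrow(ch), 1L)
  expect_equal(nchar(ch$chunk), 60L)
})

test_that("chunks containing N are dropped", {
  rs <- read_set(c("a", "b"),
                 c(paste0(strrep("A", 40), "N", strrep("C", 120)),
                   strrep("G", 150)))
  ch <- chunk_reads(rs, 100, 50)
  # read a: offsets 0 and 50 both cover the N at position 41 -> dropped
  expect_true(all(ch$read == 2L | ch$offset > 41))
  expect_false(any(grepl("N", ch$chunk)))
})

test_that("overlapping words reproduce the worked stride-1 example", {
  expect_equal(words_from_chunk("AATCGGCGCT", 4, 1),
               c("AATC", "ATCG", "TCGG", "CGGC", "GGCG", "GCGC", "CGCT"))
  expect_equal(words_from_chunk("ACGT", 1, 1), c("A", "C", "G", "T"))
  expect_equal(words_from_chunk("ACGT", 4, 1), "ACGT")
  expect_equal(words_from_chunk("ACG", 4, 1), character())
})

test_that("word count law and chunk reconstruction hold", {
  set.seed(33)
  for (rep_i in 1:20) {
    len <- sample(5:60, 1)
    w <- sample(1:4, 1)
    stride <- sample(1:3, 1)
    chunk <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
    words <- words_from_chunk(chunk, w, stride)
    if (len < w) {
      expect_length(words, 0)
      next
    }
    expect_length(words, (len - w) %/% stride + 1)
    if (stride == 1) {
      rebuilt <- paste0(paste(substr(words, 1, 1), collapse = ""),
                        substr(words[length(words)], 2, w))
      expect_equal(rebuilt, chunk)
    }
  }
})

test_that("encode_corpus keeps chunks independent and traceable", {
  rs <- read_set("r1", "AATCGGCGCT")
  corp <- encode_corpus(rs, w = 4, chunk_len = 100, chunk_stride = 50)
  expect_length(corp$sequences, 1)
  expect_length(corp$sequences[[1]], 7)
  expect_equal(decode_ids(corp$sequences[[1]], corp$vocab),
               c("AATC", "ATCG", "TCGG", "CGGC", "GGCG", "GCGC", "CGCT"))

  # permuting reads permutes chunks but changes no chunk's token content
  rs2 <- random_read_set(10, len = 120, seed = 44)
  c1 <- encode_corpus(rs2, w = 3)
  perm <- c(4, 1, 10, 2, 9, 3, 8, 5, 7, 6)
  rs3 <- read_set(rs2$id[perm], rs2$seq[perm])
  c2 <- encode_corpus(rs3, w = 3)
  key <- function(cc) sort(vapply(cc$sequences, paste, "", collapse = ","))
  expect_equal(key(c1), key(c2))

  # provenance maps every chunk back to the exact substring
  for (i in seq_along(c1$sequences)) {
    read <- c1$provenance$read[i]
    off <- c1$provenance$offset[i]
    words <- decode_ids(c1$sequences[[i]], c1$vocab)
    rebuilt <- paste0(paste(substr(words, 1, 1), collapse = ""),
                      substr(words[length(words)], 2, 3))
    expect_equal(rebuilt, substr(rs2$seq[read], off + 1, off + nchar(rebuilt)))
  }
  # an all-A corpus uses a single token id
  allA <- encode_corpus(read_set("a", strrep("A", 30)), w = 4)
  expect_equal(unique(unlist(allA$sequences)), 0L)
  expect_error(encode_corpus(rs, w = 5, chunk_len = 4), "exceeds")
})

test_that("stride-1 word conditionals carry character-level information", {
  # P(next word | prev word) under a word bigram equals P(next char | last
  # w chars) under a character model with w-length context, on one corpus
  set.seed(55)
  txt <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                      prob = c(.4, .3, .2, .1)), collapse = "")
  rs <- read_set("t", txt)
  w <- 3L
  word_corp <- encode_corpus(rs, w = w, chunk_len = 400, chunk_stride = 400)
  char_corp <- encode_corpus(rs, w = 1, chunk_len = 400, chunk_stride = 400)
  word_lm <- train_ngram(word_corp, n = 1, lambda = 0)
  char_lm <- train_ngram(char_corp, n = w, lambda = 0)
  vw <- vocabulary(w); v1 <- vocabulary(1)
  seen <- words_from_chunk(txt, w)
  for (ctx_word in unique(seen[c(1, 50, 100)])) {
    ctx_id <- encode_words(ctx_word, vw)
    for (nxt in c("A", "C", "G", "T")) {
      nxt_word <- paste0(substr(ctx_word, 2, w), nxt)
      p_word <- kanneal:::.ngram_prob(word_lm, ctx_id,
                                      encode_words(nxt_word, vw))
      p_char <- kanneal:::.ngram_prob(char_lm,
                                      encode_words(strsplit(ctx_word,
                                                            "")[[1]], v1),
                                      encode_words(nxt, v1))
      expect_equal(p_word, p_char, tolerance = 1e-12)
    }
  }
})
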