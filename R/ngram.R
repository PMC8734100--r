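#' Train a count-based N-gram language model
#'
#' The chain probability of a token sequence is approximated by
#' `prod_i P(W_i | W_{i-1}, ..., W_{i-n})`.  Conditionals are additive
#' (add-lambda) smoothed counts,
#' `P(tok | ctx) = (c(ctx, tok) + lambda) / (c(ctx) + lambda * |V|)`.
#' A context never seen at order `n` backs off to order `n-1`, recursively
#' down to the unigram; positions near a chunk start use the longest
#' available context.  Counts never cross chunk boundaries.
#'
#' @param corpus a `token_corpus`.
#' @param n context length (order), `>= 1`.
#' @param lambda additive smoothing constant (default 1, add-one);
#'   `lambda = 0` gives maximum-likelihood estimates (probability zero, and
#'   infinite perplexity, for unseen continuations of seen contexts).
#' @return a `language_model` of kind `"ngram"`.
#' @export
train_ngram <- function(corpus, n, lambda = 1) {
  stopifnot(inherits(corpus, "token_corpus"), n >= 1, lambda >= 0)
  n <- as.integer(n)
  tables <- vector("list", n + 1L)
  # order j table: counts of (ctx = j previous tokens, tok)
  for (j in 0:n) {
    rows <- lapply(corpus$sequences, function(s) {
      m <- length(s)
      if (m < j + 1L) return(NULL)
      i <- seq.int(j + 1L, m)
      ctx <- if (j == 0L) rep("@", length(i))  # sentinel for empty context
             else vapply(i, function(p)
               paste(s[(p - j):(p - 1L)], collapse = ","), character(1))
      data.table::data.table(ctx = ctx, tok = s[i])
    })
    rows <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
    if (!length(rows) || !nrow(rows)) {
      tables[[j + 1L]] <- list(counts = new.env(parent = emptyenv()),
                               totals = new.env(parent = emptyenv()))
      next
    }
    counts <- rows[, list(N = .N), by = c("ctx", "tok")]
    totals <- counts[, list(Nc = sum(N)), by = "ctx"]
    # environments give O(1) lookups without any non-standard evaluation
    tables[[j + 1L]] <- list(
      counts = list2env(setNames(as.list(counts$N),
                                 paste(counts$ctx, counts$tok, sep = "|")),
                        parent = emptyenv()),
      totals = list2env(setNames(as.list(totals$Nc), totals$ctx),
                        parent = emptyenv()))
  }
  structure(list(kind = "ngram", vocab = corpus$vocab, order = n,
                 lambda = lambda, tables = tables,
                 corpus_digest = .corpus_digest(corpus)),
            class = "language_model")
}

# probability of `tok` after `ctx_tokens` (integer vector, may be shorter
# than the model order); applies the back-off rule
.ngram_prob <- function(lm, ctx_tokens, tok) {
  V <- lm$vocab$size
  lam <- lm$lambda
  j <- min(length(ctx_tokens), lm$order)
  repeat {
    key <- if (j == 0L) "@" else paste(tail(ctx_tokens, j), collapse = ",")
    tt <- lm$tables[[j + 1L]]
    tot <- tt$totals[[key]]
    if (!is.null(tot) || j == 0L) {
      if (is.null(tot)) tot <- 0L
      cnt <- tt$counts[[paste(key, tok, sep = "|")]]
      if (is.null(cnt)) cnt <- 0L
      return((cnt + lam) / (tot + lam * V))
    }
    j <- j - 1L
  }
}

# per-position log-probabilities (nats) for one token sequence
.ngram_seq_nats <- function(lm, s) {
  m <- length(s)
  if (!m) return(numeric())
  vapply(seq_len(m), function(i) {
    ctx <- if (i == 1L) integer() else s[max(1L, i - lm$order):(i - 1L)]
    p <- .ngram_prob(lm, ctx, s[i])
    -log(p)
  }, numeric(1))
}
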