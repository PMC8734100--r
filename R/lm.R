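#' Sinusoidal positional encoding
#'
#' Element `2i` is `sin(pos / 10000^(2i/d_model))` and element `2i+1` is
#' `cos(pos / 10000^(2i/d_model))` (dimension indices 0-based).
#'
#' @param pos position index, `>= 0`.
#' @param d_model embedding dimension (even).
#' @return numeric vector of length `d_model`, all elements in `[-1, 1]`.
#' @export
positional_encoding <- function(pos, d_model) {
  stopifnot(pos >= 0, d_model %% 2 == 0)
  i <- seq.int(0L, d_model / 2 - 1L)
  freq <- 10000^(2 * i / d_model)
  out <- numeric(d_model)
  out[2 * i + 1] <- sin(pos / freq)
  out[2 * i + 2] <- cos(pos / freq)
  out
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, softmax row-wise.  No causal mask is
#' applied anywhere in this package: every query attends to every key, so
#' the representation of a position encodes both its left and right context.
#'
#' @param Q,K,V numeric matrices; `Q` and `K` share the inner dimension
#'   `d_k`, `K` and `V` have the same number of rows.
#' @return matrix with `nrow(Q)` rows and `ncol(V)` columns.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must share the inner dimension d_k")
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows")
  S <- Q %*% t(K) / sqrt(ncol(K))
  P <- exp(S - apply(S, 1L, max))
  P <- P / rowSums(P)
  P %*% V
}

#' Multi-head attention
#'
#' Each head applies [scaled_dot_attention] to its own projections of
#' `Q`, `K`, `V`; the head outputs are concatenated and projected by `W_O`.
#'
#' @param Q,K,V numeric matrices with `d_model` columns.
#' @param h head count; `d_model` must be divisible by `h`.
#' @param Wq,Wk,Wv lists of `h` projection matrices (`d_model x d_k` each);
#'   `NULL` means identity slices (each head reads its own column block).
#' @param Wo output projection (`d_model x d_model`); `NULL` means identity.
#' @return matrix with `nrow(Q)` rows and `d_model` columns.
#' @export
multi_head_attention <- function(Q, K, V, h, Wq = NULL, Wk = NULL, Wv = NULL,
                                 Wo = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  d <- ncol(Q)
  if (d %% h != 0) stop("d_model must be divisible by the head count")
  dk <- d %/% h
  slice <- function(M, i, W) {
    if (is.null(W)) M[, ((i - 1) * dk + 1):(i * dk), drop = FALSE]
    else M %*% W[[i]]
  }
  heads <- lapply(seq_len(h), function(i)
    scaled_dot_attention(slice(Q, i, Wq), slice(K, i, Wk), slice(V, i, Wv)))
  out <- do.call(cbind, heads)
  if (!is.null(Wo)) out <- out %*% Wo
  out
}

#' Transformer configuration
#'
#' Defaults follow the reference architecture for this task: vocabulary and
#' token count `4^|w|`, embedding size `4^|w|` for `|w| < 4` and 128
#' otherwise, 4 encoder layers, context window (`bptt`) of 99 tokens, and
#' training batches at least as large as evaluation batches (large training
#' batches average the noise of erroneous reads out, small evaluation
#' batches expose rare sequences).
#'
#' Training replaces the tokens of contiguous spans (`mask_span` tokens, one
#' span per block of `mask_span * mask_phases` positions) by a reserved
#' placeholder and predicts them from the full unmasked window; with
#' stride-1 words an isolated masked token would be exactly recoverable
#' from its overlapping neighbours, so spans of `|w|` tokens (the
#' default) are used: each span hides exactly one base, and predicting
#' it amounts to learning the local k-mer statistics that separate solid
#' from insolid content.  Longer spans hide more bases but push the task
#' toward whole-genome memorization, which trains far more slowly.
#'
#' @param word_length word length `|w|` (default 4).
#' @param n_layers encoder layers (default 4).
#' @param n_heads attention heads (default 4; divides both 128 and 256).
#' @param d_model embedding dimension; default `4^|w|` if `|w| < 4` else 128.
#' @param d_ff feed-forward inner dimension (default `2 * d_model`).
#' @param bptt context window in tokens (default 99); longer token
#'   sequences are split into non-overlapping `bptt` windows.
#' @param epochs,learning_rate,train_batch,eval_batch,clip optimizer
#'   settings (Adam, gradient-norm clipping).
#' @param mask_span,mask_phases masked-span geometry (see Details).
#' @param seed integer seed governing weight init, shuffling and phases.
#' @return an object of class `transformer_config`.
#' @export
transformer_config <- function(word_length = 4L, n_layers = 4L, n_heads = 4L,
                               d_model = NULL, d_ff = NULL, bptt = 99L,
                               epochs = 5L, learning_rate = 1e-3,
                               train_batch = 64L, eval_batch = 16L,
                               clip = 1.0, mask_span = NULL, mask_phases = 4L,
                               seed = 1L) {
  n_tokens <- vocab_size(word_length)
  if (is.null(d_model)) d_model <- if (word_length < 4) n_tokens else 128L
  if (is.null(d_ff)) d_ff <- 2L * d_model
  if (is.null(mask_span)) mask_span <- as.integer(word_length)
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  if (d_model %% 2 != 0) stop("d_model must be even (sinusoidal encoding)")
  if (train_batch < eval_batch)
    stop("train_batch must be >= eval_batch")
  if (bptt < 1) stop("bptt must be >= 1")
  structure(list(word_length = as.integer(word_length),
                 n_tokens = as.integer(n_tokens),
                 d_model = as.integer(d_model), d_ff = as.integer(d_ff),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), bptt = as.integer(bptt),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 train_batch = as.integer(train_batch),
                 eval_batch = as.integer(eval_batch), clip = clip,
                 mask_span = as.integer(mask_span),
                 mask_phases = as.integer(mask_phases),
                 seed = as.integer(seed)),
            class = "transformer_config")
}

.init_params <- function(cfg) {
  gl <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -lim, lim), nin, nout)
  }
  d <- cfg$d_model; V <- cfg$n_tokens; dff <- cfg$d_ff
  layers <- lapply(seq_len(cfg$n_layers), function(i) list(
    Wq = gl(d, d), Wk = gl(d, d), Wv = gl(d, d), Wo = gl(d, d),
    W1 = gl(d, dff), W2 = gl(dff, d),
    g1 = rep(1, d), b1 = rep(0, d), g2 = rep(1, d), b2 = rep(0, d),
    bf1 = rep(0, dff), bf2 = rep(0, d)))
  # unit-variance embeddings: after the sqrt(d) scale they dominate the
  # O(1) positional encodings, so token identity, not position, carries
  # the early training signal
  list(Emb = matrix(rnorm((V + 1) * d, sd = 1), V + 1, d),
       Wout = matrix(rnorm(d * V, sd = 0.02), d, V),
       bout = rep(0, V), gF = rep(1, d), bF = rep(0, d), layers = layers)
}

# split token sequences into bptt windows; returns list(sequences, map)
# where map[i] is the source chunk of window i
.split_bptt <- function(sequences, bptt) {
  map <- integer(0); out <- list()
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    if (length(s) <= bptt) {
      out[[length(out) + 1L]] <- s
      map <- c(map, i)
    } else {
      starts <- seq.int(1L, length(s), by = bptt)
      for (st in starts) {
        piece <- s[st:min(st + bptt - 1L, length(s))]
        out[[length(out) + 1L]] <- piece
        map <- c(map, i)
      }
    }
  }
  list(sequences = out, map = map)
}

#' Train the non-directional transformer language model
#'
#' @param corpus a `token_corpus` from [encode_corpus].
#' @param config a [transformer_config]; its vocabulary must match the
#'   corpus.
#' @param verbose print per-epoch mean training loss.
#' @return a `language_model` (kind `"transformer"`) carrying the trained
#'   parameters, config, per-epoch losses and a corpus digest.
#' @export
train_transformer <- function(corpus, config = transformer_config(),
                              verbose = FALSE) {
  stopifnot(inherits(corpus, "token_corpus"),
            inherits(config, "transformer_config"))
  if (corpus$vocab$size != config$n_tokens)
    stop("corpus vocabulary (", corpus$vocab$size,
         ") does not match config n_tokens (", config$n_tokens, ")")
  if (!length(corpus$sequences)) stop("empty corpus: nothing to train on")
  sp <- .split_bptt(corpus$sequences, config$bptt)
  n <- length(sp$sequences)
  set.seed(config$seed)
  params <- .init_params(config)
  block <- config$mask_span * config$mask_phases
  phases <- matrix(sample.int(block, n * config$epochs, replace = TRUE) - 1L,
                   n, config$epochs)
  order <- vapply(seq_len(config$epochs), function(e) sample.int(n) - 1L,
                  integer(n))
  order <- matrix(order, n, config$epochs)
  fit <- cpp_transformer_train(sp$sequences, params, unclass(config),
                               config$epochs, config$learning_rate,
                               config$train_batch, config$clip,
                               phases, order)
  if (verbose)
    for (e in seq_len(config$epochs))
      message(sprintf("epoch %d: mean loss %.4f nats/token",
                      e, fit$epoch_loss[e]))
  structure(list(kind = "transformer", vocab = corpus$vocab,
                 config = config, params = fit$params,
                 epoch_loss = as.numeric(fit$epoch_loss),
                 corpus_digest = .corpus_digest(corpus)),
            class = "language_model")
}

.corpus_digest <- function(corpus) {
  sprintf("chunks=%d;tokens=%d;w=%d", length(corpus$sequences),
          corpus$n_tokens, corpus$vocab$word_length)
}

#' @export
print.language_model <- function(x, ...) {
  cat(sprintf("language_model (%s): |w|=%d, |V|=%d\n", x$kind,
              x$vocab$word_length, x$vocab$size))
  if (x$kind == "transformer")
    cat(sprintf("  d_model=%d, layers=%d, heads=%d, final loss %.4f\n",
                x$config$d_model, x$config$n_layers, x$config$n_heads,
                tail(x$epoch_loss, 1)))
  if (x$kind == "ngram")
    cat(sprintf("  order n=%d, lambda=%g\n", x$order, x$lambda))
  invisible(x)
}

#' Predictive distribution at masked positions
#'
#' Masks the given positions of one token sequence (their inputs become the
#' reserved placeholder) and returns the model's predictive distribution
#' over the vocabulary at each.  Each row sums to 1.
#'
#' @param lm a transformer `language_model`.
#' @param ids integer token ids (0-based).
#' @param masked 1-based positions to mask and predict.
#' @return matrix `length(masked) x |V|` of probabilities.
#' @export
predict_masked <- function(lm, ids, masked) {
  stopifnot(inherits(lm, "language_model"), lm$kind == "transformer")
  cpp_transformer_probs(as.integer(ids), lm$params, unclass(lm$config),
                        as.integer(masked) - 1L)
}

#' Save / load a language model checkpoint
#'
#' The checkpoint is a single-file container holding parameters, config and
#' vocabulary; reloading is bit-stable.
#' @param lm a `language_model`.
#' @param path checkpoint path.
#' @return `path` invisibly ([save_model]); the model ([load_model]).
#' @export
save_model <- function(lm, path) {
  stopifnot(inherits(lm, "language_model"))
  saveRDS(lm, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  lm <- readRDS(path)
  if (!inherits(lm, "language_model")) stop("not a language model checkpoint")
  lm
}

# Pure-R forward pass of the trained transformer, used as an independent
# cross-check of the compiled scoring path (built from positional_encoding,
# multi_head_attention and plain matrix algebra).
.r_transformer_probs <- function(params, cfg, ids, masked) {
  d <- cfg$d_model; h <- cfg$n_heads; V <- cfg$n_tokens
  T <- length(ids)
  input <- ids
  input[masked] <- V  # 0-based placeholder id
  X <- t(vapply(seq_len(T), function(t)
    params$Emb[input[t] + 1L, ] * sqrt(d) + positional_encoding(t - 1L, d),
    numeric(d)))
  ln <- function(M, g, b) {
    t(apply(M, 1L, function(x) {
      mu <- mean(x); v <- mean((x - mu)^2)
      ((x - mu) / sqrt(v + 1e-5)) * g + b
    }))
  }
  for (L in params$layers) {
    Y1 <- ln(X, L$g1, L$b1)
    Q <- Y1 %*% L$Wq; K <- Y1 %*% L$Wk; Vv <- Y1 %*% L$Wv
    X <- X + multi_head_attention(Q, K, Vv, h) %*% L$Wo
    Y2 <- ln(X, L$g2, L$b2)
    H <- pmax(Y2 %*% L$W1 + matrix(L$bf1, T, cfg$d_ff, byrow = TRUE), 0)
    X <- X + H %*% L$W2 + matrix(L$bf2, T, d, byrow = TRUE)
  }
  X <- ln(X, params$gF, params$bF)
  logits <- X[masked, , drop = FALSE] %*% params$Wout +
    matrix(params$bout, length(masked), V, byrow = TRUE)
  P <- exp(logits - apply(logits, 1L, max))
  P / rowSums(P)
}

# note: multi_head_attention with NULL projections slices column blocks,
# matching the compiled implementation's per-head layout exactly.
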