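test_that("cross-entropy and KL divergence match direct evaluation", {
  u4 <- rep(0.25, 4)
  expect_equal(cross_entropy(u4, u4), 2)  # log2 4 bits
  onehot <- c(1, 0, 0, 0)
  expect_equal(cross_entropy(onehot, onehot), 0)
  p <- c(0.5, 0.5); q <- c(0.25, 0.75)
  ce <- -0.5 * log2(0.25) - 0.5 * log2(0.75)
  expect_equal(cross_entropy(p, q), ce, tolerance = 1e-12)
  expect_equal(kl_divergence(p, q), ce - 1, tolerance = 1e-12)
  expect_equal(kl_divergence(q, q), 0)
  expect_identical(cross_entropy(onehot, c(0, 1, 0, 0)), Inf)

  # H(P,Q) = H(P) + D(P||Q); D >= 0 on random distribution pairs
  set.seed(21)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    p <- runif(n); p <- p / sum(p)
    q <- runif(n); q <- q / sum(q)
    d <- kl_divergence(p, q)
    expect_gte(d, 0)
    expect_equal(cross_entropy(p, q), cross_entropy(p, p) + d,
                 tolerance = 1e-9)
  }
  expect_error(cross_entropy(c(0.5, 0.4), q), "sum to 1")
})

test_that("perplexity hits its analytic limits", {
  # a uniform model (untrained smoothed N-gram) scores any corpus at |V|
  corp <- token_corpus_from_ids(list(sample(0:255, 50, replace = TRUE)),
                                w = 4)
  empty <- token_corpus_from_ids(list(0L), w = 4)
  uniform <- train_ngram(empty, n = 1, lambda = 1e9)
  rep <- corpus_perplexity(uniform, corp, eval_batch = 4)
  expect_equal(rep$mean_ppl, 256, tolerance = 1e-6)
  # a perfect predictor scores a deterministic corpus at 1 (a constant
  # token: even the context-free marginal is then a point mass)
  det <- token_corpus_from_ids(list(rep(7L, 40)), w = 4)
  perfect <- train_ngram(det, n = 1, lambda = 0)
  expect_equal(corpus_perplexity(perfect, det, 4)$mean_ppl, 1,
               tolerance = 1e-12)
})

test_that("N-gram corpus perplexity equals the inverse-probability form", {
  # 10-token corpus, order 2: brute-force product of conditionals
  s <- c(0L, 1L, 2L, 0L, 1L, 3L, 0L, 1L, 2L, 3L)
  corp <- token_corpus_from_ids(list(s), w = 1)
  lam <- 1
  m <- train_ngram(corp, n = 2, lambda = lam)
  # hand model: counts over the single sequence
  count_ctx <- function(ctx) {
    n <- length(ctx); tot <- 0L
    for (i in seq_len(10 - n))
      if (all(s[i:(i + n - 1)] == ctx)) tot <- tot + 1L
    tot
  }
  count_ctx_tok <- function(ctx, tok) {
    n <- length(ctx); hits <- 0L
    for (i in seq_len(10 - n))
      if (all(s[i:(i + n - 1)] == ctx) && s[i + n] == tok) hits <- hits + 1L
    hits
  }
  probs <- numeric(10)
  for (i in 1:10) {
    ctx <- if (i == 1) integer() else s[max(1, i - 2):(i - 1)]
    # back-off: drop to the longest context that occurs
    repeat {
      if (length(ctx) == 0 || count_ctx(ctx) > 0) break
      ctx <- ctx[-1]
    }
    tot <- if (length(ctx)) count_ctx(ctx) else 10L
    hits <- if (length(ctx)) count_ctx_tok(ctx, s[i]) else sum(s == s[i])
    probs[i] <- (hits + lam) / (tot + lam * 4)
  }
  expected <- (1 / prod(probs))^(1 / 10)  # m-th-root inverse probability
  got <- corpus_perplexity(m, corp, eval_batch = 1)$mean_ppl
  expect_equal(got, expected, tolerance = 1e-9)
  # identical to exp(mean cross-entropy): the two formulations agree
  expect_equal(got, exp(mean(-log(probs))), tolerance = 1e-9)
})

test_that("reducing probability on observed tokens raises perplexity", {
  s <- rep(c(0L, 1L, 2L), 10)
  corp <- token_corpus_from_ids(list(s), w = 1)
  sharp <- train_ngram(corp, n = 1, lambda = 0.01)
  flat <- train_ngram(corp, n = 1, lambda = 10)   # flatter conditionals
  expect_lt(corpus_perplexity(sharp, corp, 4)$mean_ppl,
            corpus_perplexity(flat, corp, 4)$mean_ppl)
})

test_that("perplexity report batching and per-read aggregation are sound", {
  rs <- random_read_set(12, len = 120, seed = 22)
  corp <- encode_corpus(rs, w = 2)
  m <- train_ngram(corp, n = 1, lambda = 1)
  rep <- corpus_perplexity(m, corp, eval_batch = 4)
  expect_gte(rep$mean_ppl, 1)
  expect_gte(rep$sd_ppl, 0)
  expect_equal(rep$n_tokens_scored, sum(rep$per_chunk$ntok))
  expect_equal(nrow(rep$per_chunk), length(corp$sequences))
  rp <- read_perplexities(rep)
  expect_setequal(rp$read, unique(corp$provenance$read))
  expect_true(all(rp$ppl >= 1))
  # vocab mismatch is refused
  corp4 <- encode_corpus(rs, w = 4)
  expect_error(corpus_perplexity(m, corp4, 4), "do not match")
})

test_that("transformer scoring is deterministic and offset modes agree", {
  rs <- random_read_set(24, len = 100, seed = 23)
  corp <- encode_corpus(rs, w = 2)
  cfg <- transformer_config(word_length = 2, n_layers = 1, n_heads = 2,
                            d_model = 16, d_ff = 32, epochs = 2,
                            train_batch = 8, eval_batch = 4, seed = 24)
  lm <- train_transformer(corp, cfg)
  r1 <- corpus_perplexity(lm, corp, eval_batch = 4, offsets = "all")
  r2 <- corpus_perplexity(lm, corp, eval_batch = 4, offsets = "all")
  expect_identical(r1$mean_ppl, r2$mean_ppl)
  rot <- corpus_perplexity(lm, corp, eval_batch = 4, offsets = "rotate")
  expect_lt(rot$n_tokens_scored, r1$n_tokens_scored)
  # the rotating estimate tracks the full one
  expect_equal(log(rot$mean_ppl), log(r1$mean_ppl), tolerance = 0.25)
  # thinning caps the chunks scored, deterministically
  thin <- corpus_perplexity(lm, corp, eval_batch = 4, max_chunks = 10)
  expect_equal(nrow(thin$per_chunk), 10L)
  expect_identical(thin$mean_ppl,
                   corpus_perplexity(lm, corp, 4, max_chunks = 10)$mean_ppl)
  # eval batches cannot exceed the training batch size
  expect_error(corpus_perplexity(lm, corp, eval_batch = 64), "train_batch")
})

test_that("normalized correlation equals plain Pearson on z-scores", {
  xs <- c(5, 4, 6, 8, 7)
  ys <- 100 - 2 * xs
  expect_equal(normalized_correlation(xs, ys), -1)
  expect_equal(normalized_correlation(xs, xs), 1)
  set.seed(25)
  a <- rnorm(5); b <- rnorm(5)
  expect_equal(normalized_correlation(a, b), cor(a, b), tolerance = 1e-12)
  # 5-point hand example against the textbook formula
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  hand <- sum((x - 3) * (y - mean(y))) /
    sqrt(sum((x - 3)^2) * sum((y - mean(y))^2))
  expect_equal(normalized_correlation(x, y), hand, tolerance = 1e-12)
  expect_error(normalized_correlation(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  expect_error(normalized_correlation(1:2, 1:2), "at least 3")
})
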