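test_that("positional encoding matches its sinusoidal definition", {
  pe0 <- positional_encoding(0, 8)
  expect_equal(pe0[c(1, 3, 5, 7)], rep(0, 4))  # sin 0
  expect_equal(pe0[c(2, 4, 6, 8)], rep(1, 4))  # cos 0
  pe1 <- positional_encoding(1, 8)
  expect_equal(pe1[1], sin(1), tolerance = 1e-12)
  expect_equal(pe1[2], cos(1), tolerance = 1e-12)
  expect_equal(pe1[3], sin(1 / 10000^(2 / 8)), tolerance = 1e-12)
  set.seed(1)
  for (pos in sample(0:500, 5))
    expect_true(all(abs(positional_encoding(pos, 64)) <= 1))
  # compiled path builds the identical table
  pe_cpp <- kanneal:::cpp_sinusoidal_pe(5, 8)
  pe_r <- t(vapply(0:4, positional_encoding, numeric(8), d_model = 8))
  expect_equal(pe_cpp, pe_r, tolerance = 1e-12)
})

test_that("scaled dot-product attention matches hand evaluation", {
  x <- matrix(3.7)
  expect_equal(scaled_dot_attention(x, x, x), x)  # softmax of scalar = 1

  I2 <- diag(2)
  out <- scaled_dot_attention(I2, I2, I2)
  # row 1 scores: (1,0)/sqrt2 -> softmax(0.7071, 0)
  w11 <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + exp(0))
  expect_equal(out[1, ], c(w11, 1 - w11), tolerance = 1e-12)
  expect_equal(out[2, ], c(1 - w11, w11), tolerance = 1e-12)

  set.seed(2)
  Q <- matrix(rnorm(12), 3); K <- matrix(rnorm(20), 5); V <- matrix(rnorm(10), 5)
  S <- Q %*% t(K) / sqrt(4)
  P <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(scaled_dot_attention(Q, K, V), P %*% V, tolerance = 1e-12)
  expect_equal(dim(scaled_dot_attention(Q, K, V)), c(3L, 2L))
  expect_error(scaled_dot_attention(Q, K[, 1:3], V), "inner dimension")
})

test_that("multi-head attention concatenates per-head outputs", {
  set.seed(3)
  X <- matrix(rnorm(4 * 6), 4, 6)
  # h = 1 with identity projections reduces to single-head attention
  expect_equal(multi_head_attention(X, X, X, h = 1),
               scaled_dot_attention(X, X, X))
  # h = 2 equals direct per-head evaluation then concatenation
  got <- multi_head_attention(X, X, X, h = 2)
  ref <- cbind(
    scaled_dot_attention(X[, 1:3], X[, 1:3], X[, 1:3]),
    scaled_dot_attention(X[, 4:6], X[, 4:6], X[, 4:6]))
  expect_equal(got, ref, tolerance = 1e-12)
  expect_equal(ncol(multi_head_attention(X, X, X, h = 3)), 6L)
  expect_error(multi_head_attention(X, X, X, h = 4), "divisible")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- transformer_config(word_length = 1, n_layers = 2, n_heads = 2,
                            d_model = 8, d_ff = 16, mask_span = 2,
                            mask_phases = 2, train_batch = 4,
                            eval_batch = 2, seed = 5)
  set.seed(42)
  params <- kanneal:::.init_params(cfg)
  seqs <- list(c(0L, 1L, 2L, 3L, 0L, 1L, 2L), c(3L, 3L, 1L, 0L, 2L))
  masked <- list(c(1L, 4L), c(0L, 3L))
  res <- kanneal:::cpp_transformer_loss_grads(seqs, masked, params,
                                              unclass(cfg))
  eps <- 1e-5
  perturb <- function(field, layer, idx, delta) {
    p <- params
    if (is.null(layer)) p[[field]][idx] <- p[[field]][idx] + delta
    else p$layers[[layer]][[field]][idx] <-
        p$layers[[layer]][[field]][idx] + delta
    kanneal:::cpp_transformer_loss_grads(seqs, masked, p, unclass(cfg))$loss
  }
  cases <- list(list("Emb", NULL, 17), list("Wout", NULL, 5),
                list("bout", NULL, 2), list("gF", NULL, 3),
                list("bF", NULL, 6), list("Wq", 1L, 10),
                list("Wk", 1L, 20), list("Wv", 2L, 30), list("Wo", 2L, 40),
                list("W1", 1L, 50), list("W2", 2L, 60), list("g1", 1L, 3),
                list("b2", 2L, 4), list("bf1", 1L, 7), list("g2", 1L, 8))
  for (cs in cases) {
    g_num <- (perturb(cs[[1]], cs[[2]], cs[[3]], eps) -
                perturb(cs[[1]], cs[[2]], cs[[3]], -eps)) / (2 * eps)
    g_ana <- if (is.null(cs[[2]])) res$grads[[cs[[1]]]][cs[[3]]]
             else res$grads$layers[[cs[[2]]]][[cs[[1]]]][cs[[3]]]
    expect_equal(g_ana, g_num, tolerance = 1e-5,
                 label = paste("grad", cs[[1]]))
  }
})

test_that("compiled forward agrees with the pure-R reference forward", {
  rs <- random_read_set(5, len = 40, seed = 6)
  corp <- encode_corpus(rs, w = 2)
  cfg <- transformer_config(word_length = 2, n_layers = 2, n_heads = 2,
                            d_model = 12, d_ff = 24, epochs = 2,
                            train_batch = 4, eval_batch = 2, seed = 7)
  lm <- train_transformer(corp, cfg)
  ids <- corp$sequences[[1]]
  masked <- c(2L, 10L, 25L)
  pc <- predict_masked(lm, ids, masked)
  pr <- kanneal:::.r_transformer_probs(lm$params, lm$config, ids, masked)
  expect_equal(pc, pr, tolerance = 1e-10)
  expect_equal(rowSums(pc), rep(1, 3), tolerance = 1e-6)
})

test_that("training is deterministic per seed and learns a trivial language", {
  rs <- read_set(paste0("r", 1:20), rep(strrep("A", 60), 20))
  corp <- encode_corpus(rs, w = 2)
  cfg <- transformer_config(word_length = 2, n_layers = 1, n_heads = 2,
                            d_model = 16, d_ff = 32, epochs = 30,
                            train_batch = 8, eval_batch = 4, seed = 9)
  lm1 <- train_transformer(corp, cfg)
  lm2 <- train_transformer(corp, cfg)
  expect_identical(lm1$epoch_loss, lm2$epoch_loss)
  expect_identical(lm1$params$Wout, lm2$params$Wout)
  # a constant-token language is learned to near-certainty: ppl -> 1
  rep <- corpus_perplexity(lm1, corp, eval_batch = 4)
  expect_lt(rep$mean_ppl, 1.5)
  expect_error(train_transformer(corp, transformer_config(word_length = 4)),
               "does not match")
})

test_that("no model beats the vocabulary-size floor on i.i.d. random tokens", {
  # token streams with no structure: held-out perplexity ~ |V|
  set.seed(15)
  V <- 16L
  train <- token_corpus_from_ids(
    lapply(1:40, function(i) sample(0:(V - 1L), 50, replace = TRUE)), w = 2)
  held <- token_corpus_from_ids(
    lapply(1:10, function(i) sample(0:(V - 1L), 50, replace = TRUE)), w = 2)
  cfg <- transformer_config(word_length = 2, n_layers = 1, n_heads = 2,
                            d_model = 16, d_ff = 32, epochs = 3,
                            train_batch = 8, eval_batch = 4, seed = 16)
  lm <- train_transformer(train, cfg)
  expect_gt(corpus_perplexity(lm, held, 4)$mean_ppl, V * 0.9)
  ng <- train_ngram(train, n = 2, lambda = 1)
  expect_gt(corpus_perplexity(ng, held, 4)$mean_ppl, V * 0.9)
})

test_that("the model is non-directional: later tokens shape earlier predictions", {
  rs <- random_read_set(8, len = 50, seed = 10)
  corp <- encode_corpus(rs, w = 2)
  cfg <- transformer_config(word_length = 2, n_layers = 1, n_heads = 2,
                            d_model = 16, d_ff = 32, epochs = 3,
                            train_batch = 8, eval_batch = 4, seed = 11)
  lm <- train_transformer(corp, cfg)
  ids <- corp$sequences[[1]]
  i <- 5L; j <- 20L  # predict position i, change position j > i
  p1 <- predict_masked(lm, ids, i)
  ids2 <- ids
  ids2[j + 1L] <- (ids2[j + 1L] + 7L) %% 16L
  p2 <- predict_masked(lm, ids2, i)
  expect_gt(max(abs(p1 - p2)), 1e-8)
})

test_that("models serialize and reload bit-stably", {
  rs <- random_read_set(5, len = 40, seed = 12)
  corp <- encode_corpus(rs, w = 2)
  cfg <- transformer_config(word_length = 2, n_layers = 1, n_heads = 2,
                            d_model = 8, d_ff = 16, epochs = 1,
                            train_batch = 4, eval_batch = 2, seed = 13)
  lm <- train_transformer(corp, cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(lm, f)
  back <- load_model(f)
  expect_identical(back$params, lm$params)
  expect_identical(corpus_perplexity(back, corp, 2)$mean_ppl,
                   corpus_perplexity(lm, corp, 2)$mean_ppl)
})

test_that("N-gram conditionals match closed-form counts with back-off", {
  # corpus A C A C (w = 1), n = 1, no smoothing: P(C|A) = P(A|C) = 1
  corp <- token_corpus_from_ids(list(c(0L, 1L, 0L, 1L)), w = 1)
  m <- train_ngram(corp, n = 1, lambda = 0)
  expect_equal(kanneal:::.ngram_prob(m, 0L, 1L), 1)
  expect_equal(kanneal:::.ngram_prob(m, 1L, 0L), 1)
  expect_equal(kanneal:::.ngram_prob(m, 0L, 0L), 0)

  # smoothing makes every probability strictly positive
  ms <- train_ngram(corp, n = 1, lambda = 1)
  probs <- vapply(0:3, function(tok)
    kanneal:::.ngram_prob(ms, 0L, tok), numeric(1))
  expect_true(all(probs > 0))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  # seen A twice as context: P(C|A) = (2+1)/(2+4)
  expect_equal(probs[2], 3 / 6)

  # unseen context backs off to the marginal (5-token corpus, hand counts)
  corp5 <- token_corpus_from_ids(list(c(0L, 0L, 1L, 2L, 0L)), w = 1)
  m5 <- train_ngram(corp5, n = 1, lambda = 0)
  # context 3 (T) never occurs; unigram marginal: 0 thrice, 1 once, 2 once
  expect_equal(kanneal:::.ngram_prob(m5, 3L, 0L), 3 / 5)
  expect_equal(kanneal:::.ngram_prob(m5, 3L, 1L), 1 / 5)

  # exact oracle equivalence on a random corpus <= 100 tokens
  set.seed(14)
  s <- sample(0:3, 60, replace = TRUE)
  corp_r <- token_corpus_from_ids(list(as.integer(s)), w = 1)
  mr <- train_ngram(corp_r, n = 2, lambda = 0.5)
  # brute-force counts
  bf_prob <- function(ctx, tok) {
    n <- length(ctx)
    hits <- 0L; tot <- 0L
    for (i in seq_len(60 - n)) {
      if (all(s[i:(i + n - 1)] == ctx) || n == 0) {
        tot <- tot + 1L
        if (s[i + n] == tok) hits <- hits + 1L
      }
    }
    if (tot == 0) return(NA_real_)
    (hits + 0.5) / (tot + 0.5 * 4)
  }
  for (i in 3:60) {
    ctx <- s[(i - 2):(i - 1)]
    expected <- bf_prob(ctx, s[i])
    if (!is.na(expected))
      expect_equal(kanneal:::.ngram_prob(mr, ctx, s[i]), expected,
                   tolerance = 1e-12)
  }
})
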