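#' Cross-entropy between two distributions
#'
#' `H(P,Q) = -sum_i P_i log2 Q_i = H(P) + D(P||Q)`, reported in bits by
#' default (internal computations elsewhere in the package use natural
#' logs; conversions are explicit).
#'
#' @param p,q probability vectors of equal length, each summing to 1
#'   (tolerance 1e-6).
#' @param base logarithm base (default 2, bits).
#' @return the cross-entropy; `Inf` when some `q_i = 0` with `p_i > 0`.
#' @export
cross_entropy <- function(p, q, base = 2) {
  .check_dist(p); .check_dist(q)
  if (length(p) != length(q)) stop("p and q must have equal length")
  active <- p > 0
  if (any(q[active] == 0)) return(Inf)
  -sum(p[active] * log(q[active])) / log(base)
}

#' Kullback-Leibler divergence in bits
#'
#' `D(P||Q) = sum_i P_i log2(P_i / Q_i)`; non-negative, zero iff `p == q`,
#' and `H(P,Q) - H(P) == D(P||Q)`.
#'
#' @inheritParams cross_entropy
#' @return the divergence in bits (or base-`base` units).
#' @export
kl_divergence <- function(p, q, base = 2) {
  .check_dist(p); .check_dist(q)
  if (length(p) != length(q)) stop("p and q must have equal length")
  active <- p > 0
  if (any(q[active] == 0)) return(Inf)
  sum(p[active] * log(p[active] / q[active])) / log(base)
}

.check_dist <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1 (tol 1e-6)")
  invisible(TRUE)
}

#' Corpus perplexity under a language model
#'
#' Perplexity is the exponential of the mean per-token cross-entropy,
#' `exp(CE)`; for the N-gram back end this equals the m-th-root inverse
#' probability of the scored tokens (geometric-mean inverse probability).
#' Chunks are grouped into evaluation batches of `eval_batch` sequences;
#' the report carries the mean and the across-batch standard deviation of
#' the per-batch perplexities, and the number of tokens scored.
#'
#' For the transformer back end, tokens are scored under the masked-span
#' protocol used in training.  `offsets = "all"` scores every position
#' exactly once (one pass per span phase); `offsets = "rotate"` scores one
#' phase per chunk, rotating the phase deterministically with the chunk
#' index — an unbiased, several-fold cheaper estimate used by the k-scan.
#' `max_chunks` deterministically thins large corpora (evenly spaced
#' chunks), keeping scans across k on identical footing.
#'
#' @param lm a `language_model` (transformer or ngram).
#' @param corpus a `token_corpus` with the same vocabulary.
#' @param eval_batch sequences per evaluation batch; must not exceed the
#'   transformer's training batch size.
#' @param offsets `"all"` or `"rotate"` (transformer only).
#' @param max_chunks optional cap on the number of chunks scored.
#' @return a `perplexity_report`: `mean_ppl`, `sd_ppl`, `n_tokens_scored`,
#'   `n_batches`, `per_chunk` (data frame `read`, `offset`, `nats`,
#'   `ntok`), `model_digest`, `corpus_digest`.
#' @export
corpus_perplexity <- function(lm, corpus, eval_batch = 16L,
                              offsets = c("all", "rotate"),
                              max_chunks = NULL) {
  stopifnot(inherits(lm, "language_model"), inherits(corpus, "token_corpus"))
  offsets <- match.arg(offsets)
  if (lm$vocab$size != corpus$vocab$size ||
      lm$vocab$word_length != corpus$vocab$word_length)
    stop("model and corpus vocabularies do not match")
  if (lm$kind == "transformer" && eval_batch > lm$config$train_batch)
    stop("eval_batch must be <= the model's train_batch")
  n <- length(corpus$sequences)
  if (!n) stop("empty corpus: nothing to score")
  idx <- seq_len(n)
  if (!is.null(max_chunks) && max_chunks < n)
    idx <- unique(round(seq(1L, n, length.out = max_chunks)))
  prov <- corpus$provenance[idx, , drop = FALSE]

  if (lm$kind == "transformer") {
    cfg <- lm$config
    sp <- .split_bptt(corpus$sequences[idx], cfg$bptt)
    ph <- if (offsets == "all") rep(-1L, length(sp$sequences))
          else cfg$mask_span *
            ((sp$map - 1L) %% cfg$mask_phases)
    sc <- cpp_transformer_score(sp$sequences, lm$params, unclass(cfg),
                                as.integer(ph), as.integer(eval_batch))
    nats <- as.numeric(rowsum(sc$nats, sp$map)[, 1L])
    ntok <- as.integer(rowsum(sc$ntok, sp$map)[, 1L])
  } else {
    per <- lapply(corpus$sequences[idx], function(s) .ngram_seq_nats(lm, s))
    nats <- vapply(per, sum, numeric(1))
    ntok <- lengths(corpus$sequences[idx])
  }

  grp <- ceiling(seq_along(idx) / eval_batch)
  bn <- rowsum(nats, grp)[, 1L]
  bt <- rowsum(as.numeric(ntok), grp)[, 1L]
  keep <- bt > 0
  ppl_b <- exp(bn[keep] / bt[keep])
  mean_ppl <- mean(ppl_b)
  sd_ppl <- if (length(ppl_b) > 1L) sd(ppl_b) else 0
  structure(list(mean_ppl = mean_ppl, sd_ppl = sd_ppl,
                 n_batches = sum(keep),
                 n_tokens_scored = sum(ntok),
                 overall_ppl = exp(sum(nats) / max(sum(ntok), 1)),
                 per_chunk = data.frame(read = prov$read,
                                        offset = prov$offset,
                                        nats = nats, ntok = ntok),
                 model_digest = .model_digest(lm),
                 corpus_digest = .corpus_digest(corpus)),
            class = "perplexity_report")
}

.model_digest <- function(lm) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(lm$params %||% lm$tables, f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.perplexity_report <- function(x, ...) {
  cat(sprintf(
    "perplexity_report: mean %.4f (sd %.4f over %d batches), %d tokens\n",
    x$mean_ppl, x$sd_ppl, x$n_batches, x$n_tokens_scored))
  invisible(x)
}

#' Per-read perplexities
#'
#' Aggregates a report's per-chunk cross-entropies by source read:
#' `exp(total nats / total tokens)` per read.
#'
#' @param report a `perplexity_report`.
#' @return data frame `read` (index), `ppl`, `ntok`.
#' @export
read_perplexities <- function(report) {
  stopifnot(inherits(report, "perplexity_report"))
  pc <- report$per_chunk
  nats <- rowsum(pc$nats, pc$read)
  ntok <- rowsum(pc$ntok, pc$read)
  data.frame(read = as.integer(rownames(nats)),
             ppl = exp(nats[, 1L] / pmax(ntok[, 1L], 1L)),
             ntok = ntok[, 1L], row.names = NULL)
}

#' Correlation between perplexities and alignment rates
#'
#' Pearson correlation of the z-scored series (identical to the plain
#' Pearson coefficient; the standard normalization is retained for report
#' parity with the k-scan tables).
#'
#' @param xs perplexities, one per k.
#' @param ys alignment rates (percent), same length, `>= 3` points.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
normalized_correlation <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 3L) stop("need at least 3 points")
  if (sd(xs) == 0 || sd(ys) == 0)
    stop("correlation undefined: zero variance")
  cor(as.numeric(scale(xs)), as.numeric(scale(ys)))
}
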