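#' Pipeline run configuration
#'
#' Collects every knob of the four-step workflow (sub-sample, train
#' language model, correct, evaluate) in one validated list.  Values come
#' from, in increasing precedence: package defaults, a YAML config file,
#' and arguments to this function.
#'
#' @param file optional YAML file of key/value overrides (nested keys
#'   mirror the list structure below).
#' @param ... named overrides, e.g. `reads = "r.fastq"`,
#'   `tokenize = list(word_length = 4)`.
#' @return an object of class `run_config` with components `reads`,
#'   `workdir`, `genome`, `truth`, `model_path`, `genome_size`,
#'   `subsample` (fraction, min_coverage), `tokenize` (word_length,
#'   chunk_len, chunk_stride, word_stride), `model`
#'   ([transformer_config] arguments), `anneal` ([anneal_config]
#'   arguments), `adapter` (`"toy"` or a `{input}/{output}/{k}` command
#'   template), `eval` (eval_batch, max_chunks, offsets), `seed`.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- list(
    reads = NULL, workdir = ".", genome = NULL, truth = NULL,
    model_path = NULL, genome_size = NULL,
    subsample = list(fraction = 0.05, min_coverage = 30),
    tokenize = list(word_length = 4L, chunk_len = 100L, chunk_stride = 50L,
                    word_stride = 1L),
    model = list(n_layers = 4L, n_heads = 4L, d_model = NULL, d_ff = NULL,
                 bptt = 99L, epochs = 5L, learning_rate = 1e-3,
                 train_batch = 64L, eval_batch = 16L),
    anneal = list(k_min = 11L, k_max = 31L, delta = 1L, T0 = 2.8,
                  alpha = 0.7, cycles = 8L, trials_per_cycle = 3L,
                  parity = "odd"),
    adapter = "toy",
    eval = list(eval_batch = 16L, max_chunks = 4000L, offsets = "rotate"),
    sim = list(genome_size = 50000L, coverage = 40, read_len = c(100L, 100L),
               sub_rate = 0.02, ins_rate = 0, del_rate = 0, gc = 0.5),
    seed = 1L)
  if (!is.null(file)) cfg <- utils::modifyList(cfg, yaml::read_yaml(file))
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("config overrides must be named")
    cfg <- utils::modifyList(cfg, dots)
  }
  structure(cfg, class = "run_config")
}

.resolve_adapter <- function(cfg) {
  if (identical(cfg$adapter, "toy"))
    toy_adapter(k_min = cfg$anneal$k_min, k_max = cfg$anneal$k_max,
                parity = cfg$anneal$parity)
  else if (inherits(cfg$adapter, "ec_adapter")) cfg$adapter
  else external_adapter(cfg$adapter,
                        workdir = file.path(cfg$workdir, "ec_scratch"),
                        k_min = cfg$anneal$k_min, k_max = cfg$anneal$k_max,
                        parity = cfg$anneal$parity)
}

.tcfg <- function(cfg) {
  do.call(transformer_config,
          c(list(word_length = cfg$tokenize$word_length, seed = cfg$seed),
            cfg$model))
}

.encode_cfg <- function(rs, cfg) {
  encode_corpus(rs, w = cfg$tokenize$word_length,
                chunk_len = cfg$tokenize$chunk_len,
                chunk_stride = cfg$tokenize$chunk_stride,
                word_stride = cfg$tokenize$word_stride)
}

#' Simulate a dataset into a working directory
#'
#' Writes `genome.fasta`, `reads.fastq` and `truth.tsv` under
#' `cfg$workdir` from the `cfg$sim` parameters, fully determined by
#' `cfg$seed`.
#'
#' @param cfg a [run_config].
#' @return invisibly, a list with the three paths plus the read count and
#'   realized coverage.
#' @export
cmd_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$workdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  genome <- generate_genome(cfg$sim$genome_size, gc = cfg$sim$gc)
  em <- error_model(cfg$sim$sub_rate, cfg$sim$ins_rate, cfg$sim$del_rate)
  sim <- simulate_reads(genome, cfg$sim$coverage, cfg$sim$read_len, em)
  gpath <- file.path(cfg$workdir, "genome.fasta")
  rpath <- file.path(cfg$workdir, "reads.fastq")
  tpath <- file.path(cfg$workdir, "truth.tsv")
  write_sequences(read_set("genome", genome), gpath, "fasta")
  write_sequences(sim$reads, rpath, "fastq")
  write_truth(sim$truth, tpath)
  cov <- sum(nchar(sim$reads$seq)) / nchar(genome)
  message(sprintf("simulated %d reads at %.1fx coverage (genome %d bp)",
                  length(sim$reads), cov, nchar(genome)))
  invisible(list(genome = gpath, reads = rpath, truth = tpath,
                 n_reads = length(sim$reads), coverage = cov))
}

# shared front half of scan/tune: load reads, subsample, train or load LM
.prepare <- function(cfg) {
  if (is.null(cfg$reads)) stop("config error: 'reads' path is required")
  rs <- read_sequences(cfg$reads)
  gsize <- cfg$genome_size
  if (is.null(gsize) && !is.null(cfg$genome))
    gsize <- sum(nchar(read_sequences(cfg$genome)$seq))
  sub <- if (is.null(gsize)) {
    message("no genome size given: using all reads (no sub-sampling)")
    rs
  } else {
    subsample_reads(rs, cfg$subsample$fraction, gsize,
                    cfg$subsample$min_coverage, seed = cfg$seed)
  }
  list(rs = rs, sub = sub, gsize = gsize)
}

#' Train the language model on the uncorrected sub-sample
#'
#' @param cfg a [run_config]; `cfg$reads` must exist, and the checkpoint
#'   goes to `cfg$model_path` (default `workdir/model.rds`).
#' @return the trained `language_model`, invisibly.
#' @export
cmd_train <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  pre <- .prepare(cfg)
  corpus <- .encode_cfg(pre$sub, cfg)
  message(sprintf("training on %d chunks (%d tokens)",
                  length(corpus$sequences), corpus$n_tokens))
  lm <- train_transformer(corpus, .tcfg(cfg), verbose = TRUE)
  path <- cfg$model_path %||% file.path(cfg$workdir, "model.rds")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  save_model(lm, path)
  losses <- data.frame(epoch = seq_along(lm$epoch_loss),
                       loss = lm$epoch_loss)
  write.csv(losses, file.path(cfg$workdir, "train_loss.csv"),
            row.names = FALSE)
  message("checkpoint written to ", path)
  invisible(lm)
}

#' Perplexity evaluator over k
#'
#' Returns a memoizable `k -> mean perplexity` closure: correct the
#' sub-sample at k with the adapter, tokenize, and score under the model.
#' Results are cached; the same closure can back both [sa_search] and
#' [exhaustive_search] so no k is ever corrected twice.
#'
#' @param lm trained `language_model`.
#' @param sub the sub-sampled [read_set] fed to the EC tool.
#' @param adapter an `ec_adapter`.
#' @param cfg a [run_config] (tokenizer and eval settings are used).
#' @return function `k -> mean_ppl` with attribute `cache` (an
#'   environment also recording each k's full `perplexity_report`).
#' @export
make_evaluator <- function(lm, sub, adapter, cfg) {
  cache <- new.env(parent = emptyenv())
  f <- function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]]$mean_ppl)
    corrected <- adapter$invoke(sub, k)
    corpus <- .encode_cfg(corrected, cfg)
    rep <- corpus_perplexity(lm, corpus,
                             eval_batch = cfg$eval$eval_batch,
                             offsets = cfg$eval$offsets,
                             max_chunks = cfg$eval$max_chunks)
    cache[[key]] <- list(mean_ppl = rep$mean_ppl, report = rep,
                         corrected = corrected)
    rep$mean_ppl
  }
  attr(f, "cache") <- cache
  f
}

#' Exhaustive k-scan
#'
#' Evaluates every requested k, writes `scan.csv` (k, mean_ppl, sd_ppl,
#' n_tokens, and alignment_rate when ground truth is available) and, with
#' truth, reports the Pearson correlation between perplexity and
#' alignment rate — the reference-free proxy's quality check.
#'
#' @param cfg a [run_config].
#' @param k_list k values to scan (default: `anneal$k_min..k_max`
#'   honouring parity).
#' @param lm optional pre-trained model (otherwise loaded from
#'   `cfg$model_path` or trained on the spot).
#' @return data frame of the scan table, with attribute `correlation`
#'   when truth was given.
#' @export
cmd_scan <- function(cfg, k_list = NULL, lm = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(k_list)) {
    k_list <- seq.int(cfg$anneal$k_min, cfg$anneal$k_max)
    if (identical(cfg$anneal$parity, "odd"))
      k_list <- k_list[k_list %% 2L == 1L]
  }
  k_list <- sort(unique(as.integer(k_list)))
  pre <- .prepare(cfg)
  lm <- lm %||% .load_or_train(cfg)
  adapter <- .resolve_adapter(cfg)
  evaluate <- make_evaluator(lm, pre$sub, adapter, cfg)
  res <- exhaustive_search(evaluate, k_list)
  cache <- attr(evaluate, "cache")
  tab <- data.frame(
    k = k_list,
    mean_ppl = res$table$energy,
    sd_ppl = vapply(as.character(k_list), function(key)
      if (is.null(cache[[key]])) NA_real_ else cache[[key]]$report$sd_ppl,
      numeric(1)),
    n_tokens = vapply(as.character(k_list), function(key)
      if (is.null(cache[[key]])) NA_real_
      else as.numeric(cache[[key]]$report$n_tokens_scored), numeric(1)),
    row.names = NULL)
  # two SD flavours, labelled distinctly: sd_ppl above is the per-k
  # across-batch SD; these summarize the perplexity spread across the
  # scanned k values
  ok_ppl <- !is.na(tab$mean_ppl)
  attr(tab, "across_k_mean_ppl") <- mean(tab$mean_ppl[ok_ppl])
  attr(tab, "across_k_sd_ppl") <- if (sum(ok_ppl) > 1)
    sd(tab$mean_ppl[ok_ppl]) else 0
  truth <- .load_truth(cfg)
  if (!is.null(truth)) {
    tab$alignment_rate <- vapply(as.character(k_list), function(key) {
      if (is.null(cache[[key]])) return(NA_real_)
      alignment_rate_oracle(cache[[key]]$corrected, truth)
    }, numeric(1))
    ok <- !is.na(tab$mean_ppl) & !is.na(tab$alignment_rate)
    if (sum(ok) >= 3 && sd(tab$mean_ppl[ok]) > 0 &&
        sd(tab$alignment_rate[ok]) > 0) {
      attr(tab, "correlation") <-
        normalized_correlation(tab$mean_ppl[ok], tab$alignment_rate[ok])
      message(sprintf("perplexity vs alignment-rate correlation: %.3f",
                      attr(tab, "correlation")))
    }
  }
  dir.create(cfg$workdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(tab, file.path(cfg$workdir, "scan.csv"), row.names = FALSE)
  message(sprintf("best k by perplexity: %d", res$best_k))
  tab
}

.load_or_train <- function(cfg) {
  path <- cfg$model_path %||% file.path(cfg$workdir, "model.rds")
  if (file.exists(path)) load_model(path) else cmd_train(cfg)
}

.load_truth <- function(cfg) {
  if (is.null(cfg$truth) || is.null(cfg$genome)) return(NULL)
  if (!file.exists(cfg$truth) || !file.exists(cfg$genome)) return(NULL)
  genome <- read_sequences(cfg$genome)$seq[1]
  read_truth(cfg$truth, genome)
}

#' Tune k by simulated annealing
#'
#' Runs the full loop — for each proposed k: correct the sub-sample,
#' tokenize, score perplexity, update the annealing state — and writes the
#' search trace (`sa_trace.csv`) and a JSON summary (`sa_summary.json`:
#' best_k, best_perplexity, n_evaluations).
#'
#' @param cfg a [run_config].
#' @param lm optional pre-trained model.
#' @return list with `best_k`, `best_perplexity`, `history`,
#'   `n_evaluations`.
#' @export
cmd_tune <- function(cfg, lm = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  pre <- .prepare(cfg)
  lm <- lm %||% .load_or_train(cfg)
  adapter <- .resolve_adapter(cfg)
  evaluate <- make_evaluator(lm, pre$sub, adapter, cfg)
  acfg <- do.call(anneal_config, c(cfg$anneal, list(seed = cfg$seed)))
  res <- sa_search(evaluate, acfg)
  dir.create(cfg$workdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$history, file.path(cfg$workdir, "sa_trace.csv"),
            row.names = FALSE)
  summary <- list(best_k = res$best_k, best_perplexity = res$best_energy,
                  n_evaluations = res$n_evaluations)
  jsonlite::write_json(summary, file.path(cfg$workdir, "sa_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("selected k = %d (perplexity %.4f, %d evaluations)",
                  res$best_k, res$best_energy, res$n_evaluations))
  list(best_k = res$best_k, best_perplexity = res$best_energy,
       history = res$history, n_evaluations = res$n_evaluations)
}
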