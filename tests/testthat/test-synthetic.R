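test_that("generated genomes are deterministic with the requested GC", {
  g1 <- generate_genome(500, seed = 51)
  g2 <- generate_genome(500, seed = 51)
  expect_identical(g1, g2)
  expect_equal(nchar(g1), 500L)
  big <- generate_genome(100000, gc = 0.6, seed = 52)
  gc_obs <- mean(strsplit(big, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.6), 0.01)
  expect_error(generate_genome(10, gc = 1.0), "open interval")
  expect_error(generate_genome(0), ">= 1")
})

test_that("error-free simulation yields exact genome substrings", {
  genome <- generate_genome(5000, seed = 53)
  sim <- simulate_reads(genome, 5, c(60, 120), error_model(0, 0, 0),
                        seed = 54)
  expect_gte(sum(nchar(sim$reads$seq)), 5 * 5000)
  tr <- sim$truth$reads
  for (i in seq_len(10)) {
    tmpl <- kanneal:::.true_template(sim$truth, i)
    expect_identical(sim$reads$seq[i], tmpl)
  }
  expect_true(all(tr$n_sub + tr$n_ins + tr$n_del == 0))
  expect_length(label_erroneous(sim$truth)$erroneous, 0)
  expect_equal(alignment_rate_oracle(sim$reads, sim$truth), 100)
})

test_that("recorded edits reproduce every read byte-for-byte", {
  genome <- generate_genome(4000, seed = 55)
  sim <- simulate_reads(genome, 3, c(80, 150),
                        error_model(0.05, 0.02, 0.02), seed = 56)
  for (i in seq_along(sim$reads$id)) {
    tmpl <- kanneal:::.true_template(sim$truth, i)
    expect_identical(apply_edits(tmpl, sim$truth$edits[[i]]),
                     sim$reads$seq[i])
  }
  # edit counts agree with summing the edit tables
  tr <- sim$truth$reads
  expect_equal(tr$n_sub + tr$n_ins + tr$n_del,
               vapply(sim$truth$edits, nrow, integer(1)))
})

test_that("observed substitution rate matches the model", {
  genome <- generate_genome(20000, seed = 57)
  sim <- simulate_reads(genome, 50, c(100, 100), error_model(0.02, 0, 0),
                        seed = 58)  # 10^6 simulated bases
  total <- sum(sim$truth$reads$tmpl_len)
  nsub <- sum(sim$truth$reads$n_sub)
  expect_gte(total, 1e6)
  expect_lt(abs(nsub / total - 0.02), 0.002)
})

test_that("coverage arithmetic produces the expected read count", {
  genome <- generate_genome(50000, seed = 59)
  sim <- simulate_reads(genome, 40, c(100, 100), error_model(0, 0, 0),
                        seed = 60)
  expect_equal(length(sim$reads), 20000L)
  expect_error(simulate_reads(genome, 40, c(100, 60001)), "exceeds")
  expect_error(simulate_reads(genome, 0, c(100, 100)), "positive")
})

test_that("alignment oracle separates real reads from noise", {
  sim <- .small_sim()
  expect_gt(alignment_rate_oracle(sim$reads, sim$truth, 0.1), 99)
  junk <- sim$reads
  set.seed(61)
  junk$seq <- vapply(nchar(junk$seq), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  expect_lt(alignment_rate_oracle(junk, sim$truth, 0.1), 1)
  unknown <- read_set("nope", "ACGT")
  expect_error(alignment_rate_oracle(unknown, sim$truth), "unknown read id")
})

test_that("reverting a true correction cannot raise the alignment rate", {
  sim <- .small_sim()
  sp <- build_spectrum(sim$reads, 13)
  corrected <- toy_correct(sim$reads, 13, sp)
  # reads the corrector restored exactly to their true template
  tmpl <- vapply(seq_along(sim$reads$id), function(i)
    kanneal:::.true_template(sim$truth, i), character(1))
  changed <- which(corrected$seq != sim$reads$seq & corrected$seq == tmpl)
  expect_gt(length(changed), 0)
  thr <- 0.004
  base_rate <- alignment_rate_oracle(corrected, sim$truth, thr)
  for (i in head(changed, 5)) {
    reverted <- corrected
    reverted$seq[i] <- sim$reads$seq[i]  # undo all fixes in read i
    expect_lte(alignment_rate_oracle(reverted, sim$truth, thr), base_rate)
  }
})

test_that("banded edit distance agrees with full dynamic programming", {
  set.seed(62)
  for (i in 1:1000) {
    La <- sample(1:200, 1)
    a <- paste(sample(c("A", "C", "G", "T"), La, replace = TRUE),
               collapse = "")
    # b: either a mutated copy of a (near) or an unrelated string (far)
    if (runif(1) < 0.7) {
      b <- a
      for (j in seq_len(sample(0:8, 1))) {
        p <- sample(nchar(b), 1)
        b <- paste0(substr(b, 1, p - 1),
                    sample(c("", "A", "C", "G", "T", "AA"), 1),
                    substr(b, p + 1, nchar(b)))
      }
      if (!nchar(b)) b <- "A"
    } else {
      b <- paste(sample(c("A", "C", "G", "T"), sample(1:200, 1),
                        replace = TRUE), collapse = "")
    }
    band <- sample(1:30, 1)
    full <- full_edit_distance(a, b)
    got <- kanneal:::cpp_banded_edit(a, b, band)
    if (full <= band) expect_equal(got, full)
    else expect_true(is.na(got))
  }
})

test_that("truth sidecars round-trip through TSV", {
  genome <- generate_genome(3000, seed = 63)
  sim <- simulate_reads(genome, 2, c(80, 120),
                        error_model(0.03, 0.01, 0.01), seed = 64)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, f)
  back <- read_truth(f, genome)
  expect_equal(back$reads, sim$truth$reads)
  for (i in seq_along(sim$truth$edits))
    expect_equal(back$edits[[i]], sim$truth$edits[[i]],
                 ignore_attr = TRUE)
  expect_equal(alignment_rate_oracle(sim$reads, back),
               alignment_rate_oracle(sim$reads, sim$truth))
})
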