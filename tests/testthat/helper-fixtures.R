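# shared fixtures, all generated in code

random_read_set <- function(n, len = 50, seed = 1) {
  set.seed(seed)
  read_set(sprintf("r%03d", seq_len(n)),
           vapply(seq_len(n), function(i)
             paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = ""), character(1)))
}

# small simulated dataset reused across tests (memoized per session)
.small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      genome <- generate_genome(3000, seed = 301)
      cache <<- c(simulate_reads(genome, 30, c(100, 100),
                                 error_model(0.02), seed = 302),
                  list(genome = genome))
    }
    cache
  }
})

# brute-force full-DP edit distance oracle
full_edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

expect_read_sets_equal <- function(a, b) {
  expect_equal(a$id, b$id)
  expect_equal(a$seq, b$seq)
}
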