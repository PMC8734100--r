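#' Sequencing error model
#'
#' Per-base substitution, insertion and deletion probabilities.  Typical
#' regimes: Illumina short reads below 3% substitutions; PacBio / Nanopore
#' long reads 15-40% total error.
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities in `[0, 1)`
#'   with `sub_rate + ins_rate + del_rate < 1`.
#' @return an object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.02, ins_rate = 0, del_rate = 0) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 1)
    stop("rates must lie in [0, 1) and sum to < 1")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate), class = "error_model")
}

#' Generate a random genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc`.
#'
#' @param length genome length in bases, `>= 1`.
#' @param gc GC content in the open interval (0, 1).
#' @param seed optional integer seed.
#' @return a single string over `{A,C,G,T}`.
#' @export
generate_genome <- function(length, gc = 0.5, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (gc <= 0 || gc >= 1) stop("gc must be in the open interval (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Simulate reads with recorded ground truth
#'
#' Reads are drawn with uniform start offsets and uniform lengths until the
#' total base count reaches `coverage * nchar(genome)`; strand is chosen
#' uniformly (minus-strand reads are reverse-complemented before errors are
#' injected, as in an unstranded library); substitution / insertion /
#' deletion errors are injected per the error model with every edit
#' recorded against the oriented template, so that re-applying the recorded
#' edits to the genome substring reproduces each read exactly.
#'
#' @param genome genome string.
#' @param coverage target fold-coverage, `> 0`.
#' @param read_len length-2 vector `(min, max)` of template lengths.
#' @param model an [error_model].
#' @param seed optional integer seed.
#' @return list with `reads` (a [read_set]) and `truth` (a
#'   `synthetic_truth`: genome, per-read data frame `id`, `offset` (1-based
#'   genome start), `strand`, `tmpl_len`, edit counts, and the per-read
#'   edit tables).
#' @export
simulate_reads <- function(genome, coverage, read_len, model = error_model(),
                           seed = NULL) {
  G <- nchar(genome)
  if (coverage <= 0) stop("coverage must be positive")
  if (length(read_len) == 1L) read_len <- c(read_len, read_len)
  if (read_len[1] > read_len[2]) stop("read_len must be (min, max)")
  if (read_len[2] > G) stop("max read length exceeds the genome length")
  if (!is.null(seed)) set.seed(seed)
  mean_len <- mean(read_len)
  n <- ceiling(coverage * G / mean_len)
  lens <- if (read_len[1] == read_len[2]) rep(read_len[1], n)
          else sample(seq.int(read_len[1], read_len[2]), n, replace = TRUE)
  while (sum(lens) < coverage * G) {
    extra <- if (read_len[1] == read_len[2]) read_len[1]
             else sample(seq.int(read_len[1], read_len[2]), 1L)
    lens <- c(lens, extra)
  }
  n <- length(lens)
  starts <- 1L + floor(runif(n) * (G - lens + 1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tmpl <- substring(genome, starts, starts + lens - 1L)
  neg <- strand == "-"
  if (any(neg))
    tmpl[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(tmpl[neg])))
  inj <- cpp_inject_errors(tmpl, model$sub_rate, model$ins_rate,
                           model$del_rate)
  ids <- sprintf("read%06d", seq_len(n))
  edit_counts <- t(vapply(inj$edits, function(e)
    c(sum(e$op == "S"), sum(e$op == "I"), sum(e$op == "D")), numeric(3)))
  reads <- read_set(ids, as.character(inj$seq), NULL, "fastq")
  truth <- structure(list(
    genome = genome,
    reads = data.frame(id = ids, offset = starts, strand = strand,
                       tmpl_len = lens,
                       n_sub = edit_counts[, 1], n_ins = edit_counts[, 2],
                       n_del = edit_counts[, 3],
                       stringsAsFactors = FALSE),
    edits = inj$edits), class = "synthetic_truth")
  list(reads = reads, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: genome %d bp, %d reads, %d with >=1 recorded edit\n",
    nchar(x$genome), nrow(x$reads),
    sum(x$reads$n_sub + x$reads$n_ins + x$reads$n_del > 0)))
  invisible(x)
}

#' Re-apply recorded edits to an oriented template
#'
#' @param template oriented (strand-adjusted) genome substring.
#' @param edits data frame `pos` (1-based template position), `op`
#'   (`"S"`, `"I"`, `"D"`), `base`.
#' @return the reconstructed read string.
#' @export
apply_edits <- function(template, edits) {
  if (!nrow(edits)) return(template)
  chars <- strsplit(template, "")[[1]]
  out <- character(0)
  ed <- split(edits, edits$pos)
  for (p in seq_along(chars)) {
    e <- ed[[as.character(p)]]
    if (is.null(e)) { out <- c(out, chars[p]); next }
    if (e$op == "D") next
    if (e$op == "S") { out <- c(out, e$base); next }
    out <- c(out, chars[p], e$base)  # insertion after p
  }
  paste(out, collapse = "")
}

# oriented template of read i (strand-adjusted genome substring)
.true_template <- function(truth, i) {
  r <- truth$reads[i, ]
  s <- substr(truth$genome, r$offset, r$offset + r$tmpl_len - 1L)
  if (r$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Ground-truth alignment rate
#'
#' A corrected read counts as aligned when its edit distance to the genome
#' substring at its TRUE origin (strand-adjusted), divided by the read
#' length, is at most `max_divergence`.  The edit distance is computed by
#' banded dynamic programming with the band sized from the divergence
#' budget and the recorded indels, so any returned distance is exact.
#' Aligning at the recorded origin rather than searching the genome
#' decouples the measurement from aligner heuristics and is exact on
#' synthetic data.
#'
#' @param corrected a [read_set]; every id must exist in `truth`.
#' @param truth a `synthetic_truth`.
#' @param max_divergence maximum edit distance per base (default 0.1, so
#'   uncorrected ~2%-error short reads align while heavily mis-corrected
#'   reads fail).
#' @return percentage of reads aligned, in `[0, 100]`.
#' @export
alignment_rate_oracle <- function(corrected, truth, max_divergence = 0.1) {
  stopifnot(inherits(corrected, "read_set"),
            inherits(truth, "synthetic_truth"))
  pos <- match(corrected$id, truth$reads$id)
  if (anyNA(pos))
    stop("unknown read id(s): ",
         paste(head(corrected$id[is.na(pos)], 3), collapse = ", "))
  tr <- truth$reads[pos, ]
  tmpl <- substring(truth$genome, tr$offset, tr$offset + tr$tmpl_len - 1L)
  neg <- tr$strand == "-"
  if (any(neg))
    tmpl[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(tmpl[neg])))
  lens <- nchar(corrected$seq)
  indels <- truth$reads$n_ins[pos] + truth$reads$n_del[pos]
  band <- as.integer(ceiling(max_divergence * lens) +
                       abs(lens - nchar(tmpl)) + indels + 1L)
  d <- cpp_banded_edit(corrected$seq, tmpl, band)
  aligned <- !is.na(d) & d / lens <= max_divergence
  100 * mean(aligned)
}

#' Partition reads into erroneous and error-free
#'
#' Erroneous reads are those with at least one recorded edit; the
#' partition is exact by construction.
#'
#' @param truth a `synthetic_truth`.
#' @return list with character vectors `erroneous` and `error_free`.
#' @export
label_erroneous <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  err <- truth$reads$n_sub + truth$reads$n_ins + truth$reads$n_del > 0
  list(erroneous = truth$reads$id[err],
       error_free = truth$reads$id[!err])
}

#' Write / read a ground-truth sidecar
#'
#' Tab-separated: read id, 1-based genome offset, strand, template length
#' and the edit list as a compact `op:pos:base` string (`.` when
#' error-free).  The genome itself travels separately as FASTA.
#'
#' @param truth a `synthetic_truth`.
#' @param path output TSV path.
#' @return `path` invisibly ([write_truth]); a `synthetic_truth`
#'   ([read_truth]).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ed <- vapply(truth$edits, function(e) {
    if (!nrow(e)) "."
    else paste(sprintf("%s:%d:%s", e$op, e$pos, e$base), collapse = ";")
  }, character(1))
  df <- truth$reads[, c("id", "offset", "strand", "tmpl_len")]
  df$edits <- ed
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @param genome the genome string (e.g. read back from its FASTA).
#' @export
read_truth <- function(path, genome) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer", "character",
                                  "integer", "character"))
  edits <- lapply(df$edits, function(s) {
    if (s == ".")
      return(data.frame(pos = integer(), op = character(),
                        base = character(), stringsAsFactors = FALSE))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(pos = as.integer(vapply(parts, `[`, "", 2L)),
               op = vapply(parts, `[`, "", 1L),
               base = vapply(parts, `[`, "", 3L), stringsAsFactors = FALSE)
  })
  counts <- t(vapply(edits, function(e)
    c(sum(e$op == "S"), sum(e$op == "I"), sum(e$op == "D")), numeric(3)))
  structure(list(
    genome = genome,
    reads = data.frame(id = df$id, offset = df$offset, strand = df$strand,
                       tmpl_len = df$tmpl_len,
                       n_sub = counts[, 1], n_ins = counts[, 2],
                       n_del = counts[, 3], stringsAsFactors = FALSE),
    edits = edits), class = "synthetic_truth")
}
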