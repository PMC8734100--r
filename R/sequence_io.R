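#' Construct a read set
#'
#' A `read_set` is the unit that flows through the pipeline: an ordered
#' collection of named nucleotide reads, optionally with per-base qualities.
#' Ids are preserved verbatim and need not be unique.
#'
#' @param id character vector of read labels.
#' @param seq character vector of sequences over `{A,C,G,T,N}`; lowercase is
#'   uppercased, any other character is replaced by `N` with a warning.
#' @param qual optional character vector of per-base quality strings, same
#'   lengths as `seq`.
#' @param source_format `"fasta"` or `"fastq"`, recorded for round-trips.
#' @return an object of class `read_set`.
#' @export
read_set <- function(id, seq, qual = NULL, source_format = "fasta") {
  stopifnot(is.character(id), is.character(seq), length(id) == length(seq))
  seq <- toupper(seq)
  if (length(seq) && any(nchar(seq) < 1L))
    stop("every read must have at least one base")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    warning(sum(bad), " read(s) contained characters outside {A,C,G,T,N}; ",
            "replaced by N")
    seq[bad] <- gsub("[^ACGTN]", "N", seq[bad])
  }
  if (!is.null(qual)) {
    stopifnot(length(qual) == length(seq))
    if (any(nchar(qual) != nchar(seq), na.rm = TRUE))
      stop("quality strings must match sequence lengths")
  }
  structure(list(id = id, seq = seq, qual = qual,
                 source_format = match.arg(source_format, c("fasta", "fastq"))),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  n <- length(x$id)
  cat(sprintf("read_set: %d read(s), %s bases, source %s\n",
              n, format(sum(nchar(x$seq))), x$source_format))
  if (n) {
    show <- head(seq_len(n), 3L)
    for (i in show)
      cat(sprintf("  %s  %s%s\n", x$id[i],
                  substr(x$seq[i], 1, 50),
                  if (nchar(x$seq[i]) > 50) "..." else ""))
    if (n > 3L) cat("  ...\n")
  }
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$id)

#' Read sequences from FASTA or FASTQ
#'
#' Parsing is delegated to \pkg{Biostrings}; multi-line FASTA records are
#' concatenated, the 4-line FASTQ dialect is expected, and gzip-compressed
#' files are handled transparently.  Sequences are uppercased and characters
#' outside `{A,C,G,T,N}` become `N`.
#'
#' @param path path to the file (optionally `.gz`).
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (sniff the first record
#'   character, `>` vs `@`).
#' @return a [read_set].
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (!length(first) || !nzchar(first[1]))
    return(read_set(character(), character(), NULL,
                    if (format == "fastq") "fastq" else "fasta"))
  if (format == "auto") {
    if (startsWith(first, ">")) {
      format <- "fasta"
    } else if (startsWith(first, "@")) {
      format <- "fastq"
    } else stop("cannot auto-detect format of ", path,
                ": first character is neither '>' nor '@'")
  }
  if (format == "fastq") .validate_fastq(path)
  res <- tryCatch({
    if (format == "fasta") {
      x <- Biostrings::readDNAStringSet(path, format = "fasta")
      list(id = names(x), seq = unname(as.character(x)), qual = NULL)
    } else {
      x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
      list(id = names(x), seq = unname(as.character(x)),
           qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
    }
  }, error = function(e) {
    stop("failed to parse ", path, " as ", format, ": ",
         conditionMessage(e), call. = FALSE)
  })
  read_set(res$id, res$seq, res$qual, source_format = format)
}

# pre-scan a 4-line FASTQ so seq/qual length mismatches are reported with
# the record id and line number instead of a parser-internal message
.validate_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  ln <- 0L
  repeat {
    rec <- readLines(con, n = 4L)
    if (!length(rec)) break
    if (length(rec) < 4L)
      stop("truncated FASTQ record at line ", ln + 1L, " of ", path)
    if (!startsWith(rec[1], "@"))
      stop("malformed FASTQ header at line ", ln + 1L, " of ", path)
    if (nchar(rec[2]) != nchar(rec[4]))
      stop("FASTQ record '", sub("^@", "", sub("\\s.*$", "", rec[1])),
           "' at line ", ln + 1L, ": sequence length ", nchar(rec[2]),
           " != quality length ", nchar(rec[4]))
    ln <- ln + 4L
  }
  invisible(TRUE)
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTA is wrapped at 80 columns.  Writing FASTQ for reads without stored
#' qualities synthesizes constant `'I'` (Phred 40) strings: qualities are
#' pure format plumbing here, the method never uses them.
#'
#' @param rs a [read_set].
#' @param path output path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(rs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(inherits(rs, "read_set"))
  x <- Biostrings::DNAStringSet(rs$seq)
  names(x) <- rs$id
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  } else {
    qual <- rs$qual
    if (is.null(qual)) qual <- strrep("I", nchar(rs$seq))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual))
  }
  invisible(path)
}

#' Sub-sample a read set to a target fraction under a coverage floor
#'
#' Draws a uniform without-replacement sample of whole reads.  The fraction
#' is raised (capped at 1) whenever the requested fraction would drop the
#' realized coverage below `min_coverage`; sub-samples below roughly 30x
#' coverage starve k-spectrum EC tools of signal.
#'
#' @param rs a [read_set].
#' @param fraction requested proportion of reads in `(0, 1]`; the default
#'   0.05 reflects the usual 4-5% working sample.
#' @param genome_size genome length in bases (used for the coverage bound).
#' @param min_coverage minimum fold-coverage of the sample (default 30).
#' @param seed optional integer seed for reproducibility.
#' @return a [read_set] with attributes `realized_coverage` and
#'   `fraction_used`.
#' @export
subsample_reads <- function(rs, fraction = 0.05, genome_size,
                            min_coverage = 30, seed = NULL) {
  stopifnot(inherits(rs, "read_set"))
  if (!is.numeric(genome_size) || genome_size <= 0)
    stop("genome_size must be a positive number of bases")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  total <- sum(nchar(rs$seq))
  fmin <- min(1, min_coverage * genome_size / total)
  f <- max(fraction, fmin)
  n <- length(rs$id)
  m <- min(n, ceiling(f * n))
  if (!is.null(seed)) set.seed(seed)
  idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
  out <- read_set(rs$id[idx], rs$seq[idx],
                  if (is.null(rs$qual)) NULL else rs$qual[idx],
                  rs$source_format)
  attr(out, "realized_coverage") <- sum(nchar(out$seq)) / genome_size
  attr(out, "fraction_used") <- f
  out
}
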