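#' Build a k-mer spectrum
#'
#' Counts every k-length substring of every read (windows containing `N`
#' are skipped).  k-mers at or above the count threshold are *solid*
#' (trusted); the rest are *insolid* and presumed erroneous.
#' `threshold = "auto"` picks the first local minimum of the k-mer count
#' histogram — the valley between the error peak near count 1 and the
#' coverage peak — after smoothing with a width-3 moving average (raw
#' histograms at low coverage are jagged), falling back to 2.
#'
#' The counts live in native code behind an external pointer; use
#' [spectrum_counts] to look k-mers up and `as.data.frame()` to
#' materialize small spectra.  Spectra are session objects and are not
#' serializable.
#'
#' @param rs a [read_set].
#' @param k k-mer length in `[1, 31]`.
#' @param threshold `"auto"` or a minimum count `>= 1`.
#' @return an object of class `kmer_spectrum` with fields `k`,
#'   `threshold`, `n_distinct`, `histogram`.
#' @export
build_spectrum <- function(rs, k, threshold = "auto") {
  stopifnot(inherits(rs, "read_set"))
  k <- as.integer(k)
  if (!length(rs$seq) || max(nchar(rs$seq)) < k)
    stop("no countable k-mers: k exceeds every read length")
  ptr <- cpp_count_kmers(rs$seq, k)
  n_distinct <- cpp_spectrum_size(ptr)
  if (n_distinct == 0) stop("no countable k-mers (all windows contain N)")
  hist <- cpp_spectrum_histogram(ptr)
  hist <- hist[order(hist$count), , drop = FALSE]
  rownames(hist) <- NULL
  if (identical(threshold, "auto")) {
    threshold <- .valley_threshold(hist)
  } else {
    threshold <- as.integer(threshold)
    if (threshold < 1) stop("threshold must be >= 1")
  }
  structure(list(k = k, threshold = as.integer(threshold), ptr = ptr,
                 n_distinct = n_distinct, histogram = hist),
            class = "kmer_spectrum")
}

# first local minimum of the (width-3 smoothed) multiplicity histogram
.valley_threshold <- function(hist) {
  cnt <- seq_len(max(hist$count))
  y <- numeric(length(cnt))
  y[hist$count] <- hist$n_kmers
  if (length(y) >= 3L) {
    ys <- stats::filter(y, rep(1 / 3, 3), sides = 2)
    ys[is.na(ys)] <- y[is.na(ys)]
  } else ys <- y
  for (i in seq_len(length(ys) - 1L)[-1L])
    if (ys[i] < ys[i - 1L] && ys[i] <= ys[i + 1L]) return(i)
  2L
}

#' Look up k-mer counts in a spectrum
#' @param spectrum a `kmer_spectrum`.
#' @param kmers character vector of k-mers.
#' @return integer counts (0 for unseen, `NA` for malformed k-mers).
#' @export
spectrum_counts <- function(spectrum, kmers) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  cpp_spectrum_lookup(spectrum$ptr, kmers, spectrum$k)
}

#' @export
as.data.frame.kmer_spectrum <- function(x, ...) {
  df <- cpp_spectrum_as_df(x$ptr, x$k)
  df[order(df$kmer), , drop = FALSE]
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("kmer_spectrum: k=%d, %s distinct k-mers, threshold %d\n",
              x$k, format(x$n_distinct), x$threshold))
  invisible(x)
}

#' Built-in substitution-only corrector
#'
#' A deliberately simple k-spectrum corrector that exists so the tuning
#' pipeline can be exercised without an external binary: it converts
#' insolid k-mers to solid ones by single-base substitutions.  Reads are
#' scanned left to right; at the first insolid window the 3 alternative
#' bases at each of its k positions are tried and the substitution that
#' maximizes the number of solid k-mers covering the changed position is
#' committed (strict improvement required; ties go to the leftmost
#' position, then the lexicographically smallest base).  At most one
#' substitution per window and `ceil(len/k)` per read; reads never change
#' length, count, order or id.
#'
#' @param rs a [read_set].
#' @param k k-mer length; must match the spectrum's.
#' @param spectrum a `kmer_spectrum` built from `rs` (or a superset) at
#'   the same k.
#' @return a corrected [read_set] with attribute `n_substitutions`.
#' @export
toy_correct <- function(rs, k, spectrum) {
  stopifnot(inherits(rs, "read_set"), inherits(spectrum, "kmer_spectrum"))
  if (spectrum$k != k) stop("spectrum was built at k = ", spectrum$k,
                            ", not ", k)
  res <- cpp_toy_correct(rs$seq, as.integer(k), spectrum$ptr,
                         spectrum$threshold)
  out <- read_set(rs$id, res$seq, rs$qual, rs$source_format)
  attr(out, "n_substitutions") <- sum(res$n_sub)
  out
}

#' EC adapter around the built-in corrector
#'
#' @param threshold passed to [build_spectrum].
#' @param k_min,k_max,parity supported k range advertised to the search.
#' @return an `ec_adapter` whose `invoke(rs, k)` builds the spectrum from
#'   `rs` at k and runs [toy_correct].
#' @export
toy_adapter <- function(threshold = "auto", k_min = 3L, k_max = 31L,
                        parity = "any") {
  structure(list(
    name = "toy-kspectrum",
    k_min = as.integer(k_min), k_max = as.integer(k_max), parity = parity,
    invoke = function(rs, k) {
      .check_adapter_k(k, k_min, k_max, parity)
      toy_correct(rs, k, build_spectrum(rs, k, threshold))
    }), class = "ec_adapter")
}

.check_adapter_k <- function(k, k_min, k_max, parity) {
  if (k < k_min || k > k_max)
    stop("k = ", k, " outside the supported range [", k_min, ", ",
         k_max, "]")
  if (identical(parity, "odd") && k %% 2L == 0L)
    stop("k = ", k, " rejected: this tool requires odd k")
  invisible(TRUE)
}

#' Adapter for an external error-correction tool
#'
#' Treats the EC tool as a black box: `invoke(rs, k)` writes the reads,
#' substitutes `{input}`, `{output}` and `{k}` in the command template,
#' runs it through the shell, and parses the declared output file.  A
#' nonzero exit, a missing output file, or unparsable output raises an
#' adapter error carrying the captured tool output, which the search
#' treats as an infeasible k.
#'
#' @param command_template shell command containing `{input}`, `{output}`
#'   and `{k}` placeholders.
#' @param workdir scratch directory for input/output files.
#' @param format `"fasta"` or `"fastq"` exchange format.
#' @param name label used in logs.
#' @param k_min,k_max,parity supported k range.
#' @return an `ec_adapter`.
#' @export
external_adapter <- function(command_template, workdir = tempfile("ec"),
                             format = c("fasta", "fastq"),
                             name = "external", k_min = 1L, k_max = 127L,
                             parity = "any") {
  format <- match.arg(format)
  for (ph in c("{input}", "{output}", "{k}"))
    if (!grepl(ph, command_template, fixed = TRUE))
      stop("command_template must contain the ", ph, " placeholder")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  structure(list(
    name = name,
    k_min = as.integer(k_min), k_max = as.integer(k_max), parity = parity,
    invoke = function(rs, k) {
      .check_adapter_k(k, k_min, k_max, parity)
      fin <- file.path(workdir, sprintf("in_k%d.%s", k, format))
      fout <- file.path(workdir, sprintf("out_k%d.%s", k, format))
      unlink(fout)  # never parse a stale output from a previous run
      write_sequences(rs, fin, format)
      cmd <- command_template
      cmd <- gsub("{input}", fin, cmd, fixed = TRUE)
      cmd <- gsub("{output}", fout, cmd, fixed = TRUE)
      cmd <- gsub("{k}", as.character(k), cmd, fixed = TRUE)
      out <- suppressWarnings(
        system2("sh", c("-c", shQuote(cmd)), stdout = TRUE, stderr = TRUE))
      status <- attr(out, "status") %||% 0L
      if (status != 0L)
        stop("EC tool '", name, "' exited with status ", status, " at k = ",
             k, ": ", paste(out, collapse = " | "))
      if (!file.exists(fout))
        stop("EC tool '", name, "' produced no output file at k = ", k)
      read_sequences(fout, format)
    }), class = "ec_adapter")
}

#' @export
print.ec_adapter <- function(x, ...) {
  cat(sprintf("ec_adapter '%s': k in [%d, %d], parity %s\n",
              x$name, x$k_min, x$k_max, x$parity))
  invisible(x)
}
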