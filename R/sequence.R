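# Low-level DNA string utilities.
#
# Sequences are plain uppercase character strings over {A,C,G,T,N}; circular
# molecules are handled by explicit modular indexing (see circ_substr). All
# internal coordinates are 0-based half-open; conversion to the 1-based
# inclusive convention happens only in reports and printed output.

.psv_alphabet <- c("A", "C", "G", "T", "N")

psv_error <- function(class, message, data = list()) {
  cond <- structure(
    class = c(class, "plastomeSV_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}

check_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq)) {
    psv_error("psv_bad_input", sprintf("%s must be a single character string", what))
  }
  bad <- regexpr("[^ACGTN]", seq)[1L]
  if (bad != -1L) {
    psv_error(
      "psv_bad_alphabet",
      sprintf(
        "%s contains non-ACGTN character '%s' at position %d",
        what, substr(seq, bad, bad), bad
      ),
      data = list(position = bad)
    )
  }
  invisible(seq)
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed. `N` maps to `N`. The empty string is
#' its own reverse complement.
#'
#' @param seq A single character string over the alphabet `A`, `C`, `G`,
#'   `T`, `N` (uppercase).
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("TTTTTTTTTTC")  # "GAAAAAAAAAA"
#' @export
reverse_complement <- function(seq) {
  check_dna(seq)
  if (nchar(seq) == 0L) return("")
  comp <- chartr("ACGTN", "TGCAN", seq)
  rawToChar(rev(charToRaw(comp)))
}

# Vectorized reverse complement (Biostrings, C speed) for read sets.
revcomp_many <- function(seqs) {
  if (length(seqs) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# Byte-level complement lookup used by the vectorized extension code.
.comp_raw_table <- local({
  tab <- as.raw(0:255)
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (b in names(map)) tab[as.integer(charToRaw(b)) + 1L] <- charToRaw(map[[b]])
  tab
})

comp_raw <- function(r) .comp_raw_table[as.integer(r) + 1L]

# Substring of a circular sequence: 0-based start, len bases, wrapping as
# needed. start may be any integer (taken mod n).
circ_substr <- function(seq, start, len) {
  n <- nchar(seq)
  stopifnot(n > 0L, len >= 0L)
  if (len == 0L) return("")
  start <- ((start %% n) + n) %% n
  if (start + len <= n) return(substr(seq, start + 1L, start + len))
  if (len > n) {
    reps <- paste(rep(seq, ceiling((start + len) / n)), collapse = "")
    return(substr(reps, start + 1L, start + len))
  }
  paste0(substr(seq, start + 1L, n), substr(seq, 1L, start + len - n))
}

# Rotate a circular sequence so that 0-based position `offset` becomes
# position 0.
rotate_seq <- function(seq, offset) {
  n <- nchar(seq)
  offset <- ((offset %% n) + n) %% n
  if (offset == 0L) return(seq)
  paste0(substr(seq, offset + 1L, n), substr(seq, 1L, offset))
}

# Random DNA of length n at a given GC fraction (A/T and G/C equiprobable
# within their class). Uses the current RNG state.
random_dna <- function(n, gc = 0.375) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

gc_fraction <- function(seq) {
  if (nchar(seq) == 0L) return(NA_real_)
  counts <- table(strsplit(seq, "", fixed = TRUE)[[1]])
  gc <- sum(counts[names(counts) %in% c("G", "C")])
  acgt <- sum(counts[names(counts) %in% c("A", "C", "G", "T")])
  if (acgt == 0L) return(NA_real_)
  gc / acgt
}

#' Read a FASTA file as named character strings
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]; sequences are
#' uppercased.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) psv_error("psv_missing_file", sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA strings.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read FASTQ reads as a character vector
#'
#' Qualities are discarded beyond an optional mean-quality filter.
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @param min_mean_quality Optional minimum mean Phred quality; reads below
#'   it are dropped. `NULL` (default) keeps everything.
#' @return Character vector of read sequences (names = read ids).
#' @export
read_fastq <- function(path, min_mean_quality = NULL) {
  if (!file.exists(path)) psv_error("psv_missing_file", sprintf("FASTQ file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  reads <- toupper(as.character(set))
  names(reads) <- sub("\\s.*$", "", names(set))
  if (!is.null(min_mean_quality)) {
    # 4-line FASTQ records; mean Phred+33 quality per read.
    lines <- readLines(path)
    qual <- lines[seq(4L, length(lines), by = 4L)]
    mq <- vapply(qual, function(q) mean(as.integer(charToRaw(q))) - 33, numeric(1), USE.NAMES = FALSE)
    reads <- reads[mq >= min_mean_quality]
  }
  reads
}
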