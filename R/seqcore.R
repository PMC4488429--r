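#' @useDynLib mitoforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_ALPHABET_RE <- "^[ACGTN]*$"

#' Validate DNA sequences
#'
#' Uppercases and validates character sequences against the `{A,C,G,T,N}`
#' alphabet.  Ambiguity codes other than `N` are rejected (not coerced) so
#' that k-mer arithmetic downstream stays well-defined.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return the validated, uppercased character vector.
#' @export
as_dna <- function(x, what = "sequence") {
  if (!is.character(x)) stop(what, " must be a character vector", call. = FALSE)
  x <- toupper(x)
  bad <- !grepl(DNA_ALPHABET_RE, x)
  if (any(bad)) {
    stop(what, " ", which(bad)[1], " contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  x
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences (`A,C,G,T,N`; `N` maps to `N`).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("AAAC")  # "GTTT"
#' @export
revcomp <- function(x) {
  C_revcomp(as_dna(x))
}

#' Decode / encode Phred+33 quality strings
#'
#' @param qual a single quality string (Phred+33 ASCII).
#' @return `phred_decode`: integer vector of Phred scores; `phred_encode`:
#'   a single quality string.
#' @examples
#' phred_decode("I!")    # 40 0
#' phred_encode(c(40, 0))
#' @export
phred_decode <- function(qual) {
  stopifnot(is.character(qual), length(qual) == 1L)
  if (nchar(qual) == 0L) return(integer(0))
  utf8ToInt(qual) - 33L
}

#' @rdname phred_decode
#' @param scores integer vector of Phred scores in `[0, 93]`.
#' @export
phred_encode <- function(scores) {
  scores <- as.integer(scores)
  if (length(scores) == 0L) return("")
  if (any(scores < 0L | scores > 93L)) stop("Phred scores must be in [0, 93]")
  intToUtf8(scores + 33L)
}

#' Construct a set of quality reads
#'
#' The package's read container: a data frame with columns `id`, `seq`
#' (uppercase DNA) and `qual` (Phred+33 string, same length as `seq`).
#'
#' @param id,seq,qual character vectors of equal length.
#' @return a `quality_reads` data frame.
#' @export
quality_reads <- function(id, seq, qual) {
  seq <- as_dna(seq, "read sequence")
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (any(nchar(seq) != nchar(qual))) {
    bad <- which(nchar(seq) != nchar(qual))[1]
    stop("read ", bad, " (", id[bad], "): sequence and quality lengths differ",
         call. = FALSE)
  }
  # Phred range check: chars above '}' - 33 = 60 are out of the modelled range
  if (any(grepl("[\\x5E-\\x7E]", qual, perl = TRUE))) {
    stop("quality scores above Phred 60 are outside the modelled range",
         call. = FALSE)
  }
  out <- data.frame(id = unname(as.character(id)), seq = unname(seq),
                    qual = unname(as.character(qual)),
                    stringsAsFactors = FALSE)
  class(out) <- c("quality_reads", "data.frame")
  out
}

#' Minimum Phred score of each read
#'
#' `QV >= t "for all bases"` is equivalent to `min_phred(reads) >= t`; reads
#' of length zero vacuously pass every threshold.
#'
#' @param reads a `quality_reads` data frame (or its `qual` column).
#' @return integer vector of per-read minimum Phred scores (`NA` for empty
#'   reads).
#' @export
min_phred <- function(reads) {
  qual <- if (is.data.frame(reads)) reads$qual else reads
  C_min_phred(qual)
}

#' Read a FASTQ file
#'
#' Four-line records, Phred+33 quality encoding, optionally gzip-compressed.
#'
#' @param path path to the FASTQ file.
#' @param offset quality ASCII offset of the *input* file; 64 converts legacy
#'   Phred+64 input to the package's Phred+33 representation on ingest.
#' @return a [quality_reads()] data frame (one row per record, order kept).
#' @export
read_fastq <- function(path, offset = 33) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  stopifnot(offset %in% c(33, 64))
  res <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(ids = names(x), seqs = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }, error = function(e) .fastq_diagnose(path, conditionMessage(e)))
  if (length(res$ids) == 0L)
    return(quality_reads(character(0), character(0), character(0)))
  seqs <- res$seqs
  qual <- res$qual
  if (any(nchar(seqs) != nchar(qual))) {
    bad <- which(nchar(seqs) != nchar(qual))[1]
    stop("malformed FASTQ record ", bad, " in ", path,
         ": sequence and quality line lengths differ", call. = FALSE)
  }
  if (offset == 64) {
    qual <- vapply(qual, function(q) {
      v <- utf8ToInt(q) - 64L
      if (any(v < 0L)) stop("quality string not Phred+64 encoded", call. = FALSE)
      intToUtf8(v + 33L)
    }, character(1), USE.NAMES = FALSE)
  }
  quality_reads(res$ids, seqs, qual)
}

# locate the first malformed record for a readable error message
.fastq_diagnose <- function(path, msg) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L)   # empty file: an empty read set, not an error
    return(list(ids = character(0), seqs = character(0), qual = character(0)))
  nrec <- length(lines) %/% 4L
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ record ", nrec + 1L, " in ", path,
         ": truncated record (line count not a multiple of 4)", call. = FALSE)
  }
  for (i in seq_len(nrec)) {
    blk <- lines[(4L * (i - 1L) + 1L):(4L * i)]
    if (!startsWith(blk[1], "@"))
      stop("malformed FASTQ record ", i, " in ", path, ": header lacks '@'",
           call. = FALSE)
    if (!startsWith(blk[3], "+"))
      stop("malformed FASTQ record ", i, " in ", path, ": separator lacks '+'",
           call. = FALSE)
    if (nchar(blk[2]) != nchar(blk[4]))
      stop("malformed FASTQ record ", i, " in ", path,
           ": sequence and quality line lengths differ", call. = FALSE)
  }
  stop("malformed FASTQ in ", path, ": ", msg, call. = FALSE)
}

#' Write a FASTQ file (Phred+33)
#'
#' Inverse of [read_fastq()]: `read_fastq(write_fastq(x, p))` returns `x`.
#'
#' @param reads a [quality_reads()] data frame.
#' @param path output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0L) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    close(con)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path path to a FASTA file (wrapped or single-line, optionally gzip).
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(x) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  out <- as_dna(as.character(x))
  names(out) <- names(x)
  out
}

#' Write a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  seqs <- as_dna(seqs)
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(x) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(x, path, format = "fasta", width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Pair two synchronized read sets
#'
#' Mate tokens (trailing `/1`, `/2` or a space-delimited suffix) are stripped
#' from read ids; the files are assumed record-synchronized (R1[i] pairs
#' R2[i]) and this is verified by comparing id stems.
#'
#' @param r1,r2 [quality_reads()] data frames of equal length.
#' @return a `read_pairs` data frame with columns `id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`.
#' @export
pair_reads <- function(r1, r2) {
  if (nrow(r1) != nrow(r2))
    stop("R1 and R2 have different record counts (", nrow(r1), " vs ",
         nrow(r2), ")", call. = FALSE)
  stem1 <- id_stem(r1$id)
  stem2 <- id_stem(r2$id)
  bad <- which(stem1 != stem2)
  if (length(bad) > 0)
    stop("record ", bad[1], ": mate id stems differ ('", stem1[bad[1]],
         "' vs '", stem2[bad[1]], "')", call. = FALSE)
  out <- data.frame(id = stem1, seq1 = r1$seq, qual1 = r1$qual,
                    seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' @rdname pair_reads
#' @param id character vector of read ids.
#' @export
id_stem <- function(id) {
  id <- sub("\\s.*$", "", id)     # drop space-delimited mate token
  sub("/[12]$", "", id)           # drop /1, /2
}

#' Write a pair set as R1/R2 FASTQ files
#'
#' @param pairs a `read_pairs` data frame.
#' @param r1_path,r2_path output paths.
#' @return `c(r1_path, r2_path)`, invisibly.
#' @export
write_pairs <- function(pairs, r1_path, r2_path) {
  write_fastq(quality_reads(paste0(pairs$id, "/1", recycle0 = TRUE),
                            pairs$seq1, pairs$qual1), r1_path)
  write_fastq(quality_reads(paste0(pairs$id, "/2", recycle0 = TRUE),
                            pairs$seq2, pairs$qual2), r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read R1/R2 FASTQ files as a pair set
#'
#' @param r1_path,r2_path paths to mate FASTQ files.
#' @param offset quality ASCII offset, see [read_fastq()].
#' @return a `read_pairs` data frame.
#' @export
read_pairs_fastq <- function(r1_path, r2_path, offset = 33) {
  pair_reads(read_fastq(r1_path, offset), read_fastq(r2_path, offset))
}
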