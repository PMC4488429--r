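# Independent brute-force oracles, deliberately implemented with different
# primitives than the package (chartr/strsplit/rotation enumeration) so they
# can arbitrate the optimized paths.

oracle_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

oracle_canonical <- function(s) {
  r <- oracle_rc(s)
  if (s <= r) s else r
}

# all k-mers of a sequence (wrapped when circular), canonicalized
oracle_kmer_set <- function(seq, k, circular = FALSE) {
  if (circular) seq <- paste0(seq, substr(seq, 1, k - 1))
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  unique(vapply(kmers, oracle_canonical, character(1), USE.NAMES = FALSE))
}

oracle_rotations <- function(s) {
  n <- nchar(s)
  vapply(0:(n - 1), function(i) paste0(substr(s, i + 1, n), substr(s, 1, i)),
         character(1))
}

# least string over all rotations of s and of its reverse complement
oracle_canonical_rotation <- function(s) {
  sort(c(oracle_rotations(s), oracle_rotations(oracle_rc(s))))[1]
}

# longest suffix==prefix overlap by scanning every m
oracle_end_overlap <- function(s, min_overlap) {
  n <- nchar(s)
  for (m in seq.int(n - 1, 1)) {
    if (m < min_overlap) break
    if (substr(s, 1, m) == substr(s, n - m + 1, n)) return(m)
  }
  NA_integer_
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# small helper to make a quality_reads set with constant quality
const_qual_reads <- function(seqs, q = 35, ids = NULL) {
  ids <- ids %||% paste0("r", seq_along(seqs))
  quality_reads(ids, seqs, vapply(nchar(seqs),
                                  function(n) strrep(intToUtf8(q + 33), n),
                                  character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pairs with specified per-mate minimum quality (constant across bases except
# one base dipped to the stated minimum)
pairs_with_minq <- function(minq1, minq2, len = 30, base_q = 40) {
  n <- length(minq1)
  dip <- function(minq) {
    vapply(minq, function(m) {
      q <- rep(base_q, len)
      q[sample.int(len, 1)] <- m
      intToUtf8(q + 33L)
    }, character(1))
  }
  df <- data.frame(id = sprintf("p%03d", seq_len(n)),
                   seq1 = vapply(rep(len, n), random_dna, character(1)),
                   qual1 = dip(minq1),
                   seq2 = vapply(rep(len, n), random_dna, character(1)),
                   qual2 = dip(minq2), stringsAsFactors = FALSE)
  class(df) <- c("read_pairs", "data.frame")
  df
}
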