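#' Build a reference seed index for read baiting
#'
#' Collects every canonical seed k-mer of the reference treated as a circular
#' molecule (wrap-around seeds spanning the linearization point included;
#' both strands represented through canonicalization).  This replaces
#' read mapping as the read-recruitment step: a read is putatively
#' mitochondrial when it shares seed k-mers with the reference.
#'
#' @param reference a single DNA sequence (character) or the first record of
#'   a named vector as returned by [read_fasta()].
#' @param seed_k odd seed length `>= 11` (default 31).  Odd k keeps canonical
#'   tie-handling well-defined (no self-complementary k-mers).
#' @return a `ref_index` object (canonical seed set + metadata).
#' @export
build_reference_index <- function(reference, seed_k = 31) {
  if (length(reference) > 1) reference <- reference[[1]]
  reference <- as_dna(reference, "reference")
  if (seed_k < 11) stop("seed_k must be >= 11", call. = FALSE)
  if (seed_k %% 2 == 0) stop("seed_k must be odd", call. = FALSE)
  if (nchar(reference) <= seed_k)
    stop("reference (", nchar(reference), " bp) must be longer than seed_k (",
         seed_k, ")", call. = FALSE)
  sp <- C_kmer_spectrum(reference, seed_k, circular = TRUE)
  out <- list(seed_k = as.integer(seed_k), seeds = sp$kmer,
              ref_length = nchar(reference))
  class(out) <- "ref_index"
  out
}

#' @export
print.ref_index <- function(x, ...) {
  cat("Reference seed index: ", length(x$seeds), " canonical ", x$seed_k,
      "-mers from a ", x$ref_length, " bp circular reference\n", sep = "")
  invisible(x)
}

#' Bait read pairs against a reference index
#'
#' A pair is selected when at least one mate contains `min_hits` or more
#' canonical seed k-mers present in the index; both mates of a selected pair
#' are kept (pair rescue), mirroring read-id retrieval "even if only one mate
#' was mapped".  Seeds containing `N` never match; reads shorter than the
#' seed length contribute no hits and can only be rescued via their mate.
#'
#' @param pairs a `read_pairs` data frame (see [pair_reads()]).
#' @param index a `ref_index` from [build_reference_index()].
#' @param min_hits minimum number of matching seed positions in a mate
#'   (default 1).
#' @return list with `pairs` (the selected `read_pairs`) and `report`
#'   (a `bait_report`).
#' @export
bait_pairs <- function(pairs, index, min_hits = 1) {
  stopifnot(inherits(index, "ref_index"))
  if (min_hits < 1) stop("min_hits must be >= 1", call. = FALSE)
  n <- nrow(pairs)
  if (n == 0L) {
    report <- bait_report(0L, 0L, 0L, 0L, 0)
    return(list(pairs = pairs, report = report))
  }
  h1 <- C_seed_hits(pairs$seq1, index$seeds, index$seed_k) >= min_hits
  h2 <- C_seed_hits(pairs$seq2, index$seeds, index$seed_k) >= min_hits
  sel <- h1 | h2
  both <- h1 & h2
  one <- xor(h1, h2)
  rate <- round_half_up(100 * sum(h1 + h2) / (2 * n), 2)
  report <- bait_report(n, sum(sel), sum(one), sum(both), rate)
  list(pairs = pairs[sel, , drop = FALSE], report = report)
}

bait_report <- function(total_pairs, baited_pairs, one_mate, both_mates, rate) {
  out <- list(total_pairs = as.integer(total_pairs),
              baited_pairs = as.integer(baited_pairs),
              pairs_hit_by_one_mate = as.integer(one_mate),
              pairs_hit_by_both = as.integer(both_mates),
              alignment_rate = rate)
  stopifnot(out$baited_pairs == out$pairs_hit_by_one_mate + out$pairs_hit_by_both)
  class(out) <- "bait_report"
  out
}

#' @export
print.bait_report <- function(x, ...) {
  cat("Bait report\n",
      "  pairs screened:     ", x$total_pairs, "\n",
      "  pairs selected:     ", x$baited_pairs,
      " (", x$pairs_hit_by_both, " both mates, ",
      x$pairs_hit_by_one_mate, " rescued via one mate)\n",
      "  alignment rate:     ", sprintf("%.2f%%", x$alignment_rate), "\n",
      sep = "")
  invisible(x)
}

#' Overall alignment rate
#'
#' Percentage of reads recruited out of all reads, rounded half-up to two
#' decimals — the convention behind reporting e.g. 222,251 recruited of
#' 574,495,990 total reads as 0.04%.
#'
#' @param mapped_reads,total_reads read counts (`total_reads > 0`).
#' @return the rate in percent (two decimals).
#' @examples
#' alignment_rate(222251, 574495990)  # 0.04
#' @export
alignment_rate <- function(mapped_reads, total_reads) {
  if (total_reads <= 0) stop("total_reads must be positive", call. = FALSE)
  if (mapped_reads > total_reads)
    stop("mapped_reads exceeds total_reads", call. = FALSE)
  round_half_up(100 * mapped_reads / total_reads, 2)
}
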