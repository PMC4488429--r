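#' Classify a pair against an all-bases quality threshold
#'
#' A mate passes when every base has Phred `>= qv_threshold` (i.e. its
#' minimum base quality meets the threshold); zero-length mates pass
#' vacuously.
#'
#' @param pairs a `read_pairs` data frame.
#' @param qv_threshold integer Phred threshold.
#' @return factor with levels `BOTH_PASS`, `FIRST_ONLY`, `SECOND_ONLY`,
#'   `NONE`, one per pair.
#' @export
filter_pair <- function(pairs, qv_threshold) {
  m1 <- min_phred(pairs$qual1)
  m2 <- min_phred(pairs$qual2)
  p1 <- is.na(m1) | m1 >= qv_threshold
  p2 <- is.na(m2) | m2 >= qv_threshold
  out <- ifelse(p1 & p2, "BOTH_PASS",
         ifelse(p1, "FIRST_ONLY",
         ifelse(p2, "SECOND_ONLY", "NONE")))
  factor(out, levels = c("BOTH_PASS", "FIRST_ONLY", "SECOND_ONLY", "NONE"))
}

#' Build quality-stratified read pools
#'
#' For each threshold two pools are built: `PE` (only pairs in which both
#' mates pass) and `PE+SE` (the same pairs plus the surviving mate of pairs
#' in which exactly one mate passed).  The default thresholds `20, 25, 30`
#' yield the six-pool design whose variability across pools supports the
#' multi-k consensus.
#'
#' @param pairs a `read_pairs` data frame.
#' @param thresholds integer vector of Phred thresholds (default `c(20,25,30)`).
#' @return list of `read_pool` objects of length `2 * length(thresholds)`,
#'   labelled `"QV{t}_PE"` and `"QV{t}_PE+SE"`.
#' @export
build_pools <- function(pairs, thresholds = c(20, 25, 30)) {
  if (length(thresholds) == 0) stop("thresholds must be nonempty", call. = FALSE)
  pools <- list()
  for (t in thresholds) {
    cls <- filter_pair(pairs, t)
    keep <- pairs[cls == "BOTH_PASS", , drop = FALSE]
    s1 <- pairs[cls == "FIRST_ONLY", , drop = FALSE]
    s2 <- pairs[cls == "SECOND_ONLY", , drop = FALSE]
    singles <- quality_reads(
      c(paste0(s1$id, "/1", recycle0 = TRUE),
        paste0(s2$id, "/2", recycle0 = TRUE)),
      c(s1$seq1, s2$seq2),
      c(s1$qual1, s2$qual2))
    pe <- read_pool(t, "PE", keep, singles[0, , drop = FALSE])
    pese <- read_pool(t, "PE+SE", keep, singles)
    pools[[pe$label]] <- pe
    pools[[pese$label]] <- pese
  }
  pools
}

read_pool <- function(qv_threshold, mode, pairs, singles) {
  stopifnot(mode %in% c("PE", "PE+SE"))
  out <- list(qv_threshold = as.integer(qv_threshold), mode = mode,
              pairs = pairs, singles = singles,
              label = paste0("QV", qv_threshold, "_", mode))
  class(out) <- "read_pool"
  out
}

#' All read sequences of a pool
#'
#' @param pool a `read_pool`.
#' @return character vector of the pool's read sequences (both mates of each
#'   pair, then singles).
#' @export
pool_reads <- function(pool) {
  c(pool$pairs$seq1, pool$pairs$seq2, pool$singles$seq)
}

#' @export
print.read_pool <- function(x, ...) {
  cat("Read pool ", x$label, ": ", nrow(x$pairs), " pairs",
      if (x$mode == "PE+SE") paste0(" + ", nrow(x$singles), " singles"),
      "\n", sep = "")
  invisible(x)
}

#' Coverage estimate from read counts
#'
#' Implements the closed-form coverage estimate `C = (N * L * 2) / G` for
#' paired-end reads plus `C = (N * L) / G` for single-end reads, reported as
#' the nearest integer (half-up).
#'
#' @param n_pairs number of read *pairs* (the PE term counts both mates).
#' @param n_singles number of single-end reads.
#' @param read_length read length `L` in bp.
#' @param genome_size assumed target genome size `G` in bp (default 16500).
#' @return a `pool_stats` list: `n_pairs`, `n_singles`, `read_length`,
#'   `genome_size_assumed`, `total_bases`, `coverage`.
#' @examples
#' estimate_coverage(64998, 76644, 90, 16500)$coverage  # 1127
#' @export
estimate_coverage <- function(n_pairs, n_singles, read_length, genome_size = 16500) {
  if (read_length <= 0) stop("read_length must be positive", call. = FALSE)
  if (genome_size <= 0) stop("genome_size must be positive", call. = FALSE)
  total <- n_pairs * read_length * 2 + n_singles * read_length
  out <- list(n_pairs = n_pairs, n_singles = n_singles,
              read_length = read_length, genome_size_assumed = genome_size,
              total_bases = total,
              coverage = round_half_up(total / genome_size))
  class(out) <- "pool_stats"
  out
}

#' @export
print.pool_stats <- function(x, ...) {
  cat(x$n_pairs, " pairs + ", x$n_singles, " singles x ", x$read_length,
      " bp = ", format(x$total_bases, big.mark = ","), " bases -> ",
      x$coverage, "x over ", format(x$genome_size_assumed, big.mark = ","),
      " bp\n", sep = "")
  invisible(x)
}

#' Per-pool statistics table
#'
#' One row per pool with pair/single counts, total bases (summing actual read
#' lengths, so variable-length input is handled) and the closed-form coverage
#' for the assumed genome size.
#'
#' @param pools list of `read_pool` objects from [build_pools()].
#' @param genome_size assumed genome size in bp.
#' @return data frame with columns `label`, `qv_threshold`, `mode`,
#'   `n_pairs`, `n_singles`, `total_bases`, `coverage`.
#' @export
pool_stats_table <- function(pools, genome_size = 16500) {
  rows <- lapply(pools, function(p) {
    total <- sum(nchar(p$pairs$seq1)) + sum(nchar(p$pairs$seq2)) +
      sum(nchar(p$singles$seq))
    data.frame(label = p$label, qv_threshold = p$qv_threshold, mode = p$mode,
               n_pairs = nrow(p$pairs), n_singles = nrow(p$singles),
               total_bases = total,
               coverage = round_half_up(total / genome_size),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a pool to FASTQ files
#'
#' @param pool a `read_pool`.
#' @param prefix output path prefix; writes `<prefix>.R1.fastq`,
#'   `<prefix>.R2.fastq` and (for PE+SE pools with singles)
#'   `<prefix>.SE.fastq`.
#' @return character vector of written paths, invisibly.
#' @export
write_pool <- function(pool, prefix) {
  paths <- write_pairs(pool$pairs, paste0(prefix, ".R1.fastq"),
                       paste0(prefix, ".R2.fastq"))
  if (nrow(pool$singles) > 0) {
    se <- paste0(prefix, ".SE.fastq")
    write_fastq(pool$singles, se)
    paths <- c(paths, se)
  }
  invisible(paths)
}
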