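#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: a 16,563 bp
#' circular genome at GC 0.44 sequenced as 2x90 bp pairs from ~500 bp
#' gel-excised fragments, 1% substitution error, with 20% of pairs drawn
#' from a non-target ("nuclear") decoy sequence.  The default 37,500 total
#' pairs contain 30,000 genome-origin pairs, i.e. ~326x raw coverage of the
#' target circle.
#'
#' The quality profile couples base qualities to error state: erroneous
#' bases receive Phred 2-19 (below every pool threshold), correct bases a
#' per-read tier (high 30-40, mid 25-29, low 20-24 with probabilities
#' 0.45/0.30/0.25), so the QV 20/25/30 pools nest and genuinely differ.
#'
#' @param genome_length target circle length in bp.
#' @param gc_fraction target GC fraction.
#' @param n_pairs total read pairs (genome + decoy origin).
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd fragment (insert) size distribution in bp
#'   (truncated normal; clamped to `[read_length, insert_mean + 3*insert_sd]`).
#' @param substitution_error_rate per-base substitution probability.
#' @param decoy_fraction fraction of pairs drawn from the decoy sequence.
#' @param decoy_length decoy sequence length in bp (GC 0.40, checked to
#'   share no canonical 31-mer with the target).
#' @param ref_divergence per-base substitution divergence of the simulated
#'   baiting reference from the target (default 0.044, i.e. ~95.6% identity,
#'   the distance of a congeneric reference mitogenome).
#' @param quality_profile list with `error = c(lo, hi)` Phred range for
#'   erroneous bases and `tiers` (data frame `prob`, `lo`, `hi`).
#' @param seed integer seed driving all randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 16563, gc_fraction = 0.44,
                       n_pairs = 37500, read_length = 90,
                       insert_mean = 500, insert_sd = 25,
                       substitution_error_rate = 0.01,
                       decoy_fraction = 0.2, decoy_length = 50000,
                       ref_divergence = 0.044,
                       quality_profile = NULL, seed = 1) {
  if (is.null(quality_profile)) {
    quality_profile <- list(
      error = c(2L, 19L),
      tiers = data.frame(prob = c(0.45, 0.30, 0.25),
                         lo = c(30L, 25L, 20L), hi = c(40L, 29L, 24L)))
  }
  rates <- c(substitution_error_rate, decoy_fraction, gc_fraction, ref_divergence)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]", call. = FALSE)
  if (2 * read_length > insert_mean + 3 * insert_sd)
    stop("insert size distribution cannot accommodate two reads ",
         "(need 2*read_length <= insert_mean + 3*insert_sd)", call. = FALSE)
  out <- list(genome_length = as.integer(genome_length),
              gc_fraction = gc_fraction, n_pairs = as.integer(n_pairs),
              read_length = as.integer(read_length),
              insert_mean = insert_mean, insert_sd = insert_sd,
              substitution_error_rate = substitution_error_rate,
              decoy_fraction = decoy_fraction,
              decoy_length = as.integer(decoy_length),
              ref_divergence = ref_divergence,
              quality_profile = quality_profile, seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

.sample_dna <- function(length, gc_fraction) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a repeat-free circular genome
#'
#' I.i.d. bases at the requested GC fraction, regenerated (bounded retries)
#' until no exact 100-mer repeats on the circle — a repeat-free circle is
#' single-unitig assemblable at every k used by the sweep.
#'
#' @param length genome length in bp.
#' @param gc_fraction GC fraction.
#' @param seed optional seed (`NULL` uses the current RNG state).
#' @param max_tries retry bound for the repeat-free constraint.
#' @return the genome as a character scalar.
#' @export
simulate_genome <- function(length, gc_fraction = 0.44, seed = NULL,
                            max_tries = 20) {
  if (length <= 0) stop("length must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    g <- .sample_dna(length, gc_fraction)
    if (length < 100) return(g)
    doubled <- paste0(g, substr(g, 1, 99))
    w <- substring(doubled, 1:length, 100:(length + 99))
    if (!anyDuplicated(w)) return(g)
  }
  stop("could not generate a repeat-free genome in ", max_tries, " tries",
       call. = FALSE)
}

# substitution-mutate a sequence at the given per-base rate
.mutate_seq <- function(s, rate) {
  n <- nchar(s)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(s)
  pos <- sample.int(n, k)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

#' Simulate a diverged baiting reference
#'
#' A substitution-mutated copy of the target genome standing in for the
#' congeneric reference used to recruit reads (indel divergence is not
#' modelled).
#'
#' @param genome target genome (character scalar).
#' @param divergence per-base substitution rate.
#' @param seed optional seed.
#' @return the reference sequence (character scalar).
#' @export
simulate_reference <- function(genome, divergence = 0.044, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .mutate_seq(as_dna(genome), divergence)
}

#' Simulate paired-end reads with retained ground truth
#'
#' Fragments are drawn uniformly on the circle (wrapping the origin, so the
#' junction is covered and end-overlap circularization is testable) with
#' truncated-normal insert sizes; mates read inward from the fragment ends
#' (R2 reverse-complemented).  Substitution errors are Bernoulli per base;
#' qualities follow the config's profile.  Decoy pairs are drawn from an
#' independently simulated linear sequence (GC 0.40) sharing no canonical
#' 31-mer with the target.  Fully reproducible from `config$seed`.
#'
#' @param genome the circular target genome (character scalar).
#' @param config a [sim_config()].
#' @return list with `pairs` (a `read_pairs` data frame), `truth` (a
#'   `ground_truth` list: `genome`, `decoy`, `reads` per-read ledger,
#'   `errors` planted-substitution ledger) and `config`.
#' @export
simulate_pairs <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- as_dna(genome)
  set.seed(config$seed)
  rl <- config$read_length
  n_total <- config$n_pairs
  n_decoy <- round(n_total * config$decoy_fraction)
  n_genome <- n_total - n_decoy

  decoy <- if (n_decoy > 0) .simulate_decoy(genome, config) else ""

  glen <- nchar(genome)
  doubled <- paste0(genome, genome)
  origin <- sample(c(rep("genome", n_genome), rep("decoy", n_decoy)))

  ins <- round(stats::rnorm(n_total, config$insert_mean, config$insert_sd))
  ins <- pmax(rl, pmin(ins, round(config$insert_mean + 3 * config$insert_sd)))
  ins <- pmin(ins, ifelse(origin == "decoy", config$decoy_length, glen))

  start <- integer(n_total)
  g_idx <- origin == "genome"
  d_idx <- !g_idx
  frag <- character(n_total)
  if (any(g_idx)) {
    start[g_idx] <- sample.int(glen, sum(g_idx), replace = TRUE)
    frag[g_idx] <- substring(doubled, start[g_idx], start[g_idx] + ins[g_idx] - 1L)
  }
  if (any(d_idx)) {
    start[d_idx] <- vapply(ins[d_idx], function(i)
      sample.int(config$decoy_length - i + 1L, 1L), integer(1))
    frag[d_idx] <- substring(decoy, start[d_idx], start[d_idx] + ins[d_idx] - 1L)
  }
  strand <- sample(c("+", "-"), n_total, replace = TRUE)
  frag[strand == "-"] <- C_revcomp(frag[strand == "-"])

  r1 <- substring(frag, 1L, rl)
  r2 <- C_revcomp(substring(frag, ins - rl + 1L, ins))

  planted <- .plant_errors(c(r1, r2), config)
  reads <- planted$reads
  r1 <- reads[seq_len(n_total)]
  r2 <- reads[n_total + seq_len(n_total)]
  quals <- .draw_quals(planted$err_pos, rl, n_total * 2L, config$quality_profile)

  ids <- sprintf("sim_%06d", seq_len(n_total))
  pairs <- data.frame(id = ids, seq1 = r1, qual1 = quals[seq_len(n_total)],
                      seq2 = r2, qual2 = quals[n_total + seq_len(n_total)],
                      stringsAsFactors = FALSE)
  class(pairs) <- c("read_pairs", "data.frame")

  err_df <- planted$err_df
  err_df$id <- ids[(err_df$read_index - 1L) %% n_total + 1L]
  err_df$mate <- ifelse(err_df$read_index > n_total, 2L, 1L)

  truth <- list(genome = genome, decoy = decoy,
                reads = data.frame(id = ids, origin = origin, start = start,
                                   insert = ins, strand = strand,
                                   stringsAsFactors = FALSE),
                errors = err_df[, c("id", "mate", "pos", "from", "to")])
  class(truth) <- "ground_truth"
  list(pairs = pairs, truth = truth, config = config)
}

# decoy sequence with no canonical 31-mer in common with the target
.simulate_decoy <- function(genome, config, max_tries = 10) {
  target_kmers <- C_kmer_spectrum(genome, 31L, circular = TRUE)$kmer
  for (i in seq_len(max_tries)) {
    d <- .sample_dna(config$decoy_length, 0.40)
    shared <- intersect(C_kmer_spectrum(d, 31L, circular = FALSE)$kmer,
                        target_kmers)
    if (length(shared) == 0) return(d)
  }
  stop("could not generate a decoy sharing no 31-mer with the target",
       call. = FALSE)
}

# Bernoulli substitution errors over a read vector; returns mutated reads,
# a per-read list of error positions, and a flat ledger
.plant_errors <- function(reads, config) {
  rate <- config$substitution_error_rate
  n <- length(reads)
  rl <- nchar(reads)
  n_err <- stats::rbinom(n, rl, rate)
  err_pos <- vector("list", n)
  ledger <- list()
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sort(sample.int(rl[i], n_err[i]))
    v <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    from <- v[pos]
    to <- vapply(from, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
      USE.NAMES = FALSE)
    v[pos] <- to
    reads[i] <- paste(v, collapse = "")
    err_pos[[i]] <- pos
    ledger[[length(ledger) + 1]] <- data.frame(
      read_index = i, pos = pos, from = from, to = to,
      stringsAsFactors = FALSE)
  }
  err_df <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(read_index = integer(0), pos = integer(0),
               from = character(0), to = character(0), stringsAsFactors = FALSE)
  list(reads = reads, err_pos = err_pos, err_df = err_df)
}

# qualities: per-read tier for correct bases, low Phred at error positions
.draw_quals <- function(err_pos, rl, n_reads, profile) {
  tiers <- profile$tiers
  tier <- sample.int(nrow(tiers), n_reads, replace = TRUE, prob = tiers$prob)
  qmat <- matrix(0L, nrow = rl, ncol = n_reads)
  for (t in seq_len(nrow(tiers))) {
    cols <- which(tier == t)
    if (length(cols) == 0) next
    qmat[, cols] <- sample(tiers$lo[t]:tiers$hi[t], rl * length(cols),
                           replace = TRUE)
  }
  elo <- profile$error[1]; ehi <- profile$error[2]
  for (i in seq_len(n_reads)) {
    p <- err_pos[[i]]
    if (!is.null(p)) qmat[p, i] <- sample(elo:ehi, length(p), replace = TRUE)
  }
  vapply(seq_len(n_reads), function(i) intToUtf8(qmat[, i] + 33L), character(1))
}

#' Simulate a complete dataset
#'
#' Genome, diverged baiting reference, reads and ground truth from one seed.
#'
#' @param config a [sim_config()].
#' @return list `genome`, `reference`, `pairs`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  genome <- simulate_genome(config$genome_length, config$gc_fraction)
  reference <- simulate_reference(genome, config$ref_divergence)
  sim <- simulate_pairs(genome, config)
  list(genome = genome, reference = reference, pairs = sim$pairs,
       truth = sim$truth, config = config)
}

#' Compare an assembled sequence with the simulated truth
#'
#' @param selected assembled circular sequence (character scalar).
#' @param truth a `ground_truth` (or the true genome as a character scalar).
#' @return a `recovery` list: `status` one of `"EXACT"` (identical strings),
#'   `"ROTATION_RC_EXACT"` (identical after rotation/strand canonicalization),
#'   `"MISMATCHES"` (equal-length canonical forms differing at `n_mismatches`
#'   sites) or `"FAIL"`; plus `n_mismatches` and `length_diff`.
#' @export
recovery_check <- function(selected, truth) {
  true_genome <- if (inherits(truth, "ground_truth")) truth$genome else truth
  stopifnot(nchar(selected) > 0, nchar(true_genome) > 0)
  if (identical(selected, true_genome))
    return(structure(list(status = "EXACT", n_mismatches = 0L,
                          length_diff = 0L), class = "recovery"))
  cs <- canonicalize(selected)$canonical_seq
  ct <- canonicalize(true_genome)$canonical_seq
  if (identical(cs, ct))
    return(structure(list(status = "ROTATION_RC_EXACT", n_mismatches = 0L,
                          length_diff = 0L), class = "recovery"))
  ld <- abs(nchar(cs) - nchar(ct))
  if (ld == 0) {
    mm <- .circular_mismatches(cs, ct)
    if (!is.na(mm))
      return(structure(list(status = "MISMATCHES", n_mismatches = mm,
                            length_diff = 0L), class = "recovery"))
  }
  structure(list(status = "FAIL", n_mismatches = NA_integer_,
                 length_diff = ld), class = "recovery")
}

# Hamming distance between equal-length circular sequences after anchoring
# the rotation/strand: exact 31-mer anchors drawn along b locate the offset
# of a (or its reverse complement); NA when no anchor aligns (sequences
# effectively unrelated).
.circular_mismatches <- function(a, b) {
  n <- nchar(a)
  if (n <= 31) {
    cands <- c(vapply(0:(n - 1), function(i) .rotate(a, i), character(1)),
               vapply(0:(n - 1), function(i) .rotate(C_revcomp(a), i),
                      character(1)))
    vb <- utf8ToInt(b)
    return(min(vapply(cands, function(s) sum(utf8ToInt(s) != vb), numeric(1))))
  }
  anchors <- unique(round(seq(1, n - 30, length.out = 8)))
  best <- NA_integer_
  vb <- utf8ToInt(b)
  for (s in c(a, C_revcomp(a))) {
    doubled <- paste0(s, s)
    for (ap in anchors) {
      p <- regexpr(substr(b, ap, ap + 30), doubled, fixed = TRUE)
      if (p < 0) next
      off <- (as.integer(p) - ap) %% n
      mm <- sum(utf8ToInt(.rotate(s, off)) != vb)
      best <- if (is.na(best)) mm else min(best, mm)
    }
  }
  best
}

#' @export
print.recovery <- function(x, ...) {
  cat("Recovery: ", x$status,
      if (x$status == "MISMATCHES") paste0(" (", x$n_mismatches, " sites)"),
      if (x$status == "FAIL") paste0(" (length difference ", x$length_diff, " bp)"),
      "\n", sep = "")
  invisible(x)
}
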