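# --- end-overlap detection -------------------------------------------------

# KMP failure function (lengths of longest proper borders) for integer codes
.kmp_failure <- function(v) {
  n <- length(v)
  f <- integer(n)
  b <- 0L
  for (i in 2:n) {
    while (b > 0L && v[i] != v[b + 1L]) b <- f[b]
    if (v[i] == v[b + 1L]) b <- b + 1L
    f[i] <- b
  }
  f
}

#' Detect an end overlap in a linear contig
#'
#' A linear assembly of a circular molecule carries a duplicated (overlap)
#' region at its 5'- and 3'-ends.  Returns the longest `m >= min_overlap`
#' such that the contig's length-`m` suffix matches its length-`m` prefix —
#' exactly by default, or within `max_mismatch_rate` mismatches per base.
#'
#' @param contig a DNA sequence (character scalar).
#' @param min_overlap minimum overlap length in bp (default 20; assembler
#'   ends of a circular genome overlap by `k - 1`, so this is conservative).
#' @param max_mismatch_rate tolerated mismatch fraction within the overlap
#'   (default 0 = exact).
#' @return integer overlap length, or `NA_integer_` when none qualifies
#'   (including contigs shorter than `2 * min_overlap`).
#' @export
find_end_overlap <- function(contig, min_overlap = 20, max_mismatch_rate = 0) {
  if (min_overlap < 1) stop("min_overlap must be >= 1", call. = FALSE)
  contig <- as_dna(contig, "contig")
  n <- nchar(contig)
  if (n < 2 * min_overlap) return(NA_integer_)
  v <- utf8ToInt(contig)
  if (max_mismatch_rate == 0) {
    # exact suffix == prefix matches are exactly the borders of the string;
    # the KMP failure chain enumerates them longest-first
    f <- .kmp_failure(v)
    b <- f[n]
    while (b > 0L && b < min_overlap) b <- f[b]
    return(if (b >= min_overlap) b else NA_integer_)
  }
  for (m in seq.int(n - 1L, min_overlap)) {
    mm <- sum(v[seq_len(m)] != v[seq.int(n - m + 1L, n)])
    if (mm <= max_mismatch_rate * m) return(m)
  }
  NA_integer_
}

#' Circularize a contig by trimming its end overlap
#'
#' On overlap `m` the duplicated junction copy is removed exactly once (the
#' last `m` bases are dropped), giving one full traversal of the circle.
#'
#' @inheritParams find_end_overlap
#' @return the circularized sequence (character), or `NA_character_` when no
#'   qualifying overlap exists.
#' @export
circularize <- function(contig, min_overlap = 20, max_mismatch_rate = 0) {
  m <- find_end_overlap(contig, min_overlap, max_mismatch_rate)
  if (is.na(m)) return(NA_character_)
  substr(contig, 1, nchar(contig) - m)
}

# --- canonical rotation ----------------------------------------------------

# Booth's algorithm: 0-based index of the lexicographically least rotation,
# O(n) over integer codes
.least_rotation <- function(v) {
  n <- length(v)
  if (n == 0L) return(0L)
  at <- function(i) v[(i %% n) + 1L]    # 0-based circular access
  f <- rep.int(-1L, 2L * n)
  k <- 0L
  for (j in seq_len(2L * n - 1L)) {     # j = 1 .. 2n-1 (0-based positions)
    sj <- at(j)
    i <- f[j - k]                        # f is 0-based stored at +1 offset
    while (i != -1L && sj != at(k + i + 1L)) {
      if (sj < at(k + i + 1L)) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != at(k + i + 1L)) {
      if (sj < at(k)) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  k
}

.rotate <- function(s, k0) {
  n <- nchar(s)
  k0 <- k0 %% n
  if (k0 == 0L) return(s)
  paste0(substr(s, k0 + 1L, n), substr(s, 1L, k0))
}

# byte-wise a <= b (locale-independent)
.byte_leq <- function(a, b) {
  va <- utf8ToInt(a); vb <- utf8ToInt(b)
  d <- which(va != vb)
  if (length(d) == 0L) TRUE else va[d[1]] < vb[d[1]]
}

#' Canonical form of a circular sequence
#'
#' The canonical form is the lexicographically least string among all
#' rotations of the sequence and all rotations of its reverse complement —
#' so two circular sequences are the same molecule iff their canonical forms
#' are equal, independent of linearization point and strand.  Computed with
#' Booth's linear-time least-rotation algorithm on each strand.
#'
#' @param circular_seq a DNA sequence (character scalar) read around the
#'   circle.
#' @return list with `canonical_seq` and `strand_form` (`"FORWARD"` when the
#'   minimum arises from the given sequence's own rotations, ties included;
#'   `"REVERSE"` otherwise).
#' @export
canonicalize <- function(circular_seq) {
  s <- as_dna(circular_seq, "sequence")
  if (nchar(s) == 0) stop("cannot canonicalize an empty sequence", call. = FALSE)
  rot_f <- .rotate(s, .least_rotation(utf8ToInt(s)))
  rc <- C_revcomp(s)
  rot_r <- .rotate(rc, .least_rotation(utf8ToInt(rc)))
  if (.byte_leq(rot_f, rot_r)) {
    list(canonical_seq = rot_f, strand_form = "FORWARD")
  } else {
    list(canonical_seq = rot_r, strand_form = "REVERSE")
  }
}

# --- candidates, clustering, consensus ------------------------------------

#' Circularize and canonicalize assembled contigs into genome candidates
#'
#' Contigs without a qualifying end overlap are dropped; the rest are
#' circularized, canonicalized and recorded with their (k, pool) provenance
#' and observed strand form.
#'
#' @param contigs contig data frame from [multi_k_assemble()] (columns `seq`,
#'   `k`, `pool`).
#' @inheritParams find_end_overlap
#' @return a `circular_candidates` data frame: `canonical_seq`, `length`,
#'   `source_k`, `source_pool`, `strand_form`.
#' @export
circularize_contigs <- function(contigs, min_overlap = 20, max_mismatch_rate = 0) {
  rows <- list()
  for (i in seq_len(nrow(contigs))) {
    circ <- circularize(contigs$seq[i], min_overlap, max_mismatch_rate)
    if (is.na(circ)) next
    can <- canonicalize(circ)
    rows[[length(rows) + 1]] <- data.frame(
      canonical_seq = can$canonical_seq, length = nchar(can$canonical_seq),
      source_k = contigs$k[i],
      source_pool = if ("pool" %in% names(contigs)) contigs$pool[i] else NA_character_,
      strand_form = can$strand_form, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(canonical_seq = character(0), length = integer(0),
               source_k = integer(0), source_pool = character(0),
               strand_form = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("circular_candidates", "data.frame")
  out
}

#' Retain candidates inside the expected genome-size window
#'
#' @param candidates a `circular_candidates` data frame.
#' @param lo,hi inclusive size bounds in bp (defaults 16500 and 16700, the
#'   span of known macaque mitogenomes).
#' @return the filtered data frame.
#' @export
size_filter <- function(candidates, lo = 16500, hi = 16700) {
  if (lo > hi) stop("lo must be <= hi", call. = FALSE)
  out <- candidates[candidates$length >= lo & candidates$length <= hi, ,
                    drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster canonicalized candidates by exact identity
#'
#' Clusters are equivalence classes of exact canonical-sequence equality
#' (rotation- and strand-independent by construction), sorted by size
#' descending with lexicographic ties.  Forward/reverse strand-form counts
#' are recorded per cluster.
#'
#' @param candidates a `circular_candidates` data frame (already canonical).
#' @return list of `candidate_cluster` objects (`representative`, `members`,
#'   `n_forward`, `n_reverse`).
#' @export
cluster_candidates <- function(candidates) {
  if (nrow(candidates) == 0) return(list())
  groups <- split(seq_len(nrow(candidates)), candidates$canonical_seq)
  reps <- names(groups)
  sizes <- lengths(groups)
  ord <- order(-sizes, reps, method = "radix")
  lapply(ord, function(g) {
    members <- candidates[groups[[g]], , drop = FALSE]
    rownames(members) <- NULL
    out <- list(representative = reps[g], members = members,
                n_forward = sum(members$strand_form == "FORWARD"),
                n_reverse = sum(members$strand_form == "REVERSE"))
    class(out) <- "candidate_cluster"
    out
  })
}

#' @export
print.candidate_cluster <- function(x, ...) {
  cat("Cluster of ", nrow(x$members), " identical ", nchar(x$representative),
      " bp candidates (", x$n_forward, " forward / ", x$n_reverse,
      " reverse strand forms)\n", sep = "")
  invisible(x)
}

#' Cluster summary table
#'
#' @param clusters list from [cluster_candidates()].
#' @return data frame: `size`, `length`, `n_forward`, `n_reverse`, `ks`,
#'   `pools`.
#' @export
cluster_table <- function(clusters) {
  rows <- lapply(clusters, function(cl) {
    data.frame(size = nrow(cl$members), length = nchar(cl$representative),
               n_forward = cl$n_forward, n_reverse = cl$n_reverse,
               ks = paste(sort(unique(cl$members$source_k)), collapse = ","),
               pools = paste(sort(unique(cl$members$source_pool)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||% data.frame()
  rownames(out) <- NULL
  out
}

#' Select the consensus genome
#'
#' The sequence represented by the cluster with the largest number of
#' identical candidates is concluded as the assembled genome.  A tie for the
#' largest cluster is a hard error (condition class `mitoforge_tie`, carrying
#' both representatives): a silent arbitrary choice would be unreproducible.
#'
#' @param clusters list from [cluster_candidates()] (sorted by size).
#' @return a `consensus` object: `sequence`, `length`, `support`,
#'   `n_forward`, `n_reverse`, `source_k`, `source_pools`, `cluster_sizes`.
#' @export
select_consensus <- function(clusters) {
  if (length(clusters) == 0)
    stop("no candidate: no circularized sequence survived the size filter",
         call. = FALSE)
  sizes <- vapply(clusters, function(cl) nrow(cl$members), integer(1))
  if (length(clusters) > 1 && sizes[2] == sizes[1]) {
    cond <- structure(
      class = c("mitoforge_tie", "error", "condition"),
      list(message = paste0("ambiguous consensus: two clusters of size ",
                            sizes[1], " tie for the largest"),
           call = sys.call(),
           representatives = c(clusters[[1]]$representative,
                               clusters[[2]]$representative)))
    stop(cond)
  }
  top <- clusters[[1]]
  out <- list(sequence = top$representative, length = nchar(top$representative),
              support = sizes[1], n_forward = top$n_forward,
              n_reverse = top$n_reverse,
              source_k = sort(unique(top$members$source_k)),
              source_pools = sort(unique(top$members$source_pool)),
              cluster_sizes = sizes)
  class(out) <- "consensus"
  out
}

#' @export
print.consensus <- function(x, ...) {
  cat("Consensus genome: ", format(x$length, big.mark = ","), " bp, supported by ",
      x$support, " identical candidates (", x$n_forward, " forward / ",
      x$n_reverse, " reverse strand forms)\n", sep = "")
  cat("  cluster sizes: ", paste(x$cluster_sizes, collapse = ", "), "\n", sep = "")
  cat("  winner provenance: k in {", paste(x$source_k, collapse = ", "),
      "}, pools {", paste(x$source_pools, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Rotate and strand-match a circular sequence to a reference start
#'
#' Reporting aid: the canonical rotation is an arbitrary linearization, so
#' this rotates (and, if needed, reverse-complements) the assembled circle to
#' start at the position best matching the reference's first `anchor_k`
#' bases, mirroring orientation unification against a chosen reference.
#'
#' @param seq assembled circular sequence (character scalar).
#' @param reference reference sequence (character scalar or [read_fasta()]
#'   result).
#' @param anchor_k anchor length (default 31).
#' @return the rotated sequence; unchanged when no anchor matches.
#' @export
rotate_like <- function(seq, reference, anchor_k = 31) {
  if (length(reference) > 1) reference <- reference[[1]]
  reference <- as_dna(reference, "reference")
  n <- nchar(seq)
  # successive anchors: a diverged reference's first k-mer may not occur
  # verbatim in the assembly, so slide until one does
  starts <- seq(1, min(nchar(reference) - anchor_k + 1, 100 * anchor_k),
                by = anchor_k)
  for (s in c(seq, C_revcomp(seq))) {
    doubled <- paste0(s, substr(s, 1, anchor_k - 1))
    for (ap in starts) {
      anchor <- substr(reference, ap, ap + anchor_k - 1)
      pos <- regexpr(anchor, doubled, fixed = TRUE)
      if (pos > 0) return(.rotate(s, (as.integer(pos) - ap) %% n))
    }
  }
  seq
}
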