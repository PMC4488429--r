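#' Build a de Bruijn graph from reads
#'
#' Counts canonical k-mers (lexicographic min of each k-mer and its reverse
#' complement, so both strands contribute to the same edge) and applies a
#' coverage floor: k-mers seen fewer than `min_count` times are discarded,
#' which removes most substitution-error artefacts at high coverage.
#' K-mers containing `N` are skipped; reads shorter than `k` are skipped.
#'
#' @param reads character vector of read sequences (e.g. [pool_reads()]).
#' @param k odd k-mer size, `11 <= k`; must not exceed every read length.
#' @param min_count k-mer coverage floor (default 1; the assembly pipeline
#'   uses 3).
#' @return a `dbg` object holding the floored canonical k-mer spectrum.
#' @export
build_graph <- function(reads, k, min_count = 1) {
  k <- as.integer(k)
  if (k %% 2 == 0) stop("k must be odd", call. = FALSE)
  if (k < 11) stop("k must be >= 11", call. = FALSE)
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  reads <- as_dna(reads, "read")
  if (length(reads) > 0 && k > max(nchar(reads)))
    stop("k (", k, ") exceeds every read length", call. = FALSE)
  sp <- C_kmer_spectrum(reads, k, circular = FALSE)
  keep <- sp$count >= min_count
  kmers <- sp$kmer[keep]
  counts <- sp$count[keep]
  ord <- order(kmers, method = "radix")   # byte order, locale-independent
  out <- list(k = k, min_count = as.integer(min_count),
              kmers = kmers[ord], counts = counts[ord])
  class(out) <- "dbg"
  out
}

#' @export
print.dbg <- function(x, ...) {
  cat("de Bruijn graph: k=", x$k, ", ", length(x$kmers),
      " canonical k-mers (min_count=", x$min_count, ")\n", sep = "")
  invisible(x)
}

#' Number of distinct edges / nodes of a de Bruijn graph
#'
#' Edges are the distinct (canonical) k-mers; nodes the distinct
#' strand-paired (k-1)-mers they connect.
#'
#' @param graph a `dbg` object.
#' @return integer count.
#' @export
dbg_n_edges <- function(graph) length(graph$kmers)

#' @rdname dbg_n_edges
#' @export
dbg_n_nodes <- function(graph) {
  if (length(graph$kmers) == 0) return(0L)
  k <- graph$k
  ends <- c(substr(graph$kmers, 1, k - 1), substr(graph$kmers, 2, k))
  as.integer(length(unique(c(ends, C_revcomp(ends)))) / 2)
}

# oriented-node adjacency for the bidirected graph: node i in 1..m is the
# canonical k-mer, node m+i its reverse complement.  Returns the unique
# successor id per oriented node (NA when out-degree != 1) plus out-degrees.
.dbg_adjacency <- function(kmers, k) {
  m <- length(kmers)
  O <- c(kmers, C_revcomp(kmers))
  suf <- substr(O, 2, k)
  cand <- paste0(rep(suf, each = 4), c("A", "C", "G", "T"))
  ids <- match(cand, O)
  succ <- matrix(ids, nrow = 4)
  outdeg <- colSums(!is.na(succ))
  uniq <- rep(NA_integer_, 2 * m)
  one <- outdeg == 1
  if (any(one)) uniq[one] <- succ[, one][!is.na(succ[, one])]
  list(O = O, m = m, succ_unique = uniq, outdeg = outdeg)
}

# maximal non-branching paths over the oriented graph; returns a list of
# list(seq=, ids=<canonical kmer ids>, dead_start=, dead_end=)
.dbg_unitigs <- function(kmers, k) {
  adj <- .dbg_adjacency(kmers, k)
  m <- adj$m
  if (m == 0) return(list())
  twin <- function(i) ifelse(i > m, i - m, i + m)
  cid <- function(i) ifelse(i > m, i - m, i)
  visited <- logical(m)

  walk <- function(x) {
    # extend forward from oriented node x (already visited); returns appended
    # chars, traversed canonical ids, and the final oriented node
    chars <- character(0)
    ids <- integer(0)
    repeat {
      y <- adj$succ_unique[x]
      if (is.na(y)) break                        # out-degree != 1
      if (adj$outdeg[twin(y)] != 1) break        # y has in-degree != 1
      cy <- cid(y)
      if (visited[cy]) break                     # cycle closure or merge
      visited[cy] <<- TRUE
      chars <- c(chars, substr(adj$O[y], k, k))
      ids <- c(ids, cy)
      x <- y
    }
    list(chars = chars, ids = ids, end = x)
  }

  unitigs <- list()
  for (c0 in seq_len(m)) {
    if (visited[c0]) next
    visited[c0] <- TRUE
    fwd <- walk(c0)
    bwd <- walk(twin(c0))
    # twin-side string is O[twin(c0)] + bwd$chars; its revcomp prefixes O[c0]
    left <- if (length(bwd$chars)) C_revcomp(paste(bwd$chars, collapse = "")) else ""
    seq <- paste0(left, adj$O[c0], paste(fwd$chars, collapse = ""))
    start_o <- twin(bwd$end)
    dead_start <- adj$outdeg[twin(start_o)] == 0
    dead_end <- adj$outdeg[fwd$end] == 0
    unitigs[[length(unitigs) + 1]] <- list(
      seq = seq, ids = c(rev(bwd$ids), c0, fwd$ids),
      dead_start = dead_start, dead_end = dead_end)
  }
  unitigs
}

#' Assemble unitigs from a de Bruijn graph
#'
#' Emits the maximal non-branching paths (unitigs) of the graph after
#' iterative tip clipping: a unitig with exactly one dead end and length
#' `< 2k` is treated as an error tip and its k-mers removed, then unitigs are
#' recomputed, until stable.  A repeat-free circular genome at adequate
#' coverage yields a single unitig whose ends overlap by `k - 1` bases.
#' Output is deterministic — unitig walks start at the lexicographically
#' least unvisited canonical k-mer and contigs are sorted by canonical
#' sequence — but each contig's strand orientation is the traversal's own,
#' as with any assembler.
#'
#' @param graph a `dbg` from [build_graph()].
#' @return data frame with columns `seq`, `length`, `k`, `mean_kmer_coverage`.
#' @export
assemble_contigs <- function(graph) {
  stopifnot(inherits(graph, "dbg"))
  kmers <- graph$kmers
  counts <- graph$counts
  k <- graph$k
  unitigs <- list()
  for (round in 1:20) {
    unitigs <- .dbg_unitigs(kmers, k)
    is_tip <- vapply(unitigs, function(u) {
      xor(u$dead_start, u$dead_end) && nchar(u$seq) < 2 * k
    }, logical(1))
    if (!any(is_tip) || all(is_tip)) break
    drop_ids <- unlist(lapply(unitigs[is_tip], `[[`, "ids"))
    keep <- setdiff(seq_along(kmers), drop_ids)
    kmers <- kmers[keep]
    counts <- counts[keep]
    unitigs <- list()
  }
  if (length(unitigs) == 0 && length(kmers) > 0)
    unitigs <- .dbg_unitigs(kmers, k)
  if (length(unitigs) == 0) {
    return(data.frame(seq = character(0), length = integer(0), k = integer(0),
                      mean_kmer_coverage = numeric(0), stringsAsFactors = FALSE))
  }
  # orientation is the traversal's (walks start at the lexicographically
  # least unvisited canonical k-mer, so it is deterministic but strand-
  # arbitrary, like any assembler); output order is by canonical sequence
  seqs <- vapply(unitigs, `[[`, character(1), "seq")
  cov <- vapply(unitigs, function(u) mean(counts[u$ids]), numeric(1))
  ord <- order(C_canonical(seqs), method = "radix")
  data.frame(seq = seqs[ord], length = nchar(seqs[ord]), k = k,
             mean_kmer_coverage = cov[ord], stringsAsFactors = FALSE)
}

#' Multi-k, multi-pool assembly sweep
#'
#' Runs one independent de Bruijn assembly per (pool, k) combination —
#' the default six pools and fifteen k values give the 90-job sweep — and
#' pools all contigs with their provenance.  A failing job (e.g. k larger
#' than the pool's reads) is recorded, not fatal.
#'
#' @param pools list of `read_pool` objects (see [build_pools()]).
#' @param k_values odd k-mer sizes (default `seq(61, 89, by = 2)`).
#' @param min_count k-mer coverage floor per job (default 3).
#' @return list with `contigs` (data frame `seq`, `length`, `k`, `pool`,
#'   `mean_kmer_coverage`) and `jobs` (per-job status data frame).
#' @export
multi_k_assemble <- function(pools, k_values = seq(61, 89, by = 2), min_count = 3) {
  contigs <- list()
  jobs <- list()
  for (pool in pools) {
    reads <- pool_reads(pool)
    for (k in k_values) {
      res <- tryCatch({
        g <- build_graph(reads, k, min_count)
        cc <- assemble_contigs(g)
        list(status = "ok", contigs = cc, message = "")
      }, error = function(e) {
        list(status = "error", contigs = NULL, message = conditionMessage(e))
      })
      jobs[[length(jobs) + 1]] <- data.frame(
        pool = pool$label, k = k, status = res$status,
        n_contigs = if (is.null(res$contigs)) 0L else nrow(res$contigs),
        message = res$message, stringsAsFactors = FALSE)
      if (!is.null(res$contigs) && nrow(res$contigs) > 0) {
        cc <- res$contigs
        cc$pool <- pool$label
        contigs[[length(contigs) + 1]] <- cc
      }
    }
  }
  contigs <- if (length(contigs)) do.call(rbind, contigs) else
    data.frame(seq = character(0), length = integer(0), k = integer(0),
               mean_kmer_coverage = numeric(0), pool = character(0),
               stringsAsFactors = FALSE)
  rownames(contigs) <- NULL
  list(contigs = contigs[, c("seq", "length", "k", "pool", "mean_kmer_coverage")],
       jobs = do.call(rbind, jobs))
}

#' Write contigs to a multi-FASTA file
#'
#' Headers encode provenance, e.g. `contig1 pool=QV20_PE+SE k=75 cov=812.4`.
#'
#' @param contigs contig data frame from [multi_k_assemble()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  seqs <- contigs$seq
  names(seqs) <- sprintf("contig%d pool=%s k=%d cov=%.1f",
                         seq_len(nrow(contigs)),
                         contigs$pool %||% "NA", contigs$k,
                         contigs$mean_kmer_coverage)
  write_fasta(seqs, path)
}
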