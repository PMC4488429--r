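#' Run the full assembly pipeline
#'
#' Executes the four stages end to end: reference baiting of read pairs,
#' quality-stratified pool construction, the multi-k de Bruijn assembly
#' sweep, and finishing (circularization, size filter, canonicalization,
#' identical-sequence clustering, consensus selection).  Deterministic:
#' rerunning with the same inputs and parameters gives byte-identical
#' output.
#'
#' @param r1,r2 paths to mate FASTQ files, or a `read_pairs` data frame in
#'   `r1` (with `r2 = NULL`).
#' @param reference path to the reference FASTA, or a character sequence.
#' @param seed_k,min_hits baiting parameters ([build_reference_index()],
#'   [bait_pairs()]).
#' @param thresholds pool quality thresholds ([build_pools()]).
#' @param k_values,min_count assembly sweep parameters ([multi_k_assemble()]).
#' @param min_overlap,max_mismatch_rate circularization parameters
#'   ([find_end_overlap()]).
#' @param size_lo,size_hi candidate size window in bp ([size_filter()]).
#' @param genome_size assumed genome size for coverage reporting.
#' @param rotate_to_reference rotate/strand-match the final genome to the
#'   reference start ([rotate_like()]) instead of reporting the canonical
#'   rotation.
#' @param out_dir optional directory; when given, all stage artifacts are
#'   written there (baited FASTQ, pool table TSV, contig FASTA, cluster TSV,
#'   final genome FASTA, JSON summary and parameter echo).
#' @return a `mito_run` object: `consensus`, `genome` (final sequence),
#'   `bait_report`, `pool_table`, `jobs`, `clusters`, `candidates`,
#'   `params`.
#' @export
mito_run <- function(r1, r2 = NULL, reference,
                     seed_k = 31, min_hits = 1,
                     thresholds = c(20, 25, 30),
                     k_values = seq(61, 89, by = 2), min_count = 3,
                     min_overlap = 20, max_mismatch_rate = 0,
                     size_lo = 16500, size_hi = 16700,
                     genome_size = 16500,
                     rotate_to_reference = FALSE, out_dir = NULL) {
  pairs <- if (is.data.frame(r1)) r1 else read_pairs_fastq(r1, r2)
  ref <- if (length(reference) == 1 && !grepl("^[ACGTNacgtn]+$", reference) &&
             file.exists(reference)) read_fasta(reference)[[1]] else reference
  params <- list(seed_k = seed_k, min_hits = min_hits, thresholds = thresholds,
                 k_values = k_values, min_count = min_count,
                 min_overlap = min_overlap,
                 max_mismatch_rate = max_mismatch_rate,
                 size_lo = size_lo, size_hi = size_hi,
                 genome_size = genome_size,
                 rotate_to_reference = rotate_to_reference)

  index <- build_reference_index(ref, seed_k)
  baited <- bait_pairs(pairs, index, min_hits)
  pools <- build_pools(baited$pairs, thresholds)
  ptab <- pool_stats_table(pools, genome_size)
  asm <- multi_k_assemble(pools, k_values, min_count)
  cands <- circularize_contigs(asm$contigs, min_overlap, max_mismatch_rate)
  kept <- size_filter(cands, size_lo, size_hi)
  clusters <- cluster_candidates(kept)
  consensus <- select_consensus(clusters)
  genome <- if (rotate_to_reference) rotate_like(consensus$sequence, ref) else
    consensus$sequence

  out <- list(consensus = consensus, genome = genome,
              bait_report = baited$report, pool_table = ptab,
              jobs = asm$jobs, clusters = clusters,
              cluster_table = cluster_table(clusters),
              candidates = kept, params = params)
  class(out) <- "mito_run"
  if (!is.null(out_dir)) .write_run(out, baited, pools, asm, out_dir)
  out
}

.write_run <- function(run, baited, pools, asm, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pairs(baited$pairs, file.path(out_dir, "baited.R1.fastq"),
              file.path(out_dir, "baited.R2.fastq"))
  utils::write.table(run$pool_table, file.path(out_dir, "pools.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_contigs(asm$contigs, file.path(out_dir, "contigs.fasta"))
  utils::write.table(run$cluster_table, file.path(out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  genome <- run$genome
  names(genome) <- sprintf("assembled_mitogenome length=%d support=%d",
                           run$consensus$length, run$consensus$support)
  write_fasta(genome, file.path(out_dir, "genome.fasta"))
  summary <- list(
    bait = unclass(run$bait_report),
    pools = run$pool_table,
    jobs_ok = sum(run$jobs$status == "ok"),
    jobs_total = nrow(run$jobs),
    n_candidates = nrow(run$candidates),
    cluster_sizes = run$consensus$cluster_sizes,
    genome_length = run$consensus$length,
    support = run$consensus$support)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$params, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.mito_run <- function(x, ...) {
  cat("Mitogenome assembly run\n")
  cat("  baited pairs:  ", x$bait_report$baited_pairs, " of ",
      x$bait_report$total_pairs, "\n", sep = "")
  cat("  assembly jobs: ", sum(x$jobs$status == "ok"), "/", nrow(x$jobs),
      " ok (", length(unique(x$jobs$pool)), " pools x ",
      length(unique(x$jobs$k)), " k values)\n", sep = "")
  cat("  candidates in size window: ", nrow(x$candidates), " in ",
      length(x$clusters), " clusters\n", sep = "")
  print(x$consensus)
  invisible(x)
}

#' @export
summary.mito_run <- function(object, ...) {
  cat("Pool table:\n")
  print(object$pool_table)
  cat("\nCluster table:\n")
  print(object$cluster_table)
  cat("\n")
  print(object)
  invisible(object)
}
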