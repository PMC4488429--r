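#' Feature tables on a circular genome
#'
#' A feature table is a data frame with one row per annotated feature and
#' columns `name`, `start`, `end` (1-based inclusive, GenBank convention,
#' `start <= end`, no origin-spanning features), `strand` (`"H"` heavy /
#' `"L"` light) and `ftype` (`PCG`, `tRNA`, `rRNA`, `control`, `other`).
#'
#' @param df data frame with at least `name`, `start`, `end`, `strand`;
#'   `ftype` defaults to `"other"`.
#' @param genome_length genome length in bp.
#' @param circular whether the genome is circular (default `TRUE`).
#' @return a `feature_table` data frame, sorted by `start`, with attributes
#'   `genome_length` and `circular`.
#' @export
feature_table <- function(df, genome_length, circular = TRUE) {
  req <- c("name", "start", "end", "strand")
  if (!all(req %in% names(df)))
    stop("feature table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!"ftype" %in% names(df)) df$ftype <- "other"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start < 1 | df$end > genome_length | df$start > df$end))
    stop("feature coordinates must satisfy 1 <= start <= end <= genome_length",
         call. = FALSE)
  if (!all(df$strand %in% c("H", "L")))
    stop("strand must be 'H' or 'L'", call. = FALSE)
  if (anyDuplicated(df$name))
    stop("feature names must be unique", call. = FALSE)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "genome_length") <- as.integer(genome_length)
  attr(df, "circular") <- circular
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Read a feature table from TSV or GFF3
#'
#' The TSV layout mirrors a GenBank-style organization table: columns
#' `name`, `start`, `end`, `strand` (H/L), `ftype`.  GFF3 input (1-based
#' inclusive) is read through rtracklayer; `+`/`-` map to H/L and the
#' `Name`/`ID` attribute and `type` column fill `name`/`ftype`.
#'
#' @param path input path.
#' @param genome_length genome length in bp.
#' @param format `"tsv"` or `"gff3"` (guessed from the extension by default).
#' @return a [feature_table()].
#' @export
read_features <- function(path, genome_length,
                          format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("GFF3 input requires the rtracklayer package", call. = FALSE)
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    nm <- if (!is.null(md$Name)) as.character(md$Name) else as.character(md$ID)
    df <- data.frame(name = nm,
                     start = BiocGenerics::start(gr),
                     end = BiocGenerics::end(gr),
                     strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-",
                                     "L", "H"),
                     ftype = as.character(md$type),
                     stringsAsFactors = FALSE)
  }
  feature_table(df, genome_length)
}

#' Feature length in bp
#'
#' @param f one-row slice of a [feature_table()] (or any list with `start`,
#'   `end`); vectorized over rows.
#' @return `end - start + 1`.
#' @examples
#' feature_length(list(start = 12326, end = 14137))  # 1812
#' @export
feature_length <- function(f) {
  f$end - f$start + 1L
}

#' Intergenic spacer between two features in genome order
#'
#' Nucleotides separating two adjacent features; negative values are
#' overlapping nucleotides.  Strand is ignored (spacers are computed between
#' adjacent genes regardless of which strand encodes them).
#'
#' @param a,b one-row feature slices with `a$start <= b$start`.
#' @return signed bp: `b$start - a$end - 1`.
#' @examples
#' # ATP8 (8355-8561) vs ATP6 (8516-9196): 46 bp overlap
#' intergenic_spacer(list(start = 8355, end = 8561),
#'                   list(start = 8516, end = 9196))  # -46
#' @export
intergenic_spacer <- function(a, b) {
  if (any(a$start > b$start))
    stop("features must be given in genome order (a.start <= b.start)",
         call. = FALSE)
  b$start - a$end - 1L
}

#' Gap across the origin of a circular genome
#'
#' Distance from the last feature before the origin wrap to the first
#' feature after it — e.g. the control region between the last tRNA and the
#' first tRNA of the next turn.
#'
#' @param a the last feature (before the wrap); `b` the first feature after.
#' @param b see `a`.
#' @param genome_length genome length in bp.
#' @return bp between `a$end` and `b$start` going through the origin:
#'   `(genome_length - a$end) + (b$start - 1)`.
#' @examples
#' circular_gap(list(end = 16012), list(start = 538), 16563)  # 1088
#' @export
circular_gap <- function(a, b, genome_length) {
  if (a$end > genome_length || b$start > genome_length)
    stop("coordinates exceed genome_length", call. = FALSE)
  (as.integer(genome_length) - a$end) + (b$start - 1L)
}

#' Spacer table for a full feature table
#'
#' One entry per consecutive feature pair (named after the first of the
#' pair), plus — for circular genomes — a final wrap entry from the last
#' feature back to the first across the origin.
#'
#' @param t a [feature_table()].
#' @return data frame `name` (first feature of the pair), `next_name`,
#'   `spacer` (signed bp).
#' @export
spacer_table <- function(t) {
  n <- nrow(t)
  if (n == 0) return(data.frame(name = character(0), next_name = character(0),
                                spacer = integer(0)))
  rows <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      rows[[i]] <- data.frame(
        name = t$name[i], next_name = t$name[i + 1],
        spacer = intergenic_spacer(t[i, ], t[i + 1, ]),
        stringsAsFactors = FALSE)
    }
  }
  if (isTRUE(attr(t, "circular"))) {
    rows[[length(rows) + 1]] <- data.frame(
      name = t$name[n], next_name = t$name[1],
      spacer = circular_gap(t[n, ], t[1, ], attr(t, "genome_length")),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Base composition of a sequence
#'
#' Counts and percentages per base, G+C percentage and the CpG count (number
#' of `CG` dinucleotides on the presented strand, counted linearly without
#' origin wrap).  Percentages are reported to two decimals.
#'
#' @param seq a DNA sequence (character scalar).
#' @return a `composition_stats` list: `counts` (named A/C/G/T/N), `percents`,
#'   `gc_percent`, `cpg_count`, `length`.
#' @export
composition <- function(seq) {
  seq <- as_dna(seq, "sequence")
  if (nchar(seq) == 0) stop("sequence must be nonempty", call. = FALSE)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T", "N")
  counts <- vapply(bases, function(b) sum(v == b), integer(1))
  n <- nchar(seq)
  out <- list(counts = counts,
              percents = round_half_up(100 * counts / n, 2),
              gc_percent = round_half_up(100 * (counts["C"] + counts["G"]) / n, 2),
              cpg_count = .count_overlapping(seq, "CG"),
              length = n)
  names(out$gc_percent) <- NULL
  class(out) <- "composition_stats"
  out
}

.count_overlapping <- function(s, pat) {
  count <- 0L
  from <- 1L
  repeat {
    hit <- regexpr(pat, substr(s, from, nchar(s)), fixed = TRUE)
    if (hit < 0) break
    count <- count + 1L
    from <- from + as.integer(hit)   # advance one base: overlapping counting
  }
  count
}

#' @export
print.composition_stats <- function(x, ...) {
  cat("Length ", x$length, " bp | ",
      paste(sprintf("%s %d (%.2f%%)", names(x$counts), x$counts, x$percents),
            collapse = ", "),
      " | G+C ", sprintf("%.2f%%", x$gc_percent),
      " | CpG ", x$cpg_count, "\n", sep = "")
  invisible(x)
}

#' Initiation and termination codons of a protein-coding gene
#'
#' Extracts the feature sequence from the genome (reverse-complemented for
#' L-strand genes), returning the first three bases and the terminal codon.
#' When the feature length is not a multiple of three the gene ends in an
#' incomplete stop (completed post-transcriptionally by polyadenylation),
#' rendered as the leftover base(s) followed by `"--"`, e.g. `"T--"`.
#'
#' @param genome the genome sequence (character scalar).
#' @param f one-row [feature_table()] slice with `ftype == "PCG"`.
#' @return list with `start_codon` and `stop_codon`.
#' @export
terminal_codons <- function(genome, f) {
  genome <- as_dna(genome, "genome")
  len <- feature_length(f)
  if (len < 3) stop("feature shorter than one codon", call. = FALSE)
  s <- substr(genome, f$start, f$end)
  if (f$strand == "L") s <- C_revcomp(s)
  rem <- len %% 3
  stop_codon <- if (rem == 0) substr(s, len - 2, len) else
    paste0(substr(s, len - rem + 1, len), strrep("-", 3 - rem))
  list(start_codon = substr(s, 1, 3), stop_codon = stop_codon)
}

#' Write a feature table as TSV
#'
#' @param t a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(t, path) {
  utils::write.table(as.data.frame(t)[, c("name", "start", "end", "strand", "ftype")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
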