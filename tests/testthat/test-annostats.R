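# the packaged macaque mitogenome organization table (published coordinates,
# genome length 16,563 bp) doubles as a realistic fixture
features_path <- system.file("extdata", "mcyclopis_mito_features.tsv",
                             package = "mitoforge")
feats <- read_features(features_path, genome_length = 16563)

test_that("feature lengths reproduce the published Length column", {
  expect_equal(feature_length(feats), feats$printed_length)
  expect_equal(feature_length(feats[feats$name == "ND5", ]), 1812L)
  expect_equal(feature_length(feats[feats$name == "tRNA-Phe", ]), 72L)
  expect_equal(feature_length(list(start = 5, end = 5)), 1L)
})

test_that("intergenic spacers give published overlaps and gaps", {
  at <- function(nm) feats[feats$name == nm, ]
  expect_equal(intergenic_spacer(at("ATP8"), at("ATP6")), -46L)
  expect_equal(intergenic_spacer(at("COX1"), at("tRNA-Ser(S2)")), -28L)
  expect_equal(intergenic_spacer(at("ND4L"), at("ND4")), -7L)
  expect_equal(intergenic_spacer(at("tRNA-Ile"), at("tRNA-Gln")), -3L)
  expect_equal(intergenic_spacer(at("tRNA-Asn"), at("tRNA-Cys")), 32L)
  expect_equal(intergenic_spacer(at("COX2"), at("tRNA-Lys")), 73L)
  expect_equal(intergenic_spacer(list(start = 1, end = 10),
                                 list(start = 11, end = 20)), 0L)
  expect_error(intergenic_spacer(at("ND4"), at("ND4L")), "genome order")
})

test_that("the wrap gap through the control region is 1088 bp", {
  at <- function(nm) feats[feats$name == nm, ]
  expect_equal(circular_gap(at("tRNA-Pro"), at("tRNA-Phe"), 16563), 1088L)
  expect_equal(circular_gap(list(end = 100), list(start = 1), 100), 0L)
  expect_equal(circular_gap(list(end = 95), list(start = 6), 100), 10L)
  expect_error(circular_gap(list(end = 200), list(start = 1), 100), "exceed")
})

test_that("the spacer table reproduces the published spacer column", {
  sp <- spacer_table(feats)
  expect_equal(nrow(sp), nrow(feats))   # consecutive pairs + wrap entry
  expect_equal(sp$spacer[-nrow(sp)], feats$printed_spacer[-nrow(feats)])
  expect_equal(sp$spacer[nrow(sp)], 1088L)
  expect_equal(sp$name[nrow(sp)], "tRNA-Pro")
  expect_equal(sp$next_name[nrow(sp)], "tRNA-Phe")
})

test_that("spacer arithmetic is consistent with feature lengths", {
  # spacer(a,b) + len(a) + (b.end - b.start + 1) == b.end - a.start + 1
  for (i in seq_len(nrow(feats) - 1)) {
    a <- feats[i, ]; b <- feats[i + 1, ]
    expect_equal(intergenic_spacer(a, b) + feature_length(a) + feature_length(b),
                 b$end - a$start + 1L)
  }
})

test_that("spacer values match a brute-force coordinate scan on random tables", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    starts <- sort(sample(1:900, n))
    ends <- pmin(starts + sample(10:80, n, TRUE), 1000L)
    tab <- feature_table(data.frame(name = paste0("f", 1:n), start = starts,
                                    end = ends, strand = "H"),
                         genome_length = 1000)
    sp <- spacer_table(tab)
    for (i in seq_len(n - 1)) {
      # brute force: count positions strictly between a.end and b.start
      gap <- sum(seq_len(1000) > tab$end[i] & seq_len(1000) < tab$start[i + 1])
      if (tab$start[i + 1] > tab$end[i]) {
        expect_equal(sp$spacer[i], gap)
      } else {
        expect_equal(sp$spacer[i], tab$start[i + 1] - tab$end[i] - 1L)
      }
    }
  }
})

test_that("single-feature circular tables have only the wrap entry", {
  tab <- feature_table(data.frame(name = "only", start = 10, end = 20,
                                  strand = "H"), genome_length = 100)
  sp <- spacer_table(tab)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$spacer, (100 - 20) + (10 - 1))
})

test_that("composition reproduces the published control-region GC%", {
  s <- paste0(strrep("A", 316), strrep("C", 340), strrep("G", 142), strrep("T", 290))
  st <- composition(s)
  expect_equal(st$length, 1088L)
  expect_equal(st$gc_percent, 44.30)
  expect_equal(unname(st$counts), c(316L, 340L, 142L, 290L, 0L))
  expect_equal(sum(st$counts), 1088L)
})

test_that("composition counts, percents and CpG follow their definitions", {
  st <- composition("AAAA")
  expect_equal(st$gc_percent, 0)
  expect_equal(st$cpg_count, 0L)
  expect_equal(composition("CGCGCG")$cpg_count, 3L)
  # permutation invariance and strand symmetry of GC%
  set.seed(62)
  s <- random_dna(500)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(composition(perm)$counts, composition(s)$counts)
  expect_equal(composition(revcomp(s))$gc_percent, composition(s)$gc_percent)
  expect_equal(sum(composition(s)$percents), 100, tolerance = 0.05)
})

test_that("terminal codons handle complete, incomplete and L-strand genes", {
  # H-strand gene of length 6
  g <- paste0("AA", "ATGTAA", "CC")
  f <- list(start = 3, end = 8, strand = "H", ftype = "PCG")
  expect_equal(terminal_codons(g, f), list(start_codon = "ATG", stop_codon = "TAA"))
  # L-strand: genome text is the reverse complement of the gene
  gl <- paste0("AA", revcomp("ATGTAA"), "CC")
  fl <- list(start = 3, end = 8, strand = "L", ftype = "PCG")
  expect_equal(terminal_codons(gl, fl), list(start_codon = "ATG", stop_codon = "TAA"))
  # length = 1 mod 3: incomplete stop rendered as remainder + dashes
  g7 <- paste0("T", "ATGAAAT", "G")     # gene length 7, ends in lone T
  f7 <- list(start = 2, end = 8, strand = "H", ftype = "PCG")
  expect_equal(terminal_codons(g7, f7)$stop_codon, "T--")
  # length = 2 mod 3
  g8 <- paste0("ATGAAATA")
  f8 <- list(start = 1, end = 8, strand = "H", ftype = "PCG")
  expect_equal(terminal_codons(g8, f8)$stop_codon, "TA-")
  expect_error(terminal_codons("ACGT", list(start = 1, end = 2, strand = "H")),
               "codon")
})

test_that("feature tables validate coordinates, strands and names", {
  expect_error(feature_table(data.frame(name = "a", start = 0, end = 5,
                                        strand = "H"), 100), "coordinates")
  expect_error(feature_table(data.frame(name = "a", start = 1, end = 500,
                                        strand = "H"), 100), "coordinates")
  expect_error(feature_table(data.frame(name = "a", start = 1, end = 5,
                                        strand = "+"), 100), "strand")
  expect_error(feature_table(data.frame(name = c("a", "a"), start = c(1, 10),
                                        end = c(5, 20), strand = "H"), 100),
               "unique")
})

test_that("TSV round trip preserves the table", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_features(feats, tmp)
  back <- read_features(tmp, 16563)
  expect_equal(back$name, feats$name)
  expect_equal(back$start, feats$start)
  expect_equal(back$end, feats$end)
  expect_equal(back$strand, feats$strand)
})

test_that("GFF3 input maps +/- strands to H/L", {
  skip_if_not_installed("rtracklayer")
  tmp <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chrM", "test", "gene", "10", "50", ".", "+", ".",
                     "ID=g1;Name=geneA", sep = "\t"),
               paste("chrM", "test", "gene", "60", "90", ".", "-", ".",
                     "ID=g2;Name=geneB", sep = "\t")), tmp)
  tab <- read_features(tmp, 100)
  expect_equal(tab$name, c("geneA", "geneB"))
  expect_equal(tab$strand, c("H", "L"))
  expect_equal(tab$start, c(10L, 60L))
})
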