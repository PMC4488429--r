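test_that("constructed end overlaps are recovered exactly (brute-force checked)", {
  set.seed(41)
  core <- random_dna(5000)
  # k - 1 = 74 style construction
  contig <- paste0(core, substr(core, 1, 74))
  expect_equal(find_end_overlap(contig, 20), 74L)
  expect_equal(find_end_overlap(contig, 20), oracle_end_overlap(contig, 20))

  # sampled overlap lengths across the full 20..200 range vs brute force
  for (m in c(20, 21, 37, 100, 199, 200)) {
    ctg <- paste0(core, substr(core, 1, m))
    expect_equal(find_end_overlap(ctg, 20), m)
    expect_equal(find_end_overlap(ctg, 20), oracle_end_overlap(ctg, 20))
  }
})

test_that("sequences without repeated ends yield no overlap", {
  set.seed(42)
  s <- random_dna(3000)
  got <- find_end_overlap(s, 20)
  expect_identical(got, oracle_end_overlap(s, 20))
  # a short contig cannot self-overlap
  expect_identical(find_end_overlap(random_dna(30), 20), NA_integer_)
  expect_error(find_end_overlap(s, 0), ">= 1")
})

test_that("mismatch-tolerant overlap mode accepts bounded divergence", {
  set.seed(43)
  core <- random_dna(2000)
  ov <- substr(core, 1, 100)
  substr(ov, 50, 50) <- if (substr(ov, 50, 50) == "A") "C" else "A"
  contig <- paste0(core, ov)   # one mismatch in a 100 bp overlap
  expect_identical(find_end_overlap(contig, 20, 0), NA_integer_)
  expect_equal(find_end_overlap(contig, 20, 0.02), 100L)
})

test_that("circularize removes the overlap exactly once and feeds a stable canonical form", {
  set.seed(44)
  s <- random_dna(4000)
  contig <- paste0(s, substr(s, 1, 100))
  circ <- circularize(contig, 20)
  expect_equal(nchar(circ), 4000L)
  expect_equal(circ, s)
  expect_identical(circularize(random_dna(500), 20), NA_character_)

  # re-linearizing the circle elsewhere gives the same canonical form
  can0 <- canonicalize(circ)$canonical_seq
  for (off in c(1, 777, 3999)) {
    rot <- paste0(substr(s, off + 1, 4000), substr(s, 1, off))
    contig2 <- paste0(rot, substr(rot, 1, 80))
    expect_equal(canonicalize(circularize(contig2, 20))$canonical_seq, can0)
  }
})

test_that("canonicalization is rotation- and strand-invariant and idempotent", {
  set.seed(45)
  s <- random_dna(1000)
  can <- canonicalize(s)
  for (i in c(0, 1, 500, 999)) {
    rot <- paste0(substr(s, i + 1, 1000), substr(s, 1, i))
    expect_equal(canonicalize(rot)$canonical_seq, can$canonical_seq)
  }
  expect_equal(canonicalize(revcomp(s))$canonical_seq, can$canonical_seq)
  # fixed point
  expect_equal(canonicalize(can$canonical_seq)$canonical_seq, can$canonical_seq)
  expect_equal(canonicalize(can$canonical_seq)$strand_form, "FORWARD")
  expect_error(canonicalize(""), "empty")
})

test_that("minimal rotation matches brute force over all 2L rotations", {
  set.seed(46)
  for (i in 1:200) {
    s <- random_dna(60)
    expect_equal(canonicalize(s)$canonical_seq, oracle_canonical_rotation(s))
  }
  # degenerate and periodic cases
  for (s in c("A", "AC", "ACAC", "AAAT", strrep("ACGT", 5))) {
    expect_equal(canonicalize(s)$canonical_seq, oracle_canonical_rotation(s))
  }
})

test_that("size filter keeps the inclusive window", {
  cands <- data.frame(canonical_seq = c("A", "B", "C", "D"),
                      length = c(16499L, 16500L, 16563L, 16701L),
                      source_k = 61L, source_pool = "x",
                      strand_form = "FORWARD", stringsAsFactors = FALSE)
  kept <- size_filter(cands)
  expect_equal(kept$length, c(16500L, 16563L))
  expect_equal(nrow(size_filter(cands[0, ])), 0L)
  expect_error(size_filter(cands, 10, 5), "<=")
})

test_that("rotation/revcomp copies of one genome form a single cluster with strand counts", {
  set.seed(47)
  g <- random_dna(500)
  rots <- c(0, 17, 100, 230)
  fwd <- vapply(rots, function(i) paste0(substr(g, i + 1, 500), substr(g, 1, i)),
                character(1))
  rev3 <- vapply(c(5, 50, 499), function(i) {
    r <- revcomp(g)
    paste0(substr(r, i + 1, 500), substr(r, 1, i))
  }, character(1))
  cands <- do.call(rbind, lapply(seq_along(c(fwd, rev3)), function(i) {
    x <- c(fwd, rev3)[i]
    can <- canonicalize(x)
    data.frame(canonical_seq = can$canonical_seq, length = nchar(x),
               source_k = 61L + 2L * i, source_pool = "QV20_PE+SE",
               strand_form = can$strand_form, stringsAsFactors = FALSE)
  }))
  clusters <- cluster_candidates(cands)
  expect_length(clusters, 1L)
  expect_equal(nrow(clusters[[1]]$members), 7L)
  expect_equal(clusters[[1]]$n_forward + clusters[[1]]$n_reverse, 7L)
  # strand forms split between the two source orientations
  expect_true(clusters[[1]]$n_forward %in% c(3L, 4L))
})

test_that("clustering is by exact identity and cluster sizes sum to the input", {
  set.seed(48)
  g1 <- random_dna(300); g2 <- random_dna(300); g3 <- random_dna(300)
  mk <- function(s, n) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      can <- canonicalize(s)
      data.frame(canonical_seq = can$canonical_seq, length = nchar(s),
                 source_k = 61L, source_pool = "p", strand_form = can$strand_form,
                 stringsAsFactors = FALSE)
    }))
  }
  near <- g1
  substr(near, 150, 150) <- if (substr(near, 150, 150) == "G") "T" else "G"
  cands <- rbind(mk(g1, 5), mk(g2, 1), mk(g3, 1), mk(near, 1))
  clusters <- cluster_candidates(cands)
  expect_length(clusters, 4L)
  sizes <- vapply(clusters, function(cl) nrow(cl$members), integer(1))
  expect_equal(sizes[1], 5L)
  expect_equal(sum(sizes), nrow(cands))
  # the 1-substitution neighbour stays a singleton
  expect_true(canonicalize(near)$canonical_seq %in%
                vapply(clusters[-1], `[[`, character(1), "representative"))
})

test_that("consensus selection picks the largest cluster and refuses ties", {
  set.seed(49)
  g1 <- random_dna(300); g2 <- random_dna(300)
  mk <- function(s, n, k0 = 61L) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      can <- canonicalize(s)
      data.frame(canonical_seq = can$canonical_seq, length = nchar(s),
                 source_k = k0 + 2L * i, source_pool = "QV20_PE",
                 strand_form = can$strand_form, stringsAsFactors = FALSE)
    }))
  }
  clusters <- cluster_candidates(rbind(mk(g1, 7), mk(g2, 1)))
  cons <- select_consensus(clusters)
  expect_equal(cons$support, 7L)
  expect_equal(cons$sequence, canonicalize(g1)$canonical_seq)
  expect_equal(cons$cluster_sizes, c(7L, 1L))

  expect_error(select_consensus(list()), "no candidate")
  tied <- cluster_candidates(rbind(mk(g1, 3), mk(g2, 3)))
  err <- tryCatch(select_consensus(tied), error = function(e) e)
  expect_s3_class(err, "mitoforge_tie")
  expect_length(err$representatives, 2L)
})

test_that("rotate_like recovers the reference's linearization point and strand", {
  set.seed(50)
  g <- random_dna(800)
  rot <- paste0(substr(g, 301, 800), substr(g, 1, 300))
  expect_equal(rotate_like(rot, g), g)
  expect_equal(rotate_like(revcomp(rot), g), g)
})
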