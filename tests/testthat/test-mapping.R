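# Read placement, link evidence, long-read alignment filtering and
# barcode counting.

make_lib <- function(r1, r2, type = "paired", insert = 400L) {
  structure(list(reads1 = r1, reads2 = r2,
                 spec = library_spec(type, read_len = max(nchar(r1)),
                                     insert_mean = insert, coverage = 1),
                 placements = NULL),
            class = "read_library")
}

test_that("reads place by unique exact seeds; duplicated seeds never place", {
  set.seed(21)
  nodes <- c(random_dna(500), random_dna(500))
  # plant a duplicate 40-mer in both nodes
  dup <- random_dna(40)
  substr(nodes[1], 101, 140) <- dup
  substr(nodes[2], 301, 340) <- dup
  lib <- make_lib(substring(nodes[1], 201, 300), substring(nodes[1], 350, 449))
  mp <- map_short_reads(nodes, lib)
  p1 <- mp$placements[mp$placements$mate == 1L, ]
  expect_true(all(p1$node == 1L))
  expect_equal(p1$rstart[1], 200L)
  # a read that is exactly the planted duplicate: no placement anywhere
  lib_dup <- make_lib(dup, revcomp(dup))
  mp2 <- map_short_reads(nodes, lib_dup)
  expect_equal(nrow(mp2$placements), 0L)
  # uniqueness restored by extending the seed to 64/96
  ext <- substring(nodes[1], 101, 196) # dup + unique continuation
  mp3 <- map_short_reads(nodes, make_lib(ext, revcomp(ext)))
  expect_true(any(mp3$placements$seed_len > 32L))
  expect_true(all(mp3$placements$node == 1L))
})

test_that("a read straddling two nodes emits a single-read link with the layout gap", {
  set.seed(22)
  a <- random_dna(300)
  b <- random_dna(300)
  read <- paste0(substring(a, 205, 300), substring(b, 1, 96))
  lib <- make_lib(read, revcomp(read))
  mp <- map_short_reads(c(a, b), lib)
  lk <- mp$links[mp$links$class == "single", ]
  expect_gte(nrow(lk), 1L)
  expect_equal(sort(c(lk$a[1], lk$b[1])), c(1L, 2L))
  expect_equal(lk$gap[1], 0) # adjacent in the read
  expect_equal(lk$ea[1], 1L) # leaves a's 3' end
  expect_equal(lk$eb[1], 0L) # enters b's 5' end
})

test_that("read pairs yield links with insert-derived gaps", {
  set.seed(23)
  a <- random_dna(400)
  gap_truth <- 150L
  b <- random_dna(400)
  frag_mid <- random_dna(gap_truth)
  frag <- paste0(a, frag_mid, b) # insert spans a..b
  insert <- nchar(frag)
  r1 <- substring(frag, 1, 100)
  r2 <- revcomp(substring(frag, insert - 99, insert))
  lib <- make_lib(r1, r2, insert = insert)
  mp <- map_short_reads(c(a, b), lib)
  lk <- mp$links[mp$links$class == "paired-end", ]
  expect_equal(nrow(lk), 1L)
  expect_equal(lk$gap[1], gap_truth)
  # mate-pair library: outward reads, same link after normalisation
  libmp <- make_lib(revcomp(r1), revcomp(r2), type = "mate",
                    insert = insert)
  mp2 <- map_short_reads(c(a, b), libmp)
  lk2 <- mp2$links[mp2$links$class == "mate-pair", ]
  expect_equal(lk2$gap[1], gap_truth)
})

test_that("long-alignment filter applies identity/length/coverage bounds", {
  aln <- data.frame(query = "q", qlen = 10000L,
                    qstart = c(0L, 2000L), qend = c(1000L, 2500L),
                    target = c(1L, 2L), tlen = c(1000L, 1000L),
                    tstart = 0L, tend = c(1000L, 500L),
                    strand = "+", matches = c(800L, 425L),
                    aln_len = c(1000L, 500L))
  # identity 0.80, length 1000, coverage 0.1: kept (boundary)
  # identity 0.85, length 500, coverage 0.5: fails both sub-conditions
  out <- filter_long_alignments(aln, k = 32)
  expect_equal(nrow(out), 1L)
  expect_equal(out$target, 1L)
})

test_that("greedy selection keeps the higher-matching of overlapping alignments", {
  aln <- data.frame(query = "q", qlen = 3000L,
                    qstart = c(0L, 100L), qend = c(1100L, 1200L),
                    target = c(1L, 2L), tlen = 2000L, tstart = 0L,
                    tend = c(1100L, 1100L), strand = "+",
                    matches = c(900L, 800L), aln_len = c(1100L, 1100L))
  out <- filter_long_alignments(aln, k = 32)
  expect_equal(out$matches, 900L)
})

test_that("greedy selection matches the step-by-step oracle on random sets", {
  set.seed(24)
  for (trial in 1:50) {
    n <- sample(2:8, 1)
    qs <- sort(sample(0:5000, n))
    aln <- data.frame(query = "q", qlen = 10000L, qstart = qs,
                      qend = qs + sample(500:2000, n, TRUE),
                      target = seq_len(n), tlen = 5000L, tstart = 0L,
                      tend = 1000L, strand = "+",
                      matches = sample(500:1500, n), aln_len = 1500L)
    aln$tend <- aln$qend - aln$qstart
    got <- filter_long_alignments(aln, k = 32, min_id = 0, min_len = 0,
                                  min_cov = 0)
    expect_equal(sort(got$target), aln$target[oracle_greedy_select(aln, 32)])
  }
})

test_that("long-read positions are length-weighted means; spans give links", {
  aln <- data.frame(query = "q", qlen = 5000L,
                    qstart = c(0L, 1000L), qend = c(100L, 1300L),
                    target = 1L, tlen = 5000L, tstart = c(0L, 1000L),
                    tend = c(100L, 1300L), strand = "+",
                    matches = c(95L, 290L), aln_len = c(100L, 300L))
  pos <- long_read_position(aln)
  expect_equal(pos$positions$position, (0 * 100 + 1000 * 300) / 400)
  # spanning read: node A then 500 query bases then node B
  aln2 <- data.frame(query = "q", qlen = 5000L,
                     qstart = c(0L, 1500L), qend = c(1000L, 2500L),
                     target = c(1L, 2L), tlen = 2000L,
                     tstart = 0L, tend = 1000L, strand = "+",
                     matches = c(950L, 960L), aln_len = 1000L)
  lr <- long_read_position(aln2)
  expect_equal(nrow(lr$links), 1L)
  expect_equal(lr$links$gap, 500L)
  expect_equal(lr$links$matches, 950 + 960)
})

test_that("barcode counts drop entries at or below three reads", {
  set.seed(25)
  node <- random_dna(600)
  mk <- function(n, bc, offset) {
    r <- substring(node, offset + seq_len(n) * 10, offset + seq_len(n) * 10 + 99)
    names(r) <- sprintf("r%d_%d BX:Z:%s", offset, seq_len(n), bc)
    r
  }
  lib <- structure(list(reads1 = c(mk(3, "BC1", 0), mk(4, "BC2", 100)),
                        reads2 = NULL,
                        spec = library_spec("linked", coverage = 1),
                        placements = NULL), class = "read_library")
  tab <- count_barcodes(lib, node)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$barcode, "BC2")
  expect_equal(tab$count, 4L)
  # the space variant of the tag is accepted too
  nm <- names(lib$reads1)
  names(lib$reads1) <- sub("BX:Z:", "BX: Z:", nm)
  tab2 <- count_barcodes(lib, node)
  expect_equal(tab2$count, 4L)
  # reads without tags: empty table with a warning
  names(lib$reads1) <- sprintf("plain%d", seq_along(lib$reads1))
  expect_warning(tab3 <- count_barcodes(lib, node), "barcode")
  expect_equal(nrow(tab3), 0L)
})

test_that("libraries are processed in ascending insert order", {
  set.seed(26)
  src <- random_dna(800)
  mk_pairs <- function(ins, seed) {
    set.seed(seed)
    st <- sample(1:(800 - ins), 30, TRUE)
    make_lib(substring(src, st, st + 99),
             revcomp(substring(src, st + ins - 100, st + ins - 1)),
             insert = ins)
  }
  big <- mk_pairs(600, 1)
  small <- mk_pairs(300, 2)
  mp <- map_short_reads(src, list(big, small))
  expect_equal(mp$lib_order, c(300, 600))
})
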