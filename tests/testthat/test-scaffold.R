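# Scaffold graph construction, joins, and haplotype synteny-based
# correction (division boundaries, edge-contig rule, bubble pairing).

test_that("division boundaries follow the majority-counterpart score", {
  d <- compute_division(c(2, 0, 2), c(100, 50, 100))
  expect_equal(d$B_max, 2)
  expect_equal(d$d_min, 1L)
  expect_equal(d$d_max, 3L)
  expect_equal(d$S, c(-100, -100, -200))
  expect_false(d$changed)

  d2 <- compute_division(c(2, 3, 3, 2, 2), c(10, 40, 40, 10, 10))
  expect_equal(d2$B_max, 3) # L_sum(3) = 80 > L_sum(2) = 30
  expect_equal(d2$d_min, 2L)
  expect_equal(d2$d_max, 3L)

  d3 <- compute_division(c(5, 2, 5), c(10, 100, 10))
  expect_equal(d3$d_min, 2L)

  expect_null(compute_division(c(0, 0), c(10, 10)))
})

test_that("compute_division matches the brute-force recursion on random vectors", {
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(1:20, 1)
    b <- sample(0:5, n, replace = TRUE)
    l <- sample(1:100, n, replace = TRUE)
    got <- compute_division(b, l)
    exp <- oracle_division(b, l)
    if (is.null(exp)) {
      expect_null(got)
    } else {
      expect_equal(got$B_max, exp$B_max)
      expect_equal(got$d_min, exp$d_min)
      expect_equal(got$d_max, exp$d_max)
    }
  }
})

test_that("bundles respect the minimum-link threshold and median gap", {
  set.seed(42)
  contigs <- data.frame(seq = c(random_dna(500), random_dna(500),
                                random_dna(500)), depth = 10)
  ss <- scaffold_init(contigs)
  mk_links <- function(a, ea, b, eb, gaps) {
    data.frame(a = a, ea = ea, b = b, eb = eb, gap = gaps,
               class = "paired-end", lib = 1L, matches = NA_real_)
  }
  links <- mk_links(1L, 1L, 2L, 0L, c(180, 200, 210, 190, 220))
  sg <- build_scaffold_graph(ss, links, min_link = 2L)
  expect_equal(nrow(sg$bundles), 1L)
  expect_equal(sg$bundles$support, 5L)
  expect_equal(sg$bundles$gap, 200)
  j <- haplotangle:::join_unambiguous(ss, sg$bundles)
  expect_equal(j$n_joined, 1L)
  seqs <- scaffold_seqs(j$ss)
  joined <- seqs[which.max(nchar(seqs))]
  expect_equal(nchar(joined), 500 + 200 + 500)
  expect_equal(substring(joined, 501, 700), strrep("N", 200))
  # a single link is below the default threshold: no bundle, no join
  sg1 <- build_scaffold_graph(ss, mk_links(1L, 1L, 2L, 0L, 200),
                              min_link = 2L)
  expect_equal(nrow(sg1$bundles), 0L)
  # two incompatible candidate joins from one end: ambiguity, no join
  links3 <- rbind(mk_links(1L, 1L, 2L, 0L, c(200, 200, 200)),
                  mk_links(1L, 1L, 3L, 0L, c(190, 210, 200)))
  sg3 <- build_scaffold_graph(ss, links3, min_link = 2L)
  j3 <- haplotangle:::join_unambiguous(ss, sg3$bundles)
  expect_equal(j3$n_joined, 0L)
})

test_that("short scaffolds are excluded unless they contain anchor bubbles", {
  set.seed(43)
  contigs <- data.frame(seq = c(random_dna(1000), random_dna(100),
                                random_dna(100)), depth = 10)
  ss <- scaffold_init(contigs)
  sg <- build_scaffold_graph(ss, haplotangle:::empty_links(),
                             min_link = 2L, short_len = 400L,
                             anchored_contigs = 3L)
  expect_equal(sg$excluded, 2L) # contig 3 is anchored, contig 1 is long
})

test_that("scaffold-level crosses untangle with link evidence", {
  set.seed(44)
  # centre contig 5, externals 1..4; parallel solution supported 8:1
  contigs <- data.frame(seq = vapply(c(800, 800, 800, 800, 600),
                                     random_dna, character(1)),
                        depth = c(10, 10, 10, 10, 20))
  ss <- scaffold_init(contigs)
  mk <- function(a, ea, b, eb, n, gap) {
    data.frame(a = a, ea = ea, b = b, eb = eb, gap = gap,
               class = "mate-pair", lib = 1L, matches = NA_real_)[
                 rep(1, n), ]
  }
  links <- rbind(mk(1L, 1L, 5L, 0L, 5L, 50), mk(2L, 1L, 5L, 0L, 5L, 50),
                 mk(5L, 1L, 3L, 0L, 5L, 50), mk(5L, 1L, 4L, 0L, 5L, 50),
                 mk(1L, 1L, 3L, 0L, 8L, 700), mk(2L, 1L, 4L, 0L, 8L, 700),
                 mk(1L, 1L, 4L, 0L, 1L, 700))
  sg <- build_scaffold_graph(ss, links, min_link = 2L)
  u <- untangle_scaffold(sg, c_hetero = 10)
  expect_equal(u$n_untangled, 1L)
  lens <- sort(nchar(scaffold_seqs(u$ss)), decreasing = TRUE)
  expect_equal(length(lens), 2L) # two haplotype scaffolds
  # scores 2 vs 1 stays unresolved
  links2 <- rbind(links[links$gap == 50, ],
                  mk(1L, 1L, 3L, 0L, 2L, 700), mk(1L, 1L, 4L, 0L, 1L, 700))
  sg2 <- build_scaffold_graph(ss, links2, min_link = 2L)
  u2 <- untangle_scaffold(sg2, c_hetero = 10)
  expect_equal(u2$n_untangled, 0L)
})

test_that("synteny correction divides at internal contigs matching edge contigs", {
  set.seed(45)
  # anchors a1, a2, a3; node X = [a1 .. a2] (a2 at X's edge), node Y
  # carries the counterpart of a2 internally followed by foreign sequence
  br <- function() random_dna(60)
  a1 <- c(br(), br()); a2 <- c(br(), br()); a3 <- c(br(), br())
  anc <- hand_anchors(c(a1[1], a2[1], a3[1]), c(a1[2], a2[2], a3[2]))
  fill <- function(n) random_dna(n)
  x <- paste0(a1[1], fill(200), a2[1])
  y <- paste0(a1[2], fill(200), a2[2], fill(300), a3[2])
  z <- paste0(a3[1], fill(100))
  ss <- haplotangle:::scaffold_from_seqs(
    c(x, y, z), list(contigs = data.frame(seq = character(0),
                                          len = integer(0),
                                          depth = numeric(0))))
  sc <- synteny_correct(ss, anc)
  expect_gt(sc$n_divisions, 0L)
  out <- scaffold_seqs(sc$ss)
  # base content is conserved up to re-partitioning
  expect_equal(sum(nchar(gsub("N", "", out))),
               sum(nchar(gsub("N", "", c(x, y, z)))))
  # y is divided right after its a2 occurrence
  expect_true(any(out == paste0(a1[2], substring(y, 61, 260), a2[2])))
})

test_that("bubble pairing assigns primary by non-N bases with id tie-break", {
  set.seed(46)
  br <- function() random_dna(60)
  a1 <- c(br(), br()); a2 <- c(br(), br())
  anc <- hand_anchors(c(a1[1], a2[1]), c(a1[2], a2[2]))
  x <- paste0(a1[1], random_dna(400), a2[1])
  y <- paste0(a1[2], random_dna(300), a2[2])
  free <- random_dna(500)
  ss <- haplotangle:::scaffold_from_seqs(
    c(x, y, free), list(contigs = data.frame(seq = character(0),
                                             len = integer(0),
                                             depth = numeric(0))))
  pb <- pair_bubbles(ss, anc)
  b <- pb$blocks
  expect_equal(sum(b$role == "primary"), 1L)
  expect_equal(b$seq[b$role == "primary"], x) # more non-N bases
  expect_equal(b$seq[b$role == "secondary"], y)
  expect_equal(b$seq[b$role == "nonbubble"], free)
  expect_true(all(nchar(gsub("N", "", b$seq[b$role == "primary"])) >=
                    nchar(gsub("N", "", b$seq[b$role == "secondary"]))))
})
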