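# de Bruijn core: counting, cutoff estimation, graph construction and the
# increasing-k schedule.

test_that("k-mer counting enumerates canonical windows", {
  h <- count_kmers("ACGTA", 4)
  expect_equal(nrow(h$table), 2L)
  expect_equal(unname(h$counts), c(2L))
  h2 <- count_kmers(c("AAAA", "AAAA"), 4)
  expect_equal(h2$table$count, 2L)
  expect_equal(h2$counts, c(0L, 1L))
  expect_error(count_kmers("ACG", 10), "exceeds")
})

test_that("counting agrees with brute-force enumeration and conserves windows", {
  set.seed(5)
  src <- random_dna(1000)
  starts <- seq(1, 901, by = 10) # 10x error-free 100-bp reads
  reads <- substring(src, starts, starts + 99)
  h <- count_kmers(reads, 21)
  oracle <- oracle_count_kmers(reads, 21)
  got <- setNames(h$table$count, h$table$kmer)[names(oracle)]
  expect_equal(unname(got), unname(oracle))
  # conservation: sum occurrence x count over the histogram = total windows
  expect_equal(sum(seq_along(h$counts) * h$counts), h$windows)
  # histogram mode near the expected per-k-mer depth
  mode_occ <- which.max(h$counts)
  expected_depth <- length(reads) * (100 - 21 + 1) / (1000 - 21 + 1)
  expect_lte(abs(mode_occ - expected_depth), 3)
})

test_that("initial cutoff takes half the leftmost local minimum", {
  expect_equal(initial_cutoff(c(100, 50, 10, 20, 80)), 1L)
  # local minimum at occurrence 8
  h <- c(100, 90, 80, 70, 60, 50, 40, 30, 60, 90)
  expect_equal(initial_cutoff(h), 4L)
  expect_equal(initial_cutoff(c(100, 20, 30)), 1L)
  expect_warning(v <- initial_cutoff(c(100, 80, 60, 40)), "local minimum")
  expect_equal(v, 1L)
})

test_that("a non-repetitive source assembles into one straight node", {
  set.seed(11)
  src <- random_dna(1500)
  reads <- substring(src, seq(1, 1401, 7), seq(1, 1401, 7) + 99)
  g <- build_graph(count_kmers(reads, 31))
  expect_equal(nrow(g$nodes), 1L)
  expect_false(g$nodes$junction[1])
  expect_true(g$nodes$seq[1] == src ||
                g$nodes$seq[1] == rc_oracle(src))
})

test_that("a central SNV yields a simple bubble and kept branches", {
  set.seed(12)
  a <- random_dna(200)
  b <- a
  substr(b, 100, 100) <- if (substr(a, 100, 100) == "A") "C" else "A"
  starts <- seq(1, 151, 3)
  reads <- c(substring(a, starts, starts + 49),
             substring(b, starts, starts + 49))
  g <- build_graph(count_kmers(reads, 21))
  expect_equal(sum(g$nodes$junction), 2L)
  expect_equal(sum(!g$nodes$junction), 4L) # two flanks + two branches
  branches <- g$nodes[!g$nodes$junction & g$nodes$len == 2 * 21 - 1, ]
  expect_equal(nrow(branches), 2L)
  expect_equal(nrow(g$edges), 6L)
})

test_that("an exact two-copy repeat collapses with doubled coverage", {
  set.seed(13)
  unit <- random_dna(80)
  src <- paste0(random_dna(200), unit, random_dna(200), unit,
                random_dna(200))
  starts <- seq(1, nchar(src) - 49, 2)
  reads <- substring(src, starts, starts + 49)
  g <- build_graph(count_kmers(reads, 21))
  rep_node <- g$nodes[!g$nodes$junction &
                        vapply(g$nodes$seq, function(s)
                          grepl(s, unit, fixed = TRUE) ||
                            grepl(rc_oracle(s), unit, fixed = TRUE),
                          logical(1)), ]
  expect_gte(nrow(rep_node), 1L)
  flank_cov <- median(g$nodes$cov[!g$nodes$junction &
                                    g$nodes$len > 100])
  expect_gt(max(rep_node$cov), 1.6 * flank_cov)
})

test_that("build_graph matches the brute-force constructor on small inputs", {
  set.seed(14)
  for (trial in 1:5) {
    a <- random_dna(600)
    b <- a
    for (p in sample(50:550, 6)) # a few SNVs
      substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(a, p, p)), 1)
    starts <- seq(1, 501, 4)
    reads <- c(substring(a, starts, starts + 99),
               substring(b, starts, starts + 99))
    g <- build_graph(count_kmers(reads, 25))
    bf <- oracle_dbg(reads, 25)
    got <- sort(vapply(g$nodes$seq[!g$nodes$junction], function(s)
      min(s, rc_oracle(s)), character(1), USE.NAMES = FALSE))
    expect_equal(got, bf$straight)
    expect_equal(sum(g$nodes$junction), bf$n_junction)
  }
})

test_that("raise_k preserves bubbles and rejects non-increasing k", {
  set.seed(15)
  a <- random_dna(2000)
  b <- a
  for (p in seq(100, 1900, 50))
    substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(a, p, p)), 1)
  starts <- seq(1, 1851, 3)
  reads <- c(substring(a, starts, starts + 149),
             substring(b, starts, starts + 149))
  g32 <- build_graph(count_kmers(reads, 32))
  expect_error(raise_k(g32, reads, 32), "exceed")
  junctions <- sum(g32$nodes$junction)
  g <- g32
  for (k in c(52, 72)) {
    g <- raise_k(g, reads, k)
    expect_lte(sum(g$nodes$junction), junctions)
    junctions <- sum(g$nodes$junction)
  }
  # heterozygous bubbles persist at the final k
  expect_gt(sum(g$nodes$junction), 0)
  # homozygous source: k-invariant single node
  reads_h <- substring(a, starts, starts + 149)
  gh32 <- build_graph(count_kmers(reads_h, 32))
  gh <- raise_k(gh32, reads_h, 72)
  expect_equal(nrow(gh$nodes), 1L)
  expect_true(gh$nodes$seq[1] %in% c(gh32$nodes$seq[1],
                                     rc_oracle(gh32$nodes$seq[1])))
})

test_that("straight-node walks reproduce source substrings (round trip)", {
  set.seed(16)
  src <- random_dna(3000)
  starts <- seq(1, 2901, 5)
  reads <- substring(src, starts, starts + 99)
  g <- build_graph(count_kmers(reads, 31))
  for (s in g$nodes$seq[!g$nodes$junction]) {
    expect_true(grepl(s, src, fixed = TRUE) ||
                  grepl(rc_oracle(s), src, fixed = TRUE))
  }
})

test_that("GFA round trip preserves the graph", {
  set.seed(17)
  a <- random_dna(300)
  b <- a
  substr(b, 150, 150) <- if (substr(a, 150, 150) == "G") "T" else "G"
  starts <- seq(1, 251, 2)
  reads <- c(substring(a, starts, starts + 49),
             substring(b, starts, starts + 49))
  g <- build_graph(count_kmers(reads, 21))
  f <- tempfile(fileext = ".gfa")
  write_gfa(g, f)
  g2 <- read_gfa(f)
  expect_equal(g2$k, g$k)
  expect_equal(g2$nodes$seq, g$nodes$seq)
  expect_equal(g2$nodes$junction, g$nodes$junction)
  expect_equal(nrow(g2$edges), nrow(g$edges))
  unlink(f)
})
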