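# Assembly statistics, fragment recall/precision, het 1k-mer pairs,
# phased rates, reference-absent screening, switch errors.

test_that("NG50/LG50 follow the cumulative-length definition", {
  s <- assembly_stats(vapply(c(5, 4, 3, 2, 1) * 10, function(n)
    strrep("A", n), character(1)), genome_size = 100, min_len = 0)
  expect_equal(s$scaffold_ng50, 40L)
  expect_equal(s$scaffold_lg50, 2L)
  one <- assembly_stats(strrep("C", 1000), genome_size = 1000, min_len = 0)
  expect_equal(one$scaffold_ng50, 1000L)
  expect_equal(one$scaffold_lg50, 1L)
  # contigs split at N runs
  ns <- assembly_stats("AAAANNAAA", genome_size = 6, min_len = 0)
  expect_equal(ns$contig_ng50, 4L)
  expect_equal(sort(unlist(lapply("AAAANNAAA", function(x)
    nchar(haplotangle:::split_at_gaps(x))))), c(3L, 4L))
  # total below half the genome size: undefined, flagged 0
  und <- assembly_stats(strrep("A", 100), genome_size = 1000, min_len = 0)
  expect_equal(und$scaffold_ng50, 0L)
  expect_true(und$undefined)
  # the >= 500 bp filter
  filt <- assembly_stats(c(strrep("A", 499), strrep("A", 600)),
                         genome_size = 1000)
  expect_equal(filt$n_seq, 1L)
})

test_that("assembly statistics match sort-and-scan brute force", {
  set.seed(61)
  for (i in 1:1000) {
    lens <- sample(1:5000, sample(1:30, 1), replace = TRUE)
    g <- sample(1000:100000, 1)
    s <- assembly_stats(vapply(lens, function(n) strrep("A", n),
                               character(1)), g, min_len = 0)
    o <- oracle_ng50(lens, g)
    expect_equal(s$scaffold_ng50, o$ng50)
    expect_equal(s$scaffold_lg50, o$lg50)
  }
})

test_that("fragment recall and precision count exact strand-symmetric matches", {
  set.seed(62)
  truth <- c(random_dna(5000), random_dna(5000))
  blocks <- truth
  rp <- fragment_recall_precision(blocks, truth, 1000)
  expect_equal(rp$recall, 1)
  expect_equal(rp$precision, 1)
  expect_equal(rp$f_measure, 1)
  # half the truth verbatim
  rp2 <- fragment_recall_precision(truth[1], truth, 1000)
  expect_equal(rp2$recall, 0.5)
  # one mismatch breaks a fragment
  mut <- truth[1]
  substr(mut, 500, 500) <- setdiff(c("A", "C", "G", "T"),
                                   substr(mut, 500, 500))[1]
  rp3 <- fragment_recall_precision(mut, truth[1], 1000)
  expect_equal(rp3$precision, 4 / 5)
  # strand symmetry: reverse-complementing blocks changes nothing
  rp4 <- fragment_recall_precision(revcomp(blocks), truth, 1000)
  expect_equal(rp4$recall, 1)
  expect_equal(rp4$precision, 1)
})

test_that("het 1k-mer pairs reproduce truth-table counts on planted SNVs", {
  set.seed(63)
  dip <- simulate_diploid(diploid_spec(length = 50000, snv_rate = 0.01,
                                       indel_rate = 0, seed = 631))
  pairs <- build_het_pairs(c(hapA = dip$hap_a, hapB = dip$hap_b),
                           min_exact = 1)
  expect_equal(nrow(pairs), 50L)
  # per-block heterozygosity equals direct counting from the truth table
  v <- dip$variants$pos
  for (i in seq_len(nrow(pairs))) {
    n_snv <- sum(v > pairs$pos[i] & v <= pairs$pos[i] + 1000)
    expect_equal(pairs$het[i], n_snv / 1000)
  }
  # identical duplicate sequences: near-exact, zero pairs
  same <- random_dna(20000)
  expect_equal(nrow(build_het_pairs(c(a = same, b = same), min_exact = 1)),
               0L)
  # below the identity floor: zero pairs
  unrelated <- c(a = random_dna(20000), b = random_dna(20000))
  expect_equal(nrow(build_het_pairs(unrelated, min_exact = 1)), 0L)
})

test_that("the exact-match confirmation threshold filters single-copy pairs", {
  set.seed(64)
  dip <- simulate_diploid(diploid_spec(length = 20000, snv_rate = 0.01,
                                       indel_rate = 0, seed = 641))
  srcs <- c(hapA = dip$hap_a, hapB = dip$hap_b)
  p1 <- build_het_pairs(srcs, min_exact = 1)
  expect_gt(nrow(p1), 0L)
  # each locus occurs once: the default two-exact-match rule drops all
  p2 <- build_het_pairs(srcs, min_exact = 2)
  expect_equal(nrow(p2), 0L)
  # duplicated sources restore the confirmation
  p3 <- build_het_pairs(c(srcs, a2 = unname(srcs[1]), b2 = unname(srcs[2])),
                        min_exact = 2)
  expect_gt(nrow(p3), 0L)
})

test_that("phased rate requires both sides and bubble rate one bubble pair", {
  set.seed(65)
  pairs <- data.frame(seq1 = vapply(rep(1000, 4), random_dna, character(1)),
                      seq2 = vapply(rep(1000, 4), random_dna, character(1)),
                      het = 0.01, source = "hapA",
                      pos = c(0, 1000, 2000, 3000))
  blocks <- phased_block_set(
    primary = paste0(pairs$seq1[1], pairs$seq1[2], pairs$seq1[3]),
    secondary = paste0(pairs$seq2[1], pairs$seq2[2], revcomp(pairs$seq2[3])),
    nonbubble = pairs$seq1[4]) # pair 4: one side only
  pr <- phased_pair_rate(blocks, pairs, window = 1e6)
  expect_equal(pr$n_pairs, 4L)
  expect_equal(pr$phased_rate, 3 / 4)
  expect_equal(pr$bubble_rate, 3 / 4)
  # smaller windows split the rates
  pr2 <- phased_pair_rate(blocks, pairs, window = 2000)
  expect_equal(nrow(pr2), 2L)
})

test_that("switch errors and mis-assemblies are classified from fragments", {
  set.seed(66)
  dip <- simulate_diploid(diploid_spec(length = 20000, snv_rate = 0.02,
                                       indel_rate = 0, seed = 661))
  # a block identical to haplotype A: clean
  sw0 <- count_switch_errors(dip$hap_a, dip$hap_a, dip$hap_b)
  expect_equal(sw0$switches, 0L)
  expect_equal(sw0$misassemblies, 0L)
  # A-half followed by B-half at the same locus: one switch
  chim <- paste0(substring(dip$hap_a, 1, 10000),
                 substring(dip$hap_b, 10001, 20000))
  sw1 <- count_switch_errors(chim, dip$hap_a, dip$hap_b)
  expect_equal(sw1$switches, 1L)
  expect_equal(sw1$misassemblies, 0L)
  # an internal translocated segment: at least one mis-assembly
  tl <- paste0(substring(dip$hap_a, 1, 5000),
               substring(dip$hap_a, 12001, 14000),
               substring(dip$hap_a, 7001, 20000))
  sw2 <- count_switch_errors(tl, dip$hap_a, dip$hap_b)
  expect_gte(sw2$misassemblies, 1L)
  expect_equal(sw2$switches, 0L)
})

test_that("reference-absent bubbles pass all four filters exactly", {
  set.seed(67)
  ref <- random_dna(200000)
  novel_a <- random_dna(120000)
  # sample haplotypes carry the insertion; reference does not
  ins_at <- 100000L
  hap_a <- paste0(substring(ref, 1, ins_at), novel_a,
                  substring(ref, ins_at + 1))
  hap_b_novel <- novel_a
  for (p in sample(120000, 600)) # ~0.5% divergence between alleles
    substr(hap_b_novel, p, p) <- sample(c("A", "C", "G", "T"), 1)
  hap_b <- paste0(substring(ref, 1, ins_at), hap_b_novel,
                  substring(ref, ins_at + 1))
  truth <- c(substring(hap_a, seq(1, nchar(hap_a), 10000),
                       seq(10000, nchar(hap_a) + 9999, 10000)),
             substring(hap_b, seq(1, nchar(hap_b), 10000),
                       seq(10000, nchar(hap_b) + 9999, 10000)))
  truth <- truth[nchar(truth) >= 1000]
  # bubble 1: the insertion with 10-kbp flanks; bubble 2: reference-only
  b1p <- substring(hap_a, ins_at - 9999, ins_at + 130000)
  b1s <- substring(hap_b, ins_at - 9999, ins_at + 130000)
  b2p <- substring(ref, 10001, 130000)
  b2s <- b2p
  blocks <- phased_block_set(primary = c(b1p, b2p),
                             secondary = c(b1s, b2s))
  hits <- find_reference_absent_bubbles(blocks, ref, truth)
  expect_equal(hits$pair, 1L)
  expect_gte(hits$rate, 0.25)
  # a 50-kbp novel bubble fails the length filter
  small <- phased_block_set(primary = substring(novel_a, 1, 25000),
                            secondary = substring(hap_b_novel, 1, 25000))
  expect_equal(nrow(find_reference_absent_bubbles(small, ref, truth)), 0L)
  # null run: bubbles fully present in the reference report nothing
  null_blocks <- phased_block_set(primary = b2p, secondary = b2s)
  expect_equal(nrow(find_reference_absent_bubbles(null_blocks, ref, truth)),
               0L)
})
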