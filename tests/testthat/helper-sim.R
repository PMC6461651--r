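# Shared fixtures. The standard simulation mirrors the study conditions:
# a 200-kbp diploid at 1% background heterozygosity with one 10-kbp HDR at
# 5% divergence carrying an inversion, sequenced error-free with a 40x
# paired-end library (insert 400) and a 40x mate-pair library (insert
# 3000). Full-scale runs are cached so several test files can share them.

standard_spec <- function(seed) {
  diploid_spec(length = 200000L, snv_rate = 0.01, indel_rate = 5e-4,
               hdr = data.frame(start = 95001L, length = 10000L,
                                divergence = 0.05, inversion = TRUE),
               seed = seed)
}

standard_libs <- function(dip, seed, with_mp = TRUE) {
  libs <- list(simulate_reads(dip, library_spec(
    "paired", read_len = 150L, insert_mean = 400L, coverage = 40,
    error_rate = 0, seed = seed * 100L + 1L)))
  if (with_mp) {
    libs <- c(libs, list(simulate_reads(dip, library_spec(
      "mate", read_len = 150L, insert_mean = 3000L, coverage = 40,
      error_rate = 0, seed = seed * 100L + 2L))))
  }
  libs
}

# small fixture for quick end-to-end tests
small_run <- function(seed = 7L, genome = 20000L, with_mp = TRUE) {
  dip <- simulate_diploid(diploid_spec(length = genome, snv_rate = 0.01,
                                       indel_rate = 0, seed = seed))
  libs <- standard_libs(dip, seed, with_mp)
  res <- run_pipeline(libs, pipeline_config(genome_size = genome,
                                            consensus = FALSE))
  list(dip = dip, libs = libs, res = res)
}

.run_cache <- new.env(parent = emptyenv())

# full-scale standard run, cached across test files
std_run <- function(seed, with_mp = TRUE, consensus = FALSE) {
  key <- sprintf("s%d_%d_%d", seed, with_mp, consensus)
  if (!exists(key, envir = .run_cache)) {
    dip <- simulate_diploid(standard_spec(seed))
    libs <- standard_libs(dip, seed, with_mp)
    res <- run_pipeline(libs, pipeline_config(genome_size = 200000L,
                                              consensus = consensus))
    assign(key, list(dip = dip, res = res), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# hand-built graph: nodes given as (seq, depth, junction), edges as a
# 4-column matrix (a, ea, b, eb)
hand_graph <- function(k, seqs, depths, junction, edges) {
  nodes <- data.frame(seq = seqs, cov = depths, depth = depths,
                      junction = junction, stringsAsFactors = FALSE)
  ed <- if (is.null(edges) || nrow(edges) == 0L)
    data.frame(a = integer(0), ea = integer(0), b = integer(0),
               eb = integer(0))
  else data.frame(a = edges[, 1], ea = edges[, 2], b = edges[, 3],
                  eb = edges[, 4])
  haplotangle:::new_dbg(k, nodes, ed)
}

# anchor_set with explicit branch sequences
hand_anchors <- function(seq1, seq2, c_hetero = 10) {
  bub <- data.frame(b1 = seq_along(seq1), b2 = seq_along(seq1),
                    j1 = 0L, j2 = 0L, len1 = nchar(seq1),
                    len2 = nchar(seq2), depth1 = c_hetero,
                    depth2 = c_hetero, seq1 = seq1, seq2 = seq2,
                    anchor = TRUE, stringsAsFactors = FALSE)
  structure(list(bubbles = bub, c_hetero = c_hetero, r_upper = 1.75),
            class = "anchor_set")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
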