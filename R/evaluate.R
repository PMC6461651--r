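# Phasing evaluation: assembly statistics (NG50/LG50), heterozygous 1k-mer
# pair construction, fragment-based recall/precision/F-measure, per-window
# phased-pair rates, reference-absent bubble screening, and switch-error /
# mis-assembly counting. Exact matching is strand-symmetric throughout:
# assemblies are strand-arbitrary.

#' Assembly statistics (NG50/LG50, gap content)
#'
#' Sequences shorter than `min_len` are excluded. NG50 is the largest
#' length L such that sequences of length >= L together cover more than
#' half the genome size; LG50 is their number. Contig statistics are
#' computed after splitting sequences at runs of one or more `N`s.
#'
#' @param seqs character vector of scaffold/block sequences.
#' @param genome_size reference genome size in bp (> 0).
#' @param min_len minimum sequence length (default 500).
#' @return list of class `assembly_stats`: totals, scaffold and contig
#'   NG50/LG50, `%gaps`, counts. NG50 is 0 (flagged `undefined`) when the
#'   total does not reach half the genome size.
#' @export
assembly_stats <- function(seqs, genome_size, min_len = 500L) {
  stopifnot(genome_size > 0)
  seqs <- seqs[nchar(seqs) >= min_len]
  scaf_lens <- nchar(seqs)
  n_bases <- sum(scaf_lens)
  gap_bases <- sum(nchar(seqs)) - sum(nchar(gsub("N", "", seqs, fixed = TRUE)))
  contig_lens <- unlist(lapply(seqs, function(s) nchar(split_at_gaps(s))))
  ng <- function(lens) {
    if (length(lens) == 0L) return(list(ng50 = 0L, lg50 = 0L,
                                        undefined = TRUE))
    lens <- sort(lens, decreasing = TRUE)
    cum <- cumsum(as.numeric(lens))
    if (!any(cum > genome_size / 2))
      return(list(ng50 = 0L, lg50 = 0L, undefined = TRUE))
    i <- which(cum > genome_size / 2)[1]
    list(ng50 = lens[i], lg50 = i, undefined = FALSE)
  }
  s <- ng(scaf_lens)
  cg <- ng(contig_lens)
  structure(list(total = n_bases, n_seq = length(seqs),
                 scaffold_ng50 = s$ng50, scaffold_lg50 = s$lg50,
                 contig_ng50 = cg$ng50, contig_lg50 = cg$lg50,
                 pct_gaps = if (n_bases > 0) 100 * gap_bases / n_bases else 0,
                 genome_size = genome_size, min_len = min_len,
                 undefined = s$undefined),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    "assembly_stats (genome %s bp, min_len %d):\n  %d seqs, %s bp total; scaffold NG50 %s / LG50 %d; contig NG50 %s / LG50 %d; %.2f%% gaps\n",
    format(x$genome_size, big.mark = ","), x$min_len, x$n_seq,
    format(x$total, big.mark = ","), format(x$scaffold_ng50, big.mark = ","),
    x$scaffold_lg50, format(x$contig_ng50, big.mark = ","), x$contig_lg50,
    x$pct_gaps))
  invisible(x)
}

block_seqs <- function(blocks) {
  if (inherits(blocks, "phased_blocks")) blocks$blocks$seq else
    as.character(blocks)
}

#' Fragment-based recall, precision and F-measure
#'
#' Both sets are divided into non-overlapping fixed-length fragments
#' (starting at position 0; trailing partial fragments discarded;
#' N-containing fragments dropped). Recall is the fraction of truth
#' fragments with an exact match (either strand) in the blocks; precision
#' the fraction of block fragments exactly matching the truth; F-measure
#' their harmonic mean.
#'
#' @param blocks `phased_blocks` or character vector of assembled
#'   sequences.
#' @param truth character vector of truth sequences.
#' @param fragment_len fragment length (1000 or 5000 in the benchmarks).
#' @return list: `recall`, `precision`, `f_measure`, fragment counts.
#' @export
fragment_recall_precision <- function(blocks, truth, fragment_len = 1000L) {
  stopifnot(fragment_len > 0)
  bs <- block_seqs(blocks)
  tf <- fragmentize(truth, fragment_len)
  bf <- fragmentize(bs, fragment_len)
  recall <- matched_fraction(tf$frag, bs)
  precision <- matched_fraction(bf$frag, truth)
  f <- if (recall + precision > 0)
    2 * precision * recall / (precision + recall) else 0
  list(recall = recall, precision = precision, f_measure = f,
       n_truth_fragments = nrow(tf), n_block_fragments = nrow(bf))
}

matched_fraction <- function(frags, subjects) {
  if (length(frags) == 0L) return(0)
  hits <- cpp_locate(frags, subjects, 32L, 1L)
  length(unique(hits$pattern)) / length(frags)
}

#' Construct heterozygous 1k-mer pairs from a source sequence set
#'
#' The phasing-evaluation currency: homologous ~1-kbp sequence pairs
#' carrying at least one heterozygous difference. Low-quality bases are
#' masked, the set is aligned all-vs-all, near-exact alignments
#' (edit distance <= N bases in the aligned regions: self or
#' same-haplotype hits) are discarded, the best remaining hit per sequence
#' is kept if identity >= `min_id` and alignment length >= `min_aln_len`,
#' alignments are cut into blocks in which the shorter side holds
#' `block_bases` bases, N-containing and homozygous blocks are dropped,
#' and each surviving pair must have at least `min_exact` exact matches in
#' the source set (use 1 when each locus occurs once, as with a pair of
#' truth haplotypes).
#'
#' @param sources named character vector of source sequences (>= 1 kbp).
#' @param quals optional named vector of phred+33 quality strings; bases
#'   with quality <= `qual_mask` are masked to `N`.
#' @param qual_mask quality masking threshold (default 40).
#' @param block_bases bases of the shorter side per block (default 1000).
#' @param min_id,min_aln_len alignment filters (defaults 0.8 and 500).
#' @param min_exact exact-match confirmation count (default 2).
#' @return data.frame of pairs: `seq1`, `seq2`, `het` (1 - matches /
#'   alignment columns), `source` (target contig of the alignment), `pos`
#'   (0-based start of the block on it).
#' @export
build_het_pairs <- function(sources, quals = NULL, qual_mask = 40L,
                            block_bases = 1000L, min_id = 0.8,
                            min_aln_len = 500L, min_exact = 2L) {
  names(sources) <- names(sources) %||% paste0("src", seq_along(sources))
  empty <- data.frame(seq1 = character(0), seq2 = character(0),
                      het = numeric(0), source = character(0),
                      pos = integer(0), stringsAsFactors = FALSE)
  if (!is.null(quals)) {
    sources <- mapply(function(s, q) {
      qv <- utf8ToInt(q) - 33L
      b <- strsplit(s, "")[[1]]
      b[qv <= qual_mask] <- "N"
      paste(b, collapse = "")
    }, sources, quals[names(sources)])
  }
  paf <- self_align_minimap2(sources, cs = TRUE)
  if (nrow(paf) == 0L) return(empty)
  # near-exact: edit distance bounded by the N content of the regions
  nb <- vapply(seq_len(nrow(paf)), function(i)
    n_bases_in_alignment(paf[i, ], sources, sources), numeric(1))
  paf <- paf[!is.na(paf$NM) & paf$NM > nb, , drop = FALSE]
  if (nrow(paf) == 0L) return(empty)
  # best hit per query by match sites
  paf <- paf[order(paf$query, -paf$matches), , drop = FALSE]
  paf <- paf[!duplicated(paf$query), , drop = FALSE]
  paf$identity <- paf$matches / paf$aln_len
  paf <- paf[paf$identity >= min_id & paf$aln_len >= min_aln_len, ,
             drop = FALSE]
  if (nrow(paf) == 0L) return(empty)
  pairs <- do.call(rbind, lapply(seq_len(nrow(paf)), function(i)
    alignment_blocks(paf[i, ], block_bases)))
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)
  # deduplicate reciprocal alignments: the same genomic pair found from
  # both sides would be double-counted
  key <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$seq1[i]; b <- pairs$seq2[i]
    a <- min(a, revcomp(a)); b <- min(b, revcomp(b))
    paste(sort(c(a, b)), collapse = "|")
  }, character(1))
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  if (min_exact > 0L) {
    c1 <- exact_match_count(pairs$seq1, sources)
    c2 <- exact_match_count(pairs$seq2, sources)
    pairs <- pairs[c1 >= min_exact & c2 >= min_exact, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

exact_match_count <- function(patterns, subjects) {
  if (length(patterns) == 0L) return(integer(0))
  hits <- cpp_locate(patterns, subjects, 32L, 100L)
  tabulate(hits$pattern, nbins = length(patterns))
}

# cut one cs-bearing alignment into blocks where the shorter side holds
# `block_bases` non-gap bases; drops N-containing and homozygous blocks
alignment_blocks <- function(paf_row, block_bases) {
  if (is.na(paf_row$cs)) return(NULL)
  al <- cs_to_alignment(paf_row$cs)
  t <- strsplit(al$target, "")[[1]]
  q <- strsplit(al$query, "")[[1]]
  t_span <- paf_row$tend - paf_row$tstart
  q_span <- paf_row$qend - paf_row$qstart
  short_is_target <- t_span <= q_span
  short <- if (short_is_target) t else q
  nongap <- short != "-"
  cum <- cumsum(nongap)
  n_blocks <- cum[length(cum)] %/% block_bases
  if (n_blocks == 0L) return(NULL)
  out <- list()
  t_nongap <- cumsum(t != "-")
  for (b in seq_len(n_blocks)) {
    i0 <- which(cum == (b - 1L) * block_bases + 1L)[1]
    i1 <- which(cum == b * block_bases)[1]
    bt <- paste(t[i0:i1][t[i0:i1] != "-"], collapse = "")
    bq <- paste(q[i0:i1][q[i0:i1] != "-"], collapse = "")
    if (grepl("N", bt, fixed = TRUE) || grepl("N", bq, fixed = TRUE)) next
    ncol_b <- i1 - i0 + 1L
    matches <- sum(t[i0:i1] == q[i0:i1] & t[i0:i1] != "-")
    if (matches == ncol_b) next # homozygous block
    out[[length(out) + 1L]] <- data.frame(
      seq1 = bt, seq2 = bq, het = 1 - matches / ncol_b,
      source = paf_row$target,
      pos = paf_row$tstart + (if (i0 > 1L) t_nongap[i0 - 1L] else 0L),
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Per-window phased 1k-mer pair rates
#'
#' A pair is phased when both of its sequences have exact matches (either
#' strand) in the block set, and bubble-phased when its two sides land in
#' the two members of a single bubble pair. Rates and mean heterozygosity
#' are reported per window of the source coordinate system.
#'
#' @param blocks a `phased_blocks` object or character vector.
#' @param pairs het pair table from [build_het_pairs()].
#' @param window window size in bp (1 Mbp or 100 kbp in the benchmarks).
#' @return data.frame: `source`, `window` (0-based index), `n_pairs`,
#'   `phased_rate`, `bubble_rate`, `het`.
#' @export
phased_pair_rate <- function(blocks, pairs, window = 1e6) {
  if (nrow(pairs) == 0L)
    return(data.frame(source = character(0), window = integer(0),
                      n_pairs = integer(0), phased_rate = numeric(0),
                      bubble_rate = numeric(0), het = numeric(0)))
  bs <- block_seqs(blocks)
  h1 <- cpp_locate(pairs$seq1, bs, 32L, 10L)
  h2 <- cpp_locate(pairs$seq2, bs, 32L, 10L)
  phased <- seq_len(nrow(pairs)) %in% h1$pattern &
    seq_len(nrow(pairs)) %in% h2$pattern
  bubble <- logical(nrow(pairs))
  if (inherits(blocks, "phased_blocks")) {
    b <- blocks$blocks
    role <- b$role; pair_id <- b$pair
    for (i in which(phased)) {
      s1 <- h1$subject[h1$pattern == i]
      s2 <- h2$subject[h2$pattern == i]
      ok <- FALSE
      for (x in s1) for (y in s2) {
        if (!is.na(pair_id[x]) && !is.na(pair_id[y]) &&
            pair_id[x] == pair_id[y] && role[x] != role[y]) ok <- TRUE
      }
      bubble[i] <- ok
    }
  }
  win <- pairs$pos %/% window
  agg <- split(data.frame(phased = phased, bubble = bubble, het = pairs$het),
               list(pairs$source, win), drop = TRUE)
  out <- do.call(rbind, lapply(names(agg), function(nm) {
    g <- agg[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(source = paste(head(parts, -1L), collapse = "."),
               window = as.integer(tail(parts, 1L)), n_pairs = nrow(g),
               phased_rate = mean(g$phased), bubble_rate = mean(g$bubble),
               het = mean(g$het), stringsAsFactors = FALSE)
  }))
  out[order(out$source, out$window), , drop = FALSE]
}

#' Screen bubbles for sequence absent from a reference genome
#'
#' Each bubble pair is divided into non-overlapping 1-kbp fragments
#' (N-containing dropped); fragments whose best reference alignment is
#' shorter than 500 bp or below 0.9 identity (or absent) are
#' reference-unaligned; unaligned fragments without an exact match in the
#' truth set are discarded as potential mis-assemblies. Bubbles with
#' total length (primary + secondary) >= `min_total_len` and confirmed
#' unaligned-fragment rate >= `min_rate` are reported.
#'
#' @param blocks a `phased_blocks` object with bubble pairs.
#' @param reference character vector (or single string) reference genome.
#' @param truth character vector of trusted sequences for confirmation.
#' @param fragment_len fragment size (default 1000).
#' @param min_aln_len,min_id reference-unaligned thresholds (500, 0.9).
#' @param min_total_len,min_rate report filters (100 kbp, 0.25).
#' @return data.frame: `pair`, `total_len`, `n_fragments`, `n_unaligned`,
#'   `rate`.
#' @export
find_reference_absent_bubbles <- function(blocks, reference, truth,
                                          fragment_len = 1000L,
                                          min_aln_len = 500L, min_id = 0.9,
                                          min_total_len = 100000L,
                                          min_rate = 0.25) {
  b <- blocks$blocks
  out <- list()
  for (pid in unique(b$pair[!is.na(b$pair)])) {
    seqs <- b$seq[!is.na(b$pair) & b$pair == pid]
    fr <- fragmentize(seqs, fragment_len)
    if (nrow(fr) == 0L) next
    paf <- align_minimap2(setNames(fr$frag, seq_len(nrow(fr))), reference,
                          preset = c("-c", "-k", "19", "-p", "1"),
                          cs = FALSE)
    aligned_ok <- logical(nrow(fr))
    if (nrow(paf)) {
      paf$identity <- paf$matches / paf$aln_len
      good <- paf[paf$aln_len >= min_aln_len & paf$identity >= min_id, ,
                  drop = FALSE]
      aligned_ok[as.integer(unique(good$query))] <- TRUE
    }
    una <- which(!aligned_ok)
    confirmed <- integer(0)
    if (length(una)) {
      cnt <- exact_match_count(fr$frag[una], truth)
      confirmed <- una[cnt >= 1L]
    }
    rate <- length(confirmed) / nrow(fr)
    out[[length(out) + 1L]] <- data.frame(
      pair = pid, total_len = sum(nchar(seqs)), n_fragments = nrow(fr),
      n_unaligned = length(confirmed), rate = rate)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(pair = integer(0), total_len = integer(0),
               n_fragments = integer(0), n_unaligned = integer(0),
               rate = numeric(0))
  res[res$total_len >= min_total_len & res$rate >= min_rate, , drop = FALSE]
}

#' Count switch errors and mis-assemblies against truth haplotypes
#'
#' Blocks are divided into consecutive non-overlapping fragments; each
#' fragment is assigned its haplotype of origin by exact match (fragments
#' matching both haplotypes are phase-uninformative; fragments matching
#' neither are unassignable and excluded from adjacency). A switch error
#' is an adjacent informative fragment pair flipping haplotype at
#' collinear truth coordinates; a mis-assembly is an adjacent assigned
#' pair whose truth positions violate order, orientation or distance
#' beyond `slack`.
#'
#' @param blocks `phased_blocks` or character vector.
#' @param hap_a,hap_b truth haplotype sequences.
#' @param fragment_len fragment length (default 1000).
#' @param slack collinearity tolerance in bp (default `fragment_len`).
#' @return list: `switches`, `misassemblies`, `n_fragments`,
#'   `n_unassigned`, `per_block` data.frame.
#' @export
count_switch_errors <- function(blocks, hap_a, hap_b, fragment_len = 1000L,
                                slack = fragment_len) {
  bs <- block_seqs(blocks)
  total_sw <- 0L; total_mis <- 0L; total_frag <- 0L; total_un <- 0L
  per_block <- list()
  for (bi in seq_along(bs)) {
    fr <- fragmentize(bs[bi], fragment_len, drop_n = FALSE)
    if (nrow(fr) == 0L) next
    has_n <- grepl("N", fr$frag, fixed = TRUE)
    hA <- cpp_locate(fr$frag, hap_a, 32L, 2L)
    hB <- cpp_locate(fr$frag, hap_b, 32L, 2L)
    inA <- seq_len(nrow(fr)) %in% hA$pattern
    inB <- seq_len(nrow(fr)) %in% hB$pattern
    hap <- ifelse(has_n | (!inA & !inB), "U",
                  ifelse(inA & inB, "AB", ifelse(inA, "A", "B")))
    posA <- hA$pos[match(seq_len(nrow(fr)), hA$pattern)]
    strA <- hA$strand[match(seq_len(nrow(fr)), hA$pattern)]
    posB <- hB$pos[match(seq_len(nrow(fr)), hB$pattern)]
    strB <- hB$strand[match(seq_len(nrow(fr)), hB$pattern)]
    pos <- ifelse(hap %in% c("A", "AB"), posA, posB)
    str <- ifelse(hap %in% c("A", "AB"), strA, strB)
    keep <- which(hap %in% c("A", "B"))
    sw <- 0L; mis <- 0L
    if (length(keep) >= 2L) {
      for (j in seq_len(length(keep) - 1L)) {
        i1 <- keep[j]; i2 <- keep[j + 1L]
        d_frag <- (i2 - i1) * fragment_len
        d_pos <- (pos[i2] - pos[i1]) * ifelse(str[i1] == 1L, 1L, -1L)
        collinear <- str[i1] == str[i2] &&
          abs(d_pos - d_frag) <= slack + abs(i2 - i1 - 1L) * slack
        if (!collinear) mis <- mis + 1L
        else if (hap[i1] != hap[i2]) sw <- sw + 1L
      }
    }
    total_sw <- total_sw + sw
    total_mis <- total_mis + mis
    total_frag <- total_frag + nrow(fr)
    total_un <- total_un + sum(hap == "U")
    per_block[[length(per_block) + 1L]] <- data.frame(
      block = bi, n_fragments = nrow(fr), switches = sw,
      misassemblies = mis, unassigned = sum(hap == "U"))
  }
  list(switches = total_sw, misassemblies = total_mis,
       n_fragments = total_frag, n_unassigned = total_un,
       per_block = if (length(per_block)) do.call(rbind, per_block) else NULL)
}
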