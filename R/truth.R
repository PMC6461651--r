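# Truth-based evaluation helpers: emulate a synthetic long-read contig set
# from known haplotypes so the het 1k-mer pair machinery (designed for
# ~10-kbp locally assembled contigs) applies to simulated truth.

#' Heterozygous 1k-mer pairs from a pair of truth haplotypes
#'
#' Tiles both haplotypes into contig-sized chunks (the shape of a
#' synthetic long-read set, where each locus appears once per haplotype)
#' and runs [build_het_pairs()] with `min_exact = 1`. Pair coordinates are
#' translated back to whole-haplotype coordinates.
#'
#' @param hap_a,hap_b truth haplotype sequences.
#' @param chunk chunk length in bp (default 10000).
#' @param ... passed to [build_het_pairs()].
#' @return pair table as from [build_het_pairs()], with `source` in
#'   `c("hapA", "hapB")` and `pos` in haplotype coordinates.
#' @export
truth_het_pairs <- function(hap_a, hap_b, chunk = 10000L, ...) {
  chunker <- function(s, tag) {
    n <- nchar(s)
    starts <- seq(1L, n, by = chunk)
    setNames(substring(s, starts, pmin(starts + chunk - 1L, n)),
             sprintf("%s:%d", tag, starts - 1L))
  }
  sources <- c(chunker(hap_a, "hapA"), chunker(hap_b, "hapB"))
  sources <- sources[nchar(sources) >= 1000L]
  pairs <- build_het_pairs(sources, min_exact = 1L, ...)
  if (nrow(pairs) == 0L) return(pairs)
  parts <- strsplit(pairs$source, ":", fixed = TRUE)
  pairs$pos <- pairs$pos + as.integer(vapply(parts, `[`, character(1), 2L))
  pairs$source <- vapply(parts, `[`, character(1), 1L)
  pairs
}

#' Check that an HDR is phased inside a single bubble pair with inversion
#'
#' Locates the haplotype-A version of an HDR interval in the block set
#' (exact, either strand), requires it to sit inside one bubble-pair
#' member, aligns that member to its mate, and tests that the alignment
#' segment covering the HDR runs on the opposite strand of the flanking
#' (majority) alignment.
#'
#' @param blocks a `phased_blocks` object.
#' @param hap_a truth haplotype A.
#' @param hdr_start,hdr_len HDR interval on haplotype A (1-based start).
#' @param min_cover minimum fraction of the HDR covered by the inverted
#'   alignment segment.
#' @return list: `in_single_bubble`, `inverted`, `detail`.
#' @export
hdr_inversion_check <- function(blocks, hap_a, hdr_start, hdr_len,
                                min_cover = 0.5) {
  b <- blocks$blocks
  hdr_seq <- substring(hap_a, hdr_start, hdr_start + hdr_len - 1L)
  hit <- cpp_locate(hdr_seq, b$seq, 32L, 5L)
  if (nrow(hit) != 1L || is.na(b$pair[hit$subject]))
    return(list(in_single_bubble = FALSE, inverted = FALSE,
                detail = "HDR not found intact inside one bubble member"))
  pid <- b$pair[hit$subject]
  mate_idx <- which(!is.na(b$pair) & b$pair == pid &
                      seq_len(nrow(b)) != hit$subject)
  if (length(mate_idx) != 1L)
    return(list(in_single_bubble = FALSE, inverted = FALSE,
                detail = "bubble mate missing"))
  paf <- align_minimap2(setNames(b$seq[hit$subject], "member"),
                        setNames(b$seq[mate_idx], "mate"), cs = FALSE)
  paf <- paf[paf$aln_len >= 1000L, , drop = FALSE]
  if (nrow(paf) == 0L)
    return(list(in_single_bubble = TRUE, inverted = FALSE,
                detail = "no alignment between bubble members"))
  hdr_q0 <- hit$pos
  hdr_q1 <- hit$pos + hdr_len
  ov <- pmin(paf$qend, hdr_q1) - pmax(paf$qstart, hdr_q0)
  inside <- ov > min_cover * hdr_len
  outside <- paf[ov <= 0, , drop = FALSE]
  if (!any(inside) || nrow(outside) == 0L)
    return(list(in_single_bubble = TRUE, inverted = FALSE,
                detail = "HDR or flank alignment segment missing"))
  flank_strand <- outside$strand[which.max(outside$aln_len)]
  hdr_strand <- paf$strand[inside][which.max(ov[inside])]
  list(in_single_bubble = TRUE, inverted = hdr_strand != flank_strand,
       detail = sprintf("flank strand %s, HDR strand %s", flank_strand,
                        hdr_strand))
}
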