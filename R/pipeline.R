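# Full pipeline: contig assembly -> (de Bruijn untangling -> scaffolding
# with scaffold-graph untangling -> haplotype synteny-based correction ->
# bubble pairing -> gap closing) x outer iterations -> optional consensus.

#' Pipeline configuration
#'
#' @param k0 initial k-mer size (default 32).
#' @param k_step k increment per contig-assembly iteration (default 20).
#' @param k_max maximal k (`NULL`: `min(read length - 4, k0 + 3*k_step)`).
#' @param r_upper repeat-exclusion coverage ratio (default 1.75).
#' @param ratio evidence dominance ratio for untangling (default 4).
#' @param barcode_min barcode read-count threshold; counts at or below are
#'   dropped (default 3).
#' @param untangle_rounds untangling iteration cap per graph (default 5).
#' @param outer_iterations phasing/scaffolding/correction/gap-closing
#'   iterations (default 2).
#' @param min_link minimum links per scaffold bundle (default 2).
#' @param short_len scaffold-graph short-node exclusion length (`NULL`:
#'   the smallest library insert mean).
#' @param min_block_len minimum emitted block length (default 200).
#' @param genome_size haploid genome size for statistics (`NULL`: half the
#'   total block length).
#' @param consensus build consensus scaffolds as well (default TRUE).
#' @param verbose print stage progress.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(k0 = 32L, k_step = 20L, k_max = NULL,
                            r_upper = 1.75, ratio = 4, barcode_min = 3L,
                            untangle_rounds = 5L, outer_iterations = 2L,
                            min_link = 2L, short_len = NULL,
                            min_block_len = 200L, genome_size = NULL,
                            consensus = TRUE, verbose = FALSE) {
  stopifnot(k0 >= 2, k_step > 0, r_upper > 0, ratio > 0,
            outer_iterations >= 1, min_link >= 1, untangle_rounds >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full haplotype-aware assembly pipeline
#'
#' Contig assembly with increasing k (bubbles kept), anchor-bubble
#' detection on the initial graph, iterative cross-structure untangling of
#' the de Bruijn graph, then `outer_iterations` rounds of scaffolding
#' (with scaffold-graph untangling), haplotype synteny-based correction,
#' bubble pairing and gap closing. Requires at least one paired-end
#' library. Deterministic for fixed inputs.
#'
#' @param libs a `read_library` or list of them (from [simulate_reads()]
#'   or [read_fastq()] + [library_spec()]).
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `blocks` (a `phased_blocks`),
#'   `consensus`, `stats` (per-iteration `assembly_stats`), `anchors`,
#'   `logs` (stage counters and untangle decisions), `config`.
#' @export
run_pipeline <- function(libs, config = pipeline_config()) {
  if (inherits(libs, "read_library")) libs <- list(libs)
  types <- vapply(libs, function(l) l$spec$type, character(1))
  if (!any(types == "paired"))
    stop("at least one paired-end library is required")
  n_reads <- vapply(libs, function(l) length(l$reads1), integer(1))
  if (any(n_reads == 0L)) stop("empty read library")
  cfg <- config
  logs <- list()
  vmsg <- function(...) if (cfg$verbose) message(sprintf(...))

  short_libs <- libs[types %in% c("paired", "mate")]
  asm <- assemble_contigs(libs[types != "long"], k0 = cfg$k0,
                          k_step = cfg$k_step, k_max = cfg$k_max,
                          verbose = cfg$verbose)
  k_final <- asm$graph$k
  anchors <- suppressWarnings(
    detect_anchor_bubbles(asm$initial_graph, cfg$r_upper))
  logs$n_bubbles <- nrow(anchors$bubbles)
  logs$n_anchors <- sum(anchors$bubbles$anchor %||% logical(0))
  logs$c_hetero <- anchors$c_hetero
  vmsg("anchors: %d/%d bubbles, c_hetero %.2f", logs$n_anchors,
       logs$n_bubbles, anchors$c_hetero)

  unt <- untangle_graph(asm$graph, libs, anchors$c_hetero,
                        r_upper = cfg$r_upper, ratio = cfg$ratio,
                        rounds = cfg$untangle_rounds,
                        barcode_min = cfg$barcode_min, verbose = cfg$verbose)
  logs$untangle_dbg <- unt$log
  contigs <- dbg_contigs(unt$graph, min_len = k_final)

  short_len <- cfg$short_len %||%
    min(vapply(short_libs, function(l) l$spec$insert_mean, numeric(1)))
  stats <- list()
  blocks <- NULL
  for (iter in seq_len(cfg$outer_iterations)) {
    vmsg("outer iteration %d: %d contigs", iter, nrow(contigs))
    mp <- map_short_reads(contigs$seq, libs)
    links <- mp$links
    pseudo_graph <- list(nodes = data.frame(seq = contigs$seq,
                                            stringsAsFactors = FALSE),
                         k = k_final)
    class(pseudo_graph) <- "dbg"
    long_links <- gather_long_links(pseudo_graph, libs)
    if (!is.null(long_links) && nrow(long_links))
      links <- rbind(links, long_links)
    bctab <- gather_barcode_tab(pseudo_graph, libs, cfg$barcode_min)
    anchored <- anchored_contig_ids(contigs$seq, anchors)
    ss <- scaffold_init(contigs)
    ph <- scaffold_phase(ss, links, c_hetero = anchors$c_hetero,
                         min_link = cfg$min_link, short_len = short_len,
                         anchored_contigs = anchored,
                         r_upper = cfg$r_upper, ratio = cfg$ratio,
                         bctab = bctab)
    logs[[sprintf("scaffold_iter%d", iter)]] <-
      list(n_untangled = ph$n_untangled, n_joined = ph$n_joined,
           log = ph$log)
    sc <- synteny_correct(ph$ss, anchors)
    logs[[sprintf("synteny_iter%d", iter)]] <-
      list(n_divisions = sc$n_divisions, rounds = sc$rounds)
    vmsg("  scaffolds: %d untangled, %d joined, %d divisions",
         ph$n_untangled, ph$n_joined, sc$n_divisions)
    blocks <- pair_bubbles(sc$ss, anchors, min_len = 0L)
    blocks <- close_gaps(blocks, short_libs,
                         k_local = max(15L, k_final %/% 2L))
    gr <- attr(blocks, "gap_report")
    logs[[sprintf("gaps_iter%d", iter)]] <- gr
    vmsg("  gaps: %d closed / %d",
         if (is.null(gr)) 0L else sum(gr$status == "closed"),
         if (is.null(gr)) 0L else nrow(gr))
    gsize <- cfg$genome_size %||%
      (sum(nchar(blocks$blocks$seq)) / 2)
    stats[[iter]] <- assembly_stats(blocks$blocks$seq, 2 * gsize,
                                    min_len = 500L)
    if (iter < cfg$outer_iterations) {
      contigs <- data.frame(id = seq_len(nrow(blocks$blocks)),
                            seq = blocks$blocks$seq,
                            len = nchar(blocks$blocks$seq),
                            depth = mean(contigs$depth),
                            stringsAsFactors = FALSE)
    }
  }
  if (cfg$min_block_len > 0L) {
    keep <- nchar(blocks$blocks$seq) >= cfg$min_block_len
    # never break a bubble pair: keep both members if either passes
    pr <- blocks$blocks$pair
    for (p in unique(pr[!is.na(pr)]))
      if (any(keep[!is.na(pr) & pr == p])) keep[!is.na(pr) & pr == p] <- TRUE
    blocks$blocks <- blocks$blocks[keep, , drop = FALSE]
  }
  cons <- NULL
  if (cfg$consensus) {
    cons <- build_consensus(blocks, k_final, libs = short_libs,
                            min_link = cfg$min_link)
  }
  structure(list(blocks = blocks, consensus = cons, stats = stats,
                 anchors = anchors, logs = logs, config = cfg,
                 k_final = k_final),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$blocks)
  if (!is.null(x$consensus))
    cat(sprintf("consensus: %d scaffolds, %d bp\n", length(x$consensus),
                sum(nchar(x$consensus))))
  print(x$stats[[length(x$stats)]])
  invisible(x)
}

anchored_contig_ids <- function(seqs, anchors) {
  if (!is.finite(anchors$c_hetero)) return(integer(0))
  bub <- anchors$bubbles[anchors$bubbles$anchor, , drop = FALSE]
  if (nrow(bub) == 0L) return(integer(0))
  hits <- cpp_locate(c(bub$seq1, bub$seq2), seqs, 32L, 2L)
  sort(unique(hits$subject))
}

#' Construct a phased block set from sequences
#'
#' Builds the container emitted by [pair_bubbles()] from explicit primary
#' / secondary / non-bubble sequences, e.g. when loading an assembly from
#' FASTA for evaluation.
#'
#' @param primary,secondary character vectors of equal length (bubble
#'   pairs, in order).
#' @param nonbubble character vector of non-bubble sequences.
#' @return a `phased_blocks` object.
#' @export
phased_block_set <- function(primary = character(0),
                             secondary = character(0),
                             nonbubble = character(0)) {
  stopifnot(length(primary) == length(secondary))
  rows <- list()
  for (i in seq_along(primary)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("primary_bubble_%d", i), seq = primary[i],
      role = "primary", pair = i, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("secondary_bubble_%d", i), seq = secondary[i],
      role = "secondary", pair = i, stringsAsFactors = FALSE)
  }
  for (j in seq_along(nonbubble)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("nonbubble_%d", j), seq = nonbubble[j],
      role = "nonbubble", pair = NA_integer_, stringsAsFactors = FALSE)
  }
  blocks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), seq = character(0), role = character(0),
               pair = integer(0), stringsAsFactors = FALSE)
  structure(list(blocks = blocks, pairing = NULL), class = "phased_blocks")
}

#' Write phased blocks to FASTA and the pairing table to TSV
#'
#' @param blocks a `phased_blocks` object.
#' @param prefix output path prefix (`<prefix>.fa`, `<prefix>_pairs.tsv`).
#' @return the FASTA path, invisibly.
#' @export
write_blocks <- function(blocks, prefix) {
  fa <- paste0(prefix, ".fa")
  write_fasta(setNames(blocks$blocks$seq, blocks$blocks$name), fa)
  if (!is.null(blocks$pairing))
    write_tsv(blocks$pairing, paste0(prefix, "_pairs.tsv"))
  invisible(fa)
}
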