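# de Bruijn graph core: canonical k-mer counting, coverage-cutoff
# estimation, graph construction with straight/junction nodes, and the
# increasing-k iteration. Bubbles are never removed: they carry the
# heterozygous signal the phasing stages consume.

empty_edges <- function() {
  data.frame(a = integer(0), ea = integer(0), b = integer(0), eb = integer(0))
}

new_dbg <- function(k, nodes, edges) {
  nodes$len <- nchar(nodes$seq)
  structure(list(k = as.integer(k), nodes = nodes, edges = edges),
            class = "dbg")
}

#' @export
print.dbg <- function(x, ...) {
  cat(sprintf("de Bruijn graph (k = %d): %d straight + %d junction nodes, %d edges\n",
              x$k, sum(!x$nodes$junction), sum(x$nodes$junction),
              nrow(x$edges)))
  cat(sprintf("  straight bases: %d; median depth %.1f\n",
              sum(x$nodes$len[!x$nodes$junction]),
              median(x$nodes$depth[!x$nodes$junction])))
  invisible(x)
}

#' Count canonical k-mers and build the occurrence histogram
#'
#' Every length-`k` window free of `N` is counted once under its canonical
#' form (the lexicographic minimum of the window and its reverse
#' complement). The histogram maps occurrence to the number of distinct
#' canonical k-mers with that occurrence, over the contiguous range
#' `1..max`.
#'
#' @param reads character vector of reads (or a `read_library`, or a list of
#'   them).
#' @param k k-mer length (>= 2).
#' @return an object of class `kmer_hist` with elements `k`, `counts`
#'   (integer vector indexed by occurrence), `table` (k-mer occurrence
#'   table) and `windows` (total windows counted).
#' @export
count_kmers <- function(reads, k) {
  stopifnot(k >= 2)
  reads <- gather_reads(reads)
  if (length(reads) == 0L || k > max(nchar(reads)))
    stop("k exceeds every read length: no k-mer can be counted")
  res <- cpp_count_kmers(reads, as.integer(k))
  if (length(res$kmer) == 0L)
    stop("no valid k-mer windows (reads shorter than k or all-N)")
  hist <- tabulate(res$count)
  structure(list(k = as.integer(k), counts = hist,
                 table = data.frame(kmer = res$kmer, count = res$count,
                                    stringsAsFactors = FALSE),
                 windows = res$windows),
            class = "kmer_hist")
}

# flatten read inputs: character vectors, read_library objects, lists
gather_reads <- function(x) {
  if (is.character(x)) return(unname(x))
  if (inherits(x, "read_library"))
    return(unname(c(x$reads1, x$reads2)))
  if (is.list(x)) return(unlist(lapply(x, gather_reads), use.names = FALSE))
  stop("unsupported read input")
}

#' Initial k-mer coverage cutoff from the occurrence histogram
#'
#' Finds the leftmost local minimum `m >= 2` of the unsmoothed histogram
#' (`counts(m) <= counts(m-1)` and `counts(m) <= counts(m+1)`; ties resolve
#' to the smallest occurrence) and returns `floor(m/2)`, at least 1. A
#' monotone histogram has no local minimum; the cutoff falls back to 1 with
#' a warning.
#'
#' @param hist a `kmer_hist` (or a bare numeric histogram vector indexed by
#'   occurrence).
#' @return integer coverage cutoff (>= 1).
#' @export
initial_cutoff <- function(hist) {
  counts <- if (inherits(hist, "kmer_hist")) hist$counts else as.numeric(hist)
  if (length(counts) == 0L) stop("empty histogram")
  cnt <- function(i) if (i >= 1L && i <= length(counts)) counts[i] else 0
  for (m in 2:max(2L, length(counts))) {
    if (cnt(m) <= cnt(m - 1L) && cnt(m) <= cnt(m + 1L))
      return(max(1L, m %/% 2L))
  }
  warning("no local minimum in k-mer histogram; cutoff set to 1")
  1L
}

#' Build the de Bruijn graph from a k-mer occurrence table
#'
#' k-mers with occurrence below the cutoff are removed; maximal
#' non-branching paths become straight nodes and branching k-mers become
#' junction nodes, connected by exact (k-1)-mer overlap edges. Bubbles are
#' kept. Per-node coverage is the mean constituent k-mer occurrence;
#' `depth` additionally normalises k-mer coverage to read depth by the
#' factor `L/(L-k+1)` (`L` = `norm_read_len`) minus `contig_counted` (the
#' +1 contribution of previous-iteration contigs at raised k).
#'
#' @param tab k-mer table (`data.frame` with `kmer`, `count`) or a
#'   `kmer_hist`.
#' @param cutoff minimum occurrence kept (>= 1).
#' @param k k-mer length; taken from the `kmer_hist` when omitted.
#' @param norm_read_len read length used for depth normalisation (`NULL`
#'   leaves depth = coverage).
#' @param contig_counted how many counts per k-mer came from included
#'   previous contigs rather than reads (0 on the first iteration).
#' @return a `dbg` object: `k`, `nodes` (seq, cov, depth, junction, len)
#'   and `edges` (a, ea, b, eb; end 1 = 3' of the stored sequence).
#' @export
build_graph <- function(tab, cutoff = 1L, k = NULL,
                        norm_read_len = NULL, contig_counted = 0) {
  if (inherits(tab, "kmer_hist")) {
    k <- tab$k
    tab <- tab$table
  }
  stopifnot(!is.null(k), cutoff >= 1)
  keep <- tab$count >= cutoff
  if (!any(keep)) {
    warning("empty graph: no k-mer passes the coverage cutoff")
    nodes <- data.frame(seq = character(0), cov = numeric(0),
                        depth = numeric(0), junction = logical(0))
    return(new_dbg(k, nodes, empty_edges()))
  }
  g <- cpp_build_dbg(tab$kmer[keep], as.numeric(tab$count[keep]),
                     as.integer(k))
  f <- if (is.null(norm_read_len)) 1 else
    norm_read_len / max(norm_read_len - k + 1, 1)
  nodes <- data.frame(seq = g$seq, cov = g$cov,
                      depth = pmax(g$cov - contig_counted, 0) * f,
                      junction = g$junction, stringsAsFactors = FALSE)
  edges <- data.frame(a = g$edge_a, ea = g$edge_ea,
                      b = g$edge_b, eb = g$edge_eb)
  new_dbg(k, nodes, edges)
}

#' Rebuild the graph at a larger k
#'
#' Recounts k-mers at `k_new` from the reads plus the previous straight-node
#' sequences (each contributing one extra count, so low-coverage regions
#' already assembled stay connected), then rebuilds the graph. Heterozygous
#' bubbles persist; no read-based contig correction is applied.
#'
#' @param graph current `dbg`.
#' @param reads read input as in [count_kmers()].
#' @param k_new new k; must exceed `graph$k` and not exceed the read length.
#' @param cutoff occurrence cutoff at the raised k (default 1: the initial
#'   cutoff already removed noise k-mers and previous contigs are trusted).
#' @param norm_read_len read length for depth normalisation.
#' @return a new `dbg` at `k_new`.
#' @export
raise_k <- function(graph, reads, k_new, cutoff = 1L, norm_read_len = NULL) {
  stopifnot(inherits(graph, "dbg"))
  if (k_new <= graph$k) stop("k_new must exceed the current k")
  reads <- gather_reads(reads)
  if (k_new > max(nchar(reads))) stop("k_new exceeds every read length")
  contigs <- graph$nodes$seq[!graph$nodes$junction]
  contigs <- contigs[nchar(contigs) >= k_new]
  res <- cpp_count_kmers(c(reads, contigs), as.integer(k_new))
  tab <- data.frame(kmer = res$kmer, count = res$count,
                    stringsAsFactors = FALSE)
  build_graph(tab, cutoff = cutoff, k = k_new,
              norm_read_len = norm_read_len,
              contig_counted = if (length(contigs)) 1 else 0)
}

#' Contig assembly with increasing k
#'
#' Runs the full contig-assembly schedule: count k-mers at `k0`, estimate
#' the initial coverage cutoff as floor(leftmost-local-minimum / 2), build
#' the graph, then raise k in steps of `k_step` up to `k_max` (default
#' `min(read length - 4, k0 + 3 * k_step)`).
#'
#' @param libs a `read_library`, list of them, or character vector of reads.
#' @param k0 initial k (default 32).
#' @param k_step k increment per iteration (default 20).
#' @param k_max maximal k (`NULL` for the default schedule).
#' @param verbose print per-iteration summaries.
#' @return list: final `graph`, `initial_graph` (the k0 graph, substrate for
#'   anchor-bubble detection), `cutoff`, `k_schedule`.
#' @export
assemble_contigs <- function(libs, k0 = 32L, k_step = 20L, k_max = NULL,
                             verbose = FALSE) {
  reads <- gather_reads(libs)
  read_len <- round(mean(nchar(reads)))
  k_max <- k_max %||% min(max(nchar(reads)) - 4L, k0 + 3L * k_step)
  hist <- count_kmers(reads, k0)
  cutoff <- suppressWarnings(initial_cutoff(hist))
  g0 <- build_graph(hist, cutoff = cutoff, norm_read_len = read_len)
  if (verbose) print(g0)
  g <- g0
  ks <- k0
  k <- k0 + k_step
  while (k <= k_max) {
    g <- raise_k(g, reads, k, norm_read_len = read_len)
    ks <- c(ks, k)
    if (verbose) print(g)
    k <- k + k_step
  }
  list(graph = g, initial_graph = g0, cutoff = cutoff, k_schedule = ks)
}

#' Extract contigs (straight nodes) from a graph
#'
#' @param graph a `dbg`.
#' @param min_len minimum contig length kept.
#' @return data.frame with `id`, `seq`, `len`, `depth`.
#' @export
dbg_contigs <- function(graph, min_len = 0L) {
  nd <- graph$nodes
  keep <- !nd$junction & nd$len >= min_len
  data.frame(id = which(keep), seq = nd$seq[keep], len = nd$len[keep],
             depth = nd$depth[keep], stringsAsFactors = FALSE)
}

# adjacency in long format: one row per (node,end) incidence
dbg_adjacency <- function(graph) {
  ed <- graph$edges
  rbind(
    data.frame(node = ed$a, end = ed$ea, other = ed$b, other_end = ed$eb,
               edge = seq_len(nrow(ed))),
    data.frame(node = ed$b, end = ed$eb, other = ed$a, other_end = ed$ea,
               edge = seq_len(nrow(ed))))
}

# degree of each (node, end)
end_degree <- function(graph) {
  adj <- dbg_adjacency(graph)
  n <- nrow(graph$nodes)
  deg <- matrix(0L, nrow = n, ncol = 2)
  if (nrow(adj)) {
    t1 <- table(factor(adj$node[adj$end == 0L], levels = seq_len(n)))
    t2 <- table(factor(adj$node[adj$end == 1L], levels = seq_len(n)))
    deg[, 1] <- as.integer(t1)
    deg[, 2] <- as.integer(t2)
  }
  deg
}
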