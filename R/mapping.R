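# Read-to-graph mapping: exact unique fixed-length seed placement for short
# reads (seed lengths 32/64/96, shortest unique accepted), link evidence
# from read pairs and from single reads spanning nodes, long-read alignment
# filtering/selection, and linked-read barcode counting.

#' Map short reads onto graph nodes
#'
#' Each read is probed at offsets 0, 32, 64, ... with fixed-length seeds of
#' 32, 64 and 96 bp; a seed is placed where it matches exactly and uniquely
#' across all nodes, and the shortest unique length wins. Mated libraries
#' yield paired link evidence with the gap estimated from the insert size;
#' a single read whose seeds place on several nodes yields single-read
#' links with the gap read off the read coordinates. Mate-pair reads are
#' reverse-complemented up front so all pairs are inward-facing.
#'
#' Libraries are processed individually in ascending order of insert size
#' (the processing order is recorded in the returned `lib_order`).
#'
#' @param graph a `dbg` object, or a character vector of node sequences.
#' @param libs a `read_library` or list of them.
#' @param seed_len base seed length (default 32).
#' @return list with `placements` (read-level placements), `links`
#'   (oriented node-pair link evidence: `a`,`ea`,`b`,`eb`,`gap`,`class`,
#'   `lib`, and `matches` for long-read links), and `lib_order`.
#' @export
map_short_reads <- function(graph, libs, seed_len = 32L) {
  node_seqs <- if (inherits(graph, "dbg")) graph$nodes$seq else
    as.character(graph)
  if (length(node_seqs) == 0L) stop("empty graph")
  if (inherits(libs, "read_library")) libs <- list(libs)
  short <- Filter(function(l) l$spec$type != "long", libs)
  ord <- order(vapply(short, function(l) l$spec$insert_mean, numeric(1)))
  short <- short[ord]
  placements <- list()
  links <- list()
  for (li in seq_along(short)) {
    lib <- short[[li]]
    r1 <- unname(lib$reads1)
    r2 <- unname(lib$reads2)
    if (lib$spec$type == "mate") { # normalise outward pairs to inward
      r1 <- revcomp(r1)
      r2 <- revcomp(r2)
    }
    n1 <- length(r1)
    pl <- cpp_map_reads(node_seqs, c(r1, r2), as.integer(seed_len))
    # one placement per (read, node): the smallest-offset seed
    pl <- pl[!duplicated(paste(pl$read, pl$node)), , drop = FALSE]
    pl$mate <- ifelse(pl$read <= n1, 1L, 2L)
    pl$pair <- ifelse(pl$read <= n1, pl$read, pl$read - n1)
    pl$lib <- rep(li, nrow(pl))
    nlen <- nchar(node_seqs)
    links[[li]] <- rbind(
      pair_links(pl, nlen, lib$spec$insert_mean, lib$spec$type, li),
      single_read_links(pl, nlen, li))
    placements[[li]] <- pl
  }
  list(placements = do.call(rbind, placements),
       links = do.call(rbind, links),
       lib_order = vapply(short, function(l) l$spec$insert_mean, numeric(1)))
}

# primary placement per (read, mate): the placement at the smallest offset
primary_placements <- function(pl) {
  o <- order(pl$pair, pl$mate, pl$offset)
  pl <- pl[o, , drop = FALSE]
  pl[!duplicated(pl[c("pair", "mate")]), , drop = FALSE]
}

# link evidence from read pairs placed on two different nodes.
# Both mates are in fragment orientation (mate 2 still as sequenced, i.e.
# reverse complement of the fragment end): for mate 1 the fragment runs
# with the read; for mate 2 it runs against it.
pair_links <- function(pl, nlen, insert, type, li) {
  p1 <- primary_placements(pl[pl$mate == 1L, , drop = FALSE])
  p2 <- primary_placements(pl[pl$mate == 2L, , drop = FALSE])
  m <- merge(p1, p2, by = "pair", suffixes = c("1", "2"))
  m <- m[m$node1 != m$node2, , drop = FALSE]
  if (nrow(m) == 0L) return(empty_links())
  # exit end of node1 (downstream direction of the fragment)
  e1 <- ifelse(m$strand1 == 1L, 1L, 0L)
  a1 <- ifelse(m$strand1 == 1L, nlen[m$node1] - m$rstart1, m$rstart1 + 1L)
  # mate2 as sequenced points upstream; fragment enters node2 at:
  e2 <- ifelse(m$strand2 == 1L, 1L, 0L)
  b2 <- ifelse(m$strand2 == 1L, nlen[m$node2] - m$rstart2, m$rstart2 + 1L)
  gap <- insert - a1 - b2
  normalize_links(data.frame(
    a = m$node1, ea = e1, b = m$node2, eb = e2, gap = gap,
    class = if (type == "mate") "mate-pair" else
      if (type == "linked") "linked" else "paired-end",
    lib = li, matches = NA_real_, stringsAsFactors = FALSE))
}

# link evidence from one read whose seeds place on multiple nodes
single_read_links <- function(pl, nlen, li) {
  key <- paste(pl$pair, pl$mate)
  multi <- key %in% key[duplicated(key)] # reads placed on >= 2 nodes
  pl <- pl[multi, , drop = FALSE]
  if (nrow(pl) == 0L) return(empty_links())
  pl <- pl[order(pl$pair, pl$mate, pl$offset), , drop = FALSE]
  n <- nrow(pl)
  # adjacent placements of the same read, by offset order
  i <- seq_len(n - 1L)
  same <- pl$pair[i] == pl$pair[i + 1L] & pl$mate[i] == pl$mate[i + 1L]
  x <- i[same]; y <- x + 1L
  if (length(x) == 0L) return(empty_links())
  i_exit <- ifelse(pl$strand[x] == 1L, nlen[pl$node[x]] - 1L - pl$rstart[x],
                   pl$rstart[x])
  i_entry <- ifelse(pl$strand[y] == 1L, -pl$rstart[y],
                    pl$rstart[y] - nlen[pl$node[y]] + 1L)
  normalize_links(data.frame(
    a = pl$node[x], ea = ifelse(pl$strand[x] == 1L, 1L, 0L),
    b = pl$node[y], eb = ifelse(pl$strand[y] == 1L, 0L, 1L),
    gap = i_entry - i_exit - 1L, class = "single", lib = li,
    matches = NA_real_, stringsAsFactors = FALSE))
}

empty_links <- function() {
  data.frame(a = integer(0), ea = integer(0), b = integer(0), eb = integer(0),
             gap = numeric(0), class = character(0), lib = integer(0),
             matches = numeric(0), stringsAsFactors = FALSE)
}

# canonical link orientation: smaller (node, end) first
normalize_links <- function(lk) {
  if (nrow(lk) == 0L) return(lk)
  swap <- lk$a > lk$b | (lk$a == lk$b & lk$ea > lk$eb)
  if (any(swap)) {
    tmp <- lk[swap, ]
    lk$a[swap] <- tmp$b; lk$ea[swap] <- tmp$eb
    lk$b[swap] <- tmp$a; lk$eb[swap] <- tmp$ea
  }
  lk
}

#' Filter and greedily select long-read alignments
#'
#' Keeps alignments with sequence identity >= `min_id` and (alignment
#' length >= `min_len` or alignment coverage >= `min_cov`), where identity
#' = matched sites / alignment length and coverage = alignment length /
#' min(query length, target length). Survivors are then greedily selected
#' per query in decreasing matched-sites order such that no two selected
#' alignments overlap by `k` or more bases on the query.
#'
#' @param aln data.frame with columns `query`, `qlen`, `qstart`, `qend`
#'   (0-based half-open on the query), `target`, `tlen`, `tstart`, `tend`,
#'   `strand` (`"+"`/`"-"`), `matches`, `aln_len`.
#' @param k overlap tolerance on the query (the graph k).
#' @param min_id,min_len,min_cov filter thresholds.
#' @return the selected subset, with `identity` and `coverage` columns.
#' @export
filter_long_alignments <- function(aln, k, min_id = 0.8, min_len = 1000,
                                   min_cov = 0.8) {
  if (nrow(aln) == 0L) return(aln)
  aln$identity <- aln$matches / aln$aln_len
  aln$coverage <- aln$aln_len / pmin(aln$qlen, aln$tlen)
  aln <- aln[aln$identity >= min_id &
               (aln$aln_len >= min_len | aln$coverage >= min_cov), ,
             drop = FALSE]
  if (nrow(aln) == 0L) return(aln)
  sel <- lapply(split(aln, aln$query), function(g) {
    g <- g[order(-g$matches, g$qstart, g$tstart), , drop = FALSE]
    taken <- logical(nrow(g))
    for (i in seq_len(nrow(g))) {
      ov <- pmin(g$qend[taken], g$qend[i]) - pmax(g$qstart[taken], g$qstart[i])
      if (!any(ov >= k)) taken[i] <- TRUE
    }
    g[taken, , drop = FALSE]
  })
  out <- do.call(rbind, sel)
  rownames(out) <- NULL
  out
}

#' Final long-read position and spanning-read link evidence
#'
#' For each (query, target) pair the local alignment positions are averaged
#' weighted by alignment length. A query spanning several targets emits
#' link evidence between consecutive targets (by query order) with the gap
#' read off the query coordinates, carrying the supporting matched sites.
#'
#' @param aln selected alignments from [filter_long_alignments()].
#' @return list with `positions` (query, target, position) and `links`.
#' @export
long_read_position <- function(aln) {
  if (nrow(aln) == 0L)
    return(list(positions = data.frame(query = character(0),
                                       target = integer(0),
                                       position = numeric(0)),
                links = empty_links()))
  key <- paste(aln$query, aln$target)
  pos <- do.call(rbind, lapply(split(aln, key), function(g) {
    data.frame(query = g$query[1], target = g$target[1],
               position = weighted.mean(g$tstart, g$aln_len),
               stringsAsFactors = FALSE)
  }))
  rownames(pos) <- NULL
  links <- list()
  for (g in split(aln, aln$query)) {
    g <- g[order(g$qstart), , drop = FALSE]
    g <- g[!duplicated(g$target), , drop = FALSE]
    if (nrow(g) < 2L) next
    for (i in seq_len(nrow(g) - 1L)) {
      x <- g[i, ]; y <- g[i + 1L, ]
      links[[length(links) + 1L]] <- data.frame(
        a = x$target, ea = ifelse(x$strand == "+", 1L, 0L),
        b = y$target, eb = ifelse(y$strand == "+", 0L, 1L),
        gap = y$qstart - x$qend, class = "long", lib = NA_integer_,
        matches = x$matches + y$matches, stringsAsFactors = FALSE)
    }
  }
  links <- if (length(links)) normalize_links(do.call(rbind, links)) else
    empty_links()
  list(positions = pos, links = links)
}

#' Count linked-read barcodes per node
#'
#' Parses the `BX:Z:` tag (with or without a space after `BX:`) from read
#' names, maps the reads, and counts reads per (node, barcode). Counts of 3
#' or fewer are discarded as likely mis-mappings.
#'
#' @param lib a linked `read_library` (barcode in the read names).
#' @param graph `dbg` or character vector of node sequences.
#' @param min_count counts at or below this are dropped (default 3).
#' @param seed_len seed length for placement.
#' @return data.frame (`node`, `barcode`, `count`).
#' @export
count_barcodes <- function(lib, graph, min_count = 3L, seed_len = 32L) {
  node_seqs <- if (inherits(graph, "dbg")) graph$nodes$seq else
    as.character(graph)
  reads <- c(lib$reads1, lib$reads2)
  bc <- extract_barcodes(names(reads) %||% character(length(reads)))
  ok <- !is.na(bc)
  if (!any(ok)) {
    warning("no BX:Z: barcode tags found in read names")
    return(data.frame(node = integer(0), barcode = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  n_bad <- sum(!ok)
  if (n_bad > 0L)
    message(sprintf("count_barcodes: %d reads without barcode tag skipped",
                    n_bad))
  pl <- cpp_map_reads(node_seqs, unname(reads[ok]), as.integer(seed_len))
  pl <- primary_placements(transform(pl, pair = read, mate = 1L))
  pl$barcode <- bc[ok][pl$read]
  tab <- stats::aggregate(list(count = pl$read),
                          by = list(node = pl$node, barcode = pl$barcode),
                          FUN = length)
  tab <- tab[tab$count > min_count, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

extract_barcodes <- function(names) {
  m <- regmatches(names, regexpr("BX:\\s?Z:\\s?(\\S+)", names))
  out <- rep(NA_character_, length(names))
  has <- grepl("BX:\\s?Z:\\s?\\S+", names)
  out[has] <- sub("BX:\\s?Z:\\s?", "", m)
  out
}
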