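# Haplotype synteny-based correction. Anchor bubbles from the initial de
# Bruijn graph associate homologous scaffolds: each scaffold is tiled into
# anchor segments (carrying the scaffold-ID of the counterpart branch) and
# non-anchor segments (b = 0), the majority counterpart B_max and the
# division score decide where a scaffold is trimmed, and mutually-majority
# scaffold pairs become phased bubbles.

#' Annotate scaffolds with anchor-bubble occurrences
#'
#' Locates both branch sequences of every anchor bubble in the scaffold
#' sequences; an anchor contributes only when each branch occurs exactly
#' once and the two branches sit on different scaffolds. Overlapping
#' occurrences on a scaffold keep the first.
#'
#' @param seqs character vector of scaffold sequences.
#' @param anchors an `anchor_set` from [detect_anchor_bubbles()].
#' @return data.frame: `scaf`, `pos` (0-based), `len`, `b` (counterpart
#'   scaffold id), `counter_scaf`, `anchor`, `branch`, `strand`, ordered by
#'   scaffold and position.
#' @export
annotate_anchors <- function(seqs, anchors) {
  empty <- data.frame(scaf = integer(0), pos = integer(0), len = integer(0),
                      b = integer(0), anchor = integer(0),
                      branch = integer(0), strand = integer(0))
  bub <- anchors$bubbles
  bub <- bub[bub$anchor %||% rep(TRUE, nrow(bub)), , drop = FALSE]
  if (is.null(bub) || nrow(bub) == 0L) return(empty)
  pats <- c(bub$seq1, bub$seq2)
  hits <- cpp_locate(pats, seqs, 32L, 3L)
  cnt <- tabulate(hits$pattern, nbins = length(pats))
  nb <- nrow(bub)
  u1 <- cnt[seq_len(nb)] == 1L
  u2 <- cnt[nb + seq_len(nb)] == 1L
  h1 <- hits[match(seq_len(nb), hits$pattern), ]
  h2 <- hits[match(nb + seq_len(nb), hits$pattern), ]
  ok <- u1 & u2 & h1$subject != h2$subject
  if (!any(ok)) return(empty)
  ann <- rbind(
    data.frame(scaf = h1$subject[ok], pos = h1$pos[ok],
               len = nchar(bub$seq1[ok]), b = h2$subject[ok],
               anchor = which(ok), branch = 1L, strand = h1$strand[ok]),
    data.frame(scaf = h2$subject[ok], pos = h2$pos[ok],
               len = nchar(bub$seq2[ok]), b = h1$subject[ok],
               anchor = which(ok), branch = 2L, strand = h2$strand[ok]))
  ann <- ann[order(ann$scaf, ann$pos), , drop = FALSE]
  # drop occurrences overlapping the previous kept one on the same scaffold
  keep <- logical(nrow(ann))
  last_scaf <- -1L; last_end <- -1L
  for (i in seq_len(nrow(ann))) {
    if (ann$scaf[i] != last_scaf || ann$pos[i] >= last_end) {
      keep[i] <- TRUE
      last_scaf <- ann$scaf[i]
      last_end <- ann$pos[i] + ann$len[i]
    }
  }
  ann <- ann[keep, , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

# tile one scaffold into segments: anchor segments plus the non-anchor
# stretches between/around them (b = 0); returns b, l vectors and segment
# boundaries (0-based, half-open)
tile_scaffold <- function(ann_s, slen) {
  starts <- integer(0); ends <- integer(0); b <- integer(0)
  aid <- integer(0)
  cur <- 0L
  for (i in seq_len(nrow(ann_s))) {
    p <- ann_s$pos[i]; l <- ann_s$len[i]
    if (p > cur) {
      starts <- c(starts, cur); ends <- c(ends, p); b <- c(b, 0L)
      aid <- c(aid, 0L)
    }
    starts <- c(starts, p); ends <- c(ends, p + l); b <- c(b, ann_s$b[i])
    aid <- c(aid, ann_s$anchor[i])
    cur <- p + l
  }
  if (cur < slen) {
    starts <- c(starts, cur); ends <- c(ends, slen); b <- c(b, 0L)
    aid <- c(aid, 0L)
  }
  data.frame(start = starts, end = ends, len = ends - starts, b = b,
             anchor = aid)
}

#' Division boundaries of a scaffold node from its anchor annotation
#'
#' `B_max` is the counterpart scaffold-ID with the largest total length of
#' supporting contigs (`L_sum`); `d_min`/`d_max` are the first and last
#' contigs pointing at `B_max`. The division score `S` walks from `d_min`
#' to `d_max` (base case `S(d_min - 1) = 0`), unchanged on non-anchor
#' contigs, decreasing by the contig length on `B_max` anchors and
#' increasing on foreign anchors; when any `S(x) > 0` the argmax (ties to
#' the smallest index) becomes the new `d_min`. A symmetric backward pass
#' corrects `d_max`.
#'
#' @param b integer vector: counterpart scaffold-ID per contig (0 =
#'   non-anchor).
#' @param l numeric vector of contig lengths.
#' @return list: `B_max`, `d_min`, `d_max`, `S` (forward score trace over
#'   `d_min..d_max` before correction), `changed`. `NULL` when all `b` are
#'   0 (no division applies).
#' @export
compute_division <- function(b, l) {
  stopifnot(length(b) == length(l))
  if (all(b == 0L)) return(NULL)
  ids <- sort(unique(b[b != 0L]))
  lsum <- vapply(ids, function(x) sum(l[b == x]), numeric(1))
  B_max <- ids[which.max(lsum)] # which.max takes the smallest id on ties
  idx <- which(b == B_max)
  d_min0 <- min(idx); d_max0 <- max(idx)
  xs <- d_min0:d_max0
  step <- ifelse(b[xs] == 0L, 0, ifelse(b[xs] == B_max, -l[xs], l[xs]))
  S <- cumsum(step)
  d_min <- d_min0
  if (any(S > 0)) d_min <- xs[which.max(S)]
  step_b <- ifelse(b[xs] == 0L, 0, ifelse(b[xs] == B_max, -l[xs], l[xs]))
  Sb <- rev(cumsum(rev(step_b)))
  d_max <- d_max0
  if (any(Sb > 0)) d_max <- xs[which.max(Sb)]
  if (d_min > d_max) { d_min <- d_min0; d_max <- d_max0 }
  list(B_max = B_max, d_min = d_min, d_max = d_max, S = S,
       changed = d_min != d_min0 || d_max != d_max0)
}

strip_gap_ends <- function(x) gsub("^N+|N+$", "", x)

# split a scaffold sequence at 0-based cut coordinates; returns the non-empty
# pieces with flanking gap Ns removed
split_seq_at <- function(seq, cuts) {
  cuts <- sort(unique(c(0L, cuts, nchar(seq))))
  pieces <- substring(seq, head(cuts, -1L) + 1L, tail(cuts, -1L))
  pieces <- strip_gap_ends(pieces)
  pieces[nzchar(pieces)]
}

#' Haplotype synteny-based correction
#'
#' Iterates two passes until the number of divisions reaches zero: (a)
#' every scaffold with anchors is reduced to its `[d_min, d_max]` segment
#' range (out-of-range pieces become separate scaffolds); (b) a scaffold
#' is divided at an internal anchor whose counterpart is the edge (first
#' or last) anchor segment of another scaffold, on the side implied by the
#' counterpart's edge and the relative strand of the two branch
#' occurrences. Divided pieces re-enter the pool as single-contig
#' scaffolds.
#'
#' @param ss a `scaffold_set`.
#' @param anchors an `anchor_set`.
#' @param max_rounds safety cap on correction rounds.
#' @return list: corrected `ss`, `n_divisions`, `rounds`.
#' @export
synteny_correct <- function(ss, anchors, max_rounds = 20L) {
  if (!is.finite(anchors$c_hetero))
    return(list(ss = ss, n_divisions = 0L, rounds = 0L))
  total_div <- 0L
  for (round in seq_len(max_rounds)) {
    seqs <- scaffold_seqs(ss)
    ann <- annotate_anchors(seqs, anchors)
    divisions <- 0L
    out_seqs <- character(0)
    # pass (a): trim to [d_min, d_max]
    pieces_of <- vector("list", length(seqs))
    for (si in seq_along(seqs)) {
      ann_s <- ann[ann$scaf == si, , drop = FALSE]
      if (nrow(ann_s) == 0L) { pieces_of[[si]] <- seqs[si]; next }
      tl <- tile_scaffold(ann_s, nchar(seqs[si]))
      dv <- compute_division(tl$b, tl$len)
      if (is.null(dv)) { pieces_of[[si]] <- seqs[si]; next }
      cuts <- c(tl$start[dv$d_min], tl$end[dv$d_max])
      pieces <- split_seq_at(seqs[si], cuts)
      if (length(pieces) > 1L) divisions <- divisions + length(pieces) - 1L
      pieces_of[[si]] <- pieces
    }
    if (divisions == 0L) {
      # pass (b): divide at internal anchors whose counterparts are edge
      # segments of other scaffolds
      edge_info <- edge_anchor_table(ann, seqs)
      cuts_of <- rep(list(integer(0)), length(seqs))
      for (i in seq_len(nrow(edge_info))) {
        e <- edge_info[i, ]
        if (e$counter_internal) {
          cuts_of[[e$counter_scaf]] <-
            c(cuts_of[[e$counter_scaf]], e$counter_cut)
        }
      }
      for (si in seq_along(seqs)) {
        if (length(cuts_of[[si]]) == 0L) next
        pieces <- split_seq_at(seqs[si], cuts_of[[si]])
        if (length(pieces) > 1L) {
          divisions <- divisions + length(pieces) - 1L
          pieces_of[[si]] <- pieces
        }
      }
    }
    new_seqs <- unlist(pieces_of, use.names = FALSE)
    if (divisions == 0L) break
    total_div <- total_div + divisions
    ss <- scaffold_from_seqs(new_seqs, ss)
  }
  list(ss = ss, n_divisions = total_div, rounds = round)
}

# for every anchor whose occurrence is the edge (first/last) anchor segment
# of its scaffold, find whether the counterpart occurrence is internal on
# its scaffold and where that scaffold would be cut
edge_anchor_table <- function(ann, seqs) {
  empty <- data.frame(counter_scaf = integer(0), counter_cut = integer(0),
                      counter_internal = logical(0))
  if (nrow(ann) == 0L) return(empty)
  ann$row <- seq_len(nrow(ann))
  is_edge <- rep(NA_character_, nrow(ann))
  for (g in split(ann, ann$scaf)) {
    if (nrow(g) < 2L) next # a single anchor gives no edge direction
    is_edge[g$row[1]] <- "first"
    is_edge[g$row[nrow(g)]] <- "last"
  }
  out <- list()
  for (i in seq_len(nrow(ann))) {
    if (is.na(is_edge[i])) next
    a <- ann[i, ]
    # counterpart occurrence: same anchor id, other branch
    j <- which(ann$anchor == a$anchor & ann$branch != a$branch)
    if (length(j) != 1L) next
    cp <- ann[j, ]
    if (!is.na(is_edge[j])) next # counterpart itself an edge: consistent
    rel_same <- a$strand == cp$strand
    # edge-ness transfers: first&same or last&opposite => counterpart
    # should start its scaffold (cut before it); otherwise end it
    cut_before <- (is_edge[i] == "first" & rel_same) |
      (is_edge[i] == "last" & !rel_same)
    cut <- if (cut_before) cp$pos else cp$pos + cp$len
    out[[length(out) + 1L]] <- data.frame(
      counter_scaf = cp$scaf, counter_cut = cut, counter_internal = TRUE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

# rebuild a scaffold_set from bare sequences (each piece one contig);
# depth approximated from the previous set's mean depth
scaffold_from_seqs <- function(seqs, old_ss) {
  depth <- if (nrow(old_ss$contigs))
    weighted.mean(old_ss$contigs$depth, old_ss$contigs$len) else 1
  contigs <- data.frame(seq = seqs, len = nchar(seqs), depth = depth,
                        stringsAsFactors = FALSE)
  scaffolds <- lapply(seq_along(seqs), function(i)
    data.frame(contig = i, orient = "+", gap_after = 0L,
               stringsAsFactors = FALSE))
  new_scaffold_set(contigs, scaffolds)
}

#' Pair anchor-containing scaffolds into phased bubbles
#'
#' Each scaffold's counterpart is the `B_max` of its annotation; mutual
#' majorities become bubble pairs, the member with more non-N bases is the
#' primary-bubble (ties break to the smaller scaffold id). Remaining
#' scaffolds are emitted as non-bubble sequences; scaffolds whose
#' annotation is not mutual (two distinct counterparts claimed) fall back
#' to non-bubble.
#'
#' @param ss a `scaffold_set`.
#' @param anchors an `anchor_set`.
#' @param min_len drop output sequences shorter than this many bases.
#' @return object of class `phased_blocks`: `blocks` data.frame (`name`,
#'   `seq`, `role`, `pair`), plus the `pairing` table.
#' @export
pair_bubbles <- function(ss, anchors, min_len = 0L) {
  seqs <- scaffold_seqs(ss)
  ann <- if (is.finite(anchors$c_hetero))
    annotate_anchors(seqs, anchors) else
    data.frame(scaf = integer(0), b = integer(0), len = integer(0))
  counterpart <- rep(NA_integer_, length(seqs))
  for (si in unique(ann$scaf)) {
    g <- ann[ann$scaf == si, ]
    dv <- compute_division(g$b, g$len)
    if (!is.null(dv)) counterpart[si] <- dv$B_max
  }
  mutual <- function(i) {
    cp <- counterpart[i]
    !is.na(cp) && cp >= 1L && cp <= length(seqs) && !is.na(counterpart[cp]) &&
      counterpart[cp] == i
  }
  paired <- which(vapply(seq_along(seqs), mutual, logical(1)))
  pairs <- if (length(paired))
    unique(t(vapply(paired, function(i)
      sort(c(i, counterpart[i])), integer(2)))) else NULL
  blocks <- list(); pairing <- list()
  nonN <- nchar(gsub("N", "", seqs, fixed = TRUE))
  pid <- 0L
  in_pair <- logical(length(seqs))
  if (!is.null(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      x <- pairs[i, 1]; y <- pairs[i, 2]
      if (x == y) next
      pid <- pid + 1L
      prim <- if (nonN[x] > nonN[y]) x else if (nonN[y] > nonN[x]) y else
        min(x, y)
      sec <- if (prim == x) y else x
      blocks[[length(blocks) + 1L]] <- data.frame(
        name = sprintf("primary_bubble_%d", pid), seq = seqs[prim],
        role = "primary", pair = pid, stringsAsFactors = FALSE)
      blocks[[length(blocks) + 1L]] <- data.frame(
        name = sprintf("secondary_bubble_%d", pid), seq = seqs[sec],
        role = "secondary", pair = pid, stringsAsFactors = FALSE)
      pairing[[length(pairing) + 1L]] <- data.frame(
        pair = pid, primary_scaf = prim, secondary_scaf = sec,
        primary_len = nchar(seqs[prim]), secondary_len = nchar(seqs[sec]))
      in_pair[c(x, y)] <- TRUE
    }
  }
  nb <- which(!in_pair)
  for (j in seq_along(nb)) {
    blocks[[length(blocks) + 1L]] <- data.frame(
      name = sprintf("nonbubble_%d", j), seq = seqs[nb[j]],
      role = "nonbubble", pair = NA_integer_, stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, blocks)
  blocks <- blocks[nchar(blocks$seq) >= min_len, , drop = FALSE]
  rownames(blocks) <- NULL
  structure(list(blocks = blocks,
                 pairing = if (length(pairing)) do.call(rbind, pairing) else
                   NULL),
            class = "phased_blocks")
}

#' @export
print.phased_blocks <- function(x, ...) {
  b <- x$blocks
  cat(sprintf("phased_blocks: %d bubble pairs, %d non-bubble sequences, %d bp total\n",
              sum(b$role == "primary"), sum(b$role == "nonbubble"),
              sum(nchar(b$seq))))
  invisible(x)
}
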