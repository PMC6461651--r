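# Graph untangling: anchor-bubble detection and c_hetero estimation on the
# initial graph, cross-structure detection under the coverage conditions,
# evidence-based parallel-vs-cross resolution (links, long-read match
# sites, linked-read barcodes), and the center-duplication rewrite that
# turns a resolved cross into two haplotype paths.

#' Detect simple bubbles and anchor bubbles; estimate c_hetero
#'
#' A simple bubble consists of two straight nodes (the branches), two
#' junction nodes and four (k-1)-overlap edges. Most simple bubbles are
#' heterozygous, so the length-weighted mean depth of all branch nodes
#' estimates the coverage of non-repetitive heterozygous regions,
#' `c_hetero`. A bubble is an anchor when both branch depths are at most
#' `r_upper * c_hetero` (repeat-derived bubbles are excluded this way).
#' Branch sequences are reported oriented consistently from the first
#' junction to the second, so counterpart branches run in the same
#' direction.
#'
#' @param graph the initial `dbg` (first-k graph).
#' @param r_upper repeat-exclusion ratio (default 1.75).
#' @return object of class `anchor_set`: `bubbles` data.frame (`b1`, `b2`,
#'   `j1`, `j2`, depths, lengths, oriented `seq1`/`seq2`, `anchor` flag),
#'   `c_hetero`, `r_upper`.
#' @export
detect_anchor_bubbles <- function(graph, r_upper = 1.75) {
  bub <- find_simple_bubbles(graph)
  if (nrow(bub) == 0L) {
    warning("no simple bubbles: c_hetero undefined; synteny correction disabled")
    return(structure(list(bubbles = bub, c_hetero = NA_real_,
                          r_upper = r_upper), class = "anchor_set"))
  }
  nd <- graph$nodes
  c_het <- weighted.mean(c(nd$depth[bub$b1], nd$depth[bub$b2]),
                         c(nd$len[bub$b1], nd$len[bub$b2]))
  bub$anchor <- nd$depth[bub$b1] <= r_upper * c_het &
    nd$depth[bub$b2] <= r_upper * c_het
  structure(list(bubbles = bub, c_hetero = c_het, r_upper = r_upper),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("anchor_set: %d simple bubbles, %d anchors, c_hetero = %.2f\n",
              nrow(x$bubbles), sum(x$bubbles$anchor %||% FALSE),
              x$c_hetero))
  invisible(x)
}

find_simple_bubbles <- function(graph) {
  empty <- data.frame(b1 = integer(0), b2 = integer(0), j1 = integer(0),
                      j2 = integer(0), len1 = integer(0), len2 = integer(0),
                      depth1 = numeric(0), depth2 = numeric(0),
                      seq1 = character(0), seq2 = character(0),
                      stringsAsFactors = FALSE)
  nd <- graph$nodes
  adj <- dbg_adjacency(graph)
  if (nrow(adj) == 0L) return(empty)
  deg <- end_degree(graph)
  # straight nodes with exactly one edge per end, both to junctions
  cand <- which(!nd$junction & deg[, 1] == 1L & deg[, 2] == 1L)
  if (length(cand) == 0L) return(empty)
  a0 <- adj[adj$end == 0L, ]
  a1 <- adj[adj$end == 1L, ]
  n0 <- setNames(a0$other, a0$node)[as.character(cand)]
  n1 <- setNames(a1$other, a1$node)[as.character(cand)]
  ok <- !is.na(n0) & !is.na(n1) & nd$junction[n0] & nd$junction[n1] & n0 != n1
  cand <- cand[ok]; n0 <- n0[ok]; n1 <- n1[ok]
  if (length(cand) == 0L) return(empty)
  key <- paste(pmin(n0, n1), pmax(n0, n1))
  out <- list()
  for (k2 in unique(key)) {
    idx <- which(key == k2)
    if (length(idx) != 2L) next
    b1 <- cand[idx[1]]; b2 <- cand[idx[2]]
    # orient both branches from the smaller junction id to the larger
    jlo <- pmin(n0[idx[1]], n1[idx[1]])
    s1 <- if (n0[idx[1]] == jlo) nd$seq[b1] else revcomp(nd$seq[b1])
    s2 <- if (n0[idx[2]] == jlo) nd$seq[b2] else revcomp(nd$seq[b2])
    out[[length(out) + 1L]] <- data.frame(
      b1 = b1, b2 = b2, j1 = jlo, j2 = max(n0[idx[1]], n1[idx[1]]),
      len1 = nd$len[b1], len2 = nd$len[b2],
      depth1 = nd$depth[b1], depth2 = nd$depth[b2],
      seq1 = s1, seq2 = s2, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Find cross structures eligible for untangling
#'
#' A cross structure is a straight center flanked by two junctions, each
#' junction attaching two further straight (external) nodes: five straight
#' nodes and two junctions in total. Eligibility requires center depth <=
#' `2 * r_upper * c_hetero` and min(external depths) <= `r_upper *
#' c_hetero`, targeting collapsed homozygous centers between heterozygous
#' flanks.
#'
#' @param graph a `dbg`.
#' @param c_hetero heterozygous-node depth estimate (> 0).
#' @param r_upper threshold ratio (default 1.75).
#' @return data.frame of cross structures, one row each: center node `s`,
#'   junctions, externals `e1`..`e4` with their center-facing ends
#'   `f1`..`f4`, the merged center sequence and its depth/length.
#' @export
find_cross_structures <- function(graph, c_hetero, r_upper = 1.75) {
  stopifnot(is.finite(c_hetero), c_hetero > 0)
  empty <- cross_empty()
  nd <- graph$nodes
  adj <- dbg_adjacency(graph)
  if (nrow(adj) == 0L) return(empty)
  deg <- end_degree(graph)
  k <- graph$k
  cand <- which(!nd$junction &
                  (deg[, 1] == 1L | deg[, 1] == 2L) &
                  (deg[, 2] == 1L | deg[, 2] == 2L) &
                  nd$depth <= 2 * r_upper * c_hetero)
  adj_by_node <- split(adj, adj$node)
  rows <- vector("list", length(cand))
  nr <- 0L
  for (s in cand) {
    side1 <- cross_side(adj_by_node, nd, s, 0L)
    side2 <- cross_side(adj_by_node, nd, s, 1L)
    if (is.null(side1) || is.null(side2)) next
    ext <- c(side1$ext, side2$ext)
    if (anyDuplicated(ext) || s %in% ext) next
    if (any(nd$junction[ext])) next
    if (!is.na(side1$j) && side1$j %in% ext) next
    if (!is.na(side2$j) && side2$j %in% ext) next
    if (min(nd$depth[ext]) > r_upper * c_hetero) next
    cseq <- center_sequence(nd$seq, k, s, side1, side2)
    nr <- nr + 1L
    rows[[nr]] <- list(s, side1$j, side2$j, side1$ext[1], side1$f[1],
                       side1$ext[2], side1$f[2], side2$ext[1], side2$f[1],
                       side2$ext[2], side2$f[2], cseq)
  }
  if (nr == 0L) return(empty)
  rows <- rows[seq_len(nr)]
  get_col <- function(i, mode = "integer")
    vapply(rows, function(r) r[[i]], vector(mode, 1))
  cseq <- get_col(12, "character")
  data.frame(
    s = get_col(1), j1 = get_col(2), j2 = get_col(3),
    e1 = get_col(4), f1 = get_col(5), e2 = get_col(6), f2 = get_col(7),
    e3 = get_col(8), f3 = get_col(9), e4 = get_col(10), f4 = get_col(11),
    center_seq = cseq, center_len = nchar(cseq),
    center_depth = nd$depth[get_col(1)], stringsAsFactors = FALSE)
}

cross_empty <- function() {
  data.frame(s = integer(0), j1 = integer(0), j2 = integer(0),
             e1 = integer(0), f1 = integer(0), e2 = integer(0),
             f2 = integer(0), e3 = integer(0), f3 = integer(0),
             e4 = integer(0), f4 = integer(0), center_seq = character(0),
             center_len = integer(0), center_depth = numeric(0),
             stringsAsFactors = FALSE)
}

# one side of a putative cross at (s, end): either a junction node with two
# externals on its far end, or (after earlier untangling absorbed the
# junctions) two direct edges to straight externals
cross_side <- function(adj_by_node, nd, s, end) {
  es <- adj_by_node[[as.character(s)]]
  es <- es[es$end == end, , drop = FALSE]
  if (nrow(es) == 1L) {
    j <- es$other[1]
    if (!nd$junction[j] || j == s) return(NULL)
    ej <- adj_by_node[[as.character(j)]]
    if (nrow(ej) != 3L) return(NULL)
    if (sum(ej$end == es$other_end[1]) != 1L) return(NULL)
    others <- ej[ej$end == (1L - es$other_end[1]), , drop = FALSE]
    if (nrow(others) != 2L) return(NULL)
    list(j = j, j_end = es$other_end[1], ext = others$other,
         f = others$other_end)
  } else if (nrow(es) == 2L) {
    if (any(nd$junction[es$other])) return(NULL)
    list(j = NA_integer_, j_end = NA_integer_, ext = es$other,
         f = es$other_end)
  } else NULL
}

# merged center node: any flanking junctions are collapsed into the center
# over their (k-1) overlaps, adding one base on the corresponding side
center_sequence <- function(seqs, k, s, side1, side2) {
  left <- ""
  if (!is.na(side1$j)) {
    o1 <- if (side1$j_end == 1L) seqs[side1$j] else revcomp(seqs[side1$j])
    left <- substr(o1, 1L, 1L)
  }
  right <- ""
  if (!is.na(side2$j)) {
    o2 <- if (side2$j_end == 0L) seqs[side2$j] else revcomp(seqs[side2$j])
    right <- substr(o2, k, k)
  }
  paste0(left, seqs[s], right)
}

#' Decide a cross-structure solution from evidence scores
#'
#' One solution is adopted when its score is at least `ratio` times the
#' alternative's and at least 1 (zero evidence never phases). The barcode
#' method is disabled for centers of 200 kbp or longer (linked-read DNA
#' fragments cannot span them).
#'
#' @param par_score evidence supporting the parallel solution
#'   (e1-e3 / e2-e4).
#' @param cross_score evidence supporting the crossed solution
#'   (e1-e4 / e2-e3).
#' @param method evidence class: `"link"` (link counts), `"match"`
#'   (long-read match-site sums) or `"barcode"` (common-barcode read
#'   counts).
#' @param center_len center node length in bp (used by the barcode rule).
#' @param ratio required dominance ratio (default 4).
#' @return list: `decision` (`"parallel"`, `"cross"` or `"unresolved"`),
#'   `winning`, `alternative`, `method`.
#' @export
resolve_cross <- function(par_score, cross_score,
                          method = c("link", "match", "barcode"),
                          center_len = 0L, ratio = 4) {
  method <- match.arg(method)
  if (method == "barcode" && center_len >= 200000L)
    return(list(decision = "unresolved", winning = NA_real_,
                alternative = NA_real_, method = method))
  if (par_score >= max(1, ratio * cross_score))
    return(list(decision = "parallel", winning = par_score,
                alternative = cross_score, method = method))
  if (cross_score >= max(1, ratio * par_score))
    return(list(decision = "cross", winning = cross_score,
                alternative = par_score, method = method))
  list(decision = "unresolved", winning = NA_real_,
       alternative = NA_real_, method = method)
}

# precomputed support per oriented node pair: key -> count (or weight sum)
link_index <- function(links, weight = NULL) {
  if (nrow(links) == 0L) return(numeric(0))
  key <- paste(links$a, links$ea, links$b, links$eb)
  w <- if (is.null(weight)) rep(1, nrow(links)) else links[[weight]]
  tapply(w, key, sum, na.rm = TRUE)
}

# count link support between an oriented external pair
link_support <- function(idx, x, fx, y, fy) {
  if (length(idx) == 0L) return(0)
  if (x > y || (x == y && fx > fy)) {
    tmp <- x; x <- y; y <- tmp
    tmp <- fx; fx <- fy; fy <- tmp
  }
  v <- idx[paste(x, fx, y, fy)]
  if (is.na(v)) 0 else as.numeric(v)
}

cross_scores <- function(cs, idx) {
  par <- link_support(idx, cs$e1, cs$f1, cs$e3, cs$f3) +
    link_support(idx, cs$e2, cs$f2, cs$e4, cs$f4)
  crs <- link_support(idx, cs$e1, cs$f1, cs$e4, cs$f4) +
    link_support(idx, cs$e2, cs$f2, cs$e3, cs$f3)
  c(par = par, cross = crs)
}

# barcode-method scores: reads over barcodes common to an external pair
barcode_scores <- function(cs, bctab) {
  pair_score <- function(x, y) {
    bx <- bctab[bctab$node == x, ]
    by <- bctab[bctab$node == y, ]
    common <- intersect(bx$barcode, by$barcode)
    if (length(common) == 0L) return(0)
    sum(bx$count[bx$barcode %in% common]) +
      sum(by$count[by$barcode %in% common])
  }
  c(par = pair_score(cs$e1, cs$e3) + pair_score(cs$e2, cs$e4),
    cross = pair_score(cs$e1, cs$e4) + pair_score(cs$e2, cs$e3))
}

#' Untangle cross structures iteratively
#'
#' Per round: reads are mapped to the current node set, evidence is
#' evaluated per library in ascending insert order plus all libraries
#' combined (and, when available, long-read match sites and linked-read
#' barcodes), eligible crosses are detected, and every resolved cross is
#' rewritten by duplicating its center (each copy inherits half the depth)
#' into two haplotype paths, followed by chain merging. Conflicting
#' decisions across evidence classes leave a cross unresolved. The
#' iteration stops after `rounds` rounds or when no cross is untangled.
#'
#' @param graph a `dbg`.
#' @param libs read libraries (see [map_short_reads()]); long libraries are
#'   aligned with minimap2 when present.
#' @param c_hetero heterozygous depth estimate from
#'   [detect_anchor_bubbles()].
#' @param r_upper,ratio thresholds (defaults 1.75 and 4).
#' @param rounds iteration cap (default 5).
#' @param barcode_min barcode count threshold (counts <= this dropped).
#' @param verbose print per-round progress.
#' @return list: `graph` (untangled), `log` (per-cross decisions:
#'   round, center length, scores, method, decision).
#' @export
untangle_graph <- function(graph, libs, c_hetero, r_upper = 1.75, ratio = 4,
                           rounds = 5L, barcode_min = 3L, verbose = FALSE) {
  if (inherits(libs, "read_library")) libs <- list(libs)
  log <- list()
  for (round in seq_len(rounds)) {
    if (!is.finite(c_hetero) || c_hetero <= 0) break
    crosses <- find_cross_structures(graph, c_hetero, r_upper)
    if (nrow(crosses) == 0L) break
    mp <- map_short_reads(graph, libs)
    evidence_sets <- lapply(split(mp$links, mp$links$lib), link_index)
    names(evidence_sets) <- paste0("lib", names(evidence_sets))
    evidence_sets$all <- link_index(mp$links)
    long_links <- gather_long_links(graph, libs)
    long_idx <- if (!is.null(long_links) && nrow(long_links))
      link_index(long_links, weight = "matches") else NULL
    bctab <- gather_barcode_tab(graph, libs, barcode_min)
    n_cross <- nrow(crosses)
    dec_v <- character(n_cross)
    method_v <- rep(NA_character_, n_cross)
    win_v <- rep(NA_real_, n_cross)
    alt_v <- rep(NA_real_, n_cross)
    touched <- integer(0)
    ext_used <- integer(0)
    accept_idx <- integer(0)
    for (ci in seq_len(n_cross)) {
      cs <- crosses[ci, ]
      core <- c(cs$s, cs$j1, cs$j2)
      core <- core[!is.na(core)]
      exts <- c(cs$e1, cs$e2, cs$e3, cs$e4)
      dec_v[ci] <- "unresolved"
      if (length(intersect(core, c(touched, ext_used))) ||
          length(intersect(exts, touched))) next
      decisions <- character(0)
      rec <- NULL
      for (en in names(evidence_sets)) {
        sc <- cross_scores(cs, evidence_sets[[en]])
        r <- resolve_cross(sc["par"], sc["cross"], "link", cs$center_len,
                           ratio)
        if (r$decision != "unresolved") {
          decisions <- c(decisions, r$decision)
          rec <- rec %||% c(en, r$decision, r$winning, r$alternative)
        }
      }
      if (!is.null(long_idx)) {
        sc <- cross_scores(cs, long_idx)
        r <- resolve_cross(sc["par"], sc["cross"], "match", cs$center_len,
                           ratio)
        if (r$decision != "unresolved") {
          decisions <- c(decisions, r$decision)
          rec <- rec %||% c("long", r$decision, r$winning, r$alternative)
        }
      }
      if (!is.null(bctab) && nrow(bctab)) {
        sc <- barcode_scores(cs, bctab)
        r <- resolve_cross(sc["par"], sc["cross"], "barcode", cs$center_len,
                           ratio)
        if (r$decision != "unresolved") {
          decisions <- c(decisions, r$decision)
          rec <- rec %||% c("barcode", r$decision, r$winning, r$alternative)
        }
      }
      decision <- if (length(unique(decisions)) == 1L) decisions[1] else
        "unresolved" # none, or conflicting evidence classes
      dec_v[ci] <- decision
      if (!is.null(rec)) {
        method_v[ci] <- rec[1]
        win_v[ci] <- as.numeric(rec[3])
        alt_v[ci] <- as.numeric(rec[4])
      }
      if (decision == "unresolved") next
      accept_idx <- c(accept_idx, ci)
      touched <- c(touched, core)
      ext_used <- c(ext_used, exts)
    }
    log[[length(log) + 1L]] <- data.frame(
      round = round, center_len = crosses$center_len, method = method_v,
      winning = win_v, alternative = alt_v, decision = dec_v,
      stringsAsFactors = FALSE)
    if (length(accept_idx) == 0L) break
    accepted <- crosses[accept_idx, , drop = FALSE]
    accepted$decision <- dec_v[accept_idx]
    graph <- apply_untangles(graph, accepted)
    graph <- merge_chains(graph)
    if (verbose)
      message(sprintf("untangle round %d: %d crosses resolved; %d nodes",
                      round, nrow(accepted), nrow(graph$nodes)))
  }
  list(graph = graph,
       log = if (length(log)) do.call(rbind, log) else NULL)
}

gather_long_links <- function(graph, libs, k = graph$k) {
  long <- Filter(function(l) l$spec$type == "long", libs)
  if (length(long) == 0L || !minimap2_available()) return(NULL)
  reads <- unlist(lapply(long, function(l) l$reads1))
  targets <- setNames(graph$nodes$seq, seq_len(nrow(graph$nodes)))
  paf <- align_minimap2(reads, targets,
                        preset = c("-c", "-k", "15"), cs = FALSE)
  if (nrow(paf) == 0L) return(NULL)
  aln <- data.frame(query = paf$query, qlen = paf$qlen, qstart = paf$qstart,
                    qend = paf$qend, target = as.integer(paf$target),
                    tlen = paf$tlen, tstart = paf$tstart, tend = paf$tend,
                    strand = paf$strand, matches = paf$matches,
                    aln_len = paf$aln_len, stringsAsFactors = FALSE)
  sel <- filter_long_alignments(aln, k)
  long_read_position(sel)$links
}

gather_barcode_tab <- function(graph, libs, barcode_min) {
  linked <- Filter(function(l) l$spec$type == "linked", libs)
  if (length(linked) == 0L) return(NULL)
  do.call(rbind, lapply(linked, count_barcodes, graph = graph,
                        min_count = barcode_min))
}

# rewrite each resolved cross: drop center + junctions, add two center
# copies wired to the externals according to the decision
apply_untangles <- function(graph, resolved) {
  nd <- graph$nodes
  ed <- graph$edges
  n0 <- nrow(nd)
  m <- nrow(resolved)
  drop_nodes <- logical(n0)
  core <- c(resolved$s, resolved$j1, resolved$j2)
  drop_nodes[core[!is.na(core)]] <- TRUE
  # two centre copies per cross, ids idA = n0 + 2i - 1, idB = n0 + 2i
  idA <- n0 + 2L * seq_len(m) - 1L
  idB <- idA + 1L
  new_nodes <- data.frame(
    seq = rep(resolved$center_seq, each = 2L),
    cov = rep(nd$cov[resolved$s], each = 2L),
    depth = rep(nd$depth[resolved$s] / 2, each = 2L),
    junction = FALSE, len = rep(nchar(resolved$center_seq), each = 2L),
    stringsAsFactors = FALSE)
  par <- resolved$decision == "parallel"
  new_edges <- data.frame(
    a = c(resolved$e1, ifelse(par, resolved$e3, resolved$e4),
          resolved$e2, ifelse(par, resolved$e4, resolved$e3)),
    ea = c(resolved$f1, ifelse(par, resolved$f3, resolved$f4),
           resolved$f2, ifelse(par, resolved$f4, resolved$f3)),
    b = c(idA, idA, idB, idB),
    eb = rep(c(0L, 1L, 0L, 1L), each = m))
  keep_edge <- !(drop_nodes[ed$a] | drop_nodes[ed$b])
  nodes <- rbind(nd, new_nodes)
  edges <- rbind(ed[keep_edge, , drop = FALSE], new_edges)
  compact_graph(new_dbg(graph$k, nodes, edges),
                !c(drop_nodes, logical(2L * m)))
}

# drop flagged-out nodes and renumber edges
compact_graph <- function(graph, keep) {
  map <- integer(length(keep))
  map[keep] <- seq_len(sum(keep))
  ed <- graph$edges
  ed <- ed[keep[ed$a] & keep[ed$b], , drop = FALSE]
  ed$a <- map[ed$a]
  ed$b <- map[ed$b]
  new_dbg(graph$k, graph$nodes[keep, , drop = FALSE], ed)
}

#' Merge forced chains of nodes
#'
#' Concatenates nodes connected through ends of degree one on both sides
#' (collapsing the (k-1)-mer overlap), so untangled haplotype paths become
#' single straight nodes. Depth is length-weighted; merged nodes lose the
#' junction flag.
#'
#' @param graph a `dbg`.
#' @return the simplified `dbg`.
#' @export
merge_chains <- function(graph) {
  nd <- graph$nodes
  ed <- graph$edges
  if (nrow(ed) == 0L) return(graph)
  deg <- end_degree(graph)
  joinable <- deg[cbind(ed$a, ed$ea + 1L)] == 1L &
    deg[cbind(ed$b, ed$eb + 1L)] == 1L & ed$a != ed$b
  if (!any(joinable)) return(graph)
  jmap <- new.env(parent = emptyenv())
  for (i in which(joinable)) {
    assign(paste(ed$a[i], ed$ea[i]), c(ed$b[i], ed$eb[i]), envir = jmap)
    assign(paste(ed$b[i], ed$eb[i]), c(ed$a[i], ed$ea[i]), envir = jmap)
  }
  joined_end <- function(n, e) exists(paste(n, e), envir = jmap)
  n_nodes <- nrow(nd)
  visited <- logical(n_nodes)
  chains <- list()
  # start at chain termini: a joined node whose other end is not joined
  for (n in seq_len(n_nodes)) {
    if (visited[n]) next
    outer <- if (!joined_end(n, 0L) && joined_end(n, 1L)) 0L
      else if (!joined_end(n, 1L) && joined_end(n, 0L)) 1L
      else next
    ch <- walk_chain(n, outer, jmap)
    visited[ch$node] <- TRUE
    chains[[length(chains) + 1L]] <- ch
  }
  # cycles of forced joins: break at the smallest node id
  for (n in seq_len(n_nodes)) {
    if (visited[n] || !(joined_end(n, 0L) && joined_end(n, 1L))) next
    partner <- get(paste(n, 0L), envir = jmap)
    rm(list = c(paste(n, 0L), paste(partner[1], partner[2])), envir = jmap)
    ch <- walk_chain(n, 0L, jmap)
    visited[ch$node] <- TRUE
    chains[[length(chains) + 1L]] <- ch
  }
  chains <- Filter(function(ch) length(ch$node) > 1L, chains)
  if (length(chains) == 0L) return(graph)
  k <- graph$k
  new_nodes <- list()
  remap <- list() # old (node,end) -> new (node,end) for terminus ends
  drop <- logical(n_nodes)
  for (ch in chains) {
    m <- length(ch$node)
    seqs <- nd$seq[ch$node]
    seqs[ch$rev] <- revcomp(seqs[ch$rev])
    pieces <- c(seqs[1], substring(seqs[-1L], k, nchar(seqs[-1L])))
    newseq <- paste(pieces, collapse = "")
    newid <- n_nodes + length(new_nodes) + 1L
    new_nodes[[length(new_nodes) + 1L]] <- data.frame(
      seq = newseq, cov = weighted.mean(nd$cov[ch$node], nd$len[ch$node]),
      depth = weighted.mean(nd$depth[ch$node], nd$len[ch$node]),
      junction = FALSE, len = nchar(newseq), stringsAsFactors = FALSE)
    drop[ch$node] <- TRUE
    remap[[length(remap) + 1L]] <- data.frame(
      node = c(ch$node[1], ch$node[m]),
      end = c(ch$outer_first, ch$outer_last),
      new = newid, new_end = c(0L, 1L))
  }
  remap <- do.call(rbind, remap)
  # rewrite edges still touching dropped terminus ends
  rewrite <- function(nodes, ends) {
    idx <- match(paste(nodes, ends), paste(remap$node, remap$end))
    list(node = ifelse(is.na(idx), nodes, remap$new[idx]),
         end = ifelse(is.na(idx), ends, remap$new_end[idx]))
  }
  ra <- rewrite(ed$a, ed$ea)
  rb <- rewrite(ed$b, ed$eb)
  ed2 <- data.frame(a = ra$node, ea = ra$end, b = rb$node, eb = rb$end)
  keep_edge <- !(drop[pmin(ed2$a, n_nodes)] & ed2$a <= n_nodes) &
    !(drop[pmin(ed2$b, n_nodes)] & ed2$b <= n_nodes)
  ed2 <- ed2[keep_edge, , drop = FALSE]
  nodes <- rbind(nd, do.call(rbind, new_nodes))
  g <- new_dbg(k, nodes, ed2)
  compact_graph(g, !c(drop, logical(length(new_nodes))))
}

walk_chain <- function(start, outer, jmap) {
  node <- start
  rev <- outer == 1L # orient so the outer end is on the left
  inner <- 1L - outer
  nodes <- node
  revs <- rev
  repeat {
    key <- paste(node, inner)
    if (!exists(key, envir = jmap)) break
    nxt <- get(key, envir = jmap)
    node <- nxt[1]
    entry <- nxt[2]
    rev <- entry == 1L
    inner <- 1L - entry
    nodes <- c(nodes, node)
    revs <- c(revs, rev)
  }
  list(node = nodes, rev = revs, outer_first = outer, outer_last = inner)
}
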