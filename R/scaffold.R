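# Scaffolding and haplotype synteny-based correction. Scaffolds are
# ordered contigs with estimated gaps; link evidence from all libraries is
# lifted to scaffold ends and bundled, cross structures in the scaffold
# graph are untangled with the same evidence rules as in the de Bruijn
# graph, and scaffolds are corrected and paired through anchor bubbles.

new_scaffold_set <- function(contigs, scaffolds) {
  structure(list(contigs = contigs, scaffolds = scaffolds),
            class = "scaffold_set")
}

#' Initialise scaffolds from a contig table
#'
#' @param contigs data.frame with `seq`, `depth` (e.g. from
#'   [dbg_contigs()]).
#' @return a `scaffold_set` with one single-contig scaffold per contig.
#' @export
scaffold_init <- function(contigs) {
  contigs <- data.frame(seq = contigs$seq, len = nchar(contigs$seq),
                        depth = contigs$depth, stringsAsFactors = FALSE)
  scaffolds <- lapply(seq_len(nrow(contigs)), function(i)
    data.frame(contig = i, orient = "+", gap_after = 0L,
               stringsAsFactors = FALSE))
  new_scaffold_set(contigs, scaffolds)
}

#' @export
print.scaffold_set <- function(x, ...) {
  sl <- scaffold_lengths(x)
  cat(sprintf("scaffold_set: %d scaffolds over %d contigs; total %d bp; max %d bp\n",
              length(x$scaffolds), nrow(x$contigs), sum(sl), max(sl, 0L)))
  invisible(x)
}

#' Materialise scaffold sequences
#'
#' @param ss a `scaffold_set`.
#' @return character vector; inter-contig gaps rendered as `N` runs.
#' @export
scaffold_seqs <- function(ss) {
  vapply(ss$scaffolds, function(m) {
    s <- ss$contigs$seq[m$contig]
    s[m$orient == "-"] <- revcomp(s[m$orient == "-"])
    gaps <- strrep("N", pmax(m$gap_after, 0L))
    gaps[length(gaps)] <- ""
    paste(paste0(s, gaps), collapse = "")
  }, character(1))
}

scaffold_lengths <- function(ss) {
  vapply(ss$scaffolds, function(m) {
    n <- nrow(m)
    sum(ss$contigs$len[m$contig]) + sum(pmax(m$gap_after[-n], 0L))
  }, integer(1))
}

scaffold_depths <- function(ss) {
  vapply(ss$scaffolds, function(m)
    weighted.mean(ss$contigs$depth[m$contig], ss$contigs$len[m$contig]),
    numeric(1))
}

# contig placement table: scaffold, index, 0-based start, orientation
contig_places <- function(ss) {
  out <- lapply(seq_along(ss$scaffolds), function(si) {
    m <- ss$scaffolds[[si]]
    lens <- ss$contigs$len[m$contig]
    starts <- cumsum(c(0L, head(lens + pmax(m$gap_after, 0L), -1L)))
    data.frame(contig = m$contig, scaf = si, idx = seq_len(nrow(m)),
               start = starts, orient = m$orient, len = lens,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

reverse_members <- function(m) {
  n <- nrow(m)
  data.frame(contig = rev(m$contig),
             orient = ifelse(rev(m$orient) == "+", "-", "+"),
             gap_after = rev(c(0L, m$gap_after[-n])),
             stringsAsFactors = FALSE)
}

# orient a scaffold so the given end is on the right (end 1)
orient_members <- function(m, end_right) {
  if (end_right == 1L) m else reverse_members(m)
}

join_members <- function(ma, gap, mb) {
  ma$gap_after[nrow(ma)] <- max(as.integer(round(gap)), 1L)
  rbind(ma, mb)
}

# lift contig-level links to scaffold ends; drops intra-scaffold links
lift_links <- function(ss, links) {
  if (nrow(links) == 0L) return(cbind(links, ga = numeric(0)))
  cp <- contig_places(ss)
  slen <- scaffold_lengths(ss)
  ia <- match(links$a, cp$contig)
  ib <- match(links$b, cp$contig)
  ok <- !is.na(ia) & !is.na(ib)
  links <- links[ok, , drop = FALSE]
  ia <- ia[ok]; ib <- ib[ok]
  lift_one <- function(i, e) {
    dir_out <- ifelse(cp$orient[i] == "+", e, 1L - e)
    d <- ifelse(dir_out == 1L,
                slen[cp$scaf[i]] - cp$start[i] - cp$len[i],
                cp$start[i])
    list(scaf = cp$scaf[i], end = dir_out, d = d)
  }
  la <- lift_one(ia, links$ea)
  lb <- lift_one(ib, links$eb)
  out <- data.frame(a = la$scaf, ea = la$end, b = lb$scaf, eb = lb$end,
                    gap = links$gap - la$d - lb$d, class = links$class,
                    lib = links$lib, matches = links$matches,
                    stringsAsFactors = FALSE)
  out <- out[out$a != out$b, , drop = FALSE]
  normalize_links(out)
}

#' Build a scaffold graph from contigs and link evidence
#'
#' Links are lifted to scaffold ends and bundled per oriented scaffold
#' pair; bundles below the minimum-link threshold are dropped, and the
#' bundle gap is the median of the per-link estimates. Scaffolds shorter
#' than `short_len` are excluded from the graph unless they contain an
#' anchor bubble (candidate heterozygous nodes are never excluded).
#'
#' @param ss a `scaffold_set`.
#' @param links contig-level link evidence from [map_short_reads()].
#' @param min_link minimum supporting links per bundle (default 2).
#' @param short_len short-node exclusion length (0 disables exclusion).
#' @param anchored_contigs integer ids of contigs carrying anchor bubbles.
#' @return object of class `scaffold_graph`: the `scaffold_set`, the
#'   `bundles` table and the excluded scaffold ids.
#' @export
build_scaffold_graph <- function(ss, links, min_link = 2L, short_len = 0L,
                                 anchored_contigs = integer(0)) {
  lifted <- lift_links(ss, links)
  slen <- scaffold_lengths(ss)
  has_anchor <- vapply(ss$scaffolds, function(m)
    any(m$contig %in% anchored_contigs), logical(1))
  excluded <- which(slen < short_len & !has_anchor)
  if (length(excluded) && nrow(lifted))
    lifted <- lifted[!(lifted$a %in% excluded | lifted$b %in% excluded), ,
                     drop = FALSE]
  bundles <- bundle_links(lifted, min_link)
  structure(list(ss = ss, lifted = lifted, bundles = bundles,
                 excluded = excluded),
            class = "scaffold_graph")
}

bundle_links <- function(lifted, min_link) {
  if (nrow(lifted) == 0L)
    return(data.frame(a = integer(0), ea = integer(0), b = integer(0),
                      eb = integer(0), support = integer(0),
                      gap = numeric(0)))
  key <- paste(lifted$a, lifted$ea, lifted$b, lifted$eb)
  sp <- split(lifted, key)
  out <- do.call(rbind, lapply(sp, function(g)
    data.frame(a = g$a[1], ea = g$ea[1], b = g$b[1], eb = g$eb[1],
               support = nrow(g), gap = median(g$gap))))
  rownames(out) <- NULL
  out[out$support >= min_link, , drop = FALSE]
}

# bundles incident to each scaffold end
end_bundle_count <- function(bundles, n_scaf) {
  cnt <- matrix(0L, n_scaf, 2)
  if (nrow(bundles)) {
    for (i in seq_len(nrow(bundles))) {
      cnt[bundles$a[i], bundles$ea[i] + 1L] <-
        cnt[bundles$a[i], bundles$ea[i] + 1L] + 1L
      cnt[bundles$b[i], bundles$eb[i] + 1L] <-
        cnt[bundles$b[i], bundles$eb[i] + 1L] + 1L
    }
  }
  cnt
}

#' Untangle cross structures in the scaffold graph
#'
#' A scaffold-level cross is a center scaffold whose two ends each carry
#' exactly two bundles to distinct external scaffolds, with the same
#' coverage-depth eligibility and the same 4x evidence rules as in the de
#' Bruijn graph; edges here derive from read-mapping links rather than
#' (k-1) overlaps. Resolved crosses are rewritten into two joined
#' haplotype scaffolds.
#'
#' @param sg a `scaffold_graph` from [build_scaffold_graph()].
#' @param c_hetero heterozygous depth estimate (NA skips untangling).
#' @param r_upper,ratio thresholds.
#' @param bctab optional contig-level barcode table (node = contig id).
#' @return list: updated `scaffold_set` (`ss`), `n_untangled`, `log`.
#' @export
untangle_scaffold <- function(sg, c_hetero, r_upper = 1.75, ratio = 4,
                              bctab = NULL) {
  ss <- sg$ss
  bundles <- sg$bundles
  log <- list()
  if (!is.finite(c_hetero) || nrow(bundles) == 0L)
    return(list(ss = ss, n_untangled = 0L, log = NULL))
  n <- length(ss$scaffolds)
  cnt <- end_bundle_count(bundles, n)
  depths <- scaffold_depths(ss)
  slens <- scaffold_lengths(ss)
  sbc <- NULL
  if (!is.null(bctab) && nrow(bctab)) {
    cp <- contig_places(ss)
    idx <- match(bctab$node, cp$contig)
    ok <- !is.na(idx)
    sbc <- stats::aggregate(
      list(count = bctab$count[ok]),
      by = list(node = cp$scaf[idx[ok]], barcode = bctab$barcode[ok]),
      FUN = sum)
  }
  end_partners <- function(s, e) {
    ba <- bundles[bundles$a == s & bundles$ea == e, c("b", "eb", "gap")]
    bb <- bundles[bundles$b == s & bundles$eb == e, c("a", "ea", "gap")]
    names(ba) <- names(bb) <- c("node", "end", "gap")
    rbind(ba, bb)
  }
  used <- logical(n)
  applied <- list()
  sets <- lapply(split(sg$lifted, sg$lifted$lib), link_index)
  sets$all <- link_index(sg$lifted)
  long_lift <- sg$lifted[sg$lifted$class == "long", , drop = FALSE]
  long_idx <- if (nrow(long_lift)) link_index(long_lift, weight = "matches")
    else NULL
  centers <- which(cnt[, 1] == 2L & cnt[, 2] == 2L &
                     depths <= 2 * r_upper * c_hetero)
  for (s in centers) {
    if (used[s]) next
    p0 <- end_partners(s, 0L)
    p1 <- end_partners(s, 1L)
    ext <- c(p0$node, p1$node)
    if (length(ext) != 4L || anyDuplicated(ext) || s %in% ext) next
    if (any(used[ext])) next
    if (min(depths[ext]) > r_upper * c_hetero) next
    cs <- data.frame(e1 = p0$node[1], f1 = p0$end[1],
                     e2 = p0$node[2], f2 = p0$end[2],
                     e3 = p1$node[1], f3 = p1$end[1],
                     e4 = p1$node[2], f4 = p1$end[2],
                     center_len = slens[s])
    decisions <- character(0); rec <- NULL
    for (en in names(sets)) {
      sc <- cross_scores(cs, sets[[en]])
      r <- resolve_cross(sc["par"], sc["cross"], "link", cs$center_len, ratio)
      if (r$decision != "unresolved") {
        decisions <- c(decisions, r$decision)
        rec <- rec %||% c(en, r$decision, r$winning, r$alternative)
      }
    }
    if (!is.null(long_idx)) {
      sc <- cross_scores(cs, long_idx)
      r <- resolve_cross(sc["par"], sc["cross"], "match", cs$center_len, ratio)
      if (r$decision != "unresolved") {
        decisions <- c(decisions, r$decision)
        rec <- rec %||% c("long", r$decision, r$winning, r$alternative)
      }
    }
    if (!is.null(sbc) && nrow(sbc)) {
      sc <- barcode_scores(cs, sbc)
      r <- resolve_cross(sc["par"], sc["cross"], "barcode", cs$center_len,
                         ratio)
      if (r$decision != "unresolved") {
        decisions <- c(decisions, r$decision)
        rec <- rec %||% c("barcode", r$decision, r$winning, r$alternative)
      }
    }
    decision <- if (length(unique(decisions)) == 1L) decisions[1] else
      "unresolved"
    log[[length(log) + 1L]] <- data.frame(
      center = s, center_len = cs$center_len,
      method = if (is.null(rec)) NA_character_ else rec[1],
      decision = decision, stringsAsFactors = FALSE)
    if (decision == "unresolved") next
    gaps0 <- p0$gap; gaps1 <- p1$gap
    pairing <- if (decision == "parallel") list(c(1L, 1L), c(2L, 2L)) else
      list(c(1L, 2L), c(2L, 1L))
    for (pr in pairing) {
      i0 <- pr[1]; i1 <- pr[2]
      # the external's linked end must face the center: put it on the right
      left <- orient_members(ss$scaffolds[[p0$node[i0]]],
                             end_right = p0$end[i0])
      mid <- ss$scaffolds[[s]] # center end 0 on the left
      right <- orient_members(ss$scaffolds[[p1$node[i1]]],
                              end_right = 1L - p1$end[i1])
      m <- join_members(join_members(left, gaps0[i0], mid), gaps1[i1], right)
      applied[[length(applied) + 1L]] <- m
    }
    used[c(s, ext)] <- TRUE
  }
  if (length(applied) == 0L)
    return(list(ss = ss, n_untangled = 0L,
                log = if (length(log)) do.call(rbind, log) else NULL))
  keep <- which(!used)
  ss2 <- new_scaffold_set(ss$contigs, c(ss$scaffolds[keep], applied))
  list(ss = ss2, n_untangled = length(applied) / 2L,
       log = if (length(log)) do.call(rbind, log) else NULL)
}

# joins between scaffold ends. Long-insert links span several scaffolds
# ahead, so an end may legitimately carry bundles to every scaffold within
# insert reach: the join candidate is the nearest partner by estimated
# gap, rejected when the second-nearest partner's gap falls inside the
# nearest partner's span (two scaffolds competing for the same position,
# e.g. an unresolved haplotype fork), and a join is made only when the
# choice is mutual.
join_unambiguous <- function(ss, bundles, slack = 200) {
  n <- length(ss$scaffolds)
  if (nrow(bundles) == 0L) return(list(ss = ss, n_joined = 0L))
  slen <- scaffold_lengths(ss)
  ends <- rbind(
    data.frame(s = bundles$a, e = bundles$ea, t = bundles$b, te = bundles$eb,
               gap = bundles$gap),
    data.frame(s = bundles$b, e = bundles$eb, t = bundles$a, te = bundles$ea,
               gap = bundles$gap))
  ends <- ends[ends$s != ends$t, , drop = FALSE]
  cand <- list()
  for (g in split(ends, paste(ends$s, ends$e))) {
    g <- g[order(g$gap), , drop = FALSE]
    if (nrow(g) > 1L &&
        g$gap[2] < g$gap[1] + slen[g$t[1]] - slack) next # competing partner
    cand[[paste(g$s[1], g$e[1])]] <- g[1, ]
  }
  jb <- list()
  for (key in names(cand)) {
    x <- cand[[key]]
    back <- cand[[paste(x$t, x$te)]]
    if (is.null(back) || back$t != x$s || back$te != x$e) next
    if (x$s < x$t || (x$s == x$t && x$e <= x$te))
      jb[[length(jb) + 1L]] <- data.frame(a = x$s, ea = x$e, b = x$t,
                                          eb = x$te, gap = x$gap)
  }
  jb <- if (length(jb)) do.call(rbind, jb) else NULL
  if (is.null(jb)) return(list(ss = ss, n_joined = 0L))
  jmap <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(jb))) {
    assign(paste(jb$a[i], jb$ea[i]), c(jb$b[i], jb$eb[i], jb$gap[i]),
           envir = jmap)
    assign(paste(jb$b[i], jb$eb[i]), c(jb$a[i], jb$ea[i], jb$gap[i]),
           envir = jmap)
  }
  joined <- function(s, e) exists(paste(s, e), envir = jmap)
  visited <- logical(n)
  merged <- list()
  for (s in seq_len(n)) {
    if (visited[s]) next
    outer <- if (!joined(s, 0L) && joined(s, 1L)) 0L
      else if (!joined(s, 1L) && joined(s, 0L)) 1L
      else next
    # walk the chain, merging members
    cur <- s; inner <- 1L - outer
    mem <- orient_members(ss$scaffolds[[s]], end_right = inner)
    visited[s] <- TRUE
    repeat {
      key <- paste(cur, inner)
      if (!exists(key, envir = jmap)) break
      nxt <- get(key, envir = jmap)
      s2 <- nxt[1]; e2 <- nxt[2]; gap <- nxt[3]
      if (visited[s2]) break
      mem <- join_members(mem, gap,
                          orient_members(ss$scaffolds[[s2]],
                                         end_right = 1L - e2))
      visited[s2] <- TRUE
      cur <- s2; inner <- 1L - e2
    }
    merged[[length(merged) + 1L]] <- mem
  }
  n_chained <- sum(visited)
  keep <- which(!visited)
  ss2 <- new_scaffold_set(ss$contigs, c(ss$scaffolds[keep], merged))
  list(ss = ss2, n_joined = n_chained - length(merged))
}

#' Scaffold contigs with untangling
#'
#' Iterates bundle construction, scaffold-level cross untangling and
#' unambiguous end joining until no change (at most `rounds` rounds).
#'
#' @param ss a `scaffold_set` (from [scaffold_init()]).
#' @param links contig-level link evidence.
#' @param c_hetero heterozygous depth estimate.
#' @param min_link,short_len,anchored_contigs see
#'   [build_scaffold_graph()].
#' @param r_upper,ratio evidence thresholds.
#' @param rounds iteration cap.
#' @param bctab optional contig-level barcode table.
#' @return list: `ss`, `log` (untangle decisions), counters.
#' @export
scaffold_phase <- function(ss, links, c_hetero = NA_real_, min_link = 2L,
                           short_len = 0L, anchored_contigs = integer(0),
                           r_upper = 1.75, ratio = 4, rounds = 5L,
                           bctab = NULL) {
  logs <- list()
  n_unt <- 0L; n_join <- 0L
  for (round in seq_len(rounds)) {
    sg <- build_scaffold_graph(ss, links, min_link, short_len,
                               anchored_contigs)
    u <- untangle_scaffold(sg, c_hetero, r_upper, ratio, bctab)
    if (!is.null(u$log)) logs[[length(logs) + 1L]] <- cbind(round = round,
                                                            u$log)
    changed <- u$n_untangled > 0L
    ss <- u$ss
    sg <- build_scaffold_graph(ss, links, min_link, short_len,
                               anchored_contigs)
    j <- join_unambiguous(ss, sg$bundles)
    ss <- j$ss
    changed <- changed || j$n_joined > 0L
    n_unt <- n_unt + u$n_untangled
    n_join <- n_join + j$n_joined
    if (!changed) break
  }
  list(ss = ss, log = if (length(logs)) do.call(rbind, logs) else NULL,
       n_untangled = n_unt, n_joined = n_join)
}
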